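# Readers and writers for the plain-text gait interchange formats (TRC
# marker trajectories, MOT/STO force-plate and result series), stance
# detection, and the trial container. Everything crossing module boundaries
# is SI (metres, newtons, seconds); marker files in millimetres are
# converted on read.

#' Marker trajectory set
#'
#' @param data frames x markers x 3 numeric array (metres)
#' @param labels marker names (length = dim 2)
#' @param rate sampling rate (Hz)
#' @param time optional time vector (s); defaults to (0:(n-1))/rate
#' @param visible optional frames x markers logical visibility mask
#' @return object of class `marker_trajectories`
#' @export
marker_trajectories <- function(data, labels, rate, time = NULL, visible = NULL) {
  if (rate <= 0) stop("sampling rate must be positive")
  if (length(dim(data)) != 3 || dim(data)[3] != 3)
    stop("marker data must be a frames x markers x 3 array")
  if (dim(data)[2] != length(labels))
    stop("number of labels (", length(labels), ") does not match data (",
         dim(data)[2], " markers)")
  n <- dim(data)[1]
  time <- time %||% ((seq_len(n) - 1) / rate)
  visible <- visible %||% apply(!is.na(data[, , 1, drop = FALSE]), c(1, 2), all)
  dimnames(data)[[2]] <- labels
  structure(list(rate = rate, frames = n, labels = labels, data = data,
                 time = time, visible = matrix(visible, n, length(labels))),
            class = "marker_trajectories")
}

#' @export
print.marker_trajectories <- function(x, ...) {
  cat(sprintf("<marker_trajectories> %d frames at %g Hz, %d markers (%.1f%% visible)\n",
              x$frames, x$rate, length(x$labels), 100 * mean(x$visible)))
  invisible(x)
}

#' Read a TRC marker file
#'
#' Parses the standard tab-separated TRC layout (header with DataRate,
#' NumFrames, NumMarkers, Units; two label rows; Frame#/Time plus X/Y/Z
#' triplets). Coordinates are converted to metres; missing samples become
#' NA and are masked.
#'
#' @param path file path
#' @return a `marker_trajectories`
#' @export
read_trc <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6) stop("malformed TRC file (too short): ", path)
  keys <- strsplit(lines[2], "\t")[[1]]
  vals <- strsplit(lines[3], "\t")[[1]]
  hdr <- stats::setNames(as.list(vals), keys)
  need <- c("DataRate", "NumFrames", "NumMarkers", "Units")
  if (!all(need %in% names(hdr)))
    stop("malformed TRC header, missing: ",
         paste(setdiff(need, names(hdr)), collapse = ", "))
  rate <- as.numeric(hdr$DataRate)
  nframes <- as.integer(hdr$NumFrames)
  nmark <- as.integer(hdr$NumMarkers)
  scale <- switch(hdr$Units, mm = 1e-3, m = 1,
                  stop("unknown TRC unit token: ", hdr$Units))
  labels <- strsplit(lines[4], "\t")[[1]]
  labels <- labels[labels != ""][-(1:2)]   # drop Frame#, Time
  if (length(labels) != nmark)
    stop("TRC header NumMarkers (", nmark, ") does not match label row (",
         length(labels), ")")
  body <- lines[-(1:5)]
  body <- body[nzchar(trimws(body))]
  rows <- strsplit(body, "\t")
  ncol_expected <- 2 + 3 * nmark
  mat <- t(vapply(rows, function(r) {
    r <- r[seq_len(ncol_expected)]
    suppressWarnings(as.numeric(r))
  }, numeric(ncol_expected)))
  if (nrow(mat) != nframes)
    stop("TRC header NumFrames (", nframes, ") does not match data rows (",
         nrow(mat), ")")
  time <- mat[, 2]
  xyz <- array(NA_real_, c(nframes, nmark, 3))
  for (m in seq_len(nmark)) xyz[, m, ] <- mat[, 2 + (m - 1) * 3 + 1:3] * scale
  marker_trajectories(xyz, labels, rate, time)
}

#' Write a TRC marker file
#' @param x a `marker_trajectories`
#' @param path output path
#' @param units "mm" (default, conventional) or "m"
#' @export
write_trc <- function(x, path, units = "mm") {
  scale <- switch(units, mm = 1000, m = 1, stop("unknown unit token: ", units))
  nmark <- length(x$labels)
  hdr1 <- sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path))
  hdr2 <- "DataRate\tCameraRate\tNumFrames\tNumMarkers\tUnits\tOrigDataRate\tOrigDataStartFrame\tOrigNumFrames"
  hdr3 <- sprintf("%g\t%g\t%d\t%d\t%s\t%g\t1\t%d", x$rate, x$rate, x$frames,
                  nmark, units, x$rate, x$frames)
  lab <- paste(c("Frame#", "Time",
                 as.vector(rbind(x$labels, "", ""))), collapse = "\t")
  sub <- paste(c("", "", as.vector(vapply(seq_len(nmark), function(i)
    paste0(c("X", "Y", "Z"), i), character(3)))), collapse = "\t")
  rows <- vapply(seq_len(x$frames), function(f) {
    vals <- as.vector(t(x$data[f, , ])) * scale
    paste(c(f, format(x$time[f], digits = 12),
            format(vals, digits = 12, trim = TRUE)), collapse = "\t")
  }, character(1))
  writeLines(c(hdr1, hdr2, hdr3, lab, sub, rows), path)
  invisible(path)
}

#' Force-plate series
#'
#' @param time time vector (s)
#' @param force n x 3 ground reaction force (N, lab/model frame, Y up)
#' @param cop n x 3 centre of pressure (m); masked to NA where the vertical
#'   force is at or below the contact threshold
#' @param free_moment n x 3 free moment (N m)
#' @param rate sampling rate (Hz)
#' @param contact_threshold vertical-force threshold (N) below which the COP
#'   is undefined
#' @return object of class `forceplate_series`
#' @export
forceplate_series <- function(time, force, cop, free_moment = NULL, rate = NULL,
                              contact_threshold = 20) {
  n <- length(time)
  force <- rbind(force); cop <- rbind(cop)
  free_moment <- if (is.null(free_moment)) matrix(0, n, 3) else rbind(free_moment)
  stopifnot(nrow(force) == n, nrow(cop) == n, nrow(free_moment) == n)
  rate <- rate %||% (1 / stats::median(diff(time)))
  if (rate <= 0) stop("force-plate rate must be positive")
  off <- force[, 2] <= contact_threshold
  if (any(off & apply(is.finite(cop), 1, all) & rowSums(abs(cop)) > 0)) {
    warning("COP defined while vertical force is below the contact threshold; masking")
  }
  cop[off, ] <- NA_real_
  structure(list(rate = rate, time = time, force = force, cop = cop,
                 free_moment = free_moment, contact_threshold = contact_threshold),
            class = "forceplate_series")
}

#' @export
print.forceplate_series <- function(x, ...) {
  cat(sprintf("<forceplate_series> %d frames at %g Hz, peak vertical force %.1f N\n",
              length(x$time), x$rate, max(x$force[, 2])))
  invisible(x)
}

#' Read ground reaction data from a MOT/STO file
#'
#' Requires column triplets `ground_force_v{x,y,z}`, `ground_force_p{x,y,z}`
#' and `ground_torque_{x,y,z}` (the conventional naming), plus `time`.
#'
#' @param path file path
#' @param contact_threshold vertical-force threshold (N)
#' @return a `forceplate_series`
#' @export
read_grf_mot <- function(path) {
  tab <- read_sto_table(path)
  pick <- function(stem) {
    cols <- paste0(stem, c("x", "y", "z"))
    if (!all(cols %in% names(tab)))
      stop("MOT file missing column triplet ", stem, "{x,y,z}: ", path)
    m <- as.matrix(tab[cols])
    dimnames(m) <- NULL
    m
  }
  forceplate_series(tab$time, pick("ground_force_v"), pick("ground_force_p"),
                    pick("ground_torque_"))
}

read_sto_table <- function(path) {
  lines <- readLines(path)
  end <- match(TRUE, trimws(lines) == "endheader")
  if (is.na(end)) stop("malformed MOT/STO file (no endheader): ", path)
  tab <- utils::read.table(text = lines[-(1:end)], header = TRUE, sep = "\t",
                           check.names = FALSE)
  if (!("time" %in% names(tab))) stop("MOT/STO file has no time column: ", path)
  tab
}

#' Write a time-series table as STO
#'
#' @param tab data.frame whose first column is `time`
#' @param path output path
#' @param name header name
#' @export
write_sto <- function(tab, path, name = "series") {
  stopifnot(names(tab)[1] == "time")
  hdr <- c(name, "version=1", sprintf("nRows=%d", nrow(tab)),
           sprintf("nColumns=%d", ncol(tab)), "inDegrees=no", "endheader")
  body <- apply(tab, 1, function(r) paste(format(r, digits = 12, trim = TRUE),
                                          collapse = "\t"))
  writeLines(c(hdr, paste(names(tab), collapse = "\t"), body), path)
  invisible(path)
}

#' Resample a force-plate series (linear interpolation)
#'
#' @param grf a `forceplate_series`
#' @param time target time vector (s)
#' @return resampled `forceplate_series`
#' @export
resample_grf <- function(grf, time) {
  interp <- function(M) {
    out <- vapply(1:3, function(j) {
      y <- M[, j]
      ok <- is.finite(y)
      if (sum(ok) < 2) return(rep(NA_real_, length(time)))
      stats::approx(grf$time[ok], y[ok], xout = time, rule = 2)$y
    }, numeric(length(time)))
    matrix(out, length(time), 3)
  }
  force <- interp(grf$force)
  cop <- interp(grf$cop)
  cop[force[, 2] <= grf$contact_threshold, ] <- NA_real_
  forceplate_series(time, force, cop, interp(grf$free_moment),
                    rate = 1 / stats::median(diff(time)),
                    contact_threshold = grf$contact_threshold)
}

#' Detect the stance window from the vertical ground reaction force
#'
#' Foot-strike is the first and foot-off the last sample of the longest
#' run of frames whose vertical force exceeds the threshold (the
#' longest-run rule ignores brief noise spikes outside true contact).
#'
#' @param grf a `forceplate_series`
#' @param threshold force threshold (N); 20 N is a conventional
#'   force-plate noise floor
#' @return list with `foot_strike`, `foot_off` (s) and the frame indices
#' @export
detect_stance <- function(grf, threshold = 20) {
  above <- grf$force[, 2] > threshold
  if (!any(above)) stop("no samples above the stance threshold (", threshold, " N)")
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i0 <- starts[best]; i1 <- ends[best]
  list(foot_strike = grf$time[i0], foot_off = grf$time[i1],
       frames = c(i0, i1))
}

#' Assemble a gait trial
#'
#' @param markers a `marker_trajectories`
#' @param grf a `forceplate_series` or NULL (static trials)
#' @param events list with `foot_strike`, `foot_off` (s); detected from the
#'   GRF when omitted for walking trials
#' @param kind "static" or "walking"
#' @return object of class `gait_trial`
#' @export
gait_trial <- function(markers, grf = NULL, events = NULL, kind = c("walking", "static")) {
  kind <- match.arg(kind)
  if (kind == "walking") {
    if (is.null(grf)) stop("walking trials need force-plate data")
    if (is.null(events)) events <- detect_stance(grf, grf$contact_threshold)
    dur <- range(markers$time)
    if (events$foot_strike >= events$foot_off)
      stop("stance window is empty (foot-strike at or after foot-off)")
    if (events$foot_strike < dur[1] - 1e-9 || events$foot_off > dur[2] + 1e-9)
      stop("stance events fall outside the trial duration")
  }
  structure(list(markers = markers, grf = grf, events = events, kind = kind),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("<gait_trial> %s, %d frames at %g Hz\n", x$kind,
              x$markers$frames, x$markers$rate))
  if (!is.null(x$events))
    cat(sprintf("  stance %.3f - %.3f s\n", x$events$foot_strike, x$events$foot_off))
  invisible(x)
}
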