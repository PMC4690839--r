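# Sensitivity protocols: one-at-a-time 5-mm perturbation of the muscle
# points either side of the ankle (in the hindfoot coordinate frame), the
# one- vs two-segment GRF assignment comparison, and the image-based vs
# marker-based ankle frame comparison.

#' Specify a muscle-point perturbation
#'
#' A perturbation displaces one path point of one or more muscle paths
#' (paths sharing an anatomical structure, e.g. the triceps surae sharing
#' the Achilles insertion, move together) by a signed magnitude along one
#' axis of the hindfoot coordinate frame.
#'
#' @param structure label for reporting (e.g. "achilles")
#' @param muscles muscle path name(s)
#' @param point point index per muscle (recycled), 1 = origin, last =
#'   insertion
#' @param axis "x", "y" or "z" (hindfoot frame: anterior, vertical, lateral)
#' @param magnitude signed displacement (m), |magnitude| <= 0.02
#' @return object of class `perturbation_spec`
#' @export
perturbation_spec <- function(structure, muscles, point, axis = c("x", "y", "z"),
                              magnitude = 0.005) {
  axis <- match.arg(axis)
  if (abs(magnitude) > 0.02)
    stop("perturbation magnitude beyond the 20 mm sanity bound")
  structure(list(structure = structure, muscles = muscles,
                 point = rep_len(point, length(muscles)), axis = axis,
                 magnitude = magnitude),
            class = "perturbation_spec")
}

#' Apply a muscle-point perturbation to a model
#'
#' Returns a copy of the model with the specified point(s) displaced by the
#' magnitude along the chosen hindfoot-frame axis, expressed back into the
#' owning segment's frame (evaluated at the reference pose). Everything
#' else is identical.
#'
#' @param model a `msk_model`
#' @param spec a `perturbation_spec`
#' @return perturbed `msk_model`
#' @export
perturb_model <- function(model, spec) {
  ax <- match(spec$axis, c("x", "y", "z"))
  ref <- forward_kinematics(model, kinematic_state(model))
  disp_world <- ref$hindfoot[1:3, ax] * spec$magnitude
  for (i in seq_along(spec$muscles)) {
    mn <- spec$muscles[i]
    m <- model$muscles[[mn]]
    if (is.null(m)) stop("unknown muscle: ", mn)
    k <- spec$point[i]
    if (k < 1 || k > length(m$points))
      stop("muscle '", mn, "' has no point ", k)
    seg <- m$points[[k]]$segment
    disp_local <- as.numeric(t(ref[[seg]][1:3, 1:3]) %*% disp_world)
    model$muscles[[mn]]$points[[k]]$p <- m$points[[k]]$p + disp_local
  }
  model
}

#' Default perturbation specs: the ten structures either side of the ankle
#'
#' The Achilles tendon insertion (the shared calcaneal insertion of the
#' medial and lateral gastrocnemius and soleus paths, moved together) and,
#' for tibialis anterior/posterior, peroneus longus/tertius/brevis and the
#' long flexors/extensors of the hallux and digits, the via point
#' immediately proximal to the ankle and the first point distal to it.
#' Each point is perturbed by `magnitude` along both directions of all
#' three hindfoot axes.
#'
#' @param model a `msk_model`
#' @param magnitude unsigned displacement (m), default 0.005
#' @param axes hindfoot axes to perturb along
#' @param signs directions
#' @return list of `perturbation_spec`
#' @export
default_ankle_perturbation_specs <- function(model, magnitude = 0.005,
                                             axes = c("x", "y", "z"),
                                             signs = c(1, -1)) {
  foot_segs <- joint_subtrees(model)$ankle
  structures <- list(list(structure = "achilles",
                          muscles = c("gastroc_med", "gastroc_lat", "soleus"),
                          points = c(3, 3, 2), label = "I"))
  for (mn in c("tib_ant", "tib_post", "per_long", "per_tert", "per_brev",
               "flex_hal_long", "flex_dig_long", "ext_hal_long", "ext_dig_long")) {
    pts <- model$muscles[[mn]]$points
    distal <- vapply(pts, function(p) p$segment %in% foot_segs, logical(1))
    k <- which(!distal[-length(distal)] & distal[-1])[1]
    for (kk in c(k, k + 1)) {
      lab <- if (kk == length(pts)) "I" else paste0("via", kk - 1)
      structures[[length(structures) + 1]] <-
        list(structure = mn, muscles = mn, points = kk, label = lab)
    }
  }
  specs <- list()
  for (st in structures)
    for (ax in axes)
      for (sg in signs)
        specs[[length(specs) + 1]] <-
          structure(list(structure = st$structure, muscles = st$muscles,
                         point = st$points, axis = ax, magnitude = sg * magnitude,
                         label = st$label),
                    class = "perturbation_spec")
  specs
}

#' Muscle-point sensitivity table
#'
#' For every perturbation spec: rerun the pipeline on the perturbed model
#' (reusing the baseline kinematics and inverse dynamics, which muscle
#' geometry does not affect), compute the per-frame percentage change of
#' the JRF magnitude over stance (perturbed minus original), resample
#' stance to 101 points, then take the mean across stance and across trials
#' (mean table) and the extreme value across stance, mean across trials
#' (maximum table). Signed values are retained. The report filter keeps
#' muscles whose |mean| reaches `filter_pct` in at least one perturbation.
#'
#' @param model an assembled `msk_model`
#' @param trials list of walking `gait_trial`s
#' @param specs list of `perturbation_spec` (default
#'   [default_ankle_perturbation_specs()])
#' @param config a [pipeline_config()]
#' @param filter_pct report inclusion threshold on |mean %change| (default 0.5)
#' @param baselines optional precomputed baseline `gait_result`s
#' @return object of class `sensitivity_table`: data.frame with one row per
#'   (structure, point, axis, sign): `mean_pct`, `max_pct`
#' @export
sensitivity_table <- function(model, trials, specs = NULL,
                              config = pipeline_config(), filter_pct = 0.5,
                              baselines = NULL) {
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  specs <- specs %||% default_ankle_perturbation_specs(model)
  baselines <- baselines %||% lapply(trials, function(tr)
    run_pipeline(model, tr, config))
  base_curves <- lapply(baselines, function(b) resample_stance(b$jrf))

  rows <- list()
  for (spec in specs) {
    cell <- tryCatch({
      pm <- perturb_model(model, spec)
      means <- maxs <- numeric(length(trials))
      for (ti in seq_along(trials)) {
        pert <- rerun_muscle_stages(baselines[[ti]], pm)
        pc <- 100 * (resample_stance(pert$jrf) - base_curves[[ti]]) / base_curves[[ti]]
        means[ti] <- mean(pc)
        maxs[ti] <- pc[which.max(abs(pc))]
      }
      list(mean_pct = mean(means), max_pct = mean(maxs), error = "")
    }, error = function(e) list(mean_pct = NA_real_, max_pct = NA_real_,
                                error = conditionMessage(e)))
    rows[[length(rows) + 1]] <- data.frame(
      structure = spec$structure, point = spec$label %||% as.character(spec$point[1]),
      axis = spec$axis, magnitude_mm = spec$magnitude * 1000,
      mean_pct = cell$mean_pct, max_pct = cell$max_pct, error = cell$error,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "filter_pct") <- filter_pct
  attr(out, "included") <- included_structures(out, filter_pct)
  class(out) <- c("sensitivity_table", "data.frame")
  out
}

included_structures <- function(tab, filter_pct) {
  agg <- tapply(abs(tab$mean_pct), tab$structure, max, na.rm = TRUE)
  names(agg)[agg >= filter_pct]
}

#' @export
print.sensitivity_table <- function(x, ...) {
  inc <- attr(x, "included")
  cat(sprintf("<sensitivity_table> %d perturbations; structures with |mean %%change| >= %.1f%%: %s\n",
              nrow(x), attr(x, "filter_pct"),
              if (length(inc)) paste(inc, collapse = ", ") else "(none)"))
  keep <- x$structure %in% inc
  if (any(keep)) print.data.frame(x[keep, setdiff(names(x), "error")],
                                  digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a sensitivity table and its caption-rule report as CSV/text
#' @param tab a `sensitivity_table`
#' @param path CSV output path (a `.txt` report is written alongside)
#' @export
write_sensitivity_csv <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  inc <- attr(tab, "included")
  rep_path <- sub("\\.csv$", "_report.txt", path)
  writeLines(c(
    sprintf("Structures with mean percentage change >= %.1f%% in at least one perturbation:",
            attr(tab, "filter_pct")),
    if (length(inc)) paste(" -", inc) else " (none)"), rep_path)
  invisible(path)
}

#' One- vs two-segment GRF assignment experiment
#'
#' Runs the pipeline under both GRF segment assumptions and returns the
#' per-stance-percent difference of the mean JRF magnitude across trials
#' (two-segment minus one-segment), with peak summary statistics.
#'
#' @param model an assembled `msk_model`
#' @param trials list of walking `gait_trial`s
#' @param config a [pipeline_config()] (its `mode` is overridden)
#' @return list with `stance_pct`, `jrf_1seg`, `jrf_2seg`, `difference`
#'   (%BW, mean across trials), `peak_difference_bw`, `peak_jrf_bw`,
#'   `pct_of_peak`
#' @export
segment_assumption_experiment <- function(model, trials, config = pipeline_config()) {
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  run_mode <- function(mode) {
    cfg <- config; cfg$mode <- mode
    curves <- vapply(trials, function(tr)
      resample_stance(run_pipeline(model, tr, cfg)$jrf), numeric(101))
    rowMeans(matrix(curves, 101))
  }
  one <- run_mode("1SEG")
  two <- run_mode("2SEG")
  diff <- two - one
  peak_diff <- diff[which.max(abs(diff))]
  peak <- max(two)
  list(stance_pct = 0:100, jrf_1seg = one, jrf_2seg = two, difference = diff,
       peak_difference_bw = peak_diff / 100, peak_jrf_bw = peak / 100,
       pct_of_peak = 100 * abs(peak_diff) / peak)
}

#' Ankle frame definition experiment (image-based vs marker-based)
#'
#' Runs the pipeline with the cylinder-based ankle frame and with the
#' marker-based frame, and returns the JRF difference series together with
#' the scalar frame difference. Runs that are infeasible without reserve
#' actuators are rerun with reserves enabled and flagged.
#'
#' @param model an assembled `msk_model`
#' @param trials list of walking `gait_trial`s
#' @param config a [pipeline_config()] (its `axes` is overridden;
#'   `reserves = "auto"` is used so infeasible runs recover)
#' @return list with the two mean JRF curves, `difference` (%BW),
#'   `frame_difference` (angle deg, offset mm), `reserves_used` per mode
#' @export
axes_experiment <- function(model, trials, config = pipeline_config()) {
  if (inherits(trials, "gait_trial")) trials <- list(trials)
  config$reserves <- "auto"
  run_axes <- function(axes) {
    cfg <- config; cfg$axes <- axes
    res <- lapply(trials, function(tr) run_pipeline(model, tr, cfg))
    list(curve = rowMeans(matrix(vapply(res, function(r)
      resample_stance(r$jrf), numeric(101)), 101)),
      reserves = any(vapply(res, function(r) r$muscle_state$reserves_used,
                            logical(1))))
  }
  mr <- run_axes("MR")
  cga <- run_axes("CGA")

  ref <- forward_kinematics(model, kinematic_state(model))
  fr_mr <- anatomical_frame(tf_apply(ref$shank, model$joints$ankle$location),
                            tf_rot(ref$shank) %*% model$joints$ankle$orientation)
  cga_model <- set_ankle_axes(model, "CGA")
  fr_cga <- cga_model$ankle_cga_frame
  list(stance_pct = 0:100, jrf_mr = mr$curve, jrf_cga = cga$curve,
       difference = cga$curve - mr$curve,
       frame_difference = frame_difference(fr_mr, fr_cga),
       reserves_used = c(MR = mr$reserves, CGA = cga$reserves))
}
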