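test_that("muscle-point perturbations are local, exact and involutive", {
  m <- get_model()
  spec0 <- perturbation_spec("achilles", c("gastroc_med", "gastroc_lat", "soleus"),
                             c(3, 3, 2), "x", 0)
  expect_identical(perturb_model(m, spec0)$muscles, m$muscles)

  spec <- perturbation_spec("achilles", "soleus", 2, "x", 0.005)
  mp <- perturb_model(m, spec)
  # only the named point moved, by exactly 5 mm
  moved <- mp$muscles$soleus$points[[2]]$p - m$muscles$soleus$points[[2]]$p
  expect_equal(sqrt(sum(moved^2)), 0.005, tolerance = 1e-12)
  expect_identical(mp$muscles$soleus$points[[1]], m$muscles$soleus$points[[1]])
  others <- setdiff(names(m$muscles), "soleus")
  expect_identical(mp$muscles[others], m$muscles[others])

  # +5 mm then -5 mm restores the original point
  back <- perturb_model(mp, perturbation_spec("achilles", "soleus", 2, "x", -0.005))
  expect_lt(max(abs(back$muscles$soleus$points[[2]]$p -
                    m$muscles$soleus$points[[2]]$p)), 1e-15)

  expect_error(perturb_model(m, perturbation_spec("x", "nope", 1, "x", 0.005)),
               "unknown muscle")
  expect_error(perturbation_spec("x", "soleus", 1, "x", 0.05), "sanity bound")
})

test_that("zero-magnitude perturbations yield an exactly zero table", {
  model <- get_model()
  specs <- lapply(c("x", "y", "z"), function(ax)
    perturbation_spec("achilles", c("gastroc_med", "gastroc_lat", "soleus"),
                      c(3, 3, 2), ax, 0))
  tab <- sensitivity_table(model, list(get_walk()$trial), specs,
                           config = get_run_1seg()$config,
                           baselines = list(get_run_1seg()))
  expect_true(all(tab$mean_pct == 0))
  expect_true(all(tab$max_pct == 0))
  expect_length(attr(tab, "included"), 0)
})

test_that("the cached fast rerun equals a full pipeline rerun", {
  model <- get_model()
  spec <- perturbation_spec("achilles", c("gastroc_med", "gastroc_lat", "soleus"),
                            c(3, 3, 2), "x", 0.005)
  pm <- perturb_model(model, spec)
  fast <- mskfoot:::rerun_muscle_stages(get_run_1seg(), pm)
  full <- run_pipeline(pm, get_walk()$trial, get_run_1seg()$config)
  expect_equal(fast$jrf$mag_bw, full$jrf$mag_bw, tolerance = 1e-9)
  expect_equal(fast$muscle_state$activations, full$muscle_state$activations,
               tolerance = 1e-9)
})

test_that("sensitivity tables are deterministic", {
  model <- get_model()
  specs <- list(perturbation_spec("achilles", c("gastroc_med", "gastroc_lat", "soleus"),
                                  c(3, 3, 2), "x", 0.005),
                perturbation_spec("tib_ant", "tib_ant", 3, "y", -0.005))
  t1 <- sensitivity_table(model, list(get_walk()$trial), specs,
                          baselines = list(get_run_1seg()))
  t2 <- sensitivity_table(model, list(get_walk()$trial), specs,
                          baselines = list(get_run_1seg()))
  expect_identical(t1$mean_pct, t2$mean_pct)
  expect_identical(t1$max_pct, t2$max_pct)
})

test_that("perturbation response is not assumed proportional", {
  model <- get_model()
  s5 <- perturbation_spec("achilles", c("gastroc_med", "gastroc_lat", "soleus"),
                          c(3, 3, 2), "x", 0.005)
  s10 <- perturbation_spec("achilles", c("gastroc_med", "gastroc_lat", "soleus"),
                           c(3, 3, 2), "x", 0.010)
  tab <- sensitivity_table(model, list(get_walk()$trial), list(s5, s10),
                           baselines = list(get_run_1seg()))
  # both recomputed in full; no exact doubling is asserted or expected
  expect_true(all(is.finite(tab$mean_pct)))
  expect_false(isTRUE(all.equal(2 * tab$mean_pct[1], tab$mean_pct[2])))
})

test_that("the two-segment effect appears only after the crossing", {
  seg <- segment_assumption_experiment(get_model(), list(get_walk()$trial))
  cross_pct <- round(100 * get_walk()$truth$cop_cross_frac)
  before <- seg$difference[1:(cross_pct - 3)]
  expect_true(all(abs(before) < 1e-9))
  expect_gt(max(abs(seg$difference)), 1)   # a visible effect exists (%BW)
  # printed-summary arithmetic: a 1.3 BW difference at a 5.1 BW peak
  expect_equal(100 * 1.3 / 5.1, 25.5, tolerance = 0.01)
})

test_that("the axes experiment reports frames, differences and reserves", {
  ax <- fixture("axes_experiment", function()
    axes_experiment(get_model(), list(get_walk()$trial)))
  expect_equal(unname(ax$reserves_used["MR"]), FALSE)
  expect_equal(unname(ax$reserves_used["CGA"]), TRUE)
  expect_gt(ax$frame_difference$angle_deg, 5)
  expect_gt(ax$frame_difference$offset_mm, 5)
  expect_gt(max(abs(ax$difference)), 10)   # %BW
})

test_that("identical ankle frames give a zero axes difference", {
  # degenerate construction: malleolar markers placed exactly on the dome
  # axis endpoints, so the marker frame coincides with the cylinder frame
  cfg <- default_template_config()
  for (mk in list(list("RANK", c(0, -0.400, 0.045)),
                  list("RMMA", c(0, -0.400, -0.045)))) {
    i <- which(vapply(cfg$markers, `[[`, character(1), "name") == mk[[1]])
    cfg$markers[[i]]$p <- mk[[2]]
  }
  tmpl <- build_template(cfg)
  mcga <- set_ankle_axes(tmpl, "CGA")
  ref <- forward_kinematics(tmpl, kinematic_state(tmpl))
  fr_mr <- anatomical_frame(tf_apply(ref$shank, tmpl$joints$ankle$location),
                            tf_rot(ref$shank) %*% tmpl$joints$ankle$orientation)
  d <- frame_difference(fr_mr, mcga$ankle_cga_frame)
  expect_lt(d$angle_deg, 1e-9)
  expect_lt(d$offset_mm, 1e-9)
})
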