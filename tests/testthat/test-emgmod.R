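test_that("force-length and force-velocity curves match their definitions", {
  expect_equal(force_length(1, 0.6), 1)
  expect_equal(force_length(1.6, 0.6), exp(-1))
  d <- runif(20, 0, 0.5)
  expect_equal(force_length(1 + d, 0.4), force_length(1 - d, 0.4))

  expect_equal(force_velocity(0, 0.5, 0.8), 1)
  expect_equal(force_velocity(1, 0.5, 0.8), 1.5)
  expect_equal(force_velocity(-1, 0.5, 1), 0)
  # saturation beyond the reference velocity
  expect_equal(force_velocity(3, 0.5, 0.8), 1.5)
  expect_equal(force_velocity(-3, 0.5, 0.6), 0.4)
})

test_that("parameter vector construction enforces bounds", {
  expect_error(muscle_model_params(5, 1.1, 10, 0.3, 0.5, 0.6, 0.6),
               "gain")
  expect_error(muscle_model_params(60, 1.1, 10, 0.3, 1.5, 0.6, 0.6),
               "con_scale")
  p <- default_true_params()
  expect_length(unclass(p), 7L)
})

test_that("passive moment is slack upright and engages at the analytic angle", {
  geo <- fixture_geometry()
  p <- default_true_params()
  expect_equal(passive_moment(c(0, 0.1, 0.2), p, geo), c(0, 0, 0))
  # slack-to-taut transition: lambda = lambda0 at
  # theta = theta_opt + (lambda0 - 1) / strain
  ext <- geo[geo$role == "extensor", ]
  theta_on <- p[["optimum_angle"]] +
    (p[["passive_offset"]] - 1) / max(ext$strain_per_rad)
  expect_equal(passive_moment(theta_on - 1e-3, p, geo), 0)
  expect_gt(passive_moment(theta_on + 1e-2, p, geo), 0)
  ramp <- seq(theta_on, 1.2, length.out = 50)
  expect_true(all(diff(passive_moment(ramp, p, geo)) > 0))
})

test_that("active moment is linear in gain and matches hand computation", {
  geo <- fixture_geometry()
  p <- default_true_params()
  n <- 10
  emg0 <- matrix(0, n, 12, dimnames = list(NULL, emg_channel_names()))
  th <- rep(p[["optimum_angle"]], n)
  expect_equal(active_moment(emg0, th, numeric(n), p, geo), numeric(n))

  # single extensor element, isometric at optimum length
  emg1 <- emg0
  emg1[, "LTpl_L"] <- 0.5
  row <- geo[geo$name == "LTpl_L", ]
  m <- active_moment(emg1, th, numeric(n), p, geo)
  expect_equal(m, rep(p[["gain"]] * 0.5 * row$pcsa_cm2 * row$moment_arm_m,
                      n))
  p2 <- p; p2[["gain"]] <- 2 * p[["gain"]]
  expect_equal(active_moment(emg1, th, numeric(n), p2, geo), 2 * m)
  expect_error(active_moment(emg1[, 1:10], th, numeric(n), p, geo),
               "12 channels")
})

test_that("prediction decomposes into active plus passive exactly", {
  tr <- fixture_trial(15, "free", "normal")
  geo <- fixture_geometry()
  p <- fixture_truth_clean()$params_true
  ks <- trial_kinematic_signals(tr)
  act <- active_moment(tr$emg, ks$lumbar_flexion, ks$lumbar_velocity, p,
                       geo)
  pas <- passive_moment(ks$lumbar_flexion, p, geo)
  pred <- predict_human_moment(tr, p, geo)
  expect_identical(pred$values_nm, act + pas)
  # noise-free round trip against the generator truth
  ref <- reference_human_moment(tr, fixture_subject())
  expect_lt(max(abs(pred$values_nm - ref$values_nm)), 1e-6)
})

test_that("the analytic objective gradient matches finite differences", {
  bat <- fixture_cal_battery()
  data <- exomoment:::calibration_data(bat$trials[1:3], bat$refs[1:3])
  ob <- exomoment:::emgmod_obj_factory(data, fixture_geometry(), 2L)
  for (p0 in list(c(60, 1.1, 10, 0.3, 0.5, 0.6, 0.6),
                  c(30, 1.0, 25, 0.6, 0.9, 0.3, 0.35))) {
    gnum <- vapply(1:7, function(i) {
      h <- 1e-6 * max(abs(p0[i]), 1)
      pp <- p0; pm <- p0
      pp[i] <- pp[i] + h; pm[i] <- pm[i] - h
      (ob$fn(pp) - ob$fn(pm)) / (2 * h)
    }, numeric(1))
    expect_equal(ob$gr(p0), gnum, tolerance = 1e-5)
  }
})

test_that("calibration recovers the generating parameters without noise", {
  bat <- fixture_cal_battery()
  geo <- fixture_geometry()
  fit <- calibrate_emgmod(bat$trials, bat$refs, geo,
                          options = list(n_starts = 3L, maxit = 150L,
                                         stride = 2L))
  pt <- unclass(fixture_truth_clean()$params_true)
  est <- unclass(fit$params)
  expect_lt(abs(est[["gain"]] - pt[["gain"]]) / pt[["gain"]], 0.05)
  expect_lt(abs(est[["optimum_angle"]] - pt[["optimum_angle"]]) /
              pt[["optimum_angle"]], 0.05)
  b <- param_bounds()
  expect_true(all(est >= b["lower", ] & est <= b["upper", ]))
  # the truth attains a (numerically) zero objective, and the optimizer
  # must do at least as well
  data <- exomoment:::calibration_data(bat$trials, bat$refs)
  j_truth <- exomoment:::emgmod_objective(unclass(pt), data, geo)
  j_fit <- exomoment:::emgmod_objective(unclass(fit$params), data, geo)
  expect_lt(j_truth / length(bat$trials), 1e-6)
  expect_lte(j_fit, j_truth + 1e-4)
})

test_that("data without passive contribution yields none when calibrated", {
  # generate with the passive curve slack everywhere (offset at its upper
  # bound): the fitted model must not invent a passive moment
  subj <- fixture_subject()
  geo <- fixture_geometry()
  truth <- ground_truth(
    muscle_model_params(60, 1.3, 10, 0.3, 0.5, 0.55, 0.6),
    cocontraction_level = 0, emg_noise_sd = 0, kin_noise_sd = 0)
  cal <- calibration_conditions()[c(1, 4, 11), ]
  trials <- list(); refs <- list()
  for (k in seq_len(nrow(cal))) {
    cond <- trial_condition(cal$mass_kg[k], cal$technique[k],
                            cal$velocity[k], "calibration_lift")
    trials[[k]] <- generate_trial(cond, subj, truth, trial_id = "t",
                                  seed = k, geometry = geo)
    refs[[k]] <- human_moment(bottom_up_moment(trials[[k]], subj),
                              trials[[k]]$exo_torque_nm)
  }
  fit <- calibrate_emgmod(trials, refs, geo,
                          options = list(n_starts = 3L, maxit = 150L,
                                         stride = 2L))
  theta_max <- max(vapply(trials, function(tr)
    max(trial_kinematic_signals(tr)$lumbar_flexion), 0))
  expect_lt(max(passive_moment(seq(0, theta_max, length.out = 50),
                               fit$params, geo)), 2)
})

test_that("one noise-free trial calibrates nearly as well as the full set", {
  bat <- fixture_cal_battery()
  geo <- fixture_geometry()
  subj <- fixture_subject()
  opts <- list(n_starts = 3L, maxit = 150L, stride = 2L)
  fit_full <- calibrate_emgmod(bat$trials, bat$refs, geo, opts)
  k <- match("free_7p5_normal", calibration_conditions()$condition_id)
  fit_one <- calibrate_emgmod(bat$trials[k], bat$refs[k], geo,
                              list(n_starts = 5L, maxit = 250L,
                                   stride = 1L))
  test_tr <- fixture_trial(7.5, "free", "normal", "exo_lift",
                           "inclination")
  ref <- reference_human_moment(test_tr, subj)$values_nm
  rmse_for <- function(fit)
    rms(predict_human_moment(test_tr, fit$params, geo)$values_nm - ref)
  expect_lt(rmse_for(fit_one), 1.1 * rmse_for(fit_full) + 0.1)
})

test_that("calibration errors are informative", {
  bat <- fixture_cal_battery()
  expect_error(calibrate_emgmod(bat$trials[1], list(1:5),
                                fixture_geometry()),
               "overlap")
})
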