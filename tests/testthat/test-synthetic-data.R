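test_that("generated postures match the lifting techniques", {
  stoop <- generate_kinematics(
    trial_condition(15, "stoop", "slow", "calibration_lift"))$angles
  knee_flex <- stoop$alpha_shank - stoop$alpha_thigh
  trunk_flex <- stoop$alpha_trunk - stoop$alpha_thigh
  expect_lt(max(knee_flex), 10 * pi / 180)
  expect_lt(max(knee_flex), max(trunk_flex))
  squat <- generate_kinematics(
    trial_condition(15, "squat", "slow", "calibration_lift"))$angles
  expect_lt(max(squat$alpha_trunk), 35 * pi / 180)
  expect_gt(max(squat$alpha_shank - squat$alpha_thigh), 100 * pi / 180)
})

test_that("faster velocity classes reach higher peak trunk velocity", {
  peak_vel <- function(vel) {
    ang <- generate_kinematics(
      trial_condition(15, "free", vel, "calibration_lift"))$angles
    max(abs(numeric_derivatives(ang$alpha_trunk, 50)$velocity))
  }
  v <- vapply(c("very_slow", "normal", "fast"), peak_vel, numeric(1))
  expect_true(all(diff(v) > 0))
})

test_that("whole-body ground reaction obeys statics and impulse balance", {
  subj <- fixture_subject()
  tr0 <- make_static_trial(upright)
  expect_equal(tr0$grf$fz_n, rep(subj$body_mass_kg * 9.81, 120),
               tolerance = 1e-6 / 700)
  expect_equal(tr0$grf$fx_n, numeric(120), tolerance = 1e-9)
  tr15 <- make_static_trial(upright, mass_kg = 15)
  expect_equal(tr15$grf$fz_n,
               rep((subj$body_mass_kg + 15) * 9.81, 120),
               tolerance = 1e-9)
  # dynamic lift returning to rest: mean vertical force = mean weight
  lift <- fixture_trial(15, "free", "normal")
  expect_equal(mean(lift$grf$fz_n), (subj$body_mass_kg + 15) * 9.81,
               tolerance = 0.005 * (subj$body_mass_kg + 15) * 9.81)
})

test_that("static reference moments equal hand-computed statics", {
  subj <- fixture_subject()
  seg <- subj$segments
  g <- function(nm, col) seg[[col]][seg$segment == nm]
  tr0 <- make_static_trial(upright)
  m0 <- top_down_moment(tr0, subj)
  expect_lt(max(abs(m0$values_nm)), 1)

  # flexed stoop posture, 15 kg at the hands: sum of weight x lever
  x_knee <- g("shank", "length_m") * sin(0.08)
  x_hip <- x_knee
  x_l5 <- x_hip + g("pelvis", "length_m") * sin(0.75)
  x_sh <- x_l5 + g("trunk_head", "length_m") * sin(1.5)
  x_trcom <- x_l5 + g("trunk_head", "com_from_distal") *
    g("trunk_head", "length_m") * sin(1.5)
  m_hand <- 9.81 * (g("trunk_head", "mass_kg") * (x_trcom - x_l5) +
                      g("arms", "mass_kg") * (x_sh - x_l5) +
                      15 * (x_sh - x_l5))
  tr15 <- make_static_trial(stooped, mass_kg = 15)
  m15 <- top_down_moment(tr15, subj)
  mid <- 30:90
  expect_equal(mean(m15$values_nm[mid]), m_hand, tolerance = 1e-6)

  # adding 7.5 kg at fixed posture adds exactly 7.5*g*(hand lever)
  tr225 <- make_static_trial(stooped, mass_kg = 22.5)
  m225 <- top_down_moment(tr225, subj)
  expect_equal(mean(m225$values_nm[mid] - m15$values_nm[mid]),
               7.5 * 9.81 * (x_sh - x_l5), tolerance = 1e-6)
})

test_that("exoskeleton control laws produce the documented torques", {
  kin <- data.frame(trunk_inclination = c(0, 0.5, 1),
                    trunk_velocity = c(0, 0.2, 0),
                    trunk_acceleration = c(0, 0, 1))
  expect_equal(exo_torque(kin, "inclination"), c(0, 15, 30))
  expect_equal(exo_torque(kin, "dynamic"), c(0, 15, 31))
  expect_equal(exo_torque(kin, "velocity"), c(0, 16, 30))
  expect_equal(exo_torque(kin, "transparent"), c(0, 0, 0))
  expect_error(exo_torque(kin, "hybrid"))
})

test_that("inverting the muscle model reproduces the target moment", {
  geo <- fixture_geometry()
  truth <- fixture_truth_clean()
  tr <- fixture_trial(15, "stoop", "slow")
  ks <- trial_kinematic_signals(tr)
  kin <- data.frame(lumbar_flexion = ks$lumbar_flexion,
                    lumbar_velocity = ks$lumbar_velocity)
  target <- 80 * sin(seq(0, pi, length.out = nrow(kin)))
  eg <- emg_from_moment(target, kin, truth, geo)
  fwd <- active_moment(eg$emg, kin$lumbar_flexion, kin$lumbar_velocity,
                       truth$params_true, geo) +
    passive_moment(kin$lumbar_flexion, truth$params_true, geo)
  expect_lt(max(abs(fwd - target)), 1e-6)

  # doubling the required moment scales through the model inverse exactly
  eg2 <- emg_from_moment(2 * target, kin, truth, geo)
  fwd2 <- active_moment(eg2$emg, kin$lumbar_flexion, kin$lumbar_velocity,
                        truth$params_true, geo) +
    passive_moment(kin$lumbar_flexion, truth$params_true, geo)
  expect_lt(max(abs(fwd2 - 2 * target)), 1e-6)

  # co-contraction raises flexor activity but leaves the net moment alone
  truth_cc <- ground_truth(truth$params_true, cocontraction_level = 0.05,
                           emg_noise_sd = 0, kin_noise_sd = 0)
  eg_cc <- emg_from_moment(target, kin, truth_cc, geo)
  fwd_cc <- active_moment(eg_cc$emg, kin$lumbar_flexion,
                          kin$lumbar_velocity, truth$params_true, geo) +
    passive_moment(kin$lumbar_flexion, truth$params_true, geo)
  expect_lt(max(abs(fwd_cc - target)), 1e-6)
  flex <- muscle_geometry()$role == "flexor"
  expect_gt(sum(eg_cc$emg[, flex]), sum(eg$emg[, flex]))
})

test_that("study generation is deterministic and correctly sized", {
  st <- fixture_small_study()
  man <- st$manifest
  expect_identical(sum(man$subject_id == "S01" &
                         man$task_group == "calibration_lift"), 28L)
  expect_identical(length(unique(man$condition_id[
    man$task_group == "calibration_lift"])), 14L)
  expect_setequal(unique(man$task_group[man$task_group !=
                                          "calibration_lift"]),
                  c("exo_lift", "stack_lift", "stack_carry", "shelf_lift",
                    "push_pull"))

  # identical seeds give byte-identical files; repetitions share the
  # condition but differ in their noise
  tid <- man$trial_id[1]
  st2 <- generate_study(1, seed = 42L, noise = TRUE)
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_trial(st$trials[[tid]], p1)
  write_trial(st2$trials[[tid]], p2)
  expect_identical(readLines(p1), readLines(p2))
  r1 <- man$trial_id[man$condition_id == "stoop_7p5_slow" &
                       man$subject_id == "S01"]
  expect_false(identical(st$trials[[r1[1]]]$emg, st$trials[[r1[2]]]$emg))
  expect_identical(st$trials[[r1[1]]]$condition,
                   st$trials[[r1[2]]]$condition)
})

test_that("peak reference moment grows with box mass", {
  subj <- fixture_subject()
  peak <- function(mass) {
    tr <- fixture_trial(mass, "stoop", "slow")
    max(reference_human_moment(tr, subj)$values_nm)
  }
  expect_gt(peak(15), peak(7.5))
})
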