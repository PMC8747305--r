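# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

fixture_subject <- function() memo("subject", subject_model(73.8, 1.82))

fixture_truth_clean <- function()
  memo("truth_clean",
       ground_truth(params_true = muscle_model_params(
         gain = 72, passive_offset = 1.08, passive_scale = 12,
         ecc_scale = 0.3, con_scale = 0.45, optimum_angle = 0.55,
         fl_width = 0.62),
         cocontraction_level = 0, emg_noise_sd = 0, kin_noise_sd = 0,
         seed = 7L))

fixture_geometry <- function()
  memo("geometry", muscle_geometry(fixture_subject()))

# One noise-free trial per named condition, cached.
fixture_trial <- function(mass_kg, technique, velocity,
                          task_group = "calibration_lift",
                          exo_strategy = "none") {
  key <- paste("trial", mass_kg, technique, velocity, task_group,
               exo_strategy, sep = "_")
  memo(key, {
    cond <- trial_condition(mass_kg, technique, velocity, task_group,
                            exo_strategy)
    generate_trial(cond, fixture_subject(), fixture_truth_clean(),
                   trial_id = key, seed = 11L,
                   geometry = fixture_geometry())
  })
}

# Noise-free Full calibration battery (one repetition) with ID references.
fixture_cal_battery <- function() {
  memo("cal_battery", {
    cal <- calibration_conditions()
    subj <- fixture_subject()
    trials <- list(); refs <- list()
    for (k in seq_len(nrow(cal))) {
      tr <- fixture_trial(cal$mass_kg[k], cal$technique[k],
                          cal$velocity[k])
      trials[[k]] <- tr
      refs[[k]] <- human_moment(bottom_up_moment(tr, subj),
                                tr$exo_torque_nm)
    }
    list(trials = trials, refs = refs)
  })
}

# Small noisy synthetic study (2 subjects), shared by pipeline tests.
fixture_small_study <- function()
  memo("small_study", generate_study(2, seed = 42L, noise = TRUE))

rms <- function(x) sqrt(mean(x^2))

# A static trial at a fixed posture, for statics checks.
make_static_trial <- function(posture, mass_kg = 0, n = 120,
                              hand_fx = 0) {
  subj <- fixture_subject()
  angles <- as.data.frame(lapply(posture, rep, n))
  km <- process_kinematics(angles, subj, 50, lowpass_hz = 5)
  hf <- data.frame(fx_n = rep(hand_fx, n), fz_n = numeric(n))
  grf <- whole_body_grf(km, subj, mass_kg, hf)
  cond <- trial_condition(mass_kg, "n/a", "n/a", "push_pull")
  new_trial("static", subj$subject_id, cond,
            seq(0, by = 0.02, length.out = n), angles,
            matrix(0, n, 12, dimnames = list(NULL, emg_channel_names())),
            grf, hand_force = hf)
}

upright <- c(alpha_shank = 0, alpha_thigh = 0, alpha_pelvis = 0,
             alpha_trunk = 0, alpha_arm = 0)
stooped <- c(alpha_shank = 0.08, alpha_thigh = 0, alpha_pelvis = 0.75,
             alpha_trunk = 1.5, alpha_arm = 0)

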