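# Synthetic study generator: planar lifting/handling trials with known
# ground-truth muscle parameters.  Kinematics are minimum-jerk keyframe
# tracks; the ground reaction is synthesized from the whole-body balance;
# EMG is produced by inverting the ground-truth muscle model (equal drive to
# all agonist elements, fixed antagonist co-contraction) plus multiplicative
# noise, so the calibration problem has a known recoverable optimum.

#' Minimum-jerk angle trajectory
#'
#' Quintic minimum-jerk interpolation from `theta0` to `theta1`: velocity
#' and acceleration are zero at both ends and the peak angular velocity is
#' `1.875 * (theta1 - theta0) / duration_s`.
#'
#' @param theta0,theta1 Start and end angles (rad).
#' @param duration_s Movement duration (s), > 0.
#' @param fs Sampling frequency (Hz).
#' @return Angle vector including both endpoints
#'   (`round(duration_s * fs) + 1` samples).
#' @export
minimum_jerk <- function(theta0, theta1, duration_s, fs = TRIAL_FS) {
  stopifnot(duration_s > 0)
  n <- round(duration_s * fs)
  tau <- seq(0, 1, length.out = n + 1L)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  theta0 + (theta1 - theta0) * s
}

#' Lift profile: durations and target postures
#'
#' Movement durations per velocity class (one direction of the lift) and
#' the flexed-posture keyframes per lifting technique, as absolute segment
#' angles.  Stoop reaches the box with trunk flexion and nearly extended
#' knees; squat with knee flexion and a nearly extended trunk; free is an
#' intermediate self-selected mix.  The defaults are configurable
#' conventions of the generator (the velocity classes are ordinal:
#' durations strictly decrease from very slow to fast).
#'
#' @param durations_s Named vector of per-phase durations for
#'   `very_slow`, `slow`, `normal`, `fast`.
#' @param hold_s Quiet hold at each keyframe (s).
#' @return List of class `"lift_profile"`.
#' @export
lift_profile <- function(durations_s = c(very_slow = 6, slow = 4,
                                         normal = 2.5, fast = 1.5),
                         hold_s = 0.2) {
  if (any(diff(durations_s[c("very_slow", "slow", "normal", "fast")]) >= 0))
    stop("durations must strictly decrease with velocity class")
  postures <- list(
    upright = c(alpha_shank = 0, alpha_thigh = 0, alpha_pelvis = 0,
                alpha_trunk = 0, alpha_arm = 0),
    stoop = c(alpha_shank = 0.08, alpha_thigh = 0, alpha_pelvis = 0.75,
              alpha_trunk = 1.50, alpha_arm = 0),
    squat = c(alpha_shank = 0.70, alpha_thigh = -1.22, alpha_pelvis = 0.38,
              alpha_trunk = 0.50, alpha_arm = 0),
    free = c(alpha_shank = 0.45, alpha_thigh = -0.55, alpha_pelvis = 0.55,
             alpha_trunk = 1.00, alpha_arm = 0))
  structure(list(durations_s = durations_s, hold_s = hold_s,
                 postures = postures),
            class = "lift_profile")
}

#' Ground truth of a synthetic subject
#'
#' The hidden physiology of a simulated subject: the true muscle-model
#' parameter vector, the antagonist co-contraction level, and the EMG and
#' kinematic noise magnitudes.
#'
#' @param params_true A `"muscle_model_params"` (defaults to
#'   [default_true_params()]).
#' @param cocontraction_level Baseline antagonist activation as a fraction
#'   of MVC, in \[0, 0.2\].
#' @param emg_noise_sd SD of the multiplicative log-normal EMG noise.
#' @param kin_noise_sd SD of the additive angle noise (rad).
#' @param seed Integer seed for the subject's noise streams.
#' @return List of class `"ground_truth"`.
#' @export
ground_truth <- function(params_true = default_true_params(),
                         cocontraction_level = 0.03, emg_noise_sd = 0.05,
                         kin_noise_sd = 0.005, seed = 1L) {
  stopifnot(emg_noise_sd >= 0, kin_noise_sd >= 0,
            cocontraction_level >= 0, cocontraction_level <= 0.2)
  structure(list(params_true = as_params(params_true),
                 cocontraction_level = cocontraction_level,
                 emg_noise_sd = emg_noise_sd, kin_noise_sd = kin_noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Default ground-truth muscle parameters
#'
#' @return A `"muscle_model_params"` used as the nominal hidden physiology.
#' @export
default_true_params <- function() {
  muscle_model_params(gain = 60, passive_offset = 1.10, passive_scale = 10,
                      ecc_scale = 0.3, con_scale = 0.5,
                      optimum_angle = 0.6, fl_width = 0.6)
}

# Assemble a multi-phase track: hold at keyframe 1, minimum-jerk to
# keyframe 2, hold, ... . keyframes: k x p matrix; durations: length k-1.
keyframe_track <- function(keyframes, durations, hold_s, fs = TRIAL_FS) {
  k <- nrow(keyframes)
  pieces <- list()
  nh <- max(1L, round(hold_s * fs))
  for (i in seq_len(k)) {
    pieces[[length(pieces) + 1L]] <-
      matrix(rep(keyframes[i, ], each = nh), nrow = nh)
    if (i < k) {
      mv <- vapply(seq_len(ncol(keyframes)), function(j)
        minimum_jerk(keyframes[i, j], keyframes[i + 1L, j], durations[i],
                     fs), numeric(round(durations[i] * fs) + 1L))
      pieces[[length(pieces) + 1L]] <- mv[-1L, , drop = FALSE]
    }
  }
  out <- do.call(rbind, pieces)
  colnames(out) <- colnames(keyframes)
  out
}

#' Generate the planar kinematics of one trial
#'
#' Builds the absolute segment-angle tracks (and any external hand-force
#' track) for a condition.  Lifts are a lower-then-lift cycle: quiet
#' upright hold, minimum-jerk descent to the technique's flexed posture,
#' hold, mirrored ascent, hold, with the box in the hands throughout.
#' Shelf lifts raise the load from hip level to shelf height through an arm
#' elevation track with a small trunk counter-motion; push/pull is a static
#' upright posture with a smoothly ramped constant horizontal hand force;
#' the stacking carry phase is an upright hold with the load and a small
#' trunk sway.
#'
#' @param condition A [trial_condition()].
#' @param profile A [lift_profile()].
#' @return List with `angles` (data frame of the five `alpha_*` columns)
#'   and `hand_force` (data frame `fx_n`, `fz_n`).
#' @export
generate_kinematics <- function(condition, profile = lift_profile()) {
  fs <- TRIAL_FS
  po <- profile$postures
  hold <- profile$hold_s
  tg <- condition$task_group
  mk <- function(...) do.call(rbind, list(...))
  if (tg %in% c("calibration_lift", "exo_lift", "stack_lift")) {
    tech <- if (tg == "calibration_lift") condition$technique else "free"
    if (!tech %in% c("stoop", "squat", "free"))
      stop("parameter error: unknown technique '", tech, "' for task ", tg)
    dur <- profile$durations_s[[condition$velocity]]
    ang <- keyframe_track(mk(po$upright, po[[tech]], po$upright),
                          c(dur, dur), hold, fs)
    hf <- NULL
  } else if (tg == "stack_carry") {
    sway1 <- po$upright; sway1["alpha_trunk"] <- 0.10
    sway2 <- sway1; sway2["alpha_trunk"] <- 0.18
    sway1["alpha_arm"] <- sway2["alpha_arm"] <- 0.30
    ang <- keyframe_track(mk(sway1, sway2, sway1), c(1.2, 1.2), 0.4, fs)
    hf <- NULL
  } else if (tg == "shelf_lift") {
    lowp <- po$upright; lowp["alpha_arm"] <- 0.35; lowp["alpha_trunk"] <- 0.12
    highp <- po$upright; highp["alpha_arm"] <- 1.75
    highp["alpha_trunk"] <- -0.03
    dur <- profile$durations_s[["normal"]]
    ang <- keyframe_track(mk(lowp, highp, lowp), c(dur, dur), hold, fs)
    hf <- NULL
  } else if (tg == "push_pull") {
    p <- po$upright; p["alpha_arm"] <- 1.30
    ang <- keyframe_track(matrix(p, nrow = 1,
                                 dimnames = list(NULL, names(p))),
                          numeric(0), 4.0, fs)
    n <- nrow(ang)
    dir <- if (condition$mass_kg < 0) -1 else attr(condition, "pull_dir")
    if (is.null(dir)) dir <- 1
    ramp <- c(minimum_jerk(0, dir * 98.1, 0.8, fs),
              rep(dir * 98.1, n - 2 * (round(0.8 * fs) + 1L)),
              minimum_jerk(dir * 98.1, 0, 0.8, fs))
    hf <- data.frame(fx_n = ramp[seq_len(n)], fz_n = numeric(n))
  } else {
    stop("parameter error: unknown task group ", tg)
  }
  n <- nrow(ang)
  if (is.null(hf)) hf <- data.frame(fx_n = numeric(n), fz_n = numeric(n))
  list(angles = as.data.frame(ang), hand_force = hf)
}

#' Exoskeleton support torque from trunk kinematics
#'
#' Control laws of the actuated back-support exoskeleton: `inclination`
#' gives torque proportional to the trunk inclination angle, `dynamic` adds
#' an angular-acceleration term, `velocity` adds an angular-velocity term,
#' and `transparent` gives zero net support (the actuators only compensate
#' their own friction and inertia).
#'
#' @param kin Data frame with `trunk_inclination`, `trunk_velocity`,
#'   `trunk_acceleration` (as from [trial_kinematic_signals()]).
#' @param strategy One of `"inclination"`, `"dynamic"`, `"velocity"`,
#'   `"transparent"`.
#' @param gains Named list/vector: `k1` (N·m/rad), `k2` (N·m·s^2/rad),
#'   `k3` (N·m·s/rad).
#' @return Torque series in N·m (extension positive).
#' @export
exo_torque <- function(kin, strategy,
                       gains = c(k1 = 30, k2 = 1, k3 = 5)) {
  strategy <- match.arg(strategy,
                        c("inclination", "dynamic", "velocity",
                          "transparent"))
  a <- kin$trunk_inclination
  switch(strategy,
         inclination = gains[["k1"]] * a,
         dynamic = gains[["k1"]] * a + gains[["k2"]] * kin$trunk_acceleration,
         velocity = gains[["k1"]] * a + gains[["k3"]] * kin$trunk_velocity,
         transparent = numeric(length(a)))
}

#' Invert the muscle model: EMG envelopes from a target human moment
#'
#' Computes the twelve normalized EMG envelopes that make the ground-truth
#' muscle model reproduce `m_human` exactly (before noise): the passive
#' moment at the true parameters is subtracted, the antagonist group is
#' held at the co-contraction baseline, and a single activation shared by
#' all agonist elements solves the active-moment equation (extensors are
#' agonists when the required active moment is positive, flexors when it is
#' negative).  Multiplicative log-normal noise is then applied per channel
#' and activations are clipped to \[0, 1.5\].
#'
#' @param m_human Human-moment values (numeric vector or
#'   [moment_series()]).
#' @param kin Data frame with `lumbar_flexion` and `lumbar_velocity`.
#' @param truth A [ground_truth()].
#' @param geometry Muscle geometry table.
#' @return List with `emg` (N x 12 matrix), `infeasible` (TRUE when the
#'   required activation exceeded 1.5 before noise) and `a_required`.
#' @export
emg_from_moment <- function(m_human, kin, truth, geometry) {
  m <- if (inherits(m_human, "moment_series")) m_human$values_nm else m_human
  p <- truth$params_true
  cc <- truth$cocontraction_level
  pas <- passive_moment(kin$lumbar_flexion, p, geometry)
  m_req <- m - pas
  cap <- moment_capacity(kin$lumbar_flexion, kin$lumbar_velocity, p,
                         geometry)
  pos <- m_req >= 0
  a_ag <- ifelse(pos,
                 (m_req + cc * cap$flex_total) / cap$ext_total,
                 (-m_req + cc * cap$ext_total) / cap$flex_total)
  infeasible <- any(a_ag > 1.5)
  n <- length(m)
  emg <- matrix(cc, n, 12L, dimnames = list(NULL, emg_channel_names()))
  emg[, cap$is_ext][pos, ] <- a_ag[pos]
  emg[, !cap$is_ext][!pos, ] <- a_ag[!pos]
  if (truth$emg_noise_sd > 0) {
    noise <- matrix(exp(stats::rnorm(n * 12L, 0, truth$emg_noise_sd)),
                    n, 12L)
    emg <- emg * noise
  }
  emg <- pmin(pmax(emg, 0), 1.5)
  list(emg = emg, infeasible = infeasible, a_required = a_ag)
}

#' Generate one synthetic trial
#'
#' Builds the ideal kinematics for the condition, synthesizes the exact
#' whole-body ground reaction and the top-down reference net moment from
#' the low-pass-filtered trajectories, applies the exoskeleton control law,
#' inverts the ground-truth muscle model into EMG envelopes, and finally
#' adds kinematic noise to the stored angle channels.  With both noise
#' magnitudes at zero, bottom-up inverse dynamics and the forward muscle
#' model reproduce the generated moments to numerical precision.
#'
#' @param condition A [trial_condition()].
#' @param subject A [subject_model()].
#' @param truth A [ground_truth()].
#' @param profile A [lift_profile()].
#' @param trial_id Identifier for the trial.
#' @param seed Integer seed for this trial's noise.
#' @param geometry Optional geometry table (defaults to
#'   `muscle_geometry(subject)`).
#' @return A `"lift_trial"`.
#' @export
generate_trial <- function(condition, subject, truth,
                           profile = lift_profile(),
                           trial_id = "trial", seed = 1L,
                           geometry = NULL) {
  if (is.null(geometry)) geometry <- muscle_geometry(subject)
  gk <- generate_kinematics(condition, profile)
  n <- nrow(gk$angles)
  time_s <- seq(0, by = 1 / TRIAL_FS, length.out = n)
  km <- process_kinematics(gk$angles, subject, TRIAL_FS, lowpass_hz = 5)
  grf <- whole_body_grf(km, subject, condition$mass_kg, gk$hand_force)
  m_net <- top_down_moment_km(km, subject, condition$mass_kg,
                              gk$hand_force, time_s)
  kin <- data.frame(
    trunk_inclination = km$angles$alpha_trunk,
    trunk_velocity = km$omega$alpha_trunk,
    trunk_acceleration = km$omega_dot$alpha_trunk,
    lumbar_flexion = km$angles$alpha_trunk - km$angles$alpha_pelvis,
    lumbar_velocity = km$omega$alpha_trunk - km$omega$alpha_pelvis)
  tau <- if (condition$exo_strategy == "none") numeric(n)
         else exo_torque(kin, condition$exo_strategy)
  m_human <- m_net$values_nm - tau
  set.seed(seed)
  eg <- emg_from_moment(m_human, kin, truth, geometry)
  angles <- gk$angles
  if (truth$kin_noise_sd > 0)
    angles[] <- lapply(angles, function(a)
      a + stats::rnorm(n, 0, truth$kin_noise_sd))
  meta <- list()
  if (eg$infeasible)
    meta$warnings <- sprintf(
      "activation demand exceeded 1.5 before noise (max %.2f)",
      max(eg$a_required))
  new_trial(trial_id = trial_id, subject_id = subject$subject_id,
            condition = condition, time_s = time_s, angles = angles,
            emg = eg$emg, grf = grf, hand_force = gk$hand_force,
            exo_torque_nm = tau, meta = meta)
}

#' Reference human moment of a trial (oracle)
#'
#' Top-down Newton-Euler moment over trunk, arms, hand load and hand force,
#' minus the stored exoskeleton support.  This is the generator-side
#' counterpart of [bottom_up_moment()] + [human_moment()] and serves as an
#' independent oracle for the inverse dynamics implementation.
#'
#' @inheritParams top_down_moment
#' @return A [moment_series()] with `component = "human"`.
#' @export
reference_human_moment <- function(trial, subject, lowpass_hz = 5) {
  human_moment(top_down_moment(trial, subject, lowpass_hz),
               trial$exo_torque_nm)
}

#' The fourteen calibration lift conditions
#'
#' Two masses (7.5, 15 kg) crossed with stoop and squat technique at slow
#' and normal velocity (2 x 2 x 2), plus both masses lifted with the free
#' technique at very slow, normal and fast velocity (2 x 1 x 3).
#'
#' @return Data frame with columns `condition_id`, `mass_kg`, `technique`,
#'   `velocity`.
#' @export
calibration_conditions <- function() {
  a <- expand.grid(technique = c("stoop", "squat"), mass_kg = c(7.5, 15),
                   velocity = c("slow", "normal"),
                   stringsAsFactors = FALSE)
  b <- expand.grid(technique = "free", mass_kg = c(7.5, 15),
                   velocity = c("very_slow", "normal", "fast"),
                   stringsAsFactors = FALSE)
  cond <- rbind(a, b)[c("mass_kg", "technique", "velocity")]
  cond$condition_id <- sprintf("%s_%s_%s", cond$technique,
                               sub("\\.", "p", cond$mass_kg),
                               cond$velocity)
  cond[c("condition_id", "mass_kg", "technique", "velocity")]
}

#' The test-task conditions
#'
#' The evaluation battery: exoskeleton-assisted free lifts (two masses, two
#' velocities, four control strategies), box stacking (lift and carry
#' phases under the inclination strategy), shelf lifts at two masses, and
#' isometric push and pull.
#'
#' @return Data frame with columns `condition_id`, `mass_kg`, `technique`,
#'   `velocity`, `task_group`, `exo_strategy`, `pull_dir`.
#' @export
test_conditions <- function() {
  exo <- expand.grid(mass_kg = c(7.5, 15), velocity = c("normal", "fast"),
                     exo_strategy = c("inclination", "dynamic", "velocity",
                                      "transparent"),
                     stringsAsFactors = FALSE)
  exo$technique <- "free"; exo$task_group <- "exo_lift"
  exo$condition_id <- sprintf("exo_%s_%s_%s", sub("\\.", "p", exo$mass_kg),
                              exo$velocity, exo$exo_strategy)
  other <- data.frame(
    condition_id = c("stack_lift", "stack_carry", "shelf_7p5", "shelf_15",
                     "push", "pull"),
    mass_kg = c(7.5, 7.5, 7.5, 15, 0, 0),
    technique = c("free", "n/a", "n/a", "n/a", "n/a", "n/a"),
    velocity = c("normal", "n/a", "normal", "normal", "n/a", "n/a"),
    task_group = c("stack_lift", "stack_carry", "shelf_lift", "shelf_lift",
                   "push_pull", "push_pull"),
    exo_strategy = c("inclination", "inclination", "none", "none", "none",
                     "none"),
    stringsAsFactors = FALSE)
  out <- rbind(exo[names(other)[1:6]], other)
  out$pull_dir <- ifelse(out$condition_id == "push", -1, 1)
  rownames(out) <- NULL
  out
}

# Deterministic 31-bit hash of a string combined with a base seed.
trial_seed <- function(seed, ...) {
  s <- paste(..., sep = "|")
  h <- as.integer(seed) %% 2147483647
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Generate a full synthetic study
#'
#' Simulates `n_subjects` subjects (anthropometry drawn around a 73.8 kg /
#' 1.82 m cohort, hidden muscle parameters drawn within documented ranges)
#' and, for each, the 14 calibration conditions and the full test battery,
#' all with two repetitions.  Every trial is seeded deterministically from
#' `(seed, subject, trial_id)`, so the same call reproduces identical data.
#'
#' @param n_subjects Number of subjects.
#' @param seed Master integer seed.
#' @param noise `TRUE` for the default EMG/kinematic noise and
#'   co-contraction, `FALSE` for exact noise-free data.
#' @param profile A [lift_profile()].
#' @param n_reps Repetitions per condition (default 2).
#' @return List of class `"synthetic_study"` with `subjects`, `truths`,
#'   `trials` (named list of `"lift_trial"`), and a `manifest` data frame.
#' @export
generate_study <- function(n_subjects = 10, seed = 1L, noise = TRUE,
                           profile = lift_profile(), n_reps = 2L) {
  rtrunc <- function(mean, sd) mean + sd * max(-1.5, min(1.5,
                                                         stats::rnorm(1)))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    # per-subject seed so subject i is identical whatever the cohort size
    set.seed(trial_seed(seed, "anthropometry", i))
    subject_model(rtrunc(73.8, 7.6), rtrunc(1.82, 0.09),
                  sprintf("S%02d", i))
  })
  truths <- lapply(seq_len(n_subjects), function(i) {
    set.seed(trial_seed(seed, "truth", i))
    ground_truth(
      params_true = muscle_model_params(
        gain = stats::runif(1, 50, 90),
        passive_offset = stats::runif(1, 1.05, 1.15),
        passive_scale = stats::runif(1, 8, 15),
        ecc_scale = stats::runif(1, 0.2, 0.4),
        con_scale = stats::runif(1, 0.3, 0.6),
        optimum_angle = stats::runif(1, 0.45, 0.75),
        fl_width = stats::runif(1, 0.5, 0.7)),
      cocontraction_level = if (noise) 0.03 else 0,
      emg_noise_sd = if (noise) 0.05 else 0,
      kin_noise_sd = if (noise) 0.005 else 0,
      seed = trial_seed(seed, "truth", i))
  })
  cal <- calibration_conditions()
  test <- test_conditions()
  trials <- list()
  manifest <- list()
  for (i in seq_len(n_subjects)) {
    subj <- subjects[[i]]
    geo <- muscle_geometry(subj)
    add <- function(cond, cid, rep) {
      tid <- sprintf("%s_%s_r%d", subj$subject_id, cid, rep)
      tr <- generate_trial(cond, subj, truths[[i]], profile, tid,
                           seed = trial_seed(seed, subj$subject_id, tid),
                           geometry = geo)
      trials[[tid]] <<- tr
      manifest[[length(manifest) + 1L]] <<- data.frame(
        subject_id = subj$subject_id, trial_id = tid, condition_id = cid,
        task_group = cond$task_group, mass_kg = cond$mass_kg,
        technique = cond$technique, velocity = cond$velocity,
        exo_strategy = cond$exo_strategy, rep = rep,
        stringsAsFactors = FALSE)
    }
    for (k in seq_len(nrow(cal))) {
      cond <- trial_condition(cal$mass_kg[k], cal$technique[k],
                              cal$velocity[k], "calibration_lift")
      for (r in seq_len(n_reps)) add(cond, cal$condition_id[k], r)
    }
    for (k in seq_len(nrow(test))) {
      cond <- trial_condition(test$mass_kg[k], test$technique[k],
                              test$velocity[k], test$task_group[k],
                              test$exo_strategy[k])
      attr(cond, "pull_dir") <- test$pull_dir[k]
      for (r in seq_len(n_reps)) add(cond, test$condition_id[k], r)
    }
  }
  structure(list(subjects = subjects, truths = truths, trials = trials,
                 manifest = do.call(rbind, manifest), seed = seed,
                 noise = noise),
            class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Writes one trial file per trial plus `manifest.csv` and per-subject
#' `subject_*.txt` files.
#'
#' @param study A `"synthetic_study"`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  man <- study$manifest
  man$file <- file.path(out_dir, paste0(man$trial_id, ".csv"))
  for (i in seq_len(nrow(man)))
    write_trial(study$trials[[man$trial_id[i]]], man$file[i])
  for (s in study$subjects)
    write_subject(s, file.path(out_dir,
                               paste0("subject_", s$subject_id, ".txt")))
  utils::write.csv(man, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
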