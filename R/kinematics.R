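# Planar kinematic processing shared by the trial generator and by inverse
# dynamics: low-pass filtering of segment angles, forward kinematics of the
# five-segment sagittal chain, and numerical differentiation.

#' Numerical derivatives of a uniformly sampled series
#'
#' Central differences on the interior, one-sided differences at the
#' endpoints.  Applied twice for accelerations.
#'
#' @param x Numeric series (length >= 3), assumed low-pass filtered.
#' @param fs Sampling frequency in Hz.
#' @return List with elements `velocity` and `acceleration`, same length as
#'   `x`.
#' @export
numeric_derivatives <- function(x, fs) {
  if (length(x) < 3L) stop("series must have at least 3 samples")
  v <- diff_central(x, fs)
  a <- diff_central(v, fs)
  list(velocity = v, acceleration = a)
}

diff_central <- function(x, fs) {
  n <- length(x)
  v <- numeric(n)
  v[1] <- (x[2] - x[1]) * fs
  v[n] <- (x[n] - x[n - 1]) * fs
  if (n > 2L) v[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * fs / 2
  v
}

# Angle columns of the planar chain, distal to proximal, plus the arm.
ANGLE_COLS <- c("alpha_shank", "alpha_thigh", "alpha_pelvis", "alpha_trunk",
                "alpha_arm")

# Segments whose dynamics enter the moment balance, with the joint they
# hang from.  The load (box) is handled as a point mass at the hand.
LOWER_SEGMENTS <- c("feet", "shank", "thigh", "pelvis")
UPPER_SEGMENTS <- c("trunk_head", "arms")

#' Process planar kinematics for dynamic analysis
#'
#' Low-pass filters the five absolute segment angle series (zero-phase
#' Butterworth, default 5 Hz cutoff, matching the marker/force conditioning
#' stage), runs forward kinematics of the chain
#' ankle-knee-hip-L5/S1-shoulder(-hand), and differentiates angles and
#' centre-of-mass positions numerically.  Both the synthetic ground-reaction
#' generator and the inverse dynamics implementation consume this one
#' representation, so their moment balances share identical accelerations.
#'
#' @param angles Data frame with the five `alpha_*` columns (rad).
#' @param subject A [subject_model()].
#' @param fs Sampling frequency (Hz).
#' @param lowpass_hz Low-pass cutoff applied to the angle series before
#'   differentiation; `NULL` skips filtering.
#' @return List with filtered `angles`, angular velocities/accelerations
#'   (`omega`, `omega_dot`), joint positions (`joints`), per-segment centre
#'   of mass positions and accelerations (`com`, `com_acc`), and the hand
#'   position and acceleration.
#' @export
process_kinematics <- function(angles, subject, fs = TRIAL_FS,
                               lowpass_hz = 5) {
  ang <- as.data.frame(angles)[ANGLE_COLS]
  n <- nrow(ang)
  if (!is.null(lowpass_hz)) {
    spec <- filter_spec("lowpass", 2L, lowpass_hz)
    ang[] <- lapply(ang, butterworth, fs = fs, spec = spec)
  }
  omega <- lapply(ang, diff_central, fs = fs)
  omega_dot <- lapply(omega, diff_central, fs = fs)

  seg <- subject$segments
  len <- function(s) seg$length_m[seg$segment == s]
  cfrac <- function(s) seg$com_from_distal[seg$segment == s]
  uv <- function(a) cbind(sin(a), cos(a))          # up-chain unit vector
  dv <- function(a) cbind(sin(a), -cos(a))         # hanging unit vector

  ankle <- matrix(0, n, 2)
  knee <- ankle + len("shank") * uv(ang$alpha_shank)
  hip <- knee + len("thigh") * uv(ang$alpha_thigh)
  l5s1 <- hip + len("pelvis") * uv(ang$alpha_pelvis)
  shoulder <- l5s1 + len("trunk_head") * uv(ang$alpha_trunk)
  hand <- shoulder + len("arms") * dv(ang$alpha_arm)

  com <- list(
    feet = cbind(rep(subject$foot_com_x, n), rep(0.02, n)),
    shank = ankle + cfrac("shank") * len("shank") * uv(ang$alpha_shank),
    thigh = knee + cfrac("thigh") * len("thigh") * uv(ang$alpha_thigh),
    pelvis = hip + cfrac("pelvis") * len("pelvis") * uv(ang$alpha_pelvis),
    trunk_head = l5s1 + cfrac("trunk_head") * len("trunk_head") *
      uv(ang$alpha_trunk),
    arms = shoulder + cfrac("arms") * len("arms") * dv(ang$alpha_arm))

  acc2 <- function(p) cbind(diff_central(diff_central(p[, 1], fs), fs),
                            diff_central(diff_central(p[, 2], fs), fs))
  com_acc <- lapply(com, acc2)
  com_acc$feet[] <- 0

  seg_angle <- list(feet = NULL, shank = ang$alpha_shank,
                    thigh = ang$alpha_thigh, pelvis = ang$alpha_pelvis,
                    trunk_head = ang$alpha_trunk, arms = ang$alpha_arm)
  omega_dot_seg <- list(
    feet = numeric(n),
    shank = omega_dot$alpha_shank, thigh = omega_dot$alpha_thigh,
    pelvis = omega_dot$alpha_pelvis, trunk_head = omega_dot$alpha_trunk,
    arms = omega_dot$alpha_arm)

  list(n = n, fs = fs, angles = ang, omega = omega, omega_dot = omega_dot,
       joints = list(ankle = ankle, knee = knee, hip = hip, l5s1 = l5s1,
                     shoulder = shoulder, hand = hand),
       com = com, com_acc = com_acc, hand_acc = acc2(hand),
       omega_dot_seg = omega_dot_seg)
}

#' Exoskeleton-measurable kinematic signals of a trial
#'
#' The five kinematic predictors available from sensors embedded in a
#' back-support exoskeleton: trunk inclination (thorax vs. the global
#' vertical), its angular velocity and acceleration, trunk flexion (thorax
#' vs. thigh), and hip angle (pelvis vs. thigh); plus lumbar flexion
#' (thorax vs. pelvis) and its velocity, which drive the muscle model.
#' Angle series are low-pass filtered before differentiation.
#'
#' @param trial A `"lift_trial"`.
#' @param lowpass_hz Low-pass cutoff for the angle series (Hz).
#' @return Data frame with columns `trunk_inclination`, `trunk_velocity`,
#'   `trunk_acceleration`, `trunk_flexion`, `hip_angle`, `lumbar_flexion`,
#'   `lumbar_velocity`.
#' @export
trial_kinematic_signals <- function(trial, lowpass_hz = 5) {
  ang <- trial$angles[ANGLE_COLS]
  if (!is.null(lowpass_hz)) {
    spec <- filter_spec("lowpass", 2L, lowpass_hz)
    ang[] <- lapply(ang, butterworth, fs = TRIAL_FS, spec = spec)
  }
  incl <- ang$alpha_trunk
  d <- numeric_derivatives(incl, TRIAL_FS)
  lumbar <- ang$alpha_trunk - ang$alpha_pelvis
  data.frame(
    trunk_inclination = incl,
    trunk_velocity = d$velocity,
    trunk_acceleration = d$acceleration,
    trunk_flexion = ang$alpha_trunk - ang$alpha_thigh,
    hip_angle = ang$alpha_pelvis - ang$alpha_thigh,
    lumbar_flexion = lumbar,
    lumbar_velocity = diff_central(lumbar, TRIAL_FS))
}
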