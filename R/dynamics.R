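# Planar Newton-Euler dynamics about the L5/S1 joint.  The same segment
# representation (process_kinematics) feeds three computations: synthesis of
# the whole-body ground reaction (generator), the top-down reference moment
# over trunk + arms + load (generator oracle), and the bottom-up recursion
# from the ground reaction through the legs and pelvis (the inverse dynamics
# implementation).  Extension moments are positive; x points forward, z up.

G_GRAV <- 9.81

segment_masses <- function(subject) {
  m <- subject$segments$mass_kg
  names(m) <- subject$segments$segment
  m
}

segment_inertias <- function(subject) {
  i <- subject$segments$i_com
  names(i) <- subject$segments$segment
  i
}

# z-component of the torque of force (fx, fz) applied at (x, z) about (x0, z0)
torque_about <- function(x, z, fx, fz, x0, z0) {
  (x - x0) * fz - (z - z0) * fx
}

#' Synthesize the whole-body ground reaction
#'
#' Computes the ground reaction force and centre of pressure implied by the
#' planar whole-body Newton-Euler balance: the vertical force carries total
#' weight plus vertical inertial force, the horizontal force carries
#' horizontal inertial force minus any external hand force, and the centre
#' of pressure closes the whole-body moment equation exactly.  This is the
#' force-plate stand-in of the synthetic generator; because it is exact,
#' bottom-up inverse dynamics applied to it must reproduce the top-down
#' reference moment.
#'
#' @param km Output of [process_kinematics()].
#' @param subject A [subject_model()].
#' @param load_mass Box mass carried at the hands, kg (scalar or per-sample
#'   vector).
#' @param hand_force Optional data frame (`fx_n`, `fz_n`) of external force
#'   applied to the hands (push/pull), defaults to zero.
#' @return Data frame with columns `fx_n`, `fz_n`, `cop_x_m`.
#' @export
whole_body_grf <- function(km, subject, load_mass = 0, hand_force = NULL) {
  n <- km$n
  if (length(load_mass) == 1L) load_mass <- rep(load_mass, n)
  if (is.null(hand_force))
    hand_force <- data.frame(fx_n = numeric(n), fz_n = numeric(n))
  m <- segment_masses(subject)
  icom <- segment_inertias(subject)
  segs <- names(km$com)

  sum_max <- numeric(n); sum_maz <- numeric(n)
  dL <- numeric(n); tau_grav <- numeric(n)
  for (s in segs) {
    p <- km$com[[s]]; a <- km$com_acc[[s]]
    sum_max <- sum_max + m[s] * a[, 1]
    sum_maz <- sum_maz + m[s] * a[, 2]
    dL <- dL + icom[s] * km$omega_dot_seg[[s]] +
      m[s] * (p[, 1] * a[, 2] - p[, 2] * a[, 1])
    tau_grav <- tau_grav - m[s] * G_GRAV * p[, 1]
  }
  ph <- km$joints$hand; ah <- km$hand_acc
  sum_max <- sum_max + load_mass * ah[, 1]
  sum_maz <- sum_maz + load_mass * ah[, 2]
  dL <- dL + load_mass * (ph[, 1] * ah[, 2] - ph[, 2] * ah[, 1])
  tau_grav <- tau_grav - load_mass * G_GRAV * ph[, 1]

  fx <- sum_max - hand_force$fx_n
  fz <- sum_maz + (sum(m) + load_mass) * G_GRAV - hand_force$fz_n
  tau_hand <- torque_about(ph[, 1], ph[, 2], hand_force$fx_n,
                           hand_force$fz_n, 0, 0)
  cop_x <- (dL - tau_grav - tau_hand) / fz
  data.frame(fx_n = fx, fz_n = fz, cop_x_m = cop_x)
}

# Moment about L5/S1 from a set of segments' inertial and gravity terms.
moment_terms <- function(km, subject, segs) {
  m <- segment_masses(subject)
  icom <- segment_inertias(subject)
  xl <- km$joints$l5s1[, 1]; zl <- km$joints$l5s1[, 2]
  out <- numeric(km$n)
  for (s in segs) {
    p <- km$com[[s]]; a <- km$com_acc[[s]]
    out <- out + icom[s] * km$omega_dot_seg[[s]] +
      m[s] * ((p[, 1] - xl) * a[, 2] - (p[, 2] - zl) * a[, 1]) +
      m[s] * G_GRAV * (p[, 1] - xl)
  }
  out
}

#' Top-down net L5/S1 moment (reference model)
#'
#' Newton-Euler balance of the upper body (trunk+head, arms, hand load and
#' any external hand force) about L5/S1.  Serves as the generator's
#' ground-truth net moment and as the independent oracle against the
#' bottom-up inverse dynamics implementation.
#'
#' @param trial A `"lift_trial"`.
#' @param subject A [subject_model()].
#' @param lowpass_hz Angle low-pass cutoff before differentiation.
#' @return A [moment_series()] with `component = "net"`.
#' @export
top_down_moment <- function(trial, subject, lowpass_hz = 5) {
  km <- process_kinematics(trial$angles, subject, TRIAL_FS, lowpass_hz)
  top_down_moment_km(km, subject, trial$condition$mass_kg,
                     trial$hand_force, trial$time_s)
}

top_down_moment_km <- function(km, subject, load_mass, hand_force, time_s) {
  n <- km$n
  if (length(load_mass) == 1L) load_mass <- rep(load_mass, n)
  xl <- km$joints$l5s1[, 1]; zl <- km$joints$l5s1[, 2]
  ph <- km$joints$hand; ah <- km$hand_acc
  m_val <- moment_terms(km, subject, UPPER_SEGMENTS) +
    load_mass * ((ph[, 1] - xl) * ah[, 2] - (ph[, 2] - zl) * ah[, 1]) +
    load_mass * G_GRAV * (ph[, 1] - xl) -
    torque_about(ph[, 1], ph[, 2], hand_force$fx_n, hand_force$fz_n, xl, zl)
  moment_series(time_s, m_val, "net")
}

#' Bottom-up net L5/S1 moment (inverse dynamics)
#'
#' Newton-Euler recursion from the measured ground reaction upward through
#' feet, shank, thigh and pelvis in the sagittal plane: the moment the
#' trunk must exert at L5/S1 is minus the residual moment of the lower-body
#' free body loaded by the ground reaction.  Anything above the cut (hand
#' load, external hand forces, box mass) never enters the computation,
#' which is why this route works with force-plate data alone.
#'
#' @param trial A `"lift_trial"` with ground reaction channels.
#' @param subject A [subject_model()].
#' @param lowpass_hz Angle low-pass cutoff before differentiation (the
#'   marker-conditioning cutoff).
#' @return A [moment_series()] with `component = "net"`, extension
#'   positive.
#' @export
bottom_up_moment <- function(trial, subject, lowpass_hz = 5) {
  grf <- trial$grf
  if (is.null(grf) || !all(c("fx_n", "fz_n", "cop_x_m") %in% names(grf)))
    stop("input error: trial lacks ground reaction channels")
  km <- process_kinematics(trial$angles, subject, TRIAL_FS, lowpass_hz)
  xl <- km$joints$l5s1[, 1]; zl <- km$joints$l5s1[, 2]
  tau_grf <- torque_about(grf$cop_x_m, 0, grf$fx_n, grf$fz_n, xl, zl)
  m_on_lower <- moment_terms(km, subject, LOWER_SEGMENTS) - tau_grf
  moment_series(trial$time_s, -m_on_lower, "net")
}

#' Human moment: net moment minus exoskeleton support
#'
#' @param m_net A [moment_series()] (`component = "net"`).
#' @param exo_torque_nm Exoskeleton support moment series, aligned with
#'   `m_net` (N·m, extension positive).
#' @return A [moment_series()] with `component = "human"`.
#' @export
human_moment <- function(m_net, exo_torque_nm) {
  if (length(exo_torque_nm) != length(m_net$values_nm))
    stop("input error: series length mismatch")
  moment_series(m_net$time_s, m_net$values_nm - exo_torque_nm, "human")
}
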