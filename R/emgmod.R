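# EMG-driven trunk muscle model: twelve Hill-type muscle elements acting
# about L5/S1, seven subject-specific parameters, forward prediction of
# active and passive moments, and least-squares calibration against the
# inverse-dynamics human moment.

PARAM_NAMES <- c("gain", "passive_offset", "passive_scale", "ecc_scale",
                 "con_scale", "optimum_angle", "fl_width")

#' Bounds of the seven calibratable muscle-model parameters
#'
#' @return A 2 x 7 matrix with rows `lower` and `upper`.
#' @export
param_bounds <- function() {
  b <- rbind(lower = c(10, 0.9, 0, 0, 0, 0, 0.2),
             upper = c(120, 1.3, 60, 0.8, 1, 1.2, 1.0))
  colnames(b) <- PARAM_NAMES
  b
}

#' Construct a muscle-model parameter vector
#'
#' The seven subject-specific parameters of the EMG-driven trunk muscle
#' model: `gain` maps normalized EMG amplitude to muscle stress (N/cm^2 per
#' unit activation); `passive_offset` places the passive length-tension
#' curve relative to the optimum length (normalized length at which passive
#' tension starts); `passive_scale` scales the passive curve (N/cm^2);
#' `ecc_scale` and `con_scale` scale the eccentric and concentric limbs of
#' the tension-velocity curve; `optimum_angle` is the lumbar flexion angle
#' (rad) at which the muscles are at optimum length; `fl_width` is the
#' width of the Gaussian active force-length curve in normalized-length
#' units.
#'
#' @param gain,passive_offset,passive_scale,ecc_scale,con_scale,optimum_angle,fl_width
#'   Parameter values; each must lie within [param_bounds()].
#' @return A named numeric vector of class `"muscle_model_params"`.
#' @export
muscle_model_params <- function(gain, passive_offset, passive_scale,
                                ecc_scale, con_scale, optimum_angle,
                                fl_width) {
  p <- c(gain = gain, passive_offset = passive_offset,
         passive_scale = passive_scale, ecc_scale = ecc_scale,
         con_scale = con_scale, optimum_angle = optimum_angle,
         fl_width = fl_width)
  b <- param_bounds()
  bad <- p < b["lower", ] - 1e-12 | p > b["upper", ] + 1e-12
  if (any(bad))
    stop("parameter(s) out of bounds: ",
         paste(PARAM_NAMES[bad], collapse = ", "))
  structure(p, class = "muscle_model_params")
}

as_params <- function(p) {
  if (inherits(p, "muscle_model_params")) return(p)
  stopifnot(length(p) == 7L)
  do.call(muscle_model_params, as.list(unname(p)))
}

#' Default trunk muscle geometry
#'
#' Twelve muscle elements matching the EMG channels: bilateral rectus
#' abdominis, internal and external oblique (flexors) and iliocostalis
#' lumborum, longissimus thoracis pars lumborum and pars thoracis
#' (extensors).  Each element has an extension-positive moment arm about
#' L5/S1 (sign through its role), a physiological cross-sectional area, a
#' nominal fiber length, and the derived normalized-length strain per
#' radian of lumbar flexion (moment arm / fiber length).  Values are
#' generic literature-style constants; when a subject is supplied, moment
#' arms scale with stature and PCSAs with body mass^(2/3) so muscle
#' strength tracks body size.
#'
#' @param subject Optional [subject_model()] used for scaling.
#' @return Data frame with one row per element.
#' @export
muscle_geometry <- function(subject = NULL) {
  ch <- emg_channel_names()
  geo <- data.frame(
    name = ch,
    side = rep(c("L", "R"), 6),
    role = rep(c("flexor", "flexor", "flexor", "extensor", "extensor",
                 "extensor"), each = 2),
    moment_arm_m = rep(c(0.080, 0.045, 0.050, 0.055, 0.060, 0.055),
                       each = 2),
    pcsa_cm2 = rep(c(6, 8, 9, 8, 10, 6), each = 2),
    fiber_length_m = rep(c(0.30, 0.12, 0.15, 0.11, 0.12, 0.11), each = 2),
    emg_channel = seq_along(ch),
    stringsAsFactors = FALSE)
  if (!is.null(subject)) {
    geo$moment_arm_m <- geo$moment_arm_m * subject$stature_m / 1.82
    geo$pcsa_cm2 <- geo$pcsa_cm2 * (subject$body_mass_kg / 73.8)^(2 / 3)
  }
  geo$strain_per_rad <- geo$moment_arm_m / geo$fiber_length_m
  geo$sign <- ifelse(geo$role == "extensor", 1, -1)
  geo
}

#' Active force-length factor
#'
#' Gaussian curve `exp(-((lambda - 1) / w)^2)`, equal to 1 at optimum
#' length.
#'
#' @param lambda Normalized muscle length.
#' @param w Curve width in normalized-length units.
#' @return Factor in (0, 1].
#' @export
force_length <- function(lambda, w) {
  stopifnot(all(lambda > 0), w > 0)
  exp(-((lambda - 1) / w)^2)
}

# Reference normalized lengthening velocity at which the velocity scaling
# factors apply fully (s^-1).
LAMBDA_DOT_REF <- 1.0

#' Active force-velocity factor
#'
#' Piecewise-linear, clipped: lengthening (positive velocity) raises the
#' factor to at most `1 + s_e`; shortening lowers it to at least
#' `1 - s_c` (floored at 0).  Isometric contraction gives exactly 1.
#'
#' @param lambda_dot Normalized velocity (s^-1, positive = lengthening).
#' @param s_e Eccentric scaling factor.
#' @param s_c Concentric scaling factor.
#' @param v_ref Reference velocity at which the scaling saturates.
#' @return Non-negative factor.
#' @export
force_velocity <- function(lambda_dot, s_e, s_c, v_ref = LAMBDA_DOT_REF) {
  r <- pmin(abs(lambda_dot) / v_ref, 1)
  ifelse(lambda_dot >= 0, 1 + s_e * r, pmax(0, 1 - s_c * r))
}

# Normalized length and velocity of every element (n x 12 matrices).
muscle_state <- function(theta_lumbar, theta_dot_lumbar, params, geometry) {
  p <- as_params(params)
  dtheta <- outer(theta_lumbar - p[["optimum_angle"]],
                  geometry$strain_per_rad * geometry$sign)
  lambda <- 1 + dtheta
  lambda_dot <- outer(theta_dot_lumbar,
                      geometry$strain_per_rad * geometry$sign)
  list(lambda = lambda, lambda_dot = lambda_dot)
}

PASSIVE_SHAPE_C <- 8  # fixed exponential shape of the passive curve

#' Passive moment about L5/S1
#'
#' Exponential passive length-tension curve of the extensor elements:
#' stress `S_p * (exp(c * max(0, lambda - lambda0)) - 1)` with fixed shape
#' `c = 8`, converted to a moment through PCSA and moment arm.  Zero
#' whenever all extensors are slack (`lambda <= lambda0`).
#'
#' @param theta_lumbar Lumbar flexion series (rad).
#' @param params Muscle-model parameters.
#' @param geometry Muscle geometry table ([muscle_geometry()]).
#' @return Passive moment in N·m (vector, extension positive).
#' @export
passive_moment <- function(theta_lumbar, params, geometry) {
  p <- as_params(params)
  ext <- geometry[geometry$role == "extensor", ]
  lam <- 1 + outer(theta_lumbar - p[["optimum_angle"]], ext$strain_per_rad)
  stretch <- pmax(lam - p[["passive_offset"]], 0)
  stress <- p[["passive_scale"]] * (exp(PASSIVE_SHAPE_C * stretch) - 1)
  drop(stress %*% (ext$pcsa_cm2 * ext$moment_arm_m))
}

#' Active moment about L5/S1
#'
#' Sum over the twelve elements of
#' `sign * gain * activation * PCSA * f_l * f_v * moment_arm`; extensors
#' contribute positively, flexors negatively.
#'
#' @param emg N x 12 matrix of normalized EMG activations (columns in
#'   [emg_channel_names()] order).
#' @param theta_lumbar,theta_dot_lumbar Lumbar flexion (rad) and its
#'   velocity (rad/s).
#' @param params Muscle-model parameters.
#' @param geometry Muscle geometry table.
#' @return Active moment in N·m (vector).
#' @export
active_moment <- function(emg, theta_lumbar, theta_dot_lumbar, params,
                          geometry) {
  if (ncol(emg) != 12L) stop("input error: emg must have 12 channels")
  p <- as_params(params)
  st <- muscle_state(theta_lumbar, theta_dot_lumbar, p, geometry)
  fl <- force_length(st$lambda, p[["fl_width"]])
  fv <- force_velocity(st$lambda_dot, p[["ecc_scale"]], p[["con_scale"]])
  contrib <- emg * fl * fv
  coeff <- p[["gain"]] * geometry$pcsa_cm2 * geometry$moment_arm_m *
    geometry$sign
  drop(contrib %*% coeff)
}

# Per-muscle moment coefficients G*A*pcsa*fl*fv*arm without sign, split by
# role; used by the generator to invert the model.
moment_capacity <- function(theta_lumbar, theta_dot_lumbar, params,
                            geometry) {
  p <- as_params(params)
  st <- muscle_state(theta_lumbar, theta_dot_lumbar, p, geometry)
  fl <- force_length(st$lambda, p[["fl_width"]])
  fv <- force_velocity(st$lambda_dot, p[["ecc_scale"]], p[["con_scale"]])
  phi <- sweep(fl * fv, 2,
               p[["gain"]] * geometry$pcsa_cm2 * geometry$moment_arm_m, "*")
  ext <- geometry$role == "extensor"
  list(phi = phi,
       ext_total = rowSums(phi[, ext, drop = FALSE]),
       flex_total = rowSums(phi[, !ext, drop = FALSE]),
       is_ext = ext)
}

#' Predict the human moment with the muscle model
#'
#' Active plus passive moment from a trial's twelve EMG envelopes and its
#' lumbar kinematics.
#'
#' @param trial A `"lift_trial"`.
#' @param params Muscle-model parameters.
#' @param geometry Muscle geometry table.
#' @param lowpass_hz Angle low-pass cutoff for the kinematic signals.
#' @return A [moment_series()] with `component = "human"`.
#' @export
predict_human_moment <- function(trial, params, geometry,
                                 lowpass_hz = 5) {
  ks <- trial_kinematic_signals(trial, lowpass_hz)
  act <- active_moment(trial$emg, ks$lumbar_flexion, ks$lumbar_velocity,
                       params, geometry)
  pas <- passive_moment(ks$lumbar_flexion, params, geometry)
  moment_series(trial$time_s, act + pas, "human")
}

# Assemble the concatenated calibration data once so the objective is a
# cheap vectorized evaluation.
calibration_data <- function(trials, m_ref, lowpass_hz = 5) {
  stopifnot(length(trials) >= 1L, length(trials) == length(m_ref))
  theta <- list(); theta_dot <- list(); emg <- list(); ref <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    mi <- m_ref[[i]]
    vals <- if (inherits(mi, "moment_series")) mi$values_nm else mi
    if (length(vals) != length(tr$time_s))
      stop("input error: reference moment does not overlap trial ",
           tr$trial_id)
    ks <- trial_kinematic_signals(tr, lowpass_hz)
    theta[[i]] <- ks$lumbar_flexion
    theta_dot[[i]] <- ks$lumbar_velocity
    emg[[i]] <- tr$emg
    ref[[i]] <- vals
  }
  list(theta = unlist(theta), theta_dot = unlist(theta_dot),
       emg = do.call(rbind, emg), ref = unlist(ref), dt = 1 / TRIAL_FS)
}

emgmod_objective <- function(pvec, data, geometry, stride = 1L) {
  idx <- seq(1L, length(data$ref), by = stride)
  act <- active_moment(data$emg[idx, , drop = FALSE], data$theta[idx],
                       data$theta_dot[idx], pvec, geometry)
  pas <- passive_moment(data$theta[idx], pvec, geometry)
  sum((data$ref[idx] - act - pas)^2) * data$dt * stride
}

# Objective and analytic gradient sharing one forward evaluation; returns
# closures fn/gr for optim.  Muscle elements with identical kinematic
# constants (the left/right pairs) are collapsed by summing their EMG
# drive, since force-length/velocity factors coincide.  Note the
# concentric factor 1 - S_c * min(|v|, 1) cannot go negative within the
# parameter bounds (S_c <= 1), so no clipping branch is needed here.  The
# gradient is checked against finite differences in the test suite.
emgmod_obj_factory <- function(data, geometry, stride = 1L) {
  idx <- seq(1L, length(data$ref), by = stride)
  theta <- data$theta[idx]
  theta_dot <- data$theta_dot[idx]
  ref <- data$ref[idx]
  w_dt <- data$dt * stride
  sig_m <- geometry$strain_per_rad * geometry$sign
  cs_m <- geometry$pcsa_cm2 * geometry$moment_arm_m
  key <- paste(sig_m, cs_m, geometry$sign)
  grp <- match(key, unique(key))
  G_n <- max(grp)
  sig <- vapply(seq_len(G_n), function(g) sig_m[grp == g][1], 0)
  cs <- vapply(seq_len(G_n), function(g) cs_m[grp == g][1], 0)
  sgn <- vapply(seq_len(G_n), function(g) geometry$sign[grp == g][1], 0)
  mult <- tabulate(grp, G_n)
  ext <- vapply(seq_len(G_n), function(g)
    geometry$role[grp == g][1] == "extensor", TRUE)
  A <- vapply(seq_len(G_n), function(g)
    rowSums(data$emg[idx, grp == g, drop = FALSE]), numeric(length(idx)))
  scs <- cs * sgn
  v <- outer(theta_dot, sig)
  rv <- pmin(abs(v), 1)
  rvp <- rv * (v >= 0)
  rvn <- rv - rvp
  cache <- new.env(parent = emptyenv())
  cache$p <- NULL
  forward <- function(p) {
    if (!is.null(cache$p) && identical(cache$p, p)) return()
    G <- p[1]; lam0 <- p[2]; Sp <- p[3]; Se <- p[4]; Sc <- p[5]
    thopt <- p[6]; w <- p[7]
    x <- outer(theta - thopt, sig)
    fl <- exp(-(x / w)^2)
    fv <- 1 + Se * rvp - Sc * rvn
    B <- A * fl * fv
    m_act_unit <- drop(B %*% scs)                  # active moment per gain
    xe <- x[, ext, drop = FALSE]
    u <- xe + 1 - lam0
    u[u < 0] <- 0
    e8 <- exp(PASSIVE_SHAPE_C * u)
    upos <- u > 0
    m_pas_unit <- drop((e8 - 1) %*% (cs[ext] * mult[ext]))  # passive / Sp
    r <- ref - G * m_act_unit - Sp * m_pas_unit
    cache$p <- p
    cache$vals <- list(G = G, Sp = Sp, x = x, fl = fl, B = B,
                       m_act_unit = m_act_unit, m_pas_unit = m_pas_unit,
                       e8 = e8, upos = upos, r = r, w = w)
  }
  fn <- function(p) {
    forward(p)
    sum(cache$vals$r^2) * w_dt
  }
  gr <- function(p) {
    forward(p)
    z <- cache$vals
    G <- z$G
    ce <- cs[ext] * mult[ext]
    dM <- matrix(0, length(ref), 7L)
    dM[, 1] <- z$m_act_unit
    dM[, 2] <- -PASSIVE_SHAPE_C * z$Sp * drop((z$e8 * z$upos) %*% ce)
    dM[, 3] <- z$m_pas_unit
    Afl <- A * z$fl
    dM[, 4] <- G * drop((Afl * rvp) %*% scs)
    dM[, 5] <- -G * drop((Afl * rvn) %*% scs)
    dM[, 6] <- G * drop((z$B * (2 * z$x / z$w^2)) %*% (scs * sig)) -
      z$Sp * PASSIVE_SHAPE_C * drop((z$e8 * z$upos) %*% (ce * sig[ext]))
    dM[, 7] <- G * drop((z$B * (2 * z$x^2 / z$w^3)) %*% scs)
    drop(-2 * w_dt * (z$r %*% dM))
  }
  list(fn = fn, gr = gr)
}

#' Calibrate the muscle model to a subject
#'
#' Minimizes the integrated squared difference between the reference
#' (inverse dynamics) human moment and the model's active-plus-passive
#' moment over a set of calibration trials,
#' `J = sum_trials sum_t (M_ref - M_active(P) - M_passive(P))^2 * dt`,
#' by bounded quasi-Newton (L-BFGS-B) from multiple seeded Latin-hypercube
#' starts; the best converged solution is returned with diagnostics.
#'
#' @param trials List of calibration `"lift_trial"`s.
#' @param m_ref List of reference human-moment series (one per trial),
#'   typically from [bottom_up_moment()] / [human_moment()].
#' @param geometry Muscle geometry table.
#' @param options List of optimizer options: `n_starts` (default 5),
#'   `maxit` (default 200), `stride` (objective sample stride, default 1),
#'   `seed` (multi-start seed, default 1), `lowpass_hz` (default 5).
#' @return List of class `"emgmod_fit"` with elements `params`
#'   (a `"muscle_model_params"`), `objective` (J at the optimum),
#'   `start_objectives`, `convergence` and `n_samples`.
#' @export
calibrate_emgmod <- function(trials, m_ref, geometry, options = list()) {
  opt <- utils::modifyList(list(n_starts = 5L, maxit = 200L, stride = 1L,
                                seed = 1L, lowpass_hz = 5), options)
  data <- calibration_data(trials, m_ref, opt$lowpass_hz)
  calibrate_emgmod_data(data, geometry, opt)
}

# Calibration on a prebuilt data bundle (see calibration_data); the study
# module uses this entry to avoid re-deriving kinematic signals for every
# calibration-set evaluation.
calibrate_emgmod_data <- function(data, geometry, options = list()) {
  opt <- utils::modifyList(list(n_starts = 5L, maxit = 200L, stride = 1L,
                                seed = 1L), options)
  b <- param_bounds()
  lower <- b["lower", ]; upper <- b["upper", ]
  mid <- (lower + upper) / 2
  starts <- matrix(mid, nrow = 1L)
  if (opt$n_starts > 1L) {
    u <- withr_seed(opt$seed, lhs::randomLHS(opt$n_starts - 1L, 7L))
    starts <- rbind(starts, sweep(sweep(u, 2, upper - lower, "*"),
                                  2, lower, "+"))
  }
  ob <- emgmod_obj_factory(data, geometry, opt$stride)
  fits <- vector("list", nrow(starts))
  for (k in seq_len(nrow(starts))) {
    fits[[k]] <- tryCatch(
      stats::optim(starts[k, ], ob$fn, ob$gr,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = opt$maxit)),
      error = function(e) NULL)
  }
  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("optimization error: all starts failed; check reference moments")
  obj <- vapply(fits, function(f) f$value, numeric(1))
  # tie-break: lowest J, then lowest gain
  ord <- order(obj, vapply(fits, function(f) f$par[1], numeric(1)))
  best <- fits[[ord[1]]]
  structure(
    list(params = as_params(pmin(pmax(best$par, lower), upper)),
         objective = best$value, start_objectives = obj,
         convergence = best$convergence,
         n_samples = length(data$ref)),
    class = "emgmod_fit")
}

#' @export
print.emgmod_fit <- function(x, ...) {
  cat(sprintf("<emgmod_fit: J = %.4g over %d samples, convergence %d>\n",
              x$objective, x$n_samples, x$convergence))
  print(round(unclass(x$params), 4))
  invisible(x)
}

# Evaluate an expression under a temporary RNG state.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
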