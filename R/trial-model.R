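# Core data types: trial conditions, trials, subjects, moment series, and the
# plain-text trial file format shared by every stage of the pipeline.

TRIAL_FS <- 50

#' EMG channel names
#'
#' The twelve bilateral trunk-muscle EMG channels, in the fixed column order
#' used throughout the package: rectus abdominis (RA), internal oblique (IO),
#' external oblique (EO), iliocostalis lumborum (IL), longissimus thoracis
#' pars lumborum (LTpl) and pars thoracis (LTpt), left then right.
#'
#' @return Character vector of length 12.
#' @export
emg_channel_names <- function() {
  c("RA_L", "RA_R", "IO_L", "IO_R", "EO_L", "EO_R",
    "IL_L", "IL_R", "LTpl_L", "LTpl_R", "LTpt_L", "LTpt_R")
}

#' Reduced EMG channel set used by the regression model
#'
#' The four back-muscle channels (bilateral longissimus thoracis pars
#' lumborum and pars thoracis) retained when the sensor count is reduced
#' for exoskeleton operation.
#'
#' @return Character vector of length 4.
#' @export
regmod_emg_channels <- function() {
  c("LTpl_L", "LTpl_R", "LTpt_L", "LTpt_R")
}

TECHNIQUES <- c("stoop", "squat", "free", "n/a")
VELOCITIES <- c("very_slow", "slow", "normal", "fast", "n/a")
TASK_GROUPS <- c("calibration_lift", "exo_lift", "stack_lift", "stack_carry",
                 "shelf_lift", "push_pull")
EXO_STRATEGIES <- c("none", "inclination", "dynamic", "velocity", "transparent")

#' Construct a trial condition
#'
#' A trial condition records the load mass, lifting technique, velocity
#' class, task group and exoskeleton control strategy of one trial.
#' Calibration lifts are always performed without the exoskeleton; stoop and
#' squat lifts exist only at slow/normal speed while free-technique
#' calibration lifts exist at very slow, normal and fast speed.
#'
#' @param mass_kg Load mass in kg (0 for unloaded tasks).
#' @param technique One of `"stoop"`, `"squat"`, `"free"`, `"n/a"`.
#' @param velocity One of `"very_slow"`, `"slow"`, `"normal"`, `"fast"`,
#'   `"n/a"`.
#' @param task_group One of `"calibration_lift"`, `"exo_lift"`,
#'   `"stack_lift"`, `"stack_carry"`, `"shelf_lift"`, `"push_pull"`.
#' @param exo_strategy One of `"none"`, `"inclination"`, `"dynamic"`,
#'   `"velocity"`, `"transparent"`.
#' @return An object of class `"trial_condition"`.
#' @export
trial_condition <- function(mass_kg, technique, velocity, task_group,
                            exo_strategy = "none") {
  technique <- match.arg(technique, TECHNIQUES)
  velocity <- match.arg(velocity, VELOCITIES)
  task_group <- match.arg(task_group, TASK_GROUPS)
  exo_strategy <- match.arg(exo_strategy, EXO_STRATEGIES)
  stopifnot(is.numeric(mass_kg), length(mass_kg) == 1L, mass_kg >= 0)
  cond <- structure(
    list(mass_kg = mass_kg, technique = technique, velocity = velocity,
         task_group = task_group, exo_strategy = exo_strategy),
    class = "trial_condition")
  validate_condition(cond)
  cond
}

validate_condition <- function(cond) {
  if (cond$task_group == "calibration_lift" && cond$exo_strategy != "none")
    stop("calibration_lift trials must have exo_strategy = 'none'")
  if (cond$technique %in% c("stoop", "squat") &&
      !cond$velocity %in% c("slow", "normal"))
    stop("stoop/squat trials must have velocity in {slow, normal}")
  if (cond$technique == "free" && cond$task_group == "calibration_lift" &&
      !cond$velocity %in% c("very_slow", "normal", "fast"))
    stop("free calibration lifts must have velocity in {very_slow, normal, fast}")
  invisible(cond)
}

# Default planar anthropometry, as fractions of body mass and stature.  The
# chain runs ankle -> knee -> hip -> L5/S1 -> shoulder; the arms hang from
# the shoulder.  Mass fractions sum to 1; length fractions are of stature;
# com_from_distal is the centre-of-mass position along the segment measured
# from the distal joint; rog is the radius of gyration about the centre of
# mass as a fraction of segment length.  Values are generic cadaver-table
# style constants for a synthetic planar model (both limbs pooled).
SEGMENT_TABLE <- data.frame(
  segment = c("feet", "shank", "thigh", "pelvis", "trunk_head", "arms"),
  mass_fraction = c(0.029, 0.093, 0.200, 0.142, 0.436, 0.100),
  length_fraction = c(NA, 0.246, 0.245, 0.100, 0.300, 0.400),
  com_from_distal = c(NA, 0.567, 0.567, 0.500, 0.550, 0.550),
  rog = c(0, 0.302, 0.323, 0.350, 0.450, 0.300),
  stringsAsFactors = FALSE
)

#' Construct a planar subject model
#'
#' Builds the per-subject anthropometry used by the forward simulation and
#' by inverse dynamics: segment lengths, masses, centre-of-mass positions
#' and moments of inertia for a sagittal five-segment chain (feet, shank,
#' thigh, pelvis, trunk+head) plus arms, scaled from body mass and stature
#' by a documented fraction table.
#'
#' @param body_mass_kg Body mass in kg.
#' @param stature_m Stature in m.
#' @param subject_id Identifier string.
#' @param mvc_peaks Optional named numeric vector of per-channel MVC
#'   envelope peaks (arbitrary amplitude units); defaults to 1 for every
#'   channel, i.e. envelopes are already MVC-normalized.
#' @return An object of class `"subject_model"`.
#' @export
subject_model <- function(body_mass_kg, stature_m, subject_id = "S01",
                          mvc_peaks = NULL) {
  stopifnot(body_mass_kg > 0, stature_m > 0)
  seg <- SEGMENT_TABLE
  if (abs(sum(seg$mass_fraction) - 1) > 1e-9)
    stop("segment mass fractions must sum to 1")
  seg$mass_kg <- seg$mass_fraction * body_mass_kg
  seg$length_m <- seg$length_fraction * stature_m
  seg$length_m[seg$segment == "feet"] <- 0.25 * stature_m / 1.82
  seg$i_com <- seg$mass_kg * (seg$rog * ifelse(is.na(seg$length_m), 0,
                                               seg$length_m))^2
  if (is.null(mvc_peaks)) {
    mvc_peaks <- rep(1, 12)
    names(mvc_peaks) <- emg_channel_names()
  }
  if (length(mvc_peaks) != 12L || any(mvc_peaks <= 0))
    stop("mvc_peaks must be 12 positive values")
  structure(
    list(subject_id = subject_id,
         body_mass_kg = body_mass_kg,
         stature_m = stature_m,
         segments = seg,
         # horizontal offset of the foot centre of mass ahead of the ankle
         foot_com_x = 0.05 * stature_m / 1.82,
         mvc_peaks = mvc_peaks),
    class = "subject_model")
}

#' Construct a moment series
#'
#' A time series of moments about the L5/S1 joint, extension positive.
#'
#' @param time_s Time stamps in s.
#' @param values_nm Moments in newton-metres.
#' @param component One of `"net"`, `"human"`, `"active"`, `"passive"`.
#' @return An object of class `"moment_series"`.
#' @export
moment_series <- function(time_s, values_nm,
                          component = c("net", "human", "active", "passive")) {
  component <- match.arg(component)
  if (length(time_s) != length(values_nm))
    stop("time_s and values_nm must have equal length")
  structure(list(time_s = time_s, values_nm = values_nm,
                 component = component),
            class = "moment_series")
}

#' @export
print.moment_series <- function(x, ...) {
  cat(sprintf("<moment_series: %s, %d samples, range [%.1f, %.1f] N·m>\n",
              x$component, length(x$values_nm),
              min(x$values_nm), max(x$values_nm)))
  invisible(x)
}

# Column layout of a trial file (after the 12 EMG columns are expanded).
trial_columns <- function() {
  c("time_s", "alpha_shank", "alpha_thigh", "alpha_pelvis", "alpha_trunk",
    "alpha_arm", paste0("emg_", emg_channel_names()),
    "grf_fx_n", "grf_fz_n", "grf_cop_x_m", "hand_fx_n", "hand_fz_n",
    "exo_torque_nm")
}

#' Construct a trial
#'
#' A trial is a uniformly sampled (50 Hz) multi-channel record of one task:
#' planar segment orientations (absolute angles from the vertical, rad,
#' forward lean positive), twelve MVC-normalized EMG envelopes, ground
#' reaction force and centre of pressure, any external hand force, and the
#' exoskeleton support moment.
#'
#' @param trial_id,subject_id Identifier strings.
#' @param condition A [trial_condition()].
#' @param time_s Time vector at 50 Hz.
#' @param angles Data frame with columns `alpha_shank`, `alpha_thigh`,
#'   `alpha_pelvis`, `alpha_trunk`, `alpha_arm` (rad).
#' @param emg N x 12 matrix of normalized EMG envelopes, columns in
#'   [emg_channel_names()] order.
#' @param grf Data frame with columns `fx_n`, `fz_n`, `cop_x_m`.
#' @param hand_force Data frame with columns `fx_n`, `fz_n`: external force
#'   applied to the hands (push/pull tasks); zero otherwise.
#' @param exo_torque_nm Exoskeleton support moment series (N·m, extension
#'   positive; identically zero without an exoskeleton).
#' @param meta Optional list of free-form metadata (e.g. generator
#'   warnings).
#' @return An object of class `"lift_trial"`.
#' @export
new_trial <- function(trial_id, subject_id, condition, time_s, angles, emg,
                      grf, hand_force = NULL, exo_torque_nm = NULL,
                      meta = list()) {
  n <- length(time_s)
  if (is.null(hand_force))
    hand_force <- data.frame(fx_n = numeric(n), fz_n = numeric(n))
  if (is.null(exo_torque_nm)) exo_torque_nm <- numeric(n)
  trial <- structure(
    list(trial_id = trial_id, subject_id = subject_id, condition = condition,
         time_s = time_s, angles = angles, emg = emg, grf = grf,
         hand_force = hand_force, exo_torque_nm = exo_torque_nm,
         meta = meta),
    class = "lift_trial")
  validate_trial(trial)
}

#' Validate a trial against its invariants
#'
#' Checks channel lengths, the 50 Hz time base, EMG non-negativity and the
#' zero-exoskeleton-torque invariant, raising an informative error on the
#' first violation.
#'
#' @param trial A `"lift_trial"`.
#' @return The trial, invisibly validated.
#' @export
validate_trial <- function(trial) {
  n <- length(trial$time_s)
  if (n < 3L) stop("trial too short")
  dt <- diff(trial$time_s)
  if (any(abs(dt - 1 / TRIAL_FS) > 1e-6))
    stop("sampling error: time base is not uniform 50 Hz")
  ang_cols <- c("alpha_shank", "alpha_thigh", "alpha_pelvis", "alpha_trunk",
                "alpha_arm")
  if (!all(ang_cols %in% names(trial$angles)))
    stop("missing angle column(s): ",
         paste(setdiff(ang_cols, names(trial$angles)), collapse = ", "))
  lens <- c(nrow(trial$angles), nrow(trial$emg), nrow(trial$grf),
            nrow(trial$hand_force), length(trial$exo_torque_nm))
  if (any(lens != n))
    stop("all channels must share one length (", n, " samples)")
  if (!identical(colnames(trial$emg), emg_channel_names()))
    stop("emg matrix must have the 12 standard channel columns in order")
  if (any(trial$emg < 0)) stop("normalized EMG must be >= 0 everywhere")
  if (!all(c("fx_n", "fz_n", "cop_x_m") %in% names(trial$grf)))
    stop("grf must have columns fx_n, fz_n, cop_x_m")
  if (trial$condition$exo_strategy == "none" &&
      any(trial$exo_torque_nm != 0))
    stop("exo_torque_nm must be identically 0 when exo_strategy = 'none'")
  invisible(trial)
}

#' @export
print.lift_trial <- function(x, ...) {
  cat(sprintf(
    "<lift_trial %s  subject %s  %s  %.1f kg  %s/%s  %s  %d samples>\n",
    x$trial_id, x$subject_id, x$condition$task_group, x$condition$mass_kg,
    x$condition$technique, x$condition$velocity, x$condition$exo_strategy,
    length(x$time_s)))
  invisible(x)
}

#' Write a trial to a plain-text file
#'
#' Trials are stored one per file as UTF-8 comma-delimited samples preceded
#' by a `#`-prefixed `key: value` metadata header.  Numeric values are
#' written with 15 significant digits so a read/write round trip preserves
#' them to better than 1e-10.
#'
#' @param trial A validated `"lift_trial"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_trial()]
#' @export
write_trial <- function(trial, path) {
  validate_trial(trial)
  con <- tryCatch(file(path, open = "wb"),
                  error = function(e) stop("cannot write trial file: ", path))
  on.exit(close(con))
  hdr <- c(trial_id = trial$trial_id, subject_id = trial$subject_id,
           mass_kg = format(trial$condition$mass_kg, digits = 15),
           technique = trial$condition$technique,
           velocity = trial$condition$velocity,
           task_group = trial$condition$task_group,
           exo_strategy = trial$condition$exo_strategy,
           fs_hz = as.character(TRIAL_FS))
  if (!is.null(trial$meta$warnings) && length(trial$meta$warnings))
    hdr <- c(hdr, warnings = paste(trial$meta$warnings, collapse = "; "))
  writeLines(sprintf("# %s: %s", names(hdr), unname(hdr)), con)
  df <- data.frame(time_s = trial$time_s,
                   trial$angles[c("alpha_shank", "alpha_thigh",
                                  "alpha_pelvis", "alpha_trunk",
                                  "alpha_arm")],
                   trial$emg,
                   grf_fx_n = trial$grf$fx_n, grf_fz_n = trial$grf$fz_n,
                   grf_cop_x_m = trial$grf$cop_x_m,
                   hand_fx_n = trial$hand_force$fx_n,
                   hand_fz_n = trial$hand_force$fz_n,
                   exo_torque_nm = trial$exo_torque_nm,
                   check.names = FALSE)
  names(df)[7:18] <- paste0("emg_", emg_channel_names())
  writeLines(paste(trial_columns(), collapse = ","), con)
  fmt <- vapply(df, function(col) format(col, digits = 15, trim = TRUE,
                                         scientific = FALSE),
                character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1L)
  writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  invisible(path)
}

#' Read a trial from a plain-text file
#'
#' Parses the documented trial file dialect (see [write_trial()]) and
#' returns a fully validated trial.  A missing channel column raises a
#' format error naming the column; a non-uniform time base raises a
#' sampling error.
#'
#' @param path Path to a trial file.
#' @return A `"lift_trial"`.
#' @export
read_trial <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr_idx <- grep("^#", lines)
  hdr_lines <- lines[hdr_idx]
  kv <- sub("^#\\s*", "", hdr_lines)
  keys <- sub(":.*$", "", kv)
  vals <- trimws(sub("^[^:]*:", "", kv))
  names(vals) <- trimws(keys)
  body <- lines[-hdr_idx]
  body <- body[nzchar(body)]
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  missing <- setdiff(trial_columns(), cols)
  if (length(missing))
    stop("format error: missing column(s): ", paste(missing, collapse = ", "))
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        check.names = FALSE)
  cond <- trial_condition(mass_kg = as.numeric(vals[["mass_kg"]]),
                          technique = vals[["technique"]],
                          velocity = vals[["velocity"]],
                          task_group = vals[["task_group"]],
                          exo_strategy = vals[["exo_strategy"]])
  emg <- as.matrix(df[paste0("emg_", emg_channel_names())])
  colnames(emg) <- emg_channel_names()
  meta <- list()
  if ("warnings" %in% names(vals))
    meta$warnings <- strsplit(vals[["warnings"]], "; ", fixed = TRUE)[[1]]
  new_trial(trial_id = vals[["trial_id"]], subject_id = vals[["subject_id"]],
            condition = cond, time_s = df$time_s,
            angles = df[c("alpha_shank", "alpha_thigh", "alpha_pelvis",
                          "alpha_trunk", "alpha_arm")],
            emg = emg,
            grf = data.frame(fx_n = df$grf_fx_n, fz_n = df$grf_fz_n,
                             cop_x_m = df$grf_cop_x_m),
            hand_force = data.frame(fx_n = df$hand_fx_n,
                                    fz_n = df$hand_fz_n),
            exo_torque_nm = df$exo_torque_nm,
            meta = meta)
}

#' Write a subject model to a flat key-value text file
#'
#' @param subject A `"subject_model"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_subject <- function(subject, path) {
  lines <- c(sprintf("subject_id: %s", subject$subject_id),
             sprintf("body_mass_kg: %s",
                     format(subject$body_mass_kg, digits = 15)),
             sprintf("stature_m: %s", format(subject$stature_m, digits = 15)),
             sprintf("mvc_%s: %s", emg_channel_names(),
                     format(subject$mvc_peaks, digits = 15)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a subject model from a flat key-value text file
#'
#' @param path Path to a subject file written by [write_subject()].
#' @return A `"subject_model"`.
#' @export
read_subject <- function(path) {
  lines <- readLines(path)
  keys <- trimws(sub(":.*$", "", lines))
  vals <- trimws(sub("^[^:]*:", "", lines))
  names(vals) <- keys
  mvc <- as.numeric(vals[paste0("mvc_", emg_channel_names())])
  names(mvc) <- emg_channel_names()
  subject_model(body_mass_kg = as.numeric(vals[["body_mass_kg"]]),
                stature_m = as.numeric(vals[["stature_m"]]),
                subject_id = vals[["subject_id"]],
                mvc_peaks = mvc)
}
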