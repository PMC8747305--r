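# Reduced-sensor regression model: Gaussian-kernel support-vector
# regression predicting the actively generated lumbar moment from four
# back-muscle EMG channels plus five exoskeleton-measurable kinematic
# signals.

FEATURE_COLS <- c("LTpl_L", "LTpl_R", "LTpt_L", "LTpt_R",
                  "trunk_inclination", "trunk_velocity",
                  "trunk_acceleration", "trunk_flexion", "hip_angle")

#' Build the reduced-sensor feature matrix of a trial
#'
#' One row per 50 Hz sample; columns, in fixed order: the four back-muscle
#' EMG envelopes (bilateral longissimus thoracis pars lumborum and pars
#' thoracis) and the five kinematic signals available from exoskeleton
#' sensors (trunk inclination, angular velocity, angular acceleration,
#' trunk flexion, hip angle).
#'
#' @param trial A `"lift_trial"`.
#' @param lowpass_hz Angle low-pass cutoff before differentiation.
#' @return N x 9 numeric matrix with fixed column names.
#' @export
build_features <- function(trial, lowpass_hz = 5) {
  ks <- trial_kinematic_signals(trial, lowpass_hz)
  x <- cbind(trial$emg[, regmod_emg_channels(), drop = FALSE],
             trunk_inclination = ks$trunk_inclination,
             trunk_velocity = ks$trunk_velocity,
             trunk_acceleration = ks$trunk_acceleration,
             trunk_flexion = ks$trunk_flexion,
             hip_angle = ks$hip_angle)
  colnames(x) <- FEATURE_COLS
  x
}

#' Train the support-vector regression model
#'
#' Epsilon-SVR with a radial-basis kernel on z-scored features, using the
#' coarse-Gaussian convention: kernel scale `4 * sqrt(n_features)` (i.e.
#' `gamma = 1 / (2 * (4 * sqrt(9))^2)`), box constraint `IQR(y) / 1.349`
#' and epsilon-tube `IQR(y) / 13.49`.  An optional blocked k-fold
#' cross-validation (contiguous blocks by trial, to respect serial
#' correlation) reports a training-diagnostic RMSE.  Training sets larger
#' than `max_rows` are thinned by a uniform stride: at 50 Hz the envelopes
#' and kinematics are heavily oversampled relative to their 2.5 Hz
#' bandwidth.
#'
#' @param features N x 9 matrix from [build_features()].
#' @param response Active-moment response (N·m), as predicted by the
#'   calibrated muscle model (never the inverse dynamics moment).
#' @param options List: `cv_folds` (default 10; 0 disables), `max_rows`
#'   (default 2000), `groups` (per-row trial labels for fold blocking).
#' @return Object of class `"regmod"` holding the fitted SVR, the frozen
#'   standardization constants, hyperparameters and the CV diagnostic.
#' @export
train_regmod <- function(features, response, options = list()) {
  opt <- utils::modifyList(list(cv_folds = 10L, max_rows = 2000L,
                                groups = NULL), options)
  n <- nrow(features)
  if (n < 100L) stop("need at least 100 training samples")
  if (opt$cv_folds > 0L && n < opt$cv_folds)
    stop("parameter error: fewer samples than folds")
  stopifnot(length(response) == n)
  groups <- if (is.null(opt$groups)) rep("all", n) else opt$groups
  if (n > opt$max_rows) {
    keep <- unique(round(seq(1L, n, length.out = opt$max_rows)))
    features <- features[keep, , drop = FALSE]
    response <- response[keep]
    groups <- groups[keep]
    n <- length(keep)
  }
  center <- colMeans(features)
  scale_ <- apply(features, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  xs <- sweep(sweep(features, 2, center), 2, scale_, "/")
  kernel_scale <- 4 * sqrt(ncol(features))
  gamma <- 1 / (2 * kernel_scale^2)
  iqr <- stats::IQR(response)
  cost <- max(iqr / 1.349, 1e-3)
  epsilon <- max(iqr / 13.49, 1e-6)
  fit_svm <- function(x, y)
    e1071::svm(x, y, type = "eps-regression", kernel = "radial",
               gamma = gamma, cost = cost, epsilon = epsilon,
               scale = FALSE, fitted = FALSE)
  cv_rmse <- NA_real_
  if (opt$cv_folds > 0L) {
    ug <- unique(groups)
    fold_of_group <- ceiling(seq_along(ug) / length(ug) * opt$cv_folds)
    fold <- fold_of_group[match(groups, ug)]
    if (length(ug) < opt$cv_folds)
      fold <- ceiling(seq_len(n) / n * opt$cv_folds)
    sse <- 0
    for (f in unique(fold)) {
      hold <- fold == f
      m <- fit_svm(xs[!hold, , drop = FALSE], response[!hold])
      pr <- if (m$tot.nSV == 0L) rep(mean(response[!hold]), sum(hold))
            else stats::predict(m, xs[hold, , drop = FALSE])
      sse <- sse + sum((response[hold] - pr)^2)
    }
    cv_rmse <- sqrt(sse / n)
  }
  model <- fit_svm(xs, response)
  structure(list(svm = model, fallback = mean(response),
                 center = center, scale = scale_,
                 kernel_scale = kernel_scale, gamma = gamma, cost = cost,
                 epsilon = epsilon, cv_rmse = cv_rmse, n_train = n,
                 feature_names = colnames(features)),
            class = "regmod")
}

#' Predict the active moment with a trained regression model
#'
#' Applies the frozen training standardization and the fitted SVR to new
#' feature rows.  Features are instantaneous, so prediction is causal
#' sample by sample.
#'
#' @param model A `"regmod"`.
#' @param features N x 9 matrix with the training column schema.
#' @return Predicted active moment (N·m), length N.
#' @export
predict_regmod <- function(model, features) {
  if (!identical(colnames(features), model$feature_names))
    stop("input error: feature schema does not match training schema")
  xs <- sweep(sweep(features, 2, model$center), 2, model$scale, "/")
  # a response entirely inside the epsilon tube yields no support vectors;
  # the flat fit is then the response mean
  if (model$svm$tot.nSV == 0L) return(rep(model$fallback, nrow(xs)))
  as.numeric(stats::predict(model$svm, xs))
}

#' @export
print.regmod <- function(x, ...) {
  cat(sprintf(
    "<regmod: eps-SVR, %d SV, n_train %d, C %.3g, eps %.3g, cv RMSE %s>\n",
    x$svm$tot.nSV, x$n_train, x$cost, x$epsilon,
    ifelse(is.na(x$cv_rmse), "n/a", sprintf("%.2f", x$cv_rmse))))
  invisible(x)
}
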