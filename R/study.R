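# Calibration-set construction and the evaluation study: subset
# enumeration, the Selected family, Worst-selected and Quasi-static sets,
# the calibrate-train-predict pipeline per set, per-task-group RMSE
# pooling, and the two-way repeated-measures ANOVA with Bonferroni
# post-hoc comparisons.

#' Identifiers of the fourteen calibration conditions
#'
#' @return Character vector of length 14, in canonical order.
#' @export
calibration_condition_ids <- function() calibration_conditions()$condition_id

#' Enumerate all n-element calibration subsets
#'
#' All `choose(14, n)` subsets of the fourteen calibration conditions, in
#' deterministic (combinatorial) order.  Both repetitions of a chosen
#' condition are always included downstream.
#'
#' @param n Subset size, 1..14.
#' @return List of character vectors of condition ids.
#' @export
enumerate_subsets <- function(n) {
  ids <- calibration_condition_ids()
  if (n < 1 || n > length(ids))
    stop("parameter error: n must be in 1..", length(ids))
  m <- utils::combn(ids, n)
  lapply(seq_len(ncol(m)), function(j) m[, j])
}

VELOCITY_ORDER <- c(very_slow = 1, slow = 2, normal = 3, fast = 4)

# Does a set of condition ids satisfy the extreme-coverage criterion?
covers_extremes <- function(ids, cond = calibration_conditions()) {
  rows <- cond[match(ids, cond$condition_id), ]
  if (anyNA(rows$condition_id)) stop("unknown condition id")
  vr <- VELOCITY_ORDER[rows$velocity]
  all(c(7.5, 15) %in% rows$mass_kg) &&
    all(c("stoop", "squat") %in% rows$technique) &&
    min(vr) <= VELOCITY_ORDER[["slow"]] &&
    max(vr) == max(VELOCITY_ORDER[cond$velocity])
}

#' The Selected family of three-trial calibration sets
#'
#' All 3-element subsets of the fourteen calibration conditions that cover
#' both extremes of every lifting characteristic: both masses (7.5 and
#' 15 kg), both technique extremes (stoop and squat), and both velocity
#' extremes (a very-slow-or-slow trial and a trial of the fastest class
#' present in the battery).  Velocity classes are ordinal: very slow <
#' slow < normal < fast; since fast lifts exist only with the free
#' technique, the extreme-coverage rule applies to the set as a whole, not
#' per technique.
#'
#' @return Named list of character id triples (`sel_01`, `sel_02`, ...),
#'   deterministic order.
#' @export
selected_family <- function() {
  subs <- enumerate_subsets(3L)
  cond <- calibration_conditions()
  keep <- Filter(function(s) covers_extremes(s, cond), subs)
  keep <- keep[order(vapply(keep, paste, "", collapse = "+"))]
  names(keep) <- sprintf("sel_%02d", seq_along(keep))
  keep
}

#' The Quasi-static calibration set
#'
#' The two free-technique very-slow conditions (7.5 and 15 kg): trials in
#' which dynamically induced loads are minimal, so calibration could in
#' practice be done with reduced instrumentation.
#'
#' @return Character vector of the two condition ids.
#' @export
quasi_static_set <- function() {
  cond <- calibration_conditions()
  ids <- cond$condition_id[cond$technique == "free" &
                             cond$velocity == "very_slow"]
  if (length(ids) != 2L) stop("input error: quasi-static conditions missing")
  ids
}

# Default pipeline evaluation options.  The optimizer and row budgets are
# the package's study-scale settings; calibrate_emgmod() keeps its own,
# heavier defaults for one-off use.
study_options <- function(options = list()) {
  utils::modifyList(list(n_starts = 3L, maxit = 80L, stride = 2L,
                         seed = 1L, cv_folds = 0L, max_rows = 1000L,
                         test_stride = 2L, lowpass_hz = 5), options)
}

#' Prepare one subject's data for repeated calibration-set evaluation
#'
#' Derives, once per subject, everything the pipeline needs per trial:
#' lumbar kinematic signals, the reference human moment from bottom-up
#' inverse dynamics (minus any exoskeleton support), and the reduced
#' feature matrix.  Evaluating a calibration set then reduces to
#' concatenating cached arrays, which makes the subset sweep tractable.
#'
#' @param study A `"synthetic_study"` (or compatible list with `trials`,
#'   `subjects`, `manifest`).
#' @param subject_id Subject to prepare.
#' @param lowpass_hz Angle low-pass cutoff.
#' @return List of class `"subject_prep"`.
#' @export
prepare_subject_data <- function(study, subject_id, lowpass_hz = 5) {
  man <- study$manifest[study$manifest$subject_id == subject_id, ]
  if (!nrow(man)) stop("unknown subject ", subject_id)
  subj <- Find(function(s) s$subject_id == subject_id, study$subjects)
  geometry <- muscle_geometry(subj)
  prep_one <- function(tid) {
    tr <- study$trials[[tid]]
    ks <- trial_kinematic_signals(tr, lowpass_hz)
    ref <- human_moment(bottom_up_moment(tr, subj, lowpass_hz),
                        tr$exo_torque_nm)
    list(trial_id = tid, theta = ks$lumbar_flexion,
         theta_dot = ks$lumbar_velocity, emg = tr$emg,
         ref = ref$values_nm, features = build_features(tr, lowpass_hz),
         n = length(tr$time_s))
  }
  cal_man <- man[man$task_group == "calibration_lift", ]
  cal <- split(cal_man$trial_id, cal_man$condition_id)
  cal_data <- lapply(cal, function(tids) lapply(tids, prep_one))
  test_man <- man[man$task_group != "calibration_lift", ]
  test_data <- lapply(test_man$trial_id, prep_one)
  for (i in seq_along(test_data))
    test_data[[i]]$task_group <- test_man$task_group[i]
  structure(list(subject_id = subject_id, subject = subj,
                 geometry = geometry, cal = cal_data, test = test_data),
            class = "subject_prep")
}

#' Evaluate one calibration set on one subject
#'
#' Runs the full pipeline for a calibration set: calibrate the muscle
#' model on the set's trials against the inverse-dynamics human moment,
#' train the regression model on the same trials (response: the calibrated
#' muscle model's active moment), predict on every test trial, add the
#' muscle model's passive moment, and score both models with the RMSE
#' against the inverse-dynamics human moment per trial.
#'
#' @param prep A `"subject_prep"` from [prepare_subject_data()].
#' @param condition_ids Calibration condition ids in the set (both
#'   repetitions of each are used).
#' @param options Pipeline options (see Details of [train_regmod()] /
#'   [calibrate_emgmod()]); `test_stride` thins test rows for scoring.
#' @return List with `results` (data frame: trial_id, task_group, n,
#'   rmse_emgmod, rmse_regmod), `params`, `fit`, `model`.
#' @export
evaluate_calibration_set <- function(prep, condition_ids, options = list()) {
  opt <- study_options(options)
  if (!length(condition_ids)) stop("input error: empty calibration set")
  missing <- setdiff(condition_ids, names(prep$cal))
  if (length(missing))
    stop("input error: unknown condition(s): ",
         paste(missing, collapse = ", "))
  bundles <- unlist(prep$cal[condition_ids], recursive = FALSE)
  data <- list(theta = unlist(lapply(bundles, `[[`, "theta")),
               theta_dot = unlist(lapply(bundles, `[[`, "theta_dot")),
               emg = do.call(rbind, lapply(bundles, `[[`, "emg")),
               ref = unlist(lapply(bundles, `[[`, "ref")),
               dt = 1 / TRIAL_FS)
  fit <- calibrate_emgmod_data(data, prep$geometry, opt)
  p <- fit$params
  response <- active_moment(data$emg, data$theta, data$theta_dot, p,
                            prep$geometry)
  features <- do.call(rbind, lapply(bundles, `[[`, "features"))
  groups <- rep(vapply(bundles, `[[`, "", "trial_id"),
                vapply(bundles, `[[`, 0L, "n"))
  model <- train_regmod(features, response,
                        options = c(opt[c("cv_folds", "max_rows")],
                                    list(groups = groups)))
  res <- lapply(prep$test, function(te) {
    idx <- seq(1L, te$n, by = opt$test_stride)
    pas <- passive_moment(te$theta[idx], p, prep$geometry)
    act_emg <- active_moment(te$emg[idx, , drop = FALSE], te$theta[idx],
                             te$theta_dot[idx], p, prep$geometry)
    act_reg <- predict_regmod(model, te$features[idx, , drop = FALSE])
    ref <- te$ref[idx]
    data.frame(trial_id = te$trial_id, task_group = te$task_group,
               n = length(idx),
               rmse_emgmod = sqrt(mean((ref - act_emg - pas)^2)),
               rmse_regmod = sqrt(mean((ref - act_reg - pas)^2)),
               stringsAsFactors = FALSE)
  })
  list(results = do.call(rbind, res), params = p, fit = fit, model = model)
}

#' Pick the Worst-selected calibration set
#'
#' The Selected-family member with the largest across-subject mean
#' regression-model RMSE over all test trials; ties are broken by set
#' label.
#'
#' @param family_results Data frame with columns `set` and `rmse_regmod`
#'   (per subject and test trial).
#' @return The label of the worst member.
#' @export
worst_selected <- function(family_results) {
  if (!nrow(family_results)) stop("input error: empty family results")
  agg <- stats::aggregate(rmse_regmod ~ set, family_results, mean)
  agg <- agg[order(-agg$rmse_regmod, agg$set), ]
  agg$set[1]
}

#' Pool RMSEs by task group
#'
#' Pools per-trial errors within subject x calibration set x model x task
#' group as the root of the sample-weighted mean squared error (so
#' concatenating the group's samples and recomputing the RMSE gives the
#' same value).
#'
#' @param results Data frame with `subject_id`, `set`, `task_group`, `n`,
#'   `rmse_emgmod`, `rmse_regmod`.
#' @return Long data frame: `subject_id`, `set`, `task_group`, `model`,
#'   `rmse`.
#' @export
task_group_rmse <- function(results) {
  if (!all(results$task_group %in% TASK_GROUPS))
    stop("input error: unknown task group")
  out <- list()
  for (model in c("emgmod", "regmod")) {
    col <- paste0("rmse_", model)
    sse <- stats::aggregate(
      cbind(wsq = results[[col]]^2 * results$n, n = results$n) ~
        subject_id + set + task_group, data = results, FUN = sum)
    out[[model]] <- data.frame(sse[c("subject_id", "set", "task_group")],
                               model = model,
                               rmse = sqrt(sse$wsq / sse$n),
                               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-way repeated-measures ANOVA with Bonferroni post-hocs
#'
#' Classical sums-of-squares decomposition for a complete balanced
#' within-subject design with two factors: each effect is tested against
#' its interaction with subjects (no sphericity correction).  Post-hoc
#' pairwise comparisons of each factor's levels use paired t-tests on the
#' subject-level means with Bonferroni adjustment
#' `p_adj = min(1, p * m)` over the `m` comparisons in that family.
#'
#' @param data Data frame in long format.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject column.
#' @param factors Character vector of the two within-subject factor
#'   columns.
#' @param alpha Significance level used for flagging (default 0.05).
#' @return List of class `"rm_anova"` with `table` (effect, df, SS, MS, F,
#'   p) and `posthoc`.
#' @export
rm_anova <- function(data, dv, subject, factors, alpha = 0.05) {
  stopifnot(length(factors) == 2L)
  y <- data[[dv]]
  s <- factor(data[[subject]])
  A <- factor(data[[factors[1]]])
  B <- factor(data[[factors[2]]])
  tab <- table(s, A, B)
  if (any(tab != 1L)) {
    miss <- which(tab == 0L, arr.ind = TRUE)
    stop("input error: unbalanced design; missing/duplicated cells: ",
         paste(apply(miss, 1, function(r)
       paste(dimnames(tab)[[1]][r[1]], dimnames(tab)[[2]][r[2]],
             dimnames(tab)[[3]][r[3]], sep = ":")), collapse = ", "))
  }
  ns <- nlevels(s); na <- nlevels(A); nb <- nlevels(B)
  gm <- mean(y)
  ssfun <- function(means, mult) mult * sum((means - gm)^2)
  m_a <- tapply(y, A, mean); m_b <- tapply(y, B, mean)
  m_s <- tapply(y, s, mean)
  m_ab <- tapply(y, list(A, B), mean)
  m_as <- tapply(y, list(A, s), mean)
  m_bs <- tapply(y, list(B, s), mean)
  ss_a <- ssfun(m_a, ns * nb)
  ss_b <- ssfun(m_b, ns * na)
  ss_s <- ssfun(m_s, na * nb)
  ss_ab <- ssfun(m_ab, ns) - ss_a - ss_b
  ss_as <- ssfun(m_as, nb) - ss_a - ss_s
  ss_bs <- ssfun(m_bs, na) - ss_b - ss_s
  ss_tot <- sum((y - gm)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_s - ss_ab - ss_as - ss_bs
  eff <- data.frame(
    effect = c(factors[1], factors[2], paste(factors, collapse = ":")),
    df1 = c(na - 1, nb - 1, (na - 1) * (nb - 1)),
    df2 = c((na - 1) * (ns - 1), (nb - 1) * (ns - 1),
            (na - 1) * (nb - 1) * (ns - 1)),
    ss = c(ss_a, ss_b, ss_ab),
    ss_error = c(ss_as, ss_bs, ss_abs),
    stringsAsFactors = FALSE)
  eff$ms <- eff$ss / eff$df1
  eff$ms_error <- eff$ss_error / eff$df2
  eff$f <- ifelse(eff$ms_error > 0, eff$ms / eff$ms_error,
                  ifelse(eff$ms > 0, Inf, 0))
  eff$p <- stats::pf(eff$f, eff$df1, eff$df2, lower.tail = FALSE)
  eff$p[eff$f == 0] <- 1
  posthoc <- list()
  for (k in 1:2) {
    fac <- list(A, B)[[k]]
    lev <- levels(fac)
    if (length(lev) < 2L) next
    prs <- utils::combn(lev, 2)
    m <- ncol(prs)
    rows <- lapply(seq_len(m), function(j) {
      y1 <- tapply(y[fac == prs[1, j]], s[fac == prs[1, j]], mean)
      y2 <- tapply(y[fac == prs[2, j]], s[fac == prs[2, j]], mean)
      tt <- stats::t.test(y1, y2, paired = TRUE)
      data.frame(factor = factors[k], level_1 = prs[1, j],
                 level_2 = prs[2, j], estimate = mean(y1 - y2),
                 p_raw = tt$p.value,
                 p_adj = min(1, tt$p.value * m),
                 stringsAsFactors = FALSE)
    })
    posthoc[[factors[k]]] <- do.call(rbind, rows)
  }
  posthoc <- do.call(rbind, posthoc)
  rownames(posthoc) <- NULL
  posthoc$significant <- posthoc$p_adj < alpha
  structure(list(table = eff, posthoc = posthoc, alpha = alpha,
                 n_subjects = ns),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Two-way repeated-measures ANOVA (", x$n_subjects, "subjects )\n")
  print(cbind(x$table[c("effect", "df1", "df2")],
              round(x$table[c("ss", "ms", "f", "p")], 4)))
  invisible(x)
}

#' Run the complete calibration-set study
#'
#' Generates (or takes) a synthetic cohort, runs the pipeline for the Full
#' set, every Selected-family member and the Quasi-static set on every
#' subject, identifies the Worst-selected member, pools RMSEs by task
#' group, and runs the two-way repeated-measures ANOVA (calibration set x
#' task group) per model.  Optionally sweeps all calibration subsets of
#' size `1..sweep_max_n` (on `sweep_subjects` subjects) to locate the
#' minimum number of calibration trials that approaches the Full-set
#' accuracy.
#'
#' @param n_subjects Number of synthetic subjects.
#' @param seed Master seed.
#' @param noise Use the default noise model (`TRUE`) or exact noise-free
#'   data.
#' @param sweep Run the subset-size sweep (expensive).
#' @param sweep_max_n Largest subset size in the sweep.
#' @param sweep_subjects Number of subjects used in the sweep (default:
#'   all).
#' @param options Pipeline options overriding the study defaults.
#' @param sweep_options Lighter pipeline options for the subset sweep
#'   (default: `options` plus a reduced optimizer/row budget, since the
#'   sweep evaluates every one of the 469 subsets of size 1..3 per
#'   subject).
#' @param study Optional pre-generated `"synthetic_study"` (overrides
#'   `n_subjects`/`seed`/`noise`).
#' @param out_dir Optional directory: writes the long results table, the
#'   task-group table, ANOVA summaries and a run log as CSV/text.
#' @return List of class `"study_result"`.
#' @export
run_study <- function(n_subjects = 10, seed = 1L, noise = TRUE,
                      sweep = FALSE, sweep_max_n = 3L,
                      sweep_subjects = NULL, options = list(),
                      sweep_options = NULL, study = NULL, out_dir = NULL) {
  opt <- study_options(options)
  sw_opt <- study_options(utils::modifyList(
    list(n_starts = 2L, maxit = 50L, stride = 3L, test_stride = 3L,
         max_rows = 700L), sweep_options %||% options))
  if (is.null(study))
    study <- generate_study(n_subjects, seed, noise)
  subject_ids <- vapply(study$subjects, `[[`, "", "subject_id")
  preps <- lapply(subject_ids, function(sid)
    prepare_subject_data(study, sid, opt$lowpass_hz))
  names(preps) <- subject_ids

  family <- selected_family()
  sets <- c(list(full = calibration_condition_ids(),
                 quasi_static = quasi_static_set()), family)
  rows <- list()
  for (sid in subject_ids) {
    for (lab in names(sets)) {
      ev <- evaluate_calibration_set(preps[[sid]], sets[[lab]], opt)
      rows[[length(rows) + 1L]] <- data.frame(subject_id = sid, set = lab,
                                              ev$results,
                                              stringsAsFactors = FALSE)
    }
  }
  trial_results <- do.call(rbind, rows)
  fam_rows <- trial_results[trial_results$set %in% names(family), ]
  worst <- worst_selected(fam_rows)
  wrows <- trial_results[trial_results$set == worst, ]
  wrows$set <- "worst_selected"
  trial_results <- rbind(trial_results, wrows)

  set_means <- stats::aggregate(
    cbind(rmse_emgmod, rmse_regmod) ~ set, trial_results, mean)
  anova_rows <- trial_results[
    trial_results$set %in% c("full", "worst_selected", "quasi_static"), ]
  task_table <- task_group_rmse(anova_rows)
  anova <- lapply(c(emgmod = "emgmod", regmod = "regmod"), function(mod)
    rm_anova(task_table[task_table$model == mod, ], "rmse", "subject_id",
             c("set", "task_group")))

  sweep_summary <- NULL
  if (sweep) {
    sw_ids <- subject_ids[seq_len(min(length(subject_ids),
                                      sweep_subjects %||%
                                        length(subject_ids)))]
    sw <- list()
    for (n in seq_len(sweep_max_n)) {
      subs <- enumerate_subsets(n)
      means <- vapply(subs, function(ids) {
        mean(vapply(sw_ids, function(sid)
          mean(evaluate_calibration_set(preps[[sid]], ids,
                                        sw_opt)$results$rmse_regmod),
          numeric(1)))
      }, numeric(1))
      sw[[n]] <- data.frame(
        n = n, n_subsets = length(subs), best_rmse = min(means),
        mean_rmse = mean(means), worst_rmse = max(means),
        best_subset = paste(subs[[which.min(means)]], collapse = "+"))
    }
    sweep_summary <- do.call(rbind, sw)
    sweep_summary$full_rmse <- mean(
      trial_results$rmse_regmod[trial_results$set == "full" &
                                  trial_results$subject_id %in% sw_ids])
  }
  res <- structure(
    list(trial_results = trial_results, set_means = set_means,
         task_table = task_table, anova = anova,
         worst_selected = worst, family = family,
         sweep = sweep_summary,
         config = list(n_subjects = length(subject_ids), seed = study$seed,
                       noise = study$noise, options = opt)),
    class = "study_result")
  if (!is.null(out_dir)) write_study_result(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_study_result <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$trial_results,
                   file.path(out_dir, "trial_results.csv"),
                   row.names = FALSE)
  utils::write.csv(res$task_table, file.path(out_dir, "task_group_rmse.csv"),
                   row.names = FALSE)
  for (mod in names(res$anova))
    utils::write.csv(res$anova[[mod]]$table,
                     file.path(out_dir, paste0("anova_", mod, ".csv")),
                     row.names = FALSE)
  if (!is.null(res$sweep))
    utils::write.csv(res$sweep, file.path(out_dir, "subset_sweep.csv"),
                     row.names = FALSE)
  grDevices::pdf(file.path(out_dir, "figures.pdf"), width = 7, height = 5)
  plot_task_rmse(res)
  if (!is.null(res$sweep)) plot_sweep(res)
  grDevices::dev.off()
  log <- c(sprintf("subjects: %d", res$config$n_subjects),
           sprintf("seed: %d", res$config$seed),
           sprintf("noise: %s", res$config$noise),
           sprintf("worst_selected: %s", res$worst_selected),
           sprintf("generated: %s", format(Sys.time())))
  writeLines(log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Grouped-bar plot of task-group RMSEs per calibration set
#'
#' Mirrors the task-specific summary of the study: mean across-subject
#' RMSE per task group, grouped by calibration set, one panel per model.
#'
#' @param res A `"study_result"`.
#' @return Invisibly, the plotted matrix list.
#' @export
plot_task_rmse <- function(res) {
  tt <- res$task_table
  out <- list()
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  for (mod in c("emgmod", "regmod")) {
    d <- tt[tt$model == mod, ]
    m <- tapply(d$rmse, list(d$set, d$task_group), mean)
    graphics::barplot(m, beside = TRUE, las = 2,
                      ylab = "RMSE (N·m)", main = mod,
                      legend.text = rownames(m),
                      args.legend = list(cex = 0.6, x = "topleft"))
    out[[mod]] <- m
  }
  invisible(out)
}

#' RMSE versus number of calibration trials
#'
#' Best, mean and worst across-subset regression RMSE as a function of the
#' calibration-set size, with the Full-set level as a dashed reference
#' line.
#'
#' @param res A `"study_result"` produced with `sweep = TRUE`.
#' @return Invisibly, the sweep table.
#' @export
plot_sweep <- function(res) {
  sw <- res$sweep
  if (is.null(sw)) stop("study was run without the subset sweep")
  graphics::matplot(sw$n, sw[c("best_rmse", "mean_rmse", "worst_rmse")],
                    type = "b", pch = 1:3, lty = 1, xlab = "trials in set",
                    ylab = "RegMod RMSE (N·m)", xaxt = "n")
  graphics::axis(1, at = sw$n)
  graphics::abline(h = sw$full_rmse[1], lty = 2)
  graphics::legend("topright", c("best", "mean", "worst", "full"),
                   pch = c(1:3, NA), lty = c(1, 1, 1, 2), cex = 0.8)
  invisible(sw)
}

#' @export
print.study_result <- function(x, ...) {
  cat("Calibration-set study:", x$config$n_subjects, "subjects, seed",
      x$config$seed, "\n\nMean RMSE (N·m) over all test trials:\n")
  sm <- x$set_means
  keep <- sm$set %in% c("full", "worst_selected", "quasi_static")
  fam <- sm[!keep & sm$set != "full", ]
  print(cbind(sm[keep, "set", drop = FALSE],
              round(sm[keep, c("rmse_emgmod", "rmse_regmod")], 2)),
        row.names = FALSE)
  if (nrow(fam))
    cat(sprintf("Selected family (%d sets): RegMod RMSE %.2f-%.2f N·m\n",
                nrow(fam), min(fam$rmse_regmod), max(fam$rmse_regmod)))
  if (!is.null(x$sweep)) {
    cat("\nSubset sweep (best/mean RegMod RMSE by n):\n")
    print(round(x$sweep[c("n", "best_rmse", "mean_rmse", "full_rmse")], 2),
          row.names = FALSE)
  }
  invisible(x)
}
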