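test_that("subset enumeration matches binomial coefficients", {
  expect_length(enumerate_subsets(1), 14L)
  expect_length(enumerate_subsets(2), choose(14, 2))
  expect_length(enumerate_subsets(3), 364L)
  s14 <- enumerate_subsets(14)
  expect_length(s14, 1L)
  expect_setequal(s14[[1]], calibration_condition_ids())
  expect_error(enumerate_subsets(0), "parameter")
  expect_error(enumerate_subsets(15), "parameter")
})

test_that("the Selected family equals a brute-force filter", {
  # independent oracle: filter all 364 triples directly on the published
  # criterion (both masses, stoop and squat, a very-slow-or-slow trial and
  # a fast trial)
  cond <- calibration_conditions()
  cmb <- utils::combn(cond$condition_id, 3)
  oracle <- list()
  for (j in seq_len(ncol(cmb))) {
    rows <- cond[cond$condition_id %in% cmb[, j], ]
    if (all(c(7.5, 15) %in% rows$mass_kg) &&
        all(c("stoop", "squat") %in% rows$technique) &&
        any(rows$velocity %in% c("very_slow", "slow")) &&
        "fast" %in% rows$velocity)
      oracle[[length(oracle) + 1L]] <- sort(cmb[, j])
  }
  fam <- selected_family()
  expect_length(fam, length(oracle))
  expect_setequal(vapply(fam, function(s) paste(sort(s), collapse = "+"),
                         ""),
                  vapply(oracle, paste, "", collapse = "+"))
  expect_true(all(lengths(fam) == 3L))

  # worked membership examples
  member <- c("stoop_15_slow", "squat_7p5_slow", "free_7p5_fast")
  expect_true(any(vapply(fam, setequal, TRUE, member)))
  non_member <- c("stoop_15_normal", "squat_7p5_normal",
                  "free_7p5_normal")
  expect_false(any(vapply(fam, setequal, TRUE, non_member)))
})

test_that("the quasi-static set is the two very-slow free lifts", {
  qs <- quasi_static_set()
  expect_length(qs, 2L)
  cond <- calibration_conditions()
  rows <- cond[match(qs, cond$condition_id), ]
  expect_true(all(rows$technique == "free"))
  expect_true(all(rows$velocity == "very_slow"))
  expect_setequal(rows$mass_kg, c(7.5, 15))
})

test_that("task-group pooling is the sample-weighted root mean square", {
  one <- data.frame(subject_id = "S01", set = "full",
                    task_group = "exo_lift", trial_id = "t1", n = 100L,
                    rmse_emgmod = 3, rmse_regmod = 4)
  out <- task_group_rmse(one)
  expect_equal(out$rmse[out$model == "regmod"], 4)
  two <- rbind(one, within(one, {
    trial_id <- "t2"; rmse_regmod <- 6; rmse_emgmod <- 5
  }))
  out2 <- task_group_rmse(two)
  expect_equal(out2$rmse[out2$model == "regmod"], sqrt((4^2 + 6^2) / 2))
  expect_equal(out2$rmse[out2$model == "emgmod"], sqrt((3^2 + 5^2) / 2))
  bad <- one; bad$task_group <- "warmup"
  expect_error(task_group_rmse(bad), "task group")
})

test_that("the worst Selected member maximizes the across-subject mean", {
  res <- data.frame(set = rep(c("sel_01", "sel_02", "sel_03"), each = 4),
                    rmse_regmod = c(1, 2, 3, 4, 9, 9, 9, 9, 2, 2, 2, 2))
  expect_identical(worst_selected(res), "sel_02")
  expect_identical(worst_selected(res[1:4, ]), "sel_01")
  agg <- aggregate(rmse_regmod ~ set, res, mean)
  expect_true(all(agg$rmse_regmod[agg$set == worst_selected(res)] >=
                    agg$rmse_regmod))
  expect_error(worst_selected(res[0, ]), "empty")
  # ties break lexicographically
  tie <- data.frame(set = c("sel_09", "sel_02"), rmse_regmod = c(5, 5))
  expect_identical(worst_selected(tie), "sel_02")
})

test_that("repeated-measures ANOVA reproduces hand-computed sums of squares", {
  # 3 subjects x 2 x 2 fixture; all SS computed by hand from cell means
  fx <- expand.grid(subject = c("s1", "s2", "s3"), A = c("a1", "a2"),
                    B = c("b1", "b2"), stringsAsFactors = FALSE)
  fx$y <- c(10, 11, 12, 14, 15, 16, 12, 13, 14, 18, 19, 23)
  out <- rm_anova(fx, "y", "subject", c("A", "B"))
  tab <- out$table
  expect_equal(tab$ss, c(90.75, 36.75, 6.75))
  expect_equal(tab$ss_error, c(1.5, 1.5, 1.5))
  expect_equal(tab$f, c(121, 49, 9))
  expect_equal(tab$df1, c(1, 1, 1))
  expect_equal(tab$df2, c(2, 2, 2))
  expect_equal(tab$p, pf(c(121, 49, 9), 1, 2, lower.tail = FALSE))

  # independent cross-check against the stock aov error decomposition
  fit <- stats::aov(y ~ A * B + Error(subject / (A * B)), data = fx)
  sm <- summary(fit)
  f_aov <- c(sm[["Error: subject:A"]][[1]]["A", "F value"],
             sm[["Error: subject:B"]][[1]]["B", "F value"],
             sm[["Error: subject:A:B"]][[1]]["A:B", "F value"])
  expect_equal(tab$f, unname(f_aov), tolerance = 1e-10)
})

test_that("ANOVA degenerate and malformed inputs are handled", {
  fx <- expand.grid(subject = c("s1", "s2", "s3"), A = c("a1", "a2"),
                    B = c("b1", "b2"), stringsAsFactors = FALSE)
  fx$y <- 7
  out <- rm_anova(fx, "y", "subject", c("A", "B"))
  expect_equal(out$table$f, c(0, 0, 0))
  expect_equal(out$table$p, c(1, 1, 1))
  expect_error(rm_anova(fx[-1, ], "y", "subject", c("A", "B")),
               "unbalanced")
})

test_that("Bonferroni adjustment is min(1, m * p)", {
  set.seed(9)
  fx <- expand.grid(subject = paste0("s", 1:6), A = c("a1", "a2", "a3"),
                    B = c("b1", "b2"), stringsAsFactors = FALSE)
  fx$y <- rnorm(nrow(fx)) + (fx$A == "a2") * 2
  out <- rm_anova(fx, "y", "subject", c("A", "B"))
  ph <- out$posthoc
  phA <- ph[ph$factor == "A", ]
  expect_identical(nrow(phA), 3L)        # choose(3, 2) comparisons
  expect_equal(phA$p_adj, pmin(1, phA$p_raw * 3))
  phB <- ph[ph$factor == "B", ]
  expect_equal(phB$p_adj, pmin(1, phB$p_raw * 1))
})

test_that("the noise-free pipeline is exact and deterministic", {
  st <- generate_study(1, seed = 5L, noise = FALSE)
  prep <- prepare_subject_data(st, "S01")
  opts <- list(n_starts = 2L, maxit = 120L, stride = 2L)
  ev <- evaluate_calibration_set(prep, calibration_condition_ids(), opts)
  # with exact data the muscle model reproduces the reference on every
  # test trial
  expect_lt(max(ev$results$rmse_emgmod), 1)
  ev2 <- evaluate_calibration_set(prep, calibration_condition_ids(), opts)
  expect_identical(ev$results, ev2$results)
  expect_error(evaluate_calibration_set(prep, character(0)), "empty")
  expect_error(evaluate_calibration_set(prep, "nonexistent"), "unknown")
})
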