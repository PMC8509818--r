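test_that("LOOCV scores separate well-separated classes with the right sign", {
  d <- separable_data(n_per = 10)
  sc <- loocv_scores(d$x, d$labels)
  expect_true(all(sc[d$labels == "CTS"] > 0))
  expect_true(all(sc[d$labels == "non-CTS"] < 0))

  # duplicating every subject leaves each original score's sign unchanged
  d2x <- rbind(d$x, d$x); d2l <- c(d$labels, d$labels)
  sc2 <- loocv_scores(d2x, d2l)[seq_along(sc)]
  expect_identical(sign(sc2), sign(sc))

  expect_error(loocv_scores(d$x, rep("CTS", 20)), "both classes")
  expect_error(loocv_scores(d$x[1:2, , drop = FALSE], d$labels[1:2]),
               "at least 3")
  xna <- d$x; xna[1] <- NA
  expect_error(loocv_scores(xna, d$labels), "non-finite")
})

test_that("permuted labels destroy discrimination", {
  # Note: LOOCV decision scores under balanced permuted labels are biased
  # BELOW 0.5 (holding out a subject makes its class the fold minority, the
  # classic LOOCV anti-learning artifact); an independent scikit-learn LOOCV
  # run on this exact data shows the same sub-0.5 mean. The meaningful
  # property is that no discrimination survives the permutation.
  d <- separable_data(n_per = 10)
  true_auc <- roc_analysis(loocv_scores(d$x, d$labels), d$labels)$auc
  expect_equal(true_auc, 1)
  set.seed(99)
  aucs <- vapply(1:20, function(i) {
    labs <- sample(d$labels)
    roc_analysis(loocv_scores(d$x, labs), labs)$auc
  }, numeric(1))
  expect_lte(mean(aucs), 0.65)
  expect_lt(mean(aucs), true_auc - 0.3)
})

test_that("ROC analysis reproduces hand-counted AUC and degenerate cases", {
  scores <- c(0.1, 0.2, 0.35, 0.4, 0.8)
  labels <- c("non-CTS", "non-CTS", "CTS", "non-CTS", "CTS")
  rep1 <- roc_analysis(scores, labels)
  expect_equal(rep1$auc, 5 / 6)   # 5 concordant of 6 pos-neg pairs
  expect_equal(rep1$roc$fpr[1], 0); expect_equal(rep1$roc$tpr[1], 0)
  expect_equal(rep1$roc$fpr[nrow(rep1$roc)], 1)
  expect_equal(rep1$roc$tpr[nrow(rep1$roc)], 1)
  expect_true(all(diff(rep1$roc$fpr) >= 0), all(diff(rep1$roc$tpr) >= 0))

  # perfectly ordered scores
  rep2 <- roc_analysis(c(-3, -2, -1, 1, 2, 3),
                       rep(c("non-CTS", "CTS"), each = 3))
  expect_equal(rep2$auc, 1)
  expect_equal(rep2$sensitivity, 1)
  expect_equal(rep2$specificity, 1)
  expect_equal(rep2$accuracy, 1)

  # constant scores: valid degenerate report with a warning
  expect_warning(rep3 <- roc_analysis(rep(1, 6),
                                      rep(c("non-CTS", "CTS"), 3)),
                 "degenerate")
  expect_equal(rep3$auc, 0.5)
  expect_true(rep3$degenerate)
})

test_that("trapezoid AUC equals pairwise concordance on random score sets", {
  for (s in 1:20) {
    set.seed(s)
    n <- sample(6:40, 1)
    labels <- c("non-CTS", "CTS",
                sample(c("non-CTS", "CTS"), n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)   # coarse rounding forces ties
    rep_s <- suppressWarnings(roc_analysis(scores, labels))
    expect_equal(rep_s$auc, concordance_auc(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("ROC agrees with an established implementation", {
  set.seed(123)
  scores <- rnorm(40)
  labels <- sample(c("non-CTS", "CTS"), 40, replace = TRUE,
                   prob = c(0.5, 0.5))
  rep1 <- roc_analysis(scores, labels)
  ref <- pROC::roc(response = labels, predictor = scores,
                   levels = c("non-CTS", "CTS"), direction = "<",
                   quiet = TRUE)
  expect_equal(rep1$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("ROC, AUC and operating point are invariant to monotone score maps", {
  set.seed(8)
  scores <- rnorm(30)
  labels <- sample(c("non-CTS", "CTS"), 30, replace = TRUE)
  if (length(unique(labels)) < 2) labels[1:2] <- c("non-CTS", "CTS")
  a <- roc_analysis(scores, labels)
  b <- roc_analysis(exp(2 * scores) + 5, labels)   # strictly increasing map
  expect_equal(a$auc, b$auc, tolerance = 1e-12)
  expect_equal(a$roc$fpr, b$roc$fpr); expect_equal(a$roc$tpr, b$roc$tpr)
  expect_equal(a$sensitivity, b$sensitivity)
  expect_equal(a$specificity, b$specificity)

  # swapping class labels maps AUC to its complement
  swapped <- ifelse(labels == "CTS", "non-CTS", "CTS")
  expect_equal(roc_analysis(scores, swapped)$auc, 1 - a$auc,
               tolerance = 1e-12)
})

test_that("hyperparameter tuning minimizes the distance to the ROC corner", {
  d <- separable_data(n_per = 8)
  single <- tune_model(d$x, d$labels, degree_grid = 2, c_grid = 0.5)
  expect_equal(single$kernel_degree, 2L)
  expect_equal(single$regularization, 0.5)

  best <- tune_model(d$x, d$labels, degree_grid = 1:2, c_grid = c(0.1, 1))
  expect_equal(attr(best, "criterion"), 0)   # separable: perfect corner

  # exhaustive re-evaluation oracle: no grid point beats the winner
  grid <- attr(best, "grid")
  for (i in seq_len(nrow(grid))) {
    cfg <- model_config(kernel_degree = grid$degree[i],
                        regularization = grid$C[i])
    rep_i <- roc_analysis(loocv_scores(d$x, d$labels, cfg), d$labels)
    crit <- sqrt((1 - rep_i$sensitivity)^2 + (1 - rep_i$specificity)^2)
    expect_gte(crit + 1e-12, attr(best, "criterion"))
    expect_equal(crit, grid$criterion[i], tolerance = 1e-12)
  }
  expect_error(tune_model(d$x, d$labels, integer(0), 1), "empty")
})

test_that("cts_screen fit object supports print, summary, plot and predict", {
  d <- separable_data(n_per = 8)
  fit <- cts_screen(d$x, d$labels)
  expect_s3_class(fit, "cts_screen")
  expect_output(print(fit), "LOOCV AUC")
  expect_output(summary(fit), "confusion")
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(fit))
  pr <- predict(fit, matrix(c(-1, 1), ncol = 1))
  expect_identical(as.character(pr$class), c("non-CTS", "CTS"))
})

test_that("the combination grid covers all 15 subsets consistently", {
  set.seed(77)
  bundles <- c(lapply(1:6, function(i) make_bundle(paste0("n", i), "non-CTS",
                                                   k = 8, seed = i)),
               lapply(1:6, function(i) make_bundle(paste0("c", i), "CTS",
                                                   k = 8, seed = 100 + i)))
  grid <- combination_grid(bundles)
  expect_equal(nrow(grid), 15)
  expect_identical(grid$combination[1:5],
                   c("1", "2", "3", "4", "1+2"))
  expect_identical(grid$combination[15], "1+2+3+4")
  expect_true(all(grid$auc >= 0 & grid$auc <= 1))

  # compositional oracle: row "2" equals a standalone run on set 2
  m2 <- bundle_to_matrix(bundles, 2)
  solo <- cts_screen(m2$x, m2$labels)
  row2 <- grid[grid$combination == "2", ]
  expect_equal(row2$auc, solo$report$auc)
  expect_equal(row2$sensitivity, 100 * solo$report$sensitivity)
  expect_equal(row2$specificity, 100 * solo$report$specificity)
  expect_equal(row2$accuracy, 100 * solo$report$accuracy)

  # identical rerun gives identical metrics
  grid2 <- combination_grid(bundles)
  expect_equal(as.data.frame(grid), as.data.frame(grid2))
})
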