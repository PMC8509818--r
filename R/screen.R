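#' SVM model configuration for the screening classifier
#'
#' The screening classifier is a soft-margin SVM with a polynomial kernel
#' \eqn{(\gamma u'v + c_0)^{degree}}; the kernel degree and the regularization
#' parameter C are the tuned hyperparameters. Feature columns are z-scored on
#' each training fold by default, because the spectral magnitudes, the RMSE
#' (cm) and the maximum pressure (device units) live on very different scales;
#' the standardization is fitted on the training fold only and applied to the
#' held-out subject, so no information leaks across folds.
#'
#' @param kernel_degree polynomial degree (>= 1).
#' @param regularization soft-margin cost C (> 0).
#' @param kernel \code{"polynomial"} (default) or \code{"radial"}.
#' @param coef0 kernel offset c0 (default 1, the inhomogeneous polynomial).
#' @param gamma kernel scale; \code{NULL} = 1/d (the libsvm default).
#' @param standardize z-score columns per training fold (default TRUE).
#' @return an object of class \code{model_config}.
#' @export
model_config <- function(kernel_degree = 3L, regularization = 1,
                         kernel = c("polynomial", "radial"),
                         coef0 = 1, gamma = NULL, standardize = TRUE) {
  kernel <- match.arg(kernel)
  if (kernel_degree < 1L) stop("kernel_degree must be >= 1")
  if (regularization <= 0) stop("regularization must be > 0")
  structure(list(kernel_degree = as.integer(kernel_degree),
                 regularization = regularization, kernel = kernel,
                 coef0 = coef0, gamma = gamma, standardize = standardize),
            class = "model_config")
}

as_screen_labels <- function(labels) {
  if (!is.factor(labels)) labels <- factor(labels, levels = c("non-CTS", "CTS"))
  else labels <- factor(as.character(labels), levels = c("non-CTS", "CTS"))
  if (anyNA(labels)) stop("labels must be 'non-CTS' or 'CTS'")
  labels
}

# train an SVM with optional fold-local standardization
fit_screen_svm <- function(x, y, config) {
  mu <- rep(0, ncol(x)); sdv <- rep(1, ncol(x))
  if (config$standardize) {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    sdv[!is.finite(sdv) | sdv == 0] <- 1
    x <- scale(x, center = mu, scale = sdv)
  }
  gamma <- if (is.null(config$gamma)) 1 / ncol(x) else config$gamma
  model <- e1071::svm(x, y, kernel = config$kernel,
                      degree = config$kernel_degree,
                      cost = config$regularization,
                      coef0 = config$coef0, gamma = gamma,
                      scale = FALSE)
  list(model = model, mu = mu, sd = sdv)
}

# signed decision value oriented so larger = more CTS-like
svm_score <- function(fit, xnew) {
  xs <- scale(xnew, center = fit$mu, scale = fit$sd)
  pred <- stats::predict(fit$model, xs, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  pos_class <- strsplit(colnames(dv)[1], "/", fixed = TRUE)[[1]][1]
  if (identical(pos_class, "CTS")) as.numeric(dv) else -as.numeric(dv)
}

#' Leave-one-out cross-validated decision scores
#'
#' For each subject, an SVM is trained on the remaining n - 1 subjects (with
#' per-fold standardization if enabled) and the held-out subject's signed
#' decision value is recorded, oriented so that larger scores indicate the
#' CTS class. Deterministic given the data and configuration.
#'
#' @param x n-by-d numeric feature matrix.
#' @param labels vector/factor of \code{"non-CTS"} / \code{"CTS"}.
#' @param config a \code{model_config}.
#' @return numeric vector of n decision scores (names = row names of x).
#' @export
loocv_scores <- function(x, labels, config = model_config()) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("non-finite feature values")
  labels <- as_screen_labels(labels)
  n <- nrow(x)
  if (n < 3L) stop("need at least 3 subjects for LOOCV")
  if (length(labels) != n) stop("labels length must match rows of x")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  scores <- vapply(seq_len(n), function(i) {
    fit <- fit_screen_svm(x[-i, , drop = FALSE], droplevels(labels[-i]), config)
    svm_score(fit, x[i, , drop = FALSE])
  }, numeric(1))
  names(scores) <- rownames(x)
  scores
}

#' ROC analysis of decision scores
#'
#' Sweeps a threshold over the unique scores (rule: score >= threshold is
#' called CTS), builds the ROC curve, integrates the AUC by the trapezoid
#' rule, and selects the operating cutoff as the threshold whose ROC point
#' is closest (Euclidean) to the ideal top-left corner (0, 1); ties are
#' broken toward higher sensitivity, the screening-appropriate direction.
#'
#' @param scores numeric decision scores, larger = more CTS-like.
#' @param labels vector/factor of \code{"non-CTS"} / \code{"CTS"}.
#' @return object of class \code{eval_report}: list with \code{roc}
#'   (data.frame threshold, fpr, tpr), \code{auc}, \code{cutoff},
#'   \code{sensitivity}, \code{specificity}, \code{accuracy} (fractions),
#'   \code{degenerate} (TRUE when all scores are tied).
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as_screen_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  pos <- labels == "CTS"
  if (!any(pos) || all(pos)) stop("both classes must be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  k <- nrow(roc)
  auc <- sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-k]) / 2)
  degenerate <- length(thr) == 1L
  if (degenerate)
    warning("constant decision scores: ROC is degenerate (AUC 0.5)")
  # cutoff among the real thresholds, closest to (0, 1)
  dist2 <- fpr^2 + (1 - tpr)^2
  best <- which(dist2 == min(dist2))
  if (length(best) > 1L) best <- best[which.max(tpr[best])]
  cutoff <- thr[best]
  pred_pos <- scores >= cutoff
  sens <- mean(pred_pos[pos]); spec <- mean(!pred_pos[!pos])
  acc <- mean(pred_pos == pos)
  structure(list(roc = roc, auc = auc, cutoff = cutoff,
                 sensitivity = sens, specificity = spec, accuracy = acc,
                 degenerate = degenerate),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> AUC %.3f | cutoff %.4g -> sens %.1f%%, spec %.1f%%, acc %.1f%%\n",
              x$auc, x$cutoff, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy))
  invisible(x)
}

#' Fit the spiral-drawing screening classifier
#'
#' The central fit of the package: leave-one-out cross-validated SVM decision
#' scores, ROC analysis with the closest-to-top-left operating cutoff, and a
#' final SVM trained on all subjects for scoring new drawings. The
#' cross-validated scores (not the resubstitution scores) feed the ROC, so
#' the reported sensitivity/specificity/AUC reflect held-out performance.
#'
#' @param x n-by-d feature matrix (see \code{\link{bundle_to_matrix}}).
#' @param labels vector/factor of \code{"non-CTS"} / \code{"CTS"}.
#' @param config a \code{model_config}.
#' @return object of class \code{cts_screen} with the LOOCV scores, the
#'   \code{eval_report}, the configuration and the full-data SVM fit.
#' @seealso \code{\link{roc_analysis}}, \code{\link{tune_model}},
#'   \code{\link{combination_grid}}
#' @export
cts_screen <- function(x, labels, config = model_config()) {
  x <- as.matrix(x)
  labels <- as_screen_labels(labels)
  scores <- loocv_scores(x, labels, config)
  report <- roc_analysis(scores, labels)
  final <- fit_screen_svm(x, labels, config)
  structure(list(scores = scores, labels = labels, report = report,
                 config = config, fit = final, n = nrow(x), d = ncol(x)),
            class = "cts_screen")
}

#' @export
print.cts_screen <- function(x, ...) {
  cat(sprintf("Spiral-drawing CTS screen (SVM, %s kernel degree %d, C = %g)\n",
              x$config$kernel, x$config$kernel_degree, x$config$regularization))
  cat(sprintf("  n = %d subjects (%d non-CTS / %d CTS), d = %d features\n",
              x$n, sum(x$labels == "non-CTS"), sum(x$labels == "CTS"), x$d))
  cat(sprintf("  LOOCV AUC %.3f | sensitivity %.0f%% | specificity %.0f%% | accuracy %.0f%%\n",
              x$report$auc, 100 * x$report$sensitivity,
              100 * x$report$specificity, 100 * x$report$accuracy))
  invisible(x)
}

#' @export
summary.cts_screen <- function(object, ...) {
  print(object)
  cut <- object$report$cutoff
  pred <- factor(ifelse(object$scores >= cut, "CTS", "non-CTS"),
                 levels = c("non-CTS", "CTS"))
  cat(sprintf("  operating cutoff (closest to top-left): %.4g\n", cut))
  cat("  confusion at cutoff (rows = truth):\n")
  print(table(truth = object$labels, predicted = pred))
  invisible(object)
}

#' @export
plot.cts_screen <- function(x, ...) {
  roc <- x$report$roc
  plot(roc$fpr, roc$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "1 - specificity", ylab = "Sensitivity",
       main = sprintf("LOOCV ROC (AUC = %.2f)", x$report$auc), ...)
  abline(0, 1, lty = 3, col = "grey50")
  i <- which(roc$threshold == x$report$cutoff)
  points(roc$fpr[i], roc$tpr[i], pch = 19)
  invisible(x)
}

#' @export
predict.cts_screen <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$d)
    stop("newdata must have ", object$d, " feature columns")
  score <- vapply(seq_len(nrow(newdata)), function(i)
    svm_score(object$fit, newdata[i, , drop = FALSE]), numeric(1))
  data.frame(score = score,
             class = factor(ifelse(score >= object$report$cutoff,
                                   "CTS", "non-CTS"),
                            levels = c("non-CTS", "CTS")))
}

#' Tune SVM hyperparameters toward the top-left ROC corner
#'
#' Evaluates every (degree, C) grid point by LOOCV + ROC and selects the
#' configuration whose chosen operating cutoff lies closest to the ideal
#' (0, 1) corner of ROC space. Ties are broken toward the smaller degree,
#' then the smaller C (simpler models first). Grid points whose evaluation
#' fails are recorded and skipped.
#'
#' @inheritParams cts_screen
#' @param degree_grid integer vector of polynomial degrees.
#' @param c_grid numeric vector of regularization values.
#' @param base a \code{model_config} supplying the non-tuned settings.
#' @return the winning \code{model_config}, with attributes
#'   \code{criterion} (distance to (0,1)) and \code{grid} (a data.frame of
#'   all evaluated points).
#' @export
tune_model <- function(x, labels, degree_grid = 1:4,
                       c_grid = 10^seq(-2, 2), base = model_config()) {
  if (!length(degree_grid) || !length(c_grid)) stop("empty tuning grid")
  rows <- list(); best <- NULL; best_crit <- Inf
  for (deg in sort(degree_grid)) for (cc in sort(c_grid)) {
    cfg <- base
    cfg$kernel_degree <- as.integer(deg); cfg$regularization <- cc
    rep_i <- tryCatch(
      roc_analysis(loocv_scores(x, labels, cfg), labels),
      error = function(e) e)
    if (inherits(rep_i, "error")) {
      rows[[length(rows) + 1L]] <- data.frame(
        degree = deg, C = cc, criterion = NA_real_, auc = NA_real_,
        error = conditionMessage(rep_i))
      next
    }
    crit <- sqrt((1 - rep_i$sensitivity)^2 + (1 - rep_i$specificity)^2)
    rows[[length(rows) + 1L]] <- data.frame(
      degree = deg, C = cc, criterion = crit, auc = rep_i$auc, error = "")
    if (crit < best_crit) { best_crit <- crit; best <- cfg }
  }
  grid <- do.call(rbind, rows)
  if (is.null(best)) stop("all tuning grid points failed")
  attr(best, "criterion") <- best_crit
  attr(best, "grid") <- grid
  best
}

# the 15 non-empty feature-set combinations in the conventional order:
# singles, pairs, triples, all four
set_combinations <- function() {
  unlist(lapply(1:4, function(k) utils::combn(4, k, simplify = FALSE)),
         recursive = FALSE)
}

#' Evaluate every feature-set combination
#'
#' Runs the full screen (\code{\link{cts_screen}}) on each of the 15
#' non-empty subsets of the four training-data sets (pressure-jerk spectrum,
#' trajectory-jerk spectrum, spiral RMSE, max pressure) and tabulates
#' sensitivity, specificity, accuracy (percent) and AUC per combination.
#' A failing combination is reported as NA and the run continues.
#'
#' @param bundles list of \code{feature_bundle} with both classes present.
#' @param config a \code{model_config} applied to every combination, or
#'   \code{NULL} to tune per combination via \code{\link{tune_model}}.
#' @param degree_grid,c_grid tuning grids, used when \code{config} is NULL.
#' @return object of class \code{screen_grid}: a data.frame with columns
#'   \code{combination}, \code{d}, \code{sensitivity}, \code{specificity},
#'   \code{accuracy} (percent), \code{auc}; the per-row \code{cts_screen}
#'   fits are attached as attribute \code{fits}.
#' @export
combination_grid <- function(bundles, config = model_config(),
                             degree_grid = 1:3, c_grid = 10^seq(-1, 1)) {
  stopifnot(length(bundles) >= 3L)
  combos <- set_combinations()
  fits <- vector("list", length(combos))
  rows <- lapply(seq_along(combos), function(i) {
    sel <- combos[[i]]
    nm <- paste(sel, collapse = "+")
    out <- tryCatch({
      mat <- bundle_to_matrix(bundles, sel)
      cfg <- if (is.null(config))
        tune_model(mat$x, mat$labels, degree_grid, c_grid) else config
      fit <- cts_screen(mat$x, mat$labels, cfg)
      fits[[i]] <<- fit
      data.frame(combination = nm, d = ncol(mat$x),
                 sensitivity = 100 * fit$report$sensitivity,
                 specificity = 100 * fit$report$specificity,
                 accuracy = 100 * fit$report$accuracy,
                 auc = fit$report$auc)
    }, error = function(e) {
      message("combination ", nm, " failed: ", conditionMessage(e))
      data.frame(combination = nm, d = NA_integer_, sensitivity = NA_real_,
                 specificity = NA_real_, accuracy = NA_real_, auc = NA_real_)
    })
    out
  })
  grid <- do.call(rbind, rows)
  attr(grid, "fits") <- fits
  class(grid) <- c("screen_grid", class(grid))
  grid
}

#' @export
print.screen_grid <- function(x, ...) {
  cat("Feature-set combination screen (sets: 1 pressure-jerk spectrum,",
      "2 trajectory-jerk spectrum, 3 spiral RMSE, 4 max pressure)\n")
  df <- data.frame(Combination = x$combination, d = x$d,
                   `Sensitivity %` = round(x$sensitivity),
                   `Specificity %` = round(x$specificity),
                   `Accuracy %` = round(x$accuracy),
                   AUC = round(x$auc, 2), check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}
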