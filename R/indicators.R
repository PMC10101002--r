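#' Random-forest indicator-metabolite selection
#'
#' Fits a random-forest classifier of sample groups on metabolite
#' concentrations, ranks metabolites by permutation importance (mean
#' decrease in accuracy), and computes an rfcv-style cross-validation
#' curve: at each feature count k on a halving grid, features are
#' re-ranked within each training fold (avoiding selection bias), the
#' forest is refit on the top-k features, and the held-out error is
#' recorded over stratified 10-fold CV, repeated `n_repeats` times with
#' fresh fold assignments to smooth the curve. The selected feature count
#' is the smallest k whose mean CV error is within one standard error of
#' the global minimum (the one-standard-error rule -- the operational
#' meaning of the error curve "stabilizing").
#'
#' @param met a [metabolite_table()] (metabolites x samples).
#' @param meta metadata data.frame, rownames = sample IDs.
#' @param group_factor metadata column with >= 2 levels.
#' @param n_trees trees per forest, default 500.
#' @param seed RNG seed (forest and fold assignment).
#' @param n_folds folds, default 10 (reduced with a warning when a class
#'   has fewer samples).
#' @param n_repeats independent CV repetitions averaged into the curve,
#'   default 5.
#' @return object of class `indicator_result`: `importance` (data.frame,
#'   sorted), `cv_curve` (k, mean error, sd over folds), `selected_k`,
#'   `selected` (top features), `oob_error`, `cv_error`, `accuracy`
#'   (1 - OOB error), `n_trees`, `seed`.
#' @export
indicator_select <- function(met, meta, group_factor, n_trees = 500,
                             seed = 1, n_folds = 10, n_repeats = 5) {
  X <- t(as.matrix(met))  # samples x features
  if (!all(rownames(X) %in% rownames(meta))) {
    stop2("samples missing from metadata: ",
          paste(setdiff(rownames(X), rownames(meta)), collapse = ", "))
  }
  y <- factor(meta[rownames(X), group_factor])
  if (nlevels(y) < 2L) stop2("need at least two group levels")
  if (nrow(X) < 10L) stop2("need at least 10 samples")
  min_class <- min(table(y))
  if (min_class < n_folds) {
    warn2("smallest class has ", min_class, " samples; reducing folds to ", min_class)
    n_folds <- min_class
  }
  colnames(X) <- make.names(colnames(X))  # randomForest-safe names
  feat_names <- colnames(X)
  P <- ncol(X)

  rf_fit <- function(x, yy, importance = FALSE) {
    randomForest::randomForest(x, yy, ntree = n_trees, importance = importance)
  }
  rank_features <- function(x, yy) {
    imp <- randomForest::importance(rf_fit(x, yy, importance = TRUE),
                                    type = 1, scale = TRUE)[, 1]
    order(imp, decreasing = TRUE)
  }
  # halving grid P, P/2, P/4, ..., 1 (rfcv convention, step = 0.5)
  grid <- P
  while (utils::tail(grid, 1) > 1) grid <- c(grid, max(floor(utils::tail(grid, 1) / 2), 1))
  grid <- unique(grid)

  res <- with_seed(seed, {
    full <- rf_fit(X, y, importance = TRUE)
    imp <- randomForest::importance(full, type = 1, scale = TRUE)[, 1]
    fold_err <- matrix(NA_real_, n_folds * n_repeats, length(grid),
                       dimnames = list(NULL, grid))
    for (rep_i in seq_len(n_repeats)) {
      # stratified fold assignment, fresh per repetition
      fold <- integer(nrow(X))
      for (lv in levels(y)) {
        idx <- which(y == lv)
        fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
      }
      for (f in seq_len(n_folds)) {
        tr <- fold != f; te <- !tr
        ord <- rank_features(X[tr, , drop = FALSE], y[tr])
        for (ki in seq_along(grid)) {
          k <- grid[ki]
          sel <- ord[seq_len(k)]
          fit_k <- rf_fit(X[tr, sel, drop = FALSE], y[tr])
          pred <- stats::predict(fit_k, X[te, sel, drop = FALSE])
          fold_err[(rep_i - 1L) * n_folds + f, ki] <- mean(pred != y[te])
        }
      }
    }
    list(full = full, imp = imp, fold_err = fold_err)
  })
  cv_mean <- colMeans(res$fold_err)
  cv_sd <- apply(res$fold_err, 2, stats::sd)
  # repeats reduce curve noise but are not independent draws; the SE uses
  # the fold count as the effective sample size
  cv_se <- cv_sd / sqrt(n_folds)
  best <- which.min(cv_mean)
  ok <- cv_mean <= cv_mean[best] + cv_se[best]
  selected_k <- min(grid[ok])
  imp_df <- data.frame(metabolite = feat_names, importance = unname(res$imp),
                       stringsAsFactors = FALSE)
  imp_df <- imp_df[order(imp_df$importance, decreasing = TRUE), ]
  rownames(imp_df) <- NULL
  oob <- res$full$err.rate[n_trees, "OOB"]
  structure(list(
    importance = imp_df,
    cv_curve = data.frame(k = grid, error = unname(cv_mean), sd = unname(cv_sd)),
    selected_k = selected_k,
    selected = imp_df$metabolite[seq_len(selected_k)],
    oob_error = unname(oob),
    cv_error = unname(cv_mean[as.character(selected_k) == colnames(res$fold_err)][1]),
    accuracy = 1 - unname(oob),
    n_trees = n_trees, n_folds = n_folds, n_repeats = n_repeats, seed = seed
  ), class = "indicator_result")
}

#' @export
print.indicator_result <- function(x, ...) {
  cat(sprintf("random-forest indicator selection: accuracy %.1f%% (OOB), %d trees\n",
              100 * x$accuracy, x$n_trees))
  cat(sprintf("  CV error stabilizes at k = %d features: %s\n",
              x$selected_k, paste(x$selected, collapse = ", ")))
  invisible(x)
}

#' @export
plot.indicator_result <- function(x, ...) {
  cc <- x$cv_curve[order(x$cv_curve$k), ]
  graphics::plot(cc$k, cc$error, type = "b", log = "x",
                 xlab = "number of metabolites", ylab = "10-fold CV error", ...)
  graphics::abline(v = x$selected_k, lty = 2)
  invisible(x)
}
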