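#' Fit the Sloan neutral community model
#'
#' The Sloan model predicts, for a set of local communities sampled from a
#' shared metacommunity under drift and immigration, the probability of
#' detecting a taxon as a function of its metacommunity relative
#' abundance. With community size `N` (mean reads per sample, rounded),
#' detection limit `d = 1/N`, immigration rate `m`, and metacommunity
#' abundance `p`, the expected occurrence frequency is
#' `f_pred(p) = 1 - pbeta(d, N m p, N m (1 - p))`.
#'
#' `m` is estimated by least squares of the observed occurrence
#' frequencies on `f_pred` over taxa (the standard frequency-scale
#' convention; `method = "binomial"` maximizes a binomial likelihood
#' instead). The 95% band comes from bootstrapping taxa with replacement,
#' refitting `m` per replicate, and drawing for each taxon an occurrence
#' frequency from the binomial sampling distribution (S samples) under
#' the refitted curve; the 2.5/97.5 percentiles of those draws give a
#' prediction band that reflects both parameter and sampling uncertainty
#' (widened if needed to contain the point prediction). Each taxon is
#' partitioned as `"above"` (observed frequency above the band),
#' `"below"`, or `"neutral"` -- within the band, i.e. consistent with
#' purely neutral assembly at this sample size.
#'
#' @param t an [abundance_table()] of integer counts with at least 5
#'   samples and 10 taxa of nonzero abundance.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level of the band, default 0.95.
#' @param method `"ls"` (default) or `"binomial"`.
#' @return object of class `neutral_fit`: `m`, `N`, `d`, `R2`, `taxa`
#'   (data.frame: taxon, p, f_obs, f_pred, lower, upper, partition),
#'   `partition_counts`, `partition_cum_ra` (cumulative mean relative
#'   abundance per partition), `n_boot`, `seed`, `m_boot`.
#' @seealso [simulate_neutral()], and the `coef`, `predict`, `plot`,
#'   `simulate`, `residuals` methods.
#' @export
fit_neutral_model <- function(t, n_boot = 1000, seed = 1, conf = 0.95,
                              method = c("ls", "binomial")) {
  method <- match.arg(method)
  stopifnot(inherits(t, "abundance_table"))
  x <- t$counts
  if (t$is_relative || any(abs(x - round(x)) > 1e-8)) {
    stop2("fit_neutral_model needs raw integer counts, not relative abundances")
  }
  if (ncol(x) < 5L) stop2("need at least 5 samples")
  depths <- colSums(x)
  N <- round(mean(depths))
  d <- 1 / N
  ra <- sweep(x, 2, depths, "/")
  p <- rowMeans(ra)
  f_obs <- rowMeans(x > 0)
  keep <- p > 0
  p <- p[keep]; f_obs <- f_obs[keep]
  if (length(p) < 10L) stop2("need at least 10 taxa with nonzero abundance")
  S <- ncol(x)

  f_pred_fun <- function(m, pp = p) {
    stats::pbeta(d, N * m * pp, N * m * (1 - pp), lower.tail = FALSE)
  }
  objective <- function(log_m, fo = f_obs, pp = p) {
    fp <- f_pred_fun(exp(log_m), pp)
    if (method == "ls") {
      sum((fo - fp)^2)
    } else {
      fp <- pmin(pmax(fp, 1e-12), 1 - 1e-12)
      succ <- round(fo * S)
      -sum(stats::dbinom(succ, S, fp, log = TRUE))
    }
  }
  fit_m <- function(fo = f_obs, pp = p) {
    opt <- stats::optimize(objective, interval = log(c(1e-6, 10)),
                           fo = fo, pp = pp, tol = 1e-10)
    exp(opt$minimum)
  }
  m_hat <- fit_m()
  if (m_hat <= 1.0001e-6 || m_hat >= 9.999) {
    stop2("neutral-model fit failed: optimum at the boundary (m = ",
          signif(m_hat, 4), "); the occurrence/abundance relationship may ",
          "not be neutral-like")
  }
  f_pred <- f_pred_fun(m_hat)
  sst <- sum((f_obs - mean(f_obs))^2)
  R2 <- 1 - sum((f_obs - f_pred)^2) / sst

  m_boot <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(length(p), replace = TRUE)
    fit_m(f_obs[idx], p[idx])
  }, numeric(1)))
  alpha <- (1 - conf) / 2
  # prediction band: each replicate draws an observed frequency from the
  # binomial sampling distribution at S samples under its refitted curve,
  # so the band reflects both parameter and sampling uncertainty -- the
  # width that makes "within the 95% CI" a meaningful neutrality call
  pred_boot <- with_seed(seed + 1L, vapply(m_boot, function(mb) {
    stats::rbinom(length(p), S, f_pred_fun(mb)) / S
  }, numeric(length(p))))
  lower <- pmin(apply(pred_boot, 1, stats::quantile, probs = alpha), f_pred)
  upper <- pmax(apply(pred_boot, 1, stats::quantile, probs = 1 - alpha), f_pred)
  partition <- ifelse(f_obs > upper, "above",
                      ifelse(f_obs < lower, "below", "neutral"))
  taxa <- data.frame(taxon = names(p), p = unname(p), f_obs = unname(f_obs),
                     f_pred = unname(f_pred), lower = unname(lower),
                     upper = unname(upper), partition = unname(partition),
                     stringsAsFactors = FALSE, row.names = NULL)
  lv <- c("above", "neutral", "below")
  counts <- table(factor(partition, levels = lv))
  cum_ra <- vapply(lv, function(g) sum(p[partition == g]) / sum(p), numeric(1))
  structure(list(m = m_hat, N = N, d = d, R2 = R2, taxa = taxa,
                 partition_counts = stats::setNames(as.integer(counts), lv),
                 partition_cum_ra = cum_ra, n_boot = n_boot, seed = seed,
                 conf = conf, method = method, m_boot = m_boot,
                 n_samples = S),
            class = "neutral_fit")
}

#' @export
print.neutral_fit <- function(x, ...) {
  cat("Sloan neutral community model fit\n")
  cat(sprintf("  m = %.4g, N = %d, R2 = %.3f (%d taxa, %d samples)\n",
              x$m, x$N, x$R2, nrow(x$taxa), x$n_samples))
  pc <- x$partition_counts
  cat(sprintf("  partition: %d neutral / %d above / %d below\n",
              pc[["neutral"]], pc[["above"]], pc[["below"]]))
  invisible(x)
}

#' @export
summary.neutral_fit <- function(object, ...) {
  ci <- stats::quantile(object$m_boot, c(0.025, 0.975))
  cat("Sloan neutral community model\n")
  cat(sprintf("  migration rate m: %.4g (bootstrap 95%% CI %.4g - %.4g)\n",
              object$m, ci[1], ci[2]))
  cat(sprintf("  community size N: %d reads; detection limit d = %.3g\n",
              object$N, object$d))
  cat(sprintf("  R2 = %.3f over %d taxa\n", object$R2, nrow(object$taxa)))
  frac <- object$partition_counts / sum(object$partition_counts)
  cat(sprintf("  taxa: %.1f%% neutral, %.1f%% above, %.1f%% below prediction\n",
              100 * frac[["neutral"]], 100 * frac[["above"]], 100 * frac[["below"]]))
  cat(sprintf("  cumulative RA: %.1f%% neutral, %.1f%% above, %.1f%% below\n",
              100 * object$partition_cum_ra[["neutral"]],
              100 * object$partition_cum_ra[["above"]],
              100 * object$partition_cum_ra[["below"]]))
  invisible(object)
}

#' @export
coef.neutral_fit <- function(object, ...) {
  c(m = object$m, N = object$N, R2 = object$R2)
}

#' Predicted occurrence frequency at given metacommunity abundances
#' @param object a `neutral_fit`.
#' @param newdata numeric vector of metacommunity relative abundances; the
#'   fitted taxa's abundances when omitted.
#' @param ... unused.
#' @export
predict.neutral_fit <- function(object, newdata = NULL, ...) {
  p <- if (is.null(newdata)) object$taxa$p else as.numeric(newdata)
  stats::pbeta(object$d, object$N * object$m * p,
               object$N * object$m * (1 - p), lower.tail = FALSE)
}

#' @export
residuals.neutral_fit <- function(object, ...) {
  stats::setNames(object$taxa$f_obs - object$taxa$f_pred, object$taxa$taxon)
}

#' @export
plot.neutral_fit <- function(x, ...) {
  tx <- x$taxa[order(x$taxa$p), ]
  cols <- c(neutral = "grey40", above = "red3", below = "orange2")
  graphics::plot(log10(tx$p), tx$f_obs, col = cols[tx$partition], pch = 16,
                 cex = 0.6, xlab = "log10 metacommunity relative abundance",
                 ylab = "occurrence frequency", ...)
  graphics::lines(log10(tx$p), tx$f_pred, col = "blue", lwd = 2)
  graphics::lines(log10(tx$p), tx$lower, col = "blue", lty = 2)
  graphics::lines(log10(tx$p), tx$upper, col = "blue", lty = 2)
  invisible(x)
}

#' Simulate local communities under Sloan neutral dynamics
#'
#' Draws each local community's composition from the stationary local
#' distribution `Dirichlet(N m p)` and then sequencing counts from a
#' multinomial at depth `N`. Large `m` concentrates local compositions at
#' the metacommunity composition; small `m` lets drift dominate.
#'
#' @param meta_p metacommunity relative abundances (must sum to 1); names
#'   become taxon IDs.
#' @param N reads per sample.
#' @param m immigration rate (> 0).
#' @param n_samples number of local communities.
#' @param seed RNG seed.
#' @param domain domain label for the resulting table.
#' @return an [abundance_table()] of counts (taxa x samples; column sums
#'   all equal `N`).
#' @export
simulate_neutral <- function(meta_p, N, m, n_samples, seed = 1,
                             domain = "bacteria") {
  ids <- names(meta_p)
  meta_p <- as.numeric(meta_p)
  if (abs(sum(meta_p) - 1) > 1e-6) stop2("meta_p must sum to 1")
  if (any(meta_p < 0)) stop2("meta_p must be non-negative")
  if (m <= 0) stop2("m must be > 0")
  K <- length(meta_p)
  if (is.null(ids)) ids <- sprintf("taxon%04d", seq_len(K))
  counts <- with_seed(seed, {
    out <- matrix(0L, K, n_samples)
    shape <- N * m * meta_p
    for (j in seq_len(n_samples)) {
      g <- stats::rgamma(K, shape = shape)
      if (sum(g) == 0) g[which.max(meta_p)] <- 1
      out[, j] <- stats::rmultinom(1, size = N, prob = g / sum(g))
    }
    out
  })
  dimnames(counts) <- list(ids, sprintf("sample%02d", seq_len(n_samples)))
  abundance_table(counts, domain = domain, is_relative = FALSE)
}

#' @rdname simulate_neutral
#' @param object a `neutral_fit`.
#' @param nsim number of local communities to simulate.
#' @param ... unused.
#' @export
simulate.neutral_fit <- function(object, nsim = 1, seed = 1, ...) {
  p <- object$taxa$p / sum(object$taxa$p)
  names(p) <- object$taxa$taxon
  simulate_neutral(p, N = object$N, m = object$m, n_samples = nsim,
                   seed = seed)
}
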