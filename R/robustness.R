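#' Network robustness under random node removal
#'
#' For each removal fraction f and each replicate, removes
#' `round(f * N)` nodes uniformly at random (round half up) and then
#' iteratively deletes nodes left with no remaining edge (secondary
#' extinction, to a fixed point). Nodes that were isolated in the original
#' network cannot lose links and are exempt from secondary extinction by
#' default. The curve reports, per fraction, the mean and sd over
#' replicates of the proportion of surviving nodes. Targeted
#' (degree-ordered) attack replaces the random removal set with the
#' highest-degree nodes.
#'
#' @param net a `cooccurrence_network` with at least 2 nodes.
#' @param fractions removal-fraction grid, default `seq(0.005, 1, 0.005)`.
#' @param n_sim replicates per fraction, default 200.
#' @param seed RNG seed.
#' @param exempt_isolated exempt originally isolated nodes from secondary
#'   extinction (default `TRUE`).
#' @param mode `"random"` or `"targeted"` (decreasing degree; deterministic,
#'   replicated only for the sd bookkeeping).
#' @return object of class `robustness_curve`: data.frame with `fraction`,
#'   `mean`, `sd`, `n`; attributes `n_sim`, `seed`, and the replicate
#'   matrix `draws` (fractions x replicates) for downstream comparison.
#' @export
robustness <- function(net, fractions = seq(0.005, 1, by = 0.005),
                       n_sim = 200, seed = 1, exempt_isolated = TRUE,
                       mode = c("random", "targeted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "cooccurrence_network"))
  if (n_sim < 1) stop2("n_sim must be >= 1")
  if (!length(fractions)) stop2("empty fraction grid")
  taxa <- net$nodes$taxon
  N <- length(taxa)
  if (N < 2) stop2("need at least 2 nodes")
  ef <- match(net$edges$from, taxa)
  et <- match(net$edges$to, taxa)
  deg0 <- tabulate(c(ef, et), nbins = N)
  orig_isolated <- deg0 == 0L

  survivors_after <- function(removed_idx) {
    alive <- rep(TRUE, N)
    alive[removed_idx] <- FALSE
    repeat {
      ok <- alive[ef] & alive[et]
      deg <- tabulate(c(ef[ok], et[ok]), nbins = N)
      dying <- alive & deg == 0L
      if (exempt_isolated) dying <- dying & !orig_isolated
      if (!any(dying)) break
      alive[dying] <- FALSE
    }
    sum(alive)
  }

  draws <- matrix(NA_real_, length(fractions), n_sim)
  with_seed(seed, {
    for (fi in seq_along(fractions)) {
      r <- min(round_half_up(fractions[fi] * N), N)
      for (b in seq_len(n_sim)) {
        removed <- if (mode == "random") {
          sample.int(N, r)
        } else {
          order(deg0, decreasing = TRUE)[seq_len(r)]
        }
        draws[fi, b] <- if (r >= N) 0 else survivors_after(removed) / N
      }
    }
  })
  out <- data.frame(fraction = fractions,
                    mean = rowMeans(draws),
                    sd = apply(draws, 1, stats::sd),
                    n = n_sim)
  attr(out, "draws") <- draws
  attr(out, "n_sim") <- n_sim
  attr(out, "seed") <- seed
  attr(out, "mode") <- mode
  class(out) <- c("robustness_curve", "data.frame")
  out
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat(sprintf("robustness_curve: %d fractions, %d replicates (%s removal)\n",
              nrow(x), attr(x, "n_sim"), attr(x, "mode")))
  mid <- which.min(abs(x$fraction - 0.5))
  cat(sprintf("  remaining at f = %.3g: %.3f (sd %.3f)\n",
              x$fraction[mid], x$mean[mid], x$sd[mid]))
  invisible(x)
}

#' @export
plot.robustness_curve <- function(x, ...) {
  graphics::plot(x$fraction, x$mean, type = "l",
                 xlab = "proportion of nodes removed",
                 ylab = "proportion of species remaining", ylim = c(0, 1), ...)
  graphics::lines(x$fraction, pmin(x$mean + x$sd, 1), lty = 3)
  graphics::lines(x$fraction, pmax(x$mean - x$sd, 0), lty = 3)
  invisible(x)
}

#' Compare two robustness curves
#'
#' Per-fraction mean difference (A minus B) with a bootstrap percentile
#' confidence interval obtained by resampling replicates of each curve.
#'
#' @param curveA,curveB [robustness()] results on identical fraction grids.
#' @param conf confidence level, default 0.95.
#' @param n_boot bootstrap resamples, default 1000.
#' @param seed RNG seed.
#' @return data.frame with `fraction`, `diff`, `lower`, `upper`.
#' @export
compare_robustness <- function(curveA, curveB, conf = 0.95, n_boot = 1000,
                               seed = 1) {
  stopifnot(inherits(curveA, "robustness_curve"),
            inherits(curveB, "robustness_curve"))
  if (!isTRUE(all.equal(curveA$fraction, curveB$fraction))) {
    stop2("fraction grids differ")
  }
  da <- attr(curveA, "draws"); db <- attr(curveB, "draws")
  d_obs <- rowMeans(da) - rowMeans(db)
  alpha <- (1 - conf) / 2
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ia <- sample.int(ncol(da), replace = TRUE)
      ib <- sample.int(ncol(db), replace = TRUE)
      rowMeans(da[, ia, drop = FALSE]) - rowMeans(db[, ib, drop = FALSE])
    }, numeric(nrow(da)))
  })
  data.frame(fraction = curveA$fraction, diff = d_obs,
             lower = apply(boot, 1, stats::quantile, probs = alpha),
             upper = apply(boot, 1, stats::quantile, probs = 1 - alpha))
}
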