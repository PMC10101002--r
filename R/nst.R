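#' Normalized stochasticity ratio (NST)
#'
#' Quantifies, per sample group, how close observed pairwise community
#' dissimilarities sit to the expectation under a null model in which
#' assembly is purely stochastic. For every within-group sample pair
#' (i, j) the observed dissimilarity `D_ij` is compared with the mean
#' `E_ij` over `n_rand` null communities; a per-pair stochasticity ratio
#'
#' * `SS_ij = (1 - E_ij) / (1 - D_ij)` when `D_ij < E_ij` (deterministic
#'   convergence: observed similarity exceeds the null),
#' * `SS_ij = E_ij / D_ij` when `D_ij > E_ij` (deterministic divergence),
#' * `SS_ij = 1` when they coincide,
#'
#' is averaged into `ST`. Because sampling noise keeps `SS_ij` below 1
#' even for data generated by the null model itself, `ST` is normalized
#' per pair against the null model's own spread: with
#' `SS_min,ij` the all-deterministic extreme (`1 - E_ij` if `D_ij < E_ij`,
#' else `E_ij`) and `SS_null,ij` the mean of the same ratio computed for
#' each null draw against `E_ij`,
#' `NST_ij = (SS_ij - SS_min,ij) / (SS_null,ij - SS_min,ij)`, clamped to
#' `[0, 1]` (`variant = "simple"` uses denominator `1 - SS_min,ij`
#' instead). `NST` is the pair average, reported as a percentage: above
#' 50% reads as predominantly stochastic assembly, below 50% as
#' predominantly deterministic.
#'
#' The null model preserves each sample's richness and total abundance;
#' taxa enter a null sample with inclusion probability proportional to
#' their observed occurrence frequency (capped at 1, exact via systematic
#' PPS sampling), and abundance is allocated proportionally to their mean
#' relative abundance conditional on presence (proportional-proportional
#' null, parameterized so the observed occupancy and abundance marginals
#' are fixed points of the randomization). Samples are the randomization
#' unit; the seed fixes the whole ensemble.
#'
#' @param t an [abundance_table()] of counts.
#' @param groups factor (or metadata column values) over the samples;
#'   `NULL` treats all samples as one group.
#' @param metric `"jaccard"` (default; quantitative Ruzicka form when
#'   weighted) or `"bray"`.
#' @param abundance_weighted logical, default `TRUE`.
#' @param n_rand null-model draws, default 1000.
#' @param seed RNG seed.
#' @param variant `"null_calibrated"` (default) or `"simple"`.
#' @return data.frame of class `nst_result`, one row per group: `group`,
#'   `n_samples`, `ST` and `NST` (percent), `mean_D`, `mean_E`; attribute
#'   `pairs` holds the per-pair table.
#' @export
nst <- function(t, groups = NULL, metric = c("jaccard", "bray"),
                abundance_weighted = TRUE, n_rand = 1000, seed = 1,
                variant = c("null_calibrated", "simple")) {
  metric <- match.arg(metric); variant <- match.arg(variant)
  stopifnot(inherits(t, "abundance_table"))
  if (n_rand < 1) stop2("n_rand must be >= 1")
  x <- t$counts
  if (is.null(groups)) groups <- rep("all", ncol(x))
  groups <- factor(groups)
  if (length(groups) != ncol(x)) stop2("groups must match the sample count")
  rows <- list(); pair_rows <- list()
  for (gi in seq_along(levels(groups))) {
    g <- levels(groups)[gi]
    xg <- x[, groups == g, drop = FALSE]
    if (ncol(xg) < 3L) stop2("group ", g, " has fewer than 3 samples")
    res <- nst_one_group(xg, metric, abundance_weighted, n_rand,
                         seed = stage_seed(seed, gi), variant = variant)
    rows[[g]] <- data.frame(group = g, n_samples = ncol(xg),
                            ST = 100 * res$ST, NST = 100 * res$NST,
                            mean_D = res$mean_D, mean_E = res$mean_E,
                            stringsAsFactors = FALSE)
    pair_rows[[g]] <- cbind(group = g, res$pairs)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "pairs") <- do.call(rbind, c(pair_rows, list(make.row.names = FALSE)))
  attr(out, "metric") <- metric
  attr(out, "abundance_weighted") <- abundance_weighted
  attr(out, "n_rand") <- n_rand
  attr(out, "seed") <- seed
  attr(out, "variant") <- variant
  class(out) <- c("nst_result", "data.frame")
  out
}

nst_one_group <- function(xg, metric, abundance_weighted, n_rand, seed,
                          variant) {
  n <- ncol(xg)
  if (any(colSums(xg) == 0)) stop2("all-zero sample in group")
  f_occ <- rowMeans(xg > 0)
  p <- rowMeans(sweep(xg, 2, colSums(xg), "/"))
  richness <- colSums(xg > 0)
  depths <- colSums(xg)
  dist_fun <- function(m) {
    as.matrix(vegan::vegdist(t(m), method = metric,
                             binary = !abundance_weighted))
  }
  D <- dist_fun(xg)
  if (all(D[lower.tri(D)] < 1e-12)) {
    warn2("all samples identical within group; NST = 0")
  }
  npair <- n * (n - 1) / 2
  pos <- which(f_occ > 0)
  f <- f_occ[pos]
  cond_w <- p[pos] / f
  pi_j <- lapply(seq_len(n), function(j) {
    S <- min(richness[j], length(pos))
    if (S == length(pos)) NULL else inclusion_probs(f, S)
  })
  E_sum <- matrix(0, n, n)
  null_draws <- array(NA_real_, c(n, n, n_rand))
  with_seed(seed, {
    for (b in seq_len(n_rand)) {
      null_m <- draw_null_matrix(nrow(xg), n, pos, cond_w, pi_j, depths)
      Db <- dist_fun(null_m)
      null_draws[, , b] <- Db
      E_sum <- E_sum + Db
    }
  })
  E <- E_sum / n_rand

  ss_of <- function(d, e) {
    ifelse(abs(d - e) < 1e-12, 1,
           ifelse(d < e, (1 - e) / (1 - d), e / d))
  }
  li <- lower.tri(D)
  d_v <- D[li]; e_v <- E[li]
  ss_obs <- ss_of(d_v, e_v)
  ss_min <- ifelse(abs(d_v - e_v) < 1e-12, 1,
                   ifelse(d_v < e_v, 1 - e_v, e_v))
  if (variant == "null_calibrated") {
    ss_null <- rowMeans(vapply(seq_len(n_rand), function(b) {
      ss_of(null_draws[, , b][li], e_v)
    }, numeric(npair)))
    denom <- ss_null - ss_min
  } else {
    denom <- 1 - ss_min
  }
  nst_pair <- ifelse(denom <= 1e-12, 1, (ss_obs - ss_min) / denom)
  nst_pair <- pmin(pmax(nst_pair, 0), 1)
  pairs <- data.frame(
    i = row(D)[li], j = col(D)[li], D = d_v, E = e_v,
    SS = pmin(pmax(ss_obs, 0), 1), NST_pair = nst_pair
  )
  list(ST = mean(pairs$SS), NST = mean(nst_pair),
       mean_D = mean(d_v), mean_E = mean(e_v), pairs = pairs)
}

# One proportional-proportional null community matrix. Per sample: the
# occupied set is drawn with inclusion probabilities proportional to the
# observed occurrence frequencies (capped at 1 and rescaled to the
# sample's richness; randomized systematic PPS sampling makes the
# inclusion probabilities exact), each occupied taxon gets one read, and
# the remaining depth is allocated multinomially with weights
# proportional to each taxon's conditional mean relative abundance when
# present (p / f). Both choices make the observed occupancy and
# abundance marginals fixed points of the randomization, so data drawn
# from the null score NST near 100%.
null_community <- function(K, n, f_occ, p, richness, depths) {
  pos <- which(f_occ > 0)
  f <- f_occ[pos]
  cond_w <- p[pos] / f  # mean relative abundance conditional on presence
  # richness is fixed per sample across the ensemble: precompute inclusion
  # probabilities once per sample
  pi_j <- lapply(seq_len(n), function(j) {
    S <- min(richness[j], length(pos))
    if (S == length(pos)) NULL else inclusion_probs(f, S)
  })
  draw_null_matrix(K, n, pos, cond_w, pi_j, depths)
}

draw_null_matrix <- function(K, n, pos, cond_w, pi_j, depths) {
  out <- matrix(0L, K, n)
  for (j in seq_len(n)) {
    occ_local <- if (is.null(pi_j[[j]])) seq_along(pos) else {
      pps_systematic(pi_j[[j]])
    }
    occ <- pos[occ_local]
    counts <- rep(1L, length(occ))
    extra <- depths[j] - length(occ)
    if (extra > 0) {
      pr <- cond_w[occ_local]
      if (sum(pr) == 0) pr <- rep(1, length(occ))
      counts <- counts + stats::rmultinom(1, extra, pr)[, 1]
    }
    out[occ, j] <- counts
  }
  out
}

# Inclusion probabilities pi = pmin(c * w, 1) with sum(pi) = S (bisection).
inclusion_probs <- function(w, S) {
  lo <- 0; hi <- (S / sum(w)) * 2 + 1
  while (sum(pmin(hi * w, 1)) < S) hi <- hi * 2
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    if (sum(pmin(mid * w, 1)) < S) lo <- mid else hi <- mid
  }
  pmin(((lo + hi) / 2) * w, 1)
}

# Randomized systematic probability-proportional-to-size sampling: returns
# indices of the selected units; each unit's inclusion probability equals
# pi exactly (sum(pi) must be an integer).
pps_systematic <- function(pi) {
  ord <- sample.int(length(pi))
  cs <- cumsum(pi[ord])
  S <- round(cs[length(cs)])
  pts <- stats::runif(1) + seq_len(S) - 1
  sel <- findInterval(pts, cs, left.open = TRUE) + 1L
  ord[pmin(sel, length(pi))]
}

#' @export
print.nst_result <- function(x, ...) {
  cat(sprintf("NST (%s%s, %d null draws)\n", attr(x, "metric"),
              if (attr(x, "abundance_weighted")) ", abundance-weighted" else "",
              attr(x, "n_rand")))
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %s: NST = %.1f%% (%s), ST = %.1f%%\n", x$group[i],
                x$NST[i],
                if (x$NST[i] > 50) "more stochastic" else "more deterministic",
                x$ST[i]))
  }
  invisible(x)
}
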