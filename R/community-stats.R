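#' Prevalence / mean-abundance filtering of taxa
#'
#' Keeps taxa detected (nonzero) in strictly more than `min_prevalence` of
#' samples AND with mean relative abundance strictly greater than
#' `min_mean_ra`. Defaults follow the field's common screen for network
#' construction: present in more than 20% of samples and mean relative
#' abundance above 0.01%. Both comparisons are strict, so a taxon sitting exactly on a
#' threshold is removed.
#'
#' @param t an [abundance_table()] (counts or relative; relative abundances
#'   are computed per sample for the mean-RA criterion).
#' @param min_prevalence fraction of samples, default `0.20`.
#' @param min_mean_ra mean relative abundance, default `1e-4`.
#' @return filtered [abundance_table()].
#' @export
filter_taxa <- function(t, min_prevalence = 0.20, min_mean_ra = 1e-4) {
  stopifnot(inherits(t, "abundance_table"))
  ra <- to_relative(t)$counts
  prev <- rowMeans(t$counts > 0)
  mra <- rowMeans(ra)
  keep <- prev > min_prevalence & mra > min_mean_ra
  if (!any(keep)) {
    stop2("all taxa removed by filtering; relax min_prevalence/min_mean_ra")
  }
  abundance_table(t$counts[keep, , drop = FALSE], t$domain[keep],
                  is_relative = t$is_relative)
}

#' Shannon diversity index of one sample
#'
#' H = -sum p_i log p_i in nats, with abundances renormalized over the
#' requested taxon subset within the sample (conditional composition), so
#' that the index measures evenness/richness of the subset and not the
#' subset's share of the community. A subset with zero total abundance gives
#' H = 0 with a warning.
#'
#' @param t an [abundance_table()].
#' @param sample sample ID.
#' @param taxa_subset optional character vector of taxon IDs; default all.
#' @return numeric scalar, nats.
#' @export
shannon_index <- function(t, sample, taxa_subset = NULL) {
  stopifnot(inherits(t, "abundance_table"))
  if (!sample %in% sample_ids(t)) stop2("unknown sample: ", sample)
  x <- t$counts[, sample]
  if (!is.null(taxa_subset)) {
    taxa_subset <- intersect(taxa_subset, taxa_ids(t))
    if (!length(taxa_subset)) stop2("taxa_subset is empty after intersecting with table")
    x <- x[taxa_subset]
  }
  s <- sum(x)
  if (s == 0) {
    warn2("zero total abundance in subset for sample ", sample, "; H = 0")
    return(0)
  }
  p <- x[x > 0] / s
  -sum(p * log(p))
}

#' Pairwise sample dissimilarities
#'
#' Bray-Curtis (`metric = "bray"`) or Jaccard (`metric = "jaccard"`).
#' When `abundance_weighted = TRUE`, Jaccard is the quantitative
#' (Ruzicka) form `1 - sum(min) / sum(max)`; when `FALSE` both metrics use
#' presence/absence. Computation is delegated to [vegan::vegdist()].
#'
#' @param t an [abundance_table()].
#' @param metric `"bray"` or `"jaccard"`.
#' @param abundance_weighted logical, default `TRUE`.
#' @return object of class `dissimilarity_matrix`: a symmetric matrix in
#'   `[0, 1]` with zero diagonal and sample IDs as dimnames.
#' @export
dissimilarity <- function(t, metric = c("bray", "jaccard"),
                          abundance_weighted = TRUE) {
  metric <- match.arg(metric)
  x <- if (inherits(t, "abundance_table")) t$counts else as.matrix(t)
  if (ncol(x) < 2L) stop2("need at least 2 samples")
  zero <- colSums(x) == 0
  if (any(zero)) {
    stop2("all-zero samples: ", paste(colnames(x)[zero], collapse = ", "))
  }
  d <- vegan::vegdist(t(x), method = metric, binary = !abundance_weighted)
  D <- as.matrix(d)
  dimnames(D) <- list(colnames(x), colnames(x))
  structure(D, class = c("dissimilarity_matrix", "matrix", "array"),
            metric = metric, abundance_weighted = abundance_weighted)
}

as_dissimilarity <- function(D) {
  D <- as.matrix(D)
  if (!isSymmetric(unname(D), tol = 1e-8)) stop2("dissimilarity matrix must be symmetric")
  D
}

#' Principal-coordinate analysis (classical metric scaling)
#'
#' Double-centers `-D^2/2` and eigendecomposes it ([stats::cmdscale()]).
#' Axes are ordered by eigenvalue; negative eigenvalues are reported, not
#' corrected. If `k` exceeds the number of positive eigenvalues, all
#' available axes are returned with a warning.
#'
#' @param D a dissimilarity matrix (as from [dissimilarity()]).
#' @param k number of axes requested.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   including negatives), `share` (eigenvalue / sum of positive
#'   eigenvalues for the returned axes).
#' @export
pcoa <- function(D, k = 2) {
  D <- as_dissimilarity(D)
  stopifnot(k >= 1)
  n <- nrow(D)
  fit <- suppressWarnings(
    stats::cmdscale(stats::as.dist(D), k = min(k, n - 1), eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig), 1))
  if (k > npos) {
    warn2("k = ", k, " exceeds the rank (", npos, "); returning all available axes")
  }
  if (npos == 0L) {  # degenerate: all points coincide
    coords <- matrix(0, n, 1, dimnames = list(rownames(D), "PCo1"))
    return(list(coordinates = coords, eigenvalues = eig, share = NA_real_))
  }
  coords <- fit$points[, seq_len(min(k, npos, ncol(fit$points))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       share = eig[seq_len(ncol(coords))] / sum(eig[eig > 0]))
}

# Gower-centered inner-product matrix of a dissimilarity matrix:
# G = (I - 11'/n) (-D^2/2) (I - 11'/n). tr(G) is the total sum of squares.
gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions a dissimilarity matrix by the factors of a one-sided formula
#' using the Gower-centered trace decomposition, with a pseudo-F statistic
#' per term and permutation p-values. Terms are decomposed sequentially
#' (Type I, in formula order) by default, or marginally with
#' `by = "margin"`. Permutations are unrestricted; p-values use the add-one
#' convention `(1 + b) / (1 + n_perm)`.
#'
#' @param formula one-sided formula naming metadata columns, e.g.
#'   `~ group + time`.
#' @param D dissimilarity matrix with sample IDs as dimnames.
#' @param data data.frame of sample metadata, rownames = sample IDs.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutation draw.
#' @param by `"terms"` (sequential) or `"margin"`.
#' @return data.frame of class `permanova` with one row per term plus a
#'   residual row: `df`, `SS`, `R2`, `F`, `p`. R2 values plus the residual
#'   R2 sum to 1 for `by = "terms"`.
#' @export
permanova <- function(formula, D, data, n_perm = 999, seed = NULL,
                      by = c("terms", "margin")) {
  by <- match.arg(by)
  D <- as_dissimilarity(D)
  if (n_perm < 1) stop2("n_perm must be >= 1")
  ids <- rownames(D)
  if (!is.null(ids)) {
    if (anyDuplicated(ids)) stop2("duplicated sample IDs in D")
    missing <- setdiff(ids, rownames(data))
    if (length(missing)) stop2("samples missing from metadata: ",
                               paste(missing, collapse = ", "))
    data <- data[ids, , drop = FALSE]
  }
  n <- nrow(D)
  tf <- stats::terms(formula)
  term_labels <- attr(tf, "term.labels")
  if (!length(term_labels)) stop2("formula has no terms")
  mf <- stats::model.frame(formula, data)
  for (v in colnames(mf)) if (is.character(mf[[v]])) mf[[v]] <- factor(mf[[v]])
  G <- gower_center(D)
  ss_total <- sum(diag(G))

  hat <- function(X) {
    qrX <- qr(X)
    Q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
    tcrossprod(Q)
  }
  # model matrices for nested sequences of terms (always with intercept)
  mm_for <- function(labels) {
    f <- stats::reformulate(if (length(labels)) labels else "1")
    stats::model.matrix(f, mf)
  }
  # hat matrices depend only on the design: precompute the per-term
  # projector increments; each (permuted) G then needs only elementwise
  # products, since tr(H G) = sum(H * G) for symmetric H, G
  H0 <- hat(mm_for(character(0)))
  H_full <- hat(mm_for(term_labels))
  deltas <- vector("list", length(term_labels))
  df <- numeric(length(term_labels))
  if (by == "terms") {
    H_prev <- H0
    for (i in seq_along(term_labels)) {
      H_i <- if (i == length(term_labels)) H_full else hat(mm_for(term_labels[seq_len(i)]))
      deltas[[i]] <- H_i - H_prev
      df[i] <- sum(diag(H_i)) - sum(diag(H_prev))
      H_prev <- H_i
    }
  } else {
    for (i in seq_along(term_labels)) {
      H_wo <- hat(mm_for(term_labels[-i]))
      deltas[[i]] <- H_full - H_wo
      df[i] <- sum(diag(H_full)) - sum(diag(H_wo))
    }
  }
  df_res <- n - sum(diag(H_full))
  decompose <- function(Gp) {
    ss <- vapply(deltas, function(d) sum(d * Gp), numeric(1))
    ss_res <- sum(diag(Gp)) - sum(H_full * Gp)
    list(ss = ss, ss_res = ss_res)
  }

  obs <- decompose(G)
  obs$df <- df; obs$df_res <- df_res
  F_obs <- (obs$ss / df) / (obs$ss_res / df_res)
  exceed <- rep(0L, length(term_labels))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      perm <- decompose(G[idx, idx])
      F_b <- (perm$ss / df) / (perm$ss_res / df_res)
      exceed <- exceed + (F_b >= F_obs - 1e-12)
    }
  })
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(
    term = c(term_labels, "Residual"),
    df = c(obs$df, obs$df_res),
    SS = c(obs$ss, obs$ss_res),
    R2 = c(obs$ss, obs$ss_res) / ss_total,
    F = c(F_obs, NA),
    p = c(p, NA),
    stringsAsFactors = FALSE
  )
  attr(out, "n_perm") <- n_perm
  attr(out, "by") <- by
  class(out) <- c("permanova", "data.frame")
  out
}

#' Mantel test between two dissimilarity matrices
#'
#' Correlates the lower triangles of two matrices over the same samples and
#' assesses significance by permuting the sample order of `D2`
#' (one-sided, `r_perm >= r_obs`, the convention of community ecology).
#' P-values use the add-one convention.
#'
#' @param D1,D2 dissimilarity matrices over the same sample set and order.
#' @param method `"pearson"` or `"spearman"`.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `r`, `p`, `n_perm`, `method`.
#' @export
mantel <- function(D1, D2, method = c("pearson", "spearman"),
                   n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  D1 <- as_dissimilarity(D1); D2 <- as_dissimilarity(D2)
  if (!all(dim(D1) == dim(D2))) stop2("dissimilarity matrices differ in size")
  if (!is.null(rownames(D1)) && !is.null(rownames(D2)) &&
      !identical(rownames(D1), rownames(D2))) {
    stop2("sample IDs/order differ between matrices")
  }
  v1 <- lower_tri(D1)
  r_obs <- stats::cor(v1, lower_tri(D2), method = method)
  n <- nrow(D1)
  exceed <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      r_b <- stats::cor(v1, lower_tri(D2[idx, idx]), method = method)
      exceed <- exceed + (r_b >= r_obs - 1e-12)
    }
  })
  list(r = r_obs, p = (1 + exceed) / (1 + n_perm), n_perm = n_perm,
       method = method)
}

#' Per-taxon differential enrichment between two groups
#'
#' Volcano-style screen: for each taxon, a two-sided test on relative
#' abundances between the two levels of `group_factor` (Wilcoxon rank-sum
#' by default, Welch t-test with `test = "t"`), BH adjustment across taxa,
#' and a log2 fold change of group mean relative abundances with a
#' pseudo-count of half the smallest nonzero relative abundance. A taxon is
#' called enriched in a group when `p_adj <= alpha` and its mean RA is
#' higher there; it is flagged dominant when its overall mean RA is
#' strictly greater than `dominance_ra` (default 0.1%).
#'
#' @param t an [abundance_table()].
#' @param meta metadata data.frame, rownames = sample IDs.
#' @param group_factor name of the metadata column (exactly two levels).
#' @param alpha BH-adjusted significance level, default 0.05.
#' @param dominance_ra dominance threshold on overall mean RA, default 1e-3.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return data.frame of class `enrichment_result`: per taxon `log2fc`
#'   (first level over second), `p`, `p_adj`, `enriched_in` (level name or
#'   `NA`), `dominant`, `mean_ra`.
#' @export
differential_enrichment <- function(t, meta, group_factor, alpha = 0.05,
                                    dominance_ra = 1e-3,
                                    test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  stopifnot(inherits(t, "abundance_table"))
  ra <- to_relative(t)$counts
  g <- factor(meta[colnames(ra), group_factor])
  if (nlevels(g) != 2L) stop2("group_factor must have exactly two levels")
  if (any(table(g) < 3L)) stop2("each group needs at least 3 samples")
  lv <- levels(g)
  a <- ra[, g == lv[1], drop = FALSE]
  b <- ra[, g == lv[2], drop = FALSE]
  pc <- min(ra[ra > 0]) / 2
  mean_a <- rowMeans(a); mean_b <- rowMeans(b)
  log2fc <- log2((mean_a + pc) / (mean_b + pc))
  p <- vapply(seq_len(nrow(ra)), function(i) {
    if (stats::sd(ra[i, ]) == 0) return(1)
    if (test == "wilcoxon") {
      stats::wilcox.test(a[i, ], b[i, ], exact = FALSE)$p.value
    } else {
      stats::t.test(a[i, ], b[i, ])$p.value
    }
  }, numeric(1))
  p_adj <- stats::p.adjust(p, method = "BH")
  enriched_in <- ifelse(p_adj <= alpha, ifelse(log2fc > 0, lv[1], lv[2]), NA)
  mean_ra <- rowMeans(ra)
  out <- data.frame(taxon = rownames(ra), log2fc = log2fc, p = p,
                    p_adj = p_adj, enriched_in = enriched_in,
                    dominant = mean_ra > dominance_ra, mean_ra = mean_ra,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "levels") <- lv
  class(out) <- c("enrichment_result", "data.frame")
  out
}
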