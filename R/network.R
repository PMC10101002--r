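#' Build a co-occurrence network from an abundance table
#'
#' Computes rank correlations (Spearman by default) and two-sided p-values
#' for all taxon pairs, adjusts p-values across all tested pairs
#' (Benjamini-Hochberg by default), and keeps an edge iff
#' `|rho| >= rho_min` AND `p_adj <= p_max`. The defaults reproduce the
#' common stringent screen `|rho| >= 0.8`, `p_adj <= 0.01`. Constant
#' (zero-variance) taxa are excluded from testing with a warning and can
#' never be edge endpoints; taxa left without edges stay in the node set,
#' flagged isolated.
#'
#' P-values use the t-distribution approximation for `n >= 10` samples and
#' the exact permutation distribution of the correlation for `n < 10`
#' (average ranks for ties in both cases).
#'
#' @param t a filtered [abundance_table()] with at least 4 samples.
#' @param rho_min minimum absolute correlation, default 0.8.
#' @param p_max maximum adjusted p, default 0.01.
#' @param fdr `"BH"` (adjust over all tested pairs) or `"none"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return object of class `cooccurrence_network`: list with `nodes`
#'   (data.frame: taxon, domain, constant, isolated), `edges` (data.frame:
#'   from, to, rho, p_raw, p_adj, sign), `partition` (`NULL` until
#'   [detect_modules()]), `Q`, `algorithm_Q`.
#' @export
build_network <- function(t, rho_min = 0.8, p_max = 0.01,
                          fdr = c("BH", "none"),
                          method = c("spearman", "pearson")) {
  fdr <- match.arg(fdr); method <- match.arg(method)
  stopifnot(inherits(t, "abundance_table"))
  x <- t$counts
  n <- ncol(x)
  if (n < 4L) stop2("need at least 4 samples")
  sds <- apply(x, 1, stats::sd)
  constant <- sds == 0
  if (any(constant)) {
    warn2(sum(constant), " constant taxa excluded from correlation testing")
  }
  tested <- rownames(x)[!constant]
  edges <- data.frame(from = character(0), to = character(0),
                      rho = numeric(0), p_raw = numeric(0),
                      p_adj = numeric(0), sign = integer(0))
  if (length(tested) >= 2L) {
    xt <- t(x[tested, , drop = FALSE])
    rho <- stats::cor(xt, method = method)
    pairs <- which(upper.tri(rho), arr.ind = TRUE)
    r <- rho[pairs]
    p_raw <- pair_cor_pvalues(xt, pairs, r, n, method)
    p_adj <- if (fdr == "BH") stats::p.adjust(p_raw, method = "BH") else p_raw
    keep <- abs(r) >= rho_min - 1e-12 & p_adj <= p_max + 1e-12
    edges <- data.frame(
      from = tested[pairs[keep, 1]],
      to = tested[pairs[keep, 2]],
      rho = r[keep], p_raw = p_raw[keep], p_adj = p_adj[keep],
      sign = ifelse(r[keep] >= 0, 1L, -1L),
      stringsAsFactors = FALSE
    )
  }
  in_edge <- unique(c(edges$from, edges$to))
  nodes <- data.frame(taxon = rownames(x),
                      domain = unname(t$domain),
                      constant = constant,
                      isolated = !(rownames(x) %in% in_edge),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, partition = NULL,
                 Q = NA_real_, algorithm_Q = NULL,
                 rho_min = rho_min, p_max = p_max, method = method),
            class = "cooccurrence_network")
}

# Two-sided p-values for pairwise correlations: t approximation for
# n >= 10, exact enumeration of all n! permutations below that.
pair_cor_pvalues <- function(xt, pairs, r, n, method) {
  if (n >= 10L) {
    tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    return(pmin(p, 1))
  }
  perms <- all_permutations(n)
  vapply(seq_len(nrow(pairs)), function(k) {
    a <- xt[, pairs[k, 1]]; b <- xt[, pairs[k, 2]]
    if (method == "spearman") { a <- rank(a); b <- rank(b) }
    r_obs <- stats::cor(a, b)
    r_perm <- apply(perms, 1, function(ix) stats::cor(a, b[ix]))
    mean(abs(r_perm) >= abs(r_obs) - 1e-12)
  }, numeric(1))
}

# All permutations of 1..n as a matrix (n! rows); n is small by construction.
all_permutations <- function(n) {
  if (n > 9L) stop2("exact permutation enumeration limited to n <= 9")
  rec <- function(v) {
    if (length(v) == 1L) return(matrix(v, 1))
    do.call(rbind, lapply(seq_along(v), function(i) {
      cbind(v[i], rec(v[-i]))
    }))
  }
  rec(seq_len(n))
}

# igraph view of the network (all nodes, including isolated ones).
network_igraph <- function(net, weighted = FALSE) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$taxon)
  igraph::E(g)$rho <- net$edges$rho
  igraph::E(g)$sign <- net$edges$sign
  igraph::E(g)$p_adj <- net$edges$p_adj
  if (weighted) igraph::E(g)$weight <- abs(net$edges$rho)
  igraph::V(g)$domain <- net$nodes$domain
  if (!is.null(net$partition)) {
    igraph::V(g)$module <- unname(net$partition[net$nodes$taxon])
  }
  g
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(sprintf("cooccurrence_network: %d nodes, %d edges (%d +, %d -)\n",
              nrow(x$nodes), nrow(x$edges),
              sum(x$edges$sign == 1), sum(x$edges$sign == -1)))
  if (!is.null(x$partition)) {
    cat(sprintf("  %d modules, modularity Q = %.4f\n",
                length(unique(x$partition)), x$Q))
  }
  invisible(x)
}

#' Detect network modules by several modularity algorithms
#'
#' Runs greedy agglomerative modularity optimization, Louvain (multilevel),
#' and label propagation on the unweighted, sign-agnostic edge skeleton,
#' computes Newman-Girvan modularity Q for each partition, and keeps the
#' partition with the highest Q (ties resolved in that fixed algorithm
#' order). Module IDs are relabeled 0, 1, 2, ... by decreasing module size,
#' so module 0 is always the largest ecological cluster. Set
#' `weighted = TRUE` to let `|rho|` weight both the algorithms and Q.
#'
#' @param net a [build_network()] result with at least one edge (an
#'   edgeless network yields one singleton module per node and Q = 0).
#' @param algorithms subset of `c("fast_greedy", "louvain",
#'   "label_prop")`.
#' @param seed RNG seed (Louvain and label propagation are stochastic).
#' @param weighted use `|rho|` edge weights, default `FALSE`.
#' @return the network with `partition` (named integer vector, 0-based
#'   module IDs), `Q`, and `algorithm_Q` filled.
#' @export
detect_modules <- function(net, algorithms = c("fast_greedy", "louvain", "label_prop"),
                           seed = 1, weighted = FALSE) {
  stopifnot(inherits(net, "cooccurrence_network"))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  g <- network_igraph(net, weighted = weighted)
  w <- if (weighted) igraph::E(g)$weight else NULL
  if (igraph::ecount(g) == 0L) {
    part <- seq_len(nrow(net$nodes)) - 1L
    names(part) <- net$nodes$taxon
    net$partition <- part
    net$Q <- 0
    net$algorithm_Q <- stats::setNames(numeric(length(algorithms)), algorithms)
    return(net)
  }
  run_algo <- function(a) {
    comm <- with_seed(seed, switch(a,
      fast_greedy = igraph::cluster_fast_greedy(g, weights = w),
      louvain = igraph::cluster_louvain(g, weights = w),
      label_prop = igraph::cluster_label_prop(g, weights = w)
    ))
    memb <- igraph::membership(comm)
    list(membership = memb, Q = igraph::modularity(g, memb, weights = w))
  }
  res <- lapply(algorithms, run_algo)
  qs <- vapply(res, `[[`, numeric(1), "Q")
  best <- res[[which.max(qs)]]  # which.max takes the first maximum: fixed order
  memb <- best$membership
  # relabel by decreasing module size, 0-based; ties broken by old label
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes) - 1L, names(sizes))
  part <- relab[as.character(memb)]
  names(part) <- names(memb)
  net$partition <- part[net$nodes$taxon]
  names(net$partition) <- net$nodes$taxon
  net$Q <- best$Q
  net$algorithm_Q <- stats::setNames(qs, algorithms)
  net
}

#' Topology summary of a co-occurrence network
#'
#' Node/edge counts, signed edge counts, density `2E / (N (N - 1))`, mean
#' local clustering coefficient (nodes with degree < 2 contribute 0),
#' modularity Q of the stored partition, and the number and node share of
#' large modules (>= `large_module_min` nodes, default 5).
#'
#' @param net a network with a module partition ([detect_modules()]).
#' @param large_module_min minimum size of a "large" module, default 5.
#' @return data.frame with one row of summary statistics.
#' @export
summarize_network <- function(net, large_module_min = 5L) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (is.null(net$partition)) stop2("run detect_modules() first")
  g <- network_igraph(net)
  n <- igraph::vcount(g); e <- igraph::ecount(g)
  cc_local <- igraph::transitivity(g, type = "local", isolates = "zero")
  cc_local[igraph::degree(g) < 2] <- 0
  sizes <- table(net$partition)
  large <- sizes[sizes >= large_module_min]
  data.frame(
    nodes = n,
    edges = e,
    positive_edges = sum(net$edges$sign == 1),
    negative_edges = sum(net$edges$sign == -1),
    clustering = mean(cc_local),
    density = if (n > 1) 2 * e / (n * (n - 1)) else 0,
    modularity = net$Q,
    n_modules = length(sizes),
    n_large_modules = length(large),
    frac_nodes_large_modules = sum(large) / n
  )
}
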