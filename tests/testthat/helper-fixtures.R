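# Fixture builders and independent oracles used across the suite.
# Oracles deliberately re-derive every quantity from its definition, on a
# different code path than the implementation they check.

tiny_counts <- function() {
  matrix(c(5, 3, 0, 2, 1, 4), nrow = 3,
         dimnames = list(paste0("otu", 1:3), c("s1", "s2")))
}

random_table <- function(n_taxa, n_samples, seed = 1, lambda = 20,
                         domain = "bacteria") {
  set.seed(seed)
  m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
              dimnames = list(sprintf("t%03d", seq_len(n_taxa)),
                              sprintf("s%02d", seq_len(n_samples))))
  abundance_table(m, domain = domain, is_relative = FALSE)
}

# Build a cooccurrence_network by hand from an edge list (testing the
# topology machinery without correlation inference).
manual_network <- function(node_ids, edges_from, edges_to,
                           domain = "bacteria", partition = NULL) {
  edges <- data.frame(from = edges_from, to = edges_to,
                      rho = rep(0.9, length(edges_from)),
                      p_raw = rep(1e-6, length(edges_from)),
                      p_adj = rep(1e-5, length(edges_from)),
                      sign = rep(1L, length(edges_from)),
                      stringsAsFactors = FALSE)
  in_edge <- unique(c(edges$from, edges$to))
  nodes <- data.frame(taxon = node_ids,
                      domain = rep_len(domain, length(node_ids)),
                      constant = FALSE,
                      isolated = !(node_ids %in% in_edge),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges, partition = partition,
                 Q = if (is.null(partition)) NA_real_ else 0,
                 algorithm_Q = NULL, rho_min = 0.8, p_max = 0.01,
                 method = "spearman"),
            class = "cooccurrence_network")
}

# All permutations of 1..n (recursive; oracle-side implementation).
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  # step-up: adjusted p_(i) = min_{j >= i} sorted_j, capped at 1
  run_min <- rev(cummin(rev(sorted)))
  adj[o] <- pmin(run_min, 1)
  adj
}

# Brute-force pairwise Spearman edge selection: cor.test per pair (its own
# p-value code path) + oracle BH + threshold screen.
oracle_edge_set <- function(counts, rho_min = 0.8, p_max = 0.01) {
  ids <- rownames(counts)
  pairs <- t(combn(length(ids), 2))
  rho <- p <- numeric(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    ct <- suppressWarnings(
      cor.test(counts[pairs[k, 1], ], counts[pairs[k, 2], ],
               method = "spearman", exact = FALSE))
    rho[k] <- unname(ct$estimate)
    p[k] <- ct$p.value
  }
  p_adj <- oracle_bh(p)
  keep <- abs(rho) >= rho_min & p_adj <= p_max
  ek <- cbind(ids[pairs[keep, 1]], ids[pairs[keep, 2]])
  sort(apply(ek, 1, function(r) paste(sort(r), collapse = "|")))
}

edge_keys <- function(net) {
  if (!nrow(net$edges)) return(character(0))
  sort(apply(net$edges[, c("from", "to")], 1,
             function(r) paste(sort(r), collapse = "|")))
}

# Definition-level Zi/Pi recomputation from an edge list and partition.
oracle_zipi <- function(node_ids, edges_from, edges_to, partition) {
  k_is <- function(i) {
    nb <- c(edges_to[edges_from == i], edges_from[edges_to == i])
    table(factor(partition[nb], levels = sort(unique(partition))))
  }
  zi <- pi_c <- numeric(length(node_ids))
  names(zi) <- names(pi_c) <- node_ids
  kw <- vapply(node_ids, function(i) {
    as.numeric(k_is(i)[as.character(partition[i])])
  }, numeric(1))
  for (i in node_ids) {
    mod_members <- node_ids[partition[node_ids] == partition[i]]
    mu <- mean(kw[mod_members])
    sd_pop <- sqrt(mean((kw[mod_members] - mu)^2))
    zi[i] <- if (sd_pop == 0 || length(mod_members) <= 1) 0 else (kw[i] - mu) / sd_pop
    ki <- k_is(i)
    tot <- sum(ki)
    pi_c[i] <- if (tot == 0) 0 else 1 - sum((as.numeric(ki) / tot)^2)
  }
  list(Zi = zi, Pi = pi_c)
}

# Exhaustive-permutation PERMANOVA for one factor, from the direct
# within/between sum-of-squares formulas (McArdle-Anderson identity),
# not the projector trace used by the implementation.
oracle_permanova_exhaustive <- function(D, labels) {
  n <- nrow(D)
  ss_total <- sum(D[lower.tri(D)]^2) / n
  f_stat <- function(lab) {
    ss_within <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      sub <- D[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[lower.tri(sub)]^2) / length(idx)
    }
    ss_b <- ss_total - ss_within
    a <- length(unique(lab))
    (ss_b / (a - 1)) / (ss_within / (n - a))
  }
  F_obs <- f_stat(labels)
  perms <- oracle_perms(n)
  F_all <- apply(perms, 1, function(ix) f_stat(labels[ix]))
  list(F = F_obs,
       R2 = 1 - 1 / (1 + F_obs * (length(unique(labels)) - 1) /
                       (n - length(unique(labels)))),
       p_exhaustive = mean(F_all >= F_obs - 1e-12))
}

# Exhaustive Mantel: correlation of lower triangles over all permutations.
oracle_mantel_exhaustive <- function(D1, D2, method = "pearson") {
  lt <- function(m) m[lower.tri(m)]
  r_obs <- cor(lt(D1), lt(D2), method = method)
  perms <- oracle_perms(nrow(D1))
  r_all <- apply(perms, 1, function(ix) cor(lt(D1), lt(D2[ix, ix]), method = method))
  list(r = r_obs, p_exhaustive = mean(r_all >= r_obs - 1e-12))
}

# Independent robustness simulator: igraph-based secondary-extinction
# count, a separate code path from the package's edge-list loop.
oracle_robustness_once <- function(net, removed, exempt_isolated = TRUE) {
  g <- igraph::graph_from_data_frame(net$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = net$nodes$taxon)
  orig_iso <- igraph::degree(g) == 0
  names(orig_iso) <- net$nodes$taxon
  alive <- setdiff(net$nodes$taxon, removed)
  repeat {
    sub <- igraph::induced_subgraph(g, alive)
    deg <- igraph::degree(sub)
    dying <- names(deg)[deg == 0]
    if (exempt_isolated) dying <- dying[!orig_iso[dying]]
    if (!length(dying)) break
    alive <- setdiff(alive, dying)
  }
  length(alive) / nrow(net$nodes)
}
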