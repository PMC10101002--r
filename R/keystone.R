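#' Within-module (Zi) and among-module (Pi) connectivity and node roles
#'
#' For every node of a partitioned network, computes the within-module
#' degree z-score `Zi = (k_within - mean(k_within)) / sd(k_within)` (mean
#' and population-denominator sd taken over the node's module) and the
#' participation coefficient `Pi = 1 - sum_s (k_is / k_i)^2`, where `k_is`
#' counts links from node i into module s. Modules of size 1 or with zero
#' within-degree variance give `Zi = 0`, and isolated nodes give `Pi = 0`,
#' so every node is classifiable. Degree counts positive and negative
#' edges alike.
#'
#' Topological roles follow the standard Zi/Pi grid with inclusive
#' boundaries: network hub (`Zi >= 2.5` and `Pi >= 0.62`), module hub
#' (`Zi >= 2.5`, `Pi < 0.62`), connector (`Zi < 2.5`, `Pi >= 0.62`),
#' peripheral otherwise.
#'
#' @param net a `cooccurrence_network` with a module partition.
#' @param zi_threshold,pi_threshold role thresholds, defaults 2.5 and 0.62.
#' @return data.frame of class `node_roles`: per node `taxon`, `domain`,
#'   `module`, `k` (degree), `Zi`, `Pi`, `role`, `closeness`.
#' @export
zi_pi <- function(net, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(inherits(net, "cooccurrence_network"))
  if (is.null(net$partition)) stop2("run detect_modules() first")
  taxa <- net$nodes$taxon
  if (!all(taxa %in% names(net$partition))) {
    stop2("nodes missing from partition: ",
          paste(setdiff(taxa, names(net$partition)), collapse = ", "))
  }
  mod <- net$partition[taxa]
  g <- network_igraph(net)
  A_from <- match(net$edges$from, taxa)
  A_to <- match(net$edges$to, taxa)
  n <- length(taxa)
  k <- tabulate(c(A_from, A_to), nbins = n)

  # k_is: links of node i into module s
  mods <- sort(unique(mod))
  k_is <- matrix(0L, n, length(mods), dimnames = list(taxa, mods))
  for (e in seq_along(A_from)) {
    i <- A_from[e]; j <- A_to[e]
    k_is[i, as.character(mod[j])] <- k_is[i, as.character(mod[j])] + 1L
    k_is[j, as.character(mod[i])] <- k_is[j, as.character(mod[i])] + 1L
  }
  stopifnot(all(rowSums(k_is) == k))  # links must be fully attributed

  k_within <- k_is[cbind(seq_len(n), match(as.character(mod), colnames(k_is)))]
  zi <- numeric(n)
  for (m in mods) {
    idx <- which(mod == m)
    kw <- k_within[idx]
    mu <- mean(kw)
    sd_pop <- sqrt(mean((kw - mu)^2))
    zi[idx] <- if (length(idx) <= 1L || sd_pop == 0) 0 else (kw - mu) / sd_pop
  }
  pi_coef <- ifelse(k == 0, 0, 1 - rowSums((k_is / pmax(k, 1))^2))
  role <- ifelse(zi >= zi_threshold,
                 ifelse(pi_coef >= pi_threshold, "network_hub", "module_hub"),
                 ifelse(pi_coef >= pi_threshold, "connector", "peripheral"))
  clo <- suppressWarnings(igraph::closeness(g, normalized = TRUE))
  clo[!is.finite(clo)] <- 0
  out <- data.frame(taxon = taxa, domain = net$nodes$domain,
                    module = unname(mod), k = k, Zi = zi, Pi = pi_coef,
                    role = role, closeness = unname(clo[taxa]),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("node_roles", "data.frame")
  out
}

#' Keystone taxa from node roles
#'
#' Keystone taxa are the union of network hubs, module hubs, and
#' connectors. Also reports per-role counts (the connector count is the
#' figure usually quoted for these networks).
#'
#' @param roles a [zi_pi()] result.
#' @return list with `keystone` (character vector of taxa), `counts`
#'   (named integer vector over all four roles), `n_connectors`.
#' @export
keystone_set <- function(roles) {
  stopifnot(inherits(roles, "node_roles"))
  keystone_roles <- c("network_hub", "module_hub", "connector")
  counts <- table(factor(roles$role,
                         levels = c("network_hub", "module_hub",
                                    "connector", "peripheral")))
  list(keystone = roles$taxon[roles$role %in% keystone_roles],
       counts = stats::setNames(as.integer(counts), names(counts)),
       n_connectors = as.integer(counts[["connector"]]))
}
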