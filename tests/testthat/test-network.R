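test_that("monotone transforms give rho = 1 edges; constant taxa never do", {
  set.seed(2)
  x <- rnorm(24)
  m <- rbind(a = x - min(x) + 1, b = exp(x), c = rep(3, 24),
             d = abs(rnorm(24)))
  colnames(m) <- sprintf("s%02d", 1:24)
  t <- abundance_table(m)
  expect_warning(net <- build_network(t, rho_min = 0.8, p_max = 0.01),
                 "constant")
  expect_true("a|b" %in% edge_keys(net))
  expect_false(any(grepl("c", net$edges$from)) || any(grepl("c", net$edges$to)))
  expect_equal(net$edges$rho[net$edges$from == "a" & net$edges$to == "b"], 1)
})

test_that("edge set equals the brute-force Spearman + step-up BH oracle", {
  # moderately correlated fixture so thresholds actually bind
  set.seed(31)
  z <- matrix(rnorm(5 * 24), 5, 24)
  m <- matrix(0, 20, 24, dimnames = list(sprintf("t%02d", 1:20),
                                         sprintf("s%02d", 1:24)))
  for (i in 1:20) {
    m[i, ] <- exp(z[(i - 1) %% 5 + 1, ] + rnorm(24, sd = c(0.1, 0.6)[1 + i %% 2]))
  }
  t <- abundance_table(m)
  net <- build_network(t, rho_min = 0.8, p_max = 0.01)
  expect_identical(edge_keys(net), oracle_edge_set(m, 0.8, 0.01))
  # permutation invariance to taxon order
  t2 <- abundance_table(m[sample(20), ])
  expect_identical(edge_keys(build_network(t2)), edge_keys(net))
})

test_that("small-sample p-values come from the exact permutation distribution", {
  set.seed(6)
  m <- matrix(rpois(4 * 6, 30), 4, 6,
              dimnames = list(paste0("t", 1:4), paste0("s", 1:6)))
  net <- build_network(abundance_table(m), rho_min = 0, p_max = 1)
  # oracle: enumerate all 720 permutations per pair
  perms <- oracle_perms(6)
  for (k in seq_len(nrow(net$edges))) {
    a <- rank(m[net$edges$from[k], ]); b <- rank(m[net$edges$to[k], ])
    r_obs <- cor(a, b)
    r_all <- apply(perms, 1, function(ix) cor(a, b[ix]))
    expect_equal(net$edges$p_raw[k], mean(abs(r_all) >= abs(r_obs) - 1e-12),
                 tolerance = 1e-12)
  }
})

test_that("with thresholds disabled the network is complete on non-constant taxa", {
  t <- random_table(7, 12, seed = 9)
  net <- build_network(t, rho_min = 0, p_max = 1)
  expect_equal(nrow(net$edges), choose(7, 2))
})

test_that("module detection recovers planted cliques and reports the best Q", {
  # two 5-cliques joined by one edge
  ids <- sprintf("n%02d", 1:10)
  ef <- c(); et <- c()
  for (blk in list(1:5, 6:10)) {
    for (i in blk) for (j in blk) if (i < j) { ef <- c(ef, ids[i]); et <- c(et, ids[j]) }
  }
  ef <- c(ef, ids[5]); et <- c(et, ids[6])
  net <- manual_network(ids, ef, et)
  net <- detect_modules(net, seed = 1)
  part <- net$partition
  expect_equal(length(unique(part[ids[1:5]])), 1L)
  expect_equal(length(unique(part[ids[6:10]])), 1L)
  expect_false(part[ids[1]] == part[ids[10]])
  # closed-form Newman-Girvan Q for the two-clique split:
  # m = 21 edges; within = 10 per block; block degree sum = 21 each
  q_hand <- sum(sapply(c(10, 10), function(e_in) e_in / 21) -
                  sapply(c(21, 21), function(dsum) (dsum / (2 * 21))^2))
  expect_equal(net$Q, q_hand, tolerance = 1e-12)
  expect_true(all(net$Q >= net$algorithm_Q - 1e-12))
  # complete graph collapses to one module
  efc <- c(); etc_ <- c()
  for (i in 1:6) for (j in 1:6) if (i < j) { efc <- c(efc, ids[i]); etc_ <- c(etc_, ids[j]) }
  one <- detect_modules(manual_network(ids[1:6], efc, etc_), seed = 1)
  expect_equal(length(unique(one$partition)), 1L)
  # edgeless: singleton modules, Q = 0
  iso <- detect_modules(manual_network(ids[1:3], character(0), character(0)), seed = 1)
  expect_equal(length(unique(iso$partition)), 3L)
  expect_equal(iso$Q, 0)
})

test_that("module IDs are 0-based and ordered by decreasing size", {
  d <- generate_dataset(seed = 3)
  merged <- merge_domains(d$bacteria, d$fungi, normalize = "domain")
  f <- filter_taxa(merge_domains(d$bacteria, d$fungi, normalize = "none"))
  fra <- abundance_table(merged$counts[rownames(f$counts), ],
                         merged$domain[rownames(f$counts)], is_relative = FALSE)
  net <- detect_modules(build_network(fra), seed = 2)
  sizes <- as.integer(table(net$partition))
  expect_equal(sort(unique(net$partition)), seq_along(sizes) - 1L)
  expect_true(all(diff(as.integer(table(net$partition))) <= 0))
})

test_that("summarize_network reports exact closed-form topology values", {
  ids <- c("a", "b", "c")
  tri <- manual_network(ids, c("a", "a", "b"), c("b", "c", "c"),
                        partition = setNames(c(0L, 0L, 0L), ids))
  s <- summarize_network(tri)
  expect_equal(s$clustering, 1)
  expect_equal(s$density, 1)
  path <- manual_network(ids, c("a", "b"), c("b", "c"),
                         partition = setNames(c(0L, 0L, 0L), ids))
  sp <- summarize_network(path)
  expect_equal(sp$clustering, 0)
  expect_equal(sp$density, 2 / 3)
  # density recount on a random graph
  set.seed(17)
  n <- 15
  all_pairs <- t(combn(n, 2))
  pick <- all_pairs[runif(nrow(all_pairs)) < 0.3, , drop = FALSE]
  idsr <- sprintf("v%02d", 1:n)
  netr <- manual_network(idsr, idsr[pick[, 1]], idsr[pick[, 2]])
  netr <- detect_modules(netr, seed = 1)
  sr <- summarize_network(netr)
  expect_equal(sr$density, 2 * nrow(pick) / (n * (n - 1)))
  expect_equal(sr$edges, nrow(pick))
})
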