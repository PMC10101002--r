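complete_net <- function(n) {
  ids <- sprintf("k%02d", seq_len(n))
  pairs <- t(combn(ids, 2))
  manual_network(ids, pairs[, 1], pairs[, 2])
}

star_net <- function(n_leaves) {
  ids <- c("hub", sprintf("leaf%02d", seq_len(n_leaves)))
  manual_network(ids, rep("hub", n_leaves), ids[-1])
}

test_that("a clique loses exactly the removed fraction (no secondary extinction)", {
  net <- complete_net(10)
  rc <- robustness(net, fractions = c(0.1, 0.3, 0.5, 0.8), n_sim = 5, seed = 1)
  expect_equal(rc$mean, 1 - c(0.1, 0.3, 0.5, 0.8))
  expect_equal(rc$sd, rep(0, 4))
})

test_that("removing a star's hub annihilates the network", {
  net <- star_net(9)
  # fraction 0.1 of 10 nodes removes exactly one node; find a seed whose
  # single removal is the hub, then everything must die
  hub_idx <- which(net$nodes$taxon == "hub")
  seed_hits_hub <- NULL
  for (s in 1:200) {
    pick <- fermnet:::with_seed(s, sample.int(10, 1))
    if (pick == hub_idx) { seed_hits_hub <- s; break }
  }
  rc <- robustness(net, fractions = 0.1, n_sim = 1, seed = seed_hits_hub)
  expect_equal(rc$mean, 0)
  # removing one leaf instead keeps everything else alive
  seed_hits_leaf <- NULL
  for (s in 1:200) {
    pick <- fermnet:::with_seed(s, sample.int(10, 1))
    if (pick != hub_idx) { seed_hits_leaf <- s; break }
  }
  rc2 <- robustness(net, fractions = 0.1, n_sim = 1, seed = seed_hits_leaf)
  expect_equal(rc2$mean, 0.9)
})

test_that("fraction 1.0 removes everything and counts use round-half-up", {
  net <- complete_net(10)
  rc <- robustness(net, fractions = 1.0, n_sim = 2, seed = 1)
  expect_equal(rc$mean, 0)
  # 0.05 * 10 = 0.5 rounds up to 1 removed node
  rc2 <- robustness(net, fractions = 0.05, n_sim = 3, seed = 1)
  expect_equal(rc2$mean, 0.9)
})

test_that("originally isolated nodes are exempt from secondary extinction", {
  ids <- c("a", "b", "c", "lone")
  net <- manual_network(ids, c("a", "b"), c("b", "c"))
  # remove b: a and c become isolated and die; lone survives (exempt)
  for (s in 1:200) {
    pick <- fermnet:::with_seed(s, sample.int(4, 1))
    if (ids[pick] == "b") {
      rc <- robustness(net, fractions = 0.25, n_sim = 1, seed = s)
      expect_equal(rc$mean, 0.25)  # only "lone" survives
      rc_inc <- robustness(net, fractions = 0.25, n_sim = 1, seed = s,
                           exempt_isolated = FALSE)
      expect_equal(rc_inc$mean, 0)
      break
    }
  }
})

test_that("simulated curves match an independently coded simulator", {
  set.seed(23)
  ids <- sprintf("v%02d", 1:50)
  pairs <- t(combn(ids, 2))
  pick <- pairs[runif(nrow(pairs)) < 0.06, , drop = FALSE]
  net <- manual_network(ids, pick[, 1], pick[, 2])
  # same removal sets, two implementations
  for (s in 1:20) {
    removed <- fermnet:::with_seed(s, sample(ids, 10))
    rc <- local({
      alive_frac <- fermnet:::with_seed(s, {
        r <- robustness(net, fractions = 0.2, n_sim = 1, seed = s)
        r$mean
      })
      alive_frac
    })
    expect_equal(rc, oracle_robustness_once(net, removed))
  }
})

test_that("mean curves are monotone non-increasing within Monte-Carlo noise", {
  set.seed(29)
  ids <- sprintf("v%02d", 1:40)
  pairs <- t(combn(ids, 2))
  pick <- pairs[runif(nrow(pairs)) < 0.08, , drop = FALSE]
  net <- manual_network(ids, pick[, 1], pick[, 2])
  rc <- robustness(net, fractions = seq(0.05, 1, by = 0.05), n_sim = 200, seed = 5)
  mc_sd <- rc$sd / sqrt(rc$n)
  diffs <- diff(rc$mean)
  tol <- 2 * sqrt(mc_sd[-1]^2 + mc_sd[-length(mc_sd)]^2)
  expect_true(all(diffs <= tol))
  # remaining proportion bounded by 1 - f plus the isolated-node allowance
  n_iso <- sum(net$nodes$isolated)
  expect_true(all(rc$mean <= 1 - rc$fraction + n_iso / 40 + 1e-12))
})

test_that("compare_robustness is zero against itself and orders dense over sparse", {
  set.seed(37)
  ids <- sprintf("v%02d", 1:30)
  pairs <- t(combn(ids, 2))
  dense <- pairs[runif(nrow(pairs)) < 0.35, , drop = FALSE]
  sparse <- pairs[runif(nrow(pairs)) < 0.05, , drop = FALSE]
  net_d <- manual_network(ids, dense[, 1], dense[, 2])
  net_s <- manual_network(ids, sparse[, 1], sparse[, 2])
  fr <- seq(0.1, 0.9, by = 0.1)
  cd <- robustness(net_d, fr, n_sim = 100, seed = 1)
  cs <- robustness(net_s, fr, n_sim = 100, seed = 2)
  self <- compare_robustness(cd, cd, n_boot = 50, seed = 1)
  expect_equal(self$diff, rep(0, length(fr)))
  cmp <- compare_robustness(cd, cs, n_boot = 200, seed = 1)
  expect_true(all(cmp$diff >= 0))
  # CI width shrinks with more replicates
  cs2 <- robustness(net_s, fr, n_sim = 800, seed = 3)
  cd2 <- robustness(net_d, fr, n_sim = 800, seed = 4)
  cmp2 <- compare_robustness(cd2, cs2, n_boot = 200, seed = 1)
  expect_lt(mean(cmp2$upper - cmp2$lower), mean(cmp$upper - cmp$lower))
})
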