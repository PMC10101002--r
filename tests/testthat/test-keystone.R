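test_that("participation coefficient matches closed forms", {
  # star-within-module: all links inside -> Pi = 0
  ids <- sprintf("n%02d", 1:9)
  part <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L), ids)
  ef <- c("n01", "n01")          # n01: both links inside module 0
  et <- c("n02", "n03")
  # n04 splits k = 3 evenly over the three modules -> Pi = 2/3
  ef <- c(ef, "n04", "n04", "n04")
  et <- c(et, "n05", "n03", "n07")
  net <- manual_network(ids, ef, et, partition = part)
  roles <- zi_pi(net)
  expect_equal(roles$Pi[roles$taxon == "n01"], 0)
  expect_equal(roles$Pi[roles$taxon == "n04"], 2 / 3, tolerance = 1e-12)
  expect_equal(roles$role[roles$taxon == "n04"], "connector")
  # isolated node: Pi = 0, classifiable
  expect_equal(roles$Pi[roles$taxon == "n09"], 0)
  expect_equal(roles$role[roles$taxon == "n09"], "peripheral")
})

test_that("Zi/Pi equal a definition-level recomputation on a planted bridge graph", {
  set.seed(4)
  ids <- sprintf("v%02d", 1:30)
  part <- setNames(rep(0:2, each = 10), ids)
  ef <- et <- character(0)
  # dense random blocks, leaving the bridge node v01 out of the random part
  for (blk in split(setdiff(ids, "v01"), part[setdiff(ids, "v01")])) {
    pairs <- t(combn(blk, 2))
    pick <- pairs[runif(nrow(pairs)) < 0.6, , drop = FALSE]
    ef <- c(ef, pick[, 1]); et <- c(et, pick[, 2])
  }
  # bridge node v01: 4 links inside its module, 3 into each other module
  bridge_targets <- c("v02", "v03", "v04", "v05",
                      "v12", "v13", "v14", "v22", "v23", "v24")
  ef <- c(ef, rep("v01", 10)); et <- c(et, bridge_targets)
  net <- manual_network(ids, ef, et, partition = part)
  roles <- zi_pi(net)
  orc <- oracle_zipi(ids, ef, et, part)
  expect_equal(setNames(roles$Zi, roles$taxon), orc$Zi, tolerance = 1e-12)
  expect_equal(setNames(roles$Pi, roles$taxon), orc$Pi, tolerance = 1e-12)
  expect_equal(roles$role[roles$taxon == "v01"], "connector")
  # per-module link counts sum to the degree (asserted internally, spot-check)
  g <- igraph::graph_from_data_frame(data.frame(ef, et), directed = FALSE,
                                     vertices = ids)
  expect_equal(setNames(roles$k, roles$taxon)[ids],
               igraph::degree(g)[ids])
})

test_that("Pi is invariant under module relabeling and bounded by 1 - 1/M", {
  set.seed(10)
  ids <- sprintf("n%02d", 1:12)
  part <- setNames(rep(0:3, each = 3), ids)
  pairs <- t(combn(ids, 2))
  pick <- pairs[runif(nrow(pairs)) < 0.4, , drop = FALSE]
  net <- manual_network(ids, pick[, 1], pick[, 2], partition = part)
  roles <- zi_pi(net)
  relab <- setNames((part + 7L) %% 11L, names(part))  # arbitrary relabel
  net2 <- manual_network(ids, pick[, 1], pick[, 2], partition = relab)
  roles2 <- zi_pi(net2)
  expect_equal(roles$Pi, roles2$Pi, tolerance = 1e-12)
  # bound: Pi <= 1 - 1/(modules touched)
  for (i in seq_along(ids)) {
    nb <- c(pick[pick[, 1] == ids[i], 2], pick[pick[, 2] == ids[i], 1])
    M <- length(unique(part[nb]))
    if (M > 0) expect_lte(roles$Pi[i], 1 - 1 / M + 1e-12)
  }
  # equal within-degrees give Zi = 0: a clique module
  idc <- c("c1", "c2", "c3")
  efc <- c("c1", "c1", "c2"); etc_ <- c("c2", "c3", "c3")
  netc <- manual_network(idc, efc, etc_, partition = setNames(rep(0L, 3), idc))
  expect_equal(zi_pi(netc)$Zi, rep(0, 3))
})

test_that("keystone_set unions hub and connector roles and counts add up", {
  ids <- sprintf("n%02d", 1:9)
  part <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L), ids)
  ef <- c("n01", "n01", "n04", "n04", "n04")
  et <- c("n02", "n03", "n05", "n01", "n07")
  roles <- zi_pi(manual_network(ids, ef, et, partition = part))
  ks <- keystone_set(roles)
  expect_equal(sum(ks$counts), length(ids))
  expect_setequal(ks$keystone, roles$taxon[roles$role != "peripheral"])
  expect_equal(ks$n_connectors, sum(roles$role == "connector"))
  # all-peripheral network: empty keystone set
  iso <- manual_network(ids[1:3], c("n01"), c("n02"),
                        partition = setNames(rep(0L, 3), ids[1:3]))
  expect_length(keystone_set(zi_pi(iso))$keystone, 0)
})

test_that("planted connectors in the synthetic network are recovered exactly", {
  d <- generate_dataset(seed = 3)
  merged <- merge_domains(d$bacteria, d$fungi, normalize = "domain")
  f <- filter_taxa(merge_domains(d$bacteria, d$fungi, normalize = "none"))
  fra <- abundance_table(merged$counts[rownames(f$counts), ],
                         merged$domain[rownames(f$counts)], is_relative = FALSE)
  net <- detect_modules(build_network(fra), seed = 2)
  roles <- zi_pi(net)
  found <- roles$taxon[roles$Pi >= 0.62]
  expect_setequal(found, d$truth$connectors)
})
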