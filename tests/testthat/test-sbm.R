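test_that("description length matches an independent longhand evaluation", {
  for (sd in 1:10) {
    g <- random_graph(6, 0.6, seed = 500 + sd)
    set.seed(sd)
    part <- sample(1:3, 6, replace = TRUE)
    part <- as.integer(factor(part))           # canonical non-empty labels
    st <- description_length(g, part)
    expect_equal(st$dl_total, dl_longhand(g, part), tolerance = 1e-9)
    expect_equal(st$dl_total, sum(st$dl_components), tolerance = 1e-12)
  }
})

test_that("degenerate description-length cases behave as the formula says", {
  g <- random_graph(6, 0.7, seed = 3)
  # single block: partition prior N ln 1 = 0
  st1 <- description_length(g, rep(1L, 6))
  expect_equal(unname(st1$dl_components["partition_prior"]), 0)
  # all weights identical -> a single occupied bin -> the weight channels
  # carry no information and cost nothing, under any partition
  gflat <- g
  gflat$edges$w_les <- 0.5
  gflat$edges$w_def <- 1.0
  stf <- description_length(gflat, rep(1L, 6), n_bins = 4)
  expect_equal(unname(stf$dl_components["weights_lesion"]), 0)
  expect_equal(unname(stf$dl_components["weights_deficit"]), 0)
  stf2 <- description_length(gflat, c(1L, 1L, 1L, 2L, 2L, 2L), n_bins = 4)
  expect_equal(unname(stf2$dl_components["weights_deficit"]), 0)
  expect_error(description_length(g, c(1L, 1L, 3L, 3L, 3L, 3L)),
               "partition error")
  expect_error(description_length(g, rep(1L, 4)), "cover")
})

test_that("description length is invariant to node and block relabelling", {
  g <- random_graph(8, 0.5, seed = 17)
  part <- c(1L, 1L, 2L, 2L, 3L, 3L, 3L, 1L)
  base <- description_length(g, part)$dl_total
  # permute block labels
  relab <- c(2L, 3L, 1L)[part]
  expect_equal(description_length(g, relab)$dl_total, base,
               tolerance = 1e-12)
  # permute node identities (consistently on edges and partition)
  set.seed(1)
  perm <- sample(8)
  g2 <- g
  g2$nodes <- g$nodes[perm]
  expect_equal(description_length(g2, part[perm])$dl_total, base,
               tolerance = 1e-12)
})

test_that("the exhaustive oracle enumerates Bell(n) partitions and guards size", {
  expect_length(all_set_partitions(1), 1L)
  expect_length(all_set_partitions(4), 15L)
  expect_length(all_set_partitions(8), 4140L)
  g1 <- edge_graph(c("a", "b"), cbind("a", "b", 0.5, 1, 3))
  st <- exhaustive_oracle(g1)
  expect_equal(st$B, 1L)
  big <- random_graph(9, 0.5, seed = 1)
  expect_error(exhaustive_oracle(big), "size guard")
})

test_that("two cliques with distinct deficit levels are split into two blocks", {
  # disconnected cliques {1..4} and {5..8}; deficit high inside the first,
  # low inside the second
  edges <- NULL
  for (i in 1:3) for (j in (i + 1):4)
    edges <- rbind(edges, c(i, j, 0.5, 2.0, 5))
  for (i in 5:7) for (j in (i + 1):8)
    edges <- rbind(edges, c(i, j, 0.5, -1.0, 5))
  g <- edge_graph(1:8, edges)
  or <- exhaustive_oracle(g)
  expect_equal(or$B, 2L)
  expect_length(unique(or$partition[1:4]), 1L)
  expect_length(unique(or$partition[5:8]), 1L)
  expect_false(or$partition[1] == or$partition[5])
  fit <- fit_sbm(g, b_max = 8, n_sweeps = 5, seed = 1)
  expect_equal(fit$dl_total, or$dl_total, tolerance = 1e-9)
})

test_that("unstructured graphs collapse to a single block in most runs", {
  b_one <- vapply(1:20, function(sd) {
    g <- random_graph(7, 0.5, seed = 700 + sd)   # i.i.d. weights, ER edges
    fit_sbm(g, b_max = 7, n_sweeps = 3, seed = sd)$B
  }, integer(1))
  expect_gt(mean(b_one == 1L), 0.5)
})

test_that("fitting is deterministic and every accepted move decreases the objective", {
  g <- random_graph(12, 0.4, seed = 31)
  a <- fit_sbm(g, b_max = 12, n_sweeps = 3, seed = 7)
  b <- fit_sbm(g, b_max = 12, n_sweeps = 3, seed = 7)
  expect_identical(a$partition, b$partition)
  expect_identical(a$dl_total, b$dl_total)
  # accepted-move trajectories are strictly decreasing within each level
  for (tr in a$trace) if (length(tr) > 1)
    expect_true(all(diff(tr) < 0))
  # the returned state is the best visited one
  expect_true(all(vapply(a$trace, function(tr)
    all(tr >= a$dl_total - 1e-9), logical(1))))
})

test_that("heuristic fit attains the exhaustive optimum on 50 random graphs", {
  matches <- 0L
  for (k in 1:50) {
    N <- sample(4:8, 1)
    g <- random_graph(N, 0.5, seed = 1000 + k)
    fit <- fit_sbm(g, b_max = N, n_sweeps = 5, seed = k)
    or <- exhaustive_oracle(g)
    expect_gte(fit$dl_total, or$dl_total - 1e-9)  # oracle is a lower bound
    if (abs(fit$dl_total - or$dl_total) < 1e-9) matches <- matches + 1L
  }
  expect_equal(matches, 50L)
})

test_that("model comparison reports delta in nats and formats the odds label", {
  cmp <- compare_models(476362, 725748)
  expect_equal(cmp$delta, 249386)
  expect_equal(cmp$log_odds, 249386)
  expect_equal(cmp$odds_label, "e249386")
  expect_equal(compare_models(451868, 699072)$delta, 247204)
  same <- compare_models(100, 100)
  expect_equal(same$delta, 0)
  expect_equal(same$odds_label, "e0")
  # block_state inputs are unwrapped; mismatched node sets are rejected
  g <- random_graph(6, 0.6, seed = 2)
  s1 <- description_length(g, rep(1L, 6))
  s2 <- description_length(g, c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_equal(compare_models(s1, s2)$delta, s2$dl_total - s1$dl_total)
  g2 <- random_graph(5, 0.6, seed = 3)
  s3 <- description_length(g2, rep(1L, 5))
  expect_error(compare_models(s1, s3), "comparability")
})

test_that("the merge record renders as a Newick tree", {
  g <- random_graph(6, 0.8, seed = 5)
  fit <- fit_sbm(g, b_max = 4, n_sweeps = 2, seed = 1)
  nwk <- merge_newick(fit)
  expect_match(nwk, "^\\(.*\\);$|^B1;$")
  expect_equal(nrow(fit$merges), fit$merges$B_before[1] - 1L)
})
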