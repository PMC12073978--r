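test_that("node strengths backproject edge weights as documented", {
  # node p has edges with supports (2, 4) and w_def (1.0, 0.25):
  # support-weighted mean = (2*1 + 4*0.25)/6 = 0.5
  g <- edge_graph(c("p", "q", "r"),
                  rbind(c("p", "q", 0.2, 1.0, 2),
                        c("p", "r", 0.4, 0.25, 4)))
  st <- node_strengths(g)
  expect_equal(st$deficit_strength[st$node == "p"], 0.5)
  expect_equal(st$lesion_strength[st$node == "p"], 0.3)
  # a single-edge node inherits that edge's weights
  expect_equal(st$deficit_strength[st$node == "q"], 1.0)
  expect_equal(st$lesion_strength[st$node == "q"], 0.2)
  # constant w_def propagates to every strength
  gconst <- random_graph(8, 0.5, seed = 2)
  gconst$edges$w_def <- 0.7
  stc <- node_strengths(gconst)
  expect_true(all(abs(stc$deficit_strength[!stc$isolated] - 0.7) < 1e-12))
  # isolated nodes are flagged with undefined strengths
  giso <- edge_graph(c("a", "b", "c"), rbind(c("a", "b", 0.5, 1, 3)))
  sti <- node_strengths(giso)
  expect_true(sti$isolated[sti$node == "c"])
  expect_true(is.na(sti$deficit_strength[sti$node == "c"]))
})

test_that("matrix and edge-list strength computations agree", {
  set.seed(15)
  dbin <- matrix(rbinom(60 * 10, 1, 0.3), 60, 10)
  colnames(dbin) <- paste0("p", 1:10)
  z <- rnorm(60)
  g <- build_graph(dbin, z, m_min = 2)
  st_edge <- node_strengths(g)
  st_mat <- gldmap:::.node_strengths_mat(dbin, z, m_min = 2)
  expect_equal(st_edge$deficit_strength, unname(st_mat[, "deficit_strength"]))
  expect_equal(st_edge$lesion_strength, unname(st_mat[, "lesion_strength"]))
})

test_that("constant z yields degenerate deficit intervals", {
  set.seed(16)
  dbin <- matrix(rbinom(50 * 6, 1, 0.5), 50, 6)
  colnames(dbin) <- paste0("p", 1:6)
  cis <- bootstrap_cis(dbin, rep(1.25, 50), n_boot = 150, seed = 1)
  ok <- cis$n_replicates > 0
  expect_true(all(abs(cis$def_ci_low[ok] - 1.25) < 1e-12))
  expect_true(all(abs(cis$def_ci_high[ok] - 1.25) < 1e-12))
  expect_true(all(cis$les_ci_low <= cis$les_ci_high, na.rm = TRUE))
  expect_error(bootstrap_cis(dbin, rep(1, 50), n_boot = 50), "n_boot")
})

test_that("bootstrap intervals stabilize as replicates grow", {
  sch <- default_scheme()
  tr <- ground_truth(sch, effect_beta = 30, noise_sd = 5)
  sim <- simulate_cohort(sch, tr, 200, 60, seed = 19)
  dm <- damage_matrix(sim$masks, sch)
  z <- deficit_scores(sim$cohort)
  dbin <- binarize_damage(dm)
  ci1 <- bootstrap_cis(dbin, z, n_boot = 1000, seed = 5)
  ci2 <- bootstrap_cis(dbin, z, n_boot = 2000, seed = 5)
  w1 <- ci1$def_ci_high - ci1$def_ci_low
  w2 <- ci2$def_ci_high - ci2$def_ci_low
  ok <- ci1$n_replicates > 800 & w1 > 0.05
  expect_gt(sum(ok), 5)
  expect_lt(median(abs(w2[ok] - w1[ok]) / w1[ok]), 0.10)
})

test_that("retention requires the deficit interval to sit above the lesion interval", {
  st <- data.frame(node = c("a", "b", "c", "d"),
                   deficit_strength = c(1, 0.5, -0.5, NA),
                   lesion_strength = c(0.2, 0.2, 0.2, NA),
                   degree = c(2L, 2L, 2L, 0L),
                   isolated = c(FALSE, FALSE, FALSE, TRUE))
  cis <- data.frame(node = c("a", "b", "c", "d"),
                    def_ci_low = c(0.8, 0.25, -0.7, NA),
                    def_ci_high = c(1.2, 0.8, -0.3, NA),
                    les_ci_low = c(0.1, 0.1, 0.1, NA),
                    les_ci_high = c(0.3, 0.3, 0.3, NA),
                    n_replicates = c(100L, 100L, 100L, 0L))
  map <- retention_rule(st, cis)
  expect_true(map$retained[map$node == "a"])     # disjoint, deficit above
  expect_false(map$retained[map$node == "b"])    # overlapping intervals
  expect_false(map$retained[map$node == "c"])    # disjoint but below
  expect_false(map$retained[map$node == "d"])    # missing CI
  expect_equal(map$retain_reason[map$node == "d"], "missing CI")
})

test_that("substrate recovery computes Jaccard, sensitivity and specificity", {
  sch <- small_scheme()
  truth <- ground_truth(sch, substrate_parcels = c(2L, 3L, 4L))
  mk_map <- function(retained) {
    m <- data.frame(node = as.character(1:8),
                    retained = as.character(1:8) %in% retained)
    class(m) <- c("network_map", "data.frame")
    m
  }
  exact <- substrate_recovery(mk_map(c("2", "3", "4")), truth)
  expect_equal(exact$jaccard, 1)
  expect_equal(exact$sensitivity, 1)
  expect_equal(exact$specificity, 1)
  disjoint <- substrate_recovery(mk_map(c("5", "6")), truth)
  expect_equal(disjoint$jaccard, 0)
  # retained {1,2,3}, substrate {2,3,4}: |intersect| 2, |union| 4
  half <- substrate_recovery(mk_map(c("1", "2", "3")), truth)
  expect_equal(half$jaccard, 0.5)
  expect_equal(half$sensitivity, 2 / 3)
  expect_equal(half$specificity, 4 / 5)
})

test_that("parcel maps export as parcel-constant volumes and round-trip", {
  sch <- small_scheme()
  map <- data.frame(node = as.character(1:8),
                    deficit_strength = seq(0.1, 0.8, by = 0.1),
                    lesion_strength = 0.2,
                    retained = c(FALSE, TRUE, FALSE, FALSE, TRUE,
                                 FALSE, FALSE, FALSE))
  class(map) <- c("network_map", "data.frame")
  path <- tempfile(fileext = ".nii.gz")
  export_parcel_map(map, sch, path)
  img <- RNifti::readNifti(path)
  vol <- array(as.numeric(img), dim = dim(img))
  expect_equal(unique(vol[sch$labels == 2L]), 0.2)
  expect_equal(unique(vol[sch$labels == 5L]), 0.5)
  expect_true(all(vol[!(sch$labels %in% c(2L, 5L))] == 0))
  side <- utils::read.delim(gldmap:::.sidecar_path(path))
  expect_equal(nrow(side), 8L)
  unlink(c(path, gldmap:::.sidecar_path(path)))
  # with nothing retained the exported volume is identically zero
  map$retained <- FALSE
  path2 <- tempfile(fileext = ".nii.gz")
  export_parcel_map(map, sch, path2)
  expect_true(all(as.numeric(RNifti::readNifti(path2)) == 0))
  unlink(c(path2, gldmap:::.sidecar_path(path2)))
})

test_that("gldm assembles the full analysis and its methods run", {
  sch <- default_scheme()
  tr <- ground_truth(sch, effect_beta = 30, noise_sd = 5)
  sim <- simulate_cohort(sch, tr, 150, 50, seed = 23)
  dm <- damage_matrix(sim$masks, sch)
  fit <- gldm(dm, sim$cohort, n_boot = 150, b_max = 8, seed = 23)
  expect_s3_class(fit, "gldm")
  expect_s3_class(fit$comparison, "model_comparison")
  expect_equal(fit$comparison$delta,
               fit$null_fit$dl_total - fit$fit$dl_total)
  expect_equal(length(coef(fit)), 64L)
  expect_output(print(fit), "Layered lesion-deficit graph")
  expect_output(print(summary(fit)), "model comparison")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  # reruns with the same seed are identical
  fit2 <- gldm(dm, sim$cohort, n_boot = 150, b_max = 8, seed = 23)
  expect_identical(fit$comparison$delta, fit2$comparison$delta)
  expect_identical(fit$map$retained, fit2$map$retained)
})
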