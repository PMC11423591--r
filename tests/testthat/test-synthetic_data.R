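test_that("simulated trees are rooted, binary, reproducible, with the stated depth law", {
  expect_equal(length(simulate_tree(2, seed = 1)$tip.label), 2)
  expect_error(simulate_tree(1), "n_taxa")

  t1 <- simulate_tree(100, seed = 1)
  t2 <- simulate_tree(100, seed = 1)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(ape::is.rooted(t1) && ape::is.binary(t1))
  expect_true(all(t1$edge.length >= 0))

  # conditional on the topology, branch lengths are iid Exp(1): the mean
  # root-to-tip depth is sum_e b_e * k_e / T with k_e tips below edge e,
  # so E = sum(k_e)/T and Var = sum((k_e/T)^2)
  tr <- simulate_tree(200, seed = 7)
  ntip <- length(tr$tip.label)
  # count tips below each edge via the clade membership of its child node
  below <- vapply(seq_len(nrow(tr$edge)), function(e) {
    node <- tr$edge[e, 2]
    if (node <= ntip) 1L else length(ape::extract.clade(tr, node)$tip.label)
  }, integer(1))
  depth <- ape::node.depth.edgelength(tr)[seq_len(ntip)]
  expectation <- sum(below) / ntip
  se <- sqrt(sum((below / ntip)^2))
  expect_lt(abs(mean(depth) - expectation), 3 * se)
})

test_that("the neutral generator matches its stated limits and is reproducible", {
  # m = 1: per-sample expected proportions equal the pool, and the mean
  # absolute deviation of observed means from the pool shrinks with n
  pool <- planktonet:::pn_source_pool(50, shape = 0.5)
  mad_n <- vapply(c(10, 80), function(n) {
    ds <- simulate_neutral_dataset(n, 50, N = 2000, m = 1, seed = 5,
                                   pool = pool)
    rel <- relative_abundance(ds$table)
    mean(abs(colMeans(rel) - pool))
  }, numeric(1))
  expect_lt(mad_n[2], mad_n[1])
  expect_lt(mad_n[2], 0.002)

  ds1 <- simulate_neutral_dataset(6, 40, N = 500, m = 0.2, seed = 9)
  ds2 <- simulate_neutral_dataset(6, 40, N = 500, m = 0.2, seed = 9)
  expect_identical(ds1$table, ds2$table)
  expect_true(all(rowSums(ds1$table) == 500))
  expect_error(simulate_neutral_dataset(5, 40, N = 500, m = 0), "migration")
})

test_that("zero selection degenerates exactly to the neutral generator", {
  a <- simulate_neutral_dataset(8, 60, N = 800, m = 0.15, seed = 21)
  b <- simulate_selection_dataset(8, 60, N = 800, selection_strength = 0,
                                  m = 0.15, seed = 21)
  expect_identical(a$table, b$table)
  expect_error(simulate_selection_dataset(4, 20, selection_strength = -1),
               "selection_strength")
})

test_that("niche optima carry phylogenetic signal unless decoupled", {
  ds <- simulate_selection_dataset(6, 120, N = 500, selection_strength = 4,
                                   seed = 31)
  D <- ape::cophenetic.phylo(ds$tree)
  o <- ds$truth$optima[rownames(D)]
  dif <- abs(outer(o, o, "-"))
  r_cons <- cor(D[upper.tri(D)], dif[upper.tri(dif)])
  expect_gt(r_cons, 0.1)  # close relatives have closer optima

  ds0 <- simulate_selection_dataset(6, 120, N = 500, selection_strength = 4,
                                    phylo_signal = FALSE, seed = 31)
  o0 <- ds0$truth$optima[rownames(D)]
  dif0 <- abs(outer(o0, o0, "-"))
  r_rand <- cor(D[upper.tri(D)], dif0[upper.tri(dif0)])
  expect_lt(abs(r_rand), r_cons)
})

test_that("mixed-mode weights are recorded and bounded", {
  w <- c(rep(0, 3), rep(0.5, 3), rep(1, 3))
  ds <- simulate_selection_dataset(9, 40, N = 500, selection_strength = 3,
                                   mix_weights = w, seed = 3)
  expect_equal(ds$truth$assembly_mode, "mixed")
  expect_equal(ds$truth$mix_weights, w)
  expect_error(simulate_selection_dataset(4, 20, mix_weights = 2, seed = 1),
               "mix_weights")
})

test_that("the occurrence-frequency law of the neutral generator matches the fitted model", {
  # generator draws samples; the fitter integrates the Beta law -- an
  # independent cross-check of both implementations
  ds <- simulate_neutral_dataset(100, 200, N = 1000, m = 0.1, seed = 11)
  fit <- fit_ncm(ds$table)
  expect_gt(fit$R2, 0.9)
})

test_that("the cross-kingdom fixture has the survey's structure", {
  fx <- simulate_cross_kingdom_fixture(seed = 1)
  expect_equal(nrow(fx$eukaryote$table), 38)
  expect_equal(nrow(fx$prokaryote$table), 38)
  expect_identical(fx$eukaryote$metadata, fx$prokaryote$metadata)
  for (k in c("eukaryote", "prokaryote")) {
    tab <- fx[[k]]$table
    expect_true(all(colSums(tab) > 0))
    expect_setequal(colnames(tab), fx[[k]]$tree$tip.label)
    cls <- classify_abundance_groups(tab)
    expect_gt(sum(cls$class == "abundant"), 0)
    expect_gt(mean(cls$class == "rare"), 0.5)
  }
})
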