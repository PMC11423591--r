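test_that("the neutral-model fit recovers structure and flags boundaries", {
  ds <- simulate_neutral_dataset(50, 150, N = 1000, m = 0.1, seed = 2)
  fit <- fit_ncm(ds$table)
  expect_s3_class(fit, "ncm_fit")
  expect_true(fit$m > 0 && fit$m <= 1)
  expect_equal(fit$Nm, fit$N * fit$m)
  expect_gt(fit$R2, 0.85)
  expect_true(all(fit$freq$pred_freq >= 0 & fit$freq$pred_freq <= 1))
  expect_true(all(fit$freq$lower <= fit$freq$pred_freq + 1e-12 &
                    fit$freq$upper >= fit$freq$pred_freq - 1e-12))
  expect_output(print(fit), "Nm")
  # the classic sharp-threshold variant runs and reports its limit
  fit2 <- fit_ncm(ds$table, detection = "threshold")
  expect_equal(fit2$detection_limit, 1 / fit2$N)
})

test_that("MNTD on forced topologies and degenerate nulls behave as defined", {
  # two-taxon sample on a cherry: MNTD is the tip-tip distance
  tr <- ape::read.tree(text = "((a:1,b:2):1,c:5):0;")
  tab <- rbind(s1 = c(a = 1, b = 1, c = 0))
  out <- suppressWarnings(ses_mntd(tab, tr, n_null = 99, seed = 1))
  expect_equal(out$mntd_obs[1], 3)
  # a sample holding every tip is invariant under label shuffles
  tab2 <- rbind(s1 = c(a = 1, b = 1, c = 1))
  out2 <- ses_mntd(tab2, tr, n_null = 99, seed = 1)
  expect_true(is.na(out2$ses[1]))
  expect_lt(out2$null_sd[1], 1e-12)
})

test_that("beta-MNTD agrees with brute force and an independent library", {
  skip_if_not_installed("picante")
  ds <- simulate_neutral_dataset(3, 6, N = 300, m = 0.3, seed = 5)
  D <- ape::cophenetic.phylo(ds$tree)[colnames(ds$table), colnames(ds$table)]
  ours <- as.matrix(beta_mntd(ds$table, ds$tree, weighted = TRUE))
  expect_equal(ours, bmntd_brute(ds$table, D, weighted = TRUE),
               tolerance = 1e-9)
  pic <- as.matrix(picante::comdistnt(ds$table, D, abundance.weighted = TRUE))
  expect_equal(ours, pic[rownames(ours), colnames(ours)], tolerance = 1e-9,
               ignore_attr = TRUE)
  # identical communities have zero turnover
  same <- rbind(s1 = c(a = 2, b = 1, c = 0), s2 = c(a = 2, b = 1, c = 0))
  tr <- ape::read.tree(text = "((a:1,b:2):1,c:5):0;")
  expect_equal(as.matrix(beta_mntd(same, tr))["s1", "s2"], 0)
  # two single-taxon communities: beta-MNTD is the tip-tip distance
  single <- rbind(s1 = c(a = 3, b = 0, c = 0), s2 = c(a = 0, b = 0, c = 4))
  expect_equal(as.matrix(beta_mntd(single, tr))["s1", "s2"], 7)
})

test_that("beta-NTI is symmetric and detects simulated variable selection", {
  ds <- simulate_selection_dataset(8, 200, N = 2000, selection_strength = 6,
                                   niche_width_mean = 0.5, seed = 13)
  bn <- beta_nti(ds$table, ds$tree, n_null = 99, seed = 1)
  expect_equal(bn$bnti, t(bn$bnti))
  expect_true(all(is.na(diag(bn$bnti))))
  # extreme-gradient pair shows strong phylogenetic turnover
  expect_gt(bn$bnti[1, 8], 2)
})

test_that("Raup-Crick hits its boundary case and stays in range", {
  set.seed(99)
  tab <- rbind(s1 = c(a = 50, b = 31, c = 22, d = 13, e = 9, f = 40, g = 17, h = 5),
               s2 = c(a = 50, b = 31, c = 22, d = 13, e = 9, f = 40, g = 17, h = 5),
               s3 = c(a = 10, b = 0, c = 90, d = 20, e = 1, f = 2, g = 44, h = 30))
  rc <- raup_crick_bray(tab, n_null = 99, seed = 3)
  expect_equal(rc["s1", "s2"], -1)  # identical pair: below every null draw
  expect_true(all(rc[!is.na(rc)] >= -1 & rc[!is.na(rc)] <= 1))
  expect_equal(rc, t(rc))
})

test_that("assembly classification applies the two-stage thresholds exactly", {
  b <- matrix(NA_real_, 6, 6)
  r <- matrix(NA_real_, 6, 6)
  set <- function(m, i, j, v) { m[i, j] <- v; m[j, i] <- v; m }
  b <- set(b, 1, 2, -2.5)               # homogeneous selection
  b <- set(b, 1, 3, 2.5)                # variable selection
  b <- set(b, 1, 4, 1.0); r <- set(r, 1, 4, 0.97)   # dispersal limitation
  b <- set(b, 2, 3, -2.0); r <- set(r, 2, 3, -0.97) # boundary: stochastic
  b <- set(b, 2, 4, 0.0); r <- set(r, 2, 4, 0.95)   # boundary: drift
  b <- set(b, 3, 4, 2.0); r <- set(r, 3, 4, 0.0)    # boundary: drift
  b <- set(b, 5, 6, 0.5); r <- set(r, 5, 6, -0.99)  # homogenizing dispersal
  out <- classify_assembly(b, r)
  lab <- stats::setNames(as.character(out$pairs$process),
                         paste(out$pairs$sample_1, out$pairs$sample_2))
  expect_equal(lab[["1 2"]], "homogeneous selection")
  expect_equal(lab[["1 3"]], "variable selection")
  expect_equal(lab[["1 4"]], "dispersal limitation")
  expect_equal(lab[["2 3"]], "homogenizing dispersal")
  expect_equal(lab[["2 4"]], "drift")
  expect_equal(lab[["3 4"]], "drift")
  expect_equal(lab[["5 6"]], "homogenizing dispersal")
  expect_equal(sum(out$fractions), 1)
  # a stochastic pair without an RC value is an error
  b2 <- set(matrix(NA_real_, 3, 3), 1, 2, 0.5)
  expect_error(classify_assembly(b2), "Raup-Crick")
})

test_that("process fractions recover the generating regime", {
  neutral_frac <- selection_frac <- numeric(0)
  for (s in 1:8) {
    dn <- simulate_neutral_dataset(10, 120, N = 1000, m = 0.1, seed = 400 + s)
    bn <- beta_nti(dn$table, dn$tree, n_null = 99, seed = s)
    rc <- raup_crick_bray(dn$table, n_null = 99, seed = s + 50)
    f <- classify_assembly(bn, rc)$fractions
    neutral_frac <- c(neutral_frac,
                      1 - f[["homogeneous selection"]] - f[["variable selection"]])
    md <- planktonet:::pn_make_metadata(12, seed = 500 + s)
    md$latitude <- rep(c(32, 39.5), each = 6) + seq(0, 0.25, length.out = 12)
    dsl <- simulate_selection_dataset(12, 400, N = 8000,
                                      selection_strength = 8,
                                      niche_width_mean = 0.5,
                                      seed = 600 + s, metadata = md)
    bns <- beta_nti(dsl$table, dsl$tree, n_null = 99, seed = s)
    rcs <- raup_crick_bray(dsl$table, n_null = 99, seed = s + 70)
    fs <- classify_assembly(bns, rcs)$fractions
    selection_frac <- c(selection_frac,
                        fs[["homogeneous selection"]] + fs[["variable selection"]])
  }
  expect_gt(mean(neutral_frac), 0.7)
  expect_gt(mean(selection_frac), 0.5)
})
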