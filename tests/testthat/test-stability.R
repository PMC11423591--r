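test_that("random-removal robustness matches forced outcomes", {
  # triangle, one node removed: the remaining pair keeps its edge
  tri <- robustness_random(make_triangle(), remove_fraction = 1 / 3,
                           reps = 20, seed = 1)
  expect_equal(tri$mean, 2 / 3)
  expect_equal(tri$sd, 0)
  # complete graph: no secondary extinctions are possible
  k10 <- robustness_random(make_complete(10), remove_fraction = 0.5,
                           reps = 50, seed = 2)
  expect_equal(k10$mean, 0.5)
  expect_equal(k10$sd, 0)
  expect_error(robustness_random(make_triangle(), remove_fraction = 1.2),
               "remove_fraction")
})

test_that("hub removal cascades through secondary extinctions", {
  st <- make_star(3)
  metrics <- data.frame(feature_id = igraph::V(st)$name,
                        role = c("module hub", rep("peripheral", 3)))
  out <- robustness_targeted(st, metrics, reps = 10, seed = 3)
  expect_equal(out$mean, 0)   # hub removed -> every leaf isolated
  expect_equal(out$n_removed, 1)

  no_hubs <- data.frame(feature_id = igraph::V(st)$name,
                        role = rep("peripheral", 4))
  expect_warning(v <- robustness_targeted(st, no_hubs, reps = 5, seed = 1),
                 "no module hubs")
  expect_equal(v$mean, 1)
})

test_that("targeted hub removal is more damaging than random removal", {
  # three stars whose centres form a triangle: centres are cut vertices
  el <- rbind(cbind(paste0("c", rep(1:3, each = 4)),
                    paste0("l", 1:12)),
              cbind(c("c1", "c2", "c3"), c("c2", "c3", "c1")))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  metrics <- data.frame(feature_id = igraph::V(g)$name,
                        role = ifelse(grepl("^c", igraph::V(g)$name),
                                      "module hub", "peripheral"))
  targeted <- robustness_targeted(g, metrics, reps = 40, seed = 5)
  random <- robustness_random(g, remove_fraction = targeted$n_removed /
                                igraph::vcount(g), reps = 40, seed = 5)
  expect_lt(targeted$mean, random$mean)
})

test_that("robustness decreases with removal fraction and respects the seed", {
  g <- make_complete(10)
  r <- vapply(c(0.2, 0.5, 0.8), function(f) {
    robustness_random(g, f, reps = 30, seed = 7)$mean
  }, numeric(1))
  expect_true(all(diff(r) < 0))
  a <- robustness_random(make_star(6), 0.5, reps = 30, seed = 11)
  b <- robustness_random(make_star(6), 0.5, reps = 30, seed = 11)
  expect_identical(a$values, b$values)
})

test_that("vulnerability matches the 3-path and complete-graph closed forms", {
  p3 <- vulnerability(make_path3())
  expect_equal(unname(p3$per_node["b"]), 1)
  expect_equal(p3$max, 1)
  expect_equal(p3$which, "b")
  # removing an endpoint of the path raises efficiency: negative V
  expect_lt(p3$per_node[["a"]], 0)
  expect_equal(p3$per_node[["a"]], (5 / 6 - 1) / (5 / 6))
  for (n in 3:5) {
    expect_true(all(abs(vulnerability(make_complete(n))$per_node) < 1e-12))
  }
  expect_error(vulnerability(make_path3() - "b"), "nodes")
})

test_that("betweenness-targeted fragmentation follows the component formula", {
  fr <- fragmentation_series(make_path3(), n_steps = 1)
  expect_equal(fr$fragmentation[fr$step == 0], 0)  # connected at step 0
  expect_equal(fr$removed[fr$step == 1], "b")
  expect_equal(fr$fragmentation[fr$step == 1], 1)  # {a}, {c}

  # on a path, each adaptive removal hits a cut vertex: F never decreases
  pg <- igraph::make_ring(8, circular = FALSE)
  pg <- igraph::set_vertex_attr(pg, "name", value = paste0("p", 1:8))
  fr8 <- fragmentation_series(pg, n_steps = 5)
  expect_true(all(diff(fr8$fragmentation) >= 0))
  expect_true(all(fr8$lcc_fraction >= 0 & fr8$lcc_fraction <= 1))
  expect_error(fragmentation_series(make_path3(), n_steps = 3), "n_steps")
})

test_that("a denser network is at least as robust and no more vulnerable than its sparsification", {
  ds <- simulate_selection_dataset(24, 300, N = 4000, selection_strength = 1,
                                   n_guilds = 8, guild_noise = 1.2,
                                   drift_noise = 0.6, seed = 23)
  tab <- ds$table[, colSums(ds$table) > 0, drop = FALSE]
  dense <- build_network(filter_features(tab), r_min = 0.6)
  # sparser variant of the same construction: stricter correlation cutoff
  sparse <- build_network(filter_features(tab), r_min = 0.8)
  expect_gt(igraph::ecount(dense), igraph::ecount(sparse))
  rd <- robustness_random(dense, 0.5, reps = 50, seed = 9)
  rs <- robustness_random(sparse, 0.5, reps = 50, seed = 9)
  expect_gte(rd$mean, rs$mean)
  expect_lte(vulnerability(dense)$max, vulnerability(sparse)$max)
})
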