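test_that("a consistent table/tree/metadata triple loads unchanged", {
  dir <- withr::local_tempdir()
  paths <- write_toy_files(dir)
  ds <- load_dataset(paths$table, paths$tree, paths$metadata)
  expect_equal(ds$table, toy_table())
  expect_setequal(ds$tree$tip.label, colnames(ds$table))
  expect_equal(ds$metadata$sample_id, rownames(ds$table))
})

test_that("extra tree tips are pruned; missing tips and duplicates are errors", {
  dir <- withr::local_tempdir()
  # tree with 5 tips, table with 4 features -> pruned to 4
  paths <- write_toy_files(dir, tree = toy_tree(paste0("ASV_", 1:5)))
  ds <- load_dataset(paths$table, paths$tree, paths$metadata)
  expect_setequal(ds$tree$tip.label, paste0("ASV_", 1:4))

  # a table feature absent from the tree names the offender
  tab <- toy_table()
  colnames(tab)[4] <- "ASV_9"
  write_abundance_table(tab, paths$table)
  expect_error(load_dataset(paths$table, paths$tree, paths$metadata),
               "ASV_9")

  # duplicate feature ids are a hard error
  writeLines(c("sample_id\tASV_1\tASV_1\tASV_2",
               "s1\t1\t2\t3", "s2\t4\t5\t6"),
             file.path(dir, "dup.tsv"))
  expect_error(read_abundance_table(file.path(dir, "dup.tsv")), "duplicate")
})

test_that("both table orientations load to the same canonical matrix", {
  dir <- withr::local_tempdir()
  tab <- toy_table()
  write_abundance_table(tab, file.path(dir, "by_sample.tsv"),
                        samples_as_rows = TRUE)
  write_abundance_table(tab, file.path(dir, "by_feature.tsv"),
                        samples_as_rows = FALSE)
  a <- read_abundance_table(file.path(dir, "by_sample.tsv"))
  b <- read_abundance_table(file.path(dir, "by_feature.tsv"),
                            samples_as_rows = FALSE)
  expect_identical(a, b)
})

test_that("row order on disk never permutes values silently", {
  dir <- withr::local_tempdir()
  tab <- toy_table()
  shuffled <- tab[c(3, 1, 2), ]
  md <- toy_metadata()[c(2, 3, 1), ]
  paths <- write_toy_files(dir, table = shuffled, metadata = md)
  ds <- load_dataset(paths$table, paths$tree, paths$metadata)
  # spot values follow their ids, and metadata is realigned to the table
  expect_equal(ds$table["s1", "ASV_1"], 5)
  expect_equal(ds$table["s2", "ASV_3"], 4)
  expect_equal(ds$metadata$sample_id, rownames(ds$table))
  expect_equal(ds$metadata$latitude[ds$metadata$sample_id == "s3"], 39.5)
})

test_that("load -> write -> load is idempotent", {
  dir <- withr::local_tempdir()
  paths <- write_toy_files(dir)
  ds1 <- load_dataset(paths$table, paths$tree, paths$metadata)
  write_abundance_table(ds1$table, file.path(dir, "t2.tsv"))
  ape::write.tree(ds1$tree, file.path(dir, "tr2.nwk"))
  write_sample_metadata(ds1$metadata, file.path(dir, "md2.tsv"))
  ds2 <- load_dataset(file.path(dir, "t2.tsv"), file.path(dir, "tr2.nwk"),
                      file.path(dir, "md2.tsv"))
  expect_identical(ds1$table, ds2$table)
  expect_equal(ds1$metadata, ds2$metadata)
  expect_equal(ape::cophenetic.phylo(ds1$tree), ape::cophenetic.phylo(ds2$tree))
})

test_that("networks round-trip through graphml and TSV edge lists", {
  g <- make_triangle()
  g <- igraph::set_edge_attr(g, "r", value = c(0.9, -0.7, 0.8))
  g <- igraph::set_edge_attr(g, "sign",
                             value = c("positive", "negative", "positive"))
  g <- igraph::set_edge_attr(g, "q", value = c(0.01, 0.002, 0.04))
  g <- igraph::set_vertex_attr(g, "module", value = c(1L, 1L, 2L))
  for (fmt in c("graphml", "edge_list_tsv")) {
    path <- file.path(withr::local_tempdir(), "net.out")
    write_network(g, path, format = fmt)
    g2 <- read_network(path, format = fmt)
    expect_setequal(igraph::V(g2)$name, igraph::V(g)$name)
    expect_equal(igraph::ecount(g2), 3)
    m1 <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    m2 <- igraph::as_adjacency_matrix(g2, sparse = FALSE)
    expect_equal(m2[rownames(m1), colnames(m1)], m1)
    e1 <- igraph::as_data_frame(g)
    e2 <- igraph::as_data_frame(g2)
    key <- function(d) d[order(d$from, d$to), c("r", "sign", "q")]
    expect_equal(key(e2), key(e1), ignore_attr = TRUE)
    mod2 <- igraph::V(g2)$module[match(igraph::V(g)$name, igraph::V(g2)$name)]
    expect_equal(as.integer(mod2), c(1L, 1L, 2L))
  }
  expect_error(write_network(g, tempfile(), format = "dot"))
})
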