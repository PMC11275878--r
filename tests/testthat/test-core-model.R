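test_that("SWC chains parse with identity and anisotropic scaling", {
  f <- write_swc_text(c("# comment",
                        "1 1 10 20 30 5 -1",
                        "2 3 11 21 31 1 1",
                        "3 3 12 22 32 1 2"))
  sk <- read_swc(f, voxel_scaling(), cell_id = "c1", cell_class = "TC")
  expect_s3_class(sk, "neuron_skeleton")
  expect_equal(nrow(sk$nodes), 3L)
  expect_equal(sk$nodes$node_id[sk$nodes$parent_id == -1L], 1L)
  expect_equal(sk$nodes$x, c(10, 11, 12))
  expect_equal(sk$soma_node_ids, 1L)

  sk2 <- read_swc(f, voxel_scaling(c(26, 20, 40)), cell_id = "c1",
                  cell_class = "TC")
  expect_equal(sk2$nodes$x, c(10, 11, 12) * 26)
  expect_equal(sk2$nodes$y, c(20, 21, 22) * 20)
  expect_equal(sk2$nodes$z, c(30, 31, 32) * 40)
})

test_that("SWC structural and parse errors are specific", {
  f <- write_swc_text(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 99"))
  expect_error(read_swc(f, cell_class = "other"), "node 2.*parent 99")

  f2 <- write_swc_text(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 3", "3 3 2 0 0 1 2"))
  expect_error(read_swc(f2), "cyclic")

  f3 <- write_swc_text(c("1 1 0 0 0 5 -1", "2 3 x 0 0 1 1"))
  expect_error(read_swc(f3), "line 2.*non-numeric")

  f4 <- write_swc_text(c("1 1 0 0 0 5 -1", "2 3 0 0 1 1"))
  expect_error(read_swc(f4), "7 SWC columns")

  # two roots
  f5 <- write_swc_text(c("1 1 0 0 0 5 -1", "2 3 1 0 0 1 -1"))
  expect_error(read_swc(f5), "exactly one root")
})

test_that("scaling then unscaling is the identity on coordinates", {
  set.seed(4)
  xyz <- matrix(runif(300, -1e5, 1e5), ncol = 3)
  sc <- voxel_scaling(c(26, 20, 40))
  inv <- voxel_scaling(1 / c(26, 20, 40))
  back <- circuitseg:::apply_scaling(circuitseg:::apply_scaling(xyz, sc), inv)
  expect_lt(max(abs(back - xyz) / pmax(abs(xyz), 1)), 1e-9)
  expect_error(voxel_scaling(c(26, 0, 40)), "positive")
})

test_that("synapse tables validate enums and reject malformed records", {
  df <- data.frame(synapse_id = c("s1", "s2"), pre_cell = c("r1", "r2"),
                   post_cell = c("t1", "t1"), x_nm = c(0, 1), y_nm = c(0, 1),
                   z_nm = c(0, 1), pre_class = "RGC", post_class = "TC")
  st <- synapse_table(df)
  expect_equal(nrow(st), 2L)
  expect_true(all(st$pre_class == "RGC"))

  bad <- df; bad$pre_class <- "axon7"
  expect_error(synapse_table(bad), "axon7.*RGC, LIN, cortical, other")

  self <- df; self$post_cell <- self$pre_cell
  expect_error(synapse_table(self), "pre_cell equals post_cell")

  f <- tempfile(fileext = ".csv")
  write.csv(df[0, ], f, row.names = FALSE)
  expect_equal(nrow(read_synapse_table(f)), 0L)

  # scaling applied on load
  write.csv(df, f, row.names = FALSE)
  st2 <- read_synapse_table(f, voxel_scaling(c(26, 20, 40)))
  expect_equal(st2$x_nm, c(0, 26))
  expect_equal(st2$z_nm, c(0, 40))
})

test_that("record validation matches the stated invariants (property)", {
  set.seed(11)
  for (i in 1:40) {
    df <- data.frame(synapse_id = sprintf("s%d", i), pre_cell = "a",
                     post_cell = "b",
                     x_nm = runif(1, -1e6, 1e6), y_nm = runif(1, -1e6, 1e6),
                     z_nm = runif(1, -1e6, 1e6),
                     pre_class = sample(c("RGC", "LIN", "cortical", "other"), 1),
                     post_class = sample(c("TC", "LIN", "other"), 1))
    expect_silent(synapse_table(df))
    corrupt <- df
    field <- sample(c("pre_class", "post_class", "pos", "self"), 1)
    if (field == "pre_class") corrupt$pre_class <- "bouton"
    if (field == "post_class") corrupt$post_class <- "soma"
    if (field == "pos") corrupt$x_nm <- NaN
    if (field == "self") corrupt$post_cell <- corrupt$pre_cell
    expect_error(synapse_table(corrupt))
  }
})

test_that("datasets round-trip through a directory within 1e-6 nm", {
  g <- generate_circuit(generator_config(seed = 21, tc_count = 3L,
                                         dendrites_per_tc = c(2, 3, 4),
                                         island_bouton_count = 300L,
                                         nonisland_bouton_count = 800L,
                                         lin_count = 1L))
  dir <- file.path(tempdir(), "roundtrip")
  manifest <- write_dataset(g$dataset, dir)
  expect_true(all(c("synapses.csv", "provenance.json", "manifest.json") %in%
                    c(manifest, "manifest.json")))
  back <- read_dataset(dir)
  expect_setequal(names(back$skeletons), names(g$dataset$skeletons))
  for (id in names(g$dataset$skeletons)) {
    a <- g$dataset$skeletons[[id]]$nodes
    b <- back$skeletons[[id]]$nodes
    expect_equal(a$node_id, b$node_id)
    expect_equal(a$parent_id, b$parent_id)
    expect_lt(max(abs(as.matrix(a[, c("x", "y", "z")]) -
                        as.matrix(b[, c("x", "y", "z")]))), 1e-6)
    expect_equal(g$dataset$skeletons[[id]]$cell_class, back$skeletons[[id]]$cell_class)
  }
  expect_equal(as.data.frame(back$synapses)[, c(1:3, 7:8)],
               as.data.frame(g$dataset$synapses)[, c(1:3, 7:8)],
               ignore_attr = TRUE)
  expect_lt(max(abs(circuitseg:::synapse_xyz(back$synapses) -
                      circuitseg:::synapse_xyz(g$dataset$synapses))), 1e-6)

  # orphan RGC boutons are allowed and flagged in the manifest
  expect_gt(length(g$dataset$orphans), 0)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  expect_setequal(man$orphan_endpoints, g$dataset$orphans)
  expect_setequal(back$orphans, g$dataset$orphans)
})

test_that("skeleton invariants are enforced at construction", {
  nodes <- data.frame(node_id = 1:2, parent_id = c(-1L, 1L),
                      x = 0, y = 0, z = 0, radius = 1, structure_code = c(1L, 3L))
  expect_silent(neuron_skeleton("a", "TC", nodes))
  bad <- nodes; bad$radius[2] <- -1
  expect_error(neuron_skeleton("a", "TC", bad), "radii")
  bad <- nodes; bad$x[2] <- Inf
  expect_error(neuron_skeleton("a", "TC", bad), "non-finite")
  nosoma <- nodes; nosoma$structure_code <- 3L
  expect_error(neuron_skeleton("a", "TC", nosoma), "no soma")
  expect_silent(neuron_skeleton("a", "RGC", nosoma))
})
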