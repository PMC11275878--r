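test_that("two well-separated balls are labeled with no ambiguity", {
  fx <- two_ball_fixture(n = 500)
  lab <- fx$labeling
  expect_false(lab$no_split)
  expect_equal(sum(lab$labels == "ambiguous"), 0L)
  # labels must coincide with the true partition (one ball per field)
  l1 <- lab$labels[fx$ball == 1]
  l2 <- lab$labels[fx$ball == 2]
  expect_gte(mean(l1 == names(which.max(table(l1)))), 0.99)
  expect_gte(mean(l2 == names(which.max(table(l2)))), 0.99)
  expect_false(names(which.max(table(l1))) == names(which.max(table(l2))))
  # conservation
  expect_equal(sum(table(factor(lab$labels,
                                levels = c("island", "nonisland", "ambiguous")))),
               length(lab$labels))
})

test_that("a single ball yields the no-split flag rather than an error", {
  pos <- ball_points(400, c(0, 0, 0), 8000, seed = 3)
  lab <- classify_boutons(pos)
  expect_true(lab$no_split)
  expect_true(all(lab$labels %in% c("island", "ambiguous")))
})

test_that("mid-shell boutons are labeled ambiguous, and only they are", {
  g <- generate_circuit(generator_config(seed = 13, midshell_bouton_count = 3L))
  lab <- classify_boutons(g$dataset)
  gt <- g$ground_truth$boutons
  idx <- match(gt$synapse_id, lab$bouton_ids)
  mid <- gt$true_field == "ambiguous"
  expect_equal(sum(mid), 3L)
  expect_true(all(lab$labels[idx[mid]] == "ambiguous"))
  expect_equal(sum(lab$labels[idx[!mid]] == "ambiguous"), 0L)
})

test_that("bouton labels recover generator ground truth across seeds", {
  for (s in 1:4) {
    g <- generate_circuit(generator_config(seed = s))
    lab <- classify_boutons(g$dataset)
    gt <- g$ground_truth$boutons
    idx <- match(gt$synapse_id, lab$bouton_ids)
    expect_gte(mean(lab$labels[idx] == gt$true_field), 0.99)
  }
})

test_that("the separation projection recovers a constructed slab gap", {
  set.seed(7)
  for (rep in 1:3) {
    gap <- runif(1, 5000, 15000)
    a <- cbind(runif(300, 0, 3e4), runif(300, 0, 3e4), runif(300, -2e4, 0))
    b <- cbind(runif(300, 0, 3e4), runif(300, 0, 3e4), runif(300, gap, gap + 2e4))
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    pos <- rbind(a, b) %*% t(R)
    labels <- rep(c("island", "nonisland"), each = 300)
    proj <- find_separation_projection(labels, pos, angular_resolution = 2)
    # margin equals the construction gap up to the support shortfall of
    # finite samples (points rarely sit exactly on the slab faces)
    expect_gt(proj$margin, gap * 0.95)
    # the margin can never exceed the smallest inter-class distance
    d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
    expect_lte(proj$margin, sqrt(min(d2)) + 1e-9)
    # recovered axis within the angular resolution of the true normal
    true_normal <- R %*% c(0, 0, 1)
    ang <- acos(min(1, abs(sum(proj$axis * true_normal)))) * 180 / pi
    expect_lt(ang, 2.5)
    expect_equal(proj$overlap_count, 0L)
    # rotation is orthonormal with determinant +1
    expect_lt(max(abs(proj$rotation %*% t(proj$rotation) - diag(3))), 1e-9)
    expect_equal(det(proj$rotation), 1, tolerance = 1e-9)
  }
})

test_that("interpenetrating clouds give zero margin and a positive overlap count", {
  set.seed(8)
  pos <- matrix(rnorm(1200, sd = 5000), ncol = 3)
  labels <- rep(c("island", "nonisland"), each = 200)
  proj <- find_separation_projection(labels, pos)
  expect_equal(proj$margin, 0)
  expect_gt(proj$overlap_count, 0L)
  expect_error(find_separation_projection(rep("island", 400), pos), "non-empty")
})

test_that("the exclusion-zone width is recovered from synthetic geometry", {
  w <- 10000
  for (s in c(2, 31)) {
    g <- generate_circuit(generator_config(seed = s, exclusion_width = w))
    lab <- classify_boutons(g$dataset)
    gap <- measure_exclusion_zone(lab)
    expect_gte(gap$median_gap, 0.8 * w)
    expect_lte(gap$median_gap, 1.3 * w)
    expect_false(gap$no_zone)
    expect_equal(gap$n_rays_excluded, 500L - gap$n_rays_used)
  }
})

test_that("touching fields are flagged as having no zone", {
  # Two abutting balls: the between-field gap is just inter-bouton spacing.
  a <- ball_points(500, c(0, 0, 0), 10000, seed = 5)
  b <- ball_points(500, c(20200, 0, 0), 10000, seed = 6)
  pos <- rbind(a, b)
  lab <- classify_boutons(pos)
  if (!lab$no_split) {
    gap <- measure_exclusion_zone(lab)
    expect_true(gap$no_zone)
  } else {
    succeed("fields merged at zero separation; no-split flag raised instead")
  }
})

test_that("doubling bouton density leaves the measured gap stable", {
  base <- generator_config(seed = 17)
  dense <- generator_config(seed = 17, island_bouton_count = 1600L,
                            nonisland_bouton_count = 6600L)
  g1 <- measure_exclusion_zone(classify_boutons(generate_circuit(base)$dataset))
  g2 <- measure_exclusion_zone(classify_boutons(generate_circuit(dense)$dataset))
  expect_lt(abs(g1$median_gap - g2$median_gap) / g1$median_gap, 0.10)
})

test_that("labeling, margin and gap are equivariant under rigid motions", {
  g <- generate_circuit(generator_config(seed = 9))
  pos <- rgc_bouton_positions(g$dataset)
  lab1 <- classify_boutons(pos)
  gap1 <- measure_exclusion_zone(lab1)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(0.4), -sin(0.4)), c(0, sin(0.4), cos(0.4)))
  pos2 <- pos %*% t(R) + matrix(c(1e5, -5e4, 2e5), nrow(pos), 3, byrow = TRUE)
  rownames(pos2) <- rownames(pos)
  lab2 <- classify_boutons(pos2)
  expect_identical(lab1$labels, lab2$labels)
  gap2 <- measure_exclusion_zone(lab2)
  expect_equal(gap1$median_gap, gap2$median_gap, tolerance = 1e-6)
  expect_equal(gap1$min_gap, gap2$min_gap, tolerance = 1e-6)
  expect_equal(gap1$max_gap, gap2$max_gap, tolerance = 1e-6)
})
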