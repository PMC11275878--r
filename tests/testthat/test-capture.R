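test_that("single-cell capture probability matches enumeration", {
  expect_equal(capture_probability(1), 1.0)
  # k = 2: 2 agreeing of 4 assignments; k = 7: 2 of 128
  for (k in c(2, 3, 7)) {
    assign <- expand.grid(rep(list(0:1), k))
    agree <- mean(rowSums(assign) %in% c(0, k))
    expect_equal(capture_probability(k), agree, tolerance = 1e-15)
  }
  expect_equal(capture_probability(7), 0.015625)
  expect_error(capture_probability(0), "counts must be >= 1")
})

test_that("the Poisson-binomial convolution equals full enumeration", {
  cases <- list(1, c(2, 2), c(2, 2, 3), c(3, 4, 5), c(1, 1, 1, 1),
                c(2, 2, 3, 4, 5), c(4, 4, 4, 4), c(7, 7), c(1, 2, 3, 4, 5))
  for (counts in cases) {
    expect_lt(max(abs(exact_capture_distribution(counts) -
                        brute_force_capture_dist(counts))), 1e-12)
  }
  expect_equal(exact_capture_distribution(c(2, 2)), c(0.25, 0.5, 0.25))
  expect_equal(exact_capture_distribution(1), c(0, 1))
  expect_equal(exact_capture_distribution(integer(0)), 1)
  expect_equal(sum(exact_capture_distribution(c(2, 2, 3, 4, 4, 4, 5, 5, 7))), 1,
               tolerance = 1e-12)
  expect_equal(sum(exact_capture_distribution(c(2, 2, 3, 4, 4, 4, 5, 5, 7)) * 0:9),
               1.765625, tolerance = 1e-12)
})

test_that("the Monte Carlo null converges to the exact distribution", {
  counts <- c(2, 2, 3, 4, 4, 4, 5, 5, 7)
  null <- monte_carlo_null(counts, trials = 100000L, seed = 1L, levels = 0.99)
  expect_equal(sum(null$captured_count_histogram), null$trials)
  tv <- 0.5 * sum(abs(null$captured_count_histogram / null$trials -
                        null$exact_distribution))
  expect_lt(tv, 0.01)
  # DKW band over a seed sweep (alpha = 1e-6)
  eps <- sqrt(log(2 / 1e-6) / (2 * 1e5))
  for (s in 2:4) {
    nl <- monte_carlo_null(counts, trials = 100000L, seed = s)
    sup <- max(abs(cumsum(nl$captured_count_histogram) / nl$trials -
                     cumsum(nl$exact_distribution)))
    expect_lt(sup, eps)
  }
  # deterministic given seed
  expect_identical(monte_carlo_null(counts, 1000L, seed = 9)$captured_count_histogram,
                   monte_carlo_null(counts, 1000L, seed = 9)$captured_count_histogram)
})

test_that("all-single-dendrite cells are captured in every trial", {
  null <- monte_carlo_null(c(1, 1, 1), trials = 2000L, seed = 3)
  expect_equal(unname(null$captured_count_histogram[4]), 2000L)
  expect_equal(null$exact_mean, 3)
})

test_that("exceedance reporting is definitionally consistent with thresholds", {
  counts <- c(2, 2, 3, 4, 4, 4, 5, 5, 7)
  null <- monte_carlo_null(counts, trials = 100000L, seed = 2, levels = 0.99)
  expect_equal(compare_observed_to_null(0, null)$exact_tail, 1)
  obs9 <- compare_observed_to_null(9, null)
  expect_equal(obs9$exact_tail, 2^(9 - sum(counts)), tolerance = 1e-12)
  for (m in 0:9) {
    cmp <- compare_observed_to_null(m, null)
    above <- unname(cmp$exceeds_threshold["0.99"])
    expect_equal(above, cmp$empirical_tail < 0.01 + 1 / null$trials)
  }
  expect_error(compare_observed_to_null(10, null), "0..9")
})

test_that("capture classification is exhaustive, exclusive, and symmetric", {
  for (i in 0:4) for (n in 0:4) for (a in 0:4) {
    cls <- classify_tc(i, n, a)
    expect_true(cls %in% c("pure_island", "pure_nonisland", "mixed",
                           "ambiguous_zone", "no_rgc"))
    swapped <- classify_tc(n, i, a)
    if (cls == "pure_island") expect_equal(swapped, "pure_nonisland")
    if (cls == "pure_nonisland") expect_equal(swapped, "pure_island")
    if (cls %in% c("mixed", "no_rgc", "ambiguous_zone")) expect_equal(swapped, cls)
  }
  expect_equal(classify_tc(118, 0, 0), "pure_island")
  expect_equal(classify_tc(1, 1, 0), "mixed")
  expect_equal(classify_tc(0, 0, 0), "no_rgc")
  # a cell whose inputs sit mostly in the exclusion zone
  expect_equal(classify_tc(2, 0, 3), "ambiguous_zone")
})

test_that("innervation profiles count inputs per primary dendrite subtree", {
  fx <- two_ball_fixture(n = 400, seed = 21)
  lab <- fx$labeling
  ball1 <- fx$positions[fx$ball == 1, ]
  ball2 <- fx$positions[fx$ball == 2, ]
  f1 <- circuitseg:::label_points(lab, ball1[1, , drop = FALSE])
  # TC with two dendrites into ball 1 and one into ball 2
  tc <- chain_skeleton("tc_a", "TC", c(20000, 0, 0),
                       list(ball1[1:5, ], ball1[6:9, ], ball2[1:6, ]))
  syn <- rgc_synapses_at(rbind(ball1[1:9, ], ball2[1:6, ]), "tc_a")
  prof <- profile_tc(tc, syn, lab)
  expect_equal(prof$n_total_rgc, 15)
  expect_equal(prof$primary_dendrite_count, 3)
  expect_equal(prof$capture_class, "mixed")
  if (f1 == "island") {
    expect_equal(prof$n_island, 9); expect_equal(prof$n_nonisland, 6)
  } else {
    expect_equal(prof$n_island, 6); expect_equal(prof$n_nonisland, 9)
  }

  # no RGC inputs at all
  tc0 <- chain_skeleton("tc_b", "TC", c(20000, 0, 0), list(ball1[10:12, ]))
  prof0 <- profile_tc(tc0, rgc_synapses_at(ball1[0, , drop = FALSE], "tc_b"), lab)
  expect_equal(prof0$capture_class, "no_rgc")
  expect_equal(prof0$primary_dendrite_count, 0)

  # distant synapse triggers a warning but is still counted
  far <- matrix(c(20000, 90000, 0), 1)
  expect_warning(
    proff <- profile_tc(tc0, rgc_synapses_at(far, "tc_b"), lab),
    "farther than")
  expect_equal(proff$n_total_rgc, 1)
})

test_that("soma-to-mean-synapse offsets follow their definition", {
  tc <- chain_skeleton("tc_c", "TC", c(0, 0, 0),
                       list(matrix(c(1000, 0, 0, 3000, 0, 0), 2, byrow = TRUE)))
  v <- soma_synapse_vector(tc, matrix(c(1000, 0, 0, 3000, 0, 0), 2, byrow = TRUE))
  expect_equal(v$offset, c(2000, 0, 0))
  expect_equal(v$offset_norm, 2000)

  sym <- rbind(c(5000, 0, 0), c(-5000, 0, 0), c(0, 7000, 0), c(0, -7000, 0))
  v2 <- soma_synapse_vector(tc, sym)
  expect_equal(v2$offset_norm, 0, tolerance = 1e-9)

  expect_error(soma_synapse_vector(tc, sym[0, , drop = FALSE]), "no RGC inputs")
  nos <- tc; nos$soma_node_ids <- integer(0)
  expect_error(soma_synapse_vector(nos, sym), "no soma")
})

test_that("captured TCs point their arbors away from the opposite field", {
  hits <- 0; total <- 0
  for (s in c(3, 14)) {
    g <- generate_circuit(generator_config(seed = s, segregation = 1))
    lab <- classify_boutons(g$dataset)
    syn <- as.data.frame(g$dataset$synapses)
    gt <- g$ground_truth$tc
    for (i in seq_len(nrow(gt))) {
      id <- gt$tc_id[i]
      pos <- as.matrix(syn[syn$post_cell == id & syn$pre_class == "RGC",
                           c("x_nm", "y_nm", "z_nm")])
      v <- soma_synapse_vector(g$dataset$skeletons[[id]], pos, lab)
      want <- if (gt$true_capture[i] == "pure_island") -1 else 1
      hits <- hits + (sign(v$outward_projection) == want)
      total <- total + 1
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("the cumulative bouton curve is ordered and sums correctly", {
  profs <- data.frame(tc_id = c("a", "b", "c"), n_total_rgc = c(10, 3, 7),
                      capture_class = "pure_island")
  cv <- cumulative_bouton_curve(profs)
  expect_equal(cv$n_total_rgc, c(3, 7, 10))
  expect_equal(cv$cumulative, c(3, 10, 20))
})
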