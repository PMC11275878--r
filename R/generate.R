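#' Configuration for the synthetic circuit generator
#'
#' Describes the geometry and connectivity statistics of a synthetic
#' dLGN patch: a dense ellipsoidal island of RGC boutons, a bouton-free
#' exclusion shell of constant width around it, a surrounding non-island
#' bouton field, TC somata scattered across the shell with a fixed list of
#' RGC-connected primary dendrites each, and LINs with long shaft
#' neurites and short synapse-dense targeted neurites.
#'
#' @param seed Integer RNG seed; the entire circuit is a deterministic
#'   function of the config including the seed.
#' @param island_center Ellipsoid centre, nm.
#' @param island_radii Ellipsoid semi-axes, nm.
#' @param exclusion_width Width of the bouton-free shell, nm.
#' @param surround_thickness Radial thickness of the non-island bouton
#'   shell beyond the exclusion zone, nm.
#' @param island_bouton_count,nonisland_bouton_count Boutons per field.
#' @param tc_count Number of TC cells.
#' @param dendrites_per_tc Integer vector (recycled to `tc_count`) of
#'   RGC-connected primary dendrites per TC. The default is the observed
#'   per-cell count list `(2,2,3,4,4,4,5,5,7)` for nine exclusion-zone
#'   TCs.
#' @param boutons_per_tc_range Integer `(min, max)`; each TC's total RGC
#'   input count is drawn uniformly from this range, then raised to at
#'   least its dendrite count so that every RGC-connected dendrite
#'   receives at least one bouton (the dendrite list counts *connected*
#'   dendrites by definition).
#' @param segregation Real in `[0, 1]`. Each TC draws a home field; each
#'   of its dendrites follows the home field with probability
#'   `segregation` and otherwise picks island/non-island independently
#'   with probability 1/2. At 1 every TC is fully captured by one field;
#'   at 0 the circuit realises the independent-dendrite null model
#'   exactly.
#' @param lin_count Number of LINs.
#' @param targeted_neurite_reach Length scale of LIN targeted neurites,
#'   nm (default 20 um).
#' @param midshell_bouton_count Extra boutons placed at mid-shell depth
#'   inside the exclusion zone, with true field label `"ambiguous"`
#'   (mimics the handful of boutons observed in the middle of the zone).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 1L,
                             island_center = c(0, 0, 0),
                             island_radii = c(15000, 12000, 10000),
                             exclusion_width = 10000,
                             surround_thickness = 6000,
                             island_bouton_count = 800L,
                             nonisland_bouton_count = 3300L,
                             tc_count = 9L,
                             dendrites_per_tc = c(2, 2, 3, 4, 4, 4, 5, 5, 7),
                             boutons_per_tc_range = c(0L, 118L),
                             segregation = 1,
                             lin_count = 2L,
                             targeted_neurite_reach = 20000,
                             midshell_bouton_count = 0L) {
  cfg <- list(seed = as.integer(seed), island_center = as.numeric(island_center),
              island_radii = as.numeric(island_radii),
              exclusion_width = as.numeric(exclusion_width),
              surround_thickness = as.numeric(surround_thickness),
              island_bouton_count = as.integer(island_bouton_count),
              nonisland_bouton_count = as.integer(nonisland_bouton_count),
              tc_count = as.integer(tc_count),
              dendrites_per_tc = as.integer(rep_len(dendrites_per_tc, tc_count)),
              boutons_per_tc_range = as.integer(boutons_per_tc_range),
              segregation = as.numeric(segregation),
              lin_count = as.integer(lin_count),
              targeted_neurite_reach = as.numeric(targeted_neurite_reach),
              midshell_bouton_count = as.integer(midshell_bouton_count))
  if (!is_vec3(cfg$island_center) || !is_vec3(cfg$island_radii) ||
      any(cfg$island_radii <= 0)) {
    stopf("island_center/island_radii must be finite 3-vectors, radii > 0")
  }
  if (cfg$exclusion_width <= 0) stopf("exclusion_width must be > 0")
  if (cfg$surround_thickness <= 0) stopf("surround_thickness must be > 0")
  if (cfg$segregation < 0 || cfg$segregation > 1) stopf("segregation must be in [0, 1]")
  if (any(cfg$dendrites_per_tc < 1)) stopf("dendrites_per_tc entries must be >= 1")
  if (length(cfg$boutons_per_tc_range) != 2L ||
      cfg$boutons_per_tc_range[1] < 0 ||
      diff(cfg$boutons_per_tc_range) < 0) {
    stopf("boutons_per_tc_range must be a non-decreasing pair of non-negative integers")
  }
  # Feasibility: refuse bouton densities beyond physical packing (~one
  # bouton per (500 nm)^3 is already far denser than tissue).
  v_island <- 4 / 3 * pi * prod(cfg$island_radii)
  v_surround <- ellipsoid_volume(cfg$island_radii + cfg$exclusion_width +
                                   cfg$surround_thickness) -
    ellipsoid_volume(cfg$island_radii + cfg$exclusion_width)
  if (cfg$island_bouton_count > v_island / 500^3 ||
      cfg$nonisland_bouton_count > v_surround / 500^3) {
    stopf("requested bouton count infeasible for the configured volume")
  }
  structure(cfg, class = "generator_config")
}

ellipsoid_volume <- function(radii) 4 / 3 * pi * prod(radii)

# Normalised ellipsoidal radius: <= 1 inside the ellipsoid (center, radii).
ellipsoid_u <- function(xyz, center, radii) {
  sqrt(colSums((t(xyz) - center)^2 / radii^2))
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

sample_in_ellipsoid <- function(n, center, radii) {
  if (n == 0L) return(matrix(numeric(0), 0, 3))
  g <- matrix(stats::rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  r <- stats::runif(n)^(1 / 3)
  sweep(g * r, 2L, radii, `*`) + matrix(center, n, 3, byrow = TRUE)
}

# Uniform sample between two confocal-ish ellipsoids (inner excluded),
# by rejection from the outer bounding box.
sample_in_annulus <- function(n, center, inner_radii, outer_radii) {
  out <- matrix(numeric(0), 0, 3)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 256L)
    cand <- sweep(matrix(stats::runif(3 * m, -1, 1), ncol = 3), 2L,
                  outer_radii, `*`) +
      matrix(center, m, 3, byrow = TRUE)
    keep <- ellipsoid_u(cand, center, inner_radii) > 1 &
      ellipsoid_u(cand, center, outer_radii) <= 1
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}

#' Generate a synthetic circuit with ground truth
#'
#' Draws a full circuit dataset (skeletons + synapse table) and the
#' ground truth used to score downstream analyses: the true field label
#' of every RGC bouton, each TC's true per-dendrite field assignment and
#' capture class, the island geometry, and the true type and field of
#' every LIN neurite. Deterministic given the config (including its
#' seed).
#'
#' @param config A [generator_config()].
#' @return List with elements `dataset` (a [circuit_dataset()]) and
#'   `ground_truth` (see Details).
#' @details `ground_truth` contains `boutons` (data frame: `synapse_id`,
#'   `true_field`), `tc` (data frame: `tc_id`, `home_field`,
#'   `n_dendrites`, `true_capture`, `n_boutons`), `dendrite_fields`
#'   (list per TC), `island` (centre/radii/exclusion width) and
#'   `lin_neurites` (data frame: `lin_id`, `branch_label`, `true_type`,
#'   `true_field`).
#' @export
generate_circuit <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  with_seed(config$seed, generate_circuit_impl(config))
}

generate_circuit_impl <- function(cfg) {
  ctr <- cfg$island_center; rad <- cfg$island_radii
  w <- cfg$exclusion_width; thick <- cfg$surround_thickness

  ## Bouton fields -----------------------------------------------------
  isl <- sample_in_ellipsoid(cfg$island_bouton_count, ctr, rad)
  non <- sample_in_annulus(cfg$nonisland_bouton_count, ctr, rad + w,
                           rad + w + thick)
  mid <- if (cfg$midshell_bouton_count > 0L) {
    # Points on the mid-shell ellipsoid: inside the exclusion zone.
    d <- fibonacci_sphere(cfg$midshell_bouton_count)
    sweep(d, 2L, rad + w / 2, `*`) + matrix(ctr, nrow(d), 3, byrow = TRUE)
  } else matrix(numeric(0), 0, 3)

  boutons <- rbind(isl, non, mid)
  n_b <- nrow(boutons)
  bouton_field <- c(rep("island", nrow(isl)), rep("nonisland", nrow(non)),
                    rep("ambiguous", nrow(mid)))
  bouton_id <- sprintf("syn_%04d", seq_len(n_b))
  rgc_id <- sprintf("rgc_%04d", seq_len(n_b))
  post_cell <- rep("unassigned", n_b)
  post_class <- rep("other", n_b)
  available <- bouton_field %in% c("island", "nonisland")

  skeletons <- list()
  extra_syn <- list()

  ## TC cells ----------------------------------------------------------
  soma_dirs <- fibonacci_sphere(max(cfg$tc_count, 1L))
  tc_ids <- sprintf("tc_%02d", seq_len(cfg$tc_count))
  dendrite_fields <- vector("list", cfg$tc_count)
  tc_truth <- data.frame(tc_id = tc_ids, home_field = NA_character_,
                         n_dendrites = cfg$dendrites_per_tc,
                         true_capture = NA_character_,
                         n_boutons = NA_integer_)
  rng <- cfg$boutons_per_tc_range
  for (i in seq_len(cfg$tc_count)) {
    k <- cfg$dendrites_per_tc[i]
    # Somata sit in the inner part of the exclusion shell; a cell captured
    # by the surround must reach across the zone, as its arbor does.
    soma_pos <- ctr + (rad + w / 4) * soma_dirs[i, ]
    home <- sample(c("island", "nonisland"), 1L)
    follow <- stats::runif(k) < cfg$segregation
    indep <- sample(c("island", "nonisland"), k, replace = TRUE)
    fields <- ifelse(follow, home, indep)
    dendrite_fields[[i]] <- fields
    n_syn <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    n_syn <- max(n_syn, k)
    per_dend <- rep(1L, k)
    if (n_syn > k) {
      extra <- stats::rmultinom(1L, n_syn - k, rep(1 / k, k))[, 1]
      per_dend <- per_dend + extra
    }
    nodes <- data.frame(node_id = 1L, parent_id = -1L,
                        x = soma_pos[1], y = soma_pos[2], z = soma_pos[3],
                        radius = 7000, structure_code = 1L)
    next_id <- 2L
    for (j in seq_len(k)) {
      pool <- which(available & bouton_field == fields[j])
      if (length(pool) < per_dend[j]) {
        stopf("bouton field '%s' exhausted while wiring %s; increase bouton counts",
              fields[j], tc_ids[i])
      }
      d2 <- sqrt(rowSums((boutons[pool, , drop = FALSE] -
                            matrix(soma_pos, length(pool), 3, byrow = TRUE))^2))
      # Proximal RGC-receiving dendrites collect input locally: Gaussian
      # distance decay keeps each arbor within a few tens of micrometres
      # (an exponential tail would let the sheer volume of distant
      # neuropil outweigh the near field).
      wgt <- exp(-0.5 * (d2 / 10000)^2)
      sel <- pool[sample.int(length(pool), per_dend[j], prob = wgt)]
      available[sel] <- FALSE
      post_cell[sel] <- tc_ids[i]
      post_class[sel] <- "TC"
      ord <- sel[order(sqrt(rowSums((boutons[sel, , drop = FALSE] -
                                       matrix(soma_pos, length(sel), 3, byrow = TRUE))^2)))]
      parent <- 1L
      for (b in ord) {
        nodes <- rbind(nodes, data.frame(node_id = next_id, parent_id = parent,
                                         x = boutons[b, 1], y = boutons[b, 2],
                                         z = boutons[b, 3], radius = 500,
                                         structure_code = 3L))
        parent <- next_id
        next_id <- next_id + 1L
      }
    }
    skeletons[[tc_ids[i]]] <- neuron_skeleton(tc_ids[i], "TC", nodes)
    tc_truth$home_field[i] <- home
    tc_truth$n_boutons[i] <- n_syn
    tc_truth$true_capture[i] <-
      if (all(fields == "island")) "pure_island"
      else if (all(fields == "nonisland")) "pure_nonisland"
      else "mixed"
  }

  ## LIN cells ----------------------------------------------------------
  lin_truth <- data.frame(lin_id = character(0), branch_label = character(0),
                          true_type = character(0), true_field = character(0))
  shaft_half <- sum(rad) / 3 + w + thick + 80000  # reaches well beyond the surround
  for (li in seq_len(cfg$lin_count)) {
    lin_id <- sprintf("lin_%02d", li)
    dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
    soma_pos <- ctr + (rad + w / 2) * dir
    lin <- build_lin(lin_id, soma_pos, dir, ctr, rad, w, thick, shaft_half,
                     cfg$targeted_neurite_reach)
    skeletons[[lin_id]] <- lin$skeleton
    lin_truth <- rbind(lin_truth, lin$truth)
    # Input synapses: adopt unused boutons near targeted neurites / shaft.
    for (br in lin$input_sites) {
      pool <- which(available & bouton_field == br$field)
      if (length(pool) == 0L) next
      d2 <- sqrt(rowSums((boutons[pool, , drop = FALSE] -
                            matrix(br$center, length(pool), 3, byrow = TRUE))^2))
      near <- pool[d2 <= br$reach]
      take <- utils::head(near[order(d2[d2 <= br$reach])], br$n)
      if (length(take)) {
        available[take] <- FALSE
        post_cell[take] <- lin_id
        post_class[take] <- "LIN"
      }
    }
    extra_syn[[lin_id]] <- lin$outputs
  }

  syn_df <- data.frame(synapse_id = bouton_id, pre_cell = rgc_id,
                       post_cell = post_cell,
                       x_nm = boutons[, 1], y_nm = boutons[, 2],
                       z_nm = boutons[, 3],
                       pre_class = "RGC", post_class = post_class)
  if (length(extra_syn)) {
    outs <- do.call(rbind, extra_syn)
    if (!is.null(outs) && nrow(outs)) {
      outs$synapse_id <- sprintf("syn_out_%04d", seq_len(nrow(outs)))
      syn_df <- rbind(syn_df, outs[, names(syn_df)])
    }
  }

  dataset <- circuit_dataset(
    skeletons = unname(skeletons),
    synapses = synapse_table(syn_df),
    scaling = voxel_scaling(),
    provenance = list(generator = "circuitseg synthetic circuit",
                      seed = cfg$seed,
                      segregation = cfg$segregation,
                      synthetic = TRUE))

  ground_truth <- list(
    boutons = data.frame(synapse_id = bouton_id, true_field = bouton_field),
    tc = tc_truth,
    dendrite_fields = stats::setNames(dendrite_fields, tc_ids),
    island = list(center = ctr, radii = rad, exclusion_width = w),
    lin_neurites = lin_truth)
  list(dataset = dataset, ground_truth = ground_truth)
}

# One LIN: soma in the exclusion zone, two long shaft branches running
# through the island and out past the surround, one island-affiliated and
# one non-island-affiliated targeted neurite, and a small output-only
# axon-like branch.
build_lin <- function(lin_id, soma_pos, dir, ctr, rad, w, thick, shaft_half,
                      reach) {
  step <- 2000
  nodes <- data.frame(node_id = 1L, parent_id = -1L,
                      x = soma_pos[1], y = soma_pos[2], z = soma_pos[3],
                      radius = 6000, structure_code = 1L)
  next_id <- 2L
  branch_nodes <- list()
  add_path <- function(from_id, pts, radius, code) {
    parent <- from_id
    ids <- integer(0)
    for (r in seq_len(nrow(pts))) {
      nodes <<- rbind(nodes, data.frame(node_id = next_id, parent_id = parent,
                                        x = pts[r, 1], y = pts[r, 2],
                                        z = pts[r, 3], radius = radius,
                                        structure_code = code))
      parent <- next_id
      ids <- c(ids, next_id)
      next_id <<- next_id + 1L
    }
    ids
  }
  # Shaft branch 1: inward through the island centre and beyond.
  t1 <- seq(step, shaft_half + sum(rad) / 3 + w, by = step)
  p1 <- matrix(soma_pos, length(t1), 3, byrow = TRUE) -
    outer(t1, dir)
  ids1 <- add_path(1L, p1, 800, 3L)
  branch_nodes$shaft_in <- ids1
  # Shaft branch 2: outward.
  t2 <- seq(step, shaft_half, by = step)
  p2 <- matrix(soma_pos, length(t2), 3, byrow = TRUE) + outer(t2, dir)
  ids2 <- add_path(1L, p2, 800, 3L)
  branch_nodes$shaft_out <- ids2

  # Targeted neurites: branch from a shaft node well inside each field.
  u1 <- ellipsoid_u(p1, ctr, rad)
  anchor_isl <- which(u1 < 0.7)[1]
  u2 <- ellipsoid_u(p2, ctr, rad + w)
  d_out <- ellipsoid_u(p2, ctr, rad + w + thick)
  anchor_non <- which(u2 > 1.05 & d_out < 0.95)[1]
  perp <- c(-dir[2], dir[1], 0)
  if (sum(perp^2) < 1e-12) perp <- c(1, 0, 0)
  perp <- perp / sqrt(sum(perp^2))
  mk_targeted <- function(anchor_xyz, anchor_id, label) {
    n_pts <- 15L
    # Tortuous but short: smooth random-walk wiggle around a straight run.
    wiggle <- apply(matrix(stats::rnorm(3 * n_pts, sd = 400), ncol = 3), 2L, cumsum)
    pts <- matrix(anchor_xyz, n_pts, 3, byrow = TRUE) +
      outer(seq_len(n_pts) * (0.6 * reach / n_pts), perp) + wiggle
    ids <- add_path(anchor_id, pts, 300, 3L)
    branch_nodes[[label]] <<- ids
    colMeans(pts)
  }
  input_sites <- list()
  truth <- data.frame(lin_id = character(0), branch_label = character(0),
                      true_type = character(0), true_field = character(0))
  if (!is.na(anchor_isl)) {
    c_isl <- mk_targeted(p1[anchor_isl, ], ids1[anchor_isl], "targeted_island")
    input_sites$targeted_island <- list(center = c_isl, reach = reach,
                                        field = "island", n = 20L)
    truth <- rbind(truth, data.frame(lin_id = lin_id,
                                     branch_label = "targeted_island",
                                     true_type = "targeted",
                                     true_field = "island"))
  }
  if (!is.na(anchor_non)) {
    c_non <- mk_targeted(p2[anchor_non, ], ids2[anchor_non], "targeted_nonisland")
    input_sites$targeted_nonisland <- list(center = c_non, reach = reach,
                                           field = "nonisland", n = 20L)
    truth <- rbind(truth, data.frame(lin_id = lin_id,
                                     branch_label = "targeted_nonisland",
                                     true_type = "targeted",
                                     true_field = "nonisland"))
  }
  # Sparse shaft inputs, one site per field, away from the shell.
  input_sites$shaft_isl <- list(center = ctr, reach = min(rad) * 0.8,
                                field = "island", n = 4L)
  far_non <- soma_pos + dir * (sum(rad) / 3 + w + thick / 2)
  input_sites$shaft_non <- list(center = far_non, reach = thick,
                                field = "nonisland", n = 4L)
  truth <- rbind(truth,
                 data.frame(lin_id = lin_id,
                            branch_label = c("shaft_in", "shaft_out"),
                            true_type = "shaft", true_field = "both"))

  # Axon-like branch: short, output-only, running outward (tilted off the
  # shaft line) so its boutons land in non-island neuropil, clear of the
  # shell and of the shaft's input field.
  dir_ax <- dir - perp  # targeted neurites run along +perp; keep clear
  dir_ax <- dir_ax / sqrt(sum(dir_ax^2))
  ax_pts <- matrix(soma_pos, 6L, 3, byrow = TRUE) +
    outer(w / 2 + seq_len(6L) * 1500, dir_ax)
  ax_ids <- add_path(1L, ax_pts, 250, 2L)
  branch_nodes$axon <- ax_ids
  truth <- rbind(truth, data.frame(lin_id = lin_id, branch_label = "axon",
                                   true_type = "axon", true_field = "none"))

  # Output synapses: on shaft nodes outside the exclusion shell and on
  # targeted/axon branches; postsynaptic TC dendrites untraced (orphans).
  out_rows <- list()
  emit_outputs <- function(ids, every) {
    pick <- ids[seq(1L, length(ids), by = every)]
    xyz <- nodes[match(pick, nodes$node_id), c("x", "y", "z")]
    u_in <- ellipsoid_u(as.matrix(xyz), ctr, rad)
    u_out <- ellipsoid_u(as.matrix(xyz), ctr, rad + w)
    keep <- u_in <= 1 | u_out > 1   # never inside the exclusion shell
    xyz <- xyz[keep, , drop = FALSE]
    if (nrow(xyz)) {
      out_rows[[length(out_rows) + 1L]] <<- data.frame(
        synapse_id = NA_character_, pre_cell = lin_id,
        post_cell = sprintf("%s_target_%03d", lin_id,
                            length(out_rows) * 100L + seq_len(nrow(xyz))),
        x_nm = xyz$x, y_nm = xyz$y, z_nm = xyz$z,
        pre_class = "LIN", post_class = "TC")
    }
  }
  emit_outputs(branch_nodes$shaft_in, every = 8L)
  emit_outputs(branch_nodes$shaft_out, every = 8L)
  if (!is.null(branch_nodes$targeted_island)) emit_outputs(branch_nodes$targeted_island, 2L)
  if (!is.null(branch_nodes$targeted_nonisland)) emit_outputs(branch_nodes$targeted_nonisland, 2L)
  emit_outputs(branch_nodes$axon, 1L)

  list(skeleton = neuron_skeleton(lin_id, "LIN", nodes),
       truth = truth,
       input_sites = input_sites,
       outputs = if (length(out_rows)) do.call(rbind, out_rows) else NULL)
}

#' Degrade a dataset to emulate partial reconstruction
#'
#' Drops synapses independently and jitters the surviving positions with
#' isotropic Gaussian noise; skeletons are untouched. Used as a
#' robustness harness: every real reconstruction is partial.
#'
#' @param dataset A [circuit_dataset()].
#' @param drop_fraction Probability in `[0, 1)` that a synapse is removed.
#' @param jitter_sd Per-axis Gaussian SD of positional noise, nm (RMS 3D
#'   displacement is `jitter_sd * sqrt(3)`).
#' @param seed Integer seed.
#' @return A degraded [circuit_dataset()].
#' @export
degrade_circuit <- function(dataset, drop_fraction = 0, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(dataset, "circuit_dataset"))
  if (drop_fraction < 0 || drop_fraction >= 1) stopf("drop_fraction must be in [0, 1)")
  if (jitter_sd < 0) stopf("jitter_sd must be >= 0")
  with_seed(seed, {
    syn <- as.data.frame(dataset$synapses)
    if (drop_fraction > 0 && nrow(syn)) {
      syn <- syn[stats::runif(nrow(syn)) >= drop_fraction, , drop = FALSE]
    }
    if (jitter_sd > 0 && nrow(syn)) {
      syn[, c("x_nm", "y_nm", "z_nm")] <-
        syn[, c("x_nm", "y_nm", "z_nm")] +
        matrix(stats::rnorm(3L * nrow(syn), sd = jitter_sd), ncol = 3)
    }
    circuit_dataset(unname(dataset$skeletons), synapse_table(syn),
                    dataset$scaling,
                    c(dataset$provenance,
                      list(degraded = sprintf("drop=%g jitter_sd=%g seed=%d",
                                              drop_fraction, jitter_sd, seed))))
  })
}
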