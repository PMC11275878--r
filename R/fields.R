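FIELD_LABELS <- c("island", "nonisland", "ambiguous")

# Mean nearest-neighbour distance of a point cloud (n x 3). For large
# clouds the mean is taken over a deterministic stride subsample of query
# points (each query still sees every point), which leaves the estimator
# unbiased and the result reproducible.
mean_nn_spacing <- function(xyz, max_queries = 1024L) {
  n <- nrow(xyz)
  if (n < 2L) return(NA_real_)
  q <- if (n > max_queries) {
    unique(as.integer(round(seq(1L, n, length.out = max_queries))))
  } else seq_len(n)
  sq <- rowSums(xyz^2)
  block <- 256L
  nn <- numeric(length(q))
  for (s in seq(1L, length(q), by = block)) {
    idx <- q[s:min(s + block - 1L, length(q))]
    d2 <- outer(sq[idx], sq, `+`) - 2 * xyz[idx, , drop = FALSE] %*% t(xyz)
    d2[cbind(seq_along(idx), idx)] <- Inf
    nn[s:(s + length(idx) - 1L)] <- sqrt(pmax(apply(d2, 1L, min), 0))
  }
  mean(nn)
}

# Separable Gaussian blur of a 3D count array; sigma in grid-step units.
gaussian_blur3 <- function(arr, sigma) {
  dm <- dim(arr)
  for (ax in 1:3) {
    n <- dm[ax]
    K <- exp(-(outer(seq_len(n), seq_len(n), `-`))^2 / (2 * sigma^2))
    K <- K / (sqrt(2 * pi) * sigma)
    if (ax == 1L) {
      arr <- array(K %*% matrix(arr, dm[1], dm[2] * dm[3]), dm)
    } else {
      perm <- if (ax == 2L) c(2L, 1L, 3L) else c(3L, 2L, 1L)
      a2 <- aperm(arr, perm)
      d2 <- dim(a2)
      a2 <- array(K %*% matrix(a2, d2[1], d2[2] * d2[3]), d2)
      arr <- aperm(a2, perm)  # both perms are involutions
    }
  }
  arr
}

grid_voxel_index <- function(xyz, origin, step, dm) {
  ijk <- floor(sweep(xyz, 2L, origin, `-`) / step) + 1L
  ok <- ijk[, 1] >= 1 & ijk[, 1] <= dm[1] &
    ijk[, 2] >= 1 & ijk[, 2] <= dm[2] &
    ijk[, 3] >= 1 & ijk[, 3] <= dm[3]
  lin <- rep(NA_integer_, nrow(xyz))
  lin[ok] <- as.integer(ijk[ok, 1] + (ijk[ok, 2] - 1L) * dm[1] +
                          (ijk[ok, 3] - 1L) * dm[1] * dm[2])
  lin
}

# Connected components (6-connectivity) of TRUE voxels in a 3D mask.
# Returns an integer array: 0 outside, component id inside.
connected_components3 <- function(mask) {
  dm <- dim(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(array(0L, dm))
  rank <- integer(length(mask))
  rank[idx] <- seq_along(idx)
  i <- ((idx - 1L) %% dm[1]) + 1L
  j <- (((idx - 1L) %/% dm[1]) %% dm[2]) + 1L
  k <- ((idx - 1L) %/% (dm[1] * dm[2])) + 1L
  neigh <- function(stride, keep) {
    a <- idx[keep & (idx + stride) <= length(mask)]
    a <- a[mask[a + stride]]
    if (length(a)) cbind(rank[a], rank[a + stride]) else NULL
  }
  e <- rbind(neigh(1L, i < dm[1]),
             neigh(dm[1], j < dm[2]),
             neigh(dm[1] * dm[2], k < dm[3]))
  g <- igraph::graph_from_edgelist(
    rbind(e, cbind(seq_along(idx), seq_along(idx))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(idx)]
  out <- array(0L, dm)
  out[idx] <- as.integer(comp)
  out
}

#' Classify RGC boutons into island and non-island fields
#'
#' Computational surrogate for the optical identification of the bouton
#' island: a gridded Gaussian kernel density of bouton positions is
#' thresholded at a fraction of its maximum; connected voxel components
#' above threshold define candidate fields; the most compact
#' high-density component (smallest volume-to-bouton-count ratio) is the
#' island, boutons in any other component are non-island, and boutons in
#' no component — those in gap regions such as the exclusion zone — are
#' ambiguous. Deterministic.
#'
#' @param boutons Numeric n x 3 matrix of RGC bouton positions (nm), or a
#'   [circuit_dataset()] (its RGC synapse positions are used).
#' @param bandwidth Gaussian kernel SD in nm; default 2x the mean
#'   nearest-neighbour bouton spacing.
#' @param level_fraction Density threshold as a fraction of the maximum
#'   density, in (0, 1); default 0.1.
#' @param grid_step Grid spacing in nm; default `bandwidth / 2`.
#' @return An object of class `bouton_field_labeling`: per-bouton
#'   `labels` (`"island"`, `"nonisland"`, `"ambiguous"`), the density
#'   grid (origin, step, dims, threshold), the component map, the island
#'   component id and centroid, a `no_split` flag (set when all boutons
#'   fall in a single component), and the method parameters.
#' @export
classify_boutons <- function(boutons, bandwidth = NULL, level_fraction = 0.1,
                             grid_step = NULL) {
  if (inherits(boutons, "circuit_dataset")) boutons <- rgc_bouton_positions(boutons)
  boutons <- as.matrix(boutons)
  if (nrow(boutons) < 2L) stopf("need at least 2 boutons to classify")
  if (level_fraction <= 0 || level_fraction >= 1) {
    stopf("level_fraction must be in (0, 1)")
  }
  spacing <- mean_nn_spacing(boutons)
  if (is.null(bandwidth)) bandwidth <- 2 * spacing
  if (bandwidth <= 0) stopf("bandwidth must be > 0")
  if (is.null(grid_step)) grid_step <- bandwidth / 2

  pad <- 3 * bandwidth
  origin <- apply(boutons, 2L, min) - pad
  upper <- apply(boutons, 2L, max) + pad
  dm <- pmax(as.integer(ceiling((upper - origin) / grid_step)), 2L)

  counts <- array(0, dm)
  lin <- grid_voxel_index(boutons, origin, grid_step, dm)
  tab <- table(lin)
  counts[as.integer(names(tab))] <- as.numeric(tab)
  dens <- gaussian_blur3(counts, bandwidth / grid_step)
  threshold <- level_fraction * max(dens)
  comp <- connected_components3(dens >= threshold)

  bouton_comp <- comp[lin]
  comp_ids <- sort(unique(bouton_comp[bouton_comp > 0L]))
  if (length(comp_ids) == 0L) stopf("no bouton lies in an above-threshold component; lower level_fraction")
  vox_per_comp <- tabulate(comp, nbins = max(comp))
  b_per_comp <- tabulate(bouton_comp[bouton_comp > 0L], nbins = max(comp))
  compactness <- ifelse(b_per_comp[comp_ids] > 0,
                        vox_per_comp[comp_ids] / b_per_comp[comp_ids], Inf)
  island_id <- comp_ids[order(compactness, comp_ids)][1]

  labels <- rep("ambiguous", nrow(boutons))
  labels[bouton_comp == island_id] <- "island"
  labels[bouton_comp > 0L & bouton_comp != island_id] <- "nonisland"
  no_split <- length(comp_ids) < 2L

  structure(list(
    labels = labels,
    boutons = boutons,
    bouton_ids = rownames(boutons),
    grid = list(origin = origin, step = grid_step, dim = dm,
                threshold = threshold),
    density = dens,
    components = comp,
    island_component = island_id,
    island_centroid = colMeans(boutons[labels == "island", , drop = FALSE]),
    no_split = no_split,
    params = list(bandwidth = bandwidth, level_fraction = level_fraction,
                  mean_nn_spacing = spacing)),
    class = "bouton_field_labeling")
}

#' @export
print.bouton_field_labeling <- function(x, ...) {
  tb <- table(factor(x$labels, levels = FIELD_LABELS))
  cat(sprintf("<bouton_field_labeling> %d boutons: %d island, %d nonisland, %d ambiguous%s\n",
              length(x$labels), tb["island"], tb["nonisland"], tb["ambiguous"],
              if (isTRUE(x$no_split)) " [no-split]" else ""))
  invisible(x)
}

#' Field label of arbitrary points under a labeling
#'
#' @param labeling A [classify_boutons()] result.
#' @param xyz Numeric n x 3 matrix of positions (nm).
#' @return Character vector: `"island"`, `"nonisland"` or `"ambiguous"`
#'   (below the density threshold or outside the analysed grid).
#' @export
label_points <- function(labeling, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  lin <- grid_voxel_index(xyz, labeling$grid$origin, labeling$grid$step,
                          labeling$grid$dim)
  comp <- rep(0L, nrow(xyz))
  ok <- !is.na(lin)
  comp[ok] <- labeling$components[lin[ok]]
  out <- rep("ambiguous", nrow(xyz))
  out[comp == labeling$island_component] <- "island"
  out[comp > 0L & comp != labeling$island_component] <- "nonisland"
  out
}

margin_along <- function(u, isl, non) {
  p_i <- isl %*% u
  p_n <- non %*% u
  max(min(p_n) - max(p_i), min(p_i) - max(p_n))
}

golden_max <- function(f, lo, hi, tol = 1e-4, iters = 40L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  for (i in seq_len(iters)) {
    if (b - a < tol) break
    if (f1 < f2) { a <- c1; c1 <- c2; f1 <- f2; c2 <- a + gr * (b - a); f2 <- f(c2) }
    else { b <- c2; c2 <- c1; f2 <- f1; c1 <- b - gr * (b - a); f1 <- f(c1) }
  }
  (a + b) / 2
}

sph_to_unit <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

#' Find the projection axis of clearest island/non-island separation
#'
#' Rotating the bouton cloud to the orientation in which the two fields
#' separate most cleanly is the quantitative analogue of rotating a 3D
#' rendering until the gap between them is widest. The search scans unit
#' axes on a deterministic Fibonacci-sphere grid at the requested angular
#' resolution, then refines the best axis by golden-section search on the
#' two spherical angles. The margin along an axis is the 1D gap between
#' the projected supports of the two classes (negative when they
#' overlap); ambiguous boutons are excluded.
#'
#' @param labeling A [classify_boutons()] result (positions and labels
#'   are taken from it), or a character label vector if `boutons` is
#'   given.
#' @param boutons Optional n x 3 position matrix matching `labeling` when
#'   the latter is a plain label vector.
#' @param angular_resolution Grid resolution in degrees (default 2).
#' @return An object of class `separation_projection`: `axis` (unit
#'   3-vector, oriented so the island projects low), `rotation`
#'   (orthonormal 3 x 3, determinant +1, third row = axis), `margin`
#'   (nm, 0 when classes overlap), `overlap_count` (points inside the
#'   overlap interval).
#' @export
find_separation_projection <- function(labeling, boutons = NULL,
                                       angular_resolution = 2) {
  if (inherits(labeling, "bouton_field_labeling")) {
    boutons <- labeling$boutons
    labels <- labeling$labels
  } else {
    labels <- as.character(labeling)
    if (is.null(boutons)) stopf("boutons must be supplied with a plain label vector")
    boutons <- as.matrix(boutons)
  }
  isl <- boutons[labels == "island", , drop = FALSE]
  non <- boutons[labels == "nonisland", , drop = FALSE]
  if (nrow(isl) == 0L || nrow(non) == 0L) {
    stopf("both island and nonisland classes must be non-empty")
  }
  n_dirs <- max(200L, as.integer(ceiling(41253 / angular_resolution^2)))
  U <- fibonacci_sphere(n_dirs)
  best <- -Inf; best_u <- c(1, 0, 0)
  block <- 512L
  for (s in seq(1L, n_dirs, by = block)) {
    Uc <- U[s:min(s + block - 1L, n_dirs), , drop = FALSE]
    Pi <- isl %*% t(Uc)
    Pn <- non %*% t(Uc)
    mi_hi <- apply(Pi, 2L, max); mi_lo <- apply(Pi, 2L, min)
    nn_hi <- apply(Pn, 2L, max); nn_lo <- apply(Pn, 2L, min)
    m <- pmax(nn_lo - mi_hi, mi_lo - nn_hi)
    w <- which(m > best + 1e-12 |
                 (abs(m - best) <= 1e-12 & apply(Uc, 1L, function(u)
                   isTRUE(lex_less(u, best_u)))))
    if (length(w)) {
      w_best <- w[order(-m[w])][1]
      best <- m[w_best]; best_u <- Uc[w_best, ]
    }
  }
  # Golden-section refinement, alternating over the two spherical angles.
  th0 <- acos(max(-1, min(1, best_u[3])))
  ph0 <- atan2(best_u[2], best_u[1])
  half <- angular_resolution * pi / 180
  for (round in 1:3) {
    th0 <- golden_max(function(t) margin_along(sph_to_unit(t, ph0), isl, non),
                      th0 - half, th0 + half, tol = 1e-6)
    ph0 <- golden_max(function(p) margin_along(sph_to_unit(th0, p), isl, non),
                      ph0 - half, ph0 + half, tol = 1e-6)
    half <- half / 4
  }
  u <- sph_to_unit(th0, ph0)
  m <- margin_along(u, isl, non)
  if (m < best) { u <- best_u; m <- best }  # refinement never loses ground

  # Orient so the island side projects low.
  if (mean(isl %*% u) > mean(non %*% u)) u <- -u
  p_i <- drop(isl %*% u); p_n <- drop(non %*% u)
  overlap <- if (m >= 0) 0L else
    sum(p_i >= min(p_n)) + sum(p_n <= max(p_i))
  rot <- rotation_with_axis(u)
  structure(list(axis = u, rotation = rot, margin = max(m, 0),
                 raw_margin = m, overlap_count = overlap,
                 angular_resolution = angular_resolution),
            class = "separation_projection")
}

lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i] - 1e-12) return(TRUE)
    if (a[i] > b[i] + 1e-12) return(FALSE)
  }
  FALSE
}

# Right-handed orthonormal matrix whose third row is the given unit axis.
rotation_with_axis <- function(u) {
  u <- u / sqrt(sum(u^2))
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * u) * u
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])
  rbind(e1, e2, u, deparse.level = 0)
}

#' Measure the exclusion zone around the island
#'
#' Casts rays from the island centroid through a deterministic uniform
#' sample of directions; along each ray the gap between the last island
#' bouton and the first non-island bouton (within a perpendicular tube
#' radius) estimates the local shell thickness. Rays that meet no
#' non-island bouton are excluded and counted.
#'
#' @param labeling A [classify_boutons()] result.
#' @param n_rays Number of ray directions (default 500).
#' @param tube_radius Perpendicular capture radius in nm; default 2x the
#'   classification bandwidth.
#' @param no_zone_factor The zone is flagged absent when the median gap
#'   falls below `no_zone_factor` x mean nearest-neighbour bouton
#'   spacing (default 3).
#' @return List with `median_gap`, `min_gap`, `max_gap` (nm), the raw
#'   per-ray `gaps`, `n_rays_used`, `n_rays_excluded`, and `no_zone`.
#' @export
measure_exclusion_zone <- function(labeling, n_rays = 500L, tube_radius = NULL,
                                   no_zone_factor = 3) {
  stopifnot(inherits(labeling, "bouton_field_labeling"))
  labels <- labeling$labels
  if (!any(labels == "island") || !any(labels == "nonisland")) {
    stopf("labeling must contain both island and nonisland boutons")
  }
  if (is.null(tube_radius)) tube_radius <- 2 * labeling$params$bandwidth
  ctr <- labeling$island_centroid
  X <- sweep(labeling$boutons, 2L, ctr)
  r2 <- rowSums(X^2)
  # Direction sample expressed in the island's principal-axis frame, so
  # that the measurement is equivariant under rigid motions of the data.
  isl_pts <- X[labels == "island", , drop = FALSE]
  ev <- eigen(stats::cov(isl_pts), symmetric = TRUE)$vectors
  ic <- sweep(isl_pts, 2L, colMeans(isl_pts))
  for (j in 1:3) {  # intrinsic sign convention: positive third moment
    if (sum((ic %*% ev[, j])^3) < 0) ev[, j] <- -ev[, j]
  }
  U <- fibonacci_sphere(n_rays) %*% t(ev)
  gaps <- rep(NA_real_, n_rays)
  for (i in seq_len(n_rays)) {
    t <- drop(X %*% U[i, ])
    perp2 <- r2 - t^2
    in_tube <- t > 0 & perp2 <= tube_radius^2
    t_isl <- t[in_tube & labels == "island"]
    t_non <- t[in_tube & labels == "nonisland"]
    if (!length(t_isl) || !length(t_non)) next
    last_isl <- max(t_isl)
    beyond <- t_non[t_non > last_isl]
    if (!length(beyond)) next
    gaps[i] <- min(beyond) - last_isl
  }
  used <- !is.na(gaps)
  if (!any(used)) stopf("no ray crossed from island to nonisland boutons")
  g <- gaps[used]
  med <- stats::median(g)
  list(median_gap = med, min_gap = min(g), max_gap = max(g),
       gaps = g, n_rays_used = sum(used), n_rays_excluded = sum(!used),
       no_zone = med < no_zone_factor * labeling$params$mean_nn_spacing,
       tube_radius = tube_radius)
}
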