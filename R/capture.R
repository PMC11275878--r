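CAPTURE_CLASSES <- c("pure_island", "pure_nonisland", "mixed",
                     "ambiguous_zone", "no_rgc")

#' Capture class from innervation counts
#'
#' A TC is "captured" when every RGC input it receives comes from a
#' single bouton field. Cells with no RGC input at all, and cells whose
#' inputs sit mostly inside the exclusion zone (ambiguous field), get
#' their own classes.
#'
#' @param n_island,n_nonisland,n_ambiguous Non-negative input counts.
#' @param ambiguous_fraction Fraction of ambiguous inputs above which the
#'   cell is classed `ambiguous_zone` (default 0.5).
#' @return One of `"pure_island"`, `"pure_nonisland"`, `"mixed"`,
#'   `"ambiguous_zone"`, `"no_rgc"`.
#' @export
classify_tc <- function(n_island, n_nonisland, n_ambiguous,
                        ambiguous_fraction = 0.5) {
  stopifnot(n_island >= 0, n_nonisland >= 0, n_ambiguous >= 0)
  total <- n_island + n_nonisland + n_ambiguous
  if (total == 0) return("no_rgc")
  if (n_ambiguous / total > ambiguous_fraction) return("ambiguous_zone")
  if (n_island > 0 && n_nonisland == 0) return("pure_island")
  if (n_nonisland > 0 && n_island == 0) return("pure_nonisland")
  if (n_island > 0 && n_nonisland > 0) return("mixed")
  "ambiguous_zone"  # only ambiguous inputs but at or below the fraction
}

#' Innervation profile of one TC
#'
#' Counts the cell's RGC inputs by field label and the number of primary
#' dendrites (soma-adjacent subtrees) whose subtree receives at least one
#' RGC synapse — the quantity the independent-dendrite null model is
#' built on.
#'
#' @param tc A [neuron_skeleton()] with a soma.
#' @param synapses A [synapse_table()] (rows with `post_cell == tc` and
#'   `pre_class == "RGC"` are counted).
#' @param labeling A [classify_boutons()] result; each input synapse is
#'   matched to its bouton record by synapse id when available, otherwise
#'   its position is looked up with [label_points()].
#' @param ambiguous_fraction Passed to [classify_tc()].
#' @param attachment_tolerance Warn when an input synapse lies farther
#'   than this from every node of the skeleton (nm, default 500);
#'   partial reconstructions make distant attachments expected, so such
#'   synapses are still counted.
#' @return A one-row data frame (class `innervation_profile`): `tc_id`,
#'   `n_island`, `n_nonisland`, `n_ambiguous`, `n_total_rgc`,
#'   `primary_dendrite_count`, `capture_class`.
#' @export
profile_tc <- function(tc, synapses, labeling, ambiguous_fraction = 0.5,
                       attachment_tolerance = 500) {
  stopifnot(inherits(tc, "neuron_skeleton"))
  if (length(tc$soma_node_ids) == 0L) stopf("cell '%s' has no soma", tc$cell_id)
  syn <- as.data.frame(synapses)
  syn <- syn[syn$post_cell == tc$cell_id & syn$pre_class == "RGC", , drop = FALSE]
  if (nrow(syn)) {
    pos <- as.matrix(syn[, c("x_nm", "y_nm", "z_nm")])
    lab <- synapse_field_labels(syn, labeling)
    xyz <- node_xyz(tc)
    d2 <- outer(rowSums(pos^2), rowSums(xyz^2), `+`) - 2 * pos %*% t(xyz)
    nearest <- apply(d2, 1L, which.min)
    mind <- sqrt(pmax(d2[cbind(seq_len(nrow(pos)), nearest)], 0))
    far <- mind > attachment_tolerance
    if (any(far)) {
      warnf("cell '%s': %d RGC input(s) farther than %g nm from the skeleton (partial reconstruction?); counted anyway",
            tc$cell_id, sum(far), attachment_tolerance)
    }
    subtrees <- primary_subtrees(tc)
    node_of_syn <- tc$nodes$node_id[nearest]
    innervated <- vapply(subtrees, function(ids) any(node_of_syn %in% ids), logical(1))
    pdc <- sum(innervated)
  } else {
    lab <- character(0)
    pdc <- 0L
  }
  n_isl <- sum(lab == "island"); n_non <- sum(lab == "nonisland")
  n_amb <- sum(lab == "ambiguous")
  out <- data.frame(tc_id = tc$cell_id, n_island = n_isl, n_nonisland = n_non,
                    n_ambiguous = n_amb, n_total_rgc = n_isl + n_non + n_amb,
                    primary_dendrite_count = pdc,
                    capture_class = classify_tc(n_isl, n_non, n_amb,
                                                ambiguous_fraction))
  class(out) <- c("innervation_profile", "data.frame")
  out
}

# Field labels for synapse rows: by bouton id when the labeling covers the
# same synapse table, else by position.
synapse_field_labels <- function(syn, labeling) {
  if (!is.null(labeling$bouton_ids)) {
    idx <- match(syn$synapse_id, labeling$bouton_ids)
    lab <- labeling$labels[idx]
    if (!anyNA(lab)) return(lab)
    miss <- is.na(lab)
    lab[miss] <- label_points(labeling, as.matrix(syn[miss, c("x_nm", "y_nm", "z_nm")]))
    return(lab)
  }
  label_points(labeling, as.matrix(syn[, c("x_nm", "y_nm", "z_nm")]))
}

#' Innervation profiles for every TC in a dataset
#'
#' @param dataset A [circuit_dataset()].
#' @param labeling A [classify_boutons()] result.
#' @inheritParams profile_tc
#' @return Data frame with one [profile_tc()] row per TC skeleton.
#' @export
profile_all_tcs <- function(dataset, labeling, ambiguous_fraction = 0.5,
                            attachment_tolerance = 500) {
  tcs <- Filter(function(s) s$cell_class == "TC", dataset$skeletons)
  if (!length(tcs)) stopf("dataset contains no TC skeletons")
  do.call(rbind, lapply(tcs, profile_tc, synapses = dataset$synapses,
                        labeling = labeling,
                        ambiguous_fraction = ambiguous_fraction,
                        attachment_tolerance = attachment_tolerance))
}

#' Probability that one TC is fully captured under the null
#'
#' Under the independent-dendrite null each of a TC's `k` RGC-connected
#' primary dendrites connects to the island or the non-island field with
#' probability 1/2, independently. The cell is captured when all `k`
#' agree, which happens with probability `2^(1-k)`.
#'
#' @param k Integer vector of dendrite counts, each >= 1.
#' @return `2^(1-k)`.
#' @export
capture_probability <- function(k) {
  if (any(k < 1)) stopf("dendrite counts must be >= 1")
  2^(1 - k)
}

#' Exact null distribution of the number of captured TCs
#'
#' The number of captured TCs under the independent-dendrite null is a
#' sum of independent, non-identical Bernoulli indicators with
#' `p_i = 2^(1-k_i)` — a Poisson-binomial variable. Computed by
#' sequential convolution (exact to floating point; O(n^2) in the number
#' of cells, which is tens at most).
#'
#' @param dendrite_counts Integer vector of per-TC dendrite counts (>= 1).
#' @return Numeric vector of length `length(dendrite_counts) + 1` with
#'   `P(X = 0), ..., P(X = n)`; sums to 1. An empty input yields the
#'   distribution concentrated at 0.
#' @export
exact_capture_distribution <- function(dendrite_counts) {
  if (length(dendrite_counts) == 0L) return(1)
  p <- capture_probability(dendrite_counts)
  d <- 1
  for (pi in p) d <- c(d * (1 - pi), 0) + c(0, d * pi)
  d
}

#' Monte Carlo simulation of the independent-dendrite null
#'
#' Simulates the null model directly: in each trial every primary
#' dendrite is assigned to the island or non-island field with equal
#' probability, a TC is captured when all its dendrites agree, and the
#' number of captured TCs is recorded. For each requested level the
#' smallest integer `m` whose empirical CDF reaches the level is
#' reported ("m or fewer captured TCs in at least level of trials").
#'
#' @param dendrite_counts Integer vector of per-TC dendrite counts (>= 1).
#' @param trials Number of Monte Carlo trials (default 100000).
#' @param seed Integer RNG seed; recorded in the result.
#' @param levels CDF levels for quantile thresholds (default 0.99).
#' @return An object of class `null_model_result`: `dendrite_counts`,
#'   `trials`, `seed`, `captured_count_histogram` (over 0..n),
#'   `empirical_quantile_thresholds` (named by level),
#'   `exact_distribution` (the Poisson-binomial oracle),
#'   `exact_quantile_thresholds`, and `exact_mean` (= sum of
#'   `2^(1-k_i)`).
#' @export
monte_carlo_null <- function(dendrite_counts, trials = 100000L, seed = 1L,
                             levels = 0.99) {
  if (trials < 1) stopf("trials must be >= 1")
  p <- capture_probability(dendrite_counts)  # validates counts
  n <- length(dendrite_counts)
  captured <- with_seed(seed, {
    tot <- integer(trials)
    for (k in dendrite_counts) {
      heads <- stats::rbinom(trials, k, 0.5)
      tot <- tot + (heads == 0L | heads == k)
    }
    tot
  })
  hist <- tabulate(captured + 1L, nbins = n + 1L)
  ecdf_vals <- cumsum(hist) / trials
  thresholds <- vapply(levels, function(lv) which(ecdf_vals >= lv)[1] - 1L, integer(1))
  exact <- exact_capture_distribution(dendrite_counts)
  exact_cdf <- cumsum(exact)
  exact_thresholds <- vapply(levels, function(lv) which(exact_cdf >= lv)[1] - 1L, integer(1))
  structure(list(dendrite_counts = dendrite_counts, trials = trials,
                 seed = seed,
                 captured_count_histogram = stats::setNames(hist, 0:n),
                 empirical_quantile_thresholds = stats::setNames(thresholds, levels),
                 exact_distribution = exact,
                 exact_quantile_thresholds = stats::setNames(exact_thresholds, levels),
                 exact_mean = sum(p)),
            class = "null_model_result")
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf("<null_model_result> %d TCs (dendrites: %s), %d trials, seed %d\n",
              length(x$dendrite_counts),
              paste(x$dendrite_counts, collapse = ","), x$trials, x$seed))
  cat(sprintf("  exact mean captured: %.6f\n", x$exact_mean))
  for (i in seq_along(x$empirical_quantile_thresholds)) {
    cat(sprintf("  level %s: MC threshold %d (exact %d)\n",
                names(x$empirical_quantile_thresholds)[i],
                x$empirical_quantile_thresholds[i],
                x$exact_quantile_thresholds[i]))
  }
  invisible(x)
}

#' Compare an observed capture count to the null model
#'
#' Reports the exact and empirical upper tail probabilities
#' `P(X >= observed)` and whether the observation exceeds each quantile
#' threshold. Deliberately reports probabilities only — no significance
#' wording — since the null is a reference model, not a designed
#' hypothesis test.
#'
#' @param observed_captured Observed number of fully captured TCs.
#' @param null A [monte_carlo_null()] result.
#' @return List with `observed`, `exact_tail`, `empirical_tail`, and
#'   `exceeds_threshold` (named logical per level).
#' @export
compare_observed_to_null <- function(observed_captured, null) {
  stopifnot(inherits(null, "null_model_result"))
  n <- length(null$dendrite_counts)
  if (observed_captured < 0 || observed_captured > n) {
    stopf("observed count must be in 0..%d", n)
  }
  exact_tail <- sum(null$exact_distribution[(observed_captured + 1L):(n + 1L)])
  hist <- null$captured_count_histogram
  emp_tail <- sum(hist[(observed_captured + 1L):(n + 1L)]) / null$trials
  list(observed = observed_captured,
       exact_tail = exact_tail,
       empirical_tail = emp_tail,
       exceeds_threshold = observed_captured > null$empirical_quantile_thresholds)
}

#' Soma-to-mean-synapse offset of a TC
#'
#' The displacement from a TC's soma to the centroid of its RGC input
#' positions summarises dendritic-arbor asymmetry: captured cells near
#' the exclusion zone collect their inputs on one side, so the offset
#' points away from the zone, into the capturing field.
#'
#' @param tc A [neuron_skeleton()] with a soma.
#' @param rgc_positions n x 3 matrix of the cell's RGC input positions
#'   (nm); must be non-empty.
#' @param labeling Optional [classify_boutons()] result; when given, the
#'   offset is also projected onto the outward radial direction from the
#'   island centroid through the soma (positive = pointing away from the
#'   island).
#' @return List (class `soma_synapse_vector`): `tc_id`, `soma_position`,
#'   `mean_synapse_position`, `offset`, `offset_norm`, and
#'   `outward_projection` (NA without a labeling).
#' @export
soma_synapse_vector <- function(tc, rgc_positions, labeling = NULL) {
  stopifnot(inherits(tc, "neuron_skeleton"))
  if (length(tc$soma_node_ids) == 0L) stopf("cell '%s' has no soma", tc$cell_id)
  rgc_positions <- matrix(as.numeric(rgc_positions), ncol = 3)
  if (nrow(rgc_positions) == 0L) {
    stopf("cell '%s' has no RGC inputs; offset undefined", tc$cell_id)
  }
  soma <- unname(soma_centroid(tc))
  msp <- unname(colMeans(rgc_positions))
  offset <- msp - soma
  outward <- NA_real_
  if (!is.null(labeling)) {
    normal <- soma - labeling$island_centroid
    nn <- sqrt(sum(normal^2))
    if (nn > 0) outward <- sum(offset * normal / nn)
  }
  structure(list(tc_id = tc$cell_id, soma_position = soma,
                 mean_synapse_position = msp, offset = offset,
                 offset_norm = sqrt(sum(offset^2)),
                 outward_projection = outward),
            class = "soma_synapse_vector")
}

#' Cumulative bouton-count curve over TCs
#'
#' TCs ordered by their RGC input count, with the running cumulative
#' total — the standard summary of how unevenly retinal input is spread
#' across cells.
#'
#' @param profiles Data frame from [profile_all_tcs()].
#' @return Data frame: `tc_id`, `n_total_rgc`, `capture_class`,
#'   `cumulative`.
#' @export
cumulative_bouton_curve <- function(profiles) {
  ord <- order(profiles$n_total_rgc, profiles$tc_id)
  out <- profiles[ord, c("tc_id", "n_total_rgc", "capture_class")]
  out$cumulative <- cumsum(out$n_total_rgc)
  rownames(out) <- NULL
  out
}
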