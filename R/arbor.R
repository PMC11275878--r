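NEURITE_TYPES <- c("tc_proximal", "tc_distal", "lin_shaft", "lin_targeted",
                   "lin_axon_like", "unclassified")

# Decompose a skeleton into branches: for every soma-adjacent subtree the
# trunk is the longest root-to-tip path; side subtrees hanging off a trunk
# are decomposed recursively. Returns a list of integer node-id vectors
# (trunk order, attachment first).
neurite_branches <- function(skel) {
  nodes <- skel$nodes
  id <- nodes$node_id
  pidx <- match(nodes$parent_id, id)
  xyz <- node_xyz(skel)
  elen <- ifelse(is.na(pidx), 0,
                 sqrt(rowSums((xyz - xyz[ifelse(is.na(pidx), 1L, pidx), , drop = FALSE])^2)))
  children <- split(seq_along(id), factor(nodes$parent_id, levels = id))
  kids_of <- function(i) children[[as.character(id[i])]] %||% integer(0)

  soma <- which(nodes$structure_code == SWC_SOMA)
  if (!length(soma)) soma <- which(nodes$parent_id == -1L)
  starts <- which(pidx %in% soma & !(seq_along(id) %in% soma))

  branches <- list()
  decompose <- function(root_i) {
    # Path length from root_i to every node of its subtree.
    dist <- stats::setNames(0, root_i)
    order_bfs <- root_i
    queue <- root_i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in kids_of(v)) {
        dist[as.character(u)] <- dist[as.character(v)] + elen[u]
        order_bfs <- c(order_bfs, u)
        queue <- c(queue, u)
      }
    }
    tip <- order_bfs[which.max(dist[as.character(order_bfs)])]
    trunk <- tip
    while (trunk[1] != root_i) trunk <- c(pidx[trunk[1]], trunk)
    branches[[length(branches) + 1L]] <<- trunk
    for (v in order_bfs) {
      if (!(v %in% trunk) && pidx[v] %in% trunk) decompose(v)
    }
  }
  for (s in starts) decompose(s)
  lapply(branches, function(b) id[b])
}

branch_path_length <- function(skel, branch_ids) {
  nodes <- skel$nodes
  i <- match(branch_ids, nodes$node_id)
  xyz <- node_xyz(skel)[i, , drop = FALSE]
  if (nrow(xyz) < 2L) return(0)
  sum(sqrt(rowSums(diff(xyz)^2)))
}

# Sample points along a branch polyline at arc-length steps <= `step` nm.
sample_branch_points <- function(skel, branch_ids, step = 200) {
  i <- match(branch_ids, skel$nodes$node_id)
  xyz <- node_xyz(skel)[i, , drop = FALSE]
  if (nrow(xyz) == 1L) return(xyz)
  pts <- list(xyz[1, , drop = FALSE])
  for (r in 2:nrow(xyz)) {
    a <- xyz[r - 1, ]; b <- xyz[r, ]
    len <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(len / step))
    t <- seq_len(n) / n
    pts[[r]] <- cbind(a[1] + t * (b[1] - a[1]),
                      a[2] + t * (b[2] - a[2]),
                      a[3] + t * (b[3] - a[3]))
  }
  do.call(rbind, pts)
}

# Exclusion-zone membership: below the density threshold but adjacent to
# the island (within the measured gap plus one kernel bandwidth of the
# nearest island bouton).
points_in_zone <- function(xyz, labeling, gap_stats) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  below <- label_points(labeling, xyz) == "ambiguous"
  out <- logical(nrow(xyz))
  if (!any(below)) return(out)
  isl <- labeling$boutons[labeling$labels == "island", , drop = FALSE]
  sub <- xyz[below, , drop = FALSE]
  d2 <- outer(rowSums(sub^2), rowSums(isl^2), `+`) - 2 * sub %*% t(isl)
  dmin <- sqrt(pmax(apply(d2, 1L, min), 0))
  reach <- gap_stats$median_gap + labeling$params$bandwidth
  out[below] <- dmin <= reach
  out
}

#' Per-branch exclusion-zone crossing profiles
#'
#' Splits a skeleton into branches (trunks of soma-adjacent subtrees plus
#' their side branches), tests each branch polyline for intersection with
#' the exclusion zone at arc-length steps of at most `step` nm, and
#' attributes the cell's synapses to branches (nearest node) and to the
#' side of the zone where they sit.
#'
#' @param skel A [neuron_skeleton()].
#' @param synapses A [synapse_table()]; rows with `post_cell == skel` are
#'   inputs, rows with `pre_cell == skel` are outputs.
#' @param labeling A [classify_boutons()] result.
#' @param gap_stats Optional [measure_exclusion_zone()] result (computed
#'   from `labeling` if missing).
#' @param step Arc-length sampling step, nm (default 200).
#' @return Data frame (class `neurite_profiles`), one row per branch:
#'   `cell_id`, `branch_id`, `root_node_id`, `path_length`,
#'   `mean_radius`, `n_inputs_island`, `n_inputs_nonisland`,
#'   `n_inputs_ambiguous`, `n_outputs`, `n_synapses_in_zone`,
#'   `crosses_zone`, `neurite_type`. For TC cells branches are typed
#'   `tc_proximal` (mean radius above 400 nm or carrying an RGC input)
#'   or `tc_distal`; other cells start `unclassified` (see
#'   [classify_lin_neurites()]). An empty data frame with attribute
#'   `outside_volume = TRUE` is returned when the whole skeleton lies
#'   outside the analysed grid.
#' @export
zone_crossings <- function(skel, synapses, labeling, gap_stats = NULL,
                           step = 200) {
  stopifnot(inherits(skel, "neuron_skeleton"),
            inherits(labeling, "bouton_field_labeling"))
  if (is.null(gap_stats)) gap_stats <- measure_exclusion_zone(labeling)
  branches <- neurite_branches(skel)
  empty <- data.frame(cell_id = character(0), branch_id = integer(0),
                      root_node_id = integer(0), path_length = numeric(0),
                      mean_radius = numeric(0), n_inputs_island = integer(0),
                      n_inputs_nonisland = integer(0),
                      n_inputs_ambiguous = integer(0), n_outputs = integer(0),
                      n_synapses_in_zone = integer(0),
                      crosses_zone = logical(0), neurite_type = character(0))
  if (!length(branches)) {
    class(empty) <- c("neurite_profiles", "data.frame")
    return(empty)
  }
  # Skeleton entirely outside the analysed volume?
  lin <- grid_voxel_index(node_xyz(skel), labeling$grid$origin,
                          labeling$grid$step, labeling$grid$dim)
  if (all(is.na(lin))) {
    class(empty) <- c("neurite_profiles", "data.frame")
    attr(empty, "outside_volume") <- TRUE
    return(empty)
  }

  syn <- as.data.frame(synapses)
  syn_in <- syn[syn$post_cell == skel$cell_id, , drop = FALSE]
  syn_out <- syn[syn$pre_cell == skel$cell_id, , drop = FALSE]
  branch_of_node <- integer(nrow(skel$nodes))
  names(branch_of_node) <- as.character(skel$nodes$node_id)
  for (b in seq_along(branches)) {
    ids <- as.character(branches[[b]])
    unset <- branch_of_node[ids] == 0L
    branch_of_node[ids[unset]] <- b
  }
  attach_branch <- function(df) {
    if (!nrow(df)) return(integer(0))
    pos <- as.matrix(df[, c("x_nm", "y_nm", "z_nm")])
    xyz <- node_xyz(skel)
    d2 <- outer(rowSums(pos^2), rowSums(xyz^2), `+`) - 2 * pos %*% t(xyz)
    nearest <- apply(d2, 1L, which.min)
    branch_of_node[as.character(skel$nodes$node_id[nearest])]
  }
  in_branch <- attach_branch(syn_in)
  out_branch <- attach_branch(syn_out)
  in_labels <- if (nrow(syn_in)) synapse_field_labels(syn_in, labeling) else character(0)
  in_zone_syn <- if (nrow(syn_in))
    points_in_zone(as.matrix(syn_in[, c("x_nm", "y_nm", "z_nm")]), labeling, gap_stats)
  else logical(0)
  out_zone_syn <- if (nrow(syn_out))
    points_in_zone(as.matrix(syn_out[, c("x_nm", "y_nm", "z_nm")]), labeling, gap_stats)
  else logical(0)

  parent_of <- function(node_id) {
    skel$nodes$parent_id[match(node_id, skel$nodes$node_id)]
  }
  rows <- lapply(seq_along(branches), function(b) {
    ids <- branches[[b]]
    # The crossing test covers the attachment edge too: the branch starts
    # where it leaves its parent (soma or shaft), not at its first node.
    par <- parent_of(ids[1])
    samp_ids <- if (!is.na(par) && par != -1L) c(par, ids) else ids
    pts <- sample_branch_points(skel, samp_ids, step)
    crosses <- any(points_in_zone(pts, labeling, gap_stats))
    i_mask <- in_branch == b
    radius <- skel$nodes$radius[match(ids, skel$nodes$node_id)]
    is_rgc_input <- if (nrow(syn_in)) syn_in$pre_class == "RGC" else logical(0)
    data.frame(cell_id = skel$cell_id, branch_id = b, root_node_id = ids[1],
               path_length = branch_path_length(skel, ids),
               mean_radius = mean(radius),
               n_inputs_island = sum(i_mask & in_labels == "island"),
               n_inputs_nonisland = sum(i_mask & in_labels == "nonisland"),
               n_inputs_ambiguous = sum(i_mask & in_labels == "ambiguous"),
               n_outputs = sum(out_branch == b),
               n_synapses_in_zone = sum(in_zone_syn[i_mask]) +
                 sum(out_zone_syn[out_branch == b]),
               crosses_zone = crosses,
               neurite_type = "unclassified")
  })
  out <- do.call(rbind, rows)
  if (skel$cell_class == "TC") {
    rgc_any <- out$n_inputs_island + out$n_inputs_nonisland +
      out$n_inputs_ambiguous > 0
    out$neurite_type <- ifelse(out$mean_radius > 400 | rgc_any,
                               "tc_proximal", "tc_distal")
  }
  class(out) <- c("neurite_profiles", "data.frame")
  out
}

#' Classify LIN neurites as shaft, targeted or axon-like
#'
#' LINs form three neurite types: long input/output shaft dendrites that
#' span hundreds of micrometres and cross the exclusion zone, short
#' synapse-dense input/output targeted neurites that extend roughly
#' 20 um from the shafts and follow local RGC axons, and small
#' output-only axons. Branch profiles from [zone_crossings()] are typed
#' by path length, synapse density and input/output composition, and
#' each carries its island/non-island input counts.
#'
#' @param lin A [neuron_skeleton()] of class LIN (soma required).
#' @param synapses A [synapse_table()] containing the cell's inputs
#'   (`post_cell == lin`) and outputs (`pre_cell == lin`); direction is
#'   inferred from which side the cell appears on.
#' @param labeling A [classify_boutons()] result.
#' @param targeted_reach Nominal targeted-neurite extent, nm (default
#'   20000); branches up to `reach_tolerance` times this length qualify.
#' @param reach_tolerance Multiplier on `targeted_reach` (default 2).
#' @param density_threshold Minimum synapse linear density for a
#'   targeted neurite, synapses per um (default 0.5).
#' @param shaft_min_length Minimum shaft path length, nm (default 1e5 =
#'   100 um).
#' @param gap_stats,step Passed to [zone_crossings()].
#' @return The [zone_crossings()] data frame with `neurite_type` filled
#'   in (`lin_shaft`, `lin_targeted`, `lin_axon_like` or
#'   `unclassified`).
#' @export
classify_lin_neurites <- function(lin, synapses, labeling,
                                  targeted_reach = 20000,
                                  reach_tolerance = 2,
                                  density_threshold = 0.5,
                                  shaft_min_length = 1e5,
                                  gap_stats = NULL, step = 200) {
  stopifnot(inherits(lin, "neuron_skeleton"))
  if (length(lin$soma_node_ids) == 0L) stopf("LIN '%s' has no soma", lin$cell_id)
  syn <- as.data.frame(synapses)
  if (!any(syn$post_cell == lin$cell_id | syn$pre_cell == lin$cell_id)) {
    stopf("no synapses reference cell '%s'; export the cell's synapses with both directions",
          lin$cell_id)
  }
  prof <- zone_crossings(lin, synapses, labeling, gap_stats = gap_stats,
                         step = step)
  if (!nrow(prof)) return(prof)
  n_in <- prof$n_inputs_island + prof$n_inputs_nonisland + prof$n_inputs_ambiguous
  dens <- ifelse(prof$path_length > 0,
                 (n_in + prof$n_outputs) / (prof$path_length / 1000), 0)
  type <- rep("unclassified", nrow(prof))
  type[prof$path_length >= shaft_min_length] <- "lin_shaft"
  axonish <- type == "unclassified" & prof$n_outputs > 0 & n_in == 0
  type[axonish] <- "lin_axon_like"
  targeted <- type == "unclassified" &
    prof$path_length <= targeted_reach * reach_tolerance &
    dens >= density_threshold
  type[targeted] <- "lin_targeted"
  prof$neurite_type <- type
  prof
}

#' Field purity of a neurite profile
#'
#' Fraction of a branch's field-assignable inputs that come from its
#' majority field; ambiguous inputs are excluded. Purity below 1 means
#' the branch samples both fields (field restriction is a strong
#' tendency, not an absolute rule).
#'
#' @param profile One row of a [zone_crossings()] /
#'   [classify_lin_neurites()] data frame (or any list with
#'   `n_inputs_island` and `n_inputs_nonisland`).
#' @return `max(island, nonisland) / (island + nonisland)`, or `NA` when
#'   the branch has no field-assignable inputs.
#' @export
field_purity <- function(profile) {
  i <- profile$n_inputs_island
  n <- profile$n_inputs_nonisland
  tot <- i + n
  ifelse(tot > 0, pmax(i, n) / tot, NA_real_)
}
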