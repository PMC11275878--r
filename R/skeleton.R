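CELL_CLASSES <- c("RGC", "TC", "LIN", "other")

# SWC structure codes (de-facto convention): 1 = soma, 2 = axon, 3 = dendrite.
SWC_SOMA <- 1L

#' Neuron skeleton
#'
#' A rooted tree of 3D nodes with radii, the standard representation of a
#' traced neuron (one SWC file per cell). Positions are stored in
#' nanometres; voxel scaling is applied exactly once, on load.
#'
#' @param cell_id Character scalar identifying the cell.
#' @param cell_class One of `"RGC"`, `"TC"`, `"LIN"`, `"other"`.
#' @param nodes Data frame with columns `node_id` (integer),
#'   `parent_id` (integer; `-1` for the root), `x`, `y`, `z` (nm),
#'   `radius` (nm, >= 0) and `structure_code` (integer; 1 marks soma
#'   nodes).
#' @return An object of class `neuron_skeleton`.
#' @details Invariants enforced at construction: exactly one root, every
#'   parent references an existing node, no cycles (a single connected
#'   tree), finite positions, non-negative radii, and at least one soma
#'   node for TC and LIN cells (their somata anchor the downstream
#'   primary-dendrite and innervation analyses).
#' @export
neuron_skeleton <- function(cell_id, cell_class, nodes) {
  cell_class <- match.arg(cell_class, CELL_CLASSES)
  required <- c("node_id", "parent_id", "x", "y", "z", "radius", "structure_code")
  if (!all(required %in% names(nodes))) {
    stopf("skeleton nodes need columns: %s", paste(required, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, required]
  nodes$node_id <- as.integer(nodes$node_id)
  nodes$parent_id <- as.integer(nodes$parent_id)
  nodes$structure_code <- as.integer(nodes$structure_code)
  validate_skeleton_nodes(cell_id, nodes)
  soma_ids <- nodes$node_id[nodes$structure_code == SWC_SOMA]
  if (cell_class %in% c("TC", "LIN") && length(soma_ids) == 0L) {
    stopf("cell '%s' (%s) has no soma node (structure code 1)", cell_id, cell_class)
  }
  structure(list(cell_id = as.character(cell_id),
                 cell_class = cell_class,
                 nodes = nodes,
                 soma_node_ids = soma_ids),
            class = "neuron_skeleton")
}

validate_skeleton_nodes <- function(cell_id, nodes) {
  if (nrow(nodes) == 0L) stopf("cell '%s': skeleton has no nodes", cell_id)
  if (anyDuplicated(nodes$node_id)) {
    stopf("cell '%s': duplicate node ids", cell_id)
  }
  xyz <- as.matrix(nodes[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stopf("cell '%s': non-finite node position", cell_id)
  if (any(!is.finite(nodes$radius)) || any(nodes$radius < 0)) {
    stopf("cell '%s': radii must be finite and >= 0", cell_id)
  }
  roots <- nodes$node_id[nodes$parent_id == -1L]
  if (length(roots) != 1L) {
    stopf("cell '%s': expected exactly one root (parent -1), found %d",
          cell_id, length(roots))
  }
  idx <- match(nodes$parent_id, nodes$node_id)
  bad <- which(nodes$parent_id != -1L & is.na(idx))
  if (length(bad)) {
    stopf("cell '%s': node %d references missing parent %d",
          cell_id, nodes$node_id[bad[1]], nodes$parent_id[bad[1]])
  }
  # Connectivity + acyclicity: walk to the root from every node.
  depth <- rep(NA_integer_, nrow(nodes))
  for (i in seq_len(nrow(nodes))) {
    j <- i
    seen <- integer(0)
    while (is.na(depth[j])) {
      if (j %in% seen) {
        stopf("cell '%s': cyclic parent references involving node %d",
              cell_id, nodes$node_id[j])
      }
      seen <- c(seen, j)
      if (nodes$parent_id[j] == -1L) { depth[j] <- 0L; break }
      j <- idx[j]
    }
    base <- depth[j]
    if (length(seen)) depth[seen] <- base + rev(seq_along(seen))
  }
  invisible(TRUE)
}

#' @export
print.neuron_skeleton <- function(x, ...) {
  cat(sprintf("<neuron_skeleton> %s (%s): %d nodes, %d soma node(s), cable %.1f um\n",
              x$cell_id, x$cell_class, nrow(x$nodes), length(x$soma_node_ids),
              total_cable_length(x) / 1e3))
  invisible(x)
}

node_xyz <- function(skel) as.matrix(skel$nodes[, c("x", "y", "z")])

#' Soma centroid of a skeleton
#'
#' @param skel A [neuron_skeleton()].
#' @return Length-3 numeric vector (nm), the mean position of all soma
#'   nodes.
#' @export
soma_centroid <- function(skel) {
  ids <- skel$soma_node_ids
  if (length(ids) == 0L) stopf("cell '%s' has no soma nodes", skel$cell_id)
  colMeans(node_xyz(skel)[skel$nodes$node_id %in% ids, , drop = FALSE])
}

total_cable_length <- function(skel) {
  idx <- match(skel$nodes$parent_id, skel$nodes$node_id)
  has_par <- !is.na(idx)
  if (!any(has_par)) return(0)
  xyz <- node_xyz(skel)
  sum(sqrt(rowSums((xyz[has_par, , drop = FALSE] - xyz[idx[has_par], , drop = FALSE])^2)))
}

#' Read a neuron skeleton from an SWC file
#'
#' Parses the standard 7-column SWC dialect (`id type x y z radius parent`,
#' `#` comments) and applies voxel scaling to the coordinates, yielding a
#' skeleton in nanometres.
#'
#' @param path Path to an SWC file.
#' @param scaling A [voxel_scaling()]; coordinates are multiplied per axis.
#' @param cell_id Cell identifier; defaults to the file name without
#'   extension.
#' @param cell_class Cell class; defaults to `"other"`.
#' @return A [neuron_skeleton()].
#' @export
read_swc <- function(path, scaling = voxel_scaling(), cell_id = NULL,
                     cell_class = "other") {
  if (!file.exists(path)) stopf("SWC file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  fields <- strsplit(trimws(lines[keep]), "\\s+")
  n_fields <- lengths(fields)
  if (any(n_fields != 7L)) {
    stopf("%s line %d: expected 7 SWC columns, found %d",
          path, keep[which(n_fields != 7L)[1]], n_fields[n_fields != 7L][1])
  }
  m <- suppressWarnings(matrix(as.numeric(unlist(fields)), ncol = 7L, byrow = TRUE))
  if (anyNA(m)) {
    bad <- which(apply(m, 1L, anyNA))[1]
    stopf("%s line %d: non-numeric SWC field", path, keep[bad])
  }
  nodes <- data.frame(node_id = as.integer(m[, 1]),
                      parent_id = as.integer(m[, 7]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6],
                      structure_code = as.integer(m[, 2]))
  nodes[, c("x", "y", "z")] <- apply_scaling(nodes[, c("x", "y", "z")], scaling)
  nodes$radius <- nodes$radius * mean(scaling$scale)
  if (is.null(cell_id)) cell_id <- sub("\\.[sS][wW][cC]$", "", basename(path))
  neuron_skeleton(cell_id, cell_class, nodes)
}

#' Write a neuron skeleton to an SWC file
#'
#' Inverse of [read_swc()] at unit scaling: coordinates are written in
#' nanometres.
#'
#' @param skel A [neuron_skeleton()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(skel, path) {
  n <- skel$nodes
  lines <- c(sprintf("# SWC export of cell %s (%s); coordinates in nm",
                     skel$cell_id, skel$cell_class),
             sprintf("%d %d %.6f %.6f %.6f %.6f %d",
                     n$node_id, n$structure_code, n$x, n$y, n$z, n$radius,
                     n$parent_id))
  writeLines(lines, path)
  invisible(path)
}

# Node ids of each soma-adjacent subtree ("primary" dendrite/neurite),
# returned as a list of integer vectors. Subtrees are rooted at non-soma
# children of soma nodes (or at children of the root for soma-less cells).
primary_subtrees <- function(skel) {
  nodes <- skel$nodes
  soma <- if (length(skel$soma_node_ids)) skel$soma_node_ids else
    nodes$node_id[nodes$parent_id == -1L]
  children <- split(nodes$node_id, factor(nodes$parent_id, levels = nodes$node_id))
  starts <- nodes$node_id[nodes$parent_id %in% soma &
                            !(nodes$node_id %in% soma)]
  lapply(starts, function(s) {
    out <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      out <- c(out, v)
      kids <- children[[as.character(v)]]
      kids <- kids[!(kids %in% soma)]
      if (length(kids)) queue <- c(queue, kids)
    }
    out
  })
}
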