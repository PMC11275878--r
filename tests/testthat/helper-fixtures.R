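# Shared fixtures, built in code at test time.

write_swc_text <- function(lines) {
  f <- tempfile(fileext = ".swc")
  writeLines(lines, f)
  f
}

# Uniform ball of points (deterministic given seed).
ball_points <- function(n, center, radius, seed) {
  set.seed(seed)
  g <- matrix(rnorm(3 * n), ncol = 3)
  g <- g / sqrt(rowSums(g^2))
  r <- runif(n)^(1 / 3) * radius
  sweep(g * r, 2L, center, `+`)
}

# Two well-separated uniform balls plus their classification; returns the
# labeling, the positions, and the true partition (1 = first ball).
two_ball_fixture <- function(n = 400, gap_center = c(40000, 0, 0),
                             radius = 8000, seed = 1) {
  a <- ball_points(n, c(0, 0, 0), radius, seed)
  b <- ball_points(n, gap_center, radius, seed + 1)
  pos <- rbind(a, b)
  rownames(pos) <- sprintf("syn_%04d", seq_len(2 * n))
  list(labeling = classify_boutons(pos), positions = pos,
       ball = rep(1:2, each = n))
}

# Exact capture-count distribution by full enumeration of all 2^sum(k)
# dendrite assignments (independent oracle for the Poisson-binomial path).
brute_force_capture_dist <- function(counts) {
  K <- sum(counts)
  stopifnot(K <= 24)
  masks <- 0:(2^K - 1)
  tot <- integer(length(masks))
  off <- 0L
  for (k in counts) {
    sub <- bitwAnd(bitwShiftR(masks, off), 2^k - 1L)
    tot <- tot + (sub == 0L | sub == 2^k - 1L)
    off <- off + as.integer(k)
  }
  tabulate(tot + 1L, nbins = length(counts) + 1L) / 2^K
}

# Minimal skeleton: a soma node plus one chain of nodes per branch.
chain_skeleton <- function(cell_id, cell_class, soma_pos, branches,
                           radius = 500) {
  nodes <- data.frame(node_id = 1L, parent_id = -1L,
                      x = soma_pos[1], y = soma_pos[2], z = soma_pos[3],
                      radius = 5000, structure_code = 1L)
  next_id <- 2L
  for (br in branches) {
    parent <- 1L
    for (r in seq_len(nrow(br))) {
      nodes <- rbind(nodes, data.frame(node_id = next_id, parent_id = parent,
                                       x = br[r, 1], y = br[r, 2],
                                       z = br[r, 3], radius = radius,
                                       structure_code = 3L))
      parent <- next_id
      next_id <- next_id + 1L
    }
  }
  neuron_skeleton(cell_id, cell_class, nodes)
}

# Synapse table rows at given positions, all RGC -> one postsynaptic cell.
rgc_synapses_at <- function(pos, post_cell, id_prefix = "s") {
  if (nrow(pos) == 0L) return(synapse_table(circuitseg:::empty_synapse_df()))
  synapse_table(data.frame(
    synapse_id = sprintf("%s_%04d", id_prefix, seq_len(nrow(pos))),
    pre_cell = sprintf("rgc_%s_%04d", id_prefix, seq_len(nrow(pos))),
    post_cell = post_cell,
    x_nm = pos[, 1], y_nm = pos[, 2], z_nm = pos[, 3],
    pre_class = "RGC", post_class = "TC"))
}
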