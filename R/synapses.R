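PRE_CLASSES <- c("RGC", "LIN", "cortical", "other")
POST_CLASSES <- c("TC", "LIN", "other")

SYNAPSE_COLUMNS <- c("synapse_id", "pre_cell", "post_cell",
                     "x_nm", "y_nm", "z_nm", "pre_class", "post_class")

#' Construct a synapse table
#'
#' One row per counted synaptic contact: presynaptic cell, postsynaptic
#' cell, 3D position (nm) and the class of each partner. A bouton with
#' several release sites onto the same target is represented by a single
#' record, i.e. one record = one counted input.
#'
#' @param df Data frame with columns
#'   `synapse_id, pre_cell, post_cell, x_nm, y_nm, z_nm, pre_class,
#'   post_class`.
#' @return A validated data frame of class `synapse_table`.
#' @export
synapse_table <- function(df) {
  df <- as.data.frame(df)
  if (!all(SYNAPSE_COLUMNS %in% names(df))) {
    stopf("synapse table needs columns: %s", paste(SYNAPSE_COLUMNS, collapse = ", "))
  }
  df <- df[, SYNAPSE_COLUMNS]
  for (col in c("synapse_id", "pre_cell", "post_cell", "pre_class", "post_class")) {
    df[[col]] <- as.character(df[[col]])
  }
  if (nrow(df)) {
    xyz <- as.matrix(df[, c("x_nm", "y_nm", "z_nm")])
    if (!is.numeric(xyz) || !all(is.finite(xyz))) {
      stopf("synapse positions must be finite numbers")
    }
    bad_pre <- setdiff(unique(df$pre_class), PRE_CLASSES)
    if (length(bad_pre)) {
      stopf("unknown pre_class '%s'; allowed: %s", bad_pre[1],
            paste(PRE_CLASSES, collapse = ", "))
    }
    bad_post <- setdiff(unique(df$post_class), POST_CLASSES)
    if (length(bad_post)) {
      stopf("unknown post_class '%s'; allowed: %s", bad_post[1],
            paste(POST_CLASSES, collapse = ", "))
    }
    self <- df$pre_cell == df$post_cell
    if (any(self)) {
      stopf("synapse '%s': pre_cell equals post_cell", df$synapse_id[which(self)[1]])
    }
    if (anyDuplicated(df$synapse_id)) stopf("duplicate synapse ids")
  }
  class(df) <- c("synapse_table", "data.frame")
  df
}

#' Read a synapse table from CSV
#'
#' Comma-separated, UTF-8, mandatory header row naming the eight fields
#' `synapse_id,pre_cell,post_cell,x_nm,y_nm,z_nm,pre_class,post_class`.
#' Positions are voxel-scaled on load, mirroring [read_swc()].
#'
#' @param path CSV file path.
#' @param scaling A [voxel_scaling()].
#' @return A [synapse_table()].
#' @export
read_synapse_table <- function(path, scaling = voxel_scaling()) {
  if (!file.exists(path)) stopf("synapse table not found: %s", path)
  df <- utils::read.csv(path, colClasses = c(synapse_id = "character",
                                             pre_cell = "character",
                                             post_cell = "character",
                                             pre_class = "character",
                                             post_class = "character"))
  missing <- setdiff(SYNAPSE_COLUMNS, names(df))
  if (length(missing)) {
    stopf("%s: header is missing columns: %s", path, paste(missing, collapse = ", "))
  }
  if (nrow(df)) {
    df[, c("x_nm", "y_nm", "z_nm")] <-
      apply_scaling(df[, c("x_nm", "y_nm", "z_nm")], scaling)
  }
  synapse_table(df)
}

#' Write a synapse table to CSV
#'
#' @param synapses A [synapse_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_synapse_table <- function(synapses, path) {
  utils::write.csv(as.data.frame(synapses), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

synapse_xyz <- function(synapses) {
  as.matrix(as.data.frame(synapses)[, c("x_nm", "y_nm", "z_nm")])
}

#' Positions of RGC boutons in a dataset
#'
#' RGC boutons are the presynaptic terminals of retinal axons; in the data
#' model each synapse record with `pre_class == "RGC"` marks one bouton
#' position.
#'
#' @param dataset A [circuit_dataset()] or a [synapse_table()].
#' @return Numeric matrix (n x 3) of positions in nm, with the synapse ids
#'   as row names.
#' @export
rgc_bouton_positions <- function(dataset) {
  syn <- if (inherits(dataset, "circuit_dataset")) dataset$synapses else dataset
  syn <- syn[syn$pre_class == "RGC", , drop = FALSE]
  m <- synapse_xyz(syn)
  rownames(m) <- syn$synapse_id
  m
}
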