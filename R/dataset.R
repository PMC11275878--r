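#' Circuit dataset
#'
#' In-memory container for one reconstructed (or synthetic) circuit:
#' skeletons keyed by cell id, a synapse table, the voxel scaling that was
#' applied on load, and free-text provenance (including the generator seed
#' for synthetic data).
#'
#' Synapse endpoints need not resolve to a skeleton: RGC axons are
#' typically represented by their boutons only (boutons are labeled
#' without tracing the parent axon), so unresolved endpoints are flagged
#' as orphans rather than rejected.
#'
#' @param skeletons List of [neuron_skeleton()] objects.
#' @param synapses A [synapse_table()].
#' @param scaling The [voxel_scaling()] already applied to coordinates.
#' @param provenance Named list of free-text metadata.
#' @return An object of class `circuit_dataset`.
#' @export
circuit_dataset <- function(skeletons = list(), synapses = synapse_table(empty_synapse_df()),
                            scaling = voxel_scaling(), provenance = list()) {
  if (length(skeletons)) {
    stopifnot(all(vapply(skeletons, inherits, logical(1), "neuron_skeleton")))
    names(skeletons) <- vapply(skeletons, `[[`, character(1), "cell_id")
    if (anyDuplicated(names(skeletons))) stopf("duplicate cell ids among skeletons")
  }
  synapses <- synapse_table(synapses)
  ds <- structure(list(skeletons = skeletons, synapses = synapses,
                       scaling = scaling, provenance = provenance),
                  class = "circuit_dataset")
  ds$orphans <- orphan_endpoints(ds)
  ds
}

empty_synapse_df <- function() {
  data.frame(synapse_id = character(0), pre_cell = character(0),
             post_cell = character(0), x_nm = numeric(0), y_nm = numeric(0),
             z_nm = numeric(0), pre_class = character(0),
             post_class = character(0))
}

orphan_endpoints <- function(ds) {
  known <- names(ds$skeletons)
  sort(unique(c(setdiff(ds$synapses$pre_cell, known),
                setdiff(ds$synapses$post_cell, known))))
}

#' @export
print.circuit_dataset <- function(x, ...) {
  cls <- table(vapply(x$skeletons, `[[`, character(1), "cell_class"))
  cat(sprintf("<circuit_dataset> %d skeletons (%s), %d synapses, %d orphan endpoint(s)\n",
              length(x$skeletons),
              paste(sprintf("%s: %d", names(cls), cls), collapse = ", "),
              nrow(x$synapses), length(x$orphans)))
  invisible(x)
}

#' Write a circuit dataset to a directory
#'
#' Emits one SWC file per skeleton, `synapses.csv`, and a JSON
#' `provenance.json` (which also records orphan endpoints), plus a
#' `manifest.json` listing every file written. [read_dataset()] of the
#' result reproduces the dataset up to float formatting (1e-6 nm).
#'
#' @param dataset A [circuit_dataset()].
#' @param dir Output directory (created if needed).
#' @return Character vector of files written (the manifest), invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stopf("cannot create output directory: %s", dir)
  files <- character(0)
  for (skel in dataset$skeletons) {
    f <- file.path(dir, paste0(skel$cell_id, ".swc"))
    write_swc(skel, f)
    files <- c(files, basename(f))
  }
  write_synapse_table(dataset$synapses, file.path(dir, "synapses.csv"))
  files <- c(files, "synapses.csv")
  prov <- c(dataset$provenance,
            list(scaling_nm = dataset$scaling$scale,
                 cell_classes = lapply(dataset$skeletons, `[[`, "cell_class"),
                 orphan_endpoints = dataset$orphans,
                 synapse_counting = "one record = one counted input (multi-contact boutons collapsed)"))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, "provenance.json")
  manifest <- list(files = files, n_skeletons = length(dataset$skeletons),
                   n_synapses = nrow(dataset$synapses),
                   orphan_endpoints = dataset$orphans)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(files, "manifest.json"))
}

#' Read a circuit dataset from a directory
#'
#' Counterpart of [write_dataset()]: loads every `.swc` file, the synapse
#' CSV and the provenance JSON. Coordinates on disk are in nm, so no
#' voxel scaling is applied (it was applied at original load).
#'
#' @param dir Directory written by [write_dataset()].
#' @return A [circuit_dataset()].
#' @export
read_dataset <- function(dir) {
  if (!dir.exists(dir)) stopf("dataset directory not found: %s", dir)
  prov_path <- file.path(dir, "provenance.json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path, simplifyVector = TRUE) else list()
  classes <- prov$cell_classes %||% list()
  swc_files <- list.files(dir, pattern = "\\.swc$", full.names = TRUE)
  skeletons <- lapply(swc_files, function(f) {
    id <- sub("\\.swc$", "", basename(f))
    read_swc(f, voxel_scaling(), cell_id = id,
             cell_class = classes[[id]] %||% "other")
  })
  syn_path <- file.path(dir, "synapses.csv")
  synapses <- if (file.exists(syn_path)) read_synapse_table(syn_path) else
    synapse_table(empty_synapse_df())
  keep <- setdiff(names(prov), c("cell_classes", "orphan_endpoints"))
  circuit_dataset(skeletons, synapses, voxel_scaling(), prov[keep])
}
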