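#' Build a pipeline run configuration
#'
#' One object drives a full run: where the data come from (a generator
#' config for synthetic circuits, or a dataset directory written by
#' [write_dataset()]), the spatial-classification parameters, the null
#' model parameters, the neurite thresholds, and the output directory.
#'
#' @param generator A [generator_config()], or `NULL` when reading from
#'   `dataset_dir`.
#' @param dataset_dir Directory containing SWC files + `synapses.csv`
#'   (ignored when `generator` is given).
#' @param out_dir Output directory for the report bundle.
#' @param bandwidth,level_fraction,angular_resolution Spatial parameters
#'   (see [classify_boutons()], [find_separation_projection()]).
#' @param trials,seed,levels,ambiguous_fraction Null-model and capture
#'   parameters (see [monte_carlo_null()], [classify_tc()]).
#' @param targeted_reach,density_threshold,shaft_min_length Neurite
#'   thresholds (see [classify_lin_neurites()]).
#' @param figures Emit figure files (default TRUE).
#' @return An object of class `run_config`.
#' @export
run_config <- function(generator = NULL, dataset_dir = NULL, out_dir,
                       bandwidth = NULL, level_fraction = 0.1,
                       angular_resolution = 2,
                       trials = 100000L, seed = 1L, levels = 0.99,
                       ambiguous_fraction = 0.5,
                       targeted_reach = 20000, density_threshold = 0.5,
                       shaft_min_length = 1e5, figures = TRUE) {
  if (is.null(generator) && is.null(dataset_dir)) {
    stopf("run_config needs a generator config or a dataset directory")
  }
  if (!is.null(generator)) stopifnot(inherits(generator, "generator_config"))
  structure(list(generator = generator, dataset_dir = dataset_dir,
                 out_dir = out_dir,
                 spatial = list(bandwidth = bandwidth,
                                level_fraction = level_fraction,
                                angular_resolution = angular_resolution),
                 capture = list(trials = as.integer(trials),
                                seed = as.integer(seed),
                                levels = as.numeric(levels),
                                ambiguous_fraction = ambiguous_fraction),
                 neurites = list(targeted_reach = targeted_reach,
                                 density_threshold = density_threshold,
                                 shaft_min_length = shaft_min_length),
                 figures = isTRUE(figures)),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with the [run_config()] fields; a `generator`
#'   object inside is passed to [generator_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  gen <- if (!is.null(j$generator)) do.call(generator_config, j$generator)
  args <- j[setdiff(names(j), "generator")]
  do.call(run_config, c(list(generator = gen), args))
}

pipeline_log <- function(con, stage, msg) {
  line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(con)) writeLines(line, con)
}

run_stage <- function(con, stage, expr) {
  pipeline_log(con, stage, "start")
  t0 <- proc.time()[3]
  res <- tryCatch(expr, error = function(e) {
    pipeline_log(con, stage, paste("FAILED:", conditionMessage(e)))
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
  pipeline_log(con, stage, sprintf("done (%.1f s)", proc.time()[3] - t0))
  res
}

#' Run the full segregation analysis pipeline
#'
#' Generate (or load) a circuit, classify its RGC boutons into fields,
#' measure the exclusion zone and best separation projection, profile
#' every TC and compare the observed capture count to the
#' independent-dendrite null, classify LIN neurites, and write a report
#' bundle (summary JSON, CSV tables, optional figures, run log, resolved
#' config). Identical config + seed gives identical JSON/CSV output.
#'
#' @param config A [run_config()].
#' @return The report bundle, invisibly: a list with `dataset`,
#'   `ground_truth` (synthetic runs only), `labeling`, `gap_stats`,
#'   `projection`, `profiles`, `null`, `exceedance`, `soma_vectors`,
#'   `neurites`, and `summary` (what was written to `summary.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(config$out_dir, "run.log"), open = "wt")
  on.exit(close(con), add = TRUE)

  resolved <- unclass(config)
  resolved$generator <- if (!is.null(config$generator)) unclass(config$generator)
  jsonlite::write_json(resolved, file.path(config$out_dir, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")

  ground_truth <- NULL
  dataset <- run_stage(con, "load", {
    if (!is.null(config$generator)) {
      g <- generate_circuit(config$generator)
      ground_truth <- g$ground_truth
      g$dataset
    } else read_dataset(config$dataset_dir)
  })

  labeling <- run_stage(con, "classify", {
    classify_boutons(dataset, bandwidth = config$spatial$bandwidth,
                     level_fraction = config$spatial$level_fraction)
  })
  gap_stats <- run_stage(con, "exclusion_zone", measure_exclusion_zone(labeling))
  projection <- run_stage(con, "projection", {
    find_separation_projection(labeling,
                               angular_resolution = config$spatial$angular_resolution)
  })

  cap <- config$capture
  profiles <- run_stage(con, "capture", {
    profile_all_tcs(dataset, labeling,
                    ambiguous_fraction = cap$ambiguous_fraction)
  })
  eligible <- profiles[profiles$capture_class != "no_rgc" &
                         profiles$primary_dendrite_count >= 1, , drop = FALSE]
  observed <- sum(eligible$capture_class %in% c("pure_island", "pure_nonisland"))
  null <- run_stage(con, "null_model", {
    monte_carlo_null(eligible$primary_dendrite_count, trials = cap$trials,
                     seed = cap$seed, levels = cap$levels)
  })
  exceedance <- compare_observed_to_null(observed, null)

  soma_vectors <- run_stage(con, "soma_vectors", {
    rows <- lapply(names(dataset$skeletons), function(id) {
      skel <- dataset$skeletons[[id]]
      if (skel$cell_class != "TC") return(NULL)
      syn <- dataset$synapses
      pos <- synapse_xyz(syn[syn$post_cell == id & syn$pre_class == "RGC", ,
                             drop = FALSE])
      if (nrow(pos) == 0L) return(NULL)
      v <- soma_synapse_vector(skel, pos, labeling)
      data.frame(tc_id = v$tc_id,
                 soma_x = v$soma_position[1], soma_y = v$soma_position[2],
                 soma_z = v$soma_position[3],
                 mean_x = v$mean_synapse_position[1],
                 mean_y = v$mean_synapse_position[2],
                 mean_z = v$mean_synapse_position[3],
                 offset_norm = v$offset_norm,
                 outward_projection = v$outward_projection)
    })
    do.call(rbind, Filter(Negate(is.null), rows))
  })

  neurites <- run_stage(con, "neurites", {
    lins <- Filter(function(s) s$cell_class == "LIN", dataset$skeletons)
    nt <- config$neurites
    rows <- lapply(lins, function(l) {
      classify_lin_neurites(l, dataset$synapses, labeling,
                            targeted_reach = nt$targeted_reach,
                            density_threshold = nt$density_threshold,
                            shaft_min_length = nt$shaft_min_length,
                            gap_stats = gap_stats)
    })
    if (length(rows)) do.call(rbind, rows) else NULL
  })

  curve <- cumulative_bouton_curve(profiles)
  label_counts <- as.list(table(factor(labeling$labels, levels = FIELD_LABELS)))
  captured_frac <- if (nrow(eligible)) observed / nrow(eligible) else NA_real_
  summary <- list(
    schema_version = "1.0",
    seed = cap$seed,
    bouton_labels = label_counts,
    no_split = labeling$no_split,
    gap_nm = list(median = gap_stats$median_gap, min = gap_stats$min_gap,
                  max = gap_stats$max_gap, no_zone = gap_stats$no_zone),
    projection = list(axis = projection$axis, margin_nm = projection$margin,
                      overlap_count = projection$overlap_count),
    capture = list(n_tc = nrow(profiles), n_eligible = nrow(eligible),
                   observed_captured = observed,
                   captured_fraction = captured_frac,
                   dendrite_counts = eligible$primary_dendrite_count,
                   thresholds = as.list(null$empirical_quantile_thresholds),
                   exact_mean = null$exact_mean,
                   exact_tail = exceedance$exact_tail,
                   empirical_tail = exceedance$empirical_tail),
    class_counts = as.list(table(factor(profiles$capture_class,
                                        levels = CAPTURE_CLASSES))))

  run_stage(con, "report", {
    utils::write.csv(profiles, file.path(config$out_dir, "tc_profiles.csv"),
                     row.names = FALSE)
    utils::write.csv(curve, file.path(config$out_dir, "cumulative_curve.csv"),
                     row.names = FALSE)
    if (!is.null(soma_vectors)) {
      utils::write.csv(soma_vectors, file.path(config$out_dir, "soma_vectors.csv"),
                       row.names = FALSE)
    }
    if (!is.null(neurites)) {
      utils::write.csv(neurites, file.path(config$out_dir, "neurite_profiles.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  })

  bundle <- list(dataset = dataset, ground_truth = ground_truth,
                 labeling = labeling, gap_stats = gap_stats,
                 projection = projection, profiles = profiles,
                 curve = curve, null = null, exceedance = exceedance,
                 soma_vectors = soma_vectors, neurites = neurites,
                 summary = summary, out_dir = config$out_dir)
  if (config$figures) {
    run_stage(con, "figures", make_figures(bundle, config$out_dir))
  }
  invisible(bundle)
}

#' Check a pipeline summary against the shipped schema
#'
#' Structural validation of `summary.json` against the versioned schema
#' in `inst/schema/summary-schema.json`: required keys present, types as
#' declared.
#'
#' @param summary The `summary` element of a [run_pipeline()] bundle, or
#'   a path to a `summary.json`.
#' @return TRUE invisibly; errors otherwise.
#' @export
validate_summary <- function(summary) {
  if (is.character(summary)) summary <- jsonlite::read_json(summary, simplifyVector = TRUE)
  schema <- jsonlite::read_json(system.file("schema", "summary-schema.json",
                                            package = "circuitseg"),
                                simplifyVector = TRUE)
  for (key in schema$required) {
    if (is.null(summary[[key]])) stopf("summary is missing required key '%s'", key)
  }
  if (!identical(as.character(summary$schema_version), schema$version)) {
    stopf("summary schema version '%s' does not match shipped schema '%s'",
          summary$schema_version, schema$version)
  }
  invisible(TRUE)
}

#' Emit the standard figure set for a report bundle
#'
#' Four figures: (a) the best-separation 2D projection of the bouton
#' cloud (island green, non-island magenta, ambiguous grey), (b) the
#' cumulative bouton-count curve over TCs, (c) the null histogram of
#' captured-TC counts with the observed value and quantile threshold
#' marked, (d) soma-to-mean-synapse offset vectors in the projection
#' plane.
#'
#' @param bundle A [run_pipeline()] bundle (or a compatible list).
#' @param dir Output directory.
#' @param format `"png"` or `"svg"`.
#' @return Character vector of files written, invisibly.
#' @export
make_figures <- function(bundle, dir, format = c("png", "svg")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  dev <- function(f) file.path(dir, paste0(f, ".", format))
  save_plot <- function(p, name, width = 6, height = 5) {
    f <- dev(name)
    ggplot2::ggsave(f, p, width = width, height = height, dpi = 120)
    files <<- c(files, f)
  }
  field_cols <- c(island = "#1b9e77", nonisland = "#d02090", ambiguous = "grey60")

  if (!is.null(bundle$labeling) && !is.null(bundle$projection)) {
    R <- bundle$projection$rotation
    P <- bundle$labeling$boutons %*% t(R)
    df <- data.frame(u = P[, 1] / 1000, v = P[, 3] / 1000,
                     field = bundle$labeling$labels)
    p <- ggplot2::ggplot(df, ggplot2::aes(u, v, colour = field)) +
      ggplot2::geom_point(size = 0.6, alpha = 0.8) +
      ggplot2::scale_colour_manual(values = field_cols) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "in-plane (um)", y = "separation axis (um)",
                    title = sprintf("Best separation projection (margin %.1f um)",
                                    bundle$projection$margin / 1000)) +
      ggplot2::theme_minimal()
    save_plot(p, "projection_scatter")
  } else warnf("make_figures: labeling/projection missing; scatter skipped")

  if (!is.null(bundle$curve)) {
    cv <- bundle$curve
    cv$rank <- seq_len(nrow(cv))
    p <- ggplot2::ggplot(cv, ggplot2::aes(rank, cumulative)) +
      ggplot2::geom_step() +
      ggplot2::geom_point(ggplot2::aes(colour = capture_class), size = 2) +
      ggplot2::labs(x = "TCs ordered by RGC input count",
                    y = "cumulative RGC boutons",
                    title = "Cumulative bouton-count curve") +
      ggplot2::theme_minimal()
    save_plot(p, "cumulative_curve")
  } else warnf("make_figures: cumulative curve missing; skipped")

  if (!is.null(bundle$null)) {
    nl <- bundle$null
    hs <- data.frame(m = as.integer(names(nl$captured_count_histogram)),
                     frac = as.numeric(nl$captured_count_histogram) / nl$trials)
    thr <- nl$empirical_quantile_thresholds[1]
    obs <- bundle$exceedance$observed %||% NA
    p <- ggplot2::ggplot(hs, ggplot2::aes(m, frac)) +
      ggplot2::geom_col(fill = "grey40") +
      ggplot2::geom_vline(xintercept = thr + 0.5, colour = "red",
                          linetype = 2) +
      ggplot2::scale_x_continuous(breaks = hs$m,
                                  limits = c(-0.5, max(hs$m) + 0.5)) +
      ggplot2::labs(x = "captured TCs", y = "fraction of trials",
                    title = sprintf("Independent-dendrite null (%d trials; threshold %d%s)",
                                    nl$trials, thr,
                                    if (!is.na(obs)) sprintf(", observed %d", obs) else "")) +
      ggplot2::theme_minimal()
    if (!is.na(obs)) {
      p <- p + ggplot2::annotate("point", x = obs, y = max(hs$frac) * 0.05,
                                 shape = 25, size = 4, fill = "blue")
    }
    save_plot(p, "null_histogram")
  } else warnf("make_figures: null model missing; histogram skipped")

  if (!is.null(bundle$soma_vectors) && nrow(bundle$soma_vectors) &&
      !is.null(bundle$projection)) {
    R <- bundle$projection$rotation
    sv <- bundle$soma_vectors
    S <- as.matrix(sv[, c("soma_x", "soma_y", "soma_z")]) %*% t(R) / 1000
    M <- as.matrix(sv[, c("mean_x", "mean_y", "mean_z")]) %*% t(R) / 1000
    df <- data.frame(sx = S[, 1], sy = S[, 3], mx = M[, 1], my = M[, 3],
                     tc_id = sv$tc_id)
    p <- ggplot2::ggplot(df) +
      ggplot2::geom_segment(ggplot2::aes(x = sx, y = sy, xend = mx, yend = my),
                            arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
      ggplot2::geom_point(ggplot2::aes(sx, sy), colour = "blue", size = 2) +
      ggplot2::geom_point(ggplot2::aes(mx, my), colour = "black", size = 2) +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "in-plane (um)", y = "separation axis (um)",
                    title = "Soma (blue) to mean RGC input position (black)") +
      ggplot2::theme_minimal()
    save_plot(p, "soma_vectors")
  } else warnf("make_figures: soma vectors missing; skipped")

  invisible(files)
}
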