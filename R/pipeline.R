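#' Run configuration for an end-to-end experiment
#'
#' Collects every tunable of the pipeline in one serializable object. A
#' run re-executed from its saved config (and seed) reproduces all
#' outputs bitwise.
#'
#' @param seed integer seed driving all simulation randomness.
#' @param pixel_size_um pixel size for simulated fields / input images.
#' @param simulate list describing simulated conditions:
#'   `conditions` (named list mapping condition label to a
#'   [scenario_preset()] name), `n_cells` (cells per condition; one cell
#'   is simulated per field), `field_size_px`, and an optional
#'   `overrides` list of [scene_params()] arguments applied to every
#'   condition. Set to `NULL` when quantifying real images.
#' @param inputs optional list of lists with `path` and `condition` for
#'   TIFF inputs (used when `simulate` is NULL).
#' @param background list: `method` ("mode"/"percentile"), `level`.
#' @param segmentation list: `nucleus_min_area_um2`, `mito_method`,
#'   `mito_min_object_area_um2`, `border_margin_um`, `exclude_border`.
#' @param rings list: `ring_width_um` (default 1), `n_rings` (default 4),
#'   `clip_to_territory`.
#' @param ratio_mode `"sum"` or `"pixel_mean"`.
#' @param stats list: `family` ("vs_reference"/"all_pairs") for the
#'   ring-wise comparisons, `control` condition label, `alpha`.
#' @param connectivity 4 or 8, for morphology.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       pixel_size_um = 0.25,
                       simulate = list(conditions = list(vehicle = "vehicle"),
                                       n_cells = 8L,
                                       field_size_px = c(160L, 160L)),
                       inputs = NULL,
                       background = list(method = "mode", level = 1),
                       segmentation = list(nucleus_min_area_um2 = 20,
                                           mito_method = "otsu_per_cell",
                                           mito_min_object_area_um2 = 0.1,
                                           border_margin_um = 4,
                                           exclude_border = FALSE),
                       rings = list(ring_width_um = 1.0, n_rings = 4L,
                                    clip_to_territory = TRUE),
                       ratio_mode = c("sum", "pixel_mean"),
                       stats = list(family = "vs_reference",
                                    control = "vehicle", alpha = 0.05),
                       connectivity = 8) {
  cfg <- list(seed = as.integer(seed), pixel_size_um = pixel_size_um,
              simulate = simulate, inputs = inputs,
              background = background, segmentation = segmentation,
              rings = rings, ratio_mode = match.arg(ratio_mode),
              stats = stats, connectivity = connectivity)
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    stop("run_config needs either 'simulate' or 'inputs'")
  if (!is.null(cfg$simulate)) {
    if (is.null(names(cfg$simulate$conditions)))
      stop("simulate$conditions must be a named list (label = preset)")
    cfg$simulate$n_cells <- as.integer(cfg$simulate$n_cells)
    cfg$simulate$field_size_px <- as.integer(unlist(cfg$simulate$field_size_px))
  }
  if (!cfg$stats$family %in% c("vs_reference", "all_pairs"))
    stop("stats$family must be 'vs_reference' or 'all_pairs'")
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as YAML
#'
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` a
#'   `run_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(run_config, raw[!vapply(raw, is.null, logical(1))])
}

#' Quantify one image: segmentation, metrics, rings, morphology
#'
#' @param image a [mito_image()].
#' @param config a [run_config()] supplying all options.
#' @return A list: `seg` (the [segment_cells()] result), `cells`
#'   ([whole_cell_metrics()]), `rings` ([ring_metrics()]), `morphology`
#'   ([measure_morphology()] per cell; empty when no cell detected).
#' @export
quantify_image <- function(image, config = run_config()) {
  stopifnot(inherits(image, "mito_image"), inherits(config, "run_config"))
  seg <- segment_cells(image,
                       background_method = config$background$method,
                       background_level = config$background$level,
                       nucleus_min_area_um2 = config$segmentation$nucleus_min_area_um2,
                       mito_method = config$segmentation$mito_method,
                       mito_min_object_area_um2 = config$segmentation$mito_min_object_area_um2,
                       border_margin_um = config$segmentation$border_margin_um,
                       exclude_border = isTRUE(config$segmentation$exclude_border))
  n_cells <- length(unique(seg$nucleus_labels[seg$nucleus_labels > 0]))
  if (n_cells == 0) {
    morph <- measure_morphology(seg$mito_mask, seg$pixel_size_um,
                                config$connectivity)
    morph <- morph[morph$valid, , drop = FALSE]
    return(list(seg = seg, cells = whole_cell_metrics(seg),
                rings = ring_metrics(seg), morphology = morph))
  }
  cells <- whole_cell_metrics(seg, config$ratio_mode)
  rings <- ring_metrics(seg,
                        ring_width_um = config$rings$ring_width_um,
                        n_rings = config$rings$n_rings,
                        clip_to_territory = isTRUE(config$rings$clip_to_territory),
                        ratio_mode = config$ratio_mode)
  morph <- measure_morphology(seg$mito_mask, seg$pixel_size_um,
                              config$connectivity)
  list(seg = seg, cells = cells, rings = rings, morphology = morph)
}

.metrics <- c("ratio_potential_marker", "potential_per_area", "marker_per_area")

#' Run a full experiment from a configuration
#'
#' Orchestrates simulate (or load) -> quantify -> profile -> compare and
#' writes tabular outputs plus a QC report and a provenance record to
#' `out_dir`: `cells.csv`, `rings.csv`, `profiles.csv`, `morphology.csv`,
#' `comparisons.csv`, `qc.json`, `provenance.json` and the resolved
#' `config.yaml`. Runs with the same config and seed reproduce these
#' files bitwise. A field with no detected cells produces empty tables
#' and a QC note, not an error.
#'
#' Comparisons cover, for each of the three readouts: every treated
#' condition against the control (whole-cell values, Bonferroni family =
#' number of treated conditions) and, within each condition, rings
#' compared by one-way ANOVA with Bonferroni-corrected pairwise t-tests
#' using the configured family mode (ring 1 is the reference for
#' `"vs_reference"`).
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with all tables (`cells`, `rings`,
#'   `profiles`, `morphology`, `comparisons`), the `qc` list and the
#'   `provenance` list.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  cells <- rings <- morph <- list()
  qc_seg <- list()
  if (!is.null(config$simulate)) {
    conds <- names(config$simulate$conditions)
    for (ci in seq_along(conds)) {
      cond <- conds[ci]
      preset <- config$simulate$conditions[[ci]]
      for (i in seq_len(config$simulate$n_cells)) {
        par <- do.call(scenario_preset, c(
          list(preset,
               seed = config$seed + ci * 100000L + i,
               field_size_px = config$simulate$field_size_px,
               pixel_size_um = config$pixel_size_um,
               n_cells = 1L),
          config$simulate$overrides))
        q <- quantify_image(render(generate_scene(par)), config)
        cells[[length(cells) + 1]] <- .tag(q$cells, cond, i)
        rings[[length(rings) + 1]] <- .tag(q$rings, cond, i)
        morph[[length(morph) + 1]] <- .tag(q$morphology, cond, i)
      }
    }
  } else {
    for (i in seq_along(config$inputs)) {
      inp <- config$inputs[[i]]
      img <- read_image(inp$path, config$pixel_size_um)
      q <- quantify_image(img, config)
      cond <- if (is.null(inp$condition)) "all" else inp$condition
      cells[[length(cells) + 1]] <- .tag(q$cells, cond, i)
      rings[[length(rings) + 1]] <- .tag(q$rings, cond, i)
      morph[[length(morph) + 1]] <- .tag(q$morphology, cond, i)
    }
  }
  cells <- do.call(rbind, cells)
  rings <- do.call(rbind, rings)
  morph <- do.call(rbind, morph)

  ## ring profiles (normalized to ring 1), per condition and metric
  profiles <- list(); qc_excluded <- list()
  conds <- unique(rings$condition)
  for (cond in conds) {
    sub <- rings[rings$condition == cond, ]
    sub$cell <- paste(sub$condition, sub$field, sub$cell, sep = "_")
    for (m in .metrics) {
      pr <- ring_profile(sub, m)
      if (nrow(pr)) {
        pr$condition <- cond
        profiles[[length(profiles) + 1]] <- pr
      }
      qc_excluded[[paste(cond, m, sep = ".")]] <-
        attr(pr, "qc")$excluded_cells
    }
  }
  profiles <- if (length(profiles)) do.call(rbind, profiles) else
    data.frame(cell = character(0), ring = integer(0), metric = character(0),
               value = numeric(0), normalized = numeric(0),
               condition = character(0))

  ## comparisons
  comparisons <- list()
  ctl <- config$stats$control
  alpha <- config$stats$alpha
  valid_cells <- cells[!is.na(cells$ratio_potential_marker) & cells$valid, ]
  treat_conds <- setdiff(unique(valid_cells$condition), ctl)
  if (ctl %in% valid_cells$condition && length(treat_conds) > 0 &&
      all(table(valid_cells$condition) >= 2)) {
    for (m in .metrics) {
      for (tc in treat_conds) {
        row <- t_test_two_tailed(valid_cells[[m]][valid_cells$condition == tc],
                                 valid_cells[[m]][valid_cells$condition == ctl],
                                 alpha = alpha,
                                 comparison = paste(tc, "vs", ctl))
        row$family_size <- length(treat_conds)
        row$p_adjusted <- min(1, row$p_raw * row$family_size)
        row$significant <- row$p_adjusted < alpha
        row$metric <- m; row$scope <- "whole_cell"; row$condition <- NA
        comparisons[[length(comparisons) + 1]] <- row
      }
    }
  }
  vr <- rings[rings$valid & !is.na(rings$ratio_potential_marker), ]
  for (cond in unique(vr$condition)) {
    sub <- vr[vr$condition == cond, ]
    ringlab <- paste0("ring", sub$ring)
    if (length(unique(ringlab)) < 2 || any(table(ringlab) < 2)) next
    for (m in .metrics) {
      ab <- anova_bonferroni(sub[[m]], ringlab,
                             family = config$stats$family,
                             reference = "ring1", alpha = alpha)
      pw <- ab$pairwise
      pw$metric <- m; pw$scope <- "rings"; pw$condition <- cond
      comparisons[[length(comparisons) + 1]] <- pw
    }
  }
  comparisons <- if (length(comparisons)) do.call(rbind, comparisons) else
    data.frame(test = character(0), comparison = character(0),
               statistic = numeric(0), df = numeric(0), p_raw = numeric(0),
               p_adjusted = numeric(0), family_size = integer(0),
               significant = logical(0), metric = character(0),
               scope = character(0), condition = character(0))

  ## QC: segmented vs excluded vs analyzed accounting
  n_segmented <- nrow(cells)
  qc <- list(cells_segmented = n_segmented,
             cells_border_flagged = if (n_segmented) sum(cells$border) else 0L,
             ring1_excluded = qc_excluded,
             note = if (n_segmented == 0) "no cells detected" else "ok")

  ## outputs
  cfg_path <- file.path(out_dir, "config.yaml")
  write_config(config, cfg_path)
  provenance <- list(package = "mitoring",
                     version = as.character(utils::packageVersion("mitoring")),
                     seed = config$seed,
                     config_md5 = unname(tools::md5sum(cfg_path)))
  .write_table <- function(df, name)
    write.csv(df, file.path(out_dir, name), row.names = FALSE)
  .write_table(cells, "cells.csv")
  .write_table(rings, "rings.csv")
  .write_table(profiles, "profiles.csv")
  .write_table(morph, "morphology.csv")
  .write_table(comparisons, "comparisons.csv")
  jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cells = cells, rings = rings, profiles = profiles,
                 morphology = morph, comparisons = comparisons,
                 qc = qc, provenance = provenance))
}

.tag <- function(df, condition, field) {
  if (is.null(df) || nrow(df) == 0) {
    if (is.null(df)) return(NULL)
    df$condition <- character(0); df$field <- integer(0)
    return(df)
  }
  df$condition <- condition
  df$field <- field
  df
}
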