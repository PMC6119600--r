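#' Ratio metrics for one (cell x region)
#'
#' Sums marker and potential intensities over the intersection of the
#' mitochondrial compartment with a region of interest and derives the
#' three readouts: `ratio_potential_marker` (MitoTracker/Tom70),
#' `potential_per_area` and `marker_per_area` (a.u. per um^2 of
#' mitochondrial area). By default the ratio is the ratio of summed
#' intensities (`ratio_mode = "sum"`), which weights pixels by their
#' marker content and is robust to dim pixels; `"pixel_mean"` averages the
#' per-pixel potential/marker quotient instead. Empty intersections give
#' `valid = FALSE` with undefined (NA) ratios, never zeros.
#'
#' @param mito_mask logical/0-1/label matrix of the mitochondrial
#'   compartment (nonzero = mitochondrial).
#' @param region_mask logical/0-1 matrix of the region of interest.
#' @param marker,potential background-corrected intensity matrices.
#' @param pixel_size_um pixel size in micrometres.
#' @param ratio_mode `"sum"` or `"pixel_mean"`.
#' @param cell_id,region_id identifiers copied into the output row.
#' @return A one-row data.frame: `cell`, `region`, `mito_area_px`,
#'   `mito_area_um2`, `sum_marker`, `sum_potential`,
#'   `ratio_potential_marker`, `potential_per_area`, `marker_per_area`,
#'   `valid`.
#' @export
compute_region_metrics <- function(mito_mask, region_mask, marker, potential,
                                   pixel_size_um,
                                   ratio_mode = c("sum", "pixel_mean"),
                                   cell_id = NA_integer_,
                                   region_id = NA_character_) {
  ratio_mode <- match.arg(ratio_mode)
  mito_mask <- .as_matrix(mito_mask)
  region_mask <- .as_matrix(region_mask)
  marker <- .as_matrix(marker)
  potential <- .as_matrix(potential)
  if (!identical(dim(mito_mask), dim(marker)) ||
      !identical(dim(region_mask), dim(marker)) ||
      !identical(dim(potential), dim(marker)))
    stop("mask and channel dimensions differ")
  stopifnot(pixel_size_um > 0)
  sel <- mito_mask > 0 & region_mask > 0
  area_px <- sum(sel)
  area_um2 <- area_px * pixel_size_um^2
  sm <- sum(marker[sel])
  sp <- sum(potential[sel])
  valid <- area_px > 0 && sm > 0
  if (ratio_mode == "sum") {
    ratio <- if (valid) sp / sm else NA_real_
  } else {
    mv <- marker[sel]; pv <- potential[sel]
    pos <- mv > 0
    ratio <- if (valid && any(pos)) mean(pv[pos] / mv[pos]) else NA_real_
  }
  data.frame(cell = cell_id, region = region_id,
             mito_area_px = area_px, mito_area_um2 = area_um2,
             sum_marker = sm, sum_potential = sp,
             ratio_potential_marker = ratio,
             potential_per_area = if (area_px > 0) sp / area_um2 else NA_real_,
             marker_per_area = if (area_px > 0) sm / area_um2 else NA_real_,
             valid = valid)
}

#' Whole-cell metrics for every segmented cell
#'
#' Computes [compute_region_metrics()] with each cell's entire territory
#' as the region, using the corrected channels stored in the
#' segmentation.
#'
#' @param seg a [segment_cells()] result.
#' @param ratio_mode see [compute_region_metrics()].
#' @return A data.frame with one row per cell, plus a `border` flag.
#' @export
whole_cell_metrics <- function(seg, ratio_mode = c("sum", "pixel_mean")) {
  stopifnot(inherits(seg, "cell_segmentation"))
  ratio_mode <- match.arg(ratio_mode)
  labs <- sort(unique(seg$nucleus_labels[seg$nucleus_labels > 0]))
  if (length(labs) == 0) return(.empty_metrics_df(border = TRUE))
  rows <- lapply(labs, function(k)
    compute_region_metrics(seg$mito_mask == k, seg$territory_labels == k,
                           seg$marker, seg$potential, seg$pixel_size_um,
                           ratio_mode, cell_id = k, region_id = "cell"))
  out <- do.call(rbind, rows)
  out$border <- out$cell %in% seg$border_cells
  out
}

.empty_metrics_df <- function(border = FALSE) {
  df <- data.frame(cell = integer(0), region = character(0),
                   mito_area_px = integer(0), mito_area_um2 = numeric(0),
                   sum_marker = numeric(0), sum_potential = numeric(0),
                   ratio_potential_marker = numeric(0),
                   potential_per_area = numeric(0),
                   marker_per_area = numeric(0), valid = logical(0))
  if (border) df$border <- logical(0)
  df
}

#' Ring-resolved metrics for every segmented cell
#'
#' Builds a [build_rings()] ring set around each nucleus and evaluates
#' the three readouts in every ring.
#'
#' @param seg a [segment_cells()] result.
#' @param ring_width_um,n_rings,clip_to_territory see [build_rings()].
#' @param ratio_mode see [compute_region_metrics()].
#' @return A data.frame with one row per (cell x ring); `region` is
#'   `"ring1"` ... `"ringN"`, and `ring` the numeric index.
#' @export
ring_metrics <- function(seg, ring_width_um = 1.0, n_rings = 4L,
                         clip_to_territory = TRUE,
                         ratio_mode = c("sum", "pixel_mean")) {
  stopifnot(inherits(seg, "cell_segmentation"))
  ratio_mode <- match.arg(ratio_mode)
  labs <- sort(unique(seg$nucleus_labels[seg$nucleus_labels > 0]))
  rows <- list()
  for (k in labs) {
    rs <- build_rings(seg$nucleus_labels == k, seg$pixel_size_um,
                      ring_width_um, n_rings,
                      territory_mask = seg$territory_labels == k,
                      clip_to_territory = clip_to_territory, cell_id = k)
    for (r in seq_len(n_rings)) {
      row <- compute_region_metrics(seg$mito_mask == k, rs$ring_masks[[r]],
                                    seg$marker, seg$potential,
                                    seg$pixel_size_um, ratio_mode,
                                    cell_id = k,
                                    region_id = paste0("ring", r))
      row$ring <- r
      row$truncated <- rs$truncated
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    df <- .empty_metrics_df()
    df$ring <- integer(0); df$truncated <- logical(0)
    return(df)
  }
  do.call(rbind, rows)
}

#' Ring profiles normalized to ring 1
#'
#' Converts per-(cell x ring) metrics into per-cell profiles normalized to
#' ring 1, the perinuclear reference. Cells whose ring-1 value is invalid
#' or zero cannot be normalized; they are excluded and reported in the QC
#' attribute rather than failing the run.
#'
#' @param rm a [ring_metrics()] data.frame.
#' @param metric one of `"ratio_potential_marker"`, `"potential_per_area"`,
#'   `"marker_per_area"`.
#' @return A data.frame with columns `cell`, `ring`, `value`,
#'   `normalized` (ring 1 = 1.0) and attribute `"qc"`, a list with
#'   `excluded_cells` and `n_analyzed`.
#' @export
ring_profile <- function(rm, metric = c("ratio_potential_marker",
                                        "potential_per_area",
                                        "marker_per_area")) {
  metric <- match.arg(metric)
  stopifnot(all(c("cell", "ring", metric, "valid") %in% names(rm)))
  cells <- unique(rm$cell)
  out <- list(); excluded <- integer(0)
  for (k in cells) {
    sub <- rm[rm$cell == k, ]
    sub <- sub[order(sub$ring), ]
    r1 <- sub[sub$ring == 1, ]
    if (nrow(r1) != 1 || !isTRUE(r1$valid) || is.na(r1[[metric]]) ||
        r1[[metric]] == 0) {
      excluded <- c(excluded, k)
      next
    }
    out[[length(out) + 1]] <- data.frame(
      cell = k, ring = sub$ring, metric = metric, value = sub[[metric]],
      normalized = sub[[metric]] / r1[[metric]])
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(cell = integer(0), ring = integer(0), metric = character(0),
               value = numeric(0), normalized = numeric(0))
  attr(res, "qc") <- list(excluded_cells = excluded,
                          n_analyzed = length(cells) - length(excluded))
  res
}

#' Average normalized ring profile over cells
#'
#' @param profile a [ring_profile()] data.frame.
#' @return A data.frame per ring: mean normalized value, SEM and n.
#' @export
ring_profile_summary <- function(profile) {
  rings <- sort(unique(profile$ring))
  do.call(rbind, lapply(rings, function(r) {
    v <- profile$normalized[profile$ring == r & !is.na(profile$normalized)]
    data.frame(ring = r, mean_normalized = mean(v),
               sem = if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_,
               n = length(v))
  }))
}
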