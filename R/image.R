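#' Multi-channel fluorescence image container
#'
#' Three aligned 2D intensity grids sharing one pixel size: a nucleus
#' channel (DAPI), a mitochondrial-marker channel (Tom70) and a
#' potential-reporter channel (MitoTracker CMX ROS). Intensities are
#' arbitrary units, nonnegative.
#'
#' @param nucleus,marker,potential numeric matrices of identical shape.
#' @param pixel_size_um positive pixel size in micrometres.
#' @return An object of class `mito_image`.
#' @export
mito_image <- function(nucleus, marker, potential, pixel_size_um) {
  stopifnot(is.matrix(nucleus), is.matrix(marker), is.matrix(potential))
  if (!identical(dim(nucleus), dim(marker)) ||
      !identical(dim(nucleus), dim(potential)))
    stop("all three channels must share the same dimensions")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  if (min(nucleus) < 0 || min(marker) < 0 || min(potential) < 0)
    stop("channel intensities must be nonnegative")
  structure(list(nucleus = nucleus, marker = marker, potential = potential,
                 pixel_size_um = pixel_size_um),
            class = "mito_image")
}

#' @export
print.mito_image <- function(x, ...) {
  cat(sprintf("mito_image: %dx%d px @ %.3g um/px\n",
              nrow(x$nucleus), ncol(x$nucleus), x$pixel_size_um))
  for (ch in c("nucleus", "marker", "potential"))
    cat(sprintf("  %-9s range [%.3g, %.3g]\n", ch, min(x[[ch]]), max(x[[ch]])))
  invisible(x)
}

#' Write an image (and optionally a scene's truth) to disk
#'
#' The image is written as a multi-page 16-bit TIFF with page order
#' nucleus, marker, potential (intensities rounded to integer counts).
#' When a scene is supplied, its label masks are written as 16-bit TIFFs
#' and the truth table plus parameters as a JSON sidecar.
#'
#' @param image a [mito_image()].
#' @param path output TIFF path.
#' @param scene optional `mito_scene` providing ground truth.
#' @return Invisibly, the paths written.
#' @export
write_image <- function(image, path, scene = NULL) {
  stopifnot(inherits(image, "mito_image"))
  pages <- lapply(image[c("nucleus", "marker", "potential")], function(m)
    pmin(round(m), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  written <- path
  if (!is.null(scene)) {
    stopifnot(inherits(scene, "mito_scene"))
    base <- sub("\\.tiff?$", "", path)
    for (nm in c("nuclei", "mito_objects", "mito_cells")) {
      mp <- paste0(base, "_", nm, ".tif")
      tiff::writeTIFF(scene[[nm]] / 65535, mp, bits.per.sample = 16L)
      written <- c(written, mp)
    }
    tj <- paste0(base, "_truth.json")
    jsonlite::write_json(list(params = unclass(scene$params),
                              truth_table = scene$truth_table),
                         tj, auto_unbox = TRUE, digits = NA)
    written <- c(written, tj)
  }
  invisible(written)
}

#' Read a multi-page TIFF written by [write_image()]
#'
#' @param path TIFF path with pages nucleus, marker, potential.
#' @param pixel_size_um pixel size in micrometres (TIFF carries none).
#' @return A [mito_image()]. Stored 16-bit counts are restored as a.u.
#' @export
read_image <- function(path, pixel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) < 3)
    stop("expected a 3-page TIFF (nucleus, marker, potential) in ", path)
  ch <- lapply(pages[1:3], function(m) round(m * 65535))
  mito_image(ch[[1]], ch[[2]], ch[[3]], pixel_size_um)
}
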