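#' Parameters for a synthetic fluorescence scene
#'
#' Bundles and validates the generative parameters for a synthetic
#' multi-channel micrograph: field geometry, nucleus and mitochondrial
#' object geometry, the linear radial intensity laws, and the camera noise
#' model. Intensities are in arbitrary units (a.u.); distances in
#' micrometres.
#'
#' The generative model places elliptical, non-overlapping nuclei and, for
#' each cell, `mito_object_count_per_cell` curvilinear mitochondrial
#' objects (random-walk polylines with outward drift, dilated to
#' `mito_width_um`). On every mitochondrial pixel at Euclidean distance
#' `d` (micrometres) from its own nucleus boundary, pre-noise intensities
#' follow
#' \deqn{marker(d) = marker\_density \cdot (1 + marker\_slope\_per\_um \cdot d)}
#' \deqn{potential(d) = marker(d) \cdot polarization\_base \cdot
#'       (1 + polarization\_slope\_per\_um \cdot d)}
#' so the programmed potential/marker ratio at distance `d` is
#' `polarization_base * (1 + polarization_slope_per_um * d)`. Camera noise
#' is Poisson on the signal (`poisson_scaling` counts per a.u.; 0 disables
#' it) plus additive Gaussian background noise, clipped at zero.
#'
#' @param field_size_px integer pair, field size in pixels (rows, cols).
#' @param pixel_size_um pixel size in micrometres (isotropic).
#' @param n_cells number of cells (nuclei) to place.
#' @param nucleus_radii_um range (min, max) of the nucleus semi-axes, um.
#' @param mito_object_count_per_cell mitochondrial objects per cell.
#' @param mito_object_length_um mean curvilinear object length, um.
#' @param mito_width_um object width (diameter), um.
#' @param marker_density marker intensity per mitochondrial pixel at the
#'   nucleus boundary, a.u.
#' @param polarization_base potential per marker unit at the nucleus
#'   boundary (d = 0), a.u./a.u.
#' @param polarization_slope_per_um fractional change of the
#'   potential/marker ratio per micrometre of distance from the nucleus.
#' @param marker_slope_per_um fractional change of marker density per um.
#' @param background_level additive background, a.u.
#' @param gaussian_noise_sd standard deviation of additive Gaussian noise.
#' @param poisson_scaling Poisson counts per a.u.; 0 disables shot noise.
#' @param nucleus_level nucleus-channel intensity inside nuclei, a.u.
#' @param min_gap_um minimum enforced gap between distinct mitochondrial
#'   objects, um (keeps programmed object counts recoverable).
#' @param step_um random-walk step length, um.
#' @param seed integer seed; identical parameters (including the seed)
#'   yield bit-identical scenes and renders.
#' @return An object of class `scene_params` (a validated list).
#' @seealso [scenario_preset()], [generate_scene()], [render()]
#' @export
#' @examples
#' p <- scene_params(field_size_px = c(128, 128), n_cells = 1,
#'                   mito_object_count_per_cell = 10, seed = 1)
#' p$polarization_base
scene_params <- function(field_size_px = c(256L, 256L),
                         pixel_size_um = 0.2,
                         n_cells = 1L,
                         nucleus_radii_um = c(4, 6),
                         mito_object_count_per_cell = 40L,
                         mito_object_length_um = 3,
                         mito_width_um = 0.5,
                         marker_density = 100,
                         polarization_base = 1.5,
                         polarization_slope_per_um = 0.08,
                         marker_slope_per_um = -0.04,
                         background_level = 20,
                         gaussian_noise_sd = 8,
                         poisson_scaling = 2,
                         nucleus_level = 200,
                         min_gap_um = 0.4,
                         step_um = 0.3,
                         seed = 1L) {
  p <- list(field_size_px = as.integer(field_size_px),
            pixel_size_um = pixel_size_um,
            n_cells = as.integer(n_cells),
            nucleus_radii_um = as.numeric(nucleus_radii_um),
            mito_object_count_per_cell = as.integer(mito_object_count_per_cell),
            mito_object_length_um = mito_object_length_um,
            mito_width_um = mito_width_um,
            marker_density = marker_density,
            polarization_base = polarization_base,
            polarization_slope_per_um = polarization_slope_per_um,
            marker_slope_per_um = marker_slope_per_um,
            background_level = background_level,
            gaussian_noise_sd = gaussian_noise_sd,
            poisson_scaling = poisson_scaling,
            nucleus_level = nucleus_level,
            min_gap_um = min_gap_um,
            step_um = step_um,
            seed = as.integer(seed))
  stopifnot(length(p$field_size_px) == 2, all(p$field_size_px >= 16),
            p$pixel_size_um > 0, p$n_cells >= 1,
            length(p$nucleus_radii_um) == 2, all(p$nucleus_radii_um > 0),
            p$nucleus_radii_um[1] <= p$nucleus_radii_um[2],
            p$mito_object_count_per_cell >= 1,
            p$mito_object_length_um > 0, p$mito_width_um > 0,
            p$marker_density > 0, p$polarization_base > 0,
            p$background_level >= 0, p$gaussian_noise_sd >= 0,
            p$poisson_scaling >= 0, p$nucleus_level > 0,
            p$min_gap_um >= 0, p$step_um > 0)
  class(p) <- "scene_params"
  p
}

#' @export
print.scene_params <- function(x, ...) {
  cat(sprintf("scene_params: %dx%d px @ %.3g um/px, %d cell(s), %d mito objects/cell\n",
              x$field_size_px[1], x$field_size_px[2], x$pixel_size_um,
              x$n_cells, x$mito_object_count_per_cell))
  cat(sprintf("  ratio law: %.3g * (1 + %.3g d); marker law: %.3g * (1 + %.3g d)\n",
              x$polarization_base, x$polarization_slope_per_um,
              x$marker_density, x$marker_slope_per_um))
  cat(sprintf("  background %.3g, gaussian sd %.3g, poisson scaling %.3g, seed %d\n",
              x$background_level, x$gaussian_noise_sd, x$poisson_scaling, x$seed))
  invisible(x)
}

#' Named scenario presets for simulated treatment conditions
#'
#' Returns documented parameter sets emulating qualitative treatment
#' effects: `"vehicle"` (control: potential/marker ratio rises with
#' distance from the nucleus, marker density falls),
#' `"hyperpolarized_fragmented"` (raised potential baseline, more and
#' shorter objects), `"marker_up_gradient_steep"` (raised marker density,
#' steepened radial gradient) and `"gradient_flattened"` (radial ratio
#' gradient pulled toward zero). All magnitudes are free design parameters
#' of the simulator, chosen for qualitative direction only.
#'
#' @param name preset name; unknown names raise an error listing the
#'   available presets.
#' @param ... overrides forwarded to [scene_params()] (e.g. `seed`,
#'   `field_size_px`).
#' @return A `scene_params` object.
#' @export
#' @examples
#' v <- scenario_preset("vehicle", seed = 7)
#' f <- scenario_preset("gradient_flattened", seed = 7)
#' abs(f$polarization_slope_per_um) < abs(v$polarization_slope_per_um)
scenario_preset <- function(name, ...) {
  presets <- list(
    vehicle = list(),
    hyperpolarized_fragmented = list(polarization_base = 1.5 * 1.3,
                                     mito_object_count_per_cell = 64L,
                                     mito_object_length_um = 1.4),
    marker_up_gradient_steep = list(marker_density = 160,
                                    polarization_slope_per_um = 0.16),
    gradient_flattened = list(polarization_slope_per_um = 0.02))
  if (!is.character(name) || length(name) != 1 || !name %in% names(presets))
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ", paste(names(presets), collapse = ", "))
  do.call(scene_params, modifyList(presets[[name]], list(...)))
}

# ellipse radius along direction phi (relative to ellipse frame rotation theta)
.ellipse_radius <- function(a, b, theta, phi) {
  ca <- cos(phi - theta); sa <- sin(phi - theta)
  (a * b) / sqrt((b * ca)^2 + (a * sa)^2)
}

.ellipse_mask <- function(nr, nc, cx, cy, a, b, theta) {
  x <- matrix(seq_len(nr), nr, nc) - cx
  y <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cy
  ct <- cos(theta); st <- sin(theta)
  u <- x * ct + y * st
  v <- -x * st + y * ct
  (u / a)^2 + (v / b)^2 <= 1
}

# distance (px) of each pixel to the nearest nonzero pixel of `mask`;
# 0 on the mask itself. Exact Euclidean via EBImage's distance transform.
.dist_to_mask_px <- function(mask) {
  EBImage::imageData(EBImage::distmap(1 - (mask > 0)))
}

#' Generate a synthetic scene with ground truth
#'
#' Places `n_cells` non-overlapping elliptical nuclei in the field, then
#' grows each cell's mitochondrial network as dilated random-walk
#' polylines seeded near the nucleus boundary with outward drift. Objects
#' of all cells keep a minimum mutual gap (`min_gap_um`) so programmed
#' object counts remain recoverable by connected-component analysis.
#' Distances entering the radial intensity laws are Euclidean distances
#' from the owning nucleus boundary (distance transform of the nucleus
#' complement), the same convention [build_rings()] uses.
#'
#' @param params a [scene_params()] object.
#' @return An object of class `mito_scene`: `params`; `nuclei` (integer
#'   label matrix); `mito_objects` (label matrix, one label per object);
#'   `mito_cells` (label matrix carrying the owning cell's label);
#'   `object_owner` (integer vector mapping object label to cell label);
#'   `mito_dist_um` (matrix of distances from the owning nucleus at
#'   mitochondrial pixels, 0 elsewhere); and `truth_table`, a data.frame
#'   with per-cell programmed object count, mitochondrial area (px and
#'   um^2), a field-border flag and the true potential/marker ratio in
#'   rings 1-4 (1 um wide, from the owning nucleus boundary).
#' @export
#' @examples
#' sc <- generate_scene(scene_params(field_size_px = c(128, 128),
#'   n_cells = 1, mito_object_count_per_cell = 8, seed = 2))
#' sc$truth_table$n_objects
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  p <- params
  set.seed(p$seed)
  nr <- p$field_size_px[1]; nc <- p$field_size_px[2]
  px <- p$pixel_size_um

  ## --- nuclei -------------------------------------------------------------
  nuclei <- matrix(0L, nr, nc)
  ninfo <- vector("list", p$n_cells)
  nuc_sep_px <- 2 / px   # >= 2 um between nuclei
  for (k in seq_len(p$n_cells)) {
    placed <- FALSE
    for (try in 1:300) {
      a <- runif(1, p$nucleus_radii_um[1], p$nucleus_radii_um[2]) / px
      b <- runif(1, p$nucleus_radii_um[1], p$nucleus_radii_um[2]) / px
      th <- runif(1, 0, pi)
      m <- max(a, b) + 2
      if (nr - 2 * m < 1 || nc - 2 * m < 1) break
      cx <- runif(1, m, nr - m); cy <- runif(1, m, nc - m)
      msk <- .ellipse_mask(nr, nc, cx, cy, a, b, th)
      if (!any(msk)) next
      if (k > 1) {
        d <- .dist_to_mask_px(nuclei)
        if (min(d[msk]) < nuc_sep_px) next
      }
      nuclei[msk] <- k
      ninfo[[k]] <- list(cx = cx, cy = cy, a = a, b = b, theta = th)
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place ", p$n_cells, " non-overlapping nuclei in a ",
           nr, "x", nc, " field (cell ", k, "): field too small or crowded")
  }

  ## per-cell distance maps (um from own nucleus boundary; same half-pixel
  ## edge convention as build_rings so truth and analysis share distances)
  dist_um <- lapply(seq_len(p$n_cells), function(k)
    .boundary_dist_px(nuclei == k) * px)

  ## --- mitochondrial objects ----------------------------------------------
  mito_obj <- matrix(0L, nr, nc)
  mito_cell <- matrix(0L, nr, nc)
  mito_d <- matrix(0, nr, nc)
  object_owner <- integer(0)
  rpx <- (p$mito_width_um / 2) / px
  gap_px <- p$min_gap_um / px
  step_px <- p$step_um / px
  obj_id <- 0L

  for (k in seq_len(p$n_cells)) {
    info <- ninfo[[k]]
    for (j in seq_len(p$mito_object_count_per_cell)) {
      ok <- FALSE
      for (try in 1:200) {
        phi <- runif(1, 0, 2 * pi)
        ## perinuclear-dense seeding; the scale widens with failed attempts
        ## so crowded shells spill outward instead of failing
        d0 <- min(8, 0.3 + stats::rexp(1, rate = 1 / (1.2 * (1 + try / 20))))
        r0 <- .ellipse_radius(info$a, info$b, info$theta, phi) + d0 / px
        pt <- c(info$cx + r0 * cos(phi), info$cy + r0 * sin(phi))
        len_um <- max(0.5, rnorm(1, p$mito_object_length_um,
                                 0.25 * p$mito_object_length_um))
        nsteps <- max(2L, as.integer(round(len_um / p$step_um)))
        dir <- phi
        pts <- matrix(NA_real_, nsteps + 1, 2)
        pts[1, ] <- pt
        for (s in seq_len(nsteps)) {
          radial <- atan2(pt[2] - info$cy, pt[1] - info$cx)
          ddir <- atan2(sin(radial - dir), cos(radial - dir))
          dir <- dir + rnorm(1, 0, 0.45) + 0.15 * ddir
          pt <- pt + step_px * c(cos(dir), sin(dir))
          pt <- pmin(pmax(pt, 1), c(nr, nc))
          pts[s + 1, ] <- pt
        }
        ## densify the polyline so distance-to-points approximates
        ## distance-to-curve to well under half a pixel
        seg <- sqrt(rowSums((pts[-1, , drop = FALSE] -
                             pts[-nrow(pts), , drop = FALSE])^2))
        dens <- lapply(seq_along(seg), function(s) {
          n <- max(2L, ceiling(seg[s] / 0.35) + 1L)
          t <- seq(0, 1, length.out = n)
          cbind(pts[s, 1] + t * (pts[s + 1, 1] - pts[s, 1]),
                pts[s, 2] + t * (pts[s + 1, 2] - pts[s, 2]))
        })
        sp <- do.call(rbind, dens)
        ## rasterize: pixels within rpx of the curve (local bounding box)
        x0 <- max(1L, floor(min(sp[, 1]) - rpx - gap_px - 1))
        x1 <- min(nr, ceiling(max(sp[, 1]) + rpx + gap_px + 1))
        y0 <- max(1L, floor(min(sp[, 2]) - rpx - gap_px - 1))
        y1 <- min(nc, ceiling(max(sp[, 2]) + rpx + gap_px + 1))
        gx <- rep(x0:x1, times = y1 - y0 + 1)
        gy <- rep(y0:y1, each = x1 - x0 + 1)
        d2 <- matrix(Inf, length(gx), 1)
        dd <- (outer(gx, sp[, 1], "-"))^2 + (outer(gy, sp[, 2], "-"))^2
        dmin <- sqrt(apply(dd, 1, min))
        inside <- dmin <= rpx
        near <- dmin <= rpx + gap_px
        pix <- cbind(gx[inside], gy[inside])
        if (nrow(pix) == 0) next
        lin <- pix[, 1] + (pix[, 2] - 1) * nr
        lin <- lin[nuclei[lin] == 0]                 # never inside a nucleus
        if (length(lin) < 3) next
        ## minimum-gap constraint against already placed objects
        nearpix <- cbind(gx[near], gy[near])
        nearlin <- nearpix[, 1] + (nearpix[, 2] - 1) * nr
        if (any(mito_obj[nearlin] > 0)) next
        obj_id <- obj_id + 1L
        mito_obj[lin] <- obj_id
        mito_cell[lin] <- k
        mito_d[lin] <- dist_um[[k]][lin]
        object_owner[obj_id] <- k
        ok <- TRUE
        break
      }
      if (!ok)
        stop("could not place mitochondrial object ", j, " for cell ", k,
             " after 200 attempts: minimum inter-object gap (",
             p$min_gap_um, " um) cannot be satisfied; reduce ",
             "mito_object_count_per_cell or min_gap_um, or enlarge the field")
    }
  }

  ## --- truth table ---------------------------------------------------------
  n_truth_rings <- 4L
  border_margin_um <- n_truth_rings * 1.0
  rows <- lapply(seq_len(p$n_cells), function(k) {
    sel <- which(mito_cell == k)
    d <- mito_d[sel]
    m <- p$marker_density * (1 + p$marker_slope_per_um * d)
    pot <- m * p$polarization_base * (1 + p$polarization_slope_per_um * d)
    ring <- floor(d / 1.0) + 1
    rr <- vapply(seq_len(n_truth_rings), function(i) {
      in_ring <- ring == i
      if (!any(in_ring) || sum(m[in_ring]) <= 0) return(NA_real_)
      sum(pot[in_ring]) / sum(m[in_ring])
    }, numeric(1))
    nucpix <- which(nuclei == k, arr.ind = TRUE)
    edge_um <- min(nucpix[, 1] - 1, nr - nucpix[, 1],
                   nucpix[, 2] - 1, nc - nucpix[, 2]) * px
    data.frame(cell = k,
               n_objects = p$mito_object_count_per_cell,
               mito_area_px = length(sel),
               mito_area_um2 = length(sel) * px^2,
               border = edge_um < border_margin_um,
               ring1_true_ratio = rr[1], ring2_true_ratio = rr[2],
               ring3_true_ratio = rr[3], ring4_true_ratio = rr[4])
  })

  structure(list(params = p,
                 nuclei = nuclei,
                 mito_objects = mito_obj,
                 mito_cells = mito_cell,
                 object_owner = object_owner,
                 mito_dist_um = mito_d,
                 truth_table = do.call(rbind, rows)),
            class = "mito_scene")
}

#' @export
print.mito_scene <- function(x, ...) {
  cat(sprintf("mito_scene: %dx%d px, %d cell(s), %d mitochondrial objects\n",
              nrow(x$nuclei), ncol(x$nuclei), x$params$n_cells,
              max(x$mito_objects)))
  print(x$truth_table, row.names = FALSE)
  invisible(x)
}

#' Render a scene to a multi-channel image
#'
#' Applies the radial intensity laws on mitochondrial pixels, paints the
#' nucleus channel, adds the background level and the camera noise model
#' (Poisson on signal, additive Gaussian), and clips at zero. With all
#' noise parameters zero, pre-noise intensities are returned exactly, so
#' the potential/marker quotient on every mitochondrial pixel equals the
#' programmed profile.
#'
#' @param scene a `mito_scene` from [generate_scene()].
#' @return A [mito_image()] with channels `nucleus`, `marker`, `potential`.
#' @export
render <- function(scene) {
  stopifnot(inherits(scene, "mito_scene"))
  p <- scene$params
  sel <- scene$mito_cells > 0
  d <- scene$mito_dist_um[sel]
  mfac <- 1 + p$marker_slope_per_um * d
  pfac <- 1 + p$polarization_slope_per_um * d
  if (any(mfac < 0))
    stop("marker_slope_per_um = ", p$marker_slope_per_um,
         " drives the marker intensity negative at distance ",
         round(max(d), 2), " um; slopes must keep intensities >= 0")
  if (any(pfac < 0))
    stop("polarization_slope_per_um = ", p$polarization_slope_per_um,
         " drives the potential intensity negative at distance ",
         round(max(d), 2), " um; slopes must keep intensities >= 0")
  dims <- dim(scene$nuclei)
  marker <- matrix(0, dims[1], dims[2])
  potential <- matrix(0, dims[1], dims[2])
  marker[sel] <- p$marker_density * mfac
  potential[sel] <- marker[sel] * p$polarization_base * pfac
  nucleus <- p$nucleus_level * (scene$nuclei > 0)

  noisy <- function(x) {
    x <- x + p$background_level
    if (p$poisson_scaling > 0)
      x <- rpois(length(x), lambda = x * p$poisson_scaling) / p$poisson_scaling
    if (p$gaussian_noise_sd > 0)
      x <- x + rnorm(length(x), 0, p$gaussian_noise_sd)
    matrix(pmax(x, 0), dims[1], dims[2])
  }
  set.seed(p$seed + 1L)   # render noise reproducible independently of generation
  mito_image(noisy(nucleus), noisy(marker), noisy(potential), p$pixel_size_um)
}
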