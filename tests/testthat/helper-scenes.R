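# Shared fixtures: small single-cell scenes built in code.

small_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(field_size_px = c(160L, 160L),
                                 pixel_size_um = 0.25, n_cells = 1L,
                                 mito_object_count_per_cell = 25L),
                            list(...))
  do.call(scene_params, c(list(seed = seed), args))
}

# all camera noise off; intensities are the programmed laws exactly
noiseless_params <- function(seed = 1L, ...) {
  args <- utils::modifyList(list(background_level = 0, gaussian_noise_sd = 0,
                                 poisson_scaling = 0), list(...))
  do.call(small_params, c(list(seed = seed), args))
}

default_config <- function(...) run_config(...)

# exhaustive per-pixel distance (px) to the nearest nucleus pixel:
# the independent oracle for the distance-transform ring construction
brute_force_dist_px <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  nr <- nrow(mask); nc <- ncol(mask)
  X <- rep(seq_len(nr), nc); Y <- rep(seq_len(nc), each = nr)
  d2min <- rep(Inf, nr * nc)
  for (q in seq_len(nrow(idx)))
    d2min <- pmin(d2min, (X - idx[q, 1])^2 + (Y - idx[q, 2])^2)
  matrix(sqrt(d2min), nr, nc)
}

# same boundary convention as the package: half a pixel inside the
# nearest nucleus pixel centre
brute_force_boundary_dist_px <- function(mask) {
  pmax(brute_force_dist_px(mask) - 0.5, 0)
}

# random blobby nucleus mask (one or two ellipses) for oracle tests
random_nucleus_mask <- function(nr = 128, nc = 128) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(sample(1:2, 1))) {
    cx <- runif(1, 30, nr - 30); cy <- runif(1, 30, nc - 30)
    a <- runif(1, 6, 16); b <- runif(1, 6, 16); th <- runif(1, 0, pi)
    x <- matrix(seq_len(nr), nr, nc) - cx
    y <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cy
    u <- x * cos(th) + y * sin(th); v <- -x * sin(th) + y * cos(th)
    m <- m | ((u / a)^2 + (v / b)^2 <= 1)
  }
  m
}

# ring index assignment from an arbitrary distance map (same half-open
# binning convention as build_rings)
bin_rings <- function(d_um, nucleus_mask, w, n) {
  idx <- floor(d_um / w) + 1
  idx[nucleus_mask | idx > n] <- 0
  matrix(as.integer(idx), nrow(nucleus_mask), ncol(nucleus_mask))
}
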