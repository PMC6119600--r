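make_grids <- function() {
  mito <- matrix(0L, 20, 20); mito[5:14, 5:14] <- 1L   # 100 px
  region <- matrix(TRUE, 20, 20)
  marker <- matrix(0, 20, 20); marker[mito > 0] <- 1
  potential <- matrix(0, 20, 20); potential[mito > 0] <- 2
  list(mito = mito, region = region, marker = marker, potential = potential)
}

test_that("region metrics compute the three readouts from summed intensities", {
  g <- make_grids()
  m <- compute_region_metrics(g$mito, g$region, g$marker, g$potential,
                              pixel_size_um = 1)
  expect_equal(m$mito_area_um2, 100)
  expect_equal(m$sum_marker, 100)
  expect_equal(m$sum_potential, 200)
  expect_equal(m$ratio_potential_marker, 2.0)
  expect_equal(m$potential_per_area, 2.0)
  expect_equal(m$marker_per_area, 1.0)
  expect_true(m$valid)
})

test_that("empty intersections are invalid with undefined ratios", {
  g <- make_grids()
  empty_region <- matrix(FALSE, 20, 20)
  m <- compute_region_metrics(g$mito, empty_region, g$marker, g$potential, 1)
  expect_false(m$valid)
  expect_true(is.na(m$ratio_potential_marker))
  expect_true(is.na(m$potential_per_area))
  expect_equal(m$mito_area_px, 0)
  expect_error(compute_region_metrics(g$mito, g$region, g$marker[1:10, 1:10],
                                      g$potential, 1), "dimensions")
})

test_that("metrics are linear and scale-covariant in the channels", {
  g <- make_grids()
  base <- compute_region_metrics(g$mito, g$region, g$marker, g$potential, 1)
  scaled <- compute_region_metrics(g$mito, g$region, g$marker,
                                   g$potential * 3, 1)
  expect_identical(scaled$ratio_potential_marker,
                   base$ratio_potential_marker * 3)
  expect_identical(scaled$potential_per_area, base$potential_per_area * 3)
  expect_identical(scaled$marker_per_area, base$marker_per_area)
  both <- compute_region_metrics(g$mito, g$region, g$marker * 5,
                                 g$potential * 5, 1)
  expect_identical(both$ratio_potential_marker, base$ratio_potential_marker)
})

test_that("metrics over disjoint regions add (sums; ratios from totals)", {
  g <- make_grids()
  left <- matrix(FALSE, 20, 20); left[, 1:10] <- TRUE
  right <- !left
  a <- compute_region_metrics(g$mito, left, g$marker, g$potential, 1)
  b <- compute_region_metrics(g$mito, right, g$marker, g$potential, 1)
  whole <- compute_region_metrics(g$mito, g$region, g$marker, g$potential, 1)
  expect_equal(a$sum_marker + b$sum_marker, whole$sum_marker)
  expect_equal(a$sum_potential + b$sum_potential, whole$sum_potential)
  expect_equal(a$mito_area_um2 + b$mito_area_um2, whole$mito_area_um2)
  expect_equal((a$sum_potential + b$sum_potential) /
                 (a$sum_marker + b$sum_marker),
               whole$ratio_potential_marker)
})

test_that("ring profiles normalize to ring 1 and exclude invalid cells", {
  rm <- data.frame(cell = 1, ring = 1:4, region = paste0("ring", 1:4),
                   ratio_potential_marker = c(2, 3, 4, 5), valid = TRUE)
  pr <- ring_profile(rm, "ratio_potential_marker")
  expect_equal(pr$normalized, c(1, 1.5, 2, 2.5))
  # a cell with invalid ring 1 is excluded and accounted, not an error
  rm2 <- rbind(rm, data.frame(cell = 2, ring = 1:4,
                              region = paste0("ring", 1:4),
                              ratio_potential_marker = c(NA, 3, 4, 5),
                              valid = c(FALSE, TRUE, TRUE, TRUE)))
  pr2 <- ring_profile(rm2, "ratio_potential_marker")
  qc <- attr(pr2, "qc")
  expect_equal(qc$excluded_cells, 2)
  expect_equal(qc$n_analyzed, 1)
  expect_equal(qc$n_analyzed + length(qc$excluded_cells),
               length(unique(rm2$cell)))
})

test_that("noiseless gradient profiles match the pixel-level oracle within 1%", {
  p <- noiseless_params(seed = 25)
  sc <- generate_scene(p)
  q <- quantify_image(render(sc), default_config())
  pr <- ring_profile(q$rings, "ratio_potential_marker")
  truth <- unlist(sc$truth_table[1, paste0("ring", 1:4, "_true_ratio")])
  truth_norm <- truth / truth[1]
  est <- pr$normalized[order(pr$ring)]
  expect_equal(length(est), 4)
  expect_lt(max(abs(est / truth_norm - 1)), 0.01)
  # flat programmed gradient stays flat through the whole pipeline
  pf <- noiseless_params(seed = 26, polarization_slope_per_um = 0)
  qf <- quantify_image(render(generate_scene(pf)), default_config())
  prf <- ring_profile(qf$rings, "ratio_potential_marker")
  expect_lt(max(abs(prf$normalized - 1)), 1e-9)
})

test_that("whole-cell metrics recover a programmed treatment effect", {
  f <- 1.5; n <- 8
  ratios <- function(base, seeds) vapply(seeds, function(s) {
    q <- quantify_image(render(generate_scene(
      small_params(seed = s, polarization_base = base))), default_config())
    q$cells$ratio_potential_marker
  }, numeric(1))
  veh <- ratios(1.5, 1:n)
  trt <- ratios(1.5 * f, 100 + 1:n)
  expect_lt(abs(mean(trt) / mean(veh) - f), 0.05 * f)
})

test_that("ring sums add up to the unclipped whole-cell totals", {
  p <- noiseless_params(seed = 27)
  sc <- generate_scene(p)
  q <- quantify_image(render(sc), default_config())
  seg <- q$seg
  # rings extended to cover the full territory, unclipped
  rs <- build_rings(seg$nucleus_labels == 1, seg$pixel_size_um,
                    ring_width_um = 1, n_rings = 200,
                    clip_to_territory = FALSE)
  tot <- 0
  for (k in seq_len(rs$n_rings)) {
    if (!any(rs$ring_masks[[k]])) next
    tot <- tot + compute_region_metrics(seg$mito_mask == 1, rs$ring_masks[[k]],
                                        seg$marker, seg$potential,
                                        seg$pixel_size_um)$sum_marker
  }
  whole <- whole_cell_metrics(seg)
  expect_equal(tot, whole$sum_marker, tolerance = 1e-12)
})
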