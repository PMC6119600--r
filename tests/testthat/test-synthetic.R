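test_that("scenes report programmed object counts and conserve truth areas", {
  sc <- generate_scene(small_params(seed = 11, mito_object_count_per_cell = 20))
  expect_equal(sc$truth_table$n_objects, 20)
  expect_equal(max(sc$mito_objects), 20)
  # truth conservation: per-cell areas sum to the total mask area
  expect_equal(sum(sc$truth_table$mito_area_px), sum(sc$mito_cells > 0))
  # mitochondria never overlap nuclei; every object has exactly one owner
  expect_equal(sum(sc$mito_cells > 0 & sc$nuclei > 0), 0)
  owners <- tapply(sc$mito_cells[sc$mito_objects > 0],
                   sc$mito_objects[sc$mito_objects > 0],
                   function(v) length(unique(v)))
  expect_true(all(owners == 1))
})

test_that("equal seeds give bit-identical scenes and renders", {
  p <- small_params(seed = 42)
  sc1 <- generate_scene(p); sc2 <- generate_scene(p)
  expect_identical(sc1$mito_objects, sc2$mito_objects)
  expect_identical(sc1$nuclei, sc2$nuclei)
  expect_identical(sc1$truth_table, sc2$truth_table)
  im1 <- render(sc1); im2 <- render(sc2)
  expect_identical(im1$marker, im2$marker)
  expect_identical(im1$potential, im2$potential)
  expect_identical(im1$nucleus, im2$nucleus)
})

test_that("multiple nuclei are placed pairwise disjoint", {
  sc <- generate_scene(scene_params(field_size_px = c(512L, 512L),
                                    pixel_size_um = 0.2, n_cells = 5L,
                                    mito_object_count_per_cell = 5L,
                                    seed = 7))
  labs <- sort(unique(sc$nuclei[sc$nuclei > 0]))
  expect_equal(labs, 1:5)
  # brute-force pairwise intersection of the individual masks
  masks <- lapply(labs, function(k) sc$nuclei == k)
  for (i in 1:4) for (j in (i + 1):5)
    expect_equal(sum(masks[[i]] & masks[[j]]), 0)
})

test_that("noiseless renders reproduce the programmed ratio law exactly", {
  p <- noiseless_params(seed = 5)
  sc <- generate_scene(p)
  img <- render(sc)
  sel <- sc$mito_cells > 0
  d <- sc$mito_dist_um[sel]
  ratio <- img$potential[sel] / img$marker[sel]
  programmed <- p$polarization_base * (1 + p$polarization_slope_per_um * d)
  expect_lt(max(abs(ratio / programmed - 1)), 1e-9)
  # marker law as well
  expect_lt(max(abs(img$marker[sel] /
                      (p$marker_density * (1 + p$marker_slope_per_um * d)) - 1)),
            1e-9)
})

test_that("zero polarization slope gives a flat potential/marker quotient", {
  p <- noiseless_params(seed = 6, polarization_slope_per_um = 0)
  sc <- generate_scene(p)
  img <- render(sc)
  sel <- sc$mito_cells > 0
  ratio <- img$potential[sel] / img$marker[sel]
  expect_lt(diff(range(ratio)), 1e-9)
  expect_equal(ratio[1], p$polarization_base, tolerance = 1e-12)
  # truth table mirrors the flat profile
  tt <- sc$truth_table
  rr <- unlist(tt[1, grep("ring\\d_true_ratio", names(tt))])
  expect_equal(unname(rr[!is.na(rr)]),
               rep(p$polarization_base, sum(!is.na(rr))), tolerance = 1e-12)
})

test_that("background level sets the modal intensity of non-cell pixels", {
  p <- noiseless_params(seed = 8, background_level = 50)
  sc <- generate_scene(p)
  img <- render(sc)
  bg <- img$marker[sc$mito_cells == 0 & sc$nuclei == 0]
  mode_val <- as.numeric(names(which.max(table(bg))))
  expect_equal(mode_val, 50)
})

test_that("slopes that drive intensities negative are rejected at render", {
  p <- noiseless_params(seed = 9, marker_slope_per_um = -0.5)
  sc <- generate_scene(p)
  expect_error(render(sc), "negative")
  p2 <- noiseless_params(seed = 9, polarization_slope_per_um = -0.5)
  expect_error(render(generate_scene(p2)), "negative")
})

test_that("nucleus placement fails loudly when the field is too small", {
  expect_error(generate_scene(scene_params(field_size_px = c(64L, 64L),
                                           pixel_size_um = 0.2, n_cells = 6L,
                                           seed = 1)),
               "nuclei")
})

test_that("presets are ordered as documented and render cleanly", {
  v <- scenario_preset("vehicle", seed = 3)
  fl <- scenario_preset("gradient_flattened", seed = 3)
  hf <- scenario_preset("hyperpolarized_fragmented", seed = 3)
  st <- scenario_preset("marker_up_gradient_steep", seed = 3)
  # control has a nonzero outward-rising gradient (peripheral > perinuclear)
  expect_gt(v$polarization_slope_per_um, 0)
  expect_lt(abs(fl$polarization_slope_per_um), abs(v$polarization_slope_per_um))
  expect_gt(hf$polarization_base, v$polarization_base)
  expect_gt(hf$mito_object_count_per_cell, v$mito_object_count_per_cell)
  expect_lt(hf$mito_object_length_um, v$mito_object_length_um)
  expect_gt(st$polarization_slope_per_um, v$polarization_slope_per_um)
  expect_error(scenario_preset("nope"), "available presets")
  # smoke: every preset renders at 512x512, 0.2 um/px
  for (nm in c("vehicle", "hyperpolarized_fragmented",
               "marker_up_gradient_steep", "gradient_flattened")) {
    img <- render(generate_scene(scenario_preset(nm, seed = 2,
                                                 field_size_px = c(512L, 512L),
                                                 pixel_size_um = 0.2)))
    expect_s3_class(img, "mito_image")
  }
})
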