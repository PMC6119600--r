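test_that("background subtraction removes scalar offsets", {
  expect_equal(as.numeric(subtract_background(matrix(10, 5, 5), "percentile",
                                              level = 1)),
               rep(0, 25))
  x <- matrix(5, 10, 10); x[1:10] <- 105     # 10% bright, 90% at 5
  cor <- subtract_background(x, "mode")
  expect_setequal(unique(as.numeric(cor)), c(0, 100))
  expect_equal(attr(cor, "background"), 5)
  expect_error(subtract_background(matrix(numeric(0), 0, 0)), "empty")
})

test_that("background estimate recovers the generator's level", {
  p <- noiseless_params(seed = 12, background_level = 37)
  sc <- generate_scene(p)
  img <- render(sc)
  cor <- subtract_background(img$marker, "mode")
  noncell <- sc$mito_cells == 0 & sc$nuclei == 0
  expect_equal(median(cor[noncell]), 0)
  expect_equal(attr(cor, "background"), 37)
})

test_that("background subtraction is idempotent on constant background", {
  x <- matrix(20, 20, 20); x[5:8, 5:8] <- 150
  once <- subtract_background(x, "mode")
  twice <- subtract_background(once, "mode")
  expect_equal(as.numeric(twice), as.numeric(once))
  oncep <- subtract_background(x, "percentile", level = 1)
  twicep <- subtract_background(oncep, "percentile", level = 1)
  expect_equal(as.numeric(twicep), as.numeric(oncep))
})

test_that("nucleus segmentation recovers discs, areas and centroids", {
  # one bright disc, radius 10 um on zero background (pixel 0.5 um)
  nr <- 120; px <- 0.5
  x <- matrix(seq_len(nr), nr, nr); y <- t(x)
  disc <- (x - 60)^2 + (y - 60)^2 <= (10 / px)^2
  lab <- segment_nuclei(disc * 100, pixel_size_um = px)
  expect_equal(max(lab), 1)
  expect_lt(abs(sum(lab == 1) * px^2 - pi * 100) / (pi * 100), 0.05)

  expect_warning(lab0 <- segment_nuclei(matrix(0, 32, 32), 1), "no nucleus")
  expect_equal(max(lab0), 0)

  # two discs 30 um apart: two labels, centroids within 1 px of truth
  two <- ((x - 30)^2 + (y - 30)^2 <= 100) | ((x - 90)^2 + (y - 90)^2 <= 100)
  lab2 <- segment_nuclei(two * 80, pixel_size_um = px)
  expect_equal(max(lab2), 2)
  for (ctr in list(c(30, 30), c(90, 90))) {
    k <- lab2[ctr[1], ctr[2]]
    pix <- which(lab2 == k, arr.ind = TRUE)
    expect_lt(max(abs(colMeans(pix) - ctr)), 1)
  }
})

test_that("territories assign each pixel to its nearest nucleus", {
  # single nucleus claims the whole field
  nuc <- matrix(0L, 40, 40); nuc[18:22, 18:22] <- 1L
  expect_true(all(assign_cell_territories(nuc) == 1))

  # two identical nuclei symmetric about the midline
  nuc2 <- matrix(0L, 40, 60)
  nuc2[18:22, 12:16] <- 1L; nuc2[18:22, 44:48] <- 2L
  terr <- assign_cell_territories(nuc2)
  expect_true(all(terr[, 1:29] == 1))
  expect_true(all(terr[, 31:60] == 2))

  # random 3-nucleus layout vs brute-force nearest-pixel scan
  set.seed(31)
  nuc3 <- matrix(0L, 64, 64)
  nuc3[5:12, 6:13] <- 1L; nuc3[40:52, 10:18] <- 2L; nuc3[20:28, 45:58] <- 3L
  terr3 <- assign_cell_territories(nuc3)
  d <- lapply(1:3, function(k) brute_force_dist_px(nuc3 == k))
  for (i in seq(1, 64, by = 3)) for (j in seq(1, 64, by = 3)) {
    dd <- c(d[[1]][i, j], d[[2]][i, j], d[[3]][i, j])
    expect_equal(dd[terr3[i, j]], min(dd))
  }
})

test_that("mitochondrial demarcation matches generator truth", {
  p <- noiseless_params(seed = 14)
  sc <- generate_scene(p)
  q <- quantify_image(render(sc), default_config())
  est <- q$seg$mito_mask > 0
  tru <- sc$mito_cells > 0
  iou <- sum(est & tru) / sum(est | tru)
  expect_equal(iou, 1.0)

  # noisy case, fixed seed: IoU >= 0.8 against truth
  pn <- small_params(seed = 14)
  scn <- generate_scene(pn)
  qn <- quantify_image(render(scn), default_config())
  estn <- qn$seg$mito_mask > 0; trun <- scn$mito_cells > 0
  expect_gte(sum(estn & trun) / sum(estn | trun), 0.8)
})

test_that("zero marker channel yields an empty mask with a warning", {
  terr <- matrix(1L, 16, 16); nuc <- matrix(0L, 16, 16); nuc[8, 8] <- 1L
  expect_warning(m <- segment_mitochondria(matrix(0, 16, 16), terr, nuc),
                 "all-zero")
  expect_equal(sum(m), 0)
})

test_that("segmentation masks are invariant to positive channel scaling", {
  p <- small_params(seed = 15)
  img <- render(generate_scene(p))
  scaled <- mito_image(img$nucleus * 3.7, img$marker * 3.7,
                       img$potential * 3.7, img$pixel_size_um)
  s1 <- segment_cells(img)
  s2 <- segment_cells(scaled)
  expect_identical(s1$nucleus_labels, s2$nucleus_labels)
  expect_equal(s1$mito_mask, s2$mito_mask, ignore_attr = TRUE)
  # ... while the thresholds themselves scale with the channel
  expect_equal(unname(s2$thresholds / s1$thresholds), 3.7, tolerance = 1e-6)
})

test_that("segmentation satisfies the partition and disjointness invariants", {
  sc <- generate_scene(scene_params(field_size_px = c(256L, 256L),
                                    pixel_size_um = 0.2, n_cells = 3L,
                                    mito_object_count_per_cell = 15L,
                                    seed = 16))
  q <- quantify_image(render(sc), default_config())
  seg <- q$seg
  # territories partition the field
  expect_true(all(seg$territory_labels > 0))
  # mito pixels carry their territory's label and avoid nuclei
  sel <- seg$mito_mask > 0
  expect_true(all(seg$mito_mask[sel] == seg$territory_labels[sel]))
  expect_equal(sum(sel & seg$nucleus_labels > 0), 0)
  # nucleus and territory label sets coincide
  expect_setequal(unique(seg$territory_labels[seg$territory_labels > 0]),
                  unique(seg$nucleus_labels[seg$nucleus_labels > 0]))
})
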