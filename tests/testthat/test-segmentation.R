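test_that("featureless maps yield a no-cell error", {
  expect_error(segment_cell(matrix(0, 45, 45)), class = "cryoraman_no_cell")
  expect_error(segment_cell(matrix(1, 8, 8)), class = "cryoraman_shape_error")
})

test_that("a centered disk is recovered with high overlap", {
  m <- matrix(5, 45, 45)
  truth <- (row(m) - 23)^2 + (col(m) - 23)^2 <= 100
  m[truth] <- 100
  cell <- segment_cell(m)
  expect_gte(mask_iou(cell, truth), 0.90)
  ctr <- mask_centroid(cell)
  expect_lte(max(abs(ctr - c(23, 23))), 1)
})

test_that("border-touching cells are cleared away", {
  m <- matrix(5, 45, 45)
  m[(row(m) - 10)^2 + (col(m) - 3)^2 <= 100] <- 100
  expect_error(segment_cell(m), class = "cryoraman_no_cell")
})

test_that("cell masks track ground truth across seeded noise-free geometries", {
  set.seed(31)
  for (k in 1:20) {
    radius <- sample(8:12, 1)
    ctr <- c(sample(18:27, 1), sample(18:27, 1))
    sc <- generate_scene(scene_params(seed = 200 + k, cell_radius = radius,
                                      cell_center = ctr, noise_sd = 0))
    amide <- compute_intensity_map(render_cube(sc), default_bands()$protein,
                                   analysis_config())
    cell <- segment_cell(amide)
    expect_gte(mask_iou(cell, sc$truth_masks$cell), 0.90)
    expect_lte(max(abs(mask_centroid(cell) - ctr)), 1)
  }
})

test_that("raising the edge sensitivity never admits more edge pixels", {
  set.seed(32)
  m <- matrix(5, 45, 45)
  m[(row(m) - 23)^2 + (col(m) - 23)^2 <= 100] <- 100
  m <- m + stats::rnorm(2025, 0, 2)
  counts <- vapply(seq(0.5, 0.9, by = 0.1),
                   function(s) sum(detect_edges(m, s)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("ice segmentation splits compartments and discards singleton noise", {
  sc <- generate_scene(scene_params(seed = 33, noise_sd = 0))
  ice_map <- compute_intensity_map(render_cube(sc), default_bands()$ice,
                                   analysis_config())
  ice <- segment_ice(ice_map, sc$truth_masks$cell)
  expect_equal(sum(ice$ice_intracellular), 0)
  expect_gte(mask_iou(ice$ice_extracellular, sc$truth_masks$ice_extracellular), 0.95)

  # a pocket of intracellular ice at extracellular amplitude is recovered
  sci <- generate_scene(scene_params(seed = 34, intracellular_ice_fraction = 0.05,
                                     noise_sd = 0))
  icm <- compute_intensity_map(render_cube(sci), default_bands()$ice,
                               analysis_config())
  icei <- segment_ice(icm, sci$truth_masks$cell)
  truth_in <- sci$truth_masks$ice_intracellular
  expect_gt(sum(truth_in), 0)
  mismatch <- sum(xor(icei$ice_intracellular, truth_in))
  expect_lte(mismatch, ceiling(0.1 * sum(truth_in)))

  # degenerate constant map: no ice at all
  flat <- segment_ice(matrix(3, 45, 45), sc$truth_masks$cell)
  expect_equal(sum(flat$ice_extracellular) + sum(flat$ice_intracellular), 0)

  # single supra-threshold pixels inside the cell are discarded as shot noise
  v <- matrix(1, 15, 15)
  cellm <- (row(v) - 8)^2 + (col(v) - 8)^2 <= 25
  v[1:15, 1:2] <- 100            # extracellular ice slab
  v[8, 8] <- 100                 # lone intracellular pixel
  lone <- segment_ice(v, cellm)
  expect_equal(sum(lone$ice_intracellular), 0)
})

test_that("channels are the extracellular complement and partition the raster", {
  h <- matrix(FALSE, 12, 12)
  cell <- h; cell[4:8, 4:8] <- TRUE
  ice <- !cell
  expect_error(derive_channels(cell, ice), class = "cryoraman_empty_channel")

  sc <- phantom(35)
  an <- analyze_cube(render_cube(sc))
  ch <- an$masks$channel
  expect_gte(mask_iou(ch, sc$truth_masks$channel), 0.90)
  expect_true(all(an$masks$cell | an$masks$ice_extracellular | ch))
  expect_equal(sum(an$masks$cell & ch), 0)
  expect_equal(sum(an$masks$ice_extracellular & ch), 0)
})

test_that("mask bundles enforce the partition invariants", {
  m <- matrix(FALSE, 10, 10)
  cell <- m; cell[4:6, 4:6] <- TRUE
  ice <- m; ice[1:2, ] <- TRUE
  chan <- !cell & !ice
  expect_s3_class(compartment_masks(cell, ice, m, chan), "compartment_masks")
  expect_error(compartment_masks(cell, cell, m, chan), class = "cryoraman_mask_error")
  ice_in_bad <- m; ice_in_bad[1, 1] <- TRUE
  expect_error(compartment_masks(cell, ice, ice_in_bad, chan),
               class = "cryoraman_mask_error")
  expect_error(compartment_masks(cell, ice, m, m), class = "cryoraman_mask_error")
})

test_that("line-scan boundary crossings coincide with the mask boundary", {
  for (k in 1:5) {
    sc <- generate_scene(scene_params(seed = 300 + k, noise_sd = 0))
    amide <- compute_intensity_map(render_cube(sc), default_bands()$protein,
                                   analysis_config())
    cell <- segment_cell(amide)
    r <- round(mask_centroid(cell)["row"])
    vals <- amide$values[r, ]
    cols <- which(cell[r, ])
    # midpoint threshold crossing along the scan
    thr <- (max(vals) + min(vals)) / 2
    above <- which(vals >= thr)
    expect_lte(abs(min(above) - min(cols)), 1)
    expect_lte(abs(max(above) - max(cols)), 1)
  }
})
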