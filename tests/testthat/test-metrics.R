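make_masks <- function(h = 20, w = 20, r = 5) {
  m <- matrix(FALSE, h, w)
  cell <- (row(m) - h / 2)^2 + (col(m) - w / 2)^2 <= r^2
  ice <- m; ice[, 1:3] <- TRUE; ice <- ice & !cell
  chan <- !cell & !ice
  compartment_masks(cell, ice, m, chan)
}

test_that("the partitioning ratio is the channel-to-cell mean intensity ratio", {
  masks <- make_masks()
  uni <- matrix(3.7, 20, 20)
  res <- partitioning_ratio(uni, masks)
  expect_equal(res$P, 1)

  two <- matrix(2, 20, 20); two[masks$cell] <- 1
  res2 <- partitioning_ratio(two, masks)
  expect_equal(res2$P, 2, tolerance = 1e-9)
  expect_equal(res2$C_o, 2); expect_equal(res2$C_i, 1)

  zero <- matrix(1, 20, 20); zero[masks$cell] <- 0
  expect_error(partitioning_ratio(zero, masks), class = "cryoraman_degenerate_cell")

  none <- compartment_masks(masks$cell, !masks$cell,
                            matrix(FALSE, 20, 20) , masks$cell & FALSE)
  expect_error(partitioning_ratio(uni, none), class = "cryoraman_empty_channel")
})

test_that("P is invariant to permuting pixels within each compartment", {
  set.seed(41)
  masks <- make_masks()
  v <- matrix(stats::runif(400, 1, 5), 20, 20)
  p0 <- partitioning_ratio(v, masks)$P
  v2 <- v
  for (mk in list(masks$cell, masks$channel, masks$ice_extracellular)) {
    v2[mk] <- sample(v2[mk])
  }
  expect_equal(partitioning_ratio(v2, masks)$P, p0, tolerance = 1e-12)
})

test_that("the reported ratio always equals C_o / C_i to machine precision", {
  for (k in 1:5) {
    sc <- phantom(400 + k, true_P = c(0.5, 0.9, 1, 1.3, 2)[k])
    an <- analyze_cube(render_cube(sc))
    expect_equal(an$result$P, an$result$C_o / an$result$C_i, tolerance = 1e-12)
  }
})

test_that("coefficient of variation matches hand computation and is scale-free", {
  masks <- make_masks(10, 10, 2)
  v <- matrix(0, 10, 10)
  cells <- which(masks$cell)
  expect_gte(length(cells), 4)
  v[cells] <- rep(c(2, 2, 4, 4), length.out = length(cells))
  # for values {2,2,4,4}: mean 3, sample sd = sqrt(4/3)
  keep <- cells[1:4]
  m2 <- matrix(FALSE, 10, 10); m2[keep] <- TRUE
  expect_equal(coefficient_of_variation(v, m2), sqrt(4 / 3) / 3, tolerance = 1e-12)
  expect_equal(coefficient_of_variation(v * 13, m2),
               coefficient_of_variation(v, m2), tolerance = 1e-12)
  vc <- matrix(5, 10, 10)
  expect_equal(coefficient_of_variation(vc, m2), 0)
  expect_error(coefficient_of_variation(matrix(0, 10, 10), m2),
               class = "cryoraman_degenerate_cell")
})

test_that("ice area fraction counts intracellular ice pixels over cell pixels", {
  m <- matrix(FALSE, 20, 20)
  cell <- m; cell[1:10, 1:10] <- TRUE      # 100 pixels
  ice_in <- m; ice_in[1:2, 1:5] <- TRUE    # 10 pixels
  ice_out <- m; chan <- !cell
  masks0 <- compartment_masks(cell, ice_out, m, chan)
  expect_equal(ice_area_fraction(masks0), 0)
  masks1 <- compartment_masks(cell, ice_out, ice_in, chan)
  expect_equal(ice_area_fraction(masks1), 0.10)
  masks2 <- compartment_masks(cell, ice_out, cell, chan)
  expect_equal(ice_area_fraction(masks2), 1)
})

test_that("line scans carry compartment labels consistent with the masks", {
  sc <- phantom(42, true_P = 1.5)
  an <- analyze_cube(render_cube(sc))
  ls <- an$scan
  expect_equal(length(ls$values), 45)
  r <- ls$row
  expect_identical(ls$labels == "cell", unname(an$masks$cell[r, ]))
  expect_identical(ls$labels == "ice", unname(an$masks$ice_extracellular[r, ]))
  # with P > 1 the channel side of the scan is brighter than the cell side
  expect_gt(mean(ls$values[ls$labels == "channel"]),
            mean(ls$values[ls$labels == "cell"]))
  expect_error(line_scan(an$maps$dmso, an$masks, row = 99),
               class = "cryoraman_index_error")

  uni <- matrix(4, 45, 45)
  flat <- line_scan(uni, an$masks)
  expect_equal(diff(range(flat$values)), 0)
})

test_that("gap profiles are flat for uniform channels and rise under solute polarization", {
  masks <- make_masks()
  uni <- matrix(6, 20, 20)
  gp <- gap_profile(uni, masks)
  expect_true(all(abs(gp$mean_intensity - 6) < 1e-12))

  sc <- generate_scene(scene_params(seed = 43, gradient_toward_ice = TRUE,
                                    noise_sd = 0))
  an <- analyze_cube(render_cube(sc))
  gpp <- gap_profile(an$maps$dmso, an$masks)
  expect_true(all(diff(gpp$mean_intensity) > 0))

  # degenerate geometry: every channel pixel at distance 1 from ice
  m <- matrix(FALSE, 12, 12)
  cell <- m; cell[5:7, 5:7] <- TRUE
  chan <- m; chan[4:8, 4:8] <- TRUE; chan <- chan & !cell
  ice <- !cell & !chan
  masks1 <- compartment_masks(cell, ice, m, chan)
  gp1 <- gap_profile(uni[1:12, 1:12], masks1)
  expect_equal(length(gp1$mean_intensity), 1L)

  no_ice <- compartment_masks(cell, m, m, !cell)
  expect_error(gap_profile(uni[1:12, 1:12], no_ice), class = "cryoraman_no_profile")
})

test_that("nucleus-to-cytosol ratio recovers the constructed contrast", {
  sc <- generate_scene(scene_params(seed = 44, nucleus_dmso_factor = 0.95,
                                    noise_sd = 0, heterogeneity_sd = 0))
  an <- analyze_cube(render_cube(sc))
  r <- nucleus_cytosol_ratio(an$maps$dmso, an$maps$dna, an$masks$cell)
  expect_equal(r, 0.95, tolerance = 0.01)

  uni <- matrix(8, 45, 45)
  r1 <- nucleus_cytosol_ratio(uni, an$maps$dna, an$masks$cell)
  expect_equal(r1, 1)

  expect_error(nucleus_cytosol_ratio(an$maps$dmso, matrix(0, 45, 45),
                                     an$masks$cell),
               class = "cryoraman_no_nucleus")
})

test_that("replicate summaries report mean, standard error and Welch comparisons", {
  s <- replicate_summary(c(1, 1, 1))
  expect_equal(s$mean, 1); expect_equal(s$se, 0)

  s2 <- replicate_summary(c(1, 2, 3))
  expect_equal(s2$mean, 2)
  expect_equal(s2$se, 1 / sqrt(3), tolerance = 1e-12)

  same <- replicate_summary(c(1, 2, 3), other = c(1, 2, 3))
  expect_equal(same$comparison$t, 0)
  expect_equal(same$comparison$p, 1)
  expect_false(same$comparison$significant)

  diff_ <- replicate_summary(c(1.0, 1.1, 0.9, 1.05), other = c(2.0, 2.1, 1.9, 2.05))
  expect_true(diff_$comparison$significant)

  expect_error(replicate_summary(1), class = "cryoraman_insufficient_replicates")
  expect_error(replicate_summary(c(1, 2), other = 3),
               class = "cryoraman_insufficient_replicates")
})
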