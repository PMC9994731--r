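test_that("derivative-threshold windows match the brute-force boundary oracle", {
  ax <- tiny_axis(21)
  band <- band_definition("t", ax$wavenumbers_cm1[1] - 1,
                          ax$wavenumbers_cm1[21] + 1, ax$wavenumbers_cm1[11])
  # symmetric triangle, half-width 3: boundary lands on the foot each side
  y <- triangle_spectrum(21, 11, 3, height = 30)
  win <- find_peak_window(y, ax, band)
  expect_equal(c(win$lower_idx, win$upper_idx), c(8, 14))
  expect_equal(win$width_steps, 6)
  ob <- oracle_window(y, 1, 21, 11, 0.1)
  expect_equal(c(win$lower_idx, win$upper_idx), unname(ob))

  # asymmetric piecewise-linear peaks agree with the oracle when no clamping
  # is needed
  for (hw in list(c(2, 3), c(3, 2), c(2, 2))) {
    y2 <- pmax(triangle_spectrum(21, 11, hw[1], 30) * (seq_len(21) <= 11),
               triangle_spectrum(21, 11, hw[2], 30) * (seq_len(21) >= 11))
    w2 <- find_peak_window(y2, ax, band)
    o2 <- oracle_window(y2, 1, 21, 11, 0.1)
    expect_equal(c(w2$lower_idx, w2$upper_idx), unname(o2))
  }
})

test_that("broad peaks clamp into the documented 4-8 step width", {
  ax <- spectral_axis(seq(600, 740, by = 4.83))
  band <- default_bands()$dmso
  y <- gaussian_spectrum(ax, 673, amplitude = 100, sd_steps = 2, baseline = 10)
  win <- find_peak_window(y, ax, band)
  expect_gte(win$width_steps, 4)
  expect_lte(win$width_steps, 8)
  expect_true(win$lower_idx < win$peak_idx && win$peak_idx < win$upper_idx)
})

test_that("flat spectra are flagged and integrate to zero", {
  ax <- tiny_axis(21)
  band <- band_definition("t", ax$wavenumbers_cm1[2], ax$wavenumbers_cm1[20],
                          ax$wavenumbers_cm1[11])
  y <- rep(7, 21)
  win <- find_peak_window(y, ax, band)
  expect_true(win$flat)
  expect_equal(integrate_peak(y, ax, win), 0)
})

test_that("band must overlap the axis over at least nine samples", {
  ax <- tiny_axis(21, from = 650)
  off <- band_definition("off", 3087, 3162, 3125)
  expect_error(find_peak_window(rep(1, 21), ax, off), class = "cryoraman_band_error")
})

test_that("trapezoidal integration is exact on piecewise-linear peaks", {
  ax <- tiny_axis(21)
  band <- band_definition("t", ax$wavenumbers_cm1[1] - 1,
                          ax$wavenumbers_cm1[21] + 1, ax$wavenumbers_cm1[11])
  # triangle height 12 over total base 4 steps: area = 0.5 * 12 * 4 * 4.83
  y <- triangle_spectrum(21, 11, 2, height = 12)
  win <- find_peak_window(y, ax, band)
  expect_equal(c(win$lower_idx, win$upper_idx), c(9, 13))
  expect_equal(integrate_peak(y, ax, win), 115.92, tolerance = 1e-9)
})

test_that("integration is offset-invariant and scale-linear", {
  ax <- tiny_axis(21)
  band <- band_definition("t", ax$wavenumbers_cm1[1] - 1,
                          ax$wavenumbers_cm1[21] + 1, ax$wavenumbers_cm1[11])
  set.seed(3)
  for (r in 1:10) {
    y <- gaussian_spectrum(ax, ax$wavenumbers_cm1[11], amplitude = runif(1, 10, 200),
                           sd_steps = runif(1, 1, 2.5), baseline = runif(1, 0, 50)) +
      stats::rnorm(21, 0, 0.5)
    win <- find_peak_window(y, ax, band)
    base <- integrate_peak(y, ax, win)
    expect_gte(base, 0)
    expect_equal(integrate_peak(y + 37.5, ax, win), base, tolerance = 1e-12)
    a <- runif(1, 0.1, 10)
    expect_equal(integrate_peak(a * y, ax, win), a * base, tolerance = 1e-12)
  }
  win <- find_peak_window(triangle_spectrum(21, 11, 2, 12), ax, band)
  bad <- win; bad$upper_idx <- 40
  expect_error(integrate_peak(rep(1, 21), ax, bad), class = "cryoraman_index_error")
})

test_that("intensity maps are constant for uniform scenes and linear in concentration", {
  sc <- generate_scene(scene_params(seed = 21, heterogeneity_sd = 0, noise_sd = 0))
  cube <- render_cube(sc)
  m <- compute_intensity_map(cube, default_bands()$dmso, analysis_config())
  cell_vals <- m$values[sc$truth_masks$cell]
  expect_lt(diff(range(cell_vals)) / mean(cell_vals), 1e-9)

  sc2 <- generate_scene(scene_params(seed = 22, noise_sd = 0))
  m2 <- compute_intensity_map(render_cube(sc2), default_bands()$dmso,
                              analysis_config())
  r <- stats::cor(as.vector(m2$values),
                  as.vector(sc2$concentration_fields$dmso))
  expect_gte(r, 0.999)
})

test_that("doubling every concentration field doubles the integrated maps", {
  sc <- generate_scene(scene_params(seed = 23, noise_sd = 0))
  sc2 <- sc
  sc2$concentration_fields <- lapply(sc$concentration_fields, function(x) 2 * x)
  m1 <- compute_intensity_map(render_cube(sc), default_bands()$dmso, analysis_config())
  m2 <- compute_intensity_map(render_cube(sc2), default_bands()$dmso, analysis_config())
  nz <- m1$values > 1e-6 * max(m1$values)
  expect_equal(m2$values[nz] / m1$values[nz], rep(2, sum(nz)), tolerance = 1e-9)
})

test_that("spike detection flags exactly the injected artifacts", {
  expect_equal(sum(detect_spikes(matrix(5, 9, 9))), 0)

  set.seed(11)
  smooth <- matrix(10, 15, 15) + stats::rnorm(225, 0, 0.1)
  smooth[7, 9] <- smooth[7, 9] * 100
  flagged <- which(detect_spikes(smooth), arr.ind = TRUE)
  expect_equal(nrow(flagged), 1L)
  expect_equal(unname(flagged[1, ]), c(7L, 9L))

  # smooth radial gradient, brute-force check on a 9x9 instance: no pixel is
  # an outlier relative to its own neighborhood
  g <- outer(1:9, 1:9, function(i, j) 100 - ((i - 5)^2 + (j - 5)^2))
  expect_equal(sum(detect_spikes(g)), 0)
})

test_that("despiking repairs sparse spikes and is idempotent on clean maps", {
  cfg <- analysis_config()
  set.seed(12)
  clean <- matrix(100, 20, 20) + stats::rnorm(400)
  d <- despike_map(clean, cfg)
  expect_identical(d$values, clean)
  expect_equal(d$spike_count, 0L)
  expect_equal(d$despike_passes_used, 1L)

  spiked <- clean
  pos <- rbind(c(3, 4), c(10, 15), c(17, 6))
  for (r in 1:3) spiked[pos[r, 1], pos[r, 2]] <- 5000
  d3 <- despike_map(spiked, cfg)
  expect_equal(d3$spike_count, 3L)
  expect_false(d3$rejected)
  expect_equal(sum(detect_spikes(d3$values, cfg$spike_k)), 0)
  # repaired pixels are back at the local level
  for (r in 1:3) expect_lt(abs(d3$values[pos[r, 1], pos[r, 2]] - 100), 5)

  over <- clean
  idx <- cbind(c(2, 2, 2, 6, 6, 6, 10, 10, 10, 14, 14),
               c(2, 8, 14, 2, 8, 14, 2, 8, 14, 2, 8))
  for (r in 1:11) over[idx[r, 1], idx[r, 2]] <- 5000
  dr <- despike_map(over, cfg)
  expect_true(dr$rejected)
  expect_identical(dr$values, over)
  expect_gt(dr$spike_count, cfg$scatter_reject_threshold)
})

test_that("every pixel of a rendered phantom obeys the 4-8 step window contract", {
  sc <- phantom(24)
  cube <- render_cube(sc)
  cfg <- analysis_config()
  bands <- default_bands()
  widths <- integer(0)
  set.seed(25)
  px <- cbind(sample(45, 60, replace = TRUE), sample(45, 60, replace = TRUE))
  for (b in bands[c("dmso", "ice", "protein")]) {
    for (r in seq_len(nrow(px))) {
      w <- find_peak_window(cube$intensities[px[r, 1], px[r, 2], ], cube$axis, b,
                            cfg$derivative_sensitivity)
      widths <- c(widths, w$width_steps)
    }
  }
  expect_true(all(widths >= 4 & widths <= 8))
})
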