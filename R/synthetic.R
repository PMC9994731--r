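# Ground-truthed synthetic phantoms: a roughly circular cell with a nucleus,
# extracellular ice crystals separated by unfrozen channels, per-band
# concentration fields with a controllable true partitioning ratio, optional
# intracellular ice, heterogeneity, detector noise and cosmic-ray spikes.

#' Parameters of a synthetic scene
#'
#' Defaults reproduce the study's baseline imaging condition: a 45 x 45
#' raster, one centered cell, extracellular ice tiled by unfrozen channels,
#' intracellular heterogeneity with relative spread 0.15 (the coefficient of
#' variation observed for cells frozen in 5-10% DMSO), and a true
#' partitioning ratio just above 1 (1.07, the 10% DMSO / 1 C per min value).
#'
#' @param height,width Raster size in pixels.
#' @param cell_center `(row, col)` of the cell center (default: image center).
#' @param cell_radius,nucleus_radius Disk radii in pixels.
#' @param n_ice_crystals Number of extracellular ice crystals.
#' @param channel_width Width scale of the unfrozen channels between
#'   crystals, and of the unfrozen halo around the cell, in pixels.
#' @param dmso_cell,dmso_channel Intracellular / channel DMSO concentration
#'   levels (arbitrary units); their ratio sets the nominal true P.
#' @param nucleus_dmso_factor Nuclear DMSO level relative to the cytosol.
#' @param intracellular_ice_fraction Target intracellular ice area fraction
#'   (0 disables; pockets are grown to the target within +/- 0.02).
#' @param heterogeneity_sd Relative standard deviation of the lognormal
#'   intracellular DMSO field.
#' @param gradient_toward_ice If `TRUE`, channel DMSO rises with distance
#'   from the ice interface (solute polarization).
#' @param noise_sd Detector noise scale: per-sample Gaussian noise with
#'   sd = `noise_sd` x local signal + floor (floor = 10 x `noise_sd`).
#' @param n_spikes Number of single-sample cosmic-ray spikes.
#' @param spike_amplitude Spike height as a multiple of the maximum clean
#'   signal.
#' @param spike_band Band whose peak region receives the spikes (default
#'   `"dmso"`), so spike counts on that band's map equal `n_spikes`.
#' @param seed Integer seed; geometry, fields, noise and spikes draw from
#'   named substreams derived from it.
#' @return An object of class `scene_params`.
#' @export
scene_params <- function(height = 45L, width = 45L,
                         cell_center = NULL,
                         cell_radius = 10, nucleus_radius = 4,
                         n_ice_crystals = 6L, channel_width = 4,
                         dmso_cell = 30, dmso_channel = 32.1,
                         nucleus_dmso_factor = 1.0,
                         intracellular_ice_fraction = 0,
                         heterogeneity_sd = 0.15,
                         gradient_toward_ice = FALSE,
                         noise_sd = 0.01,
                         n_spikes = 0L, spike_amplitude = 10,
                         spike_band = "dmso",
                         seed = 1L) {
  if (is.null(cell_center)) cell_center <- c((height + 1) / 2, (width + 1) / 2)
  if (cell_center[1] - cell_radius < 4 || cell_center[1] + cell_radius > height - 3 ||
      cell_center[2] - cell_radius < 4 || cell_center[2] + cell_radius > width - 3) {
    cr_abort("cell does not fit inside the image with a 3-pixel border margin",
             "cryoraman_geometry_error")
  }
  if (dmso_cell <= 0 || dmso_channel <= 0) {
    cr_abort("concentrations must be positive", "cryoraman_geometry_error")
  }
  if (intracellular_ice_fraction < 0 || intracellular_ice_fraction >= 1) {
    cr_abort("intracellular_ice_fraction must lie in [0, 1)", "cryoraman_geometry_error")
  }
  structure(as.list(environment()), class = "scene_params")
}

neighbor_count <- function(mask) {
  # number of TRUE pixels among the 8-neighborhood
  n <- matrix(0L, nrow(mask), ncol(mask))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    sh <- shift_mat(mask, dr, dc)
    # zero out the replicated border row/col so off-image counts as FALSE
    if (dr == 1L) sh[1, ] <- FALSE else if (dr == -1L) sh[nrow(sh), ] <- FALSE
    if (dc == 1L) sh[, 1] <- FALSE else if (dc == -1L) sh[, ncol(sh)] <- FALSE
    n <- n + sh
  }
  n
}

#' Named phantom presets for the study conditions
#'
#' Parameter sets emulating the experimental conditions the analysis was
#' applied to: `"baseline"` (10% DMSO at 1 C/min, partitioning ratio ~1.07),
#' `"low-dmso"` (1% DMSO, ratio ~0.21 — cryoprotectant trapped inside the
#' cell, with the elevated intracellular heterogeneity seen there),
#' `"fast-cool"` (5 C/min, ratio ~1.30 — incomplete dehydration), and
#' `"iif"` (rapid cooling with intracellular ice at ~9% of the cell
#' cross-section).
#'
#' @param preset Condition name.
#' @param seed Integer seed.
#' @param ... Overrides passed on to [scene_params()].
#' @return A [scene_params()] object.
#' @export
scene_preset <- function(preset = c("baseline", "low-dmso", "fast-cool", "iif"),
                         seed = 1L, ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
    "baseline"  = list(dmso_cell = 30, dmso_channel = 30 * 1.07),
    "low-dmso"  = list(dmso_cell = 30, dmso_channel = 30 * 0.21,
                       heterogeneity_sd = 0.42),
    "fast-cool" = list(dmso_cell = 30, dmso_channel = 30 * 1.30),
    "iif"       = list(dmso_cell = 30, dmso_channel = 30 * 1.20,
                       intracellular_ice_fraction = 0.09)
  )
  do.call(scene_params, utils::modifyList(c(args, seed = seed), list(...)))
}

chebyshev_to_set <- function(from_idx, to_idx) {
  vapply(seq_len(nrow(from_idx)), function(k) {
    min(pmax(abs(to_idx[, 1] - from_idx[k, 1]), abs(to_idx[, 2] - from_idx[k, 2])))
  }, numeric(1))
}

lognormal_field <- function(n, rel_sd) {
  if (rel_sd <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + rel_sd^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

grow_pockets <- function(cell, n_target, n_seeds) {
  h <- nrow(cell); w <- ncol(cell)
  pocket <- matrix(FALSE, h, w)
  inside <- which(cell)
  seeds <- sample(inside, n_seeds)
  pocket[seeds] <- TRUE
  while (sum(pocket) < n_target) {
    # frontier: cell pixels 4-adjacent to the pocket
    frontier <- (shift_mat(pocket, 1, 0) | shift_mat(pocket, -1, 0) |
                   shift_mat(pocket, 0, 1) | shift_mat(pocket, 0, -1)) &
      cell & !pocket
    cand <- which(frontier)
    if (!length(cand)) break
    need <- n_target - sum(pocket)
    take <- if (length(cand) > need) sample(cand, need) else cand
    pocket[take] <- TRUE
  }
  pocket
}

#' Generate a ground-truthed synthetic scene
#'
#' Builds the geometry (disk cell and nucleus, Voronoi-tiled extracellular
#' ice crystals separated by unfrozen channels of the configured width, an
#' unfrozen halo around the cell, optional intracellular ice pockets grown
#' to the target area fraction) and the per-band concentration fields (DMSO,
#' protein Amide I, ice OH, DNA). DMSO is zero on all ice pixels — the
#' solute is excluded from the ice phase. Deterministic in `params$seed`.
#'
#' @param params A [scene_params()] object.
#' @return An object of class `synthetic_scene` with `params`, `truth_masks`
#'   (a validated `compartment_masks`), `concentration_fields` (named list of
#'   matrices: `dmso`, `protein`, `ice`, `dna`), `true_P`, `true_cv`,
#'   `true_aic`, and the noise/spike substream seeds used by [render_cube()].
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  ss <- sample.int(.Machine$integer.max - 1L, 4L)  # geometry, field, noise, spikes

  h <- params$height; w <- params$width
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  r0 <- params$cell_center[1]; c0 <- params$cell_center[2]
  dcenter <- sqrt((rr - r0)^2 + (cc - c0)^2)
  cell <- dcenter <= params$cell_radius
  nucleus <- dcenter <= params$nucleus_radius

  # -- geometry substream: ice crystal layout and intracellular pockets
  set.seed(ss[1])
  extra <- !cell
  far <- extra & (dcenter > params$cell_radius + params$channel_width + 1)
  seeds_pool <- which(far)
  seeds <- sample(seeds_pool, min(params$n_ice_crystals, length(seeds_pool)))
  sr <- ((seeds - 1L) %% h) + 1L
  sc <- ((seeds - 1L) %/% h) + 1L
  d_seed <- array(0, c(h, w, length(seeds)))
  for (k in seq_along(seeds)) {
    d_seed[, , k] <- sqrt((rr - sr[k])^2 + (cc - sc[k])^2)
  }
  gap <- if (length(seeds) >= 2L) {
    d_sorted <- apply(d_seed, c(1, 2), function(v) sort(v)[1:2])
    (d_sorted[2, , ] - d_sorted[1, , ]) < params$channel_width
  } else matrix(FALSE, h, w)
  halo <- dcenter <= params$cell_radius + params$channel_width
  channel <- extra & (gap | halo)
  ice_out <- extra & !channel
  # crystal-front smoothing: real ice crystals are compact at this
  # resolution, so single-pixel protrusions of either phase are reassigned
  # to the local majority (2 passes)
  for (pass in 1:2) {
    n_ice <- neighbor_count(ice_out)
    n_ch <- neighbor_count(channel)
    flip_to_ch <- ice_out & (n_ch >= n_ice + 3L)
    flip_to_ice <- channel & (n_ice >= n_ch + 3L)
    ice_out <- (ice_out & !flip_to_ch) | flip_to_ice
    channel <- extra & !ice_out
  }
  if (!any(ice_out)) {
    cr_abort("geometry infeasible: no extracellular ice remains",
             "cryoraman_geometry_error")
  }

  ice_in <- matrix(FALSE, h, w)
  if (params$intracellular_ice_fraction > 0) {
    n_target <- max(2L, round(params$intracellular_ice_fraction * sum(cell)))
    n_seeds <- max(1L, min(3L, n_target %/% 6L))
    ice_in <- grow_pockets(cell, n_target, n_seeds)
  }

  # -- field substream: concentration fields
  set.seed(ss[2])
  dmso <- matrix(0, h, w)
  cyto <- cell & !ice_in
  dmso[cyto] <- params$dmso_cell * lognormal_field(sum(cyto), params$heterogeneity_sd)
  nuc_px <- nucleus & cyto
  dmso[nuc_px] <- dmso[nuc_px] * params$nucleus_dmso_factor
  if (params$gradient_toward_ice && any(channel)) {
    ch_idx <- which(channel, arr.ind = TRUE)
    ice_idx <- which(ice_out, arr.ind = TRUE)
    d <- chebyshev_to_set(ch_idx, ice_idx)
    dmax <- max(d)
    f <- if (dmax > 0) 0.7 + 0.6 * d / dmax else rep(1, length(d))
    dmso[channel] <- params$dmso_channel * f
  } else {
    dmso[channel] <- params$dmso_channel
  }

  protein <- matrix(5, h, w)
  protein[cell] <- 100 * lognormal_field(sum(cell), 0.10)

  ice_field <- matrix(20, h, w)
  ice_field[channel] <- 25
  ice_field[ice_out | ice_in] <- 100

  dna <- matrix(0, h, w)
  dna[cyto] <- 4
  dna[nuc_px] <- 40 * lognormal_field(sum(nuc_px), 0.10)

  truth_masks <- compartment_masks(cell, ice_out, ice_in, channel)
  structure(list(
    params = params,
    truth_masks = truth_masks,
    concentration_fields = list(dmso = dmso, protein = protein,
                                ice = ice_field, dna = dna),
    true_P = mean(dmso[channel]) / mean(dmso[cell]),
    true_cv = stats::sd(dmso[cell]) / mean(dmso[cell]),
    true_aic = sum(ice_in) / sum(cell),
    noise_seed = ss[3], spike_seed = ss[4]
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d, true P = %.4f, CV = %.4f, AIC = %.4f\n",
              x$params$height, x$params$width, x$true_P, x$true_cv, x$true_aic))
  invisible(x)
}

sample_sparse_pixels <- function(h, w, n, min_sep = 2L) {
  picked <- matrix(numeric(0), 0, 2)
  tries <- 0L
  while (nrow(picked) < n && tries < 10000L) {
    tries <- tries + 1L
    i <- sample.int(h, 1L); j <- sample.int(w, 1L)
    if (nrow(picked) == 0L ||
        all(pmax(abs(picked[, 1] - i), abs(picked[, 2] - j)) >= min_sep)) {
      picked <- rbind(picked, c(i, j))
    }
  }
  if (nrow(picked) < n) {
    cr_abort("could not place the requested number of sparse spikes",
             "cryoraman_geometry_error")
  }
  picked
}

#' Render a synthetic scene into a spectral cube
#'
#' Each pixel's spectrum is the sum over bands of the pixel's concentration
#' level times a Gaussian line shape centered at the band's starting
#' wavenumber (sd = 2 axis steps), plus a constant baseline, plus zero-mean
#' Gaussian noise with sd proportional to the local clean signal. Cosmic-ray
#' spikes are then injected as single-sample spikes at sparse random pixels
#' within the configured band's peak region. Deterministic in the scene's
#' seed.
#'
#' @param scene A [generate_scene()] result.
#' @param axis A [spectral_axis()] spanning all four band ranges.
#' @param bands Band definitions (default [default_bands()]).
#' @param baseline Constant baseline level in detector units.
#' @return A [spectral_cube()].
#' @export
render_cube <- function(scene, axis = default_axis(), bands = default_bands(),
                        baseline = 20) {
  stopifnot(inherits(scene, "synthetic_scene"))
  wn <- axis$wavenumbers_cm1
  for (b in bands) {
    if (b$range_low_cm1 < min(wn) || b$range_high_cm1 > max(wn)) {
      cr_abort(sprintf("axis does not span band '%s'", b$name),
               "cryoraman_axis_error")
    }
  }
  p <- scene$params
  h <- p$height; w <- p$width; L <- length(wn)
  sigma <- 2 * axis$step_cm1
  band_names <- intersect(names(bands), names(scene$concentration_fields))
  G <- t(vapply(band_names, function(nm) {
    exp(-(wn - bands[[nm]]$initial_cm1)^2 / (2 * sigma^2))
  }, numeric(L)))
  A <- vapply(band_names, function(nm) as.vector(scene$concentration_fields[[nm]]),
              numeric(h * w))
  clean <- A %*% G + baseline                     # (h*w) x L, column-major pixels

  set.seed(scene$noise_seed)
  vals <- if (p$noise_sd > 0) {
    floor_sd <- 10 * p$noise_sd
    clean + matrix(stats::rnorm(length(clean), 0, 1), nrow(clean)) *
      (p$noise_sd * clean + floor_sd)
  } else clean

  if (p$n_spikes > 0) {
    set.seed(scene$spike_seed)
    px <- sample_sparse_pixels(h, w, p$n_spikes, min_sep = 2L)
    center_idx <- which.min(abs(wn - bands[[p$spike_band]]$initial_cm1))
    cand_k <- max(1L, center_idx - 2L):min(L, center_idx + 2L)
    amp <- p$spike_amplitude * max(clean)
    for (s in seq_len(p$n_spikes)) {
      k <- if (length(cand_k) > 1L) sample(cand_k, 1L) else cand_k
      vals[px[s, 1] + (px[s, 2] - 1) * h, k] <- vals[px[s, 1] + (px[s, 2] - 1) * h, k] + amp
    }
  }

  spectral_cube(array(vals, dim = c(h, w, L)), axis)
}
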