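# End-to-end orchestration: spectral cube -> four band maps -> QC ->
# compartment masks -> partitioning statistics, plus the analytic
# lateral-resolution check.

#' Analyze one spectral cube end to end
#'
#' Computes the four band intensity maps, evaluates the scattered-signal
#' rejection rule (by default on the union of the DMSO and ice spike masks,
#' since cosmic rays are band-agnostic), despikes, segments the cell from
#' the Amide I map and the ice from the OH map, derives the unfrozen
#' channels, and computes the partitioning statistics. Cells with extensive
#' intracellular ice (area fraction at or above `config$iif_reject_aic`) are
#' rejected unless `allow_iif = TRUE`.
#'
#' @param cube A [spectral_cube()] or a path to a cube table.
#' @param bands Band definitions (default [default_bands()]); must contain
#'   `dmso`, `protein`, `ice` (and `dna` for the nucleus statistic).
#' @param config An [analysis_config()].
#' @param allow_iif Process cells with extensive intracellular ice instead
#'   of rejecting them.
#' @return An object of class `raman_analysis`: `maps` (named list of
#'   `intensity_map`s), `masks` (`compartment_masks`), `result`
#'   (`partitioning_result`), `scan` (the centroid-row [line_scan()]), and
#'   `manifest` (config echo, input digest, per-stage QC, package version,
#'   timestamp).
#' @export
analyze_cube <- function(cube, bands = default_bands(),
                         config = analysis_config(), allow_iif = FALSE) {
  digest <- NA_character_
  if (is.character(cube)) {
    digest <- unname(tools::md5sum(cube))
    cube <- read_cube(cube)
  }
  stopifnot(inherits(cube, "spectral_cube"))
  required <- c("dmso", "protein", "ice")
  if (!all(required %in% names(bands))) {
    cr_abort("bands must include 'dmso', 'protein' and 'ice'",
             "cryoraman_band_error")
  }

  maps <- lapply(bands, function(b) compute_intensity_map(cube, b, config,
                                                          despike = FALSE))

  # scattered-signal QC: cosmic rays hit all bands, so the rejection rule is
  # evaluated on the union of the DMSO and ice spike masks by default
  spike_masks <- lapply(maps[required[c(1, 3)]],
                        function(m) detect_spikes(m$values, k = config$spike_k))
  n_scatter <- if (config$spike_scope == "union") {
    sum(Reduce(`|`, spike_masks))
  } else {
    max(vapply(spike_masks, sum, integer(1)))
  }
  if (n_scatter > config$scatter_reject_threshold) {
    cr_abort(sprintf("rejected: scattered signal on %d pixels (> %d)",
                     n_scatter, config$scatter_reject_threshold),
             "cryoraman_rejected")
  }
  maps <- lapply(maps, despike_map, config = config)

  masks <- segment_compartments(maps$protein, maps$ice, config)
  result <- partitioning_ratio(maps$dmso, masks, config)

  if (!allow_iif && result$aic >= config$iif_reject_aic) {
    cr_abort(sprintf("rejected: extensive intracellular ice (AIC = %.3f)",
                     result$aic), "cryoraman_iif")
  }

  structure(list(
    maps = maps, masks = masks, result = result,
    scan = line_scan(maps$dmso, masks),
    manifest = list(
      config = unclass(config),
      input_digest = digest,
      dims = c(height = cube$height, width = cube$width,
               samples = length(cube$axis$wavenumbers_cm1)),
      qc = list(
        scattered_pixels = n_scatter,
        spike_counts = vapply(maps, function(m) m$spike_count, integer(1)),
        despike_passes = vapply(maps, function(m) m$despike_passes_used, integer(1)),
        mask_pixels = c(cell = result$n_cell, channel = result$n_channel,
                        ice_in = result$n_ice_in, ice_out = result$n_ice_out)
      ),
      version = as.character(utils::packageVersion("cryoraman")),
      timestamp = format(Sys.time(), tz = "UTC")
    )
  ), class = "raman_analysis")
}

#' @export
print.raman_analysis <- function(x, ...) {
  cat("<raman_analysis>\n")
  print(x$result)
  invisible(x)
}

#' Write a structured results report
#'
#' JSON report holding the partitioning statistics, pixel counts, QC flags
#' and the manifest (everything needed to re-run the analysis
#' bit-identically, except the timestamp).
#'
#' @param analysis A `raman_analysis` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(analysis, path) {
  stopifnot(inherits(analysis, "raman_analysis"))
  r <- analysis$result
  jsonlite::write_json(list(
    P = r$P, C_o = r$C_o, C_i = r$C_i,
    cv_intracellular = r$cv_intracellular, aic = r$aic,
    n_cell = r$n_cell, n_channel = r$n_channel,
    n_ice_in = r$n_ice_in, n_ice_out = r$n_ice_out,
    qc = r$qc, manifest = analysis$manifest
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Abbe lateral-resolution check
#'
#' The diffraction-limited lateral resolution lambda / (2 NA), returned in
#' micrometers. With the instrument's 532 nm excitation and NA 0.90
#' objective this gives 0.296 um, i.e. the ~0.3 um figure quoted for the
#' system. (The Rayleigh variant `0.61 lambda / NA` is available via
#' `rayleigh = TRUE` but does not correspond to that figure.)
#'
#' @param wavelength_nm Excitation wavelength in nanometers (> 0).
#' @param numerical_aperture Objective NA, in (0, 1.5].
#' @param rayleigh Use the 0.61 lambda / NA form instead.
#' @return Resolution in micrometers.
#' @export
abbe_resolution <- function(wavelength_nm, numerical_aperture, rayleigh = FALSE) {
  if (!is.finite(wavelength_nm) || wavelength_nm <= 0 ||
      !is.finite(numerical_aperture) || numerical_aperture <= 0 ||
      numerical_aperture > 1.5) {
    cr_abort("need wavelength > 0 and 0 < NA <= 1.5", "cryoraman_domain_error")
  }
  um <- wavelength_nm / 1000
  if (rayleigh) 0.61 * um / numerical_aperture else um / (2 * numerical_aperture)
}
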