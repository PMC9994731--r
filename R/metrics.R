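# Derived statistics: partitioning ratio (P = C_o / C_i), intracellular
# coefficient of variation, intracellular ice area fraction, line scans,
# extracellular gap profiles, nucleus/cytosol ratio, replicate summaries.

#' Intracellular coefficient of variation
#'
#' Sample (n-1) standard deviation over mean of the map values on the cell
#' mask — the heterogeneity measure of the intracellular cryoprotectant
#' distribution. Scale-invariant by construction.
#'
#' @param dmso_map An `intensity_map` (or matrix).
#' @param cell Logical cell mask (>= 2 pixels).
#' @return Nonnegative ratio.
#' @export
coefficient_of_variation <- function(dmso_map, cell) {
  vals <- if (inherits(dmso_map, "intensity_map")) dmso_map$values else dmso_map
  x <- vals[cell]
  if (length(x) < 2L) {
    cr_abort("coefficient of variation needs >= 2 cell pixels",
             "cryoraman_degenerate_cell")
  }
  m <- mean(x)
  if (m == 0) cr_abort("mean intracellular intensity is zero", "cryoraman_degenerate_cell")
  stats::sd(x) / m
}

#' Intracellular ice area fraction
#'
#' AIC = (cross-sectional area of intracellular ice) / (area of the cell),
#' in pixels; 0 when no intracellular ice is present.
#'
#' @param masks A `compartment_masks` object.
#' @return Ratio in `[0, 1]`.
#' @export
ice_area_fraction <- function(masks) {
  n_cell <- sum(masks$cell)
  if (n_cell < 1L) cr_abort("empty cell mask", "cryoraman_degenerate_cell")
  sum(masks$ice_intracellular) / n_cell
}

#' Partitioning ratio of a cryoprotectant
#'
#' The headline statistic: `P = C_o / C_i`, where `C_o` is the mean
#' background-subtracted integrated DMSO intensity over the unfrozen-channel
#' pixels (never over extracellular ice, which excludes the solute) and
#' `C_i` the mean over the cell pixels. Intracellular-ice pixels count
#' toward `C_i` by default (`config$exclude_iif_from_ci` drops them).
#'
#' @param dmso_map Non-rejected `intensity_map` of the DMSO CS-stretch band.
#' @param masks A `compartment_masks` object.
#' @param config An [analysis_config()].
#' @return An object of class `partitioning_result` with fields `C_o`, `C_i`,
#'   `P`, `cv_intracellular`, `aic`, pixel counts `n_cell`, `n_channel`,
#'   `n_ice_in`, `n_ice_out`, and a `qc` list (`low_confidence` when the cell
#'   has fewer than 50 pixels, plus the map's despiking fields).
#' @export
partitioning_ratio <- function(dmso_map, masks, config = analysis_config()) {
  vals <- if (inherits(dmso_map, "intensity_map")) {
    if (dmso_map$rejected) {
      cr_abort("DMSO map was rejected by QC", "cryoraman_rejected")
    }
    dmso_map$values
  } else dmso_map
  stopifnot(inherits(masks, "compartment_masks"),
            identical(dim(vals), dim(masks$cell)))

  n_cell <- sum(masks$cell)
  n_channel <- sum(masks$channel)
  if (n_channel < 1L) cr_abort("empty channel mask", "cryoraman_empty_channel")
  if (n_cell < 1L) cr_abort("empty cell mask", "cryoraman_degenerate_cell")

  ci_mask <- if (config$exclude_iif_from_ci) {
    masks$cell & !masks$ice_intracellular
  } else masks$cell
  C_i <- mean(vals[ci_mask])
  C_o <- mean(vals[masks$channel])
  if (C_i == 0) cr_abort("mean intracellular DMSO intensity is zero",
                         "cryoraman_degenerate_cell")

  structure(list(
    C_o = C_o, C_i = C_i, P = C_o / C_i,
    cv_intracellular = coefficient_of_variation(vals, masks$cell),
    aic = ice_area_fraction(masks),
    n_cell = n_cell, n_channel = n_channel,
    n_ice_in = sum(masks$ice_intracellular),
    n_ice_out = sum(masks$ice_extracellular),
    qc = list(
      low_confidence = n_cell < 50L,
      spike_count = if (inherits(dmso_map, "intensity_map")) dmso_map$spike_count else NA_integer_,
      despike_passes_used = if (inherits(dmso_map, "intensity_map")) dmso_map$despike_passes_used else NA_integer_,
      rejected = FALSE
    )
  ), class = "partitioning_result")
}

#' @export
print.partitioning_result <- function(x, ...) {
  cat(sprintf("<partitioning_result> P = %.4f (C_o = %.4g, C_i = %.4g)\n",
              x$P, x$C_o, x$C_i))
  cat(sprintf("  CV(intracellular) = %.4f, AIC = %.4f\n", x$cv_intracellular, x$aic))
  cat(sprintf("  pixels: cell %d, channel %d, ice in/out %d/%d%s\n",
              x$n_cell, x$n_channel, x$n_ice_in, x$n_ice_out,
              if (x$qc$low_confidence) "  [low confidence: n_cell < 50]" else ""))
  invisible(x)
}

#' Line scan across a heat map
#'
#' Returns one image row's intensities together with per-pixel compartment
#' labels (`cell`, `ice` for extracellular ice, `channel`). The default row
#' passes through the cell centroid.
#'
#' @param map An `intensity_map` (or matrix).
#' @param masks A `compartment_masks` object.
#' @param row Image row index (default: cell centroid row).
#' @return A list of class `line_scan` with `row`, `values`, `labels`.
#' @export
line_scan <- function(map, masks, row = NULL) {
  vals <- if (inherits(map, "intensity_map")) map$values else map
  if (is.null(row)) row <- round(mask_centroid(masks$cell)["row"])
  row <- as.integer(row)
  if (row < 1L || row > nrow(vals)) {
    cr_abort("line-scan row outside the image", "cryoraman_index_error")
  }
  labels <- ifelse(masks$cell[row, ], "cell",
                   ifelse(masks$ice_extracellular[row, ], "ice", "channel"))
  structure(list(row = row, values = vals[row, ], labels = labels),
            class = "line_scan")
}

#' Partitioning ratio estimated from line scans
#'
#' The cross-validation estimator: mean DMSO intensity over the
#' channel-labeled pixels divided by the mean over the cell-labeled pixels,
#' pooled across a narrow horizontal and vertical band of scans through the
#' cell centroid (`half_width = 1` gives 3-pixel-wide bands; averaging
#' across the scan width suppresses single-row sampling noise, as when a
#' drawn line has finite thickness).
#'
#' @param map `intensity_map` or matrix of DMSO intensity.
#' @param masks A `compartment_masks` object.
#' @param half_width Scan band half-width in pixels.
#' @return The line-scan partitioning-ratio estimate.
#' @export
line_scan_ratio <- function(map, masks, half_width = 1L) {
  vals <- if (inherits(map, "intensity_map")) map$values else map
  ctr <- round(mask_centroid(masks$cell))
  rows <- pmin(pmax(ctr["row"] + (-half_width:half_width), 1L), nrow(vals))
  cols <- pmin(pmax(ctr["col"] + (-half_width:half_width), 1L), ncol(vals))
  sel <- matrix(FALSE, nrow(vals), ncol(vals))
  sel[rows, ] <- TRUE
  sel[, cols] <- TRUE
  cell_px <- vals[sel & masks$cell]
  chan_px <- vals[sel & masks$channel]
  if (!length(cell_px) || !length(chan_px)) {
    cr_abort("line scans do not cross both compartments", "cryoraman_index_error")
  }
  mean(chan_px) / mean(cell_px)
}

#' Extracellular gap profile of DMSO
#'
#' For each unfrozen-channel pixel, the Chebyshev distance to the nearest
#' extracellular-ice pixel is computed; distances are cut into `n_bins`
#' equal-width bins and the mean DMSO intensity of the channel pixels in
#' each bin is reported. A rising profile indicates solute polarization:
#' concentration higher at the gap center than at the ice interface.
#'
#' @param dmso_map `intensity_map` or matrix.
#' @param masks A `compartment_masks` object (ice and channel nonempty).
#' @param n_bins Number of distance bins (default 6).
#' @return A list of class `gap_profile` with `distance_bins` (upper edges),
#'   `mean_intensity`, `n_pixels`.
#' @export
gap_profile <- function(dmso_map, masks, n_bins = 6L) {
  vals <- if (inherits(dmso_map, "intensity_map")) dmso_map$values else dmso_map
  if (!any(masks$ice_extracellular)) {
    cr_abort("no extracellular ice; gap profile undefined", "cryoraman_no_profile")
  }
  if (!any(masks$channel)) {
    cr_abort("no channel pixels; gap profile undefined", "cryoraman_no_profile")
  }
  ch <- which(masks$channel, arr.ind = TRUE)
  ice <- which(masks$ice_extracellular, arr.ind = TRUE)
  d <- vapply(seq_len(nrow(ch)), function(k) {
    min(pmax(abs(ice[, 1] - ch[k, 1]), abs(ice[, 2] - ch[k, 2])))
  }, numeric(1))
  inten <- vals[masks$channel]
  if (length(unique(d)) == 1L) {
    return(structure(list(distance_bins = unique(d),
                          mean_intensity = mean(inten),
                          n_pixels = length(d)), class = "gap_profile"))
  }
  breaks <- seq(min(d) - 0.5, max(d) + 0.5, length.out = n_bins + 1L)
  bin <- cut(d, breaks, labels = FALSE)
  keep <- sort(unique(bin))
  structure(list(
    distance_bins = breaks[-1][keep],
    mean_intensity = vapply(keep, function(b) mean(inten[bin == b]), numeric(1)),
    n_pixels = vapply(keep, function(b) sum(bin == b), numeric(1))
  ), class = "gap_profile")
}

#' Nucleus-to-cytosol DMSO ratio
#'
#' The nucleus is segmented as the DNA (O-P-O) intensity at or above an
#' automatic bimodal threshold within the cell; the statistic is the mean
#' DMSO intensity over the nucleus divided by the mean over the remaining
#' (cytosolic) cell pixels.
#'
#' @param dmso_map,dna_map `intensity_map`s (or matrices); the DNA map must
#'   not be QC-rejected.
#' @param cell Logical cell mask.
#' @return Ratio of nuclear to cytosolic mean DMSO intensity.
#' @export
nucleus_cytosol_ratio <- function(dmso_map, dna_map, cell) {
  dmso <- if (inherits(dmso_map, "intensity_map")) dmso_map$values else dmso_map
  if (inherits(dna_map, "intensity_map")) {
    if (dna_map$rejected) cr_abort("DNA map was rejected by QC", "cryoraman_rejected")
    dna <- dna_map$values
  } else dna <- dna_map
  if (!any(cell)) cr_abort("empty cell mask", "cryoraman_degenerate_cell")
  th <- otsu_threshold_subset(dna[cell])
  if (is.na(th)) cr_abort("no nucleus found (degenerate DNA signal)",
                          "cryoraman_no_nucleus")
  nucleus <- cell & (dna >= th)
  cytosol <- cell & !nucleus
  if (!any(nucleus) || !any(cytosol)) {
    cr_abort("nucleus segmentation degenerate", "cryoraman_no_nucleus")
  }
  mean(dmso[nucleus]) / mean(dmso[cytosol])
}

otsu_threshold_subset <- function(vals) {
  rg <- range(vals)
  if (diff(rg) <= 0) return(NA_real_)
  otsu_threshold(matrix(vals, nrow = 1))
}

#' Manual-region partitioning ratio
#'
#' The hand-validation estimator: the partitioning ratio recomputed from
#' manually selected pixel regions instead of the automated masks, as an
#' analyst would click more than 50 unambiguous pixels per compartment. Cell
#' pixels are drawn from the interior of the reference cell mask (pixels
#' whose 4-neighbors all lie in the cell, avoiding the boundary) and channel
#' pixels from channel regions not adjacent to the cell. Used to
#' cross-validate [partitioning_ratio()].
#'
#' @param dmso_map `intensity_map` or matrix of DMSO intensity.
#' @param masks Reference `compartment_masks` (e.g. a phantom's truth masks).
#' @param n_pixels Pixels drawn per compartment (>= 50; capped at the number
#'   available).
#' @param seed Integer seed for the draw.
#' @return The manual-region estimate of P.
#' @export
manual_region_ratio <- function(dmso_map, masks, n_pixels = 100L, seed = 1L) {
  vals <- if (inherits(dmso_map, "intensity_map")) dmso_map$values else dmso_map
  interior <- masks$cell &
    shift_mat(masks$cell, 1, 0) & shift_mat(masks$cell, -1, 0) &
    shift_mat(masks$cell, 0, 1) & shift_mat(masks$cell, 0, -1)
  near_cell <- masks$cell | (neighbor_count(masks$cell) > 0L)
  deep_channel <- masks$channel & !near_cell
  if (sum(interior) < 50L || sum(deep_channel) < 50L) {
    cr_abort("fewer than 50 unambiguous pixels available per compartment",
             "cryoraman_degenerate_cell")
  }
  set.seed(seed)
  px_cell <- sample(which(interior), min(n_pixels, sum(interior)))
  px_chan <- sample(which(deep_channel), min(n_pixels, sum(deep_channel)))
  mean(vals[px_chan]) / mean(vals[px_cell])
}

#' Summarize per-cell partitioning ratios across replicates
#'
#' Mean and standard error of a group of per-cell values; when a second
#' group is supplied, a two-sample t-test (Welch by default) with two-sided
#' p-value and a significance flag at 0.05.
#'
#' @param per_cell_P Numeric vector, length >= 2.
#' @param other Optional second group, length >= 2.
#' @param welch Use the Welch unequal-variance test (default) rather than the
#'   pooled-variance Student test.
#' @return A list of class `replicate_summary` with `n`, `mean`, `se` and,
#'   when `other` is given, `comparison` (`t`, `df`, `p`, `significant`).
#' @export
replicate_summary <- function(per_cell_P, other = NULL, welch = TRUE) {
  if (length(per_cell_P) < 2L || (!is.null(other) && length(other) < 2L)) {
    cr_abort("replicate summaries need >= 2 values per group",
             "cryoraman_insufficient_replicates")
  }
  out <- list(n = length(per_cell_P), mean = mean(per_cell_P),
              se = stats::sd(per_cell_P) / sqrt(length(per_cell_P)),
              comparison = NULL)
  if (!is.null(other)) {
    tt <- stats::t.test(per_cell_P, other, var.equal = !welch)
    out$comparison <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                           p = tt$p.value, significant = tt$p.value < 0.05)
  }
  structure(out, class = "replicate_summary")
}
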