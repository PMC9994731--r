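# Compartment segmentation: cell mask from the Amide I map via the classical
# edge-detect / dilate / fill / clear-border / smooth morphological chain,
# ice masks by bimodal thresholding of the OH map, unfrozen channels as the
# extracellular complement.

shift_mat <- function(m, dr, dc) {
  # shift with replicated borders (exact arithmetic; no FFT roundoff)
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

sobel_magnitude <- function(m) {
  gx <- (shift_mat(m, -1, -1) + 2 * shift_mat(m, 0, -1) + shift_mat(m, 1, -1)) -
        (shift_mat(m, -1,  1) + 2 * shift_mat(m, 0,  1) + shift_mat(m, 1,  1))
  gy <- (shift_mat(m, -1, -1) + 2 * shift_mat(m, -1, 0) + shift_mat(m, -1, 1)) -
        (shift_mat(m,  1, -1) + 2 * shift_mat(m,  1, 0) + shift_mat(m,  1, 1))
  sqrt(gx^2 + gy^2)
}

#' Detect edge pixels of an intensity map
#'
#' Sobel gradient magnitude thresholded at `sensitivity` times an automatic
#' level (four times the mean gradient magnitude of the image, the
#' convention of classical gradient edge detectors). Lower sensitivity
#' admits more edge pixels.
#'
#' @param values Numeric matrix.
#' @param sensitivity Multiplier in `[0.5, 0.9]`.
#' @return Logical edge mask.
#' @export
detect_edges <- function(values, sensitivity = 0.65) {
  g <- sobel_magnitude(values)
  auto <- 4 * mean(g)
  g > sensitivity * auto
}

label_components <- function(mask) {
  # 4-connected labeling (EBImage::bwlabel, verified 4-connected)
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask)))
  matrix(as.integer(lab), nrow(mask))
}

clear_border <- function(mask) {
  lab <- label_components(mask)
  h <- nrow(mask); w <- ncol(mask)
  touching <- unique(c(lab[1, ], lab[h, ], lab[, 1], lab[, w]))
  touching <- touching[touching > 0L]
  mask & !(lab %in% touching)
}

as_binary <- function(x) matrix(as.numeric(x) > 0.5, nrow(x))

diamond_brush <- function() matrix(c(0, 1, 0, 1, 1, 1, 0, 1, 0), 3, 3)

#' Segment the cell from the Amide I intensity map
#'
#' The chain: (1) Sobel gradient-magnitude edge detection thresholded at
#' `edge_sensitivity` times the automatic level; (2) dilation of the binary
#' edge image with two perpendicular line structuring elements (length
#' `line_strel_length`, orientations 0 and 90 degrees); (3) hole filling;
#' (4) clearing of components touching the image border; (5) smoothing by
#' one erosion (`smooth_strel`: a 5x5 box matched to the accumulated
#' dilation, or a radius-1 diamond); (6) the largest remaining 4-connected
#' component is returned as the cell.
#'
#' @param amide_map Despiked, non-rejected `intensity_map` (or matrix) of the
#'   protein Amide I band.
#' @param config An [analysis_config()].
#' @return Logical cell mask (single 4-connected component, off-border).
#' @export
segment_cell <- function(amide_map, config = analysis_config()) {
  vals <- if (inherits(amide_map, "intensity_map")) {
    if (amide_map$rejected) {
      cr_abort("map was rejected by QC; refusing to segment", "cryoraman_rejected")
    }
    amide_map$values
  } else amide_map
  if (nrow(vals) < 9L || ncol(vals) < 9L) {
    cr_abort("segmentation needs at least a 9 x 9 raster", "cryoraman_shape_error")
  }

  edges <- detect_edges(vals, config$edge_sensitivity)
  if (!any(edges)) cr_abort("no edges detected; no cell found", "cryoraman_no_cell")

  len <- config$line_strel_length
  line_h <- matrix(1, 1, len)
  line_v <- matrix(1, len, 1)
  dil <- as_binary(EBImage::dilate(matrix(as.numeric(edges), nrow(edges)), line_h))
  dil <- as_binary(EBImage::dilate(matrix(as.numeric(dil), nrow(dil)), line_v))

  filled <- as_binary(EBImage::fillHull(matrix(as.numeric(dil), nrow(dil))))
  cleared <- clear_border(filled)
  kern <- if (config$smooth_strel == "box5") matrix(1, 5, 5) else diamond_brush()
  smoothed <- as_binary(EBImage::erode(matrix(as.numeric(cleared), nrow(cleared)), kern))

  lab <- label_components(smoothed)
  if (max(lab) == 0L) cr_abort("no cell component survives the chain", "cryoraman_no_cell")
  sizes <- tabulate(lab[lab > 0L])
  cell <- lab == which.max(sizes)
  if (sum(cell) < 50L) {
    cr_abort(sprintf("largest component has %d pixels (< 50)", sum(cell)),
             "cryoraman_too_small")
  }
  cell
}

otsu_threshold <- function(vals) {
  rg <- range(vals)
  if (diff(rg) <= 0) return(NA_real_)
  x <- matrix((vals - rg[1]) / diff(rg), nrow = 1)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  rg[1] + th * diff(rg)
}

#' Segment extracellular and intracellular ice from the OH intensity map
#'
#' Ice pixels are those at or above an automatic bimodal (Otsu) threshold
#' over the whole map (or a manual threshold from the config), split by the
#' cell mask. Intracellular single-pixel components are discarded as shot
#' noise. A degenerate (constant) map yields empty masks.
#'
#' @param ice_map Despiked `intensity_map` (or matrix) of the OH stretch band.
#' @param cell Logical cell mask from [segment_cell()].
#' @param config An [analysis_config()].
#' @return List with logical `ice_extracellular` and `ice_intracellular`.
#' @export
segment_ice <- function(ice_map, cell, config = analysis_config()) {
  vals <- if (inherits(ice_map, "intensity_map")) ice_map$values else ice_map
  stopifnot(identical(dim(vals), dim(cell)))
  th <- if (identical(config$ice_threshold, "otsu")) {
    otsu_threshold(vals)
  } else as.numeric(config$ice_threshold)
  if (is.na(th)) {
    empty <- matrix(FALSE, nrow(vals), ncol(vals))
    return(list(ice_extracellular = empty, ice_intracellular = empty))
  }
  ice <- vals >= th
  ice_out <- ice & !cell
  ice_in <- ice & cell
  if (any(ice_in)) {
    lab <- label_components(ice_in)
    sizes <- tabulate(lab[lab > 0L])
    singletons <- which(sizes == 1L)
    if (length(singletons)) ice_in <- ice_in & !(lab %in% singletons)
  }
  list(ice_extracellular = ice_out, ice_intracellular = ice_in)
}

#' Derive the unfrozen-channel mask
#'
#' The extracellular space partitions into ice and unfrozen channel:
#' `channel = !cell & !ice_extracellular`.
#'
#' @param cell,ice_extracellular Logical masks of identical shape.
#' @return Logical channel mask.
#' @export
derive_channels <- function(cell, ice_extracellular) {
  stopifnot(identical(dim(cell), dim(ice_extracellular)))
  channel <- !cell & !ice_extracellular
  if (!any(channel)) {
    cr_abort("unfrozen channel is empty; C_o undefined", "cryoraman_empty_channel")
  }
  channel
}

#' Bundle and validate compartment masks
#'
#' Checks the partition invariants: cell, extracellular ice and channel are
#' pairwise disjoint and jointly cover the raster; intracellular ice lies
#' inside the cell.
#'
#' @param cell,ice_extracellular,ice_intracellular,channel Logical matrices
#'   of identical shape.
#' @return An object of class `compartment_masks`.
#' @export
compartment_masks <- function(cell, ice_extracellular, ice_intracellular,
                              channel) {
  stopifnot(identical(dim(cell), dim(ice_extracellular)),
            identical(dim(cell), dim(ice_intracellular)),
            identical(dim(cell), dim(channel)))
  if (any(cell & ice_extracellular) || any(cell & channel) ||
      any(ice_extracellular & channel)) {
    cr_abort("cell / extracellular ice / channel masks overlap",
             "cryoraman_mask_error")
  }
  if (any(ice_intracellular & !cell)) {
    cr_abort("intracellular ice outside the cell mask", "cryoraman_mask_error")
  }
  if (!all(cell | ice_extracellular | channel)) {
    cr_abort("masks do not cover the raster", "cryoraman_mask_error")
  }
  structure(list(cell = cell, ice_extracellular = ice_extracellular,
                 ice_intracellular = ice_intracellular, channel = channel),
            class = "compartment_masks")
}

#' Segment all compartments of one image
#'
#' Convenience wrapper: [segment_cell()] on the Amide I map, [segment_ice()]
#' on the OH map, [derive_channels()], bundled through [compartment_masks()].
#'
#' @param amide_map,ice_map Despiked `intensity_map`s.
#' @param config An [analysis_config()].
#' @return A `compartment_masks` object.
#' @export
segment_compartments <- function(amide_map, ice_map, config = analysis_config()) {
  cell <- segment_cell(amide_map, config)
  ice <- segment_ice(ice_map, cell, config)
  channel <- derive_channels(cell, ice$ice_extracellular)
  compartment_masks(cell, ice$ice_extracellular, ice$ice_intracellular, channel)
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(row = mean(idx[, 1]), col = mean(idx[, 2]))
}
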