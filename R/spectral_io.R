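# Classed errors so callers (and the analysis scripts) can branch on the
# failure mode rather than on message text.
cr_abort <- function(message, class) {
  stop(structure(
    class = c(class, "cryoraman_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

#' Construct a spectral axis
#'
#' A shared wavenumber axis for every pixel of a spectral cube. The axis must
#' be strictly increasing and close to uniformly spaced: all "step"-denominated
#' rules downstream (the 4--8 step peak-width contract) count samples on this
#' axis, so the nominal step is derived from the axis itself rather than
#' assumed.
#'
#' @param wavenumbers_cm1 Numeric vector of wavenumbers (cm^-1), strictly
#'   increasing, length >= 2.
#' @param step_cm1 Nominal spacing in cm^-1. Defaults to the median successive
#'   difference of `wavenumbers_cm1`. Successive differences may deviate from
#'   it by at most 10%.
#' @return An object of class `spectral_axis`.
#' @export
spectral_axis <- function(wavenumbers_cm1, step_cm1 = stats::median(diff(wavenumbers_cm1))) {
  wavenumbers_cm1 <- as.numeric(wavenumbers_cm1)
  if (length(wavenumbers_cm1) < 2L || anyNA(wavenumbers_cm1)) {
    cr_abort("spectral axis needs >= 2 finite wavenumbers", "cryoraman_axis_error")
  }
  d <- diff(wavenumbers_cm1)
  if (any(d <= 0)) {
    cr_abort("spectral axis must be strictly increasing", "cryoraman_axis_error")
  }
  if (!is.finite(step_cm1) || step_cm1 <= 0) {
    cr_abort("step_cm1 must be a positive number", "cryoraman_axis_error")
  }
  if (max(abs(d - step_cm1)) > 0.1 * step_cm1) {
    cr_abort("axis spacing deviates from nominal step by more than 10%",
             "cryoraman_axis_error")
  }
  structure(list(wavenumbers_cm1 = wavenumbers_cm1, step_cm1 = step_cm1),
            class = "spectral_axis")
}

#' Default spectral axis for the shipped phantoms
#'
#' Spans all four default band search ranges at the instrument's nominal
#' 4.83 cm^-1 per step.
#' @param from,to Axis limits in cm^-1.
#' @param step_cm1 Spacing in cm^-1.
#' @return A `spectral_axis`.
#' @export
default_axis <- function(from = 600, to = 3250, step_cm1 = 4.83) {
  spectral_axis(seq(from, to, by = step_cm1), step_cm1 = step_cm1)
}

#' Construct a spectral cube
#'
#' The raw H x W raster of per-pixel Raman spectra on a shared axis. Pixels
#' are addressed `(row, col)` row-major from the top-left.
#'
#' @param intensities Numeric array of dimension `c(height, width, length(axis))`,
#'   all values finite.
#' @param axis A [spectral_axis()].
#' @return An object of class `spectral_cube` with fields `height`, `width`,
#'   `axis`, `intensities`.
#' @export
spectral_cube <- function(intensities, axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    cr_abort("intensities must be a 3-d array (row, col, axis index)",
             "cryoraman_shape_error")
  }
  dm <- dim(intensities)
  if (dm[3] != length(axis$wavenumbers_cm1)) {
    cr_abort("third dimension must match the axis length", "cryoraman_shape_error")
  }
  if (dm[1] < 3L || dm[2] < 3L) {
    cr_abort("cube must be at least 3 x 3 pixels", "cryoraman_shape_error")
  }
  if (!all(is.finite(intensities))) {
    cr_abort("all intensities must be finite", "cryoraman_shape_error")
  }
  structure(list(height = dm[1], width = dm[2], axis = axis,
                 intensities = intensities),
            class = "spectral_cube")
}

#' @export
print.spectral_cube <- function(x, ...) {
  cat(sprintf("<spectral_cube> %d x %d pixels, %d samples (%.2f-%.2f cm^-1, step %.3f)\n",
              x$height, x$width, length(x$axis$wavenumbers_cm1),
              min(x$axis$wavenumbers_cm1), max(x$axis$wavenumbers_cm1),
              x$axis$step_cm1))
  invisible(x)
}

#' Define a Raman band
#'
#' A band is a search range on the wavenumber axis plus the starting
#' wavenumber near which the peak maximum is sought.
#'
#' @param name Label (e.g. `"dmso"`).
#' @param range_low_cm1,range_high_cm1 Search bounds (cm^-1).
#' @param initial_cm1 Starting wavenumber, strictly inside the range.
#' @param assignment Free-text vibrational assignment.
#' @return An object of class `band_definition`.
#' @export
band_definition <- function(name, range_low_cm1, range_high_cm1, initial_cm1,
                            assignment = "") {
  if (!(range_low_cm1 < initial_cm1 && initial_cm1 < range_high_cm1)) {
    cr_abort(sprintf("band '%s': need range_low < initial < range_high", name),
             "cryoraman_band_error")
  }
  structure(list(name = name, range_low_cm1 = range_low_cm1,
                 range_high_cm1 = range_high_cm1, initial_cm1 = initial_cm1,
                 assignment = assignment),
            class = "band_definition")
}

#' Default band definitions
#'
#' The four marker bands used throughout: the ice OH stretch, the protein
#' Amide I / alkyl C=C stretch marking the cell, the symmetric CS stretch of
#' DMSO, and the O-P-O backbone stretch of DNA marking the nucleus. The
#' protein/lipid search range is taken symmetric about its 1660 cm^-1
#' starting wavenumber (1610--1710), in line with the ~75--95 cm^-1 spans of
#' the other bands.
#'
#' @return Named list of [band_definition()] objects
#'   (`ice`, `protein`, `dmso`, `dna`).
#' @export
default_bands <- function() {
  list(
    ice     = band_definition("ice",     3087, 3162, 3125, "OH stretching"),
    protein = band_definition("protein", 1610, 1710, 1660, "Amide I/alkyl C=C stretching"),
    dmso    = band_definition("dmso",     650,  740,  673, "Symmetric CS stretching"),
    dna     = band_definition("dna",      760,  810,  785, "O-P-O stretching of DNA")
  )
}

#' Analysis configuration
#'
#' Tunable parameters of the pipeline, with the defaults used throughout the
#' study: derivative-threshold sensitivity 0.1 for peak-width detection,
#' edge-detection sensitivity 0.65 (allowed 0.5--0.9) for cell segmentation,
#' at most 3 despiking passes, and rejection of an image when more than 10
#' pixels carry scattered (cosmic-ray) signal.
#'
#' @param derivative_sensitivity Flank-flattening ratio in (0, 1).
#' @param edge_sensitivity Multiplier on the automatic gradient threshold,
#'   in `[0.5, 0.9]`; lower values admit more edges.
#' @param max_despike_passes Maximum neighbor-average replacement rounds (1--3).
#' @param scatter_reject_threshold Spike-pixel count above which the image is
#'   rejected unmodified.
#' @param min_peak_steps,max_peak_steps Width clamp for integrated peaks, in
#'   axis steps.
#' @param spike_k Robust z cutoff of the median/MAD spike detector.
#' @param spike_scope `"union"` evaluates the rejection rule on the union of
#'   the DMSO and ice spike masks (cosmic rays are band-agnostic);
#'   `"per_band"` evaluates each map alone.
#' @param line_strel_length Length of the two perpendicular line structuring
#'   elements used to dilate the edge image.
#' @param smooth_strel Structuring element of the final smoothing erosion:
#'   `"box5"` (default; matched to the accumulated dilation so convex cells
#'   are recovered exactly) or `"diamond1"`.
#' @param ice_threshold `"otsu"` or a numeric manual threshold for the ice
#'   mask.
#' @param exclude_iif_from_ci If `TRUE`, intracellular-ice pixels are dropped
#'   from the intracellular mean `C_i`.
#' @param iif_reject_aic Intracellular ice area fraction at or above which
#'   [analyze_cube()] treats the cell as exhibiting extensive intracellular
#'   ice and rejects it (unless `allow_iif`).
#' @param welch If `TRUE` (default) replicate comparisons use the Welch
#'   unequal-variance t-test; otherwise the pooled-variance Student t-test.
#' @param rng_seed Integer seed for any stochastic step.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(derivative_sensitivity = 0.1,
                            edge_sensitivity = 0.65,
                            max_despike_passes = 3L,
                            scatter_reject_threshold = 10L,
                            min_peak_steps = 4L,
                            max_peak_steps = 8L,
                            spike_k = 5,
                            spike_scope = c("union", "per_band"),
                            line_strel_length = 3L,
                            smooth_strel = c("box5", "diamond1"),
                            ice_threshold = "otsu",
                            exclude_iif_from_ci = FALSE,
                            iif_reject_aic = 0.05,
                            welch = TRUE,
                            rng_seed = 1L) {
  spike_scope <- match.arg(spike_scope)
  smooth_strel <- match.arg(smooth_strel)
  if (!(derivative_sensitivity > 0 && derivative_sensitivity < 1)) {
    cr_abort("derivative_sensitivity must lie in (0, 1)", "cryoraman_config_error")
  }
  if (!(edge_sensitivity >= 0.5 && edge_sensitivity <= 0.9)) {
    cr_abort("edge_sensitivity must lie in [0.5, 0.9]", "cryoraman_config_error")
  }
  if (!(max_despike_passes >= 1L && max_despike_passes <= 3L)) {
    cr_abort("max_despike_passes must lie in 1..3", "cryoraman_config_error")
  }
  if (min_peak_steps > max_peak_steps) {
    cr_abort("min_peak_steps must be <= max_peak_steps", "cryoraman_config_error")
  }
  structure(list(
    derivative_sensitivity = derivative_sensitivity,
    edge_sensitivity = edge_sensitivity,
    max_despike_passes = as.integer(max_despike_passes),
    scatter_reject_threshold = as.integer(scatter_reject_threshold),
    min_peak_steps = as.integer(min_peak_steps),
    max_peak_steps = as.integer(max_peak_steps),
    spike_k = spike_k,
    spike_scope = spike_scope,
    line_strel_length = as.integer(line_strel_length),
    smooth_strel = smooth_strel,
    ice_threshold = ice_threshold,
    exclude_iif_from_ci = isTRUE(exclude_iif_from_ci),
    iif_reject_aic = iif_reject_aic,
    welch = isTRUE(welch),
    rng_seed = as.integer(rng_seed)
  ), class = "analysis_config")
}

# ---- cube table IO ---------------------------------------------------------

#' Write a spectral cube to a plain-text table
#'
#' Line 1 declares the raster shape (`# height=H width=W`); an optional second
#' comment line carries metadata; each following row holds one axis sample:
#' the wavenumber followed by the H*W pixel intensities in row-major order.
#' Values are written at full double precision so the file round-trips
#' exactly.
#'
#' @param cube A [spectral_cube()].
#' @param path Output file path.
#' @param meta Optional named character vector written as `# meta k=v ...`.
#' @param sep Delimiter, tab (default) or comma.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, meta = NULL, sep = "\t") {
  stopifnot(inherits(cube, "spectral_cube"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# height=%d width=%d", cube$height, cube$width), con)
  if (!is.null(meta)) {
    writeLines(paste("# meta", paste(names(meta), unname(meta), sep = "=",
                                     collapse = " ")), con)
  }
  n <- length(cube$axis$wavenumbers_cm1)
  # row-major pixel order: (0,0), (0,1), ..., i.e. transpose of R's column-major
  flat <- matrix(aperm(cube$intensities, c(2, 1, 3)),
                 nrow = cube$height * cube$width, ncol = n)
  for (k in seq_len(n)) {
    writeLines(paste(sprintf("%.17g", c(cube$axis$wavenumbers_cm1[k], flat[, k])),
                     collapse = sep), con)
  }
  invisible(path)
}

#' Read a spectral cube from a plain-text table
#'
#' Parses the dialect written by [write_cube()]. The delimiter (tab or comma)
#' is auto-detected from the first data line.
#'
#' @param path File path.
#' @return A validated [spectral_cube()].
#' @export
read_cube <- function(path) {
  if (!file.exists(path)) {
    cr_abort(sprintf("no such file: %s", path), "cryoraman_format_error")
  }
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 3L) {
    cr_abort("cube file too short", "cryoraman_format_error")
  }
  m <- regmatches(lines[1],
                  regexec("^#\\s*height=(\\d+)\\s+width=(\\d+)\\s*$", lines[1]))[[1]]
  if (length(m) != 3L) {
    cr_abort("malformed header: expected '# height=H width=W'",
             "cryoraman_format_error")
  }
  h <- as.integer(m[2]); w <- as.integer(m[3])
  data_lines <- lines[-1]
  data_lines <- data_lines[!grepl("^#", data_lines)]
  data_lines <- data_lines[nzchar(data_lines)]
  sep <- if (grepl(",", data_lines[1], fixed = TRUE)) "," else "\t"
  rows <- strsplit(data_lines, sep, fixed = TRUE)
  ncols <- lengths(rows)
  if (any(ncols != ncols[1])) {
    cr_abort("ragged rows in cube table", "cryoraman_format_error")
  }
  if (ncols[1] != 1L + h * w) {
    cr_abort(sprintf("expected %d spectral columns for %dx%d pixels, found %d",
                     h * w, h, w, ncols[1] - 1L), "cryoraman_shape_error")
  }
  vals <- matrix(as.numeric(unlist(rows)), nrow = ncols[1])
  if (anyNA(vals)) cr_abort("non-numeric entries in cube table", "cryoraman_format_error")
  wn <- vals[1, ]
  if (any(diff(wn) <= 0)) {
    cr_abort("wavenumber axis is not strictly increasing", "cryoraman_axis_error")
  }
  axis <- spectral_axis(wn)
  flat <- vals[-1, , drop = FALSE]                  # (h*w) x n, row-major pixels
  arr <- aperm(array(flat, dim = c(w, h, length(wn))), c(2, 1, 3))
  spectral_cube(arr, axis)
}

# ---- band config IO --------------------------------------------------------

#' Read / write band definitions
#'
#' Band definitions are stored as a YAML map: one entry per band with `low`,
#' `high`, `initial` (cm^-1) and `assignment`. The shipped default
#' (`system.file("extdata", "bands_default.yml", package = "cryoraman")`)
#' mirrors [default_bands()].
#'
#' @param path File path.
#' @return `read_bands()`: a named list of [band_definition()] objects.
#' @export
read_bands <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    b <- raw[[nm]]
    band_definition(nm, b$low, b$high, b$initial,
                    assignment = if (is.null(b$assignment)) "" else b$assignment)
  })
  names(out) <- names(raw)
  out
}

#' @rdname read_bands
#' @param bands Named list of [band_definition()] objects.
#' @export
write_bands <- function(bands, path) {
  yaml::write_yaml(lapply(bands, function(b) {
    list(low = b$range_low_cm1, high = b$range_high_cm1,
         initial = b$initial_cm1, assignment = b$assignment)
  }), path)
  invisible(path)
}

# ---- mask export -----------------------------------------------------------

#' Export or read a binary mask
#'
#' Masks are written as 0/1 text grids (one image row per line, space
#' separated); `format = "png"` additionally supports portable grayscale
#' images when the `png` package is available.
#'
#' @param mask Logical matrix.
#' @param path Output path.
#' @param format `"text"` or `"png"`.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path, format = c("text", "png")) {
  format <- match.arg(format)
  if (format == "text") {
    writeLines(apply(matrix(as.integer(mask), nrow(mask)), 1L, paste, collapse = " "),
               path)
  } else {
    if (!requireNamespace("png", quietly = TRUE)) {
      cr_abort("png package not available for format='png'", "cryoraman_format_error")
    }
    png::writePNG(matrix(as.numeric(mask), nrow(mask)), path)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  rows <- strsplit(trimws(readLines(path)), "\\s+")
  m <- do.call(rbind, lapply(rows, as.integer))
  m == 1L
}
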