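# Shared fixtures: all phantoms are generated in code at test time.

# a small axis for unit-level spectral tests
tiny_axis <- function(n = 21, from = 650, step = 4.83) {
  spectral_axis(seq(from, by = step, length.out = n))
}

# triangular peak of given half-width (steps) centered at index `center`
triangle_spectrum <- function(n, center, half_width, height, baseline = 0) {
  x <- abs(seq_len(n) - center)
  baseline + pmax(0, height * (1 - x / half_width))
}

gaussian_spectrum <- function(axis, center_cm1, amplitude, sd_steps = 2,
                              baseline = 0) {
  wn <- axis$wavenumbers_cm1
  baseline + amplitude * exp(-(wn - center_cm1)^2 / (2 * (sd_steps * axis$step_cm1)^2))
}

# brute-force oracle for the derivative-threshold boundary rule: scan every
# candidate index outward from the peak and apply the stopping condition
# directly (independent of the implementation's walk)
oracle_window <- function(y, lo, hi, p, sensitivity) {
  lower <- lo
  for (x in (p - 1):lo) {
    if (x - 1 < 1) { lower <- x; break }
    s_out <- y[x - 1] - y[x]
    s_in <- y[x] - y[x + 1]
    if (abs(s_out) <= sensitivity * abs(s_in)) { lower <- x; break }
    lower <- x
  }
  upper <- hi
  for (x in (p + 1):hi) {
    if (x + 1 > length(y)) { upper <- x; break }
    s_out <- y[x + 1] - y[x]
    s_in <- y[x] - y[x - 1]
    if (abs(s_out) <= sensitivity * abs(s_in)) { upper <- x; break }
    upper <- x
  }
  c(lower = lower, upper = upper)
}

# default-condition phantom of the requested nominal true P
phantom <- function(seed, true_P = 1.07, ...) {
  generate_scene(scene_params(seed = seed, dmso_cell = 30,
                              dmso_channel = 30 * true_P, ...))
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)
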