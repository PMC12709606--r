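#' Simulate focused RF channel data for a phantom
#'
#' Produces per-scan-line element x time-sample arrays of focused receive
#' signals using a single-scattering, attenuation-free linear model. Each
#' line fires a focused transmit from a walking aperture centered on the
#' line (the transmit waveform at a scatterer is the superposition of
#' per-element Gaussian-windowed tones with focal delays), and each receive
#' element records the spherically spread (1/r) echo delayed by the
#' scatterer-to-element path.
#'
#' Lesions with a positive `clutter_level` additionally inject band-limited
#' noise into the channel signals at time samples whose round-trip depth
#' falls inside the lesion. The noise is a mixture of an element-correlated
#' component (shared trace added to every element) and element-independent
#' components; `correlated_fraction` sets the shared share of the noise
#' power. Purely independent noise would be removed almost perfectly by
#' coherence imaging, so the correlated component is what makes cluttered
#' cysts a nontrivial target for SLSC.
#'
#' @param phantom a [make_phantom()] object.
#' @param geometry an [array_geometry()].
#' @param line_positions lateral beam origins in meters; must lie within the
#'   phantom's lateral extent.
#' @param pulse_cycles transmit pulse length in periods of the center
#'   frequency.
#' @param seed integer seed controlling the clutter noise draws.
#' @param correlated_fraction fraction (in `[0, 1]`) of injected clutter
#'   power shared across elements.
#' @param cull_margin scatterers farther from a line than the geometric
#'   transmit-beam half-width plus this margin (m) are skipped when
#'   synthesizing that line; raise to `Inf`-like values (e.g. `1`) for
#'   exact summation in small test cases.
#' @param n_time number of RF samples per line; default covers the deepest
#'   scatterer's round trip.
#'
#' @return an object of class `channel_data`: list of `n_time x N` matrices
#'   (one per line, row `n` holds time `(n-1)/sampling_freq`), the line
#'   positions, the geometry and the seed.
#' @export
simulate_channel_data <- function(phantom, geometry, line_positions,
                                  pulse_cycles = 1.5, seed = 1L,
                                  correlated_fraction = 0.5,
                                  cull_margin = 1.5e-3,
                                  n_time = NULL) {
  stopifnot(inherits(phantom, "phantom"), inherits(geometry, "array_geometry"))
  sc <- phantom$scatterers
  if (nrow(sc) > 0 && any(sc$axial <= 0)) {
    stop("scatterer behind the array (axial position <= 0)")
  }
  if (any(line_positions < phantom$extent$lateral[1] - 1e-12) ||
      any(line_positions > phantom$extent$lateral[2] + 1e-12)) {
    stop("line_positions must lie within the phantom's lateral extent")
  }
  if (correlated_fraction < 0 || correlated_fraction > 1) {
    stop("correlated_fraction must be in [0, 1]")
  }
  c0 <- geometry$sound_speed
  fs <- geometry$sampling_freq
  off <- element_offsets(geometry)
  half_ap <- max(abs(off))
  z_max <- max(phantom$extent$axial[2], phantom$extent$axial[1])
  if (is.null(n_time)) {
    t_max <- (z_max + sqrt(half_ap^2 + z_max^2)) / c0 +
      2 * pulse_cycles / geometry$center_freq
    n_time <- ceiling(t_max * fs) + 8L
  }
  n_time <- as.integer(n_time)

  lines <- cpp_simulate_lines(
    sc$lateral, sc$axial, sc$amplitude,
    off, as.numeric(line_positions),
    geometry$transmit_focus_depth, c0, fs, geometry$center_freq,
    pulse_cycles, n_time, cull_margin
  )

  # clutter injection (channel-level, gated to the lesion's round-trip depth)
  cluttered <- Filter(function(l) l$clutter_level > 0, phantom$lesions)
  if (length(cluttered) > 0) {
    lines <- with_seed(seed, {
      inject_clutter(lines, cluttered, line_positions, geometry,
                     pulse_cycles, correlated_fraction)
    })
  }

  structure(
    list(
      samples = lines,
      line_positions = as.numeric(line_positions),
      geometry = geometry,
      pulse_cycles = pulse_cycles,
      correlated_fraction = correlated_fraction,
      rng_seed = as.integer(seed)
    ),
    class = "channel_data"
  )
}

#' @export
print.channel_data <- function(x, ...) {
  cat(sprintf("<channel_data> %d lines x %d elements x %d samples (fs %.3g MHz)\n",
              length(x$samples), x$geometry$n_elements, nrow(x$samples[[1]]),
              x$geometry$sampling_freq / 1e6))
  invisible(x)
}

# Band-limited mixture clutter added inside each lesion's depth gate.
#
# The element-correlated component emulates reverberant clutter arriving
# along tissue-like wavefronts: a shared trace is written onto each element
# at that element's geometric receive delay for the lesion depth, so after
# dynamic receive focusing it sums near-coherently (it fills the lesion on
# B-mode) while remaining less coherent than focused speckle across lags.
# The element-independent component is thermal-like noise that coherent
# summation suppresses. Called inside with_seed(); returns the mutated RF
# matrices.
inject_clutter <- function(lines, lesions, line_positions, geometry,
                           pulse_cycles, correlated_fraction) {
  c0 <- geometry$sound_speed
  fs <- geometry$sampling_freq
  f0 <- geometry$center_freq
  n_el <- geometry$n_elements
  off <- element_offsets(geometry)
  # band-limiting kernel: the transmit pulse sampled at the RF rate
  tt <- seq(0, pulse_cycles / f0, by = 1 / fs)
  sigma <- pulse_cycles / f0 / 6
  kern <- exp(-(tt - max(tt) / 2)^2 / (2 * sigma^2)) *
    cos(2 * pi * f0 * (tt - max(tt) / 2))

  kpad <- length(kern)
  bandlimit <- function(x) {
    # zero-pad so gates shorter than the kernel are still filterable
    xp <- c(numeric(kpad), x, numeric(kpad))
    y <- stats::filter(xp, kern, sides = 2)
    y[is.na(y)] <- 0
    as.numeric(y)[kpad + seq_along(x)] / sqrt(sum(kern^2))
  }

  for (l in seq_along(lines)) {
    rf <- lines[[l]]
    n_time <- nrow(rf)
    ref <- sqrt(mean(rf^2))
    if (ref == 0) ref <- 1
    for (les in lesions) {
      dx <- line_positions[l] - les$center[1]
      if (abs(dx) > les$radius) next
      h <- sqrt(les$radius^2 - dx^2)
      zc <- les$center[2]
      t0 <- 2 * (zc - h) / c0
      t1 <- 2 * (zc + h) / c0
      rows <- max(1L, floor(t0 * fs) + 1L):min(n_time, ceiling(t1 * fs) + 1L)
      if (length(rows) < 2L) next
      # the shared trace is written onto element j pre-delayed by its
      # receive path for the lesion depth, rf[r, j] += sh(r - shift_j), so
      # dynamic receive focusing (which reads element j at r + shift_j)
      # recovers the same trace from every element
      shift <- (sqrt(off^2 + zc^2) - zc) / c0 * fs
      pad <- ceiling(max(shift)) + 2L
      sh <- bandlimit(stats::rnorm(length(rows) + pad))
      sh_rows <- seq_along(sh)
      indep <- matrix(stats::rnorm(length(rows) * n_el), length(rows), n_el)
      indep <- apply(indep, 2, bandlimit)
      amp <- les$clutter_level * ref
      for (j in seq_len(n_el)) {
        aligned_shared <- stats::approx(sh_rows, sh,
                                        xout = seq_along(rows) - shift[j] + pad,
                                        rule = 2)$y
        rf[rows, j] <- rf[rows, j] + amp *
          (sqrt(correlated_fraction) * aligned_shared +
             sqrt(1 - correlated_fraction) * indep[, j])
      }
    }
    lines[[l]] <- rf
  }
  lines
}
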