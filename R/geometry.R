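#' Linear-array geometry
#'
#' Describes the receive (and transmit) aperture used to simulate and
#' beamform radio-frequency channel data. The default mirrors a
#' high-frequency linear breast probe: 64 active elements at 0.3 mm pitch,
#' 8 MHz center frequency sampled at 40 MHz, 1540 m/s sound speed and a
#' 20 mm transmit focus.
#'
#' @param n_elements number of active receive elements (N).
#' @param pitch element spacing in meters.
#' @param center_freq transmit center frequency in Hz.
#' @param sampling_freq RF sampling rate in Hz; must exceed twice the
#'   center frequency.
#' @param sound_speed speed of sound in m/s.
#' @param transmit_focus_depth fixed per-line transmit focal depth in meters.
#'
#' @return an object of class `array_geometry`.
#' @export
array_geometry <- function(n_elements = 64L,
                           pitch = 0.3e-3,
                           center_freq = 8e6,
                           sampling_freq = 40e6,
                           sound_speed = 1540,
                           transmit_focus_depth = 20e-3) {
  n_elements <- as.integer(n_elements)
  if (n_elements < 2L) stop("n_elements must be >= 2")
  if (pitch <= 0) stop("pitch must be > 0")
  if (sound_speed <= 0) stop("sound_speed must be > 0")
  if (sampling_freq <= 2 * center_freq) {
    stop("sampling_freq must exceed 2 * center_freq (Nyquist for RF data)")
  }
  if (transmit_focus_depth <= 0) stop("transmit_focus_depth must be > 0")
  structure(
    list(
      n_elements = n_elements,
      pitch = pitch,
      center_freq = center_freq,
      sampling_freq = sampling_freq,
      sound_speed = sound_speed,
      transmit_focus_depth = transmit_focus_depth
    ),
    class = "array_geometry"
  )
}

#' @export
print.array_geometry <- function(x, ...) {
  cat(sprintf(
    "<array_geometry> %d elements, pitch %.3g mm, f0 %.3g MHz, fs %.3g MHz, c %.4g m/s, focus %.3g mm\n",
    x$n_elements, x$pitch * 1e3, x$center_freq / 1e6,
    x$sampling_freq / 1e6, x$sound_speed, x$transmit_focus_depth * 1e3
  ))
  invisible(x)
}

# Element lateral offsets relative to the beam (line) origin, centered at 0.
element_offsets <- function(geometry) {
  n <- geometry$n_elements
  (seq_len(n) - (n + 1) / 2) * geometry$pitch
}

#' Wavelength of the transmit pulse
#' @param geometry an [array_geometry()].
#' @return wavelength in meters.
#' @export
wavelength <- function(geometry) geometry$sound_speed / geometry$center_freq
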