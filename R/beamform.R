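#' SLSC imaging parameters
#'
#' @param M short-lag cutoff: number of element lags summed. The study
#'   default is 7, i.e. 10% of the 64-element receive aperture.
#' @param kernel_samples axial correlation-kernel length in RF samples
#'   (odd). Defaults to one wavelength of round-trip RF samples,
#'   `2 * sampling_freq / center_freq`, resolved when the image is formed.
#' @param truncate_negative truncate negative pixel values to zero after the
#'   lag sum (the "full linear scale after truncating negatives" display).
#' @param normalize_by_M divide pixels by `M` so values lie in `[0, 1]`.
#' @param per_lag_truncate truncate each lag correlation at zero before
#'   summing instead of truncating the sum.
#'
#' @return an object of class `slsc_params`.
#' @export
slsc_params <- function(M = 7L, kernel_samples = NULL,
                        truncate_negative = TRUE, normalize_by_M = FALSE,
                        per_lag_truncate = FALSE) {
  M <- as.integer(M)
  if (M < 1L) stop("M must be >= 1")
  if (!is.null(kernel_samples)) {
    kernel_samples <- as.integer(kernel_samples)
    if (kernel_samples < 1L) stop("kernel_samples must be >= 1")
  }
  structure(
    list(M = M, kernel_samples = kernel_samples,
         truncate_negative = isTRUE(truncate_negative),
         normalize_by_M = isTRUE(normalize_by_M),
         per_lag_truncate = isTRUE(per_lag_truncate)),
    class = "slsc_params"
  )
}

resolve_kernel <- function(params, geometry) {
  k <- params$kernel_samples %||%
    as.integer(round(2 * geometry$sampling_freq / geometry$center_freq))
  k <- max(1L, as.integer(k))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

#' Ultrasound image container
#'
#' @param values numeric matrix, rows = axial samples (depth increasing with
#'   row index), columns = scan lines.
#' @param kind `"bmode_linear"`, `"bmode_log"` or `"slsc"`.
#' @param axial_spacing,lateral_spacing pixel spacing in meters.
#' @param depth_offset depth of the first row in meters.
#' @param dynamic_range_db display range used by [log_compress()].
#' @return object of class `ultrasound_image`.
#' @export
ultrasound_image <- function(values, kind = c("bmode_linear", "bmode_log", "slsc"),
                             axial_spacing, lateral_spacing, depth_offset = 0,
                             dynamic_range_db = 60) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (kind %in% c("bmode_linear") && any(values < 0)) {
    stop("bmode_linear images must be non-negative")
  }
  structure(
    list(values = values, kind = kind,
         axial_spacing = axial_spacing, lateral_spacing = lateral_spacing,
         depth_offset = depth_offset, dynamic_range_db = dynamic_range_db),
    class = "ultrasound_image"
  )
}

#' @export
print.ultrasound_image <- function(x, ...) {
  cat(sprintf("<ultrasound_image:%s> %d x %d px, dz %.3g mm, dx %.3g mm, depth offset %.3g mm\n",
              x$kind, nrow(x$values), ncol(x$values),
              x$axial_spacing * 1e3, x$lateral_spacing * 1e3, x$depth_offset * 1e3))
  invisible(x)
}

#' Dynamic receive focusing
#'
#' Aligns each element's RF signal to every depth sample of each line by
#' its pixel-to-element geometric delay (linear interpolation between RF
#' samples; out-of-range samples are zero). With a walking aperture the
#' delay table is shared by all lines.
#'
#' @param channel_data a [simulate_channel_data()] object.
#' @param depth_range optional `c(min, max)` depths in meters; defaults to
#'   the full recorded round-trip range.
#' @return object of class `aligned_channels`: per line an
#'   `n_depth x N` matrix, plus the depth grid (at the RF sampling rate,
#'   `dz = c / (2 fs)`).
#' @export
apply_receive_delays <- function(channel_data, depth_range = NULL) {
  stopifnot(inherits(channel_data, "channel_data"))
  geom <- channel_data$geometry
  c0 <- geom$sound_speed
  fs <- geom$sampling_freq
  n_time <- nrow(channel_data$samples[[1]])
  dz <- c0 / (2 * fs)
  if (is.null(depth_range)) depth_range <- c(dz, n_time * dz / 2)
  if (any(depth_range <= 0)) stop("pixel depths must be > 0")
  k0 <- max(1L, ceiling(depth_range[1] / dz))
  k1 <- floor(depth_range[2] / dz)
  if (k1 < k0) stop("empty depth range")
  depths <- (k0:k1) * dz
  off <- element_offsets(geom)

  # fractional RF row for each (depth, element): t = (z + |r_e - p|)/c
  tmat <- outer(depths, off, function(z, o) (z + sqrt(o^2 + z^2)) / c0)
  u <- tmat * fs + 1
  i0 <- floor(u)
  frac <- u - i0
  valid <- i0 >= 1 & i0 <= (n_time - 1)
  i0v <- pmax(pmin(i0, n_time - 1), 1)
  colix <- col(u)
  lin0 <- (colix - 1L) * n_time + i0v

  if (!all(valid)) {
    bad_rows <- unique(row(u)[!valid])
    warning(sprintf("%d pixel depth(s) outside the recorded time range; set to zero",
                    length(bad_rows)))
  }

  aligned <- lapply(channel_data$samples, function(rf) {
    A <- rf[lin0] * (1 - frac) + rf[lin0 + 1L] * frac
    A[!valid] <- 0
    dim(A) <- dim(u)
    A
  })

  structure(
    list(lines = aligned, depths = depths, dz = dz,
         line_positions = channel_data$line_positions, geometry = geom),
    class = "aligned_channels"
  )
}

#' Delay-and-sum B-mode image
#'
#' Sums the aligned aperture signals across elements (uniform apodization),
#' detects the envelope as the magnitude of the axial analytic signal, and
#' decimates axially to the pixel grid.
#'
#' @param aligned an [apply_receive_delays()] object.
#' @param decimation axial decimation factor applied after envelope
#'   detection.
#' @return an [ultrasound_image()] of kind `bmode_linear`.
#' @export
das_bmode <- function(aligned, decimation = 4L) {
  stopifnot(inherits(aligned, "aligned_channels"))
  rows <- seq(1L, length(aligned$depths), by = as.integer(decimation))
  vals <- vapply(aligned$lines, function(A) {
    envelope(rowSums(A))[rows]
  }, numeric(length(rows)))
  ultrasound_image(
    vals, "bmode_linear",
    axial_spacing = aligned$dz * decimation,
    lateral_spacing = if (length(aligned$line_positions) > 1) {
      mean(diff(aligned$line_positions))
    } else aligned$geometry$pitch,
    depth_offset = aligned$depths[rows[1]]
  )
}

#' Log-compress a linear B-mode image
#'
#' @param image an [ultrasound_image()] of kind `bmode_linear`.
#' @param dynamic_range_db display range; the maximum maps to 0 dB and
#'   values are clipped at `-dynamic_range_db`.
#' @return an [ultrasound_image()] of kind `bmode_log`.
#' @export
log_compress <- function(image, dynamic_range_db = 60) {
  stopifnot(inherits(image, "ultrasound_image"))
  if (image$kind != "bmode_linear") stop("log_compress expects a bmode_linear image")
  mx <- max(image$values)
  if (mx <= 0) stop("cannot log-compress an all-zero image")
  v <- 20 * log10(pmax(image$values, mx * 10^(-(dynamic_range_db + 20) / 20)) / mx)
  v <- pmax(v, -dynamic_range_db)
  out <- image
  out$values <- v
  out$kind <- "bmode_log"
  out$dynamic_range_db <- dynamic_range_db
  out
}

#' Normalized spatial coherence at one pixel (reference estimator)
#'
#' Computes the lag-`m` normalized correlation of delay-aligned aperture
#' signals over an axial kernel:
#' `R(m) = mean_i [ sum_n s_i(n) s_{i+m}(n) / sqrt(sum s_i^2 sum s_{i+m}^2) ]`.
#' Element pairs with a zero-energy member are skipped (the averaging
#' denominator shrinks accordingly); if every pair is skipped the value
#' is 0.
#'
#' @param signals `kernel_samples x N` matrix of aligned signals centered
#'   on the pixel (columns = elements).
#' @param m lag, `1 <= m <= N - 1`.
#' @return correlation value in `[-1, 1]`.
#' @export
spatial_coherence <- function(signals, m) {
  signals <- as.matrix(signals)
  n_el <- ncol(signals)
  m <- as.integer(m)
  if (m < 1L || m > n_el - 1L) stop("lag m must satisfy 1 <= m <= N - 1")
  e <- colSums(signals^2)
  acc <- 0
  used <- 0L
  for (i in seq_len(n_el - m)) {
    if (e[i] <= 0 || e[i + m] <= 0) next
    acc <- acc + sum(signals[, i] * signals[, i + m]) / sqrt(e[i] * e[i + m])
    used <- used + 1L
  }
  if (used == 0L) 0 else acc / used
}

#' Short-lag spatial coherence image
#'
#' Each pixel is the sum of the normalized inter-element correlations
#' `R(m)` over the first `M` lags, estimated on an axial kernel centered at
#' the pixel. Negative pixel values are truncated after the sum by default
#' ("full linear scale after truncating negatives"); per-lag truncation is
#' available via [slsc_params()].
#'
#' @param aligned an [apply_receive_delays()] object.
#' @param params an [slsc_params()].
#' @param decimation axial decimation factor from the RF-rate depth grid to
#'   image pixels.
#' @param keep_lags if `TRUE`, attach the per-pixel lag profiles (an
#'   `n_pixels x M` matrix per line, pre-truncation) as attribute
#'   `"lag_profiles"`.
#' @return an [ultrasound_image()] of kind `slsc` with values in
#'   `[0, M]` (or `[0, 1]` when `normalize_by_M`).
#' @export
slsc_image <- function(aligned, params = slsc_params(), decimation = 4L,
                       keep_lags = FALSE) {
  stopifnot(inherits(aligned, "aligned_channels"), inherits(params, "slsc_params"))
  geom <- aligned$geometry
  if (params$M >= geom$n_elements) {
    stop("M must be smaller than the number of receive elements")
  }
  kern <- resolve_kernel(params, geom)
  kh <- (kern - 1L) %/% 2L
  rows <- seq(1L, length(aligned$depths), by = as.integer(decimation))
  lag_list <- lapply(aligned$lines, function(A) {
    cpp_slsc_aligned(A, as.integer(rows - 1L), kh, params$M)
  })
  pix <- vapply(lag_list, function(lags) {
    if (params$per_lag_truncate) rowSums(pmax(lags, 0)) else rowSums(lags)
  }, numeric(length(rows)))
  if (params$truncate_negative) pix <- pmax(pix, 0)
  if (params$normalize_by_M) pix <- pix / params$M
  img <- ultrasound_image(
    pix, "slsc",
    axial_spacing = aligned$dz * decimation,
    lateral_spacing = if (length(aligned$line_positions) > 1) {
      mean(diff(aligned$line_positions))
    } else geom$pitch,
    depth_offset = aligned$depths[rows[1]]
  )
  if (keep_lags) attr(img, "lag_profiles") <- lag_list
  img
}

#' Mean coherence lag profile over image pixels
#'
#' Averages the per-pixel lag correlations `R(m)` (m = 1..M) over all
#' pixels of all lines, optionally restricted to a depth band. For diffuse
#' fully developed speckle imaged at the transmit focus, the van
#' Cittert-Zernike theorem predicts the triangle `1 - m/N`.
#'
#' @inheritParams slsc_image
#' @param M number of lags to report.
#' @param depth_range optional `c(min, max)` depth band in meters over which
#'   to average.
#' @return numeric vector of length `M`: mean `R(m)`.
#' @export
mean_lag_profile <- function(aligned, M = 20L, params = slsc_params(M = M),
                             decimation = 4L, depth_range = NULL) {
  params$M <- as.integer(M)
  img <- slsc_image(aligned, params, decimation, keep_lags = TRUE)
  lag_list <- attr(img, "lag_profiles")
  rows <- seq(1L, length(aligned$depths), by = as.integer(decimation))
  keep <- rep(TRUE, length(rows))
  if (!is.null(depth_range)) {
    z <- aligned$depths[rows]
    keep <- z >= depth_range[1] & z <= depth_range[2]
  }
  profs <- do.call(rbind, lapply(lag_list, function(lags) lags[keep, , drop = FALSE]))
  colMeans(profs)
}
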