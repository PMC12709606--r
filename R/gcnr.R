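#' ROI pair (mass + same-depth tissue)
#'
#' The support of the gCNR computation: a mass mask and an equal-area
#' background-tissue mask occupying the same depth band (rows), disjoint
#' from the mass.
#'
#' @param mass_mask,tissue_mask logical matrices on the image pixel grid.
#' @return object of class `roi_pair`.
#' @export
roi_pair <- function(mass_mask, tissue_mask) {
  mass_mask <- as.matrix(mass_mask)
  tissue_mask <- as.matrix(tissue_mask)
  if (!identical(dim(mass_mask), dim(tissue_mask))) {
    stop("mass and tissue masks must share the pixel grid")
  }
  storage.mode(mass_mask) <- "logical"
  storage.mode(tissue_mask) <- "logical"
  if (!any(mass_mask) || !any(tissue_mask)) stop("both ROIs must be nonempty")
  if (sum(mass_mask) != sum(tissue_mask)) {
    stop("mass and tissue ROIs must contain the same number of pixels")
  }
  if (any(mass_mask & tissue_mask)) stop("mass and tissue ROIs must be disjoint")
  structure(list(mass_mask = mass_mask, tissue_mask = tissue_mask),
            class = "roi_pair")
}

#' Automatic tissue ROI placement
#'
#' Translates the mass mask laterally (same rows, hence same depth band) by
#' the mass width plus a margin, preferring the side with more room, to
#' produce an equal-area, disjoint background-tissue ROI — the automated
#' counterpart of placing the tissue ROI "at the same depth, same size".
#'
#' @param mass_mask logical matrix (rows = depth, columns = lateral).
#' @param margin_px lateral gap between mass and tissue ROI, in pixels.
#' @return an [roi_pair()].
#' @export
auto_tissue_roi <- function(mass_mask, margin_px = 2L) {
  mass_mask <- as.matrix(mass_mask)
  storage.mode(mass_mask) <- "logical"
  if (!any(mass_mask)) stop("mass mask is empty")
  cols_in <- which(colSums(mass_mask) > 0)
  c0 <- min(cols_in)
  c1 <- max(cols_in)
  width <- c1 - c0 + 1L
  shift <- width + as.integer(margin_px)
  n_col <- ncol(mass_mask)
  room_right <- n_col - c1
  room_left <- c0 - 1L
  side <- if (room_right >= room_left) "right" else "left"
  s <- if (side == "right") shift else -shift
  if ((side == "right" && c1 + s > n_col) || (side == "left" && c0 + s < 1L)) {
    stop("no lateral room for a same-depth tissue ROI on either side; use a smaller mass ROI")
  }
  tissue <- matrix(FALSE, nrow(mass_mask), n_col)
  idx <- which(mass_mask, arr.ind = TRUE)
  tissue[cbind(idx[, 1], idx[, 2] + s)] <- TRUE
  roi_pair(mass_mask, tissue)
}

#' Generalized contrast-to-noise ratio
#'
#' `gCNR = 1 - OVL`, where OVL is the overlap of the two ROIs' pixel-value
#' histograms estimated on a shared binning that spans the pooled value
#' range. 1 means perfectly separable distributions, 0 identical ones.
#' Computed on linear-scale pixel values (B-mode envelope or SLSC sums),
#' not on display-compressed images. Up to histogram discretization, the
#' statistic is invariant under strictly increasing transforms of the
#' pixel values.
#'
#' @param image an [ultrasound_image()] of kind `bmode_linear` or `slsc`,
#'   or a plain numeric matrix.
#' @param rois an [roi_pair()] on the same pixel grid.
#' @param n_bins number of shared histogram bins (default 256).
#' @return gCNR value in `[0, 1]`.
#' @export
gcnr <- function(image, rois, n_bins = 256L) {
  stopifnot(inherits(rois, "roi_pair"))
  vals <- if (inherits(image, "ultrasound_image")) {
    if (!image$kind %in% c("bmode_linear", "slsc")) {
      stop("gcnr expects a linear-scale image (bmode_linear or slsc)")
    }
    image$values
  } else {
    as.matrix(image)
  }
  if (!identical(dim(vals), dim(rois$mass_mask))) {
    stop("image and ROI grids do not match")
  }
  x <- vals[rois$mass_mask]
  y <- vals[rois$tissue_mask]
  rng <- range(c(x, y))
  if (diff(rng) == 0) return(0)  # single shared bin: identical histograms
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  hx <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(x)
  hy <- tabulate(findInterval(y, breaks, rightmost.closed = TRUE,
                              all.inside = TRUE), n_bins) / length(y)
  1 - sum(pmin(hx, hy))
}

#' Threshold classifier parameters
#'
#' @param threshold gCNR cutoff in `[0, 1]`. The study default 0.76 was
#'   chosen within the acceptable range 0.62-0.85.
#' @param acceptable_range admissible threshold interval.
#' @return object of class `classifier_params`.
#' @export
classifier_params <- function(threshold = 0.76, acceptable_range = c(0.62, 0.85)) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  if (threshold < acceptable_range[1] || threshold > acceptable_range[2]) {
    warning(sprintf("threshold %.3f lies outside the acceptable range [%.2f, %.2f]",
                    threshold, acceptable_range[1], acceptable_range[2]))
  }
  structure(list(threshold = threshold, acceptable_range = acceptable_range),
            class = "classifier_params")
}

#' Classify mass contents from a gCNR value
#'
#' Fluid if the gCNR is at or above the threshold, solid otherwise (fluid
#' lesions are incoherent or anechoic, so their ROI distributions separate
#' sharply from surrounding tissue and the gCNR is high).
#'
#' @param gcnr_value numeric vector of gCNR values in `[0, 1]`.
#' @param params a [classifier_params()].
#' @return character vector, `"fluid"` or `"solid"`.
#' @export
classify_mass <- function(gcnr_value, params = classifier_params()) {
  stopifnot(inherits(params, "classifier_params"))
  if (any(is.na(gcnr_value)) || any(gcnr_value < 0 | gcnr_value > 1)) {
    stop("gCNR values must lie in [0, 1]")
  }
  ifelse(gcnr_value >= params$threshold, "fluid", "solid")
}

# Disk-shaped mass mask for a lesion on an image grid, shrunk away from the
# lesion boundary (ROI rules avoid mass boundaries).
lesion_mass_mask <- function(image, lesion, line_positions, shrink = 0.7) {
  stopifnot(inherits(image, "ultrasound_image"))
  z <- image$depth_offset + (seq_len(nrow(image$values)) - 1L) * image$axial_spacing
  x <- line_positions
  r2 <- (lesion$radius * shrink)^2
  outer(z, x, function(zz, xx) {
    (xx - lesion$center[1])^2 + (zz - lesion$center[2])^2 <= r2
  })
}
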