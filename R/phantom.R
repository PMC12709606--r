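#' Lesion specification
#'
#' Describes one circular lesion embedded in a speckle phantom. `content`
#' distinguishes fluid (anechoic or nearly so) from solid (tissue-like
#' backscatter) masses. `clutter_level` injects partially correlated
#' acoustic clutter into the channel signals at the lesion's depth, the
#' mechanism by which complicated cysts mimic solid masses on B-mode
#' images while remaining incoherent in SLSC images.
#'
#' @param center numeric length-2, (lateral, axial) position in meters.
#'   Axial center must be at least 5 mm deep: shallower masses cannot be
#'   focused properly and are excluded from coherence imaging.
#' @param radius lesion radius in meters (> 0).
#' @param content `"fluid"` or `"solid"`.
#' @param echogenicity scatterer-amplitude scale relative to the background
#'   (fluid typically 0, solid in (0, 1]).
#' @param clutter_level RMS amplitude of injected clutter relative to the
#'   background speckle channel RMS (>= 0).
#'
#' @return an object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius,
                        content = c("fluid", "solid"),
                        echogenicity = if (content == "fluid") 0 else 0.5,
                        clutter_level = 0) {
  content <- match.arg(content)
  center <- as.numeric(center)
  if (length(center) != 2L) stop("center must be (lateral, axial)")
  if (radius <= 0) stop("radius must be > 0")
  if (echogenicity < 0) stop("echogenicity must be >= 0")
  if (clutter_level < 0) stop("clutter_level must be >= 0")
  if (center[2] < 5e-3) {
    stop("lesion axial center must be >= 5 mm: shallower masses are not suitable for coherence imaging")
  }
  structure(
    list(center = center, radius = radius, content = content,
         echogenicity = echogenicity, clutter_level = clutter_level),
    class = "lesion_spec"
  )
}

#' Random point-scatterer phantom
#'
#' Draws uniformly distributed point scatterers with i.i.d. standard-normal
#' amplitudes over a rectangular region, then rescales the amplitude of
#' every scatterer falling inside a lesion by that lesion's echogenicity
#' (fluid lesions with echogenicity 0 become anechoic).
#'
#' @param extent list with `lateral = c(min, max)` and `axial = c(min, max)`
#'   bounds in meters; axial bounds must be positive (in front of the array).
#' @param scatterer_density scatterers per square meter. Fully developed
#'   speckle needs several scatterers per resolution cell; the helpers in
#'   this package use 2e8 (200/mm^2) for speckle-statistics work.
#' @param lesions list of [lesion_spec()] objects, all inside `extent`.
#' @param seed integer seed; the phantom is a pure function of its
#'   arguments and the seed.
#'
#' @return object of class `phantom`: data frame of scatterers
#'   (`lateral`, `axial`, `amplitude`), the lesion list and the extent.
#' @export
make_phantom <- function(extent, scatterer_density, lesions = list(), seed = 1L) {
  stopifnot(is.list(extent), !is.null(extent$lateral), !is.null(extent$axial))
  if (scatterer_density <= 0) stop("scatterer_density must be > 0")
  if (any(extent$axial <= 0)) stop("axial extent must be positive (in front of the array)")
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  for (i in seq_along(lesions)) {
    les <- lesions[[i]]
    if (!inherits(les, "lesion_spec")) stop("lesions must be lesion_spec objects")
    inside <-
      les$center[1] - les$radius >= extent$lateral[1] &&
      les$center[1] + les$radius <= extent$lateral[2] &&
      les$center[2] - les$radius >= extent$axial[1] &&
      les$center[2] + les$radius <= extent$axial[2]
    if (!inside) {
      stop(sprintf("lesion %d (center %.4g, %.4g m; radius %.4g m) lies outside the phantom extent",
                   i, les$center[1], les$center[2], les$radius))
    }
  }
  area <- diff(extent$lateral) * diff(extent$axial)
  n <- round(scatterer_density * area)
  draws <- with_seed(seed, {
    list(
      lateral = stats::runif(n, extent$lateral[1], extent$lateral[2]),
      axial = stats::runif(n, extent$axial[1], extent$axial[2]),
      amplitude = stats::rnorm(n)
    )
  })
  lateral <- draws$lateral
  axial <- draws$axial
  amplitude <- draws$amplitude
  for (les in lesions) {
    inside <- (lateral - les$center[1])^2 + (axial - les$center[2])^2 <= les$radius^2
    amplitude[inside] <- amplitude[inside] * les$echogenicity
  }
  structure(
    list(
      scatterers = data.frame(lateral = lateral, axial = axial, amplitude = amplitude),
      lesions = lesions,
      extent = extent,
      seed = as.integer(seed)
    ),
    class = "phantom"
  )
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> %d scatterers, %d lesion(s), lateral [%.1f, %.1f] mm, axial [%.1f, %.1f] mm\n",
              nrow(x$scatterers), length(x$lesions),
              x$extent$lateral[1] * 1e3, x$extent$lateral[2] * 1e3,
              x$extent$axial[1] * 1e3, x$extent$axial[2] * 1e3))
  invisible(x)
}

# Evaluate `code` under a fixed RNG seed, then restore the caller's RNG
# state so seeded helpers do not disturb the surrounding random stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}
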