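#' Default imaging options for single-mass phantoms
#'
#' Problem sizes for the per-mass imaging pipeline: a 14 mm-wide, 10 mm-deep
#' speckle band around the 20 mm transmit focus, 24 scan lines at 0.6 mm
#' spacing, 35 scatterers per square millimeter, and gCNR on 64 shared
#' histogram bins (ROIs of this size hold one to two hundred pixels, for
#' which 256 bins would be needlessly sparse).
#'
#' @param lateral_halfwidth phantom lateral half-extent, m.
#' @param depth_range phantom axial band, m.
#' @param image_depth_range beamformed image band, m.
#' @param line_spacing scan-line pitch, m.
#' @param scatterer_density scatterers per square meter.
#' @param decimation axial image decimation from the RF rate.
#' @param n_bins shared histogram bins for gCNR.
#' @param roi_shrink mass-ROI radius as a fraction of the lesion radius
#'   (ROI rules avoid lesion boundaries).
#' @return list of options.
#' @export
imaging_options <- function(lateral_halfwidth = 7e-3,
                            depth_range = c(15e-3, 25e-3),
                            image_depth_range = c(16.5e-3, 23.5e-3),
                            line_spacing = 0.6e-3,
                            scatterer_density = 3.5e7,
                            decimation = 4L,
                            n_bins = 64L,
                            roi_shrink = 0.6) {
  list(lateral_halfwidth = lateral_halfwidth, depth_range = depth_range,
       image_depth_range = image_depth_range, line_spacing = line_spacing,
       scatterer_density = scatterer_density, decimation = as.integer(decimation),
       n_bins = as.integer(n_bins), roi_shrink = roi_shrink)
}

#' Beamform one lesion phantom and score it with gCNR
#'
#' Runs the full physics pipeline for a single mass: speckle phantom with
#' an embedded lesion, focused RF channel data, dynamic receive focusing,
#' B-mode and SLSC images, automatic same-depth tissue ROI, and gCNR on
#' both images.
#'
#' @param lesion a [lesion_spec()]; its lateral center should be 0 (the
#'   image is centered on the lesion).
#' @param geometry an [array_geometry()].
#' @param params an [slsc_params()].
#' @param opts an [imaging_options()] list.
#' @param seed integer seed (phantom and clutter).
#' @param keep_images if `TRUE`, include the B-mode and SLSC images and the
#'   ROI pair in the result.
#' @return list with `gcnr_bmode`, `gcnr_slsc`, and optionally `bmode`,
#'   `slsc`, `rois`.
#' @export
image_mass_gcnr <- function(lesion, geometry = array_geometry(),
                            params = slsc_params(), opts = imaging_options(),
                            seed = 1L, keep_images = FALSE) {
  extent <- list(lateral = c(-1, 1) * opts$lateral_halfwidth,
                 axial = opts$depth_range)
  phantom <- make_phantom(extent, opts$scatterer_density, list(lesion),
                          seed = seed)
  lines_x <- seq(-1, 1, by = opts$line_spacing / opts$lateral_halfwidth) *
    opts$lateral_halfwidth
  cd <- simulate_channel_data(phantom, geometry, lines_x, seed = seed + 1L)
  aligned <- apply_receive_delays(cd, depth_range = opts$image_depth_range)
  bmode <- das_bmode(aligned, decimation = opts$decimation)
  slsc <- slsc_image(aligned, params, decimation = opts$decimation)
  mass <- lesion_mass_mask(bmode, lesion, lines_x, shrink = opts$roi_shrink)
  rois <- auto_tissue_roi(mass)
  out <- list(
    gcnr_bmode = gcnr(bmode, rois, n_bins = opts$n_bins),
    gcnr_slsc = gcnr(slsc, rois, n_bins = opts$n_bins)
  )
  if (keep_images) {
    out$bmode <- bmode
    out$slsc <- slsc
    out$rois <- rois
  }
  out
}

#' Simulate a beamformed imaging cohort
#'
#' Generates `n_fluid` cluttered fluid lesions (anechoic interiors with
#' partially correlated clutter, the sonographic mimics of solid masses)
#' and `n_solid` hypoechoic solid lesions, images each through the full
#' channel-data / beamforming pipeline, and records per-mass gCNR on the
#' B-mode and SLSC images. The default counts mirror the analysis subgroup
#' (16 fluid positives, 96 solid negatives).
#'
#' @param n_fluid,n_solid mass counts.
#' @param geometry,params,opts pipeline settings, see [image_mass_gcnr()].
#' @param fluid_clutter range of the per-mass clutter level for fluid
#'   lesions (uniform draw).
#' @param solid_echogenicity range of the per-mass echogenicity for solid
#'   lesions (uniform draw).
#' @param radius_range lesion radius range, m.
#' @param malignant_fraction share of solid masses labelled malignant.
#' @param seed integer seed.
#' @return a cohort table of eligible masses; per-mass pipeline gCNR values
#'   are attached via [reader_scores()] (single "reader" `R1`, since the
#'   pipeline's ROI placement is deterministic).
#' @export
simulate_imaging_cohort <- function(n_fluid = 16L, n_solid = 96L,
                                    geometry = array_geometry(),
                                    params = slsc_params(),
                                    opts = imaging_options(),
                                    fluid_clutter = c(0.3, 0.9),
                                    solid_echogenicity = c(0.15, 0.7),
                                    radius_range = c(2e-3, 3e-3),
                                    malignant_fraction = 25 / 96,
                                    seed = 1L) {
  n <- n_fluid + n_solid
  if (n == 0) stop("cohort must contain at least one mass")
  draws <- with_seed(seed, {
    list(
      radius = stats::runif(n, radius_range[1], radius_range[2]),
      clutter = stats::runif(n, fluid_clutter[1], fluid_clutter[2]),
      echo = stats::runif(n, solid_echogenicity[1], solid_echogenicity[2]),
      mal = stats::runif(n)
    )
  })
  depth <- mean(opts$depth_range)
  truth <- c(rep("complicated_cyst", n_fluid),
             ifelse(draws$mal[seq_len(n_solid) + n_fluid] < malignant_fraction,
                    "solid_malignant", "solid_benign"))
  gcnr_b <- gcnr_s <- numeric(n)
  for (i in seq_len(n)) {
    fluid <- truth[i] == "complicated_cyst"
    lesion <- lesion_spec(
      center = c(0, depth), radius = draws$radius[i],
      content = if (fluid) "fluid" else "solid",
      echogenicity = if (fluid) 0 else draws$echo[i],
      clutter_level = if (fluid) draws$clutter[i] else 0
    )
    res <- image_mass_gcnr(lesion, geometry, params, opts,
                           seed = derive_seed(seed, paste0("mass", i)))
    gcnr_b[i] <- res$gcnr_bmode
    gcnr_s[i] <- res$gcnr_slsc
  }
  df <- data.frame(
    mass_id = sprintf("M%03d", seq_len(n)),
    patient_id = sprintf("P%03d", seq_len(n)),
    truth_category = truth,
    reference_standard = ifelse(truth == "complicated_cyst", "aspiration", "biopsy"),
    exclusion_reason = NA_character_,
    depth_mm = depth * 1e3,
    size_mm = draws$radius * 2e3,
    stringsAsFactors = FALSE
  )
  scores <- data.frame(mass_id = df$mass_id, reader_id = "R1",
                       gcnr_bmode = gcnr_b, gcnr_slsc = gcnr_s,
                       stringsAsFactors = FALSE)
  as_cohort_table(df, scores)
}
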