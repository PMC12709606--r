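#' Default generative gCNR parameters per mass category
#'
#' Mean and standard deviation of the latent per-mass gCNR on each imaging
#' arm (SLSC and B-mode), chosen once so that the synthetic cohort emulates
#' the separations seen clinically: fluid masses score high and solid
#' masses low on SLSC images (binormal AUC near 0.96), with a compressed
#' separation on B-mode images (binormal AUC near 0.80). Mixed-content
#' masses sit in between. All values are free parameters of the generator.
#'
#' @return nested list `category -> arm -> c(mean, sd)`.
#' @export
default_gcnr_params <- function() {
  list(
    complicated_cyst = list(slsc = c(0.86, 0.10), bmode = c(0.70, 0.15)),
    simple_cyst      = list(slsc = c(0.90, 0.07), bmode = c(0.74, 0.12)),
    solid_benign     = list(slsc = c(0.40, 0.17), bmode = c(0.49, 0.12)),
    solid_malignant  = list(slsc = c(0.38, 0.16), bmode = c(0.48, 0.12)),
    mixed            = list(slsc = c(0.62, 0.15), bmode = c(0.58, 0.13))
  )
}

#' Default eligibility-exclusion counts
#'
#' Thirty excluded records: hyperechoic content (2), unknown contents (16),
#' incomplete follow-up (2), no clinical screenshots (2), superficial
#' location (4), not fully inside the field of view (4).
#' @return named integer vector.
#' @export
default_exclusion_counts <- function() {
  c(hyperechoic = 2L, unknown_content = 16L, incomplete_followup = 2L,
    no_screenshots = 2L, superficial = 4L, not_in_fov = 4L)
}

#' Default eligible-category counts
#'
#' 96 solid masses (71 benign, 25 malignant), 16 complicated cysts,
#' 11 simple cysts and 22 mixed-content masses: 145 eligible in total.
#' @return named integer vector.
#' @export
default_category_counts <- function() {
  c(complicated_cyst = 16L, solid_benign = 71L, solid_malignant = 25L,
    simple_cyst = 11L, mixed = 22L)
}

normalize_category_counts <- function(category_counts) {
  category_counts <- unlist(category_counts)
  if (is.null(names(category_counts)) && length(category_counts) > 0) {
    stop("category_counts must be named")
  }
  if ("solid" %in% names(category_counts)) {
    n_solid <- category_counts[["solid"]]
    n_mal <- round(n_solid * 25 / 96)   # default cohort's malignant share
    category_counts <- category_counts[names(category_counts) != "solid"]
    add <- c(solid_benign = n_solid - n_mal, solid_malignant = n_mal)
    for (nm in names(add)) {
      cur <- if (nm %in% names(category_counts)) category_counts[[nm]] else 0
      category_counts[nm] <- cur + add[[nm]]
    }
  }
  bad <- !names(category_counts) %in% TRUTH_CATEGORIES
  if (any(bad)) stop("unknown categories: ",
                     paste(names(category_counts)[bad], collapse = ", "))
  if (any(category_counts < 0)) stop("category counts must be >= 0")
  category_counts
}

#' Simulate a mass cohort with per-reader gCNR scores
#'
#' Creates one record per mass with a truth category and, optionally,
#' directly sampled gCNR scores per reader and imaging arm (truncated to
#' `[0, 1]`), for statistics-only analyses that bypass beamforming. Each
#' mass receives a latent gCNR per arm drawn from its category's
#' mean/standard deviation; per-reader values add independent ROI jitter
#' (`reader_sd`). Excluded records (if requested) carry an exclusion
#' reason and no scores.
#'
#' @param category_counts named counts of eligible masses per truth
#'   category; `"solid"` is accepted as shorthand and split into benign and
#'   malignant at the default cohort's 71:25 ratio.
#' @param gcnr_generative_params nested list `category -> arm -> c(mean, sd)`
#'   on `[0, 1]`; see [default_gcnr_params()].
#' @param seed integer seed.
#' @param n_readers number of readers drawing ROIs (scores per mass).
#' @param reader_sd standard deviation of per-reader ROI jitter on the
#'   latent gCNR.
#' @param exclusion_counts named counts of additional ineligible records to
#'   prepend (see [default_exclusion_counts()]); use `NULL` or an empty
#'   vector for an eligible-only cohort.
#' @param sample_scores if `FALSE`, skip gCNR sampling.
#'
#' @return a cohort table; per-reader scores are available via
#'   [reader_scores()].
#' @export
simulate_cohort <- function(category_counts = default_category_counts(),
                            gcnr_generative_params = default_gcnr_params(),
                            seed = 1L,
                            n_readers = 6L,
                            reader_sd = 0.12,
                            exclusion_counts = NULL,
                            sample_scores = TRUE) {
  category_counts <- normalize_category_counts(category_counts)
  for (cat in names(category_counts)) {
    if (sample_scores && category_counts[[cat]] > 0) {
      pars <- gcnr_generative_params[[cat]]
      if (is.null(pars)) stop("no generative gCNR parameters for category ", cat)
      for (arm in c("slsc", "bmode")) {
        if (pars[[arm]][1] < 0 || pars[[arm]][1] > 1) {
          stop("generative gCNR means must lie in [0, 1]")
        }
      }
    }
  }
  if (!is.null(exclusion_counts)) {
    exclusion_counts <- unlist(exclusion_counts)
    bad <- !names(exclusion_counts) %in% EXCLUSION_REASONS
    if (any(bad)) stop("unknown exclusion reasons: ",
                       paste(names(exclusion_counts)[bad], collapse = ", "))
  }

  with_seed(seed, {
    cats <- rep(names(category_counts), times = category_counts)
    reasons <- if (length(exclusion_counts)) {
      rep(names(exclusion_counts), times = exclusion_counts)
    } else character(0)
    n_elig <- length(cats)
    n_excl <- length(reasons)
    n <- n_elig + n_excl
    if (n == 0) {
      return(as_cohort_table(data.frame(
        mass_id = character(0), patient_id = character(0),
        truth_category = character(0), reference_standard = character(0),
        exclusion_reason = character(0), depth_mm = numeric(0),
        size_mm = numeric(0), stringsAsFactors = FALSE
      )))
    }
    # excluded records get plausible categories; superficial ones are shallow
    excl_cats <- if (n_excl) sample(TRUTH_CATEGORIES, n_excl, replace = TRUE) else character(0)
    truth <- c(cats, excl_cats)
    reason <- c(rep(NA_character_, n_elig), reasons)
    depth <- pmax(5, stats::rnorm(n, 11, 4))
    depth[which(reason == "superficial")] <- stats::runif(sum(reason == "superficial", na.rm = TRUE), 2, 4.9)
    size <- pmax(3, stats::rnorm(n, 13.8, 9.8))
    ref_std <- vapply(truth, function(cat) {
      switch(cat,
             simple_cyst = "bmode_features",
             complicated_cyst = sample(c("aspiration", "followup"), 1, prob = c(0.95, 0.05)),
             solid_benign = sample(c("biopsy", "excision"), 1, prob = c(0.9, 0.1)),
             solid_malignant = sample(c("biopsy", "excision"), 1, prob = c(0.9, 0.1)),
             mixed = "biopsy")
    }, character(1))
    new_patient <- c(TRUE, stats::runif(n - 1) < 0.8)
    patient_id <- sprintf("P%03d", cumsum(new_patient))
    mass_id <- sprintf("M%03d", seq_len(n))

    df <- data.frame(
      mass_id = mass_id, patient_id = patient_id, truth_category = truth,
      reference_standard = ref_std, exclusion_reason = reason,
      depth_mm = depth, size_mm = size, stringsAsFactors = FALSE
    )

    scores <- NULL
    if (sample_scores && n_elig > 0) {
      elig_ids <- mass_id[seq_len(n_elig)]
      latent_slsc <- latent_bmode <- numeric(n_elig)
      for (i in seq_len(n_elig)) {
        pars <- gcnr_generative_params[[cats[i]]]
        latent_slsc[i] <- stats::rnorm(1, pars$slsc[1], pars$slsc[2])
        latent_bmode[i] <- stats::rnorm(1, pars$bmode[1], pars$bmode[2])
      }
      scores <- expand.grid(reader_id = sprintf("R%d", seq_len(n_readers)),
                            mass_id = elig_ids, stringsAsFactors = FALSE)
      scores <- scores[, c("mass_id", "reader_id")]
      idx <- match(scores$mass_id, elig_ids)
      clamp01 <- function(x) pmin(1, pmax(0, x))
      scores$gcnr_bmode <- clamp01(latent_bmode[idx] +
                                     stats::rnorm(nrow(scores), 0, reader_sd))
      scores$gcnr_slsc <- clamp01(latent_slsc[idx] +
                                    stats::rnorm(nrow(scores), 0, reader_sd))
      rownames(scores) <- NULL
    }
    as_cohort_table(df, scores)
  })
}

#' Reader-panel specification
#'
#' Truth-conditioned categorical rating model for a panel of readers.
#' Readers classify each mass's content as solid, fluid, mixed or
#' uncertain. For a true-fluid mass the probability of a "fluid" rating is
#' `sens_fluid`; for a true-solid mass the probability of a "solid" rating
#' is `spec_fluid`; `mixed_rate` and `uncertain_rate` set those ratings'
#' probabilities, and the remainder goes to the wrong content class.
#' `agreement_coupling` is the probability that a reader copies a shared
#' per-mass latent rating instead of drawing independently, which tunes the
#' panel's Fleiss kappa between chance-level (0) and perfect (1) agreement.
#'
#' @param n_readers number of readers (default 6).
#' @param sens_fluid probability a true-fluid mass is rated fluid.
#' @param spec_fluid probability a true-solid mass is rated solid.
#' @param mixed_rate,uncertain_rate probabilities of "mixed"/"uncertain"
#'   ratings; with the correct-call probability they must sum to <= 1.
#' @param agreement_coupling in `[0, 1]`.
#' @return object of class `reader_panel_spec`.
#' @export
reader_panel_spec <- function(n_readers = 6L, sens_fluid = 0.5,
                              spec_fluid = 0.84, mixed_rate = 0.08,
                              uncertain_rate = 0.06,
                              agreement_coupling = 0.38) {
  probs <- c(sens_fluid, spec_fluid, mixed_rate, uncertain_rate, agreement_coupling)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (sens_fluid + mixed_rate + uncertain_rate > 1 + 1e-12 ||
      spec_fluid + mixed_rate + uncertain_rate > 1 + 1e-12) {
    stop("rating probabilities must sum to <= 1 per truth category")
  }
  structure(
    list(n_readers = as.integer(n_readers), sens_fluid = sens_fluid,
         spec_fluid = spec_fluid, mixed_rate = mixed_rate,
         uncertain_rate = uncertain_rate,
         agreement_coupling = agreement_coupling),
    class = "reader_panel_spec"
  )
}

rating_probs <- function(truth, spec) {
  base <- c(solid = 0, fluid = 0, mixed = spec$mixed_rate,
            uncertain = spec$uncertain_rate)
  if (truth %in% c("complicated_cyst", "simple_cyst")) {
    base["fluid"] <- spec$sens_fluid
    base["solid"] <- 1 - sum(base)
  } else if (truth %in% c("solid_benign", "solid_malignant")) {
    base["solid"] <- spec$spec_fluid
    base["fluid"] <- 1 - sum(base)
  } else { # mixed-content masses: correct call is "mixed"
    correct <- (spec$sens_fluid + spec$spec_fluid) / 2
    base["mixed"] <- min(1 - spec$uncertain_rate, correct)
    rest <- 1 - base["mixed"] - base["uncertain"]
    base["solid"] <- rest / 2
    base["fluid"] <- rest / 2
  }
  pmax(base, 0)
}

#' Simulate a reader panel
#'
#' Draws a content rating (solid / fluid / mixed / uncertain) for every
#' mass x reader x task from the truth-conditioned categorical model of a
#' [reader_panel_spec()]. With `agreement_coupling = 1` all readers copy
#' the shared latent rating, forcing perfect agreement.
#'
#' @param cohort a nonempty cohort table (eligible records are rated).
#' @param spec a [reader_panel_spec()], or a named list of specs, one per
#'   task (e.g. a more accurate spec for the task in which readers also see
#'   SLSC images).
#' @param seed integer seed.
#' @param tasks character vector of task names.
#' @return data frame of class `reader_panel` with columns `mass_id`,
#'   `reader_id`, `task`, `rating`.
#' @export
simulate_reader_panel <- function(cohort, spec = reader_panel_spec(), seed = 1L,
                                  tasks = c("task1_bmode", "task2_bmode_slsc")) {
  stopifnot(inherits(cohort, "cohort_table"))
  elig <- cohort[is.na(cohort$exclusion_reason), , drop = FALSE]
  if (nrow(elig) == 0) stop("cohort has no eligible masses to rate")
  if (inherits(spec, "reader_panel_spec")) {
    spec <- stats::setNames(rep(list(spec), length(tasks)), tasks)
  }
  if (!all(tasks %in% names(spec))) stop("spec list must name every task")

  out <- with_seed(seed, {
    res <- list()
    for (task in tasks) {
      sp <- spec[[task]]
      ratings <- matrix(NA_character_, nrow(elig), sp$n_readers)
      for (i in seq_len(nrow(elig))) {
        p <- rating_probs(elig$truth_category[i], sp)
        latent <- sample(names(p), 1, prob = p)
        copy <- stats::runif(sp$n_readers) < sp$agreement_coupling
        own <- sample(names(p), sp$n_readers, replace = TRUE, prob = p)
        ratings[i, ] <- ifelse(copy, latent, own)
      }
      res[[task]] <- data.frame(
        mass_id = rep(elig$mass_id, sp$n_readers),
        reader_id = rep(sprintf("R%d", seq_len(sp$n_readers)), each = nrow(elig)),
        task = task,
        rating = as.vector(ratings),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, res)
  })
  rownames(out) <- NULL
  class(out) <- c("reader_panel", "data.frame")
  out
}

#' Ratings matrix for one task
#'
#' @param panel a [simulate_reader_panel()] data frame.
#' @param task task name to extract.
#' @return character matrix masses x readers.
#' @export
panel_ratings_matrix <- function(panel, task) {
  stopifnot(inherits(panel, "reader_panel"))
  sub <- panel[panel$task == task, , drop = FALSE]
  if (nrow(sub) == 0) stop("no ratings for task ", task)
  readers <- sort(unique(sub$reader_id))
  masses <- unique(sub$mass_id)
  mat <- matrix(NA_character_, length(masses), length(readers),
                dimnames = list(masses, readers))
  mat[cbind(match(sub$mass_id, masses), match(sub$reader_id, readers))] <- sub$rating
  if (anyNA(mat)) stop("every (mass, reader) pair must be rated exactly once")
  mat
}
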