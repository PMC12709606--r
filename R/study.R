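#' Deterministic per-stage seed derivation
#'
#' Derives a stage seed from the master seed and the stage name (a
#' multiplicative congruential step on the master combined with a
#' polynomial hash of the name, all modulo 2^31 - 1), so that pipeline
#' stages can be re-run in isolation with reproducible draws.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @return integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  p <- 2147483647
  h <- 0
  for (code in utf8ToInt(as.character(stage))) h <- (h * 31 + code) %% p
  s <- ((as.numeric(master) %% p) * 48271) %% p
  out <- (s + h) %% p
  as.integer(max(1, out))
}

#' Study configuration
#'
#' Collects every tunable of the end-to-end study in one validated object:
#' array geometry, SLSC parameters (M = 7 by default), the classification
#' threshold (0.76) and the secondary reporting threshold (0.73), cohort
#' category counts, reader-panel specifications per task, bootstrap
#' iteration count (1000) and the master seed.
#'
#' @param mode `"statistics"` (direct gCNR sampling, full 175-record
#'   accounting) or `"beamformed"` (per-mass channel-data simulation and
#'   beamforming of the analysis subgroup).
#' @param seed master seed (mandatory; all stage seeds derive from it).
#' @param output_dir directory for report files.
#' @param geometry an [array_geometry()].
#' @param slsc an [slsc_params()].
#' @param classifier a [classifier_params()].
#' @param secondary_threshold additional reporting threshold.
#' @param category_counts eligible-category counts (statistics mode).
#' @param exclusion_counts ineligible-record counts (statistics mode).
#' @param gcnr_params generative gCNR parameters, see
#'   [default_gcnr_params()].
#' @param reader_specs named list of [reader_panel_spec()] per task.
#' @param n_readers readers drawing gCNR ROIs.
#' @param reader_sd per-reader ROI jitter on latent gCNR scores.
#' @param n_bootstrap bootstrap iterations.
#' @param imaging an [imaging_options()] list (beamformed mode).
#' @param n_fluid,n_solid beamformed-mode mass counts.
#' @return object of class `study_config`.
#' @export
study_config <- function(mode = c("statistics", "beamformed"),
                         seed,
                         output_dir = tempfile("study_"),
                         geometry = array_geometry(),
                         slsc = slsc_params(),
                         classifier = classifier_params(),
                         secondary_threshold = 0.73,
                         category_counts = default_category_counts(),
                         exclusion_counts = default_exclusion_counts(),
                         gcnr_params = default_gcnr_params(),
                         reader_specs = list(
                           task1_bmode = reader_panel_spec(),
                           task2_bmode_slsc = reader_panel_spec(
                             sens_fluid = 0.62, spec_fluid = 0.86,
                             mixed_rate = 0.06, uncertain_rate = 0.04,
                             agreement_coupling = 0.42)
                         ),
                         n_readers = 6L,
                         reader_sd = 0.12,
                         n_bootstrap = 1000L,
                         imaging = imaging_options(),
                         n_fluid = 16L, n_solid = 96L) {
  mode <- match.arg(mode)
  if (missing(seed) || is.null(seed)) {
    stop("a master seed is mandatory for stochastic runs")
  }
  stopifnot(inherits(geometry, "array_geometry"), inherits(slsc, "slsc_params"),
            inherits(classifier, "classifier_params"))
  for (sp in reader_specs) stopifnot(inherits(sp, "reader_panel_spec"))
  structure(
    list(mode = mode, seed = as.integer(seed), output_dir = output_dir,
         geometry = geometry, slsc = slsc, classifier = classifier,
         secondary_threshold = secondary_threshold,
         category_counts = category_counts,
         exclusion_counts = exclusion_counts,
         gcnr_params = gcnr_params, reader_specs = reader_specs,
         n_readers = as.integer(n_readers), reader_sd = reader_sd,
         n_bootstrap = as.integer(n_bootstrap), imaging = imaging,
         n_fluid = as.integer(n_fluid), n_solid = as.integer(n_solid)),
    class = "study_config"
  )
}

# Per-reader score matrix (masses x readers) for one arm, aligned to the
# subgroup's mass order.
score_matrix <- function(scores, mass_ids, arm) {
  readers <- sort(unique(scores$reader_id))
  mat <- matrix(NA_real_, length(mass_ids), length(readers),
                dimnames = list(mass_ids, readers))
  keep <- scores$mass_id %in% mass_ids
  sub <- scores[keep, , drop = FALSE]
  mat[cbind(match(sub$mass_id, mass_ids), match(sub$reader_id, readers))] <-
    sub[[paste0("gcnr_", arm)]]
  mat
}

# Percentile bootstrap CI for the mean AUC across readers: masses are
# resampled jointly, each reader's rank AUC recomputed, then averaged.
bootstrap_mean_auc_ci <- function(score_mat, pos, n_iter, seed, conf = 0.95) {
  n <- nrow(score_mat)
  with_seed(seed, {
    means <- numeric(n_iter)
    for (b in seq_len(n_iter)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(pos[idx]) && any(!pos[idx])) break
      }
      means[b] <- mean(apply(score_mat[idx, , drop = FALSE], 2, auc_rank,
                             pos = pos[idx]))
    }
    alpha <- (1 - conf) / 2
    unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
  })
}

# Reader operating points (sens, spec) from a ratings matrix: sensitivity is
# the fraction of fluid positives rated "fluid"; specificity the fraction of
# solid negatives rated "solid".
reader_operating_points <- function(ratings, pos) {
  t(apply(ratings, 2, function(r) {
    c(sens = mean(r[pos] == "fluid"), spec = mean(r[!pos] == "solid"))
  }))
}

#' Per-threshold classification trade-off
#'
#' For each candidate gCNR threshold, counts the complicated cysts called
#' fluid, the solid masses called solid, and the malignant solid masses
#' misclassified as fluid ("missed cancers", score at or above the
#' threshold). Lower thresholds identify more cysts but risk calling
#' cancers fluid.
#'
#' @param scores per-mass gCNR values.
#' @param truth_category per-mass truth (`complicated_cyst`,
#'   `solid_benign`, `solid_malignant`).
#' @param thresholds thresholds to tabulate.
#' @return data frame with one row per threshold.
#' @export
threshold_tradeoff_report <- function(scores, truth_category,
                                      thresholds = c(0.76, 0.73)) {
  if (length(scores) != length(truth_category)) {
    stop("scores and truth_category differ in length")
  }
  ok <- truth_category %in% c("complicated_cyst", "solid_benign", "solid_malignant")
  if (!all(ok)) stop("truth categories must be complicated_cyst / solid_benign / solid_malignant")
  cyst <- truth_category == "complicated_cyst"
  solid <- !cyst
  malignant <- truth_category == "solid_malignant"
  rows <- lapply(thresholds, function(tau) {
    called_fluid <- scores >= tau
    data.frame(
      threshold = tau,
      n_cysts = sum(cyst),
      cysts_called_fluid = sum(called_fluid & cyst),
      n_solid = sum(solid),
      solids_called_solid = sum(!called_fluid & solid),
      n_malignant = sum(malignant),
      missed_cancers = sum(called_fluid & malignant)
    )
  })
  do.call(rbind, rows)
}

#' Run the end-to-end synthetic study
#'
#' Simulates (or beamforms) a cohort, applies the eligibility and
#' statistical-subgroup filters, scores readers and gCNR arms, and writes a
#' statistical report: per-arm ROC/AUC with bootstrap CIs, per-threshold
#' confusion counts, the Fleiss-kappa table with difference tests, the
#' threshold trade-off table, the filter accounting, and a manifest with
#' every seed and parameter value. Any stage failure aborts with a
#' stage-named error and removes partial outputs.
#'
#' @param config a [study_config()].
#' @return object of class `study_report` (also written to
#'   `config$output_dir` as CSV/JSON), invisibly.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  out_dir <- config$output_dir
  created_dir <- !dir.exists(out_dir)
  if (created_dir) dir.create(out_dir, recursive = TRUE)
  written <- character(0)
  emit <- function(writer, obj, name) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    written <<- c(written, path)
    path
  }
  stage <- "setup"
  report <- tryCatch({
    ## stage: cohort ------------------------------------------------------
    stage <- "cohort"
    cohort <- if (config$mode == "statistics") {
      simulate_cohort(
        category_counts = config$category_counts,
        gcnr_generative_params = config$gcnr_params,
        seed = derive_seed(config$seed, "cohort"),
        n_readers = config$n_readers, reader_sd = config$reader_sd,
        exclusion_counts = config$exclusion_counts
      )
    } else {
      simulate_imaging_cohort(
        n_fluid = config$n_fluid, n_solid = config$n_solid,
        geometry = config$geometry, params = config$slsc,
        opts = config$imaging, seed = derive_seed(config$seed, "cohort")
      )
    }
    message(sprintf("[cohort] %d records simulated", nrow(cohort)))

    ## stage: filters -----------------------------------------------------
    stage <- "filters"
    eligible <- apply_eligibility_filters(cohort)
    filter_report <- attr(eligible, "filter_report")
    subgroup <- select_statistical_subgroup(eligible)
    subgroup_counts <- attr(subgroup, "subgroup_counts")
    labels <- binary_truth_labels(subgroup)
    pos <- labels == "positive"
    message(sprintf("[filters] %d eligible -> %d analysis masses (%d positive, %d negative)",
                    nrow(eligible), nrow(subgroup),
                    subgroup_counts$n_positive, subgroup_counts$n_negative))

    ## stage: readers -----------------------------------------------------
    stage <- "readers"
    panel <- simulate_reader_panel(eligible, config$reader_specs,
                                   seed = derive_seed(config$seed, "readers"),
                                   tasks = names(config$reader_specs))
    reader_points <- lapply(names(config$reader_specs), function(task) {
      ratings <- panel_ratings_matrix(panel, task)[subgroup$mass_id, , drop = FALSE]
      pts <- reader_operating_points(ratings, pos)
      lb <- lower_bound_auc(pts[, "sens"], pts[, "spec"])
      boot <- bootstrap_reader_mean_auc(
        data.frame(sens = pts[, "sens"], spec = pts[, "spec"]),
        n_iter = config$n_bootstrap,
        seed = derive_seed(config$seed, paste0("readers_boot_", task))
      )
      list(task = task, points = pts, lower_bound_auc = lb, mean_ci = boot,
           ratings = ratings)
    })
    names(reader_points) <- names(config$reader_specs)

    ## stage: gcnr_stats --------------------------------------------------
    stage <- "gcnr_stats"
    scores <- reader_scores(subgroup)
    if (is.null(scores)) stop("cohort carries no gCNR scores")
    arms <- c("bmode", "slsc")
    gcnr_stats <- lapply(arms, function(arm) {
      mat <- score_matrix(scores, subgroup$mass_id, arm)
      per_reader_auc <- apply(mat, 2, auc_rank, pos = pos)
      mean_scores <- rowMeans(mat)
      roc <- roc_curve(mean_scores, pos)
      ci <- bootstrap_mean_auc_ci(
        mat, pos, config$n_bootstrap,
        seed = derive_seed(config$seed, paste0("gcnr_boot_", arm))
      )
      thresholds <- c(config$classifier$threshold, config$secondary_threshold)
      confusion <- do.call(rbind, lapply(thresholds, function(tau) {
        calls <- mat >= tau
        data.frame(
          arm = arm, threshold = tau, reader = colnames(mat),
          tp = colSums(calls[pos, , drop = FALSE]),
          fn = colSums(!calls[pos, , drop = FALSE]),
          tn = colSums(!calls[!pos, , drop = FALSE]),
          fp = colSums(calls[!pos, , drop = FALSE]),
          row.names = NULL
        )
      }))
      list(arm = arm, per_reader_auc = per_reader_auc,
           mean_auc = mean(per_reader_auc), mean_auc_ci = ci,
           roc_mean_scores = roc, confusion = confusion,
           score_matrix = mat)
    })
    names(gcnr_stats) <- arms

    # paired DeLong per reader: B-mode gCNR vs SLSC gCNR
    delong <- lapply(colnames(gcnr_stats$slsc$score_matrix), function(r) {
      res <- delong_test(gcnr_stats$slsc$score_matrix[, r],
                         gcnr_stats$bmode$score_matrix[, r], pos)
      data.frame(reader = r, auc_slsc = res$auc_a, auc_bmode = res$auc_b,
                 delta = res$delta, p_value = res$p_value)
    })
    delong <- do.call(rbind, delong)

    ## stage: agreement ---------------------------------------------------
    stage <- "agreement"
    # agreement is assessed over every rated (eligible) mass, as in the
    # reading tasks; binary truth is only needed for the ROC analyses
    thresholds <- c(config$classifier$threshold, config$secondary_threshold)
    kappas <- list()
    for (task in names(reader_points)) {
      kappas[[task]] <- fleiss_kappa(panel_ratings_matrix(panel, task),
                                     categories = c("solid", "fluid", "mixed", "uncertain"))
    }
    # agreement of thresholded gCNR calls needs >= 2 ROI readers (the
    # beamformed pipeline places one deterministic ROI per mass)
    all_scores <- reader_scores(eligible)
    eligible_mat <- score_matrix(all_scores, eligible$mass_id, "slsc")
    multi_reader <- ncol(eligible_mat) >= 2
    if (multi_reader) {
      for (tau in thresholds) {
        key <- sprintf("gcnr_slsc_%0.2f", tau)
        calls <- ifelse(eligible_mat >= tau, "fluid", "solid")
        kappas[[key]] <- fleiss_kappa(calls, categories = c("solid", "fluid"))
      }
      kappa_diffs <- lapply(thresholds, function(tau) {
        key <- sprintf("gcnr_slsc_%0.2f", tau)
        kd <- kappa_difference_test(kappas[[key]], kappas[[names(reader_points)[1]]])
        data.frame(comparison = sprintf("%s_vs_%s", key, names(reader_points)[1]),
                   delta = kd$delta, z = kd$z, p_value = kd$p_value)
      })
      kappa_diffs <- do.call(rbind, kappa_diffs)
    } else {
      kappa_diffs <- data.frame(comparison = character(0), delta = numeric(0),
                                z = numeric(0), p_value = numeric(0))
    }

    ## stage: tradeoff ----------------------------------------------------
    stage <- "tradeoff"
    mean_slsc <- rowMeans(gcnr_stats$slsc$score_matrix)
    tradeoff <- threshold_tradeoff_report(mean_slsc, subgroup$truth_category,
                                          thresholds = sort(unique(c(thresholds, 0.62, 0.85))))

    ## stage: write -------------------------------------------------------
    stage <- "write"
    emit(write_cohort_csv, cohort, "cohort.csv")
    emit(write_panel_csv, panel, "reader_panel.csv")
    roc_pts <- do.call(rbind, lapply(arms, function(arm) {
      cbind(arm = arm, gcnr_stats[[arm]]$roc_mean_scores$points)
    }))
    emit(function(obj, path) utils::write.csv(obj, path, row.names = FALSE),
         roc_pts, "roc_points.csv")
    emit(function(obj, path) utils::write.csv(obj, path, row.names = FALSE),
         do.call(rbind, lapply(gcnr_stats, function(g) g$confusion)),
         "confusion.csv")
    emit(function(obj, path) utils::write.csv(obj, path, row.names = FALSE),
         tradeoff, "threshold_tradeoff.csv")
    emit(function(obj, path) utils::write.csv(obj, path, row.names = FALSE),
         delong, "delong_tests.csv")

    kappa_table <- data.frame(
      panel = names(kappas),
      kappa = vapply(kappas, function(k) k$kappa, numeric(1)),
      variance = vapply(kappas, function(k) k$variance, numeric(1)),
      z = vapply(kappas, function(k) k$z, numeric(1)),
      p_value = vapply(kappas, function(k) k$p_value, numeric(1)),
      band = vapply(kappas, function(k) k$band, character(1)),
      row.names = NULL
    )
    emit(function(obj, path) utils::write.csv(obj, path, row.names = FALSE),
         kappa_table, "kappa_table.csv")
    emit(function(obj, path) utils::write.csv(obj, path, row.names = FALSE),
         kappa_diffs, "kappa_differences.csv")

    stats_json <- list(
      filter_report = filter_report,
      subgroup_counts = subgroup_counts,
      mean_auc = lapply(gcnr_stats, function(g) {
        list(mean = g$mean_auc, ci = as.numeric(g$mean_auc_ci),
             per_reader = as.list(g$per_reader_auc))
      }),
      reader_lower_bound_auc = lapply(reader_points, function(rp) {
        list(per_reader = as.list(rp$lower_bound_auc),
             mean = rp$mean_ci$mean, ci = c(rp$mean_ci$ci_low, rp$mean_ci$ci_high))
      }),
      kappa = stats::setNames(lapply(kappas, function(k) {
        list(kappa = k$kappa, z = k$z, p_value = k$p_value, band = k$band)
      }), names(kappas))
    )
    emit(function(obj, path) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }, stats_json, "stats.json")

    manifest <- list(
      package_version = as.character(utils::packageVersion("slscgcnr")),
      mode = config$mode,
      master_seed = config$seed,
      stage_seeds = list(
        cohort = derive_seed(config$seed, "cohort"),
        readers = derive_seed(config$seed, "readers")
      ),
      n_bootstrap = config$n_bootstrap,
      threshold = config$classifier$threshold,
      secondary_threshold = config$secondary_threshold,
      slsc_M = config$slsc$M,
      geometry = unclass(config$geometry),
      category_counts = as.list(config$category_counts),
      exclusion_counts = as.list(config$exclusion_counts),
      n_readers = config$n_readers,
      reader_sd = config$reader_sd
    )
    emit(function(obj, path) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }, manifest, "manifest.json")

    structure(
      list(cohort = cohort, eligible = eligible, subgroup = subgroup,
           filter_report = filter_report, subgroup_counts = subgroup_counts,
           reader_points = reader_points, gcnr_stats = gcnr_stats,
           delong = delong, kappas = kappas, kappa_differences = kappa_diffs,
           tradeoff = tradeoff, kappa_table = kappa_table,
           manifest = manifest, output_dir = out_dir, files = written),
      class = "study_report"
    )
  }, error = function(e) {
    unlink(written)
    if (created_dir) unlink(out_dir, recursive = TRUE)
    stop(sprintf("study stage '%s' failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })
  invisible(report)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("<study_report> %d masses (%d analysis subgroup); mean AUC slsc %.3f, bmode %.3f\n",
              nrow(x$cohort), nrow(x$subgroup),
              x$gcnr_stats$slsc$mean_auc, x$gcnr_stats$bmode$mean_auc))
  cat(sprintf("  kappa: %s\n",
              paste(sprintf("%s %.2f", x$kappa_table$panel, x$kappa_table$kappa),
                    collapse = ", ")))
  cat(sprintf("  outputs: %s\n", x$output_dir))
  invisible(x)
}
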