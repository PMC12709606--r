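fast_cfg <- function(seed, dir = tempfile("study_")) {
  study_config(mode = "statistics", seed = seed, output_dir = dir,
               n_bootstrap = 50L)
}

test_that("a statistics-only study produces a complete, reproducible report", {
  rep <- suppressMessages(run_study(fast_cfg(101)))
  on.exit(unlink(rep$output_dir, recursive = TRUE), add = TRUE)
  expect_s3_class(rep, "study_report")
  expect_equal(rep$subgroup_counts$n_total, 112)
  expect_equal(rep$subgroup_counts$n_positive, 16)
  expect_equal(rep$subgroup_counts$n_negative, 96)
  expect_true(all(c("bmode", "slsc") %in% names(rep$gcnr_stats)))
  expect_true(is.finite(rep$gcnr_stats$slsc$mean_auc))
  expect_length(rep$gcnr_stats$slsc$per_reader_auc, 6)
  expect_true(all(file.exists(rep$files)))
  expect_equal(rep$manifest$master_seed, 101)
  expect_equal(rep$manifest$stage_seeds$cohort, derive_seed(101, "cohort"))
  # kappa table covers both tasks and both thresholds
  expect_setequal(rep$kappa_table$panel,
                  c("task1_bmode", "task2_bmode_slsc",
                    "gcnr_slsc_0.76", "gcnr_slsc_0.73"))
})

test_that("the same seed yields byte-identical study outputs", {
  r1 <- suppressMessages(run_study(fast_cfg(77)))
  r2 <- suppressMessages(run_study(fast_cfg(77)))
  on.exit(unlink(c(r1$output_dir, r2$output_dir), recursive = TRUE), add = TRUE)
  for (f in basename(r1$files)) {
    expect_identical(readLines(file.path(r1$output_dir, f)),
                     readLines(file.path(r2$output_dir, f)),
                     info = f)
  }
})

test_that("stage failures abort with a stage-named error and clean up outputs", {
  dir <- tempfile("study_fail_")
  cfg <- fast_cfg(5, dir)
  cfg$gcnr_params$complicated_cyst$slsc <- c(2, 0.1)  # invalid mean
  expect_error(suppressMessages(run_study(cfg)), "stage 'cohort'")
  expect_false(dir.exists(dir))
})

test_that("seed derivation is deterministic, stage-sensitive and in range", {
  expect_identical(derive_seed(42, "cohort"), derive_seed(42, "cohort"))
  expect_false(derive_seed(42, "cohort") == derive_seed(42, "readers"))
  expect_false(derive_seed(42, "cohort") == derive_seed(43, "cohort"))
  seeds <- vapply(1:50, function(s) derive_seed(s, "x"), integer(1))
  expect_true(all(seeds >= 1 & seeds < 2^31))
})

test_that("threshold trade-off counts match a brute-force recount", {
  set.seed(40)
  truth <- sample(c("complicated_cyst", "solid_benign", "solid_malignant"),
                  50, replace = TRUE)
  scores <- runif(50)
  taus <- c(0.3, 0.62, 0.76)
  rep <- threshold_tradeoff_report(scores, truth, taus)
  for (i in seq_along(taus)) {
    tau <- taus[i]
    expect_equal(rep$cysts_called_fluid[i],
                 sum(scores >= tau & truth == "complicated_cyst"))
    expect_equal(rep$solids_called_solid[i],
                 sum(scores < tau & truth != "complicated_cyst"))
    expect_equal(rep$missed_cancers[i],
                 sum(scores >= tau & truth == "solid_malignant"))
  }
})

test_that("threshold trade-off endpoints behave", {
  truth <- c(rep("complicated_cyst", 3), rep("solid_benign", 4),
             rep("solid_malignant", 3))
  zeros <- rep(0, 10)
  rep0 <- threshold_tradeoff_report(zeros, truth, c(0.5, 0.76))
  expect_true(all(rep0$missed_cancers == 0))
  expect_true(all(rep0$solids_called_solid == 7))
  rep1 <- threshold_tradeoff_report(runif(10), truth, 0)
  expect_equal(rep1$cysts_called_fluid, 3)
  expect_equal(rep1$solids_called_solid, 0)
  expect_equal(rep1$missed_cancers, 3)
})

test_that("a small beamformed study runs end to end", {
  cfg <- study_config(mode = "beamformed", seed = 9,
                      output_dir = tempfile("study_bf_"),
                      n_bootstrap = 30L, n_fluid = 3L, n_solid = 5L)
  rep <- suppressMessages(run_study(cfg))
  on.exit(unlink(rep$output_dir, recursive = TRUE), add = TRUE)
  expect_equal(rep$subgroup_counts$n_positive, 3)
  expect_equal(rep$subgroup_counts$n_negative, 5)
  expect_true(is.finite(rep$gcnr_stats$slsc$mean_auc))
  expect_true(is.finite(rep$gcnr_stats$bmode$mean_auc))
})
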