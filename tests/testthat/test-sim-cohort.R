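test_that("category counts are honored, including the 'solid' shorthand", {
  co <- simulate_cohort(category_counts = c(solid = 96, complicated_cyst = 16,
                                            simple_cyst = 11, mixed = 22),
                        seed = 1)
  expect_equal(nrow(co), 145)
  expect_equal(sum(co$truth_category %in% c("solid_benign", "solid_malignant")), 96)
  empty <- simulate_cohort(category_counts = c(complicated_cyst = 0), seed = 2)
  expect_equal(nrow(empty), 0)
})

test_that("sampled scores reproduce the closed-form binormal AUC", {
  pars <- default_gcnr_params()
  pars$complicated_cyst$slsc <- c(0.9, 0.05)
  pars$solid_benign$slsc <- c(0.3, 0.15)
  co <- simulate_cohort(category_counts = c(complicated_cyst = 500,
                                            solid_benign = 500),
                        gcnr_generative_params = pars,
                        n_readers = 1, reader_sd = 0, seed = 3)
  sc <- reader_scores(co)
  pos <- co$truth_category[match(sc$mass_id, co$mass_id)] == "complicated_cyst"
  emp <- roc_curve(sc$gcnr_slsc, pos)$auc
  closed <- pnorm((0.9 - 0.3) / sqrt(0.05^2 + 0.15^2))
  # Monte-Carlo sd of the empirical AUC (Hanley-McNeil approximation)
  a <- closed
  q1 <- a / (2 - a); q2 <- 2 * a^2 / (1 + a)
  se <- sqrt((a * (1 - a) + 499 * (q1 - a^2) + 499 * (q2 - a^2)) / (500 * 500))
  expect_lt(abs(emp - closed), 3 * se + 1e-4)
})

test_that("reader panels respect coupling and accuracy limits", {
  co <- simulate_cohort(category_counts = c(complicated_cyst = 30,
                                            solid_benign = 50), seed = 4)
  # full coupling forces perfect agreement
  p1 <- simulate_reader_panel(co, reader_panel_spec(agreement_coupling = 1),
                              seed = 5, tasks = "task1_bmode")
  k1 <- fleiss_kappa(panel_ratings_matrix(p1, "task1_bmode"))
  expect_equal(k1$kappa, 1)
  # perfect readers match truth exactly
  p2 <- simulate_reader_panel(
    co, reader_panel_spec(sens_fluid = 1, spec_fluid = 1, mixed_rate = 0,
                          uncertain_rate = 0, agreement_coupling = 0),
    seed = 6, tasks = "task1_bmode")
  truth_call <- ifelse(co$truth_category == "complicated_cyst", "fluid", "solid")
  expect_true(all(p2$rating == truth_call[match(p2$mass_id, co$mass_id)]))
})

test_that("uninformative independent readers agree only by chance", {
  co <- simulate_cohort(category_counts = c(complicated_cyst = 200,
                                            solid_benign = 200), seed = 7)
  p <- simulate_reader_panel(
    co, reader_panel_spec(sens_fluid = 0.5, spec_fluid = 0.5, mixed_rate = 0,
                          uncertain_rate = 0, agreement_coupling = 0),
    seed = 8, tasks = "task1_bmode")
  k <- fleiss_kappa(panel_ratings_matrix(p, "task1_bmode"))
  # chance agreement: kappa ~ 0 within Monte-Carlo error
  expect_lt(abs(k$kappa), 4 * sqrt(k$variance))
})

test_that("panel generation is deterministic and covers every mass-reader-task", {
  co <- simulate_cohort(category_counts = c(complicated_cyst = 10,
                                            solid_benign = 10), seed = 9)
  a <- simulate_reader_panel(co, seed = 10)
  b <- simulate_reader_panel(co, seed = 10)
  expect_identical(a, b)
  expect_equal(nrow(a), 20 * 6 * 2)
  expect_true(all(a$rating %in% c("solid", "fluid", "mixed", "uncertain")))
})

test_that("panel spec validation rejects inconsistent probabilities", {
  expect_error(reader_panel_spec(sens_fluid = 0.9, mixed_rate = 0.2,
                                 uncertain_rate = 0.2), "sum to <= 1")
  expect_error(reader_panel_spec(agreement_coupling = 1.2), "\\[0, 1\\]")
})
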