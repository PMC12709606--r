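test_that("ROC endpoints and degenerate cases behave", {
  scores <- c(0.9, 0.8, 0.85, 0.2, 0.1, 0.3)
  labels <- c(1, 1, 1, 0, 0, 0)
  roc <- roc_curve(scores, labels)
  expect_equal(roc$auc, 1)
  expect_true(any(roc$points$sens == 1 & roc$points$one_minus_spec == 0))
  expect_true(any(roc$points$sens == 0 & roc$points$one_minus_spec == 0))
  expect_true(any(roc$points$sens == 1 & roc$points$one_minus_spec == 1))
  # all-tied scores carry no information
  expect_equal(roc_curve(rep(0.5, 6), labels)$auc, 0.5)
  expect_error(roc_curve(scores, rep(1, 6)), "one positive and one negative")
})

test_that("sens and 1-spec are non-increasing along the threshold grid", {
  set.seed(20)
  scores <- round(runif(40), 2)
  labels <- rbinom(40, 1, 0.4)
  if (sum(labels) %in% c(0, 40)) labels[1:5] <- c(0, 1, 0, 1, 0)
  roc <- roc_curve(scores, labels)
  o <- order(roc$points$threshold)
  expect_true(all(diff(roc$points$sens[o]) <= 1e-12))
  expect_true(all(diff(roc$points$one_minus_spec[o]) <= 1e-12))
})

test_that("trapezoidal AUC equals the pairwise Mann-Whitney statistic with ties", {
  set.seed(21)
  for (rep in 1:25) {
    n_pos <- sample(2:5, 1)
    n_neg <- sample(2:5, 1)
    scores <- sample(seq(0, 1, by = 0.25), n_pos + n_neg, replace = TRUE)
    pos <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    expect_equal(roc_curve(scores, pos)$auc, mw_auc(scores, pos))
  }
})

test_that("auc_trapezoid matches closed forms and a quadrature oracle", {
  expect_equal(auc_trapezoid(c(0, 0, 1), c(0, 1, 1)), 1)
  expect_equal(auc_trapezoid(c(0, 1), c(0, 1)), 0.5)
  x <- c(0, 0.25, 1)
  y <- c(0, 0.75, 1)
  quad <- integrate(approxfun(x, y), 0, 1, abs.tol = 1e-10)$value
  expect_equal(auc_trapezoid(x, y), quad, tolerance = 1e-6)
  expect_message(auc_trapezoid(c(0.5, 0, 1), c(0.6, 0, 1)), "unsorted")
})

test_that("bootstrap AUC interval is deterministic and degenerate when warranted", {
  scores <- c(rep(0.9, 10), rep(0.1, 10))
  labels <- rep(c(1, 0), each = 10)
  ci <- bootstrap_auc_ci(scores, labels, n_iter = 200, seed = 3)
  expect_equal(as.numeric(ci), c(1, 1))
  set.seed(22)
  s2 <- runif(30)
  l2 <- rbinom(30, 1, 0.5)
  if (sum(l2) %in% c(0, 30)) l2[1:2] <- c(0, 1)
  a <- bootstrap_auc_ci(s2, l2, n_iter = 300, seed = 9)
  b <- bootstrap_auc_ci(s2, l2, n_iter = 300, seed = 9)
  expect_identical(a, b)
  expect_true(a[1] <= roc_curve(s2, l2)$auc && roc_curve(s2, l2)$auc <= a[2])
})

test_that("lower-bound AUC is the two-segment trapezoid through the operating point", {
  expect_equal(lower_bound_auc(1, 1), 1)
  expect_equal(lower_bound_auc(0.5, 0.5), 0.5)
  set.seed(23)
  for (rep in 1:10) {
    s <- runif(1); sp <- runif(1)
    f <- approxfun(c(0, 1 - sp, 1), c(0, s, 1))
    # quadrature split at the operating-point kink, where f is smooth
    quad <- integrate(f, 0, 1 - sp)$value + integrate(f, 1 - sp, 1)$value
    expect_equal(lower_bound_auc(s, sp), quad, tolerance = 1e-8)
  }
  # never exceeds the full trapezoidal AUC through the same point
  roc_auc <- auc_trapezoid(c(0, 0.3, 1), c(0, 0.8, 1))
  expect_lte(lower_bound_auc(0.8, 0.7), roc_auc)
  expect_error(lower_bound_auc(1.2, 0.5), "\\[0, 1\\]")
})

test_that("reader-mean bootstrap reproduces the exhaustive two-reader distribution", {
  pts <- data.frame(sens = c(1, 0.5), spec = c(1, 0.5))
  res <- bootstrap_reader_mean_auc(pts, n_iter = 4000, seed = 5)
  expect_equal(res$mean, 0.75)
  # resampling 2 readers with replacement: mean in {0.5, 0.75, 1} w.p. 1/4, 1/2, 1/4
  same <- bootstrap_reader_mean_auc(pts, n_iter = 4000, seed = 5)
  expect_identical(res, same)
  ident <- bootstrap_reader_mean_auc(data.frame(sens = c(0.8, 0.8),
                                                spec = c(0.6, 0.6)),
                                     n_iter = 100, seed = 1)
  expect_equal(ident$ci_low, ident$ci_high)
  expect_equal(ident$mean, 0.7)
})

test_that("bootstrap reader means have the enumerated support and frequencies", {
  pts <- data.frame(sens = c(1, 0.5), spec = c(1, 0.5))
  lb <- lower_bound_auc(pts$sens, pts$spec)
  set.seed(6)
  draws <- replicate(4000, mean(lb[sample.int(2, 2, replace = TRUE)]))
  expect_setequal(sort(unique(draws)), c(0.5, 0.75, 1))
  freq <- table(draws) / 4000
  expect_equal(unname(freq[["0.75"]]), 0.5, tolerance = 0.05)
  expect_equal(unname(freq[["0.5"]]), 0.25, tolerance = 0.05)
})

test_that("DeLong test is null for identical scores and consistent with the ROC AUC", {
  set.seed(24)
  scores <- runif(40)
  labels <- rep(c(1, 0), 20)
  res <- delong_test(scores, scores, labels)
  expect_equal(res$delta, 0)
  expect_equal(res$p_value, 1)
  s2 <- scores + rnorm(40, 0, 0.2)
  res2 <- delong_test(scores, s2, labels)
  expect_equal(res2$auc_a, roc_curve(scores, labels)$auc)
  expect_equal(res2$auc_b, roc_curve(s2, labels)$auc)
})

test_that("DeLong agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(25)
  for (rep in 1:5) {
    labels <- rep(c(1, 0), c(12, 18))
    a <- runif(30) + 0.4 * labels
    b <- runif(30) + 0.2 * labels
    ours <- delong_test(a, b, labels)
    ra <- pROC::roc(labels, a, quiet = TRUE, direction = "<")
    rb <- pROC::roc(labels, b, quiet = TRUE, direction = "<")
    ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
    expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
    expect_equal(ours$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  }
})

test_that("binary reader calls are accepted as two-valued scores", {
  labels <- rep(c(1, 0), c(10, 20))
  calls <- ifelse(labels == 1, 0.9, 0.2)
  calls[1:3] <- 0.2   # three false negatives
  res <- delong_test(calls, calls, labels)
  expect_equal(res$auc_a, res$auc_b)
  expect_equal(res$p_value, 1)
})
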