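mk_img <- function(vals) ultrasound_image(vals, "slsc", 1e-4, 1e-4)

two_block_rois <- function(n) {
  mass <- tissue <- matrix(FALSE, n, 2)
  mass[, 1] <- TRUE
  tissue[, 2] <- TRUE
  roi_pair(mass, tissue)
}

test_that("gCNR is 1 for disjoint and 0 for identical ROI distributions", {
  rois <- two_block_rois(100)
  img <- mk_img(cbind(rep(0, 100), rep(1, 100)))
  expect_equal(gcnr(img, rois), 1)
  set.seed(10)
  v <- runif(100)
  expect_equal(gcnr(mk_img(cbind(v, v)), rois), 0)
  expect_equal(gcnr(mk_img(matrix(0.4, 100, 2)), rois), 0)  # constant value
})

test_that("gCNR reproduces the hand-computed three-bin overlap", {
  rois <- two_block_rois(4)
  img <- mk_img(cbind(c(0, 0, 1, 1), c(1, 1, 2, 2)))
  expect_equal(gcnr(img, rois, n_bins = 3), 0.5)
})

test_that("gCNR matches a brute-force histogram-overlap oracle and is symmetric", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rnorm(300, 0.4, 0.12)
    y <- rnorm(300, 0.4 + 0.1 * rep, 0.12)
    rois <- two_block_rois(300)
    img <- mk_img(cbind(x, y))
    img_sw <- mk_img(cbind(y, x))
    expect_equal(gcnr(img, rois, 64), brute_force_gcnr(x, y, 64), tolerance = 1e-10)
    expect_equal(gcnr(img, rois, 64), gcnr(img_sw, rois, 64))
  }
})

test_that("gCNR is invariant under increasing transforms up to discretization", {
  set.seed(12)
  sigma_m <- 0.3
  x <- sigma_m * sqrt(-2 * log(runif(4000)))   # Rayleigh mass
  y <- 1.0 * sqrt(-2 * log(runif(4000)))       # Rayleigh tissue
  rois <- two_block_rois(4000)
  lin <- gcnr(mk_img(cbind(x, y)), rois, 256)
  eps <- max(c(x, y)) * 1e-4
  logv <- gcnr(mk_img(cbind(log(x + eps), log(y + eps))), rois, 256)
  expect_lt(abs(lin - logv), 0.02)
})

test_that("increasing the separation of Gaussian ROIs never decreases gCNR", {
  set.seed(13)
  base <- rnorm(500, 0, 1)
  rois <- two_block_rois(500)
  vals <- sapply(seq(0, 3, by = 0.25), function(d) {
    gcnr(mk_img(cbind(base, base + d)), rois, 64)
  })
  expect_equal(vals[1], 0)  # zero separation: identical distributions
  expect_true(all(diff(vals) >= -1 / 64))  # tolerance of one histogram bin
})

test_that("threshold classification reproduces the worked clinical examples", {
  params <- classifier_params(0.76)
  expect_identical(classify_mass(0.91, params), "fluid")
  expect_identical(classify_mass(0.75, params), "solid")
  expect_identical(classify_mass(c(0.14, 0.36), params),
                   c("solid", "solid"))
  expect_identical(classify_mass(0.76, params), "fluid")  # tie goes to fluid
  expect_error(classify_mass(1.2, params), "\\[0, 1\\]")
  expect_warning(classifier_params(0.5), "acceptable range")
})

test_that("auto tissue ROI translates the mass mask at the same depth", {
  mass <- matrix(FALSE, 50, 100)
  mass[20:29, 45:54] <- TRUE
  rois <- auto_tissue_roi(mass)
  expect_equal(sum(rois$tissue_mask), sum(rois$mass_mask))
  expect_equal(which(rowSums(rois$tissue_mask) > 0),
               which(rowSums(rois$mass_mask) > 0))  # same depth rows
  expect_false(any(rois$mass_mask & rois$tissue_mask))
})

test_that("auto tissue ROI fails when the mass leaves no lateral room", {
  mass <- matrix(TRUE, 10, 20)
  expect_error(auto_tissue_roi(mass), "no lateral room")
})

test_that("translated masks preserve pixel counts for arbitrary blobs", {
  set.seed(14)
  for (rep in 1:20) {
    mask <- matrix(FALSE, 40, 120)
    ctr <- c(sample(10:30, 1), sample(40:80, 1))
    pts <- cbind(pmin(pmax(ctr[1] + rnorm(60, 0, 3), 1), 40),
                 pmin(pmax(ctr[2] + rnorm(60, 0, 4), 1), 120))
    mask[round(pts)] <- TRUE
    rois <- auto_tissue_roi(mask)
    expect_equal(sum(rois$tissue_mask), sum(mask))
    expect_false(any(rois$mass_mask & rois$tissue_mask))
  }
})

test_that("ROI pairs are validated", {
  m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE
  t2 <- matrix(FALSE, 5, 5); t2[2, 4] <- TRUE
  expect_s3_class(roi_pair(m, t2), "roi_pair")
  expect_error(roi_pair(m, m), "disjoint")
  t3 <- t2; t3[3, 4] <- TRUE
  expect_error(roi_pair(m, t3), "same number")
  expect_error(roi_pair(matrix(FALSE, 5, 5), t2), "nonempty")
})
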