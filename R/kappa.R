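#' Agreement interpretation band for a kappa value
#'
#' Standard interpretation cutpoints: below 0 poor; 0-0.20 slight;
#' 0.21-0.40 fair; 0.41-0.60 moderate; 0.61-0.80 substantial; above 0.81
#' perfect.
#'
#' @param kappa numeric kappa value(s).
#' @return character vector of band labels.
#' @export
kappa_band <- function(kappa) {
  vapply(kappa, function(k) {
    if (is.na(k)) return(NA_character_)
    if (k < 0) "poor"
    else if (k <= 0.20) "slight"
    else if (k <= 0.40) "fair"
    else if (k <= 0.60) "moderate"
    else if (k <= 0.80) "substantial"
    else "perfect"
  }, character(1))
}

#' Fleiss' kappa for multi-reader categorical ratings
#'
#' Chance-corrected agreement `kappa = (Pbar - Pe) / (1 - Pe)` over the
#' rating categories, with a large-sample variance under the null
#' hypothesis `kappa = 0`, the z score `kappa / se` and its two-sided
#' p-value. Two variance estimators are available: the corrected
#' Fleiss-Nee-Landis form (default) and the original large-sample form.
#'
#' @param ratings masses x readers character (or factor) matrix of
#'   categorical ratings, or a data frame coercible to one; every mass must
#'   be rated by the same number (>= 2) of readers.
#' @param categories optional fixed category vocabulary; defaults to the
#'   observed categories. (The content vocabulary in this package is
#'   solid / fluid / mixed / uncertain.)
#' @param variance one of `"fnl"` (Fleiss-Nee-Landis, default) or
#'   `"fleiss1971"`.
#' @return object of class `kappa_result`: `kappa`, `variance`, `se`, `z`,
#'   `p_value`, `band`, the agreement components `p_bar` and `p_e`, and a
#'   `degenerate` flag (all ratings in a single category, reported as
#'   kappa 1).
#' @export
fleiss_kappa <- function(ratings, categories = NULL,
                         variance = c("fnl", "fleiss1971")) {
  variance <- match.arg(variance)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("every mass must be rated by every reader")
  N <- nrow(ratings)
  n <- ncol(ratings)
  if (N < 1 || n < 2) stop("need >= 1 mass and >= 2 readers")
  categories <- categories %||% sort(unique(as.vector(ratings)))
  counts <- vapply(categories, function(cat) {
    rowSums(ratings == cat)
  }, numeric(N))
  counts <- matrix(counts, nrow = N)
  if (any(rowSums(counts) != n)) {
    stop("ratings outside the category vocabulary")
  }

  p_j <- colSums(counts) / (N * n)
  P_i <- (rowSums(counts^2) - n) / (n * (n - 1))
  p_bar <- mean(P_i)
  p_e <- sum(p_j^2)

  if (1 - p_e <= .Machine$double.eps) {
    # every rating in one category: agreement is trivially perfect but
    # chance correction is undefined
    res <- list(kappa = 1, variance = NA_real_, se = NA_real_, z = NA_real_,
                p_value = NA_real_, band = "perfect", p_bar = p_bar,
                p_e = p_e, n_masses = N, n_readers = n,
                variance_method = variance, degenerate = TRUE)
    class(res) <- "kappa_result"
    return(res)
  }

  kappa <- (p_bar - p_e) / (1 - p_e)
  q_j <- 1 - p_j
  s <- sum(p_j * q_j)
  v <- if (variance == "fnl") {
    2 * (s^2 - sum(p_j * q_j * (q_j - p_j))) / (N * n * (n - 1) * s^2)
  } else {
    2 * (p_e - (2 * n - 3) * p_e^2 + 2 * (n - 2) * sum(p_j^3)) /
      (N * n * (n - 1) * (1 - p_e)^2)
  }
  se <- sqrt(v)
  z <- kappa / se
  p <- 2 * stats::pnorm(-abs(z))
  res <- list(kappa = kappa, variance = v, se = se, z = z,
              p_value = max(p, .Machine$double.xmin), band = kappa_band(kappa),
              p_bar = p_bar, p_e = p_e, n_masses = N, n_readers = n,
              variance_method = variance, degenerate = FALSE)
  class(res) <- "kappa_result"
  res
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa_result> kappa %.4f (%s agreement), z %.3f, p %.3g, %d masses x %d readers\n",
              x$kappa, x$band, x$z, x$p_value, x$n_masses, x$n_readers))
  invisible(x)
}

#' Significance of a difference between two kappa values
#'
#' Two-sided z-test with the variances added as if the two panels were
#' independent (no covariance term is available for paired panels; the
#' approximation is flagged in the output).
#'
#' @param result_a,result_b [fleiss_kappa()] results carrying variances.
#' @return list with `delta`, `z`, `p_value` and
#'   `independence_approximation = TRUE`.
#' @export
kappa_difference_test <- function(result_a, result_b) {
  stopifnot(inherits(result_a, "kappa_result"), inherits(result_b, "kappa_result"))
  if (is.na(result_a$variance) || is.na(result_b$variance)) {
    stop("both kappa results must carry a variance (non-degenerate panels)")
  }
  delta <- result_a$kappa - result_b$kappa
  se <- sqrt(result_a$variance + result_b$variance)
  z <- delta / se
  p <- 2 * stats::pnorm(-abs(z))
  list(delta = delta, z = z, p_value = p, independence_approximation = TRUE)
}
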