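as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  pos <- labels %in% c("positive", "fluid", "1", "TRUE", "case")
  neg <- labels %in% c("negative", "solid", "0", "FALSE", "control")
  if (!all(pos | neg)) stop("labels must be binary (positive/fluid vs negative/solid)")
  pos
}

#' Empirical ROC curve with trapezoidal AUC
#'
#' Sweeps thresholds over all observed score values (plus 0 and 1): a mass
#' is called fluid (positive) when its score is at or above the threshold.
#' A true positive is a fluid mass at/above threshold; a true negative is a
#' solid mass below it. Endpoints (0,0) and (1,1) are always included, and
#' the AUC is the trapezoidal integral of sensitivity against
#' 1 - specificity.
#'
#' @param scores numeric vector of per-mass gCNR values.
#' @param labels binary truth per mass (`"positive"`/`"fluid"`/`TRUE` are
#'   the fluid class).
#' @param threshold_grid optional ascending threshold vector; defaults to
#'   the observed scores plus 0 and 1.
#' @return object of class `roc_result`: data frame of operating points
#'   (`threshold`, `sens`, `one_minus_spec`), `auc`, class counts.
#' @export
roc_curve <- function(scores, labels, threshold_grid = NULL) {
  pos <- as_binary_labels(labels)
  if (length(scores) != length(pos)) stop("scores and labels differ in length")
  n_pos <- sum(pos)
  n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("need at least one positive and one negative mass")
  }
  thr <- sort(unique(c(0, 1, threshold_grid, scores)))
  sens <- vapply(thr, function(t) sum(scores[pos] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / n_neg, numeric(1))
  # a threshold above every score yields the (0, 0) endpoint
  sens <- c(sens, 0)
  fpr <- c(fpr, 0)
  thr <- c(thr, Inf)
  pts <- data.frame(threshold = thr, sens = sens, one_minus_spec = fpr)
  pts <- pts[order(pts$one_minus_spec, pts$sens), ]
  rownames(pts) <- NULL
  structure(
    list(points = pts,
         auc = auc_trapezoid(pts$one_minus_spec, pts$sens),
         n_pos = n_pos, n_neg = n_neg),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.4f (%d positives, %d negatives, %d points)",
              x$auc, x$n_pos, x$n_neg, nrow(x$points)))
  if (!is.null(x$ci)) cat(sprintf(", 95%% CI [%.4f, %.4f]", x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

#' Trapezoidal area under a curve
#'
#' Standard trapezoid sum over points sorted by x; duplicate x values
#' contribute zero width (vertical ROC segments).
#'
#' @param x,y coordinates (1 - specificity and sensitivity for an ROC).
#' @return the trapezoidal integral.
#' @export
auc_trapezoid <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (is.unsorted(x)) {
    o <- order(x, y)
    x <- x[o]
    y <- y[o]
    message("auc_trapezoid: points were unsorted; sorted by x")
  }
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

# Rank-based AUC (Mann-Whitney with ties counted 1/2); equals the
# trapezoidal AUC of the empirical ROC and is O(n log n) for bootstrap use.
auc_rank <- function(scores, pos) {
  r <- rank(scores)
  (sum(r[pos]) - sum(pos) * (sum(pos) + 1) / 2) / (sum(pos) * sum(!pos))
}

#' Percentile bootstrap CI for the AUC
#'
#' Resamples (score, label) pairs jointly with replacement and returns the
#' 2.5/97.5 percentile interval of the resampled AUCs. Resamples that lose
#' one of the classes are redrawn (their count is reported as attribute
#' `"n_redrawn"`).
#'
#' @param scores,labels as in [roc_curve()].
#' @param n_iter bootstrap iterations (study default 1000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return numeric `c(low, high)` with attribute `n_redrawn`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_iter = 1000L, seed = 1L,
                             conf = 0.95) {
  pos <- as_binary_labels(labels)
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (sum(pos) == 0 || sum(!pos) == 0) stop("both classes must be present")
  n <- length(scores)
  with_seed(seed, {
    aucs <- numeric(n_iter)
    redrawn <- 0L
    for (b in seq_len(n_iter)) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        if (any(pos[idx]) && any(!pos[idx])) break
        redrawn <- redrawn + 1L
      }
      aucs[b] <- auc_rank(scores[idx], pos[idx])
    }
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(aucs, c(alpha, 1 - alpha), type = 7))
    attr(ci, "n_redrawn") <- redrawn
    ci
  })
}

#' Lower-bound AUC of a single operating point
#'
#' Area of the two-segment ROC running from (0,0) to the operating point
#' (1 - specificity, sensitivity) to (1,1); equals
#' `(sensitivity + specificity) / 2`. Used to score a categorical reader
#' assessment that yields a single point rather than a curve.
#'
#' @param sens,spec sensitivity and specificity in `[0, 1]`.
#' @return the lower-bound AUC.
#' @export
lower_bound_auc <- function(sens, spec) {
  if (any(c(sens, spec) < 0) || any(c(sens, spec) > 1)) {
    stop("sens and spec must lie in [0, 1]")
  }
  (sens + spec) / 2
}

#' Bootstrap CI for the mean lower-bound AUC of a reader panel
#'
#' Resamples the readers' operating points with replacement (duplicates
#' allowed), averages their lower-bound AUCs per iteration, and returns the
#' mean with its percentile CI.
#'
#' @param points matrix or data frame with columns `sens` and `spec`, one
#'   row per reader (>= 2 readers).
#' @param n_iter bootstrap iterations (study default 1000).
#' @param seed integer seed.
#' @param conf confidence level.
#' @return list with `mean`, `ci_low`, `ci_high`.
#' @export
bootstrap_reader_mean_auc <- function(points, n_iter = 1000L, seed = 1L,
                                      conf = 0.95) {
  points <- as.data.frame(points)
  if (nrow(points) < 2) stop("need at least two reader operating points")
  lb <- lower_bound_auc(points$sens, points$spec)
  k <- length(lb)
  with_seed(seed, {
    means <- vapply(seq_len(n_iter), function(b) {
      mean(lb[sample.int(k, k, replace = TRUE)])
    }, numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
    list(mean = mean(lb), ci_low = ci[1], ci_high = ci[2])
  })
}

#' DeLong's paired test for correlated AUCs
#'
#' Nonparametric comparison of the AUCs of two score sets measured on the
#' same masses, via placement-value structural components. Binary reader
#' calls may be supplied as two-valued scores. Returns the two AUCs, their
#' difference and the two-sided normal-approximation p-value.
#'
#' @param scores_a,scores_b paired score vectors on the same masses.
#' @param labels binary truth (shared).
#' @return list with `auc_a`, `auc_b`, `delta`, `z`, `p_value` and a
#'   `degenerate` flag (zero variance with a nonzero difference; the
#'   p-value is then reported as `1e-16`).
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  pos <- as_binary_labels(labels)
  if (length(scores_a) != length(pos) || length(scores_b) != length(pos)) {
    stop("scores_a, scores_b and labels must be paired on the same masses")
  }
  if (sum(pos) == 0 || sum(!pos) == 0) stop("both classes must be present")
  xa <- scores_a[pos]; ya <- scores_a[!pos]
  xb <- scores_b[pos]; yb <- scores_b[!pos]
  m <- length(xa); n <- length(ya)

  placements <- function(x, y) {
    # psi(X_i, Y_j) = 1 if X>Y, 1/2 if tie, 0 otherwise
    psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  pa <- placements(xa, ya)
  pb <- placements(xb, yb)
  delta <- pa$auc - pb$auc

  var_delta <- if (m > 1 && n > 1) {
    s10 <- stats::var(pa$v10 - pb$v10)
    s01 <- stats::var(pa$v01 - pb$v01)
    s10 / m + s01 / n
  } else {
    0
  }
  degenerate <- var_delta <= 0
  if (degenerate) {
    p <- if (delta == 0) 1 else 1e-16
    z <- if (delta == 0) 0 else sign(delta) * Inf
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = pa$auc, auc_b = pb$auc, delta = delta, z = z, p_value = p,
       degenerate = degenerate && delta != 0)
}
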