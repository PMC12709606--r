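# Independent oracles and small fixture builders shared across tests.

# Histogram-overlap gCNR computed through hist() with explicit breaks --
# an independent code path from the package's findInterval/tabulate.
brute_force_gcnr <- function(x, y, n_bins) {
  rng <- range(c(x, y))
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  hx <- hist(x, breaks = breaks, plot = FALSE)$counts / length(x)
  hy <- hist(y, breaks = breaks, plot = FALSE)$counts / length(y)
  1 - sum(pmin(hx, hy))
}

# Mann-Whitney AUC by explicit pairwise comparison, ties counted 1/2.
mw_auc <- function(scores, pos) {
  x <- scores[pos]
  y <- scores[!pos]
  mean(outer(x, y, ">") + 0.5 * outer(x, y, "=="))
}

# Wrap a list of aligned n_depth x N matrices as an aligned_channels object
# so beamformers can be exercised on synthetic aperture data.
fake_aligned <- function(mats, geometry = array_geometry(),
                         dz = geometry$sound_speed / (2 * geometry$sampling_freq),
                         depth0 = 0.01) {
  n_depth <- nrow(mats[[1]])
  structure(
    list(lines = mats, depths = depth0 + (seq_len(n_depth) - 1) * dz, dz = dz,
         line_positions = seq(0, by = 0.6e-3, length.out = length(mats)),
         geometry = geometry),
    class = "aligned_channels"
  )
}

# Deterministic 10-mass x 3-reader, 2-category toy panel; hand computation
# gives Pbar = 0.6, Pe = 0.5, kappa = 0.2 exactly.
toy_ratings <- function() {
  rows <- c("aaa", "aab", "abb", "bbb", "aba", "bba", "aaa", "bbb", "aab", "bab")
  t(vapply(strsplit(rows, ""), identity, character(3)))
}
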