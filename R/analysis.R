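#' Spatial information per spike
#'
#' Skaggs-style mutual-information score of place selectivity.  For each
#' cell, with occupancy `p_i` of position bin `i`, bin-conditional mean
#' rate `lambda_i`, and overall mean rate `lambda` (all over moving
#' periods only):
#' \deqn{\sum_i \frac{\lambda_i}{\lambda}
#'       \log_2\frac{\lambda_i}{\lambda}\, p_i .}
#' Cells whose overall mean rate does not exceed `rate_threshold` are
#' excluded from the average; bins with zero rate contribute zero (the
#' `x log x -> 0` limit).  The score is invariant to a uniform rescaling of
#' all rates.
#'
#' @param z Rate matrix (cells x time samples, kHz).
#' @param pos Position at each sample.
#' @param moving Logical (or 0/1) vector: samples to include.
#' @param n_bin Number of position bins (per arm if `arm` is given).
#' @param arm Optional arm index per sample (Y-maze); bins are then nested
#'   within arms (`3 * n_bin` bins total) and `pos` spans \[0, 0.5\].
#' @param pos_range Range of positions covered by the bins.
#' @param rate_threshold Inclusion threshold on the mean rate (kHz);
#'   default 0.001 kHz = 1 Hz.
#' @param base Logarithm base (default 2: bits per spike).
#' @return A list of class `"place_field_summary"`: `info_mean` (average
#'   over included cells; `NA` if none), `info` (per included cell),
#'   `included` (logical per cell), `lambda_mean`, `rate_map` (cells x
#'   bins), `occupancy`.
#' @export
information_per_spike <- function(z, pos, moving, n_bin = 50, arm = NULL,
                                  pos_range = c(0, 1),
                                  rate_threshold = 0.001, base = 2) {
  stopifnot(ncol(z) == length(pos), length(moving) == length(pos))
  sel <- as.logical(moving)
  if (!any(sel)) stop("information_per_spike: no moving samples")
  pos <- pos[sel]
  z <- z[, sel, drop = FALSE]
  eps <- 1e-12
  b <- pmin(pmax(1L + floor((pos - pos_range[1]) /
                              (diff(pos_range) + eps) * n_bin), 1L), n_bin)
  if (!is.null(arm)) {
    arm <- arm[sel]
    b <- (pmax(arm, 1L) - 1L) * n_bin + b
    n_bin <- 3L * n_bin
  }
  counts <- tabulate(b, nbins = n_bin)
  occupancy <- counts / sum(counts)
  # bin-wise mean rates: sum per bin / count per bin
  sums <- matrix(0, nrow(z), n_bin)
  for (i in seq_len(n_bin)) {
    if (counts[i] > 0)
      sums[, i] <- rowSums(z[, b == i, drop = FALSE]) / counts[i]
  }
  lambda_mean <- rowMeans(z)
  info <- vapply(seq_len(nrow(z)), function(ci) {
    lam <- lambda_mean[ci]
    if (lam <= 0) return(0)
    r <- sums[ci, ] / lam
    ok <- r > 0 & occupancy > 0
    sum(r[ok] * log(r[ok], base = base) * occupancy[ok])
  }, numeric(1))
  included <- lambda_mean > rate_threshold
  structure(list(
    info_mean = if (any(included)) mean(info[included]) else NA_real_,
    info = info[included], included = included,
    lambda_mean = lambda_mean, rate_map = sums, occupancy = occupancy,
    n_bin = n_bin),
    class = "place_field_summary")
}

#' Weight-contrast statistic between two input groups
#'
#' The sum of weights from group A minus the sum from group B.  Positive
#' values mean the minority (cross-compartment correlated) group dominates,
#' i.e. CCA-like learning; negative values mean the majority group
#' dominates (PCA-like learning).
#'
#' @param w Weight vector over presynaptic inputs (or a 1-row matrix).
#' @param groups A list with elements `A` and `B` of input indices; they
#'   must not overlap.
#' @return The scalar contrast `sum(w[A]) - sum(w[B])`.
#' @export
weight_contrast <- function(w, groups) {
  w <- drop(w)
  A <- groups[[1]]; B <- groups[[2]]
  if (length(intersect(A, B)) > 0)
    stop("weight_contrast: overlapping groups")
  sum(w[A]) - sum(w[B])
}

#' Count propagating firing sequences per branch
#'
#' Detects population-activity events that traverse a branch of the
#' network.  Per branch, the neuron-index center of mass of the (Gaussian
#' smoothed) branch rates is tracked while the branch population rate is
#' above `rate_threshold`; an event is counted when the center of mass
#' starts within the first `enter_frac` of the branch and advances beyond
#' `1 - enter_frac` (i.e. traverses at least `traverse_frac` of the branch)
#' within `max_lag_ms`.
#'
#' @param z Rate matrix (neurons x time samples, kHz).
#' @param time_ms Time axis of the samples (ms), equally spaced.
#' @param branches Named list of neuron-index vectors, ordered along the
#'   propagation direction.
#' @param window_ms Optional `c(start, end)` restriction of the counting
#'   window.
#' @param smooth_ms Gaussian smoothing width (SD, ms) of the rate traces.
#' @param rate_threshold Branch mean-rate threshold defining active
#'   episodes (kHz).
#' @param enter_frac,traverse_frac Entry band (fraction of the branch
#'   within which the center of mass must start) and required coverage.
#' @param max_lag_ms Maximum traversal time.
#' @return A list of class `"sequence_count"` with integer `counts` per
#'   branch and per-branch event onset times `events`.
#' @export
count_branch_sequences <- function(z, time_ms, branches,
                                   window_ms = NULL, smooth_ms = 100,
                                   rate_threshold = 0.004,
                                   enter_frac = 0.15, traverse_frac = 0.75,
                                   max_lag_ms = 2000) {
  stopifnot(ncol(z) == length(time_ms))
  dt <- diff(time_ms[1:2])
  keep <- rep(TRUE, length(time_ms))
  if (!is.null(window_ms))
    keep <- time_ms >= window_ms[1] & time_ms < window_ms[2]
  tms <- time_ms[keep]
  # Gaussian smoothing kernel
  hw <- max(1L, round(3 * smooth_ms / dt))
  kern <- stats::dnorm(seq(-hw, hw) * dt, sd = smooth_ms)
  kern <- kern / sum(kern)
  smooth1 <- function(v) {
    out <- stats::filter(c(rep(v[1], hw), v, rep(v[length(v)], hw)), kern,
                         sides = 2)
    as.numeric(out[(hw + 1):(hw + length(v))])
  }
  counts <- integer(length(branches))
  events <- vector("list", length(branches))
  names(counts) <- names(branches)
  names(events) <- names(branches)
  for (bi in seq_along(branches)) {
    idx <- branches[[bi]]
    L <- length(idx)
    zb <- z[idx, keep, drop = FALSE]
    num <- smooth1(colSums(zb * seq_len(L)))
    den <- smooth1(colSums(zb))
    active <- den / L > rate_threshold
    com <- ifelse(active, num / pmax(den, 1e-12) / L, NA_real_)
    # episodes of contiguous activity
    r <- rle(active)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    ev <- numeric(0)
    for (e in which(r$values)) {
      s <- starts[e]; en <- ends[e]
      cc <- com[s:en]
      t0_rel <- which(cc <= enter_frac)[1]
      if (is.na(t0_rel)) next
      horizon <- min(length(cc), t0_rel + ceiling(max_lag_ms / dt))
      if (any(cc[t0_rel:horizon] >= enter_frac + traverse_frac,
              na.rm = TRUE)) {
        counts[bi] <- counts[bi] + 1L
        ev <- c(ev, tms[s + t0_rel - 1L])
      }
    }
    events[[bi]] <- ev
  }
  structure(list(counts = counts, events = events,
                 params = list(smooth_ms = smooth_ms,
                               rate_threshold = rate_threshold,
                               enter_frac = enter_frac,
                               traverse_frac = traverse_frac,
                               max_lag_ms = max_lag_ms)),
            class = "sequence_count")
}

#' Reference PCA and CCA on input traces
#'
#' Standard principal component analysis of each pathway's postsynaptic
#' input traces and canonical correlation analysis across the two pathways.
#' This serves as the external signal-processing benchmark against which
#' the learned synaptic weights are compared: PCA extracts the dominant
#' (majority-group) components within each pathway, CCA the correlated
#' (minority-group) pair across pathways.
#'
#' Near-singular covariance is handled by a small ridge regularization
#' applied to the within-set covariances before whitening.
#'
#' @param I_som,I_dnd Trace matrices (time samples x inputs).
#' @param n_components Number of components to return.
#' @param ridge Ridge coefficient (relative to the mean covariance
#'   diagonal) applied before whitening.
#' @return A list with `pca_som`, `pca_dnd` (loadings and sdev), and `cca`
#'   (canonical correlations `cor`, loadings `xcoef`, `ycoef`).
#' @export
reference_pca_cca <- function(I_som, I_dnd, n_components = 2,
                              ridge = 1e-8) {
  if (nrow(I_som) != nrow(I_dnd))
    stop("reference_pca_cca: traces of unequal length")
  if (nrow(I_som) < 2) stop("reference_pca_cca: need at least 2 samples")
  pca_som <- stats::prcomp(I_som, center = TRUE, scale. = FALSE)
  pca_dnd <- stats::prcomp(I_dnd, center = TRUE, scale. = FALSE)
  X <- scale(I_som, center = TRUE, scale = FALSE)
  Y <- scale(I_dnd, center = TRUE, scale = FALSE)
  Sxx <- crossprod(X) / (nrow(X) - 1)
  Syy <- crossprod(Y) / (nrow(Y) - 1)
  Sxy <- crossprod(X, Y) / (nrow(X) - 1)
  whiten <- function(S) {
    S <- S + diag(ridge * mean(diag(S)), nrow(S))
    e <- eigen(S, symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300))) %*% t(e$vectors)
  }
  Wx <- whiten(Sxx); Wy <- whiten(Syy)
  sv <- svd(Wx %*% Sxy %*% Wy)
  k <- min(n_components, length(sv$d))
  list(pca_som = list(loadings = pca_som$rotation[, 1:n_components,
                                                  drop = FALSE],
                      sdev = pca_som$sdev),
       pca_dnd = list(loadings = pca_dnd$rotation[, 1:n_components,
                                                  drop = FALSE],
                      sdev = pca_dnd$sdev),
       cca = list(cor = pmin(sv$d[1:k], 1),
                  xcoef = (Wx %*% sv$u)[, 1:k, drop = FALSE],
                  ycoef = (Wy %*% sv$v)[, 1:k, drop = FALSE]))
}
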