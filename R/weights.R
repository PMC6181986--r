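#' Initial recurrent weights of a chain network
#'
#' Gaussian connectivity profile in the index distance,
#' `w_ij = w_max * exp(-0.5 ((i - j) / w_width)^2)`, optionally with additive
#' standard-normal fluctuations.  Negative entries are clipped to zero and
#' self-connections are always zero.
#'
#' @param n Number of neurons (>= 2).
#' @param w_max Peak weight.
#' @param w_width Profile width (in neuron indices).
#' @param noise Add standard-normal fluctuations to every entry.
#' @return An `n` x `n` weight matrix.
#' @export
build_chain_weights <- function(n, w_max = 18, w_width = 5, noise = TRUE) {
  stopifnot(n >= 2, w_width > 0)
  d <- outer(seq_len(n), seq_len(n), "-")
  w <- w_max * exp(-0.5 * (d / w_width)^2)
  if (noise) w <- w + matrix(stats::rnorm(n * n), n, n)
  w[w < 0] <- 0
  diag(w) <- 0
  w
}

#' Initial EC-to-CA3 weights
#'
#' Familiar track: a Gaussian profile peaking where the EC neuron index
#' matches the CA3 neuron index, `w_ij = w_dnd_max * exp(-0.5 ((i - j) /
#' w_width)^2)`.  Unfamiliar track: the familiar weights with each
#' postsynaptic row independently permuted over the presynaptic index, so
#' every neuron keeps the same weight multiset but loses the spatial
#' arrangement.
#'
#' @param n_ca3,n_ec Matrix dimensions.
#' @param w_dnd_max Peak weight.
#' @param w_width Profile width.
#' @param familiarity `"familiar"` or `"unfamiliar"`.
#' @return An `n_ca3` x `n_ec` weight matrix.
#' @export
build_ec_weights <- function(n_ca3, n_ec, w_dnd_max = 5, w_width = 5,
                             familiarity = c("familiar", "unfamiliar")) {
  familiarity <- match.arg(familiarity)
  d <- outer(seq_len(n_ca3), seq_len(n_ec), "-")
  w <- w_dnd_max * exp(-0.5 * (d / w_width)^2)
  if (familiarity == "unfamiliar") {
    for (i in seq_len(n_ca3)) w[i, ] <- w[i, sample.int(n_ec)]
  }
  w
}

#' Initial uniform EC-to-CA3 weights
#'
#' Uniformly sampled weights on \[0, w_max\], used when EC inputs carry no
#' preconfigured spatial arrangement (Y-maze and branching protocols).
#'
#' @param n_ca3,n_ec Matrix dimensions.
#' @param w_max Upper bound of the uniform distribution.
#' @return An `n_ca3` x `n_ec` weight matrix.
#' @export
build_uniform_ec_weights <- function(n_ca3, n_ec, w_max = 2) {
  matrix(stats::runif(n_ca3 * n_ec, 0, w_max), n_ca3, n_ec)
}

#' Initial recurrent weights of the Y-maze network
#'
#' Three disjoint chain groups with within-group Gaussian profiles and zero
#' weights across groups, so the network holds three independent preexisting
#' firing sequences.
#'
#' @param n_group Neurons per group.
#' @param w_max Peak weight (default 20).
#' @param w_width Profile width.
#' @param noise Add standard-normal fluctuations within groups.
#' @return A `3 n_group` x `3 n_group` weight matrix.
#' @export
build_ymaze_weights <- function(n_group = 150, w_max = 20, w_width = 5,
                                noise = TRUE) {
  n <- 3 * n_group
  w <- matrix(0, n, n)
  for (g in 0:2) {
    idx <- g * n_group + seq_len(n_group)
    w[idx, idx] <- build_chain_weights(n_group, w_max, w_width, noise)
  }
  w
}

#' Initial recurrent weights of the branching network
#'
#' A root chain feeding two branch chains.  Within each group the usual
#' chain profile applies (peak `w_max`); root-to-branch couplings use peak
#' `w_prime_max` and are symmetric.  For branch A the coupling depends on
#' `i - j`; for branch B it depends on the combined distance from the
#' junction, `(n_root - i) + (j - root_plus_A)`, so both branches attach to
#' the end of the root.  Weights between the two branches are exactly zero.
#'
#' @param n_root,n_branch Neurons in the root and in each branch.
#' @param w_max Within-group peak weight.
#' @param w_prime_max Root-branch coupling peak weight.
#' @param w_width Profile width.
#' @param noise Add standard-normal fluctuations (not across branches).
#' @return A square weight matrix of size `n_root + 2 n_branch`, plus
#'   attributes `root`, `branch_a`, `branch_b` with the index ranges.
#' @export
build_branching_weights <- function(n_root = 100, n_branch = 150,
                                    w_max = 18, w_prime_max = 14,
                                    w_width = 5, noise = TRUE) {
  n <- n_root + 2 * n_branch
  root <- seq_len(n_root)
  br_a <- n_root + seq_len(n_branch)
  br_b <- n_root + n_branch + seq_len(n_branch)
  w <- matrix(0, n, n)
  for (idx in list(root, br_a, br_b))
    w[idx, idx] <- w_max * exp(-0.5 * (outer(idx, idx, "-") / w_width)^2)
  # root <-> branch A: distance i - j
  d_a <- outer(root, br_a, "-")
  w[root, br_a] <- w_prime_max * exp(-0.5 * (d_a / w_width)^2)
  w[br_a, root] <- t(w[root, br_a])
  # root <-> branch B: distance (n_root - i) + (j - (n_root + n_branch))
  d_b <- outer(n_root - root, br_b - (n_root + n_branch), "+")
  w[root, br_b] <- w_prime_max * exp(-0.5 * (d_b / w_width)^2)
  w[br_b, root] <- t(w[root, br_b])
  if (noise) {
    eps <- matrix(stats::rnorm(n * n), n, n)
    eps[br_a, br_b] <- 0
    eps[br_b, br_a] <- 0
    w <- w + eps
  }
  w[w < 0] <- 0
  diag(w) <- 0
  w[br_a, br_b] <- 0
  w[br_b, br_a] <- 0
  structure(w, root = root, branch_a = br_a, branch_b = br_b)
}
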