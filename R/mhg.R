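# The minimum hypergeometric (mHG) ranked-list test.
#
# For a ranked list of N guides containing the B guides of one gene, the
# mHG statistic is the minimum, over list prefixes of length n = 1..N-1,
# of the hypergeometric upper-tail probability of the gene's guides seen
# so far.  Because the minimum is taken over prefixes, the statistic is
# not itself a p-value; the exact null p-value (labels uniformly placed
# among ranks) is computed by a lattice dynamic program in compiled code,
# with a permutation estimator kept as an independent Monte-Carlo oracle.

# relative tolerance when comparing tail probabilities computed by
# different routes (R phyper vs compiled log-gamma sums); exact ties on
# the discrete tail support must compare equal
.mhg_rel_tol <- 1e-9

#' Hypergeometric upper-tail probability
#'
#' `P(X >= b)` for `X` hypergeometric: `n` draws without replacement from
#' a population of `N` containing `B` successes.
#'
#' @param b Number of successes (0 gives 1 for any valid setup).
#' @param n Draws.
#' @param B Successes in the population.
#' @param N Population size.
#' @return Probability in `[0, 1]`.
#' @export
hypergeometric_tail <- function(b, n, B, N) {
  if (any(b < 0) || any(b > pmin(n, B)) || any(n > N) || any(B > N) ||
      any(n < 0) || any(B < 0))
    stop("hypergeometric_tail: require 0 <= b <= min(n, B), n <= N, B <= N",
         call. = FALSE)
  phyper(b - 1, B, N - B, n, lower.tail = FALSE)
}

# mHG statistic from the sorted rank positions of a gene's guides.
#
# For a fixed count of guides seen, the upper tail grows with the prefix
# length, so the minimum over prefixes is attained immediately after a
# guide position; only those prefixes are evaluated.  When `groups` is
# given (tie-block ids of the ranked deltas, nondecreasing), prefixes may
# only cut between blocks of tied values: each candidate moves to the
# first block boundary at or after the guide position.  This makes the
# statistic invariant to the arbitrary ordering within ties and returns 1
# when the whole list is tied.
.mhg_rank_stat <- function(positions, N, groups = NULL) {
  B <- length(positions)
  if (B == 0) stop("mHG statistic: no labelled items", call. = FALSE)
  if (N < 2) return(list(stat = 1, pivot = NA_integer_))
  positions <- sort.int(positions)
  if (is.null(groups)) {
    cand <- positions[positions <= N - 1]
  } else {
    valid <- which(groups[-N] != groups[-1])  # cuts after these positions
    if (length(valid) == 0) return(list(stat = 1, pivot = NA_integer_))
    idx <- findInterval(positions - 1L, valid) + 1L
    cand <- valid[idx[idx <= length(valid)]]
    cand <- unique(cand)
  }
  if (length(cand) == 0) return(list(stat = 1, pivot = NA_integer_))
  b_at <- findInterval(cand, positions)
  tails <- phyper(b_at - 1, B, N - B, cand, lower.tail = FALSE)
  i <- which.min(tails)
  stat <- min(tails[i], 1)
  list(stat = stat, pivot = as.integer(cand[i]))
}

#' mHG statistic of a ranked binary label vector
#'
#' @param labels Binary (0/1) vector ordered by rank; the 1s mark the
#'   gene's guides.  Must contain at least one 1.
#' @param groups Optional integer vector of tie-block ids (same length as
#'   `labels`, nondecreasing): prefixes are only evaluated where the
#'   underlying ranked values change, so the statistic does not depend on
#'   the arbitrary order within ties.
#' @return List with `stat` (the minimum prefix tail, capped at 1) and
#'   `pivot` (smallest prefix length attaining it, `NA` when the
#'   statistic is 1 without an attaining prefix).
#' @export
mhg_statistic <- function(labels, groups = NULL) {
  if (!all(labels %in% c(0, 1)))
    stop("mhg_statistic: labels must be binary", call. = FALSE)
  positions <- which(labels == 1)
  if (length(positions) == 0)
    stop("mhg_statistic: no labelled items in list", call. = FALSE)
  .mhg_rank_stat(positions, length(labels), groups)
}

#' Exact null p-value of the mHG statistic
#'
#' `P(mHG <= stat)` under uniform placement of the `B` labels among `N`
#' ranks, by dynamic programming over the (ranks seen, labels seen)
#' lattice: the null probability mass of label placements whose prefix
#' tails ever reach `stat` is accumulated exactly (no Monte-Carlo, no
#' prefix union bound).
#'
#' @param stat Observed mHG statistic in `(0, 1]`.
#' @param N Length of the ranked list.
#' @param B Number of labelled items, `0 < B <= N`.
#' @param max_cells Lattice-size budget; `N * (B + 1)` beyond it raises a
#'   resource error suggesting [permutation_pvalue()].
#' @return Exact p-value in `(0, 1]`.
#' @export
mhg_exact_pvalue <- function(stat, N, B, max_cells = 1e8) {
  stopifnot(length(stat) == 1, length(N) == 1, length(B) == 1)
  if (B < 1 || B > N) stop("mhg_exact_pvalue: require 0 < B <= N",
                           call. = FALSE)
  if (is.na(stat) || stat <= 0 || stat > 1)
    stop("mhg_exact_pvalue: stat must be in (0, 1]", call. = FALSE)
  if (as.numeric(N) * (B + 1) > max_cells)
    stop("mhg_exact_pvalue: lattice of ", N, " x ", B + 1,
         " cells exceeds the budget; use permutation_pvalue() instead",
         call. = FALSE)
  mhg_dp_pvalue_cpp(stat, as.integer(N), as.integer(B), .mhg_rel_tol)
}

#' Permutation p-value of the mHG statistic
#'
#' Monte-Carlo estimate of the exact null p-value by re-placing the `B`
#' labels uniformly among the `N` ranks; uses the add-one correction
#' `p = (1 + #{perm <= obs}) / (n_perm + 1)`.  Serves as an independent
#' oracle for [mhg_exact_pvalue()].
#'
#' @param labels Binary label vector ordered by rank.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation stream.
#' @return List with `p` and the binomial Monte-Carlo standard error
#'   `mc_se`.
#' @export
permutation_pvalue <- function(labels, n_perm, seed) {
  stopifnot(n_perm >= 1)
  obs <- mhg_statistic(labels)$stat
  N <- length(labels)
  B <- sum(labels == 1)
  thresh <- obs * (1 + .mhg_rel_tol)
  set.seed(seed)
  hits <- 0L
  bseq <- seq_len(B) - 1
  for (i in seq_len(n_perm)) {
    pos <- sort.int(sample.int(N, B))
    keep <- pos <= N - 1
    if (!any(keep)) {
      stat <- 1
    } else {
      stat <- min(phyper(bseq[keep], B, N - B, pos[keep],
                         lower.tail = FALSE))
    }
    if (stat <= thresh) hits <- hits + 1L
  }
  p <- (1 + hits) / (n_perm + 1)
  list(p = p, mc_se = sqrt(p * (1 - p) / n_perm))
}
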