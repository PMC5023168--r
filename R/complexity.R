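#' Step-complexity formulas for uniform SAT solutions
#'
#' Closed-form step counts of three uniform spiking-neural-P-system
#' solutions to `SAT(n, m)`:
#' * `budding`: systems using neuron division and budding, `2n + mn + 6`;
#' * `division`: systems using neuron division only, `4n + mn + 5`;
#' * `ddsn`: the division-and-dissolution construction of this package,
#'   `2n + m + 3`.
#'
#' @param n number of variables (>= 1).
#' @param m number of clauses (>= 1).
#' @return Named integer vector with elements `budding`, `division`, `ddsn`.
#' @examples
#' sat_steps(3, 3)   # budding 21, division 26, ddsn 12
#' @export
sat_steps <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 1L, m >= 1L)
  c(budding = 2L * n + m * n + 6L,
    division = 4L * n + m * n + 5L,
    ddsn = 2L * n + m + 3L)
}

#' Step-complexity formulas for uniform Subset Sum solutions
#'
#' Closed-form step counts of five solutions to a Subset Sum instance
#' `(X, S)`.  The first four are nondeterministic: a single run checks one
#' random candidate subset, so judging the whole instance requires
#' traversing all `2^n - 1` nonempty subsets; their totals multiply the
#' per-subset cost accordingly (the per-subset sums add up to
#' `2^(n-1) * sum(X)`).
#' * `binary_snp`: standard systems with binary encoding, per subset
#'   `3k + 2`, where `k` is the minimal bit width holding every value and
#'   the target (`k = ceil(log2(max(x_max, S) + 1))`);
#' * `unary_snp`: standard systems with unary encoding, per subset
#'   `3 * sum(B) + 6`;
#' * `snpsp`: systems with structural plasticity, per subset
#'   `2 * sum(B) + 6`;
#' * `timefree`: time-free systems, per subset `3 * sum(B) + 2`;
#' * `ddsn`: the deterministic division-and-dissolution construction,
#'   `2n + x_max + S + 5` for the single run that enumerates all subsets.
#'
#' @param X integer vector of values, or a [subsetsum_instance()].
#' @param S positive integer target (ignored when `X` is an instance).
#' @return Named numeric vector with elements `binary_snp`, `unary_snp`,
#'   `snpsp`, `timefree`, `ddsn` (numeric: the traversal totals grow as
#'   `2^n`).
#' @examples
#' sat <- subsetsum_steps(c(1, 2, 3, 4), 5)
#' sat[["binary_snp"]]   # 165
#' sat[["ddsn"]]         # 22
#' @export
subsetsum_steps <- function(X, S = NULL) {
  if (inherits(X, "subsetsum_instance")) {
    S <- X$S; X <- X$X
  }
  X <- as.integer(X); S <- as.integer(S)
  stopifnot(length(X) >= 1L, all(X >= 1L), length(S) == 1L, S >= 1L)
  n <- length(X); x_max <- max(X)
  k <- ceiling(log2(max(x_max, S) + 1L))
  n_subsets <- 2^n - 1                       # nonempty subsets
  sum_over_subsets <- 2^(n - 1) * sum(X)     # sum of sum(B) over all B
  c(binary_snp = n_subsets * (3 * k + 2),
    unary_snp = 3 * sum_over_subsets + 6 * n_subsets,
    snpsp = 2 * sum_over_subsets + 6 * n_subsets,
    timefree = 3 * sum_over_subsets + 2 * n_subsets,
    ddsn = 2 * n + x_max + S + 5)
}

#' Step-count table for SAT over a grid of problem sizes
#'
#' Evaluates the three [sat_steps()] formulas on every `(n, m)` in the grid.
#'
#' @param n_max,m_max grid bounds (defaults 50).
#' @return Data frame with columns `n`, `m`, `budding`, `division`, `ddsn`
#'   (`n_max * m_max` rows).
#' @export
sat_step_table <- function(n_max = 50L, m_max = 50L) {
  grid <- expand.grid(n = seq_len(n_max), m = seq_len(m_max))
  grid$budding <- 2L * grid$n + grid$m * grid$n + 6L
  grid$division <- 4L * grid$n + grid$m * grid$n + 5L
  grid$ddsn <- 2L * grid$n + grid$m + 3L
  grid
}

#' Step-count series for Subset Sum over X = \{1, ..., n\}
#'
#' Evaluates the five [subsetsum_steps()] formulas on the instance family
#' `X = {1, ..., n}` with a fixed target, using the closed form
#' `sum over subsets of sum(B) = 2^(n-1) * n (n + 1) / 2`.
#'
#' @param n_max largest `n` (default 50).
#' @param S target (default 5).
#' @return Data frame with columns `n`, `binary_snp`, `unary_snp`, `snpsp`,
#'   `timefree`, `ddsn`.
#' @export
subsetsum_step_series <- function(n_max = 50L, S = 5L) {
  n <- seq_len(n_max)
  k <- ceiling(log2(pmax(n, S) + 1))
  n_subsets <- 2^n - 1
  sum_over_subsets <- 2^(n - 1) * n * (n + 1) / 2
  data.frame(
    n = n,
    binary_snp = n_subsets * (3 * k + 2),
    unary_snp = 3 * sum_over_subsets + 6 * n_subsets,
    snpsp = 2 * sum_over_subsets + 6 * n_subsets,
    timefree = 3 * sum_over_subsets + 2 * n_subsets,
    ddsn = 2 * n + n + S + 5)
}
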