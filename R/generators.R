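#' Seeded random CNF instances
#'
#' Draws `m` clauses over `n` variables: each clause picks a width uniformly
#' from `1..min(width_max, n)`, then that many distinct variables (so no
#' clause ever contains a variable and its negation) with uniform random
#' polarity.  Identical seed and parameters yield identical instances.
#'
#' @param n number of variables (>= 2).
#' @param m number of clauses (>= 1).
#' @param seed RNG seed; `NULL` uses the session RNG state.
#' @param width_max largest clause width (default 3).
#' @return A [cnf_instance()].
#' @export
random_cnf <- function(n, m, seed = NULL, width_max = 3L) {
  n <- as.integer(n); m <- as.integer(m)
  stopifnot(n >= 2L, m >= 1L, width_max >= 1L)
  with_seed(seed, {
    clauses <- lapply(seq_len(m), function(i) {
      w <- sample.int(min(width_max, n), 1L)
      vars <- sample.int(n, w)
      signs <- sample(c(1L, -1L), w, replace = TRUE)
      vars * signs
    })
    cnf_instance(n, clauses)
  })
}

#' Seeded random Subset Sum instances
#'
#' Draws `n` values uniformly from `1..value_max`.  The target is either
#' drawn uniformly from `1..sum(X)` (so at least the full set reaches it
#' when equality happens to hold) or, with `planted = TRUE`, set to the sum
#' of a random nonempty subset, guaranteeing at least one solution.
#'
#' @param n number of values (>= 2).
#' @param value_max largest value (default 8).
#' @param seed RNG seed; `NULL` uses the session RNG state.
#' @param planted whether to plant a guaranteed solution subset.
#' @return A [subsetsum_instance()].
#' @export
random_subsetsum <- function(n, value_max = 8L, seed = NULL, planted = FALSE) {
  n <- as.integer(n); value_max <- as.integer(value_max)
  stopifnot(n >= 2L, value_max >= 1L)
  with_seed(seed, {
    X <- sample.int(value_max, n, replace = TRUE)
    S <- if (planted) {
      mask <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (!any(mask)) mask[sample.int(n, 1L)] <- TRUE
      sum(X[mask])
    } else {
      sample.int(sum(X), 1L)
    }
    subsetsum_instance(X, S)
  })
}
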