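#' CNF instances
#'
#' A SAT instance in conjunctive normal form: `n_vars` Boolean variables and
#' a list of clauses, each a set of signed 1-based variable indices (positive
#' for the literal `x_j`, negative for its negation).  Duplicate literals in
#' a clause collapse; a clause containing both `x_j` and its negation is
#' rejected (it is not representable in the spike encoding, which reserves
#' one spike for a positive and two spikes for a negative occurrence).
#'
#' The uniform construction requires `n_vars >= 2`: with a single variable
#' the output family's forgetting-rule ladder is empty while the cleanup
#' spike of the generation stage would trigger the dissolution guard, so the
#' system family is ill-defined at `n = 1`.
#'
#' @param n_vars number of variables (>= 2).
#' @param clauses list of integer vectors of signed variable indices
#'   (at least one clause).
#' @return An object of class `cnf_instance` with fields `n` and `clauses`.
#' @examples
#' cnf_instance(3, list(c(1, 2), c(-2, 3), c(-1, 2, 3)))
#' @export
cnf_instance <- function(n_vars, clauses) {
  n_vars <- as.integer(n_vars)
  if (length(n_vars) != 1L || is.na(n_vars) || n_vars < 2L) {
    stop("a CNF instance needs at least two variables")
  }
  if (!is.list(clauses) || length(clauses) < 1L) {
    stop("a CNF instance needs at least one clause")
  }
  clauses <- lapply(clauses, function(cl) {
    cl <- unique(as.integer(cl))
    if (any(is.na(cl)) || any(cl == 0L) || any(abs(cl) > n_vars)) {
      stop("clause literals must be signed variable indices in 1..n")
    }
    if (any(cl %in% -cl)) {
      stop(errorCondition(
        "a clause containing a variable and its negation is not representable in the spike encoding",
        class = "ddsnp_complementary_literal_error"))
    }
    sort(cl)
  })
  structure(list(n = n_vars, clauses = clauses), class = "cnf_instance")
}

#' @export
print.cnf_instance <- function(x, ...) {
  lit <- function(l) if (l > 0) paste0("x", l) else paste0("-x", -l)
  cls <- vapply(x$clauses, function(cl) paste(vapply(cl, lit, ""), collapse = " | "), "")
  cat(sprintf("<cnf_instance: %d variables, %d clauses>\n", x$n, length(x$clauses)))
  cat(paste0("  (", cls, ")", collapse = " &\n"), "\n")
  invisible(x)
}

#' Spike encoding of one clause
#'
#' Each clause is encoded variable by variable: one spike when the positive
#' literal occurs, two spikes when the negated literal occurs, no spike when
#' the variable is absent.
#'
#' @param clause integer vector of signed variable indices.
#' @param n number of variables.
#' @return Integer vector of length `n` with values in \{0, 1, 2\}.
#' @examples
#' encode_clause(c(-1, 2, 3), 3)  # 2 1 1
#' @export
encode_clause <- function(clause, n) {
  clause <- unique(as.integer(clause))
  if (any(clause == 0L) || any(abs(clause) > n)) {
    stop("clause literals must be signed variable indices in 1..n")
  }
  if (any(clause %in% -clause)) {
    stop(errorCondition(
      "a clause containing a variable and its negation is not representable in the spike encoding",
      class = "ddsnp_complementary_literal_error"))
  }
  alpha <- integer(n)
  alpha[clause[clause > 0L]] <- 1L
  alpha[-clause[clause < 0L]] <- 2L
  alpha
}

# Dictionary pairs from a per-variable source family to the output neurons:
# (prefix(i), o_b) for every bitstring b of length i whose last bit equals
# `bit`.  Used by both uniform constructions.
output_dict_pairs <- function(n, prefix_for, bit) {
  pairs <- NULL
  for (i in seq_len(n)) {
    b <- bitstrings(i)
    b <- b[substr(b, i, i) == bit]
    pairs <- rbind(pairs, cbind(prefix_for(i), paste0("o_", b)))
  }
  pairs
}

#' Build the uniform DDSN P system for SAT(n, m)
#'
#' Constructs the system family solving every SAT instance with `n` variables
#' and `m` clauses.  The `3n + 5` initial neurons comprise the division seed
#' (label `0`), the generation-stage clock (`1`, `2`, `3`), the input gate
#' driver `d` holding `2m` spikes, and per variable an input neuron `in_xi`
#' and the two polarity checkers `Cxi_1` / `Cxi_0`.  During the first
#' `2n - 1` steps the seed's descendants divide into the `2^n` output neurons
#' `o_<bitstring>`, one per truth assignment; each clause then dissolves the
#' output neurons whose assignment falsifies it.  The survivors at halting
#' are exactly the satisfying assignments.
#'
#' @param n number of variables (>= 2).
#' @param m number of clauses (>= 1).
#' @return A [ddsn_system()] with declared horizon `2n + m + 3`.
#' @export
build_sat_system <- function(n, m) {
  n <- as.integer(n); m <- as.integer(m)
  if (length(n) != 1L || is.na(n) || n < 2L) stop("build_sat_system requires n >= 2")
  if (length(m) != 1L || is.na(m) || m < 1L) stop("build_sat_system requires m >= 1")
  in_x <- paste0("in_x", seq_len(n))
  cx1 <- paste0("Cx", seq_len(n), "_1")
  cx0 <- paste0("Cx", seq_len(n), "_0")
  labels <- c("0", "1", "2", "3", "d", in_x, cx1, cx0)
  spikes <- integer(length(labels))
  spikes[labels %in% c("0", "2", "3")] <- 1L
  spikes[labels == "d"] <- 2L * m
  syn <- rbind(
    c("3", "2"), c("2", "1"), c("1", "2"), c("1", "0"), c("3", "d"),
    cbind("d", in_x),
    cbind(in_x, cx1), cbind(in_x, cx0),
    output_dict_pairs(n, function(i) paste0("Cx", i, "_1"), "1"),
    output_dict_pairs(n, function(i) paste0("Cx", i, "_0"), "0"))
  blocks <- list(
    rule_block("1", list(rule_fire(spike_set(1), 1))),
    rule_block("2", list(rule_fire(spike_set(1), 1), rule_forget(spike_set(2), 2))),
    rule_block("3", list(rule_fire(spike_set(1), 1, delay = 2L * n - 1L))),
    rule_block("d", list(rule_fire(spike_set(3, 2), 2))),      # a(a^2)^+/a^2 -> a
    rule_block("^in_x[0-9]+$", list(
      rule_fire(spike_set(1), 1),
      rule_fire(spike_set(2), 2, 2),
      rule_fire(spike_set(3), 3, 3)), regex = TRUE),
    rule_block("^Cx[0-9]+_1$", list(
      rule_fire(spike_set(1), 1),
      rule_fire(spike_set(3), 3, 1),
      rule_forget(spike_set(2), 2)), regex = TRUE),
    rule_block("^Cx[0-9]+_0$", list(
      rule_fire(spike_set(1), 1),
      rule_fire(spike_set(2), 2, 1),
      rule_forget(spike_set(3), 3)), regex = TRUE),
    rule_block("0", list(rule_divide(spike_set(1), "o_1", "o_0"))),
    rule_block(sprintf("^o_[01]{1,%d}$", n - 1L),
               list(rule_divide(spike_set(1), "{label}1", "{label}0")),
               regex = TRUE),
    rule_block(sprintf("^o_[01]{%d}$", n),
               c(lapply(seq_len(n - 1L), function(k) rule_forget(spike_set(k), k)),
                 list(rule_dissolve(spike_set(n)))),
               regex = TRUE))
  ddsn_system(
    neurons = data.frame(label = labels, spikes = spikes, stringsAsFactors = FALSE),
    syn = syn, rules = blocks, input = in_x,
    out_pattern = sprintf("^o_[01]{%d}$", n),
    horizon = 2L * n + m + 3L)
}

#' Encode a CNF instance as input spike trains
#'
#' Each variable's train carries `2n` leading empty steps (buying time for
#' the generation stage) followed by the clause encodings: clause `c` enters
#' at step `2n + c`.
#'
#' @param cnf a [cnf_instance()].
#' @return Named list of integer vectors, one per input label `in_xi`, each
#'   of length `2n + m`.
#' @export
build_sat_input <- function(cnf) {
  stopifnot(inherits(cnf, "cnf_instance"))
  n <- cnf$n; m <- length(cnf$clauses)
  alpha <- vapply(cnf$clauses, encode_clause, integer(n), n = n)
  alpha <- matrix(alpha, nrow = n)            # rows: variables, cols: clauses
  trains <- lapply(seq_len(n), function(j) c(integer(2L * n), alpha[j, ]))
  names(trains) <- paste0("in_x", seq_len(n))
  trains
}

#' Solve a SAT instance with the DDSN P system
#'
#' Builds the `SAT(n, m)` system family, feeds the encoded instance, runs the
#' engine in strict (deterministic) mode, and decodes the surviving output
#' labels into satisfying assignments.
#'
#' @param cnf a [cnf_instance()].
#' @param max_steps optional step budget (default: ten times the horizon
#'   `2n + m + 3`).
#' @param trace,history passed to [ddsn_run()].
#' @return List with `assignments` (sorted character bitstrings, position
#'   `i` giving the value of `x_i`, `"1"` for true; empty when
#'   unsatisfiable), `steps` (halting step) and `run` (the full
#'   [ddsn_run()] result).
#' @examples
#' cnf <- sat_example_instance()
#' sol <- solve_sat(cnf)
#' sol$assignments   # "011" "101" "111"
#' sol$steps         # 12
#' @export
solve_sat <- function(cnf, max_steps = NULL, trace = FALSE, history = FALSE) {
  stopifnot(inherits(cnf, "cnf_instance"))
  system <- build_sat_system(cnf$n, length(cnf$clauses))
  trains <- build_sat_input(cnf)
  run <- ddsn_run(system, trains, max_steps = max_steps, mode = "strict",
                  trace = trace, history = history)
  list(assignments = sort(sub("^o_", "", run$surviving)),
       steps = run$steps, run = run)
}

#' Brute-force SAT oracle
#'
#' Enumerates all `2^n` assignments and keeps those satisfying every clause.
#' Independent of the simulator; used to cross-check it.
#'
#' @param cnf a [cnf_instance()].
#' @return Sorted character vector of satisfying assignments as bitstrings.
#' @export
brute_force_sat <- function(cnf) {
  stopifnot(inherits(cnf, "cnf_instance"))
  n <- cnf$n
  if (n > 20L) stop("brute force is limited to n <= 20")
  bits <- as.matrix(expand.grid(rep(list(0:1), n)))  # column j: value of x_j
  ok <- rep(TRUE, nrow(bits))
  for (cl in cnf$clauses) {
    cl_ok <- rep(FALSE, nrow(bits))
    for (l in cl) {
      cl_ok <- cl_ok | (if (l > 0L) bits[, l] == 1L else bits[, -l] == 0L)
    }
    ok <- ok & cl_ok
  }
  if (!any(ok)) return(character(0))
  sort(apply(bits[ok, , drop = FALSE], 1L, paste0, collapse = ""))
}
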