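#' Subset Sum instances
#'
#' A set of positive integers `X = {x_1, ..., x_n}` and a positive target
#' `S`; the question is which subsets of `X` sum exactly to `S`.  Duplicate
#' values are allowed: subsets are index-based, so equal-valued distinct
#' solutions are reported separately.  The spike encoding `3 x_i + 3`
#' requires every `x_i >= 1`, and the division chain requires `n >= 2`.
#'
#' @param X integer vector of values (all >= 1, length >= 2).
#' @param S positive integer target.
#' @return An object of class `subsetsum_instance` with fields `X`, `S`, `n`
#'   and `x_max`.
#' @examples
#' subsetsum_instance(c(1, 2, 3, 4), 5)
#' @export
subsetsum_instance <- function(X, S) {
  X <- as.integer(X); S <- as.integer(S)
  if (length(X) < 2L) stop("a Subset Sum instance needs at least two values")
  if (anyNA(X) || any(X < 1L)) stop("all values must be positive integers")
  if (length(S) != 1L || is.na(S) || S < 1L) stop("the target must be a positive integer")
  structure(list(X = X, S = S, n = length(X), x_max = max(X)),
            class = "subsetsum_instance")
}

#' @export
print.subsetsum_instance <- function(x, ...) {
  cat(sprintf("<subsetsum_instance: X = {%s}, S = %d>\n",
              paste(x$X, collapse = ", "), x$S))
  invisible(x)
}

#' Build the uniform DDSN P system for Subset Sum with n values
#'
#' Constructs the system family solving every Subset Sum instance with `n`
#' values.  The `3n + 6` initial neurons comprise the division seed (`0`),
#' the generation-stage clock (`1`, `2`, `3`), the completion counter `4`,
#' the target neuron `s`, and per value an input neuron `in_i` with two
#' relays `di_1` (completion signalling) and `di_2` (value transfer).  The
#' generation stage enumerates the `2^n` subsets as output neurons
#' `o_<bitstring>`; the input stage deposits `3 x_i` spikes into every output
#' neuron whose subset contains `x_i`; the checking stage then pays out the
#' target `S` in instalments of two spikes plus a final single spike,
#' dissolving the output neurons whose subset sum falls short of or exceeds
#' `S`.
#'
#' @param n number of values (>= 2).
#' @return A [ddsn_system()]; the step horizon depends on the instance, so
#'   [solve_subsetsum()] sets the step budget.
#' @export
build_subsetsum_system <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) stop("build_subsetsum_system requires n >= 2")
  in_i <- paste0("in_", seq_len(n))
  d1 <- paste0("d", seq_len(n), "_1")
  d2 <- paste0("d", seq_len(n), "_2")
  labels <- c("0", "1", "2", "3", "4", "s", in_i, d1, d2)
  spikes <- integer(length(labels))
  spikes[labels %in% c("0", "2", "3")] <- 1L
  syn <- rbind(
    c("3", "2"), c("2", "1"), c("1", "2"), c("1", "0"), c("4", "s"), c("s", "0"),
    cbind(in_i, d1), cbind(in_i, d2), cbind(d1, "4"),
    output_dict_pairs(n, function(i) paste0("d", i, "_2"), "1"))
  blocks <- list(
    rule_block("1", list(rule_fire(spike_set(1), 1))),
    rule_block("2", list(rule_fire(spike_set(1), 1), rule_forget(spike_set(2), 2))),
    rule_block("3", list(rule_fire(spike_set(1), 1, delay = 2L * n - 1L))),
    rule_block("^in_[0-9]+$", list(
      rule_fire(spike_set(6, 3), 3, 3),        # a^3(a^3)^+/a^3 -> a^3
      rule_fire(spike_set(3), 3, 1)), regex = TRUE),
    rule_block("^d[0-9]+_1$", list(
      rule_fire(spike_set(1), 1),
      rule_forget(spike_set(3), 3)), regex = TRUE),
    rule_block("^d[0-9]+_2$", list(
      rule_fire(spike_set(3), 3, 3),
      rule_forget(spike_set(1), 1)), regex = TRUE),
    rule_block("4", list(rule_fire(spike_set(n), n, 1))),
    rule_block("s", list(
      rule_fire(spike_set(3, 2), 2, 2),        # a(a^2)^+/a^2 -> a^2
      rule_fire(spike_set(1), 1))),
    rule_block("0", list(rule_divide(spike_set(1), "o_1", "o_0"))),
    rule_block(sprintf("^o_[01]{1,%d}$", n - 1L),
               list(rule_divide(spike_set(1), "{label}1", "{label}0")),
               regex = TRUE),
    rule_block(sprintf("^o_[01]{%d}$", n), list(
      rule_forget(spike_set(5, 3), 5),         # a^2(a^3)^+/a^5 -> lambda
      rule_forget(spike_set(1), 1),
      rule_dissolve(spike_set(4, 3)),          # [a(a^3)^+] -> delta
      rule_dissolve(spike_set(2))),            # [a^2] -> delta
      regex = TRUE))
  ddsn_system(
    neurons = data.frame(label = labels, spikes = spikes, stringsAsFactors = FALSE),
    syn = syn, rules = blocks, input = c(in_i, "s"),
    out_pattern = sprintf("^o_[01]{%d}$", n))
}

#' Encode a Subset Sum instance as input spike trains
#'
#' After `2n` empty steps (the generation stage), neuron `in_i` receives
#' `3 x_i + 3` spikes and the target neuron `s` receives `2 S` spikes, all at
#' step `2n + 1`.  The even count parked in `s` matches none of its guards
#' until the completion spike from neuron `4` arrives, which starts the
#' checking stage with `2S + 1` spikes.
#'
#' @param inst a [subsetsum_instance()].
#' @return Named list of integer vectors of length `2n + 1`.
#' @export
build_subsetsum_input <- function(inst) {
  stopifnot(inherits(inst, "subsetsum_instance"))
  n <- inst$n
  trains <- lapply(seq_len(n), function(i) c(integer(2L * n), 3L * inst$X[i] + 3L))
  names(trains) <- paste0("in_", seq_len(n))
  trains$s <- c(integer(2L * n), 2L * inst$S)
  trains
}

#' Step horizon of the Subset Sum construction
#'
#' The declared step-complexity formula `2n + x_max + S + 5`.  Under the
#' engine's step semantics the simulated halting step is this value plus one
#' (the last payout spike is processed one step after the final instalment);
#' the offset is a fixed regression constant of the implementation.
#'
#' @param inst a [subsetsum_instance()].
#' @return Integer.
#' @export
subsetsum_horizon <- function(inst) {
  stopifnot(inherits(inst, "subsetsum_instance"))
  2L * inst$n + inst$x_max + inst$S + 5L
}

#' Constant offset between the Subset Sum horizon formula and the simulated
#' halting step
#'
#' @return Integer, `+1`.
#' @seealso [subsetsum_horizon()]
#' @export
subsetsum_halting_offset <- function() 1L

#' Solve a Subset Sum instance with the DDSN P system
#'
#' Builds the family for `n` values, feeds the encoded instance, runs the
#' engine in strict mode, and decodes the surviving output labels into
#' subsets summing to the target.
#'
#' @param inst a [subsetsum_instance()].
#' @param max_steps optional step budget (default: ten times the horizon).
#' @param trace,history passed to [ddsn_run()].
#' @return List with `subsets` (sorted character bitstrings; bit `i` is 1
#'   when `x_i` belongs to the subset; empty when no subset attains the
#'   target), `steps` (halting step) and `run` (the [ddsn_run()] result).
#' @examples
#' sol <- solve_subsetsum(subsetsum_example_instance())
#' sol$subsets   # "0110" "1001"
#' @export
solve_subsetsum <- function(inst, max_steps = NULL, trace = FALSE, history = FALSE) {
  stopifnot(inherits(inst, "subsetsum_instance"))
  system <- build_subsetsum_system(inst$n)
  trains <- build_subsetsum_input(inst)
  if (is.null(max_steps)) max_steps <- 10L * subsetsum_horizon(inst)
  run <- ddsn_run(system, trains, max_steps = max_steps, mode = "strict",
                  trace = trace, history = history)
  list(subsets = sort(sub("^o_", "", run$surviving)),
       steps = run$steps, run = run)
}

#' Brute-force Subset Sum oracle
#'
#' Enumerates all `2^n` subsets and keeps those whose sum equals the target.
#' Independent of the simulator; used to cross-check it.
#'
#' @param inst a [subsetsum_instance()].
#' @return Sorted character vector of subset bitstrings.
#' @export
brute_force_subsetsum <- function(inst) {
  stopifnot(inherits(inst, "subsetsum_instance"))
  n <- inst$n
  if (n > 20L) stop("brute force is limited to n <= 20")
  bits <- as.matrix(expand.grid(rep(list(0:1), n)))
  sums <- as.vector(bits %*% inst$X)
  hit <- sums == inst$S
  if (!any(hit)) return(character(0))
  sort(apply(bits[hit, , drop = FALSE], 1L, paste0, collapse = ""))
}

#' Closed-form replay of the checking stage for one output neuron
#'
#' During the checking stage an output neuron holding `3 * sum_B` spikes
#' (three per selected value) receives two spikes per step for `S` steps and
#' then a single spike.  Its per-step behaviour depends only on
#' `(sum_B, S)`:
#' * `sum_B = S`: each instalment enables the forgetting rule consuming 5
#'   spikes; the final single spike is forgotten and the neuron survives.
#' * `sum_B < S`: after `sum_B` forgettings the neuron holds exactly the two
#'   freshly delivered spikes and dissolves.
#' * `sum_B > S`: after `S` forgettings a surplus of `3 (sum_B - S)` spikes
#'   remains; the final single spike makes the count `1 mod 3` and the
#'   neuron dissolves.
#'
#' @param sum_B nonnegative integer: sum of the subset the neuron encodes.
#' @param S positive integer target.
#' @return List with `counts` (start-of-step spike counts at offsets `0, 1,
#'   ...` from the first payout step), `survives`, `event` (`"forget-final"`,
#'   `"dissolve-short"` or `"dissolve-long"`) and `event_offset` (offset of
#'   the dissolution or final forgetting).
#' @examples
#' checking_stage_trace(5, 5)$survives   # TRUE
#' checking_stage_trace(3, 5)$event      # "dissolve-short"
#' checking_stage_trace(7, 5)$event      # "dissolve-long"
#' @export
checking_stage_trace <- function(sum_B, S) {
  sum_B <- as.integer(sum_B); S <- as.integer(S)
  stopifnot(sum_B >= 0L, S >= 1L)
  counts <- integer(0)
  c_now <- 3L * sum_B
  offset <- 0L
  repeat {
    counts <- c(counts, c_now)
    # rule applied at this offset (the neuron's start-of-step count)
    if (c_now == 2L) {
      return(list(counts = counts, survives = FALSE,
                  event = "dissolve-short", event_offset = offset))
    }
    if (c_now >= 4L && c_now %% 3L == 1L) {
      return(list(counts = counts, survives = FALSE,
                  event = "dissolve-long", event_offset = offset))
    }
    final <- FALSE
    if (c_now >= 5L && c_now %% 3L == 2L) {
      c_now <- c_now - 5L
    } else if (c_now == 1L) {
      c_now <- 0L
      final <- TRUE
    }
    # delivery at the end of this offset: 2 spikes for offsets 0..S-1,
    # the single closing spike at offset S
    if (offset < S) {
      c_now <- c_now + 2L
    } else if (offset == S) {
      c_now <- c_now + 1L
    } else if (final || c_now == 0L) {
      return(list(counts = counts, survives = TRUE,
                  event = "forget-final", event_offset = offset))
    }
    offset <- offset + 1L
  }
}

#' Minimal system exercising the checking stage
#'
#' A two-neuron system -- the target neuron `s` primed with `2S + 1` spikes
#' and a single output neuron `o_1` primed with `3 * sum_B` spikes -- whose
#' run reproduces, step for step, the checking-stage behaviour of an output
#' neuron of the full Subset Sum construction.  Useful for comparing the
#' engine against [checking_stage_trace()].
#'
#' @param sum_B nonnegative integer subset sum of the output neuron.
#' @param S positive integer target.
#' @return A [ddsn_system()].
#' @export
checking_stage_system <- function(sum_B, S) {
  sum_B <- as.integer(sum_B); S <- as.integer(S)
  stopifnot(sum_B >= 0L, S >= 1L)
  blocks <- list(
    rule_block("s", list(
      rule_fire(spike_set(3, 2), 2, 2),
      rule_fire(spike_set(1), 1))),
    rule_block("^o_[01]$", list(
      rule_forget(spike_set(5, 3), 5),
      rule_forget(spike_set(1), 1),
      rule_dissolve(spike_set(4, 3)),
      rule_dissolve(spike_set(2))),
      regex = TRUE))
  ddsn_system(
    neurons = data.frame(label = c("s", "o_1"),
                         spikes = c(2L * S + 1L, 3L * sum_B),
                         stringsAsFactors = FALSE),
    syn = rbind(c("s", "o_1")), rules = blocks,
    out_pattern = "^o_[01]$", horizon = S + 3L)
}
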