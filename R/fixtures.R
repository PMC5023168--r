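#' Built-in demonstration systems and instances
#'
#' Small objects used throughout the documentation and tests, constructed in
#' code:
#'
#' * `division_demo_system()`: three neurons labelled `1`, `2`, `3` with
#'   synapses `(1,2)` and `(2,3)`; neuron `3` holds one spike and two
#'   division rules, `[a]_3 -> [ ]_2 || [ ]_3` and `[a]_3 -> [ ]_3 || [ ]_4`.
#'   The first is blocked by the existing synapse between labels 2 and 3, so
#'   only the second applies: after one step the system has four neurons and
#'   synapses `(1,2)`, `(2,3)`, `(2,4)` -- the children inherit the synapse
#'   from neuron `2` to their parent.
#' * `dissolution_demo_system()`: two neurons labelled `1` (one spike, rule
#'   `[a]_1 -> delta`) and `2`, synapse `(1,2)`.  After one step neuron `1`
#'   and its synapse are gone.
#' * `sat_example_instance()`: the 3-variable, 3-clause CNF
#'   `(x1 | x2) & (-x2 | x3) & (-x1 | x2 | x3)`, whose satisfying
#'   assignments are `111`, `101` and `011`.
#' * `subsetsum_example_instance()`: `X = {1, 2, 3, 4}`, `S = 5`, whose
#'   solutions are the subsets `{x2, x3}` and `{x1, x4}` (bitstrings `0110`
#'   and `1001`).
#'
#' @return A [ddsn_system()], [cnf_instance()] or [subsetsum_instance()].
#' @examples
#' res <- ddsn_run(division_demo_system(), max_steps = 5)
#' config_synapses(res$config)[, c("from_label", "to_label")]
#' @name ddsn_demos
NULL

#' @rdname ddsn_demos
#' @export
division_demo_system <- function() {
  ddsn_system(
    neurons = data.frame(label = c("1", "2", "3"), spikes = c(0L, 0L, 1L),
                         stringsAsFactors = FALSE),
    syn = rbind(c("1", "2"), c("2", "3")),
    rules = list(rule_block("3", list(
      rule_divide(spike_set(1), "2", "3"),
      rule_divide(spike_set(1), "3", "4")))))
}

#' @rdname ddsn_demos
#' @export
dissolution_demo_system <- function() {
  ddsn_system(
    neurons = data.frame(label = c("1", "2"), spikes = c(1L, 0L),
                         stringsAsFactors = FALSE),
    syn = rbind(c("1", "2")),
    rules = list(rule_block("1", list(rule_dissolve(spike_set(1))))))
}

#' @rdname ddsn_demos
#' @export
sat_example_instance <- function() {
  cnf_instance(3, list(c(1L, 2L), c(-2L, 3L), c(-1L, 2L, 3L)))
}

#' @rdname ddsn_demos
#' @export
subsetsum_example_instance <- function() {
  subsetsum_instance(c(1L, 2L, 3L, 4L), 5L)
}
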