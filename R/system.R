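#' Define a DDSN P system
#'
#' A spiking neural P system with neuron division and dissolution is a
#' directed graph of neurons exchanging spikes of a single type.  The static
#' description consists of the initial neurons with their spike counts, the
#' synapse dictionary (ordered label pairs that both wire the initial graph
#' and prescribe which synapses a newly created neuron acquires), the rule
#' resolver binding label patterns to developmental rules, the input labels
#' through which spike trains enter, and a pattern singling out the output
#' neuron family.
#'
#' @param neurons data frame with columns `label` (character) and `spikes`
#'   (nonnegative integer): the initial neurons.  Labels may repeat; runtime
#'   neurons carry unique integer ids.
#' @param syn two-column character matrix (or data frame) of directed label
#'   pairs `(from, to)`.  Self pairs `(l, l)` are rejected.  The runtime graph
#'   starts as `syn` restricted to label pairs both present initially;
#'   thereafter the dictionary is consulted only when division creates new
#'   neurons.
#' @param rules a [rule_resolver()] or list of [rule_block()]s.
#' @param input character vector of input neuron labels.
#' @param out_pattern regular expression matched against labels of live
#'   neurons at halting to read off the result, or `NULL` for no outputs.
#' @param horizon optional declared step horizon of a constructed family;
#'   [ddsn_run()] defaults its step budget to ten times the horizon.
#' @return An object of class `ddsn_system`.
#' @seealso [ddsn_run()], [build_sat_system()], [build_subsetsum_system()]
#' @export
ddsn_system <- function(neurons, syn, rules, input = character(0),
                        out_pattern = NULL, horizon = NULL) {
  neurons <- as.data.frame(neurons, stringsAsFactors = FALSE)
  stopifnot(all(c("label", "spikes") %in% names(neurons)))
  neurons$label <- as.character(neurons$label)
  neurons$spikes <- as.integer(neurons$spikes)
  if (any(neurons$spikes < 0L)) stop("initial spike counts are nonnegative")
  syn <- as.matrix(syn)
  if (length(syn) == 0L) {
    syn <- matrix(character(0), ncol = 2L)
  }
  if (ncol(syn) != 2L) stop("syn must have two columns (from, to)")
  storage.mode(syn) <- "character"
  colnames(syn) <- c("from", "to")
  if (any(syn[, 1L] == syn[, 2L])) {
    stop("the synapse dictionary admits no self pair (i, i)")
  }
  resolver <- rule_resolver(rules)
  stopifnot(is.character(input))
  if (!is.null(out_pattern)) stopifnot(is.character(out_pattern), length(out_pattern) == 1L)
  if (!is.null(horizon)) horizon <- as.integer(horizon)
  structure(list(neurons = neurons, syn = syn, resolver = resolver,
                 input = input, out_pattern = out_pattern, horizon = horizon),
            class = "ddsn_system")
}

#' @export
print.ddsn_system <- function(x, ...) {
  cat(sprintf("<ddsn_system: %d initial neurons, %d dictionary pairs, %d rule blocks>\n",
              nrow(x$neurons), nrow(x$syn), length(x$resolver$blocks)))
  cat("  labels:", paste(utils::head(x$neurons$label, 8L), collapse = ", "),
      if (nrow(x$neurons) > 8L) "..." else "", "\n")
  if (length(x$input)) cat("  input:", paste(utils::head(x$input, 8L), collapse = ", "),
                           if (length(x$input) > 8L) "..." else "", "\n")
  if (!is.null(x$out_pattern)) cat("  out pattern:", x$out_pattern, "\n")
  invisible(x)
}

#' Initial configuration of a system
#'
#' Instantiates the runtime state: one neuron per row of the system's initial
#' neuron table, and one runtime synapse for every dictionary pair whose two
#' labels are both present (between every pair of distinct neurons bearing
#' those labels).
#'
#' @param system a [ddsn_system()].
#' @return An object of class `ddsn_config`: a list with parallel vectors
#'   `id`, `label`, `spikes`, `open_at` (first step at which the neuron is
#'   open again; 0 when open), runtime synapses `syn_from`/`syn_to` (ids),
#'   pending deliveries `pend_due`/`pend_target`/`pend_amount`/`pend_source`,
#'   and the `step` counter.
#' @export
ddsn_config <- function(system) {
  stopifnot(inherits(system, "ddsn_system"))
  n0 <- nrow(system$neurons)
  label <- system$neurons$label
  config <- list(
    id = seq_len(n0), label = label,
    spikes = system$neurons$spikes, open_at = rep(0L, n0),
    syn_from = integer(0), syn_to = integer(0),
    pend_due = integer(0), pend_target = integer(0),
    pend_amount = integer(0), pend_source = integer(0),
    step = 0L, next_id = n0 + 1L)
  if (nrow(system$syn) > 0L) {
    ef <- integer(0); et <- integer(0)
    for (r in seq_len(nrow(system$syn))) {
      from_ids <- which(label == system$syn[r, 1L])
      to_ids <- which(label == system$syn[r, 2L])
      if (length(from_ids) && length(to_ids)) {
        grid <- expand.grid(from = from_ids, to = to_ids)
        grid <- grid[grid$from != grid$to, , drop = FALSE]
        ef <- c(ef, grid$from); et <- c(et, grid$to)
      }
    }
    keep <- !duplicated(cbind(ef, et))
    config$syn_from <- ef[keep]; config$syn_to <- et[keep]
  }
  class(config) <- "ddsn_config"
  config
}

#' @export
print.ddsn_config <- function(x, ...) {
  cat(sprintf("<ddsn_config: step %d, %d neurons, %d synapses, %d pending>\n",
              x$step, length(x$id), length(x$syn_from), length(x$pend_due)))
  show <- utils::head(order(x$label), 12L)
  for (i in show) {
    cat(sprintf("  sigma_%s (id %d): %d spike%s%s\n", x$label[i], x$id[i],
                x$spikes[i], if (x$spikes[i] == 1L) "" else "s",
                if (x$open_at[i] > x$step + 1L)
                  sprintf(" [closed until step %d]", x$open_at[i]) else ""))
  }
  if (length(x$id) > 12L) cat("  ...\n")
  invisible(x)
}

#' Snapshot a configuration as a data frame
#'
#' @param config a `ddsn_config`.
#' @return Data frame with one row per live neuron: `id`, `label`, `spikes`,
#'   `open_at`.
#' @export
config_neurons <- function(config) {
  data.frame(id = config$id, label = config$label, spikes = config$spikes,
             open_at = config$open_at, stringsAsFactors = FALSE)
}

#' Runtime synapses of a configuration as a data frame
#'
#' @param config a `ddsn_config`.
#' @return Data frame with columns `from`, `to` (neuron ids) and
#'   `from_label`, `to_label`.
#' @export
config_synapses <- function(config) {
  data.frame(from = config$syn_from, to = config$syn_to,
             from_label = config$label[match(config$syn_from, config$id)],
             to_label = config$label[match(config$syn_to, config$id)],
             stringsAsFactors = FALSE)
}
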