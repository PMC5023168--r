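#' @title Execution engine
#'
#' @description A computation proceeds in synchronous steps.  Within step `t`
#' each open neuron selects at most one applicable rule from its
#' start-of-step spike count (phase 1); selected rules consume spikes,
#' schedule emissions and perform structural changes (phase 2); and due
#' emissions plus external input are deposited into neurons that are live and
#' open at that point (phase 3).  Spikes deposited during step `t` are first
#' usable at step `t + 1`.  A firing rule with delay `d` applied at step `t`
#' schedules its emission for step `t + d` and closes the neuron through step
#' `t + d - 1`; spikes sent to a closed, dissolved or divided-away neuron are
#' lost.
#'
#' @name ddsn-engine
NULL

ambiguity_error <- function(label, step, k) {
  stop(errorCondition(
    sprintf("neuron labelled '%s' has %d applicable rules at step %d; the system is not deterministic",
            label, k, step),
    class = "ddsnp_ambiguity_error"))
}

# Applicability of a single rule for a neuron holding h spikes.
# For division rules the structural side condition is checked against the
# precomputed endpoint label vectors labf/labt (runtime synapse endpoints).
rule_applicable <- function(rule, h, label, labf, labt) {
  if (!spike_set_contains(rule$guard, h)) return(FALSE)
  switch(rule$kind,
    fire = ,
    forget = h >= rule$consume,
    divide = {
      kids <- c(rule$left, rule$right)
      !any((labf == label & labt %in% kids) | (labf %in% kids & labt == label))
    },
    dissolve = TRUE)
}

#' Structural precondition of a division rule
#'
#' A division `[E]_i -> [ ]_j || [ ]_k` is blocked while any runtime synapse
#' connects a neuron labelled `i` with one labelled `j` or `k`, in either
#' direction (otherwise synapse inheritance could create a self loop).  A
#' blocked division is simply inapplicable; other rules of the neuron remain
#' eligible.
#'
#' @param config a `ddsn_config`.
#' @param id id of the candidate neuron.
#' @param rule a division rule (see [ddsn_rules]).
#' @return `TRUE` when no such synapse exists.
#' @export
division_allowed <- function(config, id, rule) {
  stopifnot(rule$kind == "divide")
  idx <- match(id, config$id)
  if (is.na(idx)) stop("no live neuron with id ", id)
  labf <- config$label[match(config$syn_from, config$id)]
  labt <- config$label[match(config$syn_to, config$id)]
  lab <- config$label[idx]
  kids <- c(rule$left, rule$right)
  !any((labf == lab & labt %in% kids) | (labf %in% kids & labt == lab))
}

#' Select the rule a neuron applies this step
#'
#' Collects the rules of the neuron's label whose guard admits its current
#' spike count (divisions additionally passing [division_allowed()]).  In
#' `strict` mode more than one applicable rule raises an error of class
#' `ddsnp_ambiguity_error`, signalling that a system claimed deterministic is
#' not; in `random` mode one applicable rule is chosen uniformly (seed the
#' session RNG, e.g. via the `seed` argument of [ddsn_run()]).
#'
#' @param system a [ddsn_system()].
#' @param config a `ddsn_config`.
#' @param id id of an open, live neuron.
#' @param mode `"strict"` or `"random"`.
#' @return The selected rule, or `NULL` if none is applicable.
#' @export
select_rule <- function(system, config, id, mode = c("strict", "random")) {
  mode <- match.arg(mode)
  idx <- match(id, config$id)
  if (is.na(idx)) stop("no live neuron with id ", id)
  if (config$open_at[idx] > config$step + 1L) stop("neuron ", id, " is closed")
  labf <- config$label[match(config$syn_from, config$id)]
  labt <- config$label[match(config$syn_to, config$id)]
  select_rule_at(system, config, idx, config$spikes[idx], mode,
                 labf, labt, config$step + 1L)
}

select_rule_at <- function(system, config, idx, h, mode, labf, labt, step) {
  rules <- resolve_rules(system$resolver, config$label[idx])
  if (length(rules) == 0L) return(NULL)
  apps <- Filter(function(r) rule_applicable(r, h, config$label[idx], labf, labt), rules)
  if (length(apps) == 0L) return(NULL)
  if (length(apps) == 1L) return(apps[[1L]])
  if (mode == "strict") ambiguity_error(config$label[idx], step, length(apps))
  apps[[sample.int(length(apps), 1L)]]
}

ev <- function(step, id, label, event, amount, detail = "") {
  list(step = step, id = id, label = label, event = event,
       amount = amount, detail = detail)
}

#' Apply a dissolution to a configuration
#'
#' Removes the neuron, all its spikes, every incident synapse, and every
#' pending delivery addressed to it.
#'
#' @param config a `ddsn_config`.
#' @param id id of the dissolving neuron.
#' @return The updated configuration.
#' @export
apply_dissolution <- function(config, id) {
  idx <- match(id, config$id)
  if (is.na(idx)) stop("no live neuron with id ", id)
  drop_neurons(config, idx)
}

# Remove neuron rows (by index), incident synapses and pending deliveries.
drop_neurons <- function(config, idxs) {
  if (length(idxs) == 0L) return(config)
  ids <- config$id[idxs]
  keep <- setdiff(seq_along(config$id), idxs)
  for (f in c("id", "label", "spikes", "open_at")) config[[f]] <- config[[f]][keep]
  ekeep <- !(config$syn_from %in% ids | config$syn_to %in% ids)
  config$syn_from <- config$syn_from[ekeep]; config$syn_to <- config$syn_to[ekeep]
  pkeep <- !(config$pend_target %in% ids)
  for (f in c("pend_due", "pend_target", "pend_amount", "pend_source")) {
    config[[f]] <- config[[f]][pkeep]
  }
  config
}

#' Apply a division to a configuration
#'
#' The parent is removed (its spikes consumed) and replaced by two empty open
#' children labelled by the rule.  Each child inherits every incoming and
#' outgoing synapse of the parent; in addition, every dictionary pair
#' mentioning a child's label is instantiated against every currently
#' existing neuron bearing the partner label.  Pending deliveries addressed
#' to the parent are discarded.
#'
#' @param config a `ddsn_config`.
#' @param system the [ddsn_system()] (supplies the synapse dictionary).
#' @param id id of the dividing neuron.
#' @param rule the division rule being applied.
#' @return The updated configuration; the two children receive the next two
#'   fresh ids.
#' @export
apply_division <- function(config, system, id, rule) {
  stopifnot(rule$kind == "divide")
  idx <- match(id, config$id)
  if (is.na(idx)) stop("no live neuron with id ", id)
  out_nbr <- config$syn_to[config$syn_from == id]
  in_nbr <- config$syn_from[config$syn_to == id]
  config <- drop_neurons(config, idx)
  config <- add_children(config, system, rule, out_nbr, in_nbr)
  config
}

# Create the two children of one division: inherit the parent's neighbours
# (already filtered to live neurons by the caller) and instantiate the
# dictionary for each child label against all current neurons.
add_children <- function(config, system, rule, out_nbr, in_nbr) {
  kid_ids <- config$next_id + 0:1
  config$next_id <- config$next_id + 2L
  config$id <- c(config$id, kid_ids)
  config$label <- c(config$label, rule$left, rule$right)
  config$spikes <- c(config$spikes, 0L, 0L)
  config$open_at <- c(config$open_at, 0L, 0L)
  out_nbr <- out_nbr[out_nbr %in% config$id]
  in_nbr <- in_nbr[in_nbr %in% config$id]
  ef <- c(config$syn_from, rep(kid_ids, each = length(out_nbr)), in_nbr, in_nbr)
  et <- c(config$syn_to, out_nbr, out_nbr, rep(kid_ids, each = length(in_nbr)))
  # dictionary synapses for the new labels
  for (w in 1:2) {
    kid <- kid_ids[w]; lab <- c(rule$left, rule$right)[w]
    hit <- system$syn[, 1L] == lab | system$syn[, 2L] == lab
    for (r in which(hit)) {
      if (system$syn[r, 1L] == lab) {
        partners <- setdiff(config$id[config$label == system$syn[r, 2L]], kid)
        ef <- c(ef, rep(kid, length(partners))); et <- c(et, partners)
      }
      if (system$syn[r, 2L] == lab) {
        partners <- setdiff(config$id[config$label == system$syn[r, 1L]], kid)
        ef <- c(ef, partners); et <- c(et, rep(kid, length(partners)))
      }
    }
  }
  keep <- !duplicated(cbind(ef, et)) & ef != et
  config$syn_from <- ef[keep]; config$syn_to <- et[keep]
  config
}

#' Advance a configuration by one step
#'
#' Executes the three phases described in [ddsn-engine] for step
#' `config$step + 1`.
#'
#' @param config a `ddsn_config`.
#' @param system the [ddsn_system()].
#' @param trains optional named list of spike trains (label -> integer
#'   vector; position `j` enters at step `j`).
#' @param mode `"strict"` (error on nondeterministic choice) or `"random"`.
#' @param trace whether to collect trace events.
#' @return List with elements `config` (the advanced configuration) and
#'   `events` (list of trace event records, empty unless `trace = TRUE`).
#' @export
ddsn_step <- function(config, system, trains = NULL,
                      mode = c("strict", "random"), trace = FALSE) {
  mode <- match.arg(mode)
  t <- config$step + 1L
  events <- list()
  note <- function(e) if (trace) events[[length(events) + 1L]] <<- e

  ## phase 1: rule selection from start-of-step spike counts
  labf <- config$label[match(config$syn_from, config$id)]
  labt <- config$label[match(config$syn_to, config$id)]
  n <- length(config$id)
  chosen <- vector("list", n)
  for (i in seq_len(n)) {
    if (config$open_at[i] > t) next
    h <- config$spikes[i]
    if (h < resolve_min_spikes(system$resolver, config$label[i])) next
    r <- select_rule_at(system, config, i, h, mode, labf, labt, t)
    if (!is.null(r)) chosen[[i]] <- r
  }

  ## phase 2: consume spikes, schedule emissions, structural changes
  edge_from <- config$syn_from; edge_to <- config$syn_to  # pre-structural snapshot
  dissolved <- integer(0)
  divisions <- list()
  for (i in seq_len(n)) {
    r <- chosen[[i]]
    if (is.null(r)) next
    h <- config$spikes[i]
    if (r$kind == "fire") {
      config$spikes[i] <- h - r$consume
      if (r$delay > 0L) config$open_at[i] <- t + r$delay
      targets <- edge_to[edge_from == config$id[i]]
      if (length(targets)) {
        config$pend_due <- c(config$pend_due, rep(t + r$delay, length(targets)))
        config$pend_target <- c(config$pend_target, targets)
        config$pend_amount <- c(config$pend_amount, rep(r$produce, length(targets)))
        config$pend_source <- c(config$pend_source, rep(config$id[i], length(targets)))
      }
      note(ev(t, config$id[i], config$label[i], "fire", r$consume,
              sprintf("p=%d d=%d targets=%d", r$produce, r$delay, length(targets))))
    } else if (r$kind == "forget") {
      config$spikes[i] <- h - r$consume
      note(ev(t, config$id[i], config$label[i], "forget", r$consume, ""))
    } else if (r$kind == "dissolve") {
      dissolved <- c(dissolved, i)
      note(ev(t, config$id[i], config$label[i], "dissolve", h, ""))
    } else if (r$kind == "divide") {
      divisions[[length(divisions) + 1L]] <- list(idx = i, rule = r)
      note(ev(t, config$id[i], config$label[i], "divide", h,
              sprintf("children=%s,%s", r$left, r$right)))
    }
  }
  if (any(config$spikes < 0L)) stop("internal error: negative spike count")

  if (length(dissolved) || length(divisions)) {
    removed_ids <- config$id[c(dissolved, vapply(divisions, `[[`, 0L, "idx"))]
    # parent neighbourhoods from the pre-structural snapshot, minus neurons
    # removed this step (synapses must reference live neurons)
    inherit <- lapply(divisions, function(d) {
      pid <- config$id[d$idx]
      list(rule = d$rule,
           out = setdiff(edge_to[edge_from == pid], removed_ids),
           inc = setdiff(edge_from[edge_to == pid], removed_ids))
    })
    lost_p <- config$pend_target %in% removed_ids
    if (trace && any(lost_p)) {
      for (j in which(lost_p)) {
        note(ev(t, config$pend_target[j], NA_character_, "lost",
                config$pend_amount[j], "target removed"))
      }
    }
    config <- drop_neurons(config, c(dissolved, vapply(divisions, `[[`, 0L, "idx")))
    for (d in inherit) {
      config <- add_children(config, system, d$rule, d$out, d$inc)
    }
  }

  ## phase 3: deliver due emissions, then external input
  if (length(config$pend_due)) {
    due <- which(config$pend_due == t)
    for (j in due) {
      tidx <- match(config$pend_target[j], config$id)
      if (is.na(tidx) || config$open_at[tidx] > t) {
        note(ev(t, config$pend_target[j], NA_character_, "lost",
                config$pend_amount[j],
                if (is.na(tidx)) "target gone" else "target closed"))
      } else {
        config$spikes[tidx] <- config$spikes[tidx] + config$pend_amount[j]
        note(ev(t, config$id[tidx], config$label[tidx], "deliver",
                config$pend_amount[j],
                sprintf("from=%d", config$pend_source[j])))
      }
    }
    if (length(due)) {
      keep <- setdiff(seq_along(config$pend_due), due)
      for (f in c("pend_due", "pend_target", "pend_amount", "pend_source")) {
        config[[f]] <- config[[f]][keep]
      }
    }
  }
  if (!is.null(trains)) {
    for (lbl in names(trains)) {
      tr <- trains[[lbl]]
      if (t > length(tr) || tr[t] == 0L) next
      idxs <- which(config$label == lbl & config$open_at <= t)
      if (length(idxs) == 0L) {
        note(ev(t, NA_integer_, lbl, "lost", as.integer(tr[t]),
                "input neuron closed or gone"))
      } else {
        for (i in idxs) {
          config$spikes[i] <- config$spikes[i] + as.integer(tr[t])
          note(ev(t, config$id[i], lbl, "input", as.integer(tr[t]), ""))
        }
      }
    }
  }

  config$step <- t
  list(config = config, events = events)
}

#' Has a computation halted?
#'
#' A computation halts at a configuration where every neuron is open, no rule
#' is applicable in any neuron, no delayed emission is pending, and no
#' further external input is scheduled.
#'
#' @param config a `ddsn_config`.
#' @param system the [ddsn_system()].
#' @param trains optional spike trains (a train with a nonzero entry beyond
#'   the current step keeps the system live).
#' @return `TRUE` when halted.
#' @export
is_halted <- function(config, system, trains = NULL) {
  if (any(config$open_at > config$step + 1L)) return(FALSE)
  if (length(config$pend_due)) return(FALSE)
  if (!is.null(trains)) {
    for (tr in trains) {
      if (length(tr) > config$step && any(tr[(config$step + 1L):length(tr)] > 0L)) {
        return(FALSE)
      }
    }
  }
  labf <- config$label[match(config$syn_from, config$id)]
  labt <- config$label[match(config$syn_to, config$id)]
  for (i in seq_along(config$id)) {
    h <- config$spikes[i]
    if (h < resolve_min_spikes(system$resolver, config$label[i])) next
    rules <- resolve_rules(system$resolver, config$label[i])
    for (r in rules) {
      if (rule_applicable(r, h, config$label[i], labf, labt)) return(FALSE)
    }
  }
  TRUE
}

#' Run a computation to halting
#'
#' Iterates [ddsn_step()] from the initial configuration until the system
#' halts (see [is_halted()]) or the step budget is exhausted, then reads off
#' the surviving output labels.
#'
#' @param system a [ddsn_system()].
#' @param trains optional named list of input spike trains.
#' @param max_steps step budget; defaults to ten times the system's declared
#'   horizon, or 10000 when none is declared.  Exceeding it raises an error
#'   of class `ddsnp_max_steps_error` (a non-halting computation or a
#'   construction bug).
#' @param mode `"strict"` (default; deterministic systems, error on
#'   ambiguity) or `"random"` (requires `seed`).
#' @param seed RNG seed for `"random"` mode.
#' @param trace whether to collect a trace (data frame of events).
#' @param history whether to record per-step spike-count snapshots.
#' @return An object of class `ddsn_run`: list with `config` (final
#'   configuration), `steps` (halting step), `surviving` (sorted labels of
#'   live neurons matching the system's out pattern), `trace` (data frame or
#'   `NULL`) and `history` (data frame of start-of-step snapshots or `NULL`;
#'   the snapshot at `step = t` is the state in which step `t + 1` selects
#'   rules).
#' @examples
#' sys <- division_demo_system()
#' res <- ddsn_run(sys, max_steps = 5)
#' config_synapses(res$config)
#' @export
ddsn_run <- function(system, trains = NULL, max_steps = NULL,
                     mode = c("strict", "random"), seed = NULL,
                     trace = FALSE, history = FALSE) {
  mode <- match.arg(mode)
  if (mode == "random" && is.null(seed)) {
    stop("random mode requires an explicit seed for reproducibility")
  }
  if (is.null(max_steps)) {
    max_steps <- if (!is.null(system$horizon)) 10L * system$horizon else 10000L
  }
  if (max_steps < 1L) stop("max_steps must be at least 1")
  run_body <- function() {
    config <- ddsn_config(system)
    events <- list()
    snaps <- if (history) list(history_snapshot(config)) else NULL
    while (!is_halted(config, system, trains)) {
      if (config$step >= max_steps) {
        stop(errorCondition(
          sprintf("system did not halt within %d steps", max_steps),
          class = "ddsnp_max_steps_error"))
      }
      st <- ddsn_step(config, system, trains, mode, trace)
      config <- st$config
      if (trace && length(st$events)) events <- c(events, st$events)
      if (history) snaps[[length(snaps) + 1L]] <- history_snapshot(config)
    }
    list(config = config, events = events, snaps = snaps)
  }
  out <- if (mode == "random") with_seed(seed, run_body()) else run_body()
  config <- out$config
  surviving <- character(0)
  if (!is.null(system$out_pattern)) {
    surviving <- sort(config$label[grepl(system$out_pattern, config$label)])
  }
  structure(list(
    config = config, steps = config$step, surviving = surviving,
    trace = if (trace) events_to_df(out$events) else NULL,
    history = if (history) do.call(rbind, out$snaps) else NULL),
    class = "ddsn_run")
}

history_snapshot <- function(config) {
  data.frame(step = config$step, id = config$id, label = config$label,
             spikes = config$spikes, stringsAsFactors = FALSE)
}

events_to_df <- function(events) {
  if (length(events) == 0L) {
    return(data.frame(step = integer(0), id = integer(0), label = character(0),
                      event = character(0), amount = integer(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  data.frame(
    step = vapply(events, function(e) as.integer(e$step), integer(1)),
    id = vapply(events, function(e) as.integer(e$id), integer(1)),
    label = vapply(events, function(e) as.character(e$label), character(1)),
    event = vapply(events, function(e) e$event, character(1)),
    amount = vapply(events, function(e) as.integer(e$amount), integer(1)),
    detail = vapply(events, function(e) e$detail, character(1)),
    stringsAsFactors = FALSE)
}

#' @export
print.ddsn_run <- function(x, ...) {
  cat(sprintf("<ddsn_run: halted at step %d; %d live neurons>\n",
              x$steps, length(x$config$id)))
  if (length(x$surviving)) {
    cat("  surviving outputs:", paste(x$surviving, collapse = ", "), "\n")
  } else {
    cat("  no surviving output neurons\n")
  }
  invisible(x)
}
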