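#' Developmental rules
#'
#' The four rule kinds of a DDSN P system.  Every rule carries a guard: a
#' [spike_set()] of admissible spike counts.  A rule is applicable in a neuron
#' holding `h` spikes when `h` lies in the guard (and, for firing and
#' forgetting, `h >= consume`; for division, when the structural side
#' condition of [division_allowed()] holds).
#'
#' * `rule_fire(guard, consume, produce, delay)` -- the firing rule
#'   `E/a^c -> a^p; d`: consume `c` spikes, emit `p` spikes along every
#'   outgoing synapse after `d` steps; the neuron is closed while the delay
#'   runs (it neither selects rules nor receives spikes).
#' * `rule_forget(guard, consume)` -- the forgetting rule `E/a^s -> lambda`:
#'   remove `s` spikes, emit nothing.
#' * `rule_divide(guard, left, right)` -- the division rule
#'   `[E]_i -> [ ]_j || [ ]_k`: replace the neuron by two empty children
#'   labelled `left` and `right` which inherit its synapses and gain the
#'   synapses the dictionary prescribes for their labels.  In a pattern rule
#'   block, child labels may contain the token `"{label}"`, replaced by the
#'   matched neuron label at resolution time (so `"{label}1"` appends a bit).
#' * `rule_dissolve(guard)` -- the dissolution rule `[E]_i -> delta`: remove
#'   the neuron together with every incident synapse; spikes in transit to it
#'   are lost.
#'
#' @param guard a [spike_set()] of admissible spike counts.
#' @param consume positive integer: spikes consumed (`c`, or `s` for
#'   forgetting).
#' @param produce positive integer: spikes emitted by a firing rule (`p`,
#'   with `consume >= produce >= 1`).
#' @param delay nonnegative integer firing delay (`d`).
#' @param left,right labels of the two children of a division rule.
#' @return A list of class `ddsn_rule` with a `kind` field
#'   (`"fire"`, `"forget"`, `"divide"` or `"dissolve"`).
#' @examples
#' rule_fire(spike_set(3, 2), consume = 2, produce = 1)  # a(a^2)^+/a^2 -> a
#' rule_forget(spike_set(2), consume = 2)                # a^2 -> lambda
#' rule_divide(spike_set(1), "o_1", "o_0")
#' rule_dissolve(spike_set(4, 3))                        # [a(a^3)^+] -> delta
#' @name ddsn_rules
NULL

new_rule <- function(kind, guard, ...) {
  stopifnot(inherits(guard, "spike_set"))
  structure(list(kind = kind, guard = guard, ...), class = "ddsn_rule")
}

#' @rdname ddsn_rules
#' @export
rule_fire <- function(guard, consume, produce = 1L, delay = 0L) {
  consume <- as.integer(consume); produce <- as.integer(produce); delay <- as.integer(delay)
  if (consume < 1L || produce < 1L || consume < produce) {
    stop("firing rule needs c >= p >= 1")
  }
  if (delay < 0L) stop("firing delay must be nonnegative")
  if (spike_set_min(guard) < consume) {
    stop("every admissible spike count must be at least the consumed amount")
  }
  new_rule("fire", guard, consume = consume, produce = produce, delay = delay)
}

#' @rdname ddsn_rules
#' @export
rule_forget <- function(guard, consume) {
  consume <- as.integer(consume)
  if (consume < 1L) stop("forgetting rule consumes at least one spike")
  if (spike_set_min(guard) < consume) {
    stop("every admissible spike count must be at least the consumed amount")
  }
  new_rule("forget", guard, consume = consume)
}

#' @rdname ddsn_rules
#' @export
rule_divide <- function(guard, left, right) {
  stopifnot(is.character(left), length(left) == 1L,
            is.character(right), length(right) == 1L)
  new_rule("divide", guard, left = left, right = right)
}

#' @rdname ddsn_rules
#' @export
rule_dissolve <- function(guard) {
  new_rule("dissolve", guard)
}

#' @export
print.ddsn_rule <- function(x, ...) {
  g <- paste(apply(unclass(x$guard), 1L, function(r) {
    if (r[["period"]] == 0L) sprintf("%d", r[["offset"]])
    else sprintf("%d+%dk", r[["offset"]], r[["period"]])
  }), collapse = ",")
  desc <- switch(x$kind,
    fire = sprintf("fire E={%s}/a^%d -> a^%d; %d", g, x$consume, x$produce, x$delay),
    forget = sprintf("forget E={%s}/a^%d -> lambda", g, x$consume),
    divide = sprintf("divide [E={%s}] -> [ ]_%s || [ ]_%s", g, x$left, x$right),
    dissolve = sprintf("dissolve [E={%s}] -> delta", g))
  cat("<ddsn_rule: ", desc, ">\n", sep = "")
  invisible(x)
}

#' Rule blocks and the label-pattern resolver
#'
#' Rules are attached to neuron *labels*, not to individual neurons: a child
#' created by division owns whatever rules its new label resolves to.  A
#' resolver is an ordered list of blocks, each binding a label pattern --
#' either a literal label or a regular expression over labels (for
#' parameterised families such as the output neurons `o_<bitstring>`) -- to a
#' rule list.  Resolving a concrete label concatenates the rule lists of all
#' matching blocks, in block order, substituting the matched label into any
#' `"{label}"` template inside division child labels.  Resolution is cached
#' per label, so it is order-stable and cheap.
#'
#' @param pattern literal label, or (with `regex = TRUE`) a regular
#'   expression anchored against the whole label.
#' @param rules list of [ddsn_rules] objects.
#' @param regex whether `pattern` is a regular expression.
#' @param blocks list of `rule_block` objects (a bare list of blocks is also
#'   accepted wherever a resolver is expected).
#' @return `rule_block()` returns a `ddsn_rule_block`; `rule_resolver()` a
#'   `ddsn_rule_resolver`.
#' @examples
#' res <- rule_resolver(list(
#'   rule_block("2", list(rule_fire(spike_set(1), 1), rule_forget(spike_set(2), 2))),
#'   rule_block("^o_[01]$", list(rule_divide(spike_set(1), "{label}1", "{label}0")),
#'              regex = TRUE)
#' ))
#' resolve_rules(res, "o_1")[[1]]$left   # "o_11"
#' @export
rule_block <- function(pattern, rules, regex = FALSE) {
  stopifnot(is.character(pattern), length(pattern) == 1L, is.list(rules))
  if (!all(vapply(rules, inherits, logical(1), "ddsn_rule"))) {
    stop("rules must be ddsn_rule objects")
  }
  structure(list(pattern = pattern, regex = isTRUE(regex), rules = rules),
            class = "ddsn_rule_block")
}

#' @rdname rule_block
#' @export
rule_resolver <- function(blocks) {
  if (inherits(blocks, "ddsn_rule_resolver")) return(blocks)
  if (!all(vapply(blocks, inherits, logical(1), "ddsn_rule_block"))) {
    stop("a resolver is built from rule_block() objects")
  }
  structure(list(blocks = blocks, cache = new.env(parent = emptyenv())),
            class = "ddsn_rule_resolver")
}

block_matches <- function(block, label) {
  if (block$regex) grepl(block$pattern, label) else identical(block$pattern, label)
}

instantiate_rule <- function(rule, label) {
  if (rule$kind == "divide") {
    rule$left <- gsub("{label}", label, rule$left, fixed = TRUE)
    rule$right <- gsub("{label}", label, rule$right, fixed = TRUE)
  }
  rule
}

#' Resolve the rule list owned by a concrete label
#'
#' @param resolver a [rule_resolver()].
#' @param label a concrete neuron label.
#' @return The (possibly empty) ordered list of concrete [ddsn_rules] for
#'   `label`, with division child templates instantiated.
#' @export
resolve_rules <- function(resolver, label) {
  resolver <- rule_resolver(resolver)
  key <- label
  hit <- resolver$cache[[key]]
  if (!is.null(hit)) return(hit$rules)
  rules <- list()
  for (block in resolver$blocks) {
    if (block_matches(block, label)) {
      rules <- c(rules, lapply(block$rules, instantiate_rule, label = label))
    }
  }
  min_needed <- if (length(rules) == 0L) Inf else
    min(vapply(rules, function(r) spike_set_min(r$guard), numeric(1)))
  resolver$cache[[key]] <- list(rules = rules, min = min_needed)
  rules
}

# Cached minimal spike count any rule of this label can accept; Inf when the
# label owns no rules.  Lets the engine skip (typically empty) neurons fast.
resolve_min_spikes <- function(resolver, label) {
  resolve_rules(resolver, label)
  resolver$cache[[label]]$min
}
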