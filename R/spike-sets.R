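#' Semilinear spike-count sets
#'
#' Rule guards in a spiking neural P system are regular languages over the
#' single symbol `a`, so the set of admissible spike counts is always a finite
#' union of arithmetic progressions \{offset + k * period : k >= 0\}.  A
#' `spike_set` stores those progressions as a two-column integer matrix; a
#' period of 0 denotes the singleton \{offset\}.
#'
#' Common guards and their progressions:
#' * `a^c` (exactly c spikes): `spike_set(c)`
#' * `a(a^2)^+` (odd counts >= 3): `spike_set(3, 2)`
#' * `a^3(a^3)^+` (multiples of 3 >= 6): `spike_set(6, 3)`
#' * `a^2(a^3)^+` (5, 8, 11, ...): `spike_set(5, 3)`
#'
#' @param offset nonnegative integer vector of progression offsets.
#' @param period nonnegative integer vector of progression periods, recycled
#'   against `offset`.  Period 0 denotes a singleton.
#' @return An object of class `spike_set`: an integer matrix with columns
#'   `offset` and `period`.  Zero rows denote the empty set.
#' @examples
#' g <- spike_set(3, 2)           # a(a^2)^+ : {3, 5, 7, ...}
#' spike_set_contains(g, 7)       # TRUE
#' spike_set_contains(g, 4)       # FALSE
#' @export
spike_set <- function(offset = integer(0), period = 0L) {
  offset <- as.integer(offset)
  if (length(offset) == 0L) {
    m <- matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("offset", "period")))
    class(m) <- c("spike_set", class(m))
    return(m)
  }
  period <- rep_len(as.integer(period), length(offset))
  if (anyNA(offset) || anyNA(period) || any(offset < 0L) || any(period < 0L)) {
    stop("spike_set progressions need nonnegative offsets and periods")
  }
  m <- cbind(offset = offset, period = period)
  class(m) <- c("spike_set", class(m))
  m
}

#' Test membership of a spike count in a spike set
#'
#' @param set a [spike_set()].
#' @param h nonnegative integer vector of spike counts.
#' @return Logical vector: for each element of `h`, whether it lies in some
#'   progression of `set`.  Pure; decidable in O(rows of `set`).
#' @export
spike_set_contains <- function(set, h) {
  stopifnot(inherits(set, "spike_set"))
  h <- as.integer(h)
  if (any(h < 0L)) stop("spike counts are nonnegative")
  if (nrow(set) == 0L) return(rep(FALSE, length(h)))
  vapply(h, function(x) {
    any(ifelse(set[, "period"] == 0L,
               x == set[, "offset"],
               x >= set[, "offset"] & (x - set[, "offset"]) %% set[, "period"] == 0L))
  }, logical(1))
}

# Smallest member of the set (Inf for the empty set); used to validate that
# every admissible count can actually pay the consumed spikes, and to
# fast-path rule selection for empty neurons.
spike_set_min <- function(set) {
  if (nrow(set) == 0L) return(Inf)
  min(set[, "offset"])
}

#' @export
print.spike_set <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("<spike_set: empty>\n")
    return(invisible(x))
  }
  parts <- apply(x, 1L, function(r) {
    if (r[["period"]] == 0L) sprintf("{%d}", r[["offset"]])
    else sprintf("{%d + %dk}", r[["offset"]], r[["period"]])
  })
  cat("<spike_set: ", paste(parts, collapse = " U "), ">\n", sep = "")
  invisible(x)
}
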