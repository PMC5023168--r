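#' Read a DIMACS CNF file
#'
#' Standard DIMACS: optional `c` comment lines, a `p cnf <n> <m>` header, and
#' whitespace-separated signed literals with each clause terminated by `0`
#' (clauses may span lines).
#'
#' @param x path to a file, or the text itself (a character vector of lines,
#'   or one string containing newlines).
#' @return A [cnf_instance()].
#' @section Errors: a missing or malformed header raises
#'   `ddsnp_parse_error` (with the line number); a mismatch between the
#'   header counts and the parsed clauses raises `ddsnp_count_mismatch`.
#' @export
parse_dimacs <- function(x) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  parse_err <- function(msg, lineno) {
    stop(errorCondition(sprintf("%s (line %d)", msg, lineno),
                        class = "ddsnp_parse_error"))
  }
  header <- NULL
  body <- character(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "c") || startsWith(ln, "%")) next
    if (is.null(header)) {
      toks <- strsplit(ln, "[[:space:]]+")[[1L]]
      if (length(toks) != 4L || toks[1L] != "p" || toks[2L] != "cnf") {
        parse_err("expected DIMACS header 'p cnf <vars> <clauses>'", i)
      }
      n <- suppressWarnings(as.integer(toks[3L]))
      m <- suppressWarnings(as.integer(toks[4L]))
      if (is.na(n) || is.na(m) || n < 1L || m < 1L) {
        parse_err("DIMACS header counts must be positive integers", i)
      }
      header <- c(n = n, m = m)
    } else {
      body <- c(body, ln)
    }
  }
  if (is.null(header)) {
    stop(errorCondition("no DIMACS header found",
                        class = "ddsnp_parse_error"))
  }
  toks <- unlist(strsplit(paste(body, collapse = " "), "[[:space:]]+"))
  toks <- toks[toks != ""]
  lits <- suppressWarnings(as.integer(toks))
  if (anyNA(lits)) {
    stop(errorCondition("non-integer literal in DIMACS clause section",
                        class = "ddsnp_parse_error"))
  }
  clauses <- list()
  cur <- integer(0)
  for (l in lits) {
    if (l == 0L) {
      clauses[[length(clauses) + 1L]] <- cur
      cur <- integer(0)
    } else {
      cur <- c(cur, l)
    }
  }
  if (length(cur)) clauses[[length(clauses) + 1L]] <- cur  # unterminated last clause
  if (length(clauses) != header[["m"]]) {
    stop(errorCondition(
      sprintf("header declares %d clauses but %d were parsed",
              header[["m"]], length(clauses)),
      class = "ddsnp_count_mismatch"))
  }
  if (length(clauses) && max(c(0L, abs(unlist(clauses)))) > header[["n"]]) {
    stop(errorCondition(
      sprintf("literal exceeds the %d variables declared in the header",
              header[["n"]]),
      class = "ddsnp_count_mismatch"))
  }
  cnf_instance(header[["n"]], clauses)
}

#' Write a CNF instance in DIMACS format
#'
#' @param cnf a [cnf_instance()].
#' @param file path, or `NULL` to return the lines.
#' @return The DIMACS lines, invisibly when written to a file.
#' @export
write_dimacs <- function(cnf, file = NULL) {
  stopifnot(inherits(cnf, "cnf_instance"))
  lines <- c(sprintf("p cnf %d %d", cnf$n, length(cnf$clauses)),
             vapply(cnf$clauses, function(cl) paste(c(cl, 0L), collapse = " "), ""))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

guard_to_list <- function(guard) {
  unname(apply(unclass(guard), 1L, function(r) as.integer(r), simplify = FALSE))
}

rule_to_list <- function(rule) {
  out <- list(kind = rule$kind, guard = guard_to_list(rule$guard))
  if (rule$kind == "fire") {
    out$consume <- rule$consume; out$produce <- rule$produce; out$delay <- rule$delay
  } else if (rule$kind == "forget") {
    out$consume <- rule$consume
  } else if (rule$kind == "divide") {
    out$children <- c(rule$left, rule$right)
  }
  out
}

rule_from_list <- function(x) {
  guard <- if (length(x$guard) == 0L) spike_set() else {
    m <- do.call(rbind, lapply(x$guard, function(p) as.integer(unlist(p))))
    spike_set(m[, 1L], m[, 2L])
  }
  switch(x$kind,
    fire = rule_fire(guard, x$consume, x$produce, x$delay),
    forget = rule_forget(guard, x$consume),
    divide = rule_divide(guard, as.character(x$children[[1L]]),
                         as.character(x$children[[2L]])),
    dissolve = rule_dissolve(guard),
    stop("unknown rule kind: ", x$kind))
}

#' Serialize a system specification to canonical JSON
#'
#' The representation is canonical (fixed field order, integers only, no
#' optional field emitted when absent), so serializing, reading back and
#' serializing again is byte-identical.
#'
#' @param system a [ddsn_system()].
#' @param file path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @seealso [system_from_json()]
#' @export
system_to_json <- function(system, file = NULL) {
  stopifnot(inherits(system, "ddsn_system"))
  spec <- list(
    labels = as.list(system$neurons$label),
    syn = unname(apply(system$syn, 1L, function(r) as.list(unname(r)),
                       simplify = FALSE)),
    initial = unname(lapply(seq_len(nrow(system$neurons)), function(i) {
      list(label = system$neurons$label[i], spikes = system$neurons$spikes[i])
    })),
    rules = lapply(system$resolver$blocks, function(b) {
      list(pattern = b$pattern, regex = b$regex,
           rules = lapply(b$rules, rule_to_list))
    }),
    "in" = as.list(system$input))
  if (!is.null(system$out_pattern)) spec$out_pattern <- system$out_pattern
  if (!is.null(system$horizon)) spec$horizon <- system$horizon
  txt <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (is.null(file)) return(txt)
  cat(txt, file = file)
  invisible(txt)
}

#' Read a system specification from JSON
#'
#' @param x path to a file or a JSON string.
#' @return A [ddsn_system()].
#' @seealso [system_to_json()]
#' @export
system_from_json <- function(x) {
  spec <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  for (f in c("labels", "syn", "initial", "rules", "in")) {
    if (is.null(spec[[f]])) {
      stop(errorCondition(sprintf("system spec is missing field '%s'", f),
                          class = "ddsnp_schema_error"))
    }
  }
  syn <- if (length(spec$syn) == 0L) matrix(character(0), ncol = 2L) else {
    do.call(rbind, lapply(spec$syn, function(p) as.character(unlist(p))))
  }
  if (nrow(syn) && any(syn[, 1L] == syn[, 2L])) {
    stop(errorCondition("system spec contains a self-loop synapse pair",
                        class = "ddsnp_schema_error"))
  }
  neurons <- data.frame(
    label = vapply(spec$initial, function(e) as.character(e$label), ""),
    spikes = vapply(spec$initial, function(e) as.integer(e$spikes), 0L),
    stringsAsFactors = FALSE)
  blocks <- lapply(spec$rules, function(b) {
    rule_block(as.character(b$pattern), lapply(b$rules, rule_from_list),
               regex = isTRUE(b$regex))
  })
  ddsn_system(neurons = neurons, syn = syn, rules = blocks,
              input = as.character(unlist(spec[["in"]])),
              out_pattern = spec$out_pattern,
              horizon = spec$horizon)
}

#' Serialize input spike trains to JSON
#'
#' @param trains named list of integer vectors (label -> spikes per step).
#' @param file path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
trains_to_json <- function(trains, file = NULL) {
  stopifnot(is.list(trains), !is.null(names(trains)))
  txt <- jsonlite::toJSON(lapply(trains, as.integer), digits = NA, pretty = TRUE)
  txt <- paste0(as.character(txt), "\n")
  if (is.null(file)) return(txt)
  cat(txt, file = file)
  invisible(txt)
}

#' Read input spike trains from JSON
#'
#' @param x path to a file or a JSON string.
#' @return Named list of integer vectors.
#' @export
trains_from_json <- function(x) {
  raw <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  out <- lapply(raw, function(v) as.integer(unlist(v)))
  if (any(vapply(out, function(v) any(is.na(v)) || any(v < 0L), TRUE))) {
    stop(errorCondition("spike trains must be nonnegative integers",
                        class = "ddsnp_schema_error"))
  }
  out
}

#' Write or read a trace as JSON lines
#'
#' One JSON object per line, one line per trace event.
#'
#' @param trace trace data frame from [ddsn_run()].
#' @param file path.
#' @return `read_trace` returns the trace data frame.
#' @export
write_trace <- function(trace, file) {
  stopifnot(is.data.frame(trace))
  con <- file(file, open = "w")
  on.exit(close(con))
  jsonlite::stream_out(trace, con, verbose = FALSE)
  invisible(file)
}

#' @rdname write_trace
#' @export
read_trace <- function(file) {
  con <- file(file, open = "r")
  on.exit(close(con))
  jsonlite::stream_in(con, verbose = FALSE)
}

#' Export a configuration as a DOT graph
#'
#' Neurons become nodes labelled `label : spikes`; runtime synapses become
#' directed edges.  Node identifiers are `label@id`, so duplicate labels
#' remain distinguishable.
#'
#' @param x a `ddsn_config`, [ddsn_system()] (its initial configuration) or
#'   `ddsn_run` result (its final configuration).
#' @param file path, or `NULL` to return the DOT lines.
#' @return Character vector of DOT lines, invisibly when written to a file.
#' @export
system_to_dot <- function(x, file = NULL) {
  config <- if (inherits(x, "ddsn_system")) ddsn_config(x)
    else if (inherits(x, "ddsn_run")) x$config
    else if (inherits(x, "ddsn_config")) x
    else stop("cannot render object of class ", paste(class(x), collapse = "/"))
  node_id <- function(i) sprintf("\"%s@%d\"", config$label[i], config$id[i])
  nodes <- vapply(seq_along(config$id), function(i) {
    sprintf("  %s [label=\"%s : %d\"];", node_id(i), config$label[i], config$spikes[i])
  }, "")
  fi <- match(config$syn_from, config$id)
  ti <- match(config$syn_to, config$id)
  edges <- vapply(seq_along(fi), function(e) {
    sprintf("  %s -> %s;", node_id(fi[e]), node_id(ti[e]))
  }, "")
  lines <- c("digraph ddsn {", nodes, edges, "}")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}
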