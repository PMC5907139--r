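#' Parse a Boolean network from the plain-text rule dialect
#'
#' The dialect has one statement per line:
#' \itemize{
#'   \item \code{Name* = expr} — update rule for \code{Name}; \code{expr}
#'     combines node names with \code{and}, \code{or}, \code{not}
#'     (case-insensitive) and parentheses, with the usual precedence
#'     \code{not} > \code{and} > \code{or}.
#'   \item \code{Name = True|False} — initial value for \code{Name}
#'     (for input nodes this is the default clamp).
#'   \item \code{#input: A B ...} — declares externally clamped input nodes.
#'   \item \code{#readout: A B ...} — flags output nodes.
#'   \item \code{# ...} — comment (also allowed after a statement).
#' }
#'
#' Every name referenced in a rule must be declared (have a rule or be an
#' input); inputs must not have a rule; each non-input node has exactly one
#' rule.
#'
#' @param text Character vector: lines of rule text, or a single string
#'   containing newlines.
#' @return An object of class \code{boolean_network} with components
#'   \code{nodes} (declaration order), \code{rules} (named list of parsed
#'   expressions), \code{rule_text}, \code{inputs}, \code{readouts} and
#'   \code{init} (named integer vector of declared initial values).
#' @seealso [read_boolean_network()] to read a model file,
#'   [simulate_network()], [find_attractor()]
#' @examples
#' net <- parse_rules(c(
#'   "#input: HER2",
#'   "ERK* = HER2 and not DUSP5",
#'   "DUSP5* = ERK"))
#' net$nodes
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  inputs <- character()
  readouts <- character()
  rule_text <- character()   # named by node
  rule_line <- integer()
  init <- integer()          # named by node
  order_seen <- character()

  note <- function(nm) {
    if (!nm %in% order_seen) order_seen <<- c(order_seen, nm)
  }

  for (i in seq_along(lines)) {
    raw <- lines[i]
    line <- trimws(raw)
    if (line == "") next
    if (startsWith(line, "#")) {
      m <- regmatches(line,
        regexec("^#\\s*(input|readout)s?\\s*:\\s*(.+)$", line,
                ignore.case = TRUE))[[1]]
      if (length(m) == 3L) {
        nms <- strsplit(trimws(m[3]), "[,[:space:]]+")[[1]]
        ok <- grepl("^[A-Za-z][A-Za-z0-9_]*$", nms)
        if (!all(ok))
          stop(sprintf("invalid node name '%s' in directive (line %d)",
                       nms[!ok][1], i), call. = FALSE)
        if (tolower(m[2]) == "input") {
          inputs <- union(inputs, nms)
          for (nm in nms) note(nm)
        } else {
          readouts <- union(readouts, nms)
        }
      }
      next
    }
    line <- trimws(sub("#.*$", "", line))  # trailing comment
    if (line == "") next

    if (grepl("^[A-Za-z][A-Za-z0-9_]*\\s*\\*\\s*=", line)) {
      nm <- trimws(sub("\\*.*$", "", line))
      expr <- trimws(sub("^[^=]*=", "", line))
      if (expr == "")
        stop(sprintf("empty rule expression for node '%s' (line %d)", nm, i),
             call. = FALSE)
      if (nm %in% names(rule_text))
        stop(sprintf("duplicate rule for node '%s' (line %d)", nm, i),
             call. = FALSE)
      rule_text[nm] <- expr
      rule_line[nm] <- i
      note(nm)
    } else if (grepl("^[A-Za-z][A-Za-z0-9_]*\\s*=\\s*(true|false|1|0)$",
                     line, ignore.case = TRUE)) {
      nm <- trimws(sub("=.*$", "", line))
      val <- tolower(trimws(sub("^[^=]*=", "", line)))
      init[nm] <- as.integer(val %in% c("true", "1"))
      note(nm)
    } else {
      stop(sprintf("cannot parse line %d: '%s'", i, raw), call. = FALSE)
    }
  }

  nodes <- order_seen
  dup_input_rule <- intersect(inputs, names(rule_text))
  if (length(dup_input_rule))
    stop(sprintf("input node '%s' must not have an update rule",
                 dup_input_rule[1]), call. = FALSE)
  free_nodes <- setdiff(nodes, inputs)
  missing_rule <- setdiff(free_nodes, names(rule_text))
  if (length(missing_rule))
    stop(sprintf("node '%s' has an initial value but no rule and is not an input",
                 missing_rule[1]), call. = FALSE)
  bad_readout <- setdiff(readouts, nodes)
  if (length(bad_readout))
    stop(sprintf("readout '%s' is not a declared node", bad_readout[1]),
         call. = FALSE)

  rules <- vector("list", length(rule_text))
  names(rules) <- names(rule_text)
  for (nm in names(rule_text)) {
    rules[[nm]] <- translate_rule_expr(rule_text[[nm]], nm, rule_line[[nm]],
                                       nodes)
  }

  structure(
    list(nodes = nodes, rules = rules, rule_text = rule_text,
         inputs = inputs, readouts = readouts, init = init),
    class = "boolean_network")
}

# Translate the dialect's and/or/not into R's logical operators and parse.
# Validates that only Boolean connectives and declared node names appear.
translate_rule_expr <- function(expr_text, node, line, nodes) {
  s <- gsub("\\band\\b", "&", expr_text, ignore.case = TRUE)
  s <- gsub("\\bor\\b", "|", s, ignore.case = TRUE)
  s <- gsub("\\bnot\\b", "!", s, ignore.case = TRUE)
  e <- tryCatch(parse(text = s, keep.source = FALSE)[[1]],
                error = function(err)
                  stop(sprintf("cannot parse rule for '%s' (line %d): %s",
                               node, line, expr_text), call. = FALSE))
  ops <- setdiff(all.names(e, unique = TRUE), all.vars(e))
  bad_ops <- setdiff(ops, c("&", "|", "!", "("))
  if (length(bad_ops))
    stop(sprintf("rule for '%s' (line %d) uses unsupported operator '%s'",
                 node, line, bad_ops[1]), call. = FALSE)
  undeclared <- setdiff(all.vars(e), nodes)
  if (length(undeclared))
    stop(sprintf("rule for '%s' (line %d) references undeclared node '%s'",
                 node, line, undeclared[1]), call. = FALSE)
  if (length(all.vars(e)) == 0L)
    stop(sprintf("rule for '%s' (line %d) references no node", node, line),
         call. = FALSE)
  e
}

#' Read a Boolean network model file
#'
#' @param path Path to a UTF-8 model file in the rule dialect of
#'   [parse_rules()].
#' @return A \code{boolean_network}.
#' @export
read_boolean_network <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path),
                               call. = FALSE)
  parse_rules(readLines(path, warn = FALSE, encoding = "UTF-8"))
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes (%d inputs)\n",
              length(x$nodes), length(x$inputs)))
  if (length(x$inputs))
    cat("  inputs:  ", paste(x$inputs, collapse = ", "), "\n")
  if (length(x$readouts))
    cat("  readouts:", paste(x$readouts, collapse = ", "), "\n")
  for (nm in setdiff(x$nodes, x$inputs))
    cat(sprintf("  %s* = %s\n", nm, x$rule_text[[nm]]))
  if (length(x$init)) {
    iv <- paste(sprintf("%s=%d", names(x$init), x$init), collapse = ", ")
    cat("  init:    ", iv, "\n")
  }
  invisible(x)
}

#' Default initial state of a network
#'
#' Starts from all-OFF, applies the initial values declared in the model
#' file, then any overrides.
#'
#' @param net A \code{boolean_network}.
#' @param overrides Named vector of 0/1 values taking precedence over the
#'   declared initial values.
#' @return Named integer vector over all nodes.
#' @export
initial_state <- function(net, overrides = NULL) {
  st <- stats::setNames(integer(length(net$nodes)), net$nodes)
  decl <- intersect(names(net$init), net$nodes)
  st[decl] <- net$init[decl]
  if (length(overrides)) {
    bad <- setdiff(names(overrides), net$nodes)
    if (length(bad))
      stop(sprintf("unknown node in state override: '%s'", bad[1]),
           call. = FALSE)
    st[names(overrides)] <- as.integer(overrides)
  }
  check_state(net, st)
  st
}

check_state <- function(net, state) {
  if (is.null(names(state)) || !setequal(names(state), net$nodes))
    stop("state must be a named 0/1 vector covering every node",
         call. = FALSE)
  if (!all(state %in% c(0L, 1L)))
    stop("state values must be 0 or 1", call. = FALSE)
  invisible(TRUE)
}

check_clamps <- function(net, clamps) {
  if (length(net$inputs) == 0L) return(stats::setNames(integer(0), character(0)))
  if (is.null(clamps)) clamps <- integer(0)
  missing <- setdiff(net$inputs, names(clamps))
  # fall back to declared initial values for unclamped inputs
  defaulted <- intersect(missing, names(net$init))
  if (length(defaulted))
    clamps[defaulted] <- net$init[defaulted]
  missing <- setdiff(net$inputs, names(clamps))
  if (length(missing))
    stop(sprintf("missing clamp for input node '%s'", missing[1]),
         call. = FALSE)
  extra <- setdiff(names(clamps), net$inputs)
  if (length(extra))
    stop(sprintf("clamp given for non-input node '%s'", extra[1]),
         call. = FALSE)
  out <- as.integer(clamps[net$inputs])
  if (!all(out %in% c(0L, 1L)))
    stop("clamp values must be 0 or 1", call. = FALSE)
  stats::setNames(out, net$inputs)
}
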