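dusp_kinases <- c("ERK", "JNK", "p38")

# Literature regulation facts for the modelled DUSPs. Inducers are NA where
# the inducing MAP kinase is unknown; predicted_inducers then carries the
# model-based prediction shipped with the package.
.dusp_facts <- data.frame(
  dusp       = c("DUSP1", "DUSP2", "DUSP3", "DUSP4",
                 "DUSP5", "DUSP9", "DUSP16", "DUSP23"),
  inducers   = c("ERK,p38", "ERK,JNK", NA, "ERK",
                 "ERK", NA, NA, NA),
  substrates = c("JNK", "ERK,p38", "ERK,JNK,p38", "ERK,JNK",
                 "ERK", "ERK", "JNK,p38", "ERK,JNK,p38"),
  predicted_inducers = c(NA, NA, "JNK", NA, NA, "JNK", "ERK", "JNK"),
  provenance = c("known", "known", "predicted", "known",
                 "known", "predicted", "predicted", "predicted"),
  stringsAsFactors = FALSE)

split_csv <- function(x) if (is.na(x)) character(0) else strsplit(x, ",")[[1]]

#' Literature regulation facts for a modelled DUSP
#'
#' Which MAP kinases induce the DUSP's expression and which are its
#' dephosphorylation substrates. Inducers are \code{"UNKNOWN"} for the four
#' DUSPs whose inducing kinase is not established (DUSP3, DUSP9, DUSP16,
#' DUSP23) — these are the targets of [infer_regulators()].
#'
#' @param dusp_id Gene symbol, e.g. \code{"DUSP2"} (a bare number is also
#'   accepted). Modelled set: DUSP 1, 2, 3, 4, 5, 9, 16, 23.
#' @return List with \code{dusp}, \code{inducers} (character vector of
#'   kinases or \code{"UNKNOWN"}), \code{substrates}, \code{provenance}
#'   (\code{"known"} or \code{"predicted"}) and, where applicable,
#'   \code{predicted_inducers}.
#' @examples
#' get_regulation_facts("DUSP2")$inducers
#' @export
get_regulation_facts <- function(dusp_id) {
  id <- normalize_dusp_id(dusp_id)
  row <- .dusp_facts[.dusp_facts$dusp == id, ]
  if (nrow(row) == 0L)
    stop(sprintf("'%s' is not in the modelled DUSP set (%s)",
                 id, paste(.dusp_facts$dusp, collapse = ", ")),
         call. = FALSE)
  ind <- split_csv(row$inducers)
  list(dusp = id,
       inducers = if (length(ind)) ind else "UNKNOWN",
       substrates = split_csv(row$substrates),
       predicted_inducers = split_csv(row$predicted_inducers),
       provenance = row$provenance)
}

normalize_dusp_id <- function(dusp_id) {
  id <- toupper(as.character(dusp_id))
  if (grepl("^[0-9]+$", id)) id <- paste0("DUSP", id)
  sub("^DUSP0*", "DUSP", id)
}

#' Regulation facts table for all modelled DUSPs
#'
#' @return A data frame with one row per modelled DUSP: inducers,
#'   substrates, shipped predicted inducers and provenance.
#' @export
regulation_facts_table <- function() .dusp_facts

#' Build the Boolean model for a DUSP
#'
#' Constructs the per-cluster signalling scaffold around one DUSP:
#' \itemize{
#'   \item \code{HER2* = not Herceptin} (receptor blockade),
#'   \item each substrate kinase \code{K* = (HER2 or Basal) and not DUSP}
#'     — a Herceptin-insensitive basal drive keeps the negative-feedback
#'     loop engaged; non-substrate kinases follow HER2 alone,
#'   \item \code{DUSP* = } OR over its inducing kinases,
#'   \item \code{Survival* = ERK or not (JNK and p38)} — proliferative ERK
#'     signalling sustains survival; simultaneous JNK and p38 activity
#'     triggers apoptosis,
#'   \item inputs \code{Herceptin} and \code{Basal}, both clamped ON by
#'     default.
#' }
#' The default initial condition is the pre-treatment steady state: ERK ON,
#' JNK/p38 OFF (held down by the DUSP before treatment), DUSP ON, Survival
#' ON, and HER2 at the value its rule takes under the Herceptin clamp
#' (receptor inhibition is fast on the Boolean timescale).
#'
#' @param dusp_id Modelled DUSP (see [get_regulation_facts()]).
#' @param inducers For DUSPs with \emph{unknown} induction, a non-empty
#'   subset of \code{c("ERK","JNK","p38")} to hypothesize; must be omitted
#'   for DUSPs whose induction is known.
#' @return A \code{dusp_model}: list with \code{dusp_id}, \code{network}
#'   (a \code{boolean_network}), \code{inducers}, \code{substrates},
#'   \code{provenance} (\code{"known"} or \code{"hypothesis"}).
#' @examples
#' m <- build_model("DUSP5")
#' classify_node_pattern(model_attractor(m), "DUSP5")  # OSCILLATING
#' @export
build_model <- function(dusp_id, inducers = NULL) {
  facts <- get_regulation_facts(dusp_id)
  id <- facts$dusp
  known <- !identical(facts$inducers, "UNKNOWN")
  if (known && !is.null(inducers))
    stop(sprintf("induction of %s is known; do not supply a hypothesis", id),
         call. = FALSE)
  if (!known) {
    if (is.null(inducers) || length(inducers) == 0L)
      stop(sprintf("induction of %s is unknown; supply a non-empty inducer hypothesis",
                   id), call. = FALSE)
    bad <- setdiff(inducers, dusp_kinases)
    if (length(bad))
      stop(sprintf("unknown kinase '%s' in inducer hypothesis", bad[1]),
           call. = FALSE)
  }
  ind <- if (known) facts$inducers else unique(inducers)
  net <- parse_rules(dusp_rule_lines(id, ind, facts$substrates))
  structure(list(dusp_id = id, network = net, inducers = ind,
                 substrates = facts$substrates,
                 provenance = if (known) "known" else "hypothesis"),
            class = "dusp_model")
}

dusp_rule_lines <- function(id, inducers, substrates) {
  kin_rule <- function(k) {
    if (k %in% substrates)
      sprintf("%s* = (HER2 or Basal) and not %s", k, id)
    else
      sprintf("%s* = HER2", k)
  }
  c(sprintf("# %s regulation model", id),
    "#input: Herceptin Basal",
    "#readout: Survival",
    "HER2* = not Herceptin",
    vapply(dusp_kinases, kin_rule, character(1)),
    sprintf("%s* = %s", id, paste(inducers, collapse = " or ")),
    "Survival* = ERK or not (JNK and p38)",
    "Herceptin = True",
    "Basal = True",
    "HER2 = False",
    "ERK = True",
    "JNK = False",
    "p38 = False",
    sprintf("%s = True", id),
    "Survival = True")
}

#' @export
print.dusp_model <- function(x, ...) {
  cat(sprintf("%s model (%s induction: %s; substrates: %s)\n",
              x$dusp_id, x$provenance,
              paste(x$inducers, collapse = " or "),
              paste(x$substrates, collapse = ", ")))
  print(x$network)
  invisible(x)
}

#' Initial state of a DUSP model under a Herceptin setting
#'
#' @param model A \code{dusp_model}.
#' @param herceptin 0/1 clamp for Herceptin; HER2 starts at
#'   \code{1 - herceptin}.
#' @return Named 0/1 state vector.
#' @export
model_initial_state <- function(model, herceptin = 1L) {
  initial_state(model$network,
                overrides = c(Herceptin = as.integer(herceptin),
                              HER2 = as.integer(1L - herceptin)))
}

model_clamps <- function(herceptin) {
  c(Herceptin = as.integer(herceptin), Basal = 1L)
}

#' Synchronous attractor of a DUSP model
#'
#' @inheritParams model_initial_state
#' @return A \code{bn_attractor}.
#' @export
model_attractor <- function(model, herceptin = 1L) {
  find_attractor(model$network,
                 init = model_initial_state(model, herceptin),
                 clamps = model_clamps(herceptin))
}

#' Simulate a DUSP model
#'
#' @inheritParams model_initial_state
#' @param n_steps,mode,seed See [simulate_network()].
#' @return A \code{bn_trajectory}.
#' @export
simulate_model <- function(model, herceptin = 1L, n_steps = NULL,
                           mode = "synchronous", seed = NULL) {
  simulate_network(model$network,
                   init = model_initial_state(model, herceptin),
                   clamps = model_clamps(herceptin),
                   n_steps = n_steps, mode = mode, seed = seed)
}

#' Expected qualitative outcomes of the shipped models
#'
#' The pattern classes each shipped model must reproduce under continuous
#' Herceptin exposure: oscillation of DUSP2/4/5, decay of DUSP1 after an
#' initially stable phase, survival ON in every model except DUSP16, where
#' survival switches OFF after a finite transient.
#'
#' @param dusp_id Modelled DUSP.
#' @return Named character vector, node -> expected pattern class.
#' @export
expected_outcomes <- function(dusp_id) {
  id <- normalize_dusp_id(dusp_id)
  out <- switch(id,
    DUSP1  = c(DUSP1 = "ON_THEN_OFF", Survival = "CONSTANT_ON"),
    DUSP2  = c(DUSP2 = "OSCILLATING", Survival = "CONSTANT_ON"),
    DUSP4  = c(DUSP4 = "OSCILLATING", Survival = "CONSTANT_ON"),
    DUSP5  = c(DUSP5 = "OSCILLATING", Survival = "CONSTANT_ON"),
    DUSP16 = c(DUSP16 = "ON_THEN_OFF", Survival = "ON_THEN_OFF"),
    DUSP3  = c(Survival = "CONSTANT_ON"),
    DUSP9  = c(Survival = "CONSTANT_ON"),
    DUSP23 = c(Survival = "CONSTANT_ON"),
    stop(sprintf("no expected outcomes for '%s'", id), call. = FALSE))
  out
}

#' Path to a shipped model rule file
#'
#' The package ships one rule file per modelled DUSP under
#' \code{inst/models/dusp<id>.bn}; files for DUSP3/9/16/23 use the
#' predicted inducer (provenance \code{"predicted"}).
#'
#' @param dusp_id Modelled DUSP.
#' @return File path.
#' @export
dusp_model_file <- function(dusp_id) {
  id <- normalize_dusp_id(dusp_id)
  path <- system.file("models", paste0(tolower(id), ".bn"),
                      package = "duspboolnet")
  if (path == "") stop(sprintf("no shipped model file for '%s'", id),
                       call. = FALSE)
  path
}

#' Check a model against its expected qualitative outcomes
#'
#' @param model A \code{dusp_model} (or a DUSP id, in which case the model
#'   is built with its known or shipped-predicted inducers).
#' @param herceptin Herceptin clamp (default ON).
#' @return Data frame with node, expected, observed and ok columns.
#' @export
check_expected_outcomes <- function(model, herceptin = 1L) {
  if (!inherits(model, "dusp_model")) model <- default_model(model)
  exp <- expected_outcomes(model$dusp_id)
  att <- model_attractor(model, herceptin)
  obs <- vapply(names(exp), function(n) classify_node_pattern(att, n),
                character(1))
  data.frame(dusp = model$dusp_id, node = names(exp),
             expected = unname(exp), observed = unname(obs),
             ok = unname(exp == obs), row.names = NULL,
             stringsAsFactors = FALSE)
}

# Build the model with known inducers, or the shipped predicted inducers
# for the inference-target DUSPs.
default_model <- function(dusp_id) {
  facts <- get_regulation_facts(dusp_id)
  if (identical(facts$inducers, "UNKNOWN"))
    build_model(facts$dusp, facts$predicted_inducers)
  else build_model(facts$dusp)
}
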