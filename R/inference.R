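#' Enumerate candidate inducer hypotheses for a DUSP
#'
#' All 7 non-empty subsets of the three MAP kinases, OR-combined, in a
#' deterministic order (by subset size, then lexicographically with
#' ERK < JNK < p38).
#'
#' @param dusp_id A DUSP whose induction is unknown (DUSP3, DUSP9, DUSP16
#'   or DUSP23); an error otherwise.
#' @return List of character vectors (inducer sets).
#' @export
enumerate_hypotheses <- function(dusp_id) {
  facts <- get_regulation_facts(dusp_id)
  if (!identical(facts$inducers, "UNKNOWN"))
    stop(sprintf("induction of %s is known; nothing to infer", facts$dusp),
         call. = FALSE)
  hyps <- list()
  for (size in 1:3) {
    idx <- utils::combn(seq_along(dusp_kinases), size, simplify = FALSE)
    for (ii in idx) hyps[[length(hyps) + 1L]] <- dusp_kinases[ii]
  }
  hyps
}

hypothesis_id <- function(inducers) paste(inducers, collapse = "+")

swap_jnk_p38 <- function(inducers) {
  out <- inducers
  out[inducers == "JNK"] <- "p38"
  out[inducers == "p38"] <- "JNK"
  # keep canonical ERK < JNK < p38 order
  dusp_kinases[dusp_kinases %in% out]
}

# TRUE when the scaffold treats JNK and p38 identically (both or neither
# are substrates), so swapping their labels yields an isomorphic network.
jnk_p38_symmetric <- function(dusp_id) {
  subs <- get_regulation_facts(dusp_id)$substrates
  ("JNK" %in% subs) == ("p38" %in% subs)
}

# Is a simulated pattern class compatible with an experimental symbol
# string? Used for the small agreement bonus.
class_compatible <- function(pattern_class, symbols) {
  sym <- strsplit(symbols, "")[[1]]
  has_up <- "+" %in% sym
  has_down <- "-" %in% sym
  switch(pattern_class,
         OSCILLATING = has_up && has_down,
         ON_THEN_OFF = has_down && !has_up,
         OFF_THEN_ON = has_up && !has_down,
         CONSTANT_ON = !has_up && !has_down,
         CONSTANT_OFF = !has_up && !has_down,
         FALSE)
}

#' Score one inducer hypothesis against an experimental pattern
#'
#' Builds the DUSP model under the hypothesis, simulates it under
#' continuous Herceptin, reads the DUSP node's direction-symbol string over
#' transient plus one cycle, and scores agreement with the experimental
#' string as 1 minus the normalized Levenshtein distance, plus a bonus of
#' 0.1 (capped at 1) when the simulated pattern class is compatible with
#' the experimental string. Boolean time is aligned to experimental time
#' only ordinally, hence string comparison rather than pointwise matching.
#'
#' @param dusp_id Inference-target DUSP.
#' @param inducers Non-empty subset of \code{c("ERK","JNK","p38")}.
#' @param experimental Experimental direction-symbol string (over
#'   \code{+ - 0}), e.g. from [assign_patterns()].
#' @param herceptin Herceptin clamp (default ON).
#' @return An \code{agreement_report}: list with \code{dusp_id},
#'   \code{inducers}, \code{hypothesis} (id string),
#'   \code{simulated_pattern} (symbol string), \code{pattern_class},
#'   \code{experimental_pattern} and \code{score} in [0, 1].
#' @export
score_hypothesis <- function(dusp_id, inducers, experimental,
                             herceptin = 1L) {
  stopifnot(is.character(experimental), length(experimental) == 1L)
  if (!grepl("^[-+0]*$", experimental))
    stop("experimental pattern must be a string over + - 0", call. = FALSE)
  model <- build_model(dusp_id, inducers)
  att <- model_attractor(model, herceptin)
  sim <- node_symbols(att, model$dusp_id)
  cls <- classify_node_pattern(att, model$dusp_id)
  score <- edit_similarity(sim, experimental)
  if (class_compatible(cls, experimental)) score <- min(1, score + 0.1)
  structure(list(dusp_id = model$dusp_id, inducers = inducers,
                 hypothesis = hypothesis_id(inducers),
                 simulated_pattern = sim, pattern_class = cls,
                 experimental_pattern = experimental, score = score),
            class = "agreement_report")
}

#' Normalized edit similarity of two symbol strings
#'
#' \code{1 - levenshtein(a, b) / max(nchar(a), nchar(b))}; 1 iff the
#' strings are identical, and never below 0.
#'
#' @param a,b Strings.
#' @return Similarity in [0, 1].
#' @export
edit_similarity <- function(a, b) {
  if (nchar(a) == 0L && nchar(b) == 0L) return(1)
  d <- utils::adist(a, b)[1, 1]
  1 - d / max(nchar(a), nchar(b))
}

#' Infer candidate inducers for a DUSP from its expression pattern
#'
#' Scores all 7 OR-combined inducer hypotheses (see
#' [enumerate_hypotheses()]) against the experimental direction-symbol
#' string, merges hypotheses related by the JNK/p38 network symmetry into
#' one class, and returns the classes in descending score order. Classes
#' with equal scores share a rank (ties are reported jointly, never broken
#' arbitrarily).
#'
#' @inheritParams score_hypothesis
#' @param experimental Experimental symbol string for the DUSP's cluster.
#' @return An \code{inference_report} data frame, one row per hypothesis:
#'   \code{hypothesis, symmetry_class, score, rank, simulated_pattern,
#'   pattern_class, experimental_pattern}, ordered by rank.
#' @examples
#' rep <- infer_regulators("DUSP16", "----")
#' subset(rep, rank == 1)$hypothesis
#' @export
infer_regulators <- function(dusp_id, experimental, herceptin = 1L) {
  hyps <- enumerate_hypotheses(dusp_id)
  reports <- lapply(hyps, function(h)
    score_hypothesis(dusp_id, h, experimental, herceptin))
  ids <- vapply(reports, `[[`, character(1), "hypothesis")
  scores <- vapply(reports, `[[`, numeric(1), "score")

  symmetric <- jnk_p38_symmetric(dusp_id)
  class_of <- vapply(hyps, function(h) {
    if (!symmetric) return(hypothesis_id(h))
    pair <- sort(c(hypothesis_id(h), hypothesis_id(swap_jnk_p38(h))))
    paste(unique(pair), collapse = " | ")
  }, character(1))

  # symmetry soundness: members of a class must score identically
  for (cl in unique(class_of)) {
    s <- scores[class_of == cl]
    if (max(s) - min(s) > 0)
      stop(sprintf("symmetry violation: class '%s' members score differently",
                   cl), call. = FALSE)
  }

  class_score <- tapply(scores, class_of, max)
  uniq_scores <- sort(unique(unname(class_score)), decreasing = TRUE)
  class_rank <- stats::setNames(match(unname(class_score), uniq_scores),
                                names(class_score))

  df <- data.frame(
    dusp = normalize_dusp_id(dusp_id),
    hypothesis = ids,
    symmetry_class = class_of,
    score = scores,
    rank = unname(class_rank[class_of]),
    simulated_pattern = vapply(reports, `[[`, character(1),
                               "simulated_pattern"),
    pattern_class = vapply(reports, `[[`, character(1), "pattern_class"),
    experimental_pattern = experimental,
    stringsAsFactors = FALSE)
  df <- df[order(df$rank, nchar(df$hypothesis), df$hypothesis), ]
  rownames(df) <- NULL
  class(df) <- c("inference_report", "data.frame")
  df
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("%s <- %s: score %.3f (sim '%s' [%s] vs exp '%s')\n",
              x$dusp_id, x$hypothesis, x$score, x$simulated_pattern,
              x$pattern_class, x$experimental_pattern))
  invisible(x)
}
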