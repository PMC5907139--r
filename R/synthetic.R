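#' Default planted cluster structure for synthetic qPCR data
#'
#' 21 DUSP genes: seven clusters mirroring the reported memberships
#' (cluster 1: DUSP2/6/8, 2: DUSP9/11, 3: DUSP4/7, 4: DUSP23/28,
#' 5: DUSP5/22, 6: DUSP3/21, 7: DUSP1/12) plus six unclustered genes
#' (DUSP10/14/15/16/18/19), each with its own singleton template.
#'
#' @return Named character vector gene -> cluster id or
#'   \code{"UNCLUSTERED"}.
#' @export
default_cluster_assignment <- function() {
  c(DUSP2 = "1", DUSP6 = "1", DUSP8 = "1",
    DUSP9 = "2", DUSP11 = "2",
    DUSP4 = "3", DUSP7 = "3",
    DUSP23 = "4", DUSP28 = "4",
    DUSP5 = "5", DUSP22 = "5",
    DUSP3 = "6", DUSP21 = "6",
    DUSP1 = "7", DUSP12 = "7",
    DUSP10 = "UNCLUSTERED", DUSP14 = "UNCLUSTERED",
    DUSP15 = "UNCLUSTERED", DUSP16 = "UNCLUSTERED",
    DUSP18 = "UNCLUSTERED", DUSP19 = "UNCLUSTERED")
}

#' Default temporal templates (log2 fold change at 0, 2, 4, 12, 24 h)
#'
#' Transcriptions of the qualitative per-cluster shapes into log2
#' fold-change anchors (amplitudes are free design parameters): cluster 1
#' dips, rises sharply to a 12 h peak, then drops; cluster 2 is flat to
#' 4 h, peaks at 12 h, eases off; cluster 3 falls to 4 h then recovers;
#' cluster 4 alternates down/up/down/up; cluster 5 oscillates in a small
#' range; cluster 6 declines to 12 h then rebounds; cluster 7 rises
#' slightly then falls sharply. Unclustered genes get singleton shapes
#' (step drop, late drop, 4 h peak, gradual decline for DUSP16, gradual
#' rise, 2 h peak).
#'
#' @return Named list of numeric length-5 vectors (first entry 0,
#'   control-relative), keyed by cluster id or unclustered gene name.
#' @export
default_cluster_templates <- function() {
  list(
    "1" = c(0, -1.0, 1.0, 2.0, -1.0),
    "2" = c(0, -0.1, 0.05, 2.0, 1.5),
    "3" = c(0, -1.0, -2.0, 0.5, 0.5),
    "4" = c(0, -1.5, 1.0, -2.0, 0.0),
    "5" = c(0, 0.3, -0.4, 0.3, -0.4),
    "6" = c(0, -0.8, -1.5, -2.5, -0.5),
    "7" = c(0, 0.4, 0.2, -2.0, -2.5),
    DUSP10 = c(0, -2.2, -2.2, -2.2, -2.2),
    DUSP14 = c(0, 0.1, 0.1, 0.1, -2.5),
    DUSP15 = c(0, -0.3, 1.8, -0.8, -1.2),
    DUSP16 = c(0, -0.5, -1.0, -1.5, -2.0),
    DUSP18 = c(0, 0.5, 1.0, 1.5, 2.0),
    DUSP19 = c(0, 1.5, 0.3, -1.0, -1.5))
}

#' Configuration for the synthetic qPCR generator
#'
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @param assignment Gene -> cluster id (or \code{"UNCLUSTERED"}) vector;
#'   default [default_cluster_assignment()].
#' @param templates Cluster/singleton log2 fold-change templates; default
#'   [default_cluster_templates()]. Every template starts at 0
#'   (control-relative) and every assigned cluster id (and every
#'   unclustered gene) must have one.
#' @param times Time points in hours.
#' @param bio_reps,tech_reps Replicate structure (2 biological x 3
#'   technical, the study design).
#' @param ct_noise_sd Gaussian noise on the CT scale, cycles (default
#'   0.15, typical qPCR technical variability).
#' @param template_jitter_sd Per-gene, per-time jitter of the template on
#'   the log2 scale (default 0.1): within-cluster biological variation.
#' @param ref_ct Baseline CT of the two reference genes, cycles.
#' @param dusp_ct_offset Mean CT offset of targets above the reference
#'   baseline (DUSPs are expressed well below Actinb/GAPDH).
#' @param gene_offset_sd SD of the per-gene expression-level offset,
#'   cycles (cancels in the delta-delta-Ct).
#' @return A \code{synth_config} list.
#' @export
synth_config <- function(seed = 1L,
                         assignment = default_cluster_assignment(),
                         templates = default_cluster_templates(),
                         times = c(0, 2, 4, 12, 24),
                         bio_reps = 2L, tech_reps = 3L,
                         ct_noise_sd = 0.15,
                         template_jitter_sd = 0.1,
                         ref_ct = c(Actinb = 17, GAPDH = 16),
                         dusp_ct_offset = 8,
                         gene_offset_sd = 1) {
  cfg <- list(seed = as.integer(seed), assignment = assignment,
              templates = templates, times = times,
              bio_reps = as.integer(bio_reps),
              tech_reps = as.integer(tech_reps),
              ct_noise_sd = ct_noise_sd,
              template_jitter_sd = template_jitter_sd,
              ref_ct = ref_ct, dusp_ct_offset = dusp_ct_offset,
              gene_offset_sd = gene_offset_sd)
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (length(cfg$assignment) == 0L || is.null(names(cfg$assignment)))
    stop("assignment must be a named gene -> cluster vector", call. = FALSE)
  if (cfg$ct_noise_sd < 0 || cfg$template_jitter_sd < 0 ||
      cfg$gene_offset_sd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  if (cfg$bio_reps < 1L || cfg$tech_reps < 1L)
    stop("replicate counts must be >= 1", call. = FALSE)
  if (length(cfg$ref_ct) < 1L || is.null(names(cfg$ref_ct)))
    stop("ref_ct must be a named vector of reference-gene CTs",
         call. = FALSE)
  needed <- unique(ifelse(cfg$assignment == "UNCLUSTERED",
                          names(cfg$assignment), cfg$assignment))
  missing <- setdiff(needed, names(cfg$templates))
  if (length(missing))
    stop(sprintf("no template for: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  for (nm in needed) {
    tp <- cfg$templates[[nm]]
    if (length(tp) != length(cfg$times))
      stop(sprintf("template '%s' must have %d values", nm,
                   length(cfg$times)), call. = FALSE)
    if (tp[1L] != 0)
      stop(sprintf("template '%s' must start at 0 (control-relative)", nm),
           call. = FALSE)
  }
  invisible(TRUE)
}

#' Generate a synthetic CT table with planted cluster structure
#'
#' Reference genes are emitted at their baseline CT plus technical noise;
#' each target's CT is the reference-mean baseline plus a per-gene
#' expression offset minus the gene's realized log2 fold change (template
#' plus jitter) plus technical noise, so higher expression means a lower
#' threshold cycle. With all noise terms at 0 the delta-delta-Ct pipeline
#' recovers the planted fold changes exactly. The planted truth is
#' returned alongside the records and is never encoded in the table
#' itself.
#'
#' @param cfg A \code{synth_config}.
#' @return A \code{synth_qpcr} list: \code{records} (CT data frame:
#'   \code{gene, time_h, bio_rep, tech_rep, ct}) and \code{truth} (list
#'   with \code{assignment}, \code{log2_fold_change} and
#'   \code{fold_change} gene x time matrices of the realized planted
#'   values).
#' @export
generate_ct_table <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed), add = TRUE)
  set.seed(cfg$seed)

  genes <- names(cfg$assignment)
  nt <- length(cfg$times)
  ref_base <- mean(cfg$ref_ct)

  l2fc <- matrix(NA_real_, length(genes), nt,
                 dimnames = list(genes, as.character(cfg$times)))
  offset <- stats::setNames(
    stats::rnorm(length(genes), cfg$dusp_ct_offset, cfg$gene_offset_sd),
    genes)
  for (g in genes) {
    tkey <- if (cfg$assignment[[g]] == "UNCLUSTERED") g else cfg$assignment[[g]]
    jit <- stats::rnorm(nt, 0, cfg$template_jitter_sd)
    jit[1L] <- 0                       # anchor the control point
    l2fc[g, ] <- cfg$templates[[tkey]] + jit
  }

  grid <- expand.grid(time_h = cfg$times, bio_rep = seq_len(cfg$bio_reps),
                      tech_rep = seq_len(cfg$tech_reps),
                      KEEP.OUT.ATTRS = FALSE)
  recs <- list()
  for (rg in names(cfg$ref_ct)) {
    recs[[rg]] <- data.frame(
      gene = rg, grid,
      ct = cfg$ref_ct[[rg]] + stats::rnorm(nrow(grid), 0, cfg$ct_noise_sd),
      stringsAsFactors = FALSE)
  }
  for (g in genes) {
    fc_at <- l2fc[g, as.character(grid$time_h)]
    recs[[g]] <- data.frame(
      gene = g, grid,
      ct = ref_base + offset[[g]] - fc_at +
        stats::rnorm(nrow(grid), 0, cfg$ct_noise_sd),
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL

  structure(list(records = records,
                 truth = list(assignment = cfg$assignment,
                              log2_fold_change = l2fc,
                              fold_change = 2^l2fc)),
            class = "synth_qpcr")
}

#' Generate an expression series realizing a direction-symbol pattern
#'
#' Builds a fold-change time course whose differenced log10 sign string
#' equals \code{pattern} at zero noise: each \code{"+"}/\code{"-"} moves
#' the log10 level by \code{step}, \code{"0"} keeps it.
#'
#' @param pattern String over \code{+ - 0}, one symbol per time interval
#'   (4 symbols for the default five time points).
#' @param noise_sd Gaussian noise on the log10 scale.
#' @param seed Seed used when \code{noise_sd > 0}.
#' @param times Time points in hours.
#' @param step Log10 step size per interval (default 0.3, well above the
#'   default pattern dead band of 0.05).
#' @param gene Gene label for the output series.
#' @return An \code{expression_series}-style data frame (\code{gene,
#'   time_h, fold_change}).
#' @export
generate_pattern_series <- function(pattern, noise_sd = 0, seed = NULL,
                                    times = c(0, 2, 4, 12, 24),
                                    step = 0.3, gene = "synthetic") {
  sym <- strsplit(pattern, "")[[1]]
  if (length(sym) != length(times) - 1L)
    stop(sprintf("pattern must have %d symbols (one per interval)",
                 length(times) - 1L), call. = FALSE)
  bad <- setdiff(sym, c("+", "-", "0"))
  if (length(bad))
    stop(sprintf("bad pattern symbol '%s'", bad[1]), call. = FALSE)
  delta <- c(0, ifelse(sym == "+", step, ifelse(sym == "-", -step, 0)))
  lvl <- cumsum(delta)
  if (noise_sd > 0) {
    old_seed <- get_rng_state()
    on.exit(restore_rng_state(old_seed), add = TRUE)
    if (!is.null(seed)) set.seed(seed)
    lvl <- lvl + stats::rnorm(length(lvl), 0, noise_sd)
  }
  data.frame(gene = gene, time_h = times, fold_change = 10^lvl,
             stringsAsFactors = FALSE)
}

#' Write a synthetic dataset to disk
#'
#' Writes the CT table as CSV and the planted truth as JSON.
#'
#' @param synth A \code{synth_qpcr} object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two paths written.
#' @export
write_synth_data <- function(synth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ct_path <- file.path(dir, "ct_table.csv")
  truth_path <- file.path(dir, "truth.json")
  utils::write.csv(synth$records, ct_path, row.names = FALSE)
  jsonlite::write_json(
    list(assignment = as.list(synth$truth$assignment),
         log2_fold_change = as.data.frame(synth$truth$log2_fold_change)),
    truth_path, auto_unbox = TRUE, digits = NA)
  invisible(c(ct = ct_path, truth = truth_path))
}
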