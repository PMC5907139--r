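#' Read a CT table
#'
#' @param path CSV file with columns \code{gene, time_h, bio_rep, tech_rep,
#'   ct}.
#' @return Validated data frame of CT records.
#' @export
read_ct_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_ct_records(df)
  df
}

validate_ct_records <- function(records) {
  need <- c("gene", "time_h", "bio_rep", "tech_rep", "ct")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop(sprintf("CT table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (!all(is.finite(records$ct)) || any(records$ct <= 0))
    stop("all CT values must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

#' Relative expression time course by the delta-delta-Ct method
#'
#' Per replicate (biological x technical), the gene's CT is normalized
#' against the arithmetic mean CT of the reference genes measured in the
#' same replicate (\eqn{\Delta CT}); the treatment effect is
#' \eqn{\Delta\Delta CT = \Delta CT(t) - \overline{\Delta CT}(control)} and
#' the per-replicate fold change \eqn{2^{-\Delta\Delta CT}}. The series
#' fold change is \eqn{2^{-\overline{\Delta\Delta CT}}} (geometric mean on
#' the expression scale), so the control time point is exactly 1; the
#' standard error is that of the per-replicate fold changes. Significance
#' versus the control uses a two-sided Welch t-test on the per-replicate
#' \eqn{\Delta CT} values.
#'
#' @param records CT records (see [read_ct_table()]).
#' @param gene Target gene symbol.
#' @param refs Reference gene symbols, both required at every replicate
#'   where the target was measured.
#' @param control_time Control time point in hours (default 0).
#' @param alpha Significance level for the flag (default 0.05).
#' @return An \code{expression_series} data frame: \code{gene, time_h,
#'   fold_change, se, p_value, significant, n}.
#' @examples
#' recs <- expand.grid(gene = c("G", "Actinb", "GAPDH"),
#'                     time_h = c(0, 2, 4), bio_rep = 1, tech_rep = 1:2,
#'                     stringsAsFactors = FALSE)
#' recs$ct <- ifelse(recs$gene == "G", 20 + match(recs$time_h, c(0, 2, 4)) - 1, 15)
#' delta_delta_ct(recs, "G")$fold_change  # 1, 0.5, 0.25
#' @export
delta_delta_ct <- function(records, gene, refs = c("Actinb", "GAPDH"),
                           control_time = 0, alpha = 0.05) {
  validate_ct_records(records)
  if (!gene %in% records$gene)
    stop(sprintf("gene '%s' not present in CT table", gene), call. = FALSE)
  gr <- records[records$gene == gene, ]
  if (!control_time %in% gr$time_h)
    stop(sprintf("control time %s missing for gene '%s'",
                 format(control_time), gene), call. = FALSE)

  dct <- replicate_delta_ct(records, gene, refs)
  ctrl <- dct$delta_ct[dct$time_h == control_time]
  if (length(ctrl) == 0L)
    stop(sprintf("no control replicates for gene '%s'", gene), call. = FALSE)
  mean_ctrl <- mean(ctrl)
  dct$ddct <- dct$delta_ct - mean_ctrl
  dct$fc <- 2^(-dct$ddct)

  times <- sort(unique(dct$time_h))
  out <- lapply(times, function(tt) {
    sub <- dct[dct$time_h == tt, ]
    s <- summarize_replicates(sub$fc)
    if (tt == control_time) {
      p <- NA_real_
    } else {
      p <- test_vs_control(sub$delta_ct, ctrl)$p_value
    }
    data.frame(gene = gene, time_h = tt,
               # the control time point is 1 by construction
               fold_change = if (tt == control_time) 1
                             else 2^(-mean(sub$ddct)),
               se = s$se,
               p_value = p,
               significant = !is.na(p) && p < alpha,
               n = s$n, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  class(res) <- c("expression_series", "data.frame")
  res
}

# Per-replicate delta CT for one gene: CT_gene - mean(CT_refs), matched on
# (time, biological replicate, technical replicate).
replicate_delta_ct <- function(records, gene, refs) {
  gr <- records[records$gene == gene, ]
  key <- function(d) paste(d$time_h, d$bio_rep, d$tech_rep, sep = "|")
  gk <- key(gr)
  ref_ct <- sapply(refs, function(rf) {
    rr <- records[records$gene == rf, ]
    idx <- match(gk, key(rr))
    if (anyNA(idx)) {
      miss <- gr[which(is.na(idx))[1L], ]
      stop(sprintf("reference gene '%s' missing at time %s (bio %s, tech %s)",
                   rf, miss$time_h, miss$bio_rep, miss$tech_rep),
           call. = FALSE)
    }
    rr$ct[idx]
  })
  ref_mean <- rowMeans(matrix(ref_ct, nrow = nrow(gr)))
  data.frame(time_h = gr$time_h, bio_rep = gr$bio_rep,
             tech_rep = gr$tech_rep, delta_ct = gr$ct - ref_mean)
}

#' Mean and standard error over replicate values
#'
#' @param x Numeric vector of per-replicate values (at least one).
#' @return List with \code{mean}, \code{se} (\code{sd/sqrt(n)}; \code{NA}
#'   and flagged when only a single replicate is available), \code{n} and
#'   \code{single_replicate}.
#' @export
summarize_replicates <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0L) stop("no replicate values to summarize", call. = FALSE)
  single <- n < 2L
  if (single)
    warning("single replicate: standard error undefined", call. = FALSE)
  list(mean = mean(x),
       se = if (single) NA_real_ else stats::sd(x) / sqrt(n),
       n = n, single_replicate = single)
}

#' Two-sample test of a time point against the control
#'
#' Welch two-sided t-test. When both groups have (numerically) zero
#' variance the p-value is 1 if the means are equal and 0 otherwise, by
#' convention.
#'
#' @param treated,control Numeric vectors of per-replicate values.
#' @param alpha Significance level.
#' @return List with \code{statistic}, \code{p_value}, \code{significant}.
#' @export
test_vs_control <- function(treated, control, alpha = 0.05) {
  if (length(treated) < 2L || length(control) < 2L)
    stop("need at least two replicates in each group", call. = FALSE)
  v1 <- stats::var(treated); v2 <- stats::var(control)
  if (v1 < .Machine$double.eps && v2 < .Machine$double.eps) {
    same <- isTRUE(all.equal(mean(treated), mean(control)))
    p <- if (same) 1 else 0
    return(list(statistic = if (same) 0 else Inf, p_value = p,
                significant = p < alpha))
  }
  tt <- stats::t.test(treated, control, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Delta-delta-Ct series for every target gene in a CT table
#'
#' @inheritParams delta_delta_ct
#' @param genes Target genes; defaults to every gene except the references.
#' @return Long \code{expression_series} data frame over all genes.
#' @export
qpcr_series <- function(records, genes = NULL, refs = c("Actinb", "GAPDH"),
                        control_time = 0, alpha = 0.05) {
  validate_ct_records(records)
  if (is.null(genes)) genes <- setdiff(unique(records$gene), refs)
  res <- do.call(rbind, lapply(genes, function(g)
    delta_delta_ct(records, g, refs, control_time, alpha)))
  class(res) <- c("expression_series", "data.frame")
  res
}

#' Write / read an expression series table
#'
#' @param series Expression series data frame.
#' @param path TSV path.
#' @return \code{write_series_tsv}: the path, invisibly;
#'   \code{read_series_tsv}: the series data frame.
#' @export
write_series_tsv <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  class(df) <- c("expression_series", "data.frame")
  df
}
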