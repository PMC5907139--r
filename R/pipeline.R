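#' Default pipeline configuration
#'
#' @return Named list of pipeline settings: \code{seed}; \code{stages}
#'   (subset of \code{synth, qpcr, cluster, models, inference} — the
#'   \code{synth} stage is skipped automatically when \code{ct_file}
#'   points at a real CT table); \code{ct_file} (optional CSV of measured
#'   CTs); \code{refs}; \code{control_time}; \code{cut_height} for the
#'   average-linkage tree (default 0.5, calibrated on the default
#'   synthetic fixture to yield the planted seven clusters);
#'   \code{epsilon}, the log10 dead band for pattern symbols;
#'   \code{herceptin} clamp; \code{synth}, a list of overrides passed to
#'   [synth_config()].
#' @export
default_run_config <- function() {
  list(seed = 1L,
       stages = c("synth", "qpcr", "cluster", "models", "inference"),
       ct_file = NULL,
       refs = c("Actinb", "GAPDH"),
       control_time = 0,
       cut_height = 0.5,
       epsilon = 0.05,
       herceptin = 1L,
       synth = list())
}

#' Run the full analysis pipeline
#'
#' Orchestrates synthetic-data generation (or loading of a measured CT
#' table), delta-delta-Ct processing, correlation clustering, simulation
#' of every shipped DUSP model against its expected qualitative outcomes,
#' and inducer inference for the four DUSPs with unknown regulation, with
#' a single reproducibility seed. All stage outputs land in
#' \code{out_dir}; the summary report is written as JSON and Markdown and
#' is byte-stable for a fixed config.
#'
#' @param config Named list overriding [default_run_config()], or a path
#'   to a JSON file with the overrides.
#' @param out_dir Output directory (created if needed).
#' @return The report, invisibly: list with \code{models} (expected vs
#'   observed pattern classes), \code{clustering}, \code{inference} and
#'   \code{all_ok} (TRUE when every expected model outcome is
#'   reproduced).
#' @export
run_pipeline <- function(config = list(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop(sprintf("config file not found: %s", config), call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  cfg <- utils::modifyList(default_run_config(), config)
  if (length(cfg$stages) &&
      !is.null(cfg$ct_file) && "synth" %in% cfg$stages)
    cfg$stages <- setdiff(cfg$stages, "synth")
  unknown <- setdiff(cfg$stages,
                     c("synth", "qpcr", "cluster", "models", "inference"))
  if (length(unknown))
    stop(sprintf("unknown stage '%s'", unknown[1]), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  report <- list(seed = cfg$seed, stages = cfg$stages)
  records <- NULL
  truth <- NULL
  series <- NULL
  clusters <- NULL
  patterns <- NULL

  if ("synth" %in% cfg$stages) {
    synth <- run_stage("synth", function() {
      sc <- do.call(synth_config, utils::modifyList(list(seed = cfg$seed),
                                                    cfg$synth))
      out <- generate_ct_table(sc)
      write_synth_data(out, out_dir)
      out
    })
    records <- synth$records
    truth <- synth$truth
  } else if (!is.null(cfg$ct_file)) {
    records <- run_stage("qpcr", function() {
      if (!file.exists(cfg$ct_file))
        stop(sprintf("CT file not found: %s", cfg$ct_file))
      read_ct_table(cfg$ct_file)
    })
  }

  if ("qpcr" %in% cfg$stages) {
    series <- run_stage("qpcr", function() {
      if (is.null(records))
        stop("no CT records: enable the synth stage or set ct_file")
      s <- qpcr_series(records, refs = cfg$refs,
                       control_time = cfg$control_time)
      write_series_tsv(s, file.path(out_dir, "series.tsv"))
      s
    })
    report$qpcr <- list(n_genes = length(unique(series$gene)),
                        n_significant = sum(series$significant, na.rm = TRUE))
  }

  if ("cluster" %in% cfg$stages) {
    clus <- run_stage("cluster", function() {
      if (is.null(series)) stop("no expression series: enable qpcr stage")
      cmat <- correlation_matrix(series)
      cl <- cluster_genes(cmat, cfg$cut_height)
      write_correlation_tsv(cmat, file.path(out_dir, "correlation.tsv"))
      write_clusters_tsv(cl, file.path(out_dir, "clusters.tsv"))
      plot_clustermap(cmat, cl, file.path(out_dir, "clustermap.png"))
      list(cmat = cmat, cl = cl)
    })
    clusters <- clus$cl
    patterns <- assign_patterns(series, clusters, cfg$epsilon)
    report$clustering <- list(
      n_clusters = length(setdiff(unique(clusters$assignment),
                                  "UNCLUSTERED")),
      n_unclustered = sum(clusters$assignment == "UNCLUSTERED"),
      assignment = as.list(clusters$assignment),
      patterns = as.list(patterns))
  }

  if ("models" %in% cfg$stages) {
    model_res <- run_stage("models", function() {
      ids <- regulation_facts_table()$dusp
      res <- lapply(ids, function(id) {
        model <- default_model(id)
        traj <- simulate_model(model, herceptin = cfg$herceptin)
        export_heatmap(traj, file.path(out_dir,
                                       paste0(tolower(id), "_trajectory")))
        check_expected_outcomes(model, herceptin = cfg$herceptin)
      })
      do.call(rbind, res)
    })
    report$models <- model_res
  }

  if ("inference" %in% cfg$stages) {
    inf <- run_stage("inference", function() {
      targets <- c("DUSP9", "DUSP23", "DUSP3", "DUSP16")
      out <- list()
      for (d in targets) {
        exp_pat <- experimental_pattern_for(d, clusters, patterns)
        if (is.null(exp_pat)) next
        rep <- infer_regulators(d, exp_pat, herceptin = cfg$herceptin)
        top <- rep[rep$rank == 1L, ]
        out[[d]] <- list(experimental_pattern = exp_pat,
                         top_classes = unique(top$symmetry_class),
                         top_score = top$score[1L],
                         ranking = rep)
      }
      out
    })
    report$inference <- inf
  }

  if (!is.null(report$models))
    report$all_ok <- all(report$models$ok)

  write_report(report, out_dir)
  invisible(report)
}

# Pattern string for an inference target: its recovered cluster's
# descriptor, or its own per-gene descriptor if unclustered; NULL when the
# gene (or the clustering stage) is absent.
experimental_pattern_for <- function(dusp, clusters, patterns) {
  if (is.null(clusters) || is.null(patterns)) return(NULL)
  a <- clusters$assignment
  if (!dusp %in% names(a)) return(NULL)
  key <- if (a[[dusp]] == "UNCLUSTERED") dusp else a[[dusp]]
  if (!key %in% names(patterns)) return(NULL)
  patterns[[key]]
}

write_report <- function(report, out_dir) {
  json <- report
  if (!is.null(json$models)) json$models <- as.data.frame(json$models)
  if (!is.null(json$inference))
    json$inference <- lapply(json$inference, function(x) {
      x$ranking <- as.data.frame(x$ranking); x
    })
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  md <- c("# Pipeline report", "",
          sprintf("Seed: %d; stages: %s", report$seed,
                  paste(report$stages, collapse = ", ")), "")
  if (!is.null(report$clustering)) {
    md <- c(md, "## Clustering",
            sprintf("%d clusters, %d unclustered gene(s)",
                    report$clustering$n_clusters,
                    report$clustering$n_unclustered), "")
  }
  if (!is.null(report$models)) {
    m <- report$models
    md <- c(md, "## Model outcomes",
            "| model | node | expected | observed | ok |",
            "|---|---|---|---|---|",
            sprintf("| %s | %s | %s | %s | %s |", m$dusp, m$node,
                    m$expected, m$observed, m$ok), "")
  }
  if (!is.null(report$inference)) {
    md <- c(md, "## Inducer inference")
    for (d in names(report$inference)) {
      x <- report$inference[[d]]
      md <- c(md, sprintf("- %s (pattern `%s`): top class %s (score %.3f)",
                          d, x$experimental_pattern,
                          paste(x$top_classes, collapse = "; "),
                          x$top_score))
    }
    md <- c(md, "")
  }
  if (!is.null(report$all_ok))
    md <- c(md, sprintf("All expected model outcomes reproduced: %s",
                        report$all_ok))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(NULL)
}
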