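#' Run the full analysis workflow
#'
#' Wires the modules into the complete pipeline: (optionally) simulate a
#' cohort, log-normalize, run the selective-voting ensemble and the
#' traditional single-classifier baseline for each requested classifier
#' kind, compute consensus maps, score both against the clinical labels,
#' and report the samples mismatched under every ensemble variant (the
#' cross-variant consistency set).
#'
#' All outputs are plain text (CSV/TSV/JSON) plus optional PNG heatmaps,
#' written under `out_dir` together with a run manifest sufficient to
#' re-execute the run bit-identically.
#'
#' @param out_dir output directory (created if absent).
#' @param table a raw-scale [biomarker_table()], or `NULL` to simulate one
#'   from `spec`.
#' @param spec a [cohort_spec()] used when `table` is `NULL`.
#' @param Nb,k1,seed cross-validation realizations, fold size, and RNG seed
#'   shared by every configuration.
#' @param classifiers classifier kinds to run (default all four).
#' @param make_plots write consensus heatmap PNGs.
#' @return Invisibly, a list with per-classifier results (`sva`,
#'   `traditional`, `mismatch`), `mismatch_intersection`, `truth` (when
#'   simulated), and the `manifest`.
#' @export
run_all <- function(out_dir, table = NULL, spec = cohort_spec(),
                    Nb = 100L, k1 = 10L, seed = 1L,
                    classifiers = c("lda", "qda", "nb", "svm"),
                    make_plots = TRUE) {
  t0 <- Sys.time()
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth <- NULL
  if (is.null(table)) {
    sim <- generate_cohort(spec)
    table <- sim$table
    truth <- sim$truth
    write_biomarker_table(table, file.path(out_dir, "cohort.csv"))
    utils::write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  }
  input_path <- file.path(out_dir, "cohort.csv")
  if (!file.exists(input_path)) {
    write_biomarker_table(table, input_path)
  }
  norm <- log_normalize(table)
  results <- list()
  metrics <- list()
  paths <- list(input = input_path)
  for (kind in classifiers) {
    cfg <- sva_config(Nb = Nb, k1 = k1, classifier = kind, seed = seed)
    res <- run_sva(norm, cfg)
    psets <- persistent_sets(res)
    cmap <- consensus_map(psets)
    prefix <- file.path(out_dir, paste0("sva-", kind))
    utils::write.csv(proclivity_table(res),
                     paste0(prefix, "-proclivity.csv"), row.names = FALSE)
    export_heatmap(cmap,
                   image_path = if (make_plots) paste0(prefix, "-consensus.png"),
                   matrix_path = paste0(prefix, "-tau.tsv"))
    write_persistent_sets(psets, paste0(prefix, "-ensembles.json"))
    perf_sva <- summarize_performance(res$per_realization_labels,
                                      table$labels, seed = seed)
    perf_trad <- run_traditional(norm, cfg)
    mism <- identify_mismatch(res)
    results[[kind]] <- list(sva = res, consensus = cmap,
                            sva_performance = perf_sva,
                            traditional = perf_trad, mismatch = mism)
    metrics[[kind]] <- list(
      sva = list(mean = as.list(perf_sva$mean), sd = as.list(perf_sva$sd),
                 mismatch_ids = mism),
      traditional = list(mean = as.list(perf_trad$mean),
                         sd = as.list(perf_trad$sd)))
    paths[[paste0("sva_", kind)]] <- paste0(prefix, "-proclivity.csv")
  }
  mi <- Reduce(intersect, lapply(results, `[[`, "mismatch"))
  metrics$mismatch_intersection <- mi
  metrics_path <- file.path(out_dir, "metrics.json")
  jsonlite::write_json(metrics, metrics_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- list(
    package = "selvote",
    version = as.character(utils::packageVersion("selvote")),
    seed = seed, Nb = Nb, k1 = k1, classifiers = classifiers,
    simulated = !is.null(truth),
    input_md5 = unname(tools::md5sum(input_path)),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = paths)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, mismatch_intersection = mi,
                 truth = truth, manifest = manifest))
}

# persistent ensemble sets as JSON: sample -> list of [i, j] pairs per class
write_persistent_sets <- function(psets, path) {
  to_pairs <- function(idx) {
    lapply(idx, function(b) unname(psets$pairs[, b]))
  }
  obj <- stats::setNames(lapply(seq_along(psets$sample_ids), function(k) {
    list(g = to_pairs(psets$g_star[[k]]), p = to_pairs(psets$p_star[[k]]))
  }), psets$sample_ids)
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML (or JSON) file mirroring the [run_all()] arguments: `out_dir`,
#' `input` (path to a cohort CSV, optional), `Nb`, `k1`, `seed`,
#' `classifiers`, `make_plots`, and an optional `simulate` block with
#' `n_gin`, `n_per`, `planted_swap_fraction`, `seed`.
#'
#' @param path configuration file path.
#' @return The parsed configuration list.
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Execute [run_all()] from a configuration file
#'
#' @param path configuration file path (see [read_run_config()]).
#' @return See [run_all()].
#' @export
run_all_from_config <- function(path) {
  cfg <- read_run_config(path)
  table <- if (!is.null(cfg$input)) read_biomarker_table(cfg$input)
  spec <- if (is.null(cfg$simulate)) cohort_spec() else
    do.call(cohort_spec, cfg$simulate[names(cfg$simulate) %in%
      c("n_gin", "n_per", "planted_swap_fraction", "family", "seed")])
  run_all(out_dir = cfg$out_dir %||% "results",
          table = table, spec = spec,
          Nb = cfg$Nb %||% 100L, k1 = cfg$k1 %||% 10L,
          seed = cfg$seed %||% 1L,
          classifiers = cfg$classifiers %||% c("lda", "qda", "nb", "svm"),
          make_plots = cfg$make_plots %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
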