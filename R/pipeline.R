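#' Read a flat key = value pipeline configuration
#'
#' One `key = value` per line; `#` starts a comment. Recognized keys:
#' `replicons` (path to a [read_replicon_config()] TSV), `samples` (path
#' to a TSV with columns `sample_id`, `group`, `path`, `replicon`),
#' `out_dir`, `seed`, `window_bp`, `n_segments`, `samples_per_segment`,
#' `coverage_window_bp`, `min_mapq`, `region` (e.g. `1300000-1900000`),
#' `diff_window_bp`, `pseudocount`, `group_a`. Unset keys fall back to the
#' defaults documented in [run_pipeline()].
#'
#' @param path Path to the config file.
#' @return A named list of configuration values (strings unparsed).
#' @export
read_pipeline_config <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  setNames(lapply(kv, function(x) paste(x[-1], collapse = "=")),
           vapply(kv, `[[`, "", 1))
}

#' Run the full per-sample analysis pipeline
#'
#' For every sample: import alignments, export windowed coverage as
#' bedGraph, and compute the ter-enrichment row; write a combined
#' enrichment table. If the samples carry at least two group labels and a
#' `region` is configured, also compute the TMM-normalized per-window log2
#' fold-change of every other group against the baseline group. A
#' manifest recording every parameter and seed is written alongside the
#' results, so any output can be regenerated from the manifest alone.
#'
#' @param config A list as returned by [read_pipeline_config()], or a path
#'   to a config file. Defaults applied: `seed` 1, `n_segments` 10,
#'   `samples_per_segment` 20, `coverage_window_bp` 8000, `min_mapq` 0,
#'   `diff_window_bp` 500, `pseudocount` 0.5, `window_bp` = ter length.
#' @return Invisibly, a named list of the files written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_pipeline_config(config)
  get <- function(key, default = NULL) config[[key]] %||% default
  num <- function(key, default) as.numeric(get(key, default))
  stage <- function(label, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", label,
                    conditionMessage(e)),
            class = "terenrich_pipeline_error")
    })
  }
  out_dir <- get("out_dir") %||% abort("config needs out_dir",
                                       class = "terenrich_pipeline_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(num("seed", 1))
  specs <- stage("replicon-config", read_replicon_config(get("replicons")))
  samples <- stage("sample-table",
                   readr::read_tsv(get("samples"), show_col_types = FALSE,
                                   progress = FALSE))
  outputs <- list()

  results <- list()
  mapsets <- list()
  for (i in seq_len(nrow(samples))) {
    id <- samples$sample_id[i]
    sp <- specs[[samples$replicon[i]]]
    if (is.null(sp))
      abort(sprintf("sample '%s' references unknown replicon '%s'", id,
                    samples$replicon[i]),
            class = "terenrich_pipeline_error")
    maps <- stage(paste0("read-alignments:", id),
                  read_alignments(samples$path[i], sp,
                                  min_mapq = num("min_mapq", 0)))
    mapsets[[id]] <- maps
    track <- stage(paste0("coverage:", id), per_base_coverage(maps))
    cw <- as.integer(num("coverage_window_bp", 8000))
    wc <- sliding_windows(track, window_bp = cw, step_bp = cw)
    bg <- file.path(out_dir, paste0(id, ".coverage.bedGraph"))
    stage(paste0("bedgraph:", id), write_bedgraph(wc, bg))
    outputs[[paste0(id, ".coverage")]] <- bg
    wbp <- get("window_bp")
    res <- stage(paste0("enrich:", id),
                 compute_enrichment(maps, sp,
                                    window_bp = if (is.null(wbp)) NULL else as.numeric(wbp),
                                    n_segments = as.integer(num("n_segments", 10)),
                                    samples_per_segment = as.integer(num("samples_per_segment", 20)),
                                    seed = seed))
    results[[id]] <- res
    etsv <- file.path(out_dir, paste0(id, ".enrichment.tsv"))
    tab <- tidy(res)
    tab <- dplyr::bind_cols(tibble(sample_id = id), tab)
    readr::write_tsv(tab, etsv, progress = FALSE)
    outputs[[paste0(id, ".enrichment")]] <- etsv
  }
  combined <- file.path(out_dir, "enrichment_table.tsv")
  readr::write_tsv(purrr::map_dfr(names(results), function(id) {
    dplyr::bind_cols(tibble(sample_id = id), tidy(results[[id]]))
  }), combined, progress = FALSE)
  outputs[["enrichment_table"]] <- combined

  region_str <- get("region")
  if (!is.null(region_str) && "group" %in% names(samples) &&
      length(unique(samples$group)) >= 2) {
    bounds <- as.numeric(strsplit(region_str, "-")[[1]])
    region <- genome_interval(bounds[1], bounds[2])
    group_a <- get("group_a", samples$group[1])
    cm <- stage("count-matrix",
                build_count_matrix(mapsets, region,
                                   window_bp = as.integer(num("diff_window_bp", 500)),
                                   groups = samples$group))
    fac <- stage("tmm", tmm_factors(cm))
    for (gb in setdiff(unique(samples$group), group_a)) {
      fc <- stage(paste0("log2fc:", gb),
                  log2_fold_change(cm, fac, group_a = group_a, group_b = gb,
                                   pseudocount = num("pseudocount", 0.5)))
      dtsv <- file.path(out_dir, sprintf("differential_%s_vs_%s.tsv", gb, group_a))
      readr::write_tsv(as_tibble(fc), dtsv, progress = FALSE)
      outputs[[paste0("differential_", gb)]] <- dtsv
    }
  }

  manifest <- file.path(out_dir, "manifest.tsv")
  keys <- c("replicons", "samples", "out_dir", "seed", "window_bp",
            "n_segments", "samples_per_segment", "coverage_window_bp",
            "min_mapq", "region", "diff_window_bp", "pseudocount", "group_a")
  defaults <- list(seed = "1", n_segments = "10", samples_per_segment = "20",
                   coverage_window_bp = "8000", min_mapq = "0",
                   diff_window_bp = "500", pseudocount = "0.5")
  vals <- vapply(keys, function(k)
    as.character(get(k, defaults[[k]] %||% NA_character_)), "")
  readr::write_tsv(tibble(key = keys, value = vals), manifest, progress = FALSE)
  outputs[["manifest"]] <- manifest
  invisible(outputs)
}

#' Collect per-sample enrichment rows into one summary table
#'
#' Reads every `*.enrichment.tsv` under `results_dir` (as written by
#' [run_pipeline()]) and concatenates them in the published summary-column
#' order.
#'
#' @param results_dir Directory containing enrichment TSVs.
#' @param path Optional output path for the combined TSV.
#' @return A tibble, one row per sample.
#' @export
report_table <- function(results_dir, path = NULL) {
  files <- sort(list.files(results_dir, pattern = "\\.enrichment\\.tsv$",
                           full.names = TRUE))
  if (length(files) == 0)
    abort(sprintf("no enrichment tables under '%s'", results_dir),
          class = "terenrich_no_input_error")
  tab <- purrr::map_dfr(files, readr::read_tsv, show_col_types = FALSE,
                        progress = FALSE)
  if (!is.null(path)) readr::write_tsv(tab, path, progress = FALSE)
  tab
}
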