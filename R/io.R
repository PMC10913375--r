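#' Read mapped reads from a SAM/BAM or BED file
#'
#' Imports the primary mapped alignments on one replicon. SAM and BAM input
#' goes through Rsamtools/GenomicAlignments with the standard exclusions
#' (unmapped 0x4, secondary 0x100, supplementary 0x800); BED6 input
#' (0-based half-open) is converted to the 1-based inclusive internal
#' convention on read. Records on other replicons are dropped; the target
#' replicon must appear in the SAM header (or BED chrom column).
#'
#' @param path Path to a `.sam`, `.bam` or `.bed` file.
#' @param replicon A [replicon_spec()]; records are matched against its
#'   `accession`.
#' @param min_mapq Minimum mapping quality (SAM/BAM only; default 0, i.e.
#'   every primary mapped read is kept, since published ter-enrichment
#'   counts apply no quality filter).
#' @return A [read_mappings()] tibble.
#' @export
read_alignments <- function(path, replicon, min_mapq = 0) {
  stopifnot(inherits(replicon, "replicon_spec"))
  if (!file.exists(path))
    abort(sprintf("cannot read '%s'", path), class = "terenrich_format_error")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    sam = , bam = read_alignments_bam(path, replicon, min_mapq, is_sam = ext == "sam"),
    bed = read_alignments_bed(path, replicon),
    abort(sprintf("unsupported alignment format '.%s'", ext),
          class = "terenrich_format_error"))
}

read_alignments_bam <- function(path, replicon, min_mapq, is_sam) {
  bam <- if (is_sam) {
    dest <- tempfile(fileext = "")
    tryCatch(
      Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE),
      error = function(e) abort(sprintf("not a parseable SAM file: %s",
                                        conditionMessage(e)),
                                class = "terenrich_format_error"))
  } else path
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!replicon$accession %in% names(hdr))
    abort(sprintf("replicon '%s' not in alignment header", replicon$accession),
          class = "terenrich_missing_reference_error")
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
  ga <- suppressWarnings(GenomicAlignments::readGAlignments(bam, param = param))
  df <- as.data.frame(ga)
  df <- df[as.character(df$seqnames) == replicon$accession, , drop = FALSE]
  read_mappings(
    tibble(start = df$start,
           end = df$end,  # may exceed L for reads wrapping the origin
           strand = ifelse(as.character(df$strand) == "-", "-", "+")),
    replicon)
}

read_alignments_bed <- function(path, replicon) {
  bed <- tryCatch(
    readr::read_tsv(path, col_names = c("chrom", "start0", "end0", "name",
                                        "score", "strand"),
                    col_types = "cddcdc", comment = "#", progress = FALSE),
    error = function(e) abort(sprintf("not a parseable BED file: %s",
                                      conditionMessage(e)),
                              class = "terenrich_format_error"))
  if (!replicon$accession %in% bed$chrom)
    abort(sprintf("replicon '%s' not present in BED file", replicon$accession),
          class = "terenrich_missing_reference_error")
  bed <- dplyr::filter(bed, .data$chrom == replicon$accession)
  read_mappings(
    tibble(start = bed$start0 + 1, end = bed$end0, strand = bed$strand),
    replicon)
}

#' Write mapped reads to SAM or BED
#'
#' Emits a minimal spec-compliant file that [read_alignments()] round-trips
#' exactly. Reads wrapping the origin of a circular replicon are written
#' with their end coordinate continuing past the reference end (neither
#' linear format can express a wrap); the reader folds them back.
#'
#' @param mappings A [read_mappings()] tibble.
#' @param path Output path.
#' @param format `"sam"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_mappings <- function(mappings, path, format = c("sam", "bed")) {
  format <- match.arg(format)
  rep <- replicon_of(mappings)
  L <- rep$length_bp
  end_lin <- ifelse(mappings$end >= mappings$start, mappings$end,
                    mappings$end + L)  # linearized end, may exceed L
  ok <- tryCatch({
    con <- file(path, open = "wt")
    on.exit(close(con))
    TRUE
  }, error = function(e) FALSE)
  if (!ok)
    abort(sprintf("cannot write '%s'", path), class = "terenrich_io_error")
  n <- nrow(mappings)
  if (format == "sam") {
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", rep$accession, as.integer(L))),
               con)
    if (n > 0) {
      len <- end_lin - mappings$start + 1
      writeLines(sprintf("read%d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                         seq_len(n),
                         ifelse(mappings$strand == "-", 16L, 0L),
                         rep$accession, as.integer(mappings$start),
                         as.integer(len)),
                 con)
    }
  } else {
    if (n > 0) {
      writeLines(sprintf("%s\t%d\t%d\tread%d\t0\t%s",
                         rep$accession, as.integer(mappings$start - 1),
                         as.integer(end_lin), seq_len(n), mappings$strand),
                 con)
    }
  }
  invisible(path)
}

#' Export a coverage track or windowed coverage as bedGraph
#'
#' Coordinates are converted to the bedGraph convention (0-based
#' half-open) on write; equal-depth runs are merged.
#'
#' @param x A [per_base_coverage()] track or [sliding_windows()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  rep <- replicon_of(x)
  if (inherits(x, "coverage_track")) {
    r <- rle(x$depth)
    ends <- cumsum(r$lengths)
    gr <- GenomicRanges::GRanges(rep$accession,
                                 IRanges::IRanges(start = c(1, head(ends, -1) + 1),
                                                  end = ends),
                                 score = r$values)
  } else if (inherits(x, "windowed_coverage")) {
    step <- attr(x, "step_bp")
    gr <- GenomicRanges::GRanges(rep$accession,
                                 IRanges::IRanges(start = x$center,
                                                  width = step),
                                 score = x$value)
    gr <- gr[GenomicRanges::end(gr) <= rep$length_bp]
  } else {
    abort("x must be a coverage_track or windowed_coverage",
          class = "terenrich_format_error")
  }
  tryCatch(rtracklayer::export(gr, path, format = "bedGraph"),
           error = function(e) abort(sprintf("cannot write '%s'", path),
                                     class = "terenrich_io_error"))
  invisible(path)
}

#' Write enrichment results as a tab-separated summary table
#'
#' One row per replicon/sample in the published column order: replicon,
#' ter bounds, total and ter-assigned read counts, the null-distribution
#' mean/median/standard deviation, and the integer enrichment.
#'
#' @param results A single enrichment result or a list of them.
#' @param path Output path.
#' @return The table written, invisibly, as a tibble.
#' @export
write_enrichment_table <- function(results, path) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  if (length(results) == 0)
    abort("no results to write", class = "terenrich_io_error")
  tab <- purrr::map_dfr(results, tidy)
  tryCatch(readr::write_tsv(tab, path, progress = FALSE),
           error = function(e) abort(sprintf("cannot write '%s'", path),
                                     class = "terenrich_io_error"))
  invisible(tab)
}

#' Read replicon specifications from a tab-separated config file
#'
#' Expected columns: `accession`, `name`, `length_bp`, `circular`
#' (TRUE/FALSE), `ter_start`, `ter_end`, and optionally `dif_pos`,
#' `ori_pos` (NA for absent).
#'
#' @param path Path to the TSV file.
#' @return A named list of [replicon_spec()] objects keyed by accession.
#' @export
read_replicon_config <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("accession", "name", "length_bp", "circular", "ter_start", "ter_end")
  if (!all(need %in% names(tab)))
    abort(sprintf("replicon config must have columns: %s",
                  paste(need, collapse = ", ")),
          class = "terenrich_format_error")
  opt <- function(row, col) {
    v <- if (col %in% names(tab)) row[[col]] else NA
    if (is.na(v)) NULL else v
  }
  specs <- purrr::map(seq_len(nrow(tab)), function(i) {
    row <- tab[i, ]
    replicon_spec(row$name, row$accession, row$length_bp,
                  circular = as.logical(row$circular),
                  ter_start = row$ter_start, ter_end = row$ter_end,
                  dif_pos = opt(row, "dif_pos"), ori_pos = opt(row, "ori_pos"))
  })
  setNames(specs, tab$accession)
}
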