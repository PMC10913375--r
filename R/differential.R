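#' Tile a region into windows and count reads per sample
#'
#' Builds the window-by-sample count matrix used for between-strain
#' comparison of ter-region coverage. The region is tiled into consecutive
#' windows of `window_bp` every `step_bp` bases (default `step_bp =
#' window_bp`, i.e. non-overlapping tiles, which keeps the counts
#' uncorrelated for normalization); reads are assigned to windows by start
#' coordinate via [count_reads_in()].
#'
#' @param mappings_per_sample Named list of [read_mappings()] on the same
#'   replicon; names become sample ids.
#' @param region A non-wrapping [genome_interval()] (e.g. the 1.3-1.9 Mb
#'   span flanking ter on the E. coli chromosome).
#' @param window_bp Window width in bp (default 500, the display
#'   resolution of published ter-region profiles).
#' @param step_bp Tile step (default `window_bp`).
#' @param groups Optional per-sample labels (e.g. `"WT"`, `"xerC"`),
#'   recycled against the sample list.
#' @return A `coverage_count_matrix`: list with `windows` (tibble of
#'   `start`, `end`), integer `counts` (windows x samples), `sample_ids`,
#'   `group`, and the shared `replicon`.
#' @export
build_count_matrix <- function(mappings_per_sample, region, window_bp = 500,
                               step_bp = window_bp, groups = NULL) {
  stopifnot(length(mappings_per_sample) >= 1)
  if (region$wraps)
    abort("count-matrix region must not wrap the origin",
          class = "terenrich_interval_error")
  reps <- purrr::map(mappings_per_sample, replicon_of)
  acc <- purrr::map_chr(reps, "accession")
  if (length(unique(acc)) != 1)
    abort("all samples must be mapped to the same replicon",
          class = "terenrich_incompatible_samples_error")
  rp <- reps[[1]]
  if (region$end > rp$length_bp)
    abort("region outside replicon bounds", class = "terenrich_bounds_error")
  starts <- seq(region$start, region$end - window_bp + 1, by = step_bp)
  windows <- tibble(start = starts, end = starts + window_bp - 1)
  ids <- names(mappings_per_sample) %||% paste0("S", seq_along(mappings_per_sample))
  if (is.null(names(mappings_per_sample))) names(mappings_per_sample) <- ids
  counts <- vapply(mappings_per_sample, function(m) {
    s <- sort(m$start)
    as.integer(findInterval(windows$end, s) - findInterval(windows$start - 1, s))
  }, integer(nrow(windows)))
  counts <- matrix(counts, nrow = nrow(windows),
                   dimnames = list(NULL, ids))
  if (!is.null(groups)) groups <- base::rep(as.character(groups), length.out = length(ids))
  structure(list(windows = windows, counts = counts, sample_ids = ids,
                 group = groups, replicon = rp, region = region),
            class = "coverage_count_matrix")
}

#' @export
print.coverage_count_matrix <- function(x, ...) {
  cat(sprintf("<coverage_count_matrix> %d windows x %d samples on %s\n",
              nrow(x$counts), ncol(x$counts), x$replicon$name))
  if (!is.null(x$group))
    cat("  groups:", paste(sprintf("%s=%s", x$sample_ids, x$group),
                           collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.coverage_count_matrix <- function(x, ...) {
  long <- as_tibble(x$counts)
  long <- dplyr::bind_cols(x$windows, long)
  tidyr::pivot_longer(long, cols = -c("start", "end"),
                      names_to = "sample", values_to = "count")
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Between-sample scaling factors for a window count matrix, following the
#' standard TMM procedure: a reference sample is chosen as the one whose
#' upper-quartile/library-size ratio is closest to the mean such ratio;
#' for every sample, per-window log2 ratios to the reference (M, library
#' size scaled) and average log2 abundances (A) are computed over windows
#' nonzero in both; the top and bottom 30% by M and 5% by A are trimmed;
#' the factor is two to the precision-weighted mean of the remaining M
#' values, with inverse-variance weights from the binomial (delta-method)
#' approximation. Factors are rescaled to geometric mean 1.
#'
#' @param matrix A [build_count_matrix()] result.
#' @param ref_sample Optional sample id to use as the reference.
#' @param trim_m,trim_a Two-sided trim fractions for M and A (defaults
#'   0.30 and 0.05, the method's published constants).
#' @return Named numeric vector of positive per-sample factors with
#'   geometric mean 1.
#' @export
tmm_factors <- function(matrix, ref_sample = NULL, trim_m = 0.30, trim_a = 0.05) {
  counts <- matrix$counts
  if (ncol(counts) < 2)
    abort("TMM needs at least two samples", class = "terenrich_domain_error")
  lib <- colSums(counts)
  if (any(lib <= 0))
    abort("every sample must have a positive total count",
          class = "terenrich_domain_error")
  if (is.null(ref_sample)) {
    f75 <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref_i <- which.min(abs(f75 - mean(f75)))
  } else {
    ref_i <- match(ref_sample, matrix$sample_ids)
    if (is.na(ref_i))
      abort(sprintf("unknown ref_sample '%s'", ref_sample),
            class = "terenrich_domain_error")
  }
  refc <- counts[, ref_i]
  nR <- lib[ref_i]
  f <- vapply(seq_len(ncol(counts)), function(i) {
    if (i == ref_i) return(1)
    obs <- counts[, i]
    nO <- lib[i]
    keep <- obs > 0 & refc > 0
    if (!any(keep))
      abort("no common nonzero windows for TMM",
            class = "terenrich_degenerate_normalization_error")
    o <- obs[keep]; r <- refc[keep]
    M <- log2((o / nO) / (r / nR))
    A <- 0.5 * log2((o / nO) * (r / nR))
    n <- length(M)
    loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
    rkM <- rank(M); rkA <- rank(A)
    use <- rkM >= loM & rkM <= hiM & rkA >= loA & rkA <= hiA
    if (!any(use)) return(1)
    w <- (nO - o) / (nO * o) + (nR - r) / (nR * r)  # var(M) approximation
    iw <- 1 / w[use]
    if (!all(is.finite(iw))) return(2^mean(M[use]))  # degenerate weights
    2^(sum(M[use] * iw) / sum(iw))
  }, numeric(1))
  f <- f / exp(mean(log(f)))  # geometric mean 1
  setNames(f, matrix$sample_ids)
}

#' Per-window log2 fold-change between two groups
#'
#' Counts are put on a common scale by dividing by the effective library
#' size (library size times TMM factor) and re-scaling to the mean
#' effective library; group means are compared per window on that scale
#' with a pseudocount guarding against empty windows. With identical
#' groups the fold-change is exactly zero, and swapping the groups flips
#' its sign exactly.
#'
#' @param matrix A [build_count_matrix()] result.
#' @param factors Per-sample normalization factors (default
#'   [tmm_factors()] of `matrix`).
#' @param group_a,group_b Group labels (fold-change is b over a, i.e.
#'   mutant over wild type when `group_a` is the wild type).
#' @param pseudocount Reads added to each group mean on the normalized
#'   scale (default 0.5).
#' @param lib_sizes Optional per-sample library sizes (default: column
#'   sums of the count matrix).
#' @return A tibble of class `log2fc_windows` with columns `start`, `end`,
#'   `mean_a`, `mean_b` (normalized means) and `log2fc`.
#' @export
log2_fold_change <- function(matrix, factors = tmm_factors(matrix),
                             group_a, group_b, pseudocount = 0.5,
                             lib_sizes = NULL) {
  grp <- matrix$group
  if (is.null(grp))
    abort("count matrix has no group labels", class = "terenrich_domain_error")
  ia <- which(grp == group_a); ib <- which(grp == group_b)
  if (length(ia) == 0 || length(ib) == 0)
    abort("both groups must be non-empty", class = "terenrich_domain_error")
  lib <- lib_sizes %||% colSums(matrix$counts)
  eff <- lib * factors[matrix$sample_ids]
  norm <- sweep(matrix$counts, 2, eff / mean(eff), "/")
  mean_a <- rowMeans(norm[, ia, drop = FALSE])
  mean_b <- rowMeans(norm[, ib, drop = FALSE])
  structure(
    dplyr::bind_cols(matrix$windows,
                     tibble(mean_a = mean_a, mean_b = mean_b,
                            log2fc = log2((mean_b + pseudocount) /
                                          (mean_a + pseudocount)))),
    replicon = matrix$replicon, group_a = group_a, group_b = group_b,
    class = c("log2fc_windows", class(tibble())))
}

#' @export
autoplot.log2fc_windows <- function(object, ...) {
  rep <- attr(object, "replicon")
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                    y = .data$log2fc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Position (Mb)",
                  y = sprintf("log2 FC (%s / %s)", attr(object, "group_b"),
                              attr(object, "group_a"))) +
    ggplot2::theme_minimal()
  if (!is.null(rep$dif_pos))
    p <- p + ggplot2::geom_vline(xintercept = rep$dif_pos / 1e6,
                                 linetype = "dashed")
  p
}
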