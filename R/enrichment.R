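#' Null distribution of read counts in random non-ter windows
#'
#' The replicon minus the *ter* window is treated as one contiguous arc
#' (joining across the origin on circular replicons) and divided into
#' `n_segments` equal parts — any remainder bases go to the last segment.
#' Within each segment, `samples_per_segment` window start positions are
#' drawn uniformly at random such that each window of `window_bp` fits
#' entirely inside its segment (so every sampled window lies wholly
#' outside *ter*); windows within a segment may overlap. Reads are counted
#' per window by their start coordinate, and the counts are summarized by
#' mean, median (midpoint convention over the even sample count) and
#' sample standard deviation (n-1 denominator). With the defaults this is
#' a 10 x 20 = 200-window null.
#'
#' @param mappings A [read_mappings()] tibble.
#' @param ter A [genome_interval()], the *ter* window to exclude.
#' @param window_bp Null window width in bp (typically the *ter* window
#'   length; 8000 is the common alternative preset).
#' @param n_segments Number of equal segments of the non-ter arc.
#' @param samples_per_segment Windows sampled per segment.
#' @param seed Integer seed; identical seeds give identical samples. The
#'   global RNG state is left untouched.
#' @return A `null_distribution`: list with the sampling parameters, a
#'   tibble `samples` (`segment`, `start` as genome position, `count`),
#'   and fields `mean`, `median`, `std`, `seed`.
#' @export
sample_null <- function(mappings, ter, window_bp, n_segments = 10,
                        samples_per_segment = 20, seed = 1L) {
  rep <- replicon_of(mappings)
  L <- rep$length_bp
  ter_len <- interval_length(ter, rep)
  L_out <- L - ter_len
  window_bp <- as.double(window_bp)
  if (L_out < n_segments * window_bp)
    abort("non-ter portion too short for the requested sampling",
          class = "terenrich_sampling_error")

  # arc coordinate u in [1, L_out] maps to genome position just after ter;
  # on a linear replicon the two flanks are concatenated the same way
  arc_to_genome <- function(u) wrap1(ter$end + u, L)
  # read starts in arc coordinates (reads inside ter are excluded)
  in_ter <- position_in_interval(mappings$start, ter, rep)
  arc_start <- wrap1(mappings$start[!in_ter] - ter$end, L)
  arc_sorted <- sort(arc_start)

  base_len <- floor(L_out / n_segments)
  seg_len <- rep.int(base_len, n_segments)
  seg_len[n_segments] <- seg_len[n_segments] + (L_out - base_len * n_segments)
  if (any(seg_len < window_bp))
    abort("segment shorter than the null window",
          class = "terenrich_sampling_error")
  seg_off <- cumsum(c(0, seg_len[-n_segments]))

  u <- withr::with_seed(seed, {
    unlist(lapply(seq_len(n_segments), function(s) {
      lo <- seg_off[s] + 1
      hi <- seg_off[s] + seg_len[s] - window_bp + 1
      lo + floor(runif(samples_per_segment) * (hi - lo + 1))
    }))
  })
  counts <- findInterval(u + window_bp - 1, arc_sorted) -
    findInterval(u - 1, arc_sorted)
  samples <- tibble(segment = base::rep(seq_len(n_segments), each = samples_per_segment),
                    start = arc_to_genome(u), count = as.integer(counts))
  structure(
    list(window_bp = window_bp, n_segments = n_segments,
         samples_per_segment = samples_per_segment, samples = samples,
         mean = mean(counts), median = median(counts), std = sd(counts),
         seed = seed, replicon = rep),
    class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %d windows of %s bp (%d x %d)\n",
              nrow(x$samples), format(x$window_bp, big.mark = ","),
              x$n_segments, x$samples_per_segment))
  cat(sprintf("  mean %.1f, median %.1f, sd %.1f (seed %d)\n",
              x$mean, x$median, x$std, x$seed))
  invisible(x)
}

#' @export
tidy.null_distribution <- function(x, ...) x$samples

#' @export
glance.null_distribution <- function(x, ...) {
  tibble(window_bp = x$window_bp, n_windows = nrow(x$samples),
         mean = x$mean, median = x$median, std = x$std, seed = x$seed)
}

#' The enrichment kernel: rounded ratio of ter count to null median
#'
#' The pure arithmetic at the heart of the statistic, factored out so
#' published count pairs can be checked directly: the ratio of the
#' ter-window read count to the null median, rounded to the nearest
#' integer with halves away from zero. When the median is zero (ultra
#' sparse coverage outside ter) the convention is to report the ter count
#' itself.
#'
#' @param ter_reads Non-negative read count in the *ter* window.
#' @param median Non-negative null median.
#' @return A non-negative integer-valued enrichment.
#' @examples
#' enrichment_from_counts(11395, 1234) # 9
#' enrichment_from_counts(28376, 2051) # 14
#' enrichment_from_counts(92377, 0)    # 92377
#' @export
enrichment_from_counts <- function(ter_reads, median) {
  if (any(ter_reads < 0) || any(median < 0))
    abort("counts must be non-negative", class = "terenrich_domain_error")
  ifelse(median > 0, floor(ter_reads / median + 0.5), ter_reads)
}

#' Ter-region enrichment of a read-mapping set
#'
#' Counts the reads assigned to the replicon's *ter* window, samples the
#' random-window null with [sample_null()], and reports the enrichment as
#' the rounded ratio of the ter count to the null median
#' ([enrichment_from_counts()]). The full result is a pure function of
#' (mappings, replicon, window_bp, seed).
#'
#' @param mappings A [read_mappings()] tibble.
#' @param spec The [replicon_spec()] (defaults to the one attached to
#'   `mappings`); must define the ter window.
#' @param window_bp Null window width; defaults to the ter window length.
#' @param n_segments,samples_per_segment Passed to [sample_null()].
#' @param seed Integer seed for the null sampling.
#' @return An `enrichment_result`: list with `replicon`, `total_reads`,
#'   `ter_reads`, the `null` distribution and the integer `enrichment`.
#' @export
compute_enrichment <- function(mappings, spec = replicon_of(mappings),
                               window_bp = NULL, n_segments = 10,
                               samples_per_segment = 20, seed = 1L) {
  ter <- ter_interval(spec)
  if (is.null(window_bp)) window_bp <- interval_length(ter, spec)
  ter_reads <- count_reads_in(mappings, ter)
  null <- sample_null(mappings, ter, window_bp, n_segments,
                      samples_per_segment, seed)
  structure(
    list(replicon = spec, total_reads = nrow(mappings), ter_reads = ter_reads,
         null = null,
         enrichment = enrichment_from_counts(ter_reads, null$median)),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s\n", x$replicon$name))
  cat(sprintf("  total %s reads, ter %s; null median %.1f -> enrichment %s\n",
              format(x$total_reads, big.mark = ","),
              format(x$ter_reads, big.mark = ","), x$null$median,
              format(x$enrichment, big.mark = ",")))
  invisible(x)
}

#' @describeIn compute_enrichment One-row tibble in the published summary
#'   column order (replicon, ter bounds, total, ter, mean, median, std,
#'   enrichment).
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  tibble(replicon = x$replicon$accession,
         ter_start = as.integer(x$replicon$ter_start),
         ter_end = as.integer(x$replicon$ter_end),
         total = x$total_reads, ter = x$ter_reads,
         mean = x$null$mean, median = x$null$median, std = x$null$std,
         enrichment = x$enrichment)
}

#' @export
glance.enrichment_result <- function(x, ...) {
  dplyr::bind_cols(tidy(x),
                   tibble(window_bp = x$null$window_bp, seed = x$null$seed))
}

#' @export
autoplot.enrichment_result <- function(object, ...) {
  ggplot2::ggplot(object$null$samples, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$ter_reads, colour = "firebrick") +
    ggplot2::labs(x = "Reads per null window", y = "Windows",
                  title = sprintf("%s: ter count vs null (enrichment %s)",
                                  object$replicon$name,
                                  format(object$enrichment, big.mark = ","))) +
    ggplot2::theme_minimal()
}
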