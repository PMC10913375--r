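#' Per-nucleotide read depth along a replicon
#'
#' Each mapped base of each read contributes exactly one unit of depth, so
#' the depths sum to the total mapped bases. Reads wrapping the origin of
#' a circular replicon contribute on both sides of the origin.
#'
#' @param mappings A [read_mappings()] tibble.
#' @return A `coverage_track`: a list with the replicon and an integer
#'   `depth` vector of length `length_bp` (index i = position i).
#' @export
per_base_coverage <- function(mappings) {
  rep <- replicon_of(mappings)
  L <- rep$length_bp
  if (nrow(mappings) == 0) {
    depth <- integer(L)
  } else {
    wrap <- mappings$end < mappings$start
    starts <- c(mappings$start[!wrap], mappings$start[wrap], rep(1, sum(wrap)))
    ends <- c(mappings$end[!wrap], rep(L, sum(wrap)), mappings$end[wrap])
    cvg <- IRanges::coverage(IRanges::IRanges(start = starts, end = ends),
                             width = L)
    depth <- as.integer(cvg)
  }
  structure(list(replicon = rep, depth = depth), class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s bp on %s; mean depth %.3f, max %d\n",
              format(length(x$depth), big.mark = ","), x$replicon$name,
              mean(x$depth), max(x$depth)))
  invisible(x)
}

#' @export
as_tibble.coverage_track <- function(x, ...) {
  tibble(position = seq_along(x$depth), depth = x$depth)
}

#' @export
tidy.coverage_track <- function(x, ...) as_tibble(x)

#' Sliding-window mean coverage
#'
#' Summarizes a per-base coverage track as the mean depth in windows of
#' `window_bp` placed every `step_bp` bases. On circular replicons the
#' windows wrap through the origin; on linear replicons windows are
#' truncated at the ends and averaged over their actual width. Published
#' vesicle-coverage profiles use 8 kb analysis windows and 0.5 kb display
#' windows; `window_bp` is always explicit.
#'
#' @param track A [per_base_coverage()] result.
#' @param window_bp Window width in bp (must not exceed the replicon).
#' @param step_bp Distance between window centres (default 1, a true
#'   rolling mean).
#' @return A tibble of class `windowed_coverage` with columns `center`
#'   (1-based position) and `value` (mean depth), plus `window_bp` /
#'   `step_bp` attributes.
#' @export
sliding_windows <- function(track, window_bp, step_bp = 1) {
  stopifnot(inherits(track, "coverage_track"))
  rep <- track$replicon
  L <- length(track$depth)
  window_bp <- as.integer(window_bp); step_bp <- as.integer(step_bp)
  if (window_bp < 1 || window_bp > L)
    abort("window_bp must be in [1, length_bp]",
          class = "terenrich_window_error")
  stopifnot(step_bp >= 1)
  centers <- seq.int(1L, L, by = step_bp)
  lo <- centers - (window_bp - 1L) %/% 2L
  hi <- lo + window_bp - 1L
  if (rep$circular) {
    # pad one window round the origin so every wrapped window is contiguous
    pad <- window_bp
    x <- c(tail(track$depth, pad), track$depth, head(track$depth, pad))
    cs <- c(0, cumsum(x))
    vals <- (cs[hi + pad + 1] - cs[lo + pad]) / window_bp
  } else {
    cs <- c(0, cumsum(track$depth))
    lo2 <- pmax(lo, 1L); hi2 <- pmin(hi, L)
    vals <- (cs[hi2 + 1] - cs[lo2]) / (hi2 - lo2 + 1)
  }
  structure(tibble(center = centers, value = vals),
            replicon = rep, window_bp = window_bp, step_bp = step_bp,
            class = c("windowed_coverage", class(tibble())))
}

#' Count reads assigned to a region
#'
#' A read is assigned to the region by its start (5'-most mapped
#' coordinate on the forward genome axis), so every read is assigned to
#' exactly one position and region counts over any partition of the
#' replicon sum to the total read count — the property the ter-versus-rest
#' comparison relies on.
#'
#' @param mappings A [read_mappings()] tibble.
#' @param region A [genome_interval()].
#' @return Integer count of reads whose start lies in `region`.
#' @export
count_reads_in <- function(mappings, region) {
  rep <- replicon_of(mappings)
  if (region$start > rep$length_bp || region$end > rep$length_bp)
    abort("region outside replicon bounds", class = "terenrich_bounds_error")
  sum(position_in_interval(mappings$start, region, rep))
}

#' @rdname sliding_windows
#' @param x A `windowed_coverage` tibble (for `autoplot`).
#' @param ... Unused.
#' @export
autoplot.windowed_coverage <- function(x, ...) {
  rep <- attr(x, "replicon")
  p <- ggplot2::ggplot(x, ggplot2::aes(x = .data$center / 1e6, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Position (Mb)", y = "Mean depth",
                  title = rep$name,
                  subtitle = sprintf("%d bp windows", attr(x, "window_bp"))) +
    ggplot2::theme_minimal()
  if (!is.null(rep$dif_pos))
    p <- p + ggplot2::geom_vline(xintercept = rep$dif_pos / 1e6,
                                 linetype = "dashed", colour = "black")
  p
}

#' @export
autoplot.coverage_track <- function(object, ...) {
  autoplot(sliding_windows(object, window_bp = max(1L, length(object$depth) %/% 2000L),
                           step_bp = max(1L, length(object$depth) %/% 2000L)), ...)
}
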