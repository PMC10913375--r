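#' Build a set of mapped reads on one replicon
#'
#' The central data container: a tibble with one row per mapped read and
#' columns `start`, `end` (1-based inclusive) and `strand` (`"+"`/`"-"`),
#' carrying its [replicon_spec()] as an attribute. A read whose `end` is
#' smaller than its `start` wraps through the origin, which is only legal
#' on a circular replicon. Ends one past the reference (as written by
#' linear file formats for wrapping reads) are folded back automatically.
#'
#' @param reads A data frame with columns `start`, `end`, `strand`.
#' @param replicon A [replicon_spec()].
#' @return A tibble of class `read_mappings`.
#' @export
read_mappings <- function(reads, replicon) {
  stopifnot(inherits(replicon, "replicon_spec"))
  reads <- as_tibble(reads)
  stopifnot(all(c("start", "end", "strand") %in% names(reads)))
  reads$start <- as.double(reads$start)
  reads$end <- as.double(reads$end)
  reads$strand <- as.character(reads$strand)
  L <- replicon$length_bp
  if (nrow(reads) > 0) {
    if (any(reads$start < 1 | reads$start > L))
      abort("read start outside replicon bounds",
            class = "terenrich_bounds_error")
    over <- reads$end > L
    if (any(over)) {
      if (!replicon$circular)
        abort("read extends past the end of a non-circular replicon",
              class = "terenrich_bounds_error")
      reads$end[over] <- reads$end[over] - L
      if (any(reads$end > L))
        abort("read longer than the replicon", class = "terenrich_bounds_error")
    }
    if (any(reads$end < reads$start) && !replicon$circular)
      abort("wrapping read on a non-circular replicon",
            class = "terenrich_bounds_error")
    if (!all(reads$strand %in% c("+", "-")))
      abort("strand must be '+' or '-'", class = "terenrich_format_error")
  }
  structure(reads[c("start", "end", "strand")],
            replicon = replicon,
            class = c("read_mappings", class(tibble())))
}

#' @export
print.read_mappings <- function(x, ...) {
  rep <- attr(x, "replicon")
  cat(sprintf("<read_mappings> %s reads on %s (%s bp)\n",
              format(nrow(x), big.mark = ","), rep$name,
              format(rep$length_bp, big.mark = ",")))
  NextMethod()
}

#' Replicon attached to a result object
#' @param x A `read_mappings`, `coverage_track` or related object.
#' @return The [replicon_spec()].
#' @export
replicon_of <- function(x) attr(x, "replicon") %||% x$replicon

#' Number of reads in a mapping set
#' @param x A `read_mappings` tibble.
#' @return Integer count.
#' @export
n_reads <- function(x) nrow(x)

# read lengths in bp, honouring origin wrap
read_lengths <- function(x) {
  rep <- replicon_of(x)
  ifelse(x$end >= x$start, x$end - x$start + 1,
         rep$length_bp - x$start + 1 + x$end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
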