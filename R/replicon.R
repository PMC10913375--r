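#' Describe a replicon's coordinate frame
#'
#' A `replicon_spec` fixes the coordinate frame of one chromosome or
#' plasmid: its length, whether it is circular, the position of the *dif*
#' site, and the *ter* window used by the enrichment statistic. All
#' coordinates are 1-based and inclusive, matching the convention in which
#' *ter* bounds are usually published; conversion to 0-based half-open
#' happens only at file-format boundaries.
#'
#' The *ter* window may wrap through the origin, but only on a circular
#' replicon, and must be shorter than a tenth of the replicon so that ten
#' non-*ter* null segments exist. If `dif_pos` is given it must lie inside
#' the *ter* window (modulo wrap).
#'
#' @param name Free-text replicon name (e.g. strain and chromosome).
#' @param accession Sequence accession used to match alignment records
#'   (e.g. `"NZ_CP009273.1"`). Defaults to `name`.
#' @param length_bp Replicon length in bp (positive integer).
#' @param circular Is the replicon circular? Default `TRUE`.
#' @param ter_start,ter_end 1-based inclusive bounds of the *ter* window.
#' @param dif_pos 1-based position of the *dif* site, or `NULL`.
#' @param ori_pos 1-based position of the replication origin, or `NULL`.
#'
#' @return An object of class `replicon_spec`.
#' @examples
#' ecoli <- replicon_spec("E. coli BW25113", "NZ_CP009273.1",
#'   length_bp = 4631469, ter_start = 1582052, ter_end = 1588052,
#'   dif_pos = 1585052)
#' @export
replicon_spec <- function(name, accession = name, length_bp, circular = TRUE,
                          ter_start, ter_end, dif_pos = NULL, ori_pos = NULL) {
  length_bp <- as.double(length_bp)
  stopifnot(length(length_bp) == 1, length_bp >= 1, is.logical(circular))
  chk_pos <- function(p, lab) {
    if (!is.null(p)) {
      p <- as.double(p)
      if (length(p) != 1 || is.na(p) || p < 1 || p > length_bp)
        abort(sprintf("`%s` must lie in [1, %d]", lab, as.integer(length_bp)),
              class = "terenrich_bounds_error")
    }
    p
  }
  ter_start <- chk_pos(ter_start, "ter_start")
  ter_end <- chk_pos(ter_end, "ter_end")
  dif_pos <- chk_pos(dif_pos, "dif_pos")
  ori_pos <- chk_pos(ori_pos, "ori_pos")
  wraps <- ter_end < ter_start
  if (wraps && !circular)
    abort("ter window wraps the origin but the replicon is not circular",
          class = "terenrich_interval_error")
  ter_len <- if (wraps) length_bp - ter_start + 1 + ter_end else ter_end - ter_start + 1
  if (ter_len >= length_bp / 10)
    abort("ter window must span less than a tenth of the replicon",
          class = "terenrich_bounds_error")
  x <- structure(
    list(name = name, accession = accession, length_bp = length_bp,
         circular = circular, ter_start = ter_start, ter_end = ter_end,
         dif_pos = dif_pos, ori_pos = ori_pos),
    class = "replicon_spec")
  if (!is.null(dif_pos) &&
      !position_in_interval(dif_pos, ter_interval(x), x))
    abort("dif_pos must lie inside the ter window",
          class = "terenrich_bounds_error")
  x
}

#' @export
print.replicon_spec <- function(x, ...) {
  cat(sprintf("<replicon_spec> %s (%s)\n", x$name, x$accession))
  cat(sprintf("  length %s bp, %s\n", format(x$length_bp, big.mark = ","),
              if (x$circular) "circular" else "linear"))
  cat(sprintf("  ter [%d, %d]%s\n", as.integer(x$ter_start),
              as.integer(x$ter_end),
              if (is.null(x$dif_pos)) "" else sprintf(", dif at %d", as.integer(x$dif_pos))))
  invisible(x)
}

#' The ter window of a replicon as an interval
#' @param replicon A [replicon_spec()].
#' @return A [genome_interval()].
#' @export
ter_interval <- function(replicon) {
  genome_interval(replicon$ter_start, replicon$ter_end,
                  wraps = replicon$ter_end < replicon$ter_start)
}

# wrap an arbitrary (possibly out-of-range) position back onto [1, L]
wrap1 <- function(pos, length_bp) ((pos - 1) %% length_bp) + 1

#' A 1-based inclusive genomic interval
#'
#' Intervals are closed on both ends. `wraps = TRUE` marks an interval that
#' runs through the origin of a circular replicon (so `end < start`).
#'
#' @param start,end 1-based inclusive bounds.
#' @param wraps Does the interval pass through the origin?
#' @return An object of class `genome_interval`.
#' @examples
#' genome_interval(10, 19)
#' genome_interval(96, 5, wraps = TRUE) # 10 bp on a 100 bp circle
#' @export
genome_interval <- function(start, end, wraps = FALSE) {
  start <- as.double(start); end <- as.double(end)
  stopifnot(length(start) == 1, length(end) == 1, start >= 1, end >= 1)
  if (!wraps && end < start)
    abort("end < start in a non-wrapping interval",
          class = "terenrich_interval_error")
  structure(list(start = start, end = end, wraps = isTRUE(wraps)),
            class = "genome_interval")
}

#' @export
print.genome_interval <- function(x, ...) {
  cat(sprintf("<genome_interval> [%d, %d]%s\n", as.integer(x$start),
              as.integer(x$end), if (x$wraps) " (wraps origin)" else ""))
  invisible(x)
}

#' Number of bases covered by an interval
#'
#' @param iv A [genome_interval()].
#' @param replicon The [replicon_spec()] providing length and circularity.
#' @return Integer-valued width in bp.
#' @examples
#' circ <- replicon_spec("toy", length_bp = 100, ter_start = 1, ter_end = 5)
#' interval_length(genome_interval(96, 5, wraps = TRUE), circ) # 10
#' @export
interval_length <- function(iv, replicon) {
  stopifnot(inherits(iv, "genome_interval"), inherits(replicon, "replicon_spec"))
  if (iv$start > replicon$length_bp || iv$end > replicon$length_bp)
    abort("interval outside replicon bounds", class = "terenrich_bounds_error")
  if (iv$wraps) {
    if (!replicon$circular)
      abort("wrapping interval on a non-circular replicon",
            class = "terenrich_interval_error")
    replicon$length_bp - iv$start + 1 + iv$end
  } else {
    iv$end - iv$start + 1
  }
}

# vectorized membership of positions in an interval
position_in_interval <- function(pos, iv, replicon) {
  if (iv$wraps) {
    if (!replicon$circular)
      abort("wrapping interval on a non-circular replicon",
            class = "terenrich_interval_error")
    pos >= iv$start | pos <= iv$end
  } else {
    pos >= iv$start & pos <= iv$end
  }
}
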