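#' Published vesicle-DNA ter-region read counts
#'
#' The per-sample read-count summaries reported for DNase-protected
#' vesicle DNA across six species (total mapped reads, reads in the *ter*
#' window, and the mean/median/standard deviation of the 200-random-window
#' null), together with the published integer enrichment. Shipped as a
#' plain-text table; the `enrichment` column is reproduced exactly by
#' [enrichment_from_counts()] applied to `ter` and `median`.
#'
#' @return A tibble with columns `strain`, `replicon`, `ter_start`,
#'   `ter_end`, `total`, `ter`, `mean`, `median`, `std`, `enrichment`,
#'   `accession`.
#' @examples
#' counts <- published_ter_counts()
#' all(enrichment_from_counts(counts$ter, counts$median) == counts$enrichment)
#' @export
published_ter_counts <- function() {
  readr::read_tsv(system.file("extdata", "vesicle_ter_counts.tsv",
                              package = "terenrich"),
                  show_col_types = FALSE, progress = FALSE)
}
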