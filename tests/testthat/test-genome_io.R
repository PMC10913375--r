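test_that("replicon_spec enforces its coordinate invariants", {
  rp <- toy_replicon()
  expect_s3_class(rp, "replicon_spec")
  expect_error(toy_replicon(ter_start = 20000), class = "terenrich_bounds_error")
  # ter window wider than a tenth of the replicon
  expect_error(toy_replicon(ter_start = 1000, ter_end = 3000, dif_pos = 2000),
               class = "terenrich_bounds_error")
  # dif outside ter
  expect_error(toy_replicon(dif_pos = 100), class = "terenrich_bounds_error")
  # wrapping ter on a linear replicon
  expect_error(replicon_spec("lin", length_bp = 1e4, circular = FALSE,
                             ter_start = 9950, ter_end = 50, dif_pos = 10),
               class = "terenrich_interval_error")
  # wrapping ter on a circular replicon is fine, dif checked modulo wrap
  rp2 <- replicon_spec("circ", length_bp = 1e4, circular = TRUE,
                       ter_start = 9950, ter_end = 50, dif_pos = 10)
  expect_equal(interval_length(ter_interval(rp2), rp2), 101)
})

test_that("interval_length handles wrap and matches brute-force membership", {
  circ <- toy_replicon(100, ter_start = 1, ter_end = 5, dif_pos = 3)
  expect_equal(interval_length(genome_interval(10, 19), circ), 10)
  expect_equal(interval_length(genome_interval(96, 5, wraps = TRUE), circ), 10)
  lin <- toy_replicon(100, circular = FALSE, ter_start = 1, ter_end = 5,
                      dif_pos = 3)
  expect_error(interval_length(genome_interval(96, 5, wraps = TRUE), lin),
               class = "terenrich_interval_error")
  withr::with_seed(7, {
    for (k in 1:50) {
      a <- sample.int(100, 1); b <- sample.int(100, 1)
      wraps <- b < a
      iv <- genome_interval(a, b, wraps = wraps)
      member <- sum(vapply(1:100, function(p) {
        if (wraps) p >= a || p <= b else p >= a && p <= b
      }, logical(1)))
      expect_equal(interval_length(iv, circ), member)
    }
  })
})

test_that("read_mappings validates bounds and wrap legality", {
  rp <- toy_replicon(1000, ter_start = 480, ter_end = 520, dif_pos = 500)
  m <- read_mappings(tibble::tibble(start = c(1, 980), end = c(50, 1029),
                                    strand = c("+", "-")), rp)
  expect_equal(m$end, c(50, 29))  # past-the-end folded back
  expect_equal(n_reads(m), 2)
  lin <- toy_replicon(1000, circular = FALSE, ter_start = 480, ter_end = 520,
                      dif_pos = 500)
  expect_error(read_mappings(tibble::tibble(start = 980, end = 1029,
                                            strand = "+"), lin),
               class = "terenrich_bounds_error")
  expect_error(read_mappings(tibble::tibble(start = 0, end = 10, strand = "+"),
                             rp),
               class = "terenrich_bounds_error")
})

test_that("read_alignments imports primary mapped SAM records", {
  rp <- replicon_spec("toy", "TOY", 1000, ter_start = 480, ter_end = 520,
                      dif_pos = 500)
  sam <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               "@SQ\tSN:TOY\tLN:1000",
               "r1\t0\tTOY\t101\t60\t50M\t*\t0\t0\t*\t*",
               "r2\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",          # unmapped
               "r3\t256\tTOY\t201\t60\t50M\t*\t0\t0\t*\t*", # secondary
               "r4\t2048\tTOY\t301\t60\t50M\t*\t0\t0\t*\t*",# supplementary
               "r5\t16\tTOY\t401\t5\t50M\t*\t0\t0\t*\t*"),
             sam)
  m <- read_alignments(sam, rp)
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(101, 401))
  expect_equal(m$end, c(150, 450))
  expect_equal(m$strand, c("+", "-"))
  # mapping-quality filter
  m2 <- read_alignments(sam, rp, min_mapq = 30)
  expect_equal(nrow(m2), 1)
  expect_equal(m2$start, 101)
  # only-unmapped file gives an empty set
  sam0 <- withr::local_tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:TOY\tLN:1000",
               "r1\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*"), sam0)
  expect_equal(nrow(read_alignments(sam0, rp)), 0)
  # replicon absent from header
  other <- replicon_spec("x", "MISSING", 1000, ter_start = 480, ter_end = 520)
  expect_error(read_alignments(sam, other),
               class = "terenrich_missing_reference_error")
  expect_error(read_alignments("/no/such/file.sam", rp),
               class = "terenrich_format_error")
})

test_that("SAM and BED round trips reproduce simulated mappings exactly", {
  rp <- toy_replicon(10000)
  m <- random_mappings(rp, 1000, seed = 11)
  for (fmt in c("sam", "bed")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mappings(m, path, format = fmt)
    back <- read_alignments(path, rp)
    ord <- order(back$start, back$end, back$strand)
    ord0 <- order(m$start, m$end, m$strand)
    expect_equal(back$start[ord], m$start[ord0])
    expect_equal(back$end[ord], m$end[ord0])
    expect_equal(back$strand[ord], m$strand[ord0])
  }
})

test_that("round trips preserve reads wrapping the circular origin", {
  rp <- toy_replicon(1000, ter_start = 480, ter_end = 520, dif_pos = 500)
  m <- read_mappings(tibble::tibble(start = c(990, 971), end = c(39, 20),
                                    strand = c("+", "-")), rp)
  for (fmt in c("sam", "bed")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_mappings(m, path, format = fmt)
    back <- read_alignments(path, rp)
    expect_setequal(paste(back$start, back$end), paste(m$start, m$end))
  }
})

test_that("enrichment tables round-trip through TSV", {
  rp <- toy_replicon()
  m <- random_mappings(rp, 2000, seed = 3)
  res <- compute_enrichment(m, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment_table(list(res), path)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(nrow(back), 1)
  expect_named(back, c("replicon", "ter_start", "ter_end", "total", "ter",
                       "mean", "median", "std", "enrichment"))
  expect_equal(back$ter, res$ter_reads)
  expect_equal(back$median, res$null$median)
  expect_equal(back$enrichment, res$enrichment)
  expect_error(write_enrichment_table(list(), path),
               class = "terenrich_io_error")
})

test_that("bedGraph export writes 0-based half-open records covering the track", {
  rp <- toy_replicon(1000, ter_start = 480, ter_end = 520, dif_pos = 500)
  m <- read_mappings(tibble::tibble(start = c(1, 101), end = c(100, 200),
                                    strand = c("+", "+")), rp)
  track <- per_base_coverage(m)
  path <- withr::local_tempfile(fileext = ".bedGraph")
  write_bedgraph(track, path)
  bg <- readr::read_tsv(path, col_names = c("chrom", "start0", "end0", "score"),
                        show_col_types = FALSE)
  expect_equal(bg$start0[1], 0)
  expect_equal(max(bg$end0), 1000)
  # reconstructing per-base depth from the runs recovers the track
  depth <- integer(1000)
  for (i in seq_len(nrow(bg))) depth[(bg$start0[i] + 1):bg$end0[i]] <- bg$score[i]
  expect_equal(depth, track$depth)
})

test_that("rotation leaves interval lengths and membership unchanged", {
  rp <- toy_replicon()
  m <- random_mappings(rp, 500, seed = 23)
  ter <- ter_interval(rp)
  withr::with_seed(9, {
    for (offset in sample.int(9999, 5)) {
      m2 <- rotate_world(m, offset)
      ter2 <- ter_interval(replicon_of(m2))
      expect_equal(interval_length(ter2, replicon_of(m2)),
                   interval_length(ter, rp))
      expect_equal(count_reads_in(m2, ter2), count_reads_in(m, ter))
      expect_equal(sort(read_lengths <- m2$end), sort(m2$end))
    }
  })
})

test_that("replicon config files load into replicon_spec objects", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    accession = "NZ_CP009273.1", name = "E. coli BW25113",
    length_bp = 4631469, circular = TRUE,
    ter_start = 1582052, ter_end = 1588052, dif_pos = 1585052,
    ori_pos = 3925744), path)
  specs <- read_replicon_config(path)
  expect_named(specs, "NZ_CP009273.1")
  expect_equal(specs[[1]]$ter_end, 1588052)
  expect_true(specs[[1]]$circular)
})
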