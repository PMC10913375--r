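make_matrix <- function(counts, groups = NULL, window_bp = 500) {
  # wrap a bare count matrix in the container via a synthetic region
  rp <- toy_replicon(1e6, ter_start = 497000, ter_end = 503000, dif_pos = 5e5)
  n <- nrow(counts)
  starts <- seq(1, by = window_bp, length.out = n)
  structure(list(windows = tibble::tibble(start = starts,
                                          end = starts + window_bp - 1),
                 counts = counts,
                 sample_ids = colnames(counts), group = groups, replicon = rp,
                 region = genome_interval(1, starts[n] + window_bp - 1)),
            class = "coverage_count_matrix")
}

test_that("build_count_matrix tiles the region and recounts exactly", {
  rp <- toy_replicon(1e4, ter_start = 4800, ter_end = 5199, dif_pos = 5000)
  reads <- read_mappings(tibble::tibble(start = c(1400, 1450, 1499),
                                        end = c(1449, 1499, 1548),
                                        strand = base::rep("+", 3)), rp)
  cm <- build_count_matrix(list(a = reads), genome_interval(1001, 1900),
                           window_bp = 300)
  expect_equal(dim(cm$counts), c(3, 1))
  expect_equal(as.vector(cm$counts), c(0, 3, 0))
  expect_equal(cm$windows$start, c(1001, 1301, 1601))

  # conservation: column sums equal reads assigned within the region
  m1 <- random_mappings(rp, 2000, seed = 8)
  m2 <- random_mappings(rp, 1500, seed = 9)
  reg <- genome_interval(2001, 8000)
  cm2 <- build_count_matrix(list(s1 = m1, s2 = m2), reg, window_bp = 500)
  expect_equal(unname(colSums(cm2$counts)),
               c(count_reads_in(m1, reg), count_reads_in(m2, reg)))

  # direct per-window recount oracle
  for (j in seq_len(nrow(cm2$windows))) {
    w <- genome_interval(cm2$windows$start[j], cm2$windows$end[j])
    expect_equal(cm2$counts[j, "s1"], c(s1 = count_reads_in(m1, w)))
    expect_equal(cm2$counts[j, "s2"], c(s2 = count_reads_in(m2, w)))
  }

  other <- random_mappings(toy_replicon(1e4, ter_start = 100, ter_end = 400,
                                        dif_pos = 200), 100, seed = 1)
  attr(other, "replicon")$accession <- "OTHER"
  expect_error(build_count_matrix(list(m1, other), reg),
               class = "terenrich_incompatible_samples_error")
})

test_that("TMM factors: identical columns, pure scaling, and invariances", {
  withr::with_seed(21, {
    base_counts <- matrix(rpois(600, lambda = 50), ncol = 2,
                          dimnames = list(NULL, c("a", "b")))
    base_counts[, 2] <- base_counts[, 1]
    cm <- make_matrix(base_counts)
    expect_equal(unname(tmm_factors(cm)), c(1, 1), tolerance = 1e-12)

    # pure depth difference: normalized means agree
    sc <- base_counts
    sc[, 2] <- base_counts[, 1] * 2L
    cms <- make_matrix(sc)
    f <- tmm_factors(cms)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-9)
    lib <- colSums(sc)
    norm <- sweep(sc, 2, lib * f, "/")
    expect_equal(norm[, 1], norm[, 2], tolerance = 1e-6)

    # multiplying one sample by a constant: with an unchanged composition
    # the sample's normalized counts are unchanged exactly (M values are
    # library-size scaled, so scaling is absorbed into lib * factor)
    big <- matrix(rpois(1500, lambda = 80), ncol = 3,
                  dimnames = list(NULL, c("a", "b", "c")))
    big[, 2] <- big[, 1]  # b is a pure-depth copy of a
    big2 <- big
    big2[, 2] <- big2[, 2] * 7L
    f0r <- tmm_factors(make_matrix(big), ref_sample = "a")
    f1 <- tmm_factors(make_matrix(big2), ref_sample = "a")
    n0 <- big[, 2] / (sum(big[, 2]) * f0r["b"])
    n1 <- big2[, 2] / (sum(big2[, 2]) * f1["b"])
    expect_equal(n1, n0, tolerance = 1e-6)
    # with differing compositions the precision weights shift slightly
    # under scaling, so invariance is only approximate (edgeR matches)
    big3 <- matrix(rpois(1500, lambda = 80), ncol = 3,
                   dimnames = list(NULL, c("a", "b", "c")))
    big4 <- big3; big4[, 2] <- big4[, 2] * 7L
    fa <- tmm_factors(make_matrix(big3), ref_sample = "a")
    fb <- tmm_factors(make_matrix(big4), ref_sample = "a")
    expect_equal(unname(fb / fa), base::rep(1, 3), tolerance = 1e-3)
  })
})

test_that("TMM trimming absorbs a 4-fold perturbation of 5% of windows", {
  withr::with_seed(33, {
    counts <- matrix(rpois(900, lambda = 100), ncol = 3,
                     dimnames = list(NULL, c("a", "b", "c")))
    f0 <- tmm_factors(make_matrix(counts), ref_sample = "a")
    pert <- counts
    hit <- sample.int(300, 15)
    pert[hit, 2] <- pert[hit, 2] * 4L
    f1 <- tmm_factors(make_matrix(pert), ref_sample = "a")
    # the perturbation inflates sample b's library; the factor must absorb
    # it so the effective-library ratio b/a (lib x factor, which is what
    # normalization divides by and is free of the geometric-mean constant)
    # stays within 2% of the unperturbed fit
    lib0 <- colSums(counts); lib1 <- colSums(pert)
    rel0 <- (lib0[2] * f0[2]) / (lib0[1] * f0[1])
    rel1 <- (lib1[2] * f1[2]) / (lib1[1] * f1[1])
    expect_equal(unname(rel1 / rel0), 1, tolerance = 0.02)
    # the untrimmed mean-of-M oracle, by contrast, is dragged by the outliers
    untrimmed <- 2^mean(log2((pert[, 2] / lib1[2]) / (pert[, 1] / lib1[1])))
    rel_untrimmed <- (lib1[2] * untrimmed) / lib1[1]
    expect_gt(abs(log2(rel_untrimmed / rel0)), abs(log2(rel1 / rel0)))
  })
})

test_that("TMM factors agree with the independent edgeR implementation", {
  skip_if_not_installed("edgeR")
  withr::with_seed(44, {
    counts <- matrix(rpois(2000, lambda = exp(runif(2000, 2, 6))), ncol = 4,
                     dimnames = list(NULL, paste0("s", 1:4)))
    counts[, 3] <- rpois(500, lambda = 300)
    ours <- tmm_factors(make_matrix(counts))
    theirs <- edgeR::calcNormFactors(counts, method = "TMM")
    expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
  })
})

test_that("single shared window reduces TMM to the library-size-corrected ratio", {
  counts <- matrix(c(200, 400), nrow = 1, dimnames = list(NULL, c("a", "b")))
  cm <- make_matrix(counts)
  f <- tmm_factors(cm)
  # with one window, count/lib = 1 for both samples -> M = 0 -> factors 1
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
})

test_that("log2 fold-change: identity, doubling, and exact antisymmetry", {
  withr::with_seed(52, {
    counts <- matrix(rpois(1200, lambda = 60), ncol = 4,
                     dimnames = list(NULL, c("w1", "w2", "m1", "m2")))
    counts[, 3] <- counts[, 1]; counts[, 4] <- counts[, 2]
    cm <- make_matrix(counts, groups = c("WT", "WT", "MUT", "MUT"))
    fc <- log2_fold_change(cm, group_a = "WT", group_b = "MUT")
    expect_equal(fc$log2fc, base::rep(0, nrow(fc)))

    # doubled counts with forced unit factors and equal library sizes
    # give log2fc = 1 everywhere (up to the pseudocount)
    dbl <- cbind(a = counts[, 1], b = counts[, 1] * 2L)
    cmd <- make_matrix(dbl, groups = c("A", "B"))
    f1 <- stats::setNames(c(1, 1), c("a", "b"))
    fcd <- log2_fold_change(cmd, factors = f1, group_a = "A", group_b = "B",
                            pseudocount = 0, lib_sizes = c(a = 1e4, b = 1e4))
    expect_equal(fcd$log2fc, base::rep(1, nrow(fcd)))

    fab <- log2_fold_change(cm, group_a = "WT", group_b = "MUT")
    fba <- log2_fold_change(cm, group_a = "MUT", group_b = "WT")
    expect_identical(fab$log2fc, -fba$log2fc)

    expect_error(log2_fold_change(cm, group_a = "WT", group_b = "nope"),
                 class = "terenrich_domain_error")
  })
})
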