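# Windowed density, enrichment ratio, centromere calling and summaries.

make_track <- function(values, lens = NULL, window = 100000L,
                       label = "chip", total = 1000L) {
  # build a density_track by hand for rule-level tests
  if (is.null(lens)) lens <- c(chr1 = window * length(values))
  starts <- seq(0L, by = window, length.out = length(values))
  structure(data.frame(chrom = "chr1", start = starts,
                       end = pmin(starts + window, lens[[1]]),
                       count = as.integer(round(values * total / 1e4)),
                       value = values, stringsAsFactors = FALSE),
            class = c("density_track", "data.frame"),
            window_size = window, label = label, total_count = total)
}

test_that("window density normalises to reads-per-million / 100", {
  lens <- c(chr1 = 100000L)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = sample(1:99000, 100, replace = TRUE), width = 100))
  fs <- fragment_set(gr, "chip", lens)
  d <- compute_window_density(fs, lens, window_size = 100000)
  expect_equal(nrow(d), 1L)
  expect_equal(d$value, 10000)   # (100/100) * 1e6 / 100
  expect_error(compute_window_density(
    fragment_set(GenomicRanges::GRanges(character(0), IRanges::IRanges()),
                 "chip"), lens), "empty")
})

test_that("density is invariant to library size and sums correctly", {
  set.seed(401)
  lens <- c(chr1 = 1000000L)
  mk <- function(n) {
    st <- sample(1:999900, n, replace = TRUE)
    fragment_set(GenomicRanges::GRanges("chr1",
                                        IRanges::IRanges(st, width = 100)),
                 "input", lens)
  }
  f1 <- mk(10000)
  d1 <- compute_window_density(f1, lens, 100000)
  # doubling all fragments leaves values unchanged
  gr2 <- c(f1$fragments, f1$fragments)
  d2 <- compute_window_density(fragment_set(gr2, "input", lens), lens,
                               100000)
  expect_equal(d1$value, d2$value)
  # per-chromosome window values sum to 1e4 x (fraction on chromosome)
  expect_equal(sum(d1$value), 1e4)
  # uniform fragments: each of 10 windows within multinomial bounds
  expval <- 1000
  sdv <- sqrt(10000 * 0.1 * 0.9) / 10000 * 1e4
  expect_true(all(abs(d1$value - expval) < 3.5 * sdv))
})

test_that("enrichment ratio follows the pseudocount arithmetic", {
  chip <- make_track(c(200, 100))
  input <- make_track(c(100, 100), label = "input")
  r0 <- enrichment_ratio(chip, input, pseudocount = 0)
  expect_equal(r0$ratio, c(2, 1))
  expect_equal(r0$log2_ratio, c(1, 0))
  # chip == input everywhere -> ratio 1 (any pseudocount)
  r1 <- enrichment_ratio(input, input, pseudocount = 1)
  expect_equal(r1$ratio, rep(1, 2))
  # mismatched windows rejected
  bad <- make_track(c(1, 2, 3))
  expect_error(enrichment_ratio(chip, bad), "mismatch")
})

test_that("centromere calling applies run/gap/length rules", {
  mk_ratio <- function(log2s) {
    n <- length(log2s)
    structure(data.frame(chrom = "chr1",
                         start = seq(0L, by = 100000L, length.out = n),
                         end = seq(100000L, by = 100000L, length.out = n),
                         chip = 2^log2s, input = rep(1, n),
                         ratio = 2^log2s, log2_ratio = log2s,
                         zero_input = FALSE, stringsAsFactors = FALSE),
              class = c("ratio_track", "data.frame"),
              window_size = 100000L, pseudocount = 1)
  }
  calls <- call_centromeres(mk_ratio(c(0, 0, 2, 2, 2, 0, 0)),
                            min_log2 = 1, min_windows = 3, merge_gap = 0)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$start, 200000L)
  expect_equal(calls$end, 500000L)
  expect_equal(calls$size_mb, 0.3)
  expect_true(calls$primary)

  expect_equal(nrow(call_centromeres(mk_ratio(rep(0, 7)))), 0L)

  # merge_gap bridges one low window
  calls2 <- call_centromeres(mk_ratio(c(0, 2, 2, 0, 2, 2, 0)),
                             min_log2 = 1, min_windows = 3, merge_gap = 1)
  expect_equal(nrow(calls2), 1L)
  expect_equal(calls2$n_windows, 5L)
})

test_that("simulated centromeres are recovered within one window", {
  lens <- c(chr1 = 10000000L)
  truth <- interval_truth(lens, c(chr1 = 4500001L), c(chr1 = 5500000L))
  fr <- simulate_fragments(lens, truth, n_input = 100000, n_chip = 100000,
                           chip_centromere_fraction = 0.7, seed = 402)
  ratio <- enrichment_ratio(
    compute_window_density(fr$chip, lens, 100000),
    compute_window_density(fr$input, lens, 100000))
  # separation property: centromere windows clear the arm windows
  cen_win <- ratio$start >= 4500000 & ratio$end <= 5500000
  expect_gt(mean(ratio$log2_ratio[cen_win]) -
              mean(ratio$log2_ratio[!cen_win]), 1)
  calls <- call_centromeres(ratio)
  expect_equal(nrow(calls), 1L)
  expect_lte(abs(calls$start - 4500000), 100000)
  expect_lte(abs(calls$end - 5500000), 100000)
})

test_that("centromere summary reproduces simple arithmetic and an oracle", {
  s <- centromere_summary(c(1.0), 100)
  expect_equal(s$total_mb, 1.0)
  expect_equal(s$percent_2dp, 1.00)
  expect_equal(s$mean_mb_1dp, 1.0)
  expect_error(centromere_summary(numeric(0), 100), "no centromere")

  set.seed(403)
  sizes <- round(runif(20, 0.2, 2), 3)
  s2 <- centromere_summary(sizes, 700)
  # independent re-summation oracle
  tot <- 0; for (x in sizes) tot <- tot + x
  expect_equal(s2$total_mb, tot)
  expect_equal(s2$min_mb, sort(sizes)[1])
  expect_equal(s2$max_mb, sort(sizes)[20])
  expect_equal(s2$percent_of_genome, 100 * tot / 700)
})

test_that("feature enrichment ranks classes by construction", {
  lens <- c(chr1 = 1000000L)
  truth <- interval_truth(lens, c(chr1 = 400001L), c(chr1 = 500000L))
  fr <- simulate_fragments(lens, truth, n_input = 20000, n_chip = 20000,
                           chip_centromere_fraction = 0.8, seed = 404)
  feats <- list(
    satellite = GenomicRanges::GRanges("chr1",
                                       IRanges::IRanges(400001, 500000)),
    arm_ltr = GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(c(100001, 700001),
                                                      width = 5000)))
  fe <- feature_enrichment(fr$chip, fr$input, feats)
  expect_gt(fe$log2_ratio[fe$class == "satellite"],
            fe$log2_ratio[fe$class == "arm_ltr"])

  # whole-genome class with chip == input -> log2 ratio 0
  whole <- list(all = GenomicRanges::GRanges("chr1",
                                             IRanges::IRanges(1, 1000000)))
  fe2 <- feature_enrichment(fr$input, fr$input, whole)
  expect_equal(fe2$log2_ratio, 0)

  # duplicated features leave the class ratio unchanged
  dup <- list(satellite = c(feats$satellite, feats$satellite))
  fe3 <- feature_enrichment(fr$chip, fr$input, dup)
  expect_equal(fe3$log2_ratio,
               fe$log2_ratio[fe$class == "satellite"])

  # empty class flagged undefined, not zero
  fe4 <- feature_enrichment(fr$chip, fr$input,
                            list(none = GenomicRanges::GRanges()))
  expect_false(fe4$defined)
  expect_true(is.na(fe4$log2_ratio))
})
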