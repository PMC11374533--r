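# Generator: construction guarantees, determinism, fragment statistics.

test_that("built chromosome contains the planted structures exactly", {
  mono <- random_monomer(356, seed = 201)
  spec <- chromosome_spec("chr1", 60000,
                          telomere_copies_5p = 10,
                          centromere_start = 20001,
                          centromere_end = 20000 + 356 * 50,
                          satellite_monomer = mono,
                          satellite_mutation_rate = 0)
  b <- build_chromosome(spec, seed = 1)
  expect_equal(substr(b$sequence, 1, 70), strrep("CCCTAAA", 10))
  expect_equal(b$truth$satellite$period, 356L)
  expect_equal(b$truth$satellite$copies, 50L)
  # zero mutation: the array is an exact tandem of the monomer
  expect_equal(substr(b$sequence, 20001, 20000 + 356), mono)
  expect_equal(substr(b$sequence, 20001 + 356 * 49, 20000 + 356 * 50), mono)
})

test_that("two seeds give identical structure but different background", {
  mono <- random_monomer(100, seed = 202)
  spec <- chromosome_spec("chr1", 30000,
                          centromere_start = 10001, centromere_end = 15000,
                          satellite_monomer = mono,
                          satellite_mutation_rate = 0)
  b1 <- build_chromosome(spec, seed = 1)
  b2 <- build_chromosome(spec, seed = 2)
  expect_equal(b1$truth$satellite, b2$truth$satellite)
  expect_equal(substr(b1$sequence, 10001, 15000),
               substr(b2$sequence, 10001, 15000))
  expect_false(substr(b1$sequence, 1, 5000) == substr(b2$sequence, 1, 5000))
  # same seed: identical bytes
  b1b <- build_chromosome(spec, seed = 1)
  expect_identical(b1$sequence, b1b$sequence)
})

test_that("zero-mutation LTR insertion emits two identical LTR copies", {
  spec <- chromosome_spec("chr1", 20000, ltr_insertions = list(
    ltr_insertion_spec(5000, 300, 2000, per_ltr_mutation_load = 0)))
  b <- build_chromosome(spec, seed = 3)
  tr <- b$truth$ltr_elements
  l5 <- substr(b$sequence, tr$ltr5_start, tr$ltr5_end)
  l3 <- substr(b$sequence, tr$ltr3_start, tr$ltr3_end)
  expect_identical(l5, l3)
  expect_equal(tr$true_K, 0)
})

test_that("invalid specs are rejected", {
  mono <- random_monomer(100, seed = 203)
  expect_error(chromosome_spec("c", 1000, centromere_start = 500,
                               centromere_end = 2000,
                               satellite_monomer = mono),
               "outside chromosome")
  expect_error(chromosome_spec("c", 1000, ltr_insertions = list(
    ltr_insertion_spec(900, 200, 500))), "exceeds chromosome")
  expect_error(chromosome_spec("c", 1000, satellite_mutation_rate = 0.5,
                               centromere_start = 100, centromere_end = 800,
                               satellite_monomer = mono),
               "satellite_mutation_rate")
})

test_that("fragment counts are exact and null ChIP matches input", {
  mono <- random_monomer(200, seed = 204)
  b <- array_genome(mono, 100, chrom_len = 3e5, seed = 5)
  fr <- simulate_fragments(b$genome, b$truth, n_input = 10000,
                           n_chip = 5000, chip_centromere_fraction = 0,
                           seed = 6)
  expect_equal(fr$input$total_count, 10000L)
  expect_equal(fr$chip$total_count, 5000L)
  # fraction 0: ChIP and input midpoints statistically indistinguishable
  ks <- suppressWarnings(stats::ks.test(
    fragment_midpoints(fr$chip), fragment_midpoints(fr$input)))
  expect_gt(ks$p.value, 0.01)
})

test_that("centromeric ChIP fraction concentrates midpoints in the array", {
  mono <- random_monomer(356, seed = 205)
  # array ~ 1% of a lengths-only genome
  lens <- c(chr1 = 3560000L)
  truth <- interval_truth(lens, c(chr1 = 2000001L),
                          c(chr1 = 2000000L + 35600L))
  fr <- simulate_fragments(lens, truth, n_input = 1000, n_chip = 10000,
                           chip_centromere_fraction = 0.8, seed = 7)
  mid <- fragment_midpoints(fr$chip)
  inside <- mean(mid >= 2000000 & mid < 2035600)
  expect_gte(inside, 0.70)   # >= 70% at three-sigma under Binomial(0.8+)
})

test_that("phased midpoints fall at planted offsets", {
  lens <- c(chr1 = 500000L)
  truth <- interval_truth(lens, c(chr1 = 200001L), c(chr1 = 271200L),
                          period = 356)
  fr <- simulate_fragments(lens, truth, n_input = 100, n_chip = 5000,
                           chip_centromere_fraction = 1,
                           phase_positions = c(100), phase_sd = 0.5,
                           seed = 8)
  phase <- (fragment_midpoints(fr$chip) - 200000L) %% 356L
  expect_gt(mean(abs(phase - 100) <= 2), 0.95)
})

test_that("fixture write/read round-trips and is deterministic", {
  mono <- random_monomer(120, seed = 206)
  b <- array_genome(mono, 40, chrom_len = 1e5, seed = 9)
  fr <- simulate_fragments(b$genome, b$truth, n_input = 500, n_chip = 500,
                           chip_centromere_fraction = 0.5, seed = 10)
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  write_fixture(b$genome, b$truth, fr, d1)
  back <- read_fixture(d1)
  expect_equal(as.character(back$genome), as.character(b$genome))
  expect_equal(back$truth$seed, b$truth$seed)
  expect_equal(back$truth$chromosomes$chr1$satellite$period,
               b$truth$chromosomes$chr1$satellite$period)
  expect_equal(back$fragments$chip$total_count, fr$chip$total_count)

  # regenerating from the same seed gives byte-identical files
  b2 <- array_genome(mono, 40, chrom_len = 1e5, seed = 9)
  fr2 <- simulate_fragments(b2$genome, b2$truth, n_input = 500,
                            n_chip = 500, chip_centromere_fraction = 0.5,
                            seed = 10)
  write_fixture(b2$genome, b2$truth, fr2, d2)
  for (f in c("genome.fa", "truth.json", "chip.bed", "input.bed")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }

  # empty fragment set still writes a valid (empty) BED
  empty_fs <- fragment_set(
    GenomicRanges::GRanges(character(0), IRanges::IRanges()), "chip")
  p <- tempfile(fileext = ".bed")
  write_fragments_bed(empty_fs, p)
  expect_equal(read_fragments_bed(p, b$genome, "chip")$total_count, 0L)
})

test_that("truth arrays satisfy period x copies ~ interval length", {
  for (s in 1:5) {
    mono <- random_monomer(sample(60:700, 1))
    b <- array_genome(mono, sample(10:40, 1), seed = s)
    sat <- b$truth$chromosomes$chr1$satellite
    len <- sat$end - sat$start + 1
    expect_lte(abs(len - sat$period * sat$copies), sat$period)
  }
})

test_that("elements sharing an ancestor are similar, others are not", {
  ins <- list(
    ltr_insertion_spec(1000, 300, 1500, 0.01, ancestor = "A"),
    ltr_insertion_spec(8000, 300, 1500, 0.01, ancestor = "A"),
    ltr_insertion_spec(15000, 300, 1500, 0.01))
  b <- build_chromosome(chromosome_spec("chr1", 30000,
                                        ltr_insertions = ins), seed = 11)
  tr <- b$truth$ltr_elements
  seqs <- substr(rep(b$sequence, 3), tr$start, tr$end)
  same <- mapply(function(a, b2) mean(strsplit(a, "")[[1]] ==
                                        strsplit(b2, "")[[1]]),
                 seqs[1], seqs[2])
  diff <- mapply(function(a, b2) mean(strsplit(a, "")[[1]] ==
                                        strsplit(b2, "")[[1]]),
                 seqs[1], seqs[3])
  expect_gt(same, 0.9)
  expect_lt(diff, 0.5)
})
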