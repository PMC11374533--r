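# Tandem-array discovery, consensus building, families, composition,
# dot plots.

test_that("exact tandem arrays are found with exact period and count", {
  set.seed(601)
  mono <- random_monomer(356)
  seq1 <- paste0(random_seq_str(20000), strrep(mono, 50),
                 random_seq_str(20000))
  arr <- find_tandem_arrays(seq1)
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$period, 356L)
  expect_equal(arr$copy_number, 50L)
  expect_equal(arr$consensus, canonical_rotation(mono))
  expect_gt(arr$mean_copy_identity, 0.999)
  # boundaries within a few bases (random flanks mimic the monomer at
  # 25% per base, so exact edges are not identifiable)
  expect_lte(abs(arr$start - 20001L), 12L)
  expect_lte(abs(arr$end - (20000L + 356L * 50L)), 12L)
})

test_that("mutated arrays are recovered within tolerance", {
  for (s in 1:3) {
    set.seed(610 + s)
    mono <- random_monomer(732)
    b <- array_genome(mono, 40, mutation_rate = 0.02, seed = 610 + s)
    arr <- find_tandem_arrays(b$genome[1])
    expect_equal(nrow(arr), 1L)
    expect_lte(abs(arr$period - 732L), 2L)
    expect_lte(abs(arr$copy_number - 40L), 1L)
    expect_equal(arr$consensus, canonical_rotation(mono))
  }
})

test_that("random sequence yields no arrays", {
  for (s in 1:5) {
    set.seed(620 + s)
    expect_equal(nrow(find_tandem_arrays(random_seq_str(100000))), 0L)
  }
})

test_that("majority consensus recovers the master and validates input", {
  set.seed(602)
  master <- random_monomer(200)
  copies <- vapply(1:50, function(i) mutate_str_oracle(master, 0.02),
                   character(1))
  expect_equal(build_consensus(copies), master)
  expect_equal(build_consensus(rep(master, 3)), master)
  expect_error(build_consensus(copies[1:2]), "at least 3")
  # unequal-length copies go through the star alignment
  copies2 <- c(master, master, paste0(substr(master, 1, 100),
                                      substr(master, 102, 200)))
  expect_equal(nchar(build_consensus(copies2)), 200L)
})

test_that("families merge rotations and split unrelated monomers", {
  set.seed(603)
  m356 <- random_monomer(356)
  m530 <- random_monomer(530)
  rot <- paste0(substr(m356, 101, 356), substr(m356, 1, 100))
  arrays <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 60000L, 1000L),
    end = c(1000L + 356L * 30L, 60000L + 356L * 20L, 1000L + 530L * 25L),
    period = c(356L, 356L, 530L),
    copy_number = c(30L, 20L, 25L),
    mean_copy_identity = c(0.99, 0.99, 0.99),
    consensus = c(canonical_rotation(m356), canonical_rotation(rot),
                  canonical_rotation(m530)),
    stringsAsFactors = FALSE)
  fam <- classify_families(arrays)
  expect_equal(nrow(fam$families), 2L)
  expect_setequal(fam$families$family, c("CentFs356", "CentFs530"))
  # the two 356 arrays (one a rotation) share a family
  expect_equal(fam$arrays$family[1], fam$arrays$family[2])
  # permutation invariance
  fam2 <- classify_families(arrays[c(3, 1, 2), ])
  expect_setequal(fam2$arrays$family, fam$arrays$family)
  expect_equal(fam2$families$total_span_mb, fam$families$total_span_mb)
})

test_that("centromere composition reports overlap fractions", {
  calls <- structure(data.frame(chrom = "chr1", start = 0L, end = 100000L,
                                size_mb = 0.1, n_windows = 1L,
                                mean_log2 = 2, primary = TRUE,
                                stringsAsFactors = FALSE),
                     class = c("centromere_calls", "data.frame"))
  arrays <- data.frame(chrom = "chr1", start = 1L, end = 50000L,
                       period = 356L, copy_number = 140L,
                       mean_copy_identity = 0.98, consensus = "x",
                       family = "CentFs356", stringsAsFactors = FALSE)
  comp <- centromere_composition(calls, arrays)
  expect_equal(comp$fraction, 0.5)
  expect_true(comp$dominant)
  # full coverage -> 1
  arrays$end <- 100000L
  expect_equal(centromere_composition(calls, arrays)$fraction, 1)
})

test_that("two interleaved families recover their span shares", {
  set.seed(604)
  mA <- random_monomer(356)
  mB <- random_monomer(530)
  # 60/40 split over a composite centromere
  blockA1 <- strrep(mA, 60)   # 21360
  blockB <- strrep(mB, 27)    # 14310
  blockA2 <- strrep(mA, 40)   # 14240
  seq1 <- paste0(random_seq_str(20000), blockA1, blockB, blockA2,
                 random_seq_str(20000))
  cen_len <- nchar(blockA1) + nchar(blockB) + nchar(blockA2)
  arr <- find_tandem_arrays(seq1)
  fam <- classify_families(arr)
  calls <- structure(data.frame(chrom = "chr", start = 20000L,
                                end = 20000L + cen_len, size_mb = cen_len / 1e6,
                                n_windows = 1L, mean_log2 = 2,
                                primary = TRUE, stringsAsFactors = FALSE),
                     class = c("centromere_calls", "data.frame"))
  comp <- centromere_composition(calls, fam$arrays)
  fracA <- sum(comp$fraction[grepl("356", comp$family)])
  fracB <- sum(comp$fraction[grepl("530", comp$family)])
  expect_lt(abs(fracA - (nchar(blockA1) + nchar(blockA2)) / cen_len), 0.05)
  expect_lt(abs(fracB - nchar(blockB) / cen_len), 0.05)
})

test_that("dot plots show diagonals, periodic off-diagonals and strands", {
  set.seed(605)
  s <- random_seq_str(1000)
  d <- dotplot_matrix(s, s, window = 100)
  diag_pts <- d[d$posA == d$posB & d$strand == "+", ]
  expect_equal(nrow(diag_pts), 10L)          # full main diagonal
  expect_equal(diag_pts$identity, rep(1, 10))

  # tandem array of period 200: off-diagonals at multiples of 200
  mono <- random_monomer(200)
  arr <- strrep(mono, 6)
  da <- dotplot_matrix(arr, arr, window = 100)
  fwd <- da[da$strand == "+", ]
  expect_true(all((fwd$posA - fwd$posB) %% 200 == 0))
  # brute-force oracle: every window pair at offset 200 matches
  n_win <- nchar(arr) %/% 100
  expected_pairs <- sum(outer(seq_len(n_win), seq_len(n_win),
                              function(i, j) (abs(i - j) * 100) %% 200 == 0))
  expect_equal(nrow(fwd), expected_pairs)

  # reverse complement: anti-diagonal matches on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  dr <- dotplot_matrix(s, rc, window = 100)
  mins <- dr[dr$strand == "-", ]
  expect_equal(nrow(mins), 10L)
  # A[posA..] matches revcomp(B[posB..]) with B = rc(A): posA + posB = 900
  expect_true(all(mins$posA + mins$posB == 900))
})
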