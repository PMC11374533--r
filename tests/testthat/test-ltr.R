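# LTR element detection, divergence, dating, classification, clades.

test_that("divergence arithmetic: identity, raw K and JC69", {
  set.seed(801)
  ltr <- random_monomer(500)
  d0 <- ltr_divergence(ltr, ltr)
  expect_equal(d0$identity, 1)
  expect_equal(d0$K, 0)
  expect_true(d0$reliable)

  # exactly 5 substitutions in 500 columns
  ch <- strsplit(ltr, "")[[1]]
  pos <- sample(500, 5)
  for (i in pos) ch[i] <- setdiff(BASES4, ch[i])[1]
  d5 <- ltr_divergence(ltr, paste0(ch, collapse = ""))
  expect_equal(d5$identity, 0.99)
  expect_equal(d5$K, 0.01)
  dj <- ltr_divergence(ltr, paste0(ch, collapse = ""), correction = "JC69")
  expect_equal(dj$K, -0.75 * log(1 - 4 * 0.01 / 3))
  # unrelated sequences flagged unreliable
  du <- ltr_divergence(ltr, random_monomer(500))
  expect_false(du$reliable)
})

test_that("insertion time is K/(2r) and behaves linearly", {
  expect_equal(insertion_time(0), 0)
  expect_equal(insertion_time(0.026, r = 1.3e-8), 1e6)
  expect_equal(insertion_time(0.026, dating_params(r = 1.3e-8)), 1e6)
  expect_error(insertion_time(-0.1), "non-negative")
  set.seed(802)
  K <- runif(20, 0, 0.2)
  r <- 10^runif(20, -9, -7)
  for (i in 1:20) {
    expect_equal(insertion_time(2 * K[i], r = r[i]),
                 2 * insertion_time(K[i], r = r[i]))
    expect_equal(insertion_time(K[i], r = 2 * r[i]),
                 insertion_time(K[i], r = r[i]) / 2)
  }
})

test_that("a clean LTR pair is detected with accurate boundaries", {
  spec <- chromosome_spec("chr1", 60000, ltr_insertions = list(
    ltr_insertion_spec(20000, 500, 4000, per_ltr_mutation_load = 0)))
  b <- build_chromosome(spec, seed = 803)
  el <- find_ltr_pairs(b$sequence, name = "chr1")
  expect_equal(nrow(el), 1L)
  tr <- b$truth$ltr_elements
  expect_lte(abs(el$start - tr$start), 10L)
  expect_lte(abs(el$end - tr$end), 10L)
  expect_lte(abs(el$ltr_length - 500L), 10L)
  expect_gt(el$pair_identity, 0.97)
})

test_that("a single unpaired LTR copy yields no element", {
  set.seed(804)
  seq1 <- paste0(random_seq_str(10000), random_monomer(500),
                 random_seq_str(10000))
  expect_equal(nrow(find_ltr_pairs(seq1)), 0L)
})

test_that("nested insertions are both reported and flagged", {
  set.seed(805)
  outer_ltr <- random_monomer(400)
  inner_ltr <- random_monomer(300)
  inner <- paste0(inner_ltr, random_seq_str(1500), inner_ltr)
  outer_internal <- paste0(random_seq_str(2000), inner,
                           random_seq_str(2000))
  element <- paste0(outer_ltr, outer_internal, outer_ltr)
  seq1 <- paste0(random_seq_str(8000), element, random_seq_str(8000))
  el <- find_ltr_pairs(seq1)
  expect_equal(nrow(el), 2L)
  expect_equal(sum(el$nested), 1L)
  inner_row <- el[el$nested, ]
  outer_row <- el[!el$nested, ]
  expect_gt(inner_row$start, outer_row$ltr5_end)
  expect_lt(inner_row$end, outer_row$ltr3_start)
})

test_that("divergence recovery follows the mutation clock", {
  set.seed(806)
  load <- 0.02
  ins <- lapply(seq(5000, 5000 + 99 * 6000, by = 6000), function(p)
    ltr_insertion_spec(p, 500, 1500, per_ltr_mutation_load = load))
  spec <- chromosome_spec("chr1", 650000, ltr_insertions = ins)
  b <- build_chromosome(spec, seed = 807)
  g <- Biostrings::DNAStringSet(c(chr1 = b$sequence))
  tr <- b$truth$ltr_elements
  el <- data.frame(chrom = "chr1", start = tr$start, end = tr$end,
                   ltr5_start = tr$ltr5_start, ltr5_end = tr$ltr5_end,
                   ltr3_start = tr$ltr3_start, ltr3_end = tr$ltr3_end)
  dated <- date_elements(el, g)
  # per-site difference prob: both copies mutated independently
  p_exp <- 2 * load * (1 - load) + load^2 * (2 / 3)
  sd_bin <- sqrt(p_exp * (1 - p_exp) / 500)
  expect_lt(abs(mean(dated$K) - p_exp), 3 * sd_bin / sqrt(100) * 10)
  expect_true(all(abs(dated$K - tr$true_K) < 1e-9))
  # median T within 10% of the clock prediction
  T_true <- median(tr$true_K) / (2 * 1.3e-8)
  expect_lt(abs(median(dated$T_years) - T_true) / T_true, 0.1)
})

test_that("centromere classification partitions by midpoint", {
  calls <- structure(data.frame(chrom = "chr1", start = 100000L,
                                end = 200000L, size_mb = 0.1,
                                n_windows = 1L, mean_log2 = 2,
                                primary = TRUE, stringsAsFactors = FALSE),
                     class = c("centromere_calls", "data.frame"))
  el <- data.frame(chrom = "chr1",
                   start = c(120000L, 300000L, 195001L),
                   end = c(130000L, 310000L, 215000L))
  cls <- classify_by_centromere(el, calls)
  # wholly inside; on the arm; straddling with midpoint outside
  expect_equal(cls$location_class,
               c("centromeric", "non_centromeric", "non_centromeric"))
  expect_equal(sum(table(cls$location_class)), nrow(el))
})

test_that("population comparison reports medians and detects ageing", {
  set.seed(808)
  # same distribution: no detectable difference
  el0 <- data.frame(
    ltr_identity = c(rnorm(80, 0.98, 0.005), rnorm(80, 0.98, 0.005)),
    location_class = rep(c("centromeric", "non_centromeric"), each = 80))
  s0 <- compare_populations(el0)
  expect_lt(abs(s0$medians[["centromeric"]] -
                  s0$medians[["non_centromeric"]]), 0.005)
  expect_gt(s0$wilcox$p_value, 1e-3)

  # centromeric elements aged 2x: lower identity, detected at n=100
  el1 <- data.frame(
    ltr_identity = c(1 - rbinom(100, 500, 0.04) / 500,
                     1 - rbinom(100, 500, 0.02) / 500),
    location_class = rep(c("centromeric", "non_centromeric"), each = 100))
  s1 <- compare_populations(el1)
  expect_lt(s1$medians[["centromeric"]], s1$medians[["non_centromeric"]])
  expect_lt(s1$wilcox$p_value, 0.01)

  # single element per class: medians are those identities
  el2 <- data.frame(ltr_identity = c(0.97, 0.99),
                    location_class = c("centromeric", "non_centromeric"))
  s2 <- compare_populations(el2)
  expect_equal(unname(s2$medians), c(0.97, 0.99))

  # absent class flagged
  s3 <- compare_populations(el2[1, ])
  expect_equal(s3$absent_classes, "non_centromeric")
  expect_null(s3$wilcox)
})

test_that("clade clustering recovers ancestries and is monotone", {
  set.seed(809)
  anc1 <- random_monomer(2000)
  anc2 <- random_monomer(2000)
  seqs <- c(vapply(1:4, function(i) mutate_str_oracle(anc1, 0.03),
                   character(1)),
            vapply(1:3, function(i) mutate_str_oracle(anc2, 0.03),
                   character(1)))
  cl <- cluster_clades(seqs, linkage_identity = 0.7)
  expect_equal(length(unique(cl)), 2L)
  expect_equal(length(unique(cl[1:4])), 1L)
  expect_equal(length(unique(cl[5:7])), 1L)
  # identical elements: one clade
  expect_equal(length(unique(cluster_clades(rep(anc1, 3)))), 1L)
  # loosening the linkage threshold never increases the clade count
  counts <- vapply(c(0.95, 0.8, 0.6, 0.4),
                   function(th) length(unique(cluster_clades(seqs, th))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(cluster_clades(seqs[1]), "at least 2")
})
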