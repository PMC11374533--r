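# Shared fixture builders (everything generated in code, no stored data).

BASES4 <- c("A", "C", "G", "T")

# random monomer free of the telomeric 7-mers (so telomere scans on
# synthetic chromosomes count only planted tracts)
random_monomer <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  repeat {
    m <- paste0(sample(BASES4, len, replace = TRUE), collapse = "")
    if (!grepl("CCCTAAA", m, fixed = TRUE) &&
        !grepl("TTTAGGG", m, fixed = TRUE)) {
      return(m)
    }
  }
}

random_seq_str <- function(len) {
  paste0(sample(BASES4, len, replace = TRUE), collapse = "")
}

# substitute each site with probability rate (test-local oracle,
# independent of the package's internal mutator)
mutate_str_oracle <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) ch[i] <- sample(setdiff(BASES4, ch[i]), 1L)
  paste0(ch, collapse = "")
}

# minimal single-chromosome genome with a centromeric array
array_genome <- function(monomer, n_copies, chrom_len = NULL,
                         mutation_rate = 0.02, seed = 1,
                         cen_start = NULL, ...) {
  L <- nchar(monomer)
  span <- L * n_copies
  if (is.null(chrom_len)) chrom_len <- span + 2e5
  if (is.null(cen_start)) cen_start <- (chrom_len - span) %/% 2 + 1
  spec <- chromosome_spec("chr1", chrom_len,
                          centromere_start = cen_start,
                          centromere_end = cen_start + span - 1,
                          satellite_monomer = monomer,
                          satellite_mutation_rate = mutation_rate, ...)
  build_genome(list(spec), seed = seed)
}

# lengths-only genome + hand-built truth for fragment simulation (no
# sequence needed when only interval arithmetic is exercised)
interval_truth <- function(chrom_lens, cen_start, cen_end, period = 356) {
  chroms <- lapply(names(chrom_lens), function(chr) {
    list(name = chr, length = chrom_lens[[chr]],
         satellite = list(start = cen_start[[chr]],
                          end = cen_end[[chr]],
                          period = period,
                          copies = (cen_end[[chr]] - cen_start[[chr]] + 1) %/%
                            period))
  })
  list(seed = NA, chromosomes = stats::setNames(chroms, names(chrom_lens)))
}
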