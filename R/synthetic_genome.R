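# Synthetic genomes with ground-truth annotation.
#
# The generator emulates the structures the downstream analyses assume:
# terminal telomeric tracts (CCCTAAA at the 5' end, TTTAGGG at the 3' end),
# a centromeric tandem-satellite array with per-copy substitution noise,
# and full-length LTR retrotransposons whose two LTRs carry independent
# substitution loads (the molecular clock used for insertion dating).
# Background sequence is i.i.d. with configurable GC; substitution-only
# mutation keeps period and divergence arithmetic exact for recovery tests.

TELOMERE_MOTIF_5P <- "CCCTAAA"
TELOMERE_MOTIF_3P <- "TTTAGGG"

#' Specify one LTR retrotransposon insertion
#'
#' A full-length element is `ltr_length + internal_length + ltr_length`
#' bases: two initially identical LTRs flanking an internal region. Each
#' LTR then receives independent substitutions at rate
#' `per_ltr_mutation_load` per site, emulating post-insertion divergence.
#'
#' @param position 1-based start of the element on the chromosome.
#' @param ltr_length Length of each LTR (>= 100 bases).
#' @param internal_length Length of the internal region.
#' @param per_ltr_mutation_load Expected per-site substitutions applied
#'   independently to each LTR copy.
#' @param ancestor Optional ancestor id: insertions sharing an id copy
#'   the same ancestral element (same LTR and internal sequence), so
#'   elements fall into clades; `NULL` draws an independent random
#'   element.
#' @param ancestral_divergence Per-site substitutions applied to this
#'   copy of the ancestral element before the two LTRs age
#'   independently (within-clade divergence).
#' @return A list of class `ltr_insertion_spec`.
#' @export
ltr_insertion_spec <- function(position, ltr_length, internal_length,
                               per_ltr_mutation_load = 0,
                               ancestor = NULL,
                               ancestral_divergence = 0.02) {
  .check_scalar(position, "position", lo = 1)
  .check_scalar(ltr_length, "ltr_length", lo = 100)
  .check_scalar(internal_length, "internal_length", lo = 0)
  .check_scalar(per_ltr_mutation_load, "per_ltr_mutation_load", 0, 0.75)
  .check_scalar(ancestral_divergence, "ancestral_divergence", 0, 0.5)
  structure(list(position = as.integer(position),
                 ltr_length = as.integer(ltr_length),
                 internal_length = as.integer(internal_length),
                 per_ltr_mutation_load = per_ltr_mutation_load,
                 ancestor = ancestor,
                 ancestral_divergence = ancestral_divergence),
            class = "ltr_insertion_spec")
}

#' Specify a synthetic chromosome
#'
#' @param name Chromosome name.
#' @param length Chromosome length in bases.
#' @param telomere_copies_5p,telomere_copies_3p Number of telomeric motif
#'   copies planted at each end.
#' @param centromere_start,centromere_end 1-based closed interval to fill
#'   with a tandem satellite array (both `NA` for no centromere).
#' @param satellite_monomer Monomer sequence of the planted satellite.
#' @param satellite_mutation_rate Per-site substitution probability applied
#'   independently to every monomer copy (0 to 0.2).
#' @param ltr_insertions List of [ltr_insertion_spec()] objects.
#' @param gc_background GC fraction of the background sequence.
#' @return A list of class `chromosome_spec`.
#' @export
chromosome_spec <- function(name, length,
                            telomere_copies_5p = 0L,
                            telomere_copies_3p = 0L,
                            centromere_start = NA,
                            centromere_end = NA,
                            satellite_monomer = NULL,
                            satellite_mutation_rate = 0.02,
                            ltr_insertions = list(),
                            gc_background = 0.36) {
  .check_scalar(length, "length", lo = 1)
  .check_scalar(satellite_mutation_rate, "satellite_mutation_rate", 0, 0.2)
  .check_scalar(gc_background, "gc_background", 0, 1)
  length <- as.integer(length)
  tel5 <- as.integer(telomere_copies_5p) * nchar(TELOMERE_MOTIF_5P)
  tel3 <- as.integer(telomere_copies_3p) * nchar(TELOMERE_MOTIF_3P)
  if (tel5 + tel3 > length) {
    stop("telomere tracts exceed chromosome length", call. = FALSE)
  }
  has_cen <- !is.na(centromere_start) && !is.na(centromere_end)
  if (has_cen) {
    if (is.null(satellite_monomer)) {
      stop("centromere interval given but no satellite_monomer", call. = FALSE)
    }
    if (centromere_start < 1 || centromere_end > length ||
        centromere_start >= centromere_end) {
      stop("centromere interval outside chromosome", call. = FALSE)
    }
    if (centromere_start <= tel5 || centromere_end > length - tel3) {
      stop("centromere overlaps a telomere tract", call. = FALSE)
    }
  }
  for (ins in ltr_insertions) {
    stopifnot(inherits(ins, "ltr_insertion_spec"))
    if (ins$position + 2L * ins$ltr_length + ins$internal_length - 1L > length) {
      stop("LTR insertion exceeds chromosome length", call. = FALSE)
    }
  }
  structure(list(
    name = name, length = length,
    telomere_copies_5p = as.integer(telomere_copies_5p),
    telomere_copies_3p = as.integer(telomere_copies_3p),
    centromere_start = if (has_cen) as.integer(centromere_start) else NA_integer_,
    centromere_end = if (has_cen) as.integer(centromere_end) else NA_integer_,
    satellite_monomer = if (has_cen) toupper(satellite_monomer) else NULL,
    satellite_mutation_rate = satellite_mutation_rate,
    ltr_insertions = ltr_insertions,
    gc_background = gc_background
  ), class = "chromosome_spec")
}

# Emit a mutated tandem array of n_full copies (+ a truncated partial copy
# so the array exactly fills `span` bases). Returns one string.
.satellite_array_seq <- function(monomer, span, rate) {
  m <- .chars(monomer)
  p <- length(m)
  n_full <- span %/% p
  rem <- span - n_full * p
  mat <- matrix(rep(m, n_full), nrow = p)
  if (rate > 0) {
    flat <- .mutate_chars(as.vector(mat), rate)
    mat <- matrix(flat, nrow = p)
  }
  out <- .collapse(as.vector(mat))
  if (rem > 0) {
    partial <- .mutate_chars(m[seq_len(rem)], rate)
    out <- paste0(out, .collapse(partial))
  }
  out
}

#' Build one synthetic chromosome with truth annotation
#'
#' Planted features overwrite the background in place, so every truth
#' coordinate is exact. Deterministic given `seed`.
#'
#' @param spec A [chromosome_spec()].
#' @param seed Integer seed (optional; caller may manage RNG state).
#' @param ancestors Environment holding ancestral LTR elements shared
#'   across insertions (and across chromosomes when supplied by
#'   [build_genome()]).
#' @return A list with `sequence` (character string) and `truth`
#'   (telomeres, centromere/satellite array, LTR elements, all 1-based
#'   closed coordinates).
#' @export
build_chromosome <- function(spec, seed = NULL, ancestors = new.env()) {
  stopifnot(inherits(spec, "chromosome_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$length
  chars <- .chars(.random_dna(n, spec$gc_background))

  tel5_len <- spec$telomere_copies_5p * 7L
  tel3_len <- spec$telomere_copies_3p * 7L
  telomeres <- data.frame(end = character(0), copies = integer(0),
                          start = integer(0), stop = integer(0),
                          stringsAsFactors = FALSE)
  if (tel5_len > 0) {
    chars[seq_len(tel5_len)] <-
      .chars(strrep(TELOMERE_MOTIF_5P, spec$telomere_copies_5p))
    telomeres <- rbind(telomeres, data.frame(
      end = "5p", copies = spec$telomere_copies_5p, start = 1L,
      stop = tel5_len, stringsAsFactors = FALSE))
  }
  if (tel3_len > 0) {
    chars[(n - tel3_len + 1L):n] <-
      .chars(strrep(TELOMERE_MOTIF_3P, spec$telomere_copies_3p))
    telomeres <- rbind(telomeres, data.frame(
      end = "3p", copies = spec$telomere_copies_3p,
      start = n - tel3_len + 1L, stop = n, stringsAsFactors = FALSE))
  }

  satellite <- NULL
  if (!is.na(spec$centromere_start)) {
    span <- spec$centromere_end - spec$centromere_start + 1L
    arr <- .satellite_array_seq(spec$satellite_monomer, span,
                                spec$satellite_mutation_rate)
    chars[spec$centromere_start:spec$centromere_end] <- .chars(arr)
    period <- nchar(spec$satellite_monomer)
    satellite <- list(
      start = spec$centromere_start, end = spec$centromere_end,
      period = period, copies = span %/% period,
      monomer = spec$satellite_monomer,
      monomer_canonical = canonical_rotation(spec$satellite_monomer),
      mutation_rate = spec$satellite_mutation_rate
    )
  }

  ltr <- data.frame(start = integer(0), end = integer(0),
                    ltr_length = integer(0), internal_length = integer(0),
                    ltr5_start = integer(0), ltr5_end = integer(0),
                    ltr3_start = integer(0), ltr3_end = integer(0),
                    load = numeric(0), ancestor = character(0),
                    true_K = numeric(0))
  for (ins in spec$ltr_insertions) {
    if (!is.null(ins$ancestor)) {
      key <- as.character(ins$ancestor)
      if (!exists(key, envir = ancestors, inherits = FALSE)) {
        assign(key, list(
          ltr = .chars(.random_dna(ins$ltr_length, spec$gc_background)),
          internal = .chars(.random_dna(ins$internal_length,
                                        spec$gc_background))),
          envir = ancestors)
      }
      base <- get(key, envir = ancestors, inherits = FALSE)
      if (length(base$ltr) != ins$ltr_length ||
          length(base$internal) != ins$internal_length) {
        stop("insertions sharing ancestor '", key,
             "' must have identical lengths", call. = FALSE)
      }
      ltr_seq <- .mutate_chars(base$ltr, ins$ancestral_divergence)
      internal <- .mutate_chars(base$internal, ins$ancestral_divergence)
    } else {
      ltr_seq <- .chars(.random_dna(ins$ltr_length, spec$gc_background))
      internal <- .chars(.random_dna(ins$internal_length,
                                     spec$gc_background))
    }
    ltr5 <- .mutate_chars(ltr_seq, ins$per_ltr_mutation_load)
    ltr3 <- .mutate_chars(ltr_seq, ins$per_ltr_mutation_load)
    a <- ins$position
    b <- a + 2L * ins$ltr_length + ins$internal_length - 1L
    chars[a:b] <- c(ltr5, internal, ltr3)
    ltr <- rbind(ltr, data.frame(
      start = a, end = b,
      ltr_length = ins$ltr_length, internal_length = ins$internal_length,
      ltr5_start = a, ltr5_end = a + ins$ltr_length - 1L,
      ltr3_start = b - ins$ltr_length + 1L, ltr3_end = b,
      load = ins$per_ltr_mutation_load,
      ancestor = if (is.null(ins$ancestor)) NA_character_ else
        as.character(ins$ancestor),
      true_K = .hamming_chars(ltr5, ltr3) / ins$ltr_length))
  }

  # Scrub chance telomere-motif occurrences from non-feature background so
  # terminal copy counts are exactly the planted numbers. Feature intervals
  # (telomere tracts, satellite array, LTR elements) are left untouched.
  protected <- logical(n)
  if (tel5_len > 0) protected[seq_len(tel5_len)] <- TRUE
  if (tel3_len > 0) protected[(n - tel3_len + 1L):n] <- TRUE
  if (!is.null(satellite)) {
    protected[satellite$start:satellite$end] <- TRUE
  }
  if (nrow(ltr)) {
    for (i in seq_len(nrow(ltr))) protected[ltr$start[i]:ltr$end[i]] <- TRUE
  }
  seq_str <- .collapse(chars)
  for (pass in 1:5) {
    hits <- c(gregexpr(TELOMERE_MOTIF_5P, seq_str, fixed = TRUE)[[1L]],
              gregexpr(TELOMERE_MOTIF_3P, seq_str, fixed = TRUE)[[1L]])
    hits <- hits[hits > 0L]
    # an occurrence is background iff no base of it is protected
    hits <- hits[!vapply(hits, function(h)
      any(protected[h:(h + 6L)]), logical(1))]
    if (length(hits) == 0L) break
    mid <- hits + 3L
    chars[mid] <- ifelse(chars[mid] == "T", "G", "T")
    seq_str <- .collapse(chars)
  }

  list(
    sequence = seq_str,
    truth = list(
      name = spec$name, length = n,
      telomeres = telomeres,
      centromere = if (is.null(satellite)) NULL else
        c(start = satellite$start, end = satellite$end),
      satellite = satellite,
      ltr_elements = ltr
    )
  )
}

#' Build a multi-chromosome synthetic genome
#'
#' @param specs List of [chromosome_spec()] objects (unique names).
#' @param seed Integer seed; one global RNG stream drives the whole build,
#'   so identical `(specs, seed)` yields identical bytes.
#' @return A list with `genome` (named `DNAStringSet`) and `truth`, a list
#'   with the recorded `seed` and `chromosomes` (per-chromosome truth,
#'   keyed by name).
#' @export
build_genome <- function(specs, seed = 1L) {
  nm <- vapply(specs, function(s) s$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate chromosome names", call. = FALSE)
  set.seed(seed)
  ancestors <- new.env()
  seqs <- character(length(specs))
  truth <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    built <- build_chromosome(specs[[i]], seed = NULL,
                              ancestors = ancestors)
    seqs[i] <- built$sequence
    truth[[i]] <- built$truth
  }
  genome <- Biostrings::DNAStringSet(stats::setNames(seqs, nm))
  list(genome = genome,
       truth = list(seed = seed, chromosomes = stats::setNames(truth, nm)))
}

# Accept either a full truth object (with $chromosomes) or the bare
# per-chromosome list.
.truth_chromosomes <- function(truth) {
  if (!is.null(truth$chromosomes)) truth$chromosomes else truth
}

#' Simulate ChIP and input fragment sets
#'
#' Input fragments are uniform over the genome. A
#' `chip_centromere_fraction` share of ChIP fragments has midpoints placed
#' at `array_start + k * monomer + phase + Normal(0, phase_sd)` for a
#' uniformly chosen copy `k` and planted phase position, emulating phased
#' CENH3 nucleosomes on the satellite; the rest are uniform.
#'
#' @param genome Named `DNAStringSet` (or named lengths).
#' @param truth Truth list from [build_genome()].
#' @param n_input,n_chip Fragment counts (exact).
#' @param chip_centromere_fraction Probability a ChIP fragment is
#'   centromeric/phased, in `[0, 1]`.
#' @param fragment_length Mean fragment length in bases.
#' @param fragment_sd SD of fragment length.
#' @param phase_positions Integer offsets (0-based) of planted nucleosome
#'   midpoint positions within the monomer; `NULL` for uniform placement
#'   within the array.
#' @param phase_sd SD (bases) of midpoint jitter around a phase position.
#' @param seed Integer seed.
#' @return List with `chip` and `input` [fragment_set()] objects.
#' @export
simulate_fragments <- function(genome, truth, n_input, n_chip,
                               chip_centromere_fraction = 0.8,
                               fragment_length = 150, fragment_sd = 15,
                               phase_positions = NULL, phase_sd = 10,
                               seed = 1L) {
  if (n_input <= 0 || n_chip <= 0) {
    stop("fragment counts must be positive", call. = FALSE)
  }
  .check_scalar(chip_centromere_fraction, "chip_centromere_fraction", 0, 1)
  lens <- genome_lengths(genome)
  set.seed(seed)
  truth <- .truth_chromosomes(truth)

  cen_chroms <- names(truth)[vapply(truth, function(t)
    !is.null(t$satellite), logical(1))]
  if (!is.null(phase_positions) && length(cen_chroms)) {
    period_min <- min(vapply(truth[cen_chroms],
                             function(t) t$satellite$period, numeric(1)))
    if (any(phase_positions < 0 | phase_positions >= period_min)) {
      stop("phase positions must lie within the monomer", call. = FALSE)
    }
  }

  uniform_frags <- function(n) {
    chr <- sample(names(lens), n, replace = TRUE, prob = lens / sum(lens))
    len <- pmax(20L, as.integer(round(stats::rnorm(n, fragment_length,
                                                   fragment_sd))))
    len <- pmin(len, lens[chr])
    start <- floor(stats::runif(n) * (lens[chr] - len + 1L)) + 1L
    GenomicRanges::GRanges(chr, IRanges::IRanges(start = start,
                                                 width = len))
  }

  input_gr <- uniform_frags(n_input)

  n_cen <- round(n_chip * chip_centromere_fraction)
  if (n_cen > 0 && length(cen_chroms) == 0L) {
    stop("chip_centromere_fraction > 0 but no chromosome has a satellite",
         call. = FALSE)
  }
  cen_gr <- NULL
  if (n_cen > 0) {
    arr_len <- vapply(truth[cen_chroms], function(t)
      t$satellite$end - t$satellite$start + 1, numeric(1))
    chr <- sample(cen_chroms, n_cen, replace = TRUE,
                  prob = arr_len / sum(arr_len))
    sat <- truth[chr]
    period <- vapply(sat, function(t) t$satellite$period, numeric(1))
    copies <- vapply(sat, function(t) t$satellite$copies, numeric(1))
    astart0 <- vapply(sat, function(t) t$satellite$start, numeric(1)) - 1
    k <- floor(stats::runif(n_cen) * copies)
    phase <- if (is.null(phase_positions)) {
      floor(stats::runif(n_cen) * period)
    } else {
      phase_positions[sample.int(length(phase_positions), n_cen,
                                 replace = TRUE)]
    }
    mid0 <- astart0 + k * period + phase +
      round(stats::rnorm(n_cen, 0, phase_sd))
    len <- pmax(20L, as.integer(round(stats::rnorm(n_cen, fragment_length,
                                                   fragment_sd))))
    start1 <- as.integer(mid0 - len %/% 2L + 1L)
    start1 <- pmax(1L, pmin(start1, lens[chr] - len + 1L))
    cen_gr <- GenomicRanges::GRanges(chr, IRanges::IRanges(start = start1,
                                                           width = len))
  }
  arm_gr <- if (n_chip - n_cen > 0) uniform_frags(n_chip - n_cen) else NULL
  parts <- Filter(Negate(is.null), list(cen_gr, arm_gr))
  chip_gr <- do.call(c, parts)

  list(
    chip = fragment_set(chip_gr, "chip", genome = lens),
    input = fragment_set(input_gr, "input", genome = lens)
  )
}

#' Write a simulation fixture to disk
#'
#' Emits `genome.fa`, `truth.json`, `chip.bed` and `input.bed`; the files
#' are plain text and reloading with [read_fixture()] reproduces the
#' objects.
#'
#' @param genome Named `DNAStringSet`.
#' @param truth Truth list (seed included if produced by [build_genome()]).
#' @param fragments List with `chip` and `input` fragment sets (optional).
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(genome, truth, fragments = NULL, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(genome, file.path(out_dir, "genome.fa"))
  jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "columns", null = "null")
  if (!is.null(fragments)) {
    write_fragments_bed(fragments$chip, file.path(out_dir, "chip.bed"))
    write_fragments_bed(fragments$input, file.path(out_dir, "input.bed"))
  }
  invisible(out_dir)
}

#' Reload a simulation fixture
#'
#' @param dir Directory written by [write_fixture()].
#' @return List with `genome`, `truth` and (if present) `fragments`.
#' @export
read_fixture <- function(dir) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  out <- list(genome = genome, truth = truth)
  chip_p <- file.path(dir, "chip.bed")
  if (file.exists(chip_p)) {
    out$fragments <- list(
      chip = read_fragments_bed(chip_p, genome, "chip"),
      input = read_fragments_bed(file.path(dir, "input.bed"), genome, "input")
    )
  }
  out
}
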