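# Telomeric repeat counting at chromosome ends.
#
# Plant telomeres carry tandem copies of the 7-mer CCCTAAA on the 5' end
# of the forward strand and its reverse complement TTTAGGG at the 3' end.
# Counting is exact and non-overlapping within a terminal window, so the
# simulator round-trip recovers planted copy numbers exactly.

#' Count telomeric motif copies at both ends of a chromosome
#'
#' The 5' report counts non-overlapping exact occurrences of `motif`
#' within the first `terminal_window` bases; the 3' report counts the
#' reverse-complement motif within the last `terminal_window` bases.
#' `tract_span` is the minimal interval (1-based closed) covering the
#' first to last counted occurrence.
#'
#' @param seq A single chromosome: `DNAString`, one-element
#'   `DNAStringSet`, or character string.
#' @param name Chromosome name used in the reports.
#' @param motif Telomeric 7-mer (forward-strand 5' form).
#' @param terminal_window Bases scanned at each end.
#' @param presence_min Minimum copies for `present = TRUE`.
#' @return A list with elements `p5` and `p3`, each a one-row data frame
#'   with columns `chrom`, `end`, `motif`, `copies`, `tract_start`,
#'   `tract_end`, `present`.
#' @export
count_telomere_repeats <- function(seq, name = "chr",
                                   motif = TELOMERE_MOTIF_5P,
                                   terminal_window = 100000L,
                                   presence_min = 100L) {
  if (methods::is(seq, "DNAStringSet")) {
    if (length(seq) != 1L) stop("give one chromosome at a time", call. = FALSE)
    if (!is.null(names(seq))) name <- names(seq)
    seq <- seq[[1L]]
  }
  s <- toupper(as.character(seq))
  if (nchar(motif) != 7L || grepl("[^ACGTN]", motif)) {
    stop("motif must be a 7-mer over ACGTN", call. = FALSE)
  }
  n <- nchar(s)
  w <- min(as.integer(terminal_window), n)

  count_in <- function(window, m, offset) {
    hits <- Biostrings::matchPattern(m, Biostrings::DNAString(window))
    st <- Biostrings::start(hits)
    if (length(st) == 0L) {
      return(list(copies = 0L, tract = c(NA_integer_, NA_integer_)))
    }
    # greedy non-overlapping selection (left to right)
    keep <- st[1L]
    last_end <- st[1L] + nchar(m) - 1L
    for (p in st[-1L]) {
      if (p > last_end) {
        keep <- c(keep, p)
        last_end <- p + nchar(m) - 1L
      }
    }
    list(copies = length(keep),
         tract = c(offset + keep[1L],
                   offset + keep[length(keep)] + nchar(m) - 1L))
  }

  r5 <- count_in(substr(s, 1L, w), motif, 0L)
  r3 <- count_in(substr(s, n - w + 1L, n), .revcomp_str(motif), n - w)

  row <- function(endlab, m, r) data.frame(
    chrom = name, end = endlab, motif = m, copies = r$copies,
    tract_start = r$tract[1L], tract_end = r$tract[2L],
    present = r$copies >= presence_min, stringsAsFactors = FALSE)

  list(p5 = row("5p", motif, r5), p3 = row("3p", .revcomp_str(motif), r3))
}

#' Telomere report table for a genome
#'
#' One row per chromosome end plus a `n_telomeres` attribute counting
#' ends with `present = TRUE` (a complete 14-chromosome genome with
#' telomeres at every end yields 28).
#'
#' @param genome Named `DNAStringSet`.
#' @inheritParams count_telomere_repeats
#' @return Data frame (two rows per chromosome) with attribute
#'   `n_telomeres`.
#' @export
telomere_table <- function(genome, motif = TELOMERE_MOTIF_5P,
                           terminal_window = 100000L, presence_min = 100L) {
  rows <- list()
  for (i in seq_along(genome)) {
    rep2 <- count_telomere_repeats(genome[i], motif = motif,
                                   terminal_window = terminal_window,
                                   presence_min = presence_min)
    rows[[length(rows) + 1L]] <- rep2$p5
    rows[[length(rows) + 1L]] <- rep2$p3
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(0), end = character(0),
               motif = character(0), copies = integer(0),
               tract_start = integer(0), tract_end = integer(0),
               present = logical(0), stringsAsFactors = FALSE)
  attr(tab, "n_telomeres") <- sum(tab$present)
  tab
}
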