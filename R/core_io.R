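#' Read chromosome sequences from a FASTA file
#'
#' Sequences are uppercased on read and must contain only A, C, G, T or N.
#' N is permitted but is never counted as a match by any scan in this
#' package.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet] (one entry per record).
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">a", "ACGT", ">b", "GG"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  x <- tryCatch(
    withCallingHandlers(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      # the parser silently drops invalid letters with a warning; that is
      # a format error under this package's contract
      warning = function(w) stop(conditionMessage(w), call. = FALSE)),
    error = function(e) {
      stop("malformed FASTA in ", path, ": ", conditionMessage(e),
           call. = FALSE)
    }
  )
  x <- Biostrings::DNAStringSet(toupper(as.character(x)))
  if (length(x)) {
    bad <- Biostrings::letterFrequency(x, letters = "ACGTN")
    ill <- which(as.vector(bad) != Biostrings::width(x))
    if (length(ill)) {
      stop("illegal (non-ACGTN) characters in record(s): ",
           paste(names(x)[ill], collapse = ", "), call. = FALSE)
    }
    if (anyDuplicated(names(x))) {
      stop("duplicate sequence names in ", path, call. = FALSE)
    }
  }
  x
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Chromosome lengths of a genome
#'
#' @param genome Named `DNAStringSet`, or a named integer vector of lengths
#'   (accepted anywhere a genome is needed only as a coordinate frame).
#' @return Named integer vector of chromosome lengths.
#' @export
genome_lengths <- function(genome) {
  if (is.numeric(genome)) {
    if (is.null(names(genome))) stop("length vector must be named", call. = FALSE)
    return(stats::setNames(as.integer(genome), names(genome)))
  }
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Construct a validated fragment set
#'
#' A fragment set holds sequenced ChIP or input fragments as genomic
#' intervals (a [GenomicRanges::GRanges]) plus a label. Every fragment must
#' lie within its chromosome.
#'
#' @param fragments A `GRanges` of fragment intervals (1-based closed, the
#'   native R convention; BED input is converted on read).
#' @param label Either `"chip"` or `"input"`.
#' @param genome Optional genome (sequences or named lengths) to validate
#'   fragment bounds against.
#' @return An object of class `fragment_set` with elements `label`,
#'   `fragments` and `total_count`.
#' @export
fragment_set <- function(fragments, label = c("chip", "input"), genome = NULL) {
  label <- match.arg(label)
  stopifnot(methods::is(fragments, "GRanges"))
  if (any(GenomicRanges::start(fragments) < 1L) ||
      any(GenomicRanges::width(fragments) < 1L)) {
    stop("fragment intervals must satisfy 1 <= start <= end", call. = FALSE)
  }
  if (!is.null(genome)) {
    lens <- genome_lengths(genome)
    chr <- as.character(GenomicRanges::seqnames(fragments))
    unknown <- setdiff(unique(chr), names(lens))
    if (length(unknown)) {
      stop("unknown chromosome(s) in fragments: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    over <- GenomicRanges::end(fragments) > lens[chr]
    if (any(over)) {
      stop(sum(over), " fragment(s) extend beyond chromosome ends",
           call. = FALSE)
    }
  }
  structure(
    list(label = label, fragments = fragments,
         total_count = length(fragments)),
    class = "fragment_set"
  )
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("<fragment_set> label=%s, %d fragments on %d chromosome(s)\n",
              x$label, x$total_count,
              length(unique(as.character(GenomicRanges::seqnames(x$fragments))))))
  invisible(x)
}

#' Fragment midpoints
#'
#' Midpoint is defined on the 0-based half-open frame as
#' `floor((start0 + end0) / 2)`, a deterministic integer convention used
#' for window assignment and nucleosome phasing.
#'
#' @param x A `fragment_set` or a `GRanges`.
#' @return Integer vector of 0-based midpoints.
#' @export
fragment_midpoints <- function(x) {
  gr <- if (inherits(x, "fragment_set")) x$fragments else x
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr)
  as.integer((start0 + end0) %/% 2L)
}

#' Read a fragment BED file
#'
#' Accepts BED3+ (0-based half-open). Chromosome names must resolve
#' against the genome and intervals must lie in bounds.
#'
#' @inheritParams fragment_set
#' @param path BED file path.
#' @return A `fragment_set`.
#' @export
read_fragments_bed <- function(path, genome, label = c("chip", "input")) {
  label <- match.arg(label)
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lens <- genome_lengths(genome)
  info <- file.info(path)
  if (info$size == 0) {
    gr <- GenomicRanges::GRanges(seqnames = character(0),
                                 ranges = IRanges::IRanges())
    return(fragment_set(gr, label, genome))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           comment.char = "#", quote = "",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("BED3+ requires at least 3 columns", call. = FALSE)
  chrom <- as.character(tab[[1L]])
  start0 <- as.numeric(tab[[2L]])
  end0 <- as.numeric(tab[[3L]])
  if (anyNA(start0) || anyNA(end0)) {
    stop("BED format error: non-numeric start/end", call. = FALSE)
  }
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad)) {
    stop("BED format error (start >= end or negative start) at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(chrom), names(lens))
  if (length(unknown)) {
    stop("unknown chromosome(s) in BED: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  over <- which(end0 > lens[chrom])
  if (length(over)) {
    stop("interval(s) beyond chromosome end at line(s): ",
         paste(utils::head(over, 5L), collapse = ", "), call. = FALSE)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
  )
  fragment_set(gr, label, genome)
}

#' Write fragments (or any interval set) as BED
#'
#' @param x A `fragment_set` or `GRanges`.
#' @param path Output path.
#' @param names Optional name column.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(x, path, names = NULL) {
  gr <- if (inherits(x, "fragment_set")) x$fragments else x
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (!is.null(names)) df$name <- names
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a windowed track as bedGraph
#'
#' Windows must tile each chromosome without overlap. Values are printed
#' with six significant digits.
#'
#' @param track A `density_track` or `ratio_track` (see
#'   [compute_window_density()]), or a data frame with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `value`.
#' @param path Output path.
#' @param column Which column to emit for ratio tracks (`"ratio"` or
#'   `"log2_ratio"`); ignored for plain density tracks.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, column = "value") {
  df <- as.data.frame(track)
  val <- if (column %in% names(df)) df[[column]] else df$value
  # overlap check within chromosome
  sp <- split(seq_len(nrow(df)), df$chrom)
  for (idx in sp) {
    o <- idx[order(df$start[idx])]
    if (any(df$start[o][-1] < df$end[o][-length(o)])) {
      stop("overlapping windows in track; bedGraph requires a tiling",
           call. = FALSE)
    }
  }
  lines <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), sprintf("%.6g", val))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph file into a plain window table
#'
#' @param path bedGraph path.
#' @return Data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   `value`.
#' @export
read_bedgraph <- function(path) {
  if (file.info(path)$size == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), value = numeric(0)))
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "value"),
                           colClasses = c("character", "integer", "integer",
                                          "numeric"))
  tab
}
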