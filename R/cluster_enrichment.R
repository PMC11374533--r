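# Scoring repeat clusters for centromere association.
#
# Reads sampled from ChIP and input fragment sets are aligned to repeat
# cluster consensus sequences; the per-million-normalised ChIP/input hit
# ratio measures how strongly a cluster is associated with
# CENH3-containing chromatin, and clusters are selected when that ratio
# exceeds 7 with genomic representation above 0.05%. Cluster discovery
# itself (graph-based read clustering) is out of scope: consensus
# sequences enter as FASTA input or from the satellite module.

#' Sample fixed-length reads at fragment positions
#'
#' Extracts `n` reads of `read_length` bases from the genome at sampled
#' fragment start positions (clipped at chromosome ends). Sampling is
#' without replacement when `n` does not exceed the number of fragments
#' (so `n == total` returns every fragment position once), otherwise with
#' replacement (with a message).
#'
#' @param fragments A [fragment_set()].
#' @param genome Named `DNAStringSet`.
#' @param n Number of reads.
#' @param read_length Read length in bases.
#' @param seed Integer seed.
#' @return A `DNAStringSet` of reads.
#' @export
sample_reads <- function(fragments, genome, n = 1e6L, read_length = 150L,
                         seed = 1L) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  set.seed(seed)
  total <- fragments$total_count
  if (n <= total) {
    idx <- sample.int(total, n)
  } else {
    message("sampling ", n, " reads from ", total,
            " fragments: sampling with replacement")
    idx <- sample.int(total, n, replace = TRUE)
  }
  gr <- fragments$fragments[idx]
  lens <- genome_lengths(genome)
  chr <- as.character(GenomicRanges::seqnames(gr))
  st <- GenomicRanges::start(gr)
  en <- pmin(st + read_length - 1L, lens[chr])
  reads <- character(length(idx))
  for (cc in unique(chr)) {
    i <- which(chr == cc)
    reads[i] <- as.character(Biostrings::extractAt(
      genome[[cc]], IRanges::IRanges(start = st[i], end = en[i])))
  }
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- paste0("read", seq_along(out))
  out
}

#' Align reads to repeat-cluster consensus sequences
#'
#' Each read is aligned locally against every cluster consensus
#' (concatenated head-to-tail twice so reads spanning the tandem junction
#' are not penalised), on both strands, and assigned to the best-scoring
#' cluster if the alignment reaches `min_identity` over at least
#' `min_aligned` aligned (gap-free) bases. Reads failing everywhere are
#' counted as unassigned.
#'
#' @param reads `DNAStringSet` of reads.
#' @param clusters Named `DNAStringSet` or named character vector of
#'   cluster consensus sequences (length >= 50 each).
#' @param min_identity Identity threshold (matches / aligned columns
#'   excluding gaps).
#' @param min_aligned Minimum aligned bases.
#' @param method `"seed"` (default): seed-and-vote ungapped placement at
#'   the modal shared-k-mer diagonal, scored by direct base comparison
#'   (exact under substitution-only divergence, fast); `"align"`: full
#'   Smith-Waterman local alignment.
#' @return List with `hits` (named integer vector per cluster),
#'   `unassigned` (count) and `assignment` (character vector per read,
#'   `NA` if unassigned).
#' @export
align_reads_to_clusters <- function(reads, clusters, min_identity = 0.8,
                                    min_aligned = 50L,
                                    method = c("seed", "align")) {
  method <- match.arg(method)
  if (is.character(clusters)) clusters <- Biostrings::DNAStringSet(clusters)
  if (length(clusters) == 0L) stop("no clusters given", call. = FALSE)
  if (is.null(names(clusters))) {
    names(clusters) <- paste0("cluster", seq_along(clusters))
  }
  if (any(Biostrings::width(clusters) < 50L)) {
    stop("cluster consensus must be >= 50 bases", call. = FALSE)
  }
  n <- length(reads)
  best_score <- rep(-Inf, n)
  best_cluster <- rep(NA_character_, n)
  best_ident <- rep(0, n)
  best_alen <- rep(0L, n)
  if (is.character(reads)) reads <- Biostrings::DNAStringSet(reads)
  rc_reads <- Biostrings::reverseComplement(reads)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  for (cl in names(clusters)) {
    doubled <- strrep(as.character(clusters[[cl]]), 2L)
    for (strand_reads in list(reads, rc_reads)) {
      if (method == "seed") {
        sm <- .seed_map(as.character(strand_reads), doubled)
        nm <- sm$matches
        alen <- sm$overlap
        sc <- ifelse(is.na(nm), -Inf, 2 * nm - alen)  # match 1 / mismatch -1
        nm[is.na(nm)] <- 0L
        alen[is.na(alen)] <- 0L
      } else {
        aln <- Biostrings::pairwiseAlignment(
          strand_reads, Biostrings::DNAString(doubled), type = "local",
          substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
        sc <- Biostrings::score(aln)
        nm <- Biostrings::nmatch(aln)
        nmm <- Biostrings::nmismatch(aln)
        alen <- nm + nmm
      }
      ident <- ifelse(alen > 0, nm / alen, 0)
      better <- sc > best_score
      best_score[better] <- sc[better]
      best_cluster[better] <- cl
      best_ident[better] <- ident[better]
      best_alen[better] <- alen[better]
    }
  }
  ok <- best_ident >= min_identity & best_alen >= min_aligned
  assignment <- ifelse(ok, best_cluster, NA_character_)
  hits <- stats::setNames(integer(length(clusters)), names(clusters))
  tt <- table(assignment[ok])
  hits[names(tt)] <- as.integer(tt)
  list(hits = hits, unassigned = sum(!ok), assignment = assignment)
}

#' Per-cluster ChIP/input enrichment
#'
#' Ratio of per-million-normalised hit counts with a pseudocount of one
#' read on each count; genomic representation is the fraction of input
#' reads hitting the cluster.
#'
#' @param chip_counts,input_counts Named hit-count vectors (same
#'   clusters).
#' @param n_chip_total,n_input_total Total reads aligned per set.
#' @return Data frame of class `cluster_enrichment`: `cluster_id`,
#'   `chip_hits`, `input_hits`, `ratio`, `genome_proportion`.
#' @export
cluster_enrichment_ratio <- function(chip_counts, input_counts,
                                     n_chip_total, n_input_total) {
  if (n_chip_total <= 0 || n_input_total <= 0) {
    stop("read totals must be positive", call. = FALSE)
  }
  ids <- names(chip_counts)
  stopifnot(identical(ids, names(input_counts)))
  ratio <- ((chip_counts + 1) / n_chip_total) /
    ((input_counts + 1) / n_input_total)
  out <- data.frame(cluster_id = ids,
                    chip_hits = as.integer(chip_counts),
                    input_hits = as.integer(input_counts),
                    ratio = as.numeric(ratio),
                    genome_proportion = as.numeric(input_counts) /
                      n_input_total,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("cluster_enrichment", "data.frame"))
}

#' Select centromere-associated clusters
#'
#' Keeps clusters whose ChIP/input ratio strictly exceeds `ratio_min` and
#' whose genomic representation strictly exceeds `proportion_min`
#' (defaults mirror a ratio surpassing 7 with representation above
#' 0.05%). Result is sorted by ratio, descending.
#'
#' @param enrichments A `cluster_enrichment` data frame.
#' @param ratio_min Ratio threshold (strict).
#' @param proportion_min Genome-proportion threshold (strict).
#' @return Character vector of selected cluster ids.
#' @export
select_centromeric_clusters <- function(enrichments, ratio_min = 7,
                                        proportion_min = 0.0005) {
  sel <- enrichments[enrichments$ratio > ratio_min &
                       enrichments$genome_proportion > proportion_min, ]
  sel <- sel[order(-sel$ratio), ]
  sel$cluster_id
}
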