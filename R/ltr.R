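# Full-length LTR retrotransposon detection and insertion-time dating.
#
# At insertion the two LTRs of an element are identical; substitutions
# then accumulate independently in each copy, so the per-site divergence
# K between the LTRs dates the insertion as T = K / (2 r), with r the
# substitution rate per site per year. The detector is a pair-similarity
# scan (shared k-mers at a consistent spacing, extended to maximal
# matching blocks); externally produced LTR annotations can be supplied
# instead wherever elements are consumed.

#' Dating parameters for LTR insertion-time estimation
#'
#' @param r Substitution rate per site per year. The default 1.3e-8 is a
#'   widely used plant LTR clock; always configurable and recorded in
#'   outputs.
#' @param correction `"raw"` (K = 1 - identity, the per-site difference
#'   proportion) or `"JC69"` (Jukes-Cantor multiple-hit correction).
#' @return List of class `dating_params`.
#' @export
dating_params <- function(r = 1.3e-8, correction = c("raw", "JC69")) {
  .check_scalar(r, "r", lo = .Machine$double.xmin)
  correction <- match.arg(correction)
  structure(list(r = r, correction = correction), class = "dating_params")
}

#' Detect candidate full-length LTR elements
#'
#' Finds pairs of similar same-strand segments (shared `k`-mers at a
#' consistent spacing) within the element-length window, extends them to
#' maximal matching blocks, and reports candidate 5'/3' LTR pairs with
#' the intervening internal region. Overlapping candidates are resolved
#' by higher pair identity, except that elements nested wholly inside
#' another element's internal region are kept and flagged.
#'
#' @param seq Chromosome sequence (character / `DNAString` /
#'   one-element `DNAStringSet`).
#' @param name Chromosome name.
#' @param min_ltr_len,max_ltr_len LTR length bounds (bases).
#' @param min_element_len,max_element_len Full element length bounds.
#' @param min_pair_identity Minimum LTR-LTR identity for a candidate.
#' @param k Seed k-mer length.
#' @param max_occ Skip k-mers occurring more than this many times
#'   (high-copy repeat guard).
#' @return Data frame of class `ltr_elements`: `chrom`, `start`, `end`,
#'   `ltr5_start`, `ltr5_end`, `ltr3_start`, `ltr3_end` (1-based
#'   closed), `ltr_length`, `pair_identity`, `nested`.
#' @export
find_ltr_pairs <- function(seq, name = "chr", min_ltr_len = 100L,
                           max_ltr_len = 3000L, min_element_len = 1000L,
                           max_element_len = 20000L,
                           min_pair_identity = 0.8, k = 21L,
                           max_occ = 10L) {
  if (methods::is(seq, "DNAStringSet")) {
    if (!is.null(names(seq))) name <- names(seq)[1L]
    seq <- seq[[1L]]
  }
  s <- toupper(as.character(seq))
  n <- nchar(s)
  empty <- structure(
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               ltr5_start = integer(0), ltr5_end = integer(0),
               ltr3_start = integer(0), ltr3_end = integer(0),
               ltr_length = integer(0), pair_identity = numeric(0),
               nested = logical(0), stringsAsFactors = FALSE),
    class = c("ltr_elements", "data.frame"))
  if (n < min_element_len) return(empty)
  d_min <- max(min_ltr_len, min_element_len - max_ltr_len)
  d_max <- max_element_len - min_ltr_len

  kc <- .kmer_codes(s, k)
  vi <- which(kc$valid)
  if (length(vi) < 2L) return(empty)
  codes <- kc$codes[vi]
  o <- order(codes, method = "radix")   # stable: positions ascend in runs
  cc <- codes[o]
  po <- vi[o]
  newrun <- c(TRUE, cc[-1L] != cc[-length(cc)])
  run_id <- cumsum(newrun)
  occ <- tabulate(run_id)
  occ_of <- occ[run_id]
  usable <- occ_of >= 2L & occ_of <= max_occ
  # vectorised pairs for occ == 2 (the dominant case)
  two_start <- which(newrun & occ_of == 2L & usable)
  d2 <- po[two_start + 1L] - po[two_start]
  k2 <- d2 >= d_min & d2 <= d_max
  acc_pos <- list(po[two_start][k2])
  acc_d <- list(d2[k2])
  run_starts <- which(newrun)
  multi <- which(occ >= 3L & occ <= max_occ)
  for (r_i in multi) {
    p <- po[run_starts[r_i]:(run_starts[r_i] + occ[r_i] - 1L)]
    cmb <- utils::combn(p, 2L)
    dd <- cmb[2L, ] - cmb[1L, ]
    keep <- dd >= d_min & dd <= d_max
    if (!any(keep)) next
    acc_pos[[length(acc_pos) + 1L]] <- cmb[1L, keep]
    acc_d[[length(acc_d) + 1L]] <- dd[keep]
  }
  seeds_pos <- unlist(acc_pos, use.names = FALSE)
  seeds_d <- unlist(acc_d, use.names = FALSE)
  if (length(seeds_pos) == 0L) return(empty)
  sc <- .chars(s)

  cands <- list()
  # a genuine LTR pair yields many consistent-spacing seeds; demand >= 5
  # before doing any extension work (kills tandem-array seed noise)
  tab_d <- table(seeds_d)
  good_d <- as.integer(names(tab_d)[tab_d >= 5L])
  for (d in good_d) {
    pos <- sort(seeds_pos[seeds_d == d])
    cl <- cumsum(c(1L, diff(pos) > 300L))
    for (cc in unique(cl)) {
      pg <- pos[cl == cc]
      if (length(pg) < 5L) next
      a <- min(pg)
      b <- max(pg) + k - 1L
      if (b - a + 1L > max_ltr_len + 200L) next
      # extend on the spacing-d match indicator
      lo <- max(1L, a - max_ltr_len)
      hi <- min(b + max_ltr_len, n - d)
      if (hi <= lo) next
      idx <- lo:hi
      v <- (sc[idx] == sc[idx + d]) & sc[idx] != "N"
      w <- 15L
      if (length(v) < w) next
      cs <- cumsum(c(0, v))
      sm <- (cs[(w + 1L):(length(v) + 1L)] -
               cs[1L:(length(v) - w + 1L)]) / w
      high <- sm >= 0.6
      centre <- a - lo + 1L
      runs <- rle(high)
      rends <- cumsum(runs$lengths)
      rstarts <- rends - runs$lengths + 1L
      ci <- which(runs$values & rstarts <= centre &
                    rends + w - 1L >= centre)
      if (length(ci) == 0L) next
      r1 <- rstarts[ci[1L]]
      r2 <- min(rends[ci[1L]] + w - 1L, length(v))
      # trim: endpoint must itself match and sit in a confident window
      wt <- 8L
      rng <- r1:r2
      if (length(rng) <= wt) next
      csr <- cumsum(c(0, v[rng]))
      fwd <- (csr[(wt + 1L):(length(rng) + 1L)] -
                csr[1L:(length(rng) - wt + 1L)]) / wt
      oks <- which(v[rng[seq_along(fwd)]] & fwd >= 0.75)
      bpos <- wt:length(rng)
      bwd <- (csr[bpos + 1L] - csr[bpos - wt + 1L]) / wt
      oke <- bpos[v[rng[bpos]] & bwd >= 0.75]
      if (length(oks) == 0L || length(oke) == 0L) next
      st <- lo + rng[oks[1L]] - 1L
      en <- lo + rng[oke[length(oke)]] - 1L
      if (en <= st) next
      # endpoint polish: each end must close with >= 5 matches in its
      # terminal 6 bases (random flanks match at only 25% per base)
      while (en - st + 1L >= min_ltr_len) {
        i <- en - lo + 1L
        if (v[i] && sum(v[(i - 5L):i]) >= 5L) break
        en <- en - 1L
      }
      while (en - st + 1L >= min_ltr_len) {
        i <- st - lo + 1L
        if (v[i] && sum(v[i:(i + 5L)]) >= 5L) break
        st <- st + 1L
      }
      ltr_len <- en - st + 1L
      if (ltr_len < min_ltr_len || ltr_len > max_ltr_len) next
      el_len <- d + ltr_len
      if (el_len < min_element_len || el_len > max_element_len) next
      ident <- mean(v[(st - lo + 1L):(en - lo + 1L)])
      if (ident < min_pair_identity) next
      cands[[length(cands) + 1L]] <- data.frame(
        chrom = name, start = st, end = en + d,
        ltr5_start = st, ltr5_end = en,
        ltr3_start = st + d, ltr3_end = en + d,
        ltr_length = ltr_len, pair_identity = ident,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0L) return(empty)
  out <- unique(do.call(rbind, cands))
  # collapse near-duplicates (same spacing, overlapping LTRs): keep best
  out <- out[order(-out$pair_identity, out$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(out))
  nested <- rep(FALSE, nrow(out))
  for (i in seq_len(nrow(out))) {
    kept <- which(keep)
    ok <- TRUE
    for (j in kept) {
      overlaps <- out$start[i] <= out$end[j] && out$end[i] >= out$start[j]
      if (!overlaps) next
      inside_internal <- out$start[i] > out$ltr5_end[j] &&
        out$end[i] < out$ltr3_start[j]
      contains_internal <- out$start[j] > out$ltr5_end[i] &&
        out$end[j] < out$ltr3_start[i]
      if (inside_internal) {
        nested[i] <- TRUE
      } else if (contains_internal) {
        nested[j] <- TRUE
      } else {
        ok <- FALSE
        break
      }
    }
    if (ok) keep[i] <- TRUE
  }
  out$nested <- nested
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ltr_elements", "data.frame"))
}

#' LTR-LTR divergence of one element
#'
#' Global alignment of the two LTR sequences; identity is matches over
#' aligned columns excluding gap columns, and K is either the raw
#' per-site difference `1 - identity` or its Jukes-Cantor correction
#' `-(3/4) ln(1 - (4/3)(1 - identity))`. Alignments with identity below
#' 0.5 are flagged unreliable (and are excluded from population
#' summaries).
#'
#' @param ltr5,ltr3 LTR sequences (character / `DNAString`).
#' @param correction `"raw"` or `"JC69"`.
#' @return List: `identity`, `K`, `reliable`.
#' @export
ltr_divergence <- function(ltr5, ltr3, correction = c("raw", "JC69")) {
  correction <- match.arg(correction)
  a <- Biostrings::DNAString(toupper(as.character(ltr5)))
  b <- Biostrings::DNAString(toupper(as.character(ltr3)))
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = submat,
                                       gapOpening = 5, gapExtension = 2)
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  identity <- if (nm + nmm > 0) nm / (nm + nmm) else 0
  p <- 1 - identity
  K <- if (correction == "raw") p else {
    if (p >= 0.75) Inf else -0.75 * log(1 - 4 * p / 3)
  }
  list(identity = identity, K = K, reliable = identity >= 0.5)
}

#' Insertion time from LTR divergence
#'
#' `T = K / (2 r)` years.
#'
#' @param K Per-site divergence between the two LTRs (>= 0).
#' @param params A [dating_params()] (or a bare rate passed as `r`).
#' @param r Substitution rate per site per year (used if `params` is
#'   missing).
#' @return Insertion age in years.
#' @export
insertion_time <- function(K, params = NULL, r = 1.3e-8) {
  if (!is.null(params)) {
    stopifnot(inherits(params, "dating_params"))
    r <- params$r
  }
  if (any(K < 0)) stop("K must be non-negative", call. = FALSE)
  .check_scalar(r, "r", lo = .Machine$double.xmin)
  K / (2 * r)
}

#' Date detected elements in place
#'
#' Convenience wrapper: extracts both LTR sequences of every element,
#' computes divergence and insertion time, and appends `ltr_identity`,
#' `K`, `T_years` and `reliable` columns.
#'
#' @param elements An `ltr_elements` data frame.
#' @param genome Named `DNAStringSet` containing the elements'
#'   chromosomes.
#' @param params A [dating_params()].
#' @return The input with dating columns appended.
#' @export
date_elements <- function(elements, genome, params = dating_params()) {
  if (nrow(elements) == 0L) {
    elements$ltr_identity <- numeric(0)
    elements$K <- numeric(0)
    elements$T_years <- numeric(0)
    elements$reliable <- logical(0)
    return(elements)
  }
  res <- lapply(seq_len(nrow(elements)), function(i) {
    chr <- genome[[elements$chrom[i]]]
    l5 <- Biostrings::subseq(chr, elements$ltr5_start[i],
                             elements$ltr5_end[i])
    l3 <- Biostrings::subseq(chr, elements$ltr3_start[i],
                             elements$ltr3_end[i])
    ltr_divergence(l5, l3, params$correction)
  })
  elements$ltr_identity <- vapply(res, `[[`, numeric(1), "identity")
  elements$K <- vapply(res, `[[`, numeric(1), "K")
  elements$T_years <- insertion_time(elements$K, params)
  elements$reliable <- vapply(res, `[[`, logical(1), "reliable")
  elements
}

#' Classify elements as centromeric or not
#'
#' An element is centromeric iff its midpoint falls inside any centromere
#' call; this partitions the elements (boundary-straddling elements
#' follow their midpoint).
#'
#' @param elements An `ltr_elements` data frame.
#' @param calls A `centromere_calls` data frame.
#' @return The input with a `location_class` column
#'   (`"centromeric"` / `"non_centromeric"`).
#' @export
classify_by_centromere <- function(elements, calls) {
  if (nrow(elements) == 0L) {
    elements$location_class <- character(0)
    return(elements)
  }
  mid0 <- (elements$start - 1L + elements$end) %/% 2L
  cls <- rep("non_centromeric", nrow(elements))
  for (i in seq_len(nrow(calls))) {
    inside <- elements$chrom == calls$chrom[i] &
      mid0 >= calls$start[i] & mid0 < calls$end[i]
    cls[inside] <- "centromeric"
  }
  elements$location_class <- cls
  elements
}

#' Compare centromeric and non-centromeric element populations
#'
#' Per-class median LTR identity, a two-sided Wilcoxon rank-sum test on
#' the identities, and binned identity histograms for plotting.
#' Unreliable elements (identity < 0.5) are excluded.
#'
#' @param elements Dated, classified elements (columns `ltr_identity`,
#'   `location_class`; optional `reliable`).
#' @param breaks Histogram breaks on identity.
#' @return List: `medians` (named), `wilcox` (`statistic`, `p_value`, or
#'   `NULL` when a class is absent), `histograms`, `absent_classes`.
#' @export
compare_populations <- function(elements,
                                breaks = seq(0.5, 1, by = 0.005)) {
  el <- elements
  if (!is.null(el$reliable)) el <- el[el$reliable, , drop = FALSE]
  classes <- c("centromeric", "non_centromeric")
  ids <- lapply(classes, function(cl)
    el$ltr_identity[el$location_class == cl])
  names(ids) <- classes
  absent <- classes[vapply(ids, length, integer(1)) == 0L]
  medians <- vapply(ids, function(x)
    if (length(x)) stats::median(x) else NA_real_, numeric(1))
  wil <- NULL
  if (length(absent) == 0L) {
    wt <- suppressWarnings(stats::wilcox.test(ids$centromeric,
                                              ids$non_centromeric,
                                              alternative = "two.sided"))
    wil <- list(statistic = unname(wt$statistic), p_value = wt$p.value)
  }
  hists <- lapply(ids, function(x) {
    if (length(x) == 0L) return(NULL)
    h <- graphics::hist(pmin(pmax(x, min(breaks)), max(breaks)),
                        breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  })
  list(medians = medians, wilcox = wil, histograms = hists,
       absent_classes = absent)
}

#' Cluster elements into clades
#'
#' Single-linkage agglomerative clustering on pairwise whole-element
#' sequence identity (global alignment, matches over aligned columns
#' including internal gaps); clusters at the `linkage_identity`
#' threshold are the clades. Clade labels are assigned in order of first
#' appearance, so the result is deterministic.
#'
#' @param element_seqs `DNAStringSet` / character vector of full element
#'   sequences (>= 2).
#' @param linkage_identity Identity threshold joining two clades.
#' @return Integer vector of clade assignments (parallel to input).
#' @export
cluster_clades <- function(element_seqs, linkage_identity = 0.7) {
  if (is.character(element_seqs)) {
    element_seqs <- Biostrings::DNAStringSet(element_seqs)
  }
  m <- length(element_seqs)
  if (m < 2L) stop("need at least 2 elements", call. = FALSE)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  dist_mat <- matrix(0, m, m)
  for (i in seq_len(m - 1L)) {
    aln <- Biostrings::pairwiseAlignment(
      element_seqs[(i + 1L):m], element_seqs[[i]], type = "global",
      substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
    ident <- Biostrings::pid(aln, type = "PID1") / 100
    dist_mat[i, (i + 1L):m] <- 1 - ident
    dist_mat[(i + 1L):m, i] <- 1 - ident
  }
  hc <- stats::hclust(stats::as.dist(dist_mat), method = "single")
  raw <- stats::cutree(hc, h = 1 - linkage_identity)
  # renumber in order of first appearance
  first <- !duplicated(raw)
  lut <- stats::setNames(seq_len(sum(first)), raw[first])
  as.integer(lut[as.character(raw)])
}

#' Export elements as GFF3
#'
#' @param elements An `ltr_elements` data frame (optionally dated).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ltr_gff3 <- function(elements, path) {
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(elements))) {
    id <- sprintf("LTRRT%04d", i)
    attrs <- sprintf("ID=%s", id)
    if (!is.null(elements$ltr_identity)) {
      attrs <- paste0(attrs, sprintf(";ltr_identity=%.4f",
                                     elements$ltr_identity[i]))
    }
    lines <- c(lines,
      sprintf("%s\tcentromap\trepeat_region\t%d\t%d\t.\t+\t.\t%s",
              elements$chrom[i], elements$start[i], elements$end[i], attrs),
      sprintf("%s\tcentromap\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tParent=%s",
              elements$chrom[i], elements$ltr5_start[i],
              elements$ltr5_end[i], id),
      sprintf("%s\tcentromap\tlong_terminal_repeat\t%d\t%d\t.\t+\t.\tParent=%s",
              elements$chrom[i], elements$ltr3_start[i],
              elements$ltr3_end[i], id))
  }
  writeLines(lines, path)
  invisible(path)
}
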