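# De-novo tandem-satellite discovery and monomer consensus building.
#
# Periodicity is detected from the spacing of repeated k-mers: inside a
# tandem array, identical k-mers recur at multiples of the monomer
# length, so the modal spacing of consecutive recurrences seeds a
# candidate period. Candidates are refined by maximising the fraction of
# positions matching their image one period downstream, boundaries are
# found from the same match indicator, and monomer copies are cut and
# combined into a majority-rule consensus. Because the cut phase of a
# tandem monomer is arbitrary, consensus sequences are reported in
# canonical (lexicographically minimal) rotation.

# k-mer spacing votes for one sequence: data.frame(pos, d), pos 1-based
# position of the earlier occurrence, d exact spacing to the next
# occurrence of the same k-mer.
.spacing_votes <- function(s, k, min_period, max_period) {
  if (nchar(s) < 2L * min_period) {
    return(data.frame(pos = integer(0), d = integer(0)))
  }
  v <- .kmer_spacings(s, k, min_period, max_period)
  v[order(v$pos, v$d), , drop = FALSE]
}

# Refine one candidate (approximate interval [a,b], seed period m) on the
# character vector sc. Returns NULL or list(start, end, period).
.refine_array <- function(sc, a, b, m, min_period, max_period) {
  n <- length(sc)
  ps <- max(min_period, m - 6L):min(max_period, m + 6L)
  lo <- max(1L, a - 2L * m)
  hi <- min(n, b + 2L * m)
  frac <- vapply(ps, function(p) {
    idx <- lo:(min(hi, n - p))
    if (length(idx) < p) return(0)
    mean(sc[idx] == sc[idx + p] & sc[idx] != "N")
  }, numeric(1))
  p <- ps[which.max(frac)]
  if (max(frac) < 0.5) return(NULL)
  # boundary search on the period-p match indicator
  ext <- max(5L * p, 1000L)
  lo <- max(1L, a - ext)
  hi <- min(n - p, b + ext)
  if (hi <= lo) return(NULL)
  idx <- lo:hi
  v <- as.numeric(sc[idx] == sc[idx + p] & sc[idx] != "N")
  win <- min(p, length(v))
  cs <- cumsum(c(0, v))
  sm <- (cs[(win + 1L):(length(v) + 1L)] - cs[1L:(length(v) - win + 1L)]) / win
  # sm[j] is mean of v[j .. j+win-1]; high where inside the array
  high <- sm >= 0.55
  if (!any(high)) return(NULL)
  runs <- rle(high)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  centre <- round(((a + b) / 2 - lo + 1L))
  cand <- which(runs$values & starts <= centre & ends >= centre)
  if (length(cand) == 0L) cand <- which(runs$values)[
    which.max(runs$lengths[runs$values])]
  if (length(cand) == 0L) return(NULL)
  arr_start <- lo + starts[cand[1L]] - 1L
  arr_end <- lo + ends[cand[1L]] - 1L + win - 1L + p
  arr_end <- min(arr_end, n)
  list(start = arr_start, end = arr_end, period = p)
}

#' Find tandem satellite arrays de novo
#'
#' @param seq A chromosome (`DNAString`, one-element `DNAStringSet`, or
#'   character string).
#' @param name Chromosome name for the output.
#' @param min_period,max_period Period search range in bases.
#' @param min_copies Minimum copy number for a reported array.
#' @param k Seed k-mer length.
#' @param min_votes Minimum number of k-mer spacing votes supporting a
#'   candidate (false-positive guard on random sequence).
#' @return Data frame of class `satellite_arrays`: `chrom`, `start`,
#'   `end` (1-based closed), `period`, `copy_number`,
#'   `mean_copy_identity`, `consensus` (canonical rotation). Attribute
#'   `monomers` holds the cut monomer copies per array.
#' @export
find_tandem_arrays <- function(seq, name = "chr", min_period = 50L,
                               max_period = 1000L, min_copies = 3L,
                               k = 12L, min_votes = 10L) {
  if (methods::is(seq, "DNAStringSet")) {
    if (!is.null(names(seq))) name <- names(seq)[1L]
    seq <- seq[[1L]]
  }
  s <- toupper(as.character(seq))
  n <- nchar(s)
  empty <- structure(
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               period = integer(0), copy_number = integer(0),
               mean_copy_identity = numeric(0), consensus = character(0),
               stringsAsFactors = FALSE),
    class = c("satellite_arrays", "data.frame"), monomers = list())
  if (n <= 2L * min_period) return(empty)
  votes <- .spacing_votes(s, k, min_period, max_period)
  if (nrow(votes) == 0L) return(empty)
  sc <- .chars(s)

  arrays <- list()
  monomers <- list()
  remaining <- votes
  repeat {
    if (nrow(remaining) < min_votes) break
    tt <- table(remaining$d)
    m <- as.integer(names(tt)[which.max(tt)])
    if (max(tt) < min_votes) break
    vm <- remaining[remaining$d == m, , drop = FALSE]
    # cluster supporting positions into runs (gap <= 3 periods)
    ord <- order(vm$pos)
    pos <- vm$pos[ord]
    grp <- cumsum(c(1L, diff(pos) > max(3L * m, 400L)))
    for (g in unique(grp)) {
      pg <- pos[grp == g]
      if (length(pg) < min_votes) next
      if (max(pg) - min(pg) < (min_copies - 2L) * m) next
      ref <- .refine_array(sc, min(pg), max(pg) + m + k, m,
                           min_period, max_period)
      if (is.null(ref)) next
      p <- ref$period
      nc0 <- (ref$end - ref$start + 1L) %/% p
      if (nc0 < min_copies) next
      # rough consensus from interior copies, then consensus-guided
      # boundary polish on the per-position match indicator
      cuts0 <- ref$start + (seq_len(nc0) - 1L) * p
      inner <- if (nc0 > 4L) cuts0[2L:(nc0 - 1L)] else cuts0
      rough <- build_consensus(substring(s, inner, inner + p - 1L))
      rchars <- .chars(rough)
      mar <- max(2L * p, 500L)
      lo <- max(1L, ref$start - mar)
      hi <- min(n, ref$end + mar)
      idx <- lo:hi
      phase <- ((idx - ref$start) %% p) + 1L
      u <- (sc[idx] == rchars[phase]) & sc[idx] != "N"
      w2 <- 20L   # spurious pass rate in random flank ~3e-7 per base
      if (length(u) <= w2) next
      cs2 <- cumsum(c(0, u))
      fwd <- (cs2[(w2 + 1L):(length(u) + 1L)] -
                cs2[1L:(length(u) - w2 + 1L)]) / w2
      ok_start <- which(u[seq_along(fwd)] & fwd >= 0.7)
      bwd_pos <- w2:length(u)
      bwd <- (cs2[bwd_pos + 1L] - cs2[bwd_pos - w2 + 1L]) / w2
      ok_end <- bwd_pos[u[bwd_pos] & bwd >= 0.7]
      if (length(ok_start) == 0L || length(ok_end) == 0L) next
      arr_start <- lo + ok_start[1L] - 1L
      arr_end <- lo + ok_end[length(ok_end)] - 1L
      len <- arr_end - arr_start + 1L
      if (len %/% p < min_copies) next
      # interim identity for arbitration; consensus is built after
      # overlap resolution (boundaries may still be trimmed)
      uin <- u[(arr_start - lo + 1L):(arr_end - lo + 1L)]
      arrays[[length(arrays) + 1L]] <- data.frame(
        chrom = name, start = arr_start, end = arr_end, period = p,
        polish_identity = mean(uin), stringsAsFactors = FALSE)
    }
    # drop every vote covered by an accepted array (removes harmonics)
    if (length(arrays)) {
      cov <- do.call(rbind, arrays)
      inside <- rep(FALSE, nrow(remaining))
      for (i in seq_len(nrow(cov))) {
        inside <- inside | (remaining$pos >= cov$start[i] &
                              remaining$pos <= cov$end[i])
      }
      remaining <- remaining[!inside & remaining$d != m, , drop = FALSE]
    } else {
      remaining <- remaining[remaining$d != m, , drop = FALSE]
    }
  }
  if (length(arrays) == 0L) return(empty)
  out <- do.call(rbind, arrays)
  # arbitration by higher polish identity: boundary collisions up to one
  # period are trimmed away from the already-kept array; larger overlaps
  # drop the weaker candidate
  keep <- rep(FALSE, nrow(out))
  for (i in order(-out$polish_identity, out$start)) {
    ok <- TRUE
    for (j in which(keep)) {
      ov <- min(out$end[i], out$end[j]) - max(out$start[i], out$start[j]) + 1L
      if (ov <= 0L) next
      if (ov > out$period[i]) { ok <- FALSE; break }
      if (out$start[j] > out$start[i]) {
        out$end[i] <- out$start[j] - 1L     # kept array on the right
      } else {
        out$start[i] <- out$end[j] + 1L     # kept array on the left
      }
      if (out$end[i] - out$start[i] + 1L < min_copies * out$period[i]) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep[i] <- TRUE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  # final monomer cut and majority consensus per surviving interval
  monomers <- vector("list", nrow(out))
  res <- vector("list", nrow(out))
  for (i in seq_len(nrow(out))) {
    p <- out$period[i]
    nc <- (out$end[i] - out$start[i] + 1L) %/% p
    cuts <- out$start[i] + (seq_len(nc) - 1L) * p
    copies <- substring(s, cuts, cuts + p - 1L)
    cons <- build_consensus(copies)
    ident <- vapply(copies, function(cp)
      1 - .hamming_chars(.chars(cp), .chars(cons)) / p, numeric(1))
    res[[i]] <- data.frame(
      chrom = name, start = out$start[i], end = out$end[i], period = p,
      copy_number = nc, mean_copy_identity = mean(ident),
      consensus = canonical_rotation(cons), stringsAsFactors = FALSE)
    monomers[[i]] <- unname(copies)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  structure(out, class = c("satellite_arrays", "data.frame"),
            monomers = monomers)
}

#' Majority-rule consensus of monomer copies
#'
#' Copies are star-aligned to the medoid copy and the per-column majority
#' base is taken (ties broken alphabetically); the consensus has the
#' medoid's length. When all copies have equal length (the
#' substitution-only case) the star alignment is the identity and the
#' vote is purely columnar.
#'
#' @param copies Character vector or `DNAStringSet` of >= 3 monomer
#'   copies.
#' @return Consensus string.
#' @export
build_consensus <- function(copies) {
  if (methods::is(copies, "DNAStringSet")) copies <- as.character(copies)
  copies <- toupper(copies)
  if (length(copies) < 3L) {
    stop("need at least 3 copies to build a consensus", call. = FALSE)
  }
  lens <- nchar(copies)
  if (length(unique(lens)) == 1L) {
    mat <- matrix(unlist(strsplit(copies, "", fixed = TRUE)),
                  nrow = lens[1L])
    aligned <- mat  # rows = columns of the monomer
  } else {
    # medoid = copy of median length, first on ties
    med_len <- sort(lens)[ceiling(length(lens) / 2)]
    medoid <- copies[which(lens == med_len)[1L]]
    L <- nchar(medoid)
    aligned <- matrix("-", nrow = L, ncol = length(copies))
    submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                       mismatch = -1)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(copies), Biostrings::DNAString(medoid),
      type = "global", substitutionMatrix = submat,
      gapOpening = 5, gapExtension = 2)
    pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")
    sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")
    for (j in seq_along(copies)) {
      keep <- sa[[j]] != "-"
      aligned[, j] <- pa[[j]][keep]
    }
  }
  vote <- apply(aligned, 1L, function(col) {
    col <- col[col %in% BASES]
    if (length(col) == 0L) return("N")
    tt <- table(factor(col, levels = BASES))
    BASES[which.max(tt)]   # which.max takes the first (alphabetical) tie
  })
  .collapse(vote)
}

# Circular, strand-aware identity between two monomer consensus strings:
# best local alignment of `a` against the doubled `b` (both strands),
# scored as matches over the shorter monomer length.
circular_identity <- function(a, b) {
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  dbl <- Biostrings::DNAString(strrep(b, 2L))
  pat <- Biostrings::DNAStringSet(c(a, .revcomp_str(a)))
  aln <- Biostrings::pairwiseAlignment(pat, dbl, type = "local",
                                       substitutionMatrix = submat,
                                       gapOpening = 5, gapExtension = 2)
  max(Biostrings::nmatch(aln)) / min(nchar(a), nchar(b))
}

#' Group satellite arrays into families
#'
#' Arrays are greedily merged (largest total span first) into families by
#' circular-rotation-aware consensus identity; each family is named
#' `CentFs<consensus length>` after its representative consensus, with
#' letter suffixes on length collisions.
#'
#' @param arrays A `satellite_arrays` data frame (possibly concatenated
#'   across chromosomes with [rbind()]).
#' @param identity_min Reciprocal identity threshold for family
#'   membership.
#' @return List with `families` (data frame: `family`, `consensus`,
#'   `period`, `n_arrays`, `total_span_mb`) and `arrays` (input with a
#'   `family` column).
#' @export
classify_families <- function(arrays, identity_min = 0.8) {
  if (nrow(arrays) == 0L) {
    return(list(
      families = data.frame(family = character(0), consensus = character(0),
                            period = integer(0), n_arrays = integer(0),
                            total_span_mb = numeric(0),
                            stringsAsFactors = FALSE),
      arrays = cbind(arrays, family = character(0))))
  }
  span <- arrays$end - arrays$start + 1L
  ord <- order(-span, arrays$consensus)  # deterministic, order-invariant
  rep_cons <- character(0)
  fam_of <- integer(nrow(arrays))
  for (i in ord) {
    assigned <- FALSE
    for (f in seq_along(rep_cons)) {
      if (circular_identity(arrays$consensus[i], rep_cons[f]) >=
          identity_min &&
          circular_identity(rep_cons[f], arrays$consensus[i]) >=
          identity_min) {
        fam_of[i] <- f
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_cons <- c(rep_cons, arrays$consensus[i])
      fam_of[i] <- length(rep_cons)
    }
  }
  fam_len <- nchar(rep_cons)
  name <- paste0("CentFs", fam_len)
  # disambiguate equal-length families with letter suffixes
  for (len in unique(fam_len[duplicated(fam_len)])) {
    idx <- which(fam_len == len)
    name[idx] <- paste0("CentFs", len, c("", letters[seq_len(
      length(idx) - 1L)]))
  }
  families <- data.frame(
    family = name,
    consensus = rep_cons,
    period = fam_len,
    n_arrays = as.integer(table(factor(fam_of,
                                       levels = seq_along(rep_cons)))),
    total_span_mb = vapply(seq_along(rep_cons), function(f)
      sum(span[fam_of == f]) / 1e6, numeric(1)),
    stringsAsFactors = FALSE)
  arrays$family <- name[fam_of]
  o <- order(-families$total_span_mb, families$family)
  families <- families[o, , drop = FALSE]
  rownames(families) <- NULL
  list(families = families, arrays = arrays)
}

#' Satellite-family composition of centromere calls
#'
#' For each called centromere, the base-pair overlap with each family's
#' arrays as a fraction of centromere length; the dominant family is
#' flagged.
#'
#' @param calls A `centromere_calls` data frame.
#' @param arrays Arrays with a `family` column (from
#'   [classify_families()]).
#' @return Data frame: `chrom`, `cen_start`, `cen_end`, `family`,
#'   `fraction`, `dominant`.
#' @export
centromere_composition <- function(calls, arrays) {
  out <- list()
  fams <- unique(arrays$family)
  for (i in seq_len(nrow(calls))) {
    cs <- calls$start[i] + 1L   # to 1-based closed
    ce <- calls$end[i]
    clen <- ce - cs + 1L
    fr <- vapply(fams, function(f) {
      sub <- arrays[arrays$family == f & arrays$chrom == calls$chrom[i], ,
                    drop = FALSE]
      if (nrow(sub) == 0L) return(0)
      ov <- pmin(sub$end, ce) - pmax(sub$start, cs) + 1L
      sum(pmax(ov, 0L)) / clen
    }, numeric(1))
    dom <- if (length(fr) && max(fr) > 0) fams[which.max(fr)] else
      NA_character_
    out[[i]] <- data.frame(
      chrom = calls$chrom[i], cen_start = calls$start[i],
      cen_end = calls$end[i], family = fams, fraction = as.numeric(fr),
      dominant = fams == ifelse(is.na(dom), "", dom),
      stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), cen_start = integer(0),
               cen_end = integer(0), family = character(0),
               fraction = numeric(0), dominant = logical(0))
  rownames(res) <- NULL
  res
}

#' Windowed dot-plot self-similarity matches
#'
#' Both sequences are cut into non-overlapping windows (stride = window)
#' and every window pair with ungapped identity at or above
#' `min_identity` is reported on both strands; reverse-strand matches are
#' tagged. Positions are 0-based window starts on the forward
#' coordinates of each sequence.
#'
#' @param seqA,seqB Sequences (character / `DNAString`).
#' @param window Window size in bases.
#' @param min_identity Identity threshold.
#' @return Data frame of class `dotplot_matches`: `posA`, `posB`,
#'   `strand`, `identity`.
#' @export
dotplot_matrix <- function(seqA, seqB, window = 100L, min_identity = 0.8) {
  a <- toupper(as.character(seqA))
  b <- toupper(as.character(seqB))
  if (nchar(a) < window || nchar(b) < window) {
    stop("both sequences must be at least one window long", call. = FALSE)
  }
  win_chars <- function(s) {
    n <- nchar(s) %/% window
    starts <- (seq_len(n) - 1L) * window + 1L
    w <- substring(s, starts, starts + window - 1L)
    list(mat = matrix(unlist(strsplit(w, "", fixed = TRUE)),
                      nrow = window),
         starts0 = starts - 1L)
  }
  A <- win_chars(a)
  B <- win_chars(b)
  Brc <- win_chars(.revcomp_str(b))
  nB <- nchar(b)
  res <- list()
  for (i in seq_along(A$starts0)) {
    av <- A$mat[, i]
    okA <- av != "N"
    idf <- colSums((A$mat[, i] == B$mat) & okA & (B$mat != "N")) / window
    hit <- which(idf >= min_identity)
    if (length(hit)) {
      res[[length(res) + 1L]] <- data.frame(
        posA = A$starts0[i], posB = B$starts0[hit], strand = "+",
        identity = idf[hit], stringsAsFactors = FALSE)
    }
    idr <- colSums((A$mat[, i] == Brc$mat) & okA & (Brc$mat != "N")) / window
    hit <- which(idr >= min_identity)
    if (length(hit)) {
      # map reverse-complement window start back to forward coordinates
      posB_fwd <- nB - (Brc$starts0[hit] + window)
      res[[length(res) + 1L]] <- data.frame(
        posA = A$starts0[i], posB = posB_fwd, strand = "-",
        identity = idr[hit], stringsAsFactors = FALSE)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(posA = integer(0), posB = integer(0),
               strand = character(0), identity = numeric(0))
  rownames(out) <- NULL
  structure(out, class = c("dotplot_matches", "data.frame"),
            window = as.integer(window))
}
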