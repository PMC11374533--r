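# Nucleosome phasing on satellite trimer consensus sequences.
#
# Fragments are aligned to three concatenated copies of a monomer
# consensus (the trimer) so alignments near monomer junctions are not
# penalised; midpoints landing in the central copy are folded to monomer
# coordinates, and repeated positioning shows up as peaks in the
# midpoint histogram. The monomer is treated as circular throughout.

#' Build a trimer consensus
#'
#' Three concatenated copies of the monomer consensus. Input that is
#' itself a perfect three-fold concatenation is rejected (a trimer of a
#' trimer is never intended).
#'
#' @param consensus Monomer consensus (>= 50 bases).
#' @return Trimer string of length exactly `3 * nchar(consensus)`.
#' @export
make_trimer <- function(consensus) {
  consensus <- toupper(as.character(consensus))
  L <- nchar(consensus)
  if (L < 50L) stop("consensus must be >= 50 bases", call. = FALSE)
  if (L %% 3L == 0L) {
    third <- L %/% 3L
    parts <- substring(consensus, c(1L, third + 1L, 2L * third + 1L),
                       c(third, 2L * third, L))
    if (parts[1L] == parts[2L] && parts[2L] == parts[3L]) {
      stop("input is already a trimer (three identical copies)",
           call. = FALSE)
    }
  }
  strrep(consensus, 3L)
}

#' Map fragments to a trimer and collect midpoints
#'
#' Each fragment sequence is locally aligned to the trimer on both
#' strands; fragments reaching `min_identity` (matches over gap-free
#' aligned columns) contribute the midpoint of their footprint on the
#' trimer, `floor((start0 + end0) / 2)` in 0-based trimer coordinates.
#' A numeric input is accepted as precomputed 0-based midpoints
#' (simulated data short-cut) and passed through.
#'
#' @param fragments `DNAStringSet` / character vector of fragment
#'   sequences, or numeric midpoints.
#' @param trimer Trimer string from [make_trimer()].
#' @param min_identity Identity threshold for a fragment to count.
#' @param min_aligned Minimum aligned (gap-free) bases; short spurious
#'   local matches are rejected.
#' @param method `"seed"` (default): seed-and-vote ungapped placement
#'   (exact under substitution-only divergence, fast); `"align"`: full
#'   Smith-Waterman local alignment.
#' @param recenter Because the trimer is exactly periodic, any footprint
#'   shifted by one monomer is a co-optimal placement; when `TRUE`
#'   (default) the placement whose midpoint lies in the central copy is
#'   preferred, so central-copy folding keeps the full signal. `FALSE`
#'   reports the leftmost placement.
#' @return List with `midpoints` (0-based positions on the trimer),
#'   `n_mapped` and `n_unmapped`.
#' @export
map_fragments_to_trimer <- function(fragments, trimer, min_identity = 0.8,
                                    min_aligned = 50L,
                                    method = c("seed", "align"),
                                    recenter = TRUE) {
  method <- match.arg(method)
  if (is.numeric(fragments)) {
    if (any(fragments < 0 | fragments >= nchar(trimer))) {
      stop("precomputed midpoints outside trimer bounds", call. = FALSE)
    }
    return(list(midpoints = as.integer(fragments),
                n_mapped = length(fragments), n_unmapped = 0L))
  }
  if (is.character(fragments)) {
    fragments <- Biostrings::DNAStringSet(toupper(fragments))
  }
  subject <- Biostrings::DNAString(trimer)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                     mismatch = -1)
  score_best <- rep(-Inf, length(fragments))
  mid_best <- rep(NA_integer_, length(fragments))
  ident_best <- rep(0, length(fragments))
  alen_best <- rep(0L, length(fragments))
  for (pat in list(fragments, Biostrings::reverseComplement(fragments))) {
    if (method == "seed") {
      sm <- .seed_map(as.character(pat), trimer)
      nm <- sm$matches
      alen <- sm$overlap
      sc <- ifelse(is.na(nm), -Inf, 2 * nm - alen)
      nm[is.na(nm)] <- 0L
      alen[is.na(alen)] <- 1L
      ident <- nm / alen
      nmm <- alen - nm
      s1 <- pmax(1L, sm$offset0 + 1L)
      e1 <- pmin(nchar(trimer), sm$offset0 + Biostrings::width(pat))
      s1[is.na(s1)] <- 1L
      e1[is.na(e1)] <- 1L
    } else {
      aln <- Biostrings::pairwiseAlignment(pat, subject, type = "local",
                                           substitutionMatrix = submat,
                                           gapOpening = 5, gapExtension = 2)
      sc <- Biostrings::score(aln)
      nm <- Biostrings::nmatch(aln)
      nmm <- Biostrings::nmismatch(aln)
      ident <- ifelse(nm + nmm > 0, nm / (nm + nmm), 0)
      srng <- IRanges::ranges(Biostrings::subject(aln))
      s1 <- IRanges::start(srng)
      e1 <- IRanges::end(srng)
    }
    # the trimer is exactly periodic, so a footprint shifted by one
    # monomer is a co-optimal alignment; prefer the placement whose
    # midpoint lies in the central copy (edge effects aside)
    L <- nchar(trimer) %/% 3L
    mid0 <- (s1 - 1L + e1) %/% 2L
    if (recenter) {
      up <- mid0 < L & (e1 + L) <= 3L * L
      s1[up] <- s1[up] + L; e1[up] <- e1[up] + L
      down <- mid0 >= 2L * L & (s1 - L) >= 1L
      s1[down] <- s1[down] - L; e1[down] <- e1[down] - L
      mid0 <- (s1 - 1L + e1) %/% 2L
    }
    better <- sc > score_best
    score_best[better] <- sc[better]
    mid_best[better] <- mid0[better]
    ident_best[better] <- ident[better]
    alen_best[better] <- (nm + nmm)[better]
  }
  ok <- ident_best >= min_identity & alen_best >= min_aligned &
    is.finite(score_best)
  list(midpoints = as.integer(mid_best[ok]),
       n_mapped = sum(ok), n_unmapped = sum(!ok))
}

#' Fold trimer midpoints to a monomer-coordinate profile
#'
#' By default only midpoints landing in the central monomer copy are
#' retained (avoiding alignment edge artifacts at the trimer ends);
#' `mode = "modulo"` folds all three copies. The histogram covers
#' monomer offsets 0 to `monomer_length - 1` and is smoothed with a
#' circular Gaussian kernel.
#'
#' @param midpoints 0-based midpoints on the trimer (from
#'   [map_fragments_to_trimer()]).
#' @param monomer_length Monomer length in bases.
#' @param mode `"central"` (default) or `"modulo"`.
#' @param bandwidth Gaussian kernel SD in bases.
#' @param source Label recorded in the profile (`"chip"` or `"input"`).
#' @return List of class `phasing_profile`: `histogram`, `smoothed`
#'   (length `monomer_length`), `monomer_length`, `n_retained`,
#'   `n_discarded`, `source`, `bandwidth`.
#' @export
fold_to_monomer <- function(midpoints, monomer_length,
                            mode = c("central", "modulo"),
                            bandwidth = 5, source = "chip") {
  mode <- match.arg(mode)
  L <- as.integer(monomer_length)
  if (length(midpoints) &&
      any(midpoints < 0 | midpoints >= 3L * L)) {
    stop("midpoints outside trimer bounds", call. = FALSE)
  }
  if (mode == "central") {
    keep <- midpoints >= L & midpoints < 2L * L
    offs <- midpoints[keep] - L
    n_disc <- sum(!keep)
  } else {
    offs <- midpoints %% L
    n_disc <- 0L
  }
  h <- tabulate(offs + 1L, nbins = L)
  structure(list(
    histogram = h,
    smoothed = .smooth_circular(h, bandwidth),
    monomer_length = L,
    n_retained = length(offs),
    n_discarded = n_disc,
    source = source,
    bandwidth = bandwidth
  ), class = "phasing_profile")
}

# Circular topographic prominence of local maxima in y.
.circular_peaks <- function(y) {
  n <- length(y)
  if (n < 3L || max(y) == min(y)) {
    return(data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  nxt <- c(2:n, 1L)
  prv <- c(n, 1:(n - 1L))
  is_max <- y > y[prv] & y >= y[nxt]
  cand <- which(is_max)
  if (length(cand) == 0L) {
    return(data.frame(position = integer(0), height = numeric(0),
                      prominence = numeric(0)))
  }
  prom <- vapply(cand, function(i) {
    h <- y[i]
    walk <- function(step) {
      j <- i
      lo <- h
      for (s in seq_len(n)) {
        j <- ((j - 1L + step) %% n) + 1L
        if (y[j] > h) return(lo)
        lo <- min(lo, y[j])
      }
      NA_real_   # no higher value anywhere: global max
    }
    l <- walk(-1L)
    r <- walk(1L)
    if (is.na(l) || is.na(r)) return(h - min(y))
    h - max(l, r)
  }, numeric(1))
  data.frame(position = cand - 1L, height = y[cand], prominence = prom)
}

#' Call phase peaks on a monomer profile
#'
#' Local maxima of the smoothed profile (circular topology) with
#' topographic prominence at least `min_prominence` times the profile
#' maximum, thinned so peaks are at least `min_separation` bases apart
#' (higher peak wins).
#'
#' @param profile A `phasing_profile`.
#' @param min_prominence Prominence threshold as a fraction of the
#'   profile maximum.
#' @param min_separation Minimum circular distance between reported
#'   peaks, in bases.
#' @return Data frame of class `phase_peaks`: `position` (0-based
#'   monomer offset, sorted), `height`, `prominence`.
#' @export
call_phase_peaks <- function(profile, min_prominence = 0.25,
                             min_separation = 40L) {
  stopifnot(inherits(profile, "phasing_profile"))
  y <- profile$smoothed
  L <- profile$monomer_length
  pk <- .circular_peaks(y)
  if (nrow(pk)) {
    pk <- pk[pk$prominence >= min_prominence * max(y), , drop = FALSE]
  }
  if (nrow(pk) > 1L) {
    pk <- pk[order(-pk$height), , drop = FALSE]
    keep <- logical(nrow(pk))
    kept_pos <- integer(0)
    for (i in seq_len(nrow(pk))) {
      p <- pk$position[i]
      d <- abs(p - kept_pos)
      d <- pmin(d, L - d)
      if (all(d >= min_separation)) {
        keep[i] <- TRUE
        kept_pos <- c(kept_pos, p)
      }
    }
    pk <- pk[keep, , drop = FALSE]
  }
  pk <- pk[order(pk$position), , drop = FALSE]
  rownames(pk) <- NULL
  structure(pk, class = c("phase_peaks", "data.frame"))
}

#' Circular concordance between two phasing profiles
#'
#' Pearson correlation of the smoothed profiles at zero lag and at the
#' best circular shift.
#'
#' @param chip,input `phasing_profile` objects on the same monomer
#'   length.
#' @return List: `correlation` (zero lag), `best_lag` (bases, shift of
#'   `input` maximising correlation), `best_correlation`.
#' @export
phase_concordance <- function(chip, input) {
  stopifnot(inherits(chip, "phasing_profile"),
            inherits(input, "phasing_profile"))
  if (chip$monomer_length != input$monomer_length) {
    stop("profiles have different monomer lengths", call. = FALSE)
  }
  a <- chip$smoothed
  b <- input$smoothed
  n <- length(a)
  cors <- vapply(0:(n - 1L), function(lag) {
    bs <- b[((seq_len(n) - 1L + lag) %% n) + 1L]
    if (stats::sd(a) == 0 || stats::sd(bs) == 0) return(NA_real_)
    stats::cor(a, bs)
  }, numeric(1))
  best <- which.max(cors)
  list(correlation = cors[1L],
       best_lag = best - 1L,
       best_correlation = cors[best])
}
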