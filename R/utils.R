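# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
.revcomp_str <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

.chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.collapse <- function(x) paste0(x, collapse = "")

# Random i.i.d. nucleotide sequence with a given GC fraction.
.random_dna <- function(n, gc = 0.36) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  .collapse(sample(BASES, n, replace = TRUE, prob = p))
}

# Substitution-only mutation: each site flips to one of the three other
# bases with probability `rate`. Operates on a character vector of bases.
.mutate_chars <- function(chars, rate) {
  if (rate <= 0 || length(chars) == 0L) return(chars)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit) == 0L) return(chars)
  cur <- chars[hit]
  # draw uniformly among the three non-current bases
  off <- sample.int(3L, length(hit), replace = TRUE)
  idx <- match(cur, BASES)
  idx[is.na(idx)] <- 1L   # N treated as A for replacement purposes
  chars[hit] <- BASES[((idx - 1L + off) %% 4L) + 1L]
  chars
}

.mutate_str <- function(s, rate) .collapse(.mutate_chars(.chars(s), rate))

#' Canonical rotation of a circular sequence
#'
#' The lexicographically minimal rotation. The phase of a tandem monomer
#' is unidentifiable (an array can be cut at any offset), so consensus
#' monomers are reported -- and should be compared -- in this canonical
#' rotation.
#'
#' @param s A sequence string.
#' @return The minimal rotation of `s`.
#' @export
canonical_rotation <- function(s) {
  n <- nchar(s)
  if (n <= 1L) return(s)
  d <- paste0(s, s)
  rots <- substring(d, seq_len(n), seq_len(n) + n - 1L)
  sort(rots, method = "radix")[1L]
}

# Circular Gaussian kernel smoothing of a numeric vector (index treated as
# a position on a circle). bw is the kernel standard deviation in bases.
.smooth_circular <- function(y, bw) {
  n <- length(y)
  if (bw <= 0 || n < 2L) return(y)
  half <- min(n %/% 2L, ceiling(4 * bw))
  off <- (-half):half
  k <- exp(-(off^2) / (2 * bw^2))
  k <- k / sum(k)
  out <- numeric(n)
  for (j in seq_along(off)) {
    out <- out + k[j] * y[((seq_len(n) - 1L + off[j]) %% n) + 1L]
  }
  out
}

# Hamming mismatch count between two equal-length base vectors; N never
# counts as a match.
.hamming_chars <- function(a, b) {
  stopifnot(length(a) == length(b))
  sum(a != b | a == "N" | b == "N")
}

# Positions (1-based) of all occurrences of length-k substrings repeated
# on the same strand -- used by the tandem-array and LTR seed scans.
.kmer_vector <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# Exact numeric k-mer codes (base-4; requires 4^k < 2^53, i.e. k <= 26).
# Returns codes and a validity mask (k-mers containing N are invalid).
.kmer_codes <- function(s, k) {
  v <- utf8ToInt(s)
  lut <- rep(-1L, 128L)
  lut[c(65L, 67L, 71L, 84L) + 1L] <- 0:3   # A C G T
  b <- lut[v + 1L]
  n <- length(b)
  m <- n - k + 1L
  if (m < 1L) return(list(codes = numeric(0), valid = logical(0)))
  bad <- as.integer(b < 0L)
  cs <- cumsum(bad)
  badk <- cs[k:n] - c(0L, cs[seq_len(n - k)])
  bb <- as.numeric(pmax(b, 0L))
  # rolling base-4 encoding as a one-pass convolution; exact because
  # 4^k < 2^53
  f <- stats::filter(bb, filter = 4^(0:(k - 1L)), method = "convolution",
                     sides = 1L)
  val <- as.numeric(f[k:n])
  list(codes = val, valid = badk == 0L)
}

# All (pos, d) pairs of consecutive same-k-mer occurrences with spacing d
# in [min_d, max_d]; pos is the 1-based position of the earlier
# occurrence. Used for tandem periodicity votes.
.kmer_spacings <- function(s, k, min_d, max_d) {
  kc <- .kmer_codes(s, k)
  idx <- which(kc$valid)
  if (length(idx) < 2L) return(data.frame(pos = integer(0), d = integer(0)))
  codes <- kc$codes[idx]
  o <- order(codes, method = "radix")  # stable: positions ascend in runs
  cc <- codes[o]
  pp <- idx[o]
  eq <- cc[-length(cc)] == cc[-1L]
  i <- which(eq)
  if (length(i) == 0L) return(data.frame(pos = integer(0), d = integer(0)))
  d <- pp[i + 1L] - pp[i]
  keep <- d >= min_d & d <= max_d
  data.frame(pos = pp[i][keep], d = d[keep])
}

# Vectorised seed-and-vote ungapped mapper: every read is placed on
# `target` at the diagonal (offset) collecting the most exact shared
# k-mers, then scored by direct base comparison over the overlapping
# columns. Gap-free placement is exact under a substitution-only
# divergence model and orders of magnitude faster than full local
# alignment. Returns one row per read: offset0 (0-based target offset of
# read base 1, may be negative), matches, overlap (in-bounds columns);
# NA rows for reads with no shared k-mer.
.seed_map <- function(reads, target, k = 12L) {
  nr <- length(reads)
  out <- data.frame(offset0 = rep(NA_integer_, nr),
                    matches = rep(NA_integer_, nr),
                    overlap = rep(NA_integer_, nr))
  if (nr == 0L || nchar(target) < k) return(out)
  tc <- .kmer_codes(target, k)
  tv <- which(tc$valid)
  if (length(tv) == 0L) return(out)
  o <- order(tc$codes[tv], method = "radix")
  sct <- tc$codes[tv][o]
  tpos <- tv[o]

  rlen <- nchar(reads)
  cat_reads <- paste0(reads, collapse = "N")
  read_start <- cumsum(c(1L, rlen[-nr] + 1L))  # offset of each read in cat
  rc <- .kmer_codes(cat_reads, k)
  vi <- which(rc$valid)
  if (length(vi) == 0L) return(out)
  codes <- rc$codes[vi]
  # read id and in-read position of every valid k-mer
  rid <- findInterval(vi, read_start)
  rpos <- vi - read_start[rid] + 1L
  # target matches per k-mer (possibly several)
  lo <- findInterval(codes - 0.5, sct)
  hi <- findInterval(codes, sct)
  nhit <- hi - lo
  has <- nhit > 0L
  if (!any(has)) return(out)
  idx <- which(has)
  reps <- nhit[idx]
  tp <- tpos[sequence(reps) + rep(lo[idx], reps)]
  rr <- rep(rid[idx], reps)
  rp <- rep(rpos[idx], reps)
  diag <- tp - rp   # 0-based offset of read start on target
  # votes per (read, diagonal)
  key_ord <- order(rr, diag, method = "radix")
  rr <- rr[key_ord]; diag <- diag[key_ord]
  grp <- c(TRUE, rr[-1L] != rr[-length(rr)] | diag[-1L] != diag[-length(diag)])
  gid <- cumsum(grp)
  votes <- tabulate(gid)
  g_read <- rr[grp]
  g_diag <- diag[grp]
  best <- order(g_read, -votes[seq_along(g_diag)], method = "radix")
  first <- best[!duplicated(g_read[best])]
  b_read <- g_read[first]
  b_diag <- g_diag[first]
  # direct comparison over in-bounds columns
  tlen <- nchar(target)
  tchars <- .chars(target)
  s1 <- pmax(1L, b_diag + 1L)
  e1 <- pmin(tlen, b_diag + rlen[b_read])
  ok <- e1 >= s1
  b_read <- b_read[ok]; b_diag <- b_diag[ok]
  s1 <- s1[ok]; e1 <- e1[ok]
  lens <- e1 - s1 + 1L
  tgt_idx <- sequence(lens) + rep(s1 - 1L, lens)
  rd_idx <- sequence(lens) + rep(s1 - b_diag - 1L, lens) +
    rep(read_start[b_read] - 1L, lens)
  cat_chars <- .chars(cat_reads)
  eqv <- (tchars[tgt_idx] == cat_chars[rd_idx]) &
    tchars[tgt_idx] != "N" & cat_chars[rd_idx] != "N"
  mt <- rowsum(as.integer(eqv), rep(seq_along(lens), lens))[, 1L]
  out$offset0[b_read] <- b_diag
  out$matches[b_read] <- as.integer(mt)
  out$overlap[b_read] <- lens
  out
}

# validate that a value is a single finite number
.check_scalar <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]",
                 name, format(lo), format(hi)), call. = FALSE)
  }
  invisible(x)
}
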