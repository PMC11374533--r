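# Windowed CENH3 ChIP/input enrichment and functional-centromere calling.
#
# Mapped fragment density is computed in fixed windows (default 100 kb)
# along each chromosome, normalised as reads per million divided by 100,
# and the ChIP/input ratio of those normalised densities defines the
# enrichment track from which CENH3-enriched centromere domains are
# called.

# 0-based half-open windows tiling each chromosome; last window may be
# short.
.tile_windows <- function(lens, window_size) {
  out <- lapply(names(lens), function(chr) {
    n <- lens[[chr]]
    starts <- seq.int(0L, n - 1L, by = window_size)
    data.frame(chrom = chr, start = starts,
               end = pmin(starts + window_size, n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Compute a windowed fragment-density track
#'
#' Each fragment is assigned to the window containing its midpoint; the
#' window value is `(count / total_count) * 1e6 / 100` (reads per million
#' divided by 100).
#'
#' @param fragments A [fragment_set()].
#' @param genome Genome sequences or named lengths (the window frame).
#' @param window_size Window size in bases (>= 1000).
#' @return A data frame of class `density_track` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `count`, `value`, and attributes
#'   `window_size`, `label`, `total_count`.
#' @export
compute_window_density <- function(fragments, genome, window_size = 100000L) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (window_size < 1000L) stop("window_size must be >= 1 kb", call. = FALSE)
  if (fragments$total_count == 0L) {
    stop("empty fragment set: density normalization undefined", call. = FALSE)
  }
  lens <- genome_lengths(genome)
  win <- .tile_windows(lens, as.integer(window_size))
  mid0 <- fragment_midpoints(fragments)
  chr <- as.character(GenomicRanges::seqnames(fragments$fragments))
  widx <- mid0 %/% as.integer(window_size)
  key <- paste0(chr, ":", widx)
  wkey <- paste0(win$chrom, ":", win$start %/% as.integer(window_size))
  counts <- table(key)
  win$count <- as.integer(counts[wkey])
  win$count[is.na(win$count)] <- 0L
  win$value <- win$count / fragments$total_count * 1e6 / 100
  structure(win, class = c("density_track", "data.frame"),
            window_size = as.integer(window_size),
            label = fragments$label,
            total_count = fragments$total_count)
}

#' ChIP/input enrichment ratio track
#'
#' Ratio of normalised densities with a pseudocount expressed in
#' fragment-equivalents (converted to density units per track before
#' division), so sparse windows never divide by zero. Zero-input windows
#' are flagged.
#'
#' @param chip,input `density_track` objects on identical windows.
#' @param pseudocount Pseudocount in fragments (default 1).
#' @return Data frame of class `ratio_track` with columns `chrom`,
#'   `start`, `end`, `chip`, `input`, `ratio`, `log2_ratio`,
#'   `zero_input`; attribute `pseudocount`.
#' @export
enrichment_ratio <- function(chip, input, pseudocount = 1) {
  stopifnot(inherits(chip, "density_track"), inherits(input, "density_track"))
  if (nrow(chip) != nrow(input) ||
      !all(chip$chrom == input$chrom & chip$start == input$start &
             chip$end == input$end)) {
    stop("chip and input tracks have mismatched windows", call. = FALSE)
  }
  pc <- pseudocount * 1e4 / attr(chip, "total_count")
  pi_ <- pseudocount * 1e4 / attr(input, "total_count")
  out <- data.frame(chrom = chip$chrom, start = chip$start, end = chip$end,
                    chip = chip$value, input = input$value,
                    stringsAsFactors = FALSE)
  out$ratio <- (out$chip + pc) / (out$input + pi_)
  out$log2_ratio <- log2(out$ratio)
  out$zero_input <- input$count == 0L
  structure(out, class = c("ratio_track", "data.frame"),
            window_size = attr(chip, "window_size"),
            pseudocount = pseudocount)
}

#' Call CENH3-enriched centromere domains from a ratio track
#'
#' Maximal runs of windows with `log2_ratio >= min_log2`, allowing
#' internal gaps of at most `merge_gap` windows, are kept if they span at
#' least `min_windows` windows. Boundaries snap to window edges. When
#' several runs survive on one chromosome all are reported and the run
#' with the highest mean log2 ratio is flagged primary.
#'
#' @param ratio A `ratio_track`.
#' @param min_log2 Log2 enrichment threshold.
#' @param min_windows Minimum run length in windows.
#' @param merge_gap Maximum below-threshold gap (windows) bridged inside
#'   a run.
#' @return Data frame of class `centromere_calls`: `chrom`, `start`,
#'   `end` (0-based half-open), `size_mb`, `n_windows`, `mean_log2`,
#'   `primary`. May have zero rows.
#' @export
call_centromeres <- function(ratio, min_log2 = 1, min_windows = 3L,
                             merge_gap = 1L) {
  stopifnot(inherits(ratio, "ratio_track"))
  calls <- list()
  for (chr in unique(ratio$chrom)) {
    sub <- ratio[ratio$chrom == chr, ]
    sub <- sub[order(sub$start), ]
    flag <- sub$log2_ratio >= min_log2
    hits <- which(flag)
    if (length(hits) == 0L) next
    # group flagged windows allowing gaps <= merge_gap
    grp <- cumsum(c(1L, diff(hits) > merge_gap + 1L))
    for (g in unique(grp)) {
      idx <- hits[grp == g]
      span <- seq.int(min(idx), max(idx))
      if (length(span) < min_windows) next
      calls[[length(calls) + 1L]] <- data.frame(
        chrom = chr,
        start = sub$start[min(idx)],
        end = sub$end[max(idx)],
        n_windows = length(span),
        mean_log2 = mean(sub$log2_ratio[span]),
        stringsAsFactors = FALSE)
    }
  }
  if (length(calls) == 0L) {
    out <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), size_mb = numeric(0),
                      n_windows = integer(0), mean_log2 = numeric(0),
                      primary = logical(0), stringsAsFactors = FALSE)
    return(structure(out, class = c("centromere_calls", "data.frame")))
  }
  out <- do.call(rbind, calls)
  out$size_mb <- (out$end - out$start) / 1e6
  out$primary <- FALSE
  for (chr in unique(out$chrom)) {
    i <- which(out$chrom == chr)
    out$primary[i[which.max(out$mean_log2[i])]] <- TRUE
  }
  out <- out[, c("chrom", "start", "end", "size_mb", "n_windows",
                 "mean_log2", "primary")]
  rownames(out) <- NULL
  structure(out, class = c("centromere_calls", "data.frame"))
}

#' Centromere calls as GRanges
#'
#' @param calls A `centromere_calls` data frame.
#' @return A `GRanges` (1-based closed).
#' @export
calls_to_granges <- function(calls) {
  GenomicRanges::GRanges(calls$chrom,
                         IRanges::IRanges(start = calls$start + 1L,
                                          end = calls$end))
}

#' Summary statistics over centromere sizes
#'
#' @param sizes_mb Per-chromosome centromere sizes in Mb (non-empty,
#'   positive).
#' @param genome_size_mb Genome size in Mb.
#' @return List of class `centromere_summary`: raw `total_mb`, `min_mb`,
#'   `max_mb`, `mean_mb`, `percent_of_genome`, plus `mean_mb_1dp` and
#'   `percent_2dp` rounded to the reporting precision.
#' @export
centromere_summary <- function(sizes_mb, genome_size_mb) {
  if (length(sizes_mb) == 0L) stop("no centromere sizes", call. = FALSE)
  if (any(sizes_mb <= 0)) stop("sizes must be positive", call. = FALSE)
  total <- sum(sizes_mb)
  pct <- 100 * total / genome_size_mb
  structure(list(
    n = length(sizes_mb),
    total_mb = total,
    min_mb = min(sizes_mb),
    max_mb = max(sizes_mb),
    mean_mb = mean(sizes_mb),
    percent_of_genome = pct,
    mean_mb_1dp = round(mean(sizes_mb), 1),
    percent_2dp = round(pct, 2)
  ), class = "centromere_summary")
}

#' @export
print.centromere_summary <- function(x, ...) {
  cat(sprintf(paste0("Centromeres: n=%d, total %.1f Mb ",
                     "(range %.1f-%.1f, mean %.1f), %.2f%% of genome\n"),
              x$n, x$total_mb, x$min_mb, x$max_mb, x$mean_mb_1dp,
              x$percent_2dp))
  invisible(x)
}

#' Feature-class-level ChIP enrichment
#'
#' Counts ChIP and input fragments whose midpoints fall in each feature
#' class (e.g. satellite arrays vs centromeric vs non-centromeric
#' LTR-RTs), normalises per million, and reports the class-level
#' log2(ChIP/input) with a pseudocount. Per-feature counts are retained.
#'
#' @param chip,input [fragment_set()] objects.
#' @param features Named list of `GRanges`, one entry per class.
#' @param pseudocount Pseudocount in fragments.
#' @return Data frame per class: `class`, `n_features`, `chip_hits`,
#'   `input_hits`, `log2_ratio`, `defined`; attribute `per_feature` holds
#'   per-interval hit counts.
#' @export
feature_enrichment <- function(chip, input, features, pseudocount = 1) {
  stopifnot(inherits(chip, "fragment_set"), inherits(input, "fragment_set"))
  mid_gr <- function(fs) {
    m0 <- fragment_midpoints(fs)
    GenomicRanges::GRanges(
      as.character(GenomicRanges::seqnames(fs$fragments)),
      IRanges::IRanges(start = m0 + 1L, width = 1L))
  }
  chip_mid <- mid_gr(chip)
  input_mid <- mid_gr(input)
  per_feature <- list()
  rows <- lapply(names(features), function(cl) {
    gr <- features[[cl]]
    if (length(gr) == 0L) {
      per_feature[[cl]] <<- data.frame(chip = integer(0), input = integer(0))
      return(data.frame(class = cl, n_features = 0L, chip_hits = NA_integer_,
                        input_hits = NA_integer_, log2_ratio = NA_real_,
                        defined = FALSE, stringsAsFactors = FALSE))
    }
    red <- GenomicRanges::reduce(gr)
    ch <- sum(GenomicRanges::countOverlaps(chip_mid, red) > 0L)
    ih <- sum(GenomicRanges::countOverlaps(input_mid, red) > 0L)
    per_feature[[cl]] <<- data.frame(
      chip = GenomicRanges::countOverlaps(gr, chip_mid),
      input = GenomicRanges::countOverlaps(gr, input_mid))
    rpm_c <- (ch + pseudocount) / chip$total_count * 1e6
    rpm_i <- (ih + pseudocount) / input$total_count * 1e6
    data.frame(class = cl, n_features = length(gr), chip_hits = ch,
               input_hits = ih, log2_ratio = log2(rpm_c / rpm_i),
               defined = TRUE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_feature") <- per_feature
  out
}
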