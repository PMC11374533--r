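# End-to-end orchestration: simulate (or load) -> telomeres -> enrichment
# -> centromere calls -> satellites -> cluster scoring -> phasing -> LTR
# dynamics -> report. Every output is plain text (TSV/JSON/BED/bedGraph/
# FASTA) and fully determined by the configuration seed.

#' Simulation settings for the pipeline
#'
#' @param specs List of [chromosome_spec()] objects.
#' @param n_input,n_chip Fragment counts.
#' @param chip_centromere_fraction Centromeric share of ChIP fragments.
#' @param fragment_length,fragment_sd Fragment length model (bases).
#' @param phase_positions 0-based planted nucleosome phase offsets on the
#'   satellite monomer.
#' @param phase_sd Midpoint jitter SD (bases).
#' @return List of class `simulation_settings`.
#' @export
simulation_settings <- function(specs, n_input = 50000L, n_chip = 50000L,
                                chip_centromere_fraction = 0.8,
                                fragment_length = 150, fragment_sd = 15,
                                phase_positions = c(80L, 260L),
                                phase_sd = 10) {
  structure(list(specs = specs, n_input = n_input, n_chip = n_chip,
                 chip_centromere_fraction = chip_centromere_fraction,
                 fragment_length = fragment_length,
                 fragment_sd = fragment_sd,
                 phase_positions = phase_positions, phase_sd = phase_sd),
            class = "simulation_settings")
}

#' Pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Integer seed recorded in every output's metadata.
#' @param simulation A [simulation_settings()] object, or `NULL` to read
#'   `fasta` / `chip_bed` / `input_bed` files instead.
#' @param fasta,chip_bed,input_bed Input paths (used when `simulation`
#'   is `NULL`; fragment BEDs are optional -- enrichment-dependent stages
#'   are skipped without them).
#' @param window_size Enrichment window size (bases).
#' @param min_log2,min_windows,merge_gap Centromere-calling thresholds.
#' @param pseudocount Enrichment pseudocount (fragments).
#' @param ratio_min,proportion_min Cluster selection thresholds.
#' @param n_cluster_reads Reads sampled per set for cluster scoring.
#' @param n_phasing_fragments Maximum fragments aligned per phasing
#'   profile.
#' @param min_identity Alignment identity threshold (clusters, phasing).
#' @param bandwidth,min_prominence,min_separation Phasing profile and
#'   peak parameters.
#' @param dating A [dating_params()].
#' @param table2_flank Flank (bases) around each centromere call within
#'   which satellite-array span is attributed in the report.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulation = NULL,
                            fasta = NULL, chip_bed = NULL,
                            input_bed = NULL,
                            window_size = 100000L, min_log2 = 1,
                            min_windows = 3L, merge_gap = 1L,
                            pseudocount = 1, ratio_min = 7,
                            proportion_min = 0.0005,
                            n_cluster_reads = 2000L,
                            n_phasing_fragments = 4000L,
                            min_identity = 0.8,
                            bandwidth = 5, min_prominence = 0.25,
                            min_separation = 40L,
                            dating = dating_params(),
                            table2_flank = 2e6) {
  structure(as.list(environment()), class = "pipeline_config")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "columns", null = "null")
  invisible(path)
}

#' Run the full centromere-landscape pipeline
#'
#' Executes all stages in order, writing per-stage outputs plus a
#' Table-2-style per-chromosome report, a machine-readable
#' `summary.json`, and a `MANIFEST` of completed/skipped stages. A stage
#' failure aborts with the stage name after writing the MANIFEST, so
#' partial outputs are retained. Reruns with identical configuration and
#' seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  results <- list()
  note <- function(stage, status) {
    manifest <<- c(manifest, paste0(stage, "\t", status))
    writeLines(c("stage\tstatus", manifest),
               file.path(config$out_dir, "MANIFEST"))
  }
  run_stage <- function(stage, fun) {
    out <- tryCatch(fun(), error = function(e) {
      note(stage, paste0("failed: ", conditionMessage(e)))
      stop("pipeline stage '", stage, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
    note(stage, "ok")
    out
  }

  # --- inputs -------------------------------------------------------
  have_fragments <- TRUE
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    results$inputs <- run_stage("simulate", function() {
      built <- build_genome(sim$specs, seed = config$seed)
      frags <- simulate_fragments(
        built$genome, built$truth, n_input = sim$n_input,
        n_chip = sim$n_chip,
        chip_centromere_fraction = sim$chip_centromere_fraction,
        fragment_length = sim$fragment_length,
        fragment_sd = sim$fragment_sd,
        phase_positions = sim$phase_positions,
        phase_sd = sim$phase_sd, seed = config$seed + 1L)
      write_fixture(built$genome, built$truth, frags, config$out_dir)
      list(genome = built$genome, truth = built$truth, fragments = frags)
    })
  } else {
    results$inputs <- run_stage("load", function() {
      genome <- read_fasta(config$fasta)
      frags <- NULL
      if (!is.null(config$chip_bed) && !is.null(config$input_bed)) {
        frags <- list(
          chip = read_fragments_bed(config$chip_bed, genome, "chip"),
          input = read_fragments_bed(config$input_bed, genome, "input"))
      }
      list(genome = genome, truth = NULL, fragments = frags)
    })
    have_fragments <- !is.null(results$inputs$fragments)
  }
  genome <- results$inputs$genome
  frags <- results$inputs$fragments
  lens <- genome_lengths(genome)

  # --- telomeres ----------------------------------------------------
  results$telomeres <- run_stage("telomeres", function() {
    tab <- telomere_table(genome)
    .write_tsv(tab, file.path(config$out_dir, "telomeres.tsv"))
    tab
  })

  # --- enrichment + calls -------------------------------------------
  if (have_fragments) {
    results$enrichment <- run_stage("enrich", function() {
      chip_d <- compute_window_density(frags$chip, genome,
                                       config$window_size)
      input_d <- compute_window_density(frags$input, genome,
                                        config$window_size)
      ratio <- enrichment_ratio(chip_d, input_d, config$pseudocount)
      write_bedgraph(chip_d, file.path(config$out_dir,
                                       "chip_density.bedgraph"))
      write_bedgraph(input_d, file.path(config$out_dir,
                                        "input_density.bedgraph"))
      write_bedgraph(ratio, file.path(config$out_dir,
                                      "enrichment_log2.bedgraph"),
                     column = "log2_ratio")
      list(chip = chip_d, input = input_d, ratio = ratio)
    })
    results$calls <- run_stage("callcen", function() {
      calls <- call_centromeres(results$enrichment$ratio,
                                min_log2 = config$min_log2,
                                min_windows = config$min_windows,
                                merge_gap = config$merge_gap)
      .write_tsv(calls, file.path(config$out_dir, "centromeres.tsv"))
      writeLines(sprintf("%s\t%d\t%d\tcentromere\t%.3f\t.",
                         calls$chrom, calls$start, calls$end,
                         calls$mean_log2),
                 file.path(config$out_dir, "centromeres.bed"))
      calls
    })
  } else {
    note("enrich", "skipped: no fragments")
    note("callcen", "skipped: no fragments")
    results$calls <- call_centromeres(
      structure(data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), chip = numeric(0),
                           input = numeric(0), ratio = numeric(0),
                           log2_ratio = numeric(0),
                           zero_input = logical(0)),
                class = c("ratio_track", "data.frame")))
  }
  calls <- results$calls

  # --- satellites ---------------------------------------------------
  results$satellites <- run_stage("satellites", function() {
    per_chr <- lapply(names(genome), function(chr)
      find_tandem_arrays(genome[chr]))
    arrays <- do.call(rbind, per_chr)
    fam <- classify_families(arrays)
    comp <- centromere_composition(calls, fam$arrays)
    .write_tsv(fam$arrays, file.path(config$out_dir,
                                     "satellite_arrays.tsv"))
    .write_tsv(fam$families, file.path(config$out_dir,
                                       "satellite_families.tsv"))
    if (nrow(fam$families)) {
      write_fasta(stats::setNames(fam$families$consensus,
                                  fam$families$family),
                  file.path(config$out_dir, "satellite_families.fa"))
    }
    .write_tsv(comp, file.path(config$out_dir,
                               "centromere_composition.tsv"))
    list(arrays = fam$arrays, families = fam$families,
         composition = comp)
  })
  families <- results$satellites$families

  # --- repeat-cluster enrichment ------------------------------------
  if (have_fragments && nrow(families) > 0L) {
    results$clusters <- run_stage("clusters", function() {
      n_reads <- min(config$n_cluster_reads,
                     frags$chip$total_count, frags$input$total_count)
      chip_reads <- sample_reads(frags$chip, genome, n = n_reads,
                                 seed = config$seed + 2L)
      input_reads <- sample_reads(frags$input, genome, n = n_reads,
                                  seed = config$seed + 3L)
      cons <- stats::setNames(families$consensus, families$family)
      chip_hits <- align_reads_to_clusters(chip_reads, cons,
                                           config$min_identity)
      input_hits <- align_reads_to_clusters(input_reads, cons,
                                            config$min_identity)
      enr <- cluster_enrichment_ratio(chip_hits$hits, input_hits$hits,
                                      n_reads, n_reads)
      sel <- select_centromeric_clusters(enr, config$ratio_min,
                                         config$proportion_min)
      .write_tsv(enr, file.path(config$out_dir,
                                "cluster_enrichment.tsv"))
      writeLines(sel, file.path(config$out_dir, "selected_clusters.txt"))
      list(enrichment = enr, selected = sel)
    })
  } else {
    note("clusters", "skipped: no fragments or no families")
  }

  # --- phasing ------------------------------------------------------
  if (have_fragments && nrow(families) > 0L) {
    results$phasing <- run_stage("phase", function() {
      fam <- families[1L, ]   # largest-span family
      trimer <- make_trimer(fam$consensus)
      cen_gr <- calls_to_granges(calls)
      frag_seqs <- function(fs) {
        gr <- fs$fragments
        if (length(cen_gr)) {
          ov <- GenomicRanges::countOverlaps(gr, cen_gr) > 0L
          gr <- gr[ov]
        }
        if (length(gr) > config$n_phasing_fragments) {
          gr <- gr[seq_len(config$n_phasing_fragments)]
        }
        chr <- as.character(GenomicRanges::seqnames(gr))
        out <- character(length(gr))
        for (cc in unique(chr)) {
          i <- which(chr == cc)
          out[i] <- as.character(Biostrings::extractAt(
            genome[[cc]],
            IRanges::IRanges(GenomicRanges::start(gr)[i],
                             GenomicRanges::end(gr)[i])))
        }
        out
      }
      profs <- lapply(c(chip = "chip", input = "input"), function(lb) {
        mp <- map_fragments_to_trimer(frag_seqs(frags[[lb]]), trimer,
                                      config$min_identity)
        fold_to_monomer(mp$midpoints, nchar(fam$consensus),
                        bandwidth = config$bandwidth, source = lb)
      })
      peaks <- lapply(profs, call_phase_peaks,
                      min_prominence = config$min_prominence,
                      min_separation = config$min_separation)
      conc <- phase_concordance(profs$chip, profs$input)
      .write_tsv(data.frame(position = seq_len(fam$period) - 1L,
                            chip = profs$chip$histogram,
                            chip_smoothed = profs$chip$smoothed,
                            input = profs$input$histogram,
                            input_smoothed = profs$input$smoothed),
                 file.path(config$out_dir,
                           paste0("phasing_", fam$family, ".tsv")))
      .write_json(list(family = fam$family,
                       chip_peaks = as.data.frame(peaks$chip),
                       input_peaks = as.data.frame(peaks$input),
                       concordance = conc),
                  file.path(config$out_dir, "phase_peaks.json"))
      list(family = fam$family, profiles = profs, peaks = peaks,
           concordance = conc)
    })
  } else {
    note("phase", "skipped: no fragments or no families")
  }

  # --- LTR dynamics -------------------------------------------------
  results$ltr <- run_stage("ltr", function() {
    per_chr <- lapply(names(genome), function(chr)
      find_ltr_pairs(genome[chr]))
    elements <- do.call(rbind, per_chr)
    elements <- date_elements(elements, genome, config$dating)
    elements <- classify_by_centromere(elements, calls)
    .write_tsv(elements, file.path(config$out_dir, "ltr_elements.tsv"))
    write_ltr_gff3(elements, file.path(config$out_dir, "ltr_elements.gff3"))
    summ <- NULL
    if (nrow(elements) >= 2L &&
        length(unique(elements$location_class)) == 2L) {
      summ <- compare_populations(elements)
    }
    clades <- NULL
    if (nrow(elements) >= 2L) {
      seqs <- Biostrings::DNAStringSet(vapply(
        seq_len(nrow(elements)), function(i)
          as.character(Biostrings::subseq(genome[[elements$chrom[i]]],
                                          elements$start[i],
                                          elements$end[i])),
        character(1)))
      clades <- cluster_clades(seqs)
      elements$clade <- clades
    }
    .write_json(list(
      r = config$dating$r, correction = config$dating$correction,
      n_elements = nrow(elements),
      n_centromeric = sum(elements$location_class == "centromeric"),
      median_identity = if (is.null(summ)) NULL else as.list(summ$medians),
      wilcox_p = if (is.null(summ) || is.null(summ$wilcox)) NULL else
        summ$wilcox$p_value,
      n_clades = if (is.null(clades)) 0L else max(clades)),
      file.path(config$out_dir, "ltr_summary.json"))
    list(elements = elements, summary = summ, clades = clades)
  })

  # --- report -------------------------------------------------------
  results$report <- run_stage("report", function() {
    tab2 <- render_table2(calls, results$satellites$arrays, genome,
                          flank = config$table2_flank)
    .write_tsv(tab2, file.path(config$out_dir, "table2.tsv"))
    summ <- NULL
    if (nrow(calls)) {
      summ <- centromere_summary(calls$size_mb[calls$primary],
                                 sum(lens) / 1e6)
    }
    .write_json(list(
      seed = config$seed,
      genome_size_mb = sum(lens) / 1e6,
      n_chromosomes = length(lens),
      n_telomeres = attr(results$telomeres, "n_telomeres"),
      centromere_summary = if (is.null(summ)) NULL else unclass(summ),
      n_satellite_families = nrow(families),
      n_ltr_elements = nrow(results$ltr$elements)),
      file.path(config$out_dir, "summary.json"))
    list(table2 = tab2, summary = summ)
  })

  invisible(results)
}

#' Render a Table-2-style per-chromosome report
#'
#' One row per chromosome: chromosome size, primary centromere call
#' location and size (Mb, one decimal, matching the usual reporting
#' precision), and the total satellite-array span within `flank` bases
#' of the call (satellite arrays typically extend well beyond the
#' CENH3-bound core, so a flank is required for that column to be
#' meaningful). Chromosomes without a call get empty centromere fields.
#'
#' @param calls A `centromere_calls` data frame.
#' @param arrays Satellite arrays with a `family` column.
#' @param genome Genome sequences or named lengths.
#' @param flank Flank in bases.
#' @return Data frame: `chrom`, `chr_size_mb`, `cen_location`,
#'   `cen_size_mb`, `centfs_arrays_mb`.
#' @export
render_table2 <- function(calls, arrays, genome, flank = 2e6) {
  lens <- genome_lengths(genome)
  rows <- lapply(names(lens), function(chr) {
    ci <- which(calls$chrom == chr & calls$primary)
    if (length(ci) == 0L) {
      return(data.frame(chrom = chr,
                        chr_size_mb = round(lens[[chr]] / 1e6, 1),
                        cen_location = "", cen_size_mb = NA_real_,
                        centfs_arrays_mb = NA_real_,
                        stringsAsFactors = FALSE))
    }
    ci <- ci[1L]
    a <- max(0L, calls$start[ci] - flank)
    b <- min(lens[[chr]], calls$end[ci] + flank)
    sat <- 0
    if (nrow(arrays)) {
      sub <- arrays[arrays$chrom == chr, , drop = FALSE]
      if (nrow(sub)) {
        ov <- pmin(sub$end, b) - pmax(sub$start, a + 1L) + 1L
        sat <- sum(pmax(ov, 0L))
      }
    }
    data.frame(
      chrom = chr,
      chr_size_mb = round(lens[[chr]] / 1e6, 1),
      cen_location = sprintf("%.1f-%.1f", calls$start[ci] / 1e6,
                             calls$end[ci] / 1e6),
      cen_size_mb = round(calls$size_mb[ci], 1),
      centfs_arrays_mb = round(sat / 1e6, 1),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
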