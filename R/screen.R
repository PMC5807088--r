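## End-to-end synthetic screen: one configuration drives genome and marker
## simulation, tetrasomic meiosis, pool construction, pooled counts, the
## BSA filters and track, interval detection, candidate annotation and the
## segregation test.

#' Screen configuration
#'
#' Bundles every tunable of the synthetic screen. The defaults are the
#' study conditions: 27 chromosomes, pools of 120 mutant and 120
#' phenotypically wild-type diploid segregants, 50x mean depth, and the
#' coverage (0.5x-2x mean, both pools) and quality (> 500) filters, at a
#' desk-scale 2 Mb / 100 cM per chromosome with 1 marker per kb.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Chromosome length (bp).
#' @param map_length_cM Chromosome genetic map length (cM).
#' @param marker_density_per_kb Strain-marker density per kb.
#' @param causal_chrom Chromosome carrying the causal locus.
#' @param causal_rel_pos Relative position of the causal base (0-1).
#' @param cds_n_codons Codons in the causal gene's CDS.
#' @param stop_codon_residue Residue index of the vulnerable CGA codon.
#' @param n_mutant,n_wildtype Pool sizes.
#' @param mean_depth Mean pooled sequencing depth.
#' @param error_rate Per-read allele error rate.
#' @param qual_model A [qual_model()].
#' @param filter A [filter_config()].
#' @param window_bp Smoothing window width (bp).
#' @param min_markers Minimum markers per window.
#' @param smooth_statistic Window statistic, `"mean"` or `"median"`.
#' @param peak_threshold Windowed mutant-pool frequency defining the peak.
#' @param n_decoy_genes Additional non-causal candidate genes placed near
#'   the locus (with missense / regulatory / synonymous variants) so the
#'   candidate report is exercised; default 3, giving four candidates in
#'   total.
#' @param regulatory_window Regulatory window (bp) for gene models.
#' @param seed Master seed; every random draw of the screen flows from it.
#' @return A `screen_config` list.
#' @export
screen_config <- function(n_chrom = 27, chrom_length_bp = 2e6,
                          map_length_cM = 100, marker_density_per_kb = 1,
                          causal_chrom = "chr1", causal_rel_pos = 0.5,
                          cds_n_codons = 120, stop_codon_residue = 76,
                          n_mutant = 120, n_wildtype = 120,
                          mean_depth = 50, error_rate = 0.002,
                          qual_model = tetraBSA::qual_model(),
                          filter = filter_config(),
                          window_bp = 1e5, min_markers = 5,
                          smooth_statistic = "mean", peak_threshold = 0.98,
                          n_decoy_genes = 3, regulatory_window = 1000,
                          seed = 1) {
  cfg <- list(n_chrom = n_chrom, chrom_length_bp = chrom_length_bp,
              map_length_cM = map_length_cM,
              marker_density_per_kb = marker_density_per_kb,
              causal_chrom = causal_chrom, causal_rel_pos = causal_rel_pos,
              cds_n_codons = cds_n_codons,
              stop_codon_residue = stop_codon_residue,
              n_mutant = n_mutant, n_wildtype = n_wildtype,
              mean_depth = mean_depth, error_rate = error_rate,
              qual_model = qual_model, filter = filter,
              window_bp = window_bp, min_markers = min_markers,
              smooth_statistic = smooth_statistic,
              peak_threshold = peak_threshold,
              n_decoy_genes = n_decoy_genes,
              regulatory_window = regulatory_window, seed = seed)
  stopifnot(cfg$n_mutant >= 0, cfg$n_wildtype >= 0,
            cfg$causal_chrom %in% paste0("chr", seq_len(n_chrom)))
  class(cfg) <- "screen_config"
  cfg
}

## decoy genes near the causal locus; each carries one variant of a chosen
## effect class. CDS bodies are runs of CTG (Leu): base 2 T>C gives CCG
## (Pro, missense), base 3 G>A gives CTA (Leu, synonymous).
.make_decoys <- function(genome, cfg, causal_pos) {
  n <- cfg$n_decoy_genes
  if (n == 0) return(list(genes = list(), variants = NULL, seqs = list()))
  len <- genome$length_bp[match(cfg$causal_chrom, genome$chrom)]
  effects <- rep(c("missense", "regulatory", "synonymous"), length.out = n)
  genes <- list()
  seqs <- list()
  vars <- list()
  for (i in seq_len(n)) {
    gid <- sprintf("decoy%02d", i)
    offset <- 1e4 * ceiling(i / 2) * (-1)^i
    start <- round(causal_pos + offset)
    n_codons <- 60
    start <- min(max(start, 1), len - 3 * n_codons)
    cds <- data.frame(start = start, end = start + 3 * n_codons - 1)
    g <- gene_model(gid, cfg$causal_chrom, "+", cds, cfg$regulatory_window)
    seqs[[gid]] <- paste0("ATG", strrep("CTG", n_codons - 2), "TAA")
    v <- switch(effects[i],
      missense = list(pos = start + 3 + 1, ref = "T", alt = "C"),
      synonymous = list(pos = start + 3 + 2, ref = "G", alt = "A"),
      regulatory = list(pos = start - 200, ref = "A", alt = "G"))
    genes[[gid]] <- g
    vars[[gid]] <- data.frame(chrom = cfg$causal_chrom, pos = v$pos,
                              ref = v$ref, alt = v$alt,
                              stringsAsFactors = FALSE)
  }
  list(genes = genes, variants = do.call(rbind, vars), seqs = seqs)
}

#' Run the full synthetic screen
#'
#' Executes genome construction, marker placement, causal-mutation
#' insertion, tetraploid formation, tetrasomic meiosis, pool filling,
#' pooled-count simulation (pools and parents), marker derivation,
#' filtering, allele-frequency tracking, interval detection, candidate
#' annotation and the 1:4:1 segregation test on the spores generated while
#' filling the pools. When `out_dir` is given, all intermediate artifacts
#' (VCF, TSV, GFF3, FASTA, BED, JSON, a per-chromosome plot) are written
#' there.
#'
#' @param cfg A [screen_config()].
#' @param out_dir Optional output directory.
#' @return A `screen_report` list.
#' @export
run_screen <- function(cfg = screen_config(), out_dir = NULL) {
  stopifnot(inherits(cfg, "screen_config"))
  timings <- c()
  tick <- function(stage, t0) {
    timings[stage] <<- as.numeric(Sys.time()) - t0
    as.numeric(Sys.time())
  }
  t0 <- as.numeric(Sys.time())
  set.seed(cfg$seed)

  genome <- build_genome(cfg$n_chrom, cfg$chrom_length_bp, cfg$map_length_cM)
  markers <- place_strain_markers(genome, cfg$marker_density_per_kb)
  cds <- make_causal_cds(genome, cfg$causal_chrom, cfg$causal_rel_pos,
                         cfg$cds_n_codons, cfg$stop_codon_residue,
                         regulatory_window = cfg$regulatory_window)
  ins <- insert_causal_mutation(genome, markers, cfg$causal_chrom,
                                cds$causal_pos, cds)
  markers <- ins$markers
  causal <- ins$causal
  decoys <- .make_decoys(genome, cfg, cds$causal_pos)
  gene_models <- c(stats::setNames(list(cds$gene), cds$gene$gene_id),
                   decoys$genes)
  cds_seqs <- c(stats::setNames(list(cds$seq), cds$gene$gene_id),
                decoys$seqs)
  variants <- rbind(
    data.frame(chrom = causal$chrom, pos = causal$pos_bp,
               ref = causal$ref_base, alt = causal$alt_base,
               stringsAsFactors = FALSE),
    decoys$variants)
  t0 <- tick("setup", t0)

  report <- list(config = cfg, causal = causal, track = NULL,
                 interval = NULL, wt_consistency = NULL,
                 candidates = NULL, segregation = NULL,
                 genotype_counts = NULL, n_spores = 0L)

  empty_screen <- cfg$n_mutant == 0 && cfg$n_wildtype == 0
  if (!empty_screen) {
    tet <- make_tetraploid(founder_haplotype(genome, "Vx"),
                           founder_haplotype(genome, "Gd"))
    pools <- build_pools(tet, cfg$n_mutant, cfg$n_wildtype, causal)
    report$genotype_counts <- pools$genotype_counts
    report$n_spores <- pools$n_spores
    if (pools$n_spores > 0) {
      report$segregation <- suppressWarnings(
        chisq_goodness_of_fit(pools$genotype_counts, c(1, 4, 1)))
    }
    t0 <- tick("meiosis", t0)
  }

  if (!empty_screen && cfg$n_mutant > 0 && cfg$n_wildtype > 0) {
    tbl_mut <- simulate_pool_counts(pools$mutant, markers, cfg$mean_depth,
                                    cfg$error_rate, cfg$qual_model)
    tbl_wt <- simulate_pool_counts(pools$wildtype, markers, cfg$mean_depth,
                                   cfg$error_rate, cfg$qual_model)
    parents <- simulate_parental_tables(markers, cfg$mean_depth,
                                        cfg$error_rate, cfg$qual_model)
    t0 <- tick("poolseq", t0)

    derived <- derive_strain_markers(parents$parent_A, parents$parent_B)
    combined <- combine_pool_tables(tbl_mut, tbl_wt)
    in_derived <- paste(combined$chrom, combined$pos) %in%
      paste(derived$chrom, derived$pos)
    combined <- combined[in_derived, , drop = FALSE]
    class(combined) <- c("pooled_variant_table", "data.frame")
    filtered <- filter_variants(combined, cfg$filter)
    track <- compute_allele_frequency(filtered)
    track <- smooth_track(track, cfg$window_bp, cfg$smooth_statistic,
                          cfg$min_markers)
    interval <- detect_peak_interval(track, cfg$peak_threshold)
    report$track <- track
    report$interval <- interval
    if (isTRUE(interval$found)) {
      report$wt_consistency <- wt_pool_consistency(interval, track)
      report$candidates <- list_candidates(interval, variants, gene_models,
                                           cds_seqs)
    } else {
      report$candidates <- list_candidates(interval, variants, gene_models,
                                           cds_seqs)  # empty
    }
    t0 <- tick("bsa", t0)
  } else {
    report$interval <- structure(
      list(found = FALSE, chrom = NA_character_, start_bp = NA_real_,
           end_bp = NA_real_, peak_freq_mutant = NA_real_,
           mean_freq_wildtype_in_interval = NA_real_, n_markers = 0L,
           peak_threshold = cfg$peak_threshold),
      class = "candidate_interval")
    report$candidates <- list_candidates(report$interval,
                                         variants[0, ], gene_models,
                                         cds_seqs)
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(.config_json(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    write_marker_tsv(markers, file.path(out_dir, "markers.tsv"))
    write_marker_vcf(markers, file.path(out_dir, "markers.vcf"))
    write_gene_models_gff3(gene_models, file.path(out_dir, "genes.gff3"))
    write_cds_fasta(cds_seqs, file.path(out_dir, "cds.fasta"))
    if (!is.null(report$interval)) {
      write_interval_bed(report$interval, file.path(out_dir, "interval.bed"))
    }
    if (exists("tbl_mut", inherits = FALSE)) {
      write_pooled_vcf(list(mutant = tbl_mut, wildtype = tbl_wt),
                       file.path(out_dir, "pools.vcf"))
      write_track_tsv(track, file.path(out_dir, "track.tsv"))
      write_windows_tsv(track, file.path(out_dir, "windows.tsv"))
      p <- plot_track(track, report$interval)
      ggplot2::ggsave(file.path(out_dir, "track.pdf"), p,
                      width = 12, height = 2 + 1.2 * ceiling(cfg$n_chrom / 4))
    }
    if (!is.null(report$candidates) && nrow(report$candidates)) {
      utils::write.table(report$candidates,
                         file.path(out_dir, "candidates.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(.report_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report$timings <- timings
  class(report) <- "screen_report"
  report
}

.config_json <- function(cfg) {
  c(unclass(cfg)[!(names(cfg) %in% c("qual_model", "filter"))],
    list(qual_model = unclass(cfg$qual_model),
         filter = unclass(cfg$filter)))
}

.report_json <- function(report) {
  iv <- report$interval
  list(
    seed = report$config$seed,
    n_spores = report$n_spores,
    genotype_counts = as.list(report$genotype_counts),
    segregation = if (!is.null(report$segregation))
      unclass(report$segregation)[c("statistic", "df", "p_value")],
    interval = if (!is.null(iv)) unclass(iv),
    wt_consistency = if (!is.null(report$wt_consistency))
      unclass(report$wt_consistency),
    candidates = if (!is.null(report$candidates))
      as.data.frame(report$candidates))
}

#' @export
print.screen_report <- function(x, ...) {
  cat("== Synthetic BSA screen (seed", x$config$seed, ") ==\n")
  cat("Spores examined:", x$n_spores, " genotypes:",
      paste(names(x$genotype_counts), x$genotype_counts, collapse = ", "),
      "\n")
  if (!is.null(x$segregation)) {
    cat("Segregation vs 1:4:1: ")
    print(x$segregation)
  }
  if (!is.null(x$interval)) print(x$interval)
  if (!is.null(x$wt_consistency)) print(x$wt_consistency)
  if (!is.null(x$candidates) && nrow(x$candidates)) {
    cat("Candidates (most severe first):\n")
    print(as.data.frame(x$candidates)[c("gene_id", "effect", "label",
                                        "pos")])
  }
  invisible(x)
}

#' Parameter sweep of screen recovery
#'
#' Runs seeded replicate screens over a grid of configuration overrides and
#' reports, per grid cell, the fraction of replicates whose detected
#' interval contains the causal position and the median interval width.
#' The special name `pool_size` sets `n_mutant` and `n_wildtype` jointly.
#'
#' @param cfg Base [screen_config()].
#' @param vary Named list of vectors of configuration values to cross.
#' @param n_seeds Replicates per cell (seeds `cfg$seed + 0:(n_seeds-1)`).
#' @return A data frame: one row per grid cell with `recovery_rate` and
#'   `median_width_bp`.
#' @export
sweep_screens <- function(cfg, vary, n_seeds = 5) {
  stopifnot(length(vary) >= 1, !is.null(names(vary)))
  grid <- expand.grid(vary, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    cfg_i <- cfg
    for (nm in names(grid)) {
      if (nm == "pool_size") {
        cfg_i$n_mutant <- grid[[nm]][i]
        cfg_i$n_wildtype <- grid[[nm]][i]
      } else {
        cfg_i[[nm]] <- grid[[nm]][i]
      }
    }
    hits <- logical(n_seeds)
    widths <- rep(NA_real_, n_seeds)
    for (s in seq_len(n_seeds)) {
      cfg_i$seed <- cfg$seed + s - 1
      rep_s <- run_screen(cfg_i)
      iv <- rep_s$interval
      hits[s] <- isTRUE(iv$found) &&
        iv$chrom == rep_s$causal$chrom &&
        iv$start_bp <= rep_s$causal$pos_bp &&
        iv$end_bp >= rep_s$causal$pos_bp
      if (isTRUE(iv$found)) widths[s] <- iv$end_bp - iv$start_bp + 1
    }
    cbind(grid[i, , drop = FALSE],
          data.frame(recovery_rate = mean(hits),
                     median_width_bp = stats::median(widths, na.rm = TRUE)))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
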