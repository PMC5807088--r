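## Variant effect annotation inside the candidate interval: coding /
## regulatory / intergenic classification, codon and residue consequences,
## and premature-termination-codon calls labelled HGVS-style ("R76Ter").

.SEVERITY <- c(premature_stop = 1L, missense = 2L, regulatory = 3L,
               synonymous = 4L)

.aa_label <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa) || is.na(aa)) stop("cannot translate codon ", codon)
  if (aa == "*") "Ter" else aa
}

#' Classify a variant against gene models
#'
#' A variant is `coding` if it falls in any CDS segment, else `regulatory`
#' if it lies within the gene's regulatory window upstream of the CDS start
#' (strand-aware), else `intergenic`. Overlapping genes all report.
#'
#' @param variant A list or one-row data frame with `chrom` and `pos`.
#' @param gene_models A list of [gene_model()]s.
#' @return A data frame with columns `gene_id` and `region_class`; a single
#'   row with `region_class = "intergenic"` (and `NA` gene) when no gene
#'   matches.
#' @export
classify_variant <- function(variant, gene_models) {
  chrom <- variant$chrom
  pos <- variant$pos
  hits <- list()
  for (g in gene_models) {
    if (g$chrom != chrom) next
    if (any(pos >= g$cds$start & pos <= g$cds$end)) {
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = g$gene_id, region_class = "coding",
        stringsAsFactors = FALSE)
      next
    }
    w <- g$regulatory_window
    in_reg <- if (g$strand == "+") {
      s <- min(g$cds$start)
      pos >= s - w && pos < s
    } else {
      e <- max(g$cds$end)
      pos > e && pos <= e + w
    }
    if (isTRUE(in_reg)) {
      hits[[length(hits) + 1L]] <- data.frame(
        gene_id = g$gene_id, region_class = "regulatory",
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(gene_id = NA_character_, region_class = "intergenic",
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Annotate the coding consequence of a variant
#'
#' Maps the genomic position to the transcript coordinate (strand-aware;
#' alleles are reverse-complemented on the minus strand), substitutes the
#' base in the affected codon and translates reference and alternate codons
#' with the standard genetic code. The label follows HGVS-like protein
#' naming (`refAA` + residue index + `altAA`, `Ter` for stop), so a C>T at
#' the first base of a CGA codon at residue 76 yields `"R76Ter"`.
#'
#' @param variant A list with `chrom`, `pos`, `ref`, `alt` (genome-strand
#'   alleles).
#' @param gene_model A [gene_model()] whose CDS contains the variant.
#' @param cds_sequence The gene's coding sequence (character or
#'   `DNAString`), 5'->3' in transcript orientation.
#' @return An `effect_annotation` list: `gene_id`, `region_class`,
#'   `codon_index`, `ref_codon`, `alt_codon`, `ref_aa`, `alt_aa`,
#'   `hgvs_like_label`, `is_premature_stop`.
#' @export
annotate_coding_effect <- function(variant, gene_model, cds_sequence) {
  g <- gene_model
  seq <- toupper(as.character(cds_sequence))
  total_len <- sum(g$cds$end - g$cds$start + 1)
  if (nchar(seq) != total_len) {
    stop("CDS sequence length (", nchar(seq), ") does not match the gene ",
         "model (", total_len, ")")
  }
  cds_pos <- .cds_coord(g, variant$pos)
  if (is.na(cds_pos)) stop("variant is not inside the CDS of ", g$gene_id)
  ref_tx <- if (g$strand == "+") toupper(variant$ref)
            else .revcomp_base(toupper(variant$ref))
  alt_tx <- if (g$strand == "+") toupper(variant$alt)
            else .revcomp_base(toupper(variant$alt))
  have <- substr(seq, cds_pos, cds_pos)
  if (have != ref_tx) {
    stop("reference mismatch at ", g$gene_id, " CDS position ", cds_pos,
         ": model has ", have, ", variant claims ", ref_tx)
  }
  codon_index <- ceiling(cds_pos / 3)
  offset <- cds_pos - 3 * (codon_index - 1)
  ref_codon <- substr(seq, 3 * (codon_index - 1) + 1, 3 * codon_index)
  alt_codon <- ref_codon
  substr(alt_codon, offset, offset) <- alt_tx
  ref_aa <- .aa_label(ref_codon)
  alt_aa <- .aa_label(alt_codon)
  total_codons <- total_len %/% 3
  structure(list(
    gene_id = g$gene_id, region_class = "coding",
    codon_index = codon_index, ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = ref_aa, alt_aa = alt_aa,
    hgvs_like_label = paste0(ref_aa, codon_index, alt_aa),
    is_premature_stop = alt_aa == "Ter" && codon_index < total_codons),
    class = "effect_annotation")
}

.effect_class <- function(ann) {
  if (ann$is_premature_stop) "premature_stop"
  else if (ann$ref_aa == ann$alt_aa) "synonymous"
  else "missense"
}

#' List and rank candidate genes in an interval
#'
#' Restricts variants to the candidate interval, classifies each against
#' the gene models, annotates coding consequences, groups by gene and
#' orders genes by severity (premature stop > missense > regulatory >
#' synonymous), ties broken by position.
#'
#' @param interval A `candidate_interval`.
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param gene_models List of [gene_model()]s.
#' @param cds_seqs Named character vector or list of CDS sequences, keyed
#'   by `gene_id`.
#' @return A data frame of candidates: `gene_id`, `effect`, `label`, `pos`,
#'   `is_premature_stop`, `severity_rank`, ordered most severe first. The
#'   full per-variant annotations are attached as attribute `annotations`.
#' @export
list_candidates <- function(interval, variants, gene_models, cds_seqs) {
  empty <- data.frame(gene_id = character(), effect = character(),
                      label = character(), pos = numeric(),
                      is_premature_stop = logical(),
                      severity_rank = integer(), stringsAsFactors = FALSE)
  if (!isTRUE(interval$found) || nrow(variants) == 0) return(empty)
  v <- variants[variants$chrom == interval$chrom &
                  variants$pos >= interval$start_bp &
                  variants$pos <= interval$end_bp, , drop = FALSE]
  if (nrow(v) == 0) return(empty)
  recs <- list()
  anns <- list()
  for (i in seq_len(nrow(v))) {
    var <- as.list(v[i, ])
    cls <- classify_variant(var, gene_models)
    for (j in seq_len(nrow(cls))) {
      if (cls$region_class[j] == "intergenic") next
      gid <- cls$gene_id[j]
      if (cls$region_class[j] == "coding") {
        g <- gene_models[[which(vapply(gene_models, function(x) x$gene_id,
                                       "") == gid)[1]]]
        ann <- annotate_coding_effect(var, g, cds_seqs[[gid]])
        eff <- .effect_class(ann)
        lab <- ann$hgvs_like_label
        prem <- ann$is_premature_stop
        anns[[length(anns) + 1L]] <- ann
      } else {
        eff <- "regulatory"
        lab <- paste0(gid, ":upstream")
        prem <- FALSE
      }
      recs[[length(recs) + 1L]] <- data.frame(
        gene_id = gid, effect = eff, label = lab, pos = var$pos,
        is_premature_stop = prem, severity_rank = .SEVERITY[[eff]],
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) return(empty)
  all <- do.call(rbind, recs)
  ## gene-level severity = most severe variant; order by severity, then pos
  agg <- do.call(rbind, lapply(split(all, all$gene_id), function(d) {
    d[order(d$severity_rank, d$pos), ][1, ]
  }))
  agg$n_variants <- as.integer(table(all$gene_id)[agg$gene_id])
  agg <- agg[order(agg$severity_rank, agg$pos), ]
  rownames(agg) <- NULL
  attr(agg, "annotations") <- anns
  attr(agg, "all_effects") <- all
  agg
}

#' @export
print.effect_annotation <- function(x, ...) {
  cat(sprintf("%s %s (%s->%s, codon %d)%s\n", x$gene_id, x$hgvs_like_label,
              x$ref_codon, x$alt_codon, x$codon_index,
              if (x$is_premature_stop) " [premature stop]" else ""))
  invisible(x)
}
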