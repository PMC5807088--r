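## Gene models travel as minimal GFF3 (gene + CDS features) and coding
## sequences as FASTA. Reading goes through rtracklayer / Biostrings; the
## writer emits the minimal 9-column dialect directly.

#' Write gene models as minimal GFF3
#'
#' @param gene_models List of [gene_model()]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(gene_models, path) {
  lines <- "##gff-version 3"
  for (g in gene_models) {
    gstart <- min(g$cds$start)
    gend <- max(g$cds$end)
    lines <- c(lines, paste(g$chrom, "tetraBSA", "gene", gstart, gend, ".",
                            g$strand, ".", paste0("ID=", g$gene_id),
                            sep = "\t"))
    for (i in seq_len(nrow(g$cds))) {
      lines <- c(lines, paste(g$chrom, "tetraBSA", "CDS", g$cds$start[i],
                              g$cds$end[i], ".", g$strand, "0",
                              paste0("ID=", g$gene_id, ".cds", i,
                                     ";Parent=", g$gene_id),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects gene features with `ID` and CDS features with `Parent`
#' attributes, as written by [write_gene_models_gff3()] or any conforming
#' minimal GFF3.
#'
#' @param path Path to the GFF3 file.
#' @param regulatory_window Regulatory window to attach to every model.
#' @return A list of `gene_model`s.
#' @export
read_gene_models_gff3 <- function(path, regulatory_window = 1000) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  is_cds <- toupper(df$type) == "CDS"
  parents <- vapply(df$Parent[is_cds], function(p) {
    if (length(p) == 0) NA_character_ else as.character(p[[1]])
  }, "")
  cds <- data.frame(chrom = as.character(df$seqnames[is_cds]),
                    start = df$start[is_cds], end = df$end[is_cds],
                    strand = as.character(df$strand[is_cds]),
                    gene_id = parents, stringsAsFactors = FALSE)
  lapply(split(cds, cds$gene_id), function(d) {
    gene_model(d$gene_id[1], d$chrom[1], d$strand[1],
               data.frame(start = d$start, end = d$end),
               regulatory_window)
  })
}

#' Write / read CDS sequences as FASTA
#'
#' @param cds_seqs Named character vector or list of sequences keyed by
#'   gene id.
#' @param path File path.
#' @return `path` invisibly for the writer; a named character vector for
#'   the reader.
#' @export
write_cds_fasta <- function(cds_seqs, path) {
  seqs <- Biostrings::DNAStringSet(unlist(as.list(cds_seqs)))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' @rdname write_cds_fasta
#' @export
read_cds_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- as.character(seqs)
  names(out) <- names(seqs)
  out
}
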