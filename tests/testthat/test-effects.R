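plus_gene <- function(seq, start = 1001, id = "g1", window = 1000) {
  gene_model(id, "chr1", "+",
             data.frame(start = start, end = start + nchar(seq) - 1), window)
}

# the mirror construction: same CDS placed on the minus strand such that the
# transcript sequence is identical
minus_gene <- function(seq, start = 1001, id = "g1m", window = 1000) {
  gene_model(id, "chr1", "-",
             data.frame(start = start, end = start + nchar(seq) - 1), window)
}

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

test_that("variants classify as coding / regulatory / intergenic, strand-aware", {
  seq <- paste0("ATG", strrep("GCT", 8), "TAA")
  gp <- plus_gene(seq)
  gm <- minus_gene(seq, start = 5001)
  models <- list(gp, gm)
  expect_equal(classify_variant(list(chrom = "chr1", pos = 1010),
                                models)$region_class, "coding")
  # 200 bp upstream of a + strand CDS start, window 1000 -> regulatory
  expect_equal(classify_variant(list(chrom = "chr1", pos = 801),
                                models)$region_class, "regulatory")
  # upstream of a - strand gene means beyond its genomic end
  expect_equal(classify_variant(list(chrom = "chr1", pos = 5031),
                                models)$region_class, "regulatory")
  expect_equal(classify_variant(list(chrom = "chr1", pos = 4000),
                                models)$region_class, "intergenic")
  expect_equal(classify_variant(list(chrom = "chr9", pos = 1010),
                                models)$region_class, "intergenic")
})

test_that("C>T at the first base of CGA codon 76 yields R76Ter", {
  codons <- c("ATG", rep("GCT", 100))
  codons[76] <- "CGA"
  seq <- paste(c(codons, "TAA"), collapse = "")
  g <- plus_gene(seq)
  pos <- 1001 + (76 - 1) * 3  # genomic position of the codon's first base
  ann <- annotate_coding_effect(list(chrom = "chr1", pos = pos,
                                     ref = "C", alt = "T"), g, seq)
  expect_equal(ann$hgvs_like_label, "R76Ter")
  expect_equal(ann$codon_index, 76)
  expect_equal(ann$ref_codon, "CGA")
  expect_equal(ann$alt_codon, "TGA")
  expect_true(ann$is_premature_stop)
})

test_that("third-position CTC>CTT is synonymous", {
  seq <- paste0("ATG", "CTC", strrep("GAA", 6), "TAA")
  g <- plus_gene(seq)
  pos <- 1001 + 5  # third base of codon 2
  ann <- annotate_coding_effect(list(chrom = "chr1", pos = pos,
                                     ref = "C", alt = "T"), g, seq)
  expect_equal(ann$ref_aa, "L")
  expect_equal(ann$alt_aa, "L")
  expect_equal(ann$hgvs_like_label, "L2L")
  expect_false(ann$is_premature_stop)
})

test_that("a stop created in the final codon is not premature", {
  seq <- paste0("ATG", strrep("GCT", 7), "CAA")  # ends Gln, no natural stop
  g <- plus_gene(seq)
  pos <- 1001 + nchar(seq) - 3  # first base of the last codon
  ann <- annotate_coding_effect(list(chrom = "chr1", pos = pos,
                                     ref = "C", alt = "T"), g, seq)
  expect_equal(ann$alt_aa, "Ter")
  expect_equal(ann$codon_index, 9)
  expect_false(ann$is_premature_stop)
})

test_that("annotating the reference allele against itself is a synonymous identity", {
  seq <- paste0("ATG", "CGA", strrep("GAT", 5), "TAA")
  g <- plus_gene(seq)
  for (pos in 1001 + c(0, 3, 7, 20)) {
    cds_off <- pos - 1000
    ref <- substr(seq, cds_off, cds_off)
    ann <- annotate_coding_effect(list(chrom = "chr1", pos = pos,
                                       ref = ref, alt = ref), g, seq)
    expect_equal(ann$ref_aa, ann$alt_aa)
    expect_false(ann$is_premature_stop)
  }
})

test_that("minus-strand annotation equals the plus-strand mirror annotation", {
  codons <- c("ATG", rep("AAG", 40))
  codons[20] <- "CGA"
  seq <- paste(c(codons, "TAA"), collapse = "")
  gp <- plus_gene(seq)
  gm <- minus_gene(seq, start = 1001)
  # plus-strand variant at codon 20 base 1 (C>T)
  pos_p <- 1001 + (20 - 1) * 3
  ann_p <- annotate_coding_effect(list(chrom = "chr1", pos = pos_p,
                                       ref = "C", alt = "T"), gp, seq)
  # the same transcript change on the minus-strand gene: the genomic
  # position mirrors from the other end, alleles reverse-complemented
  pos_m <- gm$cds$end - (pos_p - gp$cds$start)
  ann_m <- annotate_coding_effect(list(chrom = "chr1", pos = pos_m,
                                       ref = "G", alt = "A"), gm, seq)
  expect_equal(ann_m$hgvs_like_label, ann_p$hgvs_like_label)
  expect_equal(ann_m$codon_index, ann_p$codon_index)
  expect_equal(ann_m$is_premature_stop, ann_p$is_premature_stop)
})

test_that("reference mismatches and non-CDS positions raise errors", {
  seq <- paste0("ATG", strrep("GCT", 8), "TAA")
  g <- plus_gene(seq)
  expect_error(annotate_coding_effect(list(chrom = "chr1", pos = 1004,
                                           ref = "A", alt = "T"), g, seq),
               "reference mismatch")
  expect_error(annotate_coding_effect(list(chrom = "chr1", pos = 10,
                                           ref = "A", alt = "T"), g, seq),
               "not inside")
  expect_error(annotate_coding_effect(list(chrom = "chr1", pos = 1004,
                                           ref = "G", alt = "A"), g,
                                      substr(seq, 1, 10)),
               "does not match")
})

test_that("candidates rank premature stop > missense > regulatory > synonymous", {
  iv <- structure(list(found = TRUE, chrom = "chr1", start_bp = 1,
                       end_bp = 1e5, peak_freq_mutant = 1,
                       mean_freq_wildtype_in_interval = 0.4, n_markers = 10,
                       peak_threshold = 0.98),
                  class = "candidate_interval")
  stop_codons <- c("ATG", rep("GCT", 10)); stop_codons[5] <- "CGA"
  seq_stop <- paste(c(stop_codons, "TAA"), collapse = "")
  seq_leu <- paste0("ATG", strrep("CTG", 10), "TAA")
  genes <- list(
    gene_model("gSyn", "chr1", "+", data.frame(start = 2001, end = 2036)),
    gene_model("gStop", "chr1", "+", data.frame(start = 10001, end = 10036)),
    gene_model("gMis", "chr1", "+", data.frame(start = 20001, end = 20036)),
    gene_model("gReg", "chr1", "+", data.frame(start = 30001, end = 30036)))
  seqs <- list(gSyn = seq_leu, gStop = seq_stop, gMis = seq_leu,
               gReg = seq_leu)
  variants <- data.frame(
    chrom = "chr1",
    pos = c(2001 + 5, 10001 + 12, 20001 + 4, 30001 - 200),
    ref = c("G", "C", "T", "A"),
    alt = c("A", "T", "C", "G"),
    stringsAsFactors = FALSE)
  cand <- list_candidates(iv, variants, genes, seqs)
  expect_equal(cand$gene_id, c("gStop", "gMis", "gReg", "gSyn"))
  expect_equal(cand$effect,
               c("premature_stop", "missense", "regulatory", "synonymous"))
  expect_true(cand$is_premature_stop[1])
  expect_equal(cand$label[1], "R5Ter")
})

test_that("equal-severity candidates order by position; empty cases are empty", {
  iv <- structure(list(found = TRUE, chrom = "chr1", start_bp = 1,
                       end_bp = 1e5, peak_freq_mutant = 1,
                       mean_freq_wildtype_in_interval = 0.4, n_markers = 10,
                       peak_threshold = 0.98),
                  class = "candidate_interval")
  seq_leu <- paste0("ATG", strrep("CTG", 10), "TAA")
  genes <- list(
    gene_model("gB", "chr1", "+", data.frame(start = 5001, end = 5036)),
    gene_model("gA", "chr1", "+", data.frame(start = 1001, end = 1036)))
  seqs <- list(gA = seq_leu, gB = seq_leu)
  variants <- data.frame(chrom = "chr1", pos = c(5005, 1005),
                         ref = "T", alt = "C", stringsAsFactors = FALSE)
  cand <- list_candidates(iv, variants, genes, seqs)
  expect_equal(cand$gene_id, c("gA", "gB"))  # same severity, by position

  none <- list_candidates(iv, variants[0, ], genes, seqs)
  expect_equal(nrow(none), 0)
  outside <- data.frame(chrom = "chr2", pos = 5005, ref = "T", alt = "C")
  expect_equal(nrow(list_candidates(iv, outside, genes, seqs)), 0)
})

test_that("gene models and CDS sequences round-trip through GFF3 and FASTA", {
  genes <- list(
    g1 = gene_model("g1", "chr1", "+",
                    data.frame(start = c(101, 301), end = c(200, 350))),
    g2 = gene_model("g2", "chr2", "-", data.frame(start = 501, end = 560)))
  gff <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(genes, gff)
  back <- read_gene_models_gff3(gff)
  expect_setequal(names(back), c("g1", "g2"))
  expect_equal(back$g1$cds, genes$g1$cds)
  expect_equal(back$g2$strand, "-")

  seqs <- c(g1 = paste0("ATG", strrep("GCT", 48), "TAA"),
            g2 = paste0("ATG", strrep("AAG", 18), "TAA"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_cds_fasta(seqs, fa)
  expect_equal(read_cds_fasta(fa), seqs)
})
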