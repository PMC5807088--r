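.BASES <- c("A", "C", "G", "T")

## transition partner of each base (A<->G, C<->T); used as the default
## substitution when installing the causal mutation
.TRANSITION <- c(A = "G", C = "T", G = "A", T = "C")

#' Define a synthetic genome
#'
#' Builds a genome of `n_chrom` identically shaped chromosomes, each with a
#' physical length in bases and a genetic map length in centimorgans. The
#' genetic map is uniform within a chromosome (constant cM/bp), so physical
#' and genetic coordinates interconvert linearly. The default preserves the
#' 27-chromosome karyotype of the *Physcomitrella patens* assembly at a
#' desk-scale 2 Mb per chromosome.
#'
#' @param n_chrom Number of chromosomes (>= 1).
#' @param length_bp Physical length of every chromosome, in bases (>= 1).
#' @param map_length_cM Genetic map length of every chromosome, in
#'   centimorgans (>= 0; 0 disables recombination).
#' @return A `genome_spec` data frame with columns `chrom`, `length_bp`,
#'   `map_length_cM`.
#' @examples
#' build_genome(27, 2e6, 100)
#' @export
build_genome <- function(n_chrom = 27, length_bp = 2e6, map_length_cM = 100) {
  if (!is.numeric(n_chrom) || length(n_chrom) != 1 || n_chrom < 1 ||
      n_chrom != round(n_chrom)) {
    stop("`n_chrom` must be a positive integer")
  }
  if (!is.numeric(length_bp) || length(length_bp) != 1 || length_bp < 1) {
    stop("`length_bp` must be a positive number of bases")
  }
  if (!is.numeric(map_length_cM) || length(map_length_cM) != 1 ||
      map_length_cM < 0) {
    stop("`map_length_cM` must be non-negative")
  }
  g <- data.frame(
    chrom = paste0("chr", seq_len(n_chrom)),
    length_bp = as.numeric(length_bp),
    map_length_cM = as.numeric(map_length_cM),
    stringsAsFactors = FALSE
  )
  class(g) <- c("genome_spec", "data.frame")
  g
}

.check_genome <- function(genome) {
  if (!inherits(genome, "genome_spec")) stop("expected a `genome_spec`")
  stopifnot(all(genome$length_bp > 0), all(genome$map_length_cM >= 0),
            !anyDuplicated(genome$chrom))
  invisible(genome)
}

#' Place strain-distinguishing markers on a genome
#'
#' Scatters biallelic SNV markers that are homozygous-different between the
#' two parental strains. The marker count per chromosome is Poisson with mean
#' `density_per_kb * length_bp / 1000`; positions are uniform without
#' collision; each marker carries one allele for the A-side (mutant) strain
#' and a different allele for the B-side (wild) strain.
#'
#' @param genome A `genome_spec`.
#' @param density_per_kb Expected markers per kilobase (>= 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @param strain_A,strain_B Labels for the A-side (mutant-background) and
#'   B-side strains.
#' @return A `strain_marker_map` data frame with columns `chrom`, `pos`,
#'   `allele_A`, `allele_B`, sorted by (chrom, pos), with the strain labels
#'   and the genome attached as attributes.
#' @export
place_strain_markers <- function(genome, density_per_kb = 1, seed = NULL,
                                 strain_A = "Vx", strain_B = "Gd") {
  .check_genome(genome)
  if (!is.numeric(density_per_kb) || density_per_kb < 0) {
    stop("`density_per_kb` must be >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  per_chrom <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length_bp[i]
    n <- stats::rpois(1L, density_per_kb * len / 1000)
    n <- min(n, len)  # cannot place more collision-free sites than bases
    if (n == 0L) {
      return(data.frame(chrom = character(), pos = numeric(),
                        allele_A = character(), allele_B = character(),
                        stringsAsFactors = FALSE))
    }
    pos <- sort(sample.int(len, n))
    ia <- sample.int(4L, n, replace = TRUE)
    ib <- ((ia - 1L + sample.int(3L, n, replace = TRUE)) %% 4L) + 1L
    data.frame(chrom = genome$chrom[i], pos = as.numeric(pos),
               allele_A = .BASES[ia], allele_B = .BASES[ib],
               stringsAsFactors = FALSE)
  })
  mm <- do.call(rbind, per_chrom)
  rownames(mm) <- NULL
  attr(mm, "strain_A") <- strain_A
  attr(mm, "strain_B") <- strain_B
  attr(mm, "genome") <- genome
  class(mm) <- c("strain_marker_map", "data.frame")
  mm
}

.as_marker_map <- function(df, genome = NULL, strain_A = "Vx", strain_B = "Gd") {
  rownames(df) <- NULL
  attr(df, "strain_A") <- strain_A
  attr(df, "strain_B") <- strain_B
  attr(df, "genome") <- genome
  class(df) <- c("strain_marker_map", "data.frame")
  df
}

#' Build a gene model
#'
#' A minimal protein-coding gene model: one or more CDS segments on one
#' strand, plus a promoter-proximal regulatory window upstream of the CDS
#' start used by [classify_variant()].
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param cds Data frame with columns `start`, `end` (1-based inclusive,
#'   sorted by genomic position, non-overlapping).
#' @param regulatory_window Bases upstream of the CDS start treated as
#'   regulatory (default 1000).
#' @return A `gene_model` list.
#' @export
gene_model <- function(gene_id, chrom, strand = "+", cds,
                       regulatory_window = 1000) {
  stopifnot(strand %in% c("+", "-"), is.data.frame(cds),
            all(c("start", "end") %in% names(cds)), nrow(cds) >= 1,
            all(cds$end >= cds$start))
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  rownames(cds) <- NULL
  if (nrow(cds) > 1 && any(cds$start[-1] <= cds$end[-nrow(cds)])) {
    stop("CDS segments overlap in gene ", gene_id)
  }
  total <- sum(cds$end - cds$start + 1)
  if (total %% 3 != 0) {
    warning("total CDS length of ", gene_id, " (", total,
            ") is not divisible by 3; annotating best-effort")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 cds = cds, regulatory_window = regulatory_window),
            class = "gene_model")
}

## genomic position -> 1-based CDS (transcript) coordinate, strand aware.
## Returns NA if pos is outside every CDS segment.
.cds_coord <- function(gene, pos) {
  seg <- gene$cds
  hit <- which(pos >= seg$start & pos <= seg$end)
  if (length(hit) == 0) return(NA_real_)
  hit <- hit[1]
  lens <- seg$end - seg$start + 1
  if (gene$strand == "+") {
    before <- if (hit > 1) sum(lens[seq_len(hit - 1)]) else 0
    before + (pos - seg$start[hit] + 1)
  } else {
    after <- if (hit < nrow(seg)) sum(lens[(hit + 1):nrow(seg)]) else 0
    after + (seg$end[hit] - pos + 1)
  }
}

## 1-based CDS coordinate -> genomic position (inverse of .cds_coord)
.genomic_coord <- function(gene, cds_pos) {
  seg <- gene$cds
  lens <- seg$end - seg$start + 1
  if (gene$strand == "+") {
    cum <- cumsum(lens)
    hit <- which(cds_pos <= cum)[1]
    before <- if (hit > 1) cum[hit - 1] else 0
    seg$start[hit] + (cds_pos - before - 1)
  } else {
    cum <- cumsum(rev(lens))
    ridx <- which(cds_pos <= cum)[1]
    hit <- nrow(seg) + 1 - ridx
    before <- if (ridx > 1) cum[ridx - 1] else 0
    seg$end[hit] - (cds_pos - before - 1)
  }
}

.revcomp_base <- function(b) chartr("ACGT", "TGCA", b)

#' Construct the causal gene and its coding sequence
#'
#' Builds a synthetic single-exon gene whose CDS carries an arginine CGA codon
#' at a chosen residue so that a C>T transition at the first base of that
#' codon creates a TGA premature termination codon (the classic
#' "R76Ter"-style nonsense change). The gene is positioned so the vulnerable
#' codon sits at a chosen relative position along the chromosome.
#'
#' @param genome A `genome_spec`.
#' @param chrom Chromosome carrying the gene.
#' @param rel_pos Relative position (0-1) of the vulnerable codon base along
#'   the chromosome.
#' @param n_codons Total codons in the CDS including start and stop.
#' @param stop_codon_residue 1-based residue index of the CGA codon.
#' @param strand Gene strand.
#' @param gene_id Gene identifier.
#' @param regulatory_window Regulatory window for the gene model.
#' @return A list with the `gene` model, the wild-type CDS `seq`, the genomic
#'   `causal_pos` of the vulnerable base, and the `ref`/`alt` alleles on the
#'   genome strand.
#' @export
make_causal_cds <- function(genome, chrom = "chr1", rel_pos = 0.5,
                            n_codons = 120, stop_codon_residue = 76,
                            strand = "+", gene_id = "gene32970008",
                            regulatory_window = 1000) {
  .check_genome(genome)
  i <- match(chrom, genome$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  stopifnot(stop_codon_residue > 1, stop_codon_residue < n_codons)
  ## codons free of stops and free of leading C->T vulnerability ambiguity
  safe <- c("GCT", "GGA", "AAG", "GAA", "CTG", "TTC", "GAT", "ATC")
  body <- safe[(seq_len(n_codons - 2) %% length(safe)) + 1]
  codons <- c("ATG", body, "TAA")
  codons[stop_codon_residue] <- "CGA"
  seq <- paste(codons, collapse = "")
  len <- genome$length_bp[i]
  target <- max(1, round(rel_pos * len))
  cds_pos_of_causal <- (stop_codon_residue - 1) * 3 + 1
  if (strand == "+") {
    cds_start <- target - (cds_pos_of_causal - 1)
    cds_end <- cds_start + 3 * n_codons - 1
  } else {
    cds_end <- target + (cds_pos_of_causal - 1)
    cds_start <- cds_end - 3 * n_codons + 1
  }
  if (cds_start < 1 || cds_end > len) {
    stop("CDS does not fit on ", chrom, " at rel_pos ", rel_pos)
  }
  gene <- gene_model(gene_id, chrom, strand,
                     data.frame(start = cds_start, end = cds_end),
                     regulatory_window)
  causal_pos <- .genomic_coord(gene, cds_pos_of_causal)
  ref_tx <- "C"                       # first base of CGA
  ref <- if (strand == "+") ref_tx else .revcomp_base(ref_tx)
  alt <- unname(.TRANSITION[ref])
  list(gene = gene, seq = seq, causal_pos = causal_pos, ref = ref, alt = alt)
}

#' Install the recessive causal mutation into the marker map
#'
#' Registers a single causal SNV inside the CDS of a gene so that the
#' mutant-strain (A-side) allele at the site is the alternate base. The site
#' is inserted into the strain marker map (replacing the alleles of an
#' existing marker at the same position if present), guaranteeing the causal
#' site is genotyped in every downstream pool.
#'
#' @param genome A `genome_spec`.
#' @param markers A `strain_marker_map`.
#' @param chrom Chromosome of the causal site.
#' @param pos_bp 1-based position of the causal site.
#' @param cds A list as returned by [make_causal_cds()] (fields `gene`,
#'   `seq`).
#' @param alt_base Alternate (mutant) base on the genome strand; defaults to
#'   the transition partner of the reference base.
#' @return A list with `causal` (a `causal_variant`) and the updated
#'   `markers` map.
#' @export
insert_causal_mutation <- function(genome, markers, chrom, pos_bp, cds,
                                   alt_base = NULL) {
  .check_genome(genome)
  i <- match(chrom, genome$chrom)
  if (is.na(i)) stop("unknown chromosome: ", chrom)
  if (pos_bp < 1 || pos_bp > genome$length_bp[i]) {
    stop("position ", pos_bp, " outside ", chrom,
         " (length ", genome$length_bp[i], ")")
  }
  gene <- cds$gene
  seq <- cds$seq
  cds_pos <- .cds_coord(gene, pos_bp)
  if (is.na(cds_pos)) stop("position ", pos_bp, " is not inside the CDS of ",
                           gene$gene_id)
  ref_tx <- substr(seq, cds_pos, cds_pos)
  ref <- if (gene$strand == "+") ref_tx else .revcomp_base(ref_tx)
  if (is.null(alt_base)) alt_base <- unname(.TRANSITION[ref])
  if (identical(alt_base, ref)) stop("alternate allele equals reference")
  residue <- ceiling(cds_pos / 3)

  row <- data.frame(chrom = chrom, pos = as.numeric(pos_bp),
                    allele_A = alt_base, allele_B = ref,
                    stringsAsFactors = FALSE)
  hit <- which(markers$chrom == chrom & markers$pos == pos_bp)
  if (length(hit)) {
    markers$allele_A[hit] <- alt_base
    markers$allele_B[hit] <- ref
  } else {
    at <- attributes(markers)
    df <- rbind(as.data.frame(markers), row)
    df <- df[order(match(df$chrom, genome$chrom), df$pos), ]
    markers <- .as_marker_map(df, at$genome, at$strain_A, at$strain_B)
  }
  causal <- structure(
    list(chrom = chrom, pos_bp = as.numeric(pos_bp), ref_base = ref,
         alt_base = alt_base, gene_id = gene$gene_id,
         cds_residue_index = residue,
         recessive_phenotype_label = "no-3D"),
    class = "causal_variant")
  list(causal = causal, markers = markers)
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("Genome:", nrow(x), "chromosome(s), ",
      format(sum(x$length_bp), big.mark = ","), "bp, ",
      sum(x$map_length_cM), "cM total\n")
  invisible(x)
}

#' @export
print.strain_marker_map <- function(x, ...) {
  cat("Strain marker map:", nrow(x), "biallelic sites on",
      length(unique(x$chrom)), "chromosome(s) [",
      attr(x, "strain_A"), "vs", attr(x, "strain_B"), "]\n")
  invisible(x)
}
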