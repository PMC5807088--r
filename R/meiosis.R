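## Tetrasomic meiosis of a duplex (m/m/+/+) tetraploid.
##
## The tetraploid carries four homologs per chromosome, labelled
## V1, V2 (copies of the mutant-strain haplotype) and G1, G2 (copies of the
## wild-strain haplotype); internally the labels are the integer codes
## 1..4. At meiosis the four homologs pair into two bivalents (the three
## possible pairings equiprobable), crossovers are Poisson with mean
## 2 x map length in Morgans per bivalent with no interference, and each of
## the four spores of the tetrad receives one chromatid per bivalent, i.e.
## two copies of every chromosome: the spores are diploid.

.HOMOLOG_LABELS <- c("V1", "V2", "G1", "G2")

## A chromatid is a run-length ancestry mosaic: `ends` are strictly
## increasing segment end positions in bp (last == chromosome length) and
## `anc` the homolog code (1..4) of each segment. Segment i covers
## (ends[i-1], ends[i]].

.anc_at <- function(tid, pos) {
  tid$anc[findInterval(pos, tid$ends, left.open = TRUE) + 1L]
}

## exchange the segments distal to x between chromatids a and b
.swap_tails <- function(a, b, x) {
  ka <- sum(a$ends < x)
  kb <- sum(b$ends < x)
  na <- length(a$ends)
  nb <- length(b$ends)
  new_a <- list(
    ends = c(a$ends[seq_len(ka)], x, b$ends[seq_len(nb - kb) + kb]),
    anc  = c(a$anc[seq_len(ka)], a$anc[ka + 1L], b$anc[seq_len(nb - kb) + kb]))
  new_b <- list(
    ends = c(b$ends[seq_len(kb)], x, a$ends[seq_len(na - ka) + ka]),
    anc  = c(b$anc[seq_len(kb)], b$anc[kb + 1L], a$anc[seq_len(na - ka) + ka]))
  list(new_a, new_b)
}

.PAIRINGS <- list(
  list(c(1L, 2L), c(3L, 4L)),
  list(c(1L, 3L), c(2L, 4L)),
  list(c(1L, 4L), c(2L, 3L)))

## one chromosome through one meiosis; returns a list of 4 spore
## chromosome copies, each a list of 2 chromatids
.meiosis_chromosome <- function(len_bp, map_cM) {
  biv <- .PAIRINGS[[sample.int(3L, 1L)]]
  tids <- lapply(1:4, function(h) {
    tid <- list(ends = len_bp, anc = h)
    list(tid, tid)
  })
  if (map_cM > 0) {
    morgans <- map_cM / 100
    for (bv in biv) {
      n_xo <- stats::rpois(1L, 2 * morgans)
      if (n_xo > 0L) {
        ## uniform on the genetic map; the map is linear so cM -> bp is linear
        xo_bp <- sort(stats::runif(n_xo)) * len_bp
        ci <- sample.int(2L, n_xo, replace = TRUE)
        cj <- sample.int(2L, n_xo, replace = TRUE)
        for (k in seq_len(n_xo)) {
          sw <- .swap_tails(tids[[bv[1L]]][[ci[k]]],
                            tids[[bv[2L]]][[cj[k]]], xo_bp[k])
          tids[[bv[1L]]][[ci[k]]] <- sw[[1L]]
          tids[[bv[2L]]][[cj[k]]] <- sw[[2L]]
        }
      }
    }
  }
  out <- list(vector("list", 2L), vector("list", 2L),
              vector("list", 2L), vector("list", 2L))
  for (b in 1:2) {
    ## meiosis I: paired homologs to opposite poles, random orientation;
    ## spores 1,2 sit at pole 1 and spores 3,4 at pole 2
    first <- sample.int(2L, 1L)
    hom1 <- biv[[b]][first]
    hom2 <- biv[[b]][3L - first]
    ## meiosis II: sister chromatids separate, random assignment
    s1 <- sample.int(2L, 2L)
    s2 <- sample.int(2L, 2L)
    out[[1L]][[b]] <- tids[[hom1]][[s1[1L]]]
    out[[2L]][[b]] <- tids[[hom1]][[s1[2L]]]
    out[[3L]][[b]] <- tids[[hom2]][[s2[1L]]]
    out[[4L]][[b]] <- tids[[hom2]][[s2[2L]]]
  }
  out
}

#' Founder haplotype of a parental strain
#'
#' A whole-genome haplotype contributed by one parental strain to the
#' somatic hybrid. Founder haplotypes are pure (single-strain) ancestry;
#' mosaics arise only in the meiotic products.
#'
#' @param genome A `genome_spec`.
#' @param strain Strain label (e.g., `"Vx"` or `"Gd"`).
#' @return A `founder_haplotype` object.
#' @export
founder_haplotype <- function(genome, strain) {
  .check_genome(genome)
  structure(list(genome = genome, strain = strain),
            class = "founder_haplotype")
}

#' Self the diploid somatic hybrid into a tetraploid genotype
#'
#' Models fertilization between gametes of the diploid hybrid: the resulting
#' sporophyte carries two copies of the mutant-strain haplotype (V1, V2) and
#' two of the wild-strain haplotype (G1, G2) on every chromosome, i.e. it is
#' duplex (m/m/+/+) at the causal locus and at every strain marker.
#'
#' @param hybrid_mutant_haplotype Founder haplotype of the mutant strain
#'   (carries the A-side marker alleles and the causal alternate allele).
#' @param hybrid_wild_haplotype Founder haplotype of the wild strain.
#' @return A `tetraploid` object.
#' @export
make_tetraploid <- function(hybrid_mutant_haplotype, hybrid_wild_haplotype) {
  stopifnot(inherits(hybrid_mutant_haplotype, "founder_haplotype"),
            inherits(hybrid_wild_haplotype, "founder_haplotype"))
  if (!identical(as.data.frame(hybrid_mutant_haplotype$genome),
                 as.data.frame(hybrid_wild_haplotype$genome))) {
    stop("incompatible genomes: the two founder haplotypes cover ",
         "different genome specs")
  }
  structure(list(genome = hybrid_mutant_haplotype$genome,
                 homologs = .HOMOLOG_LABELS,
                 strains = c(mutant = hybrid_mutant_haplotype$strain,
                             wild = hybrid_wild_haplotype$strain)),
            class = "tetraploid")
}

#' Simulate tetrasomic meioses
#'
#' Runs `n_meioses` independent meioses of the tetraploid. Per chromosome
#' and meiosis the four homologs pair into two bivalents (each of the three
#' pairings with probability 1/3), crossovers per bivalent are Poisson with
#' mean 2 x map length in Morgans placed uniformly on the genetic map
#' between one uniformly chosen chromatid of each paired homolog (no
#' interference), meiosis I separates paired homologs with random
#' orientation and meiosis II separates sisters. Every spore receives one
#' chromatid per bivalent and is therefore diploid.
#'
#' @param tetraploid A `tetraploid`.
#' @param n_meioses Number of meioses (>= 1).
#' @param seed Optional integer seed.
#' @return A list of `n_meioses` tetrads; each tetrad is a list of 4
#'   `spore` objects.
#' @export
simulate_meiosis <- function(tetraploid, n_meioses, seed = NULL) {
  stopifnot(inherits(tetraploid, "tetraploid"), n_meioses >= 1)
  if (!is.null(seed)) set.seed(seed)
  genome <- tetraploid$genome
  lapply(seq_len(n_meioses), function(m) .one_tetrad(genome))
}

.one_tetrad <- function(genome) {
  chroms <- genome$chrom
  per_chrom <- lapply(seq_along(chroms), function(i) {
    .meiosis_chromosome(genome$length_bp[i], genome$map_length_cM[i])
  })
  lapply(1:4, function(s) {
    haps <- lapply(per_chrom, function(pc) pc[[s]])
    names(haps) <- chroms
    structure(list(haps = haps), class = "spore")
  })
}

#' Homolog ancestry of a spore at a position
#'
#' @param spore A `spore`.
#' @param chrom Chromosome name.
#' @param pos Position(s) in bp.
#' @return A 2-row matrix of homolog labels (`"V1"`, `"V2"`, `"G1"`,
#'   `"G2"`), one row per haplotype copy, one column per position.
#' @export
ancestry_at <- function(spore, chrom, pos) {
  h <- spore$haps[[chrom]]
  if (is.null(h)) stop("spore does not cover chromosome ", chrom)
  rbind(.HOMOLOG_LABELS[.anc_at(h[[1L]], pos)],
        .HOMOLOG_LABELS[.anc_at(h[[2L]], pos)])
}

## mutant-allele dosage (0, 1, 2) of a spore at one position; homolog codes
## 1 and 2 descend from the mutant-strain haplotype
.causal_dosage <- function(spore, chrom, pos) {
  h <- spore$haps[[chrom]]
  if (is.null(h)) return(NA_integer_)
  (.anc_at(h[[1L]], pos) <= 2L) + (.anc_at(h[[2L]], pos) <= 2L)
}

#' Causal-locus genotype of a spore
#'
#' @param spore A `spore`.
#' @param causal A `causal_variant` (or any list with `chrom` and `pos_bp`).
#' @return One of `"mm"`, `"m+"`, `"++"`.
#' @export
causal_genotype <- function(spore, causal) {
  d <- .causal_dosage(spore, causal$chrom, causal$pos_bp)
  if (is.na(d)) stop("causal site not covered by the spore's haplotypes")
  c("++", "m+", "mm")[d + 1L]
}

#' Assign the recessive phenotype
#'
#' Under the recessive model only homozygous-mutant (`mm`) segregants fail
#' to make the 2D-to-3D transition.
#'
#' @param spore A `spore`.
#' @param causal A `causal_variant`.
#' @return `"no-3D"` for `mm`, otherwise `"3D"`.
#' @export
assign_phenotype <- function(spore, causal) {
  if (causal_genotype(spore, causal) == "mm") "no-3D" else "3D"
}

#' Lazy stream of phenotyped spores
#'
#' Returns a generator closure producing one spore per call, running fresh
#' meioses on demand. Each emitted spore carries `causal_genotype` and
#' `phenotype` fields. Memory-bounded pool construction at the 1/6
#' mutant-class frequency uses this stream.
#'
#' @param tetraploid A `tetraploid`.
#' @param causal A `causal_variant`.
#' @param seed Optional integer seed applied when the stream is created.
#' @return A function of no arguments returning the next `spore`.
#' @export
spore_stream <- function(tetraploid, causal, seed = NULL) {
  stopifnot(inherits(tetraploid, "tetraploid"))
  if (!is.null(seed)) set.seed(seed)
  genome <- tetraploid$genome
  buffer <- list()
  idx <- 0L
  function() {
    if (idx == 0L) {
      buffer <<- .one_tetrad(genome)
      idx <<- 4L
    }
    sp <- buffer[[5L - idx]]
    idx <<- idx - 1L
    sp$causal_genotype <- causal_genotype(sp, causal)
    sp$phenotype <- if (sp$causal_genotype == "mm") "no-3D" else "3D"
    sp
  }
}

#' Build the phenotype-sorted segregant pools
#'
#' Fills a mutant (`no-3D`) pool and a wild-type (`3D`) pool from a spore
#' source in generation order, mirroring the screen design of 120 mutant and
#' 120 phenotypically wild-type diploid segregants.
#'
#' @param spores A `tetraploid` (spores are then generated lazily), a spore
#'   generator closure from [spore_stream()], or a finite list of spores.
#' @param n_mutant,n_wildtype Pool sizes (>= 0).
#' @param causal A `causal_variant`; required unless `spores` is a
#'   pre-phenotyped stream or list.
#' @param seed Optional integer seed (used when `spores` is a `tetraploid`).
#' @param max_spores Safety cap on the number of spores examined.
#' @return A list with `mutant` and `wildtype` `segregant_pool`s, the
#'   `genotype_counts` (mm, m+, ++) over all spores examined, and
#'   `n_spores` examined.
#' @export
build_pools <- function(spores, n_mutant = 120, n_wildtype = 120,
                        causal = NULL, seed = NULL, max_spores = NULL) {
  stopifnot(n_mutant >= 0, n_wildtype >= 0)
  finite <- NULL
  if (inherits(spores, "tetraploid")) {
    if (is.null(causal)) stop("`causal` is required to phenotype spores")
    gen <- spore_stream(spores, causal, seed)
  } else if (is.function(spores)) {
    gen <- spores
  } else if (is.list(spores)) {
    finite <- spores
  } else {
    stop("`spores` must be a tetraploid, a generator, or a list of spores")
  }
  if (is.null(max_spores)) {
    max_spores <- max(1000L, 600L * (n_mutant + n_wildtype))
  }
  mut <- vector("list", n_mutant)
  wt <- vector("list", n_wildtype)
  n_mut <- 0L
  n_wt <- 0L
  gcounts <- c(mm = 0L, `m+` = 0L, `++` = 0L)
  n_seen <- 0L
  while (n_mut < n_mutant || n_wt < n_wildtype) {
    if (!is.null(finite)) {
      if (n_seen >= length(finite)) {
        stop("insufficient segregants: spore list exhausted after ",
             n_seen, " spores (", n_mut, "/", n_mutant, " mutant, ",
             n_wt, "/", n_wildtype, " wild-type)")
      }
      sp <- finite[[n_seen + 1L]]
    } else {
      if (n_seen >= max_spores) {
        stop("insufficient segregants: examined ", n_seen,
             " spores without filling both pools")
      }
      sp <- gen()
    }
    n_seen <- n_seen + 1L
    if (is.null(sp$causal_genotype)) {
      if (is.null(causal)) stop("spores lack phenotypes and `causal` is NULL")
      sp$causal_genotype <- causal_genotype(sp, causal)
      sp$phenotype <- if (sp$causal_genotype == "mm") "no-3D" else "3D"
    }
    gcounts[sp$causal_genotype] <- gcounts[sp$causal_genotype] + 1L
    if (sp$phenotype == "no-3D") {
      if (n_mut < n_mutant) {
        n_mut <- n_mut + 1L
        mut[[n_mut]] <- sp
      }
    } else if (n_wt < n_wildtype) {
      n_wt <- n_wt + 1L
      wt[[n_wt]] <- sp
    }
  }
  list(
    mutant = structure(list(spores = mut, phenotype = "no-3D", n = n_mutant),
                       class = "segregant_pool"),
    wildtype = structure(list(spores = wt, phenotype = "3D", n = n_wildtype),
                         class = "segregant_pool"),
    genotype_counts = gcounts,
    n_spores = n_seen
  )
}

#' @export
print.segregant_pool <- function(x, ...) {
  cat("Segregant pool:", x$n, "diploid spores, phenotype", x$phenotype, "\n")
  invisible(x)
}

#' Export spore genotypes at marker positions as a multi-sample VCF
#'
#' Debugging aid: writes per-spore genotypes (GT; mutant-strain allele coded
#' as ALT) at every marker.
#'
#' @param spores List of spores.
#' @param markers A `strain_marker_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spore_vcf <- function(spores, markers, path) {
  ids <- sprintf("spore%03d", seq_along(spores))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  rows <- character(nrow(markers))
  gt_mat <- matrix("", nrow(markers), length(spores))
  for (ch in unique(markers$chrom)) {
    sel <- which(markers$chrom == ch)
    pos <- markers$pos[sel]
    for (j in seq_along(spores)) {
      h <- spores[[j]]$haps[[ch]]
      a1 <- as.integer(.anc_at(h[[1L]], pos) <= 2L)
      a2 <- as.integer(.anc_at(h[[2L]], pos) <= 2L)
      gt_mat[sel, j] <- paste0(a1, "/", a2)
    }
  }
  for (r in seq_len(nrow(markers))) {
    rows[r] <- paste(c(markers$chrom[r], format(markers$pos[r], scientific = FALSE),
                       ".", markers$allele_B[r], markers$allele_A[r], ".",
                       "PASS", ".", "GT", gt_mat[r, ]), collapse = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}
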