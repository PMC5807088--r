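## Count-level model of pooled Illumina sequencing plus variant calling.
## Read-level simulation (FASTQ, alignment, duplicate marking) is out of
## scope: the model emits per-marker allelic depths directly.

#' Quality-score proxy model
#'
#' The pipeline filters sites on a caller-style quality score (> 500). The
#' simulator has no variant caller, so site quality is modelled as
#' `scale x depth`, with a small contamination fraction of sites assigned a
#' low quality drawn uniformly on (0, `contamination_max`) so the quality
#' filter is exercised.
#'
#' @param scale Quality units per read of depth (default 50).
#' @param contamination_frac Fraction of low-quality sites (default 0.02).
#' @param contamination_max Upper bound of the low-quality draw (default 500).
#' @return A `qual_model` list.
#' @export
qual_model <- function(scale = 50, contamination_frac = 0.02,
                       contamination_max = 500) {
  stopifnot(scale > 0, contamination_frac >= 0, contamination_frac <= 1,
            contamination_max >= 0)
  structure(list(scale = scale, contamination_frac = contamination_frac,
                 contamination_max = contamination_max),
            class = "qual_model")
}

.draw_qual <- function(depth, qm) {
  q <- qm$scale * depth
  contam <- stats::runif(length(depth)) < qm$contamination_frac
  q[contam] <- stats::runif(sum(contam), 0, qm$contamination_max)
  q
}

.new_pool_table <- function(chrom, pos, allele_A, allele_B,
                            count_A, count_B, depth, qual) {
  tbl <- data.frame(chrom = chrom, pos = pos, allele_A = allele_A,
                    allele_B = allele_B, count_A = count_A,
                    count_B = count_B, depth = depth, qual = qual,
                    stringsAsFactors = FALSE)
  rownames(tbl) <- NULL
  class(tbl) <- c("pool_count_table", "data.frame")
  tbl
}

## true A-side (mutant-strain) allele frequency per marker in a pool:
## summed A-allele dosage over members / (2 x pool size)
.pool_true_freq <- function(pool, markers) {
  f <- numeric(nrow(markers))
  for (ch in unique(markers$chrom)) {
    sel <- which(markers$chrom == ch)
    pos <- markers$pos[sel]
    dos <- integer(length(sel))
    for (sp in pool$spores) {
      h <- sp$haps[[ch]]
      if (is.null(h)) stop("pool spores do not cover chromosome ", ch)
      dos <- dos + (.anc_at(h[[1L]], pos) <= 2L) + (.anc_at(h[[2L]], pos) <= 2L)
    }
    f[sel] <- dos / (2 * pool$n)
  }
  f
}

#' Simulate pooled read counts for one pool
#'
#' Per marker the true A-side allele frequency `f` is the pool's summed
#' mutant-strain allele dosage over `2 x pool size`; sequencing depth is
#' Poisson(`mean_depth`) (negative binomial when `overdispersion > 0`), and
#' the A-allele read count is Binomial(depth, `f(1-e) + (1-f)e`) with
#' symmetric base-error rate `e` (error reads are mis-assigned between the
#' two alleles, never to third alleles). Zero-depth sites are retained with
#' both counts zero; their frequency is undefined and they fall to the
#' downstream coverage filter.
#'
#' @param pool A `segregant_pool` with at least one member.
#' @param markers A `strain_marker_map`.
#' @param mean_depth Mean sequencing depth per site (> 0).
#' @param error_rate Per-read allele mis-assignment probability in [0, 0.5).
#' @param qual_model A [qual_model()].
#' @param seed Optional integer seed.
#' @param overdispersion Depth overdispersion; 0 gives Poisson depth,
#'   values > 0 give negative binomial with `size = mean_depth /
#'   overdispersion`.
#' @return A `pool_count_table` with one row per marker.
#' @export
simulate_pool_counts <- function(pool, markers, mean_depth = 50,
                                 error_rate = 0.002,
                                 qual_model = tetraBSA::qual_model(),
                                 seed = NULL, overdispersion = 0) {
  if (!inherits(pool, "segregant_pool")) stop("`pool` must be a segregant_pool")
  if (pool$n < 1 || length(pool$spores) < 1) {
    stop("invalid pool: empty pools cannot be sequenced")
  }
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  f <- .pool_true_freq(pool, markers)
  m <- nrow(markers)
  depth <- if (overdispersion > 0) {
    stats::rnbinom(m, size = mean_depth / overdispersion, mu = mean_depth)
  } else {
    stats::rpois(m, mean_depth)
  }
  p <- f * (1 - error_rate) + (1 - f) * error_rate
  count_A <- stats::rbinom(m, depth, p)
  .new_pool_table(markers$chrom, markers$pos, markers$allele_A,
                  markers$allele_B, count_A, depth - count_A, depth,
                  .draw_qual(depth, qual_model))
}

#' Simulate parental-strain count tables
#'
#' The two parental lines are sequenced alongside the pools; parent A is
#' homozygous for the A-side allele at every marker and parent B for the
#' B-side allele, subject to the same depth and error model.
#'
#' @inheritParams simulate_pool_counts
#' @param markers A `strain_marker_map`.
#' @return A list with `parent_A` and `parent_B` `pool_count_table`s.
#' @export
simulate_parental_tables <- function(markers, mean_depth = 50,
                                     error_rate = 0.002,
                                     qual_model = tetraBSA::qual_model(),
                                     seed = NULL) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 0.5)
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(markers)
  one <- function(f) {
    depth <- stats::rpois(m, mean_depth)
    p <- f * (1 - error_rate) + (1 - f) * error_rate
    count_A <- stats::rbinom(m, depth, p)
    .new_pool_table(markers$chrom, markers$pos, markers$allele_A,
                    markers$allele_B, count_A, depth - count_A, depth,
                    .draw_qual(depth, qual_model))
  }
  list(parent_A = one(1), parent_B = one(0))
}

#' Combine per-pool count tables into a two-pool variant table
#'
#' @param mutant,wildtype `pool_count_table`s over the same markers.
#' @return A `pooled_variant_table` with `_mut` and `_wt` suffixed count,
#'   depth and quality columns, sorted by (chrom, pos).
#' @export
combine_pool_tables <- function(mutant, wildtype) {
  key <- c("chrom", "pos", "allele_A", "allele_B")
  if (!identical(mutant[key], wildtype[key])) {
    m <- merge(as.data.frame(mutant), as.data.frame(wildtype), by = key,
               suffixes = c("_mut", "_wt"))
  } else {
    m <- as.data.frame(mutant)
    names(m)[5:8] <- paste0(c("count_A", "count_B", "depth", "qual"), "_mut")
    m[paste0(c("count_A", "count_B", "depth", "qual"), "_wt")] <-
      as.data.frame(wildtype)[c("count_A", "count_B", "depth", "qual")]
  }
  m <- m[order(m$chrom, m$pos), ]
  rownames(m) <- NULL
  class(m) <- c("pooled_variant_table", "data.frame")
  m
}

#' @export
print.pool_count_table <- function(x, ...) {
  cat("Pool count table:", nrow(x), "sites, mean depth",
      round(mean(x$depth), 1), "\n")
  invisible(x)
}
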