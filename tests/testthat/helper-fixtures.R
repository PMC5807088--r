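# Shared fixtures: a small 3-chromosome genome with its causal locus, and a
# reduced screen configuration that keeps unit tests fast while preserving
# every stage of the pipeline.

small_genome <- function(n_chrom = 3, len = 5e5, cM = 100) {
  build_genome(n_chrom, len, cM)
}

# genome + markers + causal variant + tetraploid, deterministically seeded
small_screen_fixture <- function(seed = 101, density = 1) {
  g <- small_genome()
  mk <- place_strain_markers(g, density, seed = seed)
  cds <- make_causal_cds(g, "chr1", 0.5)
  ins <- insert_causal_mutation(g, mk, "chr1", cds$causal_pos, cds)
  tet <- make_tetraploid(founder_haplotype(g, "Vx"),
                         founder_haplotype(g, "Gd"))
  list(genome = g, markers = ins$markers, causal = ins$causal,
       cds = cds, tetraploid = tet)
}

# 25 cM over 500 kb preserves the default 0.05 cM/kb recombination density,
# so window-scale linkage decay matches the full-size screen
small_screen_config <- function(seed = 7, n_mutant = 60, n_wildtype = 60,
                                ...) {
  screen_config(n_chrom = 3, chrom_length_bp = 5e5, map_length_cM = 25,
                marker_density_per_kb = 1, n_mutant = n_mutant,
                n_wildtype = n_wildtype, mean_depth = 50, seed = seed, ...)
}

# hand-buildable two-pool variant table
toy_pooled_table <- function(depth_mut, depth_wt, qual_mut, qual_wt,
                             count_A_mut = NULL, count_A_wt = NULL) {
  n <- length(depth_mut)
  if (is.null(count_A_mut)) count_A_mut <- round(depth_mut / 2)
  if (is.null(count_A_wt)) count_A_wt <- round(depth_wt / 2)
  tbl <- data.frame(
    chrom = rep("chr1", n), pos = seq(1000, by = 1000, length.out = n),
    allele_A = rep("T", n), allele_B = rep("C", n),
    count_A_mut = count_A_mut, count_B_mut = depth_mut - count_A_mut,
    depth_mut = depth_mut, qual_mut = qual_mut,
    count_A_wt = count_A_wt, count_B_wt = depth_wt - count_A_wt,
    depth_wt = depth_wt, qual_wt = qual_wt,
    stringsAsFactors = FALSE)
  class(tbl) <- c("pooled_variant_table", "data.frame")
  tbl
}
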