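---
title: "Mapping recessive loci through tetraploid meiosis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping recessive loci through tetraploid meiosis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tetraBSA)
```

## The mapping problem

Forward-genetics screens in mosses can yield mutants that are blocked
before the reproductive stage — for example mutants that grow indefinitely
as 2D protonemal filaments but never initiate the 3D gametophores that
bear the sexual organs. Such mutants cannot be outcrossed, so the causal
mutation cannot be mapped by a conventional cross. The strategy modelled
here escapes that dead end in three steps:

1. **Somatic hybridization.** Protoplasts of the (haploid) mutant and of a
   fertile, genetically distant strain are fused. The diploid hybrid is
   heterozygous at the causal locus; a recessive mutation is complemented
   and the hybrid is fertile.
2. **Tetraploid meiosis.** Self-fertilization of the diploid hybrid
   produces a tetraploid sporophyte. Its meiosis yields *diploid* spores
   whose genomes are recombined mosaics of the two parental backgrounds.
3. **Bulk segregant analysis.** Spores are grown clonally,
   phenotype-scored, and pooled (mutant-phenotype pool and wild-type
   phenotype pool); pooled sequencing of both pools plus the two parents
   locates the causal locus where the pools' strain-allele frequencies
   diverge.

Every stage of this design is implemented as a testable module: a genome
and marker simulator, a tetrasomic meiosis simulator, a pooled read-count
simulator, the BSA filtering/track/interval analysis, a coding-effect
annotator, and the segregation statistics.

## Tetrasomic inheritance model

Each chromosome of the tetraploid carries four homologs: two copies of the
mutant-strain haplotype (`V1`, `V2`) and two of the wild-strain haplotype
(`G1`, `G2`). Meiosis is modelled per chromosome as:

- **Bivalent pairing.** The four homologs form two bivalents; all three
  pairings are equiprobable (1/3 each). Multivalents — and therefore
  *double reduction* — are excluded: the observed segregation of such
  screens fits the random-chromosome 1:4:1 expectation that the
  bivalent-only model produces, and nothing in the data motivates a
  homoeologous pairing bias between same-strain copies (the two strains
  are conspecific).
- **Crossovers.** Per bivalent, the crossover count is Poisson with mean
  2 × (map length in Morgans) — each of the four chromatids then
  experiences on average half of that, consistent with a Haldane-type
  map — placed uniformly on the genetic map with no interference and no
  obligate chiasma. Each crossover picks one chromatid of each paired
  homolog uniformly and exchanges their distal segments.
- **Disjunction.** Meiosis I separates paired homologs to opposite poles
  with random orientation per bivalent; meiosis II separates sisters. Each
  of the four spores receives one chromatid per bivalent, hence two copies
  of every chromosome: spores are diploid.

At any single locus this reduces to drawing 2 of the 4 homolog copies
without replacement, giving `P(mm) = P(++) = 1/6` and `P(m+) = 4/6` for a
duplex locus — the 1:4:1 ratio — and the pool-level signatures: allele
frequency 1.0 in the mutant-phenotype pool and
`(4/5)(1/2) + (1/5)(0) = 0.4` in the wild-type-phenotype pool.
`tetrasomic_expectations()` derives these constants by enumeration rather
than hard-coding them.

The tetrad data structure retains full chromatid-level ancestry, and the
invariant that each homolog label appears exactly twice at every position
across a tetrad's eight chromatid copies is property-tested.

## Synthetic data model

**Genome.** Chromosomes are identically shaped with a *uniform genetic
map* (constant cM/bp), so physical and genetic coordinates interconvert
linearly. Real chromosome-scale recombination landscapes are not uniform;
nothing in the analysis depends on the map's shape, only on the local
cM/bp scale around the causal locus. The desk-scale default — 27
chromosomes × 2 Mb × 100 cM, 1 marker/kb — preserves the target species'
chromosome number and an informative marker density while keeping a full
screen at a few seconds of CPU. The real genome's ~2.3 million
strain-distinguishing SNVs over ~470 Mb correspond to a similar per-kb
marker density.

**Markers.** Marker counts per chromosome are Poisson(density × kb),
positions uniform without collision, alleles biallelic and
homozygous-different between strains. The causal variant is inserted into
the marker map (replacing any colliding marker), so it is always
genotyped.

**Causal gene.** The causal CDS carries an arginine `CGA` codon at a
configurable residue (default 76); the causal variant is the C>T
transition at its first base, producing `TGA` — a premature termination
codon annotated `R76Ter`.

**Pooled counts.** For a pool of n segregants, the true A-side frequency
at a marker is the summed mutant-strain allele dosage over 2n. Depth is
Poisson(mean depth; a negative-binomial overdispersion knob exists),
and the A-allele read count is Binomial(depth, f(1−e) + (1−f)e) with a
symmetric per-read error e: error reads are mis-assigned between the two
alleles, never to third alleles, so a 0.5-frequency site stays unbiased.
Zero-depth sites are retained with undefined frequency and removed by the
coverage filter downstream, keeping the filtering semantics observable.

**Quality proxy.** The real pipeline filters on a caller-assigned site
quality (> 500); a count-level simulator has no caller, so quality is
modelled as `50 × depth` with a 2% contamination fraction drawn
Uniform(0, 500). This is a labelled stand-in whose only purpose is to make
the quality filter's behavior testable; it makes no claim about any
caller's quality distribution.

What the generator deliberately does **not** emulate: read-level artifacts
(mapping error, duplicates, indel realignment), indels and structural
variants, chiasma interference, double reduction, aneuploidy, segregation
distortion, or non-uniform marker/recombination landscapes. Passing tests
therefore demonstrate correctness of the genetic model and of the analysis
logic under those idealizations, not robustness to every artifact of real
pooled sequencing.

## Analysis choices

- **Marker derivation** from parental tables keeps sites with parent-A
  A-side frequency ≥ 0.9, parent-B ≤ 0.1, both depths ≥ 10 (defaults):
  sites effectively fixed for different alleles in the two backgrounds.
- **Filters.** Strict inequalities on both bounds: depth must satisfy
  `0.5·mean < depth < 2·mean` in *both* pools, and quality `> 500`. The
  mean is the per-pool arithmetic mean over the *input* table, genome-wide
  — the scope is fixed to make re-filtering well defined: the recorded
  input means are attached to the output, and re-applying the filter with
  those means is a no-op (asserted in tests). Boundary rows (depth exactly
  0.5× mean, quality exactly 500) are excluded.
- **Tracks.** Per-site frequency is `count_A / depth`; zero-depth rows are
  excluded rather than imputed, matching the effect of the coverage
  filter. Windows of 100 kb slide at half-window steps; the window value
  is the mean (median available) of member-site frequencies; windows with
  fewer than 5 members are undefined. 100 kb at the default map equals
  5 cM, wide enough to average pool-composition noise, narrow enough that
  linkage decay inside a window is small.
- **Interval rule.** The candidate interval is the maximal contiguous run
  of windows ≥ 0.98 (configurable) on the chromosome holding the global
  windowed maximum, with boundaries at the outermost member markers. The
  threshold was chosen a priori from the model: with error-free counts the
  expected windowed peak is ≈ 1 − (2/3)·r̄ ≈ 0.99 at the default map and
  window (r̄ the mean within-window recombination fraction to the locus),
  with sampling noise of a few parts per thousand at 120 segregants and
  50× depth, so 0.98 is rarely broken by noise yet excludes the 0.5
  background decisively. Ties for the global maximum break to the lowest
  chromosome index, then lowest position, for determinism. A screen where
  no window reaches the threshold returns an explicit no-interval result
  (an unmapped screen), distinct from an error.
- **WT-pool diagnostic.** Inside a found interval the mean wild-type-pool
  frequency is compared to 0.4 at tolerance 0.05 — a consistency check on
  the recessive duplex model, not a gate: a dominant misconfiguration
  (wild-type pool all `++`) shows up as ≈ 0.
- **Effect annotation.** "Regulatory region" has no standard definition at
  this scale; the default is a 1 kb promoter-proximal window upstream of
  the CDS start, configurable per gene model. Residues are numbered
  1-based from the initiator methionine; stops are labelled `Ter`; a stop
  in the final codon is not premature. Candidates rank premature stop >
  missense > regulatory > synonymous, ties by position — the ranking of
  non-stop candidates is this package's own convention. Splice-isoform
  effects, indels and UTR annotation are out of scope; one canonical CDS
  per gene.
- **Segregation test.** Raw Pearson chi-square (no continuity correction),
  p-value from the chi-square survival function (`stats::pchisq`, i.e. the
  regularized incomplete gamma function); expected counts below 5 warn but
  compute. The statistic is invariant to rescaling of the expected ratio,
  and for df = 2 the p-value equals `exp(-x/2)` exactly — both are tested.
  `simulate_segregation_test()` calibrates the test's size by multinomial
  simulation (≈ 0.95 conformity at α = 0.05 under the true ratio).

## Randomness and reproducibility

All stochastic stages accept a seed; `run_screen()` seeds once from the
configuration's master seed and draws every stage from that single
sequential stream, so a (config, seed) pair reproduces a screen
bit-for-bit (asserted in tests). Spores are generated lazily when filling
pools, keeping memory bounded at the 1/6 mutant frequency. Parallel
substreams are not offered; generation is serial by design.

## Problem sizes used in the test suite

Unit tests run on 3 × 500 kb genomes at 25 cM — the same cM/bp and
marker density as the full default, so window-scale linkage behavior is
preserved. Distribution-level checks use 60,000 spores (segregation
ratios), 50 replicate pools of 120 (the 0.4 signature), and 20 replicate
full-size default screens (locus recovery ≥ 95%, background windowed
frequencies < 0.9), each asserted within 3 Monte-Carlo standard errors.
These sizes were chosen so Monte-Carlo error is small relative to the
tested effect while a complete run stays in the minutes range.

## Known limitations

- The uniform genetic map and uniform marker placement are stand-ins, not
  claims about any real genome; recovery rates on real data depend on the
  local marker density and recombination rate around the locus.
- The count-level sequencing model cannot expose alignment- or
  caller-level failure modes; the quality proxy only exercises the filter.
- The interval's edges are a thresholding convention; no confidence
  interval is attached to them.
- Only biallelic SNVs are modelled and annotated.
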