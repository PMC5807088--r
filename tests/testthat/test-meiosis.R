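test_that("tetraploid formation requires compatible genomes", {
  g <- small_genome()
  g2 <- build_genome(2, 5e5, 100)
  expect_error(make_tetraploid(founder_haplotype(g, "Vx"),
                               founder_haplotype(g2, "Gd")),
               "incompatible genomes")
  tet <- make_tetraploid(founder_haplotype(g, "Vx"),
                         founder_haplotype(g, "Gd"))
  expect_equal(tet$homologs, c("V1", "V2", "G1", "G2"))
})

test_that("zero map length yields intact parental homologs in every spore", {
  g <- build_genome(2, 1e5, 0)
  tet <- make_tetraploid(founder_haplotype(g, "Vx"),
                         founder_haplotype(g, "Gd"))
  tetrads <- simulate_meiosis(tet, 5, seed = 11)
  for (td in tetrads) {
    for (sp in td) {
      for (ch in names(sp$haps)) {
        for (tid in sp$haps[[ch]]) {
          expect_length(tid$ends, 1)  # single segment: no breakpoints
        }
      }
    }
  }
})

test_that("chromatid conservation: every homolog appears exactly twice per position", {
  fx <- small_screen_fixture()
  tetrads <- simulate_meiosis(fx$tetraploid, 20, seed = 12)
  set.seed(13)
  probes <- sort(sample.int(5e5, 100))
  for (td in tetrads[1:10]) {
    for (ch in fx$genome$chrom) {
      labs <- do.call(rbind, lapply(td, ancestry_at, chrom = ch, pos = probes))
      # labs: 8 rows (chromatid copies) x 100 probe positions; every
      # homolog label must appear exactly twice in each column
      counts <- apply(labs, 2, function(v) {
        as.vector(table(factor(v, levels = c("V1", "V2", "G1", "G2"))))
      })
      expect_true(all(counts == 2L))
    }
  }
})

test_that("segments tile each chromosome exactly with increasing breakpoints", {
  fx <- small_screen_fixture()
  tetrads <- simulate_meiosis(fx$tetraploid, 10, seed = 14)
  for (td in tetrads) {
    for (sp in td) {
      for (i in seq_along(sp$haps)) {
        len <- fx$genome$length_bp[i]
        for (tid in sp$haps[[i]]) {
          expect_true(all(diff(tid$ends) > 0))
          expect_equal(tid$ends[length(tid$ends)], len)
          expect_length(tid$anc, length(tid$ends))
        }
      }
    }
  }
})

test_that("causal-locus genotypes converge to the 1:4:1 tetrasomic ratio", {
  g <- build_genome(1, 5e5, 100)
  tet <- make_tetraploid(founder_haplotype(g, "Vx"),
                         founder_haplotype(g, "Gd"))
  causal <- list(chrom = "chr1", pos_bp = 2.5e5)
  tetrads <- simulate_meiosis(tet, 3000, seed = 15)
  gt <- table(vapply(unlist(tetrads, recursive = FALSE),
                     causal_genotype, "", causal = causal))
  n <- sum(gt)
  for (cls in c("mm", "++")) {
    se <- sqrt((1 / 6) * (5 / 6) / n)
    expect_lt(abs(gt[[cls]] / n - 1 / 6), 3 * se)
  }
  se <- sqrt((4 / 6) * (2 / 6) / n)
  expect_lt(abs(gt[["m+"]] / n - 4 / 6), 3 * se)
})

test_that("phenotype follows the recessive model", {
  fx <- small_screen_fixture()
  sps <- unlist(simulate_meiosis(fx$tetraploid, 50, seed = 16),
                recursive = FALSE)
  for (sp in sps[1:40]) {
    gt <- causal_genotype(sp, fx$causal)
    expect_equal(assign_phenotype(sp, fx$causal),
                 if (gt == "mm") "no-3D" else "3D")
  }
  bad_causal <- list(chrom = "chr99", pos_bp = 100)
  expect_error(assign_phenotype(sps[[1]], bad_causal), "not covered")
})

test_that("unlinked markers sit at frequency 0.5 even conditioned on phenotype", {
  fx <- small_screen_fixture()
  pools <- build_pools(fx$tetraploid, 60, 60, fx$causal, seed = 17)
  # chr3 carries no causal locus: expect 0.5 in the mutant pool
  probe <- fx$markers[fx$markers$chrom == "chr3", ][10, ]
  dos <- vapply(pools$mutant$spores, function(sp) {
    sum(ancestry_at(sp, "chr3", probe$pos) %in% c("V1", "V2"))
  }, numeric(1))
  f <- sum(dos) / (2 * 60)
  se <- sqrt(0.25 / (2 * 60))
  expect_lt(abs(f - 0.5), 4 * se)
})

test_that("mutant-pool allele frequency decays with distance from the causal locus", {
  fx <- small_screen_fixture()
  pools <- build_pools(fx$tetraploid, 80, 0, fx$causal, seed = 18)
  at <- function(pos) {
    dos <- vapply(pools$mutant$spores, function(sp) {
      sum(ancestry_at(sp, "chr1", pos) %in% c("V1", "V2"))
    }, numeric(1))
    sum(dos) / (2 * 80)
  }
  near <- at(fx$causal$pos_bp)
  far <- at(2.5e4)  # ~45 cM away
  expect_equal(near, 1)
  expect_lt(far, near)
  expect_gt(far, 0.3)  # still above the unlinked 0.5 minus noise? loose sanity
})

test_that("build_pools fills pools in generation order and flags exhaustion", {
  fx <- small_screen_fixture()
  pools <- build_pools(fx$tetraploid, 20, 20, fx$causal, seed = 19)
  expect_equal(pools$mutant$n, 20)
  expect_true(all(vapply(pools$mutant$spores, `[[`, "", "causal_genotype")
                  == "mm"))
  expect_true(all(vapply(pools$wildtype$spores, `[[`, "", "phenotype")
                  == "3D"))

  empty <- build_pools(fx$tetraploid, 0, 5, fx$causal, seed = 20)
  expect_equal(empty$mutant$n, 0)

  few <- unlist(simulate_meiosis(fx$tetraploid, 2, seed = 21),
                recursive = FALSE)
  expect_error(build_pools(few, 50, 50, fx$causal),
               "insufficient segregants")
})

test_that("meiosis is reproducible under a fixed seed", {
  fx <- small_screen_fixture()
  t1 <- simulate_meiosis(fx$tetraploid, 3, seed = 22)
  t2 <- simulate_meiosis(fx$tetraploid, 3, seed = 22)
  expect_identical(t1, t2)
})
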