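test_that("strain markers derived from error-free parents match the truth exactly", {
  fx <- small_screen_fixture(density = 0.5)
  pt <- simulate_parental_tables(fx$markers, 60, 0, seed = 71)
  derived <- derive_strain_markers(pt$parent_A, pt$parent_B,
                                   min_freq = 0.9, min_depth = 10)
  truth <- as.data.frame(fx$markers)
  keep <- pt$parent_A$depth >= 10 & pt$parent_B$depth >= 10
  expect_equal(as.data.frame(derived), truth[keep, ], ignore_attr = TRUE)
})

test_that("non-distinguishing and low-depth sites are excluded from derivation", {
  tblA <- data.frame(chrom = "chr1", pos = c(100, 200, 300),
                     allele_A = "T", allele_B = "C",
                     count_A = c(30, 15, 30), count_B = c(0, 15, 0),
                     depth = c(30, 30, 30), qual = 1000)
  tblB <- tblA
  tblB$count_A <- c(0, 15, 0)
  tblB$count_B <- c(30, 15, 30)
  tblB$depth[3] <- 5  # below min_depth
  tblB$count_A[3] <- 0
  tblB$count_B[3] <- 5
  mk <- derive_strain_markers(tblA, tblB, min_freq = 0.9, min_depth = 10)
  # site 200 is 0.5/0.5 in both parents (not distinguishing); 300 low depth
  expect_equal(mk$pos, 100)
})

test_that("disjoint parental tables warn and return an empty map", {
  tblA <- data.frame(chrom = "chr1", pos = 100, allele_A = "T",
                     allele_B = "C", count_A = 30, count_B = 0,
                     depth = 30, qual = 1000)
  tblB <- tblA
  tblB$pos <- 999
  expect_warning(mk <- derive_strain_markers(tblA, tblB), "no sites")
  expect_equal(nrow(mk), 0)
})

test_that("the coverage/quality filter enforces strict boundaries on the toy table", {
  # mean depth = 60 in both pools: bounds (30, 120) exclusive; qual > 500
  tbl <- toy_pooled_table(
    depth_mut = c(30, 150, 60, 55, 65, 63),
    depth_wt  = c(60, 60, 60, 62, 58, 57),
    qual_mut  = c(1000, 1000, 500, 900, 800, 700),
    qual_wt   = c(1000, 1000, 1000, 900, 800, 700))
  expect_equal(mean(tbl$depth_mut), 70.5)
  # recompute against hand-set means to pin the rule:
  out <- filter_variants(tbl, filter_config(),
                         mean_depth = c(mut = 60, wt = 60))
  # row1: depth_mut == 0.5*mean -> removed (strict); row2: > 2*mean removed;
  # row3: qual == 500 removed (strict); rows 4-6 pass
  expect_equal(out$pos, tbl$pos[4:6])
  expect_equal(nrow(out), 3)
})

test_that("filtering with recorded input means is a no-op on its own output", {
  tbl <- toy_pooled_table(
    depth_mut = c(10, 60, 60, 60, 200),
    depth_wt  = c(60, 60, 60, 60, 60),
    qual_mut  = rep(1000, 5), qual_wt = rep(1000, 5))
  out1 <- filter_variants(tbl)
  means <- attr(out1, "input_mean_depth")
  out2 <- filter_variants(out1, mean_depth = means)
  expect_equal(as.data.frame(out2), as.data.frame(out1))
})

test_that("empty input to the filter warns and returns empty", {
  tbl <- toy_pooled_table(numeric(), numeric(), numeric(), numeric())
  expect_warning(out <- filter_variants(tbl), "empty")
  expect_equal(nrow(out), 0)
})

test_that("allele frequencies are count_A/depth with zero-depth rows excluded", {
  tbl <- toy_pooled_table(
    depth_mut = c(30, 25, 30, 0),
    depth_wt  = c(30, 30, 30, 30),
    qual_mut = rep(1000, 4), qual_wt = rep(1000, 4),
    count_A_mut = c(30, 0, 12, 0),
    count_A_wt = c(12, 12, 12, 12))
  expect_message(track <- compute_allele_frequency(tbl), "zero-depth")
  expect_equal(track$markers$freq_mut, c(1, 0, 0.4))
  expect_equal(track$markers$freq_wt, c(0.4, 0.4, 0.4))
  expect_equal(nrow(track$markers), 3)
})

test_that("window smoothing averages member frequencies and respects min_markers", {
  mk <- data.frame(chrom = "chr1", pos = c(1000, 2000, 3000),
                   freq_mut = c(0.2, 0.4, 0.9), freq_wt = c(0.5, 0.5, 0.5))
  track <- structure(list(markers = mk, windows = NULL), class = "af_track")
  sm <- smooth_track(track, window_bp = 10000, min_markers = 3)
  expect_true(all(abs(sm$windows$freq_mut - 0.5) < 1e-12))
  expect_true(all(sm$windows$freq_wt == 0.5))

  # constant track stays constant under smoothing
  mk2 <- data.frame(chrom = "chr1", pos = seq(1000, 50000, by = 1000),
                    freq_mut = 0.5, freq_wt = 0.5)
  tr2 <- structure(list(markers = mk2, windows = NULL), class = "af_track")
  sm2 <- smooth_track(tr2, window_bp = 8000)
  expect_true(all(sm2$windows$freq_mut == 0.5))

  # windows below min_markers are dropped
  sm3 <- smooth_track(track, window_bp = 1500, min_markers = 2)
  expect_true(all(sm3$windows$n_markers >= 2))

  # windowed values bounded by member min/max
  expect_true(all(sm$windows$freq_mut >= 0.2 & sm$windows$freq_mut <= 0.9))
})

test_that("median smoothing is available", {
  mk <- data.frame(chrom = "chr1", pos = c(1000, 2000, 3000),
                   freq_mut = c(0, 0.4, 1), freq_wt = c(0.5, 0.5, 0.5))
  track <- structure(list(markers = mk, windows = NULL), class = "af_track")
  sm <- smooth_track(track, 10000, statistic = "median", min_markers = 3)
  expect_equal(sm$windows$freq_mut[1], 0.4)
})

test_that("a flat 0.5 track yields a no-interval result", {
  mk <- data.frame(chrom = rep(c("chr1", "chr2"), each = 50),
                   pos = rep(seq(1000, 50000, by = 1000), 2),
                   freq_mut = 0.5, freq_wt = 0.5)
  track <- structure(list(markers = mk, windows = NULL), class = "af_track")
  track <- smooth_track(track, 10000)
  iv <- detect_peak_interval(track, 0.98)
  expect_false(iv$found)
  expect_error(wt_pool_consistency(iv, track), "empty")
})

test_that("a synthetic peak is localized with the WT signature reported", {
  set.seed(72)
  pos <- seq(1000, 2e5, by = 1000)
  near <- abs(pos - 1e5) < 3e4
  mk <- rbind(
    data.frame(chrom = "chr1", pos = pos,
               freq_mut = ifelse(near, 1, 0.5),
               freq_wt = ifelse(near, 0.4, 0.5)),
    data.frame(chrom = "chr2", pos = pos, freq_mut = 0.5, freq_wt = 0.5))
  track <- structure(list(markers = mk, windows = NULL), class = "af_track")
  track <- smooth_track(track, 2e4)
  iv <- detect_peak_interval(track, 0.98)
  expect_true(iv$found)
  expect_equal(iv$chrom, "chr1")
  expect_lte(iv$start_bp, 1e5)
  expect_gte(iv$end_bp, 1e5)
  expect_equal(iv$mean_freq_wildtype_in_interval, 0.4, tolerance = 0.05)

  ok <- wt_pool_consistency(iv, track)
  expect_true(ok$pass)

  # dominance misconfiguration: WT pool all ++ would sit at 0 -> fail
  mk_dom <- mk
  mk_dom$freq_wt[mk_dom$chrom == "chr1" & near] <- 0
  tr_dom <- smooth_track(structure(list(markers = mk_dom, windows = NULL),
                                   class = "af_track"), 2e4)
  iv_dom <- detect_peak_interval(tr_dom, 0.98)
  bad <- wt_pool_consistency(iv_dom, tr_dom)
  expect_false(bad$pass)
  expect_lt(bad$observed, 0.1)
})

test_that("interval BED export is 0-based half-open", {
  iv <- structure(list(found = TRUE, chrom = "chr1", start_bp = 101,
                       end_bp = 200, peak_freq_mutant = 1,
                       mean_freq_wildtype_in_interval = 0.4,
                       n_markers = 5, peak_threshold = 0.98),
                  class = "candidate_interval")
  path <- withr::local_tempfile(fileext = ".bed")
  write_interval_bed(iv, path)
  expect_equal(readLines(path), "chr1\t100\t200\tcandidate_interval")
})
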