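## Bulk segregant analysis core: marker derivation from parental tables,
## the coverage/quality variant filters, per-pool allele-frequency tracks,
## sliding-window smoothing and candidate-interval detection. Under the
## duplex recessive model the mutant pool shows an allele-frequency peak of
## 1 at the causal locus and the wild-type pool a frequency of 0.4 there
## (4/5 heterozygotes at dosage 1/2, 1/5 homozygous wild type at 0).

#' Variant filter configuration
#'
#' The screen keeps a strain-distinguishing variant only if, in both pools,
#' the coverage depth is strictly greater than `depth_lower_mult` times and
#' strictly less than `depth_upper_mult` times the pool's mean coverage
#' depth, and the site quality is strictly greater than `min_qual`.
#'
#' @param depth_lower_mult Lower depth bound as a multiple of the mean
#'   (default 0.5).
#' @param depth_upper_mult Upper depth bound as a multiple of the mean
#'   (default 2).
#' @param min_qual Minimum site quality, exclusive (default 500).
#' @return A `filter_config` list.
#' @export
filter_config <- function(depth_lower_mult = 0.5, depth_upper_mult = 2,
                          min_qual = 500) {
  stopifnot(depth_lower_mult > 0, depth_upper_mult > depth_lower_mult,
            min_qual >= 0)
  structure(list(depth_lower_mult = depth_lower_mult,
                 depth_upper_mult = depth_upper_mult,
                 min_qual = min_qual),
            class = "filter_config")
}

#' Derive strain-distinguishing markers from parental count tables
#'
#' Compares the two parental strains' sequence data and keeps sites where
#' parent A's A-side allele frequency is at least `min_freq`, parent B's is
#' at most `1 - min_freq`, and both parents have depth at least
#' `min_depth` — i.e. sites effectively fixed for different alleles in the
#' two backgrounds.
#'
#' @param parentA_table,parentB_table `pool_count_table`s for the two
#'   parental strains.
#' @param min_freq Minimum within-parent major-allele frequency
#'   (default 0.9).
#' @param min_depth Minimum parental depth (default 10).
#' @param strain_A,strain_B Strain labels for the derived map.
#' @return A `strain_marker_map` of the retained sites.
#' @export
derive_strain_markers <- function(parentA_table, parentB_table,
                                  min_freq = 0.9, min_depth = 10,
                                  strain_A = "Vx", strain_B = "Gd") {
  key <- c("chrom", "pos")
  m <- merge(as.data.frame(parentA_table), as.data.frame(parentB_table),
             by = c(key, "allele_A", "allele_B"), suffixes = c("_pa", "_pb"))
  if (nrow(m) == 0) {
    warning("parental tables share no sites; returning an empty marker map")
    return(.as_marker_map(
      data.frame(chrom = character(), pos = numeric(),
                 allele_A = character(), allele_B = character(),
                 stringsAsFactors = FALSE), NULL, strain_A, strain_B))
  }
  fa <- ifelse(m$depth_pa > 0, m$count_A_pa / m$depth_pa, NA_real_)
  fb <- ifelse(m$depth_pb > 0, m$count_A_pb / m$depth_pb, NA_real_)
  keep <- !is.na(fa) & !is.na(fb) &
    fa >= min_freq & fb <= 1 - min_freq &
    m$depth_pa >= min_depth & m$depth_pb >= min_depth
  out <- m[keep, c("chrom", "pos", "allele_A", "allele_B")]
  out <- out[order(out$chrom, out$pos), ]
  .as_marker_map(out, NULL, strain_A, strain_B)
}

#' Apply the coverage and quality variant filters
#'
#' Mean coverage depth is computed per pool over *all* rows of the input
#' table (genome-wide scope); a row survives only if in both pools
#' `lower x mean < depth < upper x mean` (strict) and `qual > min_qual`
#' (strict). Row order is preserved. The per-pool means used are recorded
#' on the result as attribute `input_mean_depth`; re-applying the filter
#' with those recorded means is a no-op.
#'
#' @param table A `pooled_variant_table` (two-pool, `_mut`/`_wt` columns).
#' @param cfg A [filter_config()].
#' @param mean_depth Optional named vector `c(mut = , wt = )` of means to
#'   use instead of recomputing from `table`.
#' @return The filtered `pooled_variant_table`.
#' @export
filter_variants <- function(table, cfg = filter_config(), mean_depth = NULL) {
  if (nrow(table) == 0) {
    warning("empty variant table; nothing to filter")
    attr(table, "input_mean_depth") <- c(mut = NaN, wt = NaN)
    return(table)
  }
  if (is.null(mean_depth)) {
    mean_depth <- c(mut = mean(table$depth_mut), wt = mean(table$depth_wt))
  }
  lo <- cfg$depth_lower_mult
  hi <- cfg$depth_upper_mult
  keep <- table$depth_mut > lo * mean_depth[["mut"]] &
    table$depth_mut < hi * mean_depth[["mut"]] &
    table$depth_wt > lo * mean_depth[["wt"]] &
    table$depth_wt < hi * mean_depth[["wt"]] &
    table$qual_mut > cfg$min_qual &
    table$qual_wt > cfg$min_qual
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(table)
  attr(out, "input_mean_depth") <- mean_depth
  out
}

#' Compute per-pool allele-frequency tracks
#'
#' The per-site statistic is `count_A / depth` in each pool, with A the
#' mutant-strain allele. Sites with zero depth in either pool have an
#' undefined frequency and are excluded from the track (a message reports
#' how many).
#'
#' @param table A `pooled_variant_table`.
#' @return An `af_track` (list with `markers`; `windows` is filled by
#'   [smooth_track()]).
#' @export
compute_allele_frequency <- function(table) {
  defined <- table$depth_mut > 0 & table$depth_wt > 0
  if (any(!defined)) {
    message(sum(!defined), " zero-depth site(s) excluded from the track")
  }
  t2 <- table[defined, , drop = FALSE]
  markers <- data.frame(
    chrom = t2$chrom, pos = t2$pos,
    freq_mut = t2$count_A_mut / t2$depth_mut,
    freq_wt = t2$count_A_wt / t2$depth_wt,
    stringsAsFactors = FALSE)
  markers <- markers[order(markers$chrom, markers$pos), ]
  rownames(markers) <- NULL
  structure(list(markers = markers, windows = NULL,
                 window_bp = NULL, statistic = NULL),
            class = "af_track")
}

#' Smooth an allele-frequency track with sliding windows
#'
#' Windows of width `window_bp` slide with step `window_bp / 2` along each
#' chromosome's marker extent; the window value is the chosen statistic of
#' the member-marker frequencies. Windows with fewer than `min_markers`
#' members are undefined and dropped.
#'
#' @param track An `af_track`.
#' @param window_bp Window width in bases (> 0).
#' @param statistic `"mean"` or `"median"`.
#' @param min_markers Minimum markers per defined window (default 5).
#' @return The `af_track` with `windows` filled (`chrom`, `start`, `end`,
#'   `center`, `n_markers`, `freq_mut`, `freq_wt`).
#' @export
smooth_track <- function(track, window_bp = 1e5,
                         statistic = c("mean", "median"), min_markers = 5) {
  stopifnot(inherits(track, "af_track"), window_bp > 0)
  statistic <- match.arg(statistic)
  fun <- if (statistic == "mean") mean else stats::median
  mk <- track$markers
  res <- list()
  for (ch in unique(mk$chrom)) {
    sel <- mk$chrom == ch
    pos <- mk$pos[sel]
    fm <- mk$freq_mut[sel]
    fw <- mk$freq_wt[sel]
    centers <- seq(min(pos), max(pos) + window_bp / 2, by = window_bp / 2)
    lo <- centers - window_bp / 2
    hi <- centers + window_bp / 2
    i1 <- findInterval(lo, pos, left.open = TRUE) + 1L  # first pos >= lo
    i2 <- findInterval(hi, pos)                         # last pos <= hi
    nmk <- pmax(i2 - i1 + 1L, 0L)
    ok <- nmk >= min_markers
    if (!any(ok)) next
    wfm <- mapply(function(a, b) fun(fm[a:b]), i1[ok], i2[ok])
    wfw <- mapply(function(a, b) fun(fw[a:b]), i1[ok], i2[ok])
    res[[ch]] <- data.frame(chrom = ch, start = lo[ok], end = hi[ok],
                            center = centers[ok], n_markers = nmk[ok],
                            freq_mut = wfm, freq_wt = wfw,
                            stringsAsFactors = FALSE)
  }
  win <- if (length(res)) do.call(rbind, res) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               center = numeric(), n_markers = integer(),
               freq_mut = numeric(), freq_wt = numeric(),
               stringsAsFactors = FALSE)
  rownames(win) <- NULL
  track$windows <- win
  track$window_bp <- window_bp
  track$statistic <- statistic
  track
}

#' Detect the candidate interval from the mutant-pool peak
#'
#' Finds the global maximum of the windowed mutant-pool frequency (ties
#' broken by lowest chromosome index then lowest position), and on that
#' chromosome takes the maximal contiguous run of windows at or above
#' `peak_threshold` containing the maximum. The interval boundaries are the
#' outermost member-marker positions of the run; the mean wild-type-pool
#' frequency over the member markers is reported alongside.
#'
#' @param track A smoothed `af_track` (run [smooth_track()] first).
#' @param peak_threshold Windowed mutant-pool frequency defining the peak
#'   run (default 0.98).
#' @return A `candidate_interval`; when no window reaches the threshold a
#'   `candidate_interval` with `found = FALSE` (an unmapped screen, not an
#'   error).
#' @export
detect_peak_interval <- function(track, peak_threshold = 0.98) {
  stopifnot(inherits(track, "af_track"))
  win <- track$windows
  if (is.null(win)) stop("track has no windows; run smooth_track() first")
  no_hit <- structure(list(found = FALSE, chrom = NA_character_,
                           start_bp = NA_real_, end_bp = NA_real_,
                           peak_freq_mutant = if (nrow(win)) max(win$freq_mut)
                                              else NA_real_,
                           mean_freq_wildtype_in_interval = NA_real_,
                           n_markers = 0L,
                           peak_threshold = peak_threshold),
                      class = "candidate_interval")
  if (nrow(win) == 0 || max(win$freq_mut) < peak_threshold) return(no_hit)
  chrom_order <- unique(track$markers$chrom)
  ord <- order(-win$freq_mut, match(win$chrom, chrom_order), win$center)
  top <- win[ord[1], ]
  ties <- sum(win$freq_mut == top$freq_mut)
  if (ties > 1) {
    message("global maximum tied across ", ties,
            " windows; keeping lowest chromosome/position")
  }
  cw <- win[win$chrom == top$chrom, ]
  cw <- cw[order(cw$center), ]
  imax <- which(cw$center == top$center)[1]
  flag <- cw$freq_mut >= peak_threshold
  a <- imax
  while (a > 1 && flag[a - 1]) a <- a - 1
  b <- imax
  while (b < nrow(cw) && flag[b + 1]) b <- b + 1
  lo <- min(cw$start[a:b])
  hi <- max(cw$end[a:b])
  mk <- track$markers
  member <- mk$chrom == top$chrom & mk$pos >= lo & mk$pos <= hi
  structure(list(found = TRUE, chrom = top$chrom,
                 start_bp = min(mk$pos[member]),
                 end_bp = max(mk$pos[member]),
                 peak_freq_mutant = top$freq_mut,
                 mean_freq_wildtype_in_interval = mean(mk$freq_wt[member]),
                 n_markers = sum(member),
                 peak_threshold = peak_threshold),
            class = "candidate_interval")
}

#' Windowed frequency at a position
#'
#' Looks up the smoothed track value of the window whose center is nearest
#' to a genomic position (e.g., the causal marker).
#'
#' @param track A smoothed `af_track`.
#' @param chrom Chromosome name.
#' @param pos Position in bp.
#' @param pool `"mutant"` or `"wildtype"`.
#' @return The windowed frequency (numeric scalar).
#' @export
windowed_value_at <- function(track, chrom, pos,
                              pool = c("mutant", "wildtype")) {
  pool <- match.arg(pool)
  win <- track$windows
  if (is.null(win)) stop("track has no windows; run smooth_track() first")
  w <- win[win$chrom == chrom, ]
  if (nrow(w) == 0) stop("no windows on chromosome ", chrom)
  i <- which.min(abs(w$center - pos))
  if (pool == "mutant") w$freq_mut[i] else w$freq_wt[i]
}

#' Check the wild-type-pool frequency signature inside the interval
#'
#' Under the duplex recessive model the phenotypically wild-type pool mixes
#' heterozygous (4/5) and homozygous wild-type (1/5) segregants, so its
#' mutant-allele frequency at the locus is expected to be 0.4. This is a
#' diagnostic on the mapped interval, not a gate.
#'
#' @param interval A found `candidate_interval`.
#' @param track The `af_track` used to detect it.
#' @param expected Expected frequency (default 0.4).
#' @param tol Tolerance (default 0.05).
#' @return A `wt_consistency` list: `pass`, `observed`, `expected`, `tol`.
#' @export
wt_pool_consistency <- function(interval, track, expected = 0.4, tol = 0.05) {
  stopifnot(inherits(interval, "candidate_interval"))
  if (!isTRUE(interval$found)) stop("interval is empty (no peak detected)")
  mk <- track$markers
  member <- mk$chrom == interval$chrom & mk$pos >= interval$start_bp &
    mk$pos <= interval$end_bp
  observed <- mean(mk$freq_wt[member])
  structure(list(pass = abs(observed - expected) <= tol,
                 observed = observed, expected = expected, tol = tol),
            class = "wt_consistency")
}

#' Write track / window TSVs and the interval BED + JSON report
#'
#' @param track An `af_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_tsv <- function(track, path) {
  utils::write.table(track$markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @export
write_windows_tsv <- function(track, path) {
  if (is.null(track$windows)) stop("track has no windows")
  utils::write.table(track$windows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_track_tsv
#' @param interval A `candidate_interval`.
#' @export
write_interval_bed <- function(interval, path) {
  if (!isTRUE(interval$found)) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ## BED is 0-based half-open; internal coordinates are 1-based inclusive
  writeLines(paste(interval$chrom,
                   format(interval$start_bp - 1, scientific = FALSE),
                   format(interval$end_bp, scientific = FALSE),
                   "candidate_interval",
                   sep = "\t"), path)
  invisible(path)
}

#' @export
print.candidate_interval <- function(x, ...) {
  if (isTRUE(x$found)) {
    cat(sprintf(
      "Candidate interval: %s:%s-%s (%d markers)\n  peak mutant-pool freq %.3f; mean WT-pool freq %.3f\n",
      x$chrom, format(x$start_bp, big.mark = ","),
      format(x$end_bp, big.mark = ","), x$n_markers,
      x$peak_freq_mutant, x$mean_freq_wildtype_in_interval))
  } else {
    cat("No candidate interval: no window reached threshold",
        x$peak_threshold, "\n")
  }
  invisible(x)
}

#' @export
print.wt_consistency <- function(x, ...) {
  cat(sprintf("WT-pool consistency: observed %.3f vs expected %.2f (tol %.2f) -> %s\n",
              x$observed, x$expected, x$tol, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
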