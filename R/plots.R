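#' Plot allele-frequency tracks per chromosome
#'
#' One panel per chromosome, raw per-marker frequencies of both pools as
#' points plus the windowed series as lines; the detected interval, if
#' given, is shaded.
#'
#' @param track An `af_track` (smoothed or not).
#' @param interval Optional `candidate_interval` to highlight.
#' @param point_alpha Point transparency.
#' @return A ggplot object.
#' @export
plot_track <- function(track, interval = NULL, point_alpha = 0.2) {
  mk <- track$markers
  long <- rbind(
    data.frame(chrom = mk$chrom, pos = mk$pos, freq = mk$freq_mut,
               pool = "mutant", stringsAsFactors = FALSE),
    data.frame(chrom = mk$chrom, pos = mk$pos, freq = mk$freq_wt,
               pool = "wild-type", stringsAsFactors = FALSE))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = pos / 1e6, y = freq,
                                          colour = pool)) +
    ggplot2::geom_point(size = 0.3, alpha = point_alpha) +
    ggplot2::facet_wrap(~chrom, ncol = 4) +
    ggplot2::labs(x = "position (Mb)", y = "mutant-strain allele frequency",
                  colour = "pool") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_bw()
  if (!is.null(track$windows) && nrow(track$windows)) {
    win <- track$windows
    wl <- rbind(
      data.frame(chrom = win$chrom, pos = win$center, freq = win$freq_mut,
                 pool = "mutant", stringsAsFactors = FALSE),
      data.frame(chrom = win$chrom, pos = win$center, freq = win$freq_wt,
                 pool = "wild-type", stringsAsFactors = FALSE))
    p <- p + ggplot2::geom_line(data = wl, linewidth = 0.6)
  }
  if (!is.null(interval) && isTRUE(interval$found)) {
    shade <- data.frame(chrom = interval$chrom,
                        xmin = interval$start_bp / 1e6,
                        xmax = interval$end_bp / 1e6)
    p <- p + ggplot2::geom_rect(
      data = shade, ggplot2::aes(xmin = xmin, xmax = xmax),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "red",
      inherit.aes = FALSE)
  }
  p
}
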