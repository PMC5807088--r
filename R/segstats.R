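## Closed-form tetrasomic expectations and the chi-square goodness-of-fit
## machinery used to validate ploidy and segregation.

#' Closed-form tetrasomic segregation expectations
#'
#' Derives, by enumeration of the unordered draws of 2 of the 4 homologs
#' \{m, m, +, +\} under random bivalent pairing, the diploid-gamete genotype
#' probabilities P(mm) = P(++) = 1/6 and P(m+) = 4/6 (the 1:4:1 ratio), the
#' recessive phenotype probabilities (1/6 no-3D : 5/6 3D), and the
#' mutant-allele dosage frequencies expected in the two phenotype pools:
#' 1.0 in the mutant pool (all mm) and 0.4 in the phenotypically wild-type
#' pool (4/5 heterozygotes at dosage 1/2).
#'
#' @return A list: `genotype_probs` (named mm, m+, ++), `phenotype_probs`
#'   (named `no-3D`, `3D`), `wt_pool_mut_allele_freq`,
#'   `mut_pool_mut_allele_freq`.
#' @export
tetrasomic_expectations <- function() {
  homologs <- c(1, 1, 0, 0)            # m = 1, + = 0
  draws <- utils::combn(4, 2)
  dosage <- colSums(matrix(homologs[draws], nrow = 2))
  p <- tabulate(dosage + 1L, nbins = 3L) / ncol(draws)  # P(dosage 0,1,2)
  genotype_probs <- c(mm = p[3], `m+` = p[2], `++` = p[1])
  phenotype_probs <- c(`no-3D` = genotype_probs[["mm"]],
                       `3D` = genotype_probs[["m+"]] + genotype_probs[["++"]])
  ## mean mutant-allele dosage among phenotypically wild-type gametes / 2
  wt <- (genotype_probs[["m+"]] * 1 + genotype_probs[["++"]] * 0) /
    (genotype_probs[["m+"]] + genotype_probs[["++"]]) / 2
  list(genotype_probs = genotype_probs,
       phenotype_probs = phenotype_probs,
       wt_pool_mut_allele_freq = wt,
       mut_pool_mut_allele_freq = 2 / 2)
}

#' Pearson chi-square goodness-of-fit test against a segregation ratio
#'
#' Computes the raw Pearson statistic (no continuity correction) of
#' observed class counts against an expected ratio, with the p-value from
#' the chi-square survival function (the regularized incomplete gamma
#' function, `stats::pchisq`).
#'
#' @param counts Non-negative integer vector of observed class counts (or a
#'   list with a `counts` field).
#' @param expected_ratio Strictly positive ratio of the same length
#'   (default `c(1, 4, 1)`, the tetrasomic expectation; any rescaling gives
#'   the same statistic).
#' @return A `chisq_gof` list: `statistic`, `df`, `p_value`, `expected`.
#' @export
chisq_goodness_of_fit <- function(counts, expected_ratio = c(1, 4, 1)) {
  if (is.list(counts) && !is.null(counts$counts)) counts <- counts$counts
  counts <- as.numeric(counts)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  if (length(expected_ratio) != length(counts)) {
    stop("`expected_ratio` must have the same length as `counts`")
  }
  if (any(expected_ratio <= 0)) stop("`expected_ratio` must be positive")
  n <- sum(counts)
  if (n == 0) stop("total count is zero")
  expected <- n * expected_ratio / sum(expected_ratio)
  if (any(expected < 5)) {
    warning("expected count below 5 in at least one class; the chi-square ",
            "approximation may be poor")
  }
  statistic <- sum((counts - expected)^2 / expected)
  df <- length(counts) - 1L
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 expected = expected),
            class = "chisq_gof")
}

#' Monte-Carlo calibration of the segregation test
#'
#' Draws replicate progenies from Multinomial(`n_progeny`, `true_probs`)
#' and tests each against the expected ratio; returns the fraction of
#' replicates conforming at `alpha`. With data generated under the tested
#' ratio this is the test's empirical coverage, about 0.95 at the default
#' alpha.
#'
#' @param n_progeny Progeny per replicate (>= 1).
#' @param n_replicates Number of replicates.
#' @param seed Optional integer seed.
#' @param true_probs Generating class probabilities (default the tetrasomic
#'   1/6, 4/6, 1/6).
#' @param expected_ratio Ratio tested against (default 1:4:1).
#' @param alpha Significance level (default 0.05).
#' @return The conformity fraction (replicates with p > alpha).
#' @export
simulate_segregation_test <- function(n_progeny, n_replicates, seed = NULL,
                                      true_probs = c(1, 4, 1) / 6,
                                      expected_ratio = c(1, 4, 1),
                                      alpha = 0.05) {
  stopifnot(n_progeny >= 1, n_replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  draws <- stats::rmultinom(n_replicates, n_progeny, true_probs)
  p <- apply(draws, 2, function(x) {
    suppressWarnings(chisq_goodness_of_fit(x, expected_ratio)$p_value)
  })
  mean(p > alpha)
}

#' @export
print.chisq_gof <- function(x, ...) {
  cat(sprintf("Chi-square GOF: X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}
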