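## VCF-dialect import/export of pooled count tables. REF is the B-side
## (wild/reference strain) allele and ALT the A-side (mutant strain) allele;
## per-pool data travel in FORMAT fields AD (B,A order), DP and QS (the
## per-pool site quality proxy). The site QUAL column is the minimum QS
## across pools.

#' Write pooled count tables as a VCF-dialect file
#'
#' @param tables A named list of `pool_count_table`s over identical sites
#'   (names become sample columns), or a single table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pooled_vcf <- function(tables, path) {
  if (inherits(tables, "pool_count_table")) tables <- list(pool = tables)
  stopifnot(is.list(tables), length(tables) >= 1)
  if (is.null(names(tables)) || any(names(tables) == "")) {
    names(tables) <- paste0("pool", seq_along(tables))
  }
  key <- c("chrom", "pos", "allele_A", "allele_B")
  first <- tables[[1]]
  for (t in tables[-1]) {
    if (!identical(as.data.frame(t[key]), as.data.frame(first[key]))) {
      stop("all pool tables must cover identical sites")
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=tetraBSA",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=QS,Number=1,Type=Float,Description=\"Per-pool site quality proxy\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", names(tables)), collapse = "\t"))
  n <- nrow(first)
  if (n == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  quals <- do.call(pmin, lapply(tables, function(t) t$qual))
  samp_cols <- lapply(tables, function(t) {
    sprintf("%d,%d:%d:%.10g", t$count_B, t$count_A, t$depth, t$qual)
  })
  rows <- do.call(paste, c(list(
    first$chrom, format(first$pos, scientific = FALSE, trim = TRUE), ".",
    first$allele_B, first$allele_A, sprintf("%.10g", quals), "PASS", ".",
    "AD:DP:QS"), samp_cols, list(sep = "\t")))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a VCF-dialect file into pooled count tables
#'
#' Accepts files written by [write_pooled_vcf()] and externally produced
#' VCFs restricted to biallelic SNVs with AD (and optionally DP) FORMAT
#' fields. Multi-allelic records are skipped with a warning; records whose
#' AD does not sum to DP have their depth recomputed from AD with a warning;
#' files without the QS field fall back to the site QUAL column for every
#' pool.
#'
#' @param path Path to the VCF file.
#' @return A named list of `pool_count_table`s, one per sample column.
#' @export
read_pooled_vcf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## light structural pre-scan so malformed records are reported with their
  ## line number (vcfR does not track line numbers)
  lines <- readLines(path)
  is_data <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[is_data], "\t", fixed = TRUE))
  if (any(nf < 10)) {
    bad <- which(is_data)[which(nf < 10)[1]]
    stop("malformed VCF record at line ", bad,
         ": expected at least 10 tab-separated fields, found ", min(nf))
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  if (n == 0) {
    empty <- .new_pool_table(character(), numeric(), character(), character(),
                             integer(), integer(), integer(), numeric())
    out <- rep(list(empty), max(1, length(samples)))
    names(out) <- if (length(samples)) samples else "pool"
    return(out)
  }
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  snv <- nchar(fix[, "REF"]) == 1 & nchar(fix[, "ALT"]) == 1
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
  }
  keep <- !multi & snv
  if (any(!snv & !multi)) {
    warning(sum(!snv & !multi), " non-SNV record(s) skipped")
  }
  .gt <- function(el, num = TRUE) {
    tryCatch(
      suppressWarnings(vcfR::extract.gt(vcf, element = el, as.numeric = num)),
      error = function(e) matrix(NA, n, length(samples),
                                 dimnames = list(NULL, samples)))
  }
  ad <- .gt("AD", num = FALSE)
  dp <- .gt("DP")
  qs <- .gt("QS")
  site_qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  out <- lapply(seq_along(samples), function(j) {
    ads <- strsplit(ad[keep, j], ",", fixed = TRUE)
    cB <- vapply(ads, function(x) as.integer(x[1]), integer(1))
    cA <- vapply(ads, function(x) as.integer(x[2]), integer(1))
    depth <- if (all(is.na(dp[keep, j]))) cB + cA else as.integer(dp[keep, j])
    mismatch <- !is.na(depth) & depth != cB + cA
    if (any(mismatch)) {
      warning(sum(mismatch), " record(s) in sample '", samples[j],
              "' had AD not summing to DP; depth recomputed from AD")
      depth[mismatch] <- (cB + cA)[mismatch]
    }
    q <- if (all(is.na(qs[keep, j]))) site_qual[keep] else qs[keep, j]
    .new_pool_table(unname(fix[keep, "CHROM"]),
                    as.numeric(fix[keep, "POS"]),
                    unname(fix[keep, "ALT"]), unname(fix[keep, "REF"]),
                    cA, cB, depth, q)
  })
  names(out) <- samples
  out
}

#' Write a strain marker map as a two-sample VCF
#'
#' The two parental strains appear as pseudo-samples genotyped 1/1 (A-side
#' strain, carrying ALT) and 0/0 (B-side strain, carrying REF).
#'
#' @param markers A `strain_marker_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_marker_vcf <- function(markers, path) {
  sa <- attr(markers, "strain_A") %||% "strainA"
  sb <- attr(markers, "strain_B") %||% "strainB"
  header <- c("##fileformat=VCFv4.2",
              "##source=tetraBSA",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sa, sb), collapse = "\t"))
  if (nrow(markers) == 0) {
    writeLines(header, path)
    return(invisible(path))
  }
  rows <- paste(markers$chrom,
                format(markers$pos, scientific = FALSE, trim = TRUE), ".",
                markers$allele_B, markers$allele_A, ".", "PASS", ".", "GT",
                "1/1", "0/0", sep = "\t")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Write / read a strain marker map as TSV
#'
#' @param markers A `strain_marker_map`.
#' @param path File path.
#' @return `path` invisibly for the writer; a `strain_marker_map` for the
#'   reader.
#' @export
write_marker_tsv <- function(markers, path) {
  utils::write.table(as.data.frame(markers)[c("chrom", "pos", "allele_A",
                                              "allele_B")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_marker_tsv
#' @param strain_A,strain_B Strain labels to attach on read.
#' @export
read_marker_tsv <- function(path, strain_A = "Vx", strain_B = "Gd") {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "allele_A", "allele_B") %in% names(df)))
  df$pos <- as.numeric(df$pos)
  .as_marker_map(df, NULL, strain_A, strain_B)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
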