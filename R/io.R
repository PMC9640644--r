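# Plain-text interchange formats: VCF v4.2 genotypes and count-matrix TSVs.

#' Write a dosage matrix as VCF v4.2 with GT genotypes
#'
#' @param dosages n_samples x n_snps matrix with values in \{0, 1, 2, NA\}.
#' @param snp_info data.frame with chrom, pos, id, ref, alt (one row per SNP).
#' @param sample_ids character vector of sample names.
#' @param path output path.
#' @export
write_vcf <- function(dosages, snp_info, sample_ids, path) {
  stopifnot(nrow(dosages) == length(sample_ids),
            ncol(dosages) == nrow(snp_info))
  gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=endotyper-synth",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids), collapse = "\t")
  ), con)
  lines <- vapply(seq_len(nrow(snp_info)), function(j) {
    calls <- gt[as.character(dosages[, j])]
    calls[is.na(calls)] <- "./."
    paste(c(snp_info$chrom[j], snp_info$pos[j], snp_info$id[j],
            snp_info$ref[j], snp_info$alt[j], ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }, character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read GT genotypes from a VCF into a dosage matrix
#'
#' Parses the GT field of a (plain-text) VCF into alternate-allele dosages;
#' missing calls become NA.
#'
#' @param path VCF path.
#' @return list with `dosages` (samples x SNPs, dimnames set) and
#'   `snp_info` (chrom, pos, id, ref, alt).
#' @export
read_vcf_dosages <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  if (header[1] != "#CHROM") stop("not a VCF: missing #CHROM header", call. = FALSE)
  samples <- header[-(1:9)]
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  snp_info <- data.frame(
    chrom = vapply(rows, `[`, character(1), 1),
    pos = as.integer(vapply(rows, `[`, character(1), 2)),
    id = vapply(rows, `[`, character(1), 3),
    ref = vapply(rows, `[`, character(1), 4),
    alt = vapply(rows, `[`, character(1), 5),
    stringsAsFactors = FALSE
  )
  dose_of <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
               "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
  fmt_gt_index <- function(fmt) which(strsplit(fmt, ":", fixed = TRUE)[[1]] == "GT")[1]
  dosages <- matrix(NA_integer_, nrow = length(samples), ncol = length(rows),
                    dimnames = list(samples, snp_info$id))
  for (j in seq_along(rows)) {
    gi <- fmt_gt_index(rows[[j]][9])
    calls <- vapply(rows[[j]][-(1:9)], function(x) {
      strsplit(x, ":", fixed = TRUE)[[1]][gi]
    }, character(1), USE.NAMES = FALSE)
    dosages[, j] <- dose_of[calls]
  }
  list(dosages = dosages, snp_info = snp_info)
}

#' Write / read a numeric matrix TSV with row and column names
#'
#' Genes x samples (or patients x disease groups) with a leading id column.
#'
#' @param m matrix with dimnames.
#' @param path TSV path.
#' @param id_col name of the leading id column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  df <- data.frame(rownames(m), as.data.frame(m), check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
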