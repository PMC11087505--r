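vcf_header <- function(donor_cols = NULL, format_lines = character(0)) {
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  if (!is.null(donor_cols)) cols <- c(cols, "FORMAT", donor_cols)
  c("##fileformat=VCFv4.2",
    "##source=demuxbulk",
    format_lines,
    paste(cols, collapse = "\t"))
}

#' Write donor genotypes as a multi-sample VCF
#'
#' Emits a minimal VCF 4.2 with a GT column per donor, readable back by
#' [read_genotypes()]. Missing categories become "./.".
#'
#' @param G a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(G, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  body <- matrix("./.", nrow(G$G), ncol(G$G))
  ok <- !is.na(G$G)
  body[ok] <- gt_str[G$G[ok] + 1L]
  v <- G$variants
  id <- ifelse(is.na(v$id), ".", v$id)
  lines <- c(
    vcf_header(G$donors,
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
    paste(v$chrom, v$pos, id, v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write pooled allelic counts as a single-sample VCF with AD/DP
#'
#' @param counts an [allelic_counts()].
#' @param path output path.
#' @param sample_name pooled-sample column name.
#' @return `path`, invisibly.
#' @export
write_counts_vcf <- function(counts, path, sample_name = "POOL") {
  v <- counts$variants
  id <- ifelse(is.na(v$id), ".", v$id)
  fmt <- c(
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">')
  lines <- c(
    vcf_header(sample_name, fmt),
    paste(v$chrom, v$pos, id, v$ref, v$alt, ".", "PASS", ".", "AD:DP",
          sprintf("%d,%d:%d", counts$d - counts$a, counts$a, counts$d),
          sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write counts as a cellSNP-lite-style sparse trio
#'
#' Writes `<prefix>.base.vcf` (SNP list), `<prefix>.AD.mtx`,
#' `<prefix>.DP.mtx` and, for cell-level input, `<prefix>.barcodes.tsv`.
#' Round-trips through [read_bulk_counts()] / [read_cell_counts()].
#'
#' @param x an [allelic_counts()] (written as one-column matrices) or a
#'   [cell_allelic_counts()].
#' @param prefix output path prefix.
#' @return named character vector of the files written, invisibly.
#' @export
write_counts_trio <- function(x, prefix) {
  v <- x$variants
  id <- ifelse(is.na(v$id), ".", v$id)
  base <- paste0(prefix, ".base.vcf")
  lines <- c(vcf_header(),
             paste(v$chrom, v$pos, id, v$ref, v$alt, ".", "PASS", ".",
                   sep = "\t"))
  writeLines(lines, base)
  files <- c(vcf = base, ad = paste0(prefix, ".AD.mtx"),
             dp = paste0(prefix, ".DP.mtx"))
  if (inherits(x, "cell_allelic_counts")) {
    Matrix::writeMM(x$A, files["ad"])
    Matrix::writeMM(x$D, files["dp"])
    files["barcodes"] <- paste0(prefix, ".barcodes.tsv")
    writeLines(x$cells, files["barcodes"])
  } else {
    Matrix::writeMM(Matrix::Matrix(matrix(as.numeric(x$a), ncol = 1),
                                   sparse = TRUE), files["ad"])
    Matrix::writeMM(Matrix::Matrix(matrix(as.numeric(x$d), ncol = 1),
                                   sparse = TRUE), files["dp"])
  }
  invisible(files)
}
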