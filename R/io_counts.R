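#' Read pooled allelic counts
#'
#' Two input dialects are supported, both downstream of standard pileup
#' tools:
#'
#' * `"vcf_ad"`: a single-sample VCF whose FORMAT carries an AD tag with
#'   (REF, ALT) depths — `AD="30,70"` gives `a = 70`, `d = 100`. Rows whose
#'   AD lists more than two alleles are skipped and counted. Set
#'   `ad_order = "alt_only"` for dialects where AD holds only the ALT depth;
#'   a DP tag is then required for the total.
#' * `"sparse_trio"`: a base VCF naming the SNPs plus ALT-count and total
#'   depth matrices in MatrixMarket format with matching row order (the
#'   cellSNP-lite layout). Columns (cells or replicates) are summed into one
#'   pooled sample.
#'
#' Rows with `d = 0` are retained; the effective-variant filter removes them
#' later.
#'
#' @param source for `"vcf_ad"` a single path; for `"sparse_trio"` a character
#'   vector or list with elements `vcf`, `ad`, `dp` (named, or in that order).
#' @param dialect one of `"vcf_ad"`, `"sparse_trio"`.
#' @param ad_order `"ref_alt"` (VCF spec) or `"alt_only"`.
#' @return an [allelic_counts()]; `"vcf_ad"` results carry an `n_skipped`
#'   attribute.
#' @export
read_bulk_counts <- function(source, dialect = c("vcf_ad", "sparse_trio"),
                             ad_order = c("ref_alt", "alt_only")) {
  dialect <- match.arg(dialect)
  ad_order <- match.arg(ad_order)
  if (dialect == "vcf_ad") {
    read_counts_vcf_ad(source, ad_order)
  } else {
    cc <- read_cell_counts(source)
    out <- allelic_counts(cc$variants,
                          a = Matrix::rowSums(cc$A),
                          d = Matrix::rowSums(cc$D))
    out
  }
}

read_counts_vcf_ad <- function(vcf_path, ad_order = "ref_alt") {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  keep <- is_biallelic_snp(fix[, "REF"], fix[, "ALT"])
  if (!any(keep)) stop("no biallelic SNP rows in ", vcf_path)
  ad <- vcfR::extract.gt(vcf, element = "AD")[keep, 1L]
  parts <- strsplit(ad, ",", fixed = TRUE)
  nall <- lengths(parts)
  if (ad_order == "ref_alt") {
    good <- !is.na(ad) & nall == 2L
    a <- d <- rep(0L, length(ad))
    num <- vapply(parts[good], function(p) as.numeric(p), numeric(2))
    a[good] <- as.integer(num[2L, ])
    d[good] <- as.integer(num[1L, ] + num[2L, ])
    n_skipped <- sum(!is.na(ad) & nall > 2L)
  } else {
    good <- !is.na(ad) & nall == 1L
    a <- rep(0L, length(ad))
    a[good] <- as.integer(vapply(parts[good], function(p) as.numeric(p[1L]),
                                 numeric(1)))
    dp <- suppressWarnings(as.integer(vcfR::extract.gt(vcf, element = "DP")[keep, 1L]))
    if (all(is.na(dp))) stop("alt_only AD dialect requires a DP tag")
    d <- ifelse(is.na(dp), 0L, dp)
    n_skipped <- sum(!is.na(ad) & nall > 1L)
  }
  fixk <- fix[keep, , drop = FALSE]
  vt <- variant_table(fixk[, "CHROM"], as.integer(fixk[, "POS"]),
                      fixk[, "REF"], fixk[, "ALT"], fixk[, "ID"])
  out <- allelic_counts(vt, a, d)
  attr(out, "n_skipped") <- n_skipped
  if (n_skipped > 0L) message(n_skipped, " rows with >2 AD alleles zeroed")
  out
}

#' Read cell-level allelic counts from a sparse trio
#'
#' Reads the cellSNP-lite layout: a base VCF naming the SNPs, an ALT-count
#' matrix and a total-depth matrix in MatrixMarket format (SNPs x cells),
#' and optionally a one-barcode-per-line cell list.
#'
#' @param source character vector or list with elements `vcf`, `ad`, `dp`
#'   and optionally `barcodes` (named, or in that order).
#' @return a [cell_allelic_counts()].
#' @export
read_cell_counts <- function(source) {
  source <- as.list(source)
  if (is.null(names(source)) || !all(nzchar(names(source))))
    names(source) <- c("vcf", "ad", "dp", "barcodes")[seq_along(source)]
  for (f in c("vcf", "ad", "dp"))
    if (!file.exists(source[[f]])) stop(f, " file not found: ", source[[f]])

  vcf <- vcfR::read.vcfR(source$vcf, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  vt <- variant_table(fix[, "CHROM"], as.integer(fix[, "POS"]),
                      fix[, "REF"], fix[, "ALT"], fix[, "ID"])
  A <- Matrix::readMM(source$ad)
  D <- Matrix::readMM(source$dp)
  if (nrow(A) != nrow(vt) || nrow(D) != nrow(vt))
    stop(sprintf(
      "row-count mismatch: base VCF has %d SNPs but matrices have %d/%d rows",
      nrow(vt), nrow(A), nrow(D)))
  if (ncol(A) != ncol(D)) stop("AD and DP matrices differ in column count")
  cells <- if (!is.null(source$barcodes) && file.exists(source$barcodes))
    readLines(source$barcodes)
  else sprintf("cell%d", seq_len(ncol(A)))
  cell_allelic_counts(vt, cells, A, D)
}

#' Aggregate cell-level counts into pseudo-bulk
#'
#' Sums ALT and total counts across cells (optionally a barcode subset),
#' mimicking a bulk library from the same pool. Summation is additive over
#' disjoint cell partitions, and merging any two cells' columns (a synthetic
#' doublet) leaves the output unchanged — the reason pooled-read
#' deconvolution is insensitive to doublets.
#'
#' @param cc a [cell_allelic_counts()].
#' @param cell_subset optional character vector of barcodes to pool;
#'   all cells by default.
#' @return an [allelic_counts()].
#' @export
pseudobulk <- function(cc, cell_subset = NULL) {
  stopifnot(inherits(cc, "cell_allelic_counts"))
  if (is.null(cell_subset)) {
    idx <- seq_along(cc$cells)
  } else {
    if (length(cell_subset) == 0L) stop("empty cell subset")
    idx <- match(cell_subset, cc$cells)
    if (anyNA(idx))
      stop("unknown barcodes in cell subset: ",
           paste(utils::head(cell_subset[is.na(idx)], 3), collapse = ", "))
  }
  allelic_counts(cc$variants,
                 a = Matrix::rowSums(cc$A[, idx, drop = FALSE]),
                 d = Matrix::rowSums(cc$D[, idx, drop = FALSE]))
}
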