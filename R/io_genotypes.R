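# Classify VCF rows: TRUE for simple biallelic SNPs (single REF base, single
# ALT base, no symbolic alleles). Everything else is skipped and counted.
is_biallelic_snp <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  !is.na(ref) & !is.na(alt) &
    toupper(ref) %in% bases & toupper(alt) %in% bases
}

# Map diploid GT strings to categories. Phase separators are equivalent;
# half-calls, haploid calls and any allele other than 0/1 become NA.
parse_gt <- function(gt) {
  gt <- sub(":.*$", "", gt)            # strip trailing FORMAT fields if any
  out <- rep(NA_integer_, length(gt))
  out[gt %in% c("0/0", "0|0")] <- 0L
  out[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  out[gt %in% c("1/1", "1|1")] <- 2L
  out
}

#' Read donor genotypes from a multi-sample VCF
#'
#' Parses GT calls for the pooled donors, keeping only biallelic SNP rows.
#' Multiallelic, indel and symbolic-allele rows are skipped and reported via
#' the `n_skipped` attribute. "0/1" and "1/0" (and their phased equivalents)
#' both map to the heterozygous category; half-calls ("./1") and haploid
#' calls ("1") map to missing.
#'
#' @param vcf_path path to a VCF 4.x file (plain or bgzipped) with GT in
#'   FORMAT.
#' @param donor_subset optional character vector of sample names to keep, in
#'   the requested order; all samples by default.
#' @return a [genotype_matrix()] with attributes `n_skipped` (non-SNP rows
#'   dropped) and `n_half_calls` (GT strings mapped to missing).
#' @export
read_genotypes <- function(vcf_path, donor_subset = NULL) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path)
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt_raw <- vcf@gt
  if (is.null(gt_raw) || ncol(gt_raw) < 2L)
    stop("VCF has no sample (donor) columns")
  donors <- colnames(gt_raw)[-1L]      # first column is FORMAT
  if (!is.null(donor_subset)) {
    missing <- setdiff(donor_subset, donors)
    if (length(missing))
      stop("requested donors absent from VCF: ",
           paste(missing, collapse = ", "))
    donors <- donor_subset
  }

  keep <- is_biallelic_snp(fix[, "REF"], fix[, "ALT"])
  n_skipped <- sum(!keep)
  if (!any(keep))
    stop("no biallelic SNP rows in ", vcf_path)

  fmt <- gt_raw[keep, 1L]
  gt_field <- match("GT", strsplit(fmt[1L], ":", fixed = TRUE)[[1L]])
  if (is.na(gt_field)) stop("GT not present in FORMAT")
  gt <- gt_raw[keep, donors, drop = FALSE]
  # GT is required first by the VCF spec, but honor its actual position
  if (gt_field > 1L)
    gt <- apply(gt, 2, function(col)
      vapply(strsplit(col, ":", fixed = TRUE), `[`, "", gt_field))

  G <- apply(gt, 2, parse_gt)
  if (sum(keep) == 1L) G <- matrix(G, nrow = 1, dimnames = list(NULL, donors))
  n_half <- sum(is.na(G) & !is.na(gt))

  fixk <- fix[keep, , drop = FALSE]
  vt <- variant_table(fixk[, "CHROM"], as.integer(fixk[, "POS"]),
                      fixk[, "REF"], fixk[, "ALT"], fixk[, "ID"])
  out <- genotype_matrix(vt, donors, G)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_half_calls") <- n_half
  if (n_skipped > 0L)
    message(n_skipped, " non-biallelic-SNP rows skipped")
  out
}

#' Restrict to effective (demultiplexing-informative) variants
#'
#' An effective SNP (i) has genotype contrast — at least two donors in the
#' pool differ in category, (ii) is covered by at least `min_depth` reads in
#' the pooled sample, (iii) has a minor-allele read fraction strictly above
#' `min_minor_frac`, and (iv) has no missing donor genotype. The depth and
#' minor-fraction defaults (100 reads, 5%) follow common practice for pooled
#' bulk data and are fully overridable.
#'
#' @param G a [genotype_matrix()].
#' @param counts an [allelic_counts()] aligned to `G` (same SNPs, same order).
#' @param min_depth minimum pooled depth d_i (default 100).
#' @param min_minor_frac minimum minor-allele fraction min(a, d-a)/d, strict
#'   inequality (default 0.05).
#' @return list with elements `genotypes` and `counts`, both restricted to
#'   the effective rows (donor order preserved), plus `n_removed`.
#' @export
filter_effective_variants <- function(G, counts, min_depth = 100,
                                      min_minor_frac = 0.05) {
  stop_if_misaligned(G, counts)
  complete <- rowSums(is.na(G$G)) == 0L
  contrast <- complete & apply(G$G, 1, function(g) length(unique(g)) >= 2L)
  d <- counts$d; a <- counts$a
  covered <- d >= min_depth
  minor <- rep(FALSE, length(d))
  pos <- d > 0L
  minor[pos] <- pmin(a[pos], d[pos] - a[pos]) / d[pos] > min_minor_frac
  keep <- complete & contrast & covered & minor
  if (!any(keep))
    stop("no informative SNPs survive the effective-variant filter")
  list(genotypes = subset_variants(G, keep),
       counts = subset_variants(counts, keep),
       n_removed = sum(!keep))
}
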