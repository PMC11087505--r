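#' Construct a variant table
#'
#' Internal helper standardizing the per-SNP annotation shared by genotype
#' matrices and count containers.
#'
#' @param chrom,pos,ref,alt,id vectors of equal length; `pos` is 1-based
#'   (VCF convention), `ref`/`alt` single bases.
#' @return a data.frame with columns chrom, pos, id, ref, alt.
#' @keywords internal
variant_table <- function(chrom, pos, ref, alt, id = NULL) {
  n <- length(pos)
  if (is.null(id)) id <- rep(NA_character_, n)
  stopifnot(length(chrom) == n, length(ref) == n, length(alt) == n,
            length(id) == n, all(pos >= 1))
  data.frame(chrom = as.character(chrom), pos = as.integer(pos),
             id = as.character(id), ref = as.character(ref),
             alt = as.character(alt), stringsAsFactors = FALSE)
}

#' Genotype matrix for a pool of donors
#'
#' Holds per-SNP genotype categories for K donors: 0 = homozygous reference
#' (BB), 1 = heterozygous (AB), 2 = homozygous alternative (AA); `NA` marks
#' missing or unparseable calls. Only biallelic SNPs are representable.
#'
#' @param variants data.frame as returned by [variant_table()] (N rows).
#' @param donors character vector of K donor names.
#' @param G integer N x K matrix of categories in `{0, 1, 2, NA}`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, donors, G) {
  G <- as.matrix(G)
  storage.mode(G) <- "integer"
  stopifnot(nrow(G) == nrow(variants), ncol(G) == length(donors))
  ok <- is.na(G) | (G >= 0L & G <= 2L)
  if (!all(ok)) stop("genotype categories must be 0, 1, 2 or NA")
  dimnames(G) <- list(NULL, donors)
  structure(list(variants = variants, donors = as.character(donors), G = G),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d donors (%s)\n",
              nrow(x$G), length(x$donors),
              paste(utils::head(x$donors, 4), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$G)

#' Pooled allelic counts at SNPs
#'
#' Per-SNP ALT-supporting read count `a` and total depth `d` for one pooled
#' sample; the REF count is implied as `d - a`.
#'
#' @param variants data.frame as returned by [variant_table()].
#' @param a,d non-negative integer vectors with `0 <= a <= d`.
#' @return an object of class `allelic_counts`.
#' @export
allelic_counts <- function(variants, a, d) {
  a <- as.integer(round(a)); d <- as.integer(round(d))
  stopifnot(length(a) == nrow(variants), length(d) == nrow(variants))
  if (any(a < 0L) || any(d < 0L) || any(a > d))
    stop("allelic counts require 0 <= a <= d at every SNP")
  structure(list(variants = variants, a = a, d = d),
            class = "allelic_counts")
}

#' @export
print.allelic_counts <- function(x, ...) {
  cat(sprintf("allelic_counts: %d SNPs, %d total reads (%.1f mean depth)\n",
              length(x$d), sum(x$d), mean(x$d)))
  invisible(x)
}

#' Cell-level allelic counts
#'
#' Sparse per-SNP x per-cell ALT (`A`) and total (`D`) read counts, the
#' substrate for pseudo-bulk aggregation and doublet experiments.
#'
#' @param variants data.frame as returned by [variant_table()].
#' @param cells character vector of C cell barcodes.
#' @param A,D sparse (or dense) N x C matrices with `0 <= A <= D` elementwise.
#' @param labels optional per-cell donor labels (truth side in simulations).
#' @return an object of class `cell_allelic_counts`.
#' @export
cell_allelic_counts <- function(variants, cells, A, D, labels = NULL) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  D <- Matrix::Matrix(D, sparse = TRUE)
  stopifnot(nrow(A) == nrow(variants), ncol(A) == length(cells),
            all(dim(A) == dim(D)))
  if (min(D - A) < -1e-9) stop("cell counts require A <= D elementwise")
  if (!is.null(labels)) stopifnot(length(labels) == length(cells))
  structure(list(variants = variants, cells = as.character(cells),
                 A = A, D = D, labels = labels),
            class = "cell_allelic_counts")
}

#' @export
print.cell_allelic_counts <- function(x, ...) {
  cat(sprintf("cell_allelic_counts: %d SNPs x %d cells, %d reads\n",
              nrow(x$D), length(x$cells), as.integer(sum(x$D))))
  invisible(x)
}

#' Validate an allele-frequency parameter vector
#'
#' theta = (theta0, theta1, theta2) gives the expected ALT-read fraction
#' emitted by genotype categories BB/AB/AA. The default (0.01, 0.5, 0.99)
#' relaxes the theoretical (0, 0.5, 1) to absorb sequencing and genotyping
#' error.
#'
#' @param theta numeric length-3 vector, strictly increasing, in (0, 1).
#' @return theta, validated.
#' @export
check_theta <- function(theta) {
  theta <- as.numeric(theta)
  if (length(theta) != 3L || any(!is.finite(theta)) ||
      any(theta <= 0) || any(theta >= 1) || is.unsorted(theta, strictly = TRUE))
    stop("theta must be three strictly increasing values in (0, 1)")
  theta
}

#' Validate a donor-proportion vector
#'
#' @param phi non-negative numeric vector summing to 1 (tolerance 1e-9
#'   unless `renormalize`).
#' @param K expected length, or NULL to skip the length check.
#' @param renormalize divide by the sum instead of erroring on drift.
#' @return phi, validated (and possibly renormalized).
#' @export
check_phi <- function(phi, K = NULL, renormalize = FALSE) {
  phi <- as.numeric(phi)
  if (!is.null(K) && length(phi) != K)
    stop(sprintf("phi has length %d, expected %d", length(phi), K))
  if (any(phi < -1e-12)) stop("phi must be non-negative")
  s <- sum(phi)
  if (abs(s - 1) > 1e-9) {
    if (renormalize) phi <- phi / s
    else stop(sprintf("phi must sum to 1 (got %.12f)", s))
  }
  pmax(phi, 0)
}

# Shared alignment check: two containers must describe the same SNPs in the
# same order before they can be combined.
same_variants <- function(x, y) {
  vx <- x$variants; vy <- y$variants
  nrow(vx) == nrow(vy) &&
    all(vx$chrom == vy$chrom) && all(vx$pos == vy$pos) &&
    all(vx$ref == vy$ref) && all(vx$alt == vy$alt)
}

stop_if_misaligned <- function(x, y) {
  if (!same_variants(x, y))
    stop("genotypes and counts are not aligned on the same variant list")
  invisible(TRUE)
}

#' Subset aligned genotype and count containers by row
#' @param x a `genotype_matrix`, `allelic_counts` or `cell_allelic_counts`.
#' @param idx integer or logical row (SNP) index.
#' @return the same class of object restricted to `idx`.
#' @export
subset_variants <- function(x, idx) {
  if (inherits(x, "genotype_matrix")) {
    genotype_matrix(x$variants[idx, , drop = FALSE], x$donors,
                    x$G[idx, , drop = FALSE])
  } else if (inherits(x, "allelic_counts")) {
    allelic_counts(x$variants[idx, , drop = FALSE], x$a[idx], x$d[idx])
  } else if (inherits(x, "cell_allelic_counts")) {
    cell_allelic_counts(x$variants[idx, , drop = FALSE], x$cells,
                        x$A[idx, , drop = FALSE], x$D[idx, , drop = FALSE],
                        x$labels)
  } else stop("unsupported class for subset_variants")
}
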