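#' bloomsweep: sweep scans and blooming-time association for diploid panels
#'
#' Windowed pi / theta_W / F_ST scans with a log2 pi-ratio joint-outlier rule,
#' per-individual diversity summaries, LD decay, and a kinship-corrected
#' mixed-model association stage, plus a Balding-Nichols simulator that
#' produces the VCF/GFF3/sample-table inputs the pipeline consumes.
#'
#' @keywords internal
#' @importFrom stats cor optimize pt rbeta rbinom rnorm runif sd var
#' @importFrom utils read.table write.table
"_PACKAGE"

#' Construct a genotype matrix
#'
#' The central container of the package: biallelic SNP dosages for a panel of
#' diploid samples. Dosage is the count of alternate alleles (0, 1, 2) with
#' `NA` for missing genotypes. Variants are stored in genome order: grouped by
#' chromosome with strictly increasing positions within each chromosome.
#'
#' @param dosage integer matrix, variants in rows, samples in columns; values
#'   in \{0, 1, 2, NA\}. Column names are the sample identifiers.
#' @param chrom character vector of chromosome labels, one per variant.
#' @param pos integer vector of 1-based positions, one per variant.
#' @param ref,alt single-base allele strings, one per variant.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL) {
  dosage <- as.matrix(dosage)
  m <- nrow(dosage)
  if (ncol(dosage) < 2L) stop("a genotype matrix needs at least 2 samples")
  if (is.null(colnames(dosage))) {
    colnames(dosage) <- sprintf("S%02d", seq_len(ncol(dosage)))
  }
  storage.mode(dosage) <- "integer"
  bad <- !(dosage %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("dosage values must be 0, 1, 2 or NA")
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (length(chrom) != m || length(pos) != m) {
    stop("chrom/pos length must equal the number of variant rows")
  }
  if (is.null(ref)) ref <- rep("A", m)
  if (is.null(alt)) alt <- rep("T", m)
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0L)) {
      stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  structure(
    list(dosage = dosage, chrom = chrom, pos = pos,
         ref = as.character(ref), alt = as.character(alt)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d biallelic SNPs x %d samples on %d chromosome(s)\n",
              n_variants(x), n_samples(x), length(unique(x$chrom))))
  invisible(x)
}

#' Number of variants / samples / sample identifiers
#' @param x a `genotype_matrix`
#' @return integer count, or character vector for `sample_ids`.
#' @export
n_variants <- function(x) nrow(x$dosage)

#' @rdname n_variants
#' @export
n_samples <- function(x) ncol(x$dosage)

#' @rdname n_variants
#' @export
sample_ids <- function(x) colnames(x$dosage)

#' Subset a genotype matrix by variant index and/or sample id
#'
#' @param x a `genotype_matrix`
#' @param variants integer or logical index over variant rows (default: all).
#' @param samples character vector of sample ids, or index (default: all).
#' @return a `genotype_matrix` restricted to the selection.
#' @export
subset_matrix <- function(x, variants = NULL, samples = NULL) {
  if (is.null(variants)) variants <- seq_len(n_variants(x))
  if (is.null(samples)) samples <- sample_ids(x)
  genotype_matrix(x$dosage[variants, samples, drop = FALSE],
                  x$chrom[variants], x$pos[variants],
                  x$ref[variants], x$alt[variants])
}
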