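# SNP/sample quality filters, Hardy-Weinberg exact test, genomic kinship,
# EMMAX-style mixed-model association, BH correction, SNP-to-gene assignment.

#' Exact Hardy-Weinberg test p-value
#'
#' Conditional exact test on genotype counts: given the observed allele
#' counts, the p-value is the total probability of all heterozygote counts
#' whose conditional probability does not exceed that of the observed count
#' (two-sided probability-mass criterion, no mid-p). Monomorphic sites give
#' p = 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts (non-negative, sum >= 1).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(counts < 0) || sum(counts) < 1) stop("invalid genotype counts")
  n <- sum(counts)
  n_minor <- min(2 * n_hom_ref + n_het, 2 * n_hom_alt + n_het)
  if (n_minor == 0) return(1)
  hets <- seq.int(n_minor %% 2L, n_minor, by = 2L)
  # log P(het | n, n_minor) up to the shared normalizing constant
  logp <- vapply(hets, function(h) {
    hom_min <- (n_minor - h) / 2
    hom_maj <- n - h - hom_min
    h * log(2) - lgamma(h + 1) - lgamma(hom_min + 1) - lgamma(hom_maj + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  obs <- pr[hets == n_het]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Quality-filter SNPs and samples before association
#'
#' Applied in a fixed order: (1) drop samples whose genotype call rate is
#' below `sample_callrate_min`; (2) with the remaining samples, drop SNPs
#' whose missing rate exceeds `missing_max`; (3) drop SNPs with minor-allele
#' frequency (from non-missing dosages) below `maf_min`; (4) drop SNPs
#' failing the Hardy-Weinberg exact test. By convention stage 4 removes SNPs
#' with p < `hwe_alpha`; `literal_hwe = TRUE` inverts this and *keeps* only
#' p <= `hwe_alpha` instead (a non-standard reading, exposed for
#' comparability).
#'
#' @param x a [genotype_matrix()].
#' @param missing_max per-SNP missing-rate ceiling (default 0.10).
#' @param maf_min minor-allele-frequency floor (default 0.05).
#' @param sample_callrate_min per-sample call-rate floor (default 0.80).
#' @param hwe_alpha Hardy-Weinberg exact-test threshold (default 0.001).
#' @param literal_hwe keep only SNPs with HWE p <= alpha instead of dropping
#'   them (default FALSE).
#' @return list: `matrix` (filtered [genotype_matrix()]) and `report`
#'   (data.frame of stage-wise SNP counts plus dropped sample ids).
#' @export
filter_snps <- function(x, missing_max = 0.10, maf_min = 0.05,
                        sample_callrate_min = 0.80, hwe_alpha = 0.001,
                        literal_hwe = FALSE) {
  n_input <- n_variants(x)
  callrate <- colMeans(!is.na(x$dosage))
  dropped_samples <- sample_ids(x)[callrate < sample_callrate_min]
  keep_samples <- setdiff(sample_ids(x), dropped_samples)
  if (length(keep_samples) < 2L) stop("fewer than 2 samples pass the call-rate filter")
  x <- subset_matrix(x, samples = keep_samples)
  n_after_callrate <- n_variants(x)

  miss <- rowMeans(is.na(x$dosage))
  x <- subset_matrix(x, variants = miss <= missing_max)
  n_after_missing <- n_variants(x)
  if (n_after_missing == 0L) stop("no SNPs pass the missing-rate filter")

  p <- rowMeans(x$dosage, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  x <- subset_matrix(x, variants = !is.na(maf) & maf >= maf_min)
  n_after_maf <- n_variants(x)
  if (n_after_maf == 0L) stop("no SNPs pass the MAF filter")

  hwe_p <- vapply(seq_len(n_variants(x)), function(i) {
    d <- x$dosage[i, ]
    hwe_exact_p(sum(d == 0L, na.rm = TRUE), sum(d == 1L, na.rm = TRUE),
                sum(d == 2L, na.rm = TRUE))
  }, numeric(1))
  keep <- if (literal_hwe) hwe_p <= hwe_alpha else hwe_p >= hwe_alpha
  x <- subset_matrix(x, variants = keep)
  if (n_variants(x) == 0L) stop("no SNPs pass the Hardy-Weinberg filter")

  report <- data.frame(
    n_input = n_input,
    n_after_sample_callrate = n_after_callrate,
    n_after_missing = n_after_missing,
    n_after_maf = n_after_maf,
    n_after_hwe = n_variants(x),
    n_dropped_samples = length(dropped_samples)
  )
  list(matrix = x, report = report, dropped_samples = dropped_samples)
}

#' Standardized genomic kinship matrix
#'
#' `K = (1/m) * sum_sites (g - 2p)(g - 2p)' / (2p(1-p))` over the m filtered
#' SNPs, with missing dosages mean-imputed per site. Symmetric by
#' construction; under complete data each site's contribution is centered so
#' row means are ~0.
#'
#' @param x a filtered [genotype_matrix()] (>= 2 SNPs, no monomorphic sites).
#' @return n_samples x n_samples numeric matrix with sample-id dimnames.
#' @export
kinship <- function(x) {
  if (n_variants(x) < 2L) stop("kinship needs >= 2 SNPs")
  d <- x$dosage
  p <- rowMeans(d, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic site in kinship input; run filter_snps() first")
  }
  z <- (d - 2 * p) / sqrt(2 * p * (1 - p))
  z[is.na(z)] <- 0  # mean imputation in standardized units
  K <- crossprod(z) / nrow(z)
  dimnames(K) <- list(sample_ids(x), sample_ids(x))
  (K + t(K)) / 2
}

# restricted log-likelihood (up to an additive constant) for the variance
# ratio delta = sigma_e^2 / sigma_g^2, on the eigenbasis of K; intercept-only
# null model
reml_nll <- function(delta, lambda, y_rot, x_rot) {
  w <- 1 / (lambda + delta)
  xtwx <- crossprod(x_rot, w * x_rot)
  beta <- solve(xtwx, crossprod(x_rot, w * y_rot))
  r <- y_rot - x_rot %*% beta
  rss <- sum(w * r^2)
  nq <- length(y_rot) - ncol(x_rot)
  as.numeric(nq * log(rss) + sum(log(lambda + delta)) + determinant(xtwx)$modulus)
}

#' Kinship-corrected association scan (EMMAX-style)
#'
#' Single-random-effect linear mixed model `y = mu + x*beta + u + e` with
#' `cov(u) = sigma_g^2 * K`. The kinship matrix is eigendecomposed once, the
#' variance ratio `delta = sigma_e^2/sigma_g^2` is estimated by REML on the
#' null (intercept-only) model over a log-spaced grid with local refinement,
#' and every SNP is then tested by generalized least squares with the null
#' variance components held fixed — the approximation popularized by EMMAX
#' and of the same family as FaST-LMM's speedups. Missing dosages are
#' mean-imputed per SNP. Wald p-values use a t reference with n - 2 degrees
#' of freedom, so in the no-relatedness limit (K = I) they equal ordinary
#' least-squares p-values.
#'
#' @param x a filtered [genotype_matrix()].
#' @param phenotype numeric vector aligned with `sample_ids(x)` (the ordinal
#'   blooming code early=0, mid=1, late=2, or any quantitative trait).
#' @param K kinship matrix from [kinship()] (or identity for plain OLS).
#' @param delta optional fixed variance ratio, skipping REML.
#' @return data.frame: chrom, pos, beta, se, p_value, plus the fitted
#'   `delta` as an attribute. Constant phenotypes yield beta = 0, p = NA.
#' @export
lmm_assoc <- function(x, phenotype, K, delta = NULL) {
  n <- n_samples(x)
  if (length(phenotype) != n) stop("phenotype length must match sample count")
  out <- data.frame(chrom = x$chrom, pos = x$pos,
                    beta = 0, se = NA_real_, p_value = NA_real_,
                    stringsAsFactors = FALSE)
  if (stats::sd(phenotype) == 0) {
    attr(out, "delta") <- NA_real_
    return(out)
  }
  eig <- eigen(K, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  U <- eig$vectors
  y_rot <- drop(crossprod(U, phenotype))
  ones_rot <- drop(crossprod(U, rep(1, n)))
  if (is.null(delta)) {
    grid <- 10^seq(-5, 5, length.out = 61)
    nll <- vapply(grid, reml_nll, numeric(1), lambda = lambda,
                  y_rot = y_rot, x_rot = cbind(ones_rot))
    i <- which.min(nll)
    lo <- grid[max(i - 1L, 1L)]; hi <- grid[min(i + 1L, length(grid))]
    opt <- stats::optimize(function(ld) {
      reml_nll(exp(ld), lambda, y_rot, cbind(ones_rot))
    }, interval = log(c(lo, hi)))
    delta <- exp(opt$minimum)
  }
  w <- 1 / (lambda + delta)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("transformed covariance is not positive definite (delta = ", delta, ")")
  }
  df <- n - 2L
  for (i in seq_len(n_variants(x))) {
    g <- x$dosage[i, ]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (stats::sd(g) == 0) next
    X <- cbind(ones_rot, drop(crossprod(U, g)))
    xtwx <- crossprod(X, w * X)
    xtwy <- crossprod(X, w * y_rot)
    bhat <- solve(xtwx, xtwy)
    r <- y_rot - X %*% bhat
    s2 <- sum(w * r^2) / df
    se <- sqrt(s2 * solve(xtwx)[2, 2])
    out$beta[i] <- bhat[2]
    out$se[i] <- se
    out$p_value[i] <- 2 * stats::pt(-abs(bhat[2] / se), df = df)
  }
  attr(out, "delta") <- delta
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjustment: on sorted p-values, `q_(i) = min_{j >= i} p_(j)*m/j`,
#' mapped back to the input order and capped at 1. Discoveries at the
#' study's operating point are `q <= 0.01`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\] (NA passed through).
#' @return q-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  q <- rep(NA_real_, length(p_values))
  ok <- which(!is.na(p_values))
  m <- length(ok)
  if (m == 0L) return(q)
  o <- order(p_values[ok])
  ranked <- p_values[ok][o] * m / seq_len(m)
  q[ok][o] <- pmin(1, rev(cummin(rev(ranked))))
  q
}

#' Assign SNPs to genes within a flank
#'
#' A SNP is assigned to every gene whose interval extended by `flank` bp on
#' both sides (strand-agnostic) contains its position.
#'
#' @param assoc data.frame with chrom, pos (e.g. from [lmm_assoc()]).
#' @param gene_table data.frame from [read_gff()].
#' @param flank bp added on each side of the gene body (default 2000).
#' @return `assoc` with an added `genes` column (comma-joined gene ids,
#'   empty string when none).
#' @export
assign_genes <- function(assoc, gene_table, flank = 2000L) {
  assoc$genes <- rep("", nrow(assoc))
  if (nrow(assoc) == 0L || nrow(gene_table) == 0L) return(assoc)
  gr_s <- GenomicRanges::GRanges(assoc$chrom, IRanges::IRanges(assoc$pos, assoc$pos))
  gr_g <- GenomicRanges::GRanges(gene_table$chrom,
                                 IRanges::IRanges(pmax(1L, gene_table$start - flank),
                                                  gene_table$end + flank))
  hits <- GenomicRanges::findOverlaps(gr_s, gr_g)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  for (i in unique(qh)) {
    assoc$genes[i] <- paste(gene_table$gene_id[sh[qh == i]], collapse = ",")
  }
  assoc
}
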