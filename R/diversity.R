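# Per-individual diversity summaries and windowed multi-sample statistics:
# nucleotide diversity (pi), Watterson's theta, and Weir-Cockerham F_ST.

#' Per-individual diversity summary
#'
#' Summarizes one diploid sample: genotyped site count, heterozygous
#' (polymorphic-within-individual) site count, observed heterozygosity,
#' per-individual nucleotide diversity `pi = het_obs / 2`, and the inbreeding
#' coefficient `F_IS = 1 - H_obs / H_exp`. For a single diploid every
#' within-individual polymorphic site has H_obs = 1 and, at the within-sample
#' allele frequency 0.5, H_exp = 0.5, so F_IS is exactly -1 whenever the
#' sample carries any heterozygous site, and undefined (NA) otherwise.
#'
#' @param x a [genotype_matrix()].
#' @param sample sample identifier present in `x`.
#' @return one-row data.frame: sample, n_sites, n_polymorphic, n_invariant,
#'   het_obs, pi_ind, f_is.
#' @export
individual_diversity <- function(x, sample) {
  if (!sample %in% sample_ids(x)) stop("unknown sample: ", sample)
  d <- x$dosage[, sample]
  n_sites <- sum(!is.na(d))
  if (n_sites == 0L) stop("sample ", sample, " has no genotyped sites")
  n_poly <- sum(d == 1L, na.rm = TRUE)
  het <- n_poly / n_sites
  data.frame(
    sample = sample,
    n_sites = n_sites,
    n_polymorphic = n_poly,
    n_invariant = n_sites - n_poly,
    het_obs = het,
    pi_ind = het / 2,
    f_is = if (n_poly > 0L) -1 else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Per-individual diversity for every sample
#'
#' @param x a [genotype_matrix()].
#' @return data.frame with one [individual_diversity()] row per sample.
#' @export
diversity_table <- function(x) {
  do.call(rbind, lapply(sample_ids(x), function(s) individual_diversity(x, s)))
}

#' Sliding-window coordinates
#'
#' Windows of `window` bp advancing by `step` bp: the k-th window is
#' `[step*(k-1) + 1, step*(k-1) + window]`, truncated at `chrom_length`; the
#' final window may be short. With the defaults this is the 50-kb / 10-kb
#' sliding grid whose boundaries follow the x0001..y0000 pattern.
#'
#' @param chrom_length chromosome length in bp.
#' @param window window span in bp (default 50000).
#' @param step step in bp (default 10000); must satisfy window >= step >= 1.
#' @return data.frame with columns start, end (1-based inclusive).
#' @export
window_iter <- function(chrom_length, window = 50000L, step = 10000L) {
  chrom_length <- as.integer(chrom_length)
  if (is.na(chrom_length) || chrom_length < 1L) stop("chrom_length must be >= 1")
  if (step < 1L || window < step) stop("need window >= step >= 1")
  starts <- seq.int(1L, chrom_length, by = step)
  ends <- pmin(starts + window - 1L, chrom_length)
  # stop once a window reaches the chromosome end; later starts add no cover
  idx <- seq_len(which(ends >= chrom_length)[1])
  data.frame(start = starts[idx], end = ends[idx])
}

# per-site allele summaries for a set of samples: non-missing allele count n,
# alt-allele count, alt frequency, observed heterozygote count
site_summary <- function(x, samples) {
  d <- x$dosage[, samples, drop = FALSE]
  n_gen <- rowSums(!is.na(d))
  alt <- rowSums(d, na.rm = TRUE)
  n_al <- 2L * n_gen
  p <- ifelse(n_al > 0L, alt / n_al, NA_real_)
  list(n_genotyped = n_gen, n_alleles = n_al, p = p,
       n_het = rowSums(d == 1L, na.rm = TRUE))
}

#' Windowed nucleotide diversity (pi)
#'
#' Unbiased per-bp pairwise diversity from unphased dosages:
#' `pi = sum_sites [n/(n-1)] * 2*p*(1-p) / span`, with `n` the non-missing
#' allele count at the site, `p` the alternate-allele frequency, and `span`
#' the full window length in bp. Equals the mean per-bp pairwise Hamming
#' distance over haplotype pairs under Hardy-Weinberg within-sample pairing.
#'
#' @param x a [genotype_matrix()].
#' @param samples sample ids to use.
#' @param chrom chromosome label.
#' @param start,end 1-based inclusive window bounds.
#' @param max_group_missing sites with a higher missing-genotype fraction
#'   among `samples` are excluded (default 0.5).
#' @return list with per-bp `pi` and the usable segregating-site count `n_snps`.
#' @export
window_pi <- function(x, samples, chrom, start, end, max_group_missing = 0.5) {
  idx <- which(x$chrom == chrom & x$pos >= start & x$pos <= end)
  span <- end - start + 1
  if (length(idx) == 0L) return(list(pi = 0, n_snps = 0L))
  s <- site_summary(subset_matrix(x, idx), samples)
  usable <- s$n_alleles >= 2L &
    (1 - s$n_genotyped / length(samples)) <= max_group_missing
  p <- s$p[usable]
  n <- s$n_alleles[usable]
  contrib <- ifelse(n > 1L, n / (n - 1) * 2 * p * (1 - p), 0)
  list(pi = sum(contrib) / span, n_snps = sum(usable & p > 0 & p < 1))
}

#' Windowed Watterson estimator (theta_W)
#'
#' `theta_W = S / a_{n-1} / span` with S the segregating-site count among the
#' chosen samples, `a_{n-1} = sum_{i=1}^{n-1} 1/i` the harmonic number, and
#' `n = 2 x number of samples` haplotypes.
#'
#' @inheritParams window_pi
#' @return per-bp theta_W.
#' @export
window_theta_w <- function(x, samples, chrom, start, end) {
  n <- 2L * length(samples)
  if (n < 2L) stop("theta_W needs at least one diploid sample (n >= 2 haplotypes)")
  idx <- which(x$chrom == chrom & x$pos >= start & x$pos <= end)
  span <- end - start + 1
  if (length(idx) == 0L) return(0)
  s <- site_summary(subset_matrix(x, idx), samples)
  S <- sum(!is.na(s$p) & s$p > 0 & s$p < 1)
  S / harmonic_number(n - 1L) / span
}

harmonic_number <- function(k) sum(1 / seq_len(k))

# Weir & Cockerham (1984) per-site variance components a (between-population),
# b (between individuals within populations), c (within individuals), for two
# populations of diploids. Inputs are per-site vectors for each group.
wc_site_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  ok <- n1 >= 1 & n2 >= 1 & nbar > 1
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  list(a = a, b = b, c = cc)
}

# Hudson estimator numerator/denominator per site (Bhatia et al. 2013 form);
# n1/n2 are allele counts.
hudson_site_components <- function(n1, p1, n2, p2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- n1 > 1 & n2 > 1
  num[!ok] <- NA_real_; den[!ok] <- NA_real_
  list(num = num, den = den)
}

#' Windowed F_ST between two sample groups
#'
#' Multi-locus Weir-Cockerham (1984) estimate aggregated as a ratio of sums
#' over the window's usable sites: `F_ST = sum(a) / sum(a + b + c)`. Slightly
#' negative values are reported as computed. A Hudson-style estimator
#' (ratio-of-sums of the Bhatia et al. 2013 per-site components) is available
#' via `estimator = "hudson"`.
#'
#' @inheritParams window_pi
#' @param group_a,group_b sample id vectors for the two groups (>= 2 each).
#' @param estimator "wc" (default) or "hudson".
#' @return F_ST estimate, or NA when no site is informative.
#' @export
window_fst <- function(x, group_a, group_b, chrom, start, end,
                       estimator = c("wc", "hudson"),
                       max_group_missing = 0.5) {
  estimator <- match.arg(estimator)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs >= 2 samples")
  }
  idx <- which(x$chrom == chrom & x$pos >= start & x$pos <= end)
  if (length(idx) == 0L) return(NA_real_)
  sub <- subset_matrix(x, idx)
  sa <- site_summary(sub, group_a)
  sb <- site_summary(sub, group_b)
  usable <- (1 - sa$n_genotyped / length(group_a)) <= max_group_missing &
    (1 - sb$n_genotyped / length(group_b)) <= max_group_missing &
    sa$n_genotyped >= 1L & sb$n_genotyped >= 1L
  if (!any(usable)) return(NA_real_)
  if (estimator == "wc") {
    comp <- wc_site_components(
      sa$n_genotyped[usable], sa$p[usable], sa$n_het[usable] / sa$n_genotyped[usable],
      sb$n_genotyped[usable], sb$p[usable], sb$n_het[usable] / sb$n_genotyped[usable])
    num <- sum(comp$a, na.rm = TRUE)
    den <- sum(comp$a + comp$b + comp$c, na.rm = TRUE)
  } else {
    comp <- hudson_site_components(sa$n_alleles[usable], sa$p[usable],
                                   sb$n_alleles[usable], sb$p[usable])
    num <- sum(comp$num, na.rm = TRUE)
    den <- sum(comp$den, na.rm = TRUE)
  }
  if (!is.finite(den) || den == 0) return(NA_real_)
  num / den
}
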