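# Independent brute-force oracles and small fixture builders shared across
# the test files. These deliberately use the slow/obvious formulation of each
# quantity, not the package's code path.

# genotype matrix from a haplotype matrix (haplotypes in columns, 0/1);
# consecutive haplotype pairs form diploid samples
matrix_from_haps <- function(haps, chrom = "chr1", pos = NULL) {
  stopifnot(ncol(haps) %% 2 == 0)
  n <- ncol(haps) / 2
  d <- sapply(seq_len(n), function(i) haps[, 2 * i - 1] + haps[, 2 * i])
  if (is.null(dim(d))) d <- matrix(d, nrow = nrow(haps))
  colnames(d) <- sprintf("S%02d", seq_len(n))
  if (is.null(pos)) pos <- seq_len(nrow(haps))
  genotype_matrix(d, rep(chrom, nrow(haps)), pos)
}

# mean pairwise per-bp Hamming distance over all haplotype pairs
pi_pairwise_oracle <- function(haps, span) {
  nh <- ncol(haps)
  tot <- 0
  for (i in seq_len(nh - 1)) {
    for (j in (i + 1):nh) tot <- tot + sum(haps[, i] != haps[, j])
  }
  tot / choose(nh, 2) / span
}

# exact HWE p by full enumeration of the conditional het distribution,
# probabilities via choose() (normalized by construction)
hwe_enum_oracle <- function(nAA, nAB, nBB) {
  n <- nAA + nAB + nBB
  nA <- 2 * nAA + nAB
  nminor <- min(nA, 2 * n - nA)
  if (nminor == 0) return(1)
  hets <- seq(nminor %% 2, nminor, by = 2)
  pr <- sapply(hets, function(h) {
    hom_min <- (nminor - h) / 2
    hom_maj <- n - h - hom_min
    exp(lfactorial(n) - lfactorial(h) - lfactorial(hom_min) -
          lfactorial(hom_maj) + h * log(2) +
          lfactorial(nminor) + lfactorial(2 * n - nminor) - lfactorial(2 * n))
  })
  obs <- pr[hets == nAB]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

# quadratic all-pairs closed-interval intersection: TRUE at [i, j] iff
# interval set a row i intersects set b row j (both 1-based inclusive)
overlap_brute <- function(a, b) {
  out <- matrix(FALSE, nrow(a), nrow(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      out[i, j] <- a$chrom[i] == b$chrom[j] &&
        a$start[i] <= b$end[j] && b$start[j] <= a$end[i]
    }
  }
  out
}

# small three-group sample table matching simulator sample ids
sim_sample_table <- function(n_early = 6, n_mid = 5, n_late = 8) {
  data.frame(
    sample = c(sprintf("E%02d", seq_len(n_early)),
               sprintf("M%02d", seq_len(n_mid)),
               sprintf("L%02d", seq_len(n_late))),
    group = rep(c("early", "mid", "late"), c(n_early, n_mid, n_late)),
    region = "sim", stringsAsFactors = FALSE)
}

# deterministic dense toy matrix: m sites x n samples, all polymorphic-ish
toy_matrix <- function(m = 40, n = 8, seed = 7, chrom = "chr1") {
  set.seed(seed)
  d <- matrix(rbinom(m * n, 2, runif(m, 0.2, 0.8)), nrow = m,
              dimnames = list(NULL, sprintf("S%02d", seq_len(n))))
  genotype_matrix(d, rep(chrom, m), sort(sample.int(m * 50, m)))
}
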