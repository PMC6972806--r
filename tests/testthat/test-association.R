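test_that("HWE exact test matches full enumeration", {
  # monomorphic -> 1
  expect_equal(hwe_exact_p(10, 0, 0), 1)
  expect_equal(hwe_exact_p(0, 0, 7), 1)
  # (0, 2, 0): two ref + two alt alleles, het in {0, 2}
  expect_equal(hwe_exact_p(0, 2, 0), hwe_enum_oracle(0, 2, 0))
  # random counts up to n = 50 against the choose()-based enumeration
  set.seed(23)
  for (i in 1:60) {
    n <- sample(1:50, 1)
    nAB <- sample(0:n, 1)
    nAA <- sample(0:(n - nAB), 1)
    nBB <- n - nAB - nAA
    expect_equal(hwe_exact_p(nAA, nAB, nBB), hwe_enum_oracle(nAA, nAB, nBB),
                 tolerance = 1e-12)
  }
  expect_error(hwe_exact_p(-1, 0, 2), "invalid")
})

test_that("filter_snps applies thresholds in the documented order", {
  set.seed(77)
  n <- 19
  d <- matrix(rbinom(60 * n, 2, 0.4), nrow = 60,
              dimnames = list(NULL, sprintf("S%02d", 1:n)))
  d[1, 1:2] <- NA                          # 2/19 = 10.5% missing -> dropped
  d[2, ] <- 0L                             # monomorphic -> dropped at MAF
  d[3, ] <- c(1L, rep(0L, n - 1))          # singleton: MAF 1/38 < 5%
  d[4, ] <- rep(c(0L, 2L), length.out = n) # strong het deficit -> HWE fail
  x <- genotype_matrix(d, rep("c", 60), seq_len(60) * 100L)
  out <- filter_snps(x)
  r <- out$report
  expect_equal(r$n_input, 60L)
  expect_equal(r$n_after_sample_callrate, 60L)   # no sample below 80%
  expect_equal(r$n_after_missing, 59L)
  expect_true(r$n_after_maf <= 57L)
  expect_true(r$n_after_hwe <= r$n_after_maf)    # counts non-increasing
  expect_false(any(apply(out$matrix$dosage, 1, function(g) {
    p <- mean(g, na.rm = TRUE) / 2; min(p, 1 - p) < 0.05
  })))
  # the engineered HWE violator is gone under the conventional reading
  expect_false(400L %in% out$matrix$pos)
  # literal reading keeps only the violators
  lit <- filter_snps(x, literal_hwe = TRUE)
  expect_true(all(lit$matrix$pos %in% c(400L)))
})

test_that("sample call-rate filter drops low-coverage accessions first", {
  set.seed(3)
  d <- matrix(rbinom(40 * 5, 2, 0.5), nrow = 40,
              dimnames = list(NULL, sprintf("S%02d", 1:5)))
  d[1:12, 1] <- NA  # sample 1 call rate 70% < 80%
  x <- genotype_matrix(d, rep("c", 40), seq_len(40))
  out <- filter_snps(x, hwe_alpha = 0)
  expect_equal(out$dropped_samples, "S01")
  expect_false("S01" %in% sample_ids(out$matrix))
})

test_that("kinship is symmetric, centered, and separates simulated groups", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 1e6, snp_density = 0.003,
                    F = 0.15, seed = 10)
  sim <- simulate_genotypes(cfg)
  flt <- filter_snps(sim$matrix, hwe_alpha = 0)
  K <- kinship(flt$matrix)
  expect_equal(K, t(K))
  expect_true(all(abs(rowMeans(K)) < 1e-10))  # complete data: exact centering
  grp <- sim$samples$group[match(rownames(K), sim$samples$sample)]
  within <- mean(K[grp == "early", grp == "early"][upper.tri(diag(sum(grp == "early")))])
  between <- mean(K[grp == "early", grp == "late"])
  expect_gt(within, between)
  # a duplicated sample matches itself as strongly as itself
  d2 <- cbind(flt$matrix$dosage, dup = flt$matrix$dosage[, 1])
  x2 <- genotype_matrix(d2, flt$matrix$chrom, flt$matrix$pos)
  K2 <- kinship(x2)
  expect_equal(K2["dup", colnames(d2)[1]], K2["dup", "dup"])
  mono <- rbind(c(0L, 0L), c(0L, 2L))
  colnames(mono) <- c("a", "b")
  expect_error(kinship(genotype_matrix(mono, c("c", "c"), 1:2)), "monomorphic")
})

test_that("with an identity kinship the mixed model reduces to OLS", {
  set.seed(42)
  x <- toy_matrix(m = 30, n = 12, seed = 13)
  y <- rnorm(12)
  res <- lmm_assoc(x, y, diag(12))
  for (i in seq_len(30)) {
    g <- x$dosage[i, ]
    if (sd(g) == 0) next
    fit <- summary(lm(y ~ g))$coefficients
    expect_equal(res$beta[i], fit["g", "Estimate"], tolerance = 1e-8)
    expect_equal(res$p_value[i], fit["g", "Pr(>|t|)"], tolerance = 1e-8)
  }
})

test_that("a constant phenotype yields zero effects and missing p-values", {
  x <- toy_matrix(m = 10, n = 6, seed = 1)
  res <- lmm_assoc(x, rep(1, 6), diag(6))
  expect_true(all(res$beta == 0))
  expect_true(all(is.na(res$p_value)))
})

test_that("a strong causal SNP attains the minimum p-value across seeds", {
  hits <- 0L
  for (seed in 1:20) {
    cfg <- sim_config(n_chrom = 1, chrom_length = 8e5, snp_density = 0.002,
                      F = 0.1, seed = 1000L + seed)
    sim <- simulate_genotypes(cfg)
    flt <- filter_snps(sim$matrix, hwe_alpha = 0)
    xf <- flt$matrix
    # pick a common mid-chromosome SNP as causal
    p <- rowMeans(xf$dosage, na.rm = TRUE) / 2
    cand <- which(p > 0.3 & p < 0.7 & xf$pos > 3e5 & xf$pos < 5e5)
    ci <- cand[ceiling(length(cand) / 2)]
    y <- simulate_phenotype(sim$samples, xf,
                            causal_snp = list(chrom = "chr1", pos = xf$pos[ci],
                                              effect = 2),
                            noise_sd = 0.1, seed = 2000L + seed)
    res <- lmm_assoc(xf, y, kinship(xf))
    if (which.min(res$p_value) == ci) hits <- hits + 1L
  }
  expect_gte(hits, 19L)  # >= 95% of 20 seeds
})

test_that("null p-values are calibrated at n ~ 100 samples", {
  # fraction of SNPs with p < alpha under an independent Gaussian phenotype;
  # at 19 samples the far tail is not trustworthy, so calibration is checked
  # at the sample size where the Wald t reference is accurate
  cfg <- sim_config(n_per_group = c(early = 50, mid = 2, late = 50),
                    n_chrom = 1, chrom_length = 3e5, snp_density = 0.002,
                    F = 0.1, seed = 88)
  sim <- simulate_genotypes(cfg)
  xf <- filter_snps(sim$matrix, hwe_alpha = 0)$matrix
  K <- kinship(xf)
  set.seed(89)
  pvals <- unlist(lapply(1:5, function(r) {
    lmm_assoc(xf, rnorm(n_samples(xf)), K)$p_value
  }))
  pvals <- pvals[!is.na(pvals)]
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.015)
  expect_lt(abs(mean(pvals < 0.01) - 0.01), 0.008)
})

test_that("bh_adjust reproduces the step-up formula and the reference oracle", {
  expect_equal(bh_adjust(c(0.001, 0.02, 0.03, 0.04)),
               c(0.004, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_true(all(bh_adjust(c(0.5, 0.01)) >= c(0.5, 0.01)))  # q >= p
  set.seed(8)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), p.adjust(p, method = "BH"), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("assign_genes respects the 2-kb flank boundary exactly", {
  genes <- data.frame(gene_id = "g1", chrom = "c", start = 10000L,
                      end = 12000L, stringsAsFactors = FALSE)
  assoc <- data.frame(chrom = "c", pos = c(8500L, 8000L, 7999L, 14000L, 14001L))
  got <- assign_genes(assoc, genes)
  expect_equal(got$genes, c("g1", "g1", "", "g1", ""))
})

test_that("SNP-to-gene assignment matches brute-force containment", {
  set.seed(15)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:30),
                      chrom = sample(c("c1", "c2"), 30, TRUE),
                      start = sample.int(5e4, 30), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(3e3, 30)
  assoc <- data.frame(chrom = sample(c("c1", "c2"), 50, TRUE),
                      pos = sample.int(6e4, 50))
  got <- assign_genes(assoc, genes, flank = 2000)
  flanked <- transform(genes, start = pmax(1, start - 2000), end = end + 2000)
  want <- overlap_brute(data.frame(chrom = assoc$chrom, start = assoc$pos,
                                   end = assoc$pos), flanked)
  for (i in seq_len(nrow(assoc))) {
    exp_genes <- genes$gene_id[want[i, ]]
    got_genes <- if (nzchar(got$genes[i])) strsplit(got$genes[i], ",")[[1]] else character(0)
    expect_setequal(got_genes, exp_genes)
  }
})
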