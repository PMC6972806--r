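test_that("log2_ratio handles the documented cases", {
  expect_equal(log2_ratio(0.2, 0.1), 1)
  expect_equal(log2_ratio(0.37, 0.37), 0)
  expect_equal(log2_ratio(0.1966, 0.0131), log2(0.1966 / 0.0131))
  expect_equal(log2_ratio(0.1966, 0.0131), 3.9077, tolerance = 1e-4)
  expect_equal(log2_ratio(0.1, 0), Inf)
  expect_true(is.na(log2_ratio(0, 0)))
  expect_error(log2_ratio(-0.1, 0.2), "negative")
})

test_that("thresholds are nearest-rank order statistics of the usable windows", {
  w <- data.frame(chrom = "c", start = 1:20, end = 1:20, n_snps = 50L,
                  pi_high = 1, pi_low = 1, theta_w = 1,
                  fst = as.numeric(1:20), log2_ratio = as.numeric(1:20),
                  usable = TRUE)
  th <- sweep_thresholds(w, quantile = 0.05, min_windows = 20)
  expect_equal(th$fst_cut, 19)
  expect_equal(th$ratio_cut, 19)
  sig <- significant_windows(w, th)
  expect_equal(which(sig), 20L)              # exactly the top 5%
  # degenerate distribution: cut equals the common value, nothing significant
  w$fst <- 0.3; w$log2_ratio <- 0.3
  th2 <- sweep_thresholds(w, min_windows = 20)
  expect_equal(th2$fst_cut, 0.3)
  expect_equal(sum(significant_windows(w, th2)), 0L)
  expect_error(sweep_thresholds(w[1:5, ]), "usable windows")
})

test_that("joint tail on neutral data flags at most 5% of windows", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 3e6, snp_density = 0.002,
                    F = 0.1, seed = 14)
  sim <- simulate_genotypes(cfg)
  w <- scan_windows(sim$matrix, sim$samples)
  th <- sweep_thresholds(w)
  frac <- sum(significant_windows(w, th)) / th$n_usable
  expect_lte(frac, 0.05)
  # with independent tails the joint rate sits well below either marginal
  expect_gte(frac, 0)
})

test_that("call_regions merges overlapping and book-ended windows and is idempotent", {
  sig <- data.frame(chrom = c("c1", "c1", "c2"),
                    start = c(220001L, 250001L, 500001L),
                    end = c(270000L, 300000L, 550000L))
  reg <- call_regions(sig)
  expect_equal(reg$start, c(220001L, 500001L))
  expect_equal(reg$end, c(300000L, 550000L))
  expect_equal(reg$length, c(80000L, 50000L))
  expect_equal(reg$n_windows, c(2L, 1L))
  # single window region
  one <- call_regions(data.frame(chrom = "c", start = 220001L, end = 270000L))
  expect_equal(one$length, 50000L)
  # book-ended windows merge; disjoint ones do not
  be <- call_regions(data.frame(chrom = "c", start = c(1L, 51L, 200L),
                                end = c(50L, 100L, 250L)))
  expect_equal(nrow(be), 2L)
  expect_equal(be$end[1], 100L)
  # idempotence: re-merging the merged output changes nothing
  again <- call_regions(reg[, c("chrom", "start", "end")])
  expect_equal(again[, c("chrom", "start", "end", "length")],
               reg[, c("chrom", "start", "end", "length")])
  # min_length post-filter
  expect_equal(nrow(call_regions(sig, min_length = 60000)), 1L)
})

test_that("every significant window lands in exactly one called region", {
  set.seed(4)
  starts <- sort(sample(seq(1, 1e6, by = 10000), 40)) # grid-aligned
  sig <- data.frame(chrom = "c", start = starts, end = starts + 49999L)
  reg <- call_regions(sig)
  hit <- vapply(seq_len(nrow(sig)), function(i) {
    sum(reg$start <= sig$start[i] & reg$end >= sig$end[i])
  }, numeric(1))
  expect_true(all(hit == 1))
  expect_equal(sum(reg$n_windows), nrow(sig))
  # regions on one chromosome never overlap
  if (nrow(reg) > 1) expect_true(all(diff(reg$start) > 0 &
                                       reg$start[-1] > reg$end[-nrow(reg)]))
})

test_that("region_summary reproduces the published region geometry", {
  reg <- published_table("sweep_regions")
  expect_equal(nrow(reg), 21L)
  expect_equal(reg$end - reg$start + 1L, reg$length)
  s <- region_summary(reg, genome_size = 280e6)
  expect_equal(s$total_bp, 3650000)
  expect_equal(s$mean_bp, 173809.5, tolerance = 1e-6)
  expect_equal(s$max_bp, 540000)
  expect_equal(round(s$pct_genome, 1), 1.3)
  # single-region degenerate case
  s1 <- region_summary(data.frame(length = 7L), genome_size = 100)
  expect_equal(unlist(s1[c("total_bp", "mean_bp", "max_bp")]),
               c(total_bp = 7, mean_bp = 7, max_bp = 7))
  expect_error(region_summary(reg, genome_size = 0), "genome_size")
})

test_that("genes_in_regions uses closed-interval intersection", {
  regions <- data.frame(chrom = "c", start = 1000L, end = 2000L)
  genes <- data.frame(gene_id = c("in_b", "out_b", "inside", "wrongchr"),
                      chrom = c("c", "c", "c", "d"),
                      start = c(1900L, 2001L, 1500L, 1500L),
                      end = c(2500L, 2500L, 1600L, 1600L),
                      stringsAsFactors = FALSE)
  got <- genes_in_regions(regions, genes)
  expect_setequal(got$genes[[1]], c("in_b", "inside"))
})

test_that("gene-region assignment matches the quadratic brute-force oracle", {
  set.seed(9)
  regions <- data.frame(chrom = sample(c("c1", "c2"), 15, TRUE),
                        start = sample.int(1e5, 15))
  regions$end <- regions$start + sample.int(2e4, 15)
  genes <- data.frame(gene_id = sprintf("g%02d", 1:40),
                      chrom = sample(c("c1", "c2"), 40, TRUE),
                      start = sample.int(1.2e5, 40), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(5e3, 40)
  got <- genes_in_regions(regions, genes)
  want <- overlap_brute(regions, genes)
  for (i in seq_len(nrow(regions))) {
    expect_setequal(got$genes[[i]], genes$gene_id[want[i, ]])
  }
})

test_that("segment_genes applies the 1-Mb bin and gene-count rules", {
  mk <- function(n, lo, hi, ch = "c", pre = "g") {
    start <- floor(seq(lo, hi, length.out = n))
    data.frame(gene_id = paste0(pre, seq_len(n)), chrom = ch,
               start = start, end = start + 10L, stringsAsFactors = FALSE)
  }
  # 7 genes in bin 1 + 3 in adjacent bin 2 -> one kept segment of 10
  g <- rbind(mk(7, 1e5, 9e5, pre = "a"), mk(3, 1.1e6, 1.9e6, pre = "b"))
  seg <- segment_genes(g)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_genes, 10L)
  expect_equal(c(seg$start, seg$end), c(1, 2e6))
  # threshold boundary: exactly five genes discarded, six kept
  expect_equal(nrow(segment_genes(mk(5, 1e5, 9e5))), 0L)
  expect_equal(nrow(segment_genes(mk(6, 1e5, 9e5))), 1L)
  # non-adjacent bins stay separate segments
  g2 <- rbind(mk(7, 1e5, 9e5, pre = "a"), mk(7, 4.1e6, 4.9e6, pre = "b"))
  expect_equal(nrow(segment_genes(g2)), 2L)
  # midpoint decides the bin
  gmid <- data.frame(gene_id = "m", chrom = "c", start = 999000L,
                     end = 1003000L, stringsAsFactors = FALSE)
  seg2 <- segment_genes(gmid, min_genes = 0)
  expect_equal(c(seg2$start, seg2$end), c(1000001, 2e6))  # midpoint 1001000 -> second bin
})
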