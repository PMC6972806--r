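# Sliding-window scan between two blooming-time groups and reduction of the
# joint 5%-tail windows to candidate selective-sweep regions.

#' log2 diversity ratio between groups
#'
#' `log2(pi_high / pi_low)`. A sweep in the low group collapses `pi_low`, so
#' candidate regions show large positive values. `pi_low = 0` with
#' `pi_high > 0` gives `+Inf` (always in the right tail); both zero gives `NA`
#' (window unusable).
#'
#' @param pi_high,pi_low per-bp nucleotide diversity of the high (late) and
#'   low (early) blooming group. Vectorized.
#' @return log2 ratio.
#' @export
log2_ratio <- function(pi_high, pi_low) {
  if (any(pi_high < 0, na.rm = TRUE) || any(pi_low < 0, na.rm = TRUE)) {
    stop("negative nucleotide diversity")
  }
  out <- log2(pi_high / pi_low)
  out[pi_high == 0 & pi_low == 0] <- NA_real_
  out
}

#' Genome-wide sliding-window scan
#'
#' Computes, for every 50-kb/10-kb (by default) window on every chromosome:
#' per-group nucleotide diversity, Watterson's theta over the pooled contrast
#' samples, Weir-Cockerham F_ST between the groups, and the log2 pi-ratio
#' (high/low). Windows with fewer than `min_snps` usable segregating sites,
#' or with no computable F_ST or ratio, are flagged unusable and excluded
#' from threshold estimation downstream.
#'
#' Sites missing in more than `max_group_missing` of a group's samples are
#' excluded from that group's diversity; F_ST and the SNP count use sites
#' passing the rule in both groups.
#'
#' @param x a [genotype_matrix()].
#' @param sample_table data.frame from [read_sample_table()].
#' @param group_high,group_low blooming-group labels for the contrast
#'   (defaults "late" / "early"; the mid group is not used by the scan).
#' @param window,step window span and slide step in bp.
#' @param min_snps minimum usable segregating sites per window (default 10).
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the last SNP position per chromosome.
#' @param estimator F_ST estimator, "wc" or "hudson".
#' @param max_group_missing per-group missingness ceiling per site.
#' @return data.frame with one row per window: chrom, start, end, n_snps,
#'   pi_high, pi_low, theta_w, fst, log2_ratio, usable.
#' @export
scan_windows <- function(x, sample_table, group_high = "late",
                         group_low = "early", window = 50000L, step = 10000L,
                         min_snps = 10L, chrom_lengths = NULL,
                         estimator = c("wc", "hudson"),
                         max_group_missing = 0.5) {
  estimator <- match.arg(estimator)
  hi <- sample_table$sample[sample_table$group == group_high]
  lo <- sample_table$sample[sample_table$group == group_low]
  if (length(hi) < 2L || length(lo) < 2L) {
    stop("need >= 2 samples in each contrast group")
  }
  hi <- intersect(hi, sample_ids(x))
  lo <- intersect(lo, sample_ids(x))
  n_hap <- 2L * (length(hi) + length(lo))
  a_n1 <- harmonic_number(n_hap - 1L)

  per_chrom <- lapply(unique(x$chrom), function(ch) {
    idx <- which(x$chrom == ch)
    pos <- x$pos[idx]
    chlen <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      as.integer(chrom_lengths[[ch]])
    } else max(pos)
    sub <- subset_matrix(x, idx)
    sh <- site_summary(sub, hi)
    sl <- site_summary(sub, lo)
    ok_h <- (1 - sh$n_genotyped / length(hi)) <= max_group_missing & sh$n_alleles >= 2L
    ok_l <- (1 - sl$n_genotyped / length(lo)) <= max_group_missing & sl$n_alleles >= 2L
    ok_both <- ok_h & ok_l

    pi_term <- function(s, ok) {
      v <- ifelse(ok & s$n_alleles > 1L,
                  s$n_alleles / (s$n_alleles - 1) * 2 * s$p * (1 - s$p), 0)
      v[is.na(v)] <- 0
      v
    }
    contrib_h <- pi_term(sh, ok_h)
    contrib_l <- pi_term(sl, ok_l)
    # pooled-frequency segregation over the contrast samples
    p_all <- (sh$p * sh$n_alleles + sl$p * sl$n_alleles) /
      pmax(sh$n_alleles + sl$n_alleles, 1L)
    seg <- as.numeric(ok_both & p_all > 0 & p_all < 1)
    if (estimator == "wc") {
      comp <- wc_site_components(
        sh$n_genotyped, sh$p, sh$n_het / pmax(sh$n_genotyped, 1L),
        sl$n_genotyped, sl$p, sl$n_het / pmax(sl$n_genotyped, 1L))
      num_site <- comp$a
      den_site <- comp$a + comp$b + comp$c
    } else {
      comp <- hudson_site_components(sh$n_alleles, sh$p, sl$n_alleles, sl$p)
      num_site <- comp$num
      den_site <- comp$den
    }
    num_site[!ok_both | is.na(num_site)] <- 0
    den_site[!ok_both | is.na(den_site)] <- 0

    cums <- function(v) c(0, cumsum(v))
    Ch <- cums(contrib_h); Cl <- cums(contrib_l); Cs <- cums(seg)
    Cn <- cums(num_site); Cd <- cums(den_site)
    w <- window_iter(chlen, window, step)
    i1 <- findInterval(w$start - 1L, pos) + 1L
    i2 <- findInterval(w$end, pos)
    wsum <- function(C) C[i2 + 1L] - C[i1]
    span <- w$end - w$start + 1
    pi_h <- wsum(Ch) / span
    pi_l <- wsum(Cl) / span
    S <- wsum(Cs)
    den <- wsum(Cd)
    fst <- ifelse(den > 0, wsum(Cn) / den, NA_real_)
    data.frame(chrom = ch, start = w$start, end = w$end,
               n_snps = as.integer(S),
               pi_high = pi_h, pi_low = pi_l,
               theta_w = S / a_n1 / span, fst = fst,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  out$log2_ratio <- log2_ratio(out$pi_high, out$pi_low)
  out$usable <- out$n_snps >= min_snps & !is.na(out$fst) & !is.na(out$log2_ratio)
  rownames(out) <- NULL
  out
}

#' Empirical-tail significance thresholds
#'
#' Nearest-rank upper-tail cutoffs from the usable windows: each cut is the
#' order statistic at rank `ceiling((1 - quantile) * n)` of that statistic's
#' empirical distribution; a window is significant iff its F_ST *and* its
#' log2 ratio strictly exceed their cuts (joint 5% right tails by default).
#'
#' @param windows data.frame from [scan_windows()].
#' @param quantile right-tail fraction (default 0.05).
#' @param min_windows minimum usable windows required (default 20).
#' @return list with fst_cut, ratio_cut, quantile, n_usable.
#' @export
sweep_thresholds <- function(windows, quantile = 0.05, min_windows = 20L) {
  u <- windows[windows$usable, , drop = FALSE]
  n <- nrow(u)
  if (n < min_windows) {
    stop("only ", n, " usable windows; need >= ", min_windows)
  }
  cut_at <- function(v) {
    v <- sort(v[is.finite(v)])
    v[min(ceiling((1 - quantile) * length(v)), length(v))]
  }
  list(fst_cut = cut_at(u$fst), ratio_cut = cut_at(u$log2_ratio),
       quantile = quantile, n_usable = n)
}

#' Flag jointly significant windows
#'
#' @param windows data.frame from [scan_windows()].
#' @param thresholds list from [sweep_thresholds()].
#' @return logical vector over the rows of `windows`.
#' @export
significant_windows <- function(windows, thresholds) {
  windows$usable &
    !is.na(windows$fst) & windows$fst > thresholds$fst_cut &
    !is.na(windows$log2_ratio) & windows$log2_ratio > thresholds$ratio_cut
}

#' Merge significant windows into sweep regions
#'
#' Overlapping or book-ended significant windows on a chromosome are merged
#' into maximal runs; each region records how many significant windows it
#' absorbed. Regions shorter than `min_length` bp are dropped. Idempotent:
#' re-merging the output changes nothing.
#'
#' @param sig_windows data.frame of significant windows (chrom, start, end).
#' @param min_length minimum region length in bp (default 0).
#' @return data.frame: chrom, start, end, length, n_windows, sorted by
#'   chromosome then start.
#' @export
call_regions <- function(sig_windows, min_length = 0L) {
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      length = integer(), n_windows = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(sig_windows) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(sig_windows$chrom,
                               IRanges::IRanges(sig_windows$start, sig_windows$end))
  red <- GenomicRanges::reduce(gr)  # merges overlapping and adjacent
  hits <- GenomicRanges::countOverlaps(red, gr)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red),
    end = GenomicRanges::end(red),
    length = GenomicRanges::width(red),
    n_windows = as.integer(hits),
    stringsAsFactors = FALSE
  )
  out <- out[out$length >= min_length, , drop = FALSE]
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize called sweep regions
#'
#' @param regions data.frame from [call_regions()].
#' @param genome_size genome length in bp (default 280 Mb).
#' @return data.frame with n_regions, total_bp, mean_bp, max_bp, pct_genome.
#' @export
region_summary <- function(regions, genome_size = 280e6) {
  if (genome_size <= 0) stop("genome_size must be positive")
  if (nrow(regions) == 0L) stop("no regions to summarize")
  data.frame(
    n_regions = nrow(regions),
    total_bp = sum(regions$length),
    mean_bp = mean(regions$length),
    max_bp = max(regions$length),
    pct_genome = 100 * sum(regions$length) / genome_size
  )
}

#' Genes overlapping sweep regions
#'
#' A gene is assigned to a region iff their closed 1-based intervals
#' intersect; book-ended intervals (gene starting one base past a region end)
#' do not.
#'
#' @param regions data.frame with chrom, start, end.
#' @param gene_table data.frame from [read_gff()].
#' @return `regions` with list-column `genes` (character gene ids) and
#'   `n_genes`.
#' @export
genes_in_regions <- function(regions, gene_table) {
  genes <- rep(list(character()), nrow(regions))
  if (nrow(regions) > 0L && nrow(gene_table) > 0L) {
    gr_r <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start, regions$end))
    gr_g <- GenomicRanges::GRanges(gene_table$chrom,
                                   IRanges::IRanges(gene_table$start, gene_table$end))
    hits <- GenomicRanges::findOverlaps(gr_r, gr_g)
    for (i in seq_len(nrow(regions))) {
      genes[[i]] <- gene_table$gene_id[S4Vectors::subjectHits(hits)[
        S4Vectors::queryHits(hits) == i]]
    }
  }
  regions$genes <- genes
  regions$n_genes <- lengths(genes)
  regions
}

#' Group sweep genes into 1-Mb segments
#'
#' The genome is partitioned into non-overlapping `bin`-bp bins
#' ([1, 1e6], [1e6+1, 2e6], ...); each sweep gene is assigned to the bin
#' containing its midpoint; runs of adjacent non-empty bins are merged into
#' segments; segments containing no more than `min_genes` genes are
#' discarded. The surviving gene sets are the input an ontology-enrichment
#' step would take.
#'
#' @param sweep_genes data.frame with gene_id, chrom, start, end for the
#'   genes found in sweep regions.
#' @param bin bin width in bp (default 1e6).
#' @param min_genes discard segments with <= this many genes (default 5).
#' @return data.frame: chrom, start, end, n_genes, gene_ids (comma-joined).
#' @export
segment_genes <- function(sweep_genes, bin = 1e6, min_genes = 5L) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_genes = integer(), gene_ids = character(),
                      stringsAsFactors = FALSE)
  if (nrow(sweep_genes) == 0L) return(empty)
  mid <- floor((sweep_genes$start + sweep_genes$end) / 2)
  bin_idx <- ceiling(mid / bin)
  out <- list()
  for (ch in unique(sweep_genes$chrom)) {
    sel <- sweep_genes$chrom == ch
    bins <- sort(unique(bin_idx[sel]))
    run <- cumsum(c(1L, diff(bins) > 1L))  # adjacent non-empty bins share a run
    for (r in unique(run)) {
      rb <- bins[run == r]
      in_seg <- sel & bin_idx %in% rb
      if (sum(in_seg) > min_genes) {
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = (min(rb) - 1) * bin + 1, end = max(rb) * bin,
          n_genes = sum(in_seg),
          gene_ids = paste(sweep_genes$gene_id[in_seg], collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty)
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}
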