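# End-to-end drivers over the module functions, and the stable TSV reports
# they write. A thin command-line wrapper over these lives in
# inst/scripts/sweepscan.R.

#' Pipeline configuration with documented defaults
#'
#' Collects every tunable of the scan/LD/association stages in one list so
#' runs are auditable. Defaults are the study's operating point: 50-kb
#' windows sliding by 10 kb, joint 5% right tails, BH FDR 0.01, 2-kb
#' gene-assignment flank, and a 280-Mb genome for coverage percentages.
#'
#' @param window,step scan window and step (bp).
#' @param quantile right-tail fraction for both scan statistics.
#' @param min_snps minimum usable SNPs per window.
#' @param min_length minimum sweep-region length (bp, default 0).
#' @param genome_size genome length for coverage percentage (default 280 Mb).
#' @param ld_max_dist,ld_bin_width LD pair cap and bin width (bp).
#' @param fdr BH discovery threshold (default 0.01).
#' @param flank SNP-to-gene assignment flank (bp, default 2000).
#' @param estimator F_ST estimator for the scan.
#' @param seed RNG seed for any stochastic stage.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(window = 50000L, step = 10000L, quantile = 0.05,
                            min_snps = 10L, min_length = 0L,
                            genome_size = 280e6, ld_max_dist = 500000L,
                            ld_bin_width = 10000L, fdr = 0.01, flank = 2000L,
                            estimator = "wc", seed = 1L) {
  stopifnot(quantile >= 0, quantile < 1, fdr > 0, fdr < 1, genome_size > 0)
  structure(list(window = window, step = step, quantile = quantile,
                 min_snps = min_snps, min_length = min_length,
                 genome_size = genome_size, ld_max_dist = ld_max_dist,
                 ld_bin_width = ld_bin_width, fdr = fdr, flank = flank,
                 estimator = estimator, seed = seed),
            class = "pipeline_config")
}

#' Per-sample diversity report
#'
#' One row per sample in the layout Sites / Polymorphic / Invariant /
#' HetObs / pi / F_IS, with frequencies printed to 6 decimals. Recomputing
#' HetObs from the report's own counts reproduces the printed value.
#'
#' @param x a [genotype_matrix()].
#' @param path optional TSV output path.
#' @return data.frame report (invisibly writes `path` when given).
#' @export
diversity_report <- function(x, path = NULL) {
  tab <- diversity_table(x)
  out <- data.frame(
    sample = tab$sample,
    sites = tab$n_sites,
    polymorphic = tab$n_polymorphic,
    invariant = tab$n_invariant,
    het_obs = sprintf("%.6f", tab$het_obs),
    pi = sprintf("%.6f", tab$pi_ind),
    f_is = ifelse(is.na(tab$f_is), "NA", format(tab$f_is)),
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write_tsv_report(out, path)
  out
}

#' Run the full sweep scan
#'
#' Window statistics, empirical-tail thresholds, region calling, gene
#' overlap, the 1-Mb segmentation rule, and a region summary — with every
#' applied threshold echoed in the returned object. When `outdir` is given,
#' writes windows.tsv, regions.tsv, regions.bed, segments.tsv and
#' summary.tsv.
#'
#' @param x a [genotype_matrix()].
#' @param sample_table data.frame from [read_sample_table()].
#' @param gene_table optional data.frame from [read_gff()].
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param chrom_lengths optional named chromosome lengths.
#' @return list: windows, thresholds, regions (with genes when annotation is
#'   given), segments, summary.
#' @export
run_sweep_scan <- function(x, sample_table, gene_table = NULL,
                           config = pipeline_config(), outdir = NULL,
                           chrom_lengths = NULL) {
  windows <- scan_windows(x, sample_table,
                          window = config$window, step = config$step,
                          min_snps = config$min_snps,
                          chrom_lengths = chrom_lengths,
                          estimator = config$estimator)
  th <- sweep_thresholds(windows, quantile = config$quantile)
  sig <- significant_windows(windows, th)
  regions <- call_regions(windows[sig, c("chrom", "start", "end")],
                          min_length = config$min_length)
  segments <- NULL
  if (!is.null(gene_table) && nrow(regions) > 0L) {
    regions <- genes_in_regions(regions, gene_table)
    sweep_gene_ids <- unique(unlist(regions$genes))
    segments <- segment_genes(
      gene_table[gene_table$gene_id %in% sweep_gene_ids, , drop = FALSE])
  }
  summary <- if (nrow(regions) > 0L) {
    region_summary(regions, genome_size = config$genome_size)
  } else NULL
  message(sprintf(
    "sweep scan: %d/%d usable windows; F_ST cut %.4f, log2-ratio cut %.4f; %d significant windows -> %d regions",
    th$n_usable, nrow(windows), th$fst_cut, th$ratio_cut, sum(sig),
    nrow(regions)))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_report(windows, file.path(outdir, "windows.tsv"))
    reg_out <- regions
    reg_out$genes <- NULL
    write_tsv_report(reg_out, file.path(outdir, "regions.tsv"))
    write_regions_bed(regions, file.path(outdir, "regions.bed"))
    if (!is.null(segments)) {
      write_tsv_report(segments, file.path(outdir, "segments.tsv"))
    }
    if (!is.null(summary)) {
      write_tsv_report(summary, file.path(outdir, "summary.tsv"))
    }
  }
  list(windows = windows, thresholds = th, regions = regions,
       segments = segments, summary = summary)
}

#' Run the association stage
#'
#' Quality filters, kinship, the EMMAX-style mixed model on the ordinal
#' blooming phenotype, BH adjustment, and gene assignment for the
#' discoveries.
#'
#' @param x a [genotype_matrix()].
#' @param sample_table data.frame from [read_sample_table()].
#' @param gene_table optional gene annotation for SNP-to-gene assignment.
#' @param config a [pipeline_config()].
#' @param phenotype optional numeric phenotype; defaults to the ordinal
#'   blooming code early=0, mid=1, late=2.
#' @param outdir optional output directory (writes assoc.tsv + filter.tsv).
#' @return list: assoc (per-SNP table with q-values and significance flag),
#'   filter_report, delta (fitted variance ratio).
#' @export
run_association <- function(x, sample_table, gene_table = NULL,
                            config = pipeline_config(), phenotype = NULL,
                            outdir = NULL) {
  flt <- filter_snps(x)
  xf <- flt$matrix
  st <- sample_table[sample_table$sample %in% sample_ids(xf), , drop = FALSE]
  st <- st[match(sample_ids(xf), st$sample), , drop = FALSE]
  if (is.null(phenotype)) {
    phenotype <- unname(c(early = 0, mid = 1, late = 2)[st$group])
  }
  K <- kinship(xf)
  assoc <- lmm_assoc(xf, phenotype, K)
  assoc$q_value <- bh_adjust(assoc$p_value)
  assoc$significant <- !is.na(assoc$q_value) & assoc$q_value <= config$fdr
  if (!is.null(gene_table)) {
    assoc <- assign_genes(assoc, gene_table, flank = config$flank)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_report(assoc, file.path(outdir, "assoc.tsv"))
    write_tsv_report(flt$report, file.path(outdir, "filter.tsv"))
  }
  list(assoc = assoc, filter_report = flt$report,
       delta = attr(assoc, "delta"))
}

#' Published worked-example tables
#'
#' Loads the small plain-text tables shipped with the package: the reported
#' per-cultivar diversity counts (`"diversity_counts"`), the reported sweep
#' region coordinates (`"sweep_regions"`), and the per-cultivar CDS variant
#' counts (`"cds_variant_counts"`) for the 19-accession P. mume panel. These
#' serve as worked-example inputs for the column arithmetic the package
#' automates.
#'
#' @param which one of "diversity_counts", "sweep_regions",
#'   "cds_variant_counts".
#' @return data.frame.
#' @export
published_table <- function(which = c("diversity_counts", "sweep_regions",
                                      "cds_variant_counts")) {
  which <- match.arg(which)
  f <- c(diversity_counts = "mume_diversity_counts.tsv",
         sweep_regions = "mume_sweep_regions.tsv",
         cds_variant_counts = "mume_cds_variant_counts.tsv")[[which]]
  path <- system.file("extdata", f, package = "bloomsweep", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
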