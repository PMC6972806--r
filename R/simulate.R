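# Balding-Nichols genotype simulator with planted sweeps and an optional
# causal variant. Defaults mirror the study design the pipeline targets: a
# resequenced panel of ~19 diploid accessions in three blooming-time groups
# (6 early / 5 mid / 8 late) with modest background differentiation.

#' Simulation configuration
#'
#' @param n_per_group named integer vector `c(early=, mid=, late=)` of
#'   samples per blooming group (defaults 6/5/8, the panel structure the
#'   pipeline assumes).
#' @param n_chrom number of chromosomes (default 2).
#' @param chrom_length chromosome length in bp (default 5e6).
#' @param snp_density expected SNPs per bp (default 0.002, i.e. one SNP per
#'   500 bp).
#' @param F Balding-Nichols differentiation between the early and late
#'   groups, 0 < F < 1 (default 0.1).
#' @param sweep_intervals data.frame with columns chrom, start, end,
#'   intensity — intervals where the swept group's allele frequencies are
#'   pushed to fixation with probability `intensity` per site (default none).
#' @param swept_group group whose diversity collapses inside sweep intervals
#'   (default "early": the low-diversity side of the high/low ratio).
#' @param causal_snp optional list(chrom=, pos=, effect=) for the phenotype
#'   model; the position must land on a simulated SNP.
#' @param noise_sd phenotype noise standard deviation when a causal effect is
#'   active (default 0.1).
#' @param n_genes genes placed uniformly over the genome for annotation
#'   fixtures (default 200).
#' @param seed RNG seed; fully determines every output.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_per_group = c(early = 6L, mid = 5L, late = 8L),
                       n_chrom = 2L, chrom_length = 5e6, snp_density = 0.002,
                       F = 0.1, sweep_intervals = NULL, swept_group = "early",
                       causal_snp = NULL, noise_sd = 0.1, n_genes = 200L,
                       seed = 1L) {
  if (F <= 0 || F >= 1) stop("F must lie strictly between 0 and 1")
  if (!all(c("early", "mid", "late") %in% names(n_per_group))) {
    stop("n_per_group needs named entries early, mid, late")
  }
  if (!is.null(sweep_intervals)) {
    if (any(sweep_intervals$start < 1) || any(sweep_intervals$end > chrom_length)) {
      stop("sweep intervals must lie within chromosome bounds")
    }
  }
  structure(list(n_per_group = n_per_group, n_chrom = as.integer(n_chrom),
                 chrom_length = chrom_length, snp_density = snp_density,
                 F = F, sweep_intervals = sweep_intervals,
                 swept_group = swept_group, causal_snp = causal_snp,
                 noise_sd = noise_sd, n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a two-population genotype panel (Balding-Nichols)
#'
#' Per site: ancestral frequency `p ~ U(0.05, 0.95)`; the early and late
#' group frequencies are drawn independently from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)` — mean p, variance `F*p*(1-p)` — so the
#' expected Weir-Cockerham F_ST between them is ~F. The mid group is an
#' equal-weight frequency mixture of the two extremes. Genotypes are
#' `Binomial(2, p_g)` per sample. Inside each sweep interval the swept
#' group's frequency is replaced, with probability `intensity` per site, by a
#' fixed allele (1 with probability p, else 0), collapsing that group's
#' diversity and inflating local F_ST. Fully deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list: `matrix` (a [genotype_matrix()]) and `samples` (sample
#'   table with sample, group, region columns).
#' @export
simulate_genotypes <- function(config) {
  set.seed(config$seed)
  npg <- config$n_per_group
  ids <- c(sprintf("E%02d", seq_len(npg[["early"]])),
           sprintf("M%02d", seq_len(npg[["mid"]])),
           sprintf("L%02d", seq_len(npg[["late"]])))
  groups <- rep(c("early", "mid", "late"), npg[c("early", "mid", "late")])
  chrom <- character(0); pos <- integer(0); dos <- list()
  for (ci in seq_len(config$n_chrom)) {
    ch <- paste0("chr", ci)
    m <- round(config$chrom_length * config$snp_density)
    cpos <- sort(sample.int(config$chrom_length, m))
    p_anc <- runif(m, 0.05, 0.95)
    a <- p_anc * (1 - config$F) / config$F
    b <- (1 - p_anc) * (1 - config$F) / config$F
    p_g <- list(early = rbeta(m, a, b), late = rbeta(m, a, b))
    sw <- config$sweep_intervals
    if (!is.null(sw)) {
      for (k in which(sw$chrom == ch)) {
        in_iv <- cpos >= sw$start[k] & cpos <= sw$end[k]
        hit <- in_iv & runif(m) < sw$intensity[k]
        p_g[[config$swept_group]][hit] <-
          as.numeric(runif(sum(hit)) < p_anc[hit])
      }
    }
    p_g$mid <- (p_g$early + p_g$late) / 2
    d <- matrix(NA_integer_, nrow = m, ncol = length(ids),
                dimnames = list(NULL, ids))
    for (g in c("early", "mid", "late")) {
      cols <- which(groups == g)
      d[, cols] <- rbinom(m * length(cols), 2L, rep(p_g[[g]], length(cols)))
    }
    chrom <- c(chrom, rep(ch, m)); pos <- c(pos, cpos)
    dos[[ci]] <- d
  }
  x <- genotype_matrix(do.call(rbind, dos), chrom, pos)
  samples <- data.frame(sample = ids, group = groups,
                        region = "simulated", stringsAsFactors = FALSE)
  list(matrix = x, samples = samples)
}

#' Simulate the ordinal blooming phenotype
#'
#' Base phenotype is the ordinal group code (early = 0, mid = 1, late = 2).
#' With a causal SNP of nonzero effect, `y = code + effect * dosage +
#' N(0, noise_sd)`; with no causal SNP (or a zero effect) the phenotype is
#' the group code exactly.
#'
#' @param samples sample table aligned with `x`'s columns.
#' @param x a [genotype_matrix()].
#' @param causal_snp optional list(chrom=, pos=, effect=).
#' @param noise_sd Gaussian noise sd (default 0.1).
#' @param seed RNG seed for the noise.
#' @return numeric phenotype vector in `samples` order.
#' @export
simulate_phenotype <- function(samples, x, causal_snp = NULL, noise_sd = 0.1,
                               seed = 1L) {
  code <- c(early = 0, mid = 1, late = 2)[samples$group]
  names(code) <- samples$sample
  if (is.null(causal_snp) || causal_snp$effect == 0) return(unname(code))
  i <- which(x$chrom == causal_snp$chrom & x$pos == causal_snp$pos)
  if (length(i) != 1L) stop("causal SNP position not present in the matrix")
  g <- x$dosage[i, samples$sample]
  g[is.na(g)] <- mean(g, na.rm = TRUE)
  set.seed(seed)
  unname(code + causal_snp$effect * g + rnorm(length(code), 0, noise_sd))
}

#' Write simulator fixtures to disk
#'
#' Emits the exact formats the ingestion layer reads — a VCF, a GFF3 with
#' `n_genes` uniformly placed genes, the sample table TSV — plus a truth TSV
#' recording the planted sweep intervals and causal SNP for test assertions.
#' Byte-identical across runs with the same config.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if absent).
#' @return named list of file paths (vcf, gff, samples, truth) plus the
#'   in-memory `matrix`, `sample_table` and `genes`.
#' @export
emit_fixtures <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genotypes(config)
  # gene placement continues the generator's seeded stream
  genes <- do.call(rbind, lapply(seq_len(config$n_chrom), function(ci) {
    ng <- config$n_genes %/% config$n_chrom +
      as.integer(ci <= config$n_genes %% config$n_chrom)
    start <- sort(sample.int(config$chrom_length - 10000L, ng))
    len <- sample(2000:8000, ng, replace = TRUE)
    data.frame(gene_id = sprintf("gene_c%d_%04d", ci, seq_len(ng)),
               chrom = paste0("chr", ci), start = start,
               end = pmin(start + len, config$chrom_length),
               strand = sample(c("+", "-"), ng, replace = TRUE),
               stringsAsFactors = FALSE)
  }))
  paths <- list(vcf = file.path(outdir, "panel.vcf"),
                gff = file.path(outdir, "genes.gff3"),
                samples = file.path(outdir, "samples.tsv"),
                truth = file.path(outdir, "truth.tsv"))
  write_vcf(sim$matrix, paths$vcf)
  writeLines(c("##gff-version 3",
               paste(genes$chrom, "bloomsweep_sim", "gene", genes$start,
                     genes$end, ".", genes$strand, ".",
                     paste0("ID=", genes$gene_id), sep = "\t")),
             paths$gff)
  st <- sim$samples
  names(st) <- c("sample", "group", "region")
  write_tsv_report(st, paths$samples)
  truth <- if (!is.null(config$sweep_intervals)) {
    data.frame(kind = "sweep", chrom = config$sweep_intervals$chrom,
               start = config$sweep_intervals$start,
               end = config$sweep_intervals$end,
               value = config$sweep_intervals$intensity,
               stringsAsFactors = FALSE)
  } else {
    data.frame(kind = character(), chrom = character(), start = numeric(),
               end = numeric(), value = numeric(), stringsAsFactors = FALSE)
  }
  if (!is.null(config$causal_snp)) {
    truth <- rbind(truth, data.frame(
      kind = "causal_snp", chrom = config$causal_snp$chrom,
      start = config$causal_snp$pos, end = config$causal_snp$pos,
      value = config$causal_snp$effect, stringsAsFactors = FALSE))
  }
  write_tsv_report(truth, paths$truth)
  c(paths, list(matrix = sim$matrix, sample_table = sim$samples, genes = genes))
}
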