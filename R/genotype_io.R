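# VCF / GFF3 / sample-table ingestion and BED/TSV serialization.
# Parsing of the standard formats is delegated to vcfR and rtracklayer; this
# file only adapts their objects to the package's containers and enforces the
# pipeline's entry contracts (biallelic SNPs only, half-calls missing).

#' Read a multi-sample VCF into a genotype matrix
#'
#' Keeps biallelic SNP records only; multiallelic or non-SNP records are
#' skipped and counted in a message. Genotypes are collapsed to alternate
#' allele dosage from the GT field (phase ignored); any genotype containing a
#' missing allele, including half-calls such as `./1`, is stored as `NA`.
#'
#' @param path VCF 4.x file (plain or bgzipped) with a GT FORMAT field.
#' @param verbose message the skipped-record count (default TRUE).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path, verbose = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  n_in <- nrow(fix)
  if (n_in == 0L) stop("VCF contains no variant records: ", path)
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  keep <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_skip <- sum(!keep)
  if (n_skip > 0L && verbose) {
    message("read_vcf: skipped ", n_skip, " multiallelic/non-SNP record(s)")
  }
  if (!any(keep)) stop("no usable biallelic SNP records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[keep, , drop = FALSE]
  dosage <- apply(gt, 2L, gt_to_dosage)
  if (is.null(dim(dosage))) dosage <- matrix(dosage, nrow = 1, dimnames = list(NULL, colnames(gt)))
  genotype_matrix(dosage,
                  chrom = fix[keep, "CHROM"],
                  pos = as.integer(fix[keep, "POS"]),
                  ref = ref[keep], alt = alt[keep])
}

# "0/1", "1|1", ".", "./.", "./1" -> dosage; any missing allele => NA
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1L, 1L)
  a2 <- substr(gt, 3L, 3L)
  a2[a2 == ""] <- "."  # haploid-style single-allele entries treated as missing
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(gt)] <- NA_integer_
  as.integer(d)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' Deterministic serializer used by the simulator and for round-trip tests:
#' identical inputs produce byte-identical files.
#'
#' @param x a [genotype_matrix()].
#' @param path output file path.
#' @param source_tag value for the `##source=` header line.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, source_tag = "bloomsweep") {
  d <- x$dosage
  gt <- matrix(".(.)", nrow = nrow(d), ncol = ncol(d))
  gt[] <- c("0/0", "0/1", "1/1")[d + 1L]
  gt[is.na(d)] <- "./."
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=", source_tag),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_ids(x)), collapse = "\t")
  )
  body <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Extracts features of type `gene` into a gene table with 1-based inclusive
#' coordinates, as in GFF3. Records whose end precedes their start are dropped
#' with a warning (rtracklayer refuses whole files containing them, so the raw
#' lines are pre-screened).
#'
#' @param path GFF3 file.
#' @return data.frame with columns gene_id, chrom, start, end, strand.
#' @export
read_gff <- function(path) {
  lines <- readLines(path)
  feat <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(feat)) {
    parts <- strsplit(feat, "\t", fixed = TRUE)
    ok <- vapply(parts, function(p) {
      length(p) >= 9L && !is.na(suppressWarnings(as.numeric(p[4]))) &&
        suppressWarnings(as.numeric(p[5]) >= as.numeric(p[4]))
    }, logical(1))
    if (any(!ok)) {
      warning("read_gff: rejected ", sum(!ok), " malformed record(s) (end < start or short line)")
      tmp <- tempfile(fileext = ".gff3")
      on.exit(unlink(tmp), add = TRUE)
      writeLines(c(lines[startsWith(lines, "#")], feat[ok]), tmp)
      path <- tmp
    }
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L) {
    warning("read_gff: no gene features found in ", path)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- gr$ID
  if (is.null(ids)) ids <- paste0("gene", seq_along(gr))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicate gene ids in ", path)
  out <- data.frame(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
  out$strand[out$strand == "*"] <- "."
  rownames(out) <- NULL
  out
}

#' Read the sample-to-blooming-group table
#'
#' Tab-separated with header `sample\tgroup\tregion`; group must be one of
#' early/mid/late.
#'
#' @param path TSV file.
#' @return data.frame with columns sample, group, region.
#' @export
read_sample_table <- function(path) {
  st <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("sample", "group")
  if (!all(need %in% names(st))) {
    stop("sample table must have columns 'sample' and 'group'")
  }
  if (!"region" %in% names(st)) st$region <- NA_character_
  bad <- setdiff(unique(st$group), c("early", "mid", "late"))
  if (length(bad)) stop("unknown blooming group(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(st$sample)) stop("duplicate sample ids in sample table")
  st[, c("sample", "group", "region")]
}

#' Write sweep regions as BED
#'
#' Internal coordinates are 1-based inclusive; BED is 0-based half-open, so
#' `start_bed = start - 1`, `end_bed = end`. Output is sorted by chromosome
#' then start.
#'
#' @param regions data.frame with columns chrom, start, end (1-based inclusive).
#' @param path output BED path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- regions[order(regions$chrom, regions$start), , drop = FALSE]
  lines <- paste(regions$chrom, regions$start - 1L, regions$end, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a TSV report
#'
#' Fixed formatting (no quoting, no row names) so report files are stable
#' across runs and usable as golden files.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
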