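# Pairwise r^2 on unphased dosages (composite LD) and distance-binned decay.

#' Pairwise r-squared between two sites
#'
#' Squared Pearson correlation of the dosage vectors over samples non-missing
#' at both sites. Symmetric and invariant to flipping ref/alt coding at
#' either site. Returns `NA` if fewer than two complete samples remain or if
#' either site is monomorphic among them.
#'
#' @param dosage_a,dosage_b numeric dosage vectors (0/1/2/NA), same length.
#' @return r^2 in \[0, 1\], or NA.
#' @export
pair_r2 <- function(dosage_a, dosage_b) {
  ok <- !is.na(dosage_a) & !is.na(dosage_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- dosage_a[ok]; b <- dosage_b[ok]
  if (stats::var(a) == 0 || stats::var(b) == 0) return(NA_real_)
  stats::cor(a, b)^2
}

#' Linkage-disequilibrium decay curve
#'
#' Pools all intra-chromosomal SNP pairs separated by at most `max_dist` bp
#' into contiguous distance bins of `bin_width` bp and averages r^2 within
#' each bin. The half-decay distance is the smallest distance (linear
#' interpolation between adjacent bin midpoints) at which mean r^2 falls to
#' half the maximum bin mean; `NA` if that level is never reached.
#'
#' For large inputs, pairs can be subsampled (`max_pairs`, seeded) before
#' binning; with a fixed seed the curve is reproducible.
#'
#' @param x a [genotype_matrix()].
#' @param max_dist maximum pair separation in bp (default 500 kb).
#' @param bin_width distance-bin width in bp (default 10 kb).
#' @param max_pairs optional cap on the number of pairs (random subsample).
#' @param seed RNG seed used only when subsampling.
#' @return list of class `ld_curve`: `bins` (data.frame bin_start, bin_end,
#'   mid, n_pairs, mean_r2) and `half_decay_distance` (bp or NA).
#' @export
ld_curve <- function(x, max_dist = 500000L, bin_width = 10000L,
                     max_pairs = NULL, seed = 1L) {
  if (bin_width < 1L || max_dist < bin_width) stop("need max_dist >= bin_width >= 1")
  acc_a <- list(); acc_b <- list(); acc_d <- list(); k <- 0L
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    pos <- x$pos[idx]
    m <- length(idx)
    if (m < 2L) next
    for (i in seq_len(m - 1L)) {
      j_hi <- findInterval(pos[i] + max_dist, pos)
      if (j_hi > i) {
        j <- (i + 1L):j_hi
        k <- k + 1L
        acc_a[[k]] <- rep.int(idx[i], length(j))
        acc_b[[k]] <- idx[j]
        acc_d[[k]] <- pos[j] - pos[i]
      }
    }
  }
  if (k == 0L) stop("no SNP pairs within max_dist")
  i_a <- unlist(acc_a, use.names = FALSE)
  i_b <- unlist(acc_b, use.names = FALSE)
  dist <- unlist(acc_d, use.names = FALSE)
  if (!is.null(max_pairs) && length(dist) > max_pairs) {
    set.seed(seed)
    keep <- sample.int(length(dist), max_pairs)
    i_a <- i_a[keep]; i_b <- i_b[keep]; dist <- dist[keep]
  }
  r2 <- vapply(seq_along(dist), function(k) {
    pair_r2(x$dosage[i_a[k], ], x$dosage[i_b[k], ])
  }, numeric(1))
  bin <- pmin(ceiling(dist / bin_width), max_dist %/% bin_width)
  ok <- !is.na(r2)
  nb <- max_dist %/% bin_width
  n_pairs <- tabulate(bin[ok], nbins = nb)
  sums <- vapply(seq_len(nb), function(b) sum(r2[ok & bin == b]), numeric(1))
  bins <- data.frame(
    bin_start = (seq_len(nb) - 1L) * bin_width + 1L,
    bin_end = seq_len(nb) * bin_width,
    mid = (seq_len(nb) - 0.5) * bin_width,
    n_pairs = n_pairs,
    mean_r2 = ifelse(n_pairs > 0, sums / n_pairs, NA_real_)
  )
  structure(list(bins = bins,
                 half_decay_distance = half_decay(bins$mid, bins$mean_r2)),
            class = "ld_curve")
}

# smallest interpolated distance where the bin-mean curve drops to half its
# maximum; NA when never reached or with a single informative bin
half_decay <- function(mid, mean_r2) {
  ok <- !is.na(mean_r2)
  mid <- mid[ok]; y <- mean_r2[ok]
  if (length(y) < 2L) return(NA_real_)
  target <- max(y) / 2
  below <- which(y <= target)
  below <- below[below > which.max(y)]
  if (length(below) == 0L) return(NA_real_)
  j <- below[1]
  if (y[j] == target) return(mid[j])
  # interpolate between the previous (above-target) midpoint and this one
  i <- j - 1L
  mid[i] + (y[i] - target) / (y[i] - y[j]) * (mid[j] - mid[i])
}

#' @export
print.ld_curve <- function(x, ...) {
  used <- sum(x$bins$n_pairs)
  cat(sprintf("ld_curve: %d pairs in %d bins; half-decay distance: %s bp\n",
              used, nrow(x$bins),
              ifelse(is.na(x$half_decay_distance), "not reached",
                     format(round(x$half_decay_distance, 1)))))
  invisible(x)
}
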