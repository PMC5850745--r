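# Population-genetic summary statistics on genotype matrices.
# All statistics are frequency-based on non-missing calls; missing genotypes
# are never imputed.

# per-site allele bookkeeping for a column subset
site_counts <- function(calls) {
  miss <- is.na(calls)
  n_ind <- ncol(calls) - rowSums(miss)
  n <- 2 * n_ind                       # allele copies
  ac <- rowSums(calls, na.rm = TRUE)   # alt copies
  het <- rowSums(calls == 1L, na.rm = TRUE)
  p <- ifelse(n > 0, ac / n, NA_real_)
  # unbiased expected heterozygosity 2pq * n/(n-1), defined for n >= 2
  h <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
  list(n_ind = n_ind, n = n, ac = ac, het = het, p = p, h = h,
       seg = !is.na(p) & ac > 0 & ac < n)
}

# Tajima's D from precomputed site counts (shared by tajimas_d and
# sumstat_vector); returns NA silently when undefined
tajima_d_from_counts <- function(sc) {
  use <- sc$n >= 2
  S <- sum(sc$seg[use])
  if (S == 0) return(NA_real_)
  n <- round(stats::median(sc$n[use]))
  if (n < 2) return(NA_real_)
  k <- tajima_constants(n)
  (sum(sc$h[use]) - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
}

# Weir-Cockerham numerator/denominator sums from two pops' site counts
wc_from_counts <- function(scA, scB) {
  n1 <- scA$n_ind; n2 <- scB$n_ind
  ok <- n1 >= 1 & n2 >= 1 & (n1 + n2) >= 3
  p1 <- ifelse(n1 > 0, scA$ac / (2 * n1), 0)
  p2 <- ifelse(n2 > 0, scB$ac / (2 * n2), 0)
  h1 <- ifelse(n1 > 0, scA$het / n1, 0)
  h2 <- ifelse(n2 > 0, scB$het / n2, 0)
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  poly <- ok & pbar > 0 & pbar < 1
  list(num = sum(a[poly]), den = sum((a + b + cc)[poly]))
}

#' Nucleotide diversity
#'
#' Average pairwise difference per site within one population:
#' `sum_sites 2*p*q*n/(n-1) / span`, with per-site sample size `n` (allele
#' copies, missing calls excluded). For genome scans `span` is the bin
#' width in bp; for simulated SNP loci it is the number of assayed sites.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label.
#' @param span normalising span (bp or site count); default = number of
#'   assayed sites.
#' @return Per-site nucleotide diversity (>= 0).
#' @export
nucleotide_diversity <- function(gm, pop, span = nrow(gm$calls)) {
  if (!is.numeric(span) || span <= 0) stop("span must be > 0")
  idx <- pop_index(gm, pop)
  sc <- site_counts(gm$calls[, idx, drop = FALSE])
  sum(sc$h[sc$n >= 2]) / span
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' Standardised difference between the pairwise-diversity and
#' segregating-sites estimators of theta:
#' `D = (pi_total - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the standard
#' constants. Per-site sample sizes are used for the frequencies; the
#' harmonic constants use the median per-site number of allele copies
#' (documented approximation for missing data).
#'
#' @inheritParams nucleotide_diversity
#' @return Tajima's D, or `NA` with a warning when the population has no
#'   segregating sites.
#' @export
tajimas_d <- function(gm, pop) {
  idx <- pop_index(gm, pop)
  sc <- site_counts(gm$calls[, idx, drop = FALSE])
  d <- tajima_d_from_counts(sc)
  if (is.na(d))
    warning("Tajima's D undefined: no segregating sites in ", pop)
  d
}

#' Weir-Cockerham Fst
#'
#' Multi-locus Weir & Cockerham (1984) theta for two populations: the ratio
#' of summed among-population variance components `a` to summed total
#' components `a + b + c` across sites (ratio of sums, not mean of ratios).
#' Observed heterozygosity per site enters through the `b` and `c`
#' components; sites with fewer than one genotyped individual in either
#' population, or fewer than three overall, are excluded.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB population labels.
#' @return Theta estimate in \[-1, 1\], or `NA` when no site is polymorphic
#'   across the two populations.
#' @export
fst_weir_cockerham <- function(gm, popA, popB) {
  scA <- site_counts(gm$calls[, pop_index(gm, popA), drop = FALSE])
  scB <- site_counts(gm$calls[, pop_index(gm, popB), drop = FALSE])
  comp <- wc_from_counts(scA, scB)
  if (comp$den <= 0) return(NA_real_)
  comp$num / comp$den
}

#' Binned genome scan
#'
#' Tiles each chromosome into fixed bins starting at position 1 and reports
#' per-population nucleotide diversity and Tajima's D plus pairwise Fst for
#' every bin containing at least `min_variants` variants; bins below the
#' threshold are dropped. Genome-wide values are the unweighted means over
#' qualifying bins (attribute `genome_mean`).
#'
#' @param gm a [genotype_matrix()].
#' @param bin bin width in bp (default 100 kb).
#' @param min_variants minimum variants for a bin to be emitted (default 3).
#' @param pops population labels (default: all present).
#' @param span_mode `"bin"` normalises diversity per bin width (the genome
#'   scan convention for mostly-invariant windows); `"sites"` per assayed
#'   site.
#' @return data.frame with `chrom`, `bin_start`, `bin_end`, `n_variants`,
#'   `pi_<pop>`, `D_<pop>`, `fst_<A>_<B>` columns; attribute `genome_mean`.
#' @export
binned_scan <- function(gm, bin = 100000L, min_variants = 3L,
                        pops = unique(gm$pop_labels), span_mode = "bin") {
  span_mode <- match.arg(span_mode, c("bin", "sites"))
  key <- paste(gm$chrom, (gm$pos - 1L) %/% bin)
  groups <- split(seq_along(key), key)
  groups <- groups[vapply(groups, length, 1L) >= min_variants]
  if (!length(groups)) {
    out <- data.frame()
    attr(out, "genome_mean") <- numeric(0)
    return(out)
  }
  pairs <- if (length(pops) >= 2) utils::combn(pops, 2, simplify = FALSE)
           else list()
  rows <- lapply(groups, function(i) {
    sub <- gm_subset(gm, i = sort(i))
    span <- if (span_mode == "bin") bin else length(i)
    row <- list(chrom = sub$chrom[1],
                bin_start = as.integer((sub$pos[1] - 1L) %/% bin * bin + 1L),
                n_variants = length(i))
    row$bin_end <- row$bin_start + as.integer(bin) - 1L
    for (p in pops) {
      row[[paste0("pi_", p)]] <- nucleotide_diversity(sub, p, span = span)
      row[[paste0("D_", p)]] <- suppressWarnings(tajimas_d(sub, p))
    }
    for (pr in pairs)
      row[[paste0("fst_", pr[1], "_", pr[2])]] <-
        fst_weir_cockerham(sub, pr[1], pr[2])
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$bin_start),
             c("chrom", "bin_start", "bin_end", "n_variants",
               setdiff(names(out), c("chrom", "bin_start", "bin_end",
                                     "n_variants")))]
  rownames(out) <- NULL
  attr(out, "genome_mean") <-
    colMeans(out[, -(1:4), drop = FALSE], na.rm = TRUE)
  out
}

#' N50 of a set of lengths
#'
#' Smallest length L such that elements of length >= L sum to at least half
#' the total length.
#'
#' @param lengths numeric vector of positive lengths.
#' @return The N50 length.
#' @export
n50 <- function(lengths) {
  if (!length(lengths)) stop("empty length list")
  if (any(lengths <= 0)) stop("lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}
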