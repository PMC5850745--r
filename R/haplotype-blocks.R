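# Gabriel-style haplotype blocks from unphased diploid genotypes.
# The study species is highly selfing, so heterozygosity is rare;
# double-heterozygous individuals (phase-ambiguous for a pair) are excluded
# pairwise, all other genotype pairs resolve to known haplotypes.

# two-SNP haplotype cell counts (n00, n01, n10, n11) from dosage vectors
pair_hap_counts <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2) & !(g1 == 1L & g2 == 1L)
  g1 <- g1[keep]; g2 <- g2[keep]
  n <- c(`00` = 0, `01` = 0, `10` = 0, `11` = 0)
  if (!length(g1)) return(n)
  for (k in seq_along(g1)) {
    a <- g1[k]; b <- g2[k]
    if (a != 1L && b != 1L) {            # both homozygous: two equal haplotypes
      cell <- paste0(a / 2, b / 2)
      n[cell] <- n[cell] + 2
    } else if (a == 1L) {                # het at SNP1 only
      n[paste0(0, b / 2)] <- n[paste0(0, b / 2)] + 1
      n[paste0(1, b / 2)] <- n[paste0(1, b / 2)] + 1
    } else {                             # het at SNP2 only
      n[paste0(a / 2, 0)] <- n[paste0(a / 2, 0)] + 1
      n[paste0(a / 2, 1)] <- n[paste0(a / 2, 1)] + 1
    }
  }
  n
}

# likelihood-based confidence interval for |D'| (Gabriel et al. / Haploview
# approach): multinomial likelihood profiled over |D'| with allele
# frequencies fixed at their MLEs; returns c(low, high) of the 90% interval
# plus the point estimate, or NULL for uninformative pairs.
dprime_ci <- function(counts, grid_step = 0.005) {
  N <- sum(counts)
  if (N < 4) return(NULL)
  pA <- (counts["10"] + counts["11"]) / N
  pB <- (counts["01"] + counts["11"]) / N
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1) return(NULL)
  D <- counts["11"] / N - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax <= 0) return(NULL)
  sgn <- if (D >= 0) 1 else -1
  grid <- seq(0, 1, by = grid_step)
  ll <- vapply(grid, function(dp) {
    d <- sgn * dp * dmax
    p <- c(`00` = (1 - pA) * (1 - pB) + d, `01` = (1 - pA) * pB - d,
           `10` = pA * (1 - pB) - d, `11` = pA * pB + d)
    p <- pmax(p, 1e-12)
    sum(counts * log(p))
  }, numeric(1))
  w <- exp(ll - max(ll))
  cw <- cumsum(w) / sum(w)
  low <- grid[which(cw >= 0.05)[1]]
  high <- grid[which(cw >= 0.95)[1]]
  c(low = low, high = high, dprime = min(abs(D) / dmax, 1))
}

# classify a SNP pair: "strong" LD, "recomb", or "uninformative"
classify_pair <- function(g1, g2, ci_low = 0.70, ci_high = 0.98,
                          recomb_high = 0.90) {
  ci <- dprime_ci(pair_hap_counts(g1, g2))
  if (is.null(ci)) return("uninformative")
  if (ci[["low"]] >= ci_low && ci[["high"]] >= ci_high) return("strong")
  if (ci[["high"]] < recomb_high) return("recomb")
  "uninformative"
}

#' Haplotype blocks and N50
#'
#' Gabriel-style block detection: for every SNP pair within `window` bp a
#' likelihood-based confidence interval on |D'| classifies the pair as
#' showing strong LD (CI within `[ci_low, ci_high]` bounds), strong evidence
#' of historical recombination (CI upper bound below `recomb_high`), or
#' uninformative. Candidate intervals whose outermost pair is in strong LD
#' and in which at least `prop_strong` of the informative pairs are strong
#' become blocks; candidates are accepted greedily by decreasing physical
#' length without overlap. Blocks spanning `min_len` bp or less are
#' discarded before counting and N50 computation. The interval thresholds
#' are the Haploview/PLINK defaults; they are configurable because the
#' source tooling does not document every internal.
#'
#' @param gm a [genotype_matrix()].
#' @param pop population label (use a shared label, or relabel, for the
#'   whole panel).
#' @param window maximum pair distance in bp (default 2 Mb).
#' @param min_len minimum retained block span in bp (default 100; the
#'   retention rule is strictly greater than `min_len`).
#' @param ci_low,ci_high,recomb_high |D'| confidence-interval thresholds.
#' @param prop_strong minimum proportion of strong informative pairs.
#' @return An object of class `haplotype_block_set`: `blocks` (data.frame
#'   `chrom`, `start`, `end`, `n_snps`, `length`), `n50`, `total_blocks`.
#' @export
haplotype_blocks <- function(gm, pop, window = 2e6, min_len = 100,
                             ci_low = 0.70, ci_high = 0.98,
                             recomb_high = 0.90, prop_strong = 0.95) {
  idx <- pop_index(gm, pop)
  blocks <- NULL
  for (ch in unique(gm$chrom)) {
    s <- which(gm$chrom == ch)
    if (length(s) < 2) next
    pos <- gm$pos[s]
    calls <- gm$calls[s, idx, drop = FALSE]
    m <- length(s)
    cls <- matrix(NA_character_, m, m)
    for (i in seq_len(m - 1))
      for (j in (i + 1):m) {
        if (pos[j] - pos[i] > window) break
        cls[i, j] <- classify_pair(calls[i, ], calls[j, ])
      }
    # candidate intervals: outermost pair strong, proportion rule inside
    cand <- NULL
    for (i in seq_len(m - 1))
      for (j in (i + 1):m) {
        if (is.na(cls[i, j]) || cls[i, j] != "strong") next
        sub <- cls[i:j, i:j]
        n_strong <- sum(sub == "strong", na.rm = TRUE)
        n_recomb <- sum(sub == "recomb", na.rm = TRUE)
        if (n_strong + n_recomb == 0) next
        if (n_strong / (n_strong + n_recomb) >= prop_strong)
          cand <- rbind(cand, data.frame(i = i, j = j,
                                         len = pos[j] - pos[i]))
      }
    if (is.null(cand)) next
    cand <- cand[order(-cand$len, cand$i), , drop = FALSE]
    taken <- rep(FALSE, m)
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (any(taken[i:j])) next
      taken[i:j] <- TRUE
      blocks <- rbind(blocks,
                      data.frame(chrom = ch, start = pos[i], end = pos[j],
                                 n_snps = j - i + 1L, length = pos[j] - pos[i]))
    }
  }
  if (!is.null(blocks)) {
    blocks <- blocks[blocks$length > min_len, , drop = FALSE]
    blocks <- blocks[order(blocks$chrom, blocks$start), , drop = FALSE]
    rownames(blocks) <- NULL
  }
  if (is.null(blocks) || !nrow(blocks))
    return(structure(list(blocks = data.frame(), n50 = NA_real_,
                          total_blocks = 0L), class = "haplotype_block_set"))
  structure(list(blocks = blocks, n50 = n50(blocks$length),
                 total_blocks = nrow(blocks)),
            class = "haplotype_block_set")
}

#' @export
print.haplotype_block_set <- function(x, ...) {
  cat("haplotype_block_set:", x$total_blocks, "blocks, N50 =", x$n50, "bp\n")
  invisible(x)
}
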