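#' ABC summary-statistic vector
#'
#' The fixed, named statistic vector compared between observed and simulated
#' data. Per population (in the order given): segregating sites `S_`, mean
#' per-site nucleotide diversity `pi_`, mean unbiased expected
#' heterozygosity at within-population segregating sites `H_`, and Tajima's
#' D `D_`; then pairwise Weir-Cockerham `fst_A_B` for each population pair;
#' then pooled-sample `S_all` and `H_all`. The ordering is deterministic and
#' identical for observed and simulated matrices (the same computation path
#' serves both).
#'
#' @param gm a [genotype_matrix()].
#' @param pops ordered population labels (>= 2).
#' @param allow_missing if `FALSE` (default), statistics undefined on this
#'   dataset (e.g. Tajima's D with S = 0, Fst with no shared polymorphism)
#'   are returned as `NA` with a warning; `TRUE` suppresses the warnings
#'   (used by the reference-table builder, which re-draws such rows).
#' @return Named numeric vector in the fixed order.
#' @export
sumstat_vector <- function(gm, pops = c("MW", "AW", "PhI"),
                           allow_missing = FALSE) {
  if (length(pops) < 2) stop("at least two populations are required")
  for (p in pops)
    if (sum(gm$pop_labels == p) < 2)
      stop("population with fewer than 2 individuals: ", p)
  S_sites <- nrow(gm$calls)
  out <- c()
  sc_by_pop <- lapply(pops, function(p)
    site_counts(gm$calls[, pop_index(gm, p), drop = FALSE]))
  names(sc_by_pop) <- pops
  for (p in pops) {
    sc <- sc_by_pop[[p]]
    use <- sc$n >= 2
    S <- sum(sc$seg[use])
    pi <- sum(sc$h[use]) / S_sites
    H <- if (S > 0) mean(sc$h[use & sc$seg]) else 0
    D <- tajima_d_from_counts(sc)
    if (is.na(D) && !allow_missing)
      warning("Tajima's D undefined (no segregating sites): ", p)
    v <- c(S, pi, H, D)
    names(v) <- paste0(c("S_", "pi_", "H_", "D_"), p)
    out <- c(out, v)
  }
  for (pr in utils::combn(pops, 2, simplify = FALSE)) {
    comp <- wc_from_counts(sc_by_pop[[pr[1]]], sc_by_pop[[pr[2]]])
    f <- if (comp$den <= 0) NA_real_ else comp$num / comp$den
    if (is.na(f) && !allow_missing)
      warning("Fst undefined (no shared polymorphic sites): ",
              pr[1], "/", pr[2])
    out <- c(out, stats::setNames(f, paste0("fst_", pr[1], "_", pr[2])))
  }
  all_idx <- which(gm$pop_labels %in% pops)
  sc <- site_counts(gm$calls[, all_idx, drop = FALSE])
  use <- sc$n >= 2
  S_all <- sum(sc$seg[use])
  H_all <- if (S_all > 0) mean(sc$h[use & sc$seg]) else 0
  c(out, c(S_all = S_all, H_all = H_all))
}

#' Write / read a summary-statistic vector as ordered name/value TSV
#' @param ss named numeric vector from [sumstat_vector()].
#' @param path TSV path.
#' @export
write_sumstat <- function(ss, path) {
  utils::write.table(data.frame(statistic = names(ss), value = unname(ss)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sumstat
#' @export
read_sumstat <- function(path) {
  d <- utils::read.delim(path)
  stats::setNames(d$value, d$statistic)
}
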