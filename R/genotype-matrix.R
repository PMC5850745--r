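#' Genotype matrix container
#'
#' Sites x individuals biallelic genotype container used throughout the
#' package. Genotypes are stored as alt-allele dosages in \{0, 1, 2, NA\};
#' per-call genotype quality (GQ) and read depth (DP) matrices are carried
#' when available so the filter chain can operate on them.
#'
#' @param chrom character vector, chromosome identifier per site.
#' @param pos integer vector, 1-based physical coordinate per site (bp);
#'   strictly increasing within each chromosome.
#' @param ref,alt character vectors of reference/alternate alleles per site.
#' @param calls integer matrix (sites x individuals) of alt-allele dosages;
#'   missing genotypes are `NA`.
#' @param sample_ids character vector of individual identifiers (unique).
#' @param pop_labels character vector of population assignments, one per
#'   individual (e.g. `"MW"`, `"AW"`, `"PhI"`, or `"unassigned"`).
#' @param gq,dp optional numeric matrices of per-call genotype quality and
#'   read depth, same dimensions as `calls`.
#' @param multiallelic logical vector flagging sites that carried more than
#'   one alternate allele in the source file (kept at read time, removed by
#'   [apply_filters()]).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, calls, sample_ids,
                            pop_labels, gq = NULL, dp = NULL,
                            multiallelic = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  S <- nrow(calls); N <- ncol(calls)
  stopifnot(length(chrom) == S, length(pos) == S,
            length(ref) == S, length(alt) == S)
  if (length(sample_ids) != N)
    stop("sample_ids length does not match number of individuals")
  if (length(pop_labels) != N)
    stop("number of pop_labels must equal number of individuals")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosage values must be in {0, 1, 2, NA}")
  if (S > 1) {
    for (ch in unique(chrom)) {
      p <- pos[chrom == ch]
      if (length(p) > 1 && any(diff(p) <= 0))
        stop("positions must be strictly increasing within chromosome ", ch)
    }
  }
  if (is.null(multiallelic)) multiallelic <- rep(FALSE, S)
  if (!is.null(gq)) { gq <- as.matrix(gq); stopifnot(all(dim(gq) == dim(calls))) }
  if (!is.null(dp)) { dp <- as.matrix(dp); stopifnot(all(dim(dp) == dim(calls))) }
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), alt = as.character(alt),
                 calls = calls, sample_ids = as.character(sample_ids),
                 pop_labels = as.character(pop_labels),
                 gq = gq, dp = dp, multiallelic = as.logical(multiallelic)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "sites x", ncol(x$calls),
      "individuals\n")
  cat("  chromosomes:", paste(unique(x$chrom), collapse = ", "), "\n")
  tab <- table(x$pop_labels)
  cat("  populations:",
      paste(sprintf("%s (%d)", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.1f%%; multiallelic-flagged sites: %d\n",
              100 * miss, sum(x$multiallelic)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# subset sites (i) and/or individuals (j); internal
gm_subset <- function(gm, i = NULL, j = NULL) {
  if (!is.null(i)) {
    gm$chrom <- gm$chrom[i]; gm$pos <- gm$pos[i]
    gm$ref <- gm$ref[i]; gm$alt <- gm$alt[i]
    gm$multiallelic <- gm$multiallelic[i]
    gm$calls <- gm$calls[i, , drop = FALSE]
    if (!is.null(gm$gq)) gm$gq <- gm$gq[i, , drop = FALSE]
    if (!is.null(gm$dp)) gm$dp <- gm$dp[i, , drop = FALSE]
  }
  if (!is.null(j)) {
    gm$sample_ids <- gm$sample_ids[j]; gm$pop_labels <- gm$pop_labels[j]
    gm$calls <- gm$calls[, j, drop = FALSE]
    if (!is.null(gm$gq)) gm$gq <- gm$gq[, j, drop = FALSE]
    if (!is.null(gm$dp)) gm$dp <- gm$dp[, j, drop = FALSE]
  }
  gm
}

pop_index <- function(gm, pop) {
  idx <- which(gm$pop_labels == pop)
  if (!length(idx)) stop("population not present: ", pop)
  idx
}
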