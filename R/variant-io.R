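#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via Bioconductor's VariantAnnotation), retaining
#' per-call GQ and DP when present. Multiallelic records are kept at read
#' time and flagged (they are removed by the biallelic step of
#' [apply_filters()]); genotypes carrying an allele index above 1 are set
#' missing. Samples absent from the population map get the label
#' `"unassigned"`.
#'
#' @param path VCF file path (plain text or bgzipped).
#' @param pop_map optional data.frame with columns `sample_id`,
#'   `population`, or a path to such a two-column TSV
#'   (see [read_pop_map()]).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, pop_map = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_vcf_structure(path)
  vcf <- tryCatch(
    suppressWarnings(VariantAnnotation::readVcf(path)),
    error = function(e) stop("malformed VCF ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  ids <- colnames(vcf)
  if (anyDuplicated(ids))
    stop("duplicated sample id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt_list <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_list)
  multi <- n_alt > 1
  alt1 <- vapply(seq_along(alt_list), function(i)
    as.character(alt_list[[i]][1]), character(1))
  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field: ", path)
  calls <- gt_to_dosage(gt)
  gq <- dp <- NULL
  gn <- VariantAnnotation::geno(vcf)
  if ("GQ" %in% names(gn)) { gq <- gn$GQ; storage.mode(gq) <- "double" }
  if ("DP" %in% names(gn)) { dp <- gn$DP; storage.mode(dp) <- "double" }
  if (is.character(pop_map)) pop_map <- read_pop_map(pop_map)
  labels <- if (is.null(pop_map)) rep("unassigned", length(ids)) else {
    i <- match(ids, pop_map$sample_id)
    ifelse(is.na(i), "unassigned", pop_map$population[i])
  }
  genotype_matrix(chrom = as.character(GenomicRanges::seqnames(rr)),
                  pos = GenomicRanges::start(rr),
                  ref = as.character(VariantAnnotation::ref(vcf)),
                  alt = alt1, calls = calls, sample_ids = ids,
                  pop_labels = labels, gq = gq, dp = dp,
                  multiallelic = multi)
}

# quick structural scan so malformed files report a line number
check_vcf_structure <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (!length(hdr))
    stop("malformed VCF ", path, ": no #CHROM header line", call. = FALSE)
  hdr_fields <- strsplit(lines[hdr[1]], "\t")[[1]]
  if (length(hdr_fields) > 9) {
    ids <- hdr_fields[-(1:9)]
    if (anyDuplicated(ids))
      stop("duplicated sample id: ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "),
           call. = FALSE)
  }
  ncol_expected <- length(hdr_fields)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (ln in body) {
    nf <- length(strsplit(lines[ln], "\t")[[1]])
    if (nf != ncol_expected)
      stop("malformed VCF ", path, " at line ", ln, ": ", nf,
           " fields, expected ", ncol_expected, call. = FALSE)
  }
  invisible(TRUE)
}

gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g)) return(NA_integer_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(a))
    if (anyNA(a) || length(a) != 2) return(NA_integer_)
    if (any(a > 1L)) return(NA_integer_)   # allele above first alt
    sum(a)
  }, integer(1))
  out <- matrix(lut[match(as.vector(gt), u)], nrow(gt), ncol(gt))
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix as VCF 4.2
#'
#' Deterministic plain-text writer (stable field formatting, so writing the
#' result of [read_vcf()] round-trips byte-identically on normalized
#' fixtures). GQ and DP are emitted when carried.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  fmt <- c("GT", if (!is.null(gm$gq)) "GQ", if (!is.null(gm$dp)) "DP")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(gm$gq))
      "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    if (!is.null(gm$dp))
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$sample_ids), collapse = "\t")), con)
  gt_txt <- matrix(c("0/0", "0/1", "1/1")[gm$calls + 1L],
                   nrow(gm$calls), ncol(gm$calls))
  gt_txt[is.na(gm$calls)] <- "./."
  for (s in seq_len(nrow(gm$calls))) {
    cell <- gt_txt[s, ]
    if (!is.null(gm$gq))
      cell <- paste0(cell, ":", ifelse(is.na(gm$gq[s, ]), ".",
                                       format(gm$gq[s, ], trim = TRUE)))
    if (!is.null(gm$dp))
      cell <- paste0(cell, ":", ifelse(is.na(gm$dp[s, ]), ".",
                                       format(gm$dp[s, ], trim = TRUE)))
    writeLines(paste(c(gm$chrom[s], gm$pos[s], ".", gm$ref[s], gm$alt[s],
                       ".", "PASS", ".", paste(fmt, collapse = ":"), cell),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a two-column population map TSV (sample_id, population)
#' @param path TSV path with header.
#' @return data.frame with `sample_id` and `population` columns.
#' @export
read_pop_map <- function(path) {
  d <- utils::read.delim(path, colClasses = "character")
  if (!all(c("sample_id", "population") %in% names(d)))
    stop("population map needs columns sample_id, population: ", path)
  d
}

#' Genotype filter configuration
#'
#' The filter chain of the study's final VCF filtering: genotype-quality and
#' read-depth call masking, biallelic-only, individual missingness,
#' site missingness, and minor allele frequency.
#'
#' Boundary conventions (all switchable): MAF is kept when `>= min_maf`
#' (`maf_inclusive = FALSE` switches to strictly greater); read depth is
#' kept when `>= min_dp` (`dp_strict = TRUE` switches to strictly greater,
#' matching the ambiguous "higher than three reads" prose); individuals are
#' removed when their missing fraction is strictly greater than
#' `max_indiv_missing` (the usual `-mind` semantics), sites when strictly
#' greater than `max_site_missing`.
#'
#' @param min_gq genotype-quality threshold (phred), calls below are masked.
#' @param min_dp read-depth threshold (reads).
#' @param dp_strict keep DP strictly greater than `min_dp` instead of `>=`.
#' @param max_indiv_missing maximum per-individual missing fraction.
#' @param max_site_missing maximum per-site missing fraction.
#' @param min_maf minimum minor allele frequency in \[0, 0.5\].
#' @param maf_inclusive keep MAF equal to the threshold.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_gq = 10, min_dp = 3, dp_strict = FALSE,
                          max_indiv_missing = 0.1, max_site_missing = 0.2,
                          min_maf = 0.05, maf_inclusive = TRUE) {
  for (f in c(max_indiv_missing, max_site_missing))
    if (f < 0 || f > 1) stop("config error: fractions must be in [0, 1]")
  if (min_maf < 0 || min_maf > 0.5)
    stop("config error: min_maf must be in [0, 0.5]")
  structure(list(min_gq = min_gq, min_dp = min_dp, dp_strict = dp_strict,
                 max_indiv_missing = max_indiv_missing,
                 max_site_missing = max_site_missing, min_maf = min_maf,
                 maf_inclusive = maf_inclusive), class = "filter_config")
}

#' Apply the genotype filter chain
#'
#' Fixed, logged order of operations:
#' 1. mask calls failing the GQ and/or DP thresholds (when those fields are
#'    carried);
#' 2. drop multiallelic sites;
#' 3. drop individuals whose missing-call fraction exceeds
#'    `max_indiv_missing`;
#' 4. drop sites whose missing-call fraction (among remaining individuals)
#'    exceeds `max_site_missing`;
#' 5. drop sites with minor allele frequency below `min_maf`, computed on
#'    non-missing calls.
#'
#' Filtering an already-filtered matrix removes nothing further
#' (idempotence), and the per-step removal counts sum to input minus
#' output.
#'
#' @param gm a [genotype_matrix()].
#' @param cfg a [filter_config()].
#' @return List with `gm` (filtered matrix) and `report` (data.frame
#'   `step`, `sites_removed`, `indivs_removed`, `calls_masked`), of class
#'   `filter_result`.
#' @export
apply_filters <- function(gm, cfg = filter_config()) {
  stopifnot(inherits(cfg, "filter_config"))
  report <- data.frame(step = c("mask_gq_dp", "biallelic", "indiv_missing",
                                "site_missing", "maf"),
                       sites_removed = 0L, indivs_removed = 0L,
                       calls_masked = 0L)
  # 1: mask low-quality calls
  masked <- matrix(FALSE, nrow(gm$calls), ncol(gm$calls))
  if (!is.null(gm$gq))
    masked <- masked | (!is.na(gm$gq) & gm$gq < cfg$min_gq)
  if (!is.null(gm$dp)) {
    fail_dp <- if (cfg$dp_strict) gm$dp <= cfg$min_dp else gm$dp < cfg$min_dp
    masked <- masked | (!is.na(gm$dp) & fail_dp)
  }
  masked <- masked & !is.na(gm$calls)
  report$calls_masked[1] <- sum(masked)
  gm$calls[masked] <- NA_integer_
  if (!is.null(gm$gq)) gm$gq[masked] <- NA
  if (!is.null(gm$dp)) gm$dp[masked] <- NA
  # 2: biallelic only
  drop2 <- which(gm$multiallelic)
  report$sites_removed[2] <- length(drop2)
  if (length(drop2)) gm <- gm_subset(gm, i = setdiff(seq_len(nrow(gm$calls)),
                                                     drop2))
  # 3-5 iterate to a fixed point: removing high-missingness or low-MAF
  # sites can raise the missing fraction of a remaining individual above
  # threshold, so a single pass would not be idempotent
  repeat {
    changed <- FALSE
    # 3: individual missingness
    if (nrow(gm$calls)) {
      miss_frac <- colMeans(is.na(gm$calls))
      drop3 <- which(miss_frac > cfg$max_indiv_missing)
    } else drop3 <- integer(0)
    report$indivs_removed[3] <- report$indivs_removed[3] + length(drop3)
    if (ncol(gm$calls) > 0 && length(drop3) == ncol(gm$calls))
      stop("empty cohort")
    if (length(drop3)) {
      gm <- gm_subset(gm, j = setdiff(seq_len(ncol(gm$calls)), drop3))
      changed <- TRUE
    }
    # 4: site missingness
    site_miss <- rowMeans(is.na(gm$calls))
    drop4 <- which(site_miss > cfg$max_site_missing)
    report$sites_removed[4] <- report$sites_removed[4] + length(drop4)
    if (length(drop4)) {
      gm <- gm_subset(gm, i = setdiff(seq_len(nrow(gm$calls)), drop4))
      changed <- TRUE
    }
    # 5: minor allele frequency on non-missing calls
    n <- 2 * rowSums(!is.na(gm$calls))
    p <- ifelse(n > 0, rowSums(gm$calls, na.rm = TRUE) / n, 0)
    maf <- pmin(p, 1 - p)
    fail5 <- if (cfg$maf_inclusive) maf < cfg$min_maf else maf <= cfg$min_maf
    drop5 <- which(fail5 | n == 0)
    report$sites_removed[5] <- report$sites_removed[5] + length(drop5)
    if (length(drop5)) {
      gm <- gm_subset(gm, i = setdiff(seq_len(nrow(gm$calls)), drop5))
      changed <- TRUE
    }
    if (!changed) break
  }
  structure(list(gm = gm, report = report), class = "filter_result")
}

#' @export
print.filter_result <- function(x, ...) {
  cat("filter_result:", nrow(x$gm$calls), "sites x", ncol(x$gm$calls),
      "individuals retained\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}

#' Write a filter report as TSV
#' @param res a `filter_result`.
#' @param path output path.
#' @export
write_filter_report <- function(res, path) {
  utils::write.table(res$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
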