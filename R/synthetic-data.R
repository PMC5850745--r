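# Pseudo-observed datasets with known truth, and small planted-defect
# fixtures, so every pipeline stage is testable without external data.
# Fixture expectations are derived by independent bookkeeping (the
# generator's own plan), never by calling the code under test.

#' Parameter presets for pseudo-observed data
#'
#' `"table3-like"` uses the posterior point estimates reported for this
#' system as generator truth (T1 = 87,410 and T2 = 373,060 years with
#' mid-prior sizes). These values are inputs to simulation for recovery
#' experiments, never expected outputs.
#'
#' @param preset preset name (currently `"table3-like"`).
#' @param model a `demographic_model` (decides which founder sizes are
#'   needed).
#' @return Named numeric parameter vector.
#' @export
preset_params <- function(preset = "table3-like", model) {
  preset <- match.arg(preset, "table3-like")
  mid <- function(lo, hi) exp((log(lo) + log(hi)) / 2)  # log-uniform midpoint
  p <- c(N_MW = mid(1e3, 1e6), N_AW = mid(1e3, 1e6), N_PhI = mid(1e3, 1e6),
         T1 = 87410, T2 = 373060, bottleneck_dur = 100,
         N_ANC = mid(1e3, 1e6),
         NF_MW = mid(10, 1e4), NF_AW = mid(10, 1e4), NF_PhI = mid(10, 1e4))
  p[model$param_names]
}

#' Generate a pseudo-observed dataset with known truth
#'
#' Simulates one dataset under a chosen model and parameter set and bundles
#' it with its generating truth and its observed summary-statistic vector
#' (recomputed bit-stably from the dataset given the seed).
#'
#' @param model model name or `demographic_model`.
#' @param params named parameter vector, or `"table3-like"` for the preset.
#' @param sample_profile `"full"` (157/77/12 diploids), `"reduced"`
#'   (20/10/6), or a named vector; see [sample_profile()].
#' @param seed integer seed; the bundle is reproducible from it.
#' @param n_chrom,snps_per_chrom,maf_min forwarded to
#'   [simulate_dataset()].
#' @return An object of class `pseudo_observed`: `dataset`
#'   (`simulated_dataset`), `model`, `params`, `observed`
#'   (statistic vector), `seed`.
#' @export
make_pseudo_observed <- function(model, params = "table3-like",
                                 sample_profile = "reduced", seed,
                                 n_chrom = 5L, snps_per_chrom = 200L,
                                 maf_min = 0.05) {
  sizes <- sample_profile(sample_profile)
  if (!inherits(model, "demographic_model")) model <- build_model(model, sizes)
  else model$sample_sizes <- sizes
  if (is.character(params)) params <- preset_params(params, model)
  set.seed(seed)
  ds <- simulate_dataset(model, params, n_chrom = n_chrom,
                         snps_per_chrom = snps_per_chrom, maf_min = maf_min)
  obs <- sumstat_vector(ds$gm, pops = c("MW", "AW", "PhI"),
                        allow_missing = TRUE)
  structure(list(dataset = ds, model = model$name, params = unlist(params),
                 observed = obs, seed = seed), class = "pseudo_observed")
}

#' Write / read a pseudo-observed bundle as plain text
#'
#' The bundle directory holds `genotypes.vcf`, `pop_map.tsv`,
#' `observed.tsv` and `truth.json`.
#' @param bundle a `pseudo_observed`.
#' @param dir output directory (created).
#' @export
write_pseudo_observed <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gm <- bundle$dataset$gm
  write_vcf(gm, file.path(dir, "genotypes.vcf"))
  utils::write.table(data.frame(sample_id = gm$sample_ids,
                                population = gm$pop_labels),
                     file.path(dir, "pop_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sumstat(bundle$observed, file.path(dir, "observed.tsv"))
  jsonlite::write_json(list(model = bundle$model,
                            params = as.list(bundle$params),
                            seed = bundle$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Toy VCF with planted filter defects and expected outcome
#'
#' Builds a VCF exercising every branch of [apply_filters()] together with
#' the machine-readable outcome the filter chain must produce. Roles are
#' assigned to disjoint site and individual sets so the expectation follows
#' from the plan by arithmetic alone:
#'
#' * `multiallelic` - sites given a second ALT allele (removed at the
#'   biallelic step);
#' * `low_maf` - monomorphic sites (MAF 0, removed at the MAF step);
#' * `missingness` - sites with more than 20% missing calls among
#'   surviving individuals (removed at the site-missingness step) plus
#'   individuals with more than 10% missing calls (removed at the
#'   individual step);
#' * `low_gq` / `low_dp` - calls planted below the GQ/DP thresholds on
#'   hom-ref calls of surviving individuals (masked, never enough per
#'   site/individual to trigger the missingness removals).
#'
#' @param n_sites,n_indiv fixture dimensions (>= 8 sites, >= 6
#'   individuals recommended so every role fits).
#' @param planted_defects character subset of `c("multiallelic",
#'   "low_maf", "missingness", "low_gq", "low_dp")`; empty = clean input.
#' @param seed integer seed.
#' @param path optional VCF output path (the matrix is always returned).
#' @return List with `gm` (the unfiltered [genotype_matrix()]), `path`
#'   (or `NULL`), and `expected`: a list with per-step removal counts
#'   (`multiallelic_removed`, `indiv_removed`, `site_missing_removed`,
#'   `maf_removed`, `calls_masked`) and surviving `n_sites` / `n_indiv`.
#' @export
make_toy_vcf <- function(n_sites, n_indiv, planted_defects = character(),
                         seed = 1, path = NULL) {
  stopifnot(n_sites >= 1, n_indiv >= 1)
  bad <- setdiff(planted_defects, c("multiallelic", "low_maf", "missingness",
                                    "low_gq", "low_dp"))
  if (length(bad)) stop("unknown defect: ", paste(bad, collapse = ", "))
  set.seed(seed)
  want <- function(d) d %in% planted_defects
  pick <- function(x, k) x[sample.int(length(x), k)]  # safe for length-1 x
  # --- role assignment (disjoint) -----------------------------------------
  site_pool <- sample.int(n_sites)
  take_sites <- function(k) {
    if (k <= 0) return(integer(0))
    out <- head(site_pool, k); site_pool <<- tail(site_pool, -k); out
  }
  n_multi <- if (want("multiallelic")) min(sample(1:2, 1), length(site_pool) - 2) else 0
  multi_sites <- take_sites(max(n_multi, 0))
  n_lowmaf <- if (want("low_maf")) min(sample(1:2, 1), length(site_pool) - 2) else 0
  lowmaf_sites <- take_sites(max(n_lowmaf, 0))
  n_highmiss <- if (want("missingness")) min(sample(1:2, 1), length(site_pool) - 2) else 0
  highmiss_sites <- take_sites(max(n_highmiss, 0))
  clean_sites <- site_pool
  ind_pool <- sample.int(n_indiv)
  n_drop <- if (want("missingness") && n_indiv >= 4) 1 else 0
  drop_indiv <- head(ind_pool, n_drop)
  keep_indiv <- setdiff(seq_len(n_indiv), drop_indiv)
  N_surv <- length(keep_indiv)
  # --- base genotypes: every site clearly common (MAF in [0.25, 0.5])
  # among *surviving* individuals, so individual removals never drag a
  # clean site below the MAF threshold
  calls <- matrix(0L, n_sites, n_indiv)
  for (s in seq_len(n_sites)) {
    n_alt_hom <- max(1, round(stats::runif(1, 0.25, 0.5) * N_surv))
    calls[s, pick(keep_indiv, n_alt_hom)] <- 2L
  }
  calls[lowmaf_sites, ] <- 0L                      # monomorphic
  gq <- matrix(99, n_sites, n_indiv)
  dp <- matrix(30, n_sites, n_indiv)
  # --- plant defects ------------------------------------------------------
  S2 <- n_sites - length(multi_sites)   # denominator after biallelic step
  S_final_sites <- length(clean_sites)  # sites surviving all site removals
  # individual(s) to be dropped: missing at > 10% of post-biallelic sites
  # (planted on non-multiallelic sites so the fraction is exact)
  non_multi <- setdiff(seq_len(n_sites), multi_sites)
  for (i in drop_indiv) {
    k <- min(floor(0.1 * S2) + 1L, length(non_multi))
    calls[pick(non_multi, k), i] <- NA_integer_
  }
  # shared per-individual missingness budgets: a surviving individual must
  # never exceed 10% missing under any denominator the iterated chain can
  # produce (post-biallelic sites S2 at the first pass, surviving clean
  # sites at later passes), counting both planted NA calls and masked
  # low-GQ/DP calls
  budget_pass1 <- stats::setNames(
    rep(pmax(floor(0.1 * S2), 0L), n_indiv), seq_len(n_indiv))
  budget_final <- stats::setNames(
    rep(pmax(floor(0.1 * S_final_sites), 0L), n_indiv), seq_len(n_indiv))
  # high-missingness sites: > 20% missing among surviving individuals,
  # spread over individuals with remaining first-pass budget; a site is
  # demoted to clean if the budget cannot fund it
  if (length(highmiss_sites)) {
    funded <- c()
    for (s in highmiss_sites) {
      k <- min(floor(0.2 * N_surv) + 1L, N_surv)
      cand <- keep_indiv[budget_pass1[as.character(keep_indiv)] >= 1L]
      if (length(cand) < k) next
      who <- pick(cand, k)
      calls[s, who] <- NA_integer_
      budget_pass1[as.character(who)] <- budget_pass1[as.character(who)] - 1L
      funded <- c(funded, s)
    }
    clean_sites <- c(clean_sites, setdiff(highmiss_sites, funded))
    highmiss_sites <- funded
    S_final_sites <- length(clean_sites)
  }
  # masked calls: planted on hom-ref calls of surviving individuals at
  # clean sites, within both budgets and at most 20% per site
  masked_calls <- 0L
  if (want("low_gq") || want("low_dp")) {
    per_site_budget <- pmax(floor(0.2 * N_surv), 0)
    for (s in pick(clean_sites, length(clean_sites))) {
      cand <- keep_indiv[calls[s, keep_indiv] %in% 0L &
                         budget_pass1[as.character(keep_indiv)] >= 1L &
                         budget_final[as.character(keep_indiv)] >= 1L]
      if (!length(cand)) next
      k <- min(sample(0:2, 1), per_site_budget, length(cand))
      if (k == 0) next
      who <- pick(cand, k)
      for (i in who) {
        if (want("low_gq") && (!want("low_dp") || stats::runif(1) < 0.5))
          gq[s, i] <- sample(0:9, 1)
        else dp[s, i] <- sample(0:2, 1)
        budget_pass1[as.character(i)] <- budget_pass1[as.character(i)] - 1L
        budget_final[as.character(i)] <- budget_final[as.character(i)] - 1L
        masked_calls <- masked_calls + 1L
      }
    }
  }
  alt <- rep("T", n_sites)
  multi_flag <- rep(FALSE, n_sites)
  multi_flag[multi_sites] <- TRUE
  alt[multi_sites] <- "T,G"
  gm <- genotype_matrix(chrom = rep("chr1", n_sites),
                        pos = seq(100L, by = 137L, length.out = n_sites),
                        ref = rep("A", n_sites), alt = alt, calls = calls,
                        sample_ids = sprintf("ind%03d", seq_len(n_indiv)),
                        pop_labels = rep("toy", n_indiv),
                        gq = gq, dp = dp, multiallelic = multi_flag)
  expected <- list(multiallelic_removed = length(multi_sites),
                   indiv_removed = length(drop_indiv),
                   site_missing_removed = length(highmiss_sites),
                   maf_removed = length(lowmaf_sites),
                   calls_masked = masked_calls,
                   n_sites = length(clean_sites),
                   n_indiv = N_surv)
  if (!is.null(path)) {
    write_vcf(gm, path)
    jsonlite::write_json(expected, paste0(path, ".expected.json"),
                         auto_unbox = TRUE)
  }
  list(gm = gm, path = path, expected = expected)
}

#' Annotation fixture with expected neutral/genic partition
#'
#' Writes the same random feature intervals as both GFF3 and BED (0-based
#' half-open converted at the boundary) and generates SNP positions with a
#' classification expectation computed by direct all-pairs distance
#' arithmetic.
#'
#' @param n_features number of features.
#' @param spacing typical gap between features in bp (> 0).
#' @param seed integer seed.
#' @param dir output directory (created); `NULL` skips writing.
#' @param min_dist neutral-distance rule used for the expectation.
#' @return List with `features` (data.frame, 1-based inclusive), `pos`,
#'   `expected` (factor genic/neutral/intermediate), and file paths
#'   `gff3`/`bed` when written.
#' @export
make_annotation_fixture <- function(n_features, spacing, seed = 1,
                                    dir = NULL, min_dist = 5000) {
  stopifnot(spacing > 0, n_features >= 1)
  set.seed(seed)
  width <- pmax(50L, stats::rpois(n_features, 400L))
  gap <- pmax(1L, round(stats::rexp(n_features, 1 / spacing)))
  start <- cumsum(gap + c(0L, width[-n_features]))
  features <- data.frame(chrom = "chr1", start = start,
                         end = start + width - 1L)
  # SNPs: inside features, near edges, at the boundary, and far away
  pos <- sort(unique(c(
    round((features$start + features$end) / 2),          # genic
    features$end + sample(1:(min_dist - 1), n_features, TRUE),  # near
    features$end + min_dist,                              # boundary-neutral
    max(features$end) + min_dist + sample(1:10000, 3, TRUE))))  # far
  # independent all-pairs distance expectation
  expected <- vapply(pos, function(x) {
    inside <- any(x >= features$start & x <= features$end)
    if (inside) return("genic")
    d <- min(vapply(seq_len(n_features), function(i)
      if (x < features$start[i]) features$start[i] - x
      else x - features$end[i], numeric(1)))
    if (d >= min_dist) "neutral" else "intermediate"
  }, character(1))
  out <- list(features = features, pos = pos,
              expected = factor(expected,
                                levels = c("genic", "neutral",
                                           "intermediate")))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    gff3 <- file.path(dir, "features.gff3")
    writeLines(c("##gff-version 3",
                 sprintf("chr1\tsynthetic\tgene\t%d\t%d\t.\t+\t.\tID=g%03d",
                         features$start, features$end,
                         seq_len(n_features))), gff3)
    bed <- file.path(dir, "features.bed")
    writeLines(sprintf("chr1\t%d\t%d\tg%03d", features$start - 1L,
                       features$end, seq_len(n_features)), bed)
    out$gff3 <- gff3
    out$bed <- bed
  }
  out
}
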