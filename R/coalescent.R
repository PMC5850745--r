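#' Simulate a genealogy under a demographic model
#'
#' Runs the structured Kingman coalescent (continuous-time, exponential
#' waiting times) for one non-recombining locus: within each deme and epoch
#' pairs coalesce at rate k(k-1)/2 per 2N diploid generations; at each
#' divergence event (backward in time) all lineages of the derived deme
#' transfer to its source; founder episodes are epochs of the founder size.
#' Runs to the most recent common ancestor.
#'
#' @param model a [build_model()] object.
#' @param params named parameter vector covering `model$param_names`.
#' @param sample_sizes optional named diploid sample sizes (defaults to the
#'   model's); a deme may have 0 samples (the unsampled ancestor always
#'   does).
#' @return An object of class `genealogy`: `n_leaves`, `times` (node times
#'   in generations, leaves first), `parent` (1-based parent index, root =
#'   `NA`), `leaf_deme` (deme label per haploid leaf) and
#'   `total_branch_length`.
#' @export
simulate_genealogy <- function(model, params, sample_sizes = NULL) {
  hist <- compile_history(model, params)
  if (is.null(sample_sizes)) sample_sizes <- model$sample_sizes
  sim_genealogy_hist(hist, sample_sizes)
}

# hot path: run the coalescent engine on a pre-compiled history (avoids
# re-building the epoch tables for every chromosome / replicate)
sim_genealogy_hist <- function(hist, sample_sizes) {
  n_hap <- integer(length(hist$demes))
  names(n_hap) <- hist$demes
  for (d in names(sample_sizes)) n_hap[d] <- 2L * as.integer(sample_sizes[[d]])
  if (sum(n_hap) < 1) stop("no lineages sampled")
  ev <- hist$events
  g <- .sim_genealogy_cpp(unname(n_hap), hist$epoch_starts, hist$epoch_sizes,
                          ev$time, match(ev$from, hist$demes) - 1L,
                          match(ev$to, hist$demes) - 1L)
  g$parent <- ifelse(g$parent < 0L, NA_integer_, g$parent + 1L)
  g$leaf_deme <- hist$demes[g$leaf_deme]
  class(g) <- "genealogy"
  g
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", x$n_leaves, "leaves, TMRCA =",
      format(max(x$times), digits = 6), "generations, total branch length =",
      format(x$total_branch_length, digits = 6), "\n")
  invisible(x)
}

#' Place ascertained SNPs on a genealogy
#'
#' SNP-ascertainment mutation mode: each SNP is placed on a branch chosen
#' with probability proportional to its length; the leaves below the branch
#' carry the derived allele. SNPs whose pooled minor allele frequency falls
#' below `maf_min` are rejected and re-drawn until exactly `n_snps` pass.
#'
#' @param genealogy a [simulate_genealogy()] result.
#' @param n_snps number of SNPs to emit.
#' @param maf_min pooled-sample MAF ascertainment threshold (0 disables).
#' @param max_tries bound on total placement attempts before erroring (for
#'   tiny samples where no branch can satisfy the threshold).
#' @return 0/1 haplotype matrix with `n_snps` rows and one column per
#'   haploid leaf (leaf order as in the genealogy).
#' @export
drop_snps <- function(genealogy, n_snps, maf_min = 0.05,
                      max_tries = 1000L * n_snps) {
  stopifnot(n_snps >= 1)
  parent0 <- ifelse(is.na(genealogy$parent), -1L, genealogy$parent - 1L)
  .drop_snps_cpp(parent0, genealogy$times, genealogy$n_leaves,
                 as.integer(n_snps), maf_min, as.integer(max_tries))
}

#' Simulate a SNP dataset under a demographic model
#'
#' One independent genealogy per chromosome (fully linked SNPs within a
#' chromosome, free recombination between chromosomes); `snps_per_chrom`
#' ascertained SNPs are dropped on each; diploid individuals are formed by
#' pairing consecutive haplotypes within each deme (haplotypes are
#' exchangeable, so this is equivalent to random pairing under random
#' mating).
#'
#' @inheritParams simulate_genealogy
#' @param n_chrom number of chromosomes (default 5).
#' @param snps_per_chrom SNPs per chromosome (default 200, i.e. 1,000 SNPs
#'   total under the defaults).
#' @param maf_min pooled MAF ascertainment threshold (default 0.05).
#' @param chrom_length_bp physical length assigned to each simulated
#'   chromosome; SNP positions are sorted uniform draws on it.
#' @return A list of class `simulated_dataset`: `gm` (a
#'   [genotype_matrix()]), `model`, `params`.
#' @export
simulate_dataset <- function(model, params, n_chrom = 5L,
                             snps_per_chrom = 200L, maf_min = 0.05,
                             sample_sizes = NULL,
                             chrom_length_bp = 5e7) {
  if (is.null(sample_sizes)) sample_sizes <- model$sample_sizes
  hist <- compile_history(model, params)
  chrom <- pos <- NULL
  haps <- vector("list", n_chrom)
  for (k in seq_len(n_chrom)) {
    g <- sim_genealogy_hist(hist, sample_sizes)
    haps[[k]] <- drop_snps(g, snps_per_chrom, maf_min)
    chrom <- c(chrom, rep(paste0("chr", k), snps_per_chrom))
    pos <- c(pos, sort(sample.int(chrom_length_bp, snps_per_chrom)))
    if (k == 1) leaf_deme <- g$leaf_deme
  }
  hap <- do.call(rbind, haps)
  # diploids: consecutive haplotype pairs within each deme
  odd <- seq(1, ncol(hap), by = 2)
  calls <- hap[, odd, drop = FALSE] + hap[, odd + 1, drop = FALSE]
  ind_pop <- leaf_deme[odd]
  ids <- unlist(lapply(unique(ind_pop), function(p)
    sprintf("%s_%03d", p, seq_len(sum(ind_pop == p)))))
  gm <- genotype_matrix(chrom = chrom, pos = pos,
                        ref = rep("A", length(pos)),
                        alt = rep("T", length(pos)),
                        calls = calls, sample_ids = ids, pop_labels = ind_pop)
  structure(list(gm = gm, model = model$name, params = unlist(params)),
            class = "simulated_dataset")
}

#' Build an ABC reference table
#'
#' Simulates equal numbers of datasets under each model, drawing parameters
#' from the model's prior, and records `(sim_id, model, seed, parameters,
#' summary statistics)` per row. Per-simulation seeds are derived from
#' `master_seed`, so the table is reproducible row by row and chunks can be
#' rebuilt independently (resumable builds in [cmd_simulate()]). Simulations
#' with undefined statistics are re-drawn (with a fresh recorded seed) and
#' counted (attribute `n_redraws`); hard simulation errors above a 1% rate
#' abort the build.
#'
#' @param models list of `demographic_model` objects (or model names).
#' @param priors either a single prior spec used for every model or a named
#'   list of specs, one per model name; `NULL` uses [default_priors()].
#' @param n_sims_per_model simulations per model.
#' @param master_seed integer master seed (< 2^31).
#' @param sample_sizes named diploid sample sizes.
#' @param n_chrom,snps_per_chrom,maf_min forwarded to [simulate_dataset()].
#' @param progress print a progress line every 1000 simulations.
#' @return A `data.frame` of class `reference_table`: columns `sim_id`,
#'   `model`, `seed`, the union of parameter columns (NA where a parameter
#'   does not belong to a row's model) and `ss_*` statistic columns.
#' @export
build_reference_table <- function(models, priors = NULL, n_sims_per_model,
                                  master_seed, sample_sizes = NULL,
                                  n_chrom = 5L, snps_per_chrom = 200L,
                                  maf_min = 0.05, progress = FALSE) {
  stopifnot(n_sims_per_model >= 1)
  models <- lapply(models, function(m)
    if (inherits(m, "demographic_model")) m
    else build_model(m, if (is.null(sample_sizes)) sample_profile("full")
                     else sample_sizes))
  if (!is.null(sample_sizes))
    models <- lapply(models, function(m) { m$sample_sizes <- sample_sizes; m })
  model_names <- vapply(models, `[[`, "", "name")
  per_model_priors <- !is.null(priors) &&
    all(names(priors) %in% c("mesoamerican", "phi", "protovulgaris"))
  get_prior <- function(nm, model) {
    if (is.null(priors)) return(default_priors(model))
    if (per_model_priors) return(priors[[nm]])
    priors
  }
  n_total <- n_sims_per_model * length(models)
  set.seed(master_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, 8L * n_total + 1000L)
  rows <- vector("list", n_total)
  # two failure classes: hard simulation errors abort above 1%; draws whose
  # statistics are undefined (e.g. a deme monomorphic in the sample, so
  # Tajima's D does not exist) are re-drawn and logged -- the table
  # conditions on datasets with defined summaries
  errors <- 0L; redraws <- 0L; seed_cursor <- n_total
  r <- 0L
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    spec <- get_prior(model$name, model)
    for (s in seq_len(n_sims_per_model)) {
      r <- r + 1L
      seed_r <- seeds[r]
      repeat {
        set.seed(seed_r)
        params <- sample_prior(spec, model)
        ss <- tryCatch({
          ds <- simulate_dataset(model, params, n_chrom = n_chrom,
                                 snps_per_chrom = snps_per_chrom,
                                 maf_min = maf_min)
          sumstat_vector(ds$gm, pops = c("MW", "AW", "PhI"),
                         allow_missing = TRUE)
        }, error = function(e) {
          errors <<- errors + 1L
          if (errors > max(10, 0.01 * n_total))
            stop("simulation failure rate > 1% (", errors, " errors over ",
                 r, " rows); last error: ", conditionMessage(e))
          NULL
        })
        if (!is.null(ss) && !anyNA(ss)) break
        if (!is.null(ss)) redraws <- redraws + 1L
        seed_cursor <- seed_cursor + 1L
        if (seed_cursor > length(seeds))
          stop("exhausted replacement seeds (", redraws,
               " re-draws, ", errors, " errors)")
        seed_r <- seeds[seed_cursor]
      }
      rows[[r]] <- c(list(sim_id = r, model = model$name, seed = seed_r),
                     as.list(params), as.list(ss))
      if (progress && r %% 1000L == 0L)
        message("  simulated ", r, "/", n_total, " (", redraws,
                " re-draws)")
    }
  }
  all_params <- unique(unlist(lapply(models, `[[`, "param_names")))
  ss_names <- names(rows[[1]])[-seq_len(3 + length(models[[1]]$param_names))]
  cols <- c("sim_id", "model", "seed", all_params, ss_names)
  out <- as.data.frame(matrix(NA, n_total, length(cols),
                              dimnames = list(NULL, cols)))
  out$model <- vapply(rows, `[[`, "", "model")
  for (cn in setdiff(cols, "model"))
    out[[cn]] <- vapply(rows, function(x)
      if (is.null(x[[cn]])) NA_real_ else as.numeric(x[[cn]]), numeric(1))
  names(out)[names(out) %in% ss_names] <- paste0("ss_", ss_names)
  attr(out, "n_redraws") <- redraws
  attr(out, "n_errors") <- errors
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Identify the statistic columns of a reference table
#' @param ref a reference table (or data.frame with `ss_` columns).
#' @return Character vector of statistic column names.
#' @export
stat_cols <- function(ref) grep("^ss_", names(ref), value = TRUE)

#' Write / read a reference table as TSV
#'
#' The table is persisted as plain TSV (header = column names); a JSON
#' sidecar `<path>.meta.json` records provenance handed in via `meta`.
#' @param ref reference table.
#' @param path output TSV path.
#' @param meta named list written to the sidecar (seeds, priors, configs).
#' @export
write_reference_table <- function(ref, path, meta = list()) {
  utils::write.table(ref, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(meta))
    jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  out <- utils::read.delim(path, check.names = FALSE)
  class(out) <- c("reference_table", "data.frame")
  out
}
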