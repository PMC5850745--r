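# Single-deme helper model used for neutral-theory checks
single_deme_model <- function(n_diploid, N) {
  m <- build_model("mesoamerican",
                   c(MW = n_diploid, AW = 1L, PhI = 1L))
  # push the splits far beyond any coalescence of interest
  p <- c(N_MW = N, N_AW = N, N_PhI = N, T1 = 1e12, T2 = 2e12,
         bottleneck_dur = 1, NF_AW = N, NF_PhI = N)
  list(model = m, params = p)
}

test_that("pairwise coalescence time has mean 2N (Monte-Carlo)", {
  sd1 <- single_deme_model(1L, 500)
  set.seed(41)
  tm <- replicate(2000, {
    g <- simulate_genealogy(sd1$model, sd1$params,
                            sample_sizes = c(MW = 1L, AW = 0L, PhI = 0L))
    max(g$times)
  })
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2 * 500), 3 * se)
})

test_that("total branch length follows the Watterson expectation (n = 10)", {
  N <- 1000
  set.seed(42)
  sd1 <- single_deme_model(5L, N)   # 10 haploid lineages
  tbl <- replicate(2000, simulate_genealogy(
    sd1$model, sd1$params,
    sample_sizes = c(MW = 5L, AW = 0L, PhI = 0L))$total_branch_length)
  expected <- 4 * N * sum(1 / seq_len(9))
  se <- stats::sd(tbl) / sqrt(length(tbl))
  expect_lt(abs(mean(tbl) - expected), 3 * se)
})

test_that("drop_snps: ascertainment contract and two-lineage case", {
  sd1 <- single_deme_model(5L, 1000)
  set.seed(43)
  g <- simulate_genealogy(sd1$model, sd1$params,
                          sample_sizes = c(MW = 5L, AW = 0L, PhI = 0L))
  hap <- drop_snps(g, 500, maf_min = 0.2)
  freq <- rowMeans(hap)
  expect_true(all(pmin(freq, 1 - freq) >= 0.2))
  expect_equal(dim(hap), c(500L, 10L))
  # n = 2 haplotypes: every SNP has MAF 0.5
  g2 <- simulate_genealogy(sd1$model, sd1$params,
                           sample_sizes = c(MW = 1L, AW = 0L, PhI = 0L))
  hap2 <- drop_snps(g2, 50, maf_min = 0.05)
  expect_true(all(rowMeans(hap2) == 0.5))
  # impossible threshold errors after bounded retries
  expect_error(drop_snps(g2, 10, maf_min = 0.6, max_tries = 100),
               "ascertainment failed")
})

test_that("simulate_dataset: shape, determinism, exchangeability", {
  m <- build_model("mesoamerican", sample_profile("reduced"))
  p <- preset_params("table3-like", m)
  set.seed(44)
  ds <- simulate_dataset(m, p)
  expect_equal(nrow(ds$gm$calls), 1000L)   # 5 x 200 SNP columns
  expect_equal(ncol(ds$gm$calls), 36L)
  expect_equal(sort(unique(ds$gm$chrom)), paste0("chr", 1:5))
  # same seed, bit-identical
  set.seed(44)
  ds2 <- simulate_dataset(m, p)
  expect_identical(ds$gm$calls, ds2$gm$calls)
  expect_identical(ds$gm$pos, ds2$gm$pos)
  # permuting individuals within demes leaves the summary vector unchanged
  ss <- sumstat_vector(ds$gm)
  perm <- unlist(lapply(unique(ds$gm$pop_labels), function(pp) {
    i <- which(ds$gm$pop_labels == pp); sample(i)
  }))
  expect_equal(sumstat_vector(gm_subset(ds$gm, j = perm)), ss)
})

test_that("limit checks: vanishing splits recover a single population", {
  # T1 = T2 -> 0 with equal sizes and no bottleneck: Fst ~ 0 and pi equal
  # across demes
  m <- build_model("mesoamerican", sample_profile("reduced"))
  N <- 5000
  p <- c(N_MW = N, N_AW = N, N_PhI = N, T1 = 1, T2 = 2,
         bottleneck_dur = 1, NF_AW = N, NF_PhI = N)
  set.seed(45)
  fst <- pi_ratio <- numeric(30)
  for (r in 1:30) {
    ds <- simulate_dataset(m, p, n_chrom = 2, snps_per_chrom = 100)
    ss <- sumstat_vector(ds$gm, allow_missing = TRUE)
    fst[r] <- ss["fst_MW_AW"]
    pi_ratio[r] <- ss["pi_MW"] / ss["pi_AW"]
  }
  expect_lt(abs(mean(fst)), 0.03)
  expect_lt(abs(mean(pi_ratio) - 1), 0.1)
})

test_that("Fst increases monotonically with divergence time (Monte-Carlo)", {
  m <- build_model("mesoamerican", sample_profile("reduced"))
  N <- 2000
  t_grid <- c(500, 4000, 20000)
  set.seed(46)
  fst_mean <- vapply(t_grid, function(T1) {
    mean(replicate(60, {
      p <- c(N_MW = N, N_AW = N, N_PhI = N, T1 = T1, T2 = 5e4,
             bottleneck_dur = 1, NF_AW = N, NF_PhI = N)
      ds <- simulate_dataset(m, p, n_chrom = 2, snps_per_chrom = 100)
      sumstat_vector(ds$gm, allow_missing = TRUE)["fst_MW_AW"]
    }), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(fst_mean) > 0))
})

test_that("reference table: bookkeeping, reproducibility, consistency", {
  sizes <- sample_profile("reduced")
  tab <- build_reference_table(list("mesoamerican", "phi", "protovulgaris"),
                               NULL, n_sims_per_model = 10, master_seed = 7,
                               sample_sizes = sizes, n_chrom = 2,
                               snps_per_chrom = 50)
  expect_equal(nrow(tab), 30L)
  expect_equal(as.integer(table(tab$model)), rep(10L, 3))
  expect_false(anyNA(tab[, stat_cols(tab)]))
  tab2 <- build_reference_table(list("mesoamerican", "phi", "protovulgaris"),
                                NULL, n_sims_per_model = 10, master_seed = 7,
                                sample_sizes = sizes, n_chrom = 2,
                                snps_per_chrom = 50)
  expect_identical(tab, tab2)
  # statistics columns equal popgen stats on the regenerated dataset
  row <- tab[17, ]
  model <- build_model(row$model, sizes)
  prm <- unlist(row[model$param_names])
  set.seed(row$seed)
  prm_redraw <- sample_prior(default_priors(model), model)
  expect_equal(unname(prm), unname(prm_redraw))
  ds <- simulate_dataset(model, prm_redraw, n_chrom = 2, snps_per_chrom = 50)
  ss <- sumstat_vector(ds$gm, allow_missing = TRUE)
  expect_equal(unname(unlist(row[paste0("ss_", names(ss))])), unname(ss))
  # round trip through TSV
  f <- tempfile(fileext = ".tsv")
  write_reference_table(tab, f, meta = list(seed = 7))
  back <- read_reference_table(f)
  expect_equal(back$ss_pi_MW, tab$ss_pi_MW)
  expect_true(file.exists(paste0(f, ".meta.json")))
})

test_that("single-lineage and degenerate inputs error cleanly", {
  m <- build_model("mesoamerican", sample_profile("reduced"))
  p <- preset_params("table3-like", m)
  g1 <- simulate_genealogy(m, p, sample_sizes = c(MW = 0L, AW = 0L, PhI = 1L))
  # 2 haploid leaves from one diploid: still a genealogy; a single haploid
  # lineage cannot host SNPs
  expect_equal(g1$n_leaves, 2L)
  expect_error(simulate_genealogy(m, p,
                                  sample_sizes = c(MW = 0L, AW = 0L,
                                                   PhI = 0L)),
               "no lineages")
})
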