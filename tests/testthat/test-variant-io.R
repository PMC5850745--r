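test_that("read_vcf parses a toy VCF with GQ/DP and population map", {
  f <- write_toy_vcf_file()
  pm <- data.frame(sample_id = c("s1", "s2"), population = c("MW", "AW"))
  gm <- read_vcf(f, pm)
  expect_s3_class(gm, "genotype_matrix")
  expect_equal(dim(gm), c(5L, 3L))
  expect_equal(gm$pop_labels, c("MW", "AW", "unassigned"))
  expect_equal(gm$calls[1, ], c(s1 = 0L, s2 = 1L, s3 = 2L))
  expect_true(is.na(gm$calls[2, 3]))          # ./. call
  expect_equal(gm$gq[1, 2], 88)
  expect_equal(gm$dp[4, 1], 40)
  # multiallelic record retained and flagged; out-of-range allele masked
  expect_equal(gm$multiallelic, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_true(is.na(gm$calls[3, 1]))          # 0/2 genotype
  expect_equal(gm$calls[3, 2], 1L)
})

test_that("read_vcf errors carry structure information", {
  lines <- toy_vcf_text()
  lines[7] <- "chr1\t200\tbroken"
  f <- write_toy_vcf_file(lines)
  expect_error(read_vcf(f), "line 7")
  lines <- toy_vcf_text()
  lines[5] <- sub("s3", "s1", lines[5])
  f2 <- write_toy_vcf_file(lines)
  expect_error(read_vcf(f2), "duplicated sample id")
})

test_that("write_vcf / read_vcf round-trips byte-identically", {
  f <- write_toy_vcf_file()
  gm <- read_vcf(f)
  # normalize once through the writer, then round-trip
  norm1 <- tempfile(fileext = ".vcf")
  write_vcf(gm, norm1)
  norm2 <- tempfile(fileext = ".vcf")
  write_vcf(read_vcf(norm1), norm2)
  expect_identical(readLines(norm1), readLines(norm2))
})

test_that("filter steps behave per configuration", {
  f <- write_toy_vcf_file()
  gm <- read_vcf(f)
  res <- apply_filters(gm, filter_config(min_gq = 10, min_dp = 3,
                                         max_indiv_missing = 1,
                                         max_site_missing = 1, min_maf = 0))
  # only the multiallelic site is removed
  expect_equal(res$report$sites_removed[2], 1L)
  expect_equal(nrow(res$gm$calls), 4L)
  expect_false(any(res$gm$multiallelic))
  # MAF boundary: alt frequency 0.04 < 0.05 removed, 0.05 kept (inclusive)
  n_ind <- 25
  calls <- matrix(0L, 2, n_ind)
  calls[1, 1] <- 2L                        # freq 2/50 = 0.04
  calls[2, 1] <- 2L; calls[2, 2] <- 1L     # freq 3/50 = 0.06 -> keep
  gm2 <- genotype_matrix(rep("chr1", 2), c(10L, 20L), rep("A", 2),
                         rep("T", 2), calls, sprintf("i%02d", 1:n_ind),
                         rep("p", n_ind))
  res2 <- apply_filters(gm2, filter_config(min_maf = 0.05))
  expect_equal(nrow(res2$gm$calls), 1L)
  expect_equal(res2$report$sites_removed[5], 1L)
  # dp_strict switches DP >= 3 to DP > 3
  gm3 <- read_vcf(f)
  res3 <- apply_filters(gm3, filter_config(min_dp = 20, dp_strict = TRUE,
                                           max_indiv_missing = 1,
                                           max_site_missing = 1, min_maf = 0))
  expect_true(is.na(res3$gm$calls[1, 3]))  # DP 20 masked under strict rule
})

test_that("filter chain matches a hand-tallied fixture", {
  # 20 sites x 6 individuals, planted failures, tallied by hand:
  # site 3 multiallelic (removed step 2); sites 4-5 monomorphic (MAF 0,
  # removed step 5); site 6 missing for ind1+ind2, i.e. 2/5 among
  # survivors (> 0.2, removed step 4); individual 6 missing at sites 1-2,
  # i.e. 2/19 post-biallelic sites (> 0.1, removed step 3); one low-GQ
  # call masked at site 4 (a site removed later anyway, so nothing
  # cascades: every survivor ends with <= 1/19 missing and clean sites
  # keep 0 missing).
  calls <- matrix(rep(c(0L, 0L, 1L, 1L, 2L, 2L), 20), 20, 6, byrow = TRUE)
  calls[4, ] <- 0L
  calls[5, ] <- 0L
  calls[6, c(1, 2)] <- NA_integer_
  calls[c(1, 2), 6] <- NA_integer_
  gq <- matrix(99, 20, 6); gq[4, 3] <- 5
  multi <- rep(FALSE, 20); multi[3] <- TRUE
  gm <- genotype_matrix(rep("chr1", 20), seq(100L, by = 100L, length.out = 20),
                        rep("A", 20), rep("T", 20), calls,
                        sprintf("i%d", 1:6), rep("p", 6), gq = gq,
                        multiallelic = multi)
  res <- apply_filters(gm, filter_config())
  expect_equal(res$report$calls_masked[1], 1L)
  expect_equal(res$report$sites_removed[2], 1L)   # multiallelic
  expect_equal(res$report$indivs_removed[3], 1L)  # individual 6
  expect_equal(res$report$sites_removed[4], 1L)   # site 6
  expect_equal(res$report$sites_removed[5], 2L)   # monomorphic 4, 5
  expect_equal(dim(res$gm), c(16L, 5L))
})

test_that("apply_filters is idempotent and counts sum (property)", {
  set.seed(71)
  for (rep in 1:15) {
    toy <- make_toy_vcf(n_sites = sample(12:25, 1), n_indiv = sample(6:12, 1),
                        planted_defects = sample(c("multiallelic", "low_maf",
                                                   "missingness", "low_gq",
                                                   "low_dp"),
                                                 sample(0:5, 1)),
                        seed = sample.int(1e6, 1))
    res <- apply_filters(toy$gm, filter_config())
    expect_equal(nrow(toy$gm$calls),
                 nrow(res$gm$calls) + sum(res$report$sites_removed))
    res2 <- apply_filters(res$gm, filter_config())
    expect_equal(sum(res2$report$sites_removed), 0L)
    expect_equal(sum(res2$report$indivs_removed), 0L)
    expect_equal(res2$report$calls_masked[1], 0L)
    expect_identical(res2$gm$calls, res$gm$calls)
  }
})

test_that("empty cohort and bad config error", {
  gm <- rand_gm(5, c(A = 3), miss = 0)
  gm$calls[] <- NA_integer_
  expect_error(apply_filters(gm, filter_config()), "empty cohort")
  expect_error(filter_config(max_site_missing = 1.2), "config error")
  expect_error(filter_config(min_maf = 0.7), "config error")
})
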