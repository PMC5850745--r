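test_that("nucleotide diversity: trivial cases", {
  # monomorphic
  gm <- hap_to_gm(matrix(0L, 10, 4))
  expect_equal(nucleotide_diversity(gm, "toy"), 0)
  # 2 haplotypes (one diploid individual) differing at 1 of 100 sites
  hap <- matrix(0L, 100, 2)
  hap[1, 2] <- 1L
  gm2 <- hap_to_gm(hap)
  expect_equal(nucleotide_diversity(gm2, "toy", span = 100), 0.01)
  expect_error(nucleotide_diversity(gm2, "toy", span = 0), "span")
  expect_error(nucleotide_diversity(gm2, "nope"), "not present")
})

test_that("pi matches the all-pairs brute-force oracle (20+ fixtures)", {
  set.seed(11)
  for (r in 1:20) {
    hap <- rand_hap(sample(5:15, 1), 2 * sample(3:8, 1))
    gm <- hap_to_gm(hap)
    span <- nrow(hap)
    expect_equal(nucleotide_diversity(gm, "toy", span = span),
                 oracle_pi(gm$calls, span), tolerance = 1e-12)
  }
  # with missing data (allele-copy oracle handles NA individuals sitewise)
  for (r in 1:10) {
    gm <- rand_gm(12, c(A = 6), miss = 0.15)
    expect_equal(nucleotide_diversity(gm, "A"),
                 oracle_pi(gm$calls, nrow(gm$calls)), tolerance = 1e-12)
  }
})

test_that("Tajima's D: undefined, worked example, oracle fixtures", {
  gm <- hap_to_gm(matrix(0L, 10, 4))
  expect_warning(d <- tajimas_d(gm, "toy"), "undefined")
  expect_true(is.na(d))
  # 4 haplotypes, 3 segregating sites at derived counts {1, 2, 1}
  hap <- matrix(0L, 3, 4)
  hap[1, 1] <- 1L
  hap[2, c(1, 2)] <- 1L
  hap[3, 4] <- 1L
  gm2 <- hap_to_gm(hap)
  expect_equal(tajimas_d(gm2, "toy"), oracle_tajima_hap(hap),
               tolerance = 1e-12)
  set.seed(12)
  for (r in 1:20) {
    hap <- rand_hap(sample(4:20, 1), 2 * sample(3:10, 1))
    expect_equal(tajimas_d(hap_to_gm(hap), "toy"), oracle_tajima_hap(hap),
                 tolerance = 1e-12)
  }
})

test_that("Weir-Cockerham Fst: fixation, self-copy, closed form, oracle", {
  # complete fixation, no missing data
  callsA <- matrix(2L, 50, 5); callsB <- matrix(0L, 50, 5)
  gm <- genotype_matrix(rep("chr1", 50), seq_len(50) * 10L, rep("A", 50),
                        rep("T", 50), cbind(callsA, callsB),
                        sprintf("i%02d", 1:10), rep(c("A", "B"), each = 5))
  expect_equal(fst_weir_cockerham(gm, "A", "B"), 1)
  # popB an exact copy of popA
  set.seed(13)
  base <- hap_to_gm(rand_hap(250, 32))$calls  # 16 diploids in HWE
  gm2 <- genotype_matrix(rep("chr1", 250), seq_len(250) * 7L, rep("A", 250),
                         rep("T", 250), cbind(base, base),
                         sprintf("i%02d", 1:32), rep(c("A", "B"), each = 16))
  expect_lt(abs(fst_weir_cockerham(gm2, "A", "B")), 0.05)
  # single site, 10 allele copies each: 8 alt vs 2 alt
  gA <- matrix(c(2L, 2L, 2L, 1L, 1L), 1, 5)
  gB <- matrix(c(1L, 1L, 0L, 0L, 0L), 1, 5)
  gm3 <- genotype_matrix("chr1", 100L, "A", "T", cbind(gA, gB),
                         sprintf("i%02d", 1:10), rep(c("A", "B"), each = 5))
  expect_equal(fst_weir_cockerham(gm3, "A", "B"), oracle_fst_wc(gA, gB),
               tolerance = 1e-12)
  # randomized fixtures incl. missing data
  for (r in 1:20) {
    gm4 <- rand_gm(sample(10:40, 1), c(A = sample(4:8, 1), B = sample(4:8, 1)),
                   miss = 0.1)
    iA <- which(gm4$pop_labels == "A"); iB <- which(gm4$pop_labels == "B")
    expect_equal(fst_weir_cockerham(gm4, "A", "B"),
                 oracle_fst_wc(gm4$calls[, iA, drop = FALSE],
                               gm4$calls[, iB, drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("Fst is symmetric and ~0 against itself; pi/H ref-alt invariant", {
  set.seed(14)
  gm <- rand_gm(300, c(A = 6, B = 6), miss = 0.05)
  expect_equal(fst_weir_cockerham(gm, "A", "B"),
               fst_weir_cockerham(gm, "B", "A"))
  # allele relabeling: dosage d -> 2 - d
  gm_flip <- gm
  gm_flip$calls <- 2L - gm$calls
  expect_equal(nucleotide_diversity(gm_flip, "A"),
               nucleotide_diversity(gm, "A"))
  expect_equal(suppressWarnings(tajimas_d(gm_flip, "A")),
               suppressWarnings(tajimas_d(gm, "A")))
})

test_that("binned_scan honours the bin qualification rule", {
  # 3 bins with variant counts {5, 2, 4}: middle bin absent
  pos <- c(1e4 * 1:5, 1e5 + c(2e4, 5e4), 2e5 + 1e4 * 1:4)
  set.seed(15)
  calls <- matrix(sample(0:2, length(pos) * 8, TRUE), length(pos), 8)
  gm <- genotype_matrix(rep("chr1", length(pos)), as.integer(pos),
                        rep("A", length(pos)), rep("T", length(pos)), calls,
                        sprintf("i%d", 1:8), rep(c("A", "B"), each = 4))
  sc <- binned_scan(gm, bin = 1e5, min_variants = 3, pops = c("A", "B"))
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$n_variants, c(5L, 4L))
  gmean <- attr(sc, "genome_mean")
  expect_equal(unname(gmean["pi_A"]), mean(sc$pi_A))
  # all variants in one bin -> exactly one row
  gm_one <- gm_subset(gm, i = 1:5)
  sc_one <- binned_scan(gm_one, bin = 1e5, pops = c("A", "B"))
  expect_equal(nrow(sc_one), 1L)
  # bin with only 2 variants -> empty result allowed
  sc_empty <- binned_scan(gm_subset(gm, i = 6:7), bin = 1e5,
                          pops = c("A", "B"))
  expect_equal(nrow(sc_empty), 0L)
})

test_that("n50 matches examples and brute force", {
  expect_equal(n50(42), 42)
  expect_equal(n50(c(4, 3, 3, 2, 2, 2)), 3)
  expect_error(n50(numeric(0)), "empty")
  expect_error(n50(c(3, -1)), "positive")
  set.seed(16)
  for (r in 1:25) {
    lens <- sample(1:500, sample(1:30, 1), replace = TRUE)
    expect_equal(n50(lens), oracle_n50(lens))
  }
})

test_that("sumstat vector: order, degenerate input, internal consistency", {
  set.seed(17)
  gm <- rand_gm(60, c(MW = 6, AW = 5, PhI = 4))
  ss <- sumstat_vector(gm, pops = c("MW", "AW", "PhI"))
  expect_equal(names(ss),
               c("S_MW", "pi_MW", "H_MW", "D_MW", "S_AW", "pi_AW", "H_AW",
                 "D_AW", "S_PhI", "pi_PhI", "H_PhI", "D_PhI", "fst_MW_AW",
                 "fst_MW_PhI", "fst_AW_PhI", "S_all", "H_all"))
  # components equal the standalone operations
  expect_equal(unname(ss["pi_AW"]), nucleotide_diversity(gm, "AW"))
  expect_equal(unname(ss["D_MW"]), tajimas_d(gm, "MW"))
  expect_equal(unname(ss["fst_MW_PhI"]), fst_weir_cockerham(gm, "MW", "PhI"))
  # stable under individual shuffling
  perm <- sample(ncol(gm$calls))
  gm_sh <- gm_subset(gm, j = perm)
  expect_equal(sumstat_vector(gm_sh, pops = c("MW", "AW", "PhI")), ss)
  # monomorphic dataset
  gm0 <- hap_to_gm(matrix(0L, 10, 12), c(MW = 2, AW = 2, PhI = 2))
  ss0 <- suppressWarnings(sumstat_vector(gm0, pops = c("MW", "AW", "PhI"),
                                         allow_missing = TRUE))
  expect_equal(unname(ss0[c("S_MW", "pi_MW", "H_MW", "S_all")]),
               c(0, 0, 0, 0))
  expect_true(is.na(ss0["D_MW"]) && is.na(ss0["fst_MW_AW"]))
  # fewer than 2 individuals errors
  expect_error(sumstat_vector(gm_subset(gm, j = c(1, 7, 8)),
                              pops = c("MW", "AW")), "fewer than 2")
})
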