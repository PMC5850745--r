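# Fixture builders used across test files (all generated in code).

# random complete-data haplotype matrix, every site polymorphic
rand_hap <- function(n_sites, n_hap) {
  hap <- matrix(0L, n_sites, n_hap)
  for (s in seq_len(n_sites)) {
    k <- sample(seq_len(n_hap - 1), 1)
    hap[s, sample(n_hap, k)] <- 1L
  }
  hap
}

# pair haplotype columns into diploid individuals and wrap as a
# genotype_matrix with the given population labels (recycled per block)
hap_to_gm <- function(hap, pop_sizes = c(toy = ncol(hap) / 2)) {
  stopifnot(ncol(hap) %% 2 == 0)
  odd <- seq(1, ncol(hap), by = 2)
  calls <- hap[, odd, drop = FALSE] + hap[, odd + 1, drop = FALSE]
  pops <- rep(names(pop_sizes), pop_sizes)
  genotype_matrix(chrom = rep("chr1", nrow(hap)),
                  pos = seq(100L, by = 101L, length.out = nrow(hap)),
                  ref = rep("A", nrow(hap)), alt = rep("T", nrow(hap)),
                  calls = calls,
                  sample_ids = sprintf("s%03d", seq_along(pops)),
                  pop_labels = pops)
}

# random diploid genotype matrix with optional missingness
rand_gm <- function(n_sites, pop_sizes = c(A = 5, B = 5), miss = 0) {
  n_ind <- sum(pop_sizes)
  calls <- matrix(sample(0:2, n_sites * n_ind, TRUE,
                         prob = c(0.45, 0.2, 0.35)),
                  n_sites, n_ind)
  if (miss > 0)
    calls[matrix(stats::runif(length(calls)) < miss, n_sites, n_ind)] <-
      NA_integer_
  genotype_matrix(chrom = rep("chr1", n_sites),
                  pos = seq(50L, by = 97L, length.out = n_sites),
                  ref = rep("A", n_sites), alt = rep("C", n_sites),
                  calls = calls,
                  sample_ids = sprintf("i%03d", seq_len(n_ind)),
                  pop_labels = rep(names(pop_sizes), pop_sizes))
}

# tiny in-memory VCF text fixture
toy_vcf_text <- function() {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read Depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "s1", "s2", "s3"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT:GQ:DP\t0/0:99:30\t0/1:88:25\t1/1:77:20",
    "chr1\t200\t.\tC\tG\t.\tPASS\t.\tGT:GQ:DP\t0/1:60:10\t0/0:50:12\t./.:.:.",
    "chr1\t300\t.\tG\tA,C\t.\tPASS\t.\tGT:GQ:DP\t0/2:90:30\t0/1:90:30\t0/0:90:30",
    "chr1\t400\t.\tT\tC\t.\tPASS\t.\tGT:GQ:DP\t1/1:95:40\t0/1:95:33\t0/0:95:31",
    "chr2\t150\t.\tA\tG\t.\tPASS\t.\tGT:GQ:DP\t0/0:99:30\t0/0:98:28\t0/1:97:26")
}

write_toy_vcf_file <- function(lines = toy_vcf_text()) {
  f <- tempfile(fileext = ".vcf")
  writeLines(lines, f)
  f
}
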