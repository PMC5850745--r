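# Independent brute-force oracles. These deliberately share no code with
# the implementation under test: plain loops and direct transcriptions of
# published formulas.

# expand a dosage matrix into allele copies per site (list of 0/1 vectors,
# missing individuals dropped sitewise)
allele_copies <- function(calls) {
  lapply(seq_len(nrow(calls)), function(s) {
    g <- calls[s, ]
    g <- g[!is.na(g)]
    unlist(lapply(g, function(d) switch(as.character(d),
                                        "0" = c(0L, 0L),
                                        "1" = c(0L, 1L),
                                        "2" = c(1L, 1L))))
  })
}

# mean over all pairs of allele copies of per-site differences, summed over
# sites, divided by span
oracle_pi <- function(calls, span) {
  total <- 0
  for (copies in allele_copies(calls)) {
    n <- length(copies)
    if (n < 2) next
    diff_sum <- 0
    for (i in seq_len(n - 1))
      for (j in (i + 1):n)
        diff_sum <- diff_sum + as.integer(copies[i] != copies[j])
    total <- total + diff_sum / choose(n, 2)
  }
  total / span
}

# Tajima (1989) D, direct transcription, complete-data haplotype matrix
# (sites x haplotypes, 0/1)
oracle_tajima_hap <- function(hap) {
  n <- ncol(hap)
  seg <- apply(hap, 1, function(x) sum(x) > 0 && sum(x) < n)
  S <- sum(seg)
  if (S == 0) return(NA_real_)
  k_hat <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      k_hat <- k_hat + sum(hap[, i] != hap[, j])
  k_hat <- k_hat / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (k_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# Weir & Cockerham (1984) theta for two pops, scalar per-site loop
oracle_fst_wc <- function(callsA, callsB) {
  num <- den <- 0
  for (s in seq_len(nrow(callsA))) {
    gA <- callsA[s, ]; gA <- gA[!is.na(gA)]
    gB <- callsB[s, ]; gB <- gB[!is.na(gB)]
    n1 <- length(gA); n2 <- length(gB)
    if (n1 < 1 || n2 < 1 || n1 + n2 < 3) next
    p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
    h1 <- sum(gA == 1) / n1; h2 <- sum(gB == 1) / n2
    r <- 2
    nbar <- (n1 + n2) / r
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    if (pbar <= 0 || pbar >= 1) next
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  if (den <= 0) NA_real_ else num / den
}

# brute-force N50: scan candidate thresholds
oracle_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  best <- NA_real_
  for (L in cand)
    if (sum(lengths[lengths >= L]) >= total / 2) { best <- L; break }
  best
}

# brute-force HPD: all windows of ceiling(level*n) consecutive order stats
oracle_hpd <- function(draws, level = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- min(ceiling(level * n), n)
  best <- c(x[1], x[n]); bw <- Inf
  for (i in seq_len(n - m + 1)) {
    w <- x[i + m - 1] - x[i]
    if (w < bw) { bw <- w; best <- c(x[i], x[i + m - 1]) }
  }
  best
}

# all-pairs distance classification of SNP positions vs features
oracle_classify <- function(pos, features, min_dist = 5000) {
  vapply(pos, function(x) {
    d_min <- Inf; inside <- FALSE
    for (i in seq_len(nrow(features))) {
      if (x >= features$start[i] && x <= features$end[i]) inside <- TRUE
      d <- if (x < features$start[i]) features$start[i] - x
           else if (x > features$end[i]) x - features$end[i] else 0
      d_min <- min(d_min, d)
    }
    if (inside) "genic" else if (d_min >= min_dist) "neutral"
    else "intermediate"
  }, character(1))
}
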