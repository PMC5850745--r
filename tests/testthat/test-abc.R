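# synthetic reference tables built directly (no simulator) so the ABC
# machinery is tested against analytically controlled inputs
fake_ref <- function(n_per_model, centers, sd = 1, models = names(centers),
                     n_stats = length(centers[[1]])) {
  rows <- lapply(models, function(m) {
    X <- matrix(stats::rnorm(n_per_model * n_stats, sd = sd),
                n_per_model, n_stats)
    X <- sweep(X, 2, centers[[m]], "+")
    d <- as.data.frame(X)
    names(d) <- paste0("ss_stat", seq_len(n_stats))
    cbind(data.frame(model = m, theta = stats::runif(n_per_model)), d)
  })
  out <- do.call(rbind, rows)
  out$sim_id <- seq_len(nrow(out))
  class(out) <- c("reference_table", "data.frame")
  out
}

test_that("standardize: MAD oracle, constant columns, scale invariance", {
  set.seed(61)
  ref <- fake_ref(200, list(A = c(0, 0, 5), B = c(1, 0, -5)))
  ref$ss_stat2 <- 3            # constant column
  obs <- c(stat1 = 0.5, stat2 = 3, stat3 = 1)
  expect_warning(z <- standardize(ref, obs), "constant")
  expect_equal(z$cols, c("ss_stat1", "ss_stat3"))
  for (cc in z$cols) {
    x <- ref[[cc]]
    expect_equal(unname(z$scale[cc]), median(abs(x - median(x))))
  }
  # rescaling a column by 10 leaves distances unchanged
  ref10 <- ref
  ref10$ss_stat1 <- ref$ss_stat1 * 10
  obs10 <- obs; obs10["stat1"] <- obs["stat1"] * 10
  d1 <- suppressWarnings(rejection_sample(ref, obs, 0.1))
  d2 <- suppressWarnings(rejection_sample(ref10, obs10, 0.1))
  expect_equal(d1$idx, d2$idx)
  expect_equal(d1$dist, d2$dist)
  expect_error(standardize(ref, c(zzz = 1)), "no overlapping")
})

test_that("rejection sampling: acceptance counts, determinism, exact match", {
  set.seed(62)
  ref <- fake_ref(500, list(A = c(0, 0), B = c(3, 3)))
  obs <- c(stat1 = 0, stat2 = 0)
  # eps = 1 accepts everything
  expect_equal(rejection_sample(ref, obs, 1)$n_accepted, 1000L)
  # floor(eps * n) exact, including the study-scale arithmetic
  expect_equal(rejection_sample(ref, obs, 0.0132)$n_accepted,
               floor(0.0132 * 1000))
  big <- data.frame(model = "A",
                    ss_s1 = stats::rnorm(1010101), ss_s2 = stats::rnorm(1010101))
  class(big) <- c("reference_table", "data.frame")
  expect_equal(rejection_sample(big, c(s1 = 0, s2 = 0), 0.01)$n_accepted,
               10101L)
  rm(big)
  expect_error(rejection_sample(ref, obs, 1e-5), "tolerance too small")
  expect_error(rejection_sample(ref, obs, 0), "tolerance")
  # an observation equal to one simulation is always accepted at distance 0
  obs_hit <- c(stat1 = ref$ss_stat1[77], stat2 = ref$ss_stat2[77])
  acc <- rejection_sample(ref, obs_hit, 0.005)
  expect_true(77 %in% acc$idx)
  expect_equal(min(acc$dist), 0)
  # row shuffling: same accepted set (no ties here)
  perm <- sample(nrow(ref))
  ref_sh <- ref[perm, ]
  acc1 <- rejection_sample(ref, obs, 0.02)
  acc2 <- rejection_sample(ref_sh, obs, 0.02)
  expect_setequal(perm[acc2$idx], acc1$idx)
  # decreasing eps never increases the acceptance radius
  radii <- vapply(c(0.5, 0.2, 0.1, 0.02),
                  function(e) max(rejection_sample(ref, obs, e)$dist),
                  numeric(1))
  expect_true(all(diff(radii) <= 0))
})

test_that("rejection model posterior: prior recovery and separable models", {
  set.seed(63)
  ref <- fake_ref(300, list(A = c(0, 0), B = c(0, 0), C = c(0, 0)))
  mp <- model_posterior_rejection(ref, c(stat1 = 0, stat2 = 0), 1)
  expect_equal(unname(mp$PP), rep(1 / 3, 3))
  expect_equal(sum(mp$PP), 1)
  # two models 10 robust-SDs apart: obs from A recovered
  hits <- replicate(100, {
    ref2 <- fake_ref(150, list(A = c(0, 0), B = c(30, 30)), sd = 2)
    obs <- c(stat1 = rnorm(1, 0, 2), stat2 = rnorm(1, 0, 2))
    pp <- model_posterior_rejection(ref2, obs, 0.1)$PP
    pp["A"] >= 0.95
  })
  expect_gte(mean(hits), 0.95)
})

test_that("mnlogistic: uninformative limit, separable case, consistency", {
  set.seed(64)
  ref <- fake_ref(400, list(A = c(0, 0), B = c(0, 0), C = c(0, 0)))
  mp <- model_posterior_mnlogistic(ref, c(stat1 = 0, stat2 = 0), 0.5)
  expect_equal(sum(mp$PP), 1)
  expect_true(all(abs(mp$PP - 1 / 3) < 0.1))
  # linearly separable, obs deep in model A's region (accepted set still
  # contains both classes, so the regression itself is exercised)
  ref2 <- fake_ref(400, list(A = c(0, 0), B = c(8, 8)))
  mp2 <- model_posterior_mnlogistic(ref2, c(stat1 = -1, stat2 = -1), 0.7)
  expect_gte(mp2$PP[["A"]], 0.99)
  # every accepted row from one model: PP collapses there with a warning
  expect_warning(mp1 <- model_posterior_mnlogistic(
    ref2, c(stat1 = -1, stat2 = -1), 0.2), "absent")
  expect_equal(mp1$PP[["A"]], 1)
  # moderately separated: agrees with rejection within 0.10 per model
  ref3 <- fake_ref(500, list(A = c(0, 0), B = c(2, 2)))
  obs3 <- c(stat1 = 1, stat2 = 1)
  pp_rej <- model_posterior_rejection(ref3, obs3, 0.2)$PP
  pp_mnl <- model_posterior_mnlogistic(ref3, obs3, 0.2)$PP
  expect_true(all(abs(pp_rej[names(pp_mnl)] - pp_mnl) < 0.10))
})

test_that("neuralnet: uninformative limit, separable case, determinism", {
  set.seed(65)
  ref <- fake_ref(500, list(A = c(0, 0), B = c(0, 0), C = c(0, 0)))
  obs <- c(stat1 = 0, stat2 = 0)
  mp <- model_posterior_neuralnet(ref, obs, 0.4, nnet_count = 20,
                                  nnet_maxit = 500)
  expect_equal(sum(mp$PP), 1)
  expect_true(all(abs(mp$PP - 1 / 3) < 0.1))
  ref2 <- fake_ref(250, list(A = c(0, 0), B = c(8, 8)))
  mp2 <- model_posterior_neuralnet(ref2, c(stat1 = -1, stat2 = -1), 0.7,
                                   nnet_count = 8, nnet_maxit = 300)
  expect_gte(mp2$PP[["A"]], 0.95)
  set.seed(99)
  a <- model_posterior_neuralnet(ref2, c(stat1 = 0, stat2 = 0), 0.3,
                                 nnet_count = 4, nnet_maxit = 100)
  set.seed(99)
  b <- model_posterior_neuralnet(ref2, c(stat1 = 0, stat2 = 0), 0.3,
                                 nnet_count = 4, nnet_maxit = 100)
  expect_identical(a$PP, b$PP)
})

test_that("bayes factors: ratios, infinities, antisymmetry, transitivity", {
  pp <- c(A = 0.5, B = 0.25, C = 0.25)
  bf <- bayes_factors(pp)
  expect_equal(bf["A", "B"], 2)
  expect_equal(diag(bf), c(A = 1, B = 1, C = 1))
  pp0 <- c(A = 0.7, B = 0.3, C = 0)
  bf0 <- bayes_factors(pp0)
  expect_true(is.infinite(bf0["A", "C"]))
  expect_equal(bf0["C", "A"], 0)
  set.seed(66)
  for (r in 1:10) {
    p <- stats::runif(3); p <- p / sum(p); names(p) <- c("A", "B", "C")
    bf <- bayes_factors(p)
    expect_equal(bf, t(1 / bf))
    expect_equal(bf["A", "B"] * bf["B", "C"], bf["A", "C"])
  }
})

test_that("hpd: degenerate, normal draws, brute-force windows", {
  expect_equal(hpd(rep(5, 10)), c(5, 5))
  set.seed(670)
  x <- stats::rnorm(10000)
  h <- hpd(x, 0.95)
  expect_lt(abs(h[1] + 1.96), 0.1)
  expect_lt(abs(h[2] - 1.96), 0.1)
  for (r in 1:20) {
    d <- stats::rexp(20)
    expect_equal(hpd(d, 0.9), oracle_hpd(d, 0.9))
    expect_equal(hpd(d, 0.95), oracle_hpd(d, 0.95))
  }
  expect_error(hpd(x, 1.2), "level")
  expect_error(hpd(3), "at least 2")
})

test_that("estimate_parameters: degenerate posterior and hand arithmetic", {
  # all accepted draws equal c
  ref <- data.frame(model = "A", theta = rep(4.2, 100),
                    ss_s1 = c(rep(0, 50), rep(10, 50)))
  class(ref) <- c("reference_table", "data.frame")
  est <- suppressWarnings(estimate_parameters(ref, c(s1 = 0), eps = 0.1,
                                              params = "theta"))
  expect_equal(est$mean, 4.2)
  expect_equal(c(est$ci_low, est$ci_high), c(4.2, 4.2))
  expect_equal(c(est$hpd_low, est$hpd_high), c(4.2, 4.2))
  # 20 listed draws accepted exactly: mean/CI/HPD by hand formulas
  draws <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3, 5, 8, 9, 7, 9, 3, 2, 3, 8, 4)
  n <- length(draws)
  ref2 <- data.frame(model = "A", theta = c(draws, stats::runif(180, 50, 60)),
                     ss_s1 = c(rep(0, n), stats::runif(180, 50, 150)))
  class(ref2) <- c("reference_table", "data.frame")
  est2 <- suppressWarnings(estimate_parameters(ref2, c(s1 = 0), eps = 0.1,
                                               params = "theta"))
  mu <- mean(draws); se <- sd(draws) / sqrt(n)
  expect_equal(est2$mean, mu)
  expect_equal(est2$ci_low, mu - 1.96 * se, tolerance = 1e-3)
  expect_equal(est2$ci_high, mu + 1.96 * se, tolerance = 1e-3)
  expect_equal(c(est2$hpd_low, est2$hpd_high), oracle_hpd(draws))
  expect_warning(estimate_parameters(ref2, c(s1 = 0), eps = 0.1,
                                     params = "theta"), "unstable")
})

test_that("cross-validation: hand oracle and exclusion by construction", {
  set.seed(68)
  # 50-row table, theta fully determined by the statistic
  n <- 50
  theta <- stats::runif(n)
  ref <- data.frame(model = "A", theta = theta, ss_s1 = theta)
  class(ref) <- c("reference_table", "data.frame")
  cv <- cross_validate(ref, n_cv = 5, tolerances = 0.1, params = "theta")
  # independent hand computation of the same 5 held-out estimates
  # (replay the RNG stream: theta draws first, then the held-out sample)
  set.seed(68)
  invisible(stats::runif(n))
  held <- sample.int(n, 5)
  x <- ref$ss_s1 / median(abs(ref$ss_s1 - median(ref$ss_s1)))
  est <- vapply(held, function(i) {
    d <- abs(x - x[i]); d[i] <- Inf
    mean(theta[order(d)[seq_len(floor(0.1 * (n - 1)))]])
  }, numeric(1))
  epred <- sum((est - theta[held])^2) / (5 * stats::var(theta[held]))
  expect_equal(cv$Epred, epred, tolerance = 1e-12)
  expect_error(cross_validate(ref, n_cv = 20), "10x")
})
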