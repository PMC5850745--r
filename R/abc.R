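# ABC engine: model choice by rejection / multinomial logistic / neural
# network, Bayes factors, parameter posteriors, cross-validation.

#' Standardize a reference table and observed vector
#'
#' Each statistic column is divided by its median absolute deviation (raw
#' MAD, median of absolute deviations from the median) across the reference
#' table; the observed vector is scaled identically. Zero-MAD (constant)
#' columns are dropped with a warning: they carry no distance information.
#'
#' @param ref reference table with `ss_*` statistic columns.
#' @param obs named observed statistic vector ([sumstat_vector()] names).
#' @return List with `X` (scaled statistic matrix), `obs` (scaled observed
#'   vector), `scale` (per-column MAD) and `cols` (retained columns).
#' @export
standardize <- function(ref, obs) {
  cols <- stat_cols(ref)
  if (!length(cols)) stop("reference table has no statistic columns")
  obs_names <- paste0("ss_", names(obs))
  if (!is.null(names(obs)) && any(obs_names %in% cols))
    names(obs) <- obs_names
  keep <- intersect(cols, names(obs))
  if (!length(keep)) stop("no overlapping statistic columns between table and observation")
  X <- as.matrix(ref[, keep, drop = FALSE])
  mad_raw <- apply(X, 2, function(x) stats::median(abs(x - stats::median(x))))
  zero <- mad_raw == 0
  if (any(zero)) {
    warning("dropping constant statistic column(s): ",
            paste(keep[zero], collapse = ", "))
    keep <- keep[!zero]
    X <- X[, !zero, drop = FALSE]
    mad_raw <- mad_raw[!zero]
  }
  if (!length(keep)) stop("all statistic columns are constant")
  X <- sweep(X, 2, mad_raw, "/")
  list(X = X, obs = unname(obs[keep]) / mad_raw, scale = mad_raw,
       cols = keep)
}

#' Rejection sampling: nearest simulations to the observation
#'
#' Retains the `floor(eps * n)` reference rows with smallest Euclidean
#' distance to the observation on standardized statistics. Ties at the
#' acceptance boundary are broken by stable row order, so the result is
#' deterministic and invariant (up to tie sets) to row shuffling.
#'
#' @param ref reference table.
#' @param obs observed statistic vector.
#' @param eps tolerance: fraction of simulations retained, in (0, 1].
#' @return List with `idx` (accepted row indices), `dist` (their
#'   distances), `all_dist`, `eps`, `n_accepted`.
#' @export
rejection_sample <- function(ref, obs, eps) {
  if (eps <= 0 || eps > 1) stop("tolerance must be in (0, 1]")
  z <- standardize(ref, obs)
  d <- sqrt(colSums((t(z$X) - z$obs)^2))
  m <- floor(eps * nrow(z$X))
  if (m == 0) stop("tolerance too small: no simulations would be accepted")
  idx <- order(d)[seq_len(m)]   # order() is stable: ties by row order
  list(idx = idx, dist = d[idx], all_dist = d, eps = eps, n_accepted = m)
}

new_model_posterior <- function(pp, method, eps, n_accepted) {
  pp <- pp / sum(pp)
  structure(list(PP = pp, BF = bayes_factors(pp), method = method,
                 eps = eps, n_accepted = n_accepted),
            class = "model_posterior")
}

#' @export
print.model_posterior <- function(x, ...) {
  cat("model_posterior (", x$method, ", eps = ", x$eps, ", accepted = ",
      x$n_accepted, ")\n", sep = "")
  print(round(x$PP, 4))
  invisible(x)
}

#' Model posterior probabilities by rejection
#'
#' `PP_m` is the fraction of accepted simulations generated under model `m`
#' (under equal prior model probabilities and balanced tables this is the
#' standard rejection estimate); Bayes factors are posterior-probability
#' ratios.
#'
#' @param ref reference table with a `model` column.
#' @param obs observed statistic vector.
#' @param eps tolerance.
#' @return A `model_posterior`: `PP` (named, sums to 1), `BF` (pairwise
#'   matrix), `method`, `eps`, `n_accepted`.
#' @export
model_posterior_rejection <- function(ref, obs, eps) {
  acc <- rejection_sample(ref, obs, eps)
  labs <- ref$model[acc$idx]
  models <- unique(ref$model)
  pp <- vapply(models, function(m) mean(labs == m), numeric(1))
  new_model_posterior(pp, "rejection", eps, acc$n_accepted)
}

# Epanechnikov kernel weights on distances, bandwidth = max accepted
epanechnikov <- function(d) {
  h <- max(d)
  if (h == 0) return(rep(1, length(d)))
  1 - (d / h)^2
}

# weighted multinomial logistic (softmax) regression by penalised ML;
# returns class probabilities at x0
fit_softmax <- function(X, y, w, x0, ridge = 1e-6, maxit = 500) {
  K <- nlevels(y); P <- ncol(X)
  Xc <- cbind(1, X)
  Y <- diag(K)[as.integer(y), , drop = FALSE]
  nll <- function(beta) {
    B <- cbind(0, matrix(beta, P + 1, K - 1))
    eta <- Xc %*% B
    eta <- eta - apply(eta, 1, max)
    lse <- log(rowSums(exp(eta)))
    -sum(w * (rowSums(Y * eta) - lse)) + ridge * sum(beta^2)
  }
  grad <- function(beta) {
    B <- cbind(0, matrix(beta, P + 1, K - 1))
    eta <- Xc %*% B
    eta <- eta - apply(eta, 1, max)
    Pr <- exp(eta) / rowSums(exp(eta))
    G <- t(Xc) %*% (w * (Pr - Y))
    as.vector(G[, -1, drop = FALSE]) + 2 * ridge * beta
  }
  fit <- stats::optim(rep(0, (P + 1) * (K - 1)), nll, grad, method = "BFGS",
                      control = list(maxit = maxit))
  B <- cbind(0, matrix(fit$par, P + 1, K - 1))
  eta0 <- c(1, x0) %*% B
  p <- exp(eta0 - max(eta0)); p <- p / sum(p)
  stats::setNames(as.vector(p), levels(y))
}

#' Model posterior probabilities by multinomial logistic regression
#'
#' Fits a multinomial logistic regression of model label on standardized
#' statistics over the accepted simulations, weighted by an Epanechnikov
#' kernel in distance (bandwidth = largest accepted distance), and
#' evaluates the fitted class probabilities at the observation; clipped to
#' \[0, 1\] and renormalized. A small ridge penalty regularises perfectly
#' separated fits. Models absent from the accepted set are reported with
#' probability 0 and a warning.
#'
#' @inheritParams model_posterior_rejection
#' @return A `model_posterior`.
#' @export
model_posterior_mnlogistic <- function(ref, obs, eps) {
  z <- standardize(ref, obs)
  acc <- rejection_sample(ref, obs, eps)
  labs <- ref$model[acc$idx]
  models <- unique(ref$model)
  present <- intersect(models, unique(labs))
  if (length(models) < 2)
    stop("at least 2 models are required for model choice")
  if (length(present) < length(models))
    warning("model(s) absent from accepted set, reported with PP = 0: ",
            paste(setdiff(models, present), collapse = ", "))
  pp <- stats::setNames(numeric(length(models)), models)
  if (length(present) == 1) {
    pp[present] <- 1
    return(new_model_posterior(pp, "mnlogistic", eps, acc$n_accepted))
  }
  w <- epanechnikov(acc$dist)
  w[w <= 0] <- min(w[w > 0], 1e-8)   # boundary row keeps tiny weight
  p_fit <- fit_softmax(z$X[acc$idx, , drop = FALSE],
                       factor(labs, levels = present), w, z$obs)
  pp[present] <- pmin(pmax(p_fit, 0), 1)
  new_model_posterior(pp, "mnlogistic", eps, acc$n_accepted)
}

# single hidden layer (tanh) softmax network trained by weighted
# cross-entropy with weight decay; returns class probabilities at x0
fit_nnet_once <- function(X, Y, w, x0, size, maxit, decay = 0.25) {
  P <- ncol(X); K <- ncol(Y)
  n_w1 <- (P + 1) * size; n_w2 <- (size + 1) * K
  unpack <- function(th) list(W1 = matrix(th[seq_len(n_w1)], P + 1, size),
                              W2 = matrix(th[n_w1 + seq_len(n_w2)],
                                          size + 1, K))
  fwd <- function(W1, W2, Xc) {
    H <- tanh(cbind(1, Xc) %*% W1)
    eta <- cbind(1, H) %*% W2
    eta <- eta - apply(eta, 1, max)
    E <- exp(eta)
    list(H = H, Pr = E / rowSums(E))
  }
  nll <- function(th) {
    p <- unpack(th)
    f <- fwd(p$W1, p$W2, X)
    -sum(w * rowSums(Y * log(pmax(f$Pr, 1e-12)))) + decay * sum(th^2)
  }
  grad <- function(th) {
    p <- unpack(th)
    f <- fwd(p$W1, p$W2, X)
    d2 <- w * (f$Pr - Y)                         # n x K
    g2 <- t(cbind(1, f$H)) %*% d2                # (size+1) x K
    dH <- (d2 %*% t(p$W2[-1, , drop = FALSE])) * (1 - f$H^2)
    g1 <- t(cbind(1, X)) %*% dH
    c(as.vector(g1), as.vector(g2)) + 2 * decay * th
  }
  th0 <- stats::runif(n_w1 + n_w2, -0.5, 0.5)
  fit <- tryCatch(stats::optim(th0, nll, grad, method = "BFGS",
                               control = list(maxit = maxit)),
                  error = function(e) NULL)
  if (is.null(fit) || !all(is.finite(fit$par)))
    return(list(pr = NULL, converged = FALSE))
  p <- unpack(fit$par)
  f <- fwd(p$W1, p$W2, matrix(x0, 1))
  # convergence code 1 = iteration cap reached: the cap is the training
  # budget (as in nnet), not a failure
  list(pr = as.vector(f$Pr), converged = fit$convergence %in% c(0L, 1L))
}

#' Model posterior probabilities by a neural-network ensemble
#'
#' Trains an ensemble of `nnet_count` single-hidden-layer classifiers
#' (default 5 tanh units) on the accepted simulations, distance-kernel
#' weighted, each capped at `nnet_maxit` optimizer iterations; the model
#' posterior is the ensemble mean of the class probabilities at the
#' observation, renormalized. Non-converged members are dropped and
#' counted, with a warning if more than 20% drop.
#'
#' @inheritParams model_posterior_rejection
#' @param nnet_count ensemble size (the study used 100).
#' @param nnet_maxit iteration cap per member (the study used 1,000).
#' @param size hidden-layer width.
#' @param decay weight-decay (ridge) penalty; the fairly heavy default
#'   smooths each member's class-probability surface toward the locally
#'   weighted class frequencies, which is what a posterior-probability
#'   estimator should do in the uninformative limit.
#' @return A `model_posterior` (extra field `n_dropped`).
#' @export
model_posterior_neuralnet <- function(ref, obs, eps, nnet_count = 100,
                                      nnet_maxit = 1000, size = 5,
                                      decay = 0.25) {
  stopifnot(nnet_count >= 1)
  z <- standardize(ref, obs)
  acc <- rejection_sample(ref, obs, eps)
  labs <- ref$model[acc$idx]
  models <- unique(ref$model)
  present <- intersect(models, unique(labs))
  if (length(models) < 2)
    stop("at least 2 models are required for model choice")
  if (length(present) < length(models))
    warning("model(s) absent from accepted set, reported with PP = 0: ",
            paste(setdiff(models, present), collapse = ", "))
  if (length(present) == 1) {
    pp <- stats::setNames(numeric(length(models)), models)
    pp[present] <- 1
    return(new_model_posterior(pp, "neuralnet", eps, acc$n_accepted))
  }
  w <- epanechnikov(acc$dist)
  w[w <= 0] <- min(w[w > 0], 1e-8)
  Y <- diag(length(present))[match(labs, present), , drop = FALSE]
  X <- z$X[acc$idx, , drop = FALSE]
  probs <- matrix(NA_real_, nnet_count, length(present))
  dropped <- 0L
  for (b in seq_len(nnet_count)) {
    f <- fit_nnet_once(X, Y, w, z$obs, size = size, maxit = nnet_maxit,
                       decay = decay)
    if (f$converged) probs[b, ] <- f$pr else dropped <- dropped + 1L
  }
  if (dropped == nnet_count) stop("no neural-network ensemble member converged")
  if (dropped > 0.2 * nnet_count)
    warning(dropped, "/", nnet_count, " ensemble members dropped")
  pp <- stats::setNames(numeric(length(models)), models)
  pp[present] <- pmin(pmax(colMeans(probs, na.rm = TRUE), 0), 1)
  out <- new_model_posterior(pp, "neuralnet", eps, acc$n_accepted)
  out$n_dropped <- dropped
  out
}

#' Bayes-factor matrix from posterior probabilities
#'
#' `BF[i, j] = PP_i / PP_j` under equal model priors; a zero denominator
#' yields `Inf` (flagged, not an error). The matrix satisfies
#' `BF[i, i] = 1` and `BF[i, j] = 1 / BF[j, i]`.
#'
#' @param pp named posterior-probability vector (sums to 1) or a
#'   `model_posterior`.
#' @return Square named matrix of Bayes factors.
#' @export
bayes_factors <- function(pp) {
  if (inherits(pp, "model_posterior")) pp <- pp$PP
  bf <- outer(pp, pp, function(a, b) ifelse(b == 0, Inf, a / b))
  diag(bf) <- 1
  dimnames(bf) <- list(names(pp), names(pp))
  bf
}

#' Highest posterior density interval
#'
#' Shortest interval containing at least `level` of the draws: among all
#' windows of `ceiling(level * n)` consecutive order statistics, the
#' narrowest (first on ties).
#'
#' @param draws numeric vector of posterior draws (>= 2).
#' @param level interval mass in (0, 1).
#' @return Numeric `c(lower, upper)`.
#' @export
hpd <- function(draws, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  n <- length(draws)
  if (n < 2) stop("need at least 2 draws")
  x <- sort(draws)
  m <- ceiling(level * n)
  if (m >= n) return(c(x[1], x[n]))
  widths <- x[(m):n] - x[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(x[i], x[i + m - 1])
}

#' Posterior parameter summaries under one model
#'
#' Restricts the reference table to `model`, runs rejection sampling, and
#' summarises the accepted parameter draws: posterior mean, 95% confidence
#' interval of the mean (normal approximation, mean +/- 1.96 SE) and 95%
#' HPD (shortest empirical interval). Fewer than 30 accepted draws warns
#' about unstable summaries.
#'
#' @param ref reference table.
#' @param obs observed statistic vector.
#' @param model model name to restrict to (`NULL`: table already
#'   restricted).
#' @param eps tolerance.
#' @param params parameter columns to summarise (default: all non-constant
#'   parameter columns of the restricted table).
#' @param level interval mass.
#' @return data.frame of class `posterior_summary`: `parameter`, `mean`,
#'   `ci_low`, `ci_high`, `hpd_low`, `hpd_high`, `n_accepted`, `eps`;
#'   attribute `draws` holds the accepted draws matrix.
#' @export
estimate_parameters <- function(ref, obs, model = NULL, eps = 0.01,
                                params = NULL, level = 0.95) {
  if (!is.null(model)) ref <- ref[ref$model == model, , drop = FALSE]
  if (!nrow(ref)) stop("restricted reference table is empty")
  if (is.null(params)) {
    params <- setdiff(names(ref), c("sim_id", "model", "seed", stat_cols(ref)))
    ok <- vapply(params, function(p) {
      v <- ref[[p]]
      !all(is.na(v)) && stats::var(v, na.rm = TRUE) > 0
    }, logical(1))
    params <- params[ok]
  }
  acc <- rejection_sample(ref, obs, eps)
  if (acc$n_accepted < 30) warning("unstable summaries: fewer than 30 accepted draws")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  draws <- as.matrix(ref[acc$idx, params, drop = FALSE])
  rows <- lapply(params, function(p) {
    d <- draws[, p]
    mu <- mean(d); se <- stats::sd(d) / sqrt(length(d))
    h <- hpd(d, level)
    data.frame(parameter = p, mean = mu, ci_low = mu - zq * se,
               ci_high = mu + zq * se, hpd_low = h[1], hpd_high = h[2],
               n_accepted = acc$n_accepted, eps = eps)
  })
  out <- do.call(rbind, rows)
  attr(out, "draws") <- draws
  class(out) <- c("posterior_summary", "data.frame")
  out
}

#' Rejection cross-validation of parameter estimability
#'
#' For each of `n_cv` randomly sampled reference rows, treats the row's
#' statistics as the observation, runs rejection estimation against all
#' remaining rows (the held-out row is excluded from its own reference set
#' by construction), and takes the posterior mean as point estimate. The
#' prediction error per parameter and tolerance is
#' `Epred = sum((est - truth)^2) / (n_cv * Var(truth))`, so an
#' uninformative statistic set gives Epred near 1 and a perfectly
#' informative one near 0.
#'
#' @param ref reference table (single model).
#' @param n_cv held-out simulations (the study used 1,000).
#' @param tolerances tolerance levels (the study used 0.5%, 1%, 5%).
#' @param params parameter columns (default as in
#'   [estimate_parameters()]).
#' @return data.frame of class `cv_result`: `parameter`, `eps`, `Epred`,
#'   `n_cv`.
#' @export
cross_validate <- function(ref, n_cv = 1000,
                           tolerances = c(0.005, 0.01, 0.05),
                           params = NULL) {
  n <- nrow(ref)
  if (n < 10 * n_cv)
    stop("reference table must have at least 10x n_cv rows")
  if (is.null(params)) {
    params <- setdiff(names(ref), c("sim_id", "model", "seed", stat_cols(ref)))
    params <- params[vapply(params, function(p)
      !all(is.na(ref[[p]])) && stats::var(ref[[p]], na.rm = TRUE) > 0,
      logical(1))]
  }
  cols <- stat_cols(ref)
  X <- as.matrix(ref[, cols, drop = FALSE])
  mad_raw <- apply(X, 2, function(x) stats::median(abs(x - stats::median(x))))
  keep <- mad_raw > 0
  X <- sweep(X[, keep, drop = FALSE], 2, mad_raw[keep], "/")
  theta <- as.matrix(ref[, params, drop = FALSE])
  held <- sample.int(n, n_cv)
  est <- array(NA_real_, c(n_cv, length(tolerances), length(params)))
  for (k in seq_len(n_cv)) {
    i <- held[k]
    d <- sqrt(colSums((t(X) - X[i, ])^2))
    d[i] <- Inf                     # exclusion of the held-out row
    ord <- order(d)
    for (t in seq_along(tolerances)) {
      m <- floor(tolerances[t] * (n - 1))
      if (m == 0) stop("tolerance too small for cross-validation: ",
                       tolerances[t])
      est[k, t, ] <- colMeans(theta[ord[seq_len(m)], , drop = FALSE])
    }
  }
  truth <- theta[held, , drop = FALSE]
  rows <- list()
  for (t in seq_along(tolerances))
    for (p in seq_along(params)) {
      vt <- stats::var(truth[, p])
      rows[[length(rows) + 1]] <- data.frame(
        parameter = params[p], eps = tolerances[t],
        Epred = sum((est[, t, p] - truth[, p])^2) / (n_cv * vt),
        n_cv = n_cv)
    }
  out <- do.call(rbind, rows)
  class(out) <- c("cv_result", "data.frame")
  out
}
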