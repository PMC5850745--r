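#' Demographic models for the three wild common bean gene pools
#'
#' Three competing origin hypotheses are represented as structured-coalescent
#' models over the Mesoamerican (MW), southern Andean (AW) and Northern
#' Peru-Ecuador (PhI) demes. In every model the derived populations undergo a
#' founder bottleneck when they separate from their source, while one deme
#' (the hypothesised ancestral pool) keeps a constant size:
#'
#' * `mesoamerican` - MW constant; AW splits from MW at time `T1` through a
#'   founder of size `NF_AW`; PhI splits from MW at `T2` (founder `NF_PhI`).
#' * `phi` - PhI constant; AW splits from PhI at `T1` (founder `NF_AW`); MW
#'   splits from PhI at `T2` (founder `NF_MW`): the species migrated both
#'   North and South out of Northern Peru-Ecuador.
#' * `protovulgaris` - an unsampled ancestral deme of size `N_ANC` is
#'   constant; MW and AW split from it at `T1` (founders `NF_MW`, `NF_AW`)
#'   and PhI at `T2` (founder `NF_PhI`); the ancestor has no sampled
#'   descendants.
#'
#' Times are in generations; one generation is equated to one calendar year
#' for this annual species, so times are also years.
#'
#' @param name one of `"mesoamerican"`, `"phi"`, `"protovulgaris"`.
#' @param sample_sizes named integer vector of diploid sample counts for the
#'   `MW`, `AW` and `PhI` demes. Defaults to the genotyped panel
#'   (157/77/12); see [sample_profile()] for reduced test profiles.
#' @return An object of class `demographic_model` with elements `name`,
#'   `demes` (including the unsampled ancestor where relevant),
#'   `sample_sizes`, `constant_deme`, and `param_names` (the parameters the
#'   model requires).
#' @seealso [compile_history()], [sample_prior()], [simulate_dataset()]
#' @export
build_model <- function(name, sample_sizes = sample_profile("full")) {
  name <- match.arg(name, c("mesoamerican", "phi", "protovulgaris"))
  stopifnot(all(c("MW", "AW", "PhI") %in% names(sample_sizes)))
  sample_sizes <- sample_sizes[c("MW", "AW", "PhI")]
  common <- c("N_MW", "N_AW", "N_PhI", "T1", "T2", "bottleneck_dur")
  spec <- switch(name,
    mesoamerican = list(demes = c("MW", "AW", "PhI"), constant = "MW",
                        extra = c("NF_AW", "NF_PhI")),
    phi = list(demes = c("MW", "AW", "PhI"), constant = "PhI",
               extra = c("NF_MW", "NF_AW")),
    protovulgaris = list(demes = c("MW", "AW", "PhI", "ANC"), constant = "ANC",
                         extra = c("N_ANC", "NF_MW", "NF_AW", "NF_PhI")))
  structure(list(name = name, demes = spec$demes,
                 sample_sizes = sample_sizes,
                 constant_deme = spec$constant,
                 param_names = c(common, spec$extra)),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  cat("demographic_model:", x$name, "\n")
  cat("  demes:", paste(x$demes, collapse = ", "),
      "(constant:", x$constant_deme, ")\n")
  cat("  diploid samples:", paste(sprintf("%s=%d", names(x$sample_sizes),
                                          x$sample_sizes), collapse = ", "),
      "\n")
  cat("  parameters:", paste(x$param_names, collapse = ", "), "\n")
  invisible(x)
}

#' Diploid sample-size profiles
#'
#' `"full"` is the genotyped panel of the study system (157 MW, 77 AW,
#' 12 PhI diploids); `"reduced"` (20/10/6) keeps simulation-heavy tests
#' within desk-scale budgets.
#'
#' @param profile `"full"`, `"reduced"`, or a named integer vector.
#' @return Named integer vector with elements `MW`, `AW`, `PhI`.
#' @export
sample_profile <- function(profile = "full") {
  if (is.numeric(profile)) {
    stopifnot(all(c("MW", "AW", "PhI") %in% names(profile)))
    return(as.integer(profile[c("MW", "AW", "PhI")]) |>
             stats::setNames(c("MW", "AW", "PhI")))
  }
  switch(match.arg(profile, c("full", "reduced")),
         full = c(MW = 157L, AW = 77L, PhI = 12L),
         reduced = c(MW = 20L, AW = 10L, PhI = 6L))
}

#' Compile a model and parameter draw into an epoch/event history
#'
#' Translates a [build_model()] topology plus one parameter draw into the
#' piecewise-constant deme-size epochs and time-ordered divergence events
#' consumed by the coalescent engine. The founder episode is realised as an
#' epoch of size `NF_*` covering the `bottleneck_dur` generations
#' immediately after the founding (forward time), i.e. the backward-time
#' interval `[T - bottleneck_dur, T]`, followed by instantaneous growth to
#' the current size.
#'
#' @param model a `demographic_model`.
#' @param params named numeric vector or list covering `model$param_names`.
#' @return List with `demes`, per-deme `epoch_starts`/`epoch_sizes`
#'   (backward-time step functions) and `events` (data.frame `time`,
#'   `from`, `to`, sorted by time).
#' @export
compile_history <- function(model, params) {
  params <- unlist(params)
  missing <- setdiff(model$param_names, names(params))
  if (length(missing))
    stop("missing parameter(s) in spec: ", paste(missing, collapse = ", "))
  p <- as.list(params[model$param_names])
  if (any(unlist(p) <= 0)) stop("all sizes and times must be > 0")
  dur <- p$bottleneck_dur
  founder_epochs <- function(N_now, NF, T) {
    t0 <- max(T - dur, 0)
    if (t0 <= 0) list(starts = 0, sizes = NF)
    else list(starts = c(0, t0), sizes = c(N_now, NF))
  }
  const_epoch <- function(N) list(starts = 0, sizes = N)
  ep <- list(); ev <- NULL
  if (model$name == "mesoamerican") {
    ep$MW <- const_epoch(p$N_MW)
    ep$AW <- founder_epochs(p$N_AW, p$NF_AW, p$T1)
    ep$PhI <- founder_epochs(p$N_PhI, p$NF_PhI, p$T2)
    ev <- data.frame(time = c(p$T1, p$T2), from = c("AW", "PhI"),
                     to = c("MW", "MW"))
  } else if (model$name == "phi") {
    ep$PhI <- const_epoch(p$N_PhI)
    ep$AW <- founder_epochs(p$N_AW, p$NF_AW, p$T1)
    ep$MW <- founder_epochs(p$N_MW, p$NF_MW, p$T2)
    ev <- data.frame(time = c(p$T1, p$T2), from = c("AW", "MW"),
                     to = c("PhI", "PhI"))
  } else {
    ep$ANC <- const_epoch(p$N_ANC)
    ep$MW <- founder_epochs(p$N_MW, p$NF_MW, p$T1)
    ep$AW <- founder_epochs(p$N_AW, p$NF_AW, p$T1)
    ep$PhI <- founder_epochs(p$N_PhI, p$NF_PhI, p$T2)
    ev <- data.frame(time = c(p$T1, p$T1, p$T2), from = c("MW", "AW", "PhI"),
                     to = c("ANC", "ANC", "ANC"))
  }
  ev <- ev[order(ev$time), , drop = FALSE]
  rownames(ev) <- NULL
  demes <- model$demes
  list(demes = demes,
       epoch_starts = lapply(demes, function(d) ep[[d]]$starts),
       epoch_sizes = lapply(demes, function(d) ep[[d]]$sizes),
       events = ev)
}

#' Prior specification and sampling
#'
#' A prior spec is a named list, one entry per parameter, each of the form
#' `list(dist = "uniform"|"loguniform"|"fixed", min =, max =)` (or
#' `value =` for `"fixed"`).
#'
#' The shipped defaults bracket the posterior scales reported for this
#' system but are reconstructions, not published priors: log-uniform current
#' sizes N in \[1e3, 1e6\], log-uniform founder sizes NF in \[10, 1e4\],
#' uniform T1 in \[1e4, 5e5\] and T2 in \[5e4, 2e6\] years, bottleneck
#' duration fixed at 100 generations.
#'
#' @param model a `demographic_model`.
#' @return Named list prior spec covering `model$param_names`.
#' @export
default_priors <- function(model) {
  spec <- list()
  for (nm in model$param_names) {
    spec[[nm]] <-
      if (nm == "bottleneck_dur") list(dist = "fixed", value = 100)
      else if (nm == "T1") list(dist = "uniform", min = 1e4, max = 5e5)
      else if (nm == "T2") list(dist = "uniform", min = 5e4, max = 2e6)
      else if (startsWith(nm, "NF")) list(dist = "loguniform", min = 10, max = 1e4)
      else list(dist = "loguniform", min = 1e3, max = 1e6)
  }
  spec
}

validate_prior_spec <- function(spec) {
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (is.null(s$dist) ||
        !s$dist %in% c("uniform", "loguniform", "fixed"))
      stop("prior for ", nm, ": unknown distribution family")
    if (s$dist == "fixed") {
      if (is.null(s$value)) stop("prior for ", nm, ": fixed needs a value")
    } else {
      if (is.null(s$min) || is.null(s$max) || !is.finite(s$min) ||
          !is.finite(s$max) || s$min >= s$max)
        stop("prior for ", nm, ": bounds must be finite with min < max")
      if (s$dist == "loguniform" && s$min <= 0)
        stop("prior for ", nm, ": log-uniform needs min > 0")
    }
  }
  invisible(spec)
}

#' Draw one parameter vector from a prior spec
#'
#' Uses the current RNG stream, so `set.seed()` makes draws reproducible.
#'
#' @param spec prior spec as in [default_priors()].
#' @param model optional `demographic_model`; if given, the spec must cover
#'   all its parameters.
#' @return Named numeric vector, one draw per parameter.
#' @export
sample_prior <- function(spec, model = NULL) {
  validate_prior_spec(spec)
  if (!is.null(model)) {
    missing <- setdiff(model$param_names, names(spec))
    if (length(missing))
      stop("missing parameter in spec: ", paste(missing, collapse = ", "))
    spec <- spec[model$param_names]
  }
  vapply(spec, function(s) {
    switch(s$dist,
           fixed = s$value,
           uniform = stats::runif(1, s$min, s$max),
           loguniform = exp(stats::runif(1, log(s$min), log(s$max))))
  }, numeric(1))
}
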