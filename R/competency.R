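#' Prior specification for the competency and GAM models
#'
#' Weakly-informative defaults chosen to regularize complete separation in
#' desk-scale assay data without dominating it: Normal(0, 5) on intercepts
#' (after centring age), Normal(0, 2.5) on age slopes, half-Normal(0, 2) on
#' hierarchical standard deviations.
#'
#' @param intercept_sd SD of the Normal prior on cue intercepts.
#' @param slope_sd SD of the Normal prior on cue age-slopes.
#' @param sd_sd scale of the half-Normal prior on hierarchical SDs.
#' @return an object of class `prior_spec`.
#' @export
prior_spec <- function(intercept_sd = 5, slope_sd = 2.5, sd_sd = 2) {
  stopifnot(intercept_sd > 0, slope_sd > 0, sd_sd > 0)
  structure(list(intercept_sd = intercept_sd, slope_sd = slope_sd,
                 sd_sd = sd_sd), class = "prior_spec")
}

#' Binarize well-level settlement into cohort competency
#'
#' A replicate well is scored competent (1) when its settled proportion
#' reaches the settlement threshold: `n_settled / n_larvae >= threshold`
#' (inclusive by default, so 3 of 10 larvae at the default 0.3 threshold
#' counts as competent). Wells with zero larvae loaded are rejected with a
#' warning.
#'
#' @param observations assay observations (see [simulate_assays()] /
#'   [read_assay_csv()]).
#' @param threshold settlement proportion in (0, 1); default 0.3.
#' @param inclusive if `FALSE`, require strict exceedance of the threshold.
#' @return the observations with a `competent` column (0/1) and the
#'   threshold recorded as an attribute.
#' @export
binarize_competency <- function(observations, threshold = 0.3,
                                inclusive = TRUE) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold >= 1)
    cc_stop("`threshold` must lie in (0, 1)")
  bad <- observations$n_larvae < 1
  if (any(bad)) {
    cc_warn(sum(bad), " record(s) with n_larvae = 0 rejected")
    observations <- observations[!bad, , drop = FALSE]
  }
  prop <- observations$n_settled / observations$n_larvae
  observations$competent <-
    as.integer(if (inclusive) prop >= threshold else prop > threshold)
  attr(observations, "threshold") <- threshold
  observations
}

# eta on the natural (uncentred) age scale for a parameter list
competency_eta <- function(params, records, center_age = 0) {
  missing_cue <- setdiff(unique(records$cue), names(params$alpha))
  if (length(missing_cue))
    cc_stop("cue absent from parameter set: ",
            paste(missing_cue, collapse = ", "))
  eta <- params$alpha[records$cue] +
    params$beta[records$cue] * (records$age_days - center_age)
  if (!is.null(params$u)) eta <- eta + params$u[records$cohort_id]
  unname(eta)
}

#' Log posterior of the hierarchical logistic competency model
#'
#' Bernoulli log-likelihood of the binarized competency response under the
#' linear predictor `eta = alpha_cue + beta_cue * age` (plus cohort
#' deviations when supplied), plus the log prior. Exposed so the
#' likelihood/prior arithmetic can be checked against independent oracles.
#'
#' @param params list with named vectors `alpha` and `beta` (one entry per
#'   cue), optionally `u` (cohort deviations, named) and `log_sd` (their log
#'   SD).
#' @param records binarized records from [binarize_competency()].
#' @param prior a [prior_spec()].
#' @param center_age age offset subtracted before applying the intercept
#'   prior (0 = natural scale).
#' @return the log posterior density (a finite scalar for finite params).
#' @export
competency_log_posterior <- function(params, records, prior = prior_spec(),
                                     center_age = 0) {
  eta <- competency_eta(params, records, center_age)
  y <- records$competent
  ll <- sum(plogis(eta[y == 1], log.p = TRUE)) +
    sum(plogis(-eta[y == 0], log.p = TRUE))
  lp <- sum(dnorm(params$alpha, 0, prior$intercept_sd, log = TRUE)) +
    sum(dnorm(params$beta, 0, prior$slope_sd, log = TRUE))
  if (!is.null(params$u)) {
    sd_u <- exp(params$log_sd)
    lp <- lp + sum(dnorm(params$u, 0, sd_u, log = TRUE)) +
      dnorm(sd_u, 0, prior$sd_sd, log = TRUE) + log(2) + params$log_sd
  }
  ll + lp
}

separation_check <- function(records) {
  for (cue in unique(records$cue)) {
    r <- records[records$cue == cue, ]
    if (all(c(0, 1) %in% r$competent)) {
      if (max(r$age_days[r$competent == 0]) < min(r$age_days[r$competent == 1]))
        cc_warn("complete separation in age for cue \"", cue,
                "\"; priors regularize the fit")
    }
  }
}

#' Fit the hierarchical Bayesian logistic competency model
#'
#' Models the binarized competency response against the interaction of
#' larval age and settlement cue: cue-specific intercepts and age slopes on
#' the logit scale. With two or more cohorts, cohort-level varying
#' intercepts with a half-Normal SD prior are added; with a single cohort
#' (the common case) the model reduces to fixed cue effects. Age is centred
#' internally for sampling and draws are returned on the natural scale, so
#' TC50 is `-alpha/beta` per draw.
#'
#' Sampling is exact-likelihood independence Metropolis-Hastings with a
#' multivariate-t proposal built from the Laplace approximation at the
#' posterior mode, organized into chains/warmup/thinning per
#' [sampler_config()].
#'
#' @param records binarized records from [binarize_competency()], one
#'   species at a time.
#' @param config a [sampler_config()].
#' @param prior a [prior_spec()].
#' @return a `posterior_draws` object with parameters `alpha[cue]` and
#'   `beta[cue]` (and cohort terms when present); attributes carry the cue
#'   set, species, threshold, observed age range and acceptance rate.
#' @export
fit_competency_model <- function(records, config = sampler_config(),
                                 prior = prior_spec()) {
  stopifnot(all(c("cue", "age_days", "competent") %in% names(records)))
  sp <- unique(records$species_id)
  if (length(sp) > 1)
    cc_stop("fit one species at a time; found: ", paste(sp, collapse = ", "))
  cues <- sort(unique(records$cue))
  for (cue in cues) {
    r <- records[records$cue == cue, ]
    if (length(unique(r$age_days)) < 2 || length(unique(r$competent)) < 2)
      cc_warn("sparse design for cue \"", cue,
              "\": need >= 2 ages with both outcomes; estimates rely on priors")
  }
  separation_check(records)
  cohorts <- sort(unique(as.character(records$cohort_id %||% "C1")))
  hier <- length(cohorts) >= 2
  center <- mean(records$age_days)
  nc <- length(cues)
  cue_idx <- match(records$cue, cues)
  ac <- records$age_days - center
  y1 <- records$competent == 1
  theta_names <- c(paste0("alpha[", cues, "]"), paste0("beta[", cues, "]"))
  if (hier) {
    # cohort varying intercepts couple the cues: sample the joint posterior
    coh_idx <- match(as.character(records$cohort_id), cohorts)
    theta_names <- c(theta_names, paste0("u[", cohorts, "]"), "log_sd_cohort")
    log_post <- function(theta) {
      a <- theta[seq_len(nc)]; b <- theta[nc + seq_len(nc)]
      u <- theta[2 * nc + seq_along(cohorts)]
      ls <- theta[2 * nc + length(cohorts) + 1]
      eta <- a[cue_idx] + b[cue_idx] * ac + u[coh_idx]
      sd_u <- exp(ls)
      lp <- sum(dnorm(a, 0, prior$intercept_sd, log = TRUE)) +
        sum(dnorm(b, 0, prior$slope_sd, log = TRUE)) +
        sum(dnorm(u, 0, sd_u, log = TRUE)) +
        dnorm(sd_u, 0, prior$sd_sd, log = TRUE) + log(2) + ls
      sum(plogis(eta[y1], log.p = TRUE)) +
        sum(plogis(-eta[!y1], log.p = TRUE)) + lp
    }
    init <- rep(0, length(theta_names))
    init[length(init)] <- log(0.5)
    fit <- laplace_mh(log_post, init, config, theta_names,
                      model_tag = "competency_logistic")
  } else {
    # single cohort: the posterior factorizes exactly over cues, so each
    # cue's (alpha, beta) block is sampled with its own matched proposal
    nk <- n_retained(config)
    draws <- array(NA_real_, c(config$n_chains, nk, 2 * nc))
    map <- numeric(2 * nc)
    acc <- numeric(nc)
    for (ci in seq_len(nc)) {
      sel <- cue_idx == ci
      aci <- ac[sel]; y1i <- y1[sel]
      log_post <- function(theta) {
        eta <- theta[1] + theta[2] * aci
        sum(plogis(eta[y1i], log.p = TRUE)) +
          sum(plogis(-eta[!y1i], log.p = TRUE)) +
          dnorm(theta[1], 0, prior$intercept_sd, log = TRUE) +
          dnorm(theta[2], 0, prior$slope_sd, log = TRUE)
      }
      cfg <- config
      cfg$seed <- stage_seed(config$seed, ci)
      bl <- laplace_mh(log_post, c(0, 0), cfg,
                       c("alpha", "beta"), model_tag = "block")
      draws[, , ci] <- bl$draws[, , 1]
      draws[, , nc + ci] <- bl$draws[, , 2]
      map[c(ci, nc + ci)] <- attr(bl, "map")
      acc[ci] <- attr(bl, "accept_rate")
    }
    fit <- new_posterior_draws(draws, theta_names, "competency_logistic",
                               accept_rate = mean(acc),
                               map = setNames(map, theta_names),
                               config = config)
  }
  # back-transform intercepts to the natural age scale
  fit$draws[, , seq_len(nc)] <- fit$draws[, , seq_len(nc)] -
    fit$draws[, , nc + seq_len(nc)] * center
  attr(fit, "map")[seq_len(nc)] <- attr(fit, "map")[seq_len(nc)] -
    attr(fit, "map")[nc + seq_len(nc)] * center
  attr(fit, "cues") <- cues
  attr(fit, "species_id") <- if (length(sp)) sp else NA_character_
  attr(fit, "threshold") <- attr(records, "threshold")
  attr(fit, "age_range") <- range(records$age_days)
  attr(fit, "center_age") <- center
  fit
}

#' Per-draw TC50 values for one cue
#'
#' `TC50 = -alpha/beta` per posterior draw (the age at which the fitted
#' competency probability crosses 0.5). Draws with a non-positive age slope
#' never cross 0.5 from below and are mapped to `Inf` ("beyond the extent of
#' the experiment").
#'
#' @param draws a fitted `posterior_draws` from [fit_competency_model()].
#' @param cue cue label.
#' @return numeric vector, one value per retained draw.
#' @export
tc50_draws <- function(draws, cue) {
  cues <- attr(draws, "cues")
  if (!cue %in% cues) cc_stop("cue not in model: \"", cue, "\"")
  m <- as.matrix(draws)
  a <- m[, paste0("alpha[", cue, "]")]
  b <- m[, paste0("beta[", cue, "]")]
  ifelse(b > 0, -a / b, Inf)
}

#' TC50 estimate with credible interval for one cue
#'
#' Posterior median and central 95% credible interval of the per-draw TC50
#' values. The estimate is flagged `truncated` when its median exceeds the
#' experiment's extent (`max_age`), mirroring the convention of truncating
#' durations greater than the assay series.
#'
#' @param draws a fitted `posterior_draws` from [fit_competency_model()].
#' @param cue cue label.
#' @param max_age extent of the experiment in days; defaults to the largest
#'   assayed age.
#' @param threshold settlement threshold recorded with the estimate.
#' @return a one-row `data.frame`: species_id, cue, threshold, tc50_median,
#'   ci_lower, ci_upper, truncated.
#' @export
tc50_from_draws <- function(draws, cue,
                            max_age = attr(draws, "age_range")[2],
                            threshold = attr(draws, "threshold") %||% NA_real_) {
  t50 <- tc50_draws(draws, cue)
  qs <- quantile_inf(t50, c(0.025, 0.5, 0.975))
  data.frame(species_id = attr(draws, "species_id") %||% NA_character_,
             cue = cue,
             threshold = threshold,
             tc50_median = qs[2],
             ci_lower = qs[1],
             ci_upper = qs[3],
             truncated = !is.finite(qs[2]) || qs[2] > max_age,
             stringsAsFactors = FALSE)
}

is_control_cue <- function(cue) tolower(cue) == "control"

#' TC50 threshold sensitivity sweep
#'
#' Re-binarizes the raw observations at each settlement threshold in the
#' grid, refits the logistic competency model, and extracts a TC50 estimate
#' per threshold x cue. A "Best" pseudo-cue row per threshold reports
#' whichever non-control cue predicted the earliest median TC50.
#'
#' @param observations raw assay observations (one species).
#' @param thresholds settlement thresholds, a subset of `seq(0.1, 0.9, 0.1)`.
#' @param config a [sampler_config()]; each threshold uses a deterministic
#'   seed substream derived from `config$seed`.
#' @param prior a [prior_spec()].
#' @param max_age extent of the experiment (days).
#' @return a `data.frame` of TC50 estimates (one row per threshold x cue,
#'   plus "Best" rows).
#' @export
threshold_sweep <- function(observations,
                            thresholds = seq(0.1, 0.9, by = 0.1),
                            config = sampler_config(),
                            prior = prior_spec(),
                            max_age = max(observations$age_days)) {
  grid <- seq(0.1, 0.9, by = 0.1)
  if (!all(vapply(thresholds, function(t) any(abs(t - grid) < 1e-9), logical(1))))
    cc_stop("`thresholds` must be a subset of seq(0.1, 0.9, 0.1)")
  out <- lapply(thresholds, function(tau) {
    rec <- binarize_competency(observations, tau)
    cfg <- config
    cfg$seed <- stage_seed(config$seed, round(tau * 10))
    fit <- suppressWarnings(fit_competency_model(rec, cfg, prior))
    cues <- attr(fit, "cues")
    est <- do.call(rbind, lapply(cues, tc50_from_draws, draws = fit,
                                 max_age = max_age))
    cand <- est[!is_control_cue(est$cue), , drop = FALSE]
    cand <- cand[order(cand$tc50_median, cand$cue), , drop = FALSE]
    best <- cand[1, , drop = FALSE]
    best$cue <- "Best"
    attr(best, "best_cue") <- cand$cue[1]
    rbind(est, best)
  })
  do.call(rbind, out)
}

exceedance_prob <- function(x, y) mean(x < y) + 0.5 * mean(x == y)

#' Pairwise TC50 exceedance probabilities between cues
#'
#' Entry (A, B) is the posterior probability that cue A reaches competency
#' earlier than cue B: the fraction of paired draws with `tc50_A < tc50_B`,
#' ties counting one half (so `M[A,B] + M[B,A] = 1` exactly).
#'
#' @param x a fitted `posterior_draws` from [fit_competency_model()], or a
#'   named list of equal-length draw-level TC50 vectors.
#' @param cues cues to compare (default: all in the model).
#' @return a square matrix of exceedance probabilities.
#' @export
cue_tc50_contrasts <- function(x, cues = NULL) {
  if (inherits(x, "posterior_draws")) {
    cues <- cues %||% attr(x, "cues")
    samples <- lapply(cues, tc50_draws, draws = x)
    names(samples) <- cues
  } else {
    samples <- x
    cues <- cues %||% names(samples)
    samples <- samples[cues]
  }
  if (length(samples) < 2) cc_stop("need >= 2 cues to contrast")
  n <- unique(lengths(samples))
  if (length(n) != 1) cc_stop("mismatched draw counts across cues")
  M <- matrix(0.5, length(cues), length(cues), dimnames = list(cues, cues))
  for (i in seq_along(cues)) for (j in seq_along(cues)) if (i != j)
    M[i, j] <- exceedance_prob(samples[[i]], samples[[j]])
  M
}
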