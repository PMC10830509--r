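#' Cubic regression spline basis over larval age
#'
#' Builds the cubic regression-spline basis used by the settlement-through-
#' time model, with knots at empirical quantiles of the observed ages. The
#' knot count is capped at 5 by default to protect against overfitting;
#' larger values are allowed with a warning, and requests exceeding the
#' number of distinct ages are reduced with a warning. With `n_knots = 2`
#' the basis degenerates to `{1, age}` (a straight line).
#'
#' @param ages observed larval ages (days); at least `n_knots` distinct
#'   values.
#' @param n_knots basis dimension (number of knots for the cardinal cubic
#'   regression spline).
#' @return an object of class `spline_basis` with fields `knot_locations`,
#'   `basis_matrix`, `degree`, `n_knots`; use [predict()] to evaluate at new
#'   ages.
#' @export
build_spline_basis <- function(ages, n_knots = 5) {
  ux <- sort(unique(ages))
  if (length(ux) < 2) cc_stop("need >= 2 distinct ages to build a spline basis")
  if (n_knots > 5)
    cc_warn("n_knots > 5 risks overfitting settlement trends; proceeding")
  if (n_knots > length(ux)) {
    cc_warn("fewer distinct ages (", length(ux), ") than knots (", n_knots,
            "); reducing")
    n_knots <- length(ux)
  }
  if (n_knots < 2) cc_stop("`n_knots` must be >= 2")
  if (n_knots == 2) {
    structure(list(knot_locations = range(ux),
                   basis_matrix = cbind(1, ages),
                   degree = 1L, n_knots = 2L, smooth = NULL),
              class = "spline_basis")
  } else {
    sm <- mgcv::smoothCon(mgcv::s(age, bs = "cr", k = n_knots),
                          data = data.frame(age = ages),
                          absorb.cons = FALSE)[[1]]
    structure(list(knot_locations = as.numeric(sm$xp),
                   basis_matrix = sm$X,
                   degree = 3L, n_knots = as.integer(n_knots), smooth = sm),
              class = "spline_basis")
  }
}

#' Evaluate a spline basis at new ages
#'
#' @param object a `spline_basis`.
#' @param newages ages at which to evaluate.
#' @param ... unused.
#' @return basis matrix with one row per entry of `newages`.
#' @export
predict.spline_basis <- function(object, newages, ...) {
  if (is.null(object$smooth)) return(cbind(1, newages))
  mgcv::PredictMat(object$smooth, data.frame(age = newages))
}

# column indices of plate random-effect terms in a gam fit's lpmatrix
plate_cols <- function(fit) {
  idx <- integer(0)
  for (sm in fit$smooth) {
    if (any(grepl("plate_id", sm$term)))
      idx <- c(idx, sm$first.para:sm$last.para)
  }
  idx
}

#' Fit the Bayesian binomial GAM of settlement through time
#'
#' Models the proportion of larvae settled (binomial counts, logit link)
#' against a cubic regression spline of larval age conditional on settlement
#' cue, with a varying effect of well plate by age (plate-level random
#' intercept and random age slope) to absorb the dependency structure of
#' six-well plates. Smoothness and random-effect variances carry ridge-type
#' Gaussian priors whose scales are estimated by REML (empirical Bayes);
#' posterior draws of the coefficient vector are then simulated from the
#' Bayesian posterior of the penalized fit, `N(beta_hat, Vp)` (Wood-style
#' posterior simulation), organized into chains per [sampler_config()] so
#' that the usual convergence diagnostics apply.
#'
#' @param observations assay observations for a single species.
#' @param n_knots maximum spline basis dimension (default and cap 5).
#' @param config a [sampler_config()]; controls the retained draw count and
#'   seed.
#' @return a `posterior_draws` over the GAM coefficients; attributes carry
#'   the mgcv fit (for basis evaluation), cue set and observed age range.
#' @export
fit_settlement_gam <- function(observations, n_knots = 5,
                               config = sampler_config()) {
  stopifnot(all(c("age_days", "cue", "n_larvae", "n_settled") %in%
                  names(observations)))
  ux <- sort(unique(observations$age_days))
  if (length(ux) < 3)
    cc_stop("observations must span >= 3 distinct timepoints")
  if (n_knots > 5) cc_warn("n_knots > 5 risks overfitting; proceeding")
  k <- min(n_knots, length(ux))
  if (k < n_knots) cc_warn("reducing spline knots to ", k,
                           " (distinct ages limit the basis)")
  d <- data.frame(age_days = observations$age_days,
                  cue = factor(observations$cue),
                  plate_id = factor(observations$plate_id),
                  n_settled = observations$n_settled,
                  n_fail = observations$n_larvae - observations$n_settled)
  multi_plate <- nlevels(d$plate_id) >= 2
  if (!multi_plate)
    cc_warn("single plate: plate-by-age varying effects dropped")
  form <- if (multi_plate)
    cbind(n_settled, n_fail) ~ cue + s(age_days, by = cue, bs = "cr", k = k) +
      s(plate_id, bs = "re") + s(age_days, plate_id, bs = "re")
  else
    cbind(n_settled, n_fail) ~ cue + s(age_days, by = cue, bs = "cr", k = k)
  fit <- mgcv::gam(form, data = d, family = stats::binomial(),
                   method = "REML")
  mode <- coef(fit)
  L <- t(chol(make_pd((fit$Vp + t(fit$Vp)) / 2)))
  p <- length(mode)
  nk <- n_retained(config)
  arr <- array(NA_real_, c(config$n_chains, nk, p))
  with_seed(config$seed, {
    for (ch in seq_len(config$n_chains))
      for (i in seq_len(nk))
        arr[ch, i, ] <- mode + drop(L %*% rnorm(p))
  })
  draws <- new_posterior_draws(arr, names(mode), "settlement_gam",
                               map = mode, config = config)
  attr(draws, "gam_fit") <- fit
  attr(draws, "cues") <- levels(d$cue)
  attr(draws, "species_id") <- unique(observations$species_id) %||% NA_character_
  attr(draws, "age_range") <- range(observations$age_days)
  attr(draws, "n_knots") <- k
  draws
}

# population-level lpmatrix for a cue over an age grid: plate random-effect
# columns zeroed (effects marginalized at their zero mean)
gam_lpmatrix <- function(draws, cue, age_grid) {
  fit <- attr(draws, "gam_fit")
  if (is.null(fit)) cc_stop("draws do not carry a GAM fit")
  cues <- attr(draws, "cues")
  if (!cue %in% cues) cc_stop("cue not in model: \"", cue, "\"")
  rng <- attr(draws, "age_range")
  if (any(age_grid < rng[1] - 1e-9) || any(age_grid > rng[2] + 1e-9))
    cc_stop("age grid extends beyond the observed range [", rng[1], ", ",
            rng[2], "]; extrapolation refused")
  nd <- data.frame(age_days = age_grid,
                   cue = factor(cue, levels = cues),
                   plate_id = fit$model$plate_id[1] %||%
                     factor(NA))
  Xg <- predict(fit, newdata = nd, type = "lpmatrix")
  Xg[, plate_cols(fit)] <- 0
  Xg
}

#' Posterior settlement curve for one cue
#'
#' Pointwise posterior median and 95% credible interval of the fitted
#' settlement probability over an age grid (population level: plate effects
#' marginalized at zero). Extrapolation beyond the observed age range is
#' refused.
#'
#' @param draws a fitted `posterior_draws` from [fit_settlement_gam()].
#' @param cue cue label.
#' @param age_grid ages (days) within the observed range.
#' @return a `settlement_curve` data.frame: age, median, ci_lower, ci_upper.
#' @export
curve_from_draws <- function(draws, cue, age_grid) {
  Xg <- gam_lpmatrix(draws, cue, age_grid)
  B <- as.matrix(draws)
  P <- plogis(Xg %*% t(B))  # grid x draws
  qs <- t(apply(P, 1, quantile, c(0.025, 0.5, 0.975)))
  structure(data.frame(cue = cue, age = age_grid,
                       median = qs[, 2], ci_lower = qs[, 1],
                       ci_upper = qs[, 3], stringsAsFactors = FALSE),
            class = c("settlement_curve", "data.frame"))
}

# trapezoid rule over a uniform grid
trapezoid <- function(y, h) h * (sum(y) - (y[1] + y[length(y)]) / 2)

#' Posterior area under the settlement curve for one cue
#'
#' For each retained posterior draw, numerically integrates (trapezoid rule)
#' the inverse-logit settlement curve over a uniform grid of `resolution`
#' points spanning the observed age range. Units: proportion-days.
#'
#' @param draws a fitted `posterior_draws` from [fit_settlement_gam()].
#' @param cue cue label.
#' @param age_range integration range; defaults to the observed age range.
#' @param resolution number of grid points (>= 2; default 100).
#' @return an `auc_posterior`: list(cue, areas, resolution, age_range).
#' @export
auc_per_draw <- function(draws, cue, age_range = attr(draws, "age_range"),
                         resolution = 100) {
  if (resolution < 2) cc_stop("`resolution` must be >= 2")
  grid <- seq(age_range[1], age_range[2], length.out = resolution)
  Xg <- gam_lpmatrix(draws, cue, grid)
  B <- as.matrix(draws)
  if (nrow(B) == 0) cc_stop("empty draws")
  P <- plogis(Xg %*% t(B))
  h <- diff(age_range) / (resolution - 1)
  structure(list(cue = cue,
                 areas = apply(P, 2, trapezoid, h = h),
                 resolution = resolution,
                 age_range = age_range),
            class = "auc_posterior")
}

#' Rank settlement cues by posterior area under the curve
#'
#' Orders cues from strongest to weakest by the posterior median of their
#' area under the fitted settlement curve, then declares adjacent cues
#' separated (">") when the exceedance probability that the higher-ranked
#' cue's area exceeds the lower-ranked one's reaches `cutoff`, and tied
#' ("=") otherwise, chaining ties transitively into groups.
#'
#' @param aucs named list of `auc_posterior` objects (or equal-length
#'   numeric vectors of per-draw areas), one per cue, control included.
#' @param cutoff exceedance probability required to declare a separation
#'   (default 0.95).
#' @return a `cue_ranking`: list(ordered_groups, display, exceedance_cutoff,
#'   medians, exceedance matrix).
#' @export
rank_cues <- function(aucs, cutoff = 0.95) {
  areas <- lapply(aucs, function(a) if (inherits(a, "auc_posterior")) a$areas else a)
  if (length(areas) < 2) cc_stop("need >= 2 cues to rank")
  if (length(unique(lengths(areas))) != 1)
    cc_stop("mismatched draw counts across cues")
  med <- vapply(areas, median, numeric(1))
  ord <- order(-med, names(areas))  # ties broken alphabetically
  cues <- names(areas)[ord]
  M <- matrix(0.5, length(cues), length(cues), dimnames = list(cues, cues))
  for (i in seq_along(cues)) for (j in seq_along(cues)) if (i != j)
    M[i, j] <- exceedance_prob(areas[[cues[j]]], areas[[cues[i]]])
  groups <- list(cues[1])
  for (i in seq_along(cues)[-1]) {
    if (M[cues[i - 1], cues[i]] >= cutoff)
      groups <- c(groups, list(cues[i]))
    else
      groups[[length(groups)]] <- c(groups[[length(groups)]], cues[i])
  }
  display <- paste(vapply(groups, paste, character(1), collapse = " = "),
                   collapse = " > ")
  structure(list(ordered_groups = groups, display = display,
                 exceedance_cutoff = cutoff, medians = med[ord],
                 exceedance = M),
            class = "cue_ranking")
}

#' @export
print.cue_ranking <- function(x, ...) {
  cat("Cue ranking (exceedance cutoff", x$exceedance_cutoff, "):\n  ",
      x$display, "\n", sep = "")
  invisible(x)
}
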