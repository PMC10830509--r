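test_that("spline basis: shape, knots, degenerate inputs", {
  ages <- 2:10
  b <- build_spline_basis(ages, n_knots = 5)
  expect_equal(dim(b$basis_matrix), c(9, 5))
  expect_equal(b$n_knots, 5L)
  expect_equal(range(b$knot_locations), range(ages))  # quantile knots span data
  expect_true(all(is.finite(b$basis_matrix)))

  # n_knots 2 degenerates to {1, age}
  b2 <- build_spline_basis(ages, n_knots = 2)
  expect_equal(b2$basis_matrix, cbind(1, ages), ignore_attr = TRUE)

  expect_error(build_spline_basis(rep(5, 10)), "distinct ages")
  expect_warning(build_spline_basis(c(2, 4, 6), n_knots = 5), "reducing|fewer")
  expect_warning(build_spline_basis(2:20, n_knots = 7), "overfitting")
})

test_that("cubic regression spline basis is C2 across its knots", {
  ages <- seq(2, 14, by = 1)
  b <- build_spline_basis(ages, n_knots = 5)
  # an arbitrary coefficient vector defines one member of the basis family
  beta <- c(0.3, -1.2, 2.0, 0.7, -0.5)
  f <- function(x) drop(predict(b, x) %*% beta)
  h <- 1e-4
  for (k in b$knot_locations[2:4]) {
    lo <- f(k - h * c(3, 2, 1)); hi <- f(k + h * c(1, 2, 3))
    # value continuity (the 2h gap itself contributes ~2h|f'|)
    expect_equal(lo[3], hi[1], tolerance = 1e-3)
    # one-sided first derivatives agree
    d1lo <- (3 * lo[3] - 4 * lo[2] + lo[1]) / (2 * h)
    d1hi <- (-3 * hi[1] + 4 * hi[2] - hi[3]) / (2 * h)
    expect_equal(d1lo, d1hi, tolerance = 1e-3 * (1 + abs(d1lo)))
    # one-sided second differences agree (C2)
    d2lo <- (lo[1] - 2 * lo[2] + lo[3]) / h^2
    d2hi <- (hi[1] - 2 * hi[2] + hi[3]) / h^2
    expect_equal(d2lo, d2hi, tolerance = 1e-2 * (1 + abs(d2lo)))
  }
  # evaluation is finite everywhere in range
  expect_true(all(is.finite(predict(b, seq(2, 14, by = 0.05)))))
})

test_that("GAM fit: determinism, flat-truth recovery, single-plate warning", {
  # flat latent truth p = 0.4 across ages
  pr <- species_profile(onset_age = -10, onset_slope = 1.5, asymptote = 0.4,
                        cue_effects = c(Control = 0, CCA = 0),
                        plate_sd = 0.1, plate_slope_sd = 0.01)
  des <- assay_design(timepoints = seq(2, 14, by = 2), wells_per_treatment = 6)
  obs <- simulate_assays(pr, des, seed = 31)
  cfg <- quick_config(4)
  f1 <- fit_settlement_gam(obs, config = cfg)
  f2 <- fit_settlement_gam(obs, config = cfg)
  expect_identical(f1$draws, f2$draws)
  for (cue in c("Control", "CCA")) {
    cv <- curve_from_draws(f1, cue, seq(2, 14, length.out = 30))
    expect_true(all(cv$ci_lower <= 0.4 + 0.12 & cv$ci_upper >= 0.4 - 0.12))
    expect_lt(diff(range(cv$median)), 0.25)  # no spurious trend
  }
  # single plate drops the varying effects with a warning
  obs1 <- obs
  obs1$plate_id <- "P1"
  expect_warning(fit_settlement_gam(obs1, config = cfg), "single plate")
  expect_error(fit_settlement_gam(obs[obs$age_days <= 4, ], config = cfg),
               "3 distinct timepoints")
})

test_that("GAM recovers a bimodal settlement pattern at 5 knots", {
  pr <- species_profile(
    onset_age = 3, onset_slope = 2, asymptote = 0.9,
    temporal_modes = list(list(center = 10, width = 2, amplitude = -0.85)),
    plate_sd = 0.2, plate_slope_sd = 0.02)
  obs <- simulate_assays(pr, assay_design(timepoints = seq(2, 20, by = 2)),
                         seed = 21)
  fit <- fit_settlement_gam(obs, n_knots = 5, config = quick_config(2))
  cv <- curve_from_draws(fit, "Rubble", seq(2, 20, length.out = 50))
  med <- cv$median
  trough <- which.min(med[10:40]) + 9  # interior trough
  expect_gt(max(med[1:trough]) - med[trough], 0.15)
  expect_gt(max(med[trough:50]) - med[trough], 0.15)
})

test_that("curves: point mass, one-point grid, percentile oracle, bounds", {
  obs <- default_sim()
  fit <- fit_settlement_gam(obs, config = quick_config(6))
  # collapse to a point mass at the posterior mode
  pm <- fit
  mode <- attr(fit, "map")
  for (ch in seq_len(dim(pm$draws)[1]))
    pm$draws[ch, , ] <- matrix(mode, dim(pm$draws)[2], length(mode),
                               byrow = TRUE)
  cv <- curve_from_draws(pm, "CCA", c(4, 8))
  expect_equal(cv$median, cv$ci_lower)
  expect_equal(cv$median, cv$ci_upper)

  one <- curve_from_draws(fit, "CCA", 6)
  expect_equal(nrow(one), 1)
  expect_true(one$ci_lower <= one$median && one$median <= one$ci_upper)

  # 3-draw percentile oracle at a single grid point
  toy <- fit
  toy$draws <- fit$draws[1, 1:3, , drop = FALSE]
  Xg <- coralcomp:::gam_lpmatrix(toy, "CCA", 6)
  vals <- sort(plogis(drop(Xg %*% t(matrix(toy$draws[1, , ],
                                           3, dim(fit$draws)[3])))))
  cv3 <- curve_from_draws(toy, "CCA", 6)
  expect_equal(cv3$median, vals[2])
  expect_equal(cv3$ci_lower, unname(quantile(vals, 0.025)))

  expect_error(curve_from_draws(fit, "CCA", c(1, 6)), "extrapolation")
  expect_error(curve_from_draws(fit, "Kelp", 6), "cue")
})

test_that("trapezoid AUC is exact on affine curves and refines smoothly", {
  # affine integrand: exact at any resolution
  grid <- seq(0, 10, length.out = 100)
  h <- diff(grid[1:2])
  lin <- 0.1 * grid  # linear in p from 0 to 1 over 10 days
  expect_equal(coralcomp:::trapezoid(lin, h), 5.0, tolerance = 1e-12)
  const <- rep(0.5, 100)
  expect_equal(coralcomp:::trapezoid(const, h), 5.0, tolerance = 1e-12)

  obs <- default_sim()
  fit <- fit_settlement_gam(obs, config = quick_config(6))
  a100 <- auc_per_draw(fit, "Rubble", resolution = 100)
  a10k <- auc_per_draw(fit, "Rubble", resolution = 10000)
  expect_lt(max(abs(a100$areas - a10k$areas) / a10k$areas), 1e-3)
  expect_true(all(a100$areas >= 0))
  expect_true(all(a100$areas <= diff(attr(fit, "age_range")) + 1e-9))
  expect_error(auc_per_draw(fit, "Rubble", resolution = 1), "resolution")
})

test_that("cue ranking: separations, ties, oracle and invariance", {
  pm <- function(v) rep(v, 200)
  expect_equal(rank_cues(list(A = pm(8), B = pm(2)))$display, "A > B")
  expect_equal(rank_cues(list(A = pm(4), B = pm(4)))$display, "A = B")

  set.seed(44)
  areas <- list(X = rnorm(500, 10, 1), Y = rnorm(500, 9.5, 1),
                Z = rnorm(500, 5, 1))
  rk <- rank_cues(areas, cutoff = 0.95)
  # brute-force pairwise exceedance grouping oracle
  exc <- function(a, b) mean(a > b) + 0.5 * mean(a == b)
  expect_equal(rk$exceedance["X", "Y"], exc(areas$X, areas$Y), tolerance = 1e-12)
  expect_lt(exc(areas$X, areas$Y), 0.95)   # X and Y overlap -> tied
  expect_gt(exc(areas$Y, areas$Z), 0.95)   # Z separated
  expect_equal(rk$display, "X = Y > Z")
  # invariance under a common monotone rescaling
  rk2 <- rank_cues(lapply(areas, function(a) exp(a / 3)), cutoff = 0.95)
  expect_equal(rk2$display, rk$display)

  expect_error(rank_cues(list(A = 1:5)), ">= 2")
  expect_error(rank_cues(list(A = 1:5, B = 1:4)), "mismatched")
})

test_that("curve accuracy improves with replication (integrated error)", {
  pr <- species_profile(plate_sd = 0.1, plate_slope_sd = 0.01)
  grid <- seq(2, 14, length.out = 60)
  iae <- sapply(c(2, 12), function(nw) {
    obs <- simulate_assays(pr, assay_design(wells_per_treatment = nw),
                           seed = 5150)
    fit <- fit_settlement_gam(obs, config = quick_config(8))
    tot <- 0
    for (cue in c("Control", "CCA", "Rubble")) {
      cv <- curve_from_draws(fit, cue, grid)
      tot <- tot + mean(abs(cv$median -
                              true_settlement_probability(pr, grid, cue)))
    }
    tot
  })
  expect_lt(iae[2], iae[1])
})
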