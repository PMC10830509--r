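obs_row <- function(n_settled, n_larvae, age = 5, cue = "CCA") {
  data.frame(species_id = "S", cohort_id = "C1", age_days = age, cue = cue,
             plate_id = "p", well_id = "w", n_larvae = n_larvae,
             n_settled = n_settled, stringsAsFactors = FALSE)
}

test_that("binarization applies the inclusive threshold rule", {
  o <- rbind(obs_row(3, 10), obs_row(0, 10), obs_row(2, 9))
  r <- binarize_competency(o, 0.3)
  expect_equal(r$competent, c(1L, 0L, 0L))  # 3/10 >= 0.3; 2/9 = 0.222 < 0.3
  expect_equal(attr(r, "threshold"), 0.3)
  # strict variant flips only the boundary case
  expect_equal(binarize_competency(o, 0.3, inclusive = FALSE)$competent,
               c(0L, 0L, 0L))
  expect_error(binarize_competency(o, 0), "threshold")
  expect_error(binarize_competency(o, 1.5), "threshold")
  expect_warning(r0 <- binarize_competency(rbind(o, obs_row(0, 0)), 0.3),
                 "rejected")
  expect_equal(nrow(r0), 3)
})

test_that("competency log posterior matches a brute-force oracle", {
  prior <- prior_spec()
  params <- list(alpha = c(CCA = -2, Control = -4), beta = c(CCA = 0.8, Control = 0.5))
  set.seed(3)
  rec <- data.frame(
    species_id = "S", cohort_id = "C1",
    age_days = c(2, 4, 6, 8, 2, 4, 6, 8),
    cue = rep(c("CCA", "Control"), each = 4),
    competent = c(0, 1, 1, 1, 0, 0, 1, 1))
  got <- competency_log_posterior(params, rec, prior)
  # independently coded: sum of Bernoulli log-pmfs plus normal log priors
  eta <- ifelse(rec$cue == "CCA", -2 + 0.8 * rec$age_days,
                -4 + 0.5 * rec$age_days)
  p <- 1 / (1 + exp(-eta))
  oracle <- sum(log(ifelse(rec$competent == 1, p, 1 - p))) +
    sum(dnorm(c(-2, -4), 0, 5, log = TRUE)) +
    sum(dnorm(c(0.8, 0.5), 0, 2.5, log = TRUE))
  expect_equal(got, oracle, tolerance = 1e-10)

  # single record at eta = 0 contributes log(0.5) of likelihood
  one <- rec[1, ]; one$competent <- 1
  p0 <- list(alpha = c(CCA = 0), beta = c(CCA = 0))
  prior_only <- dnorm(0, 0, 5, log = TRUE) + dnorm(0, 0, 2.5, log = TRUE)
  expect_equal(competency_log_posterior(p0, one, prior), log(0.5) + prior_only)

  expect_error(
    competency_log_posterior(list(alpha = c(CCA = 0), beta = c(CCA = 0)),
                             rec, prior),
    "Control")
})

test_that("TC50 extraction: closed form, point mass, truncation", {
  d <- fake_competency_draws(alpha = list(A = rep(-4, 50)),
                             beta = list(A = rep(1, 50)), cues = "A")
  e <- tc50_from_draws(d, "A")
  expect_equal(e$tc50_median, 4)
  expect_equal(e$ci_lower, 4)
  expect_equal(e$ci_upper, 4)
  expect_false(e$truncated)

  neg <- fake_competency_draws(alpha = list(A = rep(-4, 50)),
                               beta = list(A = rep(-1, 50)), cues = "A")
  en <- tc50_from_draws(neg, "A")
  expect_true(en$truncated)
  expect_equal(en$tc50_median, Inf)

  expect_error(tc50_from_draws(d, "B"), "cue")
})

test_that("per-draw TC50 equals numeric root finding of the logistic", {
  set.seed(12)
  a <- rnorm(1000, -4, 0.1); b <- rnorm(1000, 1, 0.05)
  d <- fake_competency_draws(alpha = list(A = a), beta = list(A = b), cues = "A")
  t50 <- tc50_draws(d, "A")
  roots <- mapply(function(ai, bi)
    uniroot(function(t) plogis(ai + bi * t) - 0.5, c(-100, 100),
            tol = 1e-12)$root, a, b)
  expect_lt(max(abs(t50 - roots)), 1e-8)
  est <- tc50_from_draws(d, "A")
  expect_equal(est$tc50_median, median(roots), tolerance = 1e-8)
})

test_that("model fit is deterministic and recovers a null age effect", {
  set.seed(5)
  n <- 120
  rec <- data.frame(species_id = "S", cohort_id = "C1",
                    age_days = rep(seq(2, 12, by = 2), each = 20),
                    cue = "CCA",
                    competent = rbinom(n, 1, 0.5))
  cfg <- quick_config(seed = 9)
  f1 <- suppressWarnings(fit_competency_model(rec, cfg))
  f2 <- suppressWarnings(fit_competency_model(rec, cfg))
  expect_identical(f1$draws, f2$draws)
  b <- as.matrix(f1)[, "beta[CCA]"]
  ci <- quantile(b, c(0.025, 0.975))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("posterior medians agree with maximum likelihood at large n", {
  pr <- species_profile(cue_effects = c(Control = 0, Rubble = 1.5),
                        plate_sd = 0, plate_slope_sd = 0)
  # half-day spacing resolves the competency transition so the ML fit is
  # finite (coarser designs are quasi-separated and ML diverges)
  des <- assay_design(timepoints = seq(2, 7, by = 0.5),
                      wells_per_treatment = 60)  # 660 wells per cue
  rec <- binarize_competency(simulate_assays(pr, des, seed = 77), 0.3)
  fit <- suppressWarnings(fit_competency_model(rec, quick_config(2)))
  ml <- suppressWarnings(
    glm(competent ~ 0 + cue + cue:age_days, family = binomial(), data = rec))
  mlc <- coef(ml)
  m <- as.matrix(fit)
  for (cue in c("Control", "Rubble")) {
    pm_a <- median(m[, paste0("alpha[", cue, "]")])
    pm_b <- median(m[, paste0("beta[", cue, "]")])
    expect_lt(abs(pm_a - mlc[paste0("cue", cue)]),
              2 * sd(m[, paste0("alpha[", cue, "]")]))
    expect_lt(abs(pm_b - mlc[paste0("cue", cue, ":age_days")]),
              2 * sd(m[, paste0("beta[", cue, "]")]))
  }
})

test_that("multi-cohort data activate the hierarchical intercepts", {
  pr <- species_profile(cue_effects = c(Control = 0, CCA = 2),
                        plate_sd = 0, plate_slope_sd = 0)
  des <- assay_design(timepoints = seq(2, 10, by = 2), wells_per_treatment = 4)
  o <- rbind(simulate_assays(pr, des, seed = 1, cohort_id = "C1"),
             simulate_assays(pr, des, seed = 2, cohort_id = "C2"))
  fit <- suppressWarnings(
    fit_competency_model(binarize_competency(o, 0.3), quick_config(3)))
  expect_true(all(c("u[C1]", "u[C2]", "log_sd_cohort") %in%
                    fit$parameter_names))
})

test_that("threshold sweep is consistent, ordered, and names the best cue", {
  pr <- species_profile(plate_sd = 0, plate_slope_sd = 0)
  obs <- simulate_assays(pr, assay_design(), seed = 11)
  cfg <- quick_config(5)
  sw <- suppressWarnings(threshold_sweep(obs, c(0.3, 0.6), cfg))
  expect_true(all(c(0.3, 0.6) %in% sw$threshold))
  expect_true("Best" %in% sw$cue)
  # single-threshold sweep equals a direct fit under the same seed substream
  sw1 <- suppressWarnings(threshold_sweep(obs, 0.3, cfg))
  cfg1 <- cfg; cfg1$seed <- stage_seed(cfg$seed, 3)
  fit <- suppressWarnings(
    fit_competency_model(binarize_competency(obs, 0.3), cfg1))
  direct <- tc50_from_draws(fit, "Control", max_age = max(obs$age_days))
  expect_equal(sw1[sw1$cue == "Control", ]$tc50_median, direct$tc50_median)
  # best = argmin over non-control cues
  at3 <- sw[sw$threshold == 0.3 & !sw$cue %in% c("Best", "Control"), ]
  expect_equal(sw[sw$threshold == 0.3 & sw$cue == "Best", ]$tc50_median,
               min(at3$tc50_median))
  expect_error(threshold_sweep(obs, 0.35, cfg), "subset")
})

test_that("exceedance matrices match brute-force counting and complement", {
  set.seed(8)
  draws <- list(A = rnorm(1000, 3, 1), B = rnorm(1000, 5, 2),
                C = rnorm(1000, 4, 0.5))
  M <- cue_tc50_contrasts(draws)
  # brute-force paired counting oracle
  for (i in names(draws)) for (j in names(draws)) if (i != j) {
    cnt <- 0
    for (k in seq_len(1000)) {
      if (draws[[i]][k] < draws[[j]][k]) cnt <- cnt + 1
      else if (draws[[i]][k] == draws[[j]][k]) cnt <- cnt + 0.5
    }
    expect_equal(M[i, j], cnt / 1000, tolerance = 1e-12)
    expect_equal(M[i, j] + M[j, i], 1)
  }
  # ties and point masses
  expect_equal(cue_tc50_contrasts(list(A = rep(1, 10), B = rep(1, 10)))["A", "B"], 0.5)
  expect_equal(cue_tc50_contrasts(list(A = rep(3, 10), B = rep(5, 10)))["A", "B"], 1)
  expect_error(cue_tc50_contrasts(list(A = 1:5, B = 1:4)), "mismatched")
})
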