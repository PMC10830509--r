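#' MCMC sampler configuration
#'
#' Defaults follow the sampler settings used throughout the analysis:
#' three chains of 6000 iterations, a warm-up of 2000, thinned at a rate of
#' 10, leaving 400 retained draws per chain.
#'
#' @param n_chains number of chains (>= 1).
#' @param n_iterations iterations per chain.
#' @param warmup discarded initial iterations per chain (< `n_iterations`).
#' @param thin keep every `thin`-th post-warmup iteration (>= 1).
#' @param seed integer seed.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(n_chains = 3, n_iterations = 6000, warmup = 2000,
                           thin = 10, seed = 1) {
  if (warmup >= n_iterations) cc_stop("`warmup` must be < `n_iterations`")
  if (thin < 1) cc_stop("`thin` must be >= 1")
  if (n_chains < 1) cc_stop("`n_chains` must be >= 1")
  structure(list(n_chains = as.integer(n_chains),
                 n_iterations = as.integer(n_iterations),
                 warmup = as.integer(warmup),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "sampler_config")
}

n_retained <- function(config) {
  (config$n_iterations - config$warmup) %/% config$thin
}

new_posterior_draws <- function(draws, parameter_names, model_tag, ...) {
  stopifnot(length(dim(draws)) == 3, dim(draws)[3] == length(parameter_names))
  if (any(!is.finite(draws))) cc_stop("non-finite posterior draws")
  dimnames(draws) <- list(NULL, NULL, parameter_names)
  structure(list(parameter_names = parameter_names,
                 draws = draws,
                 model_tag = model_tag),
            class = "posterior_draws", ...)
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat("<posterior_draws>", x$model_tag, ":", d[1], "chains x", d[2],
      "draws x", d[3], "parameters\n")
  m <- as.matrix(x)
  qs <- t(apply(m, 2, quantile, c(0.025, 0.5, 0.975)))
  print(round(qs, 3))
  invisible(x)
}

#' Flatten posterior draws to a matrix
#'
#' @param x a `posterior_draws` object.
#' @param ... unused.
#' @return a (chains x retained draws) by parameters matrix.
#' @export
as.matrix.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  m <- matrix(aperm(x$draws, c(2, 1, 3)), d[1] * d[2], d[3])
  colnames(m) <- x$parameter_names
  m
}

# ---- Laplace-proposal independence Metropolis-Hastings ---------------------
#
# The posteriors fitted here (logistic regression and penalized binomial
# GAMs) are smooth, low-dimensional and close to Gaussian at assay scale, so
# an independence sampler with a multivariate-t proposal centred on the
# posterior mode is both exact (it targets the stated posterior) and nearly
# uncorrelated draw-to-draw, which keeps effective sample sizes high at the
# default thinning rate.

make_pd <- function(M) {
  e <- eigen(M, symmetric = TRUE)
  vals <- pmax(e$values, max(abs(e$values)) * 1e-8)
  e$vectors %*% (vals * t(e$vectors))
}

laplace_mh <- function(log_post, init, config, param_names,
                       mode = NULL, vcov = NULL, proposal_df = 5,
                       proposal_inflate = 1.3, model_tag = "model") {
  d <- length(init)
  if (is.null(mode) || is.null(vcov)) {
    opt <- optim(init, log_post, method = "BFGS",
                 control = list(fnscale = -1, maxit = 1000, reltol = 1e-12),
                 hessian = TRUE)
    mode <- mode %||% opt$par
    if (is.null(vcov)) {
      H <- -opt$hessian
      vcov <- tryCatch(chol2inv(chol(H)), error = function(e) solve(make_pd(H)))
    }
  }
  proposal <- function(m, V) {
    V <- make_pd((V + t(V)) / 2) * proposal_inflate
    L <- t(chol(V))
    Vinv <- chol2inv(chol(V))
    list(
      draw = function() {
        g <- sqrt(stats::rchisq(1, proposal_df) / proposal_df)
        m + drop(L %*% rnorm(d)) / g
      },
      logq = function(theta) {
        z <- theta - m
        -((proposal_df + d) / 2) *
          log1p(drop(crossprod(z, Vinv %*% z)) / proposal_df)
      })
  }
  nk <- n_retained(config)
  draws <- array(NA_real_, c(config$n_chains, nk, d))
  accepted <- 0L
  with_seed(config$seed, {
    for (ch in seq_len(config$n_chains)) {
      # Warmup runs under the Laplace proposal; at the end of warmup the
      # proposal is re-moment-matched to the warmup states and frozen, so
      # the retained chain is a valid (non-adaptive) independence sampler.
      q <- proposal(mode, vcov)
      cur <- mode
      lp_cur <- log_post(cur); lq_cur <- q$logq(cur)
      kept <- 0L
      wu <- matrix(NA_real_, config$warmup, d)
      wu_acc <- 0L
      for (it in seq_len(config$n_iterations)) {
        prop <- q$draw()
        lp_prop <- log_post(prop)
        if (is.finite(lp_prop)) {
          lq_prop <- q$logq(prop)
          if (log(runif(1)) < (lp_prop - lp_cur) + (lq_cur - lq_prop)) {
            cur <- prop; lp_cur <- lp_prop; lq_cur <- lq_prop
            if (it > config$warmup) accepted <- accepted + 1L
            else wu_acc <- wu_acc + 1L
          }
        } else runif(1)  # keep the RNG stream length fixed
        if (it <= config$warmup) {
          wu[it, ] <- cur
          if (it == config$warmup && wu_acc >= 25 && config$warmup >= 50) {
            half <- wu[seq.int(config$warmup %/% 2, config$warmup), ,
                       drop = FALSE]
            Vw <- var(half)
            q2 <- tryCatch(proposal(colMeans(half), Vw),
                           error = function(e) NULL)
            if (!is.null(q2)) {
              q <- q2
              lq_cur <- q$logq(cur)
            }
          }
        } else if ((it - config$warmup) %% config$thin == 0 && kept < nk) {
          kept <- kept + 1L
          draws[ch, kept, ] <- cur
        }
      }
    }
  })
  new_posterior_draws(draws, param_names, model_tag,
                      accept_rate = accepted /
                        (config$n_chains * (config$n_iterations - config$warmup)),
                      map = setNames(mode, param_names),
                      vcov = vcov, config = config)
}

# ---- convergence diagnostics ----------------------------------------------

split_chains <- function(ch) {
  n <- nrow(ch)
  h <- n %/% 2
  cbind(ch[seq_len(h), , drop = FALSE],
        ch[seq.int(n - h + 1, n), , drop = FALSE])
}

rhat_split <- function(ch) {
  ch <- split_chains(ch)
  n <- nrow(ch); m <- ncol(ch)
  if (n < 2) return(NA_real_)
  W <- mean(apply(ch, 2, var))
  B <- n * var(colMeans(ch))
  if (W == 0) return(if (B == 0) 1 else Inf)
  varplus <- (n - 1) / n * W + B / n
  sqrt(varplus / W)
}

ess_mean <- function(ch) {
  ch <- split_chains(ch)
  n <- nrow(ch); m <- ncol(ch)
  if (n < 3) return(NA_real_)
  W <- mean(apply(ch, 2, var))
  B <- n * var(colMeans(ch))
  varplus <- (n - 1) / n * W + B / n
  if (varplus == 0) return(NA_real_)
  # chain-averaged autocovariances (denominator n, as in split-ESS estimators)
  acov <- sapply(seq_len(m), function(j)
    drop(acf(ch[, j], lag.max = n - 1, type = "covariance",
             plot = FALSE, demean = TRUE)$acf))
  mean_acov <- rowMeans(acov) * (n - 1) / n
  rho <- 1 - (W - mean_acov) / varplus   # rho[1] is lag 0 (= ~1)
  # Geyer initial monotone positive sequence on paired sums
  maxpairs <- (n - 1) %/% 2
  s <- numeric(maxpairs)
  prev <- Inf
  total <- 0
  for (k in seq_len(maxpairs)) {
    pair <- rho[2 * k] + rho[2 * k + 1]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    total <- total + pair
  }
  tau <- 1 + 2 * total   # rho at lag 0 contributes 1
  max(n * m / tau, 0)
}

#' Convergence diagnostics for posterior draws
#'
#' Split-Rhat and effective sample size per parameter, with an overall pass
#' flag (default: all Rhat < 1.01 and all ESS > 400). With a single chain
#' Rhat is undefined and reported as `NA`; the pass flag then rests on ESS
#' alone.
#'
#' @param draws a `posterior_draws` object.
#' @param rhat_max largest acceptable split-Rhat.
#' @param ess_min smallest acceptable effective sample size.
#' @return a `convergence_report`: data.frame (parameter, rhat, ess) with
#'   attributes `pass`, `rhat_max`, `ess_min`.
#' @export
convergence_diagnostics <- function(draws, rhat_max = 1.01, ess_min = 400) {
  stopifnot(inherits(draws, "posterior_draws"))
  nc <- dim(draws$draws)[1]
  per <- lapply(seq_along(draws$parameter_names), function(j) {
    ch <- t(draws$draws[, , j, drop = TRUE])
    if (nc == 1) ch <- matrix(draws$draws[1, , j], ncol = 1)
    data.frame(parameter = draws$parameter_names[j],
               rhat = if (nc >= 2) rhat_split(ch) else NA_real_,
               ess = ess_mean(ch))
  })
  rep <- do.call(rbind, per)
  pass <- all(is.na(rep$rhat) | rep$rhat < rhat_max) &&
    all(rep$ess > ess_min, na.rm = TRUE)
  if (nc == 1)
    cc_warn("single chain: split-Rhat undefined, reported as NA")
  structure(rep, pass = pass, rhat_max = rhat_max, ess_min = ess_min,
            class = c("convergence_report", "data.frame"))
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("Convergence diagnostics (pass =", attr(x, "pass"), "; Rhat <",
      attr(x, "rhat_max"), ", ESS >", attr(x, "ess_min"), ")\n")
  print.data.frame(cbind(x[1], round(x[-1], 1)), row.names = FALSE)
  invisible(x)
}
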