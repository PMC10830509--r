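# shared helpers: reduced sampler settings keep the suite fast while leaving
# hundreds of retained draws; fake draw objects exercise closed-form paths.

quick_config <- function(seed = 1) {
  sampler_config(n_chains = 2, n_iterations = 1200, warmup = 400,
                 thin = 4, seed = seed)
}

# a posterior_draws object with prescribed per-draw alpha/beta for given cues
fake_competency_draws <- function(alpha, beta, cues = names(alpha),
                                  age_range = c(2, 14), threshold = 0.3) {
  stopifnot(is.list(alpha), is.list(beta))
  nd <- length(alpha[[1]])
  nc <- length(cues)
  arr <- array(NA_real_, c(1, nd, 2 * nc))
  for (i in seq_len(nc)) {
    arr[1, , i] <- alpha[[cues[i]]]
    arr[1, , nc + i] <- beta[[cues[i]]]
  }
  d <- coralcomp:::new_posterior_draws(
    arr, c(paste0("alpha[", cues, "]"), paste0("beta[", cues, "]")),
    "competency_logistic")
  attr(d, "cues") <- cues
  attr(d, "species_id") <- "fake"
  attr(d, "threshold") <- threshold
  attr(d, "age_range") <- age_range
  d
}

# simulated single-species dataset reused by several files
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_assays(species_profile(), assay_design(), seed = 42)
    cache
  }
})
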