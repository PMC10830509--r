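#' Ground-truth species profile for synthetic settlement assays
#'
#' A `species_profile` states the latent truth from which synthetic assay data
#' are simulated: a logistic competency onset (age at which the baseline
#' settlement probability curve crosses half its asymptote), cue-specific
#' additive shifts on the logit scale, a maximum settlement proportion, an
#' optional multiplicative temporal envelope (Gaussian activity bumps
#' emulating the multimodal settlement patterns seen in long assay series),
#' and plate-level dependency (random intercept and age-slope SDs).
#'
#' Defaults describe a typical mid-precompetency broadcast spawner: onset at
#' 4 days after fertilization, slope 1.5 logit units per day, asymptote 0.9,
#' conditioned rubble the strongest cue, and a rare spontaneous settlement
#' response in the filtered-seawater control (logit shift 0 relative to a
#' late-onset baseline, so early control settlement is near zero).
#'
#' @param species_id species label.
#' @param onset_age age (days after fertilization) at the logistic midpoint of
#'   the baseline (control) curve.
#' @param onset_slope logistic slope, logit units per day; must be positive.
#' @param cue_effects named numeric vector of additive logit shifts, one per
#'   cue; must contain a cue named `"Control"` (case-insensitive) which
#'   carries the lowest shift.
#' @param asymptote maximum settlement proportion, in (0, 1].
#' @param temporal_modes list of `list(center=, width=, amplitude=)` Gaussian
#'   bumps multiplying the onset curve; negative amplitudes create troughs.
#' @param plate_sd SD (logit scale) of plate-level random intercepts.
#' @param plate_slope_sd SD (logit scale per day) of plate-level age slopes.
#' @return an object of class `species_profile`.
#' @examples
#' pr <- species_profile(onset_age = 4, onset_slope = 1.5, asymptote = 0.9)
#' true_settlement_probability(pr, age = 6, cue = "Control")
#' @export
species_profile <- function(species_id = "SpA",
                            onset_age = 4,
                            onset_slope = 1.5,
                            cue_effects = c(Control = 0, CCA = 2.5,
                                            Extract = 1.2, Peptide = 0.8,
                                            Disc = 1.8, Rubble = 3.0),
                            asymptote = 0.9,
                            temporal_modes = list(),
                            plate_sd = 0.3,
                            plate_slope_sd = 0.05) {
  if (!is.numeric(onset_slope) || onset_slope <= 0)
    cc_stop("`onset_slope` must be > 0")
  if (asymptote <= 0 || asymptote > 1)
    cc_stop("`asymptote` must lie in (0, 1]")
  if (plate_sd < 0 || plate_slope_sd < 0)
    cc_stop("plate SDs must be >= 0")
  if (is.null(names(cue_effects)) || !any(tolower(names(cue_effects)) == "control"))
    cc_stop("`cue_effects` must contain a cue named \"Control\"")
  for (m in temporal_modes) {
    if (!all(c("center", "width", "amplitude") %in% names(m)) || m$width <= 0)
      cc_stop("each temporal mode needs center, width (> 0) and amplitude")
  }
  structure(
    list(species_id = species_id,
         onset_age = onset_age,
         onset_slope = onset_slope,
         cue_effects = cue_effects,
         asymptote = asymptote,
         temporal_modes = temporal_modes,
         plate_sd = plate_sd,
         plate_slope_sd = plate_slope_sd),
    class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile>", x$species_id, "\n")
  cat("  onset", x$onset_age, "d, slope", x$onset_slope,
      "logit/d, asymptote", x$asymptote, "\n")
  cat("  cues:", paste(sprintf("%s=%+.2f", names(x$cue_effects), x$cue_effects),
                       collapse = ", "), "\n")
  cat("  plate_sd", x$plate_sd, " plate_slope_sd", x$plate_slope_sd,
      " temporal modes:", length(x$temporal_modes), "\n")
  invisible(x)
}

#' Settlement-assay design
#'
#' Describes the factorial layout of a repeated 24-h settlement assay series:
#' which larval ages are assayed, which cues are offered, and the replication
#' per species x cue x timepoint cell. The default mirrors the common design
#' of 6 replicate wells of nominally 10 larvae each, with one six-well plate
#' per cue x timepoint assay, sampled from day 2 onwards.
#'
#' @param timepoints strictly increasing larval ages (days after
#'   fertilization), all >= 0.
#' @param cues cue labels; `NULL` means "use the profile's cues".
#' @param wells_per_treatment replicate wells per cue x timepoint (>= 1).
#' @param larvae_per_well nominal larvae loaded per well (>= 1).
#' @param poisson_larvae if `TRUE`, jitter larvae counts per well as
#'   `1 + Poisson(larvae_per_well - 1)`, reflecting occasional variation in
#'   larval availability.
#' @return an object of class `assay_design`.
#' @export
assay_design <- function(timepoints = c(2:8, 10, 12, 14),
                         cues = NULL,
                         wells_per_treatment = 6,
                         larvae_per_well = 10,
                         poisson_larvae = FALSE) {
  if (any(timepoints < 0) || is.unsorted(timepoints, strictly = TRUE))
    cc_stop("`timepoints` must be strictly increasing and >= 0")
  if (wells_per_treatment < 1 || larvae_per_well < 1)
    cc_stop("replication counts must be >= 1")
  structure(
    list(timepoints = timepoints, cues = cues,
         wells_per_treatment = as.integer(wells_per_treatment),
         larvae_per_well = as.integer(larvae_per_well),
         poisson_larvae = isTRUE(poisson_larvae)),
    class = "assay_design")
}

# temporal envelope: logistic onset times (1 + sum of Gaussian bumps),
# clipped to [0,1] before scaling by the asymptote
latent_settlement_curve <- function(profile, age, shift) {
  base <- plogis(profile$onset_slope * (age - profile$onset_age) + shift)
  env <- rep(1, length(age))
  for (m in profile$temporal_modes) {
    env <- env + m$amplitude * exp(-0.5 * ((age - m$center) / m$width)^2)
  }
  profile$asymptote * pmin(pmax(base * env, 0), 1)
}

#' Latent settlement probability of a species profile
#'
#' Evaluates the ground-truth probability that a larva settles in a 24-h
#' assay at a given age and cue: `asymptote x logistic(onset) x envelope`,
#' with the envelope `1 + sum of Gaussian bumps` clipped to `[0, 1]`.
#' Monotone non-decreasing in age when `temporal_modes` is empty.
#'
#' @param profile a [species_profile()].
#' @param age larval age(s), days after fertilization (>= 0).
#' @param cue a cue label present in `profile$cue_effects`.
#' @return settlement probabilities in `[0, 1]`, same length as `age`.
#' @export
true_settlement_probability <- function(profile, age, cue) {
  stopifnot(inherits(profile, "species_profile"))
  if (any(age < 0)) cc_stop("`age` must be >= 0")
  if (length(cue) != 1 || !cue %in% names(profile$cue_effects))
    cc_stop("unknown cue label: \"", cue, "\"")
  latent_settlement_curve(profile, age, profile$cue_effects[[cue]])
}

# run code under a temporary RNG state; restores the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a settlement-assay dataset from known ground truth
#'
#' One record per well x timepoint. Settled counts are
#' `Binomial(n_larvae, p_well)` where `logit(p_well)` adds a plate-level
#' intercept and a plate-by-age deviation, each drawn once per plate
#' (plates are one six-well dish per cue x timepoint assay). Identical
#' arguments and seed give byte-identical tables.
#'
#' @param profile a [species_profile()].
#' @param design an [assay_design()].
#' @param seed integer seed.
#' @param cohort_id cohort label stamped on every record.
#' @return a `data.frame` of assay observations with columns
#'   `species_id, cohort_id, age_days, cue, plate_id, well_id, n_larvae,
#'   n_settled`.
#' @export
simulate_assays <- function(profile, design, seed, cohort_id = "C1") {
  stopifnot(inherits(profile, "species_profile"), inherits(design, "assay_design"))
  cues <- design$cues %||% names(profile$cue_effects)
  if (!all(cues %in% names(profile$cue_effects)))
    cc_stop("design cues missing from profile: ",
            paste(setdiff(cues, names(profile$cue_effects)), collapse = ", "))
  grid <- expand.grid(cue = cues, age_days = design$timepoints,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  nw <- design$wells_per_treatment
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      cue <- grid$cue[i]; age <- grid$age_days[i]
      plate <- sprintf("%s_%s_d%g", profile$species_id, cue, age)
      p0 <- true_settlement_probability(profile, age, cue)
      if (profile$plate_sd > 0 || profile$plate_slope_sd > 0) {
        b0 <- rnorm(1, 0, profile$plate_sd)
        b1 <- rnorm(1, 0, profile$plate_slope_sd)
        # guard the logit transform at the degenerate endpoints
        p <- if (p0 <= 0 || p0 >= 1) p0 else plogis(qlogis(p0) + b0 + b1 * age)
      } else p <- p0
      n <- if (design$poisson_larvae)
        1L + rpois(nw, design$larvae_per_well - 1L)
      else rep(design$larvae_per_well, nw)
      data.frame(species_id = profile$species_id,
                 cohort_id = cohort_id,
                 age_days = age,
                 cue = cue,
                 plate_id = plate,
                 well_id = sprintf("%s_w%d", plate, seq_len(nw)),
                 n_larvae = as.integer(n),
                 n_settled = rbinom(nw, n, p),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Marginal true age at cohort competency
#'
#' Independent oracle for parameter-recovery tests: the age at which the
#' probability that a well of `n_larvae` larvae reaches the settlement
#' threshold equals 0.5, with plate-level effects integrated out numerically
#' (equal-weight normal quadrature). This is the quantity the logistic
#' competency model's TC50 estimates.
#'
#' @param profile a [species_profile()].
#' @param cue cue label.
#' @param threshold settlement proportion defining cohort competency.
#' @param n_larvae larvae per well.
#' @param max_age upper bound of the root search (days).
#' @param nodes quadrature nodes per plate-effect dimension.
#' @return age in days, or `Inf` if competency probability never reaches 0.5
#'   by `max_age`.
#' @export
true_competency_age <- function(profile, cue, threshold = 0.3, n_larvae = 10,
                                max_age = 50, nodes = 32) {
  k <- ceiling(threshold * n_larvae)
  z <- stats::qnorm((seq_len(nodes) - 0.5) / nodes)
  b0 <- if (profile$plate_sd > 0) z * profile$plate_sd else 0
  b1 <- if (profile$plate_slope_sd > 0) z * profile$plate_slope_sd else 0
  pc <- function(age) {
    p0 <- true_settlement_probability(profile, age, cue)
    if (p0 <= 0) return(0)
    if (p0 >= 1) return(1)
    eta <- qlogis(p0) + outer(b0, b1 * age, `+`)
    mean(pbinom(k - 1, n_larvae, plogis(eta), lower.tail = FALSE))
  }
  if (pc(max_age) < 0.5) return(Inf)
  if (pc(0) >= 0.5) return(0)
  uniroot(function(a) pc(a) - 0.5, c(0, max_age), tol = 1e-8)$root
}

#' Packaged 21-species competency summary table
#'
#' The species-level table of modelled TC50 (days to 50% probability of
#' exceeding a 30% settlement threshold), 95% credible bounds, the cue giving
#' the earliest TC50, the precompetency class (short < 3 d, mid 3-5 d,
#' long > 5 d) and average oocyte diameter (um) for 21 Indo-Pacific
#' broadcast-spawning coral species.
#'
#' @return a 21-row `data.frame`.
#' @examples
#' tab <- table1_fixture()
#' summarize_species_table(tab)
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "species_competency_table.csv",
                      package = "coralcomp", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Write a ground-truth sidecar for a simulated dataset
#'
#' Records the generating profile, design and seed as JSON next to a
#' simulated assay CSV, so any synthetic dataset is reproducible and its
#' latent truth recoverable.
#'
#' @param profile a [species_profile()].
#' @param design an [assay_design()].
#' @param seed the simulation seed.
#' @param path output path (JSON).
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(profile, design, seed, path) {
  jsonlite::write_json(
    list(profile = unclass(profile), design = unclass(design), seed = seed),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
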