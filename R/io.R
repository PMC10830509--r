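assay_columns <- c("species_id", "cohort_id", "age_days", "cue",
                   "plate_id", "well_id", "n_larvae", "n_settled")

#' Read a settlement-assay CSV
#'
#' Expects the canonical column set (`species_id, cohort_id, age_days, cue,
#' plate_id, well_id, n_larvae, n_settled`). Rows that fail validation
#' (settled count exceeding larvae loaded, negative counts or ages) are
#' rejected with a warning listing their row numbers.
#'
#' @param path CSV path.
#' @return a validated `data.frame` of assay observations.
#' @export
read_assay_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(assay_columns, names(d))
  if (length(missing))
    cc_stop("missing required column(s): ", paste(missing, collapse = ", "))
  bad <- d$n_settled > d$n_larvae | d$n_settled < 0 | d$n_larvae < 0 |
    d$age_days < 0
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    cc_warn("rejected ", sum(bad), " invalid row(s): ",
            paste(head(which(bad), 10), collapse = ", "))
    d <- d[!bad, , drop = FALSE]
    rownames(d) <- NULL
  }
  d[assay_columns]
}

#' Write a settlement-assay CSV
#'
#' Fixed dialect (comma separator, "." decimal mark, no quoting of plain
#' labels) so that simulated fixtures are byte-stable and round-trip exactly
#' through [read_assay_csv()].
#'
#' @param observations assay observations.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_assay_csv <- function(observations, path) {
  write.csv(observations[assay_columns], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline, defaulting each to its
#' standard analysis value: settlement threshold 0.3 with a 0.1-0.9 sweep
#' grid, 3 chains x 6000 iterations (warm-up 2000, thin 10), at most 5
#' spline knots, AUC integration resolution 100, exceedance cutoff 0.95,
#' class boundaries 3 and 5 days, survival decay 0.05 per day.
#'
#' @param input_csv assay CSV to analyse; `NULL` simulates a demonstration
#'   dataset of two synthetic species instead.
#' @param out_dir output directory for all stage artifacts.
#' @param threshold settlement threshold for the headline TC50 fit.
#' @param sweep_thresholds thresholds for the sensitivity sweep; `NULL`
#'   skips the sweep.
#' @param sampler a [sampler_config()]; its seed is overridden by `seed`.
#' @param n_knots,resolution,exceedance_cutoff GAM / AUC-ranking settings.
#' @param boundaries precompetency class boundaries (days).
#' @param decay_rate survival decay rate for the dispersal-potential stage.
#' @param seed global seed, expanded to per-stage substreams.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return a validated `run_config` list.
#' @export
run_config <- function(input_csv = NULL, out_dir = tempfile("coralcomp_run_"),
                       threshold = 0.3,
                       sweep_thresholds = seq(0.1, 0.9, by = 0.1),
                       sampler = sampler_config(),
                       n_knots = 5, resolution = 100,
                       exceedance_cutoff = 0.95,
                       boundaries = c(3, 5), decay_rate = 0.05,
                       seed = 1, log_level = "info") {
  if (threshold <= 0 || threshold >= 1)
    cc_stop("`threshold` must lie in (0, 1)")
  if (!is.null(sweep_thresholds) &&
      any(sweep_thresholds <= 0 | sweep_thresholds >= 1))
    cc_stop("sweep thresholds must lie in (0, 1)")
  if (resolution < 2) cc_stop("`resolution` must be >= 2")
  if (exceedance_cutoff <= 0.5 || exceedance_cutoff > 1)
    cc_stop("`exceedance_cutoff` must lie in (0.5, 1]")
  stopifnot(inherits(sampler, "sampler_config"))
  structure(list(input_csv = input_csv, out_dir = out_dir,
                 threshold = threshold, sweep_thresholds = sweep_thresholds,
                 sampler = sampler, n_knots = n_knots,
                 resolution = resolution,
                 exceedance_cutoff = exceedance_cutoff,
                 boundaries = boundaries, decay_rate = decay_rate,
                 seed = as.integer(seed), log_level = log_level),
            class = "run_config")
}

cc_log <- function(config, level, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level %||% "info"]] >=
      levels[[level]]) message("[coralcomp] ", ...)
  invisible(NULL)
}

demo_profiles <- function() {
  list(
    species_profile("SynA", onset_age = 3, onset_slope = 1.8,
                    asymptote = 0.85),
    species_profile("SynB", onset_age = 5, onset_slope = 1.2,
                    cue_effects = c(Control = 0, CCA = 3.0, Extract = 1.0,
                                    Peptide = 2.0, Disc = 1.5, Rubble = 2.5),
                    asymptote = 0.9))
}

#' Run the full settlement-competency pipeline
#'
#' Orchestrates the analysis sequence on one assay table: binarize at the
#' settlement threshold, fit the logistic competency model and extract TC50
#' per cue (plus the earliest non-control "best" cue), optionally sweep the
#' threshold grid, fit the settlement-through-time GAM, integrate posterior
#' AUCs and rank cues by exceedance probability, then classify and summarize
#' species. All stage outputs are plain CSV / text under `out_dir`, and a
#' JSON manifest records the configuration, seed, package version and input
#' checksums. Reruns with an identical configuration and seed reproduce all
#' outputs exactly.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  sampler <- config$sampler

  if (is.null(config$input_csv)) {
    cc_log(config, "info", "simulating demonstration assay data")
    design <- assay_design()
    obs <- do.call(rbind, lapply(demo_profiles(), function(pr)
      simulate_assays(pr, design, seed = stage_seed(config$seed, pr$species_id))))
    input_path <- file.path(config$out_dir, "assays.csv")
    write_assay_csv(obs, input_path)
  } else {
    input_path <- config$input_csv
    obs <- read_assay_csv(input_path)
  }

  species <- unique(obs$species_id)
  tc50_rows <- list(); sweep_rows <- list(); curve_rows <- list()
  auc_rows <- list(); rank_lines <- character(0); diag_lines <- character(0)

  for (sp in species) {
    o <- obs[obs$species_id == sp, , drop = FALSE]
    cc_log(config, "info", "fitting competency model: ", sp)
    cfg <- sampler; cfg$seed <- stage_seed(config$seed, paste0("tc50_", sp))
    rec <- binarize_competency(o, config$threshold)
    fit <- fit_competency_model(rec, cfg)
    diag <- convergence_diagnostics(fit)
    diag_lines <- c(diag_lines,
                    sprintf("%s competency_logistic pass=%s max_rhat=%.3f min_ess=%.0f",
                            sp, attr(diag, "pass"), max(diag$rhat, na.rm = TRUE),
                            min(diag$ess, na.rm = TRUE)))
    est <- do.call(rbind, lapply(attr(fit, "cues"), tc50_from_draws,
                                 draws = fit))
    cand <- est[!is_control_cue(est$cue), ]
    cand <- cand[order(cand$tc50_median, cand$cue), ]
    best <- cand[1, ]; best$cue <- "Best"
    tc50_rows[[sp]] <- rbind(est, best)

    M <- cue_tc50_contrasts(fit)
    write.csv(M, file.path(config$out_dir,
                           paste0("tc50_exceedance_", sp, ".csv")))

    if (!is.null(config$sweep_thresholds)) {
      cc_log(config, "info", "threshold sweep: ", sp)
      cfg2 <- sampler; cfg2$seed <- stage_seed(config$seed, paste0("sweep_", sp))
      sweep_rows[[sp]] <- threshold_sweep(o, config$sweep_thresholds, cfg2)
    }

    cc_log(config, "info", "fitting settlement GAM: ", sp)
    cfg3 <- sampler; cfg3$seed <- stage_seed(config$seed, paste0("gam_", sp))
    gfit <- fit_settlement_gam(o, n_knots = config$n_knots, config = cfg3)
    rng <- attr(gfit, "age_range")
    grid <- seq(rng[1], rng[2], length.out = config$resolution)
    aucs <- list()
    for (cue in attr(gfit, "cues")) {
      curve_rows[[paste(sp, cue)]] <-
        cbind(species_id = sp, curve_from_draws(gfit, cue, grid))
      a <- auc_per_draw(gfit, cue, resolution = config$resolution)
      aucs[[cue]] <- a
      qs <- quantile(a$areas, c(0.025, 0.5, 0.975))
      auc_rows[[paste(sp, cue)]] <-
        data.frame(species_id = sp, cue = cue, auc_median = qs[2],
                   ci_lower = qs[1], ci_upper = qs[3])
    }
    rk <- rank_cues(aucs, cutoff = config$exceedance_cutoff)
    rank_lines <- c(rank_lines, sprintf("%s: %s  [cutoff %.2f]",
                                        sp, rk$display, rk$exceedance_cutoff))

    # dispersal potential from the best cue's fitted settlement curve
    best_cue <- attr(best, "best_cue") %||% cand$cue[1]
    comp <- curve_from_draws(gfit, cand$cue[1], grid)$median
    disp <- dispersal_potential(comp, config$decay_rate, grid)
    write.csv(cbind(species_id = sp, disp),
              file.path(config$out_dir, paste0("dispersal_", sp, ".csv")),
              row.names = FALSE)
  }

  tc50_tab <- do.call(rbind, tc50_rows)
  write.csv(tc50_tab, file.path(config$out_dir, "tc50_estimates.csv"),
            row.names = FALSE)
  if (length(sweep_rows))
    write.csv(do.call(rbind, sweep_rows),
              file.path(config$out_dir, "tc50_sweep.csv"), row.names = FALSE)
  write.csv(do.call(rbind, curve_rows),
            file.path(config$out_dir, "settlement_curves.csv"),
            row.names = FALSE)
  write.csv(do.call(rbind, auc_rows),
            file.path(config$out_dir, "auc_posteriors.csv"),
            row.names = FALSE)
  writeLines(rank_lines, file.path(config$out_dir, "cue_rankings.txt"))
  writeLines(diag_lines, file.path(config$out_dir, "diagnostics.txt"))

  best_rows <- tc50_tab[tc50_tab$cue == "Best" & is.finite(tc50_tab$tc50_median) &
                          tc50_tab$tc50_median > 0, ]
  if (nrow(best_rows)) {
    best_rows$precompetency_class <-
      as.character(classify_precompetency(best_rows$tc50_median,
                                          config$boundaries))
    write.csv(best_rows, file.path(config$out_dir, "species_summary.csv"),
              row.names = FALSE)
  }

  manifest <- list(
    package = "coralcomp",
    version = as.character(packageVersion("coralcomp")),
    seed = config$seed,
    config = unclass(config)[setdiff(names(config), "sampler")],
    sampler = unclass(config$sampler),
    input = list(path = input_path,
                 md5 = unname(tools::md5sum(input_path))),
    species = species,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null")
  cc_log(config, "info", "pipeline complete: ", config$out_dir)
  invisible(manifest)
}
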