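#' Classify precompetency duration
#'
#' Species are grouped by their TC50 into short (< 3 days), mid (3-5 days)
#' and long (> 5 days) precompetency classes. Boundaries are inclusive for
#' the mid class (`[3, 5]`) and configurable.
#'
#' @param tc50 positive TC50 value(s) in days.
#' @param boundaries two increasing positive cutpoints, default `c(3, 5)`.
#' @return a factor with levels `short`, `mid`, `long`.
#' @export
classify_precompetency <- function(tc50, boundaries = c(3, 5)) {
  if (any(!is.finite(tc50)) || any(tc50 <= 0))
    cc_stop("`tc50` must be positive and finite")
  stopifnot(length(boundaries) == 2, diff(boundaries) > 0)
  cls <- ifelse(tc50 < boundaries[1], "short",
                ifelse(tc50 <= boundaries[2], "mid", "long"))
  factor(cls, levels = c("short", "mid", "long"))
}

#' Cross-species summary of a TC50 table
#'
#' Mean, extremes (with the species attaining them) and precompetency class
#' composition of a species-level TC50 table such as [table1_fixture()].
#' Display values follow the reporting conventions: TC50s to 1 decimal
#' place, class percentages to the nearest whole percent.
#'
#' @param rows data.frame with columns `tc50` and a species label column
#'   (`abbrev` or `species` or `species_id`), optionally
#'   `precompetency_class` (recomputed from `tc50` when absent).
#' @param boundaries class boundaries passed to [classify_precompetency()].
#' @return a `species_summary` list: n, mean_tc50, min/max with species,
#'   class_counts, class_pct.
#' @export
summarize_species_table <- function(rows, boundaries = c(3, 5)) {
  if (is.null(rows) || nrow(rows) == 0) cc_stop("empty species table")
  lab_col <- intersect(c("abbrev", "species", "species_id"), names(rows))[1]
  if (is.na(lab_col)) cc_stop("no species label column found")
  cls <- classify_precompetency(rows$tc50, boundaries)
  tab <- table(cls)
  counts <- setNames(as.integer(tab), names(tab))
  out <- list(n = nrow(rows),
              mean_tc50 = mean(rows$tc50),
              mean_tc50_display = round(mean(rows$tc50), 1),
              min_tc50 = min(rows$tc50),
              min_species = rows[[lab_col]][which.min(rows$tc50)],
              max_tc50 = max(rows$tc50),
              max_species = rows[[lab_col]][which.max(rows$tc50)],
              class_counts = counts,
              class_pct = setNames(as.integer(round(100 * counts / nrow(rows))),
                                   names(counts)))
  structure(out, class = "species_summary")
}

#' @export
print.species_summary <- function(x, ...) {
  cat("Species-level competency summary (n =", x$n, ")\n")
  cat(sprintf("  mean TC50 %.1f d; earliest %s (%.1f d); latest %s (%.1f d)\n",
              x$mean_tc50, x$min_species, x$min_tc50,
              x$max_species, x$max_tc50))
  cat(sprintf("  classes: short %d (%d%%), mid %d (%d%%), long %d (%d%%)\n",
              x$class_counts[["short"]], x$class_pct[["short"]],
              x$class_counts[["mid"]], x$class_pct[["mid"]],
              x$class_counts[["long"]], x$class_pct[["long"]]))
  invisible(x)
}

#' Regression of TC50 on oocyte diameter
#'
#' Gaussian GLM (identity link, hence ordinary least squares, solved by the
#' normal equations) of species TC50 against average oocyte diameter,
#' testing whether larger eggs take longer to reach settlement competency.
#'
#' @param rows data.frame with columns `tc50` and `oocyte_um`.
#' @return an `egg_regression` list: slope, intercept, r_squared,
#'   adj_r_squared, p_value (two-sided, slope t-test, n - 2 df), n.
#' @export
egg_size_regression <- function(rows) {
  ok <- complete.cases(rows[, c("tc50", "oocyte_um")])
  x <- rows$oocyte_um[ok]; y <- rows$tc50[ok]
  n <- length(x)
  if (n < 3) cc_stop("need >= 3 species with both TC50 and oocyte diameter")
  if (var(x) == 0) cc_stop("zero variance in oocyte diameter")
  X <- cbind(1, x)
  coefs <- solve(crossprod(X), crossprod(X, y))
  fitted <- drop(X %*% coefs)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  adj <- 1 - (1 - r2) * (n - 1) / (n - 2)
  se_slope <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  tval <- coefs[2] / se_slope
  p <- 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE)
  structure(list(slope = coefs[2], intercept = coefs[1],
                 r_squared = r2, adj_r_squared = adj,
                 t_value = tval, p_value = p, n = n),
            class = "egg_regression")
}

#' @export
print.egg_regression <- function(x, ...) {
  cat(sprintf(
    "TC50 ~ oocyte diameter (n = %d): slope %.4g d/um, adj R^2 = %.2f, p = %.3f\n",
    x$n, x$slope, x$adj_r_squared, x$p_value))
  invisible(x)
}

#' Passive transport distance under a steady current
#'
#' Distance travelled by a passively advected larva:
#' `speed (cm/s) x 86400 s/d x duration (d)`, converted to kilometres. At
#' 10 cm/s, a 4-day difference in precompetency corresponds to ~35 km
#' (34.56 km exact) of additional transport.
#'
#' @param current_speed current speed in cm per second (>= 0).
#' @param duration_days drift duration in days (>= 0).
#' @return distance in km (exact; round to the nearest km for display).
#' @export
transport_distance <- function(current_speed, duration_days) {
  if (any(current_speed < 0) || any(duration_days < 0))
    cc_stop("speed and duration must be >= 0")
  current_speed * 86400 * duration_days / 1e5
}

#' Competency-by-survival dispersal potential
#'
#' Combines a competency-through-time curve with exponential larval survival
#' `exp(-decay_rate * t)`: the pointwise product is the probability that a
#' larva is both alive and competent, a simple model of realized dispersal
#' potential over the pelagic larval duration.
#'
#' @param competency competency proportions in `[0, 1]`: a vector matching
#'   `age_grid`, or a function of age.
#' @param decay_rate per-day mortality rate (>= 0), default 0.05.
#' @param age_grid ages (days) at which to evaluate.
#' @return a `dispersal_curve` data.frame: age, competency, survival,
#'   product; `decay_rate` stored as an attribute.
#' @export
dispersal_potential <- function(competency, decay_rate = 0.05,
                                age_grid = seq(0, 120, by = 1)) {
  if (decay_rate < 0) cc_stop("`decay_rate` must be >= 0")
  comp <- if (is.function(competency)) competency(age_grid) else competency
  if (length(comp) != length(age_grid))
    cc_stop("competency values must match the age grid")
  if (any(comp < 0 | comp > 1)) cc_stop("competency must lie in [0, 1]")
  surv <- exp(-decay_rate * age_grid)
  structure(data.frame(age = age_grid, competency = comp,
                       survival = surv, product = comp * surv),
            decay_rate = decay_rate,
            class = c("dispersal_curve", "data.frame"))
}
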