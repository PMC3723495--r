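#' Detect the onset of resilencing from an expression series
#'
#' Resilencing onset is defined on raw sampled days, without smoothing:
#' taking the day of maximal expression at or after drug withdrawal, the
#' onset is the first later sampled day whose value is strictly below the
#' previous sampled day's value. Invariant to positive rescaling of the
#' series.
#'
#' @param series named numeric vector, names = sampled days.
#' @param treatment_end_day last day of drug exposure; the maximum is
#'   sought over days >= this.
#' @return the onset day (integer), or `NA` with attribute
#'   `reason = "unreached"` if the series never strictly decreases.
#' @export
detect_resilencing_onset <- function(series, treatment_end_day) {
  days <- as.numeric(names(series))
  if (anyNA(days)) stopf("series must be named by day")
  o <- order(days)
  days <- days[o]; vals <- as.numeric(series[o])
  post <- which(days >= treatment_end_day)
  if (length(post) < 2L) {
    stopf("need >= 2 sampled days at or after treatment_end_day")
  }
  peak <- post[which.max(vals[post])]
  for (i in seq_along(days)) {
    if (i <= peak) next
    if (vals[i] < vals[i - 1L]) return(days[i])
  }
  structure(NA_real_, reason = "unreached")
}

#' Half-recovery day of a perturbed metric
#'
#' Given a series that was driven from `baseline_value` to
#' `extreme_value` and then recovers, returns the (real-valued) day at
#' which the series first crosses the midpoint
#' `(baseline_value + extreme_value) / 2` after the day of the extreme,
#' by linear interpolation between the bracketing sampled days. Sampling
#' is sparse, so no smoothing or extrapolation is performed.
#'
#' @param series named numeric vector, names = sampled days.
#' @param baseline_value pre-perturbation level.
#' @param extreme_value most perturbed level reached.
#' @return interpolated day, or `NA` with attribute
#'   `reason = "unreached"` if the midpoint is never crossed.
#' @export
half_recovery_day <- function(series, baseline_value, extreme_value) {
  if (baseline_value == extreme_value) {
    stopf("degenerate series: baseline equals extreme")
  }
  days <- as.numeric(names(series))
  if (anyNA(days)) stopf("series must be named by day")
  o <- order(days)
  days <- days[o]; vals <- as.numeric(series[o])
  mid <- (baseline_value + extreme_value) / 2
  extreme_day <- days[which.min(abs(vals - extreme_value))]
  s <- sign(baseline_value - extreme_value)  # recovery direction
  from <- which(days >= extreme_day)
  for (k in from) {
    if (k == from[1]) next
    v1 <- vals[k - 1L]; v2 <- vals[k]
    if (s * (v1 - mid) < 0 && s * (v2 - mid) >= 0) {
      return(days[k - 1L] + (mid - v1) / (v2 - v1) * (days[k] - days[k - 1L]))
    }
  }
  # the extreme day itself may already sit on the midpoint side
  if (s * (vals[from[1]] - mid) >= 0) return(days[from[1]])
  structure(NA_real_, reason = "unreached")
}

#' Order epigenetic events by half-recovery day
#'
#' Computes the half-recovery day of each requested metric from a
#' per-day timeline and sorts the metrics by it, operationalizing the
#' event hierarchy of a resilencing time course. Exposes the headline
#' predicate `nucleosome_before_methylation`: whether nucleosome levels
#' recover to half their baseline before promoter methylation does.
#'
#' @param timeline data.frame with a `day` column and one column per
#'   metric (NA allowed for unsampled days).
#' @param metrics list: names are metric column names, each element a
#'   list with `baseline` and `extreme` values for that metric.
#' @param nucleosome_metric,methylation_metric metric names entering the
#'   ordering predicate (defaults `"nucleosome_level_pct"`,
#'   `"promoter_methylation_pct"`); the predicate is NA when either is
#'   absent or unreached.
#' @return list of class `event_timeline`: `half_recovery` (named
#'   vector), `event_order` (metric names, reached first; ties broken by
#'   listing order and flagged in `ties`), `unreached` (names), and
#'   `nucleosome_before_methylation`.
#' @export
event_order <- function(timeline, metrics,
                        nucleosome_metric = "nucleosome_level_pct",
                        methylation_metric = "promoter_methylation_pct") {
  stopifnot(is.data.frame(timeline), "day" %in% names(timeline))
  hr <- rep(NA_real_, length(metrics))
  names(hr) <- names(metrics)
  for (m in names(metrics)) {
    if (!m %in% names(timeline)) stopf("metric '%s' missing from timeline", m)
    v <- timeline[[m]]
    ok <- !is.na(v)
    series <- setNames(v[ok], timeline$day[ok])
    hr[m] <- half_recovery_day(series, metrics[[m]]$baseline,
                               metrics[[m]]$extreme)
  }
  if (all(is.na(hr))) stopf("no metric reached half recovery")
  reached <- hr[!is.na(hr)]
  ord <- names(reached)[order(reached)]  # order() is stable: listing order
  ties <- any(duplicated(reached[ord]))
  pred <- if (nucleosome_metric %in% names(reached) &&
              methylation_metric %in% names(reached)) {
    unname(reached[nucleosome_metric] < reached[methylation_metric])
  } else {
    NA
  }
  structure(list(half_recovery = hr, event_order = ord, ties = ties,
                 unreached = names(hr)[is.na(hr)],
                 nucleosome_before_methylation = pred),
            class = "event_timeline")
}

#' @export
print.event_timeline <- function(x, ...) {
  cat("<event_timeline>\n  half-recovery days:\n")
  for (m in names(x$half_recovery)) {
    cat(sprintf("    %-28s %s\n", m,
                ifelse(is.na(x$half_recovery[m]), "unreached",
                       sprintf("%.2f", x$half_recovery[m]))))
  }
  cat(sprintf("  order: %s%s\n", paste(x$event_order, collapse = " < "),
              ifelse(x$ties, "  [ties]", "")))
  cat(sprintf("  nucleosome before methylation: %s\n",
              x$nucleosome_before_methylation))
  invisible(x)
}

#' Simulate a resilencing time-course of bulk metrics
#'
#' Generates noisy per-day metric series shaped like a
#' hypomethylating-agent time course: three days of drug exposure drive
#' nucleosome levels and promoter methylation down; after withdrawal
#' each metric recovers toward baseline with its own half-recovery day.
#' The default scenario encodes the chromatin-first hierarchy (nucleosome
#' levels recover around day 6, promoter methylation around day 11);
#' `reversed = TRUE` swaps the two recovery times to emulate a
#' methylation-first world.
#'
#' Recovery follows a logistic curve between extreme and baseline;
#' i.i.d. Gaussian noise (`noise_sd`, percent points) is added to every
#' sampled value.
#'
#' @param days sampled days (default the sparse harvest grid
#'   0,3,5,6,7,8,11,17,24,31,45).
#' @param nucleosome_t50,methylation_t50 half-recovery days of the two
#'   metrics.
#' @param noise_sd Gaussian noise SD in percent points (default 4).
#' @param reversed swap the two half-recovery times.
#' @param seed integer seed.
#' @return list with `timeline` (data.frame day + metric columns) and
#'   `metrics` (baseline/extreme spec suitable for [event_order()]).
#' @export
simulate_timecourse <- function(days = c(0, 3, 5, 6, 7, 8, 11, 17, 24, 31, 45),
                                nucleosome_t50 = 6, methylation_t50 = 11,
                                noise_sd = 4, reversed = FALSE, seed = 1L) {
  if (reversed) {
    tmp <- nucleosome_t50
    nucleosome_t50 <- methylation_t50
    methylation_t50 <- tmp
  }
  curve <- function(t, baseline, extreme, t_drop, t50, tau) {
    ifelse(t <= t_drop,
           baseline + (extreme - baseline) * t / t_drop,
           extreme + (baseline - extreme) / (1 + exp(-(t - t50) / tau)))
  }
  with_seed(seed, {
    nuc <- curve(days, baseline = 100, extreme = 24, t_drop = 3,
                 t50 = nucleosome_t50, tau = 0.8) + rnorm(length(days), 0, noise_sd)
    meth <- curve(days, baseline = 95, extreme = 46, t_drop = 5,
                  t50 = methylation_t50, tau = 2.5) + rnorm(length(days), 0, noise_sd)
    timeline <- data.frame(day = days,
                           nucleosome_level_pct = pmin(pmax(nuc, 0), 130),
                           promoter_methylation_pct = pmin(pmax(meth, 0), 100))
  })
  list(timeline = timeline,
       metrics = list(
         nucleosome_level_pct = list(baseline = 100, extreme = 24),
         promoter_methylation_pct = list(baseline = 95, extreme = 46)))
}
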