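# Mean Ct per (target, day, condition) cell; replicates averaged on the Ct
# scale (linear-scale averaging available where exposed).
mean_ct <- function(ct, ..., average = c("ct", "linear"), base = 2) {
  average <- match.arg(average)
  sel <- ct
  filt <- list(...)
  for (nm in names(filt)) {
    if (!is.null(filt[[nm]])) sel <- sel[sel[[nm]] == filt[[nm]], ]
  }
  if (!nrow(sel)) return(NA_real_)
  if (average == "ct") mean(sel$ct)
  else -log(mean(base ^ -sel$ct)) / log(base)
}

#' Relative expression by the delta-delta-Ct method
#'
#' For each day, replicate Cts of target and reference gene are averaged,
#' the within-day difference `dCt = Ct_target - Ct_ref` is formed, and
#' expression relative to the calibrator day is
#' `base^-(dCt_day - dCt_calibrator)`. The calibrator day yields 1 by
#' construction. With `percent_of_max = TRUE` the series is rescaled to
#' percent of its maximum.
#'
#' @param ct Ct table (columns assay, target, condition, day, replicate,
#'   ct) with `assay == "expression"` rows for both genes.
#' @param target target gene label.
#' @param ref_gene reference (housekeeping) gene label.
#' @param calibrator_day day whose expression defines 1.
#' @param base amplification base (2 = 100% efficiency; an efficiency `e`
#'   corresponds to base `1 + e`).
#' @param percent_of_max report percent of the series maximum instead of
#'   fold change.
#' @param average replicate averaging scale, `"ct"` (default) or
#'   `"linear"`.
#' @return data.frame with columns `target`, `day`, `value`,
#'   `replicate_sd` (SD of per-replicate fold changes, replicates paired
#'   by index; NA when replicate counts differ).
#' @export
relative_expression <- function(ct, target, ref_gene, calibrator_day,
                                base = 2, percent_of_max = FALSE,
                                average = c("ct", "linear")) {
  average <- match.arg(average)
  expr <- ct[ct$assay == "expression", ]
  days <- sort(unique(expr$day[expr$target == target]))
  dct <- rep(NA_real_, length(days))
  sds <- rep(NA_real_, length(days))
  keep <- logical(length(days))
  for (i in seq_along(days)) {
    d <- days[i]
    t_ct <- expr[expr$target == target & expr$day == d, ]
    r_ct <- expr[expr$target == ref_gene & expr$day == d, ]
    if (!nrow(r_ct)) {
      warnf("day %s: reference gene '%s' missing; day omitted", d, ref_gene)
      next
    }
    keep[i] <- TRUE
    dct[i] <- mean_ct(t_ct, average = average, base = base) -
      mean_ct(r_ct, average = average, base = base)
    if (nrow(t_ct) == nrow(r_ct) && nrow(t_ct) > 1L) {
      tt <- t_ct$ct[order(t_ct$replicate)]
      rr <- r_ct$ct[order(r_ct$replicate)]
      sds[i] <- sd(base ^ -(tt - rr))
    }
  }
  days <- days[keep]; dct <- dct[keep]; sds <- sds[keep]
  if (!calibrator_day %in% days) {
    stopf("calibrator day %s has no usable measurements", calibrator_day)
  }
  dct_cal <- dct[days == calibrator_day]
  value <- base ^ -(dct - dct_cal)
  sds <- sds * base ^ dct_cal   # rescale replicate SDs to the calibrator
  if (percent_of_max) {
    mx <- max(value)
    sds <- 100 * sds / mx
    value <- 100 * value / mx
  }
  data.frame(target = target, day = days, value = value,
             replicate_sd = sds, stringsAsFactors = FALSE)
}

#' Relative nucleosome level from MNase-qPCR
#'
#' Mononucleosomal template surviving MNase digestion is quantified
#' against undigested naked genomic DNA
#' (`base^-(Ct_mono - Ct_naked)`), then expressed as percent of the
#' calibrator (untreated) day:
#' `100 * rel_day / rel_calibrator`.
#'
#' @param ct Ct table with `assay == "mnase"` rows, conditions `"mono"`
#'   and `"naked"`.
#' @param region assayed region label (the `target` column).
#' @param calibrator_day untreated reference day.
#' @param base amplification base.
#' @param average replicate averaging scale.
#' @return data.frame with columns `target`, `day`, `value` (percent).
#' @export
mnase_relative_level <- function(ct, region, calibrator_day, base = 2,
                                 average = c("ct", "linear")) {
  average <- match.arg(average)
  mn <- ct[ct$assay == "mnase" & ct$target == region, ]
  days <- sort(unique(mn$day))
  rel <- vapply(days, function(d) {
    mono <- mean_ct(mn, condition = "mono", day = d,
                    average = average, base = base)
    naked <- mean_ct(mn, condition = "naked", day = d,
                     average = average, base = base)
    if (is.na(naked)) stopf("day %s: naked genomic DNA control missing", d)
    if (is.na(mono)) stopf("day %s: mononucleosome measurement missing", d)
    base ^ -(mono - naked)
  }, 0)
  if (!calibrator_day %in% days) {
    stopf("calibrator day %s not measured", calibrator_day)
  }
  value <- 100 * rel / rel[days == calibrator_day]
  data.frame(target = region, day = days, value = value,
             stringsAsFactors = FALSE)
}

#' ChIP-qPCR enrichment normalized to input after IgG subtraction
#'
#' Linear-scale quantities are recovered from Cts as `base^-Ct` (on a
#' common dilution scale; `input_dilution` multiplies the input quantity
#' if the input was diluted relative to the IP). Enrichment is the
#' antibody quantity minus the pre-immune IgG background, floored at
#' zero, divided by the input quantity.
#'
#' @param ct Ct table with `assay == "chip"` rows, conditions
#'   `"antibody"`, `"igg"`, `"input"`. A `mark` column, when present, is
#'   used to select the antibody.
#' @param region region label (the `target` column).
#' @param mark histone-mark label (matched against the `mark` column when
#'   present).
#' @param base amplification base.
#' @param input_dilution input dilution factor (default 1).
#' @param day optional day filter.
#' @return enrichment as a single numeric value (vectorized over `day`
#'   when `day` is a vector).
#' @export
chip_enrichment <- function(ct, region, mark = NULL, base = 2,
                            input_dilution = 1, day = NULL) {
  ch <- ct[ct$assay == "chip" & ct$target == region, ]
  if (!is.null(mark) && "mark" %in% names(ch)) {
    ch <- ch[ch$condition != "antibody" |
               (!is.na(ch$mark) & ch$mark == mark), ]
  }
  one_day <- function(d) {
    sub <- if (is.null(d)) ch else ch[ch$day == d, ]
    ab <- mean_ct(sub, condition = "antibody")
    igg <- mean_ct(sub, condition = "igg")
    inp <- mean_ct(sub, condition = "input")
    if (anyNA(c(ab, igg, inp))) {
      stopf("chip enrichment needs antibody, igg and input conditions")
    }
    q_ab <- base ^ -ab
    q_igg <- if (is.infinite(igg)) 0 else base ^ -igg
    q_in <- input_dilution * base ^ -inp
    max(q_ab - q_igg, 0) / q_in
  }
  if (is.null(day)) one_day(NULL) else vapply(day, one_day, 0)
}

#' Global methylation percent from nucleoside quantities
#'
#' LC-MS/MS yields absolute quantities of 5-methyl-2'-deoxycytidine and
#' unmodified deoxycytidine; global methylation is the methylated
#' fraction of all cytosines, `100 * 5mdC / (5mdC + dC)`. Scale invariant
#' by construction.
#'
#' @param five_mdC,dC nonnegative quantities (vectors recycle).
#' @return percent methylation.
#' @export
global_methylation_percent <- function(five_mdC, dC) {
  if (any(five_mdC < 0) || any(dC < 0)) stopf("quantities must be >= 0")
  if (any(five_mdC + dC == 0)) stopf("5mdC and dC cannot both be zero")
  100 * five_mdC / (five_mdC + dC)
}

#' Average pyrosequencing methylation across five promoter CpG sites
#'
#' Each replicate contributes the mean of its five per-site percent
#' values; the assay result is the mean and SD across replicates.
#'
#' @param site_percents numeric matrix (replicates x 5 sites) or a single
#'   length-5 vector.
#' @return list with `mean` and `sd` (SD is NA with a single replicate).
#' @export
pyro_average <- function(site_percents) {
  if (is.vector(site_percents)) {
    site_percents <- matrix(site_percents, nrow = 1)
  }
  if (ncol(site_percents) != 5L) {
    stopf("expected exactly 5 CpG site values per replicate")
  }
  if (any(site_percents < 0 | site_percents > 100)) {
    stopf("site percentages must lie in [0, 100]")
  }
  per_rep <- rowMeans(site_percents)
  list(mean = mean(per_rep),
       sd = if (length(per_rep) > 1L) sd(per_rep) else NA_real_)
}
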