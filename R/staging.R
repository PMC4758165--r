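#' Per-subject dementia-probability score P(AD)
#'
#' P(AD) is the fraction of bootstrap validations in which the frozen model
#' labeled the subject mild AD: a subject consistently classified AD has
#' P(AD) = 1, one consistently classified MCI has P(AD) = 0. Subjects are
#' stratified at 50 %: `LIKELY_MCI` when P(AD) < 0.5, `LIKELY_DEMENTIA`
#' when P(AD) >= 0.5 (boundary on the dementia side). Subjects never
#' sampled by the bootstrap are flagged and excluded from the strata.
#'
#' Note that under the single-frozen-model convention a given subject's
#' features score identically in every replicate, so P(AD) is 0 or 1
#' exactly; intermediate values arise when tallies are accumulated across
#' several validations (e.g. models from both experiments, or an ensemble
#' of fold models).
#'
#' @param result a `bootstrap_validation` (or a compatible tally
#'   data.frame with `subject_id`, `times_sampled`, `times_labeled_ad`).
#' @return data.frame of class `pad_scores`: `subject_id`,
#'   `times_sampled`, `times_labeled_ad`, `pad`, `stratum`; unsampled
#'   subjects carry `NA` pad and stratum.
#' @export
compute_pad <- function(result) {
  tallies <- if (inherits(result, "bootstrap_validation")) result$tallies else result
  stopifnot(all(c("subject_id", "times_sampled", "times_labeled_ad") %in% names(tallies)))
  if (any(tallies$times_labeled_ad > tallies$times_sampled)) {
    stop("labeled-AD count exceeds sampled count")
  }
  pad <- ifelse(tallies$times_sampled > 0,
                tallies$times_labeled_ad / tallies$times_sampled, NA_real_)
  unsampled <- sum(tallies$times_sampled == 0)
  if (unsampled) {
    xmittn_log("compute_pad: ", unsampled,
               " subject(s) never sampled; flagged and excluded from strata")
  }
  out <- data.frame(
    subject_id = tallies$subject_id,
    times_sampled = tallies$times_sampled,
    times_labeled_ad = tallies$times_labeled_ad,
    pad = pad,
    stratum = ifelse(is.na(pad), NA_character_,
                     ifelse(pad >= 0.5, "LIKELY_DEMENTIA", "LIKELY_MCI")),
    stringsAsFactors = FALSE
  )
  class(out) <- c("pad_scores", "data.frame")
  out
}

# per-subject longitudinal summary: mean Z (LEVEL) or least-squares slope
# in Z per month (SLOPE, needs >= 2 visits at distinct months)
subject_trajectory_stat <- function(visits, zcol, comparison) {
  by_subj <- split(visits[c("months_from_baseline", zcol)], visits$subject_id)
  stat <- lapply(by_subj, function(v) {
    z <- v[[zcol]]
    m <- v$months_from_baseline
    keep <- !is.na(z) & !is.na(m)
    z <- z[keep]; m <- m[keep]
    if (comparison == "LEVEL") {
      if (!length(z)) return(NA_real_)
      mean(z)
    } else {
      if (length(z) < 2 || length(unique(m)) < 2) return(NA_real_)
      unname(coef(lm(z ~ m))[2])
    }
  })
  unlist(stat)
}

#' Compare longitudinal cognition between P(AD) strata
#'
#' Summarizes each subject's longitudinal executive or memory Z-scores as
#' either the per-subject mean level (`LEVEL`, Z units) or the per-subject
#' least-squares slope (`SLOPE`, Z per month), then compares the
#' `LIKELY_MCI` and `LIKELY_DEMENTIA` strata with an unequal-variance
#' (Welch) two-sample t comparison. The estimate is
#' `mean(LIKELY_MCI) - mean(LIKELY_DEMENTIA)`, so a positive value means
#' the low-P(AD) stratum has better (or more slowly declining) cognition.
#'
#' @param cohort `cohort` carrying the longitudinal visits.
#' @param pad a `pad_scores` data.frame from [compute_pad()] (or any frame
#'   with `subject_id` and `stratum`).
#' @param domain `"EXECUTIVE"` or `"MEMORY"`.
#' @param comparison `"LEVEL"` (mean Z difference) or `"SLOPE"` (Z/month
#'   difference).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `slope_comparison`: `estimate`, `conf_low`,
#'   `conf_high`, `p_value`, group sizes and the excluded-subject ids.
#'   Subjects with too few usable visits are excluded and logged; fewer
#'   than 2 usable subjects in a stratum is an error naming the stratum.
#' @export
compare_groups <- function(cohort, pad, domain = c("EXECUTIVE", "MEMORY"),
                           comparison = c("LEVEL", "SLOPE"),
                           conf_level = 0.95) {
  stopifnot(inherits(cohort, "cohort"))
  domain <- match.arg(domain)
  comparison <- match.arg(comparison)
  zcol <- if (domain == "EXECUTIVE") "executive_z" else "memory_z"
  visits <- cohort$visits
  if (!nrow(visits)) stop("cohort has no longitudinal visits")
  stat <- subject_trajectory_stat(visits, zcol, comparison)
  strata <- pad$stratum[match(names(stat), pad$subject_id)]
  usable <- !is.na(stat) & !is.na(strata)
  excluded <- names(stat)[!usable]
  if (length(excluded)) {
    xmittn_log("compare_groups(", domain, ", ", comparison, "): excluded ",
               length(excluded), " subject(s) with insufficient data: ",
               paste(excluded, collapse = ", "))
  }
  stat <- stat[usable]
  strata <- strata[usable]
  g_mci <- stat[strata == "LIKELY_MCI"]
  g_dem <- stat[strata == "LIKELY_DEMENTIA"]
  for (nmv in list(c("LIKELY_MCI", length(g_mci)), c("LIKELY_DEMENTIA", length(g_dem)))) {
    if (as.integer(nmv[2]) < 2) {
      stop("insufficient longitudinal data in stratum ", nmv[1], " (n = ",
           nmv[2], "; need >= 2 subjects with usable visits)")
    }
  }
  tt <- t.test(g_mci, g_dem, var.equal = FALSE, conf.level = conf_level)
  structure(
    list(domain = domain, comparison = comparison,
         estimate = unname(tt$estimate[1] - tt$estimate[2]),
         conf_low = tt$conf.int[1], conf_high = tt$conf.int[2],
         p_value = tt$p.value, conf_level = conf_level,
         n_likely_mci = length(g_mci), n_likely_dementia = length(g_dem),
         excluded = excluded),
    class = "slope_comparison"
  )
}

#' @export
print.slope_comparison <- function(x, ...) {
  unit <- if (x$comparison == "SLOPE") "Z/month" else "Z"
  cat("<slope_comparison> ", x$domain, " ", x$comparison,
      sprintf(": difference %.3f %s (%.0f %% CI %.3f to %.3f), p = %.4g\n",
              x$estimate, unit, 100 * x$conf_level, x$conf_low, x$conf_high,
              x$p_value),
      " groups: LIKELY_MCI n = ", x$n_likely_mci,
      ", LIKELY_DEMENTIA n = ", x$n_likely_dementia, "\n", sep = "")
  invisible(x)
}

#' Write P(AD) scores to CSV
#'
#' @param pad a `pad_scores` data.frame.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_pad <- function(pad, path) {
  write.csv(as.data.frame(pad), path, row.names = FALSE, na = "NA")
  invisible(path)
}
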