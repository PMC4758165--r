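#' Table-1-style per-group cohort summary
#'
#' One row per requested diagnosis group with n, male count/percent,
#' mean/SD age and education, APOE e4 carrier count/percent, and mean/SD of
#' each CSF analyte and of harmonized C3 (`c3_z`). Percentages are
#' `100 * count / n`. Empty groups get `n = 0` and `NA` statistics (not an
#' error); single-subject groups report `NA` SDs.
#'
#' @param cohort a `cohort`.
#' @param groups diagnosis groups to summarize (default the two AD stages).
#' @return a data.frame of class `cohort_summary`. Use [pool_groups()] for
#'   across-group (pooled) percentages and weighted means.
#' @export
summarize_cohort <- function(cohort, groups = c("MCI_AD", "AD")) {
  stopifnot(inherits(cohort, "cohort"), length(groups) >= 1)
  bad <- setdiff(groups, DIAGNOSIS_LEVELS)
  if (length(bad)) stop("unknown diagnosis group(s): ", paste(bad, collapse = ", "))
  s <- cohort$subjects
  msd <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) c(NA_real_, NA_real_)
    else c(mean(v), if (length(v) > 1) sd(v) else NA_real_)
  }
  rows <- lapply(groups, function(g) {
    gs <- s[s$diagnosis == g, , drop = FALSE]
    n <- nrow(gs)
    male_n <- sum(gs$sex == "MALE", na.rm = TRUE)
    apoe_n <- sum(gs$apoe4_carrier, na.rm = TRUE)
    age <- msd(gs$age); edu <- msd(gs$education)
    ab <- msd(gs$abeta42); tt <- msd(gs$ttau); pt <- msd(gs$ptau181)
    fh <- msd(gs$fh); cz <- msd(gs$c3_z)
    data.frame(
      cohort = cohort$cohort_id, group = g, n = n,
      male_n = if (n) male_n else NA_integer_,
      male_pct = if (n) 100 * male_n / n else NA_real_,
      age_mean = age[1], age_sd = age[2],
      education_mean = edu[1], education_sd = edu[2],
      apoe4_n = if (n) apoe_n else NA_integer_,
      apoe4_pct = if (n) 100 * apoe_n / n else NA_real_,
      abeta42_mean = ab[1], abeta42_sd = ab[2],
      ttau_mean = tt[1], ttau_sd = tt[2],
      ptau181_mean = pt[1], ptau181_sd = pt[2],
      fh_mean = fh[1], fh_sd = fh[2],
      c3_z_mean = cz[1], c3_z_sd = cz[2],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' Pool a per-group summary across groups
#'
#' Pooled counts and percentages (male, female, APOE e4) and sample-size
#' weighted means of the `*_mean` columns, computed from a
#' [summarize_cohort()] table -- or from any compatible table of printed
#' group-level statistics such as [table1_reference()].
#'
#' @param summary a `cohort_summary`-shaped data.frame (columns `n`,
#'   `male_n`, `apoe4_n` and `*_mean`).
#' @return a one-row data.frame with pooled `n`, `male_n`/`male_pct`,
#'   `female_pct`, `apoe4_n`/`apoe4_pct` and weighted `*_mean` columns.
#' @export
#' @examples
#' t1 <- table1_reference()
#' pool_groups(t1[t1$cohort == "ADNI", ]) # 66.5 % APOE e4, 74.5 yr
pool_groups <- function(summary) {
  stopifnot(is.data.frame(summary), all(c("n", "male_n", "apoe4_n") %in% names(summary)))
  n <- sum(summary$n)
  male_n <- sum(summary$male_n)
  apoe_n <- sum(summary$apoe4_n)
  out <- data.frame(
    n = n,
    male_n = male_n, male_pct = 100 * male_n / n,
    female_pct = 100 * (n - male_n) / n,
    apoe4_n = apoe_n, apoe4_pct = 100 * apoe_n / n
  )
  for (col in grep("_mean$", names(summary), value = TRUE)) {
    out[[col]] <- sum(summary$n * summary[[col]]) / n
  }
  out
}

#' Printed group-level reference statistics for the two study cohorts
#'
#' The published per-group demographic and biomarker statistics for the
#' ADNI training cohort (135 MCI-AD, 95 mild AD) and the Emory test cohort
#' (51 MCI-AD, 22 mild AD): counts of males and APOE e4 carriers, mean (SD)
#' age, education and CSF analytes, and the mean (SD) of the cohort-wise
#' z-scored log C3. These values serve two purposes: they are the default
#' parameters of the synthetic-cohort generator ([cohort_spec_adni()],
#' [cohort_spec_emory()]), and worked-example quantities (pooled APOE e4 and
#' female percentages, weighted mean age) can be recomputed from them with
#' [pool_groups()].
#'
#' @return a data.frame in [summarize_cohort()] layout, one row per
#'   cohort x group.
#' @export
table1_reference <- function() {
  df <- data.frame(
    cohort = c("ADNI", "ADNI", "Emory", "Emory"),
    group = c("MCI_AD", "AD", "MCI_AD", "AD"),
    n = c(135L, 95L, 51L, 22L),
    male_n = c(86L, 53L, 28L, 6L),
    age_mean = c(74.7, 74.3, 69.0, 65.6),
    age_sd = c(7.6, 7.7, 7.4, 8.8),
    education_mean = c(15.8, 14.9, 15.4, 13.9),
    education_sd = c(2.9, 3.1, 2.5, 2.4),
    apoe4_n = c(86L, 67L, 25L, 8L),
    abeta42_mean = c(136.7, 143.5, 129.8, 168.3),
    abeta42_sd = c(31.4, 39.9, 55.3, 104.0),
    ttau_mean = c(122.8, 122.5, 97.7, 120.3),
    ttau_sd = c(60.6, 57.8, 49.6, 60.0),
    ptau181_mean = c(42.4, 41.4, 55.6, 61.1),
    ptau181_sd = c(16.1, 19.9, 25.7, 26.2),
    fh_mean = c(1568, 1750, 1594, 1692),
    fh_sd = c(629, 835, 493, 474),
    c3_z_mean = c(-0.060, 0.061, -0.481, -0.064),
    c3_z_sd = c(0.929, 1.084, 1.031, 0.784),
    stringsAsFactors = FALSE
  )
  df$male_pct <- 100 * df$male_n / df$n
  df$apoe4_pct <- 100 * df$apoe4_n / df$n
  df
}
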