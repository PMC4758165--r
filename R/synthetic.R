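#' @name synthetic_cohort
#' @title Seeded synthetic cohorts with the study's statistical structure
#'
#' @description The real training (ADNI) and test (Emory) cohorts are
#' access-restricted, so the package ships a generator that emulates the
#' statistical structure the analysis assumes: per-group (cognitively
#' normal / MCI-AD / mild AD) class-conditional distributions with the
#' published group means and SDs as defaults, a within-group age dependence
#' of log C3 and (for subjects with AD-consistent CSF) of factor H, a
#' cohort-level multiplicative C3 assay factor standing in for the
#' between-platform shift that per-cohort z-scoring must remove, truncation
#' of analytes at zero, enforcement of the t-Tau/Abeta42 >= 0.39 inclusion
#' rule by per-subject rejection sampling, and longitudinal
#' executive/memory trajectories with per-subject random intercepts and
#' slopes. Features are drawn independently within group apart from the
#' stated age regressions; the published tables give no covariance
#' structure, which is a documented limitation.
NULL

#' Per-group distribution parameters for the synthetic generator
#'
#' @param n group size.
#' @param age_mean,age_sd age, years.
#' @param male_pct,apoe4_pct percent male / percent APOE e4 carriers.
#' @param education_mean,education_sd education, years.
#' @param abeta42_mean,abeta42_sd,ttau_mean,ttau_sd,ptau181_mean,ptau181_sd
#'   CSF analytes, pg/mL (truncated normal at 0).
#' @param fh_mean,fh_sd factor H, pg/mL (truncated normal at 0).
#' @param logc3_z_mean,logc3_z_sd group mean/SD of log C3 expressed in
#'   z-units of the cohort's normal-reference log-C3 scale (the published
#'   summaries report C3 this way).
#' @param exec_baseline,exec_slope,mem_baseline,mem_slope longitudinal
#'   executive/memory Z at baseline and slope in Z per month.
#' @return a list of class `group_spec`.
#' @export
group_spec <- function(n, age_mean = 72, age_sd = 7, male_pct = 50,
                       apoe4_pct = 50, education_mean = 15,
                       education_sd = 3, abeta42_mean = 160,
                       abeta42_sd = 50, ttau_mean = 100, ttau_sd = 50,
                       ptau181_mean = 40, ptau181_sd = 18, fh_mean = 1600,
                       fh_sd = 600, logc3_z_mean = 0, logc3_z_sd = 1,
                       exec_baseline = 0, exec_slope = 0,
                       mem_baseline = 0, mem_slope = 0) {
  out <- as.list(environment())
  stopifnot(out$n >= 0)
  sds <- grep("_sd$", names(out), value = TRUE)
  if (any(unlist(out[sds]) < 0)) stop("group_spec SDs must be >= 0")
  if (any(out$male_pct < 0 | out$male_pct > 100 |
          out$apoe4_pct < 0 | out$apoe4_pct > 100)) {
    stop("percentages must lie in [0, 100]")
  }
  structure(out, class = "group_spec")
}

#' Full cohort specification for the synthetic generator
#'
#' @param cohort_id cohort identifier.
#' @param groups named list of [group_spec()]s; names among `NORMAL`,
#'   `MCI_AD`, `AD`.
#' @param ref_logc3_mean,ref_logc3_sd location/scale of log C3 (log pg/mL)
#'   in the cognitively normal reference population; group log-C3
#'   distributions are placed relative to this scale via their
#'   `logc3_z_mean`/`logc3_z_sd`.
#' @param age_beta_logc3 within-group linear age coefficient on log C3
#'   (per year, age centered at the group mean): older subjects have
#'   greater C3. The published main text prints no coefficient; the default
#'   is a placeholder of plausible magnitude.
#' @param age_beta_fh within-group age coefficient on FH (pg/mL per year),
#'   applied only to groups in `fh_age_groups` -- age influences FH among
#'   subjects whose CSF is AD-consistent, not among biomarker-normal
#'   subjects.
#' @param fh_age_groups groups receiving the FH age effect.
#' @param c3_assay_factor cohort-level multiplicative factor on raw C3
#'   (assay/platform shift; removed by [normalize_c3()]).
#' @param ratio_groups groups whose subjects are rejection-sampled until
#'   t-Tau/Abeta42 >= `ratio_threshold` (the MCI-AD inclusion rule holds by
#'   construction).
#' @param ratio_threshold inclusion threshold (default 0.39).
#' @param rejection_cap per-subject redraw budget before an
#'   infeasible-constraint error.
#' @param visit_months visit schedule, months from baseline.
#' @param visit_groups groups that receive longitudinal visits.
#' @param intercept_sd,slope_sd,resid_sd longitudinal between-subject
#'   baseline SD (Z), between-subject slope SD (Z/month) and residual SD
#'   (Z).
#' @param master_seed integer seed; the whole cohort is reproducible from
#'   it.
#' @return a list of class `cohort_spec`.
#' @export
cohort_spec <- function(cohort_id, groups,
                        ref_logc3_mean = 10.0, ref_logc3_sd = 0.35,
                        age_beta_logc3 = 0.012, age_beta_fh = 8,
                        fh_age_groups = c("MCI_AD", "AD"),
                        c3_assay_factor = 1,
                        ratio_groups = "MCI_AD", ratio_threshold = 0.39,
                        rejection_cap = 1000L,
                        visit_months = c(0, 6, 12, 18, 24),
                        visit_groups = c("MCI_AD", "AD"),
                        intercept_sd = 0.4, slope_sd = 0.01,
                        resid_sd = 0.2, master_seed = 1L) {
  stopifnot(is.list(groups), length(groups) >= 1,
            all(names(groups) %in% DIAGNOSIS_LEVELS),
            all(vapply(groups, inherits, logical(1), "group_spec")),
            ref_logc3_sd >= 0, c3_assay_factor > 0, rejection_cap >= 1)
  structure(as.list(environment()), class = "cohort_spec")
}

truncnorm_pos <- function(n, mean, sd, cap = 1000L, what = "analyte") {
  if (n == 0) return(numeric(0))
  if (sd == 0) {
    if (mean <= 0) stop("infeasible constraint: ", what, " mean <= 0 with SD 0")
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  for (i in seq_len(cap)) {
    bad <- x <= 0
    if (!any(bad)) return(x)
    x[bad] <- rnorm(sum(bad), mean, sd)
  }
  stop("rejection budget exhausted drawing positive ", what,
       " (mean ", mean, ", sd ", sd, ")")
}

generate_group <- function(g, gs, spec) {
  n <- gs$n
  age <- truncnorm_pos(n, gs$age_mean, gs$age_sd, spec$rejection_cap, "age")
  sex <- ifelse(runif(n) < gs$male_pct / 100, "MALE", "FEMALE")
  apoe <- runif(n) < gs$apoe4_pct / 100
  edu <- pmax(0, rnorm(n, gs$education_mean, gs$education_sd))
  ptau <- truncnorm_pos(n, gs$ptau181_mean, gs$ptau181_sd, spec$rejection_cap, "ptau181")

  # tau/amyloid drawn jointly under the optional inclusion-rule constraint
  ab <- truncnorm_pos(n, gs$abeta42_mean, gs$abeta42_sd, spec$rejection_cap, "abeta42")
  tt <- truncnorm_pos(n, gs$ttau_mean, gs$ttau_sd, spec$rejection_cap, "ttau")
  if (g %in% spec$ratio_groups && n > 0) {
    for (i in seq_len(spec$rejection_cap)) {
      bad <- tt / ab < spec$ratio_threshold
      if (!any(bad)) break
      nb <- sum(bad)
      ab[bad] <- truncnorm_pos(nb, gs$abeta42_mean, gs$abeta42_sd,
                               spec$rejection_cap, "abeta42")
      tt[bad] <- truncnorm_pos(nb, gs$ttau_mean, gs$ttau_sd,
                               spec$rejection_cap, "ttau")
      if (i == spec$rejection_cap) {
        stop("rejection budget exhausted enforcing t-Tau/Abeta42 >= ",
             spec$ratio_threshold, " in group ", g)
      }
    }
  }

  age_c <- age - gs$age_mean
  fh_beta <- if (g %in% spec$fh_age_groups) spec$age_beta_fh else 0
  fh <- truncnorm_pos(n, gs$fh_mean, gs$fh_sd, spec$rejection_cap, "fh") +
    fh_beta * age_c
  fh <- pmax(fh, .Machine$double.eps)

  logc3_mean <- spec$ref_logc3_mean + gs$logc3_z_mean * spec$ref_logc3_sd
  logc3_sd <- gs$logc3_z_sd * spec$ref_logc3_sd
  logc3 <- logc3_mean + spec$age_beta_logc3 * age_c +
    (if (logc3_sd > 0) rnorm(n, 0, logc3_sd) else 0)
  c3 <- exp(logc3) * spec$c3_assay_factor

  data.frame(
    subject_id = sprintf("%s_%s_%03d", spec$cohort_id, g, seq_len(max(n, 0))),
    diagnosis = rep(g, n), age = age, sex = sex, education = edu,
    apoe4_carrier = apoe, abeta42 = ab, ttau = tt, ptau181 = ptau,
    c3_raw = c3, fh = fh, c3_z = NA_real_, stringsAsFactors = FALSE
  )
}

generate_visits <- function(subjects, gs, spec) {
  months <- spec$visit_months
  if (!length(months) || !nrow(subjects)) return(NULL)
  rows <- lapply(seq_len(nrow(subjects)), function(i) {
    b_e <- gs$exec_baseline + rnorm(1, 0, spec$intercept_sd)
    s_e <- gs$exec_slope + rnorm(1, 0, spec$slope_sd)
    b_m <- gs$mem_baseline + rnorm(1, 0, spec$intercept_sd)
    s_m <- gs$mem_slope + rnorm(1, 0, spec$slope_sd)
    data.frame(
      subject_id = subjects$subject_id[i],
      months_from_baseline = months,
      executive_z = b_e + s_e * months + rnorm(length(months), 0, spec$resid_sd),
      memory_z = b_m + s_m * months + rnorm(length(months), 0, spec$resid_sd),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Generate a synthetic cohort from a specification
#'
#' Fully reproducible from `spec$master_seed`. All generated analytes are
#' strictly positive; every subject of a ratio-constrained group (by
#' default MCI_AD) satisfies the t-Tau/Abeta42 >= 0.39 inclusion rule by
#' construction; the cohort's `normal_reference` is its NORMAL group.
#'
#' @param spec a [cohort_spec()].
#' @return a `cohort` (not yet C3-normalized; apply [normalize_c3()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(derive_seed(spec$master_seed, "cohort", spec$cohort_id), {
    order_groups <- intersect(DIAGNOSIS_LEVELS, names(spec$groups))
    subj <- list()
    vis <- list()
    for (g in order_groups) {
      gs <- spec$groups[[g]]
      sg <- generate_group(g, gs, spec)
      subj[[g]] <- sg
      if (g %in% spec$visit_groups) vis[[g]] <- generate_visits(sg, gs, spec)
    }
    subjects <- do.call(rbind, subj)
    rownames(subjects) <- NULL
    visits <- if (length(vis)) do.call(rbind, vis) else NULL
    if (!is.null(visits)) rownames(visits) <- NULL
    new_cohort(subjects, cohort_id = spec$cohort_id, visits = visits,
               metadata = list(
                 generator = "xmittn synthetic cohort",
                 master_seed = spec$master_seed,
                 c3_assay_factor = spec$c3_assay_factor,
                 c3_lower_limit_pg_ml = 143, fh_lower_limit_pg_ml = 7
               ))
  })
}

#' Default training-cohort specification (ADNI-like)
#'
#' Group sizes, demographics and analyte means/SDs are the published ADNI
#' training-cohort values (135 MCI-AD, 95 mild AD, 115 cognitively normal
#' reference subjects); log-C3 group locations are placed via the published
#' z-scores. Normal-group analyte distributions are not published and are
#' set to field-realistic values (they only serve as the C3 z-scoring
#' reference). Longitudinal defaults give patients mildly declining
#' executive/memory trajectories, steeper for dementia.
#'
#' @param master_seed integer seed.
#' @param ... overrides passed on to [cohort_spec()].
#' @return a `cohort_spec`.
#' @export
cohort_spec_adni <- function(master_seed = 1L, ...) {
  cohort_spec(
    cohort_id = "adni_like",
    groups = list(
      NORMAL = group_spec(n = 115, age_mean = 75, age_sd = 5, male_pct = 50,
                          apoe4_pct = 27, education_mean = 16,
                          education_sd = 2.7, abeta42_mean = 205,
                          abeta42_sd = 55, ttau_mean = 70, ttau_sd = 30,
                          ptau181_mean = 25, ptau181_sd = 12,
                          fh_mean = 1500, fh_sd = 500,
                          logc3_z_mean = 0, logc3_z_sd = 1),
      MCI_AD = group_spec(n = 135, age_mean = 74.7, age_sd = 7.6,
                          male_pct = 100 * 86 / 135,
                          apoe4_pct = 100 * 86 / 135,
                          education_mean = 15.8, education_sd = 2.9,
                          abeta42_mean = 136.7, abeta42_sd = 31.4,
                          ttau_mean = 122.8, ttau_sd = 60.6,
                          ptau181_mean = 42.4, ptau181_sd = 16.1,
                          fh_mean = 1568, fh_sd = 629,
                          logc3_z_mean = -0.060, logc3_z_sd = 0.929,
                          exec_baseline = -0.5, exec_slope = -0.010,
                          mem_baseline = -0.8, mem_slope = -0.015),
      AD = group_spec(n = 95, age_mean = 74.3, age_sd = 7.7,
                      male_pct = 100 * 53 / 95, apoe4_pct = 100 * 67 / 95,
                      education_mean = 14.9, education_sd = 3.1,
                      abeta42_mean = 143.5, abeta42_sd = 39.9,
                      ttau_mean = 122.5, ttau_sd = 57.8,
                      ptau181_mean = 41.4, ptau181_sd = 19.9,
                      fh_mean = 1750, fh_sd = 835,
                      logc3_z_mean = 0.061, logc3_z_sd = 1.084,
                      exec_baseline = -1.5, exec_slope = -0.045,
                      mem_baseline = -2.0, mem_slope = -0.030)
    ),
    master_seed = master_seed, ...
  )
}

#' Default test-cohort specification (Emory-like)
#'
#' Published Emory test-cohort values (51 MCI-AD, 22 mild AD, 25
#' cognitively normal reference subjects) with a cohort-level C3 assay
#' factor of 0.6, standing in for the lower raw C3 levels of the Emory
#' platform that per-cohort z-scoring must absorb.
#'
#' @inheritParams cohort_spec_adni
#' @return a `cohort_spec`.
#' @export
cohort_spec_emory <- function(master_seed = 2L, ...) {
  cohort_spec(
    cohort_id = "emory_like",
    groups = list(
      NORMAL = group_spec(n = 25, age_mean = 68, age_sd = 7, male_pct = 45,
                          apoe4_pct = 25, education_mean = 16,
                          education_sd = 2.5, abeta42_mean = 230,
                          abeta42_sd = 70, ttau_mean = 60, ttau_sd = 25,
                          ptau181_mean = 30, ptau181_sd = 12,
                          fh_mean = 1550, fh_sd = 480,
                          logc3_z_mean = 0, logc3_z_sd = 1),
      MCI_AD = group_spec(n = 51, age_mean = 69.0, age_sd = 7.4,
                          male_pct = 100 * 28 / 51,
                          apoe4_pct = 100 * 25 / 51,
                          education_mean = 15.4, education_sd = 2.5,
                          abeta42_mean = 129.8, abeta42_sd = 55.3,
                          ttau_mean = 97.7, ttau_sd = 49.6,
                          ptau181_mean = 55.6, ptau181_sd = 25.7,
                          fh_mean = 1594, fh_sd = 493,
                          logc3_z_mean = -0.481, logc3_z_sd = 1.031,
                          exec_baseline = -0.5, exec_slope = -0.010,
                          mem_baseline = -0.8, mem_slope = -0.015),
      AD = group_spec(n = 22, age_mean = 65.6, age_sd = 8.8,
                      male_pct = 100 * 6 / 22, apoe4_pct = 100 * 8 / 22,
                      education_mean = 13.9, education_sd = 2.4,
                      abeta42_mean = 168.3, abeta42_sd = 104.0,
                      ttau_mean = 120.3, ttau_sd = 60.0,
                      ptau181_mean = 61.1, ptau181_sd = 26.2,
                      fh_mean = 1692, fh_sd = 474,
                      logc3_z_mean = -0.064, logc3_z_sd = 0.784,
                      exec_baseline = -1.5, exec_slope = -0.045,
                      mem_baseline = -2.0, mem_slope = -0.030)
    ),
    c3_assay_factor = 0.6,
    master_seed = master_seed, ...
  )
}

# copy MCI_AD distributions onto the AD group (sizes kept) and constrain
# both stages by the inclusion rule, so stage labels carry no signal
equalize_stages <- function(spec) {
  stopifnot(all(c("MCI_AD", "AD") %in% names(spec$groups)))
  n_ad <- spec$groups$AD$n
  spec$groups$AD <- spec$groups$MCI_AD
  spec$groups$AD$n <- n_ad
  spec$ratio_groups <- c("MCI_AD", "AD")
  spec
}

resize_groups <- function(spec, sizes) {
  for (g in names(sizes)) {
    if (!g %in% names(spec$groups)) next
    spec$groups[[g]]$n <- as.integer(sizes[[g]])
  }
  spec
}

#' Generate a matched training/test cohort pair with no stage signal
#'
#' Both cohorts share the MCI-AD distributions for *both* stage groups
#' (labels carry no information about any feature), are drawn
#' independently, and carry different cohort-level C3 assay factors -- so a
#' correct pipeline must report chance-level classification, and per-cohort
#' z-scoring must remove the assay shift.
#'
#' @param base a `cohort_spec` for the training cohort (default
#'   [cohort_spec_adni()]).
#' @param test_sizes named group sizes for the test cohort (default the
#'   published test-cohort sizes 25/51/22).
#' @param test_assay_factor C3 assay factor of the test cohort (default
#'   0.6 vs the training cohort's 1).
#' @param master_seed seed; train and test draws are independent child
#'   streams.
#' @return list with elements `train` and `test`, both `cohort`s.
#' @export
generate_null_pair <- function(base = cohort_spec_adni(),
                               test_sizes = c(NORMAL = 25L, MCI_AD = 51L, AD = 22L),
                               test_assay_factor = 0.6,
                               master_seed = base$master_seed) {
  null_spec <- equalize_stages(base)
  train_spec <- null_spec
  train_spec$cohort_id <- paste0(base$cohort_id, "_train")
  train_spec$master_seed <- derive_seed(master_seed, "pair", "train")
  test_spec <- resize_groups(null_spec, test_sizes)
  test_spec$cohort_id <- paste0(base$cohort_id, "_test")
  test_spec$c3_assay_factor <- test_assay_factor
  test_spec$master_seed <- derive_seed(master_seed, "pair", "test")
  list(train = generate_cohort(train_spec), test = generate_cohort(test_spec))
}

#' Generate a training/test pair with signal only in C3 and factor H
#'
#' Starts from the no-signal configuration of [generate_null_pair()] and
#' shifts the AD group's log-C3 and FH means by the requested standardized
#' amounts relative to MCI-AD (negative shifts = lower levels with more
#' advanced disease), and steepens the AD executive slope by `slope_gap`.
#' All other features remain identically distributed across stages, so the
#' six-feature experiment stays null while the eight-feature experiment
#' carries the signal.
#'
#' @inheritParams generate_null_pair
#' @param c3_shift standardized mean shift of AD log C3 (default -1).
#' @param fh_shift standardized mean shift of AD FH (default -1).
#' @param slope_gap added to the AD executive slope, Z/month (default
#'   -0.035: dementia declines faster).
#' @return list with elements `train` and `test`.
#' @export
generate_staged_pair <- function(base = cohort_spec_adni(), c3_shift = -1,
                                 fh_shift = -1, slope_gap = -0.035,
                                 test_sizes = c(NORMAL = 25L, MCI_AD = 51L, AD = 22L),
                                 test_assay_factor = 0.6,
                                 master_seed = base$master_seed) {
  stopifnot(is.finite(c3_shift), is.finite(fh_shift))
  spec <- equalize_stages(base)
  ad <- spec$groups$AD
  ad$logc3_z_mean <- ad$logc3_z_mean + c3_shift * ad$logc3_z_sd
  ad$fh_mean <- ad$fh_mean + fh_shift * ad$fh_sd
  ad$exec_slope <- ad$exec_slope + slope_gap
  spec$groups$AD <- ad
  train_spec <- spec
  train_spec$cohort_id <- paste0(base$cohort_id, "_train")
  train_spec$master_seed <- derive_seed(master_seed, "pair", "train")
  test_spec <- resize_groups(spec, test_sizes)
  test_spec$cohort_id <- paste0(base$cohort_id, "_test")
  test_spec$c3_assay_factor <- test_assay_factor
  test_spec$master_seed <- derive_seed(master_seed, "pair", "test")
  list(train = generate_cohort(train_spec), test = generate_cohort(test_spec))
}
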