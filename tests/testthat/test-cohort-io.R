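test_that("write_cohort then read_cohort is the identity on all typed fields", {
  cohort <- make_toy_cohort(n_mci = 8, n_ad = 7, n_normal = 5)
  cohort$visits <- data.frame(
    subject_id = rep(cohort$subjects$subject_id[1:3], each = 3),
    months_from_baseline = rep(c(0, 6.5, 12), 3),
    executive_z = rnorm(9), memory_z = rnorm(9),
    stringsAsFactors = FALSE
  )
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.csv")
  written <- write_cohort(cohort, path)
  expect_length(written, 2) # companion visits file
  back <- read_cohort(path, visits_path = written[2], cohort_id = "toy")
  for (col in names(cohort$subjects)) {
    expect_identical(back$subjects[[col]], cohort$subjects[[col]], label = col)
  }
  expect_identical(back$visits, cohort$visits)
})

test_that("an empty cohort writes a header-only file", {
  cohort <- make_toy_cohort(n_mci = 1, n_ad = 1, n_normal = 1)
  cohort$subjects <- cohort$subjects[0, ]
  cohort$normal_reference <- cohort$normal_reference[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(cohort, path)
  expect_length(readLines(path), 1L)
})

test_that("read_cohort resolves a schema mapping and reports bad rows", {
  subj <- make_subjects(3)
  names(subj)[names(subj) == "abeta42"] <- "AB42"
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(subj, path, row.names = FALSE)
  cohort <- read_cohort(path, schema = c(abeta42 = "AB42"))
  expect_s3_class(cohort, "cohort")
  expect_equal(nrow(cohort$subjects), 3)

  # missing required column -> schema error
  expect_error(read_cohort(path), "schema error.*abeta42")

  # non-positive analyte -> validation error naming the row
  subj2 <- make_subjects(3)
  subj2$abeta42[2] <- -5
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(subj2, path2, row.names = FALSE)
  expect_error(read_cohort(path2), "non-positive abeta42 at row\\(s\\) 2")
})

test_that("cohort invariants are enforced at construction", {
  subj <- make_subjects(3)
  subj$subject_id <- c("A", "A", "B")
  expect_error(new_cohort(subj), "duplicate subject_id")

  subj <- make_subjects(3, ttau = 30, abeta42 = 100) # ratio 0.3 < 0.39
  expect_error(new_cohort(subj), "violate t-Tau/Abeta42")

  subj <- make_subjects(2, diagnosis = "AD")
  visits <- data.frame(subject_id = "S001",
                       months_from_baseline = c(0, 6, 6),
                       executive_z = 0, memory_z = 0)
  expect_error(new_cohort(subj, visits = visits), "strictly increasing")
})

test_that("the MCI-AD inclusion rule has an inclusive 0.39 boundary", {
  expect_true(apply_ad_filter(39.0, 100.0))    # ratio exactly 0.39
  expect_false(apply_ad_filter(38.9, 100.0))   # just below
  expect_true(apply_ad_filter(122.8, 136.7))   # group-mean ratio ~0.898
  expect_error(apply_ad_filter(39, 0), "positive")
  expect_error(apply_ad_filter(NA, 100), "missing")
})

test_that("the inclusion rule is monotone in t-Tau and Abeta42", {
  set.seed(TEST_SEED)
  tt <- runif(50, 20, 200)
  ab <- runif(50, 50, 250)
  base <- apply_ad_filter(tt, ab)
  more_tau <- apply_ad_filter(tt + runif(50, 0, 50), ab)
  expect_true(all(more_tau >= base)) # non-decreasing in ttau
  more_ab <- apply_ad_filter(tt, ab + runif(50, 0, 50))
  expect_true(all(more_ab <= base)) # non-increasing in abeta42
})

test_that("normalize_c3 z-scores log C3 against the cohort's own normal reference", {
  cohort <- make_toy_cohort()
  ref_log <- log(cohort$normal_reference$c3_raw)
  m <- mean(ref_log); s <- sd(ref_log)

  # inject subjects at exactly the reference mean and mean + 1 SD
  cohort$subjects$c3_raw[1] <- exp(m)
  cohort$subjects$c3_raw[2] <- exp(m + s)
  norm <- normalize_c3(cohort)
  expect_equal(norm$subjects$c3_z[1], 0, tolerance = 1e-12)
  expect_equal(norm$subjects$c3_z[2], 1, tolerance = 1e-12)

  # the reference's own z-scores have sample mean 0 and SD 1
  expect_equal(mean(norm$normal_reference$c3_z), 0, tolerance = 1e-10)
  expect_equal(sd(norm$normal_reference$c3_z), 1, tolerance = 1e-10)
})

test_that("normalize_c3 matches closed-form hand arithmetic on a 3-subject reference", {
  # reference 100/150/200 pg/mL, subject at 300 pg/mL; sample SD (n-1)
  logs <- c(log(100), log(150), log(200))
  m <- (logs[1] + logs[2] + logs[3]) / 3
  s <- sqrt(((logs[1] - m)^2 + (logs[2] - m)^2 + (logs[3] - m)^2) / 2)
  expected <- (log(300) - m) / s

  subj <- make_subjects(4, diagnosis = c("NORMAL", "NORMAL", "NORMAL", "MCI_AD"),
                        c3_raw = c(100, 150, 200, 300),
                        ttau = 100, abeta42 = 100)
  norm <- normalize_c3(new_cohort(subj))
  expect_equal(norm$subjects$c3_z[4], expected, tolerance = 1e-12)
})

test_that("normalize_c3 rejects degenerate references", {
  subj <- make_subjects(2, diagnosis = c("NORMAL", "MCI_AD"), ttau = 100, abeta42 = 100)
  expect_error(normalize_c3(new_cohort(subj)), "insufficient reference")

  subj3 <- make_subjects(3, diagnosis = c("NORMAL", "NORMAL", "MCI_AD"),
                         c3_raw = c(150, 150, 200), ttau = 100, abeta42 = 100)
  expect_error(normalize_c3(new_cohort(subj3)), "degenerate reference")
})

test_that("feature matrices have the documented shape and labels", {
  pair <- generate_null_pair(master_seed = TEST_SEED)
  cohort <- normalize_c3(pair$train) # 135 MCI_AD + 95 AD + 115 NORMAL
  fm1 <- build_feature_matrix(cohort, "EXP1")
  expect_equal(dim(fm1$x), c(230, 6))
  expect_equal(fm1$feature_names,
               c("age", "sex_male01", "apoe4_01", "abeta42", "ttau", "ptau181"))
  fm2 <- build_feature_matrix(cohort, "EXP2")
  expect_equal(dim(fm2$x), c(230, 8))
  expect_equal(fm2$feature_names[7:8], c("c3_z", "fh"))
  expect_equal(sum(fm2$y == 0), 135) # MCI_AD labeled 0
  expect_equal(sum(fm2$y == 1), 95)  # AD labeled 1
  # NORMAL subjects never appear
  expect_false(any(grepl("NORMAL", fm2$subject_ids)))
})

test_that("feature construction drops incomplete rows and demands normalization", {
  cohort <- make_toy_cohort()
  expect_error(build_feature_matrix(cohort, "EXP2"), "normalize_c3")
  cohort <- normalize_c3(cohort)
  cohort$subjects$fh[1] <- NA
  fm <- build_feature_matrix(cohort, "EXP2")
  expect_equal(fm$dropped_ids, cohort$subjects$subject_id[1])
  expect_equal(nrow(fm$x), 39)
  # a cohort with no eligible stage subjects errors
  normals <- cohort
  normals$subjects <- normals$subjects[normals$subjects$diagnosis == "NORMAL", ]
  expect_error(build_feature_matrix(normals, "EXP1"), "empty matrix")
})

test_that("cohort summaries reproduce the printed reference percentages", {
  t1 <- table1_reference()
  adni <- t1[t1$cohort == "ADNI", ]
  emory <- t1[t1$cohort == "Emory", ]
  # group percentage: 86 of 135 MCI-AD males -> 64 %
  expect_equal(round(adni$male_pct[adni$group == "MCI_AD"]), 64)
  pa <- pool_groups(adni)
  expect_equal(round(pa$apoe4_pct, 1), 66.5)
  expect_equal(round(pa$female_pct, 1), 39.6)
  expect_equal(round(pa$age_mean, 1), 74.5)
  pe <- pool_groups(emory)
  expect_equal(round(pe$apoe4_pct, 1), 45.2)
  expect_equal(round(pe$female_pct, 1), 53.4)
})

test_that("summarize_cohort computes per-group statistics and handles degenerate groups", {
  subj <- make_subjects(5, diagnosis = c("MCI_AD", "MCI_AD", "MCI_AD", "AD", "NORMAL"),
                        sex = c("MALE", "MALE", "FEMALE", "FEMALE", "MALE"),
                        apoe4_carrier = c(TRUE, FALSE, TRUE, TRUE, FALSE),
                        age = c(70, 72, 74, 80, 68),
                        ttau = 100, abeta42 = 100)
  cohort <- new_cohort(subj)
  s <- summarize_cohort(cohort, groups = c("MCI_AD", "AD", "MCI_OTHER"))
  mci <- s[s$group == "MCI_AD", ]
  expect_equal(mci$n, 3)
  expect_equal(mci$male_pct, 100 * 2 / 3)
  expect_equal(mci$age_mean, 72)
  expect_equal(mci$age_sd, 2)
  # single-subject group: SD reported as NA
  expect_true(is.na(s$age_sd[s$group == "AD"]))
  # empty group: n = 0 with NA statistics, not an error
  expect_equal(s$n[s$group == "MCI_OTHER"], 0)
  expect_true(is.na(s$age_mean[s$group == "MCI_OTHER"]))
  # pooling a computed summary works like pooling the printed table
  p <- pool_groups(s[s$group %in% c("MCI_AD", "AD"), ])
  expect_equal(p$n, 4)
  expect_equal(p$apoe4_pct, 75)
})
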