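# master seed for every randomized check in the suite
TEST_SEED <- 1234L

# brute-force Gini oracle: enumerate all positive-negative pairs, ties 1/2
gini_bruteforce <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (sp in pos) {
    for (sn in neg) {
      wins <- wins + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
    }
  }
  2 * wins / (length(pos) * length(neg)) - 1
}

# pure-R averaged perceptron, the reference for the compiled training loop
perceptron_reference <- function(x, y, order, epochs, lr) {
  yy <- ifelse(y == 1, 1, -1)
  p <- ncol(x)
  w <- numeric(p); b <- 0
  wsum <- numeric(p); bsum <- 0; count <- 0
  for (e in seq_len(epochs)) {
    for (i in order) {
      if (yy[i] * (sum(w * x[i, ]) + b) <= 0) {
        w <- w + lr * yy[i] * x[i, ]
        b <- b + lr * yy[i]
      }
      wsum <- wsum + w; bsum <- bsum + b; count <- count + 1
    }
  }
  list(w = wsum / count, b = bsum / count)
}

# minimal valid subjects table; override any column through ...
make_subjects <- function(n, diagnosis = "MCI_AD", seed = TEST_SEED, ...) {
  set.seed(seed)
  out <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    diagnosis = rep(diagnosis, length.out = n),
    age = round(runif(n, 60, 85), 1),
    sex = sample(c("MALE", "FEMALE"), n, replace = TRUE),
    education = round(runif(n, 10, 20), 1),
    apoe4_carrier = sample(c(TRUE, FALSE), n, replace = TRUE),
    abeta42 = round(runif(n, 100, 250), 1),
    ttau = round(runif(n, 100, 250), 1),
    ptau181 = round(runif(n, 20, 80), 1),
    c3_raw = round(runif(n, 10000, 40000), 1),
    fh = round(runif(n, 800, 2500), 1),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) out[[nm]] <- over[[nm]]
  out
}

# small two-stage cohort with a normal reference, optional C3/FH signal
make_toy_cohort <- function(n_mci = 20, n_ad = 20, n_normal = 10,
                            c3_shift = 0, fh_shift = 0, seed = TEST_SEED,
                            cohort_id = "toy") {
  set.seed(seed)
  n <- n_mci + n_ad + n_normal
  dx <- c(rep("MCI_AD", n_mci), rep("AD", n_ad), rep("NORMAL", n_normal))
  ad <- dx == "AD"
  abeta <- pmax(rnorm(n, 140, 30), 10)
  subj <- data.frame(
    subject_id = sprintf("%s%03d", cohort_id, seq_len(n)),
    diagnosis = dx,
    age = rnorm(n, 72, 7),
    sex = sample(c("MALE", "FEMALE"), n, replace = TRUE),
    education = rnorm(n, 15, 3),
    apoe4_carrier = sample(c(TRUE, FALSE), n, replace = TRUE),
    abeta42 = abeta,
    ttau = pmax(rnorm(n, 160, 40), 60, 0.4 * abeta), # keep MCI-AD rule satisfied
    ptau181 = pmax(rnorm(n, 42, 16), 5),
    c3_raw = exp(rnorm(n, 10, 0.35) + c3_shift * 0.35 * ad),
    fh = pmax(rnorm(n, 1600, 600) + fh_shift * 600 * ad, 10),
    stringsAsFactors = FALSE
  )
  new_cohort(subj, cohort_id = cohort_id)
}

# linearly separable 2-class feature matrix in the package's EXP1 layout:
# abeta42 carries the separation, everything else is noise
make_separable_fm <- function(n_per_class = 10, gap = 80, seed = TEST_SEED) {
  set.seed(seed)
  n <- 2 * n_per_class
  y <- rep(c(0L, 1L), each = n_per_class)
  x <- cbind(
    age = rnorm(n, 72, 5),
    sex_male01 = sample(0:1, n, replace = TRUE),
    apoe4_01 = sample(0:1, n, replace = TRUE),
    abeta42 = 150 + gap * y + rnorm(n, 0, 5),
    ttau = rnorm(n, 120, 20),
    ptau181 = rnorm(n, 42, 8)
  )
  rownames(x) <- sprintf("P%03d", seq_len(n))
  structure(
    list(x = x, y = y, feature_names = colnames(x), experiment = "EXP1",
         subject_ids = rownames(x), dropped_ids = character()),
    class = "feature_matrix"
  )
}

# synthetic two-stratum cohort with a known executive-slope gap (Z/month);
# the reference conditions mirror the longitudinal subgroups: strata of 5,
# visits every 6 months over 2 years, residual SD 0.2 Z, between-subject
# slope SD 0.01 Z/month
make_strata_cohort <- function(n_mci = 5, n_dem = 5, slope_gap = 0.035,
                               resid_sd = 0.2, slope_sd = 0.01,
                               months = c(0, 6, 12, 18, 24), seed = TEST_SEED) {
  set.seed(seed)
  n <- n_mci + n_dem
  subj <- make_subjects(n, diagnosis = "MCI_AD", ttau = 100, abeta42 = 100,
                        seed = seed)
  dem <- c(rep(FALSE, n_mci), rep(TRUE, n_dem))
  visits <- do.call(rbind, lapply(seq_len(n), function(i) {
    slope <- rnorm(1, if (dem[i]) -slope_gap else 0, slope_sd)
    data.frame(subject_id = subj$subject_id[i],
               months_from_baseline = months,
               executive_z = rnorm(1, 0, 0.3) + slope * months +
                 rnorm(length(months), 0, resid_sd),
               memory_z = NA_real_, stringsAsFactors = FALSE)
  }))
  pad <- data.frame(subject_id = subj$subject_id,
                    stratum = ifelse(dem, "LIKELY_DEMENTIA", "LIKELY_MCI"),
                    stringsAsFactors = FALSE)
  list(cohort = new_cohort(subj, visits = visits), pad = pad)
}

# feature_matrix wrapper around an arbitrary matrix
fm_from_matrix <- function(x, y, experiment = "EXP1") {
  structure(
    list(x = x, y = as.integer(y), feature_names = colnames(x),
         experiment = experiment,
         subject_ids = rownames(x) %||% sprintf("R%03d", seq_len(nrow(x))),
         dropped_ids = character()),
    class = "feature_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
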