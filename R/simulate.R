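# Synthetic multi-cohort generator.
#
# Cross-section: a five-component Gaussian mixture on a transformed scale
# (age in years, linear; BMI, HbA1c, C-peptide and HDL-cholesterol on the
# log scale, giving right-skewed, strictly positive marginals).  Component
# locations are calibrated so cohort-level medians sit near the published
# cohort descriptions (BMI ~30 kg/m2, HbA1c ~55-57 mmol/mol, C-peptide
# ~1.3 nmol/l, HDL ~1.2 mmol/l) and each component carries the defining
# signature of one archetype: SIDD high HbA1c and younger; SIRD high
# C-peptide and older; MOD high BMI and youngest; MDH older with high HDL;
# MD without extreme characteristics.
#
# Follow-up: annual visits for ten years; HbA1c follows a treat-to-target
# model (each added oral drug class halves the excess over a treated floor);
# oral medication escalates deterministically at visits; insulin initiation
# is the only stochastic event, drawn from an exponential proportional-
# hazards model whose per-archetype rates are calibrated so that the
# one-vs-rest Cox contrasts equal configured target hazard ratios.

# transformed-scale variable order: age, log(bmi), log(hba1c), log(cpep), log(hdl)
TRANSFORMED_VARS <- c("age", "log_bmi", "log_hba1c", "log_c_peptide", "log_hdl")

DEFAULT_WEIGHTS <- c(SIDD = 0.15, SIRD = 0.15, MOD = 0.20, MD = 0.32, MDH = 0.18)

# within-component standard deviations on the transformed scale
DEFAULT_SDS <- c(age = 6.5, log_bmi = 0.11, log_hba1c = 0.10,
                 log_c_peptide = 0.22, log_hdl = 0.11)

# component offsets from the cohort base, in units of the within-component sd
DEFAULT_OFFSETS <- rbind(
  SIDD = c(-1.5, -1.1,  3.8, -1.1, -0.7),
  SIRD = c( 1.8,  0.6, -0.7,  3.9, -1.1),
  MOD  = c(-2.3,  3.2, -0.5,  0.6, -0.6),
  MD   = c( 0.1,  0.0, -0.2,  0.0, -0.2),
  MDH  = c( 1.8, -0.7, -0.7, -0.7,  3.4))

default_base <- function(sex) {
  b <- c(age = 61, log_bmi = log(30), log_hba1c = log(56),
         log_c_peptide = log(1.25), log_hdl = log(1.18))
  if (sex == "female") {
    # small, realistic sex differences; removed again by per-sex z-scoring
    b["age"] <- b["age"] - 0.5
    b["log_bmi"] <- b["log_bmi"] + 0.02
    b["log_hdl"] <- b["log_hdl"] + 0.10
  }
  b
}

default_sex_components <- function(sex, separation = 1) {
  base <- default_base(sex)
  mu <- sweep(DEFAULT_OFFSETS * separation, 2, DEFAULT_SDS, `*`)
  mu <- sweep(mu, 2, base, `+`)
  dimnames(mu) <- list(ARCHETYPES, TRANSFORMED_VARS)
  sigma <- lapply(ARCHETYPES, function(a) {
    s <- diag(DEFAULT_SDS^2)
    dimnames(s) <- list(TRANSFORMED_VARS, TRANSFORMED_VARS)
    s
  })
  names(sigma) <- ARCHETYPES
  list(mu = mu, sigma = sigma)
}

#' Configuration of the cross-sectional mixture generator
#'
#' Defines the five-component mixture from which synthetic cohorts are drawn.
#' Components live on a transformed scale (age linear; BMI, HbA1c, C-peptide
#' and HDL log-transformed) so all positive-scale variables are strictly
#' positive by construction; age is truncated to \[35, 95\] years.
#'
#' @param n_subjects Number of individuals to generate (default 5000).
#' @param seed Integer seed; the same seed reproduces the same cohort.
#' @param separation Positive scalar multiplying each component's offset from
#'   the weighted mixture centre (1 = calibrated default; larger values give
#'   cleaner clusters).
#' @param male_fraction Probability that a subject is male (default 0.58).
#' @param weights Component weights over the archetypes (SIDD, SIRD, MOD, MD,
#'   MDH); must be non-negative and sum to 1.
#' @param components Optional per-sex component parameters: a list with
#'   elements `male` and `female`, each `list(mu, sigma)` where `mu` is a
#'   k x 5 matrix of component means on the transformed scale and `sigma` a
#'   list of k positive-definite 5 x 5 covariances.  Defaults to the
#'   calibrated archetype profiles.
#' @param age_bounds Truncation bounds for age at first visit.
#' @return A `mixture_config` list.
#' @seealso [simulate_cross_section()], [write_mixture_config()]
#' @export
mixture_config <- function(n_subjects = 5000, seed = 1, separation = 1,
                           male_fraction = 0.58, weights = DEFAULT_WEIGHTS,
                           components = NULL, age_bounds = c(35, 95)) {
  if (abs(sum(weights) - 1) > 1e-12 || any(weights < 0)) {
    abort_diabclust("component weights must be non-negative and sum to 1",
                    "diabclust_config_error")
  }
  if (separation <= 0) {
    abort_diabclust("separation must be positive", "diabclust_config_error")
  }
  if (is.null(components)) {
    components <- list(male = default_sex_components("male", separation),
                       female = default_sex_components("female", separation))
  } else {
    components <- lapply(components, apply_separation, separation = separation,
                         weights = weights)
  }
  for (sex in c("male", "female")) {
    for (s in components[[sex]]$sigma) {
      if (!isSymmetric(unname(s)) || any(eigen(s, symmetric = TRUE,
                                               only.values = TRUE)$values <= 0)) {
        abort_diabclust("component covariances must be symmetric positive definite",
                        "diabclust_config_error")
      }
    }
  }
  structure(list(n_subjects = n_subjects, seed = seed, separation = separation,
                 male_fraction = male_fraction,
                 weights = setNames(as.numeric(weights), ARCHETYPES),
                 components = components, age_bounds = age_bounds),
            class = "mixture_config")
}

# scale each component mean away from the weighted mixture centre
apply_separation <- function(sexcomp, separation, weights) {
  if (separation == 1) return(sexcomp)
  centre <- colSums(sexcomp$mu * weights)
  sexcomp$mu <- sweep(sweep(sexcomp$mu, 2, centre, `-`) * separation, 2, centre, `+`)
  sexcomp
}

empty_cohort <- function() {
  tibble(subject_id = character(), cohort_id = character(), sex = character(),
         age_at_diagnosis = numeric(), age_at_first_visit = numeric(),
         bmi = numeric(), hba1c_mmol_mol = numeric(),
         c_peptide_nmol_l = numeric(), hdl_mmol_l = numeric(),
         gad_positive = logical(), diagnosis_date = as.Date(character()),
         first_visit_date = as.Date(character()))
}

#' Simulate a cross-sectional cohort
#'
#' Draws `config$n_subjects` individuals from the configured five-component
#' mixture, together with their ground-truth component labels.  Generated
#' subjects satisfy the inclusion criteria by construction (diagnosis at age
#' 35+, first visit within two years of diagnosis, GAD-negative, complete
#' clustering variables).
#'
#' @param config A [mixture_config()].
#' @param cohort_id Cohort identifier written into every record.
#' @return A list with elements `cohort` (tibble in the [cohort_schema()]
#'   layout) and `labels` (tibble `subject_id`, `component`, `archetype`).
#' @export
#' @examples
#' sim <- simulate_cross_section(mixture_config(n_subjects = 100, seed = 7), "DCS")
#' dplyr::count(sim$labels, archetype)
simulate_cross_section <- function(config, cohort_id) {
  stopifnot(inherits(config, "mixture_config"))
  n <- config$n_subjects
  if (n == 0) {
    return(list(cohort = empty_cohort(),
                labels = tibble(subject_id = character(),
                                component = integer(), archetype = character())))
  }
  with_seed(config$seed, {
    sex <- ifelse(runif(n) < config$male_fraction, "male", "female")
    comp <- sample.int(5, n, replace = TRUE, prob = config$weights)
    X <- matrix(NA_real_, n, 5, dimnames = list(NULL, TRANSFORMED_VARS))
    for (sx in c("male", "female")) {
      rows <- which(sex == sx)
      if (length(rows) == 0) next
      pars <- config$components[[sx]]
      chol_s <- lapply(pars$sigma, chol)
      for (c_idx in 1:5) {
        r <- rows[comp[rows] == c_idx]
        if (length(r) == 0) next
        draw <- function(m) {
          matrix(rnorm(m * 5), m, 5) %*% chol_s[[c_idx]] +
            matrix(pars$mu[c_idx, ], m, 5, byrow = TRUE)
        }
        Z <- draw(length(r))
        # truncate age by per-row rejection
        bad <- which(Z[, 1] < config$age_bounds[1] | Z[, 1] > config$age_bounds[2])
        guard <- 0
        while (length(bad) > 0 && guard < 1000) {
          Z[bad, ] <- draw(length(bad))
          bad <- bad[Z[bad, 1] < config$age_bounds[1] | Z[bad, 1] > config$age_bounds[2]]
          guard <- guard + 1
        }
        X[r, ] <- Z
      }
    }
    lag_years <- runif(n, 0, 1.5)
    age_fv <- X[, 1]
    age_dx <- pmax(35, age_fv - lag_years)
    lag_days <- round((age_fv - age_dx) * 365)
    diagnosis_date <- as.Date("2002-01-01") +
      sample.int(4017, n, replace = TRUE) - 1   # uniform over 2002-2012
    cohort <- tibble(
      subject_id = sprintf("%s-%05d", cohort_id, seq_len(n)),
      cohort_id = cohort_id,
      sex = sex,
      age_at_diagnosis = age_dx,
      age_at_first_visit = age_fv,
      bmi = exp(X[, 2]),
      hba1c_mmol_mol = exp(X[, 3]),
      c_peptide_nmol_l = exp(X[, 4]),
      hdl_mmol_l = exp(X[, 5]),
      gad_positive = FALSE,
      diagnosis_date = diagnosis_date,
      first_visit_date = diagnosis_date + lag_days)
    labels <- tibble(subject_id = cohort$subject_id,
                     component = comp,
                     archetype = ARCHETYPES[comp])
    list(cohort = cohort, labels = labels)
  })
}

#' Calibrate per-archetype insulin-initiation rates to one-vs-rest targets
#'
#' Solves for absolute exponential event rates such that, at infinite sample
#' size, a one-vs-rest Cox model comparing each archetype with the pooled
#' remainder estimates exactly the target hazard ratios.  Because the "rest"
#' group is a mixture whose composition shifts as higher-risk members have
#' events, the estimand depends on the absolute event level, and the five
#' targets jointly pin down both the relative rates and the overall scale.
#' The solver iterates a fixed point on the closed-form large-n Cox partial
#' score under exponential survival with administrative censoring.
#'
#' @param target_hr Named target one-vs-rest hazard ratios per archetype.
#' @param weights Archetype mixing proportions.
#' @param followup_years Follow-up horizon.
#' @param detection_margin_days Days before the censor date after which an
#'   insulin start can no longer satisfy the sustained-use criterion
#'   (default 183); events are only observable before this margin.
#' @param tol,max_iter Fixed-point convergence controls.
#' @return A list: `rates` (events per person-year, per archetype), `h0`
#'   (weight-averaged rate), `log_rel_hazard` (log rates relative to `h0`),
#'   and `estimands` (the achieved one-vs-rest hazard ratios).
#' @export
calibrate_cluster_hazards <- function(target_hr = c(SIDD = 3.40, SIRD = 0.59,
                                                    MOD = 1.17, MD = 0.81,
                                                    MDH = 0.44),
                                      weights = DEFAULT_WEIGHTS,
                                      followup_years = 10,
                                      detection_margin_days = DAYS_6_MONTHS,
                                      tol = 1e-9, max_iter = 500) {
  stopifnot(length(target_hr) == length(weights), all(target_hr > 0))
  w <- as.numeric(weights) / sum(weights)
  tau <- followup_years - detection_margin_days / 365
  grid <- seq(0, tau, length.out = 2001)
  dt <- grid[2] - grid[1]
  k <- length(w)
  estimand <- function(lam, a) {
    St <- exp(-outer(grid, lam))
    YA <- w[a] * St[, a]
    YR <- as.vector(St[, -a, drop = FALSE] %*% w[-a])
    dNA <- w[a] * lam[a] * St[, a]
    dNR <- as.vector(St[, -a, drop = FALSE] %*% (w[-a] * lam[-a]))
    score <- function(b) {
      q <- exp(b) * YA / (exp(b) * YA + YR)
      sum((1 - q) * dNA - q * dNR) * dt
    }
    uniroot(score, c(-6, 6), tol = 1e-13)$root
  }
  lam <- 0.02 * as.numeric(target_hr)
  for (it in seq_len(max_iter)) {
    est <- exp(vapply(seq_len(k), function(a) estimand(lam, a), numeric(1)))
    if (max(abs(log(est / target_hr))) < tol) break
    lam <- lam * as.numeric(target_hr) / est
  }
  h0 <- sum(w * lam)
  list(rates = setNames(lam, names(target_hr)), h0 = h0,
       log_rel_hazard = setNames(log(lam / h0), names(target_hr)),
       estimands = setNames(est, names(target_hr)), iterations = it)
}

# calibration is deterministic; cache per parameter set
.calibration_cache <- new.env(parent = emptyenv())

cached_calibration <- function(target_hr, weights, followup_years,
                               detection_margin_days) {
  key <- paste(format(c(target_hr, weights, followup_years,
                        detection_margin_days), digits = 15), collapse = ",")
  if (is.null(.calibration_cache[[key]])) {
    .calibration_cache[[key]] <- calibrate_cluster_hazards(
      target_hr, weights, followup_years, detection_margin_days)
  }
  .calibration_cache[[key]]
}

#' Configuration of the longitudinal follow-up generator
#'
#' Controls the simulated visit schedule, the treat-to-target HbA1c model,
#' the deterministic oral-medication escalation and the stochastic insulin
#' initiation.  HbA1c at a visit is
#' `floor + (baseline + drift * t - floor) * response^(classes - 1) + noise`:
#' each added oral drug class shrinks the excess over the treated floor by
#' the response factor.  A class is added (the day after a visit, up to
#' `max_oral_classes`) whenever the observed value exceeds the escalation
#' threshold.  Insulin initiation is exponential with per-archetype rates
#' `h0 * exp(log_rel_hazard)`; by default these are calibrated with
#' [calibrate_cluster_hazards()] so that one-vs-rest Cox contrasts equal
#' `target_hr`.
#'
#' @param visit_interval_days Days between HbA1c measurements (default 365).
#' @param max_followup_years Administrative censoring horizon (default 10).
#' @param hba1c_drift Per-archetype underlying HbA1c drift, mmol/mol per year.
#' @param escalation_threshold HbA1c above which treatment escalates
#'   (mmol/mol, default 58).
#' @param treated_floor Asymptotic treated HbA1c level (mmol/mol, default 48).
#' @param treatment_response Multiplier applied to the excess over the floor
#'   per added oral class (default 0.5).
#' @param max_oral_classes Maximum number of non-insulin drug classes
#'   (default 3).
#' @param measurement_sd HbA1c measurement noise, mmol/mol (default 3).
#' @param target_hr Per-archetype one-vs-rest target hazard ratios used to
#'   calibrate default insulin-initiation rates.
#' @param log_rel_hazard Optional per-archetype log hazards relative to `h0`;
#'   overrides calibration when supplied.
#' @param h0 Baseline insulin-initiation rate, events per person-year;
#'   `h0 = 0` yields a fully censored cohort.  Defaults to the calibrated
#'   weight-averaged rate.
#' @param weights Archetype proportions used in the calibration.
#' @param seed Integer seed for the follow-up substream.
#' @return A `followup_config` list.
#' @seealso [simulate_followup()]
#' @export
followup_config <- function(visit_interval_days = 365, max_followup_years = 10,
                            hba1c_drift = c(SIDD = 0.8, SIRD = 0.6, MOD = 0.8,
                                            MD = 0.6, MDH = 0.3),
                            escalation_threshold = 58, treated_floor = 48,
                            treatment_response = 0.5, max_oral_classes = 3,
                            measurement_sd = 3,
                            target_hr = c(SIDD = 3.40, SIRD = 0.59, MOD = 1.17,
                                          MD = 0.81, MDH = 0.44),
                            log_rel_hazard = NULL, h0 = NULL,
                            weights = DEFAULT_WEIGHTS, seed = 1) {
  if (max_followup_years <= 0) {
    abort_diabclust("max_followup_years must be positive", "diabclust_config_error")
  }
  if (is.null(log_rel_hazard) || is.null(h0)) {
    cal <- cached_calibration(target_hr, weights, max_followup_years,
                              DAYS_6_MONTHS)
    if (is.null(log_rel_hazard)) log_rel_hazard <- cal$log_rel_hazard
    if (is.null(h0)) h0 <- cal$h0
  }
  if (h0 < 0) abort_diabclust("h0 must be non-negative", "diabclust_config_error")
  structure(list(visit_interval_days = visit_interval_days,
                 max_followup_years = max_followup_years,
                 hba1c_drift = hba1c_drift,
                 escalation_threshold = escalation_threshold,
                 treated_floor = treated_floor,
                 treatment_response = treatment_response,
                 max_oral_classes = max_oral_classes,
                 measurement_sd = measurement_sd,
                 log_rel_hazard = setNames(as.numeric(log_rel_hazard), ARCHETYPES),
                 h0 = h0, seed = seed),
            class = "followup_config")
}

ORAL_CLASSES <- c("metformin", "sulfonylurea", "dpp4_inhibitor")

# expand (start_day, last_day) into refill intervals: chunks of
# `chunk` days with a `gap`-day break between consecutive refills
refill_intervals <- function(subject_id, drug_class, is_insulin,
                             start_day, last_day, chunk = 365, gap = 10) {
  drug_class <- rep_len(drug_class, length(start_day))
  is_insulin <- rep_len(is_insulin, length(start_day))
  keep <- start_day <= last_day
  subject_id <- subject_id[keep]; drug_class <- drug_class[keep]
  is_insulin <- is_insulin[keep]
  start_day <- start_day[keep]; last_day <- last_day[keep]
  n_chunks <- pmax(1L, ceiling((last_day - start_day + 1) / chunk))
  idx <- rep(seq_along(start_day), n_chunks)
  off <- (sequence(n_chunks) - 1L) * chunk
  s <- start_day[idx] + off
  e <- pmin(s + chunk - gap, last_day[idx])
  tibble(subject_id = subject_id[idx], drug_class = drug_class[idx],
         is_insulin = is_insulin[idx], start_day = s, end_day = e)
}

#' Simulate longitudinal follow-up for a cohort
#'
#' Generates, for every subject, an annual HbA1c measurement series, oral
#' glucose-lowering prescription intervals under the deterministic
#' escalation state machine, and (stochastically) insulin prescriptions from
#' the calibrated proportional-hazards model.  All prescriptions are emitted
#' as refill intervals with short gaps, exercising downstream episode
#' merging.  Time zero is the diagnosis date.
#'
#' @param cohort A cohort tibble.
#' @param labels Truth labels covering every subject (as produced by
#'   [simulate_cross_section()]).
#' @param config A [followup_config()].
#' @return A list of tibbles: `followup` (`subject_id`, `time_zero`,
#'   `censor_date`, plus `insulin_start_day`, the ground-truth initiation
#'   day or `NA`, for recovery testing), `prescriptions` (`subject_id`,
#'   `drug_class`, `is_insulin`, `start_date`, `end_date`) and `hba1c`
#'   (`subject_id`, `date`, `value_mmol_mol`).
#' @export
simulate_followup <- function(cohort, labels, config = followup_config()) {
  stopifnot(inherits(config, "followup_config"))
  missing_lab <- setdiff(cohort$subject_id, labels$subject_id)
  if (length(missing_lab) > 0) {
    abort_diabclust(sprintf("no truth label for subject %s", missing_lab[1]),
                    "diabclust_usage_error")
  }
  n <- nrow(cohort)
  fu_days <- round(config$max_followup_years * 365)
  lab <- labels$archetype[match(cohort$subject_id, labels$subject_id)]
  comp <- match(lab, ARCHETYPES)
  if (n == 0) {
    return(list(
      followup = tibble(subject_id = character(), time_zero = as.Date(character()),
                        censor_date = as.Date(character()),
                        insulin_start_day = numeric()),
      prescriptions = tibble(subject_id = character(), drug_class = character(),
                             is_insulin = logical(),
                             start_date = as.Date(character()),
                             end_date = as.Date(character())),
      hba1c = tibble(subject_id = character(), date = as.Date(character()),
                     value_mmol_mol = numeric())))
  }
  with_seed(config$seed, {
    rate <- config$h0 * exp(config$log_rel_hazard[comp]) / 365  # per day
    t_ins <- rep(Inf, n)
    pos <- rate > 0
    t_ins[pos] <- rexp(sum(pos), rate[pos])
    ins_start <- ifelse(t_ins < fu_days, round(t_ins), NA_real_)
    ins_start[!is.na(ins_start) & ins_start < 1] <- 1

    visits <- seq(0, fu_days, by = config$visit_interval_days)
    classes <- rep(1L, n)
    hba0 <- cohort$hba1c_mmol_mol
    drift_day <- config$hba1c_drift[comp] / 365
    meas <- vector("list", length(visits))
    class2_start <- rep(NA_real_, n)
    class3_start <- rep(NA_real_, n)
    for (i in seq_along(visits)) {
      t <- visits[i]
      val <- config$treated_floor +
        (hba0 + drift_day * t - config$treated_floor) *
          config$treatment_response^(classes - 1L) +
        rnorm(n, 0, config$measurement_sd)
      val <- pmax(val, 20)
      meas[[i]] <- val
      esc <- val > config$escalation_threshold & classes < config$max_oral_classes
      classes[esc] <- classes[esc] + 1L
      class2_start[esc & classes == 2L & is.na(class2_start)] <- t + 1
      class3_start[esc & classes == 3L & is.na(class3_start)] <- t + 1
    }

    hba1c <- tibble(
      subject_id = rep(cohort$subject_id, times = length(visits)),
      day = rep(visits, each = n),
      value_mmol_mol = round(unlist(meas, use.names = FALSE), 1))

    rx <- bind_rows(
      refill_intervals(cohort$subject_id, ORAL_CLASSES[1], FALSE,
                       rep(0, n), rep(fu_days, n)),
      refill_intervals(cohort$subject_id[!is.na(class2_start)], ORAL_CLASSES[2],
                       FALSE, class2_start[!is.na(class2_start)],
                       rep(fu_days, sum(!is.na(class2_start)))),
      refill_intervals(cohort$subject_id[!is.na(class3_start)], ORAL_CLASSES[3],
                       FALSE, class3_start[!is.na(class3_start)],
                       rep(fu_days, sum(!is.na(class3_start)))),
      refill_intervals(cohort$subject_id[!is.na(ins_start)], "insulin", TRUE,
                       ins_start[!is.na(ins_start)],
                       rep(fu_days, sum(!is.na(ins_start)))))

    time_zero <- cohort$diagnosis_date
    list(
      followup = tibble(subject_id = cohort$subject_id, time_zero = time_zero,
                        censor_date = time_zero + fu_days,
                        insulin_start_day = ins_start),
      prescriptions = rx |>
        mutate(start_date = time_zero[match(.data$subject_id, cohort$subject_id)] +
                 .data$start_day,
               end_date = time_zero[match(.data$subject_id, cohort$subject_id)] +
                 .data$end_day) |>
        select("subject_id", "drug_class", "is_insulin", "start_date", "end_date") |>
        arrange(.data$subject_id, .data$drug_class, .data$start_date),
      hba1c = hba1c |>
        mutate(date = time_zero[match(.data$subject_id, cohort$subject_id)] +
                 .data$day) |>
        select("subject_id", "date", "value_mmol_mol") |>
        arrange(.data$subject_id, .data$date))
  })
}

#' Simulate a complete multi-cohort study
#'
#' Convenience wrapper generating several cohorts (cross-section plus
#' longitudinal follow-up) from one top-level seed.  Each cohort and stage
#' draws its own seed via [derive_seed()], so regenerating follow-up never
#' perturbs the cross-section.
#'
#' @param n_per_cohort Subjects per cohort.
#' @param cohort_ids Cohort identifiers (default the three study cohorts).
#' @param seed Top-level seed.
#' @param separation Passed to [mixture_config()].
#' @param followup A [followup_config()] shared by all cohorts (its seed is
#'   re-derived per cohort); `NULL` skips follow-up generation.
#' @return A named list per cohort, each with `cohort`, `labels`, and (when
#'   requested) `followup`, `prescriptions`, `hba1c`.
#' @export
#' @examples
#' study <- simulate_study(200, c("DCS", "GoDARTS"), seed = 1)
#' nrow(study$DCS$cohort)
simulate_study <- function(n_per_cohort, cohort_ids = c("DCS", "GoDARTS", "ANDIS"),
                           seed = 1, separation = 1,
                           followup = followup_config()) {
  out <- lapply(cohort_ids, function(id) {
    cfg <- mixture_config(n_subjects = n_per_cohort,
                          seed = derive_seed(seed, "cross_section", id),
                          separation = separation)
    sim <- simulate_cross_section(cfg, id)
    if (!is.null(followup)) {
      fcfg <- followup
      fcfg$seed <- derive_seed(seed, "followup", id)
      long <- simulate_followup(sim$cohort, sim$labels, fcfg)
      sim <- c(sim, long)
    }
    sim
  })
  names(out) <- cohort_ids
  out
}

#' Serialize / read generator configurations
#'
#' Mixture and follow-up configurations round-trip through YAML so that runs
#' are fully described by plain-text files.
#'
#' @param config A [mixture_config()] or [followup_config()].
#' @param path Output path.
#' @return `path` invisibly, or the configuration object.
#' @export
write_mixture_config <- function(config, path) {
  stopifnot(inherits(config, "mixture_config"))
  ser <- unclass(config)
  ser$components <- lapply(ser$components, function(sc)
    list(mu = apply(sc$mu, 1, as.list, simplify = FALSE),
         sigma = lapply(sc$sigma, function(m) apply(m, 1, as.list, simplify = FALSE))))
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' @rdname write_mixture_config
#' @export
read_mixture_config <- function(path) {
  raw <- yaml::read_yaml(path)
  comps <- lapply(raw$components, function(sc) {
    mu <- do.call(rbind, lapply(sc$mu, unlist))
    dimnames(mu) <- list(ARCHETYPES, TRANSFORMED_VARS)
    sigma <- lapply(sc$sigma, function(m) {
      mm <- do.call(rbind, lapply(m, unlist))
      dimnames(mm) <- list(TRANSFORMED_VARS, TRANSFORMED_VARS)
      mm
    })
    names(sigma) <- ARCHETYPES
    list(mu = mu, sigma = sigma)
  })
  mixture_config(n_subjects = raw$n_subjects, seed = raw$seed,
                 separation = 1, male_fraction = raw$male_fraction,
                 weights = unlist(raw$weights), components = comps,
                 age_bounds = unlist(raw$age_bounds))
}
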