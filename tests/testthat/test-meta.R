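test_that("homogeneous studies pool to their common value with zero heterogeneity", {
  est <- tibble::tibble(log_hr = rep(log(2), 3), se = rep(0.1, 3))
  mr <- meta_random_effects(est)
  expect_equal(mr$hr, 2.0)
  expect_equal(mr$tau2, 0)
  expect_equal(mr$Q, 0)
  expect_equal(mr$se, 0.1 / sqrt(3))
})

test_that("DerSimonian-Laird pooling matches the hand-computed oracle", {
  # theta = (0, 0.5, 1), se = 0.2 each:
  #   w_i = 25, theta_FE = 0.5, Q = 25*(0.25 + 0 + 0.25) = 12.5
  #   tau2 = (12.5 - 2) / (75 - 1875/75) = 10.5 / 50 = 0.21
  #   w*_i = 1/(0.04 + 0.21) = 4, pooled = 0.5, se = 1/sqrt(12)
  est <- tibble::tibble(log_hr = c(0, 0.5, 1), se = rep(0.2, 3))
  mr <- meta_random_effects(est)
  expect_equal(mr$Q, 12.5)
  expect_equal(mr$tau2, 0.21)
  expect_equal(mr$log_hr, 0.5)
  expect_equal(mr$se, 1 / sqrt(12))
  expect_equal(mr$hr, exp(0.5))
  expect_equal(mr$ci_low, exp(0.5 - qnorm(0.975) / sqrt(12)))
  expect_equal(mr$p, 2 * pnorm(-0.5 * sqrt(12)))
})

test_that("pooling agrees with metafor's DL implementation on random inputs", {
  skip_if_not_installed("metafor")
  set.seed(123)
  for (i in 1:10) {
    m <- sample(2:6, 1)
    est <- tibble::tibble(log_hr = rnorm(m, 0, 0.8), se = runif(m, 0.05, 0.5))
    ours <- meta_random_effects(est)
    ref <- metafor::rma(yi = est$log_hr, sei = est$se, method = "DL")
    expect_equal(ours$log_hr, as.numeric(ref$beta), tolerance = 1e-10)
    expect_equal(ours$se, ref$se, tolerance = 1e-10)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-10)
    expect_equal(ours$Q, ref$QE, tolerance = 1e-10)
    expect_equal(ours$ci_low, exp(ref$ci.lb), tolerance = 1e-8)
  }
})

test_that("weight algebra: duplication halves the variance, equal weights average", {
  # near-identical estimates with unequal precision: tau2 stays 0, so
  # duplicating every study preserves the pooled value and scales the
  # variance by exactly 1/2
  est <- tibble::tibble(log_hr = c(0.30, 0.32, 0.29), se = c(0.2, 0.3, 0.25))
  once <- meta_random_effects(est)
  twice <- meta_random_effects(dplyr::bind_rows(est, est))
  expect_equal(once$tau2, 0)
  expect_equal(twice$tau2, 0)
  expect_equal(twice$log_hr, once$log_hr, tolerance = 1e-12)
  expect_equal(twice$se, once$se / sqrt(2), tolerance = 1e-12)

  # equal ses and tau2 = 0: pooled equals the arithmetic mean
  eq <- tibble::tibble(log_hr = c(0.30, 0.31, 0.29), se = rep(0.5, 3))
  mr <- meta_random_effects(eq)
  expect_equal(mr$tau2, 0)
  expect_equal(mr$log_hr, mean(eq$log_hr))

  # tau2 = 0 implies exact agreement with fixed-effect inverse variance
  w <- 1 / eq$se^2
  fe <- sum(w * eq$log_hr) / sum(w)
  expect_lt(abs(mr$log_hr - fe), 1e-12)
  expect_lt(abs(mr$se - 1 / sqrt(sum(w))), 1e-12)
})

test_that("a single estimate errors unless explicitly passed through", {
  one <- tibble::tibble(log_hr = 0.5, se = 0.2)
  expect_error(meta_random_effects(one), class = "diabclust_usage_error")
  mr <- meta_random_effects(one, allow_single = TRUE)
  expect_equal(mr$hr, exp(0.5))
  expect_equal(mr$tau2, 0)
})

test_that("one-vs-rest Cox is unbiased under the null and recovers a true hazard ratio", {
  null_ok <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    n <- 2000
    grp <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.2, 0.8))
    t <- rexp(n, 0.1); cens <- t > 8
    ep <- tibble::tibble(subject_id = as.character(1:n),
                         time_days = pmin(t, 8), event = !cens)
    lab <- tibble::tibble(subject_id = as.character(1:n),
                          archetype = ifelse(grp, "SIDD", "MD"))
    est <- cox_one_vs_rest(ep, lab, "SIDD")
    abs(est$log_hr) < 2 * est$se
  }, logical(1))
  expect_gte(sum(null_ok), 18)

  cover <- vapply(1:20, function(s) {
    set.seed(3000 + s)
    n <- 4000
    grp <- sample(c(TRUE, FALSE), n, TRUE, prob = c(0.15, 0.85))
    rate <- ifelse(grp, 0.05 * 3.4, 0.05)
    t <- rexp(n, rate); cens <- t > 10
    ep <- tibble::tibble(subject_id = as.character(1:n),
                         time_days = pmin(t, 10), event = !cens)
    lab <- tibble::tibble(subject_id = as.character(1:n),
                          archetype = ifelse(grp, "SIDD", "MD"))
    est <- cox_one_vs_rest(ep, lab, "SIDD")
    ci <- est$log_hr + c(-1, 1) * qnorm(0.975) * est$se
    ci[1] <= log(3.4) && log(3.4) <= ci[2]
  }, logical(1))
  expect_gte(sum(cover), 18)
})

test_that("an all-censored group is flagged inestimable", {
  ep <- tibble::tibble(subject_id = as.character(1:100),
                       time_days = rep(1000, 100), event = FALSE)
  lab <- tibble::tibble(subject_id = as.character(1:100),
                        archetype = rep(c("SIDD", "MD"), 50))
  expect_error(cox_one_vs_rest(ep, lab, "SIDD"),
               class = "diabclust_inestimable")
})

test_that("the pooled survival table reports every archetype and marks inestimable rows", {
  set.seed(77)
  mk <- function(cohort) {
    n <- 900
    arch <- sample(c("SIDD", "SIRD", "MOD", "MD", "MDH"), n, TRUE)
    rate <- 0.06 * c(SIDD = 3, SIRD = 0.6, MOD = 1.2, MD = 0.8, MDH = 0.45)[arch]
    t <- rexp(n, rate)
    list(ep = tibble::tibble(cohort_id = cohort,
                             subject_id = paste0(cohort, 1:n),
                             time_days = pmin(t, 10), event = t <= 10),
         lab = tibble::tibble(cohort_id = cohort,
                              subject_id = paste0(cohort, 1:n),
                              archetype = arch))
  }
  parts <- lapply(c("A", "B", "C"), mk)
  ep <- dplyr::bind_rows(lapply(parts, `[[`, "ep"))
  lab <- dplyr::bind_rows(lapply(parts, `[[`, "lab"))
  tab <- survival_table(ep, lab)
  expect_equal(tab$archetype, c("SIDD", "SIRD", "MOD", "MD", "MDH"))
  expect_equal(tab$n_cohorts, rep(3L, 5))
  expect_true(all(tab$ci_low < tab$hr & tab$hr < tab$ci_high))
  expect_gt(tab$hr[tab$archetype == "SIDD"], 1)
  ests <- attr(tab, "estimates")
  expect_equal(nrow(ests), 15)

  # drop one archetype from the labels: its row is inestimable
  lab2 <- dplyr::filter(lab, archetype != "MDH")
  ep2 <- dplyr::semi_join(ep, lab2, by = c("cohort_id", "subject_id"))
  tab2 <- survival_table(ep2, lab2)
  expect_true(is.na(tab2$hr[tab2$archetype == "MDH"]))
  expect_equal(tab2$n_cohorts[tab2$archetype == "MDH"], 0L)
  expect_false(anyNA(tab2$hr[tab2$archetype != "MDH"]))

  expect_s3_class(ggplot2::autoplot(tab), "ggplot")
  prefix <- file.path(withr::local_tempdir(), "meta")
  write_survival_table(tab, prefix)
  expect_true(file.exists(paste0(prefix, ".csv")))
  expect_true(file.exists(paste0(prefix, "_estimates.csv")))
})
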