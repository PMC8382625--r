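#' One-vs-rest Cox model for a single archetype in one cohort
#'
#' Fits a Cox proportional-hazards model of the composite insulin-requirement
#' endpoint on a single binary covariate — membership of the target
#' archetype versus all other clusters pooled as reference — with Efron tie
#' handling and no further covariates.
#'
#' @param endpoints Endpoint tibble from [time_to_insulin_requirement()].
#' @param labels Tibble `subject_id`, `archetype`.
#' @param target The archetype tested against the rest.
#' @param cohort_id Optional cohort identifier carried into the output.
#' @return A one-row tibble: `cohort_id`, `archetype`, `log_hr`, `se`, `n`,
#'   `n_events`.
#' @export
cox_one_vs_rest <- function(endpoints, labels, target, cohort_id = NA_character_) {
  assert_cols(endpoints, c("subject_id", "time_days", "event"), "endpoints")
  assert_cols(labels, c("subject_id", "archetype"), "labels")
  dat <- inner_join(endpoints, select(labels, "subject_id", "archetype"),
                    by = "subject_id")
  if (nrow(dat) == 0) {
    abort_diabclust("no subjects shared between endpoints and labels",
                    "diabclust_usage_error")
  }
  dat$in_target <- dat$archetype == target
  ev <- tapply(dat$event, dat$in_target, sum)
  if (length(ev) < 2 || any(ev == 0)) {
    abort_diabclust(sprintf(
      "hazard ratio for %s is inestimable: a group has no events", target),
      "diabclust_inestimable")
  }
  fit <- survival::coxph(survival::Surv(time_days, event) ~ in_target,
                         data = dat, ties = "efron")
  tibble(cohort_id = cohort_id, archetype = target,
         log_hr = unname(coef(fit)[1]), se = sqrt(vcov(fit)[1, 1]),
         n = nrow(dat), n_events = sum(dat$event))
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Pools per-cohort log hazard ratios by inverse-variance random-effects
#' meta-analysis with the DerSimonian-Laird between-study variance:
#' with fixed-effect weights `w_i = 1/se_i^2` and pooled fixed effect
#' `theta_FE`, the heterogeneity statistic is
#' `Q = sum w_i (theta_i - theta_FE)^2` and
#' `tau^2 = max(0, (Q - (m - 1)) / (sum w_i - sum w_i^2 / sum w_i))`.
#' Random-effects weights are `1 / (se_i^2 + tau^2)`; the pooled estimate,
#' its standard error, the Wald confidence interval and the two-sided
#' p-value are computed on the log scale and exponentiated for reporting.
#' No small-sample (Knapp-Hartung) adjustment is applied by default.
#'
#' @param estimates Tibble with columns `log_hr` and `se` (one row per
#'   cohort), e.g. from [cox_one_vs_rest()].
#' @param level Confidence level (default 0.95).
#' @param allow_single Pass a single estimate through (tau^2 = 0) instead of
#'   erroring.
#' @return A `meta_result`: per-study table, `Q`, `tau2`, pooled `log_hr`
#'   and `se`, `hr`, `ci_low`, `ci_high`, `p`, `m`.
#' @export
#' @examples
#' est <- tibble::tibble(log_hr = c(0, 0.5, 1), se = rep(0.2, 3))
#' meta_random_effects(est)
meta_random_effects <- function(estimates, level = 0.95, allow_single = FALSE) {
  assert_cols(estimates, c("log_hr", "se"), "estimates")
  m <- nrow(estimates)
  if (m < 2 && !allow_single) {
    abort_diabclust("need at least 2 estimates to meta-analyse (set allow_single = TRUE to pass one through)",
                    "diabclust_usage_error")
  }
  if (any(estimates$se <= 0)) {
    abort_diabclust("standard errors must be positive", "diabclust_invariant_error")
  }
  th <- estimates$log_hr
  w <- 1 / estimates$se^2
  theta_fe <- sum(w * th) / sum(w)
  Q <- sum(w * (th - theta_fe)^2)
  tau2 <- if (m > 1) max(0, (Q - (m - 1)) / (sum(w) - sum(w^2) / sum(w))) else 0
  w_re <- 1 / (estimates$se^2 + tau2)
  theta <- sum(w_re * th) / sum(w_re)
  se <- sqrt(1 / sum(w_re))
  z <- qnorm(1 - (1 - level) / 2)
  structure(list(studies = as_tibble(estimates), Q = Q, tau2 = tau2,
                 log_hr = theta, se = se, hr = exp(theta),
                 ci_low = exp(theta - z * se), ci_high = exp(theta + z * se),
                 p = 2 * pnorm(-abs(theta / se)), m = m, level = level),
            class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects meta-analysis of %d studies\n", x$m))
  cat(sprintf("  pooled HR %.3f (%.0f%% CI %.3f, %.3f), p = %.3g\n",
              x$hr, 100 * x$level, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  Q = %.3f, tau^2 = %.4f\n", x$Q, x$tau2))
  invisible(x)
}

#' @export
tidy.meta_result <- function(x, ...) x$studies

#' @export
glance.meta_result <- function(x, ...) {
  tibble(hr = x$hr, ci_low = x$ci_low, ci_high = x$ci_high, p = x$p,
         log_hr = x$log_hr, se = x$se, tau2 = x$tau2, q = x$Q, m = x$m)
}

#' Pooled hazard-ratio table across cohorts and archetypes
#'
#' For every archetype, fits the one-vs-rest Cox model in each cohort and
#' pools the log hazard ratios by DerSimonian-Laird random-effects
#' meta-analysis, producing the familiar per-cluster HR (95% CI) / p-value
#' report.  An archetype whose hazard is inestimable in a cohort (no events
#' in a group) simply loses that cohort; with fewer than two estimable
#' cohorts the row is marked inestimable (`NA` estimates).
#'
#' @param endpoints Endpoint tibble with a `cohort_id` column (rows from all
#'   cohorts).
#' @param labels Label tibble `cohort_id`, `subject_id`, `archetype`.
#' @param archetypes Archetypes to report (default the five).
#' @param level Confidence level.
#' @return A `meta_table` tibble: `archetype`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `tau2`, `q`, `n_cohorts`; per-cohort estimates in
#'   `attr(, "estimates")`.
#' @export
survival_table <- function(endpoints, labels, archetypes = ARCHETYPES,
                           level = 0.95) {
  assert_cols(endpoints, c("cohort_id", "subject_id", "time_days", "event"),
              "endpoints")
  assert_cols(labels, c("cohort_id", "subject_id", "archetype"), "labels")
  cohorts <- unique(endpoints$cohort_id)
  ests <- purrr::map_dfr(archetypes, function(a) {
    purrr::map_dfr(cohorts, function(co) {
      ep <- filter(endpoints, .data$cohort_id == co)
      lb <- filter(labels, .data$cohort_id == co)
      tryCatch(cox_one_vs_rest(ep, lb, a, cohort_id = co),
               diabclust_inestimable = function(e) tibble())
    })
  })
  rows <- purrr::map_dfr(archetypes, function(a) {
    s <- filter(ests, .data$archetype == a)
    if (nrow(s) < 2) {
      return(tibble(archetype = a, hr = NA_real_, ci_low = NA_real_,
                    ci_high = NA_real_, p = NA_real_, tau2 = NA_real_,
                    q = NA_real_, n_cohorts = nrow(s)))
    }
    mr <- meta_random_effects(s, level = level)
    tibble(archetype = a, hr = mr$hr, ci_low = mr$ci_low, ci_high = mr$ci_high,
           p = mr$p, tau2 = mr$tau2, q = mr$Q, n_cohorts = mr$m)
  })
  structure(rows, class = c("meta_table", class(rows)), estimates = ests,
            level = level)
}

#' Forest-style plot of a pooled hazard-ratio table
#'
#' @param object A `meta_table` from [survival_table()].
#' @param ... Unused.
#' @return A ggplot (log-scaled HR axis, reference line at 1).
#' @export
autoplot.meta_table <- function(object, ...) {
  dat <- filter(as_tibble(object), !is.na(.data$hr))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$hr,
                                    y = factor(.data$archetype,
                                               levels = rev(ARCHETYPES)))) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "hazard ratio (one cluster vs rest)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Write a pooled hazard-ratio table and its per-cohort estimates
#'
#' @param x A `meta_table`.
#' @param path_prefix Writes `<prefix>.csv` (pooled) and
#'   `<prefix>_estimates.csv` (per-cohort log hazard ratios).
#' @return `path_prefix`, invisibly.
#' @export
write_survival_table <- function(x, path_prefix) {
  stopifnot(inherits(x, "meta_table"))
  readr::write_csv(as_tibble(x), paste0(path_prefix, ".csv"), progress = FALSE)
  readr::write_csv(attr(x, "estimates"), paste0(path_prefix, "_estimates.csv"),
                   progress = FALSE)
  invisible(path_prefix)
}
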