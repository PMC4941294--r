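#' Median dichotomization of a continuous marker
#'
#' Splits samples into `high` (strictly above the median) and `low`
#' (at or below it — ties go low), the package's grouping convention for
#' survival comparisons of a marker lncRNA.
#'
#' @param data A data frame with an `expression` column (or a numeric
#'   vector).
#' @return The input tibble with a `group` column added.
#' @export
median_dichotomize <- function(data) {
  if (!is.data.frame(data)) data <- tibble(expression = data)
  x <- data$expression
  if (length(x) < 4) abort("need at least 4 samples to dichotomize")
  if (length(unique(x)) == 1) {
    abort("all expression values identical: no median split possible")
  }
  mutate(as_tibble(data),
         group = ifelse(x > median(x), "high", "low"))
}

#' Kaplan-Meier product-limit estimator
#'
#' One survival curve per group (via `survival::survfit`), returned as a
#' tidy step-function table.
#'
#' @param cohort A data frame with `time`, `event` and optionally `group`.
#' @return A tibble with class `lnc_km`: `group`, `time`, `n_risk`,
#'   `n_event`, `n_censor`, `surv` (plus `S(0) = 1` anchor rows).
#' @export
kaplan_meier <- function(cohort) {
  if (nrow(cohort) < 1) abort("empty cohort")
  if (any(cohort$time < 0)) abort("negative survival times")
  if (!"group" %in% names(cohort)) cohort$group <- "all"
  fit <- survival::survfit(
    survival::Surv(time, event) ~ group,
    data = cohort
  )
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(unique(cohort$group), length(s$time)) else
    sub("^group=", "", as.character(s$strata))
  steps <- tibble(
    group = grp, time = s$time, n_risk = s$n.risk,
    n_event = s$n.event, n_censor = s$n.censor, surv = s$surv
  )
  anchor <- steps %>% distinct(.data$group) %>%
    mutate(time = 0, n_risk = NA_real_, n_event = 0, n_censor = 0, surv = 1)
  out <- bind_rows(anchor, steps) %>% arrange(.data$group, .data$time)
  class(out) <- c("lnc_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Observed-minus-expected statistic with hypergeometric variance summed
#' over event times (via `survival::survdiff`), chi-square with 1 df.
#'
#' @param cohort A data frame with `time`, `event`, `group` (two groups).
#' @return A one-row tibble: `chi_square`, `p`.
#' @export
logrank_test <- function(cohort) {
  if (length(unique(cohort$group)) != 2) abort("need exactly two groups")
  if (sum(cohort$event) == 0) abort("no events: log-rank test undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = cohort)
  tibble(chi_square = unname(sd$chisq),
         p = pchisq(unname(sd$chisq), df = 1, lower.tail = FALSE))
}

#' Univariate Cox proportional-hazards fit on a dichotomized marker
#'
#' Fits the partial likelihood for the high-vs-low group indicator
#' (Breslow tie handling by default, Efron available) and reports the
#' hazard ratio with a 95% Wald interval. Monotone-likelihood /
#' separation problems surface as `converged = FALSE` with a warning.
#'
#' @param cohort A data frame with `time`, `event`, `group`
#'   (`"high"`/`"low"`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param max_iter,tol Newton-Raphson controls.
#' @return An object of class `lnc_cox` wrapping the fit; see
#'   [tidy.lnc_cox()] / [glance.lnc_cox()].
#' @export
cox_univariate <- function(cohort, ties = c("breslow", "efron"),
                           max_iter = 50, tol = 1e-9) {
  ties <- match.arg(ties)
  if (!all(c("time", "event", "group") %in% names(cohort))) {
    abort("cohort needs time, event, group columns")
  }
  cohort <- mutate(cohort, .g = as.integer(.data$group == "high"))
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ .g, data = cohort,
                    ties = ties,
                    control = survival::coxph.control(iter.max = max_iter,
                                                      eps = tol)),
    warning = function(w) {
      if (grepl("(coefficient may be infinite|did not converge|beta may be infinite)",
                conditionMessage(w))) {
        warn(paste0("possible monotone likelihood / separation: ",
                    conditionMessage(w)))
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit))
  se <- sqrt(unname(stats::vcov(fit)[1, 1]))
  sm <- summary(fit)
  converged <- fit$iter < max_iter && is.finite(beta) && se < 1e3
  structure(
    list(
      fit = fit,
      beta = beta, se = se, hr = exp(beta),
      ci_low = exp(beta - qnorm(0.975) * se),
      ci_high = exp(beta + qnorm(0.975) * se),
      p = unname(sm$coefficients[1, "Pr(>|z|)"]),
      n = nrow(cohort), n_events = sum(cohort$event),
      converged = converged, iterations = fit$iter, ties = ties
    ),
    class = "lnc_cox"
  )
}

#' @export
print.lnc_cox <- function(x, ...) {
  cat(sprintf(
    "<lnc_cox> HR = %.3f (95%% CI %.3f-%.3f), p = %.4g, %d events / %d samples%s\n",
    x$hr, x$ci_low, x$ci_high, x$p, x$n_events, x$n,
    if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}

#' Tidy a univariate Cox fit
#'
#' @param x An `lnc_cox` object.
#' @param ... Unused.
#' @return One row per term with estimate (log HR), standard error,
#'   statistic, p-value and the HR-scale confidence interval.
#' @export
tidy.lnc_cox <- function(x, ...) {
  tibble(term = "group_high", estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$p,
         hr = x$hr, conf.low = x$ci_low, conf.high = x$ci_high)
}

#' @rdname tidy.lnc_cox
#' @return `glance()`: one-row model summary (n, events, convergence).
#' @export
glance.lnc_cox <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, hr = x$hr, p.value = x$p,
         converged = x$converged, iterations = x$iterations, ties = x$ties)
}

#' Full survival characterization of a marker
#'
#' Median-dichotomizes marker expression (when no `group` column is
#' present), then computes the Kaplan-Meier curves, log-rank test and
#' univariate Cox fit.
#'
#' @param cohort A data frame with `time`, `event` and `expression` (or a
#'   precomputed `group`).
#' @inheritParams cox_univariate
#' @return A list: `cohort` (with groups), `km`, `logrank`, `cox`.
#' @export
survival_analysis <- function(cohort, ties = "breslow") {
  if (!"group" %in% names(cohort)) cohort <- median_dichotomize(cohort)
  list(
    cohort = cohort,
    km = kaplan_meier(cohort),
    logrank = logrank_test(cohort),
    cox = cox_univariate(cohort, ties = ties)
  )
}
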