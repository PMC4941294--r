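#' Simulate a survival cohort with a planted hazard on one lncRNA
#'
#' Generates per-sample marker expression (log2 scale), splits the cohort
#' at the median into high/low groups, and draws event times from an
#' exponential model with hazard `h0 * exp(beta * g)` where `g` is the
#' high-group indicator and `beta = config$surv_true_loghr`. The baseline
#' hazard `h0` is set so the low group's median survival equals
#' `config$surv_baseline_median` months. Independent uniform censoring is
#' calibrated to achieve approximately `config$censor_rate`.
#'
#' @param config A [sim_config()] object.
#' @param expression Optional per-sample marker expression; defaults to
#'   `Normal(7, 1)` draws of size `config$surv_n`.
#' @return A tibble with `sample_id`, `time` (months), `event` (0/1),
#'   `expression`, `group`.
#' @export
simulate_survival <- function(config, expression = NULL) {
  cfg <- validate_sim_config(config)
  set.seed(stage_seed(cfg, "survival"))
  expression <- expression %||% rnorm(cfg$surv_n, mean = 7, sd = 1)
  n <- length(expression)
  if (n < 4) abort("need at least 4 samples to median-split the cohort")

  group <- median_dichotomize(tibble(expression = expression))$group
  g <- as.integer(group == "high")
  h0 <- log(2) / cfg$surv_baseline_median
  rate <- h0 * exp(cfg$surv_true_loghr * g)
  t_event <- rexp(n, rate = rate)

  if (cfg$censor_rate > 0) {
    # P(C < T) for C ~ Unif(0, u), T ~ Exp(lambda) is
    # (1 - exp(-lambda u)) / (lambda u); average over the two group
    # hazards and solve for u numerically.
    p_cens <- function(u) {
      mean((1 - exp(-rate * u)) / (rate * u))
    }
    u <- stats::uniroot(function(u) p_cens(u) - cfg$censor_rate,
                        lower = 1e-6, upper = 1e6, tol = 1e-8)$root
    t_cens <- runif(n, 0, u)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }
  tibble(
    sample_id = sprintf("SURV%03d", seq_len(n)),
    time = pmax(time, .Machine$double.eps),
    event = event,
    expression = expression,
    group = group
  )
}
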