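#' Relative qPCR fold change (delta-delta-Ct)
#'
#' `ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,ctrl -
#' Ct_ref,ctrl)`; fold change reported as `2^-ddCt`.
#'
#' @param ct_target_case,ct_ref_case Target / reference-gene Ct in the
#'   case sample.
#' @param ct_target_ctrl,ct_ref_ctrl Target / reference-gene Ct in the
#'   control sample.
#' @return Fold change (case vs control).
#' @export
ddct_fold_change <- function(ct_target_case, ct_ref_case,
                             ct_target_ctrl, ct_ref_ctrl) {
  cts <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (!all(is.finite(cts))) abort("Ct values must be finite")
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Xenograft tumor volume
#'
#' Ellipsoid approximation from caliper measurements:
#' `length x width^2 x 0.5` (mm^3).
#'
#' @param length_mm,width_mm Caliper measurements in mm (nonnegative).
#' @return Volume in mm^3.
#' @export
xenograft_volume <- function(length_mm, width_mm) {
  if (any(c(length_mm, width_mm) < 0)) abort("measurements must be nonnegative")
  length_mm * width_mm^2 * 0.5
}

#' Two-or-more group comparison
#'
#' Two groups are compared with Welch's t-test (see [welch_t_test()]);
#' three or more with classical one-way ANOVA (equal-variance F).
#'
#' @param values Numeric vector.
#' @param groups Grouping vector of the same length; every group needs at
#'   least 2 values.
#' @return A one-row tibble: `method`, `statistic`, `p`.
#' @export
group_comparison <- function(values, groups) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  counts <- table(groups)
  if (length(counts) < 2) abort("need at least 2 groups")
  if (any(counts < 2)) {
    abort(paste0("singleton group(s): ",
                 paste(names(counts)[counts < 2], collapse = ", ")))
  }
  if (length(counts) == 2) {
    nm <- names(counts)
    res <- welch_t_test(values[groups == nm[1]], values[groups == nm[2]])
    return(tibble(method = "welch_t", statistic = res$t, p = res$p))
  }
  if (var(values) == 0) {
    return(tibble(method = "anova_f", statistic = 0, p = 1))
  }
  ft <- oneway.test(values ~ factor(groups), var.equal = TRUE)
  tibble(method = "anova_f", statistic = unname(ft$statistic),
         p = unname(ft$p.value))
}
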