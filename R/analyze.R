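# Group-level scoring. The default method standardizes each group's observed
# metric against the study-wide pooled estimate using a normal approximation
# whose variance is inflated by the estimated overdispersion factor phi:
#
#   z'_i = (y_i - theta0) / sqrt(phi* V(Y | theta0))
#
# with V = p(1-p)/n_i for percentages and lambda/T_i for rates, and
# phi = mean(z_i^2) over the unadjusted z-scores. phi is clamped below at 1:
# the adjustment may widen, but never shrink, the variance (flagging more
# aggressively under apparent under-dispersion would be anti-conservative);
# the raw value is always reported alongside.

new_kri_analysis <- function(metric_id, method, metric_type, overall_estimate,
                             groups, m, phi_raw = NA_real_,
                             phi_used = NA_real_) {
  structure(
    list(metric_id = metric_id, method = method, metric_type = metric_type,
         overall_estimate = overall_estimate, phi_raw = phi_raw,
         phi_used = phi_used, m = m, groups = groups),
    class = "kri_analysis"
  )
}

#' @export
print.kri_analysis <- function(x, ...) {
  cat(sprintf("<kri_analysis: %s via %s; m = %d; overall = %.6g",
              x$metric_id %|NA|% "?", x$method, x$m, x$overall_estimate))
  if (x$method == "normal_approx") {
    cat(sprintf("; phi = %.4g (raw %.4g)", x$phi_used, x$phi_raw))
  }
  cat(">\n")
  print(x$groups, ...)
  invisible(x)
}

split_evaluable <- function(groups) {
  ok <- !is.na(groups$observed_metric) & groups$total_denominator > 0
  list(eval = groups[ok, , drop = FALSE], ne = groups[!ok, , drop = FALSE])
}

result_groups <- function(groups, score, p_value, direction, status) {
  tibble(
    group_id = groups$group_id,
    n = groups$n_participants,
    numerator = groups$total_numerator,
    denominator = groups$total_denominator,
    observed_metric = groups$observed_metric,
    score = score, p_value = p_value, direction = direction, status = status
  )
}

ne_rows <- function(ne) {
  if (nrow(ne) == 0) return(NULL)
  result_groups(ne, NA_real_, NA_real_, NA_real_, "not_evaluable")
}

#' Overdispersion factor from unadjusted z-scores
#'
#' The overdispersion factor is the average of the squared unadjusted
#' z-scores; the clamped value `max(phi, 1)` is what the adjusted scores
#' divide by, so the adjustment can widen but never shrink the variance.
#'
#' @param z Numeric vector of unadjusted z-scores (one per evaluable group).
#' @return A list with `phi_raw` and `phi_clamped`.
#' @export
#' @examples
#' overdispersion_phi(c(1, -1, 1))
overdispersion_phi <- function(z) {
  phi_raw <- mean(z^2)
  list(phi_raw = phi_raw, phi_clamped = max(phi_raw, 1))
}

#' Score groups with the overdispersion-adjusted normal approximation
#'
#' The default KRI analysis. Pools all evaluable groups into the study-wide
#' estimate (observed overall proportion for percentages; total events over
#' total exposure for rates), computes per-group unadjusted z-scores under
#' the binomial/Poisson variance, estimates the overdispersion factor as the
#' mean squared unadjusted z-score, and rescales: the reported score is
#' `z'_i = z_i / sqrt(max(phi, 1))`. Requires more than two evaluable
#' groups; groups with no denominator are reported as not evaluable and take
#' no part in the pooling or in phi.
#'
#' @param groups Group summaries from [aggregate_groups()].
#' @param metric_type `"rate"` or `"percentage"`.
#' @param metric_id Optional metric id carried into the result.
#' @return A `kri_analysis` object; see [tidy.kri_analysis()].
#' @export
analyze_normal_approx <- function(groups, metric_type = c("rate", "percentage"),
                                  metric_id = NA_character_) {
  metric_type <- match.arg(metric_type)
  parts <- split_evaluable(groups)
  g <- parts$eval
  m <- nrow(g)
  if (m <= 2) {
    stop_method("normal approximation requires m > 2 evaluable groups (got %d)", m)
  }
  theta0 <- sum(g$total_numerator) / sum(g$total_denominator)
  if (metric_type == "percentage" && (theta0 <= 0 || theta0 >= 1)) {
    stop_degenerate(
      "pooled proportion is %g; normal approximation is degenerate, consider the exact method",
      theta0)
  }
  if (metric_type == "rate" && theta0 <= 0) {
    stop_degenerate("pooled rate is 0; no events to analyze")
  }
  v <- if (metric_type == "percentage") {
    theta0 * (1 - theta0) / g$total_denominator
  } else {
    theta0 / g$total_denominator
  }
  z <- (g$observed_metric - theta0) / sqrt(v)
  phi <- overdispersion_phi(z)
  zadj <- (g$observed_metric - theta0) / sqrt(phi$phi_clamped * v)
  direction <- sign(g$observed_metric - theta0)
  rows <- bind_rows(
    result_groups(g, zadj, 2 * pnorm(-abs(zadj)), direction, "evaluable"),
    ne_rows(parts$ne)
  )
  new_kri_analysis(metric_id, "normal_approx", metric_type, theta0, rows, m,
                   phi_raw = phi$phi_raw, phi_used = phi$phi_clamped)
}

# Two-sided Fisher exact p for one 2x2 table by direct hypergeometric
# enumeration: sum the probabilities of all tables (same margins) no more
# probable than the observed one. Log-space choose() keeps this exact to
# double precision; the standard (1 + 1e-7) relative tie tolerance guards
# against representation noise in genuine ties.
fisher_p_two_sided <- function(a, n_site, k_total, n_total) {
  lo <- max(0L, n_site - (n_total - k_total))
  hi <- min(n_site, k_total)
  support <- lo:hi
  lp <- lchoose(k_total, support) + lchoose(n_total - k_total, n_site - support) -
    lchoose(n_total, n_site)
  lp_obs <- lp[support == a]
  sum(exp(lp[lp <= lp_obs + log(1 + 1e-7)]))
}

#' Score groups with Fisher's exact test (percentages)
#'
#' For each group, forms the 2x2 table of events/non-events in the group
#' versus all other groups pooled, and computes the two-sided exact p-value
#' by hypergeometric enumeration (summing the probabilities of all tables no
#' more probable than the observed one). The reported score is
#' `-log10(p)` signed by the group's direction relative to the pooled
#' proportion, so all methods emit one orderable score column; flagging for
#' this method uses the p-value and direction directly.
#'
#' @inheritParams analyze_normal_approx
#' @param metric_type Must be `"percentage"`.
#' @return A `kri_analysis` object with per-group `p_value`s.
#' @export
analyze_fisher <- function(groups, metric_type = "percentage",
                           metric_id = NA_character_) {
  if (!identical(metric_type, "percentage")) {
    stop_method("Fisher's exact test applies to percentage metrics only")
  }
  parts <- split_evaluable(groups)
  g <- parts$eval
  if (nrow(g) < 2) stop_method("Fisher's exact test requires at least 2 groups")
  k_total <- sum(g$total_numerator)
  n_total <- sum(g$total_denominator)
  theta0 <- k_total / n_total
  pvals <- vapply(seq_len(nrow(g)), function(i) {
    if (k_total == 0 || k_total == n_total) return(1)
    fisher_p_two_sided(g$total_numerator[i], g$total_denominator[i],
                       k_total, n_total)
  }, numeric(1))
  direction <- sign(g$observed_metric - theta0)
  score <- -log10(pmax(pvals, .Machine$double.xmin)) * direction
  rows <- bind_rows(
    result_groups(g, score, pvals, direction, "evaluable"),
    ne_rows(parts$ne)
  )
  new_kri_analysis(metric_id, "fisher", "percentage", theta0, rows, nrow(g))
}

#' Score groups with Poisson regression (rates)
#'
#' Fits an intercept-only Poisson model of group event counts with a
#' log-exposure offset (so the fitted mean for group *i* is the pooled rate
#' times its exposure) and reports the deviance residual of each group as
#' its score. The deviance residual has the closed form
#' `sign(O - E) * sqrt(2 * (O * log(O/E) - (O - E)))`, with the `O log(O/E)`
#' term zero when `O = 0`; it approaches the normal-approximation z-score as
#' counts grow.
#'
#' @inheritParams analyze_normal_approx
#' @param metric_type Must be `"rate"`.
#' @return A `kri_analysis` object.
#' @export
analyze_poisson <- function(groups, metric_type = "rate",
                            metric_id = NA_character_) {
  if (!identical(metric_type, "rate")) {
    stop_method("Poisson regression applies to rate metrics only")
  }
  parts <- split_evaluable(groups)
  g <- parts$eval
  if (nrow(g) < 1) stop_method("no evaluable groups")
  if (sum(g$total_numerator) == 0) {
    stop_degenerate("zero events in every group; Poisson fit is degenerate")
  }
  fit <- glm(g$total_numerator ~ 1 + offset(log(g$total_denominator)),
             family = poisson())
  dres <- unname(residuals(fit, type = "deviance"))
  theta0 <- unname(exp(coef(fit)[1]))
  direction <- sign(g$observed_metric - theta0)
  rows <- bind_rows(
    result_groups(g, dres, 2 * pnorm(-abs(dres)), direction, "evaluable"),
    ne_rows(parts$ne)
  )
  new_kri_analysis(metric_id, "poisson", "rate", theta0, rows, nrow(g))
}

analyze_with_method <- function(groups, method, metric_type, metric_id) {
  switch(method,
    normal_approx = analyze_normal_approx(groups, metric_type, metric_id),
    fisher = analyze_fisher(groups, metric_type, metric_id),
    poisson = analyze_poisson(groups, metric_type, metric_id),
    stop_config("unknown analysis method '%s'", method)
  )
}

#' @describeIn analyze_normal_approx Tidy per-group results: one row per
#'   group with identifiers, counts, observed metric, score, p-value,
#'   direction and status.
#' @param x A `kri_analysis` object.
#' @param ... Unused.
#' @export
tidy.kri_analysis <- function(x, ...) {
  mutate(x$groups, metric_id = x$metric_id, method = x$method,
         overall_estimate = x$overall_estimate, .before = 1)
}

#' @describeIn analyze_normal_approx One-row model-level summary: method,
#'   number of evaluable groups, pooled estimate, and the raw and clamped
#'   overdispersion factors.
#' @export
glance.kri_analysis <- function(x, ...) {
  tibble(metric_id = x$metric_id, method = x$method,
         metric_type = x$metric_type, m = x$m,
         overall_estimate = x$overall_estimate,
         phi_raw = x$phi_raw, phi_used = x$phi_used)
}
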