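# Directional red/amber/green flagging. One signed integer per group and
# metric captures both severity and direction: sign = side of the study-wide
# value, magnitude 2 = red, 1 = amber, 0 = green. Boundaries are inclusive
# on the more-extreme side (|score| equal to a threshold flags at that
# level), a deterministic, documented tie rule.

#' Flagging thresholds for one analysis method
#'
#' Score-based methods (normal approximation, Poisson) flag on the magnitude
#' of the score: amber at `|score| >= amber`, red at `|score| >= red`, with
#' `red > amber > 0`. Fisher flags on the p-value: red at `p <= red`, amber
#' at `red < p <= amber`, with `red < amber` (smaller p = stronger signal).
#' Defaults mirror conventional 2-sigma/3-sigma monitoring practice (amber 2,
#' red 3 on z-type scores; amber 0.05, red 0.01 on p-values); thresholds are
#' ultimately user-specified.
#'
#' @param amber,red Positive threshold magnitudes.
#' @param applied_to `"score"` or `"p_value"`.
#' @param metric_id,method Optional identifiers; when `method` is set,
#'   [assign_flags()] refuses a result from a different method.
#' @return A `threshold_spec` object.
#' @export
#' @examples
#' threshold_spec(amber = 2, red = 3)
#' default_thresholds("fisher")
threshold_spec <- function(amber, red, applied_to = c("score", "p_value"),
                           metric_id = NULL, method = NULL) {
  applied_to <- match.arg(applied_to)
  if (!is.numeric(amber) || !is.numeric(red) || amber <= 0 || red <= 0) {
    stop_config("thresholds must be positive magnitudes")
  }
  if (applied_to == "score" && red <= amber) {
    stop_config("score thresholds require red > amber (got red=%g, amber=%g)",
                red, amber)
  }
  if (applied_to == "p_value" && red >= amber) {
    stop_config("p-value thresholds require red < amber (got red=%g, amber=%g)",
                red, amber)
  }
  structure(list(metric_id = metric_id, method = method, amber = amber,
                 red = red, applied_to = applied_to),
            class = "threshold_spec")
}

#' @rdname threshold_spec
#' @export
default_thresholds <- function(method = c("normal_approx", "poisson", "fisher")) {
  method <- match.arg(method)
  if (method == "fisher") {
    threshold_spec(amber = 0.05, red = 0.01, applied_to = "p_value",
                   method = "fisher")
  } else {
    threshold_spec(amber = 2, red = 3, applied_to = "score", method = method)
  }
}

#' Assign directional flags to analyzed groups
#'
#' Converts per-group scores (or Fisher p-values) into signed flags:
#' `+2`/`-2` red, `+1`/`-1` amber, `0` green, the sign being the direction of
#' the group's observed metric relative to the study-wide value. Groups that
#' were not evaluable get flag 0 with their status carried through.
#'
#' @param result A `kri_analysis` object.
#' @param thresholds A [threshold_spec()]; defaults to the method's
#'   conventional thresholds.
#' @return A tibble with one row per group: `group_id`, `metric_id`, `flag`,
#'   `score`, `p_value`, `direction`, `status`, `amber`, `red`.
#' @export
assign_flags <- function(result, thresholds = NULL) {
  if (!inherits(result, "kri_analysis")) {
    stop_config("'result' must be a kri_analysis object")
  }
  thresholds <- thresholds %||% default_thresholds(result$method)
  if (!inherits(thresholds, "threshold_spec")) {
    stop_config("'thresholds' must be a threshold_spec object")
  }
  if (!is.null(thresholds$method) && thresholds$method != result$method) {
    stop_config("thresholds are for method '%s' but result used '%s'",
                thresholds$method, result$method)
  }
  g <- result$groups
  evaluable <- g$status == "evaluable"
  if (thresholds$applied_to == "p_value") {
    sev <- ifelse(g$p_value <= thresholds$red, 2L,
                  ifelse(g$p_value <= thresholds$amber, 1L, 0L))
  } else {
    sev <- ifelse(abs(g$score) >= thresholds$red, 2L,
                  ifelse(abs(g$score) >= thresholds$amber, 1L, 0L))
  }
  flag <- as.integer(sev * sign(g$direction %|NA|% 0))
  flag[!evaluable | is.na(flag)] <- 0L
  tibble(
    group_id = g$group_id,
    metric_id = result$metric_id,
    flag = flag,
    score = g$score,
    p_value = g$p_value,
    direction = g$direction,
    status = g$status,
    amber = thresholds$amber,
    red = thresholds$red
  )
}

#' Assemble the long-format assessment summary
#'
#' Joins flags back to the analysis into the standardized long format used
#' for stacking across KRIs and snapshots, sorted by descending score
#' magnitude within the metric (not-evaluable groups last).
#'
#' @param flags Output of [assign_flags()].
#' @param result The matching `kri_analysis` object.
#' @param meta Optional list of metadata; `snapshot_date` is carried into
#'   the rows.
#' @return A tibble with columns `snapshot_date`, `group_id`, `metric_id`,
#'   `n`, `numerator`, `denominator`, `observed_metric`, `overall_estimate`,
#'   `score`, `flag`.
#' @export
summarize_assessment <- function(flags, result, meta = list()) {
  if (!inherits(result, "kri_analysis")) {
    stop_config("'result' must be a kri_analysis object")
  }
  if (nrow(flags) > 0 &&
      !identical(sort(flags$group_id), sort(result$groups$group_id))) {
    stop_config("flags and result cover different groups")
  }
  snapshot_date <- as.Date(meta$snapshot_date %||% NA)
  g <- result$groups
  out <- tibble(
    snapshot_date = rep(snapshot_date, nrow(g)),
    group_id = g$group_id,
    metric_id = rep(result$metric_id %|NA|% NA_character_, nrow(g)),
    n = g$n,
    numerator = g$numerator,
    denominator = g$denominator,
    observed_metric = g$observed_metric,
    overall_estimate = rep(result$overall_estimate, nrow(g)),
    score = g$score,
    flag = flags$flag[match(g$group_id, flags$group_id)]
  )
  out[order(-abs(out$score), out$group_id, na.last = TRUE), ]
}
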