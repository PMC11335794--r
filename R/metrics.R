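# The key risk indicator registry and the subject-level numerator /
# denominator builders. Every KRI is a numerator over a denominator; rates
# are denominated in exposure days, percentages in discrete opportunities
# (participants, samples, queries, forms, fields).

KRI_REGISTRY <- tibble(
  metric_id = c("ae_rate", "sae_rate", "g3lab_rate", "pd_rate", "ipd_rate",
                "subj_disc", "trt_disc", "query_rate", "query_age",
                "entry_lag", "datachg_rate", "screen_fail"),
  label = c(
    "AE reporting rate (# adverse events / days in study)",
    "SAE reporting rate (# serious adverse events / days in study)",
    "G3+ lab abnormality rate (# grade 3+ abnormal samples / total samples)",
    "Non-important PD rate (# non-important protocol deviations / days in study)",
    "Important PD rate (# important protocol deviations / days in study)",
    "Subject discontinuation (# subjects discontinued study / total enrolled)",
    "Treatment discontinuation (# subjects discontinued treatment / total enrolled)",
    "Query rate (# queries / total data points)",
    "Query age (# queries open > 30 days / total queries)",
    "Visit entry lag (# forms entered > 10 days / total forms)",
    "Date change rate (# fields with >= 1 change / total fields)",
    "Screen failure (# screen failures / total screened participants)"
  ),
  metric_type = c("rate", "rate", "percentage", "rate", "rate",
                  "percentage", "percentage", "percentage", "percentage",
                  "percentage", "percentage", "percentage"),
  denominator_basis = c("exposure_days", "exposure_days", "samples",
                        "exposure_days", "exposure_days", "participants",
                        "participants", "fields", "queries", "forms",
                        "fields", "participants")
)

# Domains each metric needs beyond dm (dm is always required: it carries the
# grouping variables and the exposure/enrollment denominators).
KRI_DOMAINS <- list(
  ae_rate = "ae", sae_rate = "ae", g3lab_rate = "lb", pd_rate = "pd",
  ipd_rate = "pd", subj_disc = "ds", trt_disc = "ds",
  query_rate = c("qr", "fd"), query_age = "qr", entry_lag = "fv",
  datachg_rate = "fd", screen_fail = character()
)

# Metrics that depend on the optional audit-style field domain; workflows
# skip these with a warning (rather than erroring) when `fd` is absent.
OPTIONAL_DOMAIN_METRICS <- c("query_rate", "datachg_rate")

# Strict boundaries, per the printed definitions: a query aged exactly 30
# days or a form entered exactly 10 days after the visit is not counted.
QUERY_AGE_CUTOFF_DAYS <- 30
ENTRY_LAG_CUTOFF_DAYS <- 10

#' The key risk indicator registry
#'
#' Lists the twelve KRI metric definitions in registry order. Each metric is
#' a numerator over a denominator: `rate` metrics are denominated in exposure
#' days, `percentage` metrics in discrete opportunities (participants, lab
#' samples, queries, forms or data fields).
#'
#' @return A tibble with one row per metric: `metric_id`, `label`,
#'   `metric_type` (`"rate"` or `"percentage"`) and `denominator_basis`.
#' @export
#' @examples
#' list_metrics()
list_metrics <- function() KRI_REGISTRY

metric_def <- function(metric) {
  if (is.data.frame(metric)) {
    stopifnot(nrow(metric) == 1)
    return(metric)
  }
  row <- KRI_REGISTRY[KRI_REGISTRY$metric_id == metric, ]
  if (nrow(row) == 0) stop_config("unknown metric '%s'", metric)
  row
}

metric_required_domains <- function(metric_id) {
  c("dm", KRI_DOMAINS[[metric_id]])
}

#' Subject-subset filter
#'
#' A filter keeps the subjects having at least one row in `domain` that
#' satisfies `column <op> value`; subjects must survive every filter of a
#' workflow (set intersection), so filter order never matters. The subset
#' "randomized and treated", for example, is two `eq` filters on the `dm`
#' flags.
#'
#' @param domain Domain id the predicate is evaluated on.
#' @param column Column of that domain.
#' @param op One of `"eq"`, `"ne"`, `"in"`.
#' @param value Comparison value (a vector for `"in"`).
#' @return A `filter_spec` object.
#' @export
#' @examples
#' filter_spec("dm", "randomized_flag", "eq", "Y")
filter_spec <- function(domain, column, op = c("eq", "ne", "in"), value) {
  op <- match.arg(op)
  if (!domain %in% names(DOMAIN_SCHEMAS)) {
    stop_config("filter on unknown domain '%s'", domain)
  }
  if (!column %in% names(domain_schema(domain)$cols)) {
    stop_config("filter on unknown column '%s' of domain '%s'", column, domain)
  }
  structure(list(domain = domain, column = column, op = op, value = value),
            class = "filter_spec")
}

filtered_subjects <- function(domains, filters) {
  keep <- unique(domains$dm$subject_id)
  for (f in filters) {
    tab <- domains[[f$domain]]
    if (is.null(tab)) stop_config("filter references absent domain '%s'", f$domain)
    x <- tab[[f$column]]
    hit <- switch(f$op,
      eq = !is.na(x) & x == f$value,
      ne = !is.na(x) & x != f$value,
      `in` = !is.na(x) & x %in% f$value
    )
    keep <- intersect(keep, unique(tab$subject_id[hit]))
  }
  keep
}

default_snapshot_date <- function(domains) {
  dates <- do.call(c, c(list(as.Date(character())), unlist(
    lapply(domains, function(d) {
      schema <- domain_schema(domain_id(d))
      cols <- names(schema$cols)[schema$cols == "date"]
      lapply(cols, function(col) d[[col]])
    }), recursive = FALSE)))
  if (length(dates) == 0 || all(is.na(dates))) Sys.Date() else
    max(dates, na.rm = TRUE)
}

# Count qualifying rows of an event-style domain per subject.
count_per_subject <- function(tab, subjects, which = TRUE) {
  tab <- tab[which & tab$subject_id %in% subjects, , drop = FALSE]
  cnt <- table(factor(tab$subject_id, levels = subjects))
  as.integer(cnt)
}

# Per-subject numerator and denominator for one metric, over all subjects in
# `subjects` (row order preserved; subjects with no event rows get zeros).
subject_counts <- function(metric_id, domains, subjects, snapshot_date) {
  dm <- domains$dm
  dmx <- dm[match(subjects, dm$subject_id), ]
  rate_num <- function(tab, which) count_per_subject(tab, subjects, which)
  switch(metric_id,
    ae_rate = list(
      num = rate_num(domains$ae, TRUE),
      den = as.numeric(dmx$days_on_study)),
    sae_rate = list(
      num = rate_num(domains$ae, domains$ae$serious_flag == "Y"),
      den = as.numeric(dmx$days_on_study)),
    g3lab_rate = list(
      num = rate_num(domains$lb, !is.na(domains$lb$toxicity_grade) &
                       domains$lb$toxicity_grade >= 3),
      den = as.numeric(count_per_subject(domains$lb, subjects))),
    pd_rate = list(
      num = rate_num(domains$pd, domains$pd$important_flag != "Y"),
      den = as.numeric(dmx$days_on_study)),
    ipd_rate = list(
      num = rate_num(domains$pd, domains$pd$important_flag == "Y"),
      den = as.numeric(dmx$days_on_study)),
    subj_disc = {
      ds <- domains$ds
      disc <- ds$subject_id[ds$study_discontinued_flag == "Y"]
      enrolled <- dmx$enrolled_flag == "Y"
      list(num = as.numeric(enrolled & subjects %in% disc),
           den = as.numeric(enrolled))
    },
    trt_disc = {
      ds <- domains$ds
      disc <- ds$subject_id[ds$treatment_discontinued_flag == "Y"]
      enrolled <- dmx$enrolled_flag == "Y"
      list(num = as.numeric(enrolled & subjects %in% disc),
           den = as.numeric(enrolled))
    },
    query_rate = list(
      num = as.numeric(count_per_subject(domains$qr, subjects)),
      den = as.numeric(count_per_subject(domains$fd, subjects))),
    query_age = {
      qr <- domains$qr
      resolved <- dplyr::coalesce(qr$close_date, as.Date(snapshot_date))
      age <- as.numeric(resolved - qr$open_date)
      list(num = rate_num(qr, age > QUERY_AGE_CUTOFF_DAYS),
           den = as.numeric(count_per_subject(qr, subjects)))
    },
    entry_lag = {
      fv <- domains$fv
      lag <- as.numeric(fv$entry_date - fv$visit_date)
      list(num = rate_num(fv, lag > ENTRY_LAG_CUTOFF_DAYS),
           den = as.numeric(count_per_subject(fv, subjects)))
    },
    datachg_rate = list(
      num = rate_num(domains$fd, domains$fd$change_count >= 1),
      den = as.numeric(count_per_subject(domains$fd, subjects))),
    screen_fail = list(
      num = as.numeric(dmx$screen_failure_flag == "Y"),
      den = rep(1, length(subjects))),
    stop_config("unknown metric '%s'", metric_id)
  )
}

#' Build per-subject KRI inputs
#'
#' Computes one numerator/denominator/metric triple per subject for one KRI,
#' after applying subject filters, and attaches the subject's group at the
#' requested level (site, country, or a custom demographics column).
#' Subjects whose denominator is zero (no exposure, no queries, ...) carry a
#' missing `metric_value` and contribute nothing to group totals downstream.
#'
#' @param domains Named list of domain tables (must include `dm` plus the
#'   metric's required domains).
#' @param metric A metric id or one row of [list_metrics()].
#' @param group_level `"site"`, `"country"`, or `"custom"`.
#' @param filters List of [filter_spec()]s; subjects must satisfy all.
#' @param snapshot_date Analysis snapshot date, used for the age of open
#'   queries; defaults to the latest date observed anywhere in the data.
#' @param group_column Demographics column holding the grouping variable when
#'   `group_level = "custom"`.
#' @return A tibble with columns `subject_id`, `group_id`, `numerator`,
#'   `denominator`, `metric_value`.
#' @export
build_subject_input <- function(domains, metric,
                                group_level = c("site", "country", "custom"),
                                filters = list(), snapshot_date = NULL,
                                group_column = "custom_group") {
  group_level <- match.arg(group_level)
  def <- metric_def(metric)
  need <- metric_required_domains(def$metric_id)
  for (d in need) {
    if (is.null(domains[[d]])) stop_missing_domain(def$metric_id, d)
  }
  if (inherits(filters, "filter_spec")) filters <- list(filters)
  snapshot_date <- snapshot_date %||% default_snapshot_date(domains)

  subjects <- filtered_subjects(domains, filters)
  dm <- domains$dm
  dmx <- dm[match(subjects, dm$subject_id), ]
  group_col <- switch(group_level, site = "site_id", country = "country",
                      custom = group_column)
  if (!group_col %in% names(dm)) {
    stop_config("grouping column '%s' not present in dm", group_col)
  }

  cnt <- subject_counts(def$metric_id, domains, subjects, snapshot_date)
  tibble(
    subject_id = subjects,
    group_id = as.character(dmx[[group_col]]),
    numerator = as.numeric(cnt$num),
    denominator = as.numeric(cnt$den),
    metric_value = ifelse(cnt$den > 0, cnt$num / cnt$den, NA_real_)
  )
}

#' Aggregate subject inputs to group summaries
#'
#' Sums subject numerators and denominators within each group. Subjects with
#' a zero denominator contribute nothing (a 0/0 subject carries no
#' information); groups whose total denominator is zero are carried through
#' with a missing observed metric so downstream analysis can report them as
#' not evaluable.
#'
#' @param inputs Subject inputs from [build_subject_input()].
#' @param metric A metric id or registry row (used for validity checks).
#' @return A tibble with one row per group: `group_id`, `n_participants`
#'   (subjects contributing a non-zero denominator), `total_numerator`,
#'   `total_denominator`, `observed_metric`.
#' @export
aggregate_groups <- function(inputs, metric) {
  def <- metric_def(metric)
  if (nrow(inputs) == 0) {
    warn(sprintf("no subject inputs for metric '%s'; empty summary",
                 def$metric_id))
    return(tibble(group_id = character(), n_participants = integer(),
                  total_numerator = numeric(), total_denominator = numeric(),
                  observed_metric = numeric()))
  }
  out <- inputs %>%
    group_by(group_id = .data$group_id) %>%
    summarise(
      n_participants = sum(.data$denominator > 0),
      total_numerator = sum(.data$numerator[.data$denominator > 0]),
      total_denominator = sum(.data$denominator),
      .groups = "drop"
    ) %>%
    mutate(observed_metric = ifelse(.data$total_denominator > 0,
                                    .data$total_numerator / .data$total_denominator,
                                    NA_real_)) %>%
    arrange(.data$group_id)
  if (def$metric_type == "percentage" &&
      any(out$total_numerator > out$total_denominator)) {
    warn(sprintf("metric '%s': numerator exceeds denominator in some group",
                 def$metric_id))
  }
  out
}
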