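# Automated data checks. Findings, not exceptions: each finding names the
# domain, a fixed rule id, a severity, and where it was found. Error-severity
# findings are exactly the conditions that would corrupt a KRI numerator or
# denominator; they block analysis of the affected domain unless explicitly
# overridden at the workflow level.

finding <- function(domain_id, rule_id, severity, row, message) {
  tibble(domain_id = domain_id, rule_id = rule_id, severity = severity,
         row = as.integer(row), message = message)
}

empty_findings <- function() {
  tibble(domain_id = character(), rule_id = character(), severity = character(),
         row = integer(), message = character())
}

#' Run automated data checks on one domain table
#'
#' Applies the fixed rule set to a standardized domain table:
#' * `duplicate_key` (error) — repeated primary key;
#' * `orphan_subject` (error) — a subject in a non-demographics domain with
#'   no demographics record (requires `dm`);
#' * `negative_value` (error) — negative count or day-duration;
#' * `missing_required` (error) — missing value in a column that feeds a
#'   KRI numerator or denominator (empty `close_date` is a legitimate open
#'   query, not a finding);
#' * `missing_optional` (warning) — missing value in an optional descriptive
#'   column (e.g. `country` in `dm`).
#'
#' @param domain A domain table.
#' @param dm The demographics domain table, used for the referential rule;
#'   omit when checking `dm` itself.
#' @return A tibble of findings (zero rows when the domain is clean) with
#'   columns `domain_id`, `rule_id`, `severity`, `row`, `message`.
#' @export
check_data <- function(domain, dm = NULL) {
  id <- domain_id(domain)
  if (is.na(id)) stop_config("not a standardized domain table")
  schema <- domain_schema(id)
  out <- list()

  key <- schema$key
  keyv <- do.call(paste, c(domain[key], sep = "\r"))
  dups <- which(duplicated(keyv))
  for (i in dups) {
    out[[length(out) + 1]] <- finding(
      id, "duplicate_key", "error", i,
      sprintf("duplicate primary key (%s)",
              paste(unlist(domain[i, key]), collapse = "/")))
  }

  if (id != "dm" && !is.null(dm)) {
    orphan <- which(!domain$subject_id %in% dm$subject_id)
    for (i in orphan) {
      out[[length(out) + 1]] <- finding(
        id, "orphan_subject", "error", i,
        sprintf("subject '%s' has no demographics record", domain$subject_id[i]))
    }
  }

  int_cols <- names(schema$cols)[schema$cols == "int"]
  for (col in int_cols) {
    neg <- which(!is.na(domain[[col]]) & domain[[col]] < 0)
    for (i in neg) {
      out[[length(out) + 1]] <- finding(
        id, "negative_value", "error", i,
        sprintf("negative value %d in '%s'", domain[[col]][i], col))
    }
  }

  na_ok <- c(schema$na_ok %||% character(), schema$optional_values)
  for (col in setdiff(names(schema$cols), na_ok)) {
    miss <- which(is.na(domain[[col]]))
    for (i in miss) {
      out[[length(out) + 1]] <- finding(
        id, "missing_required", "error", i,
        sprintf("missing value in required column '%s'", col))
    }
  }
  for (col in schema$optional_values) {
    miss <- which(is.na(domain[[col]]))
    for (i in miss) {
      out[[length(out) + 1]] <- finding(
        id, "missing_optional", "warning", i,
        sprintf("missing value in optional column '%s'", col))
    }
  }

  if (length(out) == 0) empty_findings() else bind_rows(out)
}

#' Run data checks across a set of domains
#'
#' Checks each domain with [check_data()], supplying `dm` for the
#' referential rule.
#'
#' @param domains Named list of domain tables (must include `dm` for
#'   referential checks to run).
#' @return Combined findings tibble.
#' @export
check_study_data <- function(domains) {
  dm <- domains[["dm"]]
  bind_rows(lapply(names(domains), function(id) {
    check_data(domains[[id]], dm = if (id == "dm") NULL else dm)
  }))
}
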