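# Standardized domain schemas. Each domain is a subject-level table with a
# fixed set of standard columns; every other module consumes these, never the
# source dialects. Column kinds drive type coercion at load time and the
# automated data checks:
#   chr  — free identifier text
#   int  — non-negative integer count/duration
#   flag — "Y"/"N"
#   date — ISO-8601 date (may be empty where noted)

DOMAIN_SCHEMAS <- list(
  dm = list(
    label = "demographics / enrollment",
    key = "subject_id",
    cols = c(subject_id = "chr", site_id = "chr", country = "chr",
             enrolled_flag = "flag", randomized_flag = "flag",
             treated_flag = "flag", screen_failure_flag = "flag",
             days_on_study = "int"),
    optional_values = "country"
  ),
  ae = list(
    label = "adverse events",
    key = c("subject_id", "event_seq"),
    cols = c(subject_id = "chr", event_seq = "int", serious_flag = "flag"),
    optional_values = character()
  ),
  lb = list(
    label = "lab samples",
    key = c("subject_id", "sample_seq"),
    cols = c(subject_id = "chr", sample_seq = "int", toxicity_grade = "int"),
    optional_values = character()
  ),
  pd = list(
    label = "protocol deviations",
    key = c("subject_id", "deviation_seq"),
    cols = c(subject_id = "chr", deviation_seq = "int", important_flag = "flag"),
    optional_values = character()
  ),
  qr = list(
    label = "data queries",
    key = c("subject_id", "query_seq"),
    cols = c(subject_id = "chr", query_seq = "int", open_date = "date",
             close_date = "date"),
    # an open query legitimately has an empty close_date
    na_ok = "close_date",
    optional_values = character()
  ),
  fv = list(
    label = "form / visit entry",
    key = c("subject_id", "form_seq"),
    cols = c(subject_id = "chr", form_seq = "int", visit_date = "date",
             entry_date = "date"),
    optional_values = character()
  ),
  ds = list(
    label = "disposition",
    key = "subject_id",
    cols = c(subject_id = "chr", study_discontinued_flag = "flag",
             treatment_discontinued_flag = "flag"),
    optional_values = character()
  ),
  fd = list(
    label = "data fields (audit export)",
    key = c("subject_id", "field_id"),
    cols = c(subject_id = "chr", field_id = "chr", change_count = "int"),
    optional_values = character()
  )
)

#' Standard domain schemas
#'
#' Returns the schema of one standardized data domain: its column names and
#' kinds, primary key, and which columns may carry missing values. The seven
#' core domains are `dm` (demographics/enrollment), `ae` (adverse events),
#' `lb` (lab samples), `pd` (protocol deviations), `qr` (data queries),
#' `fv` (form/visit entry) and `ds` (disposition); `fd` is an optional
#' audit-style field-level domain used by the query-rate and date-change
#' metrics.
#'
#' @param domain_id One of `"dm"`, `"ae"`, `"lb"`, `"pd"`, `"qr"`, `"fv"`,
#'   `"ds"`, `"fd"`. With no argument, all schemas are returned.
#' @return A list describing the schema (or a named list of all schemas).
#' @export
#' @examples
#' domain_schema("ae")$cols
domain_schema <- function(domain_id) {
  if (missing(domain_id)) return(DOMAIN_SCHEMAS)
  if (!domain_id %in% names(DOMAIN_SCHEMAS)) {
    stop_config("unknown domain '%s'", domain_id)
  }
  DOMAIN_SCHEMAS[[domain_id]]
}

new_domain_table <- function(df, domain_id, provenance = list()) {
  out <- as_tibble(df)
  attr(out, "domain_id") <- domain_id
  attr(out, "provenance") <- provenance
  class(out) <- c("domain_tbl", class(out))
  out
}

#' Domain identifier of a standardized table
#'
#' @param x A domain table as returned by [load_domain()] or [simulate_trial()].
#' @return The domain id string, or `NA` if `x` is not a domain table.
#' @export
domain_id <- function(x) attr(x, "domain_id") %||% NA_character_

#' @export
print.domain_tbl <- function(x, ...) {
  cat(sprintf("<domain table '%s': %d rows>\n", domain_id(x), nrow(x)))
  NextMethod()
}

# dplyr verbs strip our attributes; rebuild when needed internally.
as_domain <- function(df, domain_id) new_domain_table(df, domain_id)

coerce_domain_types <- function(df, domain_id, date_format = "%Y-%m-%d",
                                source = "<data>") {
  schema <- domain_schema(domain_id)
  for (col in names(schema$cols)) {
    kind <- schema$cols[[col]]
    x <- df[[col]]
    if (kind == "int") {
      df[[col]] <- as.integer(x)
    } else if (kind == "date") {
      if (inherits(x, "Date")) next
      x <- as.character(x)
      x[!is.na(x) & trimws(x) == ""] <- NA_character_
      parsed <- as.Date(x, format = date_format)
      bad <- which(!is.na(x) & is.na(parsed))
      if (length(bad) > 0) {
        stop_input(
          "unparseable date in %s, domain '%s', column '%s', row %d: \"%s\"",
          source, domain_id, col, bad[1], x[bad[1]]
        )
      }
      df[[col]] <- parsed
    } else {
      df[[col]] <- as.character(x)
    }
  }
  df
}
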