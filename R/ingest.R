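# Ingest: read delimited source files in one of three dialects, rename
# columns to the standardized domain model, parse dates, and keep provenance.

# Built-in source-column names per dialect. "raw" is identity (source already
# uses standard names); the SDTM- and ADaM-like maps cover common EDC export
# conventions and can be overridden per column in `column_map`.
DIALECT_MAPS <- list(
  sdtm_like = list(
    dm = c(subject_id = "USUBJID", site_id = "SITEID", country = "COUNTRY",
           enrolled_flag = "ENRLFL", randomized_flag = "RANDFL",
           treated_flag = "TRTFL", screen_failure_flag = "SCRNFFL",
           days_on_study = "STUDYDUR"),
    ae = c(subject_id = "USUBJID", event_seq = "AESEQ", serious_flag = "AESER"),
    lb = c(subject_id = "USUBJID", sample_seq = "LBSEQ",
           toxicity_grade = "LBTOXGR"),
    pd = c(subject_id = "USUBJID", deviation_seq = "DVSEQ",
           important_flag = "DVIMPFL"),
    qr = c(subject_id = "USUBJID", query_seq = "QRSEQ", open_date = "QROPDT",
           close_date = "QRCLDT"),
    fv = c(subject_id = "USUBJID", form_seq = "FVSEQ", visit_date = "SVSTDTC",
           entry_date = "FVENTDTC"),
    ds = c(subject_id = "USUBJID", study_discontinued_flag = "DSSTDFL",
           treatment_discontinued_flag = "DSTRDFL"),
    fd = c(subject_id = "USUBJID", field_id = "FIELDID",
           change_count = "NCHANGE")
  ),
  adam_like = list(
    dm = c(subject_id = "USUBJID", site_id = "SITEID", country = "COUNTRY",
           enrolled_flag = "ENRLFL", randomized_flag = "RANDFL",
           treated_flag = "SAFFL", screen_failure_flag = "SCRNFFL",
           days_on_study = "TRTDURD"),
    ae = c(subject_id = "USUBJID", event_seq = "AESEQ", serious_flag = "AESER"),
    lb = c(subject_id = "USUBJID", sample_seq = "ASEQ",
           toxicity_grade = "ATOXGR"),
    pd = c(subject_id = "USUBJID", deviation_seq = "ASEQ",
           important_flag = "CRIT1FL"),
    qr = c(subject_id = "USUBJID", query_seq = "ASEQ", open_date = "ADT",
           close_date = "AENDT"),
    fv = c(subject_id = "USUBJID", form_seq = "ASEQ", visit_date = "ADT",
           entry_date = "AENDT"),
    ds = c(subject_id = "USUBJID", study_discontinued_flag = "DCSREASFL",
           treatment_discontinued_flag = "DCTREASFL"),
    fd = c(subject_id = "USUBJID", field_id = "PARAMCD",
           change_count = "AVAL")
  )
)

#' Column mapping specification for one data domain
#'
#' Describes how a source file maps onto one standardized domain: which
#' source column supplies each standard column, which dialect the source
#' follows, and how its dates are formatted. For the `sdtm_like` and
#' `adam_like` dialects a built-in default map is used as the base and
#' `column_map` overrides individual entries; for `raw`, source columns are
#' assumed to already carry the standard names unless remapped.
#'
#' @param domain_id Target standardized domain (see [domain_schema()]).
#' @param column_map Named character vector `standard_name = "SOURCE_NAME"`.
#' @param dialect One of `"raw"`, `"sdtm_like"`, `"adam_like"`.
#' @param date_format A [base::strptime()] pattern for source dates
#'   (default ISO-8601, `"%Y-%m-%d"`).
#' @return A `mapping_spec` object.
#' @export
#' @examples
#' mapping_spec("ae", c(subject_id = "USUBJID", event_seq = "AESEQ",
#'                      serious_flag = "AESER"))
mapping_spec <- function(domain_id, column_map = NULL,
                         dialect = c("raw", "sdtm_like", "adam_like"),
                         date_format = "%Y-%m-%d") {
  dialect <- match.arg(dialect)
  schema <- domain_schema(domain_id)
  std <- names(schema$cols)
  base <- if (dialect == "raw") stats::setNames(std, std) else
    DIALECT_MAPS[[dialect]][[domain_id]]
  map <- base
  if (!is.null(column_map)) {
    if (is.list(column_map)) column_map <- unlist(column_map)
    bad <- setdiff(names(column_map), std)
    if (length(bad) > 0) {
      stop_mapping("mapping for domain '%s' names unknown standard column(s): %s",
                   domain_id, paste(bad, collapse = ", "))
    }
    map[names(column_map)] <- column_map
  }
  missing_cols <- setdiff(std, names(map))
  if (length(missing_cols) > 0) {
    stop_mapping("mapping for domain '%s' lacks standard column(s): %s",
                 domain_id, paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(names(map))) {
    stop_mapping("mapping for domain '%s' lists a standard column twice",
                 domain_id)
  }
  structure(
    list(domain_id = domain_id, column_map = map[std], dialect = dialect,
         date_format = date_format),
    class = "mapping_spec"
  )
}

#' @export
print.mapping_spec <- function(x, ...) {
  cat(sprintf("<mapping_spec: %s (%s), %d columns>\n",
              x$domain_id, x$dialect, length(x$column_map)))
  invisible(x)
}

#' Load one source file into a standardized domain table
#'
#' Reads a delimited text file (header row required), renames columns per the
#' mapping specification, drops unmapped source columns, coerces types, and
#' parses dates into the canonical `Date` type. Empty date fields become `NA`
#' (an open query has an empty `close_date`). Row order is preserved.
#'
#' @param path Path to the delimited file.
#' @param spec A [mapping_spec()].
#' @param delim Field delimiter (comma by default).
#' @return A standardized domain table (tibble with class `domain_tbl`).
#' @export
load_domain <- function(path, spec, delim = ",") {
  if (!inherits(spec, "mapping_spec")) {
    stop_config("'spec' must be a mapping_spec object")
  }
  if (!file.exists(path)) stop_input("file not found: %s", path)
  raw <- readr::read_delim(
    path, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(), progress = FALSE, show_col_types = FALSE
  )
  absent <- spec$column_map[!spec$column_map %in% names(raw)]
  if (length(absent) > 0) {
    stop_mapping("domain '%s': source file '%s' lacks column '%s' mapped to '%s'",
                 spec$domain_id, basename(path), absent[[1]],
                 names(absent)[[1]])
  }
  df <- raw[, unname(spec$column_map), drop = FALSE]
  names(df) <- names(spec$column_map)
  df[] <- lapply(df, function(x) {
    x[trimws(x) == ""] <- NA_character_
    x
  })
  df <- coerce_domain_types(df, spec$domain_id, spec$date_format,
                            source = basename(path))
  new_domain_table(df, spec$domain_id,
                   provenance = list(path = path, mapping = spec))
}

#' Write standardized domain tables to CSV
#'
#' Writes each domain as `<domain_id>.csv` under `dir`, with dates in
#' ISO-8601 and missing values as empty fields, so that re-loading with an
#' identity (`raw` dialect) mapping round-trips the content exactly.
#'
#' @param domains Named list of domain tables.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_domains <- function(domains, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(domains), function(id) {
    p <- file.path(dir, paste0(id, ".csv"))
    readr::write_csv(as_tibble(as.data.frame(domains[[id]])), p, na = "")
    p
  }, character(1))
  invisible(paths)
}

#' Load a directory of standardized domain CSVs
#'
#' Convenience loader for a directory written by [write_domains()] or the
#' simulator: every `<domain_id>.csv` matching a known schema is loaded with
#' an identity mapping.
#'
#' @param dir Directory containing `dm.csv`, `ae.csv`, ...
#' @param specs Optional named list of [mapping_spec()]s overriding the
#'   identity mapping per domain.
#' @return Named list of domain tables.
#' @export
load_domains <- function(dir, specs = list()) {
  if (!dir.exists(dir)) stop_input("directory not found: %s", dir)
  ids <- intersect(names(DOMAIN_SCHEMAS),
                   sub("\\.csv$", "", list.files(dir, pattern = "\\.csv$")))
  if (length(ids) == 0) stop_input("no recognised domain CSVs in %s", dir)
  out <- lapply(ids, function(id) {
    spec <- specs[[id]] %||% mapping_spec(id)
    load_domain(file.path(dir, paste0(id, ".csv")), spec)
  })
  stats::setNames(out, ids)
}
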