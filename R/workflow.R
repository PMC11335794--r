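# Orchestration. A workflow specification names a metric, a grouping level,
# subject filters, an analysis method and thresholds; an assessment executes
# the five-stage pipeline input -> transform -> analyze -> flag -> summarize,
# keeping every intermediate artifact in a run log. Workflows stack into a
# study run; study runs accumulate into a snapshot store for longitudinal
# views. Any stage can be replaced by a user-supplied function honoring the
# same contract (stage injection by named hook).

valid_methods_for <- function(metric_type) {
  if (metric_type == "rate") c("normal_approx", "poisson") else
    c("normal_approx", "fisher")
}

#' Workflow specification
#'
#' One workflow = one KRI assessment: the metric, the grouping level, the
#' subject filters, the analysis method and the flagging thresholds. The
#' method must be valid for the metric's type: Fisher applies to percentage
#' metrics, Poisson regression to rate metrics, the normal approximation to
#' both.
#'
#' @param metric Metric id from [list_metrics()].
#' @param workflow_id Identifier; defaults to `kri_<metric>`.
#' @param group_level `"site"`, `"country"`, or `"custom"`.
#' @param method `"normal_approx"` (default), `"fisher"`, or `"poisson"`.
#' @param thresholds A [threshold_spec()]; defaults to the method's defaults.
#' @param filters List of [filter_spec()]s.
#' @param mapping Optional named list of [mapping_spec()]s (or a path to a
#'   mapping YAML file) applied when domains are loaded from disk.
#' @param group_column Demographics column used when `group_level = "custom"`.
#' @return A `workflow_spec` object.
#' @export
workflow_spec <- function(metric, workflow_id = NULL,
                          group_level = c("site", "country", "custom"),
                          method = c("normal_approx", "fisher", "poisson"),
                          thresholds = NULL, filters = list(),
                          mapping = NULL, group_column = "custom_group") {
  group_level <- match.arg(group_level)
  method <- match.arg(method)
  def <- metric_def(metric)
  if (!method %in% valid_methods_for(def$metric_type)) {
    stop_config("method '%s' is not valid for %s metric '%s'",
                method, def$metric_type, def$metric_id)
  }
  thresholds <- thresholds %||% default_thresholds(method)
  structure(
    list(workflow_id = workflow_id %||% paste0("kri_", def$metric_id),
         metric_id = def$metric_id, group_level = group_level,
         method = method, thresholds = thresholds, filters = filters,
         mapping = mapping, group_column = group_column),
    class = "workflow_spec"
  )
}

#' @export
print.workflow_spec <- function(x, ...) {
  cat(sprintf("<workflow '%s': %s by %s via %s; %d filter(s)>\n",
              x$workflow_id, x$metric_id, x$group_level, x$method,
              length(x$filters)))
  invisible(x)
}

#' Default workflows for all twelve KRIs
#'
#' One site-level workflow per registry metric, default method and
#' thresholds.
#'
#' @return List of [workflow_spec()]s in registry order.
#' @export
default_workflows <- function() {
  lapply(list_metrics()$metric_id, workflow_spec)
}

parse_workflow_yaml <- function(doc, file = "<yaml>") {
  if (!is.list(doc) || is.null(doc$metric)) {
    stop_config("workflow file '%s' lacks a 'metric' key", file)
  }
  def <- tryCatch(metric_def(doc$metric), error = function(e) {
    stop_config("workflow file '%s': unknown metric '%s'", file, doc$metric)
  })
  method <- doc$method %||% "normal_approx"
  if (!method %in% c("normal_approx", "fisher", "poisson")) {
    stop_config("workflow file '%s': unknown method '%s'", file, method)
  }
  if (!method %in% valid_methods_for(def$metric_type)) {
    stop_config("workflow file '%s': method '%s' is not valid for %s metric '%s'",
                file, method, def$metric_type, def$metric_id)
  }
  thresholds <- NULL
  if (!is.null(doc$thresholds)) {
    base <- default_thresholds(method)
    thresholds <- threshold_spec(
      amber = doc$thresholds$amber %||% base$amber,
      red = doc$thresholds$red %||% base$red,
      applied_to = base$applied_to, method = method
    )
  }
  filters <- lapply(doc$filters %||% list(), function(f) {
    if (is.null(f$domain) || is.null(f$column) || is.null(f$op) ||
        is.null(f$value)) {
      stop_config("workflow file '%s': malformed filter (need domain, column, op, value)",
                  file)
    }
    filter_spec(f$domain, f$column, f$op, f$value)
  })
  mapping <- NULL
  if (!is.null(doc$mapping)) {
    mapping <- lapply(doc$mapping, function(m) {
      mapping_spec(m$domain, column_map = m$columns,
                   dialect = m$dialect %||% "raw",
                   date_format = m$date_format %||% "%Y-%m-%d")
    })
    names(mapping) <- vapply(mapping, function(m) m$domain_id, character(1))
  }
  workflow_spec(
    metric = doc$metric,
    workflow_id = doc$workflow_id,
    group_level = doc$group_level %||% "site",
    method = method,
    thresholds = thresholds,
    filters = filters,
    mapping = mapping,
    group_column = doc$group_column %||% "custom_group"
  )
}

#' Load workflow specifications from YAML
#'
#' Reads one YAML file (one workflow per file) or every `*.yaml`/`*.yml`
#' file in a directory, validating metric ids, method/metric pairings and
#' filters, and filling defaults (method `normal_approx`, site-level
#' grouping, default thresholds).
#'
#' @param path A YAML file or a directory of YAML files.
#' @return List of `workflow_spec` objects.
#' @export
load_workflows <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "\\.ya?ml$", full.names = TRUE)
  } else if (file.exists(path)) {
    path
  } else {
    stop_input("workflow path not found: %s", path)
  }
  if (length(files) == 0) stop_config("no workflow YAML files under %s", path)
  lapply(sort(files), function(f) {
    parse_workflow_yaml(yaml::read_yaml(f), file = basename(f))
  })
}

default_stages <- function() {
  list(
    input = function(domains, spec, snapshot_date) {
      build_subject_input(domains, spec$metric_id, spec$group_level,
                          spec$filters, snapshot_date,
                          group_column = spec$group_column)
    },
    transform = function(inputs, spec) aggregate_groups(inputs, spec$metric_id),
    analyze = function(groups, spec) {
      analyze_with_method(groups, spec$method,
                          metric_def(spec$metric_id)$metric_type,
                          spec$metric_id)
    },
    flag = function(result, spec) assign_flags(result, spec$thresholds),
    summarize = function(flags, result, spec, snapshot_date) {
      summarize_assessment(flags, result,
                           meta = list(snapshot_date = snapshot_date))
    }
  )
}

empty_summary <- function(snapshot_date = as.Date(NA)) {
  tibble(snapshot_date = as.Date(character()), group_id = character(),
         metric_id = character(), n = integer(), numerator = numeric(),
         denominator = numeric(), observed_metric = numeric(),
         overall_estimate = numeric(), score = numeric(), flag = integer())
}

#' Run one assessment workflow
#'
#' Executes the five pipeline stages in order — build subject inputs,
#' aggregate to group summaries, analyze, flag, summarize — and returns the
#' long-format assessment summary. Every intermediate artifact is kept in
#' the run log (`attr(result, "log")`). Degenerate statistics (fewer than
#' three evaluable groups, pooled estimate at a boundary) downgrade the
#' workflow to status `"not_evaluable"` rather than failing; any stage can
#' be replaced via `stages`.
#'
#' @param domains Named list of domain tables.
#' @param spec A [workflow_spec()].
#' @param snapshot_date Analysis snapshot date (defaults to the latest date
#'   in the data).
#' @param check Run [check_data()] on the involved domains first (default
#'   `TRUE`); error findings abort unless `override_checks = TRUE`.
#' @param override_checks Proceed despite error findings.
#' @param stages Named list replacing any of the stages `input`,
#'   `transform`, `analyze`, `flag`, `summarize` with a function honoring
#'   the same contract.
#' @return The assessment summary tibble (class `assessment_summary`) with
#'   attributes `status` (`"ok"`, `"not_evaluable"` or `"skipped"`), `spec`,
#'   and `log` (intermediates: `input`, `groups`, `analysis`, `flags`).
#' @export
run_assessment <- function(domains, spec, snapshot_date = NULL, check = TRUE,
                           override_checks = FALSE, stages = list()) {
  if (!inherits(spec, "workflow_spec")) {
    stop_config("'spec' must be a workflow_spec object")
  }
  snapshot_date <- as.Date(snapshot_date %||% default_snapshot_date(domains))
  st <- modifyList(default_stages(), stages)
  run_log <- list()

  if (check) {
    involved <- intersect(metric_required_domains(spec$metric_id),
                          names(domains))
    findings <- check_study_data(domains[involved])
    run_log$findings <- findings
    if (any(findings$severity == "error") && !override_checks) {
      abort(sprintf(
        "workflow '%s' [check]: %d data-check error(s) in domain(s) %s; fix the data or set override_checks = TRUE",
        spec$workflow_id, sum(findings$severity == "error"),
        paste(unique(findings$domain_id[findings$severity == "error"]),
              collapse = ", ")),
        class = "statmon_check_error")
    }
  }

  wrap_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        if (inherits(e, c("statmon_degenerate_error", "statmon_method_error"))) {
          abort(conditionMessage(e), class = "statmon_not_evaluable",
                parent = e, stage = stage)
        }
        if (inherits(e, "statmon_missing_domain_error")) stop(e)
        abort(sprintf("workflow '%s' [%s]: %s", spec$workflow_id, stage,
                      conditionMessage(e)),
              class = class(e)[1], parent = e, stage = stage)
      }),
      warning = function(w) {
        run_log$warnings <<- c(run_log$warnings, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }

  status <- "ok"
  note <- NA_character_
  summary <- tryCatch({
    inputs <- wrap_stage("input", st$input(domains, spec, snapshot_date))
    run_log$input <- inputs
    groups <- wrap_stage("transform", st$transform(inputs, spec))
    run_log$groups <- groups
    analysis <- wrap_stage("analyze", st$analyze(groups, spec))
    run_log$analysis <- analysis
    flags <- wrap_stage("flag", st$flag(analysis, spec))
    run_log$flags <- flags
    wrap_stage("summarize", st$summarize(flags, analysis, spec, snapshot_date))
  }, statmon_not_evaluable = function(e) {
    status <<- "not_evaluable"
    note <<- conditionMessage(e)
    empty_summary()
  })

  structure(summary,
            class = c("assessment_summary", class(summary)),
            status = status, note = note, spec = spec,
            snapshot_date = snapshot_date, log = run_log)
}

#' Run a stacked set of workflows as one study assessment
#'
#' Runs every workflow independently on the same data snapshot; one failing
#' workflow never aborts the others — it is carried in the result with an
#' error status and message. Workflows whose metric needs the optional
#' audit-style field domain (`fd`) are skipped with a warning when that
#' domain is absent.
#'
#' @inheritParams run_assessment
#' @param specs List of [workflow_spec()]s (at least one).
#' @return A `study_result` object: snapshot date, per-workflow assessment
#'   blocks (each with status `ok`, `not_evaluable`, `skipped` or `error`),
#'   study-wide data-check findings, and site metadata. Use [tidy()] for the
#'   stacked long-format summary.
#' @export
run_study <- function(domains, specs, snapshot_date = NULL, check = TRUE,
                      override_checks = FALSE) {
  if (inherits(specs, "workflow_spec")) specs <- list(specs)
  if (length(specs) == 0) stop_config("run_study needs at least one workflow")
  snapshot_date <- as.Date(snapshot_date %||% default_snapshot_date(domains))

  findings <- check_study_data(domains)
  if (any(findings$severity == "error") && !override_checks) {
    bad <- unique(findings$domain_id[findings$severity == "error"])
    # domains with error findings are withheld from analysis
    domains_ok <- domains[setdiff(names(domains), bad)]
  } else {
    domains_ok <- domains
  }

  blocks <- lapply(specs, function(spec) {
    tryCatch({
      s <- run_assessment(domains_ok, spec, snapshot_date, check = FALSE)
      list(workflow_id = spec$workflow_id, status = attr(s, "status"),
           note = attr(s, "note"), summary = s, spec = spec)
    },
    statmon_missing_domain_error = function(e) {
      dom <- e$domain_id %||% ""
      if (spec$metric_id %in% OPTIONAL_DOMAIN_METRICS && identical(dom, "fd")) {
        warn(sprintf("workflow '%s' skipped: optional domain 'fd' not available",
                     spec$workflow_id))
        list(workflow_id = spec$workflow_id, status = "skipped",
             note = conditionMessage(e), summary = empty_summary(), spec = spec)
      } else {
        list(workflow_id = spec$workflow_id, status = "error",
             note = conditionMessage(e), summary = empty_summary(), spec = spec)
      }
    },
    error = function(e) {
      list(workflow_id = spec$workflow_id, status = "error",
           note = conditionMessage(e), summary = empty_summary(), spec = spec)
    })
  })
  names(blocks) <- vapply(blocks, `[[`, character(1), "workflow_id")

  if (all(vapply(blocks, `[[`, character(1), "status") == "error")) {
    abort(paste0("all workflows failed:\n", paste(
      vapply(blocks, function(b) sprintf("  %s: %s", b$workflow_id, b$note),
             character(1)), collapse = "\n")), class = "statmon_study_error")
  }

  structure(
    list(snapshot_date = snapshot_date, assessments = blocks,
         findings = findings, sites = site_metadata(domains)),
    class = "study_result"
  )
}

# Site metadata for reporting: country, enrollment status, subject count.
site_metadata <- function(domains) {
  dm <- domains$dm
  if (is.null(dm)) return(tibble(group_id = character(), country = character(),
                                 status = character(), n_subjects = integer()))
  disc <- if (!is.null(domains$ds)) {
    domains$ds$subject_id[domains$ds$study_discontinued_flag == "Y"]
  } else character()
  dm %>%
    mutate(active = .data$enrolled_flag == "Y" & !.data$subject_id %in% disc) %>%
    group_by(group_id = .data$site_id) %>%
    summarise(
      country = .data$country[1] %|NA|% "",
      status = ifelse(any(.data$active), "active", "inactive"),
      n_subjects = dplyr::n(),
      .groups = "drop"
    ) %>%
    arrange(.data$group_id)
}

#' @export
print.study_result <- function(x, ...) {
  st <- vapply(x$assessments, `[[`, character(1), "status")
  cat(sprintf("<study_result: snapshot %s; %d workflow(s): %s>\n",
              format(x$snapshot_date), length(st),
              paste(sprintf("%d %s", as.integer(table(st)),
                            names(table(st))), collapse = ", ")))
  invisible(x)
}

#' @describeIn run_study Stacked long-format rows across all workflows,
#'   with `workflow_id` and `status` columns prepended.
#' @param x A `study_result`.
#' @param ... Unused.
#' @export
tidy.study_result <- function(x, ...) {
  bind_rows(lapply(x$assessments, function(b) {
    s <- as_tibble(as.data.frame(b$summary))
    if (nrow(s) == 0) return(NULL)
    mutate(s, workflow_id = b$workflow_id, status = b$status, .before = 1)
  }))
}

#' @describeIn run_study One row per workflow: status, group count, flag
#'   counts.
#' @export
glance.study_result <- function(x, ...) {
  bind_rows(lapply(x$assessments, function(b) {
    s <- b$summary
    tibble(workflow_id = b$workflow_id, metric_id = b$spec$metric_id,
           status = b$status, n_groups = nrow(s),
           n_red = sum(abs(s$flag %|NA|% 0L) == 2L),
           n_amber = sum(abs(s$flag %|NA|% 0L) == 1L))
  }))
}

#' Snapshot store for longitudinal monitoring
#'
#' An ordered collection of study results at strictly increasing snapshot
#' dates, supporting extraction of per-site score/flag time series.
#'
#' @return An empty `snapshot_store`.
#' @export
snapshot_store <- function() {
  structure(list(snapshots = list()), class = "snapshot_store")
}

#' Append a study result to a snapshot store
#'
#' @param store A [snapshot_store()].
#' @param result A `study_result` whose snapshot date is strictly later than
#'   the latest stored one.
#' @return The extended store.
#' @export
append_snapshot <- function(store, result) {
  if (!inherits(store, "snapshot_store")) stop_config("not a snapshot_store")
  if (!inherits(result, "study_result")) stop_config("not a study_result")
  n <- length(store$snapshots)
  if (n > 0) {
    latest <- store$snapshots[[n]]$snapshot_date
    if (!result$snapshot_date > latest) {
      stop_config("snapshot %s is not later than the latest stored (%s)",
                  format(result$snapshot_date), format(latest))
    }
  }
  store$snapshots <- c(store$snapshots, list(result))
  store
}

#' @export
length.snapshot_store <- function(x) length(x$snapshots)

#' @export
print.snapshot_store <- function(x, ...) {
  cat(sprintf("<snapshot_store: %d snapshot(s)%s>\n", length(x),
              if (length(x) > 0) paste0(" up to ",
                format(x$snapshots[[length(x)]]$snapshot_date)) else ""))
  invisible(x)
}

#' Extract a longitudinal score series from a snapshot store
#'
#' @param store A [snapshot_store()].
#' @param group_id Site (group) identifier.
#' @param metric_id Metric identifier.
#' @return Tibble `snapshot_date`, `score`, `flag` with one row per stored
#'   snapshot in which the group/metric was assessed.
#' @export
extract_series <- function(store, group_id, metric_id) {
  bind_rows(lapply(store$snapshots, function(res) {
    s <- tidy(res)
    s[!is.na(s$metric_id) & s$metric_id == metric_id &
        s$group_id == group_id,
      c("snapshot_date", "score", "flag")]
  }))
}
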