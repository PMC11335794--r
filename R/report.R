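# Result views: the site-by-KRI heatmap table, per-metric chart data
# (scatter, observed-metric bar, score bar, longitudinal), flat exports, and
# a deterministic self-contained HTML report with embedded static charts.

FLAG_GLYPHS <- c(`-2` = "▼▼", `-1` = "▼", `0` = "✓",
                 `1` = "▲", `2` = "▲▲")

assessment_blocks <- function(study, status = NULL) {
  b <- study$assessments
  if (!is.null(status)) b <- Filter(function(x) x$status %in% status, b)
  b
}

block_metric_col <- function(blocks) {
  metrics <- vapply(blocks, function(b) b$spec$metric_id, character(1))
  ifelse(metrics %in% metrics[duplicated(metrics)],
         vapply(blocks, `[[`, character(1), "workflow_id"), metrics)
}

#' Site-by-KRI heatmap table
#'
#' One row per monitored group with metadata (country, enrollment status,
#' subject count, red/amber totals) followed by one signed flag cell per
#' assessed metric, metrics in registry order. Groups for which a metric was
#' not evaluable carry `NA` in that cell (rendered "NE" in the HTML report);
#' `n_red`/`n_amber` count cells of magnitude 2 and 1 in the row.
#'
#' @param study A `study_result` from [run_study()].
#' @return A tibble: `group_id`, `country`, `status`, `n_subjects`,
#'   `n_red`, `n_amber`, then one integer column per metric.
#' @export
heatmap_table <- function(study) {
  blocks <- assessment_blocks(study, c("ok"))
  if (length(blocks) == 0) stop_config("study contains no usable assessments")
  ord <- order(match(vapply(blocks, function(b) b$spec$metric_id, character(1)),
                     KRI_REGISTRY$metric_id))
  blocks <- blocks[ord]
  cols <- block_metric_col(blocks)

  groups <- sort(unique(unlist(lapply(blocks, function(b) b$summary$group_id))))
  grid <- tibble(group_id = groups)
  for (k in seq_along(blocks)) {
    s <- blocks[[k]]$summary
    grid[[cols[k]]] <- s$flag[match(groups, s$group_id)]
  }
  flags <- as.matrix(grid[, cols, drop = FALSE])
  meta <- study$sites
  out <- tibble(
    group_id = groups,
    country = meta$country[match(groups, meta$group_id)] %|NA|% "",
    status = meta$status[match(groups, meta$group_id)] %|NA|% "",
    n_subjects = meta$n_subjects[match(groups, meta$group_id)],
    n_red = as.integer(rowSums(abs(flags) == 2, na.rm = TRUE)),
    n_amber = as.integer(rowSums(abs(flags) == 1, na.rm = TRUE))
  )
  bind_cols(out, grid[, cols, drop = FALSE])
}

new_chart_data <- function(kind, data, ref_lines = NULL, axes = list(),
                           metric_id = NA_character_, distribution = NULL) {
  structure(list(kind = kind, data = data, ref_lines = ref_lines,
                 axes = axes, metric_id = metric_id,
                 distribution = distribution),
            class = "chart_data")
}

#' @export
print.chart_data <- function(x, ...) {
  cat(sprintf("<chart_data '%s' for %s: %d point(s)>\n", x$kind,
              x$metric_id %|NA|% "?", nrow(x$data)))
  invisible(x)
}

assessment_attrs <- function(assessment) {
  list(spec = attr(assessment, "spec"), log = attr(assessment, "log"),
       status = attr(assessment, "status"))
}

#' Chart data for one assessment
#'
#' Extracts the plottable structure behind the standard result views.
#' `scatter` plots each group's numerator against its denominator (log-x)
#' with threshold reference curves for score-based methods; `metric_bar`
#' sorts groups by descending observed metric; `score_bar` by descending
#' signed score (ties broken by group id); `longitudinal` needs a
#' [snapshot_store()] with at least two snapshots and emits per-snapshot
#' score quartiles plus the selected group's series.
#'
#' @param assessment An `assessment_summary` from [run_assessment()] (or one
#'   block summary of a study result).
#' @param kind One of `"scatter"`, `"metric_bar"`, `"score_bar"`,
#'   `"longitudinal"`.
#' @param store A [snapshot_store()] (longitudinal only).
#' @param group_id Group highlighted in the longitudinal view.
#' @return A `chart_data` object; see [autoplot.chart_data()].
#' @export
chart_data <- function(assessment, kind = c("scatter", "metric_bar",
                                            "score_bar", "longitudinal"),
                       store = NULL, group_id = NULL) {
  kind <- match.arg(kind)
  at <- assessment_attrs(assessment)
  s <- as_tibble(as.data.frame(assessment))
  metric_id <- if (nrow(s) > 0) s$metric_id[1] else
    at$spec$metric_id %||% NA_character_
  flags <- attr(assessment, "log")$flags
  get_flag <- function(g) {
    if (!is.null(flags)) flags$flag[match(g, flags$group_id)] else
      s$flag[match(g, s$group_id)]
  }

  if (kind == "scatter") {
    data <- tibble(group_id = s$group_id, x = s$denominator, y = s$numerator,
                   flag = get_flag(s$group_id)) %>%
      arrange(.data$group_id)
    ref <- scatter_reference_curves(at)
    return(new_chart_data("scatter", data, ref_lines = ref,
                          axes = list(x = "denominator", y = "numerator",
                                      log_x = TRUE),
                          metric_id = metric_id))
  }
  if (kind == "metric_bar") {
    data <- s %>%
      filter(!is.na(.data$observed_metric)) %>%
      arrange(desc(.data$observed_metric), .data$group_id) %>%
      mutate(x = .data$group_id, y = .data$observed_metric,
             flag = get_flag(.data$group_id)) %>%
      select("group_id", "x", "y", "flag")
    return(new_chart_data("metric_bar", data,
                          ref_lines = tibble(level = "overall",
                                             value = s$overall_estimate[1]),
                          axes = list(x = "group", y = "observed metric"),
                          metric_id = metric_id))
  }
  if (kind == "score_bar") {
    thr <- at$spec$thresholds %||% default_thresholds("normal_approx")
    data <- s %>%
      filter(!is.na(.data$score)) %>%
      arrange(desc(.data$score), .data$group_id) %>%
      mutate(x = .data$group_id, y = .data$score,
             flag = get_flag(.data$group_id)) %>%
      select("group_id", "x", "y", "flag")
    ref <- if (thr$applied_to == "score") {
      tibble(level = c("amber", "red", "amber", "red"),
             value = c(thr$amber, thr$red, -thr$amber, -thr$red))
    } else NULL
    return(new_chart_data("score_bar", data, ref_lines = ref,
                          axes = list(x = "group", y = "score"),
                          metric_id = metric_id))
  }

  # longitudinal
  if (is.null(store) || length(store) < 2) {
    stop_config("longitudinal view needs a snapshot store with at least 2 snapshots",
                class = "statmon_insufficient_data")
  }
  dist <- bind_rows(lapply(store$snapshots, function(res) {
    t <- tidy(res)
    t <- t[!is.na(t$metric_id) & t$metric_id == metric_id & !is.na(t$score), ]
    if (nrow(t) == 0) return(NULL)
    q <- quantile(t$score, c(0.25, 0.5, 0.75), names = FALSE)
    tibble(snapshot_date = res$snapshot_date, q1 = q[1], median = q[2],
           q3 = q[3], n_groups = nrow(t))
  }))
  series <- if (!is.null(group_id)) extract_series(store, group_id, metric_id)
  else NULL
  thr <- at$spec$thresholds %||% default_thresholds("normal_approx")
  ref <- if (thr$applied_to == "score") {
    tibble(level = c("amber", "red", "amber", "red"),
           value = c(thr$amber, thr$red, -thr$amber, -thr$red))
  } else NULL
  new_chart_data("longitudinal", series %||% tibble(), ref_lines = ref,
                 axes = list(x = "snapshot date", y = "score"),
                 metric_id = metric_id, distribution = dist)
}

# Reference curves on the numerator scale for the scatter view: the loci
# where the adjusted score equals the amber / red thresholds.
scatter_reference_curves <- function(at) {
  analysis <- at$log$analysis
  spec <- at$spec
  if (is.null(analysis) || is.null(spec) ||
      spec$thresholds$applied_to != "score" ||
      analysis$method == "fisher") {
    return(NULL)
  }
  theta0 <- analysis$overall_estimate
  phi <- if (analysis$method == "normal_approx") analysis$phi_used else 1
  den <- analysis$groups$denominator
  grid <- exp(seq(log(max(min(den), 1)), log(max(den)), length.out = 50))
  v <- if (analysis$metric_type == "percentage") {
    theta0 * (1 - theta0) / grid
  } else {
    theta0 / grid
  }
  bind_rows(lapply(c(amber = spec$thresholds$amber,
                     red = spec$thresholds$red), function(thr) {
    tibble(x = rep(grid, 2),
           y = c(theta0 * grid + thr * sqrt(phi * v) * grid,
                 theta0 * grid - thr * sqrt(phi * v) * grid),
           side = rep(c("upper", "lower"), each = length(grid)))
  }), .id = "level")
}

#' Export study results to flat files
#'
#' Writes one file per usable assessment plus a combined long-format file
#' (`study_summary`), in the assessment-summary schema.
#'
#' @param study A `study_result`.
#' @param format `"csv"` or `"json"`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_results <- function(study, format = c("csv", "json"), out_dir) {
  if (!inherits(study, "study_result")) stop_config("not a study_result")
  if (length(format) == 1 && !format %in% c("csv", "json")) {
    stop_config("unknown export format '%s'", format)
  }
  format <- match.arg(format)
  blocks <- assessment_blocks(study, "ok")
  blocks <- Filter(function(b) nrow(b$summary) > 0, blocks)
  if (length(blocks) == 0) stop_config("study contains no results to export")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  write_one <- function(df, stem) {
    path <- file.path(out_dir, paste0(stem, ".", format))
    df <- as_tibble(as.data.frame(df))
    if (format == "csv") {
      readr::write_csv(df, path, na = "")
    } else {
      jsonlite::write_json(df, path, dataframe = "rows", na = "null",
                           digits = NA, Date = "ISO8601", pretty = TRUE)
    }
    path
  }
  paths <- vapply(blocks, function(b) write_one(b$summary, b$workflow_id),
                  character(1))
  combined <- tidy(study)
  paths <- c(paths, write_one(combined, "study_summary"))
  invisible(unname(paths))
}

# -- HTML report --------------------------------------------------------------

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# One canonical number format shared by the report tables (and usable by
# consistency checks against the exported values).

#' Format a number the way the HTML report prints it
#' @param x Numeric vector.
#' @param digits Significant digits (default 4).
#' @return Character vector (`"NE"` for missing).
#' @export
report_num <- function(x, digits = 4) {
  ifelse(is.na(x), "NE", formatC(signif(x, digits), format = "fg",
                                 big.mark = "", flag = "#"))
}

html_table <- function(df, formatters = list()) {
  cells <- lapply(names(df), function(nm) {
    f <- formatters[[nm]]
    x <- df[[nm]]
    if (!is.null(f)) f(x)
    else if (is.numeric(x) && !is.integer(x)) report_num(x)
    else html_escape(as.character(x %|NA|% ""))
  })
  rows <- do.call(paste, c(lapply(cells, function(x) {
    paste0("<td>", x, "</td>")
  }), sep = ""))
  paste0(
    "<table>\n<thead><tr>",
    paste0("<th>", html_escape(names(df)), "</th>", collapse = ""),
    "</tr></thead>\n<tbody>\n",
    paste0("<tr>", rows, "</tr>", collapse = "\n"),
    "\n</tbody>\n</table>"
  )
}

embed_plot <- function(p, width = 640, height = 420) {
  path <- tempfile(fileext = ".png")
  on.exit(unlink(path), add = TRUE)
  grDevices::png(path, width = width, height = height)
  print(p)
  grDevices::dev.off()
  b64 <- jsonlite::base64_enc(readBin(path, "raw", file.info(path)$size))
  b64 <- gsub("\n", "", b64, fixed = TRUE)
  sprintf('<img width="%d" height="%d" src="data:image/png;base64,%s"/>',
          width, height, b64)
}

flag_glyph <- function(flag) {
  ifelse(is.na(flag), "NE", unname(FLAG_GLYPHS[as.character(flag)]))
}

REPORT_CSS <- "
body { font-family: sans-serif; margin: 2em; color: #222; }
table { border-collapse: collapse; margin: 1em 0; font-size: 0.85em; }
th, td { border: 1px solid #bbb; padding: 3px 8px; text-align: right; }
th { background: #eee; }
td:first-child, th:first-child { text-align: left; }
.flag-red { color: #b30000; font-weight: bold; }
.flag-amber { color: #b36b00; font-weight: bold; }
.flag-green { color: #1a7a1a; }
h2 { border-bottom: 2px solid #444; padding-bottom: 2px; }
.note { color: #666; font-style: italic; }
"

#' Render a self-contained HTML report
#'
#' Produces one deterministic HTML file (identical inputs give identical
#' bytes; no timestamps unless supplied in `subtitle`): study metadata, the
#' site-by-KRI heatmap, one section per usable assessment with embedded
#' static charts and its result table, an optional longitudinal section, and
#' an appendix listing workflows that errored or were skipped.
#'
#' @param study A `study_result`.
#' @param store Optional [snapshot_store()] for longitudinal views.
#' @param out_path Output HTML file path.
#' @param title,subtitle Report headings.
#' @return Invisibly, `out_path`.
#' @export
render_report <- function(study, store = NULL, out_path,
                          title = "Statistical monitoring report",
                          subtitle = NULL) {
  if (!inherits(study, "study_result")) stop_config("not a study_result")
  if (length(study$assessments) == 0) stop_config("study is empty")
  parts <- character()
  add <- function(...) parts <<- c(parts, ...)

  add(sprintf("<!DOCTYPE html>\n<html><head><meta charset=\"utf-8\"/><title>%s</title>",
              html_escape(title)),
      sprintf("<style>%s</style></head><body>", REPORT_CSS),
      sprintf("<h1>%s</h1>", html_escape(title)))
  if (!is.null(subtitle)) add(sprintf("<p class=\"note\">%s</p>",
                                      html_escape(subtitle)))
  st <- vapply(study$assessments, `[[`, character(1), "status")
  add(sprintf(
    "<p>Snapshot date: <b>%s</b>. Sites: %d. Subjects: %d. Workflows: %d (%d usable).</p>",
    format(study$snapshot_date), nrow(study$sites),
    sum(study$sites$n_subjects), length(st), sum(st == "ok")))

  ok_blocks <- assessment_blocks(study, "ok")
  if (length(ok_blocks) > 0) {
    add("<h2>Overview: flags by site and KRI</h2>")
    hm <- heatmap_table(study)
    metric_cols <- setdiff(names(hm), c("group_id", "country", "status",
                                        "n_subjects", "n_red", "n_amber"))
    fmt <- stats::setNames(lapply(metric_cols, function(nm) {
      function(x) {
        cls <- ifelse(is.na(x), "note",
                      ifelse(abs(x) == 2, "flag-red",
                             ifelse(abs(x) == 1, "flag-amber", "flag-green")))
        sprintf('<span class="%s">%s</span>', cls, flag_glyph(x))
      }
    }), metric_cols)
    add(html_table(hm, formatters = fmt))
  }

  for (b in ok_blocks) {
    def <- metric_def(b$spec$metric_id)
    add(sprintf("<h2>%s</h2>", html_escape(def$label)),
        sprintf("<p class=\"note\">workflow %s; method %s; grouping by %s</p>",
                html_escape(b$workflow_id), b$spec$method, b$spec$group_level))
    analysis <- attr(b$summary, "log")$analysis
    if (!is.null(analysis) && analysis$method == "normal_approx") {
      add(sprintf(
        "<p>Overall estimate %s; overdispersion &phi; = %s (raw %s); m = %d evaluable groups.</p>",
        report_num(analysis$overall_estimate), report_num(analysis$phi_used),
        report_num(analysis$phi_raw), analysis$m))
    } else if (!is.null(analysis)) {
      add(sprintf("<p>Overall estimate %s; m = %d evaluable groups.</p>",
                  report_num(analysis$overall_estimate), analysis$m))
    }
    add(embed_plot(autoplot(chart_data(b$summary, "score_bar"))),
        embed_plot(autoplot(chart_data(b$summary, "scatter"))))
    s <- as_tibble(as.data.frame(b$summary))
    s$flag <- flag_glyph(s$flag)
    add(html_table(s))
  }

  if (!is.null(store) && length(store) >= 2 && length(ok_blocks) > 0) {
    add("<h2>Longitudinal</h2>")
    for (b in ok_blocks) {
      cd <- chart_data(b$summary, "longitudinal", store = store)
      if (!is.null(cd$distribution) && nrow(cd$distribution) > 0) {
        add(sprintf("<h3>%s</h3>", html_escape(b$spec$metric_id)),
            html_table(cd$distribution))
      }
    }
  }

  other <- assessment_blocks(study, c("error", "skipped", "not_evaluable"))
  if (length(other) > 0) {
    add("<h2>Appendix: workflows without results</h2><table>",
        "<thead><tr><th>workflow</th><th>status</th><th>detail</th></tr></thead><tbody>")
    for (b in other) {
      add(sprintf("<tr><td>%s</td><td>%s</td><td>%s</td></tr>",
                  html_escape(b$workflow_id), b$status,
                  html_escape(b$note %|NA|% "")))
    }
    add("</tbody></table>")
  }
  add("</body></html>")

  con <- file(out_path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(enc2utf8(parts), con, useBytes = TRUE)
  invisible(out_path)
}
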