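study_fixture <- function(seed = 61, n_sites = 6) {
  trial <- small_trial(seed = seed, n_sites = n_sites)
  run_study(trial, default_workflows(), snapshot_date = "2024-08-01")
}

test_that("the heatmap grid has metadata plus one column per metric, with flag totals", {
  st <- study_fixture()
  hm <- heatmap_table(st)
  expect_identical(nrow(hm), 6L)
  expect_identical(names(hm)[1:6],
                   c("group_id", "country", "status", "n_subjects",
                     "n_red", "n_amber"))
  expect_identical(names(hm)[-(1:6)], list_metrics()$metric_id)
  flags <- as.matrix(hm[, -(1:6)])
  expect_identical(hm$n_red,
                   as.integer(rowSums(abs(flags) == 2, na.rm = TRUE)))
  expect_identical(hm$n_amber,
                   as.integer(rowSums(abs(flags) == 1, na.rm = TRUE)))
  # totals agree with counts recomputed from the stacked summary rows
  s <- tidy(st)
  for (g in hm$group_id) {
    expect_identical(hm$n_red[hm$group_id == g],
                     as.integer(sum(abs(s$flag[s$group_id == g]) == 2,
                                    na.rm = TRUE)))
  }
})

test_that("chart data carries the documented sort orders and points", {
  # the rates example: scatter points are (T, O) pairs
  g <- h_groups(c(2, 4, 12), c(10, 20, 30), ids = c("A", "B", "C"))
  res <- analyze_poisson(g, "rate", "ae_rate")
  flags <- assign_flags(res, default_thresholds("poisson"))
  s <- summarize_assessment(flags, res)
  a <- structure(s, class = c("assessment_summary", class(s)),
                 spec = workflow_spec("ae_rate", method = "poisson"),
                 log = list(analysis = res, flags = flags))
  sc <- chart_data(a, "scatter")
  expect_identical(sc$data$group_id, c("A", "B", "C"))
  expect_equal(sc$data$x, c(10, 20, 30))
  expect_equal(sc$data$y, c(2, 4, 12))
  expect_true(sc$axes$log_x)

  mb <- chart_data(a, "metric_bar")
  expect_equal(mb$data$y, sort(mb$data$y, decreasing = TRUE))

  sb <- chart_data(a, "score_bar")
  expect_equal(sb$data$y, sort(sb$data$y, decreasing = TRUE))

  # signed-descending sort with lexicographic tie-break
  res$groups$score <- c(1.4, -0.51, 1.4)
  flags2 <- assign_flags(res, default_thresholds("poisson"))
  s2 <- summarize_assessment(flags2, res)
  a2 <- structure(s2, class = class(a), spec = attr(a, "spec"),
                  log = list(analysis = res, flags = flags2))
  sb2 <- chart_data(a2, "score_bar")
  expect_identical(sb2$data$group_id, c("A", "C", "B"))

  expect_error(chart_data(a, "longitudinal"),
               class = "statmon_insufficient_data")
})

test_that("longitudinal chart data needs two snapshots and emits quartiles plus a series", {
  trial <- small_trial(seed = 62)
  spec <- workflow_spec("ae_rate")
  store <- snapshot_store()
  for (d in c("2024-03-31", "2024-04-30", "2024-05-31")) {
    store <- append_snapshot(store, run_study(trial, list(spec),
                                              snapshot_date = d))
  }
  a <- store$snapshots[[3]]$assessments[[1]]$summary
  site <- a$group_id[1]
  cd <- chart_data(a, "longitudinal", store = store, group_id = site)
  expect_identical(nrow(cd$distribution), 3L)
  expect_true(all(c("q1", "median", "q3") %in% names(cd$distribution)))
  expect_identical(nrow(cd$data), 3L)
  expect_s3_class(autoplot(cd), "ggplot")
})

test_that("autoplot renders every chart kind", {
  st <- study_fixture(seed = 63)
  a <- st$assessments$kri_ae_rate$summary
  for (kind in c("scatter", "metric_bar", "score_bar")) {
    expect_s3_class(autoplot(chart_data(a, kind)), "ggplot")
  }
  expect_s3_class(autoplot(attr(a, "log")$analysis), "ggplot")
})

test_that("exports produce one file per assessment plus a combined summary", {
  st <- study_fixture(seed = 64)
  dir_csv <- file.path(tempdir(), "exp-csv")
  paths <- export_results(st, "csv", dir_csv)
  expect_length(paths, 13)
  combined <- readr::read_csv(file.path(dir_csv, "study_summary.csv"),
                              show_col_types = FALSE)
  expect_identical(nrow(combined), nrow(tidy(st)))

  dir_json <- file.path(tempdir(), "exp-json")
  export_results(st, "json", dir_json)
  back <- jsonlite::fromJSON(file.path(dir_json, "kri_ae_rate.json"))
  mem <- as.data.frame(st$assessments$kri_ae_rate$summary)
  expect_equal(back$score, mem$score, tolerance = 1e-12)
  expect_equal(back$flag, mem$flag)
  expect_identical(back$group_id, mem$group_id)

  expect_error(export_results(st, "parquet", tempdir()),
               class = "statmon_config_error")
  st_empty <- st
  for (i in seq_along(st_empty$assessments)) {
    st_empty$assessments[[i]]$status <- "error"
  }
  expect_error(export_results(st_empty, "csv", tempdir()),
               class = "statmon_config_error")
})

test_that("the HTML report is deterministic and consistent with the summaries", {
  st <- study_fixture(seed = 65)
  f1 <- tempfile(fileext = ".html")
  f2 <- tempfile(fileext = ".html")
  render_report(st, out_path = f1)
  render_report(st, out_path = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  html <- readLines(f1, warn = FALSE)
  expect_identical(sum(grepl("<h2>", html)) - 1L, 12L)  # 12 metric sections
  # every score printed in a metric table appears exactly as the canonical
  # formatting of the summary value
  s <- tidy(st)
  for (v in report_num(s$score[!is.na(s$score)])) {
    expect_true(any(grepl(paste0("<td>", v, "</td>"), html, fixed = TRUE)),
                label = v)
  }

  # a study with an error workflow gains an appendix section
  specs <- default_workflows()
  specs[[2]] <- workflow_spec("sae_rate", group_level = "custom",
                              group_column = "missing_col")
  st2 <- run_study(small_trial(seed = 65), specs,
                   snapshot_date = "2024-08-01")
  f3 <- tempfile(fileext = ".html")
  render_report(st2, out_path = f3)
  html2 <- paste(readLines(f3, warn = FALSE), collapse = "\n")
  expect_match(html2, "Appendix: workflows without results")
  expect_identical(sum(grepl("<h2>", strsplit(html2, "\n")[[1]])), 13L)
})

test_that("heatmap totals are re-derivable from the exported CSVs", {
  st <- study_fixture(seed = 66)
  dir <- file.path(tempdir(), "exp-consist")
  export_results(st, "csv", dir)
  combined <- readr::read_csv(file.path(dir, "study_summary.csv"),
                              show_col_types = FALSE)
  hm <- heatmap_table(st)
  for (g in hm$group_id) {
    expect_identical(
      hm$n_red[hm$group_id == g],
      as.integer(sum(abs(combined$flag[combined$group_id == g]) == 2,
                     na.rm = TRUE)), label = g)
  }
})
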