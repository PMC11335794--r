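write_wf_yaml <- function(lines, name = "wf.yaml") {
  dir <- file.path(tempdir(), paste0("wf-", as.integer(stats::runif(1, 1, 1e8))))
  dir.create(dir)
  writeLines(lines, file.path(dir, name))
  dir
}

test_that("workflow YAML parsing fills defaults and validates pairings", {
  dir <- write_wf_yaml("metric: ae_rate")
  specs <- load_workflows(dir)
  expect_length(specs, 1)
  s <- specs[[1]]
  expect_identical(s$metric_id, "ae_rate")
  expect_identical(s$method, "normal_approx")
  expect_identical(s$group_level, "site")
  expect_equal(s$thresholds$amber, 2)
  expect_equal(s$thresholds$red, 3)

  dir2 <- write_wf_yaml(c(
    "workflow_id: ae_randomized_treated",
    "metric: ae_rate",
    "filters:",
    "  - {domain: dm, column: randomized_flag, op: eq, value: 'Y'}",
    "  - {domain: dm, column: treated_flag, op: eq, value: 'Y'}"))
  s2 <- load_workflows(dir2)[[1]]
  expect_length(s2$filters, 2)
  expect_identical(s2$filters[[1]]$column, "randomized_flag")

  dir3 <- write_wf_yaml(c("metric: ae_rate", "method: fisher"))
  expect_error(load_workflows(dir3), "fisher",
               class = "statmon_config_error")
  dir4 <- write_wf_yaml("metric: nonesuch")
  expect_error(load_workflows(dir4), "nonesuch",
               class = "statmon_config_error")
  expect_error(workflow_spec("subj_disc", method = "poisson"),
               class = "statmon_config_error")
})

test_that("run_assessment is deterministic and logs every stage artifact", {
  trial <- small_trial(seed = 31)
  spec <- workflow_spec("ae_rate")
  a <- run_assessment(trial, spec, snapshot_date = "2024-08-01")
  b <- run_assessment(trial, spec, snapshot_date = "2024-08-01")
  expect_identical(as.data.frame(a), as.data.frame(b))
  log <- attr(a, "log")
  expect_true(all(c("input", "groups", "analysis", "flags") %in% names(log)))
  expect_s3_class(log$analysis, "kri_analysis")
  expect_identical(nrow(a), length(unique(trial$dm$site_id)))
})

test_that("country grouping aggregates member sites", {
  trial <- small_trial(seed = 32, n_sites = 8)
  site <- run_assessment(trial, workflow_spec("ae_rate"))
  ctry <- run_assessment(trial, workflow_spec("ae_rate",
                                              group_level = "country"))
  lookup <- unique(trial$dm[, c("site_id", "country")])
  for (cc in unique(ctry$group_id)) {
    members <- lookup$site_id[lookup$country == cc]
    expect_equal(ctry$numerator[ctry$group_id == cc],
                 sum(site$numerator[site$group_id %in% members]), label = cc)
    expect_equal(ctry$denominator[ctry$group_id == cc],
                 sum(site$denominator[site$group_id %in% members]))
  }
})

test_that("a two-site study is reported not evaluable, not an error", {
  trial <- small_trial(seed = 33, n_sites = 2)
  a <- run_assessment(trial, workflow_spec("ae_rate"))
  expect_identical(attr(a, "status"), "not_evaluable")
  expect_match(attr(a, "note"), "m > 2")
  expect_identical(nrow(a), 0L)
})

test_that("data-check errors block the workflow unless overridden", {
  trial <- corrupt_domains(small_trial(seed = 34), "negative_duration")
  expect_error(run_assessment(trial, workflow_spec("ae_rate")),
               class = "statmon_check_error")
  a <- run_assessment(trial, workflow_spec("ae_rate"),
                      override_checks = TRUE)
  expect_identical(attr(a, "status"), "ok")
})

test_that("run_study isolates workflow failures and never drops them", {
  trial <- small_trial(seed = 35)
  specs <- default_workflows()
  st <- run_study(trial, specs)
  expect_length(st$assessments, 12)
  expect_true(all(vapply(st$assessments, `[[`, character(1), "status") == "ok"))

  # sabotage one workflow: a custom grouping column that does not exist
  specs[[3]] <- workflow_spec("g3lab_rate", group_level = "custom",
                              group_column = "no_such_column")
  st2 <- run_study(trial, specs)
  statuses <- vapply(st2$assessments, `[[`, character(1), "status")
  expect_identical(sum(statuses == "ok"), 11L)
  expect_identical(unname(statuses[3]), "error")
  expect_match(st2$assessments[[3]]$note, "no_such_column")

  expect_error(run_study(trial, list()), class = "statmon_config_error")
})

test_that("workflows needing the audit field domain are skipped when it is absent", {
  trial <- small_trial(seed = 36)
  trial$fd <- NULL
  w <- capture_warnings(st <- run_study(trial, default_workflows()))
  expect_length(w, 2)
  expect_match(w, "fd", all = TRUE)
  statuses <- vapply(st$assessments, `[[`, character(1), "status")
  expect_identical(unname(statuses[c("kri_query_rate", "kri_datachg_rate")]),
                   c("skipped", "skipped"))
  expect_identical(sum(statuses == "ok"), 10L)
})

test_that("an assessment run inside a study equals the standalone run", {
  trial <- small_trial(seed = 37)
  spec <- workflow_spec("sae_rate")
  st <- run_study(trial, list(spec), snapshot_date = "2024-08-01")
  standalone <- run_assessment(trial, spec, snapshot_date = "2024-08-01")
  strip <- function(x) {
    x <- as.data.frame(x)
    attributes(x) <- attributes(x)[c("names", "row.names", "class")]
    x
  }
  expect_identical(strip(st$assessments[[1]]$summary), strip(standalone))
})

test_that("identity stage injection leaves the pipeline output unchanged", {
  trial <- small_trial(seed = 38)
  spec <- workflow_spec("ae_rate")
  base <- run_assessment(trial, spec, snapshot_date = "2024-08-01")
  identity_stages <- list(
    transform = function(inputs, spec) aggregate_groups(inputs, spec$metric_id),
    flag = function(result, spec) assign_flags(result, spec$thresholds)
  )
  injected <- run_assessment(trial, spec, snapshot_date = "2024-08-01",
                             stages = identity_stages)
  expect_identical(as.data.frame(base), as.data.frame(injected))

  # a real replacement changes only its own stage's consequences
  doubled <- run_assessment(trial, spec, snapshot_date = "2024-08-01",
                            stages = list(
                              input = function(domains, spec, snapshot_date) {
                                inp <- build_subject_input(
                                  domains, spec$metric_id, spec$group_level,
                                  spec$filters, snapshot_date)
                                inp$numerator <- inp$numerator * 2
                                inp$denominator <- inp$denominator * 2
                                inp
                              }))
  expect_equal(sort(doubled$numerator), sort(base$numerator * 2))
})

test_that("a filter excluding k contributing subjects drops participant totals by k", {
  trial <- small_trial(seed = 39)
  base <- run_assessment(trial, workflow_spec("ae_rate"))
  filt <- workflow_spec("ae_rate", workflow_id = "ae_randomized",
                        filters = list(filter_spec("dm", "randomized_flag",
                                                   "eq", "Y")))
  sub <- run_assessment(trial, filt)
  # subjects excluded by the filter that were contributing exposure
  k <- sum(trial$dm$randomized_flag != "Y" & trial$dm$days_on_study > 0)
  expect_identical(as.integer(sum(base$n) - sum(sub$n)), as.integer(k))
  expect_gt(k, 0L)
})

test_that("snapshot stores enforce strictly increasing dates and yield series", {
  trial <- small_trial(seed = 40)
  st1 <- run_study(trial, list(workflow_spec("ae_rate")),
                   snapshot_date = "2024-03-31")
  st2 <- run_study(trial, list(workflow_spec("ae_rate")),
                   snapshot_date = "2024-04-30")
  st3 <- run_study(trial, list(workflow_spec("ae_rate")),
                   snapshot_date = "2024-05-31")
  store <- append_snapshot(snapshot_store(), st1)
  expect_length(store, 1)
  store <- append_snapshot(append_snapshot(store, st2), st3)
  expect_length(store, 3)
  site <- tidy(st1)$group_id[1]
  series <- extract_series(store, site, "ae_rate")
  expect_identical(nrow(series), 3L)
  expect_identical(series$snapshot_date,
                   as.Date(c("2024-03-31", "2024-04-30", "2024-05-31")))
  expect_error(append_snapshot(store, st1), class = "statmon_config_error")
})
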