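# Frozen expected values below were computed with oracle_normal_approx /
# oracle_deviance / exact hypergeometric enumeration before wiring them to
# the implementation.

test_that("the rate worked example reproduces (2/10, 4/20, 12/30 events/days)", {
  g <- h_groups(c(2, 4, 12), c(10, 20, 30), ids = c("A", "B", "C"),
                n = c(1, 2, 3))
  res <- analyze_normal_approx(g, "rate", "ae_rate")
  expect_equal(res$overall_estimate, 0.3)
  ora <- oracle_normal_approx(c(2, 4, 12), c(10, 20, 30), "rate")
  expect_equal(ora$z, c(-0.57735027, -0.81649658, 1), tolerance = 1e-8)
  expect_equal(res$phi_raw, 2 / 3, tolerance = 1e-12)
  expect_equal(res$phi_used, 1)
  # under-dispersion clamps to 1, so scores equal the unadjusted z
  expect_equal(res$groups$score, ora$z, tolerance = 1e-12)
})

test_that("the percentage worked example reproduces (2/10, 3/10, 8/10)", {
  g <- h_groups(c(2, 3, 8), c(10, 10, 10))
  res <- analyze_normal_approx(g, "percentage", "subj_disc")
  ora <- oracle_normal_approx(c(2, 3, 8), c(10, 10, 10), "percentage")
  expect_equal(res$overall_estimate, 13 / 30, tolerance = 1e-12)
  expect_equal(ora$z, c(-1.48902470, -0.85087126, 2.33989596),
               tolerance = 1e-7)
  expect_equal(res$phi_raw, 2.80542986, tolerance = 1e-7)
  expect_equal(res$groups$score, c(-0.88900089, -0.50800051, 1.39700140),
               tolerance = 1e-7)
  expect_equal(res$groups$score, ora$zadj, tolerance = 1e-12)
  # a group sitting exactly at the pooled estimate scores exactly zero
  g0 <- h_groups(c(2, 4, 3), c(10, 10, 10))
  res0 <- analyze_normal_approx(g0, "percentage")
  expect_identical(res0$groups$score[res0$groups$group_id == "S03"], 0)
  expect_identical(res0$groups$direction[res0$groups$group_id == "S03"], 0)
})

test_that("phi is the mean squared unadjusted z, clamped below at one", {
  expect_equal(overdispersion_phi(c(1, -1, 1)),
               list(phi_raw = 1, phi_clamped = 1))
  expect_equal(overdispersion_phi(c(-1.4890247, -0.8508713, 2.3398960))$phi_raw,
               2.8054299, tolerance = 1e-5)
  expect_equal(overdispersion_phi(c(0.1, -0.1, 0.1)),
               list(phi_raw = 0.01, phi_clamped = 1))
})

test_that("adjusted scores satisfy z' = z / sqrt(phi*) and renormalize", {
  set.seed(101)
  for (rep in 1:25) {
    m <- sample(3:12, 1)
    type <- sample(c("rate", "percentage"), 1)
    den <- if (type == "rate") sample(20:80, m) else sample(10:50, m)
    num <- if (type == "rate") rpois(m, lambda = 0.2 * den) else
      rbinom(m, den, 0.3)
    if (sum(num) == 0 || (type == "percentage" && sum(num) == sum(den))) next
    g <- h_groups(num, den)
    res <- analyze_normal_approx(g, type)
    ora <- oracle_normal_approx(num, den, type)
    expect_equal(res$groups$score, ora$z / sqrt(res$phi_used),
                 tolerance = 1e-12)
    if (res$phi_raw > 1) {
      expect_equal(mean(res$groups$score^2), 1, tolerance = 1e-9)
    }
  }
})

test_that("normal-approximation scores match the formula-direct oracle on random instances", {
  set.seed(7)
  tried <- 0
  while (tried < 200) {
    m <- sample(3:12, 1)
    type <- sample(c("rate", "percentage"), 1)
    den <- if (type == "rate") sample(10:200, m, replace = TRUE) else
      sample(5:50, m, replace = TRUE)
    num <- if (type == "rate") pmin(rpois(m, 0.15 * den), 50) else
      rbinom(m, den, runif(1, 0.05, 0.6))
    if (sum(num) == 0 || (type == "percentage" && sum(num) >= sum(den))) next
    tried <- tried + 1
    res <- analyze_normal_approx(h_groups(num, den), type)
    ora <- oracle_normal_approx(num, den, type)
    expect_equal(res$overall_estimate, ora$theta0, tolerance = 1e-10)
    expect_equal(res$phi_raw, ora$phi_raw, tolerance = 1e-10)
    expect_equal(res$groups$score, ora$zadj, tolerance = 1e-10)
  }
})

test_that("degenerate pooled estimates and m <= 2 are refused with advice", {
  expect_error(analyze_normal_approx(h_groups(c(1, 2), c(10, 10)), "percentage"),
               "m > 2", class = "statmon_method_error")
  expect_error(analyze_normal_approx(h_groups(c(0, 0, 0), c(10, 10, 10)),
                                     "percentage"),
               class = "statmon_degenerate_error")
  expect_error(analyze_normal_approx(h_groups(c(10, 10, 10), c(10, 10, 10)),
                                     "percentage"),
               class = "statmon_degenerate_error")
  expect_error(analyze_normal_approx(h_groups(c(0, 0, 0), c(10, 10, 10)),
                                     "rate"),
               class = "statmon_degenerate_error")
})

test_that("groups with no denominator are excluded from m and reported not evaluable", {
  g <- h_groups(c(2, 3, 8, 0), c(10, 10, 10, 0))
  res <- analyze_normal_approx(g, "percentage")
  expect_identical(res$m, 3L)
  expect_equal(res$phi_raw, 2.80542986, tolerance = 1e-7)
  ne <- res$groups[res$groups$status == "not_evaluable", ]
  expect_identical(nrow(ne), 1L)
  expect_true(is.na(ne$score))
})

test_that("scaling counts and exposures by k preserves estimates and grows |z|", {
  num <- c(2, 4, 12); den <- c(10, 20, 30)
  base <- analyze_normal_approx(h_groups(num, den), "rate")
  ora0 <- oracle_normal_approx(num, den, "rate")
  for (k in c(2, 5)) {
    scaled <- analyze_normal_approx(h_groups(k * num, k * den), "rate")
    orak <- oracle_normal_approx(k * num, k * den, "rate")
    expect_equal(scaled$overall_estimate, base$overall_estimate)
    expect_equal(scaled$groups$observed_metric, base$groups$observed_metric)
    expect_true(all(abs(orak$z) >= abs(ora0$z)))
  }
})

test_that("Fisher p-values match enumeration, fisher.test, and exact rational arithmetic", {
  # the observed table at the hypergeometric mode has two-sided p = 1
  res <- analyze_fisher(h_groups(c(2, 4), c(10, 20)))
  expect_equal(res$groups$p_value[1], 1)

  # 9/10 versus 3/20: exhaustive enumeration over margins (10,20; 12,18)
  res2 <- analyze_fisher(h_groups(c(9, 3), c(10, 20)))
  p_site <- res2$groups$p_value[res2$groups$group_id == "S01"]
  expect_equal(p_site, 1.3399893e-4, tolerance = 1e-6)
  expect_equal(p_site, 4026 / 30045015, tolerance = 1e-12)
  expect_equal(p_site,
               stats::fisher.test(matrix(c(9, 1, 3, 17), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  expect_true(res2$groups$score[1] > 0)
  expect_identical(res2$groups$direction[1], 1)

  # no events anywhere: degenerate all-zero column
  res3 <- analyze_fisher(h_groups(c(0, 0), c(5, 25)))
  expect_equal(res3$groups$p_value, c(1, 1))
  expect_identical(res3$groups$direction, c(0, 0))

  expect_error(analyze_fisher(h_groups(c(1, 2, 3), c(10, 10, 10)), "rate"),
               class = "statmon_method_error")

  set.seed(33)
  tables <- NULL
  while (is.null(tables) || nrow(tables) < 40) {
    N <- sample(10:60, 1)
    n <- sample(2:(N - 2), 1)
    k <- sample(1:(N - 1), 1)
    a <- sample(max(0, n - (N - k)):min(n, k), 1)
    tables <- rbind(tables, c(a, n, k, N))
  }
  exact <- oracle_fisher_exact_py(tables)
  mine <- vapply(seq_len(nrow(tables)), function(i) {
    statmon:::fisher_p_two_sided(tables[i, 1], tables[i, 2], tables[i, 3],
                                 tables[i, 4])
  }, numeric(1))
  expect_equal(mine, exact, tolerance = 1e-12)
})

test_that("Poisson deviance residuals match the closed form", {
  # sites A 2/10, B 4/20, C 12/30: pooled rate 0.3, E = (3, 6, 9)
  g <- h_groups(c(2, 4, 12), c(10, 20, 30), ids = c("A", "B", "C"))
  res <- analyze_poisson(g, "rate", "ae_rate")
  expect_equal(res$overall_estimate, 0.3, tolerance = 1e-9)
  expect_equal(res$groups$score[res$groups$group_id == "C"],
               0.95098356, tolerance = 1e-6)
  expect_equal(res$groups$score,
               vapply(1:3, function(i) oracle_deviance(c(2, 4, 12)[i],
                                                       0.3 * c(10, 20, 30)[i]),
                      numeric(1)),
               tolerance = 1e-8)

  # a group observed at its expectation has residual zero
  res2 <- analyze_poisson(h_groups(c(3, 6, 9), c(10, 20, 30)), "rate")
  expect_equal(res2$groups$score[3], 0, tolerance = 1e-7)

  # a zero-count group tends to -sqrt(2E)
  expect_equal(oracle_deviance(0, 2.5), -sqrt(5))
  g3 <- h_groups(c(0, 5, 5), c(25, 25, 25))
  res3 <- analyze_poisson(g3, "rate")
  e1 <- res3$overall_estimate * 25
  expect_equal(res3$groups$score[1], -sqrt(2 * e1), tolerance = 1e-8)

  expect_error(analyze_poisson(h_groups(c(1, 2), c(10, 10)), "percentage"),
               class = "statmon_method_error")
  expect_error(analyze_poisson(h_groups(c(0, 0), c(10, 10)), "rate"),
               class = "statmon_degenerate_error")
})

test_that("tidy and glance expose the analysis in rectangular form", {
  res <- analyze_normal_approx(h_groups(c(2, 3, 8), c(10, 10, 10)),
                               "percentage", "subj_disc")
  td <- tidy(res)
  expect_identical(nrow(td), 3L)
  expect_identical(td$metric_id[1], "subj_disc")
  gl <- glance(res)
  expect_identical(nrow(gl), 1L)
  expect_equal(gl$phi_raw, res$phi_raw)
  expect_identical(gl$m, 3L)
})
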