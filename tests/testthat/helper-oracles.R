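# Independent oracles and compact fixture builders shared across tests.

# Straight-from-the-formulas re-implementation of the overdispersion-adjusted
# normal approximation, written with explicit loops and no shared code with
# the package internals.
oracle_normal_approx <- function(num, den, type) {
  m <- length(num)
  y <- num / den
  theta0 <- sum(num) / sum(den)
  v <- numeric(m)
  for (i in seq_len(m)) {
    v[i] <- if (type == "percentage") theta0 * (1 - theta0) / den[i]
    else theta0 / den[i]
  }
  z <- numeric(m)
  for (i in seq_len(m)) z[i] <- (y[i] - theta0) / sqrt(v[i])
  phi <- sum(z^2) / m
  phistar <- if (phi < 1) 1 else phi
  zadj <- numeric(m)
  for (i in seq_len(m)) zadj[i] <- (y[i] - theta0) / sqrt(phistar * v[i])
  list(theta0 = theta0, z = z, phi_raw = phi, phi_used = phistar, zadj = zadj)
}

# Closed-form Poisson deviance residual.
oracle_deviance <- function(o, e) {
  term <- if (o == 0) 0 else o * log(o / e)
  sign(o - e) * sqrt(2 * (term - (o - e)))
}

# Exact rational-arithmetic two-sided Fisher p via the system python
# (fractions module); tables supplied as a matrix with columns a, n, k, N.
oracle_fisher_exact_py <- function(tables) {
  infile <- tempfile()
  write.table(tables, infile, row.names = FALSE, col.names = FALSE)
  script <- '
import sys
from fractions import Fraction
from math import comb
for line in open(sys.argv[1]):
    a, n, k, N = map(int, line.split())
    lo, hi = max(0, n - (N - k)), min(n, k)
    probs = {x: Fraction(comb(k, x) * comb(N - k, n - x), comb(N, n))
             for x in range(lo, hi + 1)}
    p = sum(pr for pr in probs.values() if pr <= probs[a])
    print(repr(float(p)))
'
  sfile <- tempfile(fileext = ".py")
  writeLines(script, sfile)
  out <- system2("python", c(sfile, infile), stdout = TRUE)
  as.numeric(out)
}

python_available <- function() {
  nzchar(Sys.which("python"))
}

# -- fixture builders ---------------------------------------------------------

as_dom <- function(df, id) statmon:::new_domain_table(tibble::as_tibble(df), id)

# A demographics table: one row per subject; defaults enroll everyone.
h_dm <- function(subject_id, site_id, country = "USA", days = 30L,
                 enrolled = "Y", randomized = enrolled, treated = enrolled,
                 screen_fail = ifelse(enrolled == "Y", "N", "Y")) {
  as_dom(data.frame(
    subject_id = subject_id, site_id = site_id, country = country,
    enrolled_flag = enrolled, randomized_flag = randomized,
    treated_flag = treated, screen_failure_flag = screen_fail,
    days_on_study = as.integer(days)
  ), "dm")
}

# An adverse-event table from per-subject counts.
h_ae <- function(subject_id, n_events, serious = "N") {
  idx <- rep(seq_along(subject_id), n_events)
  as_dom(data.frame(
    subject_id = subject_id[idx],
    event_seq = unlist(lapply(n_events, seq_len)),
    serious_flag = rep(serious, length.out = length(idx))
  ), "ae")
}

# Group summaries straight from numerator/denominator vectors.
h_groups <- function(num, den, ids = sprintf("S%02d", seq_along(num)),
                     n = den) {
  tibble::tibble(
    group_id = ids, n_participants = as.integer(n),
    total_numerator = as.numeric(num), total_denominator = as.numeric(den),
    observed_metric = ifelse(den > 0, num / den, NA_real_)
  )
}

# Small complete trial used by several suites.
small_trial <- function(seed = 42, n_sites = 6, ...) {
  simulate_trial(sim_params(n_sites = n_sites, seed = seed, ...))
}
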