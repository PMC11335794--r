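# Synthetic-trial simulator. Generates all standardized domains for a
# multi-site trial with multiplicative log-normal site heterogeneity and
# optional injected at-risk sites, so the whole monitoring pipeline is
# testable without any external data. Rate-type outcomes are Poisson in
# exposure days; percentage-type outcomes are Bernoulli per opportunity with
# probabilities clamped to [0, 0.99] so large site effects or injections
# keep draws valid. A single global seed drives a per-domain, per-site
# stream-split RNG, so restricting or adding domains never perturbs the
# draws of the others.

SIM_COUNTRIES <- c("USA", "DEU", "JPN", "BRA", "POL", "ZAF")

DOMAIN_STREAM <- c(structure_ = 0L, dm = 1L, ae = 2L, lb = 3L, pd = 4L,
                   ds = 5L, fv = 6L, qr = 7L, fd = 8L)

INJECTION_PARAM <- c(
  ae_rate = "lambda_ae", sae_rate = "lambda_sae", g3lab_rate = "p_g3lab",
  pd_rate = "lambda_pd", ipd_rate = "lambda_ipd", subj_disc = "p_disc",
  trt_disc = "p_trt_disc", query_rate = "p_query",
  query_age = "p_aged_query", entry_lag = "p_late_entry",
  datachg_rate = "p_field_change", screen_fail = "p_screen_fail"
)

#' Simulation parameters for a synthetic trial
#'
#' Defaults describe a mid-size phase-2/3 style study: 20 sites of about 30
#' subjects each followed for roughly 90 days, with baseline risk-indicator
#' levels in the ranges routinely seen in trial operations (about 0.1
#' adverse events per subject-day, 1 serious event per 100 subject-days,
#' 5% grade-3+ lab samples, 15% screen failure, and so on) and a log-normal
#' site effect of `site_sd = 0.2` on every rate and probability.
#'
#' @param n_sites Number of sites.
#' @param subjects_per_site Length-2 integer range; each site's enrollment is
#'   drawn uniformly from it.
#' @param exposure_days Length-2 range of per-subject days on study.
#' @param lambda_ae,lambda_sae Adverse / serious adverse events per
#'   subject-day (`lambda_sae < lambda_ae`; serious events are a subset).
#' @param p_g3lab Probability a lab sample is grade 3+ abnormal.
#' @param lambda_pd,lambda_ipd Non-important / important protocol deviations
#'   per subject-day.
#' @param p_disc,p_trt_disc Probability an enrolled subject discontinues the
#'   study / the treatment.
#' @param p_query Probability a data field receives a query.
#' @param p_aged_query Probability a query stays open more than 30 days.
#' @param p_late_entry Probability a form is entered more than 10 days after
#'   the visit.
#' @param p_field_change Probability a field is changed at least once.
#' @param p_screen_fail Probability a screened subject fails screening.
#' @param site_sd Standard deviation of the Normal site effect `b_i`; rates
#'   and probabilities are multiplied by `exp(b_i)`.
#' @param risk_injections List of `list(site =, metric =, multiplier =)`
#'   entries; the multiplier scales the named metric's baseline rate or
#'   probability at that site (site given as index or `"S0xx"` id).
#' @param seed Integer seed; the run is fully deterministic given it.
#' @param samples_per_subject,forms_per_subject Length-2 ranges of lab
#'   samples and CRF forms per enrolled subject.
#' @param fields_per_form Data fields per form (fixed).
#' @param p_query_closed Probability a query has been closed by the
#'   snapshot.
#' @param start_date Study start date (all subjects enroll at start).
#' @param snapshot_date Data-cut date; defaults to `start_date + 240` days.
#' @return A validated `sim_params` object.
#' @export
sim_params <- function(n_sites = 20,
                       subjects_per_site = c(25, 35),
                       exposure_days = c(60, 120),
                       lambda_ae = 0.10,
                       lambda_sae = 0.01,
                       p_g3lab = 0.05,
                       lambda_pd = 0.02,
                       lambda_ipd = 0.005,
                       p_disc = 0.15,
                       p_trt_disc = 0.20,
                       p_query = 0.05,
                       p_aged_query = 0.25,
                       p_late_entry = 0.10,
                       p_field_change = 0.10,
                       p_screen_fail = 0.15,
                       site_sd = 0.2,
                       risk_injections = list(),
                       seed = 1L,
                       samples_per_subject = c(4, 12),
                       forms_per_subject = c(6, 12),
                       fields_per_form = 25,
                       p_query_closed = 0.7,
                       start_date = as.Date("2024-01-01"),
                       snapshot_date = NULL) {
  p <- as.list(environment())
  p$snapshot_date <- as.Date(snapshot_date %||% (as.Date(start_date) + 240))
  p$start_date <- as.Date(start_date)

  probs <- c("p_g3lab", "p_disc", "p_trt_disc", "p_query", "p_aged_query",
             "p_late_entry", "p_field_change", "p_screen_fail",
             "p_query_closed")
  for (nm in probs) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop_config("'%s' must be in [0, 1]", nm)
  }
  for (nm in c("lambda_ae", "lambda_sae", "lambda_pd", "lambda_ipd")) {
    if (p[[nm]] < 0) stop_config("'%s' must be >= 0", nm)
  }
  if (p$site_sd < 0) stop_config("'site_sd' must be >= 0")
  if (p$n_sites < 1) stop_config("'n_sites' must be >= 1")
  for (inj in p$risk_injections) {
    if (is.null(inj$site) || is.null(inj$metric) || is.null(inj$multiplier)) {
      stop_config("each risk injection needs site, metric and multiplier")
    }
    if (!inj$metric %in% names(INJECTION_PARAM)) {
      stop_config("risk injection on unknown metric '%s'", inj$metric)
    }
    if (inj$multiplier <= 0) stop_config("injection multiplier must be > 0")
  }
  structure(p, class = "sim_params")
}

site_label <- function(i) sprintf("S%03d", i)

clamp_prob <- function(p) pmin(pmax(p, 0), 0.99)

# Multiplier applied to `param` at site i from the injection list.
injection_mult <- function(params, param, i) {
  m <- 1
  for (inj in params$risk_injections) {
    site <- inj$site
    if (is.character(site)) site <- match(site, site_label(seq_len(params$n_sites)))
    if (identical(as.integer(site), as.integer(i)) &&
        INJECTION_PARAM[[inj$metric]] == param) {
      m <- m * inj$multiplier
    }
  }
  m
}

with_stream <- function(params, domain, site, expr) {
  set.seed(substream_seed(params$seed, DOMAIN_STREAM[[domain]], site))
  force(expr)
}

sample_range <- function(range, n) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n) else
    as.integer(range[1]) + sample.int(as.integer(range[2] - range[1] + 1), n,
                                      replace = TRUE) - 1L
}

#' Simulate a complete synthetic trial
#'
#' Generates standardized subject-level domain tables for a multi-site
#' trial under the model described in [sim_params()]: per-site effect
#' `b_i ~ Normal(0, site_sd^2)`; per enrolled subject, exposure uniform in
#' range, event counts Poisson with mean `rate * exp(b_i) * exposure`, and
#' binary outcomes Bernoulli with probability `clamp(p * exp(b_i))`. Risk
#' injections multiply the target site's rate or probability. The output
#' passes [check_data()] with zero error findings and is fully deterministic
#' given the seed.
#'
#' @param params A [sim_params()] object.
#' @param domains Which domains to generate (default all eight, including
#'   the optional audit-style `fd`); `dm` is always generated.
#' @return Named list of domain tables; the parameters are attached as
#'   attribute `"params"` and site effects as `"site_effects"`.
#' @export
#' @examples
#' trial <- simulate_trial(sim_params(n_sites = 5, seed = 7))
#' names(trial)
simulate_trial <- function(params = sim_params(),
                           domains = c("dm", "ae", "lb", "pd", "qr", "fv",
                                       "ds", "fd")) {
  if (!inherits(params, "sim_params")) stop_config("'params' must be sim_params")
  domains <- match.arg(domains, several.ok = TRUE)
  domains <- union("dm", domains)
  ns <- params$n_sites

  site_eff <- with_stream(params, "structure_", 0L, {
    n_subj <- sample_range(params$subjects_per_site, ns)
    b <- rnorm(ns, 0, params$site_sd)
    list(b = b, n_subj = n_subj)
  })
  b <- site_eff$b

  # Per-site subject structure (enrollment, exposure, form counts) drawn in
  # the dm stream; event domains reuse it without consuming dm draws.
  structure_by_site <- lapply(seq_len(ns), function(i) {
    with_stream(params, "dm", i, {
      n <- site_eff$n_subj[i]
      sf <- runif(n) < clamp_prob(params$p_screen_fail *
                                    injection_mult(params, "p_screen_fail", i) *
                                    exp(b[i]))
      enrolled <- !sf
      rand <- enrolled & runif(n) < 0.97
      trt <- rand & runif(n) < 0.98
      days <- ifelse(enrolled, sample_range(params$exposure_days, n), 0L)
      forms <- ifelse(enrolled, sample_range(params$forms_per_subject, n), 0L)
      tibble(
        subject_id = sprintf("%s-%04d", site_label(i), seq_len(n)),
        site_id = site_label(i),
        country = SIM_COUNTRIES[(i - 1L) %% length(SIM_COUNTRIES) + 1L],
        enrolled_flag = ifelse(enrolled, "Y", "N"),
        randomized_flag = ifelse(rand, "Y", "N"),
        treated_flag = ifelse(trt, "Y", "N"),
        screen_failure_flag = ifelse(sf, "Y", "N"),
        days_on_study = as.integer(days),
        n_forms = as.integer(forms)
      )
    })
  })
  dm_full <- bind_rows(structure_by_site)
  out <- list(dm = new_domain_table(
    dm_full[setdiff(names(dm_full), "n_forms")], "dm",
    provenance = list(source = "simulate_trial", seed = params$seed)))

  enrolled_site <- lapply(structure_by_site, function(s) {
    s[s$enrolled_flag == "Y" & s$days_on_study > 0, ]
  })

  seq_rows <- function(subject_id, counts, seq_col, extra) {
    idx <- rep.int(seq_along(counts), counts)
    df <- tibble(subject_id = subject_id[idx])
    df[[seq_col]] <- as.integer(unlist(lapply(counts, seq_len), use.names = FALSE))
    for (nm in names(extra)) df[[nm]] <- extra[[nm]]
    df
  }

  if ("ae" %in% domains) {
    out$ae <- new_domain_table(bind_rows(lapply(seq_len(ns), function(i) {
      with_stream(params, "ae", i, {
        s <- enrolled_site[[i]]
        r_sae <- params$lambda_sae * injection_mult(params, "lambda_sae", i)
        r_tot <- params$lambda_ae * injection_mult(params, "lambda_ae", i)
        mu_sae <- r_sae * exp(b[i]) * s$days_on_study
        mu_ns <- pmax(r_tot - r_sae, 0) * exp(b[i]) * s$days_on_study
        n_sae <- rpois(nrow(s), mu_sae)
        n_ns <- rpois(nrow(s), mu_ns)
        seq_rows(s$subject_id, n_sae + n_ns, "event_seq", list(
          serious_flag = unlist(lapply(seq_len(nrow(s)), function(j) {
            c(rep("Y", n_sae[j]), rep("N", n_ns[j]))
          }), use.names = FALSE) %||% character()
        ))
      })
    })), "ae")
  }

  if ("lb" %in% domains) {
    out$lb <- new_domain_table(bind_rows(lapply(seq_len(ns), function(i) {
      with_stream(params, "lb", i, {
        s <- enrolled_site[[i]]
        n_samp <- sample_range(params$samples_per_subject, nrow(s))
        p <- clamp_prob(params$p_g3lab * injection_mult(params, "p_g3lab", i) *
                          exp(b[i]))
        total <- sum(n_samp)
        g3 <- runif(total) < p
        grade <- ifelse(g3, sample(3:5, total, replace = TRUE),
                        sample(0:2, total, replace = TRUE))
        seq_rows(s$subject_id, n_samp, "sample_seq",
                 list(toxicity_grade = as.integer(grade)))
      })
    })), "lb")
  }

  if ("pd" %in% domains) {
    out$pd <- new_domain_table(bind_rows(lapply(seq_len(ns), function(i) {
      with_stream(params, "pd", i, {
        s <- enrolled_site[[i]]
        mu_np <- params$lambda_pd * injection_mult(params, "lambda_pd", i) *
          exp(b[i]) * s$days_on_study
        mu_ip <- params$lambda_ipd * injection_mult(params, "lambda_ipd", i) *
          exp(b[i]) * s$days_on_study
        n_np <- rpois(nrow(s), mu_np)
        n_ip <- rpois(nrow(s), mu_ip)
        seq_rows(s$subject_id, n_np + n_ip, "deviation_seq", list(
          important_flag = unlist(lapply(seq_len(nrow(s)), function(j) {
            c(rep("N", n_np[j]), rep("Y", n_ip[j]))
          }), use.names = FALSE) %||% character()
        ))
      })
    })), "pd")
  }

  if ("ds" %in% domains) {
    out$ds <- new_domain_table(bind_rows(lapply(seq_len(ns), function(i) {
      with_stream(params, "ds", i, {
        s <- enrolled_site[[i]]
        pd_ <- clamp_prob(params$p_disc * injection_mult(params, "p_disc", i) *
                            exp(b[i]))
        pt_ <- clamp_prob(params$p_trt_disc *
                            injection_mult(params, "p_trt_disc", i) * exp(b[i]))
        disc <- runif(nrow(s)) < pd_
        # discontinuing the study implies discontinuing treatment
        tdisc <- disc | runif(nrow(s)) < pt_
        tibble(subject_id = s$subject_id,
               study_discontinued_flag = ifelse(disc, "Y", "N"),
               treatment_discontinued_flag = ifelse(tdisc, "Y", "N"))
      })
    })), "ds")
  }

  if ("fv" %in% domains) {
    out$fv <- new_domain_table(bind_rows(lapply(seq_len(ns), function(i) {
      with_stream(params, "fv", i, {
        s <- enrolled_site[[i]]
        p_late <- clamp_prob(params$p_late_entry *
                               injection_mult(params, "p_late_entry", i) *
                               exp(b[i]))
        bind_rows(lapply(seq_len(nrow(s)), function(j) {
          nf <- s$n_forms[j]
          if (nf == 0) return(NULL)
          offs <- sort(sample.int(max(s$days_on_study[j], 1), nf,
                                  replace = TRUE)) - 1L
          late <- runif(nf) < p_late
          lag <- ifelse(late, 11L + rpois(nf, 5), sample(0:10, nf,
                                                         replace = TRUE))
          tibble(subject_id = s$subject_id[j], form_seq = seq_len(nf),
                 visit_date = params$start_date + offs,
                 entry_date = params$start_date + offs + as.integer(lag))
        }))
      })
    })), "fv")
  }

  if ("qr" %in% domains) {
    out$qr <- new_domain_table(bind_rows(lapply(seq_len(ns), function(i) {
      with_stream(params, "qr", i, {
        s <- enrolled_site[[i]]
        p_q <- clamp_prob(params$p_query * injection_mult(params, "p_query", i) *
                            exp(b[i]))
        p_aged <- clamp_prob(params$p_aged_query *
                               injection_mult(params, "p_aged_query", i) *
                               exp(b[i]))
        n_fields <- s$n_forms * params$fields_per_form
        n_q <- rbinom(nrow(s), n_fields, p_q)
        total <- sum(n_q)
        aged <- runif(total) < p_aged
        age <- ifelse(aged, 31L + sample(0:59, total, replace = TRUE),
                      sample(0:30, total, replace = TRUE))
        closed <- runif(total) < params$p_query_closed
        # open queries are anchored so snapshot - open_date equals the age;
        # closed queries closed `age` days after opening, earlier in study
        extra <- sample(0:60, total, replace = TRUE)
        open <- ifelse(closed,
                       pmax(params$snapshot_date - age - extra,
                            params$start_date),
                       params$snapshot_date - age)
        open <- as.Date(open, origin = "1970-01-01")
        df <- seq_rows(s$subject_id, n_q, "query_seq", list())
        df$open_date <- open
        df$close_date <- as.Date(ifelse(closed, open + age, NA),
                                 origin = "1970-01-01")
        df
      })
    })), "qr")
  }

  if ("fd" %in% domains) {
    out$fd <- new_domain_table(bind_rows(lapply(seq_len(ns), function(i) {
      with_stream(params, "fd", i, {
        s <- enrolled_site[[i]]
        p_chg <- clamp_prob(params$p_field_change *
                              injection_mult(params, "p_field_change", i) *
                              exp(b[i]))
        n_fields <- s$n_forms * params$fields_per_form
        total <- sum(n_fields)
        changed <- runif(total) < p_chg
        cnt <- ifelse(changed, 1L + rpois(total, 0.7), 0L)
        idx <- rep.int(seq_len(nrow(s)), n_fields)
        tibble(subject_id = s$subject_id[idx],
               field_id = sprintf("F%05d", unlist(lapply(n_fields, seq_len),
                                                  use.names = FALSE) %||% integer()),
               change_count = as.integer(cnt))
      })
    })), "fd")
  }

  out <- out[intersect(c("dm", "ae", "lb", "pd", "qr", "fv", "ds", "fd"),
                       names(out))]
  attr(out, "params") <- params
  attr(out, "site_effects") <- b
  out
}

#' Introduce one deterministic data violation
#'
#' Corrupts a clean set of domains with exactly one violation of the named
#' kind, for exercising [check_data()]:
#' `orphan_subject` rewrites the first adverse-event row's subject id to one
#' absent from demographics; `negative_duration` sets the first demographics
#' row's `days_on_study` to -3; `duplicate_key` duplicates the first
#' adverse-event row.
#'
#' @param domains Named list of domain tables (must include `dm` and `ae`).
#' @param mode One of `"orphan_subject"`, `"negative_duration"`,
#'   `"duplicate_key"`.
#' @return The corrupted domain list.
#' @export
corrupt_domains <- function(domains, mode = c("orphan_subject",
                                              "negative_duration",
                                              "duplicate_key")) {
  mode <- match.arg(mode)
  if (mode == "orphan_subject") {
    ae <- domains$ae
    ae$subject_id[1] <- "ZZZ-9999"
    domains$ae <- new_domain_table(ae, "ae")
  } else if (mode == "negative_duration") {
    dm <- domains$dm
    dm$days_on_study[1] <- -3L
    domains$dm <- new_domain_table(dm, "dm")
  } else {
    ae <- domains$ae
    domains$ae <- new_domain_table(bind_rows(ae[1, ], ae), "ae")
  }
  domains
}

#' Write a simulated trial to disk
#'
#' Writes the domain CSVs via [write_domains()] plus a `provenance.yaml`
#' echoing the simulation parameters and seed.
#'
#' @param trial Output of [simulate_trial()].
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_trial <- function(trial, dir) {
  write_domains(trial, dir)
  params <- attr(trial, "params")
  if (!is.null(params)) {
    p <- unclass(params)
    p$start_date <- format(p$start_date)
    p$snapshot_date <- format(p$snapshot_date)
    yaml::write_yaml(p, file.path(dir, "provenance.yaml"))
  }
  invisible(dir)
}
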