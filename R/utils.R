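# Internal error helpers: every user-facing failure carries a classed
# condition so workflows can distinguish configuration problems from
# degenerate statistics and from bad input data.

stop_input <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "statmon_input_error")
}

stop_mapping <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "statmon_mapping_error")
}

stop_config <- function(msg, ..., class = character()) {
  abort(sprintf(msg, ...), class = c(class, "statmon_config_error"))
}

stop_method <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "statmon_method_error")
}

stop_degenerate <- function(msg, ...) {
  abort(sprintf(msg, ...), class = "statmon_degenerate_error")
}

stop_missing_domain <- function(metric_id, domain_id) {
  abort(
    sprintf("metric '%s' requires domain '%s' which is not available",
            metric_id, domain_id),
    class = c("statmon_missing_domain_error", "statmon_config_error"),
    metric_id = metric_id, domain_id = domain_id
  )
}

`%|NA|%` <- function(x, y) ifelse(is.na(x), y, x)

# Deterministic sub-seed for stream splitting (kept < 2^31).
substream_seed <- function(seed, domain_idx, site_idx = 0L) {
  (as.numeric(seed) * 48271 + domain_idx * 104729 + site_idx * 7919) %% 2147483647
}

is_flag <- function(x) x %in% c("Y", "N")

as_ymd <- function(x) as.Date(x, format = "%Y-%m-%d")
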