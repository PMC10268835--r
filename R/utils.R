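# Internal validation helpers. All user-facing errors carry a mutpie_error_*
# class so callers (and tests) can condition on the failure mode.

abort_invalid <- function(msg) {
  abort(msg, class = "mutpie_error_invalid_input")
}

abort_metric <- function(msg) {
  abort(msg, class = "mutpie_error_undefined_metric")
}

abort_grouping <- function(msg) {
  abort(msg, class = "mutpie_error_invalid_grouping")
}

abort_parse <- function(msg) {
  abort(msg, class = "mutpie_error_parse")
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != floor(x)) {
    abort_invalid(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict && x <= min) || (!strict && x < min)) {
    abort_invalid(sprintf("`%s` must be %s %s.", name,
                          if (strict) "greater than" else "at least", min))
  }
  as.numeric(x)
}

# central 95% interval, type-7 quantiles throughout the package
q95 <- function(x) unname(quantile(x, c(0.025, 0.975), names = FALSE))
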