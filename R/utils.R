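# Internal helpers shared across modules.

stop_invalid <- function(msg, ...) {
  rlang::abort(sprintf(msg, ...), class = "methmediate_invalid_argument")
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid("`%s` must be a single non-missing number", name)
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid("`%s` = %s is outside its allowed range", name, format(x))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  check_number(x, name, lower = min)
  if (x != as.integer(x)) stop_invalid("`%s` must be a whole number", name)
  as.integer(x)
}

check_prob_matrix <- function(x, name) {
  if (!is.matrix(x) || length(x) == 0L) {
    stop_invalid("`%s` must be a non-empty matrix", name)
  }
  if (anyNA(x) || min(x) < 0 || max(x) > 1) {
    stop_invalid("`%s` must contain values in [0, 1] with no missing entries", name)
  }
  invisible(x)
}

# Deterministic seed splitting: all randomness in a multi-step run flows from
# one master seed; sub-streams get independent seeds drawn under it.
split_seed <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(.Machine$integer.max, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
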