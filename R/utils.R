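# internal helpers: argument checks, seed splitting, logging

stop_invalid <- function(msg, class) {
  rlang::abort(msg, class = c(class, "retinaflim_error"))
}

check_number <- function(x, name, positive = FALSE, nonneg = FALSE,
                         finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(sprintf("`%s` must be a single number.", name),
                 "invalid_argument")
  }
  if (finite && !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be finite.", name), "invalid_argument")
  }
  if (positive && x <= 0) {
    stop_invalid(sprintf("`%s` must be > 0.", name), "invalid_argument")
  }
  if (nonneg && x < 0) {
    stop_invalid(sprintf("`%s` must be >= 0.", name), "invalid_argument")
  }
  invisible(x)
}

# Deterministic per-stage child seeds from one root seed; all < 2^31.
split_seed <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

rf_log <- function(verbose, ...) {
  if (isTRUE(verbose)) message(sprintf(...))
}
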