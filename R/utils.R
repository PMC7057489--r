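#' @keywords internal
"_PACKAGE"

# Validation failures get a dedicated condition class so the CLI can map them
# to exit code 2 while unexpected errors stay exit code 1.
ssm_abort <- function(..., class = "ssm_validation_error") {
  stop(errorCondition(paste0(...), class = c(class, "ssm_error")))
}

ssm_warn <- function(...) {
  warning(paste0(...), call. = FALSE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    ssm_abort(name, " must be a single finite number")
  }
  if (positive && x <= 0) {
    ssm_abort(name, " must be > 0, got ", x)
  }
  invisible(x)
}
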