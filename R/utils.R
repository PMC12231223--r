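#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Rounding used for presentation: half away from zero, as conventional in the
# diet literature (and in the published tables this package reproduces).
# The 1e-9 guard keeps values that are exactly on a half boundary after
# decimal-to-binary conversion from flipping downwards.
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_gekkodiet <- function(message, class, ...) {
  abort(message, class = c(class, "gekkodiet_error"), ...)
}

check_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || anyNA(x)) {
    stop_gekkodiet(sprintf("`%s` must be numeric and non-missing.", name),
                   "gekkodiet_domain_error")
  }
  if (positive && any(x <= 0)) {
    stop_gekkodiet(sprintf("`%s` must be strictly positive.", name),
                   "gekkodiet_domain_error")
  }
  invisible(x)
}
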