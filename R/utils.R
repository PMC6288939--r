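# Shared helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for the report percentages:
#' `round_half_up(35.45, 1)` is 35.5, whereas banker's rounding would give
#' 35.4.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Percent of `num` over `den`, half-up to one decimal; 0 when den == 0.
pct1 <- function(num, den) {
  out <- rep(0, length(num))
  ok <- rep_len(den > 0, length(num))
  out[ok] <- round_half_up(100 * num[ok] / rep_len(den, length(num))[ok], 1)
  out
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive.", name))
  }
  invisible(x)
}

# Stable non-cryptographic hash of a config list, for run manifests.
config_hash <- function(config) {
  rlang::hash(config)
}
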