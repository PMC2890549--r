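#' @keywords internal
"_PACKAGE"

## Classed conditions: validation errors (bad inputs/config) are kept distinct
## from computation errors so callers (and the CLI) can map them to exit codes.
stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("aseassoc_validation_error", "aseassoc_error")))
}

stop_computation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("aseassoc_computation_error", "aseassoc_error")))
}

#' Derive a stream-specific seed from a master seed
#'
#' One master seed governs a whole simulation; each stochastic stage (panel
#' construction, subject draws, peak noise, covariates) draws from its own
#' stream so stages can be rerun in isolation. The mapping is a fixed affine
#' hash kept below 2^31 and is stable across package versions.
#'
#' @param master integer master seed.
#' @param stream one of `"panel"`, `"subjects"`, `"noise"`, `"covariates"`.
#' @return an integer seed.
#' @export
derive_seed <- function(master, stream = c("panel", "subjects", "noise", "covariates")) {
  stream <- match.arg(stream)
  k <- match(stream, c("panel", "subjects", "noise", "covariates"))
  as.integer((as.double(master) * 48271 + k * 1000003) %% 2147483647)
}

## Half-up rounding for report percentages (base round() is banker's).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x == floor(x)

check_prob_vector <- function(p, field) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop_validation("config field '%s': probabilities must be non-negative and sum to 1", field)
  invisible(p)
}
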