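#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats qbeta qchisq pchisq optimize uniroot rmultinom runif
#'   dmultinom chisq.test rbinom
NULL

# Relative tolerance used when comparing table/outcome probabilities for
# "no more probable than observed" tie handling in the exact tests.
TIE_TOL <- 1e-7

is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x <= 1
}

check_prob <- function(x, name) {
  if (!is_prob(x)) {
    abort(sprintf("`%s` must be a single probability in [0, 1], got %s.",
                  name, deparse(substitute(x))))
  }
  invisible(x)
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != as.integer(x)) {
    abort(sprintf("`%s` must be a single nonnegative integer.", name))
  }
  as.integer(x)
}

# Round half away from zero at `digits` decimals (report layer only;
# estimates are carried at full precision everywhere else).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Named RNG substreams: each generator stage draws from a seed derived from
# (root seed, stream label), so adding a stage never perturbs another
# stage's draws. Stream seeds stay below 2^31 - 1.
stream_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) %% 1000003L) * 2011L + (h %% 65521L)
}

with_stream <- function(seed, stream, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  withr::with_seed(stream_seed(seed, stream), code)
}
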