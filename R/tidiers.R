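#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a transmission-efficiency fit
#'
#' @param x A `k_mle` object from [mle_k()].
#' @param ... Unused.
#' @return A one-row tibble with `estimate`, `ci_low`, `ci_high`,
#'   `ci_method`, `ci_level`, `informative_n`, `boundary`.
#' @method tidy k_mle
#' @export
tidy.k_mle <- function(x, ...) {
  tibble(
    term = "k",
    estimate = x$k_hat,
    ci_low = x$ci_low,
    ci_high = x$ci_high,
    ci_method = x$ci_method,
    ci_level = x$ci_level,
    informative_n = x$informative_n,
    boundary = x$boundary
  )
}

#' @rdname tidy.k_mle
#' @method glance k_mle
#' @export
glance.k_mle <- function(x, ...) {
  tibble(
    k_hat = x$k_hat,
    loglik = x$loglik_at_max,
    n = sum(x$counts),
    informative_n = x$informative_n,
    f = x$f
  )
}

#' Tidy an exact-test result
#'
#' @param x An `exact_test_result`.
#' @param ... Unused.
#' @return A one-row tibble with `p`, `method`, and whichever of
#'   `statistic`, `df`, `tables_enumerated`, `reps`, `mc_se` the method
#'   produced.
#' @method tidy exact_test_result
#' @export
tidy.exact_test_result <- function(x, ...) {
  keep <- x[!vapply(x, is.null, logical(1))]
  as_tibble(keep[setdiff(names(keep), "degenerate")])
}

#' Tidy a candidate locus interval
#'
#' @param x A `candidate_interval` from [delimit_locus()].
#' @param ... Unused.
#' @return A tibble of flanking-marker intervals with open/closed flags,
#'   span in bp (when available), and supporting plant counts.
#' @method tidy candidate_interval
#' @export
tidy.candidate_interval <- function(x, ...) {
  dplyr::mutate(x$intervals,
                span_bp = x$span_bp,
                n_plants = x$n_plants,
                n_informative = length(x$informative))
}
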