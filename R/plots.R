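#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_errorbar
#'   geom_line geom_hline labs facet_wrap
#' @export
ggplot2::autoplot

#' Plot expected selfed-family genotype frequencies
#'
#' Bar chart of the expected TT/TG/GG frequencies for one or more values
#' of the transmission efficiency `k`, against which observed families
#' can be compared by eye.
#'
#' @param k Numeric vector of transmission efficiencies.
#' @param f Female transmission.
#' @return A ggplot object.
#' @examples
#' plot_selfing_freqs(c(0, 0.11, 0.5))
#' @export
plot_selfing_freqs <- function(k, f = 0.5) {
  dat <- purrr::map_dfr(k, function(ki) {
    dplyr::mutate(expected_selfing_freqs(ki, f), k = ki)
  })
  dat$genotype <- factor(dat$genotype, levels = c("TT", "TG", "GG"))
  ggplot(dat, aes(x = .data$genotype, y = .data$freq)) +
    geom_col(fill = "grey35") +
    facet_wrap(~k, labeller = ggplot2::label_both) +
    labs(x = "genotype", y = "expected frequency")
}

#' @rdname tidy.k_mle
#' @param object A `k_mle` object.
#' @method autoplot k_mle
#' @export
autoplot.k_mle <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$term, y = .data$estimate)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.1) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::ylim(0, 1) +
    labs(x = NULL, y = "transmission efficiency k",
         subtitle = sprintf("%d%% %s interval; dashed = Mendelian",
                            round(100 * d$ci_level), d$ci_method))
}

#' Plot a transmission-table estimation result
#'
#' Point estimates with confidence intervals for every population in an
#' [estimate_k()] result, the usual summary figure for a complementation
#' series.
#'
#' @param object A tibble returned by [estimate_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_k_estimates <- function(object, ...) {
  lab <- if ("population" %in% names(object)) {
    object$population
  } else {
    as.character(seq_len(nrow(object)))
  }
  d <- dplyr::mutate(object, population = factor(lab, levels = lab))
  ggplot(d, aes(x = .data$population, y = .data$k_hat)) +
    geom_point(size = 2) +
    geom_errorbar(aes(ymin = .data$ci_low, ymax = .data$ci_high),
                  width = 0.15) +
    geom_hline(yintercept = 0.5, linetype = "dashed", colour = "grey50") +
    ggplot2::ylim(0, 1) +
    labs(x = NULL, y = "transmission efficiency k",
         subtitle = "dashed = Mendelian transmission (k = 0.5)")
}

#' @rdname recovery_experiment
#' @param object A `recovery_experiment` tibble.
#' @param ... Unused.
#' @method autoplot recovery_experiment
#' @export
autoplot.recovery_experiment <- function(object, ...) {
  d <- tidyr::pivot_longer(
    dplyr::select(as_tibble(object), "k_true", "bias", "rmse", "coverage"),
    cols = c("bias", "rmse", "coverage"),
    names_to = "summary", values_to = "value")
  ggplot(d, aes(x = .data$k_true, y = .data$value)) +
    geom_line() +
    geom_point() +
    facet_wrap(~summary, scales = "free_y") +
    labs(x = "true k", y = NULL)
}
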