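new_exact_test_result <- function(p, method, ...) {
  structure(c(list(p = p, method = method), list(...)),
            class = "exact_test_result")
}

#' @export
print.exact_test_result <- function(x, ...) {
  cat("<exact_test_result>", x$method, " p =", format(x$p, digits = 4), "\n")
  invisible(x)
}

# log conditional (multivariate hypergeometric) probability of the first
# row x1 of a 2xC table with column margins cm and first-row margin r1;
# log-gamma keeps n ~ 170+ from overflowing factorials
log_table_prob <- function(x1, cm, r1, N) {
  sum(lchoose(cm, x1)) - lchoose(N, r1)
}

# enumerate all first rows compatible with the margins, applying FUN(x1)
enumerate_rows <- function(cm, r1, FUN) {
  C <- length(cm)
  rec <- function(j, remaining, acc) {
    if (j == C) {
      if (remaining <= cm[C]) FUN(c(acc, remaining))
      return(invisible(NULL))
    }
    lo <- max(0L, remaining - sum(cm[(j + 1):C]))
    hi <- min(cm[j], remaining)
    if (lo > hi) return(invisible(NULL))
    for (x in lo:hi) rec(j + 1L, remaining - x, c(acc, x))
  }
  rec(1L, r1, integer(0))
  invisible(NULL)
}

#' Fisher-Freeman-Halton exact test for a 2 x C table
#'
#' Exact conditional test of independence for a 2-row contingency table,
#' generalizing Fisher's 2 x 2 exact test: with all margins fixed, the
#' two-sided p-value is the sum of multivariate hypergeometric
#' probabilities of every table no more probable than the one observed
#' (relative tie tolerance 1e-7 to absorb floating-point equality). Used
#' to compare a transgenic family's segregation against the non-transgenic
#' control family in complementation tests.
#'
#' @param x A 2 x C matrix of nonnegative integer counts (C <= 5), or the
#'   first row as a vector when `y` gives the second.
#' @param y Optional second row.
#' @return An `exact_test_result` with `p`, `method`, `tables_enumerated`,
#'   `observed_prob`, and `degenerate` flag.
#' @examples
#' freeman_halton_2xc(c(18, 41, 19), c(42, 43, 5))  # p ~ 0.00017
#' @export
freeman_halton_2xc <- function(x, y = NULL) {
  if (!is.null(y)) {
    x <- rbind(x, y)
  }
  x <- as.matrix(x)
  if (nrow(x) != 2L) {
    abort("`x` must have exactly 2 rows.")
  }
  if (ncol(x) > 5L) {
    abort("Enumeration supported for at most 5 columns.")
  }
  if (any(x < 0) || any(x != round(x)) || anyNA(x)) {
    abort("Counts must be nonnegative integers.")
  }
  storage.mode(x) <- "integer"
  rm_ <- rowSums(x)
  cm <- colSums(x)
  N <- sum(x)
  if (N == 0L) {
    abort("Table is empty.")
  }
  if (any(rm_ == 0L) || all(cm == 0L)) {
    warn("Degenerate margin (zero row); p = 1 by convention.")
    return(new_exact_test_result(1, "freeman_halton_enumeration",
                                 tables_enumerated = 1L,
                                 observed_prob = 1, degenerate = TRUE))
  }
  cm <- cm[cm > 0L]  # empty columns contribute nothing
  obs <- x[1, colSums(x) > 0L]
  lp_obs <- log_table_prob(obs, cm, rm_[1], N)
  cutoff <- lp_obs + log1p(TIE_TOL)
  p <- 0
  n_tab <- 0L
  enumerate_rows(cm, rm_[1], function(x1) {
    lp <- log_table_prob(x1, cm, rm_[1], N)
    n_tab <<- n_tab + 1L
    if (lp <= cutoff) {
      p <<- p + exp(lp)
    }
  })
  new_exact_test_result(min(p, 1), "freeman_halton_enumeration",
                        tables_enumerated = n_tab,
                        observed_prob = exp(lp_obs), degenerate = FALSE)
}

#' Compare each population's segregation to a control population
#'
#' Runs the Fisher-Freeman-Halton test of each row of a counts table
#' against a designated control row, the standard analysis of a
#' transgene complementation series (each transgenic family vs. the
#' non-transgenic segregants).
#'
#' @param data A counts table with columns `population`, `n_TT`, `n_TG`,
#'   `n_GG` (see [read_counts_tsv()]).
#' @param control The `population` value identifying the control row, or
#'   a length-3 numeric vector of control counts.
#' @param stars Significance thresholds used to annotate p-values
#'   (report-layer only); set `NULL` to suppress.
#' @return A tibble with one row per non-control population: `population`,
#'   `p`, `tables_enumerated`, `stars`.
#' @examples
#' tbl <- tibble::tibble(population = c("SalI", "control"),
#'                       n_TT = c(18, 42), n_TG = c(41, 43), n_GG = c(19, 5))
#' compare_to_control(tbl, control = "control")
#' @export
compare_to_control <- function(data, control,
                               stars = c(0.05, 0.01, 0.001)) {
  need <- c("n_TT", "n_TG", "n_GG")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  if (is.numeric(control) && length(control) == 3L) {
    ctrl <- as.integer(control)
    rows <- data
  } else {
    if (!"population" %in% names(data)) {
      abort("`data` needs a `population` column to locate the control row.")
    }
    hit <- which(data$population == control)
    if (length(hit) != 1L) {
      abort(sprintf("Control population \"%s\" not found exactly once.",
                    control))
    }
    ctrl <- as.integer(unlist(data[hit, need]))
    rows <- data[-hit, , drop = FALSE]
  }
  res <- purrr::pmap(rows[need], function(n_TT, n_TG, n_GG) {
    freeman_halton_2xc(c(n_TT, n_TG, n_GG), ctrl)
  })
  out <- dplyr::bind_cols(
    as_tibble(rows[setdiff(names(rows), need)]),
    as_tibble(rows[need]),
    tibble(p = purrr::map_dbl(res, "p"),
           tables_enumerated = purrr::map_int(res, "tables_enumerated"))
  )
  if (!is.null(stars)) {
    out$stars <- significance_stars(out$p, thresholds = stars)
  }
  out
}

#' Significance stars
#'
#' Annotates p-values with `*` per threshold crossed, smallest threshold
#' giving the most stars. Purely presentational.
#'
#' @param p Numeric vector of p-values.
#' @param thresholds Decreasing significance levels.
#' @return Character vector of star strings (`""` when nonsignificant).
#' @export
significance_stars <- function(p, thresholds = c(0.05, 0.01, 0.001)) {
  thresholds <- sort(thresholds, decreasing = TRUE)
  vapply(p, function(pi) {
    strrep("*", sum(pi < thresholds))
  }, character(1))
}

log_multinom_prob <- function(x, probs) {
  keep <- probs > 0
  if (any(x[!keep] > 0)) {
    return(-Inf)
  }
  lgamma(sum(x) + 1) - sum(lgamma(x[keep] + 1)) +
    sum(x[keep] * log(probs[keep]))
}

#' Exact multinomial goodness-of-fit test
#'
#' Tests observed genotype counts against null class probabilities by the
#' exact multinomial criterion: the p-value is the null probability of
#' all outcomes whose likelihood is no greater than the observed one
#' (relative tie tolerance 1e-7). `method = "enumerate"` enumerates every
#' outcome (n <= 200); `method = "monte_carlo"` samples outcomes under
#' the null and is reproducible under `seed`.
#'
#' @param counts A [seg_counts()] object or numeric vector of counts.
#' @param probs Null class probabilities summing to 1 (e.g.
#'   `expected_selfing_freqs(k)$freq`).
#' @param method `"enumerate"` or `"monte_carlo"`.
#' @param reps Monte Carlo replicates.
#' @param seed Integer seed for the Monte Carlo method.
#' @return An `exact_test_result` with `p`, `method`, and either
#'   `tables_enumerated` or `reps` + `mc_se`.
#' @examples
#' multinomial_exact_gof(seg_counts(42, 43, 5), c(0.25, 0.5, 0.25))
#' @export
multinomial_exact_gof <- function(counts, probs,
                                  method = c("enumerate", "monte_carlo"),
                                  reps = 10000, seed = NULL) {
  method <- match.arg(method)
  x <- as.numeric(if (inherits(counts, "seg_counts")) counts else counts)
  if (any(x < 0) || any(x != round(x))) {
    abort("Counts must be nonnegative integers.")
  }
  if (abs(sum(probs) - 1) > 1e-8 || any(probs < 0)) {
    abort("`probs` must be nonnegative and sum to 1.")
  }
  n <- sum(x)
  K <- length(x)
  if (length(probs) != K) {
    abort("`counts` and `probs` must have the same length.")
  }
  ll_obs <- log_multinom_prob(x, probs)
  cutoff <- ll_obs + log1p(TIE_TOL)
  if (method == "enumerate") {
    if (n > 200) {
      abort(paste("Enumeration limited to n <= 200;",
                  "use method = \"monte_carlo\" for larger families."))
    }
    p <- 0
    n_out <- 0L
    rec <- function(j, remaining, acc) {
      if (j == K) {
        y <- c(acc, remaining)
        lp <- log_multinom_prob(y, probs)
        n_out <<- n_out + 1L
        if (lp <= cutoff) {
          p <<- p + exp(lp)
        }
        return(invisible(NULL))
      }
      for (v in 0:remaining) rec(j + 1L, remaining - v, c(acc, v))
    }
    rec(1L, n, numeric(0))
    new_exact_test_result(min(p, 1), "multinomial_enumeration",
                          tables_enumerated = n_out)
  } else {
    draws <- with_stream(seed, "multinomial_gof", rmultinom(reps, n, probs))
    ll <- apply(draws, 2, log_multinom_prob, probs = probs)
    p <- mean(ll <= cutoff)
    new_exact_test_result(p, "multinomial_monte_carlo", reps = reps,
                          mc_se = sqrt(p * (1 - p) / reps))
  }
}

#' Pearson chi-squared goodness-of-fit (asymptotic cross-check)
#'
#' Pearson X-squared against null class probabilities, df = classes - 1.
#' An asymptotic companion to [multinomial_exact_gof()]; delegates to
#' [stats::chisq.test()].
#'
#' @inheritParams multinomial_exact_gof
#' @return An `exact_test_result` with `p`, `statistic`, `df`.
#' @examples
#' chi2_gof(seg_counts(42, 43, 5), c(0.25, 0.5, 0.25))
#' @export
chi2_gof <- function(counts, probs) {
  x <- as.numeric(if (inherits(counts, "seg_counts")) counts else counts)
  if (any(sum(x) * probs == 0)) {
    abort("Zero expected count; chi-squared test undefined.")
  }
  ct <- suppressWarnings(chisq.test(x, p = probs))
  new_exact_test_result(unname(ct$p.value), "chi2_asymptotic",
                        statistic = unname(ct$statistic),
                        df = unname(ct$parameter))
}
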