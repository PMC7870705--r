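#' Segregation counts at a marker linked to a sterility locus
#'
#' Genotype counts from a selfed family scored at a marker tightly linked
#' to the sterility locus: `TT` homozygous for the cultivated (functional)
#' allele, `TG` heterozygous, `GG` homozygous for the wild (sterile)
#' allele.
#'
#' @param n_TT,n_TG,n_GG Nonnegative integer counts.
#' @return An object of class `seg_counts` (a named integer vector).
#' @examples
#' seg_counts(42, 43, 5)
#' @export
seg_counts <- function(n_TT, n_TG, n_GG) {
  x <- c(TT = check_count(n_TT, "n_TT"),
         TG = check_count(n_TG, "n_TG"),
         GG = check_count(n_GG, "n_GG"))
  structure(x, class = "seg_counts")
}

as_seg_counts <- function(x) {
  if (inherits(x, "seg_counts")) {
    return(x)
  }
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      abort("Expected a single row of counts; use `estimate_k()` for tables.")
    }
    return(seg_counts(x$n_TT, x$n_TG, x$n_GG))
  }
  if (is.numeric(x) && length(x) == 3L) {
    return(seg_counts(x[[1]], x[[2]], x[[3]]))
  }
  abort("Cannot interpret `counts`; supply seg_counts() or (TT, TG, GG).")
}

#' @export
print.seg_counts <- function(x, ...) {
  cat("<seg_counts> TT =", x[["TT"]], " TG =", x[["TG"]],
      " GG =", x[["GG"]], " (n =", sum(x), ")\n")
  invisible(x)
}

#' Multinomial log-likelihood of the transmission efficiency
#'
#' Log-likelihood of `k` for selfed-family genotype counts under the
#' distorted-transmission model: `n_TT log((1-f)(1-k)) +
#' n_TG log((1-f)k + f(1-k)) + n_GG log(f k)`, with the convention
#' `0 * log(0) = 0`. With `f = 0.5` the heterozygote class has constant
#' probability 1/2, so `n_TG` carries no information about `k`. Returns
#' `-Inf` (not an error) when a positive count falls in a zero-probability
#' class.
#'
#' @param k Transmission efficiency values (vectorized).
#' @param counts A [seg_counts()] object (or coercible: a length-3 vector
#'   or one-row data frame with columns `n_TT`, `n_TG`, `n_GG`).
#' @param f Female transmission (default 0.5).
#' @return Numeric vector of log-likelihood values.
#' @examples
#' loglik_k(0.5, seg_counts(1, 2, 1))  # log(1/64)
#' @export
loglik_k <- function(k, counts, f = 0.5) {
  counts <- as_seg_counts(counts)
  if (!is.numeric(k) || anyNA(k) || any(k < 0) || any(k > 1)) {
    abort("`k` must be numeric in [0, 1].")
  }
  check_prob(f, "f")
  n <- as.numeric(counts)
  vapply(k, function(ki) {
    p <- selfing_probs(ki, f)
    terms <- ifelse(n == 0, 0, n * log(p))
    if (any(n > 0 & p == 0)) -Inf else sum(terms)
  }, numeric(1))
}

#' Maximum-likelihood estimate of pollen transmission efficiency
#'
#' Estimates `k`, the transmission efficiency of the sterile allele
#' through pollen, from selfed-family genotype counts. With `f = 0.5`
#' the MLE has the closed form `k_hat = n_GG / (n_TT + n_GG)`:
#' conditional on the number of informative (homozygous) offspring,
#' `n_GG` is binomial with success probability `k`. Boundary estimates
#' (0 or 1) are returned exactly, not clipped. For `f != 0.5` the
#' likelihood is maximized numerically.
#'
#' @inheritParams loglik_k
#' @param ci_method `"exact_binomial"` (Clopper-Pearson, default; exact at
#'   all sample sizes including zero counts) or `"profile_lrt"`.
#' @param level Confidence level for the interval.
#' @return An object of class `k_mle` with components `k_hat`,
#'   `loglik_at_max`, `ci_low`, `ci_high`, `ci_method`, `ci_level`,
#'   `informative_n`, `boundary`, `counts`, `f`. Use [generics::tidy()] /
#'   [generics::glance()] for tibble output.
#' @examples
#' mle_k(seg_counts(42, 43, 5))   # k_hat = 5/47
#' @export
mle_k <- function(counts, f = 0.5, ci_method = c("exact_binomial",
                                                 "profile_lrt"),
                  level = 0.95) {
  counts <- as_seg_counts(counts)
  check_prob(f, "f")
  ci_method <- match.arg(ci_method)
  m <- sum(counts[c("TT", "GG")])
  if (f == 0.5 && m == 0L) {
    abort("k not identifiable: no informative (homozygous) offspring.")
  }
  if (f == 0.5) {
    k_hat <- counts[["GG"]] / m
  } else {
    if (sum(counts) == 0L) {
      abort("k not identifiable: no offspring.")
    }
    opt <- optimize(function(k) loglik_k(k, counts, f),
                    interval = c(0, 1), maximum = TRUE, tol = 1e-10)
    k_hat <- opt$maximum
    # check the boundaries explicitly; optimize() never returns them
    ll_b <- loglik_k(c(0, 1), counts, f)
    if (max(ll_b) > opt$objective) {
      k_hat <- c(0, 1)[which.max(ll_b)]
    }
  }
  ci <- ci_k(counts, level = level, method = ci_method, f = f)
  structure(list(
    k_hat = unname(k_hat),
    loglik_at_max = loglik_k(k_hat, counts, f),
    ci_low = ci$low,
    ci_high = ci$high,
    ci_method = ci_method,
    ci_level = level,
    one_sided = ci$one_sided,
    informative_n = as.integer(m),
    boundary = k_hat %in% c(0, 1),
    counts = counts,
    f = f
  ), class = "k_mle")
}

#' @export
print.k_mle <- function(x, digits = 4, ...) {
  cat("<k_mle> k_hat =", format(x$k_hat, digits = digits),
      sprintf(" %d%% CI [%s, %s] (%s)\n", round(100 * x$ci_level),
              format(x$ci_low, digits = digits),
              format(x$ci_high, digits = digits), x$ci_method))
  cat("  informative n =", x$informative_n,
      " loglik =", format(x$loglik_at_max, digits = digits), "\n")
  invisible(x)
}

#' Confidence interval for the transmission efficiency
#'
#' `exact_binomial` gives the Clopper-Pearson interval for `n_GG`
#' successes out of `n_TT + n_GG` informative offspring (valid because,
#' conditional on the informative count, `n_GG` is binomial with success
#' probability `k` when `f = 0.5`). `profile_lrt` inverts the likelihood-
#' ratio test: the interval is `{k : 2[l(k_hat) - l(k)] <= qchisq(level, 1)}`.
#' Boundary estimates yield one-sided intervals, flagged in the output.
#'
#' @inheritParams mle_k
#' @param method `"exact_binomial"` or `"profile_lrt"`.
#' @return A tibble with columns `low`, `high`, `level`, `method`,
#'   `one_sided`.
#' @examples
#' ci_k(seg_counts(42, 43, 5))
#' @export
ci_k <- function(counts, level = 0.95, method = c("exact_binomial",
                                                  "profile_lrt"),
                 f = 0.5) {
  counts <- as_seg_counts(counts)
  method <- match.arg(method)
  check_prob(level, "level")
  m <- sum(counts[c("TT", "GG")])
  if (m == 0L) {
    abort("k not identifiable: no informative (homozygous) offspring.")
  }
  x <- counts[["GG"]]
  if (method == "exact_binomial") {
    a <- 1 - level
    low <- if (x == 0L) 0 else qbeta(a / 2, x, m - x + 1)
    high <- if (x == m) 1 else qbeta(1 - a / 2, x + 1, m - x)
  } else {
    k_hat <- if (f == 0.5) x / m else mle_k(counts, f, level = level)$k_hat
    ll_max <- loglik_k(k_hat, counts, f)
    crit <- qchisq(level, df = 1)
    h <- function(k) 2 * (ll_max - loglik_k(k, counts, f)) - crit
    eps <- 1e-12
    low <- if (k_hat <= eps || h(eps) < 0) {
      0
    } else {
      uniroot(h, c(eps, k_hat), tol = 1e-10)$root
    }
    high <- if (k_hat >= 1 - eps || h(1 - eps) < 0) {
      1
    } else {
      uniroot(h, c(k_hat, 1 - eps), tol = 1e-10)$root
    }
  }
  tibble(low = low, high = high, level = level, method = method,
         one_sided = (x == 0L) || (x == m))
}

#' Likelihood-ratio test of a null transmission efficiency
#'
#' Tests `k = k0` (e.g. Mendelian transmission `k0 = 0.5`, or complete
#' pollen killing `k0 = 0`) with the statistic `2[l(k_hat) - l(k0)]`
#' referred to chi-squared with 1 df. When `k0` lies on the boundary of
#' the parameter space the null distribution is the 50:50 mixture of a
#' point mass at 0 and chi-squared(1), so the p-value is halved; this is
#' flagged. If the null assigns probability zero to an observed class the
#' statistic is `+Inf` and `p = 0`, flagged.
#'
#' @inheritParams loglik_k
#' @param k0 Null value of `k` in `[0, 1]`.
#' @return A tibble with columns `statistic`, `p`, `df`, `k_hat`, `k0`,
#'   `boundary_null`, `incompatible_null`.
#' @examples
#' lrt_k(seg_counts(42, 43, 5), k0 = 0.5)
#' @export
lrt_k <- function(counts, k0, f = 0.5) {
  counts <- as_seg_counts(counts)
  check_prob(k0, "k0")
  fit <- mle_k(counts, f = f)
  ll0 <- loglik_k(k0, counts, f)
  boundary_null <- k0 %in% c(0, 1)
  if (!is.finite(ll0)) {
    return(tibble(statistic = Inf, p = 0, df = 1L, k_hat = fit$k_hat,
                  k0 = k0, boundary_null = boundary_null,
                  incompatible_null = TRUE))
  }
  stat <- max(0, 2 * (fit$loglik_at_max - ll0))
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  if (boundary_null) {
    p <- p / 2
  }
  if (stat == 0) {
    p <- 1
  }
  tibble(statistic = stat, p = p, df = 1L, k_hat = fit$k_hat, k0 = k0,
         boundary_null = boundary_null, incompatible_null = FALSE)
}

#' Estimate transmission efficiency for every population in a counts table
#'
#' Data-frame-first wrapper around [mle_k()]: takes a table with one row
#' per selfed family (columns `n_TT`, `n_TG`, `n_GG`; any identifier
#' columns are carried through) and returns one row of estimates per
#' family.
#'
#' @param data A data frame with integer columns `n_TT`, `n_TG`, `n_GG`,
#'   e.g. from [read_counts_tsv()].
#' @inheritParams mle_k
#' @return A tibble: the identifier columns of `data` plus `n`,
#'   `informative_n`, `k_hat`, `ci_low`, `ci_high`, `ci_method`, `loglik`.
#' @examples
#' tbl <- tibble::tibble(population = c("a", "b"),
#'                       n_TT = c(42, 18), n_TG = c(43, 41), n_GG = c(5, 19))
#' estimate_k(tbl)
#' @export
estimate_k <- function(data, f = 0.5,
                       ci_method = c("exact_binomial", "profile_lrt"),
                       level = 0.95) {
  ci_method <- match.arg(ci_method)
  need <- c("n_TT", "n_TG", "n_GG")
  if (!all(need %in% names(data))) {
    abort(sprintf("`data` must have columns %s.",
                  paste(need, collapse = ", ")))
  }
  id_cols <- setdiff(names(data), need)
  fits <- purrr::pmap(data[need], function(n_TT, n_TG, n_GG) {
    mle_k(seg_counts(n_TT, n_TG, n_GG), f = f, ci_method = ci_method,
          level = level)
  })
  dplyr::bind_cols(
    as_tibble(data[id_cols]),
    tibble(
      n = as.integer(data$n_TT + data$n_TG + data$n_GG),
      informative_n = purrr::map_int(fits, "informative_n"),
      k_hat = purrr::map_dbl(fits, "k_hat"),
      ci_low = purrr::map_dbl(fits, "ci_low"),
      ci_high = purrr::map_dbl(fits, "ci_high"),
      ci_method = ci_method,
      loglik = purrr::map_dbl(fits, "loglik_at_max")
    )
  )
}
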