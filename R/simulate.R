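#' Simulate selfed-family genotype counts under distorted transmission
#'
#' One multinomial draw of `n` offspring genotypes from the expected
#' selfing frequencies `((1-f)(1-k), (1-f)k + f(1-k), f k)` -- the
#' statistical structure of a T1 family scored at a marker tightly
#' linked to the sterility locus. Bit-reproducible under `seed`.
#'
#' @param n Family size (> 0).
#' @param k Pollen transmission efficiency of the sterile allele.
#' @param f Female transmission (default 0.5).
#' @param seed Integer seed (`NULL` uses the current RNG state).
#' @return A [seg_counts()] object.
#' @examples
#' simulate_selfing_counts(90, k = 0.11, seed = 1)
#' @export
simulate_selfing_counts <- function(n, k, f = 0.5, seed = NULL) {
  n <- check_count(n, "n")
  if (n == 0L) {
    abort("`n` must be positive.")
  }
  check_prob(k, "k")
  check_prob(f, "f")
  p <- selfing_probs(k, f)
  x <- with_stream(seed, "selfing_counts", rmultinom(1, n, p)[, 1])
  seg_counts(x[[1]], x[[2]], x[[3]])
}

# reps multinomial draws as a 3 x reps matrix (internal, vectorized)
r_selfing_counts <- function(reps, n, k, f = 0.5) {
  rmultinom(reps, n, selfing_probs(k, f))
}

# Haldane map function: distance (cM) -> recombination fraction
haldane_r <- function(d_cm) {
  0.5 * (1 - exp(-0.02 * d_cm))
}

# simulate `n` gametes across ordered positions with per-interval
# recombination fractions r (length = positions - 1); returns an
# n x positions 0/1 matrix of parental-chromosome origin
r_gametes <- function(n, r, allow_double_crossover = TRUE) {
  L <- length(r) + 1L
  start <- matrix(rbinom(n, 1L, 0.5), ncol = 1)
  if (L == 1L) {
    return(start)
  }
  if (allow_double_crossover) {
    # independent crossover per interval, no interference
    xo <- matrix(rbinom(n * (L - 1L), 1L, rep(r, each = n)), nrow = n)
  } else {
    # at most one crossover per gamete
    if (sum(r) > 1) {
      abort("Total recombination exceeds 1; cannot disable double crossovers.")
    }
    which_iv <- sample.int(L, n, replace = TRUE, prob = c(r, 1 - sum(r)))
    xo <- matrix(0L, nrow = n, ncol = L - 1L)
    hit <- which_iv <= L - 1L
    xo[cbind(which(hit), which_iv[hit])] <- 1L
  }
  sw <- cbind(start, xo)
  t(apply(sw, 1, cumsum)) %% 2L
}

#' Simulate a selfed mapping population with marker genotypes
#'
#' Simulates `n` offspring of a selfed plant heterozygous across the
#' whole mapped region: each gamete is a recombinant chain over the map
#' markers plus the (hidden) sterility locus, recombination fractions
#' coming from the map's cM positions through the Haldane map function.
#' On the male side, gametes carrying the sterile allele at the locus
#' are viable with probability `k / (1 - k)` (so the realized
#' transmission among functional pollen is `k`; `k = 0` means no
#' sterile-allele pollen transmits). Phenotype follows the locus
#' genotype: heterozygous plants are semi-sterile (`SS`), homozygous
#' functional plants normal (`N`). Records carry marker calls only --
#' the locus column is dropped, as in a real screen.
#'
#' @param map A [marker_map()] with `cm` positions.
#' @param locus_cm Genetic position of the sterility locus, strictly
#'   inside the map span and not coincident with a marker.
#' @param n Number of plants.
#' @param k Male transmission of the sterile allele, in `[0, 0.5]`.
#' @param seed Integer seed.
#' @param allow_double_crossover Set `FALSE` to cap each gamete at one
#'   crossover (clean single-breakpoint populations for interval tests).
#' @return A tibble with `plant_id`, one column per marker (`T`/`H`/`G`),
#'   and `phenotype` (`N`/`SS`); the true locus flank is stored in
#'   attributes `locus_cm` and `locus_after`.
#' @examples
#' m <- marker_map(paste0("m", 1:5), cm = c(0, 2, 4, 6, 8))
#' simulate_marker_population(m, locus_cm = 5, n = 20, seed = 1)
#' @export
simulate_marker_population <- function(map, locus_cm, n, k = 0, seed = NULL,
                                       allow_double_crossover = TRUE) {
  stopifnot(inherits(map, "marker_map"))
  if (anyNA(map$cm)) {
    abort("`map` must carry cm positions to simulate recombination.")
  }
  n <- check_count(n, "n")
  if (n == 0L) {
    abort("`n` must be positive.")
  }
  if (!is.numeric(locus_cm) || length(locus_cm) != 1L ||
      locus_cm <= min(map$cm) || locus_cm >= max(map$cm)) {
    abort("`locus_cm` must lie strictly inside the map span.")
  }
  if (locus_cm %in% map$cm) {
    abort("`locus_cm` must fall between markers, not on one.")
  }
  check_prob(k, "k")
  if (k > 0.5) {
    abort("`k` > 0.5 (enhanced transmission) is not modeled.")
  }
  pos <- sort(c(map$cm, locus_cm))
  locus_col <- match(locus_cm, pos)
  r_iv <- haldane_r(diff(pos))
  viab <- if (k < 0.5) k / (1 - k) else 1

  with_stream(seed, "marker_population", {
    female <- r_gametes(n, r_iv, allow_double_crossover)
    male <- r_gametes(n, r_iv, allow_double_crossover)
    # rejection-sample male gametes: sterile-allele pollen survives w.p.
    # viab = k/(1-k), giving realized transmission k among survivors;
    # each gamete is tested once, only rejected slots are redrawn
    todo <- seq_len(n)
    repeat {
      sterile <- male[todo, locus_col] == 1L
      reject <- sterile & (runif(length(todo)) >= viab)
      todo <- todo[reject]
      if (length(todo) == 0L) break
      male[todo, ] <- r_gametes(length(todo), r_iv, allow_double_crossover)
    }
    geno <- female + male  # 0 = TT, 1 = het, 2 = wild hom, per position
    locus_geno <- geno[, locus_col]
    calls <- matrix(GENO_CODES[geno[, -locus_col, drop = FALSE] + 1L],
                    nrow = n)
    colnames(calls) <- map$marker
    out <- dplyr::bind_cols(
      tibble(plant_id = as.character(seq_len(n))),
      as_tibble(calls),
      tibble(phenotype = ifelse(locus_geno == 0L, "N", "SS"))
    )
    attr(out, "locus_cm") <- locus_cm
    attr(out, "locus_after") <- map$marker[max(which(map$cm < locus_cm))]
    out
  })
}

#' Simulate a transgene-complementation T1 family
#'
#' Selfing of a plant heterozygous at the sterility locus and carrying a
#' rescuing transgene insertion. The sterile-allele abortion penetrance
#' is derived from the baseline transmission `k` via
#' [sigma_from_k()]; male gametes carrying the sterile allele abort with
#' that probability unless the transgene present in the gamete rescues
#' them (probability `rescue` per gamete carrying at least one copy),
#' matching the gametophytic interpretation of complementation: the
#' transgene acts in the haploid pollen grain that carries it. The
#' transgene segregates Mendelianly from its own insertion site, linked
#' to the sterility locus at recombination fraction `r` (0.5 =
#' unlinked). Female gametes are unselected.
#'
#' @param n Family size.
#' @param k Baseline male transmission without rescue, in `[0, 0.5]`.
#' @param rescue Probability that the transgene restores viability of a
#'   sterile-allele gamete carrying it.
#' @param zygosity `"hemizygous"` or `"homozygous"` insertion in the T0.
#' @param r Recombination fraction insertion--locus in `[0, 0.5]`.
#' @param phase For linked hemizygous insertions, `"cis_sterile"` or
#'   `"cis_functional"`.
#' @param seed Integer seed.
#' @return A list with `counts` (a [seg_counts()]) and `plants` (tibble
#'   of per-plant `genotype` and transgene `copies`).
#' @examples
#' simulate_complementation_t1(90, k = 0, rescue = 1, seed = 1)
#' @export
simulate_complementation_t1 <- function(n, k, rescue = 1,
                                        zygosity = c("hemizygous",
                                                     "homozygous"),
                                        r = 0.5, phase = "cis_sterile",
                                        seed = NULL) {
  n <- check_count(n, "n")
  if (n == 0L) {
    abort("`n` must be positive.")
  }
  check_prob(k, "k")
  check_prob(rescue, "rescue")
  zygosity <- match.arg(zygosity)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
    abort("Transgene linkage `r` must lie in [0, 0.5].")
  }
  sigma <- sigma_from_k(k)
  jt <- gamete_joint(zygosity, r, phase)  # P(allele, transgene) per gamete

  draw_gametes <- function(m) {
    cells <- sample.int(4L, m, replace = TRUE, prob = as.vector(jt))
    # as.vector(jt) order: (a0,t0), (a1,t0), (a0,t1), (a1,t1)
    allele <- as.integer(cells %in% c(2L, 4L))
    tg <- as.integer(cells >= 3L)
    cbind(allele, tg)
  }

  with_stream(seed, "complementation_t1", {
    female <- draw_gametes(n)
    male <- draw_gametes(n)
    todo <- seq_len(n)
    repeat {
      sterile <- male[todo, 1] == 1L
      abort_p <- sigma * (1 - rescue * male[todo, 2])
      reject <- sterile & (runif(length(todo)) < abort_p)
      todo <- todo[reject]
      if (length(todo) == 0L) break
      male[todo, ] <- draw_gametes(length(todo))
    }
    geno_num <- female[, 1] + male[, 1]
    genotype <- c("TT", "TG", "GG")[geno_num + 1L]
    counts <- seg_counts(sum(geno_num == 0L), sum(geno_num == 1L),
                         sum(geno_num == 2L))
    list(counts = counts,
         plants = tibble(genotype = genotype,
                         copies = as.integer(female[, 2] + male[, 2])))
  })
}

#' Estimator-recovery experiment over a grid of true transmission values
#'
#' For each `k` in `k_grid`, simulates `reps` selfed families of size
#' `n`, estimates `k` by [mle_k()]'s closed form, and summarizes bias,
#' RMSE, and the empirical coverage of the exact binomial confidence
#' interval. Deterministic under `seed`.
#'
#' @param k_grid True transmission efficiencies.
#' @param n Family size per replicate.
#' @param reps Replicates per grid point (>= 100).
#' @param seed Integer seed.
#' @param level Confidence level for the coverage check.
#' @return A tibble of class `recovery_experiment`: one row per grid
#'   point with `k_true`, `mean_k_hat`, `bias`, `rmse`, `coverage`,
#'   `mc_se` (Monte Carlo standard error of the mean), `n`, `reps`.
#' @examples
#' recovery_experiment(c(0, 0.25), n = 100, reps = 200, seed = 1)
#' @export
recovery_experiment <- function(k_grid, n, reps, seed = NULL, level = 0.95) {
  if (!is.numeric(k_grid) || anyNA(k_grid) || any(k_grid < 0 | k_grid > 1)) {
    abort("`k_grid` must be probabilities in [0, 1].")
  }
  n <- check_count(n, "n")
  reps <- check_count(reps, "reps")
  if (reps < 100L) {
    abort("`reps` must be at least 100 for stable summaries.")
  }
  a <- 1 - level
  with_stream(seed, "recovery_experiment", {
    purrr::map_dfr(k_grid, function(k_true) {
      x <- r_selfing_counts(reps, n, k_true)       # 3 x reps
      m <- x[1, ] + x[3, ]
      keep <- m > 0
      k_hat <- x[3, keep] / m[keep]
      gg <- x[3, keep]
      mk <- m[keep]
      low <- ifelse(gg == 0, 0, qbeta(a / 2, gg, mk - gg + 1))
      high <- ifelse(gg == mk, 1, qbeta(1 - a / 2, gg + 1, mk - gg))
      tibble(
        k_true = k_true,
        mean_k_hat = mean(k_hat),
        bias = mean(k_hat) - k_true,
        rmse = sqrt(mean((k_hat - k_true)^2)),
        coverage = mean(low <= k_true & k_true <= high),
        mc_se = stats::sd(k_hat) / sqrt(length(k_hat)),
        n = n,
        reps = reps,
        dropped = sum(!keep)
      )
    }) -> out
    class(out) <- c("recovery_experiment", class(out))
    out
  })
}
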