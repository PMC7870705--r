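# Independent oracles used to validate the package's implementations.
# Each is deliberately a separate code path from the function it checks.

# grid-search maximizer of the selfing multinomial likelihood in k
# (dense grid; independent of loglik_k / mle_k)
grid_mle_oracle <- function(n_TT, n_TG, n_GG, step = 1e-6) {
  k <- seq(step, 1 - step, by = step)
  # n_TG term is constant at f = 0.5; drop it and the 1/2 factors
  ll <- n_TT * log1p(-k) + n_GG * log(k)
  k[which.max(ll)]
}

# log-likelihood at a point, written independently of loglik_k
loglik_oracle <- function(k, n_TT, n_TG, n_GG) {
  p <- c((1 - k) / 2, 0.5, k / 2)
  n <- c(n_TT, n_TG, n_GG)
  if (any(n > 0 & p == 0)) {
    return(-Inf)
  }
  sum(ifelse(n == 0, 0, n * log(p)))
}

# Freeman-Halton p by a second enumeration order: iterate over the
# SECOND row's cells, factorial-based probabilities (no log-gamma)
fh_oracle <- function(row1, row2) {
  cm <- row1 + row2
  r2 <- sum(row2)
  N <- sum(cm)
  prob_of <- function(x2) {
    prod(choose(cm, x2)) / choose(N, r2)
  }
  p_obs <- prob_of(row2)
  p <- 0
  C <- length(cm)
  grid <- expand.grid(lapply(cm[-C], function(m) 0:m))
  for (i in seq_len(nrow(grid))) {
    x2 <- as.numeric(grid[i, ])
    last <- r2 - sum(x2)
    if (last < 0 || last > cm[C]) next
    x2 <- c(x2, last)
    pr <- prob_of(x2)
    if (pr <= p_obs * (1 + 1e-7)) {
      p <- p + pr
    }
  }
  p
}

# classical two-sided 2x2 Fisher p as an explicit hypergeometric sum
fisher_2x2_oracle <- function(a, b, c, d) {
  m <- a + c
  n <- b + d
  k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exact multinomial GOF p by full outcome enumeration (small n only)
multinom_gof_oracle <- function(x, probs) {
  n <- sum(x)
  K <- length(x)
  outcomes <- expand.grid(rep(list(0:n), K - 1))
  p_obs <- stats::dmultinom(x, prob = probs)
  p <- 0
  for (i in seq_len(nrow(outcomes))) {
    y <- as.numeric(outcomes[i, ])
    last <- n - sum(y)
    if (last < 0) next
    y <- c(y, last)
    pr <- stats::dmultinom(y, prob = probs)
    if (pr <= p_obs * (1 + 1e-7)) {
      p <- p + pr
    }
  }
  p
}

# brute-force expected pollen fertility: enumerate every combination of
# locus alleles and insertion-presence patterns with explicit joint
# probabilities (separate code path from expected_pollen_fertility)
fertility_oracle <- function(n_loci, sigma, rescue, transgenes = NULL) {
  if (is.null(transgenes) || nrow(transgenes) == 0) {
    transgenes <- data.frame(zygosity = character(), r = numeric(),
                             locus = integer(), phase = character())
  }
  n_ins <- nrow(transgenes)
  combos <- expand.grid(rep(list(0:1), n_loci + n_ins))
  total <- 0
  for (i in seq_len(nrow(combos))) {
    a <- as.numeric(combos[i, seq_len(n_loci)])
    t <- if (n_ins > 0) as.numeric(combos[i, n_loci + seq_len(n_ins)]) else numeric(0)
    pr <- prod(rep(0.5, n_loci))
    ok <- TRUE
    for (j in seq_len(n_ins)) {
      zg <- transgenes$zygosity[j]
      if (zg == "homozygous") {
        pj <- if (t[j] == 1) 1 else 0
      } else {
        r <- transgenes$r[j]
        al <- a[transgenes$locus[j]]
        cis_st <- transgenes$phase[j] == "cis_sterile"
        # P(transgene | allele) for a hemizygous linked insertion
        p_t_given_sterile <- if (cis_st) 1 - r else r
        p_t <- if (al == 1) p_t_given_sterile else 1 - p_t_given_sterile
        pj <- if (t[j] == 1) p_t else 1 - p_t
      }
      if (pj == 0) {
        ok <- FALSE
        break
      }
      pr <- pr * pj
    }
    if (!ok) next
    surv <- 1
    for (l in seq_len(n_loci)) {
      if (a[l] == 1) {
        present <- which(transgenes$locus == l & t == 1)
        surv <- surv * (1 - sigma * prod(1 - rep(rescue, length(present))))
      }
    }
    total <- total + pr * surv
  }
  total
}

# random small 2-row count tables for exact-test properties
random_2xc_table <- function(C = 3, max_cell = 12) {
  matrix(sample(0:max_cell, 2 * C, replace = TRUE), nrow = 2)
}
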