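#' Transmission model for a gametophytic sterility locus
#'
#' Bundles the two transmission efficiencies of the sterile allele: `k`
#' through pollen and `f` through female gametes. `k = f = 0.5` recovers
#' Mendelian expectation; a fully penetrant gametophytic pollen killer has
#' `k = 0`. Female-side distortion is not expected for pollen sterility
#' loci (the embryo sac is unaffected), so `f` defaults to 0.5 and is only
#' a free parameter for generality.
#'
#' @param k Probability in `[0, 1]` that the sterile allele is transmitted
#'   through a functional pollen grain.
#' @param f Transmission probability through female gametes (default 0.5).
#' @return An object of class `transmission_model`.
#' @examples
#' transmission_model(k = 0.11)
#' @export
transmission_model <- function(k = 0.5, f = 0.5) {
  check_prob(k, "k")
  check_prob(f, "f")
  structure(list(k = k, f = f), class = "transmission_model")
}

#' @export
print.transmission_model <- function(x, ...) {
  cat("<transmission_model> k =", format(x$k), " f =", format(x$f), "\n")
  invisible(x)
}

selfing_probs <- function(k, f = 0.5) {
  c(TT = (1 - f) * (1 - k),
    TG = (1 - f) * k + f * (1 - k),
    GG = f * k)
}

#' Expected genotype frequencies in a selfed family under distorted
#' transmission
#'
#' For a plant heterozygous at a sterility locus (alleles `T` = functional,
#' `G` = sterile) selfed with pollen transmission `k` and female
#' transmission `f`, the offspring genotype probabilities are
#' `P(TT) = (1 - f)(1 - k)`, `P(TG) = (1 - f)k + f(1 - k)`, and
#' `P(GG) = f k`. With `f = 0.5` this is `((1 - k)/2, 1/2, k/2)`: the
#' heterozygote class always has frequency 1/2, and `k = 0` gives the
#' 1:1:0 segregation characteristic of a complete gametophytic pollen
#' killer.
#'
#' @param k Pollen transmission efficiency of the sterile allele, or a
#'   [transmission_model()].
#' @param f Female transmission (ignored when `k` is a model object).
#' @return A tibble with columns `genotype` (`TT`, `TG`, `GG`) and `freq`.
#' @examples
#' expected_selfing_freqs(k = 0)    # 1:1:0
#' expected_selfing_freqs(k = 0.11)
#' @export
expected_selfing_freqs <- function(k = 0.5, f = 0.5) {
  if (inherits(k, "transmission_model")) {
    f <- k$f
    k <- k$k
  }
  check_prob(k, "k")
  check_prob(f, "f")
  p <- selfing_probs(k, f)
  tibble(genotype = names(p), freq = unname(p))
}

#' Expected genotype frequencies in a backcross
#'
#' Backcross of a heterozygote to the homozygous functional parent.
#' When the heterozygote is the pollen parent, the sterile allele is
#' transmitted with probability `k`, so `P(TG) = k`; when it is the seed
#' parent, transmission is through female gametes and `P(TG) = f`.
#'
#' @inheritParams expected_selfing_freqs
#' @param pollen_parent_het Is the heterozygote the pollen parent?
#' @return A tibble with columns `genotype` (`TT`, `TG`) and `freq`.
#' @examples
#' expected_backcross_freqs(k = 0.2)
#' @export
expected_backcross_freqs <- function(k = 0.5, f = 0.5,
                                     pollen_parent_het = TRUE) {
  if (inherits(k, "transmission_model")) {
    f <- k$f
    k <- k$k
  }
  check_prob(k, "k")
  check_prob(f, "f")
  p_het <- if (pollen_parent_het) k else f
  tibble(genotype = c("TT", "TG"), freq = c(1 - p_het, p_het))
}

#' Pollen transmission of two linked sterility loci
#'
#' Two sterility loci at recombination fraction `r`, each with its own
#' pollen transmission efficiency, in coupling (both sterile alleles on
#' the same parental chromosome) or repulsion phase. Meiotic haplotype
#' frequencies in coupling are `((1-r)/2, r/2, r/2, (1-r)/2)` over
#' `{++, +s, s+, ss}` (`+` functional, `s` sterile, locus A first).
#' Each haplotype is weighted by a viability factor and the result
#' renormalized: under the multiplicative rule the factor is the product
#' over loci of `2k_L` for a sterile allele and `2(1 - k_L)` for a
#' functional allele; the `minimum` rule takes the smaller per-locus
#' factor instead (the paper-free choice for doubly sterile haplotypes).
#' Tight coupling of two such loci makes them segregate as a single
#' Mendelian factor until recombinants separate them.
#'
#' @param kA,kB Pollen transmission efficiencies at loci A and B.
#' @param r Recombination fraction between the loci in `[0, 0.5]`.
#' @param phase `"coupling"` or `"repulsion"`.
#' @param viability_rule `"multiplicative"` (default) or `"minimum"`.
#' @return A tibble with columns `haplotype`, `meiotic` (pre-selection
#'   frequency), `weight` (viability factor), and `freq` (post-selection,
#'   renormalized).
#' @examples
#' two_locus_pollen_transmission(kA = 0, kB = 0, r = 0)
#' two_locus_pollen_transmission(kA = 0, kB = 0.5, r = 0.2)
#' @export
two_locus_pollen_transmission <- function(kA, kB, r,
                                          phase = c("coupling", "repulsion"),
                                          viability_rule = c("multiplicative",
                                                             "minimum")) {
  check_prob(kA, "kA")
  check_prob(kB, "kB")
  phase <- match.arg(phase)
  viability_rule <- match.arg(viability_rule)
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < 0 || r > 0.5) {
    abort("`r` must be a recombination fraction in [0, 0.5].")
  }
  hap <- c("++", "+s", "s+", "ss")
  meiotic <- if (phase == "coupling") {
    c((1 - r) / 2, r / 2, r / 2, (1 - r) / 2)
  } else {
    c(r / 2, (1 - r) / 2, (1 - r) / 2, r / 2)
  }
  fA <- c(2 * (1 - kA), 2 * (1 - kA), 2 * kA, 2 * kA)
  fB <- c(2 * (1 - kB), 2 * kB, 2 * (1 - kB), 2 * kB)
  weight <- switch(viability_rule,
    multiplicative = fA * fB,
    minimum = pmin(fA, fB)
  )
  w <- meiotic * weight
  tot <- sum(w)
  if (tot <= 0) {
    abort("All haplotypes have zero transmission; frequencies undefined.")
  }
  tibble(haplotype = hap, meiotic = meiotic, weight = weight, freq = w / tot)
}

#' Pollen viability model
#'
#' `sigma` is the probability that a pollen grain carrying the sterile
#' allele at an unrescued locus aborts (1 = fully penetrant killer);
#' `rescue_efficiency` is the probability that one transgene copy present
#' in the gamete restores viability.
#'
#' @param sigma Abortion probability in `[0, 1]`.
#' @param rescue_efficiency Per-copy rescue probability in `[0, 1]`.
#' @return An object of class `pollen_viability_model`.
#' @export
pollen_viability_model <- function(sigma = 1, rescue_efficiency = 1) {
  check_prob(sigma, "sigma")
  check_prob(rescue_efficiency, "rescue_efficiency")
  structure(list(sigma = sigma, rescue_efficiency = rescue_efficiency),
            class = "pollen_viability_model")
}

#' Specify transgene insertions for a complementation design
#'
#' Each insertion carries the functional allele of the sterility gene and
#' segregates Mendelianly from its own insertion site. `zygosity` is
#' `"hemizygous"` (present in half the gametes) or `"homozygous"` (all
#' gametes); `r` is the recombination fraction between the insertion site
#' and the sterility locus it rescues (0.5 = unlinked, the usual case for
#' a random T-DNA insertion); `phase` gives, for a linked hemizygous
#' insertion, which allele of the target locus it sits in cis to.
#'
#' @param zygosity Character vector, `"hemizygous"` or `"homozygous"`.
#' @param r Recombination fraction(s) to the target locus in `[0, 0.5]`.
#' @param locus Integer index of the heterozygous sterility locus each
#'   insertion rescues (for multi-locus designs).
#' @param phase `"cis_sterile"` or `"cis_functional"`.
#' @return A tibble with one row per insertion.
#' @examples
#' transgene_spec("hemizygous")             # one unlinked insertion
#' transgene_spec(c("hemizygous", "homozygous"))
#' @export
transgene_spec <- function(zygosity = character(), r = 0.5, locus = 1L,
                           phase = "cis_sterile") {
  if (length(zygosity) == 0L) {
    return(tibble(zygosity = character(), r = numeric(),
                  locus = integer(), phase = character()))
  }
  zygosity <- match.arg(zygosity, c("hemizygous", "homozygous"),
                        several.ok = TRUE)
  out <- tibble(zygosity = zygosity, r = r, locus = as.integer(locus),
                phase = phase)
  if (any(out$r < 0 | out$r > 0.5 | is.na(out$r))) {
    abort("Transgene linkage `r` must lie in [0, 0.5].")
  }
  if (!all(out$phase %in% c("cis_sterile", "cis_functional"))) {
    abort("`phase` must be \"cis_sterile\" or \"cis_functional\".")
  }
  out
}

# Joint distribution of (sterile allele carried, transgene present) in a
# gamete for one insertion linked at recombination fraction r to its
# target heterozygous locus. Rows: allele 0 = functional, 1 = sterile.
gamete_joint <- function(zygosity, r, phase) {
  if (zygosity == "homozygous") {
    # transgene in every gamete regardless of the target-locus allele
    return(matrix(c(0, 0.5, 0, 0.5), nrow = 2, byrow = TRUE,
                  dimnames = list(allele = c("0", "1"),
                                  transgene = c("0", "1"))))
  }
  # hemizygous: parental chromosomes are (cis allele, transgene) and
  # (trans allele, none)
  cis_sterile <- identical(phase, "cis_sterile")
  p11 <- if (cis_sterile) (1 - r) / 2 else r / 2      # sterile + transgene
  p10 <- 0.5 - p11                                     # sterile, none
  p01 <- 0.5 - p11                                     # functional + transgene
  p00 <- 0.5 - p01
  matrix(c(p00, p01, p10, p11), nrow = 2, byrow = TRUE,
         dimnames = list(allele = c("0", "1"), transgene = c("0", "1")))
}

#' Expected pollen fertility under transgene rescue
#'
#' Expected fraction of viable pollen from a plant heterozygous at one or
#' more gametophytic sterility loci, optionally carrying transgene copies
#' of the functional gene. Computed by exact enumeration over all gamete
#' classes (sterile/functional allele at each locus x presence/absence of
#' each insertion). A gamete carrying the sterile allele at a locus aborts
#' with probability `sigma` unless rescued; each transgene copy present in
#' the gamete and targeting that locus rescues independently with
#' probability `rescue_efficiency`. The classic dosage series for one
#' fully penetrant locus (`sigma = 1`) is 0.50 with no transgene
#' (semi-sterility), 0.75 with one hemizygous unlinked insertion, and
#' 1.00 with a homozygous insertion.
#'
#' @param het_loci Number of sterility loci at which the plant is
#'   heterozygous (loci are assumed mutually unlinked).
#' @param viability A [pollen_viability_model()].
#' @param transgenes A [transgene_spec()] tibble, or `NULL` for none.
#' @return Expected proportion of viable pollen in `[0, 1]`.
#' @examples
#' expected_pollen_fertility(1)                                  # 0.50
#' expected_pollen_fertility(1, transgenes = transgene_spec("hemizygous")) # 0.75
#' expected_pollen_fertility(1, transgenes = transgene_spec("homozygous")) # 1.00
#' @export
expected_pollen_fertility <- function(het_loci = 1,
                                      viability = pollen_viability_model(),
                                      transgenes = NULL) {
  n_loci <- check_count(het_loci, "het_loci")
  stopifnot(inherits(viability, "pollen_viability_model"))
  if (is.null(transgenes)) {
    transgenes <- transgene_spec()
  }
  transgenes <- as_tibble(transgenes)
  if (nrow(transgenes) > 0) {
    if (any(transgenes$r < 0 | transgenes$r > 0.5 | is.na(transgenes$r))) {
      abort("Transgene linkage `r` must lie in [0, 0.5].")
    }
    if (any(transgenes$locus < 1L | transgenes$locus > max(n_loci, 1L))) {
      abort("Transgene `locus` indices must name a heterozygous locus.")
    }
  }
  if (n_loci == 0L) {
    return(1)
  }
  sigma <- viability$sigma
  rescue <- viability$rescue_efficiency
  n_ins <- nrow(transgenes)

  # enumerate alleles at each locus and presence of each insertion
  states <- expand.grid(rep(list(0:1), n_loci + n_ins))
  alleles <- as.matrix(states[, seq_len(n_loci), drop = FALSE])
  present <- as.matrix(states[, n_loci + seq_len(n_ins), drop = FALSE])

  fert <- 0
  for (g in seq_len(nrow(states))) {
    p <- 1
    # insertion presence given its target locus allele; loci independent
    for (l in seq_len(n_loci)) {
      ins_l <- which(n_ins > 0 & transgenes$locus == l)
      p_l <- 0.5  # marginal allele probability at the locus
      if (length(ins_l) > 0) {
        cond <- 1
        for (i in ins_l) {
          jt <- gamete_joint(transgenes$zygosity[i], transgenes$r[i],
                             transgenes$phase[i])
          # conditional presence given locus allele (insertions to the same
          # locus are conditionally independent given the allele)
          pr <- jt[alleles[g, l] + 1L, present[g, i] + 1L] /
            sum(jt[alleles[g, l] + 1L, ])
          cond <- cond * pr
        }
        p_l <- p_l * cond
      }
      p <- p * p_l
    }
    # insertions targeting loci the plant is het at are all covered above;
    # survival: abort independently at each sterile-allele locus
    survive <- 1
    for (l in seq_len(n_loci)) {
      if (alleles[g, l] == 1L) {
        ins_l <- which(n_ins > 0 & transgenes$locus == l)
        carried <- ins_l[present[g, ins_l] == 1L]
        p_not_rescued <- prod(rep(1 - rescue, length(carried)))
        survive <- survive * (1 - sigma * p_not_rescued)
      }
    }
    fert <- fert + p * survive
  }
  fert
}

#' Map between pollen abortion penetrance and transmission efficiency
#'
#' When a fraction `sigma` of sterile-allele pollen aborts and the
#' surviving grains compete equally, the realized transmission of the
#' sterile allele is `k = (1 - sigma) / (2 - sigma)`; the inverse is
#' `sigma = (1 - 2k) / (1 - k)`. The map covers `k` in `[0, 0.5]` only:
#' transmission above the Mendelian 0.5 cannot arise from abortion of the
#' sterile class and is not modeled here.
#'
#' @param k Transmission efficiency in `[0, 0.5]`.
#' @param sigma Abortion probability in `[0, 1]`.
#' @return The corresponding `sigma` (resp. `k`), vectorized.
#' @examples
#' sigma_from_k(0)     # 1: no transmission = fully penetrant abortion
#' sigma_from_k(0.5)   # 0: Mendelian = no abortion
#' k_from_sigma(sigma_from_k(0.11))
#' @export
sigma_from_k <- function(k) {
  if (!is.numeric(k) || anyNA(k) || any(k < 0)) {
    abort("`k` must be numeric in [0, 0.5].")
  }
  if (any(k > 0.5)) {
    abort(paste("`k` > 0.5 implies enhanced transmission of the sterile",
                "allele, which abortion of the sterile pollen class cannot",
                "produce; it is outside this map's range."))
  }
  (1 - 2 * k) / (1 - k)
}

#' @rdname sigma_from_k
#' @export
k_from_sigma <- function(sigma) {
  if (!is.numeric(sigma) || anyNA(sigma) || any(sigma < 0) || any(sigma > 1)) {
    abort("`sigma` must be numeric in [0, 1].")
  }
  (1 - sigma) / (2 - sigma)
}
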