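---
title: "Transmission genetics of gametophytic pollen sterility loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transmission genetics of gametophytic pollen sterility loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametx)
```

## The biological setting

Interspecific rice hybrids are often semi-sterile: about half of their
pollen aborts. A common cause is a *gametophytic* sterility locus — the
fate of each pollen grain is decided by its own haploid genotype, not by
the diploid parent. In a heterozygote carrying a functional allele
(`T`, for the cultivated parent) and a sterile allele (`G`, from the
wild species), the half of the pollen that inherits the sterile allele
aborts, and the locus is transmitted through pollen at a distorted
rate. Two tightly linked loci of this kind, inherited in coupling phase
on the same wild-species chromosome segment, masquerade as a single
Mendelian factor until recombinants separate them.

gametx implements the quantitative genetics used to dissect such loci:
the transmission model, maximum-likelihood estimation of the pollen
transmission efficiency *k*, exact tests for transgene complementation,
pollen-fertility dosage predictions, recombinant-based interval
delimitation, and seeded simulators for every population type the
analysis consumes.

## The transmission model

Let *k* be the probability that the sterile allele is transmitted
through a (functional) pollen grain, and *f* the same probability for
female gametes. Selfing a heterozygote gives offspring genotype
probabilities

$$P(TT) = (1-f)(1-k), \quad P(TG) = (1-f)k + f(1-k), \quad P(GG) = fk.$$

Pollen sterility does not touch the embryo sac, so *f* is fixed at 0.5
throughout the package's defaults (it remains a free parameter for
generality), giving $((1-k)/2,\ 1/2,\ k/2)$. Two consequences shape the
inference:

* the heterozygote class always has probability 1/2, so `n_TG` carries
  no information about *k*;
* conditional on the number of homozygous ("informative") offspring,
  `n_GG` is binomial with success probability *k*.

The MLE is therefore the closed form
$\hat k = n_{GG} / (n_{TT} + n_{GG})$, returned exactly at the
boundaries rather than clipped. `ci_k()` offers an exact
Clopper–Pearson interval (the default — valid at all sample sizes,
including zero counts) and a profile-likelihood interval;
`lrt_k()` tests point nulls, halving the p-value for boundary nulls
(`k0 = 0` or 1), where the null distribution is the 50:50 mixture of a
point mass and $\chi^2_1$.

A fully penetrant pollen killer has $k = 0$ and segregates 1:1:0
(TT : TG : GG). When a fraction $\sigma$ of sterile-allele pollen aborts
and survivors compete equally, $k = (1-\sigma)/(2-\sigma)$;
`sigma_from_k()`/`k_from_sigma()` give this map on $k \in [0, 0.5]$.
Transmission *above* 0.5 cannot arise from abortion of the sterile
class, so the map refuses it rather than extrapolating.

## Complementation tests

Whether a candidate genomic fragment rescues the sterile pollen class
is read from T1 segregation: a rescuing transgene raises transmission
of the sterile allele towards Mendelian. Each transgenic family is
compared with the non-transgenic control family by the
Fisher–Freeman–Halton exact test — the conditional test of independence
for a 2×3 table with all margins fixed, the two-sided p summing the
multivariate hypergeometric probabilities of every table no more
probable than the observed one. Numerical choices: table probabilities
are computed with log-gamma (no factorial overflow near n ≈ 170), and
probability ties are absorbed with a relative tolerance of 1e-7.

The control-family footnote wording ("tested at empirical segregation
ratios") could also be read as a goodness-of-fit of each transgenic
family against the control's *proportions*; `multinomial_exact_gof()`
implements that reading (full enumeration to n = 200, seeded Monte
Carlo beyond), and `chi2_gof()` gives the asymptotic companion. The
independence test is the primary reading because it reproduces the
published p-values exactly.

## Pollen fertility under transgene rescue

`expected_pollen_fertility()` enumerates gamete classes exactly. A
gamete aborts with probability `sigma` at each heterozygous sterility
locus where it carries the sterile allele, unless a transgene copy
present in the same gamete rescues it (per-copy success
`rescue_efficiency`); insertions segregate Mendelianly from their own
site, optionally linked to the target locus at recombination fraction
*r* with an explicit cis phase. For one fully penetrant locus this
yields the diagnostic dosage series: 50% fertility unrescued, 75% with
one hemizygous unlinked insertion, 100% with a homozygous insertion —
the pattern by which a gametophytic (rather than sporophytic) mode of
rescue is recognized.

For two linked loci, `two_locus_pollen_transmission()` weights the four
meiotic haplotypes by per-locus transmission factors and renormalizes.
The two published loci were never measured jointly in a double
heterozygote, so the combination rule for a doubly sterile haplotype is
a modeling choice, not an empirical claim: the default is
multiplicative, and a `minimum` rule is offered as the conservative
alternative.

## Interval delimitation from recombinants

Under the 1:1:0 model a semi-sterile plant is heterozygous at the locus
and a fully fertile plant homozygous `T`; each phenotyped recombinant
therefore restricts the locus to the positions where its genotype can
equal the phenotype-implied genotype, and the candidate interval is the
intersection of those restrictions, reported as flanking markers with
half-open sides where a breakpoint tightened them.

Positions are resolved below the marker grid. For a gap between markers
with wild-allele doses $x, y \in \{0,1,2\}$, the locus dose reachable
with **at most one crossover per gamete** is any value in
$[\max(0, x+y-2),\ \min(2, x+y)]$ — e.g. flanks `T` and `G` can bracket
a heterozygous locus, because the plant's two gametes may have crossed
over in opposite directions within that gap. This is deliberately more
permissive than the classical parsimony rule (anything between the two
flanking doses): parsimony silently declares impossible the
plant-level double crossovers (two single-crossover gametes in one gap)
that do occur at rate $\approx r^2$ per plant, and in simulated
500-plant screens that produced spurious "conflicting recombinant"
errors in about 5% of replicates. With the achievability rule, only
genuinely impossible configurations conflict; an empty intersection is
reported with the offending plant named, since it signals a
phenotyping/genotyping error or a second segregating locus. Missing
calls (`-`) are compatible with anything — they widen constraints,
never tighten them. Homozygous-wild calls, impossible at the locus
itself under 1:1:0, are handled by the same rule rather than a special
case. A delimitation may legitimately end in a *marker-free* gap — that
is what successful fine mapping looks like — and non-contiguous allowed
regions (possible with sparse conflicting evidence) are returned as
multiple segments with a warning.

Plants are labelled *informative* when their own constraint sets a
final interior boundary; plants heterozygous across the whole window
but non-recombinant constrain nothing and are so labelled.

## Simulators

All generators are pure functions of `(parameters, seed)`; the root
seed is split into named substreams per stage, so adding one stage
never perturbs another's draws.

* `simulate_selfing_counts()` — one multinomial family from the selfing
  model; the study-scale default family is n ≈ 90, matching the T1
  families the tables report (n = 29–128).
* `simulate_marker_population()` — selfed mapping population with
  per-interval recombination (Haldane map function on cM distances, no
  interference), male-side rejection sampling with viability
  $k/(1-k)$ for sterile-allele gametes, and an optional switch that
  caps each gamete at one crossover for clean interval-mapping tests.
  Genetic positions are required in cM; the bundled synthetic map uses
  nominal 0.8-cM spacings typical of an SSR fine-mapping grid.
* `simulate_complementation_t1()` — gamete-level rescue: a
  sterile-allele pollen grain survives if it carries the transgene and
  the rescue succeeds, matching the gametophytic interpretation of
  complementation; the transgene segregates from its own insertion
  site, linked or unlinked.
* `recovery_experiment()` — bias/RMSE/coverage of the estimator across
  a *k* grid.

What the generators emulate — and what they do not: multinomial
sampling of genotype classes, transmission distortion on the male side
only, Mendelian transgene segregation, and crossover placement without
interference. They do not model genotyping error, segregation-distorting
loci elsewhere in the genome, pollen-count variation between flowers,
or certation (competition) dynamics beyond the $\sigma \leftrightarrow k$
map. Passing the simulation-based tests therefore demonstrates
correctness of the inference under the stated model, not robustness to
those artefacts.

## Numerical and design notes

* Estimates are carried at full precision; printed-precision rounding
  (half-up, 2 or 3 decimals as in the published tables) exists only in
  the report layer.
* Exact-test tie handling uses a 1e-7 relative tolerance; enumeration
  counts are returned so users can see the work done.
* The multinomial GOF enumerates only to n = 200 and then *refuses*
  (pointing to Monte Carlo) rather than silently switching method.
* Significance stars are presentation-only, with configurable
  thresholds, and never feed back into any computation.
* Verification problem sizes were chosen once: 200 random count vectors
  against a 1e-6 grid-search oracle, 50 random tables against an
  independent second enumeration, 1000 replicates of n = 500 families
  per grid point for estimator recovery, and 500 replicates of
  500-plant screens for interval containment.

## Known limitations

* Joint estimation of *k* and *f* from a single selfed family is
  confounded; *f* must be fixed (or estimated from reciprocal designs
  outside this package's scope).
* The exact enumeration of 2×C tables is limited to C ≤ 5; larger
  tables would need the network algorithm, which this package does not
  implement.
* Enhanced transmission (k > 0.5) is accepted by the estimator — the
  data decide — but the abortion-based $\sigma$ map and the mapping
  simulator deliberately exclude it.
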