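# gametx

Quantitative genetics of **gametophytic pollen sterility loci** — the
hybrid-incompatibility loci of interspecific rice crosses whose
semi-sterile heterozygotes abort the half of their pollen that carries
the wild-species allele. The package is for geneticists running
map-based cloning and transgene complementation of such loci: it turns
T1 segregation counts and recombinant marker tables into transmission
estimates, exact tests, fertility predictions, and candidate intervals.

## The model

For a locus with functional allele *T* and sterile allele *G*, the
transmission efficiency *k* is the probability that *G* passes through
a pollen grain (Mendelian value 0.5; a fully penetrant pollen killer
has *k* = 0). Selfing a heterozygote gives genotype probabilities

    P(TT) = (1 − k)/2,   P(TG) = 1/2,   P(GG) = k/2

so, conditional on the homozygous offspring, `n_GG` is binomial with
success probability *k* and the MLE is the closed form
`k̂ = n_GG / (n_TT + n_GG)`, with exact Clopper–Pearson or
profile-likelihood intervals. Complementation is judged by the
Fisher–Freeman–Halton exact test of each transgenic family against the
non-transgenic control, and the gametophytic mode of rescue is
recognized by the pollen-fertility dosage series 50% → 75% → 100% as
transgene copies per plant go 0 → 1 → 2. When a fraction σ of
sterile-allele pollen aborts, k = (1 − σ)/(2 − σ).

Modules: deterministic genetic models (`expected_selfing_freqs`,
`two_locus_pollen_transmission`, `expected_pollen_fertility`,
`sigma_from_k`), ML inference (`mle_k`, `ci_k`, `lrt_k`, `estimate_k`),
exact tests (`freeman_halton_2xc`, `compare_to_control`,
`multinomial_exact_gof`, `chi2_gof`), interval mapping
(`breakpoint_intervals`, `delimit_locus`, `estimate_recomb_rate`),
seeded simulators (`simulate_selfing_counts`,
`simulate_marker_population`, `simulate_complementation_t1`,
`recovery_experiment`), and TSV/JSON I/O with a thin CLI
(`inst/cli/gametx.R`). See the vignette
`vignettes/transmission-genetics.Rmd` for the methods.

## Worked example

The bundled fixture `rm7033_t1_counts.tsv` holds the T1 genotype counts
of a complementation series at a pollen sterility locus — four
transformed families plus the non-transgenic control:

```r
library(gametx)
tbl <- read_counts_tsv(system.file("extdata", "rm7033_t1_counts.tsv",
                                   package = "gametx"))
estimate_k(tbl)
#> # A tibble: 5 × 8
#>   population         n informative_n k_hat ci_low ci_high ci_method      loglik
#>   <chr>          <int>         <int> <dbl>  <dbl>   <dbl> <chr>           <dbl>
#> 1 Eco72I            33            13 0     0        0.247 exact_binomial  -22.9
#> 2 XmnI_a            52            31 0.161 0.0545   0.337 exact_binomial  -49.7
#> 3 SalI              78            37 0.514 0.344    0.681 exact_binomial  -79.7
#> 4 XmnI_b            29            17 0.118 0.0146   0.364 exact_binomial  -26.3
#> 5 Non-transgenic    90            47 0.106 0.0355   0.231 exact_binomial  -78.3

compare_to_control(tbl, control = "Non-transgenic")[, c("population", "p", "stars")]
#> # A tibble: 4 × 3
#>   population        p stars
#>   <chr>         <dbl> <chr>
#> 1 Eco72I     0.320    ""
#> 2 XmnI_a     0.524    ""
#> 3 SalI       0.000167 "***"
#> 4 XmnI_b     0.736    ""
```

Reading: in the control family the sterile allele passes through pollen
at `k̂ ≈ 0.11` instead of 0.5 — the signature of gametophytic pollen
abortion. Only the SalI fragment shifts segregation away from the
control (`p ≈ 0.00017`), restoring transmission to `k̂ ≈ 0.51`,
i.e. full Mendelian rescue: the causal gene lies on that fragment. The
other fragments leave the distortion intact.

The dosage check that the rescue acts in the haploid pollen grain:

```r
expected_pollen_fertility(1)                                        # 0.5
expected_pollen_fertility(1, transgenes = transgene_spec("hemizygous"))  # 0.75
expected_pollen_fertility(1, transgenes = transgene_spec("homozygous"))  # 1
```

And interval delimitation from phenotyped recombinants (synthetic
fixture):

```r
map  <- read_map_tsv(system.file("extdata", "marker_map_synthetic.tsv",
                                 package = "gametx"))
recs <- read_marker_tsv(system.file("extdata", "recombinants_synthetic.tsv",
                                    package = "gametx"), map)
delimit_locus(recs, map)
#> <candidate_interval> (M4, M6)
#>   span: 62,000 bp
#>   informative plants: 9-7, 23-2
```

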