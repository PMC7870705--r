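Package: gametx
Title: Gametophytic Transmission Genetics for Pollen Sterility Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative genetics of gametophytic pollen sterility loci in
    hybrid plants, built around the transmission-efficiency parameter k (the
    probability that the sterile allele is transmitted through pollen;
    Mendelian value 0.5). Provides maximum-likelihood estimation of k from
    selfed-family genotype counts with exact binomial and profile-likelihood
    confidence intervals, Fisher-Freeman-Halton exact tests of segregation
    independence for transgene complementation experiments, deterministic
    models of expected genotype frequencies and pollen-fertility dosage under
    transgene rescue, recombinant-breakpoint delimitation of candidate locus
    intervals from marker genotypes, and seeded simulators for selfed,
    backcross, mapping, and complementation populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
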