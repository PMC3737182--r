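Package: sweepIS
Title: Selection Intensity and Allele Age from Multilocus Haplotype Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structured-coalescent inference of the selection coefficient and
    allele age of a positively selected mutation from the multilocus haplotype
    structure of linked SNPs. Selected haplotypes are reduced to the extent of
    the retained ancestral segment around the mutant (two recombination
    coordinates) plus mutation coordinates under the infinitely-many-sites
    model. The likelihood is evaluated by sequential importance sampling over
    intra-allelic genealogies conditional on Wright-Fisher allele-frequency
    trajectories sampled backward in time under selection and arbitrary
    demography. Includes a Monte Carlo likelihood curve with local-linear
    smoothing, profile-likelihood confidence intervals, an allele-age
    posterior, a forward sweep-data simulator with known truth, and an exact
    two-locus dynamic-programming oracle used to validate the sampler.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
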