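Package: mecgwas
Title: Effect-Site Fentanyl MEC Phenotypes and Multi-Stage GWAS of Opioid Sensitivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates plasma and effect-site minimum effective concentrations
    (MECs) of fentanyl from postoperative patient-controlled analgesia dosing
    histories via a closed-form three-compartment effect-site pharmacokinetic
    model, and analyses the resulting log-transformed MEC phenotypes with a
    three-stage genome-wide association design (additive, dominant and
    recessive genotype codings, covariate adjustment, pooled combined tests,
    greedy linkage-disequilibrium pruning at a fixed r-squared threshold, and
    Benjamini-Hochberg false discovery rate q-values). Includes Hardy-Weinberg
    chi-square and exact tests, EM estimation of two-locus haplotype
    frequencies for D-prime and r-squared, noncentral-F power calculations for
    the per-stage regression, clinical covariate screening statistics, and a
    seeded synthetic-cohort generator (Hardy-Weinberg genotypes with optional
    LD blocks, covariates, latent MECs with genetic and covariate effects, and
    closed-loop demand dosing under pump lockout, hourly-cap and capacity
    rules) so that every stage of the pipeline is testable without patient
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
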