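Package: sasflex
Title: Small-Angle Scattering Analysis of Flexible Membrane-Receptor Oligomers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward modelling and inference for small-angle X-ray and
    neutron scattering (SAXS/SANS) of detergent-solubilized membrane
    receptor--transducer complexes. Builds coarse-grained particle models
    with flexible hinge bends and C3 trimer-of-dimers assemblies, adds a
    two-shell detergent-corona pseudo-atom belt with tabulated X-ray and
    neutron scattering properties, computes Debye-formula scattering
    curves under solvent contrast, performs model-free curve analysis
    (Guinier fits, regularized indirect Fourier transform to P(r),
    dimensionless Kratky plots), and fits experimental curves as
    Tikhonov-regularized non-negative hinge-conformer ensembles or as
    dimer/trimer-of-dimers mixtures with weight-fraction uncertainties.
    A synthetic-data generator provides ground-truth models, ensembles,
    mixtures and noisy curves for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
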