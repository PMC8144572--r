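# sasflex

Small-angle scattering (SAXS/SANS) forward modelling and inference for
detergent-solubilized membrane receptor–transducer complexes — the kind of
system where a compact transmembrane domain carries a ~200 Å flexible
cytoplasmic rod and assembles into trimers of dimers at high ionic
strength.

The package implements the full inference chain on coarse-grained bead
models:

* **Forward model** — Debye-formula scattering
  `I(q) = Σᵢⱼ Δbᵢ Δbⱼ sin(q rᵢⱼ)/(q rᵢⱼ)` under X-ray or neutron solvent
  contrast, accelerated by a weighted pair-distance histogram (Rcpp), with
  a NaCl/H₂O/D₂O solvent model and a two-shell DDM detergent-corona built
  from CH₃-chunk pseudo-atoms (9/97 of a C₁₂H₂₅ tail, 10/181 of a
  C₁₂H₂₁O₁₁ head, head hydrogens exchanging in D₂O).
* **Geometry** — membrane-frame orientation, rigid hinge bends at the
  HAMP1/HAMP2/Gly hinges (−90°…90°), exact-C3 "tripod" and
  "TM-bound" trimer-of-dimers assembly, radii of gyration, inter-dimer
  separations.
* **Model-free analysis** — iterated Guinier fits, Tikhonov-regularized
  indirect Fourier transform to P(r) with L-curve α selection, P(r)
  moments and peak detection, dimensionless Kratky plots.
* **Inference** — ensemble fitting of hinge-conformer bases by
  non-negative least squares regularized toward the least-informative
  weight distribution (per-hinge RMS bending angles as the identifiable
  statistic), and dimer / trimer-of-dimers weight-fraction deconvolution
  with uncertainties.
* **Synthetic data** — deterministic toy receptor dimers, bead spheres,
  heteroscedastic SANS-like noise, and ensemble/mixture datasets with
  known ground truth, so every stage is validated end-to-end without
  downloads.

## Worked example

Simulate a SANS curve from a 64:36 mixture of belted dimers and
tripod-shaped trimers of dimers at 4 M NaCl in D₂O, then recover the
mixture:

```r
library(sasflex)

dimer  <- build_belt(make_toy_dimer(), belt_spec())
tripod <- assemble_c3(dimer, 90 / sqrt(3), "tripod")   # inter-TM 90 A
ds  <- make_mixture_dataset(dimer, tripod, trimer_fraction = 0.36,
                            noise = noise_spec(seed = 11),
                            solvent = solvent_model(4, 1),
                            radiation = "neutron")
mixture_fractions(ds$components, ds$curve)
#>   dimer               65.5 % (+/- 0.9)
#>   trimer_of_dimers    34.5 % (+/- 0.9)
#>   chi2 = 0.875
```

The fitted weight fraction (34.5 ± 0.9 %) recovers the generating truth
(36 %), with χ² ≈ 0.9 confirming the fit sits within the declared noise.
The same machinery fits flexible-hinge ensembles:

```r
basis <- build_hinge_basis(make_toy_dimer(),
                           q = default_q_grid("saxs", 121),
                           solvent = solvent_model(0.15, 0))
ens <- make_ensemble_dataset(make_toy_dimer(), rms_deg = 55, seed = 7,
                             noise = noise_spec(seed = 7), basis = basis)
tikhonov_nnls(basis, ens$curve)
#> ensemble_fit: chi2 = 0.874, alpha = 75, effective members = 282
#> per-hinge RMS bend: HAMP1 56.7, HAMP2 53.0, Gly 57.5 deg
```

The recovered per-hinge RMS bending angles (53–58°) match the generating
ensemble (≈51° after grid snapping) within the ±10° resolution of the
method, and sit in the 50–60° range characteristic of a highly flexible
transducer rod.

The `analysis/` directory holds the numbered workflow scripts
(`01_contrast_bookkeeping.R` … `05_mixture_fit.R`) that run the complete
chain — contrast tables, forward curves, model-free diagnostics, ensemble
fit, and the salt-series mixture deconvolution — writing their tables and
curves under `results/`.

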