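---
title: "Small-angle scattering inference for flexible membrane-receptor oligomers"
author: "sasflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-angle scattering inference for flexible membrane-receptor oligomers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sasflex)
```

## The problem

Detergent-solubilized photoreceptor/transducer complexes of the
chemoreceptor family are hard targets for crystallography: a compact
membrane domain carries a ~200 Å flexible cytoplasmic rod, and the
functional unit in the membrane is a trimer of dimers. Small-angle X-ray
and neutron scattering (SAXS/SANS) sees such particles in solution, but
extracting structure from a 1-D curve requires a forward model (how does a
candidate structure scatter?), model-free diagnostics (how big, how
flexible, how many components?), and inference procedures (which ensemble
of bent conformers, which oligomer mixture, explains the data?). sasflex
implements that chain end-to-end and validates every stage on synthetic
data with known ground truth.

The scientific picture the chain is built around: at low ionic strength
the complex is a dimer whose cytoplasmic rod bends at three hinges (the
two HAMP domains and the glycine hinge of the adaptation region); at high
ionic strength dimers associate into a "tripod"-shaped trimer of dimers
that touches only at the cytoplasmic tips, leaving the transmembrane
domains ~90 Å apart.

## Forward model

Scatterers are coarse-grained beads (one per residue for protein, one
pseudo-atom per CH3-sized chunk for detergent). The orientationally
averaged intensity is the Debye sum

$$I(q) = \sum_{ij} \Delta b_i \, \Delta b_j \,
  \frac{\sin(q r_{ij})}{q r_{ij}},$$

with per-bead solvent contrasts $\Delta b_i = b_i - \rho_s V_i$ (neutrons)
or $e_i - \rho_e V_i$ (X-rays). The pairwise sum is accelerated by a
weighted pair-distance histogram (bin 0.5 Å). Two numerical choices
matter:

* each histogram bin uses the |weight|-weighted mean pair distance rather
  than the bin centre, which removes the first-order binning error — the
  accelerated sum then agrees with the exact double sum to well under
  0.3 % for positive-contrast models;
* binned sums can undershoot zero by their truncation error in deep
  form-factor minima, so intensities are clamped at zero (they are
  non-negative by construction).

Bead form-factor $q$-dependence and a hydration shell are deliberately
omitted: at the working range ($q \lesssim 0.5$ Å⁻¹) sub-residue detail is
invisible and the hydration contribution is absorbed by the fitted scale.
Against a homogeneous bead-filled sphere (boundary cells carry
partial-volume weights at their inside-sphere centroid) the engine matches
the analytic sphere form factor within 1 % up to $qR = 8$ wherever the
form factor exceeds $10^{-3}$ of $I(0)$; relative error inside the
near-zero minima is not meaningful at any discretization.

## Solvent and detergent contrast

`solvent_model()` computes the electron density and neutron SLD of
NaCl/H2O/D2O buffers from tabulated bound coherent scattering lengths
(Sears values: H −3.739, D 6.671, C 6.646, N 9.36, O 5.803 fm) with a
Masson apparent-molar-volume correction for the salt. It reproduces the
working range of the experiment: 0.334 e/Å³ for pure water rising ~11 % at
4 M NaCl, while the D2O-buffer SLD falls only ~3 % over the same range —
the quantitative reason the oligomer titration is analysed in SANS, where
the contrast is essentially salt-independent and all components (protein,
both belt shells) sit on the same side of the solvent SLD.

The DDM corona is a two-shell elliptical torus: a hydrophobic shell
(|z| ≤ t) wrapped radially and axially by a hydrophilic shell. The
per-pseudo-atom scattering follows the electron-fraction convention: a
tail pseudo-atom carries 9/97 of a C12H25 tail (9 e), a head pseudo-atom
10/181 of a C12H21O11 maltoside head (10 e), with the head's seven
exchangeable hydrogens deuterated in proportion to the solvent D2O
fraction. Those fractions identify the pseudo-atom with a CH3-sized chunk:
at the DDM molecular volume of 350 Å³ per tail and per head the chunk
volumes are 32.5 and 19.3 Å³, so a fully packed belt reproduces the
detergent electron densities 97/350 = 0.277 and 181/350 = 0.517 e/Å³ —
below and above water, giving the two shells opposite X-ray contrasts,
while in D2O both shells and the protein share one contrast sign. The
derived neutron quantities land on the printed experimental values: tail
−1.27 fm, head 7.62 fm, shell SLDs −0.39×10⁻⁶ and 3.9×10⁻⁶ Å⁻², and
equivalent CH3 perdeuteration parameters 0.1056 and 0.3904.

Pseudo-atoms are placed on a jittered hexagonal lattice (fixed seed,
reproducible) with a 1.8 Å exclusion zone around protein beads. Belt
dimensions default to a = b = 40 Å, t = 15 Å, 6 Å head shell — a
DDM-corona scale typical for a two-monomer membrane bundle; the authors'
fitted dimensions are not published, so only the fraction scheme is exact.

## Geometry: hinges and trimers

`bend_at_hinge()` rotates all scatterers distal to a pivot residue (the
centroid of that residue's beads over chains and strands) about an axis
perpendicular to the distal rod axis, $\hat z \times \hat r$, falling back
to $\hat x$ when the rod is within ~3° of the z axis — without the
threshold, numerical noise picks an arbitrary bending azimuth and can
shear the two chains through each other. The convention makes all bends
coplanar, which has a physical consequence: conformers related by a
reflection scatter almost identically, so individual ensemble weights are
only weakly identifiable (see below); even-order statistics such as RMS
bending angles are unaffected.

`assemble_c3()` builds trimers of dimers with exact C3 symmetry. In
`tripod` mode each dimer is tilted about its cytoplasmic tip so the TM
centroid moves out to the requested radius while the tips stay converged
on the axis; inter-TM distances are then radius × √3 (90 Å at the 52 Å
default used in the analysis scripts). In `tm_bound` mode the dimers are
displaced radially without tilting, keeping the membrane domains adjacent.
A fold-back clash filter (any non-local bead pair closer than 1 Å;
pairs within 7 residues along a chain are exempt because an instantaneous
bend of a thick strand bundle necessarily pinches the inner corner over a
~10 Å contour) flags and excludes unphysical conformers — on the default
toy dimer exactly one of the 343 grid conformers is excluded.

## Model-free analysis

* **Guinier**: iterated weighted fit of $\ln I$ vs $q^2$ over the largest
  window with $q_{\max} R_g \le 1.3$ (the default window rule). For
  globular shapes the truncated-window estimator carries a known bias
  below 2 %; for strongly elongated particles the window should be
  tightened (`qrg_max` ≈ 0.8), which the rod validation uses.
* **P(r)**: regularized indirect Fourier transform on a uniform 101-point
  grid, minimizing $\chi^2 + \alpha \lVert P'' \rVert^2$ with
  $P(0) = P(D_{max}) = 0$ and $P \ge 0$ (active-set NNLS on the stacked
  system); $\alpha$ = "auto" takes the L-curve corner (maximum discrete
  curvature of log-misfit vs log-seminorm). Trapezoidal quadrature
  throughout. Validated against the closed-form sphere distance
  distribution (peak at 1.05 R) and by Guinier/P(r) cross-consistency.
* **Kratky**: dimensionless $(qR_g)^2 I/I(0)$; an ideal globule peaks at
  $\sqrt3$ with value $3/e$, flexible/extended particles peak higher. The
  synthetic flexible-dimer ensemble peaks at $qR_g \approx 5$–10 depending
  on contrast and belt configuration — qualitatively the flexible regime,
  though the exact peak position of the real complex (4–7) is not
  reproduced because the toy rod cross-section and belt fine structure
  differ from the real system.
* **pr_peaks**: local maxima filtered by topographic prominence (default
  5 % of max). On the synthetic SANS series, the dimer component peaks at
  ~36 Å (membrane domain + corona cross-section) and the tripod trimer at
  ~99 Å (inter-dimer distances) — the two-peak signature by which mixtures
  of dimers and tripod trimers are recognized. In the mixed curve itself
  the long straight-dimer tail partially masks the second peak, so the
  component-wise distributions carry the diagnostic.

## Ensemble inference

`build_hinge_basis()` applies every (θ_HAMP1, θ_HAMP2, θ_Gly) triple from
−90° to 90° in 30° steps (applied proximal to distal), re-uses the rigid
belt's self-scattering across members, and collects 343 conformer curves.
`tikhonov_nnls()` then solves

$$\min_{w \ge 0} \left\lVert \frac{c\,A w - I_{exp}}{\sigma} \right\rVert^2
 + \alpha^2 \lVert \Gamma (w - u) \rVert^2,$$

where $u$ is the uniform distribution over the basis. Regularizing toward
uniform (rather than toward zero) matters: the conformer curves overlap
strongly, so unregularized NNLS returns sparse solutions concentrated on
extreme bends, inflating RMS-angle estimates by ~10°, while the
least-informative prior leaves the identifiable statistics nearly
unbiased and gives the clean limit $w \to u$ as $\alpha \to \infty$.
$\Gamma$ is the identity by default (optionally a nearest-neighbour
difference over the angle grid); $\alpha$ = "auto" by L-curve corner. The
overall scale is pinned by an unregularized pre-fit and refit after
normalization; $\chi^2$ is reduced by N − 1, treating the regularized
weights as constrained rather than free parameters.

What is and is not identifiable deserves emphasis: with 343 smooth,
strongly overlapping basis curves and ~percent-level noise, individual
member weights are not recoverable (verified directly — at 2 % noise,
member-weight errors reach 0.25 even though the fitted curve is within
noise), but ensemble functionals are. The validation therefore centres on
the per-hinge RMS bending angle
$\mathrm{RMS}_h = \sqrt{\sum_m w_m \theta_{m,h}^2}$: data generated from a
55° RMS Gaussian ensemble (snapped to the grid, 2000 draws) is recovered
within ±10° per hinge across seeds, at SANS/SAXS-like noise.

## Mixture inference

`mixture_fractions()` fits an experimental curve as a non-negative
combination of component curves normalized per complex mass (a trimer of
dimers carries three dimer masses), so the coefficients are weight
fractions in the OLIGOMER sense. Uncertainties come from the
least-squares covariance at the solution through the normalization
Jacobian, optionally replaced by a residual bootstrap (fixed seed). The
fit is scale-invariant, warns on near-collinear components (condition
number > 1e8), and survives exactly collinear input via a vanishing
ridge. On the synthetic salt series (tripod fractions 18/28/36 %,
SANS-like noise) the fractions are recovered within ±3 points with ~±1
point nominal uncertainty, and `compare_trimer_hypotheses()` ranks the
generating hypothesis (tripod vs TM-bound) first by χ².

## The synthetic-data generator

`make_toy_dimer()` builds a deterministic two-chain bead model: two
filled membrane cylinders (13 Å radius, 34 Å height, 150 beads each —
roughly half the protein mass, emulating the receptor + TM-transducer
share of the complex) and a 200 Å four-strand cytoplasmic rod (two
strands per chain at coiled-coil rise 1.5 Å/residue) with hinge pivots at
rod fractions 0.12/0.35/0.61, following the transducer construct
proportions. Geometry is seed-free; seeds only tag metadata and drive
noise. `noise_spec()` produces heteroscedastic Gaussian noise
$\sigma = a I + b \sqrt{I \cdot I_{ref}}$ (defaults a = 0.02, b = 0.015
with a small floor), i.e. ~2–4 % relative error at low q growing to
~15 % where the signal has fallen a hundredfold — the quality of typical
reactor-SANS data. Replicate averages converge to the forward curve and
the declared σ columns are χ²-consistent (mean χ² in [0.9, 1.1] over 100
seeds).

What the generator does *not* emulate: instrument resolution smearing,
inter-particle structure factor, partial disorder/unfolding of the rod,
aggregation, and buffer-subtraction artefacts. Passing tests therefore
demonstrate that the inference chain is correct and well-calibrated under
its own assumptions, not that those assumptions exhaust real data.

## Problem sizes and defaults

The validation suite runs at desk scale by choice: 41 k-bead sphere for
the forward-model check, an 812-bead dimer with ~11 k belt pseudo-atoms,
343-member bases on 121-point q grids, 2000-conformer ensembles, and
100-seed noise-calibration loops. Tolerances asserted in tests are the
ones stated above; none is tightened or loosened per seed. All lengths
are Å, q in Å⁻¹, neutron scattering lengths in fm, SLDs in Å⁻², electron
densities in e/Å³.

## Known limitations

* No hydration shell and no atomic form factors: absolute X-ray scales
  are nominal and χ² values against real curves would differ from
  CRYSOL/CRYSON-style evaluations.
* The belt geometry is parameterized, not fitted to data; only the
  scattering-fraction scheme is exact.
* Planar hinge bending under-represents out-of-plane conformers; mirror
  near-degeneracy limits per-member ensemble identifiability (even-order
  statistics are unaffected).
* The L-curve corner is a deterministic but heuristic α choice; for
  publication-grade P(r), Dmax and α should be inspected, not defaulted.
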