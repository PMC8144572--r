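#' Toy receptor-dimer specification
#'
#' Parameters of the coarse-grained two-chain dimer generator: a
#' transmembrane (TM) helix bundle emulating the receptor/transducer
#' membrane part, and a pair of long cytoplasmic rods (default 200 A,
#' the length of the transducer) carrying three bending hinges.
#'
#' @param tm_radius Radius of each monomer's membrane-domain cylinder, A.
#' @param tm_height Membrane-domain height, A.
#' @param tm_nres Beads (residues) per chain in the membrane domain; the
#'   default puts roughly half the protein mass there, emulating the
#'   receptor + transmembrane-transducer share of the complex.
#' @param tm_sep Separation of the two monomers' cylinder axes, A.
#' @param rod_length Cytoplasmic rod length, A (default 200, the length
#'   of the transducer rod).
#' @param rod_rise Axial rise per rod residue, A (one bead per residue;
#'   1.5 A emulates a coiled coil).
#' @param rod_offset Half-separation of the chain rods along x, A. Each
#'   chain's rod is a pair of strands (the up/down helices of the
#'   antiparallel hairpin) at `+/- rod_offset` in y, so the dimer rod is
#'   a four-strand bundle roughly `2*rod_offset` across.
#' @param hinge_fractions Positions of the HAMP1, HAMP2 and Gly hinges as
#'   fractions along the rod. The defaults follow the transducer
#'   construct proportions (hinges near residues 136, 230 and 340 of a
#'   cytoplasmic region spanning roughly residues 84-504).
#' @param seed Seed recorded in generated metadata (the geometry itself
#'   is deterministic).
#' @return List of class `toy_model_spec`.
#' @export
toy_model_spec <- function(tm_radius = 13, tm_height = 34, tm_nres = 150,
                           tm_sep = 22,
                           rod_length = 200, rod_rise = 1.5,
                           rod_offset = 5,
                           hinge_fractions = c(HAMP1 = 0.12, HAMP2 = 0.35,
                                               Gly = 0.61),
                           seed = 1) {
  stopifnot(tm_radius > 0, tm_height > 0, tm_nres >= 3, tm_sep >= 0,
            rod_length > 0, rod_rise > 0)
  if (any(hinge_fractions <= 0 | hinge_fractions >= 1))
    stop("hinge fractions must lie strictly inside (0, 1)")
  structure(list(tm_radius = tm_radius, tm_height = tm_height,
                 tm_nres = tm_nres, tm_sep = tm_sep,
                 rod_length = rod_length, rod_rise = rod_rise,
                 rod_offset = rod_offset, hinge_fractions = hinge_fractions,
                 seed = seed),
            class = "toy_model_spec")
}

#' Generate an oriented toy receptor dimer
#'
#' Builds a deterministic two-chain bead dimer: per chain, a helical TM
#' column inside the TM cylinder (residues labelled TM) plus a straight
#' rod of beads along +z (one bead per residue) carrying the HAMP1,
#' interHAMP/HAMP2, adaptation and tip segments, with hinge pivot
#' residues at the requested rod fractions. The model is already in the
#' membrane frame (TM centroid at the origin, rod along +z).
#'
#' @param spec `toy_model_spec`.
#' @return particle_model with a `hinges` map.
#' @export
make_toy_dimer <- function(spec = toy_model_spec()) {
  n_tm <- spec$tm_nres
  n_rod <- round(spec$rod_length / spec$rod_rise)
  # deterministic filled-cylinder lattice for one membrane monomer
  s_lat <- (pi * spec$tm_radius^2 * spec$tm_height / n_tm)^(1 / 3)
  ax_r <- seq(-spec$tm_radius, spec$tm_radius, by = s_lat)
  ax_z <- seq(-spec$tm_height / 2, spec$tm_height / 2, by = s_lat)
  g <- as.matrix(expand.grid(x = ax_r, y = ax_r, z = ax_z))
  g <- g[g[, 1]^2 + g[, 2]^2 <= spec$tm_radius^2, , drop = FALSE]
  # keep the n_tm lattice sites closest to the cylinder axis-center
  ordc <- order(g[, 1]^2 + g[, 2]^2 + (g[, 3] * 0.01)^2, g[, 1], g[, 2], g[, 3])
  tm_template <- g[ordc[seq_len(min(n_tm, nrow(g)))], , drop = FALSE]
  n_tm <- nrow(tm_template)
  chains <- list()
  for (side in c(-1, 1)) {
    ch <- if (side < 0) "A" else "B"
    tm_xyz <- tm_template
    tm_xyz[, 1] <- tm_xyz[, 1] + side * spec$tm_sep / 2
    rod_z <- spec$tm_height / 2 + spec$rod_rise * seq_len(n_rod)
    # two strands per chain (antiparallel helical hairpin): one bead on
    # each strand per residue, same residue index
    rod_xyz <- rbind(
      cbind(rep(side * spec$rod_offset, n_rod), rep(-spec$rod_offset, n_rod), rod_z),
      cbind(rep(side * spec$rod_offset, n_rod), rep(spec$rod_offset, n_rod), rod_z))
    frac <- (seq_len(n_rod) - 0.5) / n_rod
    seg_rod <- cut(frac, c(0, spec$hinge_fractions[1], spec$hinge_fractions[2],
                           spec$hinge_fractions[3], 0.95, 1),
                   labels = c("HAMP1", "HAMP2", "adaptation", "adaptation", "tip"),
                   include.lowest = TRUE)
    seg <- c(rep("TM", n_tm), rep(as.character(seg_rod), 2))
    resid <- c(seq_len(n_tm), rep(n_tm + seq_len(n_rod), 2))
    chains[[ch]] <- bead_frame(rbind(tm_xyz, rod_xyz), segment = seg,
                               resid = resid, chain = ch,
                               xray_e = c(rep(.bead_defaults$xray_e, n_tm),
                                          rep(.bead_defaults$xray_e / 2, 2 * n_rod)),
                               neutron_b = c(rep(.bead_defaults$neutron_b, n_tm),
                                             rep(.bead_defaults$neutron_b / 2, 2 * n_rod)),
                               volume = c(rep(.bead_defaults$volume, n_tm),
                                          rep(.bead_defaults$volume / 2, 2 * n_rod)),
                               n_exch_h = c(rep(.bead_defaults$n_exch_h, n_tm),
                                            rep(.bead_defaults$n_exch_h / 2, 2 * n_rod)))
  }
  df <- do.call(rbind, chains)
  hinges <- setNames(n_tm + round(spec$hinge_fractions * n_rod),
                     names(spec$hinge_fractions))
  m <- particle_model(df, hinges = hinges,
                      meta = list(spec = unclass(spec), seed = spec$seed))
  # exact membrane frame
  orient_membrane(m)
}

#' Homogeneous bead-filled sphere
#'
#' Cubic-lattice discretization of a uniform sphere for forward-model
#' validation. Boundary cells get partial-volume weights and are placed
#' at the centroid of their inside-sphere region (computed by
#' subsampling), which keeps the discretized form factor within ~1 % of
#' the analytic sphere form factor up to `q*radius ~ 8` at
#' `spacing ~ radius/20` wherever the form factor is not near a zero.
#'
#' @param radius Sphere radius, A.
#' @param spacing Lattice spacing, A.
#' @param nsub Subsamples per cell edge for boundary weighting.
#' @return particle_model with per-bead weights in `xray_e`/`neutron_b`.
#' @export
make_bead_sphere <- function(radius, spacing = radius / 20, nsub = 6) {
  stopifnot(radius > 0, spacing > 0, nsub >= 1)
  ax <- seq(-radius - spacing, radius + spacing, by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  g <- g[rowSums(g^2) <= (radius + spacing)^2, , drop = FALSE]
  off <- as.matrix(expand.grid(sx = seq_len(nsub), sy = seq_len(nsub),
                               sz = seq_len(nsub)))
  off <- (off - (nsub + 1) / 2) / nsub * spacing
  out <- matrix(NA_real_, nrow(g), 4)
  chunk <- 4000L
  for (lo in seq(1, nrow(g), by = chunk)) {
    hi <- min(lo + chunk - 1L, nrow(g))
    idx <- lo:hi
    n <- length(idx)
    pts <- g[rep(idx, each = nrow(off)), , drop = FALSE] +
      off[rep(seq_len(nrow(off)), n), , drop = FALSE]
    ins <- rowSums(pts^2) <= radius^2
    cell <- rep(seq_len(n), each = nrow(off))
    cnt <- tapply(ins, cell, sum)
    keep <- cnt > 0
    cx <- tapply(pts[, 1] * ins, cell, sum) / pmax(cnt, 1)
    cy <- tapply(pts[, 2] * ins, cell, sum) / pmax(cnt, 1)
    cz <- tapply(pts[, 3] * ins, cell, sum) / pmax(cnt, 1)
    out[idx, ] <- cbind(cx, cy, cz, cnt / nrow(off))
    out[idx[!keep], ] <- NA_real_
  }
  out <- out[!is.na(out[, 4]), , drop = FALSE]
  particle_model(bead_frame(out[, 1:3, drop = FALSE], segment = "TM",
                            resid = NA_integer_, chain = "A",
                            xray_e = out[, 4], neutron_b = out[, 4],
                            volume = 0, n_exch_h = 0),
                 meta = list(radius = radius, spacing = spacing))
}

#' Heteroscedastic noise specification for simulated curves
#'
#' `sigma(q) = a * I(q) + b * sqrt(I(q) * I_ref) + floor * I_ref` with
#' `I_ref` the first-point intensity, so the relative error grows from
#' about `a + b` at low q to `a + b / sqrt(I/I_ref)` where the signal has
#' fallen — emulating the error profile of reactor SANS / synchrotron
#' SAXS curves (roughly 2 % at low q to ~15 % where I has dropped
#' a hundredfold).
#'
#' @param a Relative error floor (multiplies I).
#' @param b Counting-statistics-like term (multiplies sqrt(I * I_ref)).
#' @param floor Absolute floor as a fraction of I_ref.
#' @param seed Random seed for noise draws.
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(a = 0.02, b = 0.015, floor = 1e-6, seed = 1) {
  stopifnot(a >= 0, b >= 0, floor >= 0)
  structure(list(a = a, b = b, floor = floor, seed = seed),
            class = "noise_spec")
}

.noise_sigma <- function(I, noise) {
  iref <- I[1]
  pmax(noise$a * I + noise$b * sqrt(pmax(I * iref, 0)), noise$floor * iref)
}

#' Simulate a noisy scattering curve from a model
#'
#' Debye forward curve plus heteroscedastic Gaussian noise per the
#' noise specification; the sigma column records the generating sigma.
#'
#' @param model particle_model.
#' @param solvent `solvent_model` or NULL.
#' @param radiation "xray" or "neutron".
#' @param noise `noise_spec`; `NULL` or zero amplitudes give the exact
#'   forward curve (with sigma attached if a spec is supplied).
#' @param q q grid.
#' @return `sas_curve` with sigma and seed metadata.
#' @export
simulate_curve <- function(model, solvent = NULL, radiation = "xray",
                           noise = noise_spec(), q = default_q_grid("saxs", 151)) {
  truth <- debye_curve(model, solvent, q, radiation)
  if (is.null(noise)) return(truth)
  sigma <- .noise_sigma(truth$I, noise)
  set.seed(noise$seed)
  I <- truth$I + rnorm(length(q), 0, sigma)
  sas_curve(q, I, sigma = sigma, radiation = radiation,
            meta = c(truth$meta, list(noise = unclass(noise), seed = noise$seed)))
}

#' Synthetic hinge-ensemble dataset with known truth weights
#'
#' Draws `n_conformers` hinge-angle triples from independent zero-mean
#' Gaussians with the requested per-hinge RMS (degrees), clips to the
#' -90..90 range, snaps each angle to the basis grid, uses the multiplicity
#' of each grid triple as its truth weight, averages the corresponding
#' member curves, and adds noise.
#'
#' @param dimer Toy dimer from [make_toy_dimer()].
#' @param rms_deg Per-hinge RMS bending angle, degrees, in (0, 90].
#' @param n_conformers Number of draws.
#' @param noise `noise_spec`.
#' @param seed Seed for the angle draws.
#' @param basis Optional precomputed `hinge_basis` (built if missing).
#' @param ... Passed to [build_hinge_basis()] when building the basis.
#' @return List with `curve` (noisy `sas_curve`), `weights` (truth, one
#'   per basis member, sum 1), `rms_truth` (realized per-hinge RMS after
#'   snapping), and `basis`.
#' @export
make_ensemble_dataset <- function(dimer, rms_deg = 55, n_conformers = 2000,
                                  noise = noise_spec(), seed = 7,
                                  basis = NULL, ...) {
  if (rms_deg <= 0 || rms_deg > 90) stop("rms_deg must be in (0, 90]")
  if (is.null(basis)) basis <- build_hinge_basis(dimer, ...)
  grid_vals <- sort(unique(basis$angles$theta1))
  step <- min(diff(grid_vals))
  set.seed(seed)
  draws <- matrix(rnorm(3 * n_conformers, 0, rms_deg), ncol = 3)
  draws <- pmin(pmax(draws, -90), 90)
  snapped <- round(draws / step) * step
  key <- paste(snapped[, 1], snapped[, 2], snapped[, 3])
  bkey <- paste(basis$angles$theta1, basis$angles$theta2, basis$angles$theta3)
  tab <- table(factor(key, levels = bkey))
  if (sum(tab) == 0) stop("no draws landed on surviving basis members")
  # draws snapped to clash-excluded triples are dropped; renormalize
  w <- as.numeric(tab) / sum(tab)
  Itruth <- as.numeric(basis$A %*% w)
  sigma <- .noise_sigma(Itruth, noise)
  set.seed(noise$seed)
  curve <- sas_curve(basis$q, Itruth + rnorm(length(Itruth), 0, sigma),
                     sigma = sigma, radiation = basis$radiation,
                     meta = list(seed = seed, rms_deg = rms_deg,
                                 n_conformers = n_conformers))
  rms_truth <- sqrt(colSums(w * as.matrix(basis$angles)^2))
  list(curve = curve, weights = w,
       rms_truth = setNames(rms_truth, c("HAMP1", "HAMP2", "Gly")),
       basis = basis)
}

#' Synthetic dimer/trimer mixture dataset with known truth fraction
#'
#' `I = (1 - f) * I_dimer/m_d + f * I_trimer/m_t` with per-complex-mass
#' normalized components (trimer mass = 3 dimer masses), plus noise.
#'
#' @param dimer_model,trimer_model particle_models.
#' @param trimer_fraction Weight fraction f of the trimer, between 0 and 1.
#' @param noise `noise_spec`.
#' @param solvent `solvent_model` or NULL.
#' @param radiation "xray" or "neutron".
#' @param q q grid.
#' @return List with `curve`, `truth` (f), and the per-mass normalized
#'   `components` list (dimer, trimer_of_dimers).
#' @export
make_mixture_dataset <- function(dimer_model, trimer_model, trimer_fraction,
                                 noise = noise_spec(), solvent = NULL,
                                 radiation = "neutron",
                                 q = default_q_grid("sans", 121)) {
  if (trimer_fraction < 0 || trimer_fraction > 1)
    stop("trimer_fraction must be in [0, 1]")
  cd <- debye_curve(dimer_model, solvent, q, radiation)
  ct <- debye_curve(trimer_model, solvent, q, radiation)
  nd <- sas_curve(q, cd$I / 1, radiation = radiation)
  nt <- sas_curve(q, ct$I / 3, radiation = radiation)   # per complex mass
  Itruth <- (1 - trimer_fraction) * nd$I + trimer_fraction * nt$I
  sigma <- .noise_sigma(Itruth, noise)
  set.seed(noise$seed)
  curve <- sas_curve(q, Itruth + rnorm(length(q), 0, sigma), sigma = sigma,
                     radiation = radiation,
                     meta = list(trimer_fraction = trimer_fraction,
                                 seed = noise$seed))
  list(curve = curve, truth = trimer_fraction,
       components = list(dimer = nd, trimer_of_dimers = nt))
}
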