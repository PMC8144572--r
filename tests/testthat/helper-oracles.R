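# Independent oracles used across the suite. These deliberately avoid the
# package's accelerated code paths.

# exact O(N^2) Debye double sum in plain R
debye_exact_r <- function(xyz, w, q) {
  dmat <- as.matrix(dist(xyz))
  vapply(q, function(qv) {
    s <- outer(w, w)
    x <- qv * dmat
    sinc <- ifelse(x < 1e-12, 1, sin(x) / x)
    sum(s * sinc)
  }, numeric(1))
}

# analytic form factor of a homogeneous sphere, normalized to 1 at q = 0
sphere_ff <- function(q, R) {
  x <- q * R
  ifelse(x < 1e-8, 1, (3 * (sin(x) - x * cos(x)) / x^3)^2)
}

# analytic pair distance distribution of a homogeneous sphere (unnormalized)
sphere_pr <- function(r, R) {
  x <- r / R
  ifelse(r >= 0 & r <= 2 * R,
         r^2 * (1 - 0.75 * x + x^3 / 16), 0)
}

# straight bead rod along z, one unit-weight bead per step
rod_model <- function(L = 120, n = 121) {
  xyz <- cbind(0, 0, seq(-L / 2, L / 2, length.out = n))
  particle_model(sasflex:::bead_frame(xyz, "TM", NA_integer_, "A"))
}

# small sphere fixture shared by several tests (cached per session)
.cache <- new.env()
cached_sphere <- function(R = 40, spacing = 2.5) {
  key <- paste0("sph", R, "_", spacing)
  if (is.null(.cache[[key]])) .cache[[key]] <- make_bead_sphere(R, spacing)
  .cache[[key]]
}

cached_dimer <- function() {
  if (is.null(.cache$dimer)) .cache$dimer <- make_toy_dimer()
  .cache$dimer
}

cached_basis <- function() {
  if (is.null(.cache$basis))
    .cache$basis <- build_hinge_basis(cached_dimer(),
                                      q = default_q_grid("saxs", 121),
                                      solvent = solvent_model(0.15, 0))
  .cache$basis
}
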