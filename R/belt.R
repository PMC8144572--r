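#' Specification of the two-shell DDM detergent belt
#'
#' Elliptical-torus belt around the transmembrane part of an oriented
#' model: a hydrophobic (tail) shell filling the elliptical annulus for
#' `|z - z_center| <= t`, wrapped radially and axially by a hydrophilic
#' (head) shell of the given thickness.
#'
#' @param a,b Outer semi-axes of the hydrophobic ellipse, A.
#' @param t Hydrophobic half-thickness along z, A.
#' @param head_thickness Head-shell thickness, A.
#' @param v_tail,v_head DDM tail/head molecular volumes, A^3. 350 A^3
#'   reproduces the detergent-belt electron densities 97/350 = 0.277
#'   (tail) and 181/350 = 0.517 e/A^3 (head).
#' @param packing Packing fraction of the shells (1 = fully detergent).
#'   Each pseudo-atom represents one CH3-sized chunk (9/97 of a tail or
#'   10/181 of a head), i.e. one atom per `v_tail*9/97` (32.5 A^3) or
#'   `v_head*10/181` (19.3 A^3) at `packing = 1`; `packing = 0` builds
#'   no belt.
#' @param z_center Belt center along z, A.
#' @param seed Seed for the jittered packing lattice.
#' @return List of class `belt_spec`.
#' @export
belt_spec <- function(a = 40, b = 40, t = 15, head_thickness = 6,
                      v_tail = 350, v_head = 350, packing = 1,
                      z_center = 0, seed = 42) {
  if (a <= 0 || b <= 0 || t <= 0 || head_thickness <= 0)
    stop("belt dimensions must be positive")
  if (v_tail <= 0 || v_head <= 0) stop("molecular volumes must be positive")
  if (packing < 0 || packing > 1) stop("packing must be in [0, 1]")
  structure(list(a = a, b = b, t = t, head_thickness = head_thickness,
                 v_tail = v_tail, v_head = v_head, packing = packing,
                 z_center = z_center, seed = seed),
            class = "belt_spec")
}

# jittered hexagonal-ish lattice filling a box, deterministic given seed
.belt_lattice <- function(xr, yr, zr, spacing, seed) {
  xs <- seq(xr[1], xr[2], by = spacing)
  ys <- seq(yr[1], yr[2], by = spacing * sqrt(3) / 2)
  zs <- seq(zr[1], zr[2], by = spacing)
  g <- expand.grid(ix = seq_along(xs), iy = seq_along(ys), iz = seq_along(zs))
  x <- xs[g$ix] + (g$iy %% 2) * spacing / 2       # hexagonal row offset
  y <- ys[g$iy]
  z <- zs[g$iz]
  set.seed(seed)
  jit <- matrix(runif(3 * length(x), -0.3, 0.3) * spacing, ncol = 3)
  cbind(x, y, z) + jit
}

#' Build the detergent-corona pseudo-atom belt
#'
#' Fills the belt region of `spec` with pseudo-atoms on a jittered
#' hexagonal lattice whose spacing reproduces the requested packing
#' density, labels them `belt_tail` (hydrophobic shell) or `belt_head`
#' (hydrophilic shell), removes any pseudo-atom within 1.8 A of a
#' protein scatterer, and appends them to the model. Scattering
#' properties are assigned by [assign_belt_scattering()].
#'
#' @param model Oriented particle_model (TM centroid within 5 A of origin).
#' @param spec belt_spec.
#' @return particle_model with belt pseudo-atoms appended.
#' @export
build_belt <- function(model, spec) {
  s <- model$scatterers
  tm <- s$segment == "TM"
  if (any(tm)) {
    tm_c <- colMeans(as.matrix(s[tm, c("x", "y", "z")]))
    if (sqrt(sum(tm_c^2)) > 5)
      stop("model is not membrane-oriented (TM centroid ",
           round(sqrt(sum(tm_c^2)), 1), " A from origin); run orient_membrane()")
  }
  if (spec$packing == 0) return(model)
  chunk_tail <- spec$v_tail * 9 / 97              # A^3 per tail pseudo-atom
  chunk_head <- spec$v_head * 10 / 181
  h <- spec$head_thickness
  ao <- spec$a + h; bo <- spec$b + h
  zr <- spec$z_center + c(-(spec$t + h), spec$t + h)
  shell_pts <- function(chunk, which_shell, seed) {
    spacing <- (chunk / spec$packing / (sqrt(3) / 2))^(1 / 3)
    pts <- .belt_lattice(c(-ao, ao), c(-bo, bo), zr, spacing, seed)
    ex <- (pts[, 1] / ao)^2 + (pts[, 2] / bo)^2   # outer ellipse coordinate
    ei <- (pts[, 1] / spec$a)^2 + (pts[, 2] / spec$b)^2
    dz <- abs(pts[, 3] - spec$z_center)
    in_tail <- ei <= 1 & dz <= spec$t
    keep <- if (which_shell == "tail") in_tail
            else ex <= 1 & !in_tail & dz <= spec$t + h
    pts[keep, , drop = FALSE]
  }
  tail_pts <- shell_pts(chunk_tail, "tail", spec$seed)
  head_pts <- shell_pts(chunk_head, "head", spec$seed + 1)
  pts <- rbind(tail_pts, head_pts)
  lab <- rep(c("belt_tail", "belt_head"), c(nrow(tail_pts), nrow(head_pts)))
  vol <- rep(c(chunk_tail, chunk_head), c(nrow(tail_pts), nrow(head_pts)))
  # exclusion zone around protein scatterers
  prot <- as.matrix(s[, c("x", "y", "z")])
  if (nrow(prot) > 0 && nrow(pts) > 0) {
    ok <- min_dist2_cpp(pts, prot) > 1.8^2
    pts <- pts[ok, , drop = FALSE]
    lab <- lab[ok]
    vol <- vol[ok]
  }
  if (nrow(pts) == 0) return(model)
  belt <- bead_frame(pts, segment = lab, resid = NA_integer_, chain = "X",
                     xray_e = 0, neutron_b = 0, volume = vol, n_exch_h = 0)
  if (!is.null(s$dimer)) belt$dimer <- NA_integer_
  out <- particle_model(rbind(s, belt), hinges = model$hinges,
                        meta = c(model$meta, list(belt = unclass(spec))))
  assign_belt_scattering(out, d2o_fraction = 0)
}

#' Assign DDM scattering properties to belt pseudo-atoms
#'
#' Tail pseudo-atoms carry 9/97 of the DDM tail (C12H25): 9 electrons and
#' (9/97) of its summed neutron scattering length. Head pseudo-atoms carry
#' 10/181 of the DDM head (C12H21O11): 10 electrons and (10/181) of its
#' summed b, with the head's seven exchangeable hydrogens deuterated at
#' `d2o_fraction`. All values come from tabulated bound coherent
#' scattering lengths.
#'
#' @param model particle_model containing `belt_tail`/`belt_head` atoms.
#' @param d2o_fraction D2O fraction applied to the head's 7 exchangeable H.
#'   The per-atom exchangeable-H count is also stored (scaled by 10/181)
#'   so solvent-dependent exchange is applied consistently at curve time.
#' @return particle_model with belt scattering columns filled in.
#' @export
assign_belt_scattering <- function(model, d2o_fraction = 0) {
  s <- model$scatterers
  tail_i <- s$segment == "belt_tail"
  head_i <- s$segment == "belt_head"
  if (!any(tail_i) && !any(head_i))
    stop("no labelled belt pseudo-atoms (belt_tail/belt_head) in model")
  tailp <- composition_scattering(c(C = 12, H = 25))
  headp <- composition_scattering(c(C = 12, H = 21, O = 11),
                                  d2o_fraction = d2o_fraction, n_exchangeable = 7)
  s$xray_e[tail_i] <- 9
  s$neutron_b[tail_i] <- 9 / 97 * tailp$neutron_b
  s$n_exch_h[tail_i] <- 0
  s$deut_frac[tail_i] <- 0
  s$xray_e[head_i] <- 10
  s$neutron_b[head_i] <- 10 / 181 * headp$neutron_b
  # remaining exchange capacity (if assigned at d2o < 1) for curve-time solvents
  s$n_exch_h[head_i] <- 10 / 181 * 7 * (1 - d2o_fraction)
  s$deut_frac[head_i] <- d2o_fraction
  model$scatterers <- s
  model
}

#' Equivalent deuteration fraction of a CH3 pseudo-atom
#'
#' Solves `b_C + 3 * ((1 - f) * b_H + f * b_D) = target_b` for `f`: the
#' fraction of the three methyl hydrogens that must be treated as
#' deuterium for a CH3 pseudo-atom to reproduce a target coherent
#' scattering length (the "perdeuteration parameter" convention of
#' neutron curve evaluators).
#'
#' @param target_b Target scattering length, fm.
#' @return Fraction `f`; values outside `[0, 1]` are clipped with a warning.
#' @export
equivalent_deuteration_fraction <- function(target_b) {
  b <- scattering_elements$b
  f <- (target_b - b[["C"]] - 3 * b[["H"]]) / (3 * (b[["D"]] - b[["H"]]))
  if (f < 0 || f > 1) {
    warning("equivalent deuteration fraction ", signif(f, 4),
            " outside [0, 1]; clipped")
    f <- min(max(f, 0), 1)
  }
  f
}

#' Scattering length densities of the belt shells
#'
#' SLD = sum(b) / V per DDM tail (C12H25) and head (C12H21O11, seven
#' exchangeable H deuterated at `d2o_fraction`).
#'
#' @param d2o_fraction Solvent D2O fraction.
#' @param v_tail,v_head Molecular volumes, A^3.
#' @return Named vector `c(tail = , head = )` in A^-2.
#' @export
belt_slds <- function(d2o_fraction = 1, v_tail = 350, v_head = 350) {
  if (v_tail <= 0 || v_head <= 0) stop("molecular volumes must be positive")
  tailp <- composition_scattering(c(C = 12, H = 25))
  headp <- composition_scattering(c(C = 12, H = 21, O = 11),
                                  d2o_fraction = d2o_fraction, n_exchangeable = 7)
  c(tail = tailp$neutron_b * 1e-5 / v_tail,
    head = headp$neutron_b * 1e-5 / v_head)
}
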