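#' Tabulated coherent scattering properties of the elements used here
#'
#' Bound coherent neutron scattering lengths (Sears compilation, fm) and
#' atomic numbers for the elements occurring in protein, detergent and
#' aqueous-buffer compositions. "D" is deuterium (2H).
#'
#' @format Named list with components `b` (fm) and `Z` (electrons), both
#'   named by element symbol.
#' @export
scattering_elements <- list(
  b = c(H = -3.739, D = 6.671, C = 6.646, N = 9.36, O = 5.803,
        Na = 3.63, Mg = 5.375, P = 5.13, S = 2.847, Cl = 9.577,
        K = 3.67, Fe = 9.45),
  Z = c(H = 1, D = 1, C = 6, N = 7, O = 8,
        Na = 11, Mg = 12, P = 15, S = 16, Cl = 17,
        K = 19, Fe = 26)
)

#' X-ray electron count and neutron scattering length of a composition
#'
#' Sums tabulated atomic numbers and bound coherent neutron scattering
#' lengths over a chemical formula. Labile (solvent-exchangeable)
#' hydrogens are replaced by deuterium in proportion to the D2O fraction
#' of the solvent: each of the `n_exchangeable` H contributes
#' `(1 - d2o) * b_H + d2o * b_D`.
#'
#' @param formula Named integer vector of element counts, e.g.
#'   `c(C = 12, H = 25)`. Use "D" for hydrogens that are deuterium
#'   regardless of solvent.
#' @param d2o_fraction D2O volume fraction of the solvent, in `[0, 1]`.
#' @param n_exchangeable Number of the H in `formula` that exchange with
#'   solvent; must not exceed the H count.
#' @return List with `electrons` (e) and `neutron_b` (fm).
#' @examples
#' composition_scattering(c(H = 2, O = 1))           # water: 10 e, -1.675 fm
#' composition_scattering(c(C = 12, H = 25))$electrons  # DDM tail: 97 e
#' @export
composition_scattering <- function(formula, d2o_fraction = 0, n_exchangeable = 0) {
  if (length(formula) == 0) stop("empty formula")
  if (is.null(names(formula)) || any(!nzchar(names(formula))))
    stop("formula must be a named vector of element counts")
  if (any(formula < 0)) stop("element counts must be >= 0")
  if (d2o_fraction < 0 || d2o_fraction > 1) stop("d2o_fraction must be in [0, 1]")
  unknown <- setdiff(names(formula), names(scattering_elements$Z))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  n_h <- if ("H" %in% names(formula)) unname(formula[["H"]]) else 0
  if (n_exchangeable > n_h)
    stop("n_exchangeable (", n_exchangeable, ") exceeds hydrogen count (", n_h, ")")
  b <- scattering_elements$b
  Z <- scattering_elements$Z
  electrons <- sum(Z[names(formula)] * formula)
  neutron_b <- sum(b[names(formula)] * formula) +
    n_exchangeable * d2o_fraction * (b[["D"]] - b[["H"]])
  list(electrons = unname(electrons), neutron_b = unname(neutron_b))
}

# molar volumes / densities used by the solvent model (20 degC)
.solvent_const <- list(
  M_h2o = 18.015, rho_h2o = 0.9982,   # g/mol, g/cm^3
  M_d2o = 20.0276, rho_d2o = 1.1044,
  avogadro = 0.6022141                # molecules per (mol * A^3/cm^3... ) scaled: 1e-24*N_A
)

#' Aqueous NaCl/D2O solvent scattering model
#'
#' Electron density and neutron scattering length density (SLD) of a
#' water/heavy-water buffer containing NaCl. The salt occupies its
#' apparent molar volume (Masson relation, `16.62 + 1.866*sqrt(c)`
#' cm^3/mol), the remainder of each litre being water of the given D2O
#' fraction.
#'
#' @param nacl_M NaCl concentration, mol/L, in `[0, 6]`.
#' @param d2o_fraction D2O volume fraction of the water component.
#' @return Object of class `solvent_model`: list with `rho_e` (e/A^3),
#'   `sld` (A^-2), `nacl_M`, `d2o_fraction`.
#' @examples
#' solvent_model(0, 0)$rho_e    # ~0.334 e/A^3
#' solvent_model(4, 0)$rho_e    # ~0.37  e/A^3
#' solvent_model(0, 1)$sld      # ~6.4e-6 A^-2
#' @export
solvent_model <- function(nacl_M = 0, d2o_fraction = 0) {
  if (nacl_M < 0 || nacl_M > 6) stop("nacl_M must be in [0, 6]")
  if (d2o_fraction < 0 || d2o_fraction > 1) stop("d2o_fraction must be in [0, 1]")
  k <- .solvent_const
  # apparent molar volume of NaCl in water, cm^3/mol
  v_phi <- 16.62 + 1.866 * sqrt(nacl_M)
  v_water_cm3 <- 1000 - nacl_M * v_phi          # per litre
  # mole-weighted water properties for the H2O/D2O mixture
  f <- d2o_fraction
  rho_mix <- (1 - f) * k$rho_h2o + f * k$rho_d2o
  M_mix <- (1 - f) * k$M_h2o + f * k$M_d2o
  n_water <- v_water_cm3 * rho_mix / M_mix      # mol per litre
  w <- composition_scattering(c(H = 2, O = 1), d2o_fraction = f, n_exchangeable = 2)
  salt <- composition_scattering(c(Na = 1, Cl = 1))
  # per litre -> per A^3: mol/L * N_A / 1e27
  per_a3 <- function(mol) mol * 6.022141e23 / 1e27
  rho_e <- per_a3(n_water) * w$electrons + per_a3(nacl_M) * salt$electrons
  sld <- (per_a3(n_water) * w$neutron_b + per_a3(nacl_M) * salt$neutron_b) * 1e-5  # fm -> A
  structure(list(rho_e = rho_e, sld = sld,
                 nacl_M = nacl_M, d2o_fraction = d2o_fraction),
            class = "solvent_model")
}

#' @export
print.solvent_model <- function(x, ...) {
  cat(sprintf("solvent: %.2f M NaCl, %.0f%% D2O | rho_e = %.4f e/A^3, SLD = %.3e A^-2\n",
              x$nacl_M, 100 * x$d2o_fraction, x$rho_e, x$sld))
  invisible(x)
}
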