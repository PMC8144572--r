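#' Build a basis of hinge-bent conformer curves
#'
#' Applies every angle triple of the grid to the dimer (bends applied in
#' order HAMP1 -> HAMP2 -> Gly, proximal to distal), appends the
#' detergent belt, evaluates the Debye curve, and collects the curves as
#' columns of a basis matrix. Members whose bent conformation clashes
#' (any non-bonded bead pair closer than 1 A) are flagged and excluded.
#' Member order is lexicographic in (theta_HAMP1, theta_HAMP2, theta_Gly).
#'
#' @param dimer Oriented particle_model with a `hinges` map.
#' @param angle_grid Numeric vector of angles per hinge (degrees),
#'   default `seq(-90, 90, by = 30)`.
#' @param solvent `solvent_model` or NULL.
#' @param radiation "xray" or "neutron".
#' @param q q grid for the member curves.
#' @param belt `belt_spec` to attach, or NULL for no belt.
#' @return Object of class `hinge_basis`: list with `A` (n_q x n_members
#'   intensity matrix), `q`, `angles` (data.frame theta1..theta3),
#'   `excluded` (data.frame of clash-filtered triples), `radiation`.
#' @export
build_hinge_basis <- function(dimer, angle_grid = seq(-90, 90, by = 30),
                              solvent = NULL, radiation = "xray",
                              q = default_q_grid("saxs", 151), belt = NULL) {
  if (length(angle_grid) == 0) stop("empty angle grid")
  if (is.null(dimer$hinges) || length(dimer$hinges) < 3)
    stop("dimer must define hinges HAMP1, HAMP2, Gly")
  hnames <- c("HAMP1", "HAMP2", "Gly")
  grid <- expand.grid(theta3 = angle_grid, theta2 = angle_grid,
                      theta1 = angle_grid)[, 3:1]
  names(grid) <- c("theta1", "theta2", "theta3")
  grid <- grid[order(grid$theta1, grid$theta2, grid$theta3), , drop = FALSE]
  rownames(grid) <- NULL
  belt_model <- if (!is.null(belt)) build_belt(dimer, belt) else dimer
  belt_sel <- is_belt(belt_model)
  # the belt is rigid across members: precompute its self-scattering once
  # and add per-member protein self + protein-belt cross terms
  bin <- 0.5
  belt_sub <- belt_model
  belt_sub$scatterers <- belt_model$scatterers[belt_sel, , drop = FALSE]
  has_belt <- nrow(belt_sub$scatterers) > 0
  if (has_belt) {
    wb <- contrast_weights(belt_sub, solvent, radiation)
    xb <- coords(belt_sub)
    phb <- pair_hist_cpp(xb, wb, bin)
    I_belt <- debye_from_hist_cpp(q, phb$self, phb$hist, phb$r)
  } else I_belt <- numeric(length(q))
  cols <- vector("list", nrow(grid))
  ok <- logical(nrow(grid))
  for (m in seq_len(nrow(grid))) {
    conf <- dimer
    for (h in 1:3) conf <- bend_at_hinge(conf, hnames[h], grid[m, h])
    if (.has_clash(conf)) { ok[m] <- FALSE; next }
    wp <- contrast_weights(conf, solvent, radiation)
    xp <- coords(conf)
    php <- pair_hist_cpp(xp, wp, bin)
    I <- debye_from_hist_cpp(q, php$self, php$hist, php$r) + I_belt
    if (has_belt) {
      chx <- cross_hist_cpp(xp, wp, xb, wb, bin)
      I <- I + debye_from_hist_cpp(q, 0, chx$hist, chx$r)
    }
    cols[[m]] <- I
    ok[m] <- TRUE
  }
  A <- do.call(cbind, cols[ok])
  structure(list(A = A, q = q, angles = grid[ok, , drop = FALSE],
                 excluded = grid[!ok, , drop = FALSE], radiation = radiation),
            class = "hinge_basis")
}

# clash if any non-local bead pair comes closer than 1 A. Pairs within 7
# residues along the same chain are exempt: an instantaneous bend of a
# thick strand bundle necessarily pinches the inner side of the hinge
# corner over a ~10 A contour, which a real flexible hinge accommodates;
# the check targets genuine fold-backs (rod onto rod, rod onto membrane
# domain), not hinge-corner strain.
.has_clash <- function(model, contour_window = 7) {
  s <- model$scatterers
  prot <- !is.na(s$resid)
  xyz <- as.matrix(s[prot, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  resid <- s$resid[prot]; chain <- s$chain[prot]
  local <- outer(chain, chain, "==") &
    abs(outer(resid, resid, "-")) <= contour_window
  any(d[!local & upper.tri(d)] < 1)
}

#' @export
print.hinge_basis <- function(x, ...) {
  cat(sprintf("hinge_basis: %d members (%d excluded by clash), %d q points (%s)\n",
              ncol(x$A), nrow(x$excluded), length(x$q), x$radiation))
  invisible(x)
}

#' Tikhonov-regularized non-negative ensemble fit
#'
#' Fits an experimental curve as a non-negative combination of basis
#' member curves by minimizing
#' `||(c A w - I_exp)/sigma||^2 + alpha^2 ||Gamma (w - u)||^2` with
#' `w >= 0` (active-set NNLS), where `u` is the uniform distribution
#' over the basis: among weightings compatible with the data the least
#' informative one is preferred, and as `alpha` grows the weights
#' converge to uniform. The overall scale `c` is estimated from an
#' unregularized pre-fit and refit after normalization to `sum(w) = 1`.
#' `Gamma` is the identity by default, or a nearest-neighbour difference
#' operator over the angle grid (`gamma = "smooth"`). `alpha = "auto"`
#' picks the L-curve corner.
#'
#' @param basis `hinge_basis`.
#' @param exp_curve `sas_curve` with sigma, overlapping the basis q grid.
#' @param alpha "auto" or a non-negative value.
#' @param gamma "identity" or "smooth".
#' @return Object of class `ensemble_fit`: weights (sum 1), `scale`,
#'   `alpha`, `chi2`, `rms_angles` (per-hinge root-mean-square bend,
#'   degrees), `angles`.
#' @export
tikhonov_nnls <- function(basis, exp_curve, alpha = "auto",
                          gamma = c("identity", "smooth")) {
  gamma <- match.arg(gamma)
  if (is.null(exp_curve$sigma)) stop("experimental curve has no sigma")
  qd <- exp_curve$q
  keep <- qd >= min(basis$q) & qd <= max(basis$q)
  if (!any(keep)) stop("basis and data q ranges do not overlap")
  qd <- qd[keep]; Ie <- exp_curve$I[keep]; se <- exp_curve$sigma[keep]
  A <- apply(basis$A, 2, function(col) approx(basis$q, col, qd)$y)
  Aw <- A / se
  yw <- Ie / se
  m <- ncol(A)
  G <- if (gamma == "identity") diag(m) else .angle_grid_smoother(basis$angles)
  u <- rep(1 / m, m)
  # unregularized pre-fit pins the overall scale
  v0 <- pracma::lsqnonneg(Aw, yw)$x
  if (sum(v0) <= 0) stop("data incompatible with basis: all-zero solution")
  c0 <- sum(v0)
  A2 <- Aw * c0                                  # unknowns are normalized weights
  Gu <- as.numeric(G %*% u)
  solve_w <- function(a) pracma::lsqnonneg(rbind(A2, a * G), c(yw, a * Gu))$x
  if (identical(alpha, "auto")) {
    a0 <- sqrt(sum(A2^2) / max(sum(G^2), 1e-12))
    grid <- a0 * 10^seq(-4, 1, length.out = 11)
    rho <- eta <- numeric(length(grid)); sols <- vector("list", length(grid))
    for (i in seq_along(grid)) {
      wv <- solve_w(grid[i])
      sols[[i]] <- wv
      rho[i] <- sum((A2 %*% wv - yw)^2)
      eta[i] <- sum((G %*% (wv - u))^2)
    }
    k <- .lcurve_corner(log(pmax(rho, 1e-300)), log(pmax(eta, 1e-300)))
    alpha <- grid[k]; wv <- sols[[k]]
  } else {
    if (alpha < 0) stop("alpha must be >= 0")
    wv <- solve_w(alpha)
  }
  if (sum(wv) <= 0) stop("data incompatible with basis: all-zero solution")
  w <- wv / sum(wv)
  # refit the overall scale for the normalized weights
  Imix <- as.numeric(A %*% w)
  cs <- sum(Imix * Ie / se^2) / sum(Imix^2 / se^2)
  # reduced by N - 1 (overall scale); the regularized weights are not
  # free parameters in the least-squares sense
  chi2 <- sum(((Ie - cs * Imix) / se)^2) / (length(qd) - 1)
  rms <- vapply(1:3, function(h) sqrt(sum(w * basis$angles[[h]]^2)), numeric(1))
  structure(list(weights = w, scale = cs, alpha = alpha, chi2 = chi2,
                 rms_angles = setNames(rms, c("HAMP1", "HAMP2", "Gly")),
                 angles = basis$angles),
            class = "ensemble_fit")
}

# first-difference operator linking members adjacent in one hinge angle
.angle_grid_smoother <- function(angles) {
  m <- nrow(angles)
  key <- function(df) paste(df[[1]], df[[2]], df[[3]])
  idx <- setNames(seq_len(m), key(angles))
  step <- min(diff(sort(unique(unlist(angles)))))
  rows <- list()
  for (i in seq_len(m)) {
    for (h in 1:3) {
      nb <- angles[i, ]
      nb[[h]] <- nb[[h]] + step
      j <- idx[key(nb)]
      if (!is.na(j)) {
        v <- numeric(m); v[i] <- 1; v[j] <- -1
        rows[[length(rows) + 1L]] <- v
      }
    }
  }
  if (!length(rows)) return(diag(m))
  do.call(rbind, rows)
}

#' @export
print.ensemble_fit <- function(x, ...) {
  cat(sprintf("ensemble_fit: chi2 = %.3g, alpha = %.3g, effective members = %.0f\n",
              x$chi2, x$alpha, 1 / sum(x$weights^2)))
  cat(sprintf("per-hinge RMS bend: HAMP1 %.1f, HAMP2 %.1f, Gly %.1f deg\n",
              x$rms_angles[1], x$rms_angles[2], x$rms_angles[3]))
  invisible(x)
}

#' Per-hinge RMS bending angles of a weight solution
#'
#' `RMS_h = sqrt(sum_m w_m theta_{m,h}^2)` for each hinge.
#'
#' @param solution `ensemble_fit` (weights summing to 1).
#' @param basis `hinge_basis` the solution was fitted on (optional; the
#'   solution carries its angle grid).
#' @return Named numeric vector of RMS angles, degrees.
#' @export
hinge_angle_stats <- function(solution, basis = NULL) {
  angles <- if (!is.null(basis)) basis$angles else solution$angles
  w <- solution$weights
  setNames(vapply(1:3, function(h) sqrt(sum(w * angles[[h]]^2)), numeric(1)),
           c("HAMP1", "HAMP2", "Gly"))
}

#' Two-component oligomer mixture fit
#'
#' Non-negative least-squares fit of an experimental curve as a mixture
#' of component curves (e.g. dimer and trimer-of-dimers). If `masses`
#' are supplied the component curves are first normalized per complex
#' mass (OLIGOMER's weight-fraction convention); the returned fractions
#' are then weight fractions. 1-sigma uncertainties come from the
#' least-squares covariance at the solution (delta method through the
#' normalization), optionally refined by residual bootstrap.
#'
#' @param components Named list of `sas_curve`s (e.g.
#'   `list(dimer = ..., trimer_of_dimers = ...)`).
#' @param exp_curve `sas_curve` with sigma.
#' @param masses Optional numeric vector of relative complex masses, one
#'   per component.
#' @param bootstrap Number of residual-bootstrap resamples (0 = none).
#' @param seed Seed for the bootstrap.
#' @return Object of class `mixture_fit`: `fractions` (%, sum 100),
#'   `se` (%), `chi2`, `scale`, `condition`, `warning`.
#' @export
mixture_fractions <- function(components, exp_curve, masses = NULL,
                              bootstrap = 0, seed = 1) {
  if (length(components) < 2) stop("need at least two component curves")
  if (is.null(exp_curve$sigma)) stop("experimental curve has no sigma")
  if (is.null(names(components)))
    names(components) <- paste0("component", seq_along(components))
  qd <- exp_curve$q; Ie <- exp_curve$I; se <- exp_curve$sigma
  A <- vapply(components, function(cc) approx(cc$q, cc$I, qd, rule = 2)$y,
              numeric(length(qd)))
  if (!is.null(masses)) A <- sweep(A, 2, masses, "/")
  Aw <- A / se
  kappa <- tryCatch(kappa(Aw, exact = TRUE), error = function(e) Inf)
  warn <- if (kappa > 1e8) "component curves nearly collinear" else NULL
  yw <- Ie / se
  # exactly collinear columns break the active-set solver; a vanishing
  # ridge keeps it solvable without changing well-posed results
  wv <- tryCatch(pracma::lsqnonneg(Aw, yw)$x, error = function(e) {
    eps <- 1e-5 * sqrt(max(colSums(Aw^2)))
    pracma::lsqnonneg(rbind(Aw, eps * diag(ncol(Aw))),
                      c(yw, numeric(ncol(Aw))))$x
  })
  if (sum(wv) <= 0) stop("data incompatible with components: all-zero solution")
  frac <- wv / sum(wv)
  fit <- as.numeric(A %*% wv)
  p <- sum(wv > 0) # fitted amplitudes
  chi2 <- sum(((Ie - fit) / se)^2) / max(length(qd) - p, 1)
  # covariance of the unnormalized amplitudes at the (assumed interior) solution
  se_frac <- rep(NA_real_, length(wv))
  act <- wv > 0
  if (sum(act) >= 1) {
    Va <- tryCatch(solve(crossprod(Aw[, act, drop = FALSE])) * chi2,
                   error = function(e) NULL)
    if (!is.null(Va)) {
      J <- matrix(0, length(wv), sum(act))       # d frac / d w_act
      Sw <- sum(wv)
      ai <- which(act)
      for (r in seq_along(wv)) for (cix in seq_along(ai))
        J[r, cix] <- ((r == ai[cix]) * Sw - wv[r]) / Sw^2
      se_frac <- sqrt(pmax(diag(J %*% Va %*% t(J)), 0))
    }
  }
  if (bootstrap > 0) {
    set.seed(seed)
    res <- (Ie - fit) / se
    bs <- matrix(NA_real_, bootstrap, length(wv))
    for (bix in seq_len(bootstrap)) {
      yb <- fit + sample(res, length(res), replace = TRUE) * se
      wb <- pracma::lsqnonneg(Aw, yb / se)$x
      if (sum(wb) > 0) bs[bix, ] <- wb / sum(wb)
    }
    se_frac <- apply(bs, 2, sd, na.rm = TRUE)
  }
  structure(list(fractions = setNames(100 * frac, names(components)),
                 se = setNames(100 * se_frac, names(components)),
                 chi2 = chi2, scale = sum(wv), condition = kappa,
                 warning = warn),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  for (nm in names(x$fractions))
    cat(sprintf("  %-18s %5.1f %% (+/- %.1f)\n", nm, x$fractions[[nm]],
                x$se[[nm]]))
  cat(sprintf("  chi2 = %.3g\n", x$chi2))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Rank trimer-of-dimers hypotheses against an experimental curve
#'
#' Runs [mixture_fractions()] once per trimer hypothesis (each mixed with
#' the same dimer) and returns both results ranked by chi-square (ties
#' reported, not broken).
#'
#' @param exp_curve `sas_curve` with sigma.
#' @param dimer_curve `sas_curve` of the dimer component.
#' @param trimer_curves Named list of `sas_curve`s, one per hypothesis
#'   (e.g. `list(tripod = ..., tm_bound = ...)`).
#' @param masses Length-2 relative masses `c(dimer, trimer)` or NULL.
#' @return List of `mixture_fit` results, sorted by increasing chi2,
#'   with a `ranking` attribute of hypothesis names.
#' @export
compare_trimer_hypotheses <- function(exp_curve, dimer_curve, trimer_curves,
                                      masses = c(1, 3)) {
  fits <- lapply(trimer_curves, function(tc)
    mixture_fractions(list(dimer = dimer_curve, trimer_of_dimers = tc),
                      exp_curve, masses = masses))
  ord <- order(vapply(fits, `[[`, numeric(1), "chi2"))
  fits <- fits[ord]
  attr(fits, "ranking") <- names(fits)
  fits
}
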