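#' Guinier fit of the low-q region
#'
#' Weighted linear fit of `ln I` against `q^2` over the largest low-q
#' window satisfying `q_max * Rg <= qrg_max`, iterated to
#' self-consistency (the window is shrunk/grown until the Rg it yields is
#' consistent with its own upper limit).
#'
#' @param curve `sas_curve` with positive intensities at low q.
#' @param qmin Lower q limit of the window (default: first point).
#' @param qrg_max Guinier window rule, default 1.3.
#' @return Object of class `sas_guinier`: list with `rg`, `i0`,
#'   `q_range`, `n`, `qrg`, `residuals`.
#' @export
guinier_fit <- function(curve, qmin = NULL, qrg_max = 1.3) {
  q <- curve$q; I <- curve$I
  s <- curve$sigma
  if (is.null(qmin)) qmin <- min(q)
  qmax <- max(q)
  for (iter in 1:60) {
    sel <- q >= qmin & q <= qmax & I > 0
    if (sum(sel) < 5) stop("Guinier window too small (< 5 points)")
    x <- q[sel]^2; y <- log(I[sel])
    wt <- if (is.null(s)) rep(1, sum(sel)) else (I[sel] / s[sel])^2
    fit <- lm(y ~ x, weights = wt)
    slope <- coef(fit)[[2]]
    if (slope >= 0) stop("non-Guinier behaviour: ln I does not decrease with q^2")
    rg <- sqrt(-3 * slope)
    qmax_new <- qrg_max / rg
    if (abs(qmax_new - qmax) < 1e-10 * qmax) break
    qmax <- min(qmax_new, max(q))
    if (qmax <= qmin) stop("Guinier window collapsed below qmin")
  }
  structure(list(rg = rg, i0 = exp(coef(fit)[[1]]),
                 q_range = c(qmin, max(q[sel])), n = sum(sel),
                 qrg = max(q[sel]) * rg,
                 residuals = stats::residuals(fit)),
            class = "sas_guinier")
}

#' @export
print.sas_guinier <- function(x, ...) {
  cat(sprintf("Guinier: Rg = %.2f A, I(0) = %.4g (%d pts, qmax*Rg = %.2f)\n",
              x$rg, x$i0, x$n, x$qrg))
  invisible(x)
}

# second-difference (curvature) operator on an M-point grid
.second_diff <- function(M) {
  D <- matrix(0, M - 2, M)
  for (i in seq_len(M - 2)) D[i, i:(i + 2)] <- c(1, -2, 1)
  D
}

#' Regularized indirect Fourier transform to P(r)
#'
#' Recovers the pair distance distribution function on `[0, dmax]` from
#' a noisy curve by minimizing
#' `sum(((I - I_P)/sigma)^2) + alpha * ||P''||^2` subject to
#' `P(0) = P(dmax) = 0` and (by default) `P >= 0`, where
#' `I_P(q) = 4*pi * integral P(r) sinc(q r) dr` (trapezoidal quadrature,
#' uniform M-point grid). `alpha = "auto"` picks the L-curve corner
#' (maximum curvature of log misfit vs log smoothness seminorm).
#'
#' @param curve `sas_curve` with sigma.
#' @param dmax Maximum particle dimension, A.
#' @param alpha "auto" or a non-negative value.
#' @param M Grid size (default 101).
#' @param positivity Constrain P >= 0 (default TRUE).
#' @return Object of class `sas_pr`: list with `r`, `pr`, `dmax`,
#'   `alpha`, `fit` (back-transformed curve on the data grid), `chi2`.
#' @export
ift_pr <- function(curve, dmax, alpha = "auto", M = 101, positivity = TRUE) {
  if (dmax <= 0) stop("dmax must be positive")
  if (is.null(curve$sigma)) stop("ift_pr needs a curve with sigma")
  q <- curve$q; I <- curve$I; s <- curve$sigma
  if (dmax < pi / max(q)) warning("dmax below the resolvable scale of the q range")
  r <- seq(0, dmax, length.out = M)
  dr <- r[2] - r[1]
  wts <- rep(dr, M); wts[c(1, M)] <- dr / 2      # trapezoid
  qr <- outer(q, r)
  sinc <- ifelse(qr < 1e-12, 1, sin(qr) / qr)
  A_full <- 4 * pi * sweep(sinc, 2, wts, "*")
  interior <- 2:(M - 1)                           # P(0)=P(dmax)=0 by construction
  A <- A_full[, interior, drop = FALSE]
  D <- .second_diff(M)[, interior, drop = FALSE]
  Aw <- A / s
  yw <- I / s
  solve_p <- function(a) {
    if (positivity) {
      sol <- pracma::lsqnonneg(rbind(Aw, sqrt(a) * D), c(yw, numeric(nrow(D))))
      sol$x
    } else {
      qr_ <- qr.solve(rbind(Aw, sqrt(a) * D), c(yw, numeric(nrow(D))))
      qr_
    }
  }
  if (identical(alpha, "auto")) {
    # scale-aware alpha grid from the normal-equation magnitudes
    a0 <- sum(Aw^2) / max(sum(D^2), 1e-12)
    grid <- a0 * 10^seq(-6, 2, length.out = 13)
    rho <- eta <- numeric(length(grid))
    sols <- vector("list", length(grid))
    for (i in seq_along(grid)) {
      p <- solve_p(grid[i])
      sols[[i]] <- p
      rho[i] <- sum((Aw %*% p - yw)^2)
      eta[i] <- sum((D %*% p)^2)
    }
    k <- .lcurve_corner(log(pmax(rho, 1e-300)), log(pmax(eta, 1e-300)))
    alpha <- grid[k]
    p <- sols[[k]]
  } else {
    if (alpha < 0) stop("alpha must be >= 0")
    p <- solve_p(alpha)
  }
  P <- numeric(M)
  P[interior] <- p
  Ifit <- as.numeric(A %*% p)
  chi2 <- sum(((I - Ifit) / s)^2) / length(I)
  structure(list(r = r, pr = P, dmax = dmax, alpha = alpha,
                 fit = sas_curve(q, Ifit, radiation = curve$radiation),
                 chi2 = chi2),
            class = "sas_pr")
}

# discrete L-curve corner: maximum curvature of (x, y); interior points only
.lcurve_corner <- function(x, y) {
  n <- length(x)
  if (n < 3) return(1L)
  kappa <- rep(-Inf, n)
  for (i in 2:(n - 1)) {
    dx1 <- x[i] - x[i - 1]; dy1 <- y[i] - y[i - 1]
    dx2 <- x[i + 1] - x[i]; dy2 <- y[i + 1] - y[i]
    cross <- dx1 * dy2 - dy1 * dx2
    den <- (dx1^2 + dy1^2) * (dx2^2 + dy2^2)
    if (den > 0) kappa[i] <- cross / sqrt(den)
  }
  which.max(kappa)
}

#' @export
print.sas_pr <- function(x, ...) {
  m <- pr_moments(x)
  cat(sprintf("P(r): dmax = %.1f A, alpha = %.3g, chi2 = %.3g | Rg = %.2f A, I(0) = %.4g\n",
              x$dmax, x$alpha, x$chi2, m$rg, m$i0))
  invisible(x)
}

#' Real-space Rg and I(0) from a distance distribution
#'
#' `Rg^2 = integral(r^2 P) / (2 integral(P))`,
#' `I(0) = 4 pi integral(P dr)` (trapezoidal quadrature).
#'
#' @param pr `sas_pr`, or a list with `r` and `pr` vectors.
#' @return List with `rg` and `i0`.
#' @export
pr_moments <- function(pr) {
  r <- pr$r; P <- pr$pr
  ip <- pracma::trapz(r, P)
  if (ip <= 0) stop("integral of P(r) is not positive")
  ir2 <- pracma::trapz(r, r^2 * P)
  list(rg = sqrt(ir2 / (2 * ip)), i0 = 4 * pi * ip)
}

#' Dimensionless Kratky transform
#'
#' Returns `(q*Rg, (q*Rg)^2 * I(q) / I(0))`. Globular particles peak
#' near `qRg = sqrt(3)` at `3/e`; extended or flexible particles peak at
#' larger `qRg`.
#'
#' @param curve `sas_curve`.
#' @param rg,i0 Radius of gyration (A) and forward intensity.
#' @return data.frame with columns `qrg`, `kratky`.
#' @export
kratky_dimensionless <- function(curve, rg, i0) {
  if (rg <= 0 || i0 <= 0) stop("rg and i0 must be positive")
  x <- curve$q * rg
  data.frame(qrg = x, kratky = x^2 * curve$I / i0)
}

#' Peaks of a distance distribution
#'
#' Local maxima of P(r) with topographic prominence above
#' `min_prominence` (as a fraction of max P), sorted by r.
#'
#' @param pr `sas_pr` (or list with `r`, `pr`).
#' @param min_prominence Prominence threshold, fraction of `max(P)`.
#' @return Numeric vector of peak positions (A); may be empty.
#' @export
pr_peaks <- function(pr, min_prominence = 0.05) {
  P <- pr$pr; r <- pr$r
  n <- length(P)
  if (n < 3 || max(P) <= 0) return(numeric(0))
  locmax <- which(diff(sign(diff(P))) < 0) + 1L
  locmax <- locmax[P[locmax] > 0]
  prom <- vapply(locmax, function(i) {
    left <- P[1:i]; right <- P[i:n]
    hl <- which(left > P[i]); hr <- which(right > P[i])
    vl <- if (length(hl)) min(left[max(hl):i]) else min(left)
    vr <- if (length(hr)) min(right[1:min(hr)]) else min(right)
    P[i] - max(vl, vr)
  }, numeric(1))
  r[locmax[prom >= min_prominence * max(P)]]
}
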