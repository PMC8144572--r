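test_that("hinge basis covers the full grid with clash logging", {
  d <- cached_dimer()
  b1 <- build_hinge_basis(d, angle_grid = 0, q = default_q_grid("saxs", 61))
  expect_equal(ncol(b1$A), 1)
  straight <- debye_curve(d, q = default_q_grid("saxs", 61))
  expect_equal(b1$A[, 1], straight$I, tolerance = 1e-9)
  basis <- cached_basis()
  expect_equal(ncol(basis$A) + nrow(basis$excluded), 343)
  expect_lte(nrow(basis$excluded), 2)
  # lexicographic member order in (theta1, theta2, theta3)
  expect_true(!is.unsorted(basis$angles$theta1))
})

test_that("a pre-bent model gives the same curve as its basis member", {
  d <- cached_dimer()
  q <- default_q_grid("saxs", 61)
  basis <- build_hinge_basis(d, angle_grid = c(-60, 0, 60), q = q,
                             solvent = solvent_model(0.15, 0))
  target <- c(60, 0, 0)
  i <- which(basis$angles$theta1 == 60 & basis$angles$theta2 == 0 &
               basis$angles$theta3 == 0)
  bent <- bend_at_hinge(d, "HAMP1", 60)
  cv <- debye_curve(bent, solvent_model(0.15, 0), q)
  expect_equal(basis$A[, i], cv$I, tolerance = 1e-9)
})

test_that("noise-free single-member data is recovered exactly", {
  basis <- cached_basis()
  i <- 137
  pure <- sas_curve(basis$q, basis$A[, i],
                    sigma = rep(1e-6 * max(basis$A[, i]), length(basis$q)))
  fit <- tikhonov_nnls(basis, pure, alpha = 0)
  expect_equal(fit$weights[i], 1, tolerance = 1e-6)
  expect_lt(max(fit$weights[-i]), 1e-6)
})

test_that("a known three-member mixture is recovered", {
  basis <- cached_basis()
  key <- paste(basis$angles$theta1, basis$angles$theta2, basis$angles$theta3)
  idx <- c(which(key == "0 0 0"), which(key == "-60 30 90"),
           which(key == "30 60 -30"))
  w_true <- c(0.5, 0.3, 0.2)
  Imix <- as.numeric(basis$A[, idx] %*% w_true)
  # per-member attribution is only sharp at very low noise: distinct
  # weightings of the smooth conformer curves fit the data equally well
  # once the noise reaches the percent level
  sig <- 5e-4 * Imix
  set.seed(14)
  noisy <- sas_curve(basis$q, Imix + rnorm(length(Imix), 0, sig), sigma = sig)
  fit <- tikhonov_nnls(basis, noisy, alpha = 1e-6)
  expect_true(all(abs(fit$weights[idx] - w_true) < 0.05))
  # at SANS-like 2 % noise the identifiable functionals still hold:
  # the fit matches within errors and the RMS bend statistics agree
  sig2 <- 0.02 * Imix
  set.seed(14)
  noisy2 <- sas_curve(basis$q, Imix + rnorm(length(Imix), 0, sig2),
                      sigma = sig2)
  fit2 <- tikhonov_nnls(basis, noisy2)
  expect_lt(fit2$chi2, 1.5)
  rms_true <- sqrt(colSums(w_true * as.matrix(basis$angles[idx, ])^2))
  expect_true(all(abs(fit2$rms_angles - rms_true) < 12))
})

test_that("weights stay on the simplex and alpha -> inf gives uniform", {
  basis <- cached_basis()
  d <- cached_dimer()
  ds <- make_ensemble_dataset(d, rms_deg = 40, n_conformers = 300, seed = 5,
                              noise = noise_spec(seed = 5), basis = basis)
  f1 <- tikhonov_nnls(basis, ds$curve)
  expect_true(all(f1$weights >= 0))
  expect_equal(sum(f1$weights), 1, tolerance = 1e-9)
  m <- ncol(basis$A)
  fbig <- tikhonov_nnls(basis, ds$curve, alpha = 1e8)
  expect_equal(unname(fbig$weights), rep(1 / m, m), tolerance = 1e-6)
  # misfit is non-decreasing in alpha
  chis <- vapply(c(1, 30, 1000), function(a)
    tikhonov_nnls(basis, ds$curve, alpha = a)$chi2, numeric(1))
  expect_true(all(diff(chis) >= -1e-8))
})

test_that("per-hinge RMS statistics follow the weight arithmetic", {
  basis <- cached_basis()
  w <- numeric(ncol(basis$A))
  i0 <- which(basis$angles$theta1 == 0 & basis$angles$theta2 == 0 &
                basis$angles$theta3 == 0)
  w[i0] <- 1
  sol <- structure(list(weights = w, angles = basis$angles),
                   class = "ensemble_fit")
  expect_equal(unname(hinge_angle_stats(sol, basis)), c(0, 0, 0))
  # uniform weights over the 7-point grid: mean theta^2 =
  # 2*(90^2 + 60^2 + 30^2)/7 = 3600, so RMS = 60 deg per hinge
  wu <- rep(1 / ncol(basis$A), ncol(basis$A))
  solu <- structure(list(weights = wu, angles = basis$angles),
                    class = "ensemble_fit")
  rms_u <- hinge_angle_stats(solu, basis)
  expect_equal(unname(rms_u), rep(sqrt(25200 / 7), 3), tolerance = 0.01)
})

test_that("flexible-ensemble RMS bending angles are recovered", {
  basis <- cached_basis()
  d <- cached_dimer()
  ds <- make_ensemble_dataset(d, rms_deg = 55, n_conformers = 2000, seed = 7,
                              noise = noise_spec(seed = 7), basis = basis)
  expect_equal(sum(ds$weights), 1, tolerance = 1e-12)
  fit <- tikhonov_nnls(basis, ds$curve)
  expect_true(all(abs(fit$rms_angles - ds$rms_truth) < 10))
  expect_lt(fit$chi2, 2)
})

test_that("mixture fractions: purity, recovery, scale invariance", {
  d <- cached_dimer()
  db <- build_belt(d, belt_spec())
  tri <- assemble_c3(db, 90 / sqrt(3), "tripod")
  solv <- solvent_model(4, 1)
  ds <- make_mixture_dataset(db, tri, 0, noise = noise_spec(seed = 3),
                             solvent = solv, radiation = "neutron")
  f0 <- mixture_fractions(ds$components, ds$curve)
  expect_gt(f0$fractions[["dimer"]], 97)
  expect_equal(sum(f0$fractions), 100, tolerance = 1e-9)
  ds36 <- make_mixture_dataset(db, tri, 0.36, noise = noise_spec(seed = 11),
                               solvent = solv, radiation = "neutron")
  f36 <- mixture_fractions(ds36$components, ds36$curve)
  expect_lt(abs(f36$fractions[["trimer_of_dimers"]] - 36), 3)
  expect_gt(f36$se[["trimer_of_dimers"]], 0)
  # scale invariance
  sc <- sas_curve(ds36$curve$q, 5.5 * ds36$curve$I, 5.5 * ds36$curve$sigma,
                  radiation = "neutron")
  fsc <- mixture_fractions(ds36$components, sc)
  expect_equal(fsc$fractions, f36$fractions, tolerance = 1e-9)
  expect_equal(fsc$chi2, f36$chi2, tolerance = 1e-9)
})

test_that("collinear components are flagged", {
  q <- default_q_grid("sans", 61)
  a <- sas_curve(q, exp(-q^2 * 900))
  b <- sas_curve(q, 2 * exp(-q^2 * 900))
  data <- sas_curve(q, 1.5 * exp(-q^2 * 900), sigma = rep(1e-3, 61))
  f <- mixture_fractions(list(a = a, b = b), data)
  expect_match(f$warning, "collinear")
})

test_that("bootstrap uncertainties are reproducible and sensible", {
  d <- cached_dimer()
  db <- build_belt(d, belt_spec())
  tri <- assemble_c3(db, 90 / sqrt(3), "tripod")
  ds <- make_mixture_dataset(db, tri, 0.3, noise = noise_spec(seed = 4),
                             solvent = solvent_model(4, 1), radiation = "neutron")
  f1 <- mixture_fractions(ds$components, ds$curve, bootstrap = 100, seed = 9)
  f2 <- mixture_fractions(ds$components, ds$curve, bootstrap = 100, seed = 9)
  expect_equal(f1$se, f2$se)
  expect_true(all(f1$se > 0 & f1$se < 10))
})

test_that("trimer hypotheses are ranked by fit quality", {
  d <- cached_dimer()
  db <- build_belt(d, belt_spec())
  solv <- solvent_model(4, 1)
  q <- default_q_grid("sans", 121)
  tripod <- assemble_c3(db, 90 / sqrt(3), "tripod")
  tmb <- assemble_c3(db, 8, "tm_bound")
  cd <- debye_curve(db, solv, q, "neutron")
  ct1 <- debye_curve(tripod, solv, q, "neutron")
  ct2 <- debye_curve(tmb, solv, q, "neutron")
  nd <- sas_curve(q, cd$I, radiation = "neutron")
  # data generated from the tripod mixture
  ds <- make_mixture_dataset(db, tripod, 0.36, noise = noise_spec(seed = 6),
                             solvent = solv, radiation = "neutron")
  fits <- compare_trimer_hypotheses(ds$curve, nd,
                                    list(tripod = ct1, tm_bound = ct2))
  expect_equal(attr(fits, "ranking")[1], "tripod")
  # data generated from the tm_bound mixture ranks tm_bound first
  ds2 <- make_mixture_dataset(db, tmb, 0.36, noise = noise_spec(seed = 6),
                              solvent = solv, radiation = "neutron")
  fits2 <- compare_trimer_hypotheses(ds2$curve, nd,
                                     list(tripod = ct1, tm_bound = ct2))
  expect_equal(attr(fits2, "ranking")[1], "tm_bound")
  # identical hypotheses tie
  fits3 <- compare_trimer_hypotheses(ds$curve, nd,
                                     list(h1 = ct1, h2 = ct1))
  expect_equal(fits3[[1]]$chi2, fits3[[2]]$chi2, tolerance = 1e-12)
})
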