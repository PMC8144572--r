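test_that("Guinier fit is exact on an ideal Gaussian curve", {
  q <- seq(0.001, 0.1, length.out = 200)
  curve <- sas_curve(q, 5 * exp(-q^2 * 30^2 / 3))
  g <- guinier_fit(curve)
  expect_equal(g$rg, 30, tolerance = 1e-9)
  expect_equal(g$i0, 5, tolerance = 1e-9)
  expect_lte(g$qrg, 1.3 + 1e-9)
})

test_that("Guinier fit rejects pathological input", {
  q <- seq(0.001, 0.1, length.out = 50)
  expect_error(guinier_fit(sas_curve(q, exp(q^2 * 100))), "non-Guinier")
  expect_error(guinier_fit(sas_curve(q[1:4], exp(-q[1:4]^2 * 900))), "window")
})

test_that("Guinier recovers rod and sphere Rg within a few percent", {
  rod <- rod_model(120, 121)
  cv <- debye_curve(rod, q = default_q_grid("saxs", 201))
  # elongated particles need the tighter window rule
  g <- guinier_fit(cv, qrg_max = 0.8)
  expect_equal(g$rg, 120 / sqrt(12), tolerance = 0.02)
  sph <- cached_sphere()
  gs <- guinier_fit(debye_curve(sph, q = seq(0.005, 0.2, length.out = 121)))
  expect_equal(gs$rg, sqrt(3 / 5) * 40, tolerance = 0.03)
})

test_that("noisy sphere curves give stable Rg across seeds", {
  sph <- cached_sphere()
  q <- seq(0.005, 0.15, length.out = 101)
  truth <- debye_curve(sph, q = q)$I
  rg_true <- sqrt(3 / 5) * 40
  # the window estimator itself carries a small (< 2 %) truncation bias;
  # 2 % noise should scatter estimates by less than 3 % around it in at
  # least 95 % of seeds
  rg_base <- guinier_fit(sas_curve(q, truth))$rg
  expect_equal(rg_base, rg_true, tolerance = 0.02)
  ok <- 0
  for (seed in 1:20) {
    sig <- 0.02 * truth + 1e-6 * truth[1]
    set.seed(seed)
    noisy <- sas_curve(q, truth + rnorm(length(q), 0, sig), sigma = sig)
    rg <- guinier_fit(noisy)$rg
    if (abs(rg - rg_base) / rg_base < 0.03) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("IFT recovers the sphere distance distribution", {
  sph <- cached_sphere(50, 2.5)
  q <- seq(0.006, 0.25, length.out = 121)
  truth <- debye_curve(sph, q = q)$I
  sig <- 0.01 * truth + 1e-4 * truth[1]
  set.seed(10)
  noisy <- sas_curve(q, truth + rnorm(length(q), 0, sig), sigma = sig)
  pr <- ift_pr(noisy, dmax = 100)
  # endpoints exactly zero by construction
  expect_identical(pr$pr[1], 0)
  expect_identical(pr$pr[length(pr$pr)], 0)
  # peak at 1.05 R within 3 %
  peak <- pr$r[which.max(pr$pr)]
  expect_equal(peak, 1.05 * 50, tolerance = 0.03)
  # shape matches the analytic sphere p(r)
  ref <- sphere_pr(pr$r, 50)
  expect_gt(cor(pr$pr, ref), 0.99)
  # back-transform fits within noise
  expect_lt(pr$chi2, 1.5)
})

test_that("IFT validates input and warns on unresolvable dmax", {
  q <- seq(0.01, 0.3, length.out = 60)
  cv <- sas_curve(q, exp(-q^2 * 400), sigma = rep(1e-3, 60))
  expect_error(ift_pr(cv, dmax = -5), "dmax")
  expect_error(ift_pr(sas_curve(q, exp(-q^2 * 400)), dmax = 100), "sigma")
  expect_warning(ift_pr(cv, dmax = 5), "resolvable")
})

test_that("regularization strength trades misfit for smoothness monotonically", {
  sph <- cached_sphere()
  q <- seq(0.006, 0.2, length.out = 81)
  truth <- debye_curve(sph, q = q)$I
  sig <- 0.03 * truth + 1e-4 * truth[1]
  set.seed(11)
  noisy <- sas_curve(q, truth + rnorm(length(q), 0, sig), sigma = sig)
  alphas <- c(1e-10, 1e-7, 1e-4, 1e-1)
  fits <- lapply(alphas, function(a) ift_pr(noisy, dmax = 85, alpha = a))
  misfit <- vapply(fits, `[[`, numeric(1), "chi2")
  rough <- vapply(fits, function(f) sum(diff(f$pr, differences = 2)^2),
                  numeric(1))
  expect_true(all(diff(misfit) >= -1e-8))
  expect_true(all(diff(rough) <= 1e-8))
})

test_that("P(r) moments match closed forms and Guinier cross-checks", {
  # analytic sphere p(r) evaluated on a fine grid
  r <- seq(0, 100, length.out = 401)
  pr <- list(r = r, pr = sphere_pr(r, 50))
  m <- pr_moments(pr)
  expect_equal(m$rg, sqrt(3 / 5) * 50, tolerance = 1e-4)
  # Rg from pr_moments vs guinier_fit on the same synthetic curve
  sph <- cached_sphere()
  q <- seq(0.005, 0.2, length.out = 101)
  truth <- debye_curve(sph, q = q)$I
  sig <- 0.02 * truth + 1e-4 * truth[1]
  set.seed(12)
  noisy <- sas_curve(q, truth + rnorm(length(q), 0, sig), sigma = sig)
  rg_pr <- pr_moments(ift_pr(noisy, dmax = 82))$rg
  rg_gu <- guinier_fit(noisy)$rg
  expect_equal(rg_pr, rg_gu, tolerance = 0.02)
  expect_error(pr_moments(list(r = r, pr = -sphere_pr(r, 50))), "positive")
})

test_that("forward model -> IFT -> moments round trip recovers model Rg", {
  sph <- cached_sphere()
  q <- seq(0.005, 0.2, length.out = 101)
  truth <- debye_curve(sph, q = q)
  nofree <- sas_curve(q, truth$I, sigma = 1e-4 * truth$I + 1e-9 * truth$I[1])
  rg_model <- radius_of_gyration(sph, "contrast")
  rg_rt <- pr_moments(ift_pr(nofree, dmax = 82))$rg
  expect_equal(rg_rt, rg_model, tolerance = 0.03)
})

test_that("dimensionless Kratky separates globular from flexible", {
  # ideal Guinier curve peaks at sqrt(3) with value 3/e
  q <- seq(0.001, 0.2, length.out = 400)
  rg <- 30
  kr <- kratky_dimensionless(sas_curve(q, 7 * exp(-q^2 * rg^2 / 3)), rg, 7)
  expect_equal(kr$qrg[which.max(kr$kratky)], sqrt(3), tolerance = 0.01)
  expect_equal(max(kr$kratky), 3 / exp(1), tolerance = 1e-3)
  # synthetic globular sphere: peak below qRg = 3
  sph <- cached_sphere()
  cs <- debye_curve(sph, q = seq(0.004, 0.2, length.out = 151))
  gs <- guinier_fit(cs)
  ks <- kratky_dimensionless(cs, gs$rg, gs$i0)
  sel <- ks$qrg <= 8
  expect_lt(ks$qrg[sel][which.max(ks$kratky[sel])], 3)
  expect_error(kratky_dimensionless(cs, -1, 1), "positive")
})

test_that("flexible hinge-ensemble curves peak at high qRg and then decay", {
  d <- cached_dimer()
  basis <- build_hinge_basis(d, angle_grid = seq(-90, 90, 45),
                             solvent = solvent_model(0.15, 0),
                             q = default_q_grid("saxs", 121),
                             belt = belt_spec(packing = 0.6))
  ds <- make_ensemble_dataset(d, rms_deg = 55, n_conformers = 500, seed = 7,
                              basis = basis)
  gu <- guinier_fit(ds$curve)
  kr <- kratky_dimensionless(ds$curve, gu$rg, gu$i0)
  sel <- kr$qrg <= 12
  peak <- kr$qrg[sel][which.max(kr$kratky[sel])]
  expect_gt(peak, 4)
  # decays after the maximum (not fully unfolded)
  expect_lt(kr$kratky[sel][length(kr$kratky[sel])], max(kr$kratky[sel]))
})

test_that("pr_peaks finds the right peaks with prominence filtering", {
  r <- seq(0, 100, length.out = 201)
  # unimodal sphere
  expect_length(pr_peaks(list(r = r, pr = sphere_pr(r, 40))), 1)
  # flat P = 0
  expect_length(pr_peaks(list(r = r, pr = rep(0, 201))), 0)
  # known bimodal: two Gaussian bumps at 30 and 75
  pr <- exp(-(r - 30)^2 / 50) + 0.6 * exp(-(r - 75)^2 / 80)
  pk <- pr_peaks(list(r = r, pr = pr), 0.05)
  expect_length(pk, 2)
  expect_equal(pk, c(30, 75), tolerance = 0.02)
  # small ripples are rejected by prominence
  pr2 <- pr + 0.01 * sin(r)
  expect_length(pr_peaks(list(r = r, pr = pr2), 0.05), 2)
})

test_that("component distance distributions separate dimer and tripod trimer", {
  d <- cached_dimer()
  db <- build_belt(d, belt_spec())
  tri <- assemble_c3(db, 90 / sqrt(3), "tripod")
  solv <- solvent_model(4, 1)
  mk <- function(f, dmax) {
    ds <- make_mixture_dataset(db, tri, f, noise = noise_spec(seed = 2),
                               solvent = solv, radiation = "neutron")
    ift_pr(ds$curve, dmax = dmax)
  }
  # dimer component peaks at small r (membrane domain + belt cross-section)
  pk_d <- pr_peaks(mk(0, 260), 0.05)
  expect_gt(length(pk_d), 0)
  expect_true(min(pk_d) > 20 && min(pk_d) < 60)
  # tripod trimer peaks near the ~90 A inter-dimer distance
  pk_t <- pr_peaks(mk(1, 330), 0.05)
  expect_gt(length(pk_t), 0)
  expect_true(any(pk_t > 80 & pk_t < 115))
  # the mixture has more long-distance mass than the pure dimer
  pr_mix <- mk(0.36, 330)
  pr_dim <- mk(0, 330)
  mass_long <- function(p) sum(p$pr[p$r > 150]) / sum(p$pr)
  expect_gt(mass_long(pr_mix), mass_long(pr_dim))
})
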