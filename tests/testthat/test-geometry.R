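make_rod_x <- function() {
  # synthetic rod along x with a small TM blob at the low-x end
  xyz <- rbind(cbind(seq(-10, 10, 2), 0.3, 0.1),
               cbind(seq(12, 200, 2), 0, 0))
  n <- nrow(xyz)
  seg <- c(rep("TM", 11), rep("adaptation", n - 11))
  particle_model(sasflex:::bead_frame(xyz, seg, seq_len(n), "A"))
}

test_that("orient_membrane puts TM centroid at origin and rod on +z", {
  m <- orient_membrane(make_rod_x())
  s <- m$scatterers
  tm <- s$segment == "TM"
  expect_equal(colMeans(as.matrix(s[tm, c("x", "y", "z")])), c(0, 0, 0),
               tolerance = 1e-9, ignore_attr = TRUE)
  # second-moment tensor diagonal with largest eigenvalue on z
  cc <- scale(as.matrix(s[, c("x", "y", "z")]), scale = FALSE)
  M <- crossprod(cc) / nrow(cc)
  expect_lt(max(abs(M[upper.tri(M)])) / M[3, 3], 1e-5)
  expect_gt(M[3, 3], M[1, 1])
  expect_gt(M[3, 3], M[2, 2])
  # cytoplasmic part points +z
  expect_gt(mean(s$z[!tm]), 0)
})

test_that("orientation is idempotent and translation invariant", {
  m <- orient_membrane(make_rod_x())
  m2 <- orient_membrane(m)
  expect_equal(coords(m2), coords(m), tolerance = 1e-9)
  shifted <- make_rod_x()
  shifted$scatterers$x <- shifted$scatterers$x + 10
  shifted$scatterers$y <- shifted$scatterers$y - 5
  shifted$scatterers$z <- shifted$scatterers$z + 3
  expect_equal(coords(orient_membrane(shifted)), coords(m), tolerance = 1e-9)
})

test_that("orient_membrane preserves pairwise distances and checks TM", {
  m0 <- make_rod_x()
  m <- orient_membrane(m0)
  expect_equal(as.numeric(dist(coords(m))), as.numeric(dist(coords(m0))),
               tolerance = 1e-9)
  empty <- m0
  empty$scatterers$segment <- "adaptation"
  expect_error(orient_membrane(empty), "TM")
})

test_that("hinge bends follow right-angle geometry and invert exactly", {
  # straight 200 A rod with hinge at midpoint
  xyz <- cbind(0, 0, seq(0, 200, 2.5))
  n <- nrow(xyz)
  m <- particle_model(sasflex:::bead_frame(xyz, "adaptation", seq_len(n), "A"),
                      hinges = c(HAMP1 = (n + 1) / 2))
  expect_equal(coords(bend_at_hinge(m, "HAMP1", 0)), coords(m))
  bent <- bend_at_hinge(m, "HAMP1", 90)
  ee <- sqrt(sum((coords(bent)[n, ] - coords(bent)[1, ])^2))
  expect_equal(ee, sqrt(100^2 + 100^2), tolerance = 1e-6)
  # distal block stays rigid
  distal <- m$scatterers$resid > m$hinges[["HAMP1"]]
  expect_equal(as.numeric(dist(coords(bent)[distal, ])),
               as.numeric(dist(coords(m)[distal, ])), tolerance = 1e-9)
  # theta then -theta restores the original coordinates
  back <- bend_at_hinge(bend_at_hinge(m, "HAMP1", 57), "HAMP1", -57)
  expect_equal(coords(back), coords(m), tolerance = 1e-9)
})

test_that("hinge bend validates input", {
  m <- cached_dimer()
  expect_error(bend_at_hinge(m, "HAMP1", 200), "180")
  expect_error(bend_at_hinge(m, 99999, 30), "absent")
  expect_error(bend_at_hinge(m, "nosuch", 30), "nosuch")
})

test_that("hinge grid over three hinges yields 343 distinct conformers", {
  m <- cached_dimer()
  grid <- expand.grid(t1 = seq(-90, 90, 30), t2 = seq(-90, 90, 30),
                      t3 = seq(-90, 90, 30))
  sig <- apply(grid, 1, function(th) {
    conf <- bend_at_hinge(m, "HAMP1", th[1])
    conf <- bend_at_hinge(conf, "HAMP2", th[2])
    conf <- bend_at_hinge(conf, "Gly", th[3])
    xyz <- coords(conf)
    paste(round(xyz[nrow(xyz), ], 3), collapse = ",")
  })
  expect_equal(length(unique(sig)), 343)
})

test_that("C3 assembly is exactly symmetric with the requested geometry", {
  d <- cached_dimer()
  tri <- assemble_c3(d, 90 / sqrt(3), "tripod")
  xyz <- coords(tri)
  # 120 degree rotation maps the coordinate set onto itself
  R <- matrix(c(cos(2 * pi / 3), -sin(2 * pi / 3), 0,
                sin(2 * pi / 3), cos(2 * pi / 3), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  rot <- xyz %*% t(R)
  n1 <- nrow(xyz) / 3
  expect_equal(rot[1:n1, ], xyz[n1 + 1:n1, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  # TM centroid pairwise distance = radial_offset * sqrt(3) = 90 A
  s <- tri$scatterers
  ctrs <- t(sapply(split(s[s$segment == "TM", ], s$dimer[s$segment == "TM"]),
                   function(d) colMeans(as.matrix(d[, c("x", "y", "z")]))))
  dd <- as.matrix(dist(ctrs))
  expect_equal(unname(dd[1, 2]), 90, tolerance = 1e-6)
  expect_equal(unname(dd[1, 3]), unname(dd[2, 3]), tolerance = 1e-6)
})

test_that("tm_bound mode with zero offset stacks TM centroids on the axis", {
  d <- cached_dimer()
  tri <- assemble_c3(d, 0, "tm_bound")
  s <- tri$scatterers
  ctrs <- t(sapply(split(s[s$segment == "TM", ], s$dimer[s$segment == "TM"]),
                   function(d) colMeans(as.matrix(d[, c("x", "y", "z")]))))
  expect_lt(max(dist(ctrs)), 1e-9)
  expect_error(assemble_c3(d, -5, "tripod"), ">= 0")
})

test_that("radius of gyration matches closed forms", {
  one <- particle_model(sasflex:::bead_frame(matrix(c(1, 2, 3), 1), "TM",
                                             NA_integer_, "A"))
  expect_equal(radius_of_gyration(one), 0)
  expect_equal(radius_of_gyration(rod_model(120, 2001)), 120 / sqrt(12),
               tolerance = 1e-3)
  # parallel-axis combination of two disjoint equal-mass sets
  set.seed(42)
  a <- matrix(rnorm(300, sd = 4), ncol = 3)
  b <- matrix(rnorm(300, sd = 4), ncol = 3)
  b[, 1] <- b[, 1] + 50
  ma <- particle_model(sasflex:::bead_frame(a, "TM", NA_integer_, "A"))
  mb <- particle_model(sasflex:::bead_frame(b, "TM", NA_integer_, "A"))
  mab <- particle_model(sasflex:::bead_frame(rbind(a, b), "TM", NA_integer_, "A"))
  d2 <- sum((colMeans(a) - colMeans(b))^2)
  expect_equal(radius_of_gyration(mab)^2,
               (radius_of_gyration(ma)^2 + radius_of_gyration(mb)^2 + d2 / 2) / 2,
               tolerance = 1e-9)
})

test_that("inter-dimer separations follow C3 geometry", {
  d <- cached_dimer()
  tri <- assemble_c3(d, 30, "tm_bound")
  res <- unique(tri$scatterers$resid[tri$scatterers$segment == "adaptation"])
  sel <- sort(res)[c(3, 10)]
  sep <- inter_dimer_separations(tri, sel)
  # site radius rho from the axis -> separation rho * sqrt(3)
  s <- tri$scatterers
  for (i in seq_along(sel)) {
    d1 <- s[s$dimer == 1 & !is.na(s$resid) & s$resid == sel[i], c("x", "y")]
    rho <- sqrt(sum(colMeans(d1)^2))
    expect_equal(unname(sep[i]), rho * sqrt(3), tolerance = 1e-6)
  }
  expect_error(inter_dimer_separations(tri, 10^6), "missing")
  expect_error(inter_dimer_separations(d, 5), "dimer index")
})

test_that("methylation-region site radii of 17-23 A give 30-40 A separations", {
  d <- cached_dimer()
  # pick a radial offset placing adaptation-region sites at ~20 A radius
  tri <- assemble_c3(d, 20, "tm_bound")
  res <- sort(unique(tri$scatterers$resid[tri$scatterers$segment == "adaptation"]))
  sep <- inter_dimer_separations(tri, res[seq(1, length(res), by = 20)])
  expect_true(all(sep >= 30 & sep <= 40))
})
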