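test_that("all formation energies vanish for an empty patch except the closed rims", {
  p <- scaled_parameters(3e-4, 2e-3, 0)
  expect_identical(dg_cap_bending(0, p), 0)
  expect_identical(dg_cap_one_defect_bending(0, p), 0)
  expect_equal(dg_ribbon_bending(0, w = 0.3, p), p$lam / (2 * pi) * 0.3)
  expect_equal(dg_belt(0, p), p$lam)                      # rim offset lam * r
  pg <- scaled_parameters(3e-4, 2e-3, 50)
  expect_equal(dg_cylinder(0, pg, r = 1.3), pg$lam * 1.3)
  expect_equal(dg_cap_general(0, pg, r = 2), 0)
})

test_that("the defectless cap energy matches term-by-term hand summation", {
  p <- scaled_parameters(1e-4, 1e-3, 0)
  x <- 0.1
  by_hand <- -(1e-3 / 4) * x^2 + (1e-4 / 2) * x + x^6 / 1536
  expect_equal(dg_cap_bending(x, p), by_hand, tolerance = 1e-14)
  expect_equal(by_hand, 2.50065104e-6, tolerance = 1e-8)
  # interior maximum (nucleation barrier) near x = lam/dmu with height
  # lam^2/(4 dmu): elastic term negligible at this size
  xs <- seq(1e-4, 0.5, by = 1e-4)
  prof <- dg_cap_bending(xs, p)
  i <- which.max(prof)
  expect_equal(xs[i], 0.1, tolerance = 1e-2)
  expect_equal(prof[i], 2.5e-6, tolerance = 1e-2)
})

test_that("the central-disclination term changes sign at sqrt(2/3)", {
  p <- scaled_parameters(0, 0, 0)
  defect_term <- function(x) dg_cap_one_defect_bending(x, p) - dg_cap_bending(x, p)
  root <- uniroot(defect_term, c(0.5, 1), tol = 1e-12)$root
  expect_equal(root, sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(defect_onset_x(), sqrt(2 / 3))
  # direct arithmetic at x = 0.5 with lam = dmu = 0: the disclination
  # contribution on top of the defect-free cap
  expect_equal(dg_cap_one_defect_bending(0.5, p) - dg_cap_bending(0.5, p),
               (0.25 / 1152) * (1 - 0.375), tolerance = 1e-14)
  # in the general form the onset moves to x/r = sqrt(2/3)
  pg <- scaled_parameters(0, 0, 10)
  r <- 1.4
  f <- function(x) dg_cap_one_defect_general(x, pg, r) - dg_cap_general(x, pg, r)
  expect_equal(uniroot(f, c(0.5, 2), tol = 1e-12)$root, sqrt(2 / 3) * r,
               tolerance = 1e-8)
})

test_that("ribbon edge energy is the perimeter identity (lam/2pi)(l + w)", {
  p <- scaled_parameters(7e-4, 0, 0)
  set.seed(42)
  for (k in 1:20) {
    w <- runif(1, 0.05, 0.8)
    x <- sqrt(runif(1, 0.01, 2 * w / pi * 2)) # keep l <= 2 pi
    l <- pi * x^2 / w
    edge <- dg_ribbon_bending(x, w, p) - (9 / 20480) * x^2 * w^4
    expect_equal(edge, p$lam / (2 * pi) * (l + w), tolerance = 1e-12)
  }
  expect_error(dg_ribbon_bending(2, w = 0.3, p), class = "capshell_belt_regime")
  expect_error(dg_ribbon_bending(0.5, w = -1, p))
})

test_that("ribbon term-by-term sum matches an independent evaluation", {
  p <- scaled_parameters(1e-4, 1e-3, 0)
  x <- 0.5; w <- 0.2
  terms <- c(-(1e-3 / 4) * 0.25, (1e-4 / 2) * 0.25 / 0.2,
             (1e-4 / (2 * pi)) * 0.2, (9 / 20480) * 0.25 * 0.2^4)
  expect_equal(dg_ribbon_bending(x, w, p), sum(terms), tolerance = 1e-14)
})

test_that("the closed belt is the ribbon at l = 2 pi up to the rim substitution", {
  # the ribbon stretching at w = x^2/2 reduces to the belt's x^10 coefficient;
  # the side-edge term (lam/2pi) w is replaced by the closed rim
  p <- scaled_parameters(2.3e-4, 1.7e-3, 0)
  for (x in c(0.3, 0.8, 1.2, 1.6)) {
    w <- x^2 / 2
    expect_equal((9 / 20480) * x^2 * w^4, (9 / 327680) * x^10,
                 tolerance = 1e-12)
    rib <- dg_ribbon_bending(x, w, p)
    expect_equal(dg_belt(x, p), rib - p$lam / (2 * pi) * w, tolerance = 1e-12)
  }
  expect_equal(dg_belt(1, scaled_parameters(0, 0, 0)), 9 / 327680,
               tolerance = 1e-14)
})

test_that("cylinder growth becomes unbounded exactly at dmu = 1/(2 gamma)", {
  gam <- 80
  r <- 1
  per_area <- function(dmu) {
    p <- scaled_parameters(0, dmu, gam)
    dg_cylinder(2, p, r) / 4   # x^2 coefficient (no rim at lam = 0)
  }
  expect_gt(per_area(1 / (2 * gam) - 1e-6), 0)
  expect_lt(per_area(1 / (2 * gam) + 1e-6), 0)
  expect_equal(1 / (2 * 80), 0.00625)
  expect_error(dg_cylinder(1, scaled_parameters(1e-4, 1e-3, 0)),
               class = "capshell_bending_excluded")
})

test_that("general-gamma caps reduce to the bending-dominated forms at r = 1", {
  pg <- scaled_parameters(1e-4, 1e-3, 40)
  p0 <- scaled_parameters(1e-4, 1e-3, 0)
  xs <- c(0.2, 0.7, 1.4)
  expect_equal(dg_cap_general(xs, pg, r = 1), dg_cap_bending(xs, p0))
  # bending prefactor from the per-curvature Helfrich model:
  # (kappa/2) sum_i (c_i - 1/R0)^2 over area pi rho0^2, scaled by 4 pi R0^2 Y
  gam <- 37; r <- 1.8; x <- 1.1
  helfrich <- 0.5 * (1 / gam) * 2 * (1 / r - 1)^2 * (pi * x^2) / (4 * pi)
  bend <- dg_cap_general(x, scaled_parameters(0, 0, gam), r) -
    (-0 / 4 * x^2 + 0 + x^6 / (1536 * r^4))
  expect_equal(bend, helfrich, tolerance = 1e-12)
})

test_that("the optimal cap radius solves the stationarity cubic", {
  expect_equal(optimal_cap_radius(c(0.3, 1, 2), 0), rep(1, 3))
  # gamma = 192, x = 1: root of r^3 - r^2 - 1 = 0 (polynomial oracle)
  oracle <- Re(polyroot(c(-1, 0, -1, 1))[abs(Im(polyroot(c(-1, 0, -1, 1)))) < 1e-9])
  expect_equal(optimal_cap_radius(1, 192), oracle, tolerance = 1e-9)
  # small gamma x^4 = 1e-3: first-order perturbation r = 1 + gamma x^4/192
  # (second-order correction is ~5e-11, below the 1e-8 absolute check)
  expect_lt(abs(optimal_cap_radius(1, 1e-3) - (1 + 1e-3 / 192)), 1e-8)
  # stationarity of the general cap energy in r at the returned root
  for (x in c(0.5, 1, 1.8)) {
    for (gam in c(20, 192, 800)) {
      r0 <- optimal_cap_radius(x, gam)
      p <- scaled_parameters(1e-4, 1e-3, gam)
      h <- 1e-6
      d <- (dg_cap_general(x, p, r0 + h) - dg_cap_general(x, p, r0 - h)) / (2 * h)
      expect_lt(abs(d), 1e-8)
    }
  }
})

test_that("nucleation estimates match the printed formulas and the landscape", {
  ne <- nucleation_estimate(p_belt_ref)
  expect_equal(ne$x_star, 0.1)
  expect_equal(ne$dg_star, 2.5e-6)
  ne0 <- nucleation_estimate(scaled_parameters(0, 1e-3, 0))
  expect_equal(ne0$x_star, 0)
  expect_equal(ne0$dg_star, 0)
  expect_error(nucleation_estimate(scaled_parameters(1e-4, -1e-3, 0)))
  # grid-scan maximum agrees to < 1% where the elastic term is negligible
  for (pars in list(c(1e-4, 1e-3), c(5e-5, 2e-3), c(2e-4, 4e-3))) {
    p <- scaled_parameters(pars[1], pars[2], 0)
    ne <- nucleation_estimate(p)
    xs <- seq(ne$x_star / 10, ne$x_star * 4, length.out = 4000)
    prof <- dg_cap_bending(xs, p)
    i <- which.max(prof)
    elastic_frac <- (ne$x_star^6 / 1536) / ne$dg_star
    if (elastic_frac < 0.01) {
      expect_equal(prof[i], ne$dg_star, tolerance = 1e-2)
      expect_equal(xs[i], ne$x_star, tolerance = 1e-2)
    }
  }
})

test_that("formation energies are monotone in dmu and lam", {
  set.seed(11)
  for (k in 1:15) {
    x <- runif(1, 0.1, 1.9)
    lam <- runif(1, 1e-5, 2e-3); dmu <- runif(1, 1e-4, 1e-2)
    d_lam <- 1.3 * lam; d_dmu <- 1.3 * dmu
    for (f in list(dg_cap_bending, dg_cap_one_defect_bending,
                   function(x, p) dg_belt(x, p),
                   function(x, p) dg_shell_n_defects(x, 12, p))) {
      expect_lt(f(x, scaled_parameters(lam, d_dmu, 0)),
                f(x, scaled_parameters(lam, dmu, 0)))
      expect_gt(f(x, scaled_parameters(d_lam, dmu, 0)),
                f(x, scaled_parameters(lam, dmu, 0)))
    }
  }
})

test_that("domain errors are raised for invalid sizes", {
  p <- scaled_parameters(1e-4, 1e-3, 0)
  expect_error(dg_cap_bending(-0.1, p))
  expect_error(dg_shell_n_defects(1, 0, p))
  expect_error(dg_shell_n_defects(1, 13, p))
  expect_error(dg_shell_n_defects(2.5, 12, p))       # beyond closure at r = 1
  expect_error(dg_belt(1, p, r = 1.5))               # r pinned at gamma = 0
  expect_error(scaled_parameters(-1e-4, 1e-3, 0))
  expect_error(scaled_parameters(1e-4, 1e-3, -1))
})
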