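test_that("the pair potential has its minimum -eps0 at the aligned contact", {
  pp <- pp_ref()
  d <- dimer_minimum()
  expect_equal(pair_energy(d$rvec, d$oi, d$oj, pp, cutoff = 1e6), -1,
               tolerance = 1e-6)
  expect_equal(pair_energy(c(60, 0, 0), d$oi, d$oj, pp, cutoff = 1e6), 0,
               tolerance = 1e-8)
  # tilting one angle by one Gaussian width scales the well by exp(-1/2)
  nu <- 1.45; al <- 0.25
  oi2 <- c(cos(nu + al), sin(nu + al), 0)
  expect_equal(pair_energy(d$rvec, oi2, d$oj, pp, cutoff = 1e6),
               -exp(-0.5), tolerance = 1e-6)
  # strict-product mode agrees on the attractive branch
  expect_equal(pair_energy(d$rvec, oi2, d$oj, pp, cutoff = 1e6,
                           strict_product = TRUE), -exp(-0.5),
               tolerance = 1e-6)
  expect_error(pair_energy(c(0, 0, 0), d$oi, d$oj, pp))
})

test_that("analytic gradients match central differences on random configurations", {
  pl <- list(m = 12, n = 6, nu = 1.45, alpha = 0.25, kt = 1.5)
  set.seed(7)
  worst <- 0
  for (k in 1:50) {
    rv <- rnorm(3); rv <- rv / sqrt(sum(rv^2)) * runif(1, 0.95, 2.2)
    a <- as.vector(random_unit()); b <- as.vector(random_unit())
    g <- capshell:::.cpp_pair_gradients(rv, a, b, pl, 1e6, FALSE)
    h <- 1e-6
    num <- function(f) vapply(1:3, function(d) {
      e <- rep(0, 3); e[d] <- h; (f(e) - f(-e)) / (2 * h)
    }, numeric(1))
    gr_n <- num(function(e) capshell:::.cpp_pair_energy(rv + e, a, b, pl, 1e6, FALSE))
    gi_n <- num(function(e) capshell:::.cpp_pair_energy(rv, a + e, b, pl, 1e6, FALSE))
    gj_n <- num(function(e) capshell:::.cpp_pair_energy(rv, a, b + e, pl, 1e6, FALSE))
    sc <- max(1e-8, sqrt(sum(c(gr_n, gi_n, gj_n)^2)))
    worst <- max(worst, max(abs(c(g$dV_drvec - gr_n, g$dV_doi - gi_n,
                                  g$dV_doj - gj_n))) / sc)
  }
  expect_lt(worst, 1e-6)
})

test_that("the aligned dimer is a stationary point with zero net force", {
  pp <- pp_ref()
  d <- dimer_minimum()
  st <- simulation_state(rbind(c(0, 0, 0), d$rvec), rbind(d$oi, d$oj))
  cfg <- simulation_config(pp, N_total = 2, density = 1e-4, seed_size = 2)
  ft <- forces_and_torques(st, cfg)
  expect_lt(max(abs(ft$force)), 1e-8)
  expect_lt(max(abs(ft$torque)), 1e-8)
  # an isolated capsomer feels nothing
  st1 <- simulation_state(matrix(0, 1, 3), matrix(c(0, 0, 1), 1, 3))
  cfg1 <- simulation_config(pp, N_total = 7, density = 1e-4, seed_size = 7)
  ft1 <- .subset2(capshell:::.cpp_forces(st1$positions, st1$orientations, 0,
                                         capshell:::.pp_list(pp), 2.5, FALSE,
                                         1e4), "force")
  expect_true(all(ft1 == 0))
})

test_that("pairwise forces obey Newton's third law", {
  pp <- pp_ref()
  set.seed(3)
  pos <- matrix(runif(60, 0, 6), 20)
  ori <- random_unit(20)
  st <- simulation_state(pos, ori, box = 6)
  cfg <- simulation_config(pp, N_total = 20, density = 0.1, seed_size = 7)
  ft <- suppressWarnings(forces_and_torques(st, cfg))
  expect_lt(sqrt(sum(colSums(ft$force)^2)), 1e-10)
})

test_that("free diffusion reproduces the Einstein relation", {
  pp <- pp_ref()
  msds <- numeric(10)
  for (s in 1:10) {
    set.seed(s)
    n <- 20
    pos <- matrix(runif(3 * n, 0, 500), n)  # dilute: no interactions
    st <- simulation_state(pos, random_unit(n), box = 0, rng_seed = s)
    cfg <- simulation_config(pp, N_total = n, density = 1e-6, seed_size = 7,
                             T_red = 0.1)
    st2 <- bd_step(st, cfg, n = 10000)
    msds[s] <- mean(rowSums((st2$positions - pos)^2))
  }
  tt <- 10000 * 5e-5
  expect_equal(mean(msds) / (6 * tt), 1, tolerance = 0.05)
})

test_that("zero-temperature relaxation reaches the dimer minimum", {
  pp <- pp_ref()
  d <- dimer_minimum()
  st <- simulation_state(rbind(c(0, 0, 0), c(1.18, 0.03, 0)),
                         rbind(d$oi, d$oj))
  cfg <- simulation_config(pp, N_total = 2, density = 1e-4, seed_size = 2)
  st2 <- bd_step(st, cfg, n = 20000, relax = TRUE)
  expect_equal(sqrt(sum((st2$positions[1, ] - st2$positions[2, ])^2)), 1,
               tolerance = 1e-4)
  # with no force and no noise the state is unchanged
  far <- simulation_state(rbind(c(0, 0, 0), c(30, 0, 0)), rbind(d$oi, d$oj))
  far2 <- bd_step(far, cfg, n = 100, relax = TRUE)
  expect_equal(far2$positions, far$positions)
  expect_equal(far2$orientations, far$orientations)
})

test_that("overdamped descent never increases the energy and keeps unit orientations", {
  pp <- pp_ref()
  set.seed(5)
  pos <- matrix(runif(45, 0, 5), 15)
  st <- simulation_state(pos, random_unit(15), box = 5)
  cfg <- simulation_config(pp, N_total = 15, density = 0.12, seed_size = 7)
  Eprev <- suppressWarnings(forces_and_torques(st, cfg))$energy
  for (k in 1:20) {
    st <- suppressWarnings(bd_step(st, cfg, n = 50, relax = TRUE))
    E <- suppressWarnings(forces_and_torques(st, cfg))$energy
    expect_lte(E, Eprev + 1e-9)
    Eprev <- E
  }
  expect_lt(max(abs(sqrt(rowSums(st$orientations^2)) - 1)), 1e-12)
})

test_that("the seed cap is hexagonally packed on the spontaneous sphere", {
  pp <- potential_parameters(24, 12, 1.45, 0.0953)
  seed <- build_seed_cap(pp, 19)
  expect_equal(nrow(seed$positions), 19)
  D <- as.matrix(dist(seed$positions))
  nn <- apply(D + diag(99, 19), 1, min)
  expect_true(all(abs(nn - 1) < 0.05))
  sf <- capshell:::.sphere_fit(seed$positions)
  R0 <- 1 / (2 * abs(cos(1.45)))
  expect_equal(sf$radius, R0, tolerance = 0.02)
  expect_true(all(abs(sf$dist - R0) / R0 < 0.02))
  expect_error(build_seed_cap(potential_parameters(24, 12, pi / 2, 0.1)))
  expect_error(build_seed_cap(pp, 3))
  # after a short relaxation the energy per bond is within 10% of -eps0
  cfg <- simulation_config(pp, N_total = 19, density = 1e-3)
  st <- bd_step(seed, cfg, n = 3000, relax = TRUE)
  E <- forces_and_torques(st, cfg)$energy
  nbonds <- (sum(as.matrix(dist(st$positions)) < 1.4) - 19) / 2
  expect_equal(E / nbonds, -1, tolerance = 0.1)
})

test_that("a dimer at T = 0.1 samples bond lengths peaked at the contact distance", {
  pp <- pp_ref()
  d <- dimer_minimum()
  st <- simulation_state(rbind(c(0, 0, 0), d$rvec), rbind(d$oi, d$oj),
                         rng_seed = 17)
  cfg <- simulation_config(pp, N_total = 2, density = 1e-4, seed_size = 2,
                           T_red = 0.1)
  seps <- numeric(400)
  for (k in seq_along(seps)) {
    st <- bd_step(st, cfg, n = 50)
    seps[k] <- sqrt(sum((st$positions[1, ] - st$positions[2, ])^2))
  }
  dens <- stats::density(seps, bw = "SJ")
  mode_sim <- dens$x[which.max(dens$y)]
  # Boltzmann-weighted 1-D oracle over the aligned-bond distance
  rs <- seq(0.9, 1.3, by = 1e-4)
  Vr <- vapply(rs, function(r) pair_energy(c(r, 0, 0), d$oi, d$oj, pp,
                                           cutoff = 1e6), numeric(1))
  mode_ref <- rs[which.max(rs^2 * exp(-Vr / 0.1))]
  expect_equal(mode_sim, mode_ref, tolerance = 0.02)
})

test_that("assembly runs are bit-reproducible for a fixed seed", {
  pp <- potential_parameters(24, 12, 1.45, 0.0953)
  cfg <- simulation_config(pp, N_total = 30, density = 0.02, n_steps = 1500,
                           rng_seed = 11, thin = 500)
  r1 <- run_assembly(cfg)
  r2 <- run_assembly(cfg)
  expect_identical(r1$state$positions, r2$state$positions)
  expect_identical(r1$state$orientations, r2$state$orientations)
  expect_identical(r1$series, r2$series)
  expect_error(run_assembly(simulation_config(pp, N_total = 400,
                                              density = 2, n_steps = 10)))
})
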