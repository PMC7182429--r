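test_that("the belt wins at the belt-dominated reference point", {
  pt <- classify_point(p_belt_ref)
  expect_equal(pt$winner$structure, "belt")
  expect_lt(pt$winner$dg, 0)
  expect_true(pt$metastable_defectless_cap)
  # the defectless cap's own minimum is negative but not global
  expect_lt(pt$energies$cap_defectless$dg, 0)
  expect_gt(pt$energies$cap_defectless$dg, pt$winner$dg)
})

test_that("the cylinder wins with unbounded growth beyond dmu = 1/(2 gamma)", {
  pt <- classify_point(scaled_parameters(5e-4, 0.01, 80))  # 0.01 > 1/160
  expect_equal(pt$winner$structure, "cylinder")
  expect_true(pt$winner$unbounded)
  expect_identical(pt$winner$dg, -Inf)
  pt2 <- classify_point(scaled_parameters(5e-4, 6e-3, 80)) # just below 1/160
  expect_false(identical(pt2$winner$structure, "cylinder"))
})

test_that("negative chemical potential disassembles everything", {
  pt <- classify_point(scaled_parameters(1e-5, -1e-3, 0))
  expect_equal(pt$winner$structure, "disassembled")
  expect_equal(pt$winner$dg, 0)
})

test_that("a 1x1 grid equals classify_point and axes are validated", {
  pt <- classify_point(scaled_parameters(3e-4, 3e-3, 0))
  g <- compute_grid(3e-4, 3e-3, 0)
  expect_equal(g$labels[1, 1], pt$winner$structure)
  expect_equal(g$dg[1, 1], pt$winner$dg, tolerance = 1e-12)
  expect_error(compute_grid(numeric(0), 1e-3, 0))
  expect_error(compute_grid(c(2e-4, 1e-4), 1e-3, 0))
})

test_that("classify_point agrees with exhaustive brute-force minimisation", {
  # dense independent grids over x (and r, n); same physics, no refinement
  brute <- function(p) {
    xs <- seq(1e-3, 2, length.out = 3000)
    cands <- list()
    if (p$gamma == 0) {
      cands$cap_defectless <- min(dg_cap_bending(xs, p))
      cands$cap_one_defect <- min(dg_cap_one_defect_bending(xs, p))
      cands$shell_n_defects <- min(vapply(2:12, function(n)
        min(dg_shell_n_defects(xs, n, p)), numeric(1)))
      cands$belt <- min(dg_belt(xs, p))
    } else {
      rs <- exp(seq(log(0.2), log(5), length.out = 90))
      best <- c(cap_defectless = Inf, cap_one_defect = Inf,
                shell_n_defects = Inf, belt = Inf, cylinder = Inf)
      for (r in rs) {
        xr <- seq(1e-3, 2 * r, length.out = 700)
        best["cap_one_defect"] <- min(best["cap_one_defect"],
                                      dg_cap_one_defect_general(xr, p, r))
        best["belt"] <- min(best["belt"], dg_belt(xr, p, r))
        best["cylinder"] <- min(best["cylinder"], dg_cylinder(xr, p, r))
        for (n in 2:12)
          best["shell_n_defects"] <- min(best["shell_n_defects"],
                                         dg_shell_n_defects(xr, n, p, r))
      }
      xs2 <- seq(1e-3, 10, length.out = 3000)
      rq <- pmin(pmax(optimal_cap_radius(xs2, p$gamma), xs2 / 2), 5)
      best["cap_defectless"] <- min(dg_cap_general(xs2, p, rq))
      cands <- as.list(best)
    }
    dgv <- unlist(cands)
    if (min(dgv) >= 0) return(list(winner = "disassembled", dg = 0))
    list(winner = names(which.min(dgv)), dg = min(dgv))
  }
  set.seed(21)
  pts <- list()
  for (k in 1:6) pts[[k]] <- scaled_parameters(runif(1, 1e-5, 2e-3),
                                               runif(1, 1e-4, 8e-3), 0)
  for (k in 7:10) pts[[k]] <- scaled_parameters(runif(1, 1e-5, 2e-3),
                                                runif(1, 1e-4, 5e-3), 80)
  for (p in pts) {
    ref <- brute(p)
    pt <- classify_point(p)
    if (pt$winner$unbounded) {
      expect_gt(p$dmu, 1 / (2 * p$gamma))
    } else {
      expect_equal(pt$winner$structure, ref$winner)
      expect_lte(pt$winner$dg, ref$dg + 1e-7)
      expect_equal(pt$winner$dg, ref$dg, tolerance = 5e-3)
    }
  }
})

test_that("phase labels do not flicker along chemical-potential rays", {
  ax <- default_grid_axes(1, 36)
  for (lam in c(2e-5, 1e-4, 3e-4, 8e-4, 1.8e-3)) {
    g <- compute_grid(lam, ax$dmu, 0)
    labs <- as.vector(g$labels)
    changes <- sum(labs[-1] != labs[-length(labs)])
    runs <- rle(labs)
    # each label forms one contiguous run (no flickering)
    expect_equal(length(runs$values), length(unique(labs)))
    expect_lte(changes, 3)
  }
})

test_that("winner energies are stable under refinement of the inner minimiser", {
  for (p in list(p_belt_ref, scaled_parameters(5e-4, 3e-3, 0),
                 scaled_parameters(1e-4, 3e-3, 80))) {
    pt <- classify_point(p)
    if (pt$winner$unbounded) next
    m <- pt$energies[[pt$winner$structure]]
    f <- function(x) switch(pt$winner$structure,
      belt = dg_belt(x, p, m$r),
      shell_n_defects = dg_shell_n_defects(x, m$n_def, p, m$r),
      cap_defectless = dg_cap_general(x, p, m$r),
      cap_one_defect = dg_cap_one_defect_general(x, p, m$r))
    xs <- seq(max(1e-4, m$x - 0.05), min(2 * m$r, m$x + 0.05),
              length.out = 20001)
    expect_equal(min(f(xs)), m$dg, tolerance = 1e-8)
  }
})

test_that("the belt/defect-shell frontier sits near 0.0020 independently of lam", {
  fb1 <- trace_boundary("belt", "shell_n_defects", gamma = 0, lam = 1e-4)
  fb5 <- trace_boundary("belt", "shell_n_defects", gamma = 0, lam = 5e-4)
  expect_equal(fb1, 0.0020, tolerance = 0.05)
  expect_equal(fb5 / fb1, 1, tolerance = 0.03)
})

test_that("the cylinder onset boundary is analytic at 1/(2 gamma)", {
  expect_equal(trace_boundary("cylinder", "shell_n_defects", 80, 1e-4),
               0.00625)
  expect_error(trace_boundary("cylinder", "belt", 0, 1e-4),
               class = "capshell_boundary_absent")
})

test_that("a boundary-absent bracket raises a classed error", {
  expect_error(trace_boundary("belt", "cap_defectless", 0, 1e-4,
                              interval = c(1e-3, 2e-3)),
               class = "capshell_boundary_absent")
})

test_that("the critical FvK number is consistent with the traced frontier", {
  gc <- critical_gamma_no_spheres(lam = 1e-4)
  fb <- trace_boundary("belt", "shell_n_defects", gamma = 0, lam = 1e-4)
  expect_equal(1 / (2 * gc), fb, tolerance = 1e-6)
  expect_equal(gc, 250, tolerance = 0.05)
})
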