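## Global-stability classification over (lambda, dmu, gamma).
##
## Each candidate structure's free energy is minimised over its size
## variables; the structure with the lowest minimum is the equilibrium
## outcome, the disassembled state winning when every minimum is
## non-negative.  The landscape is non-convex (nucleation barrier followed
## by a well), so every minimisation is seeded by a dense grid scan and then
## refined by bounded 1-D searches (coordinate descent in x and r).
##
## Domain conventions: x in (0, 2r] for every finite structure (closure at
## x = 2r, equal areas); r in [0.2, 5] wherever the radius is a free
## variable; the defectless cap takes its radius from the stationarity
## cubic r^2(r-1) = gamma x^4/192, clamped to the same box and to the
## closure constraint r >= x/2.

.R_MIN <- 0.2
.R_MAX <- 5

.xgrid <- function(xhi, n = 220L) {
  n1 <- floor(n / 2)
  unique(sort(c(exp(seq(log(1e-3), log(xhi), length.out = n1)),
                seq(xhi / (n - n1), xhi, length.out = n - n1))))
}

.rgrid <- function(n = 36L) exp(seq(log(.R_MIN), log(.R_MAX), length.out = n))

# fetch the fixed layouts for n = 2..12 once (cheap after first build)
.all_defect_layouts <- function() lapply(2:12, .defect_layout)

# fast unvalidated energy kernels used by the minimisers; x, r vectors.
# tab: element of .all_defect_layouts() for shells with n_def >= 2.
.dg_fast <- function(structure, x, r, lam, dmu, gamma, n_def = 0L,
                     tab = NULL) {
  bend <- if (gamma > 0) x^2 * (1 / r - 1)^2 / (4 * gamma) else 0
  switch(structure,
    cap_defectless = -dmu / 4 * x^2 + lam / 2 * x + x^6 / (1536 * r^4) + bend,
    cap_one_defect = -dmu / 4 * x^2 + lam / 2 * x + x^6 / (1536 * r^4) + bend +
      x^2 / 1152 * (1 - 1.5 * x^2 / r^2),
    shell_n_defects = {
      t <- pmin(x^2 / r^2, 4)
      w <- 1 / 1152 - t / 768
      defE <- if (n_def == 1L) x^2 * w else x^2 * (w * tab$f1 + tab$G2)
      -dmu / 4 * x^2 + lam / 2 * x + x^6 / (1536 * r^4) + bend + defE
    },
    belt = -dmu / 4 * x^2 + lam * r + 9 / 327680 * x^10 / r^8 + bend,
    cylinder = -dmu / 4 * x^2 + lam * r +
      x^2 * (1 + (1 / r - 1)^2) / (8 * gamma),
    stop("unknown structure: ", structure))
}

# coordinate-descent refinement from a grid seed, honouring x <= 2r
.refine_xr <- function(structure, lam, dmu, gamma, x0, r0, n_def = 0L,
                       tab = NULL, free_r = TRUE, rounds = 2L) {
  f <- function(xx, rr) .dg_fast(structure, xx, rr, lam, dmu, gamma, n_def, tab)
  x <- x0; r <- r0
  spherical <- structure %in% c("cap_defectless", "cap_one_defect",
                                "shell_n_defects")
  for (k in seq_len(rounds)) {
    x <- stats::optimize(function(xx) f(xx, r),
                         lower = 1e-6, upper = 2 * r, tol = 1e-10)$minimum
    if (free_r) {
      r <- stats::optimize(function(rr) f(x, rr),
                           lower = max(.R_MIN, x / 2), upper = .R_MAX,
                           tol = 1e-10)$minimum
    }
    if (spherical && f(2 * r, r) < f(x, r)) x <- 2 * r
  }
  # closed shells live on the boundary x = 2r, a diagonal valley in which
  # coordinate descent stalls; search along the closure line directly
  if (spherical && free_r) {
    ob <- stats::optimize(function(rr) f(2 * rr, rr),
                          lower = .R_MIN, upper = .R_MAX, tol = 1e-10)
    if (ob$objective < f(x, r)) { r <- ob$minimum; x <- 2 * r }
  }
  list(dg = f(x, r), x = x, r = r)
}

# minimise one structure's free energy over its size variables
.min_structure_fast <- function(structure, lam, dmu, gamma, n_def = 0L,
                                tab = NULL, refine = TRUE) {
  g0 <- gamma == 0
  if (structure == "cylinder") {
    if (g0) return(NULL)   # excluded in the bending-dominated limit
    if (dmu > 1 / (2 * gamma))
      return(list(dg = -Inf, x = Inf, r = 1, n_def = 0L, unbounded = TRUE))
    # bounded branch: the x^2 coefficient is >= 0 at every r, so the
    # infimum sits at x -> 0 with the smallest admissible rim
    return(list(dg = lam * .R_MIN, x = 0, r = .R_MIN, n_def = 0L,
                unbounded = FALSE))
  }
  if (g0) {
    xs <- .xgrid(2)
    dg <- .dg_fast(structure, xs, 1, lam, dmu, 0, n_def, tab)
    i <- which.min(dg)
    out <- list(dg = dg[i], x = xs[i], r = 1, n_def = n_def,
                unbounded = FALSE)
    if (!refine) return(out)
    fit <- .refine_xr(structure, lam, dmu, 0, xs[i], 1, n_def, tab,
                      free_r = FALSE)
    if (fit$dg < out$dg) out <- list(dg = fit$dg, x = fit$x, r = 1,
                                     n_def = n_def, unbounded = FALSE)
    return(out)
  }
  if (structure == "cap_defectless") {
    xs <- .xgrid(2 * .R_MAX)
    r <- pmin(pmax(optimal_cap_radius(xs, gamma), xs / 2), .R_MAX)
    dg <- .dg_fast(structure, xs, r, lam, dmu, gamma)
    i <- which.min(dg)
    out <- list(dg = dg[i], x = xs[i], r = r[i], n_def = 0L,
                unbounded = FALSE)
    if (!refine) return(out)
    fit <- .refine_xr(structure, lam, dmu, gamma, xs[i], r[i])
    if (fit$dg < out$dg) out <- list(dg = fit$dg, x = fit$x, r = fit$r,
                                     n_def = 0L, unbounded = FALSE)
    return(out)
  }
  # free-radius structures: (x, r) scan including the closure boundary
  xs <- .xgrid(2 * .R_MAX, n = 100L)
  rs <- .rgrid()
  X <- rep(xs, times = length(rs)); R <- rep(rs, each = length(xs))
  keep <- X <= 2 * R
  xb <- xs[xs / 2 >= .R_MIN & xs / 2 <= .R_MAX]
  X <- c(X[keep], xb); R <- c(R[keep], xb / 2)
  dg <- .dg_fast(structure, X, R, lam, dmu, gamma, n_def, tab)
  i <- which.min(dg)
  out <- list(dg = dg[i], x = X[i], r = R[i], n_def = n_def,
              unbounded = FALSE)
  if (!refine) return(out)
  fit <- .refine_xr(structure, lam, dmu, gamma, X[i], R[i], n_def, tab)
  if (fit$dg < out$dg) out <- list(dg = fit$dg, x = fit$x, r = fit$r,
                                   n_def = n_def, unbounded = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# best shell over the number of disclinations 2..12 (n = 1 is its own
# label).  One shared (x, r) scan; only the best defect count is refined.
.min_shell_over_n <- function(lam, dmu, gamma, tabs = .all_defect_layouts(),
                              refine = TRUE) {
  g0 <- gamma == 0
  if (g0) {
    X <- .xgrid(2); R <- 1
  } else {
    xs <- .xgrid(2 * .R_MAX, n = 100L); rs <- .rgrid()
    X <- rep(xs, times = length(rs)); R <- rep(rs, each = length(xs))
    keep <- X <= 2 * R
    xb <- xs[xs / 2 >= .R_MIN & xs / 2 <= .R_MAX]
    X <- c(X[keep], xb); R <- c(R[keep], xb / 2)
  }
  base <- .dg_fast("cap_defectless", X, R, lam, dmu, gamma)
  t <- pmin(X^2 / R^2, 4)
  w <- 1 / 1152 - t / 768
  per_n <- vector("list", length(tabs))
  for (k in seq_along(tabs)) {
    tab <- tabs[[k]]
    dg <- base + X^2 * (w * tab$f1 + tab$G2)
    i <- which.min(dg)
    per_n[[k]] <- list(dg = dg[i], x = X[i], r = if (g0) 1 else R[i],
                       n_def = k + 1L, unbounded = FALSE)
  }
  ord <- order(vapply(per_n, `[[`, numeric(1), "dg"))
  best <- per_n[[ord[1]]]
  if (refine) {
    for (k in ord[seq_len(min(2L, length(ord)))]) {
      cand <- per_n[[k]]
      fit <- .refine_xr("shell_n_defects", lam, dmu, gamma, cand$x, cand$r,
                        cand$n_def, tabs[[cand$n_def - 1L]], free_r = !g0)
      if (fit$dg < best$dg)
        best <- list(dg = fit$dg, x = fit$x, r = fit$r, n_def = cand$n_def,
                     unbounded = FALSE)
    }
  }
  best
}

#' Classify the globally stable structure at one parameter point
#'
#' Minimises the free energy of every candidate structure (defectless cap,
#' one-defect cap, shell with 2-12 disclinations, closed belt, cylinder)
#' over its size variables and reports the global minimum.  The cylinder is
#' declared the winner with unbounded growth whenever
#' \eqn{\tilde{\Delta\mu} > 1/(2\gamma)}; the disassembled state wins when
#' every minimum is non-negative.  Exact ties are broken by the order of
#' [structure_levels()] and flagged as coexistence.
#'
#' @param p a [scaled_parameters()] object.
#' @return An object of class `phase_point`: list with `params`, `winner`
#'   and `runner_up` ([structure_energy()] objects), `energies` (all
#'   minima), `metastable_defectless_cap` and `coexistence` flags.
#' @examples
#' classify_point(scaled_parameters(1e-4, 1e-3, 0))$winner
#' @export
classify_point <- function(p) {
  p <- as_scaled_parameters(p)
  if (!all(vapply(unclass(p), is.finite, logical(1))))
    stop("scaled parameters must be finite")
  tabs <- .all_defect_layouts()
  mins <- list(
    cap_defectless  = .min_structure_fast("cap_defectless", p$lam, p$dmu, p$gamma),
    cap_one_defect  = .min_structure_fast("cap_one_defect", p$lam, p$dmu, p$gamma),
    shell_n_defects = .min_shell_over_n(p$lam, p$dmu, p$gamma, tabs),
    belt            = .min_structure_fast("belt", p$lam, p$dmu, p$gamma),
    cylinder        = .min_structure_fast("cylinder", p$lam, p$dmu, p$gamma))
  mins <- Filter(Negate(is.null), mins)
  to_se <- function(nm) {
    m <- mins[[nm]]
    sz <- if (is.finite(m$x)) shell_size(min(m$x, 2 * m$r), m$r, n_def = m$n_def)
    structure_energy(nm, size = sz,
                     dg = if (m$unbounded) -Inf else m$dg,
                     unbounded = m$unbounded)
  }
  nms <- names(mins)
  dgs <- vapply(nms, function(nm) mins[[nm]]$dg, numeric(1))
  ord <- order(dgs, match(nms, structure_levels()))
  winner_nm <- nms[ord[1]]
  coexist <- length(ord) > 1 &&
    is.finite(dgs[ord[1]]) &&
    abs(dgs[ord[2]] - dgs[ord[1]]) <= 1e-10 * max(1e-8, abs(dgs[ord[1]]))
  if (dgs[ord[1]] >= -1e-12) {
    winner <- structure_energy("disassembled", dg = 0)
    runner <- to_se(winner_nm)
  } else {
    winner <- to_se(winner_nm)
    runner <- if (length(ord) > 1) to_se(nms[ord[2]])
              else structure_energy("disassembled", dg = 0)
  }
  meta <- mins$cap_defectless$dg < 0 && winner$structure != "cap_defectless"
  structure(list(params = p, winner = winner, runner_up = runner,
                 energies = mins,
                 metastable_defectless_cap = meta,
                 coexistence = coexist),
            class = "phase_point")
}

#' @export
print.phase_point <- function(x, ...) {
  print(x$params)
  cat("winner:     "); print(x$winner)
  cat("runner-up:  "); print(x$runner_up)
  if (x$metastable_defectless_cap)
    cat("(a defectless cap is locally stable but not global)\n")
  invisible(x)
}

#' Phase grid over scaled line tension and chemical potential
#'
#' Applies [classify_point()] to every cell of a `lam x dmu` grid at fixed
#' Foppl-von Karman number.
#'
#' @param lam_axis strictly increasing vector of scaled line tensions.
#' @param dmu_axis strictly increasing vector of scaled chemical potentials.
#' @param gamma Foppl-von Karman number.
#' @param progress print a dot per `lam` column.
#' @return An object of class `phase_grid`: axes, `gamma`, a character
#'   matrix `labels` (`|lam_axis| x |dmu_axis|`), and matrices `dg`,
#'   `x_opt`, `r_opt`, `n_def` of the winners.
#' @seealso [default_grid_axes()] for the reproduction-run axes.
#' @export
compute_grid <- function(lam_axis, dmu_axis, gamma = 0, progress = FALSE) {
  if (length(lam_axis) < 1L || length(dmu_axis) < 1L)
    stop("grid axes must be non-empty")
  if (length(lam_axis) > 1L && is.unsorted(lam_axis, strictly = TRUE))
    stop("'lam_axis' must be strictly increasing")
  if (length(dmu_axis) > 1L && is.unsorted(dmu_axis, strictly = TRUE))
    stop("'dmu_axis' must be strictly increasing")
  nl <- length(lam_axis); nd <- length(dmu_axis)
  labels <- matrix(NA_character_, nl, nd)
  dg <- xo <- ro <- matrix(NA_real_, nl, nd)
  ndm <- matrix(NA_integer_, nl, nd)
  for (i in seq_len(nl)) {
    for (j in seq_len(nd)) {
      pt <- classify_point(scaled_parameters(lam_axis[i], dmu_axis[j], gamma))
      w <- pt$winner
      labels[i, j] <- w$structure
      dg[i, j] <- w$dg
      xo[i, j] <- if (is.null(w$size)) NA_real_ else w$size$x
      ro[i, j] <- if (is.null(w$size)) NA_real_ else w$size$r
      ndm[i, j] <- if (is.null(w$size)) 0L else w$size$n_def
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  structure(list(lam_axis = lam_axis, dmu_axis = dmu_axis, gamma = gamma,
                 labels = labels, dg = dg, x_opt = xo, r_opt = ro,
                 n_def = ndm),
            class = "phase_grid")
}

#' Default axes for phase-diagram reproduction runs
#'
#' Log-spaced axes covering the parameter ranges of real capsids and of the
#' coarse-grained simulations: \eqn{\lambda \in [10^{-5}, 2\times10^{-3}]},
#' \eqn{\tilde{\Delta\mu} \in [10^{-4}, 10^{-2}]}.
#'
#' @param n_lam,n_dmu number of grid points per axis.
#' @return List with `lam` and `dmu` vectors.
#' @export
default_grid_axes <- function(n_lam = 60L, n_dmu = 60L) {
  list(lam = exp(seq(log(1e-5), log(2e-3), length.out = n_lam)),
       dmu = exp(seq(log(1e-4), log(1e-2), length.out = n_dmu)))
}

#' @export
print.phase_grid <- function(x, ...) {
  cat(sprintf("phase grid: %d x %d cells, gamma = %g\n",
              length(x$lam_axis), length(x$dmu_axis), x$gamma))
  print(table(factor(x$labels, levels = structure_levels())))
  invisible(x)
}

#' @export
as.data.frame.phase_grid <- function(x, ...) {
  g <- expand.grid(lam = x$lam_axis, dmu = x$dmu_axis,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(lam = g$lam, dmu = g$dmu, gamma = x$gamma,
             winner = as.vector(x$labels), dg_winner = as.vector(x$dg),
             x_opt = as.vector(x$x_opt), r_opt = as.vector(x$r_opt),
             n_def = as.vector(x$n_def))
}

# minimised dg of a named classification target at (lam, dmu, gamma)
.min_dg_named <- function(structure, lam, dmu, gamma) {
  m <- switch(structure,
              shell_n_defects = .min_shell_over_n(lam, dmu, gamma),
              cap_one_defect = .min_structure_fast("cap_one_defect", lam, dmu, gamma),
              .min_structure_fast(structure, lam, dmu, gamma))
  if (is.null(m)) Inf else m$dg
}

# indices of assembled wells in a free-energy profile: interior local
# minima beyond the left edge, plus the closure boundary when the profile
# decreases into it.  The x -> 0 limit (the disassembled branch) is never a
# well.
.well_candidates <- function(g) {
  n <- length(g)
  idx <- which(g[2:(n - 1)] <= g[1:(n - 2)] & g[2:(n - 1)] <= g[3:n]) + 1L
  if (g[n] < g[n - 1]) idx <- c(idx, n)
  idx
}

# minimum over the assembled wells of one structure (Inf when no well
# exists); used for phase-coexistence tracing, where the trivial x -> 0
# branch must not stand in for an assembled phase.
.well_min_structure <- function(structure, lam, dmu, gamma, n_def = 0L,
                                tab = NULL) {
  if (gamma == 0) {
    xs <- .xgrid(2)
    g <- .dg_fast(structure, xs, 1, lam, dmu, 0, n_def, tab)
    idx <- .well_candidates(g)
    if (length(idx) == 0L) return(Inf)
    best <- Inf
    for (i in idx) {
      lo <- xs[max(i - 1L, 1L)]; hi <- xs[min(i + 1L, length(xs))]
      v <- stats::optimize(function(xx)
        .dg_fast(structure, xx, 1, lam, dmu, 0, n_def, tab),
        lower = lo, upper = hi, tol = 1e-10)$objective
      best <- min(best, v, g[i])
    }
    return(best)
  }
  xs <- .xgrid(2 * .R_MAX, n = 100L)
  rs <- .rgrid()
  ropt <- function(xx) {
    lo <- max(.R_MIN, xx / 2)
    stats::optimize(function(rr)
      .dg_fast(structure, xx, rr, lam, dmu, gamma, n_def, tab),
      lower = lo, upper = .R_MAX, tol = 1e-9)
  }
  g <- vapply(xs, function(xx) {
    rr <- rs[rs >= xx / 2]
    if (xx / 2 >= .R_MIN && xx / 2 <= .R_MAX) rr <- c(xx / 2, rr)
    if (length(rr) == 0L) return(Inf)
    min(.dg_fast(structure, xx, rr, lam, dmu, gamma, n_def, tab))
  }, numeric(1))
  idx <- .well_candidates(g)
  if (length(idx) == 0L) return(Inf)
  best <- Inf
  for (i in idx) {
    lo <- xs[max(i - 1L, 1L)]; hi <- xs[min(i + 1L, length(xs))]
    v <- stats::optimize(function(xx) ropt(xx)$objective,
                         lower = lo, upper = hi, tol = 1e-9)$objective
    best <- min(best, v, g[i])
  }
  best
}

# well-based minimum of a named coexistence target
.well_min_named <- function(structure, lam, dmu, gamma) {
  if (structure == "shell_n_defects") {
    tabs <- .all_defect_layouts()
    return(min(vapply(seq_along(tabs), function(k)
      .well_min_structure("shell_n_defects", lam, dmu, gamma,
                          n_def = k + 1L, tab = tabs[[k]]),
      numeric(1))))
  }
  if (structure == "cylinder") {
    if (gamma == 0) return(Inf)
    if (dmu > 1 / (2 * gamma)) return(-Inf)
    return(Inf)   # no assembled well below the unbounded-growth threshold
  }
  .well_min_structure(structure, lam, dmu, gamma)
}

#' Trace a phase boundary in the scaled chemical potential
#'
#' Bisection on \eqn{\tilde{\Delta\mu}} for equality of the size-minimised
#' free energies of two structures at fixed `lam` and `gamma`.  Only
#' crossings at which both phases are genuinely assembled (negative minima)
#' qualify as a phase boundary; crossings in the disassembled region are
#' ignored.  For the belt / multi-defect-shell pair at `gamma = 0` the
#' coexistence value is approximately independent of `lam` and close to
#' 0.0020.
#'
#' @param structure_a,structure_b two of [structure_levels()]
#'   (`shell_n_defects` is minimised over 2-12 defects).
#' @param gamma Foppl-von Karman number.
#' @param lam scaled line tension.
#' @param interval search interval in `dmu`.
#' @param tol bisection tolerance.
#' @return Coexistence value of `dmu`.
#' @examples
#' \donttest{
#' trace_boundary("belt", "shell_n_defects", gamma = 0, lam = 1e-4)
#' }
#' @export
trace_boundary <- function(structure_a, structure_b, gamma, lam,
                           interval = c(2e-4, 1e-2), tol = 1e-7) {
  if ("cylinder" %in% c(structure_a, structure_b)) {
    # the cylinder becomes competitive exactly at its unbounded-growth
    # threshold: the onset boundary is analytic
    if (gamma <= 0)
      stop(structure(class = c("capshell_boundary_absent", "error", "condition"),
                     list(message = "cylinders are excluded at gamma = 0",
                          call = sys.call(-1))))
    return(1 / (2 * gamma))
  }
  pair <- function(dmu) c(.well_min_named(structure_a, lam, dmu, gamma),
                          .well_min_named(structure_b, lam, dmu, gamma))
  f <- function(dmu) { v <- pair(dmu); v[1] - v[2] }
  ds <- exp(seq(log(interval[1]), log(interval[2]), length.out = 31L))
  vs <- vapply(ds, pair, numeric(2))
  fs <- vs[1, ] - vs[2, ]
  ok <- is.finite(fs)
  assembled <- vs[1, ] < -1e-9 & vs[2, ] < -1e-9
  cross <- diff(sign(fs)) != 0 & ok[-length(fs)] & ok[-1]
  k <- which(cross & assembled[-length(fs)] & assembled[-1])
  if (length(k) == 0L) k <- which(cross)
  if (length(k) == 0L)
    stop(structure(class = c("capshell_boundary_absent", "error", "condition"),
                   list(message = sprintf(
                     "no %s/%s coexistence between dmu = %g and %g at gamma = %g, lam = %g",
                     structure_a, structure_b, interval[1], interval[2],
                     gamma, lam),
                     call = sys.call(-1))))
  k <- k[length(k)]
  stats::uniroot(f, c(ds[k], ds[k + 1L]), tol = tol)$root
}

#' Critical FvK number for the disappearance of spherical shells
#'
#' A cylinder grows without bound once
#' \eqn{\tilde{\Delta\mu} > 1/(2\gamma)}, while multi-defect spherical
#' shells only beat the belt above the belt/shell frontier
#' \eqn{\tilde{\Delta\mu}_{bs} \approx 0.0020}, which is independent of the
#' line tension in the bending-dominated regime.  The window in which a
#' defective sphere can be the global minimum closes at the Foppl-von
#' Karman number where the cylinder threshold falls to that frontier,
#' \deqn{\gamma_c = \frac{1}{2\,\tilde{\Delta\mu}_{bs}} \approx 250;}
#' above it only cylinders, belts and the disassembled state remain.  The
#' frontier is traced at a small reference line tension.  This is the
#' self-consistency estimate of the theory; in the full classification,
#' where belts and shells also relax their radius away from the spontaneous
#' one, the last multi-defect cells disappear from the grid somewhat
#' earlier (around \eqn{\gamma \approx 200}), so the estimate is an upper
#' bound on the grid observation.
#'
#' @param lam reference scaled line tension.
#' @return The critical Foppl-von Karman number (about 250).
#' @examples
#' \donttest{
#' critical_gamma_no_spheres()
#' }
#' @export
critical_gamma_no_spheres <- function(lam = 1e-4) {
  fb <- trace_boundary("belt", "shell_n_defects", gamma = 0, lam = lam)
  1 / (2 * fb)
}
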