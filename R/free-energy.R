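## Closed-form scaled free energies of formation.
##
## All energies are in units of the characteristic elastic energy
## 4 pi R0^2 Y, sizes in units of R0 (x = rho0/R0 is the radius of the
## equal-area flat disk of the patch, r = R/R0 the shell radius).  In the
## bending-dominated limit (gamma = 0) every structure adopts the
## spontaneous curvature and r is pinned to 1.

.check_x <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x))) stop("'x' must be finite numeric")
  if (any(x < 0)) stop("scaled patch size 'x' must be >= 0")
  x
}

#' Free energy of a defectless spherical cap (bending-dominated)
#'
#' \deqn{\Delta g = -\frac{\tilde{\Delta\mu}}{4} x^2 + \frac{\lambda}{2} x
#'   + \frac{x^6}{1536}}
#' The three terms are the bulk chemical-potential gain of assembled
#' subunits, the line energy of the open rim, and the in-plane stretching of
#' a hexagonal crystal forced onto a sphere of its spontaneous radius.  The
#' Foppl-von Karman number plays no role in this limit.
#'
#' @param x scaled patch size (vectorised), `x >= 0`; the sphere closes at
#'   `x = 2`.
#' @param p a [scaled_parameters()] object.
#' @return Scaled free energy of formation (vector like `x`).
#' @examples
#' p <- scaled_parameters(1e-4, 1e-3)
#' dg_cap_bending(c(0, 0.1, 1), p)
#' @export
dg_cap_bending <- function(x, p) {
  p <- as_scaled_parameters(p); .check_x(x)
  -p$dmu / 4 * x^2 + p$lam / 2 * x + x^6 / 1536
}

#' Free energy of a spherical cap with one central disclination
#' (bending-dominated)
#'
#' Adds to [dg_cap_bending()] the stretching energy of a single pentagonal
#' disclination held at the cap centre,
#' \eqn{(x^2/1152)(1 - \tfrac32 x^2)}.  The added term changes sign at
#' \eqn{x = \sqrt{2/3}}: only caps larger than that are relieved by the
#' defect.
#'
#' @inheritParams dg_cap_bending
#' @return Scaled free energy of formation.
#' @export
dg_cap_one_defect_bending <- function(x, p) {
  p <- as_scaled_parameters(p); .check_x(x)
  dg_cap_bending(x, p) + x^2 / 1152 * (1 - 1.5 * x^2)
}

#' Threshold patch size for disclination onset
#'
#' The cap size (relative to the shell radius) beyond which a central 5-fold
#' disclination lowers the elastic energy: \eqn{x/r = \sqrt{2/3}}.
#' @return `sqrt(2/3)`.
#' @export
defect_onset_x <- function() sqrt(2 / 3)

#' Free energy of a spherical shell with n disclinations
#'
#' Base cap energy plus the disclination self-energies `gs1` (screened by
#' the free rim and coupled to the background Gaussian curvature) and the
#' pairwise disclination repulsion `gs2`; see [disclination_energies()].
#' With `n_def = 1` (central placement) this reduces exactly to
#' [dg_cap_one_defect_bending()] at `r = 1`.
#'
#' @inheritParams dg_cap_bending
#' @param n_def number of 5-fold disclinations, 1-12.
#' @param r scaled shell radius; must be 1 when `gamma = 0`.
#' @return Scaled free energy of formation.
#' @examples
#' p <- scaled_parameters(1e-4, 1e-3)
#' dg_shell_n_defects(2, 12, p)   # closed icosahedral shell
#' @export
dg_shell_n_defects <- function(x, n_def, p, r = 1) {
  p <- as_scaled_parameters(p); .check_x(x)
  if (any(x <= 0)) stop("a shell with defects requires x > 0")
  if (any(x > 2 * r + 1e-9)) stop("spherical shells require x <= 2 r")
  gs <- disclination_energies(x, n_def, r)
  dg_cap_general(x, p, r) + gs$gs1 + gs$gs2
}

#' Free energy of an open ribbon (bending-dominated)
#'
#' A rectangular crystalline stripe of scaled width `w` and length
#' \eqn{l = \pi x^2 / w} growing on the spontaneous sphere:
#' \deqn{\Delta g = -\frac{\tilde{\Delta\mu}}{4}x^2
#'   + \frac{\lambda}{2}\frac{x^2}{w} + \frac{\lambda}{2\pi} w
#'   + \frac{9}{20480} x^2 w^4.}
#' The two middle terms are the edge energy \eqn{(\lambda/2\pi)(l + w)} of
#' the rectangle.  Once the length reaches \eqn{l = 2\pi} the ribbon closes
#' onto itself and the belt ([dg_belt()]) applies; calling this function
#' beyond that point raises an error of class `capshell_belt_regime`.
#'
#' @inheritParams dg_cap_bending
#' @param w scaled ribbon width, `w > 0`.
#' @return Scaled free energy of formation.
#' @export
dg_ribbon_bending <- function(x, w, p) {
  p <- as_scaled_parameters(p); .check_x(x)
  if (any(w <= 0)) stop("ribbon width 'w' must be > 0")
  l <- pi * x^2 / w
  if (any(l > 2 * pi + 1e-12)) {
    stop(structure(class = c("capshell_belt_regime", "error", "condition"),
                   list(message = "ribbon length l = pi x^2 / w exceeds 2 pi: the closed belt applies",
                        call = sys.call(-1))))
  }
  -p$dmu / 4 * x^2 + p$lam / 2 * x^2 / w + p$lam / (2 * pi) * w +
    9 / 20480 * x^2 * w^4
}

#' Free energy of a closed belt
#'
#' A ribbon closed around a great circle of the sphere (length
#' \eqn{l = 2\pi r}, width \eqn{w = x^2/(2r)}):
#' \deqn{\Delta g = -\frac{\tilde{\Delta\mu}}{4}x^2 + \lambda r
#'   + \frac{9}{327680}\frac{x^{10}}{r^8}
#'   + \frac{1}{4\gamma} x^2 \left(\frac1r - 1\right)^2,}
#' the last (bending) term only for `gamma > 0`; in the bending-dominated
#' mode `r` is pinned to 1 and the term is absent.
#'
#' @inheritParams dg_cap_bending
#' @param r scaled belt radius; must be 1 when `gamma = 0`.
#' @return Scaled free energy of formation.
#' @export
dg_belt <- function(x, p, r = 1) {
  p <- as_scaled_parameters(p); .check_x(x)
  if (any(r <= 0)) stop("'r' must be > 0")
  base <- -p$dmu / 4 * x^2 + p$lam * r + 9 / 327680 * x^10 / r^8
  if (p$gamma == 0) {
    if (any(abs(r - 1) > 1e-12))
      stop("in the bending-dominated limit (gamma = 0) the belt radius is pinned to r = 1")
    return(base + 0 * x)
  }
  base + 1 / (4 * p$gamma) * x^2 * (1 / r - 1)^2
}

#' Free energy of a cylinder
#'
#' A cylindrical shell has no in-plane stretching cost (a flat hexagonal
#' sheet bends into a cylinder without stretching) but pays bending energy:
#' \deqn{\Delta g = -\frac{\tilde{\Delta\mu}}{4}x^2 + \lambda r
#'   + \frac{1}{8\gamma} x^2\left(1 + \left(\frac1r-1\right)^2\right).}
#' At its optimal radius `r = 1` the energy per area is negative as soon as
#' \eqn{\tilde{\Delta\mu} > 1/(2\gamma)}, beyond which the cylinder grows
#' without bound.  In the bending-dominated limit (`gamma = 0`) the bending
#' penalty diverges and the cylinder is excluded; an error of class
#' `capshell_bending_excluded` is raised.
#'
#' @inheritParams dg_belt
#' @return Scaled free energy of formation.
#' @export
dg_cylinder <- function(x, p, r = 1) {
  p <- as_scaled_parameters(p); .check_x(x)
  if (any(r <= 0)) stop("'r' must be > 0")
  if (p$gamma == 0) {
    stop(structure(class = c("capshell_bending_excluded", "error", "condition"),
                   list(message = "cylinders are prevented in the bending-dominated limit (gamma = 0)",
                        call = sys.call(-1))))
  }
  -p$dmu / 4 * x^2 + p$lam * r +
    1 / (8 * p$gamma) * x^2 * (1 + (1 / r - 1)^2)
}

#' Free energy of a defectless spherical cap at arbitrary FvK number
#'
#' Generalises [dg_cap_bending()] to a cap of radius `r` away from the
#' spontaneous curvature:
#' \deqn{\Delta g = -\frac{\tilde{\Delta\mu}}{4}x^2 + \frac{\lambda}{2}x
#'   + \frac{x^6}{1536\,r^4}
#'   + \frac{1}{4\gamma} x^2 \left(\frac1r - 1\right)^2.}
#' The last term is the spontaneous-curvature (generalised Helfrich) bending
#' energy \eqn{(\kappa/2)(2/R - 2/R_0)^2} integrated over the patch area and
#' scaled by \eqn{4\pi R_0^2 Y}.
#'
#' @inheritParams dg_belt
#' @return Scaled free energy of formation.
#' @export
dg_cap_general <- function(x, p, r = 1) {
  p <- as_scaled_parameters(p); .check_x(x)
  if (any(r <= 0)) stop("'r' must be > 0")
  base <- -p$dmu / 4 * x^2 + p$lam / 2 * x + x^6 / (1536 * r^4)
  if (p$gamma == 0) {
    if (any(abs(r - 1) > 1e-12))
      stop("in the bending-dominated limit (gamma = 0) the cap radius is pinned to r = 1")
    return(base + 0 * x)
  }
  base + 1 / (4 * p$gamma) * x^2 * (1 / r - 1)^2
}

#' Free energy of a cap with one central disclination at arbitrary FvK
#'
#' [dg_cap_general()] plus the central-disclination term
#' \eqn{(x^2/1152)(1 - \tfrac32 x^2/r^2)}, favourable once
#' \eqn{x/r \ge \sqrt{2/3}}.
#'
#' @inheritParams dg_cap_general
#' @return Scaled free energy of formation.
#' @export
dg_cap_one_defect_general <- function(x, p, r = 1) {
  dg_cap_general(x, p, r) + x^2 / 1152 * (1 - 1.5 * x^2 / r^2)
}

#' Optimal radius of a defectless spherical cap
#'
#' The stationarity condition of the cap free energy with respect to the
#' shell radius is the cubic \eqn{r^2(r-1) = \gamma x^4/192}, whose left
#' side is strictly increasing for \eqn{r \ge 1}; the unique root
#' \eqn{r \ge 1} is located by bracketed root finding (Brent, tolerance
#' 1e-12).  `r = 1` exactly when \eqn{\gamma x^4 = 0}.
#'
#' @param x scaled patch size (vectorised), `x >= 0`.
#' @param gamma Foppl-von Karman number, `>= 0`.
#' @return Optimal scaled radius `r` (vector like `x`).
#' @examples
#' optimal_cap_radius(1, 192)   # root of r^3 - r^2 - 1 = 0, ~1.46557
#' @export
optimal_cap_radius <- function(x, gamma) {
  .check_x(x)
  if (length(gamma) != 1L || gamma < 0) stop("'gamma' must be a single number >= 0")
  q <- gamma * x^4 / 192
  vapply(q, function(qi) {
    if (qi == 0) return(1)
    hi <- 1 + qi^(1 / 3) + 1
    stats::uniroot(function(r) r^2 * (r - 1) - qi, c(1, hi),
                   tol = 1e-12)$root
  }, numeric(1))
}

#' Classical-nucleation estimate of the assembly barrier
#'
#' Neglecting the elastic terms, the small spherical cap that seeds every
#' structure has its free-energy maximum at
#' \eqn{x^* = \lambda/\tilde{\Delta\mu}} with barrier height
#' \eqn{\Delta g^* = \lambda^2/(4\tilde{\Delta\mu})}.  Valid where the
#' elastic energy at \eqn{x^*} is negligible (small critical sizes).
#'
#' @param p a [scaled_parameters()] object with `dmu > 0`.
#' @return An object of class `nucleation_estimate`: list with `x_star` and
#'   `dg_star`.
#' @examples
#' nucleation_estimate(scaled_parameters(1e-4, 1e-3))
#' @export
nucleation_estimate <- function(p) {
  p <- as_scaled_parameters(p)
  if (p$dmu <= 0)
    stop("no nucleation barrier: assembly is not favoured for dmu <= 0")
  structure(list(x_star = p$lam / p$dmu,
                 dg_star = p$lam^2 / (4 * p$dmu)),
            class = "nucleation_estimate")
}

#' @export
print.nucleation_estimate <- function(x, ...) {
  cat(sprintf("nucleation estimate: x* = %.6g, dg* = %.6g\n",
              x$x_star, x$dg_star))
  invisible(x)
}
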