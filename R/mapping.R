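## Mappings between coarse-grained interaction parameters, dimensional
## elastic constants and the scaled theory parameters, plus the estimator
## of scaled parameters from experimental capsid mechanics.

#' Boltzmann constant times temperature used for dimensional estimates
#'
#' `4.11e-21` J, corresponding to about 298 K.  Used wherever binding
#' energies quoted in multiples of kBT are converted to Joules.
#' @export
kbt_joule <- function() 4.11e-21

#' Coarse-grained capsomer interaction parameters
#'
#' Parameters of the pair potential \eqn{V = V_{Mie} V_a V_{tor}}: a
#' Mie-like distance term with repulsive/attractive exponents `m > n`, a
#' Gaussian angular term of preferred angle `nu` and width `alpha`, and a
#' torsion term of strength `kt`.
#'
#' @param m repulsive exponent (integer, `m > n`).
#' @param n attractive exponent (integer, `> 0`).
#' @param nu preferred interaction angle in radians.  The geometry only
#'   depends on `|cos(nu)|`; `cos(nu) = 0` (a flat sheet) is rejected where
#'   a finite spontaneous radius is required.
#' @param alpha angular width (radians), controls the local bending
#'   stiffness.
#' @param kt torsion constant (dimensionless).
#' @param eps0 binding energy in multiples of kBT.
#' @param sigma capsomer diameter (m).
#' @param conc free-capsomer concentration `c1` (arbitrary units, used only
#'   through the ratio `conc / c_star`).
#' @param c_star critical concentration (same units as `conc`).
#' @return An object of class `potential_parameters`.
#' @examples
#' potential_parameters(m = 36, n = 18, nu = 1.45, alpha = 0.1)
#' @export
potential_parameters <- function(m, n, nu, alpha, kt = 1.5, eps0 = 10,
                                 sigma = 1, conc = NA_real_,
                                 c_star = NA_real_) {
  if (m <= n || n <= 0) stop("exponents must satisfy m > n > 0")
  if (alpha <= 0) stop("'alpha' must be > 0")
  if (eps0 <= 0) stop("'eps0' must be > 0")
  if (sigma <= 0) stop("'sigma' must be > 0")
  structure(list(m = m, n = n, nu = nu, alpha = alpha, kt = kt,
                 eps0 = eps0, sigma = sigma, conc = conc, c_star = c_star),
            class = "potential_parameters")
}

#' @export
print.potential_parameters <- function(x, ...) {
  cat(sprintf(
    "capsomer potential: m = %g, n = %g, nu = %g rad, alpha = %g, kt = %g, eps0 = %g kBT\n",
    x$m, x$n, x$nu, x$alpha, x$kt, x$eps0))
  invisible(x)
}

#' Elastic constants of the shell from the capsomer potential
#'
#' \deqn{Y = \frac{2nm}{\sqrt3}\frac{\epsilon_0}{\sigma^2},\quad
#'   \kappa = \frac{3\sqrt3}{8}\frac{\epsilon_0}{\alpha^2},\quad
#'   R_0 = \frac{\sigma}{2|\cos\nu|},\quad
#'   \Lambda = \frac{2\epsilon_0}{\sqrt3\,\sigma},\quad
#'   \Delta\mu = k_BT \ln(c_1/c^*),}
#' with the area per subunit \eqn{a_1 = \pi\sigma^2/4} (the projected disk
#' of one capsomer, the convention forced by the scaled chemical-potential
#' identity).  Energies are reported in Joules using `eps0` kBT units and
#' [kbt_joule()].
#'
#' @param pp a [potential_parameters()] object.
#' @return An object of class `elastic_constants`: list with `Y` (N/m),
#'   `kappa` (J), `R0` (m), `Lambda` (N), `a1` (m^2), `dmu_dim` (J, `NA`
#'   when no concentration ratio is supplied).
#' @examples
#' potential_to_elastic(potential_parameters(36, 18, 1.45, 0.1, sigma = 1e-8))
#' @export
potential_to_elastic <- function(pp) {
  stopifnot(inherits(pp, "potential_parameters"))
  if (abs(cos(pp$nu)) < 1e-12)
    stop("cos(nu) = 0: no spontaneous curvature (flat sheet), R0 diverges")
  eps <- pp$eps0 * kbt_joule()
  Y <- 2 * pp$n * pp$m * eps / (sqrt(3) * pp$sigma^2)
  kappa <- 3 * sqrt(3) / 8 * eps / pp$alpha^2
  R0 <- pp$sigma / (2 * abs(cos(pp$nu)))
  Lambda <- 2 * eps / (sqrt(3) * pp$sigma)
  dmu <- if (is.finite(pp$conc) && is.finite(pp$c_star))
    kbt_joule() * log(pp$conc / pp$c_star) else NA_real_
  structure(list(Y = Y, kappa = kappa, R0 = R0, Lambda = Lambda,
                 a1 = pi * pp$sigma^2 / 4, dmu_dim = dmu),
            class = "elastic_constants")
}

#' @export
print.elastic_constants <- function(x, ...) {
  cat(sprintf(
    "elastic constants: Y = %.4g N/m, kappa = %.4g J, R0 = %.4g m, Lambda = %.4g N, a1 = %.4g m^2\n",
    x$Y, x$kappa, x$R0, x$Lambda, x$a1))
  if (is.finite(x$dmu_dim)) cat(sprintf("  dmu = %.4g J\n", x$dmu_dim))
  invisible(x)
}

#' Scaled theory parameters from the capsomer potential
#'
#' The closed forms
#' \deqn{\gamma = \frac{4nm\alpha^2}{9\cos^2\nu},\qquad
#'   \lambda = \frac{2|\cos\nu|}{nm},\qquad
#'   \tilde{\Delta\mu} = \frac{2\sqrt3}{\pi nm}\frac{\Delta\mu}{\epsilon_0},}
#' with \eqn{\Delta\mu/\epsilon_0 = T_{red}\ln(c_1/c^*)} at reduced
#' temperature \eqn{T_{red} = k_BT/\epsilon_0}.  These are algebraically
#' identical to assembling \eqn{\gamma = YR_0^2/\kappa},
#' \eqn{\lambda = \Lambda/(YR_0)}, \eqn{\tilde{\Delta\mu} = \Delta\mu/(Ya_1)}
#' from [potential_to_elastic()].
#'
#' @param pp a [potential_parameters()] object.
#' @return A [scaled_parameters()] object (`dmu = 0` when no concentration
#'   ratio is supplied).
#' @examples
#' potential_to_scaled(potential_parameters(36, 18, 1.45, 0.1))$lam  # 0.000372
#' @export
potential_to_scaled <- function(pp) {
  stopifnot(inherits(pp, "potential_parameters"))
  if (abs(cos(pp$nu)) < 1e-12)
    stop("cos(nu) = 0: no spontaneous curvature (flat sheet)")
  gamma <- 4 * pp$n * pp$m * pp$alpha^2 / (9 * cos(pp$nu)^2)
  lam <- 2 * abs(cos(pp$nu)) / (pp$n * pp$m)
  dmu <- if (is.finite(pp$conc) && is.finite(pp$c_star)) {
    2 * sqrt(3) / (pi * pp$n * pp$m) * log(pp$conc / pp$c_star) / pp$eps0
  } else 0
  scaled_parameters(lam = lam, dmu = dmu, gamma = gamma)
}

#' Effective capsomer diameter of a T-number shell
#'
#' A shell of radius `R` and triangulation number `T` holds
#' \eqn{10T + 2} capsomers; equating areas gives
#' \deqn{\sigma = \frac{R}{\sqrt{2\left(T + \cot(\pi/5)/\sqrt3 - 1\right)}}.}
#' Reproduces the tabulated diameters of CCMV (5.9 nm), the lambda
#' procapsid (6.8 nm), the lambda capsid (8.6 nm) and SV40 (6.1 nm).
#'
#' @param R shell outer radius.
#' @param T_number Caspar-Klug triangulation number.
#' @return Capsomer diameter in the units of `R`.
#' @export
capsomer_diameter <- function(R, T_number) {
  .check_T(T_number)
  R / sqrt(2 * (T_number + 1 / tan(pi / 5) / sqrt(3) - 1))
}

.check_T <- function(T_number) {
  # Caspar-Klug: T = h^2 + hk + k^2 for non-negative integers h, k
  ok <- FALSE
  for (h in 0:20) for (k in 0:20)
    if (h + k > 0 && h * h + h * k + k * k == T_number) ok <- TRUE
  if (!ok) stop("'T_number' is not a valid triangulation number")
  invisible(T_number)
}

#' Capsid descriptor from experimental mechanics
#'
#' Geometric and elastic descriptors of a capsid as measured by cryo-EM and
#' AFM nanoindentation.
#'
#' @param T_number triangulation number.
#' @param diameter outer diameter (nm).
#' @param h shell thickness (nm).
#' @param E 3-D Young's modulus (GPa).
#' @param nu_p 3-D Poisson ratio (default 0.3).
#' @param eps0_kT binding energy per capsomer contact in kBT (default 10).
#' @param name optional label.
#' @return An object of class `capsid_descriptor`.
#' @export
capsid_descriptor <- function(T_number, diameter, h, E, nu_p = 0.3,
                              eps0_kT = 10, name = NA_character_) {
  .check_T(T_number)
  if (diameter <= 0 || h <= 0 || E <= 0) stop("lengths and moduli must be positive")
  structure(list(T_number = T_number, diameter = diameter, h = h, E = E,
                 nu_p = nu_p, eps0_kT = eps0_kT, name = name),
            class = "capsid_descriptor")
}

#' Scaled assembly parameters of a real capsid
#'
#' From the descriptor: 2-D Young's modulus \eqn{Y = Eh}; capsomer diameter
#' \eqn{\sigma(R, T)} from [capsomer_diameter()]; line tension
#' \eqn{\Lambda = 2\epsilon_0/(\sqrt3 \sigma)} with
#' \eqn{\epsilon_0 = } `eps0_kT` kBT; scaled line tension
#' \eqn{\lambda = \Lambda/(YR)} with the outer radius standing in for the
#' spontaneous radius; Foppl-von Karman number
#' \eqn{\gamma = 12(1-\nu_p^2)(R/h)^2}.
#'
#' @param cd a [capsid_descriptor()] object.
#' @return A one-row `data.frame` with columns `name`, `T_number`,
#'   `diameter_nm`, `h_nm`, `E_gpa`, `Y_nm` (N/m), `sigma_nm`, `lam`,
#'   `gamma`.
#' @examples
#' capsid_estimate(capsid_descriptor(3, 28, 3.8, 0.14, name = "CCMV"))
#' @export
capsid_estimate <- function(cd) {
  stopifnot(inherits(cd, "capsid_descriptor"))
  R_nm <- cd$diameter / 2
  Y <- cd$E * 1e9 * cd$h * 1e-9                    # N/m
  sigma_nm <- capsomer_diameter(R_nm, cd$T_number)
  Lambda <- 2 * cd$eps0_kT * kbt_joule() / (sqrt(3) * sigma_nm * 1e-9)
  lam <- Lambda / (Y * R_nm * 1e-9)
  gamma <- 12 * (1 - cd$nu_p^2) * (R_nm / cd$h)^2
  data.frame(name = cd$name, T_number = cd$T_number,
             diameter_nm = cd$diameter, h_nm = cd$h, E_gpa = cd$E,
             Y_nm = Y, sigma_nm = sigma_nm, lam = lam, gamma = gamma)
}

#' Young's modulus from an AFM spring constant
#'
#' Thin-shell formula \eqn{k = 2.25\,E h^2/R}, inverted to
#' \eqn{E = kR/(2.25 h^2)}.  Units must be consistent (e.g. k in N/m, h and
#' R in m give E in Pa).
#'
#' @param k_spring measured spring constant.
#' @param h shell thickness.
#' @param R shell radius.
#' @return Young's modulus `E`.
#' @export
spring_constant_to_E <- function(k_spring, h, R) {
  if (any(c(k_spring, h, R) <= 0)) stop("all inputs must be positive")
  k_spring * R / (2.25 * h^2)
}

#' Reference capsid table
#'
#' Descriptors of the four reference capsids (CCMV, bacteriophage lambda
#' procapsid and mature capsid, SV40) with mechanics from AFM
#' nanoindentation, ready for [capsid_estimate()].
#'
#' @return A list of [capsid_descriptor()] objects.
#' @export
reference_capsids <- function() {
  list(
    CCMV          = capsid_descriptor(3, 28, 3.8, 0.14, name = "CCMV"),
    lambda_procapsid = capsid_descriptor(7, 50, 4.0, 0.16, name = "lambda procapsid"),
    lambda_capsid = capsid_descriptor(7, 63, 1.8, 1.0, name = "lambda capsid"),
    SV40          = capsid_descriptor(7, 45, 6.0, 0.033, name = "SV40"))
}
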