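#' Scaled control parameters of shell assembly
#'
#' The fate of the assembly of a curved elastic shell is fully determined by
#' three dimensionless numbers: the scaled line tension
#' \eqn{\lambda = \Lambda/(R_0 Y)}, the scaled chemical potential
#' \eqn{\tilde{\Delta\mu} = \Delta\mu/(Y a_1)} and the Foppl-von Karman
#' number \eqn{\gamma = Y R_0^2/\kappa}.  All free energies in this package
#' are expressed in units of the characteristic elastic energy
#' \eqn{4 \pi R_0^2 Y} and all lengths in units of the spontaneous curvature
#' radius \eqn{R_0}.
#'
#' @param lam scaled line tension, non-negative.
#' @param dmu scaled chemical potential; may be negative (disassembly
#'   favoured).
#' @param gamma Foppl-von Karman number, non-negative.  `gamma = 0` selects
#'   the bending-dominated limit in which every structure adopts the
#'   spontaneous curvature (`r = 1`).
#'
#' @return An object of class `scaled_parameters`: a list with elements
#'   `lam`, `dmu`, `gamma`.
#' @examples
#' p <- scaled_parameters(lam = 1e-4, dmu = 1e-3, gamma = 0)
#' dg_cap_bending(0.5, p)
#' @export
scaled_parameters <- function(lam, dmu, gamma = 0) {
  stopifnot(is.numeric(lam), is.numeric(dmu), is.numeric(gamma),
            length(lam) == 1L, length(dmu) == 1L, length(gamma) == 1L)
  if (!is.finite(lam) || !is.finite(dmu) || !is.finite(gamma))
    stop("scaled parameters must be finite")
  if (lam < 0) stop("scaled line tension 'lam' must be >= 0")
  if (gamma < 0) stop("FvK number 'gamma' must be >= 0")
  structure(list(lam = lam, dmu = dmu, gamma = gamma),
            class = "scaled_parameters")
}

#' @export
print.scaled_parameters <- function(x, ...) {
  cat(sprintf(
    "Scaled assembly parameters: lambda = %g, dmu = %g, gamma = %g%s\n",
    x$lam, x$dmu, x$gamma,
    if (x$gamma == 0) " (bending-dominated)" else ""))
  invisible(x)
}

as_scaled_parameters <- function(p) {
  if (inherits(p, "scaled_parameters")) return(p)
  if (is.list(p) && all(c("lam", "dmu") %in% names(p)))
    return(scaled_parameters(p$lam, p$dmu, if (is.null(p$gamma)) 0 else p$gamma))
  stop("'p' must be a scaled_parameters object")
}

#' Size descriptor of a partial or closed shell
#'
#' @param x scaled patch size \eqn{x = \rho_0/R_0} (the radius of the
#'   equal-area flat disk), non-negative.  A spherical structure of radius
#'   `r` closes at `x = 2 r` (equal areas: \eqn{\pi x^2 = 4 \pi r^2}).
#' @param r scaled radius \eqn{r = R/R_0}, positive.
#' @param w scaled ribbon width (ribbon/belt only), or `NA`.
#' @param n_def number of 5-fold disclinations (0-12).
#' @return An object of class `shell_size`.
#' @export
shell_size <- function(x, r = 1, w = NA_real_, n_def = 0L) {
  if (x < 0) stop("'x' must be >= 0")
  if (r <= 0) stop("'r' must be > 0")
  if (!is.na(n_def) && (n_def < 0 || n_def > 12)) stop("'n_def' must be in 0..12")
  if (x > 2 * r + 1e-9 && is.na(w))
    stop("spherical structures close at x = 2r; x > 2r is not a valid size")
  structure(list(x = x, r = r, w = w, n_def = as.integer(n_def)),
            class = "shell_size")
}

#' @export
print.shell_size <- function(x, ...) {
  cat(sprintf("shell size: x = %.6g, r = %.6g%s%s\n", x$x, x$r,
              if (!is.na(x$w)) sprintf(", w = %.6g", x$w) else "",
              if (x$n_def > 0) sprintf(", %d disclination(s)", x$n_def) else ""))
  invisible(x)
}

#' Candidate structure labels
#'
#' Enumeration (in tie-breaking order) of the structures competing in the
#' phase diagram: defectless spherical cap, cap with one central
#' disclination, closed/partial shell with n disclinations, open ribbon,
#' closed belt, cylinder, and the disassembled state.
#' @export
structure_levels <- function() {
  c("cap_defectless", "cap_one_defect", "shell_n_defects",
    "ribbon", "belt", "cylinder", "disassembled")
}

#' Minimized free energy of one candidate structure
#'
#' @param structure one of [structure_levels()].
#' @param size a [shell_size()] at the minimum (or `NULL` for
#'   `disassembled`).
#' @param dg minimized scaled free energy of formation (units of
#'   \eqn{4\pi R_0^2 Y}).
#' @param unbounded logical; `TRUE` when the free energy decreases without
#'   limit with size (unbounded cylinder growth).
#' @return An object of class `structure_energy`.
#' @export
structure_energy <- function(structure, size = NULL, dg = 0, unbounded = FALSE) {
  structure <- match.arg(structure, structure_levels())
  if (!unbounded && !is.finite(dg)) stop("'dg' must be finite unless unbounded")
  structure(list(structure = structure, size = size, dg = dg,
                 unbounded = unbounded),
            class = "structure_energy")
}

#' @export
print.structure_energy <- function(x, ...) {
  cat(sprintf("%-16s dg = %s%s\n", x$structure,
              if (x$unbounded) "-Inf (unbounded growth)" else format(x$dg, digits = 8),
              if (!is.null(x$size))
                sprintf("  at x = %.4g, r = %.4g, n = %d",
                        x$size$x, x$size$r, x$size$n_def) else ""))
  invisible(x)
}
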