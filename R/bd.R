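## Brownian-dynamics simulator of coarse-grained capsomers.

#' Simulation state of a capsomer system
#'
#' @param positions N x 3 matrix of capsomer centres (units of sigma).
#' @param orientations N x 3 matrix of unit orientation vectors.
#' @param box cubic box edge length (0 = no periodic boundaries).
#' @param time_step reduced time increment.
#' @param rng_seed integer seed driving the thermal noise.
#' @param step_count number of BD steps already taken.
#' @return An object of class `simulation_state`.
#' @export
simulation_state <- function(positions, orientations, box = 0,
                             time_step = 5e-5, rng_seed = 1L,
                             step_count = 0L) {
  positions <- as.matrix(positions); orientations <- as.matrix(orientations)
  if (ncol(positions) != 3L || ncol(orientations) != 3L ||
      nrow(positions) != nrow(orientations))
    stop("positions and orientations must be N x 3 matrices of equal N")
  nrm <- sqrt(rowSums(orientations^2))
  if (any(abs(nrm - 1) > 1e-6))
    warning("orientation vectors renormalised to unit length")
  orientations <- orientations / nrm
  if (box > 0) positions <- positions - box * floor(positions / box)
  structure(list(positions = positions, orientations = orientations,
                 box = box, time_step = time_step,
                 rng_seed = as.integer(rng_seed),
                 step_count = as.integer(step_count)),
            class = "simulation_state")
}

#' @export
print.simulation_state <- function(x, ...) {
  cat(sprintf("simulation state: %d capsomers, box = %g, step %d\n",
              nrow(x$positions), x$box, x$step_count))
  invisible(x)
}

#' Configuration of an assembly simulation
#'
#' Defaults follow the reference protocol: torsion constant `kt = 1.5`,
#' reduced temperature `T_red = 0.1` (a binding energy of 10 kBT), a
#' 19-capsomer spherical-cap seed, Euler time step 5e-5, interaction cutoff
#' 2.5 sigma with energy shift.  The rotational diffusion constant defaults
#' to the stick-sphere ratio `Dr = 3 D / sigma^2`.
#'
#' @param pp a [potential_parameters()] object (m, n, nu, alpha, kt).
#' @param N_total total number of capsomers (`>= seed_size`).
#' @param density number density rho in sigma^-3; sets the box edge
#'   `L = (N_total/rho)^(1/3)`.
#' @param T_red reduced temperature kBT/eps0 (> 0; a zero-temperature
#'   relaxation mode is selected by [bd_step()]'s `relax` argument).
#' @param n_steps number of Euler steps for [run_assembly()].
#' @param seed_size number of capsomers in the initial cap.
#' @param dt reduced time step.
#' @param cutoff interaction cutoff radius (sigma).
#' @param Dr rotational diffusion coefficient (units D/sigma^2).
#' @param strict_product apply the angular/torsion modulation to the whole
#'   Mie term instead of the attractive branch only.
#' @param rng_seed integer seed.
#' @param thin trajectory snapshot interval in steps (0 = none).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(pp, N_total = 60L, density = 0.02,
                              T_red = 0.1, n_steps = 1e5L, seed_size = 19L,
                              dt = 5e-5, cutoff = 2.5, Dr = 3,
                              strict_product = FALSE, rng_seed = 1L,
                              thin = 0L) {
  stopifnot(inherits(pp, "potential_parameters"))
  if (N_total < seed_size) stop("'N_total' must be >= 'seed_size'")
  if (T_red <= 0) stop("'T_red' must be > 0")
  if (density <= 0) stop("'density' must be > 0")
  structure(list(pp = pp, N_total = as.integer(N_total), density = density,
                 T_red = T_red, n_steps = as.integer(n_steps),
                 seed_size = as.integer(seed_size), dt = dt,
                 cutoff = cutoff, Dr = Dr,
                 strict_product = isTRUE(strict_product),
                 rng_seed = as.integer(rng_seed), thin = as.integer(thin)),
            class = "simulation_config")
}

.pp_list <- function(pp) list(m = pp$m, n = pp$n, nu = pp$nu,
                              alpha = pp$alpha, kt = pp$kt)

#' Pair interaction energy of two capsomers
#'
#' The product potential \eqn{V = V_{Mie} V_a V_{tor}}: a Mie distance term
#' with minimum \eqn{-\epsilon_0} at \eqn{r = \sigma}, Gaussian angular
#' factors \eqn{\exp(-(\theta_{ij}-\nu)^2/2\alpha^2)} on both orientations,
#' and the torsion factor \eqn{\exp(-k_t(1-\cos\xi)^2)} with \eqn{\xi} the
#' angle between the planes spanned by the centre-to-centre vector and each
#' orientation.  By default the modulation acts on the attractive branch
#' only (the repulsive core, `r < sigma`, is orientation-independent);
#' `strict_product = TRUE` multiplies the whole Mie term.  Reduced units:
#' lengths in sigma, energies in eps0.
#'
#' @param r_vec 3-vector from capsomer i to capsomer j.
#' @param omega_i,omega_j unit orientation vectors.
#' @param pp a [potential_parameters()] object.
#' @param cutoff interaction cutoff (energy-shifted); `Inf`-like large
#'   values give the bare potential.
#' @param strict_product see above.
#' @return Scalar energy in units of eps0.
#' @examples
#' pp <- potential_parameters(12, 6, 1.45, 0.25)
#' rhat <- c(1, 0, 0)
#' o <- c(cos(1.45), sin(1.45), 0)       # theta_ij = nu exactly
#' oj <- c(-cos(1.45), sin(1.45), 0)     # theta_ji = nu, xi = 0
#' pair_energy(rhat, o, oj, pp, cutoff = 1e6)   # -1 (the full binding energy)
#' @export
pair_energy <- function(r_vec, omega_i, omega_j, pp, cutoff = 2.5,
                        strict_product = FALSE) {
  if (sqrt(sum(r_vec^2)) < 1e-12) stop("pair distance must be > 0")
  .cpp_pair_energy(as.numeric(r_vec),
                   as.numeric(omega_i) / sqrt(sum(omega_i^2)),
                   as.numeric(omega_j) / sqrt(sum(omega_j^2)),
                   .pp_list(pp), cutoff, isTRUE(strict_product))
}

#' Forces and orientation torques of a configuration
#'
#' Negative analytic gradients of the total pairwise energy with respect to
#' positions and orientation vectors; the orientation gradient is projected
#' onto the tangent space of the unit sphere.  Forces on overlapping
#' capsomers (deep core) are clamped in magnitude, with a warning.
#'
#' @param state a [simulation_state()].
#' @param config a [simulation_config()].
#' @return List with `force` (N x 3), `torque` (N x 3, tangential), and
#'   total `energy`.
#' @export
forces_and_torques <- function(state, config) {
  out <- .cpp_forces(state$positions, state$orientations, state$box,
                     .pp_list(config$pp), config$cutoff,
                     config$strict_product, 1e4)
  if (out$n_clamped > 0)
    warning(sprintf("%d overlapping pair(s): core force clamped", out$n_clamped))
  out[c("force", "torque", "energy")]
}

#' Advance the Brownian dynamics by n steps
#'
#' Overdamped Euler updates in reduced units (D = 1, sigma = 1, eps0 = 1):
#' positions move by \eqn{F\,dt/T_{red}} plus Gaussian noise of variance
#' \eqn{2\,dt} per coordinate; orientations rotate by the tangential torque
#' times \eqn{D_r dt/T_{red}} plus rotational noise of variance
#' \eqn{2 D_r dt}, and are renormalised every step.  With `relax = TRUE`
#' the noise is dropped and the mobilities set to one: plain gradient
#' descent for zero-temperature relaxation.
#'
#' @param state a [simulation_state()].
#' @param config a [simulation_config()].
#' @param n number of steps.
#' @param relax zero-temperature relaxation mode.
#' @return The advanced `simulation_state`.
#' @export
bd_step <- function(state, config, n = 1L, relax = FALSE) {
  out <- .cpp_bd_run(state$positions, state$orientations, state$box,
                     .pp_list(config$pp), config$cutoff,
                     config$strict_product, as.integer(n), config$dt,
                     if (relax) 0 else config$T_red, config$Dr,
                     state$rng_seed + state$step_count, 0L, 1e4)
  if (out$max_displacement > 0.25)
    warning(sprintf(
      "single-step displacement reached %.3g sigma (> 0.25): reduce dt",
      out$max_displacement))
  simulation_state(out$positions, out$orientations, box = state$box,
                   time_step = config$dt, rng_seed = state$rng_seed,
                   step_count = state$step_count + as.integer(n))
}

#' Build the initial spherical-cap seed
#'
#' A hexagonally packed cap of `seed_size` capsomers on the sphere of
#' spontaneous radius \eqn{R_0 = \sigma/(2|\cos\nu|)}: a central capsomer
#' plus concentric rings of 6, 12, 18 neighbours at geodesic spacing sigma.
#' Orientations are radial, signed so that bound neighbours sit at the
#' preferred angle `nu` (towards the curvature centre for `nu < pi/2`,
#' outward otherwise).
#'
#' @param pp a [potential_parameters()] object.
#' @param seed_size number of capsomers (7 to 37).
#' @return N x 3 position and orientation matrices in a
#'   [simulation_state()] (box = 0), centred at the origin.
#' @examples
#' seed <- build_seed_cap(potential_parameters(24, 12, 1.45, 0.1))
#' nrow(seed$positions)   # 19
#' @export
build_seed_cap <- function(pp, seed_size = 19L) {
  stopifnot(inherits(pp, "potential_parameters"))
  if (seed_size < 7L || seed_size > 37L) stop("'seed_size' must be in 7..37")
  cn <- cos(pp$nu)
  if (abs(cn) < 1e-6)
    stop("cos(nu) ~ 0: flat sheet, no spherical seed can be built")
  R0 <- 1 / (2 * abs(cn))            # sigma = 1
  pts <- matrix(c(0, 0, R0), 1, 3)
  for (ring in 1:3) {
    k <- 6L * ring
    th <- ring * 1 / R0              # geodesic spacing sigma
    if (th >= pi) break
    ph <- 2 * pi * seq_len(k) / k + (ring %% 2) * pi / k
    pts <- rbind(pts, cbind(R0 * sin(th) * cos(ph), R0 * sin(th) * sin(ph),
                            R0 * cos(th)))
    if (nrow(pts) >= seed_size) break
  }
  pts <- pts[seq_len(seed_size), , drop = FALSE]
  radial <- pts / sqrt(rowSums(pts^2))
  ori <- if (cn < 0) radial else -radial
  pts <- sweep(pts, 2, colMeans(pts))
  simulation_state(pts, ori)
}

#' Run a seeded assembly simulation
#'
#' Places the [build_seed_cap()] seed at the centre of a periodic cubic box
#' of edge \eqn{(N/\rho)^{1/3}}, adds the remaining capsomers at uniformly
#' random non-overlapping positions with random orientations, and iterates
#' [bd_step()], taking trajectory snapshots every `thin` steps.
#' Deterministic for a fixed `rng_seed`.
#'
#' @param config a [simulation_config()].
#' @param progress print a dot every snapshot.
#' @return List with the final `state`, a `trajectory` (list of
#'   `simulation_state`s), and a data.frame `series` of snapshot step,
#'   energy and largest-cluster size.
#' @export
run_assembly <- function(config, progress = FALSE) {
  N <- config$N_total
  L <- (N / config$density)^(1 / 3)
  seed <- build_seed_cap(config$pp, config$seed_size)
  pos <- seed$positions + L / 2
  ori <- seed$orientations
  set.seed(config$rng_seed)
  nfree <- N - config$seed_size
  if (nfree > 0) {
    for (i in seq_len(nfree)) {
      placed <- FALSE
      for (try in 1:500) {
        cand <- stats::runif(3, 0, L)
        d <- sweep(pos, 2, cand)
        d <- d - L * round(d / L)
        if (min(sqrt(rowSums(d^2))) > 0.95) { placed <- TRUE; break }
      }
      if (!placed)
        stop("density too high: could not place capsomers without overlap")
      pos <- rbind(pos, cand)
      o <- stats::rnorm(3); ori <- rbind(ori, o / sqrt(sum(o^2)))
    }
  }
  thin <- if (config$thin > 0) config$thin else max(1L, config$n_steps %/% 50L)
  out <- .cpp_bd_run(pos, ori, L, .pp_list(config$pp), config$cutoff,
                     config$strict_product, config$n_steps, config$dt,
                     config$T_red, config$Dr, config$rng_seed, thin, 1e4)
  frames <- out$n_frames
  traj <- vector("list", frames)
  sizes <- integer(frames)
  for (f in seq_len(frames)) {
    idx <- ((f - 1) * N + 1):(f * N)
    st <- simulation_state(out$traj_positions[idx, , drop = FALSE],
                           out$traj_orientations[idx, , drop = FALSE],
                           box = L, time_step = config$dt,
                           rng_seed = config$rng_seed,
                           step_count = as.integer(out$traj_step[f]))
    traj[[f]] <- st
    sizes[f] <- max(find_clusters(st)$cluster_sizes)
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  final <- simulation_state(out$positions, out$orientations, box = L,
                            time_step = config$dt,
                            rng_seed = config$rng_seed,
                            step_count = config$n_steps)
  list(state = final, trajectory = traj,
       series = data.frame(step = out$traj_step[seq_len(frames)],
                           energy = out$traj_energy[seq_len(frames)],
                           largest_cluster = sizes))
}
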