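# shared fixtures for the test suite

p_belt_ref <- scaled_parameters(lam = 1e-4, dmu = 1e-3, gamma = 0)

pp_ref <- function() potential_parameters(12, 6, 1.45, 0.25)

# aligned dimer at the potential minimum: r = sigma, both angles at nu,
# torsion angle zero
dimer_minimum <- function(nu = 1.45) {
  list(rvec = c(1, 0, 0),
       oi = c(cos(nu), sin(nu), 0),
       oj = c(-cos(nu), sin(nu), 0))
}

random_unit <- function(n = 1) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

rigid_transform <- function(P, seed = 1) {
  set.seed(seed)
  th <- stats::runif(3, 0, 2 * pi)
  Rz <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0,
                             0, 0, 1), 3, byrow = TRUE)
  Rx <- function(a) matrix(c(1, 0, 0, 0, cos(a), -sin(a),
                             0, sin(a), cos(a)), 3, byrow = TRUE)
  M <- Rz(th[1]) %*% Rx(th[2]) %*% Rz(th[3])
  P %*% t(M) + matrix(stats::runif(3, -5, 5), nrow(P), 3, byrow = TRUE)
}
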