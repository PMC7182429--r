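## Classification of assembled clusters: sizes, coordination,
## disclination counts and gross shape (cap, closed shell, ribbon, tube,
## cone), for comparison of simulation outcomes with the theoretical phase
## diagram.

# minimum-image pairwise distance matrix
.pair_dist <- function(pos, box = 0) {
  n <- nrow(pos)
  D <- matrix(0, n, n)
  for (k in 1:3) {
    d <- outer(pos[, k], pos[, k], "-")
    if (box > 0) d <- d - box * round(d / box)
    D <- D + d^2
  }
  sqrt(D)
}

#' Cluster the capsomers of a configuration
#'
#' Single-linkage clustering by pair distance (two capsomers are connected
#' when closer than `cutoff`, default 1.4 sigma: the midpoint between the
#' first and second neighbour shells of a hexagonal lattice), with
#' minimum-image distances in a periodic box.  Clusters are ordered by
#' decreasing size.
#'
#' @param state a [simulation_state()] (or a list with `positions` and
#'   optional `box`).
#' @param cutoff neighbour distance threshold (sigma).
#' @return An object of class `cluster_report`: `cluster_sizes` (decreasing),
#'   `membership` (cluster index per capsomer, 1 = largest),
#'   `largest_cluster_members` (indices), `coordination` (neighbour counts
#'   within the largest cluster).
#' @export
find_clusters <- function(state, cutoff = 1.4) {
  pos <- state$positions
  box <- if (is.null(state$box)) 0 else state$box
  D <- .pair_dist(pos, box)
  adj <- D < cutoff & upper.tri(D)
  g <- igraph::graph_from_adjacency_matrix(adj | t(adj), mode = "undirected")
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  relabel <- match(seq_along(comp$csize), ord)
  membership <- relabel[comp$membership]
  largest <- which(membership == 1L)
  coord <- rowSums(D[largest, largest, drop = FALSE] < cutoff) - 1L
  structure(list(cluster_sizes = sort(comp$csize, decreasing = TRUE),
                 membership = membership,
                 largest_cluster_members = largest,
                 coordination = coord),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("clusters: %s (N = %d)\n",
              paste(utils::head(x$cluster_sizes, 8), collapse = ", "),
              sum(x$cluster_sizes)))
  invisible(x)
}

# least-squares sphere fit (algebraic); returns centre, radius, relative rms
.sphere_fit <- function(P) {
  A <- cbind(2 * P, 1)
  b <- rowSums(P^2)
  cf <- tryCatch(qr.solve(A, b), error = function(e) NULL)
  if (is.null(cf)) return(NULL)
  ctr <- cf[1:3]
  R <- sqrt(cf[4] + sum(ctr^2))
  d <- sqrt(rowSums(sweep(P, 2, ctr)^2))
  list(center = ctr, radius = R, rel_rms = stats::sd(d) / R, dist = d)
}

# boundary members: neighbours leave an angular gap > 60 degrees around the
# local normal (the radial direction from the cluster's fitted centre, or
# the smallest-eigenvalue direction for flat clusters)
.boundary_members <- function(P, D, cutoff, normals) {
  n <- nrow(P)
  vapply(seq_len(n), function(i) {
    nb <- which(D[i, ] < cutoff & seq_len(n) != i)
    if (length(nb) < 2L) return(TRUE)
    nrm <- normals[i, ]
    e1 <- c(nrm[2], -nrm[1], 0)
    if (sum(e1^2) < 1e-12) e1 <- c(1, 0, 0)
    e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(nrm[2] * e1[3] - nrm[3] * e1[2],
            nrm[3] * e1[1] - nrm[1] * e1[3],
            nrm[1] * e1[2] - nrm[2] * e1[1])
    v <- sweep(P[nb, , drop = FALSE], 2, P[i, ])
    ang <- sort(atan2(v %*% e2, v %*% e1))
    gaps <- diff(c(ang, ang[1] + 2 * pi))
    max(gaps) > pi / 1.5   # 120 degrees: tolerant of lattice distortion
  }, logical(1))
}

#' Classify the gross shape of a cluster
#'
#' Decides between closed shell, open cap, tube, ribbon, cone and amorphous
#' from the gyration-tensor eigenvalues, a least-squares sphere fit, the
#' presence of boundary members, and the cross-section profile along the
#' principal axis.  Thresholds are calibrated on the synthetic fixtures of
#' [make_shape_fixture()] and frozen.
#'
#' @param P cluster coordinates (N x 3, unwrapped; use
#'   [unwrap_cluster()] for periodic configurations) or a
#'   [simulation_state()] whose largest cluster is analysed.
#' @param cutoff neighbour distance threshold (sigma).
#' @return List with `shape_class` (one of `"closed_shell"`, `"cap"`,
#'   `"tube"`, `"ribbon"`, `"cone"`, `"amorphous"`), `eigenvalues` of the
#'   gyration tensor, `fitted_radius`, `n_boundary`.
#' @export
classify_shape <- function(P, cutoff = 1.4) {
  if (inherits(P, "simulation_state")) {
    rep <- find_clusters(P, cutoff)
    P <- unwrap_cluster(P, rep$largest_cluster_members, cutoff)
  }
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 12L)
    return(list(shape_class = "amorphous", eigenvalues = rep(NA_real_, 3),
                fitted_radius = NA_real_, n_boundary = NA_integer_))
  C <- sweep(P, 2, colMeans(P))
  gyr <- crossprod(C) / n
  ev <- sort(eigen(gyr, symmetric = TRUE)$values, decreasing = TRUE)
  if (ev[2] / ev[1] < 1e-3)
    return(list(shape_class = "amorphous", eigenvalues = ev,
                fitted_radius = NA_real_, n_boundary = NA_integer_))
  D <- .pair_dist(P, 0)
  sf <- .sphere_fit(P)
  # local normals: radial for curved clusters
  evec <- eigen(gyr, symmetric = TRUE)$vectors
  normals <- if (!is.null(sf)) {
    v <- sweep(P, 2, sf$center); v / sqrt(rowSums(v^2))
  } else {
    matrix(rep(evec[, 3], each = n), n, 3)
  }
  bnd <- .boundary_members(P, D, cutoff, normals)
  nb <- sum(bnd)
  out <- function(cls) list(shape_class = cls, eigenvalues = ev,
                            fitted_radius = if (is.null(sf)) NA_real_
                                            else sf$radius,
                            n_boundary = nb)
  # clusters that live on a sphere: closed shell, open cap, curved strip;
  # distinguished by the angular covariance on the fitted sphere
  if (!is.null(sf) && sf$rel_rms < 0.1 &&
      sf$radius < 10 * stats::median(D[D > 0 & D < 2])) {
    u <- sweep(P, 2, sf$center)
    u <- u / sqrt(rowSums(u^2))
    lu <- sort(eigen(crossprod(u) / n, symmetric = TRUE)$values,
               decreasing = TRUE)
    if (lu[3] / lu[1] > 0.45) return(out(if (nb == 0L) "closed_shell" else "cap"))
    mu <- colMeans(u)
    if (sqrt(sum(mu^2)) < 0.25) return(out("ribbon"))  # band girdling the sphere
    # azimuthal-equidistant chart around the mean direction: an open cap is
    # an isotropic disk there, a curved strip a thin elongated set
    m <- mu / sqrt(sum(mu^2))
    e1c <- c(m[2], -m[1], 0); if (sum(e1c^2) < 1e-12) e1c <- c(1, 0, 0)
    e1c <- e1c / sqrt(sum(e1c^2))
    e2c <- c(m[2] * e1c[3] - m[3] * e1c[2], m[3] * e1c[1] - m[1] * e1c[3],
             m[1] * e1c[2] - m[2] * e1c[1])
    th <- acos(pmin(1, pmax(-1, drop(u %*% m))))
    phi <- atan2(drop(u %*% e2c), drop(u %*% e1c))
    X <- cbind(th * cos(phi), th * sin(phi))
    lc <- sort(eigen(stats::cov(X), symmetric = TRUE)$values,
               decreasing = TRUE)
    return(out(if (lc[2] / lc[1] < 0.2) "ribbon" else "cap"))
  }
  # nearly planar clusters: flat strip or flat patch
  if (ev[3] / ev[1] < 0.02)
    return(out(if (ev[1] / ev[2] > 3) "ribbon" else "cap"))
  # axial bodies: tube (uniform circular cross-section) or cone (monotone
  # cross-section radius); the symmetry axis is the dominant eigenvector
  # for elongated bodies but the smallest one for squat wide cones
  axis_stats <- function(a) {
    z <- drop(C %*% a)
    rho <- sqrt(pmax(rowSums(C^2) - z^2, 0))
    b1 <- c(a[2], -a[1], 0); if (sum(b1^2) < 1e-12) b1 <- c(1, 0, 0)
    b1 <- b1 / sqrt(sum(b1^2))
    b2 <- c(a[2] * b1[3] - a[3] * b1[2], a[3] * b1[1] - a[1] * b1[3],
            a[1] * b1[2] - a[2] * b1[1])
    ang <- sort(atan2(C %*% b2, C %*% b1))
    cover <- 2 * pi - max(diff(c(ang, ang[1] + 2 * pi)))
    nsl <- max(4L, min(10L, floor(n / 10)))
    prof <- tapply(rho, cut(z, breaks = nsl), stats::median)
    prof <- prof[is.finite(prof)]
    mono <- length(prof) >= 3L &&
      (all(diff(prof) > 0) || all(diff(prof) < 0))
    rel_range <- (max(prof) - min(prof)) / stats::median(rho)
    list(cover = cover, mono = mono, rel_range = rel_range,
         rho_cv = stats::sd(rho) / mean(rho),
         elong = (max(z) - min(z)) / (2 * mean(rho)))
  }
  for (a in list(evec[, 1], evec[, 3])) {
    s <- axis_stats(a)
    if (s$cover > 5.2 && s$mono && s$rel_range > 0.5) return(out("cone"))
    if (s$cover > 5.2 && s$rho_cv < 0.2 && s$elong > 1.2) return(out("tube"))
  }
  if (ev[3] / ev[2] < 0.35) return(out("ribbon"))
  out("amorphous")
}

#' Unwrap a periodic cluster into contiguous coordinates
#'
#' Rebuilds a cluster that may straddle the periodic boundaries by walking
#' its neighbour graph from the first member and accumulating minimum-image
#' displacements.
#'
#' @param state a [simulation_state()].
#' @param members indices of the cluster members.
#' @param cutoff neighbour distance (sigma).
#' @return Matrix of unwrapped coordinates (one row per member).
#' @export
unwrap_cluster <- function(state, members, cutoff = 1.4) {
  pos <- state$positions[members, , drop = FALSE]
  box <- state$box
  n <- nrow(pos)
  if (box <= 0 || n == 1L) return(pos)
  D <- .pair_dist(pos, box)
  out <- pos
  done <- rep(FALSE, n); done[1] <- TRUE
  queue <- 1L
  while (length(queue) > 0L) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(D[i, ] < cutoff & !done)
    for (j in nb) {
      d <- pos[j, ] - pos[i, ]
      d <- d - box * round(d / box)
      out[j, ] <- out[i, ] + d
      done[j] <- TRUE
      queue <- c(queue, j)
    }
  }
  out
}

#' Count 5-fold disclinations in a shell-like cluster
#'
#' Interior members (those whose neighbours close a full angular fan around
#' the local normal) with exactly five neighbours.  A closed icosahedral
#' shell yields twelve; a flat hexagonal patch yields zero.
#'
#' @param P cluster coordinates (N x 3), or a [simulation_state()] whose
#'   largest cluster is analysed.
#' @param cutoff neighbour distance threshold (sigma).
#' @return List with `n_fivefold`, `coordination`, logical `interior`, and
#'   `euler_sum` (sum of `6 - coordination` over interior members; 12 for a
#'   closed triangulated shell).
#' @export
count_disclinations <- function(P, cutoff = 1.4) {
  if (inherits(P, "simulation_state")) {
    rep <- find_clusters(P, cutoff)
    P <- unwrap_cluster(P, rep$largest_cluster_members, cutoff)
  }
  P <- as.matrix(P)
  n <- nrow(P)
  if (n < 7L) stop("cluster too small for a defect count")
  D <- .pair_dist(P, 0)
  coord <- rowSums(D < cutoff) - 1L
  sf <- .sphere_fit(P)
  normals <- if (!is.null(sf) && sf$rel_rms < 0.25) {
    v <- sweep(P, 2, sf$center); v / sqrt(rowSums(v^2))
  } else {
    C <- sweep(P, 2, colMeans(P))
    matrix(rep(eigen(crossprod(C) / n, symmetric = TRUE)$vectors[, 3],
               each = n), n, 3)
  }
  interior <- !.boundary_members(P, D, cutoff, normals)
  list(n_fivefold = sum(interior & coord == 5L),
       coordination = coord,
       interior = interior,
       euler_sum = sum(6L - coord[interior]))
}

#' Synthetic cluster fixtures for the shape classifier
#'
#' Deterministic point sets emulating the assembly outcomes: a closed
#' icosadeltahedral shell (`"sphere"`; 12 or 42 capsomers for
#' subdivision frequency 1 or 2), an open spherical `"cap"`, a hexagonal
#' `"tube"` (radius 2 sigma), a curved 3 x 20 strip (`"ribbon"`), a `"cone"`
#' and a flat hexagonal `"patch"`.  Nearest-neighbour spacing is 1 sigma.
#'
#' @param shape one of `"sphere"`, `"cap"`, `"tube"`, `"ribbon"`, `"cone"`,
#'   `"patch"`.
#' @param freq subdivision frequency for the sphere (1 or 2).
#' @return N x 3 coordinate matrix.
#' @export
make_shape_fixture <- function(shape = c("sphere", "cap", "tube", "ribbon",
                                         "cone", "patch"), freq = 2L) {
  shape <- match.arg(shape)
  gold <- (1 + sqrt(5)) / 2
  ico <- rbind(
    c(-1, gold, 0), c(1, gold, 0), c(-1, -gold, 0), c(1, -gold, 0),
    c(0, -1, gold), c(0, 1, gold), c(0, -1, -gold), c(0, 1, -gold),
    c(gold, 0, -1), c(gold, 0, 1), c(-gold, 0, -1), c(-gold, 0, 1))
  ico <- ico / sqrt(rowSums(ico^2))
  if (shape %in% c("sphere", "cap")) {
    pts <- ico
    if (freq >= 2L) {
      # add edge midpoints (projected): icosadeltahedral frequency 2
      edges <- which(.pair_dist(ico, 0) < 1.2 & upper.tri(diag(12)),
                     arr.ind = TRUE)
      mids <- (ico[edges[, 1], ] + ico[edges[, 2], ]) / 2
      mids <- mids / sqrt(rowSums(mids^2))
      pts <- rbind(pts, mids)
    }
    # scale so that nearest-neighbour spacing is ~1
    D <- .pair_dist(pts, 0); diag(D) <- Inf
    pts <- pts / min(D)
    if (shape == "cap") pts <- pts[pts[, 3] > -0.2 * max(pts[, 3]), ,
                                   drop = FALSE]
    return(pts)
  }
  if (shape == "tube") {
    rad <- 2; k <- floor(2 * pi * rad)   # 12 around
    rows <- 20L
    out <- NULL
    for (i in seq_len(rows)) {
      ph <- 2 * pi * seq_len(k) / k + (i %% 2) * pi / k
      out <- rbind(out, cbind(rad * cos(ph), rad * sin(ph),
                              i * sqrt(3) / 2))
    }
    return(out)
  }
  if (shape == "ribbon") {
    Rs <- 8                              # strip curved on a sphere
    out <- NULL
    for (i in 0:2) {
      th <- pi / 2 + (i - 1) * (1 / Rs) * sqrt(3) / 2
      ph <- ((seq_len(20L) + (i %% 2) / 2) / Rs) / sin(th)
      out <- rbind(out, cbind(Rs * sin(th) * cos(ph),
                              Rs * sin(th) * sin(ph), Rs * cos(th)))
    }
    return(out)
  }
  if (shape == "cone") {
    out <- NULL
    half <- 0.45
    for (i in 3:14) {
      rad <- i * half
      k <- max(3L, floor(2 * pi * rad))
      ph <- 2 * pi * seq_len(k) / k + (i %% 2) * pi / k
      out <- rbind(out, cbind(rad * cos(ph), rad * sin(ph),
                              i * sqrt(1 - half^2)))
    }
    return(out)
  }
  # flat hexagonal patch of radius 4
  out <- NULL
  for (i in -4:4) for (j in -4:4) {
    p <- c(i + j / 2, j * sqrt(3) / 2, 0)
    if (sqrt(sum(p^2)) <= 4.01) out <- rbind(out, p)
  }
  rownames(out) <- NULL
  out
}
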