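## Tabular and trajectory I/O: phase grids as tidy CSV, capsomer
## trajectories as extended XYZ (x y z Ox Oy Oz per record, comment line
## carrying step and box).

.grid_columns <- c("lam", "dmu", "gamma", "winner", "dg_winner",
                   "x_opt", "r_opt", "n_def")

#' Write a phase grid to CSV
#'
#' Tidy long format, one row per grid cell, columns
#' `lam, dmu, gamma, winner, dg_winner, x_opt, r_opt, n_def`, floats at 12
#' significant digits with dot decimal separator.
#'
#' @param grid a [compute_grid()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phase_grid <- function(grid, path) {
  stopifnot(inherits(grid, "phase_grid"))
  df <- as.data.frame(grid)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.12g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a phase grid from CSV
#'
#' Inverse of [write_phase_grid()]; the axes are rebuilt from the unique
#' cell coordinates.  Parsing is locale-independent (dot decimal separator
#' only).
#'
#' @param path CSV file written by [write_phase_grid()].
#' @return A `phase_grid` object.
#' @export
read_phase_grid <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(winner = "character"))
  missing <- setdiff(.grid_columns, names(df))
  if (length(missing) > 0L)
    stop("malformed phase-grid CSV: missing column(s) ",
         paste(missing, collapse = ", "))
  lam_axis <- sort(unique(df$lam))
  dmu_axis <- sort(unique(df$dmu))
  nl <- length(lam_axis); nd <- length(dmu_axis)
  if (nrow(df) != nl * nd) stop("phase-grid CSV is not a complete grid")
  i <- match(df$lam, lam_axis); j <- match(df$dmu, dmu_axis)
  idx <- cbind(i, j)
  labels <- matrix(NA_character_, nl, nd); labels[idx] <- df$winner
  dg <- xo <- ro <- matrix(NA_real_, nl, nd)
  ndm <- matrix(NA_integer_, nl, nd)
  dg[idx] <- df$dg_winner; xo[idx] <- df$x_opt; ro[idx] <- df$r_opt
  ndm[idx] <- as.integer(df$n_def)
  structure(list(lam_axis = lam_axis, dmu_axis = dmu_axis,
                 gamma = df$gamma[1], labels = labels, dg = dg,
                 x_opt = xo, r_opt = ro, n_def = ndm),
            class = "phase_grid")
}

#' Write a trajectory in extended XYZ format
#'
#' One block per frame: a count line, a comment line
#' `step=<n> box=<L>`, then one `C x y z Ox Oy Oz` record per capsomer,
#' 12 significant digits.
#'
#' @param traj a single [simulation_state()] or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  if (inherits(traj, "simulation_state")) traj <- list(traj)
  con <- file(path, "w"); on.exit(close(con))
  for (st in traj) {
    n <- nrow(st$positions)
    writeLines(as.character(n), con)
    writeLines(sprintf("step=%d box=%.12g", st$step_count, st$box), con)
    rec <- sprintf("C %.12g %.12g %.12g %.12g %.12g %.12g",
                   st$positions[, 1], st$positions[, 2], st$positions[, 3],
                   st$orientations[, 1], st$orientations[, 2],
                   st$orientations[, 3])
    writeLines(rec, con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' Inverse of [write_xyz()].  Orientation vectors are renormalised on read
#' (with a warning when they deviate from unit length); an empty file
#' yields an empty list.
#'
#' @param path file written by [write_xyz()].
#' @return List of [simulation_state()] objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(lines[i]))
    if (is.na(n)) stop("malformed XYZ: expected an atom count at line ", i)
    cm <- lines[i + 1L]
    step <- as.integer(sub(".*step=([0-9]+).*", "\\1", cm))
    box <- as.numeric(sub(".*box=([0-9.eE+-]+).*", "\\1", cm))
    if (is.na(step)) step <- 0L
    if (is.na(box)) box <- 0
    rec <- lines[(i + 2L):(i + 1L + n)]
    fields <- strsplit(trimws(rec), "\\s+")
    bad <- which(lengths(fields) != 7L)
    if (length(bad) > 0L)
      stop("malformed XYZ record at line ", i + 1L + bad[1],
           ": expected 7 columns (element, x y z, Ox Oy Oz)")
    M <- matrix(as.numeric(unlist(lapply(fields, `[`, 2:7))),
                ncol = 6, byrow = TRUE)
    out[[length(out) + 1L]] <-
      simulation_state(M[, 1:3, drop = FALSE], M[, 4:6, drop = FALSE],
                       box = box, step_count = step)
    i <- i + 2L + n
  }
  out
}
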