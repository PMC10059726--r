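#' Solvent-accessible surface area settings
#'
#' @param probe_radius solvent probe radius, Angstrom (default 1.4)
#' @param n_sphere_points number of test points per atom (default 960,
#'   minimum 60); points are placed on a deterministic golden-spiral
#'   lattice
#' @param surften surface tension gamma, kcal/mol/A^2 (default 0.0072)
#' @param offset constant beta of the nonpolar term, kcal/mol (default 0)
#' @return list of class `"sasa_model"`
#' @export
sasa_model <- function(probe_radius = 1.4, n_sphere_points = 960,
                       surften = 0.0072, offset = 0) {
  if (probe_radius < 0) stop("sasa_model: probe_radius must be >= 0")
  if (n_sphere_points < 60) stop("sasa_model: need at least 60 sphere points")
  structure(list(probe_radius = probe_radius,
                 n_sphere_points = as.integer(n_sphere_points),
                 surften = surften, offset = offset),
            class = "sasa_model")
}

# deterministic quasi-uniform unit-sphere lattice (golden spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * k
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Point-rejection on each atom's solvent-accessible sphere of radius
#' `r_atom + probe`; a test point is buried if it lies inside any
#' neighbour's accessible sphere. Atomic radii are the Lennard-Jones
#' rmin/2 values of the atom kinds.
#'
#' @inheritParams effective_born_radii
#' @param model a [sasa_model()]
#' @return list with `per_atom` (A^2 per atom) and `total` (A^2)
#' @export
sasa <- function(topo, params, frame, model = sasa_model()) {
  x <- as.matrix(frame)
  kinds <- params$atom_kinds
  rad <- vapply(topo$atoms$type, function(t) kinds[[t]]$lj_rmin_half,
                numeric(1)) + model$probe_radius
  n <- nrow(x)
  pts <- sphere_points(model$n_sphere_points)
  per_atom <- numeric(n)
  d2 <- as.matrix(stats::dist(x))^2
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    if (!length(nb)) {
      per_atom[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- pts * rad[i]
    p <- sweep(p, 2, x[i, ], `+`)
    buried <- rep(FALSE, nrow(p))
    for (j in nb) {
      dj2 <- (p[, 1] - x[j, 1])^2 + (p[, 2] - x[j, 2])^2 +
        (p[, 3] - x[j, 3])^2
      buried <- buried | dj2 < rad[j]^2
      if (all(buried)) break
    }
    per_atom[i] <- 4 * pi * rad[i]^2 * mean(!buried)
  }
  list(per_atom = per_atom, total = sum(per_atom))
}

#' Nonpolar solvation energy from SASA
#'
#' \eqn{\Delta G_{np} = \gamma \cdot \mathrm{SASA} + \beta}.
#'
#' @param sasa_total total solvent-accessible surface area, A^2
#' @param model a [sasa_model()] supplying gamma and beta
#' @return kcal/mol
#' @export
nonpolar_energy <- function(sasa_total, model = sasa_model()) {
  model$surften * sasa_total + model$offset
}
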