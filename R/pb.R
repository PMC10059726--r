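#' Finite-difference Poisson-Boltzmann grid settings
#'
#' @param spacing grid spacing, Angstrom
#' @param padding margin beyond the solute extent, Angstrom
#' @param max_iterations SOR iteration cap
#' @param tol convergence tolerance on the maximum potential update per
#'   sweep, kcal/(mol e)
#' @return list of class `"pb_grid"`
#' @export
pb_grid <- function(spacing = 0.5, padding = 10, max_iterations = 10000,
                    tol = 1e-6) {
  if (!(spacing > 0)) stop("pb_grid: spacing must be > 0")
  if (!(padding > 0)) stop("pb_grid: padding must be > 0")
  structure(list(spacing = spacing, padding = padding,
                 max_iterations = as.integer(max_iterations), tol = tol),
            class = "pb_grid")
}

# trilinear distribution of point charges to the 8 surrounding nodes
spread_charges <- function(x, q, origin, h, dims) {
  rho <- array(0, dims)
  fr <- sweep(x, 2, origin, `-`) / h
  i0 <- pmin(pmax(floor(fr), 0), dims[col(fr)] - 2)
  w <- fr - i0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    idx <- cbind(i0[, 1] + dx + 1, i0[, 2] + dy + 1, i0[, 3] + dz + 1)
    for (a in seq_along(q))
      rho[idx[a, 1], idx[a, 2], idx[a, 3]] <-
        rho[idx[a, 1], idx[a, 2], idx[a, 3]] + q[a] * wt[a]
  }
  rho
}

# mark nodes/face-midpoints lying inside any atom sphere
inside_spheres <- function(px, py, pz, centers, radii) {
  inside <- array(FALSE, c(length(px), length(py), length(pz)))
  for (a in seq_len(nrow(centers))) {
    ix <- which(abs(px - centers[a, 1]) <= radii[a])
    iy <- which(abs(py - centers[a, 2]) <= radii[a])
    iz <- which(abs(pz - centers[a, 3]) <= radii[a])
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (px[ix] - centers[a, 1])^2
    dy2 <- (py[iy] - centers[a, 2])^2
    dz2 <- (pz[iz] - centers[a, 3])^2
    r2 <- radii[a]^2
    sub <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r2
    inside[ix, iy, iz] <- inside[ix, iy, iz] | sub
  }
  inside
}

#' Finite-difference linearized Poisson-Boltzmann polar solvation energy
#'
#' Reference implementation: the linearized Poisson(-Boltzmann) equation is
#' solved by successive over-relaxation on a two-dielectric map (`eps_in`
#' inside the union of atom spheres of radius `gb_radius`, `eps_out`
#' outside; face dielectrics assigned by the face midpoint). Charges are
#' spread trilinearly. The reaction-field energy is
#' \eqn{\frac12 \sum q_g (\phi_{het} - \phi_{unif})} over grid charges,
#' where the uniform-`eps_in` solve on the same grid cancels the grid
#' self-energy. Boundary potentials use the Debye-Hueckel monopole of the
#' total charge at the centre of charge (of geometry when neutral).
#'
#' @inheritParams effective_born_radii
#' @param grid a [pb_grid()]
#' @param eps_in,eps_out interior and exterior dielectric constants
#' @param kappa Debye screening constant, 1/Angstrom
#' @return polar solvation energy, kcal/mol
#' @export
pb_energy_fd <- function(topo, params, frame, grid = pb_grid(),
                         eps_in = 1, eps_out = 78.5, kappa = 0) {
  x <- as.matrix(frame)
  q <- topo$atoms$charge
  kinds <- params$atom_kinds
  rad <- vapply(topo$atoms$type, function(t) kinds[[t]]$gb_radius, numeric(1))
  h <- grid$spacing
  lo <- apply(x, 2, min) - grid$padding
  hi <- apply(x, 2, max) + grid$padding
  dims <- pmax(ceiling((hi - lo) / h) + 1L, 5L)
  origin <- lo
  ax <- origin[1] + h * (seq_len(dims[1]) - 1)
  ay <- origin[2] + h * (seq_len(dims[2]) - 1)
  az <- origin[3] + h * (seq_len(dims[3]) - 1)

  rho_grid <- spread_charges(x, q, origin, h, dims)

  # dielectric on faces: midpoint between node and +axis neighbour
  fx <- inside_spheres(ax[-length(ax)] + h / 2, ay, az, x, rad)
  fy <- inside_spheres(ax, ay[-length(ay)] + h / 2, az, x, rad)
  fz <- inside_spheres(ax, ay, az[-length(az)] + h / 2, x, rad)
  mk_eps <- function(mask) {
    e <- array(eps_out, dim(mask)); e[mask] <- eps_in
    # pad back to full node dims so the C++ kernel can index uniformly
    full <- array(eps_out, dims)
    idx <- lapply(seq_len(3), function(d) seq_len(dim(mask)[d]))
    full[idx[[1]], idx[[2]], idx[[3]]] <- e
    full
  }
  epsx <- mk_eps(fx); epsy <- mk_eps(fy); epsz <- mk_eps(fz)

  node_out <- !inside_spheres(ax, ay, az, x, rad)
  lam <- array(0, dims)
  if (kappa > 0) lam[node_out] <- eps_out * (kappa * h)^2

  qtot <- sum(q)
  cq <- if (abs(qtot) > 1e-9) colSums(x * q) / qtot else colMeans(x)
  bc_phi <- function(epsb, kap) {
    g <- expand_boundary_grid(ax, ay, az)
    r <- sqrt((g[, 1] - cq[1])^2 + (g[, 2] - cq[2])^2 + (g[, 3] - cq[3])^2)
    r <- pmax(r, h)
    phi <- array(0, dims)
    phi[g[, 4]] <- KE_COULOMB * qtot * exp(-kap * r) / (epsb * r)
    phi
  }

  run <- function(epsx, epsy, epsz, lam, bc) {
    phi <- as.numeric(bc)
    src <- 4 * pi * KE_COULOMB * as.numeric(rho_grid) / h
    omega <- 2 / (1 + sin(pi / max(dims)))
    out <- sor_poisson(phi, as.numeric(epsx), as.numeric(epsy),
                       as.numeric(epsz), as.numeric(lam), src,
                       dims[1], dims[2], dims[3],
                       omega, grid$tol, grid$max_iterations)
    if (out[2] >= grid$tol)
      stop(sprintf("pb_energy_fd: SOR did not converge in %d iterations (last max update %.3g kcal/(mol e))",
                   grid$max_iterations, out[2]))
    array(phi, dims)
  }
  phi_het <- run(epsx, epsy, epsz, lam, bc_phi(eps_out, kappa))
  ones <- array(eps_in, dims)
  phi_unif <- run(ones, ones, ones, array(0, dims), bc_phi(eps_in, 0))
  0.5 * sum(rho_grid * (phi_het - phi_unif))
}

# linear indices + coordinates of the 6 boundary planes
expand_boundary_grid <- function(ax, ay, az) {
  dims <- c(length(ax), length(ay), length(az))
  idx <- array(seq_len(prod(dims)), dims)
  take <- function(i, j, k) {
    g <- expand.grid(x = ax[i], y = ay[j], z = az[k])
    cbind(g$x, g$y, g$z, as.numeric(idx[i, j, k]))
  }
  res <- rbind(take(1, seq_len(dims[2]), seq_len(dims[3])),
               take(dims[1], seq_len(dims[2]), seq_len(dims[3])),
               take(seq_len(dims[1]), 1, seq_len(dims[3])),
               take(seq_len(dims[1]), dims[2], seq_len(dims[3])),
               take(seq_len(dims[1]), seq_len(dims[2]), 1),
               take(seq_len(dims[1]), seq_len(dims[2]), dims[3]))
  res[!duplicated(res[, 4]), , drop = FALSE]
}
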