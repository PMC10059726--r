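# shared builders for small reference systems

single_atom_system <- function(type = "ion", charge = 1, mass = 22.99,
                               rmin_half = 1.8, eps = 0.1,
                               gb_radius = 2.09, gb_screen = 0.8) {
  ak <- list(atom_kind(type, mass, rmin_half, eps, gb_radius, gb_screen))
  names(ak) <- type
  list(topo = topology(data.frame(name = "A1", type = type, charge = charge,
                                  mass = mass),
                       matrix(integer(), ncol = 2)),
       params = parameter_set(ak, list(), list(), list()))
}

pair_system <- function(charges = c(1, 1), rmin_half = 1.8, eps = 0.1,
                        gb_radius = 2.0, gb_screen = 0.8, bond = NULL,
                        mass = 12) {
  ak <- list(a = atom_kind("a", mass, rmin_half, eps, gb_radius, gb_screen))
  bp <- if (is.null(bond)) list() else list("a-a" = bond)
  bonds <- if (is.null(bond)) matrix(integer(), ncol = 2) else rbind(c(1L, 2L))
  list(topo = topology(data.frame(name = c("A1", "A2"), type = "a",
                                  charge = charges, mass = mass), bonds),
       params = parameter_set(ak, bp, list(), list()))
}

# linear chain of n identical atoms with full bonded parameterization
chain_system <- function(n, charges = rep(0, n), bond_k = 300, r0 = 1.5,
                         angle_k = 50, theta0 = 109.5,
                         torsion = torsion_param(3, 0.4, 0),
                         rmin_half = 1.9, eps = 0.1) {
  ak <- list(a = atom_kind("a", 12.011, rmin_half, eps, 1.7, 0.72))
  params <- parameter_set(ak,
                          list("a-a" = bond_param(bond_k, r0)),
                          list("a-a-a" = angle_param(angle_k, theta0)),
                          list("a-a-a-a" = torsion))
  topo <- topology(data.frame(name = sprintf("A%d", 1:n), type = "a",
                              charge = charges, mass = 12.011),
                   cbind(1:(n - 1), 2:n))
  list(topo = topo, params = params)
}

zigzag_coords <- function(n, r = 1.5, angle_deg = 109.5) {
  # planar zigzag with the prescribed bond length and angle
  half <- (180 - angle_deg) / 2 * pi / 180
  dirs <- cbind(cos(half * (-1)^(seq_len(n - 1) + 1)),
                sin(half * (-1)^(seq_len(n - 1) + 1)), 0)
  x <- matrix(0, n, 3)
  for (i in 2:n) x[i, ] <- x[i - 1, ] + r * dirs[i - 1, ]
  x
}

random_rigid_motion <- function(x, seed) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(ang[1]), -sin(ang[1])),
              c(0, sin(ang[1]), cos(ang[1])))
  Ry <- rbind(c(cos(ang[2]), 0, sin(ang[2])), c(0, 1, 0),
              c(-sin(ang[2]), 0, cos(ang[2])))
  Rz <- rbind(c(cos(ang[3]), -sin(ang[3]), 0),
              c(sin(ang[3]), cos(ang[3]), 0), c(0, 0, 1))
  sweep(x %*% (Rx %*% Ry %*% Rz), 2, runif(3, -5, 5), `+`)
}

sliced_three_ensembles <- function(toy, traj, solvent = "gb") {
  hi <- which(toy$topology$partition == "host")
  gi <- which(toy$topology$partition == "guest")
  th <- subset_topology(toy$topology, hi)
  tg <- subset_topology(toy$topology, gi)
  frames <- if (inherits(traj, "trajectory")) traj$frames else traj
  list(
    complex = ensemble_energetics(toy$topology, toy$params, traj,
                                  role = "complex", solvent = solvent),
    host = ensemble_energetics(th, toy$params,
                               lapply(frames, function(x) x[hi, , drop = FALSE]),
                               role = "host", solvent = solvent),
    guest = ensemble_energetics(tg, toy$params,
                                lapply(frames, function(x) x[gi, , drop = FALSE]),
                                role = "guest", solvent = solvent))
}
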