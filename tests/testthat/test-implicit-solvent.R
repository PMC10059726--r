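test_that("effective Born radii reduce to closed forms", {
  # isolated atom: alpha = rho - offset (tanh(0) = 0)
  s <- single_atom_system(gb_radius = 2.09)
  a <- effective_born_radii(s$topo, s$params, matrix(0, 1, 3))
  expect_equal(unname(a), 2.0, tolerance = 1e-12)
  # two atoms far apart: descreening integral vanishes
  s2 <- pair_system(gb_radius = 2.09)
  a2 <- effective_born_radii(s2$topo, s2$params,
                             rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_lt(max(abs(a2 - 2.0)), 1e-6)
  # overlap increases both effective radii
  a3 <- effective_born_radii(s2$topo, s2$params,
                             rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_true(all(a3 > 2.0))
  expect_error(effective_born_radii(s$topo, s$params, matrix(0, 1, 3),
                                    gb_model(radius_offset = 3)),
               "exceed")
})

test_that("pairwise descreening matches a numerical-quadrature oracle", {
  # I = (1/4pi) Int dV / r^4 over the screened sphere of neighbour j,
  # excluding the interior of atom i, evaluated on a midpoint grid
  quad_descreen <- function(d, s, ori, ngrid = 120) {
    h <- 2 * s / ngrid
    g <- seq(-s + h / 2, s - h / 2, length.out = ngrid)
    gx <- rep(g, times = ngrid * ngrid)
    gy <- rep(rep(g, each = ngrid), times = ngrid)
    gz <- rep(g, each = ngrid * ngrid)
    inside_j <- gx^2 + gy^2 + gz^2 <= s^2
    r2 <- (gx + d)^2 + gy^2 + gz^2
    keep <- inside_j & r2 > ori^2
    sum(1 / r2[keep]^2) * h^3 / (4 * pi)
  }
  model <- gb_model()
  rho <- c(2.09, 1.7); screen <- c(0.8, 0.9)
  for (d in c(2.0, 2.6, 4.0)) {
    x <- rbind(c(0, 0, 0), c(d, 0, 0))
    a <- endpointr:::born_radii_impl(x, rho, screen, model)
    ori <- rho[1] - model$radius_offset
    I <- quad_descreen(d, screen[2] * (rho[2] - model$radius_offset), ori)
    psi <- ori * I
    alpha_ref <- 1 / (1 / ori -
                        tanh(model$obc_alpha * psi - model$obc_beta * psi^2 +
                               model$obc_gamma * psi^3) / rho[1])
    expect_equal(unname(a[1]), alpha_ref, tolerance = 0.02)
  }
})

test_that("GB energy reproduces the Born ion and trivial limits", {
  s <- single_atom_system(gb_radius = 2.09)
  x <- matrix(0, 1, 3)
  e <- gb_energy(s$topo, s$params, x, gb_model(eps_in = 1, eps_out = 80))
  expect_equal(e, -(332.0637 / 4) * (1 - 1 / 80), tolerance = 1e-6)
  expect_equal(gb_energy(s$topo, s$params, x,
                         gb_model(eps_in = 8, eps_out = 8)), 0)
  s0 <- single_atom_system(charge = 0, gb_radius = 2.09)
  expect_equal(gb_energy(s0$topo, s0$params, x, gb_model()), 0)
})

test_that("GB energy is invariant under rigid motion and linear in the prefactor", {
  toy <- make_toy_hostguest(toy_spec())
  m <- gb_model(eps_in = 1, eps_out = 78.5)
  e0 <- gb_energy(toy$topology, toy$params, toy$frame, m)
  for (seed in 1:2) {
    e1 <- gb_energy(toy$topology, toy$params,
                    random_rigid_motion(toy$frame, seed), m)
    expect_lt(abs(e1 - e0), 1e-8)
  }
  pref <- function(ei, eo) 1 / ei - 1 / eo
  base <- e0 / pref(1, 78.5)
  for (ei in c(2, 4, 6)) {
    e2 <- gb_energy(toy$topology, toy$params, toy$frame,
                    gb_model(eps_in = ei, eps_out = 78.5))
    expect_equal(e2, base * pref(ei, 78.5), tolerance = 1e-10)
  }
})

test_that("distant like charges converge to the sum of Born self terms", {
  s2 <- pair_system(charges = c(1, 1), gb_radius = 2.09)
  m <- gb_model(eps_in = 1, eps_out = 80)
  e <- gb_energy(s2$topo, s2$params, rbind(c(0, 0, 0), c(1000, 0, 0)), m)
  self2 <- 2 * (-(332.0637 / 4) * (1 - 1 / 80))
  # residual is the screened cross interaction, < 1e-4 of a kcal beyond it
  expect_lt(abs(e - self2 + 332.0637 * (1 - 1 / 80) / 1000), 1e-4)
})

test_that("Shrake-Rupley SASA matches sphere geometry", {
  s <- single_atom_system(rmin_half = 2.0)
  a <- sasa(s$topo, s$params, matrix(0, 1, 3), sasa_model())
  expect_equal(a$total, 4 * pi * 3.4^2, tolerance = 0.005)
  # distant atoms are additive
  s2 <- pair_system(rmin_half = 2.0)
  a2 <- sasa(s2$topo, s2$params, rbind(c(0, 0, 0), c(100, 0, 0)),
             sasa_model())
  expect_equal(a2$total, 2 * a$total, tolerance = 1e-9)
  # a small atom fully inside a large one exposes nothing
  ak <- list(big = atom_kind("big", 12, 5, 0.1), sm = atom_kind("sm", 12, 0.5, 0.1))
  ps <- parameter_set(ak, list(), list(), list())
  tp <- topology(data.frame(name = c("B", "S"), type = c("big", "sm"),
                            charge = 0, mass = 12), matrix(integer(), ncol = 2))
  a3 <- sasa(tp, ps, rbind(c(0, 0, 0), c(0.5, 0, 0)), sasa_model())
  expect_equal(a3$per_atom[2], 0)
})

test_that("nonpolar term is gamma * SASA + beta", {
  m <- sasa_model()
  expect_equal(nonpolar_energy(0, m), 0)
  expect_equal(nonpolar_energy(145.267, m), 0.0072 * 145.267,
               tolerance = 1e-12)
  m2 <- sasa_model(surften = 0, offset = 0.92)
  expect_equal(nonpolar_energy(500, m2), 0.92)
})

test_that("FD-PB solver passes its consistency limits", {
  s <- single_atom_system(gb_radius = 2.0)
  x <- matrix(0, 1, 3)
  # uniform dielectric: reaction field is pure grid noise
  e_uni <- pb_energy_fd(s$topo, s$params, x, pb_grid(spacing = 0.5,
                                                     padding = 8),
                        eps_in = 4, eps_out = 4)
  expect_lt(abs(e_uni), 0.1)
  # Born ion at moderate resolution
  e <- pb_energy_fd(s$topo, s$params, x, pb_grid(spacing = 0.5, padding = 10),
                    eps_in = 1, eps_out = 80)
  born <- -(332.0637 / 4) * (1 - 1 / 80)
  expect_lt(abs(e - born) / abs(born), 0.08)
})

test_that("FD-PB and GB agree within the documented envelope on a neutral toy", {
  set.seed(21)
  n <- 10
  q <- round(runif(n, -0.4, 0.4), 2); q <- round(q - mean(q), 10)
  q[n] <- -sum(q[-n])
  s <- chain_system(n, charges = q)
  x <- zigzag_coords(n)
  gbv <- gb_energy(s$topo, s$params, x, gb_model(eps_in = 1, eps_out = 80))
  pbv <- pb_energy_fd(s$topo, s$params, x, pb_grid(spacing = 0.4,
                                                   padding = 9),
                      eps_in = 1, eps_out = 80)
  expect_lt(abs(pbv - gbv) / abs(gbv), 0.15)
})
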