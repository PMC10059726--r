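test_that("single-trajectory estimate matches hand-summed arithmetic", {
  # tiny 5-atom complex (3-atom host, 2-atom guest), 2 frames
  ak <- list(h = atom_kind("h", 12, 1.8, 0.1, 1.7, 0.72),
             g = atom_kind("g", 14, 1.7, 0.15, 1.55, 0.8))
  params <- parameter_set(ak,
                          list("h-h" = bond_param(300, 1.5),
                               "g-g" = bond_param(280, 1.4)),
                          list("h-h-h" = angle_param(50, 120)),
                          list())
  topo <- topology(data.frame(name = sprintf("A%d", 1:5),
                              type = c("h", "h", "h", "g", "g"),
                              charge = c(-0.4, 0, -0.6, 0.7, 0.3), mass = 12),
                   rbind(c(1L, 2L), c(2L, 3L), c(4L, 5L)),
                   partition = c("host", "host", "host", "guest", "guest"))
  f1 <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.3, 1.2, 0),
              c(0.7, 3, 0.5), c(2.1, 3.2, 0.4))
  f2 <- f1 + 0.1
  f2[4, ] <- f2[4, ] + c(0, -0.4, 0)
  gbm <- gb_model(eps_in = 2, eps_out = 78.5)
  sm <- sasa_model()
  ens <- ensemble_energetics(topo, params, list(f1, f2), role = "complex",
                             solvent = "gb", eps_in = 2,
                             sasa_mod = sm)
  est <- single_trajectory_estimate(ens)

  # independent composition from the public one-shot primitives
  hand <- sapply(list(f1, f2), function(x) {
    pe <- partition_energy(topo, params, x, eps_in = 2)
    th <- subset_topology(topo, 1:3); tg <- subset_topology(topo, 4:5)
    gpol <- gb_energy(topo, params, x, gbm) -
      gb_energy(th, params, x[1:3, ], gbm) -
      gb_energy(tg, params, x[4:5, ], gbm)
    gnp <- nonpolar_energy(sasa(topo, params, x, sm)$total, sm) -
      nonpolar_energy(sasa(th, params, x[1:3, ], sm)$total, sm) -
      nonpolar_energy(sasa(tg, params, x[4:5, ], sm)$total, sm)
    c(pe$inter_vdw, pe$inter_ele, gpol, gnp)
  })
  expect_equal(est$components[["vdw"]], mean(hand[1, ]), tolerance = 1e-9)
  expect_equal(est$components[["ele"]], mean(hand[2, ]), tolerance = 1e-9)
  expect_equal(est$components[["polar"]], mean(hand[3, ]), tolerance = 1e-9)
  expect_equal(est$components[["nonpolar"]], mean(hand[4, ]), tolerance = 1e-9)
  expect_equal(est$dg_total, sum(rowMeans(hand)), tolerance = 1e-9)
  expect_equal(est$dg_total, sum(est$components), tolerance = 1e-12)
})

test_that("ghost guest reduces the estimate to the entropy term", {
  ak <- list(h = atom_kind("h", 12, 1.8, 0.1, 1.7, 0.72),
             x = atom_kind("x", 12, 1.8, 0, 1.7, 0))  # eps=0, screen=0
  params <- parameter_set(ak, list("h-h" = bond_param(300, 1.5),
                                   "x-x" = bond_param(300, 1.5)),
                          list(), list())
  topo <- topology(data.frame(name = sprintf("A%d", 1:4),
                              type = c("h", "h", "x", "x"),
                              charge = c(0.5, -0.5, 0, 0), mass = 12),
                   rbind(c(1L, 2L), c(3L, 4L)),
                   partition = c("host", "host", "guest", "guest"))
  frames <- list(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 3, 0), c(1.5, 3, 0)))
  # gamma = 0 removes the cavity term a chargeless, epsilon-free guest
  # cannot cancel
  ens <- ensemble_energetics(topo, params, frames, role = "complex",
                             solvent = "gb",
                             sasa_mod = sasa_model(surften = 0))
  est <- single_trajectory_estimate(ens)
  expect_equal(unname(est$components), rep(0, 4), tolerance = 1e-10)
  expect_equal(est$dg_total, 0, tolerance = 1e-10)
})

test_that("three-trajectory on sliced ensembles collapses to single-trajectory", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 50, switch_prob = 0.2, seed = 17)
  enss <- sliced_three_ensembles(toy, tr)
  est1 <- single_trajectory_estimate(enss$complex, eps_in = 2)
  est3 <- three_trajectory_estimate(enss$complex, enss$host, enss$guest,
                                    eps_in = 2)
  expect_lt(abs(est3$dg_total - est1$dg_total), 1e-8)
  expect_lt(abs(est3$components[["internal"]]), 1e-8)
  for (k in c("vdw", "ele", "polar", "nonpolar"))
    expect_lt(abs(est3$components[[k]] - est1$components[[k]]), 1e-8)
})

test_that("independent (noisier) unbound ensembles inflate the uncertainty", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 20, seed = 23)
  enss <- sliced_three_ensembles(toy, tr)
  est_sliced <- three_trajectory_estimate(enss$complex, enss$host, enss$guest)
  # host ensemble with extra internal-energy variance (larger jitter)
  hi <- which(toy$topology$partition == "host")
  th <- subset_topology(toy$topology, hi)
  noisy <- make_ensemble(list(frame = toy$frame[hi, , drop = FALSE],
                              tails = toy$tails), 20,
                         jitter_sigma = 0.12, seed = 29)
  ens_noisy <- ensemble_energetics(th, toy$params, noisy, role = "host",
                                   solvent = "gb")
  est_noisy <- three_trajectory_estimate(enss$complex, ens_noisy, enss$guest)
  expect_gt(est_noisy$dg_se, est_sliced$dg_se)
  expect_gt(est_noisy$se[["internal"]], est_sliced$se[["internal"]])
})

test_that("single-frame ensembles give zero uncertainty and plain differences", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 1, seed = 2)
  enss <- sliced_three_ensembles(toy, tr)
  est <- three_trajectory_estimate(enss$complex, enss$host, enss$guest)
  expect_equal(est$dg_se, 0)
  expect_true(all(est$se == 0))
  expect_equal(est$dg_total, sum(est$components), tolerance = 1e-12)
})

test_that("dielectric scan rescales stored terms exactly", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 8, switch_prob = 0.3, seed = 31)
  enss <- sliced_three_ensembles(toy, tr)
  base <- three_trajectory_estimate(enss$complex, enss$host, enss$guest,
                                    eps_in = 1)
  sc1 <- dielectric_scan(enss, "3traj", eps_list = 1)
  expect_equal(sc1$estimates[[1]]$dg_total, base$dg_total, tolerance = 1e-12)
  sc <- dielectric_scan(enss, "3traj", eps_list = c(1, 2, 4, 6))
  ele <- vapply(sc$estimates, function(e) e$components[["ele"]], numeric(1))
  expect_lt(diff(range(ele * c(1, 2, 4, 6))), 1e-9)
  # vdW, internal, nonpolar do not respond to the dielectric
  for (k in c("vdw", "internal", "nonpolar")) {
    v <- vapply(sc$estimates, function(e) e$components[[k]], numeric(1))
    expect_lt(diff(range(v)), 1e-10)
  }
  # PB ensembles refuse to scan
  expect_error(dielectric_scan(structure(list(
    complex = structure(list(solvent = "pb"), class = "ensemble_energetics")),
    names = "complex"), "1traj"), "PB scan unsupported")
})

test_that("a polar-dominated complex responds monotonically to eps_in", {
  # opposite net charges: the eps-dependent part of the estimate is
  # negative, so screening it weakens binding monotonically
  ak <- list(h = atom_kind("h", 12, 1.8, 0.1, 2.0, 0.8),
             g = atom_kind("g", 12, 1.8, 0.1, 2.0, 0.8))
  params <- parameter_set(ak, list("h-h" = bond_param(300, 1.5),
                                   "g-g" = bond_param(300, 1.5)),
                          list(), list())
  topo <- topology(data.frame(name = sprintf("A%d", 1:4),
                              type = c("h", "h", "g", "g"),
                              charge = c(-1, 0, 1, 0), mass = 12),
                   rbind(c(1L, 2L), c(3L, 4L)),
                   partition = c("host", "host", "guest", "guest"))
  frames <- list(rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 4, 0), c(1.5, 4, 0)))
  ens <- ensemble_energetics(topo, params, frames, role = "complex",
                             solvent = "gb")
  sc <- dielectric_scan(ens, "1traj", eps_list = c(1, 2, 4, 6))
  expect_true(all(diff(sc$summary$dg_total) > 0))
})

test_that("dielectric response rows conserve the eps-dependent total", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 8, switch_prob = 0.3, seed = 37)
  enss <- sliced_three_ensembles(toy, tr)
  eps <- c(1, 2, 4, 6)
  for (mode in c("1traj", "3traj")) {
    sc <- dielectric_scan(enss, mode, eps)
    dec <- decompose_dielectric_response(enss, mode, eps)
    resid <- sc$summary$dg_total - dec$total_eps_dependent
    expect_lt(diff(range(resid)), 1e-9)  # constant = eps-independent part
    expect_equal(dec$total_eps_dependent,
                 dec$row1_inter_ele + dec$row2_intra_ele + dec$row3_polar,
                 tolerance = 1e-12)
  }
  dec1 <- decompose_dielectric_response(enss$complex, "1traj", eps)
  expect_true(all(dec1$row2_intra_ele == 0))
})

test_that("ghost-guest response has zero inter-molecular electrostatics", {
  ak <- list(h = atom_kind("h", 12, 1.8, 0.1, 1.7, 0.72),
             x = atom_kind("x", 12, 1.8, 0.05, 1.7, 0.7))
  params <- parameter_set(ak, list("h-h" = bond_param(300, 1.5),
                                   "x-x" = bond_param(300, 1.5)),
                          list(), list())
  topo <- topology(data.frame(name = sprintf("A%d", 1:4),
                              type = c("h", "h", "x", "x"),
                              charge = c(0.5, -0.5, 0, 0), mass = 12),
                   rbind(c(1L, 2L), c(3L, 4L)),
                   partition = c("host", "host", "guest", "guest"))
  toy <- list(topology = topo, params = params,
              frame = rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 3, 0),
                            c(1.5, 3, 0)))
  tr <- lapply(1:3, function(i) toy$frame + 0.01 * i)
  enss <- sliced_three_ensembles(toy, tr)
  dec <- decompose_dielectric_response(enss, "3traj", c(1, 2, 4))
  expect_true(all(dec$row1_inter_ele == 0))
})

test_that("estimates are frame-order invariant; duplication halves naive SEM", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 10, switch_prob = 0.4, seed = 41)
  ens <- ensemble_energetics(toy$topology, toy$params, tr, role = "complex",
                             solvent = "gb")
  perm <- rev(seq_along(tr$frames))
  ens_p <- ensemble_energetics(toy$topology, toy$params, tr$frames[perm],
                               role = "complex", solvent = "gb")
  e1 <- single_trajectory_estimate(ens)
  e2 <- single_trajectory_estimate(ens_p)
  expect_equal(e1$dg_total, e2$dg_total, tolerance = 1e-12)
  expect_equal(e1$dg_se, e2$dg_se, tolerance = 1e-12)
  ens_d <- ensemble_energetics(toy$topology, toy$params,
                               c(tr$frames, tr$frames), role = "complex",
                               solvent = "gb")
  e3 <- single_trajectory_estimate(ens_d)
  # duplicating every frame shrinks the naive SEM by ~1/sqrt(2)
  # (exactly sqrt((n-1)/(2n-1)) with the n-1 variance denominator)
  ratio <- e3$dg_se / e1$dg_se
  expect_equal(ratio, sqrt(9 / 19), tolerance = 1e-10)
})

test_that("convergence diagnostics separate noise from drift", {
  set.seed(101)
  d_noise <- convergence_diagnostics(rnorm(10000), block_count = 10)
  expect_equal(d_noise$verdict, "converged")
  expect_true(d_noise$slope_ci[1] <= 0 && d_noise$slope_ci[2] >= 0)
  d_ramp <- convergence_diagnostics(seq(0, 5, length.out = 2000) +
                                      rnorm(2000, sd = 0.2))
  expect_equal(d_ramp$verdict, "non-convergent")
  d_const <- convergence_diagnostics(rep(3.2, 100))
  expect_true(all(d_const$block_sem == 0))
  expect_equal(d_const$verdict, "converged")
  expect_error(convergence_diagnostics(rnorm(10), block_count = 10),
               "shorter")
})

test_that("uncertainty estimators match closed forms and simulations", {
  expect_equal(uncertainty(rep(1.5, 50)), 0)
  expect_equal(uncertainty(c(0, 2)), 1.0)
  set.seed(55)
  v <- rnorm(1e4)
  expect_equal(uncertainty(v), 0.01, tolerance = 0.1)
  # block SEM on iid data agrees with the naive estimate
  expect_equal(uncertainty(v, "block", block_size = 100), 0.01,
               tolerance = 0.25)
  expect_error(uncertainty(rnorm(10), "block", block_size = 10), "blocks")
})
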