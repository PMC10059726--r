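test_that("reference pair energies match closed forms", {
  # bond exactly at r0 contributes nothing
  s <- pair_system(charges = c(0, 0), eps = 0, bond = bond_param(300, 1.5))
  e <- total_energy(s$topo, s$params, rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(e[["total"]], 0, tolerance = 1e-12)
  # Coulomb's law with k_e = 332.0637 kcal A / (mol e^2)
  s2 <- pair_system(charges = c(1, 1), eps = 0)
  x <- rbind(c(0, 0, 0), c(1, 0, 0))
  e1 <- total_energy(s2$topo, s2$params, x, eps_in = 1)
  expect_equal(e1[["ele"]], 332.0637, tolerance = 1e-10)
  # exact 1/eps scaling
  e2 <- total_energy(s2$topo, s2$params, x, eps_in = 2)
  expect_equal(e2[["ele"]], e1[["ele"]] / 2, tolerance = 1e-12)
  # coincident interacting atoms are an error
  expect_error(total_energy(s2$topo, s2$params, rbind(c(0, 0, 0), c(0, 0, 0))),
               "zero interatomic distance")
})

test_that("ele * eps_in is constant over the dielectric range", {
  toy <- make_toy_hostguest(toy_spec())
  vals <- vapply(c(1, 2, 4, 6), function(e)
    total_energy(toy$topology, toy$params, toy$frame, e)[["ele"]] * e,
    numeric(1))
  expect_lt(diff(range(vals)), 1e-9)
})

# independent O(N^2) reference: plain loops, no shared code with the kernel
brute_force_nonbonded <- function(topo, params, x, eps_in) {
  n <- nrow(x)
  kinds <- params$atom_kinds
  excl <- paste(topo$excl[, 1], topo$excl[, 2])
  p14 <- paste(topo$pairs14[, 1], topo$pairs14[, 2])
  vdw <- ele <- vdw14 <- ele14 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tag <- paste(i, j)
    if (tag %in% excl) next
    r <- sqrt(sum((x[i, ] - x[j, ])^2))
    ki <- kinds[[topo$atoms$type[i]]]; kj <- kinds[[topo$atoms$type[j]]]
    rmin <- ki$lj_rmin_half + kj$lj_rmin_half
    epsij <- sqrt(ki$lj_epsilon * kj$lj_epsilon)
    lj <- epsij * ((rmin / r)^12 - 2 * (rmin / r)^6)
    coul <- 332.0637 * topo$atoms$charge[i] * topo$atoms$charge[j] /
      (eps_in * r)
    if (tag %in% p14) {
      vdw14 <- vdw14 + lj / params$scale_vdw_14
      ele14 <- ele14 + coul / params$scale_ee_14
    } else {
      vdw <- vdw + lj
      ele <- ele + coul
    }
  }
  c(vdw = vdw, ele = ele, vdw14 = vdw14, ele14 = ele14)
}

test_that("pairwise sums agree with a brute-force oracle on random systems", {
  set.seed(11)
  for (rep in 1:4) {
    n <- 20
    q <- round(runif(n, -0.5, 0.5), 3)
    q <- q - sum(q) / n  # neutral overall
    s <- chain_system(n, charges = q)
    x <- zigzag_coords(n) + matrix(rnorm(3 * n, sd = 0.3), n, 3)
    e <- total_energy(s$topo, s$params, x, eps_in = 2)
    ref <- brute_force_nonbonded(s$topo, s$params, x, eps_in = 2)
    expect_equal(e[["vdw"]], ref[["vdw"]], tolerance = 1e-10)
    expect_equal(e[["ele"]], ref[["ele"]], tolerance = 1e-10)
    expect_equal(e[["vdw14"]], ref[["vdw14"]], tolerance = 1e-10)
    expect_equal(e[["ele14"]], ref[["ele14"]], tolerance = 1e-10)
  }
})

test_that("components are invariant under rigid-body motion", {
  toy <- make_toy_hostguest(toy_spec())
  e0 <- total_energy(toy$topology, toy$params, toy$frame)
  for (seed in 1:3) {
    x2 <- random_rigid_motion(toy$frame, seed)
    e1 <- total_energy(toy$topology, toy$params, x2)
    expect_lt(max(abs(unclass(e1) - unclass(e0))), 1e-8)
  }
})

test_that("energy components always sum to the reported total", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 5, switch_prob = 0.3, seed = 2)
  for (x in tr$frames) {
    e <- total_energy(toy$topology, toy$params, x)
    expect_equal(e[["total"]],
                 sum(e[c("bond", "angle", "torsion", "vdw", "ele",
                         "vdw14", "ele14")]), tolerance = 1e-9)
  }
})

test_that("partitioned energy reconstructs the total and flags crossings", {
  set.seed(3)
  # random two-molecule system: two 4-atom chains
  q <- c(0.25, -0.25, 0.25, -0.25, 0.5, -0.5, 0.5, -0.5)
  ak <- list(a = atom_kind("a", 12, 1.9, 0.1, 1.7, 0.72))
  params <- parameter_set(ak, list("a-a" = bond_param(300, 1.5)),
                          list("a-a-a" = angle_param(50, 109.5)),
                          list("a-a-a-a" = torsion_param(3, 0.4, 0)))
  topo <- topology(data.frame(name = sprintf("A%d", 1:8), type = "a",
                              charge = q, mass = 12),
                   rbind(cbind(1:3, 2:4), cbind(5:7, 6:8)),
                   partition = rep(c("host", "guest"), each = 4))
  x <- rbind(zigzag_coords(4), sweep(zigzag_coords(4), 2, c(0, 4, 1), `+`)) +
    matrix(rnorm(24, sd = 0.1), 8, 3)
  pe <- partition_energy(topo, params, x, eps_in = 2)
  et <- total_energy(topo, params, x, eps_in = 2)
  expect_equal(pe$intra_host[["total"]] + pe$intra_guest[["total"]] +
                 pe$inter_vdw + pe$inter_ele, et[["total"]],
               tolerance = 1e-9)
  # a bond crossing the partition is rejected
  expect_error(partition_energy(topo, params, x, host_idx = c(1:3, 5),
                                guest_idx = c(4, 6:8)), "crosses")
})

test_that("ghost guest and host-only partitions give zero inter terms", {
  ak <- list(a = atom_kind("a", 12, 1.9, 0.1, 1.7, 0.72),
             ghost = atom_kind("ghost", 12, 1.9, 0, 1.7, 0))
  params <- parameter_set(ak, list("a-a" = bond_param(300, 1.5),
                                   "ghost-ghost" = bond_param(300, 1.5)),
                          list(), list())
  topo <- topology(data.frame(name = sprintf("A%d", 1:4),
                              type = c("a", "a", "ghost", "ghost"),
                              charge = c(0.5, -0.5, 0, 0), mass = 12),
                   rbind(c(1L, 2L), c(3L, 4L)),
                   partition = c("host", "host", "guest", "guest"))
  x <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(0, 3, 0), c(1.5, 3, 0))
  pe <- partition_energy(topo, params, x)
  expect_equal(pe$inter_vdw, 0)
  expect_equal(pe$inter_ele, 0)
  # host-only topology: empty guest set, intra_host equals the total
  topo2 <- topo; topo2$partition <- rep("host", 4)
  pe2 <- partition_energy(topo2, params, x,
                          host_idx = 1:4, guest_idx = integer())
  expect_equal(pe2$inter_vdw + pe2$inter_ele, 0)
  expect_equal(pe2$intra_host[["total"]],
               total_energy(topo, params, x)[["total"]], tolerance = 1e-9)
})

test_that("analytic gradient matches finite differences", {
  toy <- make_toy_hostguest(toy_spec())
  g <- as.numeric(mm_gradient(toy$topology, toy$params, toy$frame))
  nfr <- nrow(toy$frame)
  f <- function(p) total_energy(toy$topology, toy$params,
                                matrix(p, nfr, 3))[["total"]]
  p0 <- as.numeric(toy$frame); h <- 1e-5
  set.seed(12)
  for (i in sample(length(p0), 12)) {
    pp <- p0; pp[i] <- pp[i] + h
    pm <- p0; pm[i] <- pm[i] - h
    expect_equal(g[i], (f(pp) - f(pm)) / (2 * h), tolerance = 1e-5)
  }
})
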