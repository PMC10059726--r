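test_that("exclusion and 1-4 sets rebuild from a 4-atom chain", {
  s <- chain_system(4)
  excl <- s$topo$excl
  key <- paste(excl[, 1], excl[, 2])
  expect_setequal(key, c("1 2", "2 3", "3 4", "1 3", "2 4"))
  expect_equal(unname(s$topo$pairs14), rbind(c(1L, 4L)), ignore_attr = TRUE)
})

test_that("exclusion builder agrees with brute-force bond-graph search", {
  set.seed(7)
  for (rep in 1:12) {
    n <- sample(5:9, 1)
    # random connected graph: a spanning chain plus extra random edges
    bonds <- cbind(1:(n - 1), 2:n)
    extra <- sample(n, 2)
    if (extra[1] != extra[2] && abs(extra[1] - extra[2]) > 1)
      bonds <- rbind(bonds, sort(extra))
    adj <- matrix(FALSE, n, n)
    adj[bonds] <- TRUE; adj[bonds[, 2:1]] <- TRUE
    # BFS shortest path distances
    dist <- matrix(Inf, n, n); diag(dist) <- 0
    for (s0 in 1:n) {
      q <- s0
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        for (w in which(adj[v, ]))
          if (dist[s0, w] > dist[s0, v] + 1) {
            dist[s0, w] <- dist[s0, v] + 1; q <- c(q, w)
          }
      }
    }
    topo <- topology(data.frame(name = sprintf("A%d", 1:n), type = "a",
                                charge = 0, mass = 12), bonds)
    pk <- function(m) paste(m[, 1], m[, 2])
    want_excl <- which(upper.tri(dist) & (dist == 1 | dist == 2),
                       arr.ind = TRUE)
    want_14 <- which(upper.tri(dist) & dist == 3, arr.ind = TRUE)
    expect_setequal(pk(topo$excl), pk(want_excl))
    expect_setequal(pk(topo$pairs14), pk(want_14))
  }
})

test_that("topology validation rejects bad input", {
  atoms <- data.frame(name = c("A", "B"), type = "a", charge = c(0.4, 0.2),
                      mass = 12)
  expect_error(topology(atoms, rbind(c(1L, 3L))), "out of range")
  expect_error(topology(atoms, rbind(c(1L, 2L))), "integer")
  atoms$charge <- c(0.5, 0.5)
  expect_silent(topology(atoms, rbind(c(1L, 2L))))
})

test_that("JSON topology schema round-trips and validates", {
  toy <- make_toy_hostguest(toy_spec())
  path <- tempfile(fileext = ".json")
  write_topology_json(toy$topology, toy$params, path)
  got <- read_topology_json(path)
  expect_equal(got$topology$bonds, toy$topology$bonds)
  expect_equal(got$topology$partition, toy$topology$partition)
  e0 <- total_energy(toy$topology, toy$params, toy$frame)
  e1 <- total_energy(got$topology, got$params, toy$frame)
  expect_equal(unclass(e1), unclass(e0), tolerance = 1e-12)

  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  doc$version <- 99
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_topology_json(bad), "version")
})

test_that("a bonded term without parameters errors naming the key", {
  s <- chain_system(4)
  s$params$torsion_params[["a-a-a-a"]] <- NULL
  path <- tempfile(fileext = ".json")
  write_topology_json(s$topo, s$params, path)
  expect_error(read_topology_json(path), "a-a-a-a")
})

test_that("prmtop round-trip preserves energies and metadata", {
  toy <- make_toy_hostguest(toy_spec())
  path <- tempfile(fileext = ".prmtop")
  write_prmtop(toy$topology, toy$params, path)
  got <- read_prmtop(path)
  e0 <- total_energy(toy$topology, toy$params, toy$frame)
  e1 <- total_energy(got$topology, got$params, toy$frame)
  expect_lt(max(abs(unclass(e1) - unclass(e0))), 1e-6)
  expect_equal(got$topology$partition, toy$topology$partition)
  # charge unit convention: stored value is q * 18.2223
  txt <- readLines(path)
  i <- grep("FLAG CHARGE", txt)
  first_charge <- as.numeric(strsplit(trimws(txt[i + 2]),
                                      "[[:space:]]+")[[1]][1])
  expect_equal(first_charge, toy$topology$atoms$charge[1] * 18.2223,
               tolerance = 1e-10)
  s <- single_atom_system(charge = 1)
  p1 <- tempfile(); write_prmtop(s$topo, s$params, p1)
  expect_equal(read_prmtop(p1)$topology$atoms$charge, 1.0, tolerance = 1e-12)
})

test_that("truncated prmtop errors name the missing section", {
  toy <- make_toy_hostguest(toy_spec())
  path <- tempfile(fileext = ".prmtop")
  write_prmtop(toy$topology, toy$params, path)
  txt <- readLines(path)
  i <- grep("%FLAG MASS", txt)
  j <- grep("%FLAG", txt)
  nxt <- min(j[j > i])
  writeLines(txt[-(i:(nxt - 1))], path)
  expect_error(read_prmtop(path), "MASS")
})

test_that("multi-model PDB reading and atom-count validation", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 3, seed = 5)
  path <- tempfile(fileext = ".pdb")
  write_trajectory(tr, path, "pdb", toy$topology$atoms$name)
  got <- read_trajectory(path, topo = toy$topology)
  na_frame <- nrow(toy$frame)
  expect_length(got$frames, 3)
  expect_equal(nrow(got$frames[[1]]), na_frame)
  expect_lt(max(abs(got$frames[[2]] - tr$frames[[2]])), 5.1e-4)  # 3 decimals
  # drop one atom from frame 2 -> error naming the frame
  txt <- readLines(path)
  atom2 <- which(startsWith(txt, "ATOM"))
  drop <- atom2[na_frame + 1]
  writeLines(txt[-drop], path)
  expect_error(read_trajectory(path), "frame 2")
})

test_that("XYZ trajectories round-trip to well below 1e-6 Angstrom", {
  toy <- make_toy_hostguest(toy_spec())
  tr <- make_ensemble(toy, 4, seed = 9)
  path <- tempfile(fileext = ".xyz")
  write_trajectory(tr, path, "xyz", toy$topology$atoms$name)
  got <- read_trajectory(path, topo = toy$topology)
  expect_length(got$frames, 4)
  for (f in 1:4)
    expect_lt(max(abs(got$frames[[f]] - tr$frames[[f]])), 1e-6)
})

test_that("experiment CSV reading handles the shipped table and edge cases", {
  path <- system.file("extdata", "experiment_dg.csv", package = "endpointr")
  tab <- read_experiment_csv(path)
  expect_equal(nrow(tab), 13)
  expect_equal(tab$dg_exp_kcal[tab$id == "G1"], -6.53)
  empty <- tempfile(fileext = ".csv"); file.create(empty)
  expect_equal(nrow(read_experiment_csv(empty)), 0)
  dup <- tempfile(fileext = ".csv")
  writeLines(c("id,dg_exp_kcal", "G1,-6.5", "G1,-7.0"), dup)
  expect_error(read_experiment_csv(dup), "duplicate")
  bad <- tempfile(fileext = ".csv")
  writeLines(c("id,dg_exp_kcal", "G1,abc"), bad)
  expect_error(read_experiment_csv(bad), "non-numeric")
})
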