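#' Toy host-guest system specification
#'
#' The generator emulates a carboxylated macrocycle: a closed ring of
#' beads carrying pendant tails whose terminal bead is charged (a
#' -CH2-COO(-)-like rim), with a linear charged guest threaded through the
#' cavity. All parameters are made-up but physically plausible bead values
#' (bond k ~300 kcal/mol/A^2, LJ epsilon ~0.1 kcal/mol); the fixtures test
#' machinery, not chemistry.
#'
#' @param n_ring_beads beads in the macrocycle ring (>= 6)
#' @param n_tails pendant tails, attached to evenly spaced ring beads
#' @param tail_length beads per tail (>= 1); the terminal bead is charged
#' @param guest_length beads in the linear guest (>= 2)
#' @param tail_charge charge on each tail terminal bead, e (integer)
#' @param guest_charge charge on the guest head bead, e (integer)
#' @param seed RNG seed making every generated artifact reproducible
#' @return list of class `"toy_spec"`
#' @export
toy_spec <- function(n_ring_beads = 12, n_tails = 6, tail_length = 2,
                     guest_length = 4, tail_charge = -1, guest_charge = 1,
                     seed = 1) {
  if (n_ring_beads < 6) stop("toy_spec: need at least 6 ring beads")
  if (n_tails < 1 || n_tails > n_ring_beads)
    stop("toy_spec: n_tails must be in 1..n_ring_beads")
  if (tail_length < 1) stop("toy_spec: tail_length must be >= 1")
  if (guest_length < 2) stop("toy_spec: guest_length must be >= 2")
  if (tail_charge != round(tail_charge) || guest_charge != round(guest_charge))
    stop("toy_spec: bead charges must be integers (integer species charge)")
  structure(list(n_ring_beads = n_ring_beads, n_tails = n_tails,
                 tail_length = tail_length, guest_length = guest_length,
                 tail_charge = tail_charge, guest_charge = guest_charge,
                 seed = seed),
            class = "toy_spec")
}

toy_parameter_set <- function(torsion_keys) {
  kinds <- list(
    cr = atom_kind("cr", 12.011, 1.908, 0.086, 1.7, 0.72),
    cm = atom_kind("cm", 12.011, 1.908, 0.109, 1.7, 0.72),
    ct = atom_kind("ct", 15.999, 1.661, 0.210, 1.5, 0.85),
    gp = atom_kind("gp", 14.007, 1.824, 0.170, 1.55, 0.79),
    gc = atom_kind("gc", 12.011, 1.908, 0.109, 1.7, 0.72))
  bonds <- list()
  for (k in c("cr-cr", "cm-cr", "cm-cm", "cm-ct", "cr-ct", "gc-gp", "gc-gc"))
    bonds[[canon_bond_key(split_key(k))]] <- bond_param(300, 1.5)
  mk_angles <- function(keys, theta0) {
    out <- list()
    for (k in keys) out[[canon_angle_key(split_key(k))]] <-
        angle_param(50, theta0)
    out
  }
  # ring vertices keep the polygon angle; everything else is tetrahedral-ish
  angles <- c(mk_angles("cr-cr-cr", 150),
              mk_angles(c("cr-cr-cm", "cr-cr-ct"), 105),
              mk_angles(c("cr-cm-cm", "cr-cm-ct", "cm-cm-cm", "cm-cm-ct",
                          "gp-gc-gc", "gc-gc-gc"), 109.5))
  torsions <- list()
  tail_types <- c("cm", "ct")
  for (k in torsion_keys) {
    key <- canon_torsion_key(split_key(k))
    if (!is.null(torsions[[key]])) next
    torsions[[key]] <- if (any(split_key(key) %in% tail_types))
      torsion_param(c(1, 2, 3), c(0.30, 0.25, 0.45), c(0, 180, 0))
    else torsion_param(2, 1.0, 180)
  }
  parameter_set(kinds, bonds, angles, torsions)
}

#' Generate a toy host-guest complex
#'
#' Builds a macrocyclic bead ring with pendant charged tails and a linear
#' guest placed through the cavity, fully parameterized (bonds, angles,
#' Fourier torsions on the tails, Lennard-Jones, charges, GB radii).
#' Deterministic per seed; no bonded term crosses the host/guest
#' partition, and each species carries an integer net charge.
#'
#' @param spec a [toy_spec()]
#' @return list with `topology`, `params`, `frame` (n x 3 coordinates) and
#'   `tails` (tail atom bookkeeping used by [make_ensemble()])
#' @export
make_toy_hostguest <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "toy_spec"))
  nr <- spec$n_ring_beads
  r_bond <- 1.5
  R <- r_bond / (2 * sin(pi / nr))
  th <- 2 * pi * (seq_len(nr) - 1) / nr
  ring <- cbind(R * cos(th), R * sin(th), 0)
  coords <- ring
  names_ <- sprintf("R%d", seq_len(nr))
  types <- rep("cr", nr)
  charges <- rep(0, nr)
  bonds <- cbind(seq_len(nr), c(seq_len(nr)[-1], 1L))
  tails <- list()
  anchor_ids <- round(seq(1, nr, length.out = spec$n_tails + 1))[seq_len(spec$n_tails)]
  pitch <- 35 * pi / 180  # out-of-plane tilt keeps tail angles non-collinear
  for (t in seq_along(anchor_ids)) {
    a <- anchor_ids[t]
    radial <- c(cos(th[a]), sin(th[a]), 0)
    up <- c(0, 0, 1)
    prev <- a
    atoms_t <- integer(0)
    pos <- ring[a, ]
    for (k in seq_len(spec$tail_length)) {
      # zigzag outward: ~1.45 A bonds, ~110 deg angles at each bead
      pos <- pos + 1.45 * (cos(pitch) * radial + sin(pitch) * up * (-1)^k)
      coords <- rbind(coords, pos)
      id <- nrow(coords)
      last <- k == spec$tail_length
      names_ <- c(names_, sprintf("T%d%d", t, k))
      types <- c(types, if (last) "ct" else "cm")
      charges <- c(charges, if (last) spec$tail_charge else 0)
      bonds <- rbind(bonds, c(prev, id))
      prev <- id
      atoms_t <- c(atoms_t, id)
    }
    tails[[t]] <- list(anchor = a, atoms = atoms_t,
                       axis = c(-sin(th[a]), cos(th[a]), 0),
                       origin = ring[a, ])
  }
  n_host <- nrow(coords)
  gl <- spec$guest_length
  z0 <- -(gl - 1) * 1.45 / 2
  guest <- cbind(0.35 * (-1)^(seq_len(gl)), 0, z0 + (seq_len(gl) - 1) * 1.45)
  coords <- rbind(coords, guest)
  names_ <- c(names_, sprintf("G%d", seq_len(gl)))
  types <- c(types, "gp", rep("gc", gl - 1))
  charges <- c(charges, spec$guest_charge, rep(0, gl - 1))
  bonds <- rbind(bonds, cbind(n_host + seq_len(gl - 1),
                              n_host + seq_len(gl - 1) + 1L))
  atoms <- data.frame(name = names_, type = types, charge = charges,
                      mass = NA_real_, stringsAsFactors = FALSE)
  atoms$mass <- c(cr = 12.011, cm = 12.011, ct = 15.999, gp = 14.007,
                  gc = 12.011)[atoms$type]
  partition <- c(rep("host", n_host), rep("guest", gl))
  tors <- derive_torsions(bonds, nrow(coords))
  tkeys <- unique(vapply(seq_len(nrow(tors)), function(d)
    canon_torsion_key(types[tors[d, ]]), character(1)))
  params <- toy_parameter_set(tkeys)
  topo <- topology(atoms, bonds, partition = partition)
  check_parameters(topo, params)
  rownames(coords) <- NULL
  list(topology = topo, params = params, frame = coords, tails = tails,
       spec = spec)
}

rotate_about_axis <- function(points, origin, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  p <- sweep(points, 2, origin)
  cosA <- cos(angle); sinA <- sin(angle)
  rot <- t(apply(p, 1, function(v)
    v * cosA + pracma_cross(u, v) * sinA + u * sum(u * v) * (1 - cosA)))
  sweep(rot, 2, origin, `+`)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate a pseudo-trajectory for a toy system
#'
#' Per-frame Gaussian coordinate jitter plus a two-state tail-rotation
#' switch: each tail is either "open" (pointing outward, as built) or
#' "closed" (rotated out of the rim plane), emulating the rotation of
#' charged rim tails that reshapes the host surface without collapsing
#' onto the threaded guest. With a constant
#' `switch_prob` each tail flips state with that probability per frame,
#' producing a bimodal tail-torsion distribution; passing a vector of
#' per-frame closed-state probabilities (a time-ramped schedule) produces
#' a systematic drift in the polar energetics. Deterministic per seed.
#'
#' @param toy result of [make_toy_hostguest()] (or a bare frame, in which
#'   case only jitter is applied)
#' @param n_frames frames to generate
#' @param jitter_sigma Gaussian coordinate noise, Angstrom
#' @param switch_prob per-frame tail flip probability (scalar), or a
#'   length-`n_frames` vector of closed-state occupation probabilities
#' @param closed_angle rotation from open to closed, radians
#' @param seed RNG seed
#' @return a [trajectory()]
#' @export
make_ensemble <- function(toy, n_frames, jitter_sigma = 0.03,
                          switch_prob = 0, closed_angle = -pi / 2, seed = 1) {
  frame <- if (is.list(toy) && !is.null(toy$frame)) toy$frame else as.matrix(toy)
  tails <- if (is.list(toy)) toy$tails else NULL
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  scheduled <- length(switch_prob) > 1
  if (scheduled && length(switch_prob) != n_frames)
    stop("make_ensemble: switch schedule must have one probability per frame")
  state <- rep(FALSE, length(tails))
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    if (length(tails)) {
      if (scheduled) {
        state <- stats::runif(length(tails)) < switch_prob[f]
      } else if (switch_prob > 0) {
        flip <- stats::runif(length(tails)) < switch_prob
        state <- xor(state, flip)
      }
    }
    x <- frame
    for (t in seq_along(tails)) {
      if (!state[t]) next
      tl <- tails[[t]]
      x[tl$atoms, ] <- rotate_about_axis(x[tl$atoms, , drop = FALSE],
                                         tl$origin, tl$axis, closed_angle)
    }
    x <- x + matrix(stats::rnorm(length(x), sd = jitter_sigma), nrow(x), 3)
    frames[[f]] <- x
  }
  trajectory(frames, times = (seq_len(n_frames) - 1) * 10)
}

#' Printed reference tables of the WP6 host-guest benchmark
#'
#' Returns the 13-guest experimental affinity column and the sixteen
#' calculated-affinity columns (single- and three-trajectory x PB/GB x
#' GAFF/GAFF2 x TIP3P/SPC-E) shipped as plain-CSV transcriptions under
#' `inst/extdata`, together with the published summary metric rows
#' (RMSE, MSE, Kendall tau, PI, rounded to one decimal) for
#' cross-checking [compute_metrics()].
#'
#' @return list with `experiment` (an
#'   [experiment table][read_experiment_csv()]), `tables` (named list of
#'   four data frames of per-guest estimates and their reported standard
#'   errors) and `printed_metrics` (data frame of published summary rows)
#' @export
table_fixtures <- function() {
  dir <- system.file("extdata", package = "endpointr")
  expt <- read_experiment_csv(file.path(dir, "experiment_dg.csv"))
  files <- c(single_pb = "table_single_pbsa.csv",
             single_gb = "table_single_gbsa.csv",
             three_pb = "table_three_pbsa.csv",
             three_gb = "table_three_gbsa.csv")
  tables <- lapply(files, function(f)
    read.csv(file.path(dir, f), stringsAsFactors = FALSE))
  printed <- read.csv(file.path(dir, "printed_quality_metrics.csv"),
                      stringsAsFactors = FALSE)
  list(experiment = expt, tables = tables, printed_metrics = printed)
}
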