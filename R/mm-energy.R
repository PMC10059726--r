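#' Gas-phase molecular-mechanics energy
#'
#' Single-frame AMBER-style potential: \eqn{E = \sum k(r-r_0)^2 +
#' \sum k(\theta-\theta_0)^2 + \sum (V_n/2)(1+\cos(n\phi-\gamma)) +
#' \sum A/r^{12} - B/r^6 + \sum k_e q_i q_j/(\epsilon_{in} r)}.
#' All non-excluded pairs interact with no distance cutoff and no
#' periodicity (post-processing of extracted snapshots). 1-4 electrostatics
#' are divided by `scale_ee_14` and 1-4 Lennard-Jones by `scale_vdw_14`.
#' Lennard-Jones cross terms use Lorentz-Berthelot combination (arithmetic
#' rmin/2, geometric epsilon). The Coulomb constant is
#' 332.0637 kcal A mol^-1 e^-2.
#'
#' @param topo a [topology()]
#' @param params a [parameter_set()]
#' @param frame numeric matrix (n_atoms x 3), Angstrom
#' @param eps_in interior dielectric constant (>= 1)
#' @return named numeric of class `"energy_components"` with elements
#'   `bond`, `angle`, `torsion`, `vdw`, `ele`, `vdw14`, `ele14`, `total`.
#' @export
total_energy <- function(topo, params, frame, eps_in = 1) {
  ctx <- make_energy_context(topo, params)
  energy_from_context(ctx, frame, eps_in)
}

energy_components <- function(bond = 0, angle = 0, torsion = 0, vdw = 0,
                              ele = 0, vdw14 = 0, ele14 = 0) {
  v <- c(bond = bond, angle = angle, torsion = torsion, vdw = vdw,
         ele = ele, vdw14 = vdw14, ele14 = ele14)
  structure(c(v, total = sum(v)), class = "energy_components")
}

#' @export
print.energy_components <- function(x, ...) {
  cat("MM energy components (kcal/mol):\n")
  print(round(unclass(x), 6))
  invisible(x)
}

#' Precompute per-topology energy arrays
#'
#' Resolves parameter lookups and pair lists once so that per-frame energy,
#' gradient and partition evaluations are pure array arithmetic. Called
#' internally by the per-frame functions; call it directly when evaluating
#' many frames of the same system.
#'
#' @inheritParams total_energy
#' @return list of class `"energy_context"`
#' @export
make_energy_context <- function(topo, params) {
  check_parameters(topo, params)
  ty <- topo$atoms$type
  n <- n_atoms(topo)
  kinds <- params$atom_kinds
  rmh <- vapply(ty, function(t) kinds[[t]]$lj_rmin_half, numeric(1))
  eps <- vapply(ty, function(t) kinds[[t]]$lj_epsilon, numeric(1))
  q <- topo$atoms$charge

  bk <- br0 <- numeric(nrow(topo$bonds))
  for (b in seq_len(nrow(topo$bonds))) {
    p <- params$bond_params[[canon_bond_key(ty[topo$bonds[b, ]])]]
    bk[b] <- p$k; br0[b] <- p$r0
  }
  ak <- ath0 <- numeric(nrow(topo$angles))
  for (a in seq_len(nrow(topo$angles))) {
    p <- params$angle_params[[canon_angle_key(ty[topo$angles[a, ]])]]
    ak[a] <- p$k; ath0[a] <- p$theta0 * pi / 180
  }
  # expand torsions to one row per Fourier component
  tq <- matrix(integer(), ncol = 4); tn <- tv <- tg <- numeric(); tw <- integer()
  for (d in seq_len(nrow(topo$torsions))) {
    p <- params$torsion_params[[canon_torsion_key(ty[topo$torsions[d, ]])]]
    comp <- p$components
    if (nrow(comp) == 0L) next
    tq <- rbind(tq, matrix(rep(topo$torsions[d, ], nrow(comp)),
                           ncol = 4, byrow = TRUE))
    tn <- c(tn, comp$n); tv <- c(tv, comp$half_barrier)
    tg <- c(tg, comp$phase * pi / 180)
    tw <- c(tw, rep(d, nrow(comp)))
  }

  pair_key <- function(m) m[, 1] + n * m[, 2]
  all_pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  colnames(all_pairs) <- NULL
  excl_keys <- c(if (nrow(topo$excl)) pair_key(topo$excl) else numeric(),
                 if (nrow(topo$pairs14)) pair_key(topo$pairs14) else numeric())
  reg <- all_pairs[!(pair_key(all_pairs) %in% excl_keys), , drop = FALSE]
  p14 <- topo$pairs14

  lj_ab <- function(m) {
    rmin <- rmh[m[, 1]] + rmh[m[, 2]]
    e <- sqrt(eps[m[, 1]] * eps[m[, 2]])
    list(a = e * rmin^12, b = 2 * e * rmin^6)
  }
  reg_lj <- lj_ab(reg); p14_lj <- lj_ab(p14)

  part <- topo$partition
  loc_of <- function(m) {
    if (!nrow(m)) return(integer())
    labs <- matrix(part[m], nrow = nrow(m))
    host <- rowSums(labs == "host") == ncol(m)
    guest <- rowSums(labs == "guest") == ncol(m)
    ifelse(host, 1L, ifelse(guest, 2L, 0L))
  }
  structure(list(
    n = n, q = q, mass = topo$atoms$mass,
    scale_ee = params$scale_ee_14, scale_vdw = params$scale_vdw_14,
    bonds = topo$bonds, bk = bk, br0 = br0,
    angles = topo$angles, ak = ak, ath0 = ath0,
    tq = tq, tn = tn, tv = tv, tg = tg, tw = tw,
    reg = reg, reg_a = reg_lj$a, reg_b = reg_lj$b,
    reg_qq = KE_COULOMB * q[reg[, 1]] * q[reg[, 2]],
    p14 = p14, p14_a = p14_lj$a, p14_b = p14_lj$b,
    p14_qq = if (nrow(p14)) KE_COULOMB * q[p14[, 1]] * q[p14[, 2]]
             else numeric(),
    partition = part,
    bond_loc = loc_of(topo$bonds), angle_loc = loc_of(topo$angles),
    tors_loc = loc_of(tq), reg_loc = loc_of(reg), p14_loc = loc_of(p14)),
    class = "energy_context")
}

row_norm <- function(m) sqrt(rowSums(m * m))
row_dot <- function(a, b) rowSums(a * b)
row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

bond_lengths <- function(ctx, x) {
  row_norm(x[ctx$bonds[, 1], , drop = FALSE] - x[ctx$bonds[, 2], , drop = FALSE])
}

angle_values <- function(ctx, x) {
  u <- x[ctx$angles[, 1], , drop = FALSE] - x[ctx$angles[, 2], , drop = FALSE]
  v <- x[ctx$angles[, 3], , drop = FALSE] - x[ctx$angles[, 2], , drop = FALSE]
  cosv <- row_dot(u, v) / (row_norm(u) * row_norm(v))
  acos(pmin(1, pmax(-1, cosv)))
}

torsion_values <- function(ctx, x) {
  b1 <- x[ctx$tq[, 2], , drop = FALSE] - x[ctx$tq[, 1], , drop = FALSE]
  b2 <- x[ctx$tq[, 3], , drop = FALSE] - x[ctx$tq[, 2], , drop = FALSE]
  b3 <- x[ctx$tq[, 4], , drop = FALSE] - x[ctx$tq[, 3], , drop = FALSE]
  n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
  m1 <- row_cross(n1, b2 / row_norm(b2))
  atan2(row_dot(m1, n2), row_dot(n1, n2))
}

pair_r <- function(m, x, what) {
  if (!nrow(m)) return(numeric())
  r <- row_norm(x[m[, 1], , drop = FALSE] - x[m[, 2], , drop = FALSE])
  if (any(r == 0)) stop("zero interatomic distance in ", what, " pair")
  r
}

energy_from_context <- function(ctx, x, eps_in = 1, mask = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == ctx$n, ncol(x) == 3, eps_in >= 1)
  sel <- function(v, loc, want) if (is.null(mask)) v else v[loc == want]
  want <- mask %||% 0L
  eb <- if (nrow(ctx$bonds)) {
    r <- bond_lengths(ctx, x)
    sum(sel(ctx$bk * (r - ctx$br0)^2, ctx$bond_loc, want))
  } else 0
  ea <- if (nrow(ctx$angles)) {
    th <- angle_values(ctx, x)
    sum(sel(ctx$ak * (th - ctx$ath0)^2, ctx$angle_loc, want))
  } else 0
  et <- if (nrow(ctx$tq)) {
    phi <- torsion_values(ctx, x)
    sum(sel(ctx$tv * (1 + cos(ctx$tn * phi - ctx$tg)), ctx$tors_loc, want))
  } else 0
  rr <- pair_r(ctx$reg, x, "nonbonded")
  evdw_all <- ctx$reg_a / rr^12 - ctx$reg_b / rr^6
  eele_all <- ctx$reg_qq / (eps_in * rr)
  evdw <- sum(sel(evdw_all, ctx$reg_loc, want))
  eele <- sum(sel(eele_all, ctx$reg_loc, want))
  e14v <- e14e <- 0
  if (nrow(ctx$p14)) {
    r14 <- pair_r(ctx$p14, x, "1-4")
    e14v <- sum(sel((ctx$p14_a / r14^12 - ctx$p14_b / r14^6) / ctx$scale_vdw,
                    ctx$p14_loc, want))
    e14e <- sum(sel(ctx$p14_qq / (eps_in * r14) / ctx$scale_ee,
                    ctx$p14_loc, want))
  }
  energy_components(bond = eb, angle = ea, torsion = et, vdw = evdw,
                    ele = eele, vdw14 = e14v, ele14 = e14e)
}

#' Partitioned (inter/intra) molecular-mechanics energy
#'
#' Splits the single-frame MM energy of a host-guest complex into
#' intra-host and intra-guest component sets plus inter-molecular
#' Lennard-Jones and electrostatic terms. No bonded term may cross the
#' partition; inter-molecular pairs are never excluded or 1-4 scaled. The
#' parts reconstruct the unpartitioned total exactly:
#' `intra_host$total + intra_guest$total + inter_vdw + inter_ele`.
#'
#' @inheritParams total_energy
#' @param host_idx,guest_idx disjoint, covering atom index sets; default to
#'   the topology's partition labels
#' @return list of class `"partitioned_energy"` with `intra_host`,
#'   `intra_guest` ([energy components][total_energy]), `inter_vdw`,
#'   `inter_ele` (kcal/mol).
#' @export
partition_energy <- function(topo, params, frame, host_idx = NULL,
                             guest_idx = NULL, eps_in = 1) {
  n <- n_atoms(topo)
  if (is.null(host_idx)) host_idx <- host_indices(topo)
  if (is.null(guest_idx)) guest_idx <- guest_indices(topo)
  if (length(intersect(host_idx, guest_idx)) ||
      length(union(host_idx, guest_idx)) != n)
    stop("partition_energy: host_idx and guest_idx must be disjoint and cover all atoms")
  topo$partition <- ifelse(seq_len(n) %in% host_idx, "host", "guest")
  ctx <- make_energy_context(topo, params)
  partition_energy_from_context(ctx, frame, eps_in)
}

partition_energy_from_context <- function(ctx, x, eps_in = 1) {
  if (any(ctx$bond_loc == 0L) || any(ctx$angle_loc == 0L) ||
      any(ctx$tors_loc == 0L))
    stop("partition_energy: a bonded term crosses the host/guest partition")
  ih <- energy_from_context(ctx, x, eps_in, mask = 1L)
  ig <- energy_from_context(ctx, x, eps_in, mask = 2L)
  x <- as.matrix(x)
  cross <- ctx$reg_loc == 0L
  inter_vdw <- inter_ele <- 0
  if (any(cross)) {
    m <- ctx$reg[cross, , drop = FALSE]
    r <- pair_r(m, x, "inter-molecular")
    inter_vdw <- sum(ctx$reg_a[cross] / r^12 - ctx$reg_b[cross] / r^6)
    inter_ele <- sum(ctx$reg_qq[cross] / (eps_in * r))
  }
  structure(list(intra_host = ih, intra_guest = ig,
                 inter_vdw = inter_vdw, inter_ele = inter_ele),
            class = "partitioned_energy")
}

#' @export
print.partitioned_energy <- function(x, ...) {
  cat(sprintf("Partitioned MM energy (kcal/mol): intra_host %.4f, intra_guest %.4f, inter_vdw %.4f, inter_ele %.4f\n",
              x$intra_host[["total"]], x$intra_guest[["total"]],
              x$inter_vdw, x$inter_ele))
  invisible(x)
}
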