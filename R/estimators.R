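#' Per-frame energetics of one sampled ensemble
#'
#' Evaluates, for every frame of a trajectory, the gas-phase MM components
#' (stored at interior dielectric 1 so that Coulomb terms can be rescaled
#' exactly by 1/eps later), the polar solvation term (GB pair sums stored
#' epsilon-free, or PB energies at the requested dielectrics) and the
#' SASA nonpolar term. For a `"complex"` ensemble the MM energy is
#' partitioned into inter/intra parts and the solvation terms are also
#' computed on the host-only and guest-only coordinate slices, which is
#' what both the single-trajectory estimator and the bound-state leg of the
#' three-trajectory estimator consume.
#'
#' @inheritParams total_energy
#' @param traj a [trajectory()] (or list of frames)
#' @param role `"complex"` (requires a host/guest partition) or
#'   `"host"`/`"guest"`/`"species"` for single-species ensembles
#' @param solvent `"gb"` or `"pb"`
#' @param eps_in interior dielectric for reporting (PB solves use it
#'   directly; GB and Coulomb terms are stored scale-free)
#' @param eps_out exterior dielectric
#' @param gb a [gb_model()] (its `eps_in`/`eps_out` are overridden by the
#'   arguments above)
#' @param sasa_mod a [sasa_model()]
#' @param pb a [pb_grid()] (PB solvent only)
#' @param sampling_interval_ps frame spacing metadata, ps
#' @return list of class `"ensemble_energetics"`; element `series` is a
#'   per-frame data frame.
#' @export
ensemble_energetics <- function(topo, params, traj,
                                role = c("complex", "host", "guest",
                                         "species"),
                                solvent = c("gb", "pb"),
                                eps_in = 1, eps_out = 78.5,
                                gb = gb_model(), sasa_mod = sasa_model(),
                                pb = pb_grid(),
                                sampling_interval_ps = 10) {
  role <- match.arg(role)
  solvent <- match.arg(solvent)
  frames <- trajectory_frames(traj)
  nf <- length(frames)
  if (!nf) stop("ensemble_energetics: empty ensemble")
  gb$eps_in <- eps_in; gb$eps_out <- eps_out

  if (role == "complex") {
    hi <- host_indices(topo); gi <- guest_indices(topo)
    if (!length(hi) || !length(gi))
      stop("ensemble_energetics: complex role requires host and guest partition labels")
    ctx <- make_energy_context(topo, params)
    th <- subset_topology(topo, hi); tg <- subset_topology(topo, gi)
    rs <- gb_radii_screen(topo, params)
    rsh <- gb_radii_screen(th, params); rsg <- gb_radii_screen(tg, params)
    qs <- topo$atoms$charge
    ser <- vapply(frames, function(x) {
      pe <- partition_energy_from_context(ctx, x, eps_in = 1)
      xh <- x[hi, , drop = FALSE]; xg <- x[gi, , drop = FALSE]
      ih <- pe$intra_host; ig <- pe$intra_guest
      polar <- if (solvent == "gb") {
        ac <- born_radii_impl(x, rs$rho, rs$screen, gb)
        ah <- born_radii_impl(xh, rsh$rho, rsh$screen, gb)
        ag <- born_radii_impl(xg, rsg$rho, rsg$screen, gb)
        c(gb_pair_sum(x, qs, ac), gb_pair_sum(xh, qs[hi], ah),
          gb_pair_sum(xg, qs[gi], ag))
      } else {
        c(pb_energy_fd(topo, params, x, pb, eps_in, eps_out),
          pb_energy_fd(th, params, xh, pb, eps_in, eps_out),
          pb_energy_fd(tg, params, xg, pb, eps_in, eps_out))
      }
      np <- c(nonpolar_energy(sasa(topo, params, x, sasa_mod)$total, sasa_mod),
              nonpolar_energy(sasa(th, params, xh, sasa_mod)$total, sasa_mod),
              nonpolar_energy(sasa(tg, params, xg, sasa_mod)$total, sasa_mod))
      c(inter_vdw = pe$inter_vdw, inter_ele_raw = pe$inter_ele,
        bonded = ih[["bond"]] + ih[["angle"]] + ih[["torsion"]] +
          ig[["bond"]] + ig[["angle"]] + ig[["torsion"]],
        intra_vdw = ih[["vdw"]] + ih[["vdw14"]] + ig[["vdw"]] + ig[["vdw14"]],
        intra_ele_raw = ih[["ele"]] + ih[["ele14"]] +
          ig[["ele"]] + ig[["ele14"]],
        polar_complex = polar[1], polar_host = polar[2], polar_guest = polar[3],
        np_complex = np[1], np_host = np[2], np_guest = np[3])
    }, numeric(11))
    series <- as.data.frame(t(ser))
  } else {
    ctx <- make_energy_context(topo, params)
    rs <- gb_radii_screen(topo, params)
    qs <- topo$atoms$charge
    ser <- vapply(frames, function(x) {
      ec <- energy_from_context(ctx, x, eps_in = 1)
      polar <- if (solvent == "gb") {
        a <- born_radii_impl(x, rs$rho, rs$screen, gb)
        gb_pair_sum(x, qs, a)
      } else pb_energy_fd(topo, params, x, pb, eps_in, eps_out)
      c(bonded = ec[["bond"]] + ec[["angle"]] + ec[["torsion"]],
        vdw = ec[["vdw"]] + ec[["vdw14"]],
        ele_raw = ec[["ele"]] + ec[["ele14"]],
        polar = polar,
        np = nonpolar_energy(sasa(topo, params, x, sasa_mod)$total, sasa_mod))
    }, numeric(5))
    series <- as.data.frame(t(ser))
  }
  structure(list(role = role, solvent = solvent, eps_in = eps_in,
                 eps_out = eps_out, kappa = gb$kappa,
                 n_frames = nf, series = series,
                 sampling_interval_ps = sampling_interval_ps,
                 topo = topo, params = params, traj = trajectory(frames)),
            class = "ensemble_energetics")
}

#' @export
print.ensemble_energetics <- function(x, ...) {
  cat(sprintf("Ensemble energetics: role %s, %d frames, %s solvent (eps_in %g, eps_out %g)\n",
              x$role, x$n_frames, toupper(x$solvent), x$eps_in, x$eps_out))
  invisible(x)
}

gb_prefactor <- function(eps_in, eps_out) 1 / eps_in - 1 / eps_out

# gb pair sums are stored epsilon-free; polar energy at a given eps_in
polar_at_eps <- function(ens, col, eps_in) {
  if (ens$solvent == "gb")
    -KE_COULOMB / 2 * gb_prefactor(eps_in, ens$eps_out) * ens$series[[col]]
  else {
    if (eps_in != ens$eps_in)
      stop("PB polar terms were computed at eps_in = ", ens$eps_in,
           "; dielectric rescaling requires the GB solvent")
    ens$series[[col]]
  }
}

sem_naive <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0

new_binding_estimate <- function(components, se, realization, solvent,
                                 eps_in, n_frames, dg_se) {
  structure(list(dg_total = sum(components), components = components,
                 se = se, dg_se = dg_se, realization = realization,
                 solvent = solvent, eps_in = eps_in, n_frames = n_frames),
            class = "binding_estimate")
}

#' Single-trajectory end-point binding free energy
#'
#' Samples only the bound complex: per frame,
#' \deqn{\Delta G_f = E_{vdw}^{inter} + E_{ele}^{inter}(\epsilon_{in}) +
#'   [G_{pol}(C) - G_{pol}(H) - G_{pol}(G)] +
#'   [G_{np}(C) - G_{np}(H) - G_{np}(G)]}
#' with host/guest solvation evaluated on coordinates sliced from the
#' complex frames, so internal (bonded + intra-molecular nonbonded) energies
#' cancel exactly and never enter. The reported estimate is the frame mean
#' plus the optional normal-mode \eqn{-T\Delta S}.
#'
#' @param complex_ens an [ensemble_energetics()] with role `"complex"`
#' @param eps_in interior dielectric constant (GB solvent; defaults to the
#'   ensemble's value)
#' @param entropy optional result of [binding_entropy()] (adds a
#'   `minus_TdS` component)
#' @return object of class `"binding_estimate"`
#' @export
single_trajectory_estimate <- function(complex_ens, eps_in = NULL,
                                       entropy = NULL) {
  stopifnot(inherits(complex_ens, "ensemble_energetics"))
  if (complex_ens$role != "complex")
    stop("single_trajectory_estimate: need a complex ensemble")
  eps_in <- eps_in %||% complex_ens$eps_in
  s <- complex_ens$series
  vdw <- s$inter_vdw
  ele <- s$inter_ele_raw / eps_in
  pol <- polar_at_eps(complex_ens, "polar_complex", eps_in) -
    polar_at_eps(complex_ens, "polar_host", eps_in) -
    polar_at_eps(complex_ens, "polar_guest", eps_in)
  np <- s$np_complex - s$np_host - s$np_guest
  per_frame <- vdw + ele + pol + np
  comps <- c(vdw = mean(vdw), ele = mean(ele), polar = mean(pol),
             nonpolar = mean(np))
  ses <- c(vdw = sem_naive(vdw), ele = sem_naive(ele),
           polar = sem_naive(pol), nonpolar = sem_naive(np))
  dg_se <- sem_naive(per_frame)
  if (!is.null(entropy)) {
    comps <- c(comps, minus_TdS = entropy$minus_TdS_mean)
    ses <- c(ses, minus_TdS = entropy$minus_TdS_sem)
    dg_se <- sqrt(dg_se^2 + entropy$minus_TdS_sem^2)
  }
  new_binding_estimate(comps, ses, "1traj", complex_ens$solvent, eps_in,
                       complex_ens$n_frames, dg_se)
}

species_G <- function(ens, eps_in) {
  s <- ens$series
  if (ens$role == "complex") {
    list(internal = s$bonded,
         vdw = s$intra_vdw + s$inter_vdw,
         ele = (s$intra_ele_raw + s$inter_ele_raw) / eps_in,
         polar = polar_at_eps(ens, "polar_complex", eps_in),
         np = s$np_complex)
  } else {
    list(internal = s$bonded, vdw = s$vdw, ele = s$ele_raw / eps_in,
         polar = polar_at_eps(ens, "polar", eps_in), np = s$np)
  }
}

#' Three-trajectory end-point binding free energy
#'
#' Samples the bound complex and the unbound host and guest independently:
#' \eqn{\Delta G = \langle G \rangle_C - \langle G \rangle_H -
#' \langle G \rangle_G} with per-frame
#' \eqn{G = E_{MM}(\epsilon_{in}) + G_{pol} + G_{np}}. Internal
#' (reorganization) energies enter the estimate — the component report
#' includes `internal` (bond + angle + torsion change), which the
#' single-trajectory realization lacks — and uncertainties are combined in
#' quadrature across the three independent ensembles. When the host and
#' guest ensembles are exact coordinate slices of the complex ensemble the
#' estimate collapses to the single-trajectory one term by term.
#'
#' @param complex_ens,host_ens,guest_ens [ensemble_energetics()] objects
#'   (roles `"complex"`, single-species, single-species)
#' @inheritParams single_trajectory_estimate
#' @return object of class `"binding_estimate"`
#' @export
three_trajectory_estimate <- function(complex_ens, host_ens, guest_ens,
                                      eps_in = NULL, entropy = NULL) {
  enss <- list(complex_ens, host_ens, guest_ens)
  for (e in enss) stopifnot(inherits(e, "ensemble_energetics"))
  if (complex_ens$role != "complex")
    stop("three_trajectory_estimate: first ensemble must have role 'complex'")
  solvs <- vapply(enss, `[[`, character(1), "solvent")
  if (length(unique(solvs)) != 1)
    stop("three_trajectory_estimate: ensembles use different solvent models")
  eps_in <- eps_in %||% complex_ens$eps_in
  gs <- lapply(enss, species_G, eps_in = eps_in)
  comp_mean <- function(part) mean(gs[[1]][[part]]) - mean(gs[[2]][[part]]) -
    mean(gs[[3]][[part]])
  comp_se <- function(part) sqrt(sum(vapply(gs, function(g)
    sem_naive(g[[part]])^2, numeric(1))))
  parts <- c("internal", "vdw", "ele", "polar", "np")
  comps <- vapply(parts, comp_mean, numeric(1))
  ses <- vapply(parts, comp_se, numeric(1))
  names(comps) <- names(ses) <- c("internal", "vdw", "ele", "polar",
                                  "nonpolar")
  per_frame_tot <- lapply(gs, function(g) Reduce(`+`, g))
  dg_se <- sqrt(sum(vapply(per_frame_tot, function(v) sem_naive(v)^2,
                           numeric(1))))
  if (!is.null(entropy)) {
    comps <- c(comps, minus_TdS = entropy$minus_TdS_mean)
    ses <- c(ses, minus_TdS = entropy$minus_TdS_sem)
    dg_se <- sqrt(dg_se^2 + entropy$minus_TdS_sem^2)
  }
  new_binding_estimate(comps, ses, "3traj", complex_ens$solvent, eps_in,
                       vapply(enss, `[[`, numeric(1), "n_frames"), dg_se)
}

#' @export
print.binding_estimate <- function(x, ...) {
  cat(sprintf("End-point binding estimate (%s, %s solvent, eps_in = %g)\n",
              x$realization, toupper(x$solvent), x$eps_in))
  df <- data.frame(component = names(x$components),
                   mean_kcal_mol = round(unname(x$components), 4),
                   sem = round(unname(x$se), 4))
  print(df, row.names = FALSE)
  cat(sprintf("dG_bind = %.4f +/- %.4f kcal/mol over %s frames\n",
              x$dg_total, x$dg_se, paste(x$n_frames, collapse = "/")))
  invisible(x)
}

#' @export
summary.binding_estimate <- function(object, ...) {
  c(list(dg_total = object$dg_total, dg_se = object$dg_se),
    as.list(object$components))
}

#' Normal-mode binding entropy
#'
#' \eqn{-T\Delta S = \langle -TS \rangle_C - \langle -TS \rangle_H -
#' \langle -TS \rangle_G} from RRHO/NMA snapshot entropies. In the
#' single-trajectory realization (host/guest ensembles omitted) the
#' host and guest conformations are sliced from the complex frames; in the
#' three-trajectory realization each ensemble contributes its own equally
#' spaced snapshots.
#'
#' @param complex_ens an [ensemble_energetics()] with role `"complex"`
#' @param host_ens,guest_ens optional independent single-species ensembles
#' @param n_snapshots equally spaced snapshots per ensemble
#' @param grad_tol minimizer tolerance, kcal/mol/Angstrom
#' @param T_K temperature, K
#' @return list with `minus_TdS_mean`, `minus_TdS_sem` (quadrature over
#'   the contributing ensembles) and the per-species results
#' @export
binding_entropy <- function(complex_ens, host_ens = NULL, guest_ens = NULL,
                            n_snapshots = 10, grad_tol = 1e-4, T_K = 300) {
  stopifnot(complex_ens$role == "complex")
  topo <- complex_ens$topo
  hi <- host_indices(topo); gi <- guest_indices(topo)
  frames <- complex_ens$traj$frames
  ent <- function(tp, fr, n)
    ensemble_entropy(tp, complex_ens$params, fr,
                     n_snapshots = min(n, length(fr)), grad_tol = grad_tol,
                     T_K = T_K)
  ec <- ent(topo, frames, n_snapshots)
  eh <- if (is.null(host_ens))
    ent(subset_topology(topo, hi), lapply(frames, function(x)
      x[hi, , drop = FALSE]), n_snapshots)
  else ent(host_ens$topo, host_ens$traj$frames, n_snapshots)
  eg <- if (is.null(guest_ens))
    ent(subset_topology(topo, gi), lapply(frames, function(x)
      x[gi, , drop = FALSE]), n_snapshots)
  else ent(guest_ens$topo, guest_ens$traj$frames, n_snapshots)
  list(minus_TdS_mean = ec$minus_TS_mean - eh$minus_TS_mean -
         eg$minus_TS_mean,
       minus_TdS_sem = sqrt(ec$minus_TS_sem^2 + eh$minus_TS_sem^2 +
                              eg$minus_TS_sem^2),
       complex = ec, host = eh, guest = eg)
}

resolve_scan_input <- function(ensembles, realization) {
  if (realization == "1traj") {
    ens <- if (inherits(ensembles, "ensemble_energetics")) ensembles
           else ensembles$complex
    list(complex = ens)
  } else {
    stopifnot(is.list(ensembles),
              all(c("complex", "host", "guest") %in% names(ensembles)))
    ensembles
  }
}

#' Interior-dielectric-constant scan
#'
#' Re-evaluates the binding estimate over a list of interior dielectric
#' constants without re-running any energy evaluation: Coulomb terms are
#' rescaled exactly by \eqn{1/\epsilon} from the stored \eqn{\epsilon = 1}
#' values, the GB term is rescaled through its
#' \eqn{(1/\epsilon_{in} - 1/\epsilon_{out})} prefactor with effective
#' radii unchanged, and the vdW, internal, nonpolar and entropy terms are
#' held fixed. GB solvent only.
#'
#' @param ensembles a complex [ensemble_energetics()] (1-traj) or a list
#'   `list(complex =, host =, guest =)` (3-traj)
#' @param realization `"1traj"` or `"3traj"`
#' @param eps_list interior dielectric constants, all >= 1 (the standard
#'   physiochemical scan is 1, 2, 4, 6)
#' @param entropy optional [binding_entropy()] result, held fixed across
#'   the scan
#' @return list of class `"dielectric_scan"`: `estimates` (one
#'   [binding estimate][single_trajectory_estimate()] per epsilon) and
#'   `summary` data frame
#' @export
dielectric_scan <- function(ensembles, realization = c("1traj", "3traj"),
                            eps_list = c(1, 2, 4, 6), entropy = NULL) {
  realization <- match.arg(realization)
  if (any(eps_list < 1)) stop("dielectric_scan: eps values must be >= 1")
  ens <- resolve_scan_input(ensembles, realization)
  if (any(vapply(ens, `[[`, character(1), "solvent") != "gb"))
    stop("dielectric_scan: only the GB solvent supports analytic dielectric rescaling (PB scan unsupported)")
  ests <- lapply(eps_list, function(e) {
    if (realization == "1traj")
      single_trajectory_estimate(ens$complex, eps_in = e, entropy = entropy)
    else
      three_trajectory_estimate(ens$complex, ens$host, ens$guest,
                                eps_in = e, entropy = entropy)
  })
  summary <- data.frame(eps_in = eps_list,
                        dg_total = vapply(ests, `[[`, numeric(1), "dg_total"),
                        dg_se = vapply(ests, `[[`, numeric(1), "dg_se"))
  structure(list(estimates = ests, summary = summary,
                 realization = realization),
            class = "dielectric_scan")
}

#' @export
print.dielectric_scan <- function(x, ...) {
  cat(sprintf("Dielectric scan (%s realization):\n", x$realization))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Decomposition of the dielectric-dependent response
#'
#' Splits the \eqn{\epsilon_{in}}-dependent part of the estimate into three
#' rows: (1) the bound-state inter-molecular electrostatics, (2) the
#' binding-induced change of intra-molecular electrostatics (identically
#' zero in the single-trajectory realization, where the sliced intra terms
#' cancel), and (3) the binding-induced change of the GB polar solvation.
#' The rows sum to the epsilon-dependent part of the scan total exactly.
#'
#' @inheritParams dielectric_scan
#' @return object of class `"dielectric_response"`: a data frame with one
#'   row per epsilon and columns `row1_inter_ele`, `row2_intra_ele`,
#'   `row3_polar`, `total_eps_dependent`
#' @export
decompose_dielectric_response <- function(ensembles,
                                          realization = c("1traj", "3traj"),
                                          eps_list = c(1, 2, 4, 6)) {
  realization <- match.arg(realization)
  ens <- resolve_scan_input(ensembles, realization)
  if (any(vapply(ens, `[[`, character(1), "solvent") != "gb"))
    stop("decompose_dielectric_response: GB solvent required")
  sc <- ens$complex$series
  inter_raw <- mean(sc$inter_ele_raw)
  if (realization == "1traj") {
    intra_raw <- 0
    gb_raw <- mean(sc$polar_complex) - mean(sc$polar_host) -
      mean(sc$polar_guest)
  } else {
    intra_raw <- mean(sc$intra_ele_raw) - mean(ens$host$series$ele_raw) -
      mean(ens$guest$series$ele_raw)
    gb_raw <- mean(sc$polar_complex) - mean(ens$host$series$polar) -
      mean(ens$guest$series$polar)
  }
  eps_out <- ens$complex$eps_out
  rows <- data.frame(
    eps_in = eps_list,
    row1_inter_ele = inter_raw / eps_list,
    row2_intra_ele = intra_raw / eps_list,
    row3_polar = -KE_COULOMB / 2 * gb_prefactor(eps_list, eps_out) * gb_raw)
  rows$total_eps_dependent <- rows$row1_inter_ele + rows$row2_intra_ele +
    rows$row3_polar
  structure(rows, class = c("dielectric_response", "data.frame"))
}

#' Convergence diagnostics for an energy time series
#'
#' Least-squares drift slope (with a normal-approximation confidence
#' interval) and a block-averaged standard-error curve at doubling block
#' sizes. The verdict is `"non-convergent"` when the slope CI excludes
#' zero or the block-SEM curve fails to plateau (largest-block SEM more
#' than `plateau_ratio` times the naive SEM); `"converged"` otherwise.
#'
#' @param series numeric vector (one value per frame)
#' @param block_count minimum number of blocks retained at the largest
#'   block size
#' @param conf confidence level for the slope interval
#' @param plateau_ratio plateau threshold on SEM(largest block)/SEM(naive)
#' @return list of class `"convergence_diagnostics"`
#' @export
convergence_diagnostics <- function(series, block_count = 10, conf = 0.95,
                                    plateau_ratio = 3) {
  n <- length(series)
  if (n < 2 * block_count)
    stop("convergence_diagnostics: series shorter than 2 * block_count")
  t_ <- seq_len(n)
  fit <- stats::lm(series ~ t_)
  slope <- unname(coef(fit)[2])
  # a constant series gives a zero-residual fit; its SE is legitimately 0
  se <- suppressWarnings(summary(fit)$coefficients[2, 2])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- slope + c(-1, 1) * z * se
  sizes <- 1
  while (tail(sizes, 1) * 2 <= n %/% block_count)
    sizes <- c(sizes, tail(sizes, 1) * 2)
  sem_curve <- vapply(sizes, function(b) {
    nb <- n %/% b
    bm <- colMeans(matrix(series[seq_len(nb * b)], nrow = b))
    sem_naive(bm)
  }, numeric(1))
  drift <- ci[1] > 0 || ci[2] < 0
  plateau_fail <- sem_curve[length(sem_curve)] >
    plateau_ratio * sem_curve[1]
  structure(list(slope = slope, slope_ci = ci, conf = conf,
                 block_sizes = sizes, block_sem = sem_curve,
                 drift_detected = drift, plateau_failed = plateau_fail,
                 verdict = if (drift || plateau_fail) "non-convergent"
                           else "converged"),
            class = "convergence_diagnostics")
}

#' @export
print.convergence_diagnostics <- function(x, ...) {
  cat(sprintf("Drift slope %.4g [%.4g, %.4g] per frame (%.0f%% CI)\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], 100 * x$conf))
  cat(sprintf("Block SEM %.4g (b=1) -> %.4g (b=%d)\n",
              x$block_sem[1], tail(x$block_sem, 1), tail(x$block_sizes, 1)))
  cat("Verdict:", x$verdict, "\n")
  invisible(x)
}

#' Standard error of a per-frame series
#'
#' Naive SEM `sd/sqrt(n)` by default; block-averaged SEM (means over
#' consecutive blocks) on request for correlated series. Note the naive
#' SEM treats frames as independent: duplicating every frame halves it.
#'
#' @param series numeric vector
#' @param method `"naive"` or `"block"`
#' @param block_size frames per block for the block estimate
#' @return standard error of the mean
#' @export
uncertainty <- function(series, method = c("naive", "block"),
                        block_size = 50) {
  method <- match.arg(method)
  if (method == "naive") return(sem_naive(series))
  n <- length(series)
  nb <- n %/% block_size
  if (nb < 2) stop("uncertainty: fewer than 2 blocks")
  bm <- colMeans(matrix(series[seq_len(nb * block_size)], nrow = block_size))
  sem_naive(bm)
}
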