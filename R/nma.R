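#' Minimize a structure on the gas-phase MM potential
#'
#' L-BFGS minimization with the analytic gradient at `eps_in = 1` (no
#' distance-dependent dielectric), restarted until the RMS Cartesian
#' gradient drops below `grad_tol`. Deterministic given inputs.
#'
#' @inheritParams total_energy
#' @param grad_tol target RMS gradient, kcal/mol/Angstrom
#' @param max_restarts optimizer restarts before giving up
#' @param eps_in interior dielectric during minimization (default 1)
#' @return minimized coordinates (n x 3), with attributes `energy` and
#'   `rms_gradient`
#' @export
minimize_structure <- function(topo, params, frame, grad_tol = 1e-4,
                               max_restarts = 40, eps_in = 1) {
  ctx <- make_energy_context(topo, params)
  minimize_from_context(ctx, frame, grad_tol, max_restarts, eps_in)
}

rms_grad <- function(g) sqrt(mean(g^2))

minimize_from_context <- function(ctx, frame, grad_tol = 1e-4,
                                  max_restarts = 40, eps_in = 1) {
  x0 <- as.numeric(as.matrix(frame))
  n3 <- length(x0)
  fn <- function(p) energy_from_context(ctx, matrix(p, ncol = 3),
                                        eps_in)[["total"]]
  gr <- function(p) as.numeric(gradient_from_context(ctx, matrix(p, ncol = 3),
                                                     eps_in))
  if (!is.finite(fn(x0))) stop("minimize_structure: non-finite starting energy")
  p <- x0
  last_rms <- Inf
  for (r in seq_len(max_restarts)) {
    res <- stats::optim(p, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = 2000, factr = 10, pgtol = 0))
    p <- res$par
    rg <- rms_grad(gr(p))
    if (rg <= grad_tol || rg > 0.99 * last_rms) break  # converged or stalled
    last_rms <- rg
  }
  # quadratic polish: damped Newton steps on the finite-difference Hessian
  if (rms_grad(gr(p)) > grad_tol) {
    tau <- 1e-3
    for (it in seq_len(30)) {
      g <- gr(p)
      if (rms_grad(g) <= grad_tol) break
      H <- hessian_from_context(ctx, matrix(p, ncol = 3), eps_in = eps_in,
                                mass_weight = FALSE)
      step <- tryCatch(solve(H + tau * diag(n3), -g),
                       error = function(e) NULL)
      if (!is.null(step) && fn(p + step) <= fn(p)) {
        p <- p + step
        tau <- max(tau / 10, 1e-8)
      } else tau <- tau * 10
      if (tau > 1e6) break
    }
  }
  g <- gr(p)
  if (rms_grad(g) > grad_tol)
    stop(sprintf("minimize_structure: RMS gradient %.3g above tolerance %.3g after %d restarts",
                 rms_grad(g), grad_tol, max_restarts))
  out <- matrix(p, ncol = 3)
  attr(out, "energy") <- fn(p)
  attr(out, "rms_gradient") <- rms_grad(g)
  out
}

#' Mass-weighted Hessian by central differences of the analytic gradient
#'
#' \eqn{H_{\alpha\beta} = \partial^2 E / \partial x_\alpha \partial x_\beta}
#' from central finite differences of the analytic gradient (default step
#' 1e-4 Angstrom), symmetrized as \eqn{(H + H^T)/2} and mass-weighted by
#' \eqn{1/\sqrt{m_i m_j}}.
#'
#' @inheritParams total_energy
#' @param displacement finite-difference step, Angstrom
#' @return symmetric 3n x 3n matrix; eigenvalues are in
#'   kcal/mol/A^2/amu
#' @export
mass_weighted_hessian <- function(topo, params, frame, displacement = 1e-4,
                                  eps_in = 1) {
  ctx <- make_energy_context(topo, params)
  hessian_from_context(ctx, frame, displacement, eps_in)
}

hessian_from_context <- function(ctx, frame, displacement = 1e-4,
                                 eps_in = 1, mass_weight = TRUE) {
  x <- as.numeric(as.matrix(frame))
  n3 <- length(x)
  H <- matrix(0, n3, n3)
  for (a in seq_len(n3)) {
    xp <- x; xp[a] <- xp[a] + displacement
    xm <- x; xm[a] <- xm[a] - displacement
    gp <- as.numeric(gradient_from_context(ctx, matrix(xp, ncol = 3), eps_in))
    gm <- as.numeric(gradient_from_context(ctx, matrix(xm, ncol = 3), eps_in))
    H[, a] <- (gp - gm) / (2 * displacement)
  }
  H <- (H + t(H)) / 2
  if (!mass_weight) return(H)
  # coordinates are stored column-major as (x1..xn, y1..yn, z1..zn)
  m3 <- rep(ctx$mass, 3)
  H / sqrt(outer(m3, m3))
}

#' Vibrational frequencies from a mass-weighted Hessian
#'
#' Diagonalizes the mass-weighted Hessian, discards the `n_discard` modes of
#' smallest absolute eigenvalue (6 translations/rotations for a nonlinear
#' molecule, 5 for linear, 3 for a single atom) and converts the remaining
#' eigenvalues to wavenumbers.
#'
#' @param mw_hessian matrix from [mass_weighted_hessian()]
#' @param n_discard number of trans/rot modes to remove; `NULL` picks
#'   6 (nonlinear), 5 (linear) or 3 (single atom) from the eigenvalue count
#' @param linear treat the molecule as linear when choosing the default
#' @return list with `frequencies_cm1` (ascending), `eigenvalues`,
#'   `n_discarded`, `discarded_eigenvalues`
#' @export
normal_mode_frequencies <- function(mw_hessian, n_discard = NULL,
                                    linear = FALSE) {
  ev <- eigen(mw_hessian, symmetric = TRUE, only.values = TRUE)$values
  n3 <- length(ev)
  if (is.null(n_discard))
    n_discard <- if (n3 <= 3) 3L else if (linear) 5L else 6L
  n_discard <- min(n_discard, n3)
  ord <- order(abs(ev))
  discard <- ev[ord[seq_len(n_discard)]]
  keep <- sort(ev[ord[-seq_len(n_discard)]])
  if (length(keep) && any(keep < 0))
    stop("normal_mode_frequencies: imaginary frequency (negative eigenvalue beyond the discarded trans/rot set); re-minimize the structure")
  freq <- sqrt(keep * MW_EIG_TO_S2) / (2 * pi * C_LIGHT_CM)
  list(frequencies_cm1 = freq, eigenvalues = keep,
       n_discarded = n_discard, discarded_eigenvalues = discard)
}

#' Principal moments of inertia
#'
#' @param frame coordinates (n x 3), Angstrom
#' @param mass per-atom masses, amu
#' @return three principal moments, amu A^2 (ascending)
#' @export
principal_moments <- function(frame, mass) {
  x <- as.matrix(frame)
  com <- colSums(x * mass) / sum(mass)
  xc <- sweep(x, 2, com)
  I <- matrix(0, 3, 3)
  r2 <- rowSums(xc^2)
  for (a in 1:3) for (b in 1:3)
    I[a, b] <- sum(mass * ((a == b) * r2 - xc[, a] * xc[, b]))
  eigen(I, symmetric = TRUE, only.values = TRUE)$values  # amu A^2
}

#' Rigid-rotor/harmonic-oscillator entropy
#'
#' Translational entropy from the Sackur-Tetrode equation, classical
#' rigid-rotor rotational entropy from the principal moments of inertia,
#' and harmonic-oscillator vibrational entropy
#' \eqn{S_{vib} = R \sum_k [x_k/(e^{x_k}-1) - \ln(1-e^{-x_k})]},
#' \eqn{x_k = h c \tilde\nu_k / k_B T}, over the retained modes.
#'
#' @param freqs_cm1 vibrational wavenumbers, cm^-1
#' @param total_mass molecular mass, amu
#' @param moments principal moments of inertia, amu A^2 (vector of 3;
#'   near-zero entries are treated as absent rotational axes)
#' @param T_K temperature, K
#' @param P_atm pressure, atm
#' @param sigma_sym rotational symmetry number
#' @return list of class `"normal_mode_result"` with `s_trans`, `s_rot`,
#'   `s_vib` (cal/mol/K), `minus_TS` (kcal/mol), `frequencies_cm1`,
#'   `n_discarded`, `T_K`
#' @export
rrho_entropy <- function(freqs_cm1, total_mass, moments, T_K = 300,
                         P_atm = 1, sigma_sym = 1, n_discarded = NA_integer_) {
  m_kg <- total_mass * AMU_KG
  P_pa <- P_atm * 101325
  q_trans <- (2 * pi * m_kg * K_BOLTZ * T_K / H_PLANCK^2)^1.5 *
    (K_BOLTZ * T_K / P_pa)
  s_trans <- R_CAL * (log(q_trans) + 2.5)
  mom <- sort(moments, decreasing = TRUE)
  mom_si <- mom * AMU_KG * 1e-20
  active <- mom_si > 1e-53  # zero for a point mass / missing axes
  s_rot <- 0
  if (sum(active) >= 2) {
    theta <- H_PLANCK^2 / (8 * pi^2 * K_BOLTZ * mom_si[active])
    if (sum(active) == 3) {
      q_rot <- sqrt(pi) / sigma_sym * sqrt(T_K^3 / prod(theta))
      s_rot <- R_CAL * (log(q_rot) + 1.5)
    } else {
      q_rot <- T_K / (sigma_sym * theta[1])
      s_rot <- R_CAL * (log(q_rot) + 1)
    }
  }
  s_vib <- 0
  if (length(freqs_cm1)) {
    xk <- H_PLANCK * C_LIGHT_CM * freqs_cm1 / (K_BOLTZ * T_K)
    s_vib <- R_CAL * sum(xk / (exp(xk) - 1) - log(1 - exp(-xk)))
  }
  s_total <- s_trans + s_rot + s_vib
  structure(list(frequencies_cm1 = freqs_cm1, n_discarded = n_discarded,
                 s_trans = s_trans, s_rot = s_rot, s_vib = s_vib,
                 s_total = s_total, minus_TS = -T_K * s_total / 1000,
                 T_K = T_K),
            class = "normal_mode_result")
}

#' @export
print.normal_mode_result <- function(x, ...) {
  cat(sprintf("RRHO entropy at %.1f K: S_trans %.3f, S_rot %.3f, S_vib %.3f cal/mol/K; -TS = %.4f kcal/mol (%d modes, %s discarded)\n",
              x$T_K, x$s_trans, x$s_rot, x$s_vib, x$minus_TS,
              length(x$frequencies_cm1),
              ifelse(is.na(x$n_discarded), "?", x$n_discarded)))
  invisible(x)
}

#' Full NMA entropy of one snapshot
#'
#' Minimizes the snapshot, builds the mass-weighted Hessian, discards the
#' trans/rot modes by count and evaluates the RRHO entropy.
#'
#' @inheritParams minimize_structure
#' @param T_K,P_atm,sigma_sym thermodynamic state for [rrho_entropy()]
#' @param linear treat the molecule as linear
#' @return a `"normal_mode_result"`
#' @export
snapshot_entropy <- function(topo, params, frame, grad_tol = 1e-4,
                             T_K = 300, P_atm = 1, sigma_sym = 1,
                             linear = FALSE) {
  ctx <- make_energy_context(topo, params)
  xmin <- minimize_from_context(ctx, frame, grad_tol)
  # a symmetric start can relax onto a saddle; follow the imaginary mode
  # downhill (deterministically) until a true minimum is reached
  for (attempt in seq_len(6)) {
    H <- hessian_from_context(ctx, xmin)
    nm <- tryCatch(normal_mode_frequencies(H, linear = linear),
                   error = function(e) e)
    if (!inherits(nm, "error")) break
    if (attempt == 6) stop(nm)
    eig <- eigen(H, symmetric = TRUE)
    k <- which.min(eig$values)
    v <- matrix(eig$vectors[, k] / sqrt(rep(ctx$mass, 3)), ncol = 3)
    xmin <- minimize_from_context(ctx, xmin + 0.1 * v / max(abs(v)),
                                  grad_tol)
  }
  res <- rrho_entropy(nm$frequencies_cm1, sum(topo$atoms$mass),
                      principal_moments(xmin, topo$atoms$mass),
                      T_K = T_K, P_atm = P_atm, sigma_sym = sigma_sym,
                      n_discarded = nm$n_discarded)
  res
}

#' Ensemble-averaged NMA entropy
#'
#' Chooses `n_snapshots` equally spaced frames (stride
#' `floor(n_frames / n_snapshots)`, mirroring the fixed-interval snapshot
#' protocol), minimizes and analyses each, and returns the mean and
#' standard error of `-TS`.
#'
#' @inheritParams snapshot_entropy
#' @param traj a trajectory (list of frames or 3D array; see
#'   [read_trajectory()])
#' @param n_snapshots number of equally spaced snapshots to analyse
#' @return list with `minus_TS_mean`, `minus_TS_sem`, `per_snapshot`,
#'   `snapshot_index`
#' @export
ensemble_entropy <- function(topo, params, traj, n_snapshots = 100,
                             grad_tol = 1e-4, T_K = 300, P_atm = 1,
                             sigma_sym = 1, linear = FALSE) {
  frames <- trajectory_frames(traj)
  nf <- length(frames)
  if (n_snapshots > nf)
    stop("ensemble_entropy: n_snapshots exceeds available frames")
  stride <- max(1L, floor(nf / n_snapshots))
  idx <- seq(1L, by = stride, length.out = n_snapshots)
  vals <- vapply(idx, function(i)
    snapshot_entropy(topo, params, frames[[i]], grad_tol = grad_tol,
                     T_K = T_K, P_atm = P_atm, sigma_sym = sigma_sym,
                     linear = linear)$minus_TS, numeric(1))
  list(minus_TS_mean = mean(vals),
       minus_TS_sem = if (length(vals) > 1) stats::sd(vals) / sqrt(length(vals)) else 0,
       per_snapshot = vals, snapshot_index = idx)
}
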