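#' Analytic gradient of the gas-phase MM energy
#'
#' Cartesian gradient (kcal/mol/Angstrom) of the potential evaluated by
#' [total_energy()], used by the minimizer and differentiated once more by
#' finite differences for normal-mode analysis. Torsion gradients follow the
#' standard cross-product formulation; angle gradients guard against the
#' collinear singularity.
#'
#' @inheritParams total_energy
#' @return numeric matrix (n_atoms x 3)
#' @export
mm_gradient <- function(topo, params, frame, eps_in = 1) {
  gradient_from_context(make_energy_context(topo, params), frame, eps_in)
}

gradient_from_context <- function(ctx, x, eps_in = 1) {
  x <- as.matrix(x)
  g <- matrix(0, ctx$n, 3)
  # adds rows of `contrib` into g at atom indices `idx`
  acc <- function(idx, contrib) {
    for (d in 1:3) {
      s <- rowsum(contrib[, d], idx)
      g[as.integer(rownames(s)), d] <<- g[as.integer(rownames(s)), d] + s[, 1]
    }
  }

  if (nrow(ctx$bonds)) {
    i <- ctx$bonds[, 1]; j <- ctx$bonds[, 2]
    dx <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    r <- row_norm(dx)
    dEdr <- 2 * ctx$bk * (r - ctx$br0)
    f <- dx * (dEdr / r)
    acc(i, f); acc(j, -f)
  }
  if (nrow(ctx$angles)) {
    ai <- ctx$angles[, 1]; aj <- ctx$angles[, 2]; ak_ <- ctx$angles[, 3]
    u <- x[ai, , drop = FALSE] - x[aj, , drop = FALSE]
    v <- x[ak_, , drop = FALSE] - x[aj, , drop = FALSE]
    nu <- row_norm(u); nv <- row_norm(v)
    cth <- pmin(1, pmax(-1, row_dot(u, v) / (nu * nv)))
    th <- acos(cth)
    sth <- sqrt(pmax(1e-12, 1 - cth^2))
    dEdth <- 2 * ctx$ak * (th - ctx$ath0)
    # d(theta)/du = -1/sin * (v/(|u||v|) - cos * u/|u|^2)
    gi <- -(v / (nu * nv) - u * (cth / nu^2)) / sth * dEdth
    gk <- -(u / (nu * nv) - v * (cth / nv^2)) / sth * dEdth
    acc(ai, gi); acc(ak_, gk); acc(aj, -(gi + gk))
  }
  if (nrow(ctx$tq)) {
    i1 <- ctx$tq[, 1]; i2 <- ctx$tq[, 2]; i3 <- ctx$tq[, 3]; i4 <- ctx$tq[, 4]
    b1 <- x[i2, , drop = FALSE] - x[i1, , drop = FALSE]
    b2 <- x[i3, , drop = FALSE] - x[i2, , drop = FALSE]
    b3 <- x[i4, , drop = FALSE] - x[i3, , drop = FALSE]
    n1 <- row_cross(b1, b2); n2 <- row_cross(b2, b3)
    nb2 <- row_norm(b2)
    m1 <- row_cross(n1, b2 / nb2)
    phi <- atan2(row_dot(m1, n2), row_dot(n1, n2))
    dEdphi <- -ctx$tv * ctx$tn * sin(ctx$tn * phi - ctx$tg)
    n1sq <- pmax(row_dot(n1, n1), 1e-12)
    n2sq <- pmax(row_dot(n2, n2), 1e-12)
    # signs match the atan2(m1.n2, n1.n2) dihedral convention used above
    dphi1 <- n1 * (nb2 / n1sq)
    dphi4 <- -n2 * (nb2 / n2sq)
    s12 <- row_dot(b1, b2) / nb2^2
    s32 <- row_dot(b3, b2) / nb2^2
    dphi2 <- -dphi1 * (1 + s12) + dphi4 * s32
    dphi3 <- -(dphi1 + dphi2 + dphi4)
    acc(i1, dphi1 * dEdphi); acc(i2, dphi2 * dEdphi)
    acc(i3, dphi3 * dEdphi); acc(i4, dphi4 * dEdphi)
  }
  pair_acc <- function(m, a, b, qq, vsc, esc) {
    if (!nrow(m)) return()
    i <- m[, 1]; j <- m[, 2]
    dx <- x[i, , drop = FALSE] - x[j, , drop = FALSE]
    r <- row_norm(dx)
    dEdr <- (-12 * a / r^13 + 6 * b / r^7) / vsc -
      qq / (eps_in * r^2) / esc
    f <- dx * (dEdr / r)
    acc(i, f); acc(j, -f)
  }
  pair_acc(ctx$reg, ctx$reg_a, ctx$reg_b, ctx$reg_qq, 1, 1)
  pair_acc(ctx$p14, ctx$p14_a, ctx$p14_b, ctx$p14_qq,
           ctx$scale_vdw, ctx$scale_ee)
  g
}
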