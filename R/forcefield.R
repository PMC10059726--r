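#' Force-field parameter containers
#'
#' AMBER-style transferable parameter sets: harmonic bonds
#' \eqn{E = k (r - r_0)^2}, harmonic angles \eqn{E = k (\theta - \theta_0)^2},
#' Fourier torsions \eqn{E = \sum_n (V_n/2)(1 + \cos(n\phi - \gamma_n))},
#' Lennard-Jones parameters stored as rmin/2 and epsilon, and per-atom
#' generalized Born intrinsic radii and screening factors.
#'
#' Parameters are keyed by atom-type tuples joined with `"-"`; keys are
#' canonicalized so that a bond key `(X,Y)` equals `(Y,X)` and angle/torsion
#' keys equal their reversals.
#'
#' @param type_key short atom-type code (must not contain `"-"`)
#' @param mass atomic mass, amu (> 0)
#' @param lj_rmin_half Lennard-Jones rmin/2, Angstrom (>= 0)
#' @param lj_epsilon Lennard-Jones well depth, kcal/mol (>= 0)
#' @param gb_radius intrinsic (mbondi2-style) GB radius, Angstrom (> 0)
#' @param gb_screen dimensionless GB descreening scale factor
#' @return `atom_kind()` returns a list of class `"atom_kind"`.
#' @export
atom_kind <- function(type_key, mass, lj_rmin_half, lj_epsilon,
                      gb_radius = 1.5, gb_screen = 0.8) {
  stopifnot(is.character(type_key), length(type_key) == 1L,
            !grepl("-", type_key, fixed = TRUE))
  if (!(mass > 0)) stop("atom_kind: mass must be > 0")
  if (lj_epsilon < 0) stop("atom_kind: lj_epsilon must be >= 0")
  if (lj_rmin_half < 0) stop("atom_kind: lj_rmin_half must be >= 0")
  if (!(gb_radius > 0)) stop("atom_kind: gb_radius must be > 0")
  structure(list(type_key = type_key, mass = mass,
                 lj_rmin_half = lj_rmin_half, lj_epsilon = lj_epsilon,
                 gb_radius = gb_radius, gb_screen = gb_screen),
            class = "atom_kind")
}

#' @rdname atom_kind
#' @param k force constant: kcal/mol/A^2 for bonds (AMBER convention,
#'   no factor 1/2), kcal/mol/rad^2 for angles
#' @param r0 equilibrium bond length, Angstrom (> 0)
#' @export
bond_param <- function(k, r0) {
  if (k < 0) stop("bond_param: k must be >= 0")
  if (!(r0 > 0)) stop("bond_param: r0 must be > 0")
  structure(list(k = k, r0 = r0), class = "bond_param")
}

#' @rdname atom_kind
#' @param theta0 equilibrium angle, degrees (0 < theta0 <= 180)
#' @export
angle_param <- function(k, theta0) {
  if (k < 0) stop("angle_param: k must be >= 0")
  if (!(theta0 > 0 && theta0 <= 180)) stop("angle_param: theta0 out of (0, 180]")
  structure(list(k = k, theta0 = theta0), class = "angle_param")
}

#' Fourier torsion parameter
#'
#' A torsion term is a finite (possibly empty) list of Fourier components
#' \eqn{(V_n/2)(1 + \cos(n\phi - \gamma))}. An empty component list is a
#' valid "no explicit definition" torsion contributing zero energy.
#'
#' @param n periodicities, positive integers in 1..6
#' @param half_barrier the V_n/2 coefficients, kcal/mol
#' @param phase phases gamma, degrees
#' @return list of class `"torsion_param"` with a `components` data frame.
#' @export
torsion_param <- function(n = integer(), half_barrier = numeric(),
                          phase = numeric()) {
  stopifnot(length(n) == length(half_barrier), length(n) == length(phase))
  if (length(n) && (any(n < 1) || any(n > 6) || any(n != round(n))))
    stop("torsion_param: periodicities must be integers in 1..6")
  if (length(phase) && any(!is.finite(phase)))
    stop("torsion_param: phases must be finite")
  structure(list(components = data.frame(n = as.integer(n),
                                         half_barrier = as.numeric(half_barrier),
                                         phase = as.numeric(phase))),
            class = "torsion_param")
}

canon_pair_key <- function(types) {
  fwd <- paste(types, collapse = "-")
  rev_ <- paste(rev(types), collapse = "-")
  if (rev_ < fwd) rev_ else fwd
}
canon_bond_key <- canon_pair_key
canon_angle_key <- canon_pair_key
canon_torsion_key <- canon_pair_key
split_key <- function(key) strsplit(key, "-", fixed = TRUE)[[1]]

#' Assemble a force-field parameter set
#'
#' @param atom_kinds named list of [atom_kind()] objects (names = type keys)
#' @param bond_params named list of [bond_param()] keyed by canonical
#'   `"X-Y"` type pairs
#' @param angle_params named list of [angle_param()] keyed by `"X-Y-Z"`
#' @param torsion_params named list of [torsion_param()] keyed by `"W-X-Y-Z"`
#' @param scale_ee_14,scale_vdw_14 1-4 scaling divisors (> 0); AMBER
#'   defaults 1.2 and 2.0
#' @return list of class `"parameter_set"`
#' @export
parameter_set <- function(atom_kinds = list(), bond_params = list(),
                          angle_params = list(), torsion_params = list(),
                          scale_ee_14 = 1.2, scale_vdw_14 = 2.0) {
  if (!(scale_ee_14 > 0 && scale_vdw_14 > 0))
    stop("parameter_set: 1-4 scale factors must be > 0")
  for (nm in names(bond_params))
    if (nm != canon_bond_key(split_key(nm)))
      stop("parameter_set: non-canonical bond key: ", nm)
  for (nm in names(angle_params))
    if (nm != canon_angle_key(split_key(nm)))
      stop("parameter_set: non-canonical angle key: ", nm)
  for (nm in names(torsion_params))
    if (nm != canon_torsion_key(split_key(nm)))
      stop("parameter_set: non-canonical torsion key: ", nm)
  structure(list(atom_kinds = atom_kinds, bond_params = bond_params,
                 angle_params = angle_params, torsion_params = torsion_params,
                 scale_ee_14 = scale_ee_14, scale_vdw_14 = scale_vdw_14),
            class = "parameter_set")
}

#' Torsion energy profile
#'
#' Evaluates \eqn{E(\phi) = \sum_i (V_i/2)(1 + \cos(n_i \phi - \gamma_i))}
#' over a vector of dihedral angles. The profile is 360-degree periodic and
#' non-negative whenever every half-barrier is non-negative and the phases
#' are 0 or 180 degrees.
#'
#' @param param a [torsion_param()]
#' @param angles dihedral angles, degrees
#' @return numeric vector of energies, kcal/mol
#' @export
torsion_profile <- function(param, angles) {
  stopifnot(inherits(param, "torsion_param"), all(is.finite(angles)))
  comp <- param$components
  e <- numeric(length(angles))
  if (nrow(comp) == 0L) return(e)
  phi <- angles * pi / 180
  for (i in seq_len(nrow(comp)))
    e <- e + comp$half_barrier[i] *
      (1 + cos(comp$n[i] * phi - comp$phase[i] * pi / 180))
  e
}

rel_diff_category <- function(keys_a, keys_b, value_a, value_b, category) {
  shared <- intersect(keys_a, keys_b)
  va <- vapply(shared, value_a, numeric(1))
  vb <- vapply(shared, value_b, numeric(1))
  zero <- shared[va == 0]
  ok <- va != 0
  rel <- abs(vb[ok] - va[ok]) / abs(va[ok]) * 100
  list(summary = data.frame(
         category = category,
         n_shared = length(shared),
         n_zero_denominator = length(zero),
         mean_rel_pct = if (any(ok)) mean(rel) else NA_real_,
         max_rel_pct = if (any(ok)) max(rel) else NA_real_,
         stringsAsFactors = FALSE),
       zero_keys = zero,
       only_in_a = setdiff(keys_a, keys_b),
       only_in_b = setdiff(keys_b, keys_a))
}

torsion_components_equal <- function(pa, pb, tol_v = 1e-6, tol_phase = 1e-4) {
  ca <- pa$components; cb <- pb$components
  if (nrow(ca) != nrow(cb)) return(FALSE)
  if (nrow(ca) == 0L) return(TRUE)
  ca <- ca[order(ca$n, ca$phase, ca$half_barrier), , drop = FALSE]
  cb <- cb[order(cb$n, cb$phase, cb$half_barrier), , drop = FALSE]
  all(ca$n == cb$n) &&
    all(abs(ca$half_barrier - cb$half_barrier) <= tol_v) &&
    all(abs(ca$phase - cb$phase) <= tol_phase)
}

#' Term-by-term comparison of two parameter sets
#'
#' Compares shared keys of two parameter sets category by category (bond k,
#' bond r0, angle k, angle theta0, LJ sigma, LJ epsilon), reporting the mean
#' and maximum relative difference in percent, with set `a` as the reference
#' denominator: \eqn{|b - a| / |a| \times 100}. Keys whose reference value is
#' zero are excluded from the means and reported in a flagged list. Torsions
#' are compared component-wise after sorting by periodicity; the LJ size
#' parameter is \eqn{\sigma = 2 \cdot r_{min}/2 \cdot 2^{-1/6}}.
#'
#' @param a,b [parameter_set()] objects; `a` is the reference set
#' @return list of class `"param_diff_report"` with elements `categories`
#'   (summary data frame), `differing_torsions`, `only_in_a`, `only_in_b`,
#'   `zero_denominator_keys`.
#' @export
diff_parameter_sets <- function(a, b) {
  stopifnot(inherits(a, "parameter_set"), inherits(b, "parameter_set"))
  cats <- list(
    bond_k = list(names(a$bond_params), names(b$bond_params),
                  function(k) a$bond_params[[k]]$k,
                  function(k) b$bond_params[[k]]$k),
    bond_r0 = list(names(a$bond_params), names(b$bond_params),
                   function(k) a$bond_params[[k]]$r0,
                   function(k) b$bond_params[[k]]$r0),
    angle_k = list(names(a$angle_params), names(b$angle_params),
                   function(k) a$angle_params[[k]]$k,
                   function(k) b$angle_params[[k]]$k),
    angle_theta0 = list(names(a$angle_params), names(b$angle_params),
                        function(k) a$angle_params[[k]]$theta0,
                        function(k) b$angle_params[[k]]$theta0),
    lj_sigma = list(names(a$atom_kinds), names(b$atom_kinds),
                    function(k) 2 * a$atom_kinds[[k]]$lj_rmin_half * 2^(-1/6),
                    function(k) 2 * b$atom_kinds[[k]]$lj_rmin_half * 2^(-1/6)),
    lj_epsilon = list(names(a$atom_kinds), names(b$atom_kinds),
                      function(k) a$atom_kinds[[k]]$lj_epsilon,
                      function(k) b$atom_kinds[[k]]$lj_epsilon))
  summaries <- list(); zero_keys <- list(); only_a <- list(); only_b <- list()
  for (nm in names(cats)) {
    cc <- cats[[nm]]
    r <- rel_diff_category(cc[[1]] %||% character(), cc[[2]] %||% character(),
                           cc[[3]], cc[[4]], nm)
    summaries[[nm]] <- r$summary
    zero_keys[[nm]] <- r$zero_keys
    only_a[[nm]] <- r$only_in_a
    only_b[[nm]] <- r$only_in_b
  }
  ta <- names(a$torsion_params) %||% character()
  tb <- names(b$torsion_params) %||% character()
  diffs <- data.frame(key = character(), reason = character(),
                      stringsAsFactors = FALSE)
  for (k in intersect(ta, tb)) {
    pa <- a$torsion_params[[k]]; pb <- b$torsion_params[[k]]
    if (!torsion_components_equal(pa, pb)) {
      reason <- if (nrow(pa$components) == 0L) "defined only in b"
        else if (nrow(pb$components) == 0L) "defined only in a"
        else "components differ"
      diffs <- rbind(diffs, data.frame(key = k, reason = reason,
                                       stringsAsFactors = FALSE))
    }
  }
  only_a$torsion <- setdiff(ta, tb)
  only_b$torsion <- setdiff(tb, ta)
  structure(list(categories = do.call(rbind, c(summaries,
                                               make.row.names = FALSE)),
                 differing_torsions = diffs,
                 only_in_a = only_a, only_in_b = only_b,
                 zero_denominator_keys = zero_keys),
            class = "param_diff_report")
}

#' @export
print.param_diff_report <- function(x, ...) {
  cat("Parameter-set comparison (relative differences, % of set a)\n")
  print(x$categories, row.names = FALSE)
  if (nrow(x$differing_torsions)) {
    cat("Differing torsion terms:\n")
    print(x$differing_torsions, row.names = FALSE)
  } else cat("No differing torsion terms.\n")
  ua <- unlist(x$only_in_a); ub <- unlist(x$only_in_b)
  if (length(ua)) cat("Keys only in a:", paste(ua, collapse = ", "), "\n")
  if (length(ub)) cat("Keys only in b:", paste(ub, collapse = ", "), "\n")
  invisible(x)
}

#' Write a parameter diff report to CSV and plain text
#'
#' @param report a `"param_diff_report"`
#' @param csv_path path for the per-category summary CSV
#' @param txt_path optional path for the human-readable report
#' @return invisibly, the report
#' @export
write_param_diff <- function(report, csv_path, txt_path = NULL) {
  stopifnot(inherits(report, "param_diff_report"))
  write.csv(report$categories, csv_path, row.names = FALSE)
  if (!is.null(txt_path)) {
    con <- file(txt_path, "w"); on.exit(close(con))
    sink(con); print(report); sink()
  }
  invisible(report)
}
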