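#' Molecular topology
#'
#' A topology holds the atom table (name, type key, charge in e, mass in
#' amu), bonded-term index lists, the nonbonded exclusion machinery (1-2 and
#' 1-3 pairs excluded, 1-4 pairs scaled) and a host/guest partition label per
#' atom. Indices are 1-based internally. When angle, torsion, exclusion or
#' 1-4 lists are not supplied they are rebuilt from the bond graph: angles
#' are all bonded triples, torsions all bonded quadruples, 1-3 pairs the
#' ends of angles and 1-4 pairs the ends of torsions not already excluded.
#'
#' @param atoms data frame with columns `name`, `type`, `charge`, `mass`
#' @param bonds integer matrix (n x 2) of 1-based atom indices
#' @param angles optional integer matrix (n x 3); derived from bonds if NULL
#' @param torsions optional integer matrix (n x 4); derived if NULL
#' @param improper logical vector flagging improper torsions (same length
#'   as `nrow(torsions)`); derived torsions are all proper
#' @param partition character vector of `"host"`/`"guest"`/`"all"` labels,
#'   one per atom; defaults to `"all"`
#' @return list of class `"topology"`
#' @export
topology <- function(atoms, bonds, angles = NULL, torsions = NULL,
                     improper = NULL, partition = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("name", "type", "charge", "mass") %in% names(atoms)))
  n <- nrow(atoms)
  bonds <- as_index_matrix(bonds, 2L, n, "bond")
  if (is.null(angles)) angles <- derive_angles(bonds, n)
  if (is.null(torsions)) {
    torsions <- derive_torsions(bonds, n)
    improper <- rep(FALSE, nrow(torsions))
  }
  angles <- as_index_matrix(angles, 3L, n, "angle")
  torsions <- as_index_matrix(torsions, 4L, n, "torsion")
  if (is.null(improper)) improper <- rep(FALSE, nrow(torsions))
  stopifnot(length(improper) == nrow(torsions))
  if (is.null(partition)) partition <- rep("all", n)
  stopifnot(length(partition) == n,
            all(partition %in% c("host", "guest", "all")))
  total_q <- sum(atoms$charge)
  if (abs(total_q - round(total_q)) > 1e-3)
    stop(sprintf("topology: total charge %.4f is not within 1e-3 of an integer",
                 total_q))
  ex <- build_exclusions(bonds, angles, torsions[!improper, , drop = FALSE], n)
  structure(list(atoms = atoms, bonds = bonds, angles = angles,
                 torsions = torsions, improper = improper,
                 excl = ex$excl, pairs14 = ex$pairs14,
                 partition = partition),
            class = "topology")
}

as_index_matrix <- function(x, width, n_atoms, what) {
  x <- matrix(as.integer(x), ncol = width)
  if (nrow(x) && (min(x) < 1L || max(x) > n_atoms))
    stop(sprintf("topology: %s index out of range 1..%d", what, n_atoms))
  x
}

adjacency_list <- function(bonds, n) {
  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(v) sort(unique(v)))
}

derive_angles <- function(bonds, n) {
  adj <- adjacency_list(bonds, n)
  out <- matrix(integer(), ncol = 3)
  for (j in seq_len(n)) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    out <- rbind(out, cbind(cmb[1, ], j, cmb[2, ]))
  }
  out
}

derive_torsions <- function(bonds, n) {
  adj <- adjacency_list(bonds, n)
  out <- matrix(integer(), ncol = 4)
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in setdiff(adj[[j]], k)) for (l in setdiff(adj[[k]], j)) {
      if (i == l) next  # 3-membered ring closing on itself
      out <- rbind(out, c(i, j, k, l))
    }
  }
  out
}

sorted_pairs <- function(i, j) {
  m <- cbind(pmin(i, j), pmax(i, j))
  unique(m[order(m[, 1], m[, 2]), , drop = FALSE])
}

# 1-2 and 1-3 pairs are fully excluded from nonbonded sums; 1-4 pairs
# (spanning exactly three bonds and not shorter paths) are scaled.
build_exclusions <- function(bonds, angles, proper_torsions, n) {
  p12 <- if (nrow(bonds)) sorted_pairs(bonds[, 1], bonds[, 2])
         else matrix(integer(), ncol = 2)
  p13 <- if (nrow(angles)) sorted_pairs(angles[, 1], angles[, 3])
         else matrix(integer(), ncol = 2)
  excl <- unique(rbind(p12, p13))
  p14 <- if (nrow(proper_torsions))
    sorted_pairs(proper_torsions[, 1], proper_torsions[, 4])
    else matrix(integer(), ncol = 2)
  if (nrow(p14)) {
    key <- function(m) paste(m[, 1], m[, 2])
    p14 <- p14[!(key(p14) %in% key(excl)), , drop = FALSE]
  }
  list(excl = excl, pairs14 = p14)
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf(paste0("Topology: %d atoms, %d bonds, %d angles, %d torsions",
                     " (%d improper)\n"),
              nrow(x$atoms), nrow(x$bonds), nrow(x$angles), nrow(x$torsions),
              sum(x$improper)))
  tab <- table(x$partition)
  cat("Partition:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("Total charge: %+.3f e\n", sum(x$atoms$charge)))
  invisible(x)
}

n_atoms <- function(topo) nrow(topo$atoms)

host_indices <- function(topo) which(topo$partition == "host")
guest_indices <- function(topo) which(topo$partition == "guest")

#' Verify that every bonded term in a topology has parameters
#'
#' @param topo a [topology()]
#' @param params a [parameter_set()]
#' @return invisibly TRUE; errors naming the first missing key otherwise
#' @export
check_parameters <- function(topo, params) {
  ty <- topo$atoms$type
  miss <- setdiff(unique(ty), names(params$atom_kinds))
  if (length(miss)) stop("missing atom kind for type(s): ",
                         paste(miss, collapse = ", "))
  for (b in seq_len(nrow(topo$bonds))) {
    k <- canon_bond_key(ty[topo$bonds[b, ]])
    if (is.null(params$bond_params[[k]])) stop("missing bond parameter: ", k)
  }
  for (a in seq_len(nrow(topo$angles))) {
    k <- canon_angle_key(ty[topo$angles[a, ]])
    if (is.null(params$angle_params[[k]])) stop("missing angle parameter: ", k)
  }
  for (d in seq_len(nrow(topo$torsions))) {
    k <- canon_torsion_key(ty[topo$torsions[d, ]])
    if (is.null(params$torsion_params[[k]]))
      stop("missing torsion parameter: ", k)
  }
  invisible(TRUE)
}

#' Extract the sub-topology for a subset of atoms
#'
#' Keeps bonded terms entirely inside the subset and renumbers indices.
#' Used to slice host-only and guest-only species out of a complex.
#'
#' @param topo a [topology()]
#' @param idx atom indices to keep
#' @return a [topology()] for the subset
#' @export
subset_topology <- function(topo, idx) {
  idx <- sort(idx)
  map <- integer(n_atoms(topo)); map[idx] <- seq_along(idx)
  keep_rows <- function(m) m[rowSums(matrix(m %in% idx, nrow = nrow(m))) ==
                               ncol(m), , drop = FALSE]
  bonds <- keep_rows(topo$bonds)
  angles <- keep_rows(topo$angles)
  tors <- topo$torsions
  keep_t <- rowSums(matrix(tors %in% idx, nrow = nrow(tors))) == 4L
  topology(atoms = topo$atoms[idx, , drop = FALSE],
           bonds = matrix(map[bonds], ncol = 2),
           angles = matrix(map[angles], ncol = 3),
           torsions = matrix(map[tors[keep_t, , drop = FALSE]], ncol = 4),
           improper = topo$improper[keep_t],
           partition = rep("all", length(idx)))
}
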