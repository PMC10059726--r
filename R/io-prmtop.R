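# AMBER prmtop subset: FLAG/FORMAT sections sufficient for single-molecule
# end-point rescoring. Charges are stored in AMBER internal units
# (e * 18.2223), angle equilibria and dihedral phases in radians, bonded
# index lists in the 3*(i-1) coding with the usual sign conventions
# (negative 3rd index = 1-4 term already counted, negative 4th = improper).

# full double precision: 8-digit fields visibly perturb kcal/mol sums
fmt_E <- function(x) sprintf("%24.16E", x)
fmt_I <- function(x) sprintf("%8d", as.integer(x))
fmt_A <- function(x) sprintf("%-4s", substr(x, 1, 4))

emit_section <- function(con, flag, fmt, fields, per_line) {
  writeLines(sprintf("%%FLAG %s", flag), con)
  writeLines(sprintf("%%FORMAT(%s)", fmt), con)
  if (!length(fields)) { writeLines("", con); return(invisible()) }
  idx <- split(seq_along(fields), (seq_along(fields) - 1) %/% per_line)
  writeLines(vapply(idx, function(i) paste(fields[i], collapse = ""),
                    character(1)), con)
}

is_hydrogen <- function(mass) mass < 3

#' Write the prmtop subset
#'
#' Emits the FLAG/FORMAT sections required by [read_prmtop()]
#' (POINTERS, names, charges, masses, LJ type tables, bonded parameter and
#' index lists, 1-4 scale factors, GB radii/screens). The host/guest
#' partition is carried through residue labels `HST`/`GST` (`MOL` for
#' unpartitioned systems). Written energies round-trip against the JSON
#' schema to well below 1e-6 kcal/mol.
#'
#' @param topo a [topology()]
#' @param params a [parameter_set()]
#' @param path output file
#' @return invisibly, `path`
#' @export
write_prmtop <- function(topo, params, path) {
  ty <- topo$atoms$type
  types <- unique(ty)
  nty <- length(types)
  tyi <- match(ty, types)
  kinds <- params$atom_kinds
  n <- n_atoms(topo)

  # LJ triangular tables under Lorentz-Berthelot combination
  ntri <- nty * (nty + 1) / 2
  acoef <- bcoef <- numeric(ntri)
  nbidx <- integer(nty * nty)
  for (i in seq_len(nty)) for (j in seq_len(nty)) {
    lo <- min(i, j); hi <- max(i, j)
    pos <- hi * (hi - 1) / 2 + lo
    nbidx[nty * (i - 1) + j] <- pos
    rmin <- kinds[[types[i]]]$lj_rmin_half + kinds[[types[j]]]$lj_rmin_half
    e <- sqrt(kinds[[types[i]]]$lj_epsilon * kinds[[types[j]]]$lj_epsilon)
    acoef[pos] <- e * rmin^12
    bcoef[pos] <- 2 * e * rmin^6
  }

  uniq_table <- function(keys) {
    u <- unique(keys)
    list(u = u, idx = match(keys, u))
  }
  bond_keys <- vapply(seq_len(nrow(topo$bonds)), function(b)
    canon_bond_key(ty[topo$bonds[b, ]]), character(1))
  bt <- uniq_table(bond_keys)
  bond_k <- vapply(bt$u, function(k) params$bond_params[[k]]$k, numeric(1))
  bond_r0 <- vapply(bt$u, function(k) params$bond_params[[k]]$r0, numeric(1))

  angle_keys <- vapply(seq_len(nrow(topo$angles)), function(a)
    canon_angle_key(ty[topo$angles[a, ]]), character(1))
  at <- uniq_table(angle_keys)
  ang_k <- vapply(at$u, function(k) params$angle_params[[k]]$k, numeric(1))
  ang_t0 <- vapply(at$u, function(k)
    params$angle_params[[k]]$theta0 * pi / 180, numeric(1))

  # dihedral entries: one per (quadruple, Fourier component)
  dk <- dn <- dp <- numeric(0)
  entries <- matrix(integer(), ncol = 5)
  pair_seen <- character(0)
  pair_id <- function(i, j) paste(min(i, j), max(i, j))
  p14_keys <- if (nrow(topo$pairs14))
    paste(topo$pairs14[, 1], topo$pairs14[, 2]) else character(0)
  for (d in seq_len(nrow(topo$torsions))) {
    quad <- topo$torsions[d, ]
    impr <- topo$improper[d]
    key <- canon_torsion_key(ty[quad])
    comp <- params$torsion_params[[key]]$components
    # empty ("no explicit definition") torsions are emitted as a single
    # zero-barrier entry so the 1-4 pair bookkeeping survives the format
    if (!nrow(comp)) comp <- data.frame(n = 1L, half_barrier = 0, phase = 0)
    for (ci in seq_len(nrow(comp))) {
      pidx <- length(dk) + 1L
      # reuse identical parameter rows
      match_prev <- which(dk == comp$half_barrier[ci] & dn == comp$n[ci] &
                            dp == comp$phase[ci] * pi / 180)
      if (length(match_prev)) pidx <- match_prev[1]
      else { dk <- c(dk, comp$half_barrier[ci]); dn <- c(dn, comp$n[ci])
             dp <- c(dp, comp$phase[ci] * pi / 180) }
      pid <- pair_id(quad[1], quad[4])
      keep14 <- !impr && ci == 1 && (pid %in% p14_keys) &&
        !(pid %in% pair_seen)
      if (keep14) pair_seen <- c(pair_seen, pid)
      need_neg3 <- !keep14
      need_neg4 <- impr
      q <- quad
      if ((need_neg3 && q[3] == 1L) || (need_neg4 && q[4] == 1L)) q <- rev(q)
      if ((need_neg3 && q[3] == 1L) || (need_neg4 && q[4] == 1L))
        stop("write_prmtop: cannot encode sign flag on atom 1")
      e3 <- (q[3] - 1L) * 3L; if (need_neg3) e3 <- -e3
      e4 <- (q[4] - 1L) * 3L; if (need_neg4) e4 <- -e4
      entries <- rbind(entries, c((q[1] - 1L) * 3L, (q[2] - 1L) * 3L,
                                  e3, e4, pidx))
    }
  }

  hyd <- is_hydrogen(topo$atoms$mass)
  bond_h <- hyd[topo$bonds[, 1]] | hyd[topo$bonds[, 2]]
  ang_h <- hyd[topo$angles[, 1]] | hyd[topo$angles[, 2]] |
    hyd[topo$angles[, 3]]
  ent_atoms <- abs(entries[, 1:4, drop = FALSE]) / 3 + 1
  dih_h <- if (nrow(entries)) apply(matrix(hyd[ent_atoms], ncol = 4), 1, any)
           else logical(0)

  # residues follow partition-label runs
  runs <- rle(topo$partition)
  res_label <- c(host = "HST", guest = "GST", all = "MOL")[runs$values]
  res_ptr <- cumsum(c(1, head(runs$lengths, -1)))

  ptr <- integer(31)
  ptr[1] <- n; ptr[2] <- nty
  ptr[3] <- sum(bond_h); ptr[4] <- sum(!bond_h)
  ptr[5] <- sum(ang_h); ptr[6] <- sum(!ang_h)
  ptr[7] <- sum(dih_h); ptr[8] <- sum(!dih_h)
  ptr[12] <- length(res_label)
  ptr[13] <- sum(!bond_h); ptr[14] <- sum(!ang_h); ptr[15] <- sum(!dih_h)
  ptr[16] <- length(bond_k); ptr[17] <- length(ang_k); ptr[18] <- length(dk)
  ptr[19] <- nty

  con <- file(path, "w"); on.exit(close(con))
  writeLines("%VERSION  VERSION_STAMP = V0001.000", con)
  emit_section(con, "TITLE", "20a4", fmt_A("topo"), 20)
  emit_section(con, "POINTERS", "10I8", fmt_I(ptr), 10)
  emit_section(con, "ATOM_NAME", "20a4", fmt_A(topo$atoms$name), 20)
  emit_section(con, "CHARGE", "3E24.16",
               fmt_E(topo$atoms$charge * PRMTOP_CHARGE_UNIT), 3)
  emit_section(con, "MASS", "3E24.16", fmt_E(topo$atoms$mass), 3)
  emit_section(con, "ATOM_TYPE_INDEX", "10I8", fmt_I(tyi), 10)
  emit_section(con, "NONBONDED_PARM_INDEX", "10I8", fmt_I(nbidx), 10)
  emit_section(con, "RESIDUE_LABEL", "20a4", fmt_A(res_label), 20)
  emit_section(con, "RESIDUE_POINTER", "10I8", fmt_I(res_ptr), 10)
  emit_section(con, "BOND_FORCE_CONSTANT", "3E24.16", fmt_E(bond_k), 3)
  emit_section(con, "BOND_EQUIL_VALUE", "3E24.16", fmt_E(bond_r0), 3)
  emit_section(con, "ANGLE_FORCE_CONSTANT", "3E24.16", fmt_E(ang_k), 3)
  emit_section(con, "ANGLE_EQUIL_VALUE", "3E24.16", fmt_E(ang_t0), 3)
  emit_section(con, "DIHEDRAL_FORCE_CONSTANT", "3E24.16", fmt_E(dk), 3)
  emit_section(con, "DIHEDRAL_PERIODICITY", "3E24.16", fmt_E(dn), 3)
  emit_section(con, "DIHEDRAL_PHASE", "3E24.16", fmt_E(dp), 3)
  emit_section(con, "SCEE_SCALE_FACTOR", "3E24.16",
               fmt_E(rep(params$scale_ee_14, length(dk))), 3)
  emit_section(con, "SCNB_SCALE_FACTOR", "3E24.16",
               fmt_E(rep(params$scale_vdw_14, length(dk))), 3)
  emit_section(con, "LENNARD_JONES_ACOEF", "3E24.16", fmt_E(acoef), 3)
  emit_section(con, "LENNARD_JONES_BCOEF", "3E24.16", fmt_E(bcoef), 3)
  bidx <- function(sel) {
    m <- topo$bonds[sel, , drop = FALSE]
    as.integer(t(cbind((m[, 1] - 1) * 3, (m[, 2] - 1) * 3, bt$idx[sel])))
  }
  emit_section(con, "BONDS_INC_HYDROGEN", "10I8", fmt_I(bidx(bond_h)), 10)
  emit_section(con, "BONDS_WITHOUT_HYDROGEN", "10I8", fmt_I(bidx(!bond_h)), 10)
  aidx <- function(sel) {
    m <- topo$angles[sel, , drop = FALSE]
    as.integer(t(cbind((m[, 1] - 1) * 3, (m[, 2] - 1) * 3,
                       (m[, 3] - 1) * 3, at$idx[sel])))
  }
  emit_section(con, "ANGLES_INC_HYDROGEN", "10I8", fmt_I(aidx(ang_h)), 10)
  emit_section(con, "ANGLES_WITHOUT_HYDROGEN", "10I8",
               fmt_I(aidx(!ang_h)), 10)
  didx <- function(sel) as.integer(t(entries[sel, , drop = FALSE]))
  emit_section(con, "DIHEDRALS_INC_HYDROGEN", "10I8",
               fmt_I(didx(dih_h)), 10)
  emit_section(con, "DIHEDRALS_WITHOUT_HYDROGEN", "10I8",
               fmt_I(didx(!dih_h)), 10)
  emit_section(con, "AMBER_ATOM_TYPE", "20a4", fmt_A(ty), 20)
  emit_section(con, "RADII", "3E24.16",
               fmt_E(vapply(ty, function(t) kinds[[t]]$gb_radius,
                            numeric(1))), 3)
  emit_section(con, "SCREEN", "3E24.16",
               fmt_E(vapply(ty, function(t) kinds[[t]]$gb_screen,
                            numeric(1))), 3)
  invisible(path)
}

parse_prmtop_sections <- function(path) {
  lines <- readLines(path)
  starts <- grep("^%FLAG", lines)
  if (!length(starts)) stop("read_prmtop: no %FLAG sections in ", path)
  ends <- c(starts[-1] - 1, length(lines))
  out <- list()
  for (s in seq_along(starts)) {
    nm <- trimws(sub("^%FLAG", "", lines[starts[s]]))
    body <- lines[(starts[s] + 1):ends[s]]
    fmt_line <- grep("^%FORMAT", body, value = TRUE)
    if (!length(fmt_line))
      stop("read_prmtop: section ", nm, " lacks a %FORMAT line")
    body <- body[!grepl("^%", body)]
    out[[nm]] <- list(fmt = fmt_line[1], body = body)
  }
  out
}

section_values <- function(sections, name, kind = c("num", "int", "str"),
                           required = TRUE) {
  kind <- match.arg(kind)
  sec <- sections[[name]]
  if (is.null(sec)) {
    if (required) stop("read_prmtop: missing mandatory section ", name)
    return(NULL)
  }
  if (kind == "str") {
    w <- if (grepl("a4", sec$fmt)) 4L else 8L
    vals <- unlist(lapply(sec$body, function(ln) {
      nfield <- ceiling(nchar(ln) / w)
      if (!nfield) return(character(0))
      trimws(substring(ln, (seq_len(nfield) - 1) * w + 1,
                       pmin(seq_len(nfield) * w, nchar(ln))))
    }))
    return(vals[nzchar(vals)])
  }
  toks <- unlist(strsplit(trimws(sec$body), "[[:space:]]+"))
  toks <- toks[nzchar(toks)]
  vals <- suppressWarnings(as.numeric(toks))
  if (any(is.na(vals)))
    stop("read_prmtop: unparseable numeric data in section ", name)
  if (kind == "int") as.integer(vals) else vals
}

#' Read the prmtop subset
#'
#' Parses the FLAG/FORMAT sections written by [write_prmtop()] (a subset of
#' the AMBER format): charges are divided by 18.2223 to recover e, per-type
#' Lennard-Jones rmin/2 and epsilon are recovered from the diagonal
#' ACOEF/BCOEF entries, dihedral sign conventions are honoured (negative
#' 3rd index marks a 1-4-excluded duplicate, negative 4th an improper,
#' retained and flagged), and exclusion/1-4 sets are rebuilt from
#' connectivity. Missing mandatory sections and inconsistent POINTERS
#' counts are errors naming the section.
#'
#' @param path prmtop file
#' @return `list(topology =, params =)`
#' @export
read_prmtop <- function(path) {
  sec <- parse_prmtop_sections(path)
  ptr <- section_values(sec, "POINTERS", "int")
  if (length(ptr) < 19) stop("read_prmtop: POINTERS too short")
  natom <- ptr[1]; nty <- ptr[2]
  q <- section_values(sec, "CHARGE") / PRMTOP_CHARGE_UNIT
  mass <- section_values(sec, "MASS")
  names_ <- section_values(sec, "ATOM_NAME", "str")
  tyi <- section_values(sec, "ATOM_TYPE_INDEX", "int")
  nbidx <- section_values(sec, "NONBONDED_PARM_INDEX", "int")
  acoef <- section_values(sec, "LENNARD_JONES_ACOEF")
  bcoef <- section_values(sec, "LENNARD_JONES_BCOEF")
  tykey <- section_values(sec, "AMBER_ATOM_TYPE", "str")
  radii <- section_values(sec, "RADII")
  screen <- section_values(sec, "SCREEN")
  if (length(q) != natom || length(mass) != natom || length(tyi) != natom)
    stop("read_prmtop: atom-array length inconsistent with POINTERS NATOM")
  if (length(names_) != natom)
    stop("read_prmtop: ATOM_NAME count inconsistent with POINTERS NATOM")

  types <- character(nty)
  types[tyi] <- tykey
  kinds <- list()
  for (t in seq_len(nty)) {
    pos <- nbidx[nty * (t - 1) + t]
    a <- acoef[pos]; b <- bcoef[pos]
    if (a > 0 && b > 0) {
      rmin <- (2 * a / b)^(1 / 6)
      epsv <- b^2 / (4 * a)
    } else { rmin <- 0; epsv <- 0 }
    first <- which(tyi == t)[1]
    kinds[[types[t]]] <- atom_kind(types[t], mass[first], rmin / 2, epsv,
                                   radii[first], screen[first])
  }

  dec3 <- function(v) as.integer(abs(v) / 3 + 1)
  read_bonded <- function(flag_h, flag_noh, width) {
    v <- c(section_values(sec, flag_h, "int", required = FALSE) %||% integer(),
           section_values(sec, flag_noh, "int", required = FALSE) %||% integer())
    if (length(v) %% width)
      stop("read_prmtop: truncated index list in section ", flag_noh)
    matrix(v, ncol = width, byrow = TRUE)
  }
  braw <- read_bonded("BONDS_INC_HYDROGEN", "BONDS_WITHOUT_HYDROGEN", 3)
  araw <- read_bonded("ANGLES_INC_HYDROGEN", "ANGLES_WITHOUT_HYDROGEN", 4)
  draw <- read_bonded("DIHEDRALS_INC_HYDROGEN", "DIHEDRALS_WITHOUT_HYDROGEN", 5)
  if (nrow(braw) != ptr[3] + ptr[4])
    stop("read_prmtop: bond count inconsistent with POINTERS")
  if (nrow(araw) != ptr[5] + ptr[6])
    stop("read_prmtop: angle count inconsistent with POINTERS")
  if (nrow(draw) != ptr[7] + ptr[8])
    stop("read_prmtop: dihedral count inconsistent with POINTERS")

  bond_k <- section_values(sec, "BOND_FORCE_CONSTANT")
  bond_r0 <- section_values(sec, "BOND_EQUIL_VALUE")
  ang_k <- section_values(sec, "ANGLE_FORCE_CONSTANT")
  ang_t0 <- section_values(sec, "ANGLE_EQUIL_VALUE")
  dk <- section_values(sec, "DIHEDRAL_FORCE_CONSTANT")
  dn <- section_values(sec, "DIHEDRAL_PERIODICITY")
  dp <- section_values(sec, "DIHEDRAL_PHASE")
  scee <- section_values(sec, "SCEE_SCALE_FACTOR", required = FALSE)
  scnb <- section_values(sec, "SCNB_SCALE_FACTOR", required = FALSE)

  atoms <- data.frame(name = names_, type = tykey, charge = q, mass = mass,
                      stringsAsFactors = FALSE)
  ty <- tykey
  bonds <- cbind(dec3(braw[, 1]), dec3(braw[, 2]))
  bparams <- list()
  for (r in seq_len(nrow(braw))) {
    key <- canon_bond_key(ty[bonds[r, ]])
    if (is.null(bparams[[key]]))
      bparams[[key]] <- bond_param(bond_k[braw[r, 3]], bond_r0[braw[r, 3]])
  }
  angles <- cbind(dec3(araw[, 1]), dec3(araw[, 2]), dec3(araw[, 3]))
  aparams <- list()
  for (r in seq_len(nrow(araw))) {
    key <- canon_angle_key(ty[angles[r, ]])
    if (is.null(aparams[[key]]))
      aparams[[key]] <- angle_param(ang_k[araw[r, 4]],
                                    ang_t0[araw[r, 4]] * 180 / pi)
  }
  tors <- matrix(integer(), ncol = 4); impr <- logical(0)
  tparams <- list()
  if (nrow(draw)) {
    quad <- cbind(dec3(draw[, 1]), dec3(draw[, 2]), dec3(draw[, 3]),
                  dec3(draw[, 4]))
    is_imp <- draw[, 4] < 0
    # a quadruple may appear in either orientation (the writer reverses to
    # keep sign flags off atom 1); group over the orientation-free key
    qk <- apply(quad, 1, function(q) {
      f <- paste(q, collapse = "_"); r <- paste(rev(q), collapse = "_")
      if (r < f) r else f
    })
    for (u in unique(qk)) {
      rows <- which(qk == u)
      quad_u <- quad[rows[1], ]
      key <- canon_torsion_key(ty[quad_u])
      tors <- rbind(tors, quad_u)
      impr <- c(impr, any(is_imp[rows]))
      if (is.null(tparams[[key]])) {
        pidx <- draw[rows, 5]
        tparams[[key]] <- torsion_param(round(dn[pidx]), dk[pidx],
                                        dp[pidx] * 180 / pi)
      }
    }
  }
  params <- parameter_set(kinds, bparams, aparams, tparams,
                          scale_ee_14 = if (length(scee)) scee[1] else 1.2,
                          scale_vdw_14 = if (length(scnb)) scnb[1] else 2.0)
  partition <- rep("all", natom)
  rlab <- section_values(sec, "RESIDUE_LABEL", "str", required = FALSE)
  rptr <- section_values(sec, "RESIDUE_POINTER", "int", required = FALSE)
  if (!is.null(rlab) && !is.null(rptr) && any(rlab %in% c("HST", "GST"))) {
    rend <- c(rptr[-1] - 1, natom)
    for (r in seq_along(rlab))
      partition[rptr[r]:rend[r]] <-
        switch(rlab[r], HST = "host", GST = "guest", "all")
  }
  topo <- topology(atoms, bonds, angles = angles, torsions = tors,
                   improper = impr, partition = partition)
  check_parameters(topo, params)
  list(topology = topo, params = params)
}
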