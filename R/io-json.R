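TOPOLOGY_SCHEMA_NAME <- "endpointr-topology"
TOPOLOGY_SCHEMA_VERSION <- 1L

#' Read and write the versioned JSON topology + parameter schema
#'
#' The schema (`endpointr-topology`, version 1) stores the atom table,
#' 0-based bonded index lists, an optional host/guest partition, and the
#' full parameter set with explicit units (Angstrom, kcal/mol, e, amu,
#' degrees). Angle/torsion lists, exclusions and 1-4 pairs are rebuilt from
#' connectivity when absent; the partition defaults to `"all"`. Every
#' bonded term present must have a parameter key, otherwise reading fails
#' naming the key.
#'
#' @param path JSON file
#' @return `read_topology_json()` returns `list(topology =, params =)`.
#' @export
read_topology_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = TRUE, simplifyMatrix = TRUE)
  if (!identical(doc$schema, TOPOLOGY_SCHEMA_NAME))
    stop("read_topology_json: not an ", TOPOLOGY_SCHEMA_NAME, " file")
  if (!identical(as.integer(doc$version), TOPOLOGY_SCHEMA_VERSION))
    stop(sprintf("read_topology_json: schema version %s, expected %d",
                 doc$version, TOPOLOGY_SCHEMA_VERSION))
  atoms <- as.data.frame(doc$atoms)
  stopifnot(all(c("name", "type", "charge", "mass") %in% names(atoms)))
  to_mat <- function(x, width) {
    if (is.null(x) || !length(x)) return(NULL)
    m <- if (is.matrix(x)) x else matrix(unlist(x), ncol = width, byrow = TRUE)
    m + 1L  # schema stores 0-based indices
  }
  pr <- doc$parameters
  ak <- list()
  for (nm in names(pr$atom_kinds)) {
    a <- pr$atom_kinds[[nm]]
    ak[[nm]] <- atom_kind(nm, a$mass, a$lj_rmin_half, a$lj_epsilon,
                          a$gb_radius %||% 1.5, a$gb_screen %||% 0.8)
  }
  bp <- lapply(pr$bonds, function(p) bond_param(p$k, p$r0))
  ap <- lapply(pr$angles, function(p) angle_param(p$k, p$theta0))
  tp <- lapply(pr$torsions, function(p) {
    p <- as.data.frame(p)
    if (!nrow(p)) torsion_param()
    else torsion_param(p$n, p$half_barrier, p$phase)
  })
  params <- parameter_set(ak, bp, ap, tp,
                          scale_ee_14 = pr$scale_ee_14 %||% 1.2,
                          scale_vdw_14 = pr$scale_vdw_14 %||% 2.0)
  topo <- topology(atoms = atoms,
                   bonds = to_mat(doc$bonds, 2) %||% matrix(integer(), ncol = 2),
                   angles = to_mat(doc$angles, 3),
                   torsions = to_mat(doc$torsions, 4),
                   improper = if (!is.null(doc$improper)) as.logical(doc$improper),
                   partition = doc$partition)
  check_parameters(topo, params)
  list(topology = topo, params = params)
}

#' @rdname read_topology_json
#' @param topo a [topology()]
#' @param params a [parameter_set()]
#' @return `write_topology_json()` invisibly returns `path`.
#' @export
write_topology_json <- function(topo, params, path) {
  doc <- list(
    schema = TOPOLOGY_SCHEMA_NAME,
    version = TOPOLOGY_SCHEMA_VERSION,
    units = list(length = "angstrom", energy = "kcal/mol", charge = "e",
                 mass = "amu", angle = "degree"),
    atoms = topo$atoms,
    bonds = topo$bonds - 1L,
    angles = topo$angles - 1L,
    torsions = topo$torsions - 1L,
    improper = topo$improper,
    partition = topo$partition,
    parameters = list(
      atom_kinds = lapply(params$atom_kinds, function(a)
        a[c("mass", "lj_rmin_half", "lj_epsilon", "gb_radius", "gb_screen")]),
      bonds = lapply(params$bond_params, function(p) p[c("k", "r0")]),
      angles = lapply(params$angle_params, function(p) p[c("k", "theta0")]),
      torsions = lapply(params$torsion_params, function(p) p$components),
      scale_ee_14 = params$scale_ee_14,
      scale_vdw_14 = params$scale_vdw_14))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Read an experimental reference affinity table
#'
#' Two-column CSV (`id`, `dg_exp_kcal`), comma-separated with a header row
#' and `.` decimals. Duplicate identifiers and non-numeric affinities are
#' rejected; an empty file yields an empty table.
#'
#' @param path CSV file
#' @return data frame of class `"experiment_table"` with columns `id`,
#'   `dg_exp_kcal`
#' @export
read_experiment_csv <- function(path) {
  if (file.size(path) == 0)
    return(structure(data.frame(id = character(),
                                dg_exp_kcal = numeric()),
                     class = c("experiment_table", "data.frame")))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("read_experiment_csv: need columns id, dg_exp_kcal")
  names(df)[1:2] <- c("id", "dg_exp_kcal")
  if (anyDuplicated(df$id))
    stop("read_experiment_csv: duplicate id: ",
         df$id[duplicated(df$id)][1])
  if (!is.numeric(df$dg_exp_kcal)) {
    vals <- suppressWarnings(as.numeric(df$dg_exp_kcal))
    if (any(is.na(vals)))
      stop("read_experiment_csv: non-numeric affinity for id ",
           df$id[which(is.na(vals))[1]])
    df$dg_exp_kcal <- vals
  }
  structure(df[, c("id", "dg_exp_kcal")],
            class = c("experiment_table", "data.frame"))
}
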