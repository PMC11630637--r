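## Readers and writers: two-column CSV time series with unit headers, toy
## structures as PDB plus a sidecar CSV for charges/roles (PDB itself has no
## slot for either), OFF/legacy-VTK meshes, YAML/JSON configs, and run
## manifests for reproducibility.

#' Write a time series as a two-column CSV with a unit header
#'
#' Header form: `time[ns],force[pN]` -- the bracketed units are required on
#' both columns and are restored on reading.
#'
#' @param ts `time_series`.
#' @param path output file.
#' @export
write_timeseries <- function(ts, path) {
  stopifnot(inherits(ts, "time_series"))
  header <- sprintf("time[%s],%s[%s]", ts$t_unit, ts$name, ts$unit)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(sprintf("%.17g,%.17g", ts$t, ts$y), con)
  invisible(path)
}

#' Read a two-column CSV time series with a unit header
#'
#' @param path input file written by [write_timeseries()] (or compatible).
#' @return `time_series`.
#' @export
read_timeseries <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2) stop("empty or header-only time series file: ", path)
  hdr <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (length(hdr) != 2) stop("expected two header columns in ", path)
  parse_col <- function(h, which) {
    m <- regmatches(h, regexec("^\\s*([^\\[]+)\\[([^]]+)\\]\\s*$", h))[[1]]
    if (length(m) != 3)
      stop("missing unit in header for column '", h, "' (", which, ")")
    list(name = trimws(m[2]), unit = m[3])
  }
  tcol <- parse_col(hdr[1], "time column")
  ycol <- parse_col(hdr[2], "value column")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) != 2)
  vals <- suppressWarnings(
    lapply(parts, function(p) as.numeric(p[seq_len(min(2, length(p)))])))
  nonnum <- which(vapply(vals, function(v) any(is.na(v)) || length(v) < 2, TRUE))
  bad <- sort(unique(c(bad, nonnum)))
  if (length(bad))
    stop("malformed row(s) at line ", paste(bad + 1, collapse = ", "),
         " in ", path)
  m <- do.call(rbind, vals)
  time_series(m[, 1], m[, 2], unit = ycol$unit, name = ycol$name,
              t_unit = tcol$unit)
}

valid_roles <- c("none", "donor", "hydrogen", "acceptor")

#' Write a toy structure as PDB plus sidecar CSV
#'
#' Coordinates go to the PDB in Angstrom (converted from nm); masses,
#' charges, roles and donor assignments go to the sidecar keyed by atom
#' serial.
#'
#' @param struct `toy_structure`.
#' @param pdb_path,sidecar_path output files.
#' @export
write_structure <- function(struct, pdb_path, sidecar_path) {
  stopifnot(inherits(struct, "toy_structure"))
  n <- nrow(struct$coords)
  xyz <- as.vector(t(struct$coords * 10))  # nm -> Angstrom
  bio3d::write.pdb(file = pdb_path, xyz = xyz,
                   resno = struct$residue_id,
                   resid = rep("TOY", n),
                   elety = rep("CA", n),
                   chain = rep("A", n))
  donor_of <- rep(NA_integer_, n)
  if (nrow(struct$dh_pairs) > 0)
    donor_of[struct$dh_pairs[, "hydrogen"]] <- struct$dh_pairs[, "donor"]
  write.csv(data.frame(serial = seq_len(n), mass = struct$masses,
                       charge = struct$charges, role = struct$role,
                       donor_serial = donor_of),
            sidecar_path, row.names = FALSE)
  invisible(pdb_path)
}

#' Read a toy structure from PDB plus sidecar CSV
#'
#' @param pdb_path PDB with atom records (coordinates in Angstrom, converted
#'   to nm; residue ids kept).
#' @param sidecar_path CSV keyed by atom serial with columns
#'   `serial, mass, charge, role, donor_serial`.
#' @return `toy_structure`.
#' @export
read_structure <- function(pdb_path, sidecar_path) {
  pdb <- bio3d::read.pdb(pdb_path)
  at <- pdb$atom
  n <- nrow(at)
  side <- read.csv(sidecar_path, stringsAsFactors = FALSE)
  need <- c("serial", "mass", "charge", "role")
  if (!all(need %in% names(side)))
    stop("sidecar must have columns: ", paste(need, collapse = ", "))
  missing_serials <- setdiff(seq_len(n), side$serial)
  if (length(missing_serials))
    stop("sidecar is missing serial(s): ",
         paste(missing_serials, collapse = ", "))
  side <- side[match(seq_len(n), side$serial), ]
  if (!all(side$role %in% valid_roles))
    stop("unknown role string(s): ",
         paste(unique(setdiff(side$role, valid_roles)), collapse = ", "))
  dh <- NULL
  if ("donor_serial" %in% names(side)) {
    hyd <- which(!is.na(side$donor_serial))
    dh <- cbind(hydrogen = hyd, donor = as.integer(side$donor_serial[hyd]))
  }
  toy_structure(coords = angstrom_to_nm(cbind(at$x, at$y, at$z)),
                masses = side$mass, charges = side$charge,
                residue_id = at$resno, role = side$role, dh_pairs = dh)
}

#' Read a structured configuration file (YAML or JSON by extension)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return nested list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}

#' Write / read a triangle mesh in OFF format
#'
#' @param mesh `cell_mesh` (2D node coordinates are written with z = 0).
#' @param path file path.
#' @return `write_off` returns the path; `read_off` a node/element list (the
#'   boundary loop is not part of OFF and must be reconstructed by the
#'   caller).
#' @export
write_off <- function(mesh, path) {
  stopifnot(inherits(mesh, "cell_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$nodes), nrow(mesh$elements)), con)
  writeLines(sprintf("%.17g %.17g 0", mesh$nodes[, 1], mesh$nodes[, 2]), con)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L), con)
  invisible(path)
}

#' @rdname write_off
#' @export
read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (toupper(trimws(lines[1])) != "OFF") stop("not an OFF file: ", path)
  cnt <- as.integer(strsplit(trimws(lines[2]), "\\s+")[[1]])
  nv <- cnt[1]; nf <- cnt[2]
  vert <- do.call(rbind, lapply(lines[3:(2 + nv)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  face <- do.call(rbind, lapply(lines[(3 + nv):(2 + nv + nf)], function(l)
    as.integer(strsplit(trimws(l), "\\s+")[[1]])))
  if (any(face[, 1] != 3)) stop("read_off supports triangle meshes only")
  list(nodes = vert[, 1:2, drop = FALSE], elements = face[, 2:4] + 1L)
}

#' Write nodal fields on a triangle mesh as legacy ASCII VTK
#'
#' @param mesh `cell_mesh` (topology).
#' @param positions N x 2 current node coordinates (defaults to the mesh
#'   reference coordinates).
#' @param fields named list of per-node numeric vectors.
#' @param path output `.vtk` file.
#' @export
write_vtk_fields <- function(mesh, path, fields = list(), positions = NULL) {
  stopifnot(inherits(mesh, "cell_mesh"))
  if (is.null(positions)) positions <- mesh$nodes
  n <- nrow(positions); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "adhesim fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d double", n)),
             con)
  writeLines(sprintf("%.10g %.10g 0", positions[, 1], positions[, 2]), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1] - 1L,
                     mesh$elements[, 2] - 1L, mesh$elements[, 3] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(fields)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(fields)) {
      writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"),
                 con)
      writeLines(sprintf("%.10g", fields[[nm]]), con)
    }
  }
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration, its MD5 hash, the seeds and package version;
#' for the deterministic stages this is sufficient to reproduce outputs
#' bit-identically.
#'
#' @param path output JSON file.
#' @param config configuration list.
#' @param seeds seed vector used.
#' @export
write_manifest <- function(path, config, seeds) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  jsonlite::write_json(
    list(config = config, config_md5 = hash, seeds = seeds,
         package_version = as.character(utils::packageVersion("adhesim"))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
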