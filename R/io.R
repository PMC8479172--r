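# Structure and trajectory readers/writers. PDB handling is delegated to
# bio3d; DCD reading to bio3d::read.dcd. A plain-text columnar trajectory
# format (one frame per block) is supported so test fixtures stay
# human-readable.

#' Read a PDB structure
#'
#' Parses a PDB file into a topology plus the coordinates of its first
#' model. Residue ids are preserved verbatim from the file; coordinates are
#' in Angstrom. Domain labels are assigned from `domain_map` (residue-range
#' based) and default to OTHER.
#'
#' @param path Path to a PDB file.
#' @param domain_map Optional named list mapping domain labels (TM, PP, EL1,
#'   EL5, PEPTIDE, ION) to integer residue-id vectors.
#' @param param_table Optional nonbonded parameter table from
#'   [read_param_table()]; matched by (resname, atom name).
#' @return List with elements `top` (topology) and `xyz` (length-3N frame
#'   vector).
#' @export
read_structure <- function(path, domain_map = NULL, param_table = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("PDB parse error in ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  seg <- ifelse(!is.na(at$chain) & nzchar(at$chain), at$chain,
                ifelse(!is.na(at$segid), at$segid, ""))
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(elem))) {
    elem <- substr(trimws(at$elety), 1, 1)
  }
  elem <- ifelse(is.na(elem) | !nzchar(elem),
                 substr(trimws(at$elety), 1, 1), trimws(elem))
  atoms <- data.frame(
    atom_id = at$eleno,
    name = trimws(at$elety),
    element = elem,
    resid = at$resno,
    resname = trimws(at$resid),
    segment = seg,
    domain = "OTHER",
    mass = .mass_for_element(elem),
    stringsAsFactors = FALSE
  )
  if (!is.null(domain_map)) atoms$domain <- .apply_domain_map(atoms, domain_map)
  top <- new_topology(atoms)
  if (!is.null(param_table)) top <- assign_params(top, param_table)
  list(top = top, xyz = as.numeric(pdb$xyz[1, ]))
}

.apply_domain_map <- function(atoms, domain_map) {
  dom <- rep("OTHER", nrow(atoms))
  for (label in names(domain_map)) {
    if (!label %in% DOMAIN_LABELS) stop("unknown domain label: ", label)
    dom[atoms$resid %in% domain_map[[label]]] <- label
  }
  dom
}

#' Write a structure as PDB
#'
#' Inverse of [read_structure()] up to the format's fixed-width precision
#' (1e-3 Angstrom). When `rmsf` is given it is written into the B-factor
#' column, the conventional carrier for per-atom fluctuation.
#'
#' @param top A `topology`.
#' @param xyz Length-3N coordinate vector (Angstrom).
#' @param path Output path.
#' @param rmsf Optional per-atom RMSF (Angstrom) for the B-factor column.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(top, xyz, path, rmsf = NULL) {
  xyz <- as.numeric(xyz)
  if (length(xyz) != 3L * n_atoms(top)) stop("coordinate length mismatch")
  if (!all(is.finite(xyz))) stop("coordinates must be finite")
  if (any(abs(xyz) > 9999.999)) {
    stop("coordinates exceed the PDB fixed-width field limit (9999.999 A)")
  }
  at <- top$atoms
  b <- if (is.null(rmsf)) rep(0, nrow(at)) else round(rmsf, 2)
  bio3d::write.pdb(file = path, xyz = xyz, resno = at$resid,
                   resid = at$resname, eleno = at$atom_id, elety = at$name,
                   chain = ifelse(nzchar(at$segment),
                                  substr(at$segment, 1, 1), " "),
                   b = b)
  invisible(path)
}

#' Read a trajectory file
#'
#' Supports binary DCD (via bio3d) and the package's plain-text columnar
#' format (see [write_text_trajectory()]). The frame-saving stride of a
#' trajectory is not recoverable from either format, so `dt` is a required
#' input; frame times are `i * dt` for 0-based `i`.
#'
#' @param path Path to a `.dcd` or text trajectory file.
#' @param top The shared `topology`.
#' @param dt Frame spacing in ns.
#' @param replica_id,condition Labels stored on the trajectory.
#' @return A `trajectory`.
#' @export
read_trajectory <- function(path, top, dt, replica_id = "r1", condition = "") {
  if (!file.exists(path)) stop("cannot read trajectory file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext == "xtc") {
    stop("XTC trajectories are not supported; convert to DCD or the ",
         "plain-text columnar format")
  }
  xyz <- if (ext == "dcd") {
    if (file.size(path) == 0) stop("empty trajectory file: ", path)
    unclass(bio3d::read.dcd(path, verbose = FALSE))
  } else {
    read_text_trajectory(path)
  }
  if (nrow(xyz) < 1L) stop("trajectory file contains no frames: ", path)
  if (ncol(xyz) != 3L * n_atoms(top)) {
    stop(sprintf(
      "trajectory atom count (%d) does not match topology atom count (%d)",
      ncol(xyz) %/% 3L, n_atoms(top)))
  }
  new_trajectory(top, xyz, dt, replica_id = replica_id, condition = condition)
}

#' Plain-text columnar trajectory format
#'
#' One header line `natoms <N>`, then per frame a line `frame <i>` followed
#' by N whitespace-separated `x y z` rows (Angstrom, full double precision).
#'
#' @param xyz Frame matrix (frames x 3N).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_text_trajectory <- function(xyz, path) {
  xyz <- as.matrix(xyz)
  n <- ncol(xyz) %/% 3L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("natoms", n), con)
  for (i in seq_len(nrow(xyz))) {
    writeLines(paste("frame", i - 1L), con)
    m <- matrix(xyz[i, ], ncol = 3L, byrow = TRUE)
    writeLines(sprintf("%.10g %.10g %.10g", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' @rdname write_text_trajectory
#' @return For the reader, a frames x 3N matrix.
#' @export
read_text_trajectory <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[[1]], "natoms")) {
    stop("not a columnar text trajectory (missing 'natoms' header): ", path)
  }
  n <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]][2])
  body <- lines[-1]
  frame_starts <- grep("^frame\\b", body)
  if (!length(frame_starts)) stop("trajectory file contains no frames: ", path)
  rows <- lapply(frame_starts, function(s) {
    block <- body[(s + 1):(s + n)]
    vals <- scan(text = block, quiet = TRUE)
    if (length(vals) != 3L * n) stop("malformed frame block at line ", s + 1L)
    # block rows are per-atom x y z; flatten row-major
    vals
  })
  do.call(rbind, rows)
}

#' Read a sidecar nonbonded parameter table
#'
#' PDB files carry no force-field data, so charges and Lennard-Jones
#' parameters come from a TSV with header
#' `residue_name atom_name charge epsilon rmin_half`
#' (units: e, kcal/mol, Angstrom).
#'
#' @param path Path to the TSV.
#' @return data.frame of parameters.
#' @export
read_param_table <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "charge", "epsilon", "rmin_half")
  if (!all(need %in% names(tab))) {
    stop("parameter table must have columns: ", paste(need, collapse = " "))
  }
  tab
}

#' Attach nonbonded parameters to a topology
#'
#' @param top A `topology`.
#' @param params Parameter data.frame from [read_param_table()].
#' @return The topology with charge/epsilon/rmin_half filled where matched.
#' @export
assign_params <- function(top, params) {
  key_top <- paste(top$atoms$resname, top$atoms$name)
  key_par <- paste(params$residue_name, params$atom_name)
  hit <- match(key_top, key_par)
  found <- !is.na(hit)
  top$atoms$charge[found] <- params$charge[hit[found]]
  top$atoms$epsilon[found] <- params$epsilon[hit[found]]
  top$atoms$rmin_half[found] <- params$rmin_half[hit[found]]
  top
}
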