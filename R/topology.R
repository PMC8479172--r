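#' @importFrom stats sd cor setNames aggregate prcomp quantile rnorm runif
#' @importFrom utils head read.table write.table
NULL

DOMAIN_LABELS <- c("TM", "PP", "EL1", "EL5", "PEPTIDE", "ION", "OTHER")

# standard atomic masses (amu) used when the source file carries none
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, MG = 24.305, NA. = 22.990, CL = 35.45, K = 39.098,
  CA = 40.078, ZN = 65.38, FE = 55.845
)

.mass_for_element <- function(element) {
  m <- .element_masses[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Construct a topology
#'
#' A topology is the static description of a molecular system: one row per
#' atom with its identity, residue, segment, domain label, mass and optional
#' nonbonded parameters (partial charge, Lennard-Jones epsilon and r_min/2).
#' Atom order is the frame storage order and is stable across all frames of
#' every trajectory that references the topology.
#'
#' @param atoms data.frame with columns `atom_id`, `name`, `element`,
#'   `resid` (1-based residue id, preserved from the source file), `resname`,
#'   `segment`, `domain` (one of TM, PP, EL1, EL5, PEPTIDE, ION, OTHER),
#'   `mass` (amu) and optionally `charge` (e), `epsilon` (kcal/mol),
#'   `rmin_half` (Angstrom).
#' @return An object of class `topology`.
#' @export
new_topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  required <- c("atom_id", "name", "element", "resid", "resname", "segment",
                "domain", "mass")
  missing <- setdiff(required, names(atoms))
  if (length(missing)) {
    stop("topology is missing columns: ", paste(missing, collapse = ", "))
  }
  for (col in c("charge", "epsilon", "rmin_half")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  if (anyDuplicated(atoms$atom_id)) stop("atom_id values must be unique")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) {
    stop("all atom masses must be positive")
  }
  bad <- setdiff(unique(atoms$domain), DOMAIN_LABELS)
  if (length(bad)) {
    stop("unknown domain label(s): ", paste(bad, collapse = ", "))
  }
  atoms <- atoms[, c(required, "charge", "epsilon", "rmin_half")]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d residues (%s)\n",
              n_atoms(x), length(unique(x$atoms$resid)),
              paste(sort(unique(x$atoms$domain)), collapse = ", ")))
  invisible(x)
}

#' Number of atoms in a topology
#' @param top A `topology`.
#' @return Integer atom count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Residue ids of a topology
#' @param top A `topology`.
#' @return Sorted unique residue ids.
#' @export
residue_ids <- function(top) sort(unique(top$atoms$resid))

#' Construct a trajectory
#'
#' Coordinates are stored bio3d-style as an `n_frames x 3*n_atoms` matrix
#' (columns x1, y1, z1, x2, ...). Frames are 0-based with times `i * dt`.
#'
#' @param top A `topology`.
#' @param xyz Numeric matrix, one row per frame, `3 * n_atoms(top)` columns.
#' @param dt Frame spacing in ns.
#' @param replica_id Replica label.
#' @param condition Condition label (e.g. "NAT", "NAS").
#' @return An object of class `trajectory`.
#' @export
new_trajectory <- function(top, xyz, dt, replica_id = "r1", condition = "") {
  if (!inherits(top, "topology")) stop("top must be a topology")
  xyz <- as.matrix(xyz)
  if (nrow(xyz) < 1L) stop("a trajectory needs at least one frame")
  if (ncol(xyz) != 3L * n_atoms(top)) {
    stop(sprintf("coordinate columns (%d) do not match 3 x atom count (%d)",
                 ncol(xyz), 3L * n_atoms(top)))
  }
  if (!all(is.finite(xyz))) stop("all coordinates must be finite")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be a positive number of ns")
  structure(list(top = top, xyz = xyz, dt = dt,
                 replica_id = replica_id, condition = condition),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory '%s'%s: %d frames x %d atoms, dt = %g ns\n",
              x$replica_id,
              if (nzchar(x$condition)) paste0(" [", x$condition, "]") else "",
              n_frames(x), n_atoms(x$top), x$dt))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Frame times in ns
#' @param traj A `trajectory`.
#' @return Numeric vector `i * dt` for 0-based frame indices i.
#' @export
frame_times <- function(traj) (seq_len(n_frames(traj)) - 1L) * traj$dt

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj A `trajectory`.
#' @param i Frame index (1-based row into the frame matrix).
#' @return Numeric matrix with columns x, y, z.
#' @export
frame_coords <- function(traj, i) {
  matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
}

#' Convert a flat xyz vector to an n x 3 matrix (and back)
#' @param v Numeric vector of length 3n (x1, y1, z1, ...).
#' @return n x 3 matrix.
#' @export
xyz_to_mat <- function(v) matrix(v, ncol = 3L, byrow = TRUE)

#' @rdname xyz_to_mat
#' @param m n x 3 coordinate matrix.
#' @export
mat_to_xyz <- function(m) as.numeric(t(m))

#' Construct an ensemble of trajectories sharing one topology
#'
#' @param trajectories List of `trajectory` objects with identical atom
#'   count and ordering.
#' @param metadata Optional data.frame of per-replica metadata.
#' @return An object of class `ensemble`.
#' @export
new_ensemble <- function(trajectories, metadata = NULL) {
  if (!length(trajectories)) stop("ensemble needs at least one trajectory")
  if (!all(vapply(trajectories, inherits, logical(1), "trajectory"))) {
    stop("all ensemble members must be trajectory objects")
  }
  na <- vapply(trajectories, function(t) n_atoms(t$top), integer(1))
  if (length(unique(na)) != 1L) {
    stop("all ensemble members must share the same atom count")
  }
  names(trajectories) <- vapply(trajectories, function(t) t$replica_id,
                                character(1))
  structure(list(trajectories = trajectories, metadata = metadata),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  nf <- vapply(x$trajectories, n_frames, integer(1))
  cat(sprintf("ensemble: %d replicas, %d total frames, %d atoms\n",
              length(x$trajectories), sum(nf),
              n_atoms(x$trajectories[[1]]$top)))
  invisible(x)
}

#' Pool masked frames of an ensemble into one coordinate matrix
#' @param ens An `ensemble`.
#' @param frame_masks Optional list (per replica) of 1-based frame indices;
#'   `NULL` keeps all frames.
#' @return Matrix of pooled frames (rows) by 3*n_atoms columns.
#' @export
pool_frames <- function(ens, frame_masks = NULL) {
  mats <- lapply(seq_along(ens$trajectories), function(i) {
    tr <- ens$trajectories[[i]]
    m <- if (is.null(frame_masks)) seq_len(n_frames(tr)) else frame_masks[[i]]
    tr$xyz[m, , drop = FALSE]
  })
  do.call(rbind, mats)
}

# ---- selections --------------------------------------------------------

#' Selection expressions
#'
#' `sel()` builds an atomic selection from residue ids/ranges, atom names,
#' domain labels and explicit atom ids (criteria are intersected);
#' `sel_union()` and `sel_intersect()` compose selections. A selection
#' resolves (via [select_atoms()]) to a deterministic sorted atom-id set.
#'
#' @param resid Integer vector of residue ids (ranges via `seq`/`:`).
#' @param name Character vector of atom names.
#' @param domain Character vector of domain labels.
#' @param atom_id Explicit atom ids.
#' @return A `selection` object.
#' @export
sel <- function(resid = NULL, name = NULL, domain = NULL, atom_id = NULL) {
  structure(list(kind = "leaf", resid = resid, name = name,
                 domain = domain, atom_id = atom_id), class = "selection")
}

#' @rdname sel
#' @param a,b Selections to combine.
#' @export
sel_union <- function(a, b) {
  structure(list(kind = "union", a = a, b = b), class = "selection")
}

#' @rdname sel
#' @export
sel_intersect <- function(a, b) {
  structure(list(kind = "intersect", a = a, b = b), class = "selection")
}

#' Resolve a selection to atom ids
#'
#' @param top A `topology`.
#' @param expr A `selection` from [sel()]/[sel_union()]/[sel_intersect()].
#' @param warn_empty Warn when the selection resolves to no atoms.
#' @return Sorted integer vector of atom ids.
#' @export
select_atoms <- function(top, expr, warn_empty = TRUE) {
  ids <- .resolve_sel(top, expr)
  if (!length(ids) && warn_empty) warning("selection resolved to no atoms")
  sort(ids)
}

.resolve_sel <- function(top, expr) {
  if (!inherits(expr, "selection")) stop("expr must be a selection")
  if (expr$kind == "union") {
    return(union(.resolve_sel(top, expr$a), .resolve_sel(top, expr$b)))
  }
  if (expr$kind == "intersect") {
    return(intersect(.resolve_sel(top, expr$a), .resolve_sel(top, expr$b)))
  }
  at <- top$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(expr$resid)) {
    missing <- setdiff(expr$resid, at$resid)
    if (length(missing)) {
      stop("selection references nonexistent residue id(s): ",
           paste(sort(missing), collapse = ", "))
    }
    keep <- keep & at$resid %in% expr$resid
  }
  if (!is.null(expr$name)) keep <- keep & at$name %in% expr$name
  if (!is.null(expr$domain)) keep <- keep & at$domain %in% expr$domain
  if (!is.null(expr$atom_id)) keep <- keep & at$atom_id %in% expr$atom_id
  at$atom_id[keep]
}

#' Row indices (frame storage order) for a set of atom ids
#' @param top A `topology`.
#' @param atom_ids Atom ids as returned by [select_atoms()].
#' @return Integer positions into the atom table / frame rows.
#' @export
atom_index <- function(top, atom_ids) {
  idx <- match(atom_ids, top$atoms$atom_id)
  if (anyNA(idx)) {
    stop("unknown atom id(s): ",
         paste(atom_ids[is.na(idx)], collapse = ", "))
  }
  idx
}

# column indices into an xyz matrix for atom positions idx
.xyz_cols <- function(idx) {
  as.numeric(t(outer(3 * (idx - 1), 1:3, "+")))
}

#' Subset an xyz frame matrix to a set of atom positions
#' @param xyz Frame matrix (frames x 3N).
#' @param idx Atom positions (1-based storage order).
#' @return Frame matrix restricted to those atoms.
#' @export
xyz_subset <- function(xyz, idx) {
  xyz[, .xyz_cols(idx), drop = FALSE]
}
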