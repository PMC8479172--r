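# Cross-correlation matrices of atomic fluctuations, Cartesian PCA,
# subspace comparison (RMSIP) and projection densities. Both the
# correlation matrix and the PCA operate on Calpha atoms by default and
# assume frames superposed on the stable core, so that what remains is
# internal motion.

#' Dynamic cross-correlation matrix
#'
#' Normalised covariance of positional fluctuations,
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2> <|dr_j|^2>)`,
#' computed over pooled (optionally masked) frames after core alignment.
#' Atoms with zero variance get zero off-diagonal entries and a warning.
#'
#' @param ens An `ensemble` (or `trajectory`).
#' @param atom_name Atom per residue (default "CA"); ignored when
#'   `atom_ids` is given.
#' @param atom_ids Optional explicit atom ids to correlate.
#' @param core Optional `stable_core` (or residue ids) for alignment;
#'   `NULL` skips alignment.
#' @param frame_masks Optional per-replica frame masks.
#' @return A `ccmatrix`: list with `C` (symmetric, unit diagonal),
#'   `residues` (node residue ids), `atom_ids`.
#' @export
cross_correlation <- function(ens, atom_name = "CA", atom_ids = NULL,
                              core = NULL, frame_masks = NULL) {
  if (inherits(ens, "trajectory")) ens <- new_ensemble(list(ens))
  top <- ens$trajectories[[1]]$top
  if (is.null(atom_ids)) {
    atom_ids <- select_atoms(top, sel(name = atom_name))
  }
  idx <- atom_index(top, atom_ids)
  if (!is.null(frame_masks) && !is.list(frame_masks)) {
    frame_masks <- rep(list(frame_masks), length(ens$trajectories))
  }
  xyz <- pool_frames(ens, frame_masks)
  if (nrow(xyz) < 2) stop("cross-correlation needs >= 2 masked frames")
  if (!is.null(core)) {
    fit <- .core_fit_atoms(top, core)
    xyz <- align_frames(xyz, xyz[1, ], fit)
  }
  sub <- xyz_subset(xyz, idx)
  cs <- scale(sub, center = TRUE, scale = FALSE)
  n <- length(idx)
  cols_x <- seq(1, 3 * n, by = 3)
  num <- crossprod(cs[, cols_x]) + crossprod(cs[, cols_x + 1]) +
    crossprod(cs[, cols_x + 2])
  v <- diag(num)
  zero <- v < 1e-20
  if (any(zero)) {
    warning(sum(zero), " zero-variance atom(s); their correlations set to 0")
    v[zero] <- 1
  }
  C <- num / sqrt(outer(v, v))
  if (any(zero)) {
    C[zero, ] <- 0; C[, zero] <- 0
  }
  diag(C) <- 1
  resids <- top$atoms$resid[idx]
  dimnames(C) <- list(resids, resids)
  structure(list(C = C, residues = resids, atom_ids = atom_ids),
            class = "ccmatrix")
}

#' Cartesian principal component analysis
#'
#' Eigendecomposition of the coordinate covariance of pooled frames
#' (typically both conditions combined, bound frames only), on a chosen
#' atom set with optional residue-range exclusions (e.g. an unstructured
#' loop), after core alignment.
#'
#' @param ens An `ensemble`, `trajectory`, or frame matrix (frames x 3N).
#' @param atom_name Atom per residue (default "CA").
#' @param exclude_residues Residue ids to drop from the analysis.
#' @param core Optional `stable_core`/residue ids for alignment.
#' @param frame_masks Optional per-replica frame masks.
#' @param top Topology (required when `ens` is a bare matrix).
#' @return A `pca_model`: list with `mean` (3n), `vectors` (3n x k,
#'   orthonormal columns), `values` (eigenvalues, A^2, non-increasing),
#'   `var_fraction`, `projections` (frames x k), `atom_ids`.
#' @export
cartesian_pca <- function(ens, atom_name = "CA", exclude_residues = NULL,
                          core = NULL, frame_masks = NULL, top = NULL) {
  if (inherits(ens, "trajectory")) ens <- new_ensemble(list(ens))
  if (inherits(ens, "ensemble")) {
    top <- ens$trajectories[[1]]$top
    if (!is.null(frame_masks) && !is.list(frame_masks)) {
      frame_masks <- rep(list(frame_masks), length(ens$trajectories))
    }
    xyz <- pool_frames(ens, frame_masks)
  } else {
    xyz <- ens
    if (is.null(top)) stop("supply a topology with a bare frame matrix")
  }
  if (nrow(xyz) < 2) stop("PCA needs at least 2 frames")
  atom_ids <- select_atoms(top, sel(name = atom_name))
  if (!is.null(exclude_residues)) {
    drop <- select_atoms(top, sel(resid = exclude_residues,
                                  name = atom_name), warn_empty = FALSE)
    atom_ids <- setdiff(atom_ids, drop)
  }
  idx <- atom_index(top, atom_ids)
  if (!is.null(core)) {
    fit <- .core_fit_atoms(top, core)
    xyz <- align_frames(xyz, xyz[1, ], fit)
  }
  sub <- xyz_subset(xyz, idx)
  if (nrow(sub) < ncol(sub)) {
    warning("fewer frames (", nrow(sub), ") than coordinate dimensions (",
            ncol(sub), "); trailing components are noise-limited")
  }
  pc <- prcomp(sub, center = TRUE, scale. = FALSE)
  values <- pc$sdev^2
  structure(list(mean = pc$center, vectors = pc$rotation, values = values,
                 var_fraction = values / sum(values),
                 projections = pc$x, atom_ids = atom_ids),
            class = "pca_model")
}

#' Project frames onto a PCA model
#' @param model A `pca_model`.
#' @param xyz Frame matrix restricted to the model's atoms (frames x 3n),
#'   or a full frame matrix plus `top` to subset.
#' @param top Optional topology for subsetting full frames.
#' @param k Number of components (default 2).
#' @return Matrix of projections (frames x k).
#' @export
project_frames <- function(model, xyz, top = NULL, k = 2) {
  if (!is.null(top)) xyz <- xyz_subset(xyz, atom_index(top, model$atom_ids))
  sweep(xyz, 2, model$mean) %*% model$vectors[, seq_len(k), drop = FALSE]
}

#' Root mean square inner product between PCA subspaces
#'
#' `sqrt( (1/k) sum_{i<=k} sum_{j<=k} (v_i^A . v_j^B)^2 )`, a symmetric
#' measure of overlap between the leading k-dimensional subspaces.
#'
#' @param modelA,modelB `pca_model` objects over the same atom universe.
#' @param k Mode count (default 10, capped at the available modes).
#' @return Value in [0, 1].
#' @export
rmsip <- function(modelA, modelB, k = 10) {
  if (nrow(modelA$vectors) != nrow(modelB$vectors)) {
    stop("models have mismatched coordinate dimensions")
  }
  k <- min(k, ncol(modelA$vectors), ncol(modelB$vectors))
  va <- modelA$vectors[, seq_len(k), drop = FALSE]
  vb <- modelB$vectors[, seq_len(k), drop = FALSE]
  sqrt(sum((t(va) %*% vb)^2) / k)
}

#' Projection density maps over the first two principal components
#'
#' Gaussian-kernel density (normal-reference bandwidth) per condition on a
#' shared grid, each normalised to sum to 1 over grid cells, with summary
#' statistics per condition: the fraction of points inside the 1-sd
#' Mahalanobis ellipse and the tail fraction beyond 2 sd.
#'
#' @param projections Named list (per condition) of n x 2 projection
#'   matrices.
#' @param grid_n Grid points per axis (default 64).
#' @return A `projection_density`: list with `x`, `y`, per-condition
#'   `density` matrices and `summary` data.frame.
#' @export
projection_density <- function(projections, grid_n = 64) {
  if (any(!vapply(projections, nrow, integer(1)))) {
    stop("every condition needs at least one projected frame")
  }
  all_pts <- do.call(rbind, projections)
  lims <- c(range(all_pts[, 1]), range(all_pts[, 2]))
  pad <- c(diff(lims[1:2]), diff(lims[3:4])) * 0.1
  lims <- lims + c(-pad[1], pad[1], -pad[2], pad[2])
  dens <- lapply(projections, function(p) {
    h <- c(MASS::bandwidth.nrd(p[, 1]), MASS::bandwidth.nrd(p[, 2]))
    h[h <= 0] <- 0.1
    kd <- MASS::kde2d(p[, 1], p[, 2], h = h, n = grid_n, lims = lims)
    kd$z / sum(kd$z)
  })
  summ <- do.call(rbind, lapply(names(projections), function(cond) {
    p <- projections[[cond]]
    ctr <- colMeans(p)
    s <- apply(p, 2, sd); s[s <= 0] <- 1e-12
    md <- sqrt(((p[, 1] - ctr[1]) / s[1])^2 + ((p[, 2] - ctr[2]) / s[2])^2)
    data.frame(condition = cond, n = nrow(p),
               central_fraction = mean(md <= 1),
               tail_fraction = mean(md > 2),
               stringsAsFactors = FALSE)
  }))
  kd0 <- MASS::kde2d(all_pts[, 1], all_pts[, 2], n = grid_n, lims = lims)
  structure(list(x = kd0$x, y = kd0$y, density = dens, summary = summ),
            class = "projection_density")
}

#' Jack-knife analysis of the leading principal components
#'
#' Each replica is excluded in turn, the PCA recomputed on the rest, and
#' the overlap (RMSIP of the first `k` components) with the full model
#' reported. Consistently high overlaps indicate the replicas sample the
#' same conformational subspace.
#'
#' @param ens An `ensemble` with >= 3 replicas.
#' @param atom_name,exclude_residues,core,frame_masks As [cartesian_pca()].
#' @param k Modes compared (default 2).
#' @return data.frame (excluded, overlap).
#' @export
jackknife_projection <- function(ens, atom_name = "CA",
                                 exclude_residues = NULL, core = NULL,
                                 frame_masks = NULL, k = 2) {
  nrep <- length(ens$trajectories)
  if (nrep < 3) stop("jack-knife projection needs >= 3 replicas")
  if (!is.null(frame_masks) && !is.list(frame_masks)) {
    frame_masks <- rep(list(frame_masks), nrep)
  }
  full <- cartesian_pca(ens, atom_name, exclude_residues, core, frame_masks)
  out <- do.call(rbind, lapply(seq_len(nrep), function(r) {
    sub <- new_ensemble(ens$trajectories[-r])
    masks <- if (is.null(frame_masks)) NULL else frame_masks[-r]
    m <- cartesian_pca(sub, atom_name, exclude_residues, core, masks)
    data.frame(excluded = ens$trajectories[[r]]$replica_id,
               overlap = rmsip(full, m, k = k),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
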