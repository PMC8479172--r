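# Superposition, stable-core identification, average / most-populated
# structures, distance-difference maps, the hinge scan and latch-distance
# histograms. All comparative analyses assume frames have been superposed
# on the stable core first, which removes rigid-body translation/rotation
# without masking the inter-domain motion of interest.

#' Kabsch superposition
#'
#' Least-squares optimal rigid transform (rotation + translation) mapping
#' `mobile` onto `reference` over a fit atom set, via SVD of the covariance
#' of the centred coordinates with the usual reflection guard
#' (det(rotation) = +1).
#'
#' @param mobile,reference Length-3N coordinate vectors or N x 3 matrices.
#' @param atom_set 1-based atom positions used for the fit (>= 3,
#'   non-collinear). Default: all atoms.
#' @return A `superposition`: list with `rotation` (3 x 3), `translation`
#'   (length 3; apply as `x %*% rotation + translation`), `atom_set`,
#'   `rmsd` (over the fit set, Angstrom).
#' @export
kabsch_superpose <- function(mobile, reference, atom_set = NULL) {
  P <- if (is.matrix(mobile)) mobile else xyz_to_mat(mobile)
  Q <- if (is.matrix(reference)) reference else xyz_to_mat(reference)
  if (is.null(atom_set)) atom_set <- seq_len(nrow(P))
  if (length(atom_set) < 3) stop("superposition needs >= 3 fit atoms")
  p <- P[atom_set, , drop = FALSE]
  q <- Q[atom_set, , drop = FALSE]
  if (qr(sweep(p, 2, colMeans(p)))$rank < 2) {
    stop("fit atoms are collinear or degenerate")
  }
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  H <- t(pc) %*% qc
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  tr <- cq - as.numeric(cp %*% R)
  fitted <- sweep(p %*% R, 2, tr, "+")
  rmsd <- sqrt(mean(rowSums((fitted - q)^2)))
  structure(list(rotation = R, translation = tr, atom_set = atom_set,
                 rmsd = rmsd), class = "superposition")
}

#' Apply a superposition to coordinates
#' @param xyz Length-3N vector or N x 3 matrix.
#' @param sp A `superposition`.
#' @return Transformed coordinates in the input's shape.
#' @export
apply_superposition <- function(xyz, sp) {
  was_vec <- !is.matrix(xyz)
  m <- if (was_vec) xyz_to_mat(xyz) else xyz
  out <- sweep(m %*% sp$rotation, 2, sp$translation, "+")
  if (was_vec) mat_to_xyz(out) else out
}

#' Superpose every frame of a coordinate matrix onto a reference
#' @param xyz Frame matrix (frames x 3N).
#' @param ref_xyz Reference frame (length 3N).
#' @param atom_set Fit atom positions.
#' @return Frame matrix of aligned coordinates.
#' @export
align_frames <- function(xyz, ref_xyz, atom_set) {
  ref <- xyz_to_mat(ref_xyz)
  out <- xyz
  for (i in seq_len(nrow(xyz))) {
    sp <- kabsch_superpose(xyz[i, ], ref, atom_set)
    out[i, ] <- mat_to_xyz(apply_superposition(xyz_to_mat(xyz[i, ]), sp))
  }
  out
}

#' Identify the stable core of an ensemble
#'
#' Residues with the least variation in position are found by clustering
#' the inter-residue distance-fluctuation matrix (the SD over frames of
#' every pairwise atom-atom distance for one atom per residue):
#' hierarchical clustering with average linkage, cut into `n_clusters`
#' groups; the cluster (of at least `min_size` residues) with the smallest
#' mean internal fluctuation is the core. Deterministic for fixed input;
#' a zero-fluctuation (static) input ties everywhere and returns the
#' cluster containing the lowest residue id, with a warning.
#'
#' @param ens An `ensemble` (or single `trajectory`).
#' @param atom_name Atom per residue used to measure fluctuation
#'   (default "CA").
#' @param n_clusters Number of clusters to cut (default 5).
#' @param min_size Smallest usable core size (default 3, the superposition
#'   minimum).
#' @param frame_masks Optional per-replica frame masks.
#' @param exclude_domains Domain labels never admitted to the core; the
#'   default keeps the core within the protein (no ligand, no ions).
#' @return A `stable_core`: list with `residues`, per-residue `score`
#'   (mean distance fluctuation, Angstrom), `clusters` (residue -> cluster).
#' @export
find_stable_core <- function(ens, atom_name = "CA", n_clusters = 5,
                             min_size = 3, frame_masks = NULL,
                             exclude_domains = c("PEPTIDE", "ION")) {
  if (inherits(ens, "trajectory")) ens <- new_ensemble(list(ens))
  top <- ens$trajectories[[1]]$top
  keep <- top$atoms$name == atom_name &
    !(top$atoms$domain %in% exclude_domains)
  res <- sort(unique(top$atoms$resid[keep]))
  if (length(res) < n_clusters) {
    stop("fewer residues (", length(res), ") than requested clusters (",
         n_clusters, ")")
  }
  idx <- atom_index(top, select_atoms(top, sel(resid = res,
                                               name = atom_name)))
  xyz <- pool_frames(ens, frame_masks)
  if (nrow(xyz) < 2) stop("stable-core identification needs >= 2 frames")
  nr <- length(res)
  s1 <- matrix(0, nr, nr); s2 <- matrix(0, nr, nr)
  for (i in seq_len(nrow(xyz))) {
    dm <- as.matrix(stats::dist(xyz_to_mat(xyz[i, ])[idx, , drop = FALSE]))
    s1 <- s1 + dm
    s2 <- s2 + dm^2
  }
  nfr <- nrow(xyz)
  fluct <- s2 / nfr - (s1 / nfr)^2
  fluct[fluct < 0] <- 0
  fluct <- sqrt(fluct)
  if (all(fluct < 1e-5)) {
    warning("static input: all residues tie; returning the cluster ",
            "containing the lowest residue id")
  }
  hc <- stats::hclust(stats::as.dist(fluct), method = "average")
  cl <- stats::cutree(hc, k = n_clusters)
  cl_score <- vapply(seq_len(n_clusters), function(k) {
    members <- which(cl == k)
    if (length(members) < min_size) return(Inf)
    sub <- fluct[members, members]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  if (all(!is.finite(cl_score))) stop("no cluster reaches the minimum size")
  # small clusters reach low scores by selection bias alone; clusters
  # within 1.5x of the minimal fluctuation count as equally rigid and the
  # largest of them is kept (more fit atoms stabilise the superposition),
  # ties broken by lowest residue id
  near <- which(cl_score <= 1.5 * min(cl_score) + 1e-12)
  sizes <- vapply(near, function(k) sum(cl == k), integer(1))
  best <- near[sizes == max(sizes)]
  if (length(best) > 1) {
    firsts <- vapply(best, function(k) min(res[cl == k]), numeric(1))
    best <- best[which.min(firsts)]
  }
  # refinement: agglomeration can attach stray mobile residues to the
  # rigid cluster; trim members whose mean fluctuation against the rest
  # of the cluster exceeds 3x the member median
  members <- which(cl == best)
  while (length(members) > min_size) {
    sub <- fluct[members, members, drop = FALSE]
    ms <- rowSums(sub) / (length(members) - 1)
    bad <- ms > 3 * stats::median(ms) + 1e-9
    if (!any(bad) || length(members) - sum(bad) < min_size) break
    members <- members[!bad]
  }
  score <- rowMeans(fluct)
  names(score) <- res
  structure(list(residues = res[members], score = score,
                 clusters = setNames(cl, res)),
            class = "stable_core")
}

#' @export
print.stable_core <- function(x, ...) {
  cat(sprintf("stable core: %d residues (mean fluctuation %.3f A)\n",
              length(x$residues),
              mean(x$score[as.character(x$residues)])))
  invisible(x)
}

.core_fit_atoms <- function(top, core, atom_name = "CA") {
  residues <- if (inherits(core, "stable_core")) core$residues else core
  atom_index(top, select_atoms(top, sel(resid = residues, name = atom_name)))
}

#' Time-averaged structure with per-atom RMSF
#'
#' Frames (optionally masked, e.g. bound frames only) are superposed on the
#' stable core, then averaged per atom; the per-atom RMSF about that mean
#' is recorded and can be written to the B-factor column by
#' [write_structure()].
#'
#' @param x A `trajectory` or `ensemble`.
#' @param core A `stable_core` (or residue-id vector) used for alignment;
#'   `NULL` skips alignment (frames already superposed).
#' @param frame_masks Optional per-replica masks (list) or single vector.
#' @param atom_name Fit atom name for the core alignment.
#' @return An `avg_structure`: list with `top`, `xyz` (mean, length 3N),
#'   `rmsf` (per atom, Angstrom), `n_frames`.
#' @export
average_structure <- function(x, core = NULL, frame_masks = NULL,
                              atom_name = "CA") {
  if (inherits(x, "trajectory")) x <- new_ensemble(list(x))
  if (!is.null(frame_masks) && !is.list(frame_masks)) {
    frame_masks <- rep(list(frame_masks), length(x$trajectories))
  }
  top <- x$trajectories[[1]]$top
  xyz <- pool_frames(x, frame_masks)
  if (!nrow(xyz)) stop("frame mask is empty")
  if (!is.null(core)) {
    fit <- .core_fit_atoms(top, core, atom_name)
    xyz <- align_frames(xyz, xyz[1, ], fit)
  }
  mean_xyz <- colMeans(xyz)
  dev2 <- sweep(xyz, 2, mean_xyz)^2
  per_atom <- matrix(colSums(dev2), ncol = 3, byrow = TRUE)
  rmsf <- sqrt(rowSums(per_atom) / nrow(xyz))
  structure(list(top = top, xyz = mean_xyz, rmsf = rmsf,
                 n_frames = nrow(xyz)),
            class = "avg_structure")
}

#' RMSD between two structures in a common frame
#'
#' Root mean square coordinate difference over an atom subset, computed
#' without re-superposition: both structures are assumed to already sit in
#' the shared core-aligned frame.
#'
#' @param a,b `avg_structure` objects (or length-3N vectors sharing the
#'   atom ordering).
#' @param atom_set 1-based atom positions; default all atoms.
#' @return RMSD in Angstrom.
#' @export
rmsd_between_structures <- function(a, b, atom_set = NULL) {
  xa <- if (inherits(a, "avg_structure")) a$xyz else a
  xb <- if (inherits(b, "avg_structure")) b$xyz else b
  if (length(xa) != length(xb)) stop("structures differ in atom count")
  ma <- xyz_to_mat(xa); mb <- xyz_to_mat(xb)
  if (is.null(atom_set)) atom_set <- seq_len(nrow(ma))
  if (!length(atom_set)) stop("atom subset is empty")
  sqrt(mean(rowSums((ma[atom_set, , drop = FALSE] -
                       mb[atom_set, , drop = FALSE])^2)))
}

BACKBONE_ATOMS <- c("N", "CA", "C", "O")

#' Per-residue backbone RMSD between two structures
#' @param a,b `avg_structure` objects.
#' @param residues Residue ids (default: all shared residues).
#' @return Named numeric vector of per-residue backbone RMSD (Angstrom).
#' @export
per_residue_rmsd <- function(a, b, residues = NULL) {
  top <- a$top
  if (is.null(residues)) residues <- residue_ids(top)
  vapply(setNames(residues, residues), function(r) {
    idx <- atom_index(top, select_atoms(
      top, sel(resid = r, name = BACKBONE_ATOMS), warn_empty = FALSE))
    rmsd_between_structures(a, b, idx)
  }, numeric(1))
}

#' Most populated structure
#'
#' Histograms every masked frame on two order parameters - the inter-domain
#' Cα-Cα distance (centroid of `group_resids` Cα atoms to the Cα of
#' `ref_resid`) and the backbone RMSD to a reference structure - and
#' returns the frame nearest the centre of the highest-density 2-D bin
#' (ties broken by the earliest frame).
#'
#' @param traj A `trajectory` (frames already core-aligned with the
#'   reference).
#' @param group_resids Residue ids whose Cα centroid anchors the distance.
#' @param ref_resid Single residue id for the other end of the distance.
#' @param reference An `avg_structure`.
#' @param frame_mask Optional 1-based frame indices (e.g. bound frames).
#' @param dist_bin,rmsd_bin Bin widths (Angstrom), defaults 0.5 and 0.25.
#' @return List with `frame` (1-based index), `distance`, `rmsd`,
#'   `mode_distance`, `mode_rmsd` (bin centres of the modal bin).
#' @export
most_populated_structure <- function(traj, group_resids, ref_resid,
                                     reference, frame_mask = NULL,
                                     dist_bin = 0.5, rmsd_bin = 0.25) {
  if (is.null(frame_mask)) frame_mask <- seq_len(n_frames(traj))
  if (!length(frame_mask)) stop("frame mask is empty")
  top <- traj$top
  gidx <- atom_index(top, select_atoms(top, sel(resid = group_resids,
                                                name = "CA")))
  ridx <- atom_index(top, select_atoms(top, sel(resid = ref_resid,
                                                name = "CA")))
  bb <- atom_index(top, select_atoms(top, sel(name = BACKBONE_ATOMS)))
  refm <- xyz_to_mat(reference$xyz)
  dval <- numeric(length(frame_mask)); rval <- numeric(length(frame_mask))
  for (k in seq_along(frame_mask)) {
    m <- frame_coords(traj, frame_mask[k])
    cen <- colMeans(m[gidx, , drop = FALSE])
    dval[k] <- sqrt(sum((cen - m[ridx, ])^2))
    rval[k] <- sqrt(mean(rowSums((m[bb, , drop = FALSE] -
                                    refm[bb, , drop = FALSE])^2)))
  }
  bx <- floor(dval / dist_bin); by <- floor(rval / rmsd_bin)
  key <- paste(bx, by)
  counts <- table(key)
  top_key <- names(counts)[counts == max(counts)][1]
  kb <- as.numeric(strsplit(top_key, " ")[[1]])
  cx <- (kb[1] + 0.5) * dist_bin; cy <- (kb[2] + 0.5) * rmsd_bin
  score <- ((dval - cx) / dist_bin)^2 + ((rval - cy) / rmsd_bin)^2
  pick <- which.min(score)  # which.min returns the earliest tie
  list(frame = frame_mask[pick], distance = dval[pick], rmsd = rval[pick],
       mode_distance = cx, mode_rmsd = cy)
}

#' Cα-Cα distance-difference map between two conditions
#'
#' Computes the time-averaged Cα-Cα distance for every residue pair in each
#' condition and their difference (condition A minus condition B), plus
#' mean differences per domain-label block. The map is antisymmetric under
#' swapping the conditions, with zero diagonal.
#'
#' @param ensA,ensB Ensembles sharing residue numbering.
#' @param frame_masksA,frame_masksB Optional per-replica frame masks.
#' @param atom_name Atom per residue (default "CA").
#' @return A `ddmap`: list with `residues`, `delta` (pairwise matrix, A-B),
#'   `blocks` (data.frame of per-domain-pair mean differences).
#' @export
distance_difference_map <- function(ensA, ensB, frame_masksA = NULL,
                                    frame_masksB = NULL, atom_name = "CA") {
  topA <- ensA$trajectories[[1]]$top
  topB <- ensB$trajectories[[1]]$top
  resA <- sort(unique(topA$atoms$resid[topA$atoms$name == atom_name]))
  resB <- sort(unique(topB$atoms$resid[topB$atoms$name == atom_name]))
  if (!identical(resA, resB)) stop("ensembles have mismatched residue sets")
  mean_d <- function(ens, top, masks) {
    idx <- atom_index(top, select_atoms(top, sel(resid = resA,
                                                 name = atom_name)))
    xyz <- pool_frames(ens, masks)
    acc <- matrix(0, length(idx), length(idx))
    for (i in seq_len(nrow(xyz))) {
      acc <- acc + as.matrix(stats::dist(
        xyz_to_mat(xyz[i, ])[idx, , drop = FALSE]))
    }
    acc / nrow(xyz)
  }
  dA <- mean_d(ensA, topA, frame_masksA)
  dB <- mean_d(ensB, topB, frame_masksB)
  delta <- dA - dB
  dimnames(delta) <- list(resA, resA)
  dom <- topA$atoms$domain[match(resA, topA$atoms$resid)]
  labs <- unique(dom)
  blocks <- do.call(rbind, lapply(seq_along(labs), function(i) {
    do.call(rbind, lapply(seq_along(labs), function(j) {
      if (j < i) return(NULL)
      ri <- which(dom == labs[i]); rj <- which(dom == labs[j])
      sub <- delta[ri, rj, drop = FALSE]
      if (identical(labs[i], labs[j])) {
        vals <- sub[upper.tri(sub)]
        if (!length(vals)) return(NULL)
      } else {
        vals <- as.numeric(sub)
      }
      data.frame(block1 = labs[i], block2 = labs[j],
                 mean_delta = mean(vals), n_pairs = length(vals),
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(residues = resA, delta = delta, blocks = blocks),
            class = "ddmap")
}

#' Hinge scan: locate the pivot of a rigid-body domain motion
#'
#' A true hinge residue satisfies: low displacement itself, and a strong
#' linear relationship between (i) each mobile residue's distance from the
#' candidate in the reference average structure and (ii) that residue's
#' backbone RMSD between the two condition averages. For each candidate the
#' Pearson correlation of those two vectors over the mobile set is
#' reported, ranked descending.
#'
#' @param avgA,avgB `avg_structure` objects in the common core-aligned
#'   frame (A is the reference for distances).
#' @param candidates Candidate residue ids. `NULL` selects residues below
#'   the 25th percentile of per-residue backbone RMSD, optionally
#'   restricted to `interface`.
#' @param mobile Mobile residue ids (>= 10) over which correlation is
#'   computed.
#' @param interface Optional residue ids forming the declared domain
#'   interface, used to restrict the default candidate pool.
#' @return A `hinge_report`: data.frame (resid, r) ranked by r descending,
#'   with attributes `best` (top residues) and `degenerate` flag.
#' @export
hinge_scan <- function(avgA, avgB, candidates = NULL, mobile,
                       interface = NULL) {
  if (length(mobile) < 10) {
    stop("mobile set must contain >= 10 residues for a stable correlation")
  }
  rmsd_all <- per_residue_rmsd(avgA, avgB)
  if (is.null(candidates)) {
    pool <- as.numeric(names(rmsd_all))[
      rmsd_all <= quantile(rmsd_all, 0.25)]
    if (!is.null(interface)) pool <- intersect(pool, interface)
    candidates <- pool
  }
  if (!length(candidates)) stop("candidate pool is empty")
  mob_rmsd <- rmsd_all[as.character(mobile)]
  degenerate <- sd(mob_rmsd) < 1e-12
  if (degenerate) {
    warning("mobile residues show no displacement between the averages; ",
            "correlations are undefined")
  }
  top <- avgA$top
  ma <- xyz_to_mat(avgA$xyz)
  ca_of <- function(r) ma[atom_index(top, select_atoms(
    top, sel(resid = r, name = "CA"))), ]
  mob_ca <- t(vapply(mobile, ca_of, numeric(3)))
  r_vals <- vapply(candidates, function(cand) {
    if (degenerate) return(NA_real_)
    cc <- ca_of(cand)
    d <- sqrt(rowSums(sweep(mob_ca, 2, cc)^2))
    cor(d, mob_rmsd)
  }, numeric(1))
  out <- data.frame(resid = candidates, r = r_vals)
  out <- out[order(-out$r, out$resid), ]
  rownames(out) <- NULL
  attr(out, "best") <- out$resid[1]
  attr(out, "degenerate") <- degenerate
  class(out) <- c("hinge_report", "data.frame")
  out
}

#' Latch-distance histograms across conditions
#'
#' Per condition and atom pair, the distribution of an inter-atom distance
#' over masked frames, on bin edges shared across conditions and normalised
#' to sum to 1 (so conditions with different frame counts are comparable).
#' The summary gives the modal bin centre, the SD of the distances, and the
#' tail fraction beyond `mode + tail_offset`.
#'
#' @param ensembles Named list of ensembles (one per condition).
#' @param pairs List of `list(a = c(resid, name), b = c(resid, name))`.
#' @param frame_masks Optional named list (per condition) of per-replica
#'   mask lists.
#' @param bin_width Histogram bin width, Angstrom.
#' @param tail_offset Offset above the mode defining the tail, Angstrom.
#' @return Nested list: per pair, per condition, `list(mids, density,
#'   mode, sd, tail_fraction)`.
#' @export
latch_distance_histograms <- function(ensembles, pairs, frame_masks = NULL,
                                      bin_width = 0.25, tail_offset = 2) {
  dists <- lapply(pairs, function(p) {
    lapply(names(ensembles), function(cond) {
      ens <- ensembles[[cond]]
      top <- ens$trajectories[[1]]$top
      ia <- .resolve_atom(top, p$a, "pair", "latch")
      ib <- .resolve_atom(top, p$b, "pair", "latch")
      masks <- if (is.null(frame_masks)) NULL else frame_masks[[cond]]
      xyz <- pool_frames(ens, masks)
      if (!nrow(xyz)) stop("frame mask is empty for condition ", cond)
      sqrt(rowSums((xyz[, .xyz_cols(ia), drop = FALSE] -
                      xyz[, .xyz_cols(ib), drop = FALSE])^2))
    })
  })
  out <- lapply(seq_along(pairs), function(pi) {
    vals <- dists[[pi]]
    rng <- range(unlist(vals))
    edges <- seq(floor(rng[1] / bin_width) * bin_width,
                 ceiling(rng[2] / bin_width) * bin_width + bin_width,
                 by = bin_width)
    res <- lapply(vals, function(v) {
      h <- hist(v, breaks = edges, plot = FALSE)
      dens <- h$counts / sum(h$counts)
      mode <- h$mids[which.max(h$counts)]
      list(mids = h$mids, density = dens, mode = mode, sd = sd(v),
           tail_fraction = mean(v > mode + tail_offset))
    })
    names(res) <- names(ensembles)
    res
  })
  names(out) <- vapply(pairs, function(p)
    paste0(p$a[1], ":", p$a[2], "-", p$b[1], ":", p$b[2]), character(1))
  out
}

#' @importFrom graphics hist
NULL
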