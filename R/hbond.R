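# Geometric hydrogen-bond detection, occupancy statistics, the
# bound / partially-bound / unbound state machine and the trajectory
# termination metric.
#
# An H-bond is present when the donor-acceptor distance is < 3.5 A and the
# donor-hydrogen-acceptor angle (measured at the hydrogen) lies in
# (130, 180) deg. Bonds with several alternative acceptors (e.g. the two
# carboxylate oxygens) count as present if any acceptor satisfies the
# criterion; the recorded distance is the minimum over the acceptor set.

HB_DIST_CUTOFF <- 3.5
HB_ANGLE_CUTOFF <- 130

#' Define a hydrogen bond
#'
#' @param label Bond label, e.g. `"p+1 O-M318 N"`.
#' @param donor,hydrogen `c(resid, atom_name)` references.
#' @param acceptors List of `c(resid, atom_name)` references (alternatives).
#' @param group One of "A" (pocket bonds), "B" (retention bonds),
#'   "CATALYTIC", "OTHER".
#' @return An `hbond_spec` list.
#' @export
hbond_spec <- function(label, donor, hydrogen, acceptors,
                       group = c("OTHER", "A", "B", "CATALYTIC")) {
  group <- match.arg(group)
  if (!is.list(acceptors)) acceptors <- list(acceptors)
  structure(list(label = label, donor = donor, hydrogen = hydrogen,
                 acceptors = acceptors, group = group),
            class = "hbond_spec")
}

.resolve_atom <- function(top, ref, what, label) {
  ids <- select_atoms(top, sel(resid = as.integer(ref[1]), name = ref[2]),
                      warn_empty = FALSE)
  if (length(ids) != 1L) {
    stop("H-bond '", label, "': ", what, " atom ", ref[2], " of residue ",
         ref[1], if (length(ids)) " is ambiguous" else " not found")
  }
  atom_index(top, ids)
}

#' Detect hydrogen bonds along a trajectory
#'
#' @param traj A `trajectory`.
#' @param specs List of [hbond_spec()] (or synthetic-generator H-bond
#'   definitions, which share the same fields).
#' @return An `hbond_trace`: list with logical `occupancy` (frames x bonds),
#'   numeric `distance` (min donor-acceptor distance over the acceptor set),
#'   `labels`, `groups`, `dt`, `replica_id`.
#' @export
detect_hbonds <- function(traj, specs) {
  top <- traj$top
  n <- n_frames(traj)
  labels <- vapply(specs, function(s) s$label, character(1))
  groups <- vapply(specs, function(s)
    if (is.null(s$group)) "OTHER" else s$group, character(1))
  occ <- matrix(FALSE, n, length(specs), dimnames = list(NULL, labels))
  dist <- matrix(NA_real_, n, length(specs), dimnames = list(NULL, labels))
  for (b in seq_along(specs)) {
    s <- specs[[b]]
    di <- .resolve_atom(top, s$donor, "donor", s$label)
    hi <- .resolve_atom(top, s$hydrogen, "hydrogen", s$label)
    d_xyz <- traj$xyz[, .xyz_cols(di), drop = FALSE]
    h_xyz <- traj$xyz[, .xyz_cols(hi), drop = FALSE]
    present <- rep(FALSE, n)
    dmin <- rep(Inf, n)
    for (acc in s$acceptors) {
      ai <- .resolve_atom(top, acc, "acceptor", s$label)
      a_xyz <- traj$xyz[, .xyz_cols(ai), drop = FALSE]
      da <- sqrt(rowSums((d_xyz - a_xyz)^2))
      u <- d_xyz - h_xyz
      w <- a_xyz - h_xyz
      cosang <- rowSums(u * w) /
        (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      present <- present | (da < HB_DIST_CUTOFF & ang > HB_ANGLE_CUTOFF)
      dmin <- pmin(dmin, da)
    }
    occ[, b] <- present
    dist[, b] <- dmin
  }
  structure(list(occupancy = occ, distance = dist, labels = labels,
                 groups = groups, dt = traj$dt,
                 replica_id = traj$replica_id),
            class = "hbond_trace")
}

#' Detect hydrogen bonds across an ensemble
#' @param ens An `ensemble`.
#' @param specs As for [detect_hbonds()].
#' @return Named list of `hbond_trace`, one per replica.
#' @export
detect_hbonds_ensemble <- function(ens, specs) {
  lapply(ens$trajectories, detect_hbonds, specs = specs)
}

.as_trace_list <- function(traces) {
  if (inherits(traces, "hbond_trace")) list(traces) else traces
}

.mask_or_all <- function(trace, frame_mask) {
  if (is.null(frame_mask)) seq_len(nrow(trace$occupancy)) else frame_mask
}

#' Hydrogen-bond occupancy statistics
#'
#' Mean occupancy is the fraction of masked frames (pooled over replicas)
#' in which the bond is present; the standard deviation is computed across
#' the per-replica means (sample SD, n - 1), the replicate-level spread the
#' study conditions define.
#'
#' @param traces An `hbond_trace` or list of them (one per replica).
#' @param frame_mask Optional list (per replica) or vector of 1-based frame
#'   indices to include.
#' @param by_replica If TRUE (default) the SD is across per-replica means;
#'   a single replica yields `NA` SD.
#' @return data.frame with columns label, group, mean, sd, n_frames.
#' @export
hbond_probability <- function(traces, frame_mask = NULL, by_replica = TRUE) {
  traces <- .as_trace_list(traces)
  masks <- .per_replica_masks(traces, frame_mask)
  if (!sum(lengths(masks))) stop("frame mask is empty")
  per_rep <- vapply(seq_along(traces), function(r) {
    colMeans(traces[[r]]$occupancy[masks[[r]], , drop = FALSE])
  }, numeric(length(traces[[1]]$labels)))
  if (!is.matrix(per_rep)) per_rep <- matrix(per_rep, nrow = 1)
  wts <- lengths(masks)
  pooled <- as.numeric(per_rep %*% wts) / sum(wts)
  sds <- if (by_replica && length(traces) > 1) {
    apply(per_rep, 1, sd)
  } else {
    rep(NA_real_, nrow(per_rep))
  }
  data.frame(label = traces[[1]]$labels, group = traces[[1]]$groups,
             mean = pooled, sd = sds, n_frames = sum(wts),
             stringsAsFactors = FALSE)
}

.per_replica_masks <- function(traces, frame_mask) {
  if (is.null(frame_mask)) {
    lapply(traces, function(t) seq_len(nrow(t$occupancy)))
  } else if (is.list(frame_mask)) {
    frame_mask
  } else {
    rep(list(frame_mask), length(traces))
  }
}

#' Joint occupancy of a bond subset
#'
#' Fraction of masked frames in which every bond of the subset is
#' simultaneously present (`all_present`) or absent (`all_absent`).
#'
#' @param traces An `hbond_trace` or list of them.
#' @param labels Bond labels forming the subset.
#' @param mode `"all_present"` or `"all_absent"`.
#' @param frame_mask As in [hbond_probability()].
#' @return A single probability.
#' @export
joint_occupancy <- function(traces, labels,
                            mode = c("all_present", "all_absent"),
                            frame_mask = NULL) {
  mode <- match.arg(mode)
  traces <- .as_trace_list(traces)
  if (!length(labels)) stop("bond subset must be non-empty")
  missing <- setdiff(labels, traces[[1]]$labels)
  if (length(missing)) {
    stop("unknown bond label(s): ", paste(missing, collapse = ", "))
  }
  masks <- .per_replica_masks(traces, frame_mask)
  if (!sum(lengths(masks))) stop("frame mask is empty")
  hits <- 0; tot <- 0
  for (r in seq_along(traces)) {
    occ <- traces[[r]]$occupancy[masks[[r]], labels, drop = FALSE]
    ok <- if (mode == "all_present") rowSums(occ) == ncol(occ)
          else rowSums(occ) == 0
    hits <- hits + sum(ok)
    tot <- tot + length(ok)
  }
  hits / tot
}

#' Classify binding state along a trajectory
#'
#' Implements the three-state rule set: the peptide starts FULLY_BOUND (the
#' bound pose); it becomes UNBOUND once all six bonds have been
#' simultaneously lost for longer than the persistence time; it becomes
#' PARTIALLY_BOUND once the three pocket (group A) bonds have been
#' simultaneously lost for longer than the persistence time while the
#' retention (group B) bonds have held within that window - if they had not,
#' the unbound criterion fires first. Transitions are hysteretic: the
#' current state persists until a new state's full criterion (including its
#' persistence window) is met, so classification can only move toward less
#' bound states as bonds are lost. By default stable rebinding
#' (PARTIALLY_BOUND back to FULLY_BOUND after the window has completed) is
#' not permitted; set `allow_rebinding = TRUE` to allow it. UNBOUND is
#' absorbing.
#'
#' @param trace An `hbond_trace`.
#' @param groupA,groupB Character vectors of three bond labels each
#'   (disjoint). Defaults to the trace's declared "A"/"B" groups.
#' @param persistence Persistence time in ns ("lost for > persistence").
#' @param dt Frame spacing in ns; defaults to the trace's.
#' @param allow_rebinding Permit PARTIALLY_BOUND -> FULLY_BOUND.
#' @return A `binding_trace`: list with `state` (character per frame),
#'   `dt`, `replica_id`.
#' @export
classify_binding <- function(trace, groupA = NULL, groupB = NULL,
                             persistence = 5, dt = trace$dt,
                             allow_rebinding = FALSE) {
  if (is.null(groupA)) groupA <- trace$labels[trace$groups == "A"]
  if (is.null(groupB)) groupB <- trace$labels[trace$groups == "B"]
  if (length(intersect(groupA, groupB))) stop("groups A and B must be disjoint")
  occ <- trace$occupancy
  n <- nrow(occ)
  w_frames <- ceiling(persistence / dt)
  if (w_frames < 1) stop("persistence window must cover at least one frame")
  if (n <= w_frames) {
    warning("trace shorter than the persistence window; ",
            "returning a single-state classification")
  }
  a_on <- occ[, groupA, drop = FALSE]
  b_on <- occ[, groupB, drop = FALSE]
  any_a <- rowSums(a_on) >= 1
  any_b <- rowSums(b_on) >= 1
  run_a <- .running_run_length(!any_a)
  run_6 <- .running_run_length(!any_a & !any_b)
  state <- character(n)
  cur <- "FULLY_BOUND"
  for (i in seq_len(n)) {
    if (cur != "UNBOUND" && run_6[i] * dt > persistence) {
      # all six lost beyond the window: fully dissociated
      cur <- "UNBOUND"
    } else if (cur == "FULLY_BOUND" && run_a[i] * dt > persistence) {
      # pocket bonds lost beyond the window while retention bonds have
      # held within it (otherwise the unbound rule above fires first)
      cur <- "PARTIALLY_BOUND"
    } else if (cur == "PARTIALLY_BOUND" && allow_rebinding &&
               any_a[i] && any_b[i]) {
      cur <- "FULLY_BOUND"
    }
    state[i] <- cur
  }
  structure(list(state = state, dt = dt, replica_id = trace$replica_id),
            class = "binding_trace")
}

#' Frames classified as bound
#' @param binding A `binding_trace`.
#' @param states Which states count (default FULLY_BOUND).
#' @return 1-based frame indices.
#' @export
bound_frames <- function(binding, states = "FULLY_BOUND") {
  which(binding$state %in% states)
}

#' Trajectory termination metric
#'
#' Sum of four inter-atom distances per frame: the three pocket-bond
#' donor-acceptor distances plus one heavy-atom proxy pair for the buried
#' van der Waals contact. The trajectory is considered terminated at the
#' first frame where the sum strictly exceeds the threshold.
#'
#' @param traj A `trajectory`.
#' @param pairs List of exactly four `list(a = c(resid, name), b = ...)`
#'   pairs; `b` may be a list of alternative atoms (minimum distance used).
#' @param threshold Termination threshold, Angstrom (default 80).
#' @return List with `sum` (per-frame distance sum), `termination_frame`
#'   (1-based first exceedance or `NA`), `threshold`.
#' @export
termination_metric <- function(traj, pairs, threshold = 80) {
  if (length(pairs) != 4L) stop("the termination metric uses exactly four ",
                                "distance terms")
  top <- traj$top
  total <- rep(0, n_frames(traj))
  for (p in pairs) {
    ia <- .resolve_atom(top, p$a, "pair", "termination")
    bs <- if (is.list(p$b)) p$b else list(p$b)
    d <- rep(Inf, n_frames(traj))
    for (bref in bs) {
      ib <- .resolve_atom(top, bref, "pair", "termination")
      d <- pmin(d, sqrt(rowSums(
        (traj$xyz[, .xyz_cols(ia), drop = FALSE] -
           traj$xyz[, .xyz_cols(ib), drop = FALSE])^2)))
    }
    total <- total + d
  }
  exceed <- which(total > threshold)
  list(sum = total,
       termination_frame = if (length(exceed)) exceed[1] else NA_integer_,
       threshold = threshold)
}

#' Frame indices within a time window
#'
#' Selects frames with time in the half-open interval `[from_ns, to_ns)`.
#' The default `from_ns` of 50 ns drops the initial structural-equilibration
#' stretch from statistics.
#'
#' @param traj A `trajectory`.
#' @param from_ns,to_ns Window bounds in ns.
#' @return 1-based frame indices.
#' @export
frames_in <- function(traj, from_ns = 50, to_ns = Inf) {
  t <- frame_times(traj)
  which(t >= from_ns & t < to_ns)
}
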