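# Synthetic multi-replica ensembles with known ground truth. The generator
# does not attempt physical realism: it programs exactly the statistical
# structure the downstream analyses assume (H-bond geometries toggling under
# a two-state Markov schedule, rigid-body hinge rotation driven by an
# Ornstein-Uhlenbeck angle, blocks of correlated motion, scripted peptide
# drift, isotropic Gaussian noise) so that every estimator can be tested
# against the programmed truth.

#' Build a synthetic-ensemble specification
#'
#' Defaults define a two-domain membrane-enzyme mimic: a transmembrane
#' block, a periplasmic block hinging above it, and an 8-residue peptide at
#' the interface pinned by six hydrogen bonds (three "A" pocket bonds, three
#' "B" retention bonds) with occupancies patterned on a tightly bound
#' substrate.
#'
#' @param n_replicas Number of replicas.
#' @param n_frames Frames per replica.
#' @param dt Frame spacing, ns.
#' @param layout Named residue counts, e.g. `c(TM = 40, PP = 30, PEPTIDE = 8)`.
#' @param hinge List: `pivot` (residue id or NULL for the TM residue closest
#'   to the PP centre), `axis` (unit 3-vector), `mean`, `sd` (deg) and `tau`
#'   (ns) of the Ornstein-Uhlenbeck angle process.
#' @param hbonds List of H-bond definitions: each
#'   `list(label, donor = c(resid, name), hydrogen = c(resid, name),
#'   acceptors = list(c(resid, name), ...), p_on, dwell, group)`. `NULL`
#'   installs the default six-bond set (requires the default layout labels).
#' @param unbind_events Named list mapping replica id ("r1", ...) to event
#'   start time in ns.
#' @param corr_blocks List of `list(resid = <ids>, rho = <target>)` blocks
#'   of correlated residue motion.
#' @param noise_sd Isotropic positional noise, Angstrom.
#' @param seed Integer seed; replica r uses stream `seed + r - 1`.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_replicas = 3, n_frames = 2000, dt = 0.1,
                           layout = c(TM = 40, PP = 30, PEPTIDE = 8),
                           hinge = list(pivot = NULL, axis = c(1, 0, 0),
                                        mean = 0, sd = 4, tau = 5),
                           hbonds = NULL,
                           unbind_events = list(),
                           corr_blocks = list(),
                           noise_sd = 0.1,
                           seed = 1L) {
  if (any(layout < 1)) stop("layout counts must be >= 1 per used label")
  spec <- list(n_replicas = n_replicas, n_frames = n_frames, dt = dt,
               layout = layout, hinge = hinge, hbonds = hbonds,
               unbind_events = unbind_events, corr_blocks = corr_blocks,
               noise_sd = noise_sd, seed = as.integer(seed))
  class(spec) <- "synthetic_spec"
  spec
}

# default six-bond table patterned on a tightly bound substrate: three
# pocket (A) bonds and three retention (B) bonds, peptide donors, protein
# acceptors
.default_hbonds <- function(top) {
  pep <- residue_ids_of_domain(top, "PEPTIDE")
  pp <- residue_ids_of_domain(top, "PP")
  tm <- residue_ids_of_domain(top, "TM")
  if (length(pep) < 6 || length(pp) < 4 || length(tm) < 2) {
    stop("default H-bond set needs >= 6 peptide, 4 PP and 2 TM residues")
  }
  mk <- function(label, dres, ares, p_on, group, two = FALSE) {
    acc <- list(c(ares, "O"))
    if (two) acc <- c(acc, list(c(ares, "C")))
    list(label = label, donor = c(dres, "N"), hydrogen = c(dres, "H"),
         acceptors = acc, p_on = p_on, dwell = 5, group = group)
  }
  list(
    mk("pA1", pep[2], tm[length(tm)], 0.83, "A"),
    mk("pA2", pep[3], pp[1], 0.91, "A", two = TRUE),
    mk("pA3", pep[4], pp[2], 0.78, "A"),
    mk("pB1", pep[1], pp[3], 0.32, "B"),
    mk("pB2", pep[5], pp[4], 0.92, "B", two = TRUE),
    mk("pB3", pep[6], tm[length(tm) - 1], 0.81, "B")
  )
}

#' Residue ids carrying a given domain label
#' @param top A `topology`.
#' @param label Domain label.
#' @return Sorted residue ids.
#' @export
residue_ids_of_domain <- function(top, label) {
  sort(unique(top$atoms$resid[top$atoms$domain == label]))
}

# per-residue atom template: backbone N, H (amide), CA, C, O
.residue_atom_template <- function() {
  data.frame(
    name = c("N", "H", "CA", "C", "O"),
    element = c("N", "H", "C", "C", "O"),
    dx = c(-1.2, -1.2, 0, 1.25, 1.3),
    dy = c(0, 1.0, 0, 0.5, 1.7),
    dz = c(0, 0, 0, 0, 0),
    stringsAsFactors = FALSE
  )
}

# compact cubic lattice of n residue centres, spacing in Angstrom
.lattice <- function(n, spacing = 5) {
  k <- ceiling(n^(1 / 3))
  g <- expand.grid(x = seq_len(k), y = seq_len(k), z = seq_len(k))
  g <- as.matrix(g[seq_len(n), ]) * spacing
  sweep(g, 2, colMeans(g))
}

#' Build the synthetic topology and its template coordinates
#'
#' Residues are laid out on compact lattices: the TM block around the
#' origin, the PP block 30 A above it (+z), the peptide at the interface.
#' Every atom receives alternating partial charges of +/-0.4 e and uniform
#' Lennard-Jones parameters so energetics can run out of the box.
#'
#' @param spec A `synthetic_spec`.
#' @return List `top` (topology), `xyz` (template frame vector), and
#'   `pivot` (the resolved hinge pivot residue id).
#' @export
build_topology <- function(spec) {
  layout <- spec$layout
  tmpl <- .residue_atom_template()
  centers <- list()
  if (!is.na(layout["TM"])) centers$TM <- .lattice(layout[["TM"]])
  if (!is.na(layout["PP"])) {
    # the mobile domain fans out in the y-z plane from an apex just above
    # the TM block: under a hinge rotation about x through the apex, each
    # residue's displacement is proportional to its distance from the
    # apex, and only a pivot at the apex sees that distance consistently
    # across all fan angles
    npp <- layout[["PP"]]
    apex <- c(0, 0, 12)
    n_ang <- 6
    ring <- (seq_len(npp) - 1) %/% n_ang
    phi <- ((seq_len(npp) - 1) %% n_ang - (n_ang - 1) / 2) * 30 * pi / 180
    rad <- 10 + 5 * ring
    centers$PP <- cbind(rep(0, npp),
                        apex[2] + rad * sin(phi),
                        apex[3] + rad * cos(phi))
  }
  if (!is.na(layout["PEPTIDE"])) {
    npep <- layout[["PEPTIDE"]]
    centers$PEPTIDE <- cbind(seq_len(npep) * 5 - (npep + 1) * 5 / 2,
                             rep(13, npep), rep(11, npep))
  }
  rows <- list()
  coords <- list()
  resid <- 0L
  aid <- 0L
  for (dom in names(centers)) {
    cc <- centers[[dom]]
    for (r in seq_len(nrow(cc))) {
      resid <- resid + 1L
      rows[[resid]] <- data.frame(
        atom_id = aid + seq_len(nrow(tmpl)),
        name = tmpl$name, element = tmpl$element,
        resid = resid, resname = "GLY",
        segment = dom, domain = dom,
        mass = .mass_for_element(tmpl$element),
        stringsAsFactors = FALSE
      )
      coords[[resid]] <- cbind(cc[r, 1] + tmpl$dx, cc[r, 2] + tmpl$dy,
                               cc[r, 3] + tmpl$dz)
      aid <- aid + nrow(tmpl)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$charge <- rep_len(c(0.4, -0.4), nrow(atoms))
  atoms$epsilon <- ifelse(atoms$element == "H", 0.046, 0.1)
  atoms$rmin_half <- ifelse(atoms$element == "H", 0.225, 1.8)
  top <- new_topology(atoms)
  xyz <- mat_to_xyz(do.call(rbind, coords))

  hbonds <- spec$hbonds
  if (is.null(hbonds)) hbonds <- .default_hbonds(top)
  for (hb in hbonds) {
    for (ref in c(list(hb$donor, hb$hydrogen), hb$acceptors)) {
      n <- sum(top$atoms$resid == as.integer(ref[1]) &
                 top$atoms$name == ref[2])
      if (n != 1L) {
        stop("H-bond '", hb$label, "' references missing atom ",
             ref[2], " of residue ", ref[1])
      }
    }
  }

  # binding-pocket layout: each H-bond's acceptor residue is translated so
  # its carbonyl sits ~4.4 A from the donor nitrogen - the unformed-bond
  # separation is then the template geometry, as in a real pocket, and an
  # unbind event grows the donor-acceptor distances continuously
  m <- xyz_to_mat(xyz)
  for (hb in hbonds) {
    dres <- as.integer(hb$donor[1])
    ares_all <- unique(vapply(hb$acceptors, function(a) as.integer(a[1]),
                              integer(1)))
    for (ares in setdiff(ares_all, dres)) {
      d_ca <- which(top$atoms$resid == dres & top$atoms$name == "CA")
      a_ca <- which(top$atoms$resid == ares & top$atoms$name == "CA")
      a_rows <- which(top$atoms$resid == ares)
      shift <- (m[d_ca, ] + c(0, -5, 1.5)) - m[a_ca, ]
      m[a_rows, ] <- sweep(m[a_rows, , drop = FALSE], 2, shift, "+")
    }
  }
  xyz <- mat_to_xyz(m)

  pivot <- spec$hinge$pivot
  if (is.null(pivot)) {
    # default pivot: the TM residue nearest the mobile-domain centre,
    # excluding binding-site residues (their relocated positions sit in
    # the pocket, not at the domain interface)
    hb_res <- unique(unlist(lapply(hbonds, function(h)
      as.integer(c(h$donor[1], h$hydrogen[1],
                   vapply(h$acceptors, function(a) a[1], character(1)))))))
    tm_res <- setdiff(residue_ids_of_domain(top, "TM"), hb_res)
    pp_res <- setdiff(residue_ids_of_domain(top, "PP"), hb_res)
    mm <- xyz_to_mat(xyz)
    ca <- vapply(tm_res, function(r) {
      idx <- atom_index(top, select_atoms(top, sel(resid = r, name = "CA")))
      mm[idx, ]
    }, numeric(3))
    pp_center <- colMeans(mm[
      atom_index(top, select_atoms(top, sel(resid = pp_res))), ,
      drop = FALSE])
    d <- sqrt(colSums((ca - pp_center)^2))
    pivot <- tm_res[which.min(d)]
  }
  list(top = top, xyz = xyz, pivot = pivot, hbonds = hbonds)
}

# Rodrigues rotation of points (n x 3) about axis u through point p
.rotate_about <- function(m, p, u, theta_deg) {
  th <- theta_deg * pi / 180
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(sweep(m, 2, p) %*% t(R), 2, p, "+")
}

# discretized stationary Ornstein-Uhlenbeck path
.ou_path <- function(n, mean, sd, tau, dt) {
  if (sd <= 0) return(rep(mean, n))
  phi <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- rnorm(1, mean, sd)
  innov <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  for (i in seq_len(n - 1L)) x[i + 1L] <- mean + phi * (x[i] - mean) + innov[i + 1L]
  x
}

# two-state Markov schedule: stationary occupancy p_on, mean on-dwell
# (ns). Discretized with the exact continuous-time transition kernel over
# dt, which preserves the stationary occupancy at any dt.
.markov_schedule <- function(n, p_on, dwell, dt) {
  if (p_on >= 1) return(rep(TRUE, n))
  if (p_on <= 0) return(rep(FALSE, n))
  k_off <- 1 / dwell
  k_on <- k_off * p_on / (1 - p_on)
  lambda <- k_on + k_off
  relax <- 1 - exp(-lambda * dt)
  p_on2off <- (k_off / lambda) * relax
  p_off2on <- (k_on / lambda) * relax
  s <- logical(n)
  s[1] <- runif(1) < p_on
  u <- runif(n)
  for (i in seq_len(n - 1L)) {
    s[i + 1L] <- if (s[i]) u[i + 1L] >= p_on2off else u[i + 1L] < p_off2on
  }
  s
}

#' Simulate a synthetic ensemble with ground truth
#'
#' Per frame the generator (1) rotates the PP block rigidly about the pivot
#' by an Ornstein-Uhlenbeck angle, (2) adds shared latent displacements to
#' correlated blocks, (3) drifts the peptide at 0.5 A/ns after a scripted
#' unbinding event, (4) places each scheduled H-bond's acceptor atoms so the
#' donor-acceptor distance falls in [2.6, 3.3] A with a D-H-A angle in
#' [150, 180] deg when "on" and at >= 4.2 A when "off", and (5) adds
#' isotropic Gaussian noise. Only acceptor atoms are moved by the H-bond
#' machinery, decoupling H-bond statistics from backbone motion. Bonds whose
#' donor or acceptor sits in a drifting peptide are forced off after the
#' event (with a warning if scheduled fully on).
#'
#' @param spec A `synthetic_spec`.
#' @param condition Condition label stamped on every replica.
#' @return List `ensemble` (an [new_ensemble()]) and `truth` (ground-truth
#'   record: schedules, binding states, pivot, occupancies, correlations).
#' @export
simulate_ensemble <- function(spec, condition = "SYN") {
  built <- build_topology(spec)
  top <- built$top
  template <- xyz_to_mat(built$xyz)
  hbonds <- built$hbonds
  pivot <- built$pivot
  n <- spec$n_frames
  dwells <- vapply(hbonds, function(h) h$dwell, numeric(1))
  if (length(dwells) && n * spec$dt < 10 * max(dwells)) {
    warning("trajectory span is < 10x the longest H-bond dwell time; ",
            "occupancy estimates will be noisy")
  }

  pp_idx <- atom_index(top, select_atoms(top, sel(domain = "PP")))
  pep_idx <- atom_index(top, select_atoms(top, sel(domain = "PEPTIDE"),
                                          warn_empty = FALSE))
  pivot_ca <- template[atom_index(
    top, select_atoms(top, sel(resid = pivot, name = "CA"))), ]

  don_idx <- lapply(hbonds, function(h)
    atom_index(top, select_atoms(top, sel(resid = as.integer(h$donor[1]),
                                          name = h$donor[2]))))
  hyd_idx <- lapply(hbonds, function(h)
    atom_index(top, select_atoms(top, sel(resid = as.integer(h$hydrogen[1]),
                                          name = h$hydrogen[2]))))
  acc_idx <- lapply(hbonds, function(h)
    lapply(h$acceptors, function(a)
      atom_index(top, select_atoms(top, sel(resid = as.integer(a[1]),
                                            name = a[2])))))
  bond_in_pep <- vapply(seq_along(hbonds), function(b) {
    any(c(don_idx[[b]], unlist(acc_idx[[b]])) %in% pep_idx)
  }, logical(1))

  trajs <- vector("list", spec$n_replicas)
  schedules <- vector("list", spec$n_replicas)
  states <- vector("list", spec$n_replicas)
  angles <- vector("list", spec$n_replicas)
  for (r in seq_len(spec$n_replicas)) {
    set.seed(spec$seed + r - 1L)
    rid <- paste0("r", r)
    ang <- .ou_path(n, spec$hinge$mean, spec$hinge$sd, spec$hinge$tau,
                    spec$dt)
    sched <- vapply(hbonds, function(h)
      .markov_schedule(n, h$p_on, h$dwell, spec$dt), logical(n))
    if (!is.matrix(sched)) sched <- matrix(sched, nrow = n)
    colnames(sched) <- vapply(hbonds, function(h) h$label, character(1))

    ev <- spec$unbind_events[[rid]]
    ev_frame <- if (is.null(ev)) Inf else floor(ev / spec$dt) + 1L
    if (!is.null(ev)) {
      if (ev_frame <= n && any(bond_in_pep)) {
        forced_on <- vapply(hbonds[bond_in_pep], function(h) h$p_on >= 1,
                            logical(1))
        if (any(forced_on)) {
          warning("unbind event in ", rid, " conflicts with p_on = 1 ",
                  "bond(s); schedule forced off after the event")
        }
        sched[ev_frame:n, bond_in_pep] <- FALSE
      }
    }

    xyz <- matrix(0, n, 3L * nrow(top$atoms))
    for (i in seq_len(n)) {
      fr <- template
      if (spec$hinge$sd > 0 || spec$hinge$mean != 0) {
        fr[pp_idx, ] <- .rotate_about(fr[pp_idx, , drop = FALSE], pivot_ca,
                                      spec$hinge$axis, ang[i])
      }
      xyz[i, ] <- mat_to_xyz(fr)
    }

    # correlated blocks: shared 3-vector latent per block per frame,
    # scaled so corr(latent + noise) hits the target rho
    for (blk in spec$corr_blocks) {
      idx <- atom_index(top, select_atoms(top, sel(resid = blk$resid)))
      rho <- blk$rho
      if (spec$noise_sd <= 0) {
        a <- 1
      } else {
        a <- spec$noise_sd * sqrt(rho / (1 - rho))
      }
      g <- matrix(rnorm(3L * n, 0, a), n, 3L)
      cols <- .xyz_cols(idx)
      xc <- matrix(cols, ncol = 3, byrow = TRUE)
      for (k in 1:3) xyz[, xc[, k]] <- xyz[, xc[, k]] + g[, k]
    }

    # scripted peptide drift: 0.5 A/ns along +y after the event
    if (!is.null(ev)) {
      t_ns <- (seq_len(n) - 1L) * spec$dt
      drift <- pmax(0, t_ns - ev) * 0.5
      cols <- .xyz_cols(pep_idx)
      ycols <- matrix(cols, ncol = 3, byrow = TRUE)[, 2]
      xyz[, ycols] <- xyz[, ycols] + drift
    }

    if (spec$noise_sd > 0) {
      xyz <- xyz + rnorm(length(xyz), 0, spec$noise_sd)
    }

    # H-bond acceptor placement relative to the current (noisy) donor and
    # hydrogen; placed acceptors receive their own positional noise, which
    # acts over the long donor-acceptor arm and so barely perturbs the
    # D-H-A angle
    for (b in seq_along(hbonds)) {
      di <- don_idx[[b]]; hi <- hyd_idx[[b]]
      on <- sched[, b]
      d_on <- runif(n, 2.6, 3.3)
      th_on <- runif(n, 150, 180) * pi / 180
      for (i in seq_len(n)) {
        fr_d <- xyz[i, .xyz_cols(di)]
        fr_h <- xyz[i, .xyz_cols(hi)]
        u <- fr_d - fr_h
        nu <- sqrt(sum(u^2))
        u <- u / nu
        # perpendicular direction chosen out of the peptide plane so the
        # placed acceptor cannot land on a neighbouring residue
        ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        v <- ref - sum(ref * u) * u
        v <- v / sqrt(sum(v^2))
        if (on[i]) {
          # law of cosines: |h-a| from target |d-a| and D-H-A angle
          ct <- cos(th_on[i])
          ha <- nu * ct + sqrt((nu * ct)^2 + d_on[i]^2 - nu^2)
          a_dir <- ct * u + sin(th_on[i]) * v
          xyz[i, .xyz_cols(acc_idx[[b]][[1]])] <- fr_h + ha * a_dir +
            rnorm(3, 0, spec$noise_sd)
          rest <- acc_idx[[b]][-1]
        } else {
          rest <- acc_idx[[b]]
        }
        # while the peptide is in the pocket, an unformed bond's acceptor
        # hovers just outside the H-bond envelope (the pocket geometry is
        # intact, the bond just is not formed); after an unbind event the
        # acceptor stays at its template position so the donor-acceptor
        # separation grows with the drift
        in_pocket <- i < ev_frame || !bond_in_pep[b]
        for (j in seq_along(rest)) {
          ai <- rest[[j]]
          if (in_pocket) {
            xyz[i, .xyz_cols(ai)] <- fr_d + (4.3 + 0.4 * j) * u +
              rnorm(3, 0, spec$noise_sd)
          } else if (sum((xyz[i, .xyz_cols(ai)] - fr_d)^2) < 4.2^2) {
            xyz[i, .xyz_cols(ai)] <- fr_d + (4.2 + 0.3 * j) * u
          }
        }
      }
    }

    trajs[[r]] <- new_trajectory(top, xyz, spec$dt, replica_id = rid,
                                 condition = condition)
    schedules[[r]] <- sched
    angles[[r]] <- ang
    groups <- vapply(hbonds, function(h) h$group, character(1))
    states[[r]] <- if (sum(groups == "A") == 3 && sum(groups == "B") == 3) {
      .literal_binding_states(sched[, groups == "A", drop = FALSE],
                              sched[, groups == "B", drop = FALSE],
                              persistence = 5, dt = spec$dt)
    } else {
      rep(NA_character_, n)
    }
  }
  names(schedules) <- names(states) <- names(angles) <-
    vapply(trajs, function(t) t$replica_id, character(1))

  truth <- list(
    schedules = schedules,
    states = states,
    angles = angles,
    pivot = pivot,
    occupancies = vapply(hbonds, function(h) h$p_on, numeric(1)),
    bond_labels = vapply(hbonds, function(h) h$label, character(1)),
    bond_groups = vapply(hbonds, function(h) h$group, character(1)),
    corr_blocks = spec$corr_blocks,
    hbonds = hbonds
  )
  list(ensemble = new_ensemble(trajs), truth = truth)
}

# generator-owned literal evaluation of the binding rules on the *true*
# schedules (run-length based; independent of the classifier module)
.literal_binding_states <- function(a_on, b_on, persistence, dt) {
  n <- nrow(a_on)
  all_a_off <- rowSums(a_on) == 0
  all6_off <- all_a_off & rowSums(b_on) == 0
  run_a <- .running_run_length(all_a_off)
  run_6 <- .running_run_length(all6_off)
  state <- character(n)
  cur <- "FULLY_BOUND"
  for (i in seq_len(n)) {
    if (cur != "UNBOUND" && run_6[i] * dt > persistence) {
      cur <- "UNBOUND"
    } else if (cur == "FULLY_BOUND" && run_a[i] * dt > persistence) {
      cur <- "PARTIALLY_BOUND"
    }
    state[i] <- cur
  }
  state
}

.running_run_length <- function(flag) {
  n <- length(flag)
  out <- integer(n)
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (flag[i]) run + 1L else 0L
    out[i] <- run
  }
  out
}

#' Write ground truth to TSV
#' @param truth Ground-truth record from [simulate_ensemble()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  rows <- do.call(rbind, lapply(names(truth$schedules), function(rid) {
    sched <- truth$schedules[[rid]]
    data.frame(replica = rid, frame = seq_len(nrow(sched)) - 1L,
               state = truth$states[[rid]],
               sched * 1L, check.names = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
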