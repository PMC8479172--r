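# Fixture builders and independent oracles used across the suite. Oracles
# deliberately take different computational routes from the implementation
# they check.

# minimal hand-built topology: n residues x atoms N, H, CA, C, O
tiny_topology <- function(n_res = 3, domain = "TM") {
  tmpl <- data.frame(name = c("N", "H", "CA", "C", "O"),
                     element = c("N", "H", "C", "C", "O"))
  atoms <- do.call(rbind, lapply(seq_len(n_res), function(r) {
    data.frame(atom_id = (r - 1L) * 5L + 1:5, name = tmpl$name,
               element = tmpl$element, resid = r, resname = "GLY",
               segment = "A", domain = domain, mass = 12,
               charge = 0, epsilon = 0.1, rmin_half = 1.8,
               stringsAsFactors = FALSE)
  }))
  new_topology(atoms)
}

# trajectory with explicit coordinates for a tiny topology
tiny_trajectory <- function(top, frames, dt = 0.1) {
  new_trajectory(top, do.call(rbind, lapply(frames, mat_to_xyz)), dt)
}

# wrap a bare occupancy matrix as an hbond_trace (labels b1..bK; first
# three labelled group A, next three group B when 6 columns)
mock_trace <- function(occ, dt = 1) {
  occ <- as.matrix(occ)
  k <- ncol(occ)
  labels <- paste0("b", seq_len(k))
  groups <- rep("OTHER", k)
  if (k >= 6) groups[1:6] <- c("A", "A", "A", "B", "B", "B")
  colnames(occ) <- labels
  structure(list(occupancy = occ,
                 distance = ifelse(occ, 2.8, 5),
                 labels = labels, groups = groups, dt = dt,
                 replica_id = "mock"),
            class = "hbond_trace")
}

# ---- binding-state oracle: literal transcription of the three-state
# rule table, using rle-based trailing-run lengths ----------------------
trailing_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  out <- integer(length(flag))
  for (k in seq_along(r$lengths)) {
    span <- (ends[k] - r$lengths[k] + 1L):ends[k]
    out[span] <- if (r$values[k]) seq_len(r$lengths[k]) else 0L
  }
  out
}

oracle_binding_states <- function(a_on, b_on, persistence, dt,
                                  allow_rebinding = FALSE) {
  n <- nrow(a_on)
  any_a <- rowSums(a_on) >= 1
  any_b <- rowSums(b_on) >= 1
  lost_a_run <- trailing_runs(!any_a)
  lost_6_run <- trailing_runs(!any_a & !any_b)
  to_partial <- lost_a_run * dt > persistence
  to_unbound <- lost_6_run * dt > persistence
  state <- character(n)
  cur <- "FULLY_BOUND"
  for (i in seq_len(n)) {
    if (cur != "UNBOUND" && to_unbound[i]) {
      cur <- "UNBOUND"
    } else if (cur == "FULLY_BOUND" && to_partial[i]) {
      cur <- "PARTIALLY_BOUND"
    } else if (cur == "PARTIALLY_BOUND" && allow_rebinding &&
               any_a[i] && any_b[i]) {
      cur <- "FULLY_BOUND"
    }
    state[i] <- cur
  }
  state
}

# ---- brute-force nonbonded energy (plain double loop) -----------------
brute_force_energy <- function(coords, ia, ib, charge, eps, rmin_half,
                               dielectric = 1) {
  ke <- 332.0636
  elec <- 0; vdw <- 0
  for (i in ia) {
    for (j in ib) {
      r <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      elec <- elec + ke * charge[i] * charge[j] / (dielectric * r)
      em <- sqrt(eps[i] * eps[j])
      rm <- rmin_half[i] + rmin_half[j]
      vdw <- vdw + em * ((rm / r)^12 - 2 * (rm / r)^6)
    }
  }
  list(elec = elec, vdw = vdw, total = elec + vdw)
}

# ---- exhaustive simple-path enumeration on a small weighted graph -----
# adj: symmetric weight matrix with NA where no edge
enumerate_simple_paths <- function(adj, s, t) {
  n <- nrow(adj)
  paths <- list(); weights <- numeric(0)
  walk <- function(path, w) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      weights <<- c(weights, w)
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (!is.na(adj[v, u]) && !(u %in% path)) {
        walk(c(path, u), w + adj[v, u])
      }
    }
  }
  walk(s, 0)
  list(paths = paths, weights = weights)
}

# brute-force betweenness: per node, the number of minimum-weight simple
# paths (over all unordered pairs) passing through it as an interior node
brute_force_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      e <- enumerate_simple_paths(adj, s, t)
      if (!length(e$paths)) next
      wmin <- min(e$weights)
      for (k in which(abs(e$weights - wmin) < 1e-12)) {
        p <- e$paths[[k]]
        if (length(p) > 2) {
          interior <- p[-c(1, length(p))]
          btw[interior] <- btw[interior] + 1
        }
      }
    }
  }
  btw
}

# random connected weighted graph as correlation-like matrix
random_corr_graph <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  C <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) {
        C[i, j] <- C[j, i] <- runif(1, 0.71, 0.99)
      } else {
        C[i, j] <- C[j, i] <- runif(1, 0, 0.5)
      }
    }
  }
  dimnames(C) <- list(as.character(seq_len(n)), as.character(seq_len(n)))
  C
}

# ---- minimal CHARMM-format DCD writer (binary fixture generator) ------
write_dcd_fixture <- function(xyz, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  natom <- as.integer(ncol(xyz) / 3)
  nfr <- as.integer(nrow(xyz))
  wi <- function(x) writeBin(as.integer(x), con, size = 4L,
                             endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L,
                             endian = "little")
  wc <- function(s) writeBin(charToRaw(s), con)
  wi(84L); wc("CORD")
  wi(c(nfr, 1L, 1L, nfr, 0L, 0L, 0L, 0L, 0L))
  wf(1.0)
  wi(rep(0L, 9)); wi(24L)
  wi(84L)
  wi(84L); wi(1L); wc(sprintf("%-80s", "synthetic fixture")); wi(84L)
  wi(4L); wi(natom); wi(4L)
  for (i in seq_len(nfr)) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    for (k in 1:3) {
      wi(4L * natom); wf(m[, k]); wi(4L * natom)
    }
  }
  invisible(path)
}

# random rigid transform applied to an n x 3 coordinate matrix
random_rigid_transform <- function(m, seed = 1) {
  set.seed(seed)
  th <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]),
                 0, 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  shift <- runif(3, -20, 20)
  sweep(m %*% R, 2, shift, "+")
}

# benchmark spec pair used by the end-to-end tests and acceptance script
tight_loose_config <- function(seed = 7, n_frames = 600, n_replicas = 3) {
  mk <- function(s, tight) {
    occ <- if (tight) c(0.83, 0.91, 0.78, 0.32, 0.92, 0.81)
           else c(0.61, 0.68, 0.38, 0.16, 0.58, 0.36)
    sp <- synthetic_spec(
      n_replicas = n_replicas, n_frames = n_frames, dt = 0.1,
      hinge = list(pivot = NULL, axis = c(1, 0, 0),
                   mean = if (tight) 0 else 12,
                   sd = if (tight) 2 else 5, tau = 5),
      corr_blocks = if (tight)
        list(list(resid = c(20:26, 71:78), rho = 0.85)) else list(),
      noise_sd = 0.1, seed = s)
    bt <- build_topology(sp)
    hb <- bt$hbonds
    for (i in seq_along(hb)) hb[[i]]$p_on <- occ[i]
    sp$hbonds <- hb
    sp
  }
  list(
    conditions = list(tight = list(spec = mk(seed, TRUE)),
                      loose = list(spec = mk(seed + 1, FALSE))),
    equil_ns = 5, persistence = 5,
    core_residues = c(1:19, 27:40),
    latch_pairs = list(list(a = c(73, "CA"), b = c(44, "CA"))),
    sources = "74", sinks = "22",
    energy = list(groupA = sel(domain = "PEPTIDE"),
                  groupB = sel(domain = c("PP", "TM"))))
}
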