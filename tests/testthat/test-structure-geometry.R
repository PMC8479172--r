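# Superposition, stable core, averages, distance-difference maps, hinge
# scan, latch histograms.

test_that("Kabsch recovers applied rigid transforms exactly", {
  set.seed(10)
  ref <- matrix(rnorm(30 * 3, sd = 8), ncol = 3)
  expect_equal(kabsch_superpose(ref, ref)$rmsd, 0, tolerance = 1e-10)
  for (s in 1:20) {
    moved <- random_rigid_transform(ref, seed = s)
    sp <- kabsch_superpose(moved, ref)
    expect_lt(sp$rmsd, 1e-8)
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
    back <- apply_superposition(moved, sp)
    expect_equal(back, ref, tolerance = 1e-6)
  }
})

test_that("one displaced atom yields the closed-form rmsd sqrt(1/N)", {
  set.seed(3)
  a <- matrix(rnorm(20 * 3, sd = 5), ncol = 3)
  b <- a
  b[7, ] <- b[7, ] + c(1, 0, 0)
  # align on the unmoved atoms, then measure over all N = 20
  sp <- kabsch_superpose(b, a, atom_set = setdiff(1:20, 7))
  fitted <- apply_superposition(b, sp)
  rmsd_all <- sqrt(mean(rowSums((fitted - a)^2)))
  expect_equal(rmsd_all, sqrt(1 / 20), tolerance = 1e-6)
})

test_that("degenerate fit sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "collinear")
  expect_error(kabsch_superpose(matrix(rnorm(6), 2, 3),
                                matrix(rnorm(6), 2, 3)), ">= 3")
})

test_that("stable core excludes a floppy tail", {
  set.seed(21)
  top <- tiny_topology(20)
  base <- matrix(rnorm(100 * 3, sd = 6), ncol = 3)
  frames <- lapply(1:40, function(i) {
    m <- base + matrix(rnorm(300, sd = 0.05), ncol = 3)
    tail_rows <- 76:100  # residues 16-20
    m[tail_rows, ] <- m[tail_rows, ] + matrix(rnorm(75, sd = 3), ncol = 3)
    m
  })
  tr <- tiny_trajectory(top, frames)
  core <- find_stable_core(tr, n_clusters = 3)
  expect_true(all(core$residues <= 15))
  expect_gt(length(core$residues), 5)
})

test_that("two hinging rigid domains give a single-domain core", {
  spec <- synthetic_spec(n_replicas = 1, n_frames = 200, dt = 0.1,
                         hinge = list(pivot = NULL, axis = c(1, 0, 0),
                                      mean = 0, sd = 8, tau = 2),
                         noise_sd = 0.05, seed = 13)
  sim <- suppressWarnings(simulate_ensemble(spec))
  core <- find_stable_core(sim$ensemble)
  top <- sim$ensemble$trajectories[[1]]$top
  doms <- unique(top$atoms$domain[match(core$residues, top$atoms$resid)])
  expect_length(doms, 1)
})

test_that("static input warns and still returns a deterministic core", {
  top <- tiny_topology(10)
  m <- matrix(rnorm(150, sd = 5), ncol = 3)
  tr <- tiny_trajectory(top, list(m, m, m))
  expect_warning(core <- find_stable_core(tr, n_clusters = 3), "tie")
  expect_true(1 %in% core$residues)
})

test_that("average structure reduces to identity and midpoint cases", {
  top <- tiny_topology(3)
  m1 <- matrix(rnorm(45, sd = 4), ncol = 3)
  m2 <- m1
  m2[5, ] <- m1[5, ] + c(2, 0, 0)
  tr <- tiny_trajectory(top, list(m1, m2))
  avg1 <- average_structure(tr, frame_masks = 1L)
  expect_equal(avg1$xyz, mat_to_xyz(m1))
  avg <- average_structure(tr)
  expect_equal(xyz_to_mat(avg$xyz)[5, ], m1[5, ] + c(1, 0, 0))
  expect_equal(avg$rmsf[5], 1)
  expect_equal(avg$rmsf[1], 0)
  expect_error(average_structure(tr, frame_masks = integer(0)), "empty")
})

test_that("ensemble averages converge to the template at CLT rate", {
  spec <- synthetic_spec(n_replicas = 2, n_frames = 400, dt = 0.1,
                         hinge = list(pivot = NULL, axis = c(1, 0, 0),
                                      mean = 0, sd = 0, tau = 5),
                         noise_sd = 0.1, seed = 17)
  sim <- suppressWarnings(simulate_ensemble(spec))
  avg <- average_structure(sim$ensemble)
  tmpl <- build_topology(spec)$xyz
  top <- sim$ensemble$trajectories[[1]]$top
  # compare on TM Calpha atoms (H-bond machinery moves acceptor atoms)
  idx <- atom_index(top, select_atoms(top, sel(domain = "TM", name = "CA")))
  dev <- xyz_to_mat(avg$xyz)[idx, ] - xyz_to_mat(tmpl)[idx, ]
  expect_lt(max(abs(dev)), 5 * 0.1 / sqrt(800))
})

test_that("structure RMSD follows its closed forms without re-fitting", {
  top <- tiny_topology(4)
  m <- matrix(rnorm(60, sd = 6), ncol = 3)
  a <- structure(list(top = top, xyz = mat_to_xyz(m), rmsf = rep(0, 20),
                      n_frames = 1), class = "avg_structure")
  b <- a
  b$xyz <- mat_to_xyz(m + matrix(rep(c(1, 0, 0), each = 20), ncol = 3))
  expect_equal(rmsd_between_structures(a, a), 0)
  expect_equal(rmsd_between_structures(a, b), 1)
  expect_error(rmsd_between_structures(a, b, integer(0)), "empty")
})

test_that("most populated structure finds the dominant distance mode", {
  set.seed(31)
  top <- tiny_topology(6)
  n <- 400
  # bimodal inter-residue distance: 70% near 44 A, 30% near 48 A
  d_target <- ifelse(runif(n) < 0.7, rnorm(n, 44, 0.2), rnorm(n, 48, 0.2))
  frames <- lapply(seq_len(n), function(i) {
    m <- matrix(0, 30, 3)
    m[, 1] <- rep(seq(0, 25, by = 5), each = 5)
    m[13, ] <- c(0, 0, 0)        # residue 3 CA at origin
    m[28, ] <- c(d_target[i], 0, 0)  # residue 6 CA at the target distance
    m + matrix(rnorm(90, sd = 0.02), ncol = 3)
  })
  tr <- tiny_trajectory(top, frames)
  ref <- average_structure(tr)
  out <- most_populated_structure(tr, group_resids = 3, ref_resid = 6,
                                  reference = ref)
  expect_lt(abs(out$distance - 44), 0.5)
  single <- most_populated_structure(tr, group_resids = 3, ref_resid = 6,
                                     reference = ref, frame_mask = 5L)
  expect_equal(single$frame, 5L)
})

test_that("distance-difference maps are antisymmetric with zero diagonal", {
  spec <- synthetic_spec(n_replicas = 1, n_frames = 150, dt = 0.1, seed = 19)
  simA <- suppressWarnings(simulate_ensemble(spec, "A"))
  specB <- spec; specB$seed <- 119L
  simB <- suppressWarnings(simulate_ensemble(specB, "B"))
  dd <- distance_difference_map(simA$ensemble, simB$ensemble)
  dd_rev <- distance_difference_map(simB$ensemble, simA$ensemble)
  expect_equal(dd$delta, -dd_rev$delta, tolerance = 1e-12)
  expect_true(all(diag(dd$delta) == 0))
  # same ensemble twice: identically zero
  dd0 <- distance_difference_map(simA$ensemble, simA$ensemble)
  expect_true(all(abs(dd0$delta) < 1e-12))
})

test_that("intra-domain blocks of rigid synthetic domains stay near zero", {
  mk <- function(seed, mean_angle) {
    sp <- synthetic_spec(n_replicas = 1, n_frames = 300, dt = 0.1,
                         hinge = list(pivot = NULL, axis = c(1, 0, 0),
                                      mean = mean_angle, sd = 2, tau = 5),
                         noise_sd = 0.1, seed = seed)
    suppressWarnings(simulate_ensemble(sp))
  }
  closed <- mk(23, 0); open <- mk(123, 12)
  dd <- distance_difference_map(open$ensemble, closed$ensemble)
  blk <- dd$blocks
  tm_tm <- blk$mean_delta[blk$block1 == "TM" & blk$block2 == "TM"]
  tm_pp <- abs(blk$mean_delta[blk$block1 == "TM" & blk$block2 == "PP"])
  expect_lt(abs(tm_tm), 0.05)
  expect_gt(tm_pp, 4 * abs(tm_tm))
})

test_that("hinge scan flags the degenerate equal-average case", {
  spec <- synthetic_spec(n_replicas = 1, n_frames = 100, dt = 0.1, seed = 29)
  sim <- suppressWarnings(simulate_ensemble(spec))
  avg <- average_structure(sim$ensemble)
  top <- sim$ensemble$trajectories[[1]]$top
  pp <- residue_ids_of_domain(top, "PP")
  expect_warning(hs <- hinge_scan(avg, avg, candidates = 1:5, mobile = pp),
                 "undefined")
  expect_true(attr(hs, "degenerate"))
  expect_error(hinge_scan(avg, avg, candidates = 1:5, mobile = 1:5),
               ">= 10")
})

test_that("latch histograms normalise and rank spread correctly", {
  set.seed(41)
  top <- tiny_topology(2)
  mk_ens <- function(sd_d, n) {
    d <- rnorm(n, 10, sd_d)
    frames <- lapply(d, function(di) {
      m <- matrix(0, 10, 3)
      m[6:10, 1] <- 30
      m[3, ] <- c(0, 0, 0)
      m[8, ] <- c(di, 0, 0)
      m
    })
    new_ensemble(list(tiny_trajectory(top, frames)))
  }
  ens <- list(narrow = mk_ens(0.3, 400), broad = mk_ens(1.5, 300))
  out <- latch_distance_histograms(ens, list(list(a = c(1, "CA"),
                                                  b = c(2, "CA"))))
  h <- out[[1]]
  expect_equal(sum(h$narrow$density), 1, tolerance = 1e-12)
  expect_equal(sum(h$broad$density), 1, tolerance = 1e-12)
  expect_identical(length(h$narrow$mids), length(h$broad$mids))
  expect_gt(h$broad$tail_fraction, h$narrow$tail_fraction)
  # constant distance occupies a single bin containing that distance
  cens <- list(const = mk_ens(0, 50))
  hc <- latch_distance_histograms(cens, list(list(a = c(1, "CA"),
                                                  b = c(2, "CA"))))[[1]]
  expect_equal(sum(hc$const$density > 0), 1)
  expect_lt(abs(hc$const$mode - 10), 0.25)
})

test_that("geometry is invariant under a global rigid transform", {
  spec <- synthetic_spec(n_replicas = 1, n_frames = 60, dt = 0.1, seed = 37)
  sim <- suppressWarnings(simulate_ensemble(spec))
  tr <- sim$ensemble$trajectories[[1]]
  core <- residue_ids_of_domain(tr$top, "TM")[1:10]
  avg1 <- average_structure(tr, core = core)
  moved <- tr
  for (i in seq_len(n_frames(tr))) {
    moved$xyz[i, ] <- mat_to_xyz(random_rigid_transform(
      frame_coords(tr, i), seed = 999))
  }
  avg2 <- average_structure(moved, core = core)
  # align the two averages on the core: internal geometry must match
  fit <- atom_index(tr$top, select_atoms(tr$top, sel(resid = core,
                                                     name = "CA")))
  sp <- kabsch_superpose(xyz_to_mat(avg2$xyz), xyz_to_mat(avg1$xyz), fit)
  back <- apply_superposition(xyz_to_mat(avg2$xyz), sp)
  expect_equal(back, xyz_to_mat(avg1$xyz), tolerance = 1e-6)
  expect_equal(avg1$rmsf, avg2$rmsf, tolerance = 1e-6)
})
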