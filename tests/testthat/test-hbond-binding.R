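# H-bond detection geometry, occupancy statistics, the binding-state
# machine and the termination metric.

# place donor N, hydrogen H and acceptor O at prescribed distance/angle
geom_frame <- function(d_da, theta_deg) {
  nu <- 1.0
  th <- theta_deg * pi / 180
  h <- c(0, 0, 0)
  d <- c(nu, 0, 0)
  ct <- cos(th)
  ha <- nu * ct + sqrt((nu * ct)^2 + d_da^2 - nu^2)
  a <- h + ha * c(ct, sin(th), 0)
  m <- matrix(0, 10, 3)
  m[1, ] <- d   # N of residue 1 (donor)
  m[2, ] <- h   # H of residue 1
  m[10, ] <- a  # O of residue 2 (acceptor)
  m[3:9, ] <- matrix(seq(30, 50, length.out = 21), ncol = 3)
  m
}

geom_bond <- hbond_spec("g1", donor = c(1, "N"), hydrogen = c(1, "H"),
                        acceptors = list(c(2, "O")), group = "A")

test_that("detection honours the distance and angle cutoffs exactly", {
  top <- tiny_topology(2)
  cases <- list(list(2.8, 170, TRUE),   # inside both cutoffs
                list(3.6, 170, FALSE),  # distance fails
                list(2.8, 120, FALSE),  # angle fails
                list(3.49, 131, TRUE),  # just inside both
                list(3.51, 170, FALSE))
  for (cs in cases) {
    tr <- tiny_trajectory(top, list(geom_frame(cs[[1]], cs[[2]])))
    trc <- detect_hbonds(tr, list(geom_bond))
    expect_equal(unname(trc$occupancy[1, 1]), cs[[3]],
                 label = sprintf("d=%g theta=%g", cs[[1]], cs[[2]]))
  }
})

test_that("multi-acceptor bonds count if any acceptor qualifies", {
  top <- tiny_topology(2)
  m <- geom_frame(2.8, 170)
  bond2 <- hbond_spec("g2", donor = c(1, "N"), hydrogen = c(1, "H"),
                      acceptors = list(c(2, "C"), c(2, "O")))
  # acceptor C is far (frame template), O close: combined bond present
  tr <- tiny_trajectory(top, list(m))
  trc <- detect_hbonds(tr, list(bond2))
  expect_true(trc$occupancy[1, 1])
  expect_lt(trc$distance[1, 1], 3.5)
})

test_that("missing hydrogen is an error, not a donor-only fallback", {
  top <- tiny_topology(2)
  bad <- hbond_spec("g3", donor = c(1, "N"), hydrogen = c(1, "HZ9"),
                    acceptors = list(c(2, "O")))
  tr <- tiny_trajectory(top, list(geom_frame(2.8, 170)))
  expect_error(detect_hbonds(tr, list(bad)), "hydrogen")
})

test_that("detection agrees with the generator schedule at p_on = 0.5", {
  spec <- synthetic_spec(n_replicas = 1, n_frames = 2000, dt = 0.1, seed = 6)
  hb <- build_topology(spec)$hbonds
  for (i in seq_along(hb)) hb[[i]]$p_on <- 0.5
  spec$hbonds <- hb
  sim <- simulate_ensemble(spec)
  trc <- detect_hbonds(sim$ensemble$trajectories[[1]], sim$truth$hbonds)
  expect_gte(mean(trc$occupancy == sim$truth$schedules[[1]]), 0.99)
})

test_that("occupancy means and replica SDs follow their definitions", {
  all_on <- mock_trace(matrix(TRUE, 10, 1))
  p <- hbond_probability(all_on, by_replica = FALSE)
  expect_equal(p$mean, 1)
  alt <- mock_trace(matrix(c(TRUE, FALSE), 10, 1))
  expect_equal(hbond_probability(alt)$mean, 0.5)
  # replicas with occupancies 0.2 / 0.5 / 0.8: mean 0.5, sample SD 0.3
  reps <- lapply(c(0.2, 0.5, 0.8), function(p) {
    mock_trace(matrix(rep(c(TRUE, FALSE), times = c(p * 10, 10 - p * 10)),
                      ncol = 1))
  })
  out <- hbond_probability(reps)
  expect_equal(out$mean, 0.5)
  expect_equal(out$sd, 0.3)
  expect_error(hbond_probability(all_on, frame_mask = integer(0)), "empty")
})

test_that("joint occupancy reduces to marginals and follows the product law", {
  one <- mock_trace(matrix(c(TRUE, TRUE, FALSE, FALSE, TRUE), 5, 1))
  expect_equal(joint_occupancy(one, "b1"), 0.6)
  # two independent bonds at 0.5: all_present near 0.25
  set.seed(1)
  two <- mock_trace(matrix(runif(2 * 20000) < 0.5, ncol = 2))
  expect_equal(joint_occupancy(two, c("b1", "b2")), 0.25, tolerance = 0.02)
  # perfectly co-occurring bonds collapse to the marginal
  co <- mock_trace(matrix(rep(c(TRUE, FALSE, TRUE, TRUE), 2), ncol = 2))
  expect_equal(joint_occupancy(co, c("b1", "b2")),
               joint_occupancy(co, "b1"))
  expect_error(joint_occupancy(one, character(0)), "non-empty")
})

test_that("all bonds on means fully bound throughout", {
  trc <- mock_trace(matrix(TRUE, 50, 6))
  out <- classify_binding(trc, persistence = 5, dt = 1)
  expect_true(all(out$state == "FULLY_BOUND"))
})

test_that("short group-A losses inside the persistence window do not demote", {
  occ <- matrix(TRUE, 40, 6)
  occ[10:13, 1:3] <- FALSE  # 4 frames < window of 5
  out <- classify_binding(mock_trace(occ), persistence = 5, dt = 1)
  expect_true(all(out$state == "FULLY_BOUND"))
})

test_that("staged loss walks fully -> partially -> unbound at known frames", {
  occ <- matrix(FALSE, 60, 6)
  occ[1:10, ] <- TRUE          # fully bound
  occ[11:40, 4:6] <- TRUE      # A lost, B present
  # frames 41:60: everything lost
  out <- classify_binding(mock_trace(occ), persistence = 5, dt = 1)
  # A lost from frame 11; the run strictly exceeds 5 frames at frame 16
  expect_true(all(out$state[1:15] == "FULLY_BOUND"))
  expect_equal(out$state[16], "PARTIALLY_BOUND")
  # all six lost from frame 41; the run exceeds the window at frame 46
  expect_true(all(out$state[16:45] == "PARTIALLY_BOUND"))
  expect_true(all(out$state[46:60] == "UNBOUND"))
})

test_that("classifier matches the rule-table oracle on random timelines", {
  set.seed(123)
  for (rep in 1:200) {
    occ <- matrix(runif(60 * 6) < runif(1, 0.2, 0.8), 60, 6)
    for (w in c(1, 5, 25)) {
      got <- classify_binding(mock_trace(occ), persistence = w, dt = 1)
      want <- oracle_binding_states(occ[, 1:3], occ[, 4:6],
                                    persistence = w, dt = 1)
      expect_identical(got$state, want)
    }
  }
})

test_that("rebinding flag controls recovery from the partially bound state", {
  occ <- matrix(FALSE, 40, 6)
  occ[, 5] <- TRUE       # one B bond always on: never unbound
  occ[1:5, 1] <- TRUE    # A present initially
  occ[20:40, 1] <- TRUE  # A returns after the window completed
  default <- classify_binding(mock_trace(occ), persistence = 5, dt = 1)
  expect_true(all(default$state[20:40] == "PARTIALLY_BOUND"))
  allowed <- classify_binding(mock_trace(occ), persistence = 5, dt = 1,
                              allow_rebinding = TRUE)
  expect_true(all(allowed$state[20:40] == "FULLY_BOUND"))
})

test_that("monotonicity: adding occupancy never demotes a frame", {
  set.seed(77)
  rank_of <- c(FULLY_BOUND = 3, PARTIALLY_BOUND = 2, UNBOUND = 1)
  for (rep in 1:25) {
    occ <- matrix(runif(50 * 6) < 0.3, 50, 6)
    base <- classify_binding(mock_trace(occ), persistence = 3, dt = 1)
    occ2 <- occ
    flip <- which(!occ2)[sample(sum(!occ2), 5)]
    occ2[flip] <- TRUE
    more <- classify_binding(mock_trace(occ2), persistence = 3, dt = 1)
    expect_true(all(rank_of[more$state] >= rank_of[base$state]))
  }
})

test_that("traces shorter than the persistence window warn", {
  occ <- matrix(TRUE, 3, 6)
  expect_warning(classify_binding(mock_trace(occ), persistence = 5, dt = 1),
                 "shorter")
})

test_that("termination metric sums four pair distances and flags exceedance", {
  top <- tiny_topology(2)
  m <- matrix(0, 10, 3)
  m[6, ] <- c(5, 0, 0)   # residue 2 N
  m[7, ] <- c(0, 5, 0)   # residue 2 H
  m[8, ] <- c(0, 0, 5)   # residue 2 CA
  m[9, ] <- c(3, 4, 0)   # residue 2 C
  pairs <- list(list(a = c(1, "N"), b = c(2, "N")),
                list(a = c(1, "H"), b = c(2, "H")),
                list(a = c(1, "CA"), b = c(2, "CA")),
                list(a = c(1, "C"), b = c(2, "C")))
  tr <- tiny_trajectory(top, list(m))
  out <- termination_metric(tr, pairs, threshold = 80)
  expect_equal(out$sum, 20)
  expect_true(is.na(out$termination_frame))
  expect_error(termination_metric(tr, pairs[1:3]), "four")
})

test_that("scripted unbinding terminates near the drift-predicted frame", {
  spec <- synthetic_spec(n_replicas = 1, n_frames = 2200, dt = 0.1,
                         unbind_events = list(r1 = 20), seed = 8)
  sim <- simulate_ensemble(spec)
  tr <- sim$ensemble$trajectories[[1]]
  hb <- sim$truth$hbonds
  pairs <- lapply(hb[1:3], function(h)
    list(a = h$donor, b = h$acceptors[[1]]))
  pairs[[4]] <- list(a = hb[[4]]$donor, b = hb[[4]]$acceptors[[1]])
  out <- termination_metric(tr, pairs, threshold = 80)
  expect_false(is.na(out$termination_frame))
  # oracle: recompute the noiseless drift geometry directly
  bt <- build_topology(spec)
  tmpl <- xyz_to_mat(bt$xyz)
  idx <- function(ref) atom_index(bt$top, select_atoms(
    bt$top, sel(resid = as.integer(ref[1]), name = ref[2])))
  t_ns <- (seq_len(2200) - 1) * 0.1
  drift <- pmax(0, t_ns - 20) * 0.5
  pred_sum <- rep(0, 2200)
  for (p in pairs) {
    a <- tmpl[idx(p$a), ]; b <- tmpl[idx(p$b), ]
    pred_sum <- pred_sum +
      sqrt((a[1] - b[1])^2 + (a[2] + drift - b[2])^2 + (a[3] - b[3])^2)
  }
  pred_frame <- which(pred_sum > 80)[1]
  expect_lte(abs(out$termination_frame - pred_frame), 10)
})

test_that("bound-state ensembles keep the metric stable and far below 80 A", {
  spec <- synthetic_spec(n_replicas = 1, n_frames = 500, dt = 0.1, seed = 10)
  sim <- simulate_ensemble(spec)
  hb <- sim$truth$hbonds
  pairs <- c(lapply(hb[1:3], function(h) list(a = h$donor,
                                              b = h$acceptors[[1]])),
             list(list(a = hb[[4]]$donor, b = hb[[4]]$acceptors[[1]])))
  out <- termination_metric(sim$ensemble$trajectories[[1]], pairs)
  expect_true(is.na(out$termination_frame))
  expect_lt(mean(out$sum), 40)
  expect_lt(sd(out$sum), 5)
})
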