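test_that("compartment models validate rates, adjacency and initial states", {
  states <- c("A", "B")
  Q <- matrix(c(-1, 1, 2, -2), 2, 2, byrow = TRUE)
  m <- ctmc_model(states, Q, 3L, "A")
  expect_s3_class(m, "qx_ctmc")

  expect_error(ctmc_model(states, matrix(c(-1, 1, 2, -1), 2, 2,
                                         byrow = TRUE), 1L, "A"),
               "sum to 0")
  expect_error(ctmc_model(states, matrix(c(1, -1, 2, -2), 2, 2,
                                         byrow = TRUE), 1L, "A"),
               ">= 0")
  expect_error(ctmc_model(states, Q, 1L, "C"), "unknown initial")
  adj <- matrix(FALSE, 2, 2)
  expect_error(ctmc_model(states, Q, 1L, "A", adjacency = adj),
               "non-adjacent")
})

test_that("the PSII preset connects only physically adjacent compartments", {
  cm <- psii_ctmc()
  Q <- cm$Q
  expect_equal(rowSums(Q), setNames(rep(0, 8), cm$states),
               tolerance = 1e-12)
  # no direct bulk <-> cavity or bulk <-> QB transitions
  expect_equal(Q["BULK_S", "CAV_S"], 0)
  expect_equal(Q["BULK_L", "CAV_L"], 0)
  expect_equal(Q["BULK_S", "QB"], 0)
  expect_equal(Q["CH_I", "QB"], 0)
  # channels talk to both sides
  expect_gt(Q["CH_I", "BULK_S"], 0)
  expect_gt(Q["CH_I", "CAV_L"], 0)
  # one plastoquinol starts bound at QB
  expect_equal(sum(cm$init == "QB"), 1L)
  expect_identical(cm$species[cm$init == "QB"], "PLQol")
})

test_that("frozen chains stay put and seeds are reproducible and stable", {
  states <- c("A", "B")
  Q0 <- matrix(0, 2, 2)
  frozen <- ctmc_model(states, Q0, 5L, c("A", "B", "A", "B", "A"))
  p <- simulate_ctmc(frozen, 10, seed = 3)
  for (i in 1:5) {
    expect_length(p$paths[[i]]$states, 1L)
    expect_identical(p$paths[[i]]$states, frozen$init[i])
  }

  cm <- psii_ctmc(rate_scale = 5)
  p1 <- simulate_ctmc(cm, 5, seed = 11)
  p2 <- simulate_ctmc(cm, 5, seed = 11)
  expect_identical(p1$paths, p2$paths)
  p3 <- simulate_ctmc(cm, 5, seed = 12)
  expect_false(identical(p1$paths, p3$paths))

  # adding ligands does not reshuffle existing ligands' paths
  cm_more <- cm
  cm_more$n_ligands <- cm$n_ligands + 4L
  cm_more$init <- c(cm$init, rep("BULK_S", 4L))
  cm_more$species <- c(cm$species, rep("PLQ", 4L))
  p4 <- simulate_ctmc(cm_more, 5, seed = 11)
  expect_identical(p4$paths[seq_len(cm$n_ligands)], p1$paths)
})

test_that("two-state occupancy matches the stationary distribution", {
  # k12 = 1, k21 = 3 per us: stationary occupancy of state 1 is 0.75
  states <- c("S1", "S2")
  Q <- matrix(c(-1, 1, 3, -3), 2, 2, byrow = TRUE)
  cm <- ctmc_model(states, Q, 1000L, "S1")
  p <- simulate_ctmc(cm, 100, seed = 29)
  frac <- vapply(p$paths, function(path) {
    bounds <- c(path$times_us, 100)
    sum(diff(bounds)[path$states == "S1"]) / 100
  }, numeric(1))
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.75), 3 * se)
})

test_that("dwell times are exponential with the state's total exit rate", {
  states <- c("A", "B", "C")
  Q <- matrix(c(-2, 1.5, 0.5,
                1, -1.8, 0.8,
                0.3, 0.2, -0.5), 3, 3, byrow = TRUE)
  cm <- ctmc_model(states, Q, 300L, "A")
  p <- simulate_ctmc(cm, 50, seed = 31)
  log <- ground_truth_log(p)
  # dwell in A = time between entering A and the next jump
  dwells <- numeric(0)
  for (path in p$paths) {
    n <- length(path$states)
    if (n < 2L) next
    d <- diff(path$times_us)
    dwells <- c(dwells, d[path$states[-n] == "A"])
  }
  dwells <- dwells[seq_len(min(1000L, length(dwells)))]
  ks <- suppressWarnings(ks.test(dwells, "pexp", 2))
  expect_gt(ks$p.value, 0.01)
  expect_gt(length(dwells), 500L)
  expect_true(all(c("from", "to", "t_us", "ligand") %in% names(log)))
})

test_that("rendered trajectories stay inside the box and the current region", {
  g <- toy_psii_geometry(1L)
  cm <- psii_ctmc(rate_scale = 10)
  paths <- simulate_ctmc(cm, 5, seed = 37)
  rnd <- render_trajectory(paths, g, stride_ns = 1, seed = 38)
  traj <- rnd$traj
  box <- traj$box[1, ]
  expect_true(all(abs(traj$coords) <= max(box)))
  # head beads lie inside (or within the hysteresis margin of) the region
  # of their current state
  delta <- 0.3
  for (i in seq_len(3L)) {   # spot-check three ligands
    id <- paste0("L", i)
    head_col <- match(paste0(id, "_H"), traj$beads$bead_id)
    pts <- traj$coords[, head_col, ]
    p <- paths$paths[[i]]
    st <- p$states[findInterval(traj$times / 1e3, p$times_us)]
    lab <- locate(pts, g)
    side_true <- quinex:::.state_side(st)
    side_seen <- quinex:::.label_side(lab)
    # allow the one-frame gate routing at state changes
    mismatch <- which(side_true != side_seen)
    changes <- which(c(FALSE, diff(findInterval(traj$times / 1e3,
                                                p$times_us)) != 0))
    expect_true(all(mismatch %in% c(changes, changes - 1L, changes + 1L)))
  }
})

test_that("a scripted single passage round-trips through the event module", {
  g <- toy_psii_geometry(1L)
  # scripted path: bulk -> channel I -> cavity, fixed jump times
  path <- list(states = c("BULK_S", "CH_I", "CAV_S"),
               times_us = c(0, 0.4, 0.8))
  paths <- structure(list(paths = list(path),
                          model = psii_ctmc(n_bulk = 1L, n_cavity = 0L,
                                            with_qb_ligand = FALSE),
                          duration_us = 1.2, seed = 1L),
                     class = "qx_ctmcpaths")
  rnd <- render_trajectory(paths, g, stride_ns = 0.5, seed = 41)
  tr <- label_trace(rnd$traj, g, 0.3)
  ev <- detect_passages(tr)
  full <- ev[ev$completeness == "full", ]
  expect_equal(nrow(full), 1L)
  expect_equal(full$channel, "I")
  expect_equal(full$direction, "in")

  # a ligand scripted to stay in the cavity labels as cavity throughout
  path2 <- list(states = "CAV_L", times_us = 0)
  paths2 <- paths
  paths2$paths <- list(path2)
  rnd2 <- render_trajectory(paths2, g, stride_ns = 0.5, seed = 42)
  tr2 <- label_trace(rnd2$traj, g, 0.3)
  expect_true(all(tr2$L1$label == "CAVITY.1"))
})

test_that("event recovery from rendered coordinates is near-perfect", {
  g <- toy_psii_geometry(1L)
  cm <- psii_ctmc(rate_scale = 10)
  n_truth <- 0L; n_det <- 0L; n_match <- 0L
  for (s in 1:6) {
    paths <- simulate_ctmc(cm, 15, seed = 200 + s)
    rnd <- render_trajectory(paths, g, stride_ns = 0.5, seed = 300 + s)
    tr <- label_trace(rnd$traj, g, 0.3)
    ev <- detect_passages(tr)
    det <- ev[ev$completeness == "full", ]
    tru <- rnd$truth$passages
    tru <- tru[tru$completeness == "full", ]
    n_truth <- n_truth + nrow(tru)
    n_det <- n_det + nrow(det)
    for (r in seq_len(nrow(tru))) {
      hit <- det$ligand == tru$ligand[r] & det$channel == tru$channel[r] &
        det$direction == tru$direction[r] &
        abs(det$t_start_ns - tru$t_start_ns[r]) < 100
      n_match <- n_match + any(hit)
    }
  }
  expect_gt(n_truth, 10L)
  expect_gte(n_match / n_truth, 0.95)   # sensitivity
  expect_gte(n_match / n_det, 0.95)     # precision
})

test_that("configured flip-flop kinetics are recovered from rendered traces", {
  g <- toy_psii_geometry(1L)
  # ligands fixed in the cavity flip-flopping at the preset rate
  k <- 0.05  # per us per direction
  states <- c("CAV_S", "CAV_L")
  Q <- matrix(c(-k, k, k, -k), 2, 2, byrow = TRUE)
  cm <- ctmc_model(states, Q, 40L, rep(c("CAV_S", "CAV_L"), 20L))
  p <- simulate_ctmc(cm, 100, seed = 43)
  tr <- sample_state_trace(p, stride_ns = 20, model = g)
  ev <- detect_flipflops(tr, g, delta_z_nm = 0.3)
  truth <- ground_truth_flipflops(p)
  n_expected <- nrow(truth)
  expect_equal(nrow(ev), n_expected)
  # rate recovery: each leaflet state exits at rate k, so switches occur
  # at rate k per ligand
  lambda <- k * 100 * 40
  expect_lt(abs(nrow(ev) - lambda), 3 * sqrt(lambda))
  # timescale arithmetic on recovered counts: residence/n estimates 1/k
  ts <- estimate_timescale(nrow(ev), 100 * 40)
  expect_lt(abs(ts$value_us - 1 / k), 3 * sqrt(lambda) / lambda * (1 / k))
})

test_that("renders are deterministic given the seed", {
  g <- toy_psii_geometry(1L)
  cm <- psii_ctmc(rate_scale = 10)
  p <- simulate_ctmc(cm, 2, seed = 47)
  r1 <- render_trajectory(p, g, stride_ns = 1, seed = 48)
  r2 <- render_trajectory(p, g, stride_ns = 1, seed = 48)
  expect_identical(r1$traj$coords, r2$traj$coords)
  expect_identical(r1$truth, r2$truth)
})

test_that("adaptive respawn enriches the rare target against the baseline", {
  toy <- toy_rare_target()
  ratios <- vapply(1:10, function(s) {
    ad <- adaptive_respawn(toy$engine, toy$selector, "A", n_rounds = 6,
                           k_select = 12, spawn_len_us = 4, seed = s,
                           is_hit = toy$is_hit,
                           respawnable = toy$respawnable)
    bl <- plain_respawn(toy$engine, "A", 72, 4, seed = s,
                        is_hit = toy$is_hit)
    enrichment_report(ad, bl)$enrichment_ratio
  }, numeric(1))
  expect_gte(mean(ratios > 1), 0.9)
})

test_that("one-round adaptive from the initial state equals plain restarts", {
  toy <- toy_rare_target()
  ad <- adaptive_respawn(toy$engine, toy$selector, "A", n_rounds = 1,
                         k_select = 20, spawn_len_us = 5, seed = 7,
                         is_hit = toy$is_hit)
  bl <- plain_respawn(toy$engine, "A", 20, 5, seed = 7,
                      is_hit = toy$is_hit)
  expect_identical(ad$hits, bl$hits)
  expect_identical(vapply(ad$runs, `[[`, logical(1), "hit"),
                   vapply(bl$runs, `[[`, logical(1), "hit"))
  expect_error(adaptive_respawn(toy$engine, toy$selector, "A", 1, 0, 5, 1,
                                toy$is_hit), "k_select")
})

test_that("a constant selector is statistically indistinguishable from plain restarts", {
  toy <- toy_rare_target()
  tot_a <- 0L; tot_b <- 0L
  for (s in 1:20) {
    ad <- adaptive_respawn(toy$engine, function(st) 0, "A", n_rounds = 5,
                           k_select = 10, spawn_len_us = 5, seed = s,
                           is_hit = toy$is_hit,
                           respawnable = toy$respawnable)
    bl <- plain_respawn(toy$engine, "A", 50, 5, seed = s,
                        is_hit = toy$is_hit)
    tot_a <- tot_a + ad$hits
    tot_b <- tot_b + bl$hits
  }
  # 99% CI of the log hit-rate ratio must contain 0
  se <- sqrt(1 / tot_a + 1 / tot_b)
  lr <- log(tot_a / tot_b)
  expect_lt(lr - 2.576 * se, 0)
  expect_gt(lr + 2.576 * se, 0)
})
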