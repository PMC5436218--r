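toy_model <- toy_psii_geometry(1L)

# build a head-only trajectory from an explicit head path
head_traj <- function(path, stride = 0.5) {
  nf <- nrow(path)
  make_traj(c(list(Q1_H = path),
              list(R1 = matrix(rep(c(0, 0, 0), each = nf), nf),
                   R2 = matrix(rep(c(4, 0, 0), each = nf), nf),
                   R3 = matrix(rep(c(0, 4, 0), each = nf), nf))),
            roles = c("head", rep("protein", 3)),
            ligands = c("Q1", NA, NA, NA),
            times = seq(0, by = stride, length.out = nf),
            box = c(24, 24, 8))
}

test_that("a ligand fixed in the cavity yields a constant trace", {
  path <- matrix(rep(c(0, 0, 1), each = 100), 100)
  tr <- label_trace(head_traj(path), toy_model)
  expect_length(tr, 1L)
  expect_true(all(tr$Q1$label == "CAVITY.1"))
  expect_true(all(tr$Q1$leaflet == "stromal"))
})

test_that("hysteresis suppresses sub-threshold flicker at a gate", {
  # oscillate +/- delta/4 across the cavity/channel-I gate at y = -2
  n <- 60
  y <- -2 + 0.075 * rep(c(1, -1), n / 2)
  path <- cbind(0, y, 0)
  tr <- label_trace(head_traj(path), toy_model, hysteresis_delta_nm = 0.3)
  expect_length(unique(tr$Q1$label), 1L)
})

test_that("with zero hysteresis the trace equals raw locate labels", {
  set.seed(31)
  path <- cbind(runif(400, -6, 6), runif(400, -6, 6), runif(400, -3, 3))
  tr <- label_trace(head_traj(path), toy_model, hysteresis_delta_nm = 0)
  expect_identical(tr$Q1$label, locate(path, toy_model))
})

test_that("canonical passage sequences are classified correctly", {
  # B,B,I,I,C -> one full entry via channel I
  tr <- make_trace(c("BULK", "BULK", "CHANNEL_I.1", "CHANNEL_I.1",
                     "CAVITY.1"))
  ev <- detect_passages(tr, min_dwell_ns = 0)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$completeness, "full")
  expect_equal(ev$direction, "in")
  expect_equal(ev$channel, "I")

  # B,I,B -> one partial in
  ev2 <- detect_passages(make_trace(c("BULK", "CHANNEL_I.1", "BULK")),
                         min_dwell_ns = 0)
  expect_equal(ev2$completeness, "partial")
  expect_equal(ev2$direction, "in")

  # C,II,B -> full exit via II
  ev3 <- detect_passages(make_trace(c("CAVITY.1", "CHANNEL_II.1", "BULK")),
                         min_dwell_ns = 0)
  expect_equal(ev3$completeness, "full")
  expect_equal(ev3$direction, "out")
  expect_equal(ev3$channel, "II")

  # channel at the trace edges -> trapped
  ev4 <- detect_passages(make_trace(c("CHANNEL_I.1", "BULK",
                                      "CHANNEL_III.1")), min_dwell_ns = 0)
  expect_equal(ev4$completeness, c("trapped", "trapped"))

  # unknown labels error
  bad <- make_trace(c("BULK", "WAT", "BULK"))
  expect_error(detect_passages(bad), "unknown")
})

test_that("passage detection matches the excursion-scanning oracle on random sequences", {
  set.seed(41)
  for (trial in 1:1000) {
    labs <- random_label_sequence(sample(5:40, 1L))
    tr <- make_trace(labs)
    got <- detect_passages(tr, min_dwell_ns = 1)
    want <- oracle_passages(labs, tr$time, min_dwell_ns = 1)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$channel,
                   vapply(want, function(w)
                     sub("\\..*$", "", sub("^CHANNEL_", "", w$channel)),
                     character(1L)))
      expect_equal(got$completeness,
                   vapply(want, `[[`, character(1L), "completeness"))
      expect_equal(got$direction,
                   vapply(want, function(w) as.character(w$direction),
                          character(1L)))
    }
  }
})

test_that("time reversal swaps entries and exits, preserving event counts", {
  set.seed(43)
  for (trial in 1:50) {
    labs <- random_label_sequence(60)
    f <- detect_passages(make_trace(labs), min_dwell_ns = 0)
    r <- detect_passages(make_trace(rev(labs)), min_dwell_ns = 0)
    expect_equal(nrow(f), nrow(r))
    expect_equal(sum(f$completeness == "full" & f$direction == "in"),
                 sum(r$completeness == "full" & r$direction == "out"))
    expect_equal(sum(f$completeness == "full" & f$direction == "out"),
                 sum(r$completeness == "full" & r$direction == "in"))
  }
})

test_that("raising min_dwell never increases event counts and leaves full counts unchanged", {
  set.seed(47)
  labs <- random_label_sequence(500)
  tr <- make_trace(labs)
  dwells <- c(0, 0.5, 1, 2, 4, 8)
  n_total <- integer(0)
  n_full <- integer(0)
  for (d in dwells) {
    ev <- detect_passages(tr, min_dwell_ns = d)
    n_total <- c(n_total, nrow(ev))
    n_full <- c(n_full, sum(ev$completeness == "full"))
  }
  expect_true(all(diff(n_total) <= 0))
  expect_true(all(diff(n_full) <= 0))
})

test_that("orientation classification orders head vs tail gate crossings", {
  # entry through channel I (gate at y = -4): head leads
  n <- 40
  y_head <- seq(-6.5, -0.5, length.out = n)
  head <- cbind(0, y_head, 0)
  tail <- cbind(0, y_head - 1.0, 0)   # trails 1 nm behind
  nf <- n
  traj <- make_traj(list(Q1_H = head, Q1_T1 = tail,
                         R1 = matrix(0, nf, 3),
                         R2 = matrix(rep(c(4, 0, 0), each = nf), nf),
                         R3 = matrix(rep(c(0, 4, 0), each = nf), nf)),
                    roles = c("head", "tail", rep("protein", 3)),
                    ligands = c("Q1", "Q1", NA, NA, NA),
                    box = c(24, 24, 8))
  tr <- label_trace(traj, toy_model)
  ev <- detect_passages(tr, min_dwell_ns = 0)
  full <- ev[ev$completeness == "full", ]
  expect_equal(nrow(full), 1L)
  rm <- role_map(list(Q1 = list(head_beads = "Q1_H",
                                tail_beads = "Q1_T1")),
                 c("R1", "R2", "R3"))
  expect_identical(classify_orientation(traj, full[1, ], rm, toy_model),
                   "head_first")

  # swapping head and tail roles flips the verdict
  rm_swap <- role_map(list(Q1 = list(head_beads = "Q1_T1",
                                     tail_beads = "Q1_H")),
                      c("R1", "R2", "R3"))
  traj_swap <- traj
  traj_swap$beads$role[1:2] <- c("tail", "head")
  tr2 <- label_trace(traj_swap, toy_model)
  ev2 <- detect_passages(tr2, min_dwell_ns = 0)
  full2 <- ev2[ev2$completeness == "full", ]
  expect_identical(classify_orientation(traj_swap, full2[1, ], rm_swap,
                                        toy_model), "tail_first")

  # same-frame crossing -> undetermined
  traj_same <- traj
  traj_same$coords[, 2, ] <- traj_same$coords[, 1, ]
  tr3 <- label_trace(traj_same, toy_model)
  ev3 <- detect_passages(tr3, min_dwell_ns = 0)
  full3 <- ev3[ev3$completeness == "full", ]
  expect_identical(classify_orientation(traj_same, full3[1, ], rm,
                                        toy_model), "undetermined")

  # missing tail beads -> warning + undetermined
  rm_notail <- role_map(list(Q1 = list(head_beads = "Q1_H",
                                       tail_beads = character(0))),
                        c("R1", "R2", "R3"))
  expect_warning(
    out <- classify_orientation(traj, full[1, ], rm_notail, toy_model),
    "tail")
  expect_identical(out, "undetermined")
})

test_that("flip-flop detection with a dead band sees clean crossings only", {
  # clean +1 -> -1 nm crossing inside the cavity
  z <- c(rep(1, 10), seq(1, -1, length.out = 10), rep(-1, 10))
  tr <- make_trace(rep("CAVITY.1", 30), z = z)
  ev <- detect_flipflops(tr, toy_model, delta_z_nm = 0.3)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$from_leaflet, "stromal")
  expect_equal(ev$to_leaflet, "lumenal")
  expect_equal(ev$compartment, "cavity")

  # sub-threshold oscillation: no events
  z2 <- 0.2 * rep(c(1, -1), 25)
  ev2 <- detect_flipflops(make_trace(rep("CAVITY.1", 50), z = z2),
                          toy_model, delta_z_nm = 0.3)
  expect_equal(nrow(ev2), 0L)

  # a compartment exit resets the detector: no event across the gap
  z3 <- c(rep(1, 5), rep(0, 5), rep(-1, 5))
  labs3 <- c(rep("CAVITY.1", 5), rep("CHANNEL_I.1", 5), rep("BULK", 5))
  ev3 <- detect_flipflops(make_trace(labs3, z = z3), toy_model, 0.3)
  expect_equal(nrow(ev3), 0L)
})

test_that("telegraph-process flip-flop counts fall in the Poisson band", {
  # two-state telegraph z process at rate k per leg: the number of
  # detected leg switches in time T is Poisson-like with mean ~ kT
  k <- 0.02   # per us per leg
  T_us <- 500
  stride_ns <- 100
  n_lig <- 20
  set.seed(53)
  total <- 0L
  for (i in seq_len(n_lig)) {
    # exact telegraph simulation
    t <- 0; leg <- sample(c(1, -1), 1L)
    switch_times <- numeric(0)
    repeat {
      t <- t + rexp(1, k)
      if (t >= T_us) break
      switch_times <- c(switch_times, t)
    }
    grid_us <- seq(0, T_us, by = stride_ns / 1e3)
    z <- leg * (-1)^findInterval(grid_us, switch_times)
    tr <- make_trace(rep("CAVITY.1", length(grid_us)),
                     stride_ns = stride_ns, z = z)
    total <- total + nrow(detect_flipflops(tr, toy_model, 0.3))
  }
  lambda <- k * T_us * n_lig
  band <- qpois(c(0.025, 0.975), lambda)
  expect_gte(total, band[1])
  expect_lte(total, band[2])
})

test_that("unbinding detection separates full, transient and partial events", {
  nf <- 200
  stride <- 0.5
  site <- c(0, 1, 0.8)
  mk <- function(head, tail) {
    make_traj(list(Q1_H = head, Q1_T1 = tail,
                   R1 = matrix(0, nf, 3),
                   R2 = matrix(rep(c(4, 0, 0), each = nf), nf),
                   R3 = matrix(rep(c(0, 4, 0), each = nf), nf)),
              roles = c("head", "tail", rep("protein", 3)),
              ligands = c("Q1", "Q1", NA, NA, NA), box = c(24, 24, 8))
  }
  rm <- role_map(list(Q1 = list(head_beads = "Q1_H",
                                tail_beads = "Q1_T1")),
                 c("R1", "R2", "R3"))

  # clean escape: 0.3 nm from the site to 2.5 nm, never returns
  d <- c(rep(0.3, 50), seq(0.3, 2.5, length.out = 50), rep(2.5, 100))
  head <- cbind(site[1], site[2] - d, site[3])
  tail <- head
  ev <- detect_unbinding(mk(head, tail), toy_model, rm)
  expect_equal(ev$type, "full")

  # excursion to 1.5 nm returning to 0.4 nm after 5 ns (< t_rebind)
  d2 <- rep(0.3, nf)
  d2[60:70] <- 1.5
  d2[71:nf] <- 0.4
  head2 <- cbind(site[1], site[2] - d2, site[3])
  ev2 <- detect_unbinding(mk(head2, head2), toy_model, rm,
                          t_rebind_ns = 50)
  expect_equal(ev2$type, "transient")
  expect_false(is.na(ev2$rebind_t_ns))

  # head stays bound at 0.4 nm while the tail leaves channel II
  head3 <- matrix(rep(c(site[1], site[2] - 0.4, site[3]), each = nf), nf)
  tail3 <- head3
  tail3[1:100, ] <- matrix(rep(c(0, 3, 0), each = 100), 100)  # in channel II
  tail3[101:nf, ] <- matrix(rep(c(0, 0, -1), each = 100), 100)  # back in cavity
  ev3 <- detect_unbinding(mk(head3, tail3), toy_model, rm)
  expect_true("partial" %in% ev3$type)

  # thresholds must be ordered
  expect_error(detect_unbinding(mk(head, tail), toy_model, rm,
                                r_bound_nm = 1.2, r_unbound_nm = 0.6),
               "r_bound")
})

test_that("jitter below half the hysteresis margin never changes full-event counts", {
  # a clean scripted passage rendered as coordinates, then jittered
  set.seed(59)
  path <- rbind(
    matrix(rep(c(0, -6, 0.8), each = 30), 30),   # bulk
    matrix(rep(c(0, -3, 0), each = 30), 30),     # channel I
    matrix(rep(c(0, 0, 0.8), each = 30), 30),    # cavity
    matrix(rep(c(0, -3, 0), each = 30), 30),     # channel I again
    matrix(rep(c(0, -6, -0.8), each = 30), 30))  # bulk
  base <- detect_passages(label_trace(head_traj(path), toy_model, 0.3),
                          min_dwell_ns = 1)
  n_full0 <- sum(base$completeness == "full")
  expect_equal(n_full0, 2L)
  for (trial in 1:20) {
    jit <- matrix(runif(length(path), -0.14, 0.14), nrow(path))
    ev <- detect_passages(label_trace(head_traj(path + jit), toy_model,
                                      0.3), min_dwell_ns = 1)
    expect_equal(sum(ev$completeness == "full"), n_full0)
  }
})
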