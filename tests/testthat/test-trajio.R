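test_that("tabular trajectories round-trip with times, beads and boxes", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  beads <- fixture_bead_paths(3L)
  write_traj_tsv(tmp, c(0, 0.5, 1.0), beads)
  rm <- fixture_role_map()
  traj <- read_trajectory(tmp, rm)
  expect_s3_class(traj, "qx_trajectory")
  expect_equal(traj$times, c(0, 0.5, 1.0))
  expect_equal(nrow(traj$beads), 8L)
  expect_equal(sum(traj$beads$role == "head"), 1L)
  expect_equal(traj$coords[2, match("Q1_H", traj$beads$bead_id), ],
               c(1, 1, 1))
  expect_equal(traj$box[1, ], c(20, 20, 10))
})

test_that("a role map naming an absent bead errors with its name", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_traj_tsv(tmp, c(0, 0.5), fixture_bead_paths(2L))
  rm <- role_map(
    ligands = list(Q1 = list(head_beads = "Q99", tail_beads = "Q1_T1")),
    protein_reference = c("R1", "R2", "R3"))
  expect_error(read_trajectory(tmp, rm), "Q99")
})

test_that("non-monotonic frame times are rejected with the frame index", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_traj_tsv(tmp, c(0, 1.0, 0.5), fixture_bead_paths(3L))
  expect_error(read_trajectory(tmp, fixture_role_map()), "frame 3")
})

test_that("ligand paths are unwrapped across the periodic boundary", {
  nf <- 3L
  beads <- fixture_bead_paths(nf)
  # ligand jumps by +box_x between frames 2 and 3 (a wrap artefact)
  for (b in c("Q1_H", "Q1_T1", "Q1_T2", "Q1_T3"))
    beads[[b]][3, 1] <- beads[[b]][3, 1] + 20
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_traj_tsv(tmp, c(0, 0.5, 1.0), beads)
  traj <- read_trajectory(tmp, fixture_role_map())
  h <- traj$coords[, match("Q1_H", traj$beads$bead_id), ]
  expect_lt(max(abs(diff(h[, 1]))), 1e-9)   # small step, not ~box_x
  # protein beads untouched
  r1 <- traj$coords[, match("R1", traj$beads$bead_id), ]
  expect_equal(r1[3, ], c(0, 0, 0))
})

test_that("unwrap then rewrap returns the original wrapped coordinates", {
  nf <- 6L
  set.seed(5)
  beads <- fixture_bead_paths(nf)
  # a drifting ligand crossing the boundary repeatedly, stored wrapped
  drift <- cbind(cumsum(runif(nf, 2, 6)), 0, 0)
  for (b in c("Q1_H", "Q1_T1", "Q1_T2", "Q1_T3")) {
    unwrapped <- beads[[b]] + drift
    wrapped <- unwrapped
    wrapped[, 1] <- unwrapped[, 1] - 20 * floor(unwrapped[, 1] / 20)
    beads[[b]] <- wrapped
  }
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_traj_tsv(tmp, seq(0, by = 0.5, length.out = nf), beads)
  traj <- read_trajectory(tmp, fixture_role_map())
  back <- rewrap(traj)
  h1 <- back$coords[, match("Q1_H", back$beads$bead_id), ]
  expect_equal(h1, beads$Q1_H, tolerance = 1e-9)
})

test_that("alignment recovers identity, pure translations and rotations", {
  nf <- 2L
  beads <- fixture_bead_paths(nf)
  traj <- make_traj(beads,
                    roles = c("head", "tail", "tail", "tail",
                              rep("protein", 4)),
                    ligands = c(rep("Q1", 4), rep(NA, 4)))
  ref <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))

  ident <- align_frames(traj, ref)
  expect_equal(ident$coords, traj$coords, tolerance = 1e-12)

  shifted <- traj
  shifted$coords <- traj$coords + rep(c(1, 2, 3), each = nf * 8)
  back <- align_frames(shifted, ref)
  expect_equal(back$coords, traj$coords, tolerance = 1e-9)
})

test_that("alignment matches the closed-form quaternion oracle", {
  set.seed(13)
  for (trial in 1:5) {
    ang <- runif(3, -pi, pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                   0, -sin(ang[1]), cos(ang[1])), 3, 3)
    Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                   sin(ang[2]), 0, cos(ang[2])), 3, 3)
    Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                   -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
    R <- Rx %*% Ry %*% Rz
    ref <- matrix(runif(15, -3, 3), 5, 3)
    mob <- ref %*% t(R) + rep(c(0.3, -1, 2), each = 5)

    R_horn <- horn_rotation(mob, ref)
    R_pkg <- quinex:::.kabsch(sweep(mob, 2, colMeans(mob)),
                              sweep(ref, 2, colMeans(ref)))
    expect_lt(max(abs(R_pkg - R_horn)), 1e-6)
    # applying the package rotation superposes exactly
    fit <- sweep(sweep(mob, 2, colMeans(mob)) %*% R_pkg, 2,
                 colMeans(ref), `+`)
    expect_lt(max(abs(fit - ref)), 1e-9)
  }
})

test_that("alignment is idempotent and preserves inter-bead distances", {
  set.seed(17)
  nf <- 4L
  beads <- fixture_bead_paths(nf)
  # jitter all beads and rigidly move each frame
  for (b in names(beads)) beads[[b]] <- beads[[b]] + runif(3)
  traj <- make_traj(beads,
                    roles = c("head", "tail", "tail", "tail",
                              rep("protein", 4)),
                    ligands = c(rep("Q1", 4), rep(NA, 4)))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  for (f in seq_len(nf))
    traj$coords[f, , ] <- traj$coords[f, , ] %*% t(R) + f
  ref <- rbind(c(0, 0, 0), c(4, 0, 0), c(0, 4, 0), c(0, 0, 4))
  d0 <- dist(traj$coords[2, , ])
  a1 <- align_frames(traj, ref)
  a2 <- align_frames(a1, ref)
  expect_lt(max(abs(a2$coords - a1$coords)), 1e-9)
  expect_lt(max(abs(dist(a1$coords[2, , ]) - d0)), 1e-9)
})

test_that("alignment requires at least three non-collinear reference beads", {
  traj <- make_traj(fixture_bead_paths(2L),
                    roles = c("head", "tail", "tail", "tail",
                              rep("protein", 4)),
                    ligands = c(rep("Q1", 4), rep(NA, 4)))
  expect_error(align_frames(traj, rbind(c(0, 0, 0), c(4, 0, 0)),
                            ref_beads = c("R1", "R2")), "at least 3")
  col <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(align_frames(traj, col, ref_beads = c("R1", "R2", "R3")),
               "collinear")
})

test_that("equilibration trimming removes early frames and validates", {
  nf <- 200L
  traj <- make_traj(fixture_bead_paths(nf),
                    roles = c("head", "tail", "tail", "tail",
                              rep("protein", 4)),
                    ligands = c(rep("Q1", 4), rep(NA, 4)))
  trimmed <- discard_equilibration(traj, 10)
  expect_equal(length(trimmed$times), 180L)
  expect_true(all(trimmed$times >= 10))

  same <- discard_equilibration(traj, 0)
  expect_equal(same$coords, traj$coords)
  expect_equal(same$times, traj$times)

  expect_error(discard_equilibration(traj, 1000), "removes all")
})

test_that("role maps validate and read from JSON", {
  expect_error(role_map(list(Q1 = list(head_beads = "A",
                                       tail_beads = "A")),
                        c("R1", "R2", "R3")), "overlap")
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(ligands = list(Q1 = list(head_beads = "Q1_H",
                                  tail_beads = c("Q1_T1"),
                                  species = "PLQol")),
         protein_reference = c("R1", "R2", "R3")),
    tmp, auto_unbox = TRUE)
  rm <- read_role_map(tmp)
  expect_s3_class(rm, "qx_rolemap")
  expect_identical(rm$ligands$Q1$species, "PLQol")
})
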