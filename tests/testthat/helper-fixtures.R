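# Fixture builders: tiny trajectories and geometries constructed in code.

# A minimal single-monomer geometry config (square cavity, one channel)
minimal_geometry_config <- function() {
  rect <- function(cx, cy, hx, hy)
    cbind(c(cx - hx, cx + hx, cx + hx, cx - hx),
          c(cy - hy, cy - hy, cy + hy, cy + hy))
  list(
    slab = list(z_lo = -2, z_hi = 2),
    monomers = list(list(
      id = 1L,
      cavity = list(poly = rect(0, 0, 2, 2), z_lo = -2, z_hi = 2),
      site = list(center = c(0, 1, 0.8), radius = 0.5),
      channels = list(list(
        label = "I",
        interior = list(poly = rect(0, -3, 0.5, 1), z_lo = -1, z_hi = 1),
        inner_gate = list(point = c(0, -2, 0), normal = c(0, 1, 0)),
        outer_gate = list(point = c(0, -4, 0), normal = c(0, -1, 0)))))))
}

# build a qx_trajectory in memory from a list of per-bead coordinate
# matrices (frames x 3), plus roles
make_traj <- function(bead_coords, roles, ligands, species = NULL,
                      times = NULL, box = c(20, 20, 10)) {
  nb <- length(bead_coords)
  nf <- nrow(bead_coords[[1L]])
  if (is.null(times)) times <- seq(0, by = 0.5, length.out = nf)
  if (is.null(species)) species <- ifelse(is.na(ligands), NA, "PLQ")
  coords <- array(NA_real_, c(nf, nb, 3L))
  for (b in seq_len(nb)) coords[, b, ] <- bead_coords[[b]]
  structure(list(
    times = times,
    beads = data.frame(bead_id = names(bead_coords), ligand = ligands,
                       role = roles, species = species,
                       stringsAsFactors = FALSE),
    coords = coords,
    box = matrix(box, nf, 3L, byrow = TRUE),
    metadata = list(source = "fixture", n_frames = nf)),
    class = "qx_trajectory")
}

# write a tabular TSV trajectory file for a small set of beads
write_traj_tsv <- function(path, times, beads, box = c(20, 20, 10)) {
  rows <- do.call(rbind, lapply(seq_along(times), function(f) {
    do.call(rbind, lapply(names(beads), function(b)
      data.frame(frame_time_ns = times[f], bead_id = b,
                 x_nm = beads[[b]][f, 1], y_nm = beads[[b]][f, 2],
                 z_nm = beads[[b]][f, 3], box_x = box[1], box_y = box[2],
                 box_z = box[3], stringsAsFactors = FALSE)))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# a simple 4-bead ligand + 3 reference beads role map
fixture_role_map <- function() {
  role_map(
    ligands = list(Q1 = list(head_beads = "Q1_H",
                             tail_beads = c("Q1_T1", "Q1_T2", "Q1_T3"),
                             species = "PLQ")),
    protein_reference = c("R1", "R2", "R3", "R4"))
}

# static positions for the fixture beads over nf frames, optionally moved
fixture_bead_paths <- function(nf, shift = c(0, 0, 0)) {
  base <- list(Q1_H = c(1, 1, 1), Q1_T1 = c(1.5, 1, 1),
               Q1_T2 = c(2, 1, 1), Q1_T3 = c(2.5, 1, 1),
               R1 = c(0, 0, 0), R2 = c(4, 0, 0), R3 = c(0, 4, 0),
               R4 = c(0, 0, 4))
  lapply(base, function(p)
    matrix(rep(p + shift, each = nf), nf, 3L))
}
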