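#' Toy PSII geometry
#'
#' Builds a small, fully synthetic geometry in the spirit of the real
#' complex: a 4 nm membrane slab, and per monomer a square exchange cavity
#' embedded in a protein footprint, three prism channels (I and II across
#' the footprint in y, III in x) with planar gates at the cavity boundary
#' (inner) and the footprint boundary (outer), and a Q_B binding-site
#' sphere inside the cavity. Channel II is rendered narrower than I and
#' III, as in the real complex. Monomers are laid out along x; with two
#' monomers the layout is mirror-symmetric about the plane between them.
#'
#' @param n_monomers 1 or 2.
#' @param spacing_nm centre-to-centre monomer distance in nm (default 18).
#' @return a `qx_geometry`; the scene metadata used by
#'   [render_trajectory()] is attached as attribute `"scene"`.
#' @export
toy_psii_geometry <- function(n_monomers = 1L, spacing_nm = 18) {
  stopifnot(n_monomers %in% c(1L, 2L))
  centres <- if (n_monomers == 1L) 0 else c(-spacing_nm / 2, spacing_nm / 2)
  rect <- function(cx, cy, hx, hy)
    cbind(c(cx - hx, cx + hx, cx + hx, cx - hx),
          c(cy - hy, cy - hy, cy + hy, cy + hy))
  monomers <- lapply(seq_len(n_monomers), function(i) {
    cx <- centres[i]
    mirror <- if (n_monomers == 2L && i == 1L) -1 else 1  # channel III side
    list(
      id = i,
      cavity = list(poly = rect(cx, 0, 2, 2), z_lo = -2, z_hi = 2),
      site = list(center = c(cx, 1, 0.8), radius = 0.6),
      channels = list(
        list(label = "I",
             interior = list(poly = rect(cx, -3, 0.5, 1), z_lo = -1, z_hi = 1),
             inner_gate = list(point = c(cx, -2, 0), normal = c(0, 1, 0)),
             outer_gate = list(point = c(cx, -4, 0), normal = c(0, -1, 0))),
        list(label = "II",
             interior = list(poly = rect(cx, 3, 0.5, 1),
                             z_lo = -0.6, z_hi = 0.6),
             inner_gate = list(point = c(cx, 2, 0), normal = c(0, -1, 0)),
             outer_gate = list(point = c(cx, 4, 0), normal = c(0, 1, 0))),
        list(label = "III",
             interior = list(poly = rect(cx + mirror * 3, 0, 1, 0.55),
                             z_lo = -1, z_hi = 1),
             inner_gate = list(point = c(cx + mirror * 2, 0, 0),
                               normal = c(-mirror, 0, 0)),
             outer_gate = list(point = c(cx + mirror * 4, 0, 0),
                               normal = c(mirror, 0, 0))))
    )
  })
  # a footprint shared by two monomers would fuse them; the single-monomer
  # scene carries one, the dimer leaves the inter-monomer membrane as bulk
  footprint <- if (n_monomers == 1L)
    list(poly = rect(0, 0, 4, 4), z_lo = -2, z_hi = 2) else NULL
  model <- build_geometry(list(slab = list(z_lo = -2, z_hi = 2),
                               monomers = monomers,
                               footprint = footprint))
  box <- c(if (n_monomers == 1L) 24 else 24 + spacing_nm, 24, 8)
  attr(model, "scene") <- list(centres = centres, box = box,
                               n_monomers = n_monomers,
                               mirrors = vapply(seq_len(n_monomers),
                                                function(i)
                                                  if (n_monomers == 2L &&
                                                      i == 1L) -1 else 1,
                                                numeric(1L)))
  model
}

# axis-aligned sampling boxes (inset by `margin` from region boundaries)
# for each CTMC state of one monomer; bulk states use the ring handled by
# .bulk_confine. Gate metadata: axis, region face coordinate and outward
# direction of each channel's gates.
.scene_layout <- function(model, monomer, margin = 0.35) {
  scene <- attr(model, "scene")
  m <- model$monomers[[monomer]]
  cx <- scene$centres[monomer]
  mirror <- scene$mirrors[monomer]
  box3 <- function(x0, x1, y0, y1, z0, z1)
    rbind(lo = c(x0, y0, z0) + margin, hi = c(x1, y1, z1) - margin)
  cav <- box3(cx - 2, cx + 2, -2, 2, -2, 2)
  qb_h <- m$site$radii[1L] / sqrt(3) - 0.01
  boxes <- list(
    CH_I = box3(cx - 0.5, cx + 0.5, -4, -2, -1, 1),
    CH_II = box3(cx - 0.5, cx + 0.5, 2, 4, -0.6, 0.6),
    CH_III = if (mirror > 0) box3(cx + 2, cx + 4, -0.55, 0.55, -1, 1)
             else box3(cx - 4, cx - 2, -0.55, 0.55, -1, 1),
    CAV_S = rbind(lo = c(cav["lo", 1:2], margin), hi = cav["hi", ]),
    CAV_L = rbind(lo = cav["lo", ], hi = c(cav["hi", 1:2], -margin)),
    QB = rbind(lo = m$site$centers[1L, ] - qb_h,
               hi = m$site$centers[1L, ] + qb_h)
  )
  gates <- list(
    CH_I = list(axis = 2L, outer_face = -4, outer_dir = -1,
                inner_face = -2),
    CH_II = list(axis = 2L, outer_face = 4, outer_dir = 1,
                 inner_face = 2),
    CH_III = list(axis = 1L, outer_face = cx + mirror * 4,
                  outer_dir = mirror, inner_face = cx + mirror * 2)
  )
  list(boxes = boxes, gates = gates, margin = margin, cx = cx,
       scene = scene)
}

.is_bulk_state <- function(s) s %in% c("BULK_S", "BULK_L")
.is_channel_state <- function(s) startsWith(s, "CH_")
.is_cavity_state <- function(s) s %in% c("CAV_S", "CAV_L", "QB")

#' Render CTMC paths into an explicit coordinate trajectory
#'
#' Turns exact compartment paths into 3D bead coordinates inside the toy
#' geometry: each ligand's head bead performs a reflected Gaussian random
#' walk confined to its current state's sampling volume (kept a safe
#' margin inside the region so labels are unambiguous). At a state change
#' the head is routed through the shared boundary — a ligand entering a
#' channel appears just beyond the decisive gate and walks in through it,
#' so gate-crossing times are well defined. Five tail beads trail the head
#' along its recent path; ligands rendered tail first lead with the tail
#' instead (the per-ligand orientation is drawn from the seed and reported
#' as ground truth). Four static protein reference beads make the output
#' alignable.
#'
#' @param paths a `qx_ctmcpaths` on the PSII state set.
#' @param model a [toy_psii_geometry()] model.
#' @param monomer which monomer the ligands of `paths` belong to.
#' @param stride_ns frame spacing in ns (default 0.5).
#' @param seed integer seed for the walk noise.
#' @param step_sd_nm random-walk step standard deviation per axis per
#'   frame (default 0.25 nm).
#' @param tails render 5-bead tails (default TRUE).
#' @param p_head_first probability that a ligand is rendered head first
#'   (default 0.5).
#' @return list with `traj` (a `qx_trajectory`), `role_map`
#'   (a `qx_rolemap`) and `truth` (list: `passages`, `flipflops`,
#'   `orientation` per ligand).
#' @export
render_trajectory <- function(paths, model, monomer = 1L, stride_ns = 0.5,
                              seed = 1L, step_sd_nm = 0.25, tails = TRUE,
                              p_head_first = 0.5) {
  stopifnot(inherits(paths, "qx_ctmcpaths"), inherits(model, "qx_geometry"))
  scene <- attr(model, "scene")
  if (is.null(scene)) stop("model lacks scene metadata; use toy_psii_geometry()")
  lay <- .scene_layout(model, monomer)
  for (b in lay$boxes) if (any(b["hi", ] <= b["lo", ]))
    stop("a state region is too small for bead placement at margin ",
         lay$margin)
  t_ns <- seq(0, paths$duration_us * 1e3, by = stride_ns)
  nf <- length(t_ns)
  nl <- length(paths$paths)

  state_idx <- matrix(0L, nf, nl)
  for (i in seq_len(nl))
    state_idx[, i] <- findInterval(t_ns / 1e3, paths$paths[[i]]$times_us)
  state_names <- lapply(paths$paths, `[[`, "states")

  set.seed(.substream_seed(seed, 999983L))
  orientation <- ifelse(stats::runif(nl) < p_head_first,
                        "head_first", "tail_first")

  # per-frame state name matrix and per-state clamp boxes (bulk states use
  # the bounding box of the ring; the footprint push is applied after)
  all_states <- paths$model$states
  state_mat <- matrix(0L, nf, nl)
  for (i in seq_len(nl))
    state_mat[, i] <- match(state_names[[i]], all_states)[state_idx[, i]]
  bb <- .bulk_bounds(lay, monomer)
  m <- lay$margin
  lo_tab <- matrix(NA_real_, length(all_states), 3L,
                   dimnames = list(all_states, NULL))
  hi_tab <- lo_tab
  for (s in all_states) {
    if (.is_bulk_state(s)) {
      zr <- .bulk_zrange(s, m)
      lo_tab[s, ] <- c(bb$outer["lo", 1:2], zr[1])
      hi_tab[s, ] <- c(bb$outer["hi", 1:2], zr[2])
    } else {
      lo_tab[s, ] <- lay$boxes[[s]]["lo", ]
      hi_tab[s, ] <- lay$boxes[[s]]["hi", ]
    }
  }
  is_bulk <- .is_bulk_state(all_states)

  head_xyz <- array(NA_real_, c(nf, nl, 3L))
  pos <- matrix(NA_real_, nl, 3L)
  for (i in seq_len(nl))
    pos[i, ] <- .spawn_in_state(state_names[[i]][state_idx[1L, i]],
                                lay, monomer)
  head_xyz[1L, , ] <- pos
  if (nf > 1L) for (f in 2:nf) {
    st <- state_mat[f, ]
    pos <- pos + matrix(stats::rnorm(nl * 3L, 0, step_sd_nm), nl, 3L)
    pos <- pmin(pmax(pos, lo_tab[st, , drop = FALSE]),
                hi_tab[st, , drop = FALSE])
    blk <- which(is_bulk[st])
    if (length(blk)) pos[blk, ] <- .footprint_push(pos[blk, , drop = FALSE],
                                                   bb$inner, m)
    changed <- which(st != state_mat[f - 1L, ])
    for (i in changed)
      pos[i, ] <- .route_entry(pos[i, ], all_states[state_mat[f - 1L, i]],
                               all_states[st[i]], lay, monomer)
    head_xyz[f, , ] <- pos
  }

  lag <- 2L
  n_tail <- if (tails) 5L else 0L
  nb <- nl * (1L + n_tail) + 4L
  bead_ids <- character(nb)
  coords <- array(NA_real_, c(nf, nb, 3L))
  col <- 0L
  for (i in seq_len(nl)) {
    col <- col + 1L
    bead_ids[col] <- paste0("L", i, "_H")
    coords[, col, ] <- head_xyz[, i, ]
    if (n_tail > 0L) {
      dir <- if (orientation[i] == "head_first") 1L else -1L
      for (tb in seq_len(n_tail)) {
        col <- col + 1L
        bead_ids[col] <- paste0("L", i, "_T", tb)
        src <- pmin(pmax(seq_len(nf) - dir * lag * tb, 1L), nf)
        coords[, col, ] <- head_xyz[src, i, ]
      }
    }
  }
  cx <- lay$cx
  ref_pts <- rbind(c(cx - 3, -3, 1.8), c(cx + 3, -3, 1.8),
                   c(cx + 3, 3, -1.8), c(cx - 3, 3, 1.2))
  for (r in 1:4) {
    col <- col + 1L
    bead_ids[col] <- paste0("REF", r)
    coords[, col, ] <- matrix(ref_pts[r, ], nf, 3L, byrow = TRUE)
  }

  ligs <- lapply(seq_len(nl), function(i)
    list(head_beads = paste0("L", i, "_H"),
         tail_beads = if (n_tail > 0L) paste0("L", i, "_T", seq_len(n_tail))
         else character(0),
         species = paths$model$species[i]))
  names(ligs) <- paste0("L", seq_len(nl))
  rm <- role_map(ligs, paste0("REF", 1:4))
  beads <- .bead_table(bead_ids, rm)
  traj <- structure(list(
    times = t_ns, beads = beads, coords = coords,
    box = matrix(scene$box, nf, 3L, byrow = TRUE),
    metadata = list(source = "render_trajectory", n_frames = nf,
                    aligned = TRUE, seed = seed, monomer = monomer)),
    class = "qx_trajectory")
  truth <- list(passages = ground_truth_passages(paths, monomer),
                flipflops = ground_truth_flipflops(paths),
                orientation = stats::setNames(orientation,
                                              paste0("L", seq_len(nl))))
  list(traj = traj, role_map = rm, truth = truth)
}

.spawn_in_state <- function(state, lay, monomer) {
  if (.is_bulk_state(state)) return(.bulk_point(state, lay, monomer))
  b <- lay$boxes[[state]]
  b["lo", ] + stats::runif(3L) * (b["hi", ] - b["lo", ])
}

.confine <- function(p, state, lay, monomer) {
  if (.is_bulk_state(state)) return(.bulk_confine(p, state, lay, monomer))
  b <- lay$boxes[[state]]
  pmin(pmax(p, b["lo", ]), b["hi", ])
}

# place the head at a state change: channels are entered through the gate
# facing the previous compartment (the point sits just beyond the gate for
# one frame, so the subsequent inward step crosses the gate plane)
.route_entry <- function(p, st_prev, st_new, lay, monomer) {
  gap <- 0.45   # offset beyond the gate face, outside the channel region
  if (.is_bulk_state(st_new)) return(.bulk_confine(p, st_new, lay, monomer))
  q <- .confine(p, st_new, lay, monomer)
  if (.is_channel_state(st_new)) {
    g <- lay$gates[[st_new]]
    if (.is_bulk_state(st_prev))
      q[g$axis] <- g$outer_face + g$outer_dir * gap
    else if (.is_cavity_state(st_prev))
      q[g$axis] <- g$inner_face - g$outer_dir * gap
  } else if (.is_cavity_state(st_new) && .is_channel_state(st_prev)) {
    g <- lay$gates[[st_prev]]
    # come in from the channel's inner gate
    q[g$axis] <- g$inner_face - g$outer_dir * gap
    b <- lay$boxes[[st_prev]]
    other <- setdiff(1:2, g$axis)
    q[other] <- min(max(q[other], b["lo", other]), b["hi", other])
    b2 <- lay$boxes[[st_new]]
    q <- pmin(pmax(q, b2["lo", ]), b2["hi", ])
  }
  q
}

# bulk sampling shell: a ring around the monomer footprint, one leaflet
.bulk_bounds <- function(lay, monomer) {
  cx <- lay$cx
  m <- lay$margin
  list(outer = rbind(lo = c(cx - 9, -9, -2 + m), hi = c(cx + 9, 9, 2 - m)),
       inner = c(cx - 4, cx + 4, -4, 4))
}

.bulk_zrange <- function(state, m) {
  if (state == "BULK_S") c(m, 2 - m) else c(-2 + m, -m)
}

.bulk_point <- function(state, lay, monomer) {
  bb <- .bulk_bounds(lay, monomer)
  zr <- .bulk_zrange(state, lay$margin)
  repeat {
    xy <- bb$outer["lo", 1:2] +
      stats::runif(2L) * (bb$outer["hi", 1:2] - bb$outer["lo", 1:2])
    if (!(xy[1] > bb$inner[1] && xy[1] < bb$inner[2] &&
          xy[2] > bb$inner[3] && xy[2] < bb$inner[4])) break
  }
  c(xy, zr[1] + stats::runif(1L) * (zr[2] - zr[1]))
}

.bulk_confine <- function(p, state, lay, monomer) {
  bb <- .bulk_bounds(lay, monomer)
  zr <- .bulk_zrange(state, lay$margin)
  p[1] <- min(max(p[1], bb$outer["lo", 1]), bb$outer["hi", 1])
  p[2] <- min(max(p[2], bb$outer["lo", 2]), bb$outer["hi", 2])
  p[3] <- min(max(p[3], zr[1]), zr[2])
  drop(.footprint_push(matrix(p, 1L), bb$inner, lay$margin))
}

# push points out of the footprint xy rectangle along the axis of least
# penetration (vectorised)
.footprint_push <- function(p, inn, pad) {
  inside <- p[, 1] > inn[1] & p[, 1] < inn[2] &
    p[, 2] > inn[3] & p[, 2] < inn[4]
  if (!any(inside)) return(p)
  px <- p[inside, 1]; py <- p[inside, 2]
  dx <- pmin(px - inn[1], inn[2] - px)
  dy <- pmin(py - inn[3], inn[4] - py)
  use_x <- dx <= dy
  px[use_x] <- ifelse(px[use_x] - inn[1] <= inn[2] - px[use_x],
                      inn[1] - pad, inn[2] + pad)
  py[!use_x] <- ifelse(py[!use_x] - inn[3] <= inn[4] - py[!use_x],
                       inn[3] - pad, inn[4] + pad)
  p[inside, 1] <- px
  p[inside, 2] <- py
  p
}

#' Write a rendered dataset to disk
#'
#' Writes the tabular trajectory (TSV), the role map (JSON) and the
#' ground-truth passage log (TSV) of a [render_trajectory()] result.
#'
#' @param rendered list returned by [render_trajectory()].
#' @param dir output directory (created if needed).
#' @param prefix file name prefix (default `"synthetic"`).
#' @return named character vector of the written paths.
#' @export
write_rendered <- function(rendered, dir, prefix = "synthetic") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  traj <- rendered$traj
  nf <- length(traj$times); nb <- nrow(traj$beads)
  tab <- data.frame(
    frame_time_ns = rep(traj$times, times = nb),
    bead_id = rep(traj$beads$bead_id, each = nf),
    x_nm = as.vector(traj$coords[, , 1]),
    y_nm = as.vector(traj$coords[, , 2]),
    z_nm = as.vector(traj$coords[, , 3]),
    box_x = rep(traj$box[, 1], times = nb),
    box_y = rep(traj$box[, 2], times = nb),
    box_z = rep(traj$box[, 3], times = nb))
  tab <- tab[order(tab$frame_time_ns, match(tab$bead_id,
                                            traj$beads$bead_id)), ]
  paths <- c(trajectory = file.path(dir, paste0(prefix, "_trajectory.tsv")),
             role_map = file.path(dir, paste0(prefix, "_role_map.json")),
             truth = file.path(dir, paste0(prefix, "_truth_passages.tsv")))
  utils::write.table(tab, paths["trajectory"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rmap <- rendered$role_map
  jsonlite::write_json(
    list(ligands = rmap$ligands, protein_reference = rmap$protein_reference),
    paths["role_map"], auto_unbox = TRUE, digits = NA)
  write_events(rendered$truth$passages, paths["truth"])
  paths
}
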