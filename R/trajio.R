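#' Role map: which beads are ligand heads, tails and protein reference
#'
#' The role map tags the beads the analysis cares about: for every ligand
#' its headgroup beads and (ordered) tail beads plus its species (`PLQ`,
#' oxidized plastoquinone, or `PLQol`, plastoquinol), and the protein beads
#' used to define the protein-fixed reference frame.
#'
#' @param ligands named list: `ligand id -> list(head_beads, tail_beads,
#'   species)`. `tail_beads` may be empty; `species` defaults to `"PLQ"`.
#' @param protein_reference character vector of at least 3 bead ids.
#' @return an object of class `qx_rolemap`.
#' @export
role_map <- function(ligands, protein_reference) {
  stopifnot(is.list(ligands), length(protein_reference) >= 3L)
  for (id in names(ligands)) {
    lg <- ligands[[id]]
    if (length(intersect(lg$head_beads, lg$tail_beads)))
      stop("ligand '", id, "': head and tail bead sets overlap")
    if (!length(lg$head_beads))
      stop("ligand '", id, "': needs at least one head bead")
    ligands[[id]]$species <- if (is.null(lg$species)) "PLQ" else
      match.arg(lg$species, c("PLQ", "PLQol"))
  }
  structure(list(ligands = ligands,
                 protein_reference = as.character(protein_reference)),
            class = "qx_rolemap")
}

#' Read a role map from YAML or JSON
#'
#' @param path file with top-level keys `ligands` and `protein_reference`
#'   mirroring the arguments of [role_map()].
#' @return a `qx_rolemap`.
#' @export
read_role_map <- function(path) {
  if (!file.exists(path)) stop("role map file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  doc <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported role map format: .", ext)
  ligs <- lapply(doc$ligands, function(lg)
    list(head_beads = as.character(unlist(lg$head_beads)),
         tail_beads = as.character(unlist(lg$tail_beads)),
         species = if (is.null(lg$species)) "PLQ" else lg$species))
  role_map(ligs, as.character(unlist(doc$protein_reference)))
}

.rolemap_beads <- function(rm) {
  unique(c(unlist(lapply(rm$ligands, function(l)
    c(l$head_beads, l$tail_beads))), rm$protein_reference))
}

#' Read a trajectory of tagged beads
#'
#' Reads the beads named by the role map from a coordinate trajectory,
#' converts times to ns, and unwraps periodic images per ligand so each
#' ligand's path is continuous between frames (protein beads are assumed
#' whole and are never unwrapped).
#'
#' Supported inputs: the package's tabular TSV format (columns
#' `frame_time_ns`, `bead_id`, `x_nm`, `y_nm`, `z_nm`, `box_x`, `box_y`,
#' `box_z`; one row per bead per frame), or a PDB structure plus DCD
#' trajectory via the bio3d package (bead ids are then `resid_resno_name`;
#' coordinates are converted from Angstrom to nm and times taken from the
#' DCD frame index times `dt_ns`).
#'
#' @param trajectory_path TSV or DCD file.
#' @param role_map a `qx_rolemap` (or path readable by [read_role_map()]).
#' @param structure_path PDB file; required for DCD input.
#' @param dt_ns frame spacing in ns for DCD input (default 0.5, the typical
#'   coarse-grained analysis stride).
#' @param unwrap unwrap ligand paths across periodic boundaries
#'   (default TRUE).
#' @return an object of class `qx_trajectory`: times (ns), a bead table
#'   (`bead_id`, `ligand`, `role`, `species`), a coordinate array
#'   `[frame, bead, xyz]` in nm, per-frame orthorhombic box lengths, and
#'   metadata.
#' @export
read_trajectory <- function(trajectory_path, role_map,
                            structure_path = NULL, dt_ns = 0.5,
                            unwrap = TRUE) {
  if (is.character(role_map)) role_map <- read_role_map(role_map)
  stopifnot(inherits(role_map, "qx_rolemap"))
  ext <- tolower(tools::file_ext(trajectory_path))
  raw <- if (ext %in% c("tsv", "txt", "dat"))
    .read_traj_tsv(trajectory_path)
  else if (ext == "dcd")
    .read_traj_dcd(trajectory_path, structure_path, dt_ns)
  else stop("unsupported trajectory format: .", ext)

  wanted <- .rolemap_beads(role_map)
  missing <- setdiff(wanted, raw$bead_ids)
  if (length(missing))
    stop("role map names beads absent from the trajectory: ",
         paste(missing, collapse = ", "))
  keep <- match(wanted, raw$bead_ids)

  times <- raw$times
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("non-monotonic frame times at frame ",
         which(diff(times) <= 0)[1L] + 1L)

  coords <- raw$coords[, keep, , drop = FALSE]
  beads <- .bead_table(wanted, role_map)
  traj <- structure(list(times = times, beads = beads, coords = coords,
                         box = raw$box,
                         metadata = list(source = trajectory_path,
                                         n_frames = length(times))),
                    class = "qx_trajectory")
  if (unwrap) traj <- .unwrap_ligands(traj)
  traj
}

.bead_table <- function(bead_ids, rm) {
  lig <- rep(NA_character_, length(bead_ids))
  role <- rep("protein", length(bead_ids))
  species <- rep(NA_character_, length(bead_ids))
  for (id in names(rm$ligands)) {
    lg <- rm$ligands[[id]]
    lig[bead_ids %in% c(lg$head_beads, lg$tail_beads)] <- id
    role[bead_ids %in% lg$head_beads] <- "head"
    role[bead_ids %in% lg$tail_beads] <- "tail"
    species[bead_ids %in% c(lg$head_beads, lg$tail_beads)] <- lg$species
  }
  data.frame(bead_id = bead_ids, ligand = lig, role = role,
             species = species, stringsAsFactors = FALSE)
}

.read_traj_tsv <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("frame_time_ns", "bead_id", "x_nm", "y_nm", "z_nm",
            "box_x", "box_y", "box_z")
  if (!all(need %in% names(tab)))
    stop("tabular trajectory lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  times <- unique(tab$frame_time_ns)   # in file order
  bead_ids <- unique(tab$bead_id)
  fidx <- match(tab$frame_time_ns, times)
  bidx <- match(tab$bead_id, bead_ids)
  nf <- length(times); nb <- length(bead_ids)
  if (nrow(tab) != nf * nb || anyDuplicated(fidx * (nb + 1L) + bidx))
    stop("tabular trajectory: bead set is not constant across frames")
  coords <- array(NA_real_, c(nf, nb, 3L))
  lin <- cbind(fidx, bidx)
  coords[cbind(lin, 1L)] <- tab$x_nm
  coords[cbind(lin, 2L)] <- tab$y_nm
  coords[cbind(lin, 3L)] <- tab$z_nm
  box <- matrix(NA_real_, nf, 3L)
  first <- !duplicated(fidx)
  box[fidx[first], ] <- cbind(tab$box_x, tab$box_y, tab$box_z)[first, ]
  if (any(!is.finite(coords))) stop("non-finite coordinates in trajectory")
  if (any(box <= 0)) stop("non-positive box edge lengths")
  list(times = times, bead_ids = bead_ids, coords = coords, box = box)
}

.read_traj_dcd <- function(path, structure_path, dt_ns) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("DCD input requires the bio3d package")
  if (is.null(structure_path)) stop("DCD input requires a PDB structure")
  pdb <- bio3d::read.pdb(structure_path)
  dcd <- bio3d::read.dcd(path, verbose = FALSE)
  at <- pdb$atom
  bead_ids <- paste(at$resid, at$resno, at$elety, sep = "_")
  nf <- nrow(dcd)
  coords <- array(NA_real_, c(nf, length(bead_ids), 3L))
  for (k in 1:3) coords[, , k] <- dcd[, seq(k, ncol(dcd), by = 3L)] / 10
  cell <- attr(dcd, "cell")
  box <- if (!is.null(cell)) as.matrix(cell[, 1:3, drop = FALSE]) / 10
  else matrix(rep(apply(coords, 3L, function(m) diff(range(m))), each = nf),
              nf, 3L)
  list(times = (seq_len(nf) - 1) * dt_ns, bead_ids = bead_ids,
       coords = coords, box = box)
}

# per-ligand unwrapping: make each ligand whole within every frame relative
# to its first bead, then remove inter-frame box jumps of the ligand centroid
.unwrap_ligands <- function(traj) {
  nf <- length(traj$times)
  if (nf < 2L) return(traj)
  for (id in stats::na.omit(unique(traj$beads$ligand))) {
    sel <- which(traj$beads$ligand == id)
    xyz <- traj$coords[, sel, , drop = FALSE]
    for (k in 1:3) {
      bx <- traj$box[, k]
      ref <- xyz[, 1L, k]
      # make whole within frame
      if (length(sel) > 1L)
        for (b in 2:length(sel))
          xyz[, b, k] <- xyz[, b, k] - bx * round((xyz[, b, k] - ref) / bx)
      # unwrap centroid across frames
      ctr <- rowMeans(xyz[, , k, drop = FALSE])
      jump <- round(diff(ctr) / bx[-1L])
      shift <- c(0, cumsum(jump * bx[-1L]))
      xyz[, , k] <- xyz[, , k] - shift
    }
    traj$coords[, sel, ] <- xyz
  }
  traj$metadata$unwrapped <- TRUE
  traj
}

#' Rewrap coordinates into the primary box
#'
#' Inverse of the unwrapping applied by [read_trajectory()]: wraps every
#' coordinate back into `[0, box)` per axis.
#'
#' @param traj a `qx_trajectory`.
#' @return a `qx_trajectory` with wrapped coordinates.
#' @export
rewrap <- function(traj) {
  stopifnot(inherits(traj, "qx_trajectory"))
  for (k in 1:3)
    traj$coords[, , k] <- traj$coords[, , k] -
      traj$box[, k] * floor(traj$coords[, , k] / traj$box[, k])
  traj
}

#' Rigid-body alignment onto a reference
#'
#' Superposes every frame onto reference coordinates of the protein
#' reference beads by least squares (Kabsch rotation + translation) and
#' applies the transformation to all beads, putting the whole trajectory in
#' a protein-fixed reference frame. Required before region labelling and
#' density accumulation.
#'
#' @param traj a `qx_trajectory`.
#' @param reference_positions numeric matrix (n_ref x 3), one row per
#'   protein-reference bead (rows match `ref_beads`).
#' @param ref_beads bead ids used for the fit; default: all beads with role
#'   `"protein"` in the bead table, in table order.
#' @return the aligned `qx_trajectory`.
#' @export
align_frames <- function(traj, reference_positions,
                         ref_beads = traj$beads$bead_id[
                           traj$beads$role == "protein"]) {
  stopifnot(inherits(traj, "qx_trajectory"))
  reference_positions <- .as_points(reference_positions)
  if (length(ref_beads) < 3L)
    stop("alignment needs at least 3 reference beads")
  if (nrow(reference_positions) != length(ref_beads))
    stop("reference_positions must have one row per reference bead")
  idx <- match(ref_beads, traj$beads$bead_id)
  if (anyNA(idx)) stop("reference beads absent from trajectory: ",
                       paste(ref_beads[is.na(idx)], collapse = ", "))
  refc <- colMeans(reference_positions)
  ref0 <- sweep(reference_positions, 2L, refc)
  if (min(svd(ref0)$d[1:2]) < 1e-9)
    stop("reference beads are collinear; cannot define a frame")
  for (f in seq_along(traj$times)) {
    mob <- traj$coords[f, idx, , drop = TRUE]
    mobc <- colMeans(mob)
    R <- .kabsch(sweep(mob, 2L, mobc), ref0)
    all_xyz <- traj$coords[f, , , drop = TRUE]
    traj$coords[f, , ] <- sweep(sweep(all_xyz, 2L, mobc) %*% R, 2L, refc, `+`)
  }
  traj$metadata$aligned <- TRUE
  traj
}

# optimal rotation matrix mapping centred mobile onto centred reference
.kabsch <- function(mob0, ref0) {
  H <- t(mob0) %*% ref0
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Discard equilibration frames
#'
#' Removes all frames with time below `t_eq`. The default matches the
#' convention of discarding the first microsecond of each replicate as
#' equilibration.
#'
#' @param traj a `qx_trajectory`.
#' @param t_eq equilibration time in ns (default 1000 ns = 1 us).
#' @return the trimmed `qx_trajectory`; metadata records the trimmed
#'   duration.
#' @export
discard_equilibration <- function(traj, t_eq = 1000) {
  stopifnot(inherits(traj, "qx_trajectory"), t_eq >= 0)
  keep <- traj$times >= t_eq
  if (!any(keep))
    stop("t_eq = ", t_eq, " ns removes all ", length(traj$times), " frames")
  trimmed <- if (any(!keep)) max(traj$times[!keep]) - min(traj$times) else 0
  traj$times <- traj$times[keep]
  traj$coords <- traj$coords[keep, , , drop = FALSE]
  traj$box <- traj$box[keep, , drop = FALSE]
  traj$metadata$equilibration_trimmed_ns <- trimmed
  traj$metadata$n_frames <- length(traj$times)
  traj
}

# centroid time series (frames x 3) of a set of beads
.centroid_series <- function(traj, bead_ids) {
  idx <- match(bead_ids, traj$beads$bead_id)
  if (anyNA(idx)) stop("unknown beads: ",
                       paste(bead_ids[is.na(idx)], collapse = ", "))
  if (length(idx) == 1L) return(traj$coords[, idx, , drop = TRUE])
  apply(traj$coords[, idx, , drop = FALSE], c(1L, 3L), mean)
}

#' @export
print.qx_trajectory <- function(x, ...) {
  cat("Trajectory:", length(x$times), "frames,",
      nrow(x$beads), "beads,",
      sum(!is.na(unique(x$beads$ligand))), "ligand(s)\n")
  if (length(x$times))
    cat("  time", min(x$times), "-", max(x$times), "ns\n")
  invisible(x)
}

#' @export
print.qx_rolemap <- function(x, ...) {
  sp <- vapply(x$ligands, `[[`, character(1L), "species")
  cat("Role map:", length(x$ligands), "ligand(s) (",
      sum(sp == "PLQ"), "PLQ,", sum(sp == "PLQol"), "PLQol ),",
      length(x$protein_reference), "protein reference beads\n")
  invisible(x)
}
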