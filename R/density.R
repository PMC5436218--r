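#' Accumulate a 3D occupancy density grid
#'
#' Bins selected bead positions from an aligned trajectory into an
#' axis-aligned voxel grid of raw counts: each selected bead in each frame
#' increments the voxel containing it. Counts stay integers so grids from
#' replicate simulations merge exactly; normalisation (counts per frame) is
#' applied only at export. Observations outside the grid are counted
#' separately.
#'
#' @param traj an aligned `qx_trajectory`, or a numeric matrix (n x 3) of
#'   positions in nm.
#' @param origin length-3 numeric, grid origin (lower corner) in nm.
#' @param extent length-3 numeric, grid edge lengths in nm (> 0).
#' @param voxel_nm voxel edge length in nm (default 0.1).
#' @param selection which beads to bin when `traj` is a trajectory: a role
#'   (`"head"`, `"tail"`) or a character vector of bead ids. Default
#'   `"head"`, the headgroup beads.
#' @param species restrict to ligands of one species (default: all).
#' @return an object of class `qx_density` with the integer count array,
#'   grid metadata, `n_frames` and the out-of-bounds count.
#' @export
accumulate_density <- function(traj, origin, extent, voxel_nm = 0.1,
                               selection = "head", species = NULL) {
  if (any(extent <= 0)) stop("zero-size extent")
  if (voxel_nm <= 0) stop("voxel edge must be > 0")
  origin <- as.numeric(origin); extent <- as.numeric(extent)
  dims <- pmax(1L, as.integer(ceiling(extent / voxel_nm - 1e-9)))
  if (inherits(traj, "qx_trajectory")) {
    sel <- if (all(selection %in% c("head", "tail", "protein")))
      traj$beads$role %in% selection else traj$beads$bead_id %in% selection
    if (!is.null(species)) sel <- sel & traj$beads$species %in% species
    if (!any(sel)) stop("bead selection is empty")
    nb <- sum(sel)
    nf <- length(traj$times)
    pts <- matrix(aperm(traj$coords[, sel, , drop = FALSE], c(1L, 2L, 3L)),
                  nf * nb, 3L)
    descriptor <- paste0(paste(selection, collapse = "+"),
                         if (!is.null(species))
                           paste0(" (", paste(species, collapse = "+"), ")"))
  } else {
    pts <- .as_points(traj)
    nf <- nrow(pts); nb <- 1L
    descriptor <- "points"
  }
  idx <- floor(sweep(sweep(pts, 2L, origin), 2L, voxel_nm, `/`))
  inb <- idx[, 1] >= 0 & idx[, 1] < dims[1] &
    idx[, 2] >= 0 & idx[, 2] < dims[2] &
    idx[, 3] >= 0 & idx[, 3] < dims[3]
  lin <- idx[inb, 1] + dims[1] * (idx[inb, 2] + dims[2] * idx[inb, 3]) + 1
  counts <- array(tabulate(lin, nbins = prod(dims)), dims)
  structure(list(origin = origin, voxel_nm = voxel_nm, dim = dims,
                 counts = counts, n_frames = nf,
                 n_selected_beads = nb,
                 out_of_bounds = sum(!inb), selection = descriptor),
            class = "qx_density")
}

#' Merge density grids
#'
#' Sums the counts, frame counts and out-of-bounds counters of grids with
#' identical origin, voxel size and dimensions — used to combine replicate
#' simulations into one map.
#'
#' @param grids list of `qx_density` objects.
#' @return a merged `qx_density`.
#' @export
merge_grids <- function(grids) {
  stopifnot(length(grids) >= 1L)
  g0 <- grids[[1L]]
  for (g in grids[-1L]) {
    if (!isTRUE(all.equal(g$origin, g0$origin)) ||
        !isTRUE(all.equal(g$voxel_nm, g0$voxel_nm)) ||
        !identical(g$dim, g0$dim))
      stop("grids have mismatched origin/voxel/dimensions")
    g0$counts <- g0$counts + g$counts
    g0$n_frames <- g0$n_frames + g$n_frames
    g0$out_of_bounds <- g0$out_of_bounds + g$out_of_bounds
  }
  g0
}

#' Threshold a grid and project it
#'
#' Retains voxels with counts at or above `level` (zero-count voxels are
#' never retained), computes a maximum-intensity projection of the retained
#' voxels along one axis, and counts the 26-connected components of the
#' retained set — useful for asking at which threshold the channel paths
#' remain connected to the cavity density.
#'
#' @param grid a `qx_density`.
#' @param level threshold (>= 0), in raw counts.
#' @param axis projection axis, `"x"`, `"y"` or `"z"` (default `"z"`, the
#'   membrane normal, giving the stromal view).
#' @return list with `map` (2D matrix, maximum counts), `n_components`,
#'   and `n_retained` (number of retained voxels).
#' @export
threshold_and_project <- function(grid, level, axis = "z") {
  stopifnot(inherits(grid, "qx_density"), level >= 0)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  mask <- grid$counts >= level & grid$counts > 0
  kept <- grid$counts * mask
  map <- apply(kept, setdiff(1:3, ax), max)
  list(map = map, n_components = .components26(mask),
       n_retained = sum(mask))
}

# number of 26-connected components of a logical 3D array (BFS flood fill)
.components26 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(abs(nbr)) > 0, , drop = FALSE]
  ncomp <- 0L
  todo <- which(mask & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    queue <- start
    lab[start] <- ncomp
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      z <- (v - 1L) %/% (d[1] * d[2])
      rem <- (v - 1L) %% (d[1] * d[2])
      y <- rem %/% d[1]; x <- rem %% d[1]
      nx <- x + nbr[, 1]; ny <- y + nbr[, 2]; nz <- z + nbr[, 3]
      okn <- nx >= 0 & nx < d[1] & ny >= 0 & ny < d[2] & nz >= 0 & nz < d[3]
      cand <- nx[okn] + d[1] * (ny[okn] + d[2] * nz[okn]) + 1L
      cand <- cand[mask[cand] & lab[cand] == 0L]
      if (length(cand)) {
        lab[cand] <- ncomp
        queue <- c(queue, cand)
      }
    }
  }
  ncomp
}

#' Export a density grid in OpenDX format
#'
#' Writes the grid as an OpenDX scalar field readable by common molecular
#' viewers. Values are counts per frame (occupancy) unless
#' `normalize = FALSE`.
#'
#' @param grid a `qx_density`.
#' @param path output `.dx` file.
#' @param normalize divide counts by `n_frames` (default TRUE).
#' @return `path`, invisibly.
#' @export
write_opendx <- function(grid, path, normalize = TRUE) {
  stopifnot(inherits(grid, "qx_density"))
  d <- grid$dim
  vals <- as.numeric(grid$counts)
  if (normalize && grid$n_frames > 0) vals <- vals / grid$n_frames
  # OpenDX expects the last index (z) to vary fastest
  vals <- as.numeric(aperm(array(vals, d), c(3L, 2L, 1L)))
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("object 1 class gridpositions counts ", d[1], " ", d[2], " ", d[3])
  wl("origin ", paste(format(grid$origin + grid$voxel_nm / 2), collapse = " "))
  wl("delta ", grid$voxel_nm, " 0 0")
  wl("delta 0 ", grid$voxel_nm, " 0")
  wl("delta 0 0 ", grid$voxel_nm)
  wl("object 2 class gridconnections counts ", d[1], " ", d[2], " ", d[3])
  wl("object 3 class array type double rank 0 items ", prod(d),
     " data follows")
  # vals were re-ordered so x varies slowest: emit in x-major order
  full <- c(vals, rep(NA_real_, (3 - length(vals) %% 3) %% 3))
  m <- matrix(full, ncol = 3L, byrow = TRUE)
  apply(m, 1L, function(r)
    wl(paste(format(r[!is.na(r)], scientific = TRUE), collapse = " ")))
  wl('attribute "dep" string "positions"')
  wl('object "density" class field')
  wl('component "positions" value 1')
  wl('component "connections" value 2')
  wl('component "data" value 3')
  invisible(path)
}

#' Write a 2D projection as TSV
#'
#' @param map matrix from [threshold_and_project()].
#' @param path output TSV.
#' @export
write_projection <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.qx_density <- function(x, ...) {
  cat("Density grid:", paste(x$dim, collapse = " x "), "voxels of",
      x$voxel_nm, "nm;", sum(x$counts), "in-bounds observations over",
      x$n_frames, "frames (", x$out_of_bounds, "out of bounds );",
      "selection:", x$selection, "\n")
  invisible(x)
}
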