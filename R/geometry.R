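#' Region constructors
#'
#' Regions are the geometric vocabulary of the analysis: the membrane slab,
#' the exchange cavities, the channel interiors and the binding-site spheres
#' are all regions in a protein-fixed reference frame (nm, membrane normal
#' along +z with the stromal side positive).
#'
#' Three shapes are supported: a z-slab (infinite in xy), a prism (a convex
#' polygon in xy extruded between two z planes) and a union of spheres.
#'
#' @param label character label for the region.
#' @param z_lo,z_hi lower/upper z bound in nm (`z_lo < z_hi`).
#' @param poly numeric matrix (n x 2) of polygon vertices in xy, in order;
#'   must be convex with at least 3 vertices.
#' @param centers numeric matrix (n x 3) of sphere centres in nm.
#' @param radii numeric vector of sphere radii in nm (> 0).
#' @return an object of class `qx_region`.
#' @export
region_zslab <- function(label, z_lo, z_hi) {
  stopifnot(is.character(label), length(label) == 1L)
  if (!is.finite(z_lo) || !is.finite(z_hi) || z_lo >= z_hi)
    stop("region '", label, "': need z_lo < z_hi")
  structure(list(label = label, shape = "zslab", z_lo = z_lo, z_hi = z_hi),
            class = "qx_region")
}

#' @rdname region_zslab
#' @export
region_prism <- function(label, poly, z_lo, z_hi) {
  stopifnot(is.character(label), length(label) == 1L)
  poly <- as.matrix(poly)
  if (ncol(poly) != 2L || nrow(poly) < 3L)
    stop("region '", label, "': polygon needs >= 3 xy vertices")
  if (!is.finite(z_lo) || !is.finite(z_hi) || z_lo >= z_hi)
    stop("region '", label, "': need z_lo < z_hi")
  if (!.poly_is_convex(poly))
    stop("region '", label, "': polygon is not convex")
  # store counter-clockwise so inward edge normals are consistent
  if (.poly_signed_area(poly) < 0) poly <- poly[rev(seq_len(nrow(poly))), , drop = FALSE]
  structure(list(label = label, shape = "prism", poly = poly,
                 z_lo = z_lo, z_hi = z_hi),
            class = "qx_region")
}

#' @rdname region_zslab
#' @export
region_spheres <- function(label, centers, radii) {
  stopifnot(is.character(label), length(label) == 1L)
  centers <- matrix(as.numeric(centers), ncol = 3L)
  radii <- as.numeric(radii)
  if (nrow(centers) != length(radii) || any(radii <= 0))
    stop("region '", label, "': need one radius > 0 per centre")
  structure(list(label = label, shape = "spheres", centers = centers,
                 radii = radii),
            class = "qx_region")
}

.poly_signed_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.poly_is_convex <- function(poly) {
  n <- nrow(poly)
  if (n == 3L) return(TRUE)
  i <- seq_len(n); j <- c(i[-1], 1L); k <- c(j[-1], 1L)
  e1 <- poly[j, , drop = FALSE] - poly[i, , drop = FALSE]
  e2 <- poly[k, , drop = FALSE] - poly[j, , drop = FALSE]
  cross <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  cross <- cross[abs(cross) > 1e-12]
  length(cross) == 0L || all(cross > 0) || all(cross < 0)
}

#' Signed inward depth of points in a region
#'
#' Positive values are distances from the point to the nearest boundary,
#' measured inside the region; negative values are (minus) the Euclidean
#' distance from the point to the region. The zero level set is the
#' boundary. This depth drives the hysteresis rule in [label_trace()].
#'
#' @param region a `qx_region`.
#' @param pts numeric matrix (n x 3) of points in nm.
#' @return numeric vector of signed depths in nm.
#' @export
region_depth <- function(region, pts) {
  pts <- .as_points(pts)
  switch(region$shape,
    zslab = pmin(pts[, 3] - region$z_lo, region$z_hi - pts[, 3]),
    prism = {
      dxy <- .poly_signed_depth(region$poly, pts[, 1:2, drop = FALSE])
      dz <- pmin(pts[, 3] - region$z_lo, region$z_hi - pts[, 3])
      inside <- dxy >= 0 & dz >= 0
      out <- sqrt(pmax(-dxy, 0)^2 + pmax(-dz, 0)^2)
      ifelse(inside, pmin(dxy, dz), -out)
    },
    spheres = {
      d <- rep(-Inf, nrow(pts))
      for (i in seq_along(region$radii)) {
        di <- region$radii[i] -
          sqrt(colSums((t(pts) - region$centers[i, ])^2))
        d <- pmax(d, di)
      }
      d
    },
    stop("unknown region shape: ", region$shape))
}

# signed depth of 2D points w.r.t. a convex CCW polygon:
# inside -> min distance to an edge line; outside -> -distance to the polygon
.poly_signed_depth <- function(poly, xy) {
  n <- nrow(poly)
  npts <- nrow(xy)
  edge_d <- matrix(0, npts, n)   # signed distance to each edge line (inward > 0)
  seg_d <- matrix(0, npts, n)    # unsigned distance to each edge segment
  for (e in seq_len(n)) {
    a <- poly[e, ]; b <- poly[if (e == n) 1L else e + 1L, ]
    ab <- b - a; len <- sqrt(sum(ab^2))
    # inward normal of a CCW polygon edge
    nrm <- c(-ab[2], ab[1]) / len
    rel1 <- xy[, 1] - a[1]; rel2 <- xy[, 2] - a[2]
    edge_d[, e] <- rel1 * nrm[1] + rel2 * nrm[2]
    t <- pmin(pmax((rel1 * ab[1] + rel2 * ab[2]) / len^2, 0), 1)
    seg_d[, e] <- sqrt((rel1 - t * ab[1])^2 + (rel2 - t * ab[2])^2)
  }
  inside_depth <- apply(edge_d, 1L, min)
  out_dist <- apply(seg_d, 1L, min)
  ifelse(inside_depth >= 0, inside_depth, -out_dist)
}

#' @rdname region_depth
#' @export
region_contains <- function(region, pts) {
  pts <- .as_points(pts)
  switch(region$shape,
    zslab = pts[, 3] >= region$z_lo & pts[, 3] <= region$z_hi,
    prism = {
      ok <- pts[, 3] >= region$z_lo & pts[, 3] <= region$z_hi
      poly <- region$poly
      n <- nrow(poly)
      for (e in seq_len(n)) {
        if (!any(ok)) break
        a <- poly[e, ]; b <- poly[if (e == n) 1L else e + 1L, ]
        # inward side of a CCW edge
        ok <- ok & ((pts[, 1] - a[1]) * (a[2] - b[2]) +
                      (pts[, 2] - a[2]) * (b[1] - a[1])) >= 0
      }
      ok
    },
    spheres = {
      hit <- rep(FALSE, nrow(pts))
      for (i in seq_along(region$radii))
        hit <- hit | colSums((t(pts) - region$centers[i, ])^2) <=
          region$radii[i]^2
      hit
    },
    stop("unknown region shape: ", region$shape))
}

.as_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3L, byrow = TRUE)
  storage.mode(pts) <- "double"
  if (ncol(pts) != 3L) stop("points must be n x 3")
  pts
}

#' Channel specification
#'
#' A channel is a prism-shaped interior with two oriented planar gates:
#' the inner gate faces the exchange cavity and the outer gate faces the
#' bulk membrane. Gate normals point out of the channel interior, so the
#' positive side of the inner gate is the cavity and the positive side of
#' the outer gate is the bulk.
#'
#' @param label channel label, e.g. `"I"`, `"II"`, `"III"`.
#' @param monomer integer monomer id.
#' @param interior a prism `qx_region` for the channel interior.
#' @param inner_gate,outer_gate lists with elements `point` (length-3) and
#'   `normal` (length-3, need not be unit length).
#' @return an object of class `qx_channel`.
#' @export
channel_spec <- function(label, monomer, interior, inner_gate, outer_gate) {
  stopifnot(inherits(interior, "qx_region"), interior$shape == "prism")
  gates <- list(inner = .norm_gate(inner_gate), outer = .norm_gate(outer_gate))
  verts <- .prism_vertices(interior)
  for (g in names(gates)) {
    s <- .plane_side(gates[[g]], verts)
    if (all(s > 1e-9) || all(s < -1e-9))
      stop("channel '", label, "': ", g, " gate does not intersect the interior")
    ctr <- colMeans(verts)
    if (.plane_side(gates[[g]], matrix(ctr, 1L)) > 0)
      stop("channel '", label, "': ", g, " gate normal points into the interior")
  }
  structure(list(label = label, monomer = as.integer(monomer),
                 interior = interior, inner_gate = gates$inner,
                 outer_gate = gates$outer),
            class = "qx_channel")
}

.norm_gate <- function(g) {
  stopifnot(is.list(g), length(g$point) == 3L, length(g$normal) == 3L)
  n <- as.numeric(g$normal); n <- n / sqrt(sum(n^2))
  list(point = as.numeric(g$point), normal = n)
}

.prism_vertices <- function(region) {
  p <- region$poly
  rbind(cbind(p, region$z_lo), cbind(p, region$z_hi))
}

# signed distance of points to a gate plane (positive on the normal side)
.plane_side <- function(gate, pts) {
  pts <- .as_points(pts)
  (pts[, 1] - gate$point[1]) * gate$normal[1] +
    (pts[, 2] - gate$point[2]) * gate$normal[2] +
    (pts[, 3] - gate$point[3]) * gate$normal[3]
}

#' Build a validated geometry model
#'
#' Assembles the membrane slab, per-monomer exchange cavity, binding-site
#' sphere and channels (plus an optional protein footprint excluded from the
#' bulk label) into a single model used by [locate()], [label_trace()] and
#' the statistics layer.
#'
#' @param config a list (or a path to a YAML/JSON file, see
#'   [read_geometry()]) with elements:
#'   \describe{
#'     \item{slab}{`list(z_lo, z_hi)`, membrane slab bounds in nm; the
#'       midplane defaults to their mean and can be overridden with `z0`.}
#'     \item{monomers}{a list; each element has `id`, `cavity` (prism spec:
#'       `poly`, `z_lo`, `z_hi`, optional `mid_z`), optional `site`
#'       (`center`, `radius`), and `channels`, a list of channel specs
#'       (`label`, `interior` prism spec, `inner_gate`, `outer_gate`).}
#'     \item{footprint}{optional prism spec for the protein cross-section,
#'       labelled `PROTEIN` instead of `BULK` by [locate()].}
#'   }
#' @return an object of class `qx_geometry`.
#' @export
build_geometry <- function(config) {
  if (is.character(config)) config <- read_geometry(config)
  if (is.null(config$slab)) stop("geometry config: missing 'slab'")
  slab <- region_zslab("SLAB", config$slab$z_lo, config$slab$z_hi)
  z0 <- if (!is.null(config$slab$z0)) config$slab$z0 else
    (slab$z_lo + slab$z_hi) / 2
  if (is.null(config$monomers) || !length(config$monomers))
    stop("geometry config: need at least one monomer")

  monomers <- lapply(config$monomers, function(m) {
    id <- as.integer(m$id)
    cav <- region_prism(paste0("CAVITY.", id),
                        .vertex_matrix(m$cavity$poly),
                        m$cavity$z_lo, m$cavity$z_hi)
    cav_mid <- if (!is.null(m$cavity$mid_z)) m$cavity$mid_z else
      (m$cavity$z_lo + m$cavity$z_hi) / 2
    site <- NULL
    if (!is.null(m$site))
      site <- region_spheres(paste0("SITE.", id),
                             matrix(as.numeric(m$site$center), 1L),
                             m$site$radius)
    channels <- lapply(m$channels, function(ch) {
      interior <- region_prism(paste0("CHANNEL_", ch$label, ".", id),
                               .vertex_matrix(ch$interior$poly),
                               ch$interior$z_lo, ch$interior$z_hi)
      channel_spec(ch$label, id, interior, ch$inner_gate, ch$outer_gate)
    })
    for (ch in channels) {
      d <- abs(region_depth(cav, matrix(ch$inner_gate$point, 1L)))
      if (d > 1e-6)
        stop("channel '", ch$label, "' of monomer ", id,
             ": inner gate is not on the cavity boundary")
    }
    list(id = id, cavity = cav, cavity_mid = cav_mid, site = site,
         channels = channels)
  })

  ids <- vapply(monomers, `[[`, integer(1L), "id")
  if (anyDuplicated(ids)) stop("geometry config: duplicate monomer ids")
  if (length(monomers) > 1L) {
    for (i in seq_along(monomers)[-1L]) for (j in seq_len(i - 1L)) {
      if (.prisms_overlap(monomers[[i]]$cavity, monomers[[j]]$cavity))
        stop("cavities of monomers ", ids[j], " and ", ids[i], " overlap")
    }
  }

  footprint <- NULL
  if (!is.null(config$footprint))
    footprint <- region_prism("PROTEIN", .vertex_matrix(config$footprint$poly),
                              config$footprint$z_lo, config$footprint$z_hi)

  structure(list(slab = slab, z0 = z0, monomers = monomers,
                 footprint = footprint),
            class = "qx_geometry")
}

.vertex_matrix <- function(v) {
  if (is.matrix(v)) return(v)
  matrix(unlist(v), ncol = 2L, byrow = TRUE)
}

# convex polygon overlap via the separating axis theorem (same z assumed
# relevant only if z ranges intersect)
.prisms_overlap <- function(a, b) {
  if (a$z_hi <= b$z_lo || b$z_hi <= a$z_lo) return(FALSE)
  .convex_overlap(a$poly, b$poly)
}

.convex_overlap <- function(p, q) {
  axes <- function(poly) {
    n <- nrow(poly)
    e <- poly[c(seq_len(n)[-1], 1L), , drop = FALSE] - poly
    cbind(-e[, 2], e[, 1])
  }
  for (ax in list(axes(p), axes(q))) for (i in seq_len(nrow(ax))) {
    a <- ax[i, ]
    pp <- p %*% a; qq <- q %*% a
    if (max(pp) <= min(qq) || max(qq) <= min(pp)) return(FALSE)
  }
  TRUE
}

#' Read a geometry configuration file
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON (`.json`) file mirroring the
#'   `config` structure of [build_geometry()].
#' @return the parsed configuration list.
#' @export
read_geometry <- function(path) {
  if (!file.exists(path)) stop("geometry file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported geometry format: .", ext)
}

#' Locate points in the geometry model
#'
#' Assigns each point the highest-priority containing label, with the fixed
#' priority channel > cavity > binding-site sphere > protein footprint >
#' membrane slab (`BULK`) > off-membrane (`OFF`). The priority rule makes
#' labels at gate boundaries deterministic: a point inside both a channel
#' interior and the cavity margin is labelled with the channel.
#'
#' @param pts numeric matrix (n x 3) of reference-frame coordinates in nm
#'   (a length-3 vector is accepted for a single point).
#' @param model a `qx_geometry`.
#' @return character vector of labels: `"CHANNEL_<lab>.<monomer>"`,
#'   `"CAVITY.<monomer>"`, `"SITE.<monomer>"`, `"PROTEIN"`, `"BULK"` or
#'   `"OFF"`.
#' @export
locate <- function(pts, model) {
  stopifnot(inherits(model, "qx_geometry"))
  pts <- .as_points(pts)
  lab <- rep(NA_character_, nrow(pts))
  assign_in <- function(region) {
    todo <- is.na(lab)
    if (!any(todo)) return()
    hit <- region_contains(region, pts[todo, , drop = FALSE])
    lab[which(todo)[hit]] <<- region$label
  }
  for (m in model$monomers) for (ch in m$channels) assign_in(ch$interior)
  for (m in model$monomers) assign_in(m$cavity)
  for (m in model$monomers) if (!is.null(m$site)) assign_in(m$site)
  if (!is.null(model$footprint)) assign_in(model$footprint)
  assign_in(model$slab)  # labels remaining slab points "SLAB"
  lab[lab == "SLAB"] <- "BULK"
  lab[is.na(lab)] <- "OFF"
  lab
}

#' Channel cross-section from lining beads
#'
#' Measures the opening of a channel in one frame from two opposing groups
#' of channel-lining beads: the width is the minimum distance between the
#' two groups, and the height is the z extent of the opening (both groups
#' pooled) clipped to the membrane slab.
#'
#' @param group_a,group_b numeric matrices (n x 3) of bead coordinates in nm
#'   for the two opposing channel walls.
#' @param slab a `qx_region` z-slab (or a `qx_geometry`, whose slab is used).
#' @return named numeric vector `c(width_nm, height_nm)`.
#' @export
channel_cross_section <- function(group_a, group_b, slab) {
  if (inherits(slab, "qx_geometry")) slab <- slab$slab
  a <- .as_points(group_a); b <- .as_points(group_b)
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty lining group")
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  width <- sqrt(max(min(d2), 0))
  z <- c(a[, 3], b[, 3])
  height <- max(0, min(max(z), slab$z_hi) - max(min(z), slab$z_lo))
  c(width_nm = width, height_nm = height)
}

#' Leaflet assignment
#'
#' Assigns a headgroup position to the stromal (upper, z above the midplane)
#' or lumenal (lower) leaflet of the named compartment. The membrane slab
#' uses the global midplane `z0`; a cavity may override it with its own
#' mid-z. Points exactly on the midplane are assigned to the lumenal leaflet
#' (fixed, documented tie-break).
#'
#' @param pts points (n x 3) or a numeric vector of z coordinates when
#'   `region_label` is given and `z_only = TRUE`.
#' @param model a `qx_geometry`.
#' @param region_label `"BULK"` or `"CAVITY.<monomer>"`; which compartment's
#'   midplane to use.
#' @return character vector, `"stromal"` or `"lumenal"`.
#' @export
leaflet_of <- function(pts, model, region_label = "BULK") {
  stopifnot(inherits(model, "qx_geometry"))
  pts <- .as_points(pts)
  if (region_label == "BULK") {
    mid <- model$z0
    ok <- region_contains(model$slab, pts)
  } else {
    m <- .monomer_of(model, region_label)
    mid <- m$cavity_mid
    ok <- region_contains(m$cavity, pts)
    if (!is.null(m$site)) ok <- ok | region_contains(m$site, pts)
  }
  if (!all(ok)) stop("point outside ", region_label, " and slab: ",
                     paste(which(!ok), collapse = ", "))
  ifelse(pts[, 3] > mid, "stromal", "lumenal")
}

.monomer_of <- function(model, label) {
  id <- as.integer(sub("^.*\\.", "", label))
  for (m in model$monomers) if (m$id == id) return(m)
  stop("no monomer ", id, " in geometry model")
}

# side classification used by passage detection: which membrane compartment
# a label belongs to. SITE is inside the cavity compartment; PROTEIN and OFF
# count as the bulk side (a ligand should not dwell there).
.label_side <- function(labels) {
  side <- rep("bulk", length(labels))
  side[startsWith(labels, "CAVITY.") | startsWith(labels, "SITE.")] <- "cavity"
  side[startsWith(labels, "CHANNEL_")] <- "channel"
  side
}

.label_monomer <- function(labels) {
  out <- rep(NA_integer_, length(labels))
  has <- grepl("\\.", labels)
  out[has] <- as.integer(sub("^.*\\.", "", labels[has]))
  out
}

.label_channel <- function(labels) {
  out <- rep(NA_character_, length(labels))
  is_ch <- startsWith(labels, "CHANNEL_")
  out[is_ch] <- sub("\\..*$", "", sub("^CHANNEL_", "", labels[is_ch]))
  out
}

#' @export
print.qx_geometry <- function(x, ...) {
  cat("Geometry model: slab z [", x$slab$z_lo, ",", x$slab$z_hi,
      "] nm, midplane", x$z0, "nm\n")
  for (m in x$monomers) {
    cat("  monomer", m$id, "- cavity prism,",
        length(m$channels), "channel(s):",
        paste(vapply(m$channels, `[[`, character(1L), "label"),
              collapse = ", "),
        if (!is.null(m$site)) "+ binding site" else "", "\n")
  }
  if (!is.null(x$footprint)) cat("  protein footprint present\n")
  invisible(x)
}
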