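#' Hysteresis-filtered state traces
#'
#' Converts each ligand's head-centroid path into a time series of region
#' labels. The raw label per frame comes from [locate()]; a label change is
#' accepted only once the point has penetrated at least `hysteresis_delta_nm`
#' beyond the boundary of the new region (for the open labels `BULK`,
#' `PROTEIN` and `OFF` the condition is instead that the point is at least
#' that far outside the previously held region). Until then, the previous
#' label persists. This two-threshold rule suppresses single-frame flicker
#' at gate boundaries. With `hysteresis_delta_nm = 0` the trace equals the
#' raw [locate()] labels.
#'
#' Frames labelled `BULK` or `CAVITY` are annotated with the leaflet
#' (stromal/lumenal) of the head centroid.
#'
#' @param traj an aligned `qx_trajectory`.
#' @param model a `qx_geometry`.
#' @param hysteresis_delta_nm penetration depth in nm required to accept a
#'   label change (default 0.3 nm, about one coarse-grained bead radius).
#' @return a list of `qx_trace` objects, one per ligand, each with fields
#'   `ligand`, `species`, `time` (ns), `label`, `leaflet` and `z` (head
#'   centroid z in nm).
#' @export
label_trace <- function(traj, model, hysteresis_delta_nm = 0.3) {
  stopifnot(inherits(traj, "qx_trajectory"), inherits(model, "qx_geometry"),
            hysteresis_delta_nm >= 0)
  ligands <- stats::na.omit(unique(traj$beads$ligand))
  out <- vector("list", length(ligands))
  names(out) <- ligands
  for (i in seq_along(ligands)) {
    id <- ligands[i]
    lg <- traj$beads$ligand == id & traj$beads$role == "head"
    head_xyz <- .centroid_series(traj, traj$beads$bead_id[lg])
    if (is.null(dim(head_xyz))) head_xyz <- matrix(head_xyz, ncol = 3L)
    raw <- locate(head_xyz, model)
    lab <- .apply_hysteresis(raw, head_xyz, model, hysteresis_delta_nm)
    out[[i]] <- .new_trace(
      ligand = id,
      species = traj$beads$species[which(lg)[1L]],
      time = traj$times, label = lab, z = head_xyz[, 3],
      model = model)
  }
  out
}

.new_trace <- function(ligand, species, time, label, z, model = NULL,
                       leaflet = NULL) {
  if (is.null(leaflet)) {
    leaflet <- rep(NA_character_, length(label))
    if (!is.null(model)) {
      for (side_lab in unique(label[label == "BULK" |
                                    startsWith(label, "CAVITY.")])) {
        sel <- label == side_lab
        mid <- if (side_lab == "BULK") model$z0 else
          .monomer_of(model, side_lab)$cavity_mid
        leaflet[sel] <- ifelse(z[sel] > mid, "stromal", "lumenal")
      }
    }
  }
  structure(list(ligand = ligand, species = species, time = time,
                 label = label, leaflet = leaflet, z = z),
            class = "qx_trace")
}

# run-length hysteresis: scan maximal runs of the raw label; a run can take
# over from the current label only at its first frame satisfying the
# penetration condition
.apply_hysteresis <- function(raw, pts, model, delta) {
  n <- length(raw)
  if (n == 0L) return(character(0))
  if (delta == 0) return(raw)
  lab <- raw
  r <- rle(raw)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  current <- raw[1L]
  regions <- .region_index(model)
  for (k in seq_along(r$values)) {
    val <- r$values[k]
    if (val == current) next
    i <- starts[k]; j <- ends[k]
    seg <- pts[i:j, , drop = FALSE]
    depth <- if (val %in% c("BULK", "PROTEIN", "OFF")) {
      # penetration out of the old (closed) region
      if (current %in% c("BULK", "PROTEIN", "OFF")) rep(Inf, nrow(seg))
      else -region_depth(regions[[current]], seg)
    } else region_depth(regions[[val]], seg)
    sw <- which(depth >= delta)
    if (length(sw)) {
      sw <- sw[1L]
      if (sw > 1L) lab[i:(i + sw - 2L)] <- current
      current <- val
    } else {
      lab[i:j] <- current
    }
  }
  lab
}

.region_index <- function(model) {
  idx <- list()
  for (m in model$monomers) {
    for (ch in m$channels) idx[[ch$interior$label]] <- ch$interior
    idx[[m$cavity$label]] <- m$cavity
    if (!is.null(m$site)) idx[[m$site$label]] <- m$site
  }
  idx
}

#' @export
print.qx_trace <- function(x, ...) {
  cat("State trace for ligand", x$ligand, "(", x$species, "):",
      length(x$time), "frames\n")
  tb <- table(x$label)
  cat(" ", paste(names(tb), tb, sep = ":", collapse = "  "), "\n")
  invisible(x)
}

#' Detect channel passages
#'
#' Scans a hysteresis-filtered state trace for excursions through channel
#' interiors and classifies each one by its endpoints:
#' \describe{
#'   \item{full}{the excursion starts on one membrane side (bulk or cavity)
#'     and ends on the other; direction `in` (bulk to cavity) or `out`.}
#'   \item{partial}{the ligand enters a channel and retreats to the
#'     originating side; reported only when the channel dwell is at least
#'     `min_dwell_ns` (shorter pokes are boundary flicker).}
#'   \item{trapped}{the ligand is inside a channel at the start or end of
#'     the trace; excluded from flux statistics.}
#' }
#' Side-crossing excursions always count as full regardless of dwell, which
#' makes the cavity balance exact: the change in cavity count over any
#' trace equals full entries minus full exits (see [conservation_audit()]).
#'
#' @param trace a `qx_trace` (or list of traces, in which case events are
#'   concatenated).
#' @param min_dwell_ns minimum channel dwell for a partial excursion to be
#'   reported (default 1 ns, two frames at a 0.5 ns stride).
#' @return a data.frame with columns `ligand`, `species`, `monomer`,
#'   `channel`, `direction`, `completeness`, `orientation`, `t_start_ns`,
#'   `t_end_ns`, `dwell_ns`.
#' @export
detect_passages <- function(trace, min_dwell_ns = 1) {
  if (is.list(trace) && !inherits(trace, "qx_trace")) {
    out <- lapply(trace, detect_passages, min_dwell_ns = min_dwell_ns)
    return(do.call(rbind, out))
  }
  stopifnot(inherits(trace, "qx_trace"))
  lab <- trace$label
  known <- lab == "BULK" | lab == "OFF" | lab == "PROTEIN" |
    startsWith(lab, "CAVITY.") | startsWith(lab, "SITE.") |
    startsWith(lab, "CHANNEL_")
  if (!all(known))
    stop("trace for ligand '", trace$ligand, "' has unknown labels: ",
         paste(unique(lab[!known]), collapse = ", "))
  side <- .label_side(lab)
  r <- rle(side)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  stride <- if (length(trace$time) > 1L) stats::median(diff(trace$time)) else 0
  ev <- list()
  for (k in seq_along(r$values)) {
    if (r$values[k] != "channel") next
    i <- starts[k]; j <- ends[k]
    block <- lab[i:j]
    # dominant channel label of the excursion (ties: first seen)
    dw <- tapply(rep(1L, length(block)), block, sum)
    chan_lab <- names(dw)[order(-dw, match(names(dw), block))][1L]
    origin <- if (k > 1L) r$values[k - 1L] else NA_character_
    terminal <- if (k < length(r$values)) r$values[k + 1L] else NA_character_
    dwell <- length(block) * stride
    if (is.na(origin) || is.na(terminal)) {
      completeness <- "trapped"
      direction <- NA_character_
    } else if (origin != terminal) {
      completeness <- "full"
      direction <- if (terminal == "cavity") "in" else "out"
    } else {
      if (dwell < min_dwell_ns) next
      completeness <- "partial"
      direction <- if (origin == "bulk") "in" else "out"
    }
    ev[[length(ev) + 1L]] <- data.frame(
      ligand = trace$ligand, species = trace$species,
      monomer = .label_monomer(chan_lab),
      channel = .label_channel(chan_lab),
      direction = direction, completeness = completeness,
      orientation = NA_character_,
      t_start_ns = trace$time[i], t_end_ns = trace$time[j],
      dwell_ns = dwell, stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(ligand = character(), species = character(),
                      monomer = integer(), channel = character(),
                      direction = character(), completeness = character(),
                      orientation = character(), t_start_ns = numeric(),
                      t_end_ns = numeric(), dwell_ns = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' Classify the orientation of a passage
#'
#' Determines whether a ligand moved through the decisive gate of a
#' passage head first or tail first — for entries the outer (bulk-side)
#' gate, for exits the inner (cavity-side) gate. The crossing time of the
#' head centroid and of the tail-bead centroid is the first frame, within
#' the event window, at which the centroid is inside the channel interior
#' (an excursion enters the interior through its originating gate, so this
#' is the gate-crossing time); whichever crosses first leads. Crossings in
#' the same frame, or a missing tail, give `undetermined`.
#'
#' @param traj the aligned `qx_trajectory` the event came from.
#' @param event one row of the [detect_passages()] data.frame.
#' @param role_map the `qx_rolemap`.
#' @param model the `qx_geometry`.
#' @param pad_frames how many frames around the event to include when
#'   searching for the crossings (default 12; the trailing pad lets a
#'   lagging tail finish its crossing).
#' @return `"head_first"`, `"tail_first"` or `"undetermined"`.
#' @export
classify_orientation <- function(traj, event, role_map, model,
                                 pad_frames = 12L) {
  stopifnot(inherits(traj, "qx_trajectory"), inherits(model, "qx_geometry"))
  if (is.character(role_map)) role_map <- read_role_map(role_map)
  if (!event$completeness %in% c("full", "partial"))
    stop("orientation is defined for full or partial passages only")
  lg <- role_map$ligands[[event$ligand]]
  if (is.null(lg)) stop("ligand '", event$ligand, "' not in role map")
  if (!length(lg$tail_beads)) {
    warning("ligand '", event$ligand, "' has no tail beads; undetermined")
    return("undetermined")
  }
  mon <- NULL
  for (m in model$monomers) if (m$id == event$monomer) mon <- m
  if (is.null(mon)) stop("monomer ", event$monomer, " not in model")
  ch <- NULL
  for (cc in mon$channels) if (cc$label == event$channel) ch <- cc
  if (is.null(ch)) stop("channel '", event$channel, "' not in model")
  i0 <- max(1L, which.min(abs(traj$times - event$t_start_ns)) - pad_frames)
  i1 <- min(length(traj$times),
            which.min(abs(traj$times - event$t_end_ns)) + pad_frames)
  win <- i0:i1
  head_in <- region_contains(ch$interior,
                             .centroid_window(traj, lg$head_beads, win))
  tail_in <- region_contains(ch$interior,
                             .centroid_window(traj, lg$tail_beads, win))
  f_head <- if (any(head_in)) which(head_in)[1L] else NA_integer_
  f_tail <- if (any(tail_in)) which(tail_in)[1L] else NA_integer_
  if (is.na(f_head) || is.na(f_tail) || f_head == f_tail) "undetermined"
  else if (f_head < f_tail) "head_first" else "tail_first"
}

.centroid_window <- function(traj, beads, win) {
  idx <- match(beads, traj$beads$bead_id)
  if (anyNA(idx)) stop("unknown beads: ",
                       paste(beads[is.na(idx)], collapse = ", "))
  xyz <- traj$coords[win, idx, , drop = FALSE]
  apply(xyz, c(1L, 3L), mean)
}

#' Detect flip-flop events
#'
#' A flip-flop is a reorientation of the ligand headgroup between the
#' stromal and lumenal leaflets of a compartment (bulk membrane or exchange
#' cavity). Detection uses a two-threshold rule on the head z coordinate:
#' starting from a position more than `delta_z_nm` on one side of the
#' compartment midplane, an event is recorded when the head reaches more
#' than `delta_z_nm` on the other side without leaving the compartment.
#' Leaving the compartment resets the detector.
#'
#' @param trace a `qx_trace` (or list of traces; events are concatenated).
#' @param model a `qx_geometry`.
#' @param delta_z_nm dead-band half-width around the midplane (default 0.3).
#' @return data.frame with columns `ligand`, `species`, `compartment`
#'   (`"bulk"` or `"cavity"`), `monomer`, `from_leaflet`, `to_leaflet`,
#'   `time_ns`.
#' @export
detect_flipflops <- function(trace, model, delta_z_nm = 0.3) {
  if (is.list(trace) && !inherits(trace, "qx_trace")) {
    out <- lapply(trace, detect_flipflops, model = model,
                  delta_z_nm = delta_z_nm)
    return(do.call(rbind, out))
  }
  stopifnot(inherits(trace, "qx_trace"), delta_z_nm >= 0)
  lab <- trace$label
  comp <- rep(NA_character_, length(lab))
  comp[lab == "BULK"] <- "BULK"
  incav <- startsWith(lab, "CAVITY.") | startsWith(lab, "SITE.")
  comp[incav] <- paste0("CAVITY.", .label_monomer(lab)[incav])
  ev <- list()
  r <- rle(comp)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    val <- r$values[k]
    if (is.na(val)) next
    i <- starts[k]; j <- ends[k]
    mid <- if (val == "BULK") model$z0 else .monomer_of(model, val)$cavity_mid
    s <- trace$z[i:j] - mid
    v <- ifelse(s > delta_z_nm, 1L, ifelse(s < -delta_z_nm, -1L, 0L))
    nz <- which(v != 0L)
    if (length(nz) < 2L) next
    vv <- v[nz]
    flips <- which(diff(vv) != 0L)
    for (f in flips) {
      at <- i - 1L + nz[f + 1L]
      ev[[length(ev) + 1L]] <- data.frame(
        ligand = trace$ligand, species = trace$species,
        compartment = if (val == "BULK") "bulk" else "cavity",
        monomer = .label_monomer(val),
        from_leaflet = if (vv[f] > 0) "stromal" else "lumenal",
        to_leaflet = if (vv[f + 1L] > 0) "stromal" else "lumenal",
        time_ns = trace$time[at], stringsAsFactors = FALSE)
    }
  }
  if (!length(ev))
    return(data.frame(ligand = character(), species = character(),
                      compartment = character(), monomer = integer(),
                      from_leaflet = character(), to_leaflet = character(),
                      time_ns = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, ev)
}

#' Detect binding-site unbinding events
#'
#' Tracks the distance between each ligand's head centroid and a binding
#' site centre with two-threshold hysteresis. While bound (distance below
#' `r_bound_nm`), an excursion beyond `r_unbound_nm` is:
#' \describe{
#'   \item{transient}{if the head returns below `r_bound_nm` within
#'     `t_rebind_ns` (rapid rebinding; the rebinding time is recorded);}
#'   \item{full}{otherwise.}
#' }
#' Additionally, a `partial` event is recorded when the head stays below
#' `r_unbound_nm` while the tail centroid leaves the channel interiors of
#' the site's monomer (unbinding of the tail but not of the head).
#'
#' @param traj aligned `qx_trajectory`.
#' @param model `qx_geometry`; the site of monomer `monomer` is used.
#' @param role_map `qx_rolemap`.
#' @param monomer which monomer's binding site to monitor (default: first
#'   monomer with a site).
#' @param r_bound_nm,r_unbound_nm bound/unbound distance thresholds in nm
#'   (defaults 0.6 and 1.2; `r_bound_nm < r_unbound_nm`).
#' @param t_rebind_ns rebinding window in ns (default 50).
#' @return data.frame with columns `ligand`, `species`, `site`, `type`,
#'   `t_ns`, `rebind_t_ns`.
#' @export
detect_unbinding <- function(traj, model, role_map, monomer = NULL,
                             r_bound_nm = 0.6, r_unbound_nm = 1.2,
                             t_rebind_ns = 50) {
  stopifnot(inherits(traj, "qx_trajectory"), inherits(model, "qx_geometry"))
  if (is.character(role_map)) role_map <- read_role_map(role_map)
  if (r_bound_nm >= r_unbound_nm) stop("need r_bound_nm < r_unbound_nm")
  mon <- NULL
  for (m in model$monomers) {
    if (!is.null(m$site) && (is.null(monomer) || m$id == monomer)) {
      mon <- m; break
    }
  }
  if (is.null(mon)) stop("no binding site",
                         if (!is.null(monomer)) paste0(" for monomer ", monomer),
                         " in the geometry model")
  centre <- mon$site$centers[1L, ]
  site_lab <- mon$site$label
  ev <- list()
  for (id in names(role_map$ligands)) {
    lg <- role_map$ligands[[id]]
    if (!all(c(lg$head_beads, lg$tail_beads) %in% traj$beads$bead_id)) next
    head_xyz <- .centroid_series(traj, lg$head_beads)
    if (is.null(dim(head_xyz))) head_xyz <- matrix(head_xyz, ncol = 3L)
    d <- sqrt(colSums((t(head_xyz) - centre)^2))
    tail_in <- NULL
    if (length(lg$tail_beads)) {
      tail_xyz <- .centroid_series(traj, lg$tail_beads)
      if (is.null(dim(tail_xyz))) tail_xyz <- matrix(tail_xyz, ncol = 3L)
      tail_in <- rep(FALSE, nrow(tail_xyz))
      for (ch in mon$channels)
        tail_in <- tail_in | region_contains(ch$interior, tail_xyz)
    }
    ev[[id]] <- .scan_unbinding(id, lg$species, site_lab, traj$times, d,
                                tail_in, r_bound_nm, r_unbound_nm,
                                t_rebind_ns)
  }
  out <- do.call(rbind, ev)
  if (is.null(out))
    out <- data.frame(ligand = character(), species = character(),
                      site = character(), type = character(),
                      t_ns = numeric(), rebind_t_ns = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

.scan_unbinding <- function(id, species, site_lab, times, d, tail_in,
                            r_bound, r_unbound, t_rebind) {
  ev <- list()
  add <- function(type, t, rebind = NA_real_)
    ev[[length(ev) + 1L]] <<- data.frame(
      ligand = id, species = species, site = site_lab, type = type,
      t_ns = t, rebind_t_ns = rebind, stringsAsFactors = FALSE)
  bound <- d[1L] < r_bound
  was_ever_bound <- bound
  f <- 1L
  n <- length(d)
  while (f <= n) {
    if (!bound) {
      nxt <- which(d[f:n] < r_bound)
      if (!length(nxt)) break
      f <- f + nxt[1L] - 1L
      bound <- TRUE
      was_ever_bound <- TRUE
    }
    out <- which(d[f:n] > r_unbound)
    if (!length(out)) break
    t1_idx <- f + out[1L] - 1L
    t1 <- times[t1_idx]
    reb <- which(d[t1_idx:n] < r_bound &
                   times[t1_idx:n] - t1 <= t_rebind)
    if (length(reb)) {
      rb_idx <- t1_idx + reb[1L] - 1L
      add("transient", t1, times[rb_idx])
      f <- rb_idx
    } else {
      add("full", t1)
      bound <- FALSE
      f <- t1_idx + 1L
    }
  }
  # partial: head never beyond r_unbound while bound, tail leaves channels
  if (was_ever_bound && !is.null(tail_in) && any(tail_in)) {
    headish <- d < r_unbound
    leave <- which(tail_in[-length(tail_in)] & !tail_in[-1L] &
                     headish[-1L] & headish[-length(headish)])
    for (at in leave) add("partial", times[at + 1L])
  }
  if (!length(ev)) return(NULL)
  do.call(rbind, ev)
}

#' Write events to TSV
#'
#' Writes any event data.frame (passages, flip-flops, unbindings) as a
#' tab-separated file with a deterministic column order and times in ns.
#'
#' @param events a data.frame of events.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
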