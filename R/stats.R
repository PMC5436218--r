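#' Per-channel flux table
#'
#' Aggregates full passages into the mean flux per channel and direction,
#' in molecules per millisecond per monomer, with the standard error of the
#' mean computed over monomer replicates (not over events) — ten replicates
#' being the typical setup of five simulations with two monomers each.
#'
#' @param events passage data.frame from [detect_passages()]; only rows
#'   with `completeness == "full"` contribute.
#' @param per_monomer_monitored_time_ns named numeric vector: monitored
#'   time in ns per monomer id; its names define the replicate set
#'   (monomers with zero events must be listed to count as zeros).
#' @param channels channel labels to tabulate (default: those present in
#'   `events`, or `c("I","II","III")` if none).
#' @param species restrict to one ligand species (e.g. `"PLQ"`); default
#'   uses all events.
#' @return an object of class `qx_fluxtable`: a long-format `table`
#'   data.frame (`channel`, `direction`, `mean_flux_per_ms`, `sem`,
#'   `n_units`), the per-monomer `counts` array and the monitored times.
#' @export
compute_flux_table <- function(events, per_monomer_monitored_time_ns,
                               channels = NULL, species = NULL) {
  times <- per_monomer_monitored_time_ns
  if (is.null(names(times)) || any(!nzchar(names(times))))
    stop("per_monomer_monitored_time_ns must be named by monomer id")
  if (any(times <= 0)) stop("monitored times must be > 0")
  if (!is.null(species)) events <- events[events$species %in% species, ,
                                          drop = FALSE]
  full <- events[events$completeness == "full", , drop = FALSE]
  bad <- setdiff(unique(as.character(full$monomer)), names(times))
  if (length(bad))
    stop("events reference monomer(s) without monitored time: ",
         paste(bad, collapse = ", "))
  if (is.null(channels))
    channels <- if (nrow(full)) sort(unique(full$channel)) else
      c("I", "II", "III")
  monomers <- names(times)
  dirs <- c("in", "out")
  counts <- array(0L, c(length(monomers), length(channels), length(dirs)),
                  dimnames = list(monomer = monomers, channel = channels,
                                  direction = dirs))
  if (nrow(full)) {
    tb <- table(factor(as.character(full$monomer), levels = monomers),
                factor(full$channel, levels = channels),
                factor(full$direction, levels = dirs))
    counts[] <- as.integer(tb)
  }
  ns_per_ms <- 1e6
  flux <- sweep(counts, 1L, times / ns_per_ms, `/`)  # molecules / ms
  n <- length(monomers)
  tab <- expand.grid(channel = channels, direction = dirs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$mean_flux_per_ms <- NA_real_
  tab$sem <- NA_real_
  tab$n_units <- n
  for (r in seq_len(nrow(tab))) {
    v <- flux[, tab$channel[r], tab$direction[r]]
    tab$mean_flux_per_ms[r] <- mean(v)
    tab$sem[r] <- if (n > 1L) stats::sd(v) / sqrt(n) else 0
  }
  structure(list(table = tab, counts = counts, flux = flux,
                 monitored_time_ns = times),
            class = "qx_fluxtable")
}

#' @export
print.qx_fluxtable <- function(x, digits = 2, ...) {
  channels <- dimnames(x$counts)$channel
  cat("Flux (molecules per ms per monomer), mean +/- s.e.m. over",
      x$table$n_units[1L], "monomer replicates\n")
  wide <- matrix("", 2L, length(channels),
                 dimnames = list(c("Flux in", "Flux out"),
                                 paste("Channel", channels)))
  for (r in seq_len(nrow(x$table))) {
    row <- if (x$table$direction[r] == "in") 1L else 2L
    col <- match(x$table$channel[r], channels)
    wide[row, col] <- paste0(round(x$table$mean_flux_per_ms[r], digits),
                             " ± ", round(x$table$sem[r], digits))
  }
  print(wide, quote = FALSE)
  invisible(x)
}

#' Write a flux table
#'
#' Writes both the wide layout (rows flux in/out, columns channels) and a
#' long-format machine-readable table.
#'
#' @param x a `qx_fluxtable`.
#' @param path_wide,path_long output TSV paths (either may be `NULL`).
#' @export
write_flux_table <- function(x, path_wide = NULL, path_long = NULL) {
  stopifnot(inherits(x, "qx_fluxtable"))
  if (!is.null(path_long))
    utils::write.table(x$table, path_long, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_wide)) {
    channels <- dimnames(x$counts)$channel
    wide <- data.frame(flux = c("in", "out"))
    for (ch in channels) {
      m <- x$table[x$table$channel == ch, ]
      wide[[paste0("channel_", ch)]] <-
        paste0(signif(m$mean_flux_per_ms[match(c("in", "out"), m$direction)], 4),
               "+-", signif(m$sem[match(c("in", "out"), m$direction)], 4))
    }
    utils::write.table(wide, path_wide, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Exchange-cavity occupancy
#'
#' Counts, per frame and per monomer, how many ligands are labelled as
#' being inside the exchange cavity, and summarises the occupancy at the
#' end of the run: the per-monomer mean over a trailing window, then the
#' mean and s.e.m. over monomers.
#'
#' @param traces list of `qx_trace` objects (one per ligand).
#' @param model a `qx_geometry`.
#' @param end_window_ns length of the trailing window in ns; default 5% of
#'   the trace duration.
#' @param species restrict the count to one species (default: all).
#' @return an object of class `qx_occupancy`: `time`, a frames x monomers
#'   count matrix, the per-monomer end means and the end mean +/- s.e.m.
#' @export
cavity_occupancy <- function(traces, model, end_window_ns = NULL,
                             species = NULL) {
  stopifnot(length(traces) > 0L, inherits(model, "qx_geometry"))
  time <- traces[[1L]]$time
  monomers <- vapply(model$monomers, `[[`, integer(1L), "id")
  counts <- matrix(0L, length(time), length(monomers),
                   dimnames = list(NULL, monomers))
  for (tr in traces) {
    if (!is.null(species) && !tr$species %in% species) next
    if (length(tr$time) != length(time))
      stop("traces have differing frame counts")
    mono <- .label_monomer(tr$label)
    in_cav <- startsWith(tr$label, "CAVITY.")
    for (m in seq_along(monomers)) {
      sel <- in_cav & mono == monomers[m]
      counts[sel, m] <- counts[sel, m] + 1L
    }
  }
  span <- diff(range(time))
  if (is.null(end_window_ns)) end_window_ns <- 0.05 * span
  lo <- max(time) - end_window_ns
  win <- time >= lo
  if (!any(win)) stop("empty end window (", end_window_ns, " ns)")
  per_mono <- colMeans(counts[win, , drop = FALSE])
  n <- length(per_mono)
  structure(list(time = time, counts = counts,
                 end_window_ns = end_window_ns,
                 per_monomer_end = per_mono,
                 end_mean = mean(per_mono),
                 end_sem = if (n > 1L) stats::sd(per_mono) / sqrt(n) else 0),
            class = "qx_occupancy")
}

#' @export
print.qx_occupancy <- function(x, ...) {
  cat("Cavity occupancy:", round(x$end_mean, 2), "+/-",
      round(x$end_sem, 2), "molecules (s.e.m., n =",
      length(x$per_monomer_end),
      ") over the final", round(x$end_window_ns), "ns\n")
  invisible(x)
}

#' Timescale from event counts and residence time
#'
#' Converts an event count observed over a total residence time into a
#' characteristic timescale: with `n >= 1` events the point estimate is
#' `residence_time_us / n_events`; with zero events a lower bound equal to
#' the total residence time is reported (the convention that at most one
#' event was missed). For example, 14 flip-flop events over 1400 us of
#' cavity residence give a 100 us flip-flop timescale; zero events over
#' 200 us give a 200 us lower bound.
#'
#' @param n_events non-negative integer.
#' @param residence_time_us total residence time in us (>= 0).
#' @return an object of class `qx_timescale` with fields `kind`
#'   (`"point"` or `"lower_bound"`), `value_us` or `lower_bound_us`,
#'   `n_events`, `residence_time_us`.
#' @export
estimate_timescale <- function(n_events, residence_time_us) {
  if (n_events < 0 || residence_time_us < 0)
    stop("n_events and residence_time_us must be non-negative")
  out <- if (n_events >= 1)
    list(kind = "point", value_us = residence_time_us / n_events,
         n_events = n_events, residence_time_us = residence_time_us)
  else
    list(kind = "lower_bound", lower_bound_us = residence_time_us,
         n_events = 0L, residence_time_us = residence_time_us)
  structure(out, class = "qx_timescale")
}

#' @export
print.qx_timescale <- function(x, ...) {
  if (x$kind == "point")
    cat("Timescale:", signif(x$value_us, 3), "us (", x$n_events,
        "events over", signif(x$residence_time_us, 4), "us )\n")
  else
    cat("Timescale: lower bound", signif(x$lower_bound_us, 3),
        "us (no events over", signif(x$residence_time_us, 4), "us )\n")
  invisible(x)
}

#' Mean time between exchange events
#'
#' Total monitored monomer-time divided by the number of exchange events:
#' the average interval at which a cofactor enters or leaves an exchange
#' cavity.
#'
#' @param total_events number of events (>= 1).
#' @param total_monitored_monomer_time_us summed monomer-time in us.
#' @return mean inter-event time in us.
#' @export
mean_interevent_time <- function(total_events,
                                 total_monitored_monomer_time_us) {
  if (total_events < 1) stop("undefined for zero events")
  if (total_monitored_monomer_time_us < 0) stop("negative monitored time")
  total_monitored_monomer_time_us / total_events
}

#' Conservation audit
#'
#' Verifies, per monomer, that the change in cavity occupancy between the
#' start and the end of the traces equals full entries minus full exits.
#' Ligands inside a channel at a trace boundary are attributed to the
#' membrane side they came from (at the start: the side they first reach),
#' so trapped ligands do not unbalance the books.
#'
#' @param traces list of `qx_trace` objects.
#' @param events passage data.frame from [detect_passages()] on the same
#'   traces.
#' @return an object of class `qx_audit`: per-monomer table of start/end
#'   attributed cavity counts, net full events, and a `violations`
#'   data.frame naming the monomers (with involved ligand ids) where the
#'   balance fails. `ok` is `TRUE` when there are no violations.
#' @export
conservation_audit <- function(traces, events) {
  full <- events[events$completeness == "full", , drop = FALSE]
  monomers <- sort(unique(c(full$monomer,
                            unlist(lapply(traces, function(tr)
                              unique(.label_monomer(tr$label)))))))
  monomers <- monomers[!is.na(monomers)]
  per_lig <- lapply(traces, .attributed_sides)
  rows <- list()
  viol <- list()
  for (m in monomers) {
    start_cnt <- sum(vapply(per_lig, function(x)
      identical(x$start, paste0("cavity.", m)), logical(1L)))
    end_cnt <- sum(vapply(per_lig, function(x)
      identical(x$end, paste0("cavity.", m)), logical(1L)))
    entries <- sum(full$monomer == m & full$direction == "in")
    exits <- sum(full$monomer == m & full$direction == "out")
    delta <- end_cnt - start_cnt
    ok <- delta == entries - exits
    rows[[length(rows) + 1L]] <- data.frame(
      monomer = m, start_count = start_cnt, end_count = end_cnt,
      full_entries = entries, full_exits = exits, balanced = ok)
    if (!ok) {
      involved <- unique(c(
        full$ligand[full$monomer == m],
        names(per_lig)[vapply(per_lig, function(x)
          identical(x$start, paste0("cavity.", m)) ||
            identical(x$end, paste0("cavity.", m)), logical(1L))]))
      viol[[length(viol) + 1L]] <- data.frame(
        monomer = m, delta = delta, net_full_events = entries - exits,
        ligands = paste(involved, collapse = ","))
    }
  }
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(monomer = integer(), start_count = integer(),
               end_count = integer(), full_entries = integer(),
               full_exits = integer(), balanced = logical())
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(monomer = integer(), delta = integer(),
               net_full_events = integer(), ligands = character())
  structure(list(summary = summary, violations = violations,
                 ok = nrow(violations) == 0L),
            class = "qx_audit")
}

# membrane-side attribution of a ligand at the trace boundaries: channel
# frames inherit the side the ligand came from (start: first side reached)
.attributed_sides <- function(tr) {
  side <- .label_side(tr$label)
  mono <- .label_monomer(tr$label)
  tag <- ifelse(side == "cavity", paste0("cavity.", mono), side)
  non_ch <- which(side != "channel")
  if (!length(non_ch)) return(list(start = "bulk", end = "bulk"))
  list(start = tag[non_ch[1L]], end = tag[non_ch[length(non_ch)]])
}

#' @export
print.qx_audit <- function(x, ...) {
  if (x$ok) cat("Conservation audit: balanced for",
                nrow(x$summary), "monomer(s)\n")
  else {
    cat("Conservation audit: VIOLATIONS\n")
    print(x$violations)
  }
  invisible(x)
}
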