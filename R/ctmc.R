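#' Compartmental continuous-time Markov model
#'
#' A CTMC over named compartments with a per-microsecond rate matrix `Q`
#' (off-diagonal entries are transition rates, rows sum to zero). Each
#' ligand evolves independently; this is the ground-truth generator the
#' event-detection pipeline is validated against.
#'
#' @param states character vector of state names.
#' @param Q numeric rate matrix (per us), rows/cols in `states` order.
#' @param n_ligands number of ligands.
#' @param init initial state per ligand: a character vector of length
#'   `n_ligands` (recycled if length 1).
#' @param species per-ligand species labels (default `"PLQ"`).
#' @param adjacency optional logical matrix; if given, `Q` may only have
#'   nonzero off-diagonal rates where `adjacency` is `TRUE` (used by
#'   [psii_ctmc()] to enforce the physical connectivity).
#' @return an object of class `qx_ctmc`.
#' @export
ctmc_model <- function(states, Q, n_ligands, init, species = "PLQ",
                       adjacency = NULL) {
  Q <- as.matrix(Q)
  n <- length(states)
  if (!all(dim(Q) == n)) stop("Q must be ", n, " x ", n)
  dimnames(Q) <- list(states, states)
  offd <- Q; diag(offd) <- 0
  if (any(offd < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-12))
    stop("rows of Q must sum to 0 (got max |sum| = ",
         format(max(abs(rowSums(Q)))), ")")
  if (!is.null(adjacency)) {
    bad <- offd > 0 & !adjacency
    if (any(bad)) {
      idx <- which(bad, arr.ind = TRUE)[1L, ]
      stop("rate between non-adjacent states: ",
           states[idx[1L]], " -> ", states[idx[2L]])
    }
  }
  init <- rep(as.character(init), length.out = n_ligands)
  if (!all(init %in% states))
    stop("unknown initial state(s): ",
         paste(setdiff(init, states), collapse = ", "))
  species <- rep(species, length.out = n_ligands)
  structure(list(states = states, Q = Q, n_ligands = as.integer(n_ligands),
                 init = init, species = species),
            class = "qx_ctmc")
}

#' @export
print.qx_ctmc <- function(x, ...) {
  cat("CTMC model:", length(x$states), "states,", x$n_ligands,
      "ligand(s)\n  states:", paste(x$states, collapse = ", "), "\n")
  invisible(x)
}

# deterministic per-ligand substream seed: changing the ligand count never
# reshuffles the paths of existing ligands
.substream_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + i * 16807) %%
               2147483647) + 1L
}

#' Exact stochastic simulation of the compartment model
#'
#' Gillespie simulation of every ligand's chain: exponential dwell times
#' with the state's total exit rate, categorical jumps with probabilities
#' proportional to the outgoing rates. Each ligand has its own random
#' substream derived from the global seed, so results are reproducible and
#' stable under changes of the ligand count.
#'
#' @param model a `qx_ctmc`.
#' @param duration_us simulated time per ligand in us (> 0).
#' @param seed integer seed.
#' @return an object of class `qx_ctmcpaths`: per ligand a list with
#'   `states` (visited states, starting with the initial one) and
#'   `times_us` (entry time of each state, starting at 0).
#' @export
simulate_ctmc <- function(model, duration_us, seed) {
  stopifnot(inherits(model, "qx_ctmc"))
  if (duration_us <= 0) stop("duration_us must be > 0")
  Q <- model$Q
  exit_rate <- -diag(Q)
  jump_prob <- Q
  diag(jump_prob) <- 0
  nz <- exit_rate > 0
  jump_prob[nz, ] <- jump_prob[nz, , drop = FALSE] / exit_rate[nz]
  paths <- vector("list", model$n_ligands)
  for (i in seq_len(model$n_ligands)) {
    set.seed(.substream_seed(seed, i))
    s <- match(model$init[i], model$states)
    states <- s
    times <- 0
    t <- 0
    repeat {
      r <- exit_rate[s]
      if (r <= 0) break
      t <- t + stats::rexp(1L, r)
      if (t >= duration_us) break
      s <- sample.int(length(model$states), 1L, prob = jump_prob[s, ])
      states <- c(states, s)
      times <- c(times, t)
    }
    paths[[i]] <- list(states = model$states[states], times_us = times)
  }
  structure(list(paths = paths, model = model,
                 duration_us = duration_us, seed = seed),
            class = "qx_ctmcpaths")
}

#' @export
print.qx_ctmcpaths <- function(x, ...) {
  nj <- vapply(x$paths, function(p) length(p$times_us) - 1L, integer(1L))
  cat("CTMC paths:", length(x$paths), "ligand(s),", x$duration_us,
      "us, jumps per ligand:", min(nj), "-", max(nj), "\n")
  invisible(x)
}

#' Ground-truth jump log
#'
#' Flattens simulated paths into one event log: one row per state change.
#'
#' @param paths a `qx_ctmcpaths`.
#' @return data.frame with `ligand` (index), `t_us`, `from`, `to`.
#' @export
ground_truth_log <- function(paths) {
  stopifnot(inherits(paths, "qx_ctmcpaths"))
  rows <- lapply(seq_along(paths$paths), function(i) {
    p <- paths$paths[[i]]
    nj <- length(p$states) - 1L
    if (nj < 1L) return(NULL)
    data.frame(ligand = i, t_us = p$times_us[-1L],
               from = p$states[-length(p$states)], to = p$states[-1L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(ligand = integer(), t_us = numeric(),
                      from = character(), to = character(),
                      stringsAsFactors = FALSE)
  out
}

#' Ground-truth channel passages
#'
#' Derives the true passage events from simulated paths: every visit to a
#' channel state is one excursion, classified by the states before and
#' after it (full if the sides differ, partial if they match, trapped if
#' the simulation starts or ends inside the channel).
#'
#' @param paths a `qx_ctmcpaths` whose model uses the PSII state set of
#'   [psii_ctmc()] (channel states named `CH_*`).
#' @param monomer monomer id to stamp on the events (default 1).
#' @return data.frame in the layout of [detect_passages()].
#' @export
ground_truth_passages <- function(paths, monomer = 1L) {
  stopifnot(inherits(paths, "qx_ctmcpaths"))
  rows <- list()
  for (i in seq_along(paths$paths)) {
    p <- paths$paths[[i]]
    sides <- .state_side(p$states)
    in_ch <- sides == "channel"
    if (!any(in_ch)) next
    for (k in which(in_ch)) {
      origin <- if (k > 1L) sides[k - 1L] else NA_character_
      terminal <- if (k < length(sides)) sides[k + 1L] else NA_character_
      t0 <- p$times_us[k]
      t1 <- if (k < length(sides)) p$times_us[k + 1L] else paths$duration_us
      if (is.na(origin) || is.na(terminal)) {
        completeness <- "trapped"; direction <- NA_character_
      } else if (origin != terminal) {
        completeness <- "full"
        direction <- if (terminal == "cavity") "in" else "out"
      } else {
        completeness <- "partial"
        direction <- if (origin == "bulk") "in" else "out"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        ligand = paste0("L", i),
        species = paths$model$species[i], monomer = monomer,
        channel = sub("^CH_", "", p$states[k]),
        direction = direction, completeness = completeness,
        orientation = NA_character_,
        t_start_ns = t0 * 1e3, t_end_ns = t1 * 1e3,
        dwell_ns = (t1 - t0) * 1e3, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- detect_passages(.new_trace("none", "PLQ", numeric(0),
                                      character(0), numeric(0)))
  out
}

#' Ground-truth cavity flip-flops
#'
#' True leaflet-exchange events inside the cavity: jumps between
#' `CAV_S` and `CAV_L`.
#'
#' @param paths a `qx_ctmcpaths` on the PSII state set.
#' @return data.frame with `ligand`, `t_us`, `from_leaflet`, `to_leaflet`.
#' @export
ground_truth_flipflops <- function(paths) {
  log <- ground_truth_log(paths)
  ff <- log[(log$from == "CAV_S" & log$to == "CAV_L") |
              (log$from == "CAV_L" & log$to == "CAV_S"), , drop = FALSE]
  data.frame(ligand = ff$ligand, t_us = ff$t_us,
             from_leaflet = ifelse(ff$from == "CAV_S", "stromal", "lumenal"),
             to_leaflet = ifelse(ff$to == "CAV_S", "stromal", "lumenal"),
             stringsAsFactors = FALSE)
}

# side classification of PSII CTMC states
.state_side <- function(states) {
  side <- rep(NA_character_, length(states))
  side[states %in% c("BULK_S", "BULK_L")] <- "bulk"
  side[states %in% c("CAV_S", "CAV_L", "QB")] <- "cavity"
  side[startsWith(states, "CH_")] <- "channel"
  side
}

#' PSII exchange-kinetics compartment model
#'
#' Builds the eight-state CTMC of plastoquinone exchange in one PSII
#' monomer: stromal/lumenal bulk membrane, three channels, stromal/lumenal
#' exchange cavity and the Q_B binding site. Only physically adjacent
#' compartments are connected: bulk leaflets to each other and to the
#' channels, channels to the cavity, cavity leaflets to each other and to
#' the Q_B site.
#'
#' The channel attempt rates are derived from target full-passage fluxes
#' (molecules per ms per monomer): from a channel, escape to either side is
#' equally likely, so half of all attempts complete; attempt rates are
#' therefore twice the target flux, divided by the number of ligands on the
#' attempting side (`n_bulk` for entries, the nominal cavity occupancy
#' `n_cavity_nominal` for exits).
#'
#' @param entry_flux_ms,exit_flux_ms length-3 target full-passage fluxes
#'   through channels I, II, III, molecules per ms per monomer. Defaults
#'   10, 1, 8 (in) and 4, 1, 6 (out), the flux ratios of the system this
#'   generator emulates.
#' @param n_bulk number of bulk ligands (default 14, about 5 mol% of a
#'   monomer's membrane patch).
#' @param n_cavity start occupancy of the cavity (default 1).
#' @param n_cavity_nominal occupancy used to convert exit fluxes into
#'   per-ligand rates (default `n_cavity`).
#' @param with_qb_ligand add one plastoquinol starting bound at Q_B
#'   (default TRUE).
#' @param cavity_flip_us cavity leaflet-exchange rate per us (default 0.01,
#'   a 100 us flip-flop timescale).
#' @param bulk_flip_us bulk leaflet-exchange rate per us (default 1, the
#'   roughly 1 us bulk flip-flop timescale).
#' @param channel_escape_us rate from a channel to each adjacent side per
#'   us (default 0.5: mean channel dwell 1 us).
#' @param qb_bind_us,qb_unbind_us cavity-to-site and site-to-cavity rates
#'   per us (defaults 0.002 and 0.1: unbinding on the 10 us scale).
#' @param rate_scale multiply all channel attempt rates (entries and
#'   exits) by this factor; useful for high-traffic validation runs.
#' @return a `qx_ctmc` with attribute `"target_flux"` recording the
#'   configured per-channel fluxes.
#' @export
psii_ctmc <- function(entry_flux_ms = c(I = 10, II = 1, III = 8),
                      exit_flux_ms = c(I = 4, II = 1, III = 6),
                      n_bulk = 14L, n_cavity = 1L,
                      n_cavity_nominal = max(n_cavity, 1L),
                      with_qb_ligand = TRUE,
                      cavity_flip_us = 0.01, bulk_flip_us = 1,
                      channel_escape_us = 0.5,
                      qb_bind_us = 0.002, qb_unbind_us = 0.1,
                      rate_scale = 1) {
  states <- c("BULK_S", "BULK_L", "CH_I", "CH_II", "CH_III",
              "CAV_S", "CAV_L", "QB")
  n <- length(states)
  Q <- matrix(0, n, n, dimnames = list(states, states))
  ch <- c("CH_I", "CH_II", "CH_III")
  # molecules/ms -> per-us attempt rates per ligand; factor 2 compensates
  # the 1/2 completion probability of the symmetric channel escape
  entry_attempt <- 2 * (entry_flux_ms / 1e3) / n_bulk * rate_scale
  exit_attempt <- 2 * (exit_flux_ms / 1e3) / n_cavity_nominal * rate_scale
  for (k in 1:3) {
    # a ligand occupies one leaflet at a time, so each leaflet state
    # carries the ligand's full attempt rate
    Q["BULK_S", ch[k]] <- entry_attempt[k]
    Q["BULK_L", ch[k]] <- entry_attempt[k]
    Q["CAV_S", ch[k]] <- exit_attempt[k]
    Q["CAV_L", ch[k]] <- exit_attempt[k]
    # symmetric escape, split over the two leaflets of each side
    Q[ch[k], "BULK_S"] <- channel_escape_us / 2
    Q[ch[k], "BULK_L"] <- channel_escape_us / 2
    Q[ch[k], "CAV_S"] <- channel_escape_us / 2
    Q[ch[k], "CAV_L"] <- channel_escape_us / 2
  }
  Q["BULK_S", "BULK_L"] <- bulk_flip_us
  Q["BULK_L", "BULK_S"] <- bulk_flip_us
  Q["CAV_S", "CAV_L"] <- cavity_flip_us
  Q["CAV_L", "CAV_S"] <- cavity_flip_us
  # the Q_B site sits on the stromal side of the cavity: binding and
  # unbinding exchange with the stromal leaflet only
  Q["CAV_S", "QB"] <- qb_bind_us
  Q["QB", "CAV_S"] <- qb_unbind_us
  diag(Q) <- -rowSums(Q)
  adjacency <- Q > 0  # construction guarantees physical adjacency
  n_lig <- n_bulk + n_cavity + as.integer(with_qb_ligand)
  init <- c(rep(c("BULK_S", "BULK_L"), length.out = n_bulk),
            rep(c("CAV_S", "CAV_L"), length.out = n_cavity),
            if (with_qb_ligand) "QB")
  species <- c(rep("PLQ", n_bulk + n_cavity),
               if (with_qb_ligand) "PLQol")
  model <- ctmc_model(states, Q, n_lig, init, species, adjacency)
  attr(model, "target_flux") <- list(entry_ms = entry_flux_ms,
                                     exit_ms = exit_flux_ms,
                                     rate_scale = rate_scale)
  model
}

#' Sample state paths onto a frame grid as state traces
#'
#' Converts exact CTMC paths into per-ligand `qx_trace` objects on a
#' regular time grid, mapping compartment states to the region labels of a
#' geometry model (the Q_B state maps to the cavity label, matching the
#' label priority of [locate()], under which the binding-site sphere lies
#' inside the cavity). This is the coordinate-free route into the event
#' detectors; [render_trajectory()] is the full route through explicit
#' coordinates.
#'
#' @param paths a `qx_ctmcpaths` on the PSII state set.
#' @param stride_ns sampling interval in ns (default 0.5).
#' @param monomer monomer id for the labels (default 1).
#' @param z_amp synthetic head z offset from the midplane per leaflet in nm
#'   (default 1); gives the traces a usable z channel for flip-flop
#'   detection.
#' @param model optional `qx_geometry` supplying the midplanes for the
#'   synthetic z (defaults to midplane 0).
#' @return list of `qx_trace` objects.
#' @export
sample_state_trace <- function(paths, stride_ns = 0.5, monomer = 1L,
                               z_amp = 1, model = NULL) {
  stopifnot(inherits(paths, "qx_ctmcpaths"))
  t_ns <- seq(0, paths$duration_us * 1e3, by = stride_ns)
  state_to_label <- c(
    BULK_S = "BULK", BULK_L = "BULK",
    CH_I = paste0("CHANNEL_I.", monomer),
    CH_II = paste0("CHANNEL_II.", monomer),
    CH_III = paste0("CHANNEL_III.", monomer),
    CAV_S = paste0("CAVITY.", monomer),
    CAV_L = paste0("CAVITY.", monomer),
    QB = paste0("CAVITY.", monomer))
  state_leaflet <- c(BULK_S = "stromal", BULK_L = "lumenal",
                     CH_I = NA, CH_II = NA, CH_III = NA,
                     CAV_S = "stromal", CAV_L = "lumenal", QB = "stromal")
  z0 <- if (is.null(model)) 0 else model$z0
  out <- vector("list", length(paths$paths))
  for (i in seq_along(paths$paths)) {
    p <- paths$paths[[i]]
    idx <- findInterval(t_ns / 1e3, p$times_us)
    st <- p$states[idx]
    lab <- unname(state_to_label[st])
    leaf <- unname(state_leaflet[st])
    z <- z0 + ifelse(is.na(leaf), 0, ifelse(leaf == "stromal", z_amp, -z_amp))
    out[[i]] <- .new_trace(paste0("L", i), paths$model$species[i],
                           t_ns, lab, z, leaflet = leaf)
  }
  names(out) <- paste0("L", seq_along(out))
  out
}
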