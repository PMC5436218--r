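#' Adaptive respawning of short simulations
#'
#' Iterative protocol for enriching rare events: run short simulations,
#' store the configurations they visit at regular checkpoints, rank the
#' stored configurations by a progress coordinate, and restart the next
#' batch of short runs from the most promising ones. Reported alongside an
#' equal-budget baseline of plain restarts from the initial configuration,
#' this quantifies the enrichment of target-state visits.
#'
#' @param engine function `(state, duration_us, seed) -> list(states,
#'   times_us)`; simulates one short run from `state`. See [ctmc_engine()].
#' @param selector function `(state) -> numeric`; larger scores are more
#'   promising. A constant selector reduces the protocol to respawning
#'   from randomly chosen stored configurations.
#' @param init_state starting configuration for round 1 (and for every
#'   baseline run).
#' @param n_rounds number of rounds (>= 1).
#' @param k_select runs spawned per round (> 0).
#' @param spawn_len_us length of each short run in us.
#' @param seed integer seed; all runs derive substreams from it.
#' @param is_hit function `(states) -> logical(1)`; whether a run reached
#'   the target.
#' @param respawnable function `(state) -> logical(1)`; configurations for
#'   which it is `FALSE` (e.g. the target itself) are never respawned
#'   from.
#' @param checkpoint_us interval at which visited configurations are
#'   stored (default 0.5).
#' @return an object of class `qx_adaptive`: per-run records, total
#'   `hits`, and the stored configuration pool.
#' @export
adaptive_respawn <- function(engine, selector, init_state, n_rounds,
                             k_select, spawn_len_us, seed, is_hit,
                             respawnable = function(s) TRUE,
                             checkpoint_us = 0.5) {
  if (k_select <= 0) stop("k_select must be > 0")
  if (n_rounds < 1) stop("n_rounds must be >= 1")
  pool_states <- character(0)
  runs <- list()
  run_id <- 0L
  hits <- 0L
  for (round in seq_len(n_rounds)) {
    starts <- if (round == 1L || !length(pool_states)) {
      rep(init_state, k_select)
    } else {
      cand <- pool_states[vapply(pool_states, respawnable, logical(1L))]
      if (!length(cand)) rep(init_state, k_select)
      else {
        scores <- vapply(cand, selector, numeric(1L))
        set.seed(.substream_seed(seed, 500000L + round))
        ord <- order(-scores, stats::runif(length(scores)))
        cand[ord[((seq_len(k_select) - 1L) %% length(cand)) + 1L]]
      }
    }
    for (k in seq_len(k_select)) {
      run_id <- run_id + 1L
      path <- engine(starts[k], spawn_len_us,
                     .substream_seed(seed, run_id))
      hit <- isTRUE(is_hit(path$states))
      hits <- hits + hit
      cks <- .checkpoint_states(path, spawn_len_us, checkpoint_us)
      pool_states <- c(pool_states, cks)
      runs[[run_id]] <- list(round = round, start = starts[k], hit = hit)
    }
  }
  structure(list(runs = runs, hits = hits, n_runs = run_id,
                 pool = pool_states, seed = seed),
            class = "qx_adaptive")
}

.checkpoint_states <- function(path, duration_us, checkpoint_us) {
  ck <- seq(checkpoint_us, duration_us, by = checkpoint_us)
  path$states[findInterval(ck, path$times_us)]
}

#' Equal-budget baseline of plain restarts
#'
#' @inheritParams adaptive_respawn
#' @param n_runs total number of short runs.
#' @return a `qx_adaptive` with all runs started from `init_state`.
#' @export
plain_respawn <- function(engine, init_state, n_runs, spawn_len_us, seed,
                          is_hit) {
  runs <- vector("list", n_runs)
  hits <- 0L
  for (r in seq_len(n_runs)) {
    # same substream ids as the adaptive protocol, so a one-round adaptive
    # set from the initial state is identical to plain restarts
    path <- engine(init_state, spawn_len_us, .substream_seed(seed, r))
    hit <- isTRUE(is_hit(path$states))
    hits <- hits + hit
    runs[[r]] <- list(round = NA_integer_, start = init_state, hit = hit)
  }
  structure(list(runs = runs, hits = hits, n_runs = n_runs,
                 pool = character(0), seed = seed),
            class = "qx_adaptive")
}

#' Enrichment report
#'
#' Compares target hit counts between an adaptive run set and an
#' equal-budget baseline. The enrichment ratio uses a half-count
#' continuity correction so it is defined when either count is zero.
#'
#' @param adaptive,baseline `qx_adaptive` objects.
#' @return list with hit counts, run counts, hit rates and
#'   `enrichment_ratio`.
#' @export
enrichment_report <- function(adaptive, baseline) {
  list(adaptive_hits = adaptive$hits, adaptive_runs = adaptive$n_runs,
       baseline_hits = baseline$hits, baseline_runs = baseline$n_runs,
       adaptive_rate = adaptive$hits / adaptive$n_runs,
       baseline_rate = baseline$hits / baseline$n_runs,
       enrichment_ratio = ((adaptive$hits + 0.5) / adaptive$n_runs) /
         ((baseline$hits + 0.5) / baseline$n_runs))
}

#' CTMC restart engine
#'
#' Wraps a compartment model as a restartable engine for
#' [adaptive_respawn()]: each call simulates one ligand from the given
#' state.
#'
#' @param model a `qx_ctmc` (its ligand count is ignored; one chain per
#'   call).
#' @return function `(state, duration_us, seed) -> list(states, times_us)`.
#' @export
ctmc_engine <- function(model) {
  force(model)
  function(state, duration_us, seed) {
    m1 <- ctmc_model(model$states, model$Q, 1L, state)
    simulate_ctmc(m1, duration_us, seed)$paths[[1L]]
  }
}

#' Rare-target toy system
#'
#' A three-state chain used to exercise the adaptive protocol: a stable
#' state `A`, a short-lived intermediate `B` reachable from `A` at a low
#' rate, and an absorbing target `T` reachable only from `B`. Reaching `T`
#' in a short run is rare from `A` but likely from `B`, so ranking stored
#' configurations by proximity to `T` enriches hits.
#'
#' @param k_ab,k_ba,k_bt rates per us (defaults 0.08, 1, 0.25).
#' @return list with `model` (a `qx_ctmc`), `engine`, `selector`
#'   (graph distance to the target, negated), `is_hit` and `respawnable`.
#' @export
toy_rare_target <- function(k_ab = 0.08, k_ba = 1, k_bt = 0.25) {
  states <- c("A", "B", "T")
  Q <- matrix(0, 3, 3, dimnames = list(states, states))
  Q["A", "B"] <- k_ab
  Q["B", "A"] <- k_ba
  Q["B", "T"] <- k_bt
  diag(Q) <- -rowSums(Q)
  model <- ctmc_model(states, Q, 1L, "A")
  dist_to_target <- c(A = 2, B = 1, T = 0)
  list(model = model,
       engine = ctmc_engine(model),
       selector = function(s) -dist_to_target[[s]],
       is_hit = function(states) "T" %in% states,
       respawnable = function(s) s != "T")
}

#' @export
print.qx_adaptive <- function(x, ...) {
  cat("Respawn run set:", x$n_runs, "runs,", x$hits, "target hits (",
      round(100 * x$hits / x$n_runs, 1), "% )\n")
  invisible(x)
}
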