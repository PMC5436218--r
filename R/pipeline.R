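#' Run the full exchange-pathway analysis
#'
#' Config-driven orchestration of the whole pipeline: read (or synthesise)
#' trajectories, align and trim them, label states, detect passages and
#' flip-flops, aggregate flux/occupancy/timescale statistics, accumulate a
#' density grid, audit conservation, and write every report plus a run
#' manifest into an output directory. Any stage failure aborts with the
#' stage name.
#'
#' @param config a list, or a path to a YAML/JSON file, with elements:
#'   \describe{
#'     \item{input}{either `list(trajectory, role_map, geometry)` (file
#'       paths) or `list(synthetic = list(...))` with arguments for
#'       [psii_ctmc()] plus `n_monomers`, `duration_us`, `stride_ns`,
#'       `render` (logical: render coordinates, default FALSE — sample
#'       state traces directly).}
#'     \item{params}{optional overrides: `hysteresis_delta_nm`,
#'       `min_dwell_ns`, `delta_z_nm`, `end_window_ns`, `t_eq_ns`,
#'       `voxel_nm`, `density` (logical).}
#'     \item{out_dir}{output directory.}
#'     \item{seed}{integer seed (synthetic input).}
#'   }
#' @return invisibly, a list with the computed objects (`flux`,
#'   `occupancy`, `events`, `flipflops`, `audit`, `density`, paths of all
#'   written files).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- .read_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config: 'out_dir' is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- .pipeline_params(config$params)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  inputs <- character(0)
  if (!is.null(config$input$synthetic)) {
    syn <- stage("synthesis", .make_synthetic(config$input$synthetic, seed, p))
    model <- syn$model
    traces_by_monomer <- syn$traces_by_monomer
    monitored_ns <- syn$monitored_ns
    density_traj <- syn$density_traj
  } else {
    model <- stage("geometry", build_geometry(config$input$geometry))
    traj <- stage("trajectory io",
                  read_trajectory(config$input$trajectory,
                                  config$input$role_map))
    inputs <- c(config$input$trajectory, config$input$role_map,
                if (is.character(config$input$geometry))
                  config$input$geometry)
    if (p$t_eq_ns > 0 && any(traj$times >= p$t_eq_ns))
      traj <- stage("equilibration trim",
                    discard_equilibration(traj, p$t_eq_ns))
    traces <- stage("state labelling",
                    label_trace(traj, model, p$hysteresis_delta_nm))
    traces_by_monomer <- list(traces)
    span <- diff(range(traj$times))
    mono_ids <- vapply(model$monomers, `[[`, integer(1L), "id")
    monitored_ns <- stats::setNames(rep(span, length(mono_ids)), mono_ids)
    density_traj <- traj
  }

  events <- stage("passage detection", {
    ev <- do.call(rbind, lapply(traces_by_monomer, detect_passages,
                                min_dwell_ns = p$min_dwell_ns))
    ev
  })

  unbinding <- NULL
  if (is.null(config$input$synthetic)) {
    rmap <- read_role_map(config$input$role_map)
    events <- stage("orientation classification", {
      for (r in which(events$completeness %in% c("full", "partial")))
        events$orientation[r] <- classify_orientation(traj, events[r, ],
                                                      rmap, model)
      events
    })
    has_site <- any(vapply(model$monomers,
                           function(m) !is.null(m$site), logical(1L)))
    if (has_site)
      unbinding <- stage("unbinding detection",
                         detect_unbinding(traj, model, rmap))
  }
  flips <- stage("flip-flop detection",
                 do.call(rbind, lapply(traces_by_monomer, detect_flipflops,
                                       model = model,
                                       delta_z_nm = p$delta_z_nm)))
  chan_labels <- sort(unique(unlist(lapply(model$monomers, function(m)
    vapply(m$channels, `[[`, character(1L), "label")))))
  flux <- stage("flux table",
                compute_flux_table(events, monitored_ns,
                                   channels = chan_labels,
                                   species = "PLQ"))
  all_traces <- do.call(c, traces_by_monomer)
  occ <- stage("occupancy",
               cavity_occupancy(all_traces, model,
                                end_window_ns = p$end_window_ns,
                                species = "PLQ"))
  audit <- stage("conservation audit", conservation_audit(all_traces, events))

  # flip-flop timescale from cavity residence of PLQ ligands
  ts <- stage("timescale", {
    cav_res_us <- .cavity_residence_us(all_traces, "PLQ")
    n_ff <- sum(flips$compartment == "cavity" & flips$species == "PLQ")
    estimate_timescale(n_ff, cav_res_us)
  })

  dens <- NULL
  if (isTRUE(p$density) && !is.null(density_traj)) {
    dens <- stage("density", {
      ext <- c(18, 18, 4)
      accumulate_density(density_traj, origin = -ext / 2, extent = ext,
                         voxel_nm = p$voxel_nm, selection = "head")
    })
  }

  files <- c(events = file.path(out_dir, "passage_events.tsv"),
             flipflops = file.path(out_dir, "flipflop_events.tsv"),
             flux_wide = file.path(out_dir, "flux_table.tsv"),
             flux_long = file.path(out_dir, "flux_long.tsv"),
             occupancy = file.path(out_dir, "occupancy.tsv"),
             timescales = file.path(out_dir, "timescales.tsv"),
             audit = file.path(out_dir, "conservation_audit.tsv"),
             manifest = file.path(out_dir, "manifest.json"))
  stage("report writing", {
    write_events(events, files["events"])
    write_events(flips, files["flipflops"])
    write_flux_table(flux, files["flux_wide"], files["flux_long"])
    occ_df <- data.frame(monomer = names(occ$per_monomer_end),
                         end_occupancy = as.numeric(occ$per_monomer_end))
    utils::write.table(occ_df, files["occupancy"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    ts_df <- data.frame(
      quantity = "cavity_flipflop",
      kind = ts$kind,
      value_us = if (ts$kind == "point") ts$value_us else ts$lower_bound_us,
      n_events = ts$n_events, residence_time_us = ts$residence_time_us)
    utils::write.table(ts_df, files["timescales"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(audit$summary, files["audit"], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(unbinding)) {
      files["unbinding"] <- file.path(out_dir, "unbinding_events.tsv")
      write_events(unbinding, files["unbinding"])
    }
    if (!is.null(dens)) {
      files["density"] <- file.path(out_dir, "density.dx")
      write_opendx(dens, files["density"])
    }
    checksums <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
    manifest <- list(
      package = "quinex",
      version = as.character(utils::packageVersion("quinex")),
      seed = seed, params = p,
      synthetic = config$input$synthetic,
      input_checksums = checksums,
      outputs = as.list(basename(files)))
    jsonlite::write_json(manifest, files["manifest"], auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
  })
  invisible(list(flux = flux, occupancy = occ, events = events,
                 flipflops = flips, audit = audit, timescale = ts,
                 density = dens, files = files, model = model))
}

.read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: .", ext)
}

.pipeline_params <- function(params) {
  p <- list(hysteresis_delta_nm = 0.3, min_dwell_ns = 1, delta_z_nm = 0.3,
            end_window_ns = NULL, t_eq_ns = 0, voxel_nm = 0.1,
            density = FALSE)
  for (nm in names(params)) p[[nm]] <- params[[nm]]
  p
}

# total time (us) PLQ ligands spend labelled CAVITY, summed over ligands
.cavity_residence_us <- function(traces, species = "PLQ") {
  tot <- 0
  for (tr in traces) {
    if (!is.null(species) && !tr$species %in% species) next
    if (length(tr$time) < 2L) next
    stride <- stats::median(diff(tr$time))
    tot <- tot + sum(startsWith(tr$label, "CAVITY.")) * stride
  }
  tot / 1e3
}

# synthesise per-monomer traces (and optionally a rendered trajectory for
# the density map) from a psii_ctmc preset
.make_synthetic <- function(syn, seed, p) {
  args <- syn
  n_monomers <- if (is.null(args$n_monomers)) 1L else
    as.integer(args$n_monomers)
  duration_us <- if (is.null(args$duration_us)) 10 else args$duration_us
  stride_ns <- if (is.null(args$stride_ns)) 0.5 else args$stride_ns
  render <- isTRUE(args$render)
  args[c("n_monomers", "duration_us", "stride_ns", "render")] <- NULL
  model_args <- args[names(args) %in% names(formals(psii_ctmc))]
  cm <- do.call(psii_ctmc, model_args)
  geom <- toy_psii_geometry(1L)
  traces_by_monomer <- vector("list", n_monomers)
  density_traj <- NULL
  truth <- list()
  for (m in seq_len(n_monomers)) {
    paths <- simulate_ctmc(cm, duration_us, .substream_seed(seed, 7000L + m))
    if (render) {
      rnd <- render_trajectory(paths, geom, monomer = 1L,
                               stride_ns = stride_ns,
                               seed = .substream_seed(seed, 8000L + m))
      traces <- label_trace(rnd$traj, geom, p$hysteresis_delta_nm)
      if (m == 1L) density_traj <- rnd$traj
      truth[[m]] <- rnd$truth
    } else {
      traces <- sample_state_trace(paths, stride_ns, monomer = 1L,
                                   model = geom)
      truth[[m]] <- list(passages = ground_truth_passages(paths, 1L))
    }
    # stamp the monomer id into labels and ligand ids so replicates stay
    # distinguishable downstream
    traces <- lapply(traces, function(tr) {
      tr$label <- sub("\\.1$", paste0(".", m), tr$label)
      tr$ligand <- paste0("m", m, "_", tr$ligand)
      tr
    })
    names(traces) <- vapply(traces, `[[`, character(1L), "ligand")
    traces_by_monomer[[m]] <- traces
  }
  # a model whose monomer list covers all replicate ids
  geom_multi <- geom
  geom_multi$monomers <- lapply(seq_len(n_monomers), function(m) {
    mm <- geom$monomers[[1L]]
    mm$id <- m
    mm$cavity$label <- paste0("CAVITY.", m)
    if (!is.null(mm$site)) mm$site$label <- paste0("SITE.", m)
    mm
  })
  monitored_ns <- stats::setNames(rep(duration_us * 1e3, n_monomers),
                                  seq_len(n_monomers))
  list(model = geom_multi, traces_by_monomer = traces_by_monomer,
       monitored_ns = monitored_ns, density_traj = density_traj,
       truth = truth, ctmc = cm)
}

#' Write a synthetic dataset to disk
#'
#' Generates a rendered synthetic trajectory with the compartment model
#' and writes the tabular trajectory, role map, geometry configuration and
#' ground-truth event log.
#'
#' @param config list (or YAML/JSON path) with `out_dir`, `seed`,
#'   `duration_us`, `stride_ns`, `n_ligands` (optional cap) and any
#'   [psii_ctmc()] arguments under `rates`.
#' @return named character vector of written file paths, invisibly.
#' @export
simulate_dataset <- function(config) {
  if (is.character(config)) config <- .read_config(config)
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config: 'out_dir' is required")
  if (!dir.exists(out_dir)) {
    ok <- tryCatch({dir.create(out_dir, recursive = TRUE); TRUE},
                   warning = function(w) FALSE, error = function(e) FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory: ", out_dir)
  }
  duration_us <- config$duration_us
  if (is.null(duration_us) || duration_us <= 0)
    stop("duration_us must be > 0 (an empty trajectory is not a dataset)")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  stride_ns <- if (is.null(config$stride_ns)) 0.5 else config$stride_ns
  cm <- do.call(psii_ctmc, if (is.null(config$rates)) list() else
    config$rates)
  if (!is.null(config$n_ligands)) {
    n <- as.integer(config$n_ligands)
    if (n == 0L) {
      warning("n_ligands = 0: writing an empty dataset")
      cm$n_ligands <- 0L
      cm$init <- character(0)
      cm$species <- character(0)
    } else {
      cm$n_ligands <- n
      cm$init <- rep(cm$init, length.out = n)
      cm$species <- rep(cm$species, length.out = n)
    }
  }
  geom <- toy_psii_geometry(1L)
  geo_path <- file.path(out_dir, "geometry.yaml")
  .write_toy_geometry_yaml(geo_path)
  if (cm$n_ligands == 0L) {
    paths_out <- c(trajectory = file.path(out_dir, "synthetic_trajectory.tsv"),
                   role_map = file.path(out_dir, "synthetic_role_map.json"),
                   truth = file.path(out_dir, "synthetic_truth_passages.tsv"),
                   geometry = geo_path)
    utils::write.table(
      data.frame(frame_time_ns = numeric(), bead_id = character(),
                 x_nm = numeric(), y_nm = numeric(), z_nm = numeric(),
                 box_x = numeric(), box_y = numeric(), box_z = numeric()),
      paths_out["trajectory"], sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(ligands = list(),
                              protein_reference = paste0("REF", 1:4)),
                         paths_out["role_map"], auto_unbox = TRUE)
    write_events(ground_truth_passages(
      structure(list(paths = list(), model = cm, duration_us = duration_us,
                     seed = seed), class = "qx_ctmcpaths")),
      paths_out["truth"])
    return(invisible(paths_out))
  }
  paths <- simulate_ctmc(cm, duration_us, seed)
  rnd <- render_trajectory(paths, geom, stride_ns = stride_ns,
                           seed = .substream_seed(seed, 31L))
  out <- write_rendered(rnd, out_dir)
  out["geometry"] <- geo_path
  invisible(out)
}

# serialise the single-monomer toy geometry as a YAML config readable by
# build_geometry()
.write_toy_geometry_yaml <- function(path) {
  model <- toy_psii_geometry(1L)
  m <- model$monomers[[1L]]
  as_cfg_region <- function(r)
    list(poly = lapply(seq_len(nrow(r$poly)), function(i)
      as.numeric(r$poly[i, ])), z_lo = r$z_lo, z_hi = r$z_hi)
  cfg <- list(
    slab = list(z_lo = model$slab$z_lo, z_hi = model$slab$z_hi),
    monomers = list(list(
      id = m$id,
      cavity = as_cfg_region(m$cavity),
      site = list(center = as.numeric(m$site$centers[1L, ]),
                  radius = m$site$radii[1L]),
      channels = lapply(m$channels, function(ch) list(
        label = ch$label,
        interior = as_cfg_region(ch$interior),
        inner_gate = list(point = ch$inner_gate$point,
                          normal = ch$inner_gate$normal),
        outer_gate = list(point = ch$outer_gate$point,
                          normal = ch$outer_gate$normal))))),
    footprint = as_cfg_region(model$footprint))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
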