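# End-to-end orchestration: synth -> simulate -> dispersal -> network ->
# compare, with deterministic, self-describing file outputs.

#' Pipeline configuration
#'
#' Bundles every knob of the end-to-end run. Defaults mirror the study
#' design this pipeline implements (200 particles per release event, 4-day
#' pre-competency, PLD swept 10-130 days with a 30-day headline value,
#' 10,000 Mantel permutations), scaled down only in the synthetic-field
#' extent and particle counts where noted by the caller.
#'
#' @param plds pelagic larval durations in days (each a positive multiple
#'   of the output cadence).
#' @param pre_competency_days pre-competency period (default 4).
#' @param per_event_count particles per release event (default 200).
#' @param years calendar years of the release schedule.
#' @param season_months,window_days,release_hours spawning-season gating,
#'   passed to [build_release_schedule()].
#' @param lunar_mode `"synthetic"` or `"astronomical"`.
#' @param field a [field_config()], or an existing [velocity_field()].
#' @param layout a [habitat_layout()], or NULL to generate an island chain.
#' @param n_sites,n_groups chain size when `layout` is NULL.
#' @param integration an [integration_params()]; its `max_age_days` is
#'   raised to `max(plds)` automatically.
#' @param max_generations cap for stepping-stone paths (default Inf).
#' @param fst optional observed F_ST matrix (site-id dimnames); if NULL and
#'   `synth_fst = TRUE` a synthetic one is generated from the modelled
#'   dispersal at the headline PLD.
#' @param synth_fst generate a synthetic F_ST when none is supplied.
#' @param fst_params list(a, b, sd, clip) for [generate_synthetic_fst()].
#' @param headline_pld the PLD used for the compare stage (default 30).
#' @param n_perm Mantel permutations (default 10000).
#' @param seed global seed; all stage seeds derive from it.
#' @param out_dir output directory.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(plds = seq(10, 130, by = 10),
                            pre_competency_days = 4,
                            per_event_count = 200,
                            years = 2019:2023,
                            season_months = 5:8,
                            window_days = 6,
                            release_hours = c(18, 21, 24),
                            lunar_mode = "synthetic",
                            field = field_config(),
                            layout = NULL,
                            n_sites = 20, n_groups = 5,
                            integration = integration_params(),
                            max_generations = Inf,
                            fst = NULL, synth_fst = TRUE,
                            fst_params = list(a = 0.01, b = 0.005,
                                              sd = 0.003, clip = 0),
                            headline_pld = 30,
                            n_perm = 10000,
                            seed = 1L,
                            out_dir = "results") {
  stopifnot(all(plds > 0), pre_competency_days >= 0, per_event_count > 0)
  cadence <- integration$output_interval_hours / 24
  if (any(abs(plds / cadence - round(plds / cadence)) > 1e-9))
    stop("every PLD must be a positive multiple of the output cadence")
  out <- as.list(environment())
  out$cadence <- NULL
  structure(out, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys match the arguments of [pipeline_config()];
#' `field` and `integration` sub-maps are passed to [field_config()] and
#' [integration_params()].
#'
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$field)) {
    if (!is.null(y$field$origin))
      y$field$origin <- as.POSIXct(y$field$origin, tz = "Asia/Tokyo")
    y$field <- do.call(field_config, y$field)
  }
  if (!is.null(y$integration))
    y$integration <- do.call(integration_params, y$integration)
  do.call(pipeline_config, y)
}

.stage <- function(log, name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  msg <- sprintf("[%s] %s: %.2f s", format(Sys.time(), "%H:%M:%S"), name,
                 as.numeric(difftime(Sys.time(), t0, units = "secs")))
  message(msg)
  cat(msg, "\n", file = log, append = TRUE)
  res
}

#' Run the full dispersal-connectivity pipeline
#'
#' Executes synth (field, sites, calendar, optional F_ST), simulate
#' (release schedule + advection), dispersal (per-PLD matrices and group
#' tables), network (edge lists, betweenness, stepping-stone), and compare
#' (Mantel against geographic distance and dispersal distance). All outputs
#' are CSV/JSON with deterministic names keyed by PLD; a run manifest
#' records the configuration and package version.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with the in-memory stage products (`field`,
#'   `layout`, `calendar`, `schedule`, `ensemble`, `dispersal` (per PLD),
#'   `networks`, `stepping_stone`, `betweenness`, `fst`, `mantel`,
#'   `manifest_path`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cf <- config
  dir.create(cf$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(cf$out_dir, "pipeline.log")
  cat("", file = log)

  field <- .stage(log, "synth:field", {
    if (inherits(cf$field, "velocity_field")) cf$field
    else generate_jet_field(cf$field)
  })
  layout <- .stage(log, "synth:sites", {
    if (!is.null(cf$layout)) cf$layout
    else {
      lon_r <- range(field$lon); lat_r <- range(field$lat)
      generate_island_chain(cf$n_sites, cf$n_groups,
                            arc_lon = seq(lon_r[1] + 0.5, lon_r[2] - 0.5,
                                          length.out = 3),
                            arc_lat = seq(lat_r[1] + 0.5, lat_r[2] - 0.5,
                                          length.out = 3))
    }
  })
  write_sites_csv(layout, file.path(cf$out_dir, "sites.csv"))

  calendar <- .stage(log, "synth:calendar", {
    generate_lunar_calendar(min(cf$years), max(cf$years), mode = cf$lunar_mode)
  })
  write_calendar(calendar, file.path(cf$out_dir, "full_moons.txt"))

  schedule <- .stage(log, "simulate:schedule", {
    build_release_schedule(layout, calendar, cf$years,
                           per_event_count = cf$per_event_count,
                           season_months = cf$season_months,
                           window_days = cf$window_days,
                           release_hours = cf$release_hours)
  })
  write_schedule_csv(schedule, file.path(cf$out_dir, "schedule.csv"))
  cat(sprintf("scheduled particles: %d (%d events)\n",
              total_particles(schedule), nrow(schedule)),
      file = log, append = TRUE)

  params <- cf$integration
  params$max_age_days <- max(cf$plds)
  ensemble <- .stage(log, "simulate:advect", {
    advect(field, schedule, layout, params, seed = cf$seed)
  })

  dms <- list(); nets <- list(); btw <- list(); ss <- list()
  for (pld in cf$plds) {
    tag <- sprintf("pld%03d", pld)
    dm <- .stage(log, paste0("dispersal:", tag), {
      dispersal_matrix(ensemble, layout, pld_days = pld,
                       pre_competency_days = cf$pre_competency_days)
    })
    dms[[as.character(pld)]] <- dm
    write_matrix_csv(dm, file.path(cf$out_dir, paste0("P_", tag, ".csv")))
    gt <- aggregate_island_groups(dm, layout)
    write_matrix_csv(gt$mean, file.path(cf$out_dir, paste0("groups_", tag, ".csv")))

    net <- .stage(log, paste0("network:", tag), build_network(dm))
    nets[[as.character(pld)]] <- net
    write_network_csv(net, file.path(cf$out_dir, paste0("edges_", tag, ".csv")))
    cat(sprintf("%s: %d edges\n", tag, igraph::ecount(net)),
        file = log, append = TRUE)
    if (igraph::vcount(net) >= 3) {
      bw <- data.frame(site = igraph::V(net)$name,
                       weighted = as.numeric(betweenness_centrality(net, "weighted")),
                       unweighted = as.numeric(betweenness_centrality(net, "unweighted")))
      btw[[as.character(pld)]] <- bw
      utils::write.csv(bw, file.path(cf$out_dir, paste0("betweenness_", tag, ".csv")),
                       row.names = FALSE)
    }
    sres <- stepping_stone(net, max_generations = cf$max_generations)
    ss[[as.character(pld)]] <- sres
    write_matrix_csv(sres$percent,
                     file.path(cf$out_dir, paste0("stepping_stone_", tag, ".csv")))
  }

  hp <- as.character(cf$headline_pld)
  mant <- NULL; fst <- cf$fst
  if (!is.null(fst) || cf$synth_fst) {
    cmp <- .stage(log, "compare:mantel", {
      if (!hp %in% names(ss))
        stop("headline PLD ", cf$headline_pld, " not among the configured PLDs")
      psym <- symmetrize_max(ss[[hp]])
      conn <- largest_connected_subset(psym)
      if (length(conn) < 3)
        stop("fewer than 3 fully connected sites at the headline PLD")
      psym <- psym[conn, conn]
      if (is.null(fst)) {
        fp <- cf$fst_params
        fst_used <- generate_synthetic_fst(psym, a = fp$a, b = fp$b,
                                           sd = fp$sd, clip = fp$clip,
                                           seed = cf$seed + 1L)
      } else {
        if (!all(conn %in% rownames(fst)))
          stop("supplied F_ST matrix is missing modelled sites")
        fst_used <- fst[conn, conn]
      }
      geo <- geographic_distance(layout, subset = conn)
      dd <- dispersal_to_distance(psym)
      list(
        fst = fst_used,
        tests = list(
          fst_vs_geography = mantel_test(fst_used, geo, n_perm = cf$n_perm,
                                         seed = cf$seed + 2L),
          fst_vs_dispersal = mantel_test(fst_used, dd, n_perm = cf$n_perm,
                                         seed = cf$seed + 3L)
        )
      )
    })
    fst <- cmp$fst
    mant <- cmp$tests
    write_matrix_csv(fst, file.path(cf$out_dir, "fst.csv"))
    jsonlite::write_json(
      lapply(mant, function(x) x[c("r", "p", "n_perm", "tail", "method",
                                   "seed", "excluded")]),
      file.path(cf$out_dir, "mantel.json"), auto_unbox = TRUE, digits = NA)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("larvanet")),
    seed = cf$seed, plds = cf$plds,
    pre_competency_days = cf$pre_competency_days,
    per_event_count = cf$per_event_count,
    years = cf$years, lunar_mode = cf$lunar_mode,
    n_particles = total_particles(schedule),
    n_sites = nrow(layout$sites),
    headline_pld = cf$headline_pld, n_perm = cf$n_perm
  )
  manifest_path <- file.path(cf$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(field = field, layout = layout, calendar = calendar,
                 schedule = schedule, ensemble = ensemble,
                 dispersal = dms, networks = nets, betweenness = btw,
                 stepping_stone = ss, fst = fst, mantel = mant,
                 manifest_path = manifest_path))
}
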