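#' Experiment configuration
#'
#' Bundles the knobs shared by the named experiment presets. All presets run
#' at any `grid_side`; with the default density compensation the qualitative
#' regimes of the full 142 x 142 network are preserved at reduced scale.
#'
#' @param experiment One of `"overlap"`, `"response_map"`,
#'   `"discrimination"`, `"inhibition_sweep"`, `"noise_robustness"`,
#'   `"controls"`, `"failures"`, `"convergence"`.
#' @param mode Network mode: `"columnar"`, `"noncolumnar"`, `"unconnected"`,
#'   `"shuffled"`, `"distance_only"`, or `"hebbian"`.
#' @param grid_side Cells per side (default 48 for simulation presets).
#' @param seeds Integer seeds (maps, builds, and noise trials).
#' @param inhibition_scale,excitation_scale,noise_amplitude Scaling factors.
#' @param failure_band Synaptic-failure band (`"default"`, `"control"`,
#'   `"none"`).
#' @param duration_ms Trial duration (default 200).
#' @param output_dir Where result CSV/JSON files are written (`NULL` for no
#'   files; results are always returned).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment = "noise_robustness",
                              mode = "columnar", grid_side = 48,
                              seeds = 1:5, inhibition_scale = 1,
                              excitation_scale = 1, noise_amplitude = 1,
                              failure_band = "default", duration_ms = 200,
                              output_dir = NULL) {
  experiments <- c("overlap", "response_map", "discrimination",
                   "inhibition_sweep", "noise_robustness", "controls",
                   "failures", "convergence")
  if (!experiment %in% experiments) {
    stop("unknown experiment; one of: ", paste(experiments, collapse = ", "))
  }
  modes <- c("columnar", "noncolumnar", "unconnected", "shuffled",
             "distance_only", "hebbian")
  if (!mode %in% modes) {
    stop("unknown mode; one of: ", paste(modes, collapse = ", "))
  }
  if (experiment == "failures" && mode == "unconnected") {
    stop("failure bands are meaningless for the unconnected network")
  }
  structure(as.list(environment()), class = "experiment_config")
}

#' Build the network implied by a mode name
#'
#' @param mode See [experiment_config()].
#' @param grid_side Cells per side.
#' @param seed Build seed.
#' @param band Failure band.
#' @return List with elements `map` (a `cortex_map`) and `graph` (a
#'   `synapse_graph`, or `NULL` for `"unconnected"`).
#' @export
network_for_mode <- function(mode, grid_side = 48, seed = 1L,
                             band = "default") {
  map_mode <- if (mode == "noncolumnar") "noncolumnar" else "columnar"
  map <- generate_feature_map(grid_side = grid_side, mode = map_mode,
                              seed = seed)
  graph <- switch(mode,
    unconnected = NULL,
    columnar = ,
    noncolumnar = build_network(map, seed = seed + 1000L, band = band),
    hebbian = build_network(map, seed = seed + 1000L, rule = "hebbian",
                            band = band),
    distance_only = build_network(map, seed = seed + 1000L, band = band,
                                  wiring = "distance_only"),
    shuffled = {
      g <- build_network(map, seed = seed + 1000L, band = band)
      shuffle_amplitudes(g, n_swaps = 2 * nrow(g$edges), seed = seed + 2000L)
    }
  )
  list(map = map, graph = graph)
}

#' Small deterministic fixture network for tests and examples
#'
#' @param grid_side Cells per side, at most 40.
#' @param mode Map mode.
#' @param seed Seed.
#' @param band Failure band.
#' @return List with `map`, `graph`, and a default `stimulus`.
#' @export
make_fixture <- function(grid_side = 20, mode = "columnar", seed = 1L,
                         band = "default") {
  if (grid_side > 40) stop("fixtures are capped at grid_side 40")
  net <- network_for_mode(mode, grid_side = grid_side, seed = seed,
                          band = band)
  c(net, list(stimulus = stimulus_at(0)))
}

run_one_experiment <- function(config) {
  gs <- config$grid_side
  seeds <- config$seeds
  cfg0 <- trial_config(duration_ms = config$duration_ms,
                       inhibition_scale = config$inhibition_scale,
                       excitation_scale = config$excitation_scale)
  switch(config$experiment,
    overlap = dplyr::bind_rows(
      overlap_curve(grid_side = gs, mode = "columnar",
                    delta_deg = c(5, 20, 45), seeds = seeds),
      overlap_curve(grid_side = gs, mode = "noncolumnar",
                    delta_deg = 20, seeds = seeds)
    ),
    response_map = {
      net <- network_for_mode(config$mode, gs, seeds[1], config$failure_band)
      tr <- run_trial(net$graph, net$map, stimulus_at(0), cfg0)
      dplyr::left_join(tibble::as_tibble(net$map), tr$counts, by = "cell_id") |>
        dplyr::left_join(tr$vm, by = "cell_id")
    },
    discrimination = {
      purrr::map(c("columnar", "noncolumnar", "unconnected"), function(m) {
        net <- network_for_mode(m, gs, seeds[1], config$failure_band)
        discrimination_curve(net$graph, net$map, cfg0) |>
          dplyr::mutate(mode = m, .before = 1)
      }) |> dplyr::bind_rows()
    },
    inhibition_sweep = {
      net <- network_for_mode(config$mode, gs, seeds[1], config$failure_band)
      purrr::map(c(0.1, 0.3, 1, 3, 10), function(s) {
        cfg <- cfg0
        cfg$inhibition_scale <- s
        nr <- noise_recovery(net$graph, net$map, cfg,
                             amplitudes = config$noise_amplitude,
                             seeds = seeds)
        tr <- run_trial(net$graph, net$map, stimulus_at(0), cfg)
        dplyr::mutate(nr, inhibition_scale = s,
                      active_cells = sum(tr$counts$spikes > 0),
                      total_spikes = tr$diagnostics$total_spikes,
                      .before = 1)
      }) |> dplyr::bind_rows()
    },
    noise_robustness = {
      net <- network_for_mode(config$mode, gs, seeds[1], config$failure_band)
      noise_recovery(net$graph, net$map, cfg0, seeds = seeds) |>
        dplyr::mutate(mode = config$mode, .before = 1)
    },
    controls = {
      purrr::map(c("columnar", "noncolumnar", "unconnected", "shuffled",
                   "distance_only"), function(m) {
        net <- network_for_mode(m, gs, seeds[1], config$failure_band)
        noise_recovery(net$graph, net$map, cfg0,
                       amplitudes = config$noise_amplitude, seeds = seeds) |>
          dplyr::mutate(mode = m, .before = 1)
      }) |> dplyr::bind_rows()
    },
    failures = {
      purrr::map(seeds, function(s) {
        net <- network_for_mode(config$mode, gs, s, "none")
        purrr::map(c("none", "default", "control"), function(b) {
          g <- apply_failure_model(net$graph, b)
          tr <- run_trial(g, net$map, stimulus_at(0), cfg0)
          nr <- noise_recovery(g, net$map, cfg0,
                               amplitudes = config$noise_amplitude,
                               seeds = s)
          tibble::tibble(seed = s, band = b,
                         total_spikes = tr$diagnostics$total_spikes,
                         noise_r = nr$mean_r[nr$amplitude ==
                                               config$noise_amplitude])
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    },
    convergence = {
      purrr::map(c("columnar", "noncolumnar"), function(m) {
        purrr::map(seeds, function(s) {
          net <- network_for_mode(m, gs, s, config$failure_band)
          cfg <- cfg0
          cfg$record_raster <- TRUE
          clean <- run_trial(net$graph, net$map, stimulus_at(0), cfg)
          cfg$noise_relative_amplitude <- config$noise_amplitude
          cfg$seed <- s
          noisy <- run_trial(net$graph, net$map, stimulus_at(0), cfg)
          tibble::tibble(
            mode = m, seed = s,
            t95_ms = convergence_time(clean$raster, noisy$raster)
          )
        }) |> dplyr::bind_rows()
      }) |> dplyr::bind_rows()
    }
  )
}

#' Run a named experiment preset
#'
#' Builds (or reuses) the networks the preset needs, runs the trial set,
#' computes the metrics, and optionally writes a result CSV plus a JSON
#' manifest (config, seeds, package version) to `output_dir`.
#'
#' @param config An [experiment_config()].
#' @return The result tibble, invisibly also written to disk when
#'   `output_dir` is set.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  res <- run_one_experiment(config)
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(config$output_dir, config$experiment)
    readr::write_csv(res, paste0(stem, ".csv"))
    manifest <- config[setdiff(names(config), "output_dir")]
    manifest$package_version <- as.character(utils::packageVersion("cortexsheet"))
    jsonlite::write_json(manifest, paste0(stem, "_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}
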