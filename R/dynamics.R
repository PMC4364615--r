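#' Biophysical membrane and synapse parameters
#'
#' Canonical parameter set for the three-point pyramidal cell and its
#' synapses. Point 1 is the soma (input resistance 100 MOhm), point 2 the
#' proximal dendrites (250 MOhm), point 3 the distal dendrites (300 MOhm);
#' adjoining points are coupled through a 4 MOhm axial resistance. Resting
#' potential -60 mV, spike threshold -50 mV. Excitatory synapses (reversal
#' 0 mV) are rectangular conductance pulses of 0.5 ms after a 1.3 ms delay;
#' every pyramidal spike also delivers a 0.01 nS, 2 ms shunting IPSC
#' (reversal -60 mV) to the soma and proximal point of every cell after a
#' 2.5 ms delay. The action-potential marker (0 mV for one step), the
#' afterhyperpolarization reset (-65 mV), and the 3 ms absolute refractory
#' period are integration choices of this package, exposed here.
#'
#' @param ... Named overrides of the defaults.
#' @return Named numeric vector of parameters.
#' @export
membrane_params <- function(...) {
  p <- c(
    tau_m_ms = 20, r_in_soma_Mohm = 100, r_in_proximal_Mohm = 250,
    r_in_distal_Mohm = 300, r_axial_Mohm = 4,
    v_rest_mV = -60, v_threshold_mV = -50,
    v_rev_exc_mV = 0, v_rev_inh_mV = -60,
    exc_delay_ms = 1.3, inh_delay_ms = 2.5,
    epsc_duration_ms = 0.5, ipsc_duration_ms = 2, ipsc_g_nS = 0.01,
    ap_peak_mV = 0, ahp_mV = -65, refractory_ms = 3
  )
  ov <- c(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(p))
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- ov
  }
  p
}

#' Membrane derivative of the three-point cell (reference form)
#'
#' Direct R transcription of the membrane equations: at each point
#' `tau dV/dt = -(V - Vrest) + Rin (Im + Ia)` with synaptic current
#' `Im = g (Vrev - V)` and axial current `Ia = (V1 - V)/Ra` summed over
#' adjoining points. Excitatory conductance acts on the distal point,
#' inhibitory conductance on soma and proximal. Used as an independent
#' oracle for the compiled integrator.
#'
#' @param v Length-3 membrane potential (soma, proximal, distal), mV.
#' @param g_exc_nS Total excitatory conductance on the distal point, nS.
#' @param g_inh_nS Inhibitory conductance on soma and on proximal, nS each.
#' @param params See [membrane_params()].
#' @return Length-3 derivative, mV/ms.
#' @export
membrane_derivative <- function(v, g_exc_nS = 0, g_inh_nS = 0,
                                params = membrane_params()) {
  p <- params
  gi <- g_inh_nS / 1000
  ge <- g_exc_nS / 1000
  ra <- p[["r_axial_Mohm"]]
  vr <- p[["v_rest_mV"]]
  d1 <- (-(v[1] - vr) + p[["r_in_soma_Mohm"]] *
           (gi * (p[["v_rev_inh_mV"]] - v[1]) + (v[2] - v[1]) / ra)) / p[["tau_m_ms"]]
  d2 <- (-(v[2] - vr) + p[["r_in_proximal_Mohm"]] *
           (gi * (p[["v_rev_inh_mV"]] - v[2]) +
              ((v[1] - v[2]) + (v[3] - v[2])) / ra)) / p[["tau_m_ms"]]
  d3 <- (-(v[3] - vr) + p[["r_in_distal_Mohm"]] *
           (ge * (p[["v_rev_exc_mV"]] - v[3]) + (v[2] - v[3]) / ra)) / p[["tau_m_ms"]]
  c(d1, d2, d3)
}

#' Steady-state membrane potential under constant conductances
#'
#' Solves the linear fixed point of [membrane_derivative()] exactly.
#'
#' @inheritParams membrane_derivative
#' @return Length-3 steady-state potential, mV.
#' @export
membrane_steady_state <- function(g_exc_nS = 0, g_inh_nS = 0,
                                  params = membrane_params()) {
  # derivative is affine in v: d = (A v + b)/tau; solve A v = -b
  f0 <- membrane_derivative(c(0, 0, 0), g_exc_nS, g_inh_nS, params)
  A <- vapply(1:3, function(k) {
    e <- numeric(3); e[k] <- 1
    membrane_derivative(e, g_exc_nS, g_inh_nS, params) - f0
  }, numeric(3))
  as.numeric(solve(A, -f0))
}

#' Trial configuration
#'
#' @param duration_ms Trial length (default 200 ms).
#' @param dt_ms Integration step (default 0.01 ms, i.e. 10 us).
#' @param inhibition_scale,excitation_scale Multipliers on the inhibitory
#'   and recurrent excitatory conductances (default 1).
#' @param noise_relative_amplitude Overall noise scale; 0 disables noise.
#' @param noise_input_specific,noise_nonspecific Which of the two noise
#'   processes run (both default on; they act only when the amplitude is
#'   positive). Input-specific noise multiplies each cell's feedforward
#'   conductance by `1 +/- 0.33 * amplitude` (sign equiprobable, fixed per
#'   trial); nonspecific noise is a 5 nS telegraph conductance per cell,
#'   switching on with p = 0.0005 and off with p = 0.001 per millisecond
#'   (stationary on-fraction 1/3).
#' @param seed RNG seed for the noise processes.
#' @param record_raster Record per-millisecond spike counts per cell.
#' @param record_vm Return final membrane potentials.
#' @param density_compensation Scale synaptic conductances by
#'   `(142 / grid_side)^2` so that reduced-scale sheets retain the per-cell
#'   aggregate synaptic drive of the full 142 x 142 network (default TRUE;
#'   a no-op at full scale).
#' @param monitor_cell Optional cell id whose somatic potential is recorded
#'   every step (`NULL` to disable).
#' @param params Biophysical parameters, see [membrane_params()].
#' @return A `trial_config` list.
#' @export
trial_config <- function(duration_ms = 200, dt_ms = 0.01,
                         inhibition_scale = 1, excitation_scale = 1,
                         noise_relative_amplitude = 0,
                         noise_input_specific = TRUE,
                         noise_nonspecific = TRUE,
                         seed = 1L, record_raster = FALSE, record_vm = TRUE,
                         density_compensation = TRUE, monitor_cell = NULL,
                         params = membrane_params()) {
  if (dt_ms <= 0) stop("`dt_ms` must be positive")
  if (noise_relative_amplitude < 0) stop("noise amplitude must be non-negative")
  structure(as.list(environment()), class = "trial_config")
}

graph_to_csr <- function(graph, n_cells) {
  if (is.null(graph) || nrow(graph$edges) == 0) {
    return(list(offsets = integer(n_cells + 1), targets = integer(0),
                amps = numeric(0)))
  }
  e <- graph$edges[order(graph$edges$pre, graph$edges$post), ]
  amps <- e$effective_amplitude_nS %||% e$amplitude_nS
  if (is.null(amps)) stop("graph has no amplitudes; run assign_amplitudes()")
  deg <- tabulate(e$pre, nbins = n_cells)
  list(offsets = c(0L, cumsum(deg)), targets = e$post - 1L, amps = amps)
}

#' Simulate one trial of the network
#'
#' Runs the three-point conductance dynamics of every cell for
#' `duration_ms` under a constant feedforward input determined by the
#' stimulus (Gaussian tuning of [feedforward_conductance()]), recurrent
#' excitation through the graph's effective amplitudes, and global delayed
#' shunting inhibition driven by summed pyramidal spiking. Identical
#' (graph, map, stimulus, config, seed) reproduce identical results.
#'
#' @param graph A `synapse_graph` with amplitudes, or `NULL` for the
#'   unconnected (feedforward-only) network.
#' @param map The `cortex_map` the graph was built from.
#' @param stimulus Numeric 4-vector (see [stimulus_at()]).
#' @param config A [trial_config()].
#' @return A `trial_result`: list with `counts` (tibble `cell_id`,
#'   `spikes`), `vm` (tibble of final potentials, if recorded), `raster`
#'   (cells x ms matrix, if recorded), `diagnostics`, and the config.
#' @export
run_trial <- function(graph, map, stimulus = stimulus_at(0),
                      config = trial_config()) {
  n <- nrow(map)
  if (!is.null(graph) && graph$n_cells != n) {
    stop("graph and map disagree on the number of cells")
  }
  td <- tuning_distance(map[, c("p1", "p2", "p3", "p4")], stimulus)
  g_in <- feedforward_conductance(td)
  csr <- graph_to_csr(graph, n)

  gs <- attr(map, "grid_side")
  comp <- if (isTRUE(config$density_compensation)) (142 / gs)^2 else 1

  mon <- if (is.null(config$monitor_cell)) -1L else as.integer(config$monitor_cell) - 1L
  set.seed(config$seed)
  res <- cpp_run_trial(
    n, csr$offsets, csr$targets, csr$amps, g_in,
    config$duration_ms, config$dt_ms,
    config$inhibition_scale * comp, config$excitation_scale * comp,
    config$noise_relative_amplitude,
    config$noise_input_specific, config$noise_nonspecific,
    5.0, 0.0005, 0.001, 0.33,
    config$record_raster,
    numeric(0), config$params, mon
  )
  out <- list(
    counts = tibble::tibble(cell_id = seq_len(n), spikes = res$spike_count),
    vm = if (config$record_vm) {
      tibble::tibble(cell_id = seq_len(n),
                     v_soma = res$vm[, 1], v_proximal = res$vm[, 2],
                     v_distal = res$vm[, 3])
    },
    raster = res$raster,
    v_soma_monitor = res$v_soma_monitor,
    diagnostics = list(
      total_spikes = res$total_spikes,
      exc_events = res$exc_events,
      inh_compartment_events = res$inh_compartment_events,
      noise_on_fraction = res$noise_on_fraction
    ),
    g_in = g_in,
    config = config
  )
  class(out) <- "trial_result"
  out
}

#' @export
print.trial_result <- function(x, ...) {
  cat(sprintf(
    "<trial_result> %d cells, %.0f spikes (%d cells active)\n",
    nrow(x$counts), x$diagnostics$total_spikes, sum(x$counts$spikes > 0)
  ))
  invisible(x)
}

#' Integrate the passive membrane only (single cell, no network)
#'
#' Convenience wrapper used for integrator validation: one cell, no edges,
#' optional constant distal conductance, custom initial condition.
#'
#' @param v_init Length-3 initial potential, mV.
#' @param g_exc_nS Constant distal conductance, nS.
#' @param duration_ms,dt_ms Integration horizon and step.
#' @param params See [membrane_params()].
#' @return Tibble with final `v_soma`, `v_proximal`, `v_distal` and, when a
#'   monitor is implied, the per-step somatic trace as an attribute.
#' @export
integrate_single_cell <- function(v_init = c(-60, -60, -60), g_exc_nS = 0,
                                  duration_ms = 100, dt_ms = 0.01,
                                  params = membrane_params()) {
  res <- cpp_run_trial(
    1L, c(0L, 0L), integer(0), numeric(0), g_exc_nS,
    duration_ms, dt_ms, 1, 1, 0, FALSE, FALSE,
    5.0, 0.0005, 0.001, 0.33, FALSE,
    as.numeric(v_init), params, 0L
  )
  out <- tibble::tibble(
    v_soma = res$vm[, 1], v_proximal = res$vm[, 2], v_distal = res$vm[, 3],
    spikes = res$spike_count
  )
  attr(out, "v_soma_trace") <- res$v_soma_monitor
  out
}
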