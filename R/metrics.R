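#' Pearson similarity between population spike-count vectors
#'
#' Standard Pearson correlation coefficient between two equal-length
#' per-cell spike-count vectors. It is insensitive to the absolute firing
#' rate of the populations (scale invariant). If either vector has zero
#' variance (e.g. a silent network) the similarity is undefined and `NA` is
#' returned rather than a coerced value.
#'
#' @param counts_a,counts_b Equal-length numeric vectors.
#' @return Correlation in `[-1, 1]`, or `NA` if undefined.
#' @export
pearson_similarity <- function(counts_a, counts_b) {
  if (length(counts_a) != length(counts_b)) {
    stop("spike-count vectors must have equal length")
  }
  if (stats::sd(counts_a) == 0 || stats::sd(counts_b) == 0) return(NA_real_)
  stats::cor(counts_a, counts_b)
}

new_similarity_curve <- function(tbl, kind) {
  structure(tbl, class = c("similarity_curve", class(tbl)), kind = kind)
}

#' Orientation discrimination curve
#'
#' Pearson similarity between the whole-network spike-count response to a
#' reference orientation and the responses to test orientations, without
#' noise. Low similarity at small orientation differences implies good
#' discrimination.
#'
#' @param graph A `synapse_graph` (or `NULL` for the unconnected network).
#' @param map The matching `cortex_map`.
#' @param config A [trial_config()]; noise is forced off.
#' @param reference_deg Reference orientation (default 0).
#' @param test_degs Test orientations in degrees.
#' @return A `similarity_curve` tibble (`delta_deg`, `r`, `spikes_test`).
#' @export
discrimination_curve <- function(graph, map, config = trial_config(),
                                 reference_deg = 0,
                                 test_degs = c(0, 5, 10, 15, 20, 30, 45)) {
  config$noise_relative_amplitude <- 0
  ref <- run_trial(graph, map, stimulus_at(reference_deg), config)
  rows <- purrr::map(test_degs, function(d) {
    tr <- if (d == reference_deg) ref else {
      run_trial(graph, map, stimulus_at(d), config)
    }
    tibble::tibble(
      delta_deg = d - reference_deg,
      r = pearson_similarity(ref$counts$spikes, tr$counts$spikes),
      spikes_test = tr$diagnostics$total_spikes
    )
  })
  new_similarity_curve(dplyr::bind_rows(rows), kind = "discrimination")
}

#' Noise-recovery curve
#'
#' Similarity between the network's response to a stimulus without noise and
#' its response to the same stimulus with both noise processes active, per
#' relative noise amplitude. A value of 1 means total noise recovery. The
#' no-noise trial is deterministic; noise trials vary over `seeds`.
#'
#' @inheritParams discrimination_curve
#' @param orientation_deg Stimulus orientation (default 0).
#' @param amplitudes Relative noise amplitudes to probe.
#' @param seeds Seeds for the noise trials (default 1:10).
#' @return A `similarity_curve` tibble (`amplitude`, `mean_r`, `sd_r`, `n`).
#' @export
noise_recovery <- function(graph, map, config = trial_config(),
                           orientation_deg = 0,
                           amplitudes = c(0, 0.25, 0.5, 0.75, 1),
                           seeds = 1:10) {
  stim <- stimulus_at(orientation_deg)
  clean_cfg <- config
  clean_cfg$noise_relative_amplitude <- 0
  clean <- run_trial(graph, map, stim, clean_cfg)
  rows <- purrr::map(amplitudes, function(a) {
    if (a == 0) {
      return(tibble::tibble(amplitude = 0, mean_r = 1, sd_r = 0,
                            n = length(seeds)))
    }
    rs <- purrr::map_dbl(seeds, function(s) {
      cfg <- config
      cfg$noise_relative_amplitude <- a
      cfg$seed <- s
      tr <- run_trial(graph, map, stim, cfg)
      pearson_similarity(clean$counts$spikes, tr$counts$spikes)
    })
    tibble::tibble(amplitude = a, mean_r = mean(rs, na.rm = TRUE),
                   sd_r = stats::sd(rs), n = sum(!is.na(rs)))
  })
  new_similarity_curve(dplyr::bind_rows(rows), kind = "noise_recovery")
}

#' Time course of noise recovery from cumulative spike counts
#'
#' Computes the similarity between cumulative per-cell spike counts of a
#' noise trial and a no-noise trial at increasing endpoints from stimulus
#' onset, and the earliest time at which it reaches a fraction of its
#' asymptotic (end-of-trial) value.
#'
#' @param clean_raster,noise_raster Cells x milliseconds spike-count
#'   matrices from [run_trial()] with `record_raster = TRUE`.
#' @return Tibble (`t_ms`, `r`).
#' @export
similarity_time_course <- function(clean_raster, noise_raster) {
  if (!all(dim(clean_raster) == dim(noise_raster))) {
    stop("rasters must have identical dimensions")
  }
  cum_a <- t(apply(clean_raster, 1, cumsum))
  cum_b <- t(apply(noise_raster, 1, cumsum))
  tibble::tibble(
    t_ms = seq_len(ncol(clean_raster)),
    r = purrr::map_dbl(seq_len(ncol(clean_raster)), function(t) {
      pearson_similarity(cum_a[, t], cum_b[, t])
    })
  )
}

#' @rdname similarity_time_course
#' @param threshold Fraction of the asymptotic similarity (default 0.95).
#' @return `convergence_time()`: earliest time (ms) where the cumulative
#'   similarity reaches `threshold` times the end-of-trial similarity, or
#'   `NA` if never.
#' @export
convergence_time <- function(clean_raster, noise_raster, threshold = 0.95) {
  tc <- similarity_time_course(clean_raster, noise_raster)
  r_inf <- tc$r[nrow(tc)]
  if (is.na(r_inf) || r_inf <= 0) stop("asymptotic similarity is not positive")
  hit <- which(!is.na(tc$r) & tc$r >= threshold * r_inf)
  if (length(hit) == 0) return(NA_real_)
  tc$t_ms[hit[1]]
}
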