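#' Tidy a synapse graph into its edge table
#'
#' @param x A `synapse_graph`.
#' @param ... Unused.
#' @return The edge tibble (`pre`, `post`, `pd_um`, `td`, and, once
#'   computed, `n_pre`, `n_post`, `cn`, `amplitude_nS`,
#'   `effective_amplitude_nS`).
#' @export
tidy.synapse_graph <- function(x, ...) x$edges

#' One-row summary of a synapse graph
#'
#' @param x A `synapse_graph`.
#' @param ... Unused.
#' @return Tibble with cell/edge counts, degree and amplitude summaries.
#' @export
glance.synapse_graph <- function(x, ...) {
  e <- x$edges
  tibble::tibble(
    n_cells = x$n_cells,
    n_edges = nrow(e),
    mean_out_degree = nrow(e) / x$n_cells,
    mean_pd_um = mean(e$pd_um),
    mean_td = mean(e$td),
    mean_amplitude_nS = if (!is.null(e$amplitude_nS)) mean(e$amplitude_nS) else NA_real_,
    max_amplitude_nS = if (!is.null(e$amplitude_nS)) max(e$amplitude_nS) else NA_real_,
    mode = x$mode %||% NA_character_,
    kind = x$kind
  )
}

#' Tidy a trial result into per-cell rows
#'
#' @param x A `trial_result`.
#' @param ... Unused.
#' @return Tibble of per-cell spike counts (joined with final membrane
#'   potentials when recorded).
#' @export
tidy.trial_result <- function(x, ...) {
  out <- x$counts
  if (!is.null(x$vm)) out <- dplyr::left_join(out, x$vm, by = "cell_id")
  out
}

#' One-row summary of a trial
#'
#' @param x A `trial_result`.
#' @param ... Unused.
#' @export
glance.trial_result <- function(x, ...) {
  tibble::tibble(
    n_cells = nrow(x$counts),
    total_spikes = x$diagnostics$total_spikes,
    active_cells = sum(x$counts$spikes > 0),
    max_rate_hz = max(x$counts$spikes) / x$config$duration_ms * 1000,
    noise_on_fraction = x$diagnostics$noise_on_fraction
  )
}

#' Tidy a similarity curve
#'
#' @param x A `similarity_curve`.
#' @param ... Unused.
#' @export
tidy.similarity_curve <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a similarity curve
#'
#' @param x A `similarity_curve`.
#' @param ... Unused.
#' @export
glance.similarity_curve <- function(x, ...) {
  rcol <- if ("mean_r" %in% names(x)) x$mean_r else x$r
  tibble::tibble(kind = attr(x, "kind"), n_points = nrow(x),
                 min_r = min(rcol, na.rm = TRUE),
                 max_r = max(rcol, na.rm = TRUE))
}
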