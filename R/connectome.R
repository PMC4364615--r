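#' Toroidal distance between positions on the sheet
#'
#' Euclidean distance with per-axis wrap-around (the sheet is treated as a
#' torus to avoid edge artifacts), so each axis separation is at most half
#' the sheet size.
#'
#' @param pos_a,pos_b Numeric length-2 vectors or two-column matrices of
#'   (x, y) positions in micrometres.
#' @param sheet_um Sheet side length in micrometres (default 1000).
#' @return Distance(s) in micrometres.
#' @export
toroidal_distance <- function(pos_a, pos_b, sheet_um = 1000) {
  a <- matrix(as.numeric(unlist(pos_a)), ncol = 2)
  b <- matrix(as.numeric(unlist(pos_b)), ncol = 2)
  d <- abs(a - b[rep_len(seq_len(nrow(b)), nrow(a)), , drop = FALSE])
  d <- pmin(d, sheet_um - d)
  out <- sqrt(rowSums(d^2))
  if (length(out) == 1) out[[1]] else out
}

#' Pairwise connection probability
#'
#' Product of two linear factors, each clamped below at zero:
#' \deqn{P = \left(1 - \frac{pd}{pdMax}\right)_+ \left(1 - \frac{td}{tdMax}\right)_+}
#' where `pd` is the physical (toroidal) distance in micrometres, floored at
#' 7 um for distinct cells, and `td` the tuning distance.
#'
#' @param pd Physical distance(s), um.
#' @param td Tuning distance(s).
#' @param pd_max Distance at which connection probability reaches zero
#'   (default 600 um).
#' @param td_max Tuning distance at which connection probability reaches
#'   zero (default 1.1).
#' @return Probability in `[0, 1]`.
#' @export
connection_probability <- function(pd, td, pd_max = 600, td_max = 1.1) {
  if (any(pd < 0) || any(td < 0)) stop("distances must be non-negative")
  pmax(1 - pd / pd_max, 0) * pmax(1 - td / td_max, 0)
}

new_synapse_graph <- function(edges, map, kind = "tuning") {
  structure(
    list(edges = edges, n_cells = nrow(map),
         grid_side = attr(map, "grid_side"), mode = attr(map, "mode"),
         sheet_um = attr(map, "sheet_um") %||% 1000, kind = kind,
         amplitude_rule = NULL, failure_band = NULL, cells = NULL),
    class = "synapse_graph"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.synapse_graph <- function(x, ...) {
  cat(sprintf(
    "<synapse_graph> %d cells (%s, %s wiring), %d directed edges (mean out-degree %.1f)\n",
    x$n_cells, x$mode %||% "?", x$kind, nrow(x$edges),
    nrow(x$edges) / x$n_cells
  ))
  if (!is.null(x$amplitude_rule)) {
    cat(sprintf("  amplitudes: %s rule, failure band %s\n",
                x$amplitude_rule, x$failure_band %||% "none"))
  }
  invisible(x)
}

#' Sample the pyramidal-to-pyramidal wiring
#'
#' Every ordered cell pair is connected independently with the probability
#' given by [connection_probability()], using the toroidal physical distance
#' (floored at `pd_min`) and the normalized tuning distance between the two
#' cells. Pairs are visited in a fixed (pre, post) order with one RNG draw
#' per pair, so builds are exactly reproducible and can be replayed by a
#' brute-force oracle.
#'
#' @param map A `cortex_map`.
#' @param seed Integer seed for the Bernoulli sampling.
#' @param pd_max,td_max Zero-probability bounds (defaults 600 um, 1.1).
#' @param pd_min Minimum physical distance for distinct cells (default 7 um).
#' @param p_scale Global probability scale (default 1). Ignored when
#'   `target_full_degree` is given.
#' @param target_full_degree Full-scale-equivalent mean out-degree to aim
#'   for: the joint rule is rescaled globally so the expected mean degree is
#'   `target_full_degree * n_cells / 142^2` (so reduced sheets keep the
#'   full-scale connection density per unit area). The default 1000
#'   reproduces the documented network statistics (about 1000 synapses per
#'   cell, 2e7 synapses at full scale); set `NULL` to sample the unscaled
#'   rule.
#' @return A `synapse_graph` whose `edges` tibble has columns `pre`, `post`,
#'   `pd_um`, `td`.
#' @export
build_connectivity <- function(map, seed = 1L, pd_max = 600, td_max = 1.1,
                               pd_min = 7, p_scale = 1,
                               target_full_degree = 1000) {
  set.seed(seed)
  if (!is.null(target_full_degree)) {
    p_scale <- degree_calibration_scale(map, target_full_degree, pd_max,
                                        td_max, pd_min)
  }
  res <- cpp_sample_edges(
    map$x_um, map$y_um,
    as.matrix(map[, c("p1", "p2", "p3", "p4")]),
    attr(map, "sheet_um") %||% 1000, pd_max, td_max, pd_min, p_scale,
    TRUE, .circular_axes
  )
  edges <- tibble::tibble(
    pre = res$pre, post = res$post, pd_um = res$pd, td = res$td
  )
  g <- new_synapse_graph(edges, map, kind = "tuning")
  g$seed <- as.integer(seed)
  g
}

# Monte-Carlo estimate (deterministic given the RNG state set by the
# caller) of the global probability scale that yields the requested
# full-scale-equivalent mean out-degree.
degree_calibration_scale <- function(map, target_full_degree, pd_max, td_max,
                                     pd_min, n_sample = 200000) {
  n <- nrow(map)
  target_degree <- target_full_degree * n / 142^2
  i <- sample.int(n, n_sample, replace = TRUE)
  j <- sample.int(n, n_sample, replace = TRUE)
  keep <- i != j
  i <- i[keep]; j <- j[keep]
  sheet <- attr(map, "sheet_um") %||% 1000
  dx <- abs(map$x_um[i] - map$x_um[j]); dx <- pmin(dx, sheet - dx)
  dy <- abs(map$y_um[i] - map$y_um[j]); dy <- pmin(dy, sheet - dy)
  pd <- pmax(sqrt(dx^2 + dy^2), pd_min)
  pm <- as.matrix(map[, c("p1", "p2", "p3", "p4")])
  dmat <- abs(pm[i, ] - pm[j, ])
  dmat[, 1:2] <- 2 * pmin(dmat[, 1:2], 1 - dmat[, 1:2])
  td <- sqrt(rowSums(dmat^2))
  p_mean <- mean(connection_probability(pd, td, pd_max, td_max))
  scale <- target_degree / ((n - 1) * p_mean)
  if (scale > 1) stop("target degree not reachable under the wiring rule")
  scale
}

#' Distance-only control wiring
#'
#' Connection probability depends only on the physical distance,
#' `k * (1 - pd/pd_max)+`, with the global factor `k` chosen analytically so
#' the expected edge count matches `target_edge_count` (typically the edge
#' count of a matched tuning-dependent build). Feature preferences have no
#' influence on the sampled wiring.
#'
#' @inheritParams build_connectivity
#' @param target_edge_count Expected number of directed edges to match.
#' @return A `synapse_graph` (kind `"distance_only"`).
#' @export
distance_only_connectivity <- function(map, target_edge_count, seed = 1L,
                                       pd_max = 600, pd_min = 7) {
  gs <- attr(map, "grid_side")
  sheet <- attr(map, "sheet_um") %||% 1000
  pitch <- sheet / gs
  # exact sum of the distance factor over ordered pairs via grid offsets
  off <- seq_len(gs) - 1L
  wrap <- pmin(off, gs - off) * pitch
  pd <- sqrt(outer(wrap^2, wrap^2, "+"))
  pd[1, 1] <- NA  # self-pairs excluded
  pd <- pmax(pd, pd_min)
  fac_sum <- sum(pmax(1 - pd / pd_max, 0), na.rm = TRUE) * gs^2
  if (fac_sum <= 0) stop("infeasible target edge count: zero admissible pairs")
  k <- target_edge_count / fac_sum
  if (k > 1) stop("infeasible target edge count: required scale exceeds 1")
  set.seed(seed)
  res <- cpp_sample_edges(
    map$x_um, map$y_um,
    as.matrix(map[, c("p1", "p2", "p3", "p4")]),
    sheet, pd_max, Inf, pd_min, k, FALSE, .circular_axes
  )
  edges <- tibble::tibble(
    pre = res$pre, post = res$post, pd_um = res$pd, td = res$td
  )
  g <- new_synapse_graph(edges, map, kind = "distance_only")
  g$seed <- as.integer(seed)
  g
}

#' Count common neighbors for every edge
#'
#' For a connected pair (i -> j), the presynaptic common neighbors are the
#' cells projecting to both i and j (`n_pre`), and the postsynaptic common
#' neighbors are the cells receiving projections from both (`n_post`).
#' For the clustering score `cn` used in amplitude assignment, each count is
#' normalized to the maximum value realized over all edges of the graph, so
#' `cn` lies in `[0, 1]` and only the most densely embedded pair in the
#' sheet reaches 1. Per-cell mean counts over each cell's outgoing edges are
#' stored in `graph$cells`.
#'
#' @param graph A `synapse_graph`.
#' @return The graph with `n_pre`, `n_post`, `cn` edge columns and a
#'   `cells` tibble (`cell_id`, `n_pre_mean`, `n_post_mean`).
#' @export
common_neighbors <- function(graph) {
  e <- graph$edges
  if (nrow(e) == 0) stop("graph has no edges")
  cn <- cpp_common_neighbors(e$pre, e$post, graph$n_cells)
  e$n_pre <- cn$n_pre
  e$n_post <- cn$n_post
  e$cn <- (e$n_pre / max(max(e$n_pre), 1L)) *
    (e$n_post / max(max(e$n_post), 1L))
  per_cell <- e |>
    dplyr::group_by(cell_id = .data$pre) |>
    dplyr::summarise(
      n_pre_mean = mean(.data$n_pre),
      n_post_mean = mean(.data$n_post), .groups = "drop"
    )
  graph$cells <- tibble::tibble(cell_id = seq_len(graph$n_cells)) |>
    dplyr::left_join(per_cell, by = "cell_id") |>
    dplyr::mutate(
      n_pre_mean = dplyr::coalesce(.data$n_pre_mean, 0),
      n_post_mean = dplyr::coalesce(.data$n_post_mean, 0)
    )
  graph$edges <- e
  graph
}

#' Cluster-connectivity factor for edges
#'
#' Saturating (logarithmic) measure of how densely interconnected the
#' neighborhood of the target cell is:
#' \deqn{CC = \frac{(\ln \bar{n}_{pre} + C) + (\ln \bar{n}_{post} + C)}{2}}
#' with `C = 3`, where the per-cell mean common-neighbor counts are
#' normalized by their maxima over cells. The target cell of the edge
#' supplies the means. `CC` is floored at zero so amplitudes stay
#' non-negative conductances.
#'
#' @param graph A `synapse_graph` after [common_neighbors()].
#' @param C Additive constant (default 3).
#' @return Numeric vector of per-edge `CC` values, in edge order.
#' @export
cluster_connectivity <- function(graph, C = 3) {
  if (is.null(graph$cells)) stop("run common_neighbors() first")
  cells <- graph$cells
  max_pre <- max(cells$n_pre_mean)
  max_post <- max(cells$n_post_mean)
  pre_norm <- if (max_pre > 0) cells$n_pre_mean / max_pre else cells$n_pre_mean
  post_norm <- if (max_post > 0) cells$n_post_mean / max_post else cells$n_post_mean
  cc_cell <- (log(pre_norm) + C + log(post_norm) + C) / 2
  cc_cell <- pmax(cc_cell, 0)
  cc_cell[!is.finite(cc_cell)] <- 0
  cc_cell[graph$edges$post]
}

#' Assign EPSC amplitudes to edges
#'
#' Default (`"common_neighbor"`) rule: amplitude = `cn * CC * base_g` with
#' `cn` the normalized common-neighbor product and `CC` the
#' cluster-connectivity factor of the target cell. The `"hebbian"` rule
#' instead sets amplitude proportional to tuning similarity,
#' `(1 - td/td_max)+ * base_g`.
#'
#' @param graph A `synapse_graph` (after [common_neighbors()] for the
#'   default rule).
#' @param rule `"common_neighbor"` or `"hebbian"`.
#' @param base_g Base excitatory postsynaptic conductance in nS (default 0.5).
#' @param td_max Tuning-similarity scale for the hebbian rule (default 1.1).
#' @return The graph with an `amplitude_nS` edge column (and
#'   `effective_amplitude_nS` initialized equal to it).
#' @export
assign_amplitudes <- function(graph, rule = c("common_neighbor", "hebbian"),
                              base_g = 0.5, td_max = 1.1) {
  rule <- match.arg(rule)
  e <- graph$edges
  if (rule == "common_neighbor") {
    if (is.null(e$cn)) graph <- common_neighbors(graph)
    e <- graph$edges
    cc <- cluster_connectivity(graph)
    e$amplitude_nS <- e$cn * cc * base_g
  } else {
    e$amplitude_nS <- pmax(1 - e$td / td_max, 0) * base_g
  }
  e$effective_amplitude_nS <- e$amplitude_nS
  graph$edges <- e
  graph$amplitude_rule <- rule
  graph$failure_band <- "none"
  graph
}

#' Synaptic-failure correction
#'
#' Weak cortical synapses fail to release transmitter at rates inversely
#' proportional to their strength; strong synapses are reliable. The
#' correction multiplies each amplitude by a piecewise-linear reliability
#' factor of the normalized strength `s = amplitude / max(amplitude)`:
#'
#' * `"default"`: factor `min(1, s / 0.2)` -- synapses above 20% of maximum
#'   never fail, below that reliability falls linearly to zero.
#' * `"control"`: the sloped part is moved to the 20--40% band (factor 0 for
#'   `s <= 0.2`, `(s - 0.2)/0.2` for `0.2 < s < 0.4`, 1 above), so failure
#'   hits medium-strength synapses instead.
#' * `"none"`: all synapses fully reliable.
#'
#' @param graph A `synapse_graph` with amplitudes assigned.
#' @param band `"default"`, `"control"`, or `"none"`.
#' @return The graph with `effective_amplitude_nS` updated.
#' @export
apply_failure_model <- function(graph, band = c("default", "control", "none")) {
  band <- match.arg(band)
  e <- graph$edges
  if (is.null(e$amplitude_nS)) stop("assign amplitudes first")
  mx <- max(e$amplitude_nS)
  s <- if (mx > 0) e$amplitude_nS / mx else e$amplitude_nS
  mult <- switch(band,
    default = pmin(1, s / 0.2),
    control = ifelse(s <= 0.2, 0, ifelse(s < 0.4, (s - 0.2) / 0.2, 1)),
    none = rep(1, length(s))
  )
  e$effective_amplitude_nS <- e$amplitude_nS * mult
  graph$edges <- e
  graph$failure_band <- band
  graph
}

#' Shuffle synaptic strengths between edges
#'
#' Swaps the amplitudes of two randomly chosen synapses, `n_swaps` times.
#' The multiset of amplitudes (total, histogram, extremes) and the edge
#' endpoints are exactly conserved; only the assignment of strength to edge
#' is randomized. The failure correction is re-applied afterwards with the
#' graph's current band, so effective amplitudes travel with the strengths.
#'
#' @param graph A `synapse_graph` with amplitudes.
#' @param n_swaps Number of swaps (default 4e7, the full-scale protocol).
#' @param seed RNG seed.
#' @return The graph with shuffled `amplitude_nS`.
#' @export
shuffle_amplitudes <- function(graph, n_swaps = 4e7, seed = 1L) {
  e <- graph$edges
  if (is.null(e$amplitude_nS)) stop("assign amplitudes first")
  set.seed(seed)
  e$amplitude_nS <- cpp_shuffle_amplitudes(e$amplitude_nS, n_swaps)
  graph$edges <- e
  graph$kind <- paste0(graph$kind, "+shuffled")
  apply_failure_model(graph, graph$failure_band %||% "none")
}

#' Build a complete network in one call
#'
#' Convenience pipeline: sample the wiring, count common neighbors, assign
#' amplitudes, and apply the failure correction.
#'
#' @inheritParams build_connectivity
#' @inheritParams assign_amplitudes
#' @inheritParams apply_failure_model
#' @param wiring `"tuning"` (joint distance/tuning rule) or
#'   `"distance_only"` (control; edge count matched to a tuning build with
#'   the same seed).
#' @return A ready-to-simulate `synapse_graph`.
#' @export
build_network <- function(map, seed = 1L, rule = "common_neighbor",
                          band = "default", wiring = c("tuning", "distance_only"),
                          pd_max = 600, td_max = 1.1, pd_min = 7, p_scale = 1,
                          target_full_degree = 1000) {
  wiring <- match.arg(wiring)
  g <- build_connectivity(map, seed = seed, pd_max = pd_max, td_max = td_max,
                          pd_min = pd_min, p_scale = p_scale,
                          target_full_degree = target_full_degree)
  if (wiring == "distance_only") {
    g <- distance_only_connectivity(map, nrow(g$edges), seed = seed + 1L,
                                    pd_max = pd_max, pd_min = pd_min)
  }
  g <- common_neighbors(g)
  g <- assign_amplitudes(g, rule = rule, td_max = td_max)
  apply_failure_model(g, band = band)
}

#' Write an edge list as CSV
#'
#' @param graph A `synapse_graph`.
#' @param path File path.
#' @export
write_edge_list <- function(graph, path) {
  readr::write_csv(graph$edges, path)
  invisible(path)
}
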