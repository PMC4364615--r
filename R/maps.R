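#' Generate a feature map for a 1 mm2 cortical sheet
#'
#' Lays `grid_side^2` pyramidal cells on a regular square grid spanning a
#' 1 mm x 1 mm sheet and assigns each cell a preferred value for four stimulus
#' parameters, each normalized to `[0, 1)`.
#'
#' In `"columnar"` mode the first parameter (orientation, 0--180 degrees
#' mapped to `[0, 1)`) follows the horizontal axis and the second parameter
#' follows the vertical axis, each with Gaussian noise added through the
#' Box--Muller form
#' \deqn{p = m + SD \sqrt{-2 \ln x} \cos(2 \pi y)}
#' with `x`, `y` uniform on (0, 1) and `m` the normalized axis coordinate;
#' values are wrapped back into `[0, 1)`. Parameters 3 and 4 are uniform
#' (weakly- or non-mapped features). In `"noncolumnar"` (salt-and-pepper)
#' mode all four parameters are i.i.d. uniform.
#'
#' @param grid_side Cells per side of the square grid (default 142, i.e.
#'   20164 cells under 1 mm2).
#' @param mode `"columnar"` or `"noncolumnar"`.
#' @param sd_orientation Map noise SD for the orientation parameter, as a
#'   fraction of the normalized range (default 7 degrees / 180).
#' @param sd_param2 Map noise SD for the second mapped parameter (default
#'   0.10 of the range).
#' @param seed Integer seed; maps are reproducible given the seed.
#'
#' @return A `cortex_map` tibble with columns `cell_id`, `x_um`, `y_um`,
#'   `p1`..`p4`, and attributes `grid_side`, `mode`, `sheet_um`, `pitch_um`.
#' @examples
#' m <- generate_feature_map(grid_side = 20, seed = 1)
#' dplyr::glimpse(m)
#' @export
generate_feature_map <- function(grid_side = 142,
                                 mode = c("columnar", "noncolumnar"),
                                 sd_orientation = 7 / 180,
                                 sd_param2 = 0.10,
                                 seed = 1L) {
  mode <- match.arg(mode)
  if (length(grid_side) != 1 || grid_side < 2 || grid_side != round(grid_side)) {
    stop("`grid_side` must be a single integer >= 2")
  }
  if (sd_orientation < 0 || sd_param2 < 0) stop("map SDs must be non-negative")
  sheet_um <- 1000
  pitch <- sheet_um / grid_side
  n <- grid_side^2
  col <- rep(seq_len(grid_side), each = grid_side) - 1L
  row <- rep(seq_len(grid_side), times = grid_side) - 1L

  set.seed(seed)
  box_muller_map <- function(m, sd) {
    x <- runif(n)
    y <- runif(n)
    (m + sd * sqrt(-2 * log(x)) * cos(2 * pi * y)) %% 1
  }
  if (mode == "columnar") {
    p1 <- box_muller_map(col / grid_side, sd_orientation)
    p2 <- box_muller_map(row / grid_side, sd_param2)
    p3 <- runif(n)
    p4 <- runif(n)
  } else {
    p1 <- runif(n)
    p2 <- runif(n)
    p3 <- runif(n)
    p4 <- runif(n)
  }

  out <- tibble::tibble(
    cell_id = seq_len(n),
    x_um = col * pitch,
    y_um = row * pitch,
    p1 = p1, p2 = p2, p3 = p3, p4 = p4
  )
  structure(out,
    class = c("cortex_map", class(out)),
    grid_side = as.integer(grid_side), mode = mode,
    sheet_um = sheet_um, pitch_um = pitch, seed = as.integer(seed)
  )
}

#' Which feature axes are treated as mapped circular variables
#'
#' The two mapped parameters (orientation and the second, vertically mapped
#' feature) are circular; a maximal (antipodal, 90 degree) separation counts
#' as a normalized difference of 1. The two unmapped parameters use plain
#' absolute differences, also with maximum 1. All four axes therefore share
#' the same maximum per-axis difference, and the tuning distance ranges from
#' 0 to 2.
#' @keywords internal
.circular_axes <- c(TRUE, TRUE, FALSE, FALSE)

#' Tuning distance between points in the normalized feature space
#'
#' Euclidean norm of per-axis normalized feature differences. Mapped circular
#' axes (1 and 2) use wrapped differences scaled so that the antipode (a 90
#' degree orientation difference) equals 1; unmapped axes (3 and 4) use
#' absolute differences. All axes share a common maximum of 1, so the
#' distance ranges over `[0, 2]`.
#'
#' @param a Numeric 4-vector, or a matrix/data frame with 4 columns of
#'   normalized preferred values in `[0, 1)`.
#' @param b Numeric 4-vector in `[0, 1)`.
#' @return Non-negative tuning distance(s), one per row of `a`.
#' @examples
#' tuning_distance(c(.1, .2, .3, .4), c(.9, .2, .3, .4)) # wraps: 2 * 0.2
#' @export
tuning_distance <- function(a, b) {
  if (is.data.frame(a)) a <- as.matrix(a)
  if (!is.matrix(a)) a <- matrix(a, nrow = 1)
  if (ncol(a) != 4 || length(b) != 4) stop("feature vectors must have 4 components")
  if (any(a < 0 | a >= 1) || any(b < 0 | b >= 1)) {
    stop("normalized feature values must lie in [0, 1)")
  }
  d <- cpp_tuning_distance(a, as.numeric(b), .circular_axes)
  if (nrow(a) == 1) d[1] else d
}

#' Feedforward input conductance for a given tuning distance
#'
#' Gaussian tuning of the constant feedforward conductance applied to the
#' distal dendrites:
#' \deqn{g_{in}(td) = \frac{C}{2\pi\sigma^2} e^{-td^2 / 2\sigma^2}}
#' With the default variance 0.1 the conductance half-width corresponds to
#' roughly 30 degrees of orientation difference.
#'
#' @param td Tuning distance(s), >= 0.
#' @param sigma_sq Tuning variance (default 0.1).
#' @param C Scaling constant (default 15), giving ~23.87 nS at `td = 0`.
#' @return Conductance in nS.
#' @export
feedforward_conductance <- function(td, sigma_sq = 0.1, C = 15) {
  if (any(td < 0)) stop("`td` must be non-negative")
  C / (2 * pi * sigma_sq) * exp(-td^2 / (2 * sigma_sq))
}

#' Construct a stimulus in the normalized feature space
#'
#' The reference stimulus has all parameters at half maximum (designated 0
#' degrees orientation); `orientation_deg` shifts the first parameter by
#' `deg / 180` of the normalized range.
#'
#' @param orientation_deg Orientation in degrees relative to the reference.
#' @param base Baseline 4-vector (default `c(0.5, 0.5, 0.5, 0.5)`).
#' @return A numeric 4-vector in `[0, 1)`.
#' @export
stimulus_at <- function(orientation_deg = 0, base = rep(0.5, 4)) {
  s <- base
  s[1] <- (s[1] + orientation_deg / 180) %% 1
  s
}

#' The N cells best tuned to a stimulus
#'
#' Selects the `n_cells` cells minimizing [tuning_distance()] to the
#' stimulus. Ties are broken by cell id (stable), so the selection is
#' deterministic.
#'
#' @param map A `cortex_map`.
#' @param stimulus Numeric 4-vector in `[0, 1)`.
#' @param n_cells Number of cells to select (default 100).
#' @return Integer vector of cell ids, ordered by increasing distance.
#' @export
best_tuned_cells <- function(map, stimulus, n_cells = 100) {
  if (n_cells <= 0) stop("`n_cells` must be positive")
  if (n_cells > nrow(map)) stop("`n_cells` exceeds the number of cells")
  td <- tuning_distance(map[, c("p1", "p2", "p3", "p4")], stimulus)
  ord <- order(td, map$cell_id)
  map$cell_id[ord[seq_len(n_cells)]]
}

#' Percentage overlap between two equally sized cell populations
#'
#' @param set_a,set_b Integer vectors of cell ids of equal length.
#' @return Overlap as a percentage of the population size.
#' @export
population_overlap <- function(set_a, set_b) {
  if (length(set_a) != length(set_b)) stop("populations must be the same size")
  100 * length(intersect(set_a, set_b)) / length(set_a)
}

#' Mean best-tuned population overlap across seeds
#'
#' Repeats the feedforward overlap analysis: for each seed, generate a map,
#' select the `n_cells` best-tuned cells for a reference stimulus and for a
#' stimulus shifted in orientation, and record the percentage overlap.
#'
#' @inheritParams generate_feature_map
#' @param delta_deg Orientation differences (degrees) to probe.
#' @param n_cells Best-tuned population size (default 100).
#' @param seeds Integer vector of map seeds.
#' @return A tibble with columns `mode`, `delta_deg`, `mean_overlap_pct`,
#'   `sd_overlap_pct`, `n_seeds`.
#' @export
overlap_curve <- function(grid_side = 142, mode = "columnar",
                          delta_deg = c(5, 20, 45), n_cells = 100,
                          seeds = 1:20) {
  per <- purrr::map(seeds, function(s) {
    m <- generate_feature_map(grid_side = grid_side, mode = mode, seed = s)
    ref <- best_tuned_cells(m, stimulus_at(0), n_cells)
    tibble::tibble(
      seed = s, delta_deg = delta_deg,
      overlap = purrr::map_dbl(delta_deg, function(d) {
        population_overlap(ref, best_tuned_cells(m, stimulus_at(d), n_cells))
      })
    )
  }) |> dplyr::bind_rows()
  per |>
    dplyr::group_by(.data$delta_deg) |>
    dplyr::summarise(
      mean_overlap_pct = mean(.data$overlap),
      sd_overlap_pct = stats::sd(.data$overlap),
      n_seeds = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(mode = mode, .before = 1)
}

#' Write / read a feature map as CSV
#'
#' @param map A `cortex_map`.
#' @param path File path.
#' @return `write_feature_map()` returns `path` invisibly;
#'   `read_feature_map()` returns a `cortex_map`.
#' @export
write_feature_map <- function(map, path) {
  readr::write_csv(tibble::as_tibble(map), path)
  invisible(path)
}

#' @rdname write_feature_map
#' @param mode,grid_side Metadata to re-attach when reading (grid side is
#'   inferred from the cell count when `NULL`).
#' @export
read_feature_map <- function(path, mode = "columnar", grid_side = NULL) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  gs <- if (is.null(grid_side)) as.integer(round(sqrt(nrow(out)))) else grid_side
  structure(tibble::as_tibble(out),
    class = c("cortex_map", class(tibble::tibble())),
    grid_side = gs, mode = mode, sheet_um = 1000, pitch_um = 1000 / gs
  )
}
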