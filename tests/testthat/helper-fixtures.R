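# Small networks shared across test files; built once per test run.
fixture_cache <- new.env(parent = emptyenv())

fixture_net <- function(grid_side = 20, mode = "columnar", seed = 1L,
                        band = "default") {
  key <- paste(grid_side, mode, seed, band, sep = "_")
  if (is.null(fixture_cache[[key]])) {
    fixture_cache[[key]] <- make_fixture(grid_side, mode, seed, band)
  }
  fixture_cache[[key]]
}

# A hand-buildable graph: take a real build's shell and replace the edges.
graph_with_edges <- function(map, edges) {
  g <- build_connectivity(map, seed = 99L, target_full_degree = NULL)
  g$edges <- edges
  g
}

# reference (oracle) tuning distance, written independently of the compiled path
oracle_td <- function(a, b) {
  wrap2 <- function(d) {
    d <- abs(d)
    2 * pmin(d, 1 - d)
  }
  sqrt(wrap2(a[1] - b[1])^2 + wrap2(a[2] - b[2])^2 +
         abs(a[3] - b[3])^2 + abs(a[4] - b[4])^2)
}
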