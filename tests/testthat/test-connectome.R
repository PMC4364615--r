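test_that("toroidal distance wraps around the sheet", {
  expect_equal(toroidal_distance(c(0, 0), c(0, 0)), 0)
  expect_equal(toroidal_distance(c(0, 0), c(993, 0)), 7)
  expect_equal(toroidal_distance(c(0, 0), c(500, 500)), sqrt(2) * 500)
  expect_equal(toroidal_distance(c(10, 990), c(990, 10)),
               toroidal_distance(c(990, 10), c(10, 990)))
})

test_that("connection probability is the clamped product of linear factors", {
  expect_equal(connection_probability(600, 0), 0)
  expect_equal(connection_probability(7, 0), 1 - 7 / 600)
  expect_equal(connection_probability(300, 0.55), 0.25)
  expect_equal(connection_probability(900, 0.1), 0)  # clamped, not negative
  expect_equal(connection_probability(100, 2), 0)
  pd <- seq(0, 700, by = 50)
  expect_true(all(diff(connection_probability(pd, 0.3)) <= 0))
})

test_that("edge sampling replays a brute-force Bernoulli oracle exactly", {
  map <- generate_feature_map(grid_side = 6, seed = 4)
  g <- build_connectivity(map, seed = 17, target_full_degree = NULL)
  # oracle: same (pre, post) iteration order, same RNG stream
  set.seed(17)
  P <- as.matrix(map[, c("p1", "p2", "p3", "p4")])
  expected <- list()
  for (i in seq_len(36)) {
    for (j in seq_len(36)) {
      if (i == j) next
      pd <- max(toroidal_distance(c(map$x_um[i], map$y_um[i]),
                                  c(map$x_um[j], map$y_um[j])), 7)
      td <- oracle_td(P[i, ], P[j, ])
      if (runif(1) < connection_probability(pd, td)) {
        expected[[length(expected) + 1]] <- c(i, j, pd, td)
      }
    }
  }
  expected <- do.call(rbind, expected)
  expect_equal(nrow(g$edges), nrow(expected))
  expect_equal(g$edges$pre, expected[, 1])
  expect_equal(g$edges$post, expected[, 2])
  expect_equal(g$edges$pd_um, expected[, 3], tolerance = 1e-12)
  expect_equal(g$edges$td, expected[, 4], tolerance = 1e-12)
  # distances respect the floor and the sheet geometry
  expect_true(all(g$edges$pd_um >= 7))
})

test_that("common-neighbor counts match a brute-force oracle", {
  # deterministic motif: k -> i, k -> j, i -> j  gives edge i->j one
  # presynaptic common neighbor
  map <- generate_feature_map(grid_side = 2, seed = 1)
  edges <- tibble::tibble(pre = c(3L, 3L, 1L), post = c(1L, 2L, 2L),
                          pd_um = 7, td = 0)
  g <- common_neighbors(graph_with_edges(map, edges))
  e12 <- g$edges[g$edges$pre == 1 & g$edges$post == 2, ]
  expect_equal(e12$n_pre, 1L)
  expect_equal(e12$n_post, 0L)

  # random graph vs double-loop set intersections
  set.seed(42)
  n <- 50
  adj <- matrix(runif(n * n) < 0.15, n, n)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  map50 <- generate_feature_map(grid_side = 8, seed = 2)  # 64 >= 50 cells
  edges <- tibble::tibble(pre = as.integer(idx[, 1]),
                          post = as.integer(idx[, 2]), pd_um = 7, td = 0)
  g <- common_neighbors(graph_with_edges(map50, edges))
  for (e in sample(nrow(edges), 25)) {
    i <- edges$pre[e]; j <- edges$post[e]
    expect_equal(g$edges$n_pre[e], length(intersect(which(adj[, i]),
                                                    which(adj[, j]))))
    expect_equal(g$edges$n_post[e], length(intersect(which(adj[i, ]),
                                                     which(adj[j, ]))))
  }
  # normalized product lies in [0, 1]
  expect_true(all(g$edges$cn >= 0 & g$edges$cn <= 1))
  expect_equal(max(g$edges$n_pre) / max(g$edges$n_pre), 1)
})

test_that("cluster connectivity follows the saturating log rule", {
  map <- generate_feature_map(grid_side = 2, seed = 1)
  g <- graph_with_edges(map, tibble::tibble(pre = c(1L, 1L), post = c(2L, 3L),
                                            pd_um = 7, td = 0))
  g$cells <- tibble::tibble(cell_id = 1:4,
                            n_pre_mean = c(10, 5, 10, 0),
                            n_post_mean = c(8, 8, 8, 0))
  cc <- cluster_connectivity(g)
  # target cell 2: pre_norm 0.5, post_norm 1 -> (ln .5 + 3 + ln 1 + 3)/2
  expect_equal(cc[1], (log(0.5) + 3 + log(1) + 3) / 2, tolerance = 1e-12)
  expect_equal(cc[1], 2.6534, tolerance = 1e-4)
  # target cell 3: both norms 1 -> C = 3
  expect_equal(cc[2], 3)
  # floor at zero for vanishing normalized means
  g$cells$n_pre_mean <- c(1, exp(-7), 1, 0)
  g$cells$n_post_mean <- c(1, exp(-7), 1, 0)
  expect_equal(cluster_connectivity(g)[1], 0)
})

test_that("amplitude rules produce non-negative conductances", {
  fx <- fixture_net(12)
  g <- fx$graph
  expect_true(all(g$edges$amplitude_nS >= 0))
  expect_true(all(g$edges$effective_amplitude_nS <= g$edges$amplitude_nS + 1e-15))
  # zero common-neighbor product means zero amplitude
  zero_cn <- g$edges$cn == 0
  expect_true(all(g$edges$amplitude_nS[zero_cn] == 0))
  # CN = 1 with CC = 3 gives 1.5 nS at the default base conductance
  top <- which.max(g$edges$cn * 0 + g$edges$cn)  # edge with maximal cn
  cc <- cluster_connectivity(g)
  expect_equal(g$edges$amplitude_nS, g$edges$cn * cc * 0.5, tolerance = 1e-12)

  gh <- assign_amplitudes(g, rule = "hebbian")
  expect_equal(gh$edges$amplitude_nS,
               pmax(1 - gh$edges$td / 1.1, 0) * 0.5, tolerance = 1e-12)
  expect_error(assign_amplitudes(g, rule = "nonsense"))
})

test_that("failure model reshapes weak synapses as specified", {
  map <- generate_feature_map(grid_side = 2, seed = 1)
  amp <- c(0, 0.1, 0.15, 0.2, 0.3, 0.5, 1)  # max 1 -> s equals amp
  g <- graph_with_edges(map, tibble::tibble(
    pre = rep(1L, 7), post = rep(2L, 7), pd_um = 7, td = 0,
    amplitude_nS = amp, effective_amplitude_nS = amp
  ))
  gd <- apply_failure_model(g, "default")
  expect_equal(gd$edges$effective_amplitude_nS,
               amp * pmin(1, amp / 0.2))
  # s >= 0.2: unchanged; s = 0.1: halved; s = 0: zero
  expect_equal(gd$edges$effective_amplitude_nS[2], 0.05)
  expect_equal(gd$edges$effective_amplitude_nS[4:7], amp[4:7])
  gc <- apply_failure_model(g, "control")
  expect_equal(gc$edges$effective_amplitude_nS,
               amp * ifelse(amp <= 0.2, 0, ifelse(amp < 0.4, (amp - 0.2) / 0.2, 1)))
  gn <- apply_failure_model(g, "none")
  expect_equal(gn$edges$effective_amplitude_nS, amp)
  expect_error(apply_failure_model(g, "bogus"))
})

test_that("amplitude shuffling conserves the strength multiset", {
  fx <- fixture_net(12)
  g <- fx$graph
  g0 <- shuffle_amplitudes(g, n_swaps = 0, seed = 1)
  expect_equal(g0$edges$amplitude_nS, g$edges$amplitude_nS)
  gs <- shuffle_amplitudes(g, n_swaps = 5000, seed = 1)
  expect_equal(sort(gs$edges$amplitude_nS), sort(g$edges$amplitude_nS))
  expect_equal(sum(gs$edges$amplitude_nS), sum(g$edges$amplitude_nS))
  expect_identical(gs$edges[, c("pre", "post")], g$edges[, c("pre", "post")])
  expect_false(identical(gs$edges$amplitude_nS, g$edges$amplitude_nS))
  # effective amplitudes travel with the strengths
  expect_equal(sort(gs$edges$effective_amplitude_nS),
               sort(g$edges$effective_amplitude_nS))
})

test_that("distance-only wiring matches its target count and ignores tuning", {
  map <- generate_feature_map(grid_side = 15, seed = 3)
  g <- build_connectivity(map, seed = 5)
  target <- nrow(g$edges)
  gd <- distance_only_connectivity(map, target, seed = 6)
  expect_lt(abs(nrow(gd$edges) - target) / target, 0.05)
  # permuting the feature map leaves the sampled wiring unchanged
  map2 <- map
  map2$p1 <- rev(map2$p1); map2$p3 <- rev(map2$p3)
  gd2 <- distance_only_connectivity(map2, target, seed = 6)
  expect_equal(gd2$edges[, c("pre", "post")], gd$edges[, c("pre", "post")])
  # small toy map agrees with a brute-force pairwise replay
  map6 <- generate_feature_map(grid_side = 4, seed = 8)
  gsm <- distance_only_connectivity(map6, 40, seed = 9)
  pitch <- 1000 / 4
  off <- pmin(0:3, 4 - 0:3) * pitch
  pd_off <- sqrt(outer(off^2, off^2, "+")); pd_off[1, 1] <- NA
  k <- 40 / (sum(pmax(1 - pmax(pd_off, 7) / 600, 0), na.rm = TRUE) * 16)
  set.seed(9)
  keep <- list()
  for (i in 1:16) {
    for (j in 1:16) {
      if (i == j) next
      pd <- max(toroidal_distance(c(map6$x_um[i], map6$y_um[i]),
                                  c(map6$x_um[j], map6$y_um[j])), 7)
      if (runif(1) < k * max(1 - pd / 600, 0)) {
        keep[[length(keep) + 1]] <- c(i, j)
      }
    }
  }
  keep <- do.call(rbind, keep)
  expect_equal(gsm$edges$pre, keep[, 1])
  expect_equal(gsm$edges$post, keep[, 2])
})

test_that("columnar networks are more clustered than non-columnar", {
  gc <- build_network(generate_feature_map(36, "columnar", seed = 3), seed = 4)
  gn <- build_network(generate_feature_map(36, mode = "noncolumnar", seed = 3),
                      seed = 4)
  cn_c <- gc$edges$n_pre + gc$edges$n_post
  cn_n <- gn$edges$n_pre + gn$edges$n_post
  # heavier right tail of common-neighbor counts in the columnar network
  expect_gt(stats::quantile(cn_c / max(cn_c), 0.9),
            stats::quantile(cn_n / max(cn_n), 0.9))
  # more strong synapses (right-shifted normalized amplitude distribution)
  sc <- gc$edges$amplitude_nS / max(gc$edges$amplitude_nS)
  sn <- gn$edges$amplitude_nS / max(gn$edges$amplitude_nS)
  expect_gt(mean(sc > 0.5), mean(sn > 0.5))
})

test_that("binned connection frequency falls roughly linearly", {
  map <- generate_feature_map(grid_side = 30, seed = 2)
  g <- build_connectivity(map, seed = 3)
  # empirical P(connection) vs distance, compared over coarse bins
  n <- nrow(map)
  freq <- nrow(g$edges) / (n * (n - 1))
  expect_gt(freq, 0.02)
  bins <- cut(g$edges$pd_um, breaks = seq(0, 600, by = 100))
  counts <- as.numeric(table(bins))
  # connection counts per distance bin rise then fall (probability falls
  # linearly while the number of available pairs grows with distance)
  expect_gt(counts[1], 0)
  expect_lt(counts[6] / max(counts), 0.5)
})
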