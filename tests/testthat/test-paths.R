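# Contact-filtered path graphs and optimal coupling paths.

path_graph_fixture <- function(n, seed, p_edge = 0.5) {
  set.seed(seed)
  C <- matrix(0, n, n)
  pairs <- which(upper.tri(C), arr.ind = TRUE)
  corr <- runif(nrow(pairs), -1, 1)
  C[pairs] <- corr
  C <- C + t(C); diag(C) <- 1
  omega <- matrix(0, n, n)
  on <- runif(nrow(pairs)) < p_edge
  omega[pairs[on, , drop = FALSE]] <- 1
  omega <- pmax(omega, t(omega)); diag(omega) <- 1
  ids <- paste0("A:", 1:n)
  dimnames(C) <- list(ids, ids); dimnames(omega) <- list(ids, ids)
  cmap <- correlation_map(C, chain = rep("A", n), resno = 1:n)
  contacts <- structure(list(omega = omega, ids = ids,
                             chain = rep("A", n), resno = 1:n,
                             cutoff = 7.5, frames = NA),
                        class = "cdn_contacts")
  list(cmap = cmap, contacts = contacts)
}

test_that("path graph: contact filter boundary and 1-|C| weights", {
  fx <- path_graph_fixture(4, seed = 1, p_edge = 1)
  fx$contacts$omega["A:1", "A:2"] <- 0.49
  fx$contacts$omega["A:2", "A:1"] <- 0.49
  fx$contacts$omega["A:1", "A:3"] <- 0.50
  fx$contacts$omega["A:3", "A:1"] <- 0.50
  fx$cmap$C["A:1", "A:3"] <- fx$cmap$C["A:3", "A:1"] <- -0.8
  fx$cmap$C["A:2", "A:3"] <- fx$cmap$C["A:3", "A:2"] <- 1
  fx$cmap$C["A:2", "A:4"] <- fx$cmap$C["A:4", "A:2"] <- 0

  g <- build_path_graph(fx$cmap, fx$contacts)
  expect_false(igraph::are_adjacent(g$graph, "A:1", "A:2"))  # 0.49 < 0.5
  expect_true(igraph::are_adjacent(g$graph, "A:1", "A:3"))   # inclusive
  el <- igraph::as_data_frame(g$graph)
  w13 <- el$weight[(el$from == "A:1" & el$to == "A:3") |
                     (el$from == "A:3" & el$to == "A:1")]
  expect_equal(w13, 1 - 0.8)          # |C| in the weight
  w23 <- el$weight[(el$from == "A:2" & el$to == "A:3") |
                     (el$from == "A:3" & el$to == "A:2")]
  expect_equal(w23, 0)                # perfect coupling transfers free
  w24 <- el$weight[(el$from == "A:2" & el$to == "A:4") |
                     (el$from == "A:4" & el$to == "A:2")]
  expect_equal(w24, 1)                # uncorrelated costs 1
})

test_that("path graph rejects mismatched residue sets and warns on
           mismatched frames", {
  fx <- path_graph_fixture(4, seed = 2)
  other <- path_graph_fixture(5, seed = 3)
  expect_error(build_path_graph(fx$cmap, other$contacts), "different")
  fx$contacts$frames <- 100
  fx2 <- fx
  fx2$cmap$frames <- 50
  expect_warning(build_path_graph(fx2$cmap, fx$contacts),
                 "different\\s+trajectories")
})

test_that("query validation: empty, overlapping, absent residues", {
  expect_error(path_query(character(0), "A:2"), "non-empty")
  expect_error(path_query(c("A:1", "A:2"), c("A:2", "A:3")), "disjoint")
  fx <- path_graph_fixture(4, seed = 4, p_edge = 1)
  g <- build_path_graph(fx$cmap, fx$contacts)
  q <- path_query("A:1", "A:99")
  expect_error(shortest_path(g, q), "absent")
})

test_that("Dijkstra agrees with exhaustive simple-path enumeration", {
  for (seed in 1:100) {
    fx <- path_graph_fixture(8, seed = seed, p_edge = 0.45)
    g <- build_path_graph(fx$cmap, fx$contacts)
    res <- shortest_path(g, path_query("A:1", "A:8"))
    edges <- edges_from_graph(g)
    w <- igraph::E(g$graph)$weight
    best <- enumerate_shortest(edges, w, 8, 1, 8)
    row <- res$pairs[1, ]
    if (is.infinite(best)) {
      expect_true(row$unreachable)
    } else {
      expect_false(row$unreachable)
      expect_equal(row$length, best, tolerance = 1e-12)
      # reported length equals the sum of the per-edge weights
      expect_equal(row$length, sum(res$edge_weights[[1]]), tolerance = 1e-12)
    }
  }
})

test_that("deterministic tie-break prefers fewer hops then lexicographic
           order", {
  # two equal-length routes 1->4: direct (weight 0.6) and 1->2->4
  # (0.3 + 0.3); then a tie among 2-hop routes via 2 or 3
  C <- matrix(0, 4, 4)
  C[1, 4] <- C[4, 1] <- 0.4      # weight 0.6
  C[1, 2] <- C[2, 1] <- 0.7      # 0.3
  C[2, 4] <- C[4, 2] <- 0.7      # 0.3
  C[1, 3] <- C[3, 1] <- 0.7
  C[3, 4] <- C[4, 3] <- 0.7
  diag(C) <- 1
  ids <- paste0("A:", 1:4); dimnames(C) <- list(ids, ids)
  omega <- matrix(1, 4, 4, dimnames = list(ids, ids))
  cmap <- correlation_map(C, rep("A", 4), 1:4)
  contacts <- structure(list(omega = omega, ids = ids, chain = rep("A", 4),
                             resno = 1:4, cutoff = 7.5, frames = NA),
                        class = "cdn_contacts")
  g <- build_path_graph(cmap, contacts)
  res <- shortest_path(g, path_query("A:1", "A:4"))
  expect_equal(res$pairs$length[1], 0.6)
  expect_equal(res$pairs$path[1], "A:1 -> A:4")   # fewer hops wins the tie

  # remove the direct edge: now 1-2-4 and 1-3-4 tie; lexicographic wins
  C[1, 4] <- C[4, 1] <- 0
  cmap <- correlation_map(C, rep("A", 4), 1:4)
  g <- build_path_graph(cmap, contacts)
  res <- shortest_path(g, path_query("A:1", "A:4"))
  expect_equal(res$pairs$path[1], "A:1 -> A:2 -> A:4")
})

test_that("triangle inequality and contact-threshold monotonicity hold", {
  fx <- path_graph_fixture(10, seed = 7, p_edge = 0.6)
  fx$contacts$omega[fx$contacts$omega > 0] <-
    round(fx$contacts$omega[fx$contacts$omega > 0] * 0.6 + 0.4, 2)
  set.seed(7)
  ids <- fx$cmap$ids
  om <- fx$contacts$omega
  om[upper.tri(om)] <- sample(c(0.3, 0.6, 1), sum(upper.tri(om)), TRUE)
  om[lower.tri(om)] <- t(om)[lower.tri(om)]
  fx$contacts$omega <- om

  g5 <- build_path_graph(fx$cmap, fx$contacts, min_freq = 0.5)
  d <- igraph::distances(g5$graph, weights = igraph::E(g5$graph)$weight)
  for (s in 1:9) for (t in (s + 1):10) for (m in 1:10)
    expect_lte(d[s, t], d[s, m] + d[m, t] + 1e-12)

  # raising the contact threshold never shortens any path
  g9 <- build_path_graph(fx$cmap, fx$contacts, min_freq = 0.9)
  d9 <- igraph::distances(g9$graph, weights = igraph::E(g9$graph)$weight)
  fin <- is.finite(d9)
  expect_true(all(d9[fin] - d[fin] >= -1e-12))

  # path lengths are blind to the sign of the correlation
  neg <- fx
  neg$cmap <- correlation_map(-fx$cmap$C + 2 * diag(10),
                              rep("A", 10), 1:10)
  gneg <- build_path_graph(neg$cmap, fx$contacts, min_freq = 0.5)
  dneg <- igraph::distances(gneg$graph,
                            weights = igraph::E(gneg$graph)$weight)
  expect_equal(dneg, d, tolerance = 1e-12)
})

test_that("region queries report the pair matrix, best path, and census", {
  fx <- path_graph_fixture(6, seed = 11, p_edge = 1)
  g <- build_path_graph(fx$cmap, fx$contacts)
  res <- shortest_path(g, path_query(c("A:1", "A:2"), c("A:5", "A:6")))
  expect_equal(nrow(res$pairs), 4)
  expect_false(is.na(res$best))
  expect_equal(min(res$pairs$length), res$pairs$length[res$best])
  # census counts nodes on the four optimal paths
  expect_equal(sum(res$census$count),
               sum(lengths(res$paths[!res$pairs$unreachable])))

  # unreachable pairs are flagged, not errored
  fx$contacts$omega[,] <- 0
  diag(fx$contacts$omega) <- 1
  fx$contacts$omega["A:1", "A:2"] <- fx$contacts$omega["A:2", "A:1"] <- 1
  g2 <- build_path_graph(fx$cmap, fx$contacts)
  res2 <- shortest_path(g2, path_query("A:1", "A:5"))
  expect_true(res2$pairs$unreachable[1])
  expect_true(is.na(res2$pairs$length[1]))
})
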