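# Coupling-graph construction, critical-cutoff selection, bottleneck
# detection, and the static contact-count contrast network.

two_clique_bridge <- function() {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 0.8
  W[6:10, 6:10] <- 0.8
  W[5, 6] <- W[6, 5] <- 0.4
  W
}

test_that("graph construction: complete, empty, and bridged cases", {
  cm <- random_cmap(6, seed = 1)
  g0 <- build_coupling_graph(cm, 0)
  expect_equal(igraph::ecount(g0$graph), choose(6, 2))
  expect_equal(length(g0$largest), 6)

  g1 <- build_coupling_graph(cm, 1)       # above every off-diagonal weight
  expect_equal(igraph::ecount(g1$graph), 0)
  expect_equal(length(g1$largest), 1)

  g <- graph_from_weights(two_clique_bridge(), 0.5)
  comp_sizes <- sort(as.integer(table(g$membership)), decreasing = TRUE)
  expect_equal(comp_sizes, c(5, 5))
  # tie on size: largest component is the one holding the smallest residue
  expect_true("A:1" %in% g$largest)
  # retention is inclusive at the cutoff
  g2 <- graph_from_weights(two_clique_bridge(), 0.4)
  expect_true(igraph::are_adjacent(g2$graph, "A:5", "A:6"))
  expect_equal(length(g2$largest), 10)
})

test_that("missing correlations never become edges", {
  W <- two_clique_bridge()
  W[1, 2] <- W[2, 1] <- NA
  g <- graph_from_weights(W, 0.5)
  expect_false(igraph::are_adjacent(g$graph, "A:1", "A:2"))
})

test_that("cutoff selection finds the percolation transition of the
           two-clique bridge", {
  cm <- cmap_from_matrix(two_clique_bridge())
  expect_warning(select_cutoff(cm), "sharp transition")
  scan <- suppressWarnings(select_cutoff(cm))
  # candidates are the distinct weights; f drops 1.0 -> 0.5 once the bridge
  # is cut (cutoff above 0.4), and the 0.5 crossing is selected
  expect_equal(scan$cutoff, c(0, 0.4, 0.8))
  expect_equal(scan$fraction, c(1.0, 1.0, 0.5))
  expect_equal(attr(scan, "selected"), 0.8)
  expect_equal(scan$fraction[scan$cutoff == attr(scan, "selected")], 0.5)
})

test_that("degenerate all-equal map still selects by rule, with warnings", {
  W <- matrix(0.6, 5, 5)
  cm <- cmap_from_matrix(W)
  warns <- character(0)
  scan <- withCallingHandlers(select_cutoff(cm), warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  expect_equal(attr(scan, "selected"), 0.6)
  expect_true(any(grepl("no cutoff reaches", warns)))
  expect_true(any(grepl("sharp transition", warns)))
})

test_that("largest-component fraction is non-increasing in the cutoff", {
  for (seed in 1:100) {
    cm <- random_cmap(12, seed = seed)
    scan <- suppressWarnings(select_cutoff(cm))
    expect_true(all(diff(scan$fraction) <= 1e-12))
    expect_true(attr(scan, "selected") %in% scan$cutoff)
    # selected = smallest candidate at or under the target
    under <- scan$cutoff[scan$fraction <= 0.5]
    if (length(under) > 0) expect_equal(attr(scan, "selected"), min(under))
  }
})

test_that("structural critical-node cases: cycle, path, barbell", {
  # cycle: 2-connected, no critical nodes
  W <- matrix(0, 24, 24)
  for (i in 1:24) { j <- i %% 24 + 1; W[i, j] <- W[j, i] <- 0.9 }
  cyc <- find_critical_nodes(graph_from_weights(W, 0.5), 3)
  expect_equal(sum(cyc$is_critical), 0)

  # path of 25: positions 11..15 split both sides >= 10
  W <- matrix(0, 25, 25)
  for (i in 1:24) W[i, i + 1] <- W[i + 1, i] <- 0.9
  pg <- find_critical_nodes(graph_from_weights(W, 0.5), 10)
  expect_equal(sort(pg$resno[pg$is_critical]), 11:15)
  # interior non-critical nodes are still articulation points
  expect_equal(pg$n_components[pg$resno == 5], 2)

  # barbell: two 12-cliques joined through one shared linker node (13)
  W <- matrix(0, 25, 25)
  W[1:13, 1:13] <- 0.9
  W[13:25, 13:25] <- 0.9
  bb <- find_critical_nodes(graph_from_weights(W, 0.5), 10)
  expect_equal(bb$id[bb$is_critical], "A:13")
  sizes <- attr(bb, "component_sizes")[["A:13"]]
  expect_equal(sizes, c(12, 12))
})

test_that("component sizes after each removal account for every node", {
  g <- graph_from_weights(two_clique_bridge(), 0.3)
  rep10 <- find_critical_nodes(g, 2)
  sizes <- attr(rep10, "component_sizes")
  for (v in rep10$id)
    expect_equal(sum(sizes[[v]]), length(g$largest) - 1)
})

test_that("critical nodes agree with brute-force removal and are
           articulation points (random graphs)", {
  for (seed in 1:60) {
    set.seed(seed)
    n <- sample(10:40, 1)
    p <- runif(1, 0.05, 0.25)
    W <- matrix(0, n, n)
    pairs <- which(upper.tri(W), arr.ind = TRUE)
    on <- runif(nrow(pairs)) < p
    W[pairs[on, , drop = FALSE]] <- runif(sum(on), 0.5, 1)
    W <- pmax(W, t(W))
    g <- graph_from_weights(W, 0.4)
    minc <- sample(2:5, 1)
    rep_ <- find_critical_nodes(g, minc)

    edges <- edges_from_graph(g)
    oracle <- brute_critical(edges, n, minc)
    expect_setequal(rep_$resno[rep_$is_critical], oracle$critical)

    # every critical node is an articulation point of the largest component
    members <- oracle$members
    sub <- edges[edges[, 1] %in% members & edges[, 2] %in% members,
                 , drop = FALSE]
    sub2 <- cbind(match(sub[, 1], members), match(sub[, 2], members))
    aps <- members[dfs_articulation(sub2, length(members))]
    expect_true(all(rep_$resno[rep_$is_critical] %in% aps))

    # removing a non-articulation member leaves one component of size - 1
    non_ap <- setdiff(members, aps)
    for (v in utils::head(non_ap, 3)) {
      row <- rep_[rep_$resno == v, ]
      expect_equal(row$n_components, 1L)
      expect_equal(row$largest_after, length(members) - 1L)
    }
  }
})

test_that("critical-node detection is invariant under residue relabeling", {
  W <- two_clique_bridge()
  g <- graph_from_weights(W, 0.3)
  ref <- find_critical_nodes(g, 4)

  set.seed(99)
  perm <- sample(10)
  Wp <- W[perm, perm]
  gp <- graph_from_weights(Wp, 0.3)
  shuffled <- find_critical_nodes(gp, 4)
  # map shuffled residue numbers back through the permutation
  back <- perm[shuffled$resno[shuffled$is_critical]]
  expect_setequal(back, ref$resno[ref$is_critical])
})

test_that("static contact network counts heavy-atom pairs", {
  # 3 residues: A-B share 2 contact pairs, B-C one, A-C none; H ignored
  at <- data.frame(
    elety = c("CA", "CB", "H", "CA", "CB", "CA"),
    resid = "ALA", chain = "A",
    resno = c(1, 1, 1, 2, 2, 3), stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(1, 0, 0), c(1.5, 0, 0),
               c(2, 0, 0), c(3, 0, 0), c(6.5, 0, 0))
  coords <- array(0, dim = c(1, 6, 3))
  coords[1, , ] <- xyz
  traj2 <- trajectory(coords, at)
  g <- build_static_contact_graph(traj2, contact_distance = 4)
  el <- igraph::as_data_frame(g$graph)
  ab <- el$count[(el$from == "A:1" & el$to == "A:2") |
                   (el$from == "A:2" & el$to == "A:1")]
  bc <- el$count[(el$from == "A:2" & el$to == "A:3") |
                   (el$from == "A:3" & el$to == "A:2")]
  expect_equal(ab, 4L)   # hand count: (CA1,CA2) 2A, (CA1,CB2) 3A,
                         # (CB1,CA2) 1A, (CB1,CB2) 2A
  expect_equal(bc, 1L)   # only CB2-CA3 at 3.5 A
  expect_false(any((el$from == "A:1" & el$to == "A:3") |
                     (el$from == "A:3" & el$to == "A:1")))
  expect_equal(max(el$weight), 1)   # normalised by the maximum count

  # doubling the distance never shrinks a weight
  g2 <- build_static_contact_graph(traj2, contact_distance = 8)
  el2 <- igraph::as_data_frame(g2$graph)
  for (r in seq_len(nrow(el))) {
    m <- el2$count[(el2$from == el$from[r] & el2$to == el$to[r]) |
                     (el2$from == el$to[r] & el2$to == el$from[r])]
    expect_gte(m, el$count[r])
  }
})

test_that("static contact network rejects multi-frame input", {
  traj <- random_traj(3, 4, seed = 2)
  expect_error(build_static_contact_graph(traj), "one frame")
})
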