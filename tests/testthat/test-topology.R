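# Topological measures against hand-computed values and brute-force oracles.

test_that("degrees, mean degree and P(k) on canonical small graphs", {
  star <- graph_from_spec("A-B,A-C,A-D,A-E")
  k <- node_degrees(star)
  expect_equal(k[["A"]], 4)
  expect_equal(unname(k[c("B", "C", "D", "E")]), rep(1, 4))

  tri <- graph_from_spec("A-B,B-C,C-A")
  expect_equal(unname(node_degrees(tri)), rep(2, 3))
  expect_equal(mean_degree(tri), 2)

  k4 <- graph_from_spec("A-B,A-C,A-D,B-C,B-D,C-D")
  expect_equal(mean_degree(k4), 3)

  edgeless <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(edgeless)$name <- c("A", "B", "C")
  expect_equal(mean_degree(edgeless), 0)
  expect_error(mean_degree(star, nodes = character()), "no nodes")

  dd <- degree_distribution(node_degrees(star))
  expect_equal(dd$p[dd$k == 4], 1 / 5)
  expect_equal(dd$p[dd$k == 1], 4 / 5)
  ring <- graph_from_spec("A-B,B-C,C-D,D-A")
  expect_equal(degree_distribution(node_degrees(ring)),
               data.frame(k = 2L, p = 1))
})

test_that("P(k) sums to 1 and reproduces brute-force tallies; mean matches", {
  set.seed(21)
  for (rep in 1:10) {
    A <- random_adjacency(sample(5:14, 1), runif(1, 0.15, 0.6))
    g <- adjacency_to_graph(A)
    k <- node_degrees(g)
    expect_equal(unname(k[rownames(A)]), unname(rowSums(A)))  # edge-scan oracle
    dd <- degree_distribution(k)
    expect_equal(sum(dd$p), 1, tolerance = 1e-12)
    expect_equal(sum(dd$k * dd$p), mean_degree(g))
    tally <- table(rowSums(A))
    expect_equal(dd$p, as.numeric(tally) / nrow(A))
  }
})

test_that("clustering coefficient handles canonical cases and trees", {
  tri <- graph_from_spec("A-B,B-C,C-A")
  expect_equal(unname(clustering_coefficients(tri)), rep(1, 3))

  star <- graph_from_spec("A-B,A-C,A-D,A-E")
  cc <- clustering_coefficients(star)
  expect_equal(cc[["A"]], 0)
  expect_true(all(is.na(cc[c("B", "C", "D", "E")])))

  # K4 minus one edge: two degree-3 nodes C=2/3, two degree-2 nodes C=1
  g <- graph_from_spec("A-B,A-C,A-D,B-C,B-D")
  cc <- clustering_coefficients(g)
  expect_equal(cc[["A"]], 2 / 3)
  expect_equal(cc[["B"]], 2 / 3)
  expect_equal(cc[["C"]], 1)
  expect_equal(cc[["D"]], 1)

  # any tree: C = 0 wherever defined
  set.seed(8)
  tree <- igraph::sample_tree(20)
  igraph::V(tree)$name <- paste0("T", 1:20)
  cct <- clustering_coefficients(tree)
  expect_true(all(cct[!is.na(cct)] == 0))
})

test_that("betweenness on canonical graphs, both variants", {
  path <- graph_from_spec("A-B,B-C")
  expect_equal(unname(node_betweenness(path)), c(0, 1, 0))
  expect_equal(unname(node_betweenness(path, "raw_count")), c(0, 1, 0))

  star <- graph_from_spec("A-B,A-C,A-D,A-E")
  expect_equal(node_betweenness(star)[["A"]], choose(4, 2))
  expect_equal(node_betweenness(star, "raw_count")[["A"]], choose(4, 2))

  ring5 <- graph_from_spec("A-B,B-C,C-D,D-E,E-A")
  expect_equal(unname(node_betweenness(ring5)), rep(1, 5))

  # complete graph: B = 0, C = 1, gSPD = cSPD = 1
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- LETTERS[1:5]
  expect_equal(unname(node_betweenness(k5)), rep(0, 5))
  expect_equal(unname(clustering_coefficients(k5)), rep(1, 5))
  ps <- map_protein_set(c("A", "B"), k5)
  expect_equal(unname(gspd(k5, ps)$values), c(1, 1))
  expect_equal(unname(cspd(k5, ps)$values), c(1, 1))
})

test_that("shortest_path_lengths is a BFS restricted to the component", {
  path <- graph_from_spec("A-B,B-C")
  expect_equal(shortest_path_lengths(path, "A"), c(A = 0, B = 1, C = 2))
  two <- graph_from_spec("A-B,C-D")
  expect_equal(sort(names(shortest_path_lengths(two, "A"))), c("A", "B"))
  expect_error(shortest_path_lengths(path, "Z"), "not in network")

  set.seed(14)
  A <- random_adjacency(30, 0.12)
  g <- adjacency_to_graph(A)
  D <- bf_distances(A)          # Floyd-Warshall oracle
  for (s in c("A", "M", "Z")) {
    d <- shortest_path_lengths(g, s)
    row <- D[s, ][is.finite(D[s, ])]
    expect_equal(d[sort(names(d))], row[sort(names(row))])
  }
})

test_that("gSPD and cSPD match hand computation and the pairwise oracle", {
  path <- graph_from_spec("A-B,B-C")
  net <- path
  ps_a <- map_protein_set("A", net)
  expect_equal(gspd(path, ps_a)$values[["A"]], 1.5)   # (1 + 2) / 2
  ps_ac <- map_protein_set(c("A", "C"), net)
  expect_equal(unname(cspd(path, ps_ac)$values), c(2, 2))

  expect_error(gspd(path, map_protein_set(c("A", "B", "C"), net)),
               "covers network")
  expect_error(cspd(path, ps_a), "at least 2")

  set.seed(19)
  for (rep in 1:8) {
    A <- random_adjacency(12, runif(1, 0.15, 0.5))
    g <- adjacency_to_graph(A)
    members <- sample(rownames(A), sample(2:8, 1))
    ps <- map_protein_set(members, g)
    expect_equal(gspd(g, ps)$values[sort(members)],
                 bf_setdist(A, sort(members), within = FALSE))
    expect_equal(cspd(g, ps)$values[sort(members)],
                 bf_setdist(A, sort(members), within = TRUE))
  }
})

test_that("hub classification uses a strict cutoff", {
  expect_equal(classify_hubs(c(1, 6, 13), 5), list(count = 2, fraction = 2 / 3))
  expect_equal(classify_hubs(c(1, 6, 13), 12), list(count = 1, fraction = 1 / 3))
  expect_equal(classify_hubs(c(1, 6, 13), 13)$count, 0)   # strict >
  expect_equal(classify_hubs(c(2, 3, 4), 0)$fraction, 1)
  expect_error(classify_hubs(numeric(), 5), "empty")
})

test_that("build_profile assembles measures and set averages consistently", {
  k4 <- graph_from_spec("A-B,A-C,A-D,B-C,B-D,C-D")
  net <- k4
  prof <- build_profile(net, map_protein_set(c("A", "B"), net, "pair"))
  expect_equal(prof$summary$connectivity, 3)
  expect_equal(prof$summary$clustering, 1)
  expect_equal(prof$summary$gSPD, 1)
  expect_equal(prof$summary$cSPD, 1)
  expect_equal(prof$summary$betweenness, 0)
  expect_equal(prof$hubs$count[prof$hubs$cutoff == 5], 0)

  # set covering the whole network: gSPD undefined, everything else filled
  tri <- graph_from_spec("A-B,B-C,C-A")
  tnet <- tri
  pall <- build_profile(tnet, map_protein_set(c("A", "B", "C"), tnet, "all"))
  expect_true(is.na(pall$summary$gSPD))
  expect_equal(pall$summary$clustering, 1)

  # set averages equal independent recomputation from the raw per-node maps
  w <- test_world()
  prof <- build_profile(w$net, w$sets$cancer)
  members <- sort(w$sets$cancer$mapped)
  expect_equal(prof$summary$connectivity,
               mean(node_degrees(w$net)[members]))
  expect_equal(prof$summary$betweenness,
               mean(node_betweenness(w$net)[members]))
  cc <- clustering_coefficients(w$net)[members]
  expect_equal(prof$summary$clustering, mean(cc, na.rm = TRUE))
  expect_equal(prof$summary$gSPD, gspd(w$net, w$sets$cancer)$average)
  expect_equal(prof$summary$cSPD, cspd(w$net, w$sets$cancer)$average)
})

test_that("raw-count betweenness equals the path-enumeration oracle", {
  set.seed(33)
  for (rep in 1:20) {
    A <- random_adjacency(sample(5:10, 1), runif(1, 0.2, 0.6))
    g <- adjacency_to_graph(A)
    expect_equal(node_betweenness(g, "raw_count")[rownames(A)],
                 bf_betweenness(A, "raw_count"))
  }
})
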