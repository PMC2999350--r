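# Induced subnetworks, G(n,m) nulls, empirical p-values, centralization.

test_that("induced_subnetwork keeps only within-set edges", {
  k4 <- graph_from_spec("A-B,A-C,A-D,B-C,B-D,C-D")
  sub <- induced_subnetwork(k4, map_protein_set(c("A", "B"), k4, "pair"))
  expect_equal(sub$n_edges, 1)
  expect_equal(length(sub$components), 1)

  g <- graph_from_spec("A-B,C-D,B-C")
  sub2 <- induced_subnetwork(g, map_protein_set(c("A", "D"), g, "apart"))
  expect_equal(sub2$n_edges, 0)
  expect_equal(sub2$n_linked, 0)

  # edge count equals a brute-force filter of the parent edge list
  w <- test_world()
  sub3 <- induced_subnetwork(w$net, w$sets$cancer)
  ed <- interactome_edges(w$net)
  inset <- ed$a %in% w$sets$cancer$mapped & ed$b %in% w$sets$cancer$mapped
  expect_equal(sub3$n_edges, sum(inset))
  expect_equal(sub3$n_linked,
               length(unique(c(ed$a[inset], ed$b[inset]))))
})

test_that("er_gnm: forced cases, handshake identity, uniform pair inclusion", {
  k4 <- er_gnm(4, 6, seed = 1)
  expect_equal(igraph::ecount(k4), 6)
  expect_equal(igraph::vcount(k4), 4)
  expect_true(igraph::is_simple(k4))

  g <- er_gnm(254, 595, seed = 2)
  expect_equal(sum(igraph::degree(g)), 2 * 595)
  expect_error(er_gnm(4, 7), "out of range")

  # same seed -> identical graph
  expect_identical(igraph::as_edgelist(er_gnm(20, 30, seed = 5)),
                   igraph::as_edgelist(er_gnm(20, 30, seed = 5)))

  # uniformity: every specific pair appears with frequency ~ m / C(n,2)
  set.seed(9)
  n <- 20L; m <- 30L; reps <- 2000L
  hits <- matrix(0L, n, n)
  for (i in seq_len(reps)) {
    el <- igraph::as_edgelist(igraph::sample_gnm(n, m), names = FALSE)
    hits[el] <- hits[el] + 1L
    hits[el[, 2:1]] <- hits[el[, 2:1]] + 1L
  }
  freq <- hits[upper.tri(hits)] / reps
  p0 <- m / choose(n, 2)
  bound <- 3 * sqrt(p0 * (1 - p0) / reps)
  expect_true(all(abs(freq - p0) <= bound + 1e-9))
})

test_that("null_summaries matches hand values and the brute-force oracle", {
  k4 <- graph_from_spec("A-B,A-C,A-D,B-C,B-D,C-D")
  s <- null_summaries(k4)
  expect_equal(s$C, 1)
  expect_equal(s$L, 1)
  expect_equal(s$B, 0)

  p3 <- graph_from_spec("A-B,B-C")
  s3 <- null_summaries(p3)
  expect_equal(s3$L, 4 / 3)
  expect_equal(s3$B, 1 / 3)

  expect_error(null_summaries(igraph::make_empty_graph(3, directed = FALSE)),
               "L undefined")

  set.seed(27)
  for (rep in 1:5) {
    A <- random_adjacency(30, 0.1)
    g <- adjacency_to_graph(A)
    if (igraph::ecount(g) == 0) next
    s <- null_summaries(g)
    D <- bf_distances(A)
    d <- D[upper.tri(D)]
    expect_equal(s$L, mean(d[is.finite(d) & d > 0]))
    cc <- bf_clustering(A)
    expect_equal(s$C, mean(cc, na.rm = TRUE))
    expect_equal(s$B, mean(bf_betweenness(A, "pair_dependency")))
  }
})

test_that("randomization_test counts strict exceedances and is reproducible", {
  obs <- list(B = 1e9, C = -1, L = 0.5)
  r <- randomization_test(obs, n = 30, m = 60, reps = 40, seed = 3)
  expect_equal(r$counts$n_B, 0)      # nothing above an absurdly high B
  expect_equal(r$counts$n_C, 40)     # everything above C = -1
  expect_equal(r$counts$n_L, 0)      # nothing below L = 0.5
  expect_equal(r$p$p_C, 1)
  expect_equal(r$p$p_B, 0)

  r2 <- randomization_test(obs, n = 30, m = 60, reps = 40, seed = 3)
  expect_identical(r, r2)            # bit-for-bit under the same seed
  expect_error(randomization_test(obs, n = 30, m = 60, reps = 0), "reps")

  # empirical p antitone in observed B/C thresholds, monotone for L
  set.seed(8)
  thresholds <- c(0.0, 0.02, 0.05, 0.2)
  pc <- sapply(thresholds, function(th)
    randomization_test(list(B = NA, C = th, L = NA), n = 40, m = 90,
                       reps = 60, seed = 7)$p$p_C)
  expect_true(all(diff(pc) <= 0))
  pl <- sapply(c(1.5, 2.0, 2.5, 3.0), function(th)
    randomization_test(list(B = NA, C = NA, L = th), n = 40, m = 90,
                       reps = 60, seed = 7)$p$p_L)
  expect_true(all(diff(pl) >= 0))
})

test_that("subnetwork-driven randomization uses the linked node counts", {
  w <- test_world()
  sub <- induced_subnetwork(w$net, w$sets$cancer)
  r <- randomization_test(sub, reps = 30, seed = 5)
  expect_equal(r$n_nodes, sub$n_linked)
  expect_equal(r$n_edges, sub$n_edges)
  expect_true(all(unlist(r$counts) >= 0 & unlist(r$counts) <= 30))
})

test_that("degree centralization: star 1, regular 0, P4 one-third", {
  star <- graph_from_spec("A-B,A-C,A-D,A-E")
  expect_equal(degree_centralization(star), 1)
  ring <- graph_from_spec("A-B,B-C,C-D,D-A")
  expect_equal(degree_centralization(ring), 0)
  k5 <- igraph::make_full_graph(5)
  expect_equal(degree_centralization(k5), 0)
  p4 <- graph_from_spec("A-B,B-C,C-D")
  expect_equal(degree_centralization(p4), 1 / 3)   # (1+0+0+1) / (3*2)
  expect_error(degree_centralization(graph_from_spec("A-B")), "at least 3")

  # in [0,1] on random graphs; 1 only for the star
  set.seed(16)
  for (rep in 1:10) {
    g <- adjacency_to_graph(random_adjacency(sample(4:15, 1), runif(1, .2, .7)))
    ce <- degree_centralization(g)
    expect_gte(ce, 0); expect_lte(ce, 1)
  }
})

test_that("removal_effect recomputes centralization on the deleted graph", {
  star <- graph_from_spec("A-B,A-C,A-D,A-E")
  r <- removal_effect(star, "A")
  expect_equal(r$before, 1)
  expect_equal(r$after, 0)

  # adding an isolated node to P4 keeps the numerator, shrinks the scale
  p4z <- graph_from_spec("A-B,B-C,C-D", isolates = "Z")
  r2 <- removal_effect(p4z, "Z")
  # before: degrees (1,2,2,1,0), kmax=2 -> (1+0+0+1+2)/(4*3); after: P4
  expect_equal(r2$before, 4 / 12)
  expect_equal(r2$after, 1 / 3)

  expect_error(removal_effect(star, "Q"), "not in graph")
  expect_error(removal_effect(star, c("A", "B", "C")), "fewer than 3")

  # removing the top-degree hubs of a heavy-tailed subnetwork lowers
  # centralization in nearly all replicates
  net <- test_pa_network()
  set.seed(31)
  drops <- 0L
  for (i in 1:100) {
    ps <- plant_set(net, 150, alpha = 1.2, seed = 1000 + i, name = "s")
    sub <- induced_subnetwork(net, ps)
    k <- igraph::degree(sub$graph)
    keep <- names(sort(k, decreasing = TRUE))[1:4]
    r <- removal_effect(sub$graph, keep)
    if (r$after < r$before) drops <- drops + 1L
  }
  expect_gte(drops, 90)
})
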