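test_that("modularity matches hand-computed fixtures", {
  tri <- two_triangles()
  expect_equal(modularity_score(tri, rep(1, 6)), 0)
  expect_equal(modularity_score(tri, c(1, 1, 1, 2, 2, 2)), 0.5)
  k4 <- network_from_adjacency(matrix(1, 4, 4) - diag(4))
  expect_equal(modularity_score(k4, c(1, 1, 2, 2)), -1 / 6)
  empty <- weighted_network(data.frame(from = integer(), to = integer(),
                                       weight = numeric()), 3)
  expect_error(modularity_score(empty, rep(1, 3)), "edgeless")
})

test_that("modularity agrees with igraph on random weighted graphs", {
  for (i in 1:25) {
    net <- rand_network(sample(5:20, 1), p = 0.4, seed = 500 + i)
    part <- sample.int(4, net$n_nodes, replace = TRUE)
    expect_equal(modularity_score(net, part),
                 igraph::modularity(as_igraph(net), part,
                                    weights = net$edges$weight),
                 tolerance = 1e-12)
  }
})

test_that("surprise matches closed-form fixtures and conventions", {
  tri <- two_triangles()
  s <- asymptotical_surprise(tri, c(1, 1, 1, 2, 2, 2))
  expect_equal(s$value, 6 * log(2.5), tolerance = 1e-12)
  expect_equal(s$q, 1)
  expect_equal(s$q_expected, 0.4)
  # trivial partitions carry no surprise
  expect_equal(asymptotical_surprise(tri, rep(1, 6))$value, 0)
  expect_equal(asymptotical_surprise(tri, 1:6)$value, 0)
  # density at expectation: zero divergence
  k4 <- network_from_adjacency(matrix(1, 4, 4) - diag(4))
  s4 <- asymptotical_surprise(k4, c(1, 1, 2, 2))
  expect_equal(s4$q - s4$q_expected, 0)
  expect_equal(s4$value, 0)
})

test_that("scores are invariant under relabeling and node permutation", {
  net <- rand_network(12, p = 0.4, seed = 21)
  part <- sample.int(3, 12, replace = TRUE)
  relab <- c(7, 2, 9)[part]
  expect_equal(modularity_score(net, relab), modularity_score(net, part))
  expect_equal(asymptotical_surprise(net, relab)$value,
               asymptotical_surprise(net, part)$value)
  perm <- sample.int(12)
  pm <- integer(12)
  pm[perm] <- seq_len(12)
  e <- net$edges
  pnet <- weighted_network(data.frame(from = perm[e$from], to = perm[e$to],
                                      weight = e$weight), 12)
  expect_equal(modularity_score(pnet, part[pm]),
               modularity_score(net, part))
  expect_equal(asymptotical_surprise(pnet, part[pm])$value,
               asymptotical_surprise(net, part)$value)
})

test_that("louvain recovers planted clique structure deterministically", {
  cb <- two_cliques_bridge()
  part <- louvain_communities(cb, seed = 4, n_restarts = 8)
  expect_equal(as.vector(part), rep(1:2, each = 4))
  expect_equal(attr(part, "score"), modularity_score(cb, part))
  # single clique: no split improves on one community
  k5 <- network_from_adjacency(matrix(1, 5, 5) - diag(5))
  expect_equal(n_communities(louvain_communities(k5, seed = 1)), 1)
  # determinism
  expect_identical(as.vector(louvain_communities(cb, seed = 4)),
                   as.vector(louvain_communities(cb, seed = 4)))
})

test_that("paco recovers planted structure exactly on fixtures", {
  expect_equal(as.vector(paco_communities(two_triangles(), seed = 3,
                                          n_trials = 8)),
               rep(1:2, each = 3))
  expect_equal(as.vector(paco_communities(two_cliques_bridge(), seed = 3,
                                          n_trials = 8)),
               rep(1:2, each = 4))
  expect_identical(as.vector(paco_communities(two_triangles(), seed = 5)),
                   as.vector(paco_communities(two_triangles(), seed = 5)))
})

test_that("infomap adapter partitions and reports errors per contract", {
  part <- infomap_communities(two_triangles(), seed = 2)
  expect_equal(n_communities(part), 2)
  expect_equal(as.vector(part), rep(1:2, each = 3))
  expect_error(infomap_communities(two_triangles(), backend = "command",
                                   command = "no-such-binary-on-path"),
               "configuration error")
})

test_that("detect_communities dispatches the three methods", {
  tri <- two_triangles()
  for (m in c("newman", "surprise", "infomap")) {
    p <- detect_communities(tri, method = m, seed = 1, restarts = 4)
    expect_equal(n_communities(p), 2)
  }
  expect_error(detect_communities(tri, method = "walktrap"))
})
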