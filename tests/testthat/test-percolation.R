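test_that("sparsify keeps edges at or above the threshold and is idempotent", {
  net <- path3()
  expect_identical(sparsify(net, 0)$edges, net$edges)
  s6 <- sparsify(net, 0.6)
  expect_equal(nrow(s6$edges), 1)
  expect_equal(s6$edges$weight, 0.9)
  expect_equal(s6$n_nodes, 3)
  expect_identical(sparsify(s6, 0.6)$edges, s6$edges)
  expect_equal(nrow(sparsify(net, 2)$edges), 0)
  expect_error(sparsify(net, -0.1), "non-negative")
})

test_that("giant component sizes and tie-breaking are correct", {
  tri <- two_triangles()
  g <- giant_component(tri)
  expect_equal(g$size, 3)
  expect_equal(g$members, 1:3) # tie between triangles -> lowest ids
  expect_equal(giant_component(sparsify(path3(), 0.6))$size, 2)
  empty <- weighted_network(data.frame(from = integer(), to = integer(),
                                       weight = numeric()), 4)
  expect_equal(giant_component(empty)$size, 1)
})

test_that("giant sizes agree with a union-find oracle on random graphs", {
  for (i in 1:100) {
    net <- rand_network(sample(5:50, 1), p = runif(1, 0.03, 0.3),
                        seed = 300 + i)
    expect_equal(giant_component(net)$size, uf_giant_size(net))
  }
})

test_that("profile on the 3-node path matches exhaustive evaluation", {
  prof <- percolation_profile(path3())
  expect_equal(prof$thresholds, c(0.5, 0.9))
  expect_equal(prof$giant_sizes, c(3L, 2L))
  expect_equal(prof$t_star, 0.5)
  expect_equal(percolation_threshold(path3()), 0.5)
})

test_that("uniform-weight clique and star have closed-form thresholds", {
  idx <- t(utils::combn(5, 2))
  clique <- weighted_network(data.frame(from = idx[, 1], to = idx[, 2],
                                        weight = 0.7), 5)
  prof <- percolation_profile(clique)
  expect_equal(prof$thresholds, 0.7)
  expect_equal(prof$giant_sizes, 5L)
  expect_equal(prof$t_star, 0.7)
  # star: removing any spoke isolates a leaf
  spokes <- seq(0.2, 0.9, 0.1)
  star <- weighted_network(data.frame(from = 1, to = 2:9, weight = spokes),
                           9)
  expect_equal(percolation_threshold(star), min(spokes))
})

test_that("giant size is non-increasing along the threshold grid", {
  for (i in 1:20) {
    net <- rand_network(sample(10:40, 1), p = runif(1, 0.1, 0.4),
                        seed = 400 + i)
    prof <- suppressWarnings(percolation_profile(net))
    expect_true(all(diff(prof$giant_sizes) <= 0))
    expect_true(prof$t_star %in% prof$thresholds)
    g0 <- giant_component(net)$size
    expect_equal(prof$giant_sizes[1], g0)
  }
})

test_that("maxdrop rule finds the largest break", {
  # path: giant 3 -> 2 when the 0.9 threshold removes the 0.5 edge
  expect_equal(percolation_threshold(path3(), tstar_rule = "maxdrop"), 0.9)
})

test_that("quantile grids bound the sweep and still contain t*", {
  net <- rand_network(40, p = 0.3, seed = 77)
  prof <- suppressWarnings(percolation_profile(net, grid = "quantile:15"))
  expect_lte(length(prof$thresholds), 15)
  expect_true(prof$t_star %in% prof$thresholds)
  expect_error(percolation_profile(net, grid = "bogus"), "grid")
})

test_that("disconnected inputs warn and use the giant component", {
  expect_warning(percolation_profile(two_triangles()), "disconnected")
})

test_that("profile CSV records thresholds, sizes and t*", {
  path <- withr::local_tempfile(fileext = ".csv")
  prof <- percolation_profile(path3())
  write_profile_csv(prof, path)
  lines <- readLines(path)
  expect_match(lines[1], "t_star=0.5")
  back <- utils::read.csv(path, comment.char = "#")
  expect_equal(back$threshold, prof$thresholds)
  expect_equal(back$giant_size, prof$giant_sizes)
})
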