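test_that("degree and degree centrality on canonical small graphs", {
  k4 <- toy_graph(4, c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4))
  expect_equal(node_degrees(k4), rep(3, 4))
  expect_equal(degree_centralities(k4), rep(1, 4))
  path3 <- toy_graph(3, c(1,2, 2,3))
  expect_equal(node_degrees(path3), c(1, 2, 1))
  expect_equal(degree_centralities(path3), c(0.5, 1, 0.5))
  single <- toy_graph(1)
  expect_equal(node_degrees(single), 0)
  expect_equal(degree_centralities(single), 0)
})

test_that("clustering coefficients match hand-enumerated triangles", {
  expect_equal(clustering_coefficients(toy_graph(3, c(1,2, 2,3, 1,3))),
               rep(1, 3))
  expect_equal(clustering_coefficients(toy_graph(3, c(1,2, 2,3))),
               rep(0, 3))
  # K4 minus edge 3-4: a=1, b=2 keep CL 2/3; c=3, d=4 have CL 1
  g <- toy_graph(4, c(1,2, 1,3, 1,4, 2,3, 2,4))
  expect_equal(clustering_coefficients(g), c(2/3, 2/3, 1, 1))
})

test_that("closeness uses the component-size-scaled convention", {
  path4 <- toy_graph(4, c(1,2, 2,3, 3,4))
  expect_equal(closeness_centralities(path4), c(0.5, 0.75, 0.75, 0.5))
  two_edges <- toy_graph(4, c(1,2, 3,4))
  expect_equal(closeness_centralities(two_edges), rep(1/3, 4))
  expect_equal(closeness_centralities(toy_graph(1)), 0)
})

test_that("Katz centrality solves the damped walk system and normalizes", {
  # edgeless graph: all equal 1/sqrt(n)
  expect_equal(katz_centralities(toy_graph(4)), rep(0.5, 4))
  # vertex-transitive cycle: all equal
  cyc <- toy_graph(5, c(1,2, 2,3, 3,4, 4,5, 5,1))
  expect_equal(diff(range(katz_centralities(cyc))), 0, tolerance = 1e-12)
  # path a-b-c with alpha 0.1: x_a = x_c = 1.1/0.98, x_b = 1 + 0.2 x_a
  p3 <- toy_graph(3, c(1,2, 2,3))
  k <- katz_centralities(p3, katz_alpha = 0.1)
  xa <- 1.1 / 0.98; xb <- 1 + 0.2 * xa
  expected <- c(xa, xb, xa) / sqrt(2 * xa^2 + xb^2)
  expect_equal(k, expected, tolerance = 1e-12)
  # alpha beyond the spectral bound errors with guidance
  expect_error(katz_centralities(toy_graph(2, c(1, 2)), katz_alpha = 1.5),
               "lower alpha")
})

test_that("network density spans its range", {
  expect_equal(network_density(toy_graph(4, c(1,2,1,3,1,4,2,3,2,4,3,4))), 1)
  expect_equal(network_density(toy_graph(5)), 0)
  expect_equal(network_density(toy_graph(3, c(1,2, 2,3))), 2/3)
  expect_equal(network_density(toy_graph(1)), 0)
})

test_that("community structure separates components and merges cliques", {
  two_tri <- toy_graph(6, c(1,2, 2,3, 1,3, 4,5, 5,6, 4,6))
  expect_equal(community_sizes(two_tri), rep(0.5, 6))
  k4 <- toy_graph(4, c(1,2, 1,3, 1,4, 2,3, 2,4, 3,4))
  expect_equal(community_sizes(k4), rep(1, 4))
  expect_equal(community_sizes(toy_graph(1)), 1)
})

test_that("metric summarization: histogram, moments, degenerate input", {
  s <- summarize_metric(c(5, 5, 5, 5))
  expect_length(s, 15L)
  expect_equal(s[1:10], c(1, rep(0, 9)))
  expect_equal(unname(s[11:15]), c(5, 0, 5, 5, 5))
  # one value per unit bin over [0.5, 9.5]
  s2 <- summarize_metric(seq(0.5, 9.5, by = 1))
  expect_equal(s2[1:10], rep(0.1, 10))
  expect_error(summarize_metric(numeric(0)), "empty")
})

test_that("the SNA feature vector has the documented geometry", {
  tta <- simulate_tta_image(recovery_config(), 1L, seed = 31L)
  g <- build_tissue_graph(tta, "STROMA")
  v <- extract_sna_features(g)
  expect_length(v, 91L)
  expect_equal(names(v), sna_feature_names())
  expect_true(attr(v, "valid"))
  # each metric's histogram sums to 1
  for (m in 0:5) {
    expect_equal(sum(v[(m * 15 + 1):(m * 15 + 10)]), 1, tolerance = 1e-12)
  }
  # min <= median <= max per metric
  for (m in 0:5) {
    blk <- v[(m * 15 + 11):(m * 15 + 15)]
    expect_lte(blk[4], blk[5]); expect_lte(blk[5], blk[3])
  }
  expect_true(v["NED"] >= 0 && v["NED"] <= 1)
})

test_that("empty graphs give an all-zero invalid vector", {
  g0 <- build_tissue_graph(tta_image(matrix("S", 2, 2), "p"), "ITIL")
  v <- extract_sna_features(g0)
  expect_length(v, 91L)
  expect_true(all(v == 0))
  expect_false(attr(v, "valid"))
})

test_that("complete graph on 5 nodes pins density and degree centrality", {
  g <- toy_graph(5, c(1,2,1,3,1,4,1,5,2,3,2,4,2,5,3,4,3,5,4,5))
  v <- extract_sna_features(g)
  expect_equal(unname(v["NED"]), 1)
  expect_equal(unname(v["DC_mean"]), 1)
})

test_that("metrics agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (rep in 1:50) {
    g <- random_toy_graph(sample(4:12, 1))
    A <- adjacency_of(g)
    expect_equal(node_degrees(g), as.numeric(rowSums(A)))
    expect_equal(clustering_coefficients(g), oracle_clustering(A),
                 tolerance = 1e-12)
    expect_equal(closeness_centralities(g), oracle_closeness(A),
                 tolerance = 1e-12)
    alpha <- 0.85 / max(abs(eigen(A, symmetric = TRUE,
                                  only.values = TRUE)$values), 1)
    alpha <- min(0.1, alpha)
    expect_equal(katz_centralities(g, katz_alpha = alpha),
                 oracle_katz(A, alpha), tolerance = 1e-9)
    n <- nrow(A)
    expect_equal(network_density(g), sum(A) / (n * (n - 1)))
  }
})

test_that("relabel-invariant metrics survive node permutation", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    g <- random_toy_graph(n)
    e <- g$edges
    p <- sample(n)
    pe <- cbind(from = pmin(p[e[, 1]], p[e[, 2]]),
                to = pmax(p[e[, 1]], p[e[, 2]]))
    pe <- pe[order(pe[, 1], pe[, 2]), , drop = FALSE]
    storage.mode(pe) <- "integer"
    g2 <- toy_graph_from_edges(n, pe)
    for (f in list(node_degrees, clustering_coefficients,
                   closeness_centralities, degree_centralities,
                   katz_centralities)) {
      expect_equal(sort(f(g)), sort(f(g2)), tolerance = 1e-9)
    }
    expect_equal(network_density(g), network_density(g2))
  }
})

test_that("feature tables carry one named row per patient-compartment", {
  tta <- simulate_tta_image(recovery_config(), 0L, seed = 8L)
  fl <- list(p1 = list(STROMA = extract_sna_features(
    build_tissue_graph(tta, "STROMA"))))
  tab <- sna_feature_table(fl)
  expect_equal(nrow(tab), 1L)
  expect_equal(ncol(tab), 94L)   # id, compartment, valid + 91 features
  expect_true(tab$valid[1])
})
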