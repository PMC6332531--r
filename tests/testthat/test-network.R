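triangle <- as_ppi_network(data.frame(a = c("A", "B", "C"),
                                      b = c("B", "C", "A")))
path3 <- as_ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))

test_that("co-localization filtering keeps exactly edges sharing a location", {
  net <- as_ppi_network(data.frame(a = c("A", "A"), b = c("B", "C")))
  loc <- localization_table(data.frame(
    protein = c("A", "A", "B", "C"),
    location = c("nucleus", "cytoplasm", "membrane", "cytoplasm")
  ))
  clpin <- build_clpin(net, loc)
  expect_equal(clpin$edges$from, "A")
  expect_equal(clpin$edges$to, "C")   # A-B removed: no shared location
  expect_setequal(clpin$nodes, c("A", "C"))
  expect_error(build_clpin(net, localization_table(
    data.frame(protein = character(), location = character())
  )))
})

test_that("co-localization filtering matches a brute-force intersection scan", {
  withr::local_seed(11)
  for (rep in 1:3) {
    rn <- random_net(50, 0.12)
    rl <- random_locs(rn$ids)
    clpin <- build_clpin(rn$net, rl$loc, drop_unannotated = FALSE)
    kept <- purrr::map2_lgl(rn$net$edges$from, rn$net$edges$to, function(a, b) {
      length(intersect(rl$sets[[a]], rl$sets[[b]])) > 0
    })
    expect_identical(clpin$edges[c("from", "to")],
                     rn$net$edges[kept, c("from", "to")])
  }
})

test_that("co-localization filtering is idempotent and never adds anything", {
  withr::local_seed(5)
  rn <- random_net(40, 0.1)
  rl <- random_locs(rn$ids)
  c1 <- build_clpin(rn$net, rl$loc)
  c2 <- build_clpin(c1, rl$loc)
  expect_identical(c1$edges, c2$edges)
  expect_identical(c1$nodes, c2$nodes)
  expect_true(all(c1$nodes %in% rn$net$nodes))
  key <- function(n) paste(n$edges$from, n$edges$to)
  expect_true(all(key(c1) %in% key(rn$net)))
})

test_that("density matches hand values and the edge-count formula", {
  expect_equal(network_density(triangle), 1)
  net4 <- as_ppi_network(data.frame(a = c("A", "C"), b = c("B", "D")))
  expect_equal(network_density(net4), 2 / 6)
  withr::local_seed(3)
  rn <- random_net(30, 0.2)
  expect_equal(network_density(rn$net), 2 * sum(rn$A) / 2 / (30 * 29))
  expect_error(network_density(as_ppi_network(data.frame(a = "A", b = "A"))))
})

test_that("clustering coefficient and path length match hand values", {
  expect_equal(avg_clustering(triangle), 1)
  expect_equal(avg_path_length(triangle), 1)
  expect_equal(avg_clustering(path3), 0)
  expect_equal(avg_path_length(path3), 4 / 3)
})

test_that("clustering and path length match brute force on random graphs", {
  withr::local_seed(21)
  for (rep in 1:3) {
    rn <- random_net(25, 0.15)
    expect_equal(avg_clustering(rn$net), oracle_clustering(rn$A))
    expect_equal(avg_path_length(rn$net), oracle_path_length(rn$A))
  }
})

test_that("density, clustering and path length agree with brute force on all tiny graphs", {
  # exhaustive over a deterministic sample of graphs with <= 8 nodes
  withr::local_seed(31)
  for (n in 4:8) {
    for (rep in 1:20) {
      rn <- random_net(n, stats::runif(1, 0.2, 0.8))
      if (n_edges(rn$net) == 0) next
      expect_equal(network_density(rn$net), sum(rn$A) / (n * (n - 1)))
      expect_equal(avg_clustering(rn$net), oracle_clustering(rn$A))
      if (any(rowSums(rn$A) > 0)) {
        expect_equal(avg_path_length(rn$net), oracle_path_length(rn$A))
      }
    }
  }
})

test_that("degrees exclude self-pairs and sum to twice the edge count", {
  net <- as_ppi_network(data.frame(a = c("A", "A", "B"), b = c("B", "A", "C")))
  deg <- node_degrees(net)
  expect_equal(unname(deg[c("A", "B", "C")]), c(1, 2, 1))
  expect_equal(sum(deg), 2 * n_edges(net))
})

test_that("power-law fitting recovers the exponent of simulated scale-free degrees", {
  k <- 1:100
  prob <- k^-2.5
  withr::local_seed(101)
  deg <- sample(k, 20000, replace = TRUE, prob = prob)
  fit <- fit_power_law(deg)
  expect_gt(fit$gamma, 2.5 - 0.15)
  expect_lt(fit$gamma, 2.5 + 0.15)
  expect_equal(fit$fit_range[1], 1)
})

test_that("power-law fitting needs at least three distinct degrees", {
  expect_error(fit_power_law(rep(4, 50)), "distinct")
  expect_error(fit_power_law(c(0, 0, 0)), "distinct")
})

test_that("preferential-attachment graphs land in the empirical scale-free band", {
  withr::local_seed(13)
  g <- igraph::sample_pa(5000, m = 2, directed = FALSE)
  deg <- igraph::degree(g)
  fit <- fit_power_law(deg)
  expect_gt(fit$gamma, 2)
  expect_lt(fit$gamma, 3.5)
})

test_that("network_stats summarises a known toy network", {
  fx <- fig2_fixture()
  st <- network_stats(fx$network)
  expect_equal(st$n_proteins, 5)
  expect_equal(st$n_interactions, 7)
  expect_equal(st$density, 0.7)
  expect_equal(st$n_components, 1)
})
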