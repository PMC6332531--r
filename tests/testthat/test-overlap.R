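test_that("TOM matches hand evaluation on dyad, path and triangle", {
  dyad <- as_ppi_network(data.frame(a = "A", b = "B"))
  expect_equal(tom_matrix(dyad)["A", "B"], 1)

  path3 <- as_ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  tm <- tom_matrix(path3)
  expect_equal(tm["A", "C"], 0.5)  # one shared partner, no direct edge
  expect_equal(tm["A", "B"], 1)

  tri <- as_ppi_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  tm3 <- tom_matrix(tri)
  expect_true(all(tm3 == 1))
})

test_that("TOM and LTOM equal the brute-force double loop on small graphs", {
  withr::local_seed(42)
  # dense sweep over sizes 2..6, random sample at 7
  for (n in 2:7) {
    reps <- if (n < 7) 30 else 60
    for (r in seq_len(reps)) {
      rn <- random_net(n, stats::runif(1, 0.2, 0.9))
      rl <- random_locs(rn$ids)
      expect_equal(unclass(tom_matrix(rn$net)), oracle_tom(rn$A),
                   tolerance = 1e-12, ignore_attr = TRUE)
      expect_equal(unclass(ltom_matrix(rn$net, rl$loc)),
                   oracle_ltom(rn$A, rl$sets),
                   tolerance = 1e-12, ignore_attr = TRUE)
    }
  }
})

test_that("the toy fixture reproduces the location-suppressed overlap score", {
  fx <- fig2_fixture()
  expect_equal(tom_matrix(fx$network)["A", "B"], 1)
  expect_equal(ltom_matrix(fx$network, fx$localization)["A", "B"], 0.75)
  expect_equal(sigma("A", "P2", "B", fx$localization), 0)
  expect_equal(sigma("A", "P1", "B", fx$localization), 1)
  expect_equal(sigma("A", "P3", "B", fx$localization), 1)
  expect_equal(sigma_prime("A", "B", fx$localization), 1)
  expect_equal(unname(node_degrees(fx$network)[c("A", "B")]), c(4, 4))
})

test_that("sigma indicators reduce to set intersections", {
  loc <- localization_table(data.frame(
    protein = c("i", "u", "u", "j"),
    location = c("nucleus", "nucleus", "membrane", "nucleus")
  ))
  expect_equal(sigma("i", "u", "j", loc), 1)
  loc2 <- localization_table(data.frame(
    protein = c("i", "u", "j"),
    location = c("nucleus", "membrane", "nucleus")
  ))
  expect_equal(sigma("i", "u", "j", loc2), 0)
  expect_equal(sigma_prime("i", "j", loc2), 1)

  withr::local_seed(9)
  rl <- random_locs(c("x", "y", "z"))
  expect_equal(
    sigma("x", "y", "z", rl$loc),
    as.integer(length(Reduce(intersect, rl$sets[c("x", "y", "z")])) > 0)
  )
  expect_equal(sigma("x", "y", "z", rl$loc), sigma("z", "y", "x", rl$loc))
})

test_that("LTOM equals TOM when all proteins share a location, zero when none do", {
  withr::local_seed(17)
  rn <- random_net(20, 0.3)
  shared <- localization_table(
    data.frame(protein = rn$ids, location = "cytoplasm")
  )
  expect_equal(unclass(ltom_matrix(rn$net, shared)),
               unclass(tom_matrix(rn$net)), ignore_attr = TRUE)

  all6 <- localization_table(data.frame(
    protein = rep(rn$ids, each = 6),
    location = rep(major_locations, 20)
  ))
  expect_equal(unclass(ltom_matrix(rn$net, all6)),
               unclass(tom_matrix(rn$net)), ignore_attr = TRUE)

  rn6 <- random_net(6, 0.6)
  disjoint <- localization_table(data.frame(
    protein = rn6$ids, location = major_locations
  ))
  lt <- ltom_matrix(rn6$net, disjoint)
  off <- lt[upper.tri(lt)]
  expect_true(all(off == 0))
})

test_that("LTOM is bounded by TOM and both live in [0, 1]", {
  withr::local_seed(23)
  for (r in 1:25) {
    n <- sample(5:60, 1)
    rn <- random_net(n, stats::runif(1, 0.05, 0.3))
    rl <- random_locs(rn$ids)
    tm <- tom_matrix(rn$net)
    lm <- ltom_matrix(rn$net, rl$loc)
    expect_true(all(tm >= 0 & tm <= 1))
    expect_true(all(lm <= tm + 1e-12))
    expect_true(isSymmetric(unclass(tm)))
    expect_true(isSymmetric(unclass(lm)))
  }
})

test_that("overlap matrices are equivariant under node relabeling", {
  withr::local_seed(29)
  rn <- random_net(15, 0.3)
  rl <- random_locs(rn$ids)
  # relabel by reversing IDs (changes sort order)
  relabel <- stats::setNames(sprintf("Z%03d", rev(seq_along(rn$ids))), rn$ids)
  ed2 <- data.frame(from = unname(relabel[rn$net$edges$from]),
                    to = unname(relabel[rn$net$edges$to]))
  net2 <- as_ppi_network(ed2, nodes = unname(relabel))
  loc2 <- localization_table(data.frame(
    protein = unname(relabel[rl$loc$protein]), location = rl$loc$location
  ))
  t1 <- unclass(tom_matrix(rn$net))
  t2 <- unclass(tom_matrix(net2))
  l1 <- unclass(ltom_matrix(rn$net, rl$loc))
  l2 <- unclass(ltom_matrix(net2, loc2))
  perm <- unname(relabel[rownames(t1)])
  expect_equal(t2[perm, perm], t1, ignore_attr = TRUE)
  expect_equal(l2[perm, perm], l1, ignore_attr = TRUE)
})

test_that("imputation adds exactly the non-adjacent pairs at or above tau", {
  path3 <- as_ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  tm <- tom_matrix(path3)
  out <- impute_network(path3, tm, tau = 0.5)
  expect_equal(n_edges(out), 3)
  added <- out$edges[out$edges$imputed, ]
  expect_equal(paste(added$from, added$to), "A C")

  none <- impute_network(path3, tm, tau = 0.9)
  expect_equal(n_edges(none), 2)
  expect_error(impute_network(path3, tm, tau = 0))
})

test_that("imputation matches a brute-force scan of the score matrix and is monotone in tau", {
  withr::local_seed(37)
  rn <- random_net(40, 0.1)
  rl <- random_locs(rn$ids)
  sc <- ltom_matrix(rn$net, rl$loc)
  for (tau in c(0.2, 0.4, 0.6)) {
    out <- impute_network(rn$net, sc, tau = tau)
    expect_identical(out$nodes, rn$net$nodes)
    added <- out$edges[out$edges$imputed, c("from", "to")]
    S <- unclass(sc)
    exp_added <- which(upper.tri(S) & rn$A == 0 & S >= tau, arr.ind = TRUE)
    expect_equal(nrow(added), nrow(exp_added))
    expect_setequal(
      paste(added$from, added$to),
      paste(pmin(rn$ids[exp_added[, 1]], rn$ids[exp_added[, 2]]),
            pmax(rn$ids[exp_added[, 1]], rn$ids[exp_added[, 2]]))
    )
  }
  e_loose <- impute_network(rn$net, sc, tau = 0.3)$edges
  e_tight <- impute_network(rn$net, sc, tau = 0.7)$edges
  expect_true(all(paste(e_tight$from, e_tight$to) %in%
                    paste(e_loose$from, e_loose$to)))
})

test_that("top-k imputation adds exactly k pairs", {
  withr::local_seed(41)
  rn <- random_net(20, 0.2)
  sc <- tom_matrix(rn$net)
  out <- impute_network(rn$net, sc, top_k = 5)
  expect_equal(sum(out$edges$imputed), 5)
})
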