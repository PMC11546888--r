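test_that("seed construction intersects/unions and restricts to nodes", {
  net <- ppiNetwork(c(1, 2, 3), c(2, 3, 4))      # nodes 1..4
  s_int <- constructSeedSet(c(1L, 2L, 3L), c(2L, 3L, 4L), net,
                            "intersection")
  expect_identical(seedGenes(s_int), c(2L, 3L))
  s_uni <- constructSeedSet(c(1L, 2L, 3L), c(2L, 3L, 4L), net, "union")
  expect_identical(seedGenes(s_uni), 1:4)
  expect_error(constructSeedSet(99L, 99L, net, "intersection"),
               "empty seed set")
})

test_that("seed provenance flags both memberships under intersection", {
  net <- path_net(4)
  s <- constructSeedSet(c(2L, 3L), c(3L, 2L), net, "intersection")
  expect_true(all(s@provenance$is_deg & s@provenance$is_der_target))
})

test_that("restart vector is uniform over seeds and sums to one", {
  net <- path_net(4)
  s <- seed_set(c(1L, 3L), net)
  u0 <- makeRestartVector(s, net)
  expect_equal(unname(u0), c(0.5, 0, 0.5, 0))
  expect_identical(names(u0), as.character(1:4))
  s1 <- seed_set(2L, net)
  expect_equal(unname(makeRestartVector(s1, net)), c(0, 1, 0, 0))
})

test_that("restart probability 1 returns the restart vector exactly", {
  net <- random_net(20, seed = 2)
  s <- seed_set(networkNodes(net)[1:3], net)
  u0 <- makeRestartVector(s, net)
  res <- rwr(buildTransitionMatrix(net), u0, restart_p = 1)
  expect_identical(unname(walkScores(res)), unname(u0))
  expect_identical(res@iterations, 1L)
})

test_that("power iteration matches the closed-form solve on a path graph", {
  net <- path_net(3)
  A <- buildTransitionMatrix(net)
  s <- seed_set(1L, net)
  u0 <- makeRestartVector(s, net)
  res <- rwr(A, u0, restart_p = 0.5, tol = 1e-14)
  expect_equal(unname(walkScores(res)), rwr_oracle(A, u0, 0.5),
               tolerance = 1e-10)
})

test_that("iteration equals the linear solve on random graphs (oracle sweep)", {
  set.seed(99)
  for (trial in 1:100) {
    n <- sample(5:50, 1)
    net <- random_net(n, p = runif(1, 0.05, 0.3), seed = trial)
    # sometimes append an isolated node so the teleport path is exercised
    if (trial %% 4 == 0) {
      e <- networkEdges(net)
      net <- ppiNetwork(e$from, e$to, e$score, extra_nodes = n + 500L)
    }
    A <- buildTransitionMatrix(net)
    nn <- networkNodes(net)
    s <- seed_set(sample(nn, max(1, length(nn) %/% 5)), net)
    u0 <- makeRestartVector(s, net)
    p <- runif(1, 0.3, 0.9)
    res <- rwr(A, u0, restart_p = p, tol = 1e-12)
    expect_lt(sum(abs(walkScores(res) - rwr_oracle(A, u0, p))), 1e-8)
  }
})

test_that("score mass is conserved at every iteration, isolated nodes included", {
  e <- networkEdges(random_net(30, seed = 7))
  net <- ppiNetwork(e$from, e$to, e$score, extra_nodes = c(997L, 998L))
  s <- seed_set(c(networkNodes(net)[1:2], 997L), net)
  res <- rwr(buildTransitionMatrix(net), makeRestartVector(s, net))
  expect_true(all(abs(res@massTrace - 1) < 1e-9))
  expect_true(all(abs(sum(walkScores(res)) - 1) < 1e-9))
  expect_true(all(walkScores(res)[as.character(seedGenes(s))] > 0))
})

test_that("as restart_p approaches 1 every seed outranks every non-seed", {
  net <- random_net(25, seed = 11)
  nn <- networkNodes(net)
  s <- seed_set(nn[1:4], net)
  res <- rwr(buildTransitionMatrix(net), makeRestartVector(s, net),
             restart_p = 0.99)
  sc <- walkScores(res)
  expect_gt(min(sc[as.character(seedGenes(s))]),
            max(sc[setdiff(names(sc), as.character(seedGenes(s)))]))
})

test_that("boosted sets obey the level arithmetic and the tie-break", {
  net <- random_net(22, seed = 13)
  nn <- networkNodes(net)
  s <- seed_set(nn[1:2], net)
  res <- rwr(buildTransitionMatrix(net), makeRestartVector(s, net))
  n_nonseed <- length(nn) - 2L
  for (lv in c(0, 0.1, 0.25, 1)) {
    b <- selectBoosted(res, s, lv, net)
    expect_identical(length(boostedGenes(b)),
                     2L + as.integer(ceiling(lv * n_nonseed)))
  }
  b0 <- selectBoosted(res, s, 0, net)
  expect_identical(boostedGenes(b0), seedGenes(s))
  b1 <- selectBoosted(res, s, 1, net)
  expect_setequal(boostedGenes(b1), nn)
  expect_error(selectBoosted(res, s, 1.2, net), "level")
  # hand-check the added members: top-k nonseeds by (-score, entrez)
  b <- selectBoosted(res, s, 0.2, net)
  nonseed <- setdiff(nn, seedGenes(s))
  sc <- walkScores(res)[as.character(nonseed)]
  hand <- nonseed[order(-sc, nonseed)][seq_len(ceiling(0.2 * n_nonseed))]
  expect_identical(setdiff(boostedGenes(b), seedGenes(s)), hand)
})

test_that("boosted sets are nested across levels", {
  net <- random_net(40, seed = 17)
  s <- seed_set(networkNodes(net)[1:5], net)
  res <- rwr(buildTransitionMatrix(net), makeRestartVector(s, net))
  lvls <- c(0, 0.01, 0.1, 0.2, 0.5, 1)
  sets <- lapply(lvls, function(l)
    boostedGenes(selectBoosted(res, s, l, net)))
  for (i in seq_len(length(lvls) - 1L))
    expect_true(all(sets[[i]] %in% sets[[i + 1L]]))
})

test_that("direct/indirect classification is one-hop adjacency to seeds", {
  # path 1-2-3, seed {1}: 2 direct, 3 indirect
  net <- path_net(3)
  s <- seed_set(1L, net)
  res <- rwr(buildTransitionMatrix(net), makeRestartVector(s, net))
  b <- selectBoosted(res, s, 1, net)
  expect_identical(unname(geneClassification(b)[c("2", "3")]),
                   c("direct", "indirect"))
  cc <- classifyConnectivity(b, s, net)
  expect_identical(unname(cc["n_direct"] + cc["n_indirect"]),
                   length(boostedGenes(b)) - length(seedGenes(s)))
  # star with the seed at the hub: every leaf is direct
  star <- star_net(5)
  shub <- seed_set(1L, star)
  rhub <- rwr(buildTransitionMatrix(star), makeRestartVector(shub, star))
  bhub <- selectBoosted(rhub, shub, 1, star)
  expect_true(all(geneClassification(bhub) == "direct"))
  # boosted = seeds alone -> (0, 0)
  b0 <- selectBoosted(res, s, 0, net)
  expect_identical(unname(classifyConnectivity(b0, s, net)), c(0L, 0L))
})

test_that("scores table ranks by descending score with seed annotation", {
  net <- random_net(15, seed = 23)
  s <- seed_set(networkNodes(net)[1:3], net)
  res <- rwr(buildTransitionMatrix(net), makeRestartVector(s, net))
  tab <- scoresTable(res, s, net)
  expect_identical(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$score) <= 0))
  expect_identical(sum(tab$is_seed), length(seedGenes(s)))
  expect_true(all(tab$classification[tab$is_seed] == "seed"))
})

test_that("non-convergence warns and is flagged", {
  net <- random_net(30, seed = 31)
  s <- seed_set(networkNodes(net)[1], net)
  expect_warning(
    res <- rwr(buildTransitionMatrix(net), makeRestartVector(s, net),
               tol = 1e-15, max_iter = 3L),
    "did not converge")
  expect_false(res@converged)
})
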