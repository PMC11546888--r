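test_that("induced subnetworks keep exactly the interior edges", {
  tri <- complete_net(3)
  sub <- inducedSubnetwork(tri, c(1L, 2L))
  expect_identical(nrow(networkEdges(sub)), 1L)
  all3 <- inducedSubnetwork(tri, 1:3)
  expect_identical(networkEdges(all3)$score, networkEdges(tri)$score)
  none <- inducedSubnetwork(tri, c(98L, 99L))
  expect_identical(length(networkNodes(none)), 0L)
})

test_that("degrees sum to twice the edge count and match hand values", {
  k4 <- complete_net(4)
  d <- degreeReport(k4)
  expect_true(all(d$degree == 3L))
  expect_equal(attr(d, "mean_degree"), 3)
  s5 <- star_net(5)
  d5 <- degreeReport(s5)
  expect_identical(d5$degree[d5$entrez == 1L], 5L)
  expect_equal(attr(d5, "mean_degree"), 10 / 6)
  for (seed in 1:5) {
    net <- random_net(20, seed = seed)
    expect_identical(sum(degreeReport(net)$degree),
                     2L * nrow(networkEdges(net)))
  }
})

test_that("eigenvector centrality matches closed forms on symmetric graphs", {
  kn <- complete_net(6)
  cr <- eigenvectorCentrality(kn)
  expect_equal(cr@table$eigenvector, rep(1 / sqrt(6), 6), tolerance = 1e-8)
  # star: hub sqrt(1/2), each of n leaves sqrt(1/(2n))
  n <- 7
  st <- star_net(n)
  cs <- eigenvectorCentrality(st)
  hub <- cs@table$eigenvector[cs@table$entrez == 1L]
  leaf <- cs@table$eigenvector[cs@table$entrez != 1L]
  expect_equal(hub, sqrt(1 / 2), tolerance = 1e-6)
  expect_equal(leaf, rep(sqrt(1 / (2 * n)), n), tolerance = 1e-6)
  expect_equal(sum(cs@table$eigenvector^2), 1, tolerance = 1e-9)
})

test_that("power iteration matches a dense eigendecomposition oracle", {
  for (trial in 1:100) {
    net <- random_net(sample(5:30, 1), p = 0.2, seed = 1000 + trial)
    cr <- suppressWarnings(eigenvectorCentrality(net, tol = 1e-12))
    nn <- networkNodes(net)
    i <- match(networkEdges(net)$from, nn)
    j <- match(networkEdges(net)$to, nn)
    M <- matrix(0, length(nn), length(nn))
    M[cbind(i, j)] <- 1; M[cbind(j, i)] <- 1
    ev <- eigen(M, symmetric = TRUE)
    v <- ev$vectors[, 1]
    if (sum(v) < 0) v <- -v
    # power iteration can stall between equal leading eigenvalues of
    # disconnected twins; compare only when the gap is real
    if (abs(ev$values[1] - ev$values[2]) > 1e-8)
      expect_lt(max(abs(cr@table$eigenvector - pmax(v, 0))), 1e-6)
  }
})

test_that("disconnected graphs warn and concentrate mass on one component", {
  # two triangles of different internal weight structure: 4-clique dominates
  net <- ppiNetwork(c(1, 1, 1, 2, 2, 3, 10, 10, 11),
                    c(2, 3, 4, 3, 4, 4, 11, 12, 12))
  expect_warning(cr <- eigenvectorCentrality(net), "disconnected")
  expect_false(cr@connected)
  tab <- cr@table
  expect_gt(min(tab$eigenvector[tab$entrez <= 4]),
            max(tab$eigenvector[tab$entrez >= 10]) + 0.1)
})

test_that("hub calling honours both criteria and the tie-break", {
  st <- star_net(6)
  cr <- eigenvectorCentrality(st)
  expect_identical(findHubs(cr, "degree_top_k", 1L), 1L)
  k4 <- complete_net(4)
  cr4 <- eigenvectorCentrality(k4)
  expect_length(findHubs(cr4, "degree_sd", 2), 0L)   # no outliers
  expect_warning(all4 <- findHubs(cr4, "degree_top_k", 9L), "node count")
  expect_identical(sort(all4), 1:4)
  # planted degree ranking: 3 hubs wired to everything
  n <- 12
  hubs <- 1:3
  e <- expand.grid(from = hubs, to = 4:n)
  net <- ppiNetwork(e$from, e$to)
  crh <- suppressWarnings(eigenvectorCentrality(net))
  expect_identical(sort(findHubs(crh, "degree_top_k", 3L)), hubs)
})

make_overlay_fixture <- function() {
  net <- ppiNetwork(c(1, 2, 3, 4), c(2, 3, 4, 5))   # path 1..5
  s <- seed_set(c(1L, 2L), net)
  res <- rwr(buildTransitionMatrix(net), makeRestartVector(s, net))
  b <- selectBoosted(res, s, 1, net)
  ia <- data.frame(mirna = c("hsa-miR-1-5p", "hsa-miR-2-5p", "hsa-miR-2-5p"),
                   entrez = c(1L, 1L, 3L), source = "db")
  db <- new("TargetDatabase", interactions = ia, name = "db")
  list(net = net, seeds = s, boosted = b, db = db,
       ders = c("hsa-miR-1-5p", "hsa-miR-2-5p"))
}

test_that("overlay classes partition gene nodes exactly once", {
  fx <- make_overlay_fixture()
  ov <- buildOverlay(fx$boosted, fx$seeds, fx$db, fx$ders, fx$net,
                     degs = 4L)
  gn <- ov@geneNodes
  expect_identical(nrow(gn), 5L)
  expect_identical(gn$class[gn$entrez == 1L], "seed")
  expect_identical(gn$class[gn$entrez == 3L], "boosted_target")  # DER target
  expect_identical(gn$class[gn$entrez == 4L], "boosted_target")  # DEG
  expect_identical(gn$class[gn$entrez == 5L], "boosted")
  expect_identical(anyDuplicated(gn$entrez), 0L)
})

test_that("seed targeted by two DERs contributes two mirna_target edges", {
  fx <- make_overlay_fixture()
  ov <- buildOverlay(fx$boosted, fx$seeds, fx$db, fx$ders, fx$net)
  me <- ov@edges[ov@edges$type == "mirna_target", ]
  expect_identical(sum(me$to == "1"), 2L)
  expect_setequal(ov@mirnaNodes, fx$ders)
})

test_that("overlay without DER targets has no miRNA nodes", {
  fx <- make_overlay_fixture()
  ov <- buildOverlay(fx$boosted, fx$seeds, fx$db, ders = character(),
                     fx$net)
  expect_length(ov@mirnaNodes, 0L)
  expect_true(all(ov@edges$type == "ppi"))
})

test_that("graphml and json exports round-trip losslessly", {
  fx <- make_overlay_fixture()
  ov <- buildOverlay(fx$boosted, fx$seeds, fx$db, fx$ders, fx$net)
  for (fmt in c("graphml", "json")) {
    path <- tempfile(fileext = paste0(".", fmt))
    exportOverlay(ov, path, fmt)
    back <- readOverlay(path, fmt)
    o1 <- ov@geneNodes[order(ov@geneNodes$entrez), ]
    o2 <- back@geneNodes[order(back@geneNodes$entrez), ]
    rownames(o1) <- rownames(o2) <- NULL
    expect_equal(o2, o1)
    expect_identical(back@mirnaNodes, ov@mirnaNodes)
    ek <- function(e) sort(paste(pmin(e$from, e$to), pmax(e$from, e$to),
                                 e$type))
    expect_identical(ek(back@edges), ek(ov@edges))
    unlink(path)
  }
})

test_that("an empty overlay writes a valid file with zero nodes", {
  ov <- new("OverlayNetwork",
            geneNodes = data.frame(entrez = integer(), symbol = character(),
                                   class = character(), score = numeric(),
                                   degree = integer()),
            mirnaNodes = character(),
            edges = data.frame(from = character(), to = character(),
                               type = character()))
  path <- tempfile(fileext = ".graphml")
  exportOverlay(ov, path, "graphml")
  back <- readOverlay(path, "graphml")
  expect_identical(nrow(back@geneNodes), 0L)
  unlink(path)
})
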