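test_that("GMT reading maps members, collapses duplicates, sets the universe", {
  im <- tiny_id_map(10)
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c("T1\tfirst\tGENE1\tGENE2\tGENE2\tGENE3",
               "T2\tsecond\tGENE4\tNOPE\tGENE5"), tmp)
  coll <- readGmt(tmp, im)
  expect_identical(geneSets(coll)$T1, 1:3)       # duplicate collapsed
  expect_identical(geneSets(coll)$T2, 4:5)       # unmappable dropped
  expect_identical(attr(coll, "n_unmapped"), 1L)
  expect_identical(geneUniverse(coll), 1:5)      # union of members
  writeLines("T1\tonly-two-fields", tmp)
  expect_error(readGmt(tmp, im), "malformed GMT line 1")
  unlink(tmp)
})

test_that("universe override clips terms to the background", {
  im <- tiny_id_map(10)
  tmp <- tempfile(fileext = ".gmt")
  writeLines(c("T1\td\tGENE1\tGENE2\tGENE9", "T2\td\tGENE9\tGENE10"), tmp)
  coll <- readGmt(tmp, im, universe = 1:5)
  expect_identical(geneSets(coll)$T1, 1:2)
  expect_false("T2" %in% names(geneSets(coll)))  # emptied by the clip
  unlink(tmp)
})

test_that("hypergeometric tail has its closed-form anchors", {
  expect_identical(hypergeomP(0, 5, 5, 20), 1)
  expect_equal(hypergeomP(5, 5, 5, 20), 1 / choose(20, 5))
  expect_equal(hypergeomP(1, 1, 1, 2), 0.5)
  expect_error(hypergeomP(6, 5, 5, 20), "bounds")
  expect_error(hypergeomP(1, 25, 5, 20), "bounds")
})

test_that("hypergeometric tail agrees with brute-force enumeration (N <= 12)", {
  for (N in c(4L, 7L, 9L, 12L)) {
    for (n in seq_len(N - 1L)) {
      draws <- combn(N, n)
      for (K in seq_len(N)) {
        overlaps <- colSums(draws <= K)
        for (k in 0:min(K, n)) {
          expect_equal(hypergeomP(k, K, n, N), mean(overlaps >= k),
                       tolerance = 1e-12,
                       label = sprintf("P(X>=%d) N=%d K=%d n=%d", k, N, K, n))
        }
      }
    }
  }
})

test_that("hypergeometric tail is non-increasing in the overlap", {
  for (K in c(3, 8)) for (n in c(4, 10)) {
    p <- hypergeomP(0:min(K, n), K, n, 20)
    expect_true(all(diff(p) <= 1e-15))
  }
})

test_that("a planted term gets the smallest p and a full overlap", {
  coll <- planted_coll()
  r <- enrich(1:5, coll)
  expect_identical(r$term_id[1], "T1")
  expect_identical(r$overlap[1], 5L)
  expect_equal(r$p_value[1], hypergeomP(5, 5, 5, 20))
  # other terms overlap 0 and are filtered by min_overlap = 1
  expect_identical(nrow(r), 1L)
  # with min_overlap 0 they appear with p = 1
  r0 <- enrich(1:5, coll, min_overlap = 0L)
  expect_identical(nrow(r0), 3L)
  expect_true(all(r0$p_value[r0$overlap == 0] == 1))
})

test_that("a query disjoint from all terms yields an empty record list", {
  coll <- geneSetCollection(list(T1 = 1:5), universe = 1:30)
  r <- enrich(25:30, coll)
  expect_identical(nrow(r), 0L)
  expect_error(enrich(999L, coll), "empty after restriction")
})

test_that("BH adjustment follows the step-up rule over all tested terms", {
  # two disjoint terms engineered to raw p of (1/15504, 1): the BH step-up
  # doubles the small one (m = 2, rank 1) and leaves p = 1 alone
  coll <- geneSetCollection(list(A = 1:5, B = 6:10), universe = 1:20)
  r <- enrich(1:5, coll, min_overlap = 0L)
  expect_equal(r$p_adjusted, pmin(1, r$p_value * 2 / rank(r$p_value)))
  expect_true(all(r$p_adjusted >= r$p_value))
})

test_that("count of enriched terms respects threshold, scale and emptiness", {
  rec <- data.frame(p_value = c(0.005, 0.02), p_adjusted = c(0.02, 0.2))
  expect_identical(countEnriched(rec, 0.01), 1L)
  expect_identical(countEnriched(rec, 0.01, use_adjusted = TRUE), 0L)
  expect_identical(countEnriched(rec[0, ], 0.01), 0L)
  rec7 <- data.frame(p_value = rep(0.009, 7), p_adjusted = rep(0.009, 7))
  expect_identical(countEnriched(rec7, 0.01), 7L)
  # monotone in the threshold
  set.seed(1)
  recr <- data.frame(p_value = runif(50), p_adjusted = runif(50))
  for (t1 in c(0.01, 0.05)) expect_lte(countEnriched(recr, t1),
                                       countEnriched(recr, t1 + 0.2))
})

test_that("permutation empirical p uses the add-one estimator", {
  pn <- makePermutationNull(c(0L, 1L, 2L, 3L), observed = 2L)
  expect_equal(empiricalP(pn), 3 / 5)           # r = 2 -> (2+1)/(4+1)
  # observed above all null counts: floor 1/(n+1)
  pn_floor <- makePermutationNull(rep(0L, 100), observed = 5L)
  expect_equal(empiricalP(pn_floor), 1 / 101)
  # observed below all: p = 1
  pn_one <- makePermutationNull(rep(9L, 50), observed = 1L)
  expect_equal(empiricalP(pn_one), 1)
})

test_that("permutation null is deterministic under a seed and bounded below", {
  coll <- planted_coll()
  a <- permutationNull(coll, set_size = 5, n_perm = 50, observed = 2,
                       rng_seed = 42)
  b <- permutationNull(coll, set_size = 5, n_perm = 50, observed = 2,
                       rng_seed = 42)
  expect_identical(nullCounts(a), nullCounts(b))
  expect_gte(empiricalP(a), 1 / 51)
  c2 <- permutationNull(coll, set_size = 5, n_perm = 50, observed = 2,
                        rng_seed = 43)
  expect_false(identical(nullCounts(a), nullCounts(c2)))
})

test_that("random queries control the type-I rate near the nominal 0.01", {
  set.seed(7)
  universe <- 1:400
  terms <- lapply(1:20, function(i) sample(universe, 25))
  names(terms) <- paste0("T", 1:20)
  coll <- geneSetCollection(terms, universe = universe)
  hits <- 0L; total <- 0L
  for (b in 1:200) {
    q <- sample(universe, 30)
    r <- enrich(q, coll, min_overlap = 0L)
    hits <- hits + sum(r$p_value < 0.01)
    total <- total + nrow(r)
  }
  frac <- hits / total
  # binomial tolerance around 0.01 for 4000 discrete tests
  expect_lt(frac, 0.02)
})

test_that("dot-plot table is long-format with NA for absent cells", {
  r1 <- data.frame(term_id = c("A", "B"), overlap = c(3L, 2L),
                   p_value = c(1e-4, 1e-3))
  r2 <- data.frame(term_id = "B", overlap = 5L, p_value = 1e-6)
  tab <- dotplotTable(list(`1pct` = r1, `10pct` = r2))
  expect_identical(nrow(tab), 4L)            # 2 terms x 2 levels
  cellA10 <- tab[tab$term_id == "A" & tab$level == "10pct", ]
  expect_true(is.na(cellA10$p_value) && is.na(cellA10$overlap))
  expect_identical(nrow(dotplotTable(list())), 0L)
  expect_identical(nrow(dotplotTable(list(`1pct` = r1), terms = character())),
                   0L)
})
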