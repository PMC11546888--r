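# Shared in-code fixtures: tiny deterministic objects built fresh per use.

# id map over GENE1..GENEn (entrez i), every 5th gene gets alias G<i>ALT
tiny_id_map <- function(n = 10L) {
  makeIdMap(sprintf("GENE%d", seq_len(n)), seq_len(n),
            aliases = lapply(seq_len(n), function(i)
              if (i %% 5L == 0L) sprintf("G%dALT", i) else character()))
}

# path graph 1-2-3-...-n with given scores
path_net <- function(n = 3L, scores = rep(1, n - 1L)) {
  ppiNetwork(seq_len(n - 1L), seq_len(n - 1L) + 1L, scores)
}

# complete graph on n nodes
complete_net <- function(n) {
  pr <- t(combn(n, 2L))
  ppiNetwork(pr[, 1], pr[, 2])
}

# star: hub 1, leaves 2..(n_leaves + 1)
star_net <- function(n_leaves) {
  ppiNetwork(rep(1L, n_leaves), seq_len(n_leaves) + 1L)
}

# random ER-style network via edge sampling, always >= 1 edge
random_net <- function(n, p = 0.15, seed = 1L) {
  set.seed(seed)
  pr <- t(combn(n, 2L))
  keep <- runif(nrow(pr)) < p
  if (!any(keep)) keep[sample.int(nrow(pr), 1L)] <- TRUE
  ppiNetwork(pr[keep, 1], pr[keep, 2], score = runif(sum(keep), 150, 999))
}

seed_set <- function(genes, net, degs = genes, targets = genes) {
  constructSeedSet(degs, targets, net, "intersection")
}

# dense-solve oracle for the restarted walk, including the dangling-node
# teleport: u = (1-p) A u + (p + (1-p) * mass_on_isolated) u0
rwr_oracle <- function(A, u0, p) {
  M <- as.matrix(A@mat)
  n <- nrow(M)
  iso <- as.numeric(A@isolated)
  # redirected mass adds (1-p) * u0 %*% iso^T to the iteration matrix
  B <- (1 - p) * (M + outer(as.numeric(u0), iso))
  as.numeric(solve(diag(n) - B, p * as.numeric(u0)))
}

# brute-force hypergeometric upper tail: enumerate every n-subset of N
hyper_oracle <- function(k, K, n, N) {
  draws <- combn(N, n)
  overlaps <- colSums(draws <= K)
  mean(overlaps >= k)
}

# tiny planted enrichment collection: term T1 = 1..5, rest disjoint
planted_coll <- function() {
  geneSetCollection(list(T1 = 1:5, T2 = 6:12, T3 = 13:20),
                    universe = 1:20)
}
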