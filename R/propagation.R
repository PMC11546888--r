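# Random Walk with Restart over the PPI network: seed construction, the
# power iteration u <- (1 - p) A u + p u0, and extraction of boosted gene
# sets at chosen boosting levels.

#' Construct the seed gene set
#'
#' Seeds are the restart support of the walk. In intersection mode (the
#' default analysis) a gene must be both differentially expressed (DEG) and
#' a target of a differentially expressed miRNA (DER target); union mode
#' accepts either, which is also how a run degrades gracefully when only
#' one of the two lists is available. Genes absent from the network cannot
#' be walked on and are recorded in \code{dropped}.
#'
#' @param degs integer Entrez vector of differentially expressed genes.
#' @param der_targets integer Entrez vector of DER target genes.
#' @param net a [PPINetwork-class].
#' @param mode "intersection" or "union".
#' @return a [SeedSet-class]. An empty result is a hard error: propagation
#'   from no seeds is undefined.
#' @export
constructSeedSet <- function(degs, der_targets, net,
                             mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  stopifnot(is(net, "PPINetwork"), length(net@nodes) > 0L)
  degs <- unique(as.integer(degs))
  der_targets <- unique(as.integer(der_targets))
  cand <- if (mode == "intersection") intersect(degs, der_targets) else
    union(degs, der_targets)
  genes <- sort(intersect(cand, net@nodes))
  dropped <- sort(setdiff(cand, net@nodes))
  if (length(genes) == 0L)
    stop("empty seed set: no ", mode, " gene is present in the network (",
         length(dropped), " candidate(s) absent from the network)")
  new("SeedSet",
      genes = genes,
      provenance = data.frame(entrez = genes,
                              is_deg = genes %in% degs,
                              is_der_target = genes %in% der_targets),
      dropped = dropped)
}

#' Restart probability vector over the network nodes
#'
#' Seeds are marked and the vector normalised to a probability
#' distribution, i.e. \code{1/n_seeds} on each seed and 0 elsewhere.
#' (Un-normalised all-ones seed marking makes the iteration diverge, so
#' normalisation is forced.)
#'
#' @param seeds a [SeedSet-class].
#' @param net the [PPINetwork-class] the seeds were built against.
#' @return numeric vector named by Entrez ID in node order, summing to 1.
#' @export
makeRestartVector <- function(seeds, net) {
  stopifnot(is(seeds, "SeedSet"), all(seeds@genes %in% net@nodes))
  u0 <- numeric(length(net@nodes))
  names(u0) <- net@nodes
  u0[match(seeds@genes, net@nodes)] <- 1 / length(seeds@genes)
  u0
}

#' Random Walk with Restart
#'
#' Iterates \code{u <- (1 - p) * A u + p * u0} from \code{u0} until the L1
#' change drops below \code{tol} or \code{max_iter} is reached. Columns of
#' isolated nodes are zero in A; the mass a step would lose through them is
#' redirected to the restart vector, which keeps u a probability
#' distribution at every iteration (equivalent to teleporting from dangling
#' nodes). At the fixed point u equals the closed-form solution
#' \code{p * solve(I - (1 - p) A) \%*\% u0} (with the same dangling-node
#' correction folded into A).
#'
#' @param A a [TransitionMatrix-class].
#' @param u0 restart vector from [makeRestartVector()] (must sum to 1).
#' @param restart_p restart probability in (0, 1]; 0.7 by default, the
#'   common choice in network-propagation work.
#' @param tol L1 convergence tolerance.
#' @param max_iter iteration cap; non-convergence warns and returns the
#'   last iterate flagged \code{converged = FALSE}.
#' @return an [RWRScores-class].
#' @export
rwr <- function(A, u0, restart_p = 0.7, tol = 1e-10, max_iter = 1000L) {
  stopifnot(is(A, "TransitionMatrix"))
  if (!is.numeric(restart_p) || restart_p <= 0 || restart_p > 1)
    stop("restart_p must be in (0, 1]")
  if (tol <= 0) stop("tol must be positive")
  if (abs(sum(u0) - 1) > 1e-9) stop("u0 must sum to 1")
  n <- length(A@nodes)
  stopifnot(length(u0) == n)
  u <- as.numeric(u0)
  mass_trace <- numeric(0)
  iter <- 0L
  converged <- FALSE
  if (restart_p == 1) {
    # fixed point is u0 itself; one "iteration" confirms it
    u <- as.numeric(u0)
    iter <- 1L
    converged <- TRUE
    mass_trace <- sum(u)
  } else {
    for (iter in seq_len(max_iter)) {
      lost <- (1 - restart_p) * sum(u[A@isolated])
      u_new <- as.numeric((1 - restart_p) * (A@mat %*% u)) +
        (restart_p + lost) * as.numeric(u0)
      mass_trace <- c(mass_trace, sum(u_new))
      delta <- sum(abs(u_new - u))
      u <- u_new
      if (delta < tol) { converged <- TRUE; break }
    }
  }
  if (!converged)
    warning("RWR did not converge in ", max_iter, " iterations")
  new("RWRScores", scores = setNames(u, A@nodes),
      restartP = restart_p, iterations = iter, converged = converged,
      massTrace = mass_trace)
}

#' Extract the boosted gene set at a boosting level
#'
#' The boosted set is the seeds plus the top
#' \code{ceiling(level * (n_nodes - n_seeds))} non-seed nodes ranked by
#' descending walk score, ties broken by ascending Entrez ID so the cut is
#' deterministic. Level 0 returns the seeds alone; level 1 the whole
#' network. Each added gene is classified direct (has a network edge to a
#' seed) or indirect.
#'
#' @param scores an [RWRScores-class] over the same node order as
#'   \code{net}.
#' @param seeds a [SeedSet-class].
#' @param level boosting level in [0, 1].
#' @param net the [PPINetwork-class] the walk ran on.
#' @return a [BoostedGeneSet-class].
#' @export
selectBoosted <- function(scores, seeds, level, net) {
  stopifnot(is(scores, "RWRScores"), is(seeds, "SeedSet"),
            is(net, "PPINetwork"))
  if (!is.numeric(level) || length(level) != 1L || level < 0 || level > 1)
    stop("level must be a single value in [0, 1]")
  s <- scores@scores
  stopifnot(identical(as.integer(names(s)), net@nodes))
  nonseed <- net@nodes[!(net@nodes %in% seeds@genes)]
  k <- ceiling(level * length(nonseed))
  ns_scores <- s[as.character(nonseed)]
  ord <- order(-ns_scores, nonseed)
  added <- nonseed[ord][seq_len(k)]
  genes <- c(seeds@genes, added)
  cls <- .classify_direct(added, seeds@genes, net)
  new("BoostedGeneSet", level = level, genes = as.integer(genes),
      seeds = seeds@genes,
      classification = cls,
      scores = s[as.character(genes)])
}

# direct = one-hop adjacency to any seed
.classify_direct <- function(genes, seed_genes, net) {
  if (length(genes) == 0L) return(setNames(character(0), character(0)))
  e <- net@edges
  touch_seed <- e$from %in% seed_genes | e$to %in% seed_genes
  partners <- unique(c(e$from[touch_seed], e$to[touch_seed]))
  partners <- setdiff(partners, seed_genes)
  setNames(ifelse(genes %in% partners, "direct", "indirect"),
           genes)
}

#' Direct/indirect connectivity counts of a boosted set
#'
#' @param boosted a [BoostedGeneSet-class] derived from \code{net}.
#' @param seeds the [SeedSet-class] used.
#' @param net the [PPINetwork-class].
#' @return named integer vector \code{c(n_direct, n_indirect)}; the two
#'   always sum to the number of non-seed members.
#' @export
classifyConnectivity <- function(boosted, seeds, net) {
  added <- setdiff(boosted@genes, seeds@genes)
  cls <- .classify_direct(added, seeds@genes, net)
  c(n_direct = sum(cls == "direct"),
    n_indirect = sum(cls == "indirect"))
}

#' Scores table for export
#'
#' @param scores an [RWRScores-class].
#' @param seeds a [SeedSet-class].
#' @param net the [PPINetwork-class].
#' @return data.frame: entrez, symbol, score, rank (dense rank by
#'   descending score, ties by ascending entrez), is_seed, classification.
#' @export
scoresTable <- function(scores, seeds, net) {
  s <- scores@scores
  entrez <- as.integer(names(s))
  ord <- order(-s, entrez)
  is_seed <- entrez %in% seeds@genes
  cls_all <- .classify_direct(entrez[!is_seed], seeds@genes, net)
  cls <- rep("seed", length(entrez))
  cls[!is_seed] <- cls_all[as.character(entrez[!is_seed])]
  out <- data.frame(
    entrez = entrez, symbol = net@symbols[match(entrez, net@nodes)],
    score = as.numeric(s), is_seed = is_seed, classification = cls,
    stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("entrez", "symbol", "score", "rank", "is_seed", "classification")]
}
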