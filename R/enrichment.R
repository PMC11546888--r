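# Pathway enrichment of seed and boosted gene lists: exact hypergeometric
# upper tail, Benjamini-Hochberg control, cross-level comparison tables and
# the size-matched permutation null for the enriched-pathway count.

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one term per line, tab-separated as term, description,
#' then member genes. Members are mapped to Entrez through the id map;
#' unmappable members are dropped with a tally (attribute
#' \code{"n_unmapped"}). The universe defaults to the union of all term
#' members and can be overridden (e.g. to the PPI node set).
#'
#' @param path GMT file.
#' @param id_map id map from [readIdMap()].
#' @param universe optional integer Entrez vector overriding the default
#'   background.
#' @return a [GeneSetCollection-class].
#' @export
readGmt <- function(path, id_map, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  terms <- list(); descs <- character(); n_unmapped <- 0L
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("malformed GMT line ", i, ": fewer than 3 fields")
    m <- mapSymbols(f[-(1:2)], id_map)
    n_unmapped <- n_unmapped + length(m$unmapped)
    members <- sort(unique(as.integer(m$mapping)))
    if (length(members)) {
      terms[[f[1L]]] <- members
      descs[f[1L]] <- f[2L]
    }
  }
  univ <- if (is.null(universe)) sort(unique(unlist(terms, use.names = FALSE)))
    else sort(unique(as.integer(universe)))
  if (!is.null(universe)) {
    # clip terms to the supplied background
    terms <- lapply(terms, intersect, univ)
    keep <- lengths(terms) >= 1L
    terms <- terms[keep]; descs <- descs[keep]
  }
  out <- new("GeneSetCollection", terms = terms, descriptions = descs,
             universe = as.integer(univ))
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Build a collection in code (used by fixtures and tests)
#'
#' @param terms named list of integer Entrez member vectors.
#' @param descriptions optional named character; defaults to the term IDs.
#' @param universe optional background; defaults to the union of members.
#' @return a [GeneSetCollection-class].
#' @export
geneSetCollection <- function(terms, descriptions = NULL, universe = NULL) {
  terms <- lapply(terms, function(x) sort(unique(as.integer(x))))
  if (is.null(descriptions))
    descriptions <- setNames(names(terms), names(terms))
  if (is.null(universe))
    universe <- sort(unique(unlist(terms, use.names = FALSE)))
  new("GeneSetCollection", terms = terms,
      descriptions = descriptions[names(terms)],
      universe = as.integer(sort(unique(universe))))
}

#' Exact hypergeometric upper-tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least \code{k} of the \code{K} term members when \code{n} genes are
#' drawn from a universe of \code{N}. Computed by exact summation of the
#' hypergeometric mass (no normal approximation). Vectorised over
#' \code{k}, \code{K}, \code{n}.
#'
#' @param k overlap observed.
#' @param K term size.
#' @param n query size.
#' @param N universe size.
#' @return numeric vector of upper-tail probabilities.
#' @examples
#' hypergeomP(0, 3, 5, 20)          # P(X >= 0) = 1
#' hypergeomP(5, 5, 5, 20)          # 1 / choose(20, 5)
#' @export
hypergeomP <- function(k, K, n, N) {
  if (any(k < 0) || any(k > pmin(K, n)) || any(K > N) || any(n > N))
    stop("hypergeometric bounds violated: need 0 <= k <= min(K, n), K,n <= N")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Hypergeometric enrichment of a query gene set
#'
#' Every term is tested with [hypergeomP()]; Benjamini-Hochberg adjustment
#' runs over all tested terms, and only then are records filtered to
#' \code{overlap >= min_overlap} (and to raw p <= alpha when alpha < 1).
#' Query genes outside the universe are dropped with a tally (attribute
#' \code{"n_outside_universe"}).
#'
#' @param query integer Entrez vector.
#' @param coll a [GeneSetCollection-class].
#' @param alpha raw p-value cutoff for reporting; 1 reports all terms.
#' @param min_overlap minimum intersection size to report.
#' @param min_term_size,max_term_size optional term-size bounds applied
#'   before testing (NULL = off).
#' @return data.frame of enrichment records sorted by ascending p-value
#'   (ties by term ID): term_id, description, overlap, term_size,
#'   query_size, universe_size, p_value, p_adjusted.
#' @export
enrich <- function(query, coll, alpha = 1, min_overlap = 1L,
                   min_term_size = NULL, max_term_size = NULL) {
  stopifnot(is(coll, "GeneSetCollection"))
  query <- unique(as.integer(query))
  inside <- query %in% coll@universe
  n_out <- sum(!inside)
  query <- query[inside]
  if (length(query) == 0L)
    stop("query is empty after restriction to the universe")
  terms <- coll@terms
  if (!is.null(min_term_size)) terms <- terms[lengths(terms) >= min_term_size]
  if (!is.null(max_term_size)) terms <- terms[lengths(terms) <= max_term_size]
  N <- length(coll@universe)
  n <- length(query)
  K <- lengths(terms)
  k <- vapply(terms, function(mem) sum(query %in% mem), 0L)
  p <- hypergeomP(k, K, n, N)
  p_adj <- p.adjust(p, method = "BH")
  out <- data.frame(
    term_id = names(terms),
    description = unname(coll@descriptions[names(terms)]),
    overlap = as.integer(k), term_size = as.integer(K),
    query_size = n, universe_size = N,
    p_value = as.numeric(p), p_adjusted = as.numeric(p_adj),
    stringsAsFactors = FALSE
  )
  out <- out[out$overlap >= min_overlap & out$p_value <= alpha, ,
             drop = FALSE]
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_outside_universe") <- n_out
  out
}

#' Count significantly enriched terms
#'
#' @param records data.frame from [enrich()].
#' @param threshold significance threshold (strict: p < threshold).
#' @param use_adjusted count on the BH-adjusted p instead of the raw p.
#' @return integer count.
#' @export
countEnriched <- function(records, threshold = 0.01, use_adjusted = FALSE) {
  if (is.null(records) || nrow(records) == 0L) return(0L)
  p <- if (use_adjusted) records$p_adjusted else records$p_value
  sum(p < threshold)
}

#' Permutation null for the number of enriched pathways
#'
#' Draws \code{n_perm} gene sets of exactly \code{set_size} genes uniformly
#' without replacement from the collection's universe, runs the enrichment
#' test on each and counts terms passing the threshold, building the null
#' distribution of the enriched-pathway count. The empirical p-value of the
#' observed count uses the add-one estimator \code{(r + 1) / (n_perm + 1)}
#' where \code{r} is the number of null counts >= observed, so it can never
#' be smaller than \code{1 / (n_perm + 1)} (with 10,000 permutations:
#' 1/10001, i.e. 9.999e-5).
#'
#' @param coll a [GeneSetCollection-class].
#' @param set_size size of each permuted gene set (use the boosted-set
#'   size so the null is size-matched).
#' @param n_perm number of permutations.
#' @param threshold raw-p significance threshold for counting.
#' @param observed observed enriched-pathway count.
#' @param rng_seed integer seed; the draws are reproducible given this.
#' @param use_adjusted count on BH-adjusted p-values instead of raw.
#' @return a [PermutationNull-class].
#' @export
permutationNull <- function(coll, set_size, n_perm = 10000L,
                            threshold = 0.01, observed, rng_seed = 1L,
                            use_adjusted = FALSE) {
  stopifnot(is(coll, "GeneSetCollection"), n_perm >= 1L,
            set_size <= length(coll@universe))
  observed <- as.integer(observed)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(rng_seed))
  univ <- coll@universe
  N <- length(univ)
  K <- lengths(coll@terms)
  # index members once; overlaps per draw are then a single indicator sum
  idx <- lapply(coll@terms, match, univ)
  counts <- integer(n_perm)
  for (b in seq_len(n_perm)) {
    z <- logical(N)
    z[sample.int(N, set_size)] <- TRUE
    k <- vapply(idx, function(ix) sum(z[ix]), 0L)
    p <- hypergeomP(k, K, set_size, N)
    if (use_adjusted) p <- p.adjust(p, method = "BH")
    counts[b] <- sum(p < threshold)
  }
  makePermutationNull(counts, observed, rng_seed = as.integer(rng_seed))
}

#' Assemble a permutation-null summary from precomputed null counts
#'
#' Applies the same add-one estimator as [permutationNull()]; useful when
#' the null counts come from an external or distributed run.
#'
#' @param null_counts integer vector of null enriched-pathway counts.
#' @param observed observed count.
#' @param rng_seed seed that produced the counts (NA if unknown).
#' @return a [PermutationNull-class].
#' @export
makePermutationNull <- function(null_counts, observed, rng_seed = NA_integer_) {
  null_counts <- as.integer(null_counts)
  observed <- as.integer(observed)
  r <- sum(null_counts >= observed)
  new("PermutationNull", nPerm = length(null_counts),
      nullCounts = null_counts, observed = observed,
      empiricalP = (r + 1) / (length(null_counts) + 1),
      rngSeed = as.integer(rng_seed))
}

#' Long-format table of term significance across boosting levels
#'
#' One row per (term, level). Levels at which a term was not reported (or
#' not significant) carry NA in \code{p_value} and \code{overlap} — the
#' "N/A" convention of cross-level comparison tables.
#'
#' @param per_level_records named list: level label -> data.frame from
#'   [enrich()].
#' @param terms character vector of term IDs to tabulate; defaults to the
#'   union of all reported terms.
#' @return data.frame: term_id, level, overlap, p_value.
#' @export
dotplotTable <- function(per_level_records, terms = NULL) {
  if (is.null(terms))
    terms <- sort(unique(unlist(lapply(per_level_records,
                                       function(r) r$term_id))))
  if (length(terms) == 0L || length(per_level_records) == 0L)
    return(data.frame(term_id = character(), level = character(),
                      overlap = integer(), p_value = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(names(per_level_records), function(lv) {
    r <- per_level_records[[lv]]
    m <- match(terms, r$term_id)
    data.frame(term_id = terms, level = lv,
               overlap = r$overlap[m], p_value = r$p_value[m],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
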