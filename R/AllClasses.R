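#' @import methods
#' @importClassesFrom Matrix Matrix
#' @importFrom stats dhyper phyper p.adjust sd setNames runif
#' @importFrom utils read.delim read.table write.table head combn packageVersion
NULL

#' TargetDatabase: a set of miRNA-target interaction pairs
#'
#' Holds experimentally validated or predicted miRNA-target interactions as
#' a set of (mature miRNA name, Entrez gene) pairs. The pair is the identity
#' for set semantics; the source tag records provenance but is ignored when
#' databases are intersected or unioned.
#'
#' @slot interactions data.frame with columns \code{mirna} (character,
#'   canonical mature name), \code{entrez} (integer), \code{source}
#'   (character).
#' @slot name single character label for the database.
#' @slot metadata list of read-report counters (rows read, unmapped tallies).
#'
#' @seealso [readTargetTable()], [combineDatabases()], [targetsOf()]
#' @export
setClass("TargetDatabase",
  representation(
    interactions = "data.frame",
    name = "character",
    metadata = "list"
  ),
  prototype(
    interactions = data.frame(
      mirna = character(), entrez = integer(), source = character(),
      stringsAsFactors = FALSE
    ),
    name = "db",
    metadata = list()
  )
)

setValidity("TargetDatabase", function(object) {
  msg <- character()
  ia <- object@interactions
  if (!all(c("mirna", "entrez", "source") %in% names(ia)))
    msg <- c(msg, "interactions needs columns mirna, entrez, source")
  else {
    if (nrow(ia) && anyDuplicated(paste(ia$mirna, ia$entrez)))
      msg <- c(msg, "duplicate (mirna, entrez) pairs")
    if (nrow(ia) && any(ia$entrez < 1L))
      msg <- c(msg, "entrez IDs must be >= 1")
  }
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (length(msg)) msg else TRUE
})

#' PPINetwork: an undirected scored protein-protein interaction graph
#'
#' Nodes are Entrez gene IDs held in ascending order; edges are stored once
#' per unordered pair with a numeric confidence score (STRING combined-score
#' convention). Self-loops are never stored.
#'
#' @slot nodes integer vector of Entrez IDs, sorted ascending.
#' @slot symbols character vector parallel to \code{nodes} (display symbols,
#'   may be NA).
#' @slot edges data.frame with columns \code{from}, \code{to} (integer
#'   Entrez, from < to) and \code{score} (numeric).
#' @slot metadata list of read-report counters.
#'
#' @seealso [readEdgeList()], [filterTopFraction()], [buildTransitionMatrix()]
#' @export
setClass("PPINetwork",
  representation(
    nodes = "integer",
    symbols = "character",
    edges = "data.frame",
    metadata = "list"
  ),
  prototype(
    nodes = integer(),
    symbols = character(),
    edges = data.frame(from = integer(), to = integer(), score = numeric(),
                       stringsAsFactors = FALSE),
    metadata = list()
  )
)

setValidity("PPINetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "score") %in% names(e)))
    msg <- c(msg, "edges needs columns from, to, score")
  else if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be stored with from < to")
    if (anyDuplicated(paste(e$from, e$to)))
      msg <- c(msg, "duplicate edges")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
  }
  if (is.unsorted(object@nodes, strictly = TRUE) && length(object@nodes) > 1L)
    msg <- c(msg, "nodes must be strictly ascending")
  if (length(object@symbols) != length(object@nodes))
    msg <- c(msg, "symbols must be parallel to nodes")
  if (length(msg)) msg else TRUE
})

#' TransitionMatrix: column-normalised adjacency for network propagation
#'
#' Square sparse matrix over the network's node order. Every column over a
#' node with at least one edge sums to one; columns of isolated nodes sum to
#' zero and are flagged so the walker can redirect their mass to the restart
#' distribution.
#'
#' @slot mat a column-normalised \code{dgCMatrix}.
#' @slot nodes integer Entrez IDs defining row/column order.
#' @slot isolated logical vector flagging zero-degree columns.
#' @export
setClass("TransitionMatrix",
  representation(mat = "Matrix", nodes = "integer", isolated = "logical")
)

setValidity("TransitionMatrix", function(object) {
  msg <- character()
  d <- dim(object@mat)
  if (d[1L] != d[2L]) msg <- c(msg, "matrix must be square")
  if (d[1L] != length(object@nodes))
    msg <- c(msg, "matrix dimension must match node count")
  if (length(object@isolated) != length(object@nodes))
    msg <- c(msg, "isolated flag must be parallel to nodes")
  cs <- Matrix::colSums(object@mat)
  if (any(abs(cs[!object@isolated] - 1) > 1e-12))
    msg <- c(msg, "non-isolated columns must sum to 1 (tol 1e-12)")
  if (any(cs[object@isolated] != 0))
    msg <- c(msg, "isolated columns must sum to 0")
  if (length(msg)) msg else TRUE
})

#' SeedSet: restart nodes for propagation
#'
#' The seed genes are the restart support of the walk: by default the
#' intersection of the differentially expressed genes (DEGs) with the
#' targets of the differentially expressed miRNAs (DERs), restricted to the
#' network's nodes.
#'
#' @slot genes integer Entrez IDs, sorted ascending, all present in the
#'   network the set was built against.
#' @slot provenance data.frame with columns \code{entrez}, \code{is_deg},
#'   \code{is_der_target}.
#' @slot dropped integer Entrez IDs excluded because they were absent from
#'   the network.
#' @export
setClass("SeedSet",
  representation(genes = "integer", provenance = "data.frame",
                 dropped = "integer")
)

setValidity("SeedSet", function(object) {
  msg <- character()
  if (length(object@genes) == 0L) msg <- c(msg, "seed set may not be empty")
  if (is.unsorted(object@genes, strictly = TRUE) && length(object@genes) > 1L)
    msg <- c(msg, "genes must be strictly ascending")
  pv <- object@provenance
  if (!all(c("entrez", "is_deg", "is_der_target") %in% names(pv)))
    msg <- c(msg, "provenance needs columns entrez, is_deg, is_der_target")
  else if (!setequal(pv$entrez, object@genes))
    msg <- c(msg, "provenance must cover exactly the seed genes")
  if (length(msg)) msg else TRUE
})

#' RWRScores: the stationary distribution of a restarted walk
#'
#' @slot scores numeric vector named by Entrez ID; a probability
#'   distribution over the network nodes (mass 1 within 1e-9).
#' @slot restartP restart probability used.
#' @slot iterations number of power iterations performed.
#' @slot converged logical; FALSE when max_iter was hit first.
#' @slot massTrace numeric vector of total mass after each iteration
#'   (conservation diagnostic).
#' @export
setClass("RWRScores",
  representation(scores = "numeric", restartP = "numeric",
                 iterations = "integer", converged = "logical",
                 massTrace = "numeric")
)

setValidity("RWRScores", function(object) {
  msg <- character()
  if (any(object@scores < 0)) msg <- c(msg, "scores must be non-negative")
  if (abs(sum(object@scores) - 1) > 1e-9)
    msg <- c(msg, "scores must sum to 1 (tol 1e-9)")
  if (is.null(names(object@scores)))
    msg <- c(msg, "scores must be named by Entrez ID")
  if (length(msg)) msg else TRUE
})

#' BoostedGeneSet: seeds plus top-ranked propagated genes
#'
#' A boosting level of \code{l} keeps the top \code{ceiling(l * n_nonseed)}
#' non-seed nodes by descending walk score (ties broken by ascending Entrez
#' ID); the seeds are always members. Each added gene is classified
#' \emph{direct} when it has at least one network edge to a seed, otherwise
#' \emph{indirect}.
#'
#' @slot level boosting level in [0, 1].
#' @slot genes integer Entrez IDs, seeds first (ascending), then added genes
#'   by descending score.
#' @slot seeds integer Entrez IDs of the seed genes.
#' @slot classification character vector named by Entrez over the non-seed
#'   members, values "direct"/"indirect".
#' @slot scores numeric walk scores named by Entrez over all members.
#' @export
setClass("BoostedGeneSet",
  representation(level = "numeric", genes = "integer", seeds = "integer",
                 classification = "character", scores = "numeric")
)

setValidity("BoostedGeneSet", function(object) {
  msg <- character()
  if (object@level < 0 || object@level > 1)
    msg <- c(msg, "level must be in [0, 1]")
  if (!all(object@seeds %in% object@genes))
    msg <- c(msg, "seeds must be members")
  added <- setdiff(object@genes, object@seeds)
  if (!setequal(names(object@classification), as.character(added)))
    msg <- c(msg, "classification must cover exactly the non-seed members")
  if (length(object@classification) &&
      !all(object@classification %in% c("direct", "indirect")))
    msg <- c(msg, "classification values must be direct/indirect")
  if (length(msg)) msg else TRUE
})

#' GeneSetCollection: a GMT-style pathway collection
#'
#' @slot terms named list of integer Entrez vectors (term members).
#' @slot descriptions character vector named by term ID.
#' @slot universe integer vector of background genes.
#' @export
setClass("GeneSetCollection",
  representation(terms = "list", descriptions = "character",
                 universe = "integer")
)

setValidity("GeneSetCollection", function(object) {
  msg <- character()
  if (length(object@terms)) {
    if (is.null(names(object@terms)) || any(names(object@terms) == ""))
      msg <- c(msg, "terms must be named")
    sizes <- lengths(object@terms)
    if (any(sizes < 1L)) msg <- c(msg, "term sizes must be >= 1")
    if (!all(unlist(object@terms, use.names = FALSE) %in% object@universe))
      msg <- c(msg, "every term member must be in the universe")
    if (!setequal(names(object@descriptions), names(object@terms)))
      msg <- c(msg, "descriptions must cover exactly the terms")
  }
  if (length(msg)) msg else TRUE
})

#' PermutationNull: null distribution of the enriched-pathway count
#'
#' Size-matched random gene sets are drawn from the universe; the number of
#' terms passing the significance threshold in each draw forms the null.
#' The empirical p-value uses the add-one estimator
#' \eqn{(r + 1) / (n_{perm} + 1)} with \eqn{r} the number of null counts at
#' least as large as the observed count, so its floor with 10,000
#' permutations is \eqn{1/10001 \approx 9.999 \times 10^{-5}}.
#'
#' @slot nPerm number of permutations.
#' @slot nullCounts integer vector of null enriched-pathway counts.
#' @slot observed observed enriched-pathway count.
#' @slot empiricalP add-one empirical p-value.
#' @slot rngSeed seed used for the draws (NA when counts were supplied).
#' @export
setClass("PermutationNull",
  representation(nPerm = "integer", nullCounts = "integer",
                 observed = "integer", empiricalP = "numeric",
                 rngSeed = "integer")
)

setValidity("PermutationNull", function(object) {
  msg <- character()
  if (length(object@nullCounts) != object@nPerm)
    msg <- c(msg, "nullCounts must have length nPerm")
  r <- sum(object@nullCounts >= object@observed)
  expect <- (r + 1) / (object@nPerm + 1)
  if (abs(object@empiricalP - expect) > 1e-15)
    msg <- c(msg, "empiricalP must equal (r + 1) / (nPerm + 1)")
  if (length(msg)) msg else TRUE
})

#' CentralityReport: degree and eigenvector centrality of a network
#'
#' @slot table data.frame with columns \code{entrez}, \code{degree},
#'   \code{eigenvector}.
#' @slot meanDegree mean node degree.
#' @slot meanCentrality mean eigenvector centrality.
#' @slot converged logical flag from the power iteration.
#' @slot connected FALSE when the network had more than one component (the
#'   centrality mass then concentrates on the dominant component).
#' @export
setClass("CentralityReport",
  representation(table = "data.frame", meanDegree = "numeric",
                 meanCentrality = "numeric", converged = "logical",
                 connected = "logical")
)

#' OverlayNetwork: genes plus regulating miRNAs for visualisation
#'
#' Gene nodes carry one of three mutually exclusive classes: \code{seed},
#' \code{boosted_target} (a non-seed boosted gene that is a DER target or a
#' DEG) or \code{boosted} (neither). miRNA nodes attach only through
#' \code{mirna_target} edges; gene-gene edges are the induced PPI edges.
#'
#' @slot geneNodes data.frame: \code{entrez}, \code{symbol}, \code{class},
#'   \code{score}, \code{degree}.
#' @slot mirnaNodes character vector of mature miRNA names.
#' @slot edges data.frame: \code{from}, \code{to} (node identifiers as
#'   character), \code{type} ("ppi" or "mirna_target").
#' @export
setClass("OverlayNetwork",
  representation(geneNodes = "data.frame", mirnaNodes = "character",
                 edges = "data.frame")
)

setValidity("OverlayNetwork", function(object) {
  msg <- character()
  gn <- object@geneNodes
  need <- c("entrez", "symbol", "class", "score", "degree")
  if (!all(need %in% names(gn)))
    msg <- c(msg, "geneNodes needs columns entrez, symbol, class, score, degree")
  else if (nrow(gn) &&
           !all(gn$class %in% c("seed", "boosted", "boosted_target")))
    msg <- c(msg, "gene class must be seed/boosted/boosted_target")
  e <- object@edges
  if (!all(c("from", "to", "type") %in% names(e)))
    msg <- c(msg, "edges needs columns from, to, type")
  else if (nrow(e)) {
    if (!all(e$type %in% c("ppi", "mirna_target")))
      msg <- c(msg, "edge type must be ppi/mirna_target")
    mir_touch <- e$from %in% object@mirnaNodes | e$to %in% object@mirnaNodes
    if (any(mir_touch & e$type != "mirna_target"))
      msg <- c(msg, "miRNA nodes may only carry mirna_target edges")
  }
  if (length(msg)) msg else TRUE
})
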