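# STRING-style PPI ingestion, confidence filtering, and the column-
# stochastic transition matrix that drives the restarted walk.

.new_ppi <- function(edges, id_map = NULL, metadata = list(),
                     extra_nodes = integer()) {
  # canonicalise: from < to, max score per unordered pair, sorted nodes
  if (nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    o <- order(edges$from, edges$to, -edges$score)
    edges <- edges[o, , drop = FALSE]
    edges <- edges[!duplicated(paste(edges$from, edges$to)), , drop = FALSE]
  }
  nodes <- sort(unique(c(edges$from, edges$to, extra_nodes)))
  symbols <- if (is.null(id_map)) rep(NA_character_, length(nodes)) else
    entrezToSymbol(nodes, id_map)
  rownames(edges) <- NULL
  new("PPINetwork", nodes = as.integer(nodes), symbols = symbols,
      edges = edges, metadata = metadata)
}

#' Construct a PPI network from an edge data.frame
#'
#' @param from,to integer Entrez endpoints.
#' @param score numeric confidence scores (default 1).
#' @param id_map optional id map supplying display symbols.
#' @param extra_nodes Entrez IDs to include even when isolated.
#' @return a [PPINetwork-class]. Self-loops are dropped; symmetric
#'   duplicates collapse keeping the maximum score.
#' @export
ppiNetwork <- function(from, to, score = rep(1, length(from)),
                       id_map = NULL, extra_nodes = integer()) {
  e <- data.frame(from = as.integer(from), to = as.integer(to),
                  score = as.numeric(score), stringsAsFactors = FALSE)
  n_self <- sum(e$from == e$to)
  e <- e[e$from != e$to, , drop = FALSE]
  .new_ppi(e, id_map, metadata = list(self_loops = n_self),
           extra_nodes = as.integer(extra_nodes))
}

#' Read a scored protein-protein edge list
#'
#' Understands the STRING protein-links shape (whitespace-separated columns
#' \code{protein1 protein2 combined_score}, optionally with a taxon prefix
#' such as \code{9606.} on the identifiers) and a generic 3-column TSV.
#' Endpoint identifiers are resolved through the id map; edges with an
#' unmappable endpoint are dropped and tallied. Symmetric duplicates
#' collapse to one edge keeping the maximum score; self-loops are dropped
#' with a tally. The tallies are available via [readReport()].
#'
#' @param path edge-list file.
#' @param dialect "string-links" (whitespace-separated) or "generic-tsv".
#' @param id_map id map from [readIdMap()].
#' @param strip_prefix regular expression removed from the start of each
#'   identifier (STRING's taxon prefix); NULL to disable.
#' @return a [PPINetwork-class].
#' @export
readEdgeList <- function(path, dialect = c("string-links", "generic-tsv"),
                         id_map, strip_prefix = "^[0-9]+\\.") {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "string-links") "" else "\t"
  tab <- read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(tab) < 3L)
    stop("edge list needs 3 columns (node, node, score): ", path)
  a <- tab[[1L]]; b <- tab[[2L]]
  sc <- suppressWarnings(as.numeric(tab[[3L]]))
  if (anyNA(sc)) {
    bad <- which(is.na(sc))[1L]
    stop("non-numeric score at data line ", bad, " of ", path)
  }
  if (!is.null(strip_prefix)) {
    a <- sub(strip_prefix, "", a)
    b <- sub(strip_prefix, "", b)
  }
  ma <- mapSymbols(a, id_map)
  mb <- mapSymbols(b, id_map)
  ia <- ma$mapping[match(a, names(ma$mapping))]
  ib <- mb$mapping[match(b, names(mb$mapping))]
  ok <- !is.na(ia) & !is.na(ib)
  n_unmapped_edges <- sum(!ok)
  e <- data.frame(from = as.integer(ia[ok]), to = as.integer(ib[ok]),
                  score = sc[ok], stringsAsFactors = FALSE)
  n_self <- sum(e$from == e$to)
  e <- e[e$from != e$to, , drop = FALSE]
  .new_ppi(e, id_map, metadata = list(
    lines_in = nrow(tab),
    self_loops = n_self,
    unmapped_edges = n_unmapped_edges,
    unmapped_ids = length(unique(c(ma$unmapped, mb$unmapped)))
  ))
}

#' Keep the top-confidence fraction of edges
#'
#' Retains the \code{ceiling(fraction * n_edges)} highest-scoring edges;
#' all edges tied at the cutoff score are kept, so the result may slightly
#' exceed the ceiling. Nodes left without any edge are removed. The
#' fraction counts edges — "top 1 percent of interactions" reads as an
#' interaction count, not a score quantile.
#'
#' @param net a [PPINetwork-class] with at least one edge.
#' @param fraction value in (0, 1].
#' @return the filtered [PPINetwork-class].
#' @export
filterTopFraction <- function(net, fraction) {
  stopifnot(is(net, "PPINetwork"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1)
    stop("fraction must be a single value in (0, 1]")
  e <- net@edges
  if (nrow(e) == 0L) stop("network has no edges")
  k <- ceiling(fraction * nrow(e))
  cutoff <- sort(e$score, decreasing = TRUE)[k]
  keep <- e$score >= cutoff
  out <- .new_ppi(e[keep, , drop = FALSE], metadata = net@metadata)
  .carry_symbols(out, net)
}

# reattach display symbols after a node-subset operation
.carry_symbols <- function(out, net) {
  out@symbols <- net@symbols[match(out@nodes, net@nodes)]
  validObject(out)
  out
}

#' Build the column-normalised transition matrix
#'
#' Entry (i, j) is the probability of stepping to node i from node j:
#' weight(i, j) divided by the column total. Binary weighting gives every
#' retained edge weight 1 (the default — confidence has already been spent
#' by the top-fraction filter); score weighting uses the confidence scores.
#' Columns of isolated nodes are zero and flagged; [rwr()] redirects their
#' mass to the restart distribution.
#'
#' @param net a non-empty [PPINetwork-class].
#' @param weighting "binary" or "score".
#' @return a [TransitionMatrix-class].
#' @export
buildTransitionMatrix <- function(net, weighting = c("binary", "score")) {
  weighting <- match.arg(weighting)
  stopifnot(is(net, "PPINetwork"), length(net@nodes) > 0L)
  n <- length(net@nodes)
  e <- net@edges
  i <- match(e$from, net@nodes)
  j <- match(e$to, net@nodes)
  w <- if (weighting == "binary") rep(1, nrow(e)) else e$score
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = c(w, w),
                            dims = c(n, n))
  cs <- Matrix::colSums(A)
  isolated <- cs == 0
  scale <- ifelse(isolated, 0, 1 / cs)
  A <- A %*% Matrix::Diagonal(n, scale)
  new("TransitionMatrix", mat = methods::as(A, "CsparseMatrix"),
      nodes = net@nodes, isolated = as.vector(isolated))
}

#' Write a network as TSV (from, to, score)
#'
#' @param net a [PPINetwork-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeNetworkTsv <- function(net, path) {
  write.table(net@edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
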