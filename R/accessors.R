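#' @name accessors
#' @title Accessors for rwrboost classes
#'
#' @description Small accessor generics so user code never touches slots:
#' \code{interactions()} returns the pair table of a [TargetDatabase-class];
#' \code{networkNodes()}, \code{networkEdges()} and \code{nodeSymbols()}
#' expose a [PPINetwork-class]; \code{walkScores()} the named probability
#' vector of an [RWRScores-class]; \code{boostedGenes()} and
#' \code{seedGenes()} the members of a [BoostedGeneSet-class] /
#' [SeedSet-class]; \code{geneSets()} and \code{geneUniverse()} a
#' [GeneSetCollection-class]; \code{nullCounts()} and \code{empiricalP()} a
#' [PermutationNull-class].
#'
#' @param x object to access.
#' @return The slot contents described above.
NULL

#' @rdname accessors
#' @export
setGeneric("interactions", function(x) standardGeneric("interactions"))
#' @rdname accessors
#' @export
setMethod("interactions", "TargetDatabase", function(x) x@interactions)

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setMethod("networkNodes", "PPINetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "PPINetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("nodeSymbols", function(x) standardGeneric("nodeSymbols"))
#' @rdname accessors
#' @export
setMethod("nodeSymbols", "PPINetwork",
          function(x) setNames(x@symbols, x@nodes))

#' @rdname accessors
#' @export
setGeneric("readReport", function(x) standardGeneric("readReport"))
#' @rdname accessors
#' @export
setMethod("readReport", "TargetDatabase", function(x) x@metadata)
#' @rdname accessors
#' @export
setMethod("readReport", "PPINetwork", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("walkScores", function(x) standardGeneric("walkScores"))
#' @rdname accessors
#' @export
setMethod("walkScores", "RWRScores", function(x) x@scores)

#' @rdname accessors
#' @export
setGeneric("seedGenes", function(x) standardGeneric("seedGenes"))
#' @rdname accessors
#' @export
setMethod("seedGenes", "SeedSet", function(x) x@genes)
#' @rdname accessors
#' @export
setMethod("seedGenes", "BoostedGeneSet", function(x) x@seeds)

#' @rdname accessors
#' @export
setGeneric("boostedGenes", function(x) standardGeneric("boostedGenes"))
#' @rdname accessors
#' @export
setMethod("boostedGenes", "BoostedGeneSet", function(x) x@genes)

#' @rdname accessors
#' @export
setGeneric("geneClassification", function(x) standardGeneric("geneClassification"))
#' @rdname accessors
#' @export
setMethod("geneClassification", "BoostedGeneSet", function(x) x@classification)

#' @rdname accessors
#' @export
setGeneric("boostLevel", function(x) standardGeneric("boostLevel"))
#' @rdname accessors
#' @export
setMethod("boostLevel", "BoostedGeneSet", function(x) x@level)

#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@terms)

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setMethod("geneUniverse", "GeneSetCollection", function(x) x@universe)

#' @rdname accessors
#' @export
setGeneric("nullCounts", function(x) standardGeneric("nullCounts"))
#' @rdname accessors
#' @export
setMethod("nullCounts", "PermutationNull", function(x) x@nullCounts)

#' @rdname accessors
#' @export
setGeneric("empiricalP", function(x) standardGeneric("empiricalP"))
#' @rdname accessors
#' @export
setMethod("empiricalP", "PermutationNull", function(x) x@empiricalP)

setMethod("show", "TargetDatabase", function(object) {
  cat("TargetDatabase '", object@name, "': ", nrow(object@interactions),
      " interactions, ", length(unique(object@interactions$mirna)),
      " miRNAs, ", length(unique(object@interactions$entrez)),
      " genes\n", sep = "")
})

setMethod("show", "PPINetwork", function(object) {
  cat("PPINetwork: ", length(object@nodes), " nodes, ",
      nrow(object@edges), " edges\n", sep = "")
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix: ", length(object@nodes), " x ",
      length(object@nodes), ", ", sum(object@isolated),
      " isolated column(s)\n", sep = "")
})

setMethod("show", "SeedSet", function(object) {
  cat("SeedSet: ", length(object@genes), " seed genes (",
      length(object@dropped), " dropped, absent from network)\n", sep = "")
})

setMethod("show", "RWRScores", function(object) {
  cat("RWRScores over ", length(object@scores), " nodes; restart p = ",
      object@restartP, "; ", object@iterations, " iterations (",
      if (object@converged) "converged" else "NOT converged", ")\n",
      sep = "")
})

setMethod("show", "BoostedGeneSet", function(object) {
  n_added <- length(object@genes) - length(object@seeds)
  cat("BoostedGeneSet at level ", object@level, ": ",
      length(object@genes), " genes = ", length(object@seeds),
      " seeds + ", n_added, " boosted (",
      sum(object@classification == "direct"), " direct, ",
      sum(object@classification == "indirect"), " indirect)\n", sep = "")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection: ", length(object@terms), " terms over a ",
      length(object@universe), "-gene universe\n", sep = "")
})

setMethod("show", "PermutationNull", function(object) {
  cat("PermutationNull: observed ", object@observed, " vs ",
      object@nPerm, " permutations (null mean ",
      round(mean(object@nullCounts), 2), "); empirical p = ",
      format(object@empiricalP, digits = 4), "\n", sep = "")
})

setMethod("show", "CentralityReport", function(object) {
  cat("CentralityReport: ", nrow(object@table), " nodes; mean degree ",
      round(object@meanDegree, 2), ", mean centrality ",
      signif(object@meanCentrality, 3),
      if (!object@connected) " [disconnected graph]" else "", "\n",
      sep = "")
})

setMethod("show", "OverlayNetwork", function(object) {
  cat("OverlayNetwork: ", nrow(object@geneNodes), " gene nodes, ",
      length(object@mirnaNodes), " miRNA nodes, ", nrow(object@edges),
      " edges\n", sep = "")
})
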