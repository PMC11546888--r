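# Subnetwork extraction, degree / eigenvector-centrality reports, hub
# calling, and the miRNA-gene overlay network with GraphML / JSON export.

#' Induced subnetwork on a gene set
#'
#' @param net a [PPINetwork-class].
#' @param genes integer Entrez vector.
#' @return the [PPINetwork-class] on \code{genes} intersected with the
#'   nodes, keeping edges with both endpoints inside.
#' @export
inducedSubnetwork <- function(net, genes) {
  stopifnot(is(net, "PPINetwork"))
  keep <- intersect(net@nodes, as.integer(genes))
  e <- net@edges
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  out <- .new_ppi(e, extra_nodes = keep, metadata = net@metadata)
  .carry_symbols(out, net)
}

#' Per-node degree and the network mean
#'
#' @param net a [PPINetwork-class].
#' @return data.frame (entrez, degree) with the mean degree as attribute
#'   \code{"mean_degree"}. Sum of degrees is twice the edge count.
#' @export
degreeReport <- function(net) {
  stopifnot(is(net, "PPINetwork"))
  deg <- tabulate(match(c(net@edges$from, net@edges$to), net@nodes),
                  nbins = length(net@nodes))
  out <- data.frame(entrez = net@nodes, degree = as.integer(deg))
  attr(out, "mean_degree") <- if (nrow(out)) mean(deg) else NA_real_
  out
}

#' Eigenvector centrality by power iteration
#'
#' Principal eigenvector of the binary adjacency matrix, computed by power
#' iteration from a uniform start vector and normalised to unit Euclidean
#' norm, so the result is deterministic and non-negative. On a
#' disconnected graph the mass concentrates on the component with the
#' largest leading eigenvalue; the report flags this so tiny centralities
#' on dominated components are not over-read.
#'
#' @param net a [PPINetwork-class] with at least one edge.
#' @param tol L-infinity convergence tolerance on the iterate.
#' @param max_iter iteration cap (warns and flags on non-convergence).
#' @return a [CentralityReport-class].
#' @export
eigenvectorCentrality <- function(net, tol = 1e-10, max_iter = 10000L) {
  stopifnot(is(net, "PPINetwork"), nrow(net@edges) >= 1L)
  n <- length(net@nodes)
  i <- match(net@edges$from, net@nodes)
  j <- match(net@edges$to, net@nodes)
  A <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = 1, dims = c(n, n))
  x <- rep(1 / sqrt(n), n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # shifted iteration (A + I): same principal eigenvector, but immune to
    # the +/-lambda oscillation of bipartite graphs
    x_new <- as.numeric(A %*% x) + x
    nrm <- sqrt(sum(x_new^2))
    if (nrm == 0) break  # all mass on isolated nodes; keep last iterate
    x_new <- x_new / nrm
    if (max(abs(x_new - x)) < tol) { x <- x_new; converged <- TRUE; break }
    x <- x_new
  }
  if (!converged)
    warning("eigenvector centrality did not converge in ", max_iter,
            " iterations")
  deg <- degreeReport(net)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(net@edges$from),
               to = as.character(net@edges$to)),
    directed = FALSE, vertices = as.character(net@nodes))
  connected <- igraph::is_connected(g)
  if (!connected)
    warning("network is disconnected; centrality mass concentrates on ",
            "the dominant component")
  new("CentralityReport",
      table = data.frame(entrez = net@nodes, degree = deg$degree,
                         eigenvector = pmax(x, 0)),
      meanDegree = attr(deg, "mean_degree"),
      meanCentrality = mean(pmax(x, 0)),
      converged = converged, connected = connected)
}

#' Call hub genes from a centrality report
#'
#' Two criteria are offered because no single convention exists:
#' \code{degree_top_k} takes the k highest-degree nodes (ties by ascending
#' Entrez), \code{degree_sd} takes nodes with degree strictly above
#' \code{mean + param * SD} (so a regular graph yields no hubs).
#'
#' @param report a [CentralityReport-class].
#' @param method "degree_top_k" or "degree_sd".
#' @param param k for top-k (default 3), or the SD multiplier (default 2).
#' @return integer Entrez vector of hubs, ordered by descending degree.
#' @export
findHubs <- function(report, method = c("degree_top_k", "degree_sd"),
                     param = NULL) {
  method <- match.arg(method)
  tab <- report@table
  if (method == "degree_top_k") {
    k <- if (is.null(param)) 3L else as.integer(param)
    if (k > nrow(tab)) {
      warning("k exceeds node count; returning all nodes")
      k <- nrow(tab)
    }
    ord <- order(-tab$degree, tab$entrez)
    tab$entrez[ord][seq_len(k)]
  } else {
    mult <- if (is.null(param)) 2 else param
    cut <- mean(tab$degree) + mult * sd(tab$degree)
    # strict: a regular graph (SD 0) has no outliers
    hubs <- tab[tab$degree > cut, , drop = FALSE]
    hubs$entrez[order(-hubs$degree, hubs$entrez)]
  }
}

#' Build the miRNA-gene overlay network for visualisation
#'
#' Gene nodes are the boosted set, classed \code{seed},
#' \code{boosted_target} (non-seed boosted gene that is a DER target or a
#' DEG) or \code{boosted} (neither). miRNA nodes are the DERs with at
#' least one target among the gene nodes; edges are the induced PPI edges
#' plus miRNA-to-target edges.
#'
#' @param boosted a [BoostedGeneSet-class].
#' @param seeds the [SeedSet-class].
#' @param db a [TargetDatabase-class] (used for DER-target edges).
#' @param ders character vector of DER names.
#' @param net the [PPINetwork-class].
#' @param degs optional integer Entrez vector of DEGs (for the
#'   boosted_target class).
#' @return an [OverlayNetwork-class].
#' @export
buildOverlay <- function(boosted, seeds, db, ders, net, degs = integer()) {
  genes <- boosted@genes
  ia <- db@interactions
  der_ia <- ia[ia$mirna %in% ders & ia$entrez %in% genes, , drop = FALSE]
  der_targets <- unique(der_ia$entrez)
  cls <- ifelse(genes %in% seeds@genes, "seed",
         ifelse(genes %in% der_targets | genes %in% as.integer(degs),
                "boosted_target", "boosted"))
  sub <- inducedSubnetwork(net, genes)
  deg <- degreeReport(sub)
  gene_nodes <- data.frame(
    entrez = as.integer(genes),
    symbol = net@symbols[match(genes, net@nodes)],
    class = cls,
    score = as.numeric(boosted@scores[as.character(genes)]),
    degree = deg$degree[match(genes, deg$entrez)],
    stringsAsFactors = FALSE
  )
  gene_nodes$degree[is.na(gene_nodes$degree)] <- 0L
  ppi_edges <- data.frame(from = as.character(sub@edges$from),
                          to = as.character(sub@edges$to),
                          type = if (nrow(sub@edges)) "ppi" else character(),
                          stringsAsFactors = FALSE)
  mir_edges <- data.frame(from = der_ia$mirna,
                          to = as.character(der_ia$entrez),
                          type = if (nrow(der_ia)) "mirna_target"
                                 else character(),
                          stringsAsFactors = FALSE)
  new("OverlayNetwork", geneNodes = gene_nodes,
      mirnaNodes = sort(unique(der_ia$mirna)),
      edges = rbind(ppi_edges, mir_edges))
}

.overlay_igraph <- function(overlay) {
  gn <- overlay@geneNodes
  verts <- data.frame(
    name = c(as.character(gn$entrez), overlay@mirnaNodes),
    node_type = c(rep("gene", nrow(gn)),
                  rep("mirna", length(overlay@mirnaNodes))),
    class = c(gn$class, rep("mirna", length(overlay@mirnaNodes))),
    symbol = c(ifelse(is.na(gn$symbol), "", gn$symbol), overlay@mirnaNodes),
    score = c(gn$score, rep(0, length(overlay@mirnaNodes))),
    degree = c(gn$degree, rep(0L, length(overlay@mirnaNodes))),
    stringsAsFactors = FALSE
  )
  e <- overlay@edges
  igraph::graph_from_data_frame(
    data.frame(from = e$from, to = e$to, edge_type = e$type,
               stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
}

#' Export an overlay network as GraphML or node-link JSON
#'
#' Both formats carry node attributes (class, node_type, symbol, score,
#' degree) and the edge type, and round-trip losslessly through
#' [readOverlay()].
#'
#' @param overlay an [OverlayNetwork-class].
#' @param path output file.
#' @param format "graphml" or "json".
#' @return \code{path}, invisibly.
#' @export
exportOverlay <- function(overlay, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- .overlay_igraph(overlay)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    gn <- overlay@geneNodes
    obj <- list(
      nodes = data.frame(
        id = c(as.character(gn$entrez), overlay@mirnaNodes),
        node_type = c(rep("gene", nrow(gn)),
                      rep("mirna", length(overlay@mirnaNodes))),
        class = c(gn$class, rep("mirna", length(overlay@mirnaNodes))),
        symbol = c(ifelse(is.na(gn$symbol), "", gn$symbol),
                   overlay@mirnaNodes),
        score = c(gn$score, rep(0, length(overlay@mirnaNodes))),
        degree = as.integer(c(gn$degree,
                              rep(0L, length(overlay@mirnaNodes)))),
        stringsAsFactors = FALSE),
      links = overlay@edges
    )
    jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read an overlay network written by [exportOverlay()]
#'
#' @param path GraphML or JSON file.
#' @param format "graphml" or "json".
#' @return an [OverlayNetwork-class].
#' @export
readOverlay <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nv <- igraph::vcount(g)
    if (nv == 0L) {
      verts <- data.frame(name = character(), node_type = character(),
                          class = character(), symbol = character(),
                          score = numeric(), degree = numeric(),
                          stringsAsFactors = FALSE)
      edges <- data.frame(from = character(), to = character(),
                          edge_type = character(), stringsAsFactors = FALSE)
    } else {
      verts <- data.frame(
        name = igraph::V(g)$name,
        node_type = igraph::V(g)$node_type,
        class = igraph::V(g)$class,
        symbol = igraph::V(g)$symbol,
        score = igraph::V(g)$score,
        degree = igraph::V(g)$degree,
        stringsAsFactors = FALSE)
      ee <- igraph::as_data_frame(g, what = "edges")
      edges <- data.frame(from = ee$from, to = ee$to,
                          edge_type = ee$edge_type,
                          stringsAsFactors = FALSE)
    }
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    verts <- as.data.frame(obj$nodes, stringsAsFactors = FALSE)
    if (nrow(verts)) names(verts)[names(verts) == "id"] <- "name"
    else verts <- data.frame(name = character(), node_type = character(),
                             class = character(), symbol = character(),
                             score = numeric(), degree = numeric())
    lk <- as.data.frame(obj$links, stringsAsFactors = FALSE)
    edges <- if (nrow(lk))
      data.frame(from = as.character(lk$from), to = as.character(lk$to),
                 edge_type = lk$type, stringsAsFactors = FALSE)
    else data.frame(from = character(), to = character(),
                    edge_type = character(), stringsAsFactors = FALSE)
  }
  is_gene <- verts$node_type == "gene"
  gene_nodes <- data.frame(
    entrez = as.integer(verts$name[is_gene]),
    symbol = ifelse(verts$symbol[is_gene] == "", NA_character_,
                    verts$symbol[is_gene]),
    class = verts$class[is_gene],
    score = as.numeric(verts$score[is_gene]),
    degree = as.integer(verts$degree[is_gene]),
    stringsAsFactors = FALSE)
  new("OverlayNetwork", geneNodes = gene_nodes,
      mirnaNodes = sort(verts$name[!is_gene]),
      edges = data.frame(from = edges$from, to = edges$to,
                         type = edges$edge_type, stringsAsFactors = FALSE))
}
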