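# Synthetic fixture generation: scored PPI edge lists, miRNA-target
# tables, DEG/DER lists, id maps and GMT collections with planted
# structure, so the whole pipeline (and its recovery behaviour) is
# testable with no external downloads.

#' Describe a synthetic fixture
#'
#' Defaults describe a desk-scale study: a 500-gene scale-free interactome
#' (preferential attachment, 2 edges per arriving node, so hubs exist for
#' the centrality paths), 20 miRNAs with 30 targets each, STRING-like
#' integer confidence scores in 150-999, and a 20-gene planted disease
#' module.
#'
#' @param n_genes number of genes in the universe.
#' @param n_mirnas number of mature miRNAs (each present as -5p and -3p).
#' @param ppi_model "preferential_attachment" or "erdos_renyi".
#' @param ppi_params list: \code{m} (edges per arrival, PA) or \code{p}
#'   (edge probability, ER).
#' @param target_density expected targets per miRNA.
#' @param planted_module_size size of the planted connected module.
#' @param planted_term_count number of terms in the generated GMT
#'   (including the planted one).
#' @param rng_seed integer seed; all generators are reproducible under it.
#' @return a \code{fixture_spec} list.
#' @export
fixtureSpec <- function(n_genes = 500L, n_mirnas = 20L,
                        ppi_model = c("preferential_attachment",
                                      "erdos_renyi"),
                        ppi_params = list(m = 2L),
                        target_density = 30L,
                        planted_module_size = 20L,
                        planted_term_count = 50L,
                        rng_seed = 1L) {
  ppi_model <- match.arg(ppi_model)
  stopifnot(n_genes >= 3L, n_mirnas >= 1L, target_density >= 1L,
            target_density <= n_genes, planted_module_size >= 2L,
            planted_module_size <= n_genes, planted_term_count >= 1L)
  structure(list(
    n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
    ppi_model = ppi_model, ppi_params = ppi_params,
    target_density = as.integer(target_density),
    planted_module_size = as.integer(planted_module_size),
    planted_term_count = as.integer(planted_term_count),
    rng_seed = as.integer(rng_seed)
  ), class = "fixture_spec")
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(expr)
}

# preferential attachment: seed pair, then each arrival attaches
# min(m, existing) edges to distinct nodes sampled proportional to degree.
# Edge count for m = 2 is exactly 1 + 2 * (n - 2).
.pa_edges <- function(n, m) {
  from <- integer(1 + max(0, n - 2) * m)  # upper bound, trimmed below
  to <- integer(length(from))
  deg <- integer(n)
  from[1] <- 1L; to[1] <- 2L
  deg[1:2] <- 1L
  cnt <- 1L
  for (v in seq_len(n)[-(1:2)]) {
    mm <- min(m, v - 1L)
    avail <- seq_len(v - 1L)
    chosen <- integer(0)
    for (s in seq_len(mm)) {
      w <- deg[avail]
      pick <- avail[sample.int(length(avail), 1L, prob = w)]
      chosen <- c(chosen, pick)
      avail <- setdiff(avail, pick)
    }
    for (u in chosen) {
      cnt <- cnt + 1L
      from[cnt] <- u; to[cnt] <- v
      deg[u] <- deg[u] + 1L; deg[v] <- deg[v] + 1L
    }
  }
  data.frame(from = from[seq_len(cnt)], to = to[seq_len(cnt)])
}

.er_edges <- function(n, p) {
  g <- igraph::sample_gnp(n, p)
  e <- igraph::as_edgelist(g)
  data.frame(from = as.integer(e[, 1]), to = as.integer(e[, 2]))
}

.gene_symbols <- function(n) sprintf("GENE%d", seq_len(n))

#' Generate mature miRNA names for a fixture
#'
#' @param n_mirnas number of miRNA families; each contributes a -5p and a
#'   -3p mature name.
#' @return character vector of canonical names.
#' @export
syntheticMirnaNames <- function(n_mirnas) {
  as.vector(t(outer(sprintf("hsa-miR-%d", seq_len(n_mirnas)),
                    c("-5p", "-3p"), paste0)))
}

#' Generate a scored PPI edge list
#'
#' Draws the graph from the configured model and assigns each edge an
#' integer confidence score uniform in 150-999 (the realistic STRING
#' combined-score range, so a top-fraction filter has something to cut).
#' When \code{path} is given, a STRING-links dialect file is written with
#' taxon-prefixed symbols.
#'
#' @param spec a [fixtureSpec()].
#' @param path optional output path for the STRING-dialect file.
#' @param extra_edges optional data.frame (from, to) of extra edges to
#'   plant (e.g. a dense module); scores for these are drawn from the top
#'   of the range (800-999).
#' @return a [PPINetwork-class] (invisibly carries the file path in its
#'   metadata when written).
#' @export
generatePpi <- function(spec, path = NULL, extra_edges = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$rng_seed, {
    e <- switch(spec$ppi_model,
      preferential_attachment = .pa_edges(spec$n_genes,
                                          spec$ppi_params$m %||% 2L),
      erdos_renyi = .er_edges(spec$n_genes, spec$ppi_params$p %||% 0.01)
    )
    e$score <- sample(150:999, nrow(e), replace = TRUE)
    if (!is.null(extra_edges) && nrow(extra_edges)) {
      extra_edges$score <- sample(800:999, nrow(extra_edges),
                                  replace = TRUE)
      e <- rbind(e, extra_edges)
    }
    syms <- .gene_symbols(spec$n_genes)
    id_map <- makeIdMap(syms, seq_len(spec$n_genes))
    net <- ppiNetwork(e$from, e$to, e$score, id_map = id_map,
                      extra_nodes = seq_len(spec$n_genes))
    if (!is.null(path)) {
      ed <- net@edges
      write.table(
        data.frame(protein1 = paste0("9606.", syms[ed$from]),
                   protein2 = paste0("9606.", syms[ed$to]),
                   combined_score = ed$score),
        path, sep = " ", quote = FALSE, row.names = FALSE)
      net@metadata$path <- path
    }
    net
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a miRNA-target interaction table
#'
#' Each mature miRNA receives \code{target_density} targets sampled
#' without replacement from the gene universe. Names follow
#' hsa-miR-<k>-{5p,3p} so the arm-normalisation paths are exercised; with
#' \code{dialect_noise} an extra row with an unsuffixed miRNA name is
#' appended (it expands to both arms on read).
#'
#' @param spec a [fixtureSpec()].
#' @param path optional output TSV (generic dialect: columns mirna,
#'   target).
#' @param mirnas optional character vector restricting which mature names
#'   to include (default: all from [syntheticMirnaNames()]).
#' @param planted optional data.frame (mirna, entrez) of interactions that
#'   must be present (the planted module wiring).
#' @param dialect_noise append an unsuffixed-name row.
#' @param seed_offset added to the spec seed so several tables from one
#'   spec differ.
#' @return data.frame (mirna, target symbol) of the rows written.
#' @export
generateTargetDb <- function(spec, path = NULL, mirnas = NULL,
                             planted = NULL, dialect_noise = FALSE,
                             seed_offset = 0L) {
  stopifnot(inherits(spec, "fixture_spec"))
  mirnas <- mirnas %||% syntheticMirnaNames(spec$n_mirnas)
  syms <- .gene_symbols(spec$n_genes)
  .with_seed(spec$rng_seed + seed_offset, {
    rows <- do.call(rbind, lapply(mirnas, function(m) {
      data.frame(mirna = m,
                 target = syms[sample.int(spec$n_genes,
                                          spec$target_density)],
                 stringsAsFactors = FALSE)
    }))
    if (!is.null(planted) && nrow(planted)) {
      rows <- rbind(rows,
                    data.frame(mirna = planted$mirna,
                               target = syms[planted$entrez],
                               stringsAsFactors = FALSE))
      rows <- rows[!duplicated(paste(rows$mirna, rows$target)), ,
                   drop = FALSE]
    }
    if (dialect_noise) {
      base <- sub("-(5p|3p)$", "", rows$mirna[1L])
      rows <- rbind(rows, data.frame(mirna = base, target = rows$target[1L],
                                     stringsAsFactors = FALSE))
    }
    if (!is.null(path))
      write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
    rows
  })
}

#' Generate a complete synthetic case bundle
#'
#' Writes every input the pipeline consumes — DEG and DER lists, two
#' miRNA-target tables, a STRING-dialect PPI, a GMT collection and an id
#' map — into \code{dir}. With \code{plant = TRUE} a connected module of
#' \code{planted_module_size} genes is planted: half its genes (alternating
#' along a breadth-first order) are made both DEGs and DER targets (hence
#' seeds), the other half are left out of the DEG list and are recoverable
#' only through propagation; the module is densified with extra internal
#' edges (probability 0.4 per missing pair, high confidence scores) the
#' way disease modules form dense neighbourhoods; and one GMT term equals
#' the module exactly (the discoverable pathway). The planted DER-target
#' interactions are written into both target tables so database
#' intersection preserves them.
#'
#' @param spec a [fixtureSpec()].
#' @param dir output directory (created if needed).
#' @param plant plant the module (FALSE gives a structureless null case;
#'   a small DEG/DER-target overlap is still forced so the seed set is
#'   non-empty).
#' @return list with the file paths (\code{id_map}, \code{mirna_names},
#'   \code{ppi}, \code{targets} (2 paths), \code{degs}, \code{ders},
#'   \code{gmt}, \code{ground_truth}) and the ground truth itself
#'   (\code{planted_genes}, \code{planted_term}, \code{seed_expected}).
#' @export
generateCase <- function(spec, dir, plant = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- spec$n_genes
  syms <- .gene_symbols(n)
  mirna_names <- syntheticMirnaNames(spec$n_mirnas)

  # --- base interactome (module densification planted below) ---
  base_net <- generatePpi(spec)

  .with_seed(spec$rng_seed + 1000L, {
    module <- integer(0); seeds_planned <- integer(0)
    recover_half <- integer(0); extra_edges <- NULL
    if (plant) {
      deg0 <- degreeReport(base_net)
      start <- deg0$entrez[which.max(deg0$degree)]
      g <- igraph::graph_from_data_frame(
        data.frame(from = as.character(base_net@edges$from),
                   to = as.character(base_net@edges$to)),
        directed = FALSE, vertices = as.character(base_net@nodes))
      bfs_order <- as.integer(names(igraph::bfs(
        g, root = match(start, base_net@nodes))$order))
      module <- bfs_order[seq_len(spec$planted_module_size)]
      # alternate seed / recoverable genes along the BFS order so both
      # halves interleave in the module's neighbourhood structure
      seeds_planned <- module[seq_along(module) %% 2L == 1L]
      recover_half <- setdiff(module, seeds_planned)
      pairs <- t(combn(sort(module), 2L))
      have <- paste(base_net@edges$from, base_net@edges$to)
      missing <- !(paste(pairs[, 1], pairs[, 2]) %in% have)
      add <- pairs[missing & runif(nrow(pairs)) < 0.4, , drop = FALSE]
      extra_edges <- data.frame(from = add[, 1], to = add[, 2])
    }

    # final network (re-drawn with the planted edges under the same seed)
    ppi_path <- file.path(dir, "ppi_links.txt")
    net <- generatePpi(spec, path = ppi_path, extra_edges = extra_edges)

    # --- id map (every 10th gene gets an alias, exercising alias paths) ---
    id_map_path <- file.path(dir, "id_map.tsv")
    aliases <- lapply(seq_len(n), function(i)
      if (i %% 10L == 0L) sprintf("G%dALT", i) else character())
    writeIdMap(id_map_path, syms, seq_len(n), aliases)

    mirna_path <- file.path(dir, "mirna_names.txt")
    writeLines(mirna_names, mirna_path)

    # --- DERs and their planted wiring ---
    n_ders <- min(5L, length(mirna_names))
    ders <- sort(sample(mirna_names, n_ders))
    if (plant) {
      wired <- data.frame(
        mirna = ders[(seq_along(seeds_planned) - 1L) %% n_ders + 1L],
        entrez = seeds_planned)
    } else {
      # force a small DEG / DER-target overlap so seeds exist
      forced <- sample.int(n, 10L)
      wired <- data.frame(mirna = ders[(seq_along(forced) - 1L) %%
                                         n_ders + 1L],
                          entrez = forced)
    }
    t1 <- file.path(dir, "targets_db1.tsv")
    t2 <- file.path(dir, "targets_db2.tsv")
    generateTargetDb(spec, t1, planted = wired, seed_offset = 1L)
    generateTargetDb(spec, t2, planted = wired, seed_offset = 2L)

    # --- DEG list: planted seed half plus random background DEGs ---
    n_extra_degs <- max(10L, n %/% 16L)
    deg_pool <- setdiff(seq_len(n), if (plant) recover_half else integer())
    degs <- sort(unique(c(
      if (plant) seeds_planned else wired$entrez,
      sample(deg_pool, n_extra_degs))))
    deg_path <- file.path(dir, "degs.txt")
    writeLines(syms[degs], deg_path)
    der_path <- file.path(dir, "ders.txt")
    writeLines(ders, der_path)

    # --- GMT: one term equals the planted module; the rest are random ---
    gmt_path <- file.path(dir, "sets.gmt")
    n_terms <- spec$planted_term_count
    term_ids <- sprintf("SET%04d", seq_len(n_terms))
    lines <- vapply(seq_len(n_terms), function(t) {
      mem <- if (plant && t == 1L) sort(module) else
        sort(sample.int(n, sample(10:40, 1L)))
      paste(c(term_ids[t], sprintf("synthetic set %d", t), syms[mem]),
            collapse = "\t")
    }, "")
    writeLines(lines, gmt_path)

    truth <- list(
      planted_genes = if (plant) sort(module) else integer(),
      planted_term = if (plant) term_ids[1L] else NA_character_,
      seed_expected = if (plant) sort(seeds_planned) else
        sort(wired$entrez),
      ders = ders
    )
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(truth, gt_path, auto_unbox = TRUE, digits = NA)

    list(id_map = id_map_path, mirna_names = mirna_path, ppi = ppi_path,
         targets = c(t1, t2), degs = deg_path, ders = der_path,
         gmt = gmt_path, ground_truth_path = gt_path,
         ground_truth = truth)
  })
}
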