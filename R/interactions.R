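# miRNA-target interaction tables: dialect-aware readers and set algebra
# over (miRNA, gene) pairs. Databases are combined at pair level, the way
# validated-target collections are intersected in practice.

.pair_key <- function(df) paste(df$mirna, df$entrez, sep = "\r")

.new_target_db <- function(interactions, name, metadata = list()) {
  rownames(interactions) <- NULL
  new("TargetDatabase", interactions = interactions, name = name,
      metadata = metadata)
}

#' Built-in target-table dialects
#'
#' A dialect is just a column map: which header holds the miRNA name and
#' which the target gene (symbol or Entrez). The bundled dialects emulate
#' the export shapes of the common databases; customised maps can be loaded
#' from a YAML file with [readDialectConfig()] because real exports drift
#' across releases.
#'
#' @return named list of dialects, each a list with \code{mirna_col} and
#'   \code{gene_col}.
#' @export
targetDialects <- function() {
  list(
    generic           = list(mirna_col = "mirna",   gene_col = "target"),
    `mirtarbase-like` = list(mirna_col = "miRNA",   gene_col = "Target.Gene"),
    `tarbase-like`    = list(mirna_col = "mirna",   gene_col = "geneName"),
    `targetscan-like` = list(mirna_col = "miRNA",   gene_col = "Gene.Symbol"),
    `mirdb-like`      = list(mirna_col = "mirna",   gene_col = "GeneSymbol")
  )
}

#' Read dialect column maps from a YAML config
#'
#' @param path YAML file: a mapping of dialect name to
#'   \code{mirna_col}/\code{gene_col}.
#' @return named list of dialects merged over the built-ins (the file wins
#'   on name clashes).
#' @export
readDialectConfig <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(targetDialects(), user)
}

#' Read a miRNA-target interaction table
#'
#' Rows are normalised through [normalizeMirna()] (so unsuffixed names
#' expand to all known arms) and [mapSymbols()]; duplicates collapse to one
#' pair. A read report (rows in, interactions out, unmapped tallies) is
#' attached to the result and available via [readReport()].
#'
#' @param path TSV/CSV file with a header.
#' @param dialect dialect name (see [targetDialects()]) or a list with
#'   \code{mirna_col}/\code{gene_col}.
#' @param id_map id map from [readIdMap()].
#' @param known_mirnas character vector of canonical mature names.
#' @param name database label; defaults to the file name.
#' @param sep field separator; \code{"\t"} unless the file ends in .csv.
#' @return a [TargetDatabase-class].
#' @export
readTargetTable <- function(path, dialect = "generic", id_map, known_mirnas,
                            name = basename(path), sep = NULL) {
  if (is.character(dialect)) {
    dl <- targetDialects()[[dialect]]
    if (is.null(dl)) stop("unknown dialect '", dialect, "'")
  } else dl <- dialect
  if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = TRUE)
  if (nrow(tab) == 0L) {
    warning("empty target table: ", path)
    return(.new_target_db(
      data.frame(mirna = character(), entrez = integer(),
                 source = character(), stringsAsFactors = FALSE),
      name, list(rows_in = 0L, interactions_out = 0L,
                 unmapped_mirnas = 0L, unmapped_genes = 0L)))
  }
  for (col in c(dl$mirna_col, dl$gene_col)) {
    if (!make.names(col) %in% names(tab))
      stop("target table ", path, " is missing required column '", col, "'")
  }
  raw_mir <- as.character(tab[[make.names(dl$mirna_col)]])
  raw_gene <- as.character(tab[[make.names(dl$gene_col)]])

  mapped <- mapSymbols(raw_gene, id_map)
  gene_id <- rep(NA_integer_, length(raw_gene))
  gene_id[!(raw_gene %in% mapped$unmapped)] <-
    mapped$mapping[match(raw_gene[!(raw_gene %in% mapped$unmapped)],
                         names(mapped$mapping))]

  norm <- normalizeMirna(raw_mir, known_mirnas)
  if (length(raw_mir) == 1L) norm <- list(norm)
  n_per_row <- lengths(norm)
  out <- data.frame(
    mirna = unlist(norm, use.names = FALSE),
    entrez = rep(gene_id, n_per_row),
    source = name,
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$entrez), , drop = FALSE]
  out <- out[!duplicated(.pair_key(out)), , drop = FALSE]
  .new_target_db(out, name, list(
    rows_in = nrow(tab),
    interactions_out = nrow(out),
    unmapped_mirnas = sum(n_per_row == 0L),
    unmapped_genes = length(unique(mapped$unmapped))
  ))
}

#' Combine target databases by intersection, union or single selection
#'
#' Set algebra is applied to (miRNA, Entrez) pairs — not to genes — so an
#' interaction survives an intersection only when every database reports
#' that exact pairing. Source tags of the survivors are concatenated.
#'
#' @param dbs list of [TargetDatabase-class] objects.
#' @param mode "intersection", "union" or "single".
#' @return a [TargetDatabase-class] named after the inputs and the mode.
#' @export
combineDatabases <- function(dbs, mode = c("intersection", "union", "single")) {
  mode <- match.arg(mode)
  stopifnot(length(dbs) >= 1L, all(vapply(dbs, is, TRUE, "TargetDatabase")))
  if (mode == "single" && length(dbs) != 1L)
    stop("mode 'single' requires exactly one database")
  if (mode == "intersection" && length(dbs) == 1L)
    warning("intersection of a single database is the identity")
  keys <- lapply(dbs, function(d) .pair_key(d@interactions))
  all_ia <- do.call(rbind, lapply(dbs, slot, "interactions"))
  if (is.null(all_ia))
    all_ia <- data.frame(mirna = character(), entrez = integer(),
                         source = character(), stringsAsFactors = FALSE)
  keep_keys <- switch(mode,
    single = keys[[1L]],
    union = unique(unlist(keys)),
    intersection = Reduce(intersect, keys)
  )
  all_key <- .pair_key(all_ia)
  kept <- all_ia[all_key %in% keep_keys, , drop = FALSE]
  if (nrow(kept)) {
    src <- vapply(split(kept$source, .pair_key(kept)), function(s)
      paste(unique(s), collapse = "+"), "")
    kept <- kept[!duplicated(.pair_key(kept)), , drop = FALSE]
    kept$source <- src[.pair_key(kept)]
  }
  .new_target_db(
    kept,
    paste0(paste(vapply(dbs, slot, "", "name"), collapse = "_"), ".", mode))
}

#' Target genes of a list of miRNAs
#'
#' @param db a [TargetDatabase-class].
#' @param ders character vector of canonical mature miRNA names (the
#'   differentially expressed miRNAs).
#' @return integer vector of Entrez IDs (sorted, unique): the union of the
#'   targets of the listed miRNAs. miRNAs absent from the database
#'   contribute nothing and are reported in the \code{"missing"} attribute.
#' @export
targetsOf <- function(db, ders) {
  ia <- db@interactions
  present <- ders %in% ia$mirna
  genes <- sort(unique(ia$entrez[ia$mirna %in% ders]))
  structure(genes, missing = ders[!present])
}

#' Write a target database as canonical 3-column TSV
#'
#' @param db a [TargetDatabase-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTargetDatabase <- function(db, path) {
  ia <- db@interactions[order(db@interactions$mirna,
                              db@interactions$entrez), , drop = FALSE]
  write.table(ia, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
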