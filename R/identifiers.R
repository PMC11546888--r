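# Identifier handling: mature-miRNA name canonicalisation and gene symbol
# to Entrez mapping. Everything downstream works on canonical names and
# integer Entrez IDs; unmappable inputs are reported, never silently lost.

.trimws_lower <- function(x) tolower(trimws(x))

#' Canonicalise a mature miRNA name against a known-name dictionary
#'
#' Mature miRNA names carry an arm suffix ("-5p"/"-3p") in current
#' nomenclature; older lists may omit it or use the legacy "*" (star)
#' suffix for the minor arm. This function resolves a raw name against a
#' dictionary of known canonical names (a miRBase-style mature-name list):
#' an exact case-insensitive hit returns that single canonical name; a name
#' without an arm suffix (including star names, whose "*" is stripped and
#' treated as arm-unspecified) expands to every known arm variant, 5p
#' before 3p. Expansion to both arms is deliberate: it preserves recall and
#' the ambiguity is resolved downstream when targets are intersected with
#' the DEG list.
#'
#' @param raw_name character vector of raw miRNA names.
#' @param known_names character vector of canonical mature names.
#' @return For a single input, a character vector of matching canonical
#'   names (possibly empty — no match is not an error; callers tally it).
#'   For a vector input, a named list of such vectors.
#' @examples
#' known <- c("hsa-miR-21-5p", "hsa-miR-21-3p", "hsa-miR-26b-5p")
#' normalizeMirna("hsa-miR-26b-5p", known)
#' normalizeMirna("hsa-miR-21", known)    # expands to both arms
#' normalizeMirna("hsa-miR-21*", known)   # star name, same expansion
#' @export
normalizeMirna <- function(raw_name, known_names) {
  stopifnot(length(known_names) > 0L)
  if (length(raw_name) != 1L) {
    out <- lapply(raw_name, normalizeMirna, known_names = known_names)
    names(out) <- raw_name
    return(out)
  }
  raw <- trimws(raw_name)
  if (!nzchar(raw)) stop("raw_name is empty after trimming")
  known_lc <- .trimws_lower(known_names)

  # legacy star suffix marks the minor arm without naming it
  raw <- sub("\\*$", "", raw)
  hit <- match(tolower(raw), known_lc)
  if (!is.na(hit)) return(known_names[hit])
  if (grepl("-(5p|3p)$", raw, ignore.case = TRUE)) return(character())
  arms <- match(tolower(paste0(raw, c("-5p", "-3p"))), known_lc)
  known_names[arms[!is.na(arms)]]
}

#' Parse the arm annotation out of a mature miRNA name
#'
#' @param name character vector of miRNA names.
#' @return character vector in \code{c("5p", "3p", "unspecified")}.
#' @export
mirnaArm <- function(name) {
  arm <- rep("unspecified", length(name))
  arm[grepl("-5p$", name, ignore.case = TRUE)] <- "5p"
  arm[grepl("-3p$", name, ignore.case = TRUE)] <- "3p"
  arm
}

#' Read a one-name-per-line mature miRNA list
#'
#' @param path text file, one canonical mature name per line; blank lines
#'   and lines starting with "#" are skipped.
#' @return character vector of names.
#' @export
readMirnaList <- function(path) {
  ln <- trimws(readLines(path, warn = FALSE))
  ln[nzchar(ln) & !startsWith(ln, "#")]
}

#' Read a symbol/alias to Entrez mapping table
#'
#' Expects a TSV with header columns \code{symbol}, \code{aliases}
#' (pipe-separated, may be empty) and \code{entrez}. Within one table a
#' symbol or alias may map to only one Entrez ID; conflicting entries are a
#' hard error because silent tie-breaking would corrupt every downstream
#' join.
#'
#' @param path TSV file path.
#' @return An id-map object: list with \code{lookup} (named integer;
#'   names are lower-cased symbols and aliases), \code{primary}
#'   (data.frame symbol/entrez for reverse display lookup).
#' @export
readIdMap <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  need <- c("symbol", "aliases", "entrez")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("id map is missing column(s): ", paste(miss, collapse = ", "))
  entrez <- as.integer(tab$entrez)
  if (anyNA(entrez) || any(entrez < 1L))
    stop("entrez column must hold positive integers")
  keys <- character()
  vals <- integer()
  for (i in seq_len(nrow(tab))) {
    al <- strsplit(tab$aliases[i], "|", fixed = TRUE)[[1]]
    kk <- tolower(c(tab$symbol[i], al[nzchar(al)]))
    keys <- c(keys, kk)
    vals <- c(vals, rep(entrez[i], length(kk)))
  }
  dup <- duplicated(keys)
  if (any(dup)) {
    for (k in unique(keys[dup])) {
      if (length(unique(vals[keys == k])) > 1L)
        stop("conflicting id map entries for '", k, "'")
    }
    vals <- vals[!dup]
    keys <- keys[!dup]
  }
  structure(
    list(lookup = setNames(vals, keys),
         primary = data.frame(symbol = tab$symbol, entrez = entrez,
                              stringsAsFactors = FALSE)),
    class = "id_map"
  )
}

#' Build an id map directly from vectors (used by the fixture generator)
#'
#' @param symbol character vector of primary symbols.
#' @param entrez integer vector of Entrez IDs.
#' @param aliases optional list of character alias vectors per symbol.
#' @return An id-map object as returned by [readIdMap()].
#' @export
makeIdMap <- function(symbol, entrez, aliases = NULL) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeIdMap(tmp, symbol, entrez, aliases)
  readIdMap(tmp)
}

#' Write an id map TSV in the dialect [readIdMap()] consumes
#'
#' @inheritParams makeIdMap
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeIdMap <- function(path, symbol, entrez, aliases = NULL) {
  al <- if (is.null(aliases)) rep("", length(symbol)) else
    vapply(aliases, paste, "", collapse = "|")
  write.table(
    data.frame(symbol = symbol, aliases = al, entrez = as.integer(entrez),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map gene symbols to Entrez IDs
#'
#' Lookup is case-insensitive and honours aliases (an alias resolves to its
#' primary record's Entrez ID). Every input symbol lands in exactly one of
#' the mapping or the unmapped vector, in input order.
#'
#' @param symbols character vector of gene symbols (or strings of digits,
#'   which are accepted verbatim as Entrez IDs).
#' @param id_map an id map from [readIdMap()] / [makeIdMap()].
#' @return list with \code{mapping} (named integer vector, names = input
#'   symbols that mapped) and \code{unmapped} (character vector).
#' @export
mapSymbols <- function(symbols, id_map) {
  stopifnot(inherits(id_map, "id_map"), length(id_map$lookup) > 0L)
  symbols <- as.character(symbols)
  hits <- id_map$lookup[tolower(trimws(symbols))]
  numeric_in <- grepl("^[0-9]+$", trimws(symbols))
  hits[is.na(hits) & numeric_in] <-
    as.integer(trimws(symbols[is.na(hits) & numeric_in]))
  ok <- !is.na(hits)
  list(mapping = setNames(as.integer(hits[ok]), symbols[ok]),
       unmapped = symbols[!ok])
}

#' Display symbol for an Entrez ID
#'
#' @param entrez integer vector.
#' @param id_map an id map.
#' @return character vector of primary symbols (NA where unknown).
#' @export
entrezToSymbol <- function(entrez, id_map) {
  id_map$primary$symbol[match(entrez, id_map$primary$entrez)]
}
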