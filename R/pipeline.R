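# Full-pipeline orchestration from a config: preprocessing, network
# boosting by RWR, enrichment with a permutation null, and a complete
# results directory. Identical config + rng_seed gives byte-identical
# tabular outputs.

#' Default pipeline configuration
#'
#' @return named list of defaults; see [runPipeline()] for the fields.
#' @export
defaultConfig <- function() {
  list(
    der_list = NULL, deg_list = NULL,
    target_dbs = list(),          # list of list(path=, dialect=)
    ppi = NULL, gmt = NULL, id_map = NULL, mirna_names = NULL,
    out_dir = NULL,
    db_mode = "intersection",
    ppi_dialect = "string-links",
    ppi_top_fraction = 0.01,
    weighting = "binary",
    restart_p = 0.7,
    rwr_tol = 1e-10,
    rwr_max_iter = 1000L,
    boost_levels = c(0.01, 0.10, 0.20),
    enrichment_threshold = 0.01,
    use_adjusted = FALSE,
    universe = "gmt",             # or "ppi"
    n_perm = 10000L,
    overlay_level = 0.10,
    hub_k = 3L,
    rng_seed = 1L
  )
}

#' Read a pipeline config from YAML
#'
#' Unknown keys are an error; missing keys take the defaults of
#' [defaultConfig()].
#'
#' @param path YAML file.
#' @return config list.
#' @export
readPipelineConfig <- function(path) {
  user <- yaml::read_yaml(path)
  def <- defaultConfig()
  unknown <- setdiff(names(user), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  .merge_config(def, user)
}

# shallow merge: user values replace defaults wholesale (modifyList would
# recurse into and drop unnamed sub-lists such as target_dbs)
.merge_config <- function(def, user) {
  for (n in names(user)) def[[n]] <- user[[n]]
  def
}

#' Validate a pipeline config
#'
#' @param config config list.
#' @return data.frame of findings with columns \code{level}
#'   ("error"/"warning") and \code{message}; errors abort
#'   [runPipeline()] before any computation.
#' @export
validateConfig <- function(config) {
  f <- list()
  addf <- function(level, msg) f[[length(f) + 1L]] <<-
    data.frame(level = level, message = msg, stringsAsFactors = FALSE)
  need_path <- function(key, required = TRUE) {
    p <- config[[key]]
    if (is.null(p)) {
      if (required) addf("error", paste0("missing required path: ", key))
    } else if (!file.exists(p))
      addf("error", paste0(key, " does not exist: ", p))
  }
  need_path("ppi"); need_path("gmt"); need_path("id_map")
  need_path("mirna_names")
  if (is.null(config$der_list) && is.null(config$deg_list))
    addf("error", "at least one of der_list / deg_list is required")
  for (key in c("der_list", "deg_list")) need_path(key, required = FALSE)
  if (!is.null(config$der_list) && length(config$target_dbs) == 0L)
    addf("error", "der_list given but no target_dbs configured")
  for (db in config$target_dbs) {
    if (is.null(db$path) || !file.exists(db$path))
      addf("error", paste0("target db path missing or absent: ",
                           db$path %||% "<null>"))
  }
  if (is.null(config$out_dir)) addf("error", "out_dir is required")
  if (is.null(config$restart_p)) {
    addf("warning", "restart_p unset; using default 0.7")
  } else if (config$restart_p <= 0 || config$restart_p > 1)
    addf("error", "restart_p must be in (0, 1]")
  lv <- config$boost_levels
  if (any(lv < 0 | lv > 1))
    addf("error", paste0("boost level outside [0, 1]: ",
                         paste(lv[lv < 0 | lv > 1], collapse = ", ")))
  if (!is.null(config$ppi_top_fraction) &&
      (config$ppi_top_fraction <= 0 || config$ppi_top_fraction > 1))
    addf("error", "ppi_top_fraction must be in (0, 1]")
  if (!config$db_mode %in% c("intersection", "union", "single"))
    addf("error", paste0("unknown db_mode: ", config$db_mode))
  if (!config$universe %in% c("gmt", "ppi"))
    addf("error", paste0("unknown universe: ", config$universe))
  if (length(f)) do.call(rbind, f) else
    data.frame(level = character(), message = character(),
               stringsAsFactors = FALSE)
}

.level_label <- function(level) sprintf("%gpct", level * 100)

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}

#' Run the full boosting pipeline
#'
#' Executes the three analysis stages — (1) preprocessing: miRNA-name
#' canonicalisation, symbol-to-Entrez mapping, target-database combination
#' and seed construction; (2) gene boosting: RWR propagation over the
#' confidence-filtered PPI network and boosted-set extraction per boosting
#' level; (3) pathway analysis: hypergeometric enrichment per level, the
#' size-matched permutation null for the enriched-pathway count, hub and
#' centrality reports and the miRNA-gene overlay export — and writes a
#' complete results directory: seeds.tsv, scores.tsv,
#' boosted_<level>.tsv, enrichment_<level>.tsv, permutation_<level>.tsv,
#' dotplot.tsv, network.graphml, network.json, hubs.tsv, manifest.json
#' and run.log.
#'
#' When only one of the DER/DEG lists is supplied the seed set degrades
#' gracefully to the available side (logged); with both, seeds are the
#' intersection of DEGs with DER targets, restricted to the network.
#'
#' @param config config list (see [defaultConfig()] /
#'   [readPipelineConfig()]).
#' @return invisibly, a list with the key objects (seeds, scores, boosted
#'   sets, enrichment records, permutation nulls, manifest).
#' @export
runPipeline <- function(config) {
  config <- .merge_config(defaultConfig(), config)
  t0 <- Sys.time()
  findings <- validateConfig(config)
  if (any(findings$level == "error"))
    stop("config invalid: ",
         paste(findings$message[findings$level == "error"],
               collapse = "; "))
  log_lines <- character()
  logmsg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message("[rwrboost] ", line)
  }
  for (w in findings$message[findings$level == "warning"]) logmsg("WARNING: ", w)

  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$rng_seed))

  ## stage 1: preprocessing ------------------------------------------------
  id_map <- readIdMap(config$id_map)
  known <- readMirnaList(config$mirna_names)
  logmsg("id map: ", nrow(id_map$primary), " records; ",
         length(known), " known miRNA names")

  ders <- character(); der_targets <- integer(); db <- NULL
  if (!is.null(config$der_list)) {
    raw_ders <- readLines(config$der_list, warn = FALSE)
    raw_ders <- trimws(raw_ders[nzchar(trimws(raw_ders))])
    norm <- normalizeMirna(raw_ders, known)
    if (length(raw_ders) == 1L) norm <- list(norm)
    unmapped_ders <- raw_ders[lengths(norm) == 0L]
    ders <- sort(unique(unlist(norm, use.names = FALSE)))
    logmsg("DERs: ", length(raw_ders), " raw -> ", length(ders),
           " canonical (", length(unmapped_ders), " unmapped)")
    dbs <- lapply(config$target_dbs, function(d)
      readTargetTable(d$path, d$dialect %||% "generic", id_map, known))
    db <- combineDatabases(dbs,
      if (config$db_mode == "single" && length(dbs) > 1L) "union"
      else config$db_mode)
    logmsg("target databases: ", length(dbs), " combined by ",
           config$db_mode, " -> ", nrow(db@interactions), " interactions")
    der_targets <- targetsOf(db, ders)
    miss <- attr(der_targets, "missing")
    logmsg("DER targets: ", length(der_targets), " genes (",
           length(miss), " DER(s) absent from the database)")
  }
  degs <- integer()
  if (!is.null(config$deg_list)) {
    raw_degs <- readLines(config$deg_list, warn = FALSE)
    raw_degs <- trimws(raw_degs[nzchar(trimws(raw_degs))])
    m <- mapSymbols(raw_degs, id_map)
    degs <- sort(unique(as.integer(m$mapping)))
    logmsg("DEGs: ", length(raw_degs), " raw -> ", length(degs),
           " Entrez (", length(m$unmapped), " unmapped)")
  }

  net_full <- readEdgeList(config$ppi, config$ppi_dialect, id_map)
  logmsg("PPI: ", length(net_full@nodes), " nodes, ",
         nrow(net_full@edges), " edges read")
  net <- filterTopFraction(net_full, config$ppi_top_fraction)
  logmsg("top ", config$ppi_top_fraction * 100, "% filter: ",
         nrow(net@edges), " edges, ", length(net@nodes), " nodes kept")

  seed_mode <- "intersection"
  if (is.null(config$deg_list)) {
    seed_mode <- "union"
    logmsg("no DEG list: seeds degrade to DER targets on the network")
  } else if (is.null(config$der_list)) {
    seed_mode <- "union"
    logmsg("no DER list: seeds degrade to DEGs on the network")
  }
  seeds <- constructSeedSet(degs, der_targets, net, seed_mode)
  logmsg("seed set: ", length(seeds@genes), " genes (",
         length(seeds@dropped), " dropped, absent from network)")
  .write_tsv(data.frame(
    entrez = seeds@genes,
    symbol = net@symbols[match(seeds@genes, net@nodes)],
    is_deg = seeds@provenance$is_deg,
    is_der_target = seeds@provenance$is_der_target),
    file.path(out_dir, "seeds.tsv"))

  ## stage 2: boosting -----------------------------------------------------
  A <- buildTransitionMatrix(net, config$weighting)
  u0 <- makeRestartVector(seeds, net)
  scores <- rwr(A, u0, config$restart_p, config$rwr_tol,
                as.integer(config$rwr_max_iter))
  logmsg("RWR: p = ", config$restart_p, ", ", scores@iterations,
         " iterations, converged = ", scores@converged)
  .write_tsv(scoresTable(scores, seeds, net),
             file.path(out_dir, "scores.tsv"))

  boosted <- list(); enr <- list(); perms <- list()
  coll <- readGmt(config$gmt, id_map,
                  universe = if (config$universe == "ppi") net@nodes)
  logmsg("gene sets: ", length(coll@terms), " terms, universe ",
         length(coll@universe), " genes (background: ", config$universe,
         ")")
  for (li in seq_along(config$boost_levels)) {
    level <- config$boost_levels[[li]]
    lbl <- .level_label(level)
    b <- selectBoosted(scores, seeds, level, net)
    boosted[[lbl]] <- b
    cc <- classifyConnectivity(b, seeds, net)
    logmsg("boost ", lbl, ": ", length(b@genes), " genes (",
           cc[["n_direct"]], " direct, ", cc[["n_indirect"]], " indirect)")
    .write_tsv(data.frame(
      entrez = b@genes,
      symbol = net@symbols[match(b@genes, net@nodes)],
      score = as.numeric(b@scores),
      is_seed = b@genes %in% seeds@genes,
      classification = ifelse(b@genes %in% seeds@genes, "seed",
                              b@classification[as.character(b@genes)])),
      file.path(out_dir, paste0("boosted_", lbl, ".tsv")))

    ## stage 3: pathway analysis -------------------------------------------
    query <- intersect(b@genes, coll@universe)
    r <- enrich(query, coll)
    enr[[lbl]] <- r
    .write_tsv(r, file.path(out_dir, paste0("enrichment_", lbl, ".tsv")))
    observed <- countEnriched(r, config$enrichment_threshold,
                              config$use_adjusted)
    pn <- permutationNull(coll, set_size = length(query),
                          n_perm = as.integer(config$n_perm),
                          threshold = config$enrichment_threshold,
                          observed = observed,
                          rng_seed = as.integer(config$rng_seed) + li,
                          use_adjusted = config$use_adjusted)
    perms[[lbl]] <- pn
    logmsg("enrichment ", lbl, ": ", observed, " terms at p < ",
           config$enrichment_threshold, "; permutation p = ",
           format(pn@empiricalP, digits = 4))
    .write_tsv(data.frame(
      level = lbl, observed = pn@observed,
      null_mean = mean(pn@nullCounts), null_sd = sd(pn@nullCounts),
      n_perm = pn@nPerm, empirical_p = pn@empiricalP),
      file.path(out_dir, paste0("permutation_", lbl, ".tsv")))
  }
  .write_tsv(dotplotTable(lapply(enr, function(r)
    r[r$p_value < config$enrichment_threshold, , drop = FALSE])),
    file.path(out_dir, "dotplot.tsv"))

  ## network metrics and overlay ------------------------------------------
  ov_level <- config$boost_levels[
    which.min(abs(config$boost_levels - config$overlay_level))]
  b_ov <- boosted[[.level_label(ov_level)]]
  sub <- inducedSubnetwork(net, b_ov@genes)
  hubs_df <- data.frame(entrez = integer(), symbol = character(),
                        degree = integer(), eigenvector = numeric())
  if (nrow(sub@edges)) {
    cr <- suppressWarnings(eigenvectorCentrality(sub))
    hubs <- findHubs(cr, "degree_top_k", config$hub_k)
    tb <- cr@table
    hubs_df <- data.frame(
      entrez = hubs, symbol = net@symbols[match(hubs, net@nodes)],
      degree = tb$degree[match(hubs, tb$entrez)],
      eigenvector = tb$eigenvector[match(hubs, tb$entrez)])
    logmsg("hubs (top ", config$hub_k, " by degree at boost ",
           .level_label(ov_level), "): ",
           paste(hubs_df$symbol, collapse = ", "),
           "; mean degree ", round(cr@meanDegree, 2),
           ", mean centrality ", signif(cr@meanCentrality, 4))
  }
  .write_tsv(hubs_df, file.path(out_dir, "hubs.tsv"))
  overlay <- buildOverlay(b_ov, seeds, db %||% combineDatabases(list(
    new("TargetDatabase")), "single"), ders, net, degs)
  exportOverlay(overlay, file.path(out_dir, "network.graphml"), "graphml")
  exportOverlay(overlay, file.path(out_dir, "network.json"), "json")

  ## manifest and log ------------------------------------------------------
  manifest <- list(
    package_version = as.character(packageVersion("rwrboost")),
    config = config[!vapply(config, is.null, TRUE)],
    counts = list(
      seeds = length(seeds@genes),
      network_nodes = length(net@nodes),
      network_edges = nrow(net@edges),
      boosted = lapply(boosted, function(b) length(b@genes)),
      enriched = lapply(enr, function(r)
        countEnriched(r, config$enrichment_threshold,
                      config$use_adjusted))
    ),
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(seeds = seeds, scores = scores, boosted = boosted,
                 enrichment = enr, permutations = perms,
                 network = net, overlay = overlay, manifest = manifest))
}
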