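write_target_tsv <- function(rows, mirna_col = "mirna",
                             gene_col = "target") {
  tmp <- tempfile(fileext = ".tsv")
  df <- data.frame(rows$mirna, rows$gene, stringsAsFactors = FALSE)
  names(df) <- c(mirna_col, gene_col)
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  tmp
}

known2 <- c("hsa-miR-1-5p", "hsa-miR-1-3p", "hsa-miR-2-5p")

test_that("duplicate rows collapse to one interaction", {
  im <- tiny_id_map(5)
  p <- write_target_tsv(list(
    mirna = c("hsa-miR-1-5p", "hsa-miR-1-5p", "hsa-miR-2-5p"),
    gene = c("GENE1", "GENE1", "GENE2")))
  db <- readTargetTable(p, "generic", im, known2)
  expect_identical(nrow(interactions(db)), 2L)
  expect_identical(readReport(db)$rows_in, 3L)
})

test_that("unmappable symbols yield no interaction but a tally", {
  im <- tiny_id_map(5)
  p <- write_target_tsv(list(mirna = "hsa-miR-1-5p", gene = "NOPE"))
  db <- readTargetTable(p, "generic", im, known2)
  expect_identical(nrow(interactions(db)), 0L)
  expect_identical(readReport(db)$unmapped_genes, 1L)
})

test_that("unsuffixed miRNAs expand into one interaction per known arm", {
  im <- tiny_id_map(5)
  p <- write_target_tsv(list(mirna = "hsa-miR-1", gene = "GENE3"))
  db <- readTargetTable(p, "generic", im, known2)
  expect_setequal(interactions(db)$mirna,
                  c("hsa-miR-1-5p", "hsa-miR-1-3p"))
  expect_identical(unique(interactions(db)$entrez), 3L)
})

test_that("dialect column maps are honoured and missing columns fatal", {
  im <- tiny_id_map(5)
  p <- write_target_tsv(list(mirna = "hsa-miR-1-5p", gene = "GENE1"),
                        mirna_col = "miRNA", gene_col = "Target Gene")
  db <- readTargetTable(p, "mirtarbase-like", im, known2)
  expect_identical(nrow(interactions(db)), 1L)
  expect_error(readTargetTable(p, "generic", im, known2),
               "missing required column")
  expect_error(readTargetTable(p, "no-such-dialect", im, known2),
               "unknown dialect")
})

test_that("dialect configs can be loaded from YAML", {
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("my-dialect:", "  mirna_col: mir", "  gene_col: sym"), tmp)
  dl <- readDialectConfig(tmp)
  expect_identical(dl$`my-dialect`$gene_col, "sym")
  expect_true("generic" %in% names(dl))  # built-ins survive the merge
  unlink(tmp)
})

make_db <- function(pairs, name = "db") {
  ia <- data.frame(mirna = as.character(pairs$m),
                   entrez = as.integer(pairs$g),
                   source = rep(name, length(pairs$g)),
                   stringsAsFactors = FALSE)
  ia <- ia[!duplicated(paste(ia$mirna, ia$entrez)), , drop = FALSE]
  new("TargetDatabase", interactions = ia, name = name)
}

test_that("database combination follows pair-level set algebra", {
  db1 <- make_db(list(m = c("m1", "m1"), g = c(1L, 2L)), "a")
  db2 <- make_db(list(m = "m1", g = 1L), "b")
  inter <- combineDatabases(list(db1, db2), "intersection")
  expect_identical(interactions(inter)$entrez, 1L)
  expect_match(inter@name, "intersection")
  uni <- combineDatabases(list(db1, db2), "union")
  expect_setequal(interactions(uni)$entrez, c(1L, 2L))
  # empty-set absorption
  db0 <- make_db(list(m = character(), g = integer()), "e")
  expect_identical(
    nrow(interactions(combineDatabases(list(db0, db1), "intersection"))), 0L)
  # single mode arity
  expect_error(combineDatabases(list(db1, db2), "single"), "exactly one")
  expect_warning(combineDatabases(list(db1), "intersection"), "identity")
})

test_that("combination is commutative and respects size bounds", {
  set.seed(42)
  dbs <- lapply(1:3, function(i)
    make_db(list(m = sample(c("m1", "m2", "m3"), 12, TRUE),
                 g = sample(1:6, 12, TRUE)), paste0("d", i)))
  sizes <- vapply(dbs, function(d) nrow(interactions(d)), 0L)
  key <- function(d) sort(paste(interactions(d)$mirna, interactions(d)$entrez))
  for (mode in c("intersection", "union")) {
    ab <- combineDatabases(dbs, mode)
    ba <- combineDatabases(rev(dbs), mode)
    expect_identical(key(ab), key(ba))
    if (mode == "intersection")
      expect_lte(nrow(interactions(ab)), min(sizes))
    else
      expect_gte(nrow(interactions(ab)), max(sizes))
  }
})

test_that("targetsOf unions targets and reports absent miRNAs", {
  db <- make_db(list(m = c("m1", "m1", "m2"), g = c(1L, 2L, 2L)))
  expect_identical(as.integer(targetsOf(db, "m1")), c(1L, 2L))
  expect_identical(as.integer(targetsOf(db, c("m1", "m2"))), c(1L, 2L))
  t3 <- targetsOf(db, "m3")
  expect_length(t3, 0L)
  expect_identical(attr(t3, "missing"), "m3")
  # distributivity over query union
  a <- as.integer(targetsOf(db, "m1")); b <- as.integer(targetsOf(db, "m2"))
  expect_setequal(as.integer(targetsOf(db, c("m1", "m2"))), union(a, b))
})

test_that("empty target file warns and round-trips through the writer", {
  im <- tiny_id_map(5)
  tmp <- tempfile(fileext = ".tsv")
  writeLines("mirna\ttarget", tmp)
  expect_warning(db0 <- readTargetTable(tmp, "generic", im, known2),
                 "empty")
  expect_identical(nrow(interactions(db0)), 0L)
  db <- make_db(list(m = c("hsa-miR-1-5p", "hsa-miR-2-5p"), g = c(2L, 1L)))
  out <- tempfile(fileext = ".tsv")
  writeTargetDatabase(db, out)
  back <- read.delim(out, stringsAsFactors = FALSE)
  expect_identical(nrow(back), 2L)
  expect_identical(names(back), c("mirna", "entrez", "source"))
  unlink(c(tmp, out))
})
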