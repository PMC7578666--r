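test_that("read_interactions parses well-formed lines and normalizes fields", {
  tf <- small_interactions_tsv(tempfile(), c(
    "bisphenol A\tEsr1\t+\tHomo\t12345\tindustrial\t\t\t",
    "lead\tTP53\t−\tMus\t99\tpollutant\tindustrial\t\tsmelting",
    "caffeine\tADORA2A\t1\tRattus\t777\tfood components\t\t\t"
  ))
  rec <- read_interactions(tf)
  expect_equal(nrow(rec), 3)
  expect_equal(rec$gene, c("ESR1", "TP53", "ADORA2A"))
  expect_equal(rec$direction, c("+", "-", "1"))
  expect_equal(rec$use1, c("industrial", "pollutant", "food components"))
  expect_true(is.na(rec$use2[1]))
  expect_equal(rec$use2[2], "industrial")
  expect_equal(rec$pmid, c(12345L, 99L, 777L))
})

test_that("read_interactions accepts comma dialect and shuffled, case-varied headers", {
  tf <- tempfile()
  writeLines(c(
    "PMID,Gene Term,chemical term,ACTION DIRECTION,taxonomy,use1",
    "5,esr1,bpa,+,Homo,cosmetics"
  ), tf)
  rec <- read_interactions(tf, dialect = "comma")
  expect_equal(rec$gene, "ESR1")
  expect_equal(rec$chemical, "bpa")
  expect_true(is.na(rec$use2) && is.na(rec$use3))
})

test_that("read_interactions raises named schema and record errors", {
  tf <- tempfile()
  writeLines(c("chemical term\tgene term\taxonomy", "a\tb\tHomo"), tf)
  expect_error(read_interactions(tf), "action direction",
               class = "chemsens_schema_error")

  tf2 <- small_interactions_tsv(tempfile(),
    "x\tG1\t+\tHomo\tnot_a_number\tresearch\t\t\t")
  expect_error(read_interactions(tf2), "line",
               class = "chemsens_record_error")

  tf3 <- small_interactions_tsv(tempfile(),
    "x\tG1\t+\tDanio\t10\tresearch\t\t\t")
  expect_error(read_interactions(tf3), "Danio",
               class = "chemsens_record_error")
})

test_that("write then read is the identity on normalized records", {
  rec <- dplyr::bind_rows(
    make_records("ESR1", chemical = "bpa", direction = "+", pmid = 1L),
    make_records("TP53", chemical = "lead", direction = "-", pmid = 2L,
                 use1 = "pollutant", use2 = "industrial",
                 use_description = "heavy metal"),
    make_records("AHR", chemical = "tcdd", direction = "1", pmid = 3L,
                 taxon = "Rattus")
  )
  tf <- tempfile()
  write_interactions(rec, tf)
  back <- read_interactions(tf)
  expect_equal(as.data.frame(back), as.data.frame(rec))
})

test_that("validate_annotations flags unknown terms, duplicates, overflow and empties", {
  ok <- make_records("A", use1 = "pharmaceutical", use2 = "research")
  expect_equal(nrow(validate_annotations(ok)), 0)

  # case/whitespace-insensitive matching
  fuzzy <- make_records("A", use1 = "  Food   Components ")
  expect_equal(nrow(validate_annotations(fuzzy)), 0)

  bad <- dplyr::bind_rows(
    make_records("B", use1 = "plastics"),
    make_records("C", use1 = NA_character_),
    make_records("D", use1 = "research", use2 = "research")
  )
  v <- validate_annotations(bad)
  expect_equal(v$violation,
               c("unknown_term", "no_terms", "duplicate_terms"))

  over <- make_records("E", use1 = "research", use2 = "industrial",
                       use3 = "pollutant")
  over$use4 <- "cosmetics"
  expect_equal(validate_annotations(over)$violation, "too_many_terms")
})

test_that("filter_taxa keeps the order-preserving subset", {
  rec <- make_records(sprintf("G%d", 1:10),
                      taxon = rep(c("Homo", "Mus", "Rattus", "Mus",
                                    "Homo"), 2),
                      pmid = 1:10)
  one <- filter_taxa(rec, "Homo")
  expect_equal(one$gene, rec$gene[rec$taxon == "Homo"])
  expect_identical(as.data.frame(filter_taxa(rec)), as.data.frame(rec))
  kept <- filter_taxa(rec, c("Mus", "Rattus"))
  expect_equal(kept$pmid, rec$pmid[rec$taxon %in% c("Mus", "Rattus")])
  expect_error(filter_taxa(rec, character()), "nonempty")
  expect_error(filter_taxa(rec, "Danio"), "unknown")
})

test_that("filter_shared_genes drops genes missing from any genome and reports them", {
  set.seed(42)
  genes <- sprintf("G%03d", 1:100)
  presence <- tibble::tibble(gene = genes, homo = TRUE, mus = TRUE,
                             rattus = TRUE)
  dropped <- sample(genes, 20)
  cols <- sample(c("homo", "mus", "rattus"), 20, replace = TRUE)
  for (j in seq_along(dropped)) {
    presence[[cols[j]]][match(dropped[j], presence$gene)] <- FALSE
  }
  rec <- make_records(rep(genes, 2), pmid = 1:200)
  out <- filter_shared_genes(rec, presence)
  expect_setequal(out$removed_genes, dropped)
  expect_equal(length(out$removed_genes), 20)
  # conservation: kept + records of removed genes = input
  expect_equal(nrow(out$kept) + sum(rec$gene %in% out$removed_genes),
               nrow(rec))
  # order preserved and idempotent
  expect_equal(out$kept$gene, rec$gene[!(rec$gene %in% dropped)])
  again <- filter_shared_genes(out$kept, presence)
  expect_identical(as.data.frame(again$kept), as.data.frame(out$kept))

  expect_error(
    filter_shared_genes(make_records("NOT_THERE"), presence),
    "NOT_THERE", class = "chemsens_presence_error")
})

test_that("filter_taxa and filter_shared_genes commute", {
  set.seed(7)
  genes <- sprintf("G%02d", 1:30)
  presence <- tibble::tibble(gene = genes, homo = TRUE,
                             mus = rep(c(TRUE, FALSE), 15),
                             rattus = TRUE)
  rec <- make_records(sample(genes, 60, replace = TRUE),
                      taxon = sample(allowed_taxa(), 60, replace = TRUE),
                      pmid = 1:60)
  a <- filter_shared_genes(filter_taxa(rec, c("Homo", "Mus")),
                           presence)$kept
  b <- filter_taxa(filter_shared_genes(rec, presence)$kept,
                   c("Homo", "Mus"))
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("deduplicate collapses by (gene, chemical, pmid, taxon) and resolves conflicts to '1'", {
  twice <- dplyr::bind_rows(make_records("A"), make_records("A"))
  dd <- deduplicate(twice)
  expect_equal(nrow(dd$records), 1)
  expect_equal(dd$report$n_collapsed, 1)
  expect_equal(dd$report$n_direction_conflicts, 0)
  expect_equal(dd$report$n_input, dd$report$n_unique + dd$report$n_collapsed)

  conflict <- dplyr::bind_rows(make_records("A", direction = "+"),
                               make_records("A", direction = "-"))
  expect_warning(dd2 <- deduplicate(conflict), "conflicting")
  expect_equal(dd2$records$direction, "1")
  expect_equal(dd2$report$n_direction_conflicts, 1)

  # different studies of the same chemical-gene pair are distinct interactions
  two_pmids <- dplyr::bind_rows(make_records("A", pmid = 1L),
                                make_records("A", pmid = 2L))
  expect_equal(nrow(deduplicate(two_pmids)$records), 2)

  # idempotent
  dd3 <- deduplicate(dd$records)
  expect_identical(as.data.frame(dd3$records), as.data.frame(dd$records))
  expect_equal(dd3$report$n_collapsed, 0)
  expect_true(isTRUE(attr(dd3$records, "deduplicated")))
})

test_that("subset_by_use matches any of the three use slots and tallies agree with brute force", {
  rec <- dplyr::bind_rows(
    make_records("A", use1 = "pharmaceutical", use2 = "research"),
    make_records("B", use1 = "industrial"),
    make_records("C", use1 = "pollutant", use2 = "industrial",
                 use3 = "research"),
    make_records("D", use1 = "warfare")
  )
  expect_equal(subset_by_use(rec, "research")$gene, c("A", "C"))
  expect_equal(nrow(subset_by_use(rec, "cosmetics")), 0)
  expect_error(subset_by_use(rec, "plastics"), "unknown")

  for (term in use_vocabulary()) {
    brute <- sum(apply(cbind(rec$use1, rec$use2, rec$use3), 1,
                       function(u) term %in% u[!is.na(u)]))
    expect_equal(nrow(subset_by_use(rec, term)), brute)
  }
})

test_that("GMT reader/writer round-trip and reject malformed input", {
  tf <- tempfile(fileext = ".gmt")
  writeLines("SET1\tdesc\tA\tB", tf)
  coll <- read_gmt(tf, "toy")
  expect_equal(coll$sets$SET1, c("A", "B"))

  # trailing empty member is ignored
  writeLines("SET1\tdesc\tA\tB\t", tf)
  expect_equal(length(read_gmt(tf)$sets$SET1), 2)

  writeLines(c("S\td\tA", "S\td\tB"), tf)
  expect_error(read_gmt(tf), "duplicate", class = "chemsens_gmt_error")
  writeLines("ONLY_NAME\tdesc", tf)
  expect_error(read_gmt(tf), "line 1", class = "chemsens_gmt_error")

  set.seed(11)
  sets <- lapply(1:50, function(i) {
    sample(sprintf("G%04d", 1:500), sample(5:40, 1))
  })
  names(sets) <- sprintf("SET_%02d", 1:50)
  coll <- gene_set_collection("rand", sets)
  tf2 <- tempfile(fileext = ".gmt")
  write_gmt(coll, tf2)
  back <- read_gmt(tf2, "rand")
  expect_equal(names(back$sets), names(coll$sets))
  for (nm in names(sets)) expect_setequal(back$sets[[nm]], coll$sets[[nm]])
})

test_that("gene-presence reader normalizes keys, accepts truthy encodings, merges duplicates", {
  tf <- tempfile()
  writeLines(c("gene,homo,mus,rattus",
               "ESR1,1,1,1",
               "Xist,TRUE,yes,0",
               "Xist,true,Yes,no"), tf)
  tab <- read_gene_presence(tf, dialect = "comma")
  expect_equal(nrow(tab), 2)
  expect_equal(tab$gene, c("ESR1", "XIST"))
  expect_equal(unlist(tab[tab$gene == "XIST", -1], use.names = FALSE),
               c(TRUE, TRUE, FALSE))

  writeLines(c("gene,homo,mus,rattus", "A,1,1,1", "A,1,0,1"), tf)
  expect_error(read_gene_presence(tf, dialect = "comma"),
               "conflicting", class = "chemsens_schema_error")
})
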