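# Independent oracles and fixture builders shared across tests.
# The walk oracle is a deliberate straight-line re-implementation of the
# running-sum statistic (scalar loop, explicit extremum tracking) kept
# separate from the vectorized implementation it checks.

es_walk_oracle <- function(scores, hits, p = 1) {
  n <- length(scores)
  nh <- length(hits)
  total_w <- sum(abs(scores[hits])^p)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (i %in% hits) {
      run <- run + abs(scores[i])^p / total_w
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# all C(n, k) subset enrichment scores, by brute force
exhaustive_null_oracle <- function(scores, k, p = 1) {
  apply(combn(length(scores), k), 2,
        function(h) es_walk_oracle(scores, h, p))
}

make_records <- function(gene, chemical = "chemx", direction = "+",
                         taxon = "Homo", pmid = 1000L,
                         use1 = "industrial", use2 = NA_character_,
                         use3 = NA_character_, use_description = "") {
  tibble::tibble(
    chemical = chemical, gene = toupper(gene), direction = direction,
    taxon = taxon, pmid = as.integer(pmid), use1 = use1, use2 = use2,
    use3 = use3, use_description = use_description
  )
}

# a centered ranking over n genes with heavy-tailed integer raw scores
make_ranking <- function(n, seed = 1) {
  set.seed(seed)
  raw <- sort(rpois(n, exp(rnorm(n, log(20), 1))), decreasing = TRUE)
  ranked <- tibble::tibble(gene = sprintf("G%05d", seq_len(n)),
                           raw_score = raw)
  center_scores(ranked)
}

small_interactions_tsv <- function(path, lines) {
  header <- paste("chemical term", "gene term", "action direction",
                  "taxonomy", "PMID", "use1", "use2", "use3",
                  "use description", sep = "\t")
  writeLines(c(header, lines), path)
  path
}
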