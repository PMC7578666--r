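#' Restrict interaction records to selected taxa
#'
#' Keeps the order-preserving subset of records whose taxon is in
#' `allowed`. The deposited dataset is defined on human, mouse and rat
#' evidence only, so the default keeps all three.
#'
#' @param records Interaction tibble.
#' @param allowed Nonempty subset of `c("Homo", "Mus", "Rattus")`.
#' @return Filtered tibble, original relative order preserved.
#' @export
filter_taxa <- function(records, allowed = allowed_taxa()) {
  if (length(allowed) == 0) abort("`allowed` must be nonempty")
  bad <- setdiff(allowed, allowed_taxa())
  if (length(bad) > 0) {
    abort(sprintf("unknown taxa in `allowed`: %s",
                  paste(bad, collapse = ", ")))
  }
  records[records$taxon %in% allowed, , drop = FALSE]
}

#' Drop genes not present in all three genomes
#'
#' Removes records for genes that are absent from any of the human, mouse
#' or rat genomes, using a gene-presence table (see
#' [read_gene_presence()]). A gene-species pair can be missing from the
#' interaction data either because the gene is insensitive in that species
#' or because the gene does not exist in its genome; only the latter genes
#' are removed, and the presence table is the tabulated result of that
#' orthology lookup.
#'
#' @param records Interaction tibble.
#' @param presence Gene-presence tibble with columns `gene`, `homo`,
#'   `mus`, `rattus` (logical).
#' @return A list with `kept` (records whose gene has all three flags
#'   `TRUE`, order preserved) and `removed_genes` (character vector of
#'   dropped symbols).
#' @details A record gene missing from `presence` is an error naming the
#'   gene: the caller must supply a complete table rather than have genes
#'   silently kept or dropped.
#' @export
filter_shared_genes <- function(records, presence) {
  idx <- match(records$gene, presence$gene)
  if (anyNA(idx)) {
    missing <- unique(records$gene[is.na(idx)])
    abort(sprintf("gene(s) absent from presence table: %s",
                  paste(head(missing, 10), collapse = ", ")),
          class = "chemsens_presence_error")
  }
  shared <- presence$homo[idx] & presence$mus[idx] & presence$rattus[idx]
  list(
    kept = records[shared, , drop = FALSE],
    removed_genes = sort(unique(records$gene[!shared]))
  )
}

#' Collapse duplicate chemical-gene interactions
#'
#' One interaction is a unique combination of original study (PMID),
#' biological model (taxon), chemical and gene. Groups sharing that key
#' collapse to their first-seen record; if directions within a group
#' disagree the surviving record's direction is set to unspecified (`"1"`)
#' and the conflict is counted. Keeping conflicting duplicates would
#' double-count the study, so direction is excluded from the key.
#'
#' @param records Interaction tibble.
#' @return A list with `records` (unique interactions, first-seen order,
#'   carrying attribute `deduplicated = TRUE`) and `report`, a list with
#'   `n_input`, `n_unique`, `n_collapsed` (`n_input - n_unique`) and
#'   `n_direction_conflicts`.
#' @export
deduplicate <- function(records) {
  key <- paste(records$gene, records$chemical, records$pmid, records$taxon,
               sep = "\r")
  first <- !duplicated(key)
  unique_rec <- records[first, , drop = FALSE]

  n_dir <- tapply(records$direction, key, function(d) length(unique(d)))
  conflict_keys <- names(n_dir)[n_dir > 1]
  if (length(conflict_keys) > 0) {
    hit <- key[first] %in% conflict_keys
    unique_rec$direction[hit] <- "1"
    warn(sprintf(
      "%d duplicate group(s) had conflicting directions; collapsed to \"1\"",
      length(conflict_keys)
    ))
  }
  attr(unique_rec, "deduplicated") <- TRUE
  list(
    records = unique_rec,
    report = list(
      n_input = nrow(records),
      n_unique = nrow(unique_rec),
      n_collapsed = nrow(records) - nrow(unique_rec),
      n_direction_conflicts = length(conflict_keys)
    )
  )
}

#' Subset interactions by chemical-use term
#'
#' Keeps records whose chemical carries `term` in any of its up-to-three
#' use annotations. Matching is case-insensitive after whitespace
#' normalization.
#'
#' @param records Interaction tibble.
#' @param term A single term from [use_vocabulary()].
#' @return Filtered tibble, order preserved.
#' @export
subset_by_use <- function(records, term) {
  term_norm <- normalize_term(term)
  if (!(term_norm %in% normalize_term(use_vocabulary()))) {
    abort(sprintf("unknown use term: %s", term))
  }
  match_col <- function(x) !is.na(x) & normalize_term(x) == term_norm
  keep <- match_col(records$use1) | match_col(records$use2) |
    match_col(records$use3)
  out <- records[keep, , drop = FALSE]
  attr(out, "deduplicated") <- attr(records, "deduplicated")
  out
}
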