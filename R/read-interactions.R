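#' Read a chemical-gene interaction table
#'
#' Reads a delimited interaction table in the layout of the deposited
#' annotated-interactions dataset: one line per chemical-gene interaction
#' with columns `chemical term`, `gene term`, `action direction`,
#' `taxonomy`, `PMID`, `use1`, `use2`, `use3` and `use description`.
#' Header matching is case- and whitespace-insensitive and column order is
#' free. Gene symbols are uppercased, directions are normalized ("+"
#' increase, "-" decrease -- an ASCII hyphen or a typographic minus U+2212
#' both map to decrease -- and "1" unspecified), and empty `use2`/`use3`
#' cells become `NA`.
#'
#' @param file Path to a delimited text file, or a connection.
#' @param dialect Field separator: `"tab"` (default) or `"comma"`.
#' @return A tibble of interaction records with columns `chemical`, `gene`,
#'   `direction`, `taxon`, `pmid` (integer), `use1`, `use2`, `use3`,
#'   `use_description`.
#' @details Mandatory columns are `chemical term`, `gene term`,
#'   `action direction`, `taxonomy`, `PMID` and `use1`; a missing one is a
#'   schema error naming the column. A non-numeric PMID or a taxon outside
#'   Homo/Mus/Rattus is a record-level error reported with its data line
#'   number. Stray taxa are errors rather than silently dropped: the
#'   analysis is defined downstream of taxon filtering, so an unknown taxon
#'   signals a malformed export.
#' @seealso [write_interactions()], [validate_annotations()]
#' @export
read_interactions <- function(file, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  delim <- if (dialect == "tab") "\t" else ","
  raw <- readr::read_delim(
    file,
    delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    na = character(),
    trim_ws = FALSE,
    progress = FALSE,
    show_col_types = FALSE
  )
  names(raw) <- normalize_term(names(raw))

  canonical <- c(
    "chemical term" = "chemical", "gene term" = "gene",
    "action direction" = "direction", "taxonomy" = "taxon",
    "pmid" = "pmid", "use1" = "use1", "use2" = "use2", "use3" = "use3",
    "use description" = "use_description"
  )
  mandatory <- c("chemical term", "gene term", "action direction",
                 "taxonomy", "pmid", "use1")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")),
          class = "chemsens_schema_error")
  }
  for (col in setdiff(names(canonical), names(raw))) raw[[col]] <- ""
  raw <- raw[names(canonical)]
  names(raw) <- unname(canonical)

  blank_to_na <- function(x) ifelse(trimws(x) == "", NA_character_, x)

  rec <- tibble::tibble(
    chemical = trimws(raw$chemical),
    gene = toupper(trimws(raw$gene)),
    direction = normalize_direction(raw$direction),
    taxon = trimws(raw$taxon),
    pmid = suppressWarnings(as.integer(trimws(raw$pmid))),
    use1 = blank_to_na(raw$use1),
    use2 = blank_to_na(raw$use2),
    use3 = blank_to_na(raw$use3),
    use_description = trimws(raw$use_description)
  )

  bad_pmid <- which(is.na(rec$pmid) | rec$pmid <= 0)
  if (length(bad_pmid) > 0) {
    abort(sprintf("unparseable or non-positive PMID at data line(s): %s",
                  paste(head(bad_pmid, 5), collapse = ", ")),
          class = "chemsens_record_error")
  }
  bad_taxon <- which(!(rec$taxon %in% allowed_taxa()))
  if (length(bad_taxon) > 0) {
    abort(sprintf(
      "unknown taxon %s at data line(s): %s (allowed: %s)",
      paste(unique(rec$taxon[bad_taxon]), collapse = ", "),
      paste(head(bad_taxon, 5), collapse = ", "),
      paste(allowed_taxa(), collapse = ", ")
    ), class = "chemsens_record_error")
  }
  bad_dir <- which(!(rec$direction %in% direction_codes()))
  if (length(bad_dir) > 0) {
    abort(sprintf("unknown action direction at data line(s): %s",
                  paste(head(bad_dir, 5), collapse = ", ")),
          class = "chemsens_record_error")
  }
  rec
}

#' Write a chemical-gene interaction table
#'
#' Writes records in the canonical tab-separated layout read back by
#' [read_interactions()]; the round trip is the identity on normalized
#' records.
#'
#' @param records Interaction tibble as returned by [read_interactions()].
#' @param file Output path or connection.
#' @export
write_interactions <- function(records, file) {
  out <- tibble::tibble(
    `chemical term` = records$chemical,
    `gene term` = records$gene,
    `action direction` = records$direction,
    `taxonomy` = records$taxon,
    `PMID` = records$pmid,
    `use1` = records$use1,
    `use2` = records$use2,
    `use3` = records$use3,
    `use description` = records$use_description
  )
  readr::write_tsv(out, file, na = "", progress = FALSE)
  invisible(file)
}

#' Validate chemical-use annotations
#'
#' Checks every record's use terms against the eleven-term vocabulary and
#' the one-to-three-terms rule. Violations are returned as data, one row
#' per offending record, rather than raised as errors.
#'
#' @param records Interaction tibble.
#' @param vocab Character vector of legal terms; defaults to
#'   [use_vocabulary()].
#' @return A tibble with columns `row`, `gene`, `chemical`, `violation`
#'   (`"unknown_term"`, `"no_terms"`, `"duplicate_terms"`,
#'   `"too_many_terms"`); zero rows iff
#'   all records conform. Term matching is case-insensitive after
#'   whitespace normalization.
#' @export
validate_annotations <- function(records, vocab = use_vocabulary()) {
  vocab_norm <- normalize_term(vocab)
  u1 <- normalize_term(records$use1)
  u2 <- normalize_term(records$use2)
  u3 <- normalize_term(records$use3)
  u1[is.na(records$use1)] <- NA
  u2[is.na(records$use2)] <- NA
  u3[is.na(records$use3)] <- NA

  n_terms <- (!is.na(u1)) + (!is.na(u2)) + (!is.na(u3))
  unknown <- (!is.na(u1) & !(u1 %in% vocab_norm)) |
    (!is.na(u2) & !(u2 %in% vocab_norm)) |
    (!is.na(u3) & !(u3 %in% vocab_norm))
  dup <- (!is.na(u1) & !is.na(u2) & u1 == u2) |
    (!is.na(u1) & !is.na(u3) & u1 == u3) |
    (!is.na(u2) & !is.na(u3) & u2 == u3)

  # Overflow columns (use4, use5, ...) break the up-to-three-terms rule.
  extra_cols <- grep("^use[0-9]+$", names(records), value = TRUE)
  extra_cols <- extra_cols[as.integer(sub("^use", "", extra_cols)) > 3]
  too_many <- rep(FALSE, nrow(records))
  for (col in extra_cols) too_many <- too_many | !is.na(records[[col]])

  idx <- which(n_terms == 0 | unknown | dup | too_many)
  if (length(idx) == 0) {
    return(tibble::tibble(row = integer(), gene = character(),
                          chemical = character(), violation = character()))
  }
  violation <- character(length(idx))
  violation[n_terms[idx] == 0] <- "no_terms"
  violation[too_many[idx]] <- "too_many_terms"
  violation[unknown[idx]] <- "unknown_term"
  violation[dup[idx] & !unknown[idx] & n_terms[idx] > 0] <- "duplicate_terms"
  tibble::tibble(
    row = idx,
    gene = records$gene[idx],
    chemical = records$chemical[idx],
    violation = violation
  )
}
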