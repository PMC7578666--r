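#' Read and write gene-set collections in GMT format
#'
#' GMT is the standard tab-separated carrier for Hallmark/KEGG/Reactome
#' style collections: one set per line as `name<TAB>description<TAB>member
#' genes...`. Member symbols are uppercased; empty trailing fields are
#' ignored. `write_gmt()` followed by `read_gmt()` is the identity up to
#' member-set equality.
#'
#' @param file Path or connection to a GMT file.
#' @param collection_name Label for the collection (e.g. `"Hallmark"`);
#'   defaults to the file name without extension.
#' @return `read_gmt()` returns a `gene_set_collection`: a list with
#'   `collection_name`, `sets` (named list of character vectors) and
#'   `descriptions` (named character vector).
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("SET1\tdesc\tTP53\tESR1", tf)
#' read_gmt(tf, "demo")
#' @export
read_gmt <- function(file, collection_name = NULL) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(collection_name)) {
    collection_name <- if (is.character(file)) {
      sub("\\.[^.]*$", "", basename(file))
    } else {
      "collection"
    }
  }
  sets <- vector("list", length(lines))
  descriptions <- character(length(lines))
  set_names <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    fields_kept <- fields[nzchar(trimws(fields)) | seq_along(fields) <= 2]
    if (length(fields_kept) < 3) {
      abort(sprintf("GMT line %d has fewer than 3 fields", i),
            class = "chemsens_gmt_error")
    }
    set_names[[i]] <- trimws(fields_kept[[1]])
    descriptions[[i]] <- fields_kept[[2]]
    members <- toupper(trimws(fields_kept[-(1:2)]))
    sets[[i]] <- unique(members[nzchar(members)])
  }
  if (anyDuplicated(set_names)) {
    abort(sprintf("duplicate gene-set name(s): %s",
                  paste(unique(set_names[duplicated(set_names)]),
                        collapse = ", ")),
          class = "chemsens_gmt_error")
  }
  names(sets) <- set_names
  names(descriptions) <- set_names
  gene_set_collection(collection_name, sets, descriptions)
}

#' @rdname read_gmt
#' @param collection A `gene_set_collection`.
#' @export
write_gmt <- function(collection, file) {
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, collection$descriptions[[nm]], collection$sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, file)
  invisible(file)
}

#' Construct a gene-set collection
#'
#' @param collection_name Collection label.
#' @param sets Named list of character vectors of gene symbols.
#' @param descriptions Optional named character vector of descriptions
#'   (defaults to empty strings).
#' @return A `gene_set_collection` object.
#' @export
gene_set_collection <- function(collection_name, sets,
                                descriptions = NULL) {
  if (length(sets) > 0 &&
      (is.null(names(sets)) || anyDuplicated(names(sets)))) {
    abort("`sets` must be a uniquely named list")
  }
  sets <- lapply(sets, function(s) unique(toupper(s[nzchar(s)])))
  if (is.null(descriptions)) {
    descriptions <- setNames(rep("", length(sets)), names(sets))
  }
  structure(
    list(collection_name = collection_name, sets = sets,
         descriptions = descriptions[names(sets)]),
    class = "gene_set_collection"
  )
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sizes <- lengths(x$sets)
  cat(sprintf("<gene_set_collection> %s: %d sets (sizes %d-%d)\n",
              x$collection_name, length(x$sets),
              if (length(sizes)) min(sizes) else 0L,
              if (length(sizes)) max(sizes) else 0L))
  invisible(x)
}

#' Read a gene-presence table
#'
#' Reads the tabulated result of mapping gene lists to the human, mouse
#' and rat genomes: one row per gene with a presence flag per genome.
#' Flags accept `1/0`, `true/false` and `yes/no` (case-insensitive).
#' Duplicate rows with identical flags merge silently; duplicate rows with
#' conflicting flags are an error.
#'
#' @param file Path or connection to a delimited file with columns
#'   `gene`, `homo`, `mus`, `rattus`.
#' @param dialect `"tab"` or `"comma"`.
#' @return Tibble with uppercased `gene` and logical `homo`, `mus`,
#'   `rattus` columns.
#' @export
read_gene_presence <- function(file, dialect = c("tab", "comma")) {
  dialect <- match.arg(dialect)
  delim <- if (dialect == "tab") "\t" else ","
  raw <- readr::read_delim(
    file, delim = delim,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  names(raw) <- normalize_term(names(raw))
  needed <- c("gene", "homo", "mus", "rattus")
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("missing column(s) in presence table: %s",
                  paste(missing_cols, collapse = ", ")),
          class = "chemsens_schema_error")
  }
  as_flag <- function(x) {
    x <- tolower(trimws(x))
    out <- rep(NA, length(x))
    out[x %in% c("1", "true", "yes")] <- TRUE
    out[x %in% c("0", "false", "no")] <- FALSE
    if (anyNA(out)) abort("unrecognized presence flag value",
                          class = "chemsens_schema_error")
    out
  }
  tab <- tibble::tibble(
    gene = toupper(trimws(raw$gene)),
    homo = as_flag(raw$homo),
    mus = as_flag(raw$mus),
    rattus = as_flag(raw$rattus)
  )
  if (anyDuplicated(tab$gene)) {
    full_dup <- duplicated(tab)
    tab <- tab[!full_dup, , drop = FALSE]
    if (anyDuplicated(tab$gene)) {
      bad <- unique(tab$gene[duplicated(tab$gene)])
      abort(sprintf("conflicting presence flags for gene(s): %s",
                    paste(head(bad, 10), collapse = ", ")),
            class = "chemsens_schema_error")
    }
  }
  tab
}
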