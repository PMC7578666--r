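#' Count chemical-gene interactions per gene
#'
#' Computes the per-gene sensitivity statistic: the number of distinct
#' chemical-gene interactions a gene participates in, split into
#' activating (`"+"`), suppressive (`"-"`) and unspecified (`"1"`)
#' directions. The count of interactions is used as a proxy for the
#' gene's responsiveness to a broad range of chemical exposures.
#'
#' @param records Deduplicated interaction tibble (see [deduplicate()]);
#'   a warning is emitted if the deduplication flag is missing, since
#'   duplicate lines would double-count studies.
#' @return Tibble with one row per distinct gene and columns `gene`,
#'   `n_suppressive`, `n_activating`, `n_unspecified`, `n_total`
#'   (`n_total` always equals the sum of the three parts, and the column
#'   sums over genes equal the record count). Genes with no observed
#'   interaction do not appear: the gene universe is defined by observed
#'   interactions.
#' @export
count_interactions <- function(records) {
  if (!isTRUE(attr(records, "deduplicated"))) {
    warn("records are not flagged as deduplicated; counts may double-count studies")
  }
  if (nrow(records) == 0) {
    return(tibble::tibble(
      gene = character(), n_suppressive = integer(),
      n_activating = integer(), n_unspecified = integer(),
      n_total = integer()
    ))
  }
  records |>
    dplyr::count(.data$gene, .data$direction) |>
    spread_direction_counts(c("-" = "n_suppressive", "+" = "n_activating",
                  "1" = "n_unspecified")) |>
    dplyr::mutate(
      n_total = .data$n_suppressive + .data$n_activating +
        .data$n_unspecified
    ) |>
    dplyr::arrange(.data$gene)
}

# Spread direction counts into fixed columns without depending on tidyr.
spread_direction_counts <- function(counts, mapping) {
  genes <- sort(unique(counts$gene))
  out <- tibble::tibble(gene = genes)
  for (code in names(mapping)) {
    sub <- counts[counts$direction == code, ]
    v <- integer(length(genes))
    v[match(sub$gene, genes)] <- sub$n
    out[[mapping[[code]]]] <- v
  }
  out
}

#' Rank genes by interaction count
#'
#' Orders genes by the chosen sensitivity metric, descending; ties are
#' broken by gene symbol ascending so the ranking is deterministic.
#'
#' @param counts Per-gene count tibble from [count_interactions()].
#' @param metric One of `"total"` (default), `"activating"`,
#'   `"suppressive"`.
#' @return Tibble with columns `gene` and `raw_score`, ordered.
#' @export
rank_genes <- function(counts, metric = c("total", "activating",
                                          "suppressive")) {
  metric <- match.arg(metric)
  if (nrow(counts) == 0) abort("`counts` must be nonempty")
  if (anyDuplicated(counts$gene)) abort("duplicate genes in counts table")
  col <- switch(metric, total = "n_total", activating = "n_activating",
                suppressive = "n_suppressive")
  ord <- order(-counts[[col]], counts$gene)
  tibble::tibble(gene = counts$gene[ord], raw_score = counts[[col]][ord])
}

#' Center ranked interaction counts for preranked enrichment
#'
#' Interaction counts are all positive, while the enrichment walk assumes
#' a signed statistic with comparable mass on both sides. Subtracting the
#' arithmetic mean from every count is the unique single-constant shift
#' that makes the positive area under the rank curve equal the negative
#' area, because the difference of the two areas is the sum of the
#' deviations from the shift constant. The ranking order is unchanged.
#'
#' @param ranked Tibble with `gene` and `raw_score`, ordered as from
#'   [rank_genes()].
#' @return The input with a `centered_score` column appended and the
#'   shift constant stored in attribute `shift_constant`; centered scores
#'   sum to zero to within numerical tolerance.
#' @details At least two genes and at least two distinct raw scores are
#'   required: an all-equal ranking carries no ordering signal and is an
#'   error.
#' @export
center_scores <- function(ranked) {
  if (nrow(ranked) < 2) abort("need at least 2 genes to center")
  if (length(unique(ranked$raw_score)) < 2) {
    abort("all raw scores equal; degenerate ranking carries no signal")
  }
  shift <- mean(ranked$raw_score)
  out <- ranked
  out$centered_score <- ranked$raw_score - shift
  attr(out, "shift_constant") <- shift
  out
}

#' Write a preranked gene list (RNK)
#'
#' Two tab-separated columns (gene, centered score), one line per gene,
#' in ranking order, scores printed with 12 significant digits.
#'
#' @param ranked Centered ranking from [center_scores()].
#' @param file Output path or connection.
#' @export
write_rnk <- function(ranked, file) {
  lines <- sprintf("%s\t%.12g", ranked$gene, ranked$centered_score)
  writeLines(lines, file)
  invisible(file)
}

#' @rdname write_rnk
#' @return `read_rnk()` returns a tibble with `gene` and
#'   `centered_score`, in file order.
#' @export
read_rnk <- function(file) {
  raw <- readr::read_tsv(
    file, col_names = c("gene", "centered_score"),
    col_types = readr::cols(readr::col_character(), readr::col_double()),
    progress = FALSE, show_col_types = FALSE
  )
  tibble::as_tibble(raw)
}

#' Write the per-gene counts table
#'
#' Mirrors the deposited per-gene schema: columns `gene`, `suppressive`,
#' `activating`, `not specified`, `total`.
#'
#' @param counts Tibble from [count_interactions()].
#' @param file Output path or connection.
#' @export
write_gene_counts <- function(counts, file) {
  out <- tibble::tibble(
    gene = counts$gene,
    suppressive = counts$n_suppressive,
    activating = counts$n_activating,
    `not specified` = counts$n_unspecified,
    total = counts$n_total
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}
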