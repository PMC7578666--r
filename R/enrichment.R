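#' Parameters for preranked enrichment
#'
#' @param weight_exponent Exponent applied to |centered score| when a
#'   gene-set member is encountered in the walk. `1` (default) gives the
#'   classic weighted statistic; `0` reduces to the unweighted
#'   Kolmogorov-Smirnov walk.
#' @param n_permutations Number of random same-size gene sets drawn for
#'   the null distribution (default 1000; at least 10).
#' @param seed Integer seed; every random draw in a run derives from it.
#' @param min_set_size,max_set_size Bounds on gene-set size after
#'   restriction to the ranked universe (defaults 15 and 500, the common
#'   preranked conventions).
#' @param nes_threshold,q_threshold Calling thresholds: a set is called
#'   most (least) sensitive when NES >= `nes_threshold`
#'   (<= `-nes_threshold`) and FDR q <= `q_threshold`. Defaults 1.9 and
#'   0.05; comparisons are inclusive.
#' @return A list of class `enrichment_params`.
#' @export
enrichment_params <- function(weight_exponent = 1, n_permutations = 1000,
                              seed = 1L, min_set_size = 15,
                              max_set_size = 500, nes_threshold = 1.9,
                              q_threshold = 0.05) {
  stopifnot(weight_exponent >= 0, n_permutations >= 10,
            min_set_size >= 1, max_set_size >= min_set_size,
            nes_threshold > 0, q_threshold >= 0, q_threshold <= 1)
  structure(
    list(weight_exponent = weight_exponent,
         n_permutations = as.integer(n_permutations),
         seed = as.integer(seed),
         min_set_size = as.integer(min_set_size),
         max_set_size = as.integer(max_set_size),
         nes_threshold = nes_threshold, q_threshold = q_threshold),
    class = "enrichment_params"
  )
}

#' Restrict a gene set to the ranked universe
#'
#' Intersects a set with the genes of the ranked list; the set size used
#' everywhere downstream (null distribution, NES) is this restricted
#' size. Sets falling outside the configured size bounds are excluded
#' with a reason. Restriction is idempotent.
#'
#' @param set Character vector of gene symbols.
#' @param universe Character vector of ranked-universe genes.
#' @param params An [enrichment_params()] object.
#' @return List with `genes` (restricted members, `NULL` if excluded) and
#'   `exclusion` (`NA` or `"too_small"`/`"too_large"`).
#' @export
restrict_set <- function(set, universe, params = enrichment_params()) {
  genes <- intersect(toupper(set), universe)
  if (length(genes) < params$min_set_size) {
    return(list(genes = NULL, exclusion = "too_small",
                size = length(genes)))
  }
  if (length(genes) > params$max_set_size) {
    return(list(genes = NULL, exclusion = "too_large",
                size = length(genes)))
  }
  list(genes = genes, exclusion = NA_character_, size = length(genes))
}

#' Running-sum enrichment score
#'
#' Walks down the ranked gene list accumulating a running-sum statistic:
#' at a gene-set member ("hit") the sum increases by that gene's weight,
#' `|centered score|^p` normalized so all hit increments total 1; at a
#' non-member it decreases by `1/(N - N_hit)`. The profile therefore
#' returns to zero after the last gene, and the enrichment score (ES) is
#' the signed value of greatest magnitude attained along the walk, so a
#' set depleted from the top of the list receives a negative ES.
#'
#' @param centered Numeric vector of centered scores in ranking order
#'   (descending), named by gene symbol.
#' @param set Character vector of set members (must be a nonempty subset
#'   of the names of `centered`), or an integer vector of rank positions.
#' @param weight_exponent Weight exponent `p >= 0` (default 1).
#' @return List of class `running_profile` with elements `es`,
#'   `running` (per-rank profile, length N), `hit_positions` (sorted rank
#'   indices) and `es_position` (rank attaining the extremum).
#' @details All hit weights zero (possible only when every member sits
#'   exactly at the shift constant with `p > 0`) is a degenerate
#'   weighting and an error.
#' @export
enrichment_score <- function(centered, set, weight_exponent = 1) {
  n <- length(centered)
  if (is.character(set)) {
    hits <- match(set, names(centered))
    if (anyNA(hits)) {
      abort(sprintf("set member(s) not in universe: %s",
                    paste(head(set[is.na(hits)], 5), collapse = ", ")))
    }
  } else {
    hits <- as.integer(set)
    if (any(hits < 1 | hits > n)) abort("hit positions out of range")
  }
  hits <- sort(hits)
  n_hit <- length(hits)
  if (n_hit == 0) abort("empty gene set")

  w <- abs(centered[hits])^weight_exponent
  total_w <- sum(w)
  if (total_w == 0) abort("all hit weights are zero; degenerate weighting")

  steps <- if (n_hit < n) rep(-1 / (n - n_hit), n) else numeric(n)
  steps[hits] <- w / total_w
  running <- cumsum(steps)
  es_position <- which.max(abs(running))
  structure(
    list(es = unname(running[es_position]), running = unname(running),
         hit_positions = unname(hits), es_position = es_position),
    class = "running_profile"
  )
}

# Deterministic substream seed for a given run seed and set size, kept
# within 32-bit integer range so equal-size sets share one null array and
# removing a collection cannot shift another collection's null.
substream_seed <- function(seed, set_size) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(set_size) * 16807) %%
               2147483647)
}

#' Permutation null distribution of enrichment scores
#'
#' Draws `n_permutations` uniform random gene subsets of `set_size` from
#' the universe (without replacement) and records the enrichment score of
#' each. Gene-set permutation is the appropriate null for a single
#' preranked list, where phenotype permutation is not possible. One null
#' array is shared by all sets of equal size; its substream is derived
#' deterministically from `(seed, set_size)`.
#'
#' @inheritParams enrichment_score
#' @param set_size Size of the random sets, `1 <= set_size <= N`.
#' @param params An [enrichment_params()] object (supplies
#'   `n_permutations`, `seed`, `weight_exponent`).
#' @return Numeric vector of `n_permutations` signed enrichment scores.
#' @export
null_distribution <- function(centered, set_size,
                              params = enrichment_params()) {
  n <- length(centered)
  stopifnot(set_size >= 1, set_size <= n)
  rng <- local({
    set.seed(substream_seed(params$seed, set_size))
    function() sample.int(n, set_size)
  })
  vapply(seq_len(params$n_permutations), function(i) {
    enrichment_score(centered, rng(), params$weight_exponent)$es
  }, numeric(1))
}

#' Size-normalize an enrichment score
#'
#' NES = ES divided by the mean magnitude of same-sign null enrichment
#' scores for the set's size, making scores comparable across set sizes.
#' If the null array contains no value of the same sign as ES the NES is
#' undefined (`NA`) and the set is excluded from FDR estimation.
#'
#' @param es Observed enrichment score.
#' @param null_es Null enrichment scores from [null_distribution()] at
#'   the set's size.
#' @return Normalized enrichment score; sign equals the sign of `es`.
#' @export
normalize_es <- function(es, null_es) {
  same <- null_es[sign(null_es) == sign(es) & null_es != 0]
  if (es == 0 || length(same) == 0) return(NA_real_)
  es / mean(abs(same))
}

#' Nominal permutation p-value
#'
#' Sign-stratified add-one estimator:
#' p = (1 + #same-sign null with |value| >= |es|) / (1 + #same-sign null).
#' The add-one correction avoids reporting zero with a finite number of
#' permutations.
#'
#' @inheritParams normalize_es
#' @return p-value in (0, 1].
#' @export
nominal_p <- function(es, null_es) {
  same <- null_es[sign(null_es) == sign(es) & null_es != 0]
  if (es == 0 || length(same) == 0) return(NA_real_)
  (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
}

#' Sign-stratified FDR q-values
#'
#' For a positive observed NES the q-value is the fraction of positive
#' null NES at least as large, divided by the fraction of positive
#' observed NES at least as large; mirrored for negative NES. Values are
#' clipped to \[0, 1\] and made monotone: moving toward more extreme NES
#' the q-value never increases (running minimum).
#'
#' @param nes Numeric vector of observed NES (may contain `NA` for
#'   sets whose NES is undefined; these receive `NA` q).
#' @param null_nes Pooled normalized null scores: every null ES
#'   normalized by the same-sign mean of its own size-matched null array.
#' @return Numeric vector of q-values aligned with `nes`.
#' @export
fdr_q <- function(nes, null_nes) {
  q <- rep(NA_real_, length(nes))
  obs_ok <- !is.na(nes)
  null_nes <- null_nes[!is.na(null_nes)]
  for (sgn in c(1, -1)) {
    obs_side <- which(obs_ok & sign(nes) == sgn)
    if (length(obs_side) == 0) next
    null_side <- null_nes[sign(null_nes) == sgn]
    for (i in obs_side) {
      thr <- abs(nes[i])
      num <- if (length(null_side) == 0) 0 else
        mean(abs(null_side) >= thr)
      den <- mean(abs(nes[obs_side]) >= thr)
      q[i] <- min(1, max(0, num / den))
    }
    # monotone: more extreme |NES| on the same side never has larger q;
    # the running minimum walks from least to most extreme
    ord <- obs_side[order(abs(nes[obs_side]))]
    q[ord] <- cummin(q[ord])
  }
  q
}

#' Run preranked enrichment over gene-set collections
#'
#' Full enrichment of a centered ranking against one or more collections:
#' sets are restricted to the ranked universe and size-filtered, each
#' surviving set receives an enrichment score, a size-matched permutation
#' null (shared across equal-size sets), an NES, a nominal p-value, a
#' sign-stratified FDR q-value estimated over all collections jointly,
#' and a sensitivity call. Results are deterministic for a fixed seed.
#'
#' @param ranked Centered ranking from [center_scores()].
#' @param collections A `gene_set_collection` or list of them.
#' @param params An [enrichment_params()] object.
#' @return Tibble of class `enrichment_results` with columns
#'   `collection`, `set_name`, `set_size`, `es`, `nes`, `p_nominal`,
#'   `fdr_q`, `call`, sorted by `nes` descending (`NA` last). Excluded
#'   sets are recorded in attribute `excluded` (tibble with `collection`,
#'   `set_name`, `size`, `reason`); the parameters used are in attribute
#'   `params`, and each set's running profile in attribute `profiles`
#'   (named `collection||set_name`).
#' @export
run_enrichment <- function(ranked, collections,
                           params = enrichment_params()) {
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  if (length(collections) == 0) abort("`collections` must be nonempty")
  if (nrow(ranked) == 0) abort("empty ranked universe")
  centered <- setNames(ranked$centered_score, ranked$gene)

  rows <- list(); excluded <- list(); profiles <- list()
  for (coll in collections) {
    for (nm in names(coll$sets)) {
      r <- restrict_set(coll$sets[[nm]], names(centered), params)
      if (!is.na(r$exclusion)) {
        excluded[[length(excluded) + 1]] <- tibble::tibble(
          collection = coll$collection_name, set_name = nm,
          size = r$size, reason = r$exclusion
        )
        next
      }
      prof <- enrichment_score(centered, r$genes, params$weight_exponent)
      rows[[length(rows) + 1]] <- tibble::tibble(
        collection = coll$collection_name, set_name = nm,
        set_size = r$size, es = prof$es
      )
      profiles[[paste(coll$collection_name, nm, sep = "||")]] <- prof
    }
  }
  excluded <- if (length(excluded)) dplyr::bind_rows(excluded) else
    tibble::tibble(collection = character(), set_name = character(),
                   size = integer(), reason = character())
  if (length(rows) == 0) {
    res <- tibble::tibble(
      collection = character(), set_name = character(),
      set_size = integer(), es = numeric(), nes = numeric(),
      p_nominal = numeric(), fdr_q = numeric(), call = character()
    )
    attr(res, "excluded") <- excluded
    attr(res, "params") <- params
    attr(res, "profiles") <- profiles
    class(res) <- c("enrichment_results", class(res))
    return(res)
  }
  res <- dplyr::bind_rows(rows)

  # one shared null array per distinct restricted size
  sizes <- sort(unique(res$set_size))
  nulls <- lapply(sizes, function(s) null_distribution(centered, s, params))
  names(nulls) <- as.character(sizes)

  res$nes <- vapply(seq_len(nrow(res)), function(i) {
    normalize_es(res$es[i], nulls[[as.character(res$set_size[i])]])
  }, numeric(1))
  res$p_nominal <- vapply(seq_len(nrow(res)), function(i) {
    nominal_p(res$es[i], nulls[[as.character(res$set_size[i])]])
  }, numeric(1))

  null_nes <- unlist(lapply(nulls, function(ne) {
    pos_mean <- mean(abs(ne[ne > 0]))
    neg_mean <- mean(abs(ne[ne < 0]))
    out <- rep(NA_real_, length(ne))
    out[ne > 0] <- ne[ne > 0] / pos_mean
    out[ne < 0] <- -abs(ne[ne < 0]) / neg_mean
    out
  }), use.names = FALSE)
  res$fdr_q <- fdr_q(res$nes, null_nes)
  res <- classify_sensitivity(res, params)
  res <- res[order(-ifelse(is.na(res$nes), -Inf, res$nes)), , drop = FALSE]

  attr(res, "excluded") <- excluded
  attr(res, "params") <- params
  attr(res, "profiles") <- profiles
  class(res) <- c("enrichment_results", class(res))
  res
}

#' Classify pathway sensitivity from NES and FDR q
#'
#' A gene set is called `most_sensitive` when NES >= the NES threshold
#' and q <= the q threshold, `least_sensitive` when NES <= minus the NES
#' threshold and q <= the q threshold, and `neither` otherwise. Both
#' comparisons are inclusive, so NES exactly 1.9 with q exactly 0.05
#' (the defaults) is called.
#'
#' @param results Tibble with `nes` and `fdr_q` columns.
#' @param params An [enrichment_params()] object.
#' @return `results` with the `call` column filled.
#' @export
classify_sensitivity <- function(results, params = enrichment_params()) {
  call <- rep("neither", nrow(results))
  ok <- !is.na(results$nes) & !is.na(results$fdr_q)
  call[ok & results$nes >= params$nes_threshold &
         results$fdr_q <= params$q_threshold] <- "most_sensitive"
  call[ok & results$nes <= -params$nes_threshold &
         results$fdr_q <= params$q_threshold] <- "least_sensitive"
  call[!ok] <- NA_character_
  results$call <- call
  results
}

#' Plot-ready data for one enriched set
#'
#' Bundles the three index-aligned series of the classic enrichment
#' plot: the running enrichment score, tick positions where set members
#' appear in the ranked list, and the centered interaction-count bar
#' series (which sums to zero by construction of the centering).
#'
#' @param profile A `running_profile` from [enrichment_score()].
#' @param ranked Centered ranking the profile was computed on.
#' @param set_name,collection Labels carried into the bundle.
#' @return List of class `enrichment_plot_data` with `set_name`,
#'   `collection`, `running_score`, `hit_positions`, `centered_scores`,
#'   `genes`, `es`, `es_position`.
#' @export
plot_data <- function(profile, ranked, set_name = "",
                      collection = "") {
  stopifnot(length(profile$running) == nrow(ranked))
  structure(
    list(set_name = set_name, collection = collection,
         running_score = profile$running,
         hit_positions = profile$hit_positions,
         centered_scores = ranked$centered_score, genes = ranked$gene,
         es = profile$es, es_position = profile$es_position),
    class = "enrichment_plot_data"
  )
}

#' @rdname plot_data
#' @param bundle An `enrichment_plot_data` object.
#' @param file Output JSON path.
#' @export
write_plot_bundle <- function(bundle, file) {
  jsonlite::write_json(unclass(bundle), file, auto_unbox = TRUE,
                       digits = NA)
  invisible(file)
}

#' Write an enrichment results table
#'
#' Mirrors the deposited results schema: collection of gene sets, gene
#' set name, gene set size, enrichment score, normalised enrichment
#' score, nominal p-value, FDR q-value, plus the sensitivity call.
#'
#' @param results An `enrichment_results` tibble.
#' @param file Output path or connection.
#' @export
write_enrichment_results <- function(results, file) {
  out <- tibble::tibble(
    `collection of gene sets` = results$collection,
    `gene set name` = results$set_name,
    `gene set size` = results$set_size,
    `enrichment score` = formatC(results$es, digits = 12, format = "g"),
    `normalised enrichment score` = formatC(results$nes, digits = 12,
                                            format = "g"),
    `nominal p-value` = formatC(results$p_nominal, digits = 12,
                                format = "g"),
    `FDR q-value` = formatC(results$fdr_q, digits = 12, format = "g"),
    call = results$call
  )
  readr::write_tsv(out, file, na = "NA", progress = FALSE)
  invisible(file)
}
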