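#' Configuration for the synthetic toxicogenomic generator
#'
#' Defines a latent-rate model of chemical-gene interaction data: each
#' gene g has a latent sensitivity rate lambda_g drawn from a log-normal
#' (heavy right tail, matching the concave rank curve of real
#' interaction counts), and its observed interaction count is Poisson
#' with that rate. Genes in planted high-sensitivity sets have their
#' rate multiplied by an effect factor; planted-low sets are divided by
#' it, so an effect factor of 1 is the null. The defaults describe the
#' benchmark used throughout the package's tests: 2,000 genes, mean 34
#' interactions per gene (the per-gene mean of the real deposited
#' dataset), log-scale dispersion 1, three planted-high and two
#' planted-low sets of size 50 at effect factor 3, and 40 null sets of
#' size 50.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_chemicals Number of distinct chemicals.
#' @param base_rate Mean interactions per background gene (> 0).
#' @param dispersion Log-scale standard deviation of the latent rate
#'   (> 0; larger means a heavier right tail).
#' @param planted_sets Data frame with columns `name`, `size`,
#'   `effect_factor` (>= 1) and `direction` (`"high"` or `"low"`).
#' @param n_null_sets,null_set_size Number and size of random null sets
#'   drawn from non-planted genes.
#' @param taxa_weights,direction_weights Sampling probabilities for the
#'   three taxa (Homo, Mus, Rattus) and the three directions
#'   (`"+"`, `"-"`, `"1"`); each must sum to 1.
#' @param holdout_fraction Fraction of non-planted genes marked absent
#'   from one genome in the emitted presence table, to exercise the
#'   shared-genome filter (default 0.05).
#' @param seed Integer seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_genes = 2000, n_chemicals = 300,
                             base_rate = 34, dispersion = 1,
                             planted_sets = default_planted_sets(),
                             n_null_sets = 40, null_set_size = 50,
                             taxa_weights = c(1, 1, 1) / 3,
                             direction_weights = c(0.45, 0.45, 0.10),
                             holdout_fraction = 0.05, seed = 1L) {
  stopifnot(
    n_genes >= 2, n_chemicals >= 1, base_rate > 0, dispersion > 0,
    all(planted_sets$effect_factor >= 1),
    all(planted_sets$direction %in% c("high", "low")),
    sum(planted_sets$size) + null_set_size <= n_genes,
    abs(sum(taxa_weights) - 1) < 1e-9, length(taxa_weights) == 3,
    abs(sum(direction_weights) - 1) < 1e-9,
    length(direction_weights) == 3,
    holdout_fraction >= 0, holdout_fraction < 1
  )
  structure(
    list(n_genes = as.integer(n_genes),
         n_chemicals = as.integer(n_chemicals), base_rate = base_rate,
         dispersion = dispersion,
         planted_sets = tibble::as_tibble(planted_sets),
         n_null_sets = as.integer(n_null_sets),
         null_set_size = as.integer(null_set_size),
         taxa_weights = taxa_weights,
         direction_weights = direction_weights,
         holdout_fraction = holdout_fraction, seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' @rdname generator_config
#' @export
default_planted_sets <- function() {
  tibble::tibble(
    name = c("PLANTED_HIGH_1", "PLANTED_HIGH_2", "PLANTED_HIGH_3",
             "PLANTED_LOW_1", "PLANTED_LOW_2"),
    size = 50L,
    effect_factor = 3,
    direction = c("high", "high", "high", "low", "low")
  )
}

#' Draw the latent gene universe
#'
#' Draws per-gene latent sensitivity rates lambda_g from a log-normal
#' with arithmetic mean `base_rate` and log-scale standard deviation
#' `dispersion` (so `meanlog = log(base_rate) - dispersion^2/2`), then
#' applies the planted effects: rates of genes in planted-high sets are
#' multiplied by the set's effect factor, planted-low rates divided by
#' it. Planted sets occupy disjoint blocks of genes.
#'
#' @param config A [generator_config()].
#' @return List of class `ground_truth` with `genes` (symbols `G00001`
#'   ...), `lambda` (adjusted rates), `lambda_base` (pre-adjustment
#'   rates), `membership` (named list: planted set name -> genes) and
#'   `planted_sets` (the config table).
#' @export
gen_universe <- function(config) {
  set.seed(config$seed)
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  meanlog <- log(config$base_rate) - config$dispersion^2 / 2
  lambda_base <- rlnorm(config$n_genes, meanlog = meanlog,
                        sdlog = config$dispersion)
  lambda <- lambda_base

  membership <- list()
  cursor <- 1L
  ps <- config$planted_sets
  for (i in seq_len(nrow(ps))) {
    idx <- seq.int(cursor, cursor + ps$size[i] - 1L)
    cursor <- cursor + ps$size[i]
    membership[[ps$name[i]]] <- genes[idx]
    lambda[idx] <- if (ps$direction[i] == "high") {
      lambda[idx] * ps$effect_factor[i]
    } else {
      lambda[idx] / ps$effect_factor[i]
    }
  }
  structure(
    list(genes = genes, lambda = lambda, lambda_base = lambda_base,
         membership = membership, planted_sets = ps),
    class = "ground_truth"
  )
}

#' Generate an interaction table from the latent universe
#'
#' Per gene g a count k_g ~ Poisson(lambda_g) of interaction lines is
#' emitted. Each line draws a chemical uniformly, a taxon and a
#' direction from their weight vectors and a synthetic PMID; use terms
#' are fixed per chemical (one to three legal vocabulary terms), since
#' use annotation is a property of the chemical. (gene, chemical, PMID,
#' taxon) collisions are regenerated, so the emitted table is born
#' deduplicated and a clean baseline for the deduplication report. The
#' presence table marks every emitted gene present in all three genomes
#' except a holdout fraction of non-planted genes, each missing one
#' randomly chosen genome.
#'
#' @param truth A `ground_truth` from [gen_universe()].
#' @param config The same [generator_config()].
#' @return List with `records` (interaction tibble in the canonical
#'   schema) and `presence` (gene-presence tibble covering every emitted
#'   gene).
#' @export
gen_interactions <- function(truth, config) {
  set.seed(substream_seed(config$seed, 2L))
  vocab <- use_vocabulary()

  n_uses <- sample(1:3, config$n_chemicals, replace = TRUE)
  chem_uses <- lapply(n_uses, function(k) sample(vocab, k))
  chem_names <- sprintf("chem_%04d", seq_len(config$n_chemicals))

  k_g <- rpois(config$n_genes, truth$lambda)
  total <- sum(k_g)
  gene_col <- rep(truth$genes, k_g)
  chem_idx <- sample.int(config$n_chemicals, total, replace = TRUE)
  taxon <- sample(allowed_taxa(), total, replace = TRUE,
                  prob = config$taxa_weights)
  direction <- sample(direction_codes(), total, replace = TRUE,
                      prob = config$direction_weights)
  pmid <- sample.int(9000000L, total, replace = TRUE) + 1000000L

  key <- paste(gene_col, chem_idx, pmid, taxon, sep = "\r")
  dup <- duplicated(key)
  guard <- 0L
  while (any(dup)) {
    pmid[dup] <- sample.int(9000000L, sum(dup), replace = TRUE) + 1000000L
    key <- paste(gene_col, chem_idx, pmid, taxon, sep = "\r")
    dup <- duplicated(key)
    guard <- guard + 1L
    if (guard > 100L) abort("could not resolve PMID collisions")
  }

  use_mat <- vapply(chem_idx, function(ci) {
    u <- chem_uses[[ci]]
    c(u, rep(NA_character_, 3 - length(u)))
  }, character(3))

  records <- tibble::tibble(
    chemical = chem_names[chem_idx],
    gene = gene_col,
    direction = direction,
    taxon = taxon,
    pmid = as.integer(pmid),
    use1 = use_mat[1, ],
    use2 = use_mat[2, ],
    use3 = use_mat[3, ],
    use_description = ""
  )

  planted_genes <- unlist(truth$membership, use.names = FALSE)
  eligible <- setdiff(truth$genes, planted_genes)
  n_hold <- floor(config$holdout_fraction * length(eligible))
  holdout <- if (n_hold > 0) sample(eligible, n_hold) else character()
  presence <- tibble::tibble(
    gene = truth$genes, homo = TRUE, mus = TRUE, rattus = TRUE
  )
  if (n_hold > 0) {
    col <- sample(c("homo", "mus", "rattus"), n_hold, replace = TRUE)
    for (j in seq_len(n_hold)) {
      presence[[col[j]]][match(holdout[j], presence$gene)] <- FALSE
    }
  }
  list(records = records, presence = presence)
}

#' Emit gene-set collections with planted structure
#'
#' Writes every planted set plus `n_null_sets` random sets of
#' `null_set_size` drawn uniformly from non-planted genes, so null sets
#' are disjoint from planted genes by construction (different null sets
#' may overlap each other, as real pathway collections do).
#'
#' @inheritParams gen_interactions
#' @return List with `collection` (a `gene_set_collection`) and `labels`
#'   (tibble `set_name`, `status` in planted_high/planted_low/null).
#' @export
gen_collections <- function(truth, config) {
  set.seed(substream_seed(config$seed, 3L))
  planted_genes <- unlist(truth$membership, use.names = FALSE)
  background <- setdiff(truth$genes, planted_genes)
  if (config$null_set_size > length(background)) {
    abort("not enough non-planted genes for the requested null sets")
  }
  sets <- truth$membership
  status <- paste0("planted_",
                   config$planted_sets$direction[
                     match(names(sets), config$planted_sets$name)])
  for (i in seq_len(config$n_null_sets)) {
    nm <- sprintf("NULL_SET_%02d", i)
    sets[[nm]] <- sample(background, config$null_set_size)
    status <- c(status, "null")
  }
  desc <- setNames(rep("synthetic", length(sets)), names(sets))
  list(
    collection = gene_set_collection("synthetic", sets, desc),
    labels = tibble::tibble(set_name = names(sets), status = status)
  )
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running [gen_universe()], [gen_interactions()]
#' and [gen_collections()] and optionally writing the TSV/GMT artifacts
#' plus a JSON ground-truth sidecar.
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory; when given, writes
#'   `interactions.tsv`, `gene_presence.tsv`, `gene_sets.gmt` and
#'   `ground_truth.json` into it.
#' @return List with `truth`, `records`, `presence`, `collection`,
#'   `labels`.
#' @export
generate_dataset <- function(config = generator_config(), dir = NULL) {
  truth <- gen_universe(config)
  dat <- gen_interactions(truth, config)
  coll <- gen_collections(truth, config)
  out <- list(truth = truth, records = dat$records,
              presence = dat$presence, collection = coll$collection,
              labels = coll$labels)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_interactions(dat$records, file.path(dir, "interactions.tsv"))
    readr::write_tsv(
      dplyr::mutate(dat$presence,
                    dplyr::across(c("homo", "mus", "rattus"),
                                  as.integer)),
      file.path(dir, "gene_presence.tsv"), progress = FALSE
    )
    write_gmt(coll$collection, file.path(dir, "gene_sets.gmt"))
    jsonlite::write_json(
      list(membership = truth$membership,
           planted_sets = truth$planted_sets,
           labels = coll$labels),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}
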