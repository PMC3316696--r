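#' Configuration for the subsampling and mini-barcode experiments
#'
#' Defaults follow the standard design of barcoding assessment studies:
#' taxon subsampling at 75/50/25/10% of the species with 100 random
#' subsets each, mini-barcode prefixes of 450/300/200/100 alignment
#' columns, and 1000 bootstrap replicates per tree. For desk-scale runs
#' reduce `n_subsets` and `bootstrap_reps`; the semantics are unchanged.
#'
#' @param fractions Species fractions in `(0, 1]`.
#' @param n_subsets Random subsets per fraction (>= 1).
#' @param fragment_lengths Prefix lengths in alignment columns.
#' @param bootstrap_reps Bootstrap replicates per tree.
#' @param seed Integer master seed; replicate `r` of condition `k` uses a
#'   deterministic substream seed so runs are reproducible.
#' @param model Distance model, `"k2p"` or `"p"`.
#' @param support_threshold High-support threshold, default 90.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(fractions = c(0.75, 0.50, 0.25, 0.10),
                              n_subsets = 100,
                              fragment_lengths = c(450, 300, 200, 100),
                              bootstrap_reps = 1000,
                              seed = 1,
                              model = "k2p",
                              support_threshold = 90) {
  stopifnot(all(fractions > 0), all(fractions <= 1), n_subsets >= 1,
            all(fragment_lengths >= 1), bootstrap_reps >= 1)
  structure(list(fractions = fractions, n_subsets = as.integer(n_subsets),
                 fragment_lengths = as.integer(fragment_lengths),
                 bootstrap_reps = as.integer(bootstrap_reps),
                 seed = as.integer(seed), model = model,
                 support_threshold = support_threshold),
            class = "experiment_config")
}

#' Random species subsample
#'
#' Samples `round(fraction * n_species)` species (half away from zero,
#' minimum 3) uniformly without replacement and returns the ids of all
#' their records: subsampling is at species level, keeping every
#' conspecific record of a chosen species.
#'
#' @param meta Record metadata (`meta` of a [coi_alignment()]).
#' @param fraction Fraction of species in `(0, 1]`.
#' @return Character vector of record ids.
#' @export
subsample_species <- function(meta, fraction) {
  stopifnot(fraction > 0, fraction <= 1)
  species <- unique(meta$species)
  n_take <- max(3L, as.integer(floor(fraction * length(species) + 0.5)))
  if (length(species) < 3) stop("fewer than 3 species in the dataset")
  n_take <- min(n_take, length(species))
  keep <- sample(species, n_take)
  ids <- meta$id[meta$species %in% keep]
  if (length(ids) < 3) stop("subset has fewer than 3 records")
  ids
}

#' Truncate an alignment to its first columns
#'
#' Keeps alignment columns `1..length` (the mini-barcode prefix of the
#' barcode region); metadata, frame offset and code table are preserved.
#' Records left without any non-gap base are reported in the `all_gap`
#' attribute.
#'
#' @param aln A [coi_alignment()].
#' @param length Number of columns to keep (`1 <= length <= n_columns`).
#' @return A truncated [coi_alignment()].
#' @export
truncate_alignment <- function(aln, length) {
  stopifnot(inherits(aln, "coi_alignment"))
  if (length < 1 || length > n_columns(aln)) {
    stop("length must be in 1..", n_columns(aln))
  }
  out <- coi_alignment(aln$seqs[, seq_len(length), drop = FALSE],
                       aln$meta, frame_offset = aln$frame_offset,
                       code_table = aln$code_table)
  gap <- ungapped_lengths(out) == 0
  attr(out, "all_gap") <- rownames(out$seqs)[gap]
  out
}

# Shared engine: one experiment replicate = subset/truncate -> distances
# -> NJ -> bootstrap -> genus and family scores. Returns a long-format
# data.frame or NULL on failure (logged).
run_replicate <- function(aln, condition, replicate, config, seed) {
  scores <- tryCatch({
    dmat <- distance_matrix(aln, config$model)
    tree <- neighbor_joining(dmat)
    tree <- bootstrap_support(aln, config$model, tree,
                              n_reps = config$bootstrap_reps, seed = seed)
    sc <- rbind(
      as.data.frame(score_all_groups(tree, aln$meta, "genus",
                                     config$support_threshold)),
      as.data.frame(score_all_groups(tree, aln$meta, "family",
                                     config$support_threshold)))
    sc$boot_dropped <- attr(tree, "n_dropped")
    sc
  }, error = function(e) {
    warning("replicate ", replicate, " of condition ", condition,
            " failed: ", conditionMessage(e))
    NULL
  })
  if (is.null(scores)) return(NULL)
  cbind(condition = condition, replicate = replicate, scores)
}

#' Taxon-subsampling experiment
#'
#' For every fraction and every random subset: subsample species, rebuild
#' the NJ tree with bootstrap supports, and score the monophyly and
#' support of every genus and family present in the subset. Results are a
#' long table directly comparable with the full-data scores; groups
#' reduced to a single member in a subset are marked `excluded`.
#'
#' @param aln A QC-passed [coi_alignment()].
#' @param config An [experiment_config()].
#' @return `data.frame` of class `experiment_result` with columns
#'   `condition` (fraction), `replicate`, `group`, `level`, `n_members`,
#'   `monophyletic`, `support`, `excluded` and `boot_dropped` (bootstrap
#'   replicates dropped for undefined distances).
#' @export
run_subsampling <- function(aln, config = experiment_config()) {
  stopifnot(inherits(aln, "coi_alignment"),
            inherits(config, "experiment_config"))
  out <- list()
  for (k in seq_along(config$fractions)) {
    frac <- config$fractions[k]
    for (r in seq_len(config$n_subsets)) {
      sub_seed <- config$seed + 10000L * k + r
      set.seed(sub_seed)
      ids <- subsample_species(aln$meta, frac)
      sub <- subset_records(aln, ids)
      rep_res <- run_replicate(sub, frac, r, config, seed = sub_seed)
      if (!is.null(rep_res)) out[[length(out) + 1]] <- rep_res
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("experiment_result", class(res))
  attr(res, "experiment") <- "subsampling"
  res
}

#' Mini-barcode (fragment length) experiment
#'
#' For every fragment length: truncate the alignment to its first columns,
#' rebuild the NJ tree with bootstrap supports, and score every genus and
#' family — the support-versus-length series of a mini-barcode assessment.
#' Records that become all-gap after truncation are dropped from that
#' condition and reported via the `dropped` attribute; replicates whose
#' bootstrap had undefined distances are handled as in
#' [bootstrap_support()].
#'
#' @param aln A QC-passed [coi_alignment()].
#' @param config An [experiment_config()]; `fragment_lengths` may include
#'   `n_columns(aln)` to reproduce the full-length analysis.
#' @return `data.frame` of class `experiment_result` with `condition` =
#'   fragment length.
#' @export
run_fragment_series <- function(aln, config = experiment_config()) {
  stopifnot(inherits(aln, "coi_alignment"),
            inherits(config, "experiment_config"))
  if (any(config$fragment_lengths > n_columns(aln))) {
    stop("fragment length exceeds alignment columns")
  }
  out <- list()
  dropped <- list()
  for (k in seq_along(config$fragment_lengths)) {
    len <- config$fragment_lengths[k]
    sub <- truncate_alignment(aln, len)
    gap_ids <- attr(sub, "all_gap")
    if (length(gap_ids)) {
      dropped[[as.character(len)]] <- gap_ids
      sub <- subset_records(sub, setdiff(rownames(sub$seqs), gap_ids))
    }
    rep_res <- run_replicate(sub, len, 1L, config,
                             seed = config$seed + 20000L + k)
    if (!is.null(rep_res)) out[[length(out) + 1]] <- rep_res
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("experiment_result", class(res))
  attr(res, "experiment") <- "fragment"
  attr(res, "dropped") <- dropped
  res
}

#' Per-condition summary of an experiment result
#'
#' @param result An `experiment_result` from [run_subsampling()] or
#'   [run_fragment_series()].
#' @param level `"genus"`, `"family"` or `"both"`.
#' @param support_threshold High-support threshold, default 90.
#' @return `data.frame` with one row per condition: numbers of scored,
#'   monophyletic and highly supported groups and the mean support of
#'   monophyletic groups.
#' @export
summarize_experiment <- function(result, level = "genus",
                                 support_threshold = 90) {
  x <- result
  if (level != "both") x <- x[x$level == level, , drop = FALSE]
  x <- x[!x$excluded, , drop = FALSE]
  conds <- sort(unique(x$condition))
  do.call(rbind, lapply(conds, function(cc) {
    xi <- x[x$condition == cc, , drop = FALSE]
    data.frame(condition = cc,
               n_scored = nrow(xi),
               n_monophyletic = sum(xi$monophyletic, na.rm = TRUE),
               n_high_support = sum(!is.na(xi$support) &
                                      xi$support > support_threshold),
               mean_support = mean(xi$support, na.rm = TRUE))
  }))
}

#' Species-level uniqueness of a barcode prefix
#'
#' Checks whether the first `length` alignment columns still distinguish
#' every pair of species: a collision is a pair of records from different
#' species with zero differences over their comparable sites (pairs with
#' no comparable sites at all are reported as collisions too, since they
#' cannot be told apart).
#'
#' @param aln A [coi_alignment()].
#' @param length Prefix length in columns (default 100, the mini-barcode).
#' @return `data.frame` of collision pairs (`id_a`, `id_b`, `species_a`,
#'   `species_b`, `n_comparable`); zero rows means the prefix is unique at
#'   species level. Attribute `n_pairs_checked` gives the number of
#'   heterospecific pairs examined.
#' @export
species_uniqueness <- function(aln, length = 100) {
  stopifnot(inherits(aln, "coi_alignment"))
  sub <- truncate_alignment(aln, length)
  counts <- pair_counts_cpp(encode_dna(sub$seqs))
  ids <- rownames(sub$seqs)
  sp <- sub$meta$species[match(ids, sub$meta$id)]
  idx <- which(upper.tri(counts$comparable), arr.ind = TRUE)
  hetero <- sp[idx[, 1]] != sp[idx[, 2]]
  idx <- idx[hetero, , drop = FALSE]
  ndiff <- counts$transitions[idx] + counts$transversions[idx]
  collide <- ndiff == 0
  res <- data.frame(id_a = ids[idx[collide, 1]],
                    id_b = ids[idx[collide, 2]],
                    species_a = sp[idx[collide, 1]],
                    species_b = sp[idx[collide, 2]],
                    n_comparable = counts$comparable[idx[collide, ,
                                                         drop = FALSE]],
                    stringsAsFactors = FALSE)
  attr(res, "n_pairs_checked") <- nrow(idx)
  res
}
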