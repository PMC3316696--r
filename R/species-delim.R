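#' Mean interspecific divergence within a family
#'
#' Unweighted mean of all between-species pairwise distances among the
#' family's nominal species, each species represented by a single
#' reference record (the first record of the species when several exist).
#' Undefined (saturated) pairs are excluded with a warning.
#'
#' @param aln A [coi_alignment()].
#' @param family Family name.
#' @param dmat_k2p,dmat_p Optional precomputed [distance_matrix()] results;
#'   computed from `aln` when `NULL`.
#' @return Named numeric vector `c(mean_k2p = , mean_p = )`.
#' @export
mean_interspecific_divergence <- function(aln, family, dmat_k2p = NULL,
                                          dmat_p = NULL) {
  stopifnot(inherits(aln, "coi_alignment"))
  refs <- reference_records(aln$meta)
  fam_refs <- refs[refs$family == family, , drop = FALSE]
  if (nrow(fam_refs) < 2) {
    stop("family '", family, "' has fewer than 2 nominal reference species")
  }
  if (is.null(dmat_k2p)) dmat_k2p <- distance_matrix(aln, "k2p")
  if (is.null(dmat_p)) dmat_p <- distance_matrix(aln, "p")
  ids <- fam_refs$id
  mean_of <- function(dmat) {
    d <- dmat$d[ids, ids][upper.tri(diag(length(ids)))]
    if (anyNA(d)) {
      warning(sum(is.na(d)), " undefined pair(s) excluded from mean (",
              family, ")")
    }
    mean(d, na.rm = TRUE)
  }
  c(mean_k2p = mean_of(dmat_k2p), mean_p = mean_of(dmat_p))
}

# One reference record per nominal species: the first record of each
# species in alignment order (in practice most species are represented by
# a single voucher).
reference_records <- function(meta) {
  nom <- meta[meta$status == "nominal", , drop = FALSE]
  nom[!duplicated(nom$species), , drop = FALSE]
}

#' Well-supported sister-species pairs
#'
#' A pair of species qualifies when their records form a two-leaf cherry
#' in the tree whose edge support exceeds `min_support` (default ">70%"
#' bootstrap), both records belong to nominal species of the same family,
#' and the species differ. Distances are taken from the pairwise matrices.
#'
#' @param tree A `phylo` tree with bootstrap supports as node labels (see
#'   [bootstrap_support()]).
#' @param meta Record metadata (`meta` of a [coi_alignment()]).
#' @param dmat_k2p,dmat_p [distance_matrix()] results over the records.
#' @param min_support Minimum (exclusive) bootstrap support, default 70.
#' @return `data.frame` with columns `species_a`, `species_b`, `id_a`,
#'   `id_b`, `family`, `support`, `distance_k2p`, `distance_p`.
#' @export
find_sister_pairs <- function(tree, meta, dmat_k2p, dmat_p,
                              min_support = 70) {
  n <- length(tree$tip.label)
  supports <- node_supports(tree)
  out <- list()
  # cherries: internal nodes whose children are exactly two leaves
  children <- split(tree$edge[, 2], tree$edge[, 1])
  for (node in names(children)) {
    ch <- children[[node]]
    if (length(ch) != 2 || any(ch > n)) next
    supp <- supports[as.integer(node) - n]
    if (is.na(supp) || supp <= min_support) next
    ids <- tree$tip.label[ch]
    m <- meta[match(ids, meta$id), , drop = FALSE]
    if (any(m$status != "nominal")) next
    if (m$family[1] != m$family[2]) next
    if (m$species[1] == m$species[2]) next
    ord <- order(m$species)
    out[[length(out) + 1]] <- data.frame(
      species_a = m$species[ord[1]], species_b = m$species[ord[2]],
      id_a = m$id[ord[1]], id_b = m$id[ord[2]],
      family = m$family[1], support = supp,
      distance_k2p = dmat_k2p$d[ids[1], ids[2]],
      distance_p = dmat_p$d[ids[1], ids[2]],
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(species_a = character(), species_b = character(),
                      id_a = character(), id_b = character(),
                      family = character(), support = numeric(),
                      distance_k2p = numeric(), distance_p = numeric(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$family, res$species_a), , drop = FALSE]
}

#' Family-specific divergence thresholds from sister pairs
#'
#' The threshold of a family is the arithmetic mean of the distances of
#' its well-supported sister-species pairs (K2p and p separately).
#' Families with no qualifying pair get no threshold and are reported with
#' `n_pairs = 0` and `NA` thresholds.
#'
#' @param pairs Output of [find_sister_pairs()].
#' @param families Optional character vector of families that must appear
#'   in the table even without pairs.
#' @return `data.frame` with columns `family`, `n_pairs`,
#'   `threshold_k2p`, `threshold_p`.
#' @export
build_threshold_table <- function(pairs, families = NULL) {
  fams <- sort(unique(c(pairs$family, families)))
  if (!length(fams)) {
    warning("no sister pairs: empty threshold table")
  }
  res <- data.frame(family = fams,
                    n_pairs = rep(0L, length(fams)),
                    threshold_k2p = rep(NA_real_, length(fams)),
                    threshold_p = rep(NA_real_, length(fams)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(fams)) {
    p <- pairs[pairs$family == fams[i], , drop = FALSE]
    res$n_pairs[i] <- nrow(p)
    if (nrow(p)) {
      res$threshold_k2p[i] <- mean(p$distance_k2p)
      res$threshold_p[i] <- mean(p$distance_p)
    }
  }
  res
}

#' Cluster unidentified records into candidate lineages
#'
#' Candidate and unidentified records of each family are grouped into
#' lineages by single-linkage: two records join the same lineage when
#' their distance is below the family threshold. A lineage's
#' nearest-nominal distance is the minimum distance from any member to any
#' nominal-species record in the whole dataset, and the lineage is flagged
#' as a candidate species when that distance exceeds the family threshold.
#' Records in families without a threshold are returned in the
#' `unresolved` attribute rather than silently dropped.
#'
#' @param dmat A [distance_matrix()] result (model chooses which threshold
#'   column is used: `threshold_k2p` or `threshold_p`).
#' @param meta Record metadata.
#' @param thresholds A [build_threshold_table()] result.
#' @return `data.frame` with one row per lineage: `lineage_id`, `members`
#'   (semicolon-joined ids), `family`, `nearest_nominal`, `nn_distance`,
#'   `threshold_used`, `flagged`; attribute `unresolved` holds ids in
#'   families without thresholds.
#' @export
cluster_unidentified <- function(dmat, meta, thresholds) {
  stopifnot(inherits(dmat, "coi_dist"))
  thr_col <- if (dmat$model == "k2p") "threshold_k2p" else "threshold_p"
  cand <- meta[meta$status %in% c("candidate", "unidentified"), ,
               drop = FALSE]
  nominal_ids <- meta$id[meta$status == "nominal"]
  out <- list()
  unresolved <- character()
  for (fam in sort(unique(cand$family))) {
    thr <- thresholds[[thr_col]][thresholds$family == fam]
    ids <- cand$id[cand$family == fam]
    if (!length(thr) || is.na(thr)) {
      unresolved <- c(unresolved, ids)
      next
    }
    groups <- single_linkage_groups(dmat$d[ids, ids, drop = FALSE], thr)
    for (g in groups) {
      members <- ids[g]
      sub <- dmat$d[members, nominal_ids, drop = FALSE]
      if (all(is.na(sub))) {
        nn_d <- Inf
        nn_id <- NA_character_
      } else {
        nn_d <- min(sub, na.rm = TRUE)
        w <- which(sub == nn_d, arr.ind = TRUE)[1, ]
        nn_id <- nominal_ids[w[2]]
      }
      out[[length(out) + 1]] <- data.frame(
        members = paste(sort(members), collapse = ";"),
        family = fam,
        nearest_nominal = if (is.na(nn_id)) NA_character_ else
          meta$species[meta$id == nn_id],
        nn_distance = nn_d,
        threshold_used = thr,
        flagged = nn_d > thr,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) {
    res <- do.call(rbind, out)
    res <- res[order(res$family, res$members), , drop = FALSE]
    res <- cbind(lineage_id = sprintf("L%03d", seq_len(nrow(res))), res)
    rownames(res) <- NULL
  } else {
    res <- data.frame(lineage_id = character(), members = character(),
                      family = character(), nearest_nominal = character(),
                      nn_distance = numeric(), threshold_used = numeric(),
                      flagged = logical(), stringsAsFactors = FALSE)
  }
  attr(res, "unresolved") <- unresolved
  attr(res, "model") <- dmat$model
  res
}

# Single-linkage groups: union-find over pairs with distance strictly
# below the threshold. NA distances never merge. Returns a list of integer
# index vectors.
single_linkage_groups <- function(d, threshold) {
  n <- nrow(d)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq.int(i + 1, n)) {
        if (!is.na(d[i, j]) && d[i, j] < threshold) {
          parent[find(j)] <- find(i)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

#' Count candidate species across the two distance models
#'
#' The minimum count is the number of lineages flagged under both the K2p
#' and the p thresholds; the maximum is the number flagged under at least
#' one. Lineages are matched across models by their member sets.
#'
#' @param lineages_k2p,lineages_p [cluster_unidentified()] results under
#'   the two models.
#' @return List with `min_count`, `max_count` and `per_family`
#'   (`data.frame`: family, min, max).
#' @export
candidate_count <- function(lineages_k2p, lineages_p) {
  keys <- union(lineages_k2p$members, lineages_p$members)
  fam_of <- c(setNames(lineages_k2p$family, lineages_k2p$members),
              setNames(lineages_p$family, lineages_p$members))
  f_k <- setNames(lineages_k2p$flagged, lineages_k2p$members)
  f_p <- setNames(lineages_p$flagged, lineages_p$members)
  both <- vapply(keys, function(k) {
    isTRUE(f_k[k]) && isTRUE(f_p[k])
  }, logical(1))
  any1 <- vapply(keys, function(k) {
    isTRUE(f_k[k]) || isTRUE(f_p[k])
  }, logical(1))
  fams <- sort(unique(unname(fam_of[keys])))
  per_family <- data.frame(
    family = fams,
    min = vapply(fams, function(f) sum(both[fam_of[keys] == f]), 0L),
    max = vapply(fams, function(f) sum(any1[fam_of[keys] == f]), 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  list(min_count = sum(both), max_count = sum(any1),
       per_family = per_family)
}
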