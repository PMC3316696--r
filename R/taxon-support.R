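#' Monophyly and support of a named group on an unrooted tree
#'
#' A group is monophyletic when its leaf set is one side of some
#' bipartition of the unrooted tree (the convexity criterion — equivalent
#' to rooted monophyly for any root placed outside the group, and
#' invariant to rerooting). The support returned is the bootstrap value of
#' the subtending edge, `NA` when the group is not monophyletic, covers
#' all leaves, or its edge carries no support (e.g. a pendant edge for a
#' group of all-but-one leaves).
#'
#' @param tree A `phylo` tree, optionally with supports as node labels.
#' @param leafset Character vector of >= 2 leaf labels.
#' @return List with elements `monophyletic` (logical) and `support`
#'   (numeric or `NA`).
#' @export
group_monophyly <- function(tree, leafset) {
  tips <- tree$tip.label
  extra <- setdiff(leafset, tips)
  if (length(extra)) {
    stop("leafset not a subset of tree leaves: ",
         paste(extra, collapse = ", "))
  }
  if (length(leafset) < 2) stop("leafset must contain at least 2 leaves")
  leafset <- sort(unique(leafset))
  n <- length(tips)
  if (length(leafset) == n) {
    return(list(monophyletic = TRUE, support = NA_real_))
  }
  if (length(leafset) == n - 1) {
    # complement is a single leaf: trivially a split; pendant edges carry
    # no bootstrap support
    return(list(monophyletic = TRUE, support = NA_real_))
  }
  sets <- clade_tip_sets(tree)
  supports <- node_supports(tree)
  ntip <- n
  comp <- sort(setdiff(tips, leafset))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (identical(s, leafset) || identical(s, comp)) {
      node <- as.integer(names(sets)[i])
      return(list(monophyletic = TRUE,
                  support = supports[node - ntip]))
    }
  }
  list(monophyletic = FALSE, support = NA_real_)
}

#' Score monophyly of all genera or families on a tree
#'
#' One row per distinct group at the requested taxonomic level. Groups
#' with a single member cannot be scored for monophyly and are marked
#' `excluded`. A summary attribute counts monophyletic groups and groups
#' supported above `support_threshold`.
#'
#' @param tree A `phylo` tree with supports as node labels.
#' @param taxonomy `data.frame` with columns `id`, `genus`, `family`
#'   covering all tree leaves (e.g. the `meta` of a [coi_alignment()]).
#' @param level `"genus"` or `"family"`.
#' @param support_threshold Support above which a group counts as well
#'   supported (default 90, i.e. ">90%").
#' @return `data.frame` of class `group_scores` with columns `group`,
#'   `level`, `n_members`, `monophyletic`, `support`, `excluded`, and
#'   attribute `summary`.
#' @export
score_all_groups <- function(tree, taxonomy, level = c("genus", "family"),
                             support_threshold = 90) {
  level <- match.arg(level)
  tips <- tree$tip.label
  tax <- taxonomy[match(tips, taxonomy$id), , drop = FALSE]
  if (anyNA(tax$id)) {
    stop("taxonomy does not cover leaves: ",
         paste(utils::head(tips[is.na(tax$id)], 5), collapse = ", "))
  }
  groups <- split(tips, tax[[level]])
  res <- data.frame(group = names(groups),
                    level = level,
                    n_members = lengths(groups),
                    monophyletic = NA,
                    support = NA_real_,
                    excluded = lengths(groups) < 2,
                    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  for (i in seq_len(nrow(res))) {
    if (res$excluded[i]) next
    gm <- group_monophyly(tree, groups[[res$group[i]]])
    res$monophyletic[i] <- gm$monophyletic
    res$support[i] <- gm$support
  }
  scored <- !res$excluded
  attr(res, "summary") <- list(
    n_groups = nrow(res),
    n_scored = sum(scored),
    n_monophyletic = sum(res$monophyletic[scored], na.rm = TRUE),
    n_high_support = sum(scored & !is.na(res$support) &
                           res$support > support_threshold),
    support_threshold = support_threshold)
  class(res) <- c("group_scores", class(res))
  res
}

#' @export
print.group_scores <- function(x, ...) {
  s <- attr(x, "summary")
  cat(sprintf(
    "%s-level groups: %d total, %d scored, %d monophyletic, %d with support > %g\n",
    x$level[1], s$n_groups, s$n_scored, s$n_monophyletic,
    s$n_high_support, s$support_threshold))
  print.data.frame(x, ...)
  invisible(x)
}

#' Monophyly of reference genera across a set of trees
#'
#' For each genus in `genus_list`, the fraction of trees in which the
#' genus is monophyletic with support at or above `support_threshold`.
#' Trees where a genus has fewer than 2 leaves are skipped for that genus.
#' Used to summarise how reliably known-monophyletic genera are recovered
#' in subsampling experiments.
#'
#' @param trees List of `phylo` trees with supports.
#' @param taxonomy `data.frame` with columns `id`, `genus` (see
#'   [score_all_groups()]).
#' @param genus_list Character vector of genus names.
#' @param support_threshold Minimum support, default 90.
#' @return List with `per_genus` (`data.frame`: genus, n_trees_scored,
#'   n_confirmed, fraction) and `pooled` (overall fraction).
#' @export
reference_genus_check <- function(trees, taxonomy, genus_list,
                                  support_threshold = 90) {
  if (!length(genus_list)) stop("genus_list must be non-empty")
  if (inherits(trees, "phylo")) trees <- list(trees)
  res <- lapply(genus_list, function(g) {
    ids <- taxonomy$id[taxonomy$genus == g]
    scored <- 0L
    confirmed <- 0L
    for (tr in trees) {
      members <- intersect(ids, tr$tip.label)
      if (length(members) < 2) next
      gm <- group_monophyly(tr, members)
      scored <- scored + 1L
      if (gm$monophyletic && !is.na(gm$support) &&
          gm$support >= support_threshold) {
        confirmed <- confirmed + 1L
      }
    }
    c(scored = scored, confirmed = confirmed)
  })
  per_genus <- data.frame(
    genus = genus_list,
    n_trees_scored = vapply(res, `[[`, integer(1), "scored"),
    n_confirmed = vapply(res, `[[`, integer(1), "confirmed"),
    stringsAsFactors = FALSE)
  per_genus$fraction <- ifelse(per_genus$n_trees_scored > 0,
                               per_genus$n_confirmed /
                                 per_genus$n_trees_scored, NA)
  pooled <- sum(per_genus$n_confirmed) / max(sum(per_genus$n_trees_scored), 1)
  list(per_genus = per_genus, pooled = pooled)
}
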