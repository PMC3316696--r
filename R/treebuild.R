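#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration with the Studier-Keppler Q criterion.
#' Fully deterministic: ties in Q break to the smallest pair of positions
#' in the current label order, and the joined node takes the position of
#' the first member. Negative branch lengths are clamped to zero (the
#' difference is not redistributed, so the topology is unaffected). The
#' result is unrooted (trifurcating base node).
#'
#' @param dmat A [distance_matrix()] result, or a symmetric numeric matrix
#'   with dimnames.
#' @return An unrooted `phylo` tree (class from \pkg{ape}).
#' @export
neighbor_joining <- function(dmat) {
  if (inherits(dmat, "coi_dist")) {
    d <- dmat$d
  } else if (is.matrix(dmat)) {
    d <- dmat
  } else {
    stop("dmat must be a coi_dist object or a numeric matrix")
  }
  labels <- rownames(d)
  if (is.null(labels)) stop("distance matrix must have row names")
  if (nrow(d) < 3) stop("neighbor joining needs at least 3 labels")
  if (anyNA(d)) {
    idx <- which(is.na(d) & upper.tri(d), arr.ind = TRUE)
    pairs <- paste(labels[idx[, 1]], labels[idx[, 2]], sep = "--")
    stop("undefined distance for pair(s): ",
         paste(utils::head(pairs, 5), collapse = ", "),
         if (length(pairs) > 5) sprintf(" (and %d more)",
                                        length(pairs) - 5) else "")
  }
  nwk <- nj_newick_cpp(d, labels)
  ape::read.tree(text = nwk)
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One bipartition per internal edge: the two complementary leaf sets
#' induced by removing the edge. Trivial splits (one side a single leaf)
#' are excluded. Each bipartition is returned with the side containing the
#' lexicographically smallest leaf label first.
#'
#' @param tree A `phylo` tree.
#' @return List of bipartitions, each a list with elements `a` and `b`
#'   (character vectors of sorted leaf labels, `a` contains the smallest
#'   label).
#' @export
bipartitions <- function(tree) {
  sets <- clade_tip_sets(tree)
  tips <- sort(tree$tip.label)
  n <- length(tips)
  out <- list()
  for (s in sets) {
    if (length(s) < 2 || length(s) > n - 2) next
    comp <- setdiff(tips, s)
    side_a <- if (tips[1] %in% s) s else comp
    side_b <- if (tips[1] %in% s) comp else s
    out[[length(out) + 1]] <- list(a = side_a, b = side_b)
  }
  keys <- vapply(out, function(bp) paste(bp$b, collapse = "\r"), "")
  out[!duplicated(keys)]
}

# Sorted tip-label set below each internal (non-root) node, named by node
# number. Computed by postorder accumulation.
clade_tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]
    ch <- po$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  root <- n + 1L
  nodes <- setdiff(seq.int(n + 1L, n + tree$Nnode), root)
  sets <- lapply(desc[nodes], sort)
  names(sets) <- nodes
  sets
}

# Canonical string key of a split given the full (sorted) leaf set: the
# sorted side NOT containing the smallest leaf, pasted. Used for bootstrap
# counting and support lookup. Trivial splits yield NA.
split_keys <- function(tree, all_tips = sort(tree$tip.label)) {
  sets <- clade_tip_sets(tree)
  n <- length(all_tips)
  keys <- vapply(sets, function(s) {
    side <- if (all_tips[1] %in% s) setdiff(all_tips, s) else s
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    paste(side, collapse = "\r")
  }, "")
  keys
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Felsenstein nonparametric bootstrap: alignment columns are resampled
#' with replacement `n_reps` times; for every replicate the distance
#' matrix and NJ tree are rebuilt, and the support of each internal edge of
#' the reference tree is the percentage of replicate trees containing the
#' same bipartition. Replicates whose distance matrix contains undefined
#' entries are dropped and counted; more than 10% dropped is an error.
#'
#' @param aln A [coi_alignment()].
#' @param model Distance model, `"k2p"` or `"p"`.
#' @param reference_tree Optional reference `phylo`; defaults to the NJ
#'   tree of the full alignment.
#' @param n_reps Number of bootstrap replicates (>= 1); 1000 in a full
#'   analysis, 100 is plenty for desk-scale experiments.
#' @param seed Integer seed; identical seeds give identical supports.
#' @return The reference tree with internal node labels set to support
#'   values (0-100, one decimal; the base node label is empty), plus
#'   attributes `n_used` and `n_dropped`.
#' @export
bootstrap_support <- function(aln, model = "k2p", reference_tree = NULL,
                              n_reps = 1000, seed = 1) {
  stopifnot(inherits(aln, "coi_alignment"))
  if (n_reps < 1) stop("n_reps must be >= 1")
  if (is.null(reference_tree)) {
    reference_tree <- neighbor_joining(distance_matrix(aln, model))
  }
  if (!setequal(reference_tree$tip.label, rownames(aln$seqs))) {
    stop("reference tree leaves do not match alignment records")
  }
  enc <- encode_dna(aln$seqs)
  labels <- rownames(aln$seqs)
  all_tips <- sort(labels)
  L <- ncol(enc)
  set.seed(as.integer(seed))
  counts <- new.env(parent = emptyenv())
  n_used <- 0L
  n_dropped <- 0L
  for (r in seq_len(n_reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    pc <- pair_counts_cpp(enc[, cols, drop = FALSE])
    d <- dist_from_counts(pc$comparable, pc$transitions,
                          pc$transversions, model)
    if (anyNA(d)) {
      n_dropped <- n_dropped + 1L
      next
    }
    dimnames(d) <- list(labels, labels)
    tr <- ape::read.tree(text = nj_newick_cpp(d, labels))
    ks <- unique(split_keys(tr, all_tips))
    for (k in ks[!is.na(ks)]) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
    n_used <- n_used + 1L
  }
  if (n_dropped > 0.1 * n_reps) {
    stop(n_dropped, "/", n_reps,
         " bootstrap replicates had undefined distances")
  }
  ref_keys <- split_keys(reference_tree, all_tips)
  supp <- vapply(ref_keys, function(k) {
    if (is.na(k)) return(NA_real_)
    cnt <- counts[[k]]
    if (is.null(cnt)) 0 else 100 * cnt / n_used
  }, numeric(1))
  n <- length(reference_tree$tip.label)
  node_lab <- rep("", reference_tree$Nnode)
  idx <- as.integer(names(ref_keys)) - n
  node_lab[idx] <- ifelse(is.na(supp), "", as.character(round(supp, 1)))
  out <- reference_tree
  out$node.label <- node_lab
  attr(out, "n_used") <- n_used
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Read / write trees in newick format
#'
#' Thin wrappers over \pkg{ape}'s newick I/O; bootstrap supports travel as
#' internal node labels. Round-trips preserve topology, branch lengths and
#' supports.
#'
#' @param tree A `phylo` tree.
#' @param path File path.
#' @return `write_newick()` returns `tree` invisibly; `read_newick()`
#'   returns a `phylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(tree)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  if (!nzchar(trimws(txt))) stop("empty newick file: ", path)
  tr <- tryCatch(ape::read.tree(text = txt),
                 error = function(e) stop("newick parse error in ", path,
                                          ": ", conditionMessage(e)))
  if (is.null(tr)) stop("newick parse error in ", path)
  tr
}

# Numeric support of the edge above each internal node (NA where no label).
node_supports <- function(tree) {
  if (is.null(tree$node.label)) {
    return(rep(NA_real_, tree$Nnode))
  }
  suppressWarnings(as.numeric(tree$node.label))
}
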