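#' Pairwise site counts between two aligned sequences
#'
#' Counts comparable sites (both sequences have an unambiguous A/C/G/T —
#' pairwise deletion of gaps and ambiguity codes), transitions (A<->G,
#' C<->T) and transversions (all other mismatches). These are the
#' sufficient statistics for both the p and the Kimura 2-parameter
#' distance.
#'
#' @param seq_a,seq_b Equal-length character vectors (one element per
#'   column) or single strings.
#' @return A list with integer elements `comparable`, `transitions`,
#'   `transversions`.
#' @export
#' @examples
#' site_counts("ACGT", "GCGA")
site_counts <- function(seq_a, seq_b) {
  if (length(seq_a) == 1 && nchar(seq_a) > 1) {
    seq_a <- strsplit(seq_a, "")[[1]]
  }
  if (length(seq_b) == 1 && nchar(seq_b) > 1) {
    seq_b <- strsplit(seq_b, "")[[1]]
  }
  if (length(seq_a) != length(seq_b)) {
    stop("sequences have unequal lengths (", length(seq_a), " vs ",
         length(seq_b), ")")
  }
  a <- toupper(seq_a)
  b <- toupper(seq_b)
  nuc <- c("A", "C", "G", "T")
  ok <- a %in% nuc & b %in% nuc
  a <- a[ok]
  b <- b[ok]
  diff <- a != b
  purine <- c("A", "G")
  ts <- diff & ((a %in% purine) == (b %in% purine))
  list(comparable = sum(ok),
       transitions = sum(ts),
       transversions = sum(diff & !ts))
}

#' p distance from site counts
#'
#' Raw proportion of differing sites among comparable sites.
#'
#' @param counts A [site_counts()] result.
#' @return Numeric in `[0, 1]`.
#' @export
p_distance <- function(counts) {
  if (counts$comparable == 0) {
    stop("no comparable sites: p distance undefined")
  }
  (counts$transitions + counts$transversions) / counts$comparable
}

#' Kimura 2-parameter distance from site counts
#'
#' Evaluates `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)` with `P` and `Q`
#' the transition and transversion proportions. When either logarithm
#' argument is non-positive the distance is undefined (substitution
#' saturation) and `NA` is returned.
#'
#' @param counts A [site_counts()] result.
#' @return Numeric distance, or `NA` when undefined.
#' @export
#' @examples
#' k2p_distance(list(comparable = 100, transitions = 10, transversions = 5))
k2p_distance <- function(counts) {
  if (counts$comparable == 0) {
    stop("no comparable sites: K2p distance undefined")
  }
  P <- counts$transitions / counts$comparable
  Q <- counts$transversions / counts$comparable
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(NA_real_)
  -0.5 * log(w1) - 0.25 * log(w2)
}

#' Full pairwise distance matrix of an alignment
#'
#' Computes all pairwise p or K2p distances under pairwise deletion.
#' Saturated pairs (K2p undefined) are stored as `NA` and counted; a
#' warning reports how many. Pairs with zero comparable sites are also
#' `NA`.
#'
#' @param aln A [coi_alignment()].
#' @param model `"k2p"` or `"p"`.
#' @return An object of class `coi_dist`: list with `d` (symmetric numeric
#'   matrix, zero diagonal, dimnames = record ids), `labels`, `model`,
#'   `n_undefined` and the raw count matrices `comparable`, `transitions`,
#'   `transversions`.
#' @export
distance_matrix <- function(aln, model = c("k2p", "p")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "coi_alignment"))
  if (n_records(aln) < 2) stop("need at least 2 records")
  counts <- pair_counts_cpp(encode_dna(aln$seqs))
  d <- dist_from_counts(counts$comparable, counts$transitions,
                        counts$transversions, model)
  labels <- rownames(aln$seqs)
  dimnames(d) <- list(labels, labels)
  n_undef <- sum(is.na(d[upper.tri(d)]))
  if (n_undef > 0) {
    warning(n_undef, " pair(s) with undefined ", model, " distance")
  }
  structure(list(d = d, labels = labels, model = model,
                 n_undefined = n_undef,
                 comparable = counts$comparable,
                 transitions = counts$transitions,
                 transversions = counts$transversions),
            class = "coi_dist")
}

# Vectorised distance transform on count matrices.
dist_from_counts <- function(comp, ts, tv, model) {
  n <- nrow(comp)
  with_pairs <- comp > 0
  if (model == "p") {
    d <- ifelse(with_pairs, (ts + tv) / pmax(comp, 1), NA_real_)
  } else {
    P <- ts / pmax(comp, 1)
    Q <- tv / pmax(comp, 1)
    w1 <- 1 - 2 * P - Q
    w2 <- 1 - 2 * Q
    d <- ifelse(with_pairs & w1 > 0 & w2 > 0,
                -0.5 * log(pmax(w1, .Machine$double.xmin)) -
                  0.25 * log(pmax(w2, .Machine$double.xmin)),
                NA_real_)
  }
  dim(d) <- c(n, n)
  diag(d) <- 0
  d
}

#' @export
print.coi_dist <- function(x, ...) {
  cat("Pairwise ", x$model, " distances: ", length(x$labels),
      " records", sep = "")
  if (x$n_undefined > 0) cat(", ", x$n_undefined, " undefined pair(s)",
                             sep = "")
  dd <- x$d[upper.tri(x$d)]
  if (any(!is.na(dd))) {
    cat(sprintf("\n  range %.1f%% - %.1f%%, mean %.1f%%",
                100 * min(dd, na.rm = TRUE), 100 * max(dd, na.rm = TRUE),
                100 * mean(dd, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Saturation-plot table
#'
#' One row per unordered pair with transition proportion `P`, transversion
#' proportion `Q` and the K2p distance — the data behind the classic
#' transitions/transversions-versus-divergence saturation plot. Pairs with
#' undefined K2p are kept with `k2p = NA` so that saturation is visible.
#'
#' @param aln A [coi_alignment()].
#' @return `data.frame` with columns `id_a`, `id_b`, `k2p`, `P`, `Q`.
#' @export
saturation_table <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  if (n_records(aln) < 2) stop("need at least 2 records")
  counts <- pair_counts_cpp(encode_dna(aln$seqs))
  labels <- rownames(aln$seqs)
  idx <- which(upper.tri(counts$comparable), arr.ind = TRUE)
  comp <- counts$comparable[idx]
  P <- ifelse(comp > 0, counts$transitions[idx] / pmax(comp, 1), NA)
  Q <- ifelse(comp > 0, counts$transversions[idx] / pmax(comp, 1), NA)
  k2p <- dist_from_counts(counts$comparable, counts$transitions,
                          counts$transversions, "k2p")[idx]
  data.frame(id_a = labels[idx[, 1]], id_b = labels[idx[, 2]],
             k2p = k2p, P = P, Q = Q, stringsAsFactors = FALSE)
}
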