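#' Length filter for barcode reads
#'
#' A record passes if it carries at least `min_length` non-gap nucleotide
#' characters — by default 600 bp, i.e. 90% of the standard 664-bp barcode
#' region, the usual yardstick for a high-quality barcode read.
#'
#' @param aln A [coi_alignment()].
#' @param min_length Minimum number of non-gap characters (>= 1).
#' @return Logical vector, `TRUE` = passed, named by record id.
#' @export
length_filter <- function(aln, min_length = 600) {
  stopifnot(inherits(aln, "coi_alignment"), min_length >= 1)
  setNames(ungapped_lengths(aln) >= min_length, rownames(aln$seqs))
}

#' Detect the reading frame of an aligned coding region
#'
#' Returns the 0-based column offset (0, 1 or 2) at which complete codons
#' start, chosen as the offset minimising the total number of internal
#' in-frame stop codons across all records under the alignment's genetic
#' code. Ties break to the smallest offset. Codons containing gaps or
#' ambiguity codes are skipped; the last complete codon window is excluded
#' (a terminal stop is legitimate).
#'
#' @param aln A [coi_alignment()].
#' @return Integer offset in `0:2`.
#' @export
detect_frame <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  if (n_records(aln) < 1) stop("empty alignment")
  counts <- vapply(0:2, function(off) {
    sum(internal_stop_counts(aln$seqs, off, aln$code_table))
  }, numeric(1))
  as.integer(which.min(counts) - 1L)
}

# Per-record count of internal in-frame stop codons at a given 0-based
# offset. The terminal complete codon window is excluded.
internal_stop_counts <- function(seqs, offset, code_table) {
  L <- ncol(seqs)
  n_codons <- (L - offset) %/% 3
  if (n_codons < 2) return(setNames(rep(0, nrow(seqs)), rownames(seqs)))
  stops <- stop_codons(code_table)
  internal <- seq_len(n_codons - 1)  # exclude terminal codon
  starts <- offset + (internal - 1) * 3 + 1
  out <- setNames(rep(0, nrow(seqs)), rownames(seqs))
  for (s in starts) {
    cod <- seqs[, s:(s + 2), drop = FALSE]
    complete <- cod[, 1] %in% c("A", "C", "G", "T") &
      cod[, 2] %in% c("A", "C", "G", "T") &
      cod[, 3] %in% c("A", "C", "G", "T")
    triplet <- paste0(cod[, 1], cod[, 2], cod[, 3])
    out <- out + (complete & triplet %in% stops)
  }
  out
}

#' Internal stop codon filter
#'
#' Flags records containing at least one in-frame stop codon before the
#' terminal codon under the alignment's genetic code — the classic signal
#' of a nuclear mitochondrial pseudogene (NUMT) or a sequencing artefact in
#' a protein-coding barcode. Codons containing gaps or ambiguity codes
#' cannot be called stops and are skipped.
#'
#' @param aln A [coi_alignment()] with its `frame_offset` set (see
#'   [detect_frame()]).
#' @return Logical vector, `TRUE` = passed (no internal stop), named by id.
#' @export
stop_codon_filter <- function(aln) {
  stopifnot(inherits(aln, "coi_alignment"))
  n_stops <- internal_stop_counts(aln$seqs, aln$frame_offset,
                                  aln$code_table)
  n_stops == 0
}

#' Divergence outlier filter
#'
#' Flags records whose minimum distance to every other record exceeds
#' `cutoff` — sequences "suspiciously divergent" from everything else in
#' the library, another NUMT/contamination signal. Undefined (saturated)
#' distances are treated as exceeding any finite cutoff; a record with only
#' undefined distances is flagged.
#'
#' @param aln A [coi_alignment()].
#' @param dmat A [distance_matrix()] over the same records (K2p
#'   recommended).
#' @param cutoff Distance cutoff, default 0.35 K2p.
#' @return Logical vector, `TRUE` = passed, named by id.
#' @export
divergence_outlier_filter <- function(aln, dmat, cutoff = 0.35) {
  stopifnot(inherits(aln, "coi_alignment"), inherits(dmat, "coi_dist"),
            cutoff > 0)
  if (n_records(aln) < 2) stop("outlier filter needs at least 2 records")
  ids <- rownames(aln$seqs)
  if (!setequal(ids, dmat$labels)) {
    stop("distance matrix labels do not match alignment records")
  }
  d <- dmat$d[ids, ids, drop = FALSE]
  diag(d) <- NA
  min_d <- apply(d, 1, function(x) {
    if (all(is.na(x))) Inf else min(x, na.rm = TRUE)
  })
  setNames(min_d <= cutoff, ids)
}

#' Run the full sequence quality control
#'
#' Applies the three QC screens in order: minimum read length, internal
#' stop codons (after frame detection when `detect = TRUE`) and divergence
#' outliers (computed on records passing the first two screens). Every
#' record gets a row with all the reasons it failed.
#'
#' @param aln A [coi_alignment()].
#' @param min_length Minimum non-gap length, default 600.
#' @param outlier_cutoff K2p cutoff for the outlier screen, default 0.35;
#'   `NULL` skips the screen.
#' @param detect_frame Re-detect the reading frame before the stop screen.
#' @return A `data.frame` of class `coi_qc` with columns `id`, `passed`
#'   and a list-column `reasons` (subset of `too_short`, `internal_stop`,
#'   `divergence_outlier`).
#' @export
qc_report <- function(aln, min_length = 600, outlier_cutoff = 0.35,
                      detect_frame = TRUE) {
  stopifnot(inherits(aln, "coi_alignment"))
  ids <- rownames(aln$seqs)
  reasons <- setNames(vector("list", length(ids)), ids)

  len_ok <- length_filter(aln, min_length)
  for (id in ids[!len_ok]) reasons[[id]] <- c(reasons[[id]], "too_short")

  if (detect_frame && any(len_ok)) {
    sub <- subset_records(aln, ids[len_ok])
    aln$frame_offset <- detect_frame(sub)
  }
  stop_ok <- stop_codon_filter(aln)
  for (id in ids[!stop_ok]) {
    reasons[[id]] <- c(reasons[[id]], "internal_stop")
  }

  pass12 <- len_ok & stop_ok
  if (!is.null(outlier_cutoff) && sum(pass12) >= 2) {
    sub <- subset_records(aln, ids[pass12])
    dmat <- distance_matrix(sub, model = "k2p")
    out_ok <- divergence_outlier_filter(sub, dmat, outlier_cutoff)
    for (id in names(out_ok)[!out_ok]) {
      reasons[[id]] <- c(reasons[[id]], "divergence_outlier")
    }
  }

  res <- data.frame(id = ids, stringsAsFactors = FALSE)
  res$reasons <- unname(reasons)
  res$passed <- lengths(res$reasons) == 0
  res <- res[c("id", "passed", "reasons")]
  class(res) <- c("coi_qc", class(res))
  attr(res, "frame_offset") <- aln$frame_offset
  res
}

#' @export
print.coi_qc <- function(x, ...) {
  cat("QC report: ", sum(x$passed), "/", nrow(x), " records passed\n",
      sep = "")
  fails <- x[!x$passed, , drop = FALSE]
  if (nrow(fails)) {
    tab <- table(unlist(fails$reasons))
    cat("  failures: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
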