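#' Aligned COI barcode data with per-record taxonomy
#'
#' `coi_alignment()` bundles an aligned set of DNA barcode sequences with
#' the metadata the downstream analyses need: species, genus, family and an
#' identification status per record. Sequences are stored as a character
#' matrix (one row per record, one column per alignment column, uppercase
#' IUPAC letters, gaps as `-`), so the alignment is a fixed coordinate
#' system: truncation, codon positions and bootstrap resampling all operate
#' on columns.
#'
#' @param seqs Character matrix of aligned sequences (rows = records,
#'   rownames = record ids) or a named character vector of equal-length
#'   strings.
#' @param meta `data.frame` with columns `id`, `species`, `genus`,
#'   `family` and optionally `status` (`nominal`, `candidate` or
#'   `unidentified`), `voucher`, `locality`. Row order need not match
#'   `seqs`; rows are matched by `id`.
#' @param frame_offset Integer 0, 1 or 2: 0-based alignment column where
#'   the first complete codon starts. User-facing column coordinates are
#'   1-based everywhere else.
#' @param code_table Genetic code used for stop-codon screening; see
#'   [stop_codons()].
#' @param status_markers Tokens in the species label that mark a record as
#'   a candidate species when no `status` column is supplied (matched
#'   case-insensitively as whitespace-delimited tokens).
#' @return An object of class `coi_alignment`: a list with elements
#'   `seqs`, `meta`, `frame_offset`, `code_table`.
#' @export
#' @examples
#' seqs <- rbind(a = c("A", "T", "G", "C"), b = c("A", "T", "G", "-"))
#' meta <- data.frame(id = c("a", "b"), species = c("Gen sp1", "Gen sp."),
#'                    genus = "Gen", family = "Fam")
#' aln <- coi_alignment(seqs, meta)
#' aln$meta$status
coi_alignment <- function(seqs, meta, frame_offset = 0L,
                          code_table = "vert-mito",
                          status_markers = c("sp.", "aff.")) {
  if (is.character(seqs) && is.null(dim(seqs))) {
    if (is.null(names(seqs))) stop("sequence vector must be named by id")
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1) {
      stop("ragged alignment: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    seqs <- do.call(rbind, strsplit(seqs, ""))
  }
  if (!is.matrix(seqs) || is.null(rownames(seqs))) {
    stop("seqs must be a character matrix with record ids as rownames")
  }
  mode(seqs) <- "character"
  seqs[] <- toupper(seqs)
  ids <- rownames(seqs)
  if (anyDuplicated(ids)) {
    stop("duplicate id: ", ids[duplicated(ids)][1])
  }
  if (ncol(seqs) < 1) stop("seq non-empty required")

  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  req <- c("id", "species", "genus", "family")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(meta$id)) {
    stop("duplicate id in metadata: ", meta$id[duplicated(meta$id)][1])
  }
  absent <- setdiff(ids, meta$id)
  if (length(absent)) {
    stop("no metadata row for id: ", paste(absent, collapse = ", "))
  }
  meta <- meta[match(ids, meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(!nzchar(meta$genus)) || any(!nzchar(meta$family))) {
    stop("every record must have genus and family")
  }
  if (!"status" %in% names(meta) || all(is.na(meta$status))) {
    meta$status <- ifelse(has_status_marker(meta$species, status_markers),
                          "candidate", "nominal")
  } else {
    bad <- setdiff(unique(meta$status),
                   c("nominal", "candidate", "unidentified"))
    if (length(bad)) stop("unknown status value: ",
                          paste(bad, collapse = ", "))
  }
  if (!"voucher" %in% names(meta)) meta$voucher <- NA_character_
  if (!"locality" %in% names(meta)) meta$locality <- NA_character_
  meta <- meta[c("id", "species", "genus", "family", "status",
                 "voucher", "locality")]

  frame_offset <- as.integer(frame_offset)
  if (!frame_offset %in% 0:2) stop("frame_offset must be 0, 1 or 2")
  stop_codons(code_table)  # validates
  structure(list(seqs = seqs, meta = meta, frame_offset = frame_offset,
                 code_table = code_table),
            class = "coi_alignment")
}

# Case-insensitive token match of candidate-species markers ("sp.", "aff.")
# in a species label.
has_status_marker <- function(species, markers = c("sp.", "aff.")) {
  toks <- strsplit(tolower(species), "[[:space:]]+")
  vapply(toks, function(tk) any(tolower(markers) %in% tk), logical(1))
}

#' @export
print.coi_alignment <- function(x, ...) {
  cat("COI alignment: ", nrow(x$seqs), " records x ", ncol(x$seqs),
      " columns\n", sep = "")
  cat("  families: ", length(unique(x$meta$family)),
      "; genera: ", length(unique(x$meta$genus)),
      "; species: ", length(unique(x$meta$species)), "\n", sep = "")
  st <- table(x$meta$status)
  cat("  status: ", paste(names(st), st, sep = "=", collapse = ", "), "\n",
      sep = "")
  cat("  frame offset ", x$frame_offset, " (0-based), code table '",
      x$code_table, "'\n", sep = "")
  invisible(x)
}

#' Number of records / columns of an alignment
#' @param aln A [coi_alignment()].
#' @return Integer.
#' @export
n_records <- function(aln) nrow(aln$seqs)

#' @rdname n_records
#' @export
n_columns <- function(aln) ncol(aln$seqs)

#' Subset an alignment by record id
#'
#' @param aln A [coi_alignment()].
#' @param ids Record ids to keep (order is preserved as given).
#' @return A [coi_alignment()] with the selected records.
#' @export
subset_records <- function(aln, ids) {
  stopifnot(inherits(aln, "coi_alignment"))
  missing <- setdiff(ids, rownames(aln$seqs))
  if (length(missing)) {
    stop("unknown record id: ", paste(missing, collapse = ", "))
  }
  coi_alignment(aln$seqs[ids, , drop = FALSE],
                aln$meta[match(ids, aln$meta$id), , drop = FALSE],
                frame_offset = aln$frame_offset,
                code_table = aln$code_table)
}

# Integer coding used by the C++ kernels: A=0 C=1 G=2 T=3, everything else
# (gaps, ambiguities) -1.
encode_dna <- function(seqs) {
  m <- match(seqs, c("A", "C", "G", "T")) - 1L
  m[is.na(m)] <- -1L
  dim(m) <- dim(seqs)
  rownames(m) <- rownames(seqs)
  m
}

# Count of non-gap nucleotide characters per record (IUPAC letters other
# than '-' count as read bases).
ungapped_lengths <- function(aln) {
  rowSums(aln$seqs != "-" & aln$seqs != "?" & aln$seqs != ".")
}
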