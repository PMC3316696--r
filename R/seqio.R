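#' Read an aligned FASTA plus a metadata table
#'
#' Reads a pre-aligned FASTA file (gaps as `-`) and a tab-separated
#' metadata table with header columns `id`, `species`, `genus`, `family`
#' and optionally `status`, `voucher`, `locality`, and combines them into a
#' [coi_alignment()]. Every FASTA entry must have a metadata row; metadata
#' rows without a sequence are ignored. When the `status` column is absent
#' it is inferred from candidate markers (`"sp."`, `"aff."`) in the species
#' label.
#'
#' @param fasta_path Path to the aligned FASTA file.
#' @param tsv_path Path to the metadata TSV.
#' @inheritParams coi_alignment
#' @return A [coi_alignment()].
#' @export
read_coi_data <- function(fasta_path, tsv_path, frame_offset = 0L,
                          code_table = "vert-mito",
                          status_markers = c("sp.", "aff.")) {
  dna <- ape::read.FASTA(fasta_path)
  if (length(dna) == 0) stop("no sequences in ", fasta_path)
  lens <- lengths(dna)
  if (length(unique(lens)) > 1) {
    stop("ragged alignment in ", fasta_path, ": lengths ",
         paste(unique(lens), collapse = ", "))
  }
  if (anyDuplicated(names(dna))) {
    stop("duplicate id: ", names(dna)[duplicated(names(dna))][1])
  }
  seqs <- toupper(as.character(as.matrix(dna)))
  meta <- read.delim(tsv_path, sep = "\t", stringsAsFactors = FALSE,
                     colClasses = "character")
  meta <- meta[meta$id %in% rownames(seqs), , drop = FALSE]
  coi_alignment(seqs, meta, frame_offset = frame_offset,
                code_table = code_table, status_markers = status_markers)
}

#' Write an alignment back to FASTA plus metadata TSV
#'
#' Inverse of [read_coi_data()]: writing and re-reading reproduces the same
#' records.
#'
#' @param aln A [coi_alignment()].
#' @param fasta_path,tsv_path Output paths.
#' @return Invisibly, `aln`.
#' @export
write_coi_data <- function(aln, fasta_path, tsv_path) {
  stopifnot(inherits(aln, "coi_alignment"))
  dna <- ape::as.DNAbin(tolower(aln$seqs))
  ape::write.FASTA(dna, fasta_path)
  write.table(aln$meta, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(aln)
}

#' Write a QC report as TSV
#'
#' @param report A QC report from [qc_report()].
#' @param path Output path. Reasons are semicolon-joined.
#' @return Invisibly, `report`.
#' @export
write_qc_report <- function(report, path) {
  out <- data.frame(id = report$id, passed = report$passed,
                    reasons = vapply(report$reasons, paste,
                                     collapse = ";", FUN.VALUE = ""),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Write a distance matrix as TSV
#'
#' Writes either a square matrix (`format = "square"`, ids in the first
#' column) or a long table (`format = "long"`, columns `id_a`, `id_b`,
#' `model`, `distance`) with one row per unordered pair. Undefined
#' distances are written as `NA`.
#'
#' @param dmat A [distance_matrix()] result.
#' @param path Output path.
#' @param format `"square"` or `"long"`.
#' @return Invisibly, `dmat`.
#' @export
write_distance_tsv <- function(dmat, path, format = c("square", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(dmat, "coi_dist"))
  if (format == "square") {
    out <- data.frame(id = dmat$labels, dmat$d, check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    idx <- which(upper.tri(dmat$d), arr.ind = TRUE)
    out <- data.frame(id_a = dmat$labels[idx[, 1]],
                      id_b = dmat$labels[idx[, 2]],
                      model = dmat$model,
                      distance = dmat$d[idx])
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dmat)
}
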