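# Genetic code tables used for stop-codon screening. Only the stop codons
# matter for QC, so codes are stored as their stop-codon sets.

.stop_codons <- list(
  # NCBI translation table 2 (vertebrate mitochondrial): AGA/AGG are stops.
  "vert-mito" = c("TAA", "TAG", "AGA", "AGG"),
  # NCBI translation table 1 (standard nuclear code).
  "standard"  = c("TAA", "TAG", "TGA")
)

#' Stop codons of a genetic code
#'
#' Returns the stop codons of a supported genetic code. The vertebrate
#' mitochondrial code (`"vert-mito"`, NCBI translation table 2) is the
#' default throughout the package because COI is a mitochondrial gene; the
#' standard nuclear code (`"standard"`) is useful for screening suspected
#' nuclear copies (NUMTs).
#'
#' @param code_table Character; one of `"vert-mito"` or `"standard"`.
#' @return Character vector of stop-codon triplets.
#' @export
#' @examples
#' stop_codons("vert-mito")
stop_codons <- function(code_table = "vert-mito") {
  if (!code_table %in% names(.stop_codons)) {
    stop("unknown code_table: '", code_table, "' (supported: ",
         paste(names(.stop_codons), collapse = ", "), ")")
  }
  .stop_codons[[code_table]]
}
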