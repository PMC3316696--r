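# Shared fixtures, built in code.

# Tiny hand-written alignment: 4 records, 12 columns, in frame 0, no stops
# under the vertebrate mitochondrial code.
tiny_alignment <- function() {
  seqs <- c(
    a = "ATGCTACTAGCA",
    b = "ATGCTACTGGCA",
    c = "ATACTTCTAGCA",
    d = "ATGTTACTAGTA")
  meta <- data.frame(
    id = c("a", "b", "c", "d"),
    species = c("Genus1 alpha", "Genus1 beta", "Genus2 gamma",
                "Genus2 delta"),
    genus = c("Genus1", "Genus1", "Genus2", "Genus2"),
    family = "Fam1",
    stringsAsFactors = FALSE)
  coi_alignment(seqs, meta)
}

# Small simulated dataset reused across test files (2 families keeps the
# suite fast); regenerated deterministically.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_coi_dataset(
        sim_config(n_families = 2, genera_per_family = 2,
                   species_per_genus = 4, seed = 101))
    }
    cache
  }
})

# Manual generating tree wrapped as a sim_truth so evolve_sequences() can
# be driven with hand-chosen topologies and branch lengths.
manual_truth <- function(newick, taxonomy) {
  structure(list(tree = ape::read.tree(text = newick),
                 taxonomy = taxonomy,
                 expected_sister = numeric(),
                 family_stems = numeric(),
                 family_trees = list()),
            class = "sim_truth")
}

simple_taxonomy <- function(ids) {
  data.frame(id = ids, species = paste("Genus", ids),
             genus = "Genus", family = "Fam",
             status = "nominal", stringsAsFactors = FALSE)
}

# Canonical representation of the non-trivial split set of a tree, for
# topology comparisons.
split_set <- function(tree) {
  sort(vapply(bipartitions(tree),
              function(bp) paste(bp$b, collapse = "|"), ""))
}
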