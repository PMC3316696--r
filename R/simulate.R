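#' Configuration of the COI-like dataset simulator
#'
#' The generator emulates a multi-family barcode reference library: deep
#' divergences between families, substantial divergence between congeneric
#' and confamilial species, shallow intraspecific variation, coding
#' sequences free of internal stop codons, and optional planted
#' "unidentified" lineages above or below the delimitation threshold.
#' Depths are expected substitutions per site and denote half the expected
#' pairwise path (two lineages diverged at depth `t` are `2t` apart).
#'
#' Defaults mirror a desk-scale reptile-like assemblage: 8 families x 3
#' genera x 4 species x 1 sample (~96 records plus planted lineages),
#' within-family mean interspecific divergence near 20% K2p and
#' family-level thresholds near 9-14%, with `min_species_separation`
#' enforcing that "good" nominal species are at least 8% apart — the
#' hallmark of a well-curated reference set.
#'
#' @param n_families,genera_per_family,species_per_genus,samples_per_species
#'   Taxonomic shape of the dataset. Genera are carved out of each family
#'   tree as monophyletic clades, so genus sizes vary around
#'   `species_per_genus`.
#' @param seq_length Alignment columns (default 664, the full barcode
#'   region).
#' @param kappa Transition/transversion rate ratio of the generating
#'   two-parameter substitution process (default 4).
#' @param family_depth,species_depth,intraspecific_depth Expected
#'   substitutions/site at the three levels; must be strictly decreasing.
#' @param min_species_separation Minimum pairwise path between any two
#'   species of a family (expected substitutions/site).
#' @param min_family_stem Minimum length of the stem branch subtending
#'   each family (expected substitutions/site). The default (0.05, about
#'   33 stem substitutions over a 664-column barcode) makes every family a
#'   strongly divergent lineage, the situation of old families whose
#'   monophyly is not in doubt.
#' @param planted_candidates `data.frame` with columns `family` (index,
#'   1-based) and `multiplier`: each row plants one unidentified lineage at
#'   `multiplier` times the family's expected sister-species divergence
#'   from its nearest nominal species. Multipliers > 1 are true candidate
#'   species, multipliers < 1 decoys. `NULL` plants nothing.
#' @param gamma_shape Optional gamma shape for among-site rate variation
#'   (`NULL` = equal rates).
#' @param stop_free Keep the coding sequence free of internal stop codons
#'   by reverting codons that mutate into stops (default). Turning this
#'   off gives a pure two-parameter process, useful when checking distance
#'   estimators against nominal branch lengths.
#' @param code_table Genetic code used for stop-codon avoidance.
#' @param seed Integer seed; the full dataset is deterministic given the
#'   config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_families = 8, genera_per_family = 3,
                       species_per_genus = 4, samples_per_species = 1,
                       seq_length = 664, kappa = 4,
                       family_depth = 0.175, species_depth = 0.10,
                       intraspecific_depth = 0.005,
                       min_species_separation = 0.08,
                       min_family_stem = 0.05,
                       planted_candidates = default_planted(n_families),
                       gamma_shape = NULL,
                       stop_free = TRUE,
                       code_table = "vert-mito",
                       seed = 1) {
  stopifnot(n_families >= 1, genera_per_family >= 1,
            species_per_genus >= 2, samples_per_species >= 1,
            seq_length >= 3, kappa > 0)
  if (!(family_depth > species_depth &&
        species_depth > intraspecific_depth && intraspecific_depth >= 0)) {
    stop("depths must satisfy family > species > intraspecific >= 0")
  }
  if (!is.null(planted_candidates)) {
    stopifnot(is.data.frame(planted_candidates),
              all(c("family", "multiplier") %in%
                    names(planted_candidates)))
    if (any(planted_candidates$multiplier <= 0)) {
      stop("planted multiplier must be > 0")
    }
  }
  structure(list(n_families = n_families,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 samples_per_species = samples_per_species,
                 seq_length = as.integer(seq_length), kappa = kappa,
                 family_depth = family_depth,
                 species_depth = species_depth,
                 intraspecific_depth = intraspecific_depth,
                 min_species_separation = min_species_separation,
                 min_family_stem = min_family_stem,
                 planted_candidates = planted_candidates,
                 gamma_shape = gamma_shape,
                 stop_free = isTRUE(stop_free),
                 code_table = code_table,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Default planted design: two deep lineages (true candidates) and two
# shallow decoys, in four different families.
default_planted <- function(n_families) {
  fams <- c(1, 3, 5, 7)
  fams <- fams[fams <= n_families]
  if (!length(fams)) fams <- rep(1, 4)
  data.frame(family = rep_len(fams, 4), multiplier = c(2, 2, 0.5, 0.5))
}

#' Simulate the generating taxonomy and trees
#'
#' Per family: a pure-birth species tree rescaled so the mean
#' interspecific path equals `2 * species_depth`, genera carved out as
#' `genera_per_family` monophyletic clades, and terminal branches extended
#' where needed so every interspecific path reaches
#' `min_species_separation`. Families are joined on a star backbone at
#' `family_depth`; conspecific samples are appended as shallow radiations
#' at `intraspecific_depth`. Call [set.seed()] upstream or use
#' [simulate_coi_dataset()] for full determinism.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_truth` with `tree` (full `phylo`, tips =
#'   record ids), `taxonomy` (metadata `data.frame`), `expected_sister`
#'   (named numeric: expected sister-pair path per family) and
#'   `family_trees`.
#' @export
simulate_taxonomy_trees <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  fam_newicks <- character(config$n_families)
  fam_trees <- vector("list", config$n_families)
  taxonomy <- list()
  expected_sister <- numeric(config$n_families)
  stems <- numeric(config$n_families)
  fam_names <- sprintf("Famil%02d", seq_len(config$n_families))
  names(expected_sister) <- names(stems) <- fam_names

  for (f in seq_len(config$n_families)) {
    n_sp <- config$genera_per_family * config$species_per_genus
    tr <- ape::rphylo(n_sp, birth = 1, death = 0)
    coph <- ape::cophenetic.phylo(tr)
    scale <- 2 * config$species_depth / mean(coph[upper.tri(coph)])
    tr$edge.length <- tr$edge.length * scale

    # genus assignment: cut the ultrametric tree into monophyletic clades
    genus_of <- if (config$genera_per_family > 1) {
      hc <- ape::as.hclust.phylo(tr)
      ct <- stats::cutree(hc, k = config$genera_per_family)
      ct[match(tr$tip.label, names(ct))]
    } else {
      setNames(rep(1L, n_sp), tr$tip.label)
    }

    # enforce the species-separation floor by extending terminal branches
    coph <- ape::cophenetic.phylo(tr)
    diag(coph) <- Inf
    ext <- pmax(0, apply((config$min_species_separation - coph) / 2, 1,
                         max))
    names(ext) <- rownames(coph)
    tip_edges <- match(seq_len(n_sp), tr$edge[, 2])
    tr$edge.length[tip_edges] <- tr$edge.length[tip_edges] +
      ext[tr$tip.label]

    # expected sister divergence: mean path over the tree's cherries
    coph <- ape::cophenetic.phylo(tr)
    expected_sister[f] <- mean_cherry_path(tr, coph)

    # record ids and names
    sp_meta <- data.frame(
      tip = tr$tip.label,
      genus = sprintf("Genus%02d%02d", f, genus_of),
      stringsAsFactors = FALSE)
    sp_idx <- stats::ave(seq_len(n_sp), sp_meta$genus,
                         FUN = seq_along)
    sp_meta$species <- sprintf("%s sim%02d", sp_meta$genus, sp_idx)
    sp_meta$family <- fam_names[f]

    # conspecific samples: replace each tip by a shallow radiation
    nwk <- ape::write.tree(tr)
    rec <- list()
    for (i in seq_len(n_sp)) {
      base_id <- sprintf("r%02d%s%02d", f,
                         sub("Genus", "g", sp_meta$genus[i]), i)
      k <- config$samples_per_species
      if (k == 1) {
        ids <- base_id
        repl <- base_id
      } else {
        ids <- paste0(base_id, letters[seq_len(k)])
        repl <- paste0("(",
                       paste0(ids, ":", config$intraspecific_depth,
                              collapse = ","), ")")
      }
      nwk <- sub(paste0(sp_meta$tip[i], ":"), paste0(repl, ":"), nwk,
                 fixed = TRUE)
      rec[[i]] <- data.frame(id = ids, species = sp_meta$species[i],
                             genus = sp_meta$genus[i],
                             family = sp_meta$family[i],
                             status = "nominal",
                             stringsAsFactors = FALSE)
    }
    taxonomy[[f]] <- do.call(rbind, rec)
    fam_tr <- ape::read.tree(text = nwk)
    fam_trees[[f]] <- fam_tr

    # stem so that root-to-tip depth averages family_depth
    depths <- ape::node.depth.edgelength(fam_tr)
    h <- mean(depths[seq_along(fam_tr$tip.label)])
    stem <- max(config$family_depth - h, config$min_family_stem)
    stems[f] <- stem
    fam_newicks[f] <- paste0(sub(";$", "", ape::write.tree(fam_tr)),
                             ":", format(stem, digits = 10))
  }

  full <- ape::read.tree(
    text = paste0("(", paste(fam_newicks, collapse = ","), ");"))
  taxonomy <- do.call(rbind, taxonomy)
  rownames(taxonomy) <- NULL
  structure(list(tree = full, taxonomy = taxonomy,
                 expected_sister = expected_sister,
                 family_stems = stems,
                 family_trees = setNames(fam_trees, fam_names)),
            class = "sim_truth")
}

# Mean path length over the cherries (two-leaf sister pairs) of a tree.
mean_cherry_path <- function(tree, coph = ape::cophenetic.phylo(tree)) {
  n <- length(tree$tip.label)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  paths <- numeric()
  for (node in names(children)) {
    ch <- children[[node]]
    if (length(ch) == 2 && all(ch <= n)) {
      paths <- c(paths, coph[tree$tip.label[ch[1]], tree$tip.label[ch[2]]])
    }
  }
  mean(paths)
}

# K80 per-site substitution probabilities at branch length d (expected
# substitutions/site) and ts/tv rate ratio kappa. Returns c(p_ts, p_tv)
# where p_tv is the probability of EACH of the two transversions.
k80_probs <- function(d, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  p_ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  p_tv <- 0.25 - 0.25 * e1
  cbind(p_ts, p_tv)
}

# Evolve an integer-coded sequence (0=A,1=C,2=G,3=T) along one branch
# under K80, then revert any codon that became an in-frame stop to its
# pre-mutation (parent) state. site_rates multiplies the branch length
# per site.
evolve_branch <- function(seq, d, kappa, stop_idx, site_rates = NULL) {
  L <- length(seq)
  dd <- if (is.null(site_rates)) rep(d, L) else d * site_rates
  pr <- k80_probs(dd, kappa)
  u <- runif(L)
  ts_partner <- (seq + 2L) %% 4L
  # transversion targets: the two bases of opposite parity
  tv1 <- ifelse(seq %% 2L == 0L, 1L, 0L)
  tv2 <- ifelse(seq %% 2L == 0L, 3L, 2L)
  out <- seq
  is_ts <- u < pr[, 1]
  is_tv1 <- !is_ts & u < pr[, 1] + pr[, 2]
  is_tv2 <- !is_ts & !is_tv1 & u < pr[, 1] + 2 * pr[, 2]
  out[is_ts] <- ts_partner[is_ts]
  out[is_tv1] <- tv1[is_tv1]
  out[is_tv2] <- tv2[is_tv2]
  revert_stops(out, seq, stop_idx)
}

# Replace codons that are stops (by codon index c1*16+c2*4+c3) with the
# parent codon. Only complete in-frame codons are considered; a trailing
# partial codon is left alone.
revert_stops <- function(seq, parent, stop_idx) {
  L <- length(seq)
  n_cod <- L %/% 3
  if (n_cod == 0) return(seq)
  pos1 <- 3 * (seq_len(n_cod) - 1) + 1
  cod <- seq[pos1] * 16L + seq[pos1 + 1] * 4L + seq[pos1 + 2]
  bad <- which(cod %in% stop_idx)
  for (b in bad) {
    idx <- (3 * (b - 1) + 1):(3 * b)
    seq[idx] <- parent[idx]
  }
  seq
}

# Integer codon indices of the stop codons of a code table.
stop_codon_indices <- function(code_table) {
  nuc <- c("A", "C", "G", "T")
  vapply(stop_codons(code_table), function(s) {
    v <- match(strsplit(s, "")[[1]], nuc) - 1L
    v[1] * 16L + v[2] * 4L + v[3]
  }, integer(1))
}

# Random stop-free root sequence of given length (integer coded).
random_root_seq <- function(L, stop_idx) {
  nuc_codes <- 0:3
  n_cod <- L %/% 3
  sense <- setdiff(0:63, stop_idx)
  cods <- sample(sense, n_cod, replace = TRUE)
  seq <- integer(3 * n_cod)
  seq[seq(1, by = 3, length.out = n_cod)] <- cods %/% 16L
  seq[seq(2, by = 3, length.out = n_cod)] <- (cods %/% 4L) %% 4L
  seq[seq(3, by = 3, length.out = n_cod)] <- cods %% 4L
  extra <- L - 3 * n_cod
  if (extra > 0) seq <- c(seq, sample(nuc_codes, extra, replace = TRUE))
  seq
}

#' Evolve sequences along a generating tree
#'
#' Simulates a coding sequence down the tree under a two-parameter
#' (kappa) substitution process. The root is drawn uniformly over sense
#' codons; after each branch, any codon that has become an in-frame stop
#' is reverted to its pre-mutation state, so the output passes the stop
#' codon screen by construction.
#'
#' @param truth A [simulate_taxonomy_trees()] result.
#' @param config The [sim_config()] used to build it.
#' @return A [coi_alignment()] with one record per tree tip.
#' @export
evolve_sequences <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  tree <- truth$tree
  stop_idx <- if (isTRUE(config$stop_free)) {
    stop_codon_indices(config$code_table)
  } else {
    integer(0)
  }
  L <- config$seq_length
  site_rates <- if (is.null(config$gamma_shape)) NULL else
    rgamma(L, shape = config$gamma_shape, rate = config$gamma_shape)
  n <- length(tree$tip.label)
  seqs_at <- vector("list", n + tree$Nnode)
  root <- n + 1L
  seqs_at[[root]] <- random_root_seq(L, stop_idx)
  pre <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]
    ch <- pre$edge[e, 2]
    seqs_at[[ch]] <- evolve_branch(seqs_at[[p]], pre$edge.length[e],
                                   config$kappa, stop_idx, site_rates)
  }
  nuc <- c("A", "C", "G", "T")
  seq_mat <- do.call(rbind, lapply(seqs_at[seq_len(n)], function(s) {
    nuc[s + 1L]
  }))
  rownames(seq_mat) <- tree$tip.label
  coi_alignment(seq_mat, truth$taxonomy, frame_offset = 0L,
                code_table = config$code_table)
}

#' Plant unidentified lineages with known divergence
#'
#' For each row of `config$planted_candidates`, evolves one extra record
#' from a nominal anchor species of the requested family at a target
#' distance of `multiplier` times that family's expected sister-species
#' divergence. Because the new record hangs off the anchor's tip, its
#' nearest-nominal distance is the target distance in expectation.
#' Planted records get `status = "unidentified"` and a `"Genus sp."`
#' label.
#'
#' @param aln Alignment from [evolve_sequences()].
#' @param truth The matching `sim_truth`.
#' @param config The [sim_config()].
#' @return List with the augmented `alignment` and `truth`; `truth$planted`
#'   records each planted id, anchor, family, multiplier, target distance
#'   and whether it should be flagged (`multiplier > 1`).
#' @export
plant_candidates <- function(aln, truth, config) {
  planted <- config$planted_candidates
  if (is.null(planted) || nrow(planted) == 0) {
    truth$planted <- data.frame(id = character(), anchor = character(),
                                family = character(), multiplier = numeric(),
                                target_distance = numeric(),
                                expected_flag = logical(),
                                stringsAsFactors = FALSE)
    return(list(alignment = aln, truth = truth))
  }
  stop_idx <- if (isTRUE(config$stop_free)) {
    stop_codon_indices(config$code_table)
  } else {
    integer(0)
  }
  fam_names <- names(truth$expected_sister)
  rows <- list()
  seqs <- aln$seqs
  meta <- aln$meta
  used <- character()
  for (i in seq_len(nrow(planted))) {
    fam <- fam_names[planted$family[i]]
    mult <- planted$multiplier[i]
    cand_anchors <- setdiff(meta$id[meta$family == fam &
                                      meta$status == "nominal"], used)
    anchor <- sort(cand_anchors)[1]
    used <- c(used, anchor)
    target <- mult * truth$expected_sister[fam]
    parent <- encode_dna(seqs[anchor, , drop = FALSE])[1, ]
    child <- evolve_branch(parent, target, config$kappa, stop_idx)
    new_id <- paste0(anchor, "u")
    nuc <- c("A", "C", "G", "T")
    seqs <- rbind(seqs,
                  matrix(nuc[child + 1L], nrow = 1,
                         dimnames = list(new_id, NULL)))
    am <- meta[meta$id == anchor, ]
    meta <- rbind(meta, data.frame(
      id = new_id, species = paste(am$genus, "sp."), genus = am$genus,
      family = fam, status = "unidentified", voucher = NA_character_,
      locality = NA_character_, stringsAsFactors = FALSE))
    rows[[i]] <- data.frame(id = new_id, anchor = anchor, family = fam,
                            multiplier = mult, target_distance = target,
                            expected_flag = mult > 1,
                            stringsAsFactors = FALSE)
  }
  truth$planted <- do.call(rbind, rows)
  out_aln <- coi_alignment(seqs, meta, frame_offset = aln$frame_offset,
                           code_table = aln$code_table)
  list(alignment = out_aln, truth = truth)
}

#' Simulate a complete COI-like dataset with ground truth
#'
#' One-stop generator: taxonomy and trees, sequences, planted lineages.
#' Fully deterministic given the config (including its seed).
#'
#' @param config A [sim_config()].
#' @return List with `alignment` (a [coi_alignment()]) and `truth` (a
#'   `sim_truth` with `planted` filled in).
#' @export
#' @examples
#' sim <- simulate_coi_dataset(sim_config(n_families = 2, seed = 42))
#' sim$alignment
simulate_coi_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  truth <- simulate_taxonomy_trees(config)
  aln <- evolve_sequences(truth, config)
  plant_candidates(aln, truth, config)
}
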