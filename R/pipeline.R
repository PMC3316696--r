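#' Run the full barcoding assessment on an alignment
#'
#' The central analysis of the package. Starting from an aligned barcode
#' library with taxonomy it runs, in order: sequence QC (length, reading
#' frame, internal stops, divergence outliers), K2p and p distance
#' matrices, the neighbor-joining tree with bootstrap supports, monophyly
#' scores of genera and families, well-supported sister-species pairs,
#' family-specific divergence thresholds, and single-linkage clustering of
#' candidate/unidentified records into candidate-species lineages counted
#' under both distance models.
#'
#' @param aln A [coi_alignment()], e.g. from [read_coi_data()] or
#'   [simulate_coi_dataset()].
#' @param min_length QC minimum non-gap length (default 600).
#' @param outlier_cutoff QC divergence-outlier cutoff (default 0.35 K2p);
#'   `NULL` disables the screen.
#' @param bootstrap_reps Bootstrap replicates for the NJ tree (1000 for a
#'   full analysis; 100 is adequate at desk scale).
#' @param min_support_sister Minimum (exclusive) bootstrap support of a
#'   sister pair, default 70.
#' @param support_threshold High-support threshold for group summaries,
#'   default 90.
#' @param seed Integer seed for the bootstrap.
#' @return An object of class `barcode_pipeline`: a list with the
#'   alignment actually analysed (`alignment`), `qc`, `dist_k2p`,
#'   `dist_p`, `tree` (NJ with supports), `genus_scores`,
#'   `family_scores`, `sister_pairs`, `thresholds`, `lineages_k2p`,
#'   `lineages_p`, `candidates`, `divergence` (per-family means),
#'   `saturation`, and the call parameters in `params`.
#' @export
#' @examples
#' sim <- simulate_coi_dataset(sim_config(n_families = 3, seed = 7))
#' fit <- barcode_pipeline(sim$alignment, bootstrap_reps = 25, seed = 7)
#' fit
barcode_pipeline <- function(aln, min_length = 600, outlier_cutoff = 0.35,
                             bootstrap_reps = 1000,
                             min_support_sister = 70,
                             support_threshold = 90, seed = 1) {
  stopifnot(inherits(aln, "coi_alignment"))
  qc <- qc_report(aln, min_length = min_length,
                  outlier_cutoff = outlier_cutoff)
  keep <- qc$id[qc$passed]
  if (length(keep) < 4) stop("fewer than 4 records pass QC")
  aln2 <- subset_records(aln, keep)
  aln2$frame_offset <- attr(qc, "frame_offset")

  dk <- distance_matrix(aln2, "k2p")
  dp <- distance_matrix(aln2, "p")
  tree <- neighbor_joining(dk)
  tree <- bootstrap_support(aln2, "k2p", tree, n_reps = bootstrap_reps,
                            seed = seed)

  genus_scores <- score_all_groups(tree, aln2$meta, "genus",
                                   support_threshold)
  family_scores <- score_all_groups(tree, aln2$meta, "family",
                                    support_threshold)

  pairs <- find_sister_pairs(tree, aln2$meta, dk, dp,
                             min_support = min_support_sister)
  fams <- sort(unique(aln2$meta$family))
  thresholds <- build_threshold_table(pairs, families = fams)

  lk <- cluster_unidentified(dk, aln2$meta, thresholds)
  lp <- cluster_unidentified(dp, aln2$meta, thresholds)
  cand <- candidate_count(lk, lp)

  refs <- reference_records(aln2$meta)
  div <- do.call(rbind, lapply(fams, function(f) {
    if (sum(refs$family == f) < 2) {
      return(data.frame(family = f, n_reference_species =
                          sum(refs$family == f),
                        mean_k2p = NA_real_, mean_p = NA_real_))
    }
    m <- mean_interspecific_divergence(aln2, f, dk, dp)
    data.frame(family = f, n_reference_species = sum(refs$family == f),
               mean_k2p = m[["mean_k2p"]], mean_p = m[["mean_p"]])
  }))

  structure(list(alignment = aln2, qc = qc, dist_k2p = dk, dist_p = dp,
                 tree = tree, genus_scores = genus_scores,
                 family_scores = family_scores, sister_pairs = pairs,
                 thresholds = thresholds, lineages_k2p = lk,
                 lineages_p = lp, candidates = cand, divergence = div,
                 saturation = saturation_table(aln2),
                 params = list(min_length = min_length,
                               outlier_cutoff = outlier_cutoff,
                               bootstrap_reps = bootstrap_reps,
                               min_support_sister = min_support_sister,
                               support_threshold = support_threshold,
                               seed = seed)),
            class = "barcode_pipeline")
}

#' @export
print.barcode_pipeline <- function(x, ...) {
  cat("Barcoding assessment\n")
  cat("  records analysed: ", n_records(x$alignment), " (",
      sum(!x$qc$passed), " failed QC)\n", sep = "")
  gs <- attr(x$genus_scores, "summary")
  fs <- attr(x$family_scores, "summary")
  cat(sprintf("  genera: %d/%d monophyletic (%d with support > %g)\n",
              gs$n_monophyletic, gs$n_scored, gs$n_high_support,
              gs$support_threshold))
  cat(sprintf("  families: %d/%d monophyletic (%d with support > %g)\n",
              fs$n_monophyletic, fs$n_scored, fs$n_high_support,
              fs$support_threshold))
  cat("  sister pairs (support > ", x$params$min_support_sister, "): ",
      nrow(x$sister_pairs), "\n", sep = "")
  cat("  candidate species: ", x$candidates$min_count, "-",
      x$candidates$max_count, "\n", sep = "")
  invisible(x)
}

#' Per-family summary table of a barcoding assessment
#'
#' The per-family digest of the analysis: number of reference species,
#' mean interspecific divergence (K2p/p, percent, one decimal), number of
#' well-supported sister pairs, the derived thresholds and the candidate
#' count range.
#'
#' @param object A [barcode_pipeline()] result.
#' @param ... Unused.
#' @return `data.frame`, one row per family.
#' @export
summary.barcode_pipeline <- function(object, ...) {
  x <- object
  fams <- x$thresholds$family
  cand <- x$candidates$per_family
  pct <- function(v) round(100 * v, 1)
  out <- data.frame(
    family = fams,
    n_reference_species =
      x$divergence$n_reference_species[match(fams, x$divergence$family)],
    mean_divergence_k2p_pct =
      pct(x$divergence$mean_k2p[match(fams, x$divergence$family)]),
    mean_divergence_p_pct =
      pct(x$divergence$mean_p[match(fams, x$divergence$family)]),
    n_sister_pairs = x$thresholds$n_pairs,
    threshold_k2p_pct = pct(x$thresholds$threshold_k2p),
    threshold_p_pct = pct(x$thresholds$threshold_p),
    candidates_min = ifelse(fams %in% cand$family,
                            cand$min[match(fams, cand$family)], 0L),
    candidates_max = ifelse(fams %in% cand$family,
                            cand$max[match(fams, cand$family)], 0L),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Plot a barcoding assessment
#'
#' Two panels: the NJ tree with bootstrap supports, and the saturation
#' plot of transition/transversion proportions against K2p divergence.
#'
#' @param x A [barcode_pipeline()] result.
#' @param which `"tree"`, `"saturation"` or `"both"`.
#' @param ... Passed to [ape::plot.phylo()].
#' @return `x`, invisibly.
#' @export
plot.barcode_pipeline <- function(x, which = "both", ...) {
  op <- NULL
  if (which == "both") {
    op <- graphics::par(mfrow = c(1, 2))
    on.exit(graphics::par(op))
  }
  if (which %in% c("both", "tree")) {
    ape::plot.phylo(x$tree, cex = 0.5, no.margin = FALSE, ...)
    ape::nodelabels(text = x$tree$node.label, frame = "none", cex = 0.5,
                    adj = c(1.1, -0.3))
  }
  if (which %in% c("both", "saturation")) {
    s <- x$saturation
    ok <- !is.na(s$k2p)
    graphics::plot(s$k2p[ok], s$P[ok], pch = 1, col = "grey30",
                   xlab = "K2p distance", ylab = "proportion of sites",
                   main = "substitution saturation")
    graphics::points(s$k2p[ok], s$Q[ok], pch = 2, col = "grey60")
    graphics::legend("topleft", legend = c("transitions (P)",
                                           "transversions (Q)"),
                     pch = c(1, 2), col = c("grey30", "grey60"),
                     bty = "n")
  }
  invisible(x)
}

#' Run the pipeline end to end and write all artifacts
#'
#' Runs [barcode_pipeline()] on the input files and writes the QC report,
#' distance matrices, saturation table, NJ tree with supports (newick),
#' group scores, sister pairs, threshold table, candidate report and a
#' run manifest into `outdir`. Optionally also runs the subsampling and
#' fragment-length experiments.
#'
#' @param fasta_path,tsv_path Input files (see [read_coi_data()]).
#' @param outdir Output directory (created if missing).
#' @param experiments Run the two simulation series too (slow at full
#'   bootstrap settings).
#' @param experiment_cfg An [experiment_config()] used when
#'   `experiments = TRUE`.
#' @param ... Passed to [barcode_pipeline()].
#' @return The `barcode_pipeline` object, invisibly.
#' @export
run_full_pipeline <- function(fasta_path, tsv_path, outdir,
                              experiments = FALSE,
                              experiment_cfg = experiment_config(),
                              ...) {
  aln <- read_coi_data(fasta_path, tsv_path)
  fit <- barcode_pipeline(aln, ...)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(outdir, f)
  write_qc_report(fit$qc, fp("qc_report.tsv"))
  write_distance_tsv(fit$dist_k2p, fp("dist_k2p.tsv"), "long")
  write_distance_tsv(fit$dist_p, fp("dist_p.tsv"), "long")
  write.table(fit$saturation, fp("saturation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_newick(fit$tree, fp("nj_tree.nwk"))
  write.table(as.data.frame(fit$genus_scores), fp("genus_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(fit$family_scores), fp("family_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fit$sister_pairs, fp("sister_pairs.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fit$thresholds, fp("thresholds.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fit$lineages_k2p, fp("lineages_k2p.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fit$lineages_p, fp("lineages_p.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(summary(fit), fp("family_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (experiments) {
    sub <- run_subsampling(fit$alignment, experiment_cfg)
    write.table(sub, fp("subsampling.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    lens <- pmin(experiment_cfg$fragment_lengths,
                 n_columns(fit$alignment))
    frag_cfg <- experiment_cfg
    frag_cfg$fragment_lengths <- lens
    frag <- run_fragment_series(fit$alignment, frag_cfg)
    write.table(frag, fp("fragments.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  manifest <- c(
    sprintf("coibarcode %s", as.character(utils::packageVersion("coibarcode"))),
    sprintf("fasta: %s", normalizePath(fasta_path)),
    sprintf("meta: %s", normalizePath(tsv_path)),
    vapply(names(fit$params), function(k) {
      sprintf("%s: %s", k, format(fit$params[[k]]))
    }, ""),
    sprintf("experiments: %s", experiments),
    if (experiments) {
      vapply(setdiff(names(experiment_cfg), "model"), function(k) {
        sprintf("experiment_%s: %s", k,
                paste(format(experiment_cfg[[k]]), collapse = ","))
      }, "")
    })
  writeLines(manifest, fp("manifest.txt"))
  invisible(fit)
}
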