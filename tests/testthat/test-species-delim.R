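# hand-built alignment whose distances are controlled through a fixed
# distance matrix is awkward; these tests instead drive the delimitation
# functions with small synthetic matrices and metadata built in code.

fake_dist <- function(d, model) {
  structure(list(d = d, labels = rownames(d), model = model,
                 n_undefined = sum(is.na(d[upper.tri(d)]))),
            class = "coi_dist")
}

sym <- function(labels, fill = 0.5) {
  n <- length(labels)
  d <- matrix(fill, n, n, dimnames = list(labels, labels))
  diag(d) <- 0
  d
}

test_that("mean interspecific divergence averages reference species pairs", {
  sim <- small_sim()
  aln <- sim$alignment
  dk <- distance_matrix(aln, "k2p")
  dp <- distance_matrix(aln, "p")
  fam <- aln$meta$family[1]
  m <- mean_interspecific_divergence(aln, fam, dk, dp)
  # brute-force double loop over the family's nominal species
  refs <- aln$meta[aln$meta$status == "nominal" &
                     aln$meta$family == fam, ]
  refs <- refs[!duplicated(refs$species), ]
  vals <- c()
  for (i in seq_len(nrow(refs) - 1)) {
    for (j in seq.int(i + 1, nrow(refs))) {
      vals <- c(vals, dk$d[refs$id[i], refs$id[j]])
    }
  }
  expect_equal(unname(m["mean_k2p"]), mean(vals), tolerance = 1e-12)
  expect_error(mean_interspecific_divergence(aln, "Absentidae", dk, dp),
               "fewer than 2")
})

test_that("arithmetic of family means matches simple hand cases", {
  labels <- c("s1", "s2", "s3")
  d <- sym(labels)
  d["s1", "s2"] <- d["s2", "s1"] <- 0.1
  d["s1", "s3"] <- d["s3", "s1"] <- 0.2
  d["s2", "s3"] <- d["s3", "s2"] <- 0.3
  seqs <- matrix("A", 3, 4, dimnames = list(labels, NULL))
  meta <- data.frame(id = labels, species = paste("G", labels),
                     genus = "G", family = "F", stringsAsFactors = FALSE)
  aln <- coi_alignment(seqs, meta)
  m <- mean_interspecific_divergence(aln, "F", fake_dist(d, "k2p"),
                                     fake_dist(d, "p"))
  expect_equal(unname(m["mean_k2p"]), 0.2)
  # two species at 0.1
  aln2 <- subset_records(aln, c("s1", "s2"))
  m2 <- mean_interspecific_divergence(
    aln2, "F", fake_dist(d[1:2, 1:2], "k2p"), fake_dist(d[1:2, 1:2], "p"))
  expect_equal(unname(m2["mean_k2p"]), 0.1)
})

test_that("sister pairs are well-supported same-family nominal cherries", {
  nwk <- paste0("(((a1:1,a2:1)95:1,(a3:1,a4:1)65:1)99:1,",
                "((b1:1,u1:1)99:1,(a5:1,b2:1)99:1)99:1);")
  tr <- ape::read.tree(text = nwk)
  ids <- c("a1", "a2", "a3", "a4", "a5", "b1", "b2", "u1")
  meta <- data.frame(
    id = ids,
    species = c("Ga one", "Ga two", "Ga three", "Ga four", "Ga five",
                "Gb one", "Gb two", "Gb sp."),
    genus = rep(c("Ga", "Gb"), c(5, 3)),
    family = c(rep("FamA", 5), "FamB", "FamB", "FamB"),
    status = c(rep("nominal", 7), "unidentified"),
    stringsAsFactors = FALSE)
  d <- sym(ids, 0.2)
  d["a1", "a2"] <- d["a2", "a1"] <- 0.06
  dk <- fake_dist(d, "k2p")
  dp <- fake_dist(d / 2, "p")
  pairs <- find_sister_pairs(tr, meta, dk, dp, min_support = 70)
  # a1-a2 qualifies (support 95); a3-a4 fails support (65);
  # b1-u1 has an unidentified member; a5-b2 is cross-family
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$species_a, "Ga one")
  expect_identical(pairs$species_b, "Ga two")
  expect_equal(pairs$distance_k2p, 0.06)
  expect_equal(pairs$distance_p, 0.03)
  # raising min_support can only shrink the pair list
  for (ms in c(0, 50, 90, 96)) {
    p_lo <- find_sister_pairs(tr, meta, dk, dp, min_support = ms)
    expect_gte(nrow(find_sister_pairs(tr, meta, dk, dp, 0)), nrow(p_lo))
  }
  expect_identical(nrow(find_sister_pairs(tr, meta, dk, dp, 96)), 0L)
})

test_that("threshold table averages pair distances per family", {
  pairs <- data.frame(
    species_a = c("x", "y", "z"), species_b = c("x2", "y2", "z2"),
    family = c("Boidae", "Scincidae", "Scincidae"),
    support = 99,
    distance_k2p = c(0.066, 0.04, 0.06),
    distance_p = c(0.062, 0.03, 0.05),
    stringsAsFactors = FALSE)
  tab <- build_threshold_table(pairs, families = c("Boidae", "Scincidae",
                                                   "Empty"))
  # a single pair: its distance IS the threshold
  expect_equal(tab$threshold_k2p[tab$family == "Boidae"], 0.066)
  expect_equal(tab$threshold_p[tab$family == "Boidae"], 0.062)
  # two pairs: arithmetic mean
  expect_equal(tab$threshold_k2p[tab$family == "Scincidae"], 0.05)
  # family with no pair: reported, no threshold
  expect_identical(tab$n_pairs[tab$family == "Empty"], 0L)
  expect_true(is.na(tab$threshold_k2p[tab$family == "Empty"]))
  expect_warning(build_threshold_table(pairs[0, ]), "no sister pairs")
})

test_that("unidentified records cluster by single linkage and flag by nn", {
  ids <- c("n1", "n2", "u1", "u2", "u3", "v1")
  meta <- data.frame(
    id = ids,
    species = c("G one", "G two", "G sp.", "G sp.", "G sp. 2", "H sp."),
    genus = "G", family = c(rep("FamA", 5), "FamB"),
    status = c("nominal", "nominal", "unidentified", "unidentified",
               "unidentified", "candidate"),
    stringsAsFactors = FALSE)
  d <- sym(ids, 0.30)
  # u1 and u2 are conspecific-grade (0.02 apart), both far from nominals
  d["u1", "u2"] <- d["u2", "u1"] <- 0.02
  # u3 sits 0.05 from n1: below threshold
  d["u3", "n1"] <- d["n1", "u3"] <- 0.05
  thr <- data.frame(family = "FamA", n_pairs = 2L,
                    threshold_k2p = 0.10, threshold_p = 0.08,
                    stringsAsFactors = FALSE)
  lin <- cluster_unidentified(fake_dist(d, "k2p"), meta, thr)
  expect_identical(nrow(lin), 2L)
  merged <- lin[lin$members == "u1;u2", ]
  expect_identical(nrow(merged), 1L)
  expect_true(merged$flagged)
  expect_equal(merged$threshold_used, 0.10)
  single <- lin[lin$members == "u3", ]
  expect_false(single$flagged)
  expect_equal(single$nn_distance, 0.05)
  # v1 is in a family without a threshold: unresolved, not dropped
  expect_identical(attr(lin, "unresolved"), "v1")
  # lowering the family threshold never decreases the flagged count
  thr_lo <- thr
  thr_lo$threshold_k2p <- 0.04
  lin_lo <- cluster_unidentified(fake_dist(d, "k2p"), meta, thr_lo)
  expect_gte(sum(lin_lo$flagged), sum(lin$flagged))
})

test_that("candidate counts split into both-model and either-model", {
  lk <- data.frame(lineage_id = c("L1", "L2", "L3"),
                   members = c("u1;u2", "u3", "u4"),
                   family = c("FamA", "FamA", "FamB"),
                   nearest_nominal = "G one", nn_distance = 0.2,
                   threshold_used = 0.1,
                   flagged = c(TRUE, TRUE, FALSE),
                   stringsAsFactors = FALSE)
  lp <- lk
  lp$flagged <- c(TRUE, FALSE, TRUE)
  cc <- candidate_count(lk, lp)
  expect_identical(cc$min_count, 1L)
  expect_identical(cc$max_count, 3L)
  expect_lte(cc$min_count, cc$max_count)
  expect_identical(cc$per_family$min[cc$per_family$family == "FamA"], 1L)
  expect_identical(cc$per_family$max[cc$per_family$family == "FamA"], 2L)
  # full agreement collapses the range
  cc2 <- candidate_count(lk, lk)
  expect_identical(cc2$min_count, cc2$max_count)
})
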