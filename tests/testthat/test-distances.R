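test_that("site counts implement pairwise deletion and ts/tv split", {
  expect_identical(site_counts("ACGT", "ACGT"),
                   list(comparable = 4L, transitions = 0L,
                        transversions = 0L))
  # A<->G is a transition, T<->A a transversion
  sc <- site_counts("ACGT", "GCGA")
  expect_identical(sc$comparable, 4L)
  expect_identical(sc$transitions, 1L)
  expect_identical(sc$transversions, 1L)
  # gap and ambiguity columns drop out for the pair: only the third
  # column (gap vs N) is excluded here
  expect_identical(site_counts("AC-T", "ACNT")$comparable, 3L)
  expect_identical(site_counts("AC-T", "ACN-")$comparable, 2L)
  expect_error(site_counts("ACGT", "ACG"), "unequal lengths")
})

test_that("p distance is the raw mismatch proportion", {
  expect_identical(p_distance(site_counts("ACGT", "ACGT")), 0)
  expect_identical(p_distance(site_counts("ACGT", "ACGA")), 0.25)
  expect_error(p_distance(site_counts("----", "ACGT")),
               "no comparable sites")
})

test_that("K2p matches its closed form and detects saturation", {
  # independent evaluation of -1/2 log(1-2P-Q) - 1/4 log(1-2Q)
  # at P = 0.1, Q = 0.05
  expected <- -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05)
  got <- k2p_distance(list(comparable = 100L, transitions = 10L,
                           transversions = 5L))
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got, 0.1701811651403470, tolerance = 1e-10)
  # identity
  expect_equal(k2p_distance(list(comparable = 10L, transitions = 0L,
                                 transversions = 0L)), 0)
  # log-domain boundaries are undefined, not errors
  expect_true(is.na(k2p_distance(list(comparable = 10L, transitions = 5L,
                                      transversions = 0L))))
  expect_true(is.na(k2p_distance(list(comparable = 10L, transitions = 0L,
                                      transversions = 5L))))
  expect_error(k2p_distance(list(comparable = 0L, transitions = 0L,
                                 transversions = 0L)), "no comparable")
})

test_that("K2p dominates p and is invariant to swap and complement", {
  set.seed(31)
  nuc <- c("A", "C", "G", "T")
  compl <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:20) {
    a <- sample(nuc, 300, replace = TRUE)
    b <- a
    mut <- sample(300, 25)
    b[mut] <- sample(nuc, 25, replace = TRUE)
    sc <- site_counts(a, b)
    k <- k2p_distance(sc)
    p <- p_distance(sc)
    if (!is.na(k) && sc$transitions > 0 && sc$transversions > 0) {
      expect_gt(k, p)
    }
    expect_identical(site_counts(b, a), sc[c(1, 2, 3)])
    expect_identical(site_counts(unname(compl[a]), unname(compl[b])), sc)
  }
  # k2p converges to p at low divergence
  sc <- site_counts(c(rep("A", 999), "G"), rep("A", 1000))
  expect_lt(abs(k2p_distance(sc) / p_distance(sc) - 1), 0.01)
})

test_that("distance matrix equals a per-pair oracle and ape::dist.dna", {
  sim <- small_sim()
  aln <- subset_records(sim$alignment, sim$alignment$meta$id[1:10])
  for (model in c("k2p", "p")) {
    dmat <- distance_matrix(aln, model)
    expect_identical(dmat$d, t(dmat$d))
    expect_identical(unname(diag(dmat$d)), rep(0, 10))
    # element-wise brute force via the single-pair path
    for (i in 1:9) for (j in (i + 1):10) {
      sc <- site_counts(aln$seqs[i, ], aln$seqs[j, ])
      ref <- if (model == "k2p") k2p_distance(sc) else p_distance(sc)
      expect_equal(dmat$d[i, j], ref, tolerance = 1e-12)
    }
  }
  # independent implementation check (ape, pairwise deletion)
  dnab <- ape::as.DNAbin(tolower(aln$seqs))
  ref_k80 <- as.matrix(ape::dist.dna(dnab, model = "K80",
                                     pairwise.deletion = TRUE))
  got <- distance_matrix(aln, "k2p")$d
  expect_equal(got, ref_k80[rownames(got), colnames(got)],
               tolerance = 1e-9)
})

test_that("p model never yields undefined entries", {
  sim <- small_sim()
  dmat <- distance_matrix(sim$alignment, "p")
  expect_identical(dmat$n_undefined, 0L)
  expect_false(anyNA(dmat$d))
  expect_true(all(dmat$d >= 0 & dmat$d <= 1))
})

test_that("K2p estimates are unbiased on sequences evolved at known d", {
  # pair separated by total path d, 200 replicates, length 600
  for (d in c(0.05, 0.15, 0.30)) {
    cfg <- sim_config(n_families = 1, genera_per_family = 1,
                      species_per_genus = 2, seq_length = 600,
                      planted_candidates = NULL, stop_free = FALSE,
                      seed = 1)
    set.seed(900 + round(1000 * d))
    ests <- replicate(200, {
      truth <- manual_truth(
        sprintf("(a:%f,b:%f);", d / 2, d / 2),
        simple_taxonomy(c("a", "b")))
      aln <- evolve_sequences(truth, cfg)
      k2p_distance(site_counts(aln$seqs[1, ], aln$seqs[2, ]))
    })
    se <- sd(ests) / sqrt(length(ests))
    expect_lt(abs(mean(ests) - d), 3 * se + 1e-9)
  }
})

test_that("saturation table shows P plateauing while Q keeps rising", {
  cfg <- sim_config(n_families = 1, genera_per_family = 1,
                    species_per_genus = 2, seq_length = 664, kappa = 8,
                    planted_candidates = NULL, seed = 1)
  ds <- rep(c(0.05, 0.2, 0.4, 0.8, 1.2, 1.6), each = 15)
  set.seed(77)
  res <- t(vapply(ds, function(d) {
    truth <- manual_truth(sprintf("(a:%f,b:%f);", d / 2, d / 2),
                          simple_taxonomy(c("a", "b")))
    aln <- evolve_sequences(truth, cfg)
    sc <- site_counts(aln$seqs[1, ], aln$seqs[2, ])
    c(P = sc$transitions / sc$comparable,
      Q = sc$transversions / sc$comparable)
  }, c(P = 0, Q = 0)))
  # transversions accumulate monotonically with divergence time
  expect_gt(cor(ds, res[, "Q"], method = "spearman"), 0.5)
  # transitions rise early then saturate
  mean_P <- tapply(res[, "P"], ds, mean)
  expect_gt(mean_P[["0.4"]], mean_P[["0.05"]])
  expect_lt(abs(mean_P[["1.6"]] - mean_P[["0.8"]]), 0.05)
})

test_that("saturation table has one row per pair with P, Q and K2p", {
  sim <- small_sim()
  aln <- subset_records(sim$alignment, sim$alignment$meta$id[1:5])
  tab <- saturation_table(aln)
  expect_identical(nrow(tab), 10L)
  i <- which(tab$id_a == aln$meta$id[1] & tab$id_b == aln$meta$id[2])
  sc <- site_counts(aln$seqs[1, ], aln$seqs[2, ])
  expect_equal(tab$P[i], sc$transitions / sc$comparable)
  expect_equal(tab$Q[i], sc$transversions / sc$comparable)
  # identical pair gives the zero row
  dup <- coi_alignment(
    rbind(x = aln$seqs[1, ], y = aln$seqs[1, ]),
    data.frame(id = c("x", "y"), species = c("G x", "G y"), genus = "G",
               family = "F", stringsAsFactors = FALSE))
  expect_equal(unlist(saturation_table(dup)[1, c("k2p", "P", "Q")],
                      use.names = FALSE), c(0, 0, 0))
})

test_that("distance matrices round-trip through the TSV writers", {
  sim <- small_sim()
  aln <- subset_records(sim$alignment, sim$alignment$meta$id[1:6])
  dmat <- distance_matrix(aln, "k2p")
  sq <- withr::local_tempfile(fileext = ".tsv")
  lg <- withr::local_tempfile(fileext = ".tsv")
  write_distance_tsv(dmat, sq, "square")
  write_distance_tsv(dmat, lg, "long")
  back_sq <- read.delim(sq, row.names = 1, check.names = FALSE)
  expect_equal(as.matrix(back_sq), dmat$d, tolerance = 1e-12)
  back_lg <- read.delim(lg)
  expect_identical(nrow(back_lg), 15L)
  expect_equal(back_lg$distance[1],
               dmat$d[back_lg$id_a[1], back_lg$id_b[1]],
               tolerance = 1e-12)
})
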