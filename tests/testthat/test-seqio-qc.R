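test_that("FASTA + metadata round-trip reproduces identical records", {
  sim <- small_sim()
  aln <- sim$alignment
  fa <- withr::local_tempfile(fileext = ".fasta")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_coi_data(aln, fa, tsv)
  back <- read_coi_data(fa, tsv)
  expect_identical(back$seqs, aln$seqs)
  expect_identical(back$meta$id, aln$meta$id)
  expect_identical(back$meta$species, aln$meta$species)
  expect_identical(back$meta$status, aln$meta$status)
})

test_that("metadata contract is enforced", {
  seqs <- c(a = "ACGTACGT", b = "ACGTACGT")
  meta <- data.frame(id = "a", species = "G s", genus = "G", family = "F",
                     stringsAsFactors = FALSE)
  expect_error(coi_alignment(seqs, meta), "no metadata row for id: b")
  # duplicate sequence id
  m2 <- rbind(meta, data.frame(id = "b", species = "G t", genus = "G",
                               family = "F"))
  seqs_dup <- matrix("A", 2, 4, dimnames = list(c("a", "a"), NULL))
  expect_error(coi_alignment(seqs_dup, m2), "duplicate id: a")
  # ragged alignment
  expect_error(coi_alignment(c(a = "ACGT", b = "ACG"), m2), "ragged")
  # unknown status value
  m3 <- m2
  m3$status <- c("nominal", "mystery")
  expect_error(coi_alignment(c(a = "ACGT", b = "ACGT"), m3),
               "unknown status value: mystery")
})

test_that("candidate status is inferred from sp./aff. markers", {
  seqs <- c(a = "ACGT", b = "ACGT", c = "ACGT")
  meta <- data.frame(
    id = c("a", "b", "c"),
    species = c("Phelsuma sp. aff. lineata", "Phelsuma lineata",
                "Phelsuma grandis"),
    genus = "Phelsuma", family = "Gekkonidae", stringsAsFactors = FALSE)
  aln <- coi_alignment(seqs, meta)
  expect_identical(aln$meta$status, c("candidate", "nominal", "nominal"))
  # markers are matched as tokens, not substrings
  m2 <- meta
  m2$species <- c("Phelsuma spectabilis", "Phelsuma affinis", "P. l sp.")
  aln2 <- coi_alignment(seqs, m2)
  expect_identical(aln2$meta$status, c("nominal", "nominal", "candidate"))
})

test_that("length filter counts non-gap bases with a 600 bp boundary", {
  base <- strrep("ACGT", 166)  # 664 columns
  seqs <- c(
    full = base,
    at600 = paste0(strrep("-", 64), substr(base, 65, 664)),
    at599 = paste0(strrep("-", 65), substr(base, 66, 664)),
    gaps = strrep("-", 664))
  meta <- data.frame(id = names(seqs), species = paste("G", names(seqs)),
                     genus = "G", family = "F", stringsAsFactors = FALSE)
  ok <- length_filter(coi_alignment(seqs, meta))
  expect_identical(unname(ok), c(TRUE, TRUE, FALSE, FALSE))
})

test_that("frame detection recovers the simulated frame and shifts", {
  sim <- small_sim()
  aln <- sim$alignment
  expect_identical(detect_frame(aln), 0L)
  # removing the first column moves the first complete codon to offset 2
  shifted <- coi_alignment(aln$seqs[, -1], aln$meta)
  expect_identical(detect_frame(shifted), 2L)
  expect_error(detect_frame(subset_records(aln, character(0))))
})

test_that("stop codon screen flags internal stops under the chosen code", {
  # in-frame TAA and AGA (stops in the vertebrate mito code) mid-sequence
  seqs <- c(
    clean = "ATGCTACTAGCAATT",
    taa   = "ATGTAACTAGCAATT",
    aga   = "ATGAGACTAGCAATT",
    # TAA spans codons 2-3 (columns 5-7, out of frame); in-frame codons
    # ATG TTA ACT GCA are all sense codons
    spanning = "ATGTTAACTGCAATT",
    # stop codon containing a gap is skipped
    gapped = "ATGTA-CTAGCAATT",
    # terminal complete codon may be a stop
    terminal = "ATGCTACTAGCATAA")
  meta <- data.frame(id = names(seqs), species = paste("G", names(seqs)),
                     genus = "G", family = "F", stringsAsFactors = FALSE)
  aln <- coi_alignment(seqs, meta)
  ok <- stop_codon_filter(aln)
  expect_identical(unname(ok), c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  # AGA is NOT a stop under the standard nuclear code
  aln_std <- coi_alignment(seqs, meta, code_table = "standard")
  expect_true(stop_codon_filter(aln_std)[["aga"]])
  expect_error(coi_alignment(seqs, meta, code_table = "insect-mito"),
               "unknown code_table")
})

test_that("stop codon screen agrees with a brute-force codon scan", {
  set.seed(7)
  nuc <- c("A", "C", "G", "T")
  n <- 15
  L <- 60
  seqs <- matrix(sample(c(nuc, "-"), n * L, replace = TRUE,
                        prob = c(rep(0.23, 4), 0.08)),
                 n, L, dimnames = list(sprintf("r%02d", 1:n), NULL))
  meta <- data.frame(id = rownames(seqs),
                     species = paste("G", rownames(seqs)),
                     genus = "G", family = "F", stringsAsFactors = FALSE)
  aln <- coi_alignment(seqs, meta)
  got <- stop_codon_filter(aln)
  stops <- c("TAA", "TAG", "AGA", "AGG")
  for (i in seq_len(n)) {
    has_stop <- FALSE
    n_codons <- L %/% 3
    for (ci in seq_len(n_codons - 1)) {   # internal codons only
      cod <- paste(seqs[i, (3 * ci - 2):(3 * ci)], collapse = "")
      if (grepl("^[ACGT]{3}$", cod) && cod %in% stops) has_stop <- TRUE
    }
    expect_identical(unname(got[i]), !has_stop)
  }
})

test_that("divergence outliers are records far from everything", {
  sim <- small_sim()
  aln <- sim$alignment
  set.seed(42)
  # plant a random non-homologous sequence
  junk <- matrix(sample(c("A", "C", "G", "T"), n_columns(aln),
                        replace = TRUE), nrow = 1,
                 dimnames = list("junk", NULL))
  meta2 <- rbind(aln$meta,
                 data.frame(id = "junk", species = "X x", genus = "X",
                            family = "X", status = "nominal",
                            voucher = NA, locality = NA))
  aln2 <- coi_alignment(rbind(aln$seqs, junk), meta2)
  dmat <- suppressWarnings(distance_matrix(aln2, "k2p"))
  ok <- divergence_outlier_filter(aln2, dmat, cutoff = 0.35)
  expect_false(ok[["junk"]])
  # oracle: the rule is exactly min distance vs cutoff, undefined
  # distances treated as beyond any cutoff
  d <- dmat$d
  diag(d) <- NA
  expected <- apply(d, 1, function(x) {
    if (all(is.na(x))) FALSE else min(x, na.rm = TRUE) <= 0.35
  })
  expect_identical(unname(ok), unname(expected[names(ok)]))
  # a duplicate of an existing record has min distance 0
  dup <- aln$seqs[1, , drop = FALSE]
  rownames(dup) <- "dup"
  meta3 <- rbind(aln$meta,
                 data.frame(id = "dup", species = aln$meta$species[1],
                            genus = aln$meta$genus[1],
                            family = aln$meta$family[1],
                            status = "nominal", voucher = NA,
                            locality = NA))
  aln3 <- coi_alignment(rbind(aln$seqs, dup), meta3)
  d3 <- distance_matrix(aln3, "k2p")
  expect_true(all(divergence_outlier_filter(aln3, d3, cutoff = 0.35)))
  # infinite cutoff flags nothing
  expect_true(all(divergence_outlier_filter(aln2, dmat, cutoff = Inf)))
  expect_error(divergence_outlier_filter(subset_records(aln, aln$meta$id[1]),
                                         dmat), "at least 2")
})

test_that("QC reports are order-independent and reasons accumulate", {
  sim <- small_sim()
  aln <- sim$alignment
  # corrupt two records: one too short, one with an internal stop
  seqs <- aln$seqs
  seqs[1, 101:664] <- "-"
  seqs[2, 31:33] <- c("T", "A", "A")
  aln2 <- coi_alignment(seqs, aln$meta)
  rep1 <- suppressWarnings(qc_report(aln2))
  expect_s3_class(rep1, "coi_qc")
  expect_false(rep1$passed[1])
  expect_true("too_short" %in% rep1$reasons[[1]])
  expect_false(rep1$passed[2])
  expect_true("internal_stop" %in% rep1$reasons[[2]])
  expect_true(all(rep1$passed[-(1:2)]))
  # permuting the records permutes but does not change outcomes
  set.seed(5)
  perm <- sample(rownames(seqs))
  rep2 <- suppressWarnings(qc_report(subset_records(aln2, perm)))
  m <- match(rep1$id, rep2$id)
  expect_identical(rep1$passed, rep2$passed[m])
  expect_identical(lapply(rep1$reasons, sort),
                   lapply(rep2$reasons[m], sort))
})

test_that("QC report writer emits semicolon-joined reasons", {
  sim <- small_sim()
  aln <- sim$alignment
  seqs <- aln$seqs
  seqs[1, 101:664] <- "-"
  rep1 <- suppressWarnings(qc_report(coi_alignment(seqs, aln$meta)))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_qc_report(rep1, out)
  back <- read.delim(out, stringsAsFactors = FALSE)
  expect_identical(nrow(back), nrow(rep1))
  expect_identical(back$reasons[match(rep1$id[1], back$id)], "too_short")
})
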