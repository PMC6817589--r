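test_that("k-mer enumeration emits every canonical window with provenance", {
  prot <- data.frame(protein_id = "P1", gene_symbol = "G1",
                     sequence = paste(rep("ACDEFGHIKL", 2), collapse = ""))
  km <- enumerate_kmers(prot, k = 9)
  expect_equal(km$n_windows, 12L)
  expect_lte(length(km$peptides), 12L)
  expect_equal(nrow(km$provenance) + km$n_skipped, km$n_windows)

  # duplicate sequence across proteins merges with both provenances
  dup <- data.frame(protein_id = c("P1", "P2"), gene_symbol = c("G1", "G2"),
                    sequence = c("AASLLMWITQCAA", "TTSLLMWITQCTT"))
  km2 <- enumerate_kmers(dup, k = 9)
  expect_true("SLLMWITQC" %in% km2$peptides)
  prov <- km2$provenance[km2$provenance$peptide == "SLLMWITQC", ]
  expect_equal(sort(prov$protein_id), c("P1", "P2"))
  expect_equal(prov$start, c(3L, 3L))

  # a non-canonical letter knocks out exactly the windows covering it
  withx <- data.frame(protein_id = "P1", gene_symbol = "G1",
                      sequence = "AAAAXAAAAAAAA")  # 13 aa, 5 windows, X at 5
  km3 <- enumerate_kmers(withx, k = 9)
  expect_equal(km3$n_windows, 5L)
  expect_equal(km3$n_skipped, 5L)
  expect_length(km3$peptides, 0L)
})

test_that("window accounting reconciles over a multi-protein set", {
  set.seed(11)
  prot <- data.frame(protein_id = sprintf("P%d", 1:20),
                     gene_symbol = sprintf("G%d", 1:20),
                     sequence = random_peptide(20, k = 50))
  km <- enumerate_kmers(prot, k = 9)
  expect_equal(km$n_windows, sum(pmax(0, nchar(prot$sequence) - 9 + 1)))
  expect_equal(nrow(km$provenance), km$n_windows - km$n_skipped)
  expect_setequal(km$peptides, unique(km$provenance$peptide))
})

test_that("affinity filtering is boundary-inclusive and counts drops", {
  aff <- c(A = 100, B = 600, C = 500)
  names(aff) <- c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD")
  kept <- filter_by_affinity(names(aff), aff, 500)
  expect_setequal(as.character(kept), c("AAAAAAAAA", "DDDDDDDDD"))
  expect_equal(attr(kept, "n_above_cutoff"), 1L)
  expect_equal(attr(kept, "n_unpredicted"), 0L)

  none <- filter_by_affinity(names(aff), setNames(numeric(), character()))
  expect_length(none, 0L)
  expect_equal(attr(none, "n_unpredicted"), 3L)

  all_kept <- filter_by_affinity(names(aff), aff, Inf)
  expect_length(all_kept, 3L)
})

test_that("ranking is deterministic with lexicographic tie-breaks", {
  sc <- synthetic_scenario(noise_cv = 0, replicates = 1)
  kern <- make_kernel(sc)
  ms <- simulate_measurements(kern, sc)
  fp <- tcr_fingerprint(ms, sc$epitope, sc$anchors)

  set.seed(5)
  peptides <- c(random_peptide(50), sc$epitope, "SGLMWITQG")
  ranked <- rank_peptides(fp, peptides)
  # the scanning epitope scores 1.0; its anchor-variant ties at 1.0 and the
  # lexicographically smaller sequence wins the tie
  expect_equal(ranked$combined[1:2], c(1, 1))
  expect_equal(ranked$peptide[1:2], sort(c(sc$epitope, "SGLMWITQG")))

  shuffled <- rank_peptides(fp, sample(peptides))
  expect_identical(ranked$peptide, shuffled$peptide)
  expect_identical(ranked$rank, seq_len(nrow(ranked)))
})

test_that("score bins produce per-position frequency motifs", {
  scored <- data.frame(peptide = c("SLLMWITQV", "ALLMWITQV", "AAAAAAAAA"),
                       combined = c(0.95, 0.90, 0.30))
  motifs <- bin_motifs(scored)
  expect_length(motifs, 5L)
  top <- motifs[[5]]
  expect_equal(top$n_peptides, 2L)
  expect_equal(unname(rowSums(top$counts)), rep(2, 9))
  expect_equal(unname(rowSums(top$frequencies)), rep(1, 9))
  expect_equal(top$counts["5", "W"], 2L)
  expect_equal(unname(top$frequencies["1", c("S", "A")]), c(0.5, 0.5))

  # one-peptide bin is one-hot; empty bin flagged with NA frequencies
  low <- motifs[[1]]
  expect_equal(low$n_peptides, 1L)
  expect_true(all(low$frequencies %in% c(0, 1)))
  expect_equal(motifs[[2]]$n_peptides, 0L)
  expect_true(all(is.na(motifs[[2]]$frequencies)))

  oob <- data.frame(peptide = "AAAAAAAAA", combined = 0.1)
  expect_equal(attr(bin_motifs(oob), "n_out_of_range"), 1L)
  expect_error(bin_motifs(scored, bin_edges = c(0.5, 0.4)), "increasing")
})

test_that("top-bin motif recovers the kernel's critical residues", {
  sc <- synthetic_scenario(noise_cv = 0, replicates = 1)
  kern <- make_kernel(sc)
  planted <- plant_peptides(kern, 12, seed = 77)
  motifs <- bin_motifs(data.frame(peptide = planted$peptide,
                                  combined = planted$intended_score))
  top <- motifs[[5]]
  expect_equal(top$n_peptides, 12L)
  # modal residues at the critical positions match the epitope
  expect_equal(AMINO_ACIDS[which.max(top$counts["5", ])], "W")
  expect_equal(AMINO_ACIDS[which.max(top$counts["8", ])], "Q")
})

test_that("expression annotation reports max TPM and tissue counts", {
  expr <- data.frame(liver = c(50, 0.2), brain = c(0, 12),
                     row.names = c("COG7", "NYESO1"))
  scored <- data.frame(peptide = c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD"),
                       combined = c(0.9, 0.8, 0.7),
                       genes = c("COG7", "COG7;NYESO1", "UNKNOWN"))
  ann <- annotate_expression(scored, expr, tpm_threshold = 10)
  expect_equal(ann$max_tpm, c(50, 50, NA))
  expect_equal(ann$tissues_above_tpm, c(1L, 2L, NA_integer_))
  expect_equal(ann$expression_flag,
               c("ok", "ok", "no-expression-data"))
})
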