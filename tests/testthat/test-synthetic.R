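test_that("every generator output is a pure function of scenario and seed", {
  sc <- synthetic_scenario(n_proteins = 30, protein_length = 60,
                           n_planted = 3)
  expect_identical(make_kernel(sc)$weights, make_kernel(sc)$weights)
  expect_identical(simulate_measurements(make_kernel(sc), sc),
                   simulate_measurements(make_kernel(sc), sc))
  expect_identical(simulate_proteome(sc), simulate_proteome(sc))
  peps <- replacement_library(sc$epitope)
  expect_identical(simulate_affinity(peps, seed = 1),
                   simulate_affinity(peps, seed = 1))
  sc2 <- synthetic_scenario(seed = 1, n_proteins = 30, protein_length = 60)
  expect_false(identical(make_kernel(sc)$weights, make_kernel(sc2)$weights))
})

test_that("the truth kernel encodes critical and tolerant positions", {
  sc <- synthetic_scenario()
  kern <- make_kernel(sc)
  w <- kern$weights
  epi <- strsplit(sc$epitope, "")[[1]]
  for (p in sc$critical_positions) {
    other <- setdiff(AMINO_ACIDS, epi[p])
    expect_true(all(w[other, as.character(p)] <= 10))
  }
  expect_true(all(w[cbind(epi[kern$positions],
                          as.character(kern$positions))] == 100))
  # any peptide deviating at both critical positions is capped at
  # (5*100 + 2*10) / 700
  set.seed(2)
  devs <- vapply(1:50, function(i) {
    v <- epi
    v[5] <- sample(setdiff(AMINO_ACIDS, epi[5]), 1)
    v[8] <- sample(setdiff(AMINO_ACIDS, epi[8]), 1)
    paste(v, collapse = "")
  }, character(1))
  expect_true(all(score_peptides(kern, devs) <= (5 * 100 + 2 * 10) / 700))

  flat <- make_kernel(sc, critical_positions = integer())
  expect_true(all(flat$weights >= 10))
})

test_that("noiseless measurements round-trip the kernel through build_pwm", {
  sc <- synthetic_scenario(noise_cv = 0, replicates = 1)
  kern <- make_kernel(sc)
  ms <- simulate_measurements(kern, sc, assays = "activation")
  rec <- build_pwm(ms, "activation", sc$epitope, sc$anchors)
  expect_equal(rec$weights, kern$weights, tolerance = 1e-12)
})

test_that("recovered fingerprints track the kernel under replicate noise", {
  sc <- synthetic_scenario()  # 3 replicates, 10% CV
  kern <- make_kernel(sc)
  ms <- simulate_measurements(kern, sc)
  fp <- tcr_fingerprint(ms, sc$epitope, sc$anchors)
  sims <- vapply(fp$pwms, pwm_similarity, numeric(1), b = kern)
  expect_true(all(sims >= 0.95))
  # inter-assay concordance mirrors the shared kernel
  pairs <- utils::combn(names(fp$pwms), 2)
  inter <- apply(pairs, 2, function(p) {
    pwm_similarity(fp$pwms[[p[1]]], fp$pwms[[p[2]]])
  })
  expect_true(all(inter >= 0.9))
})

test_that("synthetic proteomes embed planted peptides at recorded positions", {
  sc <- synthetic_scenario(n_proteins = 40, protein_length = 80,
                           n_planted = 5)
  prot <- simulate_proteome(sc)
  expect_equal(nrow(prot$proteins), 40L)
  expect_true(all(nchar(prot$proteins$sequence) == 80L))
  expect_equal(prot$truth$peptide[1], sc$epitope)
  km <- enumerate_kmers(prot$proteins, k = 9)
  for (j in seq_len(nrow(prot$truth))) {
    prov <- km$provenance[km$provenance$peptide == prot$truth$peptide[j], ]
    expect_true(prot$truth$protein_id[j] %in% prov$protein_id)
    expect_true(prot$truth$start[j] %in%
                  prov$start[prov$protein_id == prot$truth$protein_id[j]])
  }
  none <- simulate_proteome(synthetic_scenario(n_proteins = 10,
                                               protein_length = 40,
                                               n_planted = 0))
  expect_equal(nrow(none$truth), 0L)
  expect_error(simulate_proteome(synthetic_scenario(protein_length = 5)),
               "longer")
})

test_that("synthetic affinities follow the anchor rule", {
  aff <- simulate_affinity(c("SLLMWITQV", "SGLMWITQV", "SLLMWITQG"), seed = 4)
  expect_lte(aff[["SLLMWITQV"]], 500)
  expect_gt(aff[["SGLMWITQV"]], 500)   # P2 = G violates the rule
  expect_gt(aff[["SLLMWITQG"]], 500)   # P9 = G violates the rule

  # binder fraction on random decoys matches the combinatorial rule
  # probability (2/20 * 3/20 = 0.015) within 3 standard errors
  set.seed(5)
  decoys <- unique(random_peptide(20000))
  aff2 <- simulate_affinity(decoys, seed = 6)
  p_hat <- mean(aff2 <= 500)
  p <- (2 / 20) * (3 / 20)
  se <- sqrt(p * (1 - p) / length(decoys))
  expect_lt(abs(p_hat - p), 3 * se)

  # planted peptides keep their anchors, hence always pass the filter
  sc <- synthetic_scenario()
  planted <- plant_peptides(make_kernel(sc), 10, seed = sc$seed + 1)
  aff3 <- simulate_affinity(planted$peptide, seed = sc$seed)
  expect_true(all(aff3 <= 500))
  expect_true(all(planted$intended_score > 0.9))
})

test_that("simulated outcomes separate activators perfectly at zero flip rate", {
  set.seed(8)
  scored <- data.frame(peptide = random_peptide(100),
                       combined = c(runif(20, 0.92, 1), runif(80, 0.2, 0.8)))
  out <- simulate_outcomes(scored, true_cutoff = 0.9, flip_rate = 0, seed = 9)
  expect_equal(out$label, scored$combined >= 0.9)
  roc <- roc_curve(out$score, out$label)
  expect_equal(roc$auc, 1.0)
  cut <- select_cutoff(roc)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)

  # label noise leaves the ranking informative even if cutoff must drop
  noisy <- simulate_outcomes(scored, true_cutoff = 0.9, flip_rate = 0.1,
                             seed = 9)
  expect_gt(roc_curve(noisy$score, noisy$label)$auc, 0.75)
  expect_identical(noisy, simulate_outcomes(scored, true_cutoff = 0.9,
                                            flip_rate = 0.1, seed = 9))
  expect_error(simulate_outcomes(scored, flip_rate = 0.6), "flip_rate")
})
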