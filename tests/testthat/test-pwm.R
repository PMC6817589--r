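test_that("build_pwm normalizes, trims and zeroes per the replacement-scan model", {
  W <- matrix(50, nrow = 20, ncol = 7,
              dimnames = list(AMINO_ACIDS, c(1, 3:8)))
  W["A", 1] <- 100    # variant mean equal to epitope mean
  W["C", 1] <- 120    # exceeds the epitope -> trimmed
  W["D", 1] <- -10    # below background -> zeroed
  ms <- measurements_from_weights(W, "SLLMWITQV")
  pwm <- build_pwm(ms, "binding", "SLLMWITQV")
  expect_equal(pwm$weights["A", "1"], 100)
  expect_equal(pwm$weights["C", "1"], 100)
  expect_equal(pwm$weights["D", "1"], 0)
  expect_equal(pwm$weights["G", "4"], 50)
  expect_equal(ncol(pwm$weights), 7L)
  expect_identical(pwm$positions, c(1L, 3:8))
  # epitope residues pinned at 100 on every scored position
  epi <- strsplit("SLLMWITQV", "")[[1]]
  expect_true(all(pwm$weights[cbind(epi[pwm$positions],
                                    as.character(pwm$positions))] == 100))
  expect_true(all(pwm$weights >= 0 & pwm$weights <= 100))
})

test_that("background subtraction is per replicate, before averaging", {
  # replicate-specific backgrounds: subtracting the mean background instead
  # would give a different ratio
  ms <- measurement_set(data.frame(
    peptide = rep(c("SLLMWITQV", "ALLMWITQV"), each = 2),
    assay = "binding",
    replicate_id = c("r1", "r2", "r1", "r2"),
    signal = c(52, 42, 27, 22),
    background = c(2, 2, 2, 2)))
  pwm <- build_pwm(ms, "binding", "SLLMWITQV",
                   on_missing = "impute") |> suppressWarnings()
  # L_epitope = mean(50, 40) = 45; L_A1 = mean(25, 20) = 22.5 -> W = 50
  expect_equal(pwm$weights["A", "1"], 50)
})

test_that("build_pwm is invariant to replicate order and uniform rescaling", {
  sc <- synthetic_scenario(replicates = 3, noise_cv = 0.08)
  kern <- make_kernel(sc)
  ms <- simulate_measurements(kern, sc, assays = "binding")
  ref <- build_pwm(ms, "binding", sc$epitope, sc$anchors)

  shuffled <- measurement_set(ms[sample.int(nrow(ms)), ])
  expect_equal(build_pwm(shuffled, "binding", sc$epitope,
                         sc$anchors)$weights, ref$weights)

  scaled <- ms
  scaled$signal <- scaled$signal * 3.7
  scaled$background <- scaled$background * 3.7
  expect_equal(build_pwm(measurement_set(scaled), "binding", sc$epitope,
                         sc$anchors)$weights, ref$weights)
})

test_that("build_pwm rejects degenerate and malformed inputs", {
  W <- matrix(50, nrow = 20, ncol = 7,
              dimnames = list(AMINO_ACIDS, c(1, 3:8)))
  ms <- measurements_from_weights(W, "SLLMWITQV")
  expect_error(build_pwm(ms, "staining", "SLLMWITQV"), "assay")

  # epitope signal at background level -> degenerate normalization
  flat <- measurement_set(data.frame(
    peptide = "SLLMWITQV", assay = "binding", replicate_id = "r1",
    signal = 2, background = 2))
  expect_error(build_pwm(flat, "binding", "SLLMWITQV"), "degenerate")

  # variant substituting an anchor position
  anchor_var <- measurement_set(data.frame(
    peptide = c("SLLMWITQV", "SALMWITQV"), assay = "binding",
    replicate_id = "r1", signal = c(50, 30), background = 2))
  expect_error(build_pwm(anchor_var, "binding", "SLLMWITQV"), "anchor")

  # variant two substitutions away
  double <- measurement_set(data.frame(
    peptide = c("SLLMWITQV", "ALAMWITQV"), assay = "binding",
    replicate_id = "r1", signal = c(50, 30), background = 2))
  expect_error(build_pwm(double, "binding", "SLLMWITQV"), "ALAMWITQV")
})

test_that("unmeasured cells impute to zero with a warning, or hard-error", {
  ms <- measurement_set(data.frame(
    peptide = c("SLLMWITQV", "ALLMWITQV"), assay = "binding",
    replicate_id = "r1", signal = c(52, 27), background = 2))
  expect_warning(pwm <- build_pwm(ms, "binding", "SLLMWITQV"), "imputed")
  expect_equal(pwm$weights["A", "1"], 50)
  expect_equal(pwm$weights["C", "1"], 0)
  expect_error(build_pwm(ms, "binding", "SLLMWITQV", on_missing = "error"),
               "unmeasured")
})

test_that("pwm_similarity is symmetric plain Pearson over flattened cells", {
  a <- random_pwm(21)
  expect_equal(pwm_similarity(a, a), 1.0)

  b <- a
  b$weights <- 100 - a$weights
  expect_equal(pwm_similarity(a, b), -1.0)

  d <- random_pwm(22)
  # hand-coded covariance/variance Pearson on the flattened vectors
  x <- as.vector(a$weights); y <- as.vector(d$weights)
  n <- length(x)
  covxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  oracle <- covxy / sqrt(sum((x - mean(x))^2) / (n - 1) *
                           sum((y - mean(y))^2) / (n - 1))
  expect_equal(pwm_similarity(a, d), oracle, tolerance = 1e-10)
  expect_equal(pwm_similarity(a, d), pwm_similarity(d, a))

  short <- random_pwm(23, epitope = "SLLMWITV", anchors = c(2, 8))
  expect_error(pwm_similarity(a, short), "mismatch")
})

test_that("alanine-scan PWMs mark permissive positions as fully tolerant", {
  positions <- c(1, 3:8)
  all_perm <- build_alanine_pwm(setNames(rep(1, 7), positions), "SLLMWITQV")
  set.seed(31)
  expect_true(all(score_peptides(all_perm, random_peptide(20)) == 1))

  none <- build_alanine_pwm(setNames(rep(0, 7), positions), "SLLMWITQV")
  expect_equal(score_peptides(none, "SLLMWITQV"), 1)
  expect_equal(score_peptides(none, "ALLMWITQV"), 6 / 7)

  expect_error(build_alanine_pwm(setNames(rep(0, 6), positions[-1]),
                                 "SLLMWITQV"), "position")
  expect_error(build_alanine_pwm(setNames(rep(0, 7), positions), "SLLMWITQV",
                                 permissive_threshold = 0), "threshold")
})

test_that("alanine PWM scores peptides by permissive-position membership", {
  # EVDPIGHLY scanned with anchors 2 and 9; alanine retains signal only at
  # positions 1, 6 and 7 -> those become fully permissive
  positions <- c(1, 3:8)
  vals <- setNames(c(0.9, 0.1, 0, 0.2, 0.8, 0.7, 0.05), positions)
  pwm <- build_alanine_pwm(vals, "EVDPIGHLY", permissive_threshold = 0.5)
  permissive <- c(1, 6, 7)
  epi <- strsplit("EVDPIGHLY", "")[[1]]
  # enumerate all single and double substitutions; brute-force the expected
  # score: 1 iff all substituted positions are permissive
  for (i in setdiff(positions, 0)) {
    for (a in setdiff(c("A", "W", "K"), epi[i])) {
      v <- epi; v[i] <- a
      p1 <- paste(v, collapse = "")
      expect_equal(score_peptides(pwm, p1), brute_score(pwm, p1))
      if (i %in% permissive) expect_equal(score_peptides(pwm, p1), 1)
      for (j in setdiff(positions, i)) {
        v2 <- v; v2[j] <- "F"
        p2 <- paste(v2, collapse = "")
        expect_equal(score_peptides(pwm, p2), brute_score(pwm, p2))
        if (all(c(i, j) %in% permissive) && "F" != epi[j]) {
          expect_equal(score_peptides(pwm, p2), 1)
        }
      }
    }
  }
})

test_that("combined recognition score is the mean of the three assays", {
  expect_equal(combine_scores(1, 1, 1)$combined, 1)
  expect_equal(combine_scores(0.9, 0.8, 1.0)$combined, 0.9)
  expect_equal(combine_scores(0, 0, 0)$combined, 0)
  expect_error(combine_scores(1.2, 0.5, 0.5), "\\[0, 1\\]")
})

test_that("fingerprint methods expose per-assay PWMs and concordance", {
  sc <- synthetic_scenario(replicates = 2, noise_cv = 0.05)
  kern <- make_kernel(sc)
  ms <- simulate_measurements(kern, sc)
  fp <- tcr_fingerprint(ms, sc$epitope, sc$anchors)
  expect_named(fp$pwms, c("binding", "activation", "killing"))
  expect_named(coef(fp), c("binding", "activation", "killing"))
  sm <- summary(fp)
  expect_s3_class(sm, "summary.tcr_fingerprint")
  expect_true(all(sm$pairwise_similarity$pearson > 0.9))

  pred <- predict(fp, c(sc$epitope, "ALLMWITQV"))
  expect_equal(pred$combined,
               rowMeans(cbind(pred$binding, pred$activation, pred$killing)))
  expect_equal(pred$combined[1], 1)
  expect_equal(pred$hamming[1], 0)

  resim <- simulate(fp, nsim = 2, seed = 99)
  expect_s3_class(resim, "measurement_set")
  expect_equal(length(unique(resim$peptide)), 134L)
})
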