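# fixtures and independent oracles shared across the suite

# Build a measurement_set that implies the given weight matrix under the
# replacement-scan model: signal = background + epitope_signal * W/100,
# exactly, with per-replicate backgrounds.  W may exceed [0, 100] to
# exercise clamping.
measurements_from_weights <- function(W, epitope, anchors = c(2, 9),
                                      assay = "binding", replicates = 2,
                                      background = 2, epitope_signal = 50) {
  positions <- as.integer(colnames(W))
  epi_res <- strsplit(epitope, "")[[1]]
  peptides <- epitope
  fracs <- 1
  for (j in seq_along(positions)) {
    for (a in setdiff(rownames(W), epi_res[positions[j]])) {
      v <- epi_res
      v[positions[j]] <- a
      peptides <- c(peptides, paste(v, collapse = ""))
      fracs <- c(fracs, W[a, j] / 100)
    }
  }
  df <- expand.grid(replicate_id = paste0("r", seq_len(replicates)),
                    idx = seq_along(peptides), stringsAsFactors = FALSE)
  measurement_set(data.frame(
    peptide = peptides[df$idx],
    assay = assay,
    replicate_id = df$replicate_id,
    signal = background + epitope_signal * fracs[df$idx],
    background = background))
}

# random PWM with epitope residues pinned at 100
random_pwm <- function(seed, epitope = "SLLMWITQV", anchors = c(2, 9),
                       assay = "binding") {
  set.seed(seed)
  k <- nchar(epitope)
  positions <- setdiff(seq_len(k), anchors)
  w <- matrix(runif(20 * length(positions), 0, 100), nrow = 20,
              dimnames = list(AMINO_ACIDS, positions))
  epi_res <- strsplit(epitope, "")[[1]]
  w[cbind(match(epi_res[positions], AMINO_ACIDS), seq_along(positions))] <- 100
  pwm <- build_alanine_pwm(setNames(rep(0, length(positions)), positions),
                           epitope, anchors)  # shape carrier
  pwm$weights <- w
  pwm$assay <- assay
  pwm
}

# independent brute-force peptide scorer: per-position table lookup and sum
brute_score <- function(pwm, peptide) {
  res <- strsplit(peptide, "")[[1]]
  total <- 0
  for (i in pwm$positions) {
    total <- total + pwm$weights[res[i], as.character(i)]
  }
  total / (100 * length(pwm$positions))
}

# exhaustive pairwise-concordance AUC oracle (0.5 credit for ties)
brute_auc <- function(score, label) {
  pos <- score[label]
  neg <- score[!label]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

random_peptide <- function(n, k = 9) {
  vapply(seq_len(n), function(i) {
    paste(sample(AMINO_ACIDS, k, replace = TRUE), collapse = "")
  }, character(1))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
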