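#' Define a synthetic study scenario
#'
#' Bundles every parameter of the synthetic-data generator: the scanned
#' epitope and its anchors, the planted recognition kernel's critical
#' positions, the replicate/noise structure of the simulated assays, the
#' decoy proteome size, and the synthetic MHC-binding anchor rule.  A
#' scenario plus its seed fully determines every generated dataset.
#'
#' Defaults emulate the NY-ESO-1 study conditions: the anchor-optimized
#' 9-mer SLLMWITQV scanned at all positions except the HLA-A*02:01 anchors
#' P2/P9, with P5 and P8 critical for recognition; three replicates per
#' assay with 10% multiplicative noise and a 2% background; and a decoy
#' proteome of 2,000 proteins of 300 residues carrying 10 planted
#' cross-reactive peptides.
#'
#' @param seed integer master seed (default 20191022).
#' @param epitope scanned reference peptide.
#' @param anchors anchor positions (fixed during the scan).
#' @param critical_positions scored positions where almost no substitution is
#'   tolerated.
#' @param replicates replicates per peptide/assay.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   replicate noise.
#' @param background_level mean background (percent positive cells).
#' @param epitope_signal mean background-corrected epitope signal (percent
#'   positive cells).
#' @param n_proteins,protein_length decoy proteome dimensions.
#' @param n_planted number of planted cross-reactive peptides (the scanning
#'   epitope is always the first).
#' @param anchor_rule named list mapping a 1-based position to the residues
#'   that grant a low synthetic IC50 (binder); default L/M at P2 and V/L/C at
#'   P9, the HLA-A*02:01 convention.
#' @param true_cutoff combined-score threshold above which simulated peptides
#'   activate T cells.
#' @param flip_rate label-noise rate for simulated activation outcomes.
#' @param n_tissues number of tissues in the synthetic expression table.
#' @return an object of class `synthetic_scenario` (a named list).
#' @export
synthetic_scenario <- function(seed = 20191022L,
                               epitope = "SLLMWITQV",
                               anchors = c(2L, 9L),
                               critical_positions = c(5L, 8L),
                               replicates = 3L,
                               noise_cv = 0.1,
                               background_level = 2,
                               epitope_signal = 60,
                               n_proteins = 2000L,
                               protein_length = 300L,
                               n_planted = 10L,
                               anchor_rule = list(`2` = c("L", "M"),
                                                  `9` = c("V", "L", "C")),
                               true_cutoff = 0.9,
                               flip_rate = 0,
                               n_tissues = 37L) {
  check_canonical(epitope, "epitope")
  k <- nchar(epitope)
  anchors <- validate_anchors(anchors, k)
  if (!all(critical_positions %in% setdiff(seq_len(k), anchors))) {
    stop("critical_positions must be scored (non-anchor) positions",
         call. = FALSE)
  }
  stopifnot(replicates >= 1L, noise_cv >= 0, flip_rate >= 0, flip_rate < 0.5)
  structure(list(seed = as.integer(seed), epitope = epitope,
                 anchors = anchors,
                 critical_positions = as.integer(critical_positions),
                 replicates = as.integer(replicates), noise_cv = noise_cv,
                 background_level = background_level,
                 epitope_signal = epitope_signal,
                 n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 n_planted = as.integer(n_planted),
                 anchor_rule = anchor_rule,
                 true_cutoff = true_cutoff, flip_rate = flip_rate,
                 n_tissues = as.integer(n_tissues)),
            class = "synthetic_scenario")
}

#' @export
print.synthetic_scenario <- function(x, ...) {
  cat("Synthetic replacement-scan scenario\n")
  cat(sprintf("  epitope %s, anchors %s, critical %s\n", x$epitope,
              paste(x$anchors, collapse = ","),
              paste(x$critical_positions, collapse = ",")))
  cat(sprintf("  %d replicates, noise CV %.2f, background %.1f%%\n",
              x$replicates, x$noise_cv, x$background_level))
  cat(sprintf("  proteome %d x %d aa, %d planted peptides, seed %d\n",
              x$n_proteins, x$protein_length, x$n_planted, x$seed))
  invisible(x)
}

#' Draw a ground-truth recognition kernel
#'
#' Generates the PWM the simulated assays report on.  Epitope residues weigh
#' 100; at critical positions every other residue weighs at most 10 (almost
#' nothing but the epitope residue is recognized, as with the crucial
#' tryptophan at P5 and glutamine at P8 in the NY-ESO-1 fingerprint); at
#' tolerant positions the other residues draw from a broad uniform
#' distribution on `[10, 100]`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param seed,epitope,anchors,critical_positions individual overrides.
#' @return a [tcr_pwm] with assay label `"truth-kernel"`.
#' @export
make_kernel <- function(scenario = synthetic_scenario(),
                        seed = scenario$seed,
                        epitope = scenario$epitope,
                        anchors = scenario$anchors,
                        critical_positions = scenario$critical_positions) {
  k <- nchar(epitope)
  anchors <- validate_anchors(anchors, k)
  positions <- setdiff(seq_len(k), anchors)
  stopifnot(all(critical_positions %in% positions))
  epi_res <- strsplit(epitope, "")[[1]]
  with_seed(seed, {
    w <- matrix(runif(20L * length(positions), min = 10, max = 100),
                nrow = 20L, dimnames = list(AMINO_ACIDS, positions))
    for (i in critical_positions) {
      j <- match(i, positions)
      w[, j] <- runif(20L, min = 0, max = 10)
    }
    w[cbind(match(epi_res[positions], AMINO_ACIDS),
            seq_along(positions))] <- 100
    new_tcr_pwm(epitope = epitope, anchors = anchors, weights = w,
                assay = "truth-kernel")
  })
}

# mean-one multiplicative lognormal noise with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate replacement-scan measurements from a kernel
#'
#' For every peptide of the replacement library and every assay, the true
#' read-out is `background + epitope_signal * W/100`, where `W` is the
#' kernel cell of the peptide's substitution (100 for the epitope itself).
#' Each replicate multiplies the true signal by mean-one lognormal noise with
#' the scenario's coefficient of variation, and each replicate's matched
#' background control is drawn around the scenario's background level.  With
#' `noise_cv = 0`, [build_pwm()] recovers the kernel exactly.
#'
#' @param kernel a [tcr_pwm] ground-truth kernel (cells in `[0, 100]`).
#' @param scenario a [synthetic_scenario()].
#' @param assays assay labels to simulate (each with an independent noise
#'   stream derived from the scenario seed).
#' @return a [measurement_set()].
#' @export
simulate_measurements <- function(kernel, scenario = synthetic_scenario(),
                                  assays = c("binding", "activation",
                                             "killing")) {
  stopifnot(inherits(kernel, "tcr_pwm"), scenario$replicates >= 1L)
  library_peptides <- replacement_library(kernel$epitope, kernel$anchors)
  # kernel-implied signal fraction of each library peptide: the cell of its
  # single substitution (1 for the epitope)
  k <- nchar(kernel$epitope)
  epi_res <- strsplit(kernel$epitope, "")[[1]]
  pm <- peptide_matrix(library_peptides, k)
  frac <- vapply(seq_along(library_peptides), function(r) {
    d <- which(pm[r, ] != epi_res)
    if (length(d) == 0L) return(1)
    kernel$weights[pm[r, d], as.character(d)] / 100
  }, numeric(1))

  out <- lapply(assays, function(a) {
    seed_a <- scenario$seed + 7919L * match(a, ASSAYS)
    with_seed(seed_a, {
      n <- length(library_peptides) * scenario$replicates
      true_signal <- rep(scenario$background_level +
                           scenario$epitope_signal * frac,
                         each = scenario$replicates)
      signal <- true_signal * lognormal_noise(n, scenario$noise_cv)
      background <- scenario$background_level *
        lognormal_noise(n, scenario$noise_cv)
      data.frame(peptide = rep(library_peptides,
                               each = scenario$replicates),
                 assay = a,
                 replicate_id = paste0("r", seq_len(scenario$replicates)),
                 signal = signal,
                 background = background,
                 stringsAsFactors = FALSE)
    })
  })
  measurement_set(do.call(rbind, out))
}

#' Design planted cross-reactive peptides for a kernel
#'
#' The first planted peptide is the scanning epitope; the rest substitute one
#' to three tolerant (non-anchor, non-critical) positions with residues whose
#' kernel weight is at least `min_weight`, so every planted peptide scores
#' near 1 under the kernel while differing from the epitope in sequence.
#' Anchor residues are untouched, so planted peptides always satisfy the
#' synthetic binder rule.
#'
#' @param kernel a [tcr_pwm] truth kernel.
#' @param n number of planted peptides (including the epitope).
#' @param seed integer seed.
#' @param min_weight minimum kernel weight of a substituting residue.
#' @return data.frame with `peptide` and `intended_score` (kernel score).
#' @export
plant_peptides <- function(kernel, n, seed, min_weight = 90) {
  k <- nchar(kernel$epitope)
  epi_res <- strsplit(kernel$epitope, "")[[1]]
  tolerant <- kernel$positions[
    apply(kernel$weights, 2L, function(col) sum(col >= min_weight) >= 2L)]
  if (length(tolerant) == 0L && n > 1L) {
    stop("kernel has no tolerant positions to plant substitutions at",
         call. = FALSE)
  }
  peptides <- kernel$epitope
  with_seed(seed, {
    guard <- 0L
    while (length(peptides) < n && guard < 1000L) {
      guard <- guard + 1L
      m <- sample.int(min(3L, length(tolerant)), 1L)
      pos <- tolerant[sample.int(length(tolerant), m)]
      v <- epi_res
      for (i in pos) {
        ok <- AMINO_ACIDS[kernel$weights[, as.character(i)] >= min_weight]
        ok <- setdiff(ok, epi_res[i])
        if (length(ok) > 0L) v[i] <- sample(ok, 1L)
      }
      cand <- paste(v, collapse = "")
      if (!cand %in% peptides) peptides <- c(peptides, cand)
    }
  })
  if (length(peptides) < n) {
    stop("could not generate ", n, " distinct planted peptides", call. = FALSE)
  }
  data.frame(peptide = peptides,
             intended_score = score_peptides(kernel, peptides),
             stringsAsFactors = FALSE)
}

#' Simulate a decoy proteome with planted cross-reactive peptides
#'
#' Generates random-composition proteins and embeds each planted peptide at a
#' recorded position in a distinct randomly chosen protein.
#'
#' @param scenario a [synthetic_scenario()].
#' @param kernel truth kernel used to design the planted peptides; defaults
#'   to [make_kernel()] on the scenario.
#' @return list with `proteins` (data.frame: `protein_id`, `gene_symbol`,
#'   `sequence`) and `truth` (data.frame: `peptide`, `intended_score`,
#'   `protein_id`, `start`).
#' @export
simulate_proteome <- function(scenario = synthetic_scenario(),
                              kernel = make_kernel(scenario)) {
  k <- nchar(scenario$epitope)
  if (k > scenario$protein_length) {
    stop("planted peptide longer than protein_length", call. = FALSE)
  }
  planted <- if (scenario$n_planted > 0L) {
    plant_peptides(kernel, scenario$n_planted, seed = scenario$seed + 1L)
  } else {
    data.frame(peptide = character(), intended_score = numeric())
  }
  with_seed(scenario$seed + 2L, {
    seqs <- vapply(seq_len(scenario$n_proteins), function(i) {
      paste(sample(AMINO_ACIDS, scenario$protein_length, replace = TRUE),
            collapse = "")
    }, character(1))
    ids <- sprintf("SYNP%04d", seq_len(scenario$n_proteins))
    genes <- sprintf("SYNG%04d", seq_len(scenario$n_proteins))
    truth <- planted
    if (nrow(planted) > 0L) {
      hosts <- sample(scenario$n_proteins, nrow(planted))
      starts <- sample(scenario$protein_length - k + 1L, nrow(planted),
                       replace = TRUE)
      for (j in seq_len(nrow(planted))) {
        s <- seqs[hosts[j]]
        substr(s, starts[j], starts[j] + k - 1L) <- planted$peptide[j]
        seqs[hosts[j]] <- s
      }
      truth$protein_id <- ids[hosts]
      truth$start <- starts
    }
    list(proteins = data.frame(protein_id = ids, gene_symbol = genes,
                               sequence = seqs, stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Simulate peptide-MHC binding affinities
#'
#' Peptides whose residues at every anchor-rule position are among the
#' allowed residues (e.g. L/M at P2 and V/L/C at P9, mirroring the anchor
#' preference of HLA-A*02:01 binders) draw an IC50 log-uniformly in
#' (1, 500] nM; all other peptides draw in (500, 50000] nM.  Values are
#' assigned in sorted peptide order so the map is invariant to input order.
#'
#' @param peptides character vector of peptides.
#' @param anchor_rule named list: position -> allowed residues.
#' @param seed integer seed.
#' @return named numeric vector of IC50 (nM), one entry per unique peptide.
#' @export
simulate_affinity <- function(peptides,
                              anchor_rule = list(`2` = c("L", "M"),
                                                 `9` = c("V", "L", "C")),
                              seed = 20191022L) {
  peptides <- sort(unique(peptides))
  binder <- rep(TRUE, length(peptides))
  for (pos in names(anchor_rule)) {
    i <- as.integer(pos)
    binder <- binder & substr(peptides, i, i) %in% anchor_rule[[pos]]
  }
  with_seed(seed + 3L, {
    u <- runif(length(peptides))
    ic50 <- ifelse(binder,
                   exp(log(1) + u * (log(500) - log(1))),
                   exp(log(500) + u * (log(50000) - log(500))))
  })
  setNames(ic50, peptides)
}

#' Simulate a gene-by-tissue expression table
#'
#' Lognormal TPM values for each gene across synthetic tissues, emulating a
#' Human Protein Atlas style RNA-consensus table.
#'
#' @param genes character vector of gene symbols.
#' @param n_tissues number of tissues.
#' @param seed integer seed.
#' @return data.frame, rownames = genes, one numeric TPM column per tissue.
#' @export
simulate_expression <- function(genes, n_tissues = 37L, seed = 20191022L) {
  genes <- unique(genes)
  with_seed(seed + 4L, {
    tpm <- matrix(rlnorm(length(genes) * n_tissues,
                         meanlog = log(3), sdlog = 1.5),
                  nrow = length(genes))
  })
  out <- as.data.frame(round(tpm, 3))
  names(out) <- sprintf("tissue_%02d", seq_len(n_tissues))
  rownames(out) <- genes
  out
}

#' Simulate activation outcomes for scored peptides
#'
#' Peptides whose combined recognition score reaches `true_cutoff` activate
#' (normalized activation drawn in a high band), the rest do not (low band);
#' with probability `flip_rate` a peptide's band is flipped, adding label
#' noise.
#'
#' @param scored data.frame with columns `peptide` and `combined` (e.g. from
#'   [rank_peptides()] or [predict.tcr_fingerprint()]).
#' @param true_cutoff combined-score threshold for true activators.
#' @param flip_rate label-noise probability in `[0, 0.5)`.
#' @param seed integer seed.
#' @param activation_threshold threshold defining the boolean label from the
#'   simulated activation fraction (default 0.75).
#' @return data.frame: `peptide`, `score`, `activation_observed`, `label`.
#' @export
simulate_outcomes <- function(scored, true_cutoff = 0.9, flip_rate = 0,
                              seed = 20191022L,
                              activation_threshold = 0.75) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5)
  n <- nrow(scored)
  with_seed(seed + 5L, {
    active <- scored$combined >= true_cutoff
    flip <- runif(n) < flip_rate
    active <- xor(active, flip)
    activation <- ifelse(active, runif(n, 0.85, 1.2), runif(n, 0, 0.35))
  })
  data.frame(peptide = scored$peptide,
             score = scored$combined,
             activation_observed = activation,
             label = activation > activation_threshold,
             stringsAsFactors = FALSE)
}

#' Write every synthetic input of a scenario to disk
#'
#' Generates the kernel, measurements, proteome, affinity table (for all
#' 9-mers of the proteome plus the replacement library), expression table and
#' ground-truth description, and writes them as plain-text files
#' (`measurements.tsv`, `proteome.fa`, `affinity.tsv`, `expression.tsv`,
#' `truth.json`) into `dir`.
#'
#' @param scenario a [synthetic_scenario()].
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the written paths.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kernel <- make_kernel(scenario)
  ms <- simulate_measurements(kernel, scenario)
  prot <- simulate_proteome(scenario, kernel)
  kmers <- enumerate_kmers(prot$proteins, k = nchar(scenario$epitope))
  universe <- unique(c(kmers$peptides,
                       replacement_library(scenario$epitope,
                                           scenario$anchors)))
  ic50 <- simulate_affinity(universe, scenario$anchor_rule, scenario$seed)
  expr <- simulate_expression(prot$proteins$gene_symbol,
                              scenario$n_tissues, scenario$seed)

  paths <- list(
    measurements = file.path(dir, "measurements.tsv"),
    proteome = file.path(dir, "proteome.fa"),
    affinity = file.path(dir, "affinity.tsv"),
    expression = file.path(dir, "expression.tsv"),
    truth = file.path(dir, "truth.json"),
    kernel = file.path(dir, "truth_kernel.pwm"))

  write.table(as.data.frame(ms), paths$measurements, sep = "\t",
              quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  writeLines(paste0(">", prot$proteins$protein_id, " gene=",
                    prot$proteins$gene_symbol, "\n", prot$proteins$sequence),
             paths$proteome)
  write.table(data.frame(peptide = names(ic50),
                         ic50_nm = format(unname(ic50), digits = 10,
                                          scientific = FALSE, trim = TRUE)),
              paths$affinity, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  write.table(cbind(gene_symbol = rownames(expr), expr), paths$expression,
              sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(seed = scenario$seed, epitope = scenario$epitope,
         anchors = scenario$anchors,
         critical_positions = scenario$critical_positions,
         true_cutoff = scenario$true_cutoff,
         planted = prot$truth),
    paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_pwm(kernel, paths$kernel)
  invisible(paths)
}
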