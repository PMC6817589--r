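#' Assemble a pipeline configuration
#'
#' All thresholds of the screening pipeline are explicit configuration: the
#' scanned epitope and anchors, the Hamming reference for reported edit
#' distances, the IC50 binder cutoff, the activation labelling threshold and
#' the motif bin edges.  Either a [synthetic_scenario()] (inputs generated
#' and written to disk, then read back through the package's own readers) or
#' a set of input file paths must be supplied.
#'
#' @param epitope scanned reference peptide.
#' @param anchors anchor positions.
#' @param hamming_reference reference peptide for reported edit distances
#'   (defaults to the epitope; for the NY-ESO-1 system the wild-type
#'   SLLMWITQC would be used while SLLMWITQV is scanned).
#' @param ic50_max_nm inclusive binder cutoff in nM.
#' @param activation_threshold activation labelling threshold.
#' @param bin_edges motif score-bin breakpoints.
#' @param tpm_threshold expression annotation threshold in TPM.
#' @param seed integer seed (used by synthetic stages).
#' @param scenario optional [synthetic_scenario()].
#' @param measurements,proteome,affinity,expression,outcomes optional input
#'   file paths (used when `scenario` is NULL; `expression` and `outcomes`
#'   are optional stages).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(epitope = "SLLMWITQV", anchors = c(2L, 9L),
                            hamming_reference = epitope,
                            ic50_max_nm = 500,
                            activation_threshold = 0.75,
                            bin_edges = c(0.25, 0.40, 0.55, 0.70, 0.85, 1.00),
                            tpm_threshold = 10,
                            seed = 20191022L,
                            scenario = NULL,
                            measurements = NULL, proteome = NULL,
                            affinity = NULL, expression = NULL,
                            outcomes = NULL) {
  structure(list(epitope = epitope, anchors = anchors,
                 hamming_reference = hamming_reference,
                 ic50_max_nm = ic50_max_nm,
                 activation_threshold = activation_threshold,
                 bin_edges = bin_edges, tpm_threshold = tpm_threshold,
                 seed = as.integer(seed), scenario = scenario,
                 measurements = measurements, proteome = proteome,
                 affinity = affinity, expression = expression,
                 outcomes = outcomes),
            class = "pipeline_config")
}

#' Run the full off-target screening pipeline
#'
#' Fixed stage order: read (or simulate and write, then read) the inputs;
#' fit the per-assay PWMs; enumerate proteome k-mers; filter by binding
#' affinity; score and rank; bin motifs; label activation outcomes; ROC and
#' max-sensitivity cutoff; classify; annotate expression; write reports.
#' Identical configuration and inputs produce byte-identical report files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return an object of class `tcr_pipeline`: list with `fingerprint`,
#'   `kmers` counts, `ranked` (annotated ranked peptides), `motifs`, `roc`,
#'   `cutoff`, `calls`, `truth` (synthetic mode only), `counts` (per-stage
#'   reconciliation counts) and `paths` of the written reports.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (!is.null(config$scenario)) {
    inputs <- write_scenario(config$scenario, file.path(out_dir, "inputs"))
    config$measurements <- inputs$measurements
    config$proteome <- inputs$proteome
    config$affinity <- inputs$affinity
    config$expression <- inputs$expression
    truth <- jsonlite::read_json(inputs$truth, simplifyVector = TRUE)
  }
  for (f in c("measurements", "proteome", "affinity")) {
    if (is.null(config[[f]])) {
      stop("pipeline stage '", f, "': no input file configured", call. = FALSE)
    }
    if (!file.exists(config[[f]])) {
      stop("pipeline stage '", f, "': input file not found: ", config[[f]],
           call. = FALSE)
    }
  }

  ms <- read_measurements(config$measurements)
  fp <- tcr_fingerprint(ms, config$epitope, config$anchors,
                        hamming_reference = config$hamming_reference)
  for (a in names(fp$pwms)) {
    write_pwm(fp$pwms[[a]], file.path(out_dir, paste0(a, ".pwm")))
  }

  proteins <- read_proteins(config$proteome)
  kmers <- enumerate_kmers(proteins, k = nchar(config$epitope))
  affinity <- read_affinity_table(config$affinity)
  binders <- filter_by_affinity(kmers$peptides, affinity, config$ic50_max_nm)
  ranked <- rank_peptides(fp, as.character(binders), affinity, kmers)
  motifs <- bin_motifs(ranked, config$bin_edges)

  # activation outcomes: simulated from ground truth in synthetic mode,
  # read from a labelled table otherwise
  outcomes <- NULL
  if (!is.null(config$scenario)) {
    eval_set <- evaluation_set(ranked)
    outcomes <- simulate_outcomes(eval_set,
                                  true_cutoff = config$scenario$true_cutoff,
                                  flip_rate = config$scenario$flip_rate,
                                  seed = config$scenario$seed,
                                  activation_threshold =
                                    config$activation_threshold)
  } else if (!is.null(config$outcomes)) {
    lab <- read_delimited(config$outcomes)
    lab$activation_observed <- as.numeric(lab$activation_observed)
    idx <- match(lab$peptide, ranked$peptide)
    outcomes <- data.frame(peptide = lab$peptide,
                           score = ranked$combined[idx],
                           activation_observed = lab$activation_observed)
    outcomes <- outcomes[!is.na(outcomes$score), , drop = FALSE]
    outcomes$label <- activation_labels(outcomes$activation_observed,
                                        config$activation_threshold)
  }

  roc <- cutoff <- calls <- NULL
  if (!is.null(outcomes)) {
    roc <- roc_curve(outcomes$score, outcomes$label)
    cutoff <- select_cutoff(roc)
    calls <- classify(setNames(ranked$combined, ranked$peptide), cutoff)
    ranked$predicted_cross_reactive <- unname(calls)
    write.table(roc$points, file.path(out_dir, "roc.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  if (!is.null(config$expression) && file.exists(config$expression)) {
    expr <- read_expression_table(config$expression)
    ranked <- annotate_expression(ranked, expr, config$tpm_threshold)
  }

  counts <- data.frame(
    stage = c("windows_enumerated", "windows_skipped", "unique_peptides",
              "affinity_unpredicted", "affinity_above_cutoff",
              "binders_scored", "motif_out_of_range"),
    count = c(kmers$n_windows, kmers$n_skipped, length(kmers$peptides),
              attr(binders, "n_unpredicted"), attr(binders, "n_above_cutoff"),
              nrow(ranked), attr(motifs, "n_out_of_range")))

  write_report(ranked, file.path(out_dir, "hits.tsv"))
  write.table(counts, file.path(out_dir, "stage_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  meta <- list(tool = "tcrfingerprint",
               version = as.character(utils::packageVersion("tcrfingerprint")),
               epitope = config$epitope, anchors = config$anchors,
               hamming_reference = config$hamming_reference,
               ic50_max_nm = config$ic50_max_nm,
               activation_threshold = config$activation_threshold,
               bin_edges = config$bin_edges,
               tpm_threshold = config$tpm_threshold, seed = config$seed,
               auc = if (!is.null(roc)) roc$auc else NULL,
               cutoff = if (!is.null(cutoff)) cutoff$cutoff else NULL,
               sensitivity = if (!is.null(cutoff)) cutoff$sensitivity else NULL,
               specificity = if (!is.null(cutoff)) cutoff$specificity else NULL,
               accuracy = if (!is.null(cutoff)) cutoff$accuracy else NULL)
  jsonlite::write_json(meta[!vapply(meta, is.null, logical(1))],
                       file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  structure(list(fingerprint = fp, kmers = kmers[c("n_windows", "n_skipped")],
                 ranked = ranked, motifs = motifs, outcomes = outcomes,
                 roc = roc, cutoff = cutoff, calls = calls, truth = truth,
                 counts = counts,
                 paths = list(out_dir = out_dir,
                              hits = file.path(out_dir, "hits.tsv"))),
            class = "tcr_pipeline")
}

# deterministic evaluation set for the synthetic classifier stage: the top
# of the ranking plus an even sample across the rest of the distribution
evaluation_set <- function(ranked, n_top = 30L, n_rest = 170L) {
  n <- nrow(ranked)
  n_top <- min(n_top, n)
  rest <- setdiff(seq_len(n), seq_len(n_top))
  if (length(rest) > n_rest) {
    rest <- rest[round(seq(1L, length(rest), length.out = n_rest))]
  }
  ranked[c(seq_len(n_top), rest), , drop = FALSE]
}

#' @export
print.tcr_pipeline <- function(x, ...) {
  cat("TCR off-target screening pipeline run\n")
  print(x$counts, row.names = FALSE)
  if (!is.null(x$roc)) {
    cat(sprintf("  AUC %.4f; cutoff %.4g (sens %.3f, spec %.3f, acc %.3f)\n",
                x$roc$auc, x$cutoff$cutoff, x$cutoff$sensitivity,
                x$cutoff$specificity, x$cutoff$accuracy))
  }
  cat("  reports in:", x$paths$out_dir, "\n")
  invisible(x)
}
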