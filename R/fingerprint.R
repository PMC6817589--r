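#' Fit the full TCR fingerprint (one PWM per assay)
#'
#' Fits [build_pwm()] for each assay present in the measurement set and
#' bundles the per-assay position weight matrices into a single fingerprint
#' object whose `predict` method scores peptides with every assay and
#' averages them into the combined TCR recognition score.
#'
#' @param measurements a [measurement_set()] covering the replacement library
#'   in one or more assays.
#' @param epitope the scanned reference peptide.
#' @param anchors anchor positions excluded from scanning/scoring.
#' @param assays assays to fit; defaults to those present in `measurements`.
#' @param hamming_reference peptide used as the reference for reported edit
#'   distances; defaults to `epitope`.  For the NY-ESO-1 system the scan uses
#'   the anchor-optimized SLLMWITQV while distances are reported against the
#'   wild-type SLLMWITQC, so the two are separate fields.
#' @param ... passed to [build_pwm()].
#' @return an object of class `tcr_fingerprint`: a list with `pwms` (named
#'   list of [tcr_pwm]), `epitope`, `anchors`, `hamming_reference`, `call`.
#' @export
tcr_fingerprint <- function(measurements, epitope, anchors = c(2L, 9L),
                            assays = NULL, hamming_reference = epitope, ...) {
  stopifnot(inherits(measurements, "measurement_set"))
  if (is.null(assays)) assays <- intersect(ASSAYS, unique(measurements$assay))
  if (length(assays) == 0L) stop("no assays to fit", call. = FALSE)
  pwms <- lapply(assays, function(a) {
    build_pwm(measurements, a, epitope, anchors, ...)
  })
  names(pwms) <- assays
  structure(list(pwms = pwms,
                 epitope = epitope,
                 anchors = validate_anchors(anchors, nchar(epitope)),
                 hamming_reference = hamming_reference,
                 call = match.call()),
            class = "tcr_fingerprint")
}

#' @export
print.tcr_fingerprint <- function(x, ...) {
  cat("TCR fingerprint\n")
  cat(sprintf("  epitope : %s  (anchors %s)\n", x$epitope,
              paste(x$anchors, collapse = ", ")))
  cat(sprintf("  assays  : %s\n", paste(names(x$pwms), collapse = ", ")))
  cat(sprintf("  hamming reference: %s\n", x$hamming_reference))
  invisible(x)
}

#' @method summary tcr_fingerprint
#' @export
summary.tcr_fingerprint <- function(object, ...) {
  assays <- names(object$pwms)
  sims <- NULL
  if (length(assays) >= 2L) {
    pairs <- utils::combn(assays, 2L)
    sims <- data.frame(
      assay_a = pairs[1, ], assay_b = pairs[2, ],
      pearson = apply(pairs, 2L, function(p) {
        pwm_similarity(object$pwms[[p[1]]], object$pwms[[p[2]]])
      }))
  }
  out <- list(epitope = object$epitope, anchors = object$anchors,
              assays = assays, pairwise_similarity = sims)
  class(out) <- "summary.tcr_fingerprint"
  out
}

#' @export
print.summary.tcr_fingerprint <- function(x, ...) {
  cat("TCR fingerprint:", x$epitope, "\n")
  cat("  assays:", paste(x$assays, collapse = ", "), "\n")
  if (!is.null(x$pairwise_similarity)) {
    cat("  pairwise PWM Pearson similarity:\n")
    print(x$pairwise_similarity, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' @method coef tcr_fingerprint
#' @export
coef.tcr_fingerprint <- function(object, ...) {
  lapply(object$pwms, coef)
}

#' @method plot tcr_fingerprint
#' @export
plot.tcr_fingerprint <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, length(x$pwms)))
  on.exit(graphics::par(old))
  for (p in x$pwms) plot(p, ...)
  invisible(x)
}

#' Score peptides with a fitted TCR fingerprint
#'
#' @param object a [tcr_fingerprint].
#' @param peptides character vector of candidate peptides.
#' @param ... unused.
#' @return data.frame with one row per peptide: per-assay scores, `combined`
#'   (their arithmetic mean — the TCR recognition score) and `hamming` (edit
#'   distance to the fingerprint's Hamming reference).
#' @export
predict.tcr_fingerprint <- function(object, peptides, ...) {
  scores <- as.data.frame(lapply(object$pwms, score_peptides,
                                 peptides = peptides))
  out <- data.frame(peptide = peptides, scores,
                    stringsAsFactors = FALSE, row.names = NULL)
  out$combined <- rowMeans(as.matrix(scores))
  out$hamming <- hamming_distance(peptides, object$hamming_reference)
  out
}

#' Simulate replacement-scan measurements from a fitted fingerprint
#'
#' Treats each fitted PWM as the data-generating kernel and draws new noisy
#' replicate measurements for the full replacement library, using the same
#' noise model as [simulate_measurements()].
#'
#' @param object a [tcr_fingerprint].
#' @param nsim number of replicates per peptide and assay.
#' @param seed integer RNG seed.
#' @param ... passed to [simulate_measurements()] (e.g. `noise_cv`).
#' @return a [measurement_set()].
#' @export
simulate.tcr_fingerprint <- function(object, nsim = 3L, seed = 20191022L,
                                     ...) {
  sets <- lapply(names(object$pwms), function(a) {
    sc <- synthetic_scenario(epitope = object$epitope,
                             anchors = object$anchors,
                             replicates = nsim,
                             seed = seed + match(a, ASSAYS), ...)
    ms <- simulate_measurements(object$pwms[[a]], sc, assays = a)
    ms
  })
  measurement_set(do.call(rbind, sets))
}

#' Combine per-assay recognition scores
#'
#' The overall TCR recognition score of a peptide is the arithmetic mean of
#' its binding, activation and killing PWM scores.
#'
#' @param binding,activation,killing numeric scores in `[0, 1]` (vectors
#'   recycled to a common length).
#' @return data.frame with the three inputs and `combined`.
#' @export
combine_scores <- function(binding, activation, killing) {
  s <- cbind(binding, activation, killing)
  if (any(s < 0 | s > 1)) {
    stop("assay scores must lie in [0, 1]", call. = FALSE)
  }
  data.frame(binding = s[, 1], activation = s[, 2], killing = s[, 3],
             combined = rowMeans(s))
}
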