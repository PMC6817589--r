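#' Fit a position weight matrix from a single-substitution replacement scan
#'
#' Constructs the per-assay "TCR fingerprint": a 20 amino-acid by scored-
#' position matrix of normalized recognition values.  For the variant
#' carrying substitution `a` at position `i`,
#' \deqn{W_{a,i} = 100 \cdot L_{a,i} / L_{epitope}}
#' where `L` is the mean over replicates of the background-corrected signal
#' (the matched background is subtracted from each replicate *before*
#' averaging).  Values above 100 are trimmed to 100 and negative values set
#' to 0; the epitope's own residue at every scored position is pinned at 100.
#' Anchor positions (those contacting the MHC groove rather than the TCR,
#' e.g. P2 and P9 for HLA-A*02:01 9-mers) are not scanned and are not stored
#' in the matrix.
#'
#' @param measurements a [measurement_set()] containing the epitope and its
#'   single-substitution variants for `assay`.
#' @param assay one of `"binding"`, `"activation"`, `"killing"`.
#' @param epitope the scanned reference peptide (uppercase).
#' @param anchors integer vector of 1-based anchor positions excluded from
#'   scanning and scoring (default `c(2, 9)`).
#' @param on_missing what to do with cells for which no variant was measured:
#'   `"impute"` (default) sets them to 0 with a warning — unmeasured is
#'   conservatively treated as not recognized — while `"error"` aborts.
#' @return an object of class `tcr_pwm` with components `epitope`, `anchors`,
#'   `positions` (the scored positions), `weights` (20 x |positions| matrix,
#'   values 0-100), `assay`, `n_replicates`, and `missing_cells`.
#' @examples
#' sc <- synthetic_scenario(noise_cv = 0, replicates = 1)
#' kern <- make_kernel(sc)
#' ms <- simulate_measurements(kern, sc)
#' pwm <- build_pwm(ms, "binding", sc$epitope, sc$anchors)
#' pwm
#' @export
build_pwm <- function(measurements, assay, epitope, anchors = c(2L, 9L),
                      on_missing = c("impute", "error")) {
  stopifnot(inherits(measurements, "measurement_set"))
  on_missing <- match.arg(on_missing)
  if (!assay %in% ASSAYS) {
    stop("unknown assay: ", assay, call. = FALSE)
  }
  check_canonical(epitope, "epitope")
  k <- nchar(epitope)
  anchors <- validate_anchors(anchors, k)
  positions <- setdiff(seq_len(k), anchors)
  epi_res <- strsplit(epitope, "")[[1]]

  m <- measurements[measurements$assay == assay, , drop = FALSE]
  if (nrow(m) == 0L) {
    stop("no measurements for assay '", assay, "'", call. = FALSE)
  }
  if (!epitope %in% m$peptide) {
    stop("epitope peptide ", epitope, " has no measurements for assay '",
         assay, "'", call. = FALSE)
  }
  # per-replicate background subtraction, then mean per peptide
  corrected <- m$signal - m$background
  L <- tapply(corrected, m$peptide, mean)
  L_epitope <- L[[epitope]]
  if (L_epitope <= 0) {
    stop(sprintf(
      "degenerate normalization: epitope signal is %.4g after background correction",
      L_epitope), call. = FALSE)
  }

  w <- matrix(NA_real_, nrow = 20L, ncol = length(positions),
              dimnames = list(AMINO_ACIDS, positions))
  variants <- setdiff(names(L), epitope)
  if (length(variants) > 0L) {
    vm <- peptide_matrix(variants, k)
    if (any(nchar(variants) != k)) {
      stop("variant peptide length differs from epitope: ",
           variants[nchar(variants) != k][1], call. = FALSE)
    }
    diffs <- vm != matrix(epi_res, nrow = length(variants), ncol = k,
                          byrow = TRUE)
    ndiff <- rowSums(diffs)
    if (any(ndiff != 1L)) {
      stop("variant differs from the epitope at ", ndiff[ndiff != 1L][1],
           " positions (expected exactly 1): ",
           variants[ndiff != 1L][1], call. = FALSE)
    }
    pos <- apply(diffs, 1L, which)
    if (any(pos %in% anchors)) {
      stop("variant substitutes an anchor position: ",
           variants[pos %in% anchors][1], call. = FALSE)
    }
    aa <- vm[cbind(seq_along(variants), pos)]
    w[cbind(match(aa, AMINO_ACIDS), match(pos, positions))] <-
      100 * L[variants] / L_epitope
  }
  # the epitope's own residue is the normalization reference at each position
  w[cbind(match(epi_res[positions], AMINO_ACIDS), seq_along(positions))] <- 100

  missing_cells <- which(is.na(w), arr.ind = TRUE)
  if (nrow(missing_cells) > 0L) {
    if (on_missing == "error") {
      stop(nrow(missing_cells), " unmeasured PWM cell(s), e.g. ",
           AMINO_ACIDS[missing_cells[1, 1]], " at position ",
           positions[missing_cells[1, 2]], call. = FALSE)
    }
    warning(nrow(missing_cells),
            " unmeasured PWM cell(s) imputed as 0 (not recognized)",
            call. = FALSE)
    w[is.na(w)] <- 0
  }
  w <- pmin(pmax(w, 0), 100)  # trim >100, zero <0

  reps <- length(unique(m$replicate_id))
  new_tcr_pwm(epitope = epitope, anchors = anchors, weights = w,
              assay = assay, n_replicates = reps,
              missing_cells = missing_cells)
}

validate_anchors <- function(anchors, k) {
  anchors <- sort(unique(as.integer(anchors)))
  if (length(anchors) > 0L && (min(anchors) < 1L || max(anchors) > k)) {
    stop("anchor positions out of range 1..", k, call. = FALSE)
  }
  anchors
}

new_tcr_pwm <- function(epitope, anchors, weights, assay,
                        n_replicates = NA_integer_, missing_cells = NULL,
                        notes = NULL) {
  positions <- as.integer(colnames(weights))
  stopifnot(identical(rownames(weights), AMINO_ACIDS),
            length(positions) == nchar(epitope) - length(anchors))
  structure(list(epitope = epitope,
                 anchors = anchors,
                 positions = positions,
                 weights = weights,
                 assay = assay,
                 n_replicates = n_replicates,
                 missing_cells = missing_cells,
                 notes = notes),
            class = "tcr_pwm")
}

#' @export
print.tcr_pwm <- function(x, ...) {
  cat(sprintf("TCR recognition PWM (%s assay)\n", x$assay))
  cat(sprintf("  epitope : %s\n", x$epitope))
  cat(sprintf("  anchors : %s (excluded)\n", paste(x$anchors, collapse = ", ")))
  cat(sprintf("  scored positions: %s\n", paste(x$positions, collapse = ", ")))
  cat("  weights (percent of epitope signal):\n")
  print(round(x$weights, 1))
  invisible(x)
}

#' @method coef tcr_pwm
#' @export
coef.tcr_pwm <- function(object, ...) object$weights

#' @method as.matrix tcr_pwm
#' @export
as.matrix.tcr_pwm <- function(x, ...) x$weights

#' Heatmap of a TCR recognition PWM
#'
#' @param x a [tcr_pwm] object.
#' @param ... passed to [graphics::image()].
#' @return invisibly, `x`.
#' @method plot tcr_pwm
#' @export
plot.tcr_pwm <- function(x, ...) {
  w <- x$weights
  graphics::image(x = seq_along(x$positions), y = seq_len(20L),
                  z = t(w[rev(seq_len(20L)), , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  zlim = c(0, 100), axes = FALSE,
                  xlab = "peptide position", ylab = "",
                  main = sprintf("TCR fingerprint (%s)", x$assay), ...)
  graphics::axis(1, at = seq_along(x$positions), labels = x$positions)
  graphics::axis(2, at = seq_len(20L), labels = rev(AMINO_ACIDS), las = 2,
                 cex.axis = 0.7)
  invisible(x)
}

#' Pearson similarity between two position weight matrices
#'
#' Flattens both matrices into paired cell vectors (20 rows x scored
#' positions) and returns the plain Pearson correlation coefficient, the
#' package's measure of inter-assay fingerprint concordance.
#'
#' @param a,b [tcr_pwm] objects sharing epitope length, anchors and scored
#'   positions.
#' @return correlation coefficient in `[-1, 1]`.
#' @export
pwm_similarity <- function(a, b) {
  stopifnot(inherits(a, "tcr_pwm"), inherits(b, "tcr_pwm"))
  if (!identical(dim(a$weights), dim(b$weights)) ||
      !identical(a$positions, b$positions) ||
      !identical(a$anchors, b$anchors)) {
    stop("PWMs have mismatched dimensions, positions or anchors",
         call. = FALSE)
  }
  stats::cor(as.vector(a$weights), as.vector(b$weights))
}

#' Build a PWM from an alanine scan
#'
#' An alanine scan substitutes only alanine at each position.  Positions
#' where the alanine variant retains at least `permissive_threshold` of the
#' epitope signal are treated as permissive — putatively allowing any amino
#' acid, so all 20 residues get weight 100.  At non-permissive positions the
#' epitope residue keeps weight 100, alanine gets `100 * value`, and every
#' other residue gets 0.
#'
#' @param alanine_values named numeric vector in `[0, 1]`: normalized
#'   alanine-substitution signal (relative to the epitope) for every
#'   non-anchor position; names are the 1-based positions.
#' @param epitope the reference peptide.
#' @param anchors anchor positions (default `c(2, 9)`).
#' @param permissive_threshold fraction of epitope signal above which a
#'   position counts as permissive; in `(0, 1]`, default 0.5.
#' @return a [tcr_pwm] with assay label `"alanine-scan"`.
#' @export
build_alanine_pwm <- function(alanine_values, epitope, anchors = c(2L, 9L),
                              permissive_threshold = 0.5) {
  if (!is.numeric(permissive_threshold) || length(permissive_threshold) != 1L ||
      permissive_threshold <= 0 || permissive_threshold > 1) {
    stop("permissive_threshold must lie in (0, 1]", call. = FALSE)
  }
  check_canonical(epitope, "epitope")
  k <- nchar(epitope)
  anchors <- validate_anchors(anchors, k)
  positions <- setdiff(seq_len(k), anchors)
  have <- as.integer(names(alanine_values))
  missing <- setdiff(positions, have)
  if (length(missing) > 0L) {
    stop("missing alanine value for position(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- pmin(pmax(as.numeric(alanine_values[as.character(positions)]), 0), 1)
  epi_res <- strsplit(epitope, "")[[1]]
  w <- matrix(0, nrow = 20L, ncol = length(positions),
              dimnames = list(AMINO_ACIDS, positions))
  for (j in seq_along(positions)) {
    if (vals[j] >= permissive_threshold) {
      w[, j] <- 100
    } else {
      w[epi_res[positions[j]], j] <- 100
      w["A", j] <- max(w["A", j], 100 * vals[j])
    }
  }
  new_tcr_pwm(epitope = epitope, anchors = anchors, weights = w,
              assay = "alanine-scan")
}
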