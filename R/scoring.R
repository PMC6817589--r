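#' Generate the single-substitution replacement library
#'
#' The epitope plus, for every non-anchor position, the 19 variants carrying
#' each alternative amino acid at that position.  For a 9-mer with two
#' anchors this is the canonical 134-peptide library (7 x 19 + 1).
#'
#' @param epitope uppercase reference peptide.
#' @param anchors 1-based anchor positions held fixed (default `c(2, 9)`).
#' @return character vector: the epitope first, then variants in
#'   position-major, alphabetical-residue order; no duplicates.
#' @examples
#' length(replacement_library("SLLMWITQV"))  # 134
#' @export
replacement_library <- function(epitope, anchors = c(2L, 9L)) {
  check_canonical(epitope, "epitope")
  k <- nchar(epitope)
  anchors <- validate_anchors(anchors, k)
  positions <- setdiff(seq_len(k), anchors)
  epi_res <- strsplit(epitope, "")[[1]]
  variants <- character(0)
  for (i in positions) {
    for (a in setdiff(AMINO_ACIDS, epi_res[i])) {
      v <- epi_res
      v[i] <- a
      variants <- c(variants, paste(v, collapse = ""))
    }
  }
  c(epitope, variants)
}

#' Score peptides against a TCR recognition PWM
#'
#' The recognition score of a query sequence is the sum of the PWM weights of
#' its residues over the scored (non-anchor) positions, normalized by the
#' maximum possible score `100 * |P|` — the score of the epitope itself, whose
#' residues are pinned at 100.  Anchor-position residues contribute nothing.
#'
#' @param pwm a [tcr_pwm] object.
#' @param peptides character vector of peptides, each the same length as the
#'   PWM's epitope, canonical residues only.
#' @return numeric vector of scores in `[0, 1]`, one per peptide.
#' @examples
#' sc <- synthetic_scenario()
#' kern <- make_kernel(sc)
#' score_peptides(kern, sc$epitope)  # 1 by construction
#' @export
score_peptides <- function(pwm, peptides) {
  stopifnot(inherits(pwm, "tcr_pwm"))
  if (length(peptides) == 0L) return(numeric(0))
  k <- nchar(pwm$epitope)
  if (any(nchar(peptides) != k)) {
    stop("peptide length differs from the PWM epitope length (", k, "): ",
         peptides[nchar(peptides) != k][1], call. = FALSE)
  }
  bad <- !is_canonical(peptides)
  if (any(bad)) {
    stop("peptide(s) with non-canonical residues cannot be scored: ",
         paste(head(unique(peptides[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  pm <- peptide_matrix(peptides, k)[, pwm$positions, drop = FALSE]
  idx_aa <- match(pm, AMINO_ACIDS)
  idx_pos <- rep(seq_along(pwm$positions), each = length(peptides))
  sums <- rowSums(matrix(pwm$weights[cbind(idx_aa, idx_pos)],
                         nrow = length(peptides)))
  unname(sums / (100 * length(pwm$positions)))
}

#' Hamming distance between equal-length peptides
#'
#' The minimum number of substitutions transforming one sequence into the
#' other; the dissimilarity reported between candidate off-target peptides
#' and the reference epitope.
#'
#' @param a,b character vectors of equal-length peptides (recycled).
#' @return integer vector of position-wise mismatch counts.
#' @examples
#' hamming_distance("FLTLWLTQV", "SLLMWITQC")  # 5
#' @export
hamming_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (any(nchar(a) != nchar(b))) {
    stop("peptides must have equal lengths", call. = FALSE)
  }
  mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, a, b, USE.NAMES = FALSE)
}
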