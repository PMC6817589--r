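#' Replacement-scan measurement sets
#'
#' A `measurement_set` holds per-replicate assay read-outs (percent positive
#' cells) for a library of peptides, together with the matched no-peptide
#' background read-out of each replicate.  It is the input to [build_pwm()].
#'
#' @param data a data.frame with columns `peptide`, `assay`, `replicate_id`,
#'   `signal`, `background`.  `signal` and `background` are raw
#'   percent-positive-cells values on a 0-100 scale; the background is the
#'   vehicle/no-peptide control measured for the same replicate.
#' @return an object of class `measurement_set` (a validated data.frame).
#' @details Valid assay labels are `"binding"`, `"activation"` and
#'   `"killing"`.  Peptides must be uppercase and use only the 20 canonical
#'   one-letter amino-acid codes; signals and backgrounds must be finite.
#' @export
measurement_set <- function(data) {
  required <- c("peptide", "assay", "replicate_id", "signal", "background")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0L) {
    stop("measurement table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[required]
  data$peptide <- as.character(data$peptide)
  data$assay <- as.character(data$assay)
  data$replicate_id <- as.character(data$replicate_id)
  if (nrow(data) > 0L) {
    check_canonical(data$peptide)
    bad_assay <- !data$assay %in% ASSAYS
    if (any(bad_assay)) {
      stop("unknown assay label(s): ",
           paste(unique(data$assay[bad_assay]), collapse = ", "),
           " (expected one of: ", paste(ASSAYS, collapse = ", "), ")",
           call. = FALSE)
    }
    if (any(!nzchar(data$replicate_id)) || anyNA(data$replicate_id)) {
      stop("replicate_id must be non-empty", call. = FALSE)
    }
    if (!is.numeric(data$signal) || !is.numeric(data$background) ||
        any(!is.finite(data$signal)) || any(!is.finite(data$background))) {
      stop("signal and background must be finite numbers", call. = FALSE)
    }
  }
  class(data) <- c("measurement_set", "data.frame")
  data
}

ASSAYS <- c("binding", "activation", "killing")

#' @export
print.measurement_set <- function(x, ...) {
  cat("Replacement-scan measurement set\n")
  tab <- table(x$assay[!duplicated(paste(x$peptide, x$assay))])
  cat(sprintf("  %d records, %d distinct peptides\n",
              nrow(x), length(unique(x$peptide))))
  for (a in names(tab)) {
    cat(sprintf("  assay %-10s: %d peptides\n", a, tab[[a]]))
  }
  invisible(x)
}

#' Distinct peptides per assay
#'
#' @param x a [measurement_set()].
#' @return named list of character vectors, one per assay present.
#' @export
peptides_by_assay <- function(x) {
  stopifnot(inherits(x, "measurement_set"))
  lapply(split(x$peptide, x$assay), unique)
}
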