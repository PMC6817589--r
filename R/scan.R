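#' Enumerate unique k-mer peptides from a proteome
#'
#' Slides a length-`k` window over every protein, skipping (and counting)
#' windows containing non-canonical letters, and deduplicates peptides at the
#' sequence level while keeping full provenance: every (protein, gene,
#' 1-based start) at which each peptide occurs.
#'
#' @param proteins data.frame with columns `protein_id`, `gene_symbol`,
#'   `sequence` (e.g. from [read_proteins()] or [simulate_proteome()]).
#' @param k window length (default 9, the preferred HLA class I length).
#' @return an object of class `kmer_set`: list with `peptides` (unique
#'   sequences), `provenance` (data.frame `peptide`, `protein_id`,
#'   `gene_symbol`, `start`), `n_windows`, `n_skipped`.
#' @export
enumerate_kmers <- function(proteins, k = 9L) {
  stopifnot(k >= 1L, all(c("protein_id", "sequence") %in% names(proteins)))
  if (!"gene_symbol" %in% names(proteins)) proteins$gene_symbol <- NA
  per_protein <- lapply(seq_len(nrow(proteins)), function(r) {
    s <- proteins$sequence[r]
    n <- nchar(s)
    if (n < k) return(NULL)
    starts <- seq_len(n - k + 1L)
    data.frame(peptide = substring(s, starts, starts + k - 1L),
               protein_id = proteins$protein_id[r],
               gene_symbol = proteins$gene_symbol[r],
               start = starts, stringsAsFactors = FALSE)
  })
  prov <- do.call(rbind, per_protein)
  if (is.null(prov)) {
    prov <- data.frame(peptide = character(), protein_id = character(),
                       gene_symbol = character(), start = integer())
  }
  n_windows <- nrow(prov)
  ok <- is_canonical(prov$peptide)
  n_skipped <- sum(!ok)
  prov <- prov[ok, , drop = FALSE]
  structure(list(peptides = unique(prov$peptide),
                 provenance = prov,
                 n_windows = n_windows,
                 n_skipped = n_skipped),
            class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf(
    "k-mer set: %d windows scanned, %d skipped (non-canonical), %d unique peptides\n",
    x$n_windows, x$n_skipped, length(x$peptides)))
  invisible(x)
}

#' Filter peptides by predicted MHC binding affinity
#'
#' Keeps peptides predicted to bind (IC50 at or below the cutoff; the
#' boundary is inclusive, so IC50 = 500 nM counts as a binder under the
#' default).  Peptides absent from the affinity map are dropped and counted
#' separately from above-threshold drops.
#'
#' @param peptides character vector of peptides.
#' @param affinity named numeric vector of IC50 (nM), e.g. from
#'   [read_affinity_table()] or [simulate_affinity()].
#' @param ic50_max_nm inclusive binder cutoff in nM (default 500).
#' @return character vector of retained peptides, with attributes
#'   `n_unpredicted` (no IC50 available) and `n_above_cutoff`.
#' @export
filter_by_affinity <- function(peptides, affinity, ic50_max_nm = 500) {
  stopifnot(ic50_max_nm > 0)
  ic50 <- affinity[peptides]
  unpredicted <- is.na(ic50)
  keep <- !unpredicted & ic50 <= ic50_max_nm
  out <- peptides[keep]
  attr(out, "n_unpredicted") <- sum(unpredicted)
  attr(out, "n_above_cutoff") <- sum(!unpredicted & !keep)
  out
}

#' Score and rank candidate peptides against a TCR fingerprint
#'
#' Scores every peptide with each per-assay PWM, averages into the combined
#' TCR recognition score, and sorts by combined score (descending), breaking
#' ties lexicographically by sequence so the ranking is deterministic.
#'
#' @param fingerprint a [tcr_fingerprint].
#' @param peptides character vector of candidate peptides.
#' @param affinity optional named IC50 vector; adds an `ic50_nm` column.
#' @param kmers optional [enumerate_kmers()] result; adds a `provenance`
#'   column (`protein:gene:start`, semicolon-joined) and a `genes` string.
#' @return data.frame of class `ranked_peptides`, one row per peptide, with
#'   `rank`, per-assay scores, `combined`, `hamming` and any join columns.
#' @export
rank_peptides <- function(fingerprint, peptides, affinity = NULL,
                          kmers = NULL) {
  stopifnot(inherits(fingerprint, "tcr_fingerprint"))
  scored <- predict(fingerprint, peptides)
  ord <- order(-scored$combined, scored$peptide, method = "radix")
  scored <- scored[ord, , drop = FALSE]
  scored$rank <- seq_len(nrow(scored))
  if (!is.null(affinity)) scored$ic50_nm <- unname(affinity[scored$peptide])
  if (!is.null(kmers)) {
    prov <- kmers$provenance
    prov_str <- tapply(sprintf("%s:%s:%d", prov$protein_id, prov$gene_symbol,
                               prov$start),
                       prov$peptide, paste, collapse = ";")
    genes_str <- tapply(prov$gene_symbol, prov$peptide, function(g) {
      paste(unique(g), collapse = ";")
    })
    scored$provenance <- unname(prov_str[scored$peptide])
    scored$genes <- unname(genes_str[scored$peptide])
  }
  rownames(scored) <- NULL
  scored <- scored[c("rank", setdiff(names(scored), "rank"))]
  class(scored) <- c("ranked_peptides", "data.frame")
  scored
}

#' @export
print.ranked_peptides <- function(x, n = 10L, ...) {
  cat(sprintf("Ranked peptides (%d candidates), top %d:\n", nrow(x),
              min(n, nrow(x))))
  print.data.frame(head(as.data.frame(x), n), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Bin scored peptides and build per-bin sequence motifs
#'
#' Splits peptides into score bins (half-open `[lo, hi)` intervals, last bin
#' closed) and builds one position frequency matrix per bin over the full
#' peptide length, anchors included — the per-group sequence motifs of the
#' score-ranked peptide universe.
#'
#' @param scored data.frame with columns `peptide` and `combined`.
#' @param bin_edges strictly increasing breakpoints within `[0, 1]`; the
#'   default `c(0.25, 0.40, 0.55, 0.70, 0.85, 1.00)` yields the five
#'   canonical score groups.  Peptides outside the outer edges are dropped
#'   and counted in the `n_out_of_range` attribute.
#' @return list of `motif_matrix` objects, each with `bin_label`, `counts`
#'   (k x 20 integer matrix), `frequencies` (per-position, rows sum to 1;
#'   `NA` for an empty bin) and `n_peptides`.
#' @export
bin_motifs <- function(scored,
                       bin_edges = c(0.25, 0.40, 0.55, 0.70, 0.85, 1.00)) {
  if (any(diff(bin_edges) <= 0) || min(bin_edges) < 0 || max(bin_edges) > 1) {
    stop("bin_edges must be strictly increasing within [0, 1]", call. = FALSE)
  }
  n_bins <- length(bin_edges) - 1L
  k <- nchar(scored$peptide[1] %||% "")
  s <- scored$combined
  idx <- findInterval(s, bin_edges, rightmost.closed = TRUE)
  in_range <- idx >= 1L & idx <= n_bins
  out <- lapply(seq_len(n_bins), function(b) {
    peps <- scored$peptide[in_range & idx == b]
    counts <- matrix(0L, nrow = k, ncol = 20L,
                     dimnames = list(seq_len(k), AMINO_ACIDS))
    if (length(peps) > 0L) {
      pm <- peptide_matrix(peps, k)
      for (j in seq_len(k)) {
        tab <- table(factor(pm[, j], levels = AMINO_ACIDS))
        counts[j, ] <- as.integer(tab)
      }
    }
    freq <- if (length(peps) > 0L) counts / length(peps) else counts * NA_real_
    structure(list(bin_label = sprintf("[%g,%g%s", bin_edges[b],
                                       bin_edges[b + 1L],
                                       if (b == n_bins) "]" else ")"),
                   counts = counts, frequencies = freq,
                   n_peptides = length(peps)),
              class = "motif_matrix")
  })
  attr(out, "n_out_of_range") <- sum(!in_range)
  out
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("Sequence motif for score bin %s (%d peptides)\n",
              x$bin_label, x$n_peptides))
  if (x$n_peptides > 0L) {
    modal <- AMINO_ACIDS[apply(x$counts, 1L, which.max)]
    cat("  modal residues:", paste(modal, collapse = ""), "\n")
  }
  invisible(x)
}

#' Annotate ranked peptides with tissue expression
#'
#' Joins the genes in each peptide's provenance against a gene-by-tissue TPM
#' table and reports, per peptide, the maximum TPM over its source genes and
#' the number of tissues in which any source gene exceeds the TPM threshold —
#' a proxy for how broadly a potential off-target antigen is expressed in
#' normal tissue.
#'
#' @param scored a [rank_peptides()] result carrying a `genes` column.
#' @param expr gene-by-tissue TPM data.frame (rownames = genes), e.g. from
#'   [read_expression_table()] or [simulate_expression()].
#' @param tpm_threshold expression threshold in TPM (default 10).
#' @return `scored` with added columns `max_tpm`, `tissues_above_tpm` and
#'   `expression_flag` (`"ok"` or `"no-expression-data"`).
#' @export
annotate_expression <- function(scored, expr, tpm_threshold = 10) {
  if (!"genes" %in% names(scored)) {
    stop("scored peptides carry no provenance genes; rank with kmers=",
         call. = FALSE)
  }
  mat <- as.matrix(expr)
  gene_lists <- strsplit(scored$genes, ";", fixed = TRUE)
  res <- lapply(gene_lists, function(gs) {
    gs <- gs[gs %in% rownames(mat)]
    if (length(gs) == 0L) {
      return(list(max_tpm = NA_real_, above = NA_integer_,
                  flag = "no-expression-data"))
    }
    sub <- mat[gs, , drop = FALSE]
    list(max_tpm = max(sub),
         above = sum(apply(sub > tpm_threshold, 2L, any)),
         flag = "ok")
  })
  scored$max_tpm <- vapply(res, `[[`, numeric(1), "max_tpm")
  scored$tissues_above_tpm <- vapply(res, `[[`, integer(1), "above")
  scored$expression_flag <- vapply(res, `[[`, character(1), "flag")
  scored
}
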