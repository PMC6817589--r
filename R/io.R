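#' Read a replacement-scan measurement table
#'
#' Reads a delimited text file (tab or comma, auto-detected) with header
#' columns `peptide`, `assay`, `replicate_id`, `signal`, `background` into a
#' [measurement_set()].
#'
#' @param path path to a delimited text file.
#' @param dialect `"strict"` (default) requires exact, case-sensitive column
#'   names; `"lenient"` matches column names case-insensitively.
#' @return a [measurement_set()].
#' @export
read_measurements <- function(path, dialect = c("strict", "lenient")) {
  dialect <- match.arg(dialect)
  df <- read_delimited(path)
  required <- c("peptide", "assay", "replicate_id", "signal", "background")
  if (dialect == "lenient") {
    idx <- match(required, tolower(names(df)))
    if (anyNA(idx)) {
      stop(sprintf("%s: missing column(s): %s", path,
                   paste(required[is.na(idx)], collapse = ", ")),
           call. = FALSE)
    }
    df <- df[idx]
    names(df) <- required
  } else {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0L) {
      stop(sprintf("%s: missing column(s): %s (strict column matching)", path,
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
    df <- df[required]
  }
  for (col in c("signal", "background")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("%s: non-numeric %s at data row %d ('%s')", path, col,
                   bad[1], df[[col]][bad[1]]), call. = FALSE)
    }
    df[[col]] <- v
  }
  measurement_set(df)
}

# delimiter auto-detection between tab and comma, on the header line
read_delimited <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  read.delim(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character",
             fileEncoding = "UTF-8")
}

#' Read a protein FASTA file
#'
#' Parses a FASTA file of protein sequences.  The first whitespace-separated
#' header token is the protein identifier; a `gene=SYMBOL` key anywhere in the
#' header, or otherwise the second token, supplies the gene symbol.
#' Sequences are uppercased; non-canonical letters are retained (they are
#' skipped later, during k-mer enumeration).
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `protein_id`, `gene_symbol` (NA when
#'   absent) and `sequence`, in file order.
#' @export
read_proteins <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  tokens <- strsplit(headers, "\\s+")
  ids <- vapply(tokens, `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate protein_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  genes <- vapply(tokens, function(tok) {
    g <- grep("^gene=", tok, value = TRUE)
    if (length(g) > 0L) return(sub("^gene=", "", g[1]))
    if (length(tok) >= 2L) return(tok[2])
    NA_character_
  }, character(1))
  data.frame(protein_id = ids,
             gene_symbol = genes,
             sequence = toupper(as.character(aa)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a peptide binding-affinity table
#'
#' Two-column delimited text (`peptide`, `ic50_nm`) giving a predicted
#' peptide-MHC half-maximal inhibitory concentration in nanomolar, e.g.
#' exported from a netMHCpan run.  Duplicate peptide rows keep the minimum
#' IC50 with a warning.
#'
#' @param path path to a delimited text file with header.
#' @return a named numeric vector: names are peptides, values IC50 in nM.
#' @export
read_affinity_table <- function(path) {
  df <- read_delimited(path)
  required <- c("peptide", "ic50_nm")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  pep <- as.character(df$peptide)
  ic50 <- suppressWarnings(as.numeric(df$ic50_nm))
  if (anyNA(ic50)) {
    stop(sprintf("%s: non-numeric ic50_nm at data row %d", path,
                 which(is.na(ic50))[1]), call. = FALSE)
  }
  if (any(ic50 <= 0)) {
    stop(sprintf("%s: non-positive ic50_nm at data row %d (%g)", path,
                 which(ic50 <= 0)[1], ic50[ic50 <= 0][1]), call. = FALSE)
  }
  check_canonical(pep)
  if (anyDuplicated(pep)) {
    warning(sprintf("%d duplicate peptide row(s); keeping minimum IC50",
                    sum(duplicated(pep))), call. = FALSE)
    ic50 <- tapply(ic50, pep, min)
    return(ic50[unique(pep)])
  }
  setNames(ic50, pep)
}

#' Read a gene-by-tissue expression table
#'
#' First column `gene_symbol`, remaining columns one per tissue, values in
#' transcripts per million (Human Protein Atlas RNA-consensus style).
#'
#' @param path path to a delimited text file with header.
#' @return a data.frame with rownames = gene symbols and one numeric column
#'   per tissue.
#' @export
read_expression_table <- function(path) {
  df <- read_delimited(path)
  if (names(df)[1] != "gene_symbol") {
    stop(sprintf("%s: first column must be 'gene_symbol'", path),
         call. = FALSE)
  }
  genes <- as.character(df[[1]])
  tpm <- as.data.frame(lapply(df[-1], function(v) {
    v <- suppressWarnings(as.numeric(v))
    v
  }))
  names(tpm) <- names(df)[-1]
  if (anyNA(as.matrix(tpm)) || any(as.matrix(tpm) < 0)) {
    stop(sprintf("%s: TPM values must be non-negative numbers", path),
         call. = FALSE)
  }
  rownames(tpm) <- genes
  tpm
}

#' Serialize a position weight matrix to a text file
#'
#' The format is a set of `#`-prefixed metadata header lines (epitope,
#' anchors, assay, free-text notes) followed by a tab-separated matrix: 20
#' rows labelled by amino acid, one column per scored position.  Entries
#' survive a round-trip through [read_pwm()] to at least 12 significant
#' digits.
#'
#' @param pwm a [tcr_pwm] object.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_pwm <- function(pwm, path) {
  stopifnot(inherits(pwm, "tcr_pwm"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# epitope: %s", pwm$epitope),
    sprintf("# anchors: %s", paste(pwm$anchors, collapse = ",")),
    sprintf("# assay: %s", pwm$assay),
    sprintf("# notes: %s", pwm$notes %||% "")
  ), con)
  m <- pwm$weights
  header <- paste(c("aa", colnames(m)), collapse = "\t")
  writeLines(header, con)
  for (i in seq_len(nrow(m))) {
    writeLines(paste(c(rownames(m)[i],
                       format(m[i, ], digits = 15, scientific = FALSE,
                              trim = TRUE)),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a position weight matrix written by [write_pwm()]
#'
#' @param path path to a PWM file.
#' @return a [tcr_pwm] object.
#' @export
read_pwm <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- sub("^#\\s*", "", ln)
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*:\\s*", "", kv)
    meta[[trimws(key)]] <- trimws(val)
  }
  if (is.null(meta$epitope) || !nzchar(meta$epitope)) {
    stop(sprintf("%s: missing 'epitope' metadata line", path), call. = FALSE)
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  positions <- as.integer(header[-1])
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  aa <- vapply(rows, `[`, character(1), 1L)
  bad <- setdiff(aa, AMINO_ACIDS)
  if (length(bad) > 0L) {
    stop(sprintf("%s: row label(s) outside the 20 canonical amino acids: %s",
                 path, paste(bad, collapse = ", ")), call. = FALSE)
  }
  w <- t(vapply(rows, function(r) as.numeric(r[-1]),
                numeric(length(positions))))
  rownames(w) <- aa
  colnames(w) <- positions
  w <- w[AMINO_ACIDS, , drop = FALSE]
  anchors <- if (!is.null(meta$anchors) && nzchar(meta$anchors)) {
    as.integer(strsplit(meta$anchors, ",")[[1]])
  } else integer()
  new_tcr_pwm(epitope = meta$epitope, anchors = anchors, weights = w,
              assay = meta$assay %||% "unknown", notes = meta$notes)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a ranked off-target hit report
#'
#' Tab-separated report with one row per candidate peptide: rank, sequence,
#' per-assay and combined recognition scores, IC50, Hamming distance to the
#' reference epitope, provenance (`protein:gene:start`, semicolon-joined) and,
#' when expression annotation is present, maximum TPM and the number of
#' tissues above the TPM threshold.
#'
#' @param scored a ranked data.frame from [rank_peptides()] (optionally
#'   passed through [annotate_expression()]).
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_report <- function(scored, path) {
  cols <- intersect(
    c("rank", "peptide", "binding", "activation", "killing", "combined",
      "ic50_nm", "hamming", "provenance", "max_tpm", "tissues_above_tpm",
      "expression_flag"),
    names(scored))
  out <- scored[cols]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), "NA", format(v, digits = 12, scientific = FALSE,
                                  trim = TRUE))
  })
  write.table(out, file = path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}
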