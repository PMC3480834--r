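#' Read a 3'UTR FASTA file
#'
#' Reads a multi-record FASTA file of 3'UTR sequences (sense strand,
#' 5'->3') into a named [Biostrings::DNAStringSet]. Sequences are
#' uppercased and RNA `U` is normalized to `T`. The gene identifier is the
#' first whitespace-delimited token of each header line.
#'
#' @param path Path to a FASTA file. Line-wrapped sequences are allowed.
#' @return A named `DNAStringSet`; names are unique gene identifiers.
#' @details Characters outside `A`, `C`, `G`, `T`, `N` (after
#'   normalization) are an error, as are duplicated identifiers and empty
#'   sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1 some description", "TCAT", "CTCA"), fa)
#' read_utr_fasta(fa)
#' @export
read_utr_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate identifier ", paste(unique(dup), collapse = ", "))
  }
  seqs <- chartr("U", "T", toupper(as.character(x)))
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty sequence for: ", paste(ids[empty], collapse = ", "))
  }
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop(
      "illegal character '", substr(seqs[i], bad[i], bad[i]),
      "' in sequence ", ids[i], " at position ", bad[i]
    )
  }
  names(seqs) <- ids
  Biostrings::DNAStringSet(seqs)
}

#' Coerce UTR input to a validated DNAStringSet
#'
#' Accepts a named character vector or a `DNAStringSet` and applies the
#' same normalization rules as [read_utr_fasta()].
#' @param utrs Named character vector or `DNAStringSet` of UTR sequences.
#' @return A named `DNAStringSet`.
#' @export
as_utr_set <- function(utrs) {
  if (methods::is(utrs, "DNAStringSet")) {
    seqs <- as.character(utrs)
  } else if (is.character(utrs)) {
    seqs <- chartr("U", "T", toupper(utrs))
  } else {
    stop("utrs must be a named character vector or a DNAStringSet")
  }
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all UTR sequences must be named")
  if (anyDuplicated(ids)) {
    stop("duplicate identifier ", ids[duplicated(ids)][1L])
  }
  if (any(!nzchar(seqs))) stop("empty sequence for: ", ids[!nzchar(seqs)][1L])
  bad <- regexpr("[^ACGTN]", seqs)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop("illegal character in sequence ", ids[i], " at position ", bad[i])
  }
  Biostrings::DNAStringSet(seqs)
}

#' Write UTR sequences to FASTA
#'
#' @param utrs Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @param width Line-wrap width in nucleotides.
#' @return Invisibly, `path`.
#' @export
write_utr_fasta <- function(utrs, path, width = 70L) {
  utrs <- as_utr_set(utrs)
  Biostrings::writeXStringSet(utrs, path, width = width)
  invisible(path)
}

#' Read a gene-level fold-change table
#'
#' Reads a TSV with (at least) columns `gene_id` and `logFC`; `logFC` is a
#' base-2 log fold change (e.g. miRNA transfection vs mock). Rows with a
#' missing or non-numeric `logFC` are dropped with a message; duplicate
#' gene identifiers are an error.
#'
#' @param path Path to a tab-separated file with a header.
#' @return A `data.frame` with columns `gene_id` (character) and `logfc`
#'   (numeric).
#' @export
read_foldchange_table <- function(path) {
  if (!file.exists(path)) stop("fold-change table not found: ", path)
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  cols <- names(raw)
  id_col <- match("gene_id", cols)
  fc_col <- match("logFC", cols)
  if (is.na(fc_col)) fc_col <- match("logfc", cols)
  if (is.na(id_col) || is.na(fc_col)) {
    stop("expected columns gene_id and logFC; found: ",
         paste(cols, collapse = ", "))
  }
  fc <- data.frame(
    gene_id = as.character(raw[[id_col]]),
    logfc = suppressWarnings(as.numeric(raw[[fc_col]])),
    stringsAsFactors = FALSE
  )
  if (nrow(fc) == 0) {
    warning("fold-change table has no data rows")
    return(fc)
  }
  drop <- !is.finite(fc$logfc)
  if (any(drop)) {
    message("dropped ", sum(drop), " row(s) with missing/non-numeric logFC")
    fc <- fc[!drop, , drop = FALSE]
  }
  if (anyDuplicated(fc$gene_id)) {
    stop("duplicate gene_id in fold-change table: ",
         fc$gene_id[duplicated(fc$gene_id)][1L])
  }
  rownames(fc) <- NULL
  fc
}

#' Read a per-array expression matrix
#'
#' TSV with a `gene_id` column followed by one numeric column per array
#' (log2 intensities).
#'
#' @param path Path to a tab-separated file with a header.
#' @return A numeric matrix with gene identifiers as row names.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  raw <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (!"gene_id" %in% names(raw)) {
    stop("expected a gene_id column; found: ", paste(names(raw), collapse = ", "))
  }
  ids <- as.character(raw$gene_id)
  if (anyDuplicated(ids)) stop("duplicate gene_id in expression matrix")
  m <- as.matrix(raw[, setdiff(names(raw), "gene_id"), drop = FALSE])
  storage.mode(m) <- "double"
  if (ncol(m) < 2) stop("expression matrix needs at least 2 array columns")
  rownames(m) <- ids
  m
}

#' Write a result table as deterministic TSV
#'
#' Writes a data frame as a tab-separated file with a header, `.` decimal
#' separator, no quoting and no row names. Rows are ordered by `sort_by`
#' (default: the first column) so that identical inputs produce
#' byte-identical files.
#'
#' @param x A data frame with a fixed schema.
#' @param path Output path.
#' @param sort_by Column name(s) to sort by, or `NULL` to keep row order
#'   (used when the table carries its own rank order).
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path, sort_by = names(x)[1L]) {
  stopifnot(is.data.frame(x))
  if (!is.null(sort_by) && nrow(x) > 0) {
    missing_cols <- setdiff(sort_by, names(x))
    if (length(missing_cols)) stop("unknown sort column: ", missing_cols[1L])
    x <- x[do.call(order, unname(x[sort_by])), , drop = FALSE]
  }
  # doubles are serialized with 17 significant digits so that reading the
  # file back reproduces the values bit-exactly
  for (j in seq_along(x)) {
    if (is.double(x[[j]])) x[[j]] <- sprintf("%.17g", x[[j]])
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, dec = ".", eol = "\n")
  invisible(path)
}

#' Read back a TSV written by [write_tsv()]
#'
#' @param path Path to a tab-separated file with a header.
#' @return A `data.frame`.
#' @export
read_tsv <- function(path) {
  read.delim(path, header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Analysis configuration
#'
#' Bundles the tunable parameters of the pipeline.
#'
#' @param fc_cutoff Linear fold-change threshold (> 1). Genes with
#'   `|logFC| >= log2(fc_cutoff)` enter the up/down sets; the default 1.1
#'   corresponds to `|logFC| >= log2(1.1) ~ 0.1375`.
#' @param variance_cutoff Between-array variance threshold for the
#'   non-specific filter (log2 scale).
#' @param variance_mode `"absolute"` (retain variance >= cutoff) or
#'   `"quantile"` (retain above the `variance_cutoff` quantile of the
#'   variance distribution).
#' @param k Word length for the k-mer analysis (6 or 7 typical).
#' @param n_permutations Number of ranked-list permutations for the word
#'   statistic null.
#' @param rng_seed Integer seed governing all randomized steps.
#' @param nochange_size Number of genes in the no-change set, or
#'   `"match-down"` to balance it against the down set.
#' @param mutual_exclusivity Logical; count each seed-core occurrence
#'   under its strongest matching site class only.
#' @return A list of class `"analysis_config"`.
#' @export
analysis_config <- function(fc_cutoff = 1.1,
                            variance_cutoff = 0.25,
                            variance_mode = c("absolute", "quantile"),
                            k = 7L,
                            n_permutations = 100L,
                            rng_seed = 1L,
                            nochange_size = "match-down",
                            mutual_exclusivity = TRUE) {
  variance_mode <- match.arg(variance_mode)
  stopifnot(fc_cutoff > 1, n_permutations >= 1, k >= 1)
  if (!identical(nochange_size, "match-down")) {
    stopifnot(is.numeric(nochange_size), nochange_size >= 0)
    nochange_size <- as.integer(nochange_size)
  }
  structure(
    list(
      fc_cutoff = fc_cutoff,
      variance_cutoff = variance_cutoff,
      variance_mode = variance_mode,
      k = as.integer(k),
      n_permutations = as.integer(n_permutations),
      rng_seed = as.integer(rng_seed),
      nochange_size = nochange_size,
      mutual_exclusivity = isTRUE(mutual_exclusivity)
    ),
    class = "analysis_config"
  )
}

#' @export
print.analysis_config <- function(x, ...) {
  cat("Analysis configuration\n")
  cat("  fc_cutoff:          ", x$fc_cutoff,
      " (|logFC| >= ", signif(log2(x$fc_cutoff), 4), ")\n", sep = "")
  cat("  variance_cutoff:    ", x$variance_cutoff,
      " [", x$variance_mode, "]\n", sep = "")
  cat("  k:                  ", x$k, "\n", sep = "")
  cat("  n_permutations:     ", x$n_permutations, "\n", sep = "")
  cat("  rng_seed:           ", x$rng_seed, "\n", sep = "")
  cat("  nochange_size:      ", x$nochange_size, "\n", sep = "")
  cat("  mutual_exclusivity: ", x$mutual_exclusivity, "\n", sep = "")
  invisible(x)
}
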