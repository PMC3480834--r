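#' Non-specific variance filter
#'
#' Removes genes with low expression variance across arrays before
#' differential analysis. The default reading of the cutoff is an
#' absolute threshold on the between-array sample variance of log2
#' intensities (denominator `n - 1`); genes with variance at or above
#' the cutoff are retained. A quantile mode retains genes above the
#' given quantile of the variance distribution.
#'
#' @param expr Numeric matrix of log2 intensities, genes in rows
#'   (row names are gene identifiers), arrays in columns.
#' @param variance_cutoff Variance threshold (absolute mode) or quantile
#'   in `[0, 1]` (quantile mode).
#' @param mode `"absolute"` or `"quantile"`.
#' @return Character vector of retained gene identifiers.
#' @export
variance_filter <- function(expr, variance_cutoff = 0.25,
                            mode = c("absolute", "quantile")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 2) stop("variance filter needs at least 2 arrays")
  if (is.null(rownames(expr))) stop("expression matrix must have gene row names")
  mu <- rowMeans(expr)
  v <- rowSums((expr - mu)^2) / (ncol(expr) - 1L)
  thr <- if (mode == "absolute") variance_cutoff else quantile(v, variance_cutoff)
  rownames(expr)[v >= thr]
}

#' Partition genes into up, down and no-change sets
#'
#' Genes with `logFC <= -log2(fc_cutoff)` form the down set and genes
#' with `logFC >= log2(fc_cutoff)` the up set (inclusive thresholds).
#' The no-change set holds the remaining genes with smallest `|logFC|`
#' (fold changes centered on zero), with ties broken lexicographically by
#' gene identifier; its size is `nochange_size`, or the size of the down
#' set when `"match-down"`.
#'
#' @param fc A fold-change `data.frame` with columns `gene_id` and
#'   `logfc` (see [read_foldchange_table()]).
#' @param fc_cutoff Linear fold-change threshold (> 1); the default 1.1
#'   gives `|logFC| >= log2(1.1)`.
#' @param nochange_size Integer, or `"match-down"`.
#' @return An object of class `"gene_sets"`: a list with character
#'   vectors `up`, `down`, `nochange`, a named numeric `mean_logfc`, the
#'   threshold used, and an assignment table `table` with columns
#'   `gene_id`, `logfc`, `set`.
#' @examples
#' fc <- data.frame(gene_id = c("A", "B", "C", "D"),
#'                  logfc = c(-0.5, -0.05, 0.3, 0.01))
#' define_gene_sets(fc)
#' @export
define_gene_sets <- function(fc, fc_cutoff = 1.1,
                             nochange_size = "match-down") {
  stopifnot(is.data.frame(fc), all(c("gene_id", "logfc") %in% names(fc)))
  if (nrow(fc) == 0) stop("empty fold-change table")
  if (anyDuplicated(fc$gene_id)) stop("duplicate gene_id in fold-change table")
  stopifnot(fc_cutoff > 1)
  thr <- log2(fc_cutoff)
  down <- fc$gene_id[fc$logfc <= -thr]
  up <- fc$gene_id[fc$logfc >= thr]
  if (length(down) == 0) warning("down set is empty at fc_cutoff ", fc_cutoff)
  if (length(up) == 0) warning("up set is empty at fc_cutoff ", fc_cutoff)

  rest <- fc[!(fc$gene_id %in% c(down, up)), , drop = FALSE]
  n_nc <- if (identical(nochange_size, "match-down")) length(down)
          else as.integer(nochange_size)
  n_nc <- min(n_nc, nrow(rest))
  rest <- rest[order(abs(rest$logfc), rest$gene_id), , drop = FALSE]
  nochange <- rest$gene_id[seq_len(n_nc)]

  set <- rep("unassigned", nrow(fc))
  set[fc$gene_id %in% up] <- "up"
  set[fc$gene_id %in% down] <- "down"
  set[fc$gene_id %in% nochange] <- "nochange"
  tab <- data.frame(gene_id = fc$gene_id, logfc = fc$logfc, set = set,
                    stringsAsFactors = FALSE)

  set_mean <- function(ids) {
    if (length(ids) == 0) return(NA_real_)
    mean(fc$logfc[match(ids, fc$gene_id)])
  }
  structure(
    list(
      up = up,
      down = down,
      nochange = nochange,
      mean_logfc = c(up = set_mean(up), down = set_mean(down),
                     nochange = set_mean(nochange)),
      fc_cutoff = fc_cutoff,
      logfc_threshold = thr,
      table = tab
    ),
    class = "gene_sets"
  )
}

#' @export
print.gene_sets <- function(x, ...) {
  cat("Gene sets at |logFC| >= ", signif(x$logfc_threshold, 4),
      " (FC ", x$fc_cutoff, ")\n", sep = "")
  for (s in c("up", "down", "nochange")) {
    cat(sprintf("  %-9s %5d genes  mean logFC % .4f\n",
                s, length(x[[s]]), x$mean_logfc[[s]]))
  }
  invisible(x)
}
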