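#' Candidate miRNA target table
#'
#' Filters the down set to genes carrying at least one site of class
#' 7mer-m8, 7mer-1A or 8mer in their 3'UTR (6mer-only genes are
#' excluded), and orders the result by ascending logFC (strongest
#' down-regulation first).
#'
#' @param sets A `"gene_sets"` object from [define_gene_sets()].
#' @param site_counts A `data.frame` from [scan_utrs()].
#' @param fc Fold-change `data.frame` (`gene_id`, `logfc`).
#' @return A `data.frame` with columns `gene_id`, `logfc`, `n_8mer`,
#'   `n_7mer_m8`, `n_7mer_1a`, `n_6mer`, `best_class`, possibly empty.
#' @export
candidate_targets <- function(sets, site_counts, fc) {
  stopifnot(inherits(sets, "gene_sets"))
  down <- sets$down
  idx <- match(down, site_counts$gene_id)
  if (anyNA(idx)) {
    stop("no site counts for gene: ", down[is.na(idx)][1L])
  }
  sc <- site_counts[idx, , drop = FALSE]
  keep <- (sc$n_8mer + sc$n_7mer_m8 + sc$n_7mer_1a) >= 1
  sc <- sc[keep, , drop = FALSE]
  lf <- fc$logfc[match(sc$gene_id, fc$gene_id)]
  out <- data.frame(
    gene_id = sc$gene_id,
    logfc = lf,
    n_8mer = sc$n_8mer,
    n_7mer_m8 = sc$n_7mer_m8,
    n_7mer_1a = sc$n_7mer_1a,
    n_6mer = sc$n_6mer,
    best_class = sc$best_class,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$logfc, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pearson correlation between paired expression vectors
#'
#' Sample Pearson correlation with a two-sided p-value from the exact t
#' transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of
#' freedom (via [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length (`n >= 3`), e.g. miRNA and
#'   mRNA expression across the same samples.
#' @param n_permutations If `NULL` (default), the p-value comes from the
#'   exact t transform; otherwise a two-sided permutation p-value is
#'   computed from this many random pairings of `x` against shuffled `y`.
#' @param rng_seed Integer seed for the permutation option.
#' @return A list with `r`, `p_value` and `n`.
#' @examples
#' pearson_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4)) # r = 0.8, p = 0.2
#' @export
pearson_correlation <- function(x, y, n_permutations = NULL, rng_seed = 1L) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (anyNA(x) || anyNA(y)) stop("missing values in input vectors")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance in input vector")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  p <- ct$p.value
  if (!is.null(n_permutations)) {
    stopifnot(n_permutations >= 1)
    set.seed(rng_seed)
    r_obs <- unname(ct$estimate)
    r_perm <- vapply(seq_len(n_permutations),
                     function(i) cor(x, y[sample.int(length(y))]),
                     numeric(1))
    p <- (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_permutations + 1)
  }
  list(r = unname(ct$estimate), p_value = p, n = length(x))
}
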