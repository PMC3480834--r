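#' Per-gene k-mer count matrix
#'
#' Counts overlapping occurrences of every DNA word of length `k` in
#' each sequence. Windows containing `N` contribute to no word.
#'
#' @param utrs Named character vector or `DNAStringSet`.
#' @param k Word length (1 to 12 practical).
#' @return Integer matrix, genes in rows (row names are gene ids), all
#'   `4^k` words in columns (lexicographic order).
#' @export
kmer_count_matrix <- function(utrs, k) {
  utrs <- as_utr_set(utrs)
  k <- as.integer(k)
  stopifnot(k >= 1, k <= 12)
  if (k > max(Biostrings::width(utrs))) {
    stop("k = ", k, " exceeds the longest sequence (",
         max(Biostrings::width(utrs)), " nt)")
  }
  m <- Biostrings::oligonucleotideFrequency(utrs, width = k)
  rownames(m) <- names(utrs)
  m
}

#' Rank sequences by fold change
#'
#' Produces the deterministic ranked list used by the word analysis:
#' ascending logFC (most down-regulated first), ties broken
#' lexicographically by gene identifier. Every fold-change gene must have
#' a UTR sequence.
#'
#' @param utrs Named character vector or `DNAStringSet`.
#' @param fc Fold-change `data.frame` (`gene_id`, `logfc`).
#' @return A list with `utrs` (a `DNAStringSet` in rank order), `gene_id`
#'   and `logfc` vectors in the same order.
#' @export
rank_sequences <- function(utrs, fc) {
  utrs <- as_utr_set(utrs)
  stopifnot(is.data.frame(fc), all(c("gene_id", "logfc") %in% names(fc)))
  if (nrow(fc) < 2) stop("need at least 2 genes to rank")
  missing_ids <- setdiff(fc$gene_id, names(utrs))
  if (length(missing_ids)) stop("no UTR sequence for gene: ", missing_ids[1L])
  ord <- order(fc$logfc, fc$gene_id)
  list(
    utrs = utrs[fc$gene_id[ord]],
    gene_id = fc$gene_id[ord],
    logfc = fc$logfc[ord]
  )
}

#' Running-sum overrepresentation profile for one word
#'
#' Given per-gene occurrence counts `x_i` and sequence lengths `L_i` in
#' ranked-list order, computes length-normalized rates `r_i = x_i / L_i`,
#' mean-centered increments `u_i = r_i - mean(r)` and the running sum
#' `R_j = sum_{i <= j} u_i`. The max-deviation statistic is
#' `D = max_j R_j` (0 when the profile never rises above zero). By
#' construction `R_n = 0`, so a positive `D` measures
#' overrepresentation at the head of the list.
#'
#' @param counts Non-negative numeric vector of word counts, ranked order.
#' @param lengths Positive numeric vector of sequence lengths (nt).
#' @param two_sided Use `max |R_j|` instead of `max R_j`.
#' @return A list with `profile` (numeric vector `R`) and `d_stat`.
#' @export
running_sum_profile <- function(counts, lengths, two_sided = FALSE) {
  stopifnot(length(counts) == length(lengths), length(counts) >= 2)
  if (any(lengths <= 0)) stop("sequence lengths must be positive")
  r <- counts / lengths
  u <- r - mean(r)
  R <- cumsum(u)
  d <- if (two_sided) max(abs(R)) else max(0, max(R))
  list(profile = R, d_stat = d)
}

#' Permutation Z-score for one word
#'
#' Standardizes the observed max-deviation statistic against its null
#' distribution under uniformly random re-orderings of the gene list.
#'
#' @inheritParams running_sum_profile
#' @param n_permutations Number of random permutations (default 100).
#' @param rng_seed Integer seed.
#' @return A list with `d_obs`, `z_score`, `empirical_p`
#'   (`(1 + #\{d_perm >= d_obs\}) / (n_permutations + 1)`), `degenerate`
#'   (`TRUE` when the permutation distribution has zero spread, in which
#'   case `z_score` is 0) and the permutation summaries `perm_mean`,
#'   `perm_sd`.
#' @export
permutation_z <- function(counts, lengths, n_permutations = 100L,
                          rng_seed = 1L, two_sided = FALSE) {
  n <- length(counts)
  if (n < 3) stop("permutation null needs at least 3 genes")
  stopifnot(n_permutations >= 1)
  obs <- running_sum_profile(counts, lengths, two_sided = two_sided)
  u <- counts / lengths
  u <- u - mean(u)
  set.seed(rng_seed)
  d_perm <- vapply(seq_len(n_permutations), function(i) {
    R <- cumsum(u[sample.int(n)])
    if (two_sided) max(abs(R)) else max(0, max(R))
  }, numeric(1))
  mu <- mean(d_perm)
  s <- sd(d_perm)
  degenerate <- !is.finite(s) || s == 0
  list(
    d_obs = obs$d_stat,
    z_score = if (degenerate) 0 else (obs$d_stat - mu) / s,
    empirical_p = (1 + sum(d_perm >= obs$d_stat)) / (n_permutations + 1),
    degenerate = degenerate,
    perm_mean = mu,
    perm_sd = s
  )
}

#' Rank all k-mer words by permutation Z-score
#'
#' Scores every word of length `k` by its running-sum max-deviation
#' statistic on the fold-change-ranked UTR list, standardized against a
#' permutation null. One set of `n_permutations` random orderings is
#' drawn per run and shared across all words, so ranks are mutually
#' consistent. Words are ranked by descending Z, ties broken
#' lexicographically.
#'
#' @param utrs Named character vector or `DNAStringSet`.
#' @param fc Fold-change `data.frame` (`gene_id`, `logfc`).
#' @param k Word length.
#' @param n_permutations Permutations of the ranked gene list.
#' @param rng_seed Integer seed.
#' @param two_sided Use `max |R_j|` as the deviation statistic.
#' @param adjust_p Add a `p_adjusted` column (Benjamini-Hochberg on the
#'   empirical p-values).
#' @return A `data.frame` sorted by `rank` with columns `word`, `d_stat`,
#'   `z_score`, `empirical_p`, `degenerate`, `rank` (and optionally
#'   `p_adjusted`). Attributes `k`, `n_genes`, `n_permutations`,
#'   `rng_seed` record the run.
#' @export
rank_words <- function(utrs, fc, k = 7L, n_permutations = 100L,
                       rng_seed = 1L, two_sided = FALSE, adjust_p = FALSE) {
  ranked <- rank_sequences(utrs, fc)
  n <- length(ranked$gene_id)
  if (n < 3) stop("permutation null needs at least 3 genes")
  counts <- kmer_count_matrix(ranked$utrs, k)
  lens <- Biostrings::width(ranked$utrs)
  if (any(lens <= 0)) stop("sequence lengths must be positive")

  set.seed(rng_seed)
  orders <- cbind(seq_len(n),
                  replicate(n_permutations, sample.int(n)))
  d <- dstat_by_order(counts, as.numeric(lens), orders, two_sided)
  d_obs <- d[1L, ]
  d_perm <- d[-1L, , drop = FALSE]
  mu <- colMeans(d_perm)
  s <- sqrt(colSums((d_perm - rep(mu, each = n_permutations))^2) /
              max(1L, n_permutations - 1L))
  degenerate <- !is.finite(s) | s == 0
  z <- ifelse(degenerate, 0, (d_obs - mu) / s)
  emp_p <- (1 + colSums(d_perm >= rep(d_obs, each = n_permutations))) /
    (n_permutations + 1)

  res <- data.frame(
    word = colnames(counts),
    d_stat = d_obs,
    z_score = z,
    empirical_p = emp_p,
    degenerate = degenerate,
    stringsAsFactors = FALSE
  )
  ord <- order(-res$z_score, res$word)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  if (adjust_p) res$p_adjusted <- p.adjust(res$empirical_p, method = "BH")
  rownames(res) <- NULL
  attr(res, "k") <- as.integer(k)
  attr(res, "n_genes") <- n
  attr(res, "n_permutations") <- as.integer(n_permutations)
  attr(res, "rng_seed") <- as.integer(rng_seed)
  res
}

#' Running-sum trace for a word with its permutation ensemble
#'
#' Recreates the visualization substrate for a single word: the observed
#' running-sum profile over the ranked list together with the profiles of
#' the permuted lists (the "grey lines").
#'
#' @inheritParams rank_words
#' @param word The word to trace (length-`k` DNA string).
#' @param include_permutations Include per-permutation profile columns.
#' @return A `data.frame` with columns `position`, `gene_id`, `logfc`,
#'   `R_obs` and, optionally, `R_perm_1` ... `R_perm_P`.
#' @export
word_profile <- function(utrs, fc, word, n_permutations = 100L,
                         rng_seed = 1L, include_permutations = TRUE) {
  stopifnot(is.character(word), length(word) == 1L)
  word <- chartr("U", "T", toupper(word))
  if (grepl("[^ACGT]", word)) stop("word must be over A/C/G/T")
  ranked <- rank_sequences(utrs, fc)
  n <- length(ranked$gene_id)
  counts <- Biostrings::vcountPattern(word, ranked$utrs, fixed = TRUE)
  lens <- Biostrings::width(ranked$utrs)
  u <- counts / lens
  u <- u - mean(u)
  out <- data.frame(
    position = seq_len(n),
    gene_id = ranked$gene_id,
    logfc = ranked$logfc,
    R_obs = cumsum(u),
    stringsAsFactors = FALSE
  )
  if (include_permutations && n_permutations >= 1) {
    set.seed(rng_seed)
    for (p in seq_len(n_permutations)) {
      out[[paste0("R_perm_", p)]] <- cumsum(u[sample.int(n)])
    }
  }
  out
}
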