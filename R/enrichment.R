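#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value by the minimum-likelihood rule:
#' with margins fixed, the p-value is the sum of the probabilities of all
#' tables whose point probability is at most that of the observed table
#' (with a relative tolerance of `1e-7` on the comparison, the convention
#' also used by [stats::fisher.test()]). Vectorized over tables.
#'
#' @param a,b,c,d Cell counts of the table `rbind(c(a, b), c(c, d))`,
#'   where rows are groups (e.g. gene sets) and columns are
#'   with/without-site status.
#' @return Numeric vector of p-values in `(0, 1]`.
#' @examples
#' fisher_exact_two_sided(6, 4, 1, 9) # 10582/184756
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) stop("cell counts must be non-negative")
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  m1 <- a + b   # row margins
  m2 <- c + d
  if (any(m1 == 0 | m2 == 0)) stop("empty table margin")
  k <- a + c    # first-column margin
  p <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(0, k[i] - m2[i])
    hi <- min(k[i], m1[i])
    probs <- dhyper(lo:hi, m1[i], m2[i], k[i])
    p_obs <- dhyper(a[i], m1[i], m2[i], k[i])
    p[i] <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  p
}

#' Gene-fraction seed-site enrichment between gene sets
#'
#' Compares the fraction of genes carrying at least one site of a given
#' class between the down set and the up set, and between the down set
#' and the no-change set, with a two-sided Fisher exact test of the null
#' hypothesis that the with-site gene fractions are equal.
#'
#' A gene "has" a site class when its (exclusive) occurrence count for
#' that class is at least 1; for `site_class = "combined"` a gene
#' qualifies when it has any 7mer-m8, 7mer-1A or 8mer site.
#'
#' @param sets A `"gene_sets"` object from [define_gene_sets()].
#' @param site_counts A `data.frame` from [scan_utrs()].
#' @param site_class Site class or classes; default: all four plus
#'   `"combined"`.
#' @param test `"exact"` (Fisher, default) or `"chisq"` (chi-square with
#'   continuity correction).
#' @return A `data.frame` with one row per site class x comparison:
#'   columns `site_class`, `comparison`, `method`, `a_with`, `a_without`,
#'   `b_with`, `b_without`, `statistic` (difference of with-site
#'   fractions, set A minus set B) and `p_value`. Empty sets yield `NA`
#'   results with a warning.
#' @export
gene_fraction_enrichment <- function(sets, site_counts,
                                     site_class = c(SITE_CLASSES, "combined"),
                                     test = c("exact", "chisq")) {
  test <- match.arg(test)
  stopifnot(inherits(sets, "gene_sets"))
  comparisons <- list("down-vs-up" = c("down", "up"),
                      "down-vs-nochange" = c("down", "nochange"))
  out <- list()
  for (cls in site_class) {
    counts <- site_class_counts(site_counts, cls)
    for (cmp_name in names(comparisons)) {
      cmp <- comparisons[[cmp_name]]
      ga <- sets[[cmp[1]]]
      gb <- sets[[cmp[2]]]
      missing_ids <- setdiff(c(ga, gb), names(counts))
      if (length(missing_ids)) {
        stop("no site counts for gene: ", missing_ids[1L])
      }
      row <- data.frame(
        site_class = cls, comparison = cmp_name, method = "gene-fraction",
        a_with = NA_integer_, a_without = NA_integer_,
        b_with = NA_integer_, b_without = NA_integer_,
        statistic = NA_real_, p_value = NA_real_,
        stringsAsFactors = FALSE
      )
      if (length(ga) == 0 || length(gb) == 0) {
        warning("empty set in comparison ", cmp_name)
      } else {
        aw <- sum(counts[ga] >= 1); bw <- sum(counts[gb] >= 1)
        row$a_with <- aw; row$a_without <- length(ga) - aw
        row$b_with <- bw; row$b_without <- length(gb) - bw
        row$statistic <- aw / length(ga) - bw / length(gb)
        row$p_value <- if (test == "exact") {
          fisher_exact_two_sided(aw, length(ga) - aw, bw, length(gb) - bw)
        } else {
          suppressWarnings(stats::chisq.test(
            rbind(c(aw, length(ga) - aw), c(bw, length(gb) - bw)),
            correct = TRUE
          ))$p.value
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}

#' Size-corrected seed-site occurrence counts
#'
#' Corrects the up, down and no-change sets to the same size by repeated
#' subsampling without replacement to the smallest set's size, and
#' reports the mean total occurrence count of a site class per
#' subsample, with 2.5/97.5 percentile bounds.
#'
#' @inheritParams gene_fraction_enrichment
#' @param site_class A single site class (see [site_class_counts()]).
#' @param n_resamples Number of subsampling repetitions.
#' @param rng_seed Integer seed; results are deterministic given the seed.
#' @return A `data.frame` with columns `set`, `site_class`, `method`,
#'   `set_size`, `subsample_size`, `mean_occurrences`, `q025`, `q975`.
#' @export
size_corrected_occurrences <- function(sets, site_counts, site_class = "combined",
                                       n_resamples = 1000L, rng_seed = 1L) {
  stopifnot(inherits(sets, "gene_sets"), length(site_class) == 1L)
  counts <- site_class_counts(site_counts, site_class)
  members <- list(up = sets$up, down = sets$down, nochange = sets$nochange)
  sizes <- lengths(members)
  if (any(sizes == 0)) {
    stop("empty gene set: ", paste(names(sizes)[sizes == 0], collapse = ", "))
  }
  missing_ids <- setdiff(unlist(members), names(counts))
  if (length(missing_ids)) stop("no site counts for gene: ", missing_ids[1L])
  s <- min(sizes)
  set.seed(rng_seed)
  out <- lapply(names(members), function(nm) {
    x <- counts[members[[nm]]]
    totals <- if (length(x) == s) {
      rep(sum(x), n_resamples)
    } else {
      vapply(seq_len(n_resamples), function(i) sum(sample(x, s)), numeric(1))
    }
    data.frame(
      set = nm, site_class = site_class, method = "size-corrected-occurrence",
      set_size = length(x), subsample_size = s,
      mean_occurrences = mean(totals),
      q025 = unname(quantile(totals, 0.025)),
      q975 = unname(quantile(totals, 0.975)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Seed-site density per kilobase of UTR
#'
#' Total (exclusive) occurrences of a site class in a gene set, per
#' kilobase of total UTR sequence in that set.
#'
#' @param gene_ids Character vector of set members.
#' @param utrs UTR sequences (named character vector or `DNAStringSet`)
#'   covering all members.
#' @param site_counts A `data.frame` from [scan_utrs()].
#' @param site_class A single site class (see [site_class_counts()]).
#' @return Occurrences per kb (numeric scalar).
#' @export
per_kb_density <- function(gene_ids, utrs, site_counts, site_class = "combined") {
  utrs <- as_utr_set(utrs)
  if (length(gene_ids) == 0) stop("empty gene set")
  missing_ids <- setdiff(gene_ids, names(utrs))
  if (length(missing_ids)) stop("no UTR sequence for gene: ", missing_ids[1L])
  counts <- site_class_counts(site_counts, site_class)
  missing_ids <- setdiff(gene_ids, names(counts))
  if (length(missing_ids)) stop("no site counts for gene: ", missing_ids[1L])
  total_nt <- sum(Biostrings::width(utrs[gene_ids]))
  if (total_nt == 0) stop("zero total UTR length")
  1000 * sum(counts[gene_ids]) / total_nt
}
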