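# Independent brute-force oracles used to validate the implementation.
# These deliberately share no code with the package internals: plain
# character vectors, per-position loops and explicit enumerations.

# the study miRNA, reconstructed from its perfectly complementary
# reporter insert
MIR143_MATURE <- "TGAGATGAAGCACTGTAGCTC"

mir143_sites <- function() seed_sites(MIR143_MATURE, name = "miR-143")

# naive per-position scanner with explicit hierarchy resolution
oracle_scan <- function(seq, sites, exclusive = TRUE) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  counts <- c("8mer" = 0L, "7mer-m8" = 0L, "7mer-1A" = 0L, "6mer" = 0L)
  window_eq <- function(p, pat) {
    k <- nchar(pat)
    if (p < 1 || p + k - 1 > L) return(FALSE)
    identical(paste(chars[p:(p + k - 1)], collapse = ""), pat)
  }
  if (exclusive) {
    if (L >= 6) {
      for (p in seq_len(L - 5)) {
        if (!window_eq(p, sites$site_6mer)) next
        m8_ok <- window_eq(p - 1, sites$site_7mer_m8)
        a1_ok <- window_eq(p, sites$site_7mer_1a)
        cls <- if (m8_ok && a1_ok) "8mer"
               else if (m8_ok) "7mer-m8"
               else if (a1_ok) "7mer-1A"
               else "6mer"
        counts[cls] <- counts[cls] + 1L
      }
    }
  } else {
    count_sub <- function(pat) {
      k <- nchar(pat)
      if (L < k) return(0L)
      sum(vapply(seq_len(L - k + 1), window_eq, logical(1), pat = pat))
    }
    counts["8mer"] <- count_sub(sites$site_8mer)
    counts["7mer-m8"] <- count_sub(sites$site_7mer_m8)
    counts["7mer-1A"] <- count_sub(sites$site_7mer_1a)
    counts["6mer"] <- count_sub(sites$site_6mer)
  }
  counts
}

# naive sliding-window k-mer counter; windows containing N count nowhere
oracle_kmer_counts <- function(seq, k) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- integer(0)
  if (L >= k) {
    for (p in seq_len(L - k + 1)) {
      w <- paste(chars[p:(p + k - 1)], collapse = "")
      if (grepl("[^ACGT]", w)) next
      out[w] <- (if (is.na(out[w])) 0L else out[w]) + 1L
    }
  }
  out
}

# two-sided exact p by explicit enumeration of the hypergeometric support
# using log-binomial coefficients (independent of stats::dhyper)
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  k <- a + c
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(m1, a) + lchoose(m2, c) - lchoose(m1 + m2, k))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# brute-force running sum (plain loop, no vectorized cumsum)
oracle_running_sum <- function(counts, lengths) {
  r <- counts / lengths
  mu <- sum(r) / length(r)
  R <- numeric(length(r))
  s <- 0
  for (i in seq_along(r)) {
    s <- s + (r[i] - mu)
    R[i] <- s
  }
  d <- max(R)
  if (d < 0) d <- 0
  list(profile = R, d_stat = d)
}

# all permutations of a vector (n <= 7 sensible)
all_perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  do.call(rbind, lapply(seq_along(v), function(i) {
    cbind(v[i], all_perms(v[-i]), deparse.level = 0)
  }))
}

# random DNA sequences, optionally salted with N characters
rand_seqs <- function(n, len_range = c(20, 120), n_prob = 0,
                      prefix = "s") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    x <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    if (n_prob > 0) {
      hit <- runif(L) < n_prob
      x[hit] <- "N"
    }
    paste(x, collapse = "")
  }, character(1))
  names(seqs) <- paste0(prefix, seq_len(n))
  seqs
}

rand_mirna <- function(len = 21) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
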