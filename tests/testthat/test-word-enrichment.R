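test_that("k-mer counting uses overlapping windows and skips N", {
  m <- kmer_count_matrix(c(g = "ACGTACGT"), 4)
  expect_equal(m[1, "ACGT"], 2L, ignore_attr = TRUE)
  expect_equal(m[1, "CGTA"], 1L, ignore_attr = TRUE)
  expect_equal(sum(m), 5L) # 5 windows total

  m <- kmer_count_matrix(c(g = "AAAA"), 2)
  expect_equal(m[1, "AA"], 3L, ignore_attr = TRUE)
  expect_equal(sum(m), 3L)

  m <- kmer_count_matrix(c(g = "ANA"), 2)
  expect_equal(sum(m), 0L)

  expect_error(kmer_count_matrix(c(g = "ACG"), 4), "exceeds")
})

test_that("k-mer counting matches the naive sliding-window oracle", {
  set.seed(19)
  seqs <- rand_seqs(30, c(3, 50), n_prob = 0.05)
  for (k in c(2, 3, 5)) {
    m <- kmer_count_matrix(seqs, k)
    for (i in seq_along(seqs)) {
      want <- oracle_kmer_counts(seqs[[i]], k)
      got <- m[i, ]
      expect_equal(sum(got), sum(want))
      if (length(want) > 0) {
        expect_equal(got[names(want)], want, ignore_attr = TRUE)
      }
    }
  }
})

test_that("running-sum profile matches hand computation", {
  rs <- running_sum_profile(c(2, 1, 0), c(1000, 1000, 1000))
  expect_equal(rs$profile, c(0.001, 0.001, 0.0))
  expect_equal(rs$d_stat, 0.001)

  # equal rates: centered profile vanishes
  rs <- running_sum_profile(c(3, 6), c(100, 200))
  expect_equal(rs$profile, c(0, 0))
  expect_equal(rs$d_stat, 0)

  # reversed order: profile never rises above zero
  rs <- running_sum_profile(c(0, 1, 2), c(1000, 1000, 1000))
  expect_equal(rs$profile, c(-0.001, -0.001, 0))
  expect_equal(rs$d_stat, 0)

  expect_error(running_sum_profile(c(1, 1), c(10, 0)), "positive")
})

test_that("running sum is conserved and scale-invariant", {
  set.seed(37)
  for (i in 1:50) {
    n <- sample(3:40, 1)
    counts <- rpois(n, 2)
    lens <- sample(50:500, n, replace = TRUE)
    rs <- running_sum_profile(counts, lens)
    expect_lt(abs(rs$profile[n]), 1e-9) # R_n == 0
    expect_gte(rs$d_stat, 0)
    # consistent rescaling of counts and lengths leaves rates unchanged
    rs2 <- running_sum_profile(3 * counts, 3 * lens)
    expect_equal(rs2$profile, rs$profile)
    # brute-force loop oracle agrees
    expect_equal(oracle_running_sum(counts, lens)$d_stat, rs$d_stat)
  }
})

test_that("permutation_z handles degenerate and seeded cases", {
  z <- permutation_z(c(0, 0, 0, 0), c(10, 20, 30, 40), 50, rng_seed = 2)
  expect_true(z$degenerate)
  expect_equal(z$z_score, 0)
  expect_equal(z$d_obs, 0)
  expect_equal(z$empirical_p, 1)

  counts <- c(5, 3, 1, 0, 0, 0)
  lens <- rep(100, 6)
  z1 <- permutation_z(counts, lens, 200, rng_seed = 9)
  z2 <- permutation_z(counts, lens, 200, rng_seed = 9)
  expect_identical(z1, z2)
  expect_error(permutation_z(c(1, 2), c(10, 10)), "at least 3")
})

test_that("sampled permutation null matches exhaustive enumeration", {
  counts <- c(4, 2, 1, 0, 3)
  lens <- c(120, 80, 100, 60, 140)
  perms <- all_perms(1:5) # all 120 orders
  d_all <- apply(perms, 1, function(p) {
    oracle_running_sum(counts[p], lens[p])$d_stat
  })
  z <- permutation_z(counts, lens, n_permutations = 2000, rng_seed = 4)
  # sampled mean/sd within 3 MC standard errors of the exhaustive truth
  se_mean <- sd(d_all) / sqrt(2000)
  expect_lt(abs(z$perm_mean - mean(d_all)), 3 * se_mean)
  expect_lt(abs(z$perm_sd - sd(d_all)), 3 * se_mean)
})

test_that("rank_words is consistent with the single-word path", {
  set.seed(43)
  seqs <- rand_seqs(30, c(30, 120))
  fc <- data.frame(gene_id = names(seqs), logfc = rnorm(30))
  res <- rank_words(seqs, fc, k = 3, n_permutations = 60, rng_seed = 5)
  expect_equal(nrow(res), 64L)
  expect_equal(sort(res$rank), 1:64)
  # d_stat agrees with the pure-R profile for every word
  ranked <- rank_sequences(seqs, fc)
  lens <- Biostrings::width(ranked$utrs)
  m <- kmer_count_matrix(ranked$utrs, 3)
  for (w in sample(colnames(m), 12)) {
    expect_equal(res$d_stat[res$word == w],
                 running_sum_profile(m[, w], lens)$d_stat,
                 tolerance = 1e-12)
  }
})

test_that("words with identical counts tie and rank lexicographically", {
  # AC and GT occur identically in every sequence
  seqs <- c(a = "ACGTAA", b = "AACGTT", c = "ACCGGT", d = "TTTTTT")
  fc <- data.frame(gene_id = names(seqs), logfc = c(-2, -1, 1, 2))
  res <- rank_words(seqs, fc, k = 2, n_permutations = 40, rng_seed = 6)
  i_ac <- which(res$word == "AC")
  i_gt <- which(res$word == "GT")
  expect_equal(res$z_score[i_ac], res$z_score[i_gt])
  expect_lt(res$rank[i_ac], res$rank[i_gt]) # AC before GT
  # within any tie group, rank order is lexicographic word order
  tied <- res[res$z_score == res$z_score[i_ac], ]
  expect_equal(tied$word, sort(tied$word))
})

test_that("a fixed relabeling of the input leaves observed statistics unchanged", {
  set.seed(47)
  seqs <- rand_seqs(20, c(30, 80))
  fc <- data.frame(gene_id = names(seqs), logfc = rnorm(20))
  res1 <- rank_words(seqs, fc, k = 2, n_permutations = 30, rng_seed = 7)
  shuf <- sample(20)
  res2 <- rank_words(seqs[shuf], fc[shuf, ], k = 2, n_permutations = 30,
                     rng_seed = 7)
  # the ranked list is the same, so observed d and z ranking agree
  expect_equal(res1$d_stat, res2$d_stat)
  expect_equal(res1$word, res2$word)
})

test_that("adding head-of-list occurrences never decreases d_stat", {
  set.seed(53)
  lens <- rep(100, 10)
  counts <- rpois(10, 1)
  d0 <- running_sum_profile(counts, lens)$d_stat
  for (extra in 1:5) {
    counts[1] <- counts[1] + 1 # most down-regulated gene
    d1 <- running_sum_profile(counts, lens)$d_stat
    expect_gte(d1, d0)
    d0 <- d1
  }
})

test_that("word_profile reproduces the ranked trace with its ensemble", {
  seqs <- c(g1 = "TCATCTCAAA", g2 = "ACGTACGTAA", g3 = "TTTTTTTTTT",
            g4 = "TCATCTCTTT")
  fc <- data.frame(gene_id = names(seqs), logfc = c(-1, 0.5, 1, -2))
  prof <- word_profile(seqs, fc, "TCATCTC", n_permutations = 5, rng_seed = 8)
  expect_equal(prof$gene_id, c("g4", "g1", "g2", "g3")) # ascending logFC
  expect_lt(abs(prof$R_obs[4]), 1e-12)
  expect_equal(ncol(prof), 4 + 5)
  # the observed trace rises over the site-carrying head of the list
  expect_gt(max(prof$R_obs), 0)
})
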