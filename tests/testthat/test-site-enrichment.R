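test_that("Fisher exact p matches the worked table and degenerate cases", {
  expect_equal(fisher_exact_two_sided(6, 4, 1, 9), 10582 / 184756,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(5, 5, 5, 5), 1.0)
  expect_error(fisher_exact_two_sided(0, 0, 0, 5), "empty table margin")
  expect_error(fisher_exact_two_sided(-1, 2, 3, 4), "non-negative")
})

test_that("Fisher exact p agrees with stats::fisher.test on random tables", {
  set.seed(23)
  for (i in 1:300) {
    tab <- matrix(rpois(4, sample(c(2, 10, 40), 1)), 2)
    if (any(rowSums(tab) == 0)) next
    expect_equal(
      fisher_exact_two_sided(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
      stats::fisher.test(tab)$p.value,
      tolerance = 1e-10
    )
  }
})

test_that("Fisher exact p is symmetric under row swap", {
  set.seed(41)
  a <- sample(0:20, 50, TRUE); b <- sample(1:20, 50, TRUE)
  c <- sample(0:20, 50, TRUE); d <- sample(1:20, 50, TRUE)
  expect_equal(fisher_exact_two_sided(a, b, c, d),
               fisher_exact_two_sided(c, d, a, b))
})

test_that("enriched-direction tail shrinks as a_with grows", {
  # moving one gene into the with-site cell of the enriched set never
  # increases the enriched-direction one-sided tail
  tail_ge <- function(a, b, c, d) {
    # P(X >= a) under the fixed-margin hypergeometric null
    sum(dhyper(a:min(a + b, a + c), a + b, c + d, a + c))
  }
  for (a in 5:9) {
    expect_lte(tail_ge(a + 1, 9 - a, 1, 9), tail_ge(a, 10 - a, 1, 9))
  }
})

test_that("gene-fraction enrichment reproduces the worked contingency", {
  counts <- data.frame(
    gene_id = paste0("g", 1:20),
    n_8mer = c(rep(1L, 6), rep(0L, 4), 1L, rep(0L, 9)),
    n_7mer_m8 = 0L, n_7mer_1a = 0L, n_6mer = 0L,
    best_class = "x", stringsAsFactors = FALSE
  )
  fc <- data.frame(gene_id = paste0("g", 1:20),
                   logfc = c(rep(-1, 10), rep(1, 10)))
  gs <- define_gene_sets(fc, nochange_size = 0)
  res <- suppressWarnings(
    gene_fraction_enrichment(gs, counts, site_class = "8mer")
  )
  row <- res[res$comparison == "down-vs-up", ]
  expect_equal(row$a_with, 6L)
  expect_equal(row$b_with, 1L)
  expect_equal(row$a_with + row$a_without, 10L)
  expect_equal(row$p_value, 10582 / 184756, tolerance = 1e-12)
  expect_equal(row$statistic, 0.5)

  # identical fractions give p = 1
  counts$n_8mer <- rep(c(1L, 0L), 10)
  res <- suppressWarnings(
    gene_fraction_enrichment(gs, counts, site_class = "8mer")
  )
  expect_equal(res$p_value[res$comparison == "down-vs-up"], 1.0)

  # missing site counts are a named hard error
  expect_error(
    gene_fraction_enrichment(gs, counts[-1, ], site_class = "8mer"),
    "g1"
  )
})

test_that("size-corrected occurrences are exact for equal-size sets", {
  counts <- data.frame(
    gene_id = paste0("g", 1:9),
    n_8mer = c(2L, 0L, 1L, 0L, 0L, 3L, 1L, 1L, 0L),
    n_7mer_m8 = 0L, n_7mer_1a = 0L, n_6mer = 0L, best_class = "x",
    stringsAsFactors = FALSE
  )
  fc <- data.frame(gene_id = paste0("g", 1:9),
                   logfc = c(rep(-1, 3), rep(1, 3), rep(0, 3)))
  gs <- define_gene_sets(fc, nochange_size = 3)
  res <- size_corrected_occurrences(gs, counts, "8mer", n_resamples = 50)
  expect_equal(res$mean_occurrences[res$set == "down"], 3) # 2+0+1
  expect_equal(res$q025, res$q975) # all resamples identical
})

test_that("size-corrected subsample mean converges to its expectation", {
  counts <- data.frame(
    gene_id = c("a", "b", "u1", "n1"),
    n_8mer = c(2L, 0L, 1L, 1L),
    n_7mer_m8 = 0L, n_7mer_1a = 0L, n_6mer = 0L, best_class = "x",
    stringsAsFactors = FALSE
  )
  fc <- data.frame(gene_id = c("a", "b", "u1", "n1"),
                   logfc = c(-1, -1, 1, 0))
  gs <- define_gene_sets(fc, nochange_size = 1)
  res <- size_corrected_occurrences(gs, counts, "8mer",
                                    n_resamples = 1000, rng_seed = 3)
  # down = {2, 0} subsampled to size 1: expectation 1, MC se = sd/sqrt(R)
  mc_se <- 1 / sqrt(1000) # sd of a fair draw from {0, 2} is 1
  expect_lt(abs(res$mean_occurrences[res$set == "down"] - 1), 3 * mc_se)

  res2 <- size_corrected_occurrences(gs, counts, "8mer",
                                     n_resamples = 1000, rng_seed = 3)
  expect_identical(res, res2) # seeded determinism

  gs$nochange <- character(0)
  expect_error(size_corrected_occurrences(gs, counts, "8mer"),
               "empty gene set")
})

test_that("per-kb density is total occurrences per total kilobase", {
  ss <- mir143_sites()
  utrs <- c(g1 = paste0(strrep("G", 496), "TCATCTCA", strrep("G", 496)),
            g2 = paste0(strrep("G", 492), "TCATCTCA"),
            g3 = paste0(strrep("G", 742), "TCATCTCA", strrep("G", 742),
                        "TCATCTCA"))
  counts <- scan_utrs(utrs, ss)
  expect_equal(per_kb_density("g1", utrs, counts, "8mer"), 1.0)
  expect_equal(per_kb_density(c("g2", "g3"), utrs, counts, "8mer"), 1.5)
  expect_error(per_kb_density(character(0), utrs, counts, "8mer"),
               "empty gene set")
})

test_that("chi-square mode approximates the exact test at large counts", {
  counts <- data.frame(
    gene_id = paste0("g", 1:400),
    n_8mer = rep(c(1L, 0L, 0L, 0L), 100),
    n_7mer_m8 = 0L, n_7mer_1a = 0L, n_6mer = 0L, best_class = "x",
    stringsAsFactors = FALSE
  )
  fc <- data.frame(gene_id = paste0("g", 1:400),
                   logfc = rep(c(-1, 1), each = 200))
  gs <- define_gene_sets(fc, nochange_size = 0)
  exact <- suppressWarnings(
    gene_fraction_enrichment(gs, counts, "8mer", test = "exact"))
  chisq <- suppressWarnings(
    gene_fraction_enrichment(gs, counts, "8mer", test = "chisq"))
  i <- exact$comparison == "down-vs-up"
  expect_equal(chisq$p_value[i], exact$p_value[i], tolerance = 0.1)
})
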