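#' Synthetic-scenario configuration
#'
#' Parameters of the seeded generator that emulates the statistical
#' structure of a miRNA overexpression microarray experiment: a UTR
#' collection with a controllable fraction of site-carrying genes, a
#' seed-dependent down-shift of carrier fold changes, replicate-array
#' noise for the variance filter, and paired sample-level expression
#' with a target correlation.
#'
#' @param n_genes Number of genes.
#' @param utr_length_mean,utr_length_sd Mean and standard deviation (nt)
#'   of the log-normal UTR length distribution.
#' @param gc_content Fraction of G+C in the i.i.d. base model.
#' @param carrier_fraction Fraction of genes receiving one planted copy
#'   of `planted_word`.
#' @param planted_word The site string written into carriers. Default:
#'   the miR-143 8mer site context `"TCATCTCA"`.
#' @param delta Mean extra down-shift of carrier logFC (log2 units).
#' @param sigma Standard deviation of per-gene logFC noise.
#' @param effect_model `"presence"`: carriers are shifted by `-delta`
#'   regardless of copy number; `"per-site"`: the shift is
#'   `-delta * copies`.
#' @param n_arrays Arrays per condition for the expression matrix
#'   (two conditions, treated and mock).
#' @param var_low,var_high Per-array noise variances of the low- and
#'   high-variability gene components of the expression matrix.
#' @param high_fraction Fraction of genes in the high-variability
#'   component.
#' @param rho Target Pearson correlation of the paired sample vectors.
#' @param n_samples Number of paired samples.
#' @param rng_seed Integer seed; per-stage sub-seeds are derived from it
#'   deterministically so stages can be regenerated independently.
#' @return A list of class `"scenario_config"`.
#' @export
scenario_config <- function(n_genes = 1000L,
                            utr_length_mean = 800,
                            utr_length_sd = 400,
                            gc_content = 0.45,
                            carrier_fraction = 0.3,
                            planted_word = "TCATCTCA",
                            delta = 0.25,
                            sigma = 0.3,
                            effect_model = c("presence", "per-site"),
                            n_arrays = 4L,
                            var_low = 0.05,
                            var_high = 0.6,
                            high_fraction = 0.5,
                            rho = -0.22,
                            n_samples = 184L,
                            rng_seed = 1L) {
  effect_model <- match.arg(effect_model)
  planted_word <- chartr("U", "T", toupper(planted_word))
  stopifnot(
    n_genes >= 1,
    utr_length_mean > 0, utr_length_sd > 0,
    gc_content >= 0, gc_content <= 1,
    carrier_fraction >= 0, carrier_fraction <= 1,
    !grepl("[^ACGT]", planted_word),
    sigma > 0,
    n_arrays >= 1,
    var_low >= 0, var_high >= 0,
    high_fraction >= 0, high_fraction <= 1,
    abs(rho) < 1,
    n_samples >= 3
  )
  structure(
    list(
      n_genes = as.integer(n_genes),
      utr_length_mean = utr_length_mean,
      utr_length_sd = utr_length_sd,
      gc_content = gc_content,
      carrier_fraction = carrier_fraction,
      planted_word = planted_word,
      delta = delta,
      sigma = sigma,
      effect_model = effect_model,
      n_arrays = as.integer(n_arrays),
      var_low = var_low,
      var_high = var_high,
      high_fraction = high_fraction,
      rho = rho,
      n_samples = as.integer(n_samples),
      rng_seed = as.integer(rng_seed)
    ),
    class = "scenario_config"
  )
}

# deterministic per-stage sub-seed, kept inside 32-bit integer range
stage_seed <- function(rng_seed, stage) {
  offsets <- c(utrs = 1, plant = 2, logfc = 3, expr = 4, pairs = 5)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  as.integer((as.double(rng_seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

#' Simulate a 3'UTR sequence collection
#'
#' I.i.d. nucleotides at the configured GC content; lengths drawn from a
#' log-normal distribution with the configured mean/sd and clamped to at
#' least the planted-word length. Background occurrences of the planted
#' word arise by chance and are left in place.
#'
#' @param config A `"scenario_config"`.
#' @return A named `DNAStringSet` (`gene_0001`, ...).
#' @export
simulate_utrs <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(stage_seed(config$rng_seed, "utrs"))
  m <- config$utr_length_mean
  s <- config$utr_length_sd
  sdlog <- sqrt(log(1 + s^2 / m^2))
  meanlog <- log(m) - sdlog^2 / 2
  lens <- pmax(nchar(config$planted_word),
               round(rlnorm(config$n_genes, meanlog, sdlog)))
  gc <- config$gc_content
  base_prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  letters_all <- sample(names(base_prob), sum(lens), replace = TRUE,
                        prob = base_prob)
  big <- paste(letters_all, collapse = "")
  ends <- cumsum(lens)
  seqs <- substring(big, ends - lens + 1L, ends)
  names(seqs) <- sprintf("gene_%04d", seq_along(seqs))
  Biostrings::DNAStringSet(seqs)
}

#' Plant a site word into a carrier subset of UTRs
#'
#' A uniformly chosen subset of `round(carrier_fraction * n)` sequences
#' receives one copy of the planted word, written at a uniform valid
#' offset (overwriting the existing bases).
#'
#' @param utrs A named `DNAStringSet` (or named character vector).
#' @param config A `"scenario_config"`.
#' @return A list with `utrs` (modified `DNAStringSet`) and `carriers`
#'   (named logical vector).
#' @export
plant_word <- function(utrs, config) {
  stopifnot(inherits(config, "scenario_config"))
  utrs <- as_utr_set(utrs)
  seqs <- as.character(utrs)
  w <- nchar(config$planted_word)
  if (any(nchar(seqs) < w)) {
    stop("planted word is longer than some sequences")
  }
  set.seed(stage_seed(config$rng_seed, "plant"))
  n <- length(seqs)
  n_car <- round(config$carrier_fraction * n)
  carriers <- rep(FALSE, n)
  names(carriers) <- names(seqs)
  if (n_car > 0) {
    chosen <- sample.int(n, n_car)
    carriers[chosen] <- TRUE
    for (i in chosen) {
      off <- sample.int(nchar(seqs[i]) - w + 1L, 1L)
      substr(seqs[i], off, off + w - 1L) <- config$planted_word
    }
  }
  list(utrs = Biostrings::DNAStringSet(seqs), carriers = carriers)
}

#' Simulate fold changes with a carrier down-shift
#'
#' `logFC_i = -delta * effect_i + eps_i` with
#' `eps ~ Normal(0, sigma^2)`; `effect_i` is the 0/1 carrier flag
#' (presence model) or the planted/background copy number
#' (per-site model, via `site_counts`).
#'
#' @param carriers Named logical vector of carrier flags.
#' @param config A `"scenario_config"`.
#' @param site_counts Optional named numeric vector of per-gene site
#'   copy numbers, used by the `"per-site"` effect model.
#' @return A fold-change `data.frame` (`gene_id`, `logfc`).
#' @export
simulate_logfc <- function(carriers, config, site_counts = NULL) {
  stopifnot(inherits(config, "scenario_config"), is.logical(carriers))
  n <- length(carriers)
  effect <- as.numeric(carriers)
  if (config$effect_model == "per-site") {
    if (is.null(site_counts)) stop("per-site effect model needs site_counts")
    effect <- as.numeric(site_counts[names(carriers)])
  }
  set.seed(stage_seed(config$rng_seed, "logfc"))
  data.frame(
    gene_id = names(carriers),
    logfc = -config$delta * effect + rnorm(n, 0, config$sigma),
    stringsAsFactors = FALSE
  )
}

#' Simulate a replicate-array expression matrix
#'
#' Per-gene baseline log2 intensity plus per-array Gaussian noise from a
#' two-component variance mixture: a low-variability component below and
#' a high-variability component above a typical non-specific-filter
#' cutoff. Column labels carry the condition
#' (`treated_1..n_arrays`, `mock_1..n_arrays`).
#'
#' @param config A `"scenario_config"`.
#' @return A numeric matrix with gene row names and an attribute
#'   `"component"`: a character vector (`"low"`/`"high"`) giving the true
#'   mixture label of each gene.
#' @export
simulate_expression_matrix <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(stage_seed(config$rng_seed, "expr"))
  n <- config$n_genes
  n_col <- 2L * config$n_arrays
  high <- runif(n) < config$high_fraction
  sd_gene <- sqrt(ifelse(high, config$var_high, config$var_low))
  baseline <- rnorm(n, mean = 8, sd = 2)
  m <- baseline + matrix(rnorm(n * n_col), n, n_col) * sd_gene
  rownames(m) <- sprintf("gene_%04d", seq_len(n))
  colnames(m) <- c(paste0("treated_", seq_len(config$n_arrays)),
                   paste0("mock_", seq_len(config$n_arrays)))
  attr(m, "component") <- ifelse(high, "high", "low")
  m
}

#' Simulate paired expression vectors with a target correlation
#'
#' Draws `n_samples` pairs from a standard bivariate normal with
#' correlation `rho`.
#'
#' @param config A `"scenario_config"`.
#' @return A `data.frame` with columns `sample_id`, `x`, `y`.
#' @export
simulate_paired_samples <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(stage_seed(config$rng_seed, "pairs"))
  n <- config$n_samples
  rho <- config$rho
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  data.frame(sample_id = sprintf("sample_%03d", seq_len(n)),
             x = x, y = y, stringsAsFactors = FALSE)
}

#' Generate a full synthetic scenario
#'
#' Runs all generator stages with per-stage sub-seeds derived from the
#' configured seed.
#'
#' @param config A `"scenario_config"`.
#' @return A list with `utrs` (`DNAStringSet` with planted sites),
#'   `carriers` (named logical), `fc` (fold-change `data.frame`), `expr`
#'   (expression matrix), `pairs` (paired-sample `data.frame`) and
#'   `config`.
#' @export
simulate_scenario <- function(config = scenario_config()) {
  utrs0 <- simulate_utrs(config)
  planted <- plant_word(utrs0, config)
  site_counts <- NULL
  if (config$effect_model == "per-site") {
    site_counts <- Biostrings::vcountPattern(config$planted_word,
                                             planted$utrs, fixed = TRUE)
    names(site_counts) <- names(planted$carriers)
  }
  fc <- simulate_logfc(planted$carriers, config, site_counts = site_counts)
  list(
    utrs = planted$utrs,
    carriers = planted$carriers,
    fc = fc,
    expr = simulate_expression_matrix(config),
    pairs = simulate_paired_samples(config),
    config = config
  )
}

#' Write a simulated scenario to files
#'
#' Produces `utrs.fa`, `fc.tsv`, `expr.tsv`, `pairs.tsv` and `truth.tsv`
#' (carrier flags) in `outdir`.
#'
#' @param scenario Output of [simulate_scenario()].
#' @param outdir Output directory, created if needed.
#' @return Invisibly, the named vector of written paths.
#' @export
write_scenario <- function(scenario, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    utrs = file.path(outdir, "utrs.fa"),
    fc = file.path(outdir, "fc.tsv"),
    expr = file.path(outdir, "expr.tsv"),
    pairs = file.path(outdir, "pairs.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_utr_fasta(scenario$utrs, paths[["utrs"]])
  fc_out <- data.frame(gene_id = scenario$fc$gene_id,
                       logFC = scenario$fc$logfc)
  write_tsv(fc_out, paths[["fc"]])
  expr_out <- data.frame(gene_id = rownames(scenario$expr),
                         scenario$expr, check.names = FALSE)
  write_tsv(expr_out, paths[["expr"]])
  write_tsv(scenario$pairs, paths[["pairs"]])
  write_tsv(data.frame(gene_id = names(scenario$carriers),
                       carrier = as.integer(scenario$carriers)),
            paths[["truth"]])
  invisible(paths)
}
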