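#' Run the full target-identification pipeline
#'
#' Orchestrates all analysis stages in order: optional variance
#' pre-filter, gene-set definition, seed-site scanning, seed-site
#' enrichment (gene-fraction, size-corrected and per-kb methods), k-mer
#' word analysis, candidate-target reporting and, when paired sample
#' vectors are supplied, expression correlation. Each stage writes its
#' TSV output into `outdir` so that any stage can be re-run and audited
#' independently; a JSON manifest records the configuration, input
#' checksums, seeds and per-stage row counts.
#'
#' @param mirna Mature miRNA sequence (or a `"seed_site_set"`).
#' @param utrs Path to a UTR FASTA, a named character vector, or a
#'   `DNAStringSet`.
#' @param fc Path to a fold-change TSV or a `data.frame`
#'   (`gene_id`, `logfc`).
#' @param outdir Output directory, created if needed.
#' @param config An [analysis_config()].
#' @param expr Optional expression matrix (path or matrix) for the
#'   variance pre-filter.
#' @param pairs Optional paired-sample table (path or `data.frame` with
#'   columns `x`, `y`) for the correlation stage.
#' @param mirna_name miRNA name used in reports when `mirna` is a bare
#'   sequence.
#' @return Invisibly, a list with the stage results (`sets`,
#'   `site_counts`, `enrichment`, `size_corrected`, `per_kb`, `words`,
#'   `targets`, `correlation`) and the `manifest`.
#' @export
run_all <- function(mirna, utrs, fc, outdir, config = analysis_config(),
                    expr = NULL, pairs = NULL, mirna_name = "miRNA") {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  input_files <- character(0)

  sites <- if (inherits(mirna, "seed_site_set")) mirna else
    seed_sites(mirna, name = mirna_name)

  if (is.character(utrs) && length(utrs) == 1L && file.exists(utrs)) {
    input_files <- c(input_files, utrs)
    utrs <- read_utr_fasta(utrs)
  } else {
    utrs <- as_utr_set(utrs)
  }
  if (is.character(fc) && length(fc) == 1L) {
    input_files <- c(input_files, fc)
    fc <- read_foldchange_table(fc)
  }
  if (!is.null(expr) && is.character(expr) && length(expr) == 1L) {
    input_files <- c(input_files, expr)
    expr <- read_expression_matrix(expr)
  }
  if (!is.null(pairs) && is.character(pairs) && length(pairs) == 1L) {
    input_files <- c(input_files, pairs)
    pairs <- read_tsv(pairs)
  }

  with_stage <- function(stage, code) {
    tryCatch(code, error = function(e) {
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  # stage: variance pre-filter + gene sets
  sets <- with_stage("gene_sets", {
    if (!is.null(expr)) {
      keep <- variance_filter(expr, config$variance_cutoff,
                              mode = config$variance_mode)
      fc <- fc[fc$gene_id %in% keep, , drop = FALSE]
      if (nrow(fc) == 0) stop("no genes left after variance filter")
    }
    define_gene_sets(fc, fc_cutoff = config$fc_cutoff,
                     nochange_size = config$nochange_size)
  })
  write_tsv(sets$table, file.path(outdir, "sets.tsv"))

  # stage: seed-site scan
  site_counts <- with_stage("scan", {
    missing_ids <- setdiff(fc$gene_id, names(utrs))
    if (length(missing_ids)) {
      stop("no UTR sequence for gene: ", missing_ids[1L])
    }
    scan_utrs(utrs[fc$gene_id], sites,
              exclusive = config$mutual_exclusivity)
  })
  write_tsv(site_counts, file.path(outdir, "sites.tsv"))

  # stage: seed-site enrichment (all three methods)
  degenerate_sets <- length(sets$down) == 0 || length(sets$up) == 0 ||
    length(sets$nochange) == 0
  enrichment <- with_stage("enrichment", {
    if (length(sets$down) == 0) {
      warning("down set empty; enrichment skipped")
      NULL
    } else {
      suppressWarnings(gene_fraction_enrichment(sets, site_counts))
    }
  })
  write_tsv(enrichment %||%
              data.frame(site_class = character(0), comparison = character(0),
                         method = character(0), a_with = integer(0),
                         a_without = integer(0), b_with = integer(0),
                         b_without = integer(0), statistic = numeric(0),
                         p_value = numeric(0)),
            file.path(outdir, "enrichment.tsv"),
            sort_by = c("site_class", "comparison"))

  size_corr <- with_stage("size_corrected", {
    if (degenerate_sets) {
      warning("empty gene set; size-corrected occurrences skipped")
      NULL
    } else {
      do.call(rbind, lapply(c(SITE_CLASSES, "combined"), function(cls) {
        size_corrected_occurrences(sets, site_counts, cls,
                                   rng_seed = config$rng_seed)
      }))
    }
  })
  if (!is.null(size_corr)) {
    write_tsv(size_corr, file.path(outdir, "size_corrected.tsv"),
              sort_by = c("site_class", "set"))
  }

  per_kb <- with_stage("per_kb", {
    if (degenerate_sets) {
      NULL
    } else {
      grid <- expand.grid(set = c("up", "down", "nochange"),
                          site_class = c(SITE_CLASSES, "combined"),
                          stringsAsFactors = FALSE)
      grid$per_kb <- vapply(seq_len(nrow(grid)), function(i) {
        per_kb_density(sets[[grid$set[i]]], utrs, site_counts,
                       grid$site_class[i])
      }, numeric(1))
      grid
    }
  })
  if (!is.null(per_kb)) {
    write_tsv(per_kb, file.path(outdir, "per_kb.tsv"),
              sort_by = c("site_class", "set"))
  }

  # stage: word analysis
  words <- with_stage("words", {
    rank_words(utrs, fc, k = config$k,
               n_permutations = config$n_permutations,
               rng_seed = config$rng_seed)
  })
  write_tsv(words, file.path(outdir, "words.tsv"), sort_by = NULL)

  # stage: candidate targets
  targets <- with_stage("targets", candidate_targets(sets, site_counts, fc))
  write_tsv(targets, file.path(outdir, "targets.tsv"), sort_by = NULL)

  # stage: correlation (optional)
  correlation <- NULL
  if (!is.null(pairs)) {
    correlation <- with_stage("correlation", {
      stopifnot(all(c("x", "y") %in% names(pairs)))
      pearson_correlation(pairs$x, pairs$y)
    })
    write_tsv(data.frame(r = correlation$r, p_value = correlation$p_value,
                         n = correlation$n),
              file.path(outdir, "correlation.tsv"), sort_by = NULL)
  }

  manifest <- list(
    tool = "mirseed",
    version = as.character(packageVersion("mirseed")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    mirna = list(name = sites$name, mature = sites$mature,
                 site_8mer = sites$site_8mer),
    input_checksums = as.list(tools::md5sum(input_files)),
    rng_seed = config$rng_seed,
    row_counts = list(
      genes = nrow(fc),
      up = length(sets$up),
      down = length(sets$down),
      nochange = length(sets$nochange),
      site_counts = nrow(site_counts),
      enrichment = if (is.null(enrichment)) 0L else nrow(enrichment),
      words = nrow(words),
      targets = nrow(targets)
    )
  )
  manifest_path <- file.path(outdir, "manifest.json")
  tmp <- paste0(manifest_path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  file.rename(tmp, manifest_path)

  invisible(list(
    sets = sets, site_counts = site_counts, enrichment = enrichment,
    size_corrected = size_corr, per_kb = per_kb, words = words,
    targets = targets, correlation = correlation, manifest = manifest
  ))
}
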