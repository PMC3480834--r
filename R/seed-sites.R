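#' Reverse complement of DNA sequences
#'
#' Plain-string reverse complement over the alphabet `A`, `C`, `G`, `T`,
#' `N` (N maps to N). Vectorized over its input.
#'
#' @param seq Character vector of DNA sequences.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("TCATCTCA") # "TGAGATGA"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq))
  seq <- toupper(seq)
  bad <- regexpr("[^ACGTN]", seq)
  if (any(bad > 0)) {
    i <- which(bad > 0)[1L]
    stop("illegal character '", substr(seq[i], bad[i], bad[i]),
         "' at position ", bad[i])
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Derive canonical seed-match site strings from a mature miRNA
#'
#' The seed region is nucleotides 2-8 of the mature miRNA (5'->3'). The
#' four canonical site strings, as they appear on the mRNA sense strand,
#' are:
#' \describe{
#'   \item{6mer}{reverse complement of miRNA positions 2-7 (the core).}
#'   \item{7mer-m8}{reverse complement of positions 2-8.}
#'   \item{7mer-1A}{the 6mer core followed by a literal adenosine,
#'     regardless of miRNA position 1.}
#'   \item{8mer}{the 7mer-m8 site followed by that adenosine.}
#' }
#'
#' @param sequence Mature miRNA sequence, 5'->3', RNA or DNA alphabet,
#'   at least 8 nucleotides.
#' @param name miRNA name used in printing and reports.
#' @return An object of class `"seed_site_set"`: a list with elements
#'   `name`, `mature`, `site_6mer`, `site_7mer_m8`, `site_7mer_1a`,
#'   `site_8mer`.
#' @examples
#' mir143 <- reverse_complement("GAGCTACAGTGCTTCATCTCA")
#' seed_sites(mir143, name = "miR-143")
#' @export
seed_sites <- function(sequence, name = "miRNA") {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- chartr("U", "T", toupper(sequence))
  if (grepl("[^ACGT]", sequence)) {
    stop("mature miRNA sequence must be over A/C/G/T (or U)")
  }
  if (nchar(sequence) < 8) {
    stop("mature miRNA sequence must be at least 8 nt; got ",
         nchar(sequence))
  }
  core <- reverse_complement(substr(sequence, 2L, 7L))
  m8 <- reverse_complement(substr(sequence, 2L, 8L))
  structure(
    list(
      name = name,
      mature = sequence,
      site_6mer = core,
      site_7mer_m8 = m8,
      site_7mer_1a = paste0(core, "A"),
      site_8mer = paste0(m8, "A")
    ),
    class = "seed_site_set"
  )
}

#' @export
print.seed_site_set <- function(x, ...) {
  cat("Seed sites for ", x$name, " (", x$mature, ")\n", sep = "")
  cat("  8mer:    ", x$site_8mer, "\n", sep = "")
  cat("  7mer-m8: ", x$site_7mer_m8, "\n", sep = "")
  cat("  7mer-1A: ", x$site_7mer_1a, "\n", sep = "")
  cat("  6mer:    ", x$site_6mer, "\n", sep = "")
  invisible(x)
}

#' Scan 3'UTR sequences for seed-match sites
#'
#' Counts occurrences of the four canonical site classes in each UTR.
#' With `exclusive = TRUE` (the default) every occurrence of the 6mer
#' core is assigned to exactly one class: the strongest class whose full
#' sequence context matches at that locus, with strength order
#' 8mer > 7mer-m8 > 7mer-1A > 6mer. With `exclusive = FALSE` each class
#' is counted as an independent substring (so a single 8mer locus also
#' counts as a 7mer-m8, a 7mer-1A and a 6mer).
#'
#' Overlapping core occurrences are each counted; windows containing `N`
#' match no site.
#'
#' @param utrs Named character vector or `DNAStringSet` of UTR sequences
#'   (mRNA sense strand).
#' @param sites A `"seed_site_set"` from [seed_sites()].
#' @param exclusive Logical; mutually exclusive site-class assignment.
#' @return A `data.frame` with columns `gene_id`, `n_8mer`, `n_7mer_m8`,
#'   `n_7mer_1a`, `n_6mer` and `best_class` (strongest class present, or
#'   `"none"`).
#' @export
scan_utrs <- function(utrs, sites, exclusive = TRUE) {
  stopifnot(inherits(sites, "seed_site_set"))
  utrs <- as_utr_set(utrs)
  raw6 <- Biostrings::vcountPattern(sites$site_6mer, utrs, fixed = TRUE)
  raw7m8 <- Biostrings::vcountPattern(sites$site_7mer_m8, utrs, fixed = TRUE)
  raw7a1 <- Biostrings::vcountPattern(sites$site_7mer_1a, utrs, fixed = TRUE)
  raw8 <- Biostrings::vcountPattern(sites$site_8mer, utrs, fixed = TRUE)
  if (exclusive) {
    # every 7mer-m8/7mer-1A occurrence extends a core occurrence; an
    # occurrence is an 8mer iff it extends both ways, so exclusive counts
    # follow by inclusion-exclusion on the raw substring counts
    n8 <- raw8
    n7m8 <- raw7m8 - raw8
    n7a1 <- raw7a1 - raw8
    n6 <- raw6 - raw7m8 - raw7a1 + raw8
  } else {
    n8 <- raw8
    n7m8 <- raw7m8
    n7a1 <- raw7a1
    n6 <- raw6
  }
  counts <- cbind(n8, n7m8, n7a1, n6)
  present <- counts >= 1L
  best <- rep("none", length(utrs))
  for (j in rev(seq_along(SITE_CLASSES))) {
    best[present[, j]] <- SITE_CLASSES[j]
  }
  data.frame(
    gene_id = names(utrs),
    n_8mer = as.integer(n8),
    n_7mer_m8 = as.integer(n7m8),
    n_7mer_1a = as.integer(n7a1),
    n_6mer = as.integer(n6),
    best_class = best,
    stringsAsFactors = FALSE
  )
}

#' Per-gene occurrence counts for one site class
#'
#' Extracts the occurrence-count vector for a site class from a
#' [scan_utrs()] table. The pseudo-class `"combined"` sums the 7mer-m8,
#' 7mer-1A and 8mer counts (the classes with position-8 or position-1
#' support).
#'
#' @param site_counts A `data.frame` from [scan_utrs()].
#' @param site_class One of `"8mer"`, `"7mer-m8"`, `"7mer-1A"`, `"6mer"`,
#'   `"combined"`.
#' @return Named integer vector of counts, names are gene identifiers.
#' @export
site_class_counts <- function(site_counts, site_class) {
  cols <- c("8mer" = "n_8mer", "7mer-m8" = "n_7mer_m8",
            "7mer-1A" = "n_7mer_1a", "6mer" = "n_6mer")
  if (identical(site_class, "combined")) {
    v <- site_counts$n_8mer + site_counts$n_7mer_m8 + site_counts$n_7mer_1a
  } else {
    col <- cols[[match.arg(site_class, names(cols))]]
    v <- site_counts[[col]]
  }
  names(v) <- site_counts$gene_id
  v
}
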