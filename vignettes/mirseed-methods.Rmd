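---
title: "Methods: seed-site enrichment and ranked-list word analysis"
author: "mirseed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-site enrichment and ranked-list word analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis

When a microRNA is reintroduced into cells that have lost it, its direct
targets are destabilized and their transcripts drop in abundance. Given a
gene-level log2 fold-change profile of such an overexpression experiment
(e.g. a limma contrast of treated vs mock arrays), `mirseed` asks two
complementary questions:

1. **Hypothesis-driven:** are canonical seed-match sites of the
   transfected miRNA overrepresented in the 3'UTRs of the down-regulated
   genes, relative to up-regulated and unchanged genes?
2. **Hypothesis-free:** if we rank *all* k-mer words by their
   overrepresentation toward the down-regulated end of the fold-change
   ranking, do the miRNA's seed words surface at the top?

Genes that are both down-regulated and carry a strong seed site are
reported as candidate targets, and an independent tumor-cohort check asks
whether miRNA and candidate-target expression are anti-correlated across
samples.

## Seed sites and scanning

The seed region is nucleotides 2–8 of the mature miRNA. Writing
`rc()` for reverse complement and `seq[i..j]` for miRNA positions, the
site strings searched on the mRNA sense strand are

| class   | construction            | length |
|---------|--------------------------|--------|
| 6mer    | `rc(seq[2..7])` (the core) | 6 |
| 7mer-m8 | `rc(seq[2..8])`          | 7 |
| 7mer-1A | core + `"A"`             | 7 |
| 8mer    | `rc(seq[2..8])` + `"A"`  | 8 |

The appended adenosine is a literal `A` on the mRNA regardless of the
nucleotide at miRNA position 1, following the standard canon. For
miR-143 (`TGAGATGAAGCACTGTAGCTC`) this yields the 7mer-m8 `TCATCTC` and
the 8mer `TCATCTCA`.

**Mutual exclusivity.** Each occurrence of the 6mer core in a UTR is one
candidate locus. Under exclusive counting (the default) a locus is
assigned to exactly one class — the strongest whose full context matches,
with strength order 8mer > 7mer-m8 > 7mer-1A > 6mer — so class counts are
additive and a single strong site is not double-counted as its weaker
sub-sites. Overlapping core occurrences are each counted. Because the
four site strings nest, exclusive counts follow from raw substring counts
by inclusion–exclusion (`n8 = raw8`, `n7m8 = raw7m8 − raw8`,
`n7a1 = raw7a1 − raw8`, `n6 = raw6 − raw7m8 − raw7a1 + raw8`); the test
suite checks this against an independent per-position classifier.
Windows containing `N` match nothing. Scanning is sense-strand only: the
UTR is the mRNA sequence, and sites are reverse complements of the seed.

## Gene sets

Fold-change thresholds are supplied on the linear scale and applied as
`|logFC| >= log2(fc_cutoff)` (default `fc_cutoff = 1.1`, i.e.
`|logFC| >= 0.1375`), with inclusive boundaries. We read the mixed
"fold change 1.1"/"logFC −1.1" conventions that circulate for such
cutoffs as the log2 reading: a literal logFC cutoff of 1.1 would imply
down-set mean log fold changes far beyond the ~−0.25 typical of miRNA
transfection experiments, whereas log2(1.1) reproduces that scale.

The no-change (background) set is the `n` unassigned genes with smallest
`|logFC|` — fold changes "centered on 0" — with ties broken
lexicographically by gene identifier so the partition is deterministic.
Its size defaults to the down-set size (`"match-down"`) so that
comparisons are size-balanced, and is capped by the number of genes left
between the cutoffs.

An optional non-specific pre-filter removes genes whose between-array
variance of log2 intensity falls below a cutoff (default 0.25,
denominator `n − 1`, inclusive retention at the boundary). Because
"variance cutoff 0.25" can also be read as a quantile in common
filtering practice, a quantile mode is available
(`mode = "quantile"`); the absolute reading is the default.

## Seed-site enrichment statistics

Three views, mirroring how such enrichments are usually presented:

- **Gene fraction.** A gene *has* a site class if its exclusive count is
  ≥ 1 (for the `combined` class: any 7mer-m8, 7mer-1A or 8mer). The
  with/without counts of two sets form a 2×2 table tested with a
  two-sided Fisher exact test. The two-sided p-value uses the
  minimum-likelihood rule — the sum of probabilities of all tables (fixed
  margins) whose point probability is at most that of the observed table,
  with a relative tolerance of 1e-7 on the comparison, the same
  convention as `stats::fisher.test`. The test is implemented as a
  vectorized hypergeometric sum so that whole table families can be
  evaluated; the suite verifies it against both an independent
  enumeration oracle and `stats::fisher.test`. An exact test is
  preferred over chi-square because set sizes and site counts can be
  small; no named test is canonical for this comparison, so exactness
  and oracle-checkability decided the default.
- **Size-corrected occurrences.** Each set is repeatedly subsampled
  without replacement to the smallest set's size (default 1000
  resamples, explicit seed); the mean and 2.5/97.5 percentiles of the
  total occurrence count per subsample are reported. This view is
  descriptive; no p-value is attached.
- **Per-kb density.** Total exclusive occurrences per kilobase of total
  UTR sequence in the set, removing UTR-length confounding. Also
  descriptive.

## Ranked-list word analysis

The word statistic is deliberately self-contained and fully specified
(it is a variant in the spirit of Sylamer/cWords-style ranked-list word
enrichment, not a re-derivation of any published tool's internals):

1. Order the `n` genes by ascending logFC (most down-regulated first),
   ties broken by gene identifier.
2. For each word `w` of length `k`, count overlapping occurrences
   `x_i` per UTR and form length-normalized rates `r_i = x_i / L_i`.
3. Center: `u_i = r_i − mean(r)`; running sum `R_j = Σ_{i≤j} u_i`.
   By construction `R_n = 0`.
4. Max deviation `D = max_j R_j` (clamped at 0 if the profile never
   rises above zero). A positive `D` means the word's occurrence rate is
   concentrated at the down-regulated head of the list. A `two_sided`
   flag scores `max_j |R_j|` instead; the default is one-sided because
   the question is overrepresentation among down-regulated transcripts.
5. Permutation null: the gene order is permuted uniformly at random
   `n_permutations` times (default 100, matching the usual size of such
   permutation ensembles); `Z = (D_obs − mean(D_perm)) / sd(D_perm)` and
   `p_emp = (1 + #{D_perm ≥ D_obs}) / (n_permutations + 1)`. If the
   permutation distribution has zero spread the word is flagged
   degenerate and `Z = 0`.
6. One permutation set is drawn per run and shared across all `4^k`
   words, so ranks are mutually consistent. Words are ranked by
   descending `Z` with lexicographic tie-breaking.

`Z` is a standardization of a maximum statistic, not an exactly standard
normal variate; calibration tests therefore bound its null mean and
spread rather than asserting normality. Benjamini–Hochberg adjustment of
the empirical p-values is available behind `adjust_p = TRUE`; the
primary output is the Z ranking.

Because between carrier genes the centered running sum decays linearly,
the maximum can only be attained immediately after a word-carrying gene;
the compiled kernel exploits this to score all words under all
permutations by streaming each ordering once over the nonzero counts.
The kernel is verified against the plain cumulative-sum implementation
in the tests.

Ranking by ascending logFC (rather than by a significance-weighted rank)
is fixed as the default and exposed as the natural knob via the input
fold-change table itself.

## Candidate targets and anti-correlation

Candidate targets are down-set genes with at least one 7mer-m8, 7mer-1A
or 8mer site (6mer-only genes are excluded as too weakly supported),
ordered by ascending logFC. The same single fold-change cutoff is used
here as in the set definition — one consistent threshold throughout.

`pearson_correlation` returns the sample Pearson r with the exact
two-sided t transform `t = r sqrt(n−2) / sqrt(1−r²)` on `n − 2` degrees
of freedom. Inputs are taken as already suitably transformed
(e.g. log-scale expression); the function does not transform.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
so every stage is testable without downloads. Defaults are the study
conditions of a typical miRNA transfection profile:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | genes after non-specific filtering (order of magnitude of a filtered array) |
| `utr_length_mean`, `utr_length_sd` | 800, 400 nt | log-normal UTR lengths, clamped ≥ planted-word length |
| `gc_content` | 0.45 | i.i.d. base model, roughly human-3'UTR-like |
| `carrier_fraction` | 0.3 | fraction of genes given one planted site copy |
| `planted_word` | `TCATCTCA` | the miR-143 8mer site context |
| `delta` | 0.25 | mean extra logFC down-shift of carriers (the ~0.25-magnitude down-set means seen in such experiments) |
| `sigma` | 0.3 | per-gene logFC noise sd |
| `n_arrays` | 4 | arrays per condition (four biological replicates) |
| `var_low`, `var_high`, `high_fraction` | 0.05, 0.6, 0.5 | variance mixture flanking the 0.25 filter cutoff |
| `rho`, `n_samples` | −0.22, 184 | paired-sample correlation target and cohort size |

The carrier effect is a mean shift (binary has-site framing); a
`per-site` dose model is available behind `effect_model`. A single
scenario seed drives everything, with per-stage sub-seeds derived
deterministically so stages can be regenerated independently; all
generators are bit-reproducible under a fixed seed.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: UTR base composition is i.i.d. (no Markov
structure, repeats, or conservation), site effects are homogeneous
across genes, fold-change noise is Gaussian and independent across
genes, and there are no probe effects, cross-hybridization or
normalization artifacts. Recovery of a planted word under these
conditions demonstrates the statistics are wired correctly and are
calibrated under the null; it does not certify power on real arrays.

## Numerical and design choices

- Thresholds (`fold change`, variance) are inclusive; boundary genes are
  retained. Fixed for determinism where common usage is silent.
- A reported borderline case in this kind of analysis (a gene at
  logFC −0.14 excluded despite |−0.14| ≥ 0.1375) shows published
  boundary handling can be inconsistent; the rule here is strictly the
  stated inclusive threshold.
- All randomized operations take explicit integer seeds and record them
  in their outputs; the pipeline manifest echoes configuration, input
  checksums and per-stage row counts.
- Stages communicate via TSV files with `.` decimals and deterministic
  row/column order; doubles are serialized with 17 significant digits so
  re-reading reproduces values bit-exactly. Auditability was preferred
  over in-memory speed.
- Degenerate inputs: empty down or up sets produce warnings and empty
  downstream outputs rather than errors; empty margins in the exact
  test, zero-length sequences, zero-variance correlation inputs and
  missing per-gene records are hard errors naming the offender.
- Test problem sizes: the oracle-equivalence suites use ~2000 random
  sequences and the full family of 2×2 tables with margins ≤ 30; the
  calibration properties use 500 null scenarios (type-I rate of the
  gene-fraction test), 200 null scenarios (word-Z moments), 100
  planted-signal scenarios (n = 1000 genes, δ = 0.4, k = 7, 100
  permutations) and 100 correlation replicates (n = 184, ρ = −0.22).
  These sizes give Monte-Carlo error comfortably inside the asserted
  bounds.

## Known limitations

- Only canonical seed classes are scanned: no G:U wobble, bulged,
  3'-compensatory or coding-region sites.
- The word statistic's permutation null conditions on the observed
  count matrix; it does not model inter-gene composition correlations.
- Absolute enrichment p-values from any particular published dataset
  depend on the UTR annotation version scanned and are not
  reproduced here; the package's claims are the property-level ones its
  tests compute.
- The Fisher exact implementation enumerates the hypergeometric support
  per table; for margins in the tens of thousands a normal approximation
  would be faster, but such sizes do not arise in this analysis.
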