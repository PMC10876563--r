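---
title: "Ancestry-stratified pathogenic-variant burden: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ancestry-stratified pathogenic-variant burden: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ancestryburden)
library(dplyr)
```

## The problem

Large sequencing cohorts make it possible to ask how often participants
carry a known pathogenic or likely pathogenic (P/LP) variant in a panel of
clinically actionable genes, and whether that rate differs between
genetically predicted ancestry groups. Observed differences can reflect
either true differences in disease-allele frequency or ascertainment bias:
most curated variant knowledge comes from studies of European-ancestry
populations, so a lower "positive rate" in another group may only mean
that group's pathogenic variation is less well catalogued.

`ancestryburden` implements the full analysis as a reusable, tested
pipeline:

1. **knowledge sources** — a curated interpretation database, a
   ClinVar-style export filtered by review status (stars), evaluation date
   and clinical significance, and per-population reference allele
   frequencies with defined subsets (full / non-cancer / non-TopMed);
2. **variant selection** — panel-region subsetting with padding, genotype
   quality (GQ) filtering, zygosity-aware matching against the P/LP set and
   classification of rare predicted loss-of-function (pLoF) variants;
3. **burden statistics** — gene-by-ancestry contingency tables, a
   chi-square independence test with sparse-cell aggregation, a pooled
   two-proportion z-test with Bonferroni control, and binomial confidence
   intervals;
4. **external comparison** — gene-level allele-rate comparison against the
   reference database and its subsets;
5. **phenotype enrichment** — selection of phenotype-defined sub-cohorts
   from condition codes and survey answers, with a P/LP enrichment test;
6. **synthetic data** — a seeded generator producing every input with
   planted parameters, so all of the above is testable without any
   controlled-access data.

The real cohort data this kind of study uses are controlled-access; the
package consumes files in the same dialects and is exercised end to end on
synthetic cohorts.

## The core statistic

Group comparisons use the pooled two-proportion z-test. With group counts
\(Y_1, Y_2\), group totals \(n_1, n_2\) and group proportions
\(\hat p_i = Y_i / n_i\),

\[
Z = \frac{\hat p_1 - \hat p_2}
         {\sqrt{\hat p (1 - \hat p)\left(\tfrac{1}{n_1} + \tfrac{1}{n_2}\right)}},
\qquad
\hat p = \frac{Y_1 + Y_2}{n_1 + n_2},
\]

with a two-tailed normal p-value \(2(1-\Phi(|Z|))\). On any 2x2 table
\(Z^2\) equals the Pearson chi-square statistic without continuity
correction; the test suite asserts this to 1e-9. When \(\hat p \in \{0,1\}\)
the variance is zero; the implementation returns `z = 0`, `p = 1` and a
`degenerate` flag rather than dividing by zero.

```{r}
two_proportion_z(26, 71468, 34, 99336)[, c("p_hat1", "p_hat2", "z", "p_value")]
```

Cohort-wide heterogeneity across all genes and groups uses the Pearson
chi-square independence test on the gene-by-group count table
(`chisq.test(correct = FALSE)` underneath). Because many panel genes and the
smaller ancestry groups have low counts, `aggregate_for_chisq()` first
merges the under-represented groups (`eas`, `mid`, `sas`, `oth` by default)
into a single column and then merges genes — smallest row total first, ties
broken by gene name — into a single row until every expected cell count is
at least 5. The merge order is a design choice the source description leaves
open; smallest-first keeps the informative rows intact as long as possible
and is deterministic.

## Filtering and counting rules

* **GQ**: a call passes only when GQ is *strictly* greater than 20.
* **pLoF**: the most severe consequence must be one of `frameshift_variant`,
  `stop_gained`, `stop_lost`, `splice_acceptor_variant`,
  `splice_donor_variant`, `start_lost`; the LoF classifier call must be
  high-confidence; and the popmax allele frequency must be strictly below
  0.001. A missing popmax frequency passes the rarity filter — absence from
  the reference database is read as rarity — and this is logged. Only the
  six listed consequence terms are used; other high-impact terms
  (e.g. `transcript_ablation`) are not part of the rule.
* **Zygosity**: heterozygous calls qualify in dominant-acting genes; the
  recessive panel genes (`MUTYH`, `ATP7B`, `KCNQ1` in the bundled
  configuration) count homozygotes only; the hereditary-hemochromatosis
  gene `HFE` counts only the configured target variant
  (C282Y, rs1800562) in the homozygous state. Compound heterozygotes in
  recessive genes do not qualify: no phasing is attempted. Hemizygous
  (single-allele) genotypes are treated as homozygous alternate.
* **ClinVar**: GRCh38 records whose clinical significance is exactly one of
  the six P/LP strings; two-star records ("criteria provided, multiple
  submitters, no conflicts") only when last evaluated on or after
  2016-01-01 (missing dates fail and are counted in a message); three- and
  four-star records regardless of date. "Conflicting interpretations of
  pathogenicity" never passes — which is why a variant as well-established
  as HFE C282Y can be absent from a ClinVar-derived P/LP set. Combined
  significance strings ("Pathogenic/Likely pathogenic", with or without
  ", risk factor") map to classification `Path`; pure likely-pathogenic
  strings map to `LPath`.
* **Keys**: every join uses a canonical `chrom:pos:ref:alt` key. Records
  are joined exactly as published — no indel left-alignment or
  normalization — so representation mismatches surface as flagged-absent
  rows in `join_frequencies()` instead of being silently repaired.

Each (participant, gene, variant) yields at most one finding with
precedence `known_plp` > `plof_known_overlap` > `plof_novel`. A
consequence of this precedence is that in a dominant gene a knowledge-base
P/LP variant that is also pLoF is reported as `known_plp`; findings carry a
separate `plof` logical flag so overlap-style summaries (how much of the
known P/LP burden is loss-of-function) remain available.

`count_cohort()` counts **distinct participants** per gene and group — a
participant with findings in two genes contributes to both gene cells but
once to the group's overall positive rate — because headline rates are
participant-level ("x% of participants carry a finding"). An
allele-instance mode (`mode = "alleles"`, 1 per het, 2 per hom) is provided
for tables where every allele instance is counted, and the two modes are
labelled in the output.

## Padding

Panel regions are widened by 2000 bp upstream and 1000 bp downstream of the
gene's coding envelope. Whether "upstream" follows the transcription strand
is not something the rule's one-line description settles; the
implementation defaults to strand-aware padding (upstream = 5' side of the
gene) with `strand_aware = FALSE` available for coordinate-symmetric
padding. Padded starts are clipped at position 1.

## Confidence intervals

Per-group rate error bars use the Wilson score interval by default. The
method is a package design choice: at the small counts typical of rare
pathogenic variants the Wald interval collapses to zero width at zero
successes and can escape \([0,1]\), while Wilson does neither. A
normal-approximation alternative is selectable, and the method is recorded
in the output. The test suite checks the Wilson bounds against an
independent numerical inversion of the score test.

For the gene-level outlier scan, every gene and non-reference group is
compared against the reference group (`eur` by default) and the Bonferroni
family size `m` is the number of comparisons actually performed — a
choice that is configurable because the appropriate family depends on how
the scan is reported. Gene/group pairs with zero counts on both sides are
skipped and recorded. Reported p-values are unadjusted; significance is
flagged against `alpha / m`.

## External comparison

Per-gene reference rates add up the alternate allele counts of the gene's
P/LP variants and divide by the **maximum** total allele number observed in
the gene (variants are genotyped in different numbers of reference
samples; the maximum is the gene's effective denominator). Cohort-side
rates for this comparison are allele-frequency-style (allele instances over
`2 x participants`) so the two sides are commensurable; a participant-rate
mode exists but is labelled distinctly. The relative difference is defined
as `(cohort - reference) / reference` (an absolute-difference view is a
one-liner on the returned table); zero references with non-zero cohort
rates return `NA` rather than infinity. `subset_resolution_report()` lays
the cohort rate against each reference subset and flags the closest one,
breaking exact ties by subset name and noting the tie.

## The synthetic cohort generator

`sim_config()` defaults are the study conditions the package emulates: a
cohort of 98,590 participants with ancestry composition 50.4% `eur`,
23.2% `afr`, 16.1% `amr`, 2.1% `eas`, 1.0% `sas`, 0.2% `mid`, 7.0% `oth`;
per-gene, per-ancestry planted carrier rates (`default_gene_rates()`)
chosen so that known-P/LP totals are ~2.13% (eur) and ~1.52% (afr),
overall positive rates run from ~2.26% (eur) down to ~1.32% (amr),
afr-vs-eur divergences are planted in `APOB` (lower in afr), `PKP2` and
`PALB2` (higher in afr), the `HFE` homozygote rate follows a ~6.4%
European allele frequency, and novel-pLoF rates are highest in `sas`
(0.85%) and `eas` (0.62%); and 5% of genotype qualities fall at or below
the GQ 20 threshold. 22% of each gene's knowledge-base P/LP variants carry
high-confidence LoF consequences, so the known-P/LP and pLoF annotations
overlap about as much as frameshift-rich panels do in practice.

The generator plants qualifying carriers with zygosity respecting each
gene's inheritance mode (so every planted carrier genuinely qualifies) and
adds decoy call classes that must never qualify: VUS/benign/risk carriers,
low-confidence LoF calls, common LoF calls (popmax above threshold),
calls outside the padded panel, heterozygous calls in recessive genes,
heterozygous and non-target-homozygous calls in `HFE`. ClinVar records are
assigned across every star/date/significance stratum, including
conflicting-interpretation decoys and GRCh37 duplicate rows, and the
frequency table inflates designated gene/subset combinations (by default
`BRCA2` and `LDLR` in the subsets that contain disease-ascertained
samples) so subset resolution is exercised.

Genomic coordinates are toy: each gene sits on its own synthetic contig
with a 50 kb coding envelope, variants are single-nucleotide (plus the
published-representation indel path in the VCF reader tests), and there is
no linkage or haplotype structure, no sequencing-read level noise, and no
relatedness. Consequently, passing tests demonstrate the *logic* of
filtering, counting and testing — not robustness to real-world VCF
pathologies such as discordant indel representations, which the design
deliberately surfaces as flagged-absent joins instead of resolving.

Randomness: one root seed fully determines every output (files are
byte-identical across runs); each generator stage draws from its own
derived stream, so adding or reordering stages does not perturb the
others.

## Problem sizes and numerical choices in the test suite

The suite runs the brute-force counting oracle on cohorts of 100
participants by 50 variants across all inheritance modes; chi-square
type-I error is measured over 2000 null replicates of a 6-gene x 3-group
design with expected cell counts of 16–200 (rejection rate must land in
[0.04, 0.06]); planted-rate recovery is a coverage check across five
independent cohorts of 20,000 participants (at least 13 of 15
seed-by-group checks must fall inside their 95% binomial CIs — a single
fixed draw would fail ~14% of the time even with a perfect generator);
and the planted 3x divergence scenario uses 20,000/50,000 afr/eur
participants at a 0.1% base rate, where the scan's power is effectively 1.

Other numerical details: chi-square requires all expected counts >= 5 and
refuses tables that cannot satisfy the rule even fully aggregated; the
orchestrating `run_burden_pipeline()` records that refusal in its JSON
output instead of aborting the remaining stages; dates accept both ISO
and "Jan 22, 2022" forms; star ratings of unrecognized review-status
strings map to 0 with a warning rather than an error.

## Interface

The package is function-first: `simulate_cohort()` \%>\%
`write_simulation()` produce inputs; `read_cohort_vcf()`,
`classify_cohort()`, `count_cohort()`, `aggregate_for_chisq()` +
`chisq_independence()`, `gene_outlier_scan()`, `gene_level_rate()` +
`subset_resolution_report()`, `select_cohort()` + `enrichment_test()` are
the stages; `run_burden_pipeline()` orchestrates them from one
configuration (R list or YAML) and writes a manifest with input checksums
so any run is reproducible from its output directory. There is no separate
shell executable: an R session or `Rscript -e` call over these functions is
the intended entry point.

## Known limitations

* Ancestry labels are consumed as given; the package neither predicts
  ancestry nor models admixture or local ancestry.
* ClinVar filtering is the simple star/date/significance scheme described
  above; finer-grained curation (e.g. rescuing well-established variants
  listed as conflicting) is out of scope.
* The pLoF rule is annotation-driven; no transcript-level NMD reasoning.
* Whether significance-and-zygosity interactions beyond the `HFE` special
  case exist (e.g. "Pathogenic, risk factor" homozygous-only semantics in
  other genes) is treated as out of scope: significance and zygosity are
  filtered independently.
* The multiple-testing family for the outlier scan is the set of performed
  comparisons; externally imposed families must be passed via `m`.
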