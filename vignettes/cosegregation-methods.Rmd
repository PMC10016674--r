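---
title: "Methods: rare-variant co-segregation and gene burden analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant co-segregation and gene burden analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cosegscan)
library(dplyr)
```

## The problem

Familial cholesteatoma — a destructive keratinizing growth of the middle ear
that clusters in some families — is studied by exome-sequencing several
affected relatives per family and asking which rare, functionally damaging
variants are carried by *every* affected member (co-segregation), which genes
are hit in more than one family, and which genes carry more qualifying
variants in cases than expected from public control cohorts. `cosegscan`
implements that prioritization pipeline as composable, tibble-based steps:

1. **Dual-caller consensus** — keep only variants reported by both of two
   independent variant callers for a sample.
2. **Filtering cascade** — keep variants that are rare, conserved, of
   high/moderate predicted impact, and (for missense) not dismissed by both
   deleteriousness predictors.
3. **Within-family intersection** — keep variants shared by all affected
   members of a family; report genes qualifying in two or more families.
4. **Gene-based burden test** — collapse qualifying variants per gene and
   compare case carrier counts against expectations from public control
   allele frequencies with a two-sided exact test (dominant and recessive
   models).
5. **Term enrichment** — hypergeometric over-representation of candidate
   genes in gene-set collections, and comparison of enriched terms between
   analyses.

## Variant identity

Two callers rarely print an indel identically, so identity is split by class:

* **SNVs** are identical iff they share `(chrom, pos, ref, alt)` exactly
  (the `bcftools isec` convention).
* **Indels and complex variants** are mapped to 0-based half-open intervals:
  a deletion or complex variant spans `[pos - 1, pos - 1 + nchar(ref))` and an
  insertion is anchored at `[pos - 1, pos)`. Two such variants on the same
  chromosome are identical when the overlap exceeds 10% of **both** interval
  lengths, strictly (`> 0.10`; exactly 10% does not match).

Two choices here were genuinely open. A bedtools-style fractional overlap
(`-f`) is asymmetric; we require the fraction on both sides because symmetric
identity is what makes within-family intersection independent of member
order for SNVs and well-behaved for indels. And when a variant has several
admissible partners, the match is greedy by maximum overlap with ties broken
by the leftmost partner interval, purely so output is deterministic.

Multi-allelic VCF records are decomposed into biallelic variants before any
comparison, since identity is defined per ALT allele. No left-alignment,
normalization or phasing is attempted.

## Censored allele frequencies

Public databases report very rare frequencies only as a bound (`"<0.001"`).
The package stores such values as `(bound, censored)` pairs and never imputes
a point value:

* A censored value passes a rarity threshold `t` when its bound is at or
  below `t` (the true frequency is then certainly below `t`); when the bound
  exceeds `t` the comparison is indeterminate and raises an error rather than
  silently guessing.
* The censoring-aware **median** evaluates the order statistic under both
  extreme resolutions of the censored entries (all at zero; all just below
  their bound). The median and quantiles are monotone in each censored
  coordinate, so agreement at the extremes means the value is exact for every
  admissible resolution; when the median position is occupied by a censored
  entry, the median itself is reported censored at that bound; anything else
  is ambiguous and errors.
* The **IQR** uses linear-interpolation quartiles under the same two
  resolutions; when they disagree, the largest admissible IQR is reported and
  flagged as a bound.

On the packaged thirteen-variant candidate table this yields a gnomAD popmax
median of 0.002 (uncensored, the 7th of 13 ordered values) and a TOPMed
median that is itself censored below 0.001 — matching the published summary.

## The filtering cascade

Stage order and defaults:

| stage | rule | default |
|---|---|---|
| rare | gnomAD popmax **and** TOPMed frequency strictly below the threshold; a frequency exactly at it is removed | 0.01 |
| conserved | PhastCons 7-way strictly above the threshold | 0.1 |
| impactful | impact tier in {high, moderate}; consequence terms are mapped through a packaged, overridable table | — |
| not benign missense | missense excluded only when SIFT says *tolerated* **and** PolyPhen says *benign* | both-tools rule |

Each stage is a pure per-variant predicate, so the cascade is idempotent and
independent of row order, and the per-stage ledger telescopes
(`n_in = n_removed + n_out`, each stage's output feeding the next). Two
readings in the source material were reconciled as follows:

* The conservation rule is applied in the *retain conserved* direction: every
  published surviving candidate has PhastCons above 0.1, which settles the
  direction empirically.
* The missense exclusion is the **AND** of the two predictors. The published
  candidate table retains variants that are tolerated-by-SIFT-only and
  benign-by-PolyPhen-only; an OR reading would delete five printed
  survivors. Both rules are implemented (`benign_rule = "both"` / `"either"`)
  and the test suite demonstrates the discriminating behaviour.

Missing annotations are handled conservatively-permissively: absent
frequencies and absent conservation scores pass (logged) — indel conservation
annotation is patchy in practice — while absent impact information is an
error.

Quality hard-filter defaults (`qual >= 30`, `depth >= 10`) are configurable
stand-ins: reasonable values for short-read exome callers, applied per caller
before consensus.

## Co-segregation and multi-family genes

Members of a family are intersected sequentially (fold-left) in family-table
order. The running representative of an indel is always the first-listed
member's variant, which makes the result deterministic for any fixed member
order; for SNV-only input the result is provably order-invariant, and the
suite checks the indel behaviour against an all-pairs brute-force matcher.

Cross-family overlap is at **gene level**, not allele level: in the published
table the same gene is hit by different rsIDs in different families. A gene
qualifies with co-segregating variants in at least `min_families` (default 2)
distinct families.

## Gene-based burden testing

Qualifying (cascade-surviving) variants are collapsed per gene:

* **Case carriers** come from genotypes: dominant = samples with >= 1
  qualifying allele; recessive = samples with >= 2 qualifying alleles, where
  a homozygote counts two and two heterozygous sites in the same gene count
  two (an unphased putative compound heterozygote — phase is unknown, so this
  deliberately over-counts *cis* pairs).
* **Control carriers** are expected counts from aggregate control allele
  frequencies under site independence: dominant
  `round(N (1 - prod(1 - af_i)))`; recessive `round(N (sum af_i)^2)` capped
  at `N`, a Hardy–Weinberg approximation. Control sites must have adequate
  depth in at least 90% of control samples (inclusive threshold; the
  conventional reading of that QC phrase).
* The 2×2 carrier/non-carrier table is tested with a **two-sided exact
  test**: the sum of hypergeometric probabilities, over tables with the
  observed margins, not exceeding the observed table's probability (relative
  slack `1e-7`, the standard convention). The implementation is a vectorized
  hypergeometric sum; the suite verifies it against brute-force enumeration
  on every table with margins up to 30 and against `stats::fisher.test` on
  random tables.

Expected-count controls are the public-control mode of collapsing burden
frameworks: genotype-level control data are unavailable from aggregate
databases, and rounding to integer cells is required by the exact test. Raw
p-values are reported at the conventional 0.05 threshold along with a
Bonferroni column, since the source analysis states no correction for this
test. On null cohorts (case carrier probability equal to the control carrier
frequency) the fraction of genes at `p < 0.05` stays below 0.07 — the exact
test is conservative at these sample sizes.

## Enrichment

Over-representation uses the upper-tail hypergeometric p-value with the
universe defaulting to all genes annotated in the term database. The original
analysis used a proprietary, structure-aware multiple-testing correction
whose algorithm is not published; Benjamini–Hochberg (default) or Bonferroni
is applied instead, per source database, and outputs say so. The display
threshold for enriched terms is a raw `p < 0.01`, reproducing the published
figure convention; both thresholds are exposed because the source text is
ambiguous about which gated its headline term count.

Between-analysis comparison (`common_terms`) reports terms significant in
both gene lists, and `proportion_increase_test` implements the one-sided
two-sample test for equality of proportions with Yates continuity correction,

$$z = \frac{\hat p_b - \hat p_a - \tfrac12(1/n_a + 1/n_b)}
{\sqrt{\hat p (1-\hat p)(1/n_a+1/n_b)}},$$

with pooled $\hat p$ and the p-value from the upper normal tail; a degenerate
pooled proportion returns 1. The uncapped continuity correction follows the
stated formula; the suite cross-checks against `prop.test` away from the
cap's edge cases.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: ten families (nine pairs,
one trio; 21 exomes), six genes planted with co-segregating deleterious
variants in two or three families (a different allele per family), a few
single-family planted genes, and 350 background variants each violating
exactly one criterion — common frequency, low conservation, low impact,
benign/tolerated missense, caller-private (15% of background, the
discordance knob), member-private, or failing the quality hard filter — so
every stage removes known variants. Planted variants always carry frequencies
below 1%, conservation above 0.1, high/moderate impact, and labels that
survive the missense rule. Frequencies come from a rare beta distribution
(shape 0.4, 400, truncated below 0.009) with censoring below 0.001;
background common variants draw from a uniform 0.02–0.4. Control tables give
planted genes a tiny allele frequency (1e-4) so burden excess is detectable,
and ~10% of control sites fail depth QC.

```{r pipeline}
cohort <- generate_cohort(cohort_config(seed = 7))
result <- suppressMessages(run_family_pipeline(cohort$callsets, cohort$families))
tidy(result$cascade)
result$multi_family_genes |> select(gene, n_families)
```

The truth table (`cohort$truth`) records each variant's expected fate, and
the suite asserts exact recovery — sensitivity 1, zero false positives — of
the planted multi-family genes across 20 seeds.

What the generator does *not* emulate: read-level error, linkage
disequilibrium and realistic pedigree transmission, annotation disagreement
between databases, overlapping genes, and multi-allelic sites in the written
VCFs. Passing tests therefore demonstrate the pipeline's logic, not its
robustness to annotation noise in real exomes.

## Problem sizes and numerical choices

The synthetic defaults (80 genes, ~1,300 call rows per cohort, control
cohorts of 5,000, null calibration over 1,000 genes) keep every check
fast and fully deterministic while leaving each filter with dozens of
removals to count; they are choices of the package, adequate because every
stage's behaviour is scale-free. Seeds are explicit everywhere; generators
save and restore the caller's RNG state. Ties in indel matching break to the
leftmost partner; integer rounding of expected control carriers is
half-away-from-zero; censored comparisons never resolve silently.

## Known limitations

* Genotype concordance between callers is not required for consensus (allele
  identity only), and within-family sharing does not require equal genotypes
  — both unstated in the source protocol.
* The recessive model's compound-heterozygote counting is unphased.
* The consequence-to-impact table approximates the annotation tool's
  versioned "impactful" list and should be overridden when exact parity with
  a specific version matters.
* The censored IQR is reported as a bound whenever censoring makes it
  indeterminate; published IQRs computed with unknown quartile conventions
  are not asserted.
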