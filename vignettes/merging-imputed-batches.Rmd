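---
title: "Merging imputed genotype batches: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging imputed genotype batches: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imputemerge)
```

## The setting

Imputation servers cap the number of samples per submission, so large
cohorts are imputed in batches: each batch is a VCF of the same
chromosome over a different (mostly disjoint) sample set, accompanied by
a Minimac-style `*.info.gz` table carrying, per variant, the ALT allele
frequency, the MAF, an imputation quality score Rsq, and whether the
variant was directly genotyped on the array or imputed. `imputemerge`
recombines such batches into one cohort VCF, one chromosome per run.

Three things make this more than column binding: the quality scores must
be combined on the correct scale, variants are not guaranteed to be
present in every batch, and a sample may have been submitted in more than
one batch.

## Combining imputation quality

Rsq is the estimated squared correlation between the imputed dosage and
the (unobserved) true genotype. Correlation coefficients have a skewed,
variance-unstable sampling distribution, so they are averaged after
Fisher's z-transformation: with per-batch values $R^2_i$ and weights
$w_i$,

$$r_i = \sqrt{R^2_i}, \qquad z_i = \operatorname{artanh}(r_i), \qquad
\bar z = \frac{\sum_i w_i z_i}{\sum_i w_i}, \qquad
R^2_{\text{comb}} = \tanh(\bar z)^2 .$$

Design points, each visible in `combine_rsq()`:

* **Only the nonnegative root is available.** Info files report $R^2$,
  not the signed dosage–genotype correlation, so $r_i \ge 0$ always. This
  loses nothing in practice: a negatively correlated imputation would be
  a pathology upstream of this tool.
* **Clamping.** Genotyped variants can carry $R^2 = 1$, where
  $\operatorname{artanh}$ diverges. $r$ is clamped at $1 - 10^{-6}$
  before the transform; the combined value is then finite and lies
  between the (clamped) extremes of its inputs.
* **Weights.** The default weight is the batch sample count $n_i$,
  consistent with how the allele frequencies are pooled and well defined
  for tiny batches. The classical weighting for a z-transformed
  correlation is $n_i - 3$; it is available as
  `weight_mode = "n-3"` and changes results only marginally once batches
  exceed a few dozen samples. Individuals in batches lacking the variant
  are not counted: those batches are simply not passed to the combiner.
* **Absent scores.** A batch can contain a variant but report a
  placeholder quality (`-`). Such batches still contribute to allele
  frequencies and genotyped status but are dropped, with their weights,
  from the z-combination. If no batch supplies a score the combined
  quality is absent — and an absent quality cannot fail the quality
  threshold.

Frequencies are combined as sample-size-weighted means with minima and
maxima (`combine_af()`, used for both AF and MAF). When per-batch
frequencies were computed from dosages, the weighted mean is *exactly*
the pooled-cohort frequency; the test suite asserts this identity to
1e-9 across 50 seeded cohorts. Genotyped status across contributing
batches is summarised as `all` / `some` / `none`.

## Retention rules

For every variant in the union of the batch info tables, two rules are
applied in a fixed order (`build_merge_plan()`):

1. **Missingness** — excluded (reason `too-many-missing`) if the variant
   is absent from more than `missing` batches. The default allowance is
   0, i.e. a variant must be present in every batch; a conservative
   default that avoids silently diluting the output with `.|.` fills.
2. **Quality** — excluded (reason `below-threshold`) if the combined Rsq
   is present and below `rsq_threshold` (default 0).

Evaluating missingness first makes the recorded exclusion reason
deterministic for variants failing both rules. The threshold is applied
uniformly — a variant genotyped in every batch is not exempted; if its
combined quality is reported and low, it is filtered like any other.
Combined statistics are computed for excluded variants too, so the
excluded table is as informative as the retained one. Retained variants
are ordered by (position, REF, ALT); the REF/ALT tie-break is a
determinism choice for same-position records, not a biological claim.

## The streaming merge

All batch VCFs are opened simultaneously and scanned once, in step with
the retained list (`merge_batches()`): for each retained variant, each
batch that contains it is advanced to that record; batches that lack it
contribute `.|.` fills (GT slot `.|.`, every other FORMAT key `.`, so
`GT:DS` fills as `.|.:.`). Each input line is read at most once and the
per-batch scan position never rewinds, so time is linear and memory flat
in file size. Records encountered at the *same position* but not
currently wanted are buffered until the scan moves past that position,
which makes the merge independent of the tie order inside the inputs.

Row assembly conventions:

* CHROM–FILTER, FORMAT, and unrecognised INFO tokens come from the first
  batch containing the variant; only AF, MAF and the quality key (`R2` or
  `Rsq`) are replaced by combined values, and a
  `TYPED_STATUS=<all|some|none>` token is appended. Token order is
  preserved.
* FORMAT strings must agree across the batches containing a variant;
  a disagreement is a fatal error rather than a silent subfield
  reordering, which would corrupt dosages. Imputation-server output is
  uniform (`GT:DS` or `GT:DS:GP`), so this bites only on mixed-source
  inputs.
* Duplicated sample IDs keep their first occurrence (lowest batch index)
  unchanged; the j-th later occurrence becomes `ID:j`, with a further
  `.k` suffix in the degenerate case where that name already exists.
  All occurrences of shared IDs are listed in `duplicates.txt`.

Error handling is deliberately strict: a position that decreases within
an input, a variant listed in an info table but missing from its VCF at
the expected position (desynchronization), or a column-count
inconsistency in assembled rows each abort the run, and partial outputs
are deleted — a truncated bgzip VCF downstream is worse than no output.
One consequence of the lazy scan: the merge stops reading each input at
its last retained variant, so a length mismatch *after* that point (e.g.
trailing info rows beyond the final VCF record when those variants are
filtered out anyway) is not detected; mismatches at or before the last
retained position surface as desynchronization errors.

Parallelism is confined to compression: merge logic is a deterministic
single scan, and `threads` only selects parallel bgzip when the htslib
binary is available. Decompressed output bytes are identical for any
worker count (tested).

## Inputs, dialects, preprocessing

Inputs may be gzip- or bgzip-compressed (bgzip is a gzip superset, so
one reader serves both; output is bgzip so tabix indexing works).
Info-table column names drifted across Minimac3/Minimac4 and the
TOPMed/Michigan servers, so columns are matched case-insensitively
against synonym sets (`Rsq`/`R2`, `ALT_Frq`/`AF`, `Genotyped`/`TYPED`);
the matched dialect is recorded in the run log. For VCFs without a
companion info table, `build_info_from_vcf()` derives one from the INFO
column (`AF=`, optional `MAF=` — else `min(AF, 1-AF)` —, `R2=`/`Rsq=`,
and a `TYPED`/`GENOTYPED`/`IMPUTED` indicator), re-emitting numbers with
6 significant digits, the precision imputation servers print. Nothing is
recomputed from dosages.

Variant identity is the exact tuple (CHROM, POS, REF, ALT): multiallelic
sites already split into per-ALT rows stay separate records, an unsplit
multiallelic row is one record keyed on its full ALT string, and no
normalisation or left-alignment is performed — merging is byte-faithful
by design. A consequence: an unsplit `G,T` ALT in one batch does not
match split `G` and `T` records in another; they are treated as distinct
variants and surface through the missingness rule.

## The synthetic-cohort generator

`generate_cohort()` emulates imputation output just far enough to make
every contract testable with known ground truth: per variant, two
Bernoulli(AF) alleles per sample; dosage = allele count plus uniform
noise on [-0.1, 0.1] truncated to [0, 2]; AF annotations recomputed from
the realized dosages so files and genotypes are exactly consistent.
Default true frequencies are uniform on (0.05, 0.95) — common variants,
where imputation output is routinely analysed — and 20% of variants are
flagged genotyped. `split_into_batches()` partitions samples
contiguously, duplicates a chosen number of batch-1 samples into batch 2
(true cross-batch duplicates), drops designated variants from all but
one batch (`private`) or from exactly one batch (`absent_one`), and
writes the same VCF/info dialect the readers consume, together with a
full-precision manifest of the ground truth.

Per-batch Rsq values are *assigned* (uniform on [0.2, 0.999], seeded
from the cohort seed), not estimated from the noisy dosages: the tool
consumes Rsq as given, and assigned values give the combination tests
exact expected inputs. All randomness flows from the single cohort seed,
and the global RNG state is restored on exit.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: linkage disequilibrium, population
structure, rare variants, realistic imputation error (noise here is
independent uniform, real dosage error is genotype- and LD-dependent),
genotype discordance between duplicated samples, and multiallelic or
symbolic alleles. The format, statistics and bookkeeping contracts are
fully exercised; the statistical realism of the data is not the claim.

## Problem sizes and runtime choices

The test suite checks the Fisher combination against an independently
coded oracle on 1000 random configurations (1–8 batches, weights up to
10 000), the AF identity on 50 seeded cohorts split 2–4 ways, exact
round-trips on a 6-sample x 50-variant cohort split 2 and 3 ways, a
3 x 3 missingness/threshold grid against brute-force enumeration, and an
end-to-end merge of 3 batches x 500 samples x 5000 variants validated
with bcftools. These sizes keep the full suite under a couple of minutes
on one CPU while every code path, including the large-merge path, runs
on every test invocation.

## Known limitations

* One chromosome per run; no cross-chromosome orchestration.
* No re-imputation of filled `.|.` cells and no concordance checking
  between duplicated samples — duplicates are disambiguated, not
  reconciled.
* No empirical-Rsq (ER2) combination; only the model-based Rsq is
  handled.
* Inputs must be position-sorted; sorting is the caller's job and
  violations are fatal by design.
* QUAL/FILTER/ID and unrecognised INFO tokens are donated by the first
  containing batch — a documented convention, not a merge.
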