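---
title: "Constructing and validating a cancer miRNA gene census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating a cancer miRNA gene census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmcensus)
```

## The problem

Literature databases of miRNA–cancer associations are large, heterogeneous
and biased toward well-studied miRNAs; almost any annotated miRNA can be
"linked" to cancer by some publication. A useful reference list therefore
has to (a) restrict itself to convincingly validated miRNA genes, (b)
aggregate several *independent* kinds of evidence, and (c) set a
conservative inclusion threshold whose behavior can be audited. This
package implements such a census construction at the miRNA *gene* level,
together with the statistics used to validate it and a synthetic-data
generator that makes the whole pipeline testable without any external
downloads.

## Gene universe and background

The unit of analysis is the miRNA gene (HUGO locus). Working at gene level
avoids the ambiguity of mature names: one mature miRNA may be produced by
several precursors (miR-1 by *MIR1-1* and *MIR1-2*), and one precursor
yields up to two arm products (-5p/-3p). The attribution rules are:
an association for a shared mature name increments *every* carrying gene;
arm-suffixed and unsuffixed names both accumulate onto the gene; both arms
of one gene are counted cumulatively. Gene-level counts can therefore
exceed record counts, never the reverse.

Only *background* genes — miRBase high-confidence and/or MirGeneDB
annotated — are scored. Poorly validated miRNAs are excluded up front
because they cannot be detected in most assays and would distort both the
rank percentiles and any enrichment baseline. The strong overlap between
the two annotation sources (quantified by `overlap_enrichment()`, an
upper-tail hypergeometric test; the published counts give FE = 2.8) is
what justifies treating their union as "validated". The hypergeometric
tail is upper because the question is specifically whether the sources
agree *more* than chance; the package treats the full annotation universe
as the sampling frame.

## The score

Seven criteria contribute points; all tunables live in `score_config()`.

| Parameter | Default | Meaning |
|---|---|---|
| `top_fraction_full` | 0.10 | fraction of the ranked background list earning 1 point per database |
| `top_fraction_half` | 0.25 | fraction earning at least 0.5 points |
| `consistency_fraction` | 0.75 | within-database same-sign fraction for criterion IV (also reused by the O/TS rules) |
| `census_threshold` | 2 | minimum total score for census membership |
| `binary_point` | 1 | weight of criteria V–VII |

Numerical choices worth stating explicitly:

* **Cutoff ranks** use the ceiling, `ceil(fraction * N)`, with *N* the full
  background list (zero-count genes included in *N* but never awarded).
  Ranking uses optimistic tie placement: any gene with the same count as
  the gene at a cutoff rank is included at that level, so tie blocks are
  never split and the total points per database can exceed the tie-free
  minimum. Both properties are exercised against an independent
  threshold-scan oracle in the tests.
* **Criterion IV** requires at least one direction-determined association
  in *each* database (cross-database agreement is meaningless for a gene
  absent from a database), the `consistency_fraction` within each, and an
  identical majority sign across all three; directionless records (NPA)
  are excluded from the denominators. An exact 50/50 split can never meet
  a fraction above one half, so the internal majority tie-break is inert.
* **Half points** exist only in criteria I–III; scores therefore live on a
  0–7 grid in steps of 0.5.

The threshold of 2 means a census gene is either highly ranked in at least
two databases or moderately ranked with corroborating functional/genetic
evidence — a deliberate bias toward false negatives over false positives.

## Validation statistics

Fold enrichment is always observed / expected under proportional chance,
tested with a **two-sided** Fisher exact test (the construction this
mirrors used a two-sided default; one-sided variants would only strengthen
enrichment claims). `leave_one_out()` removes a criterion from the score,
re-selects the census at the unchanged threshold, and measures FE of the
criterion's originally scored genes in the reduced census — a criterion
consistent with the remaining evidence lands well above 1. `graded_fe()`
repeats this per remaining-score bin (default half-point-aware bins 0,
1–1.5, 2–2.5, …) to audit the threshold placement. Pairwise database
agreement uses Spearman's rho with average ranks and the t-approximation
p-value (an exact permutation option exists for n ≤ 8; full enumeration
beyond that buys nothing at the sample sizes involved). Group means are
compared with Welch's t-test, since equal variances can never be assumed
between census and non-census groups. Multiple testing uses
Benjamini–Hochberg q-values (`bh_fdr()`), and `term_overrepresentation()`
applies plain Fisher + BH per term — deliberately *not* the EASE-modified
score of DAVID-style tools, so q-values from such tools are comparable only
qualitatively.

## Oncogene / tumor-suppressor designation

`classify_onco_ts()` labels census genes only. An oncogene needs (i) at
least two databases internally consistent with positive sign, (ii) no
database consistently negative — an *inconsistent* third database does not
block the label, only a consistently opposite one does — and (iii) at
least 75 % of its significant tumor-versus-normal calls (nominal
P < 1e-4) reporting increased levels, with **at least one significant call
required**; the tumor-suppressor rule is the mirror image. The ≥ 1-call
requirement is a design decision: labeling on zero expression evidence is
indefensible, and the fraction is computed over significant calls only.
The rules are exactly sign-symmetric, which the tests exploit by flipping
every direction and checking that the two labels swap.

## Target pooling

For each mature miRNA of each background gene (its expressed arm or arms),
`select_top_targets()` keeps the two top-validated targets, scored by
methods × papers, ties broken by strong-evidence count, then
alphabetically — a cap that prevents heavily studied miRNAs from saturating
the pools. Matching between the registry's expected mature names and the
target table is exact after case normalization; targets reported under
names the registry cannot produce are skipped. A mature miRNA shared by
several genes contributes its targets to each gene's group, mirroring the
association-attribution convention. Pool-versus-pool reference overlap
(`reference_overlap()`) is a rate ratio: hit rate of pool A over the
pooled hit rate, Fisher-tested on the 2×2 hit/miss table.

## The synthetic generator

`sim_config()` defaults define the emulated study conditions, chosen once
to echo the construction's reported setting: 634 background genes in a
1917-gene universe, 26 % latent cancer genes (165/634), a 35/65
oncogenic/suppressive split among them (echoing the 19 vs 37 labeled
genes), cross-database rank correlation targeted at 0.85 (reported band
0.79–0.88), 90 % direction consistency, a 15 % NPA fraction in the curated
database, per-database mean loads proportional to the three sources' sizes,
and exactly 7 genes with genetic evidence. Counts are gamma-mixed Poisson
(heavy-tailed, so percentile cutoffs see realistic zero-inflation and
boundary ties); the correlation is induced by blending a shared gene-level
intensity with database-private noise, and the blend weight is calibrated
by bisection against the target rho using pre-drawn randomness — outputs
remain byte-identical functions of the seed, which is mandatory. The
significant-call probabilities (0.48 latent / 0.14 background over 16
types) reproduce the reported ~7.7 vs ~2.2 significant cancer types per
gene.

What the generator does *not* emulate: literature ascertainment bias
(well-known miRNAs are over-studied in real databases), cancer-type
structure beyond a label vector, miRNA family sequence relationships, and
any correlation between a gene's expression level and its evidence counts.
Passing recovery tests therefore show the pipeline's rules behave
correctly under the stated statistical structure — not that the original
database snapshots would be reproduced.

## Problem sizes and determinism

The test suite runs the full-scale recovery check (634-gene universe,
~120 000 association records per seed) over 20 seeds, and the smaller
module tests on 120-gene universes; the acceptance script uses 5 seeds
derived from its `--seed` argument. All simulation entry points restore
the caller's RNG state. Census construction itself is a pure function of
its inputs: rebuilding from identical profiles and flags is `identical()`.

## Known limitations

* The packaged published census table validates the point algebra and the
  O/TS tallies; the original rank cutoffs cannot be re-derived without the
  source database snapshots, so per-database point totals and cutoff
  minima are out of reach by design.
* Percentile scoring is sensitive to the tie structure near the cutoffs;
  with heavy-tailed counts a single tie block can carry many genes across
  a cutoff (the "ranked upwards" rule makes this explicit rather than
  arbitrary).
* Unknown mature names are warned about and skipped, not errors — database
  snapshots and annotation versions drift, and a hard failure would make
  real inputs unusable.
* The O/TS rules do not require a minimum number of significant
  tumor-versus-normal types beyond one; with very few significant calls
  the 75 % fraction is coarse.
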