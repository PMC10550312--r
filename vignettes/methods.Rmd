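---
title: "Methods: epiallele calling and pan-genome methylation–expression analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: epiallele calling and pan-genome methylation–expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epipangene)
```

## The model in brief

A gene's methylation state in a given genome is summarized by two numbers:
its CDS-restricted weighted methylation level in the CG context (mCG) and
in the CHG context (mCHG). Weighted means reads, not sites:
\[
m = \frac{\sum_i n^{meth}_i}{\sum_i n^{tot}_i}
\]
over all cytosines of that context with at least one read inside the
gene's merged CDS intervals. UTRs and introns are deliberately excluded:
introns often carry TE insertions with TE-like methylation of their own,
and UTR annotations are imprecise, so CDS is the one region whose
methylation can be compared across tens of thousands of genes without
confounding by annotation quality.

Genes with at least 40 covered CGs and 40 covered CHGs are assigned an
epiallele: UM (mCG ≤ 0.05 and mCHG ≤ 0.05), gbM (mCG ≥ 0.2, mCHG ≤ 0.05),
teM (mCG ≥ 0.4 and mCHG ≥ 0.4). Everything in between remains
`undetermined` — genic CG methylation is a continuum and the band between
0.05 and 0.2 is genuinely ambiguous — and genes failing the coverage rule
are `low_coverage`, never silently zero. The three decision regions are
disjoint by construction (an mCHG value cannot be both ≤ 0.05 and ≥ 0.4),
so labels are mutually exclusive and exhaustive.

Across genomes, homologous genes at a syntenic position share a *pangene*.
After restricting to core pangenes (present in every genome; cells that
carry only coordinates count as present but contribute no genes) and to
*intact* genes (CDS length within 10% of the pangene's singleton-defined
median — tandem duplications frequently capture gene fragments, and split
annotations masquerade as duplicates), pangenes are classified by the
configuration of intact singletons and duplicates and of their defined
epialleles. The expression contrast of interest is computed within
unstable UM-gbM 1-to-1 pangenes: per pangene and tissue, the mean TPM of
its gbM genomes minus the mean TPM of its UM genomes,
\[
d_i \;=\; \frac{\sum_j DT_{ij} I_{gbM}(DE_{ij})}{\sum_j I_{gbM}(DE_{ij})}
\;-\; \frac{\sum_j DT_{ij} I_{UM}(DE_{ij})}{\sum_j I_{UM}(DE_{ij})},
\]
tested with the exact two-sided binomial sign test on the signs of the
\(d_i\) (ties dropped; the tied-inclusive count is reported alongside) and
with the Wilcoxon signed-rank test (zeros dropped; exact distribution up
to 25 non-zero differences, normal approximation with tie correction
above). Because a handful of highly expressed pangenes dominate any mean,
the effect size is reported as the *median* \(d_i\) normalized by the mean
UM TPM of the same pangene set and tissue, in percent.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `min_sites_CG`, `min_sites_CHG` | 40, 40 | covered cytosines required per context (coverage rule) |
| `um_max` | 0.05 | UM ceiling for mCG and mCHG; gbM ceiling for mCHG |
| `gbm_min_mCG` | 0.2 | gbM floor on mCG |
| `tem_min` | 0.4 | teM floor on both mCG and mCHG |
| `boundary_inclusive` | TRUE | ≤/≥ versus strict comparisons at the thresholds |
| intact filter `max_dev` | 0.10 | allowed relative CDS-length deviation from the singleton median (strictly less than) |
| metagene `upstream_bp` / `internal_bp` / `bin` | 3000 / 1500 / 100 bp | flank and internal window widths; the internal window is configurable to 2000 bp, a width some displays use |
| correlation `min_range` / `min_genes` | 0.2 / 3 | minimum methylation spread and usable genes per pangene |
| `min_copies` strata | 2, 4 | intact copy number defining the duplicate strata |

The threshold wording question — whether a gene sitting exactly on 0.05 or
0.2 is inside or outside a class — cannot be settled from available
descriptions, which use both phrasings. The package defaults to inclusive
comparisons and exposes `boundary_inclusive = FALSE`; at realistic depth
the probability mass exactly on a boundary is negligible, and the
switch exists precisely so a user can check that nothing depends on it.
The same holds for the CDS-TE overlap flag, which defaults to strictly
greater than 100 bp (`cds_te_strict = FALSE` gives ≥ 100).

Two readings of "average methylation by region" exist: read-weighted
(reads pooled across sites) and site-averaged (each covered site counted
equally). The package defaults to read-weighted — it is robust to uneven
depth and matches the semantics of thresholding pooled counts — and
provides `method = "site_mean"` as a sensitivity check.

For the mCHG-based correlation variant, the stated filter keeps "at least
40 CGs per gene" to preserve a comparable gene set; since mCHG itself is
undefined without covered CHG sites, the package retains the full 40/40
coverage rule for both variants.

## The synthetic pan-genome generator

`simulate_pangenome()` emulates the statistical structure of a
NAM-founder-style dataset; it is the package's test bed, not a biological
model. Its defaults are the study conditions:

- **Scale**: 26 genomes × 2000 pangenes, 10 tissues, mean read depth 20.
- **Epiallele frequencies**: UM 0.55, gbM 0.31, teM 0.12 (normalized to
  sum 1), within the per-genome ranges reported for maize.
- **Methylation**: per-site beta-binomial around type means — UM
  mCG/mCHG ≈ 0.01, gbM mCG ≈ 0.8 with mCHG ≈ 0.02, teM mCG/mCHG ≈ 0.85,
  genic mCHH ≈ 0.02 — with concentration 15. Sites are placed inside real
  CDS intervals of generated gene models (so the coverage rule, interval
  merging and weighted means are genuinely exercised), most genes get ≥ 45
  CG and CHG sites, and a 3% fraction receives 15–35 sites to exercise the
  low-coverage path. Flanks (3 kb each side) receive sites too: teM genes
  stay methylated across the TSS, UM/gbM genes get an mCHH bump in the 500
  bp upstream of the TSS, so metagene profiles have the familiar shape.
- **Pan-genome structure**: 24% of pangenes carry tandem duplicates
  (copy numbers 2 + negative binomial, capped at 47), 3.5% of
  singleton-only pangenes carry a second epiallele type, 10% are non-core,
  5% have a coordinates-only cell. 12% of duplicate genes are partial
  (30–70% of the median CDS length) so the intact filter has real work.
  Duplicates inherit the singleton type and switch with configured rates
  (UM→gbM 0.007, UM→teM 0.015, gbM→UM 0.069, gbM→teM 0.036; the teM rates,
  not reported anywhere at usable precision, default to teM→UM 0.05 and
  teM→gbM 0.02 on the reasoning that teM states decay toward demethylation
  more often than toward clean gbM).
- **Expression**: TPM\(_{ijt}\) = \(B_i \, T_t \, M(type_{ij}, t)\,
  \varepsilon_{ijt}\) with a log-normal per-pangene baseline \(B_i\)
  (meanlog log 15, sdlog 0.35), fixed per-tissue effects (sdlog 0.25,
  mean-normalized), mean-one log-normal noise (sdlog 0.2), and type
  multipliers: gbM \(1+\delta\) with \(\delta = 0.03\) by default
  (attenuated to 0.005 in endosperm, whose epigenetically distinct
  behavior the generator mimics as a simple damping), teM 0.02 (silenced),
  UM 1.

A deliberate numerical choice hides in the baseline spread. The effect
estimator normalizes a median-type numerator (median of \(d_i \approx
\delta B_i\)) by a mean-type denominator (mean UM TPM \(\approx E[B]\)),
so its large-sample value is approximately \(100\,\delta\,e^{-\sigma_B^2}\)
for a log-normal baseline with log-scale spread \(\sigma_B\). For the
generator to satisfy its own contract — the recovered normalized median
difference should approach \(100\delta\) — \(\sigma_B\) must be moderate;
at \(\sigma_B = 0.35\) the asymptotic attenuation is ≈ 12%, keeping the
recovered value in the 2–4% window around the injected 3%. Real TPM
baselines span far more orders of magnitude; with realistic spread this
estimator is *more* attenuated, which is worth remembering when reading
the analogous quantity from real data.

What the generator does **not** emulate: sequence content (no FASTA, no
reads, site positions are uniform rather than CpG-island-structured), LD
or phylogenetic structure among genomes (epialleles are drawn i.i.d. given
the pangene scaffold), annotation error beyond partial duplicates,
mapping/conversion artifacts in methylome calls, and any causal coupling
between methylation and expression beyond the constant multiplier. A
passing test suite therefore demonstrates that the *pipeline arithmetic*
is right and recoverable at study scale, not that real maize methylomes
behave this way.

## Validation experiments and problem sizes

The package validates itself at three scales, chosen to keep a full run in
a few minutes on one CPU:

- **Oracle equivalence** — region methylation, merged interval
  intersection, indicator means and pangene classification are checked
  exactly against independent brute-force implementations (per-bp
  counting, double loops, a literal restatement of the classification
  rules) on ≥ 1000 randomized fixtures each, plus the exhaustive \(3^6\)
  singleton enumeration for the classifier.
- **Classifier accuracy** — the default 2000 × 26 site-level simulation;
  epiallele calls are compared to truth for every covered gene (about
  50,000), requiring ≥ 99% agreement. With type means separated by ≥ 0.15
  from every threshold and ≈ 1200 reads informing each gene-level level,
  misclassification is confined to rare boundary fluctuations.
- **Effect recovery and calibration** — `delta_recovery_replicates()` runs
  50 replicates of a 1000-pangene × 26-genome pan-genome consisting
  entirely of unstable UM-gbM pangenes (gene-level methylation mode for
  speed; calling, intact filtering and classification still run), checking
  that the median recovered effect lies in 2–4% and the sign test rejects
  at α = 0.05 in ≥ 95% of replicates. Null calibration uses δ = 0: 200
  replicates at 300 × 12 (the test's size does not depend on scale) for
  the rejection rate, and a 1000 × 26 run for the null mCG–expression
  correlation, whose median must sit within two standard errors of zero.
- **Switch-rate recovery** — a 4000-pangene gene-level simulation;
  pooled duplicate epiallele fractions must cover the configured rates
  within binomial 95% confidence intervals.

## Degenerate inputs and tie-breaks

- A methylation level with zero covered sites is `NA`, never 0; such genes
  are `low_coverage` regardless of the other context.
- Overlapping CDS or TE intervals are merged before any length or level is
  accumulated, so nothing is counted twice; empty interval lists give
  length 0 and empty segment sets.
- Metagene bins with no contributing gene are `NA` with `n_genes = 0`;
  genes shorter than the internal window simply contribute no sites to the
  bins beyond their length. Sites of genes shorter than twice the internal
  window can contribute to both the TSS-anchored and polyA-anchored
  windows, as in standard metagene tools.
- A pangene with no singleton cell has no median CDS length and is
  excluded from classification entirely (its class is `NA`, and the
  exclusion does not revoke core status).
- Sign-test ties (\(d_i = 0\)) are dropped from the binomial count; the
  tied-inclusive p-value is reported alongside since the convention is not
  universal.
- Pearson coefficients are `NA` when either variable has zero standard
  deviation or fewer than 3 genomes are usable; `NA` coefficients are
  excluded from summaries but the per-pangene matrix keeps them visible.
- The positive:negative correlation ratio is `Inf` when no negative
  coefficients exist (rather than `NA`), keeping "all positive" and "none
  defined" distinguishable.

## Known limitations

- The pipeline consumes a pangene table; it performs no homology detection
  or synteny construction, and no subgenome assignment.
- No per-site differential methylation testing, no CHH-island statistic
  beyond the metagene report, no multiple-testing correction across
  tissues (per-tissue analyses are reported as-is, matching standard
  practice for this design).
- The expression model supports replicate columns only by summing counts
  before normalization; transcript-level quantification is out of scope.
- GFF3 reading keeps one canonical transcript per gene (by attribute, or
  the first transcript encountered); genes whose canonical transcript is
  mis-annotated will carry that error through every downstream feature.
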