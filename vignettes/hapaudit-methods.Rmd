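---
title: "Auditing mtDNA haplotype datasets: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing mtDNA haplotype datasets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapaudit)
```

## The problem

Public sequence repositories are only as useful as the quality of what was
deposited. A recurring failure mode for mtDNA control-region surveys is
that the deposited haplotype set drifts away from the chromatogram evidence
behind it: identical sequences deposited under several haplotype ids,
haplotypes listed that no trace supports, and true haplotypes missing
because reads were mis-edited. `hapaudit` implements the full audit of such
a dataset as a reusable pipeline: dual-editor re-calling with a
quality filter, exact-identity haplotype collapse, repository
deduplication, support classification against the re-edited data and an
auxiliary dataset, standard diversity statistics, AMOVA, and a two-layer
haplotype network comparing the corrected and uncorrected pictures.

The package ships, as reference data, the haplotype distribution of the
Baltic grey seal (*Halichoerus grypus*) control-region dataset across its
three breeding sites (Bay of Bothnia, Estonia, Stockholm Archipelago) —
38 haplotypes, 103 individuals, with the mapping to the 40 originally
deposited repository haplotypes. Every worked example and acceptance check
runs against this table.

## Editing model

Two editors independently call bases from the same chromatogram. The
consensus copies agreeing calls and assigns the minimal IUPAC code
covering both calls at disagreements (N whenever either call is N, or a
base faces a gap). A read whose inconsistent fraction is **one third or
more** is classed poor-quality and rejected; the boundary itself is
rejected, because "one third or more could not be scored consistently"
describes the omitted reads. Retained reads are trimmed to the maximal
window that excludes every read's terminal N-runs (intersection of clean
spans); how the original study arrived at its 489 → 435 bp reduction is
not documented, so the intersection rule is this package's own,
deterministic choice. The filter is applied before trimming. Reads that
still carry internal IUPAC codes after trimming are excluded from
haplotype collapse with a warning rather than wildcard-matched: a wildcard
match could merge distinct haplotypes, contradicting the zero-mismatch
assembly rule.

## Estimators

For haplotype counts \(c_i\), \(n = \sum c_i\), \(p_i = c_i/n\):

* **Haplotype diversity** (Nei 1987, unbiased):
  \(h = \frac{n}{n-1}(1 - \sum p_i^2)\), with sampling variance
  \(V(h) = \frac{2}{n(n-1)}\{2(n-2)[\sum p_i^3 - (\sum p_i^2)^2] +
  \sum p_i^2 - (\sum p_i^2)^2\}\) and a normal 95% CI truncated to
  \([0,1]\). This estimator and CI reproduce the reference table's printed
  values exactly (e.g. Bay of Bothnia: 0.968, CI 0.942–0.993), which is
  why it was adopted; no external program is called.
* **Nucleotide diversity**:
  \(\pi = \frac{n}{n-1}\sum_{i\ne j} p_i p_j d_{ij}/L\), identical to the
  plain mean of per-site differences over all individual pairs. Its
  variance is Tajima's (1983) *total* variance
  \(\frac{n+1}{3(n-1)}\frac{\pi}{L} + \frac{2(n^2+n+3)}{9n(n-1)}\pi^2\),
  which contains the evolutionary (stochastic) term. Published
  single-locus reports print π intervals far wider than the sampling SD
  alone would give, which only the total variance reproduces; the CI
  therefore uses it, and the pure sampling component is additionally
  returned in `V_components`.
* **Distances**: \(d_{ij}\) counts differing positions, pairwise-deleting
  any position where either sequence is unresolved (N, ambiguity, gap).
  Unresolved characters are likewise excluded from base composition, and
  a column is segregating only if it shows two resolved bases.
* **Unique-haplotype test**: Pearson chi-square without continuity
  correction on the 2 × (sites) table of unique vs shared haplotypes per
  site (a shared haplotype counts at every site where it occurs),
  df = sites − 1. On the reference table this gives χ² = 1.42, df = 2.
* **Diversity comparison**: \(t = |s_1-s_2|/\sqrt{se_1^2+se_2^2}\) with a
  two-tailed p on caller-supplied df. The standard errors are explicit
  arguments because reports rarely print them; the function does not
  guess.

## AMOVA

One-level analysis of molecular variance (Excoffier, Smouse & Quattro
1992) with the pairwise difference count serving as squared distance —
the conventional choice for haplotypic data. Sums of squared deviations
are decomposed into among- and within-population parts; variance
components use the unequal-sample-size coefficient
\(n' = (N - \sum n_p^2/N)/(P-1)\); \(\Phi_{ST} = \sigma_a^2 /
(\sigma_a^2 + \sigma_b^2)\). A negative \(\sigma_a^2\) is kept internally
but the reported Φ\_ST is clamped at zero — this is why unstructured
datasets report `0.000` alongside arbitrary P-values. The permutation
test shuffles individuals among populations with sample sizes fixed and
uses the add-one estimator \(p = (1 + \#\{\Phi^{perm} \ge
\Phi^{obs}\})/(n_{perm}+1)\), so p is never zero. The default is 10,000
permutations with a mandatory seed; the pipeline default is lower (999)
to keep routine runs fast, and tests use fewer still, with the type-I
calibration run at 199 permutations × 500 null datasets.

## Haplotype networks

The network is the **minimum spanning network**: the union of all minimum
spanning trees, built by Kruskal with tie inclusion (an edge enters if its
endpoints are in different components of the strictly-lighter subgraph).
This is deliberately simpler than statistical-parsimony construction:
deterministic, exactly characterised, and sufficient for the
shared/one-layer comparison the audit needs. Edge weight is the
mutational step count; `weight − 1` unsampled intermediates are carried
as edge annotations ("black dots") rather than explicit nodes. Two-layer
annotation marks each node shared, present in one layer only ("white
dot" in the other), or absent from both. Tie-breaking and edge order are
fixed (weight, then lexicographic labels), so exports are reproducible.

## The synthetic world

The deposited accessions and raw traces are not redistributable, so all
sequence-level fixtures are generated. The generator's defaults *are* the
stated dimensions of the reference dataset and are not tuned: 435 bp
fragments, 37 segregating sites, 103 individuals distributed exactly per
the packaged table, a 40-entry repository whose duplicate groups and
old-ID mapping follow the packaged annotations, 114 chromatograms of
489 bp (27 bp flanks) of which 11 are forced poor, and an auxiliary set
of every haplotype with a positive auxiliary count.

Mechanics: haplotypes are placed on a random attachment tree; each edge
receives at least one mutation at a fresh alignment position and the
surplus `S − (H−1)` mutations go to random edges, so all haplotypes are
distinct, the realised segregating-site count equals `S` exactly, and
every pair is connected by a single-step mutational path (networks are
connected). This requires `S ≥ H − 1`; smaller `S` is an error rather
than a silent reduction. Auxiliary-only and unsupported-variant sequences
mutate at positions outside the focal `S`, keeping the cohort's
segregating count intact. All generators draw from a private RNG stream
seeded explicitly and restore global RNG state.

What the synthetic world does **not** emulate: the real base composition
(26.8% C / 28.6% T / 26.2% A / 18.4% G — composition here is a measured
output of a uniform-background generator, not a target), the real
genealogy, real editor-error structure (disagreement positions are
i.i.d.; retained reads default to disagreement-free so that the cohort
collapses exactly to the table), and the real distribution behind the
uncorrected dataset (the packaged "erroneous" table is a synthetic
stand-in with the same shape, labelled as such). A green test therefore
establishes that the *procedures* are correct on a world with the stated
dimensions — not that the package has re-derived sequence-dependent
results (π values, Φ\_ST, network topology) of the original data; those
are covered by property-based checks against brute-force oracles instead.

## Numerical and design choices

* Rounding: diversities print to 3 decimals, percentages to 1, χ² to 2,
  matching the reference report's precision. The report's two top
  haplotype frequencies (12/103 = 11.65%, 11/103 = 10.68%) appear there
  as 11.6%/10.6%, i.e. truncated; the package returns exact proportions
  and only the acceptance check reproduces the truncation.
* Haplotype labels are rank names (`HT1`, …) by descending total count,
  ties by first appearance — the reference table's layout; repository
  representatives are labelled by the smallest member id.
* Deduplication reports both the number of duplicate *groups* (6 in the
  reference world) and the number of redundant *entries* (9); published
  prose ("nine pairs") conflates them, so the report exposes both.
* The sharedness summary is computed over distinct haplotypes with
  positive cohort counts only; auxiliary-only rows ride along as
  annotations.
* Distribution rows that index beyond the supplied haplotype list are
  warned-and-skipped, not fatal: that is exactly the situation an auditor
  faces when fewer haplotypes were deposited than reported.
* Cross-length comparison (e.g. 489 bp deposits vs 435 bp re-edited
  fragments) requires an explicit window `(offset, length)`; the package
  never guesses an alignment. In the synthetic world both sides are
  435 bp, so the default pipeline compares full-length.

## Limitations

No trace-file parsing or per-base quality scores (inputs are call
strings); no alignment (inputs are pre-aligned, equal length); no fuzzy
(≤ k mismatch) repository matching; no multi-level AMOVA or
haplotype-frequency-only F\_ST; no statistical-parsimony or
median-joining networks; no neutrality tests or multiple-testing
correction. The erroneous-dataset chi-square statistics of the original
report cannot be reconstructed from printed information (its per-site
unique counts are internally inconsistent) and are deliberately not
reproduction targets.
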