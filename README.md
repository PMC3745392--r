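# hapaudit

Quality control, reconciliation and population-genetic analysis of mtDNA
haplotype datasets.

`hapaudit` is for researchers who need to audit a published
control-region haplotype dataset against the evidence behind it — the
situation that arises when repository deposits (duplicated ids,
unsupported haplotypes, missing haplotypes) drift away from the
chromatograms they were called from. It implements the complete audit as
composable R functions plus a pipeline:

* **Editing QC** — dual-editor consensus with minimal-IUPAC resolution,
  rejection of reads with ≥ 1/3 inconsistent positions, trimming to the
  shared clean window.
* **Haplotyping** — zero-mismatch collapse, haplotype × site count
  tables, sharedness summaries.
* **Reconciliation** — repository deduplication, classification of each
  deposited haplotype as supported / aux-supported / unsupported, novel
  haplotype discovery, corrected reference assembly, and reconstruction
  of the "erroneous" dataset implied by uncorrected deposits.
* **Statistics** — Nei's unbiased haplotype diversity
  `h = n/(n−1)·(1 − Σp_i²)` with variance-based 95% CI, nucleotide
  diversity `π = n/(n−1)·Σ p_i p_j d_ij / L` with Tajima total variance,
  segregating sites, base composition, Pearson χ² on site-unique
  haplotype proportions, and a t-based comparison of diversity estimates.
* **AMOVA** — one-level variance decomposition on pairwise differences,
  Φ_ST = σ²_a/(σ²_a+σ²_b), seeded permutation P-values, pooled-site runs.
* **Networks** — minimum spanning networks (union of all MSTs,
  tie-inclusive Kruskal) with two-layer shared/one-layer annotation and
  GraphML/DOT export.
* **Synthetic data** — seeded generators for cohorts matching a count
  table, dual-editor call pairs, and repositories with duplicate groups
  and corrupted entries, so the whole pipeline is testable without the
  original accessions.

The package ships the Baltic grey seal (*Halichoerus grypus*)
control-region haplotype distribution (38 haplotypes × 3 breeding sites,
103 individuals, with repository old-ID annotations) as worked reference
data.

## Worked example

```r
library(hapaudit)

tab <- reference_distribution()
colSums(tab)
#>  BB EST STA
#>  39  36  28

haplotype_diversity(unclass(tab)[, "BB"])[c("h", "ci")]
#> $h
#> [1] 0.9676113
#> $ci
#> [1] 0.9424163 0.9928064

sharedness(tab)
#> 35 haplotypes; in-k-sites counts: 1:19 2:8 3:8
#> proportion unique per site: BB 33.3%, EST 23.8%, STA 42.9%
#> top frequencies: 11.7%, 10.7%, 8.7%

chi_square_unique(tab)
#> Pearson chi-square = 1.42, df = 2, P = 0.492

# synthetic study world realising the packaged annotations
world <- simulate_study(seed = 1)
reconcile(world$repository, collapse_haplotypes(world$records),
          world$aux_haplotypes)
#> Repository reconciliation
#>   entries: 40, distinct: 31 (6 duplicate groups, 9 redundant entries)
#>   supported: 16, aux-supported: 3, unsupported: 12 (support rate 61.3%)
#>   novel re-edited haplotypes: 19; corrected reference set: 38
```

Reading: of 40 deposited repository entries only 31 are distinct
sequences; 16 of those are confirmed by the re-edited chromatogram
cohort and 3 more by the auxiliary dataset (61.3% support), 12 are
unsupported, and 19 haplotypes found in the chromatograms were never
deposited — giving a corrected reference of 38 haplotypes. Per-site
haplotype diversities are high and statistically indistinguishable
(χ² = 1.42 on the unique-haplotype proportions).

Full pipeline (writes `table2.tsv`, `table3.tsv`, `table4.tsv`,
`reconciliation.tsv`, `network.graphml`, `manifest.json`):

```r
run_pipeline(run_config("out", seed = 1, n_perm = 999))
```

or from the shell: `inst/cli/hapaudit run --out out --seed 1`.

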