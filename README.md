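# dualTCR

Most single-cell TCR workflows keep one α- and one β-chain per cell
and silently discard everything else. But a sizable minority of mature
T cells genuinely transcribe two rearranged alleles of one chain locus
— most often two α-chains (allelic inclusion escapes exclusion more
readily at TRA than at TRB). Discarding those secondary alleles hides
a biologically distinct cell population and systematically
underestimates repertoire diversity.

`dualTCR` is an R toolkit for analysing dual TCR expression in
paired-chain single-cell V(D)J data. It is aimed at immunologists and
computational biologists working with 10x Genomics
`filtered_contig_annotations.csv` tables or AIRR Rearrangement TSVs,
plus per-cell annotations (patient, tissue compartment, CD4/CD8
subset, phenotype cluster). It provides:

- **Allele-class calling.** Each cell's accepted chains (productive
  contigs by default, with UMI thresholds and a top-two cap per locus)
  place it in one of: Single TCR (1α1β), Dual TCRα (2α1β), Dual TCRβ
  (1α2β), excluded 2α2β (indistinguishable from capture doublets), or
  incomplete (missing a locus).
- **Dual-aware clonotyping.** Clone identity is the canonical,
  order-independent multiset of `locus|V|J|CDR3nt` over *all* retained
  chains, so a dual clone never collapses onto the single clone that
  shares its primary pair. Per-tissue/subset/cluster clone sizes feed
  the expansion statistics.
- **Heteroscedastic expansion statistics, from first principles.**
  Clone-size groups are compared with Welch's ANOVA
  (variance-weighted F with fractional denominator df) and the
  Games-Howell post hoc test, whose p-values come from this package's
  own numerical integration of the studentized range distribution:
  for pair (i, j) among k groups,

      SE = sqrt(s_i^2/n_i + s_j^2/n_j),   t = |x̄_i − x̄_j| / SE,
      p = P( Q(k, ν_WS) ≥ t·√2 ),

  with Welch–Satterthwaite ν. A fold-change screen flags phenotype
  clusters where dual clones are both significantly and >2-fold more
  expanded than single clones, and V-gene usage tables expose
  pseudogene signals such as TRBV21-1 enrichment among secondary
  β rearrangements.
- **Diversity underestimation.** `dual_drop_comparison()` re-keys the
  same cells after dropping secondary alleles (the conventional
  workflow) and reports richness, Shannon, Gini-Simpson and clonality
  for both keyings; dropping can only merge clones, never split them.
- **A ground-truth simulator.** `simulate_repertoire()` emits
  realistic contig tables (both dialects) with configurable dual-α
  (~9.3%), dual-β (~3.2%) and doublet (~1.7%) rates, per-tissue dual
  expansion multipliers, V-usage skew, UMI laws and per-barcode truth
  labels — every stage of the pipeline is testable offline.

## Worked example

A small simulated dataset ships with the package (106 cells in 10x
CSV format plus a metadata TSV):

```r
library(dualTCR)
contigs <- system.file("extdata", "example_contigs.csv", package = "dualTCR")
meta    <- system.file("extdata", "example_metadata.tsv", package = "dualTCR")

tcr      <- attach_metadata(read_10x_contigs(contigs), meta)
profiles <- build_cell_profiles(tcr)
summarize_classes(profiles)
#> # A tibble: 5 × 3
#>   class                   n fraction
#>   <fct>               <int>    <dbl>
#> 1 SINGLE                 90   0.833
#> 2 DUAL_ALPHA             13   0.120
#> 3 DUAL_BETA               3   0.0278
#> 4 MULTI_BOTH_EXCLUDED     2   0.0185
#> 5 INCOMPLETE              0  NA
```

83% of cells with TCRs express one in-frame α and one β; 12% carry a
second α-chain, 2.8% a second β-chain, and 1.9% show two of each and
are excluded as possible doublets. Fractions are over cells with at
least one chain of each locus.

```r
clones <- tabulate_clones(profiles)
clone_counts_by_stratum(clones)
#>             P  N  T
#> SINGLE     19 18 26
#> DUAL_ALPHA  1  1  3
#> DUAL_BETA   0  1  2
```

Unique clones with at least one cell in peripheral blood (P), normal
adjacent (N) and tumor (T) tissue; a clone spanning compartments
counts once in each.

```r
dual_drop_comparison(profiles)
#> <dual_drop_comparison>
#>    keying richness  shannon   simpson  clonality
#> 1    full       71 4.166210 0.9829121 0.02263128
#> 2 dropped       68 4.118833 0.9820221 0.02385928
#> richness retained after dropping secondary alleles: 95.8%
```

Reducing every cell to its top-expressed chain per locus merges three
clonotypes away: the conventional workflow would report 4% fewer
clones and a lower Shannon diversity on these same cells.

On full-size data, `welch_anova()` / `games_howell()` compare mean
clone sizes across allele classes per compartment, and
`cluster_screen()` flags phenotype clusters with significant >2-fold
dual expansion. `run_analysis(run_config(...))` executes the whole
chain and writes a TSV report bundle; the `exec/dualtcr` script
exposes `simulate`, `run` and `stats` verbs for shell use.

## Vignette

`vignettes/dual-tcr-methods.Rmd` documents the model and its
assumptions: the classification rules and their configurable filters,
the clonotype definition, the exact form of the test statistics, what
the simulator does and does not emulate, and the package's numerical
and design choices.
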