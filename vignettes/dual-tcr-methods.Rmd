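---
title: "Methods: dual TCR detection, clonal expansion statistics, and diversity underestimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual TCR detection, clonal expansion statistics, and diversity underestimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualTCR)
```

## The problem

Mature αβ T cells are supposed to express one TCR, but allelic
exclusion is leaky: both TRA alleles rearrange simultaneously during
the double-positive stage, and even TRB exclusion occasionally fails.
A cell can therefore transcribe two distinct rearranged alleles of
one chain locus. Paired-chain single-cell V(D)J sequencing observes
this directly — each droplet barcode collects all TCR contigs of one
cell — yet standard workflows reduce every cell to its best α and
best β before clonotyping. This package quantifies dual TCR
expression, asks whether dual-expressing clones are differentially
expanded across tissue compartments and phenotypes, and measures the
repertoire diversity lost by the standard reduction.

## Cell classification

For each barcode we accept chains by a configurable filter
(`filter_config()`), then count distinct accepted chains per locus
and classify:

| accepted α | accepted β | class |
|---|---|---|
| 1 | 1 | `SINGLE` |
| 2 | 1 | `DUAL_ALPHA` |
| 1 | 2 | `DUAL_BETA` |
| ≥2 | ≥2 | `MULTI_BOTH_EXCLUDED` |
| 0 | any (or any | 0) | `INCOMPLETE` |

Cells with two alleles at *both* loci are excluded from all analyses
because they cannot be distinguished from two co-captured cells: a
droplet doublet of two unrelated single-TCR cells produces exactly
this profile. Incomplete cells (no accepted chain at one locus)
never enter any denominator; "cells with TCRs" means cells with at
least one accepted chain of each locus. With this denominator the
four retained classes partition it exactly, which is asserted as a
test invariant.

Filter parameters, defaults, and why:

* `frame_policy = "productive_only"`: only in-frame (productive)
  contigs count as expressed alleles. `include_nonproductive` is
  offered because out-of-frame TRAV transcripts are known to persist
  in expanded clones, and the TRBV21-1 pseudogene — likely a failed
  first β rearrangement — remains transcribed; both are invisible
  under the default.
* `min_umis = 1` (UMI count, absolute): any deduplicated molecule
  count supports a chain. Upstream pipelines have already applied
  cell and contig quality filters, so the package does not
  second-guess them by default; the knob exists to probe how fragile
  a dual call is.
* `min_umi_fraction_of_top = 0` (fraction of the locus' top chain):
  a relative evidence threshold for secondary alleles, for
  sensitivity analyses against ambient-RNA contamination.
* `max_chains_policy = "cap_at_two_by_umis"`: cells with three or
  more accepted chains at one locus keep the top two by UMIs (ties
  broken lexicographically on the CDR3 nucleotide sequence, so
  results never depend on row order). Capping rather than excluding
  keeps the class partition exhaustive; `exclude_cell` is available
  for the conservative reading.

Duplicate contigs — identical (barcode, locus, V, J, CDR3nt) — are
collapsed with summed UMIs before filtering: they are repeated
assemblies of the same transcript, not independent alleles.

## Clonotype definition

Clone identity is the lexicographically sorted concatenation of
`locus|V|J|CDR3nt` over *all* retained chains of a cell (`"nt"`
mode; amino-acid and V+CDR3-only modes are provided as options).
Consequences, both deliberate:

* identical chain multisets give identical keys regardless of contig
  order or UMI values, and
* a dual cell never shares a clone with a single cell, even when its
  primary α+β pair matches — the chain counts differ.

Clone sizes are counted within stratum (a clone's blood cells do not
inflate its tumor clone size), and clones are pooled across patients
for size statistics, mirroring how multi-patient cohorts are usually
presented; per-patient stratification is available through the
`strata` argument. CD4/CD8 identity comes from the supplied metadata
(it is a transcriptome-level call), never recomputed here.

## Expansion statistics

Clone-size distributions are strongly skewed and heteroscedastic
across allele classes, so group means are compared with Welch's
heteroscedastic one-way ANOVA: with weights $w_i = n_i/s_i^2$,
$W = \sum w_i$, weighted grand mean $\hat\mu$, and
$\lambda = \sum_i (1 - w_i/W)^2/(n_i - 1)$,

$$F = \frac{\sum_i w_i(\bar x_i - \hat\mu)^2 / (k-1)}
           {1 + \frac{2(k-2)}{k^2-1}\lambda},
\qquad \nu_1 = k - 1,\quad \nu_2 = \frac{k^2-1}{3\lambda}.$$

Pairwise comparisons use the Games-Howell procedure: each pair gets a
Welch-type standard error and Welch–Satterthwaite degrees of freedom,
and $t\sqrt2$ is referred to the studentized range distribution
$Q(k,\nu)$ for the *full* number of groups, which is what controls
the familywise error over the $k(k-1)/2$ pairs. Significance is
reported as stars at 0.05 / 0.01 / 0.001.

The studentized range upper tail is computed here by numerical
integration of the classical double integral: the probability that
the range of $k$ standard normals is below $qs$, integrated over the
density of the scale estimate $s = \sqrt{\chi^2_\nu/\nu}$. Both
integrals use R's adaptive quadrature at relative tolerance 1e-8;
agreement with `stats::ptukey` is within 2e-4 absolute everywhere we
test (and at $k = 2$, where an exact $t$ reduction exists, this
implementation is accurate to ~1e-8 while `ptukey` deviates by
~3e-5). Fractional degrees of freedom — which Games-Howell produces
for every pair — are handled natively.

Deliberate statistical choices:

* Means, not medians or log-transforms, are compared, because mean
  clone size is the quantity of interest in clonal-expansion
  analyses of this kind; the skewness is handled by the
  heteroscedasticity-robust machinery, whose null behaviour we
  verify by simulation (2,000 null datasets of k = 3 lognormal
  clone-size groups, n = 200 clones each — sizes chosen to match the
  hundreds of clones per stratum a 20,000-cell repertoire yields;
  the empirical size at α = 0.05 must land in [0.04, 0.06]).
* No additional multiple-testing correction is applied across the
  per-cluster screens beyond the familywise control inside each
  Games-Howell comparison.
* The cluster screen (`cluster_screen()`) flags a cluster only when
  the dual-vs-single comparison is significant *and* the mean-size
  fold exceeds a threshold (default 2): significance alone flags
  trivial differences in well-powered strata, fold alone flags
  noise in tiny ones. Clusters with fewer than two clones in either
  group, or with exactly tied sizes (zero variance), are reported as
  untestable rather than silently dropped; variance-based tests are
  undefined there and the package refuses to fake a p-value.

## Diversity and the cost of dropping secondary alleles

For per-clone cell counts $c_i$ with $p_i = c_i/\sum c$:
richness $= k$, Shannon $H = -\sum p_i \ln p_i$ (natural log),
Gini-Simpson $= 1 - \sum p_i^2$, and clonality
$= 1 - H/\ln k$ (defined as 0 when $k \le 1$). Conventions are
stated because they vary across the literature.

`dual_drop_comparison()` contrasts dual-aware clonotyping with the
conventional reduction on the same cells. The reduced keying keeps
one chain per locus per clone: the chain with the highest UMI count
summed over the clone's cells, ties broken lexicographically. The
UMI vote is aggregated at clone level deliberately. A per-cell vote
— "each cell keeps its own top chain" — looks equivalent but is not:
UMI counts fluctuate between cells of the same clone, and whenever
the rank of the two alleles flips, a per-cell vote *splits* one true
clone into two reduced clonotypes. Aggregating the vote makes the
reduced key a deterministic function of the full key, so the
reduction is a many-to-one merge and reduced richness can never
exceed full richness — a theorem the test suite checks on 100
simulated repertoires against an independently coded oracle, with
strict inequality exactly when some secondary chain is the only
thing separating two clones.

## What the simulator emulates — and what it does not

`simulate_repertoire()` generates clones per (class, tissue, subset)
stratum, expands them into cells, and emits one contig row per chain
with Poisson-distributed UMI counts (secondary chains drawn lower
than primary, reflecting the reduced expression of the secondary
allele). Defaults are the study conditions the package targets:

* class rates per barcode: dual-α 0.093, dual-β 0.032, doublets
  0.017 (the observed partition of a large pan-cancer T-cell atlas);
* geometric clone sizes (`1 + Geom(p)`, `p = 0.65`, so baseline mean
  ≈ 1.5 cells/clone, matching the atlas' cells-to-clones ratio), with
  mean multipliers for dual clones of 1 in blood and 2 in normal and
  tumor tissue, and a CD8 multiplier of 1.5 for all classes;
* rank-skewed V-gene usage with the TRBV21-1 pseudogene rare among
  conventional rearrangements but 10-fold enriched when drawing the
  secondary β-chain of dual-β clones;
* doublets built by merging pairs of fresh single-TCR cells captured
  in the same sample, yielding the 2α2β profiles the classifier must
  exclude;
* "shadow" clonotypes (rate 0.25 per dual clone): the primary α+β
  pair of a dual clone also observed as its own single-TCR clonotype.
  This emulates secondary-allele capture dropout, which in real data
  makes one lineage appear both ways, and is precisely what makes
  dual-aware keying richer than reduced keying.

Stratum cell budgets are covered by whole clones: the clone that
crosses the budget boundary is kept intact rather than truncated.
Truncation would size-bias the realized clone-size law — the
boundary preferentially falls inside large clones — and measurably
drag mean clone sizes below their configured expectation in small
strata; with whole clones the realized dual:single mean-size ratio
is an unbiased estimate of the configured multiplier (verified at
n = 50,000 within 10%). The cost is a realized cell count slightly
above `n_cells` — at most one clone per stratum. At the repertoire
sizes the analyses target (thousands of cells) this is negligible;
for toy repertoires of a few hundred cells the whole-clone overshoot
visibly inflates the expanded (dual) classes, so configured rates
should only be read as recovered targets at realistic sizes.

Not emulated, hence out of reach of these tests: transcriptome
clusters are labels, not expression profiles; CDR3 sequences are
random in-frame codon strings (length 27–45 nt), so sequence-level
convergence and biological V(D)J biases are absent; clones do not
span tissues or phenotype clusters; there is no ambient RNA, and
secondary-allele dropout is modelled at clone level (the shadow
mechanism) rather than per cell. Passing tests therefore demonstrate
correctness of the pipeline's logic and statistics under controlled
conditions, not robustness to every artifact of real droplet data.

## Validation design

The test suite validates each layer against an independent route:
readers against hand-written dialect fixtures; the classifier
against simulator truth (exact recovery of configured class rates at
n = 20,000, within three binomial standard errors); Welch ANOVA
against `stats::oneway.test` and an externally computed fixture;
Games-Howell against a `ptukey`-based re-implementation and the
k = 2 Welch-t reduction; the studentized range against `ptukey`,
its analytic k = 2 reduction, and a 10⁶-draw Monte-Carlo oracle
(absolute tolerance 0.005); the diversity theorem against a base-R
re-implementation of the drop rule.

The planted-expansion recovery check (tissue multiplier 3, blood 1)
runs on five simulated repertoires with pre-stated seeds: the tissue
signal must reach significance in all five, while the null blood
comparison is allowed at most one rejection — the false-positive
budget a 5%-level test nominally carries. A single-seed version of
this check would encode the luck of that seed's draw rather than the
procedure's behaviour.

## Known limitations

* The 2α2β exclusion removes true double-dual cells along with
  doublets; their frequency is unidentifiable from barcode data
  alone, and no probabilistic doublet deconvolution is attempted.
* Chain counting is at gene-level V/J resolution (allele suffixes
  stripped); two rearrangements differing only by allele are treated
  as one.
* Clonality normalizes by the log of *observed* richness, so
  repertoires of very different sampling depth should be compared
  with care; no rarefaction or richness extrapolation is provided.
* The reduced-keying comparison measures underestimation relative to
  the observed dual-aware repertoire, which is itself a lower bound:
  secondary alleles that were never captured cannot be restored.
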