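---
title: "Multi-dimensional disruption analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-dimensional disruption analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdisrupt)
```

# The problem

Cancer genomes deregulate gene expression through several DNA-level
mechanisms at once: dosage change (gain or loss of copies), allelic
conversion (loss of heterozygosity or allelic imbalance, possibly at
neutral copy number), and aberrant promoter methylation. Any single
mechanism, examined alone, undercounts how often a gene is disrupted
across a cohort; conversely, an expression change with no concordant
DNA event may be a downstream (trans) effect rather than a lesion.
`mcdisrupt` integrates the four dimensions at the level of an
individual gene in an individual sample, asks which expression changes
the DNA can *explain*, and raises the bar further to genes showing
*multiple concerted disruption* (MCD) — congruent change in all three
DNA dimensions with a consistent expression change in the same sample.

The design assumes a cancer-versus-single-reference comparison: each
cancer sample is contrasted with one non-malignant reference profile
measured on the same platforms. All operations are deterministic given
the inputs and a seed.

# Per-dimension status calling

| Dimension | Call | Rule (cancer vs reference) |
|---|---|---|
| Expression | OVER / UNDER | log2 difference strictly `> 1` / `< -1` (two-fold) |
| Expression | FILTERED | both detection calls Absent |
| Methylation | HYPER / HYPO | Δβ `>= 0.25` / `<= -0.25` (inclusive) |
| Methylation | FILTERED | either confidence p `> 0.05` |
| Copy number | GAIN / NEUTRAL / LOSS | majority base overlap of the sample's segments with the gene body |
| Allelic | ALTERED / RETENTION | strict majority of informative (L/R) markers in gene ± 100 kb |

Conventions worth noting:

* The expression threshold is strict (a difference of exactly 1.0 is
  not differential); the methylation thresholds are inclusive. Both
  conventions follow the printed definitions of the respective rules.
* All coordinates are 1-based closed intervals, declared in every file
  header.
* `ALTERED` is a single internal allelic state. Only at reporting time
  is it labeled AI (with overexpression) or LOH (with
  underexpression); the biology is the same call.
* The segment-to-gene rule aggregates overlap *per state* and takes
  the maximum — equivalent to a per-base majority vote over the gene
  body. This matters only when a gene straddles more than two
  segments; ties are broken lexicographically by state name so results
  never depend on row order. Genes covered by no segment are MISSING.
* Probe-level copy gaps can be filled with `infer_missing_copy()`:
  a missing probe takes the status of the nearest informative neighbor
  within 1 Mb, stays missing when both flanking neighbors are inside
  the window but disagree, and is never used to overwrite an observed
  status.
* When several probes of one platform map to one gene,
  `collapse_probe_statuses()` keeps a directional status only if it is
  unopposed; any OVER/UNDER (or HYPER/HYPO) conflict collapses to
  NONE. How multi-probe genes should be reconciled is genuinely open;
  we chose the conservative rule because it never manufactures a call
  from discordant probes, at the cost of discarding genes with
  isoform-specific behavior. An all-neutral probe set resolves to the
  majority of NONE versus FILTERED, ties to NONE.
* Gene-level allelic calling from markers is likewise unspecified
  territory; the strict-majority-in-window rule (window 100 kb,
  configurable) is symmetric in L and R and returns NOCALL on ties or
  empty windows rather than guessing.

# Explanation and cohort accounting

An OVER call is explained by copy GAIN, by copy-neutral ALTERED, or by
HYPO methylation; an UNDER call by LOSS, copy-neutral ALTERED, or
HYPER. The copy-neutral restriction on the allelic mechanism prevents
double counting: an allelic shift that merely reflects a dosage change
is attributed to the dosage change.

`cumulative_disruption_frequency()` counts, per gene, the samples
explained by at least one mechanism, partitioned into ordered
increments — copy number first, then methylation among the remainder,
then copy-neutral allelic change among the remainder. The order
matches the narrative convention of reporting dosage first and adding
dimensions; the cumulative count is an increment-order-invariant set
union, and each sample contributes to exactly one increment.
Percentages are *floored* whole numbers (8 of 9 prints as 88%), so
they match conventional rendering of x/9 fractions. Samples whose
expression call is FILTERED for a gene are excluded from both the
numerator and the denominator of that gene's percentage.

Cohort counting is direction-agnostic: a gene may be overexpressed in
some samples and underexpressed in others, and both count toward its
disruption frequency (each sample once). Per-sample records retain the
direction, and the funnel flags direction-heterogeneous MCD genes.

# The permutation null and thresholds

Observed cohort frequencies need a reference distribution: even
independent dimensions produce chance concordance. The null is built
by shuffling, within each sample, each dimension's status vector
across genes, independently per dimension (`shuffle_within_sample()`).
This preserves every per-sample per-dimension marginal count exactly —
a sample with many gains keeps them all — while destroying the
gene-wise alignment between dimensions, which is precisely what the
analysis measures. Whether the dimensions should be permuted jointly
or independently is an open choice; independent permutation is the one
that leaves nothing intact except the marginals, and expression is
permuted too so that the null also randomizes which genes are
differentially expressed. Statuses (not underlying values) are
shuffled: calls are deterministic functions of values, so the two are
equivalent.

Ten replicates are generated by default (`null_reps`), each from seed
`seed + r - 1`; gene-level frequency outcomes are pooled across
replicates into one distribution (with equal-size replicates, pooling
and averaging per-replicate distributions coincide).
`select_frequency_threshold()` returns the smallest frequency whose
upper-tail proportion is ≤ α (default 0.05), and returns `NA` with no
qualifying frequency rather than silently picking the maximum. The
MCD recurrence rule is the same selection restricted to nonzero
frequencies: `select_mcd_recurrence()` answers "how many MCD events
make a gene non-random", and zero events can never be evidence.

# The MCD funnel

`run_funnel()` applies four nested filters: DE frequency ≥ k₁,
explained frequency ≥ k₂, MCD count ≥ k₃, MCD count ≥ k₄ (with
k₄ ≥ k₃). In `run_pipeline()`, k₁ and k₂ default to the
null-selected disruption threshold (the two stages use one threshold
unless overridden — they are exposed separately because nothing forces
them equal), k₃ to the null-selected MCD recurrence, and k₄ to
`ceiling(4 n / 9)`, scaling the 4-of-9 high-recurrence convention to
other cohort sizes.

The MCD call itself requires `GAIN + ALTERED + HYPO` with OVER, or
`LOSS + ALTERED + HYPER` with UNDER. Note the asymmetry with the
explanation rules: in MCD the allelic alteration *accompanies* the
dosage change rather than requiring a neutral background, because the
defining scenario is dosage change → allelic imbalance → plus a
methylation shift. Consequently an MCD call implies the copy-number
and methylation explanation mechanisms but not the (copy-neutral)
allelic one.

# Downstream statistics

* `fisher_right_tail()` / `enrich_gene_sets()`: hypergeometric
  upper-tail enrichment of a gene list against GMT gene sets, with
  Benjamini–Hochberg correction across sets (`bh_adjust()`, delegating
  to `stats::p.adjust`). The universe is the harmonized gene universe
  of the analysis — the genes actually assessed — not the whole
  genome; using the genome would overstate every enrichment.
* `logrank_tertiles()`: samples are sorted by one gene's expression,
  the bottom and top `floor(n/3)` form the groups (middle discarded),
  and survival is compared by the standard two-group log-rank test
  (`survival::survdiff`; p from χ² with 1 df, two-tailed). Expression
  ties are broken by sample identifier so group membership is
  deterministic; the statistic is invariant to monotone transforms of
  expression. Excluding non-disease deaths is the caller's
  responsibility when preparing the survival table.
* `binomial_upper_tail()`: exact `P(X ≥ k)` for screening designs
  (e.g. comparing an observed fraction of survival-associated genes
  with a background rate).

# The synthetic cohort generator

`generate_cohort()` exists so that every pipeline stage is testable
with known ground truth. It emulates the *structure* of the real
inputs — a single reference column, log2 expression with detection
calls, beta-distributed methylation with confidence p-values,
SEG-like piecewise-constant copy profiles, and marker-level L/R/N
calls — and plants four gene classes: `MCD_DRIVER` (concerted copy +
allelic + methylation + expression lesion in carrier samples),
`SINGLE_MECHANISM` (exactly one DNA lesion, cycling over the three
mechanisms, with matching expression), `REACTIVE` (expression shift
without any DNA lesion; the trans-regulated case), and `NULL` (noise).

Default conditions, chosen once as a realistic small cell-line cohort:
9 cancer samples and one reference; 2000 genes; class mix 2% / 8% /
5% / 85%; penetrance 0.8 (lesion carried by 7 of 9 samples); expression
effect 2.0 log2 units against noise SD 0.3; methylation effect 0.4 β
against beta-distributed sampling at concentration 30 (per-observation
SD ≈ 0.09); genes spaced 250 kb apart on 500-gene chromosomes; copy
lesions realized as single segments of roughly 200 kb centered on the
gene (so the segment→gene overlap logic is actually exercised, unlike
whole-chromosome events); 30 markers/Mb with 90% informative
background retention and 95% LOH within lesioned windows. Class sizes
use largest-remainder rounding, so planted counts are deterministic;
everything else is reproducible from the seed. Lesioned methylation
baselines are drawn away from the boundary (e.g. 0.15–0.55 for genes
destined for hypermethylation) so the configured shift is realizable
within [0, 1].

What the generator does *not* emulate: probe-level intensity noise and
normalization artifacts, genotyping error, segmentation errors and
breakpoint uncertainty, correlated lesions spanning many genes
(each lesion is local to one gene region), tumor heterogeneity or
purity effects, and realistic linkage structure among markers.
Passing tests on synthetic cohorts therefore demonstrate the
correctness and calibration of the *integration logic* under the
stated noise model — not performance on raw platform data, which must
be normalized, segmented, and quality-filtered upstream.

# Numerical conventions and degenerate inputs

* Fractions with empty denominators (a sample with no DE genes of the
  requested direction; precision of an empty selection) return `NaN`
  rather than 0, and callers must propagate them.
* `select_frequency_threshold` on a distribution where nothing reaches
  α returns `NA_integer_`; the pipeline stops with instructions rather
  than guessing.
* Percentages are floored integers; counts are exact.
* Shuffling saves and restores the caller's RNG state, so pipeline
  results do not depend on what the session did before.
* Validation is fail-fast and names the file/identifier of the first
  violation (unknown sample columns, β outside [0, 1], unsorted probe
  positions, inconsistent funnel thresholds, impossible 2×2 margins).

# Test scale

The shipped suite exercises the full pipeline on cohorts of 40–5000
genes. Property checks use 10–50 replicate tables; the driver-recovery
check pools 20 cohorts of 800 genes at the default effect sizes and
asserts stage-4 precision and recall ≥ 0.9 against the planted truth;
a marginal-fidelity check on a 5000-gene cohort compares realized
per-sample status frequencies with the configured lesion rates within
three binomial standard errors. These sizes were chosen to make the
stochastic assertions sharp while keeping the default test run fast on
one core.

# Known limitations

* Cohort counts from any particular study are not reproducible without
  that study's full copy-number and SNP inputs; the package validates
  mechanism and calibration on synthetic data and on printed worked
  examples instead.
* The explanation model is cis-only by design: trans regulation,
  microRNA effects, and structural events that relocate regulatory
  elements all land in the "unexplained" remainder.
* Gene-level aggregation rules (probe collapse, marker majority) are
  declared package decisions where the field has no single convention;
  both are parameterized or replaceable via the plain-TSV stage
  interfaces.
* The permutation null conditions on the observed per-sample marginal
  status counts; it does not model uncertainty in the upstream calls
  themselves.
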