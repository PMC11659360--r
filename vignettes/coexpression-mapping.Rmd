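---
title: "Mapping brain-wide co-expression of two genes across paired single-cell and spatial datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping brain-wide co-expression of two genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexatlas)
```

## The estimation problem

Two G-protein coupled receptors, the ghrelin receptor (gene *Ghsr*) and the
cannabinoid receptor type 1 (*Cnr1*), act on overlapping brain circuits, and
the question of where single cells express *both* is a question about joint
expression that neither bulk data nor single-marker maps can answer. Two
modern data types answer complementary halves of it:

* a **deep scRNA-seq dataset** measures both genes in every cell, but has no
  anatomy;
* a **spatially resolved dataset** (MERFISH) places cells into anatomical
  structures, but its targeted gene panel need not contain both genes.

When both datasets are annotated with the *same hierarchical cluster
taxonomy*, co-expression measured per cluster in the deep set can be
transferred onto anatomy through the spatial set's cluster composition. This
package implements that transfer as a tested pipeline, together with a
synthetic paired-data generator whose ground truth lets every stage be
validated end to end.

## The procedure

**1. Positivity calling.** A cell is *positive* for a gene either when its
log2(CPM) exceeds a threshold `t` (default 3) — used for deep,
whole-transcriptome data — or when its raw count reaches a minimum (default
1 count, no normalization) — used for targeted panels. Both inequalities
follow the conventions of the atlas analyses they emulate: the CPM
comparison is **strict** (`log2(CPM) > t`, i.e. `CPM > 2^t`), and a zero
count is negative by construction, so no pseudocount is needed and the log
of zero is never evaluated. CPM denominators come from a `library_size`
metadata column when present; for matrices restricted to the genes of
interest (which cannot imply transcriptome totals) the column sums are the
fallback. A cell is double-positive iff it is positive for both genes.

**2. Cluster fractions.** For every cluster, the exact fractions of A-, B-
and double-positive cells (`p_a`, `p_b`, `p_ab`). These are the only
statistics carried across datasets; `p_ab <= min(p_a, p_b)` holds by
construction and is enforced in tests.

**3. Apportionment.** Cross-tabulating the spatial cells gives the count
`n(c, s)` of cluster-`c` cells in structure `s`. The estimated positive
count is

\[ \hat N_X(s) \;=\; \sum_c \big\lfloor\, n(c,s)\; \hat p_X(c) \,\big\rfloor , \]

flooring **each per-cluster contribution** before summing. The alternative
reading — summing first, flooring once — is available via
`apportion(round = "after_sum")`; the default follows the order in which
the source procedure states its operations (apportioned per cluster,
rounded, then summarized). Flooring makes estimates conservative: the
downward bias of \(\hat N\) is strictly less than the number of clusters
contributing cells to the structure, a bound the tests verify and the
recovery tolerances reuse. A small epsilon (1e-9) is added before flooring
so exact-ratio products such as `10 * 0.3` do not truncate to 2 through
floating-point double rounding. Clusters present in the spatial set but
absent from the deep set contribute zero and are reported, never silently
dropped.

**4. Partial-volume correction.** Structures whose volume is only partly
covered by the sampled sections have their counts divided by the covered
fraction `f` in (0, 1] — a ratio estimator; `f = 1` is the identity.

**5. Whole-brain calibration.** The corrected counts live on the scale of
the sectioned sample. They are mapped to whole-brain numbers with a single
proportionality factor `k` fitted by least squares **through the origin**
against literature counts of marker-defined reference populations:

\[ \hat k \;=\; \frac{\sum_i \mathrm{lit}_i\,\mathrm{est}_i}{\sum_i \mathrm{est}_i^2}. \]

A single factor with no intercept is the model implied by proportional
sampling; the closed form is checked in tests against an independent 1-D
minimizer. All references are fitted jointly (the alternative, per-structure
subsets, is under-determined with few references per structure). Because the
regressor is itself a sampled count, \(\hat k\) carries a small
errors-in-variables attenuation of order
\(\sum_i \lambda_i / \sum_i \lambda_i^2\) (Poisson means \(\lambda_i\));
with reference counts in the hundreds this is a percent-level effect, and
the recovery tolerances account for it explicitly.

**6. Summaries.** The final table mirrors the shape of published
quantitative mapping tables: per structure, whole-brain A/B/double counts,
the double share of each single-positive count (one decimal), the
neurotransmitter composition of the apportioned double-positives (integer
percentages via the cluster annotations), the double-positive density, and
a selection flag — **strictly** more than 350 double-positive cells *and*
strictly more than 50 cells/mm³. Region roll-ups report the double sum over
selected ("listed") and over all structures. All printed percentages round
half away from zero (base R's round-half-even would disagree on exact
halves).

### Rounding and the published worked examples

Feeding the published per-structure counts through this arithmetic
reproduces 24 of 33 printed percentage pairs exactly; the remainder differ
by 0.1–0.2 (e.g. 629/678 = 92.77% prints as 92.7), indicating the source
table truncated or worked from slightly different underlying counts — its
own bracketed region sums also differ from their row sums by 1–2 cells in
four regions, and two listed structures sit below the stated 350-cell
cut-off. The package applies the stated rules exactly and treats those
deviations as properties of the source table: the acceptance checks require
exact agreement on the narratively quoted values and 0.25 / 2-cell agreement
elsewhere.

## The synthetic generator

The generator emulates exactly the features the pipeline consumes, nothing
more.

* **Taxonomy**: `n_clusters` (default 50) clusters, 85% neuronal;
  neuronal clusters draw one of six neurotransmitter labels (Glut 50%,
  GABA 32%, the rest small), non-neuronal clusters are `none`.
* **Per-cluster rates**: gene A is rare — 90% of clusters draw
  `p_a ~ Beta(0.2, 200)` (mean 0.1%), 10% draw `Beta(1.5, 50)` (mean ~3%) —
  while gene B draws `Beta(1.2, 1.8)` (mean 40%), reproducing the ~100-fold
  prevalence imbalance of *Cnr1* over *Ghsr*. Co-expression is parameterized
  by an **odds multiplier** on the cell-level 2×2 table (default 4;
  1 = independence, 0 = exclusion), solved in closed form for the joint
  probability, so enrichment and independence are both expressible.
* **Counts**: per-cell positivity indicators are drawn from the cluster's
  joint law; positive cells then receive at least the minimal count that
  clears the positivity rule for their log-normal library size
  (meanlog log 2e4, sdlog 0.5), negative cells receive zero. Counts are
  therefore simulated directly at the positivity-relevant scale — the
  realized per-cell indicators are recovered *exactly* by the rule, which
  the tests assert — rather than via a transcriptome-wide model the
  pipeline would never look at.
* **Spatial sample**: 20 structures with CCF-scale volumes grouped into
  seven regions. Sectioning is emulated at the fraction level: a 10 µm
  section every 200 µm captures 5% of each structure's cells, so the true
  whole-brain proportionality factor is exactly 20; per-structure
  covered-volume fractions (four structures at 0.5–0.8 by default) stand in
  for missing sections. Observed cell numbers are Poisson around
  volume × density × 0.05 × coverage, with cluster labels drawn from sparse
  Dirichlet mixtures (concentration 0.3). The default whole-brain density,
  20 000 cells/mm³, is a desk-scale stand-in chosen to keep the spatial
  sample around 40 000 cells.
* **References**: seven marker populations (Agrp, Pomc, Npy, Gfap in ARH;
  Oxt, Avp, Crh in PVH), each pinned to a high-weight cluster of its
  structure; literature counts are the true whole-brain counts times
  log-normal noise (σ = 0.1 by default, 0 for noise-free validation). The
  relation between literature and atlas-derived counts has no established
  noise model, so the generator exposes σ as a parameter rather than
  asserting one.
* **Seeding**: one integer seed; each generator stage re-seeds
  deterministically from it (seed + fixed offset), so standalone stages and
  the composed study are both reproducible.

What the generator does *not* emulate: spatial coordinates and section
geometry, segmentation, ambient RNA, doublets, batch effects, or
transcriptome-wide expression. Passing recovery tests therefore validate
the estimator chain under the stated sampling model — not robustness to
imaging artefacts or annotation errors in real atlases.

## Validation design and problem sizes

Three layers, all in the test suite and the acceptance script:

1. **Worked examples** — the published counts through the summary
   arithmetic, as above.
2. **Oracle equivalence** — calls, fractions, cross-tabulations and
   roll-ups equal literal per-cell loops on instances of at most 1 000
   cells.
3. **Ground-truth recovery** — `recovery_config()` pins every condition:
   explicit rates (`p_a` 0.05–0.5, `p_b` 0.3–0.8, odds 2), exactly 200 deep
   cells in each of 50 clusters (10⁴ cells), 20 fully covered structures, a
   dense spatial sample (~2×10⁵ cells), noise-free references. A
   deterministic variant (exact fractions, fixed integer composition, exact
   references) isolates the floor bias and must sit within
   `k × contributing clusters` of truth; the stochastic variant must sit
   within that floor bound plus three standard errors derived a priori from
   the binomial (deep), Poisson (spatial) and calibration error terms,
   including the attenuation of `k`. Halving every covered fraction and
   re-running checks the partial-volume correction under the same bounds.
   Across seeds this yields `k` recovered within ~5% and per-structure
   double counts within ~10–20%, floor bias making the estimates
   conservative.

These problem sizes keep the full suite under ten seconds on one core while
leaving each noise source measurable; they are the package's validation
conditions, stated here so that results are interpreted at the scale that
produced them.

## Known limitations

* Apportionment flooring biases every estimate downward; at atlas scale
  (thousands of cells per cluster and structure) the bias is negligible,
  but for structures with many low-count clusters it can dominate —
  `round = "after_sum"` reduces it to at most one cell per structure at the
  cost of departing from the stated procedure.
* The through-origin calibration inherits errors-in-variables attenuation
  and gives no uncertainty on `k`; with seven references a formal standard
  error would be fragile anyway.
* Neurotransmitter identity is inherited from cluster annotations, never
  inferred from expression; mis-annotated clusters propagate directly.
* The selection thresholds (350 cells, 50 cells/mm³) are applied strictly
  as stated; they are tunable arguments, not constants.
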