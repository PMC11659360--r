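# coexatlas

Quantifying where two genes are expressed in the *same* brain cells — at
whole-brain scale — from paired single-cell and spatial transcriptomic
datasets that share a cluster taxonomy.

The package grew out of the question of where the ghrelin receptor (*Ghsr*)
and the cannabinoid receptor type 1 (*Cnr1*) converge on single neurons.
*Cnr1* is roughly 100-fold more prevalent than *Ghsr*, so their overlap is a
small, anatomically structured population that only a deep scRNA-seq dataset
can detect and only a spatially resolved dataset can place. It is written
for quantitative neuroscientists and computational biologists who want to
run, audit or adapt that estimation chain.

## The method

With a deep dataset D (both genes measured, no anatomy) and a spatial
dataset M (anatomy, shared cluster labels), the pipeline estimates
per-structure positive counts as:

1. **Positivity**: cell i is positive for gene g iff
   `log2(CPM_gi) > t` (default t = 3, strict; zero counts negative, no
   pseudocount), or `count_gi >= 1` for targeted panels. Double-positive =
   positive for both.
2. **Cluster fractions** in D: `p̂_X(c)` = positive fraction of cluster c,
   for X in {A, B, AB}.
3. **Apportionment** onto structures via M:
   `N̂_X(s) = Σ_c floor( n(c,s) · p̂_X(c) )`, with n(c,s) the spatial
   cluster-by-structure cross-tab.
4. **Partial-volume correction**: divide by the covered-volume fraction
   f(s) ∈ (0, 1] for structures with missing sections.
5. **Whole-brain calibration**: multiply by
   `k̂ = Σ lit_i·est_i / Σ est_i²` — least squares through the origin
   against literature counts of marker-defined reference populations.
6. **Summaries**: per-structure percentages (one decimal, half away from
   zero), neurotransmitter composition of the double-positives, the strict
   selection filter (> 350 double-positive cells and > 50 cells/mm³), and
   per-region listed/total roll-ups.

A synthetic paired-data generator (`sim_config()`, `simulate_paired()`)
reproduces these study conditions with known ground truth — including the
100-fold prevalence imbalance, an odds-multiplier co-expression model,
sectioning emulated as covered-volume fractions (10 µm / 200 µm ⇒ true
proportionality factor 20), and noisy literature references — so the whole
chain is validated end to end. See the methods vignette
(`vignettes/coexpression-mapping.Rmd`) for the model, assumptions and
validation design.

## Worked example

```r
library(coexatlas)

study <- simulate_paired(sim_config(seed = 1))   # paired synthetic study
res   <- run_pipeline(study)                     # calls -> fractions -> transfer -> k -> summary

res$totals$n_a; res$totals$n_b; res$totals$n_ab
#> [1] 9
#> [1] 4004
#> [1] 5
res$headline
#> $pct_ab_vs_a
#> [1] 55.6
#> $pct_ab_vs_b
#> [1] 0.1
res$model
#> <calibration_model> k = 19.9755 from 7 reference population(s)
```

Out of 9 968 simulated cells, 9 are Ghsr-like-positive and 4 004
Cnr1-like-positive (the configured ~100-fold imbalance); 55.6% of the rare
gene's cells are double-positive versus 0.1% of the prevalent gene's —
the same asymmetry the real receptors show. The fitted proportionality
factor 19.98 recovers the true sectioning factor of 20.

The same arithmetic replayed on the published per-structure counts:

```r
pub <- published_structure_summary()
s <- summarize_structures(pub, cols = c(a = "ghsr", b = "cnr1", ab = "double"))
s[s$structure_id == "CA1", c("pct_ab_vs_a", "pct_ab_vs_b")]
#>   pct_ab_vs_a pct_ab_vs_b
#> 1        96.3         1.1
```

i.e. 96.3% of hippocampal CA1 *Ghsr*+ cells also express *Cnr1*.

## Analysis workflow

`analysis/01_simulate.R` … `04_summarize.R` run the full study as numbered
steps (generate → call → transfer/calibrate → summarize), writing all
tables under `results/`; each script prints what it found.

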