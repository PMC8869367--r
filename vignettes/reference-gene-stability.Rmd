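---
title: "Selecting stable reference genes for small-RNA qPCR panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting stable reference genes for small-RNA qPCR panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rgstab)
```

## The problem

Relative qPCR quantification reports a target's abundance as a fold change
against one or more reference genes (RGs) assumed stable across samples and
conditions. For miRNAs carried by extracellular vesicles (EVs) there is no
universal RG: the stable candidates differ by cell source and culture
condition, and with the small donor numbers typical of EV studies (often
three donors per condition) a poorly chosen RG can dominate the biological
signal. `rgstab` implements the complete selection workflow for such panels:
cleaning of Ct matrices censored at the platform's detection limit, four
classical stability algorithms, a comprehensive geometric-mean-of-ranks
ordering, and comparative-Ct quantification of a target against any chosen
RG, so that the downstream cost of an unstable RG can be demonstrated
directly.

Throughout, Ct (also written C~RT~ on array-format instruments) is treated
as a log2-scale abundance: amplification efficiency is fixed at 2, so one
cycle is one log2 unit and no standard curves are involved.

## Preprocessing

The cleaning chain runs in a fixed order
(`call_presence()` → `floor_to_detection_limit()` → `filter_candidates()` →
`spike_in_equalize()` → `global_mean_equalize()`, wrapped by
`preprocess_panel()`):

1. **Presence calling** (raw values). A gene is absent in a condition when
   more than half of the condition's samples read above the detection
   threshold (27 cycles by default) or missing; for the canonical 3-sample
   condition this is the "2 of 3 censored" rule. Presence is called before
   any equalization because equalization shifts values across the
   threshold; calling it before flooring is equivalent, since missing counts
   as above-threshold either way, and keeps the report interpretable.
2. **Flooring.** Missing readings and readings above the threshold are set
   to the detection limit (28 cycles, roughly single-copy territory), which
   avoids carrying stochastic single-copy values. Flooring is idempotent.
3. **Candidate filtering.** Only genes present in every condition of the
   analysis scope are retained; the exogenous spike-in is never a candidate
   and is carried separately.
4. **Spike-in equalization.** The spike-in is added in equal amounts before
   RNA extraction, so its per-sample Ct deviations estimate technical
   recovery differences; each sample is shifted by (mean spike Ct − its
   spike Ct). Values that were floored are shifted like any other value —
   a documented caveat of equalizing after flooring.
5. **Global-mean equalization.** Each sample is centred so its mean Ct over
   retained candidates equals the grand mean, absorbing RNA-input
   differences. We read "the mean of positive candidates" as per-sample
   centring to the grand mean over retained biological miRNAs, spike-in
   excluded.

Both equalizations are additive on the Ct scale (multiplicative on the
linear scale) and preserve every within-sample Ct difference, so they can
never change pairwise stability measures — a property the test suite
checks explicitly.

## The four stability algorithms

All four operate on the preprocessed matrix and report a per-gene metric in
cycles, lower = more stable, with competition ranks (ties share the minimum
rank).

**Stepwise pairwise variation (`genorm()`).** For genes j and k the
pairwise variation V~jk~ is the n−1 standard deviation over samples of
(Ct~j~ − Ct~k~). A gene's M value is the mean V against all remaining
partners; the highest-M gene is removed and M recomputed until two genes
remain, which share the final-round M by construction (their mutual V).
Each gene's reported metric is its M at removal. Ties at the exclusion step
remove the gene later in input order, making the run deterministic. The
pairwise-variation criterion for choosing the *number* of RGs is out of
scope.

**Mean pairwise SD (`delta_ct_stability()`).** The same V~jk~ averaged over
all partners, without exclusion — identical to the first-round M, an
identity the tests assert to 10^−12^.

**Model-based variance decomposition (`normfinder()`).** Ct values are
modelled as gene effect + sample effect + gene-specific error. Raw two-way
residual variances s²~i~ are biased because every gene shares the
per-sample normalization; with k genes the relation
s²~i~ = σ²~i~(1 − 2/k) + Σ~l~σ²~l~/k² is solved for the per-gene error
variances (clamped at zero when sampling noise drives an estimate
negative; the clamp is recorded, not an error). In `single` mode the metric
is σ̂~i~. In `by_condition` mode (exactly two groups) per-group variances
are estimated the same way, the gene-by-group interaction contrast d is
shrunken by the usual empirical-Bayes factor γ̂²/(γ̂² + σ̂²~ig~/n~g~), and
the metric is the mean over groups of |d̃~ig~| + σ̂~ig~/√n~g~. `single` is
the default even for merged analyses, matching how a user pastes one table
into the classic applet; both modes are exposed because the applet's
behaviour for merged runs is not documented.

**Descriptive dispersion (`bestkeeper()`).** Per gene: geometric and
arithmetic mean, extrema, SD(±Ct) and CV%. The default dispersion is the
mean absolute deviation from the arithmetic mean — the classical SD(±CP)
definition — with the n−1 standard deviation available as an option, since
published two-decimal tables cannot distinguish the two. The per-sample
geometric mean of all candidates forms the index, and each gene's Pearson
correlation with it is reported (undefined and returned as `NA` for a
zero-variance index).

Sample-level Ct shifts leave the first three algorithms unchanged but *do*
change BestKeeper's dispersion — it is the only one of the four that looks
at raw per-gene spread rather than ratios, which is why it is run after
global-mean equalization.

## Comprehensive ranking

`aggregate_rankings()` combines the four rank vectors by the geometric mean
of ranks, sorted ascending. Ties in the geometric mean are broken by the
arithmetic mean rank, then input gene order — deterministic and consistent
with the only tie observed in published tables of this layout. The
geometric mean is kept at full precision internally and conventionally
displayed with two decimals (`render_ranking()`).

`run_stability_pipeline()` wires everything together and produces one
ranking per condition plus the merged analysis, mirroring the conventional
three-panel report.

## Quantification

`relative_expression()` computes RQ~s~ = 2^−ΔΔCt^ against a chosen RG and
milestone sample (RQ = 1). `condition_ratio()` forms per-donor
treated/control fold changes, in which the milestone cancels exactly.
`one_sample_t_test()` tests the fold changes against a hypothetical mean of
1 (two-sided — sidedness is not dictated by the convention this follows,
and two-sided is the conservative default) and, by default, applies the
compound call "mean fold ≥ 2 AND p ≤ 0.05". `grubbs_test()` offers the
closed-form two-sided single-outlier screen (G against
((n−1)/√n)·√(t²/(n−2+t²)) with t the upper α/(2n) t-quantile on n−2 df);
it is available for pre-screening ratio triplets but is not applied
automatically. Multi-RG normalization (geometric mean of several RGs) is
deliberate future work; the workflow normalizes to one RG at a time.

## The synthetic panel generator

`synthetic_spec()`/`generate_panel()` draw panels from
Ct~i,s~ = baseline~i~ + input~s~ + tech~s~ + effect~i~·[s treated] + ε~i,s~,
with Gaussian per-gene noise on the Ct scale (log-normal on the linear
scale — the standard qPCR error model and what all four algorithms
implicitly assume), a per-sample RNA-input offset, and a per-sample
technical offset shared with the spike-in row. The technical offset is
placed on the biological genes as well as the spike-in, so spike-in
equalization genuinely removes it; stability results are insensitive to
this choice because per-sample constants cancel. Readings above the
detection threshold are reported missing with probability 0.5 and otherwise
floored at the limit, so both censoring rules are exercised.

`default_panel_spec()` freezes the benchmark used throughout the tests: 15
candidates + spike-in, 3 donors × {CTRL, SF}, with

| role | gene | noise SD (cycles) | treatment effect |
|---|---|---|---|
| designated stable | miR-24-3p | 0.05 | 0 |
| designated unstable | miR-34a-5p | 1.50 | 0 |
| condition-shifted | miR-23a-3p | 0.10 | +1.6 |
| responsive target | miR-193b-5p | 0.15 | −1.0 (2-fold up) |
| near detection limit | miR-22-5p, miR-29a-5p, miR-101-3p | 0.30 | 0 |
| ordinary candidates | remaining eight | 0.30–0.80 | 0 |

Baselines span 13–24 cycles (27.5 for the near-limit trio), the RNA-input
offset SD is 0.3 and the technical offset SD 0.5 cycles. The ordinary noise
SDs were chosen to mirror the dispersion range published for panels of this
kind (roughly 0.2–1.1 cycles of per-gene dispersion in the merged
analysis); the stable/unstable/shifted/target parameters encode the
qualitative behaviours such studies report. The truth object scores each
gene as noise SD + |treatment effect|/2, so the "most stable overall"
designation penalizes condition shifts at half weight.

What the generator does **not** emulate: preamplification stochasticity and
Poisson copy-number noise near the single-copy limit, plate or position
effects, efficiency differences between assays, and correlated
(co-regulated) genes. Passing recovery tests therefore show that the
algorithms behave correctly under their own assumptions at realistic noise
levels — not that any particular real panel will be ranked correctly.

## Numerical choices

* Sample SDs use the n−1 denominator throughout; at n = 3 the estimator
  choice is material, so it is fixed and documented once.
* Stepwise exclusion ties remove the later gene in input order; geometric
  mean ties break by arithmetic mean, then input order.
* Variance estimates are clamped at zero rather than erroring; clamps are
  recorded in the result's extras.
* Flooring applies upstream only — stability algorithms never re-floor.
* Equalized sample means match the grand mean to 10^−9^; the identity
  between the mean-pairwise-SD metric and first-round M holds to 10^−12^.
* PCA (`pca_samples()`) centres gene rows, applies no scaling, and uses
  SVD; with complete matrices this matches the usual web-tool default. Axis
  signs are arbitrary.

## What to expect at three donors per condition

The benchmark's deliberately small design (3+3 samples) is the regime these
panels are actually run in, and it is unforgiving: a pairwise SD estimated
from six samples has five degrees of freedom and a coefficient of variation
of about 32%. Running `scripts/acceptance.R` quantifies the consequence on
the default benchmark: the designated near-noiseless gene tops the
comprehensive ranking in roughly four of five panels (rather than always),
the designated unstable gene lands last about as often, and the stepwise
algorithm occasionally excludes the truly quietest gene before the final
pair. Equally, with an exactly two-fold target effect the compound
"≥ 2-fold AND p ≤ 0.05" call sits at the boundary by construction
(the expected mean fold is 2.0), so it succeeds in only about half of the
simulated panels even with the best RG. These are properties of the study
size, not of the algorithms; they are the quantitative form of the usual
caution that RG selections from few donors should be revalidated. The
misnormalization effect, by contrast, is large and robust: normalizing the
target to the unstable RG inflates the spread of donor fold changes by an
order of magnitude (median ≈ 15× on the benchmark, versus the ≥ 3×
one would already call disqualifying).

## Worked example

```{r example, eval = FALSE}
panel <- generate_panel(default_panel_spec(), seed = 1)
pipeline <- run_stability_pipeline(panel$matrix)
pipeline[["ALL"]]$report          # merged-scope ranking table
tidy(pipeline)                    # all scopes, tidy

clean <- floor_to_detection_limit(panel$matrix)
rq <- relative_expression(clean, "miR-193b-5p", "miR-24-3p", milestone = "C1")
pairs <- data.frame(donor = 1:3, treated = c("S1", "S2", "S3"),
                    control = c("C1", "C2", "C3"))
one_sample_t_test(condition_ratio(rq, rq, pairs)$ratio)
```

## Known limitations

* Exactly two groups in the grouped model-based mode; more require the
  original multi-group machinery.
* No efficiency correction (no standard curves in this design) and no
  inter-plate calibration.
* The canonical CSV dialect is a package convention for genes-as-rows
  exports; vendor-native binary exports are out of scope.
* Presence filtering at the margins is seed-dependent in simulation:
  sample-level offsets occasionally rescue a near-limit gene, which is
  faithful to how borderline assays behave on real plates.
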