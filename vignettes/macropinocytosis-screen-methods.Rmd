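---
title: "Methods: scoring macropinocytosis-dependent growth screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring macropinocytosis-dependent growth screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macroscreen)
```

## The assay and its model

RAS-driven cancer cells internalise extracellular protein by
macropinocytosis and catabolise it in lysosomes. Under glutamine starvation
with 5% BSA as the only usable nitrogen source, growth becomes a direct
readout of macropinocytic flux, and a viability screen under that condition
identifies pharmacological regulators of the pathway. `macroscreen` assumes
only the measurement model of such a screen:

* one luminescence reading per well, proportional to viable cell mass;
* on every plate, DMSO vehicle wells plus two known-behaviour control
  series — EIPA (inhibits macropinocytosis-dependent growth in its
  20–100 μM window) and Torin1 (enhances it around 0.2–1 μM, kills at
  its 5 μM top dose);
* each library compound measured at an ordered concentration grid in
  several replicates, all wells of one compound in one condition.

No parametric dose–response model is fitted anywhere in the analysis: the
per-compound statistic is a model-free area under the empirical curve.

## Normalization

Relative viability is luminescence divided by the mean DMSO luminescence of
the **same plate and condition**. Cross-plate pooling of vehicle wells is
rejected by construction: plate-to-plate brightness differences are the
dominant nuisance in luminescence assays, and per-plate controls exist
precisely to absorb them. Two consequences are load-bearing and tested as
properties: scaling all wells of a plate by any constant leaves every
relative viability unchanged, and the vehicle wells of each plate average
exactly 1. Viability is never clipped above 1 — enhancers genuinely exceed
the vehicle level.

The condition fold-change utility (`fold_change()`) compares replicate
viability between the starved and BSA-supplemented arms as a ratio of means
with a two-sided, classical equal-variance two-sample t-test (the Welch
variant is an option, not the default, because the original analysis used
the classical test). Zero-variance groups produce a flagged degenerate
result (infinite or zero t, `NA` p) rather than an error: such data are
legitimate at very low replicate counts and should surface, not crash.
Grouping keys are exposed rather than fixed, since whether replicates pool
across experiments is a design choice of the laboratory, not of the package.

## The AUC statistic and its calibration

`auc_single()` integrates the piecewise-linear relative-viability curve by
the trapezoid rule on the **linear** micromolar axis from 0 to the top
tested concentration, with the vehicle anchor (0 μM, viability 1)
prepended. The axis choice is the one genuinely open design decision in the
scoring stage, and it is pinned by a single calibration fact: a compound
with no effect up to 25 μM on the 0.2/1/5/25 μM grid must score exactly 25.
Linear-axis trapezoid integration with the anchor reproduces that number
identically; log-axis integration cannot. The anchor convention (rather
than, say, starting at 0.2 μM with a rescaled width) is likewise the unique
choice consistent with the calibration, and it is frozen in the acceptance
suite.

Replicates are scored independently and averaged. Because the trapezoid is
linear in the viability values, this is provably identical (tested to
1e-12) to scoring the per-level mean profile — the per-replicate wording is
documentation of provenance, not a behavioural choice. Incomplete grids are
hard errors: silently rescaling a partial grid would shift the 0–25
calibration and make AUCs incomparable across compounds. The statistic is
left on its native μM·viability scale; hit thresholds live on the same
scale.

On the default grid the statistic's useful range is roughly 0.1 (complete
kill at all doses; only the anchor triangle remains) to 25·vmax for
enhancers.

## Hit calling

The screen summary is the mean and standard deviation of per-compound AUCs
over **library compounds only**; vehicle and controls never enter. Hits are
compounds strictly below mean − k·SD or strictly above mean + k·SD, with
k = 1 by default and configurable; ties at a threshold are deliberately
`NONE` ("lower than" is a strict comparison). Thresholds are computed in a
single pass — hits are not trimmed and thresholds recomputed, because the
procedure being reimplemented is one-pass. Sample SD (n − 1) is the default
flavor; with libraries of hundreds of compounds the population flavor
differs negligibly, but both are exposed because the choice is not
derivable from the published summary numbers.

A deliberate non-claim, encoded in the tests: on a pure-null screen the
per-side flagged fraction is *not* asserted to converge to the Gaussian
one-SD tail (the thresholds are estimated from the same data they cut);
the suite asserts only that both sides flag a fraction strictly inside
(0, 0.5) and symmetrically in expectation.

Control QC is a pair of boolean gates with artifact defaults, since the
source material gives qualitative windows only: EIPA passes when mean
viability at its top dose is below 0.5× its lowest-dose mean; Torin1 passes
when either of its two mid-window doses exceeds 1.2× vehicle. The top
Torin1 dose is allowed — expected — to kill. Gate failure annotates the run
by default and aborts it (classed condition, distinct exit status in the
CLI) under `qc_strict`.

## Target aggregation

Hits are expanded per annotated target (a multi-target compound counts once
in each target), grouped by (target, direction), and sorted by group size.
`complete = TRUE` marks targets whose entire library representation is
concordant — the strongest signal this design can produce, exemplified by
all five HDAC inhibitors and all four HSP90 inhibitors in the original
library scoring as AUC-decrease hits. Singleton groups are retained but
flagged (`multi_hit = FALSE`); no enrichment statistic is computed, because
the procedure reports raw overlap counts and a hypergeometric test over a
hand-curated library would suggest a rigor the design does not have.

## The synthetic generator: what it emulates, what it does not

Raw plate data for the original screen are not deposited, so the package
ships a generator that emulates the stated world: a 225-compound library on
the 0.2/1/5/25 μM grid in 4 replicates under glutamine starvation + 5% BSA,
96-well plates each carrying 4 DMSO wells and the two 4-point control
series (21 library compounds per plate, 44 plates), and a 9.6-fold BSA
rescue over plain starvation. Planted dose–responses are phenomenological
Hill curves: inhibitors `bottom + (1−bottom)/(1+(c/EC50)^h)`, enhancers
`1 + (Emax−1)·c^h/(c^h+EC50^h)`, and a biphasic enhance-then-kill product
for the Torin1 shape. Measurement noise is multiplicative lognormal with
mean 1 (luminescence is positive and its error scales with signal; CV is
therefore stable); additive Gaussian is available as an option. The default
`noise_cv = 0.1` is an artifact choice — true screen noise is unreported —
and the recovery tests run at the 0.05 CV the validation experiments
prescribe. The default planted-effect layout (20 strong inhibitors, EC50
0.5 μM, bottom 0; 5 strong enhancers, Emax 2) is the validation world, not
an estimate of the real library's effect distribution.

Seeding is hierarchical: one master seed, with each plate's noise drawn
from a substream keyed by (replicate, plate position), so extending a
library never changes the data of existing plates and identical
configurations are byte-identical on disk.

What a green recovery test establishes: the pipeline's arithmetic and
bookkeeping are correct, and effects several noise-SDs beyond the
thresholds are found with ≥ 95% sensitivity. What it does not establish:
performance on real screens, which have spatial plate effects (edge drift,
row/column trends — out of scope, as is B-score-style correction),
non-lognormal outliers, compound precipitation at high dose, and correlated
replicate failure modes none of which the generator produces.

## Numerical choices and degenerate inputs

* CSV numbers are written with 17 significant digits; re-reading a table or
  report reproduces every double bit-exactly (tested).
* Threshold symmetry (upper − mean = mean − lower) holds by construction
  but is asserted at 1e-12, not bitwise: `(m+h)−m` and `m−(m−h)` may differ
  in the last ulp of IEEE arithmetic.
* An all-identical AUC vector gives SD 0, thresholds equal to the mean, and
  zero hits (strict inequalities).
* Grids must be strictly increasing and positive; a viability table missing
  any (replicate, level) cell for a scored compound is an error naming the
  compound; a plate without vehicle wells is an error naming the plate; a
  row-level invariant violation on read is an error naming the row.
* The stock-into-well dilution rule `final = stock·v_stock/(v_stock+v_well)`
  is exposed (`dilution()`) because every concentration in the screen
  design derives from 10 μL additions into 40 μL wells; the generator and
  the acceptance suite both use it.

## Known limitations

Geometry is parsed but not used: well coordinates carry no spatial model.
The pipeline scores one condition at a time and does not model between-day
batch structure beyond the per-plate normalization. Dose–response
parameters (IC50, slope) are never estimated — by design, the screen
statistic is model-free — so compounds active only above the top tested
dose are invisible, exactly as in the original design.
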