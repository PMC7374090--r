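---
title: "Methods: screen scoring, signatures, pathway essentialness and drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screen scoring, signatures, pathway essentialness and drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenomics)
```

This vignette explains the models behind each stage of the toolkit, the
parameters that matter, the numerical conventions we pinned, and what the
synthetic generators do and do not emulate.

## Screen scoring model

A pooled shRNA dropout screen infects cells with a hairpin library, grows
them for several population doublings, and sequences barcode abundance at a
reference and a final time point. Hairpins targeting genes needed for
proliferation or survival drop out, so for each shRNA we score

$$\mathrm{fold} = \frac{n_\mathrm{ref} + c}{n_\mathrm{final} + c},
\qquad d = \log_2 \mathrm{fold},$$

with pseudocount $c = 1$ guarding zero final counts while leaving
large-count ratios essentially unchanged. Base 2 matches the log2
convention used for the copy-number and expression layers; hit calls are
invariant to the base because the null threshold scales with the scores.

**Gene score.** The per-gene summary is the 80th percentile of the gene's
$d$ values (`quant_log`). A high quantile (rather than the mean) tolerates
inert hairpins, which are common, and a quantile (rather than a maximum)
resists single outlier hairpins; it also removes the bias that the varying
number of hairpins per gene induces on extreme statistics. Genes with
fewer than `min_shrnas = 2` hairpins carry no within-gene evidence and are
reported as skipped rather than scored.

**Null model.** Most genes (>95%) are not essential in any one line, so
the bulk of gene scores is treated as draws from a normal null whose
parameters are estimated robustly: the mean as the median, and the standard
deviation as the 2.5--97.5 inter-quantile range divided by 4 (95% of a
normal lies within $\pm 1.96 \approx 2$ standard deviations). Both
estimates ignore the upper tail where true essentials live. A gene is a
hit when its score strictly exceeds the null's 95th percentile,
$\mu + 1.6449\,\sigma$; the constant is pinned to four decimals so results
are bit-identical across platforms.

**Calibration bias, quantified.** Dividing the inter-quantile range by 4
instead of $2 \times 1.9600$ underestimates $\sigma$ by the factor
$1.96/2 = 0.98$. The effective cut on truly null data therefore sits at
$\approx 1.6449 \times 0.98 = 1.612$ standard deviations, whose normal
exceedance is 5.35%, so an all-null screen yields about 94.65% non-hits
rather than 95.00%. The acceptance script measures exactly this number;
the test suite allows the documented one-percentage-point band around 95%.

**A note on quantile conventions.** The package uses linear interpolation
between order statistics (the type-7 convention) throughout — gene scores
and null quantiles alike — because it is deterministic and matches the
default of mainstream numerical stacks; the convention is exposed through
the `probs`/`lower`/`upper` arguments should a discrete order statistic be
preferred. One consequence is worth knowing: with 5 hairpins the
interpolated 80th percentile lies between the 4th and 5th order statistics,
so a borderline hit can clear the cut with only its single strongest
hairpin above it. Deeply depleted genes always show several hairpins above
the cut, and `hit_shrna_support()` reports the per-hit count as a
diagnostic; under a discrete lower order statistic the "at least two
hairpins above the cut" property would hold by construction, but we kept
interpolation as the primary convention.

**CERES rule.** For CRISPR screens summarised by CERES gene effects,
essentiality is a simple inclusive threshold, hit iff score $\le -0.5$.
We note the boundary convention explicitly because "below $-0.5$" is
sometimes written exclusively; the comparator value is an argument.

## Omics store and signatures

The store joins per-(cell line, gene) layers: log2 copy-number ratios
against a normal reference, expression (either log2 versus normal cells, or
median-centred across a panel — a store-level dialect that is never mixed,
and cross-dialect comparison is refused), mutation records with COSMIC
occurrence counts, an oncogene annotation set, a gene-to-drug map, screen
hit tables and RPPA protein values. Gene identity is the case-sensitive
symbol string; alias resolution is out of scope, and absent layers are
reported as absent rather than imputed.

Mutations are reported only when recurrent: strictly more than 5 COSMIC
occurrences, or — for panel-style lines where recurrence counts are not
comparable — only COSMIC hotspot annotations. Amplification is called at
log2 ratio $\ge 0.8$, inclusive; no published cut accompanies the data this
mirrors, and 0.8 sits just below the smallest amplification we have seen
reported in a signature table (0.85), so the default is deliberately
configurable. Median-centring ignores missing cells rather than
zero-filling them, which would bias the centre.

The four signatures are pure set logic over those layers, with A = altered
(amplified or retained-mutation), O = oncogene-annotated, H = screen hits:
candidate $= A \cap O$, overall $= A \cap H$, functional
$= A \cap O \cap H$, druggable $= H \cap \{\text{drug-mapped}\}$.
A gene altered only by a mutation that the COSMIC filter drops is not
"altered": the reported mutation column must justify membership. Signature
rows copy store values verbatim — nothing is recomputed at signature time —
and are ordered by expression descending (ties by symbol), matching how
such tables are conventionally presented; the druggable signature is
ordered by screen rank.

## Pathway essentialness

KGML pathway files are parsed into simple undirected gene graphs: gene-type
entries expand to one node per gene identifier, groups flatten to their
component gene entries, map/compound/ortholog entries are dropped, and
relation subtypes and directions are ignored because only adjacency enters
the score. Before any computation the graph is restricted to the screen
universe — the genes actually scored — so that the "proportion of pathway
genes that are hits" has a measured denominator.

The score combines hit enrichment, hit proportion and hit--hit linkage.
Each hit node $g$ receives weight

$$w(g) = \alpha + \lambda \cdot
\frac{\#\{\text{hit neighbours of } g\}}{\max(1, \deg g)},$$

and the pathway score is $\left(\sum_{g} w(g)\right) \times
\frac{n_\mathrm{hits}}{n_\mathrm{genes\ in\ universe}}$, defaults
$\alpha = \lambda = 1$. The formula is our own design: the stated
ingredients (enrichment, proportion, extra weight for hits directly linked
to other hits) admit many weightings, so we chose the simplest one in which
each property is separately testable — monotone in the hit set, strictly
increased by connecting two otherwise isolated hits, zero exactly when no
hits map to the pathway, and unaffected by genes outside the universe.
It is isolated behind `pathway_score()` so an alternative can be dropped
in, and because it is not the (unpublished) formula behind any particular
published score table, we make no attempt to reproduce such tables
numerically. Ranking cell lines for a pathway reuses the same scores; a
line's `rank_in_line` is the pathway's position in that line's own full
ranking, and ties order alphabetically for reproducibility. For map
export, hit annotations carry a colour intensity
$1 - (\mathrm{rank} - 1)/(n_\mathrm{screen} - 1)$, clipped to $[0, 1]$, so
the strongest hit is darkest.

## Drug response

**IC50.** The primary estimator is a four-parameter logistic on log10
concentration fitted by Levenberg--Marquardt, with the IC50 as the fitted
midpoint and its standard error propagated from the log10-midpoint
parameter. Responses that never fall below half their maximum cannot
anchor a sigmoid and raise a typed `non_sigmoid_error`; `estimate_ic50()`
then falls back to LOESS inversion: a local linear fit (tricube weights,
span 1) evaluated on a 1,000-point log-spaced grid, with the IC50 at the
first grid point where the fitted curve reaches surviving fraction 0.5, and
the error as half the concentration-width between where the 95% prediction
interval bounds (pointwise fit variance plus residual variance, $t$
quantile at $n - 2$ degrees of freedom) cross that level. The grid pins
the resolution: on exactly linear data the estimate is within one grid step
of the analytic crossing.

**Z-scores.** The panel Z-score standardises a line's IC50 against the
panel's geometric mean. Subtracting a geometric mean from a raw IC50
mixes scales, so the default computes on natural logs,
$z = (\ln \mathrm{IC50} - \overline{\ln \mathrm{IC50}})/s_{\ln}$, where the
centre is exactly the log geometric mean and $s$ is the sample standard
deviation (not a standard error, which would shrink with panel size and
break the fixed $-1.5$ interpretation). The literal raw-scale variant is
available behind `log_scale = FALSE`. Sensitivity is called inclusively at
$z \le -1.5$. External panel statistics (e.g. from a large reference
panel) can be supplied; by default the panel at hand defines its own
statistics, which makes the in-sample z's mean 0, sd 1, and invariant to
rescaling all IC50s — properties the tests assert.

## Synthetic generators: what they emulate, and what not

Every generator is a pure function of its parameters including the seed.

* `simulate_screen()` draws reference counts from a negative binomial
  (default mean depth 500, size 10) because pooled-screen read counts are
  overdispersed relative to Poisson, and depletes all hairpins of planted
  essential genes by a common `effect_log2` (default scenarios use 4, i.e.
  16-fold, a strong dropout), optionally jittered per hairpin. It does
  *not* emulate real library composition, hairpin-specific efficacy
  structure, GC/abundance biases, or replicate screens; passing recovery
  tests therefore show the statistics behave as designed under the stated
  noise model, not that any particular laboratory screen is error-free.
* `simulate_omics()` plants per-line drivers that satisfy all three
  signature predicates (amplified in $[1.0, 4.5]$ log2 and/or a hotspot
  mutation with COSMIC count $\ge 10$, oncogene-annotated, over-expressed,
  hit), plus decoys in each partial intersection and background mutations
  the COSMIC filter must drop; background copy ratios are clipped below
  the amplification cut so planted set membership is exact by construction.
* `make_toy_kgml()` writes small valid KGML with controllable multi-gene
  entries and always one non-gene entry, so readers must both expand and
  filter.
* `simulate_dose_response()` draws from a four-parameter logistic with
  truncated Gaussian noise; at the true IC50 the noiseless response is
  exactly the midpoint of top and floor.

## Problem sizes and numerical choices

The test suite and acceptance script run at these sizes, chosen to match
the scale the statistics are designed for while keeping a default run in
seconds-to-a-minute: null calibration on 20 replicates of 15,000 genes;
spike-in recovery on one screen of 15,000 genes × 5 hairpins with 2%
essential; oracle checks on 1,000 random genes; set-algebra and pathway
properties on 100 random fixtures each.

Other pinned conventions: tab-separated UTF-8 tables with missing values as
empty strings and doubles serialised with 17 significant digits so
read(write(x)) is exact; ranks tie-broken lexicographically by symbol;
degenerate inputs fail loudly (all-equal gene scores are a degenerate null;
a zero final count with zero pseudocount names the hairpin; malformed
numeric cells name their row and column rather than being coerced).

## Known limitations

* The null assumes at most a few percent of genes are truly essential;
  screens of heavily engineered or hypersensitive lines would inflate
  $\sigma$ and make calls conservative.
* The pathway score treats all relation types equally and ignores
  direction; signalling inhibition and activation are not distinguished.
* Gene joins are by exact symbol; datasets using different symbol versions
  must be harmonised upstream.
* IC50 errors from LOESS inversion depend on the grid range; curves
  crossing 0.5 outside the tested concentrations are refused, not
  extrapolated.
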