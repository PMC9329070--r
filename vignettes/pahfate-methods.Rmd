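---
title: "Models and methods behind pahfate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pahfate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahfate)
```

`pahfate` analyses short-term (two-timepoint) seawater bottle incubations
spiked with polycyclic aromatic hydrocarbons (PAHs), of the kind used to ask
whether the sea-surface microlayer (SML) removes PAHs faster than the
subsurface layer (SSL) beneath it. This vignette explains the models the
package implements, the assumptions behind them, the defaults and why they
were chosen, and what the simulation-based tests do and do not demonstrate
about real field data.

## The measurement problem

A bottle incubation measures dissolved-phase concentrations at the start
(`T0`) and end (`T24`) of an exposure. The removal rate of a compound is the
two-point difference quotient

$$r = \frac{C(t_0) - C(t_1)}{\Delta t} \quad [\mathrm{ng\,L^{-1}\,h^{-1}}],$$

and the percent decrease is $100\,(C(t_0)-C(t_1))/C(t_0)$. Two artifacts
stand between this number and "biodegradation":

1. **Re-partitioning.** Hydrophobic compounds sorb to microbial biomass and
   dissolved organic carbon (DOC). If those pools grow during the
   incubation, the dissolved concentration falls without any degradation.
2. **Bottle-common losses.** Wall sorption, handling and extraction
   recovery remove mass from every analyte in a bottle by a roughly common
   factor, especially in small glass bottles.

The package treats these with an equilibrium partitioning bound and a
benchmark-compound correction, respectively.

## Equilibrium partitioning

Sorption to organisms is modelled through a hydrophobicity-driven
bioconcentration factor,

$$\mathrm{BCF} = \frac{C_M}{C_W} = \frac{f_{OM}\,K_{OW}}{\delta},$$

with $K_{OW}$ the octanol–water partition constant, $f_{OM}$ the
organic-matter fraction of the sorbent and $\delta$ the density of octanol.
Sorption to DOC uses the common approximation $K_{DOC} = 0.1\,K_{OW}$. The
BCF is a ratio, not a mass balance; `pahfate` closes it over three pools
(dissolved, pooled biota, DOC) in a fixed volume:

$$f_{dissolved} = \frac{1}{1 + \mathrm{BCF}\cdot B + K_{DOC}\cdot D},$$

with $B$ the biota organic matter (kg/L) and $D$ the DOC mass concentration
(kg C/L); the sorbed fractions follow and the three fractions sum to one
exactly. This closure is the simplest one consistent with the BCF
definition and makes the fractions directly testable (conservation,
monotonicity in $\log K_{OW}$, dilute limits).

**Parameters and defaults.** $\delta$ = 0.82 kg/L (octanol); $f_{OM}$ = 1,
because biomass is already expressed on an organic-matter basis; bacterial
biomass from cell counts at 20 fg C per cell (a standard marine
heterotroph value) times an OM:OC ratio of 2 g/g; DOC 60 µM C, a typical
Antarctic surface value; phytoplankton biomass enters as extra kg OM/L in
the same pooled biota compartment, with no separate BCF. Every constant is
an argument of `partition_context()`. The shipped compound table
(`inst/extdata/pah_properties.csv`) carries literature $\log K_{OW}$, ring
counts and molecular weights for the 13 quantified PAHs; results depend on
$K_{OW}$ monotonically, so users with preferred property values should
supply their own table. Naphthalene, acenaphthene and acenaphthylene are
representable but flagged `volatile_excluded`, since C18/GC–MS workflows
cannot quantify them reliably.

**The sorption bound.** For contexts at $t_0$ and $t_1$,
`sorption_artifact_bound()` returns
$\max\!\left(0,\; 1 - f_{dissolved}(t_1)/f_{dissolved}(t_0)\right)$ — the
fractional dissolved-phase decrease that pure re-equilibration to the grown
organic-matter pools would produce. It is zero for static pools and floored
at zero (a biomass decline cannot explain a decrease). Attribution compares
the observed percent decrease with this bound: below a noise threshold
(default 2%, roughly the repeatability of a careful GC–MS workflow) the
verdict is `NO_REMOVAL`; within the bound, `SORPTION_POSSIBLE`; beyond it,
`BIODEGRADATION_DOMINANT`. Ties (observed decrease exactly at the bound,
which happens by construction in noiseless simulations) count as
sorption-explainable, with a $10^{-9}$ relative tolerance guarding the
comparison against floating-point roundoff.

## Benchmark correction

The correction formula is a per-bottle ratio normalization: with benchmark
concentrations $C_b(t)$, the scale factor $s(t) = C_b(t)/C_b(t_0)$ is
divided out of every compound in that bottle. Consequences, used as exact
test oracles: the corrected benchmark series is constant; any compound
whose loss equals the benchmark's shows zero corrected removal; and a
common multiplicative loss applied to all compounds leaves all corrected
rates unchanged. This is the simplest transformation that removes
multiplicative bottle-common artifacts exactly; it is a reconstruction of
the benchmarking idea rather than a transcription of any published formula,
and it is documented as such. The benchmark should be a compound whose own
removal does not differ across the conditions compared — phenanthrene by
default. Both raw and corrected rates are reported, because the benchmark's
own biological removal is subtracted from everything: corrected rates are
differences relative to the benchmark, not absolute rates.

Negative rates (apparent production) are preserved and flagged, never
truncated: truncation would bias class means upward.

## Statistical machinery

* **Mann–Whitney.** Layer contrasts use a two-sided rank-sum test. For
  pooled sizes up to 12 the permutation null is enumerated completely over
  all $\binom{n_1+n_2}{n_1}$ assignments of the observed data, with
  mid-ranks for ties; the p-value is the proportion of assignments whose
  $U$ is at least as far from $n_1 n_2/2$ as observed. At these sizes the
  normal approximation is poor and the exact p is cheap (at most 924
  assignments). Larger samples use the tie-corrected normal approximation
  from `stats::wilcox.test`. With two bottles per condition a per-compound
  test cannot dip below $p = 1/3$; significance is therefore assessed on
  rates pooled within a molecular-weight class (`compare_layers(mode =
  "pooled")`), and both pooling modes are reported.
* **t-tests.** `t_test()` wraps `stats::t.test` (Welch unpaired, or paired)
  with explicit degenerate-input errors when variances collapse to zero.
  Screen p-values use Welch on raw relative abundances — mirroring common
  practice for amplicon treatment contrasts; a log-scale variant was
  evaluated and has lower power at these sample sizes because the enriched
  arm's proportions are strongly right-skewed.
* **Fold changes.** The signed convention: $a/b$ if $a \ge b$, else
  $-b/a$, so magnitudes are $\ge 1$ and the function is antisymmetric. Zero
  means in one arm of the screen are replaced, for the fold change only, by
  half the smallest nonzero proportion in the stratum, since a ratio is
  undefined at zero.
* No multiple-testing correction is applied to the per-compound layer
  comparisons by default (raw two-sided p-values are reported);
  `stats::p.adjust` can be applied downstream by users who prefer it.

## The HCB screen

ASV tables are rarefied to a common depth (minimum sample sum by default)
by subsampling without replacement via `vegan::rrarefy` under a fixed seed;
samples below the target depth are dropped with a warning. Relative
abundances are aggregated at a chosen rank (genus by default), with
rank-unassigned taxa pooled into an `unclassified` bin. Hydrocarbonoclastic
bacteria (HCB) are selected by case-insensitive genus matching against an
editable list (`inst/extdata/hcb_genera.txt`), which assumes members of a
genus share hydrocarbon-degrading metabolism — true for most documented HCB
genera, not all. Archaea are dropped before screening by default (they are
a negligible share of 16S V4-5 surface-seawater libraries); the step is a
separate, toggleable function. The screen then reports, per
(layer × size-fraction) stratum, each genus's per-arm mean abundance, fold
change and Welch p-value. Interpretation caveat: relative abundances are
compositional, so a genuinely constant taxon shows an apparent depletion
when another taxon blooms; the screen reports this honestly rather than
attempting compositional correction.

## The synthetic-data generators

The generators exist so that every stage is testable without field data;
they encode the statistical structure the analysis assumes.

* **Incubation.** Total compound mass decays first-order,
  $\exp(-(k_{bio}+k_{wall})t)$; the measured dissolved concentration is the
  equilibrium dissolved fraction of the total times mean-one lognormal
  noise ($\sigma$ chosen so the CV is exactly `noise_cv`, default 0.10 —
  GC–MS error is roughly proportional). The generative truth is
  exponential while the estimator is a linear two-point rate —
  deliberately, so the tests quantify the estimator's behaviour instead of
  assuming it. Control bottles start at in-situ background totals (0.74
  and 3.63 ng/L for SML and SSL, spread over the 13 compounds); abiotic
  bottles carry only wall loss.
* **Community.** Baseline ASV weights are lognormal (sdlog 1.5, a typical
  rank-abundance steepness); one ASV per HCB genus, decoy marine genera
  elsewhere, a small genus-unassigned tail. PAH-arm samples at the final
  timepoint in the enrichment layers have selected genus weights
  multiplied by an enrichment factor, then renormalized; counts are
  Dirichlet-multinomial with total concentration 50 (substantial
  replicate-to-replicate overdispersion). Renormalization means the
  observable fold of an enriched genus is $f/(1+(f-1)p_0)$, below the
  injected $f$ — e.g. an eightfold weight enrichment of a genus at 3.7%
  baseline is observable as ≈ 6.35×; `true_enrichment_fold()` returns this
  closed form and is the ground truth for recovery tests.

**The reference scenario.** `scenario_paper_like()` fixes the study
conditions the pipeline is validated under: 13 compounds × 2 layers × 2
treatments × 2 bottles, 200 ng/L spike, 24 h; SML HMW two-point rates
ramping 0.29→3.08 ng/L/h with hydrophobicity (mean 1.685), SML LMW
{0.03, 0.14, 0.25} (mean 0.14), SSL LMW mean 0.17, SSL HMW zero, with the
benchmark phenanthrene at 0.14 in both layers; Antarctic-summer partition
contexts (SML 3×10⁸ cells/L + 10⁻⁸ kg/L phytoplankton OM, SSL 2×10⁸ +
5×10⁻⁹, DOC 60 µM) that put the sorbed fraction at ≈ 0.04–0.08% for LMW and
up to ≈ 9.7% for the most hydrophobic HMW compound; and an eightfold
Pseudoalteromonas weight enrichment (3.7% baseline) in the SML community.
Biodegradation constants are solved analytically from the target rates,
$k = -\ln(1 - \Delta t\, r / (f_{dissolved}\,C_0))/\Delta t$, so the
noiseless round trip is exact to machine precision. Wall loss is zero in
this scenario — a nonzero common loss would contradict its "no HMW removal
in the SSL" condition — and is exercised separately in the tests.

## Numerical and design notes

* Exact Mann–Whitney p-values are ratios of counts over
  $\binom{n}{n_1}$; mid-ranks are multiples of ½, so the extremity
  comparisons are exact in binary floating point and the enumeration is
  reproducible bitwise.
* All simulators and the rarefaction step take explicit seeds and restore
  the caller's RNG state; fixed seed implies byte-identical output.
* Two-timepoint designs are first-class; with more timepoints the rate
  uses the first and last, and intermediate points are available to the
  benchmark correction.
* Problem sizes in the test suite (e.g. 100-seed contrast loops, 50–200
  seed rarefaction averages, 100-seed enrichment recovery) were chosen to
  keep Monte-Carlo error well below the margins being asserted while the
  whole suite runs in about a minute.

## Limitations

* The partitioning closure is an equilibrium model; kinetic sorption,
  black-carbon sorption and volatilization are out of scope (defensible
  for dark, cold, low-black-carbon incubations, not in general).
* The two-point rate underestimates the initial rate of an exponential
  decay and, with 10% measurement noise, per-compound rates below ≈ 1
  ng/L/h carry relative errors that frequently exceed 50% at two bottles
  per condition — class-pooled summaries are the robust quantity at this
  design size, which is why the reporting emphasises them.
* The simulators emulate the variance structure the analysis assumes
  (lognormal measurement error, Dirichlet-multinomial counts). Passing
  recovery tests therefore shows the pipeline is correct and well-calibrated
  under those assumptions — not that real incubations satisfy them; real
  data bring cartridge recovery drift, correlated extraction errors and
  taxon-specific sequencing biases that the generators deliberately omit.
* The shipped HCB list is the well-documented polar subset; a production
  screen should extend it from current literature.
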