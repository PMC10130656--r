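---
title: "Methods: multi-modal quantification of growth attenuation during cell-cycle arrest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-modal quantification of growth attenuation during cell-cycle arrest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arrestomics)
```

## The scientific setting

Temperature-sensitive cell-division-cycle (*cdc-ts*) mutants of budding
yeast stop dividing at the restrictive temperature but keep growing, so a
culture of arrested cells becomes a population of steadily enlarging
cells. Three things happen to such cells over a 9-hour arrest: their mean
volume grows roughly exponentially, then linearly, then plateaus; the
environmental stress response (ESR) — a stereotyped program of roughly
300 induced (iESR) and over 600 repressed (rESR) genes — switches on and
strengthens; and the ribosomal share of the proteome falls, which is
visible both in TMT proteomics and in biochemical ribosome/protein
ratios, and indirectly as faster diffusion of GEM nanoparticles in a less
crowded cytoplasm. `arrestomics` implements the quantitative chain that
turns the five raw data modalities into those statements, plus a coupled
synthetic-data generator so that every stage can be validated by
parameter recovery instead of by eye.

## ssGSEA projection of the ESR

Expression input is a gene-by-sample TPM matrix. Preprocessing is
`log2(TPM + 1)` (`preprocess_tpm()`), tracked by a transform state so it
cannot be applied twice. For one sample and one gene set $S$ of size $m$
among $N$ genes, genes are sorted by decreasing expression and two
empirical cumulative distribution functions are accumulated along the
ranking: the in-set ECDF, optionally weighted by the normalized rank
$r_i = (N - i + 1)/N$ raised to the exponent $\alpha$, and the unweighted
out-of-set ECDF. The projection is
$\sum_{i=1}^{N} \left( \mathrm{ECDF}_\mathrm{in}(i) -
\mathrm{ECDF}_\mathrm{out}(i) \right)$.

Choices made where the method description is not fully specified:

* **Weighting exponent.** `alpha = 0.75` is the default, the value in
  common use for single-sample projections; `alpha = 0` (pure rank walk)
  is used for all exact tests because the walk is then rational-valued
  and can be checked against hand enumeration. The original analysis
  does not print its exponent, and projections at the two values are
  monotonically related on our synthetic data.
* **Rank normalization.** Implemented as $r_i = (N - i + 1)/N$, mapping
  the top gene to 1 and the bottom gene to $1/N$.
* **Ties.** Broken by gene identifier after sorting by value. Real TPM
  data contain many exact zeros, and a documented deterministic rule
  matters more than which rule is chosen.
* **"Absolute expression".** Read as the magnitude of the
  `log2(TPM + 1)` value, which is non-negative, not as a fold-change.

With `alpha = 0` the projection of the complement set is the exact
negation of the set's projection, and any strictly monotone transform of
the values leaves the projection unchanged; both properties are asserted
in the test suite.

## TMT ribosomal proteome fraction

The peptide-level quantification chain applies, in order: row filtering
(Mascot score $\ge 25$ and isolation interference $\le 30$, both
inclusive), per-channel median normalization, protein rollup, and the
fraction computation. The eligibility gate for proteins — TotPep $> 2$
and UniPep $> 1$, both strict — is applied to the numerator and the
denominator alike, so
$[\mathrm{RP}]/[\mathrm{Total\ Protein}]$ is the summed abundance of
eligible ribosomal proteins (40S, 60S, 60S-acidic; the packaged yeast
list has 137 gene names) over the summed abundance of all eligible
proteins. Fractions are reported per channel and as log2 relative to the
1-h channel.

Two details are underdetermined by the methods text and were fixed here:
median normalization preserves the grand median (making it idempotent
and unit-preserving rather than mapping every channel to 1), and
filtering is applied *before* normalization, so that low-quality rows
cannot distort channel medians. Both are configurable at the call sites.

## Biochemical ratios and the dilution metric

`ribosome_protein_ratio()` is deliberately primitive — A260 of the
sucrose-cushion pellet over Bradford protein concentration — because the
assay's information content is entirely relative; an optional
1 A260 $\approx$ 40 µg/mL RNA conversion exists but is off by default.
`normalize_to_control()` matches a control series by timepoint, averages
replicates, and reports log2 ratios with the figure-legend dispersion
convention (half-range for two replicates, standard deviation for three
or more). `dilution_metric()` combines protein-per-cell with mean volume
into protein-per-volume, the quantity that falls when volume growth
outruns protein synthesis.

## Coulter volumes

`mean_volume()` implements the half-maximal-count rule: keep bins whose
count strictly exceeds half the maximum bin count, return their
count-weighted mean volume. "Above" is read literally as a strict
inequality; an `inclusive` flag exposes the boundary case, which differs
only when a bin sits exactly at half maximum. If the retained bins are
non-contiguous the estimate still uses all of them, and a multimodality
warning is emitted when a secondary run of bins carries more than 20% of
the retained counts — single-bin dips from counting noise stay silent.
On log-normal populations the rule estimates the count-weighted mean of
the above-half-maximum density region; the generator reports that
analytic target per timepoint, and at $10^4$ cells and CV 0.2 the
estimate stays within 5% of it.

The reference curve is $v(t) = v_0 \cdot 2^{60 t / T_d}$ with $T_d = 90$
min. `attenuation_profile()` reports per-timepoint log2 deviations from
that reference, a plateau estimate (mean over the final 2 h by default),
and an attenuation flag when the terminal slope drops below 25% of the
initial slope. The window and threshold are configurable defaults, not
literature values: the source material describes
exponential-to-linear-to-plateau growth qualitatively.

## GEM diffusion

`time_averaged_msd()` uses overlapping windows — the standard convention
— and is gap-aware: a missing frame removes pairs rather than shifting
them. `fit_deff()` is an ordinary least-squares fit of MSD on lag over
lags strictly below 100 ms (at 100 fps, lags 1–9), with a free intercept
because static localization error adds $4\sigma^2$ to every lag of a 2D
MSD; the apparent coefficient is slope/4. Negative fitted slopes are
clamped to zero and flagged rather than propagated. Fits are
per-trajectory and conditions are summarized by the median with a
percentile bootstrap over tracks, following the per-trajectory reading
of the method description. Tracks shorter than 10 frames are skipped.

## Viability

Colony counts over cells plated (300 by default), normalized to a
reference timepoint. The reference is configurable because the source
protocol states 2 h in the methods while one figure legend states 0 h;
the default is 2 h and the tests exercise both.

## The synthetic-data generator

All five modalities derive from one latent ESR-strength trajectory
$s(t) \in [0, 1]$ (default $1 - e^{-t/3}$, strictly rising and
near-saturated by 9 h):

| quantity | coupling | default |
|---|---|---|
| iESR / rESR transcripts | $\times\, f^{\pm s(t)}$ | fold shift $f = 4$ |
| ribosomal mass fraction | $f_0 (1 - k\, s(t))$ | $f_0 = 0.2$, $k = 0.5$ |
| GEM diffusivity | $D_0 (1 + \rho\, s(t))$ | $D_0 = 0.3$ µm²/s, $\rho = 0.5$ |
| survival probability | $1 - \delta\, s(t)$ | $\delta = 0.5$ |
| mean volume | capped exponential | $v_0 = 60$ fL, plateau 800 fL, $T_d = 90$ min |

The couplings are multiplicative and monotone — the simplest family
consistent with the correlational claims being modeled ("ESR strength
correlates strongly with cell size"); no quantitative form for that link
is available, so the coupling function is a documented modeling choice,
not an inferred one. Defaults reflect a G1-type arrest: an 800-fL
plateau, a log-phase ribosome fraction near 20% halving over the arrest,
a WT-like tracer diffusivity of 0.3 µm²/s rising as the cytoplasm
dilutes, and viability staying above 50% at 9 h.

Per modality: expression baselines are log-normal (heavy-tailed like
real TPM) with multiplicative log-normal noise and TPM renormalization
after shifting; TMT protein weights are normalized within the ribosomal
and non-ribosomal groups so the group mass fractions are exact by
construction, with mean-one multiplicative noise (CV 0.05 by default) on
peptides and a configurable fraction of rows drawn to fail the quality
filters; volumes are log-normal populations (CV 0.2, the typical width
of a yeast Coulter histogram) binned uniformly; trajectories are 2D
Brownian walks with per-axis step SD $\sqrt{2 D\, dt}$, optional static
localization noise, and optional dropout truncation; viability counts
are binomial draws (or rounded expectations in deterministic mode).
Every generator call uses a single RNG stream derived from the scenario
seed plus a per-modality offset, so modalities are independent and the
whole bundle is bit-reproducible.

What the generator does **not** emulate: sequencing reads or count
overdispersion (values are TPM-level), peptide-level missingness and
isotopic impurity structure, Coulter debris and doublet tails, confined
or anomalous diffusion, and mother/daughter demixing in stationary
populations. Passing recovery tests therefore demonstrates correctness
of the estimators under the stated model, not robustness to every
artifact of real data.

## The pipeline

`run_pipeline()` takes a sample sheet (one row per sample with paths to
each modality's file) and a configuration list holding every threshold
in one place (`default_pipeline_config()`). Stages run isolated: a
corrupt file fails only its own columns, the error is recorded in the
report and the manifest, and the joined cross-modality table keeps
explicit `NA`s. The join is an outer join on condition × timepoint with
exactly one row per pair. A JSON manifest (package version, full
configuration, sample sheet, per-stage errors) makes a run reproducible;
rerunning the same sheet and configuration rewrites every stage table
byte-identically because all bootstraps are explicitly seeded.

```{r example, eval = FALSE}
sc <- arrest_scenario("G1-arrest", seed = 1L)
paths <- write_scenario_data(sc, "scenario_data")
report <- run_pipeline(scenario_sample_sheet(sc, paths),
                       config = list(tmt_reference_channel = "1h"))
report$cross_modality
```

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to make
estimator variability small relative to the assertion tolerances while
staying desk-scale: 2,000-gene universes with the canonical 300/600 ESR
split, 150–200 protein proteomes with at least 3 peptides per protein
(so every protein can pass the eligibility gate), $10^4$-cell
histograms over 120 uniform bins, and 300–1,000 tracks of 400 frames at
100 fps. Exhaustive ssGSEA oracle comparisons cover every subset of
universes up to 12 genes; at `alpha = 0` the oracle accumulates the walk
in integer arithmetic, so the comparison is against the exactly rounded
rational value. Degenerate inputs are rejected rather than repaired:
double log-transforms, overlapping gene sets, all-zero channels,
non-increasing bins, tracks shorter than two frames.

## Known limitations

The half-max volume rule is a mode-region statistic, not the population
mean; on skewed populations it sits below the arithmetic mean by design,
which is why recovery is asserted against the analytic mode-region
target. The biochemical ribosome readout only reflects assembled 80S
particles. The short-lag D fit assumes the MSD is linear below 100 ms;
subdiffusive tracers would need an anomalous-exponent model that is out
of scope here. The ESR–size correlation is reported with a bootstrap CI
but no significance machinery, matching the descriptive use of the
correlation in arrest studies.
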