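---
title: "Models and methods for single-neuron copy-number mosaicism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for single-neuron copy-number mosaicism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuromosaic)
```

# Scope

`neuromosaic` quantifies somatic genomic mosaicism in single neuronal
nuclei from four assay families: single-nucleus qPCR with
confidence-interval copy-number calling, flow-cytometry DNA-content
variation (DCV), FISH aneusomy counting, and PNA-FISH puncta
quantification. This vignette explains each model, its assumptions and
tunable parameters, the synthetic-data generators used for validation, and
the numerical and design choices that were genuinely open.

# Relative copy number from ΔΔCt

The quantification chain is `summarize_ct()` → `delta_ct()` →
calibration → `rcn_point_and_ci()`, wrapped by `rcn_table()`.

The point estimate is $\mathrm{RCN} = 2\,(1+E)^{-\Delta\Delta C_t}$, with
amplification efficiency $E = 10^{-1/\text{slope}} - 1$ estimated by
`fit_standard_curve()` from a dilution series (at least three levels;
negative slope required; curves with $R^2 \le 0.99$ are flagged unusable
and excluded from quantification). $\Delta C_t$ is the difference of
replicate-mean Cts between the target and reference assay for a nucleus;
$\Delta\Delta C_t$ subtracts the mean $\Delta C_t$ of the calibrator
nuclei — all nuclei of the same brain in the calibrator region, the
cerebellum by default, following the paired-cerebellum design. A diploid
nucleus therefore normalizes to RCN 2.00 by construction.

Replicates are aggregated by a plain arithmetic mean with no outlier
rejection by default; an optional MAD filter (`mad_filter = TRUE`,
threshold 3 scaled MADs) is available but off, because the default
reflects how the assay is normally analyzed. The QC rule is a minimum of
10 replicates per nucleus/assay pair (nominal design: 18 = 3 sample loads
× 6 assay replicates); failing pairs are dropped with a message, or kept
flagged via `drop_failed = FALSE`.

**Efficiency convention.** The quantification formula uses a single
efficiency — the target assay's — which assumes the reference assay
amplifies at a similar efficiency; measured TaqMan efficiencies in this
system cluster tightly around 1 (≈0.99–1.04), making the approximation
mild. For assay pairs where that fails, `method = "ratio"` uses each
assay's own efficiency,
$\mathrm{RCN} = 2\,(1+E_t)^{-\Delta\Delta C_t^{(t)}}(1+E_r)^{+\Delta\Delta C_t^{(r)}}$,
which reduces exactly to the single-efficiency form when $E_t = E_r$ (a
tested identity). The single-efficiency form is the default because it is
the field-standard calculation.

# The confidence-interval caller

The CI half-width on the $\Delta\Delta C_t$ scale is
$\mathrm{CI} = t_{1-\alpha/2}(\nu)\,\sigma/\sqrt{n}$ with system SD
$\sigma = 0.25$ cycles, $n = 18$ replicates, $\nu = 68$ degrees of
freedom, $\alpha = 0.05$ — all exposed as parameters with these defaults.
The modeled acceptance interval for integer copy number $k$ is
$[k\,2^{-\mathrm{CI}},\; k\,2^{+\mathrm{CI}}]$ (`build_bounds_table()`);
intervals scale multiplicatively in $k$, are pairwise disjoint through
$k = 6$, and first overlap at 6 vs 7 — which is why calls are binned 1–6
and ">6", and why states beyond six copies are reported only as "more
than six".

```{r bounds}
build_bounds_table(t_mode = "rounded2")
```

**The critical value.** The default `t_mode = "exact"` uses the Student-t
quantile ($t_{0.975}(68) = 1.9955$). The published reference table for
these bounds is consistent with the critical value rounded to 2.000, so
`t_mode = "rounded2"` reproduces that table to all five printed decimals;
the exact quantile agrees to within $2\times10^{-4}$ relative. Both are
kept because the rounded mode documents provenance of the reference
bounds while the exact mode is statistically cleaner.

**Degrees of freedom.** $\nu = 68$ is the system's stated value; a
nominal 18-replicate design alone would give 17, so 68 presumably pools
variance information across assays and runs. It is a parameter
(`df`), defaulting to the stated 68.

**Decision rule** (`call_copy_number()`): collect every modeled interval
the estimate's CI intersects. Exactly one → that bin. Several → the
nearest $k$ on the log2 scale, flagged `ambiguous` (the log2 metric
matches the multiplicative error structure of qPCR; flagging rather than
dropping preserves the nucleus for sensitivity analyses). None → ">6"
when the CI lies beyond the last interval (by CI lower bound by default;
`gt6_rule = "point"` uses the point estimate — with symmetric CIs the two
agree, but both are kept for asymmetric estimates), otherwise the nearest
$k$ with a `gap_assigned` flag. RCN below the CN-1 interval calls bin 1
with the gap flag: bins start at 1, and a sub-1 state is not separable
from measurement error at these settings. A brute-force interval-scan
oracle in the test suite verifies the rule on 10,000 random estimates.

Dual-assay concordance (`exon_concordance()`) counts units whose bins
agree within one call, treating ">6" as 7 for distance, and among
more-distant pairs counts those where both assays still call a gain
(both bins above 2) — discordant in magnitude but concordant in
direction.

# DCV flow-cytometry analysis

`detect_g0g1_peak()` locates the 2N peak as the mode of a kernel-density
estimate (Silverman bandwidth, 1024-point grid) and summarizes events in
a symmetric relative gate `mode × (1 ± w)` with $w = 0.25$ by default —
wide enough to cover a CV-8% peak, narrow enough to exclude the 4N
position at twice the mode. Two density modes within 10% of each other
are treated as genuine ambiguity only when separated by more than 15% in
intensity (adjacent KDE wiggle on a single peak is not multimodality);
the lower-intensity mode then wins, since the diploid peak sits lowest,
with a warning. CV is the arithmetic $100\,\mathrm{sd}/\mathrm{mean}$ of
the gated events (a robust variant of the commercial CV statistic exists;
the arithmetic form is the default and only implemented variant). Skew is
$(\text{mean}-\text{mode})/\text{sd}$. Degenerate constant input yields
CV 0 and undefined (NA) skew.

The DNA index divides the sample's CEN-normalized 2N peak mean by the
reference's: gain invariance is exact because a common per-tube gain
cancels in the ratio, and the peak *mean* (not median) is used as stated
for this assay. CEN events are identified by the `species_tag` column, or
as the lowest-intensity substantial density mode when untagged. NeuN
gating thresholds at the 99.9th percentile of an unlabeled control —
chosen so essentially no control event is called positive while keeping
the threshold inside the observed control range; the quantile is a
parameter. Group inference uses `aov()` + `TukeyHSD()`, paired t-tests
when a pairing column is given, and simple linear regressions for
covariates (age, PMI, Braak), with NA reported when within-group variance
is degenerate.

`hypersomy_percent_gain()` provides the interpretive yardstick: one extra
copy of a ~250 Mb chromosome against half of a tetraploid 12,800 Mb
content is a 3.9% gain, the largest DNA increase a single whole-chromosome
aneusomy could explain.

# FISH and PNA quantification

`aneusomy_rates()` validates that class counts sum to `n_nuclei` per row,
converts to fractions, and averages *rates* (not counts) across
observers so each observer weighs equally; any number of observers is
supported, since the per-brain observer count is a protocol detail the
package should not fix. The primary group test is a per-class unpaired
t-test on per-brain rates — matching brain-level error bars — with a
pooled chi-squared as a secondary, more powerful but
pseudoreplication-prone alternative, reported side by side.

For PNA puncta, a nucleus's intensity is the maximum over its
non-excluded puncta (the aggregation is otherwise unstated; the maximum
matches detection semantics — one punctum above threshold makes the
nucleus positive). Exclusions are applied first and are idempotent and
order-independent: nuclei without telomere signal are hybridization
failures and leave the denominator; lipofuscin puncta are removed but
their nuclei remain. The `"auto"` threshold is a quantile (default: the
maximum) of negative-control intensities. Positive fraction is monotone
non-increasing in the threshold, a tested invariant. The relative
intensity normalization is left to the caller (intensities are treated
as already-extracted scalars, globally comparable); per-image
normalization would belong upstream of this package.

# Synthetic data: what it emulates and what it does not

Generators live in `sim_config()` / `simulate_*()` and emit truth tables
alongside every output; identical seed and config give byte-identical
CSVs.

The Ct forward model places all biological signal in the target gene:
reference replicates are normal around a fixed base Ct, target
replicates around
$\text{base} - \log(CN/2)/\log(1+E)$, both with SD 0.25 — the simplest
model consistent with the ΔΔCt math. Calibrator (cerebellar) nuclei are
generated at true CN 2, so calibration is unbiased by construction;
non-diploid cerebellar mixtures are available as presets for stress
testing. Default cortex mixtures were chosen once to emulate the
published cohort profiles — disease cortex mean ≈ 3.9 with ~60% of nuclei
above two copies and occasional 12-copy nuclei; control cortex mean
≈ 1.6 with ~10% above two — as an *emulation* of those profiles, not a
reproduction: the study's actual group values depend on per-nucleus
source data not redistributed here.

Flow samples are four-component mixtures (main peak at
$100 \times DI$ with CV 5%, optional right shoulder at +20%, 2% uniform
debris, tagged CEN peak at 35); disease-like samples draw true DI from
N(1.08, 0.05). FISH counts are per-brain/observer multinomials (defaults:
9 vs 5 brains, 500 nuclei, 2 observers, near-null class probabilities
2%/95.5%/2%/0.5%). PNA intensities are log-normal around a fixed
threshold with group exceedance fractions 0.56/0.22/0.14 and controls
just below threshold.

What passing tests show: the pipeline inverts its own forward models —
unbiased RCN recovery, ≥95% correct bin calls at the stated noise level,
DI recovery within 0.5% on clean peaks, nominal type-I error. What they
do not show: robustness to real-data pathologies the generators omit —
PCR inhibitors and allelic dropout, cell-cycle S/G2 populations and
spillover in flow histograms, observer bias in FISH scoring, or spatially
varying image background in PNA intensities.

# Problem sizes and numerical choices

Validation simulations are sized for tight-but-fast inference: 600 nuclei
(100 per true copy number) for bin-call recovery; 2,000 replicates for
type-I error of the group tests (standard error ≈ 0.5 percentage points
at the 5% level); 8,000 events per flow sample. Ties in the caller are
broken on the log2 scale; CI bounds are ordered by construction
(`pmin`/`pmax`) rather than by a sign convention on the exponent, so the
bracketing invariant `ci_low ≤ rcn ≤ ci_high` holds for any efficiency.
Calibrator-free units, sub-minimum replicate pairs, and zero-variance
groups all degrade to explicit drops, flags, or NA rather than silent
propagation.

# Known limitations

- Copy states above six are reported only as ">6"; the CI model cannot
  separate them at SD 0.25 / n 18.
- The DCV stage does not fit cell-cycle models; S/G2 events inflate CV
  and skew if the gate is widened.
- The FISH stage analyzes counts, not images; the PNA stage analyzes
  extracted intensities, not segmentations.
- Single-nucleus mode drops a nucleus whose reference assay fails QC
  rather than borrowing a plate-level reference Ct; with the default
  design this is rare but costs data when reference reactions fail
  systematically.
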