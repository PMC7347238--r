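---
title: "Quantifying repeat instability from fragment-analysis profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying repeat instability from fragment-analysis profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repex)
```

## The measurement problem

Long CGG-repeat alleles (the fragile X locus class, here ~280 repeats in
mouse embryonic stem cells) expand progressively with time in culture.
Because expansion events are frequent and each adds only one or two repeats,
the whole cell population drifts upward "in concert": a bulk PCR over the
repeat followed by high-resolution capillary electrophoresis yields a peak
profile whose tallest peak — the *modal allele* — creeps rightward, flanked
by stutter shoulders. `repex` turns such profiles into three quantitative
readouts:

1. the modal allele and its gain between time points (Δ repeats);
2. the **Expansion Index (EI)**, a height-weighted mean repeat displacement
   that detects sub-modal shifts the modal call cannot resolve;
3. an expansion **rate** (repeats/day) from an ordinary least-squares fit of
   repeats added against days in culture.

A fourth, orthogonal readout comes from **small-pool PCR** (SP-PCR): PCR at
limiting template dilution, so individual molecules are sized and rare allele
classes are seen that bulk PCR underrepresents.

## From peak table to repeat profile

Genotyping software exports one row per called peak, `(size in bp, height in
RFU)`. `read_peak_table()` accepts comma- or tab-delimited files with a
one-line header naming a size and a height column; rows are sorted by size
and any malformed row aborts the read with its row number. Sizes become
repeat numbers through a `calibration_model()`:

\[ r = \mathrm{round}\left(\frac{\text{size} - \text{flank}}{\text{unit}}\right), \]

with unit 3 bp for CGG and rounding half away from zero (a fixed, documented
rule, immune to platform rounding modes). The flank — the non-repeat portion
of the amplicon — is **never guessed**: assay designs differ and no universal
value exists, so it must be supplied directly or solved from an *anchor*
sample of known repeat number (typically the day-0 line whose repeat count
was established independently). `bin_to_profile()` then sums heights of peaks
mapping to the same repeat number; total height is conserved and zero-height
bins are dropped.

## The Expansion Index

Given a profile with bins \((r_i, h_i)\), a reference repeat \(r_{\mathrm{ref}}\),
and a threshold fraction \(\theta\) (default 0.10):

* peaks with \(h_i \ge \theta \max_j h_j\) are retained;
* under the default `modal_and_above` window, the retained set is further
  restricted to \(r_i \ge r_{\mathrm{modal}}\) — the window runs from the
  tallest peak to the largest above-threshold allele;
* retained heights are normalized to weights \(w_i\), and
  \(EI = \sum_i w_i\,(r_i - r_{\mathrm{ref}})\).

EI is invariant under uniform height scaling, zero for a single-allele
profile referenced to itself, and non-negative when referenced to the
profile's own modal allele under the default window.

Three design points were genuinely open and are resolved as follows.

**Threshold.** Published peak-profile instability indices use a relative peak
threshold but rarely state the value; 0.10 of the tallest peak is the package
default, is configurable everywhere, and is echoed in every result object so
reports are self-describing.

**Reference policy.** The default reference is the modal allele of the same
line's earliest (day-0) sample, held fixed across later days — the "red
dotted line" baseline of bulk-profile figures, which makes ΔEI a pure
displacement measure. A `fixed` policy accepting a user-supplied reference
(for instance a parental, pre-editing allele) is also provided, because
published day-0 EI values are sometimes slightly negative, which cannot arise
when each line is referenced to its own day-0 modal allele under a
right-sided window; the exact reference used in any given paper is therefore
ambiguous, and the package asserts neither.

**Window.** `modal_and_above` implements the strict "highest peak to largest
above-threshold allele" window. The alternative `all_above_threshold` admits
peaks left of the mode, which is the only way contraction-driven (negative)
EI shifts can be expressed; the Mlh3/Pms2-null regimes make ΔEI negative
mostly through rightward movement of the *reference* relative to a drifting
mode, and both windows are exposed so users can match either convention.

One caution on intuition: EI is a *normalized* weighted mean, so adding mass
at a larger repeat does not always increase it — new mass at a displacement
below the current EI pulls the mean down. The monotonicity that does hold,
and that the tests assert, is for rightward transfers of mass between two
included peaks that leave the inclusion set and the modal bin unchanged.

**Days beyond 52.** With fast expansion the population heterogenizes and the
modal allele becomes progressively harder to call; operations on time courses
warn (but do not fail) when samples beyond 52 days are analyzed.

## Rates and event counts

`fit_expansion_rate()` is ordinary least squares of repeats added on days
(via `stats::lm`), reporting slope (repeats/day), intercept and \(R^2\)
(defined as 1 for exactly collinear points, including flat courses);
`days_per_repeat()` is the reciprocal slope. With per-event steps bounded in
\([s_{\min}, s_{\max}]\), a net gain \(G\) brackets the number of expansion
events as \(\lceil G/s_{\max}\rceil \le N \le \lfloor G/s_{\min}\rfloor\)
(`expansion_event_bounds()`): a gain of 19 repeats with 1–2 repeat steps
implies 10–19 events per allele.

## Small-pool PCR analysis

`rank_sum_test()` compares two allele lists by the Mann–Whitney U statistic
(midranks for ties). p-values are exact for small samples: from the exact
Wilcoxon distribution when there are no ties and \(\min(n_1,n_2) \le 8\), and
by complete enumeration of all \(\binom{n_1+n_2}{n_1}\) labelings when ties
are present and \(n_1+n_2 \le 12\) (above that, enumeration is no longer
sub-second). Larger samples use the normal approximation with tie-corrected
variance and a 0.5 continuity correction; across the bulk of the null
distribution (two-sided p ≳ 0.05 at \(n_1=n_2=20\)) it tracks the exact
p-value to within 5% relative error and is conservative further into the
tail.

`classify_alleles()` operationalizes "unequivocally expanded" as strictly
greater than the largest day-0 allele (margin 0 by default; a margin widens
the tolerated band symmetrically). `estimate_molecules_per_pool()` is the
Poisson zero-class estimator \(\hat\lambda = -\ln(\text{negative
pools}/\text{pools})\), undefined (with guidance to dilute further) when no
pool is negative. `compare_timepoints()` bundles test, classification and a
per-repeat histogram; the nested-PCR artifact — a constant two-repeat left
shift of called repeat numbers — is handled as an explicit `modal_shift`
offset, never silently.

## The simulator: what it emulates, and what it does not

`simulate_population()` models each cell's allele as an independent compound
Poisson process: expansion events arrive at `expansion_rate` per cell per
day and each adds a step from `step_probs` (default +1 with probability 0.8,
+2 with 0.2, reflecting that most events add one or two repeats);
contractions are an independent process with negative steps. There is no
division, selection or death — the population is treated as expanding in
concert — and no mechanistic mismatch-repair model: genotypes differ only in
their rates.

The presets encode the observed regimes:

| preset | expansion rate (events/cell/day) | steps | contraction rate | regime emulated |
|---|---|---|---|---|
| `WT` | 0.30 | +1 (0.8), +2 (0.2) | 0 | ~18 repeats gained per 52 days |
| `Mlh3_null`, `Pms2_null` | 0 | — | 0.02 (−1) | no expansion; 0 to −2 drift |
| `Pms1_null` | 0.005 | +1 | 0 | static at 52 d, one-to-two repeat shift visible by 68 d |

The absolute per-cell event frequency is not observable from bulk profiles —
only the product (rate × mean step) is constrained by the net gain — so the
WT rate is calibrated once to rate × E[step] = 0.36 repeats/day, i.e. 18.72
expected repeats in 52 days, and exposed in the config rather than treated as
an estimate. A distributional subtlety follows from the model itself: the
*mean* per-cell gain is exactly rate × E[step] × t, but the *modal* gain is
the integer mode of the compound-Poisson pmf, which for the WT preset at 52
days is 18 — slightly below the mean of 18.72. Modal-allele readouts
therefore sit about half a repeat below the closed-form mean; this is a
property of skewed discrete distributions, not simulator error.

`render_trace()` converts an allele multiset into a stuttered profile: the
histogram is convolved with a normalized geometric kernel (weight
\(s_-^k\) at −k repeats, \(s_+^k\) at +k, k ≤ span; defaults \(s_-=0.5\),
\(s_+=0.05\), span 5 — minus stutter dominates, as in real trinucleotide
PCR), conserving total height, then optionally jittered with mean-one
lognormal noise of a given CV. For unimodal populations and \(s_- \le 0.7\)
the modal call survives stuttering; on heterogeneous late-day populations
stutter can pull the apparent mode one or two repeats left of the population
mode, mirroring real bulk-PCR behaviour.

`sample_sp_pcr()` draws Poisson(λ) molecules per pool uniformly with
replacement from the population, records zero-molecule pools as negative, and
applies the nested-PCR `modal_shift` explicitly.

What the simulator does **not** emulate: passaging bottlenecks and selection,
methylation silencing, large rare expansions/contractions (steps are capped
at 2 by default; custom step maps can widen them), inter-locus context
effects, and instrument artifacts other than geometric stutter and
multiplicative height noise. Tests passing on synthetic data therefore
demonstrate the *analysis* is correct under the stated generative model, not
that the model captures every feature of real electropherograms.

## Reproducibility and numerics

Every stochastic function takes one integer seed and restores the caller's
RNG state; identical config + seed gives bit-identical populations, traces,
SP-PCR datasets and fixture files. Profile TSVs store heights with 17
significant digits, so write → read round-trips are bit-exact. Modal-allele
ties break toward the smaller repeat (stutter inflates left shoulders, so
this is conservative against calling expansion). Exact-test cutoffs
(`min(n1,n2) ≤ 8` tie-free; `n1+n2 ≤ 12` with ties) keep every exact p-value
sub-second.

Problem sizes used in the shipped tests — populations of 4,000–10,000 cells,
5-point time courses, 40–200 simulation replicates, 500-pool dilution
experiments, exhaustive rank-sum enumeration up to n1 = n2 = 6 — were chosen
as the smallest sizes at which the Monte-Carlo standard errors are far below
the effect sizes being checked.

## Worked example

```{r example}
dir <- file.path(tempdir(), "demo")
fx <- make_fixtures(dir, seed = 1)
report <- suppressWarnings(
  run_pipeline(fx$manifest, calibration = calibration_model(3, flank_bp = 120))
)
report[, c("line", "genotype", "day", "repeat_no", "delta_repeats", "ei", "delta_ei")]

wt <- report[report$line == "WT_1", ]
fit <- fit_expansion_rate(wt$day, wt$delta_repeats)
fit
days_per_repeat(fit)

ds <- read_sppcr_table(fx$sppcr, line_id = "Mlh3_1")
compare_timepoints(ds, 0, 68)
```

## Known limitations

* Overlapping-allele deconvolution and mixed-clone demultiplexing are out of
  scope; a profile is assumed to represent one (drifting) allele population.
* Binary electropherograms (.fsa) are not parsed; analysis starts at peak
  tables.
* Calibration constants are user-supplied; there is no size-standard fitting.
* The EI window/reference conventions vary across published work; results
  should always be reported together with the threshold, window and reference
  policy used (every result object carries them).
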