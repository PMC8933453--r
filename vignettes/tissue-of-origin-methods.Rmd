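---
title: "Methods: real-time PCR tissue-of-origin testing and the three-CpG age model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: real-time PCR tissue-of-origin testing and the three-CpG age model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tissueorigin)
```

# The problem

DNA collections assembled over decades mix samples extracted from whole
blood with samples extracted from lymphoblastoid cell lines (LCLs), and
the recorded origin is often missing or stale.  Blood and LCL DNA differ
in two robust, assay-friendly ways: LCLs carry a high episomal
Epstein–Barr virus (EBV) load (on the order of 2–500 genome copies per
diploid genome) that healthy blood lacks, and blood contains T
lymphocytes whose somatically rearranged TCR-γ/TCR-β loci are absent
from B-cell-derived LCLs.  `tissueorigin` turns three qPCR readouts of
these features into a three-way call — blood, LCL, or uncertain — and
combines them by a two-of-three vote.

# Signal models and calling

## Amplification curves and the Ct caller

Simulated amplification follows a saturating exponential model: starting
from $N$ template copies with per-cycle efficiency $E \in (1, 2]$, the
product approaches the reaction's half-saturation copy number $K$, so
noiseless fluorescence is logistic in cycle number,

$$F(c) = b + P\,\sigma\{\log E\,(c - c_0)\}, \qquad c_0 = \log_E(K/N),$$

with baseline $b$, plateau $P$ and $\sigma$ the standard logistic.
Multiplying the template by $f$ shifts $c_0$ by exactly $-\log_E f$,
which is the arithmetic the GAPDH-normalised ratios rely on.  The default
$K = 1.5\times10^{12}$ places a 10 ng genomic input (about 6000
single-copy targets) near Ct 26, a typical instrument value.

The quantification cycle is the **second-derivative maximum** (SDM) of
the curve — threshold-free and scale-invariant.  For a logistic the SDM
sits at $c_0 - \ln(2+\sqrt3)/k$ with $k = \log E$.  The caller fits the
4-parameter logistic by Levenberg–Marquardt least squares (initialised
from the discrete second difference of a Savitzky–Golay-smoothed copy of
the trace) and evaluates this closed form at the fitted parameters.  We
initially implemented the textbook alternative — smooth, difference
twice, refine the discrete maximum by local quadratic interpolation —
but on curves this steep ($k \approx 0.69$ at perfect efficiency) no
smoothing window satisfies both accuracy requirements at once: windows
narrow enough to keep the noiseless call within ±0.3 cycles of the
analytic SDM let percent-level fluorescence noise move calls by more
than a cycle, and windows wide enough to tame the noise bias the
noiseless call by up to two cycles.  Fitting the whole sigmoid, as
established qPCR software does for SDM quantification, uses all 50
points and achieves both (the test suite asserts noiseless agreement
with the closed form and a 95th-percentile spread ≤ 0.2 cycles at 1%
noise).  The discrete second-difference path is kept as initialisation
and as a fallback if the fit fails; there, an exactly tied discrete
maximum resolves to the earlier cycle.

A reaction is declared non-amplified when its smoothed rise amplitude is
below `min_amplitude` (default 0.5, i.e. 5% of the default plateau) or
when no positive curvature maximum lies before cycle $C-3$ — the second
clause rejects late drift that a pure amplitude criterion would accept.
The instrument's own criterion is not public; this stand-in is explicit
and configurable.

## Melting curves and Tm extraction

Each double-stranded product contributes a two-state melt transition —
a logistic drop of width 0.35 °C centred at its $T_m$ — weighted by its
fraction, on a gently decaying background, over the standard 65→95 °C
ramp at 0.2 °C per acquisition.  Peaks are the local maxima of $-dF/dT$
computed by central differences on a Savitzky–Golay-smoothed curve
(window 9, order 2), kept if their topographic prominence reaches
`min_prominence`, and refined by local quadratic interpolation (recovery
within one 0.2 °C step on noiseless curves, asserted against a
dense-grid oracle).  The default prominence of 0.5 was chosen from the
two sides of the decision: the faintest real product we simulate (a
~10% primer-dimer fraction) yields a derivative peak near 0.7 after
smoothing, while 0.5% fluorescence noise produces spurious prominences
up to about 0.5 — an important guard, because a noise peak at high
temperature would otherwise read as a specific TCR-β product and flip an
LCL sample's vote toward blood.

# Classification

Scores are GAPDH-normalised Ct ratios on a ×100 scale,
$100\,\mathrm{Ct}_{GAPDH}/\mathrm{Ct}_{target}$: GAPDH sits in the
numerator so that an *absent* target (late or imputed Ct) deflates the
ratio and an abundant one inflates it.  No-amplification reactions are
imputed at Ct 40 (EBV) and Ct 45 (TCR-γ) so the ratios stay computable.
The decision rules, with defaults:

| assay | blood | LCL | abstain |
|---|---|---|---|
| EBV ratio | < 91 | > 110 | [91, 110] |
| TCR-γ ratio | > 80 | < 70 | [70, 80] |
| TCR-β max Tm | > 89.5 °C | ≤ 89.5 °C or no peak | — |

The EBV pair and the Tm cutoff are the panel's published operating
points.  No operating point is published for TCR-γ; the 70/80 defaults
were placed inside the gap the generator produces (LCL ratios near 58
with the imputed Ct 45, blood ratios above ~83) and
`calibrate_tcrg_thresholds()` refits them from any labelled cohort by
maximising two-way accuracy and centring an abstention band in the
empirical class gap.  Ties are resolved explicitly: a ratio exactly at
either threshold abstains; a Tm exactly at the cutoff is LCL ("over" is
read strictly).  The combined rule calls blood on at least two blood
votes; symmetrically, two LCL votes call LCL, and every other pattern —
including one blood vote against discordant tests — stays uncertain.
The symmetric LCL clause is an interpretation (only the blood rule is
stated for the published panel), adopted because the combined outcome is
reported three-way; it is exercised by the brute-force enumeration of
all 27 vote triples in the tests.  Samples failing the GAPDH control are
unclassifiable and reported as such rather than silently dropped.

Performance metrics use the convention *blood = positive, LCL and
uncertain = negative*; an abstention on a true blood sample costs
sensitivity, an abstention on an LCL sample is a correct negative.
Percentages display to 1 decimal and accuracy to 3 (full precision is
always carried alongside), and zero-denominator metrics are reported as
`NA` rather than 0 — small cohorts do hit them.

# The age model

`predict_age()` is the fixed affine three-CpG clock
$-20.372 + 0.830\,E + 1.723\,K + 0.715\,T$ on percent methylation at
ELOVL2 CpG 5, KLF14 CpG 2 and TRIM59 CpG 5.  Coefficients are never
refitted and predictions are never clamped: deviations, including
impossible ages, are the readout of a disturbed methylome.  Evaluation
reports MAD — read as the *mean* absolute deviation of predicted from
chronological age, the reading consistent with its use alongside a
Pearson correlation, though a median-based reading is conceivable — and
Pearson R between predicted and chronological age, per tissue group,
with R undefined below two samples or at zero variance.

# What the synthetic generator emulates — and what it does not

The generator is the package's study population: every sample carries
ground truth (tissue, input genomes, EBV copies/genome, T-cell fraction,
age, passage effect) from which the raw signals are rendered.

* **Template arithmetic.** GAPDH templates = 2 per diploid genome; EBV
  templates = genomes × EBV copies/genome (log-uniform on [2, 500] in
  LCLs; 90% of blood has none — exercising the imputation path — and
  10% trace loads below 0.01); TCR-γ templates = genomes × T-cell
  fraction (uniform on [0.05, 0.4] in blood, exactly 0 in LCLs).
* **Melts.** Blood: one specific product drawn on [90, 91.5] °C plus an
  optional primer dimer; LCL: only primer-dimer/non-specific peaks below
  89.5 °C.
* **Methylation.** The clock maps three methylation values to one age,
  so its inverse is under-determined; the generator fixes one loading
  direction (ELOVL2-dominated, normalised so predicted age advances one
  year per year) and a baseline whose prediction at age 0 is exactly 0.
  Blood methylation is this inverse plus per-CpG Gaussian noise
  (default sd 2.6 percentage points, which propagates through the
  coefficients to roughly 4 years of age error); LCL methylation is
  mixed with an age-independent draw (decorrelation weight 0.8) and
  shifted by a per-sample passage effect (uniform 2–8 points per CpG).
  This makes the round-trip exactly testable at zero noise while
  reproducing the qualitative blood/LCL contrast.
* **Noise.** Fluorescence noise 0.5% of the plateau on every curve and
  a 0.15-cycle Ct jitter applied as a lognormal factor on effective
  template copies.  Donor ages are uniform on [19, 79] years; input is
  ~3000 diploid genomes (10 ng) with 5% CV.

Randomness derives from one seed through four per-stage streams (truth,
amplification, melts, methylation) via a Lehmer-LCG step, so identical
configurations reproduce identical cohorts byte for byte.

The generator deliberately does **not** model technical replicates,
plate or position effects, pyrosequencing peak heights, bisulfite
conversion error, EBV-positive blood from active infection, chimerism or
tissue mixtures, or inter-assay efficiency differences.  Passing tests
therefore demonstrate that the calling, classification and evaluation
machinery is correct under the assay panel's intended signal structure
— clean bimodal separation — not that the published operating points
would achieve the same performance on any real cohort; real LCL/blood
distributions near the thresholds are exactly what the abstention class
exists for.

# Problem sizes and reproducibility

The test suite runs cohorts of up to 500 + 500 samples (the size used
for the separation and no-false-positive properties) and 100-seed noise
ensembles for the Ct robustness bound; `scripts/acceptance.R` simulates
a 500 + 500 cohort from a caller-supplied seed and recomputes every
reported metric from the raw curves at run time.  These sizes give
binomial sampling error well below the asserted margins while keeping a
full run in the order of a minute on one CPU.

# Known limitations

* The classifier is strictly two-tissue; other tissues, mixtures and
  chimerism are out of scope.
* Absolute quantification (standard curves, efficiency estimation from
  dilution series) is not implemented; ratios assume the assays share
  the configured efficiency.
* The TCR-γ operating point ships as a synthetic-data calibration and
  should be recalibrated on labelled reference DNA before use on real
  measurements.
* The no-amplification criterion is a documented stand-in for an
  unpublished instrument rule.
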