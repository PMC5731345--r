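---
title: "Characterizing genetic circuits from strand-specific RNA-seq profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing genetic circuits from strand-specific RNA-seq profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

A transcriptional logic circuit encodes its state in RNA-polymerase (RNAP)
fluxes: each gate's input and output are promoters, and the signal between
gates is the rate at which polymerases stream past a position. A fluorescent
reporter reads out only the final output; strand-specific RNA-seq reads out
every position of the circuit at once. `circuitseq` turns fragment
alignments into per-nucleotide *transcription profiles* and interprets
localized changes in those profiles through small biophysical models to
quantify every promoter, terminator, ribozyme insulator, sensor and gate in
the context of the running circuit.

## The steady-state flux model

The profile value `M(x)` is the number of sequenced fragments covering
nucleotide `x`, a relative proxy (arbitrary units, au) for the steady-state
transcript count over that position. With a single degradation rate
`gamma` for all circuit transcripts,

```
dM(x)/dt = J(x) - gamma * M(x)
```

so at steady state the RNAP flux is `J(x) = gamma * M(x)`. The default
`gamma = 0.0067 s^-1` is the literature value for bacterial mRNA and is only
a units conversion between profile height and flux; ratios of fluxes are
independent of it.

Part metrics are windowed differences and ratios of `M`:

* **Promoter activity** `delta_J = (gamma/n) * (sum of M over the n nt just
  downstream - sum over the n nt just upstream)`, with `n = 10` nt by
  default. The upstream window subtracts whatever flux enters from upstream,
  so only flux originating at the promoter is counted. When the promoter is
  insulated by a self-cleaving ribozyme, the cleaved 5' RNA is lost during
  library preparation and the profile rise appears at the cleavage site;
  the downstream window therefore moves just past the annotated cut site
  while the background window stays just upstream of the promoter part.
  (Placing both windows at the cut would measure `p_c * delta_J`, biased low
  for imperfect ribozymes.) Tandem promoters feeding one ribozyme cannot be
  separated by any window placement and are measured as one combined part.
* **Terminator strength** `Ts` is the fold drop across the part: mean `M`
  over the `n` nt before the part divided by the mean over the `n` nt after
  it; the read-through fraction is about `1/Ts`. We orient the ratio so that
  a functional terminator gives `Ts >> 1`, matching the verbal definition
  ("fold decrease") and the convention of terminator part libraries.
* **Ribozyme cleavage efficiency**
  `p_c = 1 - (J_before_cut - J_bg) / (J_after_cut - J_bg)`, clamped to
  [0, 1], where `J_bg` is the background measured upstream of the first
  promoter driving the ribozyme. Coverage upstream of the cut comes only
  from the uncleaved fraction of transcripts, which is what this estimator
  inverts. It is a reconstruction validated against the package's own
  simulator (see Limitations).
* **Low-flux filter**: terminator and ribozyme measurements are flagged
  rather than reported when the flux entering the terminator or leaving the
  ribozyme is below `min_flux_filter = 1 au/s`; a part fed by almost
  nothing cannot be quantified reliably.

## Correcting transcript-end curvature

Counting covering fragments under-represents the first and last few hundred
nucleotides of every transcription unit: a fragment of length `L` can only
cover position `x` (distance `x` from the unit end) from `min(x, L)` of its
`N - L + 1` valid placements. Since parts live exactly at transcript ends,
this curvature must be removed before measuring them.

The correction uses the empirical fragment-length distribution as its only
input. Fragment lengths are drawn (default `1e6` draws, seeded) and placed
uniformly at random inside a hypothetical 2000-nt unit; the resulting
profile `T(x)`, restricted to its first 500 nt and normalized by its
maximum, is the correction factor `C(x)`. Within each annotated unit,
positions at distance `x_n <= 500` from the nearest end are divided by
`C(x_n)`; the interior and everything outside annotated units are untouched.
The closed form `min(x, L, N - x + 1, N - L + 1)` serves as an independent
oracle for the Monte Carlo in the tests. Units shorter than 1000 nt use the
distance to the *nearest* end, so each position is divided exactly once.
The unit-local profile is rebuilt from fragments falling entirely within
the unit before correcting, and the uncorrected global profile is retained
for read-through and antisense analysis, where the correction does not
apply.

Two numerical points. First, `C(x_n) = 0` (possible at insufficient
Monte-Carlo depth) raises an error rather than producing infinities.
Second, when tests compare the Monte-Carlo profile to the closed form, both
curves are normalized by their plateau mean rather than their maximum: the
maximum of hundreds of noisy values is biased upward by about half a
percent, which would leak into every position of the comparison.

## Between-sample normalization

Sequencing yields relative abundances, so between-sample comparison needs
scaling factors. `tmm_factors()` computes trimmed-mean-of-M-values factors
via edgeR (trim 30% on log-ratios, 5% on intensities, precision weighting)
and reports the *overall* scaling — compositional factor times library
size, centered to geometric mean 1 — so a sample with uniformly doubled
counts gets factors `(2^-1/2, 2^1/2)` against its partner. FPKM uses the
effective library size implied by these factors (factor times the
geometric-mean library size), which reproduces the standard
`lib.size x norm.factor` convention up to a common constant, so FPKM is
invariant to duplicating every fragment of a sample. Profiles are divided
by `factor x library_size / 1e6`, the same convention, making profile
heights comparable across states. Gene expression in profile units is the
mean corrected profile height over the gene.

## Devices: sensors, gates, series deconvolution

A sensor's response is the mean activity of its output promoter over states
with and without its inducer (`dJ_on`, `dJ_off`). A NOT gate's response is
a repressing Hill function of total input flux

```
dJ_out = dJ_min + (dJ_max - dJ_min) * K^n / (K^n + J_in^n)
```

and NOR gates are fitted as NOT gates on the summed input flux
`J_in = dJ_in,1 + dJ_in,2 + J_0`, with `J_0` the read-through entering from
upstream. Fitting minimizes the log-scale least squares error over the four
parameters with bounds `dJ_min > 0`, `dJ_max > dJ_min`, `K > 0`,
`n in (0.1, 8]`, from a small grid of starts (`K` at the input-flux
quartiles, `n in {1, 2, 4}`), using constrained L-BFGS-B; ties prefer the
smaller cooperativity. Measured activities at or below `1e-2 au/s` are
floored before logging, since off states can measure exactly zero.

When two output promoters sit in series behind one ribozyme, only their
combined activity is measurable per state, and the adapted error compares
the measured sum to the sum of the two devices' expected activities. One
structural fact deserves emphasis: that error depends on the data only
through per-state *sums*, and shifting a constant activity from one
device's levels to the other's (off and on together for a sensor; `dJ_min`
and `dJ_max` together for a gate) changes no sum. The individual levels are
therefore identifiable only up to this shift — for two sensors observed in
all four inducer combinations, four unknowns face a rank-3 design. The
package pins this gauge deterministically: device 1's lowest level is
pushed to its lower bound, attributing the shared baseline to device 2.
Differences (`dJ_on - dJ_off`, `dJ_max - dJ_min`) and the gate threshold
and cooperativity are gauge-invariant and should be preferred when
comparing devices. Splitting a combined activity into per-promoter
estimates uses fractional contributions of the expected activities, so the
estimates always sum exactly to the measurement.

With eight states and 10% multiplicative noise on the measured activities,
the sampling spread of the fitted `K` and `n` is itself on the order of
10-25%; users should treat single-experiment Hill parameters as estimates
with that precision, which mirrors the large replicate spreads typical of
in-context part characterization.

## Predicted profiles and the RPU conversion

Design tools report promoter strengths in relative promoter units (RPU).
A zero-intercept regression of measured output-gene profile height on
reported RPU gives the conversion (proportionality is what "conversion
factor" means; an intercept option exists for diagnostics). Predicted
profiles are traced 5' to 3': at each transcription start site the height
rises by the predicted strength times `(1 - p_c)` of the next downstream
ribozyme; at a ribozyme cut site the height is set to the combined strength
of the promoter group driving it plus the read-through entering that group;
past each terminator the height is multiplied by `1/Ts`. The result is
piecewise constant with change points only at TSSs, cut sites and
terminator ends. Read-through entering the circuit's 5' end defaults to 0
au unless configured.

## The forward simulator

`simulate_experiment()` generates complete, seeded multi-state experiments:
per state it applies optional lognormal noise to the promoter activities,
traces the expected profiles `M(x) = J(x)/gamma` with exactly the
prediction-module rules (antisense promoters are traced 3' to 5' on the
minus strand), and samples fragments. Sampling decomposes the expected
profile into constant-plateau segments; each fragment draws a length from
the configured distribution, then a segment with probability proportional
to abundance times the number of valid start positions, then a uniform
start. Weighting by valid starts (rather than raw segment length) makes the
expected interior coverage exactly proportional to segment abundance for
every segment length, which is the statistical structure the
characterization math assumes; the end curvature is identical either way.
Lengths that fit no segment of the profile raise an error; segments shorter
than part of the length distribution restrict to the lengths that fit,
renormalized.

The simulator emulates: plateau-exact steady-state abundance, ribozyme
cleavage (cleaved 5' fragments are simply never emitted, as they are lost
during real library preparation), terminator read-through, antisense
transcription, strand-specific sampling, multi-state (eight-combination)
designs, and the end curvature the correction removes. It does not emulate:
fragments spanning transcription-unit boundaries (read-through transcripts
in real data produce fragments across terminators, which makes real
downstream windows somewhat cleaner than simulated ones), sequence-dependent
fragmentation bias, RNAP traffic or bursting, host-genome background
transcription, or replicate-to-replicate biological variability beyond the
activity-level noise model. Passing recovery tests therefore demonstrate
correctness of the estimators under the model's own assumptions, not
robustness to every real-data artifact.

Because sequencing is relative, recovering absolute activities (au/s) from
sampled fragments requires one calibration constant; the recovery path
calibrates the corrected coverage against a single designated reference
gene (by default the circuit's output gene), mirroring the
reporter-based RPU conversion that anchors the au scale in real
experiments. Terminator strengths and cleavage efficiencies are ratios and
need no calibration.

## Conventions, problem sizes, defaults

* Coordinates are 1-based inclusive everywhere inside the package (the
  GFF/GRanges convention); BED input (0-based half-open) is converted at
  the boundary. SAM flag pairs 83/163 mark sense and 99/147 antisense
  fragments under the reverse-stranded library convention; BED strand is
  interpreted through the `library_orientation` setting (`reverse` by
  default).
* Gene counting is union-mode on the matching strand: a fragment
  overlapping exactly one gene counts for it; two or more, for none;
  fragments under the mapping-quality cutoff (default 10) are excluded when
  a quality is present.
* Default analysis settings: `gamma = 0.0067 s^-1`, window `n = 10` nt,
  low-flux filter `1 au/s`, correction window 500 nt on a 2000-nt
  hypothetical unit, `1e6` Monte-Carlo draws with the seed recorded in run
  metadata.
* The validation suite exercises recovery on a five-part circuit at `1e6`
  fragments per state (three seeds), end-correction oracle equivalence at
  `1e6` draws, flat-profile restoration at `1e5` fragments, and 100 seeded
  noisy gate fits; the bundled 46-part example circuit covers annotation,
  tracing and pipeline smoke paths at lighter depth.

```{r example}
library(circuitseq)

ann <- example_circuit_annotation()
truth <- example_circuit_truth()
fl <- fld(c(80L, 100L, 120L), c(0.25, 0.5, 0.25))
exper <- simulate_experiment(ann, truth, names(truth$promoter_activities),
                             fl, depth = 1e5, seed = 1)
prof <- exper$profiles[["+/+/-"]]
measure_parts(prof$sense, ann, analysis_config(), "+/+/-", prof$antisense)
```

## Known limitations

* The ribozyme-efficiency estimator is a documented reconstruction; the
  original model it stands in for is not public, and the estimator is
  validated only against this package's simulator.
* Apparent terminator strengths saturate near the inverse of the
  measurable read-through floor: with a downstream window near zero
  coverage, `Ts` is reported as `+Inf` with a flag rather than a number.
  Deep-corrected window estimates near transcript ends divide small counts
  by small correction factors; their variance is the dominant noise term in
  terminator recovery, and matches the large replicate spreads seen in real
  terminator tables.
* Differential expression, enrichment analysis, read mapping and the wet
  protocol are out of scope; the package starts from alignments.
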