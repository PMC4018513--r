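---
title: "Automated peptide-level HDX-MS analysis with hdxflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated peptide-level HDX-MS analysis with hdxflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdxflow)
```

## The problem

Bottom-up hydrogen–deuterium exchange mass spectrometry (HDX-MS) measures
how fast backbone amide hydrogens of a protein exchange for deuterium in
D~2~O. The protein is digested with pepsin under quench conditions and the
peptides are separated by LC and analyzed by MS at a series of incubation
times. The quantity of interest is not peptide abundance but the *mass
shift* of each peptide's isotope envelope relative to the undeuterated
reference — ideally the full distribution of deuteration states, whose
intensity-weighted mean (the centroid) is the conventional scalar readout.

hdxflow implements a fully automated pipeline for centroided (line-spectrum)
LC-MS maps:

1. **Feature detection** in the undeuterated reference map by sparse
   regression of candidate isotope patterns (non-negative LARS with BIC
   stopping);
2. **Sequence assignment** by mass against an unspecific in-silico digest,
   with internal m/z recalibration, pepsin cleavage scoring and target-decoy
   FDR estimation;
3. **Retention-time alignment** of each deuterated map to the reference by
   a piecewise-linear mapping inferred from mass-predicted co-occurrence;
4. **Deuteration-distribution estimation** by boosted Gold deconvolution of
   extracted envelopes, with centroid and optional back-exchange correction.

A synthetic-data generator produces line-spectrum maps with exact ground
truth, so every stage can be validated quantitatively.

## Feature detection model

A centroided scan is modeled as a non-negative linear combination of
candidate isotope patterns,

$$s = \sum_{i=1}^K \beta_i \phi_i = \Phi\beta,$$

where each column $\phi_i$ is an aggregated-isotopologue Averagine pattern
for a hypothesized (monoisotopic m/z, charge) pair. The coefficients are
selected by the non-negative LASSO

$$\hat\beta = \arg\min \lVert s - \Phi\beta\rVert^2 +
\lambda \sum_i \beta_i, \quad \beta_i \ge 0,$$

whose full regularization path is traced by non-negative least angle
regression; the path point minimizing the Bayesian information criterion
$n\ln(\mathrm{RSS}/n) + k\ln n$ is kept ($n$ = observed peaks in the
segment, $k$ = support size, ties toward smaller $k$). Scans are first cut
into segments at m/z gaps larger than `min_gap` (default 1.5 Th at charge
1), which keeps the per-segment problem small; runtime grows with the
number of segments rather than with the square of the scan size.

Design choices a user should know about:

* **Noise level** is the scan's median absolute intensity times 1.4826
  (robust sigma), floored at one count; peaks at `snr_threshold` (default
  3) above it seed candidates.
* **Candidate seeding.** Each seed peak spawns patterns for every charge in
  `charge_min:charge_max` and for the hypotheses that it is isotope index
  0, 1 or 2 of its envelope. Charges are restricted to those consistent
  with an observed adjacent-peak spacing of ~1.00335/z Th; isolated peaks
  admit every charge.
* **Sampling onto line positions.** Theoretical peaks are assigned to the
  nearest observed peak within `sample_tol_ppm` (default 10 ppm). A
  substantial predicted peak (≥ 10% relative intensity) with no observed
  counterpart becomes a pseudo-observation of zero intensity, so patterns
  that predict signal where none exists are penalized — without this,
  shifted-monoisotopic candidates absorb envelope tails unpunished.
* **Elution merging.** Per-scan detections of equal charge within
  `mass_tol_ppm` (10 ppm) are chained across scans, tolerating
  `max_internal_gaps` (1) missing scans; chains shorter than `min_scans`
  (2) are dropped. Afterwards, satellite detections (same charge, 1–6
  isotope spacings away, < 30% of the stronger feature's abundance),
  harmonic charge aliases (a 1+ pattern explaining every third peak of a 3+
  envelope; resolved in favor of the higher charge, which explains strictly
  more peaks) and weak "shadow" debris inside a stronger feature's envelope
  region are suppressed. The shadow rule means a genuine co-eluting peptide
  below ~30% relative abundance *inside* another envelope's m/z span can be
  lost; this is the price of a clean feature list and is stated here rather
  than hidden.

## Sequence assignment and internal recalibration

All substrings of the target protein between `min_len` (4) and `max_len`
(40) residues form the search space, reflecting pepsin's broad specificity.
Matching is two-pass: a wide pass at 30 ppm collects candidate mass errors;
the dominant error — the center of the densest window of width twice the
instrument precision, refined as the median inside the window — is taken as
a single global ppm offset (true matches pile up at the calibration error,
false ones scatter uniformly, so a mode estimator is robust where a mean is
not); after correction, the strict pass at the instrument precision
(default 4 ppm) produces the reported assignments. Per feature, assignments
are ranked by MS/MS confirmation, then pepsin cleavage score (favored P1
residues F/L/W/Y/M score +2, forbidden H/K/R/P −4, P1′ proline −4, protein
termini count as maximally favorable), then absolute ppm error. All
assignments are retained and exported; the top-ranked one drives the
downstream deuteration analysis.

FDR is estimated by target-decoy counting. One subtlety: a *reversed*
protein is useless as a decoy for mass-only matching of an unspecific
digest, because every substring of the reversed sequence is the reverse of
a forward substring and has exactly the same mass. The default decoy
therefore shuffles the residues deterministically; `reverse_protein()` is
kept for sequence-based workflows.

## Retention-time alignment

For every reference feature, all m/z values expected after deuteration —
combinations of $k$ deuterons (spacing 1.006277/z) and $i$ natural heavy
isotopes (spacing 1.00335/z) — are probed in every target scan within a
ppm box (default 4 ppm, the instrument precision). Scans where at least
`min_consecutive_isotopes` (3) consecutive isotope indices match become
(rt~ref~, rt~target~) candidates. The dense band of true correspondences is
found by five rounds of Tukey-bisquare reweighted least squares followed by
a one-standard-deviation residual cut; a continuous piecewise-linear
mapping with `n_segments` (8) equal-quantile knots is then fit, with
monotonicity enforced by knot merging (chromatography does not reorder
within a run). Because a single line underfits a curved mapping, the
one-SD cut can drop genuine candidates at the rt extremes; two refinement
passes therefore re-admit candidates consistent with the current piecewise
fit, collapse each feature's run of matching scans to its median target
time (the elution centroid, immune to window-truncation bias), and refit.

The mapped elution interval of a feature is extended by the reference peak
width, and a locally adjusted tolerance half-width
$\max(\text{floor}, 2\,\hat\sigma_\text{knot})$ (floor 10 s) makes the
search more permissive exactly where the mapping is uncertain. Deuterated
maps are never feature-detected de novo; extraction is targeted.

## Deuteration distributions by boosted Gold deconvolution

Within the mapped window, the intensity of the nearest peak inside the ppm
box at each predicted m/z position is collected per scan and isotope index.
Only the contiguous elution core around the apex scan (per-scan totals ≥
10% of the apex) is integrated, so tolerance slack does not accumulate
baseline noise; indices below 5% of the envelope maximum are zeroed for the
same reason. Envelopes without `min_consecutive` (3) consecutive
appreciable isotopes are rejected with a reason rather than silently
dropped.

The observed envelope $y$ is modeled as $y = A d$ with $d \ge 0$, where
column $k$ of $A$ is the natural isotope pattern shifted by $k$ deuteration
states. Gold's multiplicative iteration

$$d_i \leftarrow d_i \frac{(A^\top y)_i}{(A^\top A\, d)_i}$$

starts from a uniform positive vector, keeps coefficients non-negative by
construction, and favors smooth solutions; during the first
`boost_iterations` (500), the estimate is sharpened every `boost_every`
(50) iterations by $d_i \leftarrow d_i^{1.2}$ and renormalized, after which
plain iterations run to convergence — boosting applied indefinitely would
converge to a sharpness-biased fixed point instead of the exact inverse on
noise-free input. $A^\top A$ and $A^\top y$ are precomputed once per
envelope. The budget is 10,000 iterations with early stop when the relative
change of $d$ falls below 1e-8. On noise-free input the scheme inverts the forward
convolution essentially exactly (total-variation distance < 1e-3) and
conserves the centroid to < 0.05 states. On delta-spike truths the boosting
drives the solution essentially sparse — which is then correct; the
smoothing character shows on smooth (e.g. binomial) uptake distributions,
which are recovered with their spread intact instead of collapsing to a
single state.

The centroid is $\sum_j j\,d_j$ deuterons, or times 1.006277 in Da. With a
fully deuterated control, back-exchange is corrected by the ratio form
$D_\text{corr} = N\,\frac{m - m_{0\%}}{m_{100\%} - m_{0\%}}$, where the 0%
term is zero by construction of the deconvolved distribution. Without a
control the relative deuteration is reported and flagged uncorrected,
which still supports comparative experiments under identical LC-MS
conditions.

## The synthetic-data generator

`simulation_spec()` fixes the study conditions; its defaults emulate the
acquisition the pipeline targets: a 20-min gradient sampled at 0.5 Hz
(scans every 2 s over 200–1400 s), Gaussian elution profiles (SD 6 s),
exact-formula isotope envelopes at charges 1–3 within m/z 300–1500,
log-normal abundances, an acquisition intensity cutoff of 100 counts, 50
exponential-intensity background peaks per scan, per-peak m/z jitter of 4/3
ppm (so ~99.7% of mass reads fall inside a 4 ppm precision window), an
optional global multiplicative calibration error, and an optional
scan-time distortion multiplying scan times by values ascending 0.8→1.2.
Intensity noise is Poisson-like: Gaussian with variance proportional to the
expected intensity, scaled so the apex peak has SD = abundance/SNR. A
constant-variance alternative would plant pure-noise peaks at
near-zero-intensity isotope positions, which neither counting statistics
nor thresholded instrument output produce.

Planted peptides are drawn from the cleavage-favored fraction of the
unspecific digest (both termini cut after F/L/W/Y/M, or protein ends),
because a real pepsin digest consists of such peptides; sampling uniformly
over all substrings would simulate features no protease would generate.
Deuterated maps convolve each peptide's natural envelope with a known
deuteration distribution (binomial uptake with per-peptide log-normal
rates in `simulate_hdx_experiment()`), and all ground truth is returned
in machine-readable form.

What the generator does **not** emulate: chromatographic tailing, ion
suppression, co-elution-dependent ionization, detector saturation, isotope
fine structure (unresolved at the 40,000 FWHM resolution the pipeline
targets), and back-exchange kinetics during LC. Passing tests on synthetic
data therefore demonstrate algorithmic correctness under the stated model,
not instrument robustness.

## Numerical choices and degenerate inputs

* Isotope spacing: 1.00335 Da (¹³C−¹²C) within natural envelopes,
  1.006277 Da (²H−¹H) per deuteron; the probe grid merges both, since at 4
  ppm the difference only matters beyond ~10 deuterons and the box absorbs
  it.
* Monoisotopic masses from exact residue masses + H~2~O; proton mass
  1.007276 Da.
* "Improved" Averagine: the scaled unit composition
  (C~4.9384~H~7.7583~N~1.3577~O~1.4773~S~0.0417~ per 111.1254 Da) is
  rounded to an integer formula — C/N/O/S to the nearest integer, H chosen
  to match the target mass — which keeps the leading isotope ratios close
  to real peptides of that mass. This rounding rule is this package's
  explicit stand-in for the improved parameterization.
* LARS columns are L2-normalized internally; collinear columns are excluded
  rather than allowed to destabilize the direction solve; an all-zero
  spectrum yields the null path.
* `RSS` is floored at 1e-12 in the BIC to keep exact fits finite.
* Gold division guards: components with $(A^\top A d)_i = 0$ stay at zero.
* Piecewise fits fall back to the coarse line on degenerate spans; fewer
  than 10 alignment candidates abort with "insufficient alignment
  evidence".
* Calibration offsets ≥ 100 ppm are rejected as implausible and ignored
  with a warning, as are calibrations from fewer than 30 wide-pass matches.

## Problem sizes used in validation

The shipped test-suite and acceptance protocols run at desk scale chosen as
representative rather than exhaustive: alignment is validated on ~100
peptides over 600 scans; recalibration on ~500 features of a 450-residue
synthetic protein; the end-to-end run on 10 peptides, four incubation
times and three replicates at SNR 20, where every true centroid is
recovered within 0.2 deuterons.

## Known limitations

* The shadow-suppression rule can discard genuinely co-eluting low-abundance
  peptides inside another envelope's m/z span (stated above).
* Recalibration fits a single global ppm offset; per-scan drift is not
  modeled.
* The target-decoy FDR with a shuffled decoy estimates the *random-match*
  rate; exact isobars (sequence permutations) are invisible to any
  mass-only decoy.
* Back-exchange differences induced by retention-time differences between
  maps are not corrected.
* Only mzXML is read; profile-mode data are accepted with a warning but the
  pipeline assumes upstream centroiding.

## A worked example

```{r example, eval = FALSE}
spec <- simulation_spec(n_peptides = 10, rt_range = c(100, 700),
                        snr = 20, seed = 9)
ex <- simulate_hdx_experiment(spec, times = c(15, 60, 300, 1200),
                              n_replicates = 3)
deut <- purrr::pmap(list(ex$deuterated$time, ex$deuterated$replicate,
                         ex$deuterated$map),
                    function(t, r, m) list(time = t, replicate = r, map = m))
run <- run_pipeline(list(reference = ex$reference$map,
                         fasta = ex$reference$protein,
                         deuterated = deut,
                         params = list(detect = list(charge_max = 3))))
run$merged
plot_uptake(run$merged)
```
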