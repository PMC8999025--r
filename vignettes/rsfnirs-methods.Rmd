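---
title: "Methods: resting-state fNIRS connectivity and brain-network analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resting-state fNIRS connectivity and brain-network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsfnirs)
```

## Scope and model

`rsfnirs` implements a complete resting-state functional-connectivity
analysis for prefrontal-cortex fNIRS recordings in a paired (pre/post)
design, of the kind used to compare cognitive state before and after an
intervention or a work shift. The chain is:

1. **Optics to hemodynamics.** Dual-wavelength (690/830 nm) light
   intensities are converted to optical-density changes
   $\Delta OD_\lambda(t) = -\log_{10} I_\lambda(t)/\bar I_\lambda$, band-pass
   filtered to the hemodynamic band (0.02–0.1 Hz), despiked with a wavelet
   outlier rule, and inverted through the modified Beer–Lambert law
   (MBLL): $\Delta OD_\lambda = (\varepsilon_{HbO,\lambda}\,\Delta HbO +
   \varepsilon_{HbR,\lambda}\,\Delta HbR)\, d \cdot DPF$ with
   source–detector separation $d$ = 3 cm and differential pathlength
   factor DPF = 6.53 at both wavelengths. Oxy-hemoglobin is the analysis
   signal.
2. **Connectivity.** For each subject and session, the 22×22 matrix of
   Pearson correlations between channel time courses; group matrices are
   plain element-wise averages. A binary network is obtained either by the
   absolute cut $r > 0.7$ (strict) or by keeping the $\lfloor T \cdot 231
   \rfloor$ strongest edges at a sparsity $T$.
3. **Edge statistics.** Per-edge paired t-tests of pre vs post with
   Benjamini–Hochberg FDR across the 231 edges ($q < 0.05$), and a paired
   t-test of the per-subject mean connectivity scalar.
4. **Network topology.** Over the sparsity sweep $T = 0.1, \dots, 0.9$:
   clustering coefficient $C_{net}$, global efficiency $E_{glob}$, local
   efficiency $E_{loc}$, characteristic path length $L_p$, nodal
   betweenness centrality, and small-worldness
   $\sigma = \gamma/\lambda$ with $\gamma = C_{net}/C_{ran}$,
   $\lambda = L_{net}/L_{ran}$ against 100 degree-preserving random
   networks. Nodal metrics are collapsed to one value per subject by the
   width-normalized area under the sweep and compared pre vs post with
   uncorrected paired t-tests (the presentation convention of nodal
   tables).

## The montage

The packaged montage has 22 channels from 15 optodes (7 sources, 8
detectors) at 30 mm separation covering the prefrontal cortex, with MNI
coordinates and Brodmann areas per channel. The ROI partition is fixed:
dlPFC = {1–6, 8, 9, 14, 18} (BA 9/46), FPC = {7, 10–13, 15–17} (BA 10),
OFC = {19–22} (BA 11). The table's registration-weight column is stored as
metadata and feeds no computation, since its provenance is a probabilistic
spatial registration we do not re-run. The source/detector pairing of
individual channels is a nominal synthetic assignment (the published
geometry fixes only the counts and separation); no computation consumes
it.

## Synthetic cohorts: what they emulate, and what not

No recordings ship with the package; every statistical claim is exercised
on synthetic paired cohorts with known ground truth:

* The hemodynamic component is a **band-limited Gaussian process**: white
  noise pushed through the same 0.02–0.1 Hz zero-phase filter used in
  preprocessing, then mixed across channels by the symmetric square root
  of a target correlation matrix. This makes the planted quantity exactly
  the population Pearson correlation, so connectivity recovery is testable
  without bias.
* Ground truth is **ROI-block structured** (`make_block_correlation()`):
  one correlation within ROI blocks, a lower one between, repaired to the
  nearest valid correlation matrix by eigenvalue clipping and diagonal
  renormalization when needed.
* Nuisance terms are **independent per channel**: cardiac (1.2 Hz),
  respiratory (0.3 Hz), and Mayer-wave (0.1 Hz) oscillators with random
  phases, a random linear drift, white noise, and motion spikes
  (boxcar onset, exponential recovery, by default 1/min at 2×10⁻³ mM).
  Amplitudes default to a realistic fraction of the 10⁻³ mM hemodynamic
  scale. Because MBLL is linear, spikes planted in concentration space
  appear identically in optical-density space, which is where the
  despiking operates.
* Defaults mirror the study design: 300 s at 7.4074 Hz, 22 channels,
  paired pre/post sessions, group sizes 17/18/19.

What the generator does **not** emulate: task-evoked responses and any
biophysical hemodynamic model, superficial/systemic physiology shared
across channels (scalp blood flow), spatially correlated motion, and
non-Gaussian amplitude distributions. Passing parameter-recovery tests
therefore demonstrates correctness of the estimators under the stated
generative model, not robustness to every artifact of field recordings.

A note on statistical resolution: a process confined to a bandwidth of
$B = 0.08$ Hz observed for $T = 300$ s carries only about $2BT \approx 48$
effective samples per correlation estimate, regardless of the 7.4 Hz
sampling rate. Single-subject correlation estimates therefore fluctuate
with a standard error near 0.14; recovery tests average empirical
matrices over 20 independent seeds (standard error ≈ 0.03) and assert a
mean absolute deviation below 0.05.

## Numerical choices

* **Filter realization.** The nominal design is a 4th-order Butterworth
  band-pass applied forward–backward (zero phase). At $f_s = 7.4074$ Hz
  the normalized corner frequencies (0.005–0.027) make a single band-pass
  polynomial ill-conditioned, so the filter is realized as a cascade of
  4th-order high-pass (0.02 Hz) and low-pass (0.1 Hz) sections, each run
  through `signal::filtfilt`. The cascade meets the contract: mid-band
  gain within 10%, ≥ 20 dB attenuation at half the lower edge and twice
  the upper edge, linear drift suppressed ≥ 20×.
* **Wavelet despiking.** A periodized orthogonal discrete wavelet
  transform with a support-10 Daubechies-class filter (exposed under the
  acquisition-toolbox parameter name "Vaidyanathan"). Per decomposition
  level, detail coefficients are robustly z-scored (median/MAD); a
  coefficient whose two-sided Gaussian tail probability falls below the
  threshold (10⁻⁴) is zeroed before reconstruction. The `alpha` parameter
  of the original toolbox convention is stored but intentionally inert;
  the despiking contract is behavioral (a planted 10-SD spike must be
  reduced to ≤ 30% of its excursion while spike-free signals keep
  correlation ≥ 0.99 with their input). Series are reflection-padded to a
  power of two and truncated after reconstruction.
* **OD referencing.** Continuous-wave fNIRS has no absolute baseline; OD
  changes are referenced to the temporal mean intensity, which recovers
  concentration changes up to a per-channel constant. The constant is
  irrelevant downstream (the band-pass removes it; correlation is
  offset-invariant). Synthetic recordings carry their true baseline, and
  referencing against it (`reference = "baseline"`) makes the
  forward/inverse MBLL round trip exact to below 10⁻⁹, which is how the
  optical model is tested.
* **Degenerate statistics.** Zero-variance paired differences: all-zero
  differences give $t = 0, p = 1$; a constant non-zero shift is flagged
  degenerate, carries no p-value, and is excluded from the FDR family
  size rather than being assigned $p = 0$.
* **Graph conventions.** Thresholding at $r > 0.7$ is strict; sparsity
  thresholding breaks ties at the cut by ascending $(i, j)$ order.
  Nodes of degree < 2 contribute 0 to clustering and local efficiency
  (the defining ratios divide by $k_i(k_i-1)$). $L_p$ averages over
  connected pairs only (the convention of the common brain-network
  toolboxes), while the efficiency metrics use $1/\infty = 0$; both
  conventions are enforced by brute-force oracles in the test suite over
  every non-isomorphic graph on up to six nodes. Betweenness sums over
  ordered pairs with normalizer $(n-1)(n-2)$; the halved unordered
  convention is available as an option. "Matched" random networks are
  Maslov–Sneppen degree-preserving double-edge swap randomizations
  (10 attempted swaps per edge), the standard null of the brain-network
  literature; the null ensemble is seeded and fully reproducible.
  A consequence of the connected-pairs $L_p$ convention worth knowing:
  for strongly modular networks thresholded below their percolation
  density, $L_{net}$ can fall below $L_{ran}$ (λ < 1) because the intact
  null connects distant nodes that the modular graph simply does not
  count.
* **Averaging correlations.** Group matrices are plain arithmetic means
  (no Fisher z), matching the stated analysis; a z-space average is
  available (`fisher_z = TRUE`) but off by default. Negative correlations
  are retained in matrices — they simply cannot pass a positive edge
  threshold.
* **Seeds.** Every stochastic component (simulation, subject streams,
  null networks) is a pure function of an explicit integer seed; derived
  stream seeds are produced by a fixed congruential mix kept inside the
  32-bit range, and seeding never perturbs the caller's RNG state.

## Design decisions that were genuinely open

* The analysis order applies the band-pass and despiking to
  optical-density traces and inverts MBLL last; because MBLL is a fixed
  linear map per channel, this commutes with filtering either signal
  domain, and OD space is where motion artifacts physically live.
* The sparsity sweep interprets $T$ as network density (fraction of
  strongest edges kept), not an absolute correlation cut: the observation
  that efficiency rises monotonically with $T$ is only guaranteed under
  density thresholding. The absolute-r mode remains for the single-network
  $r > 0.7$ analysis.
* Nodal sweep profiles are collapsed to one scalar per subject by the
  width-normalized trapezoid AUC before the nodal paired tests (how a
  single per-subject nodal value should be formed is not dictated by the
  sweep itself; AUC is the standard toolbox choice and is insensitive to
  any single threshold).
* Edge-wise paired t-tests run on raw per-subject correlation values, not
  on binarized networks; binarization serves network construction only.
* The 2×2 extinction-coefficient table at 690/830 nm ships with standard
  compendium values in (mM·cm)⁻¹ and is user-replaceable; all tests use
  the shipped table.

## Problem sizes used by the shipped tests

The test suite chooses sizes that keep each property statistically sharp:
correlation-recovery averages use 20 seeds at 120–300 s; null error-rate
control uses 100 replicate cohorts of n = 18 with 60-s recordings (the
null distribution of a paired t statistic does not depend on recording
length); planted-direction recovery uses 50 replicate cohorts of n = 17 at
the full 300 s; determinism compares byte-identical artifacts of two
reduced-scale pipeline runs. A full study-scale run (three groups of
17/18/19 subjects × 2 sessions, 300-s recordings through the complete
optical chain, 9-point sweep, 100 nulls per network) completes in a few
minutes on one CPU core.

## Known limitations

* The wavelet basis is a Daubechies-class stand-in behind the
  "Vaidyanathan" parameter name; despiking behavior, not basis identity,
  is the contract.
* Short-separation regression, spline/TDDR motion correction, systemic
  physiology removal, deoxy-Hb analyses, partial-correlation or coherence
  connectivity, weighted-graph metrics, and between-group (unpaired)
  statistics are out of scope.
* Channel MNI coordinates are taken as published; no probabilistic
  registration is performed.
* With ~48 effective samples per 300-s recording, single-edge effects
  below Δr ≈ 0.2 are underpowered at n ≈ 18; the package reports honest
  p-values either way.
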