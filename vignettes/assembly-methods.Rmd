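---
title: "De novo assembly of densely labelled optical DNA maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{De novo assembly of densely labelled optical DNA maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(denseogm)
```

## The problem

In densely labelled optical genome mapping (OGM), single stretched DNA
molecules are imaged in nanofluidic channels and each molecule yields a
one-dimensional fluorescence intensity profile — a *barcode* — in pixel
units (here one pixel corresponds to a few hundred basepairs). Labels are
too dense to resolve individually, so the continuous profile itself carries
the sequence information. Molecules are random fragments of the genome in
random orientation, with molecule-to-molecule stretch variation of a few
percent and substantial photon noise. `denseogm` reconstructs the layout of
these fragments without a reference: it scores all pairwise overlaps,
filters them through a calibrated significance test, assembles consistent
overlaps into *barcode islands* (connected components of the overlap
graph, the OGM analogue of contigs), and reduces each island to an
amplitude-adjusted *consensus barcode*.

## Pairwise overlap model

For every unordered pair, one barcode acts as the *query* (held fixed) and
the other as the *reference*, which may be reversed and length-rescaled by
a factor from a grid (default 0.95–1.05 in steps of 0.01, matching the
few-percent stretch variation of real molecules). The *local overlap
score* $C$ is the maximum sliding-window Pearson correlation over all
placements of a window of $w$ pixels (default 300 px, roughly 150 kb — wide
enough to be informative, narrow enough to fit inside most mutual
overlaps), all rescaling factors and both orientations. The implementation
computes exact window statistics from running sums and streams the window
dot products along alignment diagonals in compiled code, so every placement
costs O(1); the result is identical to the brute-force $O(n^2 w)$
evaluation, which the test suite verifies to $10^{-8}$.

Because a high local score can arise from a spurious match of a single
window, a second statistic guards the rest of the alignment: the *leftover
score* $C^{\mathrm{leftover}}$ is the Pearson correlation over the mutually
overlapping pixels **excluded** from the best window, under the same
offset, rescaling and orientation. When fewer than 20 such pixels exist the
leftover statistic is meaningless and the pair falls back to a single-score
mode in which only the local test applies.

## Null model and significance

Both scores are converted to p-values under a null model calibrated by
Monte Carlo (`calibrate_null()`): `calib_n = 1000` pairs of independent
random profiles are generated with the same smoothness as the data
(Gaussian white noise convolved with the PSF, `random_reference()`), and
each pair is scored by the full search. Three components are fitted by
maximum likelihood:

* **Local maximum.** $\operatorname{atanh}(C_{\max})$ follows a fitted
  Gumbel law at the calibration trial count $K_{\mathrm{cal}}$ (the number
  of placements × rescalings × orientations actually examined). For a pair
  with a different trial count $K$, max-stability gives
  $P(C_{\max}\le c) = G(c)^{K/K_{\mathrm{cal}}}$, which keeps p-values
  comparable across pairs of different lengths. A simpler beta-power form
  $F(c; m)^{\nu K}$ was evaluated first but misfits the bulk of the max
  distribution (held-out Kolmogorov–Smirnov p ≈ 0.002–0.007); it is
  retained in the model object only for full-length reference alignments,
  where a window-width-transferable form is needed and only the ranking of
  p-values matters.
* **Marginal window correlation.** For a single fixed placement the
  correlation of two smooth profiles follows the classical null with
  density $\propto (1-c^2)^{(m-3)/2}$, where $m$ is an *effective* sample
  size smaller than the pixel count because the PSF correlates neighbouring
  pixels (`pcc_null_cdf()`).
* **Leftover, conditional on selection.** The leftover score is evaluated
  at the placement the local stage selected. That selection depresses the
  conditional mean slightly below zero (measured ≈ −0.11 at 60 leftover
  pixels, −0.02 at 480), so an unshifted symmetric null is measurably
  non-uniform. The calibrated leftover null is a beta law with fitted
  effective degrees of freedom $a\,n + b$ and a fitted location shift
  $s_1/n + s_2/\sqrt{n}$. Held-out simulations confirm both p-values are
  marginally uniform (KS p ≈ 0.1–0.26), which the acceptance suite
  re-checks.

A pair is *significant* when $p_{\mathrm{local}} < 0.05$ **and** (unless in
single-score mode) $p_{\mathrm{leftover}} < 0.05$. Significant pairs get a
combined Stouffer score
$s = [\Phi^{-1}(1-p_{\mathrm{local}})+\Phi^{-1}(1-p_{\mathrm{leftover}})]/\sqrt{2}$,
which orders edge insertion during assembly. Note that with two uniform,
nearly independent p-values, the dual filter passes only about
$0.05^2 = 0.25\%$ of truly non-overlapping pairs — far stricter than either
threshold alone. The package reports this rate honestly
(`scripts/acceptance.R` measures ≈ 0.3–0.5%); a single-score filter at 0.05
would pass ≈ 5%.

## Graph assembly with merge tables

Significant overlaps are inserted in descending Stouffer order (ties broken
by barcode id). Each graph vertex carries a placement — start, orientation,
rescale — in its component's frame; an edge's geometry implies a placement
of one endpoint given the other. Two placements are *consistent* when
orientations agree, starts differ by at most `px_diff` (default 50 px,
well above the few-pixel scatter of correct placements and well below the
hundreds-of-pixels scale of wrong ones) and rescales differ relatively by
at most `sc_diff` (default 0.05, the span of the search grid).

Insertion follows four cases. Both endpoints new: a fresh component. One
endpoint new: the overlap is **deferred** to the component's merge table
unless an earlier deferred overlap already connects the same new barcode
consistently — a new vertex thus needs two independent, mutually consistent
overlaps to enter a component, which removes most false positives that
survive the p-value filter. Both endpoints in one component: the edge is
accepted only if it agrees with the existing placements. Endpoints in two
components: the components merge only when a second independent
cross-component overlap implies the same inter-component frame map (same
flip, scales within `sc_diff`, mapped positions within `px_diff`); the
smaller component is re-anchored onto the larger. Islands are the
components with at least two members; single vertices are reported as
unplaced rather than as one-barcode islands.

## Consensus generation

Each island can be reduced to a consensus profile in `iterations = 5`
rounds of three steps.

1. **Amplitude adjustment.** Molecules differ in overall intensity
   (illumination, photobleaching, staining). Island members are
   single-linkage clustered on $1 - \mathrm{PCC}$ (pairs must share at
   least `min_overlap` = $w$ pixels) and the tree is cut at
   $1 - 0.5$. Traversing merges from the highest correlation downward, the
   best pair $(i_1, i_2)$ of each merge is mapped onto the shared moments
   $\tilde\mu = (\mu_{i_1}+\mu_{i_2})/2$,
   $\tilde s = \sqrt{(\sigma_{i_1}^2+\sigma_{i_2}^2)/2}$ via
   $b_i \mapsto (b_i-\mu_i)\,\tilde s/\sigma_i + \tilde\mu$. The moments
   are computed over the pair's mutual overlap region rather than over the
   whole barcodes — the two choices differ for partial overlaps, and the
   overlap-region statistics make the contract exact (equal mean and sd
   over the shared stretch, verified to $10^{-9}$).
2. **Drafting.** The consensus is the per-column mean over *covered* cells
   of the block representation; uncovered cells are missing values, never
   zeros, so genuine zero intensities are preserved. Zero-coverage columns
   are trimmed at the ends and interpolated (with coverage 0) inside.
3. **Realignment.** Each member is independently re-placed by its best
   full-length correlation against the consensus over all offsets and a
   stretch grid of ±5% in steps of 0.01 around its *assembly-time* rescale
   — anchoring to the original factor keeps the total stretch bounded
   instead of compounding by ±5% per round. Orientation is fixed.

On noiseless islands the pipeline is a fixed point after one round. On
noisy islands it converges quickly; improvements over the first draft are
modest because assembly placements are already within a few pixels of
truth, and re-fitting each barcode against a consensus that includes its
own noise can shift the converged solution by a pixel either way. In
repeated simulations the final consensus matches or beats the first draft
in roughly three quarters of trials, with gains an order of magnitude
larger than the losses.

## Synthetic data and what it does (not) show

The simulator provides study conditions without experimental data. A
*theory barcode* is computed from a DNA sequence by a deliberately simple,
pluggable model: windowed GC fraction per pixel (366.67 bp/px by default,
which maps the 4,641,652 bp *E. coli* K-12 chromosome to exactly 12,659
px), blurred by a Gaussian PSF of 1.5 px (diffraction-limited optics over
~160 nm pixels) and z-normalized. The assembler never sees the generative
model, so any sequence-to-intensity map (e.g. a competitive-binding
ligand model) can be substituted. `random_reference()` provides a
sequence-free stand-in with the same second-order statistics.

Fragments are sampled uniformly (with wrap-around on circular references),
with Normal lengths (defaults: mean 850 px, the study's average molecule
length; sd 100 px as a realistic spread; truncated below at $w$), uniform
orientation, per-fragment rescale jitter $\mathcal N(1, 0.02)$ — inside
the ±5% search grid and consistent with the few-pixel ground-truth scatter
that rescale-grid discretization produces — and additive white Gaussian
noise parameterized by the synthetic-noise variance ratio
SNVR = Var(signal)/Var(noise), added after PSF blurring. Ground-truth
tables record every draw exactly; noiseless fragments reconstruct
bit-exactly from them.

What passing tests on these data do **not** show: the GC+PSF model has no
sequence-specific binding chemistry, no camera or photophysics noise
beyond additive Gaussian, and no per-molecule amplitude drift, so absolute
accuracy numbers (e.g. placement scatter of ~2 px) transfer to real data
only approximately. The machinery-level guarantees (oracle equivalence,
exact noiseless recovery, calibrated false-positive control) are
model-independent.

## Validation

With ground truth available, validation proceeds at two levels. *Pairwise*:
the reference barcode of each significant overlap is mapped into theory
coordinates through the query's ground-truth placement; the circular
distance between the mapped start and the reference barcode's own
ground-truth start should be a few pixels (a distance ≥ 40 px, or a flipped
orientation, counts as a false positive). *Island*: every member is aligned
full-length against the theory barcode; the lowest-p-value member anchors a
rigid map of the island frame onto theory coordinates, and per-member
distances are classified at a 30 px threshold (looser than pairwise
because anchoring adds variance). `classify_and_summarize()` also emits the
true-positive-rate-versus-threshold curve used for dot plots.

## Numerical and design choices

* Coordinates are 0-based half-open pixel intervals; a placed barcode
  occupies `[start, start + round(r * n))`.
* Rescaling uses linear interpolation on the uniform pixel grid —
  appropriate for PSF-limited (smooth) profiles; the interpolation kind is
  irrelevant below the smoothness scale.
* Windows with standard deviation below $10^{-9}$ are excluded from the
  overlap maximum to avoid 0/0.
* p-values are clamped to $[10^{-15}, 1-10^{-15}]$ before the normal
  quantile in the Stouffer combination.
* All randomness derives from one integer seed through a counter-based
  splitting scheme; every pipeline stage is bit-reproducible given
  (inputs, configuration, seed).
* Problem sizes in the shipped test-suite simulations are reduced relative
  to a full study (e.g. 80 fragments instead of 175–200 on the 12,659 px
  reference for ground-truth validation, 18–20-member islands for the
  consensus experiments, 1,000-pair null ensembles); the reference length
  is kept at full scale because the fraction of truly overlapping pairs —
  which false-positive rates depend on — is set by fragment length over
  reference length, not by fragment count.

## Known limitations

* The merge-table arbitration keeps a flat list of deferred overlaps and
  resolves the first consistent partner; with more than two pending
  cross-component pairs the arbitration order is insertion order (i.e.
  Stouffer order), not a global optimum.
* No global least-squares refinement of island placements; realignment to
  the consensus is the only refinement step.
* Kymograph preprocessing implements a simple ordinary-least-squares
  shrink test and integer-pixel frame alignment; full image segmentation
  and sub-pixel frame registration are out of scope.
* Sparse-label OGM formats (BNX/CMAP) are not supported; the input is the
  package's plain-text barcode TSV.
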