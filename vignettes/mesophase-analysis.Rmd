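---
title: "Indexing peptide-DNA mesophases and membrane curvature from 1D SAXS"
author: "mesoSAXS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Indexing peptide-DNA mesophases and membrane curvature from 1D SAXS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoSAXS)
```

## The measurement and the models

Powder-averaged SAXS from a condensed peptide–DNA complex or a
peptide–lipid mesophase is a set of Bragg peaks on a smooth decaying
background. Everything the package computes flows from three pieces of
physics:

1. **Peak positions** are fixed by the mesophase and its lattice
   parameters. For a square columnar arrangement of DNA rods,
   $q_{hk} = (2\pi/d)\sqrt{h^2+k^2}$; hexagonal columnar replaces the
   modulus with $\sqrt{h^2+hk+k^2}$; a tetragonal columnar lattice adds a
   repeat $c$ along the rod axis,
   $q_{hkl} = 2\pi\sqrt{(h^2+k^2)/d^2 + l^2/c^2}$; a lamellar stack gives
   integer orders; and a Pn3m bicontinuous cubic phase gives
   $q = (2\pi/a)\sqrt{h^2+k^2+l^2}$ restricted by the space-group
   reflection conditions, producing the characteristic
   $\sqrt2:\sqrt3:\sqrt4:\sqrt6:\sqrt8:\sqrt9$ series. A bundle with only
   short-ranged positional order shows a single broad feature, and its
   spacing is estimated as $d = 2\pi/q_1$.
2. **Peak widths** carry the finite size of the ordered domains. The
   structure factor of a nanocrystal is modeled as an area-normalized
   squared-Lorentzian
   $S(q) = h^3 / \bigl(4\pi(|q-q_1|^2 + (h/2)^2)^2\bigr)$, and Warren's
   approximation converts the width to a linear domain size
   $L = \sqrt{8\pi}/(h/2)$. Exponentially decaying correlations
   (disordered bundles) give a plain Lorentzian and
   $L = \sqrt{2}/(h/2)$. The repeat count is $m = L/d$.
3. **Cubic lattice parameters** quantify induced membrane curvature: per
   unit cell the average Gaussian curvature of the midplane minimal
   surface is $\langle K\rangle = 2\pi\chi/(A_0 a^2)$, with the Euler
   characteristic $\chi = -2$ and dimensionless surface area
   $A_0 = 1.919$ for the Pn3m (double-diamond) aspect. Only the Pn3m
   constants ship with the package; Im3m/Ia3d slots exist but must be
   filled with literature values by the user, because defaults we cannot
   source would misattribute provenance.

Units are a deliberate contract: momentum transfer is handled internally
in Å⁻¹ (the unit peak positions are reported in), all spacings and domain
sizes are reported in nm, and curvature in nm⁻². The single conversion
lives in `convertQ()` (Å⁻¹→nm⁻¹ is exactly ×10); the dominant failure
mode of these formulas in practice is a silent unit mismatch, so nothing
else converts.

## Regression choices

Lattice parameters are regressed through the origin on $q^2$, which is
exactly linear in the unknowns $u = (2\pi/d)^2$ and $v = (2\pi/c)^2$:
the defining equations have no offset, so neither does the model, and the
tetragonal problem becomes an ordinary two-column linear least squares.
Consequently R² is computed with the *uncentered* total sum of squares in
$q^2$ space; it is not comparable to a centered R², and this is stated on
every object that carries it. Regressing on $q$ instead of $q^2$ (or
weighting peaks) would move fitted spacings by a fraction of a percent
for typical inputs; the package picks the linear-in-parameters space and
reports per-peak residuals so such ambiguity stays visible.

That visibility matters for real data. In the twelve-reflection
tetragonal peak list shipped with the package, the (001) position is
about 10% away from the position implied by the fitted $c$ while every
other residual is below 1%. The fit retains the point and flags it in
`peakAssignments()`; silently "fixing" a measured datum is not this
package's job.

## Reflection catalogs

`permittedModuli(phase, maxIndex)` enumerates permitted reflections with
`maxIndex` acting as a **modulus cutoff**: entries are kept while the
dimensionless modulus does not exceed it. A cutoff in modulus (rather
than a bound on individual indices) is what makes catalogs prefix-stable
— raising it only appends entries — and it matches how diffraction
patterns truncate (in q, not in index). The Pn3m catalog applies the
space-group reflection conditions (a reflection with a zero index needs
the remaining index sum even; index triples without zeros are free),
which reproduces the printed six-ratio series and extends it
(√10, √11, √12, √14, ...). Catalogs deliberately include reflections
that particular samples do not show; absence handling belongs to
assignment, not to the catalog.

## Assignment, classification, and the disordered fallback

`assignReflections()` normalizes measured positions by the first peak and
greedily matches each ratio to the nearest unused catalog ratio within a
relative tolerance (default 0.015). Catalog entries may be skipped
without penalty — weak reflections are routinely absent — and unmatched
measured peaks are flagged, not dropped. One caveat is documented on the
function: because ratios are taken to the *first* peak, a first peak that
itself sits a percent off the best-fit lattice inflates every ratio, and
reproducing hand-indexed assignments of real data can need a looser
tolerance (the shipped square-lattice peak list needs ~0.05).

`selectPhase()` tries each candidate phase, calls a candidate viable when
at least `minMatched` peaks (default 3) are assigned with all residuals
inside tolerance, and ranks viable candidates by (1) number of matched
peaks, (2) **catalog coverage** — the fraction of permitted reflections
up to the highest matched order that are actually observed — and (3) R².
Coverage is the package's own tie-break: a lamellar series indexes
perfectly on the square and hexagonal catalogs too (1:2:3 is a subset of
both), with identical R², so parsimony has to be measured; the phase
whose catalog the data fill most completely wins. With fewer than
`minMatched` assignable peaks the verdict is "disordered" with
$d = 2\pi/q_1$, mirroring how a single broad feature is treated in
practice.

The tetragonal phase cannot be reduced to one modulus list, so its
assignment is seeded differently: the $l=0$ layer is matched against the
square sub-catalog and fitted for $d$; peaks that layer leaves unassigned
generate hypotheses $c = 2\pi l/q$ which are scored by how many peaks the
full two-parameter prediction then matches; the best hypothesis is
refined by the joint least squares and re-matched once. When the user
supplies explicit $hkl$ labels (the peak-list mode), assignment is
bypassed entirely — that is the route that reproduces published lattice
parameters, since automatic ratio matching cannot be expected to
replicate judgment calls made on real spectra.

## Peak fitting on spectra

Fits multiply the *normalized* line shape by a free amplitude so the
width parameter $h$ keeps its physical meaning for the domain-size
formulas. `fitPeak()` is a bounded Levenberg–Marquardt fit
(`minpack.lm::nlsLM`) with the initial center at the window argmax and
the initial width at half the window width; non-convergence returns the
last iterate, flagged, with a warning.

Lorentzian-family tails decay slowly, so truly independent single-window
fits of neighboring peaks leave center biases of order $10^{-4}$
relative — too large for the exact-recovery guarantees the synthetic
benchmarks make. `fitPeaks()` therefore keeps the fits per-window (there
is no joint multi-peak solver) but (a) clips each window at the midpoint
to the neighboring detected peak, so no fit ever sees a neighbor's core,
and (b) iterates tail subtraction: each peak is refitted on the profile
minus the current model of all other peaks. On noiseless data this
converges to the exact generating parameters; the residual coupling for
strongly overlapped peaks (separation comparable to $h$) limits width
recovery to ~0.1%, which is far below anything the domain-size formulas
can resolve.

`indexProfile()` wraps the chain. Its default background handling
(`backgroundWindows = "auto"`) alternates peak fitting with refitting the
background model on the peak-subtracted residual over the whole grid
(power-law fitted in log–log space on positive residuals), up to 12
passes with an early stop when parameters stabilize to $10^{-10}$.
Explicit peak-free windows are also supported (`subtractBackground()`),
as is skipping subtraction. The background functional form on real
beamline data is not knowable from the profile alone; power law is the
default because it is the typical SAXS decay, and the choice is a
recorded parameter, not a reconstruction.

When fewer peaks than `minMatched` are detected, the pipeline fits a
plain Lorentzian (short-range order); otherwise a squared-Lorentzian.
This mirrors the physical reading of the two line shapes and can be
overridden per call.

## The synthetic generator and what the benchmarks show

`generateSpectrum()` builds a spectrum as the sum of amplitude-scaled
normalized peaks at exactly the positions the phase equations predict,
plus a background, plus seeded zero-mean Gaussian noise with standard
deviation $\eta\sqrt{\max(I, \mathrm{floor})}$ — Poisson-like
heteroscedasticity with a floor of 1% of the maximum intensity, in the
units where the first peak has unit height. Gaussian rather than true
Poisson noise keeps generation grid-independent; the pipeline only needs
realistic heteroscedasticity. Default amplitudes decay as
1/modulus², the way higher-order reflections weaken in experimental
spectra, and can be overridden per reflection (e.g. to mimic a missing
reflection). The default grid runs from half the first peak position to
1.3× the last peak plus several widths: a scan that ends hard at the last
peak leaves the background unidentifiable from Lorentzian tails, for any
method. Seeds are explicit everywhere and the global RNG state is left
untouched.

`generateBenchmarkSuite()` fixes the study design: six systems — square
columnar at d = 3.40 nm, tetragonal at d = 3.64/c = 3.28 nm with the
twelve-reflection pattern of the melittin-DNA complex, a disordered
Lorentzian bundle at d = 3.70 nm, Pn3m at a = 15.4 nm, and generic
lamellar (5.0 nm) and hexagonal (3.50 nm) controls — crossed with widths
{0.005, 0.01, 0.02} Å⁻¹ and noise {0, 1%, 5%}, 54 spectra in all. The
cubic entries scale widths down fourfold: at a = 15.4 nm the √8 and √9
reflections are 0.007 Å⁻¹ apart, and a 0.02 Å⁻¹ width merges them into a
single maximum that no indexing method could un-merge; the scaled widths
preserve the same width-to-peak-spacing range as the columnar entries.

The benchmarks assert, over the ≤1% noise suite: zero phase confusions;
lattice-parameter recovery better than $10^{-6}$ relative on noiseless
spectra and 0.5% at 1% noise; and the Warren width round trip. At 1%
counting noise a single spectrum determines the first-peak width with a
statistical standard error of a few tenths of a percent (occasionally
exceeding 1% for the narrowest peaks), so the width check is on the
median across the suite, with noiseless widths held to 0.1%-level
accuracy. Synthetic spectra share the generator's own line-shape and
background families with the fitter; passing these benchmarks
demonstrates the pipeline's internal consistency and numerical
correctness, not robustness to instrument resolution smearing, detector
artifacts, form-factor modulation or non-power-law backgrounds, none of
which the generator emulates.

## Peptide metrics

The charge bookkeeping is arithmetic made explicit. B-DNA presents
2 phosphate charges per 0.34 nm rise — 20 per 3.4 nm helical turn
(`dnaChargeDensity()`). A protofibril presenting $n$ cationic residues
per monomer at an axial rise $r$ presents $n \cdot 3.4/r$ per turn-length
window (`axialChargeDensity()`); for the four-fold melittin protofibril
(rise 0.82 nm, pitch 3.28 nm) the count is 20.7 ≈ 21, matching the DNA
density it compensates. Densities are returned unrounded with a rounded
companion, and the rounding convention is the report's, not the model's.

Hydrophobicity metrics depend on a residue set that published analyses
rarely state. The default here is {L, I, V, F, M, W, C} — the strongly
hydrophobic residues, excluding alanine. With alanine included the
melittin hydrophobic fraction is 12/26 ≈ 0.46, outside the 35–40% range
such peptides are usually quoted at; without it, melittin (10/26 ≈ 0.38)
and LL37 (13/37 ≈ 0.35) both land inside. The set is a constructor
argument and every report names the set used.

The hydrophobic face angle places residue $i$ at $(i-1)\cdot100°$ on an
ideal helical wheel and returns the smallest sector containing all
hydrophobic residues — equivalently 360° minus the largest
hydrophobic-free gap. When the largest gap does not exceed the wheel's
angular resolution (gcd of the step and 360°, i.e. residues tile the
wheel uniformly) the face is reported as 360°; with no hydrophobic
residues, 0°. Two caveats are deliberate: the wheel assumes a straight
ideal helix, so kinked peptides (proline/glycine hinges) should be
analyzed per segment via the `segment` argument, and face angles for
specific peptides are set-dependent, so the package treats published
face-angle values (~180°, ~120°, ~80°) as qualitative anchors rather
than point targets.

## Numerical conventions and edge cases

- Background subtraction never clips: intensities may go negative.
- The power-law background requires positive intensities in its fit
  windows and errors otherwise.
- `detectPeaks()` returns an empty vector (a valid result) on flat or
  monotone profiles; prominence is measured on the smoothed signal
  against the higher of the two flanking valleys.
- Degenerate regressions error with the missing reflection class named:
  a tetragonal fit without any $l>0$ reflection cannot determine $c$,
  and without any in-plane reflection cannot determine $d$.
- Assignment ties (two catalog entries equally near) resolve to the
  lower-order entry.
- `estimateDisorderedSpacing()` and the curvature functions reject
  non-positive inputs rather than returning NaN.

## Problem sizes

The shipped tests regenerate every fixture in code: profiles of one to a
few thousand grid points, the 54-spectrum benchmark suite, and the two
bundled peak lists (12 and 5 reflections). The full test suite, including
the end-to-end evaluation of the ≤1%-noise benchmark, completes in well
under a minute on a single core; these sizes were chosen because the
statistical properties asserted (classification, recovery tolerances)
are already stable at them.

## Known limitations

- No instrument resolution deconvolution: fitted widths fold in beam
  smearing, so domain sizes from real beamline data are lower bounds.
- No multi-peak joint refinement or intensity modeling
  (Rietveld-style whole-pattern fitting is out of scope); strongly
  overlapped reflections limit width accuracy as described above.
- Ratio-based assignment anchors on the first observed peak; if the
  first reflection of the true lattice is absent, the assignment will
  be wrong and the residual report is the guard.
- Only Pn3m curvature constants are built in.
- 2D detector images are not handled; the package starts from
  azimuthally integrated 1D profiles.
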