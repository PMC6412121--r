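---
title: "Quantifying site-specific RNA modification stoichiometry from LC-MS digests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying site-specific RNA modification stoichiometry from LC-MS digests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modstoich)
```

## The measurement

Spliceosomal snRNAs (and rRNAs, tRNAs, ...) carry post-transcriptional
modifications — ribose 2'-O-methylation (Nm), pseudouridine (Ψ), base
methylations — whose *stoichiometry* (the fraction of molecules modified
at a given position) is regulated and functionally consequential.
`modstoich` implements the LC-MS workflow that measures these fractions
from ribonuclease digests of a purified RNA:

1. **Digestion.** RNase T1 cleaves 3' of guanosine and RNase A 3' of
   pyrimidines; both require the free 2'-OH of the residue they cut
   after, so a 2'-O-methyl at that residue *blocks* the cut and extends
   the product to the next cleavable site.  Products carry 5'-OH /
   3'-phosphate ends.  A guided RNase H cut (DNA oligo directing
   cleavage at a chosen phosphodiester, leaving 5'-p / 3'-OH) can split
   the molecule first, which is how 5'-monophosphate species such as
   pUUG arise from internal regions.
2. **Internal standard.** The sample is mixed ~1:1 with an in-vitro
   transcribed copy of the same RNA, fully unmodified, synthesized with
   ¹³C-labeled NTPs: G-¹³C₁₀ alongside T1 digestion, C-¹³C₉ + U-¹³C₉
   alongside RNase A, so every informative product contains at least
   one labeled residue and resolves from its light counterpart by a
   known mass shift.
3. **LC-MS.** Digests are measured in negative mode; species are
   matched at ±5 ppm (MS1) and ±20 ppm (MS2), with at most one missed
   cleavage and at most one *variable* methylation per fragment in the
   search space (known, fixed sites are exempt from that cap, so
   multiply-methylated species like GmGmC stay reachable).
4. **Stoichiometry.** Two estimators, computed per site and replicate:

   * **Intensity ratio (internal standard).**  With light unmodified
     signal $L_u$, heavy signal $H$, and a mixing correction factor $k$,
     $$\hat f = 1 - \frac{L_u}{k\,H}.$$
     $k$ is the mean of light/heavy ratios over ~10 fragment pairs that
     carry no modifications (a median option is provided for outlier
     pairs).  When the modified species is also measured, the ratio
     $(L_u + L_m)/(kH)$ is reported as a consistency diagnostic.
     Raw estimates outside $[0,1]$ are clamped and flagged, never
     silently altered.
   * **Peak areas.**  From extracted-ion chromatograms (±5 ppm),
     $$\hat f = \frac{\sum A_{mod}}{\sum A_{mod} + \sum A_{unmod}},$$
     summing isomeric modified species for composite sites (e.g. the
     GmGmC + GmGC forms that together quantify the first of two adjacent
     methyls).

Pseudouridine is *mass-silent* (a C-glycoside isomer of U, zero
elemental delta) and is handled two ways, because mass alone cannot see
it: by depletion of the unmodified-coeluting species against the heavy
standard (intensity ratio), and by RT-resolved species of identical m/z
(peak areas) — Ψ-containing oligonucleotides separate chromatographically
from their uridine counterparts.

## Mass and ion chemistry

Elemental compositions are assembled per residue with explicit ¹²C/¹³C
pools; the heavy channel moves (label count × base count) carbons from
¹²C to ¹³C, so the heavy−light shift is exactly
$\sum_b n_b \lambda_b \cdot 1.0033548\,\mathrm{Da}$, independent of
modifications.  Negative-mode m/z is $(M - z\,m_p)/z$ with
$m_p = 1.00727646$ Da; a single constants table serves the whole
package because ppm-level matching demands consistent constants.
Species are flagged observable when their m/z falls in the survey window
(480–1980 by default).  The default 3' product chemistry is the opened
linear 3'-phosphate; the 2',3'-cyclic form (one water lighter) is
selectable per rule.  The TMG cap is modeled as a configurable 5'
end-group composition (default 2,2,7-trimethylguanosine joined by a
5'-5' triphosphate bridge), since capped species' exact cap chemistry is
a property of the sample, not of the algorithm.

MS2 product ions use the dominant CID series of RNA — c, y, w and a-B —
generated for every backbone position and charge up to a cap.  The
implementation enforces the closure $m(c_i) + m(y_{n-i}) = M +
m(\mathrm{H_2O})$, $w = y + \mathrm{HPO_3}$, and base loss for a-B.
Scores are matched-ion counts with the explained-intensity fraction as
tiebreak; permutational isobars (identical base multisets, e.g.
CACUCCG/ACCCCUG) have identical precursor m/z at every charge and are
separable only by these sequence-specific product ions or by retention
time.

## The synthetic-data generator

Because the workflow's raw instrument data are not distributable, the
package ships a generator that emulates the paired-channel design well
enough to exercise every stage end to end.  A scenario fixes molecules,
a site table with per-condition true stoichiometries, enzymes (with an
optional guided RNase H split before T1 digestion), replicate count,
mixing factor, and a noise model.  For every site cluster it emits the
light variant species (weighted by the product of per-site Bernoulli
probabilities), the heavy unmodified reference, ten unmodified
correction-pair fragments per run, and any unmodified fragment whose
m/z collides with a tracked species (kept as background so realistic
isobaric interference is present — the bundled U1-like molecule
contains the CACUCCG₆₉₋₇₅/ACCCCUG₈₅₋₉₁ collision).  MS2 spectra are
emitted for all species in shared-m/z groups.

Noise structure (all defaults, all configurable):

* **Intensity** — lognormal, CV 5%, *shared across the species of one
  fragment*: light and heavy channels of a fragment are chemically
  identical co-digested isotopologues, so preparation and ionization
  variability cancels in their ratio — this is the property that makes
  internal-standard quantification precise.  A 1% per-species lognormal
  residual models measurement noise that does not cancel.
* **Mass** — Gaussian per-scan centroid jitter, sd 2 ppm.  Drawing the
  error per scan rather than per species keeps a ±5 ppm XIC from losing
  an entire species to one unlucky draw, which is also how centroid
  error behaves on a real instrument.
* **Retention time** — Gaussian apex jitter (sd 0.02 min) on a
  deterministic RT model: fragments spaced 2.4 min apart, +0.5 min per
  methyl or Ψ (modified species elute later), +0.6 min extra per
  positional-isomer step so that same-m/z isomers (GmGC vs GGmC) are
  chromatographically separated by more than the 0.05-min peak sigma.
  Peaks are sampled as Gaussians on a 0.02-min scan grid.
* **Biology** — the true stoichiometry itself varies between replicates
  (`bio_sd` per site, fraction scale).  The bundled two-condition
  scenario draws these SDs on the scale of the replicate SEMs the
  emulated experiment reports (mean SEM × √3), with the SDs of the
  invariant sites calibrated so that the control-vs-knockdown contrast
  is a designed structural property: unaffected sites have standardized
  effects below 1 while affected sites are at 4 or more.

Under zero noise the generator is exact by construction: apexes sit on
the scan grid, all species share one peak shape, and both estimators
return the true fractions to machine precision — a property the test
suite asserts.  What the generator does **not** emulate: isotopologue
envelopes (matching is monoisotopic-only, as the quantification reads
single species), chromatographic peak-shape physics, digestion
kinetics, MS2 noise beyond uniform ladders, and sequence-dependent
ionization efficiency.  Passing tests therefore validate the pipeline's
bookkeeping, identification logic and estimator algebra — not
instrument-specific effects on real spectra.

## Quantification driver

`quantify_runs()` reads each simulated (or fixture) run: the per-run
correction factor comes from the pair species; each site cluster is
then anchored by its heavy reference peak — disambiguated by MS2
scoring when the XIC contains several peaks — and the light species are
measured at their m/z: the unmodified form as the peak co-eluting with
the anchor (heavy species co-elute with their light counterparts),
mass-shifted modified species at their own m/z with MS2 disambiguation,
and mass-silent species as the RT-shifted remainder at the unmodified
m/z.  Apex intensities are estimated by a quadratic fit to
log-intensity over the top of the peak (exact for Gaussian profiles,
robust to dropped scans); areas are trapezoidal over apex-relative
boundaries (default 1% of apex), segmented at scan gaps so that small
and large peaks in one trace are truncated identically.  Automated
boundaries replace the manual peak start/end selection of interactive
software; explicit boundaries remain available.

Replicate aggregation reports mean ± SEM (sd/√n); condition comparisons
use a pooled-variance two-sample t-test against the reference condition,
or one-way ANOVA with Tukey HSD when more than two conditions are
present (the pooled t keeps the two-condition case consistent with the
homoscedastic Tukey path).  Degenerate inputs are reported, not
errored: SEM is `NA` at n = 1, and constant identical groups get p = 1.

## Numerical choices and edge cases

* Coordinates are 1-based and inclusive everywhere; RNase H products
  are re-indexed with the offset preserved.
* Missed cleavages count *retained* cuts only; methyl-blocked positions
  are not cleavable and therefore never counted as missed.
* Base-only methylations (m⁶A etc.) never block cleavage; only
  2'-O-methyl does.
* Variant enumeration re-digests per variant, because a methyl on a
  cleavable residue changes fragment boundaries (the pUUGp → pUUGmGp
  extension); a per-fragment enumeration would miss this.
* Ties in MS2 resolution (equal score, equal |ppm|) stay ambiguous;
  isobaric groups without MS2 or RT separation are reported unresolved,
  never dropped.
* The digestion engine is validated against a brute-force cut-subset
  enumerator on 1000 random sequences per run of the acceptance suite;
  masses are validated against an independent per-atom summation oracle
  to < 10⁻⁴ Da.

## Problem sizes

The shipped scenarios are sized for routine re-running: two molecules
(164 + 188 nt), 11 tracked sites, 3 replicates × 2 conditions × 2
enzymes (24 runs, ~700 scan rows each), and a 5-site recovery scenario
at truths {0.05, 0.25, 0.50, 0.75, 0.95}.  The full test suite and the
acceptance script each complete in a few minutes on one core.

## A small worked example

```{r example, eval = FALSE}
library(modstoich)

sc <- default_scenario(seed = 101)
sim <- simulate_lcms(sc)
est <- quantify_runs(sim)
report <- site_report(est, sc)
subset(report, condition == "knockdown",
       select = c(site, mean, sem, p_value, significant, method, guide))
```

The report mirrors the field's summary-table layout: per site and
condition, the modified fraction (mean ± SEM, n), the p-value against
the reference condition, the estimator used, and the annotated guide
RNA.  See the README for the numbers this prints.
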