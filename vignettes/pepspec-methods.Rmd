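---
title: "Methods: specificity profiling and kinetic characterization with pepspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: specificity profiling and kinetic characterization with pepspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepspec)
```

## Scope and conventions

pepspec characterizes the substrate specificity and regulation of a
trypsin-like serine protease from two complementary experiment types and
ties them to enzyme kinetics. Substrate residues are labelled in
Schechter-Berger convention: P6...P1 N-terminal of the scissile bond,
P1'...P6' C-terminal, with cleavage between P1 and P1'. Amino-acid rows
are ordered alphabetically by one-letter code; positional-scanning
matrices keep a norleucine row `"n"` in place of Cys, because synthetic
libraries substitute the non-oxidizable norleucine for cysteine.

All user-facing functions take data frames and return tibbles or small
S3 objects with `tidy()`, `glance()` and `autoplot()` methods, so the
whole pipeline composes with the usual tidyverse verbs.

## Positional-scanning library reduction

A PSSCL plate holds four sub-libraries (fixed P4, P3, P2 or P1), each
with twenty fixed residues and equimolar mixtures elsewhere, measured in
replicate as fluorogenic cleavage rates. `reduce_psscl()` takes the
replicate mean of blank-subtracted rates per well group, clips negative
means to zero (rates are physically nonnegative; the clip is logged as a
warning), and optionally column-normalizes to percent-of-sum or
percent-of-maximum. Blank subtraction is optional because plate exports
differ in whether blanks are already removed; when no blank column is
present the blank is taken as zero. The default assay metadata recorded
with simulated plates (60 nM enzyme, 31.25 nM per compound, 250 uM total
substrate, 25 C) documents the emulated assay conditions; the reduction
arithmetic never uses it.

`qc_replicates()` flags well groups whose coefficient of variation
exceeds a threshold (default 0.2) or that carry fewer than two
replicates. `psscl_to_canonical()` maps a PSSCL matrix onto the
20-canonical alphabet for merging with proteome-derived profiles: the
norleucine row is dropped and Cys is assigned its background frequency,
i.e. treated as unenriched, which is the only defensible default given
that the library never measured it.

## The cleavage-site pipeline

The proteomic route digests a reference proteome in silico with a
GluC-style rule (cleave after Glu, never before Pro; Asp cleavage can be
enabled for phosphate-buffer GluC behaviour; missed cleavages
configurable, default zero). Candidate cleavage products are peptides
whose quantitative fold change (treated over control) is **strictly**
greater than 8; control intensities of zero are floored at 1e-6 of the
median positive control intensity so that treated-only peptides get
large finite ratios and pass. The boundary is strict because the
acceptance rule is an ">8-fold" increase, and the tests pin the boundary
(8.0 rejected, 8.000001 accepted).

Each accepted peptide is located in the proteome by exact substring
search. A terminus is rule-conforming if it coincides with a protein
terminus or a bond the library protease cuts; exactly one neo terminus
yields a cleavage event at that terminus, fully specific peptides are
rejected as digestion products, doubly-neo peptides as ambiguous.
Peptides matching several proteome locations are excluded by default
(`multi_locus = "count_all"` keeps every location); exclusion counts are
reported, since neither choice can be validated without knowing how the
original analysis treated them. Windows are read P6...P6' from the
protein with `"-"` beyond the termini; gap positions are excluded from
the per-position event denominators rather than imputed.

Two heat maps are emitted. The raw map is the percent-of-column residue
frequency. The corrected map divides each observed frequency by the
proteome background frequency of that residue (fold enrichment over
natural abundance) and renormalizes columns; under a uniform background
the correction is the identity, which the tests assert. Both are
exported because display conventions for such heat maps vary and the
correction formula is the standard enrichment convention rather than a
documented external algorithm.

## Log-odds scoring and scanning

`build_log_odds()` converts a counts matrix into a position weight
matrix of log2 odds against a background composition with a
background-scaled Laplace pseudocount (default 1.0): weights are zero
when observation equals background, so site scores from
`score_window()` are bits above background and additive over any window
split; gaps contribute zero. `scan_sequence()` scores every eligible P1
position (optionally restricted, e.g. to Arg/Lys for trypsin-like
enzymes), gap-pads edge windows, and ranks by descending score with ties
broken by ascending position so output is deterministic.

Profiles from too few events are unreliable; following the accepted
limit for entropy-based specificity determination, profiles with fewer
than 30 events are flagged `low_confidence`, and a seeded multinomial
bootstrap (default B = 1000) gives percentile confidence intervals for
per-position entropy. The interval width shrinks with event count, which
the tests verify at n = 30 versus n = 300.

## Kinetic models

* **Initial rates.** Least-squares slope over the leading window of a
  progress curve, limited to 10% substrate depletion (estimated from the
  curve itself) and at least `max(4, 10%)` of the points; the depletion
  cap keeps the slope within ~1% of the true initial rate, the point
  floor keeps very fast curves estimable.
* **Michaelis-Menten.** Nonlinear least squares of
  `v = kcat E_active [S]/(KM + [S])` initialized from a Hanes-Woolf
  linearization, with the active-enzyme concentration taken from a burst
  titration. The catalytic efficiency `kcat/KM` is reported in
  M^-1 s^-1 with a delta-method standard error from the fit covariance.
  Fits are flagged when KM leaves 0.01-100x the designed substrate
  range.
* **Burst titration.** `A(t) = pi(1 - e^(-kt)) + mt + A0`; the burst
  amplitude converts to the molar active-site concentration through
  Beer-Lambert with defaults epsilon = 16,600 M^-1 cm^-1 (p-nitrophenol,
  410 nm, pH 8) and l = 1 cm, both overridable since extinction
  coefficients are assay-specific. If the exponential is faster than the
  sampling resolves, the amplitude falls back to the steady-state-line
  intercept and the fit is flagged rather than failed.
* **Dose-response.** Four-parameter log-logistic with free Hill
  coefficient (initialized at 1); the bottom plateau can be fixed at 0.
  The reported IC50 is the fitted curve midpoint, `v(IC50) =
  (top + bottom)/2` by construction. For rates measured with a constant
  coefficient of variation, `weights = "relative"` (inverse-squared
  rates, floored at 5% of the maximum) matches the error model and keeps
  the 95% intervals honest - the recovery tests show ~88% empirical
  coverage with weighting at 5% noise, versus ~76% unweighted.
* **Inhibition mechanism.** Global fits of the competitive,
  noncompetitive, uncompetitive and mixed rate laws (mixed uses an
  interaction factor alpha on the uncompetitive branch, initialized at
  1), ranked by the small-sample AICc since panels rarely exceed ~40
  points; Akaike weights quantify support and Eadie-Hofstee coordinates
  per inhibitor level give the classical graphical diagnostic (parallel
  lines for noncompetitive, common intercept for competitive). Because
  the mixed model nests the pure ones, a pure-mechanism truth caps the
  top weight near 0.73; the argmax is still the correct mechanism in
  >90% of simulated panels per mechanism at 2% noise, and restricting
  `mechanisms` to the pure trio yields decisive (>0.9) weights.
* **Activation.** `v([A]) = v0 (1 + (F-1)[A]/(K_act+[A]))` with an
  optional `1/(1 + [A]/K_att)` attenuation factor for the loss of
  stimulation at very high cation concentrations; AICc selects between
  the pure and attenuated variants, which accommodates both a saturating
  2-fold stimulation in the few-hundred-micromolar range and an optimum
  near 1 mM, two behaviours seen with different substrates.
  Monotone-decreasing data are rejected ("not an activator"). When the
  fitted stimulation is negligible the half-saturation constant becomes
  unidentifiable and the Levenberg-Marquardt wrapper cannot build its
  final model object; the fitter then profiles K_act on a log grid with
  the remaining parameters solved linearly, which always succeeds and
  returns the same optimum.

All fits are deterministic given data and starting values; the only
randomness anywhere in the package is in the simulators, which are pure
functions of their seed.

## What the simulators emulate

`generate_proteome()` draws i.i.d. residues from an embedded E. coli-like
composition (gamma-distributed lengths, mean 300, floor 60), so digestion
and location behave like a bacterial proteome library. It does **not**
emulate real protein structure: no domains, no repeats, no low-complexity
regions, and therefore fewer multi-mapping peptides than a real proteome
would produce.

`simulate_pics_experiment()` plants cleavage events inside
library-protease fragments, sampling candidate sites with probability
proportional to their likelihood under a truth profile relative to the
expected likelihood of a background window (the relative form keeps
gap-padded edge windows from being over- or under-sampled). Planted
peptides get log-normal fold changes (sigma = 0.3 in log2 units) resampled
until above the threshold, so planted counts are exact by construction;
decoys are fully specific fragments with arbitrary fold changes or
semi-specific peptides at or below the threshold. The packaged
"KLK8-like" truth profile is constructed from the qualitative published
preferences (P1 Arg >> Lys, aliphatic P2 dominated by Val, basic P3,
moderate Thr/Trp P4, Ser/Met at P1', Ile/Trp at P2', His/Tyr at P5'/P6')
and is documented as an emulation, not measured data. Instrument effects
- missed identifications, charge states, retention-time artefacts - are
out of scope, so passing tests demonstrate the correctness of the
reconstruction and correction arithmetic, not robustness to MS noise.

`simulate_psscl()` perturbs a truth rate matrix with multiplicative
Gaussian noise clipped at zero; at zero noise the reduction recovers the
truth exactly, which pins the reduction arithmetic. Kinetic simulators
draw rates from the closed-form laws with multiplicative noise; progress
curves integrate substrate depletion with fixed-step RK4 at 1 s, which
matches the closed-form initial slope to <0.5% at 5% depletion.

## Numerical choices

Nonlinear fits use Levenberg-Marquardt (minpack.lm) with analytic-free
bounds keeping parameters positive, initialized from linearizations
(Hanes-Woolf for saturation kinetics, plateau/midpoint heuristics for
dose-response). Percent normalizations are checked to 1e-9. Scan ties
break by ascending P1 index. Degenerate inputs fail loudly: all-zero
matrix columns, empty proteomes or plates, flat dose-response data,
panels without the required inhibitor levels.

Problem sizes in the tests and the acceptance script are chosen at desk
scale - a 500-protein proteome (~150k residues), 50-panel selection
studies, 20-seed recovery runs - large enough for the law-of-large-number
checks (composition within 0.5% absolute; profile recovery correlation
>= 0.9 at 300 events) while keeping a full run in well under a minute
per component.

## Known limitations

* Scoring is strictly sequence-based. Substrates that are recognized
  through their tertiary structure - where a basic residue from a
  neighbouring strand substitutes for the preferred P3 side chain - will
  score poorly even when they are efficiently cleaved; this is a known
  discrepancy between synthetic-library profiles and natural substrates
  and is outside what a position weight matrix can express.
* The PICS correction assumes position-independent residue usage; real
  proteomes have local composition biases the correction ignores.
* No tight-binding (Morrison) corrections in the inhibition fits, no
  temperature or pH dependence, and no spectrum-level MS processing.
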