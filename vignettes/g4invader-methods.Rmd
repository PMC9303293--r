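---
title: "Models and methods behind g4invader"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind g4invader}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(g4invader)
```

g4invader implements the quantitative workflow around LNA (locked nucleic
acid) invader probes: short oligonucleotides, reverse-complementary to a
G-quadruplex (G4) forming DNA strand, that hybridise into the structure and
convert it to a duplex. This vignette documents the models, the tunable
parameters, and the design decisions — especially where the underlying
science left the design genuinely open.

## Probe design

A G4 target is annotated by `find_g_tracts()`: maximal runs of G of length
`min_run` or more are G-tracts (default `min_run = 3`, one guanine per
layer of a three-layer tetrad stack, which matches both bundled model
sequences); the gaps between consecutive tracts are loops. Coordinates are
1-based inclusive throughout, sequences always written 5'→3', and only the
G-rich strand is represented — probes are derived from it by reverse
complementation, so no strand flag is needed.

`design_full_probe()` places a fixed budget of LNA modifications
(`n_lna`, default 4 — roughly 20% of a ~22-nt probe, enough added affinity
without perturbing the whole duplex) on the reverse complement of a target
footprint:

* **TRACT_3P** — opposite the guanines of the target's 3'-most tract;
  when the tract has fewer than `n_lna` guanines the mask extends into the
  adjacent loop base on the 5' side of the tract.
* **MIDDLE_G** — opposite the central guanine of each tract. For an
  even-length tract the "centre" is `floor((start+end)/2)`, i.e. the tie
  breaks toward the target 5' end; the bundled designs only exercise
  odd-length tracts inside their footprints, so this is a declared
  convention rather than a constraint from data. When the footprint holds
  more than `n_lna` tracts, the 3'-most `n_lna` are used.
* **LOOP_3P** — opposite the 3'-most bases of the target's 3'-most loop.
* **SCRAMBLED_LOOPS / SCRAMBLED_MIXED** — scrambled placements are by
  nature not reproducible from a rule, so they are stored masks validated
  by `annotate_probe_positions()`, never random draws.

Two catalogued designs carry documented overrides: the loop-targeting KIT
probe is one base shorter than its unmodified parent (its 5'-terminal T is
dropped, `drop_5prime = 1`) — the reason is not recorded in the source
material, so it is kept as a per-design length override; and the
scrambled short hTelo probe applies its stored mask to the truncated
footprint directly. `truncate_probe()` keeps the first `keep` (default 10)
nucleotides from the probe 5' end and drops mask positions beyond it; this
reproduces every published "short" probe.

`predict_kinetic_class()` condenses the placement into a coarse kinetic
expectation: tetrad-guanine contacts accelerate invasion, placements
scattered over several loops decelerate it, and an all-loop block confined
to one single (necessarily tract-adjacent) loop is classed NEUTRAL. The
single-loop/multi-loop distinction is this package's reading of an
empirically ambiguous situation — a 3'-loop block behaved like unmodified
DNA while loop-scrambled placements decelerated — and is documented as a
convention, not asserted as biology. Mixed placements are ACCELERATING
when more than half the LNA contacts are tetrad guanines, NEUTRAL
otherwise.

## Bulk FRET disruption kinetics

With the probe in excess, invasion is pseudo-first-order, so a normalised
disruption trace follows

$$P(t) = \text{plateau}\,(1 - e^{-kt}), \qquad t_{1/2} = \ln 2 / k .$$

`normalize_trace()` maps the raw signal to a 0–100% scale with the t = 0
signal at 0% and the *fitted plateau* (not the maximum observed point) at
100%; the fitted plateau is robust to noise in the final points, and
`saturation = "last5"` offers the mean-of-last-5-points alternative.
`fit_one_phase()` fits by Levenberg–Marquardt (minpack.lm) with k
initialised from a log-linear regression of $\log(\hat A - P)$ on t
($\hat A = 1.05 \max P$) and bounded to $(10^{-7}, 1)\ \mathrm{s^{-1}}$.
The baseline is co-fitted rather than pinned to the first point: anchoring
the curve at one noisy observation leaks that noise into k and understates
its standard error (with the baseline free, simulation at 2% noise gives
~2 SE coverage above 90% for half-lives from 628 to 8551 s; pinned, it
falls as low as 40%).

Biphasic traces (a fast decay ahead of the slow invasion phase) are
handled by `select_slow_phase()`: a two-phase model is accepted when the
extra-sum-of-squares F-test rejects at α = 0.05 *and* the two rates are
separated (ratio > 1.5) with non-trivial amplitudes. The fitted fast
component is then subtracted and the remainder rescaled so the slow phase
can be fitted as a clean one-phase trace. The exact windowing used for the
original slow-phase analysis is not recorded; this subtract-and-rescale
procedure is the package's convention.

`compare_half_lives()` implements the summary-statistic unpaired
two-tailed Student t test, $t = |\bar a - \bar b| / \sqrt{SEM_a^2 +
SEM_b^2}$ with $df = n_a + n_b - 2$, which is exactly the classic pooled
test when group sizes are equal. It reproduces the published comparisons
(e.g. 1753 ± 70 vs 628 ± 40, n = 3 → p ≈ 0.0002); one published hTelo
comparison (1967 ± 65 vs 1539 ± 18, p = 0.001) is not reproducible from
summary statistics alone (the formula gives ≈ 0.003, presumably raw
replicates were used), so the raw-replicate mode is provided as well and
that value is not asserted. Melting temperatures come from
`extract_tm()`: the heating branch is normalised between logistic-fitted
asymptotes and the 50% crossing is linearly interpolated; a curve whose
transition width exceeds a quarter of the scanned range, or whose
asymptotes fall outside it, is rejected as having no transition.

## Single-molecule mechanics

A tether carrying N folded G4 units shows hysteresis between its stretch
and relax force–extension curves: each unfolding event releases contour
length, and above 10 pN disrupted G4s do not refold, so the relax curve is
the fully unfolded reference. ssDNA elasticity follows the extensible
Marko–Siggia worm-like chain,

$$F = \frac{k_BT}{L_p}\left(\frac{1}{4(1-\varphi)^2} - \frac14 +
\varphi\right), \qquad x = L_c\left(\varphi + F/K\right),$$

solved for φ by vectorised bisection. Defaults — $L_p$ = 0.75 nm, K =
800 pN, $k_BT$ = 4.114 pN·nm (24 °C), 0.45 nm/nt — are typical ssDNA
values; the exact constants used originally are in unpublished supporting
material, so they are exposed configuration validated only by
self-consistency (the analyser inverts the generator exactly), never
against instrument data. Folded G4s are modelled as contributing zero
extension; their finite width is absorbed into the 9 nm-per-unit constant,
and bead/trap compliance is out of scope (inputs are already
force–extension pairs).

`build_delta_l_profile()` interpolates both curves onto a 0.5 pN grid over
the 10–50 pN window and computes
$\Delta L(F) = (x_{relax} - x_{stretch}) / \varphi_{unit}(F)$, smoothed
with a 5-point running median. `count_folded_g4()` divides by 9 nm per
telomeric G4 and rounds to the nearest integer; the total count is read at
10 pN. `half_force()` reports $F_{1/2}$, the smallest grid force where the
folded count drops to half the total, refined by linear interpolation
between bracketing grid points — for symmetric unfolding-force
distributions this tracks the sample median.

## Polymerase stop assay

`predict_stall_product_length()` locates the primer on the template (its
reverse complement must occur exactly once) and computes product lengths.
The halt convention — the last incorporated nucleotide pairs with the
template position immediately 3' of the G4 motif, i.e. the polymerase
cannot enter the structure — is not observable from gel data at
single-nucleotide resolution, so a `stall_offset` parameter shifts it.
On the bundled 91-nt template (printed length used literally, although it
is described as ~90 nt) with its 20-nt primer and the G4 at positions
33–53 this gives a 38-nt stalled and a 91-nt full-length product.
`quantify_lane()` subtracts the median out-of-window intensity as
background, integrates the `full` and `stalled` windows and reports their
ratio; an optional `probe_duplex` window captures the high-molecular-weight
probe/template duplex band but is excluded from the ratio. A stalled band
within 3 standard deviations of the background noise is treated as absent
(undefined ratio) rather than producing an unstable quotient.

## Reporter statistics

`analyze_reporter()` chains the published scheme: per-well Renilla/Firefly
ratios, max-normalisation to 100% *within each biological dataset*
(normalisation of replicates is the default; normalising condition means
first is provided since the original description is ambiguous), a
Shapiro–Wilk check per condition (Royston's approximation via
`stats::shapiro.test`; at n = 3 the test has almost no power, which is
documented rather than "fixed"), a one-way ANOVA gate, and Dunnett's
many-to-one comparison against the plasmid-only control.

The Dunnett adjusted p-value is computed by deterministic quadrature:
conditioning on the shared control variate and the pooled-scale chi
variate factorises the equal-correlation multivariate t
($\rho_{jl} = \sqrt{n_j n_l/((n_j+n_0)(n_l+n_0))}$, 1/2 when balanced)
into a product of normal probabilities, integrated on a 201 × 201
trapezoidal grid (accuracy ~1e-4, checked against multcomp's
implementation in the test suite, which also verifies the
unadjusted ≤ adjusted ≤ k·unadjusted bounds and family-wise error control
under a 1000-seed null).

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its spec including an explicit seed
(no hidden RNG state), and each generator/analyser pair closes the loop:
on noise-free output the analyser returns the generating parameter
exactly. Noise is Gaussian throughout — multiplicative on the fluorescence
plateau (default 2%), additive on extension, absorbance and gel intensity —
because no noise model was published; magnitudes were chosen once to match
the order of magnitude of the published SEMs.

Defaults encode the study conditions: 30 s (hTelo) or 120 s (c-KIT1)
sampling; trace duration three times the (slow) half-life, the shortest
span that still constrains the plateau; the biphasic control condition
uses a 40% amplitude, 100 s half-life fast component ahead of its 8551 s
slow phase; pull cycles draw unfolding forces from Normal(25.4, 4) pN
truncated above 10 pN (the spread is not published; 4 pN is a convention
used only for recovery tests) on a 3000 nm handle; gel lanes place
Gaussian bands (σ = 2.5) at positions 35 and 65 over a flat background of
20 a.u., with 5% area jitter between replicate lanes. Only progression
*folds* were published, so the absolute lane ratios (K⁺ 0.5, Li⁺ 3.0,
K⁺+LNA 2.5, K⁺+DNA 0.55) are the package's fixed realisation of the ~6×
and ~5× folds.

What passing tests show is therefore internal consistency: the estimators
recover known parameters under the stated noise at desk scale. They do not
show robustness to the features real instrument data add — photobleaching
and drift in fluorescence, bead Brownian noise and tether-to-tether
variability in force spectroscopy, smears and lane distortion in gels —
all of which are explicitly out of scope.

## Numerical choices and limitations

* Problem sizes: recovery studies use 20–100 seeds per condition, five
  molecules per mechanics condition, 1000 seeds for the family-wise error
  null — sizes at which every simulation completes in seconds while the
  Monte-Carlo error stays well inside the asserted tolerances.
* Degenerate inputs fail loudly with classed errors: flat traces, melting
  ramps without plateaus, stalled bands at background, zero-variance
  samples, cycles not covering the 10–50 pN window.
* Ties and tie-breaks are declared: probe alignment ties resolve toward
  the target 3' end; even-tract centres toward the target 5' end.
* Degenerate IUPAC bases are rejected rather than expanded.
* The half-life identity $t_{1/2} k = \ln 2$ holds exactly by
  construction, and reported standard errors are delta-method propagated
  from se(k).
* Known limitations: no G4 topology or thermodynamic (ΔG/Tm) prediction
  for LNA duplexes, no off-target genome scanning, no kinetic
  (Bell/Dudko) analysis of unfolding forces, no gel image segmentation —
  lane profiles enter as 1-D traces.

## A worked micro-example

```{r example}
kit <- g4_targets()$cKIT1
probe <- design_full_probe(kit, strategy = "MIDDLE_G", name = "KIT_LNA3")
probe

tr <- gen_fret_trace(t_half = 628, sampling_interval = 120,
                     noise_sd = 0.02, seed = 1)
fit <- fit_one_phase(normalize_trace(tr))
glance(fit)
```
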