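---
title: "Methods: culm biomechanics, trial statistics and the array pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: culm biomechanics, trial statistics and the array pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Lodging — the permanent displacement of the stem from vertical — is a
major yield-limiting failure mode of rice, particularly in typhoon-prone
coastal regions. Whether a culm lodges is governed largely by its three
lowest elongated internodes (numbered I1–I3 upward from the base): their
length sets the lever arm and their cross-sectional geometry and
dry-matter density set the mechanical resistance. Nitrogen management
shifts both: heavy early nitrogen elongates the lower internodes and
thins their walls, while a reduced, delayed application shortens them
and thickens the wall. `culmr` quantifies this chain from
internode-level field measurements, analyses the accompanying
split-plot trial, and processes the companion two-color microarray
comparison of the two managements.

# Culm mechanics

The culm is treated as a hollow circular cylinder of outer radius $a$
(half the measured mid-internode diameter) and wall thickness $t$,
both taken at mid-internode. The derived quantities, with the boundary
units used throughout the package, are:

* **Section moment of area** (mm$^4$):
  $I = \dfrac{\pi a^4}{4}\left[1-\left(1-\dfrac{t}{a}\right)^4\right]
     = \dfrac{\pi}{4}\left(a^4-(a-t)^4\right).$
  At $t=a$ this reduces to the solid rod $\pi a^4/4$. The two algebraic
  forms are identical; the implementation is verified against direct
  numerical integration of $\int y^2\,\mathrm dA$ over the annulus.
* **Elastic modulus** (GPa), from a three-point bending test with
  mid-span load $F$ (N), support span $L$ (cm, default 5 — the fixture
  distance, *not* the internode length) and mid-span deflection
  $\delta$ (cm): $E = F L^3 / (48\,\delta\,I)$, computed in SI and
  reported in GPa. It is only defined for elastic tests in which the
  internode recovers after unloading.
* **Flexural rigidity / bending stiffness** ($10^{-3}$ N m$^2$): the
  product $E I$. The trial-table convention of "section modulus times
  section moment of area" is read as $E \cdot I$: this gives the
  printed units (N m$^2$) and agrees numerically with published
  stiffness columns to a few percent, the residual being a
  ratio-of-means effect (a mean of per-culm products is not the
  product of means). GPa·mm$^4$ equals $10^{-3}$ N m$^2$ exactly, so
  no rounding enters the conversion.
* **Bending moment** (gf cm): distance from the internode base to the
  panicle tip times the fresh weight of that section — the
  gravimetric self-load moment.
* **Breaking resistance** (N): the minimum mid-span force that snaps
  the internode on the 5 cm fixture. Internodes shorter than the span
  cannot be tested; their breaking force is recorded as absent, and
  `validate_internode_records()` enforces this.
* **Lodging index**: bending moment over breaking resistance; higher
  means more lodging-prone. Two denominator conventions are
  implemented and recorded in the result's `li_mode` attribute:
  `"force"` (breaking force converted to gram-force, 1 gf = 9.80665
  mN — the literal ratio) and `"moment"` (the mid-span breaking
  moment $F\,\mathrm{span}/4$, which makes the index dimensionless).
  Published lodging-index magnitudes in this literature are often not
  recoverable from the printed bending moments and breaking forces
  under either convention (they differ by two orders of magnitude),
  so the package makes the convention explicit instead of guessing a
  rescaling. Ratios and treatment contrasts of the index are
  convention-free, because both modes rescale BM/F by a constant.
* **Culm volume** (cm$^3$): $V=\pi L (2at-t^2)$, identical to the
  shell difference $\pi L (a^2-(a-t)^2)$; and the two **plumpness**
  densities, dry weight per unit length (mg cm$^{-1}$) and per unit
  volume (mg cm$^{-3}$).

`mech_profile()` derives all nine quantities per record, leaving a
field `NA` whenever any of its inputs is absent — silent zeros would
poison downstream group means, so absent stays absent and summaries
report available-case `n`.

# Field-trial statistics

The trial layout is a split-plot (split-block) design: nitrogen
management on whole plots, variety on subplots, in four replicate
blocks. The design name fixes the randomization but not the error
structure; the package fits the standard split-plot decomposition —
replicate, whole-plot factor, replicate-by-whole-plot interaction
(whole-plot error), subplot factor, interaction, residual (subplot
error). The whole-plot F test uses the whole-plot error; subplot tests
use the residual. Sums of squares are the exact balanced-design
quantities, checked in the tests against both per-observation
brute-force enumeration and `aov()` with an `Error()` stratum.
Unbalanced layouts are refused rather than imputed.

Because the replicate plot is the experimental unit, `summarize_traits()`
first averages culms within each plot and only then computes the group
mean and standard error over plot means. Treatment letters use
Fisher's LSD at $\alpha = 0.05$ with the appropriate error stratum; no
further multiplicity adjustment is applied, matching the two-treatment
comparisons of agronomy trial tables (only two nitrogen levels are
ever compared within a variety).

Percent change is always OPT relative to FFP, $(\bar x_{OPT} -
\bar x_{FFP})/\bar x_{FFP}\times 100$, rounded to one decimal as in
the tables. Multi-internode averages are the *unweighted mean of
per-internode percent changes* (mean of ratios), not the ratio of
sums — the two differ, and the mean-of-ratios convention is the one
that reproduces published multi-internode averages. Harvest index is
the literal ratio of grain yield to total biomass; note that trial
reports often print grain yield at 14% moisture against oven-dry
biomass, so a printed harvest index can sit a few percent below the
literal ratio of the printed components.

# The two-color microarray pipeline

Arrays are 44k-style two-color hybridizations with the reference
management in Cy3 and the optimized management in Cy5, three
biological replicates, no dye swap (the pipeline preserves that fixed
orientation). The stages are:

1. **Filtering** (`filter_features()`): probes flagged bad by the
   scanner are dropped; both channels are floored at intensity 1 so
   log transforms stay finite. Scanner-specific quality metrics vary,
   so the flag-plus-floor rule is deliberately minimal.
2. **MA transform**: $M=\log_2(\text{Cy5}/\text{Cy3})$,
   $A=\tfrac12\log_2(\text{Cy5}\cdot\text{Cy3})$.
3. **Loess normalization** (`loess_normalize()`): a robust
   local-linear fit of M on A (tricube weights, three robustness
   iterations, span 0.3) is subtracted. The fit is global over the
   array — print-tip layout is treated as unknown — and relies on the
   usual assumptions that most probes are non-differential and that
   differential signal is roughly symmetric; a strongly asymmetric
   DEG population would be partially absorbed into the trend. The
   span is wide enough that every window holds hundreds of probes on
   a 44k array; spans leaving fewer than 10 points per window are
   refused.
4. **Per-feature testing** (`test_features()`): the mean normalized
   log ratio over replicates, with a two-sided one-sample t test
   against zero. With three replicates this is a 2-df test — blunt,
   but it is the test implied by "mean of three biological replicates
   with a p cutoff" when no moderated statistic is specified. Probes
   with zero variance get `p_value = NA` and a `degenerate` flag; a
   p-value is never fabricated.
5. **DEG calling** (`call_degs()`): the joint criterion of at least a
   two-fold mean change ($|\overline{M}|\ge 1$) *and* raw
   $p \le 0.05$. No multiple-testing correction is applied at this
   stage — the fold-change gate is what controls the false-call rate
   (under a pure-noise array with sd $\le 0.25$ the joint rate is
   below $10^{-4}$) — while GO enrichment p-values *are*
   Benjamini–Hochberg adjusted across terms.
6. **GO enrichment** (`go_enrichment()`): upper-tail hypergeometric
   test of each term's overlap with the gene list against the
   annotated universe, verified against exhaustive combinatorial
   enumeration for small universes.
7. **qPCR concordance** (`qpcr_concordance()`): OLS of qPCR log2
   ratios on array log2 ratios for a validation panel;
   `ddct_to_log2fc()` converts comparative-Ct values
   ($\log_2 FC = -\Delta\Delta C_t$), with the reference gene a
   property of the input data, not a constant.

# Synthetic data: what it emulates and what it does not

The generators exist so that every stage is testable offline with
known truth.

`gen_field_trial()` draws culm measurements hierarchically: a
replicate-plot effect Normal$(0, sd_{plot})$ with $sd_{plot} =
SE\sqrt{n_{reps}}$ (the plot-level spread implied by a printed
standard error over $n_{reps}$ plots), then culm values around the
plot mean with $sd_{culm} = 2\,sd_{plot}$ — published tables report
only plot-level dispersion, so the within-plot factor of 2 is a
package choice on the scale typical of culm-to-culm variation.
Positivity and the wall-within-radius constraint are enforced by
rejection resampling. Three derived fields are constructed to be
internally consistent rather than independently drawn: the bending
lever arm is the simulated plant height minus the summed lengths of
the internodes below; the fresh weight above the internode equals the
sampled bending moment divided by that lever arm; and the bending-test
deflection is back-computed from the sampled elastic modulus, so
`mech_profile()` recovers the configured mechanics exactly. Internode
fresh weight assumes 75% moisture (fresh = 4 x dry). The default
configuration ships as an editable CSV emulating a two-variety,
two-management South-China trial with four replicates; with
`sd_scale = 0` the generator reproduces the configured means exactly.

`gen_two_color_arrays()` plants a known differential structure
(by default 665 up- and 713 down-regulated probes among 45,018, with
$|\log_2 FC|\sim U(1.5,3)$), adds per-replicate Gaussian log-ratio
noise (sd 0.15) and a smooth intensity-dependent dye bias (sinusoid
plus gentle quadratic in A, bounded by ~0.6 — large enough that
un-normalized calls are visibly wrong, so the loess stage is
exercised meaningfully), and reconstructs channels from (A, M).
Latent intensities are Uniform(6, 14) per probe, shared across
replicates.

What the simulations do **not** contain — and hence what passing
tests do not demonstrate about real data: spatial array artifacts and
print-tip effects, heavy-tailed or intensity-dependent noise,
probe-sequence effects, cross-hybridization, real GO annotation
structure, field spatial trends, measurement error correlated across
traits, and non-Gaussian trait distributions. The pipeline's recovery
of planted truth shows the machinery is correct, not that any
particular biological dataset meets its assumptions.

# Numerical choices and degenerate inputs

* All internal mechanics are computed in SI; boundary units are fixed
  to the field's conventions (mm geometry, cm lengths/deflections, N
  forces, GPa moduli, $10^{-3}$ N m$^2$ stiffness, gf cm moments).
  The gram-force conversion uses 1 gf = 9.80665 mN exactly and
  round-trips to $10^{-12}$.
* Degenerate ANOVA strata (zero variance) report `NA` F and p rather
  than 0/0 artifacts; empty summary groups are dropped with a
  warning; zero-denominator percent changes and harvest indices are
  domain errors.
* Letter assignment sorts means descending and gives maximal
  mutually-non-significant runs a shared letter; exact ties share a
  run by construction.
* Generators save and restore the caller's RNG state, so they are
  pure functions of (config, seed).
* Test problem sizes are chosen to make Monte-Carlo checks sharp but
  quick: 2,000 null trials for the type-I error of the whole-plot
  test, 10,000–20,000 probes for null-array rate checks, 500
  simulations for percent-change recovery, and one full-scale
  45,018-probe, three-replicate recovery run. The full suite runs in
  about a minute.

# Known limitations

* The one-sample t test with three replicates has low power for
  $|\log_2 FC|$ near 1; a moderated (empirical-Bayes) variance would
  help real data but is outside the minimal replicate-test contract
  implemented here.
* Fisher's LSD without adjustment is appropriate for the
  two-treatment contrasts it is used for; with many groups it is
  anti-conservative.
* The split-plot model assumes homoscedastic strata and no spatial
  field trend.
* Published lodging-index and harvest-index magnitudes can embed
  unit or moisture conventions that their printed components do not
  determine; the package computes the literal definitions and leaves
  such gaps visible rather than rescaling toward any particular
  published value.
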