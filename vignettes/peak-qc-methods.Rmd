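---
title: "Methods: VAF-peak quality control of copy number calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: VAF-peak quality control of copy number calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vafqc)
library(dplyr)
```

This vignette documents the statistical model behind `vafqc`, the conventions
the package fixes where several defensible choices exist, and the known
limitations of the approach. It is the design record for the package: every
rule stated here is the one implemented, with its rationale.

## The clonal peak model

A somatic mutation on a clonal segment with allele-specific copies
$n_A\!:\!n_B$ is present on $m$ of the segment's copies (its *multiplicity*)
in every tumor cell. In a bulk sample of purity $\pi$, reads covering the
locus come from $2(1-\pi)$ normal copies and $\pi(n_A+n_B)$ tumor copies per
cell on average, of which $m\pi$ carry the variant. Writing $p = n_A+n_B$,
the VAF of clonal mutations therefore concentrates at

$$ v_m(\pi) = \frac{m\,\pi}{2(1-\pi) + \pi p}, $$

one peak per legal multiplicity. For the *simple* states the legal sets are:
$m=1$ for 1:0 and 1:1, and $m \in \{1, 2\}$ for 2:0, 2:1 and 2:2 (a
single-copy gain can precede or follow the mutation). Everything else is
*complex* and screened with multiplicities $1..\max(n_A, n_B)$.

`expected_vaf()` and `peaks_for_karyotype()` implement this. The same
equation with a cancer cell fraction $c$ multiplying $m\pi$ in the numerator
gives subclonal positions, and inverting it per mutation gives the CCF
estimate in `ccf_from_vaf()` (never clipped: values above 1 are informative
noise, flagged as outliers above 1.5).

## Error propagation and the acceptance interval

The tolerance the user controls, $\epsilon$, is in *purity units*: how large
a purity error the QC should forgive. First-order propagation through
$v_m(\pi)$ gives the VAF-space equivalent

$$ \Delta v_m(\pi,\epsilon) = \frac{2m\,\epsilon}{[2(1-\pi)+\pi p]^2}, $$

(`vaf_error_from_purity_error()`), and the exact inverse direction maps a
measured VAF offset back to a purity correction
(`purity_error_from_vaf_error()`); the two compose to the identity to
machine precision, which the test suite asserts on a parameter grid.

**Interval convention.** A detected peak $d_*$ is accepted for an expected
peak $v_m$ when two intervals overlap: the expected peak's band and the data
peak's band $[d_* - \sigma_v, d_* + \sigma_v]$, where $\sigma$ (default
0.02, purity units) absorbs peak-detection noise and is converted to VAF via
$\Delta v_m$. The expected band half-width is the *exact two-sided image* of
the purity tolerance,

$$ h = v_m(\pi + \epsilon) - v_m(\pi - \epsilon) \;\approx\; 2\Delta v_m, $$

implemented in `vaf_acceptance_halfwidth()`. With the first-order one-sided
$\Delta v_m$ instead, a diploid sample at $\pi = 0.6$, $\epsilon = 0.025$
would accept peaks in $[28.75\%, 31.25\%]$; with the two-sided image it
accepts $[27.5\%, 32.5\%]$ and a purity estimate in $[55\%, 65\%]$, which is
the behavior this package fixes ($\sigma = 0$ in that statement). The
one-sided $\Delta v_m$ remains the published propagation function; only the
*matching band* uses the two-sided image.

## Peak detection

Two detectors are provided (`detect_peaks()`):

* **KDE** (`kde_peaks()`): Gaussian kernel density with *fixed* bandwidth
  0.01 — the same scale as the 0.01-wide support-counting bins — keeping
  local maxima at $\ge 1/20$ of the tallest peak and with topographic
  prominence $\ge 25\%$ of their own height. The prominence rule prunes
  sampling wiggles riding on a genuine mode while keeping well-separated
  peaks; boundary maxima are kept so a mass of near-fixed mutations at VAF
  1 is not lost.
* **Binomial mixture** (`fit_binomial_mixture()`): EM over alt/total read
  counts for 1–4 components, selected by the integrated classification
  likelihood (BIC plus twice the responsibility entropy), deterministically
  initialized (VAF quantiles plus seeded restarts).

**Peak-position refinement.** The KDE argmax is quantized by the read-count
lattice (VAFs live on multiples of $1/\mathrm{depth}$), so matched positions
are sharpened by the pooled ratio $\sum nv / \sum dp$ of the mutations
within a window around each peak (half the gap to the neighboring peak, at
most two binomial standard deviations). This estimator converges at the
usual root-$n$ rate and is what makes the sample score precise enough to
*suggest* a corrected purity, not only to pass/fail.

Refinement has a validity regime: it is applied only when the lattice
spacing $1/\mathrm{median(depth)}$ is below twice the KDE bandwidth. On
coarser data (roughly below 50x) the read-count atoms are resolved features
of the density itself, and pooling across them biases the position by up to
the lattice spacing; there the raw density modes are kept. This is also the
honest behavior for QC purposes: at 20x the data genuinely cannot localize
peaks below the lattice scale, and the calibration curves (below) quantify
the false-positive cost.

## Karyotype and sample status

Per karyotype, mutations are pooled genome-wide (or per chromosome), each
expected multiplicity peak is matched to the *closest* detected peak
(optionally only peaks to the right, to hunt miscalled deletions), and the
karyotype's status is the matched flag of the peak carrying the most
mutations — majority voting weighted by mutation counts in the 0.01 bin of
the matched peak.

At the sample level each karyotype contributes weight $w_k$ = its share of
the simple-clonal mutation mass, split evenly over its peaks. The signed
score

$$ \lambda = \sum_{k\,\in\,\mathrm{pass}} \lambda^{\mathrm{PASS}}_k +
             \sum_{k\,\in\,\mathrm{fail}} \lambda^{\mathrm{FAIL}}_k $$

is the weighted mean of peak offsets converted to purity units: pass-status
karyotypes contribute their matched-peak offsets, fail-status karyotypes
their unmatched-peak offsets. The sample **passes** when both

1. the mutation mass carried by pass-status karyotypes is at least the
   fail-status mass, and
2. $|\lambda| \le \epsilon$.

On failure, `purity + lambda` is reported as the suggested purity; feeding
it back to the caller re-centers the peaks. The two conditions play
different roles: the mass vote is the collective matched/unmatched verdict,
robust on coarse data where offsets are lattice noise; the $|\lambda|$ cut
adds a precise guard exactly in the regime (high coverage and purity) where
$\lambda$ estimates the true purity error to a few tenths of a percent. Our
simulation study (in the test suite) shows the fail fraction is ~0 for
injected errors under $\epsilon$ and ~100% from $2\epsilon$ on, with
$\lambda$ tracking the injected error linearly ($R^2 > 0.9$, slope ~1).

## Complex and subclonal segments

Complex states are screened with the KDE detector alone and a raw VAF-space
tolerance (no purity-unit conversion), reporting the fraction of matched
multiplicity peaks; they never enter the sample score (`qc_complex()`).

For a segment carrying two subclones with simple states and proportions
$\rho_1 + \rho_2 = 1$, shared mutations peak at

$$ v_{\{m_1,m_2\}} =
   \frac{(m_1\rho_1 + m_2\rho_2)\,\pi}{2(1-\pi) +
   \pi(\rho_1 p_1 + \rho_2 p_2)}, $$

and clone-private mutations at the same expression with the other clone's
multiplicity set to zero. The multiplicity pairs $(m_1, m_2)$ are not free:
they are determined by the *evolution model* connecting the two states.
`enumerate_evolution_models()` builds every branching and linear model from
a diploid ancestor by exhaustive search over shortest allele-labelled event
paths (gain/loss per allele plus whole-genome doubling), replaying events on
physical chromosome copies to count how many copies a mutation from each
era survives on. Models are deduplicated up to global allele swap; linear
chains keep only the labelled variants achieving the minimal total event
count. The enumeration is verified in the test suite against an independent
brute-force token-propagation oracle over all pairs of simple states.

A truncal configuration on an allele later lost by one clone (e.g.
$(m_1, m_2) = (1, 0)$) coincides in VAF with a clone-private peak; the peak
table collapses such duplicates and keeps the combined provenance label.

`qc_subclonal()` matches every model's predicted peaks with a raw VAF
tolerance and selects the model with the highest matched fraction;
peak-identical ties are reported as `indistinguishable` (e.g. linear versus
branching for a 1:1/1:0 pair), genuine ties as `ambiguous`, and below 50%
matched as `none`. Mirrored allelic imbalance (the two clones amplifying
*different* alleles) is detectable only through its asymmetric shared pair
— two peaks straddling the balanced position a few percentage points apart
— and therefore needs deep data: at 150x the pair physically merges under
binomial noise; the regression test uses 600x.

## CCF and multiplicity phasing

On 2:0, 2:1, 2:2 segments a mutation's multiplicity is ambiguous, so the
CCF $c_m(v) = v\,[(p-2)\pi + 2]/(m\pi)$ needs $m$ phased first. The
*entropy method* fits the two-component binomial mixture anchored at the
theoretical peaks $v_1, v_2$ (trials = median depth; mixing weights from
the VAF quantile-range counts), computes per-VAF assignment entropy
$H(z)$, and abstains (`m = NA`) inside the interval around the central
entropy spike where $H$ exceeds half of $\ln 2$. The half-height bracket is
the package's convention: the profile is located with the same KDE
machinery, but clean data has no reliable flanking minima to bracket with,
while the half-height points are stable. The *rough method* cuts at the
entropy midpoint and never abstains. `ccf_qc()` fails a karyotype when
more than 10% of mutations are unassignable (strict inequality), signaling
that downstream subclonal deconvolution would be confounded by multiplicity
intermixing.

## Fragmentation screening

Excess segmentation of a chromosome arm is screened with a one-sided
binomial tail test: under the null a fraction $\mu = 0.2$ of an arm's
segments are "short" (length under $\mu$ times the arm); an arm with $k$
segments and $s$ short ones gets $P(X \ge s)$, $X \sim \mathrm{Bin}(k,\mu)$,
Bonferroni-corrected across tested arms. Arms qualify for testing only with
$\ge 10$ segments and a total ploidy jump $\sum_i |p_{i+1} - p_i| \ge 1$;
segments are smoothed first (adjacent runs with equal alleles merged across
gaps up to 1 Mb). Arm coordinates for hg19/GRCh38 ship as plain-text
tables.

## Simulator and calibration

`simulate_tumor()` draws per-chromosome segment counts Poisson(6), simple
states with concentration weights 1:1:6:2:1 over 1:0, 2:0, 1:1, 2:1, 2:2
(pan-cancer relative frequencies), Poisson depths, and binomial alt counts
at the theoretical peak of a uniformly drawn legal multiplicity, on real
autosome lengths. Two realism rules matter downstream:

* a **detection floor** (`min_alt_reads = 2`): no variant caller emits
  mutations supported by 0–1 reads, so the simulator drops them. At 20x
  and low purity this reshapes the observable VAF distribution (the
  lattice atoms at 2/depth, 3/depth, ... are what a real call set shows);
  at 45x+ it is a no-op.
* everything is a deterministic function of `seed`.

`build_fpr_grid()` measures the false positive rate (FPR) of the sample QC:
for each purity/coverage cell and each $\epsilon$, tumors are simulated at
the true purity and QC'd with input purity $\pi + \epsilon + \varphi$,
$\varphi \sim U[0, 0.03]$ — inputs that should *fail* (the error exceeds
the tolerance) — and the pass fraction is recorded. On the shipped frozen
grid (regenerable bit-exactly from its stored seed), FPR rises with
$\epsilon$ within every cell, stays below 10% at $\epsilon = 0.01$ for
high-quality data (120x, purity 0.9), and is ~30% at $\epsilon = 0.01$ —
rising to ~100% — for 20x at purity 0.15, where the VAF lattice prevents
peak localization below the tolerance scale. `suggest_epsilon()` inverts a
per-cell binomial GLM for the largest $\epsilon$ keeping predicted FPR at
or below the target (capped to user bounds) and interpolates cells to the
query point with a tensor-product Akima non-smoothing spline (bilinear
fallback), refusing to extrapolate outside the grid hull.

Note the inversion direction: because FPR *increases* with $\epsilon$,
high-quality cells (FPR under target throughout) invert to the upper cap,
and poor cells collapse to the floor. A larger suggested $\epsilon$ does
not mean lower quality data; it means the data can afford a loose tolerance
without admitting false passes.

## Scaled-down defaults and limitations

* Test-suite and frozen-grid simulation sizes (few chromosomes, reduced
  replicates) are this package's own scaled-down study designs chosen to
  run on one CPU in minutes; the generative *model* is not simplified.
* The simulator draws mutations at theoretical peaks with pure binomial
  noise: no over-dispersion (beta-binomial), no mapping artifacts, no
  subclonal SNV clusters outside designated subclonal segments. FPR
  estimates are therefore optimistic lower bounds for messy real data.
* Complex-state screening has no evolution-model backing (multiplicities
  are unconstrained), and the two-subclone model assumes exactly two
  clones with simple states.
* The fractional-copy-number decomposition (`decompose_fractional_cn()`)
  is a heuristic grid search assuming one clonal and one subclonal integer
  solution; its published worked example contains internally inconsistent
  printed values, and this package follows the stated step formulas, which
  still select the same candidate on that input.
* Sample-level QC needs $\ge 20$ mutations per karyotype; below that the
  karyotype is skipped and, with no usable karyotype, the status is
  `CANNOT_QC` rather than a guess.
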