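---
title: "Methods: from LC-MS features to macroevolutionary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from LC-MS features to macroevolutionary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, assumptions, and numerical choices
behind each stage of the `chemophylo` pipeline, and what the synthetic
generators do and do not emulate.

## Mass arithmetic and annotation

All masses are monoisotopic, built from a fixed table of atomic masses
(C = 12 exactly, H = 1.0078250319, O = 15.9949146221, N, S, Na) with
explicit electron-mass corrections for ions: a protonated ion sits at
`M + 1.00727645` (proton mass, not the hydrogen atom mass). Two
identities anchor the rules: the [M+Na]+/[M+H]+ spacing is the Na−H *ion*
difference, 21.98194 (reported rounded as 21.98), and acetylation adds
C2H2O = 42.0106 (reported rounded as 42.011).

Cardenolide annotation proceeds per chromatographic peak group
(co-eluting features within `rt_tol`, default 0.05 min):

1. **Adduct pairing.** Positive-mode features whose spacing matches
   21.9819 within `mz_tol` (default 0.005 Da) are paired; a feature joins
   at most one pair, conflicts resolved greedily by descending combined
   intensity and, on exact ties, by lower feature id. Requiring the pair
   (the default) is what prevents in-source fragments from being mistaken
   for parent ions.
2. **Genin detection.** A genin is supported by [genin+H−kH2O]+ ions,
   k = 0, 1, 2; candidates are ranked by the number of matching ions,
   then by descending genin mass (heavier genins are harder to match by
   accident).
3. **Chain inference.** The parent-minus-genin mass difference is matched
   against all chains of at most two sugar residues plus an optional
   acetyl. The residue table creates a genuine isobaric collision —
   hexose + digitoxose equals two deoxyhexoses to within a millidalton —
   which is resolved by outer-sugar neutral-loss fragments
   ([M+H−outer]+). When no fragment discriminates, the chain is chosen
   by a deterministic priority (fewest sugars, non-acetylated,
   alphabetical) and flagged `order_resolved = FALSE` rather than
   guessed silently.
4. **Isomers.** Annotations sharing a neutral mass (within class) get
   `isomer_index` by ascending retention time, matching how isomeric
   compounds are distinguished chromatographically.

Glucosinolates are screened in negative mode against a library of [M−H]−
targets; non-library [M−H]− ions co-eluting with at least `min_diag`
(default 2) of the class-diagnostic fragments (sulfate/thio fragments,
e.g. 96.9601, 95.9528, 74.9915) are reported as unknown candidates rather
than dropped.

Quantification uses, per compound, whichever adduct ([M+H]+ or [M+Na]+)
carries more total intensity across all samples — a global choice, so a
compound is quantified on the same ion everywhere.

## Profile assembly

Standardized ion counts (divided by dry mass and dilution, scaled by the
internal standard; pooled samples use the mean contributor mass) are
transformed as `log(x + 0.1)` and combined across experiments with the
mixed model

\[ y_{sce} = \mu_c + \beta_e + u_{sc} + \varepsilon_{sce}, \qquad
   u_{sc} \sim N(0, \sigma_u^2), \]

fitted by REML (`lme4`), with the first experiment as the reference level
(\(\beta_{ref} = 0\)). Species-level profiles are \(\mu_c + u_{sc}\),
floored at zero on the log scale (a negative assembled mean means "below
the zero offset", i.e. absent). Compound totals back-transform only the
positive entries, \(\sum_{m>0} (e^m - 0.1)\). When the design has a
single experiment or is noise-free, a closed-form balanced fit replaces
the mixed model; the two agree in the noiseless limit, where recovery of
the generating parameters is exact.

The BLUPs \(\hat u_{sc}\) are shrunken toward zero relative to raw
species deviations — the test suite checks the shrinkage property rather
than pretending the raw cell means are recovered.

## Chemodiversity statistics

Bray-Curtis dissimilarities are computed on row-proportions, so profile
scale is irrelevant by construction. Chemograms use Ward clustering on
the unsquared dissimilarities (`ward.D`). Cluster support is AU
(approximately unbiased) from multiscale bootstrap: columns are resampled
at relative sizes 0.5–1.4 (step 0.1); per-cluster bootstrap probabilities
are z-transformed and fitted by weighted least squares in
\(\sqrt{scale}\); AU = \(1 - \Phi(d - c)\). Bootstrap probabilities are
clamped to \([0.5/n_{boot}, 1 - 0.5/n_{boot}]\) before the probit
transform; clusters with bp pinned at 0 or 1 on every scale are flagged,
since the curvature of the z-fit is then underdetermined and AU is
conservative.

PCoA is classical scaling of \(-D^2/2\) double-centered; axis signs are
fixed by making each axis's largest-magnitude loading positive, so
results are reproducible across platforms. Negative eigenvalues (possible
for non-Euclidean Bray-Curtis matrices) are reported, not corrected.

The Mantel test correlates upper triangles under simultaneous row/column
permutation with an add-one two-sided p. When the full permutation group
is no larger than `n_perm` the test enumerates it exhaustively (for n = 4
that is all 24 permutations) and the identity permutation plays the
add-one role, so p is never 0 and exact for tiny matrices.

## Phylogenetic statistics

Blomberg's K uses the Brownian covariance \(V\) (shared root-to-MRCA
branch length), the GLS phylogenetic mean
\(\hat a = (1'V^{-1}1)^{-1} 1'V^{-1}x\), and the ratio of observed to
Brownian-expected MSE\(_0\)/MSE, with expectation
\([\mathrm{tr}(V) - n/(1'V^{-1}1)]/(n-1)\). K is identically 1 on two-tip
trees — a degenerate case the tests pin down. Significance comes from
permuting trait values across tips (add-one p), or from Brownian
simulation as an alternative reference.

PGLS solves the GLS normal equations with the same \(V\) and tests all
non-intercept terms by an F statistic with (q, n − p) degrees of freedom.
Ancestral states solve the branch-length-weighted Laplacian system, which
for Brownian motion coincides with maximum likelihood (and with
squared-change parsimony weighted by inverse branch lengths).

Tip rates: node density (ND) is the number of internal nodes on the
root-to-tip path (root included) divided by the path depth; equal splits
(ES) sums edge lengths rootward from the tip with weight halved at each
split, and `rate_es = 1/ES`. The tip-rate correlation (TRC) test either
regresses rates on the trait by PGLS or compares the observed Pearson
correlation against correlations with Brownian traits simulated on the
tree (two-sided add-one p). `fpr_calibration()` runs all four
rate-method combinations on null traits and counts traits with two or
more significant tests — the multiple-testing safeguard for claiming a
trait-diversification link.

## Dose-response

Sample wells are modelled against log10 dilution with shared asymptotes
A (uninhibited) and B (fully inhibited), per-extract midpoints treated as
a random effect around a fixed mean (`nlme`), and the shape parameter
held fixed per fit and profiled over a 21-point log-spaced grid on
[0.05, 5] by AIC — four observations per extract cannot identify four
free parameters, hence the grid. On noise-free plates the mixed model is
degenerate (zero residual variance); the fit then falls back to profiled
least squares with per-extract fixed midpoints, and recovery of the
generating parameters is exact to numerical precision. The calibration
series (log10 molar ouabain) uses the complementary curve orientation;
if Levenberg-Marquardt fails on degenerate data, a profiled least-squares
fallback (A, B solved linearly at each midpoint/shape) takes over.

Ouabain equivalents follow from the fitted midpoints: at \(x_{mid}\) the
well contains inhibitor equivalent to the calibration IC50, so the stock
is \(IC_{50} \cdot 10^{x_{mid}} \cdot d_{well}\) molar, converted to
µg per mg dry tissue by the molar mass (584.65 g/mol) and tissue loading.
The unit chain from extract stocks to reported µg/mg is not uniquely
pinned down by convention, so every factor is explicit and overridable in
`prep_config()`. Midpoints outside the tested dilution range are flagged
as extrapolated and warned about.

## What the generators emulate — and what they do not

The simulators generate: Yule trees; Brownian or white traits; profile
matrices from exactly the combining model (with optional
phylogenetically structured species-by-compound deviations); feature
tables containing the adduct, fragment, and diagnostic ions the
annotation rules look for (plus optional m/z and RT jitter and noise
peaks); and 4PL plates with constant background. They do **not** emulate:
chromatographic peak shapes, ionization suppression, isotope envelopes,
detector saturation, retention-time drift between samples, or real
fragmentation energetics. Default retention times are laid out on
distinct slots so that the noiseless round-trip is exact by construction;
noise parameters exist to break that exactness deliberately.

## Numerical choices

- Seeds: every stochastic function takes an explicit seed and
  saves/restores the global RNG state, so calls are pure.
- The `log(x + 0.1)` offset follows the assembly model; zero maps to
  `log(0.1)` and totals invert only positive log-means.
- Tolerances default to 0.005 Da (m/z) and 0.05 min (RT); annotation is
  monotone in `mz_tol` on exact data.
- Matrix solves use dense `solve()`; trees of the intended size
  (tens of tips) make \(O(n^3)\) costs irrelevant.
- p-values from resampling use the add-one rule and are never 0.

## Limitations and open questions

- The AU approximation degrades for clusters at the bootstrap ceiling
  (bp = 1 at all scales); such values are flagged conservative, not
  "corrected".
- The combining model assumes a common residual variance across
  experiments; heteroscedastic extensions are out of scope.
- The annotation rules cover chains of at most two sugars and a single
  acetyl; longer chains would need an extended residue search.
- ND and ES are speciation-rate *proxies*; their statistical behavior
  under non-Yule diversification is checked only through the
  false-positive calibration, not derived.
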