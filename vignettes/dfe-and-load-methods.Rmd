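---
title: "Inferring the distribution of fitness effects and genetic load from site frequency spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring the distribution of fitness effects and genetic load from site frequency spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfeload)
```

## The model

`dfeload` estimates the distribution of fitness effects (DFE) of new
mutations from polymorphism data alone, together with population-level
statistics of genetic load. The data enter as a pair of unfolded site
frequency spectra (SFS): counts $x_i$ of sites carrying $i$ copies of the
derived allele in a sample of $n$ haplotypes, tallied separately for a
selected class (0-fold degenerate coding sites, where every change is
nonsynonymous) and a neutral reference class (4-fold degenerate sites).

Under the Poisson random field (PRF) model the $x_i$ are independent
Poisson. A mutation with scaled selection coefficient $S = N_e s$
(semidominant) contributes to frequency class $i$ in proportion to

$$H(S, i, n) = \binom{n}{i}\int_0^1 x^{i}(1-x)^{n-i}\,
  \frac{e^{S}-e^{Sx}}{(e^{S}-1)\,x(1-x)}\,dx,
  \qquad H(0, i, n) = 1/i .$$

The DFE is a mixture: with probability $1-p_b$ the mutation is deleterious
and $-S$ is gamma distributed with shape $b$ and mean $|S_d|$; with
probability $p_b$ it is beneficial and $S$ is exponential with mean $S_b$.
All scaled effects, the discretization bins, and the $S_{\min}=5$ bound used
for $\alpha_{\mathrm{DFE}}$ share the single unit $N_e s$. Expected counts
are

$$m_i^{\mathrm{neut}} = \theta L_{\mathrm{neut}}/i, \qquad
  m_i^{\mathrm{sel}} = \theta L_{\mathrm{sel}}
  \int \phi(S)\, H(S, i, n)\, dS ,$$

followed by two corrections applied in this order (they do not commute; the
order is a documented package choice): mixing with the mirrored spectrum at
the ancestral misidentification rate $\varepsilon_{\mathrm{anc}}$,
$\tilde m_i = (1-\varepsilon) m_i + \varepsilon m_{n-i}$, and then the
per-class distortion $e_i = r_i \tilde m_i$ with $r_1 \equiv 1$. The
$r_i$ are nuisance parameters shared by both site classes; they absorb
demography and other spectrum-wide distorters so that the DFE parameters are
identified by the *contrast* between the selected and neutral spectra.
Fixed-derived and monomorphic sites contribute only to the class totals $L$;
no divergence data are used.

$\alpha_{\mathrm{DFE}}$, the fraction of substitutions driven by beneficial
mutations, weights the DFE by the relative fixation rate
$\omega(S) = S/(1-e^{-S})$ and integrates the beneficial tail above
$S_{\min} = 5$, so that effectively-neutral beneficial mutations do not
inflate the estimate.

## Fitting protocol

Four model variants are fitted: a full DFE with and without
$\varepsilon_{\mathrm{anc}}$, and a deleterious-only DFE
($p_b \equiv 0$) with and without $\varepsilon_{\mathrm{anc}}$
(`dfe_model_set()`). Each fit maximizes the Poisson likelihood over
polymorphic classes with L-BFGS-B on log-transformed positive parameters
inside fixed boxes ($b \in [0.01, 10]$, $|S_d| \in [10^{-2}, 10^{8}]$,
$p_b \in [0, 0.5]$, $S_b \in [10^{-3}, 100]$,
$\varepsilon \in [0, 0.3]$, $r_i \in [10^{-3}, 10^{3}]$).

Two implementation choices matter:

* **Profiling.** $\theta$ and the distortion vector $r$ enter every expected
  count only through the per-class scale $c_i = \theta r_i$, which multiplies
  both site classes. For fixed shape parameters the Poisson MLE of each
  $c_i$ is closed-form ($\hat c_i$ matches the summed observed counts to the
  summed unit-rate expectations), and the map
  $(\theta, r_2..r_{n-1}) \leftrightarrow (c_1..c_{n-1})$ is a bijection, so
  profiling is exact: the optimizer only ever sees at most five parameters.
  AIC still counts the profiled parameters as free.
* **Multi-start.** The first start is a deterministic coarse grid scan over
  $(b, S_d)$ of the profiled likelihood (more robust than a moment heuristic
  across the six-orders-of-magnitude $|S_d|$ range); the remaining starts are
  uniform draws in the transformed boxes, keyed to a seed. Runs whose free
  parameters end within 1% (relative) of a box bound are flagged and only
  used if every run is flagged; convergence additionally requires a small
  scaled gradient. A zero lower bound (e.g. $p_b = 0$ in data simulated
  without beneficial mutations) is treated with an absolute tolerance; a fit
  resting on such a natural boundary is still reported, flagged.

Model averaging weights the four fits by
$w_k \propto \exp(-\Delta\mathrm{AIC}_k/2)$. Discretized DFE masses and
$\alpha_{\mathrm{DFE}}$ are averaged *as quantities* (weighted sums of
per-model values), not recomputed from averaged parameters; deleterious-only
models contribute $\alpha = 0$. Note the distinction, which the package
keeps deliberately: `discretize_dfe()` evaluated at averaged parameters is
*not* the same number as the average of per-model masses, and the two can
differ in the second decimal for heavy-tailed fits.

Bootstrap intervals resample sites multinomially within each class (totals
preserved), refit the model set, re-average, and take percentile (order
statistic) intervals. Shared-versus-independent comparisons tie a subset of
$\{b, S_d\}$ across $K$ datasets while every dataset keeps its own
$p_b$, $S_b$, $\varepsilon$, $\theta$ and $r$-vector; the deviance is
referred to $\chi^2$ with $|{\rm shared}|\times(K-1)$ degrees of freedom,
with Bonferroni as the only multiple-testing correction.

## Numerical choices

$H$ is evaluated with the endpoint singularity cancelled analytically
against the binomial kernel and the ratio computed via `expm1` on the
appropriate side of $S = 0$, so it is stable over $|S|$ up to the clipping
bound $10^8$; the integral uses a fixed composite Gauss-Legendre grid graded
geometrically towards both endpoints (boundary layers of width $1/|S|$).
The outer integral over the DFE uses the quantile transform of each mixture
component on a composite endpoint-graded Gauss-Legendre rule (about 384
nodes by default). The gamma quantile has algebraic endpoint singularities
($u^{1/b}$ as $u \to 0$), which a single global rule resolves poorly; the
graded composite rule reaches relative accuracy better than $10^{-6}$
against adaptive quadrature across the parameter range reported for the six
tree species, for every entry whose relative magnitude exceeds $10^{-9}$
(smaller entries are below any attainable Poisson expectation and are
irrelevant to the likelihood). Heavy simulation experiments in the test
suite reduce the node count (`control = list(n_nodes = 96)`), where
statistical noise dominates quadrature error by many orders of magnitude.

Projected spectra have fractional counts; the likelihood rounds them to the
nearest integer by default (`round_counts = FALSE` switches to a continuous
gamma-function Poisson density). Degenerate inputs are handled explicitly:
zero expected counts with positive observations give $-\infty$ with a flag,
empty frequency classes contribute nothing, and ties in the central-
population choice break to the lexicographically smallest label.

## Polarization

Ancestral alleles are assigned by maximum likelihood over one or two
outgroup states under a Kimura 2-parameter model. The package simplifies the
two-outgroup phylogeny to independent star-topology branches from the
ancestral node (branch lengths $t_o$ in expected substitutions per site, one
shared transition/transversion ratio $\kappa$); the full nested tree adds a
shared internal branch whose length is not separately identifiable from
short ingroup data, and the star model recovers simulated branch lengths
within 20% at realistic divergences. Per-site, the probability that the
major allele is ancestral combines a per-minor-allele-count class prior
(estimated with shrinkage towards the global mean, pseudo-count 5, to avoid
overfitting sparse classes) with the outgroup likelihoods via Bayes' rule;
class priors and branch parameters are updated alternately (EM) to a
$10^{-8}$ log-likelihood tolerance. Sites with posterior strictly inside
$(0.4, 0.6)$ cannot be polarized with confidence and are dropped; sites
with no outgroup data fall back to their class prior, i.e. are polarized on
minor-allele frequency alone. Counts above 100 haplotypes are first reduced
by a single hypergeometric draw per site.

## Load statistics

For populations $X$ and $Y$ and per-site derived-allele frequencies
$p_X, p_Y$, the package computes
$L_{X\setminus Y} = \sum p_X (1-p_Y)$ and
$L_{Y\setminus X} = \sum p_Y (1-p_X)$ and the ratio
$R_{XY} = L_{X\setminus Y}/L_{Y\setminus X}$ — the frequency-based
expectation of the "derived alleles seen in one genome from $X$ but not in
one genome from $Y$" count, which is deterministic and equals the
single-genome sampling form in expectation. $R'_{XY}$ divides the 0-fold
ratio by the 4-fold ratio to absorb demography and structure.
$F_{ST}$ uses Hudson's ratio-of-sums estimator with finite-sample
corrections (a documented switch from other estimator families).
Uncertainty comes from a weighted block jackknife: the genome is cut into
consecutive 2-Mb chunks, chunks are assembled in genome order into 100
groups of similar size, and delete-one-group estimates are combined with
group-size weights (the delete-$m_j$ jackknife); intervals are normal
approximation around the point estimate.

## What the generators emulate — and what they do not

* `simulate_sfs_dataset()` draws each SFS entry Poisson around the model
  expectation — exactly the PRF sampling assumption. It does **not**
  simulate linkage, haplotype structure, or finite-genome correlations, so
  passing recovery tests demonstrates correctness of the inference
  machinery, not robustness to linked selection.
* `simulate_population_sites()` uses a neutral-like ancestral frequency
  density ($\propto 1/x$) and a Balding-Nichols beta kernel per population
  (divergence parameter $F$), with binomial sampling noise; a per-class
  multiplier on one population's 0-fold frequencies emulates stronger
  purging, and a class-blind multiplier (`demographic_asymmetry`) emulates
  the structure-like displacement that affects both site classes alike and
  that $R'_{XY}$ is designed to absorb. Note that the pure-drift kernel
  preserves mean derived-allele frequencies, so raw $R_{XY}$ is insensitive
  to divergence asymmetry by construction — deviations from 1 require one of
  the asymmetry knobs. Real demography (expansions, bottlenecks, migration)
  is not modelled.
* `simulate_outgroup_alignment()` evolves outgroup states from the true
  ancestral nucleotide under K2P with per-outgroup divergence and draws
  ingroup derived counts from a $1/i$ spectrum. CpG hypermutability and
  alignment error are not modelled.

Default generator conditions mirror the study design the package targets:
$n = 40$ haplotypes (20 diploids), $L_{\mathrm{sel}} = 10^5$ and
$L_{\mathrm{neut}} = 4\times 10^4$ sites (the scale of a ~3 Mb exome-capture
panel split by degeneracy), $\theta = 0.008$ per site (tree-like neutral
diversity), two outgroups at divergences 0.05 and 0.10, and Balding-Nichols
divergence 0.05 between populations.

## Test-suite study sizes

The calibration experiments in `tests/testthat/` are sized to run on a
single CPU: parameter recovery uses 50 simulated datasets per configuration
at $n = 40$, $L_{\mathrm{sel}} = 10^5$ across truths spanning the reported
species range ($b \in \{0.1, 0.4, 1.6\}$,
$|S_d| \in \{64, 571, 47000\}$, paired as in the reported species table,
with $\varepsilon_{\mathrm{anc}} = 0.05$, estimated with the
deleterious-plus-$\varepsilon$ model); the null calibration of the
shared-DFE test ties $\{b, S_d\}$ over 200 replicate pairs at $n = 40$,
$L_{\mathrm{sel}} = 5\times10^4$ (at much smaller $n$ the test is
measurably conservative — the tied pair $(b, S_d)$ is then nearly
one-dimensional and the deviance falls short of $\chi^2_2$ in the tail),
and the power experiment ties $\{b, S_d\}$ over 30 pairs at $n = 40$
(tying only $b$ has little power by design: a shape difference is absorbed
by the dataset-specific mean $S_d$); bootstrap coverage uses 20 datasets
with $B = 40$ replicates at $n = 16$, $L_{\mathrm{sel}} = 3\times10^4$ with
the deleterious-only model pair (the generating truth has no beneficial
component). These sizes are the package's own choices for desk-scale
validation; the statistical thresholds they are checked against are not
adjusted to them.

## Known limitations

* The PRF likelihood ignores linkage; standard in this model family, but
  standard errors on real data should come from the block bootstrap /
  jackknife, not the curvature of the likelihood.
* $S_d$ for heavy-tailed fits (small $b$) is weakly identified — its
  bootstrap intervals legitimately span orders of magnitude; $b$ and the
  discretized masses are the stable summaries.
* The deleterious-only and full models can fit near-identically when
  $p_b$ is small; AIC weights then split nearly evenly, which is the
  intended behaviour of model averaging, not a failure of optimization.
* Polarization assumes outgroup states evolve independently from the
  ancestral node; shared internal branches, ancestral polymorphism and
  lineage sorting are absorbed into the fitted branch lengths.
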