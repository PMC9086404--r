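---
title: "Local trend analysis for dependent time series: model, conventions, calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local trend analysis for dependent time series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stlta)
```

## The problem

Association screening in biological time series — which OTUs rise and fall
together, which genes track an environmental covariate — is commonly done
on *trends* rather than values: each series is reduced to a sequence of
up/flat/down symbols and a pair is scored by its best co-trending aligned
window (the local trend score). Trend coding is robust to monotone
transformations and turns many non-stationary series into stationary
symbol chains, but it creates a statistical trap: even when the original
observations are i.i.d., consecutive trend symbols share an observation
and are therefore dependent, and real abundance series are autocorrelated
on top of that. Permutation tests and i.i.d.-theory approximations both
ignore part of this dependence and can be badly miscalibrated.

This package's central method (STLTA, `lta(..., method = "stlta")`) keeps
the convenient Brownian-extremum tail law but computes its variance from
Markov chains fitted to the *observed* trend sequences, so the p-value
adapts to the dependence actually present.

## Model and procedure

**Discretization.** For a series $X_1,\dots,X_n$ and threshold $t \ge 0$,
symbol $i$ is $+1$ if $(X_{i+1}-X_i)/|X_i| \ge t$, $-1$ if $\le -t$, and
$0$ strictly in between; when $X_i = 0$ the symbol is the sign of
$X_{i+1}$. The thresholds are *inclusive*, so at $t = 0$ a tie
($X_{i+1} = X_i$) codes $+1$; `strict = TRUE` switches to strict
inequalities, under which ties become 0. Zero-heavy abundance tables
should choose deliberately here; the default follows the printed
definition of the method. With $t = 0$ a zero-free series yields a
two-state sequence on $\{-1,+1\}$; with $t > 0$ a three-state sequence.

**Score.** $LT(D) = \max \sum_{l=0}^{k-1} d^X_{i+l} d^Y_{j+l}$ over all
windows with start offset $|i-j| \le D$, including the empty window, so
the score is a non-negative integer and a score of 0 maps to p = 1. The
dynamic program is $O(m(2D+1))$; ties among optimal windows resolve to the
smallest x-start, then y-start, then length, and reported alignments are
1-based. The score as defined rewards positive co-trending only
(anti-trending windows score negatively and are never selected); this
one-sided form is what the calibration experiments below validate.

**Tail law.** Under independence, partial sums of the product chain
$Z_i = d^X_i d^Y_i$ behave like a random walk, and the scaled score
$x = LT(D)/(\sigma\sqrt m)$ with $m = n-1$ obeys approximately
$P(LT(D) \ge s) \approx L_D(x) = 1 - \Theta(x)^{2D+1}$, where $\Theta$ is
the cdf of $\max_{0\le v\le1}|W_v|$ for standard Brownian motion. We scale
by $\sqrt{n-1}$ because the product chain — the object performing the
random walk — has length $n-1$; at the sample sizes of interest the
difference from $\sqrt n$ is visible only through the integer-score
threshold at small $n$.

**Variance.** $\sigma^2 = E(Z_1^2) + 2\sum_{k\ge1}E(Z_1 Z_{k+1})$ sums in
closed geometric form once each trend chain is given a symmetric Markov
model:

* two-state (stay probability $a$): autocovariances $(2a-1)^k$, giving
  $\sigma^2 = (1+r_Xr_Y)/(1-r_Xr_Y)$ with $r = 2a-1$;
* three-state (stay $b$, flip $c$, exit-from-0 $d$): stationary trending
  mass $\varphi_1 = d/(1-b-c+2d)$ per sign, autocovariances
  $2\varphi_1(b-c)^k$, giving
  $\sigma^2 = 4\varphi_1^X\varphi_1^Y\,(1+\rho_X\rho_Y)/(1-\rho_X\rho_Y)$
  with $\rho = b-c$;
* mixed: one factor of each kind.

Transition parameters are estimated by averaging the two trending-row
ratios (`estimate_two_state()`, `estimate_three_state()`), with no
pseudocounts. A chain is classified by its observed symbol set: no zeros
(or zeros without observed exits) means two-state; zeros plus trending
symbols means three-state; a single observed symbol is degenerate. TLTA
(`method = "tlta"`) replaces the data-fitted parameters with the values an
i.i.d. original series would imply: exactly $a = 1/3$ at $t = 0$ for any
continuous marginal, and Monte-Carlo estimates under a standard-normal
marginal at $t > 0$ (`iid_params()`, cached at $N = 10^6$ draws under a
fixed internal seed — the simulation nulls have normal innovations, and
the i.i.d. three-state parameters depend on the marginal).

## Tunable parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `t` | relative-change threshold for "no trend" | 0 | 0 gives two-state coding; 0.5 is the conventional three-state choice |
| `D` | maximum start delay between windows | 0 (pairs), 3 (network) | raises the tail-law exponent to $2D+1$ |
| `n_perm` | permutation count | 1000 | p-values are bounded below by $1/(n_{perm}+1)$ |
| `permute` | what the permutation test shuffles | `"symbols"` | see below |
| `strict` | strict threshold inequalities | `FALSE` | affects exact ties only |
| `alpha`, `q` | edge-calling thresholds in `lta_network()` | 0.05, 0.05 | q is Benjamini–Hochberg over non-degenerate tests |

## Design choices in the open corners

**Tail evaluation.** $\Theta$ is computed by its alternating theta series
$\frac4\pi\sum_k \frac{(-1)^k}{2k+1} e^{-(2k+1)^2\pi^2/(8x^2)}$ for
$x \le 1.5$ and by the equivalent reflection series in normal cdfs for
$x > 1.5$ (the theta series converges slowly for large $x$); terms are
truncated below $10^{-14}$ with a 1000-term cap, $x < 10^{-8}$ returns
p = 1 outright, and results are clipped to $[0,1]$. The two branches agree
to full precision in the overlap, and the whole function is validated in
the test suite against Brownian-path Monte Carlo with a
Broadie–Glasserman continuity correction for the discretely sampled
extremum.

**What the permutation test shuffles.** Two conventions circulate.
Shuffling the *original values* of one series and re-discretizing is an
exact test whenever those values are exchangeable — correctly sized for
i.i.d. data, inflated for autocorrelated data. Shuffling the *trend
symbols* destroys, in addition, the serial dependence that discretization
itself induces (the stay probability of an i.i.d. series' trend chain is
1/3, not 1/2), so it over-rejects mildly even for i.i.d. data. Empirically
only the symbol convention reproduces the published calibration tables
that motivate this package (e.g. rejection rate ≈ 0.157 vs ≈ 0.080 for the
value convention at the AR(1) $\rho_1=\rho_2=-0.5$, $n=200$ cell, against
a printed 0.1465), so `permute = "symbols"` is the default and
`permute = "values"` provides the exact-test variant; the null-uniformity
properties in the test suite are asserted on the value variant, where
alone they hold.

**Degenerate inputs.** A constant trend sequence (e.g. a strictly
monotone series), a chain with no observed exits from its trending
states, or an estimated decay product within $10^{-9}$ of 1 yields a
flagged degenerate result instead of a p-value — the asymptotic theory
needs an ergodic chain. The simulation harness counts degenerate
replicates as non-rejections and tallies them separately; the network
pipeline records the flag and excludes such pairs from the BH family.

**Missing data.** `lta_network()` can apply a prevalence filter (factors
observed — non-missing and non-zero — in at least a given fraction of
time points) and then fills interior gaps by linear interpolation;
leading/trailing gaps take the nearest observed value, where linear
interpolation is undefined. No abundance transformation is applied before
discretization: at $t = 0$ trend symbols are invariant to monotone
transformations anyway, and at $t > 0$ the raw relative change is the
definition of the method.

## The simulation null models

`simulate_null_pair()` generates the three stationary models used for
calibration, all with independent standard-normal innovations, first
values drawn standard normal, and a 100-sample burn-in discarded:

1. AR(1): $X_t = \rho_1 X_{t-1} + \epsilon_t$;
2. ARMA(1,1): $X_t = \rho_1 X_{t-1} + \epsilon_t + 0.5\epsilon_{t-1}$;
3. ARMA(1,1)–TAR(1): $X$ as in 2, while
   $Y_t = \rho_2 Y_{t-1} + \epsilon_t$ when $Y_{t-1} \le -1$ and
   $0.5\,Y_{t-1} + \epsilon_t$ otherwise.

`type_one_error()` derives an independent child seed per replicate from
the master seed, so any single replicate is reproducible in isolation, and
`run_table()` crosses six coefficient pairs with six sample sizes at
$D = 0$, $\alpha = 0.05$, matching the published design. The full-fidelity
experiment uses 10,000 replicates per cell (and 1,000 permutations per
replicate); the package default of 2,000 replicates gives binomial
standard errors of about 0.004 on rates near 0.05 and keeps a routine grid
run to minutes. The test suite runs the reproduced cells at 2,000
replicates and judges them within three combined Monte-Carlo standard
errors; `scripts/acceptance.R` runs the theoretical methods at the full
10,000.

## What the synthetic abundance generator does and does not emulate

`simulate_abundance_table()` produces wide factor-by-time tables from
exponentiated AR(1) latent series, with optional planted co-trending pairs
(innovation signs shared between partners) and missing values at a given
rate. It emulates the *structure* that the pipeline must handle —
autocorrelation, prevalence gaps, missingness, positive abundance scale —
but not compositional closure, sequencing depth variation, zero inflation
or taxon correlation networks. Passing tests on these tables show the
pipeline's bookkeeping and calibration are right under the stated models;
they do not certify performance on any particular real microbiome data
set.

## Known limitations

* The tail law treats the product trend chain as first-order Markov; this
  is an approximation (the product of two first-order chains need not be
  first-order), adequate in simulation but without a rigorous proof.
* STLTA is conservative at small $n$ (rejection rates well below nominal
  for $n \lesssim 60$), approaching the nominal level as $n$ grows; with
  very short series a permutation test may detect more.
* The score is one-sided: anti-correlated trends are not flagged. Score
  the pair against a negated partner if both signs are of interest.
* Two-state chains are modelled as symmetric (equal stay probabilities in
  both states), matching the symmetric-marginal assumption of the theory.
* Estimated decay products very close to 1 (near-constant trend chains)
  produce degenerate, not borderline, results by design.
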