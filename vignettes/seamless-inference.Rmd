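---
title: "Selection-conditional inference for seamless phase II/III trials with binary endpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-conditional inference for seamless phase II/III trials with binary endpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seamlessbin)
```

## The design and the inferential problem

A two-stage adaptive seamless phase II/III trial randomises subjects to a
control group ($g = 0$) and $G$ treatment groups. At the interim analysis,
stage-1 subjects contribute a rapidly observable **short-term** binary
endpoint $X_g^{(1)} \sim \mathrm{Bin}(N_g^{(1)}, \xi_g)$ on which one
treatment is selected: the group with the highest stage-1 response rate,
ties going to the smallest index (lowest dose). Stage 2 enrols additional
subjects only in the control and selected groups, and the final comparison
uses the **long-term** binary endpoint
$Y_g^{(j)} \sim \mathrm{Bin}(N_g^{(j)}, \pi_g)$, pooled over stages. The
two endpoints of one subject are correlated ($\rho_g \ge 0$), which is what
transmits the selection event into the distribution of the long-term counts
and makes naive inference invalid: the pooled proportion
$\hat\pi_{\mathrm{MLE},s} = Y_s/N_s$ is biased upward *conditional on the
selection*, and a test that ignores selection overstates significance.

The package provides, for the selected group $s$ and the control:

* **MLE** — pooled proportions (the biased benchmark);
* **CMAE** — the conditional mean-adjusted estimator: MLE minus a plug-in
  estimate of its analytic selection-conditional bias;
* **UMVCUE** — the Rao–Blackwell conditionally unbiased estimator: the
  conditional expectation of the selection-independent stage-2 proportion
  given the sufficient statistics and the selection event;
* selection-conditional **exact** and **mid-p** tests of
  $H_0\!: \Delta_g \le 0$ (log odds difference against control), and
  confidence intervals for $\Delta_s$ obtained by inverting either test.

## The endpoint model

Each subject's endpoint pair follows a hierarchical bivariate Bernoulli
law: $Y \sim \mathrm{Bernoulli}(\pi)$, then

$$\Pr(X = 1 \mid Y = 1) = \frac{\beta + \alpha}{1 + \alpha}, \qquad
  \Pr(X = 1 \mid Y = 0) = \frac{\beta}{1 + \alpha},$$

with $\beta = \xi + \alpha(\xi - \pi)$. Summed over $n$ subjects this gives
the bivariate binomial count law used everywhere in the package: given
$Y = y$, the short-term count is
$\mathrm{Bin}(y, (\beta+\alpha)/(1+\alpha)) +
 \mathrm{Bin}(n-y, \beta/(1+\alpha))$, and both marginals are preserved.

**Choice of the $\alpha$ parameterisation.** Requiring the per-subject
Pearson correlation to equal $\rho$ forces

$$\alpha = \frac{\rho}{\gamma - \rho}, \qquad
  \gamma = \sqrt{\frac{\pi(1-\pi)}{\xi(1-\xi)}},$$

which `bb_alpha()` implements; the sampler (`bb_sample()`) therefore
achieves the nominal correlation for any admissible triple, including
unequal margins. The unit tests verify this against the analytic
per-subject covariance and against empirical correlations at $n = 10^6$.

**Admissible correlation range.** The conditional probabilities above are
valid iff $\beta \in [0,1]$. That constraint alone, however, admits some
triples that the distribution's documented range excludes. `bb_feasible()`
therefore applies a symmetric two-sided rule: both the $\gamma$ orientation
and its reciprocal (the closed form obtained by exchanging the roles of the
two endpoints) must yield a valid $\beta$. The two coincide when
$\xi = \pi$. Under this rule $\rho_{\max}(0.7, 0.5) \approx 0.550$: a
correlation of $0.5$ is admissible for those margins, $0.6$ is not, while
every parameter combination in the simulation grid below is admissible.
This was a genuinely open reconstruction choice; the two-sided rule is the
weakest one consistent with both the correlation identity and the
documented exclusion, and it is frozen in the tests.

**Correlation estimation.** `pearson_rho()` computes the Pearson
correlation of the $n$ per-subject pairs from the aggregate counts
$(x, y, z)$, where $z$ counts dual responders; degenerate margins fall back
to 0, a neutral value that keeps all downstream plug-in computations
defined. `bb_profile_rho()` maximises the multinomial likelihood of the
per-subject $2\times2$ cell counts $(z,\, x-z,\, y-z,\, n-x-y+z)$ over
$\rho$ with the margins held fixed — the cell counts are observed (the
dual-responder count is required by the Rao–Blackwell estimator anyway),
and they are what makes a single trial informative about $\rho$: the
marginal count pair $(x, y)$ alone is one draw from a bivariate law and
cannot identify a correlation. The maximiser is located by a 200-point grid
presearch over the admissible interval followed by bounded 1-D refinement
(tolerance $10^{-6}$); the grid guards against the flat or boundary-hugging
likelihoods that arise at degenerate counts.

**Plug-in clamping.** Estimated probabilities entering any pmf or the
$\alpha$ formula are clamped to $[0.5/n,\, 1 - 0.5/n]$ (`clamp_prob()`),
and plug-in correlations are truncated into the admissible range for the
clamped margins. Bias subtraction in the CMAE can overshoot at boundary
data, so CMAE estimates are clipped to $[0, 1]$ after subtraction; the
UMVCUE never needs clipping on valid inputs.

## Selection probabilities

Stage-1 response rates are compared as exact integer cross-products
($x_g n_h$ vs $x_h n_g$), never floating ratios, so ties are detected
exactly even with unequal stage-1 sizes — the tie-break to the smallest
index is part of the law and enters every probability below.
`prob_select()` and `prob_select_given_count()` evaluate
$\Pr(Q = s)$ and $\Pr(Q = s \mid X_g^{(1)} = k)$ by closed-form products of
binomial distribution functions (for the candidate) and by summing out the
remaining groups (for a competitor). `expected_selected_value()` gives the
exact $E[\pi_s] = \sum_s \pi_s \Pr(Q = s)$ used as the reference point of
the operating-characteristic summaries — enumeration, not simulation.

Under the control-inclusive rule variant the control can "win", which the
package reports as a stopped trial; estimation and testing deliberately
refuse such records, since the final comparison is defined only for
continued trials. When control ties a treatment under that rule the
smallest-index convention means the control wins; this is a convention
choice, flagged here because the rule's source leaves it open.

## Estimators

The CMAE subtracts the analytic conditional bias evaluated at the MLE:
for a continued group the stage-2 contribution is selection-independent,
giving

$$b_{\pi,g} = \frac{\sum_{k_x, k_y} k_y \Pr(X_g^{(1)}=k_x, Y_g^{(1)}=k_y)
  \Pr(Q=s \mid X_g^{(1)}=k_x)}{N_g \Pr(Q=s)}
  + \frac{N_g^{(2)}}{N_g}\pi_g - \pi_g,$$

with the stage-1 joint law from the bivariate binomial model, and
analogously for $b_{\xi,g}$ (single sum). For an unselected group the
estimator is the stage-1 proportion, so its bias formula uses the stage-1
size in the denominator. With $\rho = 0$, or for the control under the
treatment-only rule, the long-term bias vanishes identically. These
functions agree with a full-enumeration oracle to $10^{-12}$ on a
$G=2,\, n_1 = n_2 = 2$ design across a parameter grid (see the test suite).

The UMVCUE applies the Rao–Blackwell theorem to the stage-2 proportion:
conditional on the pooled totals and the selection event, the
stage-1/stage-2 split of the count triple is parameter-free, so the
conditional expectation is a ratio of combinatorial sums. The triple-sum
coefficient

$$c(k_x,k_y,k_z) = \binom{n_1}{k_y}\binom{n_2}{Y-k_y}\binom{k_y}{k_z}
  \binom{n_1-k_y}{k_x-k_z}\binom{Y-k_y}{Z-k_z}
  \binom{n_2-Y+k_y}{X-k_x-Z+k_z}$$

multiplies the selection weight $\Pr(Q=s \mid W_1, X_g^{(1)}=k_x)$, which —
because $W_1$ fixes every competitor's stage-1 count — is a deterministic
win indicator for the selected group, and a constant for the control (so
the control's UMVCUE collapses to the pooled MLE). Out-of-range triples
contribute zero through the $\binom{a}{b} = 0$ convention, and the sums are
evaluated on the log scale to survive large designs. Exact conditional
unbiasedness on the enumerable design (to $10^{-12}$) is the gate that
validates this reconstruction. Unselected groups have no
selection-independent data, so no UMVCUE exists for them; the estimator
vector falls back to their stage-1 MLE.

## Tests and confidence intervals

Conditional on $Q = s$ and the total long-term count $T = t$, the selected
arm's count follows the tilted law

$$\Pr(Y_s = k \mid Q = s, T = t) \propto
  \binom{N_0}{t-k}\, h(k)\, e^{k \Delta_s},$$

where $h(k)$ convolves the stage split with the selection weight
$\Pr(Q = s \mid Y_s^{(1)} = r)$, itself obtained by passing the bivariate
binomial conditional law of $X_s^{(1)}$ given $Y_s^{(1)}$ through the
closed-form selection probabilities at plug-in parameter estimates. With
constant weights ($G = 1$, or $\hat\rho = 0$) $h(k)$ reduces to
$\binom{N_s}{k}$ by Vandermonde's identity and the $\Delta_s = 0$ law is
the central hypergeometric — the tests then reproduce Fisher's exact test,
which the suite checks to $10^{-9}$.

The exact p-value is $\sup_{\Delta \le 0} \Pr(Y_s \ge y_s \mid \cdot)$; the
mid-p variant counts half the atom at the observed count. The supremum is
evaluated on the grid $\Delta \in \{-10, -9.5, \dots, 0\}$ and refined by
bounded maximisation (tolerance $10^{-6}$); monotone likelihood ratio makes
the upper tail increasing in $\Delta$ so the supremum is expected at 0, but
this is *verified* on the grid at every call, with a dense-grid fallback if
it ever fails rather than assumed. Confidence limits invert the tails at
equal areas $\alpha/2$ (Clopper–Pearson convention, ties extending the
interval) by bisection on $[-30, 30]$ — wider than any estimable log odds
difference at these sample sizes — with tolerance $10^{-6}$; an observed
count at the end of its support yields an infinite limit, which still
counts as covering in the coverage summaries. Which estimate set feeds the
plug-in weights is the caller's choice; crossing {MLE, CMAE, UMVCUE} with
{exact, mid-p} gives the six inference methods the simulation engine
summarises.

## The simulation engine and what it emulates

`scenario_spec()` encodes five scenario families on a common control
baseline of 0.5 for the alternatives: a global null at a constant
probability (default 0.1; 0.5 and 0.7 are the other tabled baselines), a
null with different short-/long-term probabilities, a single effective
treatment, a linear dose-effect, and all treatments equally effective, with
effect size $\delta = 0.280$ at $N = 50$ and $0.145$ at $N = 200$, stage-1
fraction $\tau$, and a common correlation $\rho$. These defaults *are* the
study conditions; they are not tuning knobs. `simulate_trial()` generates
per-subject endpoint pairs (so dual-responder counts are exact, as the
UMVCUE requires), applies the selection rule, and `run_study()` aggregates
means, RMSEs (against the *realised* selected group's true value per
replicate), rejection rates at one-sided level 0.025, and coverage of the
replicate's true $\Delta_{s_r}$ by the 95% two-sided intervals, each with
its Monte Carlo standard error. Replicates run sequentially, each from its
own seed drawn once from the root seed, so results are bit-reproducible
and independent of execution order. Replicates whose interval has an
infinite limit stay in the coverage denominator (an infinite limit can
still cover).

Problem sizes used by the shipped checks: estimator summaries at
$R = 10{,}000$ and test/interval summaries at $R = 5{,}000$ replicates —
the package's desk-scale defaults, with three-combined-SE comparison bands
stated alongside each check.

What the generator does **not** emulate: over-dispersion or subject
heterogeneity beyond the binomial, dropout or missing endpoints, staggered
accrual within stages, negative endpoint correlation, or selection of more
than one treatment group. Passing operating-characteristic checks therefore
says nothing about robustness to those departures; they bound what the
simulated evidence can claim about real trials.

## Numerical choices and degenerate inputs

* All test-side pmfs are computed in log space (large case-study designs
  overflow binomial coefficients on the probability scale).
* $t = 0$ or $t = N_0 + N_s$ collapse the conditional support to a point:
  the p-value is 1 at the bottom, and the corresponding interval limit is
  infinite.
* Degenerate observed proportions are handled by the half-count clamp
  before they reach a pmf; the Pearson fallback at degenerate margins is 0.
* The profile-likelihood grid presearch (200 points) costs little and
  protects against boundary maxima; the refinement tolerance $10^{-6}$ is
  far below any quantity reported.

## Known limitations

Single-treatment selection only; nonnegative correlation only; no variance
estimators for the point estimates (uncertainty is carried by the inverted
intervals); the CMAE retains a slight residual bias because its bias
correction is evaluated at the biased MLE; and the UMVCUE, while exactly
conditionally unbiased, pays for it with a larger RMSE when $\tau$, $\rho$
or $G$ is large — the usual Rao–Blackwell trade-off in this setting.

## A worked example

```{r example}
design <- design_spec(G = 3, n1 = c(28, 28, 27, 27), n2 = c(161, 0, 0, 254))
td <- trial_data(
  design, s = 3,
  x1 = c(3, 5, 8, 9),
  y1 = c(1, NA, NA, 10), z1 = c(1, NA, NA, 7),
  x2 = c(17, NA, NA, 85), y2 = c(9, NA, NA, 89), z2 = c(8, NA, NA, 64)
)
analyze_trial(td)
```
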