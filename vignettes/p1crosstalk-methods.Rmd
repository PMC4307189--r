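---
title: "Methods: Bayesian differential-network cross-talk prediction"
author: "p1crosstalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian differential-network cross-talk prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A drug-sensitive ("parental") cancer cell line and a resistant derivative are
profiled by expression microarray under the same treatment doses. The working
hypothesis is that acquired resistance is mediated by signaling cross-talk:
gene pairs spanning the inhibited pathway (here EGFR/ErbB, targeted by
lapatinib) and a compensatory pathway that co-operate in the resistant cells
but not in the parental cells. `p1crosstalk` formalizes this as a
differential-network question: which gene pairs have a high probability of
being connected in a resistant co-expression network and a low probability in
the parental one, and which of those pairs bridge the pathway of interest to
another pathway?

The pipeline has five stages:

1. **Expression input** — probe-level tables are collapsed to gene symbols
   (arithmetic mean over probes per symbol), split into the two conditions,
   and restricted to a seed gene list (a cancer gene catalogue in the
   motivating use case).
2. **Relationship networks** — per condition, gene pairs whose absolute
   Pearson correlation exceeds a threshold become edges of an undirected
   binary network over the seed genes.
3. **Joint p1-model fit** — a hierarchical Bayesian exponential random graph
   model is fit to both networks at once by MCMC, yielding posterior edge
   probabilities per condition.
4. **Cross-talk scoring** — pairs are scored by the odds ratio of the two
   posterior probabilities, filtered, and intersected with
   membership-defined cross-talk candidates from pathway collections.
5. **Expression screens** — condition-averaged profiles are normalized for
   heatmaps; records whose genes are both up-regulated under resistance, and
   genes whose treatment fold-change flips sign, are reported.

# The undirected p1-model

A network over $g$ genes is a symmetric binary matrix $u$ with zero diagonal.
Each dyad $(i, j)$, $i < j$, carries two indicators — edge absent and edge
present — whose log-probabilities are

$$\log \Pr(Y_{ij0} = 1) = \lambda_{ij}, \qquad
  \log \Pr(Y_{ij1} = 1) = \lambda_{ij} + \theta + \alpha_i + \alpha_j,$$

where $\theta$ is a global density parameter, $\alpha_i$ a per-gene
propensity (the undirected collapse of expansiveness/attractiveness), and
$\lambda_{ij}$ the per-dyad normalizer fixed by
$\Pr(Y_{ij0}=1) + \Pr(Y_{ij1}=1) = 1$. Eliminating $\lambda_{ij}$ gives the
Bernoulli-logistic form used everywhere in the package:

$$\Pr(u_{ij} = 1) = \operatorname{logit}^{-1}(\theta + \alpha_i + \alpha_j).$$

$\lambda_{ij}$ is therefore never a free parameter or data; it is the
normalizing constant implied by the two-state dyad. Dyads are independent
given the parameters, so the likelihood factorizes over the
$\binom{g}{2}$ pairs.

## Hierarchical priors and the joint fit

The two condition networks are fit **jointly**. Each condition $c \in \{R,
P\}$ has its own $\theta_c$ with prior $\mathcal N(0, \tau_c^{-1})$ and
hyperprior $\tau_c \sim \text{Gamma}(a_0, b_0)$, $a_0 = b_0 = 0.001$
(non-informative). Each gene's propensity pair is coupled across conditions:

$$(\alpha_i^R, \alpha_i^P)^\top \sim \mathcal N_2(0, \Sigma), \qquad
  \Sigma^{-1} \sim \text{Wishart}(I_2,\ 2),$$

with the Wishart written in the rate convention (density carries
$\exp\{-\mathrm{tr}(I\,W)/2\}$, expectation $2 I^{-1}$). The resistant
likelihood touches only $(\theta_R, \alpha^R)$ and the parental likelihood
only $(\theta_P, \alpha^P)$; **the two conditions communicate solely through
$\Sigma$**. A positive posterior correlation in $\Sigma$ encodes that hub
genes tend to be hubs in both conditions, and it is exactly the deviation
from that shared tendency that the odds ratio rewards.

No sum-to-zero constraint is placed on $\alpha$: identifiability of $\theta$
against $\operatorname{mean}(\alpha)$ is left soft, handled by the prior
centering of $\alpha$ at zero. Consequently individual $\theta$ posteriors
are wide (they trade off against the propensity mean) while the dyad
probabilities — the quantities the pipeline consumes — are well identified.

## Sampling

The default sampler is exact Gibbs via Polya-Gamma data augmentation: each
dyad (per condition, per sweep) receives $\omega_{ij} \sim
\text{PG}(1, \theta_c + \alpha_i^c + \alpha_j^c)$, after which

* the whole vector $\alpha^c$ is one multivariate Gaussian block draw
  (precision $= \Sigma$-conditional prior precision on the diagonal plus the
  $\omega$ graph Laplacian-like term; the conditional prior of $\alpha_i^c$
  given $\alpha_i^{c'}$ is the usual bivariate-normal regression),
* $\theta_c$ is a scalar Gaussian draw,
* $\tau_c \sim \text{Gamma}(a_0 + 1/2,\ b_0 + \theta_c^2/2)$,
* $\Sigma^{-1} \sim \text{Wishart}(2 + g,\ (I + A^\top A)^{-1})$ in R's
  `rWishart()` scale convention, $A$ the $g \times 2$ propensity matrix.

Updating $\alpha^R$ and $\alpha^P$ as per-condition blocks (rather than
per-gene pairs) is still exact Gibbs under the augmentation and mixes at
least as well; it was chosen because the block precision is cheap to
Cholesky-factor at these problem sizes. The PG(1, z) sampler is implemented
in C++ (alternating-series rejection from a truncated inverse-Gaussian /
exponential mixture) on R's RNG stream, so whole fits are reproducible
bit-for-bit from the seed. An adaptive Metropolis-within-Gibbs fallback
(random-walk updates of $\theta_c$ and each $\alpha_i^c$, Robbins-Monro step
adaptation during burn-in, identical conjugate $\tau$/$\Sigma$ updates) is
provided and held to the same small-instance oracle in the tests.

Defaults are 6000 iterations with 5000 burn-in, i.e. 1000 retained draws, no
thinning. Posterior edge probabilities come in two estimators: `"draws"`
replicates a network per retained draw (one Bernoulli flip per dyad) and
reports the proportion of sampled networks containing each edge; `"mean"`
averages the dyad probabilities directly. Both have the same expectation;
`"mean"` has strictly smaller Monte-Carlo variance and is the package
default, while `"draws"` reproduces the replicated-network reading exactly.

## Verification against an exact oracle

`brute_force_posterior()` computes the posterior by direct grid summation
for $g \le 4$ with $\Sigma$ fixed *diagonal* (the conditions then decouple,
so each condition is an exact $(1{+}g)$-dimensional sum; a non-diagonal
fixed $\Sigma$ would force a $2(1{+}g)$-dimensional grid for little extra
insight). The acceptance tests run both samplers against this oracle on
every 2- and 3-node network configuration and require agreement of all edge
probabilities within 0.05; a grid-refinement check confirms the default step
(0.5 over $[-5, 5]$, priors $\mathcal N(0,1)$) is converged to < 0.01.

# Network construction choices

* **Strict threshold.** An edge requires $|r| > t$, strictly; ties at the
  threshold are excluded.
* **Two threshold modes.** Explicit per-condition thresholds, or a quantile
  rule: $t$ is the $(1 - f)$ empirical quantile (linear interpolation, R
  type 7) of the defined upper-triangle $|r|$ values so that about a
  fraction $f$ of pairs lie above. Exactly one mode must be configured per
  run; both exist because fixed cutoffs and "top fraction"
  prescriptions are both common and are not mutually consistent in general.
* **Zero-variance genes** yield undefined correlations; their pairs can
  never be edges, but the genes stay in the list (the model still assigns
  them a propensity).
* **Replicates, not condition averages.** Correlations are computed across
  whichever sample columns the condition matrix has; the default pipeline
  uses all replicate columns. Averaging to one column per dose first is
  possible by feeding condition means back in, but with only a handful of
  doses the correlation becomes extremely coarse, so it is not the default.
* Expression values are used as provided — no log transform precedes the
  correlation.

# Cross-talk definition and scoring

Given a pathway collection with a designated pathway of interest $E$, a
candidate cross-talk is a pair $(a, b)$ with $a \in E$, $b \in Q$ for some
other pathway $Q$, both genes restricted to the analysis universe (default:
the network gene list), **excluding** pairs whose genes co-occur in $E$ or
co-occur in $Q$. The exclusion is applied per pathway: a gene belonging to
both $E$ and $Q$ can anchor no pair within either of those sets. The same
unordered pair may be reported once per other pathway containing its second
gene — total and distinct counts therefore differ, and both are reported.

Scoring takes the odds ratio
$\text{odds} = \Pr(Y^R_{ij1}=1) / \Pr(Y^P_{ij1}=1)$ and keeps pairs with
$\text{odds} \ge 10$ and $\Pr(Y^R_{ij1}=1) \ge 0.5$ (both inclusive;
`pr_min` is configurable — a relaxed 0.15 mirrors the validation-style
setting). Note the two filters *imply* a small parental probability
($\le 0.05$ at the defaults); no third cutoff is applied. `pr_P = 0` gives
infinite odds (sorting first); `pr_R = pr_P = 0` is defined as odds 0 with a
warning.

# Expression screens

* **Condition profile.** Per gene and (condition, dose) group, replicate
  samples are averaged; the heatmap normalization z-scores each gene row
  with the *population* (divide-by-$n$) standard deviation and divides by
  the row's maximum absolute z-score, so every non-constant gene spans
  exactly $[-1, 1]$ and constant genes map to zero. Population rather than
  sample SD is an arbitrary but fixed choice — with 4–6 condition values
  either is defensible, and the max-abs rescaling absorbs the constant
  factor anyway, making the two choices produce identical heatmaps; the
  choice is documented so the intermediate z-scores are reproducible.
* **Up-regulated pairs.** A cross-talk record survives iff, for both genes,
  the mean of the resistant condition-means strictly exceeds the mean of
  the parental condition-means.
* **Fold-change reversal.** Per replicate, log2 fold-changes of each
  parental treatment dose against the parental basal sample must all share
  one strict sign while the resistant treatment doses (against the same
  parental basal) all take the opposite sign; a gene is selected if this
  holds in at least one replicate. The resistant *basal* fold-change is
  computed and reported but deliberately excluded from the predicate: the
  screen asks whether the *treatment response* reverses, and including the
  untreated resistant baseline would conflate a level shift with a response
  reversal. A fold-change of exactly 0 counts as neither direction.
  Replicate pairing comes from the sample map's replicate index.

# The synthetic experiment

`simulate_expression_pair()` generates the study conditions every test runs
against: two conditions, doses $\{0, 0.1, 1\}$ µM with 2 replicates each
(6 samples per condition), $g = 60$ genes at baseline 100 (platform-like
units), latent factor SD 10, independent noise SD 1. Structure:

* **3 blocks of 6 genes** share a latent factor in *both* conditions —
  ordinary co-regulated modules, hubs in both networks, odds near 1.
* **10 planted pairs (20 genes)** share one latent "compensatory module"
  factor *only in the resistant condition*, plus a +15 mean shift in
  resistant samples so the up-regulation screen can find them. Flags
  disable either signal.
* **8 dose responders** rise with dose in parental samples and fall in
  resistant ones (slope 30 per µM) — material for the reversal screen.
* The remaining genes are independent noise.

Two design points deserve emphasis because they determine what the
end-to-end test can and cannot show.

First, the p1-model is dyad-independent given its parameters: posterior edge
probabilities are functions of $\theta_c$ and the node propensities only, so
the fit *smooths by degree* and cannot localize a single rewired edge between
two otherwise ordinary genes. A detectable planted signal must make its genes
resistant-specific hubs. The generator therefore plants one shared
resistant-only factor across the planted genes — biologically, a compensatory
module switching on under resistance — rather than ten isolated pair
correlations, which the model provably could not see.

Second, with one shared factor, *every* pair among the 20 planted genes is
resistant-only correlated, and the degree-smoothed fit scores the
between-pair combinations as highly as the designated pairs. The toy pathway
collection resolves this the way curated databases do — through overlapping
membership: the pathway of interest holds the first gene of each pair, and
the $k$-th other pathway holds the $k$-th second gene together with the
*other* pairs' first genes, so the same-pathway exclusion rule removes every
between-pair combination and the designated pairs are the only candidate
cross-talks among planted genes. A few unstructured background genes are
mixed into each partner pathway as filler — and only into partner pathways:
a filler gene in the pathway of interest would anchor a candidate pair with
*every* partner pathway, so a single noise gene whose 6-sample correlation
with the resistant factor exceeds the cut by chance (probability a few
percent per gene) would flood the candidate set. With filler confined to
partner pathways such a chance gene anchors O(1) pairs, and that is the
residual false-positive mode the end-to-end test tolerates. The recovery
criterion thus exercises the full funnel — thresholding, the joint fit, the
odds filter, *and* the membership exclusion — and its false-positive arm is
primarily a test of the last two. A pipeline cannot pass it by network
construction alone.

For the synthetic analysis the pipeline uses explicit PCC thresholds of 0.9
in both conditions rather than the quantile mode: with 6 samples the null
$|r|$ distribution is heavy-tailed (about 1.5% of independent pairs exceed
0.9), and a forced top-fraction would inject hundreds of noise edges into
the sparse parental network, inflating every parental propensity and
compressing the odds ratios the design plants. The factor-to-noise ratio
(10:1) puts genuinely co-regulated pairs at a population $|r| \approx 0.99$;
the margin matters because with only 6 samples the *sample* correlation
fluctuates substantially (Fisher-z standard error $1/\sqrt{3}$), and a
population value of 0.96 — the first ratio considered — left co-regulated
pairs dropping below the 0.9 cut in a noticeable share of factor
realizations.

What the generator does **not** emulate: probe-level noise, platform
normalization artifacts, alias/annotation ambiguity, and correlation
structure richer than single factors. Passing tests demonstrate the
machinery end to end under a faithful generative model; they do not certify
recovery rates on real microarray data.

# Problem sizes and runtime choices

Test and acceptance runs use reduced MCMC: 1500 iterations / 1000 burn-in
for the $g = 60$ end-to-end runs (5 seeds), 2000/1000 for the $g = 30$
parameter-recovery replicates (20 seeds), and 1500/500 for the tiny oracle
comparisons — sizes at which the suite completes in about a minute on one
CPU while leaving hundreds of retained draws per fit. The package defaults
remain 6000/5000. The recovery experiment checks 90% credible-interval
coverage of both $\theta$ truths (≥ 80% of replicates) and the sign of the
posterior $\Sigma$ correlation (≥ 18/20) rather than point-estimate error,
because of the soft $\theta$ identifiability discussed above.

# Degenerate inputs and numerical notes

* Logistic terms are evaluated through `plogis(..., log.p = TRUE)`, finite
  for any finite linear predictor and stable to $|\eta| \approx 700$.
* Every $\Sigma$ draw is symmetrized after inversion; SPD-ness of all draws
  is asserted in tests.
* `n_iter - burn_in >= 100` is enforced; posterior summaries of fewer draws
  are too noisy to be meaningful.
* Correlation over fewer than 3 samples is refused (2 points give $\pm 1$
  degenerately); exactly 3 samples triggers a warning.
* Expression parsing treats any non-numeric cell (including `NA`) as a hard
  error naming row and column: silent imputation upstream of a correlation
  network is worse than failure.
* Probes mapping to multiple symbols are dropped with a warning (only
  many-probes-to-one-symbol averaging is supported); unmapped probes are
  dropped silently with a count message.
* Gene-symbol matching is case-sensitive and exact; no alias resolution is
  attempted, which would import an external database and its versioning.

# Known limitations

* Only the undirected two-state dyad model is implemented — no reciprocity
  or directionality, no four-state dyads.
* Degree smoothing means single-edge rewiring is invisible by construction
  (see the synthetic-design discussion); findings are module-level.
* The odds filter's thresholds are conventions, not estimates; no
  multiplicity control is applied, matching the screening character of the
  procedure.
* Pathway cross-talk is membership-based only; pathway topology is ignored.
* MCMC convergence is monitored by effective-sample-size diagnostics, not
  proven; the fixed-seed contract makes every reported number reproducible
  but not independent of the seed.
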