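---
title: "Morphological-clock tip dating and historical biogeography with morphoclock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological-clock tip dating and historical biogeography with morphoclock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphoclock)
```

## The problem

Dating a radiation from discrete morphology means estimating, jointly, a
rooted time tree whose terminals include both living species and dated
fossils, the rate at which morphological characters change, and how that
rate varies across lineages. `morphoclock` implements this stack end to
end: the Mk(v) likelihood for discrete characters, strict and relaxed
morphological clocks, the fossilized birth--death (FBD) tree prior with
sampled ancestors and stratigraphic tip-age calibrations, a
Metropolis--Hastings sampler with the standard convergence diagnostics,
stepping-stone marginal likelihoods for clock-model choice, posterior tree
summaries, SIMMAP-style stochastic character mapping, and
dispersal--extinction--cladogenesis (DEC) ancestral-range estimation on the
resulting non-ultrametric trees. A simulation module generates every input
with known truth, so each stage can be validated by recovery experiments.

## Character model

Characters follow the k-state symmetric Markov model with uniform
stationary frequencies. Because the rate matrix is symmetric, transition
probabilities have the closed form

$$p_{same}(t) = \frac{1}{k} + \frac{k-1}{k} e^{-kt/(k-1)}, \qquad
  p_{diff}(t) = \frac{1}{k} - \frac{1}{k} e^{-kt/(k-1)},$$

with $t$ in expected substitutions. Among-character rate variation uses a
discrete gamma mixture (four equal-probability categories by default, each
category the conditional mean of its quantile bin, renormalized to mean
exactly 1); the shape $\alpha$ gets an exponential prior with mean 1.
Morphological matrices are scored only for variable characters, so the
likelihood of each character is divided by $1 - \Pr(\text{constant})$,
where the constant-pattern probability is computed by the same pruning
engine. Two consequences worth knowing:

* the correction depends on the state count, so characters are grouped into
  state-count classes and corrected per class;
* dividing by a quantity below 1 *raises* each character's log-likelihood;
  the corrected log-likelihood always exceeds the uncorrected one.

Polymorphic scores (`{01}`) and missing scores (`?`, and inapplicable `-`)
both enter as indicator partials over the listed states; for binary
characters `{01}` is therefore indistinguishable from missing, which is a
property of the representation, not a parsing accident. One shared
$\alpha$ covers all characters by default; per-class shapes are possible
through the likelihood interface but are not the default because
morphological matrices rarely support estimating several shapes.

The pruning kernel is written in C++ (per-node rescaling, closed-form
transition probabilities hoisted per edge and rate category), which keeps a
166-taxon, 108-character evaluation under a millisecond.

## Clock models

Effective branch lengths are `duration (Ma) x base rate x branch
multiplier`. The base rate $c$ (substitutions per Ma) carries a lognormal
prior; its location is derived the way practitioners seed it from a
non-clock pre-run — median root-to-tip tree height in substitutions divided
by the median of the root-age prior, logged (`derive_clock_rate_prior()`),
with a broad scale (1.5) by default. Branch multipliers come from one of:

* **strict** — all multipliers 1;
* **iln** — independent lognormal, mean fixed to 1 *in real space*
  (location $-\tfrac{1}{2}\log(1+\nu)$, so $\nu$ is the real-space
  variance); stated explicitly because "independent lognormal" admits a
  log-space-mean convention too;
* **igr** — independent gamma with mean 1 and variance $\nu$, duration-free;
* **wn** — white noise: gamma with variance $\nu/\text{duration}$, so long
  branches average rate noise away; this is what distinguishes it from igr;
* **tk02** — autocorrelated lognormal node rates: child log-rates diffuse
  around the parent with variance $\nu t$ and drift $-\nu t/2$ (keeping the
  expected rate a martingale at 1), and a branch multiplier is the
  arithmetic mean of its endpoint node rates.

$\nu$ gets an exponential hyperprior (mean 1) by default; this choice is
explicit and configurable because no standard value exists. All five
models satisfy $E[r_b] = 1$ at the prior, tested by Monte Carlo, and all
collapse to the strict clock as $\nu \to 0$.

## Tree prior and calibrations

The FBD prior treats speciation ($\lambda$), extinction ($\mu$), fossil
sampling ($\psi$) and extant sampling ($\rho$) as one generative process.
It is parameterized by net diversification $d = \lambda - \mu$ (exponential
prior, mean 1), turnover $r = \mu/\lambda$ (uniform) and a fossil-sampling
probability $s = \psi/(\mu + \psi)$ (uniform), with $\rho$ fixed (default
1). The density is assembled from event factors — $\lambda$ per
bifurcation, $\psi p_0(y)$ per pendant fossil tip, $\psi$ per sampled
ancestor, $\rho$ per extant tip — and a per-branch factor $q(t)$ that
telescopes into a product over node ages. We condition on the root age
(which carries its own calibration) and on both root lineages having
sampled descendants; conditioning on the root rather than the origin
matches how the root is calibrated directly. The density is validated
three ways: against the closed-form Yule product, against an independently
transcribed two-tip formula, and against forward simulation (the fossil-tip
age marginal of simulated two-tip trees matches the density bin by bin).

The root age gets an offset-exponential prior: a hard minimum at the
oldest assignable fossil and a soft maximum. The published bound pair
(34, 41.2 Ma) leaves the tail mass above the soft maximum unstated, so the
default places 5% of prior mass beyond it (`semantics = "quantile"`); an
alternative reads the soft maximum as the distribution mean
(`semantics = "mean"`). Fossil tip ages are free parameters with uniform
priors over their stratigraphic ranges; a fossil may also sit directly on
its ancestral lineage as a sampled ancestor (zero-length attachment),
contributing $\psi$ instead of $\psi p_0/q$.

## Sampler

`run_mcmc()` is a single-temperature Metropolis--Hastings sampler.
Proposal classes: multiplier moves on $c$, $\alpha$, $\nu$, $d$; reflected
slides on $r$ and $s$; uniform slides on internal-node ages within their
parent/child bounds; a multiplier on the root age above its oldest child;
uniform slides on fossil tip ages within window and parent constraints;
a reversible-jump toggle between pendant-fossil and sampled-ancestor
status (the uniform-window density cancels against the tip-age prior, so
the acceptance ratio reduces to the FBD density ratio); two global moves —
a tree-wide age scaling and a joint age-up/rate-down scaling along the
rate--time ridge — without which node-age mixing is poor; per-branch (or,
for TK02, per-node) rate multipliers; and optional rooted NNI moves that
preserve age validity. Move classes are drawn with weights proportional to
their parameter counts. The sampler exposes three targets: the full
posterior, the prior with the data likelihood off, and a hyperprior-only
target (no FBD tree density) used to validate the proposal machinery
against the stated priors by KS tests — with the tree density on, the
parameter marginals are weakly conditioned by the fixed topology, so the
clean validation target excludes it. A periodic audit recomputes the
cached likelihood from scratch and errors on drift.

Convergence gates mirror standard practice: ASDSF (sample standard
deviation across runs of split frequencies, minimum frequency 0.10)
$\le$ 0.01, PSRF $\approx$ 1, ESS > 200. ASDSF and split bookkeeping are
computed from `ape::prop.part`; ESS and PSRF delegate to `coda` behind the
package's `ess()`/`psrf()` surface.

## Model selection

`stepping_stone()` estimates marginal likelihoods from power posteriors
with powers at Beta(0.4, 1) quantiles descending from 1 to 0, sampling at
the lower power of each stone and accumulating
$\ln \tfrac{1}{n}\sum_i e^{(\beta_{hi}-\beta_{lo}) \ln L_i}$ with
log-sum-exp stabilization; the standard error combines a delta-method
variance with an autocorrelation (ESS) correction. The desk profile uses
10 stones of 10k iterations; the production-scale profile (30 stones + 5
burn-in, 250M generations) is recorded as `ss_config("paper")` for
documentation. Bayes factors use the $2\Delta\ln$ convention —
`2 * (best - model)` — which is the convention under which the published
muroid clock-model table is internally consistent; BF > 5 is labelled
strong support.

## Tree summaries

Majority-rule consensus keeps splits above 0.5; `allcompat` greedily adds
the remaining splits in decreasing frequency order when compatible, ties
broken lexicographically for determinism. Node ages on the consensus are
medians over the samples containing each clade, with 95% HPD intervals
(shortest window containing $\lceil 0.95 n \rceil$ sorted samples).
Common-ancestor heights are deliberately not used; the median-over-samples
convention is stated because summary software differs here.
`mrca_age_summary()` locates a clade's MRCA in every sampled tree whether
or not it is monophyletic there.

## Stochastic character mapping

For each character, ER/SYM/ARD rate matrices are fitted by maximum
likelihood on the dated tree and ranked by AIC ($2p - 2\ln L$); ties go to
the simpler model, and a misbehaving SYM fit falls back to ER with a
message. The mapping root prior is the stationary distribution of the
fitted matrix (configurable to uniform). Ancestral-state calls use a
strictly-above 50% threshold; anything at or below reports "uncertain".
Histories are sampled by backward-drawing node states from their
conditional distributions and filling branches with endpoint-conditioned
paths by uniformization; node-state frequencies across samples converge to
the marginal posteriors, which is the property the tests assert.
Characters with fewer than two observed states after ambiguity resolution
are rejected up front — a stated convention of this package.

## Historical biogeography

DEC runs on the dated, non-ultrametric tree with fossil tips as ordinary
terminals at their ages. Ranges are subsets of the area set up to
`max_range_size` (default 4, configurable; published ancestral ranges in
the muroid system span up to three areas). Anagenetic dispersal into area
$a$ sums rate $d$ over occupied source areas connected to $a$ under the
epoch's 0/1 connectivity matrix; local extinction removes areas at rate
$e$; the empty range is absorbing. Branch propagators split at epoch
boundaries into chronologically ordered matrix exponentials
(`ape::matexpo`). At cladogenesis, narrow sympatry (single-area ranges),
subset sympatry and single-area vicariance carry equal weights; splits
into two multi-area daughters can be enabled (`wide_vicariance`). The root
prior is uniform over non-empty ranges by default. Marginal ancestral
ranges come from an up-down pass through the cladogenetic transitions, and
every range within 2 log-likelihood units of a node's best range is
reported.

### A structural caveat about the extinction rate

Recovery experiments (fitting data simulated under the model itself)
recover the dispersal rate $d$ well, but the extinction rate $e$ is driven
to the zero boundary almost regardless of its true value. This is not an
optimizer failure: on simulated data the likelihood at $e \to 0$ genuinely
exceeds the likelihood at the generating truth, because cladogenetic
subset sympatry and vicariance let ranges contract at nodes at no
rate-dependent cost, absorbing the signal that anagenetic extinction would
otherwise carry, while lineages whose ranges die are unobservable
(survivorship). The same near-zero-$e$ behaviour of DEC maximum-likelihood
fits is well documented in the biogeography literature. `morphoclock`
reports the honest boundary estimate and flags it (`at_bound`); users
should treat fitted $e$ as effectively unidentifiable under classical DEC.

## Synthetic data and what passing tests mean

`simulate_fbd_tree()` runs the birth--death-fossilization process forward
from two lineages at the root, prunes to the sampled tree, converts
fossils with sampled descendants into sampled ancestors, and jitters
stratigraphic windows around true fossil ages (uniform half-widths of
0.2--1.5 Ma). `simulate_characters()` evolves characters down the tree
under a drawn clock, with a 60/25/10/5% mixture of 2/3/4/5-state
characters resembling published morphological matrices, and rejects
constant characters when variable-only coding is requested — the same
ascertainment process the Mkv correction models. `simulate_ranges()` runs
a Gillespie walk over range states along branches (respecting the epoch
connectivity in force at each moment) with one cladogenetic scenario drawn
per node; lineages whose range hits the empty set are dropped from the
returned tree with a warning rather than resimulated, because conditioning
whole datasets on no extinction would bias the extinction signal further.

The calibration experiment the package uses as its main end-to-end check:
20 replicates of FBD trees with 15--25 tips (root age drawn from its
offset-exponential prior between 10 and 14 Ma; net diversification 0.3,
turnover 0.5, fossil-sampling probability 0.5 — a fossil-rich regime
resembling dense Neogene rodent sampling), 100 clocked characters each,
two pooled chains of 12,000 iterations per replicate. About 92-93% of
true internal-node ages fall inside the 95% HPD intervals. The residual gap to
the nominal 95% comes from two deliberate design compromises: the
generating diversification parameters are fixed rather than drawn from
their priors (prior draws occasionally produce degenerate all-fossil
shelves on which HPDs are only ~0.1 Ma wide), and accepted simulations are
conditioned on a tip-count window that the inference model does not know
about. These are properties of the experiment, not of the sampler: with
the data likelihood off, the sampler's marginals match every stated prior
by KS test, and on small fossil trees its posterior matches an exhaustive
grid evaluation of the same density.

What the synthetic experiments do **not** establish: robustness to
correlated characters, to nonuniform state frequencies, to model
misspecification between simulation and inference, or to the
paleogeographic realism of connectivity matrices. They validate the
machinery, not the biology.

## Numerical choices

* Ages are the stored quantity; branch durations are always derived, so
  lengths and ages cannot drift apart. Zero-length pendant branches mark
  sampled ancestors (tolerance $10^{-8}$ Ma).
* Newick serialization keeps durations as branch lengths plus one
  `[&root_age=...]` comment, making absolute ages round-trip losslessly;
  plain branch-length output is available for interoperability.
* The pruning kernel rescales partials lazily (threshold $10^{-120}$),
  exact to a telescoped log factor.
* State counts default to one more than the largest observed state (floor
  2), with an explicit per-character override, because published matrices
  rarely state their intended state spaces.
* Optimizers: Brent for one-parameter CTMC fits, Nelder--Mead on log-rates
  otherwise; DEC rates are optimized on the log scale and flagged when a
  rate lands below $10^{-6}$.
* Problem sizes in the test-suite experiments (tree sizes, chain lengths,
  replicate counts) are chosen so the full validation battery runs on a
  single desktop core in well under half an hour; the `ss_config("paper")`
  profile records the production-scale settings separately.

## Known limitations

* Single-temperature MCMC only; no Metropolis coupling. Mixing over
  sampled-ancestor configurations in very fossil-dense trees is slow, and
  pooled independent chains are recommended (the calibration experiment
  does exactly that).
* Clock-model selection at desk scale uses short tempered chains; its
  variance is honest but large, so it reliably separates models only when
  the rate-variation signal is strong.
* DEC's extinction rate is structurally unidentifiable (see above);
  DEC+J-style founder events and Bayesian DEC are out of scope.
* Topology inference is provided (rooted NNI) but the package's validation
  experiments fix topology; age calibration conditional on topology is the
  property that has been verified.
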