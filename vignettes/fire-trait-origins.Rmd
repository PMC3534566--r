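---
title: "Dating fire-adapted trait origins on chronograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating fire-adapted trait origins on chronograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fireclades)
```

## The problem

Fire-adapted seed syndromes — serotiny (on-plant seed storage released by
fire heat), persistent soil seed banks cued by heat or smoke, and
ant-buried arillate diaspores — are widespread in genera occupying
fireprone vegetation. `fireclades` asks *when* such traits, and the
fireprone habitats they are tied to, arose on a genus-level, time-calibrated
phylogeny, and whether lineages entering fireprone habitats diversified
faster than their sister lineages left behind in closed forest.

Inputs are an ultrametric chronogram (branch lengths in My, tips at the
present) plus per-taxon binary trait tables and habitat ranges
(`F` fireprone, `N` non-fireprone, `FN` both). None of the analyses need
real data to be validated: the `simulate_*` generators and `make_fixture()`
produce fully synthetic inputs with known truth.

## Trait evolution: Mk models, pruning, and MCMC

Each binary trait evolves by a continuous-time Markov (Mk) model with gain
rate $q_{01}$ and loss rate $q_{10}$ (events/My). The tip-data likelihood is
computed by Felsenstein's pruning algorithm; genera with species in both
states ("both") are handled by standard ambiguity coding (partial
likelihood 1 in each permitted state), not by duplicating taxa. The root is
combined with a uniform prior over states by default; a stationary-prior
option exists because the original choice in analyses of this kind is
usually unstated.

Posterior distributions of rates and of node states come from a
Metropolis–Hastings sampler:

* **Proposal.** One rate class per iteration is perturbed by a uniform
  window of half-width `ratedev`, reflected at zero. `ratedev = "auto"`
  runs three short pilot chains and rescales geometrically (with a
  log-bisection refinement once the window is bracketed) until the pooled
  acceptance rate of rate proposals lies in 20–40%.
* **Prior.** Every rate has an exponential prior whose mean is itself a
  sampled hyperparameter with a uniform(0, 30) hyperprior, updated by its
  own reflected-uniform move. With a flat likelihood the sampler
  demonstrably reproduces this hyperprior mixture (a property test checks
  this by Kolmogorov–Smirnov).
* **Reversible jump.** When enabled, the chain also moves across rate-class
  partitions: merging two classes, splitting a class along a random
  bipartition, and exchanging singleton classes with a zero-bin. New class
  values are drawn from the exponential prior, so proposal densities cancel
  against the prior and the acceptance ratio reduces to the likelihood
  ratio times the ratio of elementary-operation counts of the two
  partitions. Restricting zero-bin exchanges to singleton classes keeps
  every elementary operation exactly reversible. This independence-sampler
  construction targets the same posterior as merge/split schemes with
  explicit Jacobians and is considerably simpler to verify.
* **Node states.** At every recorded sample the internal-node states are
  drawn once from their exact joint conditional distribution given the tips
  and current rates (post-order partials, pre-order sampling) and tallied;
  tallies normalize to per-node posterior probabilities. For fixed-rate
  chains these tallies are tested against brute-force enumeration.
* **Initialization.** Rates start at $1/\text{(root age)}$ — about one
  expected event per root-to-tip path — rather than at a draw from the
  diffuse hyperprior, so that short burn-ins suffice. The starting
  hyperparameter is drawn from its prior.

Full-scale settings (preset `"paper"`: $10^7$ iterations, burn-in $10^4$,
one sample every 2000; $5\times10^6$ iterations for correlation runs) are
retained as a named preset. The working preset `"test"` ($10^5$ iterations,
burn-in $10^3$, thin 20) is what the test-suite simulation studies use;
all problem sizes quoted below (200-tip recovery study, 150-tip
calibration study, 80-tip fixture) were chosen as desk-scale study
conditions and are stated in the tests themselves.

## Marginal likelihoods and the correlated-evolution test

Two traits are tested for correlated evolution by comparing a *dependent*
8-rate model on the joint state space \{00, 01, 10, 11\} (double
transitions structurally zero) against an *independent* 4-rate model in
which each trait's rates ignore the other trait's background. Both are
summarised by the harmonic mean of the sampled log-likelihoods, computed
in log space as $\log n - \operatorname{logsumexp}(-\log L_i)$. The
log-Bayes factor is twice the difference of the harmonic means and is
referred to a $\chi^2_4$ critical value (9.49 at $\alpha = 0.05$), with a
strictly-greater-than decision rule. One `ratedev` is tuned on the
dependent model and reused for the independent chain.

The harmonic-mean estimator is retained deliberately — it is the summary
the decision rule above was designed around — but it is high-variance; the
report therefore attaches a blocked Monte-Carlo standard error, and the
calibration study in the acceptance tests measures its operating
characteristics directly (false-alarm rate at most 10%, power at least
80% under a tenfold background-dependent gain-rate contrast on 150-tip
trees). The model-dimension penalty implicit in the harmonic mean makes
the test conservative under the null, which is the safe direction.

## Habitat: two-area DEC and the trait-style alternative

Habitat occupancy is reconstructed with a two-area
dispersal–extinction–cladogenesis model. Anagenetic transitions on
branches follow the generator over \{∅, F, N, FN\}: range expansions
F→FN and N→FN at independently estimated ("unconstrained") dispersal
rates, contractions FN→F / FN→N and single-area extinctions at per-area
extirpation rates; the null range is absorbing and excluded from the root
prior and cladogenesis. At each bifurcation the daughters inherit ranges
by the classic equiprobable scenario set (identical inheritance for
single-area parents; vicariance and peripheral-isolate scenarios, six
ordered pairs at 1/6 each, for FN parents). Rates are fitted by bounded
multi-start L-BFGS-B in log-rate space (bounds $10^{-9}$–$10$ per My,
five starts); node-range probabilities come from constrained
renormalization. The model is time-homogeneous — no epochs or stratified
dispersal.

Dispersal/divergence events are read at nodes where one daughter's
most-probable range contains an area absent from the other daughter's.
This covers both ways a colonization can appear in a DEC reconstruction:
an anagenetic gain (parent F, daughter FN) and a vicariant split of a
widespread ancestor (FN dividing into F | N). The planted colonization in
the synthetic fixture is recovered by exactly this rule.

As in the source analyses, habitat can alternatively be treated as an
ordinary heritable binary trait (`FN` coded ambiguous) and pushed through
the same MCMC machinery; a fixture test checks that both routes agree at
the planted colonization node.

## Node assignment, stem propagation, and origin dating

A node's trait posterior is multiplied by the posterior probability that
the node exists in the phylogeny (its clade support, read from numeric
Newick labels in [0, 1]; defaulting to 1 where absent, and always 1 at the
root). The ancestral state is called unambiguously only when this
*corrected* posterior exceeds 0.95. Raising the threshold can only turn
calls ambiguous, never the reverse.

Assignments propagate along stems: a node's probabilities are held
constant along its supporting branch until the next decision at its
parent. Stems are half-open in age, $[\text{child age}, \text{parent
age})$, so a query at a node's own age reads that node's assignment, tips
are counted at age 0, and lineage-timeline counts at any gridpoint always
sum to the number of stems crossing it — ambiguous stems are tallied as
their own category rather than split fractionally. The origin of a derived
state is dated at the top of the oldest passing stem (the "at the root of
the clade" reading); node-age uncertainty intervals are passed
through when supplied, never recomputed.

## Diversification at habitat divergences

Divergence events are nodes where one daughter stem carries fireprone
probability above 0.80 and the other carries non-fireprone probability
above 0.80. For each side the stem-group net speciation rate is
$R_{st} = \log(N)/t$ with $N$ the summed extant species count of the clade
(species counts per genus are an input, never inferred) and $t$ the stem
age. Natural log is the default (base 10 is available and flagged in the
output); the fireprone side is always the numerator, and the summary
reports the arithmetic mean of per-event ratios with the geometric mean
alongside. Ratios are undefined when the non-fireprone rate is zero
(single-species sister); such events are excluded and counted.

## The synthetic fixture

`make_fixture()` writes a fully synthetic bundle shaped like the intended
real inputs: an 80-tip chronogram rescaled to a 113-My crown (birth 0.08,
death 0.02 per My), taxa `G001`–`G080`, synthetic clade supports in
[0.95, 1], and one planted colonization: a mid-depth clade of roughly a
third of the genera is fireprone, all other genera non-fireprone except
two mixed (`FN`) genera. Seed traits are simulated with elevated, labile
dynamics inside the fireprone radiation (gain 0.12, loss 0.08 per My
against 0.001/0.05 outside) — repeated gains and losses, as documented for
serotiny within fireprone floras, are what give a correlated-evolution
test replicated evidence rather than a single unreplicated co-origin.
Species counts are negative-binomial draws with mean 20 for fireprone and
5 for non-fireprone genera. A manifest records every true parameter; taxa
are never given real genus names.

What the fixture does *not* emulate: phylogenetic uncertainty beyond node
supports (a single tree is analysed, not a posterior sample), fossil
calibration error, within-genus trait polymorphism beyond the `both`
coding, more than two habitat classes, and extinction of entire habitats.
Passing tests on the fixture therefore demonstrate correctness of the
inference chain under its own model assumptions, not robustness to their
violation on real data.

## Numerical choices

* Matrix exponentials use scaling-and-squaring; inside the MCMC loop
  branch propagation uses an eigendecomposition with a reconstruction
  check and scaling-and-squaring fallback, and the 2-state case uses the
  closed form. The closed form also serves as an independent test oracle
  at $10^{-12}$.
* Pruning partials are rescaled per node; all marginal-likelihood algebra
  is done in log space.
* Ultrametricity tolerance is $10^{-6}$ relative to root age; tip ages are
  snapped to exactly 0 after validation.
* Ties at the corrected-posterior threshold resolve to "ambiguous"
  (strict inequality), matching the strict 9.49 rule of the correlation
  test.
* Degenerate inputs: all-ambiguous trait columns give log-likelihood 0
  with a warning; invariant trait columns abort the correlation test;
  polytomies are tolerated by the trait machinery but rejected by DEC and
  the divergence-event scan, which require bifurcations.

## Known limitations

Harmonic-mean marginal likelihoods are noisy; stepping-stone estimators
would be better statistics but a different method. The RJ move set
explores tied/zero rate partitions, not arbitrary constraints. The DEC
implementation is two-area by design. Node-age uncertainty is passed
through, never estimated. Corrected posteriors treat clade support as
independent of the trait posterior, which is an approximation inherited
from the method itself.
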