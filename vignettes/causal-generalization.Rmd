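---
title: "Modeling object-based causal generalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling object-based causal generalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localaws)
```

## The problem

A learner watches a "magic stone" (the agent, $a$) collide with a normal
stone (the recipient, $r$), which changes into a result form $r'$. From one
or a few such interactions, how should — and how do — people predict what
a *new* pair of stones will do? The package implements three models of
this inference and the experimental designs used to probe it: stones with a
small number of discrete features (color and shape; or ordinal shade and
edge count), a learning phase of one or six demonstrations, and a
generalization phase of forced-choice predictions over a candidate panel.

## Causal laws and their grammar prior

A causal law is a conjunction of assertions that define the result's
features from the agent's features, the recipient's features, or constants,
e.g. `(and (assign (color R') (color A)) (assign (shape R') square))`:
the recipient takes the agent's color and becomes a square. A probabilistic
context-free grammar generates laws by (i) binding a feature (uniformly,
without replacement), (ii) optionally conjoining another assertion
(probability 1/2 while unbound features remain), (iii) picking a relation,
and (iv) picking a relative (agent/recipient) or absolute (constant)
reference. All production probabilities are uniform, so the prior of a law
is the product of its production probabilities (for example, the law "the
recipient changes color", `(nassign (color R') (color R))`, costs five
binary choices: $0.5^5 \approx 0.03$). The geometry of the
conjunction choice makes simpler laws exponentially more probable — the
grammar's built-in parsimony bias.

Because each law binds each feature at most once, every law over a
two-feature space is semantically equivalent to one with at most two
conjuncts. `enumerate_laws()` therefore enumerates all depth-2 laws,
computes their exact priors (summing derivation orderings), merges
semantic duplicates by exhaustive truth-table comparison over the finite
object space, and renormalizes. For the ordinal experiment the relation
set gains `+1`, `-1`, `>` and `<`, uniformly weighted at the bind-relation
step.

One modeling choice deserves emphasis: features a law does not mention
keep the recipient's value (a law about color leaves shape alone). A
negated or inequality assertion admits several outcomes, which the
likelihood treats as equiprobable: $P(d \mid f) = 1/|D(f(a,r))|$ if
$r' \in D(f(a,r))$, else 0, where $D$ is the law's admissible-outcome set.
This favors deterministic laws that fit the data. An ordinal increment
that would leave the value range (e.g. adding an edge to a heptagon)
empties the domain — the law is inapplicable there — rather than clamping
to the boundary, which would manufacture spurious deterministic
predictions. A "soft" variant that mixes the law's outcome distribution
with the uniform distribution is available via `epsilon`; its default is 0
because nothing in our target analyses requires fallible laws, and the
exact mixing weight is a free choice we prefer to expose rather than fix.

## The three models

**Universal causal laws (UnCaLa).** Bayes over the enumerated law table:
posterior $\propto$ prior $\times$ likelihood, and predictions marginalize
the posterior predictive for each candidate result. One causal law governs
everything, so predictions are invariant to the order generalization
questions are asked in.

**Local causal laws (LoCaLa).** A Dirichlet-process mixture: object pairs
fall into causal categories; each category carries one law and a mean
feature profile $\mu$ (smoothed value counts). Assignment of a pair
multiplies a Chinese-restaurant-process weight (concentration $\alpha$), a
feature-similarity term (pair likelihood under $\mu$, Dirichlet smoothing
$\beta$), and — for events with observed results — the result's likelihood
under the category's law. The focus parameter $\gamma$ interpolates
between building $\mu$ from agent features only ($\gamma = 1$) and
recipient features only ($\gamma = 0$). With one learning example the
model has a closed form (`locala_single_example()`); with several it is
approximated by Gibbs sampling over partitions (`gibbs_locala()`), each
sweep reassigning every event in random order and resampling affected
categories' laws from their members' posterior. Generalization trials are
scored independently against the learning partition (each task is its own
decision problem); a joint variant — including unknown-result pairs in the
partition — is possible by passing such events to the sampler, but is not
validated here.

**Sequential process model (LoCaLaPro).** The resource-rational variant
commits to its own categorization decisions: learning events seed category
1 with a law sampled from their posterior; each task is then *sampled*
into an existing category (apply its law) or a new one (sample a law from
the prior), and the assignment is appended before the next task. Early
generalizations thereby become evidence for later ones, producing order
effects: near-first task sequences keep the learner in the learning
category (consistent predictions), far-first sequences tend to spawn a new
prior-governed category whose influence persists. Predicted proportions
are estimated by averaging many seeded runs; one simulated participant is
one run.

## Parameters

| Parameter | Meaning | Default / typical |
|---|---|---|
| $\alpha > 0$ | DP concentration; larger favors more categories | 0.38 (sequential, one-shot scale), ~5-9 (few-shot scale) |
| $\beta \ge 0$ | Dirichlet pseudo-counts on feature values; larger = less feature-sensitive | 0-4 |
| $\gamma \in [0,1]$ | agent-only (1) vs recipient-only (0) category profiles | 0.5, or 1 for agent-focused fits |
| $t \ge 0$ | softmax inverse temperature on predictive probabilities | ~10 |
| $\varepsilon$ | soft-law mixture with uniform outcomes | 0 |

The softmax exponentiates the predictive *probabilities* times $t$
(`exp(p * t)`), matching the form the models were fit with; the
conventional log-space softmax ($p^t$) sits behind `log_space = TRUE`.

Two readings of the feature-similarity term coexist in the literature on
this model family: normalizing the value counts per feature (the
Dirichlet-categorical posterior predictive) or pooled over all feature
values. We default to per-feature normalization (`mu_norm = "feature"`)
because it makes the Gibbs sampler's feature term an exchangeable
predictive — so the two-event posterior has an exact closed form we test
against — and because it gives the intuitive calibration that a pair
identical to a single-member category scores likelihood 1 at $\beta = 0$.
The pooled reading is available via `mu_norm = "pooled"`. Likewise
$\gamma$ enters as a deterministic count weight
($\gamma\,$agent + $(1-\gamma)\,$recipient) rather than a per-category
coin flip; the two coincide at the endpoints $\gamma \in \{0, 1\}$, which
is where fits are interpreted.

## The experiment designs

The one-shot design (`exp1_design()`) has six learning conditions crossing
which recipient features change and whether new values match the agent's,
followed by 15 generalization tasks ordered near-first (most similar to
the learning pair first) or far-first (exact reverse). The 15-task grid is
shipped as data (`inst/extdata/exp1_design.json`): tasks 1-3 vary
recipient features, 4-11 each agent feature crossed with recipient
variants, 12-15 both agent features — anchored to the printed instance
(condition A1: red-square agent and yellow-circle recipient in learning;
task 1 pairs the red-square agent with a blue-circle recipient). The seed
counterbalances whether color or shape variants lead within the later task
pairs; the anchor itself is held fixed for every seed so the design is
exactly reproducible.

The few-shot design (`exp2_design()`) shows six interactions consistent
with a ground-truth rule over ordinal shade (1-4) and edge count (3-7),
with either the agent or the recipient held fixed. Its 16 tasks cross
match/novel shade and edge values for the fixed-role and varied-role
objects, plus two catch trials (learning events with hidden results), with
a 20-option response menu (5 edges x 4 shades, chance 5%). The built-in
learning sets observe three shades and three edge values per condition,
reserving shade 4 and edges {6, 7} as novel: this is the unique resolution
that keeps every learning result representable, gives the novel-value task
cells two distinct edge instances, and lets the dissimilarity score
$DS = |F_i \setminus F_L|$ (novel feature values on a trial's objects)
reach its full 0-3 range. The varied objects cover as many distinct values
per varied feature as those constraints admit (three of each). Rule
consistency is machine-checked in the test suite by applying the rule's
law object to every learning event.

## Fitting and statistics

`fit_model()` fits by maximum likelihood and compares by BIC
($-2\mathrm{LL} + k\ln n$): the baseline (uniform, $k=0$), the universal
model ($t$ only), the analytic single-example local model
($\alpha, \beta, t$ jointly, bounded quasi-Newton with five seeded
starts), and the sequential model (grid over $\alpha, \beta$ with
simulation-estimated predicted proportions — the marginal probability of a
choice is the average of its softmaxed probability over runs — and $t$
optimized within each cell). Catch trials are excluded from scoring.
Inter-participant consistency uses the Kuder-Richardson 21 coefficient on
aggregated per-option selection counts with population variance (the
sample-variance convention is exposed as an option); flat count vectors
leave the statistic undefined and are flagged rather than computed.

## What the simulator does and does not emulate

`simulate_dataset()` generates populations whose every choice is sampled
from a model's softmaxed predictive — including, for the sequential model,
a fresh stochastic trajectory of category commitments per participant.
That reproduces the structural signatures of interest (order effects,
consistency gradients over dissimilarity, agent-focus asymmetries) and
supports parameter recovery, but deliberately omits things real
participants bring: attention lapses, participant-level parameter
heterogeneity, learning across the generalization phase from feedback
(there is none), and idiosyncratic symbolic theories outside the grammar.
Passing tests on synthetic populations therefore validates the inference
machinery, not the psychology.

## Numerical choices and problem sizes

Semantic law equivalence is decided by exhaustive truth tables (81
agent-recipient pairs in the one-shot space, 400 in the few-shot space),
stored as outcome bitmasks; this is exact and cheap at these scales but
caps supported spaces at 30 object configurations. Gibbs sampling uses
random-scan sweeps, a single chain, and a default burn-in of 20% of
iterations; partitions are relabeled to canonical form after every
reassignment. Ties in `argmax_choice()` break toward the lowest canonical
candidate index. The test suite's recovery harness fits 200 simulated
participants over an a-priori grid ($\alpha \in \{0.1, ..., 2\}$ in the
coarse one-shot pattern, $\beta \in \{0, 0.5, 1, 2, 4\}$) with 500 runs
per cell and asserts recovery within one grid step; the order-effect
harness uses 200 participants per arm across five conditions. These sizes
were chosen as the smallest at which the checked contrasts are stable
across seeds.

## Known limitations

- The grammar's "without replacement" feature binding caps conjunctions at
  the number of features, so the geometric tail $P(\#\text{conjuncts} > k)
  = 2^{-k}$ holds only while unbound features remain (with two features,
  three-conjunct laws are impossible — harmless, since they would be
  semantically redundant anyway).
- Fitted parameter values for real behavioral data are not reproduced
  here: that requires the external dataset, which the CSV reader accepts
  but the package does not bundle.
- No split-merge or slice-sampling accelerations for the Gibbs sampler,
  and no hierarchical priors over $\gamma$.
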