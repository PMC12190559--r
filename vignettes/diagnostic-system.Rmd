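---
title: "The three-layer diagnostic system: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The three-layer diagnostic system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfsa)
```

## The problem

Symptom-checklist diagnosis data are binary case × symptom tables with one
disease label per case. Two failure modes dominate naive classifiers on
such data: *outlying cases* (recording errors, mislabeled charts, genuinely
atypical presentations) distort the fitted conditionals, and *irrelevant
symptoms* add noise that a naive-Bayes factorization multiplies into every
posterior. `hfsa` addresses both with a pipeline of three layers — outlier
rejection, feature selection, diagnosis — each of which is independently
testable against planted ground truth from the package's own generator.

## The diagnostic model

The diagnostic layer is Bernoulli naive Bayes. For class $c$ and symptom
$f$, with $n_c$ training cases of class $c$ of which $n_{cf}$ show the
symptom,

$$\hat\theta_{cf} = \frac{n_{cf} + \alpha}{n_c + 2\alpha}, \qquad
\log P(c \mid x) \propto \log \hat\pi_c + \sum_f \big[x_f \log\hat\theta_{cf}
+ (1-x_f)\log(1-\hat\theta_{cf})\big].$$

$\alpha$ is the Laplace pseudo-count (default 1; $\alpha = 0$ is allowed
and clamps $\log 0$ at a floor rather than erroring). The event model is
Bernoulli because every feature is a presence/absence bit; no Gaussian or
multinomial variant is offered.

One numerical point matters enough to state: exact posterior ties are
*common* on small binary tables (two diseases can have identical estimated
conditionals on a masked subset), and two mathematically equivalent ways of
accumulating the log-likelihood break such ties differently through
floating-point summation order. The predictor and the wrapper fitness
therefore share a single log-posterior kernel,
$x\cdot(\ell_1-\ell_0) + \sum_f \ell_0 + \log\hat\pi$, so ties resolve
identically (toward the first class in sorted label order) everywhere in
the package. Posteriors agree with a direct-product computation to
$10^{-9}$; that agreement is a test, not an assumption.

## The wrapper fitness

The selection layer scores a candidate symptom subset $x$ by
$F(x) = \mathrm{Accuracy_{NB}}(x)$. The reference description leaves open
*which* accuracy; this package uses stratified 3-fold cross-validated
accuracy on the training partition, with the fold assignment drawn once
from the stage seed. Rationale: training-set accuracy rewards overfit
subsets, a held-out split would spend scarce rare-class cases, and a fixed
fold assignment makes the fitness landscape deterministic so the search is
reproducible and memoisable. Fitness values are cached by the mask's bit
string; wrapper searches re-evaluate duplicate masks constantly, and on the
full benchmark the cache plus precomputed per-fold sufficient statistics
(class counts and per-class feature sums, subset by column at evaluation
time) are what keep a 2,400-evaluation run near fifteen seconds.

## Fast stage: chi-square filter

Each feature's score is the Pearson statistic of its 2 × K contingency
table against the label, $\sum (O-E)^2/E$ over cells with $E > 0$. Cells
with zero expectation contribute 0 — rare classes make empty cells routine
— and a constant feature scores exactly 0. Scores rank; there is no
p-value or degrees-of-freedom thresholding, because the stage only needs an
ordering. Ties break toward the lower column index, making truncation
deterministic and nested: survivors at $v=k$ are a subset of survivors at
$v=k+1$. The default $v = \lceil u/2 \rceil$ is a neutral half-truncation;
the reference text requires only $v < u$ and never reports its value, so
$v$ is exposed everywhere in the API and CLI.

## Accurate stage: the hybrid optimizer

Candidate subsets are binary masks ("1" = selected). Each cycle is one GA
generation followed by one Tiki-Taka (T²A) generation, the GA output
population feeding the T²A input and vice versa — the hybrid's stated data
flow. The GA half uses roulette-wheel selection gated by $P_{sel}$ (with
probability $1-P_{sel}$ the pair is uniform — the reference leaves the
gate's semantics open; this reading keeps $P_{sel}$ a probability),
one-point crossover at $P_{cross} = 0.9$, single-bit flip mutation at
$P_{mut} = 0.01$, and elitism of one.

The T²A half treats each mask as a player with a continuous position and a
ball. Positions and balls are re-seeded from the incoming binary masks as
0/1 reals at each hand-off (the reference converts continuous→binary but
never the reverse; the 0/1 embedding is the natural section of the
binarization). Ball update, per player $i$ with cyclic neighbour $i+1$:
successful pass ($rand_p > \varepsilon$) moves the ball forward along the
neighbour distance scaled by $r \in (0,1]$; a lost ball
($rand_p \le \varepsilon$) reflects it by $C_1 + r$. Player update pulls
toward the own ball with weight $rC_2$ and toward the key player $q$ (the
max-fitness position) with weight $rC_3$. The neighbour ring is over
*players*: the printed wrap condition indexes by the feature count, which
cannot apply to passing between entities, so the last player passes to the
first.

**Binarization.** The printed transfer rule sets a bit when
$r \ge \mathrm{sig}(\text{position})$ — the *opposite* of standard binary
metaheuristic practice, where large positive coordinates should be likely
selections. The package implements the printed rule as the default
(`transfer_rule = "as_printed"`) and offers `"conventional"`
($r < \mathrm{sig}$) as an option. Under the printed rule the T²A half
behaves as a strong, nearly unbiased explorer while elitism and the GA half
exploit; empirically that combination still reaches exhaustive-oracle
optima on small instances (an acceptance criterion), so the literal rule is
kept rather than silently "fixed". An all-zero binarization is repaired by
setting one uniform bit, so every candidate keeps at least one feature.

Other resolved ambiguities: the ball-update coefficient printed as $C_i$ is
read as $C_1$ (the only defined reflection coefficient); the two printed
sigmoid equations are typographically identical, so one function serves
both ball and player; fitness ties break toward smaller popcount (prefer
parsimonious subsets, deterministic results).

**Stopping.** `max_it = 200` cycles (the tuned budget) or `patience = 30`
cycles without best-fitness improvement, whichever comes first; the
reference lists only the former. Population size defaults to 30 — the
reference leaves it unset ("c"/"x") — matching common GA practice at this
problem size. Best-so-far fitness is recorded per cycle; elitism makes the
history non-decreasing, which every run's tests assert.

## Rejection layer

The reference describes GA outlier rejection only narratively: evolve
subsets of "normal" points, fitness "measures how well the selected data
points fit a certain model". This package makes that concrete: the fitness
of an inlier mask is the cross-validated NB accuracy of the retained rows
minus $\lambda \cdot$ (fraction removed), $\lambda = 0.5$ by default.
Tying the fitness to the downstream classifier is in the spirit of the
wrapper layer; the penalty blocks the degenerate optimum of deleting every
hard row. Feasibility constraints — at most `max_removal_fraction` (10%)
of rows removed, every class retaining `min_per_class` (2) rows — score 0.
Masks are initialized at Bernoulli(0.95) ones plus the all-ones mask as the
first individual, so "remove nothing" is always reachable and
`max_removal_fraction = 0` reduces the layer to the identity exactly.
Operator probabilities reuse the tuned selection-layer values; mutation is
per-bit at $P_{mut}$ (row masks are long and near-saturated, so the
single-bit rule used for feature masks would mix far too slowly). The
population size (30) and generation budget (40) are package defaults — the
reference specifies neither.

Rejection runs on the training partition only. Filtering test rows would
leak the evaluation; the pipeline asserts the test partition is untouched
by any training stage.

## The synthetic world

`generator_config()` defaults emulate the reference dimensions: 41
diseases × 132 symptoms × 120 cases each = 4,920 cases, split 70/30 into
3,444/1,476. Each disease owns a *disjoint* block of 3 characteristic
symptoms, on with probability `p_on = 0.9` in its cases; all other symptoms
fire at `p_noise = 0.05`. Disjointness is a deliberate idealization: it
makes the ground-truth informative mask unambiguous, so feature-recovery
tests have an exact target. The noise rates are package choices (the
reference never characterizes its data-generating process); 0.9/0.05 gives
a benchmark hard enough that feature selection matters but clean enough
that recovery is decidable — roughly the regime its headline accuracies
suggest. Outliers are planted by choosing rows uniformly without
replacement and either reassigning the label to a different uniform class
(`label_shuffle`) or resampling the bits Bernoulli(0.5)
(`symptom_scramble`); the reference mentions both recording errors and rare
conditions, hence both modes.

What the generator does *not* emulate: correlated symptoms, diseases
sharing symptoms, class imbalance, missingness, and symptom sets of varying
size. A green recovery test therefore establishes that the machinery finds
planted independent structure at realistic noise — not that it would rank
features correctly under real comorbidity patterns.

One arithmetic consequence is worth making explicit. The standard benchmark
plants $41 \times 3 = 123$ informative features but the accurate stage
selects at most $v = 66$, so strict recall of planted features is capped at
$66/123 \approx 0.54$ by construction. The planted-recovery acceptance
test therefore measures the planted rate *among the selected features*
(the precision of the selected set, threshold 0.8) — the quantity that is
actually free to vary in this world. On the benchmark the chi-square stage
alone nearly saturates it, which is itself informative: with disjoint
informative blocks the filter does most of the work, and the wrapper's
contribution shows up on the small exhaustive-oracle fixtures instead.

## Evaluation conventions

Accuracy and error are percentages summing to 100 by construction.
Precision and recall are **macro-averaged** over classes (the reference
reports single values for a 41-class problem without stating the averaging;
macro matches its pattern of precision well below accuracy, since rare
classes weigh equally). Multiclass AUC is macro one-vs-rest, computed per
class by the Mann–Whitney rank statistic with half-credit ties and checked
against an all-pairs oracle to $10^{-6}$. Cross-validation is stratified
k-fold, default $k = 10$, the per-fold table carrying an `Average` row that
is exactly the arithmetic mean of the folds. Multi-run summaries use the
inclusive (median-of-halves) quartile convention — unambiguous and
testable. The KNN baseline uses Hamming distance, $K = 7$ (the tuned
value), distance ties toward the lower training index and vote ties toward
class order.

## Determinism and seeds

Every stage draws from a seed derived as a pure function of one global
seed (`derive_seed()`, a 32-bit linear map), and every entry point
saves/restores the caller's RNG state. Same config + seed therefore
reproduces results byte-identically — an acceptance criterion, not a hope.
Seeded determinism is also why the fitness cache is sound: the fold
assignment is part of the seed's stated world.

## Known limitations

- The printed transfer rule makes T²A exploration nearly label-blind; on
  large $v$ the GA half and elitism carry exploitation. The `conventional`
  rule is one flag away when exploitation-heavy search is wanted.
- The rejection layer's GA is expensive relative to statistical outlier
  detectors and is intended for offline use, matching its narrative source;
  at 10% planted corruption it removes outliers at far-above-chance rates
  but does not reliably remove *all* of them within the default budget.
- No support for continuous features, missing values, or sparse storage;
  CSV is the only interchange format.
- Indices are 1-based throughout, as in any R API.
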