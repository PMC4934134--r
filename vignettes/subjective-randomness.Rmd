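---
title: "Modeling subjective randomness with asymmetric entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling subjective randomness with asymmetric entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subrand)
```

## The phenomenon and the model

When people rate how "random" a binary string looks, they do not peak at the
string statistics a normative information-theoretic criterion would pick out.
Sequences whose probability of alternation

$$P(A) = \frac{r - 1}{n - 1}$$

(with $r$ runs in $n$ symbols) is around 0.6–0.7 are judged *more* random
than sequences at $P(A) = 0.5$, even though the second-order Shannon entropy

$$H_2 = H(\text{digram}) - H_1$$

is maximal at 0.5 and symmetric around it. This is the overalternating bias.
`subrand` models the bias by replacing the Shannon entropy inside $H_2$ with
families whose maximum can sit elsewhere:

* **Rényi entropy of order $\alpha$**,
  $H_\alpha(P) = \frac{1}{1-\alpha}\log_2 \sum_i p_i^\alpha$ — still
  symmetric in the event probabilities, included as the natural one-parameter
  generalization (it encompasses Hartley, collision and min entropy; at
  $\alpha \to 1$ it is Shannon).
* **Marcellin's asymmetric entropy**,
  $H_W(P) = \sum_i \frac{p_i(1-p_i)}{(1-2w_i)p_i + w_i^2}$ — maximal at a
  fitted "worst distribution" $W$ rather than at the uniform. With the four
  digram categories (OO, OX, XO, XX) as events, alternating-digram weights
  above 0.5 and uniform-digram weights below 0.5 produce exactly the
  right-skewed rating curve people exhibit.

All logarithms are base 2 (information in bits). Conventions:
$0\log(1/0) = 0$, $0^\alpha = 0$, the support size at $\alpha = 0$ counts
strictly positive masses, and $\alpha = \infty$ is an explicit sentinel
(`Inf`), never inferred from magnitude.

## Second-order entropy: two formulations

The printed definition of $H_2$ is the *difference* form: family entropy of
the digram distribution minus family entropy of the first-order symbol
distribution. For Shannon this equals, by the chain rule, the *conditional*
form — the mixture over the current symbol of the entropy of the next-symbol
conditional distribution. For Rényi with $\alpha \neq 1$ and for Marcellin
the chain rule fails, so the two formulations are genuinely different
measures; `entropy_config(formulation = )` exposes both, with `difference`
as the default because that is the form the fitting target was defined with.

Two deliberate choices here:

* The conditional form weights the per-symbol conditional entropies by the
  **digram first-symbol marginal**, not by the symbol frequencies over all
  $n$ positions. For a finite string the two differ by the last symbol;
  using the marginal keeps the Shannon chain-rule identity exact, which is
  the property that defines the formulation in the first place.
* In the conditional Marcellin form the worst-distribution pairs are
  $(w_{XX}, w_{XO})$ given X and $(w_{OO}, w_{OX})$ given O. The published
  fitted weights sum to about 2.0 over the four digrams — i.e. $W$ is not a
  distribution over digrams, but each conditional pair is nearly proper
  ($\approx 0.98$ and $\approx 1.02$) — which is why the conditional reading
  is offered at all. How the original analysis combined the four-category
  Marcellin entropy with the first-order term is not stated; both readings
  are implemented and neither is asserted to be the authors' exact
  computation.
* In the difference form, Marcellin's first-order term uses a symmetric
  worst distribution $(0.5, 0.5)$ by default. Only four digram weights were
  ever fitted, and the stimulus designs hold the symbol split nearly
  constant (11:10), so this term is a near-constant offset; fitting it would
  add parameters the target data cannot identify.

## Evaluating the model at a design level

The rating experiments present 21-symbol strings at exact alternation levels
$P(A) \in \{0.1, \ldots, 1.0\}$. `model_curve()` evaluates the model
analytically per level via `expected_digram_dist()`: alternating mass $P(A)$
split equally between XO and OX, uniform mass $1 - P(A)$ equally between XX
and OO. Within any single linear string $|c_{XO} - c_{OX}| \le 1$, and the
equivalence constraints below force the corresponding weights to be nearly
equal, so a finer split (e.g. proportional to symbol counts) changes $H_2$
negligibly; the symmetric split is exactly reproducible, which the stochastic
alternative (averaging scores over generated stimulus sets) is not. Averaging
over concrete sets remains possible by scoring a `generate_fk_set()` output
directly.

Note that every analytic level distribution is a *product* distribution
(uniform marginal times a shared conditional), so on these inputs Rényi's
additivity makes the difference and conditional formulations coincide; they
separate only on asymmetric digram distributions such as those of real
sequences.

## The fitness and its normalization

The fit minimizes the Euclidean distance between the model curve and the
mean-rating curve. Ratings (0–10) and entropies (bits, or Marcellin's
dimensionless values) are on different scales, and how the original analysis
aligned them is unstated. The default here, `minmax_both`, min–max rescales
**both** vectors to $[0, 1]$ over the evaluated levels and compares shapes —
the only option that is well defined without the unpublished rating values.
`ratings_div_scale` (divide ratings by the scale maximum, model raw) and
`none` are selectable. Published fitness magnitudes depend on this choice,
which is one reason the package does not claim to reproduce them. A flat
curve min–max normalizes to all 0.5 (degenerate-case convention; it can only
arise for parameter-free flat families such as Rényi at $\alpha = 0$).

## Differential Evolution and the constraints

`de_optimize()` is classic rand/1/bin DE: mutation
$v_m = v_1 + F (v_2 - v_3)$ from three distinct members other than the
target, binomial crossover at rate $CR$ with one forced mutant component,
greedy one-to-one selection. Defaults: population 20, 100 generations,
$F = 0.6$, $CR = 0.9$ (the best cell of the $F \times CR$ tuning grid —
`tune_parameters()` reruns that 20 × 9 grid). Choices where standard DE
practice fills gaps the description leaves open:

* Mutants are clipped to the bounds component-wise.
* Crossover always takes at least one component from the mutant.
* Psychological equivalence of XX with OO and of XO with OX is imposed as
  relative-distance constraints $2|w_a - w_b|/(w_a + w_b) \le 0.1$
  per pair. Infeasible trial vectors are discarded and regenerated, up to
  `max_retries = 100`, after which the target survives the duel — this caps
  the inner loop and guarantees termination; at tolerance 0.1 exhaustion is
  vanishingly rare once the population is feasible.
* *Initial* members are not generated by rejection: a uniform draw on
  $(0,1)^4$ satisfies both pair constraints only ~0.3% of the time, so the
  paired component is drawn directly inside its feasible band
  $[a\frac{2-\text{tol}}{2+\text{tol}}, a\frac{2+\text{tol}}{2-\text{tol}}]$.
* The Rényi search interval's upper bound is not stated anywhere; the
  default is $(0, 10]$ on a linear scale, configurable via `alpha_max`. The
  fitted orders of interest sit near 2, far from the bound.
* Convergence is defined *relative to the best fitness across runs*: a run
  converged when its best fitness is below the global best plus 1%. A single
  run therefore has no intrinsic convergence flag (`converged = NA`);
  `fit_entropy(n_runs = )` and `tune_parameters()` fill it in. Because the
  band is relative, it is unmeetable for objectives whose optimum is exactly
  0 — benchmark objectives in the tests are shifted accordingly.

Everything is driven by a single integer seed and is bitwise reproducible.

## What the synthetic generators emulate

`generate_fk_set()` reproduces the classical rating-stimulus design: sets of
ten 21-symbol strings at exact run counts $r = 20 P(A) + 1$ (exact, not in
expectation — the design fixes $r$ per level), half of each set with 11 Xs
and 10 Os and half reversed, run lengths drawn as uniform random
compositions (stars and bars), starting symbol alternating across the set to
balance XO against OX in aggregate (the fully alternating level must start
with the majority symbol). The actual 40 strings used historically were
never published; generated sets are statistically matched stand-ins, never
claimed identical.

`synth_rating_curve()` produces ground-truth rating curves for parameter
recovery: the model curve of a known configuration, min–max rescaled to the
rating scale, plus optional i.i.d. Gaussian noise in rating units, clipped
to the scale. It simulates *mean* curves only — no individual raters,
response processes, or rater counts, because the fitting target is a mean
curve. Consequently a green recovery test establishes that the
fitter inverts its own forward model (including under moderate noise); it
does not establish anything about fit quality to real human data, which the
pipeline can only assess when a user supplies a rating CSV.

`enumerate_octograms()` lists the 128 canonical length-8 sequences (all 256
modulo complementation; the canonical form is the lexicographically smaller
of a string and its complement with O < X). These feed the validation stage,
where `correlation_report()` computes Pearson correlations between measure
scores and observed classification proportions, dropping rows with undefined
scores pairwise per measure.

## Known limitations

* The published best-fit fitness values and validation correlations are not
  reproducible from printed information (the 10 target means and the
  128-sequence response proportions were never published); the package
  ingests user-supplied CSVs so they become reproducible if the data are
  obtained.
* The Difficulty Predictor is length-insensitive by construction (a long and
  a short string can share a score); this is a documented property of the
  original score, reproduced as-is.
* DP's minimal segmentation requires alternating blocks of length ≥ 3: a
  length-2 "alternation" costs 2, exactly the same as its two runs, so
  admitting it would only create ties. The score is unaffected; only the
  reported partition needs the rule (ties among minimal partitions are
  broken toward fewer alternating blocks, then fewer blocks).
* Only two-symbol alphabets are supported; two-dimensional grid stimuli are
  out of scope.

## A worked recovery example

```{r recovery, eval = FALSE}
w_star <- c(OO = 0.30, OX = 0.69, XO = 0.68, XX = 0.33)
curve <- synth_rating_curve(entropy_config("marcellin", weights = w_star))
fit <- fit_entropy("marcellin", curve, control = de_control(seed = 101))
fit$params   # recovers w_star up to swapping within the constrained pairs
```

The objective is exactly symmetric under swapping the members of each
constrained pair (the two uniform-digram terms, and the two
alternating-digram terms, enter the curve interchangeably), so recovery is
judged up to pair orientation; the constrained pairs differ by at most 0.03,
well inside the recovery tolerance.
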