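---
title: "Methods: hybrid fuzzy-rough inference for lying-pose detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid fuzzy-rough inference for lying-pose detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frsys)
```

## The problem

Depth-camera fall-detection systems for the elderly work in two stages: a
per-frame posture classifier decides whether the silhouette is in a lying
pose, and a separate movement analyser decides whether a lying pose was
preceded by a fall. `frsys` implements the first stage as a hybrid
fuzzy-rough system. A frame is summarised by four silhouette descriptors:

* `hw` — bounding-box height/width ratio (dimensionless),
* `hmax` — current silhouette height over the person's physical height,
* `sigma` — the larger of the point-cloud standard deviations along the two
  horizontal camera axes (millimetres),
* `p40` — fraction of silhouette points within 40 cm of the floor.

A standing person has large `hw` and `hmax` and small `p40`; a person lying
on the floor has the opposite signature. The classifier fuzzifies the four
features over three linguistic labels each (`Lo`, `Me`, `Hi`), fires a rule
base mapping label conjunctions to the pose classes `isLy`, `mayLy`,
`notLy`, and defuzzifies a pose output variable on $[0,1]$ by centre of
gravity; a centroid below 0.5 is read as lying.

## Fuzzy operators

All connectives operate on membership degrees in $[0,1]$ and are validated,
not clamped: out-of-range inputs are errors. Comparisons in all internal
checks use absolute tolerance $10^{-12}$.

* **Negations** — standard $1-p$; power $(1-p^w)^{1/w}$; $1-p^2$ (strict but
  not involutive, included for completeness though nothing downstream uses
  it); the Sugeno family $(1-p)/(1+\lambda p)$, $\lambda > -1$.
* **Implications** — Łukasiewicz, Fodor, Rescher, Reichenbach,
  Kleene-Dienes.
* **Aggregations** — the lattice, algebraic and Łukasiewicz t-norm/t-conorm
  pairs, arithmetic/geometric/quadratic means, and OWA (descending sort,
  then a weighted sum; weights must sum to 1 within $10^{-12}$).
* **Pre-aggregations** — $F(p,q) = p - (\max(0, p-q))^2$ and the weighted
  Lehmer mean. Both satisfy the boundary conditions but are only
  *directionally* monotone; the test suite records explicit
  counterexamples to full monotonicity.

The associative binary kinds extend to $n$ arguments by left fold. `pre_f`
and `lehmer` are deliberately **strictly binary**: in this system they only
ever appear as the outer combiner of the knowledge operator, and a silent
fold would change their meaning. The classic-mode experiment presets
therefore use `Tm`, `Tp` and `Amean` over the four premises; OWA remains
available when weights of matching arity are supplied.

## Precedence indicator and knowledge measure

The system's central construction is a graded subsethood ("precedence")
indicator on degrees,
$$\mathrm{Prec}(p,q) = \begin{cases} 1 & p \le q\\ A(N(p), q) &
\text{otherwise,}\end{cases}$$
for a negation $N$ and an aggregation $A \le \max$, checked empirically on
a $101\times101$ grid at construction. Its axioms: it vanishes only at
$(1,0)$ (P1), equals 1 exactly on $p\le q$ (P2), and is antitone/isotone in
its arguments (P3).

A knowledge measure — the dual of fuzzy entropy, maximal on crisp
membership vectors, minimal on the all-0.5 vector, monotone under
sharpening, complement-invariant — is built from any such indicator whose
$A$ is symmetric and whose $N$ is strong with equilibrium $0.5$:
$$K(R) = \frac1n \sum_i
\frac{|\mathrm{Prec}(1, x_i) - \mathrm{Prec}(x_i, 0)|}
     {1 - \min(\mathrm{Prec}(1, x_i), \mathrm{Prec}(x_i, 0))}.$$
With $A = \max$ and the standard negation each term reduces to the closed
form $|2x-1| / (1 - \min(x, 1-x))$, which the tests verify elementwise to
$10^{-12}$. Length-1 vectors are allowed ($n = 1$ is a legitimate
cardinality). Two literature measures are provided for comparison:
$K_{SLS} = \frac1n\sum 2[x_i^2 + (1-x_i)^2] - 1$ and
$K_{AK} = \log_2\left[\frac2n \sum (x_i^2 + (1-x_i)^2)\right]$.

**A numerical finding.** The construction is stated in its source for any
$A \le \max$, including $\min$ and the geometric mean. Both of those vanish
on the axes, so $\mathrm{Prec}(0.5, 0) = A(N(0.5), 0) = 0$ and P1's "only
at $(1,0)$" direction fails; the derived measure then collapses to the
fraction of crisp elements and violates K2's "iff". The construction is
sound exactly when $A(p,q) = 0$ iff $p = q = 0$ (arithmetic mean, quadratic
mean, max). The package ships all five variants as listed, and the test
suite asserts the full axiom set for the sound ones and the characterised
degeneracy for $\min$/geometric-mean.

## The knowledge-augmented inference engine

Classic Mamdani activation aggregates a rule's premise degrees with an
inner aggregation $A$. Knowledge mode replaces this by
$$\mathrm{OR} = B\bigl(A(p_1, \dots, p_n),\; K(p)\bigr),$$
where $K$ is evaluated on the same premise vector and $B$ is a binary outer
combiner. Confident premises pass through unchanged (all-1 premises give
1); maximally fuzzy premises are suppressed ($K = 0$ drags the activation
down). The operator is only directionally monotone: raising a premise can
*lower* the activation when the knowledge term falls faster than the
premise aggregation rises (the tests freeze the counterexample
$p = (0.45, 1) \to (0.5, 1)$ under the `K2` preset). We read $K$'s argument
as the premise-degree vector of the rule being fired — the alternative
reading ($K$ of the antecedent label sets on their own universes) would be
input-independent and make the operator degenerate, so it was rejected.

Five named presets `K1`–`K5` cover the studied operator combinations,
written (inner $A$, outer $B$, precedence aggregation): K1 = (qmean,
pre\_f, qmean), K2 = (qmean, pre\_f, max), K3 = (min, pre\_f, qmean),
K4 = (amean, pre\_f, amean), K5 = (amean, min, max). `K2` is the reference
configuration.

Per pose class, rule activations are combined by **maximum**; each
consequent curve is clipped at the class activation by **min** (the
standard Mamdani clip — only the premise aggregation is modified in this
system); the three class sets are merged by pointwise maximum; the merged
set is defuzzified by centre of gravity. `mayLy` rules participate: they
shape the middle mass of the output set even though the final decision is
binary.

## Fuzzification: parameters and their reading

The shipped configuration (`posture_variables()`) carries the published
expert parameters: per feature a `Lo` Z-spline, a `Me` two-sided Gaussian
(`exp(-(x-c)^2/(2*sigma^2))` flanks around a plateau) and a `Hi` S-spline,
plus the pose output (`isLy` Z, `mayLy` Gaussian, `notLy` S). Decisions
taken where the printed table was ambiguous:

* **Three-parameter Z/S.** The middle printed value is the 0.5-crossover,
  redundant with $(a+b)/2$; the curve is anchored on $(a, b)$ and a stored
  crossover deviating by more than 5% of $b-a$ warns rather than errors
  (the printed `hmax` `Lo` triple $(0.25, 0.4, 0.6)$ deviates slightly and
  must still load).
* The printed `hw` `Me` parameter string is read as
  $(c_1, \sigma_1, c_2, \sigma_2) = (2, 0.5, 2, 0.4)$ — the trailing
  "0,4" is a decimal-comma typo; parameter order is unambiguous from the
  magnitudes.
* **Universes.** Feature universe bounds are not part of the published
  set; we use `hw` $[0,5]$, `hmax` $[0,1.1]$, `sigma` $[150,500]$ mm,
  `p40` $[0,1]$ — wide enough to contain every curve support with sensor
  margin. The pose universe is $[0,1]$ (its knots span 0.22–0.77); all of
  this is configurable through the YAML schema. Inputs outside a universe
  are clamped before evaluation.
* **Coverage.** The three label curves of each variable overlap everywhere,
  but not at the 0.5 level: the Z/S crossovers sit slightly inside the
  Gaussian half-width points, so the pointwise label maximum dips to about
  0.35–0.40 in the crossover gaps. The tests assert the property that
  actually holds (maximum $> 0.3$ everywhere, no dead zones).

## Rule bases

**Knowledge approach.** The full enumeration of $3^4 = 81$ label
conjunctions over the four features. The published class split
(13/52/16) cites an external rule list that is not reproduced; the shipped
default map is a documented, user-replaceable heuristic: an antecedent is
scored by Hamming distance against the concept prototypes — lying
$(\mathrm{Lo}, \mathrm{Lo}, \mathrm{Lo}\vee\mathrm{Me}, \mathrm{Hi})$,
not-lying $(\mathrm{Hi}\,|\,\mathrm{Me}, \mathrm{Hi}\,|\,\mathrm{Me},
\mathrm{Lo}, \mathrm{Lo})$ — and the strictly nearer concept wins at
distance $\le 1$, everything else being `mayLy`. This yields a
15/46/20 split; explicit JSON maps replace it when the original list is
available.

**Rough-set approach.** LEM2 computes a local covering per concept of a
decision table: grow a complex by repeatedly taking the attribute-value
pair covering most of the remaining goal (ties: smaller block, then first
pair in canonical order — attributes in table order, values in domain
order, which pins the output deterministically), prune each complex to a
minimal one, and drop redundant complexes. Two deviations from the printed
algorithm, both forced by correctness:

* an inconsistent table (identical condition rows across the concept
  boundary) makes the goal set impossible to empty; this is detected up
  front and raised as an error naming the clashing objects, rather than
  looping;
* complex pruning never empties a complex (dropping the last pair would
  leave the all-objects block, only relevant when a concept spans the
  whole table).

Continuous features are discretised by argmax membership (ties to the
lower label). Noisy data can discretise into conflicting patterns;
`discretize(resolve = "majority")` resolves each conflicting pattern to
its majority class before induction.

## Synthetic data: what it emulates and what it does not

`synth_generate()` draws features per class uniformly from the
full-membership core of each profile's target label plus Gaussian noise
with standard deviation `noise_scale` times the label's support width
(for two-sided Gaussians, $\sigma_1 + \sigma_2$), clamped to the universe;
disjunctive targets pick one label uniformly per sample; `mislabel_rate`
flips that fraction of each class's labels. Defaults — `noise_scale` 0.15,
`mislabel_rate` 0.02, 500 frames per class — were chosen once so that
classic-mode accuracy lands in the 0.93–0.98 band of the original study
without claiming its exact values, and are not tuned thereafter.

The generator emulates the *separability structure* of the real data (two
classes anchored at the concept profiles, small label noise, a few
percent of ambiguous frames). It does **not** emulate: correlations
between features induced by body geometry, temporal continuity across
frames, the real class imbalance (about 3:1 lying/not-lying in the
benchmark counts), or genuinely intermediate postures (sitting,
crouching) whose mass falls between the label cores. Passing the
synthetic experiment therefore shows that the pipeline is wired correctly
and robust to the modelled noise — not that the published real-data
accuracies are reproduced. Accordingly, on this clean synthetic geometry
every reasonable configuration attains the same accuracy (limited only by
the flipped labels), whereas the real-data tables separate the operator
choices; the published confusion counts are shipped verbatim
(`reference_results()`) so the metric formulas themselves are verified
against all 72 printed cells. Six of those printed cells disagree with
their own counts by one unit in the last digit; the cross-check reports
them rather than hiding them.

## Evaluation conventions

The positive class is `isLy`: specificity is the not-lying detection
rate. An all-zero output set (no rule fires) maps to `notLy` with a
warning — a fail-safe, since no evidence of lying must not raise an
alarm. Table comparisons round half away from zero to the printed
precision (base R rounds half to even). Rule effectiveness after an
evaluation run is the pair (correct classifications / set size, correct
classifications / class size); a frame's correct classification is
credited to the most strongly activated rule among those concluding the
predicted label, and rankings sort by the first ratio, then the second.

## Numerical choices

* Pose grid: 1001 points (doubling it moves any centroid by well under
  $10^{-3}$; the centre of gravity agrees with a $10^5$-point quadrature
  to the same order).
* Decision threshold: 0.5, the crossover region between the `isLy` and
  `notLy` output curves; configurable.
* Spec validation grids: $101 \times 101$ at construction (aggregation
  bound, symmetry, strong-negation checks), absolute tolerance
  $10^{-12}$.
* Desk-scale problem sizes: 500 frames/class for the end-to-end
  experiment, 200 random tables (up to 10 objects, 4 attributes) for the
  LEM2 property harness, $10^4$ random vectors for the knowledge-axiom
  harness.

## A worked example

```{r example}
fr <- frsystem("knowledge", k_config("K2"))
fr
predict(fr, data.frame(hw = c(0.7, 3.0), hmax = c(0.3, 0.95),
                       sigma = c(380, 270), p40 = c(0.6, 0.2)))
```

## Limitations

The second-stage movement analysis (and its Sugeno trigger), depth-map
segmentation and feature extraction are out of scope: the package starts
from extracted feature vectors. The published real-data results depend on
the original depth-map dataset and are represented here only through
their confusion counts; the LEM2 rule count on synthetic data (typically
a handful of rules) is much smaller than the published 44 because the
synthetic geometry is cleanly separable. Interval-valued operators are
future work in the source literature and are not implemented.
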