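---
title: "Time-delayed, ontology-aware evaluation of protein function predictions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-delayed, ontology-aware evaluation of protein function predictions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funbench)
library(dplyr)
```

## The evaluation problem

Predicting the function of a protein means predicting a *set* of Gene
Ontology (GO) terms — a structured-output, hierarchical multi-label
problem, separately in each of the three GO aspects (Molecular Function,
Biological Process, Cellular Component). Scoring such predictors fairly
has two well-known difficulties, and this package implements the
community's standard answers to both:

1. **Circularity.** If the ground truth existed when predictors were
   trained, evaluation leaks. The *time-delayed* design compares two
   annotation snapshots — one frozen at a submission deadline
   (`ts`), one taken years later (`tB`) — and scores predictions only on
   the experimentally supported annotations *gained* in between.
2. **Hierarchy.** A predicted term implies all its ancestors, and a true
   term credits them. Both predictions and truth are therefore
   *propagated* to their ancestral closure in the ontology DAG before any
   counting.

From the two snapshots, every (protein, aspect) pair falls into one of
three evaluation settings: **NK** (No Knowledge: no experimental
annotation in any aspect at the deadline), **LK** (Limited Knowledge:
none in the evaluated aspect but some elsewhere), or **PK** (Partial
Knowledge: annotations in the evaluated aspect that later grew). PK is
the setting that increasingly matters for model organisms, and it is the
reason all formulas here carry a *prior-subtraction* term: predictions
of what was already known at the deadline are neither rewarded nor
penalised as discoveries.

## The metrics

For a benchmark B of n proteins, write $P_i(\tau)$ for the terms
predicted for protein $i$ with score $\ge \tau$, $T_i^{ts}$ for the
propagated deadline-time annotation (the *prior*, empty in NK/LK), and
$T_i^{tB}$ for the propagated benchmark-time annotation, so the gained
truth is $T_i^{tB} \setminus T_i^{ts}$. With
$m(\tau)$ = number of proteins whose *effective* prediction set
$P_i(\tau) \setminus T_i^{ts}$ is non-empty:

$$
pr_M(\tau) = \frac{1}{m(\tau)} \sum_{i}
  \frac{|\,(P_i(\tau)\setminus T_i^{ts}) \cap T_i^{tB}\,|}
       {|\,P_i(\tau)\setminus T_i^{ts}\,|},
\qquad
rc_M(\tau) = \frac{1}{n_e} \sum_{i}
  \frac{|\,P_i(\tau) \cap (T_i^{tB}\setminus T_i^{ts})\,|}
       {|\,T_i^{tB}\setminus T_i^{ts}\,|}
$$

and $F_{max} = \max_\tau 2\,pr\,rc/(pr+rc)$, in a **macro** flavour
(average the per-protein ratios, as above) and a **micro** flavour (pool
numerators and denominators over proteins before dividing). The
ia-weighted analogues are the remaining uncertainty and misinformation

$$
ru(\tau) = \frac{1}{n_e}\sum_i \sum_f ia(f)\,
  \mathbb{1}[f \notin P_i(\tau) \wedge f \in T_i^{tB}\setminus T_i^{ts}],
\qquad
mi(\tau) = \frac{1}{n_e}\sum_i \sum_f ia(f)\,
  \mathbb{1}[f \in P_i(\tau) \wedge f \notin T_i^{tB}],
$$

summarised by $S_{min} = \min_\tau \sqrt{ru(\tau)^2 + mi(\tau)^2}$, in
bits. The *information accretion* $ia(f)$ is
$-\log_2 \hat{P}(f \mid \text{parents of } f)$ estimated from a
reference corpus of propagated experimental annotations, so missing a
deep, specific, surprising term costs more than missing a broad one.
In **complete** mode $n_e = n$; in **incomplete** mode $n_e = m(0)$,
restricting the recall-side averages to the proteins the method chose to
predict on. Coverage $C = m(0)/n$ reports that choice separately.

## Design decisions and numerical conventions

Several points are underdetermined by the definitions above; the package
fixes them as follows, and the test suite asserts each one.

* **Propagation relations.** Ancestral closure follows `is_a` and
  `part_of` edges within an aspect, the established practice for this
  evaluation; `regulates`-type relations are excluded, and
  `read_obo(relations = "is_a")` gives an is_a-only closure.
* **Aspect roots** are removed from every propagated set. They are true
  of every annotated protein, carry $ia = 0$, and would otherwise let an
  empty predictor harvest free precision. A `keep_roots` flag exists on
  `propagate_terms()` for inspection.
* **Smin under the radical.** The minimised quantity is the Euclidean
  norm of the $(ru, mi)$ pair — the established semantic-distance
  definition. (Statements of the formula sometimes drop the radical or
  print "max"; the package implements the min-norm form deliberately.)
* **Macro precision in PK** scores effective predictions against the
  *full* benchmark-time annotation $T_i^{tB}$: re-predicting a prior
  term is excluded from the numerator and denominator by the
  subtraction, but predicting a still-true old term is not counted as
  wrong. `sweep_curve(novelty_only = TRUE)` switches the numerator to
  the strictly gained truth for sensitivity analysis; with empty priors
  the two are bit-for-bit identical (asserted on 100 random fixtures).
* **m(tau)** counts proteins with a non-empty *effective* set, so macro
  precision never averages 0/0 terms; in NK/LK this coincides with
  "proteins with at least one prediction". Per-protein recall
  denominators cannot be empty because benchmark membership requires
  non-empty gained truth (a constructor invariant, not a silent patch).
* **0/0 conventions.** $F = 0$ when $pr + rc = 0$; micro precision is 0
  when nothing is predicted; ties in $F_{max}$/$S_{min}$ resolve to the
  smallest threshold.
* **Threshold grid.** The default sweep evaluates every distinct
  submitted score plus 1.0. The curve is a step function that changes
  only at those values, so this grid is exact, and equality with a
  brute-force oracle is well-defined (asserted to machine precision on
  200 random fixtures). The historical 101-point grid
  (`thresholds = "fixed101"`) is provided for comparability and can only
  under-estimate $F_{max}$.
* **Zero-count information accretion.** A term whose conditional
  frequency cannot be estimated finitely (no reference protein carries
  all its parents, or the term is never annotated) receives the maximum
  finite ia observed in its aspect, with a message. This keeps rare
  terms maximally informative without putting infinities into $S_{min}$.
* **Duplicate predictions** (same protein, same term) collapse to the
  maximum score: deterministic and order-independent, and consistent
  with max-propagation, which already takes maxima over descendants.
* **Evidence filter.** The 13 experimental evidence codes include TAS
  and IC, which GO itself classes as author/curator statements; the
  challenge's ground-truth convention takes precedence here. Negative
  annotations are any whose qualifier contains the token `NOT`. The
  blanket "protein binding" term GO:0005515 is excluded *before*
  propagation, so its ancestors survive when other terms imply them.
* **Benchmark difference after propagation.** Gained truth is
  `propagate(tB) \ propagate(ts)`, not the propagation of the raw
  difference: a new leaf under an already-annotated branch contributes
  only its genuinely novel ancestors, and a protein whose propagated set
  did not grow is excluded entirely.
* **Common-term ontology.** When several ontology versions must agree
  (for cross-challenge comparisons), the restriction keeps the
  intersection of term sets and reconnects each surviving term to its
  minimal surviving ancestors in the *newest* version (transitive
  reduction over retained terms), preserving the newest version's
  propagation semantics across removed intermediates.
* **Bootstrap.** Confidence intervals resample benchmark *proteins* with
  replacement (the evaluation is per-protein), 1000 iterations in
  standard use, percentiles 2.5/97.5 by linear interpolation between
  order statistics (type-7), so a sort-and-index oracle can reproduce
  them exactly. Each method's interval uses an RNG stream derived from
  the master seed and the method id, so adding a method never perturbs
  existing intervals. Team-best selection happens once, on the full
  benchmark, before bootstrapping. Internally a resample is evaluated by
  reweighting per-protein threshold statistics on the union grid of all
  distinct scores; because the curves are step functions changing only
  at a resample's own score values, this is bit-identical to re-sweeping
  each resample from scratch (asserted in the tests).

## The synthetic-data generator

Real benchmark construction needs dated annotation databases and
submission archives that are neither small nor redistributable, so the
package carries a generator that emulates every input: random rooted
per-aspect DAGs (each term attaching to 1–2 earlier terms, `part_of`
with probability 0.2), snapshots with a planted NK/LK/PK mixture, and
predictors of tunable quality. Defaults describe a small but realistic
study: 20 terms per aspect, 50 proteins, a 0.3/0.2/0.5 NK/LK/PK mixture
(every setting populated, PK largest as in well-annotated proteomes),
and a mean of 3 newly annotated leaves per protein between the
snapshots.

The predictor's score model draws true gained terms from
$\mathrm{Unif}(0.75q,\,1]$ and decoy terms (outside the protein's
benchmark-time annotation) from $\mathrm{Unif}(0,\,1 - q/2]$: at
quality $q = 0$ the distributions coincide, so scores carry no signal;
at $q = 1$ they are disjoint, so one threshold recovers the gained truth
exactly and $F_{max} = 1$, $S_{min} = 0$ are attained. Scores are then
max-propagated. Note the ranges already separate at $q = 0.8$, so the
interesting graded regime is $q \lesssim 0.75$.

What the generator deliberately does **not** emulate: GO's actual
topology (depth, fan-out, term-count distributions), annotation biases
(hub terms, species composition, literature-driven bursts), retracted
annotations, or correlated errors between methods. Passing the suite
therefore demonstrates that the *arithmetic* of benchmark construction
and scoring is exact under the stated definitions — not that any
particular biological conclusion transfers.

## Problem sizes used by the test suite

The package's own checks run, per property: 200 random fixtures
(3–5 proteins, 6–12 terms per aspect) for exact oracle equivalence of
$F_{max}$ and $S_{min}$; 100 fixtures for the PK-reduction identity; 500
for curve monotonicity and propagation closure; 50 for the
information-accretion counting oracle; planted-label recovery at 1000
proteins over 5 seeds; quality-monotonicity with 20 seeds per quality on
a 200-protein benchmark; and 1000-iteration bootstrap determinism,
degeneracy and percentile-oracle checks. These sizes were chosen so each
property is exercised well past the point where set-arithmetic mistakes
would surface, while the whole suite stays comfortably interactive.

## A worked example

```{r example}
fix <- simulate_fixture(fixture_spec(n_proteins = 30,
                                     predictor_quality = 0.5, seed = 7))
ev <- evaluate_method(fix$predictions[["q0.50"]], fix$benchmark,
                      fix$ontology, fix$ia)
glance(ev)
```

```{r curves, fig.width = 5, fig.height = 3.5}
autoplot(ev)
```

```{r bootstrap}
bootstrap_ci(fix$predictions[["q0.50"]], fix$benchmark, fix$ontology,
             fix$ia, metric = "fmax_macro", n_iter = 200, seed = 1)
```

## Known limitations

* The BLAST-style baseline consumes a precomputed hit table; running the
  alignment itself is out of scope.
* Evaluation is per-protein only; term-centric (per-term AUC) and
  weighted-F variants are not implemented.
* The OBO reader interprets the fields needed for evaluation (`id`,
  `name`, `namespace`, `is_a`, `relationship: part_of`, `is_obsolete`,
  `replaced_by`, `alt_id`) and is not a general ontology toolkit; OWL is
  not supported.
* Obsolete terms resolve through `replaced_by` only; `consider`
  suggestions are deliberately not auto-applied.
* Snapshots are trusted to be deduplicated by the filter step; the
  benchmark builder tolerates annotations retracted between `ts` and
  `tB` (the nominal subset relation is not enforced) and simply treats
  surviving gains as truth.
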