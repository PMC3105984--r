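---
title: "Reconstructing directed acyclic Boolean networks by two-step counting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing directed acyclic Boolean networks by two-step counting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dabnet)
```

## The model

A directed acyclic Boolean (DAB) network describes a set of genes (or other
elements) that are each either *on* (1) or *off* (0), constrained by two
kinds of pairwise relationships:

* **similarity** (`SIM`): two elements are on and off together; the joint
  states (0,1) and (1,0) never occur.  Its dual form (`SIM_DUAL`) ties an
  element to the complement of another, forbidding (0,0) and (1,1).
* **prerequisite** (`F01`, `F10`, `F00`, `F11`): the on-state of one
  element is necessary for the on-state of another.  Together with the
  dual-element variants this gives four patterns, each forbidding exactly
  one of the four joint states (the pattern's name is the forbidden cell).

A DAB network is fully determined by its *compatible state space*: the
assignments of on/off values that violate no relationship.  The bundled
seven-element worked example (`fig2_fixture()`) has 12 relationships and
exactly 13 compatible states out of $2^7 = 128$.

Observed data are a binary element-by-sample matrix in which every entry
has been flipped independently with an unknown but small
*misclassification probability* $\varepsilon < 1/2$.  The inference task
is to recover the pairwise relationships from such noisy samples.

## The two-step procedure

For each pair of elements, the package tabulates the $2\times 2$ joint
table $(n_{00}, n_{01}, n_{10}, n_{11})$, $N$ samples in total, and scores
all six candidate relationships.

**Step 1 — counting numbers.**  The counting number of a relationship is
the number of samples lying in its allowed cells.  Without noise a true
relationship counts exactly $N$; with noise it falls slightly short, so it
is screened against a lower confidence bound:

* similar: a sample stays on the diagonal when both entries are kept or
  both flipped, so the counting number is Binomial$(N, \pi_s)$ with
  $\pi_s = (1-\varepsilon)^2 + \varepsilon^2$, and the bound is
  $N\pi_s - z_\alpha\sqrt{N\pi_s(1-\pi_s)}$;
* prerequisite: the single forbidden cell receives at most
  $\varepsilon(1-\varepsilon)$ probability through single flips plus at
  most $\varepsilon^2 \le \tfrac12\varepsilon(1-\varepsilon)$ (for
  $\varepsilon\le 1/3$) through double flips, giving the conservative
  bound $N[1 - \tfrac32\varepsilon(1-\varepsilon)] -
  z_\alpha\,\varepsilon\sqrt{N(1-\varepsilon^2)}$, with the fluctuation
  term evaluated at the double-flip rate.

Both bounds equal $N$ at $\varepsilon = 0$, are monotone increasing in
$N$ and decreasing in $\varepsilon$.  The integer screening rule is
`count >= ceiling(bound)`; the ceiling keeps the noise-free case
selectable.  At $N = 100$, $\varepsilon = 0.05$, $\alpha = 0.05$ the
integer thresholds are 86 (similar) and 93 (prerequisite); at $N = 81$,
$\varepsilon = 0.1$ they are 61 and 69.

```{r}
c(similar = ceiling(similar_threshold(100, 0.05)),
  prerequisite = ceiling(prerequisite_threshold(100, 0.05)))
```

**Step 2 — asymptotic p-values.**  Each relationship hypothesis states
that its forbidden true cell(s) carry probability zero.  The package
tests this with a *forbidden-mass contrast*: under the null the forbidden
cell is in truth the smallest cell, and misclassification only shrinks
contrasts between cells (for the mirror cell of a prerequisite pattern
the null mean of the observed contrast is exactly
$-(1-2\varepsilon)p_M \le 0$ for every $\varepsilon < 1/2$, and the
$(1-2\varepsilon)$ factors cancel from the standardised statistic, which
is why $\varepsilon$ does not appear in it).  Concretely,

$$z = \frac{n_F - n_m + \tfrac12}{2\sqrt{N\bar q(1-\bar q)}},\qquad
  \bar q = \frac{n_F + n_m}{2N},$$

where $n_F$ is the forbidden count and $n_m$ the smallest competing cell
(for the similarity kinds, the total forbidden mass $V$ against the
allowed mass $N - V$ with pooled rate one half).  The continuity
correction $+\tfrac12$ reflects the discreteness of the contrast and
keeps an exact tie from counting as full support.  The p-value is the
folded upper tail clipped at one, $p = \min\{1, 2[1-\Phi(z)]\}$, so a
forbidden mass clearly below its competitor yields exactly $p = 1$.
Step 2 selects relationships with `round(p, 4) >= 1`: an exactly-one
p-value has probability ~1/2 under a continuous statistic, whereas the
clipped contrast attains it robustly for true relationships.

**Step 3** intersects the two screens.  Both are needed: counting alone
admits near-relationships whose forbidden cell is small by chance, and
the p-value alone admits relationships with overwhelming but imperfect
support.  When a similarity is selected for a pair, the two prerequisite
patterns it logically implies are folded into it, so each selected
relationship is reported once — that is why the worked example counts 12
maximal relationships rather than 14 raw (pair, kind) combinations: the
exactly-similar pair satisfies its two implied prerequisite patterns
automatically.

```{r}
fx <- fig2_fixture()
fit <- dab_infer(fx$states, epsilon = 0)
fit
```

## Error-model machinery

`observed_cell_probs()` pushes a true cell distribution through the
per-coordinate flip kernel; `estimate_true_probs()` applies its exact
algebraic inverse to empirical frequencies (the closed-form corrected
estimator for known $\varepsilon$).  The raw inverse can leave $[0,1]$
for extreme tables; the raw values are kept for anything algebraic and a
clipped, renormalised copy is returned for reporting.

When $\varepsilon$ is unknown, `estimate_epsilon()` maximises the
multinomial likelihood jointly over $\varepsilon$ and a true distribution
*constrained to a relationship* (forbidden cells zero).  The constraint
is essential: over the unconstrained simplex the model is saturated for a
whole interval of $\varepsilon$ and the rate is not identifiable.  With
`kind = NULL` all six constrained models are fitted and the best one
reported.  The same constrained fit, read as a score, is the second
comparison baseline (`lilu_relation_epsilon()`, `lilu_screen()`): a true
relationship should need only a small error rate to explain its table.
The optimiser is deterministic (coarse grid then local refinement), and
exact-fit tables return the boundary value $\hat\varepsilon = 0$.

The first comparison baseline (`sahoo_statistics()`, `sahoo_screen()`)
is the Boolean-implication test: sparseness $(E - O)/\sqrt{E}$ of the
implication's predicted-empty quadrant against its independence
expectation, plus a symmetric error-rate statistic, with the customary
cutoffs 3 and 0.1.  On a 91-sample table with a single stray observation
in the forbidden quadrant the sparseness reaches only 2.94, illustrating
how conservative the cutoff is at moderate sample sizes.

## Network post-processing

Relations are 2-clauses over element literals, so `closure()` computes
entailment exactly: implications between literals are transitively
closed and unit literals (an element forced constant) are detected by
the merge rule.  `similarity_classes()` groups elements linked by
(entailed) similarity, tracking polarity through dual links, and
`covering_edges()` returns the transitive reduction of the class-level
partial order — the immediate edges a network diagram would draw.  A
prerequisite cycle across distinct similarity classes is an error: such
elements would be forced similar, which the input did not declare.
Contradictory pair constraints are reported with a warning, never
silently resolved.

## The simulator

`sample_states()` draws i.i.d. columns from a compatible state set —
uniformly by default, since nothing in the reference analyses specifies
otherwise and the uniform choice treats the states symmetrically;
weights are configurable.  `perturb()` applies independent bit flips.
`random_dab_network()` generates random class-level partial orders with
occasional similarity merges and dual-polarity links, giving ground
truths beyond the bundled example.  `recovery_experiment()` chains
generate → corrupt → infer → score, with the seed split into independent
sampling and perturbation streams so runs compose reproducibly.

What the simulator does *not* emulate about real expression data:
dependence between samples (time-course autocorrelation), gene-specific
error rates, and the binarisation step itself (real data are binarised
log ratios, `binarize_expression()`).  Passing recovery benchmarks here
demonstrates correctness of the inference machinery under the stated
error model, not performance on arrays.

At the reference simulation conditions (100 samples drawn uniformly from
the 13 states, $\varepsilon = 0.05$, thresholds 86/93, p-value threshold
1), the modal selected set across seeds is exactly the true
12-relationship network, but the per-seed exact-recovery probability is
only about 0.2: pairs adjacent to the true network — forbidden in just
one of the 13 states, hence with true forbidden-cell probability
$\approx 0.08$ — slip through both screens whenever sampling leaves
their forbidden cell small.  This is a property of the procedure's
operating characteristics at these thresholds, visible already in the
reference tables (near-relationships there pass one screen and miss the
other by a single count), not of any particular test formula.

## Numerical and design choices

* Pairs, states and enumerations are processed in deterministic
  lexicographic order; reports are byte-stable.
* Exhaustive state enumeration is limited to $m \le 25$ and chunked to
  bound memory.
* The p-value contrast compares against the *smallest* competing cell.
  For near-degenerate nuisance configurations (almost all true mass in
  one allowed cell) that comparison can be slightly anti-conservative;
  the mirror-cell comparison is exactly valid but blind to configurations
  where a different cell is the empty one.  The minimum matches the
  behaviour required of the screen.
* Degenerate variance (all compared counts zero) returns $p = 1$, the
  contrast being exactly its null mean.
* An exact zero log ratio binarises to *off* (configurable); samples with
  missing values are dropped whole, mirroring the exclusion of incomplete
  arrays, with pairwise handling available via `missing = "keep_na"`.
* Problem sizes in the test-suite benchmarks (100 seeds of 100 samples;
  oracle checks at $m \le 10$) were chosen so the full suite documents
  the procedure's behaviour while remaining quick to run routinely.

## Known limitations

* The asymptotic tests are contrasts between cells of one pair; no
  multiple-testing correction is applied across the $m(m-1)/2$ pairs
  (none is used in the reference analyses either).
* The constrained $\hat\varepsilon$ is a per-pair quantity; the pooled
  `epsilon = "estimate"` path takes the median across pairs.
* Cyclic (non-DAB) structure and temporal Boolean dynamics are out of
  scope.
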