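---
title: "Directional domain context: model, algorithms and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directional domain context: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domctx)
```

## The problem

Profile-HMM searches (HMMER3 against a Pfam-style library) score each
candidate domain independently. But domains co-occur in strongly preferred
orders: most family pairs that co-occur at all do so in a single orientation.
A weak match that sits downstream of a family it habitually follows deserves
more belief than its bit score alone conveys; a strong-looking match in a
combination never seen before deserves less. `domctx` post-processes a
permissive `hmmscan --domtblout` run, rescoring every candidate subset with
directional pairwise context and returning the provably optimal conflict-free
subset per protein.

## The model

Let candidates $D_1,\dots,D_k$ on one protein be ordered by start
coordinate, with family $F_i$, bit score $H_i$ and curated per-domain
gathering threshold $T^d_{F_i}$. A selected subset $D'$ scores

$$\sum_{i \in D'} \Big( H_i - T^d_{F_i} \Big)
  \;+\; \sum_{i<j \in D'} S_{F_i,F_j}
  \;-\; \sum_{F \in D'} \tilde T_F ,$$

in bits. All three parts are log-odds: $H_i - T^d$ reads as a posterior
log-odds of the family versus background once the threshold is interpreted
as a prior; $S_{i,j} = \log_2 \Pr(F_i, F_j) / (\Pr(F_i)\Pr(F_j))$ rewards or
penalizes the *ordered* co-occurrence of the two families; and
$\tilde T_F = T^s_F - T^d_F$ charges each selected family the part of its
sequence-level threshold not already covered by its domain thresholds. Every
ordered pair contributes — not only adjacent pairs — which is what
distinguishes the objective both from undirected pairwise models and from a
first-order Markov chain over adjacent domains ([markov_score()] implements
the latter for comparison; the two differ by exactly the non-adjacent
context sum, and agree for $k \le 2$).

The score can equivalently be read as the negative energy of a Markov
random field over the selection indicators, with conflict-free
configurations as the support. We never compute the partition function or
posterior selection probabilities; only the mode matters here, and the
maximizer of the score is the maximizer of the MRF probability.

The empty subset scores 0 and is always feasible: no domains are predicted
when every subset scores below the null model.

Subsets must be *compatible*: two candidates conflict when they overlap by
more than 40 residues or more than 50% of the shorter of the two ranges,
unless their families are on the curated nesting whitelist. Only spatial
overlap creates conflict in this model — same-clan candidates that do not
overlap are allowed to co-occur (clan-based exclusion belongs to the
Standard Pfam baseline, `standard_pfam_filter()`).

## Context score estimation

The directed count network stores $c_{i,j}$, the number of times an
instance of family $i$ occurred before an instance of family $j$ within one
protein, over a large annotated database; self-pairs model repeats.
`build_context_counts()` counts *instance* pairs — the architecture
`A, B, A` yields $c_{A,B} = c_{A,A} = c_{B,A} = 1$ — because the ordering
signal lives at the instance level; a binarized per-protein mode exists for
sensitivity analysis. Counts of exactly 1 are dropped at load time as
presumed annotation noise.

Pair probabilities are smoothed with a symmetric Dirichlet prior over all
$n^2$ ordered pairs:

$$\hat p_{i,j} = \frac{c_{i,j} + \alpha}{C + \alpha n^2},
  \qquad \hat p_i = \tfrac1n,
  \qquad S_{i,j} = \log_2 \frac{\hat p_{i,j}}{\hat p_i \hat p_j}
                 = \log_2\!\big( \hat p_{i,j}\, n^2 \big).$$

Every unobserved pair shares the penalty
$\log_2\!\big(\alpha n^2 / (C + \alpha n^2)\big) < 0$ (for $C > 0$), and
with an empty network all scores are exactly 0, reducing the method to the
threshold-only baseline. Two deliberate choices:

* **$n$ is supplied explicitly** (the family-metadata row count), never
  inferred from the counts file: the penalty depends on $n^2$ including
  families never observed in any pair, and inferring $n$ from observed
  pairs would silently inflate all scores.
* **$\alpha = 10^{-3}$ by default**, which outperforms the uniform prior
  $\alpha = 1$; it is exposed everywhere as `alpha`.

Scores are looked up lazily from a hash of observed pairs; no dense
$n \times n$ matrix is formed, so family universes beyond $10^4$ are fine.

## Thresholds

`load_family_meta()` derives $\tilde T_F = T^s_F - T^d_F$, forcing it to 0
when the thresholds coincide, when it would be negative, and when
$T^d_F \ge \tfrac{9}{10} T^s_F$ (families whose sequence threshold is
nearly implied by the domain threshold are treated as if it were exactly
implied). In the zero-context limit (all $S = 0$) the optimal solution
satisfies $H_i \ge T^d$ for every selected domain and
$\sum H_i \ge T^s$ for every selected family, because any violator could be
dropped without losing context terms; with context on, sub-threshold
domains *can* be selected — that is the point of the method — so those
inequalities are asserted in tests only for the zero-context configuration.

## Algorithms

### Positive elimination

Each iteration scores every remaining candidate optimistically:
$S^+_i = H_i - T^d + \sum_j \max(0, S)$ over remaining partners, taking the
direction from coordinate order and zeroing conflicting pairs (they can
never co-occur). $S^+_i < 0$ means $D_i$ hurts any subset containing it, so
it is removed; when no candidate is individually removable, any family with
$\sum_i S^+_i < \tilde T_F$ is removed whole. We apply individual removals
*before* the family test within an iteration: if negative-$S^+$ candidates
were still in the family sum, a family whose good instances alone can pay
the surcharge might be removed unsoundly. Each iteration is $O(k^2)$, and
the fixpoint preserves the optimum exactly (tested against brute-force
enumeration on a thousand random instances).

### The trivial shortcut, strengthened

A classic shortcut returns the survivors directly when they have no
conflicts and no negative pairwise context. That condition alone does not
guarantee optimality. Counterexample: two non-conflicting domains with
$H - T^d = -1.5$ each and $S = +2$ between them have $S^+_i = 0.5 > 0$
(both survive elimination), no conflicts and no negative context — yet the
pair scores $-1$ while the empty set scores $0$. The flaw is that a shared
positive pair term is counted once in the objective but twice across the
two $S^+_i$.

`is_trivial()` therefore additionally requires $H_i - T^d \ge 0$ for every
survivor and $\sum_{i \in F} (H_i - T^d) \ge \tilde T_F$ for every family.
Under the four conditions, removing any subset $R$ of survivors changes the
objective by
$-\sum_{i\in R} w_i - \sum_{\text{pairs touching } R} S
 + \sum_{F \subseteq R} \tilde T_F$,
and each group is non-positive: $w_i \ge 0$, $S \ge 0$, and each fully
removed family forfeits $\sum_{i\in F} w_i \ge \tilde T_F$. So the full
survivor set is optimal whenever the shortcut fires — which the acceptance
suite verifies against the oracle rather than assumes.

### Integer linear program

Binary variables: $x_i$ per candidate, $x_{i,j}$ per ordered pair with
nonzero $S$, $x_F$ per family with $\tilde T_F > 0$. The objective is the
model score in those variables. The AND relation $x_{i,j} = x_i \wedge x_j$
is linearized tightly as $x_{i,j} \le x_i$, $x_{i,j} \le x_j$,
$x_{i,j} \ge x_i + x_j - 1$: the polytope these cut from the unit cube has
only integral vertices, whereas the older two-constraint variant
($2x_{i,j} \le x_i + x_j$, $x_{i,j} \ge x_i + x_j - 1$) has fractional
vertices such as $(1, 0, \tfrac12)$ — both facts are asserted by exhaustive
vertex enumeration in the test suite. $x_F$ is the OR of its instances via
$x_F \ge x_i$ and $x_F \le \sum x_i$. Conflicts enter as one
$\sum_{i \in C} x_i \le 1$ row per clique of a greedy cover of the conflict
graph; any cover that contains every edge yields the same optimum (tested),
covers only change solver speed.

No MILP library is available in the supported environment, so
`solve_ilp()` is a built-in exact branch-and-bound over the $x_i$ alone:
for any candidate assignment the AND/OR constraints determine every other
variable, clique rows prune conflicting branches, and the bound credits
each free candidate with at most
$\max(0, w_i + \sum \max(0, S))$. This is exact (verified against
enumeration), deterministic, and fast at post-elimination sizes; it does
not reproduce any particular LP-relaxation trajectory of an external
solver.

Degenerate optima are possible; the package guarantees the optimal
*value*, not a canonical subset. The brute-force oracle breaks ties toward
fewer domains, then the lexicographically smallest index set, and tests
compare objective values only.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `alpha` | 1e-3 | — | Dirichlet concentration; 1 = uniform prior |
| `pvalue` ceiling | 1e-4 | — | candidate admission cut in `run` |
| `overlap-aa` | 40 | residues | conflict if overlap exceeds this |
| `overlap-frac` | 0.5 | fraction | of the shorter range |
| `overlap-coords` | `env` | — | envelope is HMMER's homology extent; `ali` available |
| `timeout` | 60 | s | per-protein ILP limit; timeout errors carry the best bound |

The documented upstream `hmmscan` invocation is
`--F1 1e-1 --F2 1e-1 --F3 1e-2 -Z 1 --domZ 1 -E 1e-4 --domE 1e-4`, which
makes the E-value columns P-values; `--z` rescales if a search ran without
`-Z 1`.

## The synthetic world

`generate_instance()` fixes the conditions the tests run under: a family
universe with gathering thresholds uniform in 18–30 bits; bit scores
`t_dom + N(0, 6)` so roughly half the candidates fail their threshold —
the regime where context decides selections and all of the PE / trivial /
ILP branches are exercised; intervals laid left to right with small gaps,
each candidate forced into a containment conflict with probability 0.25;
half of the ordered family pairs unobserved (so the negative penalty is
common); a fifth of families carrying a positive surcharge. These defaults
were chosen once as a realistic hard case and are not tuned to test
outcomes.

What the generator does *not* emulate: realistic domain-length and score
distributions, correlated architectures (counts are drawn independently of
the placed candidates), clan-level redundancy structure, or database-scale
universes. A green oracle-equivalence run therefore establishes the
*exactness of the optimization* on adversarially mixed instances, not
biological performance claims; the headline gains of context-aware
selection on real proteomes require database-scale inputs that a test
suite cannot carry.

## Evaluation utilities

`fdr_estimate()` is the macro-average over proteins (with at least one
prediction) of the per-protein FP fraction. `revseq_label()` implements
decoy labeling: predictions on reversed sequences are false positives,
except that a decoy hit overlapping a same-family real hit is removed first
(near-palindromic families would otherwise contaminate the decoy set — the
removal threshold of one shared residue is configurable since no canonical
value exists), and the reported estimate is doubled because decoys model
only one of the two error directions. The doubling is always reported
alongside the raw value, never applied silently.

## Numerical choices and degenerate inputs

Objective comparisons use 1e-6 bits absolute tolerance in solver
cross-checks and 1e-9 in test identities; ILP coefficients are passed at
full precision. Start-coordinate ties are broken by end coordinate, then
family id in the C locale, so builds are reproducible across platforms.
Empty inputs are legal everywhere: an empty domtblout yields an empty
prediction table and exit 0, an empty count network yields the all-zero
context model, an edgeless conflict graph yields no clique constraints.
Proteins are solved independently and in input order; outputs are
byte-identical across repeated runs.

## Known limitations

* The Standard Pfam selections, when pooled in via `--with-standard-pfam`,
  are treated as ordinary candidates afterwards: they are subject to
  positive elimination and negative context like any other candidate, so a
  pooled baseline prediction can still be removed. Whether reference
  implementations exempt them is unspecified; this is the more uniform
  behaviour.
* The symmetric-context ablation (`symmetrize_counts()`) is an approximate
  stand-in for older undirected formulations, estimated from
  $c_{i,j} + c_{j,i}$; it is intended for ablation only.
* Per-domain confidence updates given context (posterior error
  probabilities per prediction) are out of scope; the solver returns one
  objective per protein, not per-domain probabilities.
* The ILP path targets post-elimination problem sizes (tens of
  candidates). Pathological inputs with hundreds of mutually-rescuing
  sub-threshold candidates would need an external MILP backend, for which
  the formulation in `build_ilp()` is solver-agnostic.
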