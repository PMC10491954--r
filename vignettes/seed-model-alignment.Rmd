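---
title: "Aligning sequences to a seed model: Potts energies, indel priors, and message passing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning sequences to a seed model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pottsalign)
set_log_level("warn")
```

## The model

Profile HMMs treat alignment columns independently. Homologous families,
however, show correlated substitutions between columns (epistasis), which a
pairwise maximum-entropy — Potts / DCA — model captures. `pottsalign`
trains such a model on a curated family seed alignment and then aligns
unaligned query sequences *to the model*.

An aligned sequence $S$ over the $L$ match columns (gap `-` is an ordinary
state, so a protein alphabet has $q = 21$ states) is scored by the energy

$$H(S) \;=\; -\sum_i h_i(S_i) \;-\; \sum_{i<j} J_{ij}(S_i, S_j),$$

with fields $h$ and couplings $J$ stored in the zero-sum gauge. The
parameters are estimated by **asymmetric pseudo-likelihood maximization**:
each site's conditional $P(S_i \mid S_{\setminus i}) \propto
\exp(h_i(S_i) + \sum_{j \ne i} J_{ij}(S_i, S_j))$ is fit independently by
L-BFGS-B on the weight-averaged log conditional likelihood with
per-parameter L2 penalties ($\lambda_h = \lambda_J = 0.01$ by default,
standard plmDCA practice), and the couplings are symmetrized by averaging.
Sequences are reweighted by the usual $1/\text{(number of neighbors at
} \ge 80\% \text{ identity)}$ rule.

### Alignment variables

A query $A$ of length $N \ge L$ is aligned by a match indicator
$x_i \in \{0, 1\}$ and a pointer $n_i \in \{0, \dots, N+1\}$ per column:
$S_i = A_{n_i}$ where $x_i = 1$, and at gap columns the pointer *carries*
the last matched position. Boundaries are pinned, $n_0 = 0$ and
$n_{L+1} = N + 1$. Matched pointers must increase strictly; the carry rule
realizes that constraint at gap columns, making the pointer difference
$\Delta n_{i,j} = n_j - n_i$ count exactly the matched-plus-inserted query
residues consumed between columns $i$ and $j$ — gaps contribute zero.

### Indel statistics as informed priors

For every pair $0 \le i < j \le L+1$ the package learns the weighted
empirical distribution $P_{ij}(\Delta n_{i,j})$ over the seed rows. The
support runs to the largest observed difference plus a slack of 2, and the
histogram is mixed with a uniform floor (default
$\varepsilon = 1/(10(M_\mathrm{eff} + \text{support size}))$) so no value
in the support — and no out-of-support value, which also receives
$\varepsilon$ — is impossible at finite inverse temperature. Boundary
pairs ($i = 0$ or $j = L+1$) constrain leading and trailing unmatched
residues. Seed weights are reused in the histograms for consistency with
the Potts statistics; `unweighted_prior = TRUE` preserves the alternative.

### The alignment objective and its solver

A query is aligned by maximizing

$$e^{-\beta H(x, n)} \prod_{i<j} P_{ij}^{\beta}(n_j - n_i)$$

over feasible $(x, n)$. The normalization is intractable but constant, so
only the log-objective matters. The maximization runs on a pairwise factor
graph over the joint per-column variables $(x_i, n_i)$ (domain size
$2N + 1$): node factors carry the fields plus boundary-prior terms,
consecutive-column factors carry the hard feasibility indicator, and every
pair in the prior's pair set (union pairs with nonzero couplings)
contributes $e^{\beta J_{ij}} P_{ij}^\beta$. Loopy sum-product message
passing runs in log space with probability-scale damping while $\beta$ is
annealed geometrically; as $\beta$ grows the beliefs concentrate on the
maximizer. Decoding is an exact dynamic program over the column chain that
maximizes the summed log beliefs subject to feasibility, so a feasible
state is guaranteed whatever the message-passing state; ties prefer a
match and then the smallest pointer. Two decoded candidates are produced —
the plain final-belief decode and a decimation pass that clamps columns
one at a time by belief confidence at the final $\beta$ (the classic
message-passing decimation scheme) — and both are polished by a greedy
coordinate ascent over single-column and adjacent-pair moves on the true
objective (`refine_state()`); the candidate with the higher objective is
returned. An exhaustive solver (`exhaustive_align()`) enumerates all
feasible states (closed-form count $\sum_g \binom{L}{g}\binom{N}{L-g}$)
and serves as the exact reference on small instances.

### Numerical choices

* All message arithmetic is in log space; messages are logsumexp-normalized.
  $-\infty$ entries (hard-forbidden states) are legal throughout.
* The sweep residual is the maximum absolute message change on the
  probability scale — log-scale differences are undefined for zero-probability
  states.
* Damping mixes old and new messages on the probability scale (default 0.5).
* Messages start uniform with a seeded perturbation of amplitude $10^{-3}$:
  symmetry breaking with bit-reproducible output under a fixed seed.
* Annealing defaults: $\beta$ from 0.1 to 5, growth 1.05, at most 100 sweeps
  per $\beta$, residual tolerance $10^{-4}$. Reported experiments below use a
  faster ladder (growth 1.2–1.3, 50–60 sweeps) whose results on the
  small-instance oracle comparison are indistinguishable from the default.
* Degenerate inputs: $N < L$ queries are refused (the model is global);
  all-gap seed rows are kept with a warning; an all-gap sampled sequence is
  unalignable and rejected by the fixture generator.

## What the synthetic generator emulates

`make_planted_family()` builds a complete, fully known test family:

* a planted Potts model with a chosen set of coupled pairs (block-pattern
  couplings of strength 1.0) and i.i.d. uniform fields of strength 2.0 —
  single-site majority-residue frequencies around 0.7–0.85, the
  conservation level of curated match columns, which is the regime a
  seed-based aligner presumes;
* per-column gap probability 0.1, imposed through the gap-state field;
* a seed MSA of 1000 rows Gibbs-sampled from the model (single-site
  heat bath), each row carrying insert runs drawn per boundary with
  probability 0.1 and geometric lengths of mean 1.5 — a seed without
  insert states would teach the priors that insertions are impossible and
  make the alignment problem degenerate;
* 50 queries sampled the same way, with gaps deleted and insertions
  injected, and the true $(x, n)$ recorded; queries that end up shorter
  than $L$ are redrawn, as they are outside the aligner's domain.

What it does **not** emulate: phylogenetic correlation between rows
(samples are i.i.d.), position-dependent indel hot spots (insertions are
uniform across boundaries, whereas real seeds concentrate them in loops),
and realistic alphabet sizes in the default toy setting ($q = 4$ means
three visible letters). Passing tests on these fixtures therefore
demonstrate the correctness of the machinery — estimation, bookkeeping,
optimization — not the field performance of the method on real families.

## Known limitations

Two properties of the default study conditions deserve emphasis. First,
with three visible letters a randomly inserted residue is indistinguishable
from a plausible match at about one column in three, so the posterior over
alignments is genuinely ambiguous — even re-aligning with the *true*
generating model and noise-free priors leaves a substantial fraction of
truth columns unrecovered under these conditions. Second, the all-pairs prior product charges every pair
spanning an insertion, so the penalty of an interior insertion grows
roughly quadratically with $L$ while the energy reward for correct
placement grows linearly — the optimizer consequently prefers absorbing
scattered insertions into matches or pushing them toward the sequence
ends. Both effects are properties of the objective, not of the solver: on
small instances the annealed solver attains the exhaustive optimum in
98–99% of runs (the acceptance script recomputes this figure), and the
decoded objective always dominates the truth's objective when they
disagree. On realistic alphabets ($q = 21$) with concentrated
indel statistics the ambiguity shrinks substantially.

Problem sizes used in the reported experiments: oracle comparisons on 100
instances with $L \le 5$, $N \le 9$; chain-exactness on $L = 4..8$;
contact recovery on $L = 8$, $M = 5000$; end-to-end recovery on $L = 12$,
$M = 1000$, 50 queries.

## A worked run

```{r example, eval = FALSE}
fam <- make_planted_family(L = 8, q = 4, n_seed = 300, n_queries = 5, seed = 1)
fit <- fit_seed_model(fam$seed_msa)
summary(fit)
res <- predict(fit, fam$queries, schedule = anneal_schedule(growth = 1.2),
               seed = 1)
res[[1]]
```

The `eval` and `align` subcommands of the `pottsalign` script under
`inst/exec/` expose the same pipeline from the shell; every run writes its
effective configuration next to its outputs so it can be replayed exactly.
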