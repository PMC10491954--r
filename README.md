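# pottsalign

Alignment of biological sequences to a family **seed model** that captures
both conservation and co-evolution. Profile HMMs score alignment columns
independently; homologous families additionally show correlated
substitutions between columns. `pottsalign` trains a Potts (Direct
Coupling Analysis) model on a curated seed MSA together with empirical
priors over insertion/gap statistics, and aligns unaligned query
sequences to that model by message passing with annealing. It is aimed at
people who work with Pfam/Rfam-style seed alignments and want an
epistasis-aware alternative to profile-HMM alignment, and at
methods developers who need a fully testable reference implementation.

## The model

An aligned sequence `S` over the `L` match columns (gap is an ordinary
state; protein q = 21, RNA q = 5) is scored by the Potts energy

    H(S) = - Σ_i h_i(S_i) - Σ_{i<j} J_ij(S_i, S_j)

with `h`, `J` fitted by L2-regularized asymmetric **pseudo-likelihood
maximization** on identity-reweighted seed sequences, then symmetrized
and put in the zero-sum gauge.

A query `A` of length `N ≥ L` is aligned through match indicators
`x_i ∈ {0,1}` and monotone pointers `n_i ∈ {0..N+1}` (`S_i = A[n_i]` at
matches; gap columns carry the last matched pointer; `n_0 = 0`,
`n_{L+1} = N+1`). The pointer differences `Δn_ij = n_j − n_i` count the
query residues consumed between columns; their seed-wide empirical
distributions `P_ij(Δn)` — floored and renormalized — are the *informed
indel priors*. The alignment solves

    argmax_{feasible (x,n)}  exp(−β H(x,n)) · Π_{i<j} P_ij(n_j − n_i)^β

by loopy sum-product message passing on a factor graph over the joint
`(x_i, n_i)` variables, annealing β upward, followed by belief decimation,
an exact feasibility-preserving chain decode, and coordinate-ascent
refinement. An exhaustive solver provides exact optima on small instances.
Contact scores (Frobenius norm + APC) with PPV curves and seed-proximity
metrics cover evaluation, and a synthetic generator (planted Potts models,
Gibbs sampling, indel corruption with recorded truth) makes the whole
pipeline testable offline.

## Worked example

```r
library(pottsalign)
fam <- make_planted_family(L = 8, q = 4, n_seed = 300, n_queries = 5, seed = 1)
fit <- fit_seed_model(fam$seed_msa)
summary(fit)
#> Seed model: L=8 q=4 M_eff=101.0 prior pairs=45
#> Top coupling pairs (Frobenius-APC):
#>  i j     score
#>  1 5 1.1849762
#>  2 6 0.2510698
#>  4 7 0.1628764
#>  3 7 0.1355774
#>  4 6 0.1162214
res <- predict(fit, fam$queries, schedule = anneal_schedule(growth = 1.2), seed = 1)
res[[1]]
#> <query_alignment> query_1: L=8 N=9 matches=8 H=-1.7659 prior=-46.3314
```

The planted coupled pairs of this family are (1,5) and (2,6): they rank
first and second by Frobenius-APC score, i.e. the fit recovers the
co-evolving columns from 300 sampled rows (`M_eff = 101` after identity
reweighting). Each alignment result reports its Potts energy `H` and the
prior log-score; `x`, `n` hold the decoded match pattern and pointers.
A typical training run takes seconds; aligning one query of this size
takes about a second.

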