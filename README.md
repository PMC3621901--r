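# phyfuse

Bayesian phylogenetic inference under GTR+I+Γ, built around a **fused
single-pass conditional-likelihood engine** and a faithful **multipass
reference pipeline** with explicit memory-transfer accounting, both driving
a Metropolis-coupled MCMC (MC³) sampler.

The package is for people studying the *dataflow architecture* of
phylogenetic likelihood computation — how the pruning recursion, ambiguity
handling, per-site rescaling and the root combination can be fused into a
single pass per node without changing any result — as well as for running
desk-scale Bayesian analyses on nucleotide alignments.

## The model and the two evaluators

For an alignment compressed to `L` unique site patterns `D_z` with weights
`L_z`, the likelihood of a tree `T` under GTR+I+Γ is

```
ln L = Σ_z L_z · ln[ (1−P) · (1/K) Σ_k Σ_m π_m · clp_root(z, k, m)
                     + P · Σ_{m ∈ ∩ masks(z)} π_m ]
```

with `P` the proportion of invariable sites, `K = 4` discrete-gamma rate
categories, `π` the stationary base frequencies, and `clp` the per-node,
per-site, per-category conditional likelihoods of Felsenstein pruning.
Observed states are 4-bit masks (A=1, C=2, G=4, T=8; IUPAC ambiguity codes
are bit unions; `-` and `?` are 15). Per branch, a *transition block* holds
`K` stacked 4×4 matrices `P(r_k t) = exp(Q r_k t)` — 64 values at `K = 4`;
a per-site clp *residue* holds 16.

Two evaluators compute this quantity with identical arithmetic:

* **fused** (`phylo_loglik()`): one pass per internal node. Terminal-child
  transition blocks are transformed inline into *prelike* lookup tables,
  the clp is computed, and per-site rescaling (subtract the old scaler,
  install the new one — the maximum clp within each residue) is merged into
  the same pass, with the scaler bookkeeping flag switches deferred to the
  end of the pass. Each down node is dispatched to exactly one of **16
  variants**: its shape class `down_x` (`x` = which children are terminal)
  times the scaler shortcut `T = 2·scalersSet + scalerNode`.
* **multipass** (`evaluate_multipass()`): five separate stages (prelike
  transform, clp, old-scaler subtraction, rescaling, root combination) with
  materialized intermediates, instrumented with a `TransferLedger` counting
  every simulated global-store read/write per parameter class (`clp`,
  `tip`, `ls`). `ledger_closed_form()` gives the closed-form counts under
  the standard accounting scenario, and `verify_ledger()` confirms the
  measured counts equal them cell by cell — the normalized clp traffic
  drops from `4(N−2)+5` to `2(N−2)+2` accesses.

The MC³ sampler (`mc3()`) runs independent replicate runs of heated chains
(`β = 1/(1 + λ·i)`), advances chains serially within each generation with
one proposal per chain (branch multipliers, NNI, subtree-regraft, Dirichlet
moves on rates/frequencies, windows on α and `pinvar`, each with its
Hastings ratio and an abort flag for out-of-support proposals), attempts
one chain swap per generation, samples the cold chain, and reports the
average standard deviation of split frequencies (ASDSF) between runs.

## Worked example

Simulate data with a known truth record, run two MC³ replicates, and check
the recovery and the transfer accounting:

```r
library(phyfuse)
pars <- gtr_params(exch = c(1, 4, 1, 1, 4, 1), freqs = c(0.3, 0.2, 0.2, 0.3),
                   pinvar = 0.2, alpha = 0.5)
sim <- simulate_alignment(sim_spec(n_taxa = 12, n_columns = 1000,
                                   params = pars, seed = 42))
fit <- mc3(sim$alignment, ngen = 5000, nruns = 2, nchains = 4,
           samplefreq = 100, diagfreq = 1000, seed = 42)
print(fit)
#> MC3 fit: 12 taxa, 1000 columns (388 unique patterns)
#>   2 run(s) x 4 chain(s), 5000 generations, fused evaluator
#>   best sampled lnL per run: -5965.753, -5962.898
#>   final ASDSF: 0.014834

round(summary(fit)$params[c("r_AG", "r_CT", "pi_A", "alpha", "pinvar"), ], 4)
#>          mean     sd     q5    q95
#> r_AG   0.3004 0.0243 0.2653 0.3387
#> r_CT   0.3510 0.0222 0.3071 0.3824
#> pi_A   0.2951 0.0127 0.2752 0.3172
#> alpha  0.4741 0.0913 0.3554 0.6253
#> pinvar 0.1532 0.0707 0.0457 0.2633
```

The generating values (r_AG = r_CT = 4/12 ≈ 0.333, π_A = 0.3, α = 0.5,
P = 0.2) sit inside the 90% intervals; 8 of the 9 true splits are already
at posterior ≥ 0.95 after this short run (the one exception subtends a
branch of length ~0.01). The transfer accounting:

```r
v <- verify_ledger(N = 10, L = 100)
v$match        #> TRUE  (all 24 measured cells equal the closed forms)
v$clp_ratio    #> measured 2.0556, closed_form 2.0556  ( = (4·8+5)/(2·8+2) )
```

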