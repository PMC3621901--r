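---
title: "Fused single-pass likelihood evaluation and MC3 sampling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fused single-pass likelihood evaluation and MC3 sampling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phyfuse)
```

phyfuse computes phylogenetic likelihoods under GTR+I+Γ with two
interchangeable evaluators — a fused single-pass engine and a five-stage
multipass reference with transfer accounting — and samples posteriors with
Metropolis-coupled MCMC. This vignette records the modelling conventions,
the numerical choices, and the design decisions that were genuinely open,
so that every number the package produces can be traced to a stated rule.

## Data model

Alignments are nucleotide matrices over IUPAC codes plus `-` and `?`,
case-insensitive, with `U` read as `T`. Each character becomes a 4-bit
mask (A=1, C=2, G=4, T=8; ambiguity codes are unions; `N`, `-` and `?` are
15). Treating gaps as fully ambiguous is the standard likelihood
convention; nothing in the method distinguishes `-` from `?`. Identical
columns are collapsed to unique site patterns with multiplicity weights in
first-occurrence order (deterministic, so sampling traces are
reproducible); the pattern likelihood times its weight reproduces the
full-alignment likelihood exactly, which the tests assert to 1e-12.

## Substitution model

The GTR rate matrix has off-diagonals `q_ij = r_(ij) π_j`, is normalized to
unit mean rate at stationarity (branch lengths are expected substitutions
per site), and satisfies detailed balance by construction. Transition
probabilities come from an eigendecomposition of the symmetrized matrix
`diag(√π) Q diag(1/√π)`; tiny negative entries from rounding are clamped to
zero. Tests compare against an independent scaling-and-squaring matrix
exponential to 1e-10 and check Chapman–Kolmogorov and the `t → ∞` limit.

Among-site rate variation uses `K` equal-probability discrete-gamma
categories (default `K = 4`, the value the storage accounting assumes: a
per-site clp residue is then 16 values and a per-branch transition block
64). Category rates are *means* of the slices — the MrBayes convention —
computed in closed form from incomplete-gamma differences and verified
against adaptive quadrature.

The invariable-site class is **not** folded into the category rates: the
gamma mixture keeps mean rate 1 and the invariable term enters only at the
root combination,

`lnL_z = lnScaler_z + ln[(1−P)·mix_z + P·inv_z·exp(−lnScaler_z)]`,

where `inv_z` sums `π_m` over the states compatible with every taxon at
pattern `z`. Two consequences deserve a note. First, other implementations
(e.g. phangorn's `pml`) rescale the substitution process by `1/(1−P)` so
the *total* mean rate is 1; the two conventions coincide after dividing
branch lengths by `1−P`, which is how the external cross-check in the test
suite is phrased (it agrees to 1e-9, and exactly at `P = 0`). Second, the
`exp(−lnScaler)` correction keeps scaled and unscaled evaluations equal;
it is evaluated as a two-term log-sum-exp so the invariable term survives
arbitrarily deep rescaling instead of overflowing.

## The computation tree

Evaluation runs on a rooted binary tree: a degree-2 root, `N−2` internal
"down" nodes, each classified `down_x` with `x = (left child terminal) +
2·(right child terminal)`. Unrooted input is resolved with a zero-length
edge; under the reversible model the likelihood is invariant to that
choice (the pulley principle, asserted to 1e-10 over re-rootings). The
degree-2 root was chosen over a trifurcating basal node because the
transfer accounting and the node classification both presuppose `N−2` down
nodes plus a distinguished root; with a trifurcation there would be only
`N−3`. The `down_1`/`down_2` assignment (left- vs right-terminal) is a
fixed convention required for deterministic dispatch; only the both-
terminal class is forced by the architecture.

## The fused evaluator

Per internal node, one pass does everything:

1. **Inline prelike transform.** For each terminal child, the transition
   block is pre-summed over the states of each observed mask into a
   15×K×4 lookup table held in working storage — never materialized to the
   simulated global store, and computed fresh per (node, child) per
   evaluation. All 15 masks are tabulated (the table is 240 doubles;
   restricting to masks present in the data would complicate the pass for
   no measurable gain).
2. **clp computation.** `clp[z,k,m] = (Σ_i tipL[k,m,i]·valL(i)) ·
   (Σ_j tipR[k,m,j]·valR(j))`, terminal children via prelike lookup,
   internal children via their clp.
3. **Fused rescaling.** If the node's `scalersSet` flag is up, the stored
   old scaler is subtracted from the per-site `lnScaler`; if `scalerNode`
   is up, the new scaler — the maximum of the 16 clp values in the residue
   — divides the residue and its log is stored and added to `lnScaler`.
   The flag switches are queued and committed after the pass (deferred),
   or immediately; both orderings are tested to give identical results,
   including on the following evaluation.
4. **Root combination**, merged into the root's pass.

The scaler shortcut `T = 2S + N` times the shape class `x` selects one of
16 variants, so no per-site branch runs inside a pass; variants with and
without scaling are separate code paths. The running engine reports which
variant each node used, and the tests drive it through all 16 (the
`S=1, N=0` column arises when a node's scaler designation is withdrawn
while its old scaler is still in `lnScaler`).

A useful algebraic property: because every evaluation recomputes all
nodes, `lnScaler` after a pass always equals the sum of the scalers
installed in that pass — the old-scaler subtractions exactly cancel the
previous pass's additions. The likelihood therefore never depends on
scaler history, which is why rejected MCMC proposals need no state
restoration. Only the *rounding* of the `lnScaler` accumulation depends on
the pass count, which is why cross-evaluator tests compare like pass
counts bitwise and unlike pass counts at 1e-12 relative.

Rescaling policy is configurable: every internal node (default, matching
the accounting scenario), none, or every k-th node; all give identical
likelihoods wherever the linear domain does not underflow, and the default
keeps a 192-taxon long-branch ladder finite where the unscaled evaluation
returns `-Inf`.

### Layouts

Two loop orders mirror the two parallelization strategies: `state_major`
processes all 16 values of a site together (intra-task), `site_major` runs
sites innermost (inter-task). Both perform identical per-element
arithmetic, so they agree bitwise. `layout = "auto"` picks state-major
below 512 unique patterns; the threshold is an empirical knob with no
effect on results, and 512 is simply the default documented here.

## The multipass reference and transfer accounting

`evaluate_multipass()` runs the same arithmetic as five separate stages
with materialized intermediates: (1) prelike written to the simulated
global store, (2) clp computed from re-read prelike, (3) old-scaler
subtraction, (4) rescaling with a clp re-read and re-write, (5) root
combination with a root-clp re-read. Per node it reports the number of
stages executed — 2 for an unscaled down node, 3 for an unscaled root,
4/5 when both scaler stages are active — and a ledger of every simulated
global access.

Accounting units follow the storage constants: a clp access moves `L`
residues of 16 floats, a tip access one 64-float block, an `ls` access `L`
single floats; byte totals assume 4-byte floats. Three attribution rules
make the ledger well defined:

* tip-class traffic covers only terminal-child handling (the prelike
  machinery, or the fused direct tip read). Branch matrices for internal
  children live in working storage in both schemes and are not a ledger
  class.
* `ls` is the `lnScaler` vector: one read and one write per scaling stage
  in the multipass scheme, one fused read/write in the fused scheme. The
  per-node stored old scaler is bookkeeping, not a ledger class.
* every counted access is a whole matrix/vector transfer, not bytes moved
  per element.

Closed forms under the standard scenario — every down node and the root
with one terminal and one internal child, all nodes scaling, old scalers
present — are tabulated in `ledger_closed_form()`. That scenario is an
idealization: a finite binary tree must close with a cherry, so no real
tree satisfies it at every node. `verify_ledger()` therefore instruments a
caterpillar on `N+1` taxa whose basal cherry stands in for the unmodeled
basal subtree and is excluded from the counts, and measures the *second*
evaluation pass (the steady state of a running chain, where `scalersSet`
is active everywhere). With those two choices the measured ledger equals
the closed forms exactly, for all cells, at every `N ≥ 3`; normalized clp
traffic reproduces the `(4(N−2)+5)/(2(N−2)+2)` reduction.

## The MC³ sampler

Each of `nruns` (default 2) independent runs carries `nchains` (default 4)
chains at heats `β_i = 1/(1 + λ i)` with `λ = 0.1` — a convention chosen
because only the chain counts are architecturally fixed. Within a
generation, chains advance serially, one proposal each; then one swap is
attempted between a uniformly chosen pair, accepted with probability
`min(1, (p_i/p_j)^{β_j−β_i})` on the unheated posteriors, exchanging
heats.

Priors: Exp(10) branch lengths, flat Dirichlets on exchangeabilities and
frequencies, Exp(1) on α, Uniform(0,1) on `pinvar`. The proposal mix
(default weights in `phyfuse:::default_move_weights`) comprises a
log-multiplier on a random branch, NNI with a branch multiplier,
subtree-regraft with uniform reattachment position (Hastings ratio = target
edge length over merged origin length), Dirichlet proposals centered at the
current exchangeabilities/frequencies, a log-multiplier on α, and a
reflected window on `pinvar`. Proposals that leave the support — a branch
below the 1e-8 floor or above 100, α outside [1e-3, 1e3], an NNI on fewer
than 4 taxa — raise the abort flag and are counted without evaluation or
state change. This move set is a documented minimal surrogate, not a
claim of parity with any particular production sampler's mix or tuning.

Reproducibility: one master seed spawns L'Ecuyer-CMRG streams — one per
chain plus one per run for initialization and swaps — so the same seed
yields byte-identical sample files under any chain count, and the fused
and multipass evaluators (whose log-likelihoods agree bitwise at equal
pass counts) produce *identical chains*, proposal for proposal. Sampling
writes MrBayes-style `.p`/`.t` files; the ASDSF between runs (sample
standard deviation, n−1 denominator, over splits reaching 0.1 in either
run; 25% burn-in) is computed at each diagnosis point from the samples
accumulated to that point.

## The simulator

`simulate_alignment()` draws each column as the likelihood reads it: with
probability `pinvar` the column is invariable (root state from `π` copied
to all taxa); otherwise a gamma category is drawn and each branch
transition sampled from `P(r_k t)`. The truth record (tree, parameters,
per-column categories) is serialized next to the alignment so recovery
tests need no re-derivation. Shape presets mirror the rDNA benchmark
alignments (26×1546 up to 288×3386) and a 60-taxon grid with controlled
unique-site counts. Random topologies come from stepwise random addition
(uniform over labeled unrooted binary topologies, verified by a chi-square
test over all 105 six-taxon trees) with i.i.d. Exp(10) branch lengths by
default.

What the simulator does *not* emulate: indels and alignment error, rate
heterotachy, base-composition drift across the tree, and linkage between
sites. Passing recovery tests therefore show the sampler is correct and
calibrated *under the generating model*, not that real rDNA alignments
satisfy that model.

## Test conditions and statistical checks

The deeper statistical checks fix their study conditions once:

* evaluator-vs-evaluator chain identity: 12 taxa × 500 sites × 5000
  generations, default chain counts.
* recovery: 20 taxa × 2000 sites under GTR+I+Γ with transition bias
  (rates 1,4,1,1,4,1; frequencies 0.3,0.2,0.2,0.3; α = 0.5; P = 0.2),
  branch lengths Uniform(0.03, 0.3) — bounded away from zero because the
  check conditions on strong signal, and a split subtending a near-zero
  branch is unresolvable at any sample size; 20,000 generations, 2 runs ×
  4 chains. The run must reach ASDSF < 0.01, put every true split at
  posterior ≥ 0.95 in both runs, and cover the truth with 90% credible
  intervals in at least 4 of 6 parameter groups. The six groups —
  exchangeabilities, frequencies, α, `pinvar`, tree length, topology
  (all true splits at ≥ 0.5) — are this package's definition, stated here
  because group membership is not standardized; a group counts as covered
  only if every scalar in it is covered. Posteriors concentrate on the
  *realized* data frequencies rather than the generating values, so
  occasional per-scalar misses are expected and the group criterion
  absorbs them.
* oracle equivalence: 200 random fixtures of ≤ 6 taxa and ≤ 4 patterns
  against exhaustive ancestral-state enumeration (1e-10 relative), the
  enumeration being vectorized over all `4^(N−1)` assignments.

These sizes keep the full suite under a few minutes on one core while
leaving every check statistically meaningful.

## Known limitations

* Single partition, nucleotide data only; no codon or amino-acid models,
  no nst=1/2 submodels, no covarion.
* Every proposal re-evaluates the whole tree. The scaler-flag machinery
  would support partial updates, but the full pass keeps the state
  consistency argument above airtight; at desk scale the evaluation is
  not the bottleneck until a few hundred taxa.
* Chains are scheduled serially by design (the architecture being modeled
  is serial per chain); there is no multi-process coupling.
* Convergence diagnostics are limited to the ASDSF; no reversible-jump
  model averaging.
* The transfer ledger models matrix-sized transfers, not cache behavior;
  it is an accounting of the dataflow, not a performance simulator.
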