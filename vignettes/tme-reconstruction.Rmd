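---
title: "Reconstructing gains and losses of the anuran tympanic middle ear"
author: "tmevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gains and losses of the anuran tympanic middle ear}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmevol)
```

## The problem

Most frogs and toads hear airborne sound through a tympanic middle ear (TME)
built from three structures arranged lateral to medial: the tympanic membrane
(TM), the cartilaginous tympanic annulus (TA) supporting it, and the
columella (the middle-ear bone, CO). Many lineages — spectacularly so in true
toads — have lost some or all of these structures, and some have apparently
regained them. `tmevol` implements the comparative machinery needed to ask
how often: dependency-aware coding of the three structures, parsimony
ancestral reconstruction with honest bounds over all optimal reconstructions,
two-state Mk likelihood with model selection, and stochastic character
mapping under unconstrained, root-constrained and irreversible (Dollo)
scenarios.

## Character coding and the lateral–medial dependency

Anatomically, a lateral structure never occurs without the structures medial
to it. Coding therefore uses four completion rules: columella absent forces
annulus and membrane absent; annulus absent forces membrane absent; membrane
present forces annulus and columella present; annulus present forces
columella present. Two properties are deliberate:

* **Rules fire only from known states.** An unknown is filled, never
  invented: `(TM = ?, TA = absent, CO = ?)` completes to
  `(absent, absent, ?)` — the columella legitimately stays unknown, because a
  columella can occur without an annulus. This makes `complete_triple()`
  idempotent and monotone.
* **Contradictions are errors, not coercions.** `(TM = present, CO =
  absent)` names the violated rule instead of silently picking a winner;
  `read_character_table()` quarantines such rows into an inconsistency
  report with line numbers rather than dropping them silently.

Each structure is then analysed as an independent binary character
(0 = absent, 1 = present, repo-wide). Taxa scored but absent from the tree
are dropped with a warning; tips present but unscored enter as unknown, i.e.
with the full state set — we preferred the ambiguous-tip treatment over
dropping such tips because it uses the topology information their position
carries without asserting a state.

## Parsimony with bounds over all optimal reconstructions

Reconstruction is unordered (Fitch-style) parsimony, implemented as Sankoff
dynamic programming over the postorder edge list, so polytomies are handled
natively rather than being arbitrarily resolved — resolution would change
change counts, which are the quantity of interest. Per-node MPR state sets
come from a down-pass/up-pass (a state is in the set iff subtree cost plus
outside cost equals the optimum), never from enumeration.

A single optimal reconstruction is not unique, and gains and losses trade
off inside a fixed total. Published claims of the form "lost at least N
times" correspond to the reconstruction with the fewest losses. We compute
both directional extremes exactly with lexicographic cost pairs: the
combined cost of a transition is `changes * (E + 2) + secondary`, with `E`
the number of edges and `secondary` counting the disfavoured direction.
Because all quantities are small integers this is exact — no floating-point
epsilon device. The traceback breaks ties toward state 0; ties only ever
arise between reconstructions with identical (changes, secondary) scores, so
the reported tallies are unaffected. `count_independent_losses()` reports
the loss count of the fewest-loss reconstruction together with the
contributing edges; a loss clade nested inside an already-lost clade is
correctly not counted twice.

## Mk likelihood, ER vs ARD, and marginal reconstruction

The two-state transition probability uses the closed form
`P(t) = Pi + exp(-(q01+q10) t) (I - Pi)` (identity at `t = 0` and on
zero-length branches), rather than a generic matrix exponential — exact and
cheap. The pruning likelihood rescales each internal node's partials to sum
to one, accumulating the log factors, so deep trees cannot underflow;
unknown tips contribute the partial `(1, 1)`.

Fitting maximises the log-likelihood on the log-rate scale with a fixed
multistart grid of `{1e-3, 1e-2, 0.1, 1, 10}` expected changes per tree
height and bounded L-BFGS-B refinement from the three best starts, so fits
are deterministic. Rates are bounded in `[1e-9, 1e4]` per tree height; a
constant character is flagged and sits at the lower boundary. ER (one rate)
and ARD (gain and loss free) are compared by `AIC = 2k - 2 lnL`; exact ties
rank the model with fewer parameters first. The root prior defaults to flat
(equal state probabilities): the study's tooling default, and under ER the
flat and stationary priors coincide, which is why the choice is essentially
free where it matters here. Branch lengths are used exactly as read — no
rescaling or transformation.

Marginal ancestral probabilities combine the tipward partials with rootward
partials from a preorder sweep; both are validated against exhaustive
enumeration over all ancestral assignments on small trees at `1e-10`.

## Stochastic mapping and the counting rule

A map is drawn exactly in two stages: joint node states by tipward pruning
plus rootward sampling from the conditional distribution at each node, then
each branch path conditional on its endpoints by uniformization — the number
of candidate jumps is drawn from its exact conditional distribution (Poisson
weights times jump-chain matrix powers, normalised by the branch transition
probability) and the jump chain is bridged between the endpoints. This
terminates by construction; rejection sampling was rejected because it can
stall on long branches with improbable endpoint pairs. The jump-count series
is truncated only at three times the `1 - 1e-13` Poisson quantile, far
beyond any mass that matters.

The three scenarios: (1) ER fit with flat root prior, unconstrained; (2) the
same ER rate with the root fixed eared — the rate is deliberately *not*
refit under the constraint (the design says the ancestor was restricted, not
that rates were re-estimated; `refit_rate = TRUE` is available); (3) Dollo,
with the gain rate exactly zero (not a small positive rate — "no regains"
is absolute) and the loss rate refit by maximum likelihood with the root
fixed eared, since an earless root under Dollo could never produce an eared
tip. Default `n_sims` is 10,000 maps per scenario, the study design.

Changes are counted on the summarized node states: a node is called for a
state only when its across-map frequency strictly exceeds the 0.5 threshold,
so a node at exactly 50% support is uncalled and its edges contribute
nothing; a gain (loss) is an edge whose called parent and child states
differ. Only edges are counted — the root's own state never enters the
tally. Per-map mean gains and losses are reported alongside as a
threshold-free summary. One root seed derives all per-map seeds up front, so
results are bit-identical across runs and independent of evaluation order.

## What the synthetic generator emulates — and what it does not

`yule_tree()` (pure birth, via `ape::rphylo`) stands in for the published
supermatrix phylogeny; `simulate_mk()` evolves a binary character forward
along the tree recording the true change history; and
`simulate_dependent_triple()` builds TM/TA/CO rows in which the columella
evolves freely while each lateral structure evolves as a latent character
expressed only where its medial gate is present. The gate construction
guarantees the dependency invariants by design; we chose it over a joint
four-state chain because it is simple, sufficient for exercising the coding
rules, and immune to rate-matrix bookkeeping errors. Defaults in the
analysis scripts — 150 tips, a columella losing at 0.6 changes per tree
height and gaining at 0.1, lateral structures at 0.5/0.5 — were chosen once
as a realistic toad-like regime (losses dominating gains, lateral structures
more labile) and not revisited.

A green test on synthetic data establishes that the algorithms are correct
for data generated under the model's own assumptions. It does not establish
robustness to what real scored datasets carry: phylogenetic error,
non-random missing data (rare taxa are both harder to score and more often
earless), rate variation across clades, or correlated evolution among the
three structures beyond the structural gate.

## Numerical and degenerate-case choices

* Zero-length branches are retained; their transition matrix is the
  identity. Zero-rate models are legal; impossible endpoint/constraint
  combinations raise errors rather than returning `NaN` (`mk_loglik`
  returns `-Inf` for impossible data, the samplers refuse to start).
* Degree-1 roots are accepted with a warning; polytomies everywhere.
* Newick labels may be quoted (quotes are stripped, doubled quotes
  unescaped); underscores are preserved verbatim so taxon matching against
  the character table is exact. Bracketed comments, including this package's
  own NHX annotations, are stripped on read, so annotated output round-trips.
* Node addresses are labels, assigned at read time and preserved by
  pruning; pruning sums the branch lengths of suppressed degree-2 nodes, so
  pairwise path lengths among kept taxa are invariant to 1e-12.

## Known limitations

Binary characters only (the three structures are analysed independently, as
in the study — no joint or correlated model); a single fixed tree (no
integration over phylogenetic uncertainty); no rate heterogeneity across
branches; no ascertainment-bias correction. Reproducing the study's printed
counts would additionally require its reference phylogeny and supplementary
scorings, which are inputs, not part of this package.
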