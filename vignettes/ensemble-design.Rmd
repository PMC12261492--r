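---
title: "Ensemble free energy mRNA design: model, algorithm and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble free energy mRNA design: model, algorithm and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(efedesign)
```

## The design problem

An mRNA for a protein $p = (p_1,\dots,p_n)$ is any nucleotide string whose
codons translate to $p$; the design space $X(p)$ grows as the product of
codon multiplicities (1–6 per residue) and is astronomically large for
real proteins. The classical objective picks the sequence whose best
secondary structure is most stable,
$\min_{x \in X(p)} \min_{y \in Y(x)} \Delta G^\circ(x,y)$, a
min-over-min that dynamic programming solves exactly over a compact
automaton representation of $X(p)$. This package targets the harder and
biophysically richer objective of **ensemble free energy**,
$$\Delta G^\circ_{\mathrm{ens}}(x) = -RT \ln Q(x), \qquad
  Q(x) = \sum_{y \in Y(x)} e^{-\Delta G^\circ(x,y)/RT},$$
which rewards sequences populating *many* low-energy conformations —
flatter ensembles mean less thermodynamic penalty when the ribosome
unwinds structure during translation, and, empirically, lower average
unpaired probability (AUP), which correlates with chemical degradation.
A min-over-sum admits no Viterbi-style exact DP and is believed
intractable, hence the relaxation below.

## Codon lattice and probabilistic relaxation

$X(p)$ is represented exactly by a layered deterministic finite automaton:
offsets $0..3n$, one state layer per offset, each codon block accepting
exactly the synonymous codons of its residue (six-codon amino acids fork
into two prefix branches that re-merge at the block boundary; a trailing
`*` appends a stop-codon block). Branch indices follow sorted codon
prefixes, so lattices are byte-for-byte reproducible. `count_sequences()`
carries the accepting-path count exactly (arbitrary-precision product) —
the bundled SARS-CoV-2 spike protein gives $2.36\times10^{632}$, including
the stop-codon factor of 3.

Placing a probability $\tau(q, x)$ on each edge (normalized per node)
turns the DFA into a probabilistic lattice encoding the product
distribution $D(x) = \prod_i \tau(q_i, x_i)$. The optimization objective
is the **expected partition function**
$\tilde Q(D) = \mathbb E_{x \sim D}[Q(x)]$. By Jensen's inequality
$-RT \ln \tilde Q(D) \le \mathbb E_D[\Delta G^\circ_{\mathrm{ens}}(x)]$,
with equality exactly at one-hot (degenerate) distributions, so maximizing
$\tilde Q$ minimizes a faithful surrogate of the expected EFE, and the two
objectives agree on every integral solution. Both properties are verified
numerically in the test suite by full enumeration on small proteins.

A note on **soft-MFE initialization**: the optimizer starts each restart
from $\tau = \varepsilon\,\tau_{\mathrm{rand}} + (1-\varepsilon)\,
\tau_{\mathrm{MFE}}$, mixed at the node-parameter level. A mixture of two
product distributions is generally *not* a product distribution, so a
distribution-level blend could not be represented on the lattice; the
τ-level blend is the natural representable counterpart with the same
endpoints ($\varepsilon = 0$: one-hot MFE start; $\varepsilon = 1$: pure
random start). $\tau_{\mathrm{rand}}$ is drawn per node from a flat
Dirichlet, seeded per restart.

## Energy model

The folding model is deliberately pair-additive (Nussinov–Jacobson level):
six canonical pair types with per-type scores, a minimum hairpin of $h$
unpaired nucleotides ($j - i > h$), no stacking, loop or mismatch terms.
Defaults: CG/GC $-3$, AU/UA $-2$, GU/UG $-1$ kcal/mol (the usual 3/2/1
hydrogen-bond weighting), $h = 3$, $RT = 0.6163$ kcal/mol (37 °C). The
empty structure is always in $Y(x)$ at energy 0, so $Q \ge 1$ and EFE
$\le 0$. All constants live in `energy_model()` and flow through every
computation; no test hard-codes them. Absolute energies under this model
are not comparable to nearest-neighbor (Turner) energies — orderings and
differences between designs are the meaningful outputs.

## The engines

All dynamic programs run in log space with log-sum-exp accumulation and
are compiled (Rcpp):

* **Single-sequence folding** — Nussinov recursions for the MFE (Viterbi
  semiring) and the partition function (inside semiring); the outside pass
  yields base-pairing probabilities. Checked against exhaustive structure
  enumeration (itself validated by an independent recursive count) on
  hundreds of random sequences: energies exactly, $Q$ to $10^{-9}$
  relative, pairing probabilities to $10^{-9}$.
* **Viterbi lattice parsing** (`design_mfe()`) — the same recursion with
  spans keyed by lattice-state pairs, minimizing jointly over paths
  (sequences) and structures. No pair-type-split nonterminals are needed:
  with a pair-additive model the pair identity is read off the two edge
  labels at the span boundary.
* **Probabilistic lattice parsing** (`expected_partition_function()`) —
  the inside semiring with edges weighted by $\ln\tau$; each accepting
  path contributes its probability times its structure ensemble, so the
  goal item is exactly $\ln\tilde Q(D)$. On a degenerate distribution this
  reduces to $\ln Q(x)$ (machine-exact in the tests).
* **Gradients** (`epf_gradient()`) — $\tilde Q$ is multilinear in the edge
  parameters with nonnegative coefficients, and the outside pass
  accumulates $\partial\tilde Q / \partial\tau_e$ per edge as
  (sign, log-magnitude). One subtlety the finite-difference oracle caught
  during development: outside mass must flow *through* items of zero
  inside mass, because a $\tau_e = 0$ parameter still has a nonzero
  derivative (differentiation removes that factor). Gradients match
  central finite differences (step $10^{-6}$, parameters treated as free
  unnormalized coordinates — feasibility is the projection's job) to
  better than $10^{-4}$ relative.

## Optimization

`ensemble_design()` implements projected gradient ascent: step along the
gradient, then project each node's parameters onto the probability simplex
(exact sort-and-threshold Euclidean projection, verified against a dense
grid-search oracle). Choices the problem statement left open:

* **Ascent direction**: $\nabla \ln\tilde Q = \nabla\tilde Q / \tilde Q$
  rather than the raw gradient, whose magnitude spans hundreds of orders
  across protein lengths. This rescales the step without moving any fixed
  point and makes a single default learning rate workable.
* **Step size**: $\alpha = 0.5$ with step-halving backtracking (up to 20
  halvings if $\ln\tilde Q$ would decrease); consequently the trace is
  monotone and the returned iterate never undercuts the start.
* **Convergence**: relative change of $\ln\tilde Q$ below $10^{-6}$, cap
  of 30 iterations (ascents on desk-scale proteins converge in well under
  30; the per-run iteration counts are visible in `summary()`).
* **Restarts and decoding**: 20 independently seeded restarts by default
  ($\varepsilon = 0.5$); each final distribution is decoded into the
  edge-wise argmax plus 9 seeded samples, every candidate is scored by its
  *exact* EFE, and the best candidate across restarts is returned. The
  greedy argmax is not guaranteed to be the distribution's mode on a
  branched lattice, but at convergence the distributions are nearly
  one-hot, where the two coincide; sampling covers the residual softness.
* **Tie-breaks**: nucleotide order A<C<G<U everywhere; the MFE traceback
  prefers fewer pairs (unpaired extension first, then the smallest
  pairing partner), making all decoders deterministic.

The random-walk baseline proposes a uniformly random codon at a uniformly
random position (self-proposals count as steps) and accepts only strict
EFE improvements, starting from the MFE design.

## Beam pruning

For long designs the inside chart can be pruned: within every span cell
the competing state-pair items are ranked and only the top $b$ kept. The
ranking score is the inside value *plus the forward path log-probability
of the span's start state* — the lattice analogue of prefix-score ranking
in left-to-right beam decoders. The prefix term is what makes pruning
well-behaved: branches unreachable under the current distribution rank
last, so a one-hot distribution is searched exactly at any width, and
search error is paid only where the distribution is soft. The error is
therefore largest early in optimization (high mean node entropy) and
vanishes as distributions sharpen — `beam_error_probe()` quantifies this,
and the tests assert the entropy–error direction. Two caveats: with at
most two states per offset a cell holds at most four items, so widths
$\ge 4$ are exact under this model (the Turner-level nonterminal machinery
that makes pruning bite is out of scope here); and because pruning feeds
forward, nested widths are not guaranteed to give monotone $\tilde Q_b$,
so no such monotonicity is asserted.

## The synthetic panel, and what the tests do and do not show

`generate_fixture_panel()` draws residues uniformly from the 20 amino
acids with lengths uniform in a range; the benchmark panel is 20 proteins
of 30 aa. Uniform-random proteins have no codon-usage bias, no signal
peptides or composition structure, and 30 aa is far below natural mRNA
lengths — the panel exercises the machinery and the qualitative method
ordering, not biological effect sizes. On this panel the mean EFE ordering
(ensemble design $\le$ random walk $\le$ MFE design) holds with a clear
margin and the ensemble designs change 3–10% of codons where the walk
stays within a few percent of its start. The AUP byproduct, by contrast,
is a small effect even at full scale (reference reductions are on the
order of $2\times10^{-3}$ on long natural proteins under a nearest-
neighbor model); at 30 aa under the pair-additive model it sits within
seed noise, so the benchmark asserts only that ensemble design does not
materially worsen AUP (tolerance 0.005) and reports the signed difference
rather than claiming a reduction this artifact cannot resolve.

## Numerical and degenerate-input notes

* All partition-function arithmetic is in log space; gradients are stored
  as log-magnitudes (their sign is structurally nonnegative).
* $0 \log 0 := 0$ in every entropy; node distributions are validated to
  sum to 1 within $10^{-9}$.
* Proteins of one residue with a single codon ("M") yield a singleton
  design space: every method returns that sequence, with EFE 0 when the
  sequence is too short to pair.
* Sequence enumeration and structure enumeration are oracle tools and
  refuse instances beyond small guards (design spaces above a caller-set
  limit; sequences over 30 nt).
* Exact design-space counts use a minimal base-$10^4$ big-integer product
  (multiplicities are at most 6), carried alongside a double-precision
  $\log_{10}$; the two are cross-checked to better than six significant
  digits.

## Known limitations

* The pair-additive energy model is the point of the prototype, not a
  substitute for nearest-neighbor thermodynamics: absolute energies, AUP
  levels and structure details differ from Turner-model results.
* The distribution family is product-form by construction; mixtures over
  $X(p)$ (e.g. a true distribution-level soft-MFE blend) are not
  representable.
* Runs are sequential; restarts are independent and could be parallelized
  by the caller.
* The greedy argmax decoder and the MFE tie-break are deterministic
  conventions, not guaranteed global modes / lexicographic minima under
  exact ties.
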