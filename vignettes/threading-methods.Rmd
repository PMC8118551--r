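---
title: "Alignment CRFs, distance potentials and ADMM threading: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment CRFs, distance potentials and ADMM threading: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
tunable parameters and their defaults, the conventions adopted where the
underlying formulation leaves choices open, and what the synthetic fixtures
do and do not establish about behaviour on real proteins.

## 1. The alignment model

A pairwise alignment of a template (length $N_1$, known structure) and a
query (length $N_2$, sequence only) is an ordered list of triples
$(i, j, u)$ with 0-based residue indices, $-1$ marking the unconsumed side,
and state $u \in \{M, I_x, I_y, G_h, G_t\}$: match, template insertion,
query insertion, head gap, tail gap.  Four interconvertible representations
are provided (triples, grid path, the $5 N_1 N_2$ binary indicator array
with $-1$ flanks, and a three-line text record of two gapped rows plus a
state string).  The state string alone cannot say which protein a flank-gap
step consumes when both flanks carry gaps on both sides, so the text record
is the canonical lossless string form.

Index-advancement semantics: $M$ consumes one residue of each protein;
$I_x$/$I_y$ one template/query residue; each flank-gap triple consumes
exactly one residue of either protein.  Within any indel region or flank,
template-consuming steps precede query-consuming ones.  This canonical
ordering — together with the transition rules below — makes the
representation unique: a valid alignment is exactly determined by its set of
matched pairs, which is what `alignment_from_pairs()` constructs and what
makes exhaustive enumeration (`enumerate_alignments()`, the test oracle)
cheap: there are $\binom{N_1+N_2}{N_1} - 1$ valid alignments (69 at
$4\times4$).

**Transition model.** Of the 25 ordered state pairs, 12 are feasible:
$M \to \{M, I_x, I_y, G_t\}$, $I_x \to \{M, I_x, I_y\}$,
$I_y \to \{M, I_y\}$, $G_h \to \{M, G_h\}$, $G_t \to G_t$.
$I_y \to I_x$ is forbidden to kill duplicate representations of mixed indel
runs, and $G_h \to G_t$ is forbidden so every alignment contains at least
one match.  The scores of $M \to G_t$, $G_h \to M$, $G_h \to G_h$ and
$G_t \to G_t$ are fixed at zero so flanks are unpenalized (local
alignment); the remaining eight feasible entries default to zero and may
optionally be trained (`train_mle(..., train_transitions = TRUE)`), the
default keeping them fixed — a fixed transition matrix already supports a
strong model.  A virtual start may enter $\{G_h, M\}$ and a virtual end is
reached from $\{M, G_t\}$, which combined with the forbidden
$G_h \to G_t$ enforces the at-least-one-match rule inside the dynamic
programs.

Internally each flank state splits into a template- and a query-consuming
sub-state (7 states total) with the directional orderings ($H_y \to H_x$
and $T_y \to T_x$ forbidden); feasibility and scores act at the collapsed
5-state level.

## 2. CRF inference

All dynamic programming is in log space (max / log-sum-exp; no
probability-space recursions), implemented once in C++ over the
$(N_1{+}1)\times(N_2{+}1)\times 7$ grid:

* `viterbi()` — the highest-scoring valid alignment; ties broken
  deterministically by state preference $M > I_x > I_y > G_h > G_t$
  (template-consuming flank steps first).
* `forward_backward()` — $\log Z$ and the posterior expected indicator
  count of every emission cell; the $M$ slice is the match marginal
  $p(z_{ij}^M = 1)$.  Optionally the $5\times5$ expected transition counts.
* `maxacc_decode()` — the alignment maximizing the expected number of
  correctly aligned positions $\sum_{(i,j)\in A} p_{ij}$, i.e. Viterbi on a
  score table whose $M$ slice is the posterior (roughly twice the cost of a
  single Viterbi pass once the posteriors are in hand).
* `loglik()` — alignment score minus $\log Z$; the test suite checks that
  $\sum_A e^{\ell(A)} = 1$ by enumeration.

**Gap-emission context.** The emission table $\theta$ is indexed by
$(i, j, u)$.  A gap triple reads $\theta$ at the last consumed index of the
unconsumed side, clamped to the first position (only head gaps hit the
clamp).  The reference scorer `score_alignment()` and the DP kernels share
this convention, and the enumeration oracle verifies their agreement on
every instance with $N_1, N_2 \le 4$.

## 3. Emission scorers

Nine pairwise feature channels feed both scorers
(`pair_features()`): residue identity, BLOSUM80/62/45 (the canonical NCBI
matrices as shipped with Biostrings; residue `X` scores 0), profile products
$\langle \mathrm{PSFM}_q(j), \mathrm{PSSM}_t(i)\rangle$ and
$\langle \mathrm{PSFM}_t(i), \mathrm{PSSM}_q(j)\rangle$ (PSSM entries are
used unscaled), and agreement scores for secondary structure and solvent
accessibility, defined as the probability the query's predicted class
distribution assigns to the template's observed class (3- and 8-class
secondary structure; buried/intermediate/exposed burial classes with
thresholds 0.10 and 0.40 of relative accessibility).  Templates without a
profile use the one-hot PSFM and, as the PSSM of a single sequence, the
BLOSUM62 row of each residue.

* `linear_score()` — $\theta^M_{ij}$ affine in the channels, constant
  $I_x$/$I_y$ penalties, zero flank scores.  Exactly trainable; also the
  test oracle for the training machinery.
* `drnf_score()` — two 1D residual convolutional networks (default 10
  convolutions, kernel 3, instance normalization + ReLU after each, residual
  skips every two layers) embed each protein's 54 sequential feature
  channels (20 PSFM + 20 PSSM + 3 + 8 secondary structure + 3 burial);
  outer concatenation broadcasts the two embeddings to an $N_1 \times N_2$
  map joined with the 9 pairwise channels; a 2D residual network (default
  20 blocks of 3 convolutions, kernel 5) emits $\theta^M$.  Channel widths
  are open in the architecture description; the defaults here are 32 (1D)
  and 64 (2D), and the test suite runs widths 4/8 where an independent
  direct-loop re-evaluation of the full layer sequence serves as the
  forward-pass oracle.  By default the network emits match scores only and
  $I_x$/$I_y$ are learned scalars; `emit_gap_scores = TRUE` switches the
  head to three channels (both modes are supported because the original
  formulation does not say whether gap scores were network-emitted).
  Instance normalization can be disabled for exact desk-scale comparisons.

## 4. Maximum-likelihood training

`train_mle()` maximizes $\sum \log P(A_{\mathrm{ref}} \mid T, S)$.  The
gradient with respect to $\theta$ is observed-minus-expected indicator
counts from forward–backward; for the linear scorer this contracts against
the feature channels (exact), and for the network it backpropagates through
the 2D net, the outer concatenation and the two 1D nets (all layer
gradients are hand-derived and validated against central finite differences
to $10^{-4}$ relative error in the test suite, as is the transition-score
gradient via expected edge counts).  Pairs are grouped into minibatches by
their length product $N_1 N_2$ (budget 4000 by default: several small pairs
or one large one per batch).  The optimizer is Adam (learning rate 0.05)
with a plain small-step gradient-ascent option whose full-batch trace is
non-decreasing — the property the tests assert.  Training aborts with a
diagnostic on non-finite loss.  `epochs = 0` returns the initialization
unchanged, and every stochastic routine takes an explicit seed.

## 5. Distance potentials and the threading objective

Distances are discretized into 14 intervals.  The interval listing in the
source formulation skips 4–5 Å; the only reading consistent with "14
intervals at 1 Å steps between <4 Å and >16 Å" is
$\{<4, [4,5), \dots, [15,16), \ge 16\}$ with right-open interior bins, which
is what `distance_bins()` implements (the acceptance sweep confirms the
count).

`dfire_potential()` converts a predicted distribution $p(j, l, d)$ over the
bins into $u(j, l, d) = -\log p(j,l,d)/p_{\mathrm{ref}}(d)$ with the
distance-scaled finite ideal-gas reference
$p_{\mathrm{ref}}(d) \propto r_d^{\alpha}$, $\alpha = 1.61$ (the standard
DFIRE exponent; configurable), normalized over the 14 bins.  Bin
representatives $r_d$ are the interval midpoints, 2.0 Å for the first bin
and lower edge + 0.5 Å for the open last bin.  Potentials are clipped to
$\pm 10$ so zero-probability bins stay finite.

The threading objective is
$S = w\,S_{\mathrm{singleton}} + S_{\mathrm{pairwise}}$ with $w = 1$ by
default ($w = 20$ for clearly homologous "easy" targets — exposed as the
`--easy` flag since the package has no E-value machinery).  Conventions the
formulation leaves open, fixed here once: $S_{\mathrm{singleton}}$ is the
emission sum only (transition scores are zero by default, so decoder optima
and objective optima coincide); $\theta^{MM}_{ijkl} = -u(j, l,
\mathrm{bin}(d_T(i,k)))$ is a score (higher is better) and $S$ is maximized;
the pairwise sum runs over unordered pairs of distinct matches, self-pairs
excluded; template pairs in the $\ge 16$ Å bin contribute zero.

## 6. ADMM and multistart

Exact maximization of $S$ is intractable, so `admm_align()` duplicates the
match indicators into two copies $z, y$ with the consensus constraint
$z = y$, writing the cross term as $\tfrac12 z^\top P y$ so that each
subproblem is linear in one copy (binary variables make the quadratic
penalty linear too) and exactly solvable by Viterbi with augmented match
scores.  The scaled dual update is
$\lambda \leftarrow \lambda - \rho (z - y)$; iteration stops when the
copies agree.  Two deliberate choices: the first $z$-update omits the
proximal terms, so with a zero potential the first subproblem is exactly
plain Viterbi of $\theta$ and the procedure converges in at most two
iterations; and `keep_best` (default) evaluates every candidate alignment
under the true objective and returns the best seen — including the initial
alignment, so the returned objective never falls below the starting one
even when the consensus iteration wanders.  Defaults: $\rho = 0.5$, 20
iterations.  On exhaustive $4\times4$ oracles the heuristic attains the
global optimum on the large majority of random instances (tracked at 80%
in the tests); `multistart_align()` runs it from the Viterbi alignments of
several score tables (four, in the spirit of initializing from four
differently trained scorers) and returns the argmax, which by construction
dominates every single start.

`build_refiner_input()` and `refine_alignment()` provide the complementary
learned improvement path: three $N_1 \times N_2$ maps — the initial
alignment indicator, $\theta^M$, and the distance-potential map
$\sum_{(k,l) \in A_0,\ d_T(i,k) < 16\text{Å}} \theta^{MM}_{ijkl}$ (the
16 Å restriction is equivalent to excluding the last distance bin) — enter
a 2D residual network that emits a fresh score table for re-decoding.
ADMM and the refiner can be interleaved; keeping the best-so-far objective
across stages is monotone by construction.

## 7. Template ranking and evaluation

`selection_score()` ranks templates by
$w_1 S_{\mathrm{singleton}} + S_{\mathrm{pairwise}} + w_2\,
S_{\mathrm{pairwise}} / n_{\mathrm{aligned}}$ (defaults $w_1 = 1$,
$w_2 = 5$; $w_1 = 20$ for easy targets): the normalized term rewards
per-position quality rather than alignment length.  Ties break by higher
singleton score, then template id; ranking is invariant to input order.
`evaluate_alignment()` reports reference-dependent precision (fraction of
predicted matched pairs present in the reference) and recall (fraction of
reference pairs recovered); structure-based model quality scores are out of
scope here.

## 8. The synthetic generator — what it does and does not establish

`sample_fold()` draws compact self-avoiding chains of ideal-helix segments
(3.8 Å steps within [3.6, 4.0]; no non-consecutive contact under 3.5 Å),
deterministic per seed via rejection inside a seeded stream.
`make_pair()` derives a query by point mutations (matched positions) and
indels (rate split evenly between insertions and deletions), records the
generative correspondence as the reference alignment, gives matched query
residues the template's coordinates (a conserved fold) and inserted ones
interpolated positions, and emulates upstream predictors: one-hot profiles,
geometry-derived secondary-structure/burial labels, and one-hot true-bin
distance distributions, each blended toward uniform by the `noise`
parameter — `noise = 0` yields exact predictors.  `make_dataset()` mixes
four difficulty levels (mutation 0.10/0.30/0.50/0.70 with indel rates
0.02/0.06/0.10/0.15) in the ratio 1:2:2:1 and splits by fold identity.  Two
reference styles are available: the full generative correspondence and a
conservative variant trimming the outermost match at each end, emulating
stricter structure-alignment references.

Consequences for interpreting the tests: the fixtures have helical-only
geometry (no sheets, so the 8-class secondary-structure channels exercise
only 3 letters), profiles without real evolutionary signal, and — crucially
— distance "predictions" whose errors are independent and centred on the
truth.  Passing the distance-signal tests therefore shows the machinery
exploits exact or near-exact distance information correctly; it does not
show robustness to the correlated, contact-order-dependent errors of real
distance predictors, nor realistic template ranking difficulty.  Helix
self-similarity also means shifted alignments score deceptively well on the
pairwise term, which makes the fixtures a reasonably adversarial test of
the singleton/pairwise balance.

## 9. Numerical choices and problem sizes

Log-sum-exp throughout; instance normalization uses population variance
with $\epsilon = 10^{-5}$ (zero input maps to zero output, so all-zero
parameters emit an all-zero score table); potential clipping at
$\pm 10$; Viterbi/MaxAcc tie-breaking as in section 2; degenerate inputs
($N = 1$ proteins, empty indicator arrays, all-deleted queries) are either
handled (a $1\times1$ problem has exactly one alignment) or rejected with
a named invariant.  The test suite runs at desk scale by design: exhaustive
oracles at $N \le 4$–$6$, network configurations of widths 4–8 with 1–3
blocks, a 200-pair training corpus of 18–30-residue pairs for the
generalization check, 30–50 seeded trials for the distance-signal and
ranking properties.  These sizes were chosen so every oracle is exact and
the full suite runs in about a minute; the algorithms themselves scale as
$O(N_1 N_2)$ per DP pass and have no desk-scale assumptions.

## 10. Known limitations

* The 14-bin discretization and Cβ–Cβ pairing are fixed; no orientation
  potentials or multi-atom pair types.
* ADMM offers no optimality certificate; the keep-best contract only
  guarantees monotone improvement over the initialization.
* The refiner is provided as an architecture with correct gradients, not as
  a pre-trained model; no trained checkpoints ship with the package.
* Checkpoints and distance tensors use RDS containers (with a JSON config
  sidecar) rather than HDF5, keeping the dependency set to what the package
  already needs.
* Single templates only: no multi-template modelling, and no 3D model
  building from the final alignment.
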