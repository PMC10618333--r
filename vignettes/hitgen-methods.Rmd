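---
title: "Goal-directed SMILES generation with HitGen: models, rewards and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-directed SMILES generation with HitGen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

HitGen implements a desk-scale, fully self-contained version of a now-classic
de novo design loop: a recurrent SMILES language model proposes molecules, a
bioactivity regressor and a synthetic-accessibility heuristic judge them, a
policy-gradient update biases the language model toward better judgments, and
the surviving candidates are triaged on a Pareto front, expanded into
stereoisomers and interpreted through attention weights. This vignette is the
package's own account of the science: the models and their assumptions, the
parameters that matter, the numerical choices, and what the synthetic test
bed does and does not demonstrate.

## The generator

The generator is a token-level language model over SMILES strings: an
embedding layer, two stacked LSTM layers and a softmax-activated dense output
over the vocabulary. Multi-character chemistry tokens (`Cl`, `Br`, `@@`,
bracket atoms such as `[nH]`, two-digit ring closures) are atomic vocabulary
entries, and the stereo markers `@`, `@@`, `/`, `\` are included because
downstream stereoisomer ranking depends on them. Sequences are framed
`GO ... EOS` and right-padded; padding always has code 0.

Pre-training is teacher-forced maximum likelihood: the loss is the
categorical cross-entropy of the next-token distribution, averaged over each
sequence's length and then over the batch,
$$ J(\theta) = -\frac{1}{B}\sum_b \frac{1}{T_b} \sum_{t=1}^{T_b} \log
   \hat{y}_{t}[y_{t}] . $$
Sampling is autoregressive with a softmax temperature: logits are divided by
$\tau$ before normalization, so $\tau \to 0^{+}$ collapses to greedy argmax
decoding and $\tau = 1$ samples the model distribution unchanged. Sampling
stops at EOS or at the length cap; capped strings are kept and judged by the
validity oracle like any other sample.

Defaults follow the common practice for this model family (Adam, batch 128,
length cap 100); all sizes are configurable. The tests and the acceptance
script use embedding 64 and 128 units per layer — small enough to train in
minutes on one core, large enough to reach high syntactic validity on the
fixture corpus.

## Validity, and why the package carries its own SMILES gate

Syntactic validity is a headline metric for SMILES generators, so the
validity oracle must be strict. Structure handling in HitGen is delegated to
Open Babel (via ChemmineOB/ChemmineR), but Open Babel deliberately repairs
several classes of malformed input — unbalanced branches (`C(`), nested
branch heads (`C((C))O`), hypervalent carbons, `F=F` — that a validity
metric must count as failures. `smilesSyntaxOk()` therefore performs a
token-level structural pass before canonicalization: branch balancing,
non-empty branches, paired ring-bond digits, bond placement, and a valence
tally per atom (aromatic bonds counted as order one, common hypervalent N/S/P
forms allowed). A string is valid iff it passes this gate and Open Babel
canonicalizes it. The gate is intentionally conservative in one known spot:
aromatic rings that cannot be aromatic (e.g. `c1ccc1`) are accepted because
Open Babel kekulizes them; this affects no metric materially at fixture
scale.

## The predictor family

Bioactivity is regressed from SMILES (or fingerprints) in ten
configurations, pairing a descriptor (ECFP4, ECFP6, a path fingerprint, or
the raw token sequence) with an architecture (multi-layer feed-forward;
GRU; bidirectional GRU; bidirectional + stacked GRU; separated bidirectional
streams) and optionally an additive attention pooling. The default and
best-performing member is the stacked bidirectional recurrent model with
attention.

Attention pooling scores each hidden state $h_i$ against a learned output
query through a dense alignment layer, applies tanh then a softmax over
positions, and pools
$$ C_m = \sum_{i=1}^{T} \alpha_i h_i , \qquad
   \alpha = \mathrm{softmax}\big(\tanh(e(O_m, h_i))\big) , $$
so the weights are non-negative, sum to one, and align one-to-one with the
SMILES tokens — which is what makes the per-atom interpretability maps
possible. The alignment network $e$ is a single dense layer against a
trainable query vector; the literature leaves its form open and this is the
smallest choice that works.

Labels are standardized robustly as $z = (y - \mathrm{median})/\mathrm{IQR}$
with linear-interpolation (type-7) quartiles — the convention had to be fixed
for reproducibility and type 7 is R's default. Training uses Adam, at most 50
epochs, early stopping with patience 15 and best-checkpoint restoration.
Cross-validation follows the repeated-holdout reading of "five folds, 85/15
each": five independent 85/15 splits of the pool that remains after a 10%
hold-out carve-out. Folds are split on unique canonical SMILES, so duplicate
spellings can never leak across folds.

A deliberate implementation choice: sequence batches are grouped by exact
token length, so no padding or masking ever enters the recurrence. This
costs a little batch efficiency and buys an exact contract — a molecule's
prediction cannot depend on what else is in its batch.

Fine-tuning on a focused subset continues training at 0.1 times the base
learning rate (a conservative default; the reduction factor is exposed), and
zero epochs is the identity.

## Rewards and the self-adaptive scalarization

Each objective is mapped to $[0,1]$ by a clipped, rescaled sigmoid: predicted
pIC50 rises 0 to 1 over [4, 9] (pIC50 units); the synthetic-accessibility
score falls 1 to 0 over [1, 6]. The saturation points are pinned exactly (the
sigmoid is affinely rescaled), values beyond them clip, and the map is
strictly monotone in between. Fixed shapes — rather than per-batch min-max —
keep the reward stationary across the optimization. Invalid sampled strings
receive reward 0 on both objectives; without that penalty the policy gradient
has no signal to preserve syntactic validity.

The two rewards combine additively, $f = w_1 r_1 + w_2 r_2$ with
$w_1 + w_2 = 1$, initial weights (0.6, 0.4) favouring potency. The weights
adapt online: after each batch, if one objective is currently favoured
($w_1 f_1 > w_2 f_2$) while the other has plateaued — variation ratio
$(\max-\min)/\max$ below 0.05 over a five-batch window — weight shifts toward
the neglected objective by a fixed step, then clips to $[0,1]$ and
re-couples. The variation-ratio convention had to be declared (a
coefficient-of-variation alternative is exposed); the step defaults to 0.05,
with the alternative printed convention 0.1 equally supported. At a plateau
the trigger condition extinguishes itself after at most
$\lceil |w_1f_1 - w_2f_2| / (s(f_1+f_2)) \rceil + 1$ updates, so the rule
cannot oscillate indefinitely.

## The REINFORCE update

Conditioned generation treats sampling as a Markov decision process: states
are SMILES prefixes, actions are tokens (including EOS), and each completed
molecule earns one terminal scalar reward. The return is distributed over the
steps as $R_t = \sum_k \gamma^k r_{t+k}$ and the update descends on
$$ \mathcal{L} = -\frac{1}{B} \sum_b \sum_t \gamma^t R_t
   \ln \pi(A_t \mid S_t), $$
whose gradient is the classic score-function ascent. The discount defaults to
$\gamma = 1$ (undiscounted terminal reward; no printed value exists to adopt)
and is configurable. Plain REINFORCE is the default — no baseline — with an
optional moving-average baseline behind a flag for variance reduction, and
the gradient is norm-clipped at 5 as a standard small-batch guard. One
self-adaptive weight update runs per batch, ordered before the gradient
step. The correctness anchor is not the full pipeline but two small oracles
in the test suite: the analytic score-function gradient matches central
finite differences of the expected reward on a two-action bandit to 1e-4
relative, and the policy concentrates on the best arm of a three-armed
bandit.

## Hit selection

The optimized sample is triaged on the (pIC50, SAS) plane: a solution is
non-dominated iff no other is at least as potent and at least as
synthesizable with one strict improvement. Weak dominance is used and exact
ties on both axes are all retained; the sweep implementation is checked
against the quadratic pairwise oracle in the tests.

Stereoisomers are enumerated over unassigned tetrahedral centers: sp3
carbons whose four substituent branches (implicit hydrogen included) are
pairwise distinguishable, detected on the molecular graph by blocked
breadth-first branch hashing. The $2^c$ chirality assignments are written by
token rewriting (`C` to `[C@H]`/`[C@@H]`), canonicalized and deduplicated, so
meso collapses stay below the $2^c$ ceiling. Unassigned double-bond geometry
is not enumerated — a scope limitation: reliable E/Z marker insertion into
canonical SMILES is not supported by the underlying toolkit. Ranking is by
predicted pIC50 descending, with SAS reported alongside; no composite score
is imposed because the affinity/synthesizability trade-off is left to the
analyst.

Similarity to reference actives is reported two ways: ECFP4 Tanimoto, and a
maximum-common-substructure Tanimoto on atom counts,
$|MCS| / (|A| + |B| - |MCS|)$, computed as a maximum clique of the modular
product graph (element and bond-order matched, induced subgraphs, 10 s
timeout flagged). Attention interpretability projects token weights onto
atoms: atom tokens keep their weight, each non-atom token splits its mass
equally between the nearest preceding and following atom tokens, and the
result sums to one.

## The synthetic accessibility score

The 1-10 scale follows the fragment-contribution-plus-complexity recipe: a
rarity term (mean negative log-frequency of each atom's radius-2 circular
environment in an internal reference set of drug-like molecules, with a
deliberately over-weighted aliphatic baseline so simple chains score easy)
plus penalties for size ($n^{1.005}-n$ in heavy atoms), ring count and
stereocenters, affinely mapped onto [1, 10] and clipped. The score is a
deterministic function of the canonical SMILES. It preserves the orderings
that matter for the reward (simple < polycyclic stereo-rich) but its absolute
values are not exchangeable with other published implementations, whose
fragment statistics come from corpora this package does not ship.

## The synthetic test bed

Everything is testable offline because the fixture module generates its own
data. Corpora are built by combinatorial decoration of aryl/alicyclic
scaffolds with linkers (amides, amines, sulfonamides, hydroxyalkyl chains
that carry unassigned stereocenters) and tail groups; every emitted molecule
is valid, canonical, and inside the drug-like window (MW 200-600 g/mol, logP
-2..6 — closed intervals), and about half carry at least one unassigned
stereocenter. Affinity labels are linear in interpretable substructure
counts — nitrogens, aromatic rings, halogens (negative), amides — rescaled
to span pIC50 4-10 with Gaussian noise (default sd 0.3 pIC50 units) added
after rescaling; the default table size of 1453 mirrors the scale of a
typical augmented target-affinity set. The linearity is the point: it gives
regression tests a recoverable signal and attention tests a known ground
truth (the nitrogen positions).

What passing these tests shows: the learning machinery, the reward plumbing,
the selection logic and the metrics are correct, and the end-to-end loop
moves the property distributions in the intended directions at desk scale.
What it does not show: performance on real, heterogeneous chemistry — the
fixture corpus is combinatorial and regular (no macrocycles, no charged
species, no tautomer ambiguity), its affinity signal is far simpler than any
real structure-activity landscape, and distribution-learning scores against
it are easier than against a public compound database.

## Problem sizes and numerical choices

The test suite and the acceptance script run, by choice, at sizes a single
core handles in minutes: a 2,000-molecule corpus with a 64/128 generator
trained for 60 epochs (about 90% sampled validity at temperature 0.8); the
full 1,453-row affinity table with a 48-unit attention predictor trained for
20 epochs (hold-out Q2 above 0.8 by construction of the fixture signal); 30
REINFORCE epochs of 32 molecules. Recurrent kernels run through
RcppArmadillo; plain-R reference implementations of every forward and
backward pass live alongside them, and the tests require the two routes to
agree to 1e-10 and to match finite-difference gradients — that dual route is
the package's main defence against silent calculus errors.

Remaining numerical conventions, fixed once: Glorot-uniform initialization
with forget-gate bias 1; Adam (0.9, 0.999, 1e-8); softmax rows stabilized by
max subtraction; cross-entropy clamped at 1e-12; the adaptive-weight comparisons carry a
1e-9 tie-break margin so floating-point ties at the balance point cannot
flip-flop the weights; KL-divergence estimated on
50 equal-width bins over the reference's 0.1-99.9 percentile span
(categorical for integer-valued descriptors) with additive smoothing, fixed
direction sample-against-reference, aggregated as the mean of
$\exp(-KL)$ (a plain mean-KL aggregation is exposed as an alternative). The
Frechet-ChemNet distance field of generation reports is NA by design: it
requires an externally trained reference network that the package neither
ships nor trains.

## Known limitations

Beyond the fixture-realism caveats above: the generator has no scaffold or
property conditioning besides the RL loop; the MCS clique search is exact
but exponential in the worst case (hence the timeout flag); protonation
states, tautomers and 3D structure are out of scope; and the
self-adaptive weight rule, faithful to its printed form, compares favoured
objectives by the products $w_i f_i$, which couples the adaptation to the
current weights — an occasionally counter-intuitive but intended behaviour.
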