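---
title: "Methods: reward-guided MCTS decoding of a protein-conditioned SMILES model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reward-guided MCTS decoding of a protein-conditioned SMILES model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
# This vignette is a methods document; none of its chunks are executed so
# that building the package never trains a model or launches the chemistry
# backend.
knitr::opts_chunk$set(eval = FALSE)
```

## Problem

Given a target protein's amino-acid sequence, propose small molecules
(SMILES strings) that are chemically valid, drug-like, and — when a docking
program is available — predicted to bind the target. `mctsmol` treats this
as conditional sequence generation: an encoder–decoder transformer defines a
distribution $p(y_t \mid y_{<t}, \text{protein})$ over SMILES tokens, and a
decoding strategy turns that distribution into concrete molecules. The
package's central claim is that *reward-guided Monte Carlo Tree Search
(MCTS)* decoding produces a higher fraction of valid, property-compliant
molecules than likelihood-only decoding (greedy or beam search) from the
same model.

## Model

The prior is a standard encoder–decoder transformer implemented in base R:

* token embeddings plus fixed sinusoidal positional encodings;
* multi-head scaled dot-product attention; the decoder uses causal
  self-attention and cross-attention over the encoded protein;
* position-wise feed-forward blocks with ReLU, residual connections;
* training by teacher-forced cross-entropy with Adam.

Two deliberate simplifications, chosen for a dependency-free desk-scale
implementation, are documented rather than hidden:

* **No layer normalisation.** At the 2-layer, 32-dimensional scale used for
  the runnable configuration (`toy_transformer_config()`), training is
  stable without it; omitting it keeps the hand-written backward pass short
  and independently checkable. The full-scale configuration
  (`transformer_config()`: 6 layers, model dimension 512, 8 heads) is
  provided for completeness but is not desk-trainable in this package.
* **Exact manual backpropagation.** Gradients are verified against central
  finite differences in the test suite, which is the correctness anchor for
  everything the decoders consume.

`encode()` precomputes the per-layer cross-attention keys/values once per
protein; `decode_step()` advances an incremental key/value cache so a
length-$t$ decode costs $O(t)$ attention rows per step rather than
recomputing the full prefix.

## Rewards

`compute_reward()` scores a finished SMILES string with a weighted sum of
bounded components:

* **validity** — 1 if the string parses and sanitizes (RDKit), else 0;
* **RO5** — 1 if the molecule satisfies all four Lipinski criteria
  (MW ≤ 500 Da, logP ≤ 5, H-bond donors ≤ 5, H-bond acceptors ≤ 10,
  inclusive thresholds), else 0. Donors/acceptors use Lipinski's original
  NHOH / NO counts;
* **QED** — Bickerton's quantitative estimate of drug-likeness, already in
  $[0,1]$;
* **affinity** (optional) — a docking score $a$ in kcal/mol mapped to
  $\min(\max(a / a_{\text{floor}}, 0), 1)$ with floor $-12$ kcal/mol, so
  "more negative is better" becomes a bounded, increasing desirability.

A **hard validity gate** (default on) zeroes the composite for invalid
strings regardless of weights: partial drug-likeness of an unparseable
string is meaningless, and the gate is what drives the decoder's 100%
validity. The weighted *sum* (rather than product) was chosen so a zero in
one optional component (e.g. QED of a tiny fragment) cannot erase signal
from the others; the gate already handles the one component that must be
conjunctive.

Docking is isolated behind an adapter: `vina_affinity_scorer()` shells out
to an AutoDock-Vina-style executable through a command template and parses
the best (minimum) score, while `mock_affinity_scorer()` supplies a pure-R
stand-in. The test suite exercises the adapter contract with mocks only; no
external docking program is ever required.

## Decoding

### Greedy and beam baselines

`greedy_decode()` takes the argmax token each step (ties resolved to the
lowest vocabulary index). `beam_decode()` keeps the $k$ best partial
sequences under $\sum \log p / \text{len}^{\alpha}$; finished sequences
(EOS or length cap) occupy beam slots and compete in the final ranking.
Two exact identities are enforced by tests: beam with $k = 1$ reproduces
greedy token-for-token, and beam with $k$ at least the number of leaf
sequences equals exhaustive enumeration.

### MCTS

`mcts_generate()` runs UCT over the token-prefix tree. Each simulation:

1. **Selection** — from the root, descend to the child maximising
   $\bar r + c \sqrt{\ln N / n}$ where $\bar r$ is the child's mean
   composite reward, $n$ its visits, $N$ the parent's visits. Unvisited
   children score $+\infty$ (every child is tried once before any is
   repeated); exact ties resolve to the lowest token index.
2. **Expansion** — at a non-terminal leaf, create children for every token
   with positive model probability (zero-probability tokens are pruned:
   they can never be sampled and would only dilute exploration). A child is
   terminal if its token is EOS or it reaches the depth cap.
3. **Simulation (rollout)** — complete the prefix by sampling from the
   model until EOS or the depth cap, then score the detokenized string with
   `compute_reward()`.
4. **Backpropagation** — add the composite reward and one visit to every
   node from the expanded child up to the root.

Conventions worth stating explicitly:

* The answer returned is the **best valid terminal sequence seen anywhere
  during the search** (selection or rollout), not the most-visited root
  child; with the validity gate on, this makes the returned set 100% valid
  by construction, and the search errors if its budget finds no valid
  terminal at all.
* The exploration constant defaults to $c = 2$; all randomness is governed
  by `mcts_config(seed =)`, and the caller's RNG state is saved and
  restored around the search.
* Tree bookkeeping is invariant-checked in tests: root visits equal the
  simulation budget, parent visits dominate the sum of child visits, and
  cumulative rewards are bounded by visits times the maximum composite.

## Data handling

`filter_binding_records()` reduces BindingDB-style records to potent human
interactions. The potency rule is a **priority chain**, not an any-of:
IC50 is consulted if present; only if IC50 is missing is Kd consulted; only
if both are missing, EC50. The first *present* measurement must be
< 100 nM — a present-but-failing IC50 excludes a record even when a potent
Kd sits behind it. The synthetic fixture generator
(`generate_synthetic_pairs()`) deliberately emits such masked-Kd records so
tests distinguish the two readings, and an independent brute-force
restatement of the rule cross-checks the vectorised implementation on
random records.

`split_train_test()` makes an exact, seeded `round(n * frac)` partition
(published fraction 0.7).

## Evaluation

`compute_metrics()` follows distribution-learning conventions: validity =
valid/generated; uniqueness = distinct-canonical/valid; novelty =
distinct-not-in-training/distinct; mean QED over valid molecules. The
training set passed for novelty is expected to be canonical SMILES (the
dataset pipeline canonicalizes on pairing).

## Scale and reproducibility

At full scale the approach is trained on BindingDB-sized corpora; uniqueness,
novelty and mean QED depend on that scale and are therefore *reported, not
asserted* at desk scale. What is asserted, because the mechanism (validity
gate + RO5/QED rewards) guarantees it at any scale: the MCTS set is 100%
valid, and every generated molecule respects logP ≤ 5 and MW ≤ 500 Da.
A trained toy prior collapses toward very small molecules — expected
behaviour for a 2-layer model on a 30-template corpus, and the reason the
distributional metrics are left unasserted.

Reproducibility conventions: every stochastic step takes an explicit seed;
one global seed fans out into independent substreams (split / training /
per-molecule search) via an affine derivation, so increasing the number of
generated molecules never reshuffles earlier draws.

## Chemistry backend

Parsing, canonicalization, descriptors and QED are delegated to a
persistent RDKit worker (Python) speaking JSON-lines over named pipes, with
R-side memoisation; this keeps chemical ground truth identical to the
reference toolkit instead of reimplementing cheminformatics in R. Only the
SMILES *tokenizer* is native R, because the token alphabet — not molecule
semantics — is what the language model consumes.
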