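---
title: "Predicting RNA secondary structure from pairwise score maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA secondary structure from pairwise score maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairfold)
```

## The problem and the model

A folded RNA strand pairs bases with each other: Watson–Crick A·U and
G·C plus the G·U wobble pair, six ordered combinations in total. A
*secondary structure* for a sequence $q = (q_1, \dots, q_L)$ is a set of
index pairs $(i, j)$ such that every base has at most one partner and
$|i - j| \ge 3$. Structures whose pairs nest like balanced parentheses
are the easy case; *pseudoknots* — two pairs $(i, j)$, $(k, l)$ with
$i < k < j < l$ — break the nesting and make energy-minimization by
dynamic programming intractable in general.

`pairfold` takes a purely data-driven approach. Instead of feeding the
sequence to the network one base at a time, it encodes all *pairwise
relations* up front as an $L \times L \times 8$ one-hot tensor: six
channels mark which of the canonical pair classes the bases at $(i, j)$
could form, one channel marks the diagonal $i = j$ (where the "unpaired"
state lives), and one channel marks cells where pairing is impossible —
a non-canonical combination or a distance below the minimum. In this
representation both local and long-range pairings are visible to a
convolutional network as nearby texture: a stem (a run of consecutive
pairs) is an anti-diagonal line in the matrix.

The target is the binary matrix $T$ with $t_{ij} = t_{ji} = 1$ for every
pair and $t_{ii} = 1$ for every unpaired base, so every row sums to one.

The score network is fully convolutional: two conv blocks, then $M$
residual blocks with distinct weights, then a *single* residual block
applied $N$ times with shared weights, like a recurrent model. After
every shared pass a shared readout (a $1 \times 1$ conv block followed
by a $1 \times 1$ convolution with one output channel) emits a score
matrix $Y_n$. Every conv block is convolution + batch normalization +
LeakyReLU with 32 channels and padding that preserves the spatial size.
The loss is the masked mean-squared error
$$ l = \frac{1}{N}\sum_{n=1}^N \frac{1}{|V|} \sum_{(i,j) \in V}
   \bigl(y^{(n)}_{ij} - t_{ij}\bigr)^2, $$
where $V$ is the set of valid cells — everything except the
impossible-pairing channel. Attaching the loss to *every* shared pass
pushes the network to reach a good answer in as few iterations as
possible.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `M` | 2 | distinct residual blocks (10 in the `"short-big"` preset) |
| `N` | 2 | shared-block iterations, each with a readout and a loss term |
| `channels` | 32 | feature width of every conv block |
| `kernel` | 3 | spatial kernel of the non-readout convolutions |
| `leaky_slope` | 0.01 | LeakyReLU negative slope |
| `learning_rate` | 0.005 | Adam step size |
| `max_batch` | 16 | mini-batch cap; sequences over 1000 nt train alone |
| `k` (decoding) | 3 | per-row candidate cap for the blossom graph |

Three training presets are provided:
`variant_preset("full")` (M = 2, 30 epochs, all lengths),
`variant_preset("short")` (M = 2, 400 epochs, < 600 nt) and
`variant_preset("short-big")` (M = 10, 45 epochs, < 600 nt); the
two-model ensemble dispatches sequences of at most 600 nt to the
short-sequence model (`mix_predict()`, threshold inclusive).

Design points the architecture description leaves open, fixed here and
documented so they are falsifiable:

* **Kernel size** is not stated for the main conv blocks; we default to
  $3 \times 3$, the standard residual-network choice, and expose it in
  `model_config()`.
* **Residual block internals**: two conv blocks plus an identity skip,
  with the addition before the final activation.
* **One readout, one statistic set**: the readout weights and its
  batch-norm statistics are shared across all $N$ passes; the loss is
  attached to the shared passes (matching the $l = \frac1N \sum l_n$
  formula), not to the $M$ distinct blocks.
* **The diagonal belongs to $V$**: $t_{ii}$ carries the unpaired signal,
  so the network must be able to learn it; only impossible-pairing cells
  are excluded from the loss.
* **Distance dominates canonicity**: a canonical combination closer than
  the minimum pairing distance is still an impossible cell.
* No output symmetrization inside the network; symmetry is handled at
  decoding time, since argmax decoding explicitly tolerates asymmetry.

## Decoding

**Argmax** (the default): base $i$ is connected to the column with the
largest score in row $i$ over $V$ plus the diagonal; a diagonal winner
means unpaired; ties break to the lowest column index for determinism.
This is $O(L^2)$ but can produce conflicting choices; conflicts are
*reported* as violations, never silently repaired.

**Blossom**: the score matrix is symmetrized ($\tfrac12(Y + Y^\top)$ —
the matching needs one weight per undirected edge), pruned to the $k$
best valid candidates per row (an edge survives if either endpoint kept
it), and decoded by maximum-weight matching. Because off-the-shelf
matching has no self-loops, the graph is duplicated: nodes $u_i$ and
$v_i$, pair edges in both copies with weight $y_{ij}$, and a rung
$(u_i, v_i)$ with weight $2 y_{ii}$ representing "unpaired". Pairs are
read from the $u$ copy only, which is authoritative when a tie-broken
matcher splits the copies inconsistently. The output is always a valid
structure.

The matcher itself is an exact $O(n^3)$ primal–dual Blossom
implementation over integer weights. Two numerical choices matter:

* **Shift before matching.** The decoding objective is
  $\sum_{\text{pairs}} 2 y_{ij} + \sum_{\text{unpaired}} 2 y_{ii}$.
  With negative scores, maximum-weight matching would simply drop
  negative edges, which optimizes a *different* objective. We instead
  shift pair scores by $2c$ and diagonal scores by $c$ with $c$ chosen
  to make everything non-negative; every candidate structure's objective
  moves by the same constant $2cL$, so the optimum is preserved exactly
  and the matcher maximizes the stated objective for any sign pattern.
* **Integer scaling.** Shifted weights are scaled by $2^{42}/\max|w|$
  and rounded to 64-bit integers, so all dual updates inside the
  matching are exact and no floating-point tolerance is needed; the
  quantization error is orders of magnitude below score differences that
  occur in practice.

Degenerate inputs (nothing scores) decode to the all-unpaired structure.

## Training mechanics

Mini-batches pad every sample to the batch maximum length; padded cells
carry the impossible-pairing channel, their targets are zero and they
are excluded from every sample's mask, so they contribute exactly zero
loss and zero gradient through the loss (they do enter batch-norm
statistics, as with any rectangular-tensor framework). Records longer
than `solo_length_threshold` (1000 nt) always train alone. Optimization
is plain Adam at learning rate 0.005 with no schedule, weight decay or
gradient clipping (all exposed in `train_config()`); runs are fully
seeded and reproducible on a fixed BLAS. Gradients are analytic and are
checked against finite differences in the test suite.

`train_config(eval_every =, stop_f1 =)` optionally monitors the mean
training-set F1 (argmax decoding) and stops once a target is reached;
validation-split early stopping is deliberately off by default, since
the standard regimes train for fixed epoch counts.

## What the synthetic generator emulates

`sample_structure()` builds a nested skeleton by placing stems (3–8
consecutive pairs by default) into available unpaired intervals,
recursively splitting each interval into the regions before, inside and
after the stem; with probability `pseudoknot_prob` (default 0.3) one
extra stem runs from inside a stem's loop to a region outside it, which
necessarily crosses the enclosing stem. Rejection sampling enforces the
single-partner and minimum-distance rules, so every generated record
validates cleanly. `sample_sequence()` assigns each pair one of the six
canonical classes uniformly and fills unpaired positions uniformly.

This emulates the *combinatorial* shape of curated RNA structure
corpora — stems, loops, multiloops, crossing stems — but none of their
biology: no thermodynamic plausibility, no family-specific topologies
(tRNA cloverleafs, rRNA domains), no sequence composition bias, no
non-canonical pairs, and pair classes are uniform rather than GC-rich.
Tests passing on this generator therefore demonstrate that the
machinery is correct (encodings, losses, decoders, training dynamics),
not that the model generalizes to real families; benchmark-grade
results require curated external corpora and GPU-scale training, which
are outside this package's scope.

Problem sizes used by the shipped test suite and acceptance script were
chosen to exercise every component at realistic scale on a single CPU:
matching oracles on hundreds of exhaustive instances ($L \le 10$),
decoder validity on hundreds of random matrices up to $L = 200$, and a
memorization run — 20 records of 30–60 nt, M = 2, N = 2, 32 channels —
that reaches mean training F1 at least 0.95 within 500 Adam steps.

## Known limitations

* Training throughput is single-CPU: memorizing 20 short records takes
  a few minutes; full-corpus regimes (tens of thousands of records,
  hundreds of epochs) are out of reach without GPU hardware.
* The blossom decoder's cubic cost grows noticeable beyond ~1000 nt;
  argmax remains $O(L^2)$.
* Ambiguity codes are rejected by default; the opt-in `"block"` policy
  keeps them unpairable rather than guessing a base.
* Multi-structure CT files contribute only their first structure (with
  a warning); reference selection among alternative structures is the
  caller's responsibility (a seeded selector is trivial to write with
  `make_dataset()`-style code).
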