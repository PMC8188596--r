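---
title: "Methods: batched Bayesian optimization for virtual screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: batched Bayesian optimization for virtual screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`screenbo` prioritizes compounds in a retrospective virtual screen by
active learning over a finite molecular pool. This vignette documents the
model, the numerical choices, and the limits of what the package's own
synthetic benchmarks can demonstrate.

## The optimization problem

A virtual screening campaign evaluates an expensive black-box objective
$f$ — here, the negative docking score, so larger is always better — on
members of a finite library $\mathcal{X}$. We seek most of the top-$k$
members of $\mathcal{X}$ while evaluating as small a fraction of it as
possible. The loop:

1. Evaluate $n$ molecules drawn uniformly at random; store
   $\mathcal{D} = \{(x_i, f(x_i))\}$.
2. Train a surrogate $\hat f$ on $\mathcal{D}$; predict a mean
   $\hat\mu(x)$ and (architecture permitting) a variance
   $\hat\sigma^2(x)$ for *every* pool member.
3. Score untested members with an acquisition utility
   $\alpha(x; \hat f, f^*)$, where $f^*$ is the best *observed* objective
   value, and evaluate the $b$ highest-utility candidates.
4. Repeat until a fixed number of iterations is exhausted or the top-$k$
   trajectory converges.

Evaluation is replayed from a lookup table keyed by canonical SMILES, so
molecules generated by different tools match by identity. Library members
with no recorded score (ligands that failed to dock) may still be selected
— they consume acquisition budget — but contribute nothing to surrogate
training or to retrieval metrics. Negation of minimized raw scores happens
exactly once, at evaluation; every other component works in the
maximization convention, which avoids a whole class of sign errors in
acquisition and metric code.

## Acquisition utilities

With $\sigma = \sqrt{\hat\sigma^2(x)}$,
$\gamma = \hat\mu(x) - (f^* + \xi)$ and $z = \gamma / \sigma$:

| metric | utility |
|---|---|
| greedy | $\hat\mu(x)$ |
| UCB | $\hat\mu(x) + \beta\sigma$ |
| TS | one draw from $\mathcal{N}(\hat\mu, \hat\sigma^2)$, independent per candidate |
| EI | $\gamma\,\Phi(z) + \sigma\,\phi(z)$; at $\sigma = 0$, $\max(\gamma, 0)$ |
| PI | $\Phi(z)$; at $\sigma = 0$, $\mathbf{1}[\gamma > 0]$ |
| random | a uniform draw, ignoring predictions (the baseline) |

Defaults $\beta = 2$ and $\xi = 0.01$. Two conventions deserve note:

* **Sign of $\xi$.** Improvement-based utilities are implemented against
  the threshold $f^* + \xi$, so a positive $\xi$ demands improvement
  *beyond* the incumbent and mildly favors exploration. The opposite sign
  convention exists in the literature; $\xi$ is accepted as a signed value,
  and at the default magnitude the difference is negligible on
  docking-score scales.
* **$\sigma = 0$ limits.** EI and PI are defined at zero variance by their
  continuous limits (above) rather than left undefined; an exact surrogate
  therefore ranks identically under greedy, UCB, TS, and EI.

Batch selection takes the exact top-$b$ untested candidates by utility.
Ties at the batch boundary are resolved uniformly at random from the run's
seeded RNG: score tables quantized to 0.1 (typical of docking pipelines)
make boundary ties common, and an arbitrary-but-deterministic rule would
bias which molecules are ever explored.

## Surrogate models

All surrogates are, by default, retrained from scratch at the start of each
iteration on *all* scored acquisitions; online updating (continue training
on the newest batch only) is available but opt-in, as full retraining is
the more reliable setting. Targets are used unstandardized by the forest;
the neural models standardize targets to zero mean and unit variance on the
current training set (and invert the transform at prediction), which keeps
the prescribed fixed learning rates usable as the score scale varies.

**Random forest** (`rf`): 100 trees with depth capped at 8, fit on the
2048-bit fingerprint via `ranger`. The predictive variance is the
population variance of the per-tree predictions — the standard ensemble
estimator. The depth cap makes the forest a deliberately coarse, fast
regressor; its held-out rank correlation saturates well below 1 at small
training sizes, improving as data accrue.

**Feedforward network** (`nn`): two hidden layers of 100 ReLU units on the
fingerprint, dropout $p = 0.2$ after each hidden layer, Adam at learning
rate 0.01, mean-squared-error loss with an L2 penalty of 0.01, batch size
4096 (in practice full-batch at early-campaign training sizes), up to 50
epochs with early stopping (patience 5) on a random 20% validation split,
re-split and re-seeded at every retraining. Predictive uncertainty is
Monte-Carlo dropout: 10 stochastic forward passes with inverted dropout;
the mean and variance across passes form $\hat\mu$ and $\hat\sigma^2$. With
$p = 0$ the passes coincide and the variance is exactly zero. The network
is implemented in base-R matrix code with hand-written backpropagation (no
deep-learning runtime is required), and the gradients are verified against
central finite differences in the test suite.

**Directed message passing network** (`mpn`): messages live on directed
bonds; a bond's hidden state (300 units) is updated from the incoming
messages at its source atom excluding its own reverse bond, for 3
iterations, then aggregated per atom, transformed, and summed into a
molecule vector feeding a one-hidden-layer head. Atom features are one-hot
element, heavy-atom degree, and π-electron count on the
hydrogen-suppressed, kekulized graph; bond features are the bond order.
Atom indexing follows the canonical-SMILES order produced at parsing.
Training uses Adam under a warmup–decay schedule (10⁻⁴ → 10⁻³ over two
epochs, then exponential decay to 10⁻⁴), RMSE loss, batch size 50, up to 50
epochs, patience 10. When variances are required the head has two outputs
(mean and a softplus-positive variance) and training minimizes the Gaussian
negative log likelihood

$$\mathcal{L} = \tfrac{1}{2}\log(2\pi\hat\sigma^2) +
  \frac{(y - \hat\mu)^2}{2\hat\sigma^2},$$

averaged over the batch (`mve_loss`). This backpropagation is also
hand-derived and finite-difference-checked. A practical note: at
early-campaign training sizes (tens to hundreds of molecules) the schedule
above is conservative and the graph model underfits relative to the
fingerprint models; it is the right tool when batches reach thousands of
molecules. The learning-dynamics tests therefore verify that training
reduces error and produces positive variances at small scale rather than
asserting strong recovery there.

If the training targets contain fewer than two distinct values, the
validation split is meaningless; the neural models fall back to
fixed-epoch training with a warning. Setting `val_frac = 0` disables the
split explicitly.

## Molecular representation

The fingerprint is a 2048-bit hashed atom-pair vector: every unordered
pair of heavy atoms at topological distance 1–3 bonds contributes a
(type, type, distance) feature, with atom type = (element, heavy-atom
degree, π-electron count). Features are hashed to a bit index by a fixed
integer mixing function; presence/absence only. Two reading choices are
documented rather than silent: the distance window is interpreted as
*path lengths* 1–3 (the natural parameterization of atom pairs), and
graphs are hydrogen-suppressed (the standard choice; the alternative —
explicit hydrogens — would mostly add constant bits per heavy atom).
Fingerprints are computed once at pool load and cached; an optional
on-disk cache keyed by input-file checksums supports repeated runs over
large pools, since full-pool inference every iteration is the dominant
fixed cost.

SMILES are canonicalized with OpenBabel at load; duplicates (by canonical
string) are dropped with a count, and syntactically malformed strings are
rejected by a prefilter before OpenBabel parsing, because OpenBabel
silently repairs some malformed inputs (e.g. unbalanced parentheses) that
should be treated as data errors.

## Stopping

Besides a fixed iteration budget, `stopping = "converged"` ends the run
when the fractional difference between the current top-$k$ average and the
rolling mean of the previous `convergence_window = 3` iterations' averages
drops below `convergence_threshold = 0.01`. The comparison uses the
absolute difference by default; a signed variant (`signed_convergence`)
treats any non-improvement as converged. Convergence is only assessed once
three prior iterations exist, and a rolling mean of exactly zero falls back
to an absolute comparison to avoid dividing by zero on degenerate scales.

## Retrieval metrics

Against a full ground-truth table: (1) the **average ratio** — mean of the
best $k$ found scores over the mean of the true top-$k$ (sign preserved;
identical in raw and negated domains); (2) the **SMILES fraction** — set
intersection of found and true top-$k$ molecules over $k$; (3) the
**scores fraction** — *multiset* intersection of the two $k$-length score
lists over $k$, the tie-robust variant: molecules with equal scores are
interchangeable, so coarse score grids do not punish the search for
returning a different-but-equal molecule. Score comparison is exact on the
parsed values (tables carry fixed printed precision), and the true top-$k$
under ties at rank $k$ is fixed by a stable sort on (score, canonical
SMILES), making every metric reproducible. The **enrichment factor** is
the ratio of a strategy's scores fraction to the random baseline's at equal
budget; the baseline is produced by the `random` metric inside the same
loop (identical budget accounting, including failed evaluations), averaged
over a configurable number of seeds.

## The synthetic landscape

`generate_pool()` builds pools of valid, unique, chemically plausible
molecules — branched C/N/O/S chains without adjacent heteroatoms, sampled
from a seeded grammar and canonicalized — and assigns raw scores
$-(w \cdot \mathrm{fp}(x)) + \varepsilon$, with $w$ standard normal per
bit, optional quadratic curvature, optional quantization to a coarse grid,
optional withheld scores (failed-dock emulation), and
$\varepsilon \sim \mathcal{N}(0, \sigma_n^2)$. `noise_relative = TRUE`
expresses $\sigma_n$ as a fraction of the realized signal sd, which is how
the benchmark pins noise at 10% of signal. Because the score is a smooth
function of the exact representation the fingerprint models consume, the
landscape is learnable *by construction*. That is the point — it isolates
the acquisition machinery — but it also bounds what passing benchmarks
prove: real docking surfaces are rougher, their scores are not linear in
any fingerprint, and graph models see no representational advantage here.
Synthetic enrichment factors therefore validate the machinery, not predict
field performance.

Default benchmark conditions (used by `scripts/acceptance.R` and the
acceptance tests): 5000 molecules, linear landscape, noise at 10% of
signal sd, greedy random forest, 1% initialization plus five 1% batches
(a 6% budget), $k = 50$, five seeds per strategy. These sizes keep a full
benchmark around a minute on a single core while leaving the random
baseline's expected recovery (≈ 6%) well separated from the guided
search's.

## Numerical and design notes

* **Fraction → count.** Fractional batch sizes convert with a ceiling
  (minimum one molecule): 1% of 10,560 → 106; 1% of 50,240 → 503; 1% of
  2,141,514 → 21,416. Ceiling is the only rounding rule consistent with
  all of those published batch counts simultaneously.
* **Determinism.** Every stochastic step (initialization, tie-breaks,
  Thompson/random draws, model training, landscape generation) derives
  from explicit seeds; fixed-seed runs produce byte-identical reports.
  Forest training is single-threaded for this reason.
* **Incumbent.** $f^*$ is the maximum *observed* objective value, never a
  model prediction.
* **Degenerate inputs.** Single-heavy-atom molecules have no atom pairs
  and map to the all-zero fingerprint; empty pools and unmatchable columns
  are fatal at load; a batch request exceeding the untested remainder is
  truncated with a warning on the final iteration.
* **Known limitations.** No batch-diversity construction (batches are
  pure top-$b$); no hyperparameter search; Thompson sampling draws
  independently per candidate; the MPN is CPU-bound in interpreted matrix
  code and intended for modest pools; the synthetic grammar covers a
  narrow slice of chemistry by design.
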