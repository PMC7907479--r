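---
title: "Latent entropy and latent dimension: model, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent entropy and latent dimension: model, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentmap)
```

## The model

Each pixel of a time-resolved image stack is treated as a categorical
process `X(t)` on `n` intensity categories (the discretized color scale).
The only structural assumption is that consecutive frames are linked by a
time-homogeneous transition law, possibly routed through a *latent*
categorical variable `L_K` with `K ≤ n` states:

$$\Lambda_K = \lambda_K \gamma_K, \qquad
(\lambda_K)_{jk} = P[X(t{+}1) = x_j \mid L_K = l_k], \quad
(\gamma_K)_{ki} = P[L_K = l_k \mid X(t) = x_i].$$

No Gaussianity, no i.i.d. assumption, and no parametric emission model are
imposed; the data enter only through the average contingency table
`C[j, i]`, the relative frequency of transition `x_i → x_j` among the `N`
observed pairs. `N` always counts *transition pairs* (`T − 1` for a
`T`-frame trace): that is the number the contingency table normalizes over,
and the likelihood term below needs the two to agree.

For each `K` the factorization is fitted by **direct Bayesian model
reduction**: `γ_K` is a hard (0/1) assignment of observed categories to
latent states, and for a fixed assignment the optimal emissions have a
closed form — the count-weighted average of the empirical conditional
columns pooled into each state. The quality of a fit is its cross-entropy

$$S_K = -\sum_{ij} C_{ij} \log (\lambda_K \gamma_K)_{ij} \quad (\text{nats}),$$

with the convention $0 \log 0 = 0$; `S_K` is `+Inf` only if an observed
transition gets zero model probability, which the closed-form emissions
never produce. `S_n` is the empirical conditional cross-entropy, `S_1` the
entropy of the final-state marginal, and `S_K` is nonincreasing in `K`.
Since each latent state contributes its own emission entropy weighted by
its mass, `S_K ≤ log n` always.

Candidate dimensions are then compared by a corrected Akaike score and
model-averaged:

$$\mathrm{AICc}_K = N S_K + V_K + \frac{V_K (V_K + 1)}{N - V_K - 1},
\qquad V_K = (n-1)K + n(K-1),$$
$$p_K \propto \exp\!\big(-(\mathrm{AICc}_K - \min_K \mathrm{AICc}_K)\big),
\qquad \bar S = \sum_K p_K S_K, \qquad \bar K = \sum_K p_K K.$$

Two conventions here are deliberate and worth flagging. First, `V_K` counts
`n(K−1)` parameters for `γ_K` as if it were stochastic, although the fitted
`γ_K` is deterministic; the parameter count is used exactly as written
above rather than "corrected", because the weighting scheme is defined by
that formula. Second, the weights use the exponent `−ΔAICc` without the
conventional factor ½ of Akaike weights (and the likelihood term enters as
`N·S_K`, not `2N·S_K`); again the formulas are applied as written. Both
choices change only how sharply the weights concentrate, not the ordering
of models. Entropies are in natural log throughout so that `N·S_K` is the
(negative) log-likelihood of the data under the fitted law.

## Fitting: search, ties, degenerate inputs

Hard-assignment reduction is a combinatorial problem (set partitions of the
categories). The fitter uses alternating reassignment sweeps: each category
column in turn is moved to the latent state that minimizes the resulting
cross-entropy, with emissions re-derived per candidate move; when no single
move helps, pairwise state exchanges of two columns are tried; the descent
stops when neither helps. Evaluating moves by the exact post-move entropy
(rather than against frozen emissions) costs nothing at these alphabet
sizes and removes almost all local minima of the plain sweep. The search
runs from 10 starting points — one contiguous-blocks split (categories are
ordered intensities, so contiguous groupings are natural) plus nine seeded
random assignments — and keeps the best. The restart RNG is local and
fixed, so fits are bit-reproducible and never disturb the caller's RNG
stream. Ties between equally good states resolve to the lowest state
index. `exhaustive_reduced_model()` enumerates *all* partitions (feasible
for `n ≤ 10`) and serves as the optimality oracle in the tests; on random
tables with `n = 4..6` the heuristic matches it exactly.

Degenerate inputs degrade gracefully rather than erroring:

- a constant trace yields a single-category alphabet and exactly
  `S̄ = 0, K̄ = 1`;
- categories never observed at a pixel (empty row *and* column of `C`) are
  dropped before fitting (`n_effective ≤ n_bins`), since empty categories
  would make emission columns undefined and inflate `V_K`;
- a `K` exceeding the number of categories observed as *initial* states
  cannot keep all states distinct; such dimensions would merely duplicate
  the largest attainable model, so they receive zero posterior weight
  instead of being double-counted;
- a `K` with `V_K + 1 ≥ N` has an undefined finite-sample correction; its
  AICc is `+Inf` and its weight zero, so very short series fall back on
  small-`K` models;
- pixels with `N ≤ n_effective²` are computed but flagged
  (`size_warning`), since the contingency table is then sparse relative to
  its cells.

## Discretization

The default is 8 uniform-width bins spanning the global minimum–maximum of
the whole stack — one shared alphabet for all pixels, so entropies are
comparable across the image. Values exactly at the upper edge fall in the
last bin. A stack that is already integer-valued with at most `n_bins`
distinct values keeps its values as categories (no empty bins). The bin
count and the reference range are both configurable; passing the full-run
range to a sub-rectangle run reproduces the full run's values exactly,
because pixels are computed independently. With few bins the method is most
robust but coarse; with many bins `n_effective` (and the O(n⁴) per-pixel
cost) grows and the `N > n²` condition bites sooner. Patch pooling
(`patch = b`) concatenates the transition pairs of the `b × b` member
pixels into one sample — a coarser observable with `b²(T−1)` pairs —
rather than averaging member measures, so the sample-size scaling stays
transparent; every member pixel receives the pooled values.

## The falling-toast model

The two-parameter two-state family
`Λ = [[0.5−U_s+U_h, 0.5−U_s−U_h], [0.5+U_s−U_h, 0.5+U_s+U_h]]`
(state 1 = butter up) spans, inside the feasibility square
`|U_s| + |U_h| ≤ 0.5`, the three interpretable corners: the fair coin
(`U_s = U_h = 0`: no memory, maximal entropy), the identity
(`U_h = 0.5`: maximal memory), and the deterministic butter-down outcome
(`U_s = 0.5`: no memory, zero entropy). `sample_toast()` draws independent
experiments with a uniform initial side — the natural choice for the
Bernoulli framing, and at the corners the conditional columns make the
initial law irrelevant. `sweep_toast()` maps the square; runs default to
10,000 experiments per point because the measures at the corners are
noticeably noisy at 100 experiments.

A known statistical property of the memoryless corners deserves emphasis.
At `U_s = U_h = 0` the complexity gap between the `K = 2` and `K = 1`
models is `ΔAICc ≈ 3.0` at `N = 10{,}000`, so the two-state model always
retains posterior weight at least `e^{-3}/(1 + e^{-3}) ≈ 0.047`: `K̄` has a
deterministic floor of about 1.047, plus a fluctuation term driven by the
empirical mutual information of the table (`N·Î ~ χ²₁/2`, which does not
shrink with `N`). Typical values are `K̄ ≈ 1.05–1.15` rather than exactly
1 — visible in the acceptance runs — and the same floor of 1.047 appears
exactly in the deterministic `U_s = 0.5` corner. This is a property of the
as-written weighting, not an implementation artifact.

## The synthetic generator

No imaging dataset ships with the package; `synthetic_spec()` /
`generate_stack()` produce stacks whose ground truth is known by
construction. Each pixel evolves as an independent Markov chain under its
local transition matrix — a masked region with distinct dynamics (the
`"capillary"` preset: a branching random-walk skeleton dilated to width 2,
three branches, walk length `1.2·max(H, W)`, new branches sprouting from
the existing skeleton; mask fractions land in the 2–40% range), a linear
ramp of one parameter across columns (the `"gradient"` preset,
`U_s: 0 → 0.45`), or homogeneous dynamics (`"uniform"`). Chains start from
their local stationary distribution to avoid burn-in transients. States
emit integer intensity levels (`0, 1, …`) plus Gaussian observation noise;
the default `noise_sd = 0.1` keeps levels separated by ten noise SDs so
discretization recovers states reliably, and raising it probes robustness.
Everything is reproducible bit-for-bit from the seed.

What the generator does *not* emulate: spatially correlated noise, optical
point-spread functions, photobleaching and drift, motion, and
video-compression artifacts. Passing the recovery tests therefore shows
that the measures extract transition structure from noisy categorical
dynamics — not that any particular microscope's artifacts are harmless.

The recovery experiments run at 64×64 pixels and `T = 2000` frames with
2 intensity bins (and 10,000 experiments per toast configuration), sizes
at which the maps are statistically stable while a full run stays in the
tens of seconds on a single core; results at larger sizes only sharpen,
since pixels are independent and per-pixel errors shrink with `T`.

## Output formats

`write_maps()` writes each map as CSV (full double precision, `H` rows,
0-based column headers) and as a single-page 32-bit float TIFF. The float
TIFF is produced by a minimal built-in emitter (little-endian,
uncompressed, single strip, IEEE-float sample format) because the R `tiff`
package writes only integer sample formats, which would quantize the maps;
`tiff::readTIFF()`, ImageJ and Python's tifffile read the files, and a
write–read cycle is exact at 32-bit float precision. A JSON manifest
records the run parameters.

## Limitations

- The measures detect *that* transition dynamics differ, not *why*;
  attribution (flow, temperature, pinning, …) needs domain follow-up.
- Hard-assignment reduction is the operative definition here; soft
  (probabilistic) affiliations and regularized variants are out of scope.
- `K̄` is biased upward near memoryless dynamics (the weight floor above),
  so small `K̄` contrasts close to 1 should be read comparatively, not as
  exact dimension estimates.
- Per-pixel independence ignores spatial correlation; patch pooling is the
  only built-in spatial coupling.
- Multichannel data must be reduced to one scalar per pixel beforehand;
  registration/motion correction is assumed done.
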