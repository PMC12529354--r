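---
title: "Closed-loop buffer optimization for cell-free protein synthesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop buffer optimization for cell-free protein synthesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfpsopt)
```

## The problem

Cell-free protein synthesis (CFPS) runs transcription and translation in a
cell lysate supplemented with a defined buffer: energy source, amino acids,
magnesium and potassium salts, NTPs, crowding agents, template DNA, and so
on. Protein yield depends strongly — and non-additively — on the buffer
composition, and the response surface differs between lysate batches and
between target proteins, so recipes are re-optimized in practice. With nine
variable components at six concentration levels the discrete search space
already holds $6^9 \approx 10^7$ recipes; exhaustive screening is out of
the question, and so is manual pipetting at the nanoliter volumes an
acoustic dispenser works with.

`cfpsopt` implements the computational side of a Design–Build–Test–Learn
(DBTL) loop for this problem on a 384-well acoustic liquid-handling
platform:

* **Design** — discrete Latin-hypercube sampling (LHS) over
  dispenser-legal volume grids (`lhs_sample()`), destination/source plate
  layout (`assign_destination_wells()`, `design_source_plate()`), and
  transfer-list generation (`generate_instructions()`).
* **Test** — plate-reader import, cross-plate calibration and fold-change
  yield computation (`parse_reader_matrix()`, `calibrate_plates()`,
  `compute_yields()`).
* **Learn** — a Gaussian-process surrogate with Expected-Improvement
  acquisition and either top-$n$ ("vanilla", VAL) or Cluster-Margin (CM)
  batch selection (`fit_surrogate()`, `expected_improvement()`,
  `propose_batch()`).
* **Build** — in place of a wet lab, a virtual laboratory
  (`landscape_config()`, `run_virtual_experiment()`) that simulates reader
  output over a known yield landscape, so the closed loop can be run and
  benchmarked entirely at the desk (`closed_loop_benchmark()`).

## Discrete volume grids and the design space

All volumes are handled in nanoliters. An acoustic dispenser places
droplets of fixed granularity (2.5 nL by default) and can only transfer
volumes in a window (20–1000 nL by default); `dispenser_constraints()`
bundles these limits. A component's allowed volumes are built either from
a ratio list (e.g. `0, 0.2, ..., 1` of the maximum volume, giving six
concentration levels) or from a fixed increment (e.g. every 20 nL up to the
maximum; zero is excluded in this mode, which is what makes the
four-component step-20 space of maxima 940/200/380/480 nL come out at
$47 \times 10 \times 19 \times 24 = 214{,}320$ recipes). Ratio grids are
snapped to the nearest granularity multiple — the instrument cannot place
anything else, and rejecting instead of snapping would make most ratio
lists unusable; snapping is a deliberate package choice, since either
convention is defensible. Any non-zero level below the minimum dispense is
an error: such a design cannot be built, and the error lists the offending
levels so the user can raise the maximum volume or coarsen the grid.

## Discrete Latin-hypercube sampling

Loop 0 needs a space-filling design: a uniform random draw of ~100 recipes
from $10^7$ leaves large holes and near-duplicates. For each variable
component with $L$ levels we cut $[0,1)$ into $n$ equal strata, map each
stratum through its **midpoint** to a level index
$\lfloor (i + 0.5)\,L/n \rfloor$, and shuffle the strata with an
independent seeded permutation per component. The midpoint mapping is what
guarantees the marginal property exactly: every level occurs either
$\lfloor n/L \rfloor$ or $\lceil n/L \rceil$ times. (Drawing a uniform
point inside each stratum — the textbook continuous-LHS recipe — loses
this guarantee on a discrete grid: a stratum that straddles a level
boundary can tip either way, and marginal counts can then deviate by more
than one.) If the discretized design contains duplicate rows it is redrawn
from a derived seed a bounded number of times, then accepted with a
warning — on very small grids duplicates are unavoidable.

## Plates, dead volume, and transfer lists

Compositions are laid out row-major from A1 with replicates in adjacent
wells (replicates are blocked, not interleaved: a deterministic layout
makes instruction files byte-reproducible, and blocked replicates are
easier to eyeball on a plate map). Each well is topped up with water to the
exact reaction volume (6,500 nL in the bacterial system, 2,000 nL in the
HeLa system); water is an ordinary acoustically dispensed component.

Source wells hold a *dead volume* (20,000 nL by default) the dispenser
cannot draw. Demand above one well's usable volume rolls over into further
wells. Transfers above the split threshold are emitted as greedy
maximum-size chunks; a remainder below the minimum dispense is avoided by
rebalancing the last two chunks into a near-equal granularity-aligned pair
(2,500 → 1000+1000+500; 1,010 → 505+505). A transfer is never split across
source wells. That last rule interacts with exact-fit source planning:
when a well's residue is smaller than the next whole transfer the
instructor abandons it, so exactly-sized fills can come up short by less
than one transfer per well. `design_source_plate(overage=)` therefore adds
a configurable slack per allocated well — one maximum transfer (1,000 nL)
guarantees replay — which is also what a lab does when it overfills source
wells. The default remains 0 so that the planned dispensable volume equals
demand exactly (the conservation property tested in the suite); the
workflows pass 1,000 nL.

## Calibration and yields

CFPS signal levels drift between plates (lysate aging, reader gain,
evaporation), so each plate carries wells of shared calibration buffers
plus the standard buffer. Calibration here is a single multiplicative
factor per plate: $s_p = \bar r_{\mathrm{ref}} / \bar r_p$ over the shared
calibration compositions, with $s_{\mathrm{ref}} = 1$. A gain-only model
is the minimal contract that matches the multiplicative per-plate gain the
virtual lab simulates; an affine or regression-based scheme could be
substituted behind `calibrate_plates()` without touching anything else.
Yields are fold-changes versus the standard buffer (yield 1 by
definition). In the closed loop the yield denominator is pinned to the
standard's wells on the reference plate, so yields of already-measured
samples do not drift as new plates arrive — this is what makes the
best-so-far trace monotone by construction. An optional No-DNA blank
subtraction and an optional (off by default) MAD replicate filter are
provided; replicates are otherwise kept as measured.

## The surrogate and batch selection

Compositions are normalized to volume fractions $v_i / V_{\max,i} \in
[0,1]$ (fixed components are dropped). The surrogate is GP regression with
a Matérn 5/2 kernel, one lengthscale per component (automatic relevance),
plus a white-noise term; responses are standardized internally and
hyperparameters maximize the marginal likelihood from a fixed, seeded set
of restarts, so a fit is reproducible. The predictive standard deviation
reported includes the fitted noise, so it is the uncertainty of a new
*measurement* — at a training point it approaches the noise floor, far
from data the prior scale.

Candidates are scored by Expected Improvement over the incumbent best,
with exploration offset `xi = 0.01` by default (EI is standard for
yield maximization; the offset mildly discourages re-sampling the
incumbent's neighborhood). The pool is a fresh uniform draw of ≥1000
unique untested grid compositions per loop; when the remaining space is
smaller than the pool, the whole remainder is enumerated.

Two batch rules are provided. **VAL** takes the top-$n$ by EI. **CM**
balances EI with diversity: keep the `m_top` highest-EI candidates,
cluster the pool by average-linkage HAC, bucket the kept candidates by
cluster, order non-empty buckets smallest-first, and round-robin over them
taking each bucket's best unselected candidate until `n_batch` points are
chosen. Two choices here were genuinely open and are configurable:
bucket sizes are counted over the `m_top` candidates by default (the
alternative — pool-level sizes — via `bucket_sizes = "pool"`), and the
cluster count defaults to `k = 2 * n_batch`, which keeps buckets
meaningful relative to the batch. Convergence is a plateau rule: stop when
the relative improvement of best-so-far over the last `patience` loops
falls below `tol`.

## What the virtual lab does and does not emulate

The simulated landscape is a multiplicative Gaussian bump on the fraction
scale: $y(v) = A \prod_i \exp\!\big(-(v_i/V_i - o_i)^2 / 2w_i^2\big)$,
peaking at the optimum fractions $o_i$ (snapped to the grids so the
optimum is attainable). Multiplicative structure is deliberate — starving
any essential CFPS component should collapse yield, which additive
landscapes get wrong. When standard-buffer fractions are supplied, the
widths are rescaled by one common factor so the standard sits at true
yield exactly 1, making simulated fold-changes directly interpretable.
Observations are $g_p \cdot y \cdot e^\varepsilon$ with log-normal noise
(signals stay positive, like a reader) and a log-normal per-plate gain
$g_p$, so cross-plate calibration is exercised for real.

The virtual lab does **not** emulate: multimodal or rugged response
surfaces, component interactions beyond the product form, kinetic reads,
spatial plate effects (edge evaporation), or dispensing failures. Passing
the closed-loop benchmark therefore shows the machinery — sampling,
layout, calibration, surrogate, acquisition, batching — works end to end
and beats random search on a smooth unimodal landscape; it does not prove
performance on an arbitrary real CFPS system.

## Benchmark conditions and numerical choices

The benchmark in the test suite and acceptance script uses the
four-component step-20 space (214,320 recipes), optimum at fraction 0.75
per component, standard near 0.54 of each maximum anchored to yield 1,
amplitude 10, noise sd 0.1 and gain sd 0.2 (log scale) — roughly the
10–20% CV typical of CFPS replicates. Each run: 50 LHS compositions plus
standard and two calibration buffers, 3 replicate wells each (matching
routine practice of 3 repetitions), then 4 learning loops of 15 (VAL and
random baseline) or 8 (CM at roughly half the batch budget), over 20
seeds, pool size 1000. Under these conditions the VAL median final best
exceeds twice the standard yield and strictly beats the budget-matched
random baseline, and CM at half batch lands within 10% of VAL — the
property analogues of running the optimization with far fewer tested
points at similar performance. Problem sizes were chosen so the whole
benchmark runs in a few minutes on one core.

Numerical details worth knowing: Cholesky-based GP algebra with a 1e-8
jitter; hyperparameter bounds (lengthscales and amplitude in
[0.05, 10], noise in [1e-3, 2] on the standardized scale) keep the
marginal-likelihood search away from degenerate optima; EI ties are broken
by pool position; HAC bucket ordering breaks size ties by cluster label;
all stage seeds derive deterministically from the user seed.

## Known limitations

* The calibration contract is gain-only; affine drift (additive offsets)
  is only handled indirectly via the optional blank subtraction.
* The GP is a plain single-output surrogate; no ensembles and no
  feature-importance reporting.
* `select_cluster_margin()` re-clusters the pool each loop; for pools far
  beyond ~5,000 candidates the $O(n^2)$ HAC distance matrix becomes the
  bottleneck.
* Stock-concentration chemistry (molarity ↔ volume) is out of scope: the
  pipeline speaks volumes, like the instruments it drives.
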