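# cfpsopt

Closed-loop, active-learning optimization of **cell-free protein synthesis
(CFPS) buffer compositions** on 384-well acoustic liquid-handling
platforms.

CFPS yield depends strongly on the reaction buffer — energy source, amino
acids, Mg/K salts, NTPs, crowding agent, template DNA — and the response
surface shifts with every lysate batch and target protein. With nine
variable components at six levels the discrete recipe space already holds
6⁹ ≈ 10⁷ compositions, far beyond exhaustive screening. `cfpsopt`
implements the computational side of the Design–Build–Test–Learn loop that
searches this space with a few hundred wells:

* **Design** — discrete Latin-hypercube sampling over dispenser-legal
  volume grids (2.5 nL granularity, 20–1000 nL transfer window), 16×24
  plate layouts with replicates, water fill and dead-volume-aware source
  plates, and Echo-style "Cherry Pick" transfer CSVs with automatic volume
  splitting.
* **Test** — plate-reader matrix import, endpoint extraction, cross-plate
  calibration via shared calibration buffers, fold-change yields versus
  the standard buffer (yield ≡ 1).
* **Learn** — a Gaussian-process surrogate (Matérn 5/2, per-component
  lengthscales, white noise) over normalized compositions, scored by
  **Expected Improvement**:

  EI(x) = (μ(x) − y* − ξ) Φ(z) + σ(x) φ(z),  z = (μ(x) − y* − ξ)/σ(x),

  with batches picked either as the top-n by EI (**VAL**) or by
  **Cluster-Margin** (CM): average-linkage HAC buckets, ordered
  smallest-first, served round-robin by EI — diversity plus
  informativeness, so similar performance at roughly half the batch size.
* **Virtual lab** — a simulated yield landscape (multiplicative Gaussian
  bump with log-normal noise and per-plate gain) so the entire loop,
  calibration included, runs and is benchmarked without hardware.

## Worked example

A four-component HeLa-lysate system, maxima 940/200/380/480 nL in 20 nL
steps (47·10·19·24 = 214,320 recipes), 2,000 nL reactions:

```r
library(cfpsopt)

tsv   <- system.file("extdata", "components_eucfps.tsv", package = "cfpsopt")
specs <- with_value_grids(parse_components_table(tsv), step = 20)
design_space_size(specs)
#> [1] 214320

tab <- lhs_sample(specs, n = 50, seed = 42)
tab
#> Sample table: 50 compositions x 4 components (experiment 50)
#>   sample_id       role HeLa lysate Accessory proteins Reaction mix DNA
#> 1      S001 experiment         920                 20          340 340
#> 2      S002 experiment         700                100          380  20
#> ...

dest  <- assign_destination_wells(tab, replicates = 3, sample_volume = 2000)
src   <- design_source_plate(dest, overage = 1000)
instr <- generate_instructions(src, dest, specs)
instr
#> Instruction set: 828 transfers, 300000 nL total, 1 source-plate type(s)
#>   source_plate source_plate_type source_well destination_plate destination_well
#> 1     Source_1      384PP_AQ_GP3          A1     Destination_1               A1
#> ...          component volume_nL
#> 1        HeLa lysate       920
```

Every well receives transfers (components + water) summing exactly to the
2,000 nL reaction volume; `write_instructions()` emits one picker CSV per
source-plate type (viscous components get their own acoustic calibration
mode).

Against the virtual lab — standard buffer anchored at yield 1, optimum
amplitude 10 — a full closed loop (50 LHS samples + 4 Cluster-Margin loops
of 8, 3 replicate wells each, plate-gain drift and calibration included):

```r
land <- landscape_config(specs, optimum = 0.75, amplitude = 10, standard = 0.54)
h <- closed_loop_benchmark(specs, land, loops = 4, method = "CM", seeds = 1:3,
                           n_init = 50, n_batch = 8, m_top = 30,
                           sample_volume = 2000)
h
#> Closed-loop history: 3 seed(s), 4 loop(s), method(s): CM
#>   median final best measured yield: 9.65 (true: 8.73)
```

Reading: starting from a best-of-LHS around 3–5× the standard buffer, four
8-sample CM loops reach a median best measured yield of 9.65 — near the
landscape's true optimum of 10 — having tested only 82 of 214,320 recipes.
`best_measured` is the calibrated fold-change the pipeline reports;
`best_true` is the simulator's ground truth for the same compositions.

For lab operation the same stages are driven by `run_init()` (sampling →
layouts → instructions), `run_core()` (reader files → calibration → next
batch → instructions, with plateau-based stopping) and a YAML
configuration (`read_run_config()`); `inst/cli/cfpsopt.R` wraps the three
as `init` / `core` / `simulate` shell subcommands.

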