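# perishell

Quantifies how densely different populations of axonal varicosities appose
the cell bodies of enteric neurons in 3D confocal reconstructions — and
whether particular ChAT/NOS-defined neuron classes are innervated
preferentially.

It is written for neuroanatomists working with wholemount myenteric-plexus
preparations: cell bodies reconstructed as closed triangle meshes (µm
coordinates, PLY/OBJ/STL), varicosities as marker-tagged 3D points (CSV), and
per-cell label/QC tables. A synthetic-ganglion generator with stored ground
truth stands in for imaging data, so the entire pipeline is testable on any
machine.

## The statistic and the model

For each cell body with surface *S*, the **perisomatic shell** is
{p : |d(p, S)| ≤ t} with t = 1 µm — from 1 µm inside the membrane to 1 µm
outside. Each varicosity point is attributed to at most one cell (the one
whose surface is nearest, ties broken deterministically, no double counting),
and the **shell density** of a cell is

> density = 1000 × (attributed spots in shell) / (shell volume in µm³),

in varicosities per 1,000 µm³ — independent of cell size by construction.
Shell volumes are measured by voxel-centre counting at 0.25 µm pitch.

Densities are compared across cell types with a Bayesian negative-binomial
mixed model with log link and shell volume as offset,

> Count ~ cell_type × marker + (1 + cell_type × marker || subj/gang) +
> offset(log V),  Shape ~ cell_type × marker,

in cell-mean coding so each coefficient is a log density. Results are
posterior mean densities per type × marker and pairwise **density ratios**
with equal-tailed 95% credible intervals; an interval excluding 1 indicates
preferential innervation. Pericellular **baskets** are called from shell
count (≥ 15) and angular coverage (≥ 1/3 of 64 Fibonacci-sphere bins) and
tested for association with cell type by Pearson χ².

## Worked example

```r
library(perishell)

# simulate a small study: 4 subjects, 2 ganglia each, ~12 cells per ganglion
gen <- generate_ganglia(
  generator_params(n_subjects = 4, cells_per_ganglion = 12),
  seed = 42)

cfg <- run_config(NULL, out_dir = NULL, chains = 2, warmup = 500,
                  draws = 500, seed = 42)
report <- run_pipeline(cfg, gen$scenes, gen$labels)
print(report)
```

```
Perisomatic shell density pipeline report
  cells: 107 reconstructed, 0 excluded, 107 analysed
  posterior mean densities (per 1,000 um^3):
# A tibble: 6 × 5
  cell_type  marker median ci_lo ci_hi
  <chr>      <chr>   <dbl> <dbl> <dbl>
1 ChAT+/NOS- TH      10.0   7.95 13.2
2 ChAT+/NOS- ENK     28.4  22.3  37.6
3 ChAT-/NOS+ TH       6.39  5.36  7.78
4 ChAT-/NOS+ ENK     17.0  14.6  20.5
5 ChAT+/NOS+ TH       4.03  2.70  6.94
6 ChAT+/NOS+ ENK     17.6  12.2  28.4
  density ratios:
# A tibble: 6 × 8
  marker type_a     type_b     median ci_lo ci_hi pr_gt_1 significant
  <chr>  <chr>      <chr>       <dbl> <dbl> <dbl>   <dbl> <lgl>
1 TH     ChAT+/NOS- ChAT-/NOS+  1.56  1.15   2.12   0.998 TRUE
2 TH     ChAT+/NOS- ChAT+/NOS+  2.46  1.33   3.87   0.995 TRUE
3 TH     ChAT-/NOS+ ChAT+/NOS+  1.57  0.867  2.44   0.956 FALSE
4 ENK    ChAT+/NOS- ChAT-/NOS+  1.68  1.22   2.33   1     TRUE
5 ENK    ChAT+/NOS- ChAT+/NOS+  1.62  0.954  2.48   0.966 FALSE
6 ENK    ChAT-/NOS+ ChAT+/NOS+  0.976 0.581  1.46   0.45  FALSE
```

Reading the output: the generator's true TH densities were 7.43 / 5.59 / 6.02
per 1,000 µm³ for the three modelled types (a true TH ratio of 1.33 for the
first contrast), and at this small size the model recovers densities of the
right magnitude with a first-contrast ratio interval [1.15, 2.12] covering
the truth. ENK densities for ChAT+/NOS− cells sit above their base parameter
because 10% of those cells carry simulated baskets with tripled counts.
`plot_densities()`, `plot_mean_densities()` and `autoplot()` on the fit give
the corresponding figures; `tidy(fit)` and `glance(fit)` expose the full
posterior summary with Rhat and effective sizes.

Real data enter through a YAML scene manifest (`read_scene_manifest()` /
`load_scene()`) listing per ganglion the mesh files, spot CSV, label CSV,
bounding box and voxel size; `run_pipeline(run_config("manifest.yaml", ...))`
then writes density tables, basket calls, the χ² association, posterior
summaries and a JSON report. A thin CLI with `simulate` / `quantify` / `run`
subcommands is installed under `inst/cli/perishell`.

## Package layout

| Area | Files |
| --- | --- |
| Mesh handling and I/O | `R/mesh.R`, `R/mesh-io.R` |
| Scenes and tables | `R/scene.R`, `R/scene-io.R` |
| Shell geometry (Rcpp core) | `R/geometry.R`, `src/geometry.cpp` |
| Typing and exclusions | `R/typing.R` |
| Baskets and association | `R/baskets.R` |
| Density model and morphometrics | `R/model.R` |
| Synthetic generator | `R/synthetic.R` |
| Orchestration and plots | `R/pipeline.R`, `R/plots.R` |

The methods vignette (`vignettes/perishell-methods.Rmd`) documents the model,
its assumptions, every tunable parameter with units and defaults, and the
design decisions behind the geometry and the sampler.
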