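# nanofoci

Quantitative analysis of DNA double-strand-break (DSB) repair foci, from
super-resolution nanostructure to population-level repair-pathway choice.

STED nanoscopy resolves each micron-scale ionizing-radiation-induced
focus into discrete **nanodomains** of repair proteins: a single
BRCA1-marked nanodomain at the centre with partner proteins (RAD18,
53BP1) arranged around it. `nanofoci` implements the measurement chain
for that architecture and its downstream readouts:

* **simulate** — synthetic STED z-stacks, high-content fields and
  reporter flow events with exact ground truth (the raw microscopy data
  cannot ship with a package, so every stage is testable against truth);
* **spotfind** — nanodomain detection by topographic-prominence local
  maxima on maximum-intensity projections, refined to sub-pixel
  coordinates by least-squares fits of
  `A exp(-((x-x0)^2+(y-y0)^2)/(2 sigma^2)) + b`;
* **topology** — selection of isolated BRCA1-anchored foci, assignment
  of partner nanodomains within a strict 500 nm radial gate, per-focus
  counts and minimal/mean centre distances, focus-centred signal
  averages, Mann-Whitney U group comparisons;
* **highcontent** — nucleus segmentation, G1/S/G2M gating from total
  DAPI and EdU nuclear intensities, per-nucleus foci counts normalized
  to 2n DNA content (`count x D_2n / DAPI_total`), Pearson and
  object-level colocalization;
* **reporter** — traffic-light-reporter gating (% GFP+ = homologous
  recombination, % RFP+ = mutagenic end joining, among BFP+ transfected
  cells) and normalization to a control's total repair efficiency;
* **stats** — the study's statistical battery with exact small-sample
  behaviour: Mann-Whitney U (exact below n1+n2 = 16, tie/continuity
  corrected otherwise), pooled-variance t-test, Type II two-way ANOVA,
  two-sided Fisher's exact test with conditional-MLE odds ratio and
  exact central CI, and cohort carrier-frequency summaries.

The methods vignette (`vignettes/nanofoci-methods.Rmd`) documents the
models, conventions, parameter defaults and limitations.

## Worked example

Simulate a dual-channel STED scene, detect and localize nanodomains,
and reconstruct focus topology:

```r
library(nanofoci)

cfg <- sted_sim_config(n_foci = 8, seed = 3)   # 22 nm px, 5 z-sections
scene <- simulate_sted_scene(cfg)
nd <- rbind(detect_nanodomains(scene$stack, "center",  tolerance = 10),
            detect_nanodomains(scene$stack, "partner", tolerance = 10))
tp <- focus_topology(nd)
str(tp$summary)
#> List of 9
#>  $ defined             : logi TRUE
#>  $ n_foci              : int 8
#>  $ n_foci_zero_partners: int 0
#>  $ count_mean          : num 2.38
#>  $ count_sd            : num 0.518
#>  $ min_dist_mean       : num 119
#>  ...
```

All eight simulated foci pass the isolation filter; each carries 2-3
partner nanodomains (the generator draws uniformly from {2, 3}) at a
mean minimal distance of ~119 nm from the centre.

The full analysis chain lives in `analysis/` as numbered drivers:

```sh
Rscript analysis/01_simulate_data.R    # scenes, field, reporter tables
Rscript analysis/02_sted_topology.R    # detection -> topology -> U tests
Rscript analysis/03_highcontent.R      # segmentation -> gating -> foci
Rscript analysis/04_reporter.R         # HR/NHEJ gating + normalization
Rscript analysis/05_stats_summary.R    # worked examples + calibration
```

Each writes tables and JSON summaries under `results/`. Representative
output (from the runs in this repository):

```
proximal:   300 foci | partner count 2.51 +- 0.50 | min dist 117 +- 33 nm
peripheral: 300 foci | partner count 5.47 +- 0.50 | min dist 208 +- 33 nm
min distance: U = 2856, p = 1.1e-87
...
control:   9.39% HR, 19.09% NHEJ of 4941 BFP+ events
knockdown: 5.65% HR, 19.21% NHEJ of 4941 BFP+ events
HR reduced to 60% of control
...
carrier frequency 13/17654: 0.07%
```

The proximal/peripheral conditions emulate the two partner stainings:
the centre-proximal protein sits closer to the BRCA1 centre and in
smaller numbers than the peripheral one, and the pipeline recovers both
the generator's counts (2.5 and 5.5) and the ordering of the radial
distances. The simulated knockdown scales the true HR probability to
60% of control; gating and normalization recover exactly that.

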