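# soiltrophics

Soil food-web inference and land-use gradient analysis for eDNA
metabarcoding surveys.

Agricultural intensification is suspected to simplify soil interaction
networks long before it shows up in species counts. Testing that requires
(i) turning plot-level taxa lists into food webs, (ii) summarizing each web
with comparable topology metrics, and (iii) relating those metrics to a
management gradient with the study design respected. `soiltrophics`
implements that pipeline end to end for a nested design (plots within
fields within sites):

- **Metaweb construction** — compile a knowledge base of pairwise trophic
  interactions (predation, parasitism, symbiosis), generalize genus/family
  records across observed members, trim by soil-layer co-occurrence and
  geographic range, and extract plot-level webs as induced subgraphs with
  co-detection edge weights.
- **Trophic groups** — a directed Bernoulli stochastic block model
  (variational EM, authored here) fitted to the metaweb adjacency, with the
  group count selected by the integrated complete-data likelihood
  (ICL); taxa sharing resources and consumers cluster together regardless
  of taxonomy.
- **Network metrics** — node and trophic-group richness, group entropy
  (Hill), average degree, mean trophic level (`TL = 1 + W·TL` solved as a
  linear system), omnivory, link density L/S, average/maximum directed path
  length, % parasitic links, and bacterial:fungal and
  detritivore:root-herbivore energy-channel ratios.
- **β-diversity** — Hill-number node turnover between webs
  (`beta = gamma/alpha`, dissimilarity `beta − 1 ∈ [0,1]`, orders q = 0, 1,
  2), PCoA ordination, and a seeded one-factor PERMANOVA.
- **LUI statistics** — a multicriteria land-use intensity index (field
  scores on the first principal component of standardized management
  criteria, sign-anchored to mineral N) and per-metric mixed models
  `m ~ LUI + (1 | site)` with Satterthwaite-calibrated p-values and
  standardized effect sizes.
- **Synthetic data** — a generator with planted block structure,
  guild-coherent trophic groups, three-level energy channels and a
  LUI-dependent detection model, so the whole pipeline is testable with
  known ground truth.

## Worked example

```r
library(soiltrophics)

cfg <- pipeline_config(scenario = scenario_config(seed = 112),
                       restarts = 3, n_perm = 999,
                       sbm_seed = 112, perm_seed = 112)
res <- run_pipeline(cfg, out_dir = "soiltrophics_out")

res$metaweb
#> <food_web> 150 nodes, 1639 edges
res$sbm_fit$Q
#> [1] 8
res$permanova_field
#> Permutation F test: F = 1.398, df = (15, 48), p = 0.001 (999 permutations)
res$permanova_site
#> Permutation F test: F = 2.590, df = (3, 60), p = 0.001 (999 permutations)
res$model_table[, c("metric", "slope", "p_value", "ses")]
#>                  metric    slope  p_value    ses
#>           node_richness -8.34000 3.61e-04 -0.995
#>  trophic_group_richness -0.05070 3.15e-02 -0.538
#>   trophic_group_entropy -0.12400 8.87e-04 -0.747
#>          average_degree -1.14000 5.99e-10 -0.970
#>      mean_trophic_level  0.00923 1.26e-01  0.399
#>          omnivory_level -0.01300 1.43e-03 -0.727
#>            link_density -0.57000 5.99e-10 -0.970
#>     average_path_length -0.00973 5.75e-01 -0.240
#>         max_path_length -0.11700 2.36e-01 -0.571
#>     pct_parasitic_links -1.00000 4.99e-02 -0.769
#>           bf_path_ratio -0.03260 1.28e-02 -0.606
#>           dh_path_ratio  0.20400 1.16e-01  0.664
```

Reading the output: the synthetic scenario plants a land-use effect through
preferential taxon loss (parasites and saprotrophic fungi decline fastest
with LUI). The pipeline recovers it in the expected directions — richness,
group richness/entropy, average degree, link density, omnivory and the share
of parasitic links all decline along the recovered LUI axis (negative slopes
and SES), while mean trophic level and the path-length metrics stay flat
(no effect planted on web depth). PERMANOVA detects significant node
turnover between fields (df = 15) and sites (df = 3). All artifacts
(metric tables, dissimilarity matrix, PCoA coordinates, SBM fit, LUI
scores, manifest with input hashes) land in `soiltrophics_out/`.

A command-line entry point wraps the same pipeline:

```sh
Rscript -e 'soiltrophics::soiltrophics_cli()' run-all --seed 112 --out soiltrophics_out
Rscript -e 'soiltrophics::soiltrophics_cli()' simulate --seed 1 --out inputs/
```

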