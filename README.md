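# fermnet

Co-occurrence networks, keystone taxa, and community assembly for
fermentation microbiomes.

`fermnet` is for microbial ecologists analyzing paired bacterial (16S) and
fungal (ITS) abundance tables from fermentation time courses — solid-state
Baijiu fermentations being the motivating system — together with sample
metadata and metabolite panels. It answers three linked questions:

1. **Who holds the community together?** Spearman co-occurrence networks
   with FDR-controlled edge selection (|ρ| ≥ 0.8, BH-adjusted p ≤ 0.01),
   module detection by three modularity algorithms (best Newman–Girvan Q
   wins), and keystone classification from within-module connectivity
   *Z_i* = (k_within − k̄)/σ_k and among-module connectivity
   *P_i* = 1 − Σ_s (k_is/k_i)², with the standard role grid (network hubs:
   Z ≥ 2.5 & P ≥ 0.62; module hubs: Z ≥ 2.5; connectors: P ≥ 0.62).
   Network stability is quantified as the proportion of species surviving
   simulated random removal with secondary extinction.
2. **What do the keystones do?** Per-sample Shannon diversity of each
   ecological module, regressed against metabolite concentrations (ethyl
   acetate, higher alcohols, …) with BH correction.
3. **What assembles the community?** The Sloan neutral model — occurrence
   frequency f(p) = 1 − Beta(d; Nmp, Nm(1−p)) fitted for the immigration
   rate m, with bootstrap prediction bands partitioning taxa into
   neutral/above/below — and the normalized stochasticity ratio (NST),
   which scores observed pairwise dissimilarities against a
   proportional-proportional null model (100% = purely stochastic, <50% =
   predominantly deterministic).

Everything is validated against a bundled synthetic-data generator that
plants known structure: Sloan-neutral background taxa, temperature-selected
taxa, five correlation blocks with designated connector taxa, and
metabolites linearly coupled to module-0 diversity. PERMANOVA, Mantel
tests, PCoA, per-taxon enrichment, and random-forest indicator-metabolite
selection round out the pipeline.

## Worked example

```r
library(fermnet)

# a full synthetic survey: 2 workshops x 6 days x 4 replicates,
# 400 bacterial + 200 fungal taxa, with planted ground truth
d <- generate_dataset(seed = 1)

merged   <- merge_domains(d$bacteria, d$fungi, normalize = "none")
filtered <- filter_taxa(merged)              # >20% prevalence, >0.01% mean RA
ra  <- merge_domains(d$bacteria, d$fungi, normalize = "domain")
fra <- abundance_table(ra$counts[taxa_ids(filtered), ],
                       ra$domain[taxa_ids(filtered)], is_relative = FALSE)

net <- detect_modules(build_network(fra), seed = 1)
net
#> cooccurrence_network: 382 nodes, 566 edges (522 +, 44 -)
#>   310 modules, modularity Q = 0.6002

roles <- zi_pi(net)
keystone_set(roles)$n_connectors
#> [1] 3            # exactly the three planted connector taxa

fit <- fit_neutral_model(merged, n_boot = 1000, seed = 1)
summary(fit)
#> Sloan neutral community model
#>   migration rate m: 0.1265 (bootstrap 95% CI 0.1185 - 0.1358)
#>   community size N: 83000 reads; detection limit d = 1.2e-05
#>   R2 = 0.977 over 592 taxa
#>   taxa: 92.4% neutral, 1.9% above, 5.7% below prediction
#>   cumulative RA: 99.3% neutral, 0.0% above, 0.6% below

nst(merged, groups = d$metadata$group, n_rand = 1000, seed = 1)
#> NST (jaccard, abundance-weighted, 1000 null draws)
#>   A: NST = 23.9% (more deterministic), ST = 28.3%
#>   B: NST = 24.8% (more deterministic), ST = 28.7%
```

Read the numbers the way a practitioner would: the network's 382 retained
taxa form modules at Q = 0.60, and the three taxa planted to bridge three
modules are the three detected connectors (P_i ≥ 0.62). The neutral fit
recovers an immigration rate near the generator's planted m = 0.1 (the
mild upward bias is characteristic of the detection-threshold
approximation) and calls 92% of taxa neutrally distributed. NST sits well
below 50% for both workshops — as it should here, since the generated
communities carry planted selection and block structure on top of the
neutral background.

`run_pipeline()` chains all stages (filter → network → keystone →
robustness → module–metabolite regressions → neutral + NST → PERMANOVA +
enrichment → indicators), writes TSV/GraphML/JSON results plus a manifest
with per-stage seeds and checksums, and `truth_report()` scores any output
against the generator's planted truth. A thin command-line front end lives
at `inst/scripts/ferment.R` (`simulate` and `run` subcommands).

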