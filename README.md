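# finchmeiosis

Germline mutation and meiotic recombination from multi-sibling,
three-generation pedigrees, in the setting typical of songbirds such as
the zebra finch: ~1% nucleotide diversity, macro- and micro-chromosomes
with an obligate crossover each, and — in the absence of PRDM9 —
recombination concentrated at hypomethylated CpG islands.

The package covers the full analysis chain on multi-sample genotype
data:

* **De novo mutations.** Trio-based candidate detection (proband
  heterozygous, parents homozygous reference, cohort-clean), callable
  masks from depth tracks, read-level filtering, phasing by transmission
  and by read tracing, post-zygotic classification via three-haplotype
  configurations, and rate estimation
  `mu = n / (2 * sum(callable))` with exact Poisson intervals.
* **Crossovers.** Template-based recoding of informative sites (sites
  heterozygous in exactly one parent), majority-vote phase-switch
  calling across siblings, parity-based classification (odd changes =
  crossover, complex when more than one; even = candidate conversion),
  interval refinement, cluster masking, genetic-map statistics
  (`cM = 100 * n / meioses`) and distribution tests.
* **Non-crossovers.** Double-switch calling under stringent genotype
  filters, uniqueness across meioses, congruent flanks, read-level
  verification of converted sites, and transmission validation against
  the next generation.
* **Gene-conversion parameters.** GC-biased gene conversion with exact
  binomial intervals; mean conversion tract length by composite
  likelihood over an integer grid, assuming exponential tracts
  (`P(co-conversion at distance d) = exp(-d / mean)`), with bootstrap
  intervals; Monte-Carlo detection power (closed form `p / (p + 1/L)`
  for Poisson site density p); power-corrected totals and the NCO:CO
  ratio.
* **CpG islands and enrichment.** A sliding-window scanner, a
  methylation-aware 8-state hidden Markov model over six emission
  symbols, matched-window permutation nulls for feature enrichment
  (GC- and mappability-matched), LD-based hotspot calling, and the
  uniform-heat overlap expectation `c h / (c h + 1 - c)`.
* **Population genetics.** Watterson's theta, effective population
  size `theta / (4 mu)`, rho-to-cM/Mb conversion, low-frequency
  polymorphism spectra, ancestral-allele polarization and trinucleotide
  rescaling.
* **Synthetic pedigrees.** A fully seeded generator (founder
  haplotypes, recombining meioses with biased conversion tracts,
  germline and post-zygotic mutations, read counts and genotype
  likelihood calls) whose defaults are the study conditions above, so
  every stage is testable without sequencing data.

Everything takes and returns tibbles; fitted objects have `tidy()`,
`glance()` and `autoplot()` methods.

## Worked example

Simulate a small two-family pedigree, call recombination events and
mutations, and summarise:

```r
library(finchmeiosis)
library(dplyr)

cfg <- sim_config(
  chromosomes = chromosome_spec(c("chr1", "chr2"), c(20e6, 10e6)),
  n_families = 2, n_f2 = 2, nco_rate = 2e-6, mu = 2e-7, seed = 7)
sim <- simulate_pedigree(cfg)

fams <- pedigree_families(sim$pedigree) |> filter(n_offspring == 5)
events <- ncos <- list()
for (i in seq_len(nrow(fams))) {
  f <- fams[i, ]
  tracks <- informative_tracks(sim$sites, f$mother, f$father,
                               f$offspring[[1]])
  events[[i]] <- call_crossovers(tracks)
  nco_tracks <- nco_genotype_filter(sim$sites, f$mother, f$father,
                                    f$offspring[[1]])
  ncos[[i]] <- call_noncrossovers(nco_tracks,
                                  call_crossovers(nco_tracks),
                                  sites = sim$sites)
}
events <- bind_rows(events); ncos <- bind_rows(ncos)

map_statistics(events, filter(sim$meioses, generation == "F1"),
               cfg$chromosomes)
#> Genetic map over 20 meioses:
#> # A tibble: 3 × 5
#>   sex    n_co n_meioses per_meiosis map_cm
#>   <chr> <int>     <int>       <dbl>  <dbl>
#> 1 both     42        20         2.1    210
#> 2 F        21        10         2.1    210
#> 3 M        21        10         2.1    210

estimate_gbgc(nco_ws_sites(ncos))
#> gBGC bias: 50.7% (34 strong of 67 W/S sites), 95% CI 38-63%
#> one-tailed binomial p vs 0.5: 0.5
```

42 crossovers over 20 meioses on the 30 Mb toy genome is a 210 cM map —
2.1 events per meiosis, as expected from the configured intensity plus
the obligate crossover on each of the two chromosomes. The conversion
events carry 67 weak/strong informative sites; the interval (38–63%)
comfortably covers the generating transmission bias of 59% but, at this
sample size, cannot distinguish it from no bias — which is exactly why
the study-scale analyses pool events across every available meiosis.

The mutation side runs per trio:

```r
trios <- pedigree_trios(sim$pedigree)
mapp <- intervals(cfg$chromosomes$name, 0, cfg$chromosomes$length)
dnms <- list(); callable <- numeric(nrow(trios))
for (i in seq_len(nrow(trios))) {
  trio <- c(trios$proband[i], trios$mother[i], trios$father[i])
  mask <- callable_mask_for_trio(sim$depth, trio, sim$mean_depth,
                                 mappability = mapp)
  callable[i] <- callable_length(mask)
  cand <- detect_dnm_candidates(sim$sites, sim$pedigree,
                                trios$proband[i], callable = mask)
  dnms[[i]] <- filter_dnm_candidates(cand)
}
estimate_dnm_rate(nrow(bind_rows(dnms)), callable)
#> Mutation rate: 1.92e-07 per bp per generation (161 events / 8.4e+08 bp)
#> 95% Poisson CI: 1.63e-07 - 2.24e-07
```

The interval covers the simulated rate of 2e-7 per bp per generation
(the example inflates the rate so a 30 Mb toy genome yields enough
events to estimate from).

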