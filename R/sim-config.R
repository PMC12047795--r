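#' Chromosome specification table
#'
#' @param name chromosome names.
#' @param length lengths in bp (must be positive).
#' @param mean_depth,mean_mapq per-chromosome mean mapping depth and mean
#'   mapping quality across individuals; used to select chromosomes
#'   eligible for non-crossover calling.
#' @return tibble with columns `name`, `length`, `cls` ("macro" for
#'   autosomes longer than 40 Mb, else "micro"), `mean_depth`, `mean_mapq`.
#' @export
chromosome_spec <- function(name, length, mean_depth = 25, mean_mapq = 50) {
  if (any(length <= 0)) abort("chromosome length must be positive")
  tibble(name = as.character(name), length = as.numeric(length),
         cls = if_else(length > 40e6, "macro", "micro"),
         mean_depth = mean_depth, mean_mapq = mean_mapq)
}

#' Default seven-class mutation-type spectrum
#'
#' Proportions for the collapsed-strand classes A>C, A>G, A>T, C>A, C>G,
#' C>T (non-CpG) and CpG>TpG, with the transition and CpG>TpG excess
#' typical of vertebrate germline spectra.
#' @return named numeric vector summing to 1.
#' @export
default_spectrum <- function() {
  c("A>C" = 0.06, "A>G" = 0.27, "A>T" = 0.05, "C>A" = 0.08,
    "C>G" = 0.08, "C>T" = 0.26, "CpG>TpG" = 0.20)
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic pedigree
#' generator: founder diversity near 1% heterozygosity, roughly 20
#' crossovers per meiosis on a 1 Gb genome with an obligate crossover per
#' chromosome, exponential conversion tracts with a 32 bp mean, 59%-biased
#' transmission of strong (G/C) alleles inside tracts, a germline point
#' mutation rate of 5e-9 per bp per generation with a 1.7:1 paternal bias
#' and a 15% post-zygotic fraction, and site-level read counts around 25x.
#'
#' @param chromosomes a [chromosome_spec()] tibble.
#' @param theta expected per-bp heterozygosity of founders (default 0.01).
#' @param co_rate crossover intensity per bp per meiosis (default 2e-8,
#'   i.e. ~20 per 1 Gb genome).
#' @param obligate_co force at least one crossover per chromosome per
#'   gamete (default TRUE).
#' @param co_telomere_weight if TRUE, crossover positions on
#'   macro-chromosomes are drawn from a telomere-enriched Beta(0.5, 0.5)
#'   density; micro-chromosomes are always uniform.
#' @param nco_rate non-crossover initiation intensity per bp per meiosis
#'   (default 9e-8, ~90 per 1 Gb genome).
#' @param tract_mean mean of the exponential conversion-tract length (bp).
#' @param gbgc_bias probability that the strong allele is transmitted at a
#'   heterozygous weak/strong site inside a conversion tract.
#' @param mu de novo point mutation rate per bp per generation.
#' @param alpha paternal:maternal germline mutation ratio.
#' @param postzygotic_fraction fraction of DNMs arising after
#'   fertilization of the proband.
#' @param mosaic_range range of the uniform mosaic read fraction for
#'   post-zygotic mutations.
#' @param spectrum named 7-class mutation-type distribution.
#' @param coverage_mean mean sequencing depth per sample.
#' @param base_error per-read base error rate.
#' @param insert_size read-pair fragment span in bp (sites closer than
#'   this can co-occur on a fragment).
#' @param n_families number of three-generation families.
#' @param n_offspring F1 siblings per family.
#' @param n_f2 offspring of the first F1 sibling and an unrelated partner.
#' @param n_shared_dnms number of parental-germline-mosaic mutations
#'   shared across siblings to inject (default 0).
#' @param depth_bin resolution (bp) of the emitted per-sample depth tracks.
#' @param seed integer seed; the seed fully determines the simulation.
#' @return a `fm_sim_config` list.
#' @export
sim_config <- function(chromosomes = chromosome_spec(c("chr1", "chr2"),
                                                     c(42e6, 8e6)),
                       theta = 0.01,
                       co_rate = 2e-8,
                       obligate_co = TRUE,
                       co_telomere_weight = TRUE,
                       nco_rate = 9e-8,
                       tract_mean = 32,
                       gbgc_bias = 0.59,
                       mu = 5e-9,
                       alpha = 1.7,
                       postzygotic_fraction = 0.15,
                       mosaic_range = c(0.1, 0.4),
                       spectrum = default_spectrum(),
                       coverage_mean = 25,
                       base_error = 1e-3,
                       insert_size = 300,
                       n_families = 4,
                       n_offspring = 5,
                       n_f2 = 2,
                       n_shared_dnms = 0,
                       depth_bin = 1000,
                       seed = 1) {
  stopifnot(theta >= 0, co_rate >= 0, nco_rate >= 0, tract_mean > 0,
            mu >= 0, alpha > 0, coverage_mean > 0)
  if (gbgc_bias < 0 || gbgc_bias > 1) abort("gbgc_bias must be in [0, 1]")
  if (postzygotic_fraction < 0 || postzygotic_fraction > 1) {
    abort("postzygotic_fraction must be in [0, 1]")
  }
  spectrum <- spectrum / sum(spectrum)
  structure(list(chromosomes = chromosomes, theta = theta, co_rate = co_rate,
                 obligate_co = obligate_co,
                 co_telomere_weight = co_telomere_weight,
                 nco_rate = nco_rate, tract_mean = tract_mean,
                 gbgc_bias = gbgc_bias, mu = mu, alpha = alpha,
                 postzygotic_fraction = postzygotic_fraction,
                 mosaic_range = mosaic_range, spectrum = spectrum,
                 coverage_mean = coverage_mean, base_error = base_error,
                 insert_size = insert_size, n_families = n_families,
                 n_offspring = n_offspring, n_f2 = n_f2,
                 n_shared_dnms = n_shared_dnms, depth_bin = depth_bin,
                 seed = as.integer(seed)),
            class = "fm_sim_config")
}

# heterozygosity per segregating site when frequencies are U(0.05, 0.95)
het_per_site <- function() {
  a <- 0.05; b <- 0.95
  ef2 <- (b^3 - a^3) / (3 * (b - a))
  2 * (0.5 - ef2)
}

# segregating-site density achieving the configured heterozygosity
site_density <- function(config) config$theta / het_per_site()
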