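#' Watterson's estimator of the population mutation rate
#'
#' theta_w = S / (a_{n-1} L) with a_{n-1} = sum_{i=1}^{n-1} 1/i, per bp.
#'
#' @param s number of biallelic segregating sites.
#' @param n_chromosomes sampled chromosomes (2 x individuals), >= 2.
#' @param length_bp surveyed length in bp.
#' @return theta per bp.
#' @export
watterson_theta <- function(s, n_chromosomes, length_bp) {
  if (n_chromosomes < 2) abort("need at least two sampled chromosomes")
  a <- sum(1 / seq_len(n_chromosomes - 1))
  s / (a * length_bp)
}

#' Effective population size from diversity and mutation rate
#' @param theta per-bp diversity (e.g. [watterson_theta()]).
#' @param mu per-bp per-generation mutation rate (> 0).
#' @return Ne = theta / (4 mu).
#' @export
effective_population_size <- function(theta, mu) {
  if (mu <= 0) abort("mu must be positive")
  theta / (4 * mu)
}

#' Convert a population recombination rate to cM/Mb
#' @param rho per-bp population recombination rate (4 Ne r).
#' @param ne effective population size (> 0).
#' @return recombination rate in cM/Mb (r per bp x 1e8).
#' @export
rho_to_cm_per_mb <- function(rho, ne) {
  if (ne <= 0) abort("Ne must be positive")
  rho / (4 * ne) * 1e8
}

#' Seven-class spectrum of low-frequency polymorphisms
#'
#' Restricts to sites where the alternate allele appears in at most
#' `max_alt_copies` chromosomes, orients mutations by assuming the major
#' allele is ancestral, and classifies them with the CpG context taken
#' from `context` (reference trinucleotide).
#'
#' @param sites [site_table()] of the cohort.
#' @param context character vector of reference trinucleotides per site
#'   (centre base = ref).
#' @param max_alt_copies maximum alternate-allele count (default 3).
#' @return spectrum tibble as in [mutation_spectrum()].
#' @export
low_freq_spectrum <- function(sites, context, max_alt_copies = 3) {
  x <- filter_biallelic(sites)
  context <- context[!sites$multiallelic]
  ac <- rowSums(x$gt, na.rm = TRUE)
  an <- rowSums(!is.na(x$gt)) * 2
  keep <- ac >= 1 & ac <= max_alt_copies
  mutation_spectrum(tibble(ref = x$ref[keep], alt = x$alt[keep],
                           context = context[keep]))
}

#' Ancestral-allele probabilities for a polymorphic site
#'
#' One-sided exact binomial test of whether the major allele's frequency
#' exceeds 0.5: if significant, the major allele is ancestral with
#' probability 0.91 and each other base with 0.03; otherwise both
#' observed alleles get 0.47 and the two unobserved bases 0.03.
#' Monomorphic input keeps the 0.91 convention (flagged).
#'
#' @param n_major,n_minor allele counts among sampled chromosomes.
#' @param alpha significance level of the binomial test (default 0.05).
#' @return tibble `major`, `minor`, `other` (per unobserved base),
#'   `significant`, `monomorphic`; probabilities sum to 1.
#' @export
polarize_alleles <- function(n_major, n_minor, alpha = 0.05) {
  if (n_minor > n_major) {
    tmp <- n_major; n_major <- n_minor; n_minor <- tmp
  }
  mono <- n_minor == 0
  sig <- if (mono) TRUE else {
    binom.test(n_major, n_major + n_minor,
               alternative = "greater")$p.value < alpha
  }
  if (sig) {
    tibble(major = 0.91, minor = 0.03, other = 0.03,
           significant = TRUE, monomorphic = mono)
  } else {
    tibble(major = 0.47, minor = 0.47, other = 0.03,
           significant = FALSE, monomorphic = mono)
  }
}

#' Rescale trinucleotide-context mutation counts between species
#'
#' Multiplies each context's count by the ratio of the focal species'
#' trinucleotide frequency to the reference species' frequency (used to
#' make 96-type counts comparable to human-trained signature sets).
#' Totals are not conserved.
#'
#' @param counts tibble `context`, `count` (96-type or any context set).
#' @param freq_focal,freq_ref named frequency vectors over contexts.
#' @return `counts` with a `rescaled` column.
#' @export
rescale_trinucleotide_counts <- function(counts, freq_focal, freq_ref) {
  miss <- counts$context[!(counts$context %in% names(freq_ref)) |
                           freq_ref[counts$context] == 0]
  if (length(miss)) {
    abort(paste("zero or missing reference frequency for context(s):",
                paste(unique(miss), collapse = ", ")))
  }
  mutate(counts, rescaled = .data$count *
           unname(freq_focal[.data$context] / freq_ref[.data$context]))
}
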