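#' Simulate detected conversion tracts over informative sites
#'
#' A direct generator for the tract-length estimator: informative sites
#' are a Poisson process of the given density on a single toy
#' chromosome; conversion tracts with exponential lengths are placed
#' uniformly and kept only when they cover at least one informative site
#' (the detection condition), until `n_events` are accepted. All sites
#' covered by an accepted tract are its converted sites.
#'
#' @param n_events number of detected events to generate (default 275).
#' @param tract_mean mean tract length in bp (default 32).
#' @param site_density informative sites per bp (default 0.002).
#' @param genome_bp toy chromosome length (default 5e7).
#' @return tibble `chrom`, `pos`, `converted`, `event` suitable for
#'   [estimate_tract_length()].
#' @export
simulate_conversion_sites <- function(n_events = 275, tract_mean = 32,
                                      site_density = 0.002,
                                      genome_bp = 5e7) {
  pos <- sort(runif(rpois(1, site_density * genome_bp), 0, genome_bp))
  conv <- rep(FALSE, length(pos))
  event <- rep(NA_integer_, length(pos))
  k <- 0
  while (k < n_events) {
    len <- rexp(1, 1 / tract_mean)
    a <- runif(1, 0, genome_bp - len)
    i1 <- findInterval(a, pos) + 1L
    i2 <- findInterval(a + len, pos)
    if (i2 < i1) next
    k <- k + 1
    conv[i1:i2] <- TRUE
    event[i1:i2] <- k
  }
  tibble(chrom = "sim", pos = pos, converted = conv, event = event)
}
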