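# shared fixtures, built once per test run
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# a modest two-family pedigree with an elevated mutation rate so that the
# DNM stages have events to work with (12 Mb genome, ~25x)
sim_small <- function() {
  cached("sim_small", function() {
    cfg <- sim_config(chromosomes = chromosome_spec(c("c1", "c2"),
                                                    c(8e6, 4e6)),
                      n_families = 2, n_f2 = 2, mu = 2e-7, seed = 11)
    simulate_pedigree(cfg)
  })
}

# conversion-dense variant used by the non-crossover and gBGC stages
sim_nco <- function() {
  cached("sim_nco", function() {
    cfg <- sim_config(chromosomes = chromosome_spec(c("c1", "c2"),
                                                    c(8e6, 4e6)),
                      n_families = 2, n_f2 = 2, mu = 1e-8,
                      nco_rate = 2e-6, seed = 17)
    simulate_pedigree(cfg)
  })
}

call_nco_families <- function(sim) {
  fams <- pedigree_families(sim$pedigree) |>
    dplyr::filter(.data$n_offspring == 5)
  ncos <- list()
  for (i in seq_len(nrow(fams))) {
    f <- fams[i, ]
    tr <- nco_genotype_filter(sim$sites, f$mother, f$father,
                              f$offspring[[1]])
    ev <- call_crossovers(tr)
    ncos[[i]] <- call_noncrossovers(tr, ev, sites = sim$sites)
  }
  dplyr::bind_rows(ncos)
}

# hand-built site table: one chromosome, explicit genotypes
# gt/dp/ad/gq given as sites x samples matrices
make_sites <- function(pos, gt, ref = NULL, alt = NULL, dp = NULL,
                       ad_ref = NULL, ad_alt = NULL, gq = NULL,
                       chrom = "c1") {
  n <- length(pos)
  if (is.null(ref)) ref <- rep("A", n)
  if (is.null(alt)) alt <- rep("G", n)
  if (is.null(dp)) dp <- matrix(30L, n, ncol(gt), dimnames = dimnames(gt))
  if (is.null(gq)) gq <- matrix(99L, n, ncol(gt), dimnames = dimnames(gt))
  if (is.null(ad_ref)) {
    ad_ref <- matrix(ifelse(gt == 0, 30L, ifelse(gt == 1, 15L, 0L)),
                     n, ncol(gt), dimnames = dimnames(gt))
  }
  if (is.null(ad_alt)) ad_alt <- dp - ad_ref
  site_table(chrom = chrom, pos = pos, ref = ref, alt = alt, gt = gt,
             dp = dp, ad_ref = ad_ref, ad_alt = ad_alt, gq = gq)
}

gt_matrix <- function(samples, ...) {
  rows <- list(...)
  m <- do.call(rbind, rows)
  colnames(m) <- samples
  m
}

# random interval set on one chromosome for oracle comparisons
random_intervals <- function(n, chrom_len, chrom = "c1") {
  s <- sort(sample.int(chrom_len - 10, n))
  e <- pmin(s + sample.int(500, n, replace = TRUE), chrom_len)
  ok <- s < e
  interval_union(intervals(rep(chrom, sum(ok)), s[ok], e[ok]))
}

# three-generation mini-pedigree used by DNM phasing tests
mini_ped <- function() {
  pedigree(tibble::tibble(
    id = c("gm", "gf", "pro", "par", "kid"),
    sex = c("F", "M", "F", "M", "M"),
    mother = c(NA, NA, "gm", NA, "pro"),
    father = c(NA, NA, "gf", NA, "par"),
    generation = c("F0", "F0", "F1", "F1", "F2")))
}
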