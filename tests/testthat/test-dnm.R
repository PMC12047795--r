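# cohort: trio (kid, mom, dad) plus two unrelated samples u1, u2
dnm_ped <- function() {
  pedigree(tibble::tibble(
    id = c("mom", "dad", "kid", "um", "uf", "u1"),
    sex = c("F", "M", "M", "F", "M", "F"),
    mother = c(NA, NA, "mom", NA, NA, "um"),
    father = c(NA, NA, "dad", NA, NA, "uf"),
    generation = c("F0", "F0", "F1", "F0", "F0", "F1")))
}

test_that("candidate definition: proband het, parents hom-ref, clean cohort", {
  samples <- c("kid", "mom", "dad", "um", "uf", "u1")
  gt <- gt_matrix(samples,
                  c(1, 0, 0, 0, 0, 0),   # the textbook candidate
                  c(1, 0, 0, 0, 0, 1),   # unrelated carrier -> rejected
                  c(1, 1, 0, 0, 0, 0),   # mother het -> rejected
                  c(0, 0, 0, 0, 0, 0))   # proband hom-ref -> rejected
  sites <- make_sites(c(1000, 2000, 3000, 4000), gt)
  cand <- detect_dnm_candidates(sites, dnm_ped(), "kid")
  expect_equal(cand$pos, 1000)
  # GQ 29 in the mother kills an otherwise perfect candidate
  gq <- matrix(99L, 4, 6, dimnames = list(NULL, samples))
  gq[1, "mom"] <- 29L
  sites2 <- make_sites(c(1000, 2000, 3000, 4000), gt, gq = gq)
  expect_equal(nrow(detect_dnm_candidates(sites2, dnm_ped(), "kid")), 0)
  # siblings are exempt from the outside-family polymorphism screen
  ped_sib <- pedigree(tibble::tibble(
    id = c("mom", "dad", "kid", "sib", "um", "uf"),
    sex = c("F", "M", "M", "F", "F", "M"),
    mother = c(NA, NA, "mom", "mom", NA, NA),
    father = c(NA, NA, "dad", "dad", NA, NA)))
  gt3 <- gt_matrix(c("kid", "mom", "dad", "sib", "um", "uf"),
                   c(1, 0, 0, 1, 0, 0))
  sites3 <- make_sites(5000, gt3)
  expect_equal(nrow(detect_dnm_candidates(sites3, ped_sib, "kid")), 1)
})

test_that("read-level filters enforce alt support, parental absence and spacing", {
  base <- tibble::tibble(chrom = "c1", pos = c(100, 1000, 1009, 3000, 3010),
                         ref = "A", alt = "G", proband = "kid",
                         mother = "mom", father = "dad",
                         proband_dp = 30, proband_alt = c(1, 14, 15, 16, 13),
                         mother_alt = c(0, 0, 0, 0, 0),
                         father_alt = c(0, 0, 0, 0, 0))
  out <- filter_dnm_candidates(base)
  # pos 100 has one alt read; 1000/1009 are 9 bp apart (both dropped);
  # 3000/3010 are exactly 10 bp apart (both kept)
  expect_equal(out$pos, c(3000, 3010))
  # one parental alt read is disqualifying
  base2 <- base[4, ]
  base2$father_alt <- 1
  expect_equal(nrow(filter_dnm_candidates(base2)), 0)
})

test_that("transmission phasing follows the 75% informative-allele rule", {
  ped <- mini_ped()
  samples <- c("gm", "gf", "pro", "par", "kid")
  build <- function(n_gm, n_gf, dnm_gt_kid) {
    # informative sites: allele private to one grandparent, carried by
    # proband (het), absent from partner, transmitted to the kid
    n <- n_gm + n_gf
    gt <- rbind(
      do.call(rbind, replicate(n_gm, c(1, 0, 1, 0, 1), simplify = FALSE)),
      do.call(rbind, replicate(n_gf, c(0, 1, 1, 0, 1), simplify = FALSE)),
      c(0, 0, 1, 0, dnm_gt_kid))  # the DNM site
    colnames(gt) <- samples
    make_sites(c(seq(1000, by = 1000, length.out = n), 150000), gt)
  }
  dnm <- tibble::tibble(chrom = "c1", pos = 150000, proband = "pro")
  # 9 of 10 informative alleles from the grandmother, DNM transmitted
  ph <- phase_dnm_by_transmission(build(9, 1, 1), ped, dnm)
  expect_equal(ph$phase, "maternal")
  # same majority but DNM NOT transmitted -> the other parent
  ph2 <- phase_dnm_by_transmission(build(9, 1, 0), ped, dnm)
  expect_equal(ph2$phase, "paternal")
  # 6 of 10 is below the 75% threshold
  ph3 <- phase_dnm_by_transmission(build(6, 4, 1), ped, dnm)
  expect_equal(ph3$phase, "unresolved")
})

test_that("read tracing assigns the parent sharing the mutant fragment", {
  ped <- mini_ped()
  samples <- c("gm", "gf", "pro", "par", "kid")
  # flanking het private to the grandfather
  gt <- gt_matrix(samples, c(0, 1, 1, 0, 0), c(0, 0, 1, 0, 0))
  sites <- make_sites(c(1000, 1100), gt, ref = c("A", "C"),
                      alt = c("G", "T"))
  dnm <- tibble::tibble(chrom = "c1", pos = 1100, proband = "pro",
                        ref = "C", alt = "T")
  frag <- function(alle_at_1000) {
    tibble::tibble(sample = "pro", fragment = rep(1:4, each = 2),
                   chrom = "c1", pos = rep(c(1000, 1100), 4),
                   allele = rep(c(alle_at_1000, "T"), 4))
  }
  # mutation co-occurs with the father-only allele G -> paternal
  expect_equal(phase_dnm_by_read_tracing(dnm, frag("G"), sites,
                                         ped)$phase, "paternal")
  # mutation always opposite the father-only allele -> maternal
  expect_equal(phase_dnm_by_read_tracing(dnm, frag("A"), sites,
                                         ped)$phase, "maternal")
  # conflicting fragments -> unresolved with a conflict flag
  fr <- dplyr::bind_rows(frag("G")[1:4, ],
                         dplyr::mutate(frag("A")[5:8, ]))
  out <- phase_dnm_by_read_tracing(dnm, fr, sites, ped)
  expect_equal(out$phase, "unresolved")
  expect_true(out$conflict)
})

test_that("timing classification recognizes three-haplotype configurations", {
  samples <- c("gm", "gf", "pro", "par", "kid")
  gt <- gt_matrix(samples, c(0, 1, 1, 0, 0), c(0, 0, 1, 0, 0))
  sites <- make_sites(c(1000, 1100), gt, ref = c("A", "C"),
                      alt = c("G", "T"))
  dnm <- tibble::tibble(chrom = "c1", pos = 1100, proband = "pro",
                        ref = "C", alt = "T")
  mk <- function(combos) {
    tibble::tibble(sample = "pro",
                   fragment = rep(seq_along(combos), each = 2),
                   chrom = "c1", pos = rep(c(1000, 1100), length(combos)),
                   allele = unlist(combos))
  }
  # A-mut, A-ref, G-ref observed twice each: three haplotypes
  tri <- mk(rep(list(c("A", "T"), c("A", "C"), c("G", "C")), 2))
  expect_equal(classify_dnm_timing(dnm, tri, sites = sites)$timing,
               "postzygotic")
  # only two haplotypes: parental germline
  two <- mk(rep(list(c("A", "T"), c("G", "C")), 3))
  expect_equal(classify_dnm_timing(dnm, two, sites = sites)$timing,
               "parental_germline")
  # a parent with three haplotypes discards the record
  par3 <- dplyr::mutate(tri, sample = "gf")
  out <- classify_dnm_timing(dnm, two, parent_fragments = par3,
                             sites = sites)
  expect_equal(out$timing, "discard")
})

test_that("rate estimation reproduces the study-scale arithmetic", {
  r <- estimate_dnm_rate(202, rep(502.8e6, 40), mean_parental_age = 2.5)
  expect_equal(r$rate, 5.02e-9, tolerance = 0.001)
  expect_equal(round(r$rate, 10), 5.0e-9, tolerance = 0.01)
  expect_equal(r$rate_per_year, 2.0e-9, tolerance = 0.005)
  # exact Poisson CI reproduces the printed interval after division by 2L
  expect_equal(r$ci[["lower"]], 4.3e-9, tolerance = 0.02)
  expect_equal(r$ci[["upper"]], 5.7e-9, tolerance = 0.02)
  # germline-only count
  r2 <- estimate_dnm_rate(177, rep(502.8e6, 40))
  expect_equal(r2$rate, 4.4e-9, tolerance = 0.01)
  # zero events: rate 0 with the exact upper bound 3.69/(2L)
  r0 <- estimate_dnm_rate(0, 1e6)
  expect_equal(r0$rate, 0)
  expect_equal(r0$ci[["lower"]], 0)
  expect_equal(r0$ci[["upper"]] * 2e6, qchisq(0.975, 2) / 2,
               tolerance = 1e-10)
  expect_equal(qchisq(0.975, 2) / 2, 3.689, tolerance = 0.001)
  expect_error(estimate_dnm_rate(5, 0), "positive")
})

test_that("sex ratios and their exact binomial intervals behave", {
  expect_equal(dnm_sex_ratio(50, 50)$ratio, 1)
  # post-zygotic mode rescales by probands per sex
  r <- dnm_sex_ratio(12, 13, probands_per_sex = c(male = 20, female = 20))
  expect_equal(r$ratio, 12 / 13, tolerance = 1e-10)
  expect_equal(round(r$ratio, 2), 0.92)
  # recovery: phased counts drawn at alpha = 1.7 land inside the CI
  withr::with_seed(31, {
    n <- 200
    k <- rbinom(1, n, 1.7 / 2.7)
    rr <- dnm_sex_ratio(k, n - k)
    expect_true(rr$ci["lower"] <= 1.7 && 1.7 <= rr$ci["upper"])
  })
})

test_that("spectrum comparison is a chi-square GOF with pooling", {
  obs <- c("A>C" = 10, "A>G" = 30, "A>T" = 8, "C>A" = 12, "C>G" = 11,
           "C>T" = 25, "CpG>TpG" = 24)
  exp_prop <- obs / sum(obs)
  expect_equal(spectrum_compare(obs, exp_prop)$p.value, 1)
  # long-hand oracle on an uneven table
  exp2 <- c("A>C" = .1, "A>G" = .2, "A>T" = .1, "C>A" = .1, "C>G" = .1,
            "C>T" = .2, "CpG>TpG" = .2)
  out <- spectrum_compare(obs, exp2)
  e <- sum(obs) * exp2
  expect_equal(out$statistic, sum((obs - e)^2 / e))
  expect_equal(out$df, 6)
  expect_equal(out$p.value, pchisq(out$statistic, 6, lower.tail = FALSE))
  # sparse classes get pooled with a warning
  expect_warning(spectrum_compare(c("A>C" = 1, "A>G" = 50, "A>T" = 0,
                                    "C>A" = 0, "C>G" = 0, "C>T" = 50,
                                    "CpG>TpG" = 20),
                                  c("A>C" = .001, "A>G" = .4, "A>T" = .001,
                                    "C>A" = .001, "C>G" = .001, "C>T" = .4,
                                    "CpG>TpG" = .196)),
                 "pooling")
})

test_that("mutation-type classification collapses strands and flags CpG", {
  expect_equal(classify_mutation_type("T", "G"), "A>C")
  expect_equal(classify_mutation_type("C", "T", "ACG"), "CpG>TpG")
  expect_equal(classify_mutation_type("G", "A", "CGA"), "CpG>TpG")
  expect_equal(classify_mutation_type("C", "T", "ACA"), "C>T")
})

test_that("shared sibling mutations are detected", {
  ped <- pedigree(tibble::tibble(
    id = c("m", "f", "s1", "s2", "s3"), sex = c("F", "M", "M", "F", "M"),
    mother = c(NA, NA, "m", "m", "m"), father = c(NA, NA, "f", "f", "f")))
  recs <- tibble::tibble(proband = c("s1", "s2", "s3"), chrom = "c1",
                         pos = c(100, 100, 900), alt = c("G", "G", "T"))
  sh <- shared_sibling_dnms(recs, ped)
  expect_equal(nrow(sh), 1)
  expect_setequal(sh$carriers[[1]], c("s1", "s2"))
  expect_equal(nrow(shared_sibling_dnms(recs[c(1, 3), ], ped)), 0)
})

test_that("pipeline recovers simulated mutations: rate, fractions, sharing", {
  sim <- sim_small()
  ped <- sim$pedigree
  trios <- pedigree_trios(ped)
  mapp <- intervals(sim$config$chromosomes$name, 0,
                    sim$config$chromosomes$length)
  out <- list(); L <- numeric(nrow(trios))
  for (i in seq_len(nrow(trios))) {
    tri <- c(trios$proband[i], trios$mother[i], trios$father[i])
    cm <- callable_mask_for_trio(sim$depth, tri, sim$mean_depth,
                                 mappability = mapp)
    L[i] <- callable_length(cm)
    cand <- detect_dnm_candidates(sim$sites, ped, trios$proband[i],
                                  callable = cm)
    out[[i]] <- filter_dnm_candidates(cand)
  }
  dnm <- dplyr::bind_rows(out)
  truth <- sim$truth$dnms
  hit <- dplyr::inner_join(dnm, truth,
                           by = c("proband", "chrom", "pos"))
  # detected mutations are (almost) all real; most real ones are found
  expect_gte(nrow(hit), nrow(dnm) - 1)
  expect_gt(nrow(dnm) / nrow(truth), 0.7)
  # the rate estimate's Poisson CI covers the simulated mu
  r <- estimate_dnm_rate(nrow(dnm), L)
  expect_true(r$ci["lower"] <= sim$config$mu &&
                sim$config$mu <= r$ci["upper"])
  # post-zygotic calls sit below 50% alt fraction, germline near 50%
  expect_lt(mean(hit$proband_alt_fraction[hit$postzygotic]), 0.45)
  expect_equal(mean(hit$proband_alt_fraction[!hit$postzygotic]), 0.5,
               tolerance = 0.05)
})

test_that("both phasing routes agree on simulated mutations", {
  sim <- sim_small()
  ped <- sim$pedigree
  truth <- sim$truth$dnms
  # germline mutations in F1 probands with partner and offspring
  f1 <- ped$id[ped$generation == "F1" &
                 ped$id %in% c(ped$mother, ped$father)]
  tt <- dplyr::filter(truth, .data$proband %in% f1, !.data$postzygotic)
  expect_gt(nrow(tt), 3)
  agree <- 0; both <- 0; correct_t <- 0; resolved_t <- 0
  withr::with_seed(99, {
    for (i in seq_len(nrow(tt))) {
      d <- tt[i, ]
      pt <- phase_dnm_by_transmission(sim$sites, ped, d)
      fr <- simulate_fragments(sim, d$proband, d$chrom, d$pos)
      pr <- phase_dnm_by_read_tracing(d, fr, sim$sites, ped)
      truth_ph <- if (d$parent_sex == "F") "maternal" else "paternal"
      if (pt$phase != "unresolved") {
        resolved_t <- resolved_t + 1
        correct_t <- correct_t + (pt$phase == truth_ph)
      }
      if (pt$phase != "unresolved" && pr$phase != "unresolved") {
        both <- both + 1
        agree <- agree + (pt$phase == pr$phase)
      }
    }
  })
  expect_gt(resolved_t, 0)
  expect_equal(correct_t / resolved_t, 1)
  if (both > 0) expect_gte(agree / both, 0.9)
})
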