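test_that("switch detection matches the recoding examples", {
  expect_equal(detect_switches(c(1, 1, 2, 2)),
               tibble::tibble(left_idx = 2L, right_idx = 3L))
  # missing states are skipped so a switch can span them
  expect_equal(detect_switches(c(1, 0, 0, 2)),
               tibble::tibble(left_idx = 1L, right_idx = 4L))
  expect_equal(nrow(detect_switches(c(1, 1, 1))), 0)
  expect_equal(nrow(detect_switches(c(0, 1))), 0)
})

# build a track row directly: focal-parent transmitted alleles per
# offspring (rows = sites)
track_of <- function(A, pos = NULL, parent = "p", chrom = "c1") {
  if (is.null(pos)) pos <- seq_len(nrow(A)) * 1000
  tibble::tibble(parent = parent, chrom = chrom, pos = list(pos),
                 ref = list(rep("A", nrow(A))),
                 alt = list(rep("G", nrow(A))), alleles = list(A))
}

test_that("informative sites require het in one parent and support filters", {
  samples <- c("mo", "fa", "o1", "o2", "o3")
  gt <- gt_matrix(samples,
                  c(1, 0, 1, 0, 1),   # informative for mother
                  c(1, 1, 1, 1, 1),   # het in both parents -> dropped
                  c(1, 2, 2, 1, 2),   # informative, other parent hom-alt
                  c(0, 1, 0, 1, 1))   # informative for father
  sites <- make_sites(c(1e4, 2e4, 3e4, 4e4), gt)
  tr <- informative_tracks(sites, "mo", "fa", c("o1", "o2", "o3"))
  trm <- tr[tr$parent == "mo", ]
  expect_equal(trm$pos[[1]], c(1e4, 3e4))
  # transmitted-allele recoding: other parent hom-alt at 3e4 means an
  # offspring het got ref from the mother
  expect_equal(unname(trm$alleles[[1]][2, ]), c(1L, 0L, 1L))
  trf <- tr[tr$parent == "fa", ]
  expect_equal(trf$pos[[1]], 4e4)
  # allelic imbalance masks a het genotype (AD 20/1)
  adr <- matrix(15L, 4, 5, dimnames = list(NULL, samples))
  ada <- matrix(15L, 4, 5, dimnames = list(NULL, samples))
  adr[1, "o1"] <- 20L; ada[1, "o1"] <- 1L
  sites2 <- make_sites(c(1e4, 2e4, 3e4, 4e4), gt,
                       dp = adr + ada, ad_ref = adr, ad_alt = ada)
  tr2 <- informative_tracks(sites2, "mo", "fa", c("o1", "o2", "o3"))
  expect_true(is.na(tr2$alleles[[which(tr2$parent == "mo")]][1, "o1"]))
  # AD 10/9 is kept
  expect_gt(binom_imbalance_p(10, 9), 0.01)
  expect_lte(binom_imbalance_p(20, 1), 0.01)
})

test_that("exact binomial imbalance p-values match binom.test", {
  for (k in c(0, 3, 7, 10)) {
    expect_equal(binom_imbalance_p(k, 20 - k),
                 binom.test(k, 20, 0.5)$p.value, tolerance = 1e-12)
  }
})

test_that("crossover calling distinguishes clean, complex and paired switches", {
  # template o1 crosses over between sites 15 and 16: all others switch
  n <- 30
  A <- cbind(o1 = rep(0L, n), o2 = rep(0L, n), o3 = rep(0L, n),
             o4 = rep(0L, n))
  A[16:n, "o1"] <- 1L
  ev <- call_crossovers(track_of(A))
  co <- ev[ev$kind == "CO", ]
  expect_equal(nrow(co), 1)
  expect_equal(co$offspring, "o1")
  expect_equal(co$left, 15000); expect_equal(co$right, 16000)
  expect_equal(co$support, 3)
  # an isolated flipped site ("1 2 1" pattern) is two changes -> NCO
  B <- A; B[16:n, "o1"] <- 0L; B[15, "o1"] <- 1L
  ev2 <- call_crossovers(track_of(B))
  expect_equal(ev2$kind, "nco_candidate")
  expect_equal(ev2$n_changes, 2)
  # three changes within the cluster window -> one complex crossover
  n2 <- 40
  C <- cbind(o1 = rep(0L, n2), o2 = rep(0L, n2), o3 = rep(0L, n2),
             o4 = rep(0L, n2))
  C[16:18, "o1"] <- 1L; C[22:n2, "o1"] <- 1L
  ev3 <- call_crossovers(track_of(C))
  expect_equal(ev3$kind, "complex_CO")
  expect_equal(ev3$n_changes, 3)
})

test_that("events near track edges are removed", {
  n <- 30
  A <- cbind(o1 = rep(0L, n), o2 = rep(0L, n), o3 = rep(0L, n))
  A[1:5, "o1"] <- 1L  # switch at site 5/6, within 10 markers of the edge
  expect_equal(nrow(call_crossovers(track_of(A))), 0)
  expect_equal(nrow(call_crossovers(track_of(A), edge = 2)), 1)
})

test_that("interval refinement requires a single relaxed-track switch", {
  n <- 30
  A <- cbind(o1 = rep(0L, n), o2 = rep(0L, n), o3 = rep(0L, n))
  A[16:n, "o1"] <- 1L
  ev <- call_crossovers(track_of(A))
  # relaxed track adds a site at 15500 carrying the pre-switch phase
  Ar <- rbind(A[1:15, ], A[15, ], A[16:n, ])
  posr <- c(1:15 * 1000, 15500, 16:n * 1000)
  out <- refine_crossover_intervals(ev, track_of(Ar, posr))
  expect_true(out$refined)
  expect_equal(out$left, 15500)
  expect_equal(out$right, 16000)
  # a relaxed track that introduces a second switch keeps the original
  Ab <- Ar; Ab[16, "o1"] <- 1L; Ab[17, "o1"] <- 0L
  out2 <- refine_crossover_intervals(ev, track_of(Ab, posr))
  expect_false(out2$refined)
  expect_equal(out2$left, 15000)
})

test_that("clustered crossovers are masked per the 2 Mb / 3-event rule", {
  mk_ev <- function(offspring, mids) {
    tibble::tibble(parent = "p", offspring = offspring, chrom = "c1",
                   kind = "CO", n_changes = 1L, left = mids - 500,
                   right = mids + 500, left_idx = 1L, right_idx = 2L,
                   support = 3L, changes = list(tibble::tibble()))
  }
  # three events at 0.5 Mb spacing in one meiosis: all masked
  tight <- mk_ev("o1", c(1e6, 1.5e6, 2e6))
  out <- mask_clustered_crossovers(tight)
  expect_equal(nrow(out$events), 0)
  expect_equal(nrow(out$masked), 1)
  # two events 1 Mb apart survive (candidate class II pair)
  pair <- mk_ev("o1", c(1e6, 2e6))
  out2 <- mask_clustered_crossovers(pair)
  expect_equal(nrow(out2$events), 2)
  # events of other meioses inside the final mask are removed too
  mixed <- dplyr::bind_rows(tight, mk_ev("o2", 1.2e6), mk_ev("o2", 9e6))
  out3 <- mask_clustered_crossovers(mixed)
  expect_equal(out3$events$offspring, "o2")
  expect_equal(nrow(out3$events), 1)
  expect_equal((out3$events$left + out3$events$right) / 2, 9e6)
})

test_that("cluster masking matches hand enumeration on a random fixture", {
  withr::with_seed(17, {
    mids <- sort(runif(40, 0, 50e6))
    off <- sample(c("o1", "o2"), 40, replace = TRUE)
    ev <- tibble::tibble(parent = "p", offspring = off, chrom = "c1",
                         kind = "CO", n_changes = 1L, left = mids - 100,
                         right = mids + 100, left_idx = 1L, right_idx = 2L,
                         support = 3L,
                         changes = replicate(40, tibble::tibble(),
                                             simplify = FALSE))
    out <- mask_clustered_crossovers(ev)
    # oracle: single-linkage clusters per meiosis
    removed <- rep(FALSE, 40)
    spans <- list()
    for (o in c("o1", "o2")) {
      idx <- which(off == o)
      m <- mids[idx]
      grp <- cumsum(c(1, diff(m) > 2e6))
      for (g in unique(grp)) {
        sel <- idx[grp == g]
        if (length(sel) >= 3) {
          removed[sel] <- TRUE
          spans[[length(spans) + 1]] <- range(c(mids[sel] - 100,
                                                mids[sel] + 100))
        }
      }
    }
    if (length(spans)) {
      for (i in which(!removed)) {
        for (sp in spans) {
          if (mids[i] + 100 > sp[1] && mids[i] - 100 < sp[2]) {
            removed[i] <- TRUE
          }
        }
      }
    }
    expect_equal(nrow(out$events), sum(!removed))
  })
})

test_that("map statistics reproduce the published arithmetic", {
  mei <- tibble::tibble(parent = rep(c(paste0("m", 1:28), paste0("f", 1:26))),
                        offspring = paste0("k", 1:54),
                        parent_sex = c(rep("F", 28), rep("M", 26)))
  # 559 maternal and 529 paternal crossovers over 28 + 26 meioses
  withr::local_seed(12)
  rows <- c(sample(1:28, 559, replace = TRUE),
            sample(29:54, 529, replace = TRUE))
  ev <- tibble::tibble(parent = mei$parent[rows],
                       offspring = mei$offspring[rows],
                       chrom = "c1", kind = "CO",
                       left = 1000, right = 2000)
  chroms <- chromosome_spec("c1", 50e6)
  ms <- map_statistics(ev, mei, chroms)
  s <- ms$summary
  expect_equal(s$map_cm[s$sex == "both"], 100 * 1088 / 54)
  expect_equal(round(s$map_cm[s$sex == "both"]), 2015)
  expect_equal(s$per_meiosis[s$sex == "F"], 559 / 28)
  expect_equal(round(s$per_meiosis[s$sex == "F"], 1), 20.0)
  expect_equal(round(s$per_meiosis[s$sex == "M"], 1), 20.3)
  expect_equal(round(s$map_cm[s$sex == "F"]), 1996)
  expect_equal(round(s$map_cm[s$sex == "M"]), 2035)
  # zero crossovers give a zero-length map
  ms0 <- map_statistics(ev[0, ], mei, chroms)
  expect_equal(ms0$summary$map_cm[1], 0)
})

test_that("two-sample KS statistic matches a hand computation", {
  x <- c(0.05, 0.1, 0.2, 0.4, 0.5)
  y <- c(0.3, 0.6, 0.7, 0.8, 0.9)
  # oracle: max |ECDF difference| evaluated on the pooled points
  pool <- sort(c(x, y))
  d_oracle <- max(abs(ecdf(x)(pool) - ecdf(y)(pool)))
  expect_equal(unname(suppressWarnings(ks.test(x, y))$statistic), d_oracle)
  ev <- tibble::tibble(chrom = c(rep("ma", 5), rep("mi", 5)),
                       left = c(x, y) * 5e7, right = c(x, y) * 5e7)
  chroms <- chromosome_spec(c("ma", "mi"), c(5e7, 5e7))
  chroms$cls <- c("macro", "micro")
  ds <- distribution_statistics(ev, chroms)
  expect_equal(ds$ks_macro_micro$statistic, d_oracle)
})

test_that("uniform crossover placement is not rejected more than nominally", {
  withr::with_seed(23, {
    chroms <- chromosome_spec("c1", 10e6)
    rej <- replicate(200, {
      pos <- runif(60, 0, 10e6)
      ev <- tibble::tibble(chrom = "c1", left = pos, right = pos)
      ds <- distribution_statistics(ev, chroms)
      ds$ks_uniform$p.value[1] < 0.05
    })
    expect_equal(mean(rej), 0.05, tolerance = 0.9)
    expect_lt(mean(rej), 0.11)
  })
})

test_that("caller recovers simulated crossovers with high recall and
           truth-containing intervals", {
  sim <- sim_small()
  fams <- pedigree_families(sim$pedigree) |>
    dplyr::filter(.data$n_offspring == 5)
  evs <- list()
  for (i in seq_len(nrow(fams))) {
    f <- fams[i, ]
    tr <- informative_tracks(sim$sites, f$mother, f$father,
                             f$offspring[[1]])
    evs[[i]] <- call_crossovers(tr)
  }
  ev <- dplyr::bind_rows(evs)
  co <- ev[ev$kind %in% c("CO", "complex_CO"), ]
  truth <- sim$truth$crossovers |>
    dplyr::semi_join(dplyr::filter(sim$meioses, .data$generation == "F1"),
                     by = c("parent", "offspring"))
  contain <- vapply(seq_len(nrow(co)), function(i) {
    any(truth$parent == co$parent[i] & truth$offspring == co$offspring[i] &
          truth$chrom == co$chrom[i] & truth$pos >= co$left[i] &
          truth$pos <= co$right[i])
  }, logical(1))
  expect_true(all(contain))
  expect_gte(nrow(co) / nrow(truth), 0.95)
  # phase-change conservation: every change group accounted for
  expect_equal(sum(ev$n_changes),
               sum(vapply(ev$changes, function(x) sum(x$n_changes),
                          numeric(1))))
})

test_that("interference summaries separate within- from between-meiosis
           distances by construction", {
  withr::with_seed(41, {
    # two meioses with regularly spaced (interfering) crossovers vs
    # independent ones
    ev <- dplyr::bind_rows(
      tibble::tibble(parent = "p", offspring = "o1", chrom = "c1",
                     kind = "CO", left = c(5e6, 25e6, 45e6),
                     right = c(5e6, 25e6, 45e6) + 1000),
      tibble::tibble(parent = "p", offspring = "o2", chrom = "c1",
                     kind = "CO", left = c(6e6, 26e6, 46e6),
                     right = c(6e6, 26e6, 46e6) + 1000))
    ci <- co_interference(ev)
    w <- ci$distances$distance[ci$distances$type == "within"]
    b <- ci$distances$distance[ci$distances$type == "between"]
    expect_true(min(w) >= 19e6)
    expect_true(max(b) <= 2e6)
  })
})

test_that("mutation-recombination distances use the 200 Mb sentinel", {
  ev <- tibble::tibble(parent = "p1", offspring = "k1", chrom = "c1",
                       kind = "CO", left = 1e6, right = 1e6 + 1000)
  dn <- tibble::tibble(chrom = c("c1", "c2"), pos = c(2e6, 5e5),
                       parent = "p1", proband = "k1")
  out <- dnm_recomb_distance(dn, ev)
  w <- out$distances[out$distances$type == "within", ]
  expect_equal(sort(w$distance), c(1e6 - 500, 2e8))
})
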