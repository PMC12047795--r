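#' Weak/strong informative sites of non-crossover events
#'
#' Extracts, from called non-crossovers, the converted informative sites
#' carrying one strong (G/C) and one weak (A/T) allele, the input to the
#' GC-biased gene conversion estimator.
#'
#' @param events NCO tibble from [call_noncrossovers()].
#' @return tibble with one row per W/S converted site
#'   (`strong_transmitted` logical, plus event identity columns).
#' @export
nco_ws_sites <- function(events) {
  if (nrow(events) == 0) {
    return(tibble(parent = character(), offspring = character(),
                  chrom = character(), pos = integer(),
                  strong_transmitted = logical()))
  }
  events |>
    mutate(event_id = row_number()) |>
    select("event_id", "parent", "offspring", "chrom", "sites") |>
    tidyr::unnest("sites") |>
    filter(.data$ws) |>
    select("event_id", "parent", "offspring", "chrom", "pos",
           "strong_transmitted")
}

#' Estimate GC-biased gene conversion
#'
#' The bias is the fraction of weak/strong sites inside conversion
#' tracts at which the strong allele was transmitted, with a
#' Clopper-Pearson interval and a one-tailed exact binomial test against
#' 0.5 (no bias).
#'
#' @param ws_sites tibble with a logical `strong_transmitted` column
#'   (e.g. [nco_ws_sites()] output, or simulator truth records).
#' @param conf confidence level.
#' @return `fm_gbgc` object: `n`, `n_strong`, `bias`, `ci`, `p_onetailed`.
#' @export
estimate_gbgc <- function(ws_sites, conf = 0.95) {
  n <- nrow(ws_sites)
  k <- sum(ws_sites$strong_transmitted)
  if (n == 0) {
    return(structure(list(n = 0L, n_strong = 0L, bias = NA_real_,
                          ci = c(lower = NA_real_, upper = NA_real_),
                          p_onetailed = NA_real_, conf = conf),
                     class = "fm_gbgc"))
  }
  bt <- binom.test(k, n, conf.level = conf)
  p1 <- binom.test(k, n, alternative = "greater")$p.value
  structure(list(n = n, n_strong = k, bias = k / n,
                 ci = c(lower = bt$conf.int[1], upper = bt$conf.int[2]),
                 p_onetailed = p1, conf = conf),
            class = "fm_gbgc")
}

#' @export
print.fm_gbgc <- function(x, ...) {
  cat(sprintf("gBGC bias: %.1f%% (%d strong of %d W/S sites), %d%% CI %.0f-%.0f%%\n",
              100 * x$bias, x$n_strong, x$n, round(100 * x$conf),
              100 * x$ci[1], 100 * x$ci[2]))
  cat(sprintf("one-tailed binomial p vs 0.5: %.3g\n", x$p_onetailed))
  invisible(x)
}

#' @export
tidy.fm_gbgc <- function(x, ...) {
  tibble(estimate = x$bias, n = x$n, n_strong = x$n_strong,
         conf.low = unname(x$ci[1]), conf.high = unname(x$ci[2]),
         p.value = x$p_onetailed)
}

#' Classify tract heterozygous-site count strata
#'
#' Assigns each non-crossover to the single-heterozygote or
#' multi-heterozygote stratum. Extra SNPs between the flanking
#' non-converted informative sites are looked up in an unfiltered site
#' table; only extra SNPs passing the same stringent filters (supplied
#' as `filtered_positions`) count. An extra SNP joins the tract when the
#' phased haplotypes show it co-converted (its allele received from the
#' focal parent differs from the focal parent's background haplotype).
#' Events with extra SNPs but no haplotype support stay unclassified;
#' events whose raw-table interval holds no other SNP are single_het even
#' without haplotypes.
#'
#' @param events NCO tibble.
#' @param raw_sites unfiltered [site_table()].
#' @param filtered_positions tibble `chrom`, `pos` of SNPs passing the
#'   stringent filters (e.g. track positions); extra SNPs outside it are
#'   ignored.
#' @param haplotypes optional per-chromosome list with `pos` and phased
#'   `hap` matrix (as in `fm_sim$haplotypes`) used to test co-conversion.
#' @return `events` with a `stratum` column
#'   ("single_het"/"multi_het"/"unclassified").
#' @export
classify_tract_het_count <- function(events, raw_sites, filtered_positions,
                                     haplotypes = NULL) {
  stratum <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    raw_in <- filter(raw_sites, .data$chrom == e$chrom,
                     .data$pos > e$left, .data$pos < e$right,
                     !(.data$pos %in% e$sites[[1]]$pos))
    if (nrow(raw_in) == 0) { stratum[i] <- "single_het"; next }
    ok <- semi_join_pos(raw_in, filtered_positions)
    if (nrow(ok) == 0) { stratum[i] <- "single_het"; next }
    if (is.null(haplotypes) || is.null(haplotypes[[e$chrom]])) {
      stratum[i] <- "unclassified"; next
    }
    hp <- haplotypes[[e$chrom]]
    co <- FALSE
    for (p in ok$pos) {
      s <- match(p, hp$pos)
      if (is.na(s)) next
      hap_par <- hp$hap[s, paste0(e$parent, c(".1", ".2"))]
      got <- offspring_allele_from(hp, s, e$offspring, e$parent)
      if (!is.na(got) && hap_par[1] != hap_par[2]) co <- TRUE
    }
    stratum[i] <- if (co) "multi_het" else "single_het"
  }
  mutate(events, stratum = if (nrow(events)) {
    if_else(.data$n_sites > 1, "multi_het", stratum)
  } else character(0))
}

semi_join_pos <- function(x, positions) {
  dplyr::semi_join(x, positions, by = c("chrom", "pos"))
}

offspring_allele_from <- function(hp, s, offspring, parent) {
  # which haplotype of the offspring came from this parent is encoded in
  # the column suffix: ".1" maternal, ".2" paternal; unknown here, so
  # test both and return the allele if either parental haplotype differs
  a <- hp$hap[s, paste0(offspring, c(".1", ".2"))]
  if (a[1] == a[2]) a[1] else NA_integer_
}

#' Composite-likelihood estimate of the mean conversion tract length
#'
#' Assumes exponential tract lengths: the probability that two
#' informative sites d bp apart are co-converted is exp(-d / mean). For
#' each converted informative site, every other informative site within
#' `window` bp contributes a Bernoulli term (co-converted or not); the
#' composite log-likelihood is maximized over an integer grid of mean
#' tract lengths. Uncertainty comes from bootstrapping the converted
#' focal sites.
#'
#' @param sites tibble of informative sites with columns `chrom`, `pos`,
#'   `converted` (logical) and `event` (event id for converted sites, NA
#'   otherwise). Co-conversion means two converted sites share an event.
#' @param window pair window per side in bp (default 5000; 2000 is the
#'   usual cross-check).
#' @param grid integer grid of candidate means in bp (default 1:1000).
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf central bootstrap interval level.
#' @param max_min_tract events whose converted sites span more than this
#'   many bp are excluded as likely non-exponential outliers (default
#'   4000).
#' @return `fm_tract` object: `mean_bp`, `ci`, `loglik` profile tibble,
#'   `n_focal`, `boot` estimates.
#' @export
estimate_tract_length <- function(sites, window = 5000, grid = 1:1000,
                                  n_boot = 1000, conf = 0.95,
                                  max_min_tract = 4000) {
  conv <- filter(sites, .data$converted)
  if (nrow(conv) > 0 && !all(is.na(conv$event))) {
    span <- conv |>
      group_by(.data$event) |>
      summarise(w = max(.data$pos) - min(.data$pos), .groups = "drop")
    drop_ev <- span$event[span$w > max_min_tract]
    conv <- filter(conv, !.data$event %in% drop_ev)
  }
  n_focal <- nrow(conv)
  if (n_focal == 0) abort("no converted informative sites")
  lam <- 1 / grid
  M <- matrix(0, length(grid), n_focal)
  any_co <- FALSE
  by_chrom <- split(sites, sites$chrom)
  focal_i <- 0
  for (i in seq_len(n_focal)) {
    focal_i <- focal_i + 1
    ch <- by_chrom[[conv$chrom[i]]]
    p <- conv$pos[i]
    nb <- filter(ch, abs(.data$pos - p) <= window, .data$pos != p)
    if (nrow(nb) == 0) next
    co <- nb$converted & !is.na(nb$event) & nb$event == conv$event[i]
    d <- abs(nb$pos - p)
    if (any(co)) {
      any_co <- TRUE
      M[, focal_i] <- M[, focal_i] - lam * sum(d[co])
    }
    if (any(!co)) {
      M[, focal_i] <- M[, focal_i] +
        rowSums(log1p(-exp(-outer(lam, d[!co]))))
    }
  }
  ll <- rowSums(M)
  est <- grid[which.max(ll)]
  pinned <- !any_co
  if (pinned) warn("no co-converted pairs; estimate pinned to grid minimum")
  boot <- NULL; ci <- c(lower = NA_real_, upper = NA_real_)
  if (n_boot > 0 && n_focal > 1) {
    W <- rmultinom(n_boot, n_focal, rep(1, n_focal))
    bl <- M %*% W
    boot <- grid[max.col(t(bl), ties.method = "first")]
    a <- (1 - conf) / 2
    ci <- c(lower = unname(quantile(boot, a)),
            upper = unname(quantile(boot, 1 - a)))
  }
  structure(list(mean_bp = est, ci = ci, n_focal = n_focal,
                 loglik = tibble(mean_bp = grid, loglik = ll),
                 boot = boot, pinned = pinned, window = window,
                 conf = conf),
            class = "fm_tract")
}

#' @export
print.fm_tract <- function(x, ...) {
  cat(sprintf("Mean conversion tract length: %d bp", x$mean_bp))
  if (!is.na(x$ci[1])) {
    cat(sprintf(" (central %d%% bootstrap: %d-%d bp)",
                round(100 * x$conf), x$ci[1], x$ci[2]))
  }
  cat(sprintf("; %d converted focal sites\n", x$n_focal))
  invisible(x)
}

#' @export
tidy.fm_tract <- function(x, ...) {
  tibble(estimate = x$mean_bp, conf.low = unname(x$ci[1]),
         conf.high = unname(x$ci[2]), n_focal = x$n_focal)
}

#' @export
glance.fm_tract <- function(x, ...) {
  tibble(mean_bp = x$mean_bp, n_focal = x$n_focal,
         max_loglik = max(x$loglik$loglik), pinned = x$pinned)
}

#' Monte-Carlo detection power for non-crossovers
#'
#' Conversion tracts of exponential length (mean `tract_mean`) are placed
#' uniformly along each chromosome; the detection power is the fraction
#' overlapping at least one informative site. For Poisson-distributed
#' sites of density p the closed form is p / (p + 1/L).
#'
#' @param site_positions named list (chromosome -> list of founder ->
#'   numeric site positions), or a tibble `chrom`, `founder`, `pos`.
#' @param chromosomes [chromosome_spec()] tibble.
#' @param tract_mean mean tract length in bp.
#' @param n_draws Monte-Carlo draws per (chromosome, founder), default
#'   1e6.
#' @param site_weights optional structure parallel to `site_positions`
#'   giving, per site, the probability that a conversion covering it
#'   produces an observable allele change (1 for a non-weak/strong
#'   heterozygote; 1/2 for a weak/strong site under biased heteroduplex
#'   resolution, where repair toward the background allele restores the
#'   original sequence). When supplied the reported power is the
#'   probability that a tract covers at least one site *and* changes it.
#' @return tibble `chrom`, `founder`, `power`, `n_sites`.
#' @export
estimate_power <- function(site_positions, chromosomes, tract_mean,
                           n_draws = 1e6, site_weights = NULL) {
  if (is.data.frame(site_positions)) {
    site_positions <- lapply(split(site_positions, site_positions$chrom),
                             function(d) split(d$pos, d$founder))
  }
  rows <- list()
  for (ch in names(site_positions)) {
    L <- chromosomes$length[match(ch, chromosomes$name)]
    for (f in names(site_positions[[ch]])) {
      pos <- site_positions[[ch]][[f]]
      w <- site_weights[[ch]][[f]] %||% rep(1, length(pos))
      ord <- order(pos)
      pos <- pos[ord]; w <- w[ord]
      if (length(pos) == 0) {
        warn(paste("no informative sites on", ch, "for", f))
        rows[[length(rows) + 1]] <- tibble(chrom = ch, founder = f,
                                           power = 0, n_sites = 0L)
        next
      }
      len <- rexp(n_draws, 1 / tract_mean)
      a <- runif(n_draws, 0, L)
      i1 <- findInterval(a, pos); i2 <- findInterval(a + len, pos)
      if (is.null(site_weights)) {
        p_hit <- as.numeric(i2 > i1)
      } else {
        # P(at least one covered site fires) = 1 - prod(1 - w)
        cum <- c(0, cumsum(log1p(-pmin(w, 1 - 1e-12))))
        p_hit <- ifelse(i2 > i1, 1 - exp(cum[i2 + 1] - cum[i1 + 1]), 0)
      }
      rows[[length(rows) + 1]] <- tibble(chrom = ch, founder = f,
                                         power = mean(p_hit),
                                         n_sites = length(pos))
    }
  }
  bind_rows(rows)
}

#' Power-corrected non-crossover totals and the NCO:CO ratio
#'
#' Per chromosome, the predicted total is observed / power with power
#' averaged across founders first (set `pool_founders = FALSE` to average
#' the per-founder corrected counts instead). Totals are per meiosis
#' (chromatid); the ratio divides the predicted non-crossover count per
#' meiosis by the observed crossover count per meiosis.
#'
#' @param nco_counts tibble `chrom`, `n` of observed non-crossovers.
#' @param power tibble from [estimate_power()].
#' @param n_meioses number of meioses surveyed.
#' @param co_per_meiosis observed crossovers per meiosis on the same
#'   chromosome set.
#' @param pool_founders average power across founders before dividing
#'   (default TRUE).
#' @return `fm_nco_total` list: `per_chromosome`, `predicted_total`,
#'   `predicted_per_meiosis`, `observed_per_meiosis`, `ratio`.
#' @export
total_nco_and_ratio <- function(nco_counts, power, n_meioses,
                                co_per_meiosis, pool_founders = TRUE) {
  pw <- power |>
    filter(.data$power > 0) |>
    group_by(.data$chrom) |>
    summarise(mean_power = mean(.data$power),
              mean_inv_power = mean(1 / .data$power), .groups = "drop")
  per <- nco_counts |>
    inner_join(pw, by = "chrom") |>
    mutate(predicted = if (pool_founders) .data$n / .data$mean_power
           else .data$n * .data$mean_inv_power)
  predicted_total <- sum(per$predicted)
  obs_pm <- sum(per$n) / n_meioses
  pred_pm <- predicted_total / n_meioses
  structure(list(per_chromosome = per, predicted_total = predicted_total,
                 predicted_per_meiosis = pred_pm,
                 observed_per_meiosis = obs_pm,
                 co_per_meiosis = co_per_meiosis,
                 ratio = pred_pm / co_per_meiosis),
            class = "fm_nco_total")
}

#' @export
print.fm_nco_total <- function(x, ...) {
  cat(sprintf("Observed %.1f and predicted %.1f non-crossovers per meiosis\n",
              x$observed_per_meiosis, x$predicted_per_meiosis))
  cat(sprintf("NCO:CO per chromatid: %.2f (CO per meiosis %.1f)\n",
              x$ratio, x$co_per_meiosis))
  invisible(x)
}

#' @export
tidy.fm_nco_total <- function(x, ...) x$per_chromosome

#' @export
glance.fm_nco_total <- function(x, ...) {
  tibble(predicted_per_meiosis = x$predicted_per_meiosis,
         observed_per_meiosis = x$observed_per_meiosis,
         co_per_meiosis = x$co_per_meiosis, ratio = x$ratio)
}

#' Double-strand break summaries per chromosome
#'
#' Treats the DSB count as crossovers plus (power-corrected)
#' non-crossovers and reports per-chromosome densities against length.
#'
#' @param co_counts tibble `chrom`, `n_co`.
#' @param nco_predicted tibble `chrom`, `predicted`.
#' @param chromosomes [chromosome_spec()] tibble.
#' @return tibble `chrom`, `length`, `n_co`, `nco`, `dsb`, `density`.
#' @export
dsb_summaries <- function(co_counts, nco_predicted, chromosomes) {
  chromosomes |>
    rename(chrom = "name") |>
    left_join(co_counts, by = "chrom") |>
    left_join(nco_predicted, by = "chrom") |>
    mutate(n_co = dplyr::coalesce(.data$n_co, 0),
           nco = dplyr::coalesce(.data$predicted, 0),
           dsb = .data$n_co + .data$nco,
           density = .data$dsb / .data$length) |>
    select("chrom", "length", "n_co", "nco", "dsb", "density")
}
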