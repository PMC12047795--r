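#' Observed overlap of events with features
#'
#' An event overlaps when the gap between its interval edges and the
#' closest feature edge is at most `slop` bp (0 for touching or
#' overlapping intervals).
#'
#' @param events interval tibble (`chrom`, `start`, `end`).
#' @param features interval tibble.
#' @param slop edge distance in bp (100 for CpG islands, 500 for TSSs).
#' @return tibble `n`, `n_overlap`, `fraction`.
#' @export
overlap_observed <- function(events, features, slop = 100) {
  if (nrow(events) == 0) return(tibble(n = 0L, n_overlap = 0L,
                                       fraction = NA_real_))
  d <- interval_closest(as_intervals(events), features)$distance
  hit <- abs(d) <= slop
  hit[is.na(hit)] <- FALSE
  tibble(n = nrow(events), n_overlap = sum(hit), fraction = mean(hit))
}

# per-chromosome cumulative tracks for GC and mappability
genome_tracks <- function(genome_seq, mappability = NULL) {
  if (!is.character(genome_seq)) {
    genome_seq <- setNames(as.character(genome_seq), names(genome_seq))
  }
  lapply(setNames(names(genome_seq), names(genome_seq)), function(ch) {
    x <- seq_chars(genome_seq[[ch]])
    L <- length(x)
    mp <- logical(L)
    if (!is.null(mappability)) {
      mv <- mappability[mappability$chrom == ch, ]
      for (i in seq_len(nrow(mv))) {
        mp[(mv$start[i] + 1):min(mv$end[i], L)] <- TRUE
      }
    } else mp[] <- TRUE
    list(L = L, cum_gc = c(0, cumsum(x %in% c("G", "C"))),
         cum_map = c(0, cumsum(mp)))
  })
}

range_frac <- function(cum, a, b, L) {
  # fraction over 0-based [a, b), clipped to the chromosome
  a <- pmax(a, 0); b <- pmin(b, L)
  ifelse(b > a, (cum[b + 1] - cum[a + 1]) / (b - a), NA_real_)
}

#' Matched-window permutation null for feature overlap
#'
#' For each event, candidate placements of an equal-length window are
#' enumerated on a stride within `max_shift` bp of the original interval,
#' requiring GC content (of the 100 kb surrounding the window) within
#' `gc_tol` of the original, mappable fraction within `map_tol`, and no
#' overlap with the original interval. `n_sets` placements per event form
#' the null distribution of the overlap fraction; the empirical p-value
#' is (1 + #null >= observed) / (1 + n_sets) and the fold enrichment is
#' observed / mean(null). Events without any eligible candidate stay in
#' the observed fraction but are left out of the shuffling (logged).
#'
#' @param events interval tibble of recombination events.
#' @param features interval tibble (e.g. CpG islands).
#' @param genome_seq named character vector (or DNAStringSet) of
#'   chromosome sequences.
#' @param mappability interval tibble or NULL (fully mappable).
#' @param n_sets number of shuffled sets (default 5000).
#' @param slop overlap distance (default 100).
#' @param max_shift placement range each side (default 2.5 Mb).
#' @param gc_tol absolute GC-content tolerance (default 0.025).
#' @param gc_window width of the GC-matching context (default 100 kb).
#' @param map_tol mappable-fraction tolerance (default 0.2).
#' @param stride candidate spacing in bp (default 100; 1 enumerates
#'   every placement).
#' @return `fm_enrichment` object: `observed`, `null` (length `n_sets`),
#'   `p`, `fold`, `n_events`, `n_shuffled`.
#' @export
matched_shuffle_null <- function(events, features, genome_seq,
                                 mappability = NULL, n_sets = 5000,
                                 slop = 100, max_shift = 2.5e6,
                                 gc_tol = 0.025, gc_window = 1e5,
                                 map_tol = 0.2, stride = 100) {
  tracks <- genome_tracks(genome_seq, mappability)
  obs <- overlap_observed(events, features, slop)
  feat <- interval_union(features)
  feat_by <- split(feat, feat$chrom)
  hit_frac <- function(ch, starts, w) {
    f <- feat_by[[ch]]
    if (is.null(f) || nrow(f) == 0) return(rep(FALSE, length(starts)))
    gap <- vapply(starts, function(a) {
      min(pmax(f$start - (a + w), a - f$end, 0))
    }, numeric(1))
    gap <= slop
  }
  ind <- vector("list", nrow(events))
  n_skipped <- 0
  for (i in seq_len(nrow(events))) {
    ch <- events$chrom[i]
    tk <- tracks[[ch]]
    s <- events$start[i]; e <- events$end[i]; w <- max(e - s, 1)
    cand <- seq(max(0, s - max_shift), min(tk$L - w, e + max_shift),
                by = stride)
    cand <- cand[cand + w <= s | cand >= e]       # no overlap with original
    if (length(cand) == 0) { n_skipped <- n_skipped + 1; ind[[i]] <- NULL; next }
    mid0 <- (s + e) / 2
    gc0 <- range_frac(tk$cum_gc, round(mid0 - gc_window / 2),
                      round(mid0 + gc_window / 2), tk$L)
    map0 <- range_frac(tk$cum_map, s, e, tk$L)
    mid <- cand + w / 2
    gc <- range_frac(tk$cum_gc, round(mid - gc_window / 2),
                     round(mid + gc_window / 2), tk$L)
    mapf <- range_frac(tk$cum_map, cand, cand + w, tk$L)
    ok <- abs(gc - gc0) <= gc_tol & abs(mapf - map0) <= map_tol
    ok[is.na(ok)] <- FALSE
    cand <- cand[ok]
    if (length(cand) == 0) { n_skipped <- n_skipped + 1; ind[[i]] <- NULL; next }
    ind[[i]] <- hit_frac(ch, cand, w)
  }
  used <- which(!vapply(ind, is.null, logical(1)))
  if (n_skipped > 0) {
    inform(paste(n_skipped, "event(s) had no eligible placement and were",
                 "not shuffled"))
  }
  if (length(used) == 0) abort("no event could be shuffled")
  null <- rowMeans(vapply(used, function(i) {
    ind[[i]][sample.int(length(ind[[i]]), n_sets, replace = TRUE)]
  }, numeric(n_sets)))
  p <- (1 + sum(null >= obs$fraction)) / (1 + n_sets)
  structure(list(observed = obs$fraction, null = null, p = p,
                 fold = obs$fraction / mean(null), n_events = nrow(events),
                 n_shuffled = length(used), n_sets = n_sets, slop = slop),
            class = "fm_enrichment")
}

#' @export
print.fm_enrichment <- function(x, ...) {
  cat(sprintf("Observed overlap %.1f%% vs %.1f%% expected by chance (%0.2f-fold), p = %.4g\n",
              100 * x$observed, 100 * mean(x$null), x$fold, x$p))
  invisible(x)
}

#' @export
tidy.fm_enrichment <- function(x, ...) {
  tibble(observed = x$observed, expected = mean(x$null), fold = x$fold,
         p.value = x$p, n_events = x$n_events, n_sets = x$n_sets)
}

#' Conditional TSS / CpG-island enrichment
#'
#' Partitions islands by distance to the nearest TSS (within `dist` or
#' beyond) and TSSs by distance to the nearest island, then runs the
#' observed overlap and matched shuffle for each non-empty partition
#' (slop 100 bp for islands, 500 bp for TSSs).
#'
#' @param events,islands,tss interval tibbles.
#' @param genome_seq,mappability see [matched_shuffle_null()].
#' @param dist partition distance (default 10 kb; a feature exactly
#'   `dist` away counts as "near").
#' @param ... further arguments to [matched_shuffle_null()].
#' @return named list of `fm_enrichment` objects (partitions that are
#'   empty are skipped).
#' @export
conditional_tss_analysis <- function(events, islands, tss, genome_seq,
                                     mappability = NULL, dist = 1e4, ...) {
  parts <- list()
  if (nrow(islands) > 0 && nrow(tss) > 0) {
    d_it <- abs(interval_closest(islands, tss)$distance)
    parts$island_near_tss <- list(feat = islands[d_it <= dist, ], slop = 100)
    parts$island_far_tss <- list(feat = islands[d_it > dist, ], slop = 100)
    d_ti <- abs(interval_closest(tss, islands)$distance)
    parts$tss_near_island <- list(feat = tss[d_ti <= dist, ], slop = 500)
    parts$tss_far_island <- list(feat = tss[d_ti > dist, ], slop = 500)
  } else if (nrow(islands) > 0) {
    parts$island <- list(feat = islands, slop = 100)
  } else if (nrow(tss) > 0) {
    parts$tss <- list(feat = tss, slop = 500)
  }
  out <- list()
  for (nm in names(parts)) {
    f <- parts[[nm]]$feat
    if (nrow(f) == 0) next
    out[[nm]] <- matched_shuffle_null(events, f, genome_seq, mappability,
                                      slop = parts[[nm]]$slop, ...)
  }
  out
}

#' Call hotspots from an LD-based recombination map
#'
#' The mean rate in 1 kb windows is compared to the mean rate of the
#' 20 kb on each side (2 kb buffer between window and flank); windows
#' with a relative rate above `threshold` are kept and merged when
#' adjacent. The caller is scale-invariant in the rate units.
#'
#' @param rho_map tibble `chrom`, `start`, `end`, `rate` (per-bp
#'   population recombination rate over intervals).
#' @param win window size (default 1 kb).
#' @param flank flank width per side (default 20 kb).
#' @param buffer gap between window and flank (default 2 kb).
#' @param threshold relative-rate cutoff (default 5).
#' @return interval tibble of hotspots with a `max_ratio` column.
#' @export
ld_hotspots <- function(rho_map, win = 1000, flank = 20000, buffer = 2000,
                        threshold = 5) {
  out <- list()
  for (ch in unique(rho_map$chrom)) {
    m <- filter(rho_map, .data$chrom == ch)
    lo <- min(m$start); hi <- max(m$end)
    nb <- floor((hi - lo) / win)
    if (nb < 1) next
    # rasterize to the window grid (length-weighted)
    grid_rate <- numeric(nb)
    for (i in seq_len(nrow(m))) {
      a <- m$start[i]; b <- m$end[i]
      w1 <- floor((a - lo) / win) + 1; w2 <- ceiling((b - lo) / win)
      for (w in max(1, w1):min(nb, w2)) {
        ws <- lo + (w - 1) * win; we <- ws + win
        ov <- max(0, min(b, we) - max(a, ws))
        grid_rate[w] <- grid_rate[w] + ov * m$rate[i] / win
      }
    }
    nf <- flank / win; nbuf <- buffer / win
    cs <- c(0, cumsum(grid_rate))
    flank_mean <- vapply(seq_len(nb), function(w) {
      l1 <- max(1, w - nbuf - nf); l2 <- w - nbuf - 1
      r1 <- w + nbuf + 1; r2 <- min(nb, w + nbuf + nf)
      tot <- 0; cnt <- 0
      if (l2 >= l1) { tot <- tot + cs[l2 + 1] - cs[l1]; cnt <- cnt + l2 - l1 + 1 }
      if (r2 >= r1) { tot <- tot + cs[r2 + 1] - cs[r1]; cnt <- cnt + r2 - r1 + 1 }
      if (cnt == 0) NA_real_ else tot / cnt
    }, numeric(1))
    ratio <- grid_rate / flank_mean
    keep <- !is.na(ratio) & flank_mean > 0 & ratio > threshold
    if (!any(keep)) next
    r <- rle(keep)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    for (i in which(r$values)) {
      w1 <- starts[i]; w2 <- ends[i]
      out[[length(out) + 1]] <- tibble(
        chrom = ch, start = lo + (w1 - 1) * win, end = lo + w2 * win,
        max_ratio = max(ratio[w1:w2]))
    }
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  max_ratio = numeric()))
  }
  bind_rows(out)
}

#' Expected crossover overlap under a uniform hotspot-heat model
#'
#' If islands covering a fraction `c` of the genome carry a uniform
#' relative recombination heat `h` and the rest of the genome heat 1, the
#' expected fraction of crossovers falling in islands is
#' c h / (c h + (1 - c)).
#'
#' @param coverage island coverage fraction `c` in `[0, 1]`.
#' @param heat relative heat `h` (> 0).
#' @return expected overlap fraction.
#' @export
heat_expected_overlap <- function(coverage, heat) {
  if (any(coverage < 0 | coverage > 1)) {
    abort("coverage must be a fraction in [0, 1]")
  }
  coverage * heat / (coverage * heat + (1 - coverage))
}
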