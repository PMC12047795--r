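#' Exact two-sided binomial p-value for allelic balance
#'
#' Vectorized p-value of the two-sided exact binomial test of
#' ref/alt read counts against 0.5, as used to mask heterozygous calls
#' with allelic imbalance.
#'
#' @param ad_ref,ad_alt read counts.
#' @return numeric p-values (1 where depth is 0).
#' @export
binom_imbalance_p <- function(ad_ref, ad_alt) {
  n <- ad_ref + ad_alt
  kmin <- pmin(ad_ref, ad_alt)
  p <- pmin(1, 2 * pbinom(kmin, n, 0.5))
  p[2 * kmin == n] <- 1
  p[n == 0 | is.na(n)] <- 1
  p
}

#' Informative-site tracks for a nuclear family
#'
#' Informative sites are heterozygous in the focal parent and homozygous
#' in the other. Sites are dropped for the whole family when any member
#' is covered by fewer than `min_depth` reads or an indel lies within
#' `indel_pad` bp; heterozygous genotypes with allelic imbalance (exact
#' binomial p <= `imbalance_p`) are masked. For each offspring the allele
#' received from the focal parent is recorded (0 = ref, 1 = alt, NA when
#' unresolvable or Mendelian-inconsistent).
#'
#' @param sites cohort [site_table()].
#' @param mother,father parent ids.
#' @param offspring offspring ids (>= 2 needed for template-based calling).
#' @param min_depth per-member minimum depth (default 8; the relaxed
#'   crossover-refinement pass uses 5).
#' @param imbalance_p masking threshold for the exact binomial p (default
#'   0.01; non-crossover calling uses 0.05).
#' @param gq_min genotypes below this quality are masked (default 20,
#'   mirroring the variant callers' quality filtering; low-quality calls
#'   are overwhelmingly miscalled heterozygotes that would otherwise
#'   masquerade as double phase switches).
#' @param indels optional tibble `chrom`, `pos` of indel positions.
#' @param indel_pad indel exclusion radius in bp (default 10).
#' @param depth_range optional `c(low, high)` multipliers of each
#'   sample's per-chromosome mean depth (the non-crossover filter uses
#'   `c(0.5, 2)`); NULL disables.
#' @param mendelian drop sites with Mendelian-inconsistent offspring
#'   genotypes for the whole family (used by the non-crossover filter).
#' @return tibble, one row per (parent, chrom), with list columns `pos`,
#'   `ref`, `alt` and `alleles` (sites x offspring matrix of transmitted
#'   alleles).
#' @export
informative_tracks <- function(sites, mother, father, offspring,
                               min_depth = 8, imbalance_p = 0.01,
                               gq_min = 20, indels = NULL, indel_pad = 10,
                               depth_range = NULL, mendelian = FALSE) {
  if (length(offspring) < 2) {
    abort("template-based calling needs at least two offspring")
  }
  fam <- c(mother, father, offspring)
  bi <- !sites$multiallelic
  dp <- sites$dp[, fam, drop = FALSE]
  keep <- bi & rowSums(dp >= min_depth, na.rm = FALSE) == length(fam)
  keep[is.na(keep)] <- FALSE
  if (!is.null(depth_range)) {
    for (ch in unique(sites$chrom)) {
      rows <- sites$chrom == ch
      mu <- colMeans(dp[rows, , drop = FALSE], na.rm = TRUE)
      ok <- sweep(dp[rows, , drop = FALSE], 2, depth_range[1] * mu, ">=") &
        sweep(dp[rows, , drop = FALSE], 2, depth_range[2] * mu, "<=")
      keep[rows] <- keep[rows] & rowSums(ok, na.rm = FALSE) == length(fam)
    }
    keep[is.na(keep)] <- FALSE
  }
  if (!is.null(indels) && nrow(indels) > 0) {
    q <- intervals(sites$chrom, sites$pos - 1, sites$pos)
    iv <- intervals(indels$chrom, indels$pos - 1, indels$pos)
    near <- abs(interval_closest(q, iv)$distance) <= indel_pad
    ord <- order(sites$chrom, sites$pos)
    keep <- keep & !(near[match(seq_len(nrow(sites)), ord)] %in% TRUE)
  }
  idx <- which(keep)
  chrom_v <- sites$chrom[idx]; pos_v <- sites$pos[idx]
  ref_v <- sites$ref[idx]; alt_v <- sites$alt[idx]
  gt <- sites$gt[idx, fam, drop = FALSE]
  gt[sites$gq[idx, fam, drop = FALSE] < gq_min] <- NA
  imb <- binom_imbalance_p(sites$ad_ref[idx, fam, drop = FALSE],
                           sites$ad_alt[idx, fam, drop = FALSE])
  gt[gt == 1 & imb <= imbalance_p] <- NA
  if (mendelian) {
    gmo <- gt[, mother]; gfa <- gt[, father]
    ok <- rep(TRUE, length(idx))
    for (o in offspring) {
      go <- gt[, o]
      mind <- (gmo == 2) + (gfa == 2)
      maxd <- (gmo > 0) + (gfa > 0)
      bad <- !is.na(go) & !is.na(gmo) & !is.na(gfa) &
        (go < mind | go > maxd)
      ok <- ok & !bad
    }
    chrom_v <- chrom_v[ok]; pos_v <- pos_v[ok]
    ref_v <- ref_v[ok]; alt_v <- alt_v[ok]
    gt <- gt[ok, , drop = FALSE]
  }
  rows <- list()
  for (par in c(mother, father)) {
    other <- if (par == mother) father else mother
    inf <- gt[, par] == 1 & gt[, other] %in% c(0, 2)
    inf[is.na(inf)] <- FALSE
    for (ch in unique(chrom_v)) {
      sel <- inf & chrom_v == ch
      if (!any(sel)) next
      g_other <- gt[sel, other]
      A <- matrix(NA_integer_, sum(sel), length(offspring),
                  dimnames = list(NULL, offspring))
      for (o in offspring) {
        go <- gt[sel, o]
        A[, o] <- ifelse(g_other == 0,
                         ifelse(go == 2, NA_integer_, go),
                         ifelse(go == 0, NA_integer_, go - 1L))
      }
      rows[[length(rows) + 1]] <- tibble(
        parent = par, chrom = ch, pos = list(pos_v[sel]),
        ref = list(ref_v[sel]), alt = list(alt_v[sel]), alleles = list(A))
    }
  }
  bind_rows(rows)
}

#' Phase switches along a recoded state sequence
#'
#' States are 1 (matches the template-transmitted allele), 2 (matches the
#' untransmitted allele) and 0 (missing). A switch is recorded between
#' consecutive non-missing states that differ; missing states are skipped
#' so a switch can span them.
#'
#' @param states integer vector of 0/1/2 states (NA treated as 0).
#' @return tibble `left_idx`, `right_idx`: flanking site indices of each
#'   switch.
#' @export
detect_switches <- function(states) {
  states[is.na(states)] <- 0L
  nz <- which(states != 0L)
  if (length(nz) < 2) return(tibble(left_idx = integer(),
                                    right_idx = integer()))
  v <- states[nz]
  sw <- which(diff(v) != 0L)
  tibble(left_idx = nz[sw], right_idx = nz[sw + 1])
}

# majority-vote phase changes for one template within one track row.
# Each run of qualifying gaps [g_start, g_end] (gap g separates sites g
# and g+1) is one change group; n_changes is the modal number of
# switches the non-template offspring show across the run, so an
# isolated template conversion or genotyping error (every offspring
# switching in and back out) counts as two changes, while a crossover
# whose localization is blurred by missing data counts as one.
template_changes <- function(A, template) {
  empty <- tibble(g_start = integer(), g_end = integer(),
                  n_changes = integer(), support = integer())
  others <- setdiff(colnames(A), template)
  n <- nrow(A)
  if (n < 2 || length(others) == 0) return(empty)
  span <- def <- numeric(n - 1)
  tmpl <- A[, template]
  switch_spans <- list()
  for (o in others) {
    s <- ifelse(is.na(A[, o]) | is.na(tmpl), 0L,
                ifelse(A[, o] == tmpl, 1L, 2L))
    sw <- detect_switches(s)
    switch_spans[[o]] <- sw
    nz <- which(s != 0L)
    if (length(nz) >= 2) {
      def[nz[1]:(nz[length(nz)] - 1)] <-
        def[nz[1]:(nz[length(nz)] - 1)] + 1
    }
    for (k in seq_len(nrow(sw))) {
      span[sw$left_idx[k]:(sw$right_idx[k] - 1)] <-
        span[sw$left_idx[k]:(sw$right_idx[k] - 1)] + 1
    }
  }
  qual <- span * 2 > def & def > 0
  if (!any(qual)) return(empty)
  r <- rle(qual)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- tibble(g_start = starts[r$values], g_end = ends[r$values])
  counts <- function(i) {
    k <- vapply(switch_spans, function(sw) {
      sum(sw$left_idx <= runs$g_end[i] & sw$right_idx - 1 >= runs$g_start[i])
    }, integer(1))
    k[k > 0]
  }
  per_run <- lapply(seq_len(nrow(runs)), counts)
  runs$n_changes <- vapply(per_run, function(k) {
    tb <- table(k)
    as.integer(names(tb)[which.max(tb)][1])
  }, integer(1))
  runs$support <- vapply(per_run, length, integer(1))
  runs
}

#' Call crossovers from informative-site tracks
#'
#' Each offspring serves as the template in turn; phase changes supported
#' by the majority of the other offspring are attributed to the template's
#' meiosis. Changes within `cluster_gap` informative sites of each other
#' are clustered: odd-count clusters are crossovers (single change) or
#' complex crossovers (several), even-count clusters are candidate
#' non-crossovers. Events within `edge` informative markers of a
#' chromosome end are removed (after clustering).
#'
#' @param tracks output of [informative_tracks()].
#' @param cluster_gap site-index clustering distance (default 10).
#' @param edge edge exclusion in informative markers (default 10).
#' @return event tibble: `parent`, `offspring`, `chrom`, `kind`
#'   ("CO", "complex_CO", "nco_candidate"), `n_changes`, `left`, `right`
#'   (bp of flanking informative sites), `left_idx`, `right_idx`,
#'   `support`, and a `changes` list column of per-change gap ranges.
#' @export
call_crossovers <- function(tracks, cluster_gap = 10, edge = 10) {
  out <- list()
  for (i in seq_len(nrow(tracks))) {
    A <- tracks$alleles[[i]]
    pos <- tracks$pos[[i]]
    n <- length(pos)
    for (tmpl in colnames(A)) {
      ch <- template_changes(A, tmpl)
      if (nrow(ch) == 0) next
      grp <- cumsum(c(1, (ch$g_start[-1] - ch$g_end[-nrow(ch)]) >
                        cluster_gap))
      for (g in unique(grp)) {
        cl <- ch[grp == g, ]
        l_idx <- cl$g_start[1]; r_idx <- cl$g_end[nrow(cl)] + 1L
        if (l_idx <= edge || r_idx > n - edge) next
        nc <- sum(cl$n_changes)
        kind <- if (nc %% 2 == 1) {
          if (nc == 1) "CO" else "complex_CO"
        } else "nco_candidate"
        out[[length(out) + 1]] <- tibble(
          parent = tracks$parent[i], offspring = tmpl,
          chrom = tracks$chrom[i], kind = kind, n_changes = nc,
          left = pos[l_idx], right = pos[r_idx],
          left_idx = l_idx, right_idx = r_idx,
          support = min(cl$support), changes = list(cl))
      }
    }
  }
  if (length(out) == 0) {
    return(tibble(parent = character(), offspring = character(),
                  chrom = character(), kind = character(),
                  n_changes = integer(), left = numeric(), right = numeric(),
                  left_idx = integer(), right_idx = integer(),
                  support = integer(), changes = list()))
  }
  bind_rows(out)
}

#' Refine crossover intervals with relaxed genotype filters
#'
#' Re-evaluates each single-change crossover on a track built with
#' relaxed filters (lower depth, narrower indel exclusion); the interval
#' is replaced only when the relaxed sites inside the original interval
#' produce exactly one phase change for the same template individual.
#'
#' @param events crossover events from [call_crossovers()].
#' @param relaxed_tracks [informative_tracks()] built with relaxed
#'   filters.
#' @return `events` with updated `left`/`right` and a `refined` flag.
#' @export
refine_crossover_intervals <- function(events, relaxed_tracks) {
  events$refined <- FALSE
  for (i in seq_len(nrow(events))) {
    if (!events$kind[i] %in% c("CO", "complex_CO")) next
    tr <- filter(relaxed_tracks, .data$parent == events$parent[i],
                 .data$chrom == events$chrom[i])
    if (nrow(tr) != 1) next
    pos <- tr$pos[[1]]
    sel <- which(pos >= events$left[i] & pos <= events$right[i])
    if (length(sel) < 2) next
    A <- tr$alleles[[1]][sel, , drop = FALSE]
    if (!events$offspring[i] %in% colnames(A)) next
    ch <- template_changes(A, events$offspring[i])
    if (nrow(ch) == 1 && ch$n_changes[1] == 1) {
      events$left[i] <- pos[sel][ch$g_start[1]]
      events$right[i] <- pos[sel][ch$g_end[1] + 1]
      events$refined[i] <- TRUE
    }
  }
  events
}

#' Mask regions with implausible crossover clusters
#'
#' Within each meiosis, crossovers within `max_gap` bp of each other
#' (single linkage on interval midpoints) are grouped; clusters of
#' `min_size` or more events are removed and their merged span masked.
#' Masked spans are merged across meioses and any event from any meiosis
#' overlapping the final mask is also removed.
#'
#' @param events crossover events (kinds CO/complex_CO are considered).
#' @param max_gap linkage distance in bp (default 2 Mb).
#' @param min_size minimum cluster size to mask (default 3).
#' @return list `events` (kept events), `masked` (interval tibble).
#' @export
mask_clustered_crossovers <- function(events, max_gap = 2e6, min_size = 3) {
  co <- filter(events, .data$kind %in% c("CO", "complex_CO"))
  other <- filter(events, !.data$kind %in% c("CO", "complex_CO"))
  if (nrow(co) == 0) return(list(events = events, masked = intervals()))
  co <- co |>
    mutate(mid = (.data$left + .data$right) / 2) |>
    arrange(.data$parent, .data$offspring, .data$chrom, .data$mid)
  key <- paste(co$parent, co$offspring, co$chrom)
  grp <- integer(nrow(co)); gid <- 0
  for (k in unique(key)) {
    idx <- which(key == k)
    brk <- c(TRUE, diff(co$mid[idx]) > max_gap)
    grp[idx] <- gid + cumsum(brk)
    gid <- max(grp[idx])
  }
  sizes <- table(grp)
  bad <- grp %in% as.integer(names(sizes)[sizes >= min_size])
  mask <- if (any(bad)) {
    bd <- mutate(co[bad, ], grp = grp[bad])
    spans <- bd |>
      group_by(.data$grp) |>
      summarise(chrom = .data$chrom[1], start = min(.data$left),
                end = max(.data$right), .groups = "drop")
    interval_union(as_intervals(spans))
  } else intervals()
  kept <- co[!bad, ]
  if (nrow(mask) > 0 && nrow(kept) > 0) {
    q <- intervals(kept$chrom, kept$left, pmax(kept$right, kept$left + 1))
    d <- interval_closest(q, mask)$distance
    ord <- order(kept$chrom, kept$left)
    overlap <- logical(nrow(kept))
    overlap[ord] <- d == 0
    kept <- kept[!overlap, ]
  }
  list(events = bind_rows(select(kept, -"mid"), other), masked = mask)
}
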