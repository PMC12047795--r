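#' Chromosomes eligible for non-crossover calling
#'
#' Single-site conversion events are only trusted on chromosomes with
#' reliable mapping: mean depth above `min_depth` and mean mapping
#' quality above `min_mapq` across individuals.
#'
#' @param chromosomes [chromosome_spec()] tibble.
#' @param min_depth,min_mapq thresholds (defaults 20 and 40).
#' @return filtered chromosome tibble.
#' @export
select_nco_chromosomes <- function(chromosomes, min_depth = 20,
                                   min_mapq = 40) {
  filter(chromosomes, .data$mean_depth > min_depth,
         .data$mean_mapq > min_mapq)
}

#' Stringent genotype filter for non-crossover calling
#'
#' Convenience wrapper around [informative_tracks()] with the
#' non-crossover criteria: Mendelian-consistent genotypes only, depth
#' between half and twice the per-chromosome sample average, and
#' heterozygous calls masked at exact-binomial allelic-imbalance
#' p <= 0.05.
#'
#' @inheritParams informative_tracks
#' @return informative-site track tibble.
#' @export
nco_genotype_filter <- function(sites, mother, father, offspring,
                                min_depth = 8, gq_min = 20, indels = NULL) {
  informative_tracks(sites, mother, father, offspring,
                     min_depth = min_depth, imbalance_p = 0.05,
                     gq_min = gq_min, indels = indels,
                     depth_range = c(0.5, 2), mendelian = TRUE)
}

#' Call non-crossover events
#'
#' Takes the clustered phase changes from [call_crossovers()] and keeps
#' candidate clusters with exactly two phase changes, unique to one
#' meiosis (no phase change of any other meiosis overlapping the
#' converted tract), and surrounded by at least `congruent_flank`
#' informative sites on each side at which no meiosis changes phase. The
#' converted tract is the run of informative sites between the two
#' changes, with the allele the offspring received from the focal parent.
#'
#' @param tracks informative-site tracks ([nco_genotype_filter()]).
#' @param events event tibble from [call_crossovers()] run on `tracks`.
#' @param congruent_flank required congruent sites per side (default 10).
#' @param sites optional cohort [site_table()] used for read-level
#'   verification: a homozygous call of the focal offspring at a
#'   converted site must carry zero reads of the discordant allele
#'   (miscalled heterozygotes typically retain a stray read of the true
#'   second allele) and genotype quality of at least `hom_gq`.
#' @param hom_gq minimum genotype quality of homozygous calls at
#'   converted sites (default 50).
#' @return NCO tibble: meiosis identity, tract interval, flanking-site
#'   interval, flank congruent counts and a `sites` list column
#'   (`pos`, `ref`, `alt`, `allele`, `allele_base`, `ws`,
#'   `strong_transmitted`).
#' @export
call_noncrossovers <- function(tracks, events, congruent_flank = 10,
                               sites = NULL, hom_gq = 50) {
  cand <- filter(events, .data$kind == "nco_candidate", .data$n_changes == 2)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    e <- cand[i, ]
    tr <- filter(tracks, .data$parent == e$parent, .data$chrom == e$chrom)
    if (nrow(tr) != 1) next
    pos <- tr$pos[[1]]
    ch <- e$changes[[1]]
    first_gap <- min(ch$g_start); last_gap <- max(ch$g_end)
    A <- tr$alleles[[1]]
    range_idx <- (first_gap + 1L):last_gap
    others <- setdiff(colnames(A), e$offspring)
    # a site is converted when the majority of the other offspring flip
    # state (match/mismatch with the template) relative to the left
    # flank anchor, i.e. flipping the template's allele explains the
    # double switch
    anchor <- first_gap
    st <- function(s, o2) {
      a <- A[s, o2]; t <- A[s, e$offspring]
      if_else(is.na(a) | is.na(t), NA, a == t)
    }
    conv <- vapply(range_idx, function(s) {
      flips <- st(s, others) != st(anchor, others)
      flips <- flips[!is.na(flips)]
      length(flips) > 0 && mean(flips) > 0.5
    }, logical(1))
    conv_idx <- range_idx[conv]
    if (length(conv_idx) == 0) next
    # all phase changes on this (parent, chrom) from any meiosis
    all_ch <- filter(events, .data$parent == e$parent,
                     .data$chrom == e$chrom)
    other <- filter(all_ch, .data$offspring != e$offspring)
    tract_lo <- min(conv_idx); tract_hi <- max(conv_idx)
    clash <- FALSE
    if (nrow(other) > 0) {
      for (k in seq_len(nrow(other))) {
        oc <- other$changes[[k]]
        # change spans gaps [g_start, g_end]; its site footprint is
        # [g_start, g_end + 1]
        if (any(oc$g_start <= tract_hi & oc$g_end + 1L >= tract_lo)) {
          clash <- TRUE; break
        }
      }
    }
    if (clash) next
    # congruent flanks: count sites between this event and the nearest
    # changed gap of any meiosis on each side
    changed_gaps <- sort(unique(unlist(purrr::map(all_ch$changes, function(x) {
      unlist(purrr::map2(x$g_start, x$g_end, seq))
    }))))
    own <- unlist(purrr::map2(ch$g_start, ch$g_end, seq))
    left_gaps <- changed_gaps[changed_gaps < min(own)]
    right_gaps <- changed_gaps[changed_gaps > max(own)]
    # sites strictly left of the event's left change, after the previous
    # changed gap
    left_start <- if (length(left_gaps)) max(left_gaps) + 1L else 1L
    n_left <- first_gap - left_start + 1L
    right_end <- if (length(right_gaps)) min(right_gaps) else length(pos) - 1L
    n_right <- right_end - (last_gap + 1L) + 1L
    if (n_left < congruent_flank || n_right < congruent_flank) next
    if (!is.null(sites)) {
      # single-site conversions rest entirely on one genotype call of the
      # focal offspring; homozygous calls there must show no read of the
      # discordant allele and enough depth to rule out an unsampled
      # second allele (GQ >= hom_gq)
      bad <- FALSE
      other_parent <- setdiff(unique(tracks$parent), e$parent)
      check <- c(e$offspring, other_parent)
      for (s in conv_idx) {
        row <- sites[sites$chrom == e$chrom & sites$pos == pos[s], ]
        if (nrow(row) != 1) next
        for (who in check) {
          if (!who %in% colnames(row$gt)) next
          g <- row$gt[, who]
          if (is.na(g) || g == 1) next
          stray <- if (g == 0) row$ad_alt[, who] else row$ad_ref[, who]
          if (!is.na(stray) && stray > 0) bad <- TRUE
          if (!is.na(row$gq[, who]) && row$gq[, who] < hom_gq) bad <- TRUE
        }
      }
      if (bad) next
    }
    allele <- unname(A[conv_idx, e$offspring])
    ref <- tr$ref[[1]][conv_idx]; alt <- tr$alt[[1]][conv_idx]
    ws <- xor(ref %in% STRONG, alt %in% STRONG)
    allele_base <- if_else(allele == 0L, ref, alt)
    out[[length(out) + 1]] <- tibble(
      parent = e$parent, offspring = e$offspring, chrom = e$chrom,
      kind = "NCO",
      tract_start = pos[tract_lo], tract_end = pos[tract_hi],
      left = pos[first_gap], right = pos[last_gap + 1L],
      n_sites = length(conv_idx), flank_left = n_left,
      flank_right = n_right,
      sites = list(tibble(pos = pos[conv_idx], ref = ref, alt = alt,
                          allele = allele, allele_base = allele_base,
                          ws = ws,
                          strong_transmitted = ws &
                            allele_base %in% STRONG)))
  }
  if (length(out) == 0) {
    return(tibble(parent = character(), offspring = character(),
                  chrom = character(), kind = character(),
                  tract_start = numeric(), tract_end = numeric(),
                  left = numeric(), right = numeric(), n_sites = integer(),
                  flank_left = integer(), flank_right = integer(),
                  sites = list()))
  }
  bind_rows(out)
}

#' Post-filters for non-crossover events
#'
#' Removes events within `min_gap` bp of another (both members, midpoint
#' distance of converted tracts), events whose flanking-site interval has
#' a mappable fraction below `min_mappable`, and events whose converted
#' site lies more than `max_flank_gap` bp from the closest non-converted
#' informative site.
#'
#' @param events NCO tibble from [call_noncrossovers()].
#' @param mappability interval tibble, or NULL to skip the mappability
#'   criterion.
#' @param min_gap mutual-exclusion distance (default 1 kb).
#' @param min_mappable minimum mappable fraction (default 0.5).
#' @param max_flank_gap maximum converted-site to flank distance
#'   (default 10 kb).
#' @return filtered NCO tibble.
#' @export
nco_postfilter <- function(events, mappability = NULL, min_gap = 1000,
                           min_mappable = 0.5, max_flank_gap = 1e4) {
  if (nrow(events) == 0) return(events)
  x <- mutate(events, mid = (.data$tract_start + .data$tract_end) / 2)
  keep <- rep(TRUE, nrow(x))
  for (ch in unique(x$chrom)) {
    idx <- which(x$chrom == ch)
    if (length(idx) < 2) next
    m <- x$mid[idx]
    d <- abs(outer(m, m, "-")); diag(d) <- Inf
    keep[idx[apply(d, 1, min) < min_gap]] <- FALSE
  }
  x <- x[keep, ]
  if (!is.null(mappability) && nrow(x) > 0) {
    frac <- vapply(seq_len(nrow(x)), function(i) {
      iv <- intervals(x$chrom[i], x$left[i], max(x$right[i], x$left[i] + 1))
      hit <- interval_intersect(iv, mappability)
      sum(hit$end - hit$start) / (iv$end - iv$start)
    }, numeric(1))
    x <- x[frac >= min_mappable, ]
  }
  if (nrow(x) > 0) {
    gap <- pmax(x$tract_start - x$left, x$right - x$tract_end)
    x <- x[gap <= max_flank_gap, ]
  }
  select(x, -"mid")
}

#' Transmission of non-crossovers to the next generation
#'
#' An event in the meiosis (parent -> F1 offspring) is testable when the
#' F1 carries the converted allele heterozygously at a converted site,
#' its partner is homozygous for the other allele and a sequenced F2
#' offspring exists: the converted allele in the F2 then must have come
#' from the F1. The transmission rate comes with a Clopper-Pearson
#' interval; true events are expected near 50%.
#'
#' @param events NCO tibble.
#' @param sites cohort [site_table()].
#' @param ped pedigree tibble.
#' @param conf confidence level.
#' @return list `events` (with `transmitted`: TRUE/FALSE/NA), `n_testable`,
#'   `rate`, `ci`.
#' @export
nco_transmission <- function(events, sites, ped, conf = 0.95) {
  trans <- rep(NA, nrow(events))
  for (i in seq_len(nrow(events))) {
    o <- events$offspring[i]
    kids <- ped$id[!is.na(ped$mother) &
                     (ped$mother == o | ped$father == o)]
    if (length(kids) == 0) next
    k1 <- kids[1]
    partner <- setdiff(unlist(ped[match(k1, ped$id), c("mother", "father")]),
                       o)
    st <- events$sites[[i]]
    for (s in seq_len(nrow(st))) {
      row <- filter(sites, .data$chrom == events$chrom[i],
                    .data$pos == st$pos[s])
      if (nrow(row) != 1) next
      conv_is_alt <- st$allele[s] == 1L
      g_o <- row$gt[, o]; g_p <- row$gt[, partner]; g_k <- row$gt[, k1]
      if (is.na(g_o) || is.na(g_p) || is.na(g_k) || g_o != 1) next
      if (conv_is_alt && g_p == 0) { trans[i] <- g_k > 0; break }
      if (!conv_is_alt && g_p == 2) { trans[i] <- g_k < 2; break }
    }
  }
  n_yes <- sum(trans %in% TRUE); n_test <- sum(!is.na(trans))
  rate <- if (n_test > 0) n_yes / n_test else NA_real_
  ci <- if (n_test > 0) {
    unname(binom.test(n_yes, n_test, conf.level = conf)$conf.int)
  } else c(NA_real_, NA_real_)
  list(events = mutate(events, transmitted = trans),
       n_testable = n_test, n_transmitted = n_yes, rate = rate,
       ci = c(lower = ci[1], upper = ci[2]))
}
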