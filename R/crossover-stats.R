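#' Genetic map statistics from crossover events
#'
#' Map length in centimorgans is `100 * n_events / n_meioses`; per-sex
#' variants use the transmitting parent's sex. Each chromosome's
#' consistency with an obligate crossover per tetrad is tested by a
#' one-sided exact binomial: under one crossover per tetrad, a gamete
#' carries at least one crossover with probability >= 1/2, so the number
#' of meioses showing an event on the chromosome is compared against
#' Binomial(n_meioses, 0.5) (alternative "less").
#'
#' @param events crossover event tibble (kinds CO/complex_CO counted).
#' @param meioses tibble `parent`, `offspring`, `parent_sex` enumerating
#'   the meioses surveyed.
#' @param chromosomes [chromosome_spec()] tibble.
#' @return `fm_map` object: `summary` (overall and per-sex map lengths)
#'   and `per_chromosome` (counts, cM, cM/Mb, obligate-crossover p).
#' @export
map_statistics <- function(events, meioses, chromosomes) {
  ev <- filter(events, .data$kind %in% c("CO", "complex_CO"))
  n_mei <- nrow(meioses)
  if (n_mei == 0) abort("no meioses supplied")
  ev <- left_join(ev, meioses, by = c("parent", "offspring"))
  overall <- tibble(sex = "both", n_co = nrow(ev), n_meioses = n_mei,
                    per_meiosis = nrow(ev) / n_mei,
                    map_cm = 100 * nrow(ev) / n_mei)
  by_sex <- ev |>
    group_by(sex = .data$parent_sex) |>
    summarise(n_co = n(), .groups = "drop") |>
    left_join(meioses |> group_by(sex = .data$parent_sex) |>
                summarise(n_meioses = n(), .groups = "drop"), by = "sex") |>
    mutate(per_meiosis = .data$n_co / .data$n_meioses,
           map_cm = 100 * .data$n_co / .data$n_meioses)
  per_chrom <- chromosomes |>
    rename(chrom = "name") |>
    left_join(ev |> group_by(.data$chrom) |>
                summarise(n_co = n(),
                          n_meioses_with_event =
                            dplyr::n_distinct(paste(.data$parent,
                                                    .data$offspring)),
                          .groups = "drop"),
              by = "chrom") |>
    mutate(n_co = dplyr::coalesce(.data$n_co, 0L),
           n_meioses_with_event =
             dplyr::coalesce(.data$n_meioses_with_event, 0L),
           per_meiosis = .data$n_co / n_mei,
           cm = 100 * .data$n_co / n_mei,
           cm_per_mb = .data$cm / (.data$length / 1e6),
           obligate_p = vapply(.data$n_meioses_with_event, function(x) {
             binom.test(min(x, n_mei), n_mei, 0.5,
                        alternative = "less")$p.value
           }, numeric(1)))
  structure(list(summary = bind_rows(overall, by_sex),
                 per_chromosome = per_chrom, n_meioses = n_mei),
            class = "fm_map")
}

#' @export
print.fm_map <- function(x, ...) {
  cat(sprintf("Genetic map over %d meioses:\n", x$n_meioses))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.fm_map <- function(x, ...) x$per_chromosome

#' @export
glance.fm_map <- function(x, ...) {
  s <- x$summary
  tibble(map_cm = s$map_cm[s$sex == "both"],
         n_co = s$n_co[s$sex == "both"], n_meioses = x$n_meioses)
}

#' Normalized positions and distribution tests for recombination events
#'
#' Event positions (interval midpoints) are normalized by chromosome
#' length (unfolded, 0 at one end and 1 at the other, matching cumulative
#' distribution displays). Kolmogorov-Smirnov tests compare each
#' chromosome class against the uniform distribution and macro- versus
#' micro-chromosomes against each other.
#'
#' @param events event tibble with `chrom`, `left`, `right`.
#' @param chromosomes [chromosome_spec()] tibble.
#' @return `fm_dist` object: `positions` tibble (`chrom`, `cls`,
#'   `relpos`), `ks_uniform` per class, `ks_macro_micro`.
#' @export
distribution_statistics <- function(events, chromosomes) {
  pos <- events |>
    left_join(chromosomes |> rename(chrom = "name"), by = "chrom") |>
    mutate(relpos = ((.data$left + .data$right) / 2) / .data$length) |>
    select("chrom", "cls", "relpos")
  ks_u <- pos |>
    group_by(.data$cls) |>
    summarise(n = n(),
              statistic = if (n() >= 2) {
                suppressWarnings(ks.test(.data$relpos, "punif"))$statistic
              } else NA_real_,
              p.value = if (n() >= 2) {
                suppressWarnings(ks.test(.data$relpos, "punif"))$p.value
              } else NA_real_, .groups = "drop")
  mm <- NULL
  a <- pos$relpos[pos$cls == "macro"]; b <- pos$relpos[pos$cls == "micro"]
  if (length(a) >= 2 && length(b) >= 2) {
    kt <- suppressWarnings(ks.test(a, b))
    mm <- tibble(statistic = unname(kt$statistic), p.value = kt$p.value)
  }
  structure(list(positions = pos, ks_uniform = ks_u, ks_macro_micro = mm),
            class = "fm_dist")
}

#' @export
tidy.fm_dist <- function(x, ...) x$ks_uniform

#' Crossover interference distances
#'
#' For every crossover, the distance to the nearest other crossover in
#' the same meiosis ("within") and the nearest crossover of a different
#' meiosis on the same chromosome ("between"); interference shifts the
#' "within" distribution towards longer distances.
#'
#' @param events crossover event tibble.
#' @return list `distances` (tibble `type`, `distance`), `ks` (two-sample
#'   Kolmogorov-Smirnov tibble or NULL when either set is too small).
#' @export
co_interference <- function(events) {
  ev <- filter(events, .data$kind %in% c("CO", "complex_CO")) |>
    mutate(mid = (.data$left + .data$right) / 2,
           meiosis = paste(.data$parent, .data$offspring))
  rows <- list()
  for (ch in unique(ev$chrom)) {
    e <- filter(ev, .data$chrom == ch)
    for (i in seq_len(nrow(e))) {
      same <- abs(e$mid[e$meiosis == e$meiosis[i] &
                          seq_len(nrow(e)) != i] - e$mid[i])
      diff_ <- abs(e$mid[e$meiosis != e$meiosis[i]] - e$mid[i])
      if (length(same)) {
        rows[[length(rows) + 1]] <- tibble(type = "within",
                                           distance = min(same))
      }
      if (length(diff_)) {
        rows[[length(rows) + 1]] <- tibble(type = "between",
                                           distance = min(diff_))
      }
    }
  }
  d <- bind_rows(rows)
  ks <- NULL
  w <- d$distance[d$type == "within"]; b <- d$distance[d$type == "between"]
  if (length(w) >= 2 && length(b) >= 2) {
    kt <- suppressWarnings(ks.test(w, b))
    ks <- tibble(statistic = unname(kt$statistic), p.value = kt$p.value)
  }
  list(distances = d, ks = ks)
}

#' Distance from phased mutations to recombination events
#'
#' "Within" pairs a mutation with the nearest recombination event from
#' the same parental germline and proband; "between" uses events from
#' other parents/probands. Chromosomes without any eligible event are
#' assigned the sentinel distance (200 Mb, longer than any chromosome).
#'
#' @param dnms tibble with `chrom`, `pos`, `parent`, `proband`.
#' @param events event tibble with `parent`, `offspring`, `chrom`,
#'   `left`, `right`.
#' @param sentinel sentinel distance in bp (default 2e8).
#' @return list `distances` (`type`, `distance`), `ks`.
#' @export
dnm_recomb_distance <- function(dnms, events, sentinel = 2e8) {
  ev <- mutate(events, mid = (.data$left + .data$right) / 2)
  one <- function(chrom, pos, same) {
    e <- ev[ev$chrom == chrom & same, ]
    if (nrow(e) == 0) sentinel else min(abs(e$mid - pos))
  }
  rows <- purrr::map(seq_len(nrow(dnms)), function(i) {
    same <- ev$parent == dnms$parent[i] & ev$offspring == dnms$proband[i]
    tibble(type = c("within", "between"),
           distance = c(one(dnms$chrom[i], dnms$pos[i], same),
                        one(dnms$chrom[i], dnms$pos[i], !same)))
  })
  d <- bind_rows(rows)
  ks <- NULL
  w <- d$distance[d$type == "within"]; b <- d$distance[d$type == "between"]
  if (length(w) >= 2 && length(b) >= 2) {
    kt <- suppressWarnings(ks.test(w, b))
    ks <- tibble(statistic = unname(kt$statistic), p.value = kt$p.value)
  }
  list(distances = d, ks = ks)
}
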