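#' Exact (Garwood) confidence interval for a Poisson count
#' @param n observed count.
#' @param conf confidence level.
#' @return numeric `c(lower, upper)` on the count scale.
#' @export
poisson_ci <- function(n, conf = 0.95) {
  a <- 1 - conf
  lo <- if (n == 0) 0 else qchisq(a / 2, 2 * n) / 2
  hi <- qchisq(1 - a / 2, 2 * (n + 1)) / 2
  c(lower = lo, upper = hi)
}

#' Per-generation mutation rate from DNM counts
#'
#' The rate is `n / (2 * sum(callable))`, the mutation count divided by
#' two times the total diploid sequence surveyed across trios; the
#' confidence interval treats the count as Poisson (exact bounds).
#'
#' @param n number of de novo mutations (or a DNM record tibble, in which
#'   case `nrow` is used).
#' @param callable callable length per trio in bp (vector; summed).
#' @param mean_parental_age optional mean parental age in years; adds a
#'   per-year rate.
#' @param conf confidence level (default 0.95).
#' @return `fm_rate` object with elements `n`, `denominator`, `rate`,
#'   `ci`, `rate_per_year`.
#' @export
estimate_dnm_rate <- function(n, callable, mean_parental_age = NULL,
                              conf = 0.95) {
  if (is.data.frame(n)) n <- nrow(n)
  L <- sum(callable)
  if (L <= 0) abort("total callable length must be positive")
  denom <- 2 * L
  ci <- poisson_ci(n, conf) / denom
  out <- list(n = n, denominator = denom, rate = n / denom, ci = ci,
              rate_per_year = if (!is.null(mean_parental_age)) {
                n / denom / mean_parental_age
              } else NA_real_,
              conf = conf)
  structure(out, class = "fm_rate")
}

#' @export
print.fm_rate <- function(x, ...) {
  cat(sprintf("Mutation rate: %.3g per bp per generation (%d events / %.3g bp)\n",
              x$rate, x$n, x$denominator))
  cat(sprintf("%d%% Poisson CI: %.3g - %.3g\n", round(100 * x$conf),
              x$ci[1], x$ci[2]))
  if (!is.na(x$rate_per_year)) {
    cat(sprintf("Per year: %.3g\n", x$rate_per_year))
  }
  invisible(x)
}

#' @export
tidy.fm_rate <- function(x, ...) {
  tibble(estimate = x$rate, n = x$n, denominator = x$denominator,
         conf.low = unname(x$ci[1]), conf.high = unname(x$ci[2]),
         rate_per_year = x$rate_per_year)
}

#' Sex ratio of mutation origin
#'
#' Germline mode takes paternally vs maternally phased counts; the
#' post-zygotic mode compares male- and female-proband counts rescaled by
#' the number of probands of each sex. The confidence interval is exact
#' binomial (Clopper-Pearson) on the count pair, transformed to ratio
#' space (p / (1 - p), times the rescaling factor where applicable).
#'
#' @param n_male,n_female counts attributed to the male and female side
#'   (paternal/maternal phases, or male/female probands).
#' @param probands_per_sex optional `c(male = , female = )` census for the
#'   post-zygotic rescaling.
#' @param conf confidence level.
#' @return `fm_ratio` object (`ratio`, `ci`, counts).
#' @export
dnm_sex_ratio <- function(n_male, n_female, probands_per_sex = NULL,
                          conf = 0.95) {
  scale <- if (!is.null(probands_per_sex)) {
    probands_per_sex[["female"]] / probands_per_sex[["male"]]
  } else 1
  n <- n_male + n_female
  if (n_female == 0) {
    ci <- c(lower = if (n == 0) NA_real_ else
      scale * odds(binom.test(n_male, n, conf.level = conf)$conf.int[1]),
      upper = Inf)
    ratio <- if (n_male == 0) NA_real_ else Inf
  } else {
    bt <- binom.test(n_male, n, conf.level = conf)
    ratio <- scale * n_male / n_female
    ci <- c(lower = scale * odds(bt$conf.int[1]),
            upper = scale * odds(bt$conf.int[2]))
  }
  structure(list(ratio = ratio, ci = ci, n_male = n_male,
                 n_female = n_female, scale = scale, conf = conf),
            class = "fm_ratio")
}

odds <- function(p) p / (1 - p)

#' @export
print.fm_ratio <- function(x, ...) {
  cat(sprintf("male:female ratio %.3g (%d%% CI %.3g - %.3g), counts %d:%d\n",
              x$ratio, round(100 * x$conf), x$ci[1], x$ci[2],
              x$n_male, x$n_female))
  invisible(x)
}

#' @export
tidy.fm_ratio <- function(x, ...) {
  tibble(estimate = x$ratio, conf.low = unname(x$ci[1]),
         conf.high = unname(x$ci[2]), n_male = x$n_male,
         n_female = x$n_female)
}

#' Seven-class mutation spectrum
#'
#' Collapses strand-symmetric substitution classes and separates CpG>TpG
#' from other C>T using the trinucleotide context.
#'
#' @param x tibble with `ref`, `alt` and `context` (trinucleotide centred
#'   on the site) columns.
#' @param opportunities optional named vector of opportunity counts per
#'   class (e.g. 2 x number of A bases surveyed) used to add rates.
#' @return tibble `type`, `count`, `proportion` (+ `rate` when
#'   opportunities are given).
#' @export
mutation_spectrum <- function(x, opportunities = NULL) {
  type <- classify_mutation_type(x$ref, x$alt, x$context)
  lv <- names(default_spectrum())
  counts <- table(factor(type, levels = lv))
  out <- tibble(type = lv, count = as.integer(counts),
                proportion = as.integer(counts) / max(sum(counts), 1))
  if (!is.null(opportunities)) {
    out$rate <- out$count / (2 * opportunities[out$type])
  }
  out
}

#' @rdname mutation_spectrum
#' @param ref,alt,context vectors of alleles and trinucleotide context.
#' @export
classify_mutation_type <- function(ref, alt, context = NULL) {
  pyr <- ref %in% c("A", "C")
  r <- if_else(pyr, ref, comp_base(ref))
  a <- if_else(pyr, alt, comp_base(alt))
  type <- paste0(r, ">", a)
  if (!is.null(context)) {
    ctx <- if_else(pyr, context, revcomp(context))
    cpg <- type == "C>T" & substr(ctx, 3, 3) == "G"
    type[cpg] <- "CpG>TpG"
  }
  type
}

#' Compare a DNM spectrum with a polymorphism spectrum
#'
#' Chi-square goodness-of-fit of observed class counts against expected
#' proportions (typically from low-frequency polymorphisms), 6 degrees of
#' freedom for 7 classes. Classes with expected counts below 1 are pooled
#' into their smallest neighbour with a warning.
#'
#' @param observed named counts per class.
#' @param expected_prop named expected proportions (normalized internally).
#' @return tibble `statistic`, `df`, `p.value`.
#' @export
spectrum_compare <- function(observed, expected_prop) {
  expected_prop <- expected_prop[names(observed)] / sum(expected_prop)
  e <- sum(observed) * expected_prop
  o <- observed
  if (any(e < 1)) warn("pooling spectrum classes with expected count < 1")
  while (any(e < 1) && length(e) > 2) {
    i <- which.min(e)
    j <- which.min(replace(e, i, Inf))
    e[j] <- e[j] + e[i]; o[j] <- o[j] + o[i]
    e <- e[-i]; o <- o[-i]
  }
  stat <- sum((o - e)^2 / e)
  df <- length(o) - 1
  tibble(statistic = stat, df = df, p.value = pchisq(stat, df,
                                                     lower.tail = FALSE))
}

#' Mutations shared between siblings
#'
#' Identical (chrom, pos, alt) events in two or more siblings of the same
#' nuclear family, with both parents called homozygous reference,
#' indicating a mutation present in a parental germline mosaic.
#'
#' @param records DNM tibble with `proband`, `chrom`, `pos`, `alt`.
#' @param ped pedigree tibble.
#' @return tibble of shared events with a `carriers` list column.
#' @export
shared_sibling_dnms <- function(records, ped) {
  fam_of <- function(id) {
    i <- match(id, ped$id)
    paste(ped$mother[i], ped$father[i])
  }
  records |>
    mutate(family = fam_of(.data$proband)) |>
    group_by(.data$family, .data$chrom, .data$pos, .data$alt) |>
    summarise(carriers = list(unique(.data$proband)),
              n_carriers = dplyr::n_distinct(.data$proband),
              .groups = "drop") |>
    filter(.data$n_carriers >= 2)
}
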