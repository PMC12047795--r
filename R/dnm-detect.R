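#' Detect candidate de novo mutations in a trio
#'
#' A candidate is a biallelic site inside the trio's callable mask where
#' the proband is heterozygous, both parents are called homozygous
#' reference, genotype quality is at least `gq_min` in all three trio
#' members, and no genotyped individual outside the proband's nuclear
#' family carries the alternate allele.
#'
#' @param sites a [site_table()] covering the cohort.
#' @param ped pedigree tibble.
#' @param proband proband id; parents are taken from the pedigree.
#' @param callable interval tibble from [callable_mask_for_trio()], or
#'   NULL to skip the positional mask.
#' @param gq_min minimum genotype quality (default 30).
#' @param cohort ids used for the outside-family polymorphism screen;
#'   defaults to all samples. Siblings (same nuclear family) are exempt.
#' @return candidate tibble: `chrom`, `pos`, `ref`, `alt`, `proband`,
#'   `mother`, `father`, proband read counts and the parents' alt counts.
#' @export
detect_dnm_candidates <- function(sites, ped, proband, callable = NULL,
                                  gq_min = 30, cohort = NULL) {
  i <- match(proband, ped$id)
  if (is.na(i) || is.na(ped$mother[i])) {
    abort(paste("proband", proband, "has no recorded parents"))
  }
  mo <- ped$mother[i]; fa <- ped$father[i]
  fam <- ped$id[!is.na(ped$mother) & ped$mother == mo & ped$father == fa]
  fam <- union(fam, c(mo, fa))
  # descendants legitimately inherit a true de novo allele, so they are
  # exempt from the outside-family polymorphism screen
  desc <- character(); frontier <- proband
  repeat {
    kids <- ped$id[!is.na(ped$mother) &
                     (ped$mother %in% frontier | ped$father %in% frontier)]
    kids <- setdiff(kids, desc)
    if (length(kids) == 0) break
    desc <- c(desc, kids); frontier <- kids
  }
  if (is.null(cohort)) cohort <- site_samples(sites)
  outside <- setdiff(intersect(cohort, site_samples(sites)), c(fam, desc))
  if (length(outside) == 0) {
    warn("no samples outside the nuclear family; polymorphism screen skipped")
  }
  x <- filter_biallelic(sites)
  keep <- x$gt[, proband] == 1 &
    x$gt[, mo] == 0 & x$gt[, fa] == 0 &
    x$gq[, proband] >= gq_min & x$gq[, mo] >= gq_min & x$gq[, fa] >= gq_min
  keep[is.na(keep)] <- FALSE
  if (length(outside) > 0) {
    poly <- rowSums(x$gt[, outside, drop = FALSE] > 0, na.rm = TRUE) > 0
    keep <- keep & !poly
  }
  x <- x[keep, ]
  pro_dp <- x$dp[, proband]
  pro_alt <- x$ad_alt[, proband]
  out <- tibble(chrom = x$chrom, pos = x$pos, ref = x$ref, alt = x$alt,
                proband = proband, mother = mo, father = fa,
                proband_dp = pro_dp, proband_alt = pro_alt,
                mother_alt = x$ad_alt[, mo],
                father_alt = x$ad_alt[, fa])
  if (!is.null(callable) && nrow(out) > 0) {
    q <- intervals(out$chrom, out$pos - 1, out$pos)
    hit <- interval_closest(q, callable)$distance == 0
    out <- out[order(q$chrom, q$start), ][hit %in% TRUE, ]
  }
  arrange(out, .data$chrom, .data$pos)
}

#' Read-level filtering of candidate de novo mutations
#'
#' Keeps candidates with at least `min_alt` proband reads carrying the
#' alternate allele and zero alternate reads in either parent (pileup
#' semantics), then discards whole sets of candidates lying within
#' `proximity` bp of each other (distance strictly less than `proximity`
#' removes both members; candidates exactly `proximity` apart survive).
#'
#' @param candidates output of [detect_dnm_candidates()].
#' @param min_alt minimum proband alternate reads (default 2).
#' @param proximity clustering distance in bp (default 10).
#' @return filtered candidate tibble with a `proband_alt_fraction` column.
#' @export
filter_dnm_candidates <- function(candidates, min_alt = 2, proximity = 10) {
  x <- filter(candidates,
              .data$proband_alt >= min_alt,
              .data$mother_alt %in% 0, .data$father_alt %in% 0)
  if (nrow(x) > 1) {
    x <- arrange(x, .data$chrom, .data$pos)
    same_prev <- c(FALSE, x$chrom[-1] == x$chrom[-nrow(x)])
    gap_prev <- c(Inf, diff(x$pos)); gap_prev[!same_prev] <- Inf
    gap_next <- c(gap_prev[-1], Inf)
    x <- x[gap_prev >= proximity & gap_next >= proximity, ]
  }
  mutate(x, proband_alt_fraction = .data$proband_alt /
           pmax(.data$proband_dp, 1))
}
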