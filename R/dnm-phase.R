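#' Phase a de novo mutation by transmission
#'
#' Uses the proband's partner and descendants. Informative sites within
#' `window` bp of the mutation are positions where an allele is carried by
#' exactly one of the proband's parents, is present in the (heterozygous)
#' proband, absent from the partner, and carried by a descendant. When at
#' least `threshold` of informative alleles trace to one parent, the
#' mutation is assigned to that parent if it was itself transmitted to the
#' descendant, and to the other parent if not.
#'
#' @param sites cohort [site_table()].
#' @param ped pedigree tibble (proband must have a partner and offspring).
#' @param dnm one-row tibble with `chrom`, `pos`, `proband` (e.g. a row of
#'   [filter_dnm_candidates()] output).
#' @param window search radius in bp (default 200 kb).
#' @param threshold majority fraction over informative alleles (default
#'   0.75).
#' @return tibble `phase` ("maternal"/"paternal"/"unresolved"),
#'   `n_informative`, `frac_top`, `transmitted`.
#' @export
phase_dnm_by_transmission <- function(sites, ped, dnm, window = 2e5,
                                      threshold = 0.75) {
  pro <- dnm$proband
  i <- match(pro, ped$id)
  mo <- ped$mother[i]; fa <- ped$father[i]
  kids <- ped$id[!is.na(ped$mother) &
                   (ped$mother == pro | ped$father == pro)]
  if (length(kids) == 0) {
    abort(paste("proband", pro, "has no sequenced offspring"))
  }
  k1 <- kids[1]
  partner <- unique(if_else(ped$mother[match(kids, ped$id)] == pro,
                            ped$father[match(kids, ped$id)],
                            ped$mother[match(kids, ped$id)]))[1]
  x <- filter(sites, .data$chrom == dnm$chrom,
              abs(.data$pos - dnm$pos) <= window, .data$pos != dnm$pos)
  votes <- c(maternal = 0, paternal = 0)
  if (nrow(x) > 0) {
    for (allele in c("alt", "ref")) {
      carries <- function(s) if (allele == "alt") x$gt[, s] > 0 else x$gt[, s] < 2
      in_mo <- carries(mo) %in% TRUE; in_fa <- carries(fa) %in% TRUE
      informative <- xor(in_mo, in_fa) &
        (x$gt[, pro] == 1) %in% TRUE &
        !carries(partner) %in% TRUE &
        carries(k1) %in% TRUE
      votes["maternal"] <- votes["maternal"] + sum(informative & in_mo)
      votes["paternal"] <- votes["paternal"] + sum(informative & in_fa)
    }
  }
  n <- sum(votes)
  dnm_row <- filter(sites, .data$chrom == dnm$chrom, .data$pos == dnm$pos)
  transmitted <- if (nrow(dnm_row) == 1) {
    (dnm_row$gt[, k1] > 0) %in% TRUE
  } else NA
  if (n == 0 || max(votes) / n < threshold || is.na(transmitted)) {
    return(tibble(phase = "unresolved", n_informative = n,
                  frac_top = if (n > 0) max(votes) / n else NA_real_,
                  transmitted = transmitted))
  }
  top <- names(votes)[which.max(votes)]
  phase <- if (transmitted) top else setdiff(c("maternal", "paternal"), top)
  tibble(phase = phase, n_informative = n, frac_top = max(votes) / n,
         transmitted = transmitted)
}

#' Phase a de novo mutation by read tracing
#'
#' Inspects fragments (read pairs) spanning the mutation and a nearby
#' parent-diagnostic heterozygous site: an allele inherited by the proband
#' and carried by exactly one parent. Fragments that carry the mutant
#' allele vote for the parent whose diagnostic allele they also carry (or
#' against it when they carry the opposite allele); conflicting votes
#' leave the mutation unresolved with a conflict flag.
#'
#' @param dnm one-row candidate tibble (`chrom`, `pos`, `alt`, `proband`).
#' @param fragments linkage tibble (`sample`, `fragment`, `chrom`, `pos`,
#'   `allele`) for the proband, e.g. from [simulate_fragments()].
#' @param sites cohort [site_table()].
#' @param ped pedigree tibble.
#' @param window search radius in bp (default 300).
#' @return tibble `phase`, `n_fragments`, `conflict`.
#' @export
phase_dnm_by_read_tracing <- function(dnm, fragments, sites, ped,
                                      window = 300) {
  pro <- dnm$proband
  i <- match(pro, ped$id)
  mo <- ped$mother[i]; fa <- ped$father[i]
  x <- filter(sites, .data$chrom == dnm$chrom,
              abs(.data$pos - dnm$pos) <= window, .data$pos != dnm$pos,
              .data$gt[, pro] %in% 1)
  votes <- c(maternal = 0, paternal = 0)
  n_frag <- 0
  fr <- filter(fragments, .data$sample == pro, .data$chrom == dnm$chrom)
  mut_frags <- fr |>
    filter(.data$pos == dnm$pos, .data$allele == dnm$alt) |>
    pull("fragment")
  for (s in seq_len(nrow(x))) {
    for (al in c("alt", "ref")) {
      base <- if (al == "alt") x$alt[s] else x$ref[s]
      carries <- function(sam) {
        if (al == "alt") x$gt[s, sam] > 0 else x$gt[s, sam] < 2
      }
      in_mo <- carries(mo) %in% TRUE; in_fa <- carries(fa) %in% TRUE
      if (!xor(in_mo, in_fa)) next
      parent_of_allele <- if (in_mo) "maternal" else "paternal"
      cov <- filter(fr, .data$pos == x$pos[s],
                    .data$fragment %in% mut_frags)
      if (nrow(cov) == 0) next
      n_frag <- n_frag + nrow(cov)
      same <- sum(cov$allele == base)
      other <- nrow(cov) - same
      votes[parent_of_allele] <- votes[parent_of_allele] + same
      votes[setdiff(c("maternal", "paternal"), parent_of_allele)] <-
        votes[setdiff(c("maternal", "paternal"), parent_of_allele)] + other
    }
  }
  if (sum(votes) == 0) {
    return(tibble(phase = "unresolved", n_fragments = n_frag,
                  conflict = FALSE))
  }
  conflict <- min(votes) > 0
  phase <- if (conflict) "unresolved" else names(votes)[which.max(votes)]
  tibble(phase = phase, n_fragments = n_frag, conflict = conflict)
}

#' Classify the developmental timing of a de novo mutation
#'
#' Searches proband fragments for evidence of three distinct local
#' haplotypes at the mutation: combinations of (flanking heterozygous
#' allele, mutation allele) such as A-mut, A-ref and B-ref indicate the
#' mutation arose post-zygotically on one cell lineage. More than two
#' haplotypes in a parent's fragments instead flags a genotyping artifact
#' and discards the record. Without an informative flanking heterozygote
#' the record stays unclassified.
#'
#' @param dnm one-row candidate tibble.
#' @param fragments proband fragments (see [phase_dnm_by_read_tracing()]).
#' @param parent_fragments optional fragments of the parents at the same
#'   locus.
#' @param sites cohort [site_table()].
#' @param window flanking-het search radius in bp (default 300).
#' @param min_support fragments required per haplotype (default 2,
#'   guarding against single-read errors).
#' @return tibble `timing` ("parental_germline", "postzygotic",
#'   "unclassified", "discard"), `n_haplotypes`.
#' @export
classify_dnm_timing <- function(dnm, fragments, parent_fragments = NULL,
                                sites = NULL, window = 300,
                                min_support = 2) {
  pro <- dnm$proband
  fr <- filter(fragments, .data$sample == pro, .data$chrom == dnm$chrom)
  hets <- if (!is.null(sites)) {
    filter(sites, .data$chrom == dnm$chrom,
           abs(.data$pos - dnm$pos) <= window, .data$pos != dnm$pos,
           .data$gt[, pro] %in% 1) |> pull("pos")
  } else {
    setdiff(unique(fr$pos[abs(fr$pos - dnm$pos) <= window]), dnm$pos)
  }
  if (length(hets) == 0) {
    return(tibble(timing = "unclassified", n_haplotypes = NA_integer_))
  }
  count_haps <- function(f, focal_pos, flank_pos) {
    wide <- f |>
      filter(.data$pos %in% c(focal_pos, flank_pos)) |>
      tidyr::pivot_wider(id_cols = "fragment", names_from = "pos",
                        values_from = "allele")
    cols <- as.character(c(flank_pos, focal_pos))
    if (!all(cols %in% names(wide))) return(0L)
    wide <- wide[stats::complete.cases(wide[cols]), ]
    if (nrow(wide) == 0) return(0L)
    combos <- table(paste(wide[[cols[1]]], wide[[cols[2]]]))
    sum(combos >= min_support)
  }
  n_hap <- max(vapply(hets, function(h) count_haps(fr, dnm$pos, h),
                      integer(1)))
  if (!is.null(parent_fragments)) {
    par_ids <- unique(parent_fragments$sample)
    for (p in par_ids) {
      fp <- filter(parent_fragments, .data$sample == p,
                   .data$chrom == dnm$chrom)
      n_par <- max(vapply(hets, function(h) count_haps(fp, dnm$pos, h),
                          integer(1)), 0L)
      if (n_par > 2) {
        return(tibble(timing = "discard", n_haplotypes = n_par))
      }
    }
  }
  timing <- if (n_hap >= 3) "postzygotic"
  else if (n_hap >= 1) "parental_germline"
  else "unclassified"
  tibble(timing = timing, n_haplotypes = n_hap)
}
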