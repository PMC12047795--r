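#' Build the synthetic pedigree frame
#'
#' Each family has an F0 mother and father, `n_offspring` F1 siblings, an
#' unrelated partner for the first sibling and `n_f2` F2 offspring of that
#' pair, mirroring a multi-sibling three-generation design.
#'
#' @param config a [sim_config()].
#' @return pedigree tibble.
#' @export
sim_pedigree_frame <- function(config) {
  rows <- list()
  for (i in seq_len(config$n_families)) {
    fm <- paste0("f", i, "m"); fp <- paste0("f", i, "p")
    rows[[length(rows) + 1]] <- tibble(
      id = c(fm, fp), sex = c("F", "M"), mother = NA_character_,
      father = NA_character_, generation = "F0")
    o_sex <- rep(c("M", "F"), length.out = config$n_offspring)
    o_id <- paste0("f", i, "o", seq_len(config$n_offspring))
    rows[[length(rows) + 1]] <- tibble(
      id = o_id, sex = o_sex, mother = fm, father = fp, generation = "F1")
    if (config$n_f2 > 0) {
      x_sex <- if (o_sex[1] == "M") "F" else "M"
      x_id <- paste0("f", i, "x")
      rows[[length(rows) + 1]] <- tibble(
        id = x_id, sex = x_sex, mother = NA_character_,
        father = NA_character_, generation = "F1")
      g_mo <- if (x_sex == "F") x_id else o_id[1]
      g_fa <- if (x_sex == "F") o_id[1] else x_id
      rows[[length(rows) + 1]] <- tibble(
        id = paste0("f", i, "g", seq_len(config$n_f2)),
        sex = rep(c("F", "M"), length.out = config$n_f2),
        mother = g_mo, father = g_fa, generation = "F2")
    }
  }
  ped <- bind_rows(rows)
  ped$mean_depth <- config$coverage_mean
  pedigree(ped)
}

meiosis_seed <- function(config, chrom_i, meiosis_i) {
  as.integer((as.numeric(config$seed) + 7919 * chrom_i +
                104729 * meiosis_i) %% 2147483629)
}

#' Simulate a complete pedigree dataset
#'
#' Runs the whole generator: founder haplotypes, recombining meioses with
#' conversion tracts, de novo mutations (germline and post-zygotic),
#' read-count genotyping, and per-sample depth tracks. Output is fully
#' determined by `config$seed`.
#'
#' @param config a [sim_config()].
#' @param keep_haplotypes keep phased truth haplotypes in the result
#'   (needed for fragment simulation and tract phasing; default TRUE).
#' @return an `fm_sim` list: `config`, `pedigree`, `sites` (a
#'   [site_table()] of genotype calls with read counts), `truth` (lists
#'   `crossovers`, `ncos`, `dnms`), `haplotypes`, `depth` (bedgraph-style
#'   tibble), `meioses` (tibble `parent`, `offspring`, `parent_sex`,
#'   `generation`), `mean_depth` (named vector).
#' @export
simulate_pedigree <- function(config, keep_haplotypes = TRUE) {
  ped <- sim_pedigree_frame(config)
  samples <- ped$id
  founders <- ped$id[is.na(ped$mother)]
  offspring <- ped |> filter(!is.na(.data$mother))
  # F1 before F2 so parental haplotypes exist when needed
  offspring <- offspring[order(match(offspring$generation, c("F1", "F2"))), ]

  set.seed(config$seed + 31L)
  dnms <- simulate_dnms(ped, config)

  chroms <- config$chromosomes
  site_parts <- list(); truth_co <- list(); truth_nco <- list()
  haplotypes <- list(); depth_parts <- list()

  for (j in seq_len(nrow(chroms))) {
    cname <- chroms$name[j]; clen <- chroms$length[j]; cls <- chroms$cls[j]
    set.seed(meiosis_seed(config, j, 0L))
    panel <- founder_panel(config, clen, founders)
    dnm_c <- filter(dnms, .data$chrom == cname, !(.data$pos %in% panel$pos))
    dnm_c <- dnm_c[!duplicated(dnm_c[c("pos", "shared_id")]) |
                     !is.na(dnm_c$shared_id), ]
    pos <- c(panel$pos, unique(dnm_c$pos))
    ord <- order(pos)
    pos <- pos[ord]
    n_dnm_sites <- length(unique(dnm_c$pos))
    ref <- c(panel$ref, dnm_c$ref[!duplicated(dnm_c$pos)])[ord]
    alt <- c(panel$alt, dnm_c$alt[!duplicated(dnm_c$pos)])[ord]
    H <- matrix(0L, length(pos), 2L * length(samples))
    colnames(H) <- paste0(rep(samples, each = 2), c(".1", ".2"))
    H[, paste0(rep(founders, each = 2), c(".1", ".2"))] <-
      rbind(panel$hap, matrix(0L, n_dnm_sites, ncol(panel$hap)))[ord, ]

    hap_cols <- function(id) paste0(id, c(".1", ".2"))
    site_at <- function(p) match(p, pos)
    # mosaic sites by carrier individual, for gamete thinning
    mosaic <- filter(dnm_c, .data$postzygotic)

    for (i in seq_len(nrow(offspring))) {
      o <- offspring$id[i]
      for (side in 1:2) {  # 1 = maternal gamete, 2 = paternal
        par <- if (side == 1) offspring$mother[i] else offspring$father[i]
        set.seed(meiosis_seed(config, j, 2L * i + side - 1L))
        m <- simulate_meiosis(H[, hap_cols(par), drop = FALSE], pos, ref, alt,
                              clen, cls, config)
        g <- m$gamete
        pm <- filter(mosaic, .data$proband == par)
        if (nrow(pm) > 0) {
          for (k in seq_len(nrow(pm))) {
            s <- site_at(pm$pos[k])
            if (g[s] == 1L && runif(1) >= 2 * pm$vaf[k]) g[s] <- 0L
          }
        }
        H[, paste0(o, ".", side)] <- g
        if (length(m$crossovers)) {
          truth_co[[length(truth_co) + 1]] <- tibble(
            parent = par, offspring = o, chrom = cname, pos = m$crossovers)
        }
        if (nrow(m$tracts)) {
          truth_nco[[length(truth_nco) + 1]] <- mutate(
            m$tracts, parent = par, offspring = o, chrom = cname,
            .before = 1)
        }
      }
      # overlay this offspring's own de novo events
      dn_o <- filter(dnm_c, .data$proband == o)
      if (nrow(dn_o) > 0) {
        side <- if_else(dn_o$parent == offspring$mother[i], 1L, 2L)
        H[cbind(site_at(dn_o$pos),
                match(paste0(o, ".", side), colnames(H)))] <- 1L
      }
    }

    gt_true <- H[, paste0(samples, ".1")] + H[, paste0(samples, ".2")]
    colnames(gt_true) <- samples
    vaf <- NULL
    if (nrow(mosaic) > 0) {
      vaf <- matrix(NA_real_, nrow(gt_true), ncol(gt_true),
                    dimnames = dimnames(gt_true))
      vaf[cbind(site_at(mosaic$pos), match(mosaic$proband, samples))] <-
        mosaic$vaf
    }
    set.seed(meiosis_seed(config, j, 90000L))
    reads <- simulate_reads(gt_true, config, vaf)
    site_parts[[j]] <- site_table(
      chrom = cname, pos = pos, ref = ref, alt = alt,
      gt = reads$gt_call, dp = reads$dp, ad_ref = reads$ad_ref,
      ad_alt = reads$ad_alt, gq = reads$gq)

    set.seed(meiosis_seed(config, j, 95000L))
    nb <- ceiling(clen / config$depth_bin)
    depth_parts[[j]] <- tibble(
      sample = rep(samples, each = nb), chrom = cname,
      start = rep((seq_len(nb) - 1) * config$depth_bin, length(samples)),
      end = rep(pmin(seq_len(nb) * config$depth_bin, clen), length(samples)),
      depth = rpois(nb * length(samples), config$coverage_mean))

    haplotypes[[cname]] <- if (keep_haplotypes) {
      list(pos = pos, ref = ref, alt = alt, hap = H)
    } else NULL
    rm(H, gt_true, vaf, reads); gc(FALSE)
  }

  sites <- combine_site_tables(site_parts)
  depth <- bind_rows(depth_parts)
  mean_depth <- depth |>
    group_by(.data$sample) |>
    summarise(d = sum(.data$depth * (.data$end - .data$start)) /
                sum(.data$end - .data$start)) |>
    (\(x) setNames(x$d, x$sample))()
  meioses <- offspring |>
    tidyr::pivot_longer(c("mother", "father"), values_to = "parent") |>
    mutate(parent_sex = if_else(.data$name == "mother", "F", "M")) |>
    select(parent = "parent", offspring = "id", "parent_sex",
           generation = "generation")
  structure(list(
    config = config, pedigree = ped, sites = sites,
    truth = list(crossovers = bind_rows(truth_co),
                 ncos = bind_rows(truth_nco), dnms = dnms),
    haplotypes = haplotypes, depth = depth, meioses = meioses,
    mean_depth = mean_depth), class = "fm_sim")
}

#' Simulate read-pair fragments around a locus
#'
#' Generates paired-end fragments (span `config$insert_size`) overlapping
#' `center +/- window` for one sample, reporting the allele each fragment
#' carries at every covered variant site. Fragments originate from one of
#' the two physical haplotypes; at a mosaic (post-zygotic) site of this
#' sample, fragments from the carrier haplotype show the mutant allele
#' only with the mosaic cell fraction. Per-base errors flip alleles at
#' rate `config$base_error`.
#'
#' @param sim an `fm_sim` from [simulate_pedigree()] (haplotypes kept).
#' @param sample individual id.
#' @param chrom chromosome name.
#' @param center locus position (bp, 1-based).
#' @param window half-width of the region of interest.
#' @return tibble `sample`, `fragment`, `chrom`, `pos`, `allele` (base).
#' @export
simulate_fragments <- function(sim, sample, chrom, center, window = 300) {
  hp <- sim$haplotypes[[chrom]]
  if (is.null(hp)) abort("simulation was run without keep_haplotypes")
  cfg <- sim$config
  span <- cfg$insert_size
  lo <- center - window - span; hi <- center + window
  n_frag <- rpois(1, cfg$coverage_mean * (hi - lo) / span)
  if (n_frag == 0) return(tibble(sample = character(), fragment = integer(),
                                 chrom = character(), pos = integer(),
                                 allele = character()))
  starts <- runif(n_frag, lo, hi)
  hap_choice <- sample.int(2L, n_frag, replace = TRUE)
  mos <- filter(sim$truth$dnms, .data$postzygotic,
                .data$proband == sample, .data$chrom == !!chrom)
  out <- vector("list", n_frag)
  hcols <- paste0(sample, c(".1", ".2"))
  for (f in seq_len(n_frag)) {
    i1 <- findInterval(starts[f], hp$pos) + 1L
    i2 <- findInterval(starts[f] + span, hp$pos)
    if (i2 < i1) next
    idx <- i1:i2
    alle <- hp$hap[idx, hcols[hap_choice[f]]]
    if (nrow(mos) > 0) {
      for (k in seq_len(nrow(mos))) {
        s <- match(mos$pos[k], hp$pos[idx])
        if (!is.na(s) && alle[s] == 1L && runif(1) >= 2 * mos$vaf[k]) {
          alle[s] <- 0L
        }
      }
    }
    err <- runif(length(idx)) < cfg$base_error
    alle[err] <- 1L - alle[err]
    out[[f]] <- tibble(sample = sample, fragment = f, chrom = chrom,
                       pos = hp$pos[idx],
                       allele = if_else(alle == 0L, hp$ref[idx],
                                        hp$alt[idx]))
  }
  bind_rows(out)
}
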