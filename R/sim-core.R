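BASES <- c("A", "C", "G", "T")
STRONG <- c("C", "G")

comp_base <- function(b) chartr("ACGT", "TGCA", b)
revcomp <- function(s) {
  vapply(strsplit(chartr("ACGT", "TGCA", s), ""), function(x) {
    paste(rev(x), collapse = "")
  }, character(1))
}

# one chromosome's founder panel: segregating positions, alleles, frequencies
# and founder haplotypes (columns "<id>.1", "<id>.2")
founder_panel <- function(config, chrom_len, founder_ids) {
  n <- rpois(1, site_density(config) * chrom_len)
  pos <- sort(unique(ceiling(runif(n, 0, chrom_len))))
  n <- length(pos)
  freq <- runif(n, 0.05, 0.95)
  ref <- sample(BASES, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1),
                USE.NAMES = FALSE)
  ncol <- 2L * length(founder_ids)
  hap <- matrix(rbinom(n * ncol, 1L, freq), n, ncol)
  colnames(hap) <- paste0(rep(founder_ids, each = 2), c(".1", ".2"))
  list(pos = pos, freq = freq, ref = ref, alt = alt, hap = hap)
}

#' Simulate founder diploid haplotypes
#'
#' Segregating sites are placed as a Poisson process whose density is
#' chosen so that expected per-bp heterozygosity equals `config$theta`
#' (allele frequencies are uniform on 0.05-0.95); founder haplotypes draw
#' alleles independently at those frequencies.
#'
#' @param config a [sim_config()].
#' @param founder_ids character vector of founder individual ids.
#' @return named list (one element per chromosome) with `pos`, `freq`,
#'   `ref`, `alt` and the 0/1 haplotype matrix `hap` (sites x 2 per
#'   founder, columns `<id>.1` / `<id>.2`).
#' @export
simulate_founders <- function(config, founder_ids) {
  set.seed(config$seed)
  out <- lapply(seq_len(nrow(config$chromosomes)), function(i) {
    founder_panel(config, config$chromosomes$length[i], founder_ids)
  })
  names(out) <- config$chromosomes$name
  out
}

#' Simulate one meiosis of a diploid parent
#'
#' Draws crossovers (Poisson with per-bp intensity `config$co_rate`, at
#' least one per chromosome when `config$obligate_co`; telomere-weighted
#' placement on macro-chromosomes), forms the recombinant gamete, then
#' overlays non-crossover conversion tracts with exponential lengths. At
#' heterozygous weak/strong sites inside a tract the strong (G/C) allele
#' is transmitted with probability `config$gbgc_bias`; other heterozygous
#' tract sites copy the donor (non-background) haplotype.
#'
#' @param hap sites x 2 integer (0/1) matrix: the parent's two haplotypes.
#' @param pos site positions (bp, ascending).
#' @param ref,alt site alleles (bases).
#' @param chrom_len chromosome length in bp.
#' @param cls "macro" or "micro".
#' @param config a [sim_config()].
#' @return list with `gamete` (0/1 vector), `crossovers` (positions),
#'   `tracts` (tibble `start`, `end`, and a `sites` list column recording
#'   per converted-site truth: position, parent heterozygosity, weak/strong
#'   status, transmitted allele, and whether the conversion is observable,
#'   i.e. changed the allele relative to the background haplotype).
#' @export
simulate_meiosis <- function(hap, pos, ref, alt, chrom_len, cls, config) {
  n_co <- rpois(1, config$co_rate * chrom_len)
  if (config$obligate_co && n_co == 0) n_co <- 1L
  co_pos <- if (cls == "macro" && config$co_telomere_weight) {
    chrom_len * stats::rbeta(n_co, 0.5, 0.5)
  } else {
    runif(n_co, 0, chrom_len)
  }
  phase0 <- sample.int(2L, 1)
  seg <- findInterval(pos, sort(co_pos))
  hap_idx <- 1L + (phase0 - 1L + seg) %% 2L
  gamete <- hap[cbind(seq_along(pos), hap_idx)]

  n_nco <- rpois(1, config$nco_rate * chrom_len)
  tract_rows <- vector("list", n_nco)
  if (n_nco > 0) {
    starts <- runif(n_nco, 0, chrom_len)
    lens <- rexp(n_nco, 1 / config$tract_mean)
    strong_code <- ifelse(ref %in% STRONG, 0L, 1L)  # 0 = ref allele strong
    ws <- xor(ref %in% STRONG, alt %in% STRONG)
    for (k in seq_len(n_nco)) {
      a <- starts[k]; b <- min(starts[k] + lens[k], chrom_len)
      i1 <- findInterval(a, pos) + 1L
      i2 <- findInterval(b, pos)
      if (i2 < i1) {
        tract_rows[[k]] <- tibble(start = a, end = b,
                                  sites = list(tibble()))
        next
      }
      idx <- i1:i2
      background <- gamete[idx]
      donor <- hap[cbind(idx, 3L - hap_idx[idx])]
      het <- hap[idx, 1] != hap[idx, 2]
      new <- donor
      biased <- het & ws[idx]
      if (any(biased)) {
        pick_strong <- rbinom(sum(biased), 1L, config$gbgc_bias) == 1L
        new[biased] <- ifelse(pick_strong, strong_code[idx][biased],
                              1L - strong_code[idx][biased])
      }
      gamete[idx] <- new
      ws_i <- ws[idx]
      strong_i <- ws_i & het & (new == strong_code[idx])
      tract_rows[[k]] <- tibble(
        start = a, end = b,
        sites = list(tibble(pos = pos[idx], het = het, ws = ws_i,
                            transmitted = new,
                            transmitted_base = ifelse(new == 0L, ref[idx],
                                                      alt[idx]),
                            background = background,
                            observable = het & (new != background),
                            strong_transmitted = strong_i)))
    }
  }
  list(gamete = gamete, crossovers = sort(co_pos),
       tracts = bind_rows(tract_rows))
}

#' Simulate de novo mutation events for every non-founder
#'
#' Mutation counts per offspring per chromosome are Poisson with mean
#' `2 * length * mu`; a fraction `postzygotic_fraction` arises after
#' fertilization (mosaic read fraction uniform on `mosaic_range`, parental
#' chromosome chosen fairly), the rest in a parental germline with
#' paternal:maternal odds `alpha`. Types follow `config$spectrum`;
#' CpG>TpG mutations get a CG dinucleotide context.
#'
#' @param ped pedigree tibble.
#' @param config a [sim_config()].
#' @return tibble of mutation events with columns `proband`, `chrom`,
#'   `pos`, `type`, `ref`, `alt`, `context`, `parent`, `parent_sex`,
#'   `postzygotic`, `vaf`, `shared_id`.
#' @export
simulate_dnms <- function(ped, config) {
  offs <- filter(ped, !is.na(.data$mother))
  chroms <- config$chromosomes
  rows <- list()
  for (i in seq_len(nrow(offs))) {
    for (j in seq_len(nrow(chroms))) {
      n <- rpois(1, 2 * chroms$length[j] * config$mu)
      if (n == 0) next
      postz <- runif(n) < config$postzygotic_fraction
      pat <- ifelse(postz, runif(n) < 0.5,
                    runif(n) < config$alpha / (1 + config$alpha))
      rows[[length(rows) + 1]] <- tibble(
        proband = offs$id[i], chrom = chroms$name[j],
        pos = ceiling(runif(n, 0, chroms$length[j])),
        type = sample(names(config$spectrum), n, replace = TRUE,
                      prob = config$spectrum),
        parent = if_else(pat, offs$father[i], offs$mother[i]),
        parent_sex = if_else(pat, "M", "F"),
        postzygotic = postz,
        vaf = if_else(postz,
                      runif(n, config$mosaic_range[1], config$mosaic_range[2]),
                      0.5),
        shared_id = NA_integer_)
    }
  }
  events <- bind_rows(rows)
  if (config$n_shared_dnms > 0) {
    fams <- pedigree_families(ped) |> filter(.data$n_offspring >= 2)
    for (s in seq_len(config$n_shared_dnms)) {
      f <- fams[sample.int(nrow(fams), 1), ]
      par <- if (runif(1) < 0.5) f$father else f$mother
      carriers <- f$offspring[[1]][runif(f$n_offspring) < 0.5]
      if (length(carriers) == 0) carriers <- sample(f$offspring[[1]], 1)
      j <- sample.int(nrow(chroms), 1)
      rows_s <- tibble(
        proband = carriers, chrom = chroms$name[j],
        pos = ceiling(runif(1, 0, chroms$length[j])),
        type = sample(names(config$spectrum), 1, prob = config$spectrum),
        parent = par, parent_sex = ped$sex[match(par, ped$id)],
        postzygotic = FALSE, vaf = 0.5, shared_id = s)
      events <- bind_rows(events, rows_s)
    }
  }
  if (nrow(events) == 0) {
    return(tibble(proband = character(), chrom = character(),
                  pos = integer(), type = character(), parent = character(),
                  parent_sex = character(), postzygotic = logical(),
                  vaf = double(), shared_id = integer(), ref = character(),
                  alt = character(), context = character()))
  }
  dnm_alleles(events)
}

# assign ref/alt/context consistent with the 7-class type, random strand
dnm_alleles <- function(events) {
  n <- nrow(events)
  base_type <- sub("CpG>TpG", "C>T", events$type)
  ref <- sub(">.*", "", base_type)
  alt <- sub(".*>", "", base_type)
  left <- sample(BASES, n, replace = TRUE)
  right <- sample(BASES, n, replace = TRUE)
  is_cpg <- events$type == "CpG>TpG"
  right[is_cpg] <- "G"
  # non-CpG C>T must not sit in a CpG context
  fix <- events$type == "C>T" & right == "G"
  right[fix] <- sample(c("A", "C", "T"), sum(fix), replace = TRUE)
  context <- paste0(left, ref, right)
  flip <- runif(n) < 0.5
  ref[flip] <- comp_base(ref[flip])
  alt[flip] <- comp_base(alt[flip])
  context[flip] <- revcomp(context[flip])
  mutate(events, ref = ref, alt = alt, context = context)
}

#' Simulate per-site read counts and genotype calls
#'
#' Depth is Poisson around the configured coverage; alternate-allele
#' counts are binomial at the true allele fraction with symmetric error
#' leakage. Genotype calls and a phred-scaled genotype quality are derived
#' from the read counts by maximum likelihood over hom-ref/het/hom-alt.
#'
#' @param gt_true integer matrix (sites x samples) of true genotypes
#'   (0/1/2).
#' @param config a [sim_config()].
#' @param vaf optional matrix overriding the allele fraction (used for
#'   mosaic sites); `NA` cells fall back to the genotype-implied fraction.
#' @return list of sites x samples matrices: `dp`, `ad_ref`, `ad_alt`,
#'   `gq`, `gt_call`.
#' @export
simulate_reads <- function(gt_true, config, vaf = NULL) {
  n <- nrow(gt_true); m <- ncol(gt_true)
  e <- max(config$base_error, 1e-10)
  e3 <- e / 3   # errors spread over the three other bases
  dp <- adr <- ada <- gq <- call <- matrix(0L, n, m,
                                           dimnames = dimnames(gt_true))
  # column-wise to keep transient double vectors small
  for (j in seq_len(m)) {
    dpj <- rpois(n, config$coverage_mean)
    v <- c(e3, 0.5, 1 - e3)[gt_true[, j] + 1L]
    if (!is.null(vaf)) {
      ov <- !is.na(vaf[, j])
      v[ov] <- vaf[ov, j] * (1 - e3) + (1 - vaf[ov, j]) * e3
    }
    adaj <- rbinom(n, dpj, v)
    adrj <- dpj - adaj
    ll <- genotype_loglik(adrj, adaj, e)
    best <- pmax(ll$l0, ll$l1, ll$l2)
    cj <- (ll$l1 > ll$l0 & ll$l1 >= ll$l2) * 1L +
      (ll$l2 > ll$l0 & ll$l2 > ll$l1) * 2L
    second <- pmax(pmin(ll$l0, ll$l1), pmin(pmax(ll$l0, ll$l1), ll$l2))
    gqj <- as.integer(pmin(99, round(10 / log(10) * (best - second))))
    cj <- as.integer(cj)
    cj[dpj == 0] <- NA_integer_
    gqj[dpj == 0] <- 0L
    dp[, j] <- dpj; adr[, j] <- adrj; ada[, j] <- adaj
    gq[, j] <- gqj; call[, j] <- cj
  }
  list(dp = dp, ad_ref = adr, ad_alt = ada, gq = gq, gt_call = call)
}

genotype_loglik <- function(adr, ada, e) {
  e3 <- e / 3
  list(l0 = ada * log(e3) + adr * log1p(-e3),
       l1 = (adr + ada) * log(0.5),
       l2 = adr * log(e3) + ada * log1p(-e3))
}
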