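#' Per-site genotype tables
#'
#' A site table is a tibble with one row per variant position: `chrom`,
#' `pos` (1-based, VCF convention; interval algebra is 0-based and
#' conversion happens only at the I/O boundary), `ref`, `alt`,
#' `multiallelic`, plus matrix columns `gt` (0 = hom-ref, 1 = het,
#' 2 = hom-alt, `NA` = missing), `dp`, `ad_ref`, `ad_alt`, `gq`, one column
#' per sample. Positions are unique per chromosome.
#'
#' @param chrom,pos,ref,alt per-site vectors.
#' @param gt,dp,ad_ref,ad_alt,gq numeric matrices, sites x samples, with
#'   sample ids as column names.
#' @param multiallelic logical vector flagging records with >1 alt allele.
#' @return a site-table tibble.
#' @export
site_table <- function(chrom, pos, ref, alt, gt, dp = NULL, ad_ref = NULL,
                       ad_alt = NULL, gq = NULL,
                       multiallelic = rep(FALSE, length(pos))) {
  n <- length(pos)
  samples <- colnames(gt)
  if (is.null(samples)) abort("gt must have sample ids as column names")
  blank <- function(m) {
    if (is.null(m)) {
      matrix(NA_real_, n, length(samples), dimnames = list(NULL, samples))
    } else m
  }
  x <- tibble(chrom = as.character(chrom), pos = as.integer(pos),
              ref = as.character(ref), alt = as.character(alt),
              multiallelic = multiallelic,
              gt = gt, dp = blank(dp), ad_ref = blank(ad_ref),
              ad_alt = blank(ad_alt), gq = blank(gq))
  if (anyDuplicated(x[c("chrom", "pos")])) {
    abort("duplicated (chrom, pos) in site table")
  }
  o <- order(x$chrom, x$pos)
  if (is.unsorted(o)) x <- x[o, ]
  x
}

#' @rdname site_table
#' @param x object to query.
#' @export
site_samples <- function(x) colnames(x$gt)

#' Row-bind site tables sharing the same sample set
#' @param parts list of site tables.
#' @return a single site table.
#' @export
combine_site_tables <- function(parts) {
  parts <- parts[lengths(parts) > 0]
  site_table(chrom = unlist(lapply(parts, `[[`, "chrom")),
             pos = unlist(lapply(parts, `[[`, "pos")),
             ref = unlist(lapply(parts, `[[`, "ref")),
             alt = unlist(lapply(parts, `[[`, "alt")),
             gt = do.call(rbind, lapply(parts, `[[`, "gt")),
             dp = do.call(rbind, lapply(parts, `[[`, "dp")),
             ad_ref = do.call(rbind, lapply(parts, `[[`, "ad_ref")),
             ad_alt = do.call(rbind, lapply(parts, `[[`, "ad_alt")),
             gq = do.call(rbind, lapply(parts, `[[`, "gq")),
             multiallelic = unlist(lapply(parts, `[[`, "multiallelic")))
}

#' Restrict a site table to biallelic SNVs
#' @param x site table.
#' @return site table without multiallelic records.
#' @export
filter_biallelic <- function(x) {
  if (!any(x$multiallelic)) return(x)
  filter(x, !.data$multiallelic)
}

#' Read genotypes from a VCF file
#'
#' Parses GT, DP, AD and GQ for the requested samples. `./.` genotypes
#' become missing (`NA`), never hom-ref. Records with more than one ALT
#' allele are kept and flagged `multiallelic`; their `ad_alt` refers to the
#' first alt allele.
#'
#' @param path path to a VCF (plain or bgzipped).
#' @param samples optional character vector restricting the sample set;
#'   unknown samples raise an error naming them.
#' @return a [site_table()] tibble.
#' @export
read_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  all_samples <- colnames(v@gt)[-1]
  if (is.null(samples)) samples <- all_samples
  missing <- setdiff(samples, all_samples)
  if (length(missing)) {
    abort(paste("sample(s) not present in VCF:",
                paste(missing, collapse = ", ")))
  }
  gt_chr <- vcfR::extract.gt(v, element = "GT")[, samples, drop = FALSE]
  code_gt <- function(g) {
    g <- gsub("\\|", "/", g)
    out <- rep(NA_real_, length(g))
    out[g %in% c("0/0")] <- 0
    out[g %in% c("0/1", "1/0")] <- 1
    out[g %in% c("1/1")] <- 2
    out
  }
  n <- nrow(fix)
  gt <- matrix(code_gt(gt_chr), n, length(samples),
               dimnames = list(NULL, samples))
  num_el <- function(el) {
    m <- vcfR::extract.gt(v, element = el, as.numeric = TRUE)
    if (is.null(m)) return(NULL)
    matrix(as.numeric(m[, samples, drop = FALSE]), n, length(samples),
           dimnames = list(NULL, samples))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  ad_ref <- ad_alt <- NULL
  if (!is.null(ad)) {
    ad <- ad[, samples, drop = FALSE]
    split_ad <- function(k) {
      vals <- suppressWarnings(
        as.numeric(vapply(strsplit(ad, ",", fixed = TRUE), function(p) {
          if (length(p) >= k) p[k] else NA_character_
        }, character(1))))
      matrix(vals, n, length(samples), dimnames = list(NULL, samples))
    }
    ad_ref <- split_ad(1)
    ad_alt <- split_ad(2)
  }
  alt <- fix$ALT
  multi <- grepl(",", alt)
  alt1 <- vapply(strsplit(alt, ",", fixed = TRUE), `[[`, character(1), 1)
  site_table(chrom = fix$CHROM, pos = as.integer(fix$POS),
             ref = fix$REF, alt = alt1,
             gt = gt, dp = num_el("DP"), ad_ref = ad_ref, ad_alt = ad_alt,
             gq = num_el("GQ"), multiallelic = multi)
}

#' Write a site table as a minimal VCF 4.2 file
#'
#' Emits GT:DP:AD:GQ per sample; the round trip through [read_vcf()] is
#' lossless for these fields.
#'
#' @param x site table.
#' @param path output path (plain text).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  samples <- site_samples(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1], nrow(x), length(samples))
  gt_str[is.na(gt_str)] <- "./."
  fmt_num <- function(m) {
    s <- matrix(as.character(m), nrow(x), length(samples))
    s[is.na(s)] <- "."
    s
  }
  dp <- fmt_num(x$dp); gq <- fmt_num(x$gq)
  adr <- fmt_num(x$ad_ref); ada <- fmt_num(x$ad_alt)
  cells <- matrix(paste0(gt_str, ":", dp, ":", adr, ",", ada, ":", gq),
                  nrow(x), length(samples))
  lines <- paste(x$chrom, x$pos, ".", x$ref, x$alt, ".", "PASS", ".",
                 "GT:DP:AD:GQ",
                 apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read / write BED3 interval files
#' @param path file path.
#' @return interval tibble (0-based half-open, as in the file).
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  intervals(x[[1]], x[[2]], x[[3]])
}

#' @rdname read_bed
#' @param x interval tibble to write.
#' @export
write_bed <- function(x, path) {
  utils::write.table(x[c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
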