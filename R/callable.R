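#' Callable mask for a parent-offspring trio
#'
#' Positions usable for de novo mutation calling in one trio: every trio
#' member covered by at least `min_depth` reads and at most twice its own
#' mean autosomal depth, at least 5 bp away from any indel called in the
#' trio, outside the repeat mask and inside the mappability mask.
#'
#' @param depth bedgraph-style tibble with columns `sample`, `chrom`,
#'   `start`, `end`, `depth` (0-based half-open intervals of constant
#'   depth) covering all three trio members.
#' @param trio character vector `c(proband, mother, father)`.
#' @param mean_depth named numeric vector of mean autosomal depth per
#'   sample (computed over the mappability mask).
#' @param indels tibble with `chrom`, `pos` (1-based) of indels called in
#'   any trio member; may be empty.
#' @param repeats,mappability interval tibbles.
#' @param min_depth minimum depth, default 8.
#' @param indel_pad exclusion radius: positions closer than `indel_pad`
#'   bp to an indel are dropped (a site exactly `indel_pad` away is kept).
#' @return interval tibble of callable positions.
#' @export
callable_mask_for_trio <- function(depth, trio, mean_depth, indels = NULL,
                                   repeats = NULL, mappability = NULL,
                                   min_depth = 8, indel_pad = 5) {
  stopifnot(length(trio) == 3)
  missing_depth <- setdiff(trio, unique(depth$sample))
  if (length(missing_depth)) {
    abort(paste("no depth track for trio member(s):",
                paste(missing_depth, collapse = ", ")))
  }
  if (!all(trio %in% names(mean_depth))) {
    abort("mean_depth must name every trio member")
  }
  per_sample <- lapply(trio, function(s) {
    d <- filter(depth, .data$sample == s,
                .data$depth >= min_depth,
                .data$depth <= 2 * mean_depth[[s]])
    if (nrow(d) == 0) return(intervals())
    interval_union(as_intervals(d))
  })
  mask <- purrr::reduce(per_sample, interval_intersect)
  if (!is.null(indels) && nrow(indels) > 0) {
    # indel at 1-based pos q excludes 0-based [q-indel_pad, q+indel_pad-1)
    excl <- intervals(indels$chrom,
                      pmax(0, indels$pos - indel_pad),
                      indels$pos + indel_pad - 1)
    mask <- interval_subtract(mask, excl)
  }
  if (!is.null(repeats) && nrow(repeats) > 0) {
    mask <- interval_subtract(mask, repeats)
  }
  if (!is.null(mappability)) mask <- interval_intersect(mask, mappability)
  mask
}

#' Total callable length in bp
#' @param mask interval tibble.
#' @return numeric, summed interval widths.
#' @export
callable_length <- function(mask) sum(mask$end - mask$start)
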