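#' Pedigree tables
#'
#' A pedigree is a tibble with one row per individual: `id`, `sex`
#' ("M"/"F"), `mother`, `father` (`NA` for founders), `generation`
#' ("F0"/"F1"/"F2") and `mean_depth` (mean autosomal depth of coverage,
#' used for depth-doubling filters). Non-founders must have two recorded
#' parents of opposite sex and the parent links must be acyclic.
#'
#' @param x data frame with at least `id`, `sex`, `mother`, `father`.
#' @return validated pedigree tibble.
#' @export
pedigree <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("id", "sex", "mother", "father") %in% names(x)))
  if (!"generation" %in% names(x)) x$generation <- NA_character_
  if (!"mean_depth" %in% names(x)) x$mean_depth <- NA_real_
  if (anyDuplicated(x$id)) abort("duplicated individual ids in pedigree")
  if (!all(x$sex %in% c("M", "F"))) abort("sex must be 'M' or 'F'")
  has_m <- !is.na(x$mother); has_f <- !is.na(x$father)
  if (any(has_m != has_f)) {
    abort("each individual must have either two parents or none")
  }
  sex_of <- setNames(x$sex, x$id)
  bad <- has_m & (sex_of[x$mother] != "F" | sex_of[x$father] != "M")
  if (any(bad, na.rm = TRUE)) abort("mother must be F and father M")
  missing_parent <- c(setdiff(x$mother[has_m], x$id),
                      setdiff(x$father[has_f], x$id))
  if (length(missing_parent)) {
    abort(paste("parent not in pedigree:",
                paste(unique(missing_parent), collapse = ", ")))
  }
  # acyclicity: repeated parent lookup must terminate at founders
  depth <- setNames(rep(NA_integer_, nrow(x)), x$id)
  resolve <- function(id, seen = character()) {
    if (!is.na(depth[id])) return(depth[id])
    if (id %in% seen) abort("pedigree contains a cycle")
    i <- match(id, x$id)
    d <- if (is.na(x$mother[i])) 0L else
      1L + max(resolve(x$mother[i], c(seen, id)),
               resolve(x$father[i], c(seen, id)))
    depth[id] <<- d
    d
  }
  for (id in x$id) resolve(id)
  x
}

#' Enumerate parent-offspring trios
#' @param ped pedigree tibble.
#' @return tibble with columns `proband`, `mother`, `father`.
#' @export
pedigree_trios <- function(ped) {
  ped |>
    filter(!is.na(.data$mother)) |>
    select(proband = "id", "mother", "father")
}

#' Enumerate nuclear families (shared parent pair, >= 1 offspring)
#' @param ped pedigree tibble.
#' @return tibble with `mother`, `father`, `offspring` (list column) and
#'   `n_offspring`.
#' @export
pedigree_families <- function(ped) {
  ped |>
    filter(!is.na(.data$mother)) |>
    group_by(.data$mother, .data$father) |>
    summarise(offspring = list(.data$id), n_offspring = n(), .groups = "drop")
}

#' Read a pedigree TSV (id, sex, mother, father, ...)
#' @param path file path; `NA`, `0` or `.` mark missing parents.
#' @return pedigree tibble.
#' @export
read_pedigree <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("mother", "father")) {
    x[[col]] <- as.character(x[[col]])
    x[[col]][x[[col]] %in% c("0", ".", "")] <- NA_character_
  }
  pedigree(x)
}

#' @rdname read_pedigree
#' @param ped pedigree tibble to write.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
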