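seq_chars <- function(sequence) {
  if (!is.character(sequence)) sequence <- as.character(sequence)
  toupper(strsplit(sequence, "")[[1]])
}

run_mean <- function(x, k) {
  cs <- c(0, cumsum(x))
  (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
}

#' Scan a sequence for CpG islands
#'
#' Sliding 100-bp windows (1-bp step) are averaged over 10 consecutive
#' windows; regions of at least `min_len` bp where the averaged GC
#' content exceeds `gc_min` and the averaged observed:expected CpG ratio
#' exceeds `oe_min` are reported (O/E = CpG count / (C count x G count /
#' window length)).
#'
#' @param sequence character string or Biostrings object.
#' @param win,avg window size and number of averaged windows.
#' @param gc_min,oe_min,min_len thresholds (defaults 0.5, 0.6, 250).
#' @return tibble `chrom`("seq"), `start`, `end` (0-based half-open),
#'   `gc`, `oe`, `source` = "scanner".
#' @export
scan_cpg_islands <- function(sequence, win = 100, avg = 10, gc_min = 0.5,
                             oe_min = 0.6, min_len = 250) {
  x <- seq_chars(sequence)
  L <- length(x)
  empty <- tibble(chrom = character(), start = numeric(), end = numeric(),
                  gc = numeric(), oe = numeric(), source = character())
  if (L < 1000) {
    warn("sequence shorter than 1 kb; no islands reported")
    return(empty)
  }
  is_c <- x == "C"; is_g <- x == "G"
  is_cg <- c(is_c[-L] & is_g[-1], FALSE)
  gc_w <- run_mean(is_c + is_g, win)
  c_w <- run_mean(is_c, win) * win
  g_w <- run_mean(is_g, win) * win
  cpg_w <- run_mean(is_cg, win) * win
  oe_w <- ifelse(c_w * g_w > 0, cpg_w / (c_w * g_w / win), 0)
  gc_a <- run_mean(gc_w, avg)
  oe_a <- run_mean(oe_w, avg)
  ok <- gc_a > gc_min & oe_a > oe_min
  if (!any(ok)) return(empty)
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  rows <- list()
  for (i in which(r$values)) {
    a <- starts[i]                    # first qualifying averaged window
    b <- ends[i] + win + avg - 2      # footprint end (1-based)
    if (b - a + 1 < min_len) next
    idx <- a:b
    gc <- mean(is_c[idx] + is_g[idx])
    cg <- sum(is_cg[idx[-length(idx)]])
    nC <- sum(is_c[idx]); nG <- sum(is_g[idx])
    oe <- if (nC * nG > 0) cg / (nC * nG / length(idx)) else 0
    rows[[length(rows) + 1]] <- tibble(chrom = "seq", start = a - 1,
                                       end = b, gc = gc, oe = oe,
                                       source = "scanner")
  }
  if (length(rows) == 0) return(empty)
  bind_rows(rows)
}

# observation symbols: A C G T hC hG (hypomethylated CpG cytosine and its
# complementary-strand guanine)
cpg_symbols <- function(x, hypo_pos) {
  L <- length(x)
  sym <- x
  hy <- logical(L); hy[hypo_pos[hypo_pos >= 1 & hypo_pos <= L]] <- TRUE
  is_hypo_c <- x == "C" & hy & c(x[-1] == "G", FALSE)
  is_hypo_g <- x == "G" & c(FALSE, is_hypo_c[-L])
  sym[is_hypo_c] <- "hC"
  sym[is_hypo_g] <- "hG"
  sym
}

#' Fit the 8-state CpG-island hidden Markov model
#'
#' States are (island, non-island) x (A, C, G, T); emissions are the six
#' symbols A, C, G, T, hypomethylated-C and hypomethylated-G. Transition
#' and emission probabilities are estimated by supervised counting on a
#' labelled partition (scanner islands vs background) with pseudocount 1.
#'
#' @param sequence character string or Biostrings object.
#' @param meth methylation tibble `pos` (1-based CpG cytosine position),
#'   `fraction` (methylated-read fraction); sites with fraction < 0.5 are
#'   hypomethylated.
#' @param islands labelled island intervals (e.g. [scan_cpg_islands()]).
#' @param pseudocount added to every transition/emission cell.
#' @return model list: `states`, `symbols`, `log_trans`, `log_emis`,
#'   `log_init`.
#' @export
cpg_hmm_fit <- function(sequence, meth, islands, pseudocount = 1) {
  x <- seq_chars(sequence)
  L <- length(x)
  hypo <- meth$pos[meth$fraction < 0.5]
  sym <- cpg_symbols(x, hypo)
  lab <- logical(L)
  for (i in seq_len(nrow(islands))) {
    lab[(islands$start[i] + 1):min(islands$end[i], L)] <- TRUE
  }
  states <- c(paste0("i", BASES), paste0("n", BASES))
  symbols <- c(BASES, "hC", "hG")
  st <- paste0(if_else(lab, "i", "n"), x)
  tr <- matrix(pseudocount, 8, 8, dimnames = list(states, states))
  tt <- table(factor(st[-L], states), factor(st[-1], states))
  tr <- tr + as.matrix(tt)
  em <- matrix(pseudocount, 8, 6, dimnames = list(states, symbols))
  et <- table(factor(st, states), factor(sym, symbols))
  em <- em + as.matrix(et)
  list(states = states, symbols = symbols,
       log_trans = log(tr / rowSums(tr)),
       log_emis = log(em / rowSums(em)),
       log_init = log(rep(1 / 8, 8)))
}

#' Viterbi decode of the CpG-island model
#'
#' @param model from [cpg_hmm_fit()].
#' @param sequence sequence to decode.
#' @param meth methylation tibble (see [cpg_hmm_fit()]).
#' @return character vector of state labels, one per base.
#' @export
cpg_hmm_decode <- function(model, sequence, meth) {
  x <- seq_chars(sequence)
  L <- length(x)
  sym <- cpg_symbols(x, meth$pos[meth$fraction < 0.5])
  si <- match(sym, model$symbols)
  n_st <- length(model$states)
  delta <- model$log_init + model$log_emis[, si[1]]
  back <- matrix(0L, n_st, L)
  for (t in seq_len(L)[-1]) {
    m <- delta + model$log_trans       # m[i, j]: from i to j
    j_best <- max.col(t(m), ties.method = "first")
    back[, t] <- j_best
    delta <- m[cbind(j_best, seq_len(n_st))] + model$log_emis[, si[t]]
  }
  path <- integer(L)
  path[L] <- which.max(delta)
  for (t in rev(seq_len(L)[-1])) path[t - 1] <- back[path[t], t]
  model$states[path]
}

#' Methylation-aware CpG-island calls
#'
#' Fits the 8-state model on the scanner partition, decodes the
#' most-probable state path, merges island-state runs separated by less
#' than `merge_gap` bp and keeps merged stretches inside `len_range`.
#' Without any hypomethylated site the scanner set is returned unchanged
#' with a warning.
#'
#' @inheritParams cpg_hmm_fit
#' @param scanner_islands optional pre-computed scanner set.
#' @param merge_gap merge distance (default 50 bp).
#' @param len_range kept length range (default c(150, 2000)).
#' @return island interval tibble with `source` = "hmm".
#' @export
hmm_cpg_islands <- function(sequence, meth, scanner_islands = NULL,
                            merge_gap = 50, len_range = c(150, 2000),
                            pseudocount = 1) {
  if (is.null(scanner_islands)) scanner_islands <- scan_cpg_islands(sequence)
  if (nrow(meth) == 0 || !any(meth$fraction < 0.5)) {
    warn("no hypomethylated CpG sites; falling back to scanner islands")
    return(mutate(scanner_islands, source = "scanner"))
  }
  if (nrow(scanner_islands) == 0) {
    warn("no scanner islands to parameterize the model; returning none")
    return(scanner_islands)
  }
  model <- cpg_hmm_fit(sequence, meth, scanner_islands, pseudocount)
  path <- cpg_hmm_decode(model, sequence, meth)
  isl <- startsWith(path, "i")
  r <- rle(isl)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  iv <- tibble(start = starts[r$values] - 1, end = ends[r$values])
  if (nrow(iv) == 0) return(tibble(chrom = character(), start = numeric(),
                                   end = numeric(), source = character()))
  merged <- list(); cur <- iv[1, ]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start[i] - cur$end < merge_gap) {
      cur$end <- iv$end[i]
    } else {
      merged[[length(merged) + 1]] <- cur
      cur <- iv[i, ]
    }
  }
  merged[[length(merged) + 1]] <- cur
  out <- bind_rows(merged) |>
    mutate(chrom = "seq", source = "hmm", len = .data$end - .data$start) |>
    filter(.data$len >= len_range[1], .data$len <= len_range[2]) |>
    select("chrom", "start", "end", "source")
  out
}
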