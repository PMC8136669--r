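#' Structural Words of a labelled chain
#'
#' A Structural Word is the string of 5 consecutive overlapping 5-mer block
#' labels, describing a 9-residue stretch: a chain of length L with L-4
#' fragment labels yields L-8 words. Windows containing an `NA` label
#' (chain break, missing atoms) are skipped.
#'
#' @param labels Character vector of per-position fragment labels for one
#'   chain (position i labelling the fragment starting at residue i), `NA`
#'   where no label exists.
#' @return `data.frame` with `start` (0-based residue index of the
#'   9-residue span) and `word`; zero rows for chains shorter than 9
#'   residues.
#' @examples
#' chain_words(c("m", "n", "o", "p", "a"))
#' @export
chain_words <- function(labels) {
  n <- length(labels)
  if (n < 5) return(data.frame(start = integer(0), word = character(0)))
  starts <- seq_len(n - 4)
  words <- vapply(starts, function(s)
    paste(labels[s:(s + 4)], collapse = ""), character(1))
  ok <- !vapply(starts, function(s) anyNA(labels[s:(s + 4)]), logical(1))
  data.frame(start = starts[ok] - 1L, word = words[ok],
             stringsAsFactors = FALSE)
}

#' Catalog of Structural Words with within-word structural spread
#'
#' Counts every 5-letter Structural Word across a set of labelled chains
#' and, for words with at least two members, the mean pairwise Kabsch RMSD
#' over the 27-atom (9-residue N/CA/C) backbones of the member fragments.
#' For populous words the pairwise mean is estimated from a fixed-seed
#' random subsample of pairs; set `max_pairs = Inf` for the exact
#' all-pairs computation.
#'
#' @param chains List of chains, each a list with `labels` (per-position
#'   fragment labels, `NA` at breaks) and `coords` (3L x 3 backbone
#'   coordinate matrix, rows cycling N, CA, C).
#' @param max_pairs Cap on sampled member pairs per word (default 2000).
#' @param seed Seed for the pair subsampling.
#' @return `data.frame` with `word`, `count`, `fraction`, `mean_rmsd`
#'   (Angstrom; `NA` for single-member words), sorted by decreasing count.
#' @export
word_catalog <- function(chains, max_pairs = 2000, seed = 1) {
  words <- character(0)
  members <- list()
  for (ch in chains) {
    cw <- chain_words(ch$labels)
    if (nrow(cw) == 0) next
    for (k in seq_len(nrow(cw))) {
      s <- cw$start[k]  # 0-based residue start of the 9-mer
      rows <- (3 * s + 1):(3 * s + 27)
      if (max(rows) > nrow(ch$coords)) next
      words <- c(words, cw$word[k])
      members[[length(members) + 1L]] <- ch$coords[rows, , drop = FALSE]
    }
  }
  if (length(words) == 0)
    return(data.frame(word = character(0), count = integer(0),
                      fraction = numeric(0), mean_rmsd = numeric(0)))
  idx <- split(seq_along(words), words)
  rng <- make_rng(seed)
  res <- lapply(names(idx), function(w) {
    ii <- idx[[w]]
    n <- length(ii)
    spread <- NA_real_
    if (n >= 2) {
      pairs <- utils::combn(n, 2)
      if (ncol(pairs) > max_pairs)
        pairs <- pairs[, sample_int(rng, ncol(pairs), max_pairs), drop = FALSE]
      spread <- mean(vapply(seq_len(ncol(pairs)), function(p)
        cpp_rmsd(members[[ii[pairs[1, p]]]], members[[ii[pairs[2, p]]]]),
        numeric(1)))
    }
    data.frame(word = w, count = n, fraction = n / length(words),
               mean_rmsd = spread, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(-out$count, out$word), ]
  rownames(out) <- NULL
  out
}

# Local RNG helpers: keep package randomness isolated and seedable without
# touching the caller's .Random.seed.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$seed <- seed
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$seed)
  res <- force(expr)
  rng$seed <- rng$seed + 1L
  res
}

sample_int <- function(rng, n, size) with_rng(rng, sample.int(n, size))
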