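AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Per-residue physicochemical property table
#'
#' Ten representative property scales (hydropathy, hydrophilicity, residue
#' volume, mass, net charge at neutral pH, polarity, helix and sheet
#' propensity, accessible surface area, isoelectric point) shipped as a
#' plain-text asset. A user-supplied AAindex-style table (TSV, first column
#' `residue`, one numeric column per property) can be substituted.
#'
#' @param file Optional path to an alternative property TSV.
#' @return Numeric 20 x p matrix, rows named by one-letter residue codes.
#' @export
aa_property_table <- function(file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "aa_properties.tsv", package = "pbcoords")
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$residue
  if (!all(AA20 %in% rownames(m)))
    stop("property table must cover the 20 standard residues")
  m[AA20, , drop = FALSE]
}

#' Reduced amino-acid alphabet
#'
#' A (possibly position-specific) many-to-one mapping of the 20 standard
#' residues into identity classes, used to pool rare sequence 5-mers so
#' that their per-block RMSD statistics can be estimated.
#'
#' @param maps Either one named character vector (residue -> class symbol),
#'   applied at all 5 positions, or a list of 5 such vectors (one per
#'   fragment position).
#' @param name Alphabet name (used in feature column names).
#' @return Object of class `reduced_alphabet`.
#' @examples
#' ra <- reduced_alphabet(c(G="h",A="h",V="h",L="h",I="h",C="s",M="s",
#'   F="r",W="r",Y="r",S="p",T="p",N="p",Q="p",P="p",D="n",E="n",
#'   K="b",R="b",H="b"), "six_class")
#' reduce_sequence("GAVLI", ra)
#' @export
reduced_alphabet <- function(maps, name) {
  if (!is.list(maps)) maps <- rep(list(maps), 5)
  if (length(maps) != 5)
    stop("position-specific alphabets need one map per fragment position")
  for (m in maps)
    if (!all(AA20 %in% names(m)))
      stop("each map must be total over the 20 standard residues")
  structure(list(maps = maps, name = name), class = "reduced_alphabet")
}

#' Default reduced alphabets
#'
#' Six complementary alphabets. Five are per-position identity alphabets
#' (`pos1_identity` .. `pos5_identity`): position p keeps the full
#' 20-letter identity while all other positions collapse to a single
#' wildcard class, giving 20 well-populated classes per position whose
#' per-block distance statistics the regression can combine additively --
#' a naive-Bayes-like decomposition of the window. The sixth
#' (`six_class`) keys the whole 5-mer on standard physicochemical
#' groupings -- aliphatic `[GAVLI]`, sulfur `[CM]`, aromatic `[FWY]`,
#' polar `[STNQP]`, acidic `[DE]`, basic `[KRH]` -- and so captures
#' coarse between-position interactions.
#'
#' @return Named list of [reduced_alphabet()] objects.
#' @export
default_reduced_alphabets <- function() {
  six <- c(G = "h", A = "h", V = "h", L = "h", I = "h",
           C = "s", M = "s",
           F = "r", W = "r", Y = "r",
           S = "p", T = "p", N = "p", Q = "p", P = "p",
           D = "n", E = "n",
           K = "b", R = "b", H = "b")
  ident <- stats::setNames(AA20, AA20)
  wild <- stats::setNames(rep("x", 20), AA20)
  out <- lapply(1:5, function(p) {
    maps <- rep(list(wild), 5)
    maps[[p]] <- ident
    reduced_alphabet(maps, paste0("pos", p, "_identity"))
  })
  names(out) <- paste0("pos", 1:5, "_identity")
  c(out, list(six_class = reduced_alphabet(six, "six_class")))
}

#' Map sequence 5-mers to identity-class keys
#'
#' @param seqs Character vector of 5-letter sequences over the standard
#'   residues.
#' @param ra A [reduced_alphabet()].
#' @param nonstandard Policy for non-standard residues: `"wildcard"` maps
#'   them to the class symbol `X` (such keys typically fall back to global
#'   statistics), `"na"` marks the whole key `NA` so the fragment can be
#'   skipped.
#' @return Character vector of class keys (per-position class symbols
#'   concatenated).
#' @export
reduce_sequence <- function(seqs, ra, nonstandard = c("wildcard", "na")) {
  nonstandard <- match.arg(nonstandard)
  if (any(nchar(seqs) != 5)) stop("sequences must be 5-mers")
  chars <- matrix(unlist(strsplit(seqs, "")), ncol = 5, byrow = TRUE)
  key <- matrix("", nrow(chars), 5)
  for (p in 1:5) {
    key[, p] <- unname(ra$maps[[p]][chars[, p]])
    bad <- is.na(key[, p])
    key[bad, p] <- if (nonstandard == "wildcard") "X" else NA_character_
  }
  apply(key, 1, function(r) if (anyNA(r)) NA_character_ else paste(r, collapse = ""))
}

#' Identity-class RMSD statistics
#'
#' For each identity class (reduced-alphabet key) observed in training,
#' computes the minimal sufficient statistics of its distance distribution:
#' the occurrence count and the per-block mean and standard deviation of
#' the 16 RMSDs. Whole-sample (global) statistics are kept alongside for
#' pooled fallbacks and t-like contrasts.
#'
#' @param keys Character vector of class keys (one per training fragment).
#' @param D Numeric n x 16 matrix of structural coordinates aligned with
#'   `keys`.
#' @return Object of class `pb_class_stats`: `n_occ` (named counts), `mu`
#'   and `sigma` (K x 16 matrices; `sigma` is `NA` for singleton classes),
#'   and `global` (`mu0`, `sigma0`, `n`).
#' @export
collect_class_stats <- function(keys, D) {
  keep <- !is.na(keys)
  keys <- keys[keep]
  D <- as.matrix(D)[keep, , drop = FALSE]
  if (length(keys) == 0) stop("empty training set")
  n <- as.integer(table(keys))
  names(n) <- names(table(keys))
  sums <- rowsum(D, keys)
  mu <- sums / n[rownames(sums)]
  sq <- rowsum(D^2, keys)
  varr <- (sq - n[rownames(sq)] * mu^2) / pmax(n[rownames(sq)] - 1, 1)
  sigma <- sqrt(pmax(varr, 0))
  sigma[n[rownames(sigma)] < 2, ] <- NA_real_
  n <- n[rownames(mu)]
  structure(list(n_occ = n, mu = mu, sigma = sigma,
                 global = list(mu0 = colMeans(D),
                               sigma0 = apply(D, 2, stats::sd),
                               n = length(keys))),
            class = "pb_class_stats")
}

#' RMSD-statistic features for sequence windows
#'
#' Emits, per Protein Block j: the class mean distance `mu_j`, its standard
#' deviation `sigma_j` (pooled global sd substituted for singleton or
#' unseen classes), the t-like contrast
#' `(mu_j - mu0_j) / (sigma_j / sqrt(N_occ))` against the whole sample, and
#' the similarity-scale transform `1 / (lambda + mu_j)`; plus the class
#' occurrence count, its `log1p`, and an unseen-class indicator. Unseen
#' classes receive the global statistics with `N_occ = 0` and a zero
#' t-contrast.
#'
#' @param keys Character vector of class keys for the query fragments.
#' @param stats A [collect_class_stats()] result.
#' @param lambda Similarity smoothing constant (Angstrom).
#' @param prefix Column-name prefix (typically the alphabet name).
#' @return Numeric matrix with `length(keys)` rows and 67 named columns.
#' @export
rmsd_stat_features <- function(keys, stats, lambda = 1, prefix = "ra") {
  labs <- colnames(stats$mu)
  if (is.null(labs)) labs <- letters[1:16]
  idx <- match(keys, rownames(stats$mu))
  seen <- !is.na(idx)
  n <- nrow(stats$mu)
  mu <- matrix(stats$global$mu0, length(keys), 16, byrow = TRUE)
  mu[seen, ] <- stats$mu[idx[seen], , drop = FALSE]
  sg <- matrix(stats$global$sigma0, length(keys), 16, byrow = TRUE)
  sg_class <- stats$sigma[idx[seen], , drop = FALSE]
  pooled <- matrix(stats$global$sigma0, sum(seen), 16, byrow = TRUE)
  sg_class[is.na(sg_class)] <- pooled[is.na(sg_class)]
  sg[seen, ] <- sg_class
  nocc <- ifelse(seen, stats$n_occ[idx], 0L)
  tt <- (mu - matrix(stats$global$mu0, length(keys), 16, byrow = TRUE)) /
    (sg / sqrt(pmax(nocc, 1)))
  tt[!seen, ] <- 0
  out <- cbind(mu, sg, tt, 1 / (lambda + mu), nocc, log1p(nocc), as.numeric(!seen))
  colnames(out) <- c(paste0(prefix, ".mu.", labs),
                     paste0(prefix, ".sigma.", labs),
                     paste0(prefix, ".t.", labs),
                     paste0(prefix, ".inv.", labs),
                     paste0(prefix, ".n_occ"),
                     paste0(prefix, ".log_n_occ"),
                     paste0(prefix, ".unseen"))
  out
}

#' Periodicity of a property profile
#'
#' Squared magnitude of the discrete Fourier component of a per-residue
#' property array at period `T`:
#' `(sum_k H_k cos(2 pi k / T))^2 + (sum_k H_k sin(2 pi k / T))^2`.
#' At T = 3.6 this scores the amphipathic alternation characteristic of
#' solvent-exposed alpha-helices; at T = 2 the strand-like alternation.
#'
#' @param values Numeric vector of per-residue property values H_1..H_n.
#' @param T Period in residues (> 0).
#' @return Non-negative score (property units squared).
#' @examples
#' periodicity_feature(rep(1, 5), T = 5)  # full-period cancellation: 0
#' @export
periodicity_feature <- function(values, T) {
  if (T <= 0) stop("period must be positive")
  k <- seq_along(values)
  sum(values * cos(2 * pi * k / T))^2 + sum(values * sin(2 * pi * k / T))^2
}

# Property-transform features over fixed-length sequence contexts.
# Contexts shorter than the nominal width (chain edges) are expected to be
# padded with 'X'; padded positions take the column-mean (neutral) value.
property_features <- function(contexts, table = aa_property_table(),
                              periods = c(2, 3.6)) {
  L <- nchar(contexts[1])
  if (any(nchar(contexts) != L)) stop("contexts must share one width")
  chars <- matrix(unlist(strsplit(contexts, "")), ncol = L, byrow = TRUE)
  center <- (L + 1) %/% 2
  half <- L %/% 2
  pnames <- colnames(table)
  out <- NULL
  for (p in pnames) {
    v <- stats::setNames(table[, p], rownames(table))
    H <- matrix(v[chars], nrow(chars), L)
    H[is.na(H)] <- mean(v)
    cols <- cbind(rowMeans(H),
                  H[, center],
                  rowMeans(H[, 1:half, drop = FALSE]) -
                    rowMeans(H[, (L - half + 1):L, drop = FALSE]))
    cn <- paste0("prop.", p, c(".mean", ".center", ".nc_diff"))
    for (T in periods) {
      k <- seq_len(L)
      cols <- cbind(cols, (H %*% cos(2 * pi * k / T))^2 + (H %*% sin(2 * pi * k / T))^2)
      cn <- c(cn, paste0("prop.", p, ".period", T))
    }
    colnames(cols) <- cn
    out <- if (is.null(out)) cols else cbind(out, cols)
  }
  out
}

#' Feature-generation configuration
#'
#' @param alphabets Named list of [reduced_alphabet()] objects.
#' @param property_table Residue property matrix, see [aa_property_table()].
#' @param flank Flanking residues on each side of the 5-mer included in the
#'   property transforms (0--8).
#' @param lambda Similarity smoothing constant, also used in the
#'   `1/(lambda + mu)` transform.
#' @param periods Periodicities (residues) scored by the Fourier feature.
#' @return Object of class `pb_feature_config`.
#' @export
feature_config <- function(alphabets = default_reduced_alphabets(),
                           property_table = aa_property_table(),
                           flank = 2, lambda = 1, periods = c(2, 3.6)) {
  stopifnot(flank >= 0, flank <= 8)
  structure(list(alphabets = alphabets, property_table = property_table,
                 flank = flank, lambda = lambda, periods = periods),
            class = "pb_feature_config")
}

#' Fit training-set feature statistics
#'
#' Collects the identity-class RMSD statistics of every configured reduced
#' alphabet from the training fragments. The result, together with the
#' configuration, makes feature generation a pure deterministic function of
#' sequence.
#'
#' @param seqs Character vector of training 5-mers.
#' @param D n x 16 matrix of training structural coordinates.
#' @param config A [feature_config()].
#' @return Object of class `pb_feature_stats`.
#' @export
fit_feature_stats <- function(seqs, D, config = feature_config()) {
  stats_list <- lapply(config$alphabets, function(ra)
    collect_class_stats(reduce_sequence(seqs, ra), D))
  structure(list(stats = stats_list, config = config),
            class = "pb_feature_stats")
}

#' Generate the feature matrix for sequence windows
#'
#' @param seqs Character vector of 5-mers (the fragments to describe).
#' @param contexts Character vector of sequence contexts (5-mer plus
#'   `flank` residues each side, padded with `X` at chain edges); defaults
#'   to the bare 5-mers when `NULL` and `flank = 0`.
#' @param stats A [fit_feature_stats()] result.
#' @return Numeric feature matrix with stable, named columns.
#' @export
generate_features <- function(seqs, contexts = NULL, stats) {
  cfg <- stats$config
  if (is.null(contexts)) {
    if (cfg$flank != 0) stop("contexts required when flank > 0")
    contexts <- seqs
  }
  blocks <- lapply(names(cfg$alphabets), function(nm)
    rmsd_stat_features(reduce_sequence(seqs, cfg$alphabets[[nm]]),
                       stats$stats[[nm]], lambda = cfg$lambda, prefix = nm))
  X <- do.call(cbind, blocks)
  cbind(X, property_features(contexts, cfg$property_table, cfg$periods))
}
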