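# Mapping of common non-standard residues to their parents; anything else
# unknown ends the fragment run.
NONSTANDARD_PARENT <- c(MSE = "MET", SEC = "CYS", PYL = "LYS",
                        HYP = "PRO", SEP = "SER", TPO = "THR", PTR = "TYR")

#' Read N/CA/C backbones from a structure file
#'
#' Parses a PDB or mmCIF file (first model only), resolves alternate
#' locations to the highest-occupancy copy, maps common modified residues
#' (e.g. MSE) to their parents, and returns one chain record per chain.
#' Residues missing any of the three backbone atoms are flagged and no
#' fragment window will span them.
#'
#' @param path Structure file.
#' @param format `"auto"` (by extension), `"pdb"` or `"cif"`.
#' @return List of chain records; each is a list with `id`, `length`,
#'   `sequence` (one-letter string), `resno`, `coords` (3L x 3 matrix with
#'   `NA` rows for missing atoms) and `atom_ok` (per-residue logical).
#' @export
read_backbone <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  pdb <- if (format == "cif") bio3d::read.cif(path, verbose = FALSE)
         else bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$elety %in% c("N", "CA", "C") & at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no backbone atoms found in ", path)
  if (is.null(at$insert)) at$insert <- ""
  at$insert[is.na(at$insert)] <- ""
  if (is.null(at$o)) at$o <- 1
  at$o[is.na(at$o)] <- 1
  # highest occupancy wins among alternate locations
  at <- at[order(-at$o), ]
  key <- paste(at$chain, at$resno, at$insert, at$elety)
  at <- at[!duplicated(key), ]
  lapply(split(at, at$chain), function(ca) {
    rkey <- paste(ca$resno, ca$insert)
    ord <- order(ca$resno, ca$insert)
    ca <- ca[ord, ]
    rkey <- rkey[ord]
    resn <- unique(rkey)
    L <- length(resn)
    coords <- matrix(NA_real_, 3 * L, 3,
                     dimnames = list(rep(c("N", "CA", "C"), L),
                                     c("x", "y", "z")))
    resid3 <- character(L)
    for (r in seq_len(L)) {
      rows <- ca[rkey == resn[r], ]
      resid3[r] <- rows$resid[1]
      for (a in seq_len(nrow(rows))) {
        slot <- match(rows$elety[a], c("N", "CA", "C"))
        coords[3 * (r - 1) + slot, ] <- c(rows$x[a], rows$y[a], rows$z[a])
      }
    }
    mapped <- ifelse(resid3 %in% names(NONSTANDARD_PARENT),
                     NONSTANDARD_PARENT[resid3], resid3)
    one <- suppressWarnings(bio3d::aa321(mapped))
    known <- !is.na(one) & one != "X"
    atom_ok <- known & !apply(matrix(is.na(coords[, 1]), nrow = 3), 2, any)
    one[!known] <- "X"
    list(id = ca$chain[1], length = L,
         sequence = paste(one, collapse = ""),
         resno = unique(ca$resno[!duplicated(rkey)]),
         coords = coords, atom_ok = atom_ok)
  })
}

#' Write chain backbones to a PDB file
#'
#' @param chains A list of chain records (see [read_backbone()]) or a
#'   single chain record.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_backbone <- function(chains, path) {
  if (!is.null(chains$coords)) chains <- list(chains)
  xyz <- c(); resno <- c(); resid <- c(); elety <- c(); chain <- c()
  aa123 <- stats::setNames(bio3d::aa123(c(AA20, "X")), c(AA20, "X"))
  # the PDB chain field is a single character: remap longer ids
  ids <- vapply(chains, `[[`, character(1), "id")
  if (any(nchar(ids) != 1) || anyDuplicated(ids)) {
    pool <- c(LETTERS, letters, 0:9)
    if (length(chains) > length(pool))
      stop("too many chains for single-character PDB chain ids")
    for (k in seq_along(chains)) chains[[k]]$id <- pool[k]
  }
  for (ch in chains) {
    L <- ch$length
    seq1 <- strsplit(ch$sequence, "")[[1]]
    rn <- if (!is.null(ch$resno)) ch$resno else seq_len(L)
    ok <- !is.na(ch$coords[, 1])
    xyz <- c(xyz, as.numeric(t(ch$coords[ok, , drop = FALSE])))
    resno <- c(resno, rep(rn, each = 3)[ok])
    resid <- c(resid, rep(unname(aa123[seq1]), each = 3)[ok])
    elety <- c(elety, rep(c("N", "CA", "C"), L)[ok])
    chain <- c(chain, rep(ch$id, 3 * L)[ok])
  }
  bio3d::write.pdb(file = path, xyz = xyz, resno = resno, resid = resid,
                   elety = elety, chain = chain,
                   eleno = seq_along(resno))
  invisible(path)
}

# Per-residue run identifiers: a run ends at a missing backbone atom, an
# unknown residue, or a CA-CA step larger than max_ca_gap (chain break).
chain_runs <- function(chain, max_ca_gap = 4.5) {
  L <- chain$length
  ok <- chain$atom_ok
  run <- rep(NA_integer_, L)
  cur <- 0L
  open <- FALSE
  for (i in seq_len(L)) {
    if (!ok[i]) { open <- FALSE; next }
    if (!open) {
      cur <- cur + 1L
      open <- TRUE
    } else {
      ca_prev <- chain$coords[3 * (i - 2) + 2, ]
      ca_this <- chain$coords[3 * (i - 1) + 2, ]
      if (sqrt(sum((ca_this - ca_prev)^2)) > max_ca_gap) cur <- cur + 1L
    }
    run[i] <- cur
  }
  run
}

#' Overlapping fragment windows of a chain
#'
#' Streams every M-residue window lying fully inside an unbroken run
#' (all backbone atoms present, no CA-CA gap above `max_ca_gap`).
#'
#' @param chain A chain record (see [read_backbone()] or
#'   [generate_corpus()]).
#' @param M Window length in residues.
#' @param max_ca_gap Chain-break distance threshold (Angstrom).
#' @return List of windows; each has `start` (0-based residue index,
#'   half-open window `[start, start + M)`), `fragment` (a
#'   `backbone_fragment`) and `seq` (the window's sequence).
#' @export
iter_fragments <- function(chain, M = 5, max_ca_gap = 4.5) {
  run <- chain_runs(chain, max_ca_gap)
  L <- chain$length
  seq1 <- strsplit(chain$sequence, "")[[1]]
  out <- list()
  if (L >= M) {
    for (s in seq_len(L - M + 1)) {
      r <- run[s:(s + M - 1)]
      if (anyNA(r) || length(unique(r)) != 1) next
      rows <- (3 * (s - 1) + 1):(3 * (s + M - 1))
      out[[length(out) + 1L]] <- list(
        start = s - 1L,
        fragment = as_backbone_fragment(chain$coords[rows, , drop = FALSE]),
        seq = paste(seq1[s:(s + M - 1)], collapse = ""))
    }
  }
  out
}

# context window of width 5 + 2*flank around a 0-based fragment start,
# padded with 'X' beyond the chain
context_window <- function(sequence, start0, flank) {
  L <- nchar(sequence)
  lo <- start0 + 1 - flank
  hi <- start0 + 5 + flank
  pre <- strrep("X", max(0, 1 - lo))
  post <- strrep("X", max(0, hi - L))
  paste0(pre, substr(sequence, max(1, lo), min(L, hi)), post)
}

#' Fragment table of a corpus
#'
#' Slices every chain into overlapping 5-mers (within unbroken runs),
#' computes the 16 structural coordinates of each fragment in one batch,
#' and derives the RMSD nearest-block labels. This is the canonical input
#' to [train_predictor()].
#'
#' @param chains List of chain records, from [read_backbone()] or
#'   [generate_corpus()].
#' @param alphabet A [pb_alphabet()].
#' @param flank Context flank width for downstream feature generation.
#' @param rmsda_labels Also compute RMSDA-based labels (slower).
#' @return A list with vectors `chain`, `start` (0-based), `seq`,
#'   `context`, `label_rmsd` (upper case), optionally `label_rmsda`,
#'   `label_true` (for synthetic chains), and the n x 16 matrix `D`.
#' @export
corpus_fragments <- function(chains, alphabet = pb_alphabet(), flank = 2,
                             rmsda_labels = FALSE) {
  frag_list <- list()
  meta <- list()
  for (ch in chains) {
    wins <- iter_fragments(ch, 5)
    for (w in wins) {
      frag_list[[length(frag_list) + 1L]] <- unclass(w$fragment)
      truth <- if (!is.null(ch$labels)) ch$labels[w$start + 1L] else NA_character_
      meta[[length(meta) + 1L]] <- list(chain = ch$id, start = w$start,
                                        seq = w$seq,
                                        context = context_window(ch$sequence,
                                                                 w$start, flank),
                                        label_true = truth)
    }
  }
  if (length(frag_list) == 0) stop("no usable fragments")
  cube <- array(unlist(frag_list), dim = c(15, 3, length(frag_list)))
  D <- batch_structural_coordinates(cube, alphabet)
  out <- list(chain = vapply(meta, `[[`, character(1), "chain"),
              start = vapply(meta, `[[`, integer(1), "start"),
              seq = vapply(meta, `[[`, character(1), "seq"),
              context = vapply(meta, `[[`, character(1), "context"),
              label_true = vapply(meta, `[[`, character(1), "label_true"),
              label_rmsd = labels_from_distances(D, alphabet),
              D = D)
  if (rmsda_labels) {
    out$label_rmsda <- vapply(seq_len(dim(cube)[3]), function(k)
      assign_pb(extract_dihedrals(as_backbone_fragment(cube[, , k])),
                alphabet, metric = "rmsda"), character(1))
  }
  out
}

#' Write a fragment assignment table (TSV)
#'
#' One row per fragment: chain, 0-based start, RMSD label, RMSDA label (if
#' present) and the 16 distances.
#'
#' @param fragments A [corpus_fragments()] result.
#' @param path Output TSV.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(fragments, path) {
  df <- data.frame(chain = fragments$chain,
                   fragment_start = fragments$start,
                   label_rmsd = fragments$label_rmsd,
                   label_rmsda = if (!is.null(fragments$label_rmsda))
                     fragments$label_rmsda else NA_character_,
                   round(fragments$D, 4),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
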