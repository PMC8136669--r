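# Package-level cache for the default alphabet (built once per session).
.pbcoords_cache <- new.env(parent = emptyenv())

#' The 16 Protein Blocks as dihedral vectors and materialized backbones
#'
#' Loads the canonical Protein Blocks structural alphabet (de Brevern's 16
#' five-residue blocks, labels a..p, each defined by its 8 phi/psi torsions)
#' and materializes every block as a 15-atom N/CA/C backbone under the given
#' covalent geometry, with all peptide bonds trans. The dihedral table ships
#' with the package as a plain-text, versioned data asset
#' (`extdata/protein_blocks.tsv`).
#'
#' @param geometry A [default_geometry()] object used to build the block
#'   backbones.
#' @param file Optional path to an alternative block table (TSV with columns
#'   label, psi1, phi2, ..., phi5).
#' @return An object of class `pb_alphabet`: list with `labels` (character
#'   16), `dihedrals` (16 x 8 matrix), `backbones` (list of
#'   `backbone_fragment`), `geometry`, plus pre-centered coordinates used
#'   internally for fast distance evaluation.
#' @examples
#' A <- pb_alphabet()
#' A$labels
#' @export
pb_alphabet <- function(geometry = default_geometry(), file = NULL) {
  default_call <- is.null(file) && identical(geometry, default_geometry())
  if (default_call && !is.null(.pbcoords_cache$alphabet))
    return(.pbcoords_cache$alphabet)
  if (is.null(file))
    file <- system.file("extdata", "protein_blocks.tsv", package = "pbcoords")
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (nrow(tab) != 16 || anyDuplicated(tab$label))
    stop("a Protein Block alphabet needs 16 uniquely labelled blocks")
  tab <- tab[order(tab$label), ]
  dih <- as.matrix(tab[, -1])
  rownames(dih) <- tab$label
  backbones <- lapply(seq_len(16), function(i)
    build_backbone(dihedral_vector(dih[i, ]), geometry))
  centered <- array(0, dim = c(15, 3, 16))
  ss <- numeric(16)
  for (i in seq_len(16)) {
    Xc <- sweep(unclass(backbones[[i]]), 2, colMeans(backbones[[i]]))
    centered[, , i] <- Xc
    ss[i] <- sum(Xc^2)
  }
  A <- structure(list(labels = tab$label, dihedrals = dih,
                      backbones = backbones, geometry = geometry,
                      centered = centered, sumsq = ss),
                 class = "pb_alphabet")
  if (default_call) .pbcoords_cache$alphabet <- A
  A
}

#' @export
print.pb_alphabet <- function(x, ...) {
  cat("Protein Block alphabet:", length(x$labels), "blocks (",
      paste(x$labels, collapse = ""), ")\n")
  invisible(x)
}

#' Structural coordinates of a 5-residue fragment
#'
#' Represents a fragment by its 16 Kabsch RMSD distances to the Protein
#' Blocks, in alphabet order a..p. These 16 numbers are the fragment's
#' "structural coordinates": they locate the conformation relative to the
#' alphabet and (for a 5-mer under fixed covalent geometry) retain enough
#' information to reconstruct the dihedrals, see
#' [reconstruct_dihedrals()].
#'
#' @param f A `backbone_fragment` with 5 residues (15 atoms), or a
#'   [dihedral_vector()] with M = 5 (built with the alphabet's geometry).
#' @param alphabet A [pb_alphabet()].
#' @return Named numeric vector of 16 non-negative distances (Angstrom).
#' @examples
#' structural_coordinates(build_backbone(helix_dihedrals()))
#' @export
structural_coordinates <- function(f, alphabet = pb_alphabet()) {
  if (inherits(f, "dihedral_vector"))
    f <- build_backbone(f, alphabet$geometry)
  if (fragment_residues(f) != 5)
    stop("structural coordinates are defined for 5-residue fragments")
  r <- as.numeric(cpp_pb_distances(unclass(f), alphabet$centered, alphabet$sumsq))
  names(r) <- alphabet$labels
  r
}

# vectorized distances for an atoms x 3 x n array of fragments
batch_structural_coordinates <- function(frags, alphabet = pb_alphabet()) {
  D <- cpp_batch_pb_distances(frags, alphabet$centered, alphabet$sumsq)
  colnames(D) <- alphabet$labels
  D
}

#' Similarity transform of an RMSD distance
#'
#' Maps a distance r to the similarity score 1 / (lambda + r): strictly
#' decreasing in r, bounded by 1/lambda. The smoothing constant lambda keeps
#' the score finite at zero distance.
#'
#' @param r Non-negative distance(s) in Angstrom.
#' @param lambda Non-negative smoothing constant (Angstrom); must be
#'   positive if any `r` is 0.
#' @return Similarity score(s) in 1/Angstrom.
#' @examples
#' pb_similarity(c(0, 1), lambda = 1)
#' @export
pb_similarity <- function(r, lambda = 1) {
  if (lambda < 0) stop("lambda must be non-negative")
  if (any(r < 0)) stop("distances must be non-negative")
  if (lambda == 0 && any(r == 0))
    stop("similarity undefined at zero distance with lambda = 0")
  1 / (lambda + r)
}

#' Nearest-Protein-Block assignment
#'
#' Assigns a five-residue fragment the label of its closest block, under
#' either the RMSD metric on materialized backbones or the RMSDA metric on
#' dihedrals. Following the field's convention, RMSD assignments are
#' reported in upper case and RMSDA assignments in lower case. Exact ties go
#' to the alphabetically first label.
#'
#' @param x A `backbone_fragment` or [dihedral_vector()] (M = 5). For the
#'   RMSD metric a dihedral input is materialized with the alphabet's
#'   geometry; for RMSDA a coordinate input has its dihedrals extracted.
#' @param alphabet A [pb_alphabet()].
#' @param metric `"rmsd"` or `"rmsda"`.
#' @return Single block label (upper case for RMSD, lower for RMSDA).
#' @examples
#' assign_pb(helix_dihedrals(), metric = "rmsda")
#' @export
assign_pb <- function(x, alphabet = pb_alphabet(), metric = c("rmsd", "rmsda")) {
  metric <- match.arg(metric)
  if (metric == "rmsd") {
    r <- structural_coordinates(x, alphabet)
    toupper(alphabet$labels[which.min(r)])
  } else {
    if (inherits(x, "backbone_fragment")) x <- extract_dihedrals(x)
    if (x$M != 5) stop("assignment is defined for 5-residue fragments")
    a <- vapply(seq_along(alphabet$labels), function(i)
      rmsda(x, dihedral_vector(alphabet$dihedrals[i, ])), numeric(1))
    alphabet$labels[which.min(a)]
  }
}

# fast batch label assignment from a pre-computed distance matrix
labels_from_distances <- function(D, alphabet = pb_alphabet(), upper = TRUE) {
  lab <- alphabet$labels[max.col(-D, ties.method = "first")]
  if (upper) toupper(lab) else lab
}

#' Agreement between two label sequences
#'
#' Fraction of positions where two per-fragment block assignments carry the
#' same letter (case-insensitive, so RMSD- and RMSDA-derived labellings can
#' be compared directly). Optionally stratified by the labels of the first
#' sequence.
#'
#' @param labels1,labels2 Character vectors of equal length.
#' @param per_label If `TRUE`, also return per-block agreement stratified by
#'   `labels1`.
#' @return Agreement fraction in `[0, 1]`, or a list with `overall` and
#'   `per_label` when stratified.
#' @examples
#' assignment_agreement(c("M", "M", "D", "D"), c("m", "m", "d", "k"))
#' @export
assignment_agreement <- function(labels1, labels2, per_label = FALSE) {
  if (length(labels1) != length(labels2))
    stop("label sequences have different lengths")
  l1 <- tolower(labels1); l2 <- tolower(labels2)
  hit <- l1 == l2
  if (!per_label) return(mean(hit))
  list(overall = mean(hit),
       per_label = tapply(hit, l1, mean))
}
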