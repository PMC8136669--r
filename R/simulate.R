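#' Reference Protein Block frequencies
#'
#' Relative frequencies of the 16 blocks among RMSD-assigned 5-mer
#' fragments of representative sequence-unique PDB subsets; used as the
#' default initial/base distribution of the synthetic label chain, so the
#' generated corpora share the strong class imbalance of real data (helix
#' block m ~30%, strand block d ~13%, rare coil blocks ~1-2%).
#'
#' @return Named numeric vector over a..p summing to 1.
#' @export
pb_reference_frequencies <- function() {
  f <- c(a = 5.34, b = 5.70, c = 4.52, d = 12.84, e = 3.75, f = 5.79,
         g = 6.01, h = 1.33, i = 3.83, j = 1.73, k = 5.33, l = 4.65,
         m = 30.26, n = 3.38, o = 2.16, p = 3.37)
  f / sum(f)
}

# Signature residue of each block used by the default emission model:
# helix-like blocks (k,l,m,n) get strong helix formers, strand-like blocks
# (c,d,e,f) beta-branched or aromatic residues, coil-like blocks turn
# formers (G, P, N, D).
default_signature_residues <- function() {
  c(a = "S", b = "Y", c = "F", d = "V", e = "I", f = "T",
    g = "G", h = "N", i = "D", j = "P", k = "E", l = "M",
    m = "A", n = "L", o = "K", p = "R")
}

#' Synthetic corpus configuration
#'
#' Describes the generative model behind [generate_corpus()]: a first-order
#' Markov chain of Protein Block labels along each chain (self-transition
#' `self_transition`, otherwise proportional to `base_frequencies`);
#' per-residue phi/psi set to the block centre of the window centred on the
#' residue plus i.i.d. Gaussian angular noise; rare cis peptide bonds
#' (omega flipped from 180 to 0 with probability `cis_prob` per residue
#' bond, matching the ~0.27% rate seen in X-ray datasets); and residue
#' emission coupled to the local label (the block's signature residue with
#' probability `emission_strength`, otherwise uniform over the 20
#' residues).
#'
#' @param n_chains Number of chains.
#' @param length_range Chain lengths drawn uniformly from this range.
#' @param self_transition Probability that consecutive windows keep the
#'   same label.
#' @param base_frequencies Initial / off-diagonal label distribution.
#' @param noise_sd Angular noise standard deviation (degrees) on each
#'   phi/psi.
#' @param cis_prob Per-bond probability of a cis (omega = 0) peptide bond.
#' @param emission_strength Probability that a residue is its local
#'   block's signature residue.
#' @param signature_residues Named map block -> residue.
#' @return Object of class `pb_corpus_config`.
#' @export
synthetic_corpus_config <- function(n_chains = 150,
                                    length_range = c(80, 200),
                                    self_transition = 0.75,
                                    base_frequencies = pb_reference_frequencies(),
                                    noise_sd = 10,
                                    cis_prob = 0.0027,
                                    emission_strength = 0.5,
                                    signature_residues = default_signature_residues()) {
  stopifnot(n_chains >= 1, length_range[1] >= 9,
            self_transition >= 0, self_transition <= 1,
            noise_sd >= 0, cis_prob >= 0, cis_prob <= 1,
            emission_strength >= 0, emission_strength <= 1)
  p <- base_frequencies / sum(base_frequencies)
  if (length(p) != 16) stop("base_frequencies must cover the 16 blocks")
  structure(list(n_chains = n_chains, length_range = length_range,
                 self_transition = self_transition, base_frequencies = p,
                 noise_sd = noise_sd, cis_prob = cis_prob,
                 emission_strength = emission_strength,
                 signature_residues = signature_residues),
            class = "pb_corpus_config")
}

# label of the window centred on residue i (clamped at chain ends)
center_window_index <- function(i, n_windows) pmin(pmax(i - 2L, 1L), n_windows)

#' Generate a synthetic labelled corpus
#'
#' Samples chains from the model described in [synthetic_corpus_config()]:
#' window labels follow the Markov chain; each residue takes its phi/psi
#' from the block centre of the window centred on it (flanking residues use
#' the matching off-centre angles of the nearest window) plus Gaussian
#' noise; coordinates are built by the internal-coordinate chain builder.
#' Deterministic for a fixed seed; the caller's RNG state is left
#' untouched.
#'
#' @param config A [synthetic_corpus_config()].
#' @param seed Integer seed.
#' @param alphabet A [pb_alphabet()] supplying block centres and geometry.
#' @return List of chain records, each with `id`, `length`, `sequence`,
#'   `labels` (the per-window noise-free reference labels: the RMSD
#'   assignment of the window before angular noise -- because overlapping
#'   windows reconcile their angles through the residue-centred rule, a
#'   window at a label boundary mixes neighbouring block centres and its
#'   reference label is the block nearest to that mixture), `markov_labels`
#'   (the latent Markov path), `residue_labels`, `phi_psi`, `omega`,
#'   `coords` (3L x 3), and `atom_ok`.
#' @export
generate_corpus <- function(config = synthetic_corpus_config(), seed = 1,
                            alphabet = pb_alphabet()) {
  rng <- make_rng(seed)
  with_rng(rng, {
    labs <- names(config$base_frequencies)
    dih <- alphabet$dihedrals[labs, , drop = FALSE]
    geom <- geometry_pack(alphabet$geometry)
    trans <- matrix(rep(config$base_frequencies, each = 16), 16, 16,
                    dimnames = list(labs, labs))
    diag(trans) <- 0
    rs <- rowSums(trans)
    off <- 1 - config$self_transition
    trans[rs > 0, ] <- trans[rs > 0, ] / rs[rs > 0] * off
    trans[rs == 0, ] <- 0
    diag(trans) <- 1 - rowSums(trans)
    lapply(seq_len(config$n_chains), function(ci) {
      lens <- seq(config$length_range[1], config$length_range[2])
      L <- lens[sample.int(length(lens), 1)]
      nw <- L - 4L
      lab <- character(nw)
      lab[1] <- sample(labs, 1, prob = config$base_frequencies)
      for (w in seq_len(nw - 1))
        lab[w + 1] <- sample(labs, 1, prob = trans[lab[w], ])
      src <- center_window_index(seq_len(L), nw)
      pos <- seq_len(L) - src + 1L          # residue's position in its source window
      # pull (psi_i, phi_i) from the source block's angle table:
      # psi of window position p is column 2p-1 (p <= 4), phi is column 2p-2
      psi <- rep(NA_real_, L)
      phi <- rep(NA_real_, L)
      has_psi <- pos <= 4
      has_phi <- pos >= 2
      row <- match(lab[src], labs)
      psi[has_psi] <- dih[cbind(row[has_psi], 2 * pos[has_psi] - 1)]
      phi[has_phi] <- dih[cbind(row[has_phi], 2 * pos[has_phi] - 2)]
      phi_psi <- numeric(2 * (L - 1))
      phi_psi[seq(1, by = 2, length.out = L - 1)] <- psi[1:(L - 1)]
      phi_psi[seq(2, by = 2, length.out = L - 1)] <- phi[2:L]
      clean <- phi_psi
      phi_psi <- wrap_angle(phi_psi + stats::rnorm(2 * (L - 1),
                                                   sd = config$noise_sd))
      omega <- ifelse(stats::runif(L - 1) < config$cis_prob, 0, 180)
      coords <- cpp_build_backbone(phi_psi, omega, geom)
      # noise-free reference labels: the RMSD assignment of each window
      # built from the un-noised angles (cis bonds kept -- they are part of
      # the true conformation, not noise)
      coords0 <- cpp_build_backbone(clean, omega, geom)
      cube <- array(0, dim = c(15, 3, nw))
      for (w in seq_len(nw))
        cube[, , w] <- coords0[(3 * (w - 1) + 1):(3 * (w + 4)), ]
      lab_nf <- labels_from_distances(
        cpp_batch_pb_distances(cube, alphabet$centered, alphabet$sumsq),
        alphabet, upper = FALSE)
      sig <- config$signature_residues[lab[src]]
      use_sig <- stats::runif(L) < config$emission_strength
      seq1 <- ifelse(use_sig, sig, sample(AA20, L, replace = TRUE))
      list(id = sprintf("S%04d", ci), length = L,
           sequence = paste(seq1, collapse = ""),
           labels = lab_nf, markov_labels = lab, residue_labels = lab[src],
           phi_psi = phi_psi, omega = omega,
           coords = `dimnames<-`(coords,
                                 list(rep(c("N", "CA", "C"), L),
                                      c("x", "y", "z"))),
           atom_ok = rep(TRUE, L))
    })
  })
}
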