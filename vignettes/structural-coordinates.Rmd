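---
title: "Structural coordinates for protein backbone fragments: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural coordinates for protein backbone fragments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbcoords)
```

## The representation

Local protein structure is commonly described by assigning every
five-residue backbone fragment to its nearest member of a structural
alphabet — here the 16 Protein Blocks (PBs), labels `a` to `p`, each
defined by 8 dihedral angles $(\psi_1, \phi_2, \psi_2, \ldots, \phi_5)$.
A hard assignment discards most of the geometric information: two
fragments in the same class can differ substantially, and a fragment near
a class boundary is described no better than one at the centre.

`pbcoords` instead represents a fragment by its **structural
coordinates**: the vector of 16 root-mean-square deviations
$(\tilde R_1, \ldots, \tilde R_{16})$ between the fragment's 15 backbone
atoms (N, C$_\alpha$, C per residue) and the materialized backbone of each
block, each at the optimal rigid superposition (Kabsch). The nearest-block
label is recoverable from this vector (its argmin), but the vector also
supports two further operations that a label cannot:

* **similarity regression** — the transform $D = 1/(\lambda + \tilde R_i)$
  maps each distance to a bounded similarity that a per-block regression
  can predict from sequence, and
* **reconstruction** — for a 5-mer under fixed covalent geometry the 16
  distances pin down the 8 torsions, so the conformation can be recovered
  by minimizing
  $L(\Psi) = \sum_{i=1}^{16} \bigl(\tilde R_i - R_i(\Psi)\bigr)^2 .$

## Geometry model and assumptions

Backbones are materialized from dihedrals by sequential
internal-coordinate construction (NeRF): each atom is placed from the
previous three using one bond length, one bond angle and one torsion. The
defaults are Engh–Huber-style ideal values — N–C$_\alpha$ 1.458 Å,
C$_\alpha$–C 1.525 Å, C–N 1.329 Å; N–C$_\alpha$–C 111.2°, C$_\alpha$–C–N
117.2°, C–N–C$_\alpha$ 121.7° — held in a single editable
`default_geometry()` object so sensitivity to the table can be probed.
Peptide bonds are trans ($\omega = 180°$) unless stated; carbonyl oxygens,
side chains and hydrogens are outside the model. Torsions follow the
IUPAC right-hand sign convention and are always wrapped to $(-180, 180]$.

Two angular caveats shape several design decisions:

* **RMSDA is position-blind.** The angular metric
  $\mathrm{RMSDA} = \sqrt{\tfrac{1}{8}\sum_k \Delta_k^2}$ (circularly
  wrapped $\phi/\psi$ differences; $\omega$ is not scored) weights a
  central torsion exactly like a terminal one, although a central change
  moves far more mass in space. The package ships worked examples in the
  test suite: a fragment 14° of RMSDA away from the standard helix
  ($\phi=-57, \psi=-47$) can lie 0.08 Å or 1.0 Å away in space, and a
  single cis flip is spatially conspicuous at RMSDA 0. Assignments are
  therefore offered under both metrics (upper-case letters for RMSD,
  lower-case for RMSDA, ties alphabetically first), with RMSD the default.
* **Terminal torsions are weak levers.** $\psi_1$ and $\phi_5$ each move a
  single atom of fifteen, so distance-based criteria constrain them an
  order of magnitude more loosely than central torsions. This drives the
  reconstruction conditioning discussed below.

## Kabsch superposition

The optimal-rotation RMSD is computed from the SVD of the 3×3
cross-covariance of the centred coordinate sets, with the smallest
singular value sign-flipped when the determinant is negative, so a proper
rotation is always used and reflections are never returned (also for
rank-deficient, e.g. collinear, inputs). The compiled hot loop deliberately
uses the full SVD rather than the cheaper eigendecomposition of
$H^\top H$: taking square roots of eigenvalues halves the precision of
small singular values, and the resulting $\sim 10^{-8}$ jitter in the loss
destabilizes the finite-difference line searches of the reconstruction
optimizer. Self-distances are numerically $\lesssim 10^{-7}$ Å, which is
the scale at which "zero" should be read throughout.

## Reconstruction: optimizers, starts, conditioning

`reconstruct_dihedrals()` minimizes $L(\Psi)$ over the 8 torsions with
central-difference gradients (step $10^{-4}$ degrees) through the full
build-and-superpose pipeline. The default **quasi-Newton** route is the
PORT routine (`nlminb`) followed by restarts from the wrapped parameters
(which reset the Hessian approximation) while they improve the loss; a
**conjugate-gradient** variant (Polak–Ribière) is exposed for comparison
but converges much more slowly on this landscape. The conventional start
is the all-zero angle vector; the reference worked example (a fragment
with angles near block `b`) is inverted from that start to
$\sim 10^{-17}$ loss.

The loss surface has genuine local minima: from the all-zero start alone,
noiseless targets sampled ±30° around block centres are inverted only
about three quarters of the time, the failures stalling at small positive
losses far from the generator. `multi_start = TRUE` therefore retries
deterministically from the 16 block centres in order of increasing target
distance — the natural restart set, since the target vector itself says
which centres are plausible — and recovers essentially always in our
sweeps (200/200 at the package's test scale). Convergence is declared at
loss $< 10^{-10}$ Å²; iteration caps return the best-so-far angles with a
warning rather than failing.

**Conditioning.** The inversion is unique but not uniformly
well-conditioned: crankshaft-like torsion combinations (and the terminal
angles) move the 16 distances by as little as $\sim 10^{-3}$ Å per
degree. Independent Gaussian noise of 0.01 Å on the distances already
produces median angular errors around 10–15°, and 0.05 Å around 30°,
while the recovered structure still tracks the truth. Reconstruction from
*predicted* (noisy) distances therefore bounds angular precision well
below what noiseless inversion suggests; more basic structures would be
needed to tighten it.

**Degrees-of-freedom accounting.** `dof_count()` gives the minimal number
of independent basic-structure distances for an $N$-residue backbone:
$9N$ raw coordinates, $-6$ for rigid motions, $-(3N-1)$ fixed bond
lengths, $-(3N-2)$ fixed bond angles, $-(N-1)$ fixed $\omega$ — i.e.
$9N,\; 9N-6,\; 6N-5,\; 3N-3,\; 2N-2$. With lengths and angles fixed a
5-mer needs at least 12 basic structures and a 9-mer 24, so 16 blocks are
sufficient for 5-mers only; with everything fixed the count collapses to
the $2(N-1)$ free torsions, the dimension of the search space above. The
flag order is constrained (angles require lengths, $\omega$ requires
angles) because each row's subtraction assumes the previous ones.

## Structural Words

A Structural Word is the string of 5 consecutive overlapping fragment
labels, describing 9 residues; a chain of length $L$ yields $\max(L-8,0)$
words within unbroken runs. `word_catalog()` reports counts, fractions
and the mean pairwise 27-atom RMSD within each word (undefined, not zero,
for singletons). All-pairs RMSD is subsampled to at most 2000 seeded
random pairs per word (switchable to exact) — at the corpus sizes the
package targets this changes third-decimal digits at most. On synthetic
helix-dominant corpora the RMSD-based catalog reproduces the expected
qualitative contrast with the RMSDA-based one: more distinct words, and
lower within-word spread.

## Sequence features

The predictor pool combines two information sources, both computed from
the training set only and bundled with the trained model so that feature
generation is a pure function of sequence.

**Reduced-alphabet RMSD statistics.** With $20^5$ possible 5-mers, most
sequences are unseen; reduced alphabets pool them into identity classes
with estimable statistics $\{N_{occ}, \mu_j, \sigma_j\}_{j=1..16}$ (count,
per-block mean and sd of the 16 distances). Shipped defaults are five
per-position identity alphabets (20 well-populated classes each; the
regression combines their per-position evidence additively, a
naive-Bayes-like decomposition) plus a six-class physicochemical grouping
of the whole 5-mer (aliphatic [GAVLI], sulfur [CM], aromatic [FWY], polar
[STNQP], acidic [DE], basic [KRH]) that captures coarse interactions. An
earlier three-alphabet default with a finer position-specific map was
dropped: its $\sim 6500$-key space is too sparse at desk-scale corpora and
measurably hurt held-out accuracy. Alphabets are plain data and fully
user-replaceable. Emitted features per class and block: $\mu_j$,
$\sigma_j$ (pooled global sd substituted for singletons), the t-like
contrast $(\mu_j - \mu^0_j)\big/(\sigma_j/\sqrt{N_{occ}})$ against the
whole sample, $1/(\lambda+\mu_j)$, plus $N_{occ}$, $\log(1+N_{occ})$ and
an unseen-class indicator (unseen classes fall back to global statistics
with a zero contrast).

**Physicochemical transforms.** Ten representative per-residue scales
(hydropathy, hydrophilicity, volume, mass, charge, polarity, helix and
sheet propensity, surface area, isoelectric point) ship as a small
editable table; any AAindex-style TSV can be substituted. For each scale
the window (5-mer plus 2 flanking residues each side by default,
`X`-padded at chain ends with the neutral column mean) yields its mean,
centre value, N/C-terminal difference, and the periodicity score
$\bigl(\sum_k H_k \cos\tfrac{2\pi k}{T}\bigr)^2 +
 \bigl(\sum_k H_k \sin\tfrac{2\pi k}{T}\bigr)^2$
at $T = 3.6$ (amphipathic helical alternation: high values mean
hydrophobic and hydrophilic residues face opposite sides of a helix) and
$T = 2$ (strand alternation).

## Model fitting

Each of the 16 blocks gets its own bidirectional stepwise linear
regression of the similarity $1/(\lambda + \tilde R_i)$ (default
$\lambda = 1$ Å, configurable; the value is bundled with the model) on the
z-scored feature pool. Selection alternates a backward sweep (drop any
included feature whose partial-F p-value exceeds the exit threshold 0.05)
with a forward step (admit the best candidate whose p-value passes the
entry threshold 0.01). Entry p-values are **Bonferroni-adjusted across the
candidate pool**: with hundreds of candidates, an unadjusted per-feature
threshold would admit noise features at a rate near one per fit, whereas
the adjusted rule keeps the pure-noise selection rate at about the nominal
level — this is the package's choice where the method family is otherwise
underdetermined ("bidirectional elimination"). An AIC criterion is
available. All OLS quantities come from the Gram matrix, so each step is
independent of the row count; exact ties resolve to the lowest column
index, making the fit reproducible bit-for-bit. Exit ≥ entry prevents
add/drop cycling; a numerically exact fit stops selection.

Classification takes the argmax of the 16 predicted similarities (ties to
the alphabetically first label) — invariant under any strictly increasing
transform of the scores. Evaluation reports overall accuracy (Q16), the
16×16 confusion matrix and per-block accuracy. Train/test splits are
always at the **chain level** (a chain's overlapping windows share 4 of 5
residues; splitting within chains would leak). Models serialize to JSON
with their full feature provenance (alphabets, property table, class
statistics, scaling, $\lambda$).

## The synthetic corpus generator

`generate_corpus()` defines the conditions under which the pipeline is
validated. Per chain: window labels follow a first-order Markov chain
(self-transition 0.75; base/initial distribution = block frequencies
observed in representative sequence-unique PDB subsets, so helix block `m`
dominates at ~30%); each residue takes its $\phi/\psi$ from the block
centre of the window centred on it (flanking residues use the matching
off-centre angles of the nearest window), plus i.i.d. Gaussian noise of
10° by default; peptide bonds flip to cis with probability 0.0027 per
bond, the rate seen in X-ray datasets; residues are emitted from the local
label — the block's signature residue with probability 0.5, otherwise
uniform. Signature residues follow coarse real propensities (helix blocks
get helix formers A/L/M/E, strand blocks β-branched V/I/T/F, coil blocks
G/P/N/D). Chain count 150 and lengths uniform on 80–200 are the reference
scale (~20 000 windows); the end-to-end validation uses 185 chains so the
training split alone holds ~20 000 fragments.

Because overlapping windows share residues, a window straddling a label
boundary mixes neighbouring block centres; the per-window **reference
label** is therefore defined as the RMSD assignment of the window built
from the *un-noised* angles (cis bonds kept — they are true conformation,
not noise), with the latent Markov path kept separately. Under this
definition the RMSD assignment of the noisy structure recovers the
reference label ~95% of the time at 5° noise, degrading smoothly with
noise, and a noise-free single-block corpus is recovered perfectly.

The emission coupling (0.5) is deliberately stronger than real
sequence–structure coupling: the generator exists to verify that the
feature/selection/classification machinery recovers a known planted
signal end-to-end (held-out Q16 ≈ 0.43 versus 0.0625 chance at the
reference scale), not to estimate attainable accuracy on real proteins.
What the generator does **not** emulate: real Ramachandran anisotropy and
residue-specific torsion preferences, long-range packing constraints,
non-ideal covalent geometry, homology structure in the corpus, missing
atoms and experimental noise. Passing the synthetic pipeline therefore
demonstrates correctness of the machinery, and nothing about accuracy on
PDB-scale data.

## Problem sizes and runtimes

The shipped validation uses the sizes a desk machine handles comfortably:
1000 round-trip fragments, 100 superposition-oracle pairs (with one
10⁶-rotation deep check), 200 reconstruction recoveries, 100 stepwise
noise replicates, and one 185-chain end-to-end train/test run (~25 000
fragments, ~450 features, 16 stepwise fits — about half a minute). The
full test suite runs in roughly two minutes on one CPU.

## Known limitations

* Reconstruction assumes $\omega = 180$; cis-containing 5-mers are
  represented (and simulated) but not inverted — consistent with the
  degrees-of-freedom result that 16 blocks cannot pin down the extra
  torsions once $\omega$ is free.
* Angular precision of reconstruction from noisy distances is limited by
  sloppy torsion combinations (see Conditioning above).
* Fragments longer than 5 residues are described via Structural Words,
  not by joint reconstruction.
* The predictor is homology-free by construction; it will not benefit
  from close homologues the way profile-based methods do, and membrane or
  otherwise atypical physicochemistry is outside the feature model.
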