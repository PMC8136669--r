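#' Squared mismatch loss of a candidate conformation
#'
#' Builds the backbone of a candidate 5-mer from its 8 phi/psi angles (omega
#' fixed at 180), computes its 16 distances to the Protein Blocks, and
#' returns the squared deviation from a target structural-coordinate
#' vector: `sum_i (target_i - R_i(candidate))^2`. This pure-R evaluation is
#' the reference implementation; [reconstruct_dihedrals()] uses an
#' equivalent compiled path.
#'
#' @param phi_psi Numeric vector of 8 candidate angles (degrees), ordered
#'   psi_1, phi_2, ..., phi_5, or a [dihedral_vector()] with M = 5.
#' @param target Numeric vector of 16 target distances (Angstrom), in
#'   alphabet order.
#' @param alphabet A [pb_alphabet()].
#' @return Non-negative squared-Angstrom loss; 0 exactly when the candidate
#'   reproduces the target distances.
#' @examples
#' A <- pb_alphabet()
#' tgt <- structural_coordinates(build_backbone(helix_dihedrals()), A)
#' pb_distance_loss(helix_dihedrals(), tgt, A)
#' @export
pb_distance_loss <- function(phi_psi, target, alphabet = pb_alphabet()) {
  if (inherits(phi_psi, "dihedral_vector")) phi_psi <- phi_psi$phi_psi
  if (length(phi_psi) != 8) stop("a 5-mer candidate has 8 phi/psi angles")
  if (length(target) != 16) stop("target must hold 16 distances")
  f <- build_backbone(dihedral_vector(phi_psi), alphabet$geometry)
  r <- structural_coordinates(f, alphabet)
  sum((as.numeric(target) - r)^2)
}

#' Reconstruct backbone dihedrals from structural coordinates
#'
#' Inverts the 16-distance representation: starting from a given angle
#' vector (default all zeros), minimizes the squared mismatch loss over the
#' 8 phi/psi torsions with a quasi-Newton (BFGS) or conjugate-gradient
#' method. Gradients are central finite differences of the loss through the
#' backbone build and Kabsch superposition. Deterministic for a fixed start
#' and settings.
#'
#' @param target Numeric vector of 16 target distances (alphabet order), or
#'   a result of [structural_coordinates()].
#' @param alphabet A [pb_alphabet()].
#' @param start Numeric vector of 8 starting angles (degrees; the all-zero
#'   vector by default).
#' @param method `"quasi-newton"` (alias `"BFGS"`) or
#'   `"conjugate-gradient"` (alias `"CG"`). The quasi-Newton route is the
#'   robust default; the conjugate-gradient variant is exposed for
#'   comparison and converges more slowly on this landscape.
#' @param tolerance Loss value at which the optimization is accepted as an
#'   exact inversion (squared Angstrom); drives multi-start early exit and
#'   restart polishing.
#' @param max_iterations Iteration cap per optimizer run; exhausting all
#'   runs above `tolerance` returns the best-so-far result with
#'   `converged = FALSE`.
#' @param multi_start If `TRUE`, after a start that stalls above
#'   `tolerance`, retries deterministically from the 16 block centres in
#'   order of increasing target distance, keeping the best local minimum.
#'   The loss landscape has genuine local minima, so a noiseless target is
#'   not always inverted from the all-zero start alone; the block centres
#'   are the natural deterministic restart set.
#' @param gradient_step Central-difference step in degrees.
#' @return List with `dihedrals` (a [dihedral_vector()], angles wrapped to
#'   (-180, 180]), `loss` (achieved squared loss), `converged`, and
#'   `starts_used`.
#' @examples
#' A <- pb_alphabet()
#' tgt <- structural_coordinates(build_backbone(helix_dihedrals()), A)
#' fit <- reconstruct_dihedrals(tgt, A)
#' round(fit$dihedrals$phi_psi, 2)
#' @export
reconstruct_dihedrals <- function(target, alphabet = pb_alphabet(),
                                  start = rep(0, 8),
                                  method = c("quasi-newton", "BFGS",
                                             "conjugate-gradient", "CG"),
                                  tolerance = 1e-10,
                                  max_iterations = 3000,
                                  multi_start = FALSE,
                                  gradient_step = 1e-4) {
  method <- match.arg(method)
  method <- if (method %in% c("quasi-newton", "BFGS")) "qn" else "cg"
  target <- as.numeric(target)
  if (length(target) != 16 || any(target < 0))
    stop("target must hold 16 non-negative distances")
  if (length(start) != 8) stop("start must hold 8 angles")
  geom <- geometry_pack(alphabet$geometry)
  fn <- function(x) cpp_loss(x, target, alphabet$centered, alphabet$sumsq, geom)
  gr <- function(x) as.numeric(cpp_loss_grad(x, target, alphabet$centered,
                                             alphabet$sumsq, geom, gradient_step))
  run1 <- function(par0) {
    if (method == "qn") {
      f <- stats::nlminb(par0, fn, gr,
                         control = list(iter.max = max_iterations,
                                        eval.max = 2 * max_iterations,
                                        abs.tol = 0, rel.tol = 1e-15))
      list(par = f$par, value = f$objective)
    } else {
      f <- suppressWarnings(stats::optim(par0, fn, gr, method = "CG",
        control = list(maxit = max_iterations, reltol = 1e-15, type = 2)))
      list(par = f$par, value = f$value)
    }
  }
  # one start: optimize, then re-start from the wrapped parameters (resets
  # the Hessian approximation) while that still improves the loss
  solve_from <- function(par0) {
    f <- run1(par0)
    for (r in 1:5) {
      if (f$value < tolerance) break
      f2 <- run1(wrap_angle(f$par))
      if (f2$value < f$value) f <- f2 else break
    }
    f
  }
  best <- solve_from(start)
  starts_used <- 1L
  if (multi_start && best$value >= tolerance) {
    for (i in order(target)) {
      f <- solve_from(unname(alphabet$dihedrals[i, ]))
      starts_used <- starts_used + 1L
      if (f$value < best$value) best <- f
      if (best$value < tolerance) break
    }
  }
  if (best$value >= tolerance)
    warning("reconstruction stalled at loss ", signif(best$value, 3),
            "; returning best-so-far angles (possible local minimum)")
  list(dihedrals = dihedral_vector(wrap_angle(best$par)),
       loss = best$value,
       converged = best$value < tolerance,
       starts_used = starts_used)
}

#' Degrees of freedom of an N-residue backbone under geometric constraints
#'
#' Counts the independent parameters needed to specify an N-residue N/CA/C
#' backbone: 9N raw coordinates, minus 6 for rigid-motion invariance, minus
#' 3N-1 when bond lengths are fixed, minus a further 3N-2 when bond angles
#' are fixed, minus N-1 when the peptide-bond omega torsions are fixed.
#' The count is a lower bound on the number of (fairly unrelated) basic
#' structures whose distances determine the conformation unambiguously.
#'
#' @param N Residue count (>= 2).
#' @param rigid_invariance Discount the 6 rigid-motion degrees of freedom.
#' @param fix_bond_lengths Treat all 3N-1 bond lengths as fixed.
#' @param fix_bond_angles Treat all 3N-2 bond angles as fixed (requires
#'   `fix_bond_lengths`).
#' @param fix_omega Fix the N-1 peptide-bond torsions (requires
#'   `fix_bond_angles`): what remains are the 2(N-1) phi/psi torsions.
#' @return Integer degree-of-freedom count.
#' @examples
#' dof_count(5, fix_bond_lengths = TRUE, fix_bond_angles = TRUE)  # 12
#' dof_count(9, fix_bond_lengths = TRUE, fix_bond_angles = TRUE)  # 24
#' @export
dof_count <- function(N, rigid_invariance = TRUE,
                      fix_bond_lengths = FALSE,
                      fix_bond_angles = FALSE,
                      fix_omega = FALSE) {
  if (N < 2) stop("N must be at least 2")
  if (fix_bond_angles && !fix_bond_lengths)
    stop("fixing bond angles requires fixed bond lengths")
  if (fix_omega && !fix_bond_angles)
    stop("fixing omega torsions requires fixed bond angles")
  dof <- 9 * N
  if (rigid_invariance) dof <- dof - 6
  if (fix_bond_lengths) dof <- dof - (3 * N - 1)
  if (fix_bond_angles)  dof <- dof - (3 * N - 2)
  if (fix_omega)        dof <- dof - (N - 1)
  as.integer(dof)
}
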