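#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double DEG = M_PI / 180.0;

// Place atom D from the three preceding atoms A, B, C using the bond length
// r (C-D), the bond angle theta at C (B-C-D, degrees) and the torsion chi
// (A-B-C-D, degrees, IUPAC right-hand sign).
static arma::rowvec3 place_atom(const arma::rowvec3& A,
                                const arma::rowvec3& B,
                                const arma::rowvec3& C,
                                double r, double theta, double chi) {
  arma::rowvec3 bc = arma::normalise(C - B, 2);
  arma::rowvec3 n  = arma::normalise(arma::cross(B - A, bc), 2);
  arma::rowvec3 m  = arma::cross(n, bc);
  double th = theta * DEG, ch = chi * DEG;
  arma::rowvec3 d = -r * std::cos(th) * bc
                  +  r * std::sin(th) * std::cos(ch) * m
                  -  r * std::sin(th) * std::sin(ch) * n;
  return C + d;
}

// Sequential internal-coordinate (NeRF) construction of an M-residue
// N/CA/C backbone. phi_psi is ordered (psi_1, phi_2, psi_2, ..., phi_M),
// omega has M-1 peptide torsions. geom holds
// (b_NCA, b_CAC, b_CN, a_NCAC, a_CACN, a_CNCA) in Angstrom / degrees.
// The first three atoms sit in the canonical frame: N1 at the origin,
// CA1 on +x, C1 in the xy-plane with y > 0.
// [[Rcpp::export]]
arma::mat cpp_build_backbone(const arma::vec& phi_psi,
                             const arma::vec& omega,
                             const arma::vec& geom) {
  const int M = (int)phi_psi.n_elem / 2 + 1;
  const double bNCA = geom[0], bCAC = geom[1], bCN = geom[2];
  const double aNCAC = geom[3], aCACN = geom[4], aCNCA = geom[5];
  arma::mat X(3 * M, 3, arma::fill::zeros);
  X(1, 0) = bNCA;
  X(2, 0) = bNCA - bCAC * std::cos(aNCAC * DEG);
  X(2, 1) = bCAC * std::sin(aNCAC * DEG);
  for (int i = 0; i < M - 1; ++i) {
    int b = 3 * i;
    X.row(b + 3) = place_atom(X.row(b),     X.row(b + 1), X.row(b + 2),
                              bCN,  aCACN, phi_psi[2 * i]);       // N(i+1), psi_i
    X.row(b + 4) = place_atom(X.row(b + 1), X.row(b + 2), X.row(b + 3),
                              bNCA, aCNCA, omega[i]);             // CA(i+1), omega_i
    X.row(b + 5) = place_atom(X.row(b + 2), X.row(b + 3), X.row(b + 4),
                              bCAC, aNCAC, phi_psi[2 * i + 1]);   // C(i+1), phi_(i+1)
  }
  return X;
}

// The optimal-superposition residual needs only the singular values of the
// 3x3 cross-covariance (smallest one sign-flipped when the determinant is
// negative, excluding reflections). Full SVD keeps the loss smooth to
// machine precision, which the finite-difference gradients of the
// reconstruction optimizer rely on.
static double kabsch_rmsd_centered(const arma::mat& Pc, double ssP,
                                   const arma::mat& Qc, double ssQ) {
  arma::mat33 H = Pc.t() * Qc;
  arma::vec3 s;
  arma::mat33 U, V;
  arma::svd(U, s, V, H);
  double d = (arma::det(H) < 0.0) ? -1.0 : 1.0;
  double ss = ssP + ssQ - 2.0 * (s[0] + s[1] + d * s[2]);
  if (ss < 0.0) ss = 0.0;
  return std::sqrt(ss / (double)Pc.n_rows);
}

// Kabsch-optimal RMSD between two equal-size coordinate sets (rows = atoms).
// [[Rcpp::export]]
double cpp_rmsd(const arma::mat& P, const arma::mat& Q) {
  arma::mat Pc = P.each_row() - arma::mean(P, 0);
  arma::mat Qc = Q.each_row() - arma::mean(Q, 0);
  return kabsch_rmsd_centered(Pc, arma::accu(Pc % Pc), Qc, arma::accu(Qc % Qc));
}

// 16 distances from one fragment to pre-centered reference backbones.
// pbc: atoms x 3 x n_blocks cube of centered block coordinates; pb_ss their
// squared norms.
// [[Rcpp::export]]
arma::vec cpp_pb_distances(const arma::mat& F,
                           const arma::cube& pbc,
                           const arma::vec& pb_ss) {
  arma::mat Fc = F.each_row() - arma::mean(F, 0);
  double ssF = arma::accu(Fc % Fc);
  arma::vec out(pbc.n_slices);
  for (arma::uword i = 0; i < pbc.n_slices; ++i)
    out[i] = kabsch_rmsd_centered(Fc, ssF, pbc.slice(i), pb_ss[i]);
  return out;
}

// Batch version: frags is atoms x 3 x n_fragments; returns n_fragments x n_blocks.
// [[Rcpp::export]]
arma::mat cpp_batch_pb_distances(const arma::cube& frags,
                                 const arma::cube& pbc,
                                 const arma::vec& pb_ss) {
  arma::mat out(frags.n_slices, pbc.n_slices);
  for (arma::uword k = 0; k < frags.n_slices; ++k)
    out.row(k) = cpp_pb_distances(frags.slice(k), pbc, pb_ss).t();
  return out;
}

// Squared mismatch loss between a target 16-distance vector and the
// distances of the backbone built from candidate phi/psi angles (omega 180).
// [[Rcpp::export]]
double cpp_loss(const arma::vec& phi_psi,
                const arma::vec& target,
                const arma::cube& pbc,
                const arma::vec& pb_ss,
                const arma::vec& geom) {
  const int M = (int)phi_psi.n_elem / 2 + 1;
  arma::vec omega(M - 1);
  omega.fill(180.0);
  arma::mat F = cpp_build_backbone(phi_psi, omega, geom);
  arma::vec r = cpp_pb_distances(F, pbc, pb_ss);
  return arma::accu(arma::square(target - r));
}

// Central-difference gradient of cpp_loss; step in degrees.
// [[Rcpp::export]]
arma::vec cpp_loss_grad(const arma::vec& phi_psi,
                        const arma::vec& target,
                        const arma::cube& pbc,
                        const arma::vec& pb_ss,
                        const arma::vec& geom,
                        double step) {
  arma::vec g(phi_psi.n_elem);
  arma::vec x = phi_psi;
  for (arma::uword j = 0; j < x.n_elem; ++j) {
    double x0 = x[j];
    x[j] = x0 + step;
    double up = cpp_loss(x, target, pbc, pb_ss, geom);
    x[j] = x0 - step;
    double dn = cpp_loss(x, target, pbc, pb_ss, geom);
    x[j] = x0;
    g[j] = (up - dn) / (2.0 * step);
  }
  return g;
}
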