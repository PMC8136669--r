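# Shared helpers: random fragments and rigid transforms.

random_dihedrals <- function(M = 5, with_cis = FALSE) {
  omega <- rep(180, M - 1)
  if (with_cis) omega[sample(M - 1, 1)] <- 0
  dihedral_vector(runif(2 * (M - 1), -180, 180), omega)
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c + a * d), 2 * (b * d - a * c),
           2 * (b * c - a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d + a * b),
           2 * (b * d + a * c), 2 * (c * d - a * b), a^2 - b^2 - c^2 + d^2),
         3, 3)
}

rigid_copy <- function(f) {
  R <- random_rotation()
  t(R %*% t(unclass(f))) + matrix(rnorm(3, sd = 5), nrow(f), 3, byrow = TRUE)
}

# Circular absolute difference in degrees
ang_diff <- function(a, b) abs(wrap_angle(a - b))
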