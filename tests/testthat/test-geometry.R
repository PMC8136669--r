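test_that("build/extract dihedrals round-trip to 1e-6 degrees", {
  set.seed(11)
  for (k in 1:100) {
    d <- random_dihedrals(M = sample(2:8, 1), with_cis = k %% 5 == 0)
    d2 <- extract_dihedrals(build_backbone(d))
    expect_lt(max(ang_diff(d2$phi_psi, d$phi_psi)), 1e-6)
    expect_lt(max(ang_diff(d2$omega, d$omega)), 1e-6)
  }
  # minimal fragment, all-zero torsions
  d0 <- dihedral_vector(c(0, 0))
  f0 <- build_backbone(d0)
  expect_equal(nrow(f0), 6)
  expect_lt(max(ang_diff(extract_dihedrals(f0)$phi_psi, 0)), 1e-9)
})

test_that("built backbones respect the covalent geometry table", {
  g <- default_geometry()
  f <- build_backbone(random_dihedrals(), g)
  bonds <- sqrt(rowSums((unclass(f)[-1, ] - unclass(f)[-15, ])^2))
  expect_equal(bonds,
               rep(unname(g$bond_lengths[c("N-CA", "CA-C", "C-N")]),
                   length.out = 14),
               tolerance = 1e-9, ignore_attr = TRUE)
  # canonical frame
  expect_equal(unname(unclass(f)[1, ]), c(0, 0, 0))
  expect_equal(unname(unclass(f)[2, 2:3]), c(0, 0))
  expect_equal(unname(unclass(f)[3, 3]), 0)
})

test_that("a cis peptide bond set at build time is extracted as omega = 0", {
  d <- dihedral_vector(rep(c(-47, -57), 4), omega = c(180, 180, 0, 180))
  expect_equal(extract_dihedrals(build_backbone(d))$omega,
               c(180, 180, 0, 180), tolerance = 1e-8)
})

test_that("invalid fragments are rejected", {
  expect_error(dihedral_vector(numeric(0)), "M >= 2")
  expect_error(dihedral_vector(c(1, 2, 3)), "even length")
  expect_error(extract_dihedrals(as_collinear <- structure(
    matrix(c(0:5, rep(0, 12)), 6, 3), class = "backbone_fragment")),
    "collinear")
})

test_that("kabsch superposition is exact on rigid-transform copies", {
  set.seed(21)
  f <- build_backbone(random_dihedrals())
  shifted <- unclass(f) + matrix(c(5, -3, 2), 15, 3, byrow = TRUE)
  res <- kabsch_superpose(f, shifted)
  expect_equal(res$rmsd, 0, tolerance = 1e-9)
  expect_equal(res$rotation, diag(3), tolerance = 1e-7)
  expect_equal(res$translation, c(5, -3, 2), tolerance = 1e-7)
  rotated <- rigid_copy(f)
  expect_equal(kabsch_superpose(f, rotated)$rmsd, 0, tolerance = 1e-9)
  # applying the returned transform reproduces the target
  aligned <- unclass(f) %*% res$rotation +
    matrix(res$translation, 15, 3, byrow = TRUE)
  expect_equal(aligned, shifted, tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(kabsch_superpose(f, unclass(f)[1:9, ]), "atom counts")
})

test_that("rmsd is a pseudo-metric invariant under rigid transforms", {
  set.seed(31)
  for (k in 1:20) {
    f1 <- build_backbone(random_dihedrals())
    f2 <- build_backbone(random_dihedrals())
    r <- backbone_rmsd(f1, f2)
    expect_gte(r, 0)
    expect_equal(backbone_rmsd(f2, f1), r, tolerance = 1e-12)
    expect_equal(backbone_rmsd(rigid_copy(f1), f2), r, tolerance = 1e-9)
    expect_equal(backbone_rmsd(f1, rigid_copy(f2)), r, tolerance = 1e-9)
  }
  f <- build_backbone(helix_dihedrals())
  expect_lt(backbone_rmsd(f, f), 1e-6)
})

test_that("compiled rmsd agrees with an independent reference implementation", {
  set.seed(41)
  for (k in 1:10) {
    f1 <- build_backbone(random_dihedrals())
    f2 <- build_backbone(random_dihedrals())
    ref <- bio3d::rmsd(as.numeric(t(unclass(f1))), as.numeric(t(unclass(f2))),
                       fit = TRUE)
    expect_equal(backbone_rmsd(f1, f2), ref, tolerance = 1e-3)
  }
})

test_that("kabsch rmsd is never beaten by sampled rotations", {
  set.seed(51)
  for (k in 1:20) {
    P <- unclass(build_backbone(random_dihedrals()))
    Q <- unclass(build_backbone(random_dihedrals()))
    Pc <- scale(P, scale = FALSE); Qc <- scale(Q, scale = FALSE)
    best <- min(vapply(1:500, function(i) {
      R <- random_rotation()
      sqrt(sum((Pc %*% t(R) - Qc)^2) / nrow(P))
    }, numeric(1)))
    expect_lte(backbone_rmsd(P, Q), best + 1e-12)
  }
})

test_that("rmsda follows the circular RMS over phi/psi and skips omega", {
  h <- helix_dihedrals()
  # single 40-degree deviation in phi3 over 8 angles
  bent <- dihedral_vector({x <- rep(c(-47, -57), 4); x[4] <- -17; x})
  expect_equal(rmsda(h, bent), sqrt(40^2 / 8), tolerance = 1e-12)
  expect_equal(rmsda(bent, h), rmsda(h, bent))
  # omega excluded
  cis <- dihedral_vector(rep(c(-47, -57), 4), omega = c(180, 180, 0, 180))
  expect_equal(rmsda(h, cis), 0)
  # wrap: 179 vs -179 differ by 2, not 358
  a <- dihedral_vector(rep(179, 8)); b <- dihedral_vector(rep(-179, 8))
  expect_equal(rmsda(a, b), 2, tolerance = 1e-12)
  # invariance under full turns
  shifted <- dihedral_vector(h$phi_psi + 360)
  expect_equal(rmsda(shifted, h), 0, tolerance = 1e-9)
  expect_error(rmsda(h, dihedral_vector(c(0, 0))), "residue counts")
})
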