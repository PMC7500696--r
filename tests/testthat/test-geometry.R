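test_that("backbone dihedrals invert the ideal-helix construction", {
  for (ang in list(c(-60, -45), c(-135, 135), c(-75, -20))) {
    h <- buildIdealHelix(10, phi = ang[1], psi = ang[2])
    d <- backboneDihedrals(h)
    expect_equal(d$phi[-1], rep(ang[1], 9), tolerance = 1e-3)
    expect_equal(d$psi[-10], rep(ang[2], 9), tolerance = 1e-3)
    expect_true(is.na(d$phi[1]) && is.na(d$psi[10]))
  }
  ## 2-residue chain: no interior angles beyond phi2/psi1
  d2 <- backboneDihedrals(buildIdealHelix(2))
  expect_true(is.na(d2$phi[1]) && is.na(d2$psi[2]))
})

test_that("torsions agree with an independent oracle on random backbones", {
  set.seed(42)
  for (rep in 1:5) {
    ## random non-degenerate 4-point sets
    p <- lapply(1:4, function(i) rnorm(3, sd = 3))
    expect_equal(helixcheck:::torsionAngle(p[[1]], p[[2]], p[[3]], p[[4]]),
                 oracleTorsion(p[[1]], p[[2]], p[[3]], p[[4]]),
                 tolerance = 1e-6)
  }
  ## full backbone of a jittered helix vs bio3d residue-wise torsions
  h <- buildIdealHelix(20)
  xyz <- modelCoords(h) + matrix(rnorm(3 * nAtoms(h), sd = 0.15),
                                 ncol = 3)
  hj <- Structure(atoms(h), xyz)
  d <- backboneDihedrals(hj)
  a <- atoms(hj)
  for (r in 2:19) {
    idx <- function(nm, rr) which(a$resid == rr & a$name == nm)
    phi <- oracleTorsion(xyz[idx("C", r - 1), ], xyz[idx("N", r), ],
                         xyz[idx("CA", r), ], xyz[idx("C", r), ])
    psi <- oracleTorsion(xyz[idx("N", r), ], xyz[idx("CA", r), ],
                         xyz[idx("C", r), ], xyz[idx("N", r + 1), ])
    expect_equal(d$phi[d$resid == r], phi, tolerance = 1e-6)
    expect_equal(d$psi[d$resid == r], psi, tolerance = 1e-6)
  }
})

test_that("Kabsch superposition recovers exact and noisy fits", {
  h <- makeComplex()
  sel <- atomSelection()
  ## identity case
  s0 <- kabschSuperpose(h, h, sel)
  expect_equal(s0@rmsdFit, 0, tolerance = 1e-9)
  expect_equal(s0@rotation, diag(3), tolerance = 1e-9)
  ## rigidly moved copy: zero rmsd, recovered rotation
  R <- helixcheck:::rotationMatrix(c(2, -1, 4), 63)
  moved <- helixcheck:::rigidPlace(h, R, c(4, 9, -2))
  s1 <- kabschSuperpose(h, moved, sel)
  expect_equal(s1@rmsdFit, 0, tolerance = 1e-6)
  expect_equal(s1@rotation %*% R, diag(3), tolerance = 1e-6)
  expect_equal(s1@rmsdCalc, s1@rmsdFit, tolerance = 1e-9)
  ## noisy copy matches the independent SVD oracle
  set.seed(5)
  xyz <- modelCoords(h)
  noisy <- Structure(atoms(h), xyz + matrix(rnorm(length(xyz), 0, 0.5),
                                            ncol = 3))
  s2 <- kabschSuperpose(h, noisy, sel)
  expect_equal(s2@rmsdFit,
               oracleFitRmsd(xyz[resolveSelection(h, sel), ],
                             modelCoords(noisy)[resolveSelection(h, sel), ]),
               tolerance = 1e-6)
  ## contracts
  expect_error(kabschSuperpose(h, h, atomSelection(resids = 1,
                                                   atomNames = "CA")),
               "3 fit atoms")
})

test_that("RMSD machinery is symmetric and rigid-motion invariant", {
  set.seed(8)
  h <- makeComplex(12, 12)
  ens <- perturbEnsemble(h, 0.8, 6, seed = 3)
  sel <- atomSelection()
  pr <- pairwiseEnsembleRMSD(ens, sel)
  expect_equal(pr$matrix, t(pr$matrix))
  expect_true(all(diag(pr$matrix) == 0))
  expect_true(all(pr$matrix >= 0))
  expect_equal(pr$sem, pr$sd / sqrt(15))
  ## symmetry of a single pair both directions
  a <- selectModels(ens, 1); b <- selectModels(ens, 2)
  expect_equal(kabschSuperpose(a, b, sel)@rmsdFit,
               kabschSuperpose(b, a, sel)@rmsdFit, tolerance = 1e-6)
  ## rigidly moving one model changes nothing
  ens2 <- ens
  R <- helixcheck:::rotationMatrix(c(1, 1, 0), 120)
  m3 <- helixcheck:::rigidPlace(selectModels(ens, 3), R, c(10, 0, 5))
  ens2@coords[, , 3] <- modelCoords(m3)
  pr2 <- pairwiseEnsembleRMSD(ens2, sel)
  expect_equal(pr2$matrix, pr$matrix, tolerance = 1e-6)
})

test_that("pairwise ensemble mean matches a direct simulation expectation", {
  ## For sigma-perturbed copies the pairwise fit RMSD concentrates around
  ## an expectation estimated here by direct simulation with the oracle.
  set.seed(21)
  h <- buildIdealHelix(15)
  sel <- atomSelection()
  idx <- resolveSelection(h, sel)
  base <- modelCoords(h)[idx, ]
  sims <- replicate(300, {
    A <- base + matrix(rnorm(length(base), 0, 0.5), ncol = 3)
    B <- base + matrix(rnorm(length(base), 0, 0.5), ncol = 3)
    oracleFitRmsd(A, B)
  })
  ens <- perturbEnsemble(h, 0.5, 10, seed = 9)
  pr <- pairwiseEnsembleRMSD(ens, sel)
  ## pairwise values sharing a model are correlated, so the effective
  ## sample size of the ensemble mean is the model count, not the pair
  ## count
  se <- sd(sims) / sqrt(nModels(ens)) + sd(sims) / sqrt(300)
  expect_lt(abs(pr$mean - mean(sims)), 3 * se)
})

test_that("rolling RMSD vanishes for static and rigid-motion trajectories", {
  h <- makeComplex(10, 10)
  sel <- atomSelection()
  xyz <- modelCoords(h)
  static <- Structure(atoms(h), array(xyz, c(nrow(xyz), 3, 5)))
  expect_equal(rollingRMSD(static, 1, sel)@value, rep(0, 4),
               tolerance = 1e-9)
  ## pure rigid rotations frame to frame
  co <- array(NA_real_, c(nrow(xyz), 3, 5))
  for (t in 1:5)
    co[, , t] <- xyz %*% helixcheck:::rotationMatrix(c(0, 0, 1), 30 * t) +
      matrix(rep(c(t, 0, 0), each = nrow(xyz)), ncol = 3)
  rigid <- Structure(atoms(h), co)
  expect_equal(rollingRMSD(rigid, 1, sel)@value, rep(0, 4),
               tolerance = 1e-6)
  expect_error(rollingRMSD(static, 0, sel), "positive")
  ## drifting trajectory agrees with a frame-by-frame oracle
  traj <- synthTrajectory(h, 8, jitterSigma = 0.2, driftPerFrame = 0.1,
                          seed = 4)
  rr <- rollingRMSD(traj, 2, sel)
  idx <- resolveSelection(h, sel)
  for (t in 3:8) {
    expect_equal(rr@value[t - 2],
                 oracleFitRmsd(modelCoords(traj, t)[idx, ],
                               modelCoords(traj, t - 2)[idx, ]),
                 tolerance = 1e-6)
  }
})

test_that("dihedral RMSD uses circular differences and matches brute force", {
  h <- buildIdealHelix(12)
  tab <- makeTalos(1:12)
  expect_equal(dihedralRMSDToTarget(backboneDihedrals(h), tab, 2:11), 0,
               tolerance = 1e-3)
  ## wraparound: 179 vs -179 differs by 2 degrees
  d <- data.frame(chain = "A", resid = 5L, phi = -60, psi = -179)
  tg <- makeTalos(5L); tg$psi <- 179
  expect_equal(dihedralRMSDToTarget(d, tg, 5L),
               sqrt(mean(c(0, 2)^2)), tolerance = 1e-9)
  ## random angles vs brute-force oracle; invariant to +360 shifts
  set.seed(31)
  for (rep in 1:3) {
    obs <- data.frame(chain = "A", resid = 1:20,
                      phi = runif(20, -180, 180),
                      psi = runif(20, -180, 180))
    tg <- makeTalos(1:20)
    tg$phi <- runif(20, -180, 180); tg$psi <- runif(20, -180, 180)
    got <- dihedralRMSDToTarget(obs, tg, 1:20)
    expect_equal(got, oracleCircRmsd(c(obs$phi, obs$psi),
                                     c(tg$phi, tg$psi)),
                 tolerance = 1e-9)
    obs2 <- obs; obs2$phi <- obs2$phi + 360
    expect_equal(dihedralRMSDToTarget(obs2, tg, 1:20), got,
                 tolerance = 1e-9)
  }
})

test_that("helix axes and crossing angles behave geometrically", {
  h <- buildIdealHelix(18)
  a1 <- helixAxis(h, 1:18)
  expect_equal(sqrt(sum(a1$direction^2)), 1, tolerance = 1e-9)
  ## translated copy: zero crossing angle
  h2 <- helixcheck:::rigidPlace(h, diag(3), c(12, 3, 0))
  expect_equal(interhelixAngle(a1, helixAxis(h2, 1:18)), 0,
               tolerance = 1e-6)
  ## point inversion: antiparallel = 180
  h3 <- Structure(atoms(h), -modelCoords(h))
  expect_equal(interhelixAngle(a1, helixAxis(h3, 1:18)), 180,
               tolerance = 1e-6)
  ## supplementary-angle identity
  a3 <- helixAxis(h3, 1:18)
  b <- buildBundle(18, 35)
  bA <- helixAxis(b, 1:18, chain = "A"); bB <- helixAxis(b, 1:18, chain = "B")
  expect_equal(interhelixAngle(bA, bB) +
                 interhelixAngle(bA, list(direction = -bB$direction)),
               180, tolerance = 1e-9)
  ## constructed crossing angles recovered within 2 degrees
  for (ang in c(25, 47, 90)) {
    bb <- buildBundle(18, ang)
    expect_equal(interhelixAngle(helixAxis(bb, 1:18, chain = "A"),
                                 helixAxis(bb, 1:18, chain = "B")),
                 ang, tolerance = 2 / ang)
  }
  expect_error(helixAxis(h, 1:4), "5 CA")
})

test_that("helix/coil assignment follows the alpha window and run rule", {
  d <- backboneDihedrals(buildIdealHelix(12))
  ss <- assignHelixByDihedrals(d)
  expect_true(all(ss$ss[2:11] == "helix"))
  dext <- backboneDihedrals(buildIdealHelix(12, -135, 135))
  expect_true(all(assignHelixByDihedrals(dext)$ss == "coil"))
  ## alternating in/out-of-window residues never reach the run length
  alt <- data.frame(chain = "A", resid = 1:12,
                    phi = rep(c(-60, -135), 6),
                    psi = rep(c(-45, 135), 6))
  expect_true(all(assignHelixByDihedrals(alt)$ss == "coil"))
})

test_that("contour length is the linear coil/helix formula", {
  expect_identical(contourLength(0, 0), 0)
  expect_equal(contourLength(13, 5), 59.5)
  expect_equal(contourLength(57, 52), 306)
  ## linearity
  expect_equal(contourLength(7, 9), contourLength(7, 0) + contourLength(0, 9))
  expect_error(contourLength(-1, 5), "non-negative")
  expect_error(contourLength(1.5, 2), "integers")
})
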