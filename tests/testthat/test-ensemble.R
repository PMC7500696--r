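test_that("average structure reproduces identity, midpoint and CLT cases", {
  h <- makeComplex(10, 10)
  sel <- atomSelection()
  ## identical models average to themselves
  twice <- Structure(atoms(h), array(modelCoords(h),
                                     c(nAtoms(h), 3, 3)))
  expect_equal(modelCoords(averageStructure(twice, sel)),
               modelCoords(h), tolerance = 1e-9)
  ## mirror-jittered pair averages to the midpoint (jitter along x keeps
  ## the optimal superposition at identity by symmetry of the test set)
  d <- 0.01
  co <- array(modelCoords(h), c(nAtoms(h), 3, 2))
  co[1, 1, 1] <- co[1, 1, 1] + d
  co[1, 1, 2] <- co[1, 1, 2] - d
  pair <- Structure(atoms(h), co)
  avg <- averageStructure(pair, sel)
  expect_equal(modelCoords(avg), modelCoords(h), tolerance = 1e-4)
  ## CLT: a sigma ensemble of n models averages to the seed within 3 sigma/sqrt(n)
  ens <- perturbEnsemble(h, 0.5, 50, seed = 2)
  avg50 <- averageStructure(ens, sel)
  dev <- abs(modelCoords(avg50) - modelCoords(h))
  expect_lt(mean(dev), 3 * 0.5 / sqrt(50))
})

test_that("average structure commutes with rigid transforms", {
  h <- makeComplex(8, 8)
  ens <- perturbEnsemble(h, 0.6, 6, seed = 5)
  sel <- atomSelection()
  avg <- averageStructure(ens, sel)
  R <- helixcheck:::rotationMatrix(c(1, 0, 2), 40)
  tv <- c(3, -2, 7)
  ensT <- helixcheck:::rigidPlace(ens, R, tv)
  avgT <- averageStructure(ensT, sel)
  expect_equal(modelCoords(avgT),
               sweep(modelCoords(avg) %*% R, 2, tv, `+`),
               tolerance = 1e-9)
})

test_that("annealing convergence is zero on self and symmetric in arguments", {
  h <- makeComplex(10, 10, sep = 6)
  selFit <- atomSelection()
  selSub <- atomSelection(chain = "A")
  ensA <- perturbEnsemble(h, 0.8, 5, seed = 31)
  ensB <- perturbEnsemble(h, 0.8, 5, seed = 32)
  same <- annealingConvergence(ensA, ensA, selFit,
                               calcSelectionSubunit = selSub)
  expect_equal(same@globalRmsd, 0, tolerance = 1e-9)
  expect_equal(same@subunitRmsd, 0, tolerance = 1e-9)
  ab <- annealingConvergence(ensA, ensB, selFit,
                             calcSelectionSubunit = selSub)
  ba <- annealingConvergence(ensB, ensA, selFit,
                             calcSelectionSubunit = selSub)
  expect_equal(ab@globalRmsd, ba@globalRmsd, tolerance = 1e-9)
  expect_equal(ab@subunitRmsd, ba@subunitRmsd, tolerance = 1e-9)
  expect_equal(ab@pooled$mean, ba@pooled$mean, tolerance = 1e-9)
  expect_equal(ab@pooled$sem, ba@pooled$sem, tolerance = 1e-9)
  expect_gt(ab@globalRmsd, 0)
})

test_that("the dissociation filter excludes replicas that lost contacts", {
  h <- makeComplex(10, 10, sep = 6)
  ens <- perturbEnsemble(h, 0.3, 4, seed = 9)
  ## push chain B far away in replica 3
  bIdx <- atoms(ens)$chain == "B"
  ens@coords[bIdx, 1, 3] <- ens@coords[bIdx, 1, 3] + 100
  rep <- annealingConvergence(ens, perturbEnsemble(h, 0.3, 4, seed = 10),
                              atomSelection(),
                              calcSelectionSubunit = atomSelection("A"))
  expect_equal(rep@excluded$a, 3L)
  expect_equal(rep@excluded$b, integer(0))
  ## with everything dissociated the comparison fails loudly
  far <- ens
  far@coords[bIdx, 1, ] <- far@coords[bIdx, 1, ] + 500
  expect_error(annealingConvergence(far, far, atomSelection(),
                                    calcSelectionSubunit = atomSelection("A")),
               "retained")
})

test_that("between-average RMSD matches a direct simulation oracle", {
  ## two ensembles drawn around one seed structure: the between-average
  ## RMSD concentrates near the value simulated here with the bio3d oracle
  set.seed(77)
  h <- buildIdealHelix(12)
  sel <- atomSelection()
  idx <- resolveSelection(h, sel)
  base <- modelCoords(h)
  nm <- 5L; sig <- 1
  sims <- replicate(120, {
    avg <- function() {
      ref <- base + matrix(rnorm(length(base), 0, sig), ncol = 3)
      acc <- ref
      for (k in 2:nm) {
        m <- base + matrix(rnorm(length(base), 0, sig), ncol = 3)
        fit <- bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(m)),
                              fixed.inds = as.vector(rbind(3 * idx - 2,
                                                           3 * idx - 1,
                                                           3 * idx)),
                              mobile.inds = as.vector(rbind(3 * idx - 2,
                                                            3 * idx - 1,
                                                            3 * idx)))
        acc <- acc + matrix(fit, ncol = 3, byrow = TRUE)
      }
      acc / nm
    }
    oracleFitRmsd(avg()[idx, ], avg()[idx, ])
  })
  got <- vapply(1:40, function(s) {
    a <- perturbEnsemble(h, sig, nm, seed = 1000 + s)
    b <- perturbEnsemble(h, sig, nm, seed = 5000 + s)
    sup <- kabschSuperpose(averageStructure(a, sel),
                           averageStructure(b, sel), sel)
    sup@rmsdCalc
  }, numeric(1))
  tol <- 3 * (sd(sims) / sqrt(120) + sd(got) / sqrt(40))
  expect_lt(abs(mean(got) - mean(sims)), tol)
})

test_that("ensemble summary reports pairwise statistics", {
  h <- makeComplex(8, 8)
  same <- Structure(atoms(h), array(modelCoords(h), c(nAtoms(h), 3, 4)))
  s <- ensembleSummary(same, atomSelection())
  expect_equal(s$mean, 0, tolerance = 1e-9)
  ens <- perturbEnsemble(h, 0.5, 6, seed = 13)
  s2 <- ensembleSummary(ens, atomSelection())
  pr <- pairwiseEnsembleRMSD(ens, atomSelection())
  expect_equal(s2$mean, pr$mean)
  expect_equal(s2$nModels, 6L)
})

test_that("topology metrics separate on-target from off-target trajectories", {
  h <- buildIdealHelix(14)
  tab <- makeTalos(1:14)
  sel <- atomSelection()
  ## frozen at the target-angle structure: both metrics vanish
  frozen <- Structure(atoms(h), array(modelCoords(h), c(nAtoms(h), 3, 6)))
  repF <- topologyMetricsReport(list(frozen = frozen), tab, sel,
                                dihedralResidues = 2:13)
  expect_equal(repF$table$rollingMean, 0, tolerance = 1e-3)
  expect_equal(repF$table$dihedralMean, 0, tolerance = 1e-3)
  ## an off-target packing built 30 degrees away scores a dihedral RMSD
  ## near the offset while the on-target one stays near its jitter level
  off <- buildIdealHelix(14, phi = -90, psi = -15)
  onTraj <- synthTrajectory(h, 6, jitterSigma = 0.05, seed = 41)
  offTraj <- synthTrajectory(off, 6, jitterSigma = 0.05, seed = 42)
  rep2 <- topologyMetricsReport(list(on = onTraj, off = offTraj), tab, sel,
                                dihedralResidues = 2:13)
  mOn <- rep2$table$dihedralMean[rep2$table$trajectory == "on"]
  mOff <- rep2$table$dihedralMean[rep2$table$trajectory == "off"]
  expect_gt(rep2$dihedralRatios["off", "on"], 2)
  expect_equal(mOff, 30, tolerance = 0.1)
  ## ranking is stable under frame subsampling by 2
  sub <- function(s) selectModels(s, seq(1, nModels(s), by = 2))
  rep3 <- topologyMetricsReport(list(on = sub(onTraj), off = sub(offTraj)),
                                tab, sel, dihedralResidues = 2:13)
  expect_gt(rep3$dihedralRatios["off", "on"], 2)
})
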