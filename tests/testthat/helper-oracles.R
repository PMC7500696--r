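## Independent oracle implementations used to cross-check the package's
## numerics. These deliberately use different code paths (bio3d, brute
## force, closed forms) from the implementation under test.

## Brute-force torsion via bio3d's independent implementation.
oracleTorsion <- function(p1, p2, p3, p4) {
  bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)[1L]
}

## Optimal-fit RMSD via bio3d's independent Kabsch implementation
## (fit.xyz); the RMSD itself is evaluated here at full precision since
## bio3d::rmsd rounds its return value.
oracleFitRmsd <- function(ref, mob) {
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(ref)), as.vector(t(mob))))
  m <- matrix(as.vector(fitted), ncol = 3L, byrow = TRUE)
  sqrt(mean(rowSums((ref - m)^2)))
}

## Independent type-7 quartile (linear interpolation between order
## statistics), coded from the definition.
oracleQuartile <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

## Brute-force two-state equilibrium: bisection on the mass-action
## balance (P - c)(L - c) = kd * c down to machine precision.
oracleFractionBound <- function(P, L, kd) {
  if (P == 0 || L == 0) return(0)
  f <- function(c) (P - c) * (L - c) - kd * c
  lo <- 0; hi <- min(P, L)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2 / P
}

## Circular RMSD over pooled angle differences, coded via the sin/cos
## route rather than modular arithmetic.
oracleCircRmsd <- function(obs, target) {
  d <- atan2(sin((obs - target) * pi / 180),
             cos((obs - target) * pi / 180)) * 180 / pi
  sqrt(mean(d^2))
}

## A small two-chain helical complex used as a generic fixture.
makeComplex <- function(lenA = 20L, lenB = 20L, sep = 9) {
  a <- buildIdealHelix(lenA, chain = "A")
  b <- buildIdealHelix(lenB, chain = "B")
  b <- helixcheck:::rigidPlace(b, diag(3), c(sep, 0, 0))
  Structure(rbind(atoms(a), atoms(b)),
            rbind(modelCoords(a), modelCoords(b)))
}

## A TALOS-style table matching an ideal helix at (phi0, psi0).
makeTalos <- function(resids, phi0 = -60, psi0 = -45, s2 = 0.85,
                      cls = "Good") {
  n <- length(resids)
  data.frame(resid = resids, resname = "ALA",
             phi = rep(phi0, n), psi = rep(psi0, n),
             dphi = rep(8, n), dpsi = rep(8, n),
             dist = rep(0.1, n), s2 = rep_len(s2, n),
             count = rep(10L, n),
             class = factor(rep_len(cls, n),
                            levels = c("None", "Good", "Warn", "Dyn")),
             stringsAsFactors = FALSE)
}

## A generic non-degenerate alignment tensor.
makeTensor <- function() saupeTensor(c(0.30, -0.10, 0.20, 0.05, -0.15))
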