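## Residual dipolar couplings: extraction from splittings, alignment-tensor
## fitting, back-calculation, Q-factor/RMSD validation and dipolar waves.

#' RDC from oriented and isotropic splittings
#'
#' The residual dipolar coupling is the difference between the cross-peak
#' splitting measured in the weakly aligned (oriented) sample and in the
#' isotropic sample: `D = splitting_oriented - splitting_isotropic`. The
#' sign therefore follows the oriented-minus-isotropic convention.
#'
#' @param splittingOrientedHz,splittingIsotropicHz numeric vectors, Hz.
#' @return RDC values in Hz.
#' @export
rdcFromSplittings <- function(splittingOrientedHz, splittingIsotropicHz) {
  if (any(!is.finite(splittingOrientedHz)) ||
      any(!is.finite(splittingIsotropicHz)))
    stop("splittings must be finite")
  splittingOrientedHz - splittingIsotropicHz
}

#' Construct a SaupeTensor
#'
#' @param s 3x3 symmetric traceless matrix, or a length-5 vector
#'   `(Sxx, Syy, Sxy, Sxz, Syz)` with `Szz = -Sxx - Syy`.
#' @param dmax dipolar interaction constant (Hz scale), default 1 (scale
#'   absorbed into the tensor).
#' @return a [SaupeTensor-class].
#' @export
saupeTensor <- function(s, dmax = 1) {
  if (is.matrix(s)) {
    S <- (s + t(s)) / 2
    S <- S - diag(3) * sum(diag(S)) / 3
  } else {
    if (length(s) != 5L) stop("need 5 tensor elements")
    S <- matrix(c(s[1L], s[3L], s[4L],
                  s[3L], s[2L], s[5L],
                  s[4L], s[5L], -s[1L] - s[2L]), 3L, 3L)
  }
  new("SaupeTensor", matrix = S, dmax = dmax)
}

setMethod("show", "SaupeTensor", function(object) {
  ev <- eigen(object@matrix, symmetric = TRUE)$values
  cat("SaupeTensor (dmax =", object@dmax, "): eigenvalues",
      sprintf("%.4g", ev), "\n")
  invisible(object)
})

## Amide N-H unit vectors for the requested residues of one model. When no
## amide proton (H/HN) is present the proton is built geometrically: 1.02 A
## from N along the in-plane bisector direction opposite the C'(i-1)-N and
## CA-N bonds. First residues without a preceding carbonyl are dropped.
amideVectors <- function(structure, residueSet, chain = NULL, model = 1L) {
  a <- structure@atoms
  xyz <- modelCoords(structure, model)
  get <- function(ch, r, nms) {
    i <- which(a$chain == ch & a$resid == r & a$name %in% nms)
    if (!length(i)) return(NULL)
    xyz[i[1L], ]
  }
  chains <- if (is.null(chain)) unique(a$chain) else chain
  resids <- integer(0); vecs <- NULL
  for (ch in chains) {
    have <- sort(unique(a$resid[a$chain == ch]))
    for (r in intersect(parseResidRange(residueSet), have)) {
      N <- get(ch, r, "N")
      if (is.null(N)) next
      H <- get(ch, r, c("H", "HN"))
      if (is.null(H)) {
        CA <- get(ch, r, "CA")
        Cprev <- get(ch, r - 1L, "C")
        if (is.null(CA) || is.null(Cprev)) next
        dir <- vunit(vunit(N - Cprev) + vunit(N - CA))
        H <- N + 1.02 * dir
      }
      vecs <- rbind(vecs, vunit(H - N))
      resids <- c(resids, r)
    }
  }
  list(resid = resids, vectors = vecs)
}

## Design matrix mapping the 5 independent tensor elements to couplings:
## D = dmax * v' S v with S parameterised as (Sxx, Syy, Sxy, Sxz, Syz).
rdcDesignMatrix <- function(v) {
  cbind(v[, 1L]^2 - v[, 3L]^2,
        v[, 2L]^2 - v[, 3L]^2,
        2 * v[, 1L] * v[, 2L],
        2 * v[, 1L] * v[, 3L],
        2 * v[, 2L] * v[, 3L])
}

#' Fit an alignment tensor to observed RDCs
#'
#' Linear least-squares fit of the five independent Saupe order-matrix
#' elements to the observed amide couplings,
#' `D_i = dmax * v_i' S v_i` with `v_i` the N-H unit vector of residue i.
#' Reports back-calculated couplings, the coupling RMSD and the Q-factor.
#' By default `Q = rms(D_calc - D_obs) / rms(D_obs)`; the alternative
#' normalisation by the tensor magnitude (`qForm = "da"`) divides by
#' `sqrt(2 Da^2 (4 + 3 R^2) / 5)` with Da the axial component and R the
#' rhombicity.
#'
#' @param structure a [Structure-class].
#' @param rdcSet RDC table ([readRdcTable()] layout).
#' @param residueSet residue numbers to use.
#' @param chain optional chain id of the measured subunit.
#' @param model model index.
#' @param dmax dipolar interaction constant; default 1 (absorbed scale).
#' @param qForm Q-factor normalisation, `"obs"` (default) or `"da"`.
#' @return an [RdcFitReport-class].
#' @export
fitAlignmentTensor <- function(structure, rdcSet, residueSet, chain = NULL,
                               model = 1L, dmax = 1,
                               qForm = c("obs", "da")) {
  qForm <- match.arg(qForm)
  av <- amideVectors(structure, residueSet, chain = chain, model = model)
  keep <- av$resid %in% rdcSet$resid
  resid <- av$resid[keep]
  if (length(resid) < 5L)
    stop("need at least 5 residues with both coordinates and couplings")
  v <- av$vectors[keep, , drop = FALSE]
  dObs <- rdcSet$d_obs_hz[match(resid, rdcSet$resid)]
  A <- dmax * rdcDesignMatrix(v)
  qrA <- qr(A)
  if (qrA$rank < 5L)
    stop("rank-deficient design matrix: N-H vectors too degenerate")
  s <- qr.coef(qrA, dObs)
  dCalc <- as.numeric(A %*% s)
  res <- dCalc - dObs
  rmsd <- sqrt(mean(res^2))
  tensor <- saupeTensor(s, dmax = dmax)
  denom <- if (qForm == "obs") {
    sqrt(mean(dObs^2))
  } else {
    ev <- eigen(tensor@matrix, symmetric = TRUE)$values
    ev <- ev[order(abs(ev))]           # |Sxx'| <= |Syy'| <= |Szz'|
    da <- dmax * ev[3L] / 2
    rh <- (ev[1L] - ev[2L]) / ev[3L]
    sqrt(2 * da^2 * (4 + 3 * rh^2) / 5)
  }
  new("RdcFitReport",
      table = data.frame(resid = resid, dObs = dObs, dCalc = dCalc,
                         residual = res),
      rmsd = rmsd, qFactor = abs(rmsd / denom), tensor = tensor,
      nUsed = length(resid))
}

setMethod("show", "RdcFitReport", function(object) {
  cat(sprintf(
    "RdcFitReport: n = %d, rmsd = %.3f Hz, Q = %.3f (%.1f%%)\n",
    object@nUsed, object@rmsd, object@qFactor, 100 * object@qFactor))
  invisible(object)
})

#' Back-calculate RDCs from a structure and tensor
#'
#' Deterministic evaluation of `D = dmax * v' S v` over the amide N-H unit
#' vectors of the requested residues.
#'
#' @param structure a [Structure-class].
#' @param tensor a [SaupeTensor-class].
#' @param residueSet residue numbers.
#' @param chain optional chain id.
#' @param model model index.
#' @return data.frame `resid, d_calc_hz`.
#' @export
backcalcRDC <- function(structure, tensor, residueSet, chain = NULL,
                        model = 1L) {
  av <- amideVectors(structure, residueSet, chain = chain, model = model)
  if (!length(av$resid)) stop("no usable amide vectors in residue set")
  A <- tensor@dmax * rdcDesignMatrix(av$vectors)
  S <- tensor@matrix
  s <- c(S[1L, 1L], S[2L, 2L], S[1L, 2L], S[1L, 3L], S[2L, 3L])
  data.frame(resid = av$resid, d_calc_hz = as.numeric(A %*% s))
}

#' Dipolar-wave fit over a contiguous helix
#'
#' Fits `D(n) = Av + AII * cos(2 pi n / period + phase)` to sequential
#' couplings along a regular helix (period fixed at 3.6 residues per turn
#' unless overridden), optionally adding a second harmonic
#' `AI * cos(4 pi n / period + phase2)`. With the period fixed the model is
#' linear in its cosine/sine expansion and is solved exactly by least
#' squares; amplitude/phase and their standard errors follow from the
#' coefficient covariance (delta method for the amplitude). `Av`, the mean
#' coupling level of the helix, is the most robust parameter.
#'
#' @param rdcSet RDC table ([readRdcTable()] layout) covering at least 6
#'   consecutive residues.
#' @param residueRange residues of the helix to fit.
#' @param period helix periodicity in residues, default 3.6.
#' @param secondHarmonic fit the second harmonic too (default `FALSE`).
#' @return a [DipolarWaveFit-class].
#' @export
dipolarWaveFit <- function(rdcSet, residueRange = NULL, period = 3.6,
                           secondHarmonic = FALSE) {
  if (period <= 0) stop("period must be > 0")
  tab <- rdcSet
  if (!is.null(residueRange))
    tab <- tab[tab$resid %in% parseResidRange(residueRange), ]
  tab <- tab[!is.na(tab$d_obs_hz), ]
  tab <- tab[order(tab$resid), ]
  n <- nrow(tab)
  if (n < 6L || max(diff(tab$resid)) > 1L)
    stop("need at least 6 consecutive residues with couplings")
  nPar <- if (secondHarmonic) 5L else 3L
  if (n < nPar) stop("fewer points than parameters")
  w <- 2 * pi * tab$resid / period
  df <- data.frame(d = tab$d_obs_hz, c1 = cos(w), s1 = sin(w))
  form <- d ~ c1 + s1
  if (secondHarmonic) {
    df$c2 <- cos(2 * w); df$s2 <- sin(2 * w)
    form <- d ~ c1 + s1 + c2 + s2
  }
  fit <- stats::lm(form, data = df)
  cf <- stats::coef(fit)
  V <- stats::vcov(fit)
  amp <- function(a, b, Vab) {
    A <- sqrt(a^2 + b^2)
    g <- if (A > 0) c(a, b) / A else c(1, 0)
    list(A = A, se = sqrt(drop(t(g) %*% Vab %*% g)))
  }
  a1 <- amp(cf[["c1"]], cf[["s1"]], V[c("c1", "s1"), c("c1", "s1")])
  ## Av + a*cos(wn) + b*sin(wn) = Av + AII*cos(wn + phase) with
  ## a = AII*cos(phase), b = -AII*sin(phase)
  phase <- rad2deg(atan2(-cf[["s1"]], cf[["c1"]]))
  aI <- NA_real_
  if (secondHarmonic)
    aI <- amp(cf[["c2"]], cf[["s2"]], V[c("c2", "s2"), c("c2", "s2")])$A
  new("DipolarWaveFit",
      av = cf[["(Intercept)"]], aII = a1$A, phase = phase, aI = aI,
      period = period,
      se = c(av = sqrt(V[1L, 1L]), aII = a1$se),
      table = data.frame(resid = tab$resid, dObs = tab$d_obs_hz,
                         fitted = stats::fitted(fit),
                         residual = stats::residuals(fit)))
}

setMethod("show", "DipolarWaveFit", function(object) {
  cat(sprintf(
    "DipolarWaveFit: Av = %.2f +/- %.2f Hz, AII = %.2f +/- %.2f Hz, phase = %.1f deg (period %.1f)\n",
    object@av, object@se[["av"]], object@aII, object@se[["aII"]],
    object@phase, object@period))
  invisible(object)
})
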