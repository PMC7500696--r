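## Backbone dihedrals, superposition/RMSD machinery, helix axes and the
## contour-length formula.

#' Backbone dihedral angles of one model
#'
#' Computes phi (C'(i-1)-N-CA-C') and psi (N-CA-C'-N(i+1)) for every
#' residue of every chain, in degrees with the IUPAC sign convention
#' (trans = 180). The first residue of a chain has no phi and the last no
#' psi; residues with missing backbone atoms are marked undefined with a
#' warning.
#'
#' @param structure a [Structure-class].
#' @param model model index.
#' @return data.frame `chain, resid, phi, psi` (`NA` = undefined), angles
#'   wrapped to \[-180, 180).
#' @export
backboneDihedrals <- function(structure, model = 1L) {
  a <- structure@atoms
  xyz <- modelCoords(structure, model)
  get <- function(ch, r, nm) {
    i <- which(a$chain == ch & a$resid == r & a$name == nm)
    if (length(i) != 1L) return(NULL)
    xyz[i, ]
  }
  out <- list()
  for (ch in unique(a$chain)) {
    resids <- sort(unique(a$resid[a$chain == ch]))
    for (k in seq_along(resids)) {
      r <- resids[k]
      N <- get(ch, r, "N"); CA <- get(ch, r, "CA"); C <- get(ch, r, "C")
      phi <- psi <- NA_real_
      if (is.null(N) || is.null(CA) || is.null(C)) {
        warning("residue ", ch, ":", r,
                " lacks backbone atoms; dihedrals undefined")
      } else {
        if (k > 1L && resids[k - 1L] == r - 1L) {
          Cprev <- get(ch, r - 1L, "C")
          if (!is.null(Cprev)) phi <- torsionAngle(Cprev, N, CA, C)
        }
        if (k < length(resids) && resids[k + 1L] == r + 1L) {
          Nnext <- get(ch, r + 1L, "N")
          if (!is.null(Nnext)) psi <- torsionAngle(N, CA, C, Nnext)
        }
      }
      out[[length(out) + 1L]] <- data.frame(chain = ch, resid = r,
                                            phi = wrapAngle(phi),
                                            psi = wrapAngle(psi))
    }
  }
  do.call(rbind, out)
}

## Core Kabsch solver on paired n x 3 coordinate matrices (row vectors).
## Returns the rotation R and translation t with mobile %*% R + t ~ ref.
kabschCore <- function(ref, mob) {
  cm <- colMeans(mob)
  cr <- colMeans(ref)
  X <- sweep(mob, 2L, cm)
  Y <- sweep(ref, 2L, cr)
  sv <- svd(crossprod(X, Y))
  if (sv$d[2L] < 1e-8 * max(sv$d[1L], 1))
    warning("degenerate (collinear) fit atom set")
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  list(rotation = R, translation = as.numeric(cr - cm %*% R))
}

rmsdBetween <- function(A, B) sqrt(mean(rowSums((A - B)^2)))

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation that minimise the RMSD of the
#' mobile structure's fit atoms onto the reference's, then evaluates the
#' RMSD over a possibly different calc selection after applying the same
#' transform — the matching convention used throughout the ensemble and
#' trajectory metrics.
#'
#' @param reference,mobile [Structure-class] objects with matching
#'   selections.
#' @param fitSelection selection of the atoms the fit minimises over.
#' @param calcSelection selection the reported `rmsdCalc` is evaluated
#'   over; defaults to the fit selection.
#' @param referenceModel,mobileModel model indices.
#' @return a [SuperpositionResult-class].
#' @export
kabschSuperpose <- function(reference, mobile, fitSelection,
                            calcSelection = fitSelection,
                            referenceModel = 1L, mobileModel = 1L) {
  fi <- resolveSelection(reference, fitSelection)
  fiM <- resolveSelection(mobile, fitSelection)
  ci <- resolveSelection(reference, calcSelection)
  ciM <- resolveSelection(mobile, calcSelection)
  if (length(fi) != length(fiM))
    stop("fit selection resolves to different atom counts")
  if (length(ci) != length(ciM))
    stop("calc selection resolves to different atom counts")
  if (length(fi) < 3L) stop("need at least 3 fit atoms")
  refXYZ <- modelCoords(reference, referenceModel)
  mobXYZ <- modelCoords(mobile, mobileModel)
  tr <- kabschCore(refXYZ[fi, , drop = FALSE], mobXYZ[fiM, , drop = FALSE])
  moved <- sweep(mobXYZ %*% tr$rotation, 2L, tr$translation, `+`)
  new("SuperpositionResult",
      rotation = tr$rotation, translation = tr$translation,
      rmsdFit = rmsdBetween(refXYZ[fi, , drop = FALSE],
                            moved[fiM, , drop = FALSE]),
      rmsdCalc = rmsdBetween(refXYZ[ci, , drop = FALSE],
                             moved[ciM, , drop = FALSE]))
}

setMethod("show", "SuperpositionResult", function(object) {
  cat(sprintf("SuperpositionResult: rmsd_fit = %.4f A, rmsd_calc = %.4f A\n",
              object@rmsdFit, object@rmsdCalc))
  invisible(object)
})

#' Apply a superposition transform to a Structure
#'
#' @param structure a [Structure-class].
#' @param transform a [SuperpositionResult-class] (or list with `rotation`
#'   and `translation`).
#' @return the transformed [Structure-class] (all models moved).
#' @export
applyTransform <- function(structure, transform) {
  R <- if (is(transform, "SuperpositionResult")) transform@rotation
       else transform$rotation
  tv <- if (is(transform, "SuperpositionResult")) transform@translation
        else transform$translation
  co <- structure@coords
  for (m in seq_len(dim(co)[3L]))
    co[, , m] <- sweep(matrix(co[, , m], ncol = 3L) %*% R, 2L, tv, `+`)
  new("Structure", atoms = structure@atoms, coords = co)
}

#' Pairwise RMSD over an ensemble
#'
#' Every unordered model pair is superposed over the fit selection and the
#' RMSD evaluated over the calc selection. The summary statistics are taken
#' over the n(n-1)/2 upper-triangle values with SEM = SD/sqrt(n_pairs).
#'
#' @param ensemble a multi-model [Structure-class].
#' @param fitSelection,calcSelection atom selections (calc defaults to fit).
#' @return list with `matrix` (symmetric, zero diagonal), `mean`, `sd`,
#'   `sem`, `nPairs`.
#' @export
pairwiseEnsembleRMSD <- function(ensemble, fitSelection,
                                 calcSelection = fitSelection) {
  n <- nModels(ensemble)
  if (n < 2L) stop("need at least 2 models")
  fi <- resolveSelection(ensemble, fitSelection)
  ci <- resolveSelection(ensemble, calcSelection)
  M <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    A <- modelCoords(ensemble, i)
    for (j in seq.int(i + 1L, n)) {
      B <- modelCoords(ensemble, j)
      tr <- kabschCore(A[fi, , drop = FALSE], B[fi, , drop = FALSE])
      moved <- sweep(B %*% tr$rotation, 2L, tr$translation, `+`)
      M[i, j] <- M[j, i] <- rmsdBetween(A[ci, , drop = FALSE],
                                        moved[ci, , drop = FALSE])
    }
  }
  vals <- M[upper.tri(M)]
  list(matrix = M, mean = mean(vals), sd = stats::sd(vals),
       sem = stats::sd(vals) / sqrt(length(vals)), nPairs = length(vals))
}

#' Rolling RMSD along a trajectory
#'
#' For each frame t > lag, frame t - lag is superposed onto frame t over
#' the fit selection and the RMSD evaluated over the calc selection —
#' the drift metric used to compare candidate helix packings: rigid-body
#' motion cancels, conformational change does not.
#'
#' @param trajectory a multi-model [Structure-class] (frames = models).
#' @param lagFrames positive integer lag in frames (time lag divided by the
#'   trajectory's frame spacing).
#' @param fitSelection,calcSelection atom selections (calc defaults to fit).
#' @return a [MetricSeries-class] in Angstrom, frames `lag+1 .. n`.
#' @export
rollingRMSD <- function(trajectory, lagFrames, fitSelection,
                        calcSelection = fitSelection) {
  lagFrames <- as.integer(lagFrames)
  if (lagFrames <= 0L) stop("lag must be a positive number of frames")
  n <- nModels(trajectory)
  if (n <= lagFrames) stop("trajectory shorter than lag")
  fi <- resolveSelection(trajectory, fitSelection)
  ci <- resolveSelection(trajectory, calcSelection)
  vals <- numeric(n - lagFrames)
  for (t in seq.int(lagFrames + 1L, n)) {
    cur <- modelCoords(trajectory, t)
    prev <- modelCoords(trajectory, t - lagFrames)
    tr <- kabschCore(cur[fi, , drop = FALSE], prev[fi, , drop = FALSE])
    moved <- sweep(prev %*% tr$rotation, 2L, tr$translation, `+`)
    vals[t - lagFrames] <- rmsdBetween(cur[ci, , drop = FALSE],
                                       moved[ci, , drop = FALSE])
  }
  new("MetricSeries", frame = seq.int(lagFrames + 1L, n), value = vals,
      metric = "rolling RMSD", units = "A")
}

#' Summary statistics of a MetricSeries
#'
#' @param series a [MetricSeries-class].
#' @return list `mean`, `sd`, `sem`, `n`.
#' @export
metricSummary <- function(series) {
  v <- series@value
  list(mean = mean(v), sd = stats::sd(v),
       sem = stats::sd(v) / sqrt(length(v)), n = length(v))
}

setMethod("show", "MetricSeries", function(object) {
  s <- metricSummary(object)
  cat(sprintf("MetricSeries '%s': %d frames, mean = %.3f +/- %.3f (SD) %s\n",
              object@metric, s$n, s$mean, s$sd, object@units))
  invisible(object)
})

#' Circular RMSD of backbone dihedrals against predicted targets
#'
#' Pools the phi and psi deviations (equally weighted) over the requested
#' residues, wrapping every difference to (-180, 180] so that a 179 vs
#' -179 pair contributes 2 degrees.
#'
#' @param dihedrals data.frame from [backboneDihedrals()] (optionally
#'   already filtered to one chain).
#' @param targets TALOS-style table with `resid`, `phi`, `psi`.
#' @param residueSet residue numbers to include.
#' @param chain optional chain to filter `dihedrals` by.
#' @return RMSD in degrees.
#' @export
dihedralRMSDToTarget <- function(dihedrals, targets, residueSet,
                                 chain = NULL) {
  residueSet <- parseResidRange(residueSet)
  if (!length(residueSet)) stop("empty residue set")
  if (!is.null(chain)) dihedrals <- dihedrals[dihedrals$chain == chain, ]
  diffs <- numeric(0)
  for (r in residueSet) {
    d <- dihedrals[dihedrals$resid == r, ]
    tg <- targets[targets$resid == r, ]
    if (nrow(d) != 1L || nrow(tg) != 1L)
      stop("residue ", r, " not uniquely present in both inputs")
    for (ang in c("phi", "psi")) {
      if (!is.na(d[[ang]]) && !is.na(tg[[ang]]))
        diffs <- c(diffs, circularDiff(d[[ang]], tg[[ang]]))
    }
  }
  if (!length(diffs)) stop("no defined angle pairs in residue set")
  sqrt(mean(diffs^2))
}

#' Fit a helix axis
#'
#' The axis is the dominant principal component of the CA positions after
#' a 4-point sliding-window average (the smoothing removes the ~3.6-residue
#' helical wobble). The direction is oriented N- to C-terminal.
#'
#' @param structure a [Structure-class].
#' @param residueRange residue numbers of the helix (>= 5 CA atoms).
#' @param chain optional chain id.
#' @param model model index.
#' @return list `direction` (unit vector), `centroid` (Angstrom),
#'   `residueRange`.
#' @export
helixAxis <- function(structure, residueRange, chain = NULL, model = 1L) {
  residueRange <- parseResidRange(residueRange)
  a <- structure@atoms
  keep <- a$name == "CA" & a$resid %in% residueRange
  if (!is.null(chain)) keep <- keep & a$chain == chain
  idx <- which(keep)
  idx <- idx[order(a$resid[idx])]
  if (length(idx) < 5L) stop("need at least 5 CA atoms for an axis fit")
  ca <- modelCoords(structure, model)[idx, , drop = FALSE]
  w <- 4L
  sm <- t(vapply(seq_len(nrow(ca) - w + 1L),
                 function(i) colMeans(ca[i:(i + w - 1L), , drop = FALSE]),
                 numeric(3L)))
  ctr <- colMeans(sm)
  sv <- svd(sweep(sm, 2L, ctr))
  if (sv$d[1L] < 1e-8) stop("degenerate helix geometry")
  dir <- sv$v[, 1L]
  if (sum(dir * (sm[nrow(sm), ] - sm[1L, ])) < 0) dir <- -dir
  list(direction = dir / vnorm(dir), centroid = ctr,
       residueRange = residueRange)
}

#' Angle between two helix axes
#'
#' Signed-direction convention: the angle between the direction vectors
#' without taking absolute values, so antiparallel helices give 180
#' degrees.
#'
#' @param a,b helix axes from [helixAxis()] (or any lists with a
#'   `direction` element).
#' @return angle in degrees, in \[0, 180].
#' @export
interhelixAngle <- function(a, b) {
  d <- sum(vunit(a$direction) * vunit(b$direction))
  rad2deg(acos(max(-1, min(1, d))))
}

#' Assign helix/coil labels from backbone dihedrals
#'
#' A residue is inside the alpha window when phi is in \[-100, -30] and psi
#' in \[-80, -5]; runs of at least 4 consecutive in-window residues are
#' labelled `helix`, everything else `coil` (undefined angles count as
#' out-of-window).
#'
#' @param dihedrals data.frame from [backboneDihedrals()].
#' @return the input with an added `ss` column (`"helix"`/`"coil"`).
#' @export
assignHelixByDihedrals <- function(dihedrals) {
  inWin <- !is.na(dihedrals$phi) & !is.na(dihedrals$psi) &
    dihedrals$phi >= -100 & dihedrals$phi <= -30 &
    dihedrals$psi >= -80 & dihedrals$psi <= -5
  ss <- rep("coil", nrow(dihedrals))
  for (ch in unique(dihedrals$chain)) {
    ix <- which(dihedrals$chain == ch)
    r <- rle(inWin[ix])
    pos <- cumsum(c(1L, r$lengths))
    for (k in seq_along(r$lengths)) {
      if (r$values[k] && r$lengths[k] >= 4L)
        ss[ix[seq.int(pos[k], pos[k + 1L] - 1L)]] <- "helix"
    }
  }
  dihedrals$ss <- ss
  dihedrals
}

#' Contour length of a partly helical polypeptide segment
#'
#' Maximum end-to-end extension given the secondary-structure content:
#' `L = 4 A * n_coil + 1.5 A * n_helix` (4 Angstrom per random-coil
#' residue, 1.5 Angstrom axial rise per alpha-helical residue).
#'
#' @param nCoil number of random-coil residues.
#' @param nHelix number of alpha-helical residues.
#' @return contour length in Angstrom.
#' @export
contourLength <- function(nCoil, nHelix) {
  if (nCoil < 0 || nHelix < 0) stop("residue counts must be non-negative")
  if (nCoil != round(nCoil) || nHelix != round(nHelix))
    stop("residue counts must be integers")
  4 * nCoil + 1.5 * nHelix
}
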