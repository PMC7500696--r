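## Seed-reproducible generators emulating the statistical structure of the
## pipeline's inputs: ideal helices, helix bundles, perturbed ensembles,
## drifting trajectories, RDC sets and two-state fast-exchange titrations.

## Standard backbone internal coordinates (Angstrom / degrees).
.bb <- list(
  nCa = 1.458, caC = 1.525, cN = 1.329, cO = 1.231,
  angCNCa = 121.7, angNCaC = 111.2, angCaCN = 116.2, angCaCO = 120.8,
  omega = 180)

#' Build an ideal polyalanine backbone at fixed torsions
#'
#' Grows an N/CA/C/O backbone with standard bond lengths and angles at the
#' given uniform (phi, psi); the defaults are the canonical right-handed
#' alpha-helix region (-60, -45). [backboneDihedrals()] inverts the
#' construction to the requested angles to numerical precision.
#'
#' @param length number of residues (>= 2).
#' @param phi,psi backbone torsions, degrees.
#' @param chain chain identifier.
#' @param firstResid first residue number.
#' @return a single-model [Structure-class] (residues named ALA).
#' @export
buildIdealHelix <- function(length, phi = -60, psi = -45, chain = "A",
                            firstResid = 1L) {
  n <- as.integer(length)
  if (n < 2L) stop("need at least 2 residues")
  ## seed atoms of residue 1 in a canonical frame
  N1 <- c(0, 0, 0)
  CA1 <- c(.bb$nCa, 0, 0)
  ang <- deg2rad(.bb$angNCaC)
  C1 <- CA1 + .bb$caC * c(-cos(ang), sin(ang), 0)
  pos <- list()                       # per-residue named list N, CA, C
  pos[[1L]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq.int(2L, n)) {
    p <- pos[[i - 1L]]
    N <- placeAtom(p$N, p$CA, p$C, .bb$cN, .bb$angCaCN, psi)
    CA <- placeAtom(p$CA, p$C, N, .bb$nCa, .bb$angCNCa, .bb$omega)
    C <- placeAtom(p$C, N, CA, .bb$caC, .bb$angNCaC, phi)
    pos[[i]] <- list(N = N, CA = CA, C = C)
  }
  atomsTab <- list(); xyz <- list()
  for (i in seq_len(n)) {
    p <- pos[[i]]
    ## carbonyl O in the peptide plane, opposite the next N
    O <- placeAtom(p$N, p$CA, p$C, .bb$cO, .bb$angCaCO, psi + 180)
    for (nm in c("N", "CA", "C", "O")) {
      atomsTab[[length(atomsTab) + 1L]] <- data.frame(
        chain = chain, resid = firstResid + i - 1L, resname = "ALA",
        name = nm, element = substr(nm, 1L, 1L),
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- if (nm == "O") O else p[[nm]]
    }
  }
  Structure(do.call(rbind, atomsTab), do.call(rbind, xyz))
}

## Rotation matrix about a unit axis by angle deg (row-vector convention:
## x %*% rotationMatrix(axis, deg)).
rotationMatrix <- function(axis, deg) {
  u <- vunit(axis); th <- deg2rad(deg)
  K <- matrix(c(0, -u[3L], u[2L], u[3L], 0, -u[1L], -u[2L], u[1L], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  t(R)
}

## Rigidly place a structure: rotate (row-vector) then translate.
rigidPlace <- function(structure, rotation = diag(3),
                       translation = c(0, 0, 0)) {
  co <- structure@coords
  for (m in seq_len(dim(co)[3L]))
    co[, , m] <- sweep(matrix(co[, , m], ncol = 3L) %*% rotation, 2L,
                       translation, `+`)
  new("Structure", atoms = structure@atoms, coords = co)
}

#' Build a bundle of ideal helices at a chosen crossing angle
#'
#' Constructs identical ideal helices, aligns each on its own axis and
#' places them side by side (`separation` Angstrom apart), rotating every
#' second helix by the crossing angle about the separation direction.
#' `layout = "pair"` gives two helices whose [interhelixAngle()] recovers
#' the crossing angle; `"sidebyside"` gives four parallel-laid helices
#' (crossing angle applied pairwise) in a row; `"crisscross"` gives two
#' crossed pairs stacked so the inter-axis distance pattern differs from
#' the side-by-side layout.
#'
#' @param length residues per helix.
#' @param crossingAngle angle between consecutive helix axes, degrees.
#' @param separation inter-axis spacing, Angstrom.
#' @param layout `"pair"`, `"sidebyside"` or `"crisscross"`.
#' @param phi,psi helix torsions.
#' @return a single-model [Structure-class] with chains A, B (, C, D).
#' @export
buildBundle <- function(length = 18L, crossingAngle = 0,
                        separation = 10, layout = c("pair", "sidebyside",
                                                    "crisscross"),
                        phi = -60, psi = -45) {
  layout <- match.arg(layout)
  base <- buildIdealHelix(length, phi = phi, psi = psi)
  ## align the base helix axis with z and centre it
  ax <- helixAxis(base, seq_len(length))
  z <- c(0, 0, 1)
  v <- vcross(ax$direction, z)
  R <- if (vnorm(v) < 1e-9) diag(3)
       else rotationMatrix(v, rad2deg(acos(max(-1, min(1,
            sum(ax$direction * z))))))
  base <- rigidPlace(base, R, c(0, 0, 0))
  ctr <- colMeans(modelCoords(base, 1L))
  base <- rigidPlace(base, diag(3), -ctr)
  nH <- if (layout == "pair") 2L else 4L
  chains <- LETTERS[seq_len(nH)]
  parts <- vector("list", nH)
  for (k in seq_len(nH)) {
    h <- base
    h@atoms$chain <- chains[k]
    rot <- diag(3)
    off <- c((k - 1L) * separation, 0, 0)
    crossed <- switch(layout,
      pair = k == 2L,
      sidebyside = k %% 2L == 0L,
      crisscross = k %in% c(2L, 4L))
    if (crossed) rot <- rotationMatrix(c(1, 0, 0), crossingAngle)
    if (layout == "crisscross")
      off <- c(((k - 1L) %/% 2L) * separation, 0, 0) +
        c(0, (k %% 2L == 0L) * separation, 0)
    parts[[k]] <- rigidPlace(h, rot, off)
  }
  atomsAll <- do.call(rbind, lapply(parts, atoms))
  xyzAll <- do.call(rbind, lapply(parts, modelCoords))
  Structure(atomsAll, xyzAll)
}

#' Perturb a structure into a synthetic ensemble
#'
#' Adds i.i.d. isotropic Gaussian displacements (per atom, per model) to
#' the first model of `structure`; the generator is a pure function of its
#' seed.
#'
#' @param structure a [Structure-class] (model 1 is the seed geometry).
#' @param sigma displacement SD per coordinate, Angstrom (>= 0).
#' @param nModels number of models to generate.
#' @param seed integer RNG seed.
#' @return a multi-model [Structure-class].
#' @export
perturbEnsemble <- function(structure, sigma, nModels, seed = 1L) {
  if (sigma < 0) stop("sigma must be >= 0")
  base <- modelCoords(structure, 1L)
  co <- array(NA_real_, dim = c(nrow(base), 3L, nModels))
  set.seed(seed)
  for (m in seq_len(nModels))
    co[, , m] <- base + matrix(stats::rnorm(length(base), 0, sigma),
                               ncol = 3L)
  new("Structure", atoms = structure@atoms, coords = co)
}

#' Generate a drifting synthetic trajectory
#'
#' Frames are the seed geometry plus a cumulative per-atom Gaussian random
#' walk (drift) plus independent per-frame Gaussian jitter. With zero
#' drift the rolling RMSD is stationary; with drift it exceeds the
#' jitter-only level.
#'
#' @param structure a [Structure-class] (model 1 is the seed geometry).
#' @param nFrames number of frames.
#' @param jitterSigma per-frame jitter SD per coordinate, Angstrom.
#' @param driftPerFrame random-walk step SD per coordinate, Angstrom.
#' @param seed integer RNG seed.
#' @return a multi-model [Structure-class] (frames = models).
#' @export
synthTrajectory <- function(structure, nFrames, jitterSigma = 0,
                            driftPerFrame = 0, seed = 1L) {
  if (jitterSigma < 0 || driftPerFrame < 0) stop("scales must be >= 0")
  base <- modelCoords(structure, 1L)
  set.seed(seed)
  co <- array(NA_real_, dim = c(nrow(base), 3L, nFrames))
  walk <- base * 0
  for (t in seq_len(nFrames)) {
    walk <- walk + matrix(stats::rnorm(length(base), 0, driftPerFrame),
                          ncol = 3L)
    co[, , t] <- base + walk +
      matrix(stats::rnorm(length(base), 0, jitterSigma), ncol = 3L)
  }
  new("Structure", atoms = structure@atoms, coords = co)
}

#' Generate synthetic RDCs from a known tensor
#'
#' Back-calculates amide couplings from the structure and tensor, then
#' adds Gaussian noise.
#'
#' @param structure a [Structure-class].
#' @param tensor a [SaupeTensor-class].
#' @param residueSet residues to emit.
#' @param noiseSigmaHz Gaussian noise SD, Hz (>= 0).
#' @param seed integer RNG seed.
#' @param chain optional chain id.
#' @param model model index.
#' @return RDC table `resid, d_obs_hz, sigma_hz`.
#' @export
synthRdc <- function(structure, tensor, residueSet, noiseSigmaHz = 0,
                     seed = 1L, chain = NULL, model = 1L) {
  if (noiseSigmaHz < 0) stop("noise sigma must be >= 0")
  calc <- backcalcRDC(structure, tensor, residueSet, chain = chain,
                      model = model)
  set.seed(seed)
  data.frame(resid = calc$resid,
             d_obs_hz = calc$d_calc_hz +
               stats::rnorm(nrow(calc), 0, noiseSigmaHz),
             sigma_hz = rep(noiseSigmaHz, nrow(calc)))
}

#' Bound fraction of a two-state binding equilibrium
#'
#' Exact solution of the 1:1 binding quadratic for the fraction of labelled
#' protein in the bound state at total concentrations `P` (protein) and
#' `L` (ligand) with dissociation constant `Kd` (all molar):
#' complex `C = ((P + L + Kd) - sqrt((P + L + Kd)^2 - 4 P L)) / 2`,
#' `f_bound = C / P`.
#'
#' @param proteinConc,ligandConc total concentrations, M (>= 0).
#' @param kd dissociation constant, M (> 0).
#' @return fraction bound in \[0, 1].
#' @export
fractionBound <- function(proteinConc, ligandConc, kd) {
  if (kd <= 0) stop("Kd must be > 0")
  if (any(proteinConc < 0) || any(ligandConc < 0))
    stop("concentrations must be >= 0")
  s <- proteinConc + ligandConc + kd
  ## numerically stable root of the binding quadratic (avoids the
  ## catastrophic cancellation of (s - sqrt(s^2 - 4PL))/2 at large excess)
  disc <- pmax(s^2 - 4 * proteinConc * ligandConc, 0)
  cplx <- 2 * proteinConc * ligandConc / (s + sqrt(disc))
  ifelse(proteinConc > 0, cplx / proteinConc, 0)
}

#' Simulate a two-state fast-exchange titration
#'
#' Emits one amide peak table per titration point. Observed shifts follow
#' the fast-exchange population average
#' `delta_obs = delta_free + f_bound * delta_bound_shift`; peak intensity
#' decays with the exchange-broadening proxy
#' `I = I0 * exp(-k * f_bound * ddComp_bound)` where `ddComp_bound` is the
#' residue's compound bound-state shift — a deliberately simple stand-in
#' for intermediate-exchange broadening that concentrates attenuation on
#' the binding interface. Non-binding residues keep their free-state peak;
#' designated residues are emitted with status `overlapped`.
#'
#' @param nResidues number of residues.
#' @param bindingResidues residues with a bound-state shift.
#' @param ddBoundH,ddBoundN bound-state shift changes (ppm) for the binding
#'   residues (recycled to their number).
#' @param kd dissociation constant, M.
#' @param proteinConc total labelled-protein concentration, M.
#' @param molarRatios protein:ligand molar ratios of the titration points
#'   (40 means 40:1); ligand concentration is `proteinConc / ratio`.
#' @param attenuationK attenuation coefficient k (per ppm).
#' @param overlappedResidues residues flagged `overlapped` in every table.
#' @param shiftNoisePpm Gaussian noise SD added to every emitted shift.
#' @param seed integer RNG seed.
#' @return named list of peak tables: `free` plus one per ratio (labels
#'   like `"40:1"`).
#' @export
synthTitration <- function(nResidues = 41L,
                           bindingResidues = 18:38,
                           ddBoundH = 0.12, ddBoundN = 0.6,
                           kd = 5e-5, proteinConc = 3e-4,
                           molarRatios = c(40, 30, 20, 15, 10, 7),
                           attenuationK = 8,
                           overlappedResidues = integer(0),
                           shiftNoisePpm = 0, seed = 1L) {
  if (proteinConc < 0) stop("unphysical protein concentration")
  set.seed(seed)
  resid <- seq_len(nResidues)
  ## reproducible free-state spectrum
  freeH <- stats::runif(nResidues, 7.5, 9.5)
  freeN <- stats::runif(nResidues, 105, 130)
  dH <- dN <- rep(0, nResidues)
  dH[bindingResidues] <- rep_len(ddBoundH, length(bindingResidues))
  dN[bindingResidues] <- rep_len(ddBoundN, length(bindingResidues))
  ddComp <- sqrt(dH^2 + (dN / 6.5)^2)
  status <- rep("ok", nResidues)
  status[overlappedResidues] <- "overlapped"
  mkTable <- function(fb, label) {
    noise <- function() if (shiftNoisePpm > 0)
      stats::rnorm(nResidues, 0, shiftNoisePpm) else 0
    data.frame(resid = resid,
               dh_ppm = freeH + fb * dH + noise(),
               dn_ppm = freeN + fb * dN + noise() * 5,
               intensity = exp(-attenuationK * fb * ddComp),
               condition = label, status = status,
               stringsAsFactors = FALSE)
  }
  out <- list(free = mkTable(0, "free"))
  for (r in molarRatios) {
    lig <- proteinConc / r
    fb <- fractionBound(proteinConc, lig, kd)
    out[[paste0(r, ":1")]] <- mkTable(fb, paste0(r, ":1"))
  }
  out
}
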