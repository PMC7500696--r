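#' @import methods
NULL

#' Structure: a (multi-model) molecular coordinate container
#'
#' Holds an ordered set of models sharing one atom topology. The atom table
#' records chain, residue number, residue name, atom name and element; the
#' coordinates live in an `natoms x 3 x nmodels` array in Angstrom. All
#' models of an ensemble or all frames of a trajectory share the topology,
#' which is what every pairwise/rolling RMSD computation in the package
#' assumes.
#'
#' @slot atoms data.frame with columns `chain`, `resid`, `resname`, `name`,
#'   `element`; one row per atom, file order preserved.
#' @slot coords numeric array `c(natoms, 3, nmodels)`, Angstrom.
#' @exportClass Structure
setClass("Structure",
  representation(atoms = "data.frame", coords = "array"),
  validity = function(object) {
    msg <- character(0)
    d <- dim(object@coords)
    if (length(d) != 3L || d[2L] != 3L)
      msg <- c(msg, "coords must be an natoms x 3 x nmodels array")
    else {
      if (d[1L] != nrow(object@atoms))
        msg <- c(msg, "coords rows must match atom table rows")
      if (!all(is.finite(object@coords)))
        msg <- c(msg, "coordinates must be finite")
    }
    need <- c("chain", "resid", "resname", "name", "element")
    if (!all(need %in% names(object@atoms)))
      msg <- c(msg, paste("atom table must have columns:",
                          paste(need, collapse = ", ")))
    if (length(msg)) msg else TRUE
  })

#' AtomSelection: a chain / residue-range / atom-name selection
#'
#' Resolves against a [Structure-class] to a deterministic (file-ordered)
#' set of atom indices. `NA` chain matches any chain; an empty residue
#' vector matches all residues.
#'
#' @slot chain character(1), `NA` for any chain.
#' @slot resids integer vector of residue numbers (empty = all).
#' @slot atomNames character vector of atom names (empty = all).
#' @exportClass AtomSelection
setClass("AtomSelection",
  representation(chain = "character", resids = "integer",
                 atomNames = "character"))

#' SuperpositionResult: optimal rigid-body fit of one structure onto another
#'
#' Produced by [kabschSuperpose()]. The transform maps mobile coordinates
#' onto the reference frame as `X %*% rotation + translation` (row-vector
#' convention).
#'
#' @slot rotation 3x3 proper rotation matrix (det +1).
#' @slot translation length-3 translation, Angstrom.
#' @slot rmsdFit RMSD over the fit atoms after the transform, Angstrom.
#' @slot rmsdCalc RMSD over the calc atoms after the same transform.
#' @exportClass SuperpositionResult
setClass("SuperpositionResult",
  representation(rotation = "matrix", translation = "numeric",
                 rmsdFit = "numeric", rmsdCalc = "numeric"),
  validity = function(object) {
    msg <- character(0)
    R <- object@rotation
    if (!all(dim(R) == c(3L, 3L)))
      msg <- c(msg, "rotation must be 3x3")
    else {
      if (max(abs(crossprod(R) - diag(3))) > 1e-6)
        msg <- c(msg, "rotation must be orthonormal")
      if (abs(det(R) - 1) > 1e-6)
        msg <- c(msg, "rotation must be proper (det +1)")
    }
    if (object@rmsdFit < 0 || object@rmsdCalc < 0)
      msg <- c(msg, "RMSD values must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' MetricSeries: a per-frame scalar quality metric
#'
#' Frame-indexed series such as rolling RMSD (Angstrom) or dihedral RMSD
#' against predicted targets (degrees), with its mean/SD/SEM summary.
#'
#' @slot frame integer frame indices.
#' @slot value numeric metric values.
#' @slot metric character(1) metric name.
#' @slot units character(1) units label.
#' @exportClass MetricSeries
setClass("MetricSeries",
  representation(frame = "integer", value = "numeric",
                 metric = "character", units = "character"),
  validity = function(object) {
    if (length(object@frame) != length(object@value))
      "frame and value must have equal length" else TRUE
  })

#' SaupeTensor: symmetric traceless alignment (order) tensor
#'
#' Five independent elements of the 3x3 Saupe order matrix, together with
#' the dipolar interaction constant absorbed into the fit. With the default
#' `dmax = 1` the tensor carries the Hz scale of the couplings (the fit is
#' scale-invariant, so the product form is what is reported).
#'
#' @slot matrix symmetric traceless 3x3 matrix.
#' @slot dmax dipolar interaction constant (Hz) factored out of the tensor.
#' @exportClass SaupeTensor
setClass("SaupeTensor",
  representation(matrix = "matrix", dmax = "numeric"),
  validity = function(object) {
    msg <- character(0)
    S <- object@matrix
    if (!all(dim(S) == c(3L, 3L))) msg <- c(msg, "tensor must be 3x3")
    else {
      if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
        msg <- c(msg, "tensor must be symmetric")
      if (abs(sum(diag(S))) > 1e-8 * max(1, max(abs(S))))
        msg <- c(msg, "tensor must be traceless")
    }
    if (length(object@dmax) != 1L || object@dmax <= 0)
      msg <- c(msg, "dmax must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' RdcFitReport: alignment-tensor fit diagnostics
#'
#' Per-residue observed and back-calculated couplings with the fitted
#' tensor, the coupling RMSD (Hz) and the Q-factor.
#'
#' @slot table data.frame with columns `resid`, `dObs`, `dCalc`, `residual`.
#' @slot rmsd root-mean-square residual, Hz.
#' @slot qFactor normalised agreement metric (unitless, lower is better).
#' @slot tensor the fitted [SaupeTensor-class].
#' @slot nUsed number of couplings used in the fit.
#' @exportClass RdcFitReport
setClass("RdcFitReport",
  representation(table = "data.frame", rmsd = "numeric",
                 qFactor = "numeric", tensor = "SaupeTensor",
                 nUsed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (object@rmsd < 0) msg <- c(msg, "rmsd must be >= 0")
    if (object@qFactor < 0) msg <- c(msg, "qFactor must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' DipolarWaveFit: sinusoidal fit of sequential RDCs along a helix
#'
#' Parameters of `D(n) = Av + AII*cos(2*pi*n/period + phase)` fitted over a
#' contiguous stretch of helical residues (period fixed, default 3.6
#' residues per turn), optionally with a second harmonic.
#'
#' @slot av mean coupling level, Hz.
#' @slot aII dominant sinusoid amplitude, Hz (non-negative).
#' @slot phase phase, degrees.
#' @slot aI second-harmonic amplitude, Hz (`NA` when not fitted).
#' @slot period helix periodicity in residues.
#' @slot se named numeric of parameter standard errors (`av`, `aII`).
#' @slot table data.frame with `resid`, `dObs`, `fitted`, `residual`.
#' @exportClass DipolarWaveFit
setClass("DipolarWaveFit",
  representation(av = "numeric", aII = "numeric", phase = "numeric",
                 aI = "numeric", period = "numeric", se = "numeric",
                 table = "data.frame"),
  validity = function(object) {
    msg <- character(0)
    if (object@aII < 0) msg <- c(msg, "aII must be >= 0")
    if (!is.na(object@aI) && object@aI < 0) msg <- c(msg, "aI must be >= 0")
    if (object@period <= 0) msg <- c(msg, "period must be > 0")
    if (length(msg)) msg else TRUE
  })

#' ConvergenceReport: agreement between two refined ensembles
#'
#' Summary of an annealing-convergence comparison: ensemble averages are
#' superposed and compared globally and over a subunit, with pooled pairwise
#' RMSD statistics across the retained replicas of both ensembles.
#'
#' @slot globalRmsd RMSD between the two average structures over the global
#'   calc selection, Angstrom.
#' @slot subunitRmsd RMSD between the averages over the subunit selection.
#' @slot pooled list with `mean`, `sd`, `sem`, `nPairs` of the pooled
#'   pairwise global RMSD across all retained replicas.
#' @slot pooledSubunit same statistics over the subunit selection.
#' @slot excluded list of two integer vectors: replicas excluded from each
#'   ensemble by the dissociation filter.
#' @slot averages list of the two average [Structure-class] objects.
#' @exportClass ConvergenceReport
setClass("ConvergenceReport",
  representation(globalRmsd = "numeric", subunitRmsd = "numeric",
                 pooled = "list", pooledSubunit = "list",
                 excluded = "list", averages = "list"),
  validity = function(object) {
    if (object@globalRmsd < 0 || object@subunitRmsd < 0)
      "RMSD values must be >= 0" else TRUE
  })
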