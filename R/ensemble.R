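## Composite ensemble procedures: topology discrimination, annealing
## convergence statistics and ensemble summaries.

#' Topology discrimination metrics across candidate trajectories
#'
#' For each candidate trajectory (one per proposed helix packing) computes
#' the rolling-RMSD series and the per-frame circular dihedral RMSD
#' against the predicted torsion targets, then tabulates their means and
#' SDs plus all pairwise ratios of the dihedral-RMSD means — the
#' discriminator that flags packings whose backbones must distort away
#' from the predicted angles.
#'
#' @param trajectories named list of multi-model [Structure-class]
#'   trajectories.
#' @param talosTargets TALOS-style table with target `phi`/`psi`.
#' @param fitSelection,calcSelection selections for the rolling RMSD.
#' @param dihedralResidues residues entering the dihedral RMSD.
#' @param chain optional chain for the dihedral metric.
#' @param lagFrames rolling-RMSD lag in frames (time lag divided by the
#'   frame spacing), default 1.
#' @return list with `table` (one row per trajectory: rolling/dihedral
#'   mean and SD), `dihedralRatios` (matrix of row/column mean ratios) and
#'   `series` (per-trajectory list of the two [MetricSeries-class]).
#' @export
topologyMetricsReport <- function(trajectories, talosTargets, fitSelection,
                                  calcSelection = fitSelection,
                                  dihedralResidues, chain = NULL,
                                  lagFrames = 1L) {
  if (!length(trajectories)) stop("need at least one trajectory")
  if (is.null(names(trajectories)))
    names(trajectories) <- paste0("traj", seq_along(trajectories))
  rows <- list(); series <- list()
  for (nm in names(trajectories)) {
    traj <- trajectories[[nm]]
    roll <- rollingRMSD(traj, lagFrames, fitSelection, calcSelection)
    dih <- vapply(seq_len(nModels(traj)), function(m)
      dihedralRMSDToTarget(backboneDihedrals(traj, m), talosTargets,
                           dihedralResidues, chain = chain), numeric(1L))
    dihSeries <- new("MetricSeries", frame = seq_len(nModels(traj)),
                     value = dih, metric = "dihedral RMSD", units = "deg")
    rs <- metricSummary(roll); ds <- metricSummary(dihSeries)
    rows[[nm]] <- data.frame(trajectory = nm,
                             rollingMean = rs$mean, rollingSD = rs$sd,
                             dihedralMean = ds$mean, dihedralSD = ds$sd,
                             stringsAsFactors = FALSE)
    series[[nm]] <- list(rolling = roll, dihedral = dihSeries)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  means <- tab$dihedralMean
  ratios <- outer(means, means, `/`)
  dimnames(ratios) <- list(tab$trajectory, tab$trajectory)
  list(table = tab, dihedralRatios = ratios, series = series)
}

#' Average structure of an ensemble
#'
#' Superposes every model onto the first over the fit selection and takes
#' the per-atom coordinate mean. The result is a plain coordinate average:
#' bond lengths and angles are not re-idealised.
#'
#' @param ensemble a multi-model [Structure-class].
#' @param fitSelection selection the superposition minimises over.
#' @return a single-model [Structure-class].
#' @export
averageStructure <- function(ensemble, fitSelection) {
  n <- nModels(ensemble)
  if (n < 2L) stop("need at least 2 models")
  fi <- resolveSelection(ensemble, fitSelection)
  ref <- modelCoords(ensemble, 1L)
  acc <- ref
  for (m in seq.int(2L, n)) {
    B <- modelCoords(ensemble, m)
    tr <- kabschCore(ref[fi, , drop = FALSE], B[fi, , drop = FALSE])
    acc <- acc + sweep(B %*% tr$rotation, 2L, tr$translation, `+`)
  }
  Structure(ensemble@atoms, acc / n)
}

## Count inter-chain heavy-atom contacts closer than `cutoff` Angstrom in
## one model; hydrogen atoms are ignored.
interChainContacts <- function(structure, model = 1L, cutoff = 5) {
  a <- structure@atoms
  heavy <- a$element != "H"
  xyz <- modelCoords(structure, model)[heavy, , drop = FALSE]
  ch <- a$chain[heavy]
  chains <- unique(ch)
  if (length(chains) < 2L) return(0L)
  count <- 0L
  for (i in seq_len(length(chains) - 1L)) {
    A <- xyz[ch == chains[i], , drop = FALSE]
    for (j in seq.int(i + 1L, length(chains))) {
      B <- xyz[ch == chains[j], , drop = FALSE]
      d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
      count <- count + sum(d2 < cutoff^2)
    }
  }
  count
}

#' Convergence comparison of two refined ensembles
#'
#' Applies a dissociation filter (replicas whose final structure retains
#' fewer than `contactThreshold` inter-chain heavy-atom contacts within
#' `contactCutoff` Angstrom are excluded), averages the retained replicas
#' of each ensemble, superposes the two averages over the fit selection
#' and reports their global and subunit RMSDs, plus pooled pairwise RMSD
#' statistics (mean +/- SEM over all unordered pairs) across the retained
#' replicas of both ensembles.
#'
#' @param ensembleA,ensembleB multi-model [Structure-class] objects with
#'   identical topology.
#' @param fitSelection selection used for all superpositions.
#' @param calcSelectionGlobal selection of the global RMSD (defaults to
#'   the fit selection).
#' @param calcSelectionSubunit selection of the subunit-only RMSD.
#' @param contactCutoff contact distance cutoff, Angstrom.
#' @param contactThreshold minimum retained inter-chain contacts.
#' @return a [ConvergenceReport-class].
#' @export
annealingConvergence <- function(ensembleA, ensembleB, fitSelection,
                                 calcSelectionGlobal = fitSelection,
                                 calcSelectionSubunit,
                                 contactCutoff = 5,
                                 contactThreshold = 10L) {
  filterEns <- function(ens) {
    contacts <- vapply(seq_len(nModels(ens)), function(m)
      interChainContacts(ens, m, contactCutoff), numeric(1L))
    which(contacts < contactThreshold)
  }
  exA <- filterEns(ensembleA)
  exB <- filterEns(ensembleB)
  keepA <- setdiff(seq_len(nModels(ensembleA)), exA)
  keepB <- setdiff(seq_len(nModels(ensembleB)), exB)
  if (length(keepA) < 2L || length(keepB) < 2L)
    stop("fewer than 2 replicas retained after the dissociation filter")
  A <- selectModels(ensembleA, keepA)
  B <- selectModels(ensembleB, keepB)
  avgA <- averageStructure(A, fitSelection)
  avgB <- averageStructure(B, fitSelection)
  supG <- kabschSuperpose(avgA, avgB, fitSelection, calcSelectionGlobal)
  supS <- kabschSuperpose(avgA, avgB, fitSelection, calcSelectionSubunit)
  pooledStruct <- Structure(A@atoms,
                            array(c(A@coords, B@coords),
                                  dim = c(nAtoms(A), 3L,
                                          nModels(A) + nModels(B))))
  pg <- pairwiseEnsembleRMSD(pooledStruct, fitSelection,
                             calcSelectionGlobal)
  ps <- pairwiseEnsembleRMSD(pooledStruct, fitSelection,
                             calcSelectionSubunit)
  new("ConvergenceReport",
      globalRmsd = supG@rmsdCalc, subunitRmsd = supS@rmsdCalc,
      pooled = pg[c("mean", "sd", "sem", "nPairs")],
      pooledSubunit = ps[c("mean", "sd", "sem", "nPairs")],
      excluded = list(a = exA, b = exB),
      averages = list(a = avgA, b = avgB))
}

setMethod("show", "ConvergenceReport", function(object) {
  cat(sprintf("ConvergenceReport: between-average global RMSD = %.2f A, subunit = %.2f A\n",
              object@globalRmsd, object@subunitRmsd))
  cat(sprintf("  pooled pairwise global: %.2f +/- %.2f A (mean +/- SEM, %d pairs)\n",
              object@pooled$mean, object@pooled$sem, object@pooled$nPairs))
  cat("  excluded replicas: A =", length(object@excluded$a),
      ", B =", length(object@excluded$b), "\n")
  invisible(object)
})

#' Ensemble pairwise-RMSD summary report
#'
#' Thin composition of [pairwiseEnsembleRMSD()] with a rendering suitable
#' for JSON/TSV export.
#'
#' @param ensemble a multi-model [Structure-class].
#' @param fitSelection,calcSelection atom selections.
#' @return list `matrix`, `mean`, `sd`, `sem`, `nPairs`, `nModels`.
#' @export
ensembleSummary <- function(ensemble, fitSelection,
                            calcSelection = fitSelection) {
  res <- pairwiseEnsembleRMSD(ensemble, fitSelection, calcSelection)
  res$nModels <- nModels(ensemble)
  res
}
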