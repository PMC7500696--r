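## Readers/writers for coordinate files and the tabular NMR formats the
## pipeline consumes, plus restraint generation and rigidity classification.

#' Read a (multi-model) PDB file
#'
#' Reads `ATOM` records only; alternate locations other than blank/`A` are
#' dropped; residue numbering is taken as given in the file. Multi-model
#' files (`MODEL`/`ENDMDL`) become the models of the returned
#' [Structure-class]; all models must share one atom topology.
#'
#' Parsing is delegated to [bio3d::read.pdb()] after a light pre-scan that
#' reports malformed `ATOM` records with their line number and detects
#' inconsistent per-model atom counts.
#'
#' @param path path to a PDB file.
#' @return a [Structure-class].
#' @export
readPDB <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  isAtom <- startsWith(lines, "ATOM")
  bad <- which(isAtom & nchar(lines) < 54)
  if (length(bad))
    stop("malformed ATOM record at line ", bad[1L], ": ",
         substr(lines[bad[1L]], 1L, 30L))
  for (i in which(isAtom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz))
      stop("malformed ATOM record at line ", i,
           ": non-numeric coordinate field")
  }
  ## per-model ATOM counts must agree (topology invariant)
  modelStarts <- which(startsWith(lines, "MODEL"))
  if (length(modelStarts) > 1L) {
    modelEnds <- which(startsWith(lines, "ENDMDL"))
    if (length(modelEnds) != length(modelStarts))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(s, e) sum(isAtom[s:e]), modelStarts, modelEnds)
    if (length(unique(counts)) != 1L)
      stop("topology error: models have differing atom counts (",
           paste(counts, collapse = ", "), ")")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  keep <- pdb$atom$type == "ATOM"
  alt <- pdb$atom$alt
  keep <- keep & (is.na(alt) | alt %in% c("", "A"))
  atomTab <- data.frame(
    chain = as.character(pdb$atom$chain[keep]),
    resid = as.integer(pdb$atom$resno[keep]),
    resname = as.character(pdb$atom$resid[keep]),
    name = as.character(pdb$atom$elety[keep]),
    element = as.character(pdb$atom$elesy[keep]),
    stringsAsFactors = FALSE)
  atomTab$chain[is.na(atomTab$chain)] <- "A"
  if (anyNA(atomTab$element) || !all(nzchar(atomTab$element)))
    atomTab$element <- substr(gsub("[0-9]", "", atomTab$name), 1L, 1L)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1L)
  nm <- nrow(xyz)
  na <- sum(keep)
  colSel <- as.vector(rbind(3L * (which(keep)) - 2L,
                            3L * (which(keep)) - 1L,
                            3L * (which(keep))))
  coords <- array(NA_real_, dim = c(na, 3L, nm))
  for (m in seq_len(nm))
    coords[, , m] <- matrix(xyz[m, colSel], ncol = 3L, byrow = TRUE)
  Structure(atomTab, coords)
}

#' Write a Structure to a PDB file
#'
#' Single-model structures are written without `MODEL` records; multi-model
#' structures get one `MODEL`/`ENDMDL` block per model. Output re-reads via
#' [readPDB()] to the identical topology and to coordinates at PDB
#' precision (3 decimals).
#'
#' @param structure a [Structure-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePDB <- function(structure, path) {
  validObject(structure)
  if (max(abs(structure@coords)) > 9999.999)
    stop("coordinates exceed the fixed-width PDB limit (|x| > 9999.999)")
  a <- structure@atoms
  nm <- nModels(structure)
  xyz <- matrix(NA_real_, nrow = nm, ncol = 3L * nAtoms(structure))
  for (m in seq_len(nm))
    xyz[m, ] <- as.vector(t(modelCoords(structure, m)))
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = a$resid, resid = a$resname,
                   elety = a$name, chain = a$chain,
                   elesy = a$element)
  invisible(path)
}

## Shared delimited-table reader: accepts comma- or whitespace-delimited
## text with a header row (the supplementary spreadsheets export as either).
readDelimTable <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  tab <- if (grepl(",", first, fixed = TRUE))
    utils::read.csv(path, strip.white = TRUE)
  else
    utils::read.table(path, header = TRUE)
  names(tab) <- tolower(names(tab))
  miss <- setdiff(required, names(tab))
  if (length(miss))
    stop("table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  tab
}

#' Read a TALOS-style torsion prediction table
#'
#' Expected columns (comma- or whitespace-delimited, header row):
#' `resid, resname, phi, psi, dphi, dpsi, dist, s2, count, class`, one row
#' per residue. `phi`/`psi` are the predicted backbone torsions in degrees,
#' `dphi`/`dpsi` their standard deviations, `s2` the chemical-shift-derived
#' order parameter (RCI-S2, 0 = fully flexible, 1 = rigid) and `class` one
#' of `None`, `Good`, `Warn`, `Dyn`.
#'
#' @param path path to the table.
#' @return data.frame with the columns above; `class` is a factor with the
#'   four levels; angles wrapped to \[-180, 180).
#' @export
readTalosTable <- function(path) {
  tab <- readDelimTable(path, c("resid", "resname", "phi", "psi", "dphi",
                                "dpsi", "dist", "s2", "count", "class"))
  if (nrow(tab) == 0L)
    return(data.frame(resid = integer(0), resname = character(0),
                      phi = numeric(0), psi = numeric(0),
                      dphi = numeric(0), dpsi = numeric(0),
                      dist = numeric(0), s2 = numeric(0),
                      count = integer(0),
                      class = factor(character(0),
                                     levels = c("None", "Good", "Warn",
                                                "Dyn"))))
  lv <- c("None", "Good", "Warn", "Dyn")
  cls <- as.character(tab$class)
  if (any(!cls %in% lv))
    stop("unknown CLASS token(s): ",
         paste(unique(cls[!cls %in% lv]), collapse = ", "))
  for (ang in c("phi", "psi")) {
    v <- tab[[ang]]
    if (any(!is.na(v) & (v < -180 | v >= 360)))
      stop("angle out of range in column ", ang)
    tab[[ang]] <- wrapAngle(v)
  }
  if (any(!is.na(tab$s2) & (tab$s2 < 0 | tab$s2 > 1)))
    stop("s2 values must lie in [0, 1]")
  data.frame(resid = as.integer(tab$resid),
             resname = as.character(tab$resname),
             phi = tab$phi, psi = tab$psi,
             dphi = tab$dphi, dpsi = tab$dpsi,
             dist = tab$dist, s2 = tab$s2,
             count = as.integer(tab$count),
             class = factor(cls, levels = lv),
             stringsAsFactors = FALSE)
}

#' Read a per-residue RDC table
#'
#' Columns: `resid, d_obs_hz, sigma_hz` (observed one-bond coupling in Hz
#' and its uncertainty).
#'
#' @param path path to the table.
#' @return data.frame `resid`, `d_obs_hz`, `sigma_hz`.
#' @export
readRdcTable <- function(path) {
  tab <- readDelimTable(path, c("resid", "d_obs_hz", "sigma_hz"))
  if (any(!is.na(tab$sigma_hz) & tab$sigma_hz < 0))
    stop("negative RDC uncertainty")
  data.frame(resid = as.integer(tab$resid),
             d_obs_hz = as.numeric(tab$d_obs_hz),
             sigma_hz = as.numeric(tab$sigma_hz))
}

#' Read a per-residue amide peak table
#'
#' Columns: `resid, dh_ppm, dn_ppm, intensity, condition, status`, with
#' `status` one of `ok`, `overlapped`, `missing` (missing column defaults
#' to `ok`). Overlapped or missing rows may leave `intensity`/shifts empty.
#'
#' @param path path to the table.
#' @return data.frame with the columns above.
#' @export
readPeakTable <- function(path) {
  tab <- readDelimTable(path, c("resid", "dh_ppm", "dn_ppm", "intensity"))
  if (is.null(tab$condition)) tab$condition <- NA_character_
  if (is.null(tab$status)) tab$status <- "ok"
  tab$status[is.na(tab$status) | tab$status == ""] <- "ok"
  ok <- c("ok", "overlapped", "missing")
  if (any(!tab$status %in% ok))
    stop("unknown status token(s): ",
         paste(unique(tab$status[!tab$status %in% ok]), collapse = ", "))
  if (any(tab$status == "ok" & (is.na(tab$intensity) | tab$intensity < 0)))
    stop("rows with status 'ok' must have non-negative intensity")
  data.frame(resid = as.integer(tab$resid),
             dh_ppm = as.numeric(tab$dh_ppm),
             dn_ppm = as.numeric(tab$dn_ppm),
             intensity = as.numeric(tab$intensity),
             condition = as.character(tab$condition),
             status = as.character(tab$status),
             stringsAsFactors = FALSE)
}

#' Write a peak/RDC/TALOS table as CSV
#'
#' Companion writer used to round-trip fixtures through the readers.
#'
#' @param tab data.frame in one of the package's table layouts.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTable <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Classify rigid residues by order parameter
#'
#' A residue counts as rigid (well-structured) when its chemical-shift-derived
#' order parameter RCI-S2 is at or above the threshold; the canonical cut
#' for a well-structured region is 0.7 (inclusive).
#'
#' @param records TALOS-style table from [readTalosTable()].
#' @param threshold minimum RCI-S2, default 0.7.
#' @return sorted integer vector of rigid residue numbers.
#' @export
classifyRigidResidues <- function(records, threshold = 0.7) {
  if (nrow(records) == 0L) stop("empty prediction table")
  sort(records$resid[!is.na(records$s2) & records$s2 >= threshold])
}

#' Build flat-bottom backbone dihedral restraints
#'
#' Emits one phi and one psi restraint per rigid residue with target angles
#' taken from the torsion predictions, skipping residues in `exclude`,
#' residues whose prediction class is `None`, and the terminally undefined
#' angles (phi of the first tabulated residue, psi of the last). Force
#' constants default to rk2 = rk3 = 32.0 kcal/mol/rad on both walls. The
#' flat-bottom half-width defaults to the predicted angle uncertainty with
#' a 10 degree floor.
#'
#' @param records TALOS-style table from [readTalosTable()].
#' @param rigidSet residue numbers to restrain (e.g. from
#'   [classifyRigidResidues()]).
#' @param exclude residue numbers to leave unrestrained.
#' @param rk force constant for both walls, kcal/mol/rad.
#' @param halfWidthFloor minimum half-width, degrees.
#' @return data.frame `resid, angle, target, halfWidth, rk2, rk3`.
#' @export
dihedralRestraints <- function(records, rigidSet, exclude = integer(0),
                               rk = 32.0, halfWidthFloor = 10) {
  if (rk <= 0) stop("force constant must be > 0")
  rigidSet <- setdiff(parseResidRange(rigidSet), parseResidRange(exclude))
  missing <- setdiff(rigidSet, records$resid)
  if (length(missing))
    stop("residue(s) absent from prediction table: ",
         paste(missing, collapse = ", "))
  first <- min(records$resid)
  last <- max(records$resid)
  out <- list()
  for (r in sort(rigidSet)) {
    row <- records[records$resid == r, ][1L, ]
    if (!is.na(row$class) && row$class == "None") next
    if (r != first && !is.na(row$phi))
      out[[length(out) + 1L]] <- data.frame(
        resid = r, angle = "phi", target = row$phi,
        halfWidth = max(row$dphi, halfWidthFloor, na.rm = TRUE),
        rk2 = rk, rk3 = rk)
    if (r != last && !is.na(row$psi))
      out[[length(out) + 1L]] <- data.frame(
        resid = r, angle = "psi", target = row$psi,
        halfWidth = max(row$dpsi, halfWidthFloor, na.rm = TRUE),
        rk2 = rk, rk3 = rk)
  }
  if (!length(out))
    return(data.frame(resid = integer(0), angle = character(0),
                      target = numeric(0), halfWidth = numeric(0),
                      rk2 = numeric(0), rk3 = numeric(0)))
  do.call(rbind, out)
}

#' Render dihedral restraints as text
#'
#' `style = "generic"` writes one flat-bottom record per line
#' (`resid angle target +/-halfWidth rk2 rk3`); `style = "amber"` writes
#' `&rst`-style namelist records with the flat bottom between
#' `target - halfWidth` and `target + halfWidth` and parabolic walls of
#' force constant rk2/rk3. The rendering is a formatting choice only; the
#' restraint semantics are identical.
#'
#' @param restraints data.frame from [dihedralRestraints()].
#' @param path optional output file; when `NULL` the lines are returned.
#' @param style `"generic"` or `"amber"`.
#' @return character vector of lines, invisibly when written to `path`.
#' @export
writeDihedralRestraints <- function(restraints, path = NULL,
                                    style = c("generic", "amber")) {
  style <- match.arg(style)
  lines <- if (style == "generic") {
    sprintf("%4d %-3s %8.2f +/- %6.2f  rk2=%.1f rk3=%.1f",
            restraints$resid, restraints$angle, restraints$target,
            restraints$halfWidth, restraints$rk2, restraints$rk3)
  } else {
    apply(restraints, 1L, function(r) {
      t <- as.numeric(r[["target"]]); w <- as.numeric(r[["halfWidth"]])
      sprintf(paste0("&rst iresid=1, resid=%s, angle='%s', r1=%.2f, ",
                     "r2=%.2f, r3=%.2f, r4=%.2f, rk2=%s, rk3=%s /"),
              trimws(r[["resid"]]), trimws(r[["angle"]]),
              t - w - 30, t - w, t + w, t + w + 30,
              trimws(r[["rk2"]]), trimws(r[["rk3"]]))
    })
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
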