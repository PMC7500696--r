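#' Construct a Structure
#'
#' @param atoms atom table (`chain`, `resid`, `resname`, `name`, `element`).
#' @param coords `natoms x 3` matrix (single model) or `natoms x 3 x nmodels`
#'   array, Angstrom.
#' @return a [Structure-class] object.
#' @export
Structure <- function(atoms, coords) {
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  atoms$chain <- as.character(atoms$chain)
  atoms$resid <- as.integer(atoms$resid)
  atoms$resname <- as.character(atoms$resname)
  atoms$name <- as.character(atoms$name)
  if (is.null(atoms$element))
    atoms$element <- substr(gsub("[0-9]", "", atoms$name), 1L, 1L)
  atoms$element <- as.character(atoms$element)
  rownames(atoms) <- NULL
  new("Structure", atoms = atoms, coords = coords)
}

#' @describeIn Structure number of models (frames) in the object.
#' @param x a `Structure`.
#' @export
nModels <- function(x) dim(x@coords)[3L]

#' @describeIn Structure number of atoms per model.
#' @export
nAtoms <- function(x) dim(x@coords)[1L]

#' @describeIn Structure the atom topology table.
#' @export
atoms <- function(x) x@atoms

#' Coordinates of one model
#'
#' @param x a [Structure-class].
#' @param model model index (1-based).
#' @return `natoms x 3` numeric matrix, Angstrom.
#' @export
modelCoords <- function(x, model = 1L) {
  if (model < 1L || model > nModels(x))
    stop("model index ", model, " out of range 1..", nModels(x))
  matrix(x@coords[, , model], ncol = 3L)
}

#' Extract a subset of models as a new Structure
#'
#' @param x a [Structure-class].
#' @param models integer vector of model indices.
#' @return a [Structure-class] with the selected models, order preserved.
#' @export
selectModels <- function(x, models) {
  models <- as.integer(models)
  if (any(models < 1L | models > nModels(x)))
    stop("model indices out of range")
  new("Structure", atoms = x@atoms,
      coords = x@coords[, , models, drop = FALSE])
}

setMethod("show", "Structure", function(object) {
  a <- object@atoms
  cat("Structure: ", nAtoms(object), " atoms, ", nModels(object),
      " model(s)\n", sep = "")
  for (ch in unique(a$chain)) {
    r <- a$resid[a$chain == ch]
    cat("  chain ", ch, ": residues ", min(r), "-", max(r), " (",
        sum(a$chain == ch), " atoms)\n", sep = "")
  }
  invisible(object)
})

#' Create an atom selection
#'
#' @param chain chain identifier (`NA` = any chain).
#' @param resids residue numbers: an integer vector or a range string such
#'   as `"17-39"` or `"17-39,45"`; `NULL` selects all residues.
#' @param atomNames atom names to keep, default the backbone heavy atoms
#'   `N`, `CA`, `C`; `character(0)` keeps all atoms.
#' @return an [AtomSelection-class].
#' @export
atomSelection <- function(chain = NA_character_, resids = NULL,
                          atomNames = c("N", "CA", "C")) {
  new("AtomSelection",
      chain = as.character(chain),
      resids = if (is.null(resids)) integer(0) else parseResidRange(resids),
      atomNames = as.character(atomNames))
}

#' Parse a `chain:start-end:atoms` selection string
#'
#' The shell-facing selection syntax: `"A:17-39:N,CA,C"`. Empty fields keep
#' the defaults (`*:all:N,CA,C`).
#'
#' @param x selection string.
#' @return an [AtomSelection-class].
#' @export
parseSelection <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)[[1L]]
  chain <- if (length(parts) >= 1L && nzchar(parts[1L]) &&
               parts[1L] != "*") parts[1L] else NA_character_
  resids <- if (length(parts) >= 2L && nzchar(parts[2L]) &&
                parts[2L] != "all") parseResidRange(parts[2L]) else NULL
  atomNames <- if (length(parts) >= 3L && nzchar(parts[3L]))
    strsplit(parts[3L], ",", fixed = TRUE)[[1L]] else c("N", "CA", "C")
  atomSelection(chain, resids, atomNames)
}

setMethod("show", "AtomSelection", function(object) {
  cat("AtomSelection: chain=",
      if (is.na(object@chain)) "*" else object@chain,
      " resids=", if (length(object@resids)) paste0(min(object@resids), "-",
                                                    max(object@resids))
      else "all",
      " atoms=", if (length(object@atomNames))
        paste(object@atomNames, collapse = ",") else "all",
      "\n", sep = "")
  invisible(object)
})

#' Resolve an atom selection against a Structure
#'
#' Resolution is deterministic: indices are returned in the atom-table
#' (file) order.
#'
#' @param structure a [Structure-class].
#' @param selection an [AtomSelection-class], a selection string (parsed by
#'   [parseSelection()]), or a list of either (union, file order).
#' @return integer vector of atom indices.
#' @export
resolveSelection <- function(structure, selection) {
  if (is.character(selection)) selection <- parseSelection(selection)
  if (is.list(selection)) {
    idx <- sort(unique(unlist(lapply(selection, resolveSelection,
                                     structure = structure))))
    return(idx)
  }
  a <- structure@atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.na(selection@chain)) keep <- keep & a$chain == selection@chain
  if (length(selection@resids)) keep <- keep & a$resid %in% selection@resids
  if (length(selection@atomNames)) keep <- keep & a$name %in% selection@atomNames
  idx <- which(keep)
  if (!length(idx))
    stop("selection resolves to zero atoms")
  idx
}
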