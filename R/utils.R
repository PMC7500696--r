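## Internal numeric helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles into [-180, 180)
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval \[-180, 180).
#' @keywords internal
wrapAngle <- function(x) ((x + 180) %% 360) - 180

#' Circular difference between angles
#'
#' Difference `a - b` wrapped to the half-open interval (-180, 180], so a
#' 179 vs -179 degree pair differs by 2 degrees, never 358.
#'
#' @param a,b numeric vectors of angles in degrees.
#' @return wrapped differences in degrees.
#' @export
circularDiff <- function(a, b) {
  d <- (a - b) %% 360
  d[!is.na(d) & d > 180] <- d[!is.na(d) & d > 180] - 360
  d
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  a / n
}

## Torsion angle p1-p2-p3-p4 following the IUPAC sign convention
## (trans/anti = 180 degrees). Each argument is a length-3 coordinate.
torsionAngle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  rad2deg(atan2(-sum(m1 * n2), sum(n1 * n2)))
}

## Place a new atom D given positions of A, B, C, the C-D bond length,
## the B-C-D angle (deg) and the A-B-C-D torsion (deg); the standard
## internal-coordinate (NeRF) construction used when growing a backbone.
placeAtom <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  ## local frame at C: (bc, m, n); the sign of the n component fixes the
  ## IUPAC torsion handedness (checked against torsionAngle)
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

## Parse "17-39,45" style residue range strings into an integer vector.
parseResidRange <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  parts <- strsplit(gsub("\\s", "", x), ",")[[1L]]
  out <- integer(0)
  for (p in parts) {
    if (grepl("-", p, fixed = TRUE) && !grepl("^-", p)) {
      ab <- as.integer(strsplit(p, "-", fixed = TRUE)[[1L]])
      out <- c(out, seq.int(ab[1L], ab[2L]))
    } else {
      out <- c(out, as.integer(p))
    }
  }
  out
}
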