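## Compound chemical-shift perturbation, titration attenuation and
## quartile-based effect classification.

#' Compound chemical shift perturbation
#'
#' Per-residue compound CSP between two peak tables:
#' `ddComp = sqrt(ddH^2 + (ddN/scale)^2)` with the nitrogen shift scaled
#' down (default 6.5) to put the two nuclei on a comparable ppm scale.
#' Residues missing from either table, or flagged overlapped/missing, come
#' back with status `undetermined`. The differences are absolute, so the
#' result does not depend on which table is called free.
#'
#' @param peaksFree,peaksBound peak tables ([readPeakTable()] layout).
#' @param nitrogenScale positive scale applied to the 15N shift difference.
#' @return data.frame `resid, ddH, ddN, csp, status` with status `ok` or
#'   `undetermined`.
#' @export
compoundCSP <- function(peaksFree, peaksBound, nitrogenScale = 6.5) {
  if (nitrogenScale <= 0) stop("nitrogen scale must be > 0")
  resids <- sort(union(peaksFree$resid, peaksBound$resid))
  out <- data.frame(resid = resids, ddH = NA_real_, ddN = NA_real_,
                    csp = NA_real_, status = "undetermined",
                    stringsAsFactors = FALSE)
  for (k in seq_along(resids)) {
    f <- peaksFree[peaksFree$resid == resids[k], ]
    b <- peaksBound[peaksBound$resid == resids[k], ]
    if (nrow(f) != 1L || nrow(b) != 1L) next
    if (f$status != "ok" || b$status != "ok") next
    if (anyNA(c(f$dh_ppm, f$dn_ppm, b$dh_ppm, b$dn_ppm))) next
    ddH <- abs(b$dh_ppm - f$dh_ppm)
    ddN <- abs(b$dn_ppm - f$dn_ppm)
    out$ddH[k] <- ddH
    out$ddN[k] <- ddN
    out$csp[k] <- sqrt(ddH^2 + (ddN / nitrogenScale)^2)
    out$status[k] <- "ok"
  }
  out
}

#' Peak attenuation along a titration
#'
#' Relative intensity I/I0 of every residue's amide cross-peak at each
#' titration point, with I0 taken from the reference (ligand-free)
#' condition; the reference condition itself is reported as exactly 1.
#' Residues with I0 = 0, or flagged overlapped/missing in either table,
#' are `undetermined` at that point.
#'
#' @param titration named list of peak tables; names are the condition
#'   labels (e.g. molar-ratio tags).
#' @param referenceCondition name of the reference table in `titration`.
#' @return data.frame `resid, condition, ratio, status`, long format, with
#'   `condition` ordered as given.
#' @export
attenuationSeries <- function(titration, referenceCondition) {
  if (!referenceCondition %in% names(titration))
    stop("reference condition '", referenceCondition,
         "' not among the titration tables")
  ref <- titration[[referenceCondition]]
  out <- list()
  for (cond in names(titration)) {
    tab <- titration[[cond]]
    for (k in seq_len(nrow(tab))) {
      r <- tab$resid[k]
      f <- ref[ref$resid == r, ]
      status <- "ok"
      ratio <- NA_real_
      if (nrow(f) != 1L || f$status != "ok" || tab$status[k] != "ok" ||
          is.na(f$intensity) || is.na(tab$intensity[k]) ||
          f$intensity == 0) {
        status <- "undetermined"
      } else if (cond == referenceCondition) {
        ratio <- 1
      } else {
        ratio <- tab$intensity[k] / f$intensity
      }
      out[[length(out) + 1L]] <- data.frame(resid = r, condition = cond,
                                            ratio = ratio, status = status,
                                            stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$condition <- factor(res$condition, levels = names(titration))
  res
}

#' Quartile-based effect classification
#'
#' Splits scored residues into four groups at the quartiles of the score
#' distribution (linear interpolation between order statistics, the common
#' type-7 convention), labelled `q1` (weakest effect) to `q4` (strongest).
#' For scores where a smaller value means a stronger effect (peak
#' attenuation I/I0) set `largerIsStronger = FALSE`; q4 always collects the
#' strongest effects. Ties at a quartile boundary go to the lower class.
#' Residues with `NA` scores are `undetermined` and excluded from the
#' quartile computation.
#'
#' @param values named numeric vector (names = residue numbers) or
#'   data.frame with `resid` and `value` columns.
#' @param largerIsStronger logical flag, default `TRUE`.
#' @return data.frame `resid, value, class` with class levels
#'   `q1, q2, q3, q4, undetermined`.
#' @export
quartileClasses <- function(values, largerIsStronger = TRUE) {
  if (is.data.frame(values)) {
    resid <- values$resid
    v <- values$value
  } else {
    resid <- as.integer(names(values))
    v <- as.numeric(values)
  }
  scored <- !is.na(v)
  if (sum(scored) < 4L) stop("need at least 4 scored residues")
  s <- if (largerIsStronger) v else -v
  q <- stats::quantile(s[scored], probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  cls <- rep("undetermined", length(v))
  cls[scored & s <= q[1L]] <- "q1"
  cls[scored & s > q[1L] & s <= q[2L]] <- "q2"
  cls[scored & s > q[2L] & s <= q[3L]] <- "q3"
  cls[scored & s > q[3L]] <- "q4"
  data.frame(resid = resid, value = v,
             class = factor(cls, levels = c("q1", "q2", "q3", "q4",
                                            "undetermined")),
             stringsAsFactors = FALSE)
}

#' Map effect classes onto a sequence
#'
#' Annotates a one-letter amino acid sequence with per-residue effect
#' classes and renders a text strip: one symbol per residue under the
#' sequence (`.` `+` `*` `#` for q1-q4, `?` undetermined, space for
#' unscored residues).
#'
#' @param classes data.frame from [quartileClasses()] (may be empty).
#' @param sequence one-letter sequence string (or character vector).
#' @param firstResid residue number of the first sequence position.
#' @return list with `table` (data.frame `resid, aa, class`) and `strip`
#'   (two-line character vector).
#' @export
mapToSequence <- function(classes, sequence, firstResid = 1L) {
  aa <- if (length(sequence) == 1L) strsplit(sequence, "")[[1L]]
        else as.character(sequence)
  resids <- seq.int(firstResid, length.out = length(aa))
  cls <- rep(NA_character_, length(aa))
  if (nrow(classes)) {
    if (any(!classes$resid %in% resids))
      stop("class residue index out of sequence range")
    m <- match(classes$resid, resids)
    cls[m] <- as.character(classes$class)
  }
  sym <- c(q1 = ".", q2 = "+", q3 = "*", q4 = "#", undetermined = "?")
  strip <- ifelse(is.na(cls), " ", sym[cls])
  list(table = data.frame(resid = resids, aa = aa, class = cls,
                          stringsAsFactors = FALSE),
       strip = c(paste(aa, collapse = ""), paste(strip, collapse = "")))
}
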