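# GPS-style prediction of site-specific kinase-substrate relations
# (ssKSRs): a candidate 13-mer window is scored by its mean BLOSUM62
# similarity to the kinase's known substrate windows, thresholds are
# calibrated per kinase to a target background false-positive rate, and
# candidate edges are filtered by protein-protein interaction evidence.

# Vectorised scoring of query windows against profile windows:
# score(q) = mean over profile windows v of sum_{j=1..13} M[q_j, v_j],
# where any aligned pair involving the padding character contributes 0.
.scoreWindows <- function(windows, profile_windows, mat = blosum62Padded()) {
  qm <- windowMatrix(windows, "query window")
  pm <- windowMatrix(profile_windows, "profile window")
  total <- matrix(0, nrow(qm), nrow(pm))
  for (j in seq_len(13L)) {
    total <- total + mat[qm[, j], pm[, j], drop = FALSE]
  }
  unname(rowMeans(total))
}

#' Score a candidate window against a kinase profile
#'
#' Peptide-similarity score of a 13-mer phosphosite window: the mean, over
#' the kinase's known substrate windows, of the summed BLOSUM62
#' substitution values across the 13 aligned positions. Aligned pairs
#' involving the terminal padding character `_` contribute 0.
#'
#' @param window a 13-mer window (vectorised: a character vector).
#' @param profile a [KinaseProfile-class].
#' @param mat substitution matrix indexed by the 20 amino-acid letters and
#'   `_`; defaults to BLOSUM62 with a zero padding row/column.
#' @return numeric score(s).
#' @export
scoreSite <- function(window, profile, mat = blosum62Padded()) {
  stopifnot(is(profile, "KinaseProfile"))
  .scoreWindows(window, profile@windows, mat)
}

#' Calibrate a kinase's score threshold to a background FPR
#'
#' Scores a set of background (non-substrate) windows against the profile
#' and sets the threshold at the k-th largest background score with
#' `k = ceiling(fpr * n)`, so that (up to ties) a fraction `fpr` of
#' background windows scores at or above the threshold. `fpr = 0` gives the
#' maximum background score and `fpr = 1` the minimum. The GPS-style
#' "high" / "medium" / "low" stringency presets correspond to FPR of about
#' 2% / 6% / 10%; the default is the medium 6%.
#'
#' @param profile a [KinaseProfile-class].
#' @param background_windows character vector of background 13-mers; at
#'   least 200 are recommended (a warning is issued below that).
#' @param fpr target background false-positive rate in `[0, 1]`.
#' @param mat substitution matrix (see [scoreSite()]).
#' @return the calibrated [KinaseProfile-class] (threshold slot set).
#' @export
calibrateThreshold <- function(profile, background_windows, fpr = 0.06,
                               mat = blosum62Padded()) {
  stopifnot(is(profile, "KinaseProfile"), fpr >= 0, fpr <= 1)
  n <- length(background_windows)
  if (n == 0L) stop("background window set is empty")
  if (n < 200L) {
    warning(sprintf("only %d background window(s); >= 200 recommended for stable calibration", n))
  }
  scores <- sort(.scoreWindows(background_windows, profile@windows, mat),
                 decreasing = TRUE)
  k <- ceiling(fpr * n)
  profile@threshold <- if (k < 1L) scores[1L] else scores[k]
  profile
}

#' Calibrate a list of kinase profiles
#'
#' @param profiles list of [KinaseProfile-class] objects.
#' @inheritParams calibrateThreshold
#' @return list of calibrated profiles (names preserved).
#' @export
calibrateProfiles <- function(profiles, background_windows, fpr = 0.06,
                              mat = blosum62Padded()) {
  out <- lapply(profiles, calibrateThreshold,
                background_windows = background_windows, fpr = fpr, mat = mat)
  names(out) <- vapply(out, kinaseName, "")
  out
}

#' Predict site-specific kinase-substrate relations
#'
#' Emits a (kinase, site) edge when the site's window scores at or above
#' the kinase's calibrated threshold, the site's central residue is
#' accepted by the kinase (a serine/threonine kinase is never matched to a
#' tyrosine site), and - when `require_ppi = TRUE` - there is
#' protein-level interaction evidence between the kinase and the
#' substrate protein (or the substrate is the kinase's own protein).
#' Setting `require_ppi = FALSE` yields a superset of the filtered edges,
#' with the interaction evidence still reported in `passed_ppi`.
#'
#' @param x a [PhosphoSiteTable-class].
#' @param profiles list of calibrated [KinaseProfile-class] objects.
#' @param ppi a [PpiSet-class] (may be omitted when profiles carry their
#'   own `interactors` sets, or when `require_ppi = FALSE`).
#' @param require_ppi drop candidate edges without interaction evidence
#'   (default `TRUE`, the "Exp./String"-style contextual filter).
#' @param mat substitution matrix (see [scoreSite()]).
#' @return data.frame of edges: `kinase`, `protein`, `position`, `residue`,
#'   `window`, `score`, `passed_ppi`.
#' @export
predictKsrs <- function(x, profiles, ppi = NULL, require_ppi = TRUE,
                        mat = blosum62Padded()) {
  stopifnot(is(x, "PhosphoSiteTable"))
  s <- x@sites
  empty <- data.frame(kinase = character(0), protein = character(0),
                      position = integer(0), residue = character(0),
                      window = character(0), score = numeric(0),
                      passed_ppi = logical(0), stringsAsFactors = FALSE)
  if (nrow(s) == 0L || length(profiles) == 0L) return(empty)

  out <- lapply(profiles, function(p) {
    if (!isCalibrated(p)) {
      stop(sprintf("profile '%s' is not calibrated; run calibrateThreshold() first",
                   kinaseName(p)))
    }
    sel <- s$residue %in% p@residues
    if (!any(sel)) return(empty)
    cand <- s[sel, , drop = FALSE]
    sc <- .scoreWindows(cand$window, p@windows, mat)
    hit <- sc >= p@threshold
    if (!any(hit)) return(empty)
    cand <- cand[hit, , drop = FALSE]; sc <- sc[hit]
    evid <- if (length(p@interactors)) {
      cand$protein %in% p@interactors
    } else if (!is.null(ppi)) {
      hasInteraction(ppi, rep(kinaseName(p), nrow(cand)), cand$protein)
    } else {
      rep(FALSE, nrow(cand))
    }
    evid <- evid | cand$protein == kinaseName(p)  # autophosphorylation
    if (require_ppi) {
      cand <- cand[evid, , drop = FALSE]; sc <- sc[evid]
      evid <- evid[evid]
    }
    if (nrow(cand) == 0L) return(empty)
    data.frame(kinase = kinaseName(p), protein = cand$protein,
               position = cand$position, residue = cand$residue,
               window = cand$window, score = sc, passed_ppi = evid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Kinase substrate sets from predicted edges
#'
#' Groups predicted edges into per-kinase substrate site-key sets
#' (`protein_position`), the GMT-style input of the kinase activity
#' inference.
#'
#' @param edges data.frame from [predictKsrs()].
#' @return named list of character vectors of site keys.
#' @export
ksrSubstrateSets <- function(edges) {
  if (nrow(edges) == 0L) return(stats::setNames(list(), character(0)))
  lapply(split(siteKey(edges$protein, edges$position), edges$kinase), unique)
}
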