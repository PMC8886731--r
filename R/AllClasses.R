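#' @import methods
NULL

.SITE_COLS <- c("protein", "gene", "position", "residue", "window",
                "loc_prob", "score", "ratio", "log2_ratio")

#' Quantified phosphosite table
#'
#' Container for one quantified phosphoproteomics experiment in a pooled
#' two-group design: each row is a phosphosite (serine, threonine or
#' tyrosine) with its 13-mer flanking sequence window (positions -6..+6,
#' padded with `_` at protein termini), search-engine quality fields and a
#' single disease/control abundance ratio.
#'
#' @slot sites data.frame with columns `protein`, `gene`, `position`,
#'   `residue`, `window`, `loc_prob`, `score`, `ratio`, `log2_ratio`.
#' @slot metadata list of provenance information (source path, filters
#'   applied, generator parameters).
#'
#' @seealso [readSiteTable()], [filterSites()], [callRegulation()]
#' @export
setClass("PhosphoSiteTable",
         representation(sites = "data.frame", metadata = "list"),
         prototype(sites = data.frame(), metadata = list()))

setValidity("PhosphoSiteTable", function(object) {
  s <- object@sites
  msgs <- character(0)
  missing_cols <- setdiff(.SITE_COLS, names(s))
  if (length(missing_cols)) {
    return(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(s) == 0L) return(TRUE)
  if (!all(s$residue %in% c("S", "T", "Y"))) {
    msgs <- c(msgs, "residue must be one of S, T, Y")
  }
  if (!all(nchar(s$window) == 13L)) {
    msgs <- c(msgs, "all sequence windows must be 13 characters")
  } else if (!all(substr(s$window, 7L, 7L) == s$residue)) {
    msgs <- c(msgs, "window centre (position 7) must equal the residue")
  }
  if (!all(s$ratio > 0)) msgs <- c(msgs, "all ratios must be positive")
  if (!all(s$loc_prob >= 0 & s$loc_prob <= 1)) {
    msgs <- c(msgs, "localization probabilities must lie in [0, 1]")
  }
  if (anyDuplicated(siteKey(s$protein, s$position))) {
    msgs <- c(msgs, "(protein, position) pairs must be unique")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a PhosphoSiteTable
#'
#' @param sites data.frame of per-site records; `log2_ratio` is derived from
#'   `ratio` when absent, and `gene` defaults to the protein accession.
#' @param metadata list of provenance metadata.
#' @return A [PhosphoSiteTable-class] object.
#' @export
PhosphoSiteTable <- function(sites, metadata = list()) {
  sites <- as.data.frame(sites)
  if (!"gene" %in% names(sites)) sites$gene <- sites$protein
  if (!"log2_ratio" %in% names(sites)) sites$log2_ratio <- log2(sites$ratio)
  sites <- sites[, .SITE_COLS, drop = FALSE]
  sites$protein <- as.character(sites$protein)
  sites$gene <- as.character(sites$gene)
  sites$position <- as.integer(sites$position)
  rownames(sites) <- NULL
  new("PhosphoSiteTable", sites = sites, metadata = metadata)
}

#' Per-kinase substrate specificity profile
#'
#' A kinase's known substrate 13-mer windows together with a calibrated
#' score threshold (set by [calibrateThreshold()]) and, optionally, the set
#' of proteins it is known to interact with.
#'
#' @slot name kinase name.
#' @slot windows character vector of known substrate 13-mers.
#' @slot residues accepted central residues, a subset of S, T, Y. A
#'   serine/threonine kinase is never matched to tyrosine sites.
#' @slot threshold calibrated score cutoff (`NA` until calibrated).
#' @slot interactors optional protein identifiers with interaction evidence.
#'
#' @seealso [scoreSite()], [calibrateThreshold()], [predictKsrs()]
#' @export
setClass("KinaseProfile",
         representation(name = "character", windows = "character",
                        residues = "character", threshold = "numeric",
                        interactors = "character"),
         prototype(threshold = NA_real_, interactors = character(0)))

setValidity("KinaseProfile", function(object) {
  msgs <- character(0)
  if (length(object@name) != 1L || !nzchar(object@name)) {
    msgs <- c(msgs, "name must be a single non-empty string")
  }
  if (length(object@windows) < 1L) {
    msgs <- c(msgs, "at least one substrate window is required")
  } else if (any(nchar(object@windows) != 13L)) {
    msgs <- c(msgs, "all substrate windows must be 13-mers")
  }
  if (length(object@residues) < 1L ||
      !all(object@residues %in% c("S", "T", "Y"))) {
    msgs <- c(msgs, "residues must be a non-empty subset of S, T, Y")
  }
  if (length(object@threshold) != 1L) {
    msgs <- c(msgs, "threshold must be a single numeric (NA when uncalibrated)")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a KinaseProfile
#'
#' @param name kinase name.
#' @param windows character vector of known substrate 13-mer windows.
#' @param residues accepted central residues (default serine/threonine).
#' @param threshold calibrated score cutoff; `NA` until calibrated.
#' @param interactors optional character vector of interacting proteins.
#' @return A [KinaseProfile-class] object.
#' @export
KinaseProfile <- function(name, windows, residues = c("S", "T"),
                          threshold = NA_real_, interactors = character(0)) {
  windowMatrix(windows, "substrate window")
  new("KinaseProfile", name = name, windows = windows, residues = residues,
      threshold = as.numeric(threshold), interactors = interactors)
}

#' Position-specific motif enrichment profile
#'
#' Residue enrichment at the 12 flanking positions (-6..+6, excluding the
#' central residue) of a set of foreground windows relative to a background
#' set sharing the same central residue.
#'
#' @slot central central residue (S, T or Y).
#' @slot fgCounts,bgCounts 12 x 20 count matrices (position x amino acid);
#'   padding characters are excluded from counts and column totals.
#' @slot enrichment log2 relative frequency ratio (0.5 pseudocount).
#' @slot pValues one-sided binomial enrichment p-values.
#' @slot qValues Benjamini-Hochberg adjusted p-values across all cells.
#' @slot nForeground,nBackground numbers of foreground/background windows.
#'
#' @seealso [buildMotifProfile()], [summarizeMotifs()]
#' @export
setClass("MotifProfile",
         representation(central = "character", fgCounts = "matrix",
                        bgCounts = "matrix", enrichment = "matrix",
                        pValues = "matrix", qValues = "matrix",
                        nForeground = "integer", nBackground = "integer"))

#' Undirected protein-protein interaction set
#'
#' Stores unique undirected protein pairs; querying `(a, b)` and `(b, a)`
#' is equivalent. Self-interactions are kept but flagged.
#'
#' @slot pairs two-column character matrix of canonically ordered pairs.
#' @slot selfLoops protein identifiers that interact with themselves.
#' @seealso [readPpi()], [hasInteraction()]
#' @export
setClass("PpiSet",
         representation(pairs = "matrix", selfLoops = "character"),
         prototype(pairs = matrix(character(0), ncol = 2L),
                   selfLoops = character(0)))

#' Construct a PpiSet from an edge list
#'
#' @param a,b character vectors of interacting protein identifiers.
#' @return A [PpiSet-class] object with deduplicated undirected pairs.
#' @export
PpiSet <- function(a = character(0), b = character(0)) {
  a <- as.character(a); b <- as.character(b)
  stopifnot(length(a) == length(b))
  self <- unique(a[a == b])
  if (length(self)) {
    warning(sprintf("%d self-interaction(s) flagged: %s", length(self),
                    paste(utils::head(self, 5L), collapse = ", ")))
  }
  lo <- pmin(a, b); hi <- pmax(a, b)
  pairs <- unique(cbind(lo, hi))
  dimnames(pairs) <- NULL
  new("PpiSet", pairs = pairs, selfLoops = self)
}

#' Synthetic-data generation parameters
#'
#' All parameters of the synthetic pooled two-group TMT phosphoproteomics
#' generator: proteome size, site density, residue mix, planted kinases and
#' their activity directions, effect and noise magnitudes, and the seed.
#'
#' @slot nProteins number of proteins to simulate.
#' @slot meanSitesPerProtein mean quantified sites per protein (Poisson).
#' @slot residueMix named probabilities over S, T, Y summing to 1.
#' @slot nKinases number of synthetic kinases.
#' @slot substratesPerKinase planted substrate sites per kinase.
#' @slot nKnownWindows independently drawn "known substrate" windows per
#'   kinase used as its annotation profile (keeps prediction non-circular).
#' @slot activeKinases,inactiveKinases disjoint kinase-name subsets given
#'   positive / negative activity shifts; remaining kinases are null.
#' @slot effectSize planted log2-ratio shift for substrates of active
#'   (positive sign) and inactive (negative sign) kinases.
#' @slot baselineSd baseline log2-ratio standard deviation common to all
#'   sites.
#' @slot noiseSd measurement noise standard deviation (log2-ratio units).
#' @slot seed integer RNG seed; identical configs give identical output.
#'
#' @seealso [simConfig()], [simulateDataset()]
#' @export
setClass("SimConfig",
         representation(nProteins = "integer", meanSitesPerProtein = "numeric",
                        residueMix = "numeric", nKinases = "integer",
                        substratesPerKinase = "integer",
                        nKnownWindows = "integer",
                        activeKinases = "character",
                        inactiveKinases = "character",
                        effectSize = "numeric", baselineSd = "numeric",
                        noiseSd = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character(0)
  if (object@nProteins < 1L) msgs <- c(msgs, "nProteins must be >= 1")
  if (object@meanSitesPerProtein <= 0) {
    msgs <- c(msgs, "meanSitesPerProtein must be positive")
  }
  mix <- object@residueMix
  if (!identical(sort(names(mix)), c("S", "T", "Y"))) {
    msgs <- c(msgs, "residueMix must be named with S, T, Y")
  } else if (abs(sum(mix) - 1) > 1e-9) {
    msgs <- c(msgs, "residueMix must sum to 1 (tolerance 1e-9)")
  } else if (any(mix < 0)) {
    msgs <- c(msgs, "residueMix must be nonnegative")
  }
  if (object@nKinases < 1L) msgs <- c(msgs, "nKinases must be >= 1")
  if (object@substratesPerKinase < 1L) {
    msgs <- c(msgs, "substratesPerKinase must be >= 1")
  }
  if (object@nKnownWindows < 1L) msgs <- c(msgs, "nKnownWindows must be >= 1")
  if (length(intersect(object@activeKinases, object@inactiveKinases))) {
    msgs <- c(msgs, "activeKinases and inactiveKinases must be disjoint")
  }
  if (object@baselineSd <= 0 || object@noiseSd <= 0) {
    msgs <- c(msgs, "baselineSd and noiseSd must be positive")
  }
  if (object@effectSize < 0) msgs <- c(msgs, "effectSize must be nonnegative")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Ground truth of a synthetic dataset
#'
#' @slot sites data.frame mapping each planted substrate site (`protein`,
#'   `position`, `residue`, `window`) to its owning `kinase` and true
#'   log2 `shift`; each planted site belongs to exactly one kinase.
#' @slot kinases data.frame with one row per kinase: `kinase`, true
#'   `direction` (positive / negative / null), signature `sig_offset` and
#'   `sig_residue` of its consensus constraint.
#' @seealso [plantKinases()]
#' @export
setClass("GroundTruth",
         representation(sites = "data.frame", kinases = "data.frame"))

setValidity("GroundTruth", function(object) {
  s <- object@sites
  if (nrow(s) && anyDuplicated(siteKey(s$protein, s$position))) {
    return("each planted site must belong to exactly one kinase")
  }
  TRUE
})

#' Weighted bipartite kinase-site regulatory network
#'
#' The network object assembled by [buildNetwork()]: kinase nodes carry an
#' activity score (NES) and direction, site nodes carry the log2 ratio and
#' regulation status, and directed kinase-to-site edges are weighted by the
#' kinase-substrate prediction score.
#'
#' @slot kinases data.frame: `kinase`, `nes`, `direction`.
#' @slot sites data.frame: `protein`, `position`, `residue`, `log2_ratio`,
#'   `status`.
#' @slot edges data.frame: `kinase`, `protein`, `position`, `residue`,
#'   `score`.
#' @seealso [buildNetwork()], [asIgraph()], [writeGraphML()]
#' @export
setClass("RegulatoryNetwork",
         representation(kinases = "data.frame", sites = "data.frame",
                        edges = "data.frame"))

setValidity("RegulatoryNetwork", function(object) {
  msgs <- character(0)
  if (nrow(object@kinases) &&
      !all(object@kinases$direction %in% c("positive", "negative"))) {
    msgs <- c(msgs, "kinase direction must be positive or negative")
  }
  if (nrow(object@sites) && !all(object@sites$status %in% c("up", "down"))) {
    msgs <- c(msgs, "site status must be up or down")
  }
  e <- object@edges
  if (nrow(e)) {
    if (!all(e$kinase %in% object@kinases$kinase)) {
      msgs <- c(msgs, "edges reference unknown kinases")
    }
    if (!all(siteKey(e$protein, e$position) %in%
             siteKey(object@sites$protein, object@sites$position))) {
      msgs <- c(msgs, "edges reference unknown sites")
    }
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})
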