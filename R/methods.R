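# Accessors and show methods for the core S4 classes.

#' @rdname PhosphoSiteTable-class
#' @export
setMethod("siteData", "PhosphoSiteTable", function(x) x@sites)

#' @rdname PhosphoSiteTable-class
#' @export
setMethod("nSites", "PhosphoSiteTable", function(x) nrow(x@sites))

setMethod("show", "PhosphoSiteTable", function(object) {
  s <- object@sites
  cat(sprintf("PhosphoSiteTable with %d site(s) on %d protein(s)\n",
              nrow(s), length(unique(s$protein))))
  if (nrow(s)) {
    tab <- table(factor(s$residue, levels = c("S", "T", "Y")))
    cat(sprintf("  residues: S=%d T=%d Y=%d\n", tab["S"], tab["T"], tab["Y"]))
    cat(sprintf("  ratio range: [%.3g, %.3g]\n", min(s$ratio), max(s$ratio)))
  }
  flt <- object@metadata$filters
  if (!is.null(flt)) {
    cat(sprintf("  filters: score > %s, localization prob >= %s\n",
                flt$min_score, flt$min_loc_prob))
  }
  invisible(NULL)
})

#' @rdname KinaseProfile-class
#' @export
setMethod("kinaseName", "KinaseProfile", function(x) x@name)

#' @rdname KinaseProfile-class
#' @export
setMethod("substrateWindows", "KinaseProfile", function(x) x@windows)

#' @rdname KinaseProfile-class
#' @export
setMethod("scoreThreshold", "KinaseProfile", function(x) x@threshold)

#' @rdname KinaseProfile-class
#' @export
setMethod("isCalibrated", "KinaseProfile", function(x) !is.na(x@threshold))

setMethod("show", "KinaseProfile", function(object) {
  cat(sprintf("KinaseProfile '%s': %d known substrate window(s), central %s\n",
              object@name, length(object@windows),
              paste(object@residues, collapse = "/")))
  cat(if (is.na(object@threshold)) "  threshold: uncalibrated\n"
      else sprintf("  threshold: %.4g\n", object@threshold))
  invisible(NULL)
})

#' @rdname hasInteraction
#' @export
setMethod("hasInteraction", "PpiSet", function(x, a, b) {
  a <- as.character(a); b <- as.character(b)
  key <- paste(pmin(a, b), pmax(a, b), sep = "\r")
  key %in% paste(x@pairs[, 1L], x@pairs[, 2L], sep = "\r")
})

#' @rdname hasInteraction
#' @export
setMethod("nInteractions", "PpiSet", function(x) nrow(x@pairs))

setMethod("show", "PpiSet", function(object) {
  cat(sprintf("PpiSet with %d undirected interaction(s)", nrow(object@pairs)))
  if (length(object@selfLoops)) {
    cat(sprintf(" (%d self-loop(s))", length(object@selfLoops)))
  }
  cat("\n")
  invisible(NULL)
})

setMethod("show", "MotifProfile", function(object) {
  cat(sprintf("MotifProfile (central residue %s): %d foreground vs %d background window(s)\n",
              object@central, object@nForeground, object@nBackground))
  q <- object@qValues
  if (any(is.finite(q))) {
    i <- arrayInd(which.min(q), dim(q))
    cat(sprintf("  top cell: position %s, residue %s (log2 enrichment %.2f, q = %.3g)\n",
                rownames(q)[i[1L]], colnames(q)[i[2L]],
                object@enrichment[i[1L], i[2L]], min(q, na.rm = TRUE)))
  }
  invisible(NULL)
})

#' @rdname GroundTruth-class
#' @export
setMethod("truthSites", "GroundTruth", function(x) x@sites)

#' @rdname GroundTruth-class
#' @export
setMethod("truthKinases", "GroundTruth", function(x) x@kinases)

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: %d planted substrate site(s) across %d kinase(s)\n",
              nrow(object@sites), nrow(object@kinases)))
  if (nrow(object@kinases)) {
    d <- table(object@kinases$direction)
    cat("  directions:", paste(sprintf("%s=%d", names(d), d), collapse = " "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d proteins, %.2f sites/protein, %d kinase(s) x %d substrates\n",
              object@nProteins, object@meanSitesPerProtein, object@nKinases,
              object@substratesPerKinase))
  cat(sprintf("  residue mix S/T/Y: %s\n",
              paste(sprintf("%.2f", object@residueMix[c("S", "T", "Y")]),
                    collapse = "/")))
  cat(sprintf("  effect %.2f, baseline sd %.2f, noise sd %.2f, seed %d\n",
              object@effectSize, object@baselineSd, object@noiseSd,
              object@seed))
  invisible(NULL)
})

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkKinases", "RegulatoryNetwork", function(x) x@kinases)

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkSites", "RegulatoryNetwork", function(x) x@sites)

#' @rdname RegulatoryNetwork-class
#' @export
setMethod("networkEdges", "RegulatoryNetwork", function(x) x@edges)

setMethod("show", "RegulatoryNetwork", function(object) {
  cat(sprintf("RegulatoryNetwork: %d kinase(s), %d site(s), %d weighted edge(s)\n",
              nrow(object@kinases), nrow(object@sites), nrow(object@edges)))
  invisible(NULL)
})
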