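#' @rdname PhosphoSiteTable-class
#' @param x a `PhosphoSiteTable`.
#' @export
setGeneric("siteData", function(x) standardGeneric("siteData"))

#' @rdname PhosphoSiteTable-class
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname KinaseProfile-class
#' @param x a `KinaseProfile`.
#' @export
setGeneric("kinaseName", function(x) standardGeneric("kinaseName"))

#' @rdname KinaseProfile-class
#' @export
setGeneric("substrateWindows", function(x) standardGeneric("substrateWindows"))

#' @rdname KinaseProfile-class
#' @export
setGeneric("scoreThreshold", function(x) standardGeneric("scoreThreshold"))

#' @rdname KinaseProfile-class
#' @export
setGeneric("isCalibrated", function(x) standardGeneric("isCalibrated"))

#' Query an undirected interaction set
#'
#' Membership is symmetric: if the pair (a, b) was read, `hasInteraction`
#' is `TRUE` for both (a, b) and (b, a). Vectorised over `a` and `b`.
#'
#' @param x a [PpiSet-class].
#' @param a,b protein identifiers.
#' @return logical vector.
#' @export
setGeneric("hasInteraction", function(x, a, b) standardGeneric("hasInteraction"))

#' @rdname hasInteraction
#' @export
setGeneric("nInteractions", function(x) standardGeneric("nInteractions"))

#' @rdname RegulatoryNetwork-class
#' @param x a `RegulatoryNetwork`.
#' @export
setGeneric("networkKinases", function(x) standardGeneric("networkKinases"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("networkSites", function(x) standardGeneric("networkSites"))

#' @rdname RegulatoryNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Convert a regulatory network to an igraph object
#'
#' @param x a [RegulatoryNetwork-class].
#' @return an `igraph` directed bipartite graph with node and edge
#'   attributes (kinase NES/direction, site log2 ratio/status, edge score).
#' @export
setGeneric("asIgraph", function(x) standardGeneric("asIgraph"))

#' @rdname GroundTruth-class
#' @param x a `GroundTruth`.
#' @export
setGeneric("truthSites", function(x) standardGeneric("truthSites"))

#' @rdname GroundTruth-class
#' @export
setGeneric("truthKinases", function(x) standardGeneric("truthKinases"))
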