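# Assembly of the weighted bipartite kinase-site regulatory network from
# classified kinase activities, predicted kinase-substrate edges and the
# differential site calls.

#' Build the kinase-site regulatory network
#'
#' Keeps kinases classified `positive` or `negative`, sites called `up` or
#' `down`, and a directed kinase-to-site edge (weighted by the prediction
#' score) wherever a predicted kinase-substrate relation connects two kept
#' nodes. Nodes left without an edge are dropped; the projection never
#' invents edges.
#'
#' @param activities data.frame from [classifyKinases()].
#' @param ksr_edges data.frame from [predictKsrs()]. Every edge must
#'   reference a kinase present in `activities` and a site present in
#'   `calls`; unknown references are an error listing the offenders.
#' @param calls data.frame from [callRegulation()].
#' @return a [RegulatoryNetwork-class].
#' @export
buildNetwork <- function(activities, ksr_edges, calls) {
  ek <- setdiff(unique(ksr_edges$kinase), activities$kinase)
  es <- setdiff(unique(siteKey(ksr_edges$protein, ksr_edges$position)),
                siteKey(calls$protein, calls$position))
  if (length(ek) || length(es)) {
    stop(sprintf("KSR edges reference unknown %s%s%s",
                 if (length(ek)) paste0("kinase(s): ",
                                        paste(ek, collapse = ", ")) else "",
                 if (length(ek) && length(es)) "; " else "",
                 if (length(es)) paste0("site(s): ",
                                        paste(utils::head(es, 10L),
                                              collapse = ", ")) else ""))
  }

  kin <- activities[activities$direction %in% c("positive", "negative"),
                    c("kinase", "nes", "direction"), drop = FALSE]
  kin$direction <- as.character(kin$direction)
  sit <- calls[calls$status %in% c("up", "down"),
               c("protein", "position", "residue", "log2_ratio", "status"),
               drop = FALSE]
  sit$status <- as.character(sit$status)

  e <- ksr_edges[ksr_edges$kinase %in% kin$kinase &
                 siteKey(ksr_edges$protein, ksr_edges$position) %in%
                   siteKey(sit$protein, sit$position),
                 c("kinase", "protein", "position", "residue", "score"),
                 drop = FALSE]

  kin <- kin[kin$kinase %in% e$kinase, , drop = FALSE]
  sit <- sit[siteKey(sit$protein, sit$position) %in%
               siteKey(e$protein, e$position), , drop = FALSE]
  rownames(kin) <- rownames(sit) <- rownames(e) <- NULL
  new("RegulatoryNetwork", kinases = kin, sites = sit, edges = e)
}

#' Direction-concordant kinases of a target site
#'
#' Kinases adjacent to the target site whose activity direction matches the
#' site's regulation status (positive with up, negative with down) are the
#' network's structural analogue of a positive kinase-site correlation; in
#' a pooled one-ratio design no per-sample correlation exists.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param protein,position identify the target site.
#' @return data.frame of adjacent kinases with columns `kinase`, `nes`,
#'   `direction`, `score`, `concordant`. Empty (with a warning) when the
#'   site is not in the network.
#' @export
correlateKinaseSite <- function(network, protein, position) {
  stopifnot(is(network, "RegulatoryNetwork"))
  key <- siteKey(protein, position)
  sit <- network@sites
  empty <- data.frame(kinase = character(0), nes = numeric(0),
                      direction = character(0), score = numeric(0),
                      concordant = logical(0), stringsAsFactors = FALSE)
  hit <- match(key, siteKey(sit$protein, sit$position))
  if (is.na(hit)) {
    warning(sprintf("site %s is not in the network", key))
    return(empty)
  }
  status <- sit$status[hit]
  e <- network@edges[siteKey(network@edges$protein,
                             network@edges$position) == key, , drop = FALSE]
  k <- network@kinases[match(e$kinase, network@kinases$kinase), , drop = FALSE]
  data.frame(kinase = k$kinase, nes = k$nes, direction = k$direction,
             score = e$score,
             concordant = (k$direction == "positive" & status == "up") |
                          (k$direction == "negative" & status == "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname asIgraph
#' @export
setMethod("asIgraph", "RegulatoryNetwork", function(x) {
  kin <- x@kinases; sit <- x@sites; e <- x@edges
  site_ids <- siteKey(sit$protein, sit$position)
  nodes <- data.frame(
    name = c(kin$kinase, site_ids),
    type = c(rep("kinase", nrow(kin)), rep("site", nrow(sit))),
    nes = c(kin$nes, rep(NA_real_, nrow(sit))),
    direction = c(kin$direction, rep(NA_character_, nrow(sit))),
    log2_ratio = c(rep(NA_real_, nrow(kin)), sit$log2_ratio),
    status = c(rep(NA_character_, nrow(kin)), sit$status),
    residue = c(rep(NA_character_, nrow(kin)), sit$residue),
    stringsAsFactors = FALSE)
  edges <- data.frame(from = e$kinase,
                      to = siteKey(e$protein, e$position),
                      weight = e$score, stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
})

#' Export a regulatory network
#'
#' `writeNetworkEdges` writes the flat weighted edge list (kinase, protein,
#' position, residue, score, kinase NES, site log2 ratio); `writeGraphML`
#' writes the full attributed bipartite graph.
#'
#' @param network a [RegulatoryNetwork-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeNetworkEdges <- function(network, path) {
  stopifnot(is(network, "RegulatoryNetwork"))
  e <- network@edges
  kin <- network@kinases; sit <- network@sites
  out <- data.frame(
    kinase = e$kinase, protein = e$protein, position = e$position,
    residue = e$residue, score = e$score,
    kinase_nes = kin$nes[match(e$kinase, kin$kinase)],
    site_log2ratio = sit$log2_ratio[match(siteKey(e$protein, e$position),
                                          siteKey(sit$protein, sit$position))],
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetworkEdges
#' @export
writeGraphML <- function(network, path) {
  g <- asIgraph(network)
  # igraph cannot serialise NA character attributes; blank them
  for (a in c("direction", "status", "residue")) {
    v <- igraph::vertex_attr(g, a)
    v[is.na(v)] <- ""
    g <- igraph::set_vertex_attr(g, a, value = v)
  }
  nes <- igraph::vertex_attr(g, "nes")
  nes[is.na(nes)] <- 0
  g <- igraph::set_vertex_attr(g, "nes", value = nes)
  lr <- igraph::vertex_attr(g, "log2_ratio")
  lr[is.na(lr)] <- 0
  g <- igraph::set_vertex_attr(g, "log2_ratio", value = lr)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
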