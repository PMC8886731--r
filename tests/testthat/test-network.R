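makeActivity <- function(kinase, nes, direction) {
  data.frame(kinase = kinase, nes = nes, p_nominal = 0.01, fdr_q = 0.05,
             n_substrates_in_rank = 10L, direction = direction,
             stringsAsFactors = FALSE)
}

makeEdges <- function(kinase, protein, position) {
  data.frame(kinase = kinase, protein = protein, position = position,
             residue = "S", window = NA_character_, score = 5,
             passed_ppi = TRUE, stringsAsFactors = FALSE)
}

makeCalls <- function(protein, position, status) {
  data.frame(protein = protein, gene = protein, position = position,
             residue = "S", window = NA_character_,
             ratio = ifelse(status == "up", 2, 0.5),
             log2_ratio = ifelse(status == "up", 1, -1),
             status = factor(status, levels = c("up", "down", "unchanged")),
             stringsAsFactors = FALSE)
}

test_that("network keeps significant kinases, regulated sites and their edges", {
  act <- makeActivity("K1", 2.0, "positive")
  edges <- makeEdges("K1", c("P1", "P2"), c(10L, 20L))
  calls <- makeCalls(c("P1", "P2"), c(10L, 20L), c("up", "up"))
  net <- buildNetwork(act, edges, calls)
  expect_equal(nrow(networkKinases(net)), 1L)
  expect_equal(nrow(networkSites(net)), 2L)
  expect_equal(nrow(networkEdges(net)), 2L)

  # a not_significant kinase disappears with all its edges
  act2 <- rbind(act, makeActivity("K2", 0.5, "not_significant"))
  edges2 <- rbind(edges, makeEdges("K2", "P1", 10L))
  net2 <- buildNetwork(act2, edges2, calls)
  expect_false("K2" %in% networkKinases(net2)$kinase)
  expect_equal(nrow(networkEdges(net2)), 2L)

  # unchanged sites and their edges disappear too, and isolated nodes drop
  calls3 <- makeCalls(c("P1", "P2"), c(10L, 20L), c("up", "unchanged"))
  net3 <- buildNetwork(act, edges, calls3)
  expect_equal(nrow(networkSites(net3)), 1L)
  expect_equal(nrow(networkEdges(net3)), 1L)

  # projection never invents edges
  key <- function(e) paste(e$kinase, e$protein, e$position)
  expect_true(all(key(networkEdges(net2)) %in% key(edges2)))
})

test_that("edges referencing unknown kinases or sites are an error", {
  act <- makeActivity("K1", 2.0, "positive")
  calls <- makeCalls("P1", 10L, "up")
  expect_error(buildNetwork(act, makeEdges("KX", "P1", 10L), calls), "KX")
  expect_error(buildNetwork(act, makeEdges("K1", "P9", 99L), calls), "P9_99")
})

test_that("kinase-site concordance reflects shared direction", {
  act <- rbind(makeActivity("K1", 2.0, "positive"),
               makeActivity("K2", -1.8, "negative"))
  edges <- rbind(makeEdges(c("K1", "K2"), c("P1", "P1"), c(10L, 10L)),
                 makeEdges("K2", "P2", 20L))
  calls <- makeCalls(c("P1", "P2"), c(10L, 20L), c("up", "down"))
  net <- buildNetwork(act, edges, calls)

  co <- correlateKinaseSite(net, "P1", 10L)
  expect_setequal(co$kinase, c("K1", "K2"))
  expect_true(co$concordant[co$kinase == "K1"])    # positive kinase, up site
  expect_false(co$concordant[co$kinase == "K2"])
  co2 <- correlateKinaseSite(net, "P2", 20L)
  expect_true(co2$concordant[co2$kinase == "K2"])  # negative kinase, down site

  expect_warning(none <- correlateKinaseSite(net, "P9", 1L), "not in")
  expect_equal(nrow(none), 0L)
})

test_that("the synthetic pipeline network contains the shifted kinases only", {
  hits <- logical(8)
  for (s in 1:8) {
    ds <- simulateDataset(simConfig(seed = 100 + s))
    sites <- suppressWarnings(filterSites(ds$sites))
    sdf <- siteData(sites)
    profs <- suppressWarnings(calibrateProfiles(
      ds$profiles, sdf$window[sdf$residue %in% c("S", "T")]))
    edges <- predictKsrs(sites, profs, ds$ppi)
    act <- classifyKinases(suppressWarnings(
      runGsea(rankSites(sites, "site"), ksrSubstrateSets(edges),
              n_perm = 500, seed = s)))
    net <- buildNetwork(act, edges, callRegulation(sites))
    hits[s] <- setequal(networkKinases(net)$kinase, c("KIN1", "KIN2"))
  }
  expect_gte(mean(hits), 0.875)   # 7 of 8 replicates
})

test_that("network exports are well-formed", {
  act <- makeActivity("K1", 2.0, "positive")
  edges <- makeEdges("K1", c("P1", "P2"), c(10L, 20L))
  calls <- makeCalls(c("P1", "P2"), c(10L, 20L), c("up", "up"))
  net <- buildNetwork(act, edges, calls)

  g <- asIgraph(net)
  expect_equal(igraph::vcount(g), 3L)
  expect_equal(igraph::ecount(g), 2L)
  expect_setequal(igraph::V(g)$type, c("kinase", "site"))

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeNetworkEdges(net, tsv)
  back <- read.delim(tsv)
  expect_equal(nrow(back), 2L)
  expect_equal(back$kinase_nes, c(2, 2))

  gml <- withr::local_tempfile(fileext = ".graphml")
  writeGraphML(net, gml)
  expect_true(any(grepl("graphml", readLines(gml, n = 3L))))
})
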