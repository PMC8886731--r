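blosum <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

test_that("self-similarity is the sum of diagonal substitution values", {
  w <- "ACDEFGSHIKLMN"
  prof <- KinaseProfile("K", w)
  chars <- strsplit(w, "")[[1]]
  expected <- sum(vapply(chars, function(a) blosum[a, a], 0))
  expect_equal(scoreSite(w, prof), expected)
})

test_that("padding contributes zero and profile scores average linearly", {
  set.seed(41)
  prof1 <- KinaseProfile("K", "AAAAAASAAAAAA")
  # all padding except the centre: only the centre pair scores
  expect_equal(scoreSite("______S______", prof1), blosum["S", "S"])

  w1 <- randomWindow("S"); w2 <- randomWindow("S"); q <- randomWindow("S")
  both <- KinaseProfile("K", c(w1, w2))
  expect_equal(scoreSite(q, both),
               mean(c(scoreSite(q, KinaseProfile("K", w1)),
                      scoreSite(q, KinaseProfile("K", w2)))))
  expect_error(scoreSite("AAAAAABAAAAAA", prof1), "invalid")
})

test_that("pairwise similarity is symmetric", {
  set.seed(42)
  for (i in 1:10) {
    v <- randomWindow("S"); w <- randomWindow("T")
    expect_equal(scoreSite(w, KinaseProfile("K", v)),
                 scoreSite(v, KinaseProfile("K", w)))
  }
})

test_that("threshold calibration hits the requested background quantile", {
  set.seed(43)
  prof <- KinaseProfile("K", randomWindow("S", 10))
  bg <- randomWindow("S", 100)
  scores <- scoreSite(bg, prof)

  expect_warning(pmax_ <- calibrateThreshold(prof, bg, fpr = 0), "recommended")
  expect_equal(scoreThreshold(pmax_), max(scores))
  pmin_ <- suppressWarnings(calibrateThreshold(prof, bg, fpr = 1))
  expect_equal(scoreThreshold(pmin_), min(scores))

  p06 <- suppressWarnings(calibrateThreshold(prof, bg, fpr = 0.06))
  # exactly ceiling(0.06 * 100) = 6 background windows score at or above
  expect_equal(sum(scores >= scoreThreshold(p06)), 6L)

  expect_error(calibrateThreshold(prof, character(0)), "empty")
})

test_that("held-out background FPR is close to the configured rate", {
  set.seed(44)
  cfg <- simConfig(seed = 44)
  ds <- simulateDataset(cfg)
  bg_all <- randomWindow("S", 1200)
  calib <- bg_all[1:600]; held <- bg_all[601:1200]
  prof <- calibrateThreshold(ds$profiles$KIN1, calib, fpr = 0.06)
  emp <- mean(scoreSite(held, prof) >= scoreThreshold(prof))
  ci <- 0.06 + c(-1, 1) * 1.96 * sqrt(0.06 * 0.94 / 600)
  expect_gt(emp, ci[1])
  expect_lt(emp, ci[2])
})

test_that("prediction recovers planted substrates and respects the PPI filter", {
  cfg <- simConfig(seed = 45)
  ds <- simulateDataset(cfg)
  sites <- suppressWarnings(filterSites(ds$sites))
  sdf <- siteData(sites)
  profs <- suppressWarnings(
    calibrateProfiles(ds$profiles, sdf$window[sdf$residue %in% c("S", "T")]))

  edges <- predictKsrs(sites, profs, ds$ppi, require_ppi = TRUE)
  truth <- truthSites(ds$truth)
  truth_key <- paste(truth$kinase, truth$protein, truth$position)
  edge_key <- paste(edges$kinase, edges$protein, edges$position)
  # planted substrates that survived the quality filter
  surviving <- truth_key[paste(truth$protein, truth$position) %in%
                           paste(sdf$protein, sdf$position)]
  expect_gt(mean(surviving %in% edge_key), 0.85)

  # sensitivity of planted windows against the calibrated threshold
  k1 <- truth[truth$kinase == "KIN1", ]
  sens <- mean(scoreSite(k1$window, profs$KIN1) >=
                 scoreThreshold(profs$KIN1))
  expect_gte(sens, 0.9)

  # non-substrate emission rate stays near the configured FPR
  bg_sites <- sdf[!(paste(sdf$protein, sdf$position) %in%
                      paste(truth$protein, truth$position)) &
                    sdf$residue %in% c("S", "T"), ]
  hit_rate <- mean(scoreSite(bg_sites$window, profs$KIN1) >=
                     scoreThreshold(profs$KIN1))
  expect_lte(hit_rate, 2 * 0.06)

  # removing the PPI requirement can only add edges
  edges_all <- predictKsrs(sites, profs, ds$ppi, require_ppi = FALSE)
  expect_true(all(edge_key %in%
                    paste(edges_all$kinase, edges_all$protein,
                          edges_all$position)))
  expect_gte(nrow(edges_all), nrow(edges))

  # with no interaction evidence at all, the filter removes everything
  # except autophosphorylation (impossible here)
  edges_none <- predictKsrs(sites, profs, PpiSet(), require_ppi = TRUE)
  expect_equal(nrow(edges_none), 0L)
})

test_that("prediction enforces calibration and residue compatibility", {
  set.seed(46)
  tblY <- makeSiteTable(ratio = rep(1.5, 5), residue = rep("Y", 5))
  prof <- KinaseProfile("KST", randomWindow("S", 5))   # S/T kinase
  expect_error(predictKsrs(tblY, list(prof), require_ppi = FALSE),
               "not calibrated")
  prof@threshold <- -1000   # accept anything it is allowed to score
  # an S/T kinase emits nothing on an all-tyrosine table
  expect_equal(nrow(predictKsrs(tblY, list(prof), require_ppi = FALSE)), 0L)
})
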