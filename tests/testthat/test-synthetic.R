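test_that("generation is deterministic given the config seed", {
  cfg <- simConfig(n_proteins = 20, seed = 123)
  p1 <- generateProteome(cfg)
  p2 <- generateProteome(cfg)
  expect_identical(as.character(p1), as.character(p2))

  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  writeProteome(p1, f1); writeProteome(p2, f2)
  expect_identical(readLines(f1), readLines(f2))   # byte-identical FASTA

  d1 <- simulateDataset(cfg)
  d2 <- simulateDataset(cfg)
  expect_identical(siteData(d1$sites), siteData(d2$sites))
  expect_identical(truthSites(d1$truth), truthSites(d2$truth))
})

test_that("proteome size, length range and composition follow the config", {
  cfg <- simConfig(n_proteins = 50, seed = 5)
  prot <- generateProteome(cfg)
  expect_length(prot, 50L)
  lens <- nchar(as.character(prot))
  expect_true(all(lens >= 200 & lens <= 600))

  # at 500 proteins the empirical residue frequencies track the background
  # table within 2 percentage points
  big <- generateProteome(simConfig(n_proteins = 500, seed = 6))
  tab <- table(strsplit(paste(as.character(big), collapse = ""), "")[[1]])
  freq <- as.numeric(tab[names(attr(big, "bg_freqs"))]) / sum(tab)
  expect_true(all(abs(freq - attr(big, "bg_freqs")) < 0.02))

  expect_error(simConfig(n_proteins = 0), "nProteins")
  expect_error(simConfig(residue_mix = c(S = 0.5, T = 0.4, Y = 0.2)),
               "sum to 1")
  expect_error(simConfig(active_kinases = "KIN1", inactive_kinases = "KIN1"),
               "disjoint")
})

test_that("planted kinases satisfy their consensus and the ground-truth contract", {
  cfg <- simConfig(n_kinases = 3, substrates_per_kinase = 20, seed = 8)
  planted <- plantKinases(generateProteome(cfg), cfg)
  truth <- truthSites(planted$truth)

  # 3 kinases x 20 substrates, each site owned by exactly one kinase
  expect_equal(nrow(truth), 60L)
  expect_equal(anyDuplicated(paste(truth$protein, truth$position)), 0L)

  # the proline-directed kinase carries P at +1 in every planted window
  k1 <- truth[truth$kinase == "KIN1", ]
  expect_true(all(substr(k1$window, 8, 8) == "P"))
  # and in every annotation window of its profile
  expect_true(all(substr(substrateWindows(planted$profiles$KIN1), 8, 8) == "P"))

  # windows recorded in the truth match the rewritten sequences
  seqs <- as.character(planted$proteome)
  for (i in sample(nrow(truth), 10)) {
    s <- unname(seqs[truth$protein[i]])
    expect_equal(substr(s, truth$position[i] - 6, truth$position[i] + 6),
                 truth$window[i])
  }

  # activity directions follow the config
  kd <- truthKinases(planted$truth)
  expect_equal(kd$direction[match(c("KIN1", "KIN2", "KIN3"), kd$kinase)],
               c("positive", "negative", "null"))

  expect_error(plantKinases(Biostrings::AAStringSet(character(0)), cfg),
               "empty")
})

test_that("simulated ratios track the planted shifts and the residue mix", {
  cfg <- simConfig(seed = 9)
  ds <- simulateDataset(cfg)
  sdf <- siteData(ds$sites)
  truth <- truthSites(ds$truth)

  key <- paste(sdf$protein, sdf$position)
  for (kin in c("KIN1", "KIN2")) {
    tk <- truth[truth$kinase == kin, ]
    l2 <- sdf$log2_ratio[match(paste(tk$protein, tk$position), key)]
    mu <- mean(l2)
    expected <- unique(tk$shift)
    tol <- 3 * sqrt(cfg@noiseSd^2 + cfg@baselineSd^2) / sqrt(length(l2))
    expect_lt(abs(mu - expected), tol * 1.5)
  }

  # all planted sites appear in the quantified table
  expect_true(all(paste(truth$protein, truth$position) %in% key))

  # localization probabilities and scores live in their supports
  expect_true(all(sdf$loc_prob > 0 & sdf$loc_prob <= 1))
  expect_true(all(sdf$score >= 0))

  # residue mix at ~5000 background sites within the exact binomial 99% CI
  big <- simulateDataset(simConfig(n_proteins = 2000, n_kinases = 1,
                                   substrates_per_kinase = 2, seed = 10))
  r <- siteData(big$sites)$residue
  n <- length(r)
  for (res in c("S", "T", "Y")) {
    p0 <- big$config@residueMix[[res]]
    lo <- qbinom(0.005, n, p0); hi <- qbinom(0.995, n, p0)
    expect_gte(sum(r == res), lo - 2)   # 2 planted sites may tilt S/T
    expect_lte(sum(r == res), hi + 2)
  }
})

test_that("a null configuration collapses to unit ratios", {
  cfg <- simConfig(n_proteins = 30, effect_size = 0, baseline_sd = 1e-9,
                   noise_sd = 1e-9, seed = 11)
  ds <- simulateDataset(cfg)
  expect_true(all(abs(siteData(ds$sites)$ratio - 1) < 1e-6))
})

test_that("the null up-call rate matches the log-normal tail probability", {
  cfg <- simConfig(n_proteins = 1500, n_kinases = 1, substrates_per_kinase = 2,
                   effect_size = 0, seed = 12)
  ds <- simulateDataset(cfg)
  calls <- callRegulation(ds$sites)    # unfiltered: pure null behaviour
  sigma <- sqrt(cfg@baselineSd^2 + cfg@noiseSd^2)
  p_up <- pnorm(log2(1.3), 0, sigma, lower.tail = FALSE)
  n <- nrow(calls)
  emp <- mean(calls$status == "up")
  expect_lt(abs(emp - p_up), 3 * sqrt(p_up * (1 - p_up) / n))
})

test_that("simulated PPI evidence covers every kinase-substrate pair", {
  ds <- simulateDataset(simConfig(seed = 13))
  truth <- truthSites(ds$truth)
  expect_true(all(hasInteraction(ds$ppi, truth$kinase, truth$protein)))
})
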