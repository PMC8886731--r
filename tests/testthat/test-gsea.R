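test_that("ranking is descending with deterministic lexicographic tie-breaks", {
  set.seed(51)
  tbl <- makeSiteTable(ratio = c(2, 0.5, 1.5), protein = c("A", "B", "C"))
  r <- rankSites(tbl, "site")
  expect_equal(names(r), c("A_10", "C_10", "B_10"))
  expect_true(all(diff(r) <= 0))

  # equal values resolve lexicographically
  tbl2 <- makeSiteTable(ratio = c(1.5, 1.5), protein = c("Z", "A"))
  expect_equal(names(rankSites(tbl2, "site")), c("A_10", "Z_10"))

  # protein level aggregates by the mean of its sites
  df <- makeSiteDf(ratio = c(2, 0.5), protein = c("P1", "P1"),
                   position = c(10L, 30L))
  r3 <- rankSites(PhosphoSiteTable(df), "protein")
  expect_equal(unname(r3["P1"]), 0)
})

test_that("enrichment score has the expected analytic behaviour", {
  set.seed(52)
  v <- sort(runif(20, -1, 2), decreasing = TRUE)
  names(v) <- sprintf("s%02d", 1:20)

  # single member at the very top, unweighted: running sum peaks at 1
  expect_equal(enrichmentScore(v, names(v)[1], weight_p = 0)$es, 1)
  # members at the very bottom: negative score
  expect_lt(enrichmentScore(v, names(v)[18:20], weight_p = 0)$es, 0)
  # degenerate sets are rejected
  expect_error(enrichmentScore(v, "nonmember"), "no member")
  expect_error(enrichmentScore(v, names(v)), "universe")
})

test_that("enrichment score matches the brute-force running sum on random instances", {
  set.seed(53)
  for (i in 1:1000) {
    N <- sample(5:50, 1)
    ids <- sprintf("g%03d", sample(1000, N))
    vals <- rnorm(N)
    p <- sample(c(0, 1), 1)
    member <- sample(ids, sample(1:(N - 1), 1))
    ranked <- setNames(vals, ids)
    ranked <- ranked[order(-ranked, names(ranked), method = "radix")]
    es <- enrichmentScore(ranked, member, weight_p = p)$es
    expectEsMatchesOracle(es, vals, ids, member, p)
    expect_gte(es, -1); expect_lte(es, 1)
  }
})

test_that("enrichment score agrees with the fgsea statistic", {
  set.seed(54)
  for (i in 1:20) {
    N <- 40
    ranked <- sort(setNames(rnorm(N), sprintf("g%02d", 1:N)),
                   decreasing = TRUE)
    member <- sample(names(ranked), 8)
    mine <- enrichmentScore(ranked, member, weight_p = 1)$es
    ref <- fgsea::calcGseaStat(ranked,
                               selectedStats = which(names(ranked) %in% member),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("reversing the ranked list negates the unweighted score", {
  set.seed(55)
  for (i in 1:20) {
    N <- 30
    ranked <- sort(setNames(rnorm(N), sprintf("g%02d", 1:N)),
                   decreasing = TRUE)
    member <- sample(names(ranked), 6)
    fwd <- enrichmentScore(ranked, member, weight_p = 0)$es
    rev_ <- enrichmentScore(rev(ranked), member, weight_p = 0)$es
    expect_equal(rev_, -fwd, tolerance = 1e-12)
  }
})

test_that("permutation results are deterministic and scale-invariant", {
  set.seed(56)
  ranked <- sort(setNames(rnorm(60), sprintf("g%02d", 1:60)),
                 decreasing = TRUE)
  sets <- list(a = names(ranked)[c(1, 3, 5, 8, 13)],
               b = sample(names(ranked), 10))
  r1 <- runGsea(ranked, sets, n_perm = 200, seed = 99)
  r2 <- runGsea(ranked, sets, n_perm = 200, seed = 99)
  expect_equal(r1$nes, r2$nes)
  expect_equal(r1$p_nominal, r2$p_nominal)

  # positive rescaling leaves the unweighted score and memberships alone
  e1 <- enrichmentScore(ranked, sets$a, weight_p = 0)$es
  e2 <- enrichmentScore(ranked * 7, sets$a, weight_p = 0)$es
  expect_equal(e1, e2)

  # undersized sets are skipped with a warning
  expect_warning(
    small <- runGsea(ranked, c(sets, list(tiny = names(ranked)[1])),
                     n_perm = 100, seed = 1),
    "size bounds")
  expect_false("tiny" %in% small$set)
})

test_that("a planted active substrate set gets positive significant enrichment", {
  ds <- simulateDataset(simConfig(seed = 57))
  sites <- suppressWarnings(filterSites(ds$sites))
  ranked <- rankSites(sites, "site")
  truth <- truthSites(ds$truth)
  k1 <- truth[truth$kinase == "KIN1", ]
  set1 <- paste(k1$protein, k1$position, sep = "_")
  res <- suppressWarnings(
    runGsea(ranked, list(KIN1 = set1), n_perm = 1000, seed = 57))
  expect_gt(res$nes, 0)
  expect_lt(res$p_nominal, 0.05)
  # leading edge is drawn from the set
  expect_true(all(res$leading_edge[[1]] %in% set1))
})

test_that("kinase classification follows NES sign and significance", {
  res <- data.frame(set = c("a", "b", "c"), n_hits = c(10L, 10L, 10L),
                    es = c(0.5, -0.4, 0.3), nes = c(2.1, -1.8, 1.5),
                    p_nominal = c(0.002, 0.01, 0.2),
                    fdr_q = c(0.01, 0.03, 0.4))
  act <- classifyKinases(res)
  expect_equal(as.character(act$direction),
               c("positive", "negative", "not_significant"))
})

test_that("over-representation p-values equal exact hypergeometric tails", {
  # universe 10, set 4, hits 5, overlap 4
  uni <- letters[1:10]
  res <- runOra(hits = letters[c(1:4, 10)], universe = uni,
                sets = list(s = letters[1:4]))
  expect_equal(res$overlap, 4L)
  expect_equal(res$p, enumHyperTail(4, 4, 10, 5), tolerance = 1e-12)

  # disjoint set: overlap 0, tail P(X >= 0) = 1
  res0 <- runOra(letters[1:3], uni, list(s = letters[8:10]))
  expect_equal(res0$overlap, 0L)
  expect_equal(res0$p, 1)

  # hits = universe: every set fully overlaps with p = 1
  resA <- runOra(uni, uni, list(s = letters[2:5]))
  expect_equal(resA$overlap, 4L)
  expect_equal(resA$p, 1)

  expect_error(runOra(c("a", "zz"), uni, list(s = letters[1:3])),
               "not in the universe")
})
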