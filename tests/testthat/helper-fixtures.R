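# Fixture builders shared across test files. Everything is generated in
# code; no binary fixtures.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# random 13-mer centred on `centre`
randomWindow <- function(centre = "S", n = 1L) {
  vapply(seq_len(n), function(i) {
    w <- sample(AA20_T, 13L, replace = TRUE)
    w[7L] <- centre
    paste(w, collapse = "")
  }, "")
}

# minimal valid site data.frame
makeSiteDf <- function(ratio, protein = sprintf("P%03d", seq_along(ratio)),
                       position = rep(10L, length(ratio)),
                       residue = rep("S", length(ratio)),
                       loc_prob = rep(0.99, length(ratio)),
                       score = rep(100, length(ratio))) {
  window <- vapply(residue, function(r) randomWindow(r), "")
  data.frame(protein = protein, gene = protein, position = position,
             residue = residue, window = window, loc_prob = loc_prob,
             score = score, ratio = ratio, stringsAsFactors = FALSE)
}

makeSiteTable <- function(...) PhosphoSiteTable(makeSiteDf(...))

# write a site table TSV with MaxQuant-style headers from raw fields
writeSiteTsv <- function(df, path) {
  out <- data.frame(df$protein, df$gene, df$position, df$residue,
                    df$window, df$loc_prob, df$score, df$ratio,
                    check.names = FALSE)
  names(out) <- c("Protein", "Gene", "Position", "Amino acid",
                  "Sequence window", "Localization prob", "Score", "Ratio")
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# independent brute-force running-sum oracle: materialises the running sum
# explicitly, step by step, with its own bookkeeping.
bruteForceEs <- function(values, ids, member_ids, p = 1) {
  ord <- order(-values, ids, method = "radix")
  values <- values[ord]; ids <- ids[ord]
  in_set <- ids %in% member_ids
  nh <- sum(in_set); N <- length(ids)
  denom_hit <- sum(abs(values[in_set])^p)
  running <- numeric(N)
  cur <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) {
      cur <- cur + (if (denom_hit > 0) abs(values[i])^p / denom_hit
                    else 1 / nh)
    } else {
      cur <- cur - 1 / (N - nh)
    }
    running[i] <- cur
  }
  hi <- -Inf; lo <- Inf
  for (i in seq_len(N)) {
    if (running[i] > hi) hi <- running[i]
    if (running[i] < lo) lo <- running[i]
  }
  list(es = if (hi > -lo) hi else lo, max_dev = hi, min_dev = lo)
}

# compare an enrichment score against the brute-force oracle; when the
# positive and negative extrema tie (no canonical sign), compare magnitudes
expectEsMatchesOracle <- function(es, values, ids, member_ids, p) {
  bf <- bruteForceEs(values, ids, member_ids, p)
  if (abs(bf$max_dev + bf$min_dev) < 1e-9) {
    testthat::expect_equal(abs(es), abs(bf$es), tolerance = 1e-12)
  } else {
    testthat::expect_equal(es, bf$es, tolerance = 1e-12)
  }
}

# exact hypergeometric upper tail by direct enumeration of the pmf
enumHyperTail <- function(k, m, N, n) {
  js <- k:min(m, n)
  sum(vapply(js, function(j) {
    choose(m, j) * choose(N - m, n - j) / choose(N, n)
  }, 0))
}
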