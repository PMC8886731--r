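# Weighted running-sum enrichment with permutation-based NES and FDR.
# Used for kinase activity inference (substrate sets over the ranked
# phosphosites) and for pathway-style GSEA over user-supplied GMT
# collections. The null is a set-membership permutation: random same-size
# item sets drawn from the ranked universe, the appropriate scheme for a
# pooled design with a single ratio per site and no replicate columns.

#' Rank sites (or proteins) by log2 ratio
#'
#' Builds the ranked list for enrichment analysis: at site level, items are
#' `protein_position` keys valued by the site log2 ratio; at protein
#' level, the mean log2 ratio across each protein's sites. Ordering is
#' descending by value with deterministic lexicographic tie-breaking on the
#' item identifier.
#'
#' @param x a [PhosphoSiteTable-class].
#' @param level `"site"` or `"protein"`.
#' @return named numeric vector sorted in ranking order.
#' @export
rankSites <- function(x, level = c("site", "protein")) {
  stopifnot(is(x, "PhosphoSiteTable"))
  level <- match.arg(level)
  s <- x@sites
  v <- if (level == "site") {
    stats::setNames(s$log2_ratio, siteKey(s$protein, s$position))
  } else {
    agg <- tapply(s$log2_ratio, s$protein, mean)
    stats::setNames(as.numeric(agg), names(agg))
  }
  v[order(-v, names(v), method = "radix")]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list top to bottom; set members ("hits") increment the
#' running sum by `|value|^weight_p` normalised by the summed hit weights,
#' non-members decrement by `1/(N - Nh)`. The enrichment score is the
#' running sum's maximum deviation from zero, keeping its sign.
#'
#' @param ranked named numeric vector from [rankSites()] (descending).
#' @param set character vector of member item identifiers.
#' @param weight_p rank-value weighting exponent; 1 is the classic
#'   weighted statistic, 0 gives the unweighted Kolmogorov-Smirnov form.
#' @return list with `es` (in `[-1, 1]`), the full `running` sum, `n_hits`,
#'   and `leading_edge` (set members up to / from the extremum).
#' @export
enrichmentScore <- function(ranked, set, weight_p = 1) {
  stopifnot(is.numeric(ranked), !is.null(names(ranked)))
  N <- length(ranked)
  hit <- names(ranked) %in% set
  nh <- sum(hit)
  if (nh == 0L) stop("set has no member in the ranked list")
  if (nh == N) stop("set equals the ranked universe; enrichment undefined")
  w <- abs(ranked)^weight_p
  wh <- sum(w[hit])
  step <- numeric(N)
  step[hit] <- if (wh > 0) w[hit] / wh else 1 / nh
  step[!hit] <- -1 / (N - nh)
  running <- cumsum(step)
  maxP <- max(running); minP <- min(running)
  # on an exact tie between the positive and negative extremum the
  # negative deviation wins (the fgsea convention)
  es <- if (maxP > -minP) maxP else minP
  i <- if (es >= 0) which.max(running) else which.min(running)
  le <- if (es >= 0) names(ranked)[seq_len(i)][hit[seq_len(i)]]
        else names(ranked)[i:N][hit[i:N]]
  list(es = es, running = running, n_hits = nh, leading_edge = le)
}

# null |ES| statistics for one set size: matrix not kept, returns the
# signed null ES vector of length n_perm.
.nullEs <- function(ranked, size, n_perm, weight_p) {
  N <- length(ranked)
  ids <- names(ranked)
  vapply(seq_len(n_perm), function(i) {
    enrichmentScore(ranked, ids[sample.int(N, size)], weight_p)$es
  }, 0)
}

#' Permutation-based enrichment over a set collection
#'
#' Computes the weighted enrichment score of every set, a set-membership
#' permutation null (random same-size sets from the ranked universe; the
#' null for one size is shared by all sets of that size), a one-sided
#' continuity-corrected nominal p-value among same-sign null scores,
#' `NES = ES / mean(|null ES of the same sign|)`, and FDR q-values from the
#' pooled normalised null NES distribution with the positive and negative
#' sides handled separately.
#'
#' @param ranked named numeric vector from [rankSites()].
#' @param sets named list of character member vectors (e.g. [readGmt()] or
#'   [ksrSubstrateSets()] output).
#' @param n_perm number of permutations (default 1000; a warning is issued
#'   below 100).
#' @param weight_p rank weighting exponent (see [enrichmentScore()]).
#' @param seed integer seed; required, the permutations are deterministic
#'   given it.
#' @param min_set_size,max_set_size sets with an in-universe overlap
#'   outside these bounds are skipped with a warning.
#' @return data.frame with one row per analysed set: `set`, `n_hits`,
#'   `es`, `nes`, `p_nominal`, `fdr_q`, and a `leading_edge` list column.
#' @export
runGsea <- function(ranked, sets, n_perm = 1000, weight_p = 1, seed,
                    min_set_size = 3, max_set_size = 500) {
  if (missing(seed)) stop("a seed is required for reproducible permutations")
  if (n_perm < 100) warning("n_perm < 100 gives unstable p-values")
  stopifnot(length(sets) >= 1L, !is.null(names(sets)))

  sizes <- vapply(sets, function(s) sum(names(ranked) %in% s), 0L)
  keep <- sizes >= min_set_size & sizes <= max_set_size
  if (any(!keep)) {
    warning(sprintf("skipping %d set(s) outside size bounds [%d, %d]: %s",
                    sum(!keep), min_set_size, max_set_size,
                    paste(utils::head(names(sets)[!keep], 5L), collapse = ", ")))
  }
  sets <- sets[keep]; sizes <- sizes[keep]
  if (length(sets) == 0L) stop("no set within the size bounds")

  obs <- lapply(sets, enrichmentScore, ranked = ranked, weight_p = weight_p)
  es <- vapply(obs, `[[`, 0, "es")

  nulls <- localSeed(seed, {
    us <- sort(unique(sizes))
    stats::setNames(lapply(us, .nullEs, ranked = ranked, n_perm = n_perm,
                           weight_p = weight_p), as.character(us))
  })

  p <- nes <- numeric(length(sets))
  pooled_null_nes <- numeric(0)
  for (i in seq_along(sets)) {
    nl <- nulls[[as.character(sizes[i])]]
    if (es[i] == 0) { p[i] <- 1; nes[i] <- 0; next }
    same <- nl[sign(nl) == sign(es[i])]
    p[i] <- (sum(abs(same) >= abs(es[i])) + 1) / (length(same) + 1)
    m <- mean(abs(same))
    nes[i] <- if (length(same) && m > 0) es[i] / m else NA_real_
  }
  # pooled normalised null NES (each size's null normalised by its own
  # same-sign mean), the reference distribution for FDR
  for (nl in nulls) {
    mp <- mean(nl[nl > 0]); mn <- mean(abs(nl[nl < 0]))
    nn <- c(if (is.finite(mp) && mp > 0) nl[nl > 0] / mp,
            if (is.finite(mn) && mn > 0) nl[nl < 0] / mn)
    pooled_null_nes <- c(pooled_null_nes, nn)
  }

  q <- vapply(seq_along(sets), function(i) {
    if (is.na(nes[i]) || nes[i] == 0) return(1)
    if (nes[i] > 0) {
      d_null <- sum(pooled_null_nes > 0)
      f_null <- if (d_null) sum(pooled_null_nes >= nes[i]) / d_null else 0
      d_obs <- sum(nes > 0, na.rm = TRUE)
      f_obs <- sum(nes >= nes[i], na.rm = TRUE) / d_obs
    } else {
      d_null <- sum(pooled_null_nes < 0)
      f_null <- if (d_null) sum(pooled_null_nes <= nes[i]) / d_null else 0
      d_obs <- sum(nes < 0, na.rm = TRUE)
      f_obs <- sum(nes <= nes[i], na.rm = TRUE) / d_obs
    }
    min(1, f_null / f_obs)
  }, 0)

  out <- data.frame(set = names(sets),
                    n_hits = vapply(obs, `[[`, 0L, "n_hits"),
                    es = es, nes = nes, p_nominal = p, fdr_q = q,
                    stringsAsFactors = FALSE)
  out$leading_edge <- lapply(obs, `[[`, "leading_edge")
  rownames(out) <- NULL
  out
}

#' Classify kinase activities from enrichment results
#'
#' The normalized enrichment score of a kinase's substrate set over the
#' ranked sites is its activity score: a kinase is called `positive` when
#' its substrates are predominantly more phosphorylated (NES > 0, nominal
#' p below the cutoff), `negative` in the opposite case, and
#' `not_significant` otherwise.
#'
#' @param results data.frame from [runGsea()] run on kinase substrate sets.
#' @param p_cutoff nominal p-value cutoff (default 0.05).
#' @return data.frame: `kinase`, `nes`, `p_nominal`, `fdr_q`,
#'   `n_substrates_in_rank`, `direction`.
#' @export
classifyKinases <- function(results, p_cutoff = 0.05) {
  direction <- rep("not_significant", nrow(results))
  direction[results$nes > 0 & results$p_nominal < p_cutoff] <- "positive"
  direction[results$nes < 0 & results$p_nominal < p_cutoff] <- "negative"
  data.frame(kinase = results$set, nes = results$nes,
             p_nominal = results$p_nominal, fdr_q = results$fdr_q,
             n_substrates_in_rank = results$n_hits,
             direction = factor(direction,
                                levels = c("positive", "negative",
                                           "not_significant")),
             stringsAsFactors = FALSE)
}

#' Over-representation analysis (hypergeometric)
#'
#' One-sided hypergeometric upper-tail test `P(X >= overlap)` of a hit
#' list against each annotated set, with Benjamini-Hochberg correction
#' across sets. Set members outside the universe are ignored.
#'
#' @param hits character vector of hit items; must be a subset of
#'   `universe`.
#' @param universe character vector of all testable items.
#' @param sets named list of character member vectors.
#' @return data.frame: `set`, `set_size` (in-universe), `overlap`, `fold`
#'   (observed/expected overlap), `p`, `q`.
#' @export
runOra <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  outside <- setdiff(hits, universe)
  if (length(outside)) {
    stop(sprintf("hit(s) not in the universe: %s",
                 paste(utils::head(outside, 5L), collapse = ", ")))
  }
  N <- length(universe); n <- length(hits)
  rows <- lapply(names(sets), function(nm) {
    m <- length(intersect(sets[[nm]], universe))
    k <- length(intersect(sets[[nm]], hits))
    p <- if (m == 0L) 1 else
      stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
    fold <- if (m == 0L || n == 0L) NA_real_ else (k / n) / (m / N)
    data.frame(set = nm, set_size = m, overlap = k, fold = fold, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Write a ranked list as a two-column RNK TSV
#'
#' @param ranked named numeric vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeRnk <- function(ranked, path) {
  utils::write.table(data.frame(item = names(ranked), score = ranked),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column RNK TSV into a ranked list
#'
#' @param path TSV with header and columns item, score.
#' @return named numeric vector sorted descending with lexicographic
#'   tie-breaking.
#' @export
readRnk <- function(path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("RNK file must have two columns (item, score)")
  if (anyDuplicated(d[[1L]])) stop("duplicate item identifiers in RNK file")
  v <- stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
  v[order(-v, names(v), method = "radix")]
}
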