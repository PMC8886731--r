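# Position-specific residue enrichment around phosphosites: foreground
# windows (e.g. upregulated sites) against background windows sharing the
# same central residue, over the 12 flanking positions -6..+6.

.MOTIF_POSITIONS <- c(-6:-1, 1:6)

# position x amino-acid count matrix for a set of 13-mer windows;
# padding '_' is not counted.
.positionCounts <- function(windows) {
  m <- windowMatrix(windows)
  counts <- matrix(0L, nrow = 12L, ncol = 20L,
                   dimnames = list(as.character(.MOTIF_POSITIONS), AA20))
  cols <- c(1:6, 8:13)
  for (i in seq_len(12L)) {
    tab <- table(factor(m[, cols[i]], levels = AA20))
    counts[i, ] <- as.integer(tab)
  }
  counts
}

#' Build a position-specific motif enrichment profile
#'
#' For each flanking position (-6..+6, excluding the centre) and each of
#' the 20 amino acids, compares the foreground residue frequency with the
#' background frequency: log2 enrichment `log2((f/F)/(b/B))` with a 0.5
#' pseudocount on all four counts, and a one-sided binomial enrichment test
#' of `f` successes in `F` trials at success probability `b/B` (padding
#' excluded from both counts and totals). P-values are
#' Benjamini-Hochberg-adjusted across all tested cells.
#'
#' @param foreground,background character vectors of 13-mer windows, all
#'   centred on `central_residue`.
#' @param central_residue the shared central residue (S, T or Y).
#' @return a [MotifProfile-class].
#' @export
buildMotifProfile <- function(foreground, background,
                              central_residue = c("S", "T", "Y")) {
  central_residue <- match.arg(central_residue)
  checkCentre <- function(w, what) {
    if (length(w) == 0L) stop(sprintf("empty %s window set", what))
    centre <- substr(w, 7L, 7L)
    if (!all(centre == central_residue)) {
      stop(sprintf("%s window(s) not centred on %s (rows: %s)", what,
                   central_residue,
                   paste(utils::head(which(centre != central_residue), 5L),
                         collapse = ", ")))
    }
  }
  checkCentre(foreground, "foreground")
  checkCentre(background, "background")
  if (length(foreground) < 10L) {
    warning(sprintf("only %d foreground window(s); motif estimates will be unstable",
                    length(foreground)))
  }

  fg <- .positionCounts(foreground)
  bg <- .positionCounts(background)
  Ff <- rowSums(fg)   # per-position foreground totals (padding excluded)
  Bb <- rowSums(bg)

  enr <- p <- matrix(NA_real_, 12L, 20L, dimnames = dimnames(fg))
  for (i in seq_len(12L)) {
    if (Bb[i] == 0L) next   # enrichment undefined without background
    p0 <- bg[i, ] / Bb[i]
    enr[i, ] <- log2(((fg[i, ] + 0.5) / (Ff[i] + 0.5)) /
                     ((bg[i, ] + 0.5) / (Bb[i] + 0.5)))
    if (Ff[i] > 0L) {
      # one-sided upper tail: P(X >= f), X ~ Binomial(F, b/B)
      p[i, ] <- stats::pbinom(fg[i, ] - 1L, Ff[i], p0, lower.tail = FALSE)
    }
  }
  q <- matrix(NA_real_, 12L, 20L, dimnames = dimnames(fg))
  tested <- is.finite(p)
  q[tested] <- stats::p.adjust(p[tested], method = "BH")

  new("MotifProfile", central = central_residue, fgCounts = fg,
      bgCounts = bg, enrichment = enr, pValues = p, qValues = q,
      nForeground = length(foreground), nBackground = length(background))
}

#' Significant motif cells
#'
#' Extracts (position, residue) cells passing the significance and effect
#' cutoffs, sorted by q-value then decreasing enrichment. An empty result
#' is valid.
#'
#' @param profile a [MotifProfile-class].
#' @param q_cutoff maximum BH q-value (default 0.05).
#' @param min_log2 minimum log2 enrichment (default 1, i.e. two-fold).
#' @return data.frame with columns `position`, `residue`, `enrichment`,
#'   `p`, `q`.
#' @export
summarizeMotifs <- function(profile, q_cutoff = 0.05, min_log2 = 1.0) {
  stopifnot(is(profile, "MotifProfile"))
  q <- profile@qValues; enr <- profile@enrichment
  keep <- which(is.finite(q) & q <= q_cutoff & enr >= min_log2,
                arr.ind = TRUE)
  out <- data.frame(position = as.integer(rownames(q)[keep[, 1L]]),
                    residue = colnames(q)[keep[, 2L]],
                    enrichment = enr[keep], p = profile@pValues[keep],
                    q = q[keep], stringsAsFactors = FALSE)
  out[order(out$q, -out$enrichment), , drop = FALSE]
}

#' Position frequency matrix of a window set
#'
#' Per-position relative residue frequencies (padding excluded), the input
#' expected by sequence-logo tools.
#'
#' @param windows character vector of 13-mer windows.
#' @return 12 x 20 matrix of frequencies; rows are flanking positions.
#' @export
positionFrequencyMatrix <- function(windows) {
  counts <- .positionCounts(windows)
  sweep(counts, 1L, pmax(rowSums(counts), 1L), "/")
}

#' Write a motif profile's matrices as TSV
#'
#' Writes the enrichment, p-value and q-value matrices with a `position`
#' column.
#'
#' @param profile a [MotifProfile-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMotifProfile <- function(profile, path) {
  stopifnot(is(profile, "MotifProfile"))
  asDf <- function(m, what) {
    cbind(data.frame(matrix_ = what, position = rownames(m)),
          as.data.frame(m))
  }
  out <- rbind(asDf(profile@enrichment, "log2_enrichment"),
               asDf(profile@pValues, "p_value"),
               asDf(profile@qValues, "q_value"))
  names(out)[1L] <- "matrix"
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
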