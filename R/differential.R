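# Differential phosphosite calling by fold-change thresholds, and the
# residue / per-protein constitution summaries with the Pearson chi-squared
# comparison between up- and down-regulated groups.

#' Call up/down-regulated phosphosites
#'
#' Classifies each site by its disease/control ratio using strict
#' fold-change thresholds: `up` when `ratio > up_threshold`, `down` when
#' `ratio < down_threshold`, otherwise `unchanged`. Boundary values are
#' `unchanged` (both inequalities are strict).
#'
#' @param x a [PhosphoSiteTable-class].
#' @param up_threshold upper ratio threshold (default 1.3).
#' @param down_threshold lower ratio threshold (default 0.77); must be
#'   smaller than `up_threshold`.
#' @return data.frame with one row per site: `protein`, `gene`, `position`,
#'   `residue`, `window`, `ratio`, `log2_ratio` and `status` (factor with
#'   levels up/down/unchanged). Every site receives exactly one status.
#' @export
callRegulation <- function(x, up_threshold = 1.3, down_threshold = 0.77) {
  stopifnot(is(x, "PhosphoSiteTable"))
  if (!(down_threshold < up_threshold)) {
    stop("down_threshold must be smaller than up_threshold")
  }
  s <- x@sites
  status <- rep("unchanged", nrow(s))
  status[s$ratio > up_threshold] <- "up"
  status[s$ratio < down_threshold] <- "down"
  data.frame(protein = s$protein, gene = s$gene, position = s$position,
             residue = s$residue, window = s$window, ratio = s$ratio,
             log2_ratio = s$log2_ratio,
             status = factor(status, levels = c("up", "down", "unchanged")),
             stringsAsFactors = FALSE)
}

#' Residue composition of regulated sites
#'
#' Counts regulated sites per central residue (S, T, Y) and reports
#' nearest-integer percentages, the breakdown shown in phosphoproteome
#' profiling pie charts.
#'
#' @param calls data.frame from [callRegulation()].
#' @param status which regulation status to summarise (`"up"` or `"down"`).
#' @return data.frame with columns `residue`, `count`, `percent` (integer,
#'   `round(100 * count / total)`) and the `total` attribute; counts sum to
#'   the number of sites with the requested status.
#' @export
residueBreakdown <- function(calls, status = c("up", "down")) {
  status <- match.arg(status)
  sel <- calls[calls$status == status, , drop = FALSE]
  counts <- table(factor(sel$residue, levels = c("S", "T", "Y")))
  total <- sum(counts)
  if (total == 0L) {
    warning(sprintf("no site with status '%s'; empty breakdown", status))
    pct <- rep(NA_integer_, 3L)
  } else {
    pct <- as.integer(round(100 * as.numeric(counts) / total))
  }
  out <- data.frame(residue = c("S", "T", "Y"),
                    count = as.integer(counts),
                    percent = pct, stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Per-protein regulated-site multiplicity (constitution row)
#'
#' Bins proteins having at least one regulated site of the requested status
#' by how many such sites they carry: exactly 1, exactly 2, or 3 and more.
#' A protein with sites of both statuses contributes to both rows.
#'
#' @inheritParams residueBreakdown
#' @return data.frame with columns `bin` (`"1"`, `"2"`, `">=3"`), `count`
#'   and `fraction` (fractions sum to 1 when any protein qualifies).
#' @export
sitesPerProtein <- function(calls, status = c("up", "down")) {
  status <- match.arg(status)
  sel <- calls[calls$status == status, , drop = FALSE]
  mult <- table(sel$protein)
  counts <- c(`1` = sum(mult == 1L), `2` = sum(mult == 2L),
              `>=3` = sum(mult >= 3L))
  total <- sum(counts)
  if (total == 0L) {
    warning(sprintf("no protein with a '%s' site; empty constitution row",
                    status))
  }
  data.frame(bin = names(counts), count = as.integer(counts),
             fraction = if (total > 0) as.numeric(counts) / total
                        else rep(NA_real_, 3L),
             stringsAsFactors = FALSE)
}

#' Pearson chi-squared comparison of constitution rows
#'
#' Compares the up- and down-regulated per-protein multiplicity
#' distributions (bins 1 / 2 / >=3) on the 2 x 3 contingency table with
#' Pearson's chi-squared statistic `sum((O - E)^2 / E)`, two degrees of
#' freedom, no continuity correction. Cells in an empty bin (zero column
#' margin) contribute 0, their limiting value; a zero row margin is an
#' error (merge bins or supply counts for both statuses).
#'
#' @param up_row,down_row constitution rows from [sitesPerProtein()], or
#'   bare length-3 count vectors.
#' @return list with `statistic`, `df` (always 2) and `p.value`.
#' @export
chi2Constitution <- function(up_row, down_row) {
  getCounts <- function(r) {
    if (is.data.frame(r)) r <- r$count
    as.numeric(r)
  }
  up <- getCounts(up_row); down <- getCounts(down_row)
  if (length(up) != 3L || length(down) != 3L) {
    stop("constitution rows must have the 3 bins (1 / 2 / >=3)")
  }
  tab <- rbind(up, down)
  if (sum(tab) <= 0) stop("total count must be positive")
  if (any(rowSums(tab) == 0)) {
    stop("a status row has total 0, so expected cells are 0; merge bins or supply both statuses")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  dev <- (tab - expected)^2
  stat <- sum(ifelse(expected > 0, dev / expected, 0))
  list(statistic = stat, df = 2L,
       p.value = stats::pchisq(stat, df = 2L, lower.tail = FALSE))
}
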