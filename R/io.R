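# Readers and writers for the standard inputs: MaxQuant-style phosphosite
# tables, FASTA proteomes, GMT set collections, PPI edge lists and kinase
# substrate annotations. All tabular formats are tab-separated with a header
# row, UTF-8.

.SITE_TSV_COLS <- c(protein = "Protein", gene = "Gene", position = "Position",
                    residue = "Amino acid", window = "Sequence window",
                    loc_prob = "Localization prob", score = "Score",
                    ratio = "Ratio")

#' Read a phosphosite quantification table
#'
#' Reads a tab-separated site table with the minimal MaxQuant
#' `Phospho (STY)Sites.txt`-style columns (`Protein`, `Gene`, `Position`,
#' `Amino acid`, `Sequence window`, `Localization prob`, `Score`, `Ratio`)
#' and applies the search-quality filters: the modified-peptide score filter
#' is strict (`score > min_score`) and the localization-probability filter
#' keeps class-I sites (`loc_prob >= min_loc_prob`). Malformed rows are
#' dropped with row-level diagnostics; duplicate (protein, position) rows
#' are collapsed keeping the highest localization probability.
#'
#' @param path path to the TSV file. `Gene` is the only optional column.
#' @param min_score minimum search-engine score, exclusive (default 40).
#' @param min_loc_prob minimum localization probability, inclusive
#'   (default 0.75, the class-I convention).
#' @return A [PhosphoSiteTable-class]. If no record survives filtering an
#'   empty table is returned with a warning (not an error).
#' @export
readSiteTable <- function(path, min_score = 40, min_loc_prob = 0.75) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  required <- .SITE_TSV_COLS[setdiff(names(.SITE_TSV_COLS), "gene")]
  missing_cols <- setdiff(unname(required), names(raw))
  if (length(missing_cols)) {
    stop(sprintf("site table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  d <- data.frame(protein = as.character(raw[["Protein"]]),
                  gene = if ("Gene" %in% names(raw))
                    as.character(raw[["Gene"]]) else as.character(raw[["Protein"]]),
                  position = suppressWarnings(as.integer(raw[["Position"]])),
                  residue = as.character(raw[["Amino acid"]]),
                  window = as.character(raw[["Sequence window"]]),
                  loc_prob = suppressWarnings(as.numeric(raw[["Localization prob"]])),
                  score = suppressWarnings(as.numeric(raw[["Score"]])),
                  ratio = suppressWarnings(as.numeric(raw[["Ratio"]])),
                  stringsAsFactors = FALSE)

  bad <- is.na(d$position) | is.na(d$loc_prob) | is.na(d$score) |
    is.na(d$ratio) | d$ratio <= 0 |
    !(d$residue %in% c("S", "T", "Y")) | nchar(d$window) != 13L |
    substr(d$window, 7L, 7L) != d$residue |
    d$loc_prob < 0 | d$loc_prob > 1 | d$score < 0
  if (any(bad)) {
    warning(sprintf("dropped %d malformed row(s): %s", sum(bad),
                    paste(utils::head(which(bad), 10L), collapse = ", ")))
    d <- d[!bad, , drop = FALSE]
  }

  n_before <- nrow(d)
  d <- d[d$score > min_score & d$loc_prob >= min_loc_prob, , drop = FALSE]

  # collapse duplicates keeping the highest localization probability
  if (nrow(d)) {
    d <- d[order(siteKey(d$protein, d$position), -d$loc_prob), , drop = FALSE]
    d <- d[!duplicated(siteKey(d$protein, d$position)), , drop = FALSE]
  }
  if (nrow(d) == 0L) {
    warning(sprintf("no site passed the filters (score > %g, loc_prob >= %g); returning an empty table",
                    min_score, min_loc_prob))
  }
  PhosphoSiteTable(d, metadata = list(
    source = path,
    filters = list(min_score = min_score, min_loc_prob = min_loc_prob),
    n_input = n_before))
}

#' Filter an in-memory site table
#'
#' Applies the same strict score and localization-probability filters as
#' [readSiteTable()] to an existing table. Raising `min_score` can only
#' shrink the table (monotone filtering).
#'
#' @param x a [PhosphoSiteTable-class].
#' @inheritParams readSiteTable
#' @return the filtered [PhosphoSiteTable-class].
#' @export
filterSites <- function(x, min_score = 40, min_loc_prob = 0.75) {
  stopifnot(is(x, "PhosphoSiteTable"))
  s <- x@sites
  keep <- s$score > min_score & s$loc_prob >= min_loc_prob
  if (!any(keep)) {
    warning("no site passed the filters; returning an empty table")
  }
  meta <- x@metadata
  meta$filters <- list(min_score = min_score, min_loc_prob = min_loc_prob)
  PhosphoSiteTable(s[keep, , drop = FALSE], metadata = meta)
}

#' Write a site table as TSV
#'
#' Writes the minimal MaxQuant-style columns used by [readSiteTable()].
#'
#' @param x a [PhosphoSiteTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSiteTable <- function(x, path) {
  stopifnot(is(x, "PhosphoSiteTable"))
  s <- x@sites
  out <- data.frame(s$protein, s$gene, s$position, s$residue, s$window,
                    s$loc_prob, s$score, s$ratio, check.names = FALSE)
  names(out) <- unname(.SITE_TSV_COLS)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a protein FASTA file
#'
#' @param path FASTA file path.
#' @return a [Biostrings::AAStringSet]; duplicate record identifiers are an
#'   error. Record names are truncated at the first whitespace.
#' @export
readProteome <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  seqs <- Biostrings::readAAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop(sprintf("duplicate FASTA identifier(s): %s",
                 paste(unique(names(seqs)[duplicated(names(seqs))]),
                       collapse = ", ")))
  }
  seqs
}

#' Write a proteome to FASTA
#'
#' @param seqs a [Biostrings::AAStringSet] (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteome <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a GMT set collection
#'
#' One set per line: name, description, then members (tab-separated, Broad
#' convention). Duplicate members within a line are deduplicated; duplicate
#' set names are an error.
#'
#' @param path GMT file path.
#' @return named list of character member vectors, in file order, with the
#'   per-set descriptions in `attr(, "description")`.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 0L) < 3L
  if (any(short)) {
    stop(sprintf("GMT line(s) with fewer than 3 fields: %s",
                 paste(which(short), collapse = ", ")))
  }
  nm <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate set name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(vapply(parts, `[[`, "", 2L), nm)
  sets
}

#' Write a GMT set collection
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description (defaults to the name).
#' @return `path`, invisibly.
#' @export
writeGmt <- function(sets, path, description = NULL) {
  stopifnot(!is.null(names(sets)))
  if (is.null(description)) description <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a protein-protein interaction edge list
#'
#' Tab-separated with a header; the first two columns are the interacting
#' protein identifiers. Edges are undirected and deduplicated; self-loops
#' are kept but flagged with a warning.
#'
#' @param path TSV file path.
#' @return a [PpiSet-class].
#' @export
readPpi <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  if (nrow(d) == 0L) return(PpiSet())
  if (ncol(d) < 2L) stop("PPI table must have at least two columns")
  PpiSet(d[[1L]], d[[2L]])
}

#' Write a PPI edge list as TSV
#'
#' @param ppi a [PpiSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePpi <- function(ppi, path) {
  stopifnot(is(ppi, "PpiSet"))
  d <- as.data.frame(ppi@pairs, stringsAsFactors = FALSE)
  names(d) <- c("protein_a", "protein_b")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a kinase substrate annotation table
#'
#' Tab-separated with columns `Kinase` and `Window` (one known substrate
#' 13-mer per row), and optionally `Residues` (accepted central residues,
#' e.g. `"ST"` or `"Y"`; defaults to the central residues observed in the
#' kinase's windows).
#'
#' @param path TSV file path.
#' @return list of uncalibrated [KinaseProfile-class] objects, one per
#'   kinase.
#' @export
readKinaseAnnotations <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  d <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, quote = "")
  missing_cols <- setdiff(c("Kinase", "Window"), names(d))
  if (length(missing_cols)) {
    stop(sprintf("kinase annotation table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")))
  }
  lapply(split(d, d$Kinase), function(g) {
    res <- if ("Residues" %in% names(g) && nzchar(g$Residues[1L])) {
      strsplit(g$Residues[1L], "", fixed = TRUE)[[1L]]
    } else {
      unique(substr(g$Window, 7L, 7L))
    }
    KinaseProfile(g$Kinase[1L], unique(g$Window), residues = res)
  })
}

#' Write kinase substrate annotations as TSV
#'
#' @param profiles list of [KinaseProfile-class] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeKinaseAnnotations <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(Kinase = kinaseName(p), Window = substrateWindows(p),
               Residues = paste(p@residues, collapse = ""),
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
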