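# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical one-letter codes.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Padding character used at protein termini in 13-mer sequence windows.
PAD <- "_"

# Built-in background amino-acid frequencies (Swiss-Prot-like composition),
# normalised to sum to 1. Used by the proteome simulator and recorded in
# generated output metadata.
BG_AA_FREQS <- local({
  f <- c(A = 0.0826, R = 0.0553, N = 0.0406, D = 0.0546, C = 0.0137,
         Q = 0.0393, E = 0.0674, G = 0.0708, H = 0.0227, I = 0.0593,
         L = 0.0965, K = 0.0582, M = 0.0241, F = 0.0386, P = 0.0472,
         S = 0.0664, T = 0.0535, W = 0.0110, Y = 0.0292, V = 0.0686)
  f <- f[AA20]
  f / sum(f)
})

# Run `code` under a fixed RNG seed without disturbing the caller's RNG state.
localSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split 13-mer windows into a character matrix (one row per window),
# validating length and alphabet (20 amino acids plus the padding character).
windowMatrix <- function(windows, what = "window") {
  if (length(windows) == 0L) {
    return(matrix(character(0), nrow = 0L, ncol = 13L))
  }
  n <- nchar(windows)
  if (any(n != 13L)) {
    stop(sprintf("all %ss must be 13 characters long (found lengths: %s)",
                 what, paste(unique(n[n != 13L]), collapse = ", ")))
  }
  m <- matrix(unlist(strsplit(windows, "", fixed = TRUE), use.names = FALSE),
              ncol = 13L, byrow = TRUE)
  bad <- setdiff(unique(as.vector(m)), c(AA20, PAD))
  if (length(bad)) {
    stop(sprintf("invalid character(s) in %s: %s (allowed: 20 amino acids and '%s')",
                 what, paste(bad, collapse = ", "), PAD))
  }
  m
}

# BLOSUM62 over the 20 amino acids, extended with a zero-scoring padding
# row/column so that any aligned pair involving '_' contributes 0.
.pkg_cache <- new.env(parent = emptyenv())

blosum62Padded <- function() {
  if (is.null(.pkg_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62[AA20, AA20]
    m <- rbind(cbind(m, `_` = 0), `_` = 0)
    colnames(m)[ncol(m)] <- PAD
    rownames(m)[nrow(m)] <- PAD
    .pkg_cache$blosum62 <- m
  }
  .pkg_cache$blosum62
}

# Extract the 13-mer window centred at `position` of `sequence`, padding with
# '_' beyond the protein termini. Positions are 1-based.
extractWindow <- function(sequence, position) {
  len <- nchar(sequence)
  idx <- (position - 6L):(position + 6L)
  chars <- rep(PAD, 13L)
  ok <- idx >= 1L & idx <= len
  if (any(ok)) {
    chars[ok] <- substring(sequence, idx[ok], idx[ok])
  }
  paste(chars, collapse = "")
}

siteKey <- function(protein, position) paste(protein, position, sep = "_")
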