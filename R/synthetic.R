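# Synthetic pooled two-group TMT phosphoproteomics with known ground
# truth: a random proteome, planted kinases with short-linear-motif
# consensus constraints, and a single simulated disease/control ratio per
# site with planted activity shifts. Everything is deterministic given the
# config seed.

# signature constraints cycled over kinases: offset (relative to the
# phosphosite) and required residue. Kinase 1 is proline-directed (P at
# +1), the dominant motif class in phosphoproteomes.
.SIGNATURES <- list(c("1", "P"), c("-3", "R"), c("3", "E"), c("-2", "L"),
                    c("2", "D"), c("-4", "K"), c("4", "G"), c("-5", "F"))

# per-kinase soft-preference residue classes: at unconstrained flanking
# positions a substrate window draws, with probability 1/2, from the
# kinase's preferred biochemical class (background frequencies
# renormalised within the class) instead of the full background. Class
# members score well against each other under BLOSUM62, so windows of one
# kinase are mutually similar, while the preference is spread over several
# residues and over all positions - no single (position, residue) cell
# rivals the hard consensus constraint.
.SOFT_CLASSES <- list(c("L", "I", "V", "M"), c("G", "A"),
                      c("E", "D", "Q", "N"), c("K", "R", "H"))

#' Build a synthetic-data configuration
#'
#' Defaults emulate a pooled two-group TMT phosphoproteomics study: ~2.5
#' quantified sites per protein, an S:T:Y residue mix of 0.84:0.14:0.02,
#' three kinases (one activated, one inactivated, one null) with 20
#' planted substrate sites each, a one-unit log2 activity shift and 0.5
#' log2 units of measurement noise.
#'
#' @param n_proteins number of proteins.
#' @param mean_sites_per_protein mean quantified sites per protein.
#' @param residue_mix named S/T/Y probabilities summing to 1.
#' @param n_kinases number of synthetic kinases (named KIN1, KIN2, ...).
#' @param substrates_per_kinase planted substrate sites per kinase.
#' @param n_known_windows independently drawn annotation windows per kinase.
#' @param active_kinases,inactive_kinases disjoint kinase-name subsets;
#'   kinases in neither set are null.
#' @param effect_size planted log2 shift magnitude.
#' @param baseline_sd,noise_sd log2-ratio standard deviations (baseline
#'   biological spread and measurement noise).
#' @param seed integer RNG seed.
#' @return a validated [SimConfig-class].
#' @export
simConfig <- function(n_proteins = 200, mean_sites_per_protein = 2.5,
                      residue_mix = c(S = 0.84, T = 0.14, Y = 0.02),
                      n_kinases = 3, substrates_per_kinase = 20,
                      n_known_windows = 30,
                      active_kinases = "KIN1", inactive_kinases = "KIN2",
                      effect_size = 1.0, baseline_sd = 0.1, noise_sd = 0.5,
                      seed = 1) {
  new("SimConfig", nProteins = as.integer(n_proteins),
      meanSitesPerProtein = mean_sites_per_protein,
      residueMix = residue_mix, nKinases = as.integer(n_kinases),
      substratesPerKinase = as.integer(substrates_per_kinase),
      nKnownWindows = as.integer(n_known_windows),
      activeKinases = active_kinases, inactiveKinases = inactive_kinases,
      effectSize = effect_size, baselineSd = baseline_sd,
      noiseSd = noise_sd, seed = as.integer(seed))
}

.kinaseNames <- function(config) sprintf("KIN%d", seq_len(config@nKinases))

.kinaseDirection <- function(name, config) {
  ifelse(name %in% config@activeKinases, "positive",
         ifelse(name %in% config@inactiveKinases, "negative", "null"))
}

#' Generate a random proteome
#'
#' `n_proteins` sequences of length 200-600 (uniform) drawn i.i.d. from
#' the built-in background amino-acid frequency table. Deterministic given
#' the config seed: the same config yields byte-identical FASTA output.
#'
#' @param config a [SimConfig-class].
#' @return a named [Biostrings::AAStringSet] (PROT0001, PROT0002, ...)
#'   with the background frequency table in `attr(, "bg_freqs")`.
#' @export
generateProteome <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  seqs <- localSeed(config@seed, {
    lens <- sample(200:600, config@nProteins, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(AA20, L, replace = TRUE, prob = BG_AA_FREQS),
            collapse = "")
    }, "")
  })
  names(seqs) <- sprintf("PROT%04d", seq_len(config@nProteins))
  out <- Biostrings::AAStringSet(seqs)
  attr(out, "bg_freqs") <- BG_AA_FREQS
  out
}

# draw one 13-mer from kinase k's motif model: centre S (85%) or T,
# signature residue fixed at its offset, other positions from the
# kinase's soft class with probability 1/2, else full background.
.motifWindow <- function(sig_offset, sig_residue, soft_class) {
  chars <- sample(AA20, 13L, replace = TRUE, prob = BG_AA_FREQS)
  soft <- which(stats::runif(13L) < 0.5)
  if (length(soft)) {
    cls_freq <- BG_AA_FREQS[soft_class] / sum(BG_AA_FREQS[soft_class])
    chars[soft] <- sample(soft_class, length(soft), replace = TRUE,
                          prob = cls_freq)
  }
  chars[7L] <- sample(c("S", "T"), 1L, prob = c(0.85, 0.15))
  chars[7L + sig_offset] <- sig_residue
  paste(chars, collapse = "")
}

#' Plant synthetic kinases into a proteome
#'
#' Gives each kinase a consensus constraint (a required residue at a fixed
#' offset within -6..+6; kinase 1 is proline-directed with P at +1) plus a
#' soft flanking preference, rewrites `substrates_per_kinase` substrate
#' windows per kinase into the protein sequences (each planted site
#' matches its kinase's consensus by construction and belongs to exactly
#' one kinase), and draws an independent set of "known substrate" windows
#' per kinase from the same motif model to serve as its annotation
#' profile.
#'
#' @param proteome output of [generateProteome()] (or a named character
#'   vector of sequences).
#' @param config a [SimConfig-class].
#' @return list with `proteome` (the rewritten sequences), `profiles`
#'   (uncalibrated [KinaseProfile-class] list) and `truth`
#'   ([GroundTruth-class]).
#' @export
plantKinases <- function(proteome, config) {
  stopifnot(is(config, "SimConfig"))
  seqs <- as.character(proteome)
  if (length(seqs) == 0L) stop("proteome is empty")
  if (all(nchar(seqs) < 13L)) {
    stop("no protein long enough (13 residues) to place a substrate window")
  }
  kn <- .kinaseNames(config)
  sigs <- .SIGNATURES[((seq_along(kn) - 1L) %% length(.SIGNATURES)) + 1L]
  softs <- .SOFT_CLASSES[((seq_along(kn) - 1L) %% length(.SOFT_CLASSES)) + 1L]

  res <- localSeed(config@seed + 1L, {
    occupied <- lapply(seqs, function(x) integer(0))
    site_rows <- list()
    profiles <- vector("list", length(kn))
    for (k in seq_along(kn)) {
      off <- as.integer(sigs[[k]][1L]); resi <- sigs[[k]][2L]
      eligible <- which(nchar(seqs) >= 13L)
      for (j in seq_len(config@substratesPerKinase)) {
        placed <- FALSE
        for (attempt in seq_len(200L)) {
          pi <- sample(eligible, 1L)
          L <- nchar(seqs[pi])
          pos <- sample(7:(L - 6L), 1L)
          if (any(abs(occupied[[pi]] - pos) < 13L)) next
          w <- .motifWindow(off, resi, softs[[k]])
          seqs[pi] <- paste0(substr(seqs[pi], 1L, pos - 7L), w,
                             substr(seqs[pi], pos + 7L, L))
          occupied[[pi]] <- c(occupied[[pi]], pos)
          site_rows[[length(site_rows) + 1L]] <- data.frame(
            protein = names(seqs)[pi], position = pos,
            residue = substr(w, 7L, 7L), window = w, kinase = kn[k],
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed) {
          stop(sprintf("could not place substrate %d of kinase %s (proteins too short or saturated)",
                       j, kn[k]))
        }
      }
      known <- vapply(seq_len(config@nKnownWindows), function(i) {
        .motifWindow(off, resi, softs[[k]])
      }, "")
      profiles[[k]] <- KinaseProfile(kn[k], known, residues = c("S", "T"))
    }
    list(seqs = seqs, sites = do.call(rbind, site_rows), profiles = profiles)
  })

  dirs <- .kinaseDirection(kn, config)
  shift <- c(positive = config@effectSize, negative = -config@effectSize,
             null = 0)[dirs]
  truth_sites <- res$sites
  truth_sites$shift <- shift[match(truth_sites$kinase, kn)]
  truth <- new("GroundTruth", sites = truth_sites,
               kinases = data.frame(
                 kinase = kn, direction = dirs,
                 sig_offset = vapply(sigs, function(s) as.integer(s[1L]), 0L),
                 sig_residue = vapply(sigs, `[[`, "", 2L),
                 stringsAsFactors = FALSE))
  names(res$profiles) <- kn
  out_proteome <- Biostrings::AAStringSet(res$seqs)
  attr(out_proteome, "bg_freqs") <- attr(proteome, "bg_freqs")
  list(proteome = out_proteome, profiles = res$profiles, truth = truth)
}

#' Simulate the quantified site table
#'
#' Samples background phosphosites from each protein's actual S/T/Y
#' positions (site counts Poisson per protein, residue classes drawn from
#' the configured mix) alongside all planted substrate sites, then assigns
#' each site `log2 ratio = shift + N(0, baseline_sd) + N(0, noise_sd)`,
#' where the shift is `+effect_size` for substrates of active kinases,
#' `-effect_size` for inactive ones and 0 otherwise. Localization
#' probabilities follow a Beta(9, 1) (mode at 1); search scores follow a
#' Gamma(5, rate 0.04) so a small tail falls below the standard score
#' filter. Deterministic given the config seed.
#'
#' @param proteome the (rewritten) proteome from [plantKinases()].
#' @param truth the matching [GroundTruth-class].
#' @param config a [SimConfig-class].
#' @return an unfiltered [PhosphoSiteTable-class] (apply [filterSites()]
#'   for the quality-filtered view).
#' @export
simulateQuant <- function(proteome, truth, config) {
  stopifnot(is(config, "SimConfig"), is(truth, "GroundTruth"))
  seqs <- as.character(proteome)
  ts <- truth@sites
  if (nrow(ts) && !all(ts$protein %in% names(seqs))) {
    stop("ground truth references proteins absent from the proteome")
  }
  mix <- config@residueMix[c("S", "T", "Y")]

  localSeed(config@seed + 2L, {
    rows <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
      prot <- names(seqs)[i]
      chars <- strsplit(seqs[i], "", fixed = TRUE)[[1L]]
      planted <- ts$position[ts$protein == prot]
      n_bg <- stats::rpois(1L, config@meanSitesPerProtein)
      pos_pool <- setdiff(which(chars %in% c("S", "T", "Y")), planted)
      picked <- integer(0)
      if (n_bg > 0L && length(pos_pool)) {
        # draw the residue class of each site from the configured mix,
        # then a uniform position of that class; keeps the marginal
        # residue proportions at the mix
        pool <- split(pos_pool, chars[pos_pool])
        for (j in seq_len(n_bg)) {
          avail <- names(pool)[lengths(pool) > 0L]
          if (!length(avail)) break
          cls <- if (length(avail) == 1L) avail else
            sample(avail, 1L, prob = mix[avail] / sum(mix[avail]))
          sel <- pool[[cls]][sample.int(length(pool[[cls]]), 1L)]
          picked <- c(picked, sel)
          pool[[cls]] <- setdiff(pool[[cls]], sel)
        }
      }
      pos <- c(planted, picked)
      if (!length(pos)) next
      rows[[i]] <- data.frame(protein = prot, position = as.integer(pos),
                              residue = chars[pos], stringsAsFactors = FALSE)
    }
    d <- do.call(rbind, rows)
    d$window <- vapply(seq_len(nrow(d)), function(r) {
      extractWindow(seqs[d$protein[r]], d$position[r])
    }, "")
    shift <- rep(0, nrow(d))
    m <- match(siteKey(d$protein, d$position), siteKey(ts$protein, ts$position))
    shift[!is.na(m)] <- ts$shift[m[!is.na(m)]]
    l2 <- shift + stats::rnorm(nrow(d), 0, config@baselineSd) +
      stats::rnorm(nrow(d), 0, config@noiseSd)
    d$loc_prob <- pmin(stats::rbeta(nrow(d), 9, 1), 1)
    d$score <- stats::rgamma(nrow(d), shape = 5, rate = 0.04)
    d$ratio <- 2^l2
    d$log2_ratio <- l2
    PhosphoSiteTable(d, metadata = list(
      generator = "phosphokin synthetic",
      seed = config@seed,
      effect_size = config@effectSize,
      baseline_sd = config@baselineSd, noise_sd = config@noiseSd,
      bg_freqs = as.list(BG_AA_FREQS)))
  })
}

#' Simulate protein-protein interaction evidence
#'
#' Interaction edges between each kinase and all its planted substrate
#' proteins, plus random decoy protein-protein edges.
#'
#' @param truth a [GroundTruth-class].
#' @param proteome the proteome (for decoy endpoints).
#' @param config a [SimConfig-class].
#' @param n_decoys number of random decoy edges (default 200).
#' @return a [PpiSet-class].
#' @export
simulatePpi <- function(truth, proteome, config, n_decoys = 200) {
  ts <- truth@sites
  prots <- names(as.character(proteome))
  localSeed(config@seed + 3L, {
    a <- ts$kinase; b <- ts$protein
    if (n_decoys > 0L && length(prots) >= 2L) {
      da <- sample(prots, n_decoys, replace = TRUE)
      db <- sample(prots, n_decoys, replace = TRUE)
      ok <- da != db
      a <- c(a, da[ok]); b <- c(b, db[ok])
    }
    PpiSet(a, b)
  })
}

#' Simulate a complete synthetic dataset
#'
#' Runs [generateProteome()], [plantKinases()], [simulateQuant()] and
#' [simulatePpi()] under one config.
#'
#' @param config a [SimConfig-class].
#' @return list with `proteome`, `profiles`, `truth`, `sites` (unfiltered
#'   [PhosphoSiteTable-class]), `ppi` and the `config`.
#' @export
simulateDataset <- function(config = simConfig()) {
  proteome0 <- generateProteome(config)
  planted <- plantKinases(proteome0, config)
  sites <- simulateQuant(planted$proteome, planted$truth, config)
  ppi <- simulatePpi(planted$truth, planted$proteome, config)
  list(proteome = planted$proteome, profiles = planted$profiles,
       truth = planted$truth, sites = sites, ppi = ppi, config = config)
}

#' Write a synthetic dataset to a directory
#'
#' Writes the proteome FASTA, the MaxQuant-style site TSV, the kinase
#' annotation TSV, the PPI TSV, and the two ground-truth TSVs.
#'
#' @param dataset list from [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of written paths, invisibly.
#' @export
writeSimulation <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(proteome = file.path(dir, "proteome.fasta"),
             sites = file.path(dir, "sites.tsv"),
             kinases = file.path(dir, "kinase_substrates.tsv"),
             ppi = file.path(dir, "ppi.tsv"),
             truth_sites = file.path(dir, "truth_sites.tsv"),
             truth_kinases = file.path(dir, "truth_kinases.tsv"))
  writeProteome(dataset$proteome, paths["proteome"])
  writeSiteTable(dataset$sites, paths["sites"])
  writeKinaseAnnotations(dataset$profiles, paths["kinases"])
  writePpi(dataset$ppi, paths["ppi"])
  utils::write.table(truthSites(dataset$truth), paths["truth_sites"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truthKinases(dataset$truth), paths["truth_kinases"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}
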