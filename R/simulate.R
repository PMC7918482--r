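#' Simulation configuration
#'
#' Parameters of the synthetic two-phase proteome/acetylome experiment. The
#' defaults describe the emulated study design: ~1,000 detectable proteins of
#' 100-600 residues with log10 abundances drawn from N(3.0, 0.6), three
#' biological replicates per growth phase, lysine-acetylated proteins rising
#' in prevalence from 5% (exponential) to 11% (stationary), multiplicative
#' log-normal measurement noise, abundance-dependent detection dropout, and a
#' small fraction of contaminant records that fail the identification filters.
#'
#' @param n_proteins number of genome/detectable proteins.
#' @param length_range protein length range (residues).
#' @param abundance_mean,abundance_sd mean and sd of log10 protein abundance.
#' @param phase_effect_fraction fraction of proteins with a phase abundance
#'   shift; `phase_effect_sd` is the sd of that log10 shift.
#' @param phase_effect_sd see above.
#' @param anchor_min_log10 if non-NULL, shift all abundances by one constant
#'   so the global minimum log10 abundance equals this value (the ideal-mode
#'   alignment that makes estimated ratios equal log10 stoichiometry).
#' @param prevalence_exponential,prevalence_stationary fraction of proteins
#'   with at least one acetylation site per phase (the exponential set is a
#'   subset of the stationary set).
#' @param sites_range sites per acetylated protein (inclusive range).
#' @param stoichiometry_log10_range range of log10 site stoichiometry,
#'   sampled uniformly.
#' @param noise_sd sd of the per-record log10 multiplicative noise.
#' @param dropout overall detection dropout rate (records removed,
#'   preferentially at low MS1 area via a logistic in log10 area).
#' @param dropout_scale logistic slope scale of the dropout curve, in log10
#'   area units.
#' @param response_factor_sd sd of the per-peptide log10 response factor.
#' @param enrichment_gain linear gain of the Kac immunoaffinity enrichment.
#' @param oxidation_split fraction of an acetylated peptide's area carried by
#'   its methionine-oxidized variant (applied when the peptide contains M).
#' @param contaminant_fraction fraction of table rows that are contaminant
#'   records.
#' @param pathway_assigned_fraction fraction of proteins with a pathway
#'   assignment.
#' @param n_pathways size of the pathway vocabulary.
#' @param min_peptide_length detectability floor for simulated peptides.
#' @param n_replicates biological replicates per phase.
#' @param phases phase labels.
#' @return a named list of class `kacSimConfig`.
#' @export
simConfig <- function(n_proteins = 1000L,
                      length_range = c(100L, 600L),
                      abundance_mean = 3.0, abundance_sd = 0.6,
                      phase_effect_fraction = 0.2, phase_effect_sd = 0.5,
                      anchor_min_log10 = NULL,
                      prevalence_exponential = 0.05,
                      prevalence_stationary = 0.11,
                      sites_range = c(1L, 3L),
                      stoichiometry_log10_range = c(-2.5, 0),
                      noise_sd = 0.15,
                      dropout = 0.2, dropout_scale = 0.5,
                      response_factor_sd = 0.2,
                      enrichment_gain = 100,
                      oxidation_split = 0.3,
                      contaminant_fraction = 0.05,
                      pathway_assigned_fraction = 0.64,
                      n_pathways = 15L,
                      min_peptide_length = 6L,
                      n_replicates = 3L,
                      phases = c("exponential", "stationary")) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_proteins > 0, cfg$n_replicates >= 1,
            length(cfg$phases) == 2,
            cfg$dropout >= 0, cfg$dropout < 1,
            cfg$contaminant_fraction >= 0, cfg$contaminant_fraction < 1,
            cfg$oxidation_split >= 0, cfg$oxidation_split <= 1,
            cfg$prevalence_exponential >= 0,
            cfg$prevalence_exponential <= cfg$prevalence_stationary,
            cfg$prevalence_stationary <= 1,
            cfg$enrichment_gain > 0)
  class(cfg) <- "kacSimConfig"
  cfg
}

#' @rdname simConfig
#' @param ... overrides passed to [simConfig()].
#' @export
defaultSimConfig <- function(...) simConfig(...)

#' @describeIn simConfig noise-free preset: zero noise, dropout, response
#'   factor spread and contaminants, unit enrichment gain, no phase abundance
#'   effects, and the minimum log10 abundance anchored at 0 so that the
#'   estimated acetylation ratio of every quantified site equals the log10 of
#'   its true stoichiometry exactly.
#' @export
idealSimConfig <- function(...) {
  simConfig(noise_sd = 0, dropout = 0, response_factor_sd = 0,
            enrichment_gain = 1, contaminant_fraction = 0,
            phase_effect_fraction = 0, anchor_min_log10 = 0,
            oxidation_split = 0.5, ...)
}

## residue sampling frequencies: K+R ~11% so tryptic peptides average 8-12 aa
residueFrequencies <- function() {
  aa <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], c("K", "R"))
  p <- c(setNames(rep(0.89 / length(aa), length(aa)), aa), K = 0.06, R = 0.05)
  p[order(names(p))]
}

PATHWAY_POOL <- c(
  "carbohydrate metabolism", "energy metabolism", "translation",
  "transcription", "replication and repair",
  "folding, sorting and degradation", "membrane transport",
  "amino acid metabolism", "nucleotide metabolism", "lipid metabolism",
  "metabolism of cofactors and vitamins",
  "metabolism of terpenoids and polyketides", "cell growth and death",
  "transport and catabolism", "biosynthesis of secondary metabolites",
  "signal transduction", "xenobiotics biodegradation and metabolism",
  "glycan biosynthesis and metabolism", "cell motility",
  "metabolism of other amino acids")

## Kac-eluate peptide for a site: tryptic peptide with cleavage blocked at the
## acetylated lysine, extended to the detectability floor; NULL if impossible.
acetylPeptideForSite <- function(sequence, kpos, minLength = 6L) {
  frag <- trypticFragments(sequence, blockProline = TRUE)
  fi <- which(frag$start <= kpos & frag$end >= kpos)
  if (length(fi) != 1L) return(NULL)
  start <- frag$start[fi]; end <- frag$end[fi]
  ## acetylation blocks tryptic cleavage after this K
  if (kpos == end && fi < nrow(frag)) {
    fi2 <- fi + 1L
    end <- frag$end[fi2]
  } else {
    fi2 <- fi
  }
  ## extend to the detectability floor: following fragments first, then
  ## preceding ones
  while (end - start + 1L < minLength && fi2 < nrow(frag)) {
    fi2 <- fi2 + 1L
    end <- frag$end[fi2]
  }
  while (end - start + 1L < minLength && fi > 1L) {
    fi <- fi - 1L
    start <- frag$start[fi]
  }
  if (end - start + 1L < minLength) return(NULL)
  list(start = start, end = end,
       sequence = substr(sequence, start, end),
       acetyl_pos_in_peptide = kpos - start + 1L)
}

#' Draw the ground truth of a synthetic experiment
#'
#' Generates protein sequences (uniform residues with boosted K/R frequency),
#' log10 abundances per phase, pathway assignments, and per-site acetylation
#' stoichiometries with the configured phase prevalences. Deterministic for a
#' fixed (config, seed).
#'
#' @param config a [simConfig()] list.
#' @param seed integer RNG seed.
#' @return list of class `kacTruth` with elements `proteins` (data.frame:
#'   `protein`, `sequence`, `pathways`, `log10_exp`, `log10_stat`), `sites`
#'   (data.frame: `protein`, `position`, `stoich_exp`, `stoich_stat`),
#'   `config`, `seed`.
#' @export
buildTruth <- function(config = defaultSimConfig(), seed = 1L) {
  stopifnot(inherits(config, "kacSimConfig"))
  set.seed(seed)
  n <- config$n_proteins
  ids <- sprintf("SYN%04d", seq_len(n))
  freq <- residueFrequencies()
  lens <- sample(config$length_range[1]:config$length_range[2], n,
                 replace = TRUE)
  seqs <- vapply(lens, function(L)
    paste(sample(names(freq), L, replace = TRUE, prob = freq),
          collapse = ""), character(1))

  log10_exp <- rnorm(n, config$abundance_mean, config$abundance_sd)
  shift <- rep(0, n)
  nEff <- round(config$phase_effect_fraction * n)
  if (nEff > 0) {
    eff <- sample.int(n, nEff)
    shift[eff] <- rnorm(nEff, 0, config$phase_effect_sd)
  }
  log10_stat <- log10_exp + shift
  if (!is.null(config$anchor_min_log10)) {
    delta <- config$anchor_min_log10 - min(c(log10_exp, log10_stat))
    log10_exp <- log10_exp + delta
    log10_stat <- log10_stat + delta
  }

  nAssigned <- round(config$pathway_assigned_fraction * n)
  assigned <- sample.int(n, nAssigned)
  pool <- PATHWAY_POOL[seq_len(min(config$n_pathways, length(PATHWAY_POOL)))]
  pathways <- rep("", n)
  nPer <- sample(1:3, nAssigned, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  pathways[assigned] <- vapply(nPer, function(k)
    paste(sample(pool, k), collapse = ";"), character(1))

  nStat <- round(config$prevalence_stationary * n)
  nExp <- round(config$prevalence_exponential * n)
  statSet <- sample.int(n, nStat)
  expSet <- if (nExp > 0) sample(statSet, nExp) else integer()
  siteRows <- list()
  for (p in statSet) {
    kpos <- which(strsplit(seqs[p], "")[[1]] == "K")
    kpos <- kpos[vapply(kpos, function(k)
      !is.null(acetylPeptideForSite(seqs[p], k, config$min_peptide_length)),
      logical(1))]
    if (length(kpos) == 0L) next
    nSites <- min(length(kpos),
                  sample(config$sites_range[1]:config$sites_range[2], 1L))
    pos <- sort(sample(kpos, nSites))
    lo <- config$stoichiometry_log10_range[1]
    hi <- config$stoichiometry_log10_range[2]
    stStat <- 10^runif(nSites, lo, hi)
    stExp <- if (p %in% expSet) 10^runif(nSites, lo, hi) else rep(0, nSites)
    siteRows[[length(siteRows) + 1L]] <- data.frame(
      protein = ids[p], position = pos,
      stoich_exp = stExp, stoich_stat = stStat,
      stringsAsFactors = FALSE)
  }
  sites <- if (length(siteRows)) do.call(rbind, siteRows) else
    data.frame(protein = character(), position = integer(),
               stoich_exp = numeric(), stoich_stat = numeric(),
               stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  structure(list(proteins = data.frame(protein = ids, sequence = seqs,
                                       pathways = pathways,
                                       log10_exp = log10_exp,
                                       log10_stat = log10_stat,
                                       stringsAsFactors = FALSE),
                 sites = sites, config = config, seed = seed),
            class = "kacTruth")
}

## calibrate the logistic dropout midpoint so the mean detection probability
## equals 1 - rate over the realized log10 areas
dropoutKeep <- function(areas, rate, scale) {
  if (rate <= 0 || length(areas) == 0L) return(rep(TRUE, length(areas)))
  la <- log10(areas)
  f <- function(mu) mean(plogis((la - mu) / scale)) - (1 - rate)
  lo <- min(la) - 20; hi <- max(la) + 20
  mu <- uniroot(f, c(lo, hi))$root
  runif(length(la)) < plogis((la - mu) / scale)
}

contaminantRows <- function(nRows, fraction, fractionLabel, phases,
                            nReplicates) {
  nCont <- round(fraction / (1 - fraction) * nRows)
  if (nCont == 0L) return(NULL)
  contIds <- c("cRAP_ALBU", "cRAP_TRYP", "cRAP_KERA", "cRAP_CASB")
  pepLen <- sample(8:14, nCont, replace = TRUE)
  aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]
  pep <- vapply(pepLen, function(L)
    paste(sample(aa, L, replace = TRUE), collapse = ""), character(1))
  failMode <- sample(1:3, nCont, replace = TRUE)
  q <- ifelse(failMode %in% c(1, 3), runif(nCont, 0.01, 0.5),
              runif(nCont, 0, 0.009))
  xc <- ifelse(failMode %in% c(2, 3), runif(nCont, 0.5, 2.0),
               runif(nCont, 2.1, 5))
  data.frame(peptide = pep,
             protein = sample(contIds, nCont, replace = TRUE),
             start = NA_integer_, mods = "",
             area = 10^rnorm(nCont, 2.5, 0.8),
             xcorr = round(xc, 3), qvalue = signif(q, 4),
             phase = sample(phases, nCont, replace = TRUE),
             replicate = sample.int(nReplicates, nCont, replace = TRUE),
             fraction = fractionLabel, stringsAsFactors = FALSE)
}

#' Simulate PSM tables from a ground truth
#'
#' For every phase and replicate, each protein's fully cleaved tryptic
#' peptides (length >= the detectability floor) receive a linear MS1 area of
#' `10^log10_abundance x response_factor x lognormal noise` in the proteome
#' fraction. Every truth acetylation site spawns one Kac-eluate record from
#' the peptide whose cleavage is blocked at the acetylated lysine, with area
#' additionally multiplied by the site stoichiometry and the enrichment gain;
#' when that peptide contains a methionine, a configurable share of its area
#' is split into an oxidized variant record. Detection dropout removes
#' records preferentially at low area; contaminant records carry failing
#' scores so the identification filters remove them.
#'
#' @param truth a `kacTruth` object from [buildTruth()].
#' @param seed integer RNG seed for the measurement layer.
#' @return list of class `kacSim`: `fasta` (AAStringSet), `proteome_psms`,
#'   `kac_psms` (canonical PSM data.frames), `pathway_table`, `truth_sites`
#'   (per-site truth with the simulated peptide and site spec), and the
#'   `config`.
#' @export
simulateExperiment <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "kacTruth"))
  cfg <- truth$config
  set.seed(seed)
  prot <- truth$proteins
  phases <- cfg$phases
  nRep <- cfg$n_replicates

  ## tryptic peptides (0 missed cleavages) per protein
  pepList <- lapply(seq_len(nrow(prot)), function(i) {
    d <- trypticDigest(prot$sequence[i], maxMissed = 0L,
                       minLength = cfg$min_peptide_length)
    if (nrow(d) == 0L) return(NULL)
    data.frame(protein = prot$protein[i], peptide = d$sequence,
               start = d$start, stringsAsFactors = FALSE)
  })
  peps <- do.call(rbind, pepList)
  rf <- 10^rnorm(nrow(peps), 0, cfg$response_factor_sd)

  abund <- cbind(prot$log10_exp, prot$log10_stat)
  colnames(abund) <- phases
  rownames(abund) <- prot$protein

  protRows <- list()
  for (ph in phases) {
    for (r in seq_len(nRep)) {
      base <- 10^abund[peps$protein, ph] * rf
      noise <- 10^rnorm(nrow(peps), 0, cfg$noise_sd)
      protRows[[paste(ph, r)]] <- data.frame(
        peptide = peps$peptide, protein = peps$protein, start = peps$start,
        mods = "", area = base * noise,
        xcorr = round(runif(nrow(peps), 2.1, 5), 3),
        qvalue = signif(runif(nrow(peps), 0, 0.009), 4),
        phase = ph, replicate = r, fraction = "proteome",
        stringsAsFactors = FALSE)
    }
  }
  proteome <- do.call(rbind, protRows)
  rownames(proteome) <- NULL

  ## Kac-eluate records, one peptide per truth site
  sites <- truth$sites
  sitePeps <- lapply(seq_len(nrow(sites)), function(i) {
    seq <- prot$sequence[match(sites$protein[i], prot$protein)]
    sp <- acetylPeptideForSite(seq, sites$position[i],
                               cfg$min_peptide_length)
    if (is.null(sp)) return(NULL)
    data.frame(protein = sites$protein[i], position = sites$position[i],
               stoich_exp = sites$stoich_exp[i],
               stoich_stat = sites$stoich_stat[i],
               peptide = sp$sequence, start = sp$start,
               acetyl_pos = sp$acetyl_pos_in_peptide,
               stringsAsFactors = FALSE)
  })
  sitePeps <- do.call(rbind, sitePeps)
  kacRows <- list()
  if (!is.null(sitePeps) && nrow(sitePeps)) {
    siteRf <- 10^rnorm(nrow(sitePeps), 0, cfg$response_factor_sd)
    stoich <- cbind(sitePeps$stoich_exp, sitePeps$stoich_stat)
    colnames(stoich) <- phases
    mPos <- regexpr("M", sitePeps$peptide, fixed = TRUE)
    acMod <- sprintf("K%d(acetyl)", sitePeps$acetyl_pos)
    for (ph in phases) {
      for (r in seq_len(nRep)) {
        present <- stoich[, ph] > 0
        if (!any(present)) next
        idx <- which(present)
        base <- 10^abund[sitePeps$protein[idx], ph] * siteRf[idx] *
          stoich[idx, ph] * cfg$enrichment_gain
        noise <- 10^rnorm(length(idx), 0, cfg$noise_sd)
        area <- base * noise
        row <- data.frame(
          peptide = sitePeps$peptide[idx], protein = sitePeps$protein[idx],
          start = sitePeps$start[idx], mods = acMod[idx], area = area,
          xcorr = round(runif(length(idx), 2.1, 5), 3),
          qvalue = signif(runif(length(idx), 0, 0.009), 4),
          phase = ph, replicate = r, fraction = "kac_eluate",
          stringsAsFactors = FALSE)
        splitIdx <- which(cfg$oxidation_split > 0 & mPos[idx] > 0)
        if (length(splitIdx)) {
          ox <- row[splitIdx, , drop = FALSE]
          ox$area <- ox$area * cfg$oxidation_split
          ox$mods <- paste0(ox$mods, ";",
                            sprintf("M%d(oxidation)", mPos[idx][splitIdx]))
          row$area[splitIdx] <- row$area[splitIdx] *
            (1 - cfg$oxidation_split)
          row <- rbind(row, ox)
        }
        kacRows[[paste(ph, r)]] <- row
      }
    }
  }
  kac <- if (length(kacRows)) do.call(rbind, kacRows) else
    proteome[0, , drop = FALSE]
  rownames(kac) <- NULL

  proteome <- proteome[dropoutKeep(proteome$area, cfg$dropout,
                                   cfg$dropout_scale), , drop = FALSE]
  kac <- kac[dropoutKeep(kac$area, cfg$dropout, cfg$dropout_scale), ,
             drop = FALSE]

  nContP <- 0L; nContK <- 0L
  cp <- contaminantRows(nrow(proteome), cfg$contaminant_fraction,
                        "proteome", phases, nRep)
  if (!is.null(cp)) { proteome <- rbind(proteome, cp); nContP <- nrow(cp) }
  ck <- contaminantRows(nrow(kac), cfg$contaminant_fraction,
                        "kac_eluate", phases, nRep)
  if (!is.null(ck)) { kac <- rbind(kac, ck); nContK <- nrow(ck) }
  proteome$contaminant <- grepl("^cRAP", proteome$protein)
  kac$contaminant <- grepl("^cRAP", kac$protein)
  rownames(proteome) <- rownames(kac) <- NULL

  fasta <- Biostrings::AAStringSet(setNames(prot$sequence, prot$protein))
  truthSites <- if (!is.null(sitePeps)) sitePeps else
    data.frame(protein = character(), position = integer(),
               stoich_exp = numeric(), stoich_stat = numeric(),
               peptide = character(), start = integer(),
               acetyl_pos = integer(), stringsAsFactors = FALSE)
  if (nrow(truthSites))
    truthSites$site_spec <- sprintf("K%d", truthSites$position)

  structure(list(fasta = fasta, proteome_psms = proteome, kac_psms = kac,
                 pathway_table = prot[c("protein", "pathways")],
                 truth_sites = truthSites,
                 n_contaminants = c(proteome = nContP, kac_eluate = nContK),
                 config = cfg, seed = seed),
            class = "kacSim")
}

#' Write a simulated experiment to disk
#'
#' Writes the FASTA database, the two PSM tables, the pathway table, and the
#' per-site/per-protein truth tables (for test oracles) into a directory.
#'
#' @param sim a `kacSim` object from [simulateExperiment()].
#' @param dir output directory (created if needed).
#' @param truth optional `kacTruth` to write the protein-level truth table.
#' @return the directory, invisibly.
#' @export
writeSimulatedExperiment <- function(sim, dir, truth = NULL) {
  stopifnot(inherits(sim, "kacSim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$fasta, file.path(dir, "proteins.fasta"))
  writePsmTable(sim$proteome_psms, file.path(dir, "proteome_psms.tsv"),
                comments = "simulated total-proteome PSM table")
  writePsmTable(sim$kac_psms, file.path(dir, "kac_psms.tsv"),
                comments = "simulated Kac-eluate PSM table")
  writeTsvTable(sim$pathway_table, file.path(dir, "pathways.tsv"))
  writeTsvTable(sim$truth_sites, file.path(dir, "truth_sites.tsv"),
                comments = "simulator ground truth: acetylation sites")
  if (!is.null(truth))
    writeTsvTable(truth$proteins[c("protein", "pathways", "log10_exp",
                                   "log10_stat")],
                  file.path(dir, "truth_proteins.tsv"),
                  comments = "simulator ground truth: protein abundances")
  invisible(dir)
}
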