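## --- acetyl-site spec tokens -------------------------------------------------
##
## Each acetyl modification on a peptide maps to one site token in protein
## coordinates: "K114" (unambiguous), "K326|K327" (localization candidates),
## "protein-N-term" (peptide starts at residue 1), or "peptide-N-term@<pos>"
## (N-terminal acetylation of an internal peptide, recorded at the peptide's
## first residue). A multiply acetylated peptide joins its tokens with "+".

acetylSpecForPsm <- function(peptide, start, mods) {
  acet <- mods[mods$kind == "acetyl", , drop = FALSE]
  if (nrow(acet) == 0L) return(NA_character_)
  if (is.na(start)) stop("peptide start required to map acetyl sites")
  tokens <- vapply(acet$spec, function(spec) {
    if (spec == "N-term") {
      pos <- mapModToProtein(start, nchar(peptide), "N-term")
      if (identical(pos, "protein-N-term")) return("protein-N-term")
      return(paste0("peptide-N-term@", pos))
    }
    cand <- modPositions(spec)
    res <- modResidues(spec)
    paste(paste0(res, start + cand - 1L), collapse = "|")
  }, character(1))
  paste(sort(unname(tokens)), collapse = "+")
}

## does a site spec include at least one lysine-residue token?
specHasLysine <- function(spec) {
  vapply(strsplit(spec, "+", fixed = TRUE), function(tok)
    any(grepl("^K[0-9]+(\\|K[0-9]+)*$", tok)), logical(1))
}

#' Resolve missing peptide start positions against the sequence database
#'
#' @param psms PSM data.frame; rows with `start = NA` are located by exact
#'   string match of the peptide in its protein sequence.
#' @param proteins an `AAStringSet` (or named character vector) of protein
#'   sequences, as from [readProteinFasta()].
#' @return the PSM table with `start` filled in. Peptides absent from their
#'   protein or matching at multiple positions raise an error.
#' @export
resolvePeptideStarts <- function(psms, proteins) {
  seqs <- as.character(proteins)
  todo <- which(is.na(psms$start))
  for (i in todo) {
    seq <- seqs[[psms$protein[i]]]
    if (is.null(seq) || is.na(seq))
      stop("protein not in database: ", psms$protein[i])
    hits <- gregexpr(psms$peptide[i], seq, fixed = TRUE)[[1]]
    if (hits[1] == -1L)
      stop(sprintf("peptide %s not found in protein %s",
                   psms$peptide[i], psms$protein[i]))
    if (length(hits) > 1L)
      stop(sprintf("peptide %s matches protein %s at multiple positions",
                   psms$peptide[i], psms$protein[i]))
    psms$start[i] <- as.integer(hits[1])
  }
  psms
}

#' Collapse oxidation variants of acetylated peptides
#'
#' Kac-eluate records of the same (protein, peptide sequence, acetyl-position
#' set) within a sample that differ only in their oxidation (or static
#' carbamidomethylation) status are summed and counted as one acetylation
#' site observation.
#'
#' @param psms filtered Kac-eluate PSM data.frame; rows without an acetyl
#'   modification are ignored.
#' @param proteins optional sequence database used to resolve missing peptide
#'   start positions (see [resolvePeptideStarts()]).
#' @return data.frame with one row per (protein, peptide, site_spec, phase,
#'   replicate) and the summed linear MS1 `area`.
#' @export
collapseOxidationVariants <- function(psms, proteins = NULL) {
  if (nrow(psms) == 0L) {
    return(data.frame(protein = character(), peptide = character(),
                      site_spec = character(), phase = character(),
                      replicate = integer(), area = numeric(),
                      stringsAsFactors = FALSE))
  }
  if (!is.null(proteins)) psms <- resolvePeptideStarts(psms, proteins)
  spec <- vapply(seq_len(nrow(psms)), function(i)
    acetylSpecForPsm(psms$peptide[i], psms$start[i],
                     parseModString(psms$mods[i])), character(1))
  keep <- !is.na(spec)
  dt <- data.table::data.table(protein = psms$protein[keep],
                               peptide = psms$peptide[keep],
                               site_spec = spec[keep],
                               phase = psms$phase[keep],
                               replicate = psms$replicate[keep],
                               area = psms$area[keep])
  out <- dt[, list(area = sum(area)),
            by = c("protein", "peptide", "site_spec", "phase", "replicate")]
  as.data.frame(out)
}

#' Phase-level status of an acetylation site
#'
#' Same replicate-majority rule as for proteins: "quantified" when the site
#' has a positive area in strictly more than 50% of the phase's replicates,
#' "id." when detected in at least one replicate, "n.d." otherwise.
#'
#' @param detected logical per-replicate detection (any record).
#' @param quantified logical per-replicate positive-area presence (defaults
#'   to `detected`).
#' @param nReplicates replicates in the phase.
#' @param minFraction fraction that must be exceeded for "quantified".
#' @return one of `"quantified"`, `"id."`, `"n.d."`.
#' @export
sitePhaseStatus <- function(detected, quantified = detected,
                            nReplicates = length(detected),
                            minFraction = 0.5) {
  stopifnot(nReplicates >= 1L)
  if (sum(quantified, na.rm = TRUE) / nReplicates > minFraction)
    return("quantified")
  if (sum(detected, na.rm = TRUE) >= 1L) return("id.")
  "n.d."
}

#' Estimated log10 acetylation abundance ratio
#'
#' The ratio is the log10 MS1 area of the acetylated peptide (Kac eluate)
#' minus the median-normalized log10 abundance of the parent protein (total
#' proteome): `10^ratio` is the acetylated-peptide signal as a fraction of the
#' protein signal, so a ratio of -1 means 10%.
#'
#' @param siteLog10Area log10 summed MS1 area of the acetylated peptide.
#' @param proteinLog10Norm normalized log10 protein abundance.
#' @return numeric ratio (vectorized; NA propagates).
#' @export
estimateAcetylationRatio <- function(siteLog10Area, proteinLog10Norm) {
  siteLog10Area - proteinLog10Norm
}

#' Aggregate collapsed Kac observations into acetylation sites
#'
#' One row per (protein, peptide, acetyl-position set): per-phase status by
#' the replicate-majority rule, the phase-level mean log10 area over
#' replicates where the site was present, and — when the site is quantified
#' and its parent protein is quantified in that phase — the estimated log10
#' acetylation abundance ratio against the protein's phase-mean normalized
#' abundance.
#'
#' @param collapsed output of [collapseOxidationVariants()].
#' @param pq a normalized [ProteinQuant-class] object (may be NULL: statuses
#'   and areas are still computed, ratios stay NA).
#' @param phases phase labels.
#' @param nReplicates replicates per phase.
#' @param minFraction replicate fraction for "quantified".
#' @param replicateMatched if `TRUE`, subtract the protein abundance of the
#'   matching replicate before averaging instead of the phase mean.
#' @return data.frame with one row per site and columns `protein`, `peptide`,
#'   `site_spec`, and per phase `status_<phase>`, `log10area_<phase>`,
#'   `ratio_<phase>`.
#' @export
aggregateAcetylSites <- function(collapsed, pq = NULL,
                                 phases = c("exponential", "stationary"),
                                 nReplicates = 3L, minFraction = 0.5,
                                 replicateMatched = FALSE) {
  key <- c("protein", "peptide", "site_spec")
  if (nrow(collapsed) == 0L) {
    out <- data.frame(protein = character(), peptide = character(),
                      site_spec = character(), stringsAsFactors = FALSE)
    for (ph in phases) {
      out[[paste0("status_", ph)]] <- character()
      out[[paste0("log10area_", ph)]] <- numeric()
      out[[paste0("ratio_", ph)]] <- numeric()
    }
    return(out)
  }
  sites <- unique(collapsed[key])
  rownames(sites) <- NULL
  nrm <- if (!is.null(pq)) log10Norm(pq) else NULL
  st <- if (!is.null(pq)) proteinStatus(pq) else NULL
  cd <- if (!is.null(pq)) SummarizedExperiment::colData(pq) else NULL

  for (ph in phases) {
    statusCol <- character(nrow(sites))
    areaCol <- rep(NA_real_, nrow(sites))
    ratioCol <- rep(NA_real_, nrow(sites))
    sub <- collapsed[collapsed$phase == ph, , drop = FALSE]
    for (i in seq_len(nrow(sites))) {
      m <- sub[sub$protein == sites$protein[i] &
                 sub$peptide == sites$peptide[i] &
                 sub$site_spec == sites$site_spec[i], , drop = FALSE]
      detected <- quantified <- rep(FALSE, nReplicates)
      detected[m$replicate] <- TRUE
      quantified[m$replicate[m$area > 0]] <- TRUE
      statusCol[i] <- sitePhaseStatus(detected, quantified,
                                      nReplicates = nReplicates,
                                      minFraction = minFraction)
      if (statusCol[i] != "quantified") next
      reps <- m$replicate[m$area > 0]
      la <- log10(m$area[m$area > 0])
      areaCol[i] <- mean(la)
      if (is.null(pq)) next
      prot <- sites$protein[i]
      if (!prot %in% rownames(nrm) || st[prot, ph] != "quantified") next
      phCols <- which(cd$phase == ph)
      pv <- nrm[prot, phCols]
      if (replicateMatched) {
        repIdx <- cd$replicate[phCols]
        matched <- match(reps, repIdx)
        ok <- !is.na(matched) & !is.na(pv[matched])
        if (!any(ok)) next
        ratioCol[i] <- mean(la[ok] - pv[matched][ok])
      } else {
        ratioCol[i] <- estimateAcetylationRatio(areaCol[i],
                                                mean(pv, na.rm = TRUE))
      }
    }
    sites[[paste0("status_", ph)]] <- statusCol
    sites[[paste0("log10area_", ph)]] <- areaCol
    sites[[paste0("ratio_", ph)]] <- ratioCol
  }
  sites
}

#' Select highly acetylated sites
#'
#' A site is highly acetylated when its estimated log10 acetylation abundance
#' ratio in at least one phase reaches `threshold`. The default -1.0 follows
#' the "at least 10% of the protein MS1 signal" reading; `threshold = -1.1`
#' reproduces the slightly wider table convention.
#'
#' @param sites output of [aggregateAcetylSites()].
#' @param threshold minimum ratio (inclusive), default -1.0.
#' @return the qualifying subset of `sites` (sites with no quantified ratio
#'   are excluded).
#' @export
classifyHighlyAcetylated <- function(sites, threshold = -1.0) {
  ratioCols <- grep("^ratio_", names(sites), value = TRUE)
  if (nrow(sites) == 0L) return(sites)
  best <- apply(sites[ratioCols], 1L, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  sites[!is.na(best) & best >= threshold, , drop = FALSE]
}

#' Proportion of detected proteins with at least one acetylated lysine
#'
#' Numerator: proteins with at least one lysine-residue acetylation site
#' detected in at least one replicate of the phase (sites that are only
#' N-terminal acetylations do not count). Denominator: proteins identified or
#' quantified in the phase's total proteome.
#'
#' @param pq a [ProteinQuant-class] object.
#' @param sites output of [aggregateAcetylSites()].
#' @param phase phase label.
#' @return fraction in \[0,1\].
#' @export
acetylatedProteinProportion <- function(pq, sites, phase) {
  st <- proteinStatus(pq)
  if (!phase %in% colnames(st)) stop("unknown phase: ", phase)
  denom <- rownames(st)[st[, phase] %in% c("quantified", "identified")]
  if (length(denom) == 0L) stop("no proteins detected in phase ", phase)
  statusCol <- paste0("status_", phase)
  hit <- sites[[statusCol]] != "n.d." & specHasLysine(sites$site_spec)
  numer <- intersect(unique(sites$protein[hit]), denom)
  length(numer) / length(denom)
}

#' Per-protein acetylation-site counts
#'
#' @param sites output of [aggregateAcetylSites()].
#' @return data.frame with one row per protein carrying at least one site:
#'   `n_detected` (distinct site specs detected in any phase) and
#'   `n_quantifiable` (quantified in at least one phase).
#' @export
multiSiteSummary <- function(sites) {
  statusCols <- grep("^status_", names(sites), value = TRUE)
  if (nrow(sites) == 0L) {
    return(data.frame(protein = character(), n_detected = integer(),
                      n_quantifiable = integer(), stringsAsFactors = FALSE))
  }
  detected <- apply(sites[statusCols], 1L, function(v) any(v != "n.d."))
  quantifiable <- apply(sites[statusCols], 1L,
                        function(v) any(v == "quantified"))
  dt <- data.table::data.table(protein = sites$protein,
                               spec = sites$site_spec,
                               detected = detected,
                               quantifiable = quantifiable)
  out <- dt[, list(
    n_detected = data.table::uniqueN(spec[detected]),
    n_quantifiable = data.table::uniqueN(spec[quantifiable])),
    by = "protein"]
  out <- out[out$n_detected > 0L]
  as.data.frame(out[order(out$protein)])
}
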