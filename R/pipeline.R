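#' Default pipeline run configuration
#'
#' Thresholds default to the emulated study's printed settings: q-value
#' < 0.01, XCorr > 2.0, replicate-majority fraction 0.5, highly-acetylated
#' ratio threshold -1.0 (set `highly_acetylated_threshold = -1.1` for the
#' wider table convention).
#'
#' @param ... overrides of the default entries.
#' @return named list with input paths, thresholds, phase labels, replicate
#'   count, and ledger flags.
#' @export
defaultRunConfig <- function(...) {
  cfg <- list(fasta = NULL, proteome_psms = NULL, kac_psms = NULL,
              pathway_table = NULL, out_dir = NULL,
              q_max = 0.01, xcorr_min = 2.0, min_fraction = 0.5,
              highly_acetylated_threshold = -1.0,
              phases = c("exponential", "stationary"),
              n_replicates = 3L, contaminant_prefix = "cRAP",
              top_n = 3L, strict_top3 = FALSE, drop_shared = TRUE,
              replicate_matched = FALSE, adjust_pathways = FALSE)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration file
#'
#' Flat key-value YAML; unknown keys are an error, missing keys take their
#' defaults from [defaultRunConfig()].
#'
#' @param path path to a YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  defaults <- defaultRunConfig()
  unknown <- setdiff(names(vals), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  do.call(defaultRunConfig, vals)
}

## "n.d." / "id." / formatted ratio for the published-table-style layout
formatRatioCell <- function(status, ratio) {
  ifelse(status == "n.d.", "n.d.",
         ifelse(status == "id." | is.na(ratio), "id.",
                sprintf("%.2f", ratio)))
}

#' Express a log10 acetylation ratio as a fold change or percentage
#'
#' A ratio r corresponds to a linear factor 10^r between the acetylated
#' peptide's MS1 area and the protein's: ratios >= 0 are reported as an
#' x-fold excess (1 decimal place), negative ratios as a percentage of the
#' protein signal.
#'
#' @param ratio log10 acetylation abundance ratio.
#' @return character, e.g. `"6.9-fold"` for 0.84 or
#'   `"10.0% of protein signal"` for -1.
#' @export
formatRatioAsFold <- function(ratio) {
  fold <- 10^ratio
  ifelse(fold >= 1, sprintf("%.1f-fold", fold),
         sprintf("%.1f%% of protein signal", 100 * fold))
}

#' Run the full proteome/acetylome pipeline
#'
#' Orchestrates all stages: PSM reading and validation, confidence filtering,
#' top-3 protein quantification with normalization, growth-phase fold
#' changes, acetylation-site aggregation and ratio estimation, published-
#' table-style site reports, pathway coverage statistics for both layers, and
#' a summary whose every number is recomputable from the stage outputs.
#'
#' @param config list from [defaultRunConfig()] or [readRunConfig()]. The
#'   four inputs may be file paths or in-memory objects (an `AAStringSet` and
#'   canonical data.frames).
#' @return list of class `kacRun` with elements `proteins`
#'   ([ProteinQuant-class]), `fold_changes`, `sites`, `highly_acetylated`,
#'   `multi_site`, `site_report`, `pathways_proteome`, `pathways_acetylome`,
#'   `summary`, `config`. When `config$out_dir` is set, all tables are also
#'   written there as TSV.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  phases <- config$phases
  nRep <- config$n_replicates

  proteins <- if (is.character(config$fasta)) readProteinFasta(config$fasta)
              else config$fasta
  loadPsms <- function(x) {
    if (is.character(x))
      readPsmTable(x, contaminantPrefix = config$contaminant_prefix,
                   phases = phases)
    else x
  }
  proteomePsms <- loadPsms(config$proteome_psms)
  kacPsms <- loadPsms(config$kac_psms)
  annotation <- if (is.character(config$pathway_table))
    readPathwayTable(config$pathway_table) else config$pathway_table

  proteomeKept <- filterPsms(proteomePsms, qMax = config$q_max,
                             xcorrMin = config$xcorr_min)
  kacKept <- filterPsms(kacPsms, qMax = config$q_max,
                        xcorrMin = config$xcorr_min)

  pq <- quantifyProteins(proteomeKept, phases = phases, nReplicates = nRep,
                         topN = config$top_n, strict = config$strict_top3,
                         dropShared = config$drop_shared,
                         minFraction = config$min_fraction)
  pq <- normalizeAbundances(pq)
  fc <- phaseFoldChanges(pq, phases[1], phases[2])

  collapsed <- collapseOxidationVariants(kacKept, proteins = proteins)
  sites <- aggregateAcetylSites(collapsed, pq, phases = phases,
                                nReplicates = nRep,
                                minFraction = config$min_fraction,
                                replicateMatched = config$replicate_matched)
  high <- classifyHighlyAcetylated(sites,
                                   threshold = config$highly_acetylated_threshold)
  multi <- multiSiteSummary(sites)
  siteReport <- sites[c("protein", "site_spec")]
  for (ph in phases) {
    siteReport[[ph]] <- formatRatioCell(sites[[paste0("status_", ph)]],
                                        sites[[paste0("ratio_", ph)]])
  }

  ## detected sets for pathway coverage
  st <- proteinStatus(pq)
  raw <- log10Raw(pq)
  cd <- SummarizedExperiment::colData(pq)
  quantIds <- lapply(phases, function(ph)
    rownames(st)[st[, ph] == "quantified"])
  names(quantIds) <- phases
  repIds <- lapply(phases, function(ph) {
    lapply(which(cd$phase == ph), function(j)
      rownames(raw)[!is.na(raw[, j])])
  })
  names(repIds) <- phases
  acetIds <- lapply(phases, function(ph) {
    hit <- sites[[paste0("status_", ph)]] != "n.d." &
      specHasLysine(sites$site_spec)
    unique(sites$protein[hit])
  })
  names(acetIds) <- phases
  acetRepIds <- lapply(phases, function(ph) {
    sub <- collapsed[collapsed$phase == ph &
                       specHasLysine(collapsed$site_spec), , drop = FALSE]
    lapply(seq_len(nRep), function(r)
      unique(sub$protein[sub$replicate == r]))
  })
  names(acetRepIds) <- phases

  pwProt <- pathwayCoverageTable(
    annotation,
    detected = list(exp = quantIds[[1]], stat = quantIds[[2]]),
    detectedReplicates = list(exp = repIds[[1]], stat = repIds[[2]]),
    layer = "proteome", adjust = config$adjust_pathways)
  pwAcet <- pathwayCoverageTable(
    annotation,
    detected = list(exp = acetIds[[1]], stat = acetIds[[2]]),
    detectedReplicates = list(exp = acetRepIds[[1]], stat = acetRepIds[[2]]),
    layer = "acetylome", adjust = config$adjust_pathways)

  statusCols <- paste0("status_", phases)
  detectedAny <- apply(sites[statusCols], 1L, function(v) any(v != "n.d."))
  quantAny <- apply(sites[statusCols], 1L, function(v)
    any(v == "quantified"))
  ratioCols <- paste0("ratio_", phases)
  allRatios <- unlist(sites[ratioCols])
  topRatio <- if (any(!is.na(allRatios))) max(allRatios, na.rm = TRUE)
              else NA_real_

  summary <- list(
    n_detected_proteins = setNames(vapply(phases, function(ph)
      sum(st[, ph] != "absent"), integer(1)), phases),
    n_quantified_proteins = setNames(vapply(phases, function(ph)
      sum(st[, ph] == "quantified"), integer(1)), phases),
    n_acetylated_peptides = if (nrow(sites)) sum(detectedAny) else 0L,
    n_quantifiable_acetylated_peptides = if (nrow(sites)) sum(quantAny)
                                         else 0L,
    n_acetylated_proteins = length(unique(
      sites$protein[detectedAny & specHasLysine(sites$site_spec)])),
    acetylated_protein_proportion = setNames(vapply(phases, function(ph)
      acetylatedProteinProportion(pq, sites, ph), numeric(1)), phases),
    top_ratio = topRatio)

  out <- structure(list(proteins = pq, fold_changes = fc, sites = sites,
                        highly_acetylated = high, multi_site = multi,
                        site_report = siteReport,
                        pathways_proteome = pwProt,
                        pathways_acetylome = pwAcet,
                        summary = summary, config = config),
                   class = "kacRun")
  if (!is.null(config$out_dir)) writeRunOutputs(out, config$out_dir)
  out
}

writeRunOutputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pq <- run$proteins
  phases <- run$config$phases
  prot <- data.frame(protein = rownames(pq), stringsAsFactors = FALSE)
  nrm <- log10Norm(pq)
  colnames(nrm) <- paste0("log10norm_", colnames(nrm))
  prot <- cbind(prot, as.data.frame(nrm), proteinStatus(pq))
  writeTsvTable(prot, file.path(dir, "protein_abundances.tsv"),
                comments = "median-normalized log10 protein abundances")
  writeTsvTable(run$fold_changes, file.path(dir, "fold_changes.tsv"),
                comments = sprintf("phase fold changes: %s vs %s",
                                   phases[2], phases[1]))
  writeTsvTable(run$sites, file.path(dir, "acetyl_sites.tsv"),
                comments = "aggregated acetylation sites")
  writeTsvTable(run$site_report, file.path(dir, "site_report.tsv"),
                comments = "acetylation ratios (n.d. / id. convention)")
  writeTsvTable(run$highly_acetylated,
                file.path(dir, "highly_acetylated.tsv"),
                comments = sprintf("sites with ratio >= %s in any phase",
                                   run$config$highly_acetylated_threshold))
  writeTsvTable(run$multi_site, file.path(dir, "multi_site_proteins.tsv"))
  writeTsvTable(run$pathways_proteome,
                file.path(dir, "pathway_coverage_proteome.tsv"))
  writeTsvTable(run$pathways_acetylome,
                file.path(dir, "pathway_coverage_acetylome.tsv"))
  writeLines(renderReport(run), file.path(dir, "report.md"))
  invisible(dir)
}

#' Render a human-readable run summary
#'
#' @param run a `kacRun` object from [runPipeline()].
#' @return character vector of markdown lines.
#' @export
renderReport <- function(run) {
  s <- run$summary
  phases <- run$config$phases
  lines <- c("# Proteome / acetylome pipeline summary", "")
  for (ph in phases) {
    lines <- c(lines, sprintf(
      "- %s phase: %d proteins detected (%d quantified); acetylated-protein proportion %.1f%%",
      ph, s$n_detected_proteins[[ph]], s$n_quantified_proteins[[ph]],
      100 * s$acetylated_protein_proportion[[ph]]))
  }
  lines <- c(lines, sprintf(
    "- %d unique acetylated peptides detected, %d quantifiable, on %d proteins",
    s$n_acetylated_peptides, s$n_quantifiable_acetylated_peptides,
    s$n_acetylated_proteins))
  if (!is.na(s$top_ratio)) {
    lines <- c(lines, sprintf(
      "- highest estimated log10 acetylation abundance ratio: %.2f (%s)",
      s$top_ratio, formatRatioAsFold(s$top_ratio)))
  } else {
    lines <- c(lines, "- no quantified acetylation sites: ratio section omitted")
  }
  lines
}
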