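#' Filter peptide-spectrum matches by identification confidence
#'
#' Keeps records with `qvalue < qMax` and `xcorr > xcorrMin` (both comparisons
#' strict, matching the printed thresholds FDR < 0.01 and XCorr > 2.0) that are
#' not contaminant-flagged.
#'
#' @param psms PSM data.frame (canonical layout; a missing `contaminant`
#'   column is treated as all-FALSE).
#' @param qMax maximum Percolator q-value, exclusive (default 0.01).
#' @param xcorrMin minimum Sequest XCorr, exclusive (default 2.0).
#' @param verbose emit a message with the filter losses.
#' @return the kept subset, same columns.
#' @export
filterPsms <- function(psms, qMax = 0.01, xcorrMin = 2.0, verbose = FALSE) {
  contaminant <- if ("contaminant" %in% names(psms)) psms$contaminant
                 else rep(FALSE, nrow(psms))
  keep <- psms$qvalue < qMax & psms$xcorr > xcorrMin & !contaminant
  if (verbose) {
    message(sprintf(
      "filterPsms: kept %d/%d (removed %d contaminant, %d low-confidence)",
      sum(keep), nrow(psms), sum(contaminant),
      sum(!keep & !contaminant)))
  }
  psms[keep, , drop = FALSE]
}

#' Top-3 protein abundance roll-up
#'
#' Protein abundance in one sample is the arithmetic mean of its three largest
#' peptide-level MS1 areas. With fewer than three peptides the mean of the
#' available ones is used (configurable to a strict-3 rule via `strict`).
#'
#' @param areas numeric vector of peptide-level MS1 areas (linear scale).
#' @param n number of top peptides to average (default 3).
#' @param strict if `TRUE`, return NA when fewer than `n` peptides with
#'   positive area are available.
#' @return mean of the top areas (linear scale), or `NA_real_` when no
#'   positive area is available.
#' @export
top3Abundance <- function(areas, n = 3L, strict = FALSE) {
  areas <- areas[!is.na(areas) & areas > 0]
  if (length(areas) == 0L) return(NA_real_)
  if (strict && length(areas) < n) return(NA_real_)
  mean(sort(areas, decreasing = TRUE)[seq_len(min(n, length(areas)))])
}

#' Phase-level quantification status
#'
#' A protein is "quantified" in a phase when it has a present abundance in
#' strictly more than 50% of that phase's biological replicates (two of
#' three), "identified" when present in at least one but not enough, and
#' "absent" otherwise.
#'
#' @param present logical vector of per-replicate presence.
#' @param nReplicates total replicates of the phase (defaults to
#'   `length(present)`).
#' @param minFraction presence fraction that must be exceeded (default 0.5).
#' @return one of `"quantified"`, `"identified"`, `"absent"`.
#' @export
quantificationStatus <- function(present, nReplicates = length(present),
                                 minFraction = 0.5) {
  stopifnot(nReplicates >= 1L)
  k <- sum(present, na.rm = TRUE)
  if (k == 0L) return("absent")
  if (k / nReplicates > minFraction) return("quantified")
  "identified"
}

#' Build a ProteinQuant object from filtered proteome PSMs
#'
#' Rolls PSM areas up to peptide level (sum of PSM areas of the same peptide
#' sequence within a sample), drops peptides shared between proteins
#' (unique-peptide rule), applies the top-3 roll-up per protein and sample,
#' log10-transforms, and derives the per-phase quantification status.
#'
#' @param psms filtered proteome-fraction PSM data.frame.
#' @param phases phase labels defining the column order.
#' @param nReplicates replicates per phase (default: maximum replicate index
#'   seen in the data).
#' @param topN,strict passed to [top3Abundance()].
#' @param dropShared drop peptides observed under more than one protein ID
#'   (default TRUE).
#' @param minFraction passed to [quantificationStatus()].
#' @return a [ProteinQuant-class] object.
#' @export
quantifyProteins <- function(psms, phases = c("exponential", "stationary"),
                             nReplicates = NULL, topN = 3L, strict = FALSE,
                             dropShared = TRUE, minFraction = 0.5) {
  if (nrow(psms) == 0L) stop("no PSMs to quantify")
  dt <- data.table::as.data.table(
    psms[c("peptide", "protein", "area", "phase", "replicate")])
  if (dropShared) {
    nprot <- dt[, list(n = data.table::uniqueN(protein)), by = "peptide"]
    shared <- nprot$peptide[nprot$n > 1L]
    if (length(shared)) {
      message(sprintf("quantifyProteins: dropping %d peptide(s) shared between proteins",
                      length(shared)))
      dt <- dt[!dt$peptide %in% shared]
    }
  }
  if (is.null(nReplicates)) nReplicates <- max(dt$replicate)
  ## peptide-level area = sum of PSM areas per sample
  pep <- dt[, list(area = sum(area)),
            by = c("protein", "peptide", "phase", "replicate")]
  prot <- pep[, list(raw = top3Abundance(area, n = topN, strict = strict)),
              by = c("protein", "phase", "replicate")]
  prot <- prot[!is.na(prot$raw)]

  proteins <- sort(unique(prot$protein))
  samples <- expand.grid(replicate = seq_len(nReplicates), phase = phases,
                         stringsAsFactors = FALSE)[, c("phase", "replicate")]
  sampleIds <- paste(samples$phase, samples$replicate, sep = "_")
  mat <- matrix(NA_real_, nrow = length(proteins), ncol = nrow(samples),
                dimnames = list(proteins, sampleIds))
  idx <- cbind(match(prot$protein, proteins),
               match(paste(prot$phase, prot$replicate, sep = "_"), sampleIds))
  mat[idx] <- log10(prot$raw)

  status <- vapply(phases, function(ph) {
    cols <- which(samples$phase == ph)
    apply(mat[, cols, drop = FALSE], 1L, function(v)
      quantificationStatus(!is.na(v), nReplicates = nReplicates,
                           minFraction = minFraction))
  }, character(length(proteins)))
  status <- matrix(status, nrow = length(proteins),
                   dimnames = list(proteins, phases))
  rowdat <- S4Vectors::DataFrame(row.names = proteins)
  for (ph in phases) rowdat[[paste0("status_", ph)]] <- status[, ph]

  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log10raw = mat),
    colData = S4Vectors::DataFrame(phase = samples$phase,
                                   replicate = samples$replicate,
                                   row.names = sampleIds),
    rowData = rowdat)
  methods::new("ProteinQuant", se)
}

#' Median normalization with global-minimum-zero scaling
#'
#' Subtracts each sample's median (over that sample's present values) from its
#' log10 abundances, then adds one global constant so that the minimum over
#' all samples and proteins is exactly zero. Missing values stay missing.
#'
#' @param x a [ProteinQuant-class] object or a numeric matrix of log10
#'   abundances (proteins x samples, NA = absent).
#' @return same class as the input; for `ProteinQuant`, a `log10norm` assay is
#'   added and the per-sample medians and global shift are stored in
#'   `metadata(x)$normalization`. For a matrix, the normalized matrix with
#'   attributes `sampleMedians` and `globalShift`.
#' @export
normalizeAbundances <- function(x) {
  if (methods::is(x, "ProteinQuant")) {
    norm <- normalizeLog10Matrix(log10Raw(x))
    SummarizedExperiment::assay(x, "log10norm") <- norm
    attributes(SummarizedExperiment::assay(x, "log10norm")) <-
      attributes(norm)[c("dim", "dimnames")]
    S4Vectors::metadata(x)$normalization <-
      list(sampleMedians = attr(norm, "sampleMedians"),
           globalShift = attr(norm, "globalShift"))
    methods::validObject(x)
    return(x)
  }
  normalizeLog10Matrix(x)
}

normalizeLog10Matrix <- function(mat) {
  if (!is.matrix(mat)) stop("expected a matrix")
  nPresent <- colSums(!is.na(mat))
  if (any(nPresent == 0L))
    stop("sample(s) with no present values: ",
         paste(colnames(mat)[nPresent == 0L], collapse = ", "))
  med <- apply(mat, 2L, median, na.rm = TRUE)
  centered <- sweep(mat, 2L, med, "-")
  shift <- -min(centered, na.rm = TRUE)
  out <- centered + shift
  attr(out, "sampleMedians") <- med
  attr(out, "globalShift") <- shift
  out
}

#' Per-protein growth-phase fold changes and significance
#'
#' Computes, for every protein, the difference of phase replicate means on the
#' normalized log10 scale (phase B minus phase A), the equivalent log2 fold
#' change, and for proteins quantified in both phases a two-tailed
#' homoscedastic Student's t-test with Benjamini-Hochberg adjustment applied
#' jointly over all tested proteins.
#'
#' @param pq a normalized [ProteinQuant-class] object.
#' @param phaseA,phaseB phase labels; the fold change is `phaseB - phaseA`.
#' @return a data.frame with one row per protein: per-phase means and
#'   presence counts, `log10fc`, `log2fc`, `t`, `df`, `p_value`, `p_adj`,
#'   per-phase status, and a logical `tested` column.
#' @export
phaseFoldChanges <- function(pq, phaseA = "exponential",
                             phaseB = "stationary") {
  nrm <- log10Norm(pq)
  cd <- SummarizedExperiment::colData(pq)
  st <- proteinStatus(pq)
  colsA <- which(cd$phase == phaseA)
  colsB <- which(cd$phase == phaseB)
  matA <- nrm[, colsA, drop = FALSE]
  matB <- nrm[, colsB, drop = FALSE]
  nA <- rowSums(!is.na(matA))
  nB <- rowSums(!is.na(matB))
  meanA <- ifelse(nA > 0, rowMeans(matA, na.rm = TRUE), NA_real_)
  meanB <- ifelse(nB > 0, rowMeans(matB, na.rm = TRUE), NA_real_)
  log10fc <- meanB - meanA
  tested <- st[, phaseA] == "quantified" & st[, phaseB] == "quantified" &
    nA >= 2L & nB >= 2L
  t <- df <- p <- rep(NA_real_, nrow(nrm))
  for (i in which(tested)) {
    fit <- homoscedasticTTest(matA[i, ], matB[i, ])
    t[i] <- fit$t; df[i] <- fit$df; p[i] <- fit$p
  }
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- p.adjust(p[tested], method = "BH")
  data.frame(protein = rownames(nrm),
             mean_A = meanA, mean_B = meanB, n_A = nA, n_B = nB,
             log10fc = log10fc, log2fc = log10fc / log10(2),
             t = t, df = df, p_value = p, p_adj = p_adj,
             status_A = st[, phaseA], status_B = st[, phaseB],
             tested = tested, row.names = NULL,
             stringsAsFactors = FALSE)
}
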