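#' ProteinQuant: per-protein, per-sample log10 abundances
#'
#' An S4 container extending [SummarizedExperiment::SummarizedExperiment] for
#' top-3 protein quantification results. Rows are proteins, columns are
#' samples (phase x replicate). The `log10raw` assay holds log10-transformed
#' top-3 MS1 abundances (NA where a protein was not observed in a sample);
#' after [normalizeAbundances()] a `log10norm` assay is added. Per-phase
#' quantification status ("quantified" / "identified" / "absent") lives in
#' `rowData` columns `status_<phase>`.
#'
#' @slot .. inherits all slots from SummarizedExperiment.
#' @aliases ProteinQuant
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @export
setClass("ProteinQuant", contains = "SummarizedExperiment")

setValidity("ProteinQuant", function(object) {
  msg <- character()
  if (!"log10raw" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log10raw' is required")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("phase", "replicate") %in% colnames(cd)))
    msg <- c(msg, "colData must have 'phase' and 'replicate'")
  if ("log10norm" %in% SummarizedExperiment::assayNames(object)) {
    raw <- SummarizedExperiment::assay(object, "log10raw")
    nrm <- SummarizedExperiment::assay(object, "log10norm")
    if (!identical(is.na(raw), is.na(nrm)))
      msg <- c(msg, "log10norm must be present exactly where log10raw is")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ProteinQuant-class accessor for the raw log10 abundance matrix.
#' @param x a `ProteinQuant` object.
#' @export
log10Raw <- function(x) SummarizedExperiment::assay(x, "log10raw")

#' @describeIn ProteinQuant-class accessor for the normalized log10 abundance
#'   matrix (error if [normalizeAbundances()] has not been run).
#' @export
log10Norm <- function(x) {
  if (!"log10norm" %in% SummarizedExperiment::assayNames(x))
    stop("object has no 'log10norm' assay; run normalizeAbundances() first")
  SummarizedExperiment::assay(x, "log10norm")
}

#' @describeIn ProteinQuant-class per-phase quantification status as a
#'   character matrix (proteins x phases).
#' @export
proteinStatus <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  cols <- grep("^status_", colnames(rd), value = TRUE)
  out <- as.matrix(as.data.frame(rd[cols]))
  colnames(out) <- sub("^status_", "", cols)
  rownames(out) <- rownames(x)
  out
}

#' @describeIn ProteinQuant-class phase labels of the samples.
#' @export
phaseLabels <- function(x) {
  unique(as.character(SummarizedExperiment::colData(x)$phase))
}

#' @describeIn ProteinQuant-class compact display of dimensions, assays and
#'   per-phase status counts.
#' @param object a `ProteinQuant` object.
#' @export
setMethod("show", "ProteinQuant", function(object) {
  st <- proteinStatus(object)
  cat("ProteinQuant object\n")
  cat("  proteins:", nrow(object), " samples:", ncol(object), "\n")
  cat("  assays:",
      paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  for (ph in colnames(st)) {
    cat(sprintf("  %s: %d quantified, %d identified, %d absent\n", ph,
                sum(st[, ph] == "quantified"), sum(st[, ph] == "identified"),
                sum(st[, ph] == "absent")))
  }
  invisible(NULL)
})
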