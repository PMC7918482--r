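PSM_COLUMNS <- c("peptide", "protein", "start", "mods", "area", "xcorr",
                 "qvalue", "phase", "replicate", "fraction")

#' Read a protein sequence database in FASTA format
#'
#' @param path path to a FASTA file.
#' @return an [Biostrings::AAStringSet] named by the first whitespace-delimited
#'   token of each header; sequences are uppercased and trailing/internal `*`
#'   stop codons are stripped.
#' @export
readProteinFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(gsub("*", "", as.character(aa), fixed = TRUE))
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record(s): ", paste(ids[empty], collapse = ", "))
  dup <- duplicated(ids)
  if (any(dup))
    stop("duplicate protein ID(s): ", paste(unique(ids[dup]), collapse = ", "))
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Read a PSM (peptide-spectrum match) table
#'
#' Reads a delimited table of peptide-spectrum observations into the canonical
#' layout with columns `peptide`, `protein`, `start`, `mods`, `area`, `xcorr`,
#' `qvalue`, `phase`, `replicate`, `fraction`. Lines starting with `#` are
#' metadata comments. Every row is validated against the record invariants
#' (modification grammar and residue specificity, `area >= 0`,
#' `qvalue` in \[0,1\], known phase and fraction labels); any violation aborts
#' with the offending row numbers. Rows whose protein ID matches
#' `contaminantPrefix` are not dropped but flagged in a logical `contaminant`
#' column, mirroring exclusion via a cRAP-style contaminant database.
#'
#' @param path path to a TSV (or CSV, by file extension) table.
#' @param dialect optional named character vector mapping canonical column
#'   names to the file's column names, for foreign exporter layouts.
#' @param contaminantPrefix regular expression prefix marking contaminant
#'   protein IDs (default `"cRAP"`).
#' @param phases,fractions allowed factor levels for the respective columns.
#' @return data.frame in canonical layout plus a `contaminant` column.
#' @export
readPsmTable <- function(path, dialect = NULL, contaminantPrefix = "cRAP",
                         phases = c("exponential", "stationary"),
                         fractions = c("proteome", "kac_eluate")) {
  if (!file.exists(path)) stop("no such file: ", path)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readTsvTable(path, sep = sep)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      i <- match(dialect[[canon]], names(raw))
      if (!is.na(i)) names(raw)[i] <- canon
    }
  }
  missing <- setdiff(PSM_COLUMNS, names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  psms <- raw[PSM_COLUMNS]
  psms$peptide <- toupper(psms$peptide)
  for (col in c("start", "area", "xcorr", "qvalue", "replicate")) {
    psms[[col]] <- suppressWarnings(as.numeric(psms[[col]]))
  }
  psms$start <- as.integer(psms$start)
  psms$replicate <- as.integer(psms$replicate)
  errs <- validatePsms(psms, phases = phases, fractions = fractions)
  if (length(errs)) {
    stop("invalid PSM table ", path, ":\n  ",
         paste(errs, collapse = "\n  "))
  }
  psms$contaminant <- grepl(paste0("^", contaminantPrefix), psms$protein)
  psms
}

## per-row invariant checks; returns "row <i>: <msg>" strings
validatePsms <- function(psms, phases = c("exponential", "stationary"),
                         fractions = c("proteome", "kac_eluate")) {
  errs <- character()
  rowErr <- function(i, msg) sprintf("row %d: %s", i, msg)
  for (i in seq_len(nrow(psms))) {
    pep <- psms$peptide[i]
    if (is.na(pep) || !grepl("^[A-Z]+$", pep)) {
      errs <- c(errs, rowErr(i, "invalid peptide sequence")); next
    }
    if (is.na(psms$area[i]) || psms$area[i] < 0)
      errs <- c(errs, rowErr(i, "negative or missing MS1 area"))
    if (is.na(psms$qvalue[i]) || psms$qvalue[i] < 0 || psms$qvalue[i] > 1)
      errs <- c(errs, rowErr(i, sprintf("q-value outside [0,1]: %s",
                                        psms$qvalue[i])))
    if (is.na(psms$xcorr[i]))
      errs <- c(errs, rowErr(i, "missing XCorr"))
    if (!psms$phase[i] %in% phases)
      errs <- c(errs, rowErr(i, sprintf("unknown phase '%s'", psms$phase[i])))
    if (!psms$fraction[i] %in% fractions)
      errs <- c(errs, rowErr(i, sprintf("unknown fraction '%s'",
                                        psms$fraction[i])))
    if (is.na(psms$replicate[i]) || psms$replicate[i] < 1L)
      errs <- c(errs, rowErr(i, "replicate must be an integer >= 1"))
    mods <- tryCatch(parseModString(psms$mods[i]), error = function(e)
      conditionMessage(e))
    if (is.character(mods)) {
      errs <- c(errs, rowErr(i, mods))
    } else {
      merr <- checkMods(mods, pep)
      if (length(merr)) errs <- c(errs, vapply(merr, rowErr, "", i = i))
    }
  }
  errs
}

#' Write a PSM table in the canonical TSV layout
#'
#' @param psms data.frame as returned by [readPsmTable()] (the `contaminant`
#'   flag column, if present, is not written — it is derived on read).
#' @param path output path.
#' @param comments optional character vector of `#` metadata comment lines.
#' @export
writePsmTable <- function(psms, path, comments = character()) {
  writeTsvTable(psms[intersect(PSM_COLUMNS, names(psms))], path,
                comments = comments)
}

#' Read a pathway annotation table
#'
#' Two-column table (`protein`, `pathways`) mapping every genome-encoded
#' protein to its functional pathway assignments (GhostKOALA-style output
#' consumed as plain text). Multiple pathways are semicolon-separated; an empty
#' second field means "no pathway assigned" and the protein is retained.
#'
#' @param path path to a TSV file.
#' @return data.frame with columns `protein` and `pathways` (`;`-joined string,
#'   possibly empty).
#' @export
readPathwayTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readTsvTable(path)
  missing <- setdiff(c("protein", "pathways"), names(raw))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  raw$pathways[is.na(raw$pathways)] <- ""
  dup <- duplicated(raw$protein)
  if (any(dup))
    stop("duplicate protein ID(s) in pathway table: ",
         paste(unique(raw$protein[dup]), collapse = ", "))
  raw[c("protein", "pathways")]
}

## split a ";"-joined pathway string into a character vector (empty -> none)
splitPathways <- function(x) {
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(p) trimws(p[nzchar(trimws(p))]))
}
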