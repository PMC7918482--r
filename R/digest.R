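#' In-silico tryptic digestion
#'
#' Cleaves a protein sequence C-terminally to K or R, by default not when the
#' following residue is P (the classic Sequest trypsin rule), and returns every
#' peptide carrying between 0 and `maxMissed` internal missed cleavage sites.
#'
#' @param sequence single protein sequence (character or coercible via
#'   `as.character`), alphabetic, non-empty.
#' @param maxMissed maximum number of missed cleavages (default 4, the search
#'   setting the pipeline emulates).
#' @param minLength minimum peptide length to report (default 1; the simulator
#'   uses 6 as a detectability floor).
#' @param blockProline if `TRUE` (default) K/R followed by P is not cleaved.
#' @return data.frame with columns `start`, `end` (1-based, inclusive),
#'   `sequence`, `missed_cleavages`, ordered by (start, end).
#' @examples
#' trypticDigest("MKRAK", maxMissed = 0)$sequence  # "MK" "R" "AK"
#' @export
trypticDigest <- function(sequence, maxMissed = 4L, minLength = 1L,
                          blockProline = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop("sequence must be a single non-empty string")
  if (!grepl("^[A-Z]+$", sequence))
    stop("sequence must be alphabetic")
  if (maxMissed < 0L) stop("maxMissed must be >= 0")
  frag <- trypticFragments(sequence, blockProline)
  k <- nrow(frag)
  out <- vector("list", min(maxMissed, k - 1L) + 1L)
  for (m in 0:min(maxMissed, k - 1L)) {
    j <- seq_len(k - m)
    out[[m + 1L]] <- data.frame(start = frag$start[j],
                                end = frag$end[j + m],
                                missed_cleavages = m)
  }
  pep <- do.call(rbind, out)
  pep$sequence <- substring(sequence, pep$start, pep$end)
  pep <- pep[nchar(pep$sequence) >= minLength, , drop = FALSE]
  pep <- pep[order(pep$start, pep$end), c("start", "end", "sequence",
                                          "missed_cleavages")]
  rownames(pep) <- NULL
  pep
}

## fully cleaved fragments (0 missed cleavages)
trypticFragments <- function(sequence, blockProline = TRUE) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n]
  if (blockProline && length(cut)) cut <- cut[res[cut + 1L] != "P"]
  ends <- c(cut, n)
  starts <- c(1L, head(ends, -1L) + 1L)
  data.frame(start = starts, end = ends)
}

#' Map a within-peptide modification position onto protein coordinates
#'
#' @param peptideStart 1-based start of the peptide in the protein.
#' @param peptideLength peptide length in residues.
#' @param position 1-based position within the peptide, or `"N-term"`.
#' @return For numeric positions, the 1-based protein residue index
#'   (`peptideStart + position - 1`). `"N-term"` maps to the string
#'   `"protein-N-term"` when the peptide starts at residue 1; for an internal
#'   peptide it maps to the peptide's first residue index with attribute
#'   `peptide_nterm = TRUE` (an internal-peptide N-terminal acetylation is a
#'   peptide property, not a protein N-terminus).
#' @export
mapModToProtein <- function(peptideStart, peptideLength, position) {
  if (identical(position, "N-term")) {
    if (peptideStart == 1L) return("protein-N-term")
    return(structure(as.integer(peptideStart), peptide_nterm = TRUE))
  }
  position <- as.integer(position)
  if (is.na(position) || position < 1L || position > peptideLength)
    stop("modification position out of range: ", position)
  as.integer(peptideStart) + position - 1L
}
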