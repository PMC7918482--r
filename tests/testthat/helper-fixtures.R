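## Builders for tiny in-code fixtures.

## one canonical PSM row with sensible defaults
psmRow <- function(peptide = "AMRIKAK", protein = "P1", start = 1L,
                   mods = "", area = 100, xcorr = 3, qvalue = 0.001,
                   phase = "exponential", replicate = 1L,
                   fraction = "proteome", contaminant = FALSE) {
  data.frame(peptide = peptide, protein = protein, start = start,
             mods = mods, area = area, xcorr = xcorr, qvalue = qvalue,
             phase = phase, replicate = replicate, fraction = fraction,
             contaminant = contaminant, stringsAsFactors = FALSE)
}

psmTable <- function(...) do.call(rbind, list(...))

writeFastaFixture <- function(records, path = tempfile(fileext = ".fasta")) {
  lines <- unlist(lapply(names(records), function(h)
    c(paste0(">", h), records[[h]])))
  writeLines(lines, path)
  path
}

## a normalized ProteinQuant with one single-peptide protein per row of
## `log10abund` (proteins x 6 samples, two phases x 3 replicates)
makeProteinQuant <- function(log10abund,
                             phases = c("exponential", "stationary")) {
  stopifnot(ncol(log10abund) == 6L)
  rows <- list()
  for (i in seq_len(nrow(log10abund))) {
    for (j in seq_len(6L)) {
      v <- log10abund[i, j]
      if (is.na(v)) next
      rows[[length(rows) + 1L]] <- psmRow(
        peptide = sprintf("PEPTIDE%dA", i), protein = rownames(log10abund)[i],
        area = 10^v, phase = phases[(j - 1) %/% 3 + 1],
        replicate = (j - 1) %% 3 + 1)
    }
  }
  pq <- quantifyProteins(do.call(rbind, rows), phases = phases,
                         nReplicates = 3L)
  normalizeAbundances(pq)
}
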