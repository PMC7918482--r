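#' @import methods
#' @importFrom stats median pt rnorm runif rbinom setNames t.test p.adjust
#'   quantile plogis uniroot cor
#' @importFrom utils read.delim write.table head tail
#' @importFrom data.table as.data.table data.table uniqueN :=
NULL

.datatable.aware <- TRUE

KIND_RESIDUE <- c(acetyl = "K", oxidation = "M", carbamidomethyl = "C")

MOD_TOKEN_RE <- "^([A-Z][0-9]+(\\|[A-Z][0-9]+)*|N-term)\\((acetyl|oxidation|carbamidomethyl)\\)$"

#' Parse a modification string
#'
#' Modifications are exchanged as semicolon-joined tokens of the form
#' `"<residue><position>(<kind>)"`, with positions 1-based within the peptide,
#' e.g. `"K5(acetyl);M2(oxidation)"`. Protein/peptide N-terminal acetylation is
#' written `"N-term(acetyl)"`. Ambiguous site localization is expressed as a
#' candidate set joined by `|`, e.g. `"K326|K327(acetyl)"` (all candidates must
#' be valid positions of the stated residue).
#'
#' @param x a single modification string; `""` or `NA` means no modifications.
#' @return a data.frame with columns `spec` (the position token, e.g. `"K5"`,
#'   `"K5|K7"`, `"N-term"`) and `kind`; zero rows when unmodified.
#' @export
parseModString <- function(x) {
  if (length(x) != 1L) stop("parseModString() expects a single string")
  if (is.na(x) || !nzchar(x)) {
    return(data.frame(spec = character(), kind = character(),
                      stringsAsFactors = FALSE))
  }
  tokens <- strsplit(x, ";", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  bad <- !grepl(MOD_TOKEN_RE, tokens)
  if (any(bad)) {
    stop("unparseable modification token(s): ",
         paste(tokens[bad], collapse = ", "))
  }
  spec <- sub("\\(.*$", "", tokens)
  kind <- sub("^.*\\(", "", sub("\\)$", "", tokens))
  data.frame(spec = spec, kind = kind, stringsAsFactors = FALSE)
}

#' @rdname parseModString
#' @param mods a data.frame as returned by [parseModString()].
#' @export
formatModString <- function(mods) {
  if (nrow(mods) == 0L) return("")
  paste0(mods$spec, "(", mods$kind, ")", collapse = ";")
}

## positions encoded in a spec token: integer vector, or "N-term"
modPositions <- function(spec) {
  if (spec == "N-term") return("N-term")
  as.integer(sub("^[A-Z]", "", strsplit(spec, "|", fixed = TRUE)[[1]]))
}

modResidues <- function(spec) {
  if (spec == "N-term") return(character())
  substr(strsplit(spec, "|", fixed = TRUE)[[1]], 1L, 1L)
}

## validate one parsed mod set against its peptide; returns character errors
checkMods <- function(mods, peptide) {
  errs <- character()
  n <- nchar(peptide)
  for (i in seq_len(nrow(mods))) {
    spec <- mods$spec[i]; kind <- mods$kind[i]
    if (spec == "N-term") {
      if (kind != "acetyl")
        errs <- c(errs, sprintf("N-term modification must be acetyl, got %s", kind))
      next
    }
    pos <- modPositions(spec)
    res <- modResidues(spec)
    if (any(pos < 1L | pos > n)) {
      errs <- c(errs, sprintf("modification position out of range in %s", spec))
      next
    }
    actual <- substring(peptide, pos, pos)
    if (any(actual != res)) {
      errs <- c(errs, sprintf("residue mismatch in %s (peptide has %s)",
                              spec, paste(actual, collapse = "")))
      next
    }
    want <- KIND_RESIDUE[[kind]]
    if (any(res != want)) {
      errs <- c(errs, sprintf("%s allowed only on %s, got %s", kind, want, spec))
    }
  }
  errs
}

#' Two-tailed homoscedastic t-test with degenerate-variance handling
#'
#' Pooled-variance Student's t-test as used for protein fold changes and
#' pathway-coverage comparisons. When both groups have zero variance the test
#' statistic is undefined: equal means give p = 1, different means are reported
#' as p = 0 with `degenerate = TRUE` rather than a fabricated finite p.
#'
#' @param x,y numeric vectors (each length >= 2, NAs removed).
#' @return list with elements `t`, `df`, `p`, `degenerate`.
#' @export
homoscedasticTTest <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, degenerate = FALSE))
  }
  pooled <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2L)
  if (pooled == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2L, p = 1,
                  degenerate = FALSE))
    }
    return(list(t = sign(mean(y) - mean(x)) * Inf,
                df = length(x) + length(y) - 2L, p = 0, degenerate = TRUE))
  }
  fit <- t.test(x, y, var.equal = TRUE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value, degenerate = FALSE)
}

## TSV helpers: `#`-prefixed metadata comment lines before the header
readTsvTable <- function(path, sep = "\t") {
  read.delim(path, sep = sep, header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character", blank.lines.skip = TRUE)
}

writeTsvTable <- function(x, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, na = "")
  invisible(path)
}
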