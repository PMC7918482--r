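NO_PATHWAY <- "no pathway assigned"

#' Per-pathway coverage of the detected proteome or acetylome
#'
#' Pathway coverage is the number of detected proteins assigned to a pathway
#' divided by the number of genome-encoded proteins assigned to it. Proteins
#' belonging to several pathways count once in each; proteins without an
#' assignment are gathered in a reserved "no pathway assigned" row.
#'
#' @param annotation genome-wide annotation data.frame from
#'   [readPathwayTable()].
#' @param detectedExp,detectedStat character vectors of protein IDs detected
#'   in each phase (quantified proteins for the proteome layer, acetylated
#'   proteins for the acetylome layer).
#' @param layer `"proteome"` or `"acetylome"` (controls the zero-coverage
#'   fold-change convention, see [coverageLog2fc()]).
#' @return data.frame with columns `pathway`, `layer`, `n_genome`,
#'   `n_covered_exp`, `n_covered_stat`, `coverage_exp`, `coverage_stat`,
#'   `log2fc`.
#' @export
pathwayCoverage <- function(annotation, detectedExp, detectedStat,
                            layer = c("proteome", "acetylome")) {
  layer <- match.arg(layer)
  unknown <- setdiff(unique(c(detectedExp, detectedStat)),
                     annotation$protein)
  if (length(unknown))
    stop("detected protein(s) missing from annotation table: ",
         paste(unknown, collapse = ", "))
  paths <- splitPathways(annotation$pathways)
  paths <- lapply(paths, function(p) if (length(p)) p else NO_PATHWAY)
  long <- data.frame(
    protein = rep(annotation$protein, lengths(paths)),
    pathway = unlist(paths), stringsAsFactors = FALSE)
  nGenome <- table(long$pathway)
  pw <- names(nGenome)
  countIn <- function(ids) {
    hit <- long[long$protein %in% ids, , drop = FALSE]
    as.integer(table(factor(hit$pathway, levels = pw)))
  }
  nExp <- countIn(detectedExp)
  nStat <- countIn(detectedStat)
  out <- data.frame(pathway = pw, layer = layer,
                    n_genome = as.integer(nGenome),
                    n_covered_exp = nExp, n_covered_stat = nStat,
                    coverage_exp = nExp / as.integer(nGenome),
                    coverage_stat = nStat / as.integer(nGenome),
                    stringsAsFactors = FALSE)
  out$log2fc <- coverageLog2fc(out$coverage_exp, out$coverage_stat, layer)
  rownames(out) <- NULL
  out[order(out$pathway), ]
}

#' log2 fold change of pathway coverage between phases
#'
#' `log2(coverage_stat / coverage_exp)`. When the exponential-phase coverage
#' is zero the ratio is undefined: for the acetylome layer the fold change is
#' reported as 0 by convention (no acetylated protein detected in the
#' exponential phase), for the proteome layer as NA. Zero coverage in both
#' phases is NA in either layer.
#'
#' @param coverageExp,coverageStat coverages in \[0,1\] (vectorized).
#' @param layer `"proteome"` or `"acetylome"`.
#' @return numeric vector of log2 fold changes.
#' @export
coverageLog2fc <- function(coverageExp, coverageStat,
                           layer = c("proteome", "acetylome")) {
  layer <- match.arg(layer)
  out <- log2(coverageStat / coverageExp)
  zeroExp <- coverageExp == 0
  out[zeroExp] <- if (layer == "acetylome") 0 else NA_real_
  out[coverageExp == 0 & coverageStat == 0] <- NA_real_
  out
}

#' Significance stars for p-values
#'
#' Strict nested thresholds: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star codes (`""` when not significant or NA).
#' @export
significanceStars <- function(p) {
  out <- character(length(p))
  out[!is.na(p) & p < 0.05] <- "*"
  out[!is.na(p) & p < 0.01] <- "**"
  out[!is.na(p) & p < 0.001] <- "***"
  out
}

#' Significance of a pathway coverage change
#'
#' Two-tailed homoscedastic t-test on per-replicate coverages of the two
#' phases (the detected set evaluated separately for each replicate), with
#' the degenerate zero-variance handling of [homoscedasticTTest()].
#'
#' @param coveragesExp,coveragesStat numeric per-replicate coverages.
#' @return list with `p`, `t`, `df`, `stars`, `degenerate`.
#' @export
coverageSignificance <- function(coveragesExp, coveragesStat) {
  fit <- homoscedasticTTest(coveragesExp, coveragesStat)
  c(fit[c("p", "t", "df", "degenerate")],
    list(stars = significanceStars(fit$p)))
}

#' Full pathway coverage table for one layer
#'
#' Combines phase-level coverage (the Fig.-style columns) with per-replicate
#' significance testing.
#'
#' @param annotation genome-wide annotation data.frame.
#' @param detected named list with phase-level detected ID vectors, elements
#'   `exp` and `stat`.
#' @param detectedReplicates optional named list (`exp`, `stat`) of lists of
#'   per-replicate detected ID vectors; when supplied, a t-test on
#'   per-replicate coverages is added.
#' @param layer `"proteome"` or `"acetylome"`.
#' @param adjust apply Benjamini-Hochberg across pathway rows (default FALSE;
#'   pathway rows are reported with raw p-values).
#' @return the [pathwayCoverage()] data.frame plus `p_value`, `p_adj`,
#'   `stars`, `degenerate` columns.
#' @export
pathwayCoverageTable <- function(annotation, detected,
                                 detectedReplicates = NULL,
                                 layer = c("proteome", "acetylome"),
                                 adjust = FALSE) {
  layer <- match.arg(layer)
  out <- pathwayCoverage(annotation, detected$exp, detected$stat, layer)
  out$p_value <- NA_real_
  out$degenerate <- FALSE
  if (!is.null(detectedReplicates)) {
    covByRep <- function(repSets) {
      cols <- lapply(repSets, function(ids) {
        cov <- pathwayCoverage(annotation, ids, ids, layer)
        cov$coverage_exp[match(out$pathway, cov$pathway)]
      })
      matrix(unlist(cols), nrow = nrow(out))
    }
    covExp <- covByRep(detectedReplicates$exp)
    covStat <- covByRep(detectedReplicates$stat)
    for (i in seq_len(nrow(out))) {
      fit <- homoscedasticTTest(covExp[i, ], covStat[i, ])
      out$p_value[i] <- fit$p
      out$degenerate[i] <- fit$degenerate
    }
  }
  out$p_adj <- if (adjust) p.adjust(out$p_value, method = "BH") else NA_real_
  out$stars <- significanceStars(out$p_value)
  out
}
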