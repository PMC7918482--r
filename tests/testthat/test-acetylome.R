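kacRow <- function(..., fraction = "kac_eluate") psmRow(..., fraction = fraction)

test_that("oxidation variants of one acetylated peptide collapse into one site", {
  psms <- psmTable(
    kacRow(peptide = "AMRIKAK", start = 110L, mods = "K5(acetyl)", area = 100),
    kacRow(peptide = "AMRIKAK", start = 110L,
           mods = "K5(acetyl);M2(oxidation)", area = 50),
    kacRow(peptide = "AMRIKAK", start = 110L, mods = "K7(acetyl)", area = 30))
  coll <- collapseOxidationVariants(psms)
  coll <- coll[order(coll$site_spec), ]
  expect_equal(coll$site_spec, c("K114", "K116"))
  expect_equal(coll$area, c(150, 30))
})

test_that("collapsing conserves total MS1 area per sample", {
  set.seed(21)
  peps <- c("AMRIKAK", "MMKAYKPK")
  rows <- lapply(1:40, function(i) {
    p <- sample(peps, 1)
    kacRow(peptide = p, start = 50L,
           mods = if (runif(1) < 0.5) "K5(acetyl)" else
             "K5(acetyl);M2(oxidation)",
           area = runif(1, 1, 100), replicate = sample(1:3, 1),
           phase = sample(c("exponential", "stationary"), 1))
  })
  psms <- do.call(rbind, rows)
  coll <- collapseOxidationVariants(psms)
  for (ph in c("exponential", "stationary")) {
    for (r in 1:3) {
      inRows <- psms$phase == ph & psms$replicate == r
      outRows <- coll$phase == ph & coll$replicate == r
      expect_equal(sum(coll$area[outRows]), sum(psms$area[inRows]))
    }
  }
  ## idempotence: a table with one record per variant group is left unchanged
  unique1 <- psms[!duplicated(psms[c("peptide", "mods", "phase",
                                     "replicate")]), ]
  ## oxidised and unmodified variants of a peptide would still merge, so
  ## compare on a variant-free subset
  noOx <- unique1[!grepl("oxidation", unique1$mods), ]
  coll2 <- collapseOxidationVariants(noOx)
  expect_equal(sort(coll2$area), sort(noOx$area))
  expect_equal(nrow(coll2), nrow(noOx))
})

test_that("ambiguous localization and N-terminal acetylation get their own specs", {
  psms <- psmTable(
    kacRow(peptide = "AMRIKAK", start = 322L, mods = "K5|K7(acetyl)"),
    kacRow(peptide = "MKAYAK", start = 1L, mods = "N-term(acetyl)"),
    kacRow(peptide = "AMRIKAK", start = 7L, mods = "N-term(acetyl)"))
  coll <- collapseOxidationVariants(psms)
  expect_setequal(coll$site_spec,
                  c("K326|K328", "protein-N-term", "peptide-N-term@7"))
  expect_equal(specHasLysine(c("K10", "K3|K5", "protein-N-term",
                               "peptide-N-term@7", "K1+protein-N-term")),
               c(TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("the acetylation ratio is a pure log10 subtraction", {
  expect_equal(estimateAcetylationRatio(2.0, 3.0), -1.0)
  expect_equal(10^estimateAcetylationRatio(2.0, 3.0), 0.1)
  expect_equal(estimateAcetylationRatio(1.23, 1.23), 0)
  set.seed(4)
  a <- rnorm(50); b <- rnorm(50)
  expect_equal(estimateAcetylationRatio(a, b) + b, a)
})

test_that("site phase status follows the detected/quantified footnote rules", {
  expect_equal(sitePhaseStatus(c(TRUE, TRUE, FALSE)), "quantified")
  expect_equal(sitePhaseStatus(c(TRUE, FALSE, FALSE)), "id.")
  expect_equal(sitePhaseStatus(c(FALSE, FALSE, FALSE)), "n.d.")
  ## detected in two replicates but positive area in only one: identified
  expect_equal(sitePhaseStatus(detected = c(TRUE, TRUE, FALSE),
                               quantified = c(TRUE, FALSE, FALSE)), "id.")
})

test_that("site aggregation computes ratios against the protein phase mean", {
  ab <- rbind(P1 = c(3.0, 3.2, 3.1, 3.5, 3.6, 3.7))
  pq <- makeProteinQuant(ab)
  nrm <- log10Norm(pq)
  ## site on P1, quantified in stationary (3 replicates), id. in exponential
  collapsed <- data.frame(
    protein = "P1", peptide = "AAKAYK", site_spec = "K10",
    phase = c("stationary", "stationary", "stationary", "exponential"),
    replicate = c(1L, 2L, 3L, 1L),
    area = c(100, 120, 90, 50), stringsAsFactors = FALSE)
  sites <- aggregateAcetylSites(collapsed, pq)
  expect_equal(sites$status_stationary, "quantified")
  expect_equal(sites$status_exponential, "id.")
  expect_true(is.na(sites$ratio_exponential))
  wantArea <- mean(log10(c(100, 120, 90)))
  wantRatio <- wantArea - mean(nrm["P1", 4:6])
  expect_equal(sites$log10area_stationary, wantArea)
  expect_equal(sites$ratio_stationary, wantRatio)
})

test_that("sites of unquantified proteins keep a missing ratio", {
  ## P1 present in only one exponential replicate -> identified, no ratio
  ab <- rbind(P1 = c(3.0, NA, NA, NA, NA, NA),
              P2 = c(3, 3, 3, 3, 3, 3))
  pq <- makeProteinQuant(ab)
  collapsed <- data.frame(protein = "P1", peptide = "AAKAYK",
                          site_spec = "K10", phase = "exponential",
                          replicate = 1:3, area = c(10, 10, 10),
                          stringsAsFactors = FALSE)
  sites <- aggregateAcetylSites(collapsed, pq)
  expect_equal(sites$status_exponential, "quantified")
  expect_true(is.na(sites$ratio_exponential))
})

test_that("highly acetylated selection honours the threshold presets", {
  sites <- data.frame(protein = c("A", "B", "C"),
                      peptide = "X", site_spec = "K1",
                      ratio_exponential = c(NA, -1.02, NA),
                      ratio_stationary = c(0.84, NA, NA),
                      stringsAsFactors = FALSE)
  expect_equal(classifyHighlyAcetylated(sites, -1.0)$protein, "A")
  expect_equal(classifyHighlyAcetylated(sites, -1.1)$protein, c("A", "B"))
})

test_that("acetylated-protein proportion excludes N-term-only acetylations", {
  ab <- rbind(P1 = c(3, 3, 3, 3, 3, 3),
              P2 = c(3, 3, 3, 3, 3, 3),
              P3 = c(3, NA, NA, 3, 3, 3),
              P4 = c(3, 3, 3, 3, 3, 3))
  pq <- makeProteinQuant(ab)
  sites <- data.frame(
    protein = c("P1", "P2"), peptide = "X",
    site_spec = c("K10", "protein-N-term"),
    status_exponential = c("id.", "quantified"),
    status_stationary = c("n.d.", "quantified"),
    ratio_exponential = NA_real_, ratio_stationary = NA_real_,
    stringsAsFactors = FALSE)
  ## denominator: all four detected; numerator: only P1 (K site, detected)
  expect_equal(acetylatedProteinProportion(pq, sites, "exponential"), 0.25)
  expect_equal(acetylatedProteinProportion(pq, sites, "stationary"), 0)
  expect_error(acetylatedProteinProportion(pq, sites, "lag"), "unknown phase")
})

test_that("multi-site summary counts detected and quantifiable sites per protein", {
  sites <- data.frame(
    protein = c("P1", "P1", "P1", "P2", "P3"),
    peptide = c("A", "B", "C", "D", "E"),
    site_spec = c("K10", "K116", "K121", "K66", "K9"),
    status_exponential = c("quantified", "id.", "n.d.", "quantified", "n.d."),
    status_stationary = c("quantified", "quantified", "quantified", "id.",
                          "n.d."),
    stringsAsFactors = FALSE)
  out <- multiSiteSummary(sites)
  expect_equal(out$protein, c("P1", "P2"))
  expect_equal(out$n_detected, c(3L, 1L))
  expect_equal(out$n_quantifiable, c(3L, 1L))
})
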