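test_that("PSM filter applies strict q-value and XCorr thresholds", {
  psms <- psmTable(
    psmRow(qvalue = 0.005, xcorr = 2.5),                 # kept
    psmRow(qvalue = 0.02, xcorr = 3.0),                  # q too high
    psmRow(qvalue = 0.001, xcorr = 2.0),                 # XCorr boundary
    psmRow(qvalue = 0.01, xcorr = 3.0),                  # q boundary
    psmRow(qvalue = 0.001, xcorr = 5, protein = "cRAP_X",
           contaminant = TRUE))
  kept <- filterPsms(psms)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$qvalue, 0.005)
})

test_that("top-3 roll-up averages the three largest areas", {
  expect_equal(top3Abundance(c(10, 20, 30, 40)), 30)
  expect_equal(top3Abundance(c(10, 20)), 15)
  expect_equal(top3Abundance(7), 7)
  expect_true(is.na(top3Abundance(numeric())))
  expect_true(is.na(top3Abundance(c(0, 0))))
  expect_true(is.na(top3Abundance(c(10, 20), strict = TRUE)))
})

test_that("top-3 matches the sort-and-mean oracle on random inputs", {
  set.seed(11)
  for (i in 1:200) {
    x <- runif(sample(1:8, 1), 0, 1e6)
    expect_equal(top3Abundance(x), top3Oracle(x))
  }
})

test_that("quantification status follows the replicate-majority rule", {
  expect_equal(quantificationStatus(c(TRUE, TRUE, FALSE)), "quantified")
  expect_equal(quantificationStatus(c(TRUE, FALSE, FALSE)), "identified")
  expect_equal(quantificationStatus(c(FALSE, FALSE, FALSE)), "absent")
  ## 2 of 4 is exactly 50%: not strictly more than half
  expect_equal(quantificationStatus(c(TRUE, TRUE, FALSE, FALSE)), "identified")
})

test_that("median normalization centers samples and zeroes the global minimum", {
  one <- matrix(c(1, 2, 3), ncol = 1)
  expect_equal(as.vector(normalizeAbundances(one)), c(0, 1, 2))

  two <- cbind(A = c(1, 3), B = c(2, 6))
  norm <- normalizeAbundances(two)
  expect_equal(unname(norm[, "A"]), c(1, 3))
  expect_equal(unname(norm[, "B"]), c(0, 4))

  flat <- matrix(c(5, 5, 5), ncol = 1)
  nf <- normalizeAbundances(flat)
  expect_equal(as.vector(nf), c(0, 0, 0))

  allna <- cbind(c(1, 2), c(NA_real_, NA_real_))
  expect_error(normalizeAbundances(allna), "no present values")
})

test_that("normalization is invariant to per-sample multiplicative rescaling", {
  set.seed(3)
  mat <- matrix(rnorm(60, 3, 0.6), ncol = 6)
  mat[sample(60, 10)] <- NA
  norm1 <- normalizeAbundances(mat)
  scaled <- mat
  scaled[, 2] <- scaled[, 2] + 1  # linear areas of sample 2 times 10
  norm2 <- normalizeAbundances(scaled)
  expect_equal(norm1, norm2, ignore_attr = TRUE)
  expect_equal(min(norm1, na.rm = TRUE), 0)
  meds <- apply(norm1, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(attr(norm1, "globalShift"), 6))
})

test_that("homoscedastic t-test matches the closed-form oracle", {
  fit <- homoscedasticTTest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(fit$t), 3.674, tolerance = 1e-3)
  expect_equal(fit$df, 4)
  want <- tOracle(c(1, 2, 3), c(4, 5, 6))
  expect_equal(fit$p, want$p)
  expect_equal(fit$p, 0.0214, tolerance = 5e-3)

  same <- homoscedasticTTest(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(3:50, 1))
    expect_equal(p.adjust(p, "BH"), bhStepUp(p))
  }
})

test_that("protein quantification rolls PSMs up to peptides and drops shared peptides", {
  psms <- psmTable(
    ## P1, exponential replicate 1: peptide areas 10+30, 20, 30, 40
    psmRow(peptide = "AAAAAK", area = 10),
    psmRow(peptide = "AAAAAK", area = 30),   # same peptide, summed -> 40
    psmRow(peptide = "CCCCCK", area = 20),
    psmRow(peptide = "DDDDDK", area = 30),
    psmRow(peptide = "EEEEEK", area = 40),
    ## shared peptide must be excluded from both proteins
    psmRow(peptide = "SHAREDK", area = 1000),
    psmRow(peptide = "SHAREDK", area = 1000, protein = "P2"),
    psmRow(peptide = "GGGGGK", protein = "P2", area = 50, replicate = 2L))
  pq <- suppressMessages(quantifyProteins(psms, nReplicates = 3L))
  raw <- log10Raw(pq)
  ## top3 of P1 = mean(40, 40, 30)
  expect_equal(raw["P1", "exponential_1"], log10(mean(c(40, 40, 30))))
  expect_equal(raw["P2", "exponential_2"], log10(50))
  st <- proteinStatus(pq)
  expect_equal(unname(st["P1", ]), c("identified", "absent"))
})

test_that("phase fold changes test only proteins quantified in both phases", {
  ab <- rbind(P1 = c(1, 2, 3, 4, 5, 6),
              P2 = c(2, 2, NA, 3, 3, NA),
              P3 = c(1, NA, NA, 2, 2, 2))
  pq <- suppressMessages(makeProteinQuant(ab))
  fc <- phaseFoldChanges(pq)
  expect_equal(fc$tested, c(TRUE, TRUE, FALSE))
  p1 <- fc[fc$protein == "P1", ]
  nrm <- log10Norm(pq)
  expect_equal(p1$log10fc, mean(nrm["P1", 4:6]) - mean(nrm["P1", 1:3]))
  expect_equal(p1$log2fc, p1$log10fc / log10(2))
  want <- tOracle(nrm["P1", 1:3], nrm["P1", 4:6])
  expect_equal(p1$p_value, want$p)
  expect_equal(fc$p_adj[fc$tested], bhStepUp(fc$p_value[fc$tested]))
  expect_true(is.na(fc$p_value[3]))
})
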