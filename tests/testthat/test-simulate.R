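smallIdeal <- function(n = 40L, seedT = 101L, seedS = 202L) {
  truth <- buildTruth(idealSimConfig(n_proteins = n), seed = seedT)
  list(truth = truth, sim = simulateExperiment(truth, seed = seedS))
}

test_that("truth generation is deterministic and satisfies its invariants", {
  cfg <- defaultSimConfig(n_proteins = 80L)
  t1 <- buildTruth(cfg, seed = 5)
  t2 <- buildTruth(cfg, seed = 5)
  expect_identical(t1$proteins, t2$proteins)
  expect_identical(t1$sites, t2$sites)

  expect_true(all(t1$sites$stoich_exp >= 0 & t1$sites$stoich_exp <= 1))
  expect_true(all(t1$sites$stoich_stat > 0 & t1$sites$stoich_stat <= 1))
  ## every site position is a lysine of its protein
  seqs <- setNames(t1$proteins$sequence, t1$proteins$protein)
  res <- substring(seqs[t1$sites$protein], t1$sites$position,
                   t1$sites$position)
  expect_true(all(res == "K"))
  ## exponential-phase acetylation is a subset of the stationary set
  expect_true(all(t1$sites$protein[t1$sites$stoich_exp > 0] %in%
                    t1$sites$protein[t1$sites$stoich_stat > 0]))
  expect_true(all(is.finite(t1$proteins$log10_exp)))
})

test_that("degenerate truth configurations behave as configured", {
  none <- buildTruth(defaultSimConfig(n_proteins = 30L,
                                      prevalence_exponential = 0,
                                      prevalence_stationary = 0), seed = 3)
  expect_equal(nrow(none$sites), 0L)
  flat <- buildTruth(defaultSimConfig(n_proteins = 10L, abundance_sd = 0,
                                      phase_effect_fraction = 0), seed = 3)
  expect_true(all(flat$proteins$log10_exp == 3.0))
  expect_identical(flat$proteins$log10_exp, flat$proteins$log10_stat)
})

test_that("simulated tables are deterministic and schema-valid", {
  x <- smallIdeal()
  y <- simulateExperiment(x$truth, seed = 202L)
  expect_identical(x$sim$proteome_psms, y$proteome_psms)
  expect_identical(x$sim$kac_psms, y$kac_psms)

  ## round trip through the canonical writers/readers
  dir <- tempfile()
  writeSimulatedExperiment(x$sim, dir, truth = x$truth)
  back <- readPsmTable(file.path(dir, "kac_psms.tsv"))
  expect_equal(nrow(back), nrow(x$sim$kac_psms))
  fasta <- readProteinFasta(file.path(dir, "proteins.fasta"))
  expect_equal(length(fasta), 40L)
})

test_that("contaminant records are exactly the rows the filters remove", {
  cfg <- defaultSimConfig(n_proteins = 40L, contaminant_fraction = 0.1,
                          dropout = 0)
  sim <- simulateExperiment(buildTruth(cfg, seed = 31), seed = 32)
  psms <- sim$proteome_psms
  expect_gt(sim$n_contaminants[["proteome"]], 0)
  kept <- filterPsms(psms)
  expect_equal(nrow(kept), nrow(psms) - sim$n_contaminants[["proteome"]])
  expect_false(any(kept$contaminant))
  ## contaminant share close to the configured fraction
  expect_lt(abs(mean(psms$contaminant) - 0.1), 0.01)
})

test_that("zero-noise Kac areas equal abundance x stoichiometry exactly", {
  x <- smallIdeal()
  sim <- x$sim
  coll <- collapseOxidationVariants(
    filterPsms(sim$kac_psms), proteins = sim$fasta)
  truthKey <- sprintf("%s:%s", sim$truth_sites$protein,
                      sim$truth_sites$site_spec)
  abund <- x$truth$proteins
  for (ph in c("exponential", "stationary")) {
    sub <- coll[coll$phase == ph, ]
    i <- match(sprintf("%s:%s", sub$protein, sub$site_spec), truthKey)
    expect_false(anyNA(i))
    stoich <- if (ph == "exponential") sim$truth_sites$stoich_exp[i]
              else sim$truth_sites$stoich_stat[i]
    a <- if (ph == "exponential")
      abund$log10_exp[match(sub$protein, abund$protein)]
    else abund$log10_stat[match(sub$protein, abund$protein)]
    expect_equal(sub$area, 10^a * stoich)
  }
  ## oxidation split halves were re-merged: one row per site x sample
  expect_false(any(duplicated(
    coll[c("protein", "site_spec", "phase", "replicate")])))
})

test_that("dropout removes records at about the configured rate, low areas first", {
  cfg <- defaultSimConfig(n_proteins = 60L, contaminant_fraction = 0)
  truth <- buildTruth(cfg, seed = 41)
  simFull <- simulateExperiment(buildTruth(
    defaultSimConfig(n_proteins = 60L, contaminant_fraction = 0,
                     dropout = 0), seed = 41), seed = 42)
  simDrop <- simulateExperiment(truth, seed = 42)
  lost <- 1 - nrow(simDrop$proteome_psms) / nrow(simFull$proteome_psms)
  expect_lt(abs(lost - 0.2), 0.03)
  ## surviving records are richer in high areas than the full table
  expect_gt(median(simDrop$proteome_psms$area),
            median(simFull$proteome_psms$area))
})
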