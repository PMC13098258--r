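test_that("mutateSequence preserves length, respects rate bounds, is seeded", {
  set.seed(1)
  s <- randomSeq(500)
  expect_identical(mutateSequence(s, 0), s)

  set.seed(7); a <- mutateSequence(s, 0.1)
  set.seed(7); b <- mutateSequence(s, 0.1)
  expect_identical(a, b)
  expect_identical(nchar(a), nchar(s))

  # L = 10000, d = 0.01: Binomial(10000, 0.01) puts > 99.9% of its mass
  # in [60, 140] mismatches (qbinom(c(5e-4, 1 - 5e-4), 1e4, 0.01) = 69/133)
  set.seed(11)
  s2 <- randomSeq(10000)
  m <- mutateSequence(s2, 0.01)
  dHat <- sum(strsplit(s2, "")[[1]] != strsplit(m, "")[[1]]) / 10000
  expect_gt(dHat, 0.006)
  expect_lt(dHat, 0.014)

  expect_error(mutateSequence(s, -0.1), "0.75")
  expect_error(mutateSequence(s, 0.9), "0.75")
  expect_error(mutateSequence("ACGN", 0.1), "A, C, G, T")
  expect_error(mutateSequence("", 0.1), "nonempty")
})

test_that("simulateGenomeCollection counts, ids, and determinism", {
  cfg <- simConfig(nSpecies = 3, unitsPerSpecies = 2, magsPerUnit = 5,
                   genomeLength = 2000, nSamples = 10, rngSeed = 5)
  sim <- simulateGenomeCollection(cfg)
  tr <- truthAssignment(sim)
  expect_identical(nrow(tr), 30L)
  expect_identical(length(genomes(sim)), 30L)
  expect_identical(length(unique(tr$species)), 3L)
  expect_identical(nrow(unique(tr[, c("species", "unit")])), 6L)
  expect_false(is.unsorted(tr$mag_id))
  expect_identical(anyDuplicated(tr$mag_id), 0L)

  sim2 <- simulateGenomeCollection(cfg)
  expect_identical(as.character(genomes(sim)), as.character(genomes(sim2)))
  expect_identical(truthAssignment(sim), truthAssignment(sim2))
})

test_that("config invariants are enforced", {
  expect_error(simConfig(dWithinUnit = 0.006), "dWithinUnit")
  expect_error(simConfig(dBetweenUnits = 0.01), "dBetweenUnits")
  expect_error(simConfig(dBetweenUnits = 0.05), "dBetweenUnits")
  expect_error(simConfig(dBetweenSpecies = 0.04), "dBetweenSpecies")
  expect_error(simConfig(magsPerUnit = 50, nSamples = 30), "nSamples")
  expect_error(simConfig(novelFraction = 1.2), "novelFraction")
})

test_that("generated collections realize the configured ANI bands", {
  sim <- smallPlantedSim(seed = 31, nSpecies = 3, unitsPerSpecies = 2,
                         magsPerUnit = 3)
  tr <- truthAssignment(sim)
  ani <- aniValues(pairwiseANI(genomes(sim), method = "exact_hamming"))
  ids <- tr$mag_id
  for (i in seq_along(ids)[-1]) for (j in seq_len(i - 1)) {
    a <- ani[ids[i], ids[j]]
    sameSpecies <- tr$species[i] == tr$species[j]
    sameUnit <- sameSpecies && tr$unit[i] == tr$unit[j]
    if (sameUnit) expect_gt(a, 0.99)
    else if (sameSpecies) { expect_gt(a, 0.95); expect_lt(a, 0.99) }
    else expect_lt(a, 0.95)
  }
})

test_that("single-unit species collapse to GUN 1 downstream", {
  sim <- smallPlantedSim(seed = 13, nSpecies = 3, unitsPerSpecies = 1,
                         magsPerUnit = 4, genomeLength = 10000)
  ani <- pairwiseANI(genomes(sim), method = "exact_hamming")
  cl <- clusterGenomes(ani)
  rep <- gunTable(cl, minMags = 1)
  expect_identical(nrow(rep), 3L)
  expect_true(all(rep$gun == 1L))
})

test_that("quality metadata marginals, forcing, and reproducibility", {
  truth <- data.frame(mag_id = sprintf("M%05d", 1:10000),
                      species = 1L, unit = 1L, sample_id = "SA0001")
  q <- simulateQualityMetadata(truth, seed = 3)
  expect_identical(nrow(q), 10000L)
  expect_true(all(q$completeness > 50 & q$completeness <= 100))
  expect_true(all(q$contamination >= 0 & q$contamination < 15))
  expect_true(all(q$strain_het >= 0 & q$strain_het <= 100))
  expect_true(all(q$n50 >= 1))
  expect_true(all(q$rrna_5s %in% 0:1))
  # law of large numbers: truncated-normal mean sits between the configured
  # location (88) and the truncation-inflated value; within 3 of 88
  expect_lt(abs(mean(q$completeness) - 88), 3)

  q2 <- simulateQualityMetadata(truth, seed = 3)
  expect_identical(q, q2)

  # forced parameters make every MAG high-quality downstream
  forced <- simulateQualityMetadata(truth[1:50, ],
                                    params = list(rrnaProb = 1,
                                                  trnaLambda = 40),
                                    seed = 5)
  forced$completeness <- 95; forced$contamination <- 1
  forced$trna_count <- pmax(forced$trna_count, 18)
  tiers <- classifyTier(forced$completeness, forced$contamination,
                        forced$rrna_5s, forced$rrna_16s, forced$rrna_23s,
                        forced$trna_count)
  expect_true(all(tiers$tier == "HQ"))
})

test_that("cohort tables close to 1, hit disease prevalence, stay seeded", {
  dc <- data.frame(disease = c("dz_null", "dz_eff"),
                   prevalence = c(0.3, 0.25),
                   speciesBeta = c(0, 0.8), unitLogOR = c(0, log(0.5)),
                   targetSpecies = c(1, 2), targetUnit = c(1, 1))
  cfg <- simConfig(nSpecies = 4, unitsPerSpecies = 2, magsPerUnit = 20,
                   genomeLength = 1000, nSamples = 400,
                   diseaseConfigs = dc, rngSeed = 17)
  sim <- simulateGenomeCollection(cfg)
  tb <- simulateCohortTables(sim, seed = 4)
  expect_true(all(abs(rowSums(tb$abundance) - 1) < 1e-9))
  expect_true(all(tb$abundance >= 0))
  # calibrated intercepts land near target prevalences (binomial noise)
  expect_lt(abs(mean(tb$phenotypes$dz_null) - 0.3), 0.08)
  expect_lt(abs(mean(tb$phenotypes$dz_eff) - 0.25), 0.08)
  # recovery bookkeeping: every recovered (sample, species) is present
  hit <- tb$abundance[cbind(match(tb$recovery$sample_id,
                                  rownames(tb$abundance)),
                            tb$recovery$species)]
  expect_true(all(hit > 0))
  tb2 <- simulateCohortTables(sim, seed = 4)
  expect_identical(tb, tb2)
  expect_error(
    simulateCohortTables(simulateGenomeCollection(simConfig(
      nSpecies = 2, nSamples = 10, genomeLength = 1000,
      diseaseConfigs = data.frame(disease = "d", prevalence = 1.5,
                                  speciesBeta = 0, unitLogOR = 0,
                                  targetSpecies = 1, targetUnit = 1)))),
    "prevalence")
})

test_that("writeCohort emits FASTA per MAG and the TSV tables", {
  sim <- smallPlantedSim(seed = 23, nSpecies = 2, unitsPerSpecies = 1,
                         magsPerUnit = 2, genomeLength = 1000, nSamples = 5)
  q <- simulateQualityMetadata(sim, seed = 1)
  tb <- simulateCohortTables(sim, seed = 1)
  d <- withr::local_tempdir()
  files <- writeCohort(sim, q, tb, d)
  expect_identical(length(list.files(file.path(d, "fasta"))), 4L)
  ab <- read.table(file.path(d, "abundance.tsv"), sep = "\t", header = TRUE)
  expect_identical(nrow(ab), 5L)
  back <- Biostrings::readDNAStringSet(files[1])
  expect_identical(as.character(back)[[1]],
                   as.character(genomes(sim))[[1]])
})
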