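aniMat <- function(v, ids) {
  m <- matrix(v, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- 1
  m
}

test_that("threshold clustering splits and merges as expected", {
  m <- aniMat(0.999, c("a", "b", "c"))
  expect_identical(unname(clusterAtThreshold(m, 0.95)), rep(1L, 3))

  m2 <- aniMat(0.93, c("a", "b"))
  expect_identical(unname(clusterAtThreshold(m2, 0.95)), c(1L, 2L))

  expect_error(clusterAtThreshold(m, 1.2), "threshold")

  # labels ordered by size, then smallest member id
  m3 <- aniMat(0, c("x", "a", "b", "c"))
  m3["a", "b"] <- m3["b", "a"] <- 0.99
  expect_identical(clusterAtThreshold(m3, 0.95),
                   c(a = 1L, b = 1L, c = 2L, x = 3L))
})

test_that("genome units cut within a species at 99% ANI", {
  ids <- c("m1", "m2", "m3")
  allClose <- aniMat(0.996, ids)
  expect_identical(length(unique(clusterGenomeUnits(ids, allClose))), 1L)

  spread <- aniMat(0.97, ids)
  expect_identical(length(unique(clusterGenomeUnits(ids, spread))), 3L)

  expect_error(clusterGenomeUnits(character(), allClose), "empty")
})

test_that("planted species and units are recovered exactly (oracle check)", {
  sim <- smallPlantedSim(seed = 59)
  tr <- truthAssignment(sim)
  truthSpecies <- setNames(tr$species, tr$mag_id)
  truthUnits <- setNames(paste(tr$species, tr$unit), tr$mag_id)

  for (m in c("exact_hamming", "sketch")) {
    ani <- pairwiseANI(genomes(sim), method = m)
    sp <- clusterAtThreshold(ani, 0.95)
    expect_true(samePartition(sp, truthSpecies))
    cl <- clusterGenomes(ani)
    units <- setNames(clusterTable(cl)$genome_unit_id,
                      clusterTable(cl)$mag_id)
    expect_true(samePartition(units, truthUnits))
  }
})

test_that("genome scoring matches its formula and dominance ordering", {
  expect_equal(scoreGenome(100, 0, 0, 1e6), 103.0)
  expect_gt(scoreGenome(95, 1, 0, 1e5), scoreGenome(80, 0.5, 0, 1e5))
  expect_error(scoreGenome(101, 0), "completeness")
  expect_error(scoreGenome(90, 0, 0, 0), "N50")

  # ranking agrees with an independently written comparator on 100 tuples
  set.seed(31)
  comp <- runif(100, 50, 100); cont <- runif(100, 0, 10)
  het <- runif(100, 0, 50); n50 <- 10^runif(100, 3, 7)
  got <- order(scoreGenome(comp, cont, het, n50))
  want <- order(comp - 5 * cont - 0.1 * het + 0.5 * log(n50) / log(10))
  expect_identical(got, want)
})

test_that("representative selection: argmax score, ties to smallest id", {
  expect_identical(selectRepresentative("m9", c(m9 = 1)), "m9")
  expect_identical(selectRepresentative(c("m2", "m1"), c(m1 = 5, m2 = 5)),
                   "m1")
  expect_identical(selectRepresentative(c("m1", "m2"), c(m1 = 1, m2 = 7)),
                   "m2")
  expect_error(selectRepresentative(character(), numeric()), "empty")
})

test_that("clusterGenomes nests units in species and flags representatives", {
  sim <- smallPlantedSim(seed = 61, nSpecies = 3, unitsPerSpecies = 3,
                         magsPerUnit = 2)
  q <- simulateQualityMetadata(sim, seed = 2)
  ani <- pairwiseANI(genomes(sim), method = "exact_hamming")
  cl <- clusterGenomes(ani, quality = q)
  tb <- clusterTable(cl)

  # nesting: each unit belongs to exactly one species
  nest <- tapply(tb$species_cluster_id, tb$genome_unit_id,
                 function(x) length(unique(x)))
  expect_true(all(nest == 1))
  # one representative per species, member of its own cluster
  reps <- representatives(cl)
  expect_identical(nrow(reps), 3L)
  expect_true(all(tb$species_cluster_id[match(reps$mag_id, tb$mag_id)] ==
                    reps$species_cluster_id))
  # planted best-quality MAG wins in its cluster
  scores <- setNames(scoreGenome(q$completeness, q$contamination,
                                 q$strain_het, q$n50), q$mag_id)
  for (r in seq_len(nrow(reps))) {
    members <- tb$mag_id[tb$species_cluster_id == reps$species_cluster_id[r]]
    expect_identical(reps$mag_id[r], selectRepresentative(members, scores))
  }
  # threshold monotonicity: at least as many units as species
  expect_gte(length(unique(tb$genome_unit_id)),
             length(unique(tb$species_cluster_id)))
})

test_that("collection merge keeps the better representative per species", {
  # disjoint collections: union of species
  ids <- c("a1", "a2", "b1", "b2")
  m <- aniMat(0.5, ids)
  q <- data.frame(mag_id = ids, completeness = c(90, 85, 80, 95),
                  contamination = 1, strain_het = 0, n50 = 1e5)
  mg <- mergeCollections(m, c("a1", "a2"), c("b1", "b2"), q,
                         taxonomy = c(a1 = "s__x", a2 = NA))
  expect_identical(nrow(mg), 4L)
  expect_setequal(mg$category[mg$source == "A"],
                  c("known_absent_from_B", "novel"))
  expect_true(all(mg$category[mg$source == "B"] == "B_only"))

  # one shared species, A rep scores higher -> replacement from A
  ids2 <- c("a1", "b1")
  m2 <- aniMat(0.97, ids2)
  q2 <- data.frame(mag_id = ids2, completeness = c(95, 85),
                   contamination = 1, strain_het = 0, n50 = 1e5)
  mg2 <- mergeCollections(m2, "a1", "b1", q2, taxonomy = c(a1 = "s__x"))
  expect_identical(mg2$source, "A")
  expect_identical(mg2$category, "higher_quality_replacement")
  # and B wins when B scores higher
  q2$completeness <- c(85, 95)
  mg3 <- mergeCollections(m2, "a1", "b1", q2, taxonomy = c(a1 = "s__x"))
  expect_identical(mg3$source, "B")
  expect_identical(mg3$category, "B_only")

  expect_error(mergeCollections(m2, "a1", "a1", q2), "share")
})

test_that("synthetic merge recovers planted category counts", {
  set.seed(71)
  # 6 planted species: 2 shared (one won by A, one by B), 2 A-only
  # (one labelled, one novel), 2 B-only
  anchors <- replicate(6, randomSeq(10000))
  seqs <- list(
    sharedA_win_a = anchors[1], sharedA_win_b = mutateSequence(anchors[1], 0.01),
    sharedB_win_a = anchors[2], sharedB_win_b = mutateSequence(anchors[2], 0.01),
    onlyA_known = anchors[3], onlyA_novel = anchors[4],
    onlyB_1 = anchors[5], onlyB_2 = anchors[6])
  ani <- pairwiseANI(seqs, method = "exact_jaccard")
  idsA <- c("sharedA_win_a", "sharedB_win_a", "onlyA_known", "onlyA_novel")
  idsB <- setdiff(names(seqs), idsA)
  q <- data.frame(mag_id = names(seqs),
                  completeness = c(95, 80, 90, 70, 90, 90, 90, 90),
                  contamination = 0, strain_het = 0, n50 = 1e5)
  q$completeness[q$mag_id == "sharedA_win_b"] <- 80
  q$completeness[q$mag_id == "sharedB_win_b"] <- 95
  q$completeness[q$mag_id == "sharedB_win_a"] <- 80
  mg <- mergeCollections(ani, idsA, idsB, q,
                         taxonomy = c(sharedA_win_a = "s__s1",
                                      sharedB_win_a = "s__s2",
                                      onlyA_known = "s__s3",
                                      onlyA_novel = NA))
  expect_identical(nrow(mg), 6L)
  counts <- table(mg$category)
  expect_identical(unname(counts["novel"]), 1L)
  expect_identical(unname(counts["known_absent_from_B"]), 1L)
  expect_identical(unname(counts["higher_quality_replacement"]), 1L)
  expect_identical(unname(counts["B_only"]), 3L)
})
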