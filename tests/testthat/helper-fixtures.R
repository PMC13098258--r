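# shared fixture builders; everything is generated in code at test time

randomSeq <- function(L) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

# small planted collection used by several clustering tests
smallPlantedSim <- function(seed = 101, nSpecies = 5, unitsPerSpecies = 2,
                            magsPerUnit = 3, genomeLength = 20000,
                            nSamples = 20) {
  simulateGenomeCollection(simConfig(
    nSpecies = nSpecies, unitsPerSpecies = unitsPerSpecies,
    magsPerUnit = magsPerUnit, genomeLength = genomeLength,
    nSamples = nSamples, rngSeed = seed))
}

# phenotype frame with covariates and one bernoulli disease
nullPhenotypes <- function(n, diseaseProb = 0.3, prefix = "SA") {
  data.frame(sample_id = sprintf("%s%05d", prefix, seq_len(n)),
             age = runif(n, 23, 89),
             sex = rbinom(n, 1, 0.7),
             bmi = rnorm(n, 26, 4),
             dz = rbinom(n, 1, diseaseProb))
}

# zero-inflated log-normal abundance matrix closed to relative abundances
nullAbundance <- function(nSamples, nSpecies, presenceProb = 0.7) {
  load <- matrix(rlnorm(nSamples * nSpecies), nSamples, nSpecies) *
    matrix(rbinom(nSamples * nSpecies, 1, presenceProb), nSamples, nSpecies)
  empty <- rowSums(load) == 0
  load[empty, 1] <- rlnorm(sum(empty))
  dimnames(load) <- list(sprintf("SA%05d", seq_len(nSamples)),
                         sprintf("SP%04d", seq_len(nSpecies)))
  load / rowSums(load)
}

# truth-vs-found agreement; exact-match helper for planted partitions
samePartition <- function(found, truthLabels) {
  stopifnot(identical(names(found), names(truthLabels)) ||
              all(names(truthLabels) %in% names(found)))
  truthLabels <- truthLabels[names(found)]
  length(unique(paste(found, truthLabels))) == length(unique(found)) &&
    length(unique(found)) == length(unique(truthLabels))
}

# draw a disease from a logistic model with intercept calibrated to
# a target prevalence (mirrors the generator's phenotype model)
drawDisease <- function(offset, prevalence) {
  b0 <- uniroot(function(b) mean(plogis(b + offset)) - prevalence,
                c(-30, 30))$root
  rbinom(length(offset), 1, plogis(b0 + offset))
}
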