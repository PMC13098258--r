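#' Build a synthetic cohort configuration
#'
#' The defaults encode the ANI hierarchy the clustering stages assume:
#' members of one genome unit diverge by ~0.2% (ANI ~99.8%), unit centers
#' of one species by ~1.5% (ANI ~98.5%), and species ancestors by ~10%
#' (ANI ~90%). Distances are per-site substitution rates along a star
#' phylogeny; each branch applies half of the stated pairwise distance.
#'
#' @param nSpecies number of species.
#' @param unitsPerSpecies units per species, scalar or per-species vector.
#' @param magsPerUnit MAGs per unit, scalar or per-species vector; each
#'   MAG originates from a distinct cohort sample, so this cannot exceed
#'   `nSamples`.
#' @param genomeLength genome length in bases (default 20000).
#' @param dBetweenUnits,dWithinUnit,dBetweenSpecies per-site substitution
#'   distances (pairwise) at the three levels of the hierarchy.
#' @param nSamples cohort size.
#' @param novelFraction fraction of species left without a taxonomy label.
#' @param diseaseConfigs data.frame describing planted diseases; see
#'   [SimConfig-class]. Default: none.
#' @param rngSeed integer seed used by [simulateGenomeCollection()].
#' @return a validated [SimConfig-class] object.
#' @export
simConfig <- function(nSpecies = 5, unitsPerSpecies = 2, magsPerUnit = 5,
                      genomeLength = 20000, dBetweenUnits = 0.015,
                      dWithinUnit = 0.002, dBetweenSpecies = 0.10,
                      nSamples = 30, novelFraction = 0.2,
                      diseaseConfigs = NULL, rngSeed = 1) {
  if (is.null(diseaseConfigs))
    diseaseConfigs <- data.frame(disease = character(), prevalence = numeric(),
                                 speciesBeta = numeric(), unitLogOR = numeric(),
                                 targetSpecies = integer(),
                                 targetUnit = integer())
  new("SimConfig",
      nSpecies = as.integer(nSpecies),
      unitsPerSpecies = as.integer(rep_len(unitsPerSpecies, nSpecies)),
      magsPerUnit = as.integer(rep_len(magsPerUnit, nSpecies)),
      genomeLength = as.integer(genomeLength),
      dBetweenUnits = dBetweenUnits, dWithinUnit = dWithinUnit,
      dBetweenSpecies = dBetweenSpecies, nSamples = as.integer(nSamples),
      novelFraction = novelFraction, diseaseConfigs = diseaseConfigs,
      rngSeed = as.integer(rngSeed))
}

#' Mutate a sequence by independent per-site substitution
#'
#' Each site is substituted with probability `d` to a base chosen
#' uniformly among the three alternatives. Length is preserved; no indels
#' are introduced, so Hamming distance is an exact divergence oracle for
#' generated pairs. Uses the current RNG state.
#'
#' @param seq single nucleotide string over A/C/G/T.
#' @param d per-site substitution probability, `0 <= d < 0.75`.
#' @return mutated sequence of identical length.
#' @export
mutateSequence <- function(seq, d) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("seq must be a single nonempty string")
  if (!grepl("^[ACGTacgt]+$", seq))
    stop("seq must contain only A, C, G, T")
  if (!is.numeric(d) || length(d) != 1L || d < 0 || d >= 0.75)
    stop("d must lie in [0, 0.75)")
  bases <- c("A", "C", "G", "T")
  v <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  hit <- which(runif(length(v)) < d)
  if (length(hit)) {
    old <- match(v[hit], bases)
    # uniform among the 3 other bases: cyclic offset 1..3
    off <- sample.int(3L, length(hit), replace = TRUE)
    v[hit] <- bases[((old - 1L + off) %% 4L) + 1L]
  }
  paste(v, collapse = "")
}

#' Simulate a MAG collection with a planted species / genome-unit hierarchy
#'
#' Star-phylogeny generation: a random root genome is mutated at rate
#' `dBetweenSpecies / 2` into each species ancestor, each ancestor at
#' `dBetweenUnits / 2` into its unit centers, and each center at
#' `dWithinUnit / 2` into its member MAGs, so realized pairwise distances
#' concentrate near the configured values. Each MAG is assigned a distinct
#' sample of origin within its unit. Seeded from `cfg@rngSeed`; identical
#' configs yield byte-identical output.
#'
#' @param cfg a [SimConfig-class].
#' @return a [MagSimulation-class].
#' @export
simulateGenomeCollection <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(cfg@rngSeed)
  L <- cfg@genomeLength
  root <- randomGenome(L)

  nNovel <- round(cfg@novelFraction * cfg@nSpecies)
  novelIdx <- if (nNovel > 0) sort(sample.int(cfg@nSpecies, nNovel))
              else integer()
  phyla <- c("Bacillota", "Bacteroidota", "Bacillota_A", "Pseudomonadota",
             "Verrucomicrobiota", "Cyanobacteriota")

  seqs <- character(); truth <- list(); magNo <- 0L
  for (i in seq_len(cfg@nSpecies)) {
    ancestor <- mutateSequence(root, cfg@dBetweenSpecies / 2)
    for (j in seq_len(cfg@unitsPerSpecies[i])) {
      center <- mutateSequence(ancestor, cfg@dBetweenUnits / 2)
      origin <- sort(sample.int(cfg@nSamples, cfg@magsPerUnit[i]))
      for (l in seq_len(cfg@magsPerUnit[i])) {
        magNo <- magNo + 1L
        id <- sprintf("MAG%05d", magNo)
        seqs[[id]] <- mutateSequence(center, cfg@dWithinUnit / 2)
        truth[[id]] <- data.frame(
          mag_id = id, species = i, unit = j,
          sample_id = sprintf("SA%04d", origin[l]))
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  spec <- data.frame(
    species = seq_len(cfg@nSpecies),
    species_id = sprintf("SP%03d", seq_len(cfg@nSpecies)),
    taxonomy = sprintf("s__Simulobacter sp%03d", seq_len(cfg@nSpecies)),
    phylum = sample(phyla, cfg@nSpecies, replace = TRUE))
  spec$taxonomy[novelIdx] <- NA_character_

  new("MagSimulation",
      genomes = Biostrings::DNAStringSet(unlist(seqs)),
      truth = truth, species = spec, config = cfg)
}

#' Default parameters for simulated per-MAG quality metadata
#'
#' Marginals chosen to resemble a cohort-scale short-read binning run:
#' roughly half of MAGs almost complete, a long contamination tail, and
#' rRNA detection the limiting factor for high-quality tier membership.
#'
#' @return named list of marginal parameters.
#' @export
qualityParams <- function() {
  list(completenessMean = 88, completenessSd = 8,
       contaminationMean = 2.5, strainHetMean = 5,
       n50Meanlog = log(5e4), n50Sdlog = 1,
       rrnaProb = 0.72, trnaLambda = 35)
}

#' Simulate per-MAG quality metadata
#'
#' Completeness is truncated normal on (50, 100]; contamination is
#' exponential clipped below 15; strain heterogeneity exponential clipped
#' to \[0, 100\]; N50 log-normal; the three rRNA genes independent
#' Bernoulli; tRNA count Poisson.
#'
#' @param truth a [MagSimulation-class] or its truth data.frame.
#' @param params marginal parameters, see [qualityParams()]. Individual
#'   entries may be overridden.
#' @param seed optional integer seed; default uses the current RNG state.
#' @return data.frame with one row per MAG: `mag_id`, `sample_id`,
#'   `completeness`, `contamination`, `strain_het`, `n50`, `rrna_5s`,
#'   `rrna_16s`, `rrna_23s`, `trna_count`, plus `taxonomy` and `phylum`
#'   when a full simulation object is supplied.
#' @export
simulateQualityMetadata <- function(truth, params = qualityParams(),
                                    seed = NULL) {
  sim <- NULL
  if (is(truth, "MagSimulation")) { sim <- truth; truth <- sim@truth }
  if (!nrow(truth)) stop("truth table is empty")
  if (!is.null(seed)) set.seed(seed)
  p <- modifyList(qualityParams(), params)
  n <- nrow(truth)
  out <- data.frame(
    mag_id = truth$mag_id,
    sample_id = truth$sample_id,
    completeness = rtruncnorm(n, p$completenessMean, p$completenessSd, 50, 100),
    contamination = pmin(rexp(n, 1 / p$contaminationMean), 14.999),
    strain_het = pmin(rexp(n, 1 / p$strainHetMean), 100),
    n50 = pmax(1, round(rlnorm(n, p$n50Meanlog, p$n50Sdlog))),
    rrna_5s = rbinom(n, 1, p$rrnaProb),
    rrna_16s = rbinom(n, 1, p$rrnaProb),
    rrna_23s = rbinom(n, 1, p$rrnaProb),
    trna_count = rpois(n, p$trnaLambda))
  if (!is.null(sim)) {
    sp <- sim@species[match(truth$species, sim@species$species), ]
    out$taxonomy <- sp$taxonomy
    out$phylum <- sp$phylum
  }
  out
}

# calibrate the logistic intercept so mean fitted prevalence hits target
calibrateIntercept <- function(offset, prevalence) {
  uniroot(function(b0) mean(plogis(b0 + offset)) - prevalence,
          lower = -30, upper = 30)$root
}

#' Simulate abundance, phenotype, and MAG-recovery tables
#'
#' Species loads are zero-inflated log-normal, forced present wherever the
#' genome collection recovered a MAG of the species, then closed to
#' relative abundances. Phenotypes: age ~ Uniform(23, 89), sex ~
#' Bernoulli(0.70) (1 = female), BMI ~ Normal(26, 4). Each configured
#' disease is drawn from a logistic model whose intercept is calibrated to
#' the target prevalence, with the planted log odds ratio applied to
#' carriers of the target genome unit and mild age/sex/BMI effects; the
#' planted species effect is realized as a multiplicative load shift in
#' cases sized so the species' CLR abundance shifts by `speciesBeta`.
#'
#' @param sim a [MagSimulation-class].
#' @param seed optional integer seed.
#' @param covariateEffects named list of log-odds coefficients used when
#'   drawing diseases (per year of age, female sex, per BMI unit).
#' @return list with `abundance` (samples x species matrix of relative
#'   abundances), `phenotypes` (data.frame), `recovery` (data.frame:
#'   `sample_id`, `species`, `species_id`, `unit`, `unit_key`, `novel`).
#' @export
simulateCohortTables <- function(sim, seed = NULL,
                                 covariateEffects = list(age = 0.02,
                                                         sex = 0.2,
                                                         bmi = 0.04)) {
  stopifnot(is(sim, "MagSimulation"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- sim@config
  nS <- cfg@nSamples
  nsp <- cfg@nSpecies
  samples <- sprintf("SA%04d", seq_len(nS))
  spIds <- sim@species$species_id

  # zero-inflated log-normal loads
  prevalence <- runif(nsp, 0.15, 0.9)
  meanlog <- rnorm(nsp, 0, 1)
  present <- matrix(rbinom(nS * nsp, 1, rep(prevalence, each = nS)),
                    nrow = nS, dimnames = list(samples, spIds))
  recovery <- unique(sim@truth[, c("sample_id", "species", "unit")])
  recovery$species_id <- spIds[recovery$species]
  recovery$unit_key <- sprintf("%s_u%d", recovery$species_id, recovery$unit)
  recovery$novel <- is.na(sim@species$taxonomy)[recovery$species]
  present[cbind(match(recovery$sample_id, samples), recovery$species)] <- 1L
  empty <- rowSums(present) == 0
  present[empty, which.max(prevalence)] <- 1L
  load <- matrix(rlnorm(nS * nsp, rep(meanlog, each = nS), 1),
                 nrow = nS, dimnames = list(samples, spIds)) * present

  phen <- data.frame(
    sample_id = samples,
    age = round(runif(nS, 23, 89)),
    sex = rbinom(nS, 1, 0.70),
    bmi = round(rnorm(nS, 26, 4), 1))

  dc <- cfg@diseaseConfigs
  for (r in seq_len(nrow(dc))) {
    if (dc$prevalence[r] <= 0 || dc$prevalence[r] >= 1)
      stop("disease prevalence must lie in (0, 1)")
    carrierSamples <- recovery$sample_id[recovery$species == dc$targetSpecies[r] &
                                         recovery$unit == dc$targetUnit[r]]
    carrier <- as.integer(samples %in% carrierSamples)
    offset <- dc$unitLogOR[r] * carrier +
      covariateEffects$age * (phen$age - 56) +
      covariateEffects$sex * phen$sex +
      covariateEffects$bmi * (phen$bmi - 26)
    b0 <- calibrateIntercept(offset, dc$prevalence[r])
    y <- rbinom(nS, 1, plogis(b0 + offset))
    phen[[dc$disease[r]]] <- y
    if (dc$speciesBeta[r] != 0 && nsp > 1) {
      # CLR shift of delta needs a raw log-load shift of delta * D/(D-1)
      shift <- exp(dc$speciesBeta[r] * nsp / (nsp - 1))
      load[y == 1, dc$targetSpecies[r]] <-
        load[y == 1, dc$targetSpecies[r]] * shift
    }
  }

  abundance <- load / rowSums(load)
  rownames(recovery) <- NULL
  list(abundance = abundance, phenotypes = phen, recovery = recovery)
}

#' Write a simulated cohort to disk
#'
#' Emits one FASTA per MAG plus TSV tables (UTF-8, header row, `.`
#' decimal): quality metadata, relative abundances, phenotypes, and the
#' truth labels.
#'
#' @param sim a [MagSimulation-class].
#' @param quality data.frame from [simulateQualityMetadata()].
#' @param tables list from [simulateCohortTables()].
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
writeCohort <- function(sim, quality, tables, dir) {
  dir.create(file.path(dir, "fasta"), recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (i in seq_along(sim@genomes)) {
    f <- file.path(dir, "fasta", paste0(names(sim@genomes)[i], ".fasta"))
    Biostrings::writeXStringSet(sim@genomes[i], f)
    files <- c(files, f)
  }
  writeTsv <- function(df, name) {
    f <- file.path(dir, name)
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
    f
  }
  ab <- data.frame(sample_id = rownames(tables$abundance),
                   tables$abundance, check.names = FALSE)
  files <- c(files,
             writeTsv(quality, "metadata.tsv"),
             writeTsv(ab, "abundance.tsv"),
             writeTsv(tables$phenotypes, "phenotypes.tsv"),
             writeTsv(sim@truth, "truth.tsv"))
  invisible(files)
}
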