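#' Cohort-style collection summary
#'
#' Recomputes the headline arithmetic of a MAG-collection report from raw
#' counts: mean MAGs per sample and the percentage share of each part in
#' its whole, all rounded half-up to two decimals. Raw inputs are
#' retained alongside so every printed value is recomputable.
#'
#' @param counts named list of non-negative counts. Recognized entries
#'   (all optional except `nMags` and `nSamples`): `nAlmostComplete`
#'   (of `nMags`), `nSpecies`, `nNovel` and tier counts `nHQ`, `nMQ`,
#'   `nLQ` (of `nSpecies`), `nNovelAlmostComplete` (of `nNovel`),
#'   `mergedFromA` (of `mergedTotal`).
#' @return named list with the computed summary values (two decimals).
#' @export
summarizeCollection <- function(counts) {
  need <- c("nMags", "nSamples")
  if (!all(need %in% names(counts))) stop("counts needs nMags and nSamples")
  if (any(unlist(counts) < 0)) stop("counts must be non-negative")
  if (counts$nSamples <= 0) stop("nSamples must be positive")
  out <- list(counts = counts,
              mags_per_sample = roundHalfUp(counts$nMags / counts$nSamples, 2))
  addPct <- function(name, part, whole)
    if (!is.null(part) && !is.null(whole)) out[[name]] <<- pct2(part, whole)
  addPct("pct_almost_complete", counts$nAlmostComplete, counts$nMags)
  addPct("pct_novel", counts$nNovel, counts$nSpecies)
  addPct("pct_hq", counts$nHQ, counts$nSpecies)
  addPct("pct_mq", counts$nMQ, counts$nSpecies)
  addPct("pct_lq", counts$nLQ, counts$nSpecies)
  addPct("pct_novel_almost_complete", counts$nNovelAlmostComplete,
         counts$nNovel)
  addPct("pct_merged_from_A", counts$mergedFromA, counts$mergedTotal)
  out
}

pipelineDefaults <- function() {
  list(k = 21, s = 1000, speciesThreshold = 0.95, unitThreshold = 0.99,
       linkage = "average", minMags = 10, maxNgun = 10, minCandidateMags = 20,
       minPrevalence = 0.01, minCases = 100, minCarriers = 100, alpha = 0.05,
       seed = 1)
}

#' Run the genome-resolved cohort pipeline
#'
#' Sequences the full analysis: simulate (or load) a cohort, sketch
#' genomes, estimate pairwise ANI, cluster into species and genome units,
#' tier MAG quality, select representatives, build the GUN report, run
#' the species-level and nGUN-guided within-species association layers,
#' and write every stage as TSV plus a machine-readable run manifest.
#' Given the same configuration and seed the output files are
#' byte-identical across runs.
#'
#' @param config named list, or path to a YAML file with the same keys.
#'   Required: `outputDir` and either `simConfig` (a [SimConfig-class] or
#'   a list of [simConfig()] arguments) for synthetic mode, or the input
#'   paths `fastaDir`, `metadataFile`, `abundanceFile`, `phenotypeFile`.
#'   Optional keys override [pipelineDefaults()].
#' @param quiet suppress per-stage log lines.
#' @return invisibly, a list with every stage's result (`simulation`,
#'   `ani`, `clustering`, `quality`, `gun`, `speciesAssoc`, `unitAssoc`,
#'   `summary`, `manifest`).
#' @export
runPipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  cfg <- modifyList(pipelineDefaults(), config)
  if (is.null(cfg$outputDir)) stop("config needs an outputDir")
  synthetic <- !is.null(cfg$simConfig)
  if (!synthetic &&
      is.null(cfg$fastaDir))
    stop("config needs simConfig (synthetic mode) or input paths")
  dir.create(cfg$outputDir, recursive = TRUE, showWarnings = FALSE)
  logStage <- function(stage, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(...)))
  }
  writeTsv <- function(df, name) {
    write.table(df, file.path(cfg$outputDir, name), sep = "\t",
                quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  }

  # --- inputs -------------------------------------------------------------
  if (synthetic) {
    sc <- cfg$simConfig
    if (!is(sc, "SimConfig")) sc <- do.call(simConfig, sc)
    sc@rngSeed <- as.integer(cfg$seed)
    sim <- simulateGenomeCollection(sc)
    quality <- simulateQualityMetadata(sim)
    tables <- simulateCohortTables(sim)
    genomes <- genomes(sim)
    abundance <- tables$abundance
    phenotypes <- tables$phenotypes
    logStage("simulate", "%d MAGs, %d species, %d samples",
             length(genomes), nrow(speciesInfo(sim)), sc@nSamples)
  } else {
    sim <- NULL
    fa <- sort(list.files(cfg$fastaDir, pattern = "\\.(fa|fasta)$",
                          full.names = TRUE))
    if (!length(fa)) stop("stage input: no FASTA files in ", cfg$fastaDir)
    genomes <- Biostrings::DNAStringSet(vapply(fa, function(f)
      paste(as.character(Biostrings::readDNAStringSet(f)), collapse = ""),
      character(1)))
    names(genomes) <- sub("\\.(fa|fasta)$", "", basename(fa))
    quality <- read.table(cfg$metadataFile, sep = "\t", header = TRUE)
    ab <- read.table(cfg$abundanceFile, sep = "\t", header = TRUE,
                     check.names = FALSE)
    abundance <- as.matrix(ab[, -1, drop = FALSE])
    rownames(abundance) <- ab[[1]]
    phenotypes <- read.table(cfg$phenotypeFile, sep = "\t", header = TRUE)
    logStage("load", "%d genomes, %d samples", length(genomes),
             nrow(abundance))
  }
  missingPheno <- setdiff(rownames(abundance), phenotypes$sample_id)
  if (length(missingPheno))
    stop("stage validate: abundance sample(s) absent from phenotypes: ",
         paste(head(missingPheno, 5), collapse = ", "))

  # --- ANI + clustering ---------------------------------------------------
  ani <- pairwiseANI(genomes, method = "sketch", k = cfg$k, s = cfg$s)
  logStage("ani", "%d x %d sketch matrix", length(genomes), length(genomes))
  taxonomy <- NULL
  if ("taxonomy" %in% names(quality))
    taxonomy <- setNames(quality$taxonomy, quality$mag_id)
  clustering <- clusterGenomes(ani, quality = quality, taxonomy = taxonomy,
                               speciesThreshold = cfg$speciesThreshold,
                               unitThreshold = cfg$unitThreshold,
                               linkage = cfg$linkage)
  writeTsv(clusterTable(clustering), "clusters.tsv")
  logStage("cluster", "%d species clusters",
           nrow(representatives(clustering)))

  # --- quality tiers ------------------------------------------------------
  tiers <- classifyTier(quality$completeness, quality$contamination,
                        quality$rrna_5s, quality$rrna_16s, quality$rrna_23s,
                        quality$trna_count)
  quality$tier <- as.character(tiers$tier)
  quality$almost_complete <- as.integer(tiers$almost_complete)
  writeTsv(quality, "quality_tiers.tsv")
  logStage("tier", "HQ %d / MQ %d / LQ %d", sum(tiers$tier == "HQ"),
           sum(tiers$tier == "MQ"), sum(tiers$tier == "LQ"))

  # --- GUN report ---------------------------------------------------------
  gun <- gunTable(clustering, meta = quality, minMags = cfg$minMags,
                  nSamples = nrow(abundance))
  writeTsv(gun, "gun_report.tsv")
  logStage("gun", "%d species above %d MAGs", nrow(gun), cfg$minMags)

  # --- species-level MWAS -------------------------------------------------
  covar <- c("bmi", "sex", "age")
  diseaseCols <- setdiff(names(phenotypes), c("sample_id", covar))
  diseases <- filterDiseases(phenotypes, diseaseCols,
                             minCases = cfg$minCases)
  keepSpecies <- filterSpecies(abundance, cfg$minPrevalence)
  speciesAssoc <- emptyAssoc()
  if (length(diseases) && length(keepSpecies) >= 2) {
    clr <- clrTransform(abundance[, keepSpecies, drop = FALSE])
    speciesAssoc <- speciesMwas(clr, phenotypes, diseases,
                                covariates = covar, alpha = cfg$alpha)
  }
  writeTsv(speciesAssoc, "species_associations.tsv")
  logStage("mwas", "%d species x %d diseases, %d significant",
           length(keepSpecies), length(diseases),
           sum(speciesAssoc$significant, na.rm = TRUE))

  # --- within-species MWAS ------------------------------------------------
  candidates <- if (nrow(gun))
    selectCandidates(gun, maxNgun = cfg$maxNgun,
                     minMags = cfg$minCandidateMags) else gun
  unitAssoc <- emptyAssoc()
  if (nrow(candidates) && length(diseases)) {
    tb <- clusterTable(clustering)
    keep <- tb$species_cluster_id %in% candidates$species_id
    recov <- data.frame(
      sample_id = quality$sample_id[match(tb$mag_id[keep], quality$mag_id)],
      unit_key = tb$genome_unit_id[keep])
    presence <- unitPresenceMatrix(recov, rownames(abundance))
    unitAssoc <- withinSpeciesMwas(presence, phenotypes, diseases,
                                   covariates = c("sex", "age", "bmi"),
                                   minCarriers = cfg$minCarriers,
                                   alpha = cfg$alpha)
  }
  writeTsv(unitAssoc, "unit_associations.tsv")
  logStage("within", "%d candidate species, %d unit tests",
           nrow(candidates), nrow(unitAssoc))

  # --- summary + manifest -------------------------------------------------
  reps <- representatives(clustering)
  repQ <- quality[match(reps$mag_id, quality$mag_id), ]
  summary <- summarizeCollection(list(
    nMags = length(genomes), nSamples = nrow(abundance),
    nAlmostComplete = sum(quality$almost_complete),
    nSpecies = nrow(reps), nNovel = sum(reps$novel),
    nHQ = sum(repQ$tier == "HQ"), nMQ = sum(repQ$tier == "MQ"),
    nLQ = sum(repQ$tier == "LQ")))
  manifest <- list(
    package = "magun", version = as.character(packageVersion("magun")),
    seed = cfg$seed,
    parameters = cfg[setdiff(names(cfg), c("simConfig", "outputDir"))],
    synthetic = synthetic,
    records = list(n_mags = length(genomes),
                   n_species_clusters = nrow(reps),
                   n_gun_species = nrow(gun),
                   n_species_tests = nrow(speciesAssoc),
                   n_unit_tests = nrow(unitAssoc)))
  jsonlite::write_json(summary[names(summary) != "counts"],
                       file.path(cfg$outputDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(manifest, file.path(cfg$outputDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  logStage("report", "summary written to %s", cfg$outputDir)

  invisible(list(simulation = sim, ani = ani, clustering = clustering,
                 quality = quality, gun = gun, speciesAssoc = speciesAssoc,
                 unitAssoc = unitAssoc, summary = summary,
                 manifest = manifest))
}
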