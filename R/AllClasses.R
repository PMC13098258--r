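#' Sketch: bottom-s MinHash sketch of a genome
#'
#' Holds the `s` smallest 64-bit hash values (truncated to 53 bits, stored
#' as doubles) over the distinct canonical k-mers of a genome. Canonical
#' means the lexicographic minimum of a k-mer and its reverse complement,
#' so sketches are strand-independent.
#'
#' @slot genomeId single genome identifier.
#' @slot k k-mer length.
#' @slot s nominal sketch size; `length(hashes) <= s`.
#' @slot hashes strictly increasing hash values.
#' @export
setClass("Sketch",
  representation(genomeId = "character", k = "integer", s = "integer",
                 hashes = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@hashes) > object@s)
      msg <- c(msg, "more hashes than sketch size s")
    if (is.unsorted(object@hashes, strictly = TRUE))
      msg <- c(msg, "hashes must be strictly increasing")
    if (object@k < 1L || object@k > 31L)
      msg <- c(msg, "k must be in [1, 31]")
    if (length(msg)) msg else TRUE
  })

#' ANIMatrix: pairwise average nucleotide identity estimates
#'
#' Symmetric matrix of ANI values in \[0, 1\] with unit diagonal over an
#' ordered set of genome ids, tagged with the estimation method.
#'
#' @slot ani symmetric numeric matrix with dimnames = genome ids.
#' @slot method one of `"sketch"`, `"exact_hamming"`, `"exact_jaccard"`.
#' @export
setClass("ANIMatrix",
  representation(ani = "matrix", method = "character"),
  validity = function(object) {
    m <- object@ani
    msg <- character()
    if (is.null(rownames(m)) || !identical(rownames(m), colnames(m)))
      msg <- c(msg, "matrix must carry identical row and column genome ids")
    if (any(m < 0 | m > 1)) msg <- c(msg, "ANI values must lie in [0, 1]")
    if (max(abs(m - t(m))) > 1e-12) msg <- c(msg, "matrix must be symmetric")
    if (any(abs(diag(m) - 1) > 1e-12)) msg <- c(msg, "diagonal must be 1")
    if (!object@method %in% c("sketch", "exact_hamming", "exact_jaccard"))
      msg <- c(msg, "unknown method tag")
    if (length(msg)) msg else TRUE
  })

#' SimConfig: synthetic cohort configuration
#'
#' Generation parameters for the planted MAG hierarchy. Per-site
#' substitution distances control the realized ANI bands: members of one
#' genome unit end up above 99% ANI, units of one species between 95% and
#' 99%, and distinct species below 95%.
#'
#' @slot nSpecies number of planted species.
#' @slot unitsPerSpecies genome units per species (recycled to `nSpecies`).
#' @slot magsPerUnit MAGs generated per unit (recycled to `nSpecies`).
#' @slot genomeLength genome length in bases.
#' @slot dBetweenUnits substitution distance between unit centers of one
#'   species; must lie strictly inside (0.01, 0.05).
#' @slot dWithinUnit distance from a unit center to a member; `2 * dWithinUnit`
#'   must stay below 0.01 so within-unit ANI exceeds 99%.
#' @slot dBetweenSpecies distance between species ancestors (> 0.05).
#' @slot nSamples cohort size.
#' @slot novelFraction fraction of species carrying no taxonomy label.
#' @slot diseaseConfigs data.frame with columns `disease`, `prevalence`,
#'   `speciesBeta` (CLR mean shift in cases), `unitLogOR` (planted log
#'   odds ratio for carriers), `targetSpecies`, `targetUnit`.
#' @slot rngSeed integer seed.
#' @export
setClass("SimConfig",
  representation(nSpecies = "integer", unitsPerSpecies = "integer",
                 magsPerUnit = "integer", genomeLength = "integer",
                 dBetweenUnits = "numeric", dWithinUnit = "numeric",
                 dBetweenSpecies = "numeric", nSamples = "integer",
                 novelFraction = "numeric", diseaseConfigs = "data.frame",
                 rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@nSpecies < 1L) msg <- c(msg, "nSpecies must be >= 1")
    if (length(object@unitsPerSpecies) != object@nSpecies ||
        any(object@unitsPerSpecies < 1L))
      msg <- c(msg, "unitsPerSpecies must be positive, one per species")
    if (length(object@magsPerUnit) != object@nSpecies ||
        any(object@magsPerUnit < 1L))
      msg <- c(msg, "magsPerUnit must be positive, one per species")
    if (any(object@magsPerUnit > object@nSamples))
      msg <- c(msg, "magsPerUnit cannot exceed nSamples")
    if (object@genomeLength < 100L) msg <- c(msg, "genomeLength too small")
    if (2 * object@dWithinUnit >= 0.01)
      msg <- c(msg, "2 * dWithinUnit must be < 0.01 (within-unit ANI > 99%)")
    if (object@dBetweenUnits <= 0.01 || object@dBetweenUnits >= 0.05)
      msg <- c(msg, "dBetweenUnits must lie strictly in (0.01, 0.05)")
    if (object@dBetweenSpecies <= 0.05)
      msg <- c(msg, "dBetweenSpecies must be > 0.05")
    if (object@novelFraction < 0 || object@novelFraction > 1)
      msg <- c(msg, "novelFraction must be in [0, 1]")
    dc <- object@diseaseConfigs
    need <- c("disease", "prevalence", "speciesBeta", "unitLogOR",
              "targetSpecies", "targetUnit")
    if (!all(need %in% names(dc)))
      msg <- c(msg, "diseaseConfigs misses required columns")
    else if (nrow(dc)) {
      if (any(dc$prevalence <= 0 | dc$prevalence >= 1))
        msg <- c(msg, "disease prevalence must lie in (0, 1)")
      if (any(dc$targetSpecies < 1 | dc$targetSpecies > object@nSpecies))
        msg <- c(msg, "targetSpecies out of range")
    }
    if (length(msg)) msg else TRUE
  })

#' MagSimulation: generated MAG collection with ground truth
#'
#' @slot genomes [Biostrings::DNAStringSet] of single-contig MAG sequences.
#' @slot truth data.frame: `mag_id`, `species`, `unit`, `sample_id`.
#' @slot species data.frame: `species`, `species_id`, `taxonomy` (NA for
#'   novel species), `phylum`.
#' @slot config the [SimConfig-class] used.
#' @export
setClass("MagSimulation",
  representation(genomes = "ANY", truth = "data.frame",
                 species = "data.frame", config = "SimConfig"),
  validity = function(object) {
    msg <- character()
    tr <- object@truth
    if (anyDuplicated(tr$mag_id)) msg <- c(msg, "duplicated mag ids in truth")
    if (length(object@genomes) != nrow(tr))
      msg <- c(msg, "genomes and truth rows disagree")
    if (length(msg)) msg else TRUE
  })

#' GenomeClustering: nested species / genome-unit partition of a MAG set
#'
#' @slot table data.frame with one row per MAG: `mag_id`,
#'   `species_cluster_id` (`S1`, `S2`, ...), `genome_unit_id`
#'   (`S1_U1`, ...), `is_representative`.
#' @slot representatives data.frame with one row per species cluster:
#'   `species_cluster_id`, `mag_id`, `score`, `taxonomy`, `novel`.
#' @slot speciesThreshold ANI threshold used at the species level.
#' @slot unitThreshold ANI threshold used at the genome-unit level.
#' @export
setClass("GenomeClustering",
  representation(table = "data.frame", representatives = "data.frame",
                 speciesThreshold = "numeric", unitThreshold = "numeric"),
  validity = function(object) {
    tb <- object@table
    msg <- character()
    if (anyDuplicated(tb$mag_id)) msg <- c(msg, "duplicated mag ids")
    nest <- tapply(tb$species_cluster_id, tb$genome_unit_id,
                   function(x) length(unique(x)))
    if (length(nest) && any(nest != 1L))
      msg <- c(msg, "a genome unit spans more than one species cluster")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "Sketch", function(object) {
  cat("Sketch of", object@genomeId, ": k =", object@k,
      ", |hashes| =", length(object@hashes), "/", object@s, "\n")
})

setMethod("show", "ANIMatrix", function(object) {
  cat("ANIMatrix (", object@method, "): ", nrow(object@ani),
      " genomes\n", sep = "")
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSpecies, "species,",
      sum(object@unitsPerSpecies), "units,",
      sum(object@unitsPerSpecies * object@magsPerUnit), "MAGs, L =",
      object@genomeLength, "bp,", object@nSamples, "samples\n")
})

setMethod("show", "MagSimulation", function(object) {
  cat("MagSimulation:", nrow(object@truth), "MAGs over",
      nrow(object@species), "species\n")
})

setMethod("show", "GenomeClustering", function(object) {
  cat("GenomeClustering:", nrow(object@table), "MAGs,",
      length(unique(object@table$species_cluster_id)), "species clusters,",
      length(unique(object@table$genome_unit_id)), "genome units",
      sprintf("(t = %.2f / %.2f)\n", object@speciesThreshold,
              object@unitThreshold))
})

#' Accessors for magun S4 containers
#'
#' `genomes()` returns the simulated sequences, `truthAssignment()` the
#' planted MAG-to-(species, unit, sample) map, `speciesInfo()` the planted
#' species annotations. `aniValues()`/`aniMethod()`/`genomeIds()` expose an
#' [ANIMatrix-class]; `clusterTable()`/`representatives()` expose a
#' [GenomeClustering-class]; `sketchHashes()` a [Sketch-class].
#'
#' @param x the object.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomes", function(x) standardGeneric("genomes"))
#' @rdname accessors
#' @export
setMethod("genomes", "MagSimulation", function(x) x@genomes)

#' @rdname accessors
#' @export
setGeneric("truthAssignment", function(x) standardGeneric("truthAssignment"))
#' @rdname accessors
#' @export
setMethod("truthAssignment", "MagSimulation", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("speciesInfo", function(x) standardGeneric("speciesInfo"))
#' @rdname accessors
#' @export
setMethod("speciesInfo", "MagSimulation", function(x) x@species)

#' @rdname accessors
#' @export
setGeneric("aniValues", function(x) standardGeneric("aniValues"))
#' @rdname accessors
#' @export
setMethod("aniValues", "ANIMatrix", function(x) x@ani)

#' @rdname accessors
#' @export
setGeneric("aniMethod", function(x) standardGeneric("aniMethod"))
#' @rdname accessors
#' @export
setMethod("aniMethod", "ANIMatrix", function(x) x@method)

#' @rdname accessors
#' @export
setGeneric("genomeIds", function(x) standardGeneric("genomeIds"))
#' @rdname accessors
#' @export
setMethod("genomeIds", "ANIMatrix", function(x) rownames(x@ani))

#' @rdname accessors
#' @export
setGeneric("sketchHashes", function(x) standardGeneric("sketchHashes"))
#' @rdname accessors
#' @export
setMethod("sketchHashes", "Sketch", function(x) x@hashes)

#' @rdname accessors
#' @export
setGeneric("clusterTable", function(x) standardGeneric("clusterTable"))
#' @rdname accessors
#' @export
setMethod("clusterTable", "GenomeClustering", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("representatives", function(x) standardGeneric("representatives"))
#' @rdname accessors
#' @export
setMethod("representatives", "GenomeClustering",
          function(x) x@representatives)
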