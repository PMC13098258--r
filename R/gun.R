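#' Genome unit number (GUN) of a species
#'
#' The GUN counts the genome units (clusters of same-species genomes
#' above 99% ANI) identified for one species.
#'
#' @param units list of genome units, each a nonempty vector of member
#'   mag ids, or a named unit-assignment vector as returned by
#'   [clusterGenomeUnits()].
#' @return integer unit count.
#' @export
computeGun <- function(units) {
  if (is.atomic(units) && !is.null(names(units)))
    return(length(unique(units)))
  if (!is.list(units) || !length(units)) stop("units must be a nonempty list")
  if (any(!lengths(units))) stop("genome units must be nonempty")
  length(units)
}

#' Normalized GUN (nGUN)
#'
#' `nGUN = 100 * GUN / number of MAGs`, the number of genome units per
#' 100 recovered MAGs. Low values indicate limited within-species
#' diversity; 100 means every MAG is its own unit. Returned at full
#' precision; summaries report one decimal.
#'
#' @param gun genome unit count, `1 <= gun <= nMags`.
#' @param nMags total MAGs recovered for the species.
#' @return nGUN percentage in (0, 100].
#' @export
computeNgun <- function(gun, nMags) {
  if (any(gun < 1) || any(nMags < 1)) stop("counts must be >= 1")
  if (any(gun > nMags)) stop("GUN cannot exceed the MAG count")
  100 * gun / nMags
}

#' Per-species GUN report
#'
#' One row per species cluster with more than `minMags` members (strict,
#' default 10), sorted by MAG count descending. nGUN is reported to one
#' decimal place. Prevalence is the fraction of cohort samples in which
#' at least one MAG of the species was recovered, available when `meta`
#' carries sample ids.
#'
#' @param clustering a [GenomeClustering-class].
#' @param meta optional data.frame with `mag_id`, `sample_id` and
#'   optionally `phylum` (per MAG); phylum and prevalence columns are
#'   filled from it via the species representative.
#' @param minMags keep species with MAG count strictly above this.
#' @param nSamples cohort size for the prevalence denominator; defaults
#'   to the number of distinct samples in `meta`.
#' @return data.frame: `species_id`, `taxonomy`, `phylum`, `n_mags`,
#'   `gun`, `ngun`, `prevalence`.
#' @export
gunTable <- function(clustering, meta = NULL, minMags = 10, nSamples = NULL) {
  tb <- clusterTable(clustering)
  reps <- representatives(clustering)
  sizes <- table(tb$species_cluster_id)
  guns <- tapply(tb$genome_unit_id, tb$species_cluster_id,
                 function(x) length(unique(x)))
  sp <- names(sizes)
  out <- data.frame(
    species_id = sp,
    taxonomy = reps$taxonomy[match(sp, reps$species_cluster_id)],
    phylum = NA_character_,
    n_mags = as.integer(sizes),
    gun = as.integer(guns[sp]))
  out$ngun <- roundHalfUp(computeNgun(out$gun, out$n_mags), 1)
  out$prevalence <- NA_real_
  if (!is.null(meta)) {
    if ("phylum" %in% names(meta)) {
      repRow <- match(reps$mag_id[match(sp, reps$species_cluster_id)],
                      meta$mag_id)
      out$phylum <- meta$phylum[repRow]
    }
    if ("sample_id" %in% names(meta)) {
      if (is.null(nSamples)) nSamples <- length(unique(meta$sample_id))
      smp <- meta$sample_id[match(tb$mag_id, meta$mag_id)]
      nsmp <- tapply(smp, tb$species_cluster_id,
                     function(x) length(unique(x)))
      out$prevalence <- as.numeric(nsmp[sp]) / nSamples
    }
  }
  out <- out[out$n_mags > minMags, , drop = FALSE]
  out <- out[order(-out$n_mags, out$species_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank candidate species for within-species association analysis
#'
#' Candidates need many recovered MAGs and low within-species diversity:
#' keep species with `ngun <= maxNgun` and `n_mags >= minMags`, ranked by
#' nGUN ascending, MAG count descending, then species id.
#'
#' @param report a [gunTable()] data.frame.
#' @param maxNgun nGUN ceiling (percent).
#' @param minMags minimum MAG count (inclusive).
#' @return the filtered, ranked report.
#' @export
selectCandidates <- function(report, maxNgun = 10, minMags = 100) {
  if (!nrow(report)) stop("report is empty")
  keep <- report[report$ngun <= maxNgun & report$n_mags >= minMags, ,
                 drop = FALSE]
  keep <- keep[order(keep$ngun, -keep$n_mags, keep$species_id), ,
               drop = FALSE]
  rownames(keep) <- NULL
  keep
}

#' nGUN distribution by phylum
#'
#' Summarizes nGUN per phylum with at least `minSpecies` species
#' (default 10): species count, median, and quartiles.
#'
#' @param report a [gunTable()] data.frame with a `phylum` column.
#' @return data.frame: `phylum`, `n_species`, `ngun_q1`, `ngun_median`,
#'   `ngun_q3`.
#' @param minSpecies minimum species per phylum (inclusive).
#' @export
phylumSummary <- function(report, minSpecies = 10) {
  if (!"phylum" %in% names(report)) stop("report lacks phylum labels")
  sp <- split(report$ngun, report$phylum)
  sp <- sp[lengths(sp) >= minSpecies]
  out <- data.frame(
    phylum = names(sp),
    n_species = lengths(sp),
    ngun_q1 = vapply(sp, function(x) unname(quantile(x, 0.25)), numeric(1)),
    ngun_median = vapply(sp, median, numeric(1)),
    ngun_q3 = vapply(sp, function(x) unname(quantile(x, 0.75)), numeric(1)))
  rownames(out) <- NULL
  out[order(out$phylum), , drop = FALSE]
}
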