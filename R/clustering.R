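#' Cut a pairwise-ANI dendrogram at an identity threshold
#'
#' Agglomerative clustering (average linkage by default) on the distance
#' `1 - ANI`, cut at height `1 - threshold`: genomes merge while their
#' linkage ANI stays at or above the threshold. Genomes are processed in
#' sorted id order so dendrogram tie-breaks are reproducible; cluster
#' labels are assigned by decreasing size, then by smallest member id.
#'
#' @param ani an [ANIMatrix-class] or a symmetric named ANI matrix.
#' @param threshold ANI threshold in (0, 1), e.g. 0.95 for species.
#' @param linkage agglomeration method.
#' @return named integer vector: cluster label per genome id.
#' @export
clusterAtThreshold <- function(ani, threshold,
                               linkage = c("average", "single", "complete")) {
  linkage <- match.arg(linkage)
  m <- if (is(ani, "ANIMatrix")) aniValues(ani) else ani
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  ids <- sort(rownames(m))
  if (length(ids) == 1L) return(setNames(1L, ids))
  m <- m[ids, ids]
  hc <- hclust(as.dist(1 - m), method = linkage)
  memb <- cutree(hc, h = 1 - threshold)
  relabelBySize(setNames(as.integer(memb), ids))
}

# relabel cluster ids by decreasing size, ties by smallest member id
relabelBySize <- function(memb) {
  ids <- names(memb)
  sizes <- table(memb)
  minId <- tapply(ids, memb, min)
  ord <- order(-as.integer(sizes[names(minId)]), minId)
  map <- setNames(seq_along(ord), names(minId)[ord])
  setNames(as.integer(map[as.character(memb)]), ids)
}

#' Genome units within one species cluster
#'
#' Applies [clusterAtThreshold()] at the genome-unit threshold (default
#' 0.99) to the members of one species cluster. Units are numbered by
#' descending size, then by smallest member id.
#'
#' @param members character vector of member mag ids.
#' @param ani an [ANIMatrix-class] (or matrix) covering the members.
#' @param threshold unit-level ANI threshold.
#' @param linkage agglomeration method.
#' @return named integer vector: unit label per member.
#' @export
clusterGenomeUnits <- function(members, ani, threshold = 0.99,
                               linkage = "average") {
  if (!length(members)) stop("species cluster is empty")
  m <- if (is(ani, "ANIMatrix")) aniValues(ani) else ani
  clusterAtThreshold(m[members, members, drop = FALSE], threshold,
                     linkage = linkage)
}

#' Dereplication quality score of a genome
#'
#' `score = completeness - 5 * contamination - 0.1 * strain_het +
#' 0.5 * log10(N50)`, the common dereplication weighting of completeness,
#' contamination, strain heterogeneity and assembly contiguity. Weights
#' are configurable.
#'
#' @param completeness percent in \[0, 100\].
#' @param contamination percent, `>= 0`.
#' @param strainHet strain heterogeneity in \[0, 100\].
#' @param n50 assembly N50 in bases, `> 0`.
#' @param weights named list: `contamination`, `strainHet`, `logN50`.
#' @return numeric score(s).
#' @export
scoreGenome <- function(completeness, contamination, strainHet = 0, n50 = 1,
                        weights = list(contamination = 5, strainHet = 0.1,
                                       logN50 = 0.5)) {
  if (any(completeness < 0 | completeness > 100))
    stop("completeness must lie in [0, 100]")
  if (any(contamination < 0)) stop("contamination must be >= 0")
  if (any(n50 <= 0)) stop("N50 must be positive")
  completeness - weights$contamination * contamination -
    weights$strainHet * strainHet + weights$logN50 * log10(n50)
}

#' Representative of a cluster: highest score, ties to smallest id
#'
#' @param members character vector of member mag ids.
#' @param scores named numeric vector of genome scores covering members.
#' @return the representative mag id.
#' @export
selectRepresentative <- function(members, scores) {
  if (!length(members)) stop("cluster is empty")
  s <- scores[members]
  best <- members[s == max(s)]
  sort(best)[1]
}

#' Cluster a MAG collection into species and nested genome units
#'
#' Species clusters at `speciesThreshold` (default 0.95), genome units
#' within each species at `unitThreshold` (default 0.99), with a scored
#' representative per species. Species cluster ids are `S1`, `S2`, ... by
#' decreasing size; unit ids `S1_U1`, ... by decreasing size within each
#' species.
#'
#' @param ani an [ANIMatrix-class] over the collection.
#' @param quality optional data.frame with `mag_id`, `completeness`,
#'   `contamination`, `strain_het`, `n50` used for representative scoring;
#'   without it all scores are 0 and the smallest id wins.
#' @param taxonomy optional named character vector (mag id -> species-level
#'   label; `NA` or missing means unclassified). A species cluster whose
#'   representative has no label is flagged novel.
#' @param speciesThreshold,unitThreshold ANI thresholds.
#' @param linkage agglomeration method.
#' @return a [GenomeClustering-class].
#' @export
clusterGenomes <- function(ani, quality = NULL, taxonomy = NULL,
                           speciesThreshold = 0.95, unitThreshold = 0.99,
                           linkage = "average") {
  sp <- clusterAtThreshold(ani, speciesThreshold, linkage = linkage)
  ids <- names(sp)
  scores <- setNames(rep(0, length(ids)), ids)
  if (!is.null(quality)) {
    qs <- scoreGenome(quality$completeness, quality$contamination,
                      quality$strain_het, quality$n50)
    scores[quality$mag_id] <- qs
  }

  tab <- data.frame(mag_id = ids,
                    species_cluster_id = sprintf("S%d", sp),
                    genome_unit_id = NA_character_,
                    is_representative = FALSE)
  reps <- list()
  for (ci in sort(unique(sp))) {
    members <- ids[sp == ci]
    units <- clusterGenomeUnits(members, ani, threshold = unitThreshold,
                                linkage = linkage)
    tab$genome_unit_id[match(members, tab$mag_id)] <-
      sprintf("S%d_U%d", ci, units[members])
    rep_id <- selectRepresentative(members, scores)
    tab$is_representative[tab$mag_id == rep_id] <- TRUE
    lab <- if (!is.null(taxonomy)) unname(taxonomy[rep_id]) else NA_character_
    reps[[length(reps) + 1L]] <- data.frame(
      species_cluster_id = sprintf("S%d", ci), mag_id = rep_id,
      score = unname(scores[rep_id]), taxonomy = lab,
      novel = is.na(lab) || !nzchar(lab))
  }
  new("GenomeClustering", table = tab, representatives = do.call(rbind, reps),
      speciesThreshold = speciesThreshold, unitThreshold = unitThreshold)
}

#' Merge two representative collections into a deduplicated reference
#'
#' Cross-collection clustering at the species threshold; per merged
#' species the higher-scoring representative is retained. Categories:
#' an A-only species with no taxonomy label is `novel`; A-only with a
#' label is `known_absent_from_B`; a shared species won by A is
#' `higher_quality_replacement`; shared species won by B and B-only
#' species are `B_only`. Score ties go to the lexicographically smaller
#' representative id.
#'
#' @param ani an [ANIMatrix-class] over the union of both representative
#'   sets.
#' @param idsA,idsB representative mag ids of collection A (e.g. a new
#'   cohort) and collection B (e.g. a public reference).
#' @param quality data.frame with `mag_id`, `completeness`,
#'   `contamination`, `strain_het`, `n50` covering both collections.
#' @param taxonomy optional named character vector over A ids; `NA` means
#'   unclassified (novel candidate).
#' @param threshold species-level ANI threshold.
#' @return data.frame: `species_id`, `representative`, `source`
#'   (`"A"`/`"B"`), `category`.
#' @export
mergeCollections <- function(ani, idsA, idsB, quality, taxonomy = NULL,
                             threshold = 0.95) {
  if (length(intersect(idsA, idsB)))
    stop("collections must not share mag ids")
  cl <- clusterAtThreshold(ani, threshold)
  allIds <- names(cl)
  stopifnot(all(c(idsA, idsB) %in% allIds))
  scores <- setNames(
    scoreGenome(quality$completeness, quality$contamination,
                quality$strain_het, quality$n50), quality$mag_id)

  out <- list()
  for (ci in sort(unique(cl))) {
    members <- allIds[cl == ci]
    mA <- intersect(members, idsA); mB <- intersect(members, idsB)
    bestA <- if (length(mA)) selectRepresentative(mA, scores) else NA
    bestB <- if (length(mB)) selectRepresentative(mB, scores) else NA
    if (length(mA) && !length(mB)) {
      lab <- if (!is.null(taxonomy)) unname(taxonomy[bestA]) else NA
      cat_ <- if (is.na(lab) || !nzchar(lab)) "novel" else "known_absent_from_B"
      win <- bestA; src <- "A"
    } else if (!length(mA)) {
      cat_ <- "B_only"; win <- bestB; src <- "B"
    } else {
      aWins <- scores[bestA] > scores[bestB] ||
        (scores[bestA] == scores[bestB] && bestA < bestB)
      if (aWins) { cat_ <- "higher_quality_replacement"; win <- bestA; src <- "A" }
      else { cat_ <- "B_only"; win <- bestB; src <- "B" }
    }
    out[[length(out) + 1L]] <- data.frame(
      species_id = sprintf("S%d", ci), representative = win,
      source = src, category = cat_)
  }
  do.call(rbind, out)
}
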