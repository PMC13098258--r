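#' Almost-complete flag for a MAG
#'
#' A MAG is almost complete when completeness exceeds 90% and
#' contamination stays below 5% (both strict).
#'
#' @param completeness,contamination percent, vectorized.
#' @return logical vector.
#' @export
isAlmostComplete <- function(completeness, contamination) {
  checkQualityRange(completeness, contamination)
  completeness > 90 & contamination < 5
}

checkQualityRange <- function(completeness, contamination,
                              trna = 0, rrna = 0) {
  if (any(completeness < 0 | completeness > 100))
    stop("completeness must lie in [0, 100]")
  if (any(contamination < 0 | contamination > 100))
    stop("contamination must lie in [0, 100]")
  if (any(trna < 0)) stop("tRNA count must be >= 0")
  if (any(!rrna %in% c(0, 1))) stop("rRNA flags must be 0/1")
  invisible(TRUE)
}

#' MIMAG quality tier of a MAG
#'
#' High quality (HQ): completeness > 90, contamination < 5, all three
#' rRNA genes (5S, 16S, 23S) present, and at least 18 tRNAs. Medium
#' quality (MQ): completeness > 50 and contamination < 10. Everything
#' else is low quality (LQ). Inequalities are strict except the tRNA
#' count, so boundary values (e.g. completeness exactly 90) fall to the
#' weaker class.
#'
#' @param completeness,contamination percent, vectorized.
#' @param rrna5s,rrna16s,rrna23s 0/1 presence flags.
#' @param trnaCount number of tRNA genes.
#' @return data.frame with `tier` (factor HQ/MQ/LQ) and `almost_complete`.
#' @export
classifyTier <- function(completeness, contamination, rrna5s, rrna16s,
                         rrna23s, trnaCount) {
  checkQualityRange(completeness, contamination, trnaCount,
                    c(rrna5s, rrna16s, rrna23s))
  ac <- completeness > 90 & contamination < 5
  hq <- ac & rrna5s == 1 & rrna16s == 1 & rrna23s == 1 & trnaCount >= 18
  mq <- !hq & completeness > 50 & contamination < 10
  tier <- factor(ifelse(hq, "HQ", ifelse(mq, "MQ", "LQ")),
                 levels = c("HQ", "MQ", "LQ"))
  data.frame(tier = tier, almost_complete = ac)
}

#' Assembly statistics of a contig set
#'
#' N50 is the smallest length among the longest contigs whose cumulative
#' length reaches half of the total assembly size. GC is (G + C) /
#' (A + C + G + T); ambiguous bases are excluded from the denominator.
#'
#' @param contigs a [Biostrings::DNAStringSet] or character vector of
#'   contig sequences.
#' @return list: `n50`, `gc`, `total_length`, `contig_count`.
#' @export
assemblyStats <- function(contigs) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (!length(contigs)) stop("contig set is empty")
  len <- Biostrings::width(contigs)
  sorted <- sort(len, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= sum(len) / 2)[1]]
  counts <- colSums(Biostrings::letterFrequency(contigs,
                                                c("A", "C", "G", "T")))
  list(n50 = n50, gc = unname((counts["G"] + counts["C"]) / sum(counts)),
       total_length = sum(len), contig_count = length(contigs))
}
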