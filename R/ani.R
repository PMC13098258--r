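# normalize genome input (character contigs, DNAString(Set)) to a plain
# character vector of contigs
asContigs <- function(x) {
  if (is(x, "DNAStringSet")) return(as.character(x))
  if (is(x, "DNAString")) return(as.character(x))
  if (is.character(x)) return(x)
  stop("unsupported sequence container: ", class(x)[1])
}

#' Bottom-s MinHash sketch of a genome
#'
#' Collects the distinct canonical k-mers of a genome (pooled across
#' contigs), hashes each with a splitmix64 mixer over the 2-bit k-mer
#' encoding, and keeps the `s` smallest values. Canonical k-mers (the
#' lexicographic minimum of a k-mer and its reverse complement) make the
#' sketch strand-independent. k-mers containing non-ACGT characters are
#' skipped rather than erroring.
#'
#' @param sequence genome sequence: character vector of contigs, a
#'   [Biostrings::DNAStringSet], or a single string.
#' @param k k-mer length, default 21.
#' @param s sketch size, default 1000. When the genome holds fewer than
#'   `s` distinct k-mers the sketch keeps all of them.
#' @param genomeId identifier stored in the sketch.
#' @return a [Sketch-class].
#' @export
sketchGenome <- function(sequence, k = 21, s = 1000, genomeId = "genome") {
  contigs <- asContigs(sequence)
  if (!length(contigs) || max(nchar(contigs)) < k)
    stop("sequence shorter than k")
  new("Sketch", genomeId = as.character(genomeId), k = as.integer(k),
      s = as.integer(s),
      hashes = kmer_hashes(contigs, as.integer(k), as.integer(s)))
}

#' Mash-style Jaccard estimate from two sketches
#'
#' Merged bottom-s estimator: among the `s` smallest distinct hashes of
#' the union of the two sketches (or all of them when fewer), the shared
#' fraction estimates the Jaccard similarity of the full k-mer sets.
#'
#' @param a,b [Sketch-class] objects built with the same `k`.
#' @return Jaccard estimate in \[0, 1\].
#' @export
jaccardSketch <- function(a, b) {
  stopifnot(is(a, "Sketch"), is(b, "Sketch"))
  if (a@k != b@k) stop("sketches built with different k")
  s <- min(a@s, b@s)
  u <- sort(unique(c(a@hashes, b@hashes)))
  if (!length(u)) return(0)
  bottom <- u[seq_len(min(s, length(u)))]
  shared <- sum(bottom %in% a@hashes & bottom %in% b@hashes)
  shared / length(bottom)
}

#' ANI from a Jaccard estimate (Mash distance closed form)
#'
#' `D = -(1/k) * log(2 j / (1 + j))`, `ANI = 1 - D`, clamped to \[0, 1\];
#' `j = 0` maps to ANI 0.
#'
#' @param j Jaccard estimate(s) in \[0, 1\].
#' @param k k-mer length used for the sketches.
#' @return ANI estimate(s) in \[0, 1\], strictly increasing in `j`.
#' @export
mashANI <- function(j, k = 21) {
  if (any(j < 0 | j > 1)) stop("j must lie in [0, 1]")
  out <- ifelse(j <= 0, 0, 1 + log(2 * j / (1 + j)) / k)
  pmin(1, pmax(0, out))
}

#' Exact ANI oracles
#'
#' `method = "hamming"` computes `1 - mismatches / L` for two equal-length
#' sequences, exact for the indel-free synthetic generator.
#' `method = "jaccard"` computes the exact Jaccard similarity over the
#' full canonical k-mer sets and maps it through [mashANI()].
#'
#' @param seqA,seqB genome sequences (contig vectors allowed; the Hamming
#'   variant concatenates contigs in order).
#' @param method `"hamming"` or `"jaccard"`.
#' @param k k-mer length for the Jaccard variant.
#' @return ANI in \[0, 1\].
#' @export
exactANI <- function(seqA, seqB, method = c("hamming", "jaccard"), k = 21) {
  method <- match.arg(method)
  a <- asContigs(seqA); b <- asContigs(seqB)
  if (method == "hamming") {
    a <- paste(a, collapse = ""); b <- paste(b, collapse = "")
    if (nchar(a) != nchar(b))
      stop("Hamming ANI requires equal-length sequences")
    return(1 - hamming_mismatches(a, b) / nchar(a))
  }
  ha <- kmer_hashes(a, as.integer(k), 0L)
  hb <- kmer_hashes(b, as.integer(k), 0L)
  inter <- length(intersect(ha, hb))
  uni <- length(ha) + length(hb) - inter
  if (!uni) return(0)
  mashANI(inter / uni, k)
}

#' Pairwise ANI matrix over a genome collection
#'
#' @param collection named list of genomes (each a character vector of
#'   contigs) or a named [Biostrings::DNAStringSet] with one entry per
#'   genome. Names are the genome ids.
#' @param method `"sketch"` (default; bottom-s MinHash + [mashANI()]),
#'   `"exact_hamming"`, or `"exact_jaccard"`.
#' @param k,s sketch parameters.
#' @return an [ANIMatrix-class]; symmetric, unit diagonal. Pairs with no
#'   detectable k-mer overlap get ANI 0.
#' @export
pairwiseANI <- function(collection, method = c("sketch", "exact_hamming",
                                               "exact_jaccard"),
                        k = 21, s = 1000) {
  method <- match.arg(method)
  if (is(collection, "DNAStringSet"))
    collection <- as.list(as.character(collection))
  if (length(collection) < 2L) stop("need at least 2 genomes")
  ids <- names(collection)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop("collection must carry unique nonempty genome ids")
  n <- length(collection)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)

  if (method == "sketch") {
    sk <- lapply(seq_len(n), function(i)
      sketchGenome(collection[[i]], k = k, s = s, genomeId = ids[i]))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      v <- mashANI(jaccardSketch(sk[[i]], sk[[j]]), k)
      m[i, j] <- m[j, i] <- v
    }
  } else if (method == "exact_jaccard") {
    hs <- lapply(collection, function(g)
      kmer_hashes(asContigs(g), as.integer(k), 0L))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      inter <- length(intersect(hs[[i]], hs[[j]]))
      uni <- length(hs[[i]]) + length(hs[[j]]) - inter
      v <- if (uni) mashANI(inter / uni, k) else 0
      m[i, j] <- m[j, i] <- v
    }
  } else {
    seqs <- vapply(collection, function(g)
      paste(asContigs(g), collapse = ""), character(1))
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      v <- 1 - hamming_mismatches(seqs[[i]], seqs[[j]]) / nchar(seqs[[i]])
      m[i, j] <- m[j, i] <- v
    }
  }
  new("ANIMatrix", ani = m, method = method)
}

#' Serialize sketches to / from TSV
#'
#' Columns: `genome_id`, `k`, `s`, `hashes` (comma-separated integers as
#' decimal strings).
#'
#' @param sketches list of [Sketch-class] objects.
#' @param path TSV file path.
#' @return `writeSketches()` the path invisibly; `readSketches()` a list
#'   of [Sketch-class] objects.
#' @export
writeSketches <- function(sketches, path) {
  df <- data.frame(
    genome_id = vapply(sketches, function(x) x@genomeId, character(1)),
    k = vapply(sketches, function(x) x@k, integer(1)),
    s = vapply(sketches, function(x) x@s, integer(1)),
    hashes = vapply(sketches, function(x)
      paste(format(x@hashes, scientific = FALSE, trim = TRUE),
            collapse = ","), character(1)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeSketches
#' @export
readSketches <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = c("character", "integer", "integer",
                                  "character"))
  lapply(seq_len(nrow(df)), function(i)
    new("Sketch", genomeId = df$genome_id[i], k = df$k[i], s = df$s[i],
        hashes = as.numeric(strsplit(df$hashes[i], ",", fixed = TRUE)[[1]])))
}
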