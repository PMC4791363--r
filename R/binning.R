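#' G+C content of nucleotide sequences
#'
#' Fraction (G + C) / (A + C + G + T); ambiguous bases are excluded from
#' both numerator and denominator.
#'
#' @param seq character vector of sequences, or a `DNAStringSet`/`DNAString`.
#' @return Numeric vector of G+C fractions.
#' @examples
#' gc_content(c("ATGC", "AAAA", "GGCC"))
#' @export
gc_content <- function(seq) {
  s <- Biostrings::DNAStringSet(toupper(.as_char_seq(seq)))
  if (any(Biostrings::width(s) == 0)) stop("sequences must be non-empty")
  f <- Biostrings::letterFrequency(s, letters = c("A", "C", "G", "T"))
  tot <- rowSums(f)
  if (any(tot == 0))
    stop("G+C content undefined: sequence has no unambiguous bases")
  unname((f[, "C"] + f[, "G"]) / tot)
}

#' @noRd
.canonical_kmers <- function(k) {
  words <- Biostrings::mkAllStrings(c("A", "C", "G", "T"), k)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(words)))
  canon <- pmin(words, rc)
  list(words = words, canon = canon, levels = sort(unique(canon)))
}

#' Canonical nucleotide word frequencies
#'
#' Sliding windows of width `k` (step 1) are counted; each word is pooled
#' with its reverse complement (the lexicographically smaller of the two is
#' the canonical representative) because the strand of an assembled contig
#' is arbitrary. Windows containing ambiguous bases are skipped. Counts are
#' normalized by the number of retained windows, so the entries sum to 1.
#'
#' @param seq one sequence (character or `DNAString`), or a character
#'   vector / `DNAStringSet` of several.
#' @param k word size (default 4, tetranucleotides — the standard choice
#'   for composition binning and small enough for 3 kbp contigs).
#' @return For one sequence, a named numeric vector over canonical k-mers;
#'   for several, a matrix with one row per sequence.
#' @examples
#' word_frequency("ATAT", k = 2)
#' @export
word_frequency <- function(seq, k = 4L) {
  nms <- names(seq)
  s <- Biostrings::DNAStringSet(toupper(.as_char_seq(seq)))
  names(s) <- nms
  if (k < 1) stop("k must be >= 1")
  if (any(Biostrings::width(s) < k)) stop("k exceeds a sequence length")
  km <- .canonical_kmers(k)
  counts <- Biostrings::oligonucleotideFrequency(s, width = k, step = 1)
  # pool reverse-complement columns into canonical classes
  pooled <- t(rowsum(t(counts), group = km$canon))
  pooled <- pooled[, km$levels, drop = FALSE]
  tot <- rowSums(pooled)
  if (any(tot == 0)) stop("no unambiguous windows of width k")
  freq <- pooled / tot
  rownames(freq) <- names(s) %||% NULL
  if (length(s) == 1) freq[1, ] else freq
}

#' PCA of contig word-frequency vectors
#'
#' Mean-centers the canonical word-frequency matrix of contigs surviving a
#' length filter and projects onto principal components (no scaling:
#' frequencies share a scale). Components are ordered by decreasing
#' explained variance. Contigs at or below `min_len` are excluded, matching
#' the "> 3 kbp" screen applied before population recovery.
#'
#' @param freqs word-frequency matrix (rows = contigs), e.g. from
#'   [word_frequency()].
#' @param lengths named (or positionally matched) contig lengths.
#' @param min_len length filter: contigs with `length <= min_len` are
#'   excluded (default 3000).
#' @param n_components number of components to return (default all).
#' @return List with `coords` (surviving contigs x components),
#'   `explained_variance` (fractions, all components), `excluded`
#'   (ids of filtered contigs).
#' @export
project_pca <- function(freqs, lengths, min_len = 3000, n_components = NULL) {
  stopifnot(is.matrix(freqs), nrow(freqs) == length(lengths))
  keep <- lengths > min_len
  if (sum(keep) < 2)
    stop("fewer than 2 contigs survive the length filter")
  p <- stats::prcomp(freqs[keep, , drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  nc <- min(n_components %||% ncol(p$x), ncol(p$x))
  list(coords = p$x[, seq_len(nc), drop = FALSE],
       explained_variance = ev,
       excluded = rownames(freqs)[!keep] %||% which(!keep))
}

#' Cluster contigs into population bins
#'
#' Seeded k-means in the concatenated feature space of standardized PC
#' coordinates, G+C content and log coverage — a reproducible stand-in for
#' the by-eye circling of word-frequency PCA plots. Contigs farther from
#' every cluster centre than a distance cutoff (a quantile of the
#' within-cluster distances) are labelled `ORPHAN`.
#'
#' @param coords PC coordinate matrix (rows = contigs, rownames = ids).
#' @param gc per-contig G+C fractions (same order as `coords`).
#' @param coverage per-contig fold coverage.
#' @param n_bins number of bins (clusters) to request.
#' @param seed integer seed for the k-means starts.
#' @param orphan_quantile quantile of within-cluster centre distances used
#'   as the orphan cutoff (default 0.975); `1` disables orphaning.
#' @param centers optional user-supplied seed points (matrix in feature
#'   space), overriding `n_bins` random starts.
#' @return A tibble (one row per contig): `contig_id`, `bin` (factor-like
#'   character, `"ORPHAN"` allowed), `gc`, `coverage`, and the PC
#'   coordinates.
#' @export
assign_bins <- function(coords, gc, coverage, n_bins, seed = 1L,
                        orphan_quantile = 0.975, centers = NULL) {
  stopifnot(nrow(coords) == length(gc), length(gc) == length(coverage))
  if (n_bins > nrow(coords)) stop("requested more bins than contigs")
  feats <- cbind(coords, gc = gc, logcov = log(pmax(coverage, 1e-6)))
  sds <- apply(feats, 2, stats::sd)
  sds[sds == 0] <- 1
  feats <- scale(feats, center = TRUE, scale = sds)
  km <- withr::with_seed(as.integer(seed), {
    if (is.null(centers)) stats::kmeans(feats, centers = n_bins, nstart = 10L)
    else stats::kmeans(feats, centers = centers)
  })
  d <- sqrt(rowSums((feats - km$centers[km$cluster, , drop = FALSE])^2))
  cutoff <- stats::quantile(d, orphan_quantile, names = FALSE)
  # relabel clusters by decreasing size for deterministic bin names
  sizes <- table(km$cluster)
  relabel <- stats::setNames(rank(-as.numeric(sizes), ties.method = "first"),
                             names(sizes))
  bin <- sprintf("bin%02d", relabel[as.character(km$cluster)])
  bin[d > cutoff] <- "ORPHAN"
  out <- tibble::tibble(
    contig_id = rownames(coords) %||% sprintf("contig%04d", seq_len(nrow(coords))),
    bin = unname(bin), gc = gc, coverage = coverage)
  cbind_coords <- as.data.frame(coords)
  out[colnames(cbind_coords)] <- cbind_coords
  out
}

#' Bin contigs by composition, G+C and coverage
#'
#' Convenience pipeline over [word_frequency()], [project_pca()] and
#' [assign_bins()]: the full composition-binning stage in one call.
#'
#' @param contigs tibble with `contig_id`, `sequence`, `coverage` columns
#'   (e.g. from [fragment_and_cover()] or [read_fasta_cov()]).
#' @param k word size (default 4).
#' @param min_len length filter (default 3000; contigs `<= min_len`
#'   excluded).
#' @param n_bins number of bins.
#' @param n_components PC coordinates used for clustering (default 3).
#' @param seed integer seed.
#' @param ... further arguments to [assign_bins()].
#' @return The [assign_bins()] tibble for surviving contigs.
#' @export
bin_contigs <- function(contigs, k = 4L, min_len = 3000, n_bins,
                        n_components = 3L, seed = 1L, ...) {
  freqs <- word_frequency(stats::setNames(contigs$sequence, contigs$contig_id),
                          k = k)
  if (is.null(dim(freqs))) freqs <- matrix(freqs, nrow = 1,
                                           dimnames = list(contigs$contig_id))
  lens <- nchar(contigs$sequence)
  pca <- project_pca(freqs, lens, min_len = min_len,
                     n_components = n_components)
  keep <- match(rownames(pca$coords), contigs$contig_id)
  assign_bins(pca$coords, gc_content(contigs$sequence[keep]),
              contigs$coverage[keep], n_bins = n_bins, seed = seed, ...)
}
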