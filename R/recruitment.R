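#' Recruit reads to bin references at an identity threshold
#'
#' Aligns every read (both strands) against each bin's reference sequences
#' with the seeded local aligner and assigns it to the best-scoring bin.
#' A read is left `ORPHAN` when its best identity does not *exceed*
#' `min_identity` (strict `>`, so a read at exactly the threshold is an
#' orphan), when less than `min_cov` of the read is alignable, or when two
#' bins tie for the best score (conservative, deterministic tie policy).
#'
#' @param reads named character vector or `DNAStringSet` of reads.
#' @param references named list: bin label -> character vector /
#'   `DNAStringSet` of reference sequences (contigs are concatenated with
#'   `N` spacers internally).
#' @param min_identity identity threshold, fraction (default 0.90).
#' @param min_cov minimum alignable fraction of the read (default 0.5;
#'   prevents short spurious seeds dominating).
#' @param match,mismatch,gap DNA scoring parameters.
#' @param k,band,max_occ seeding parameters, see [local_align()].
#' @return A tibble (one row per read): `read_id`, `bin` (or `"ORPHAN"`),
#'   `identity` (best observed, `NA` if no alignment at all), `aligned_len`.
#'   Empty read set gives an empty tibble.
#' @export
recruit_reads <- function(reads, references, min_identity = 0.90,
                          min_cov = 0.5, match = 1L, mismatch = -1L,
                          gap = -3L, k = 11L, band = 16L, max_occ = 64L) {
  if (length(references) == 0 || is.null(names(references)))
    stop("references must be a non-empty named list of per-bin sequences")
  rds <- .seqs_as_named_char(reads, "read")
  if (length(rds) == 0)
    return(tibble::tibble(read_id = character(), bin = character(),
                          identity = numeric(), aligned_len = integer()))
  S <- .dna_score_matrix(match, mismatch)
  bins <- names(references)
  n <- length(rds)
  rl <- nchar(rds)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(rds)))
  score <- idmat <- alen <- matrix(0, n, length(bins))
  for (bi in seq_along(bins)) {
    subj <- paste(toupper(.as_char_seq(references[[bi]])),
                  collapse = strrep("N", 50))
    h <- .align_many_cpp(unname(rds), subj, .DNA_ALPHABET, S, as.integer(gap),
                         as.integer(k), as.integer(band), 0,
                         as.integer(max_occ))
    id <- ifelse(h[, "columns"] > 0, h[, "matches"] / h[, "columns"], 0)
    cov <- (h[, "qend"] - h[, "qstart"]) / rl
    # reads whose forward hit fails the thresholds get a reverse-strand try
    retry <- which(id <= min_identity | cov < min_cov)
    sc <- h[, "score"]; cl <- h[, "columns"]
    if (length(retry) > 0) {
      hr <- .align_many_cpp(unname(rc[retry]), subj, .DNA_ALPHABET, S,
                            as.integer(gap), as.integer(k), as.integer(band),
                            0, as.integer(max_occ))
      better <- hr[, "score"] > sc[retry]
      idx <- retry[better]
      sc[idx] <- hr[better, "score"]
      cl[idx] <- hr[better, "columns"]
      id[idx] <- ifelse(hr[better, "columns"] > 0,
                        hr[better, "matches"] / hr[better, "columns"], 0)
      cov[idx] <- (hr[better, "qend"] - hr[better, "qstart"]) / rl[idx]
    }
    ok <- cov >= min_cov
    score[, bi] <- ifelse(ok, sc, 0)
    idmat[, bi] <- id
    alen[, bi] <- cl
  }
  best <- max.col(score, ties.method = "first")
  best_score <- score[cbind(seq_len(n), best)]
  tied <- rowSums(score == best_score & best_score > 0) > 1
  best_id <- idmat[cbind(seq_len(n), best)]
  best_al <- alen[cbind(seq_len(n), best)]
  bin <- bins[best]
  bin[tied | best_id <= min_identity | best_score == 0] <- "ORPHAN"
  tibble::tibble(read_id = names(rds), bin = bin,
                 identity = ifelse(best_score > 0 | best_al > 0,
                                   best_id, NA_real_),
                 aligned_len = as.integer(best_al))
}

#' Per-bin relative abundance of recruited reads
#'
#' @param assignments tibble from [recruit_reads()].
#' @return A tibble with `bin`, `n_reads`, `percent` (summing to 100,
#'   `ORPHAN` row last and always present).
#' @export
abundance_table <- function(assignments) {
  if (nrow(assignments) == 0)
    stop("abundance undefined for zero reads")
  tab <- table(assignments$bin)
  bins <- sort(setdiff(names(tab), "ORPHAN"))
  counts <- c(as.integer(tab[bins]), as.integer(tab["ORPHAN"]))
  counts[is.na(counts)] <- 0L
  tibble::tibble(bin = c(bins, "ORPHAN"), n_reads = counts,
                 percent = 100 * counts / sum(counts))
}

#' Per-bin G+C histograms of recruited reads
#'
#' Frequency table of read G+C content (%) per bin, plus an `ALL` series
#' covering every read, for G+C frequency plots of a recruited metagenome.
#'
#' @param reads named character vector or `DNAStringSet` of reads (ids must
#'   match `assignments$read_id`).
#' @param assignments tibble from [recruit_reads()].
#' @param bin_width histogram bin width in G+C percentage points
#'   (default 1).
#' @return A tibble with `bin`, `gc_lower`, `gc_upper` (percent, half-open
#'   intervals) and `count`. Counts per bin sum to the reads in that bin.
#' @export
gc_histogram <- function(reads, assignments, bin_width = 1) {
  if (bin_width <= 0) stop("bin_width must be positive")
  rds <- .seqs_as_named_char(reads, "read")
  gc <- gc_content(rds) * 100
  names(gc) <- names(rds)
  breaks <- seq(0, 100 + bin_width, by = bin_width)
  cut_idx <- stats::setNames(findInterval(gc, breaks,
                                          rightmost.closed = FALSE),
                             names(rds))
  series <- split(assignments$read_id, assignments$bin)
  series$ALL <- names(rds)
  out <- lapply(names(series), function(bn) {
    idx <- cut_idx[series[[bn]]]
    counts <- tabulate(idx, nbins = length(breaks) - 1L)
    tibble::tibble(bin = bn, gc_lower = breaks[-length(breaks)],
                   gc_upper = breaks[-1], count = counts)
  })
  do.call(rbind, out)
}
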